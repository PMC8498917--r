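# Tabular dialect: TSV, UTF-8, "NA" missing sentinel, "." decimal.

PEPTIDE_COLS <- c("protein_id", "peptide_seq", "intensity", "score",
                  "is_unique")

#' Read a peptide quantification table
#'
#' @param path TSV with header `protein_id peptide_seq intensity score
#'   is_unique` (extra columns are preserved).
#' @return Peptide tibble with typed columns; `is_unique` is logical.
#' @export
read_peptide_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(out, PEPTIDE_COLS, sprintf("peptide table '%s'", path))
  out$intensity <- as.numeric(out$intensity)
  out$score <- as.numeric(out$score)
  out$is_unique <- as.logical(out$is_unique)
  bad <- which(is.na(out$intensity) | out$intensity < 0)
  if (length(bad) > 0) {
    abort(sprintf("negative or missing intensity at data row(s): %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "modbindr_data_error")
  }
  out
}

#' @rdname read_peptide_table
#' @param peptides peptide tibble to write.
#' @export
write_peptide_table <- function(peptides, path) {
  assert_columns(peptides, PEPTIDE_COLS, "peptide table")
  readr::write_tsv(peptides[PEPTIDE_COLS], path, progress = FALSE)
  invisible(path)
}

# write one TSV per experiment plus the design table; returns the file paths
write_pulldown_tables <- function(peptides, design, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(design$experiment_id, function(e) {
    p <- file.path(dir, paste0(e, ".tsv"))
    write_peptide_table(peptides[peptides$experiment_id == e, ], p)
    p
  }, character(1))
  readr::write_tsv(as_tibble(design), file.path(dir, "design.tsv"),
                   progress = FALSE)
  invisible(paths)
}

#' Read an experiment design table
#'
#' @param path TSV with header `experiment_id context bait replicate`.
#' @return A `study_design` tibble.
#' @export
read_design <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(out, c("experiment_id", "context", "bait", "replicate"),
                 sprintf("design table '%s'", path))
  new_modbindr_tbl(out, "study_design",
                   contexts = unique(out$context),
                   baits = unique(out$bait))
}

#' Read protein sequences from FASTA
#'
#' The id is the first whitespace-delimited token of the header; duplicate
#' ids and empty records are errors.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "modbindr_data_error")
  }
  if (any(Biostrings::width(aa) == 0)) {
    abort("empty FASTA record", class = "modbindr_data_error")
  }
  setNames(as.character(aa), ids)
}

#' @rdname read_fasta
#' @param sequences named character vector to write.
#' @export
write_fasta <- function(sequences, path) {
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, path, width = 60)
  invisible(path)
}

#' Read/write the protein annotation table
#'
#' @param path TSV with header `protein_id class family dbds`.
#' @return Annotation tibble.
#' @export
read_annotations <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           family = readr::col_character(),
                           dbds = readr::col_character()))
  assert_columns(out, c("protein_id", "class", "family", "dbds"),
                 sprintf("annotation table '%s'", path))
  out$dbds[is.na(out$dbds)] <- ""
  out
}

#' @rdname read_annotations
#' @param annotations annotation tibble to write.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path, progress = FALSE)
  invisible(path)
}

#' Read/write an omic statistics table
#'
#' @param path TSV with header `gene_id contrast layer fold_change p_value
#'   direction`.  Fold changes are linear scale; a `log2_fold_change` column
#'   is converted on read.
#' @return Omic statistics tibble.
#' @export
read_omics <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("log2_fold_change" %in% names(out) &&
      !"fold_change" %in% names(out)) {
    out$fold_change <- 2^out$log2_fold_change
  }
  assert_columns(out, c("gene_id", "contrast", "layer", "fold_change",
                        "p_value", "direction"),
                 sprintf("omic table '%s'", path))
  out
}

#' Read a TF-to-target-gene edge table
#'
#' @param path TSV with header `tf_id tg_id`.
#' @return Edge tibble.
#' @export
read_edges <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(out, c("tf_id", "tg_id"), sprintf("edge table '%s'", path))
  out
}

#' Write/read a quantification matrix
#'
#' Wide TSV: proteins as rows, experiments as columns; imputed entries can be
#' written back as `NA` to preserve the pre-imputation matrix.
#'
#' @param quant long quantification tibble.
#' @param path output TSV.
#' @param value value column.
#' @param use_na_for_imputed write imputed entries as `NA`.
#' @export
write_quant_matrix <- function(quant, path, value = "fot",
                               use_na_for_imputed = FALSE) {
  m <- quant_matrix(quant, value = value,
                    use_na_for_imputed = use_na_for_imputed)
  df <- bind_cols(tibble(protein_id = rownames(m)), as_tibble(m))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_quant_matrix
#' @param design optional design tibble to re-attach context/bait/replicate.
#' @return `read_quant_matrix()` returns a long tibble (`protein_id`,
#'   `experiment_id`, value, `imputed` flag for `NA` cells left `NA`).
#' @export
read_quant_matrix <- function(path, value = "fot", design = NULL) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(wide, "protein_id", sprintf("matrix '%s'", path))
  long <- tidyr::pivot_longer(wide, -"protein_id",
                              names_to = "experiment_id",
                              values_to = value)
  if (!is.null(design)) {
    long <- left_join(long, as_tibble(design), by = "experiment_id")
  }
  long
}

#' Write/read planted ground truth as JSON
#'
#' @param truth a `binding_truth` object.
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  rm <- truth$reader_map
  payload <- list(
    base_activity = as.list(setNames(truth$base_activity$base_activity,
                                     truth$base_activity$protein_id)),
    reader_map = lapply(seq_len(nrow(rm)), function(i) {
      list(protein_id = rm$protein_id[i], bait = rm$bait[i],
           fold = rm$fold[i], contexts = rm$contexts[[i]])
    }),
    expressed_in = split(truth$expressed_in$context,
                         truth$expressed_in$protein_id))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  payload <- jsonlite::read_json(path)
  base <- tibble(protein_id = names(payload$base_activity),
                 base_activity = unlist(payload$base_activity,
                                        use.names = FALSE))
  rm <- bind_rows(lapply(payload$reader_map, function(r) {
    tibble(protein_id = r$protein_id, bait = r$bait, fold = r$fold,
           contexts = list(unlist(r$contexts)))
  }))
  if (nrow(rm) == 0) {
    rm <- tibble(protein_id = character(0), bait = character(0),
                 fold = numeric(0), contexts = list())
  }
  expressed <- bind_rows(lapply(names(payload$expressed_in), function(p) {
    tibble(protein_id = p,
           context = unlist(payload$expressed_in[[p]]))
  }))
  structure(list(base_activity = base, reader_map = rm,
                 expressed_in = expressed),
            class = "binding_truth")
}
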