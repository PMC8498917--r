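#' Protein identification filter
#'
#' A protein is retained in an experiment when it has at least `min_unique`
#' unique peptides and at least `min_confident` peptides with identification
#' score strictly above `score_threshold`.
#'
#' @param min_unique minimum number of unique peptides.
#' @param min_confident minimum number of high-confidence peptides.
#' @param score_threshold score a peptide must exceed to count as confident.
#' @return A list of class `identification_filter`.
#' @export
identification_filter <- function(min_unique = 1L, min_confident = 2L,
                                  score_threshold = 20) {
  assert_scalar_number(min_unique, "min_unique", lower = 0)
  assert_scalar_number(min_confident, "min_confident", lower = 0)
  assert_scalar_number(score_threshold, "score_threshold", lower = 0)
  structure(list(min_unique = as.integer(min_unique),
                 min_confident = as.integer(min_confident),
                 score_threshold = score_threshold),
            class = "identification_filter")
}

#' Apply the identification filter to a peptide table
#'
#' @param peptides a peptide tibble with columns `protein_id`, `peptide_seq`,
#'   `intensity`, `score`, `is_unique`, and optionally `experiment_id` (the
#'   filter is then applied within each experiment).
#' @param filter an [identification_filter()].
#' @return A tibble of retained (`experiment_id`,) `protein_id` combinations.
#' @export
filter_identifications <- function(peptides,
                                   filter = identification_filter()) {
  assert_columns(peptides, c("protein_id", "score", "is_unique"),
                 "peptide table")
  grp <- intersect("experiment_id", names(peptides))
  peptides |>
    group_by(across(all_of(c(grp, "protein_id")))) |>
    summarise(n_unique = sum(.data$is_unique),
              n_confident = sum(.data$score > filter$score_threshold),
              .groups = "drop") |>
    filter(.data$n_unique >= filter$min_unique,
           .data$n_confident >= filter$min_confident) |>
    select(all_of(c(grp, "protein_id")))
}

#' Intensity-based absolute quantification (iBAQ)
#'
#' iBAQ for a protein is the sum of its peptide intensities divided by its
#' number of theoretically observable tryptic peptides.
#'
#' @param peptides peptide tibble (columns `protein_id`, `intensity`, and
#'   optionally `experiment_id`); normally already restricted to proteins
#'   passing [filter_identifications()].
#' @param observable_counts named integer vector from [count_observable()].
#' @return Tibble with (`experiment_id`,) `protein_id`, `ibaq`.
#' @export
compute_ibaq <- function(peptides, observable_counts) {
  assert_columns(peptides, c("protein_id", "intensity"), "peptide table")
  grp <- intersect("experiment_id", names(peptides))
  out <- peptides |>
    group_by(across(all_of(c(grp, "protein_id")))) |>
    summarise(total_intensity = sum(.data$intensity), .groups = "drop")
  counts <- observable_counts[out$protein_id]
  bad <- out$protein_id[is.na(counts) | counts < 1]
  if (length(bad) > 0) {
    abort(sprintf(
      "protein(s) without observable peptides cannot be quantified: %s",
      paste(unique(bad), collapse = ", ")),
      class = "modbindr_quantification_error")
  }
  out$ibaq <- out$total_intensity / as.numeric(counts)
  select(out, all_of(c(grp, "protein_id")), "ibaq")
}

#' Fraction-of-total (FOT) normalization
#'
#' Each protein's iBAQ divided by the summed iBAQ of all proteins in the same
#' experiment, so every experiment column sums to one.
#'
#' @param ibaq tibble with `protein_id`, `ibaq`, optionally `experiment_id`.
#' @return The input with an added `fot` column.
#' @export
compute_fot <- function(ibaq) {
  assert_columns(ibaq, c("protein_id", "ibaq"), "iBAQ table")
  grp <- intersect("experiment_id", names(ibaq))
  out <- ibaq |>
    group_by(across(all_of(grp))) |>
    mutate(fot = .data$ibaq / sum(.data$ibaq)) |>
    ungroup()
  if (any(!is.finite(out$fot))) {
    abort("an experiment has zero total iBAQ; cannot normalize",
          class = "modbindr_quantification_error")
  }
  out
}

#' Impute missing quantification values
#'
#' Missing entries are replaced by one tenth of the global minimum of the
#' non-missing entries of the expression matrix.
#'
#' @param quant a long quantification tibble with a `fot` (or `value`) column
#'   that may contain `NA`.
#' @param value column name holding the values.
#' @return The input with `NA`s replaced and a logical `imputed` column.
#' @export
impute_missing <- function(quant, value = "fot") {
  assert_columns(quant, value, "quantification table")
  v <- quant[[value]]
  if (all(is.na(v))) {
    abort("cannot impute an entirely missing matrix",
          class = "modbindr_quantification_error")
  }
  fill <- min(v, na.rm = TRUE) / 10
  quant$imputed <- is.na(v)
  quant[[value]][quant$imputed] <- fill
  quant
}

#' z-score a numeric vector
#'
#' `z = (x - mu) / sigma` with the sample (n-1) standard deviation.  A
#' zero-variance vector yields all zeros with a warning, so constant profiles
#' survive downstream aggregation.
#'
#' @param x numeric vector, length >= 2.
#' @return Numeric vector of z-scores.
#' @export
zscore <- function(x) {
  if (length(x) < 2) {
    abort("zscore() needs at least two values", class = "modbindr_input_error")
  }
  s <- sd(x)
  if (is.na(s) || s == 0) {
    warn("zero variance; returning zeros")
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Peptide tables to an imputed FOT quantification table
#'
#' Runs the full label-free quantification chain per experiment:
#' identification filtering, iBAQ, FOT, then global minimum/10 imputation over
#' the protein-by-experiment grid.
#'
#' @param peptides long peptide tibble covering all experiments
#'   (`experiment_id`, `protein_id`, `peptide_seq`, `intensity`, `score`,
#'   `is_unique`).
#' @param design experiment design tibble (`experiment_id`, `context`,
#'   `bait`, `replicate`).
#' @param sequences named character vector of protein sequences (for the
#'   observable-peptide denominator).
#' @param digestion a [digestion_rules()] object.
#' @param id_filter an [identification_filter()] object.
#' @return A tibble of class `quant_tbl`: one row per protein x experiment
#'   with `fot` (imputed) and `imputed` flag, joined to the design columns.
#' @export
quantify_experiments <- function(peptides, design, sequences,
                                 digestion = digestion_rules(),
                                 id_filter = identification_filter()) {
  assert_columns(design, c("experiment_id", "context", "bait", "replicate"),
                 "design table")
  assert_columns(peptides,
                 c("experiment_id", "protein_id", "intensity", "score",
                   "is_unique"), "peptide table")
  counts <- count_observable(sequences, digestion)
  kept <- filter_identifications(peptides, id_filter)
  fot <- peptides |>
    semi_join(kept, by = c("experiment_id", "protein_id")) |>
    compute_ibaq(counts) |>
    compute_fot() |>
    select("experiment_id", "protein_id", "fot")
  grid <- tidyr::expand_grid(experiment_id = design$experiment_id,
                             protein_id = sort(unique(fot$protein_id)))
  out <- grid |>
    left_join(fot, by = c("experiment_id", "protein_id")) |>
    impute_missing("fot") |>
    left_join(design, by = "experiment_id") |>
    arrange(.data$experiment_id, .data$protein_id)
  new_modbindr_tbl(out, "quant_tbl", scale = "fot",
                   digestion = digestion, id_filter = id_filter)
}

#' Average replicates into one value per context and bait
#'
#' @param quant a `quant_tbl` (or any tibble with `protein_id`, `context`,
#'   `bait`, and the value column).
#' @param fun aggregator, `"mean"` (default) or `"median"`.
#' @param value value column name.
#' @return Tibble with `protein_id`, `context`, `bait`, `value`,
#'   `n_replicates`, `n_observed` (replicates where the protein was not
#'   imputed; 0 when no `imputed` column is present).
#' @export
aggregate_replicates <- function(quant, fun = c("mean", "median"),
                                 value = "fot") {
  fun <- match.arg(fun)
  assert_columns(quant, c("protein_id", "context", "bait", value),
                 "quantification table")
  f <- if (fun == "mean") mean else median
  has_imp <- "imputed" %in% names(quant)
  out <- quant |>
    group_by(.data$protein_id, .data$context, .data$bait) |>
    summarise(value = f(.data[[value]]),
              n_replicates = n(),
              n_observed = if (has_imp) sum(!.data$imputed) else 0L,
              .groups = "drop")
  if (any(out$n_replicates == 0)) {
    abort("a context x bait group has no experiments",
          class = "modbindr_input_error")
  }
  out
}

#' Dynamic range of a quantification table
#'
#' Orders of magnitude spanned by the values: `max(log10 v) - min(log10 v)`,
#' per experiment and overall.
#'
#' @param quant long quantification tibble with positive values.
#' @param value value column name.
#' @return Tibble (`experiment_id`, `orders`) with the overall span stored in
#'   attribute `"overall"`.
#' @export
dynamic_range <- function(quant, value = "fot") {
  assert_columns(quant, c("experiment_id", value), "quantification table")
  v <- quant[[value]]
  if (any(v <= 0 | is.na(v))) {
    abort("dynamic_range() requires positive values (impute first)",
          class = "modbindr_input_error")
  }
  out <- quant |>
    group_by(.data$experiment_id) |>
    summarise(orders = max(log10(.data[[value]])) -
                min(log10(.data[[value]])), .groups = "drop")
  attr(out, "overall") <- max(log10(v)) - min(log10(v))
  out
}

#' Pivot a long quantification table to a protein-by-experiment matrix
#'
#' @param quant long quantification tibble.
#' @param value value column name.
#' @param use_na_for_imputed if `TRUE`, imputed entries are written back as
#'   `NA` (the pre-imputation matrix).
#' @return Numeric matrix, proteins as rows, experiments as columns.
#' @export
quant_matrix <- function(quant, value = "fot", use_na_for_imputed = FALSE) {
  assert_columns(quant, c("experiment_id", "protein_id", value),
                 "quantification table")
  q <- quant
  if (use_na_for_imputed && "imputed" %in% names(q)) {
    q[[value]][q$imputed] <- NA_real_
  }
  wide <- q |>
    select("protein_id", "experiment_id", all_of(value)) |>
    tidyr::pivot_wider(names_from = "experiment_id",
                       values_from = all_of(value)) |>
    arrange(.data$protein_id)
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$protein_id
  m
}
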