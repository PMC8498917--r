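#' Study design for a pulldown screen
#'
#' One experiment per context x bait x replicate.  Contexts are cell lines
#' (e.g. HeLa, HepG2, A549, MCF-7) or developmental time points (E14.5,
#' E16.5, E17.5, P1, W6); baits are the four cytosine states.
#'
#' @param contexts character vector of distinct context labels.
#' @param baits the four modification labels, in module order.
#' @param n_replicates replicates per context x bait.
#' @return Tibble of class `study_design` with `experiment_id`, `context`,
#'   `bait`, `replicate`; contexts and baits keep their given order.
#' @examples
#' study_design(c("HeLa", "HepG2", "A549", "MCF-7"))
#' @export
study_design <- function(contexts,
                         baits = MOD_BAITS,
                         n_replicates = 3L) {
  if (length(contexts) == 0 || anyDuplicated(contexts)) {
    abort("contexts must be non-empty and distinct",
          class = "modbindr_parameter_error")
  }
  if (length(baits) != 4 || anyDuplicated(baits)) {
    abort("baits must be exactly 4 distinct labels",
          class = "modbindr_parameter_error")
  }
  assert_scalar_number(n_replicates, "n_replicates", lower = 1)
  out <- tidyr::expand_grid(context = contexts, bait = baits,
                            replicate = seq_len(n_replicates)) |>
    mutate(experiment_id = sprintf("%s_%s_r%d", .data$context, .data$bait,
                                   .data$replicate)) |>
    select("experiment_id", "context", "bait", "replicate")
  new_modbindr_tbl(out, "study_design",
                   contexts = contexts, baits = baits,
                   n_replicates = as.integer(n_replicates))
}

design_contexts <- function(design) {
  attr(design, "contexts") %||% unique(design$context)
}
design_baits <- function(design) {
  attr(design, "baits") %||% unique(design$bait)
}

#' Replicate noise model for the simulator
#'
#' @param lognormal_cv coefficient of variation of multiplicative log-normal
#'   replicate noise (0 disables noise).
#' @param dropout_rate probability that an emitted peptide is lost.
#' @param dynamic_range_orders orders of magnitude spanned by the base
#'   binding activities (the study-scale screens span about seven).
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(lognormal_cv = 0.2, dropout_rate = 0.1,
                        dynamic_range_orders = 7) {
  assert_scalar_number(lognormal_cv, "lognormal_cv", lower = 0)
  assert_scalar_number(dropout_rate, "dropout_rate", lower = 0, upper = 1)
  assert_scalar_number(dynamic_range_orders, "dynamic_range_orders",
                       lower = 0)
  structure(list(lognormal_cv = lognormal_cv, dropout_rate = dropout_rate,
                 dynamic_range_orders = dynamic_range_orders),
            class = "noise_model")
}

# random protein built from observable tryptic blocks: each block is 6-30
# residues, interior letters exclude K/R, never starts with P, and ends in
# K or R -- so digestion recovers the blocks exactly and all are observable
random_sequence <- function(target_len) {
  interior <- setdiff(AA20, c("K", "R"))
  first <- setdiff(interior, "P")
  blocks <- character(0)
  total <- 0L
  while (total < target_len) {
    len <- sample(6:30, 1)
    block <- paste0(
      sample(first, 1),
      paste(sample(interior, len - 2L, replace = TRUE), collapse = ""),
      sample(c("K", "R"), 1))
    blocks <- c(blocks, block)
    total <- total + len
  }
  paste(blocks, collapse = "")
}

#' Generate protein annotations and sequences
#'
#' Produces the annotation table (class TF / TC / DBP, family, DNA-binding
#' domains) and a random protein sequence per protein.  Sequences are 200-800
#' residues and guaranteed to yield at least three observable tryptic
#' peptides under the default digestion rules.  Families and domains are
#' assigned only to TFs; a TF may carry several domains.
#'
#' @param n_tf,n_tc,n_dbp number of transcription factors, coregulators and
#'   other DNA-binding proteins.
#' @param family_spec named integer vector: TF family -> member count.
#' @param dbd_spec named integer vector: DNA-binding domain -> member count.
#' @param seed integer seed; output is byte-identical for a fixed seed.
#' @return List with `annotations` (tibble: `protein_id`, `class`, `family`,
#'   `dbds` semicolon-separated) and `sequences` (named character vector).
#' @export
generate_annotations <- function(n_tf, n_tc = 0L, n_dbp = 0L,
                                 family_spec = NULL, dbd_spec = NULL,
                                 seed = 1L) {
  for (nm in c("n_tf", "n_tc", "n_dbp")) {
    assert_scalar_number(get(nm), nm, lower = 0)
  }
  if (sum(unlist(family_spec)) > n_tf || sum(unlist(dbd_spec)) > 0 &&
      max(unlist(dbd_spec) %||% 0) > n_tf) {
    abort("family/domain member counts exceed the TF pool",
          class = "modbindr_parameter_error")
  }
  with_seed_(seed, {
    ids <- c(sprintf("TF%04d", seq_len(n_tf)),
             sprintf("TC%04d", seq_len(n_tc)),
             sprintf("DBP%04d", seq_len(n_dbp)))
    cls <- rep(c("TF", "TC", "DBP"), c(n_tf, n_tc, n_dbp))
    family <- rep(NA_character_, length(ids))
    if (!is.null(family_spec) && n_tf > 0) {
      pool <- seq_len(n_tf)
      for (fam in names(family_spec)) {
        take <- sample(pool, family_spec[[fam]])
        family[take] <- fam
        pool <- setdiff(pool, take)
      }
    }
    dbds <- rep("", length(ids))
    if (!is.null(dbd_spec) && n_tf > 0) {
      for (dom in names(dbd_spec)) {
        take <- sample(seq_len(n_tf), dbd_spec[[dom]])
        dbds[take] <- ifelse(dbds[take] == "", dom,
                             paste(dbds[take], dom, sep = ";"))
      }
    }
    seqs <- vapply(seq_along(ids),
                   function(i) random_sequence(sample(200:800, 1)),
                   character(1))
    names(seqs) <- ids
    list(annotations = tibble(protein_id = ids, class = cls,
                              family = family, dbds = dbds),
         sequences = seqs)
  })
}

#' Plant binding ground truth for a synthetic screen
#'
#' Draws one base binding activity per protein, log-uniform over the
#' configured dynamic range (rescaled on the log scale so the realized span
#' is exact), and plants modification-specific "readers": disjoint sets of
#' TFs whose binding to one bait is boosted by a fold factor in the contexts
#' selected by the policy.
#'
#' @param annotations annotation tibble from [generate_annotations()].
#' @param design a [study_design()].
#' @param reader_spec tibble with columns `bait`, `n_readers`, `fold`,
#'   `policy`; policy is `"all"` (specific in every context, the consensus-
#'   reader pattern), `"one"` (a single random context, the context-exclusive
#'   pattern) or `"subset:k"`.  An optional `dbd` column restricts the
#'   sampled readers to TFs carrying that DNA-binding domain (e.g. planting
#'   a SCAN-domain preference for 5fC).
#' @param noise a [noise_model()] (supplies `dynamic_range_orders`).
#' @param seed integer seed.
#' @return List of class `binding_truth`: `base_activity` (tibble
#'   `protein_id`, `base_activity`), `reader_map` (tibble `protein_id`,
#'   `bait`, `fold`, `contexts` list-column), `expressed_in` (tibble
#'   `protein_id`, `context`).
#' @export
generate_truth <- function(annotations, design, reader_spec,
                           noise = noise_model(), seed = 1L) {
  assert_columns(annotations, c("protein_id", "class"), "annotation table")
  if (!is.null(reader_spec)) {
    assert_columns(reader_spec, c("bait", "n_readers", "fold", "policy"),
                   "reader spec")
    if (any(reader_spec$fold <= 1)) {
      abort("fold_enrichment must exceed 1",
            class = "modbindr_parameter_error")
    }
  }
  contexts <- design_contexts(design)
  tf_ids <- annotations$protein_id[annotations$class == "TF"]
  total_readers <- sum(reader_spec$n_readers %||% 0)
  if (total_readers > length(tf_ids)) {
    abort("reader demand exceeds the TF pool",
          class = "modbindr_parameter_error")
  }
  with_seed_(seed, {
    n <- nrow(annotations)
    lg <- runif(n, 0, noise$dynamic_range_orders)
    if (n >= 2 && max(lg) > min(lg) && noise$dynamic_range_orders > 0) {
      lg <- (lg - min(lg)) / (max(lg) - min(lg)) * noise$dynamic_range_orders
    }
    base <- tibble(protein_id = annotations$protein_id,
                   base_activity = 10^lg)
    pool <- tf_ids
    rm_rows <- list()
    if (!is.null(reader_spec)) {
      # satisfy domain-restricted rows first so unrestricted rows cannot
      # exhaust a small domain pool
      row_order <- seq_len(nrow(reader_spec))
      if ("dbd" %in% names(reader_spec)) {
        row_order <- order(is.na(reader_spec$dbd))
      }
      for (i in row_order) {
        k <- reader_spec$n_readers[i]
        if (k == 0) next
        sub_pool <- pool
        if ("dbd" %in% names(reader_spec) && !is.na(reader_spec$dbd[i])) {
          dbds <- annotations$dbds
          if (is.null(dbds)) dbds <- rep("", nrow(annotations))
          has_dom <- annotations$protein_id[
            vapply(strsplit(dbds, ";", fixed = TRUE),
                   function(d) reader_spec$dbd[i] %in% d, logical(1))]
          sub_pool <- intersect(pool, has_dom)
        }
        if (k > length(sub_pool)) {
          abort("reader demand exceeds the eligible TF pool",
                class = "modbindr_parameter_error")
        }
        picked <- if (length(sub_pool) == 1) sub_pool else sample(sub_pool, k)
        pool <- setdiff(pool, picked)
        policy <- reader_spec$policy[i]
        ctx <- lapply(picked, function(p) {
          if (policy == "all") {
            contexts
          } else if (policy == "one") {
            sample(contexts, 1)
          } else if (startsWith(policy, "subset:")) {
            kk <- as.integer(sub("subset:", "", policy))
            sample(contexts, kk)
          } else {
            abort(sprintf("unknown context policy '%s'", policy),
                  class = "modbindr_parameter_error")
          }
        })
        rm_rows[[i]] <- tibble(protein_id = picked,
                               bait = reader_spec$bait[i],
                               fold = reader_spec$fold[i],
                               contexts = ctx)
      }
    }
    reader_map <- if (length(rm_rows) > 0) bind_rows(rm_rows) else
      tibble(protein_id = character(0), bait = character(0),
             fold = numeric(0), contexts = list())
    expressed <- tidyr::expand_grid(protein_id = annotations$protein_id,
                                    context = contexts)
    structure(list(base_activity = base, reader_map = reader_map,
                   expressed_in = expressed),
              class = "binding_truth")
  })
}

#' Simulate pulldown peptide tables
#'
#' For every experiment in the design and every protein expressed in its
#' context, the protein's total pulled-down intensity (base activity, times
#' the planted fold if the protein reads that bait in that context) is split
#' equally across its observable tryptic peptides, perturbed by multiplicative
#' log-normal noise of the configured CV (unit mean), and peptides are dropped
#' independently at the dropout rate.  Each peptide carries an identification
#' score (uniform on \[10, 60\], with the first two peptides of every protein
#' forced confident so the identification filter is exercised but not
#' saturated) and a uniqueness flag (first peptide always unique, the rest
#' shared with probability `shared_fraction`).
#'
#' @param truth a `binding_truth` from [generate_truth()].
#' @param design a [study_design()].
#' @param sequences named character vector of protein sequences.
#' @param noise a [noise_model()].
#' @param digestion a [digestion_rules()].
#' @param seed integer seed.
#' @param shared_fraction probability a non-leading peptide is flagged shared.
#' @return Long peptide tibble: `experiment_id`, `protein_id`, `peptide_seq`,
#'   `intensity`, `score`, `is_unique`.  Proteins with no observable peptide
#'   are excluded with a warning.
#' @export
simulate_pulldown <- function(truth, design, sequences,
                              noise = noise_model(),
                              digestion = digestion_rules(),
                              seed = 1L, shared_fraction = 0.2) {
  stopifnot(inherits(truth, "binding_truth"))
  peplist <- observable_peptide_list(sequences, digestion)
  n_obs <- lengths(peplist)
  if (any(n_obs == 0)) {
    warn(sprintf("excluding %d protein(s) with no observable peptides",
                 sum(n_obs == 0)))
    peplist <- peplist[n_obs > 0]
    n_obs <- n_obs[n_obs > 0]
  }
  base <- setNames(truth$base_activity$base_activity,
                   truth$base_activity$protein_id)
  base <- base[names(base) %in% names(peplist)]

  # reader lookup keyed by protein|bait|context
  rm <- truth$reader_map
  fold_key <- character(0)
  fold_val <- numeric(0)
  if (nrow(rm) > 0) {
    expanded <- tidyr::unnest(rm, "contexts")
    fold_key <- paste(expanded$protein_id, expanded$bait, expanded$contexts,
                      sep = "|")
    fold_val <- expanded$fold
  }
  folds <- setNames(fold_val, fold_key)

  expressed <- split(truth$expressed_in$protein_id, truth$expressed_in$context)

  with_seed_(seed, {
    # peptide-level frame, fixed across experiments
    prot_ids <- names(peplist)
    pep_tbl <- tibble(
      protein_id = rep(prot_ids, times = n_obs[prot_ids]),
      peptide_seq = unlist(peplist, use.names = FALSE))
    pep_tbl <- pep_tbl |>
      group_by(.data$protein_id) |>
      mutate(pep_rank = row_number(), n_obs = n()) |>
      ungroup()
    pep_tbl$is_unique <- pep_tbl$pep_rank == 1L |
      runif(nrow(pep_tbl)) > shared_fraction

    per_exp <- lapply(seq_len(nrow(design)), function(i) {
      ctx <- design$context[i]
      bait <- design$bait[i]
      keep <- pep_tbl$protein_id %in% intersect(expressed[[ctx]], prot_ids)
      tb <- pep_tbl[keep, ]
      f <- folds[paste(tb$protein_id, bait, ctx, sep = "|")]
      f[is.na(f)] <- 1
      expected <- base[tb$protein_id] * f / tb$n_obs
      if (noise$lognormal_cv > 0) {
        sdlog <- sqrt(log1p(noise$lognormal_cv^2))
        fac <- rlnorm(nrow(tb), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else {
        fac <- rep(1, nrow(tb))
      }
      score <- runif(nrow(tb), 10, 60)
      confident <- tb$pep_rank <= 2L
      score[confident] <- runif(sum(confident), 25, 60)
      kept <- if (noise$dropout_rate > 0) {
        runif(nrow(tb)) >= noise$dropout_rate
      } else rep(TRUE, nrow(tb))
      tibble(experiment_id = design$experiment_id[i],
             protein_id = tb$protein_id,
             peptide_seq = tb$peptide_seq,
             intensity = unname(expected * fac),
             score = score,
             is_unique = tb$is_unique)[kept, ]
    })
    bind_rows(per_exp)
  })
}

#' Simulate a synthetic TF-to-target-gene regulatory map
#'
#' Stand-in for a curated TF-target database: each TF regulates a random set
#' of target genes.
#'
#' @param annotations annotation tibble; only TF-class proteins get edges.
#' @param n_genes size of the target-gene universe (`G0001`...).
#' @param edges_per_tf targets sampled per TF.
#' @param seed integer seed.
#' @return Tibble with `tf_id`, `tg_id`.
#' @export
generate_tf_tg_map <- function(annotations, n_genes = 200L,
                               edges_per_tf = 5L, seed = 1L) {
  tf_ids <- annotations$protein_id[annotations$class == "TF"]
  genes <- sprintf("G%04d", seq_len(n_genes))
  with_seed_(seed, {
    bind_rows(lapply(tf_ids, function(tf) {
      tibble(tf_id = tf, tg_id = sample(genes, min(edges_per_tf, n_genes)))
    }))
  })
}

#' Simulate per-gene multi-omic statistics
#'
#' Emits one row per gene x contrast x layer (methylome, hydroxymethylome,
#' transcriptome) with a fold change, p-value and direction.  Genes listed in
#' `effect_spec` for a layer/contrast are "responsive": their fold change is
#' the planted fold (times log-normal noise of sd `fc_noise_sd`; 0 disables
#' noise) and their p-value is drawn small (uniform on \[0, 0.01\]).  All
#' other gene/layer combinations get fold changes near 1 and uniform
#' p-values, so about 5% fall below 0.05 by chance.
#'
#' @param genes character vector of gene ids.
#' @param contrasts character vector of contrast labels (convention
#'   `"<time>-vs-<reference>"`; direction `"up"` means higher at `<time>`).
#' @param effect_spec tibble (`gene_id`, `contrast`, `layer`, `fold`,
#'   `direction`) of planted responsive genes, or `NULL` for a pure null.
#' @param fc_noise_sd sd of log-normal noise on fold changes.
#' @param seed integer seed.
#' @return Omic statistics tibble: `gene_id`, `contrast`, `layer`,
#'   `fold_change`, `p_value`, `direction`.
#' @export
simulate_multiomics <- function(genes, contrasts, effect_spec = NULL,
                                fc_noise_sd = 0.1, seed = 1L) {
  layers <- c("methylome", "hydroxymethylome", "transcriptome")
  if (!is.null(effect_spec) && nrow(effect_spec) > 0) {
    assert_columns(effect_spec,
                   c("gene_id", "contrast", "layer", "fold", "direction"),
                   "effect spec")
  }
  with_seed_(seed, {
    out <- tidyr::expand_grid(gene_id = genes, contrast = contrasts,
                              layer = layers)
    n <- nrow(out)
    out$fold_change <- if (fc_noise_sd > 0) {
      exp(rnorm(n, 0, fc_noise_sd))
    } else rep(1, n)
    out$p_value <- runif(n)
    out$direction <- sample(c("up", "down"), n, replace = TRUE)
    if (!is.null(effect_spec) && nrow(effect_spec) > 0) {
      key <- paste(out$gene_id, out$contrast, out$layer, sep = "|")
      ekey <- paste(effect_spec$gene_id, effect_spec$contrast,
                    effect_spec$layer, sep = "|")
      hit <- match(key, ekey)
      resp <- !is.na(hit)
      mult <- if (fc_noise_sd > 0) exp(rnorm(sum(resp), 0, fc_noise_sd)) else 1
      out$fold_change[resp] <- effect_spec$fold[hit[resp]] * mult
      out$p_value[resp] <- runif(sum(resp), 0, 0.01)
      out$direction[resp] <- effect_spec$direction[hit[resp]]
    }
    out
  })
}
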