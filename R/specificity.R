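#' Rule for calling DNA-modification-restricted binders
#'
#' A protein is restricted to ("reads") one modification in a context when its
#' binding activity on that bait is the strict maximum across the four baits
#' and is at least `fold_threshold` times a center statistic of the four
#' values.  The main-text rule centers on the geometric mean; a median
#' variant is also in circulation, so both are supported and recorded.
#'
#' @param fold_threshold fold over the center required for a call (> 1).
#' @param center `"geometric_mean"` (default) or `"median"`.
#' @param require_strict_max if `TRUE` (default) ties at the maximum yield no
#'   call; if `FALSE` ties are broken toward the earliest bait in module
#'   order.
#' @return A list of class `dmr_rule`.
#' @export
dmr_rule <- function(fold_threshold = 2,
                     center = c("geometric_mean", "median"),
                     require_strict_max = TRUE) {
  center <- match.arg(center)
  if (!is.numeric(fold_threshold) || fold_threshold <= 1) {
    abort("fold_threshold must exceed 1", class = "modbindr_parameter_error")
  }
  structure(list(fold_threshold = fold_threshold, center = center,
                 require_strict_max = isTRUE(require_strict_max)),
            class = "dmr_rule")
}

# evaluate the rule on one positive 4-vector; returns index (1-4) or NA,
# with the specificity ratio as an attribute
dmr_call_one <- function(values, rule = dmr_rule()) {
  if (rule$center == "geometric_mean" && any(values <= 0)) {
    abort("non-positive value with geometric-mean center; impute first",
          class = "modbindr_input_error")
  }
  ctr <- if (rule$center == "geometric_mean") geomean(values) else
    median(values)
  mx <- max(values)
  which_mx <- which(values == mx)
  if (rule$require_strict_max && length(which_mx) > 1) {
    return(structure(NA_integer_, ratio = NA_real_))
  }
  idx <- which_mx[1]
  ratio <- if (ctr > 0) mx / ctr else Inf
  if (ratio >= rule$fold_threshold) {
    structure(idx, ratio = ratio)
  } else {
    structure(NA_integer_, ratio = ratio)
  }
}

#' Call DNA-modification-restricted binders
#'
#' Applies the [dmr_rule()] to each protein's four aggregated (replicate-mean,
#' imputed) values per context.  Module indices follow bait order: 5C is
#' module 1, 5mC module 2, 5hmC module 3, 5fC module 4.
#'
#' @param profiles aggregated tibble (`protein_id`, `context`, `bait`,
#'   `value`), e.g. from [aggregate_replicates()].
#' @param rule a [dmr_rule()].
#' @param baits bait labels in module order.
#' @return Tibble of class `dmr_calls`: one row per protein x context with
#'   `called_bait` (`NA` when no call), `module`, `ratio` and `center` used.
#' @export
call_dmr <- function(profiles, rule = dmr_rule(), baits = MOD_BAITS) {
  assert_columns(profiles, c("protein_id", "context", "bait", "value"),
                 "profile table")
  wide <- profiles |>
    select("protein_id", "context", "bait", "value") |>
    tidyr::pivot_wider(names_from = "bait", values_from = "value")
  missing_baits <- setdiff(baits, names(wide))
  if (length(missing_baits) > 0) {
    abort(sprintf("profiles lack bait column(s): %s",
                  paste(missing_baits, collapse = ", ")),
          class = "modbindr_schema_error")
  }
  vals <- as.matrix(wide[baits])
  calls <- lapply(seq_len(nrow(vals)), function(i) {
    dmr_call_one(vals[i, ], rule)
  })
  idx <- vapply(calls, as.integer, integer(1))
  out <- tibble(protein_id = wide$protein_id,
                context = wide$context,
                called_bait = ifelse(is.na(idx), NA_character_, baits[idx]),
                module = idx,
                ratio = vapply(calls, function(x) attr(x, "ratio"),
                               numeric(1)),
                center = rule$center)
  new_modbindr_tbl(out, "dmr_calls", rule = rule, baits = baits)
}

#' Replicate-consensus variant of restricted-binding calling
#'
#' Instead of calling on replicate means, applies the rule within each
#' replicate and keeps a call only when the same bait is called in at least
#' `min_support` replicates of the context.  More conservative than
#' [call_dmr()] on aggregated profiles; useful when replicate noise is high.
#'
#' @param quant a `quant_tbl` (per-replicate imputed FOT).
#' @param rule a [dmr_rule()].
#' @param min_support replicates that must agree (default 2).
#' @param baits bait labels in module order.
#' @return A `dmr_calls` tibble (ratio is the median ratio over supporting
#'   replicates).
#' @export
call_dmr_consensus <- function(quant, rule = dmr_rule(), min_support = 2L,
                               baits = MOD_BAITS) {
  assert_columns(quant, c("protein_id", "context", "bait", "replicate",
                          "fot"), "quantification table")
  per_rep <- quant |>
    mutate(value = .data$fot) |>
    group_by(.data$replicate) |>
    group_modify(function(df, key) {
      as_tibble(call_dmr(df, rule = rule, baits = baits))
    }) |>
    ungroup()
  out <- per_rep |>
    filter(!is.na(.data$called_bait)) |>
    group_by(.data$protein_id, .data$context, .data$called_bait,
             .data$module) |>
    summarise(n_support = n(), ratio = median(.data$ratio),
              .groups = "drop") |>
    filter(.data$n_support >= min_support) |>
    mutate(center = rule$center) |>
    select("protein_id", "context", "called_bait", "module", "ratio",
           "center", "n_support")
  # re-complete the protein x context grid so the schema matches call_dmr
  grid <- distinct(quant, .data$protein_id, .data$context)
  out <- left_join(grid, out, by = c("protein_id", "context")) |>
    mutate(center = rule$center)
  new_modbindr_tbl(out, "dmr_calls", rule = rule, baits = baits,
                   min_support = min_support)
}

#' Identification breadth across replicates and contexts
#'
#' A protein is "identified in a context" when it passes the identification
#' filter in at least `min_replicates` of the context's experiments.
#'
#' @param peptides long peptide tibble with `experiment_id`.
#' @param design design tibble mapping experiments to contexts.
#' @param filter an [identification_filter()].
#' @param min_replicates replicates required per context (default 1).
#' @return Tibble (`protein_id`, `context`) of identifications, suitable for
#'   [edo_analysis()] and [overlap_counts()].
#' @export
identified_in_context <- function(peptides, design,
                                  filter = identification_filter(),
                                  min_replicates = 1L) {
  kept <- filter_identifications(peptides, filter)
  kept |>
    left_join(as_tibble(design)[c("experiment_id", "context")],
              by = "experiment_id") |>
    group_by(.data$protein_id, .data$context) |>
    summarise(n_replicates = n(), .groups = "drop") |>
    filter(.data$n_replicates >= min_replicates) |>
    select("protein_id", "context")
}

#' Nominate consensus readers across contexts
#'
#' A protein is nominated as a reader of a modification when it carries a
#' restricted-binding call for that bait in at least `n_required` contexts
#' (default: all of them — the cross-cell-line consensus criterion).
#'
#' @param calls a `dmr_calls` tibble from [call_dmr()].
#' @param contexts contexts considered; defaults to those present in `calls`.
#' @param n_required minimum supporting contexts.
#' @return Tibble (`protein_id`, `bait`, `n_contexts`, `contexts`
#'   comma-separated) of nominated readers.
#' @export
nominate_readers <- function(calls, contexts = NULL, n_required = NULL) {
  assert_columns(calls, c("protein_id", "context", "called_bait"),
                 "dmr call table")
  contexts <- contexts %||% unique(calls$context)
  n_required <- n_required %||% length(contexts)
  calls |>
    filter(!is.na(.data$called_bait), .data$context %in% contexts) |>
    group_by(.data$protein_id, bait = .data$called_bait) |>
    summarise(n_contexts = n(),
              contexts = paste(sort(unique(.data$context)), collapse = ","),
              .groups = "drop") |>
    filter(.data$n_contexts >= n_required) |>
    arrange(.data$bait, .data$protein_id)
}

#' Venn-style overlap counts for a collection of sets
#'
#' @param sets named list of character vectors.
#' @return List with `regions` (tibble: binary membership `pattern` over the
#'   set names, `count`) and `histogram` (tibble: `k` = number of sets an
#'   element belongs to, `count`, `percent` rounded half-up).
#' @export
overlap_counts <- function(sets) {
  if (length(sets) < 2) {
    abort("overlap_counts() needs at least two sets",
          class = "modbindr_input_error")
  }
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  universe <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL,
                                                              names(sets)))
  pattern <- apply(member, 1, function(r) paste(as.integer(r),
                                                collapse = ""))
  k <- rowSums(member)
  regions <- tibble(pattern = pattern) |>
    count(.data$pattern, name = "count") |>
    arrange(desc(.data$pattern))
  hist <- tibble(k = k) |>
    count(.data$k, name = "count") |>
    tidyr::complete(k = seq_len(length(sets)), fill = list(count = 0L)) |>
    mutate(percent = as.integer(floor(100 * .data$count /
                                        length(universe) + 0.5)))
  list(regions = regions, histogram = hist,
       n_union = length(universe), set_names = names(sets))
}

#' Coefficient of variation of binding activity
#'
#' CV (sample SD / mean) of each protein's values within a group: either
#' across contexts at a fixed bait, or across baits within a fixed context.
#' Proteins observed (not imputed) in fewer than two group members are
#' excluded, as are proteins with zero mean (with a warning).
#'
#' @param quant a `quant_tbl` or aggregated tibble with `protein_id`,
#'   `context`, `bait` and the value column.
#' @param grouping `"across_contexts_fixed_bait"` or
#'   `"across_baits_fixed_context"`.
#' @param value value column name.
#' @return List with `per_protein` (tibble `group`, `protein_id`, `cv`) and
#'   `medians` (tibble `group`, `median_cv`, `n_proteins`).
#' @export
compute_cv <- function(quant,
                       grouping = c("across_contexts_fixed_bait",
                                    "across_baits_fixed_context"),
                       value = "fot") {
  grouping <- match.arg(grouping)
  assert_columns(quant, c("protein_id", "context", "bait", value),
                 "quantification table")
  gcol <- if (grouping == "across_contexts_fixed_bait") "bait" else "context"
  q <- quant
  if ("imputed" %in% names(q)) q <- filter(q, !.data$imputed)
  per <- q |>
    group_by(group = .data[[gcol]], .data$protein_id) |>
    summarise(n_obs = n(), mean_v = mean(.data[[value]]),
              sd_v = sd(.data[[value]]), .groups = "drop") |>
    filter(.data$n_obs >= 2)
  if (any(per$mean_v == 0)) {
    warn(sprintf("excluding %d protein/group pair(s) with zero mean",
                 sum(per$mean_v == 0)))
    per <- filter(per, .data$mean_v != 0)
  }
  per <- per |>
    mutate(cv = .data$sd_v / .data$mean_v) |>
    select("group", "protein_id", "cv")
  med <- per |>
    group_by(.data$group) |>
    summarise(median_cv = median(.data$cv), n_proteins = n(),
              .groups = "drop")
  list(per_protein = per, medians = med)
}

#' Spearman correlation between experiments
#'
#' Pairwise-complete Spearman correlation (midranks for ties) between
#' experiment columns of the quantification matrix; pairs sharing fewer than
#' `min_shared` proteins are flagged `NA`.
#'
#' @param quant long quantification tibble.
#' @param value value column name.
#' @param min_shared minimum pairwise-complete proteins per pair.
#' @param use_na_for_imputed correlate only genuinely observed values.
#' @return Symmetric experiment-by-experiment correlation matrix with unit
#'   diagonal.
#' @export
correlation_matrix <- function(quant, value = "fot", min_shared = 3L,
                               use_na_for_imputed = TRUE) {
  m <- quant_matrix(quant, value = value,
                    use_na_for_imputed = use_na_for_imputed)
  cc <- suppressWarnings(cor(m, method = "spearman",
                             use = "pairwise.complete.obs"))
  shared <- crossprod(!is.na(m))
  cc[shared < min_shared] <- NA_real_
  diag(cc) <- 1
  cc
}

#' Principal-component ordination of experiments
#'
#' Column-centered SVD scores of the experiment profiles; a geometric
#' diagnostic of whether experiments group by context or by bait.
#'
#' @param quant long quantification tibble.
#' @param n_components number of components to return.
#' @param value value column name.
#' @return Tibble of class `modbind_ord`: `experiment_id`, design columns if
#'   present, `PC1`..; attribute `"variance"` holds component variances
#'   (non-increasing).
#' @export
ordinate <- function(quant, n_components = 2L, value = "fot") {
  m <- quant_matrix(quant, value = value)
  x <- t(m)  # experiments as observations
  if (nrow(x) < 2) {
    abort("ordinate() needs at least two experiments",
          class = "modbindr_input_error")
  }
  k_max <- min(nrow(x) - 1L, ncol(x))
  if (n_components > k_max) {
    warn(sprintf("truncating to %d component(s)", k_max))
    n_components <- k_max
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  scores <- as_tibble(pc$x[, seq_len(n_components), drop = FALSE])
  out <- bind_cols(tibble(experiment_id = rownames(x)), scores)
  des_cols <- intersect(c("context", "bait", "replicate"), names(quant))
  if (length(des_cols) > 0) {
    des <- distinct(quant, .data$experiment_id,
                    across(all_of(des_cols)))
    out <- left_join(out, des, by = "experiment_id")
  }
  new_modbindr_tbl(out, "modbind_ord",
                   variance = pc$sdev[seq_len(n_components)]^2)
}

#' Context-exclusive restricted-binding analysis
#'
#' Labels each protein by how many contexts carry a restricted-binding call
#' for it: exactly one context is the "exclusively determined in one context"
#' (EDO) pattern; more than one is shared; none is non-restricted.  The label
#' is cross-tabulated against identification breadth.
#'
#' @param calls a `dmr_calls` tibble.
#' @param identified tibble (`protein_id`, `context`) of identifications, or
#'   named list of per-context protein-id vectors.
#' @return List with `per_protein` (tibble `protein_id`, `n_dmr_contexts`,
#'   `n_identified_contexts`, `label`) and `crosstab` (label x identification
#'   breadth counts).
#' @export
edo_analysis <- function(calls, identified) {
  if (is.list(identified) && !is.data.frame(identified)) {
    identified <- bind_rows(lapply(names(identified), function(ctx) {
      tibble(protein_id = identified[[ctx]], context = ctx)
    }))
  }
  assert_columns(identified, c("protein_id", "context"),
                 "identification table")
  id_breadth <- identified |>
    distinct(.data$protein_id, .data$context) |>
    count(.data$protein_id, name = "n_identified_contexts")
  dmr_breadth <- calls |>
    filter(!is.na(.data$called_bait)) |>
    distinct(.data$protein_id, .data$context) |>
    count(.data$protein_id, name = "n_dmr_contexts")
  per <- id_breadth |>
    left_join(dmr_breadth, by = "protein_id") |>
    mutate(n_dmr_contexts = tidyr::replace_na(.data$n_dmr_contexts, 0L),
           label = case_when(.data$n_dmr_contexts == 1L ~ "EDO",
                             .data$n_dmr_contexts > 1L ~ "shared-dmr",
                             TRUE ~ "non-dmr"))
  crosstab <- per |>
    count(.data$label, .data$n_identified_contexts, name = "count") |>
    arrange(.data$label, .data$n_identified_contexts)
  list(per_protein = per, crosstab = crosstab)
}
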