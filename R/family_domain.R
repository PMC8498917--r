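#' Per-protein z-scores across the four baits within each context
#'
#' The cross-bait z-profile is what family/domain aggregation averages: it
#' removes abundance differences between proteins so that groups mix
#' comparably scaled members.
#'
#' @param profiles aggregated tibble (`protein_id`, `context`, `bait`,
#'   `value`) from [aggregate_replicates()].
#' @return The input with a `z` column (zero for constant profiles).
#' @export
member_zscores <- function(profiles) {
  assert_columns(profiles, c("protein_id", "context", "bait", "value"),
                 "profile table")
  pair <- paste(profiles$protein_id, profiles$context, sep = "\r")
  m <- stats::ave(profiles$value, pair)
  s <- stats::ave(profiles$value, pair, FUN = sd)
  z <- (profiles$value - m) / s
  z[!is.finite(z)] <- 0  # constant profiles get a flat z of zero
  mutate(ungroup(profiles), z = z)
}

# expand annotations to one row per (protein, group) at the requested level
group_membership <- function(annotations, level = c("family", "dbd")) {
  level <- match.arg(level)
  if (level == "family") {
    assert_columns(annotations, c("protein_id", "family"), "annotation table")
    annotations |>
      filter(!is.na(.data$family), .data$family != "") |>
      transmute(.data$protein_id, group = .data$family)
  } else {
    assert_columns(annotations, c("protein_id", "dbds"), "annotation table")
    annotations |>
      filter(!is.na(.data$dbds), .data$dbds != "") |>
      transmute(.data$protein_id, group = .data$dbds) |>
      tidyr::separate_rows("group", sep = ";")
  }
}

#' Aggregate binding activity to TF-family or domain level
#'
#' Group value per context x bait is the mean of member cross-bait z-scores;
#' a protein carrying several DNA-binding domains contributes to each of its
#' domain groups.  Groups below `min_members` are kept but flagged.
#'
#' @param profiles aggregated tibble (`protein_id`, `context`, `bait`,
#'   `value`).
#' @param annotations annotation tibble (`protein_id`, `family`, `dbds`).
#' @param level `"family"` or `"dbd"`.
#' @param min_members flag groups smaller than this.
#' @return Tibble of class `group_profiles`: `group`, `level`, `context`,
#'   `bait`, `mean_z`, `n_members`, `flagged`.  Unannotated proteins are
#'   skipped with a warning.
#' @export
aggregate_by_group <- function(profiles, annotations,
                               level = c("family", "dbd"),
                               min_members = 2L) {
  level <- match.arg(level)
  members <- group_membership(annotations, level)
  z <- member_zscores(profiles)
  n_unannot <- length(setdiff(unique(z$protein_id), members$protein_id))
  if (n_unannot > 0) {
    warn(sprintf("%d protein(s) without %s annotation skipped",
                 n_unannot, level))
  }
  joined <- inner_join(z, members, by = "protein_id",
                       relationship = "many-to-many")
  if (nrow(joined) == 0) {
    abort("no overlap between profiles and annotations",
          class = "modbindr_input_error")
  }
  out <- joined |>
    group_by(.data$group, .data$context, .data$bait) |>
    summarise(mean_z = mean(.data$z),
              n_members = n_distinct(.data$protein_id),
              .groups = "drop") |>
    mutate(level = level, flagged = .data$n_members < min_members) |>
    select("group", "level", "context", "bait", "mean_z", "n_members",
           "flagged")
  new_modbindr_tbl(out, "group_profiles", level = level,
                   member_z = joined)
}

# closed-form paired t on differences; fast path used both by the user-facing
# test and by calibration simulations
paired_t <- function(d) {
  n <- length(d)
  m <- mean(d)
  s <- sd(d)
  if (is.na(s) || s == 0) {
    return(list(t = NA_real_, p = NA_real_, n = n, mean_diff = m,
                degenerate = TRUE))
  }
  t <- m / (s / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1), n = n, mean_diff = m,
       degenerate = FALSE)
}

#' Paired test of a group's preference for one bait
#'
#' For each (member protein, context) pair, the difference between the
#' member's z-score on the candidate bait and the mean of its z-scores on the
#' other three baits is computed; a paired Student's t-test on these
#' differences (two-sided, n-1 df) asks whether the group binds the bait
#' preferentially.  Preference is asserted when p < `alpha` and the mean
#' difference is positive.  All-zero differences are reported as
#' no-preference; nonzero constant differences are degenerate (preference by
#' sign, p unavailable).
#'
#' @param member_z member-level z tibble (`protein_id`, `context`, `bait`,
#'   `z`), e.g. the `"member_z"` attribute of [aggregate_by_group()] output
#'   restricted to one group.
#' @param bait candidate bait label.
#' @param contexts contexts to use (default: all present).
#' @param alpha significance level.
#' @return One-row tibble: `bait`, `t`, `p`, `n_pairs`, `mean_diff`,
#'   `direction`, `preferred`.
#' @export
test_group_preference <- function(member_z, bait, contexts = NULL,
                                  alpha = 0.05) {
  assert_columns(member_z, c("protein_id", "context", "bait", "z"),
                 "member z table")
  contexts <- contexts %||% unique(member_z$context)
  mz <- member_z[member_z$context %in% contexts, ]
  # d_i per (member, context) pair: z on the candidate bait minus the mean z
  # on the remaining baits; rowsum keeps this fast enough for large
  # calibration simulations
  pair <- paste(mz$protein_id, mz$context, sep = "\r")
  on_bait <- mz$bait == bait
  tot <- rowsum(mz$z, pair)
  n_all <- rowsum(rep(1, nrow(mz)), pair)
  zb <- rowsum(mz$z * on_bait, pair)
  nb <- rowsum(as.numeric(on_bait), pair)
  ok <- nb[, 1] == 1 & n_all[, 1] > nb[, 1]
  d <- (zb[ok, 1] - (tot[ok, 1] - zb[ok, 1]) / (n_all[ok, 1] - 1))
  if (length(d) < 3) {
    abort("test_group_preference() needs at least 3 (member, context) pairs",
          class = "modbindr_input_error")
  }
  res <- paired_t(d)
  direction <- if (res$mean_diff > 0) "up" else
    if (res$mean_diff < 0) "down" else "none"
  preferred <- if (res$degenerate) {
    res$mean_diff > 0  # degenerate: preference by sign, p unavailable
  } else {
    !is.na(res$p) && res$p < alpha && res$mean_diff > 0
  }
  if (all(d == 0)) preferred <- FALSE
  tibble(bait = bait, t = res$t, p = res$p, n_pairs = res$n,
         mean_diff = res$mean_diff, direction = direction,
         preferred = preferred)
}

#' Test every group x bait preference
#'
#' Runs [test_group_preference()] for each group at the chosen level against
#' each bait.  Raw p-values are reported by default, mirroring the
#' p < 0.05 convention; Benjamini-Hochberg adjustment is available.
#'
#' @param profiles aggregated tibble (`protein_id`, `context`, `bait`,
#'   `value`).
#' @param annotations annotation tibble.
#' @param level `"family"` or `"dbd"`.
#' @param alpha significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param min_members skip groups with fewer members.
#' @return Tibble of class `preference_tests`: `group`, `level`, `bait`,
#'   `t`, `p`, `p_adj`, `n_pairs`, `mean_diff`, `direction`, `preferred`.
#' @export
test_preferences <- function(profiles, annotations,
                             level = c("family", "dbd"), alpha = 0.05,
                             adjust = c("none", "BH"), min_members = 2L) {
  level <- match.arg(level)
  adjust <- match.arg(adjust)
  members <- group_membership(annotations, level)
  z <- member_zscores(profiles) |>
    inner_join(members, by = "protein_id", relationship = "many-to-many")
  baits <- unique(z$bait)
  keep <- z |>
    group_by(.data$group) |>
    summarise(n_members = n_distinct(.data$protein_id), .groups = "drop") |>
    filter(.data$n_members >= min_members)
  res <- bind_rows(lapply(keep$group, function(g) {
    gz <- filter(z, .data$group == g)
    bind_rows(lapply(baits, function(b) {
      test_group_preference(gz, b, alpha = alpha) |>
        mutate(group = g, n_members = keep$n_members[keep$group == g])
    }))
  }))
  if (nrow(res) == 0) {
    return(new_modbindr_tbl(
      tibble(group = character(0), level = character(0), bait = character(0),
             t = numeric(0), p = numeric(0), p_adj = numeric(0),
             n_pairs = integer(0), mean_diff = numeric(0),
             direction = character(0), preferred = logical(0)),
      "preference_tests", level = level, alpha = alpha))
  }
  res$level <- level
  res$p_adj <- if (adjust == "BH") p.adjust(res$p, "BH") else res$p
  if (adjust == "BH") {
    res$preferred <- !is.na(res$p_adj) & res$p_adj < alpha &
      res$mean_diff > 0
  }
  out <- res |>
    select("group", "level", "bait", "t", "p", "p_adj", "n_pairs",
           "n_members", "mean_diff", "direction", "preferred") |>
    arrange(.data$group, .data$bait)
  new_modbindr_tbl(out, "preference_tests", level = level, alpha = alpha,
                   adjust = adjust)
}

#' Group-by-condition heatmap table and per-group best bait
#'
#' @param groups a `group_profiles` tibble from [aggregate_by_group()].
#' @return List with `matrix_table` (wide tibble, one column per
#'   context-bait) and `best_bait` (tibble `group`, `best_bait`; the argmax
#'   bait by mean z across contexts, `NA` on exact ties or all-zero
#'   profiles).
#' @export
preference_heatmap_table <- function(groups) {
  assert_columns(groups, c("group", "context", "bait", "mean_z"),
                 "group profile table")
  if (nrow(groups) == 0) {
    abort("empty group profile table", class = "modbindr_input_error")
  }
  wide <- groups |>
    mutate(cond = paste(.data$context, .data$bait, sep = ".")) |>
    select("group", "cond", "mean_z") |>
    tidyr::pivot_wider(names_from = "cond", values_from = "mean_z")
  best <- groups |>
    group_by(.data$group, .data$bait) |>
    summarise(mz = mean(.data$mean_z), .groups = "drop_last") |>
    summarise(best_bait = {
      mx <- max(.data$mz)
      cand <- .data$bait[.data$mz == mx]
      if (length(cand) != 1 || all(.data$mz == 0)) NA_character_ else cand
    }, .groups = "drop")
  list(matrix_table = wide, best_bait = best)
}
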