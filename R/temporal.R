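#' Assign proteins to temporal modules by peak time
#'
#' For each (protein, bait), the aggregated profile over the ordered time
#' points is z-scored and the protein is assigned to the module indexed by
#' its peak time point (module 1 = earliest, module 5 = latest in the
#' five-point brain-development design).  Ties go to the earliest time point
#' and are recorded; proteins whose peak z falls below `z_floor` stay
#' unassigned, so flat profiles do not join any module.
#'
#' @param profiles aggregated tibble (`protein_id`, `context`, `bait`,
#'   `value`) where `context` is a time point.
#' @param time_order time points in developmental order; defaults to the
#'   order of first appearance.
#' @param z_floor minimum peak z for assignment.
#' @param method `"peak"` (default) assigns by the z-profile's peak time
#'   point; `"kmeans"` clusters the z-profiles into one cluster per time
#'   point and labels each cluster by its centroid's peak — a smoother
#'   alternative when profiles are broad rather than single-peaked.
#' @param seed seed for the clustering initialization (kmeans only).
#' @return Tibble of class `temporal_assignments`: `protein_id`, `bait`,
#'   `module` (`NA` when unassigned), `peak_time`, `peak_z`, `tie`.
#' @export
assign_temporal_module <- function(profiles, time_order = NULL,
                                   z_floor = 0.5,
                                   method = c("peak", "kmeans"),
                                   seed = 1L) {
  method <- match.arg(method)
  assert_columns(profiles, c("protein_id", "context", "bait", "value"),
                 "profile table")
  time_order <- time_order %||% unique(profiles$context)
  unknown <- setdiff(unique(profiles$context), time_order)
  if (length(unknown) > 0) {
    abort(sprintf("time point(s) not in time_order: %s",
                  paste(unknown, collapse = ", ")),
          class = "modbindr_input_error")
  }
  out <- profiles |>
    mutate(t_idx = match(.data$context, time_order)) |>
    group_by(.data$protein_id, .data$bait) |>
    arrange(.data$t_idx, .by_group = TRUE) |>
    summarise({
      z <- suppressWarnings(zscore(.data$value))
      mx <- max(z)
      peak <- which(z == mx)[1]
      tibble(module = if (mx >= z_floor) peak else NA_integer_,
             peak_time = time_order[peak],
             peak_z = mx,
             tie = sum(z == mx) > 1)
    }, .groups = "drop")
  if (method == "kmeans") {
    assigned <- !is.na(out$module)
    if (sum(assigned) > length(time_order)) {
      zmat <- profiles |>
        mutate(t_idx = match(.data$context, time_order)) |>
        member_zscores_over_time(time_order)
      zmat <- zmat[paste(out$protein_id, out$bait)[assigned], ,
                   drop = FALSE]
      km <- with_seed_(seed,
                       stats::kmeans(zmat, centers = length(time_order),
                                     nstart = 5))
      # label each cluster by its centroid's peak time
      cluster_module <- apply(km$centers, 1, which.max)
      out$module[assigned] <- as.integer(cluster_module[km$cluster])
      out$peak_time[assigned] <- time_order[out$module[assigned]]
    }
  }
  new_modbindr_tbl(out, "temporal_assignments", time_order = time_order,
                   z_floor = z_floor, method = method)
}

# z-profile matrix (protein x bait rows, time points as columns)
member_zscores_over_time <- function(profiles, time_order) {
  z <- profiles |>
    group_by(.data$protein_id, .data$bait) |>
    mutate(z = suppressWarnings(zscore(.data$value))) |>
    ungroup()
  wide <- z |>
    select("protein_id", "bait", "context", "z") |>
    tidyr::pivot_wider(names_from = "context", values_from = "z")
  m <- as.matrix(wide[time_order])
  rownames(m) <- paste(wide$protein_id, wide$bait)
  m
}

#' Module-core TFs: proteins in the same temporal module for all four baits
#'
#' @param assignments a `temporal_assignments` tibble covering all baits.
#' @param module module index (1 = earliest time point).
#' @param baits baits that must agree; defaults to those present.
#' @return Character vector of protein ids (the intersection of the module's
#'   per-bait protein sets).
#' @export
module_core_tfs <- function(assignments, module, baits = NULL) {
  assert_columns(assignments, c("protein_id", "bait", "module"),
                 "assignment table")
  baits <- baits %||% unique(assignments$bait)
  sets <- lapply(baits, function(b) {
    assignments$protein_id[!is.na(assignments$module) &
                             assignments$module == module &
                             assignments$bait == b]
  })
  sort(Reduce(intersect, sets))
}

#' Over-represented proteins at one time point
#'
#' A protein is over-represented at a time point when its z-score across
#' time points (within the bait profile supplied) exceeds `z_threshold`
#' there and that time point is its row maximum; ties count only at the
#' earliest tied time point.
#'
#' @param profiles tibble (`protein_id`, `context`, `value`) for one bait,
#'   `context` being the time point.
#' @param time_point the queried time point.
#' @param time_order time points in order (for the tie rule).
#' @param z_threshold minimum z at the time point.
#' @return Character vector of protein ids.
#' @export
overrepresented_tfs <- function(profiles, time_point, time_order = NULL,
                                z_threshold = 1.0) {
  assert_columns(profiles, c("protein_id", "context", "value"),
                 "profile table")
  time_order <- time_order %||% unique(profiles$context)
  hits <- profiles |>
    mutate(t_idx = match(.data$context, time_order)) |>
    group_by(.data$protein_id) |>
    arrange(.data$t_idx, .by_group = TRUE) |>
    summarise({
      z <- suppressWarnings(zscore(.data$value))
      mx <- max(z)
      peak <- time_order[which(z == mx)[1]]
      tibble(hit = peak == time_point && mx > z_threshold)
    }, .groups = "drop") |>
    filter(.data$hit)
  sort(hits$protein_id)
}
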