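bait_layer_map <- c("5mC" = "methylome", "5hmC" = "hydroxymethylome")

#' Select the dominant TF-target-gene network for a bait and time point
#'
#' An edge (TF, target gene) survives when all three conditions hold:
#' 1. the TF carries a bait-specific, over-represented binding call at the
#'    time point (the `binding_calls` input);
#' 2. the target gene is upregulated at that time point in the transcriptome
#'    layer (p < `p_cut`, fold change > `fc_cut`, direction up);
#' 3. the target gene passes p < `p_cut` and fold change > `fc_cut` in the
#'    modification layer matching the bait (5mC -> methylome,
#'    5hmC -> hydroxymethylome), in either direction, since the modification
#'    signal is required to peak, not to move one way.
#'
#' @param binding_calls tibble (`protein_id`, `bait`, `time_point`) of
#'   bait-specific over-represented TFs.
#' @param tf_tg_map edge tibble (`tf_id`, `tg_id`).
#' @param omics omic statistics tibble (`gene_id`, `contrast`, `layer`,
#'   `fold_change`, `p_value`, `direction`).
#' @param bait `"5mC"` or `"5hmC"` (the other baits have no matching omic
#'   layer and raise an error).
#' @param time_point queried time point; rows whose `contrast` starts with
#'   `"<time_point>-vs-"` are used.
#' @param p_cut,fc_cut thresholds (defaults 0.05 and 2).
#' @return Tibble of class `tftg_network`: `tf_id`, `tg_id`, `bait`,
#'   `time_point` plus per-layer provenance columns (`rna_fc`, `rna_p`,
#'   `mod_fc`, `mod_p`).  Duplicated input edges are deduplicated.
#' @export
select_dominant_network <- function(binding_calls, tf_tg_map, omics,
                                    bait, time_point,
                                    p_cut = 0.05, fc_cut = 2) {
  if (!bait %in% names(bait_layer_map)) {
    abort(sprintf(
      "no omic layer matches bait '%s' (supported: %s)",
      bait, paste(names(bait_layer_map), collapse = ", ")),
      class = "modbindr_unsupported_layer_error")
  }
  assert_columns(binding_calls, c("protein_id", "bait", "time_point"),
                 "binding call table")
  assert_columns(tf_tg_map, c("tf_id", "tg_id"), "edge table")
  assert_columns(omics, c("gene_id", "contrast", "layer", "fold_change",
                          "p_value", "direction"), "omic table")
  mod_layer <- bait_layer_map[[bait]]
  tfs <- binding_calls |>
    filter(.data$bait == !!bait, .data$time_point == !!time_point) |>
    pull("protein_id")
  om <- filter(omics, startsWith(.data$contrast,
                                 paste0(time_point, "-vs-")))
  rna <- om |>
    filter(.data$layer == "transcriptome", .data$p_value < p_cut,
           .data$fold_change > fc_cut, .data$direction == "up") |>
    select(tg_id = "gene_id", rna_fc = "fold_change", rna_p = "p_value")
  mod <- om |>
    filter(.data$layer == mod_layer, .data$p_value < p_cut,
           .data$fold_change > fc_cut) |>
    select(tg_id = "gene_id", mod_fc = "fold_change", mod_p = "p_value")
  out <- tf_tg_map |>
    distinct(.data$tf_id, .data$tg_id) |>
    filter(.data$tf_id %in% tfs) |>
    inner_join(rna, by = "tg_id") |>
    inner_join(mod, by = "tg_id") |>
    mutate(bait = bait, time_point = time_point) |>
    arrange(.data$tf_id, .data$tg_id)
  new_modbindr_tbl(out, "tftg_network", bait = bait,
                   time_point = time_point, p_cut = p_cut, fc_cut = fc_cut)
}

#' Summarize a TF-target-gene network
#'
#' @param edges a `tftg_network` (or any tibble with `tf_id`, `tg_id`).
#' @return List: `n_edges`, `n_tfs`, `n_tgs`, `out_degree` (tibble `tf_id`,
#'   `degree`, ordered by id), `nodes` (tibble `id`, `role`).
#' @export
network_summary <- function(edges) {
  assert_columns(edges, c("tf_id", "tg_id"), "edge table")
  e <- distinct(as_tibble(edges), .data$tf_id, .data$tg_id) |>
    arrange(.data$tf_id, .data$tg_id)
  deg <- count(e, .data$tf_id, name = "degree") |> arrange(.data$tf_id)
  nodes <- bind_rows(tibble(id = sort(unique(e$tf_id)), role = "TF"),
                     tibble(id = sort(unique(e$tg_id)), role = "TG"))
  list(n_edges = nrow(e), n_tfs = n_distinct(e$tf_id),
       n_tgs = n_distinct(e$tg_id), out_degree = deg, nodes = nodes,
       edges = e)
}
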