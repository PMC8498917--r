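#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run.  The default configuration is
#' a desk-scale time-course screen: five developmental time points (E14.5,
#' E16.5, E17.5, P1, W6) x four baits x three replicates, 150 TFs / 60 TCs /
#' 90 DBPs, ten planted consensus readers each for 5mC and 5hmC and five for
#' 5fC at eightfold enrichment, replicate CV 0.2, dropout 0.1, seven orders
#' of dynamic range.
#'
#' @param out_dir output directory for stage artifacts.
#' @param seed single integer driving every random draw.
#' @param contexts,baits,n_replicates study design.
#' @param n_tf,n_tc,n_dbp synthetic proteome composition.
#' @param family_spec,dbd_spec family/domain membership counts.
#' @param reader_spec tibble (`bait`, `n_readers`, `fold`, `policy`).
#' @param noise a [noise_model()].
#' @param digestion a [digestion_rules()].
#' @param id_filter an [identification_filter()].
#' @param rule a [dmr_rule()].
#' @param n_genes,edges_per_tf synthetic TF-target-gene map size.
#' @param integrate_baits,integrate_time_points which dominant networks to
#'   build (must have matching omic layers).
#' @param p_cut,fc_cut integration thresholds.
#' @param z_threshold over-representation threshold for the temporal stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            contexts = c("E14.5", "E16.5", "E17.5", "P1",
                                         "W6"),
                            baits = MOD_BAITS,
                            n_replicates = 3L,
                            n_tf = 150L, n_tc = 60L, n_dbp = 90L,
                            family_spec = c(SCAN = 7L, RFX = 6L, POU = 8L),
                            dbd_spec = c(SCAN = 7L, C2H2_ZF = 20L,
                                         RFX = 6L),
                            reader_spec = tibble(
                              bait = c("5mC", "5hmC", "5fC"),
                              n_readers = c(10L, 10L, 5L),
                              fold = 8,
                              policy = "all"),
                            noise = noise_model(),
                            digestion = digestion_rules(),
                            id_filter = identification_filter(),
                            rule = dmr_rule(),
                            n_genes = 200L, edges_per_tf = 5L,
                            integrate_baits = c("5mC", "5hmC"),
                            integrate_time_points = NULL,
                            p_cut = 0.05, fc_cut = 2,
                            z_threshold = 1.0) {
  integrate_time_points <- integrate_time_points %||%
    c(contexts[1], contexts[length(contexts)])
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              contexts = contexts, baits = baits,
              n_replicates = as.integer(n_replicates),
              n_tf = as.integer(n_tf), n_tc = as.integer(n_tc),
              n_dbp = as.integer(n_dbp),
              family_spec = family_spec, dbd_spec = dbd_spec,
              reader_spec = reader_spec, noise = noise,
              digestion = digestion, id_filter = id_filter, rule = rule,
              n_genes = as.integer(n_genes),
              edges_per_tf = as.integer(edges_per_tf),
              integrate_baits = integrate_baits,
              integrate_time_points = integrate_time_points,
              p_cut = p_cut, fc_cut = fc_cut, z_threshold = z_threshold)
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline on a synthetic study
#'
#' Executes simulate -> quantify -> classify (restricted-binding calls,
#' readers) -> family/domain aggregation -> temporal modules -> multi-omic
#' integration, writing every stage artifact as TSV/JSON plus a run manifest
#' with parameter values and output checksums.  Reruns with the same
#' configuration are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list of in-memory stage results (annotations, truth,
#'   quant, calls, readers, preferences, temporal assignments, networks,
#'   manifest).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[modbindr] ", sprintf(...))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  design <- study_design(config$contexts, config$baits,
                         config$n_replicates)

  say("simulate: %d proteins, %d experiments",
      config$n_tf + config$n_tc + config$n_dbp, nrow(design))
  ann <- generate_annotations(config$n_tf, config$n_tc, config$n_dbp,
                              family_spec = config$family_spec,
                              dbd_spec = config$dbd_spec,
                              seed = child_seed(config$seed, 1))
  truth <- generate_truth(ann$annotations, design, config$reader_spec,
                          noise = config$noise,
                          seed = child_seed(config$seed, 2))
  peptides <- simulate_pulldown(truth, design, ann$sequences,
                                noise = config$noise,
                                digestion = config$digestion,
                                seed = child_seed(config$seed, 3))
  write_fasta(ann$sequences, file.path(out, "proteins.fasta"))
  write_annotations(ann$annotations, file.path(out, "annotations.tsv"))
  write_truth(truth, file.path(out, "truth.json"))
  write_pulldown_tables(peptides, design, file.path(out, "peptides"))

  say("quantify: iBAQ -> FOT -> impute")
  quant <- quantify_experiments(peptides, design, ann$sequences,
                                digestion = config$digestion,
                                id_filter = config$id_filter)
  write_quant_matrix(quant, file.path(out, "matrix_fot_raw.tsv"),
                     use_na_for_imputed = TRUE)
  write_quant_matrix(quant, file.path(out, "matrix_fot.tsv"))
  jsonlite::write_json(
    list(scale = "fot",
         digestion = unclass(config$digestion),
         id_filter = unclass(config$id_filter),
         imputation = "global_min_over_10"),
    file.path(out, "matrix_fot.json"), auto_unbox = TRUE, pretty = TRUE)

  say("classify: restricted-binding calls and readers")
  agg <- aggregate_replicates(quant)
  calls <- call_dmr(agg, rule = config$rule, baits = config$baits)
  readers <- nominate_readers(calls, contexts = config$contexts)
  readr::write_tsv(as_tibble(calls), file.path(out, "dmr_calls.tsv"),
                   progress = FALSE)
  readr::write_tsv(readers, file.path(out, "readers.tsv"), progress = FALSE)
  cormat <- correlation_matrix(quant)
  readr::write_tsv(bind_cols(tibble(experiment_id = rownames(cormat)),
                             as_tibble(cormat)),
                   file.path(out, "correlations.tsv"), progress = FALSE)
  cv <- compute_cv(quant, "across_baits_fixed_context")
  readr::write_tsv(cv$per_protein, file.path(out, "cv_per_protein.tsv"),
                   progress = FALSE)
  identified <- filter_identifications(peptides, config$id_filter) |>
    left_join(as_tibble(design), by = "experiment_id") |>
    distinct(.data$protein_id, .data$context)
  ov <- overlap_counts(split(identified$protein_id, identified$context))
  jsonlite::write_json(list(histogram = ov$histogram,
                            n_union = ov$n_union),
                       file.path(out, "overlaps.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  say("aggregate: family and domain preference")
  prefs <- test_preferences(agg, ann$annotations, level = "dbd")
  # partial domain annotation is the norm; the skip warning is expected here
  readr::write_tsv(as_tibble(prefs), file.path(out, "preferences_dbd.tsv"),
                   progress = FALSE)
  groups <- suppressWarnings(
    aggregate_by_group(agg, ann$annotations, level = "dbd"))
  readr::write_tsv(as_tibble(groups), file.path(out, "group_profiles.tsv"),
                   progress = FALSE)

  say("temporal: peak-time modules")
  assignments <- assign_temporal_module(agg, time_order = config$contexts)
  readr::write_tsv(as_tibble(assignments),
                   file.path(out, "temporal_modules.tsv"), progress = FALSE)
  cores <- bind_rows(lapply(seq_along(config$contexts), function(m) {
    tibble(module = m, protein_id = module_core_tfs(assignments, m))
  }))
  readr::write_tsv(cores, file.path(out, "module_core.tsv"),
                   progress = FALSE)

  say("integrate: dominant TF-target networks")
  tf_tg <- generate_tf_tg_map(ann$annotations, config$n_genes,
                              config$edges_per_tf,
                              seed = child_seed(config$seed, 4))
  readr::write_tsv(tf_tg, file.path(out, "tf_tg_map.tsv"), progress = FALSE)
  reference <- config$contexts[length(config$contexts)]
  contrasts <- paste0(config$integrate_time_points, "-vs-", reference)
  # plant responsiveness in the targets of the planted readers so the
  # retained networks have recoverable structure
  planted <- truth$reader_map |>
    filter(.data$bait %in% config$integrate_baits) |>
    inner_join(tf_tg, by = c(protein_id = "tf_id"))
  effect_spec <- if (nrow(planted) > 0) {
    tidyr::expand_grid(i = seq_len(nrow(planted)),
                       contrast = contrasts) |>
      mutate(gene_id = planted$tg_id[.data$i],
             layer_bait = planted$bait[.data$i]) |>
      transmute(.data$gene_id, .data$contrast,
                layer = bait_layer_map[.data$layer_bait],
                fold = 4, direction = "up") |>
      bind_rows(tidyr::expand_grid(i = seq_len(nrow(planted)),
                                   contrast = contrasts) |>
                  transmute(gene_id = planted$tg_id[.data$i],
                            .data$contrast, layer = "transcriptome",
                            fold = 4, direction = "up")) |>
      distinct()
  } else NULL
  omics <- simulate_multiomics(sprintf("G%04d", seq_len(config$n_genes)),
                               contrasts, effect_spec,
                               seed = child_seed(config$seed, 5))
  readr::write_tsv(omics, file.path(out, "omics.tsv"), progress = FALSE)
  binding_calls <- bind_rows(lapply(config$integrate_time_points,
                                    function(tp) {
    bind_rows(lapply(config$integrate_baits, function(b) {
      bait_agg <- filter(agg, .data$bait == b)
      hits <- overrepresented_tfs(bait_agg, tp,
                                  time_order = config$contexts,
                                  z_threshold = config$z_threshold)
      dmr_here <- calls |>
        filter(.data$context == tp, .data$called_bait == b) |>
        pull("protein_id")
      tibble(protein_id = intersect(hits, dmr_here),
             bait = b, time_point = tp)
    }))
  }))
  networks <- lapply(config$integrate_time_points, function(tp) {
    lapply(config$integrate_baits, function(b) {
      select_dominant_network(binding_calls, tf_tg, omics, b, tp,
                              p_cut = config$p_cut, fc_cut = config$fc_cut)
    })
  })
  net_tbl <- bind_rows(lapply(networks, bind_rows))
  readr::write_tsv(net_tbl, file.path(out, "dominant_networks.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    lapply(unlist(networks, recursive = FALSE), function(nw) {
      s <- network_summary(nw)
      list(bait = attr(nw, "bait"), time_point = attr(nw, "time_point"),
           n_edges = s$n_edges, n_tfs = s$n_tfs, n_tgs = s$n_tgs)
    }),
    file.path(out, "network_summary.json"), auto_unbox = TRUE,
    pretty = TRUE)

  files <- sort(setdiff(list.files(out, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    package = "modbindr",
    version = as.character(utils::packageVersion("modbindr")),
    seed = config$seed,
    parameters = list(contexts = config$contexts, baits = config$baits,
                      n_replicates = config$n_replicates,
                      n_tf = config$n_tf, n_tc = config$n_tc,
                      n_dbp = config$n_dbp,
                      noise = unclass(config$noise),
                      rule = unclass(config$rule),
                      p_cut = config$p_cut, fc_cut = config$fc_cut,
                      z_threshold = config$z_threshold),
    outputs = as.list(setNames(
      unname(tools::md5sum(file.path(out, files))), files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: %d artifacts in %s", length(files) + 1L, out)
  invisible(list(design = design, annotations = ann$annotations,
                 truth = truth, quant = quant, calls = calls,
                 readers = readers, preferences = prefs,
                 assignments = assignments, networks = net_tbl,
                 manifest = manifest))
}
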