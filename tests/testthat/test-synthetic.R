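test_that("study design validates its invariants", {
  d <- study_design(CELL_LINES)
  expect_equal(nrow(d), 4 * 4 * 3)
  expect_equal(anyDuplicated(d$experiment_id), 0L)
  expect_error(study_design(character(0)), class = "modbindr_parameter_error")
  expect_error(study_design("a", baits = c("x", "x", "y", "z")),
               class = "modbindr_parameter_error")
  expect_error(study_design("a", n_replicates = 0),
               class = "modbindr_parameter_error")
})

test_that("annotation generation is seeded, sized and family-aware", {
  empty <- generate_annotations(0, 0, 0, seed = 1)
  expect_equal(nrow(empty$annotations), 0L)
  expect_length(empty$sequences, 0L)

  a1 <- generate_annotations(5, seed = 1)
  a2 <- generate_annotations(5, seed = 1)
  expect_identical(a1, a2)

  a3 <- generate_annotations(100, family_spec = c(SCAN = 7L), seed = 7)
  expect_equal(sum(a3$annotations$family == "SCAN", na.rm = TRUE), 7L)

  # sequences are in-range and give at least 3 observable peptides
  lens <- nchar(a3$sequences)
  expect_true(all(lens >= 200 & lens <= 830))
  expect_true(all(count_observable(a3$sequences) >= 3))

  expect_error(generate_annotations(-1), class = "modbindr_parameter_error")
})

test_that("planted truth spans the dynamic range and keeps readers disjoint", {
  ann <- generate_annotations(100, seed = 3)
  design <- study_design(CELL_LINES)
  spec <- tibble::tibble(bait = c("5C", "5mC", "5hmC", "5fC"),
                         n_readers = 20L, fold = 8, policy = "all")
  tr <- generate_truth(ann$annotations, design, spec,
                       noise_model(dynamic_range_orders = 7), seed = 5)
  expect_equal(nrow(tr$reader_map), 80L)
  expect_equal(anyDuplicated(tr$reader_map$protein_id), 0L)
  ratio <- max(tr$base_activity$base_activity) /
    min(tr$base_activity$base_activity)
  expect_equal(log10(ratio), 7, tolerance = 0.01)

  none <- generate_truth(ann$annotations, design,
                         tibble::tibble(bait = "5mC", n_readers = 0L,
                                        fold = 8, policy = "all"),
                         seed = 5)
  expect_equal(nrow(none$reader_map), 0L)

  expect_error(generate_truth(ann$annotations, design,
                              tibble::tibble(bait = "5mC", n_readers = 999L,
                                             fold = 8, policy = "all")),
               class = "modbindr_parameter_error")
  expect_error(generate_truth(ann$annotations, design,
                              tibble::tibble(bait = "5mC", n_readers = 1L,
                                             fold = 1, policy = "all")),
               class = "modbindr_parameter_error")
})

test_that("context policies control where specificity is planted", {
  ann <- generate_annotations(30, seed = 2)
  design <- study_design(CELL_LINES)
  tr <- generate_truth(ann$annotations, design,
                       tibble::tibble(bait = c("5mC", "5fC"),
                                      n_readers = c(3L, 3L), fold = 4,
                                      policy = c("all", "one")), seed = 9)
  n_ctx <- lengths(tr$reader_map$contexts)
  expect_equal(n_ctx[tr$reader_map$bait == "5mC"], rep(4L, 3))
  expect_equal(n_ctx[tr$reader_map$bait == "5fC"], rep(1L, 3))

  tr2 <- generate_truth(ann$annotations, design,
                        tibble::tibble(bait = "5hmC", n_readers = 2L,
                                       fold = 4, policy = "subset:2"),
                        seed = 9)
  expect_equal(lengths(tr2$reader_map$contexts), rep(2L, 2))
})

test_that("noise-free pulldown reproduces planted intensities exactly", {
  scr <- tiny_screen(seed = 21, contexts = c("HeLa", "HepG2"),
                     n_replicates = 1, n_tf = 12, n_tc = 0, n_dbp = 0,
                     cv = 0, dropout = 0,
                     reader_spec = tibble::tibble(bait = "5fC",
                                                  n_readers = 3L, fold = 8,
                                                  policy = "all"))
  sums <- scr$peptides |>
    dplyr::group_by(experiment_id, protein_id) |>
    dplyr::summarise(total = sum(intensity), .groups = "drop")
  base <- setNames(scr$truth$base_activity$base_activity,
                   scr$truth$base_activity$protein_id)
  readers <- scr$truth$reader_map$protein_id
  non_reader <- setdiff(names(base), readers)[1]
  reader <- readers[1]
  for (e in unique(sums$experiment_id)) {
    s <- sums[sums$experiment_id == e, ]
    expect_equal(s$total[s$protein_id == non_reader],
                 unname(base[non_reader]))
    expected <- unname(base[reader]) * if (grepl("_5fC_", e)) 8 else 1
    expect_equal(s$total[s$protein_id == reader], expected)
  }
})

test_that("generators are byte-identical under a fixed seed", {
  s1 <- tiny_screen(seed = 33, contexts = c("HeLa", "HepG2"),
                    n_replicates = 2, n_tf = 10, n_tc = 2, n_dbp = 2,
                    cv = 0.2, dropout = 0.1)
  s2 <- tiny_screen(seed = 33, contexts = c("HeLa", "HepG2"),
                    n_replicates = 2, n_tf = 10, n_tc = 2, n_dbp = 2,
                    cv = 0.2, dropout = 0.1)
  expect_identical(s1$peptides, s2$peptides)
  expect_identical(s1$truth$reader_map, s2$truth$reader_map)
  om1 <- simulate_multiomics(sprintf("G%03d", 1:50), "E14.5-vs-W6",
                             seed = 4)
  om2 <- simulate_multiomics(sprintf("G%03d", 1:50), "E14.5-vs-W6",
                             seed = 4)
  expect_identical(om1, om2)
})

test_that("planted folds are realized in expectation across replicates", {
  ann <- generate_annotations(6, seed = 8)
  design <- study_design("HeLa", n_replicates = 100L)
  noise <- noise_model(lognormal_cv = 0.2, dropout_rate = 0,
                       dynamic_range_orders = 2)
  tr <- generate_truth(ann$annotations, design,
                       tibble::tibble(bait = "5mC", n_readers = 1L,
                                      fold = 8, policy = "all"),
                       noise, seed = 8)
  pep <- simulate_pulldown(tr, design, ann$sequences, noise, seed = 8)
  reader <- tr$reader_map$protein_id[1]
  sums <- pep |>
    dplyr::filter(protein_id == reader) |>
    dplyr::left_join(design, by = "experiment_id") |>
    dplyr::group_by(bait, replicate) |>
    dplyr::summarise(total = sum(intensity), .groups = "drop") |>
    dplyr::group_by(bait) |>
    dplyr::summarise(m = mean(total))
  realized <- sums$m[sums$bait == "5mC"] / mean(sums$m[sums$bait != "5mC"])
  expect_equal(realized, 8, tolerance = 0.05)
})

test_that("multi-omic simulation plants responsive genes and a clean null", {
  genes <- sprintf("G%05d", 1:10000)
  om <- simulate_multiomics(genes, "E14.5-vs-W6", effect_spec = NULL,
                            seed = 11)
  frac <- mean(om$p_value[om$layer == "transcriptome"] < 0.05)
  expect_equal(frac, 0.05, tolerance = 0.02)

  spec <- tibble::tibble(gene_id = "G00001", contrast = "E14.5-vs-W6",
                         layer = "transcriptome", fold = 4,
                         direction = "up")
  om2 <- simulate_multiomics("G00001", "E14.5-vs-W6", spec,
                             fc_noise_sd = 0, seed = 11)
  hit <- om2[om2$layer == "transcriptome", ]
  expect_equal(hit$fold_change, 4)
  expect_equal(hit$direction, "up")
  expect_lt(hit$p_value, 0.05)
  flat <- om2[om2$layer != "transcriptome", ]
  expect_equal(flat$fold_change, c(1, 1))
})

test_that("readers can be planted inside a specific DNA-binding domain", {
  ann <- generate_annotations(50, dbd_spec = c(SCAN = 7L, RFX = 5L),
                              seed = 12)
  design <- study_design(CELL_LINES)
  spec <- tibble::tibble(bait = "5fC", n_readers = 7L, fold = 8,
                         policy = "all", dbd = "SCAN")
  tr <- generate_truth(ann$annotations, design, spec, seed = 13)
  scan_tfs <- ann$annotations$protein_id[
    grepl("\\bSCAN\\b", ann$annotations$dbds)]
  expect_setequal(tr$reader_map$protein_id, scan_tfs)
  # demanding more readers than the domain holds is an error
  too_many <- dplyr::mutate(spec, n_readers = 8L)
  expect_error(generate_truth(ann$annotations, design, too_many,
                              seed = 13),
               class = "modbindr_parameter_error")
})
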