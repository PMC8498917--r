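test_that("the restricted-binding rule matches hand evaluation", {
  r <- modbindr:::dmr_call_one(c(1, 8, 1, 1))
  expect_equal(as.integer(r), 2L)           # 5mC, module 2
  expect_equal(attr(r, "ratio"), 8 / 8^0.25)

  expect_true(is.na(modbindr:::dmr_call_one(c(4, 4, 4, 4))))  # tie
  expect_true(is.na(modbindr:::dmr_call_one(c(2, 1, 1, 1))))  # 2 < 2*2^0.25

  # median center calls the (2,1,1,1) profile: 2 >= 2 * 1
  r_med <- modbindr:::dmr_call_one(c(2, 1, 1, 1),
                                   dmr_rule(center = "median"))
  expect_equal(as.integer(r_med), 1L)

  expect_error(modbindr:::dmr_call_one(c(0, 1, 1, 1)),
               class = "modbindr_input_error")
  expect_error(dmr_rule(fold_threshold = 1),
               class = "modbindr_parameter_error")
})

test_that("call_dmr agrees with the brute-force oracle on random profiles", {
  withr::with_seed(101, {
    n <- 2000
    vals <- matrix(10^stats::runif(4 * n, -4, 1), ncol = 4)
    # inject exact ties so the tie path is exercised
    vals[1:50, 2] <- vals[1:50, 3]
    for (ctr in c("geometric_mean", "median")) {
      rule <- dmr_rule(center = ctr)
      got <- vapply(seq_len(n), function(i) {
        as.integer(modbindr:::dmr_call_one(vals[i, ], rule))
      }, integer(1))
      want <- vapply(seq_len(n), function(i) {
        oracle_dmr(vals[i, ], center = ctr)
      }, integer(1))
      expect_identical(got, want)
    }
  })
})

test_that("calls are scale invariant and bounded by the max/center geometry", {
  withr::with_seed(55, {
    for (i in 1:200) {
      v <- 10^stats::runif(4, -3, 1)
      c_scale <- 10^stats::runif(1, -3, 3)
      for (ctr in c("geometric_mean", "median")) {
        rule <- dmr_rule(center = ctr)
        expect_identical(as.integer(modbindr:::dmr_call_one(v, rule)),
                         as.integer(modbindr:::dmr_call_one(v * c_scale,
                                                            rule)))
      }
      # a geometric-mean call implies a strictly dominant maximum
      r <- modbindr:::dmr_call_one(v)
      if (!is.na(r)) {
        expect_gte(attr(r, "ratio"), 2)
        srt <- sort(v, decreasing = TRUE)
        expect_gt(srt[1] / srt[2], 1)
      }
    }
  })
})

test_that("call_dmr maps profiles to modules on a tidy table", {
  m <- rbind(spec_mC = c(1, 8, 1, 1), tie = c(4, 4, 4, 4),
             weak = c(2, 1, 1, 1))
  colnames(m) <- c("5C", "5mC", "5hmC", "5fC")
  calls <- call_dmr(profiles_from_matrix(m))
  expect_s3_class(calls, "dmr_calls")
  expect_equal(calls$called_bait[calls$protein_id == "spec_mC"], "5mC")
  expect_equal(calls$module[calls$protein_id == "spec_mC"], 2L)
  expect_true(is.na(calls$called_bait[calls$protein_id == "tie"]))
  expect_true(is.na(calls$called_bait[calls$protein_id == "weak"]))
  g <- generics::glance(calls)
  expect_equal(g$n_calls, 1L)
  expect_equal(g$n_module2, 1L)
})

test_that("reader nomination requires support in all contexts by default", {
  calls <- tibble::tibble(
    protein_id = c(rep("all4", 4), rep("only3", 3), "other"),
    context = c(CELL_LINES, CELL_LINES[1:3], CELL_LINES[1]),
    called_bait = c(rep("5fC", 7), NA))
  noms <- nominate_readers(calls, contexts = CELL_LINES)
  expect_equal(noms$protein_id, "all4")
  expect_equal(noms$n_contexts, 4L)
  relaxed <- nominate_readers(calls, contexts = CELL_LINES, n_required = 3)
  expect_setequal(relaxed$protein_id, c("all4", "only3"))
  empty <- nominate_readers(calls[0, ], contexts = CELL_LINES)
  expect_equal(nrow(empty), 0L)
})

test_that("overlap counts enumerate every membership region", {
  ov <- overlap_counts(list(x = c("A", "B"), y = c("B", "C")))
  expect_equal(ov$n_union, 3L)
  expect_equal(ov$regions$count[ov$regions$pattern == "11"], 1L)
  expect_equal(sum(ov$regions$count), 3L)
  expect_equal(ov$histogram$count, c(2L, 1L))

  same <- overlap_counts(list(a = letters[1:5], b = letters[1:5]))
  expect_equal(same$histogram$count[same$histogram$k == 2], 5L)
  expect_equal(same$histogram$count[same$histogram$k == 1], 0L)

  # region counts sum to the union for random 4-set collections
  withr::with_seed(77, {
    sets <- lapply(1:4, function(i) sample(sprintf("P%03d", 1:150), 100))
    names(sets) <- paste0("s", 1:4)
    ov4 <- overlap_counts(sets)
    expect_equal(sum(ov4$regions$count), ov4$n_union)
    # brute-force histogram
    u <- unique(unlist(sets))
    k <- sapply(u, function(e) sum(sapply(sets, function(s) e %in% s)))
    expect_equal(ov4$histogram$count,
                 as.integer(table(factor(k, levels = 1:4))))
  })
})

test_that("CV is sample SD over mean within the chosen grouping", {
  q <- tibble::tibble(
    protein_id = rep(c("flat", "vary"), each = 2),
    context = rep(c("c1", "c2"), 2), bait = "5mC",
    replicate = 1L,
    fot = c(1, 1, 2, 4), imputed = FALSE)
  cv <- compute_cv(q, "across_contexts_fixed_bait")
  expect_equal(cv$per_protein$cv[cv$per_protein$protein_id == "flat"], 0)
  expect_equal(cv$per_protein$cv[cv$per_protein$protein_id == "vary"],
               sqrt(2) / 3)
  expect_equal(cv$medians$median_cv, median(c(0, sqrt(2) / 3)))

  # proteins observed once (others imputed) are excluded
  q2 <- q
  q2$imputed <- c(FALSE, TRUE, FALSE, FALSE)
  cv2 <- compute_cv(q2, "across_contexts_fixed_bait")
  expect_false("flat" %in% cv2$per_protein$protein_id)
})

test_that("Spearman correlations agree with a rank-then-Pearson oracle", {
  withr::with_seed(13, {
    n <- 30
    q <- tidyr::expand_grid(protein_id = sprintf("p%02d", 1:n),
                            experiment_id = c("e1", "e2", "e3"))
    q$fot <- c(stats::rlnorm(n), stats::rlnorm(n),
               sample(rep(1:10, 3)))   # e3 has heavy ties
    cc <- correlation_matrix(q, use_na_for_imputed = FALSE)
    m <- quant_matrix(q)
    for (i in 1:3) for (j in 1:3) {
      oracle <- stats::cor(rank(m[, i]), rank(m[, j]))
      expect_equal(cc[i, j], oracle, tolerance = 1e-12)
    }
    expect_equal(diag(cc), setNames(rep(1, 3), colnames(cc)))
  })
  # perfect anti-correlation and the shared-protein floor
  q2 <- tibble::tibble(protein_id = rep(c("a", "b", "c"), 2),
                       experiment_id = rep(c("e1", "e2"), each = 3),
                       fot = c(1, 2, 3, 3, 2, 1))
  cc2 <- correlation_matrix(q2, min_shared = 3)
  expect_equal(cc2["e1", "e2"], -1)
  cc3 <- correlation_matrix(q2, min_shared = 4)
  expect_true(is.na(cc3["e1", "e2"]))
})

test_that("ordination preserves variance and orders components", {
  # right triangle in protein space
  q <- tibble::tibble(protein_id = rep(c("p1", "p2"), each = 3),
                      experiment_id = rep(c("e1", "e2", "e3"), 2),
                      fot = c(0, 1, 0, 0, 0, 1))
  ord <- ordinate(q, 2)
  v <- attr(ord, "variance")
  expect_true(all(diff(v) <= 1e-12))
  x <- t(quant_matrix(q))
  total_var <- sum(apply(x, 2, stats::var))
  expect_equal(sum(v), total_var, tolerance = 1e-12)

  # collinear points collapse onto one axis
  q_lin <- tibble::tibble(protein_id = rep(c("p1", "p2"), each = 3),
                          experiment_id = rep(c("e1", "e2", "e3"), 2),
                          fot = c(1, 2, 3, 2, 4, 6))
  expect_lt(attr(ordinate(q_lin, 2), "variance")[2], 1e-20)
  expect_warning(ordinate(q_lin, 5), "truncating")
})

test_that("context-exclusive labeling cross-tabulates against identification breadth", {
  calls <- tibble::tibble(
    protein_id = c("edo", "shared", "shared", "shared"),
    context = c("HeLa", "HeLa", "HepG2", "A549"),
    called_bait = "5mC")
  identified <- tidyr::expand_grid(protein_id = c("edo", "shared", "none"),
                                   context = CELL_LINES)
  res <- edo_analysis(calls, identified)
  pp <- res$per_protein
  expect_equal(pp$label[pp$protein_id == "edo"], "EDO")
  expect_equal(pp$n_identified_contexts[pp$protein_id == "edo"], 4L)
  expect_equal(pp$label[pp$protein_id == "shared"], "shared-dmr")
  expect_equal(pp$label[pp$protein_id == "none"], "non-dmr")
  expect_equal(sum(res$crosstab$count), 3L)
})

test_that("replicate-consensus calling requires agreement across replicates", {
  scr <- tiny_screen(seed = 91, contexts = c("HeLa", "HepG2"),
                     n_replicates = 3, n_tf = 40, n_tc = 0, n_dbp = 0,
                     cv = 0, dropout = 0,
                     reader_spec = tibble::tibble(
                       bait = c("5C", "5mC", "5hmC", "5fC"),
                       n_readers = 2L, fold = 8, policy = "all"))
  cons <- call_dmr_consensus(scr$quant, min_support = 2)
  mean_calls <- call_dmr(scr$agg)
  # noise-free: both routes find exactly the planted readers
  readers <- sort(scr$truth$reader_map$protein_id)
  for (ctx in c("HeLa", "HepG2")) {
    expect_setequal(cons$protein_id[!is.na(cons$called_bait) &
                                      cons$context == ctx], readers)
  }
  expect_setequal(
    paste(cons$protein_id, cons$context)[!is.na(cons$called_bait)],
    paste(mean_calls$protein_id,
          mean_calls$context)[!is.na(mean_calls$called_bait)])
  expect_true(all(cons$n_support[!is.na(cons$called_bait)] == 3))
})

test_that("identification breadth honors the minimum replicate requirement", {
  scr <- tiny_screen(seed = 93, contexts = c("HeLa", "HepG2"),
                     n_replicates = 2, n_tf = 15, n_tc = 0, n_dbp = 0,
                     cv = 0.3, dropout = 0.4)
  id1 <- identified_in_context(scr$peptides, scr$design,
                               min_replicates = 1)
  id2 <- identified_in_context(scr$peptides, scr$design,
                               min_replicates = 8)
  expect_true(nrow(id2) <= nrow(id1))
  # with min 1, matches the union over experiments
  kept <- filter_identifications(scr$peptides) |>
    dplyr::left_join(tibble::as_tibble(scr$design), by = "experiment_id") |>
    dplyr::distinct(protein_id, context)
  expect_equal(nrow(id1), nrow(kept))
})
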