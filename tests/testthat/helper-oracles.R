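# Independent brute-force oracles, kept deliberately separate from the
# package's implementations.

# position-by-position cleavage scan
oracle_digest <- function(seq, cleave = c("K", "R"), suppress = "P") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  peps <- character(0)
  cur <- ""
  for (i in seq_along(chars)) {
    cur <- paste0(cur, chars[i])
    nxt <- if (i < length(chars)) chars[i + 1] else NA_character_
    if (chars[i] %in% cleave && (is.na(nxt) || !(nxt %in% suppress))) {
      peps <- c(peps, cur)
      cur <- ""
    }
  }
  if (nzchar(cur)) peps <- c(peps, cur)
  peps
}

# direct evaluation of the restricted-binding rule on one 4-vector
oracle_dmr <- function(v, fold = 2, center = "geometric_mean",
                       strict = TRUE) {
  ctr <- if (center == "geometric_mean") prod(v)^(1 / length(v)) else
    median(v)
  mx <- max(v)
  idx <- which(v == mx)
  if (strict && length(idx) > 1) return(NA_integer_)
  if (mx >= fold * ctr) idx[1] else NA_integer_
}

# brute-force three-condition network filter by explicit loops
oracle_network <- function(binding_calls, edges, omics, bait, time_point,
                           p_cut = 0.05, fc_cut = 2) {
  layer <- c("5mC" = "methylome", "5hmC" = "hydroxymethylome")[[bait]]
  tfs <- binding_calls$protein_id[binding_calls$bait == bait &
                                    binding_calls$time_point == time_point]
  kept <- character(0)
  edges <- unique(edges[c("tf_id", "tg_id")])
  for (i in seq_len(nrow(edges))) {
    tf <- edges$tf_id[i]; tg <- edges$tg_id[i]
    if (!tf %in% tfs) next
    om <- omics[startsWith(omics$contrast, paste0(time_point, "-vs-")) &
                  omics$gene_id == tg, ]
    rna <- om[om$layer == "transcriptome", ]
    ok_rna <- nrow(rna) > 0 && any(rna$p_value < p_cut &
                                     rna$fold_change > fc_cut &
                                     rna$direction == "up")
    mod <- om[om$layer == layer, ]
    ok_mod <- nrow(mod) > 0 && any(mod$p_value < p_cut &
                                     mod$fold_change > fc_cut)
    if (ok_rna && ok_mod) kept <- c(kept, paste(tf, tg, sep = "->"))
  }
  sort(kept)
}

random_aa_seq <- function(len) {
  paste(sample(modbindr:::AA20, len, replace = TRUE), collapse = "")
}
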