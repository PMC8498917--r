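# Programmatic fixtures: small synthetic screens built in code.

CELL_LINES <- c("HeLa", "HepG2", "A549", "MCF-7")
TIME_POINTS <- c("E14.5", "E16.5", "E17.5", "P1", "W6")

# a small end-to-end screen with planted consensus readers
tiny_screen <- function(seed = 42, contexts = CELL_LINES,
                        n_replicates = 3L, n_tf = 40L, n_tc = 10L,
                        n_dbp = 10L, cv = 0, dropout = 0, orders = 4,
                        reader_spec = tibble::tibble(
                          bait = c("5mC", "5fC"),
                          n_readers = c(4L, 4L), fold = 8, policy = "all")) {
  ann <- generate_annotations(n_tf, n_tc, n_dbp, seed = seed)
  design <- study_design(contexts, n_replicates = n_replicates)
  noise <- noise_model(lognormal_cv = cv, dropout_rate = dropout,
                       dynamic_range_orders = orders)
  truth <- generate_truth(ann$annotations, design, reader_spec,
                          noise = noise, seed = seed + 1)
  peptides <- simulate_pulldown(truth, design, ann$sequences, noise = noise,
                                seed = seed + 2)
  quant <- quantify_experiments(peptides, design, ann$sequences)
  list(ann = ann, design = design, noise = noise, truth = truth,
       peptides = peptides, quant = quant,
       agg = aggregate_replicates(quant))
}

# aggregated bait profiles built directly from a named value matrix:
# rows proteins, cols baits, one context
profiles_from_matrix <- function(m, context = "ctx") {
  tibble::as_tibble(m, rownames = "protein_id") |>
    tidyr::pivot_longer(-protein_id, names_to = "bait",
                        values_to = "value") |>
    dplyr::mutate(context = context)
}

# member x context z-profiles with an optional planted bait preference:
# activities are lognormal around 1, the preferred bait multiplied by fold
simulate_member_z <- function(n_members, contexts, fold = 1,
                              pref_bait = "5fC", cv = 0.2,
                              baits = c("5C", "5mC", "5hmC", "5fC")) {
  grid <- tidyr::expand_grid(protein_id = sprintf("M%02d", 1:n_members),
                             context = contexts, bait = baits)
  sdlog <- sqrt(log1p(cv^2))
  grid$value <- stats::rlnorm(nrow(grid), -sdlog^2 / 2, sdlog) *
    ifelse(grid$bait == pref_bait, fold, 1)
  member_zscores(grid) |> dplyr::select(-value)
}
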