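#' In-silico proteolytic digestion rules
#'
#' Tryptic digestion cleaves C-terminal to lysine (K) and arginine (R) unless
#' the next residue is proline.  The "observable" peptide count used as the
#' iBAQ denominator counts fully tryptic peptides whose length falls in
#' `[min_len, max_len]`; by convention the denominator uses zero missed
#' cleavages even when the database search allowed more.
#'
#' @param cleave_after residues after which the backbone is cleaved.
#' @param suppress_before residues that suppress cleavage when they follow a
#'   cleavage site (classically proline).
#' @param missed_cleavages maximum number of missed cleavages to enumerate.
#' @param min_len,max_len observable peptide length window (residues).
#' @return A list of class `digestion_rules`.
#' @examples
#' digest("AAAAAAKCCCCCCRDDDDDD", digestion_rules())
#' @export
digestion_rules <- function(cleave_after = c("K", "R"),
                            suppress_before = "P",
                            missed_cleavages = 0L,
                            min_len = 6L, max_len = 30L) {
  assert_scalar_number(missed_cleavages, "missed_cleavages", lower = 0)
  assert_scalar_number(min_len, "min_len", lower = 1)
  assert_scalar_number(max_len, "max_len", lower = min_len)
  structure(list(cleave_after = cleave_after,
                 suppress_before = suppress_before,
                 missed_cleavages = as.integer(missed_cleavages),
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len)),
            class = "digestion_rules")
}

# fully tryptic peptides (0 missed cleavages) as a character vector
base_peptides <- function(sequence, rules) {
  if (nchar(sequence) == 0) return(character(0))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), AA20)
  if (length(bad) > 0) {
    abort(sprintf("sequence contains invalid residue(s): %s",
                  paste(bad, collapse = ", ")),
          class = "modbindr_input_error")
  }
  n <- length(chars)
  # cut after i when chars[i] is a cleavage residue and chars[i+1] does not
  # suppress; the C-terminus always ends a peptide
  cut_after <- chars %in% rules$cleave_after &
    !(c(chars[-1], "") %in% rules$suppress_before)
  cut_after[n] <- TRUE
  ends <- which(cut_after)
  starts <- c(1L, head(ends, -1L) + 1L)
  substring(sequence, starts, ends)
}

#' Digest a protein sequence into tryptic peptides
#'
#' @param sequence a single amino-acid string (20-letter alphabet).
#' @param rules a [digestion_rules()] object.
#' @return A tibble with one row per peptide: `peptide`, `n_missed`
#'   (missed cleavages it spans) and `observable` (length within the window).
#'   With zero missed cleavages the peptides tile the sequence.
#' @seealso [count_observable()] for the iBAQ denominator.
#' @export
digest <- function(sequence, rules = digestion_rules()) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  base <- base_peptides(sequence, rules)
  if (length(base) == 0) {
    return(tibble(peptide = character(0), n_missed = integer(0),
                  observable = logical(0)))
  }
  peps <- list(tibble(peptide = base, n_missed = 0L))
  if (rules$missed_cleavages > 0 && length(base) > 1) {
    for (mc in seq_len(min(rules$missed_cleavages, length(base) - 1L))) {
      idx <- seq_len(length(base) - mc)
      joined <- vapply(idx, function(i) {
        paste(base[i:(i + mc)], collapse = "")
      }, character(1))
      peps[[mc + 1L]] <- tibble(peptide = joined, n_missed = mc)
    }
  }
  out <- bind_rows(peps)
  out$observable <- nchar(out$peptide) >= rules$min_len &
    nchar(out$peptide) <= rules$max_len
  out
}

#' Count theoretically observable tryptic peptides
#'
#' The iBAQ denominator: the number of peptides produced by [digest()] whose
#' length lies within the observable window.
#'
#' @param sequences named character vector of protein sequences.
#' @param rules a [digestion_rules()] object.
#' @return Named integer vector, one count per sequence.
#' @export
count_observable <- function(sequences, rules = digestion_rules()) {
  vapply(sequences, function(s) {
    peps <- base_peptides(s, rules)
    if (rules$missed_cleavages > 0) {
      sum(digest(s, rules)$observable)
    } else {
      sum(nchar(peps) >= rules$min_len & nchar(peps) <= rules$max_len)
    }
  }, integer(1))
}

# observable base peptides per protein, as a named list (internal; used by
# the pulldown simulator, which partitions intensity across them)
observable_peptide_list <- function(sequences, rules = digestion_rules()) {
  lapply(sequences, function(s) {
    peps <- base_peptides(s, rules)
    peps[nchar(peps) >= rules$min_len & nchar(peps) <= rules$max_len]
  })
}
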