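#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy restricted-binding calls
#'
#' @param x a `dmr_calls` tibble.
#' @param ... unused.
#' @return A plain tibble of the calls (one row per protein x context).
#' @export
tidy.dmr_calls <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a call set
#'
#' @param x a `dmr_calls` tibble.
#' @param ... unused.
#' @return Tibble with protein/context counts, calls per module and the rule
#'   parameters used.
#' @export
glance.dmr_calls <- function(x, ...) {
  rule <- attr(x, "rule")
  mods <- table(factor(x$module, levels = 1:4))
  tibble(n_proteins = n_distinct(x$protein_id),
         n_contexts = n_distinct(x$context),
         n_calls = sum(!is.na(x$called_bait)),
         n_module1 = as.integer(mods[1]), n_module2 = as.integer(mods[2]),
         n_module3 = as.integer(mods[3]), n_module4 = as.integer(mods[4]),
         fold_threshold = rule$fold_threshold, center = rule$center)
}

#' Tidy family/domain preference tests
#'
#' @param x a `preference_tests` tibble.
#' @param ... unused.
#' @export
tidy.preference_tests <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' @rdname tidy.preference_tests
#' @export
glance.preference_tests <- function(x, ...) {
  tibble(level = attr(x, "level"), n_groups = n_distinct(x$group),
         n_tests = nrow(x), n_preferred = sum(x$preferred),
         alpha = attr(x, "alpha"))
}

#' Tidy an ordination
#'
#' @param x a `modbind_ord` tibble.
#' @param ... unused.
#' @export
tidy.modbind_ord <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' @rdname tidy.modbind_ord
#' @export
glance.modbind_ord <- function(x, ...) {
  v <- attr(x, "variance")
  tibble(n_components = length(v), total_variance = sum(v),
         prop_pc1 = v[1] / sum(v))
}
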