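# internal helpers shared across modules

# geometric mean; caller guarantees positivity
geomean <- function(x) exp(mean(log(x)))

# run `code` under a fixed seed without clobbering the caller's RNG state
with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "modbindr_schema_error")
  }
  invisible(df)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]",
                  name, format(lower), format(upper)),
          class = "modbindr_parameter_error")
  }
  invisible(x)
}

# derive a distinct child seed from a base seed, staying within 32-bit range
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 7919L
}

new_modbindr_tbl <- function(df, class, ...) {
  out <- as_tibble(df)
  attrs <- list(...)
  for (nm in names(attrs)) attr(out, nm) <- attrs[[nm]]
  class(out) <- c(class, class(out))
  out
}
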