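#' @importFrom rlang abort %||%
#' @importFrom stats setNames
NULL

# Natural-log values are converted to the requested base by dividing by log(base).
# Information quantities (entropy, MI, pmi) default to bits; interactions default
# to natural log ("energy" units, the Ising convention). Both defaults can be
# changed globally via options(mfi.info_base = , mfi.energy_base = ).
info_base <- function(base = NULL) {
  b <- base %||% getOption("mfi.info_base", 2)
  stopifnot(is.numeric(b), b > 0, b != 1)
  b
}

energy_base <- function(base = NULL) {
  b <- base %||% getOption("mfi.energy_base", exp(1))
  stopifnot(is.numeric(b), b > 0, b != 1)
  b
}

# xlogx with the 0 * log(0) == 0 convention
xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

# all subsets of `vars` (a character vector) as a list, ordered by binary
# counting over the positions of `vars` (bit i <-> vars[i]); element 1 is the
# empty set, element 2^n is `vars` itself.
subsets_of <- function(vars) {
  n <- length(vars)
  lapply(seq_len(2^n) - 1L, function(m) vars[bitwAnd(m, 2^(seq_len(n) - 1L)) > 0L])
}

set_label <- function(x) paste(x, collapse = ",")

assert_character_vars <- function(x, arg = "vars") {
  if (!is.character(x) || anyNA(x) || anyDuplicated(x) > 0) {
    abort(sprintf("`%s` must be a character vector of distinct variable names.", arg),
          class = "mfi_error_vars")
  }
  invisible(x)
}
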