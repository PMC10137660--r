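#' Exact joint probability tables
#'
#' A `joint_table` is a tibble with one integer column per variable and a
#' `prob` column, holding the full enumeration of states of a discrete joint
#' distribution (first variable varying fastest). It is the central
#' computational object of the package: every entropy, mutual-information and
#' interaction quantity is evaluated against one.
#'
#' @param x A data frame with one column per variable (integer codes
#'   `0 ... k - 1`) plus a probability column. States may be given sparsely;
#'   missing states get probability 0. Duplicated states are an error.
#' @param prob Name of the probability column (default `"prob"`).
#' @param arities Optional named integer vector of per-variable arities;
#'   inferred as `max(code) + 1` (at least 2) when absent.
#' @return A `joint_table` tibble.
#' @examples
#' fair_xy <- joint_table(data.frame(
#'   X = c(0, 1, 0, 1), Y = c(0, 0, 1, 1), prob = rep(0.25, 4)
#' ))
#' jt_prob(fair_xy, c(X = 1, Y = 1))
#' @export
joint_table <- function(x, prob = "prob", arities = NULL) {
  x <- tibble::as_tibble(x)
  if (!prob %in% names(x)) {
    abort(sprintf("Column `%s` not found.", prob), class = "mfi_error_io")
  }
  vars <- setdiff(names(x), prob)
  assert_character_vars(vars)
  if (length(vars) == 0) abort("At least one variable column is required.",
                               class = "mfi_error_vars")
  states <- as.matrix(x[vars])
  mode(states) <- "integer"
  if (anyNA(states) || any(states < 0)) {
    abort("State codes must be non-negative integers.", class = "mfi_error_state")
  }
  if (is.null(arities)) {
    arities <- pmax(apply(states, 2, max) + 1L, 2L)
  } else {
    arities <- as.integer(arities[vars])
    if (anyNA(arities) || any(arities < 2)) {
      abort("`arities` must cover every variable with values >= 2.",
            class = "mfi_error_arity")
    }
    bad <- which(states >= rep(arities, each = nrow(states)))
    if (length(bad)) abort("State codes exceed the declared arities.",
                           class = "mfi_error_state")
  }
  names(arities) <- vars
  idx <- state_index(states, arities)
  if (anyDuplicated(idx)) abort("Duplicated states in input.", class = "mfi_error_state")
  p <- numeric(prod(arities))
  p[idx] <- x[[prob]]
  if (any(p < 0) || anyNA(p)) {
    abort("Probabilities must be finite and non-negative.", class = "mfi_error_prob")
  }
  if (abs(sum(p) - 1) > 1e-6) {
    abort(sprintf("Probabilities sum to %.8f, not 1.", sum(p)),
          class = "mfi_error_prob")
  }
  new_joint_table(p, arities)
}

# p: probability vector over the canonical state enumeration
new_joint_table <- function(p, arities) {
  vars <- names(arities)
  grid <- state_grid(arities)
  out <- tibble::new_tibble(
    c(grid, list(prob = as.numeric(p))),
    nrow = length(p),
    vars = vars,
    arities = arities,
    class = "joint_table"
  )
  out
}

# list of integer columns, first variable fastest
state_grid <- function(arities) {
  k <- length(arities)
  reps_in <- cumprod(c(1L, arities[-k]))
  total <- prod(arities)
  out <- lapply(seq_len(k), function(i) {
    rep(rep(0:(arities[i] - 1L), each = reps_in[i]), length.out = total)
  })
  stats::setNames(out, names(arities))
}

# 1-based canonical index of each row of a state matrix
state_index <- function(states, arities) {
  strides <- cumprod(c(1L, arities[-length(arities)]))
  as.integer(states %*% strides) + 1L
}

#' @rdname joint_table
#' @export
is_joint_table <- function(x) inherits(x, "joint_table")

#' @rdname joint_table
#' @export
jt_vars <- function(x) attr(x, "vars")

#' @rdname joint_table
#' @export
jt_arities <- function(x) attr(x, "arities")

assert_joint_table <- function(x) {
  if (!is_joint_table(x)) abort("Expected a `joint_table`.", class = "mfi_error_type")
  invisible(x)
}

assert_binary <- function(x, vars = jt_vars(x)) {
  if (any(jt_arities(x)[vars] != 2L)) {
    abort("This operation is defined for binary variables only.",
          class = "mfi_error_arity")
  }
  invisible(x)
}

# probability of one fully specified state (named vector)
#' @rdname joint_table
#' @param state Named integer vector assigning a value to every variable.
#' @export
jt_prob <- function(x, state) {
  assert_joint_table(x)
  vars <- jt_vars(x)
  if (!all(vars %in% names(state))) {
    abort("`state` must assign a value to every variable.", class = "mfi_error_state")
  }
  s <- matrix(as.integer(state[vars]), nrow = 1)
  ar <- jt_arities(x)
  if (any(s < 0) || any(s >= ar)) {
    abort("State out of range.", class = "mfi_error_state")
  }
  x$prob[state_index(s, ar)]
}

# natural-log probability of the state with `ones` = 1 and all other
# variables of the table = 0; the table must already be marginalised to the
# background set of interest
logp_indicator <- function(x, ones) {
  vars <- jt_vars(x)
  s <- stats::setNames(integer(length(vars)), vars)
  s[ones] <- 1L
  log(x$prob[state_index(matrix(s, nrow = 1), jt_arities(x))])
}

#' Marginal and conditional distributions
#'
#' `marginalize()` sums the table down to a subset of variables;
#' `condition_on()` restricts to an assignment of some variables and
#' renormalises over the rest (the conditioned columns are dropped).
#'
#' @param x A [joint_table()].
#' @param keep Character vector of variables to keep.
#' @param ... Named integer assignments, e.g. `condition_on(tab, Z = 0)`.
#' @return A [joint_table()] over the remaining variables.
#' @examples
#' tab <- gate_table("AND", p = 0.25, eps = 0)
#' marginalize(tab, c("A", "C"))
#' condition_on(tab, C = 0)
#' @export
marginalize <- function(x, keep) {
  assert_joint_table(x)
  vars <- jt_vars(x)
  keep <- intersect(vars, keep)  # canonical order
  if (!all(keep %in% vars)) abort("Unknown variable.", class = "mfi_error_vars")
  if (length(keep) == 0) abort("Cannot marginalise to zero variables.",
                               class = "mfi_error_vars")
  if (identical(keep, vars)) return(x)
  ar <- jt_arities(x)[keep]
  idx <- state_index(as.matrix(x[keep]), ar)
  p <- numeric(prod(ar))
  agg <- rowsum(x$prob, idx)
  p[as.integer(rownames(agg))] <- agg[, 1]
  new_joint_table(p, ar)
}

#' @rdname marginalize
#' @export
condition_on <- function(x, ...) {
  assert_joint_table(x)
  assignment <- c(...)
  vars <- jt_vars(x)
  if (length(assignment) == 0 || is.null(names(assignment)) ||
      !all(names(assignment) %in% vars)) {
    abort("Provide named assignments for variables of the table.",
          class = "mfi_error_vars")
  }
  rest <- setdiff(vars, names(assignment))
  if (length(rest) == 0) abort("Cannot condition on every variable.",
                               class = "mfi_error_vars")
  sel <- rep(TRUE, nrow(x))
  for (v in names(assignment)) sel <- sel & x[[v]] == assignment[[v]]
  mass <- sum(x$prob[sel])
  if (mass <= 0) {
    abort("Conditioning on a zero-probability assignment.",
          class = "mfi_error_degenerate_condition")
  }
  ar <- jt_arities(x)[rest]
  sub <- x[sel, , drop = FALSE]
  idx <- state_index(as.matrix(sub[rest]), ar)
  p <- numeric(prod(ar))
  p[idx] <- sub$prob / mass
  new_joint_table(p, ar)
}

#' Plug-in estimation of a joint table from samples
#'
#' Computes `(count + alpha) / (M + alpha * K)` per state, where `K` is the
#' number of states; `smoothing = 0` gives the maximum-likelihood plug-in,
#' a positive pseudocount gives the usual additive-smoothing estimate. No
#' smoothing is ever applied silently: zero-probability states propagate
#' `-Inf` surprisal and non-finite interaction values downstream.
#'
#' @param samples Data frame of integer codes, one row per observation.
#' @param smoothing Pseudocount per state, `>= 0`.
#' @param arities Optional named arities; inferred as `max + 1` (>= 2) if absent.
#' @return A [joint_table()].
#' @export
estimate_joint <- function(samples, smoothing = 0, arities = NULL) {
  samples <- as.data.frame(samples)
  if (nrow(samples) < 1) abort("Need at least one observation.",
                               class = "mfi_error_empty")
  if (smoothing < 0) abort("`smoothing` must be >= 0.", class = "mfi_error_arg")
  vars <- names(samples)
  assert_character_vars(vars)
  m <- as.matrix(samples)
  mode(m) <- "integer"
  if (anyNA(m) || any(m < 0)) {
    bad <- which(is.na(m) | m < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("Invalid code at row %d, column `%s`.", bad[1], vars[bad[2]]),
          class = "mfi_error_state")
  }
  if (is.null(arities)) {
    arities <- stats::setNames(pmax(apply(m, 2, max) + 1L, 2L), vars)
  } else {
    arities <- stats::setNames(as.integer(arities[vars]), vars)
    if (anyNA(arities) || any(arities < 2)) {
      abort("`arities` must cover every column with values >= 2.",
            class = "mfi_error_arity")
    }
    over <- which(m >= rep(arities, each = nrow(m)), arr.ind = TRUE)
    if (nrow(over)) {
      abort(sprintf("Code out of range at row %d, column `%s`.",
                    over[1, 1], vars[over[1, 2]]),
            class = "mfi_error_state")
    }
  }
  counts <- tabulate(state_index(m, arities), nbins = prod(arities))
  p <- (counts + smoothing) / (nrow(m) + smoothing * prod(arities))
  new_joint_table(p, arities)
}

#' Boltzmann distribution of a generalised Ising model
#'
#' Builds the exact distribution \eqn{p(s) \propto \exp(\sum_S J_S \prod_{i
#' \in S} s_i)} over binary strings, where the sum runs over the subsets `S`
#' named in `couplings`. The model-free interactions of the resulting table
#' recover the couplings exactly: `mfi(boltzmann_table(J), S) == J[S]` for
#' every subset -- the maximum-entropy reading of the MFIs.
#'
#' @param couplings Named numeric vector; names are variable subsets joined
#'   by `":"`, e.g. `c("A" = 0.5, "A:B:C" = 0.7)`.
#' @param variables Character vector of variables (defaults to those named in
#'   `couplings`, in order of first appearance). At most 20 (exact enumeration).
#' @param constant Additive constant in the energy; cancels on normalisation.
#' @return A [joint_table()] over binary variables.
#' @examples
#' tab <- boltzmann_table(c("A:B:C" = 0.7), variables = c("A", "B", "C"))
#' mfi(tab, c("A", "B", "C"))  # 0.7
#' mfi(tab, c("A", "B"))       # 0
#' @export
boltzmann_table <- function(couplings, variables = NULL, constant = 0) {
  subsets <- strsplit(names(couplings) %||% character(0), ":", fixed = TRUE)
  if (length(couplings) && (is.null(names(couplings)) || any(!nzchar(names(couplings))))) {
    abort("`couplings` must be named by ':'-joined variable subsets.",
          class = "mfi_error_vars")
  }
  variables <- variables %||% unique(unlist(subsets))
  assert_character_vars(variables, "variables")
  if (length(variables) > 20) {
    abort("Exact enumeration is guarded at 20 binary variables.",
          class = "mfi_error_too_large")
  }
  unknown <- setdiff(unlist(subsets), variables)
  if (length(unknown)) {
    abort(sprintf("Coupling names use unknown variables: %s",
                  paste(unknown, collapse = ", ")), class = "mfi_error_vars")
  }
  if (!all(is.finite(couplings))) abort("Couplings must be finite.",
                                        class = "mfi_error_arg")
  arities <- stats::setNames(rep(2L, length(variables)), variables)
  grid <- state_grid(arities)
  energy <- rep(constant, prod(arities))
  for (i in seq_along(subsets)) {
    on <- Reduce(`*`, grid[subsets[[i]]])
    energy <- energy + couplings[[i]] * on
  }
  w <- exp(energy - max(energy))
  new_joint_table(w / sum(w), arities)
}

#' Background surprisal of a subset of variables
#'
#' The building block of every interaction: \eqn{S_{\eta;T} = \log p(\eta =
#' 1, T \setminus \eta = 0)}, the log-probability of the state in which the
#' variables in `eta` are on and the rest of the background set `within` are
#' off. Variables outside `within` are marginalised out first. States of
#' probability zero give `-Inf`, which propagates to callers as a non-finite
#' interaction flagged in scan output.
#'
#' @param x A [joint_table()] with binary variables in `within`.
#' @param eta Character vector (possibly empty) of variables set to 1.
#' @param within Background set `T`; defaults to all variables of the table.
#' @return Natural-log probability (may be `-Inf`).
#' @export
background_surprisal <- function(x, eta, within = NULL) {
  assert_joint_table(x)
  within <- within %||% jt_vars(x)
  if (is.null(eta)) eta <- character(0)
  if (!all(eta %in% within) || !all(within %in% jt_vars(x))) {
    abort("Need eta within `within` within the table's variables.",
          class = "mfi_error_vars")
  }
  tab <- marginalize(x, within)
  assert_binary(tab)
  logp_indicator(tab, eta)
}

#' Random strictly positive joint table
#'
#' Draws state probabilities from a symmetric Dirichlet via normalised gamma
#' variates, using the caller's RNG state. Used throughout the test-suite's
#' property checks and by the `ising-check` command.
#'
#' @param arities Named integer vector of arities.
#' @param concentration Dirichlet concentration (default 1, uniform simplex).
#' @return A [joint_table()].
#' @export
random_joint_table <- function(arities, concentration = 1) {
  if (is.null(names(arities))) {
    names(arities) <- paste0("X", seq_along(arities))
  }
  k <- prod(arities)
  w <- stats::rgamma(k, shape = concentration, rate = 1)
  w <- pmax(w, 1e-12)
  new_joint_table(w / sum(w), stats::setNames(as.integer(arities), names(arities)))
}

#' @export
print.joint_table <- function(x, ...) {
  ar <- jt_arities(x)
  if (is.null(ar)) return(NextMethod())  # subset/modified copies lose attrs
  cat(sprintf("# A joint_table: %d variable(s) (%s), %d states\n",
              length(ar), paste(names(ar), ar, sep = "=", collapse = ", "),
              nrow(x)))
  NextMethod()
}
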