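gate_functions <- list(
  AND  = function(s) as.integer(s[, 1] & s[, 2]),
  OR   = function(s) as.integer(s[, 1] | s[, 2]),
  NAND = function(s) as.integer(!(s[, 1] & s[, 2])),
  NOR  = function(s) as.integer(!(s[, 1] | s[, 2])),
  XOR  = function(s) as.integer(rowSums(s) %% 2L),
  XNOR = function(s) as.integer(1L - rowSums(s) %% 2L),
  AND3 = function(s) as.integer(s[, 1] & s[, 2] & s[, 3]),
  OR3  = function(s) as.integer(s[, 1] | s[, 2] | s[, 3]),
  XOR3 = function(s) as.integer(rowSums(s) %% 2L)
)

gate_inputs <- function(gate) if (grepl("3$", gate)) 3L else 2L

#' Truth table of a logic gate
#'
#' @param gate One of `"AND"`, `"OR"`, `"NAND"`, `"NOR"`, `"XOR"`, `"XNOR"`
#'   (inputs `A`, `B`, output `C`) or the three-input `"AND3"`, `"OR3"`,
#'   `"XOR3"` (inputs `A`, `B`, `C`, output `D`).
#' @return A tibble of the legal (truth-table) states.
#' @export
gate_truth_table <- function(gate) {
  gate <- match.arg(toupper(gate), names(gate_functions))
  k <- gate_inputs(gate)
  inputs <- as.matrix(expand.grid(rep(list(0:1), k), KEEP.OUT.ATTRS = FALSE))
  out <- cbind(inputs, gate_functions[[gate]](inputs))
  colnames(out) <- LETTERS[seq_len(k + 1)]
  tibble::as_tibble(out)
}

#' Noisy logic-gate distributions
#'
#' The joint distribution of a gate's inputs and output in which each of the
#' truth-table states has probability `p` and each illegal state probability
#' `eps` (so `4p + 4eps = 1` for two-input gates, `8p + 8eps = 1` for
#' three-input ones). Supply either `p` or `eps`; the other follows from
#' normalisation. As `eps -> 0` the distribution concentrates on the truth
#' table; at `eps = 0` interactions involving illegal states are `-Inf`/
#' `NaN` (flagged), while entropies and mutual information remain finite --
#' the uniform-truth-table case used for the gate information values.
#'
#' The 3-point interaction of a two-input gate is a multiple of
#' \eqn{I = 4 \log(p/\epsilon)}: \eqn{+I} for XNOR, \eqn{-I} for XOR,
#' \eqn{\pm I/2} for the AND/OR family, with logical negation flipping the
#' sign.
#'
#' @param gate Gate name, see [gate_truth_table()].
#' @param p Probability of each truth-table state.
#' @param eps Probability of each illegal state (default `1e-4` when `p` is
#'   not given).
#' @return A [joint_table()] with attributes `gate`, `gate_p`, `gate_eps`.
#' @examples
#' tab <- gate_table("XNOR", p = 0.2)      # eps = 0.05 by normalisation
#' mfi(tab, c("A", "B", "C"))              # 4 * log(4)
#' @export
gate_table <- function(gate, p = NULL, eps = NULL) {
  gate <- match.arg(toupper(gate), names(gate_functions))
  k <- gate_inputs(gate)
  n_legal <- 2^k
  n_states <- 2^(k + 1)
  n_illegal <- n_states - n_legal
  if (is.null(p) && is.null(eps)) eps <- 1e-4
  if (is.null(p)) p <- (1 - n_illegal * eps) / n_legal
  if (is.null(eps)) eps <- (1 - n_legal * p) / n_illegal
  if (abs(n_legal * p + n_illegal * eps - 1) > 1e-12) {
    abort("Gate probabilities do not normalise: need n_legal*p + n_illegal*eps = 1.",
          class = "mfi_error_prob")
  }
  if (eps < 0 || p <= eps) {
    abort("Need 0 <= eps < p.", class = "mfi_error_prob")
  }
  vars <- LETTERS[seq_len(k + 1)]
  arities <- stats::setNames(rep(2L, k + 1), vars)
  legal <- state_index(as.matrix(gate_truth_table(gate)), arities)
  probs <- rep(eps, n_states)
  probs[legal] <- p
  out <- new_joint_table(probs, arities)
  attr(out, "gate") <- gate
  attr(out, "gate_p") <- p
  attr(out, "gate_eps") <- eps
  out
}

#' Dyadic and triadic distributions
#'
#' Two distributions over three four-letter variables `X`, `Y`, `Z` that
#' share all standard Shannon-type information measures yet differ in the
#' order of the rules that build them. Writing each category as a bit pair
#' (\eqn{c \leftrightarrow c_0 c_1}, `{0,1,2,3} -> {00,01,10,11}`), the
#' dyadic distribution couples bits pairwise (\eqn{X_0 = Y_1}, \eqn{Y_0 =
#' Z_1}, \eqn{Z_0 = X_1}) while the triadic distribution uses triplet rules
#' (\eqn{X_0 + Y_0 + Z_0 = 0 \bmod 2} and \eqn{X_1 = Y_1 = Z_1}). Each has 8
#' legal states, given probability \eqn{p = (1 - 56\epsilon)/8}, with the 56
#' remaining states at \eqn{\epsilon}.
#'
#' The categorical interactions separate them: the full-range interaction
#' `(0->3; 0->3; 0->3)` is 0 (dyadic) versus \eqn{\log(\epsilon/p)}
#' (triadic), and the 216-term symmetrised sum is 0 versus
#' \eqn{64 \log(\epsilon/p)}.
#'
#' @param eps Probability of each illegal state, `0 <= eps < 1/56`
#'   (default `1e-4`; `eps = 0` gives the exact 8-point uniform support).
#' @return A [joint_table()] over `X`, `Y`, `Z` with arity 4.
#' @export
dyadic_table <- function(eps = 1e-4) {
  categorical_parity_table(eps, rule = "dyadic")
}

#' @rdname dyadic_table
#' @export
triadic_table <- function(eps = 1e-4) {
  categorical_parity_table(eps, rule = "triadic")
}

categorical_parity_table <- function(eps, rule) {
  if (eps < 0 || eps >= 1 / 56) {
    abort("Need 0 <= eps < 1/56.", class = "mfi_error_prob")
  }
  bits <- as.matrix(expand.grid(rep(list(0:1), 6), KEEP.OUT.ATTRS = FALSE))
  colnames(bits) <- c("X0", "X1", "Y0", "Y1", "Z0", "Z1")
  legal <- if (rule == "dyadic") {
    bits[, "X0"] == bits[, "Y1"] & bits[, "Y0"] == bits[, "Z1"] &
      bits[, "Z0"] == bits[, "X1"]
  } else {
    (bits[, "X0"] + bits[, "Y0"] + bits[, "Z0"]) %% 2 == 0 &
      bits[, "X1"] == bits[, "Y1"] & bits[, "Y1"] == bits[, "Z1"]
  }
  # category c <-> bit string c0 c1 (c0 the high bit): c = 2*c0 + c1
  states <- cbind(
    X = 2L * bits[, "X0"] + bits[, "X1"],
    Y = 2L * bits[, "Y0"] + bits[, "Y1"],
    Z = 2L * bits[, "Z0"] + bits[, "Z1"]
  )[legal, , drop = FALSE]
  stopifnot(nrow(states) == 8)
  p <- (1 - 56 * eps) / 8
  arities <- c(X = 4L, Y = 4L, Z = 4L)
  probs <- rep(eps, 64)
  probs[state_index(states, arities)] <- p
  out <- new_joint_table(probs, arities)
  attr(out, "gate_p") <- p
  attr(out, "gate_eps") <- eps
  out
}
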