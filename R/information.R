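#' Entropy of a marginal
#'
#' Shannon entropy \eqn{-\sum p \log p} of the marginal distribution on
#' `subset`, with the \eqn{0 \log 0 = 0} convention. The empty subset has
#' entropy 0 (trivial marginal).
#'
#' @param x A [joint_table()].
#' @param subset Character vector of variables; defaults to all of them.
#' @param base Logarithm base; default bits (`getOption("mfi.info_base", 2)`).
#' @return A numeric scalar, `>= 0`.
#' @examples
#' entropy(gate_table("AND", p = 0.25, eps = 0), "C")  # 0.811 bits
#' @export
entropy <- function(x, subset = NULL, base = NULL) {
  assert_joint_table(x)
  subset <- subset %||% jt_vars(x)
  if (length(subset) == 0) return(0)
  marg <- marginalize(x, subset)
  -sum(xlogx(marg$prob)) / log(info_base(base))
}

#' Higher-order mutual information as a Moebius inversion
#'
#' `mutual_information()` computes the co-information
#' \eqn{MI(\tau) = (-1)^{|\tau|-1} \sum_{\eta \le \tau} \mu(\eta, \tau)
#' H(\eta) = \sum_{\eta \le \tau} (-1)^{|\eta|+1} H(\eta)} over the subset
#' lattice with top `tau`. For a singleton it is the entropy; for a pair the
#' familiar \eqn{H(X) + H(Y) - H(X,Y)}; for a triple the (possibly negative)
#' co-information, which is \eqn{-1} bit for a uniform XOR/XNOR gate.
#'
#' `entropy_from_mi()` inverts the relation, reconstructing
#' \eqn{H(\tau) = \sum_{\eta \le \tau} (-1)^{|\eta|-1} MI(\eta)} by a zeta
#' sum of signed mutual informations; it must (and does, see the tests)
#' agree with [entropy()].
#'
#' @inheritParams entropy
#' @param tau Nonempty character vector of variables.
#' @return A numeric scalar.
#' @examples
#' xor <- gate_table("XOR", p = 0.25, eps = 0)
#' mutual_information(xor, c("A", "B", "C"))  # -1 bit
#' @export
mutual_information <- function(x, tau, base = NULL) {
  assert_joint_table(x)
  if (length(tau) == 0) return(0)
  lat <- subset_lattice(tau)
  sign <- (-1)^(length(tau) - 1)
  sign * moebius_inversion(function(eta) entropy(x, eta, base = base), lat, tau)
}

#' @rdname mutual_information
#' @export
entropy_from_mi <- function(x, tau, base = NULL) {
  assert_joint_table(x)
  lat <- subset_lattice(tau)
  zeta_sum(function(eta) {
    (-1)^(length(eta) - 1) * mutual_information(x, eta, base = base)
  }, lat, tau)
}

#' Conditional mutual information
#'
#' \eqn{MI(\tau \mid Z)}: the mutual information among `tau` under each
#' assignment of the conditioning set, averaged with the assignment
#' probabilities. Zero-probability assignments contribute nothing.
#'
#' @inheritParams mutual_information
#' @param given Character vector of conditioning variables.
#' @export
conditional_mutual_information <- function(x, tau, given, base = NULL) {
  assert_joint_table(x)
  if (length(intersect(tau, given))) {
    abort("`tau` and `given` must be disjoint.", class = "mfi_error_vars")
  }
  marg <- marginalize(x, given)
  states <- as.matrix(marg[given])
  total <- 0
  for (i in seq_len(nrow(states))) {
    w <- marg$prob[i]
    if (w <= 0) next
    sub <- do.call(condition_on, c(list(x), as.list(stats::setNames(states[i, ], given))))
    total <- total + w * mutual_information(sub, tau, base = base)
  }
  total
}

#' Dual (differential) mutual information
#'
#' The Moebius inversion of marginal entropy on the order-reversed subset
#' lattice over the background set `within`. `MI*` of the empty set is the
#' ordinary mutual information among all of `within`; for a singleton `X` it
#' is the differential mutual information \eqn{MI(T) - MI(T \setminus X)},
#' the change in total mutual information when `X` is marginalised out. On
#' three variables,
#' \eqn{MI^*(X) = H(X) - H(X,Y) - H(X,Z) + H(X,Y,Z)}.
#'
#' @inheritParams entropy
#' @param eta Character vector (possibly empty) of variables.
#' @param within Background set; defaults to all variables.
#' @export
dual_mutual_information <- function(x, eta, within = NULL, base = NULL) {
  assert_joint_table(x)
  within <- within %||% jt_vars(x)
  if (is.null(eta)) eta <- character(0)
  if (!all(eta %in% within)) abort("`eta` must lie within `within`.",
                                   class = "mfi_error_vars")
  lat <- dual_lattice(subset_lattice(within))
  sign <- (-1)^(length(eta) - 1)
  sign * moebius_inversion(function(a) entropy(x, a, base = base), lat, eta)
}

#' Generalised pointwise mutual information
#'
#' The signed Moebius inversion of log marginal probabilities at one
#' realization: \eqn{pmi(T = \tau) = (-1)^{|\tau|} \sum_{\eta \le \tau}
#' \mu(\eta, \tau) \log p(\eta = r_\eta)}, with \eqn{\log p(\emptyset) = 0}.
#' For two variables this reduces to the classical
#' \eqn{\log[p(x, y) / (p(x) p(y))]}, and its expectation over realizations
#' is the mutual information.
#'
#' @inheritParams entropy
#' @param realization Named integer vector giving a value for each variable
#'   of the realised subset, e.g. `c(X = 1, Y = 0)`.
#' @return A numeric scalar; `-Inf`/`NaN` (flagged non-finite downstream) if a
#'   required marginal probability is zero.
#' @export
pointwise_mi <- function(x, realization, base = NULL) {
  assert_joint_table(x)
  tau <- names(realization)
  if (is.null(tau) || !all(tau %in% jt_vars(x))) {
    abort("`realization` must be named by variables of the table.",
          class = "mfi_error_vars")
  }
  lat <- subset_lattice(tau)
  g <- function(eta) {
    if (length(eta) == 0) return(0)
    log(jt_prob(marginalize(x, eta), realization[eta]))
  }
  (-1)^length(tau) * moebius_inversion(g, lat, tau) / log(info_base(base))
}

#' Scan entropies and (dual) mutual information over all subsets
#'
#' One row per nonempty subset of the table's variables up to `max_order`,
#' with the marginal entropy, the mutual information, and the dual mutual
#' information of that subset with respect to the full variable set.
#'
#' @inheritParams entropy
#' @param max_order Largest subset size to report (default: all variables).
#' @return A tibble of class `info_scan` with columns `variables`, `order`,
#'   `entropy`, `mi`, `dual_mi`.
#' @export
info_scan <- function(x, max_order = NULL, base = NULL) {
  assert_joint_table(x)
  vars <- jt_vars(x)
  max_order <- max_order %||% length(vars)
  subs <- Filter(function(s) length(s) >= 1 && length(s) <= max_order,
                 subsets_of(vars))
  out <- purrr::map_dfr(subs, function(s) {
    tibble::tibble(
      variables = set_label(s),
      order = length(s),
      entropy = entropy(x, s, base = base),
      mi = mutual_information(x, s, base = base),
      dual_mi = dual_mutual_information(x, s, base = base)
    )
  })
  out <- out[order(out$order, out$variables), ]
  tibble::new_tibble(out, nrow = nrow(out), base = info_base(base),
                     n_vars = length(vars), class = "info_scan")
}

#' @export
tidy.info_scan <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.info_scan <- function(x, ...) {
  tibble::tibble(
    n_vars = attr(x, "n_vars"),
    n_subsets = nrow(x),
    base = attr(x, "base"),
    total_entropy = x$entropy[which.max(x$order)],
    min_mi = min(x$mi),
    max_mi = max(x$mi)
  )
}
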