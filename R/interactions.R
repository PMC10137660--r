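#' Derivative with respect to a binary variable
#'
#' Returns the finite-difference function \eqn{x \mapsto f(X_i = 1, \cdot) -
#' f(X_i = 0, \cdot)}. Iterated application over a set of variables is
#' order-independent, and expanding the iteration gives the signed sum
#' \eqn{\sum_s (-1)^{\#zeros(s)} f(s)} over the binary assignments of that
#' set -- the bridge between the derivative and lattice pictures of the
#' interactions.
#'
#' @param f A function of a named integer state vector.
#' @param variable Name of the variable to differentiate.
#' @return A function of the same signature as `f`.
#' @examples
#' f <- function(s) s[["X"]] * s[["Y"]]
#' d2 <- boolean_derivative(boolean_derivative(f, "X"), "Y")
#' d2(c(X = 0, Y = 0))  # 1
#' @export
boolean_derivative <- function(f, variable) {
  force(f); force(variable)
  function(state) {
    s1 <- s0 <- state
    s1[variable] <- 1L
    s0[variable] <- 0L
    f(s1) - f(s0)
  }
}

# shared validation + marginalisation for the interaction functions
prep_background <- function(x, tau, within) {
  assert_joint_table(x)
  within <- within %||% jt_vars(x)
  if (!all(tau %in% within) || !all(within %in% jt_vars(x))) {
    abort("Need `tau` within `within` within the table's variables.",
          class = "mfi_error_vars")
  }
  tab <- marginalize(x, within)
  assert_binary(tab)
  tab
}

to_base <- function(value_nat, base = NULL) value_nat / log(energy_base(base))

#' Model-free n-point interactions
#'
#' `mfi()` computes the model-free interaction of the variables `tau`: the
#' iterated Boolean derivative of \eqn{\log p} with every other variable of
#' the background set `within` held at 0. Order 1 is a conditional log-odds,
#' order 2 the log odds ratio, order 3 the eight-state log cross-ratio, and
#' in general the value equals the coupling \eqn{J_\tau} of the generalised
#' Ising (maximum-entropy) model of the distribution.
#'
#' `mfi_moebius()` computes the same quantity by Moebius inversion of the
#' [background_surprisal()] over the subset lattice with top `tau`,
#' \eqn{I(\tau; T) = \sum_{\eta \le \tau} \mu(\eta, \tau) S_{\eta;T}}. The
#' two routes are algebraically equal; both are kept so that each can serve
#' as an oracle for the other.
#'
#' `dual_mfi()` inverts the surprisal on the order-reversed lattice over
#' `within`: \eqn{I^*(\tau; T) = \sum_{s \supseteq \tau} (-1)^{|s| - |\tau|}
#' \log p(s = 1, T \setminus s = 0)}. The dual interaction of a singleton `X`
#' in a triple equals \eqn{I(X,Y,Z) + I(Y,Z)} -- the pair interaction of the
#' remaining variables in the context `X = 1` instead of `X = 0`.
#'
#' Interactions are reported in natural-log ("energy") units by default;
#' divide by `log(2)` (or set `options(mfi.energy_base = 2)`) for bits.
#' States of probability zero make a value non-finite (`-Inf`/`Inf`/`NaN`)
#' rather than raising, so whole-table scans complete.
#'
#' @param x A [joint_table()]; variables in `within` must be binary.
#' @param tau Nonempty character vector: the interacting variables.
#' @param within Background set `T` (default: all variables); variables
#'   outside it are marginalised out, variables inside it but outside `tau`
#'   are held at 0.
#' @param base Logarithm base for the result; default natural log
#'   (`getOption("mfi.energy_base", exp(1))`).
#' @return A numeric scalar.
#' @examples
#' xnor <- gate_table("XNOR", p = 0.2, eps = 0.05)
#' mfi(xnor, c("A", "B", "C")) / log(0.2 / 0.05)  # 4
#' @export
mfi <- function(x, tau, within = NULL, base = NULL) {
  within <- within %||% jt_vars(x)
  tab <- prep_background(x, tau, within)
  if (length(tau) == 0) abort("`tau` must be nonempty.", class = "mfi_error_vars")
  f <- function(state) logp_indicator(tab, names(state)[state == 1L])
  d <- Reduce(boolean_derivative, tau, init = f)
  zero <- stats::setNames(integer(length(within)), jt_vars(tab))
  to_base(d(zero), base)
}

#' @rdname mfi
#' @export
mfi_moebius <- function(x, tau, within = NULL, base = NULL) {
  within <- within %||% jt_vars(x)
  tab <- prep_background(x, tau, within)
  if (length(tau) == 0) abort("`tau` must be nonempty.", class = "mfi_error_vars")
  lat <- subset_lattice(tau)
  val <- moebius_inversion(function(eta) logp_indicator(tab, eta), lat, tau)
  to_base(val, base)
}

#' @rdname mfi
#' @export
dual_mfi <- function(x, tau, within = NULL, base = NULL) {
  within <- within %||% jt_vars(x)
  tab <- prep_background(x, tau, within)
  lat <- dual_lattice(subset_lattice(jt_vars(tab)))
  val <- moebius_inversion(function(s) logp_indicator(tab, s), lat, tau)
  to_base(val, base)
}

#' J-interactions of a gate-like triple
#'
#' `j_interaction()` is the difference \eqn{J^*_X = I(T) - I(T \setminus X)}
#' between the full interaction of the background set and the interaction
#' with `input` removed; on two-input logic gates the J-interactions of the
#' inputs take a distinct value for each of the six nontrivial gates.
#' `symmetric_j()` is the product of the three J-interactions of a triple.
#'
#' @inheritParams mfi
#' @param input The variable to drop.
#' @export
j_interaction <- function(x, input, within = NULL, base = NULL) {
  within <- within %||% jt_vars(x)
  if (!input %in% within || length(within) < 2) {
    abort("`input` must belong to `within` (>= 2 variables).",
          class = "mfi_error_vars")
  }
  mfi(x, within, within, base = base) -
    mfi(x, setdiff(within, input), within, base = base)
}

#' @rdname j_interaction
#' @export
symmetric_j <- function(x, within = NULL, base = NULL) {
  within <- within %||% jt_vars(x)
  if (length(within) != 3) {
    abort("The symmetric J-interaction is defined for a triple.",
          class = "mfi_error_vars")
  }
  prod(vapply(within, function(v) j_interaction(x, v, within, base = base),
              numeric(1)))
}

#' Reconstruct background surprisal from interactions
#'
#' The zeta sum inverse of the interaction definition:
#' \eqn{\log p(\tau = 1, T \setminus \tau = 0) = \sum_{\eta \le \tau}
#' I(\eta; T)}, where the order-0 term is \eqn{I_\emptyset = \log p(T = 0)}.
#' Feeding a distribution's full interaction set through this sum recovers
#' every background log-probability exactly.
#'
#' @inheritParams mfi
#' @return The natural-log background probability (in `base` units).
#' @export
surprisal_from_interactions <- function(x, tau, within = NULL, base = NULL) {
  within <- within %||% jt_vars(x)
  tab <- prep_background(x, tau, within)
  lat <- subset_lattice(tau)
  val <- zeta_sum(function(eta) {
    if (length(eta) == 0) logp_indicator(tab, character(0))   # order-0 term
    else mfi(x, eta, within, base = exp(1))
  }, lat, tau)
  to_base(val, base)
}

#' Categorical interactions on the chain-product lattice
#'
#' The interaction of categorical variables making transitions
#' \eqn{x_0 \to x_1} (with \eqn{x_1 > x_0}) while every other variable of
#' the background set is held at 0. For unit transitions this is the Moebius
#' inversion of surprisal over a unit cell of the componentwise-ordered
#' state lattice (where \eqn{\mu} vanishes except on cell corners); larger
#' jumps follow by transitivity, e.g. \eqn{I(X: 0 \to 2, \cdot) = I(X: 0 \to
#' 1, \cdot) + I(X: 1 \to 2, \cdot)}, giving the corner-signed sum
#' \eqn{\sum_{c \in \{0,1\}^k} (-1)^{\#zeros(c)} \log p(\dots)} with
#' variable i at \eqn{x_1} where \eqn{c_i = 1} and \eqn{x_0} where
#' \eqn{c_i = 0}. On binary variables with the only transition 0 -> 1 this
#' reduces exactly to [mfi()].
#'
#' @inheritParams mfi
#' @param transitions Named list, one entry per transitioning variable,
#'   each a length-2 vector `c(from, to)` with `to > from`, e.g.
#'   `list(X = c(0, 3), Y = c(0, 3), Z = c(0, 3))`.
#' @export
categorical_mfi <- function(x, transitions, within = NULL, base = NULL) {
  assert_joint_table(x)
  within <- within %||% jt_vars(x)
  vars <- names(transitions)
  if (is.null(vars) || !all(vars %in% within) || !all(within %in% jt_vars(x))) {
    abort("`transitions` must be named by variables of `within`.",
          class = "mfi_error_vars")
  }
  tab <- marginalize(x, within)
  ar <- jt_arities(tab)
  for (v in vars) {
    tr <- transitions[[v]]
    if (length(tr) != 2 || tr[2] <= tr[1] || tr[1] < 0 || tr[2] >= ar[[v]]) {
      abort(sprintf("Invalid transition for `%s`: need 0 <= from < to < arity.", v),
            class = "mfi_error_invalid_transition")
    }
  }
  k <- length(vars)
  corners <- as.matrix(expand.grid(rep(list(0:1), k), KEEP.OUT.ATTRS = FALSE))
  total <- 0
  base_state <- stats::setNames(integer(length(jt_vars(tab))), jt_vars(tab))
  for (i in seq_len(nrow(corners))) {
    s <- base_state
    for (j in seq_len(k)) {
      s[vars[j]] <- transitions[[vars[j]]][corners[i, j] + 1L]
    }
    sign <- (-1)^(k - sum(corners[i, ]))
    total <- total + sign * log(tab$prob[state_index(matrix(s, nrow = 1), ar)])
  }
  to_base(total, base)
}

#' Enumerate and symmetrise categorical interactions
#'
#' `enumerate_categorical_interactions()` evaluates [categorical_mfi()] for
#' every combination of strictly increasing transitions of the table's
#' variables (for three four-letter variables: \eqn{6^3 = 216} of them).
#' `symmetrized_interaction()` is their sum; for the dyadic distribution it
#' is 0 and for the triadic distribution \eqn{64 \log(\epsilon / p)},
#' separating two distributions that share all Shannon-type measures.
#'
#' @inheritParams mfi
#' @return A tibble with one `<var>_from`/`<var>_to` column pair per
#'   variable plus `value` and `finite`; or the scalar sum.
#' @export
enumerate_categorical_interactions <- function(x, within = NULL, base = NULL) {
  assert_joint_table(x)
  within <- within %||% jt_vars(x)
  tab <- marginalize(x, within)
  ar <- jt_arities(tab)
  vars <- jt_vars(tab)
  per_var <- lapply(vars, function(v) {
    pairs <- utils::combn(0:(ar[[v]] - 1L), 2)
    lapply(seq_len(ncol(pairs)), function(j) pairs[, j])
  })
  idx <- as.matrix(expand.grid(lapply(per_var, seq_along), KEEP.OUT.ATTRS = FALSE))
  transition_at <- function(i) {
    stats::setNames(lapply(seq_along(vars), function(j) per_var[[j]][[idx[i, j]]]),
                    vars)
  }
  vals <- vapply(seq_len(nrow(idx)), function(i) {
    categorical_mfi(tab, transition_at(i), base = base)
  }, numeric(1))
  cols <- list()
  for (j in seq_along(vars)) {
    fr <- vapply(idx[, j], function(i) per_var[[j]][[i]][1], numeric(1))
    to <- vapply(idx[, j], function(i) per_var[[j]][[i]][2], numeric(1))
    cols[[paste0(vars[j], "_from")]] <- fr
    cols[[paste0(vars[j], "_to")]] <- to
  }
  tibble::as_tibble(c(cols, list(value = vals, finite = is.finite(vals))))
}

#' @rdname enumerate_categorical_interactions
#' @export
symmetrized_interaction <- function(x, within = NULL, base = NULL) {
  sum(enumerate_categorical_interactions(x, within = within, base = base)$value)
}

#' Markov blankets and conditioning sets from a causal graph
#'
#' An n-point MFI can be nonzero only if the n variables lie in each other's
#' minimal Markov blanket, so when a causal DAG is known the stringent
#' all-other-variables background can be reduced to the union of blankets:
#' parents, children, and co-parents of the interacting set. Interactions
#' computed with only the blanket held at 0 agree with the fully conditioned
#' value whenever the omitted variables are conditionally independent of
#' `tau` given the blanket; otherwise the omission biases the estimate (by
#' an amount proportional to the pointwise mutual information of the states
#' where the omitted variables are 0).
#'
#' @param graph A two-column data frame of directed edges (`from`, `to`) or
#'   an igraph object; must be acyclic.
#' @param node,tau Variable name(s).
#' @return Character vector of variables; `conditioning_set()` includes
#'   `tau` itself, so it can be passed directly as `within` to [mfi()].
#' @examples
#' g <- dag_preset("chain")
#' conditioning_set(g, c("A", "C"))
#' @export
markov_blanket <- function(graph, node) {
  g <- as_dag(graph)
  nodes <- igraph::V(g)$name
  if (!node %in% nodes) abort("Unknown node.", class = "mfi_error_vars")
  parents <- names(igraph::neighbors(g, node, mode = "in"))
  children <- names(igraph::neighbors(g, node, mode = "out"))
  coparents <- unique(unlist(lapply(children, function(ch)
    names(igraph::neighbors(g, ch, mode = "in")))))
  setdiff(unique(c(parents, children, coparents)), node)
}

#' @rdname markov_blanket
#' @export
conditioning_set <- function(graph, tau) {
  blankets <- unlist(lapply(tau, function(v) markov_blanket(graph, v)))
  g <- as_dag(graph)
  nodes <- igraph::V(g)$name
  intersect(nodes, unique(c(tau, blankets)))
}

as_dag <- function(graph) {
  g <- if (inherits(graph, "igraph")) graph else {
    igraph::graph_from_data_frame(as.data.frame(graph), directed = TRUE)
  }
  if (!igraph::is_dag(g)) abort("Graph must be acyclic.", class = "mfi_error_cycle")
  g
}

#' Scan all interactions of a table
#'
#' Evaluates the (dual) model-free interaction of every nonempty subset of
#' `within` up to `max_order`. Returns one row per subset with a finiteness
#' flag, so tables containing zero-probability background states scan to
#' completion.
#'
#' @inheritParams mfi
#' @param max_order Largest interaction order to compute.
#' @param dual Compute [dual_mfi()] instead of [mfi()].
#' @return A tibble of class `interaction_scan` with columns `variables`,
#'   `order`, `value`, `finite`, `dual`.
#' @examples
#' interaction_scan(gate_table("XNOR", p = 0.2, eps = 0.05))
#' @export
interaction_scan <- function(x, max_order = NULL, within = NULL, dual = FALSE,
                             base = NULL) {
  within <- within %||% jt_vars(x)
  tab <- prep_background(x, character(0), within)
  max_order <- max_order %||% length(within)
  subs <- Filter(function(s) length(s) >= 1 && length(s) <= max_order,
                 subsets_of(jt_vars(tab)))
  fun <- if (dual) dual_mfi else mfi
  vals <- vapply(subs, function(s) fun(tab, s, base = base), numeric(1))
  out <- tibble::tibble(
    variables = vapply(subs, set_label, character(1)),
    order = lengths(subs),
    value = vals,
    finite = is.finite(vals),
    dual = dual
  )
  out <- out[order(out$order, out$variables), ]
  tibble::new_tibble(out, nrow = nrow(out), within = jt_vars(tab),
                     base = energy_base(base), class = "interaction_scan")
}

#' Extract generalised Ising couplings
#'
#' The full interaction set of a binary table, named in the `":"`-joined
#' form accepted by [boltzmann_table()]; for a table built by
#' `boltzmann_table(J)` this returns `J` exactly (the inverse Ising
#' solution).
#'
#' @inheritParams mfi
#' @return Named numeric vector of couplings.
#' @export
extract_couplings <- function(x, within = NULL, base = NULL) {
  scan <- interaction_scan(x, within = within, base = base)
  stats::setNames(scan$value, gsub(",", ":", scan$variables, fixed = TRUE))
}

#' @export
tidy.interaction_scan <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.interaction_scan <- function(x, ...) {
  tibble::tibble(
    n_vars = length(attr(x, "within")),
    n_interactions = nrow(x),
    max_order = max(x$order),
    n_nonfinite = sum(!x$finite),
    max_abs_value = max(abs(x$value[x$finite]), 0),
    dual = x$dual[1]
  )
}
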