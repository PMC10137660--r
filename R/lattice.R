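#' Finite posets and lattices
#'
#' The algebraic engine behind every information and interaction quantity in
#' this package: finite partially ordered sets, their Moebius functions, and
#' Moebius inversion. Three constructors cover the lattices that arise in
#' practice:
#'
#' * [subset_lattice()] -- the Boolean algebra of all subsets of a ground set
#'   of variables, ordered by inclusion. Its Hasse diagram is an n-cube; the
#'   Moebius function has the closed form \eqn{\mu(x, y) = (-1)^{|y| - |x|}}.
#' * [chain_lattice()] -- the product of chains \eqn{0 < 1 < \dots < k_i - 1},
#'   one per categorical variable, ordered componentwise. This is the state
#'   lattice on which categorical interactions live.
#' * [poset()] -- an arbitrary finite poset given by its order relation, used
#'   mainly for cross-checks of the Moebius recursion.
#'
#' [dual_lattice()] reverses the order of any of these; the dual of a lattice
#' is again a lattice, with top and bottom exchanged.
#'
#' Elements are referred to in "user form": character vectors of variable
#' names for subset lattices (the empty set is `character(0)`), integer code
#' vectors for chain lattices, and labels for generic posets.
#'
#' @param ground Character vector of variable names; order is significant and
#'   fixed at construction (results downstream are order-invariant).
#' @param arities Integer vector (optionally named) of per-variable arities,
#'   each at least 2.
#' @param leq Logical matrix: `leq[i, j]` is `TRUE` iff element i <= element j.
#'   Must be reflexive, antisymmetric and transitive.
#' @param labels Character vector of element labels for a generic poset.
#' @param lattice A poset built by one of the constructors here.
#' @return A poset object (class `mfi_poset`).
#' @examples
#' P <- subset_lattice(c("X", "Y"))
#' moebius(P, character(0), c("X", "Y"))   # (-1)^2 = 1
#' lattice_top(dual_lattice(P))            # the empty set
#' @name lattice
NULL

new_poset <- function(leq, elements, labels, kind, extra = list()) {
  p <- c(list(leq = leq, elements = elements, labels = labels, kind = kind,
              cache = new.env(parent = emptyenv())),
         extra)
  class(p) <- c(paste0("mfi_", kind, "_lattice"), "mfi_poset")
  p
}

#' @rdname lattice
#' @export
subset_lattice <- function(ground) {
  assert_character_vars(ground, "ground")
  n <- length(ground)
  if (n > 12) {
    abort("subset_lattice() enumerates 2^n elements; n > 12 is not supported.",
          class = "mfi_error_too_large")
  }
  masks <- seq_len(2^n) - 1L
  leq <- outer(masks, masks, function(a, b) bitwAnd(a, b) == a)
  elements <- subsets_of(ground)
  labels <- vapply(elements, function(e) if (length(e)) set_label(e) else "{}",
                   character(1))
  new_poset(leq, elements, labels, kind = "subset",
            extra = list(ground = ground))
}

#' @rdname lattice
#' @export
chain_lattice <- function(arities) {
  if (!is.numeric(arities) || any(arities < 2)) {
    abort("`arities` must be integers >= 2.", class = "mfi_error_arity")
  }
  arities <- as.integer(arities)
  if (prod(arities) > 2^14) {
    abort("chain_lattice() would enumerate too many elements.",
          class = "mfi_error_too_large")
  }
  grid <- as.matrix(expand.grid(lapply(arities, function(k) 0:(k - 1L)),
                                KEEP.OUT.ATTRS = FALSE))
  dimnames(grid) <- NULL
  elements <- lapply(seq_len(nrow(grid)), function(i) {
    stats::setNames(grid[i, ], names(arities))
  })
  m <- nrow(grid)
  leq <- matrix(FALSE, m, m)
  for (j in seq_len(m)) {
    leq[, j] <- rowSums(grid <= rep(grid[j, ], each = m)) == ncol(grid)
  }
  new_poset(leq, elements, vapply(elements, set_label, character(1)),
            kind = "chain", extra = list(arities = arities))
}

#' @rdname lattice
#' @export
poset <- function(leq, labels = NULL) {
  leq <- as.matrix(leq)
  m <- nrow(leq)
  if (ncol(leq) != m) abort("`leq` must be square.", class = "mfi_error_poset")
  mode(leq) <- "logical"
  if (!all(diag(leq))) abort("`leq` must be reflexive.", class = "mfi_error_poset")
  if (any(leq & t(leq) & !diag(TRUE, m))) {
    abort("`leq` must be antisymmetric.", class = "mfi_error_poset")
  }
  # transitivity: leq %*% leq reaches nothing outside leq
  if (any((leq %*% leq > 0) & !leq)) {
    abort("`leq` must be transitive.", class = "mfi_error_poset")
  }
  labels <- labels %||% as.character(seq_len(m))
  new_poset(leq, as.list(labels), labels, kind = "generic")
}

#' @rdname lattice
#' @export
dual_lattice <- function(lattice) {
  stopifnot(inherits(lattice, "mfi_poset"))
  if (lattice$kind == "dual") return(lattice$base)
  new_poset(t(lattice$leq), lattice$elements, lattice$labels,
            kind = "dual", extra = list(base = lattice))
}

#' @rdname lattice
#' @export
lattice_elements <- function(lattice) lattice$elements

#' @rdname lattice
#' @export
lattice_top <- function(lattice) {
  lattice$elements[[which(colSums(lattice$leq) == nrow(lattice$leq))[1]]]
}

#' @rdname lattice
#' @export
lattice_bottom <- function(lattice) {
  lattice$elements[[which(rowSums(lattice$leq) == nrow(lattice$leq))[1]]]
}

# map a user-form element to its index, with an element-not-found error
el_index <- function(p, x) {
  idx <- switch(
    p$kind,
    subset = {
      if (is.null(x)) x <- character(0)
      pos <- match(x, p$ground)
      if (anyNA(pos)) NA_integer_ else as.integer(1L + sum(2^(pos - 1L)))
    },
    chain = {
      x <- as.integer(x)
      if (length(x) != length(p$arities) || any(x < 0) || any(x >= p$arities)) {
        NA_integer_
      } else {
        as.integer(1L + sum(x * cumprod(c(1L, utils::head(p$arities, -1L)))))
      }
    },
    dual = el_index(p$base, x),
    generic = if (is.character(x)) match(x, p$labels) else as.integer(x)
  )
  if (is.na(idx) || idx < 1L || idx > nrow(p$leq)) {
    abort("Element not found in poset.", class = "mfi_error_element_not_found")
  }
  idx
}

#' Is x below y in a poset?
#'
#' @param lattice A poset.
#' @param x,y Elements in user form.
#' @return Logical scalar.
#' @export
poset_leq <- function(lattice, x, y) {
  lattice$leq[el_index(lattice, x), el_index(lattice, y)]
}

# Moebius function by the defining recursion, memoised per (poset, x):
# mu(x, x) = 1; mu(x, y) = -sum_{x <= z < y} mu(x, z); 0 if x is not below y.
# mu(x, z) depends only on the interval [x, z], so one dynamic-programming
# pass over the upset of x (in a linear extension) fills in every value.
moebius_recursive_idx <- function(p, xi, yi) {
  if (xi == yi) return(1L)
  if (!p$leq[xi, yi]) return(0L)
  key <- as.character(xi)
  mu_x <- get0(key, envir = p$cache)
  if (!is.null(mu_x)) return(mu_x[yi])
  mu_x <- integer(nrow(p$leq))
  up <- which(p$leq[xi, ])
  up <- up[order(colSums(p$leq[up, up, drop = FALSE]))]  # a linear extension
  for (z in up) {
    if (z == xi) {
      mu_x[z] <- 1L
    } else {
      strictly_below <- up[p$leq[up, z] & up != z]
      mu_x[z] <- -sum(mu_x[strictly_below])
    }
  }
  assign(key, mu_x, envir = p$cache)
  mu_x[yi]
}

# closed forms, used as fast paths where they are proven equal to the recursion
moebius_closed_idx <- function(p, xi, yi) {
  if (!p$leq[xi, yi]) return(0L)
  switch(
    p$kind,
    subset = {
      rank_diff <- length(p$elements[[yi]]) - length(p$elements[[xi]])
      as.integer((-1L)^rank_diff)
    },
    chain = {
      d <- p$elements[[yi]] - p$elements[[xi]]
      if (all(d <= 1L)) as.integer((-1L)^sum(d)) else 0L
    },
    dual = moebius_idx(p$base, yi, xi, method = "auto"),
    NULL
  )
}

moebius_idx <- function(p, xi, yi, method = "auto") {
  if (method == "auto") {
    v <- moebius_closed_idx(p, xi, yi)
    if (!is.null(v)) return(v)
  }
  moebius_recursive_idx(p, xi, yi)
}

#' Moebius function of a poset
#'
#' \eqn{\mu(x, y)} is 1 when `x == y`, \eqn{-\sum_{x \le z < y} \mu(x, z)}
#' when `x < y`, and 0 otherwise; it is the inverse of the zeta function in
#' the incidence algebra. On a Boolean (subset) lattice it equals
#' \eqn{(-1)^{|y| - |x|}}; on a chain product it is the product of per-chain
#' values (nonzero only on unit cells). These closed forms are used as fast
#' paths; `method = "recursive"` forces the defining recursion.
#'
#' @inheritParams poset_leq
#' @param method `"auto"` (closed form where available) or `"recursive"`.
#' @return An integer.
#' @examples
#' L <- chain_lattice(c(3, 3))
#' moebius(L, c(1, 1), c(2, 2))  #  1
#' moebius(L, c(2, 1), c(2, 2))  # -1
#' moebius(L, c(0, 1), c(2, 2))  #  0
#' @export
moebius <- function(lattice, x, y, method = c("auto", "recursive")) {
  method <- match.arg(method)
  moebius_idx(lattice, el_index(lattice, x), el_index(lattice, y), method)
}

# evaluate g (a function of user-form elements, or a label-named vector)
# on a set of element indices
eval_on_elements <- function(g, p, idx) {
  if (is.function(g)) {
    vapply(idx, function(i) as.numeric(g(p$elements[[i]])), numeric(1))
  } else {
    v <- unname(g[p$labels[idx]])
    if (anyNA(v) && !anyNA(g)) {
      abort("`g` is not defined on every element below `y`.",
            class = "mfi_error_undefined")
    }
    as.numeric(v)
  }
}

#' Moebius inversion and its inverse zeta sum
#'
#' `moebius_inversion()` computes \eqn{f(y) = \sum_{x \le y} \mu(x, y) g(x)},
#' the poset generalisation of finite differencing; `zeta_sum()` computes
#' \eqn{g(y) = \sum_{x \le y} f(x)}, its two-sided inverse. On the chain
#' \eqn{0 < 1 < 2 < \dots} the pair reduces to differencing and cumulative
#' summation -- a discrete fundamental theorem of calculus.
#'
#' Non-finite values of `g` propagate into the result rather than raising.
#'
#' @param g,f A function taking an element in user form, or a numeric vector
#'   named by element labels (see [lattice_elements()]).
#' @inheritParams poset_leq
#' @param y Target element in user form.
#' @return A numeric scalar.
#' @examples
#' P <- subset_lattice(c("X", "Y"))
#' moebius_inversion(function(s) 1, P, c("X", "Y"))  # 1 - 2 + 1 = 0
#' @export
moebius_inversion <- function(g, lattice, y) {
  yi <- el_index(lattice, y)
  below <- which(lattice$leq[, yi])
  mu <- vapply(below, function(xi) moebius_idx(lattice, xi, yi), integer(1))
  sum(as.numeric(mu) * eval_on_elements(g, lattice, below))
}

#' @rdname moebius_inversion
#' @export
zeta_sum <- function(f, lattice, y) {
  yi <- el_index(lattice, y)
  below <- which(lattice$leq[, yi])
  sum(eval_on_elements(f, lattice, below))
}

#' @export
print.mfi_poset <- function(x, ...) {
  cat(sprintf("<mfi poset: %s, %d elements>\n", x$kind, nrow(x$leq)))
  invisible(x)
}
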