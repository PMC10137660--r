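#' Three-node causal DAG presets
#'
#' Edge lists for the four standard three-node structures: the chain
#' `A -> B -> C`, the fork `B <- A -> C`, the collider `A -> C <- B`, and
#' the collider with an extra edge between the parents
#' (`A -> B`, `A -> C`, `B -> C`).
#'
#' @param name One of `"chain"`, `"fork"`, `"collider"`, `"collider_edge"`.
#' @return A tibble with columns `from`, `to`.
#' @export
dag_preset <- function(name = c("chain", "fork", "collider", "collider_edge")) {
  name <- match.arg(name)
  edges <- switch(name,
    chain = list(c("A", "B"), c("B", "C")),
    fork = list(c("A", "B"), c("A", "C")),
    collider = list(c("A", "C"), c("B", "C")),
    collider_edge = list(c("A", "B"), c("A", "C"), c("B", "C"))
  )
  tibble::tibble(
    from = vapply(edges, `[`, character(1), 1),
    to = vapply(edges, `[`, character(1), 2)
  )
}

#' Simulate binary data from a causal DAG
#'
#' Orphan (parentless) nodes draw from a Bernoulli with success probability
#' `root_p`. Every other node is set, in topological order, to the product
#' (`"multiplicative"`) or the mean (`"additive"`) of its already-resolved
#' parents, plus zero-mean Gaussian noise of variance `sigma2`, then
#' thresholded to `{0, 1}` at 0.5 (values below 0 or above 1 therefore clamp).
#' For chains and forks the two dynamics coincide: each child has one parent
#' and the update is a noisy copy.
#'
#' @param dag Edge-list data frame (`from`, `to`) or igraph DAG.
#' @param n Number of observations.
#' @param dynamics `"multiplicative"` or `"additive"`.
#' @param root_p Bernoulli success probability of orphan nodes.
#' @param sigma2 Gaussian noise variance (`>= 0`).
#' @param seed Optional integer seed; runs with the same seed are
#'   bit-reproducible.
#' @return A tibble of 0/1 integer columns, one per node.
#' @examples
#' s <- simulate_dag(dag_preset("collider"), n = 1000,
#'                   dynamics = "multiplicative", sigma2 = 0, seed = 1)
#' all(s$C == s$A * s$B)
#' @export
simulate_dag <- function(dag, n = 10000, dynamics = c("multiplicative", "additive"),
                         root_p = 0.5, sigma2 = 0.1, seed = NULL) {
  dynamics <- match.arg(dynamics)
  if (root_p <= 0 || root_p >= 1) abort("Need 0 < root_p < 1.", class = "mfi_error_arg")
  if (sigma2 < 0) abort("Need sigma2 >= 0.", class = "mfi_error_arg")
  g <- as_dag(dag)
  if (!is.null(seed)) set.seed(seed)
  order <- names(igraph::topo_sort(g))
  cols <- vector("list", length(order))
  names(cols) <- order
  for (v in order) {
    parents <- names(igraph::neighbors(g, v, mode = "in"))
    if (length(parents) == 0) {
      val <- stats::rbinom(n, 1L, root_p)
    } else {
      pm <- do.call(cbind, cols[parents])
      base <- if (dynamics == "multiplicative") {
        apply(pm, 1, prod)
      } else {
        rowMeans(pm)
      }
      if (sigma2 > 0) base <- base + stats::rnorm(n, 0, sqrt(sigma2))
      val <- as.integer(base >= 0.5)
    }
    cols[[v]] <- val
  }
  tibble::as_tibble(cols[sort(order)])
}

# --- count-based estimators for three binary variables --------------------

# coefficient matrix of the MFIs over log state probabilities: one row per
# nonempty subset tau, entry (-1)^{|tau| - |s /\ tau|} on states s <= tau
# (as bit patterns), 0 elsewhere; row sums vanish, so unnormalised log
# counts can stand in for log probabilities.
mfi_coefficients <- function(n_vars) {
  grid <- as.matrix(expand.grid(rep(list(0:1), n_vars), KEEP.OUT.ATTRS = FALSE))
  subs <- subsets_of(seq_len(n_vars))[-1]
  coef <- matrix(0, length(subs), nrow(grid))
  for (i in seq_along(subs)) {
    tau <- subs[[i]]
    outside <- setdiff(seq_len(n_vars), tau)
    inside <- rowSums(grid[, outside, drop = FALSE]) == 0
    coef[i, inside] <- (-1)^(length(tau) - rowSums(grid[inside, tau, drop = FALSE]))
  }
  list(coef = coef, subsets = subs)
}

# co-information (in bits) of each column of an 8 x B count matrix
coinfo_from_counts <- function(counts, n_vars = 3) {
  grid <- as.matrix(expand.grid(rep(list(0:1), n_vars), KEEP.OUT.ATTRS = FALSE))
  total <- colSums(counts)
  out <- 0
  for (eta in subsets_of(seq_len(n_vars))[-1]) {
    idx <- as.integer(grid[, eta, drop = FALSE] %*% 2^(seq_along(eta) - 1)) + 1L
    marg <- rowsum(counts, idx)
    p <- sweep(marg, 2, total, "/")
    h <- -colSums(xlogx(p)) / log(2)
    out <- out + (-1)^(length(eta) + 1) * h
  }
  out
}

#' Association-metric comparison panel
#'
#' Computes, for three binary columns, every association metric compared in
#' the causal-dynamics experiments: per-pair Pearson correlation, per-pair
#' partial correlation (correlation of the residuals after regressing each
#' member on the third variable), pairwise mutual information, the 3-point
#' mutual information (co-information), and all model-free interactions up
#' to order 3.
#'
#' Correlations and partial correlations carry their standard asymptotic
#' p-values, and pairwise mutual information the G-test of independence
#' (\eqn{2 n \, MI_{nats} \sim \chi^2_1}). The signed quantities -- the
#' 3-point MI and every MFI -- are assessed by a seeded nonparametric
#' bootstrap (multinomial resampling of the 8 state counts, equivalent to
#' resampling rows): significant when the percentile interval at level
#' `alpha` excludes zero. A constant column makes the metrics that involve
#' it undefined (`NA`, flagged).
#'
#' @param samples Data frame with exactly three 0/1 columns, `>= 100` rows.
#' @param n_boot Bootstrap resamples for the MFI / 3-point-MI intervals.
#' @param alpha Significance level.
#' @param smoothing Pseudocount per state for the plug-in estimates.
#' @param seed Optional seed for the bootstrap.
#' @return A tibble of class `assoc_panel` with columns `metric`,
#'   `variables`, `order`, `value`, `p_value`, `ci_lower`, `ci_upper`,
#'   `significant`, `defined`. MFIs are in natural-log units, MI in bits.
#' @export
association_panel <- function(samples, n_boot = 500, alpha = 0.05,
                              smoothing = 0, seed = NULL) {
  df <- as.data.frame(samples)
  if (ncol(df) != 3) abort("Need exactly three columns.", class = "mfi_error_vars")
  m <- as.matrix(df)
  mode(m) <- "integer"
  n <- nrow(m)
  if (n < 100) abort("Need at least 100 observations.", class = "mfi_error_empty")
  if (anyNA(m) || !all(m %in% 0:1)) {
    abort("Columns must be 0/1.", class = "mfi_error_state")
  }
  if (!is.null(seed)) set.seed(seed)
  vars <- colnames(m)
  arities <- stats::setNames(rep(2L, 3), vars)
  defined_var <- apply(m, 2, function(v) length(unique(v)) > 1)

  counts <- tabulate(state_index(m, arities), nbins = 8L)
  phat <- (counts + smoothing) / (n + 8 * smoothing)
  mc <- mfi_coefficients(3)
  sub_names <- vapply(mc$subsets, function(s) set_label(vars[s]), character(1))
  sub_defined <- vapply(mc$subsets, function(s) all(defined_var[s]), logical(1))
# masked product: only the states a subset's coefficient touches may
  # contribute, so a zero count elsewhere cannot inject 0 * -Inf = NaN
  mfi_rows <- function(logp) {
    t(vapply(seq_len(nrow(mc$coef)), function(i) {
      nz <- mc$coef[i, ] != 0
      as.numeric(mc$coef[i, nz, drop = FALSE] %*% logp[nz, , drop = FALSE])
    }, numeric(ncol(logp))))
  }
  mfi_hat <- as.numeric(mfi_rows(matrix(log(phat), ncol = 1)))

  # bootstrap the signed quantities (normalisation cancels row-wise)
  bc <- stats::rmultinom(n_boot, n, phat) + smoothing
  mfi_boot <- mfi_rows(log(bc))
  mi3_boot <- coinfo_from_counts(bc)
  ci <- function(reps) stats::quantile(reps, c(alpha / 2, 1 - alpha / 2),
                                       names = FALSE, na.rm = TRUE)

  rows <- list()
  pairs <- utils::combn(3, 2)
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]; i3 <- setdiff(1:3, c(i1, i2))
    lab <- set_label(vars[c(i1, i2)])
    ok <- defined_var[i1] && defined_var[i2]
    # Pearson
    if (ok) {
      ct <- stats::cor.test(m[, i1], m[, i2])
      rows[[length(rows) + 1]] <- panel_row("pearson", lab, 2L,
        unname(ct$estimate), ct$p.value, NA, NA, ct$p.value < alpha, TRUE)
    } else {
      rows[[length(rows) + 1]] <- panel_row("pearson", lab, 2L)
    }
    # partial correlation via residuals against the third variable
    if (ok && defined_var[i3]) {
      r1 <- stats::lm.fit(cbind(1, m[, i3]), m[, i1])$residuals
      r2 <- stats::lm.fit(cbind(1, m[, i3]), m[, i2])$residuals
      if (stats::sd(r1) > 0 && stats::sd(r2) > 0) {
        r <- stats::cor(r1, r2)
        tstat <- r * sqrt((n - 3) / max(1 - r^2, .Machine$double.eps))
        pv <- 2 * stats::pt(-abs(tstat), df = n - 3)
        rows[[length(rows) + 1]] <- panel_row("partial_cor", lab, 2L,
          r, pv, NA, NA, pv < alpha, TRUE)
      } else {
        rows[[length(rows) + 1]] <- panel_row("partial_cor", lab, 2L)
      }
    } else {
      rows[[length(rows) + 1]] <- panel_row("partial_cor", lab, 2L)
    }
    # pairwise MI with G-test
    if (ok) {
      pair_tab <- estimate_joint(df[, c(i1, i2)], smoothing = smoothing,
                                 arities = arities[c(i1, i2)])
      mi <- mutual_information(pair_tab, vars[c(i1, i2)], base = 2)
      g_stat <- 2 * n * mi * log(2)
      pv <- stats::pchisq(g_stat, df = 1, lower.tail = FALSE)
      rows[[length(rows) + 1]] <- panel_row("mi", lab, 2L, mi, pv, NA, NA,
                                            pv < alpha, TRUE)
    } else {
      rows[[length(rows) + 1]] <- panel_row("mi", lab, 2L)
    }
  }
  # 3-point MI (co-information)
  if (all(defined_var)) {
    mi3 <- coinfo_from_counts(matrix(counts + smoothing, ncol = 1))[1]
    q <- ci(mi3_boot)
    rows[[length(rows) + 1]] <- panel_row("mi", set_label(vars), 3L, mi3, NA,
      q[1], q[2], isTRUE(q[1] > 0 || q[2] < 0), TRUE)
  } else {
    rows[[length(rows) + 1]] <- panel_row("mi", set_label(vars), 3L)
  }
  # MFIs, orders 1..3
  for (i in seq_along(mc$subsets)) {
    if (sub_defined[i]) {
      q <- ci(mfi_boot[i, ])
      sig <- if (is.finite(mfi_hat[i])) isTRUE(q[1] > 0 || q[2] < 0) else NA
      rows[[length(rows) + 1]] <- panel_row("mfi", sub_names[i],
        length(mc$subsets[[i]]), mfi_hat[i], NA, q[1], q[2], sig, TRUE)
    } else {
      rows[[length(rows) + 1]] <- panel_row("mfi", sub_names[i],
                                            length(mc$subsets[[i]]))
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- out[order(match(out$metric, c("pearson", "partial_cor", "mi", "mfi")),
                   out$order, out$variables), ]
  tibble::new_tibble(out, nrow = nrow(out), n = n, n_boot = n_boot,
                     alpha = alpha, class = "assoc_panel")
}

panel_row <- function(metric, variables, order, value = NA_real_,
                      p_value = NA_real_, ci_lower = NA_real_,
                      ci_upper = NA_real_, significant = NA, defined = FALSE) {
  tibble::tibble(metric = metric, variables = variables, order = order,
                 value = as.numeric(value), p_value = as.numeric(p_value),
                 ci_lower = as.numeric(ci_lower), ci_upper = as.numeric(ci_upper),
                 significant = significant, defined = defined)
}

#' Sign/support pattern of a panel metric
#'
#' Collapses an [association_panel()] to the qualitative signature used to
#' compare dynamics: for each reported set of variables, `+`/`-` when the
#' metric is significant, `0` when not, `?` when undefined. The six
#' dynamics (4 DAGs x 2 dynamics, chains and forks collapsing) yield six
#' distinct MFI patterns, while correlation and mutual information each
#' yield far fewer.
#'
#' @param panel An [association_panel()] result.
#' @param metric Which metric to summarise (`"mfi"`, `"pearson"`,
#'   `"partial_cor"`, `"mi"`).
#' @param min_order Smallest order to include (default 2: association
#'   structure, not baseline rates).
#' @return A single string, e.g. `"A,B:+ A,C:0 B,C:+ A,B,C:0"`.
#' @export
mfi_pattern <- function(panel, metric = "mfi", min_order = 2) {
  rows <- panel[panel$metric == metric & panel$order >= min_order, ]
  sym <- ifelse(!rows$defined | is.na(rows$significant), "?",
         ifelse(!rows$significant, "0", ifelse(rows$value > 0, "+", "-")))
  paste(paste0(rows$variables, ":", sym), collapse = " ")
}

#' @export
tidy.assoc_panel <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.assoc_panel <- function(x, ...) {
  tibble::tibble(
    n = attr(x, "n"),
    n_boot = attr(x, "n_boot"),
    alpha = attr(x, "alpha"),
    n_metrics = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    mfi_pattern = mfi_pattern(x)
  )
}
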