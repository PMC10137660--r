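test_that("Boolean derivatives difference, commute, and expand to signed sums", {
  f_const <- function(s) 42
  d <- boolean_derivative(f_const, "X")
  expect_equal(d(c(X = 0, Y = 1)), 0)

  f_prod <- function(s) s[["X"]] * s[["Y"]]
  d2 <- boolean_derivative(boolean_derivative(f_prod, "X"), "Y")
  d2_swapped <- boolean_derivative(boolean_derivative(f_prod, "Y"), "X")
  for (x in 0:1) for (y in 0:1) {
    expect_equal(d2(c(X = x, Y = y)), 1)
    expect_equal(d2_swapped(c(X = x, Y = y)), 1)
  }

  # iterated derivative of log p at the zero background equals the
  # (-1)^(#zeros) signed sum, exhaustively on random tables up to n = 4
  set.seed(51)
  for (n in 2:4) {
    tab <- rand_binary_table(n)
    vars <- jt_vars(tab)
    for (tau in list(vars[1:2], vars)) {
      expect_equal(mfi(tab, tau), signed_sum_mfi(tab, tau), tolerance = 1e-10)
    }
  }
})

test_that("MFIs reproduce the low-order log-odds forms and gate values", {
  set.seed(52)
  tab <- rand_binary_table(3)
  v <- jt_vars(tab)
  p <- function(...) jt_prob(tab, c(...))
  # order 1: conditional log odds
  expect_equal(mfi(tab, v[1]),
               log(p(X1 = 1, X2 = 0, X3 = 0) / p(X1 = 0, X2 = 0, X3 = 0)))
  # order 2: log odds ratio
  expect_equal(mfi(tab, v[1:2]),
               log(p(X1 = 1, X2 = 1, X3 = 0) * p(X1 = 0, X2 = 0, X3 = 0) /
                     (p(X1 = 1, X2 = 0, X3 = 0) * p(X1 = 0, X2 = 1, X3 = 0))))

  # independent uniform bits: everything above order 1 vanishes
  uni <- boltzmann_table(stats::setNames(numeric(0), character(0)), triple)
  expect_equal(mfi(uni, c("A", "B")), 0, tolerance = 1e-12)
  expect_equal(mfi(uni, triple), 0, tolerance = 1e-12)

  # gate closed forms: XNOR log(p^4/eps^4), AND 2 log(p/eps)
  p0 <- 0.2; e0 <- 0.05
  expect_equal(mfi(gate_table("XNOR", p = p0, eps = e0), triple),
               log(p0^4 / e0^4), tolerance = 1e-12)
  expect_equal(mfi(gate_table("AND", p = p0, eps = e0), triple),
               log(e0 * p0^3 / (e0^3 * p0)), tolerance = 1e-12)

  # natural-log default, bits on request
  xnor <- gate_table("XNOR", p = p0, eps = e0)
  expect_equal(mfi(xnor, triple, base = 2), log2(p0^4 / e0^4))
})

test_that("derivative and Moebius-inversion routes agree (the core equivalence)", {
  set.seed(53)
  for (rep in 1:25) {
    n <- sample(3:4, 1)
    tab <- rand_binary_table(n)
    vars <- jt_vars(tab)
    for (tau in list(vars[1], vars[1:2], vars[1:3], vars)) {
      expect_equal(mfi_moebius(tab, tau), mfi(tab, tau), tolerance = 1e-10)
    }
  }
})

test_that("MFIs of a Boltzmann table recover the Ising couplings exactly", {
  set.seed(54)
  for (n in 2:4) {
    vars <- LETTERS[seq_len(n)]
    for (rep in 1:3) {
      j <- rand_couplings(vars)
      tab <- boltzmann_table(j, vars)
      j_hat <- extract_couplings(tab)
      expect_equal(unname(j_hat[names(j)]), unname(j), tolerance = 1e-10)
    }
  }
})

test_that("MFIs are permutation invariant and respect restricted backgrounds", {
  set.seed(55)
  tab <- rand_binary_table(4)
  v <- jt_vars(tab)
  expect_equal(mfi(tab, c(v[3], v[1], v[2])), mfi(tab, v[1:3]))
  expect_equal(mfi(tab, rev(v)), mfi(tab, v))

  # an isolated independent variable can be dropped from the background
  inner <- rand_binary_table(3)
  w <- c(0.45, 0.55)
  probs <- as.vector(outer(inner$prob, w))
  prod_tab <- joint_table(cbind(
    rbind(inner[jt_vars(inner)], inner[jt_vars(inner)]),
    W = rep(0:1, each = 8), prob = probs
  ))
  full <- mfi(prod_tab, c("X1", "X2"))
  reduced <- mfi(prod_tab, c("X1", "X2"), within = c("X1", "X2", "X3"))
  expect_equal(full, reduced, tolerance = 1e-12)
})

test_that("dual interactions equal interactions in the all-ones context", {
  set.seed(56)
  tab <- rand_binary_table(3)
  v <- jt_vars(tab)
  p <- function(...) jt_prob(tab, c(...))
  # I*(X) = I(XYZ) + I(YZ) = log(p111 p100 / (p101 p110))
  expect_equal(dual_mfi(tab, v[1]), mfi(tab, v) + mfi(tab, v[2:3]),
               tolerance = 1e-10)
  expect_equal(dual_mfi(tab, v[1]),
               log(p(X1 = 1, X2 = 1, X3 = 1) * p(X1 = 1, X2 = 0, X3 = 0) /
                     (p(X1 = 1, X2 = 0, X3 = 1) * p(X1 = 1, X2 = 1, X3 = 0))),
               tolerance = 1e-10)
  # the empty dual interaction is the signed full interaction
  expect_equal(dual_mfi(tab, character(0)), (-1)^3 * mfi(tab, v),
               tolerance = 1e-10)
  # independent triple: the singleton dual is a pair interaction in the
  # context X = 1, which vanishes under independence
  px <- c(0.3, 0.7); py <- c(0.6, 0.4); pz <- c(0.8, 0.2)
  probs <- as.vector(outer(outer(px, py), pz))
  ind3 <- joint_table(cbind(expand.grid(X = 0:1, Y = 0:1, Z = 0:1),
                            prob = probs))
  expect_equal(dual_mfi(ind3, "X"), 0, tolerance = 1e-12)
  expect_equal(dual_mfi(ind3, "X"),
               mfi(ind3, c("X", "Y", "Z")) + mfi(ind3, c("Y", "Z")),
               tolerance = 1e-12)
})

test_that("a 3-point interaction is the difference of conditioned pair interactions", {
  set.seed(57)
  tab <- rand_binary_table(3)
  v <- jt_vars(tab)
  i3 <- mfi(tab, v)
  for (k in 1:3) {
    rest <- v[-k]
    diff_k <- mfi(condition_on(tab, stats::setNames(1L, v[k])), rest) -
      mfi(condition_on(tab, stats::setNames(0L, v[k])), rest)
    expect_equal(i3, diff_k, tolerance = 1e-10)
  }
})

test_that("J-interactions separate all six gates; the gate identity holds", {
  gates <- c("XNOR", "XOR", "AND", "OR", "NAND", "NOR")
  p0 <- 0.2; e0 <- 0.05
  tabs <- lapply(gates, gate_table, p = p0, eps = e0)
  names(tabs) <- gates
  unit <- gate_unit(tabs[[1]])

  # Table-3 multiples of I for J*_A and the symmetric J-interaction
  ja_expect <- c(XNOR = 3 / 2, XOR = -3 / 2, AND = 1 / 2, OR = -1,
                 NAND = -1 / 2, NOR = 1)
  jbar_expect <- c(XNOR = 27 / 8, XOR = -27 / 8, AND = 3 / 16, OR = -3 / 4,
                   NAND = -3 / 16, NOR = 3 / 4)
  for (g in gates) {
    expect_equal(j_interaction(tabs[[g]], "A") / unit, unname(ja_expect[g]),
                 tolerance = 1e-10)
    expect_equal(symmetric_j(tabs[[g]]) / unit^3, unname(jbar_expect[g]),
                 tolerance = 1e-10)
  }
  # six distinct values
  ja <- vapply(tabs, j_interaction, numeric(1), input = "A")
  expect_equal(length(unique(round(ja, 9))), 6)

  # I_ABC + 2 I_AB = 0 for every gate
  for (g in gates) {
    expect_equal(mfi(tabs[[g]], triple) + 2 * mfi(tabs[[g]], c("A", "B")), 0,
                 tolerance = 1e-10)
  }
})

test_that("interactions zeta-sum back to the background surprisal", {
  set.seed(58)
  tab <- rand_binary_table(3)
  v <- jt_vars(tab)
  # tau = {X, Y}: sum of I over the downset is log p(1, 1, 0)
  expect_equal(surprisal_from_interactions(tab, v[1:2]),
               log(jt_prob(tab, stats::setNames(c(1L, 1L, 0L), v))),
               tolerance = 1e-10)
  # tau = empty: just the all-zeros log-probability
  expect_equal(surprisal_from_interactions(tab, character(0)),
               log(jt_prob(tab, stats::setNames(c(0L, 0L, 0L), v))))
  # every background log-probability is reconstructed
  for (tau in all_subsets(v)) {
    state <- stats::setNames(as.integer(v %in% tau), v)
    expect_equal(surprisal_from_interactions(tab, tau),
                 log(jt_prob(tab, state)), tolerance = 1e-10)
  }
  # uniform table: only the order-0 term survives
  uni <- boltzmann_table(stats::setNames(numeric(0), character(0)), triple)
  expect_equal(surprisal_from_interactions(uni, triple), log(1 / 8),
               tolerance = 1e-12)
})

test_that("categorical interactions: reduction, transitivity, dyadic/triadic", {
  # on binary variables the only increasing transition is 0 -> 1 = the MFI
  set.seed(59)
  tab <- rand_binary_table(3)
  v <- jt_vars(tab)
  tr <- stats::setNames(lapply(v, function(.) c(0, 1)), v)
  expect_equal(categorical_mfi(tab, tr), mfi(tab, v), tolerance = 1e-12)

  # transitivity on a 3-level chain lattice
  ar <- c(X = 3L, Y = 3L)
  set.seed(60)
  cat_tab <- random_joint_table(ar)
  i02 <- categorical_mfi(cat_tab, list(X = c(0, 2), Y = c(0, 1)))
  i01 <- categorical_mfi(cat_tab, list(X = c(0, 1), Y = c(0, 1)))
  i12 <- categorical_mfi(cat_tab, list(X = c(1, 2), Y = c(0, 1)))
  expect_equal(i02, i01 + i12, tolerance = 1e-10)

  expect_error(categorical_mfi(cat_tab, list(X = c(2, 1))),
               class = "mfi_error_invalid_transition")
  expect_error(categorical_mfi(cat_tab, list(X = c(0, 5))),
               class = "mfi_error_invalid_transition")

  # dyadic vs triadic at the full-range transition
  eps <- 1e-4; p <- (1 - 56 * eps) / 8
  full <- list(X = c(0, 3), Y = c(0, 3), Z = c(0, 3))
  expect_equal(categorical_mfi(dyadic_table(eps), full), 0, tolerance = 1e-10)
  expect_equal(categorical_mfi(triadic_table(eps), full), log(eps / p),
               tolerance = 1e-10)

  # 216 increasing transitions; symmetrised sums 0 and 64 log(eps/p)
  enum <- enumerate_categorical_interactions(dyadic_table(eps))
  expect_equal(nrow(enum), 216)
  expect_true(all(enum$finite))
  expect_equal(symmetrized_interaction(dyadic_table(eps)), 0, tolerance = 1e-8)
  expect_equal(symmetrized_interaction(triadic_table(eps)), 64 * log(eps / p),
               tolerance = 1e-8)
})

test_that("Markov blankets bound where interactions can live", {
  chain <- dag_preset("chain")
  expect_setequal(markov_blanket(chain, "B"), c("A", "C"))
  expect_setequal(markov_blanket(chain, "A"), "B")
  expect_setequal(conditioning_set(chain, c("A", "C")), c("A", "B", "C"))

  collider <- dag_preset("collider")
  # co-parents: A and B share the child C
  expect_setequal(markov_blanket(collider, "A"), c("B", "C"))

  full <- dag_preset("collider_edge")
  for (v in c("A", "B", "C")) {
    expect_setequal(c(v, markov_blanket(full, v)), c("A", "B", "C"))
  }

  cyc <- data.frame(from = c("A", "B"), to = c("B", "A"))
  expect_error(markov_blanket(cyc, "A"), class = "mfi_error_cycle")

  # chain dynamics: A and C do not interact once B is held at 0
  s <- simulate_dag(chain, n = 20000, dynamics = "multiplicative",
                    sigma2 = 0.25, seed = 61)
  tab <- estimate_joint(s)
  expect_lt(abs(mfi(tab, c("A", "C"))), 0.15)  # 0 up to sampling noise
})

test_that("interaction scans flag non-finite values and support tidy/glance", {
  xor0 <- gate_table("XOR", p = 0.25, eps = 0)   # illegal states have p = 0
  scan <- interaction_scan(xor0)
  expect_equal(nrow(scan), 7)
  expect_true(any(!scan$finite))
  expect_true(all(is.finite(scan$value[scan$finite])))
  g <- glance(scan)
  expect_equal(g$n_interactions, 7)
  expect_equal(g$n_nonfinite, sum(!scan$finite))

  xnor <- gate_table("XNOR", p = 0.2, eps = 0.05)
  scan2 <- interaction_scan(xnor, max_order = 2)
  expect_equal(max(scan2$order), 2)
  expect_true(all(scan2$finite))
  expect_s3_class(tidy(scan2), "tbl_df")

  dual_scan <- interaction_scan(xnor, dual = TRUE)
  row <- dual_scan[dual_scan$variables == "A", ]
  expect_equal(row$value, dual_mfi(xnor, "A"))
  expect_true(all(dual_scan$dual))
})
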