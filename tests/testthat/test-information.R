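test_that("entropy matches closed forms on gates and trivia", {
  fair <- joint_table(data.frame(X = 0:1, prob = c(0.5, 0.5)))
  expect_equal(entropy(fair, "X"), 1)
  expect_equal(entropy(fair, character(0)), 0)

  xor <- gate_table("XOR", p = 0.25, eps = 0)
  expect_equal(entropy(xor, triple), 2)
  and <- gate_table("AND", p = 0.25, eps = 0)
  expect_equal(entropy(and, "C"),
               -(3 / 4) * log2(3 / 4) - (1 / 4) * log2(1 / 4))
  # 0 log 0 convention: deterministic marginal has zero entropy
  point <- joint_table(data.frame(X = c(0, 1), prob = c(1, 0)))
  expect_equal(entropy(point, "X"), 0)
  # nats on request
  expect_equal(entropy(fair, "X", base = exp(1)), log(2))
})

test_that("gate entropies are degenerate in the two known families", {
  ent5 <- function(g) {
    tab <- gate_table(g, p = 0.25, eps = 0)
    c(entropy(tab, "A"), entropy(tab, "C"), entropy(tab, c("A", "B")),
      entropy(tab, c("A", "C")), entropy(tab, triple))
  }
  for (g in c("XOR", "XNOR")) expect_equal(ent5(g), c(1, 1, 2, 2, 2))
  hc <- 2 - (3 / 4) * log2(3)
  for (g in c("AND", "OR", "NAND", "NOR")) {
    expect_equal(ent5(g), c(1, hc, 2, 1.5, 2))
  }
})

test_that("higher-order mutual information is the alternating entropy sum", {
  xor <- gate_table("XOR", p = 0.25, eps = 0)
  expect_equal(mutual_information(xor, triple), -1)
  expect_equal(mutual_information(gate_table("XNOR", p = 0.25, eps = 0), triple), -1)
  for (g in c("AND", "OR", "NAND", "NOR")) {
    expect_equal(mutual_information(gate_table(g, p = 0.25, eps = 0), triple),
                 1 - (3 / 4) * log2(3), tolerance = 1e-12)
  }
  # and the value is reported to three decimals as -0.189
  expect_equal(round(mutual_information(gate_table("AND", p = 0.25, eps = 0),
                                        triple), 3), -0.189)

  # singleton MI is the entropy; independent variables have zero MI
  set.seed(41)
  tab <- rand_binary_table(3)
  expect_equal(mutual_information(tab, "X2"), entropy(tab, "X2"))
  px <- c(0.3, 0.7); py <- c(0.6, 0.4)
  ind <- joint_table(data.frame(X = c(0, 1, 0, 1), Y = c(0, 0, 1, 1),
                                prob = as.vector(outer(px, py))))
  expect_equal(mutual_information(ind, c("X", "Y")), 0, tolerance = 1e-12)

  # pairwise MI between the two inputs of any gate is zero
  for (g in c("AND", "OR", "NAND", "NOR", "XOR", "XNOR")) {
    expect_equal(mutual_information(gate_table(g, p = 0.2, eps = 0.05),
                                    c("A", "B")), 0, tolerance = 1e-12)
  }
})

test_that("entropy is recovered from mutual information by the signed zeta sum", {
  set.seed(42)
  for (n in 2:4) {
    tab <- rand_binary_table(n)
    vars <- jt_vars(tab)
    for (tau in list(vars[1], vars[1:2], vars)) {
      expect_equal(entropy_from_mi(tab, tau), entropy(tab, tau),
                   tolerance = 1e-10)
    }
  }
  # on XOR the pairwise terms vanish and the triple-MI-plus-marginals
  # expansion holds verbatim
  xor <- gate_table("XOR", p = 0.25, eps = 0)
  expect_equal(entropy(xor, triple),
               mutual_information(xor, triple) +
                 sum(vapply(triple, function(v) entropy(xor, v), numeric(1))))
})

test_that("dual mutual information is the differential MI", {
  set.seed(43)
  tab <- rand_binary_table(3)
  vars <- jt_vars(tab)
  expect_equal(dual_mutual_information(tab, character(0)),
               mutual_information(tab, vars))
  for (v in vars) {
    expect_equal(dual_mutual_information(tab, v),
                 mutual_information(tab, vars) -
                   mutual_information(tab, setdiff(vars, v)),
                 tolerance = 1e-10)
  }
  # explicit four-entropy expansion for a singleton on three variables
  expect_equal(dual_mutual_information(tab, "X1"),
               entropy(tab, "X1") - entropy(tab, c("X1", "X2")) -
                 entropy(tab, c("X1", "X3")) + entropy(tab, vars),
               tolerance = 1e-10)
  # Table-3 values: MI*(A) = -1/2 bit for AND, -1 bit for XNOR
  expect_equal(dual_mutual_information(gate_table("AND", p = 0.25, eps = 0), "A"),
               -0.5, tolerance = 1e-12)
  expect_equal(dual_mutual_information(gate_table("XNOR", p = 0.25, eps = 0), "A"),
               -1, tolerance = 1e-12)
})

test_that("generalised pointwise MI reduces to the classical definition", {
  px <- c(0.3, 0.7); py <- c(0.6, 0.4)
  ind <- joint_table(data.frame(X = c(0, 1, 0, 1), Y = c(0, 0, 1, 1),
                                prob = as.vector(outer(px, py))))
  for (x in 0:1) for (y in 0:1) {
    expect_equal(pointwise_mi(ind, c(X = x, Y = y)), 0, tolerance = 1e-12)
  }

  copied <- joint_table(data.frame(X = c(0, 1), Y = c(0, 1), prob = c(0.5, 0.5)))
  expect_equal(pointwise_mi(copied, c(X = 1, Y = 1)), 1)  # log2(2) = 1 bit
  expect_identical(is.finite(pointwise_mi(copied, c(X = 1, Y = 0))), FALSE)

  # expectation over realizations recovers MI, for 2 and 3 variables
  set.seed(44)
  for (n in 2:3) {
    tab <- rand_binary_table(n)
    vars <- jt_vars(tab)
    states <- as.matrix(tab[vars])
    ex <- sum(vapply(seq_len(nrow(tab)), function(i) {
      tab$prob[i] * pointwise_mi(tab, stats::setNames(states[i, ], vars))
    }, numeric(1)))
    if (n == 2) {
      expect_equal(ex, mutual_information(tab, vars), tolerance = 1e-10)
    } else {
      expect_true(is.finite(ex))  # generalised pmi aggregates but is pointwise
    }
  }
})

test_that("conditional MI is the assignment-weighted average", {
  set.seed(45)
  tab <- rand_binary_table(3)
  # independent entropy identity: MI(X,Y|Z) = H(XZ) + H(YZ) - H(XYZ) - H(Z)
  direct <- entropy(tab, c("X1", "X3")) + entropy(tab, c("X2", "X3")) -
    entropy(tab, c("X1", "X2", "X3")) - entropy(tab, "X3")
  expect_equal(conditional_mutual_information(tab, c("X1", "X2"), "X3"),
               direct, tolerance = 1e-10)
  expect_error(conditional_mutual_information(tab, c("X1", "X2"), "X2"),
               class = "mfi_error_vars")
})

test_that("triple MI is squeezed between the conditional and pairwise bounds", {
  set.seed(46)
  for (rep in 1:300) {
    tab <- rand_binary_table(3)
    v <- jt_vars(tab)
    mi3 <- mutual_information(tab, v)
    pair_min <- min(mutual_information(tab, v[c(1, 2)]),
                    mutual_information(tab, v[c(1, 3)]),
                    mutual_information(tab, v[c(2, 3)]))
    cond_min <- min(
      conditional_mutual_information(tab, v[c(1, 2)], v[3]),
      conditional_mutual_information(tab, v[c(1, 3)], v[2]),
      conditional_mutual_information(tab, v[c(2, 3)], v[1])
    )
    expect_true(mi3 <= pair_min + 1e-10)
    expect_true(mi3 >= -cond_min - 1e-10)
  }
})

test_that("info_scan tabulates H, MI and dual MI with tidy/glance support", {
  and <- gate_table("AND", p = 0.25, eps = 0)
  scan <- info_scan(and)
  expect_s3_class(scan, "info_scan")
  expect_equal(nrow(scan), 7)
  row <- scan[scan$variables == "A,B,C", ]
  expect_equal(row$mi, mutual_information(and, triple))
  expect_equal(row$entropy, 2)
  g <- glance(scan)
  expect_equal(g$n_subsets, 7)
  expect_equal(g$total_entropy, 2)
  expect_s3_class(tidy(scan), "tbl_df")
})
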