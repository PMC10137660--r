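# shared fixtures and small independent oracles for the property tests

# strictly positive random binary table over n variables named X1..Xn
rand_binary_table <- function(n, concentration = 1) {
  random_joint_table(stats::setNames(rep(2L, n), paste0("X", seq_len(n))),
                     concentration = concentration)
}

# random couplings over every nonempty subset of `vars`
rand_couplings <- function(vars, lo = -1, hi = 1) {
  subs <- Filter(length, all_subsets(vars))
  stats::setNames(stats::runif(length(subs), lo, hi),
                  vapply(subs, paste, character(1), collapse = ":"))
}

all_subsets <- function(vars) {
  n <- length(vars)
  lapply(seq_len(2^n) - 1L, function(m) vars[bitwAnd(m, 2^(seq_len(n) - 1L)) > 0L])
}

# independent signed-sum oracle for the iterated Boolean derivative of log p
# evaluated at the all-zero background: sum over assignments s of tau of
# (-1)^{#zeros(s)} log p(tau = s, rest = 0)
signed_sum_mfi <- function(tab, tau) {
  vars <- jt_vars(tab)
  k <- length(tau)
  total <- 0
  for (m in seq_len(2^k) - 1L) {
    bits <- as.integer(bitwAnd(m, 2^(seq_len(k) - 1L)) > 0L)
    state <- stats::setNames(integer(length(vars)), vars)
    state[tau] <- bits
    total <- total + (-1)^(k - sum(bits)) * log(jt_prob(tab, state))
  }
  total
}

# gate unit I = 4 log(p / eps)
gate_unit <- function(tab) {
  4 * log(attr(tab, "gate_p") / attr(tab, "gate_eps"))
}

triple <- c("A", "B", "C")

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}
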