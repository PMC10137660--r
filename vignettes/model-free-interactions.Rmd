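---
title: "Model-free interactions: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-free interactions: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfi)
```

## The model

For a set of binary random variables with joint distribution $p$, the
*model-free interaction* (MFI) of a subset $\tau = \{X_1,\dots,X_n\}$ within a
background set $T$ is the iterated finite difference of $\log p$ with every
variable of $T \setminus \tau$ held at 0:

$$
I_\tau \;=\; \frac{\partial^n \log p}{\partial X_1 \cdots \partial X_n}
\Big|_{T\setminus\tau = 0},
\qquad
\frac{\partial f}{\partial X_i} := f(X_i{=}1,\cdot) - f(X_i{=}0,\cdot).
$$

Expanding the difference gives a signed sum over the $2^n$ assignments $s$ of
$\tau$, with sign $(-1)^{\#\text{zeros}(s)}$: order 1 is a conditional
log-odds, order 2 a log odds ratio, order 3 an eight-state log cross-ratio.
Because $\log p$ of a positive discrete distribution is (up to a constant) an
energy function, $I_S$ equals the coupling $J_S$ of the generalised Ising /
maximum-entropy model that reproduces the distribution — `mfi()` applied to
`boltzmann_table(J)` returns `J` exactly, and the test-suite uses this
round-trip as its flagship oracle.

The second, equivalent route runs through order theory. Define the background
surprisal evaluation $S_{\eta;T} = \log p(\eta{=}1,\,T\setminus\eta{=}0)$ on
the lattice of subsets of $\tau$ ordered by inclusion. Then

$$
I(\tau;T) \;=\; \sum_{\eta \subseteq \tau} \mu(\eta,\tau)\, S_{\eta;T},
\qquad \mu(\eta,\tau) = (-1)^{|\tau|-|\eta|},
$$

a Möbius inversion — the poset generalisation of differencing — exactly
parallel to mutual information being the Möbius inversion of marginal
entropy. `mfi()` implements the derivative route, `mfi_moebius()` the lattice
route; their equality over random tables (to $10^{-10}$) is asserted in the
tests rather than assumed, which is why both implementations exist
independently instead of one calling the other.

Inverting the sum (`surprisal_from_interactions()`, a zeta sum) reconstructs
every background log-probability from the interaction set, so the full
interaction set is a lossless reparameterisation of the distribution.

### Duals

Reversing a lattice's order yields a lattice, so every inversion has a dual.

* **Dual mutual information** (`dual_mutual_information()`): the inversion of
  marginal entropy on the order-reversed subset lattice. For the empty set it
  is the ordinary mutual information among all variables; for a singleton $X$
  it is the differential MI, $MI(T) - MI(T\setminus X)$ — the information
  lost by marginalising $X$ out. It is an *averaged* quantity.
* **Dual interactions** (`dual_mfi()`): the inversion of background surprisal
  on the order-reversed lattice over the background set,
  $I^*(\tau;T) = \sum_{s \supseteq \tau} (-1)^{|s|-|\tau|} \log p(s{=}1,
  T\setminus s{=}0)$. The dual of a singleton $X$ in a triple equals
  $I(X,Y,Z) + I(Y,Z)$, which is the pair interaction of $Y,Z$ *in the context
  $X = 1$* rather than $X = 0$ — a *pointwise* quantity. One caution: the
  compact two-term expansion of a singleton dual in terms of the full and
  reduced interactions carries a sign of $(-1)^{|T|-1}$ on the full term, so
  the familiar "sum of the two" form holds for odd-sized backgrounds (the
  three-variable case) but not verbatim for even ones; `dual_mfi()` always
  evaluates the inversion itself, and the tests pin the three-variable
  identities.

### Categorical variables

On variables with $k$ ordered levels the states form a product of chains
ordered componentwise; the Möbius function of that lattice vanishes except on
unit cells, where it is $\pm 1$ by corner parity. `categorical_mfi()`
evaluates the interaction of per-variable transitions $x_0 \to x_1$ (others
held at 0) as the corner-signed sum over $\{x_0,x_1\}$-hypercubes; multi-step
transitions follow by transitivity,
$I(X{:}0{\to}2,\cdot) = I(X{:}0{\to}1,\cdot) + I(X{:}1{\to}2,\cdot)$, which
the tests check against the lattice directly. For three four-level variables
there are $6^3 = 216$ strictly increasing transition triples;
`symmetrized_interaction()` sums them. This symmetrised quantity separates
the dyadic from the triadic distribution — two distributions deliberately
constructed (from pairwise vs. triplet parity rules on the bit-pair encoding
$\{0,1,2,3\} \to \{00,01,10,11\}$) to share all standard Shannon-type
measures, which `dyadic_table()`/`triadic_table()` provide as fixtures.

## Conventions that matter

* **Log bases.** Interactions are energies: natural log by default
  (`options(mfi.energy_base = )` or per-call `base`). Entropy, MI and
  pointwise MI are information: bits by default (`options(mfi.info_base =)`).
  The gate fixtures' natural unit is $I = 4\log(p/\epsilon)$, base-free.
* **Surprisal sign.** Although surprisal is conventionally $-\log p$, all
  inversions here act on $+\log p(\eta{=}1, \text{rest}{=}0)$; this is the
  sign for which the lattice route coincides with the derivative route.
* **Entropy from MI.** The inverse of the MI definition is the signed zeta
  sum $H(\tau) = \sum_{\eta \subseteq \tau} (-1)^{|\eta|-1} MI(\eta)$. The
  signs alternate with $|\eta|$ — pairwise MI enters $H(X,Y,Z)$ *negatively*;
  the popular all-plus expansion is valid only when all proper-subset MIs
  vanish (e.g. parity gates). `entropy_from_mi()` is tested for equality with
  direct entropy on random tables.
* **Pointwise MI.** `pointwise_mi()` uses the prefactor $(-1)^{|\tau|}$ on
  the inversion of log *marginal* probabilities (with $\log p(\emptyset)=0$),
  fixed by requiring the two-variable case to reduce to
  $\log[p(x,y)/(p(x)p(y))]$; its expectation then equals the MI.
* **Zero probabilities.** Never smoothed silently. `background_surprisal()`
  returns $-\infty$; interactions touching zero-probability states come back
  `-Inf`/`Inf`/`NaN` with a `finite` flag in scan output, so whole-table
  scans complete. Pseudocounts are opt-in (`estimate_joint(smoothing =)`,
  with $\hat p = (c + \alpha)/(M + \alpha K)$).
* **State encoding.** Codes $0,\dots,k-1$ with 1 = "on"; the conditioning
  background is all-zeros everywhere, including for categorical variables.
* **Backgrounds.** `within` names the background set $T$: variables outside
  it are marginalised out, variables inside it but outside $\tau$ are pinned
  to 0. When a causal DAG is known, `conditioning_set()` (parents ∪ children
  ∪ co-parents of $\tau$) gives the smallest sound background: dropping
  variables that are conditionally independent of $\tau$ given the blanket
  leaves the MFI unchanged (tested in that zero-bias case); dropping
  dependent ones biases the estimate by an amount proportional to the
  pointwise mutual information of the states where the omitted variables
  are 0, so the reduction is exposed but never applied automatically.
* **Exact enumeration.** `boltzmann_table()` and the scans enumerate all
  states; construction is guarded at 20 binary variables (tables above that
  size stop being "exact small-system" objects and would need sampling
  methods that are out of scope).

## The synthetic-data generator

`simulate_dag()` emulates the study conditions under which association
metrics are compared: three-node DAGs (chain, fork, collider, collider plus
an edge between the parents), orphan nodes drawn Bernoulli($p$) with
$p = 0.5$, children set to the product (multiplicative) or mean (additive) of
their parents plus $\mathcal N(0, \sigma^2)$ noise with $\sigma^2 = 0.1$ by
default, thresholded to $\{0,1\}$ at $0.5$ (which also clamps values outside
$[0,1]$); $n = 10^4$ observations. The thresholding rule is the package's
choice of rounding convention, exposed nowhere because any monotone rule
differing only at measure-zero points gives the same distributions once
$\sigma > 0$.

Six distinct dynamics arise (chains and forks are dynamics-invariant because
their children have single parents, so mean = product). `association_panel()`
reports Pearson correlation and partial correlation with their standard
asymptotic tests, pairwise MI with the G-test of independence
($2 n\,MI_{\text{nats}} \sim \chi^2_1$), and the signed quantities — the
3-point MI and all MFIs to order 3 — with percentile intervals from a seeded
multinomial bootstrap of the 8 state counts (equivalent to resampling rows,
500 resamples by default, $\alpha = 0.05$). The pairwise-MI deviation from
pure bootstrap is deliberate: the plug-in MI of an independent pair is
positively biased by roughly $1/(2n\ln 2)$ bits, so a bootstrap percentile
interval essentially never covers 0 and would declare everything dependent;
the G-test is the calibrated test of the same null. Where the test-suite
*counts distinct qualitative patterns* across all six scenarios it aggregates
on the order of 27 significance calls per metric, so it tightens the level
Bonferroni-style to $\alpha = 0.002$; the substantive single-scenario
assertions (negative collider-parent MFI; 3-point term present under
multiplicative dynamics, absent under additive) stay at $\alpha = 0.05$.

What the generator does *not* emulate: real data with more than three
variables, unobserved confounding, non-Gaussian or state-dependent noise,
and sample-limited regimes where the all-zeros background state is rare.
Passing tests therefore certify the estimators and their qualitative
resolving power under these controlled dynamics, not performance on real
gene-expression-scale data.

## Numerical choices

* Möbius values are exact integers; the recursive definition (memoised per
  lattice) is the reference implementation, and the Boolean / chain-product
  closed forms are used as fast paths only because the tests prove them equal
  to the recursion exhaustively up to $n = 4$ and against the inverse of the
  zeta matrix on a random poset.
* `boltzmann_table()` subtracts the maximum energy before exponentiating,
  so large couplings cannot overflow.
* Probability validation tolerates $10^{-6}$ total-mass error on input
  (decimal round-trips), while internal constructions are exact to machine
  precision; equality-type tests run at $10^{-10}$–$10^{-12}$.
* Variable order is fixed at construction (bit $i$ of the state index is
  variable $i$); all reported quantities are permutation-invariant in $\tau$,
  and that invariance is itself a test.
* Entropy uses the $0\log 0 = 0$ convention; the empty marginal has zero
  entropy.
* Problem sizes in the suite — exhaustive lattices to $n = 4$, 100 tables
  for the two-route equivalence, 1000 for the MI bound check, $10^4$
  observations and 500–1000 bootstrap resamples per simulation scenario —
  were chosen so each property is exercised across its combinatorial range
  while the whole suite stays desk-scale.

## Limitations

* Interactions are defined for binary and categorical variables only;
  continuous states do not form the lattices the construction needs.
* Exact tables scale as $\prod_i k_i$; beyond ~20 binary variables the
  objects here are the wrong tool.
* Plug-in MFIs need the relevant background states observed: the estimate of
  $I(\tau;T)$ uses the $2^{|\tau|}$ states with $T\setminus\tau = 0$, which
  are rare when $|T|$ is large — this is precisely when the Markov-blanket
  reduction (or more data) is required.
* MFIs condition on all observed variables and carry no interventional
  semantics; a causal reading requires assumptions beyond this package's
  scope, even though the simulator's dynamics happen to be causal.
* Partial information decomposition (synergy/redundancy atoms) is a
  different, complementary formalism and is intentionally not implemented.
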