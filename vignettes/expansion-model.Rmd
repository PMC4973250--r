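---
title: "A burst-and-silence model of repeat-family expansion and its k-mer spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A burst-and-silence model of repeat-family expansion and its k-mer spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatburst)
```

## The model

Selfish DNA families such as the primate Alu SINEs expand by copy-and-paste
duplication during a bounded *burst of activity* and then sit in the genome
accumulating mutations. `repeatburst` implements a minimal two-phase model
of this history:

* at `t = 0` a single **active** element of length `L` appears;
* during the burst, `0 <= t <= T1`, every active element duplicates at rate
  `gamma`; each new copy is itself active with probability `delta` and
  permanently silent otherwise (so `delta = 1` is the classical transposon
  model and `delta -> 0` the master-gene model);
* after the burst all elements are silenced and only mutate, for a further
  time `T2`;
* throughout, every position mutates at the background rate `mu0`, except
  positions inside a CpG dinucleotide, which mutate `cpg_factor` (default 6)
  times faster through the deamination channels C→T and G→A.

All rates are measured in units of `mu0` and times in units of `1/mu0`; a
per-year value of `mu0` enters only through the reporting helpers
(`time_in_years()`, `mu0_from_age()`).

Because the expected number of active elements grows as
`exp(delta * gamma * t)`, the expected total count is

$$N(t) = 1 + \frac{e^{\delta\gamma t} - 1}{\delta},$$

which `expected_copies()` evaluates and `estimate_T1()` inverts. At
`delta = 0` the limit is the linear master-gene growth `1 + gamma * t`.

### The k-mer abundance tail

A k-mer inside an element is destroyed (i.e. turned into a different k-mer)
at rate `mu * k`, where `mu` is the CpG-weighted effective per-site rate

$$\mu = \frac{(L - 2 n_\mathrm{CpG}) + 2 n_\mathrm{CpG}\, c}{L}\,\mu_0,$$

with `c` the CpG factor — `effective_mu(300, 24, 6) = 1.8` for the Alu-like
geometry. During the burst a k-mer lineage is duplicated at the effective
rate `delta * gamma` while new sequence variants are seeded continuously
into an exponentially growing population. The stationary result of that
competition is a power-law abundance tail, `n_k(s) ~ s^{-\alpha(k)}`, with

$$\alpha(k) = 1 + \frac{\delta\gamma}{\delta\gamma - \mu k},$$

valid while a k-mer duplicates faster than it mutates, `mu * k <
delta * gamma`; `alpha_of_k()` raises a structured "no power-law tail"
error outside that domain rather than returning NaN, because the fitting
stages must exclude such k explicitly. Two limits anchor the formula: at
`k -> 0` (or `mu = 0`) it reduces to the Yule clone-size exponent 2, and it
rises without bound as `mu k` approaches `delta gamma`. The silent phase
multiplies the surviving tail by `p_k = exp(-mu k T2)` (`survival_prob()`).
`tail_density()` carries the `N`, `L - k + 1` and `p_k` prefactors; its
absolute normalisation is a tail-mass convention, and every test of it uses
ratio or slope properties that do not depend on that convention.

```{r}
p <- alu_params()
predict_tail(p, k = c(10, 40, 75))
```

## The simulator

`simulate_burst()` is an exact kinetic Monte Carlo implementation of the
burst: waiting times drawn from the aggregate exponential rate
`gamma * (number of active elements)`, a uniformly chosen active element
duplicating at each event. A duplication is represented as a binary node
whose first child continues the parent (keeping its active flag — the model
gives no mechanism for an active element to lose activity) and whose second
child is the new copy, active with probability `delta`. The run stops at
the first event that reaches `target_n` elements — an exact-hit rule chosen
for reproducibility — after which all edges are rescaled by a single factor
so the height of the duplication genealogy is `T1`, and every terminal edge
is extended by `T2`. The founder's pre-first-duplication time is part of
the height and is preserved as the root edge.

`evolve_sequences()` then runs a second exact KMC along every edge:
background events at total rate `mu0` per site (uniform over the three
alternative nucleotides) plus extra deamination events at CpG sites so the
total CpG-site rate is `cpg_factor * mu0`. We read the "CpG rate" of the
model as the *total* rate at such a site, not an additional channel on top
of it — that is the reading under which the effective-rate formula above
gives 1.8 for the Alu geometry, and the simulator is tested against exactly
that value. CpG context is dynamic: a CG created by mutation becomes
hypermutable, a destroyed one reverts; only the literal CG on the stored
strand counts (no reverse-complement context — the model tracks elements in
their extracted orientation).

```{r}
tr <- simulate_burst(p, target_n = 300, seed = 1)
els <- evolve_sequences(tr, make_ancestral(300, 24, seed = 1), seed = 2)
els
```

## Spectra and estimators

`count_kmers()` counts overlapping forward-strand windows;
`spectrum_from_counts()` tabulates `n_k(s)`; `log_bin()` smooths the tail
with unit bins up to `s = 7` and geometric bins of edge ratio 1.1885 above
(four bins per octave); mass is conserved exactly because the geometric
edges are integerised to half-open ranges. `zipf_ranks()` gives the
rank-abundance view, whose slope is `-1/(alpha - 1)`.

The inference pipeline mirrors the model's estimation workflow:

* `estimate_N()` — mean over `5 <= k <= 90` of (total k-mer count) /
  (`L - k + 1`); exact for equal-length sequence sets.
* `hill_exponent()` — the discrete maximum-likelihood (Hill) approximation
  `1 + n [\sum_i \ln(s_i / (s_\min - 1/2))]^{-1}` over the tail sample
  `s_i >= s_min = 3`, one observation per distinct k-mer. This half-shift
  formula is an approximation to the exact zeta-function MLE; at
  `s_min = 3` its large-sample expectation is slightly below the true
  exponent (2.446 at alpha = 2.5, 4.32 at alpha = 5). The package's tests
  therefore calibrate it against its own exact asymptotic expectation,
  computed by direct summation of the zeta-normalised mass function, and
  the same estimator is applied consistently to data and simulations, so
  the bias largely cancels in comparisons.
* `fit_ratio()` — Levenberg–Marquardt least squares of the analytic
  `alpha(k)` over `35 <= k <= 75` with the single free parameter
  `mu / (delta gamma)`; unweighted, with the starting value from inverting
  the endpoints of the curve.
* `estimate_T1()` — closed-form inversion of the growth curve.
* `fit_T2()` — grid search: simulate at each candidate `T2` (with
  `delta = 1`, where simulation is cheapest), and score by the mean squared
  difference of log10 binned densities over shared bins, summed over k.
  The original procedure was a by-eye fit; an explicit metric is needed for
  automation, and log-density MSE over shared bins weights every decade of
  the spectrum equally.

## What the synthetic data do and do not show

`make_ancestral()` builds a CpG-matched random ancestor: exactly `n_cpg`
non-overlapping CG blocks placed uniformly, remaining positions filled with
letters that never create an extra CG (verified by scanning). The package
deliberately ships no real repeat consensus; any user FASTA can serve as
the ancestor. A synthetic ancestor reproduces the length, CpG density and
base composition the model cares about, but none of the internal structure
of a real SINE (A-tail, dimeric architecture, subfamily diagnostic
positions), so passing tests demonstrate correctness of the *model
machinery*, not fidelity to every feature of genomic Alu data.

The default study conditions are the Alu-calibrated parameters
(`alu_params()`): `delta * gamma = 200 mu0` (with `delta = 1`,
`gamma = 200`), `T1` set so the expected census is 776710 elements,
`T2 = 0.024 / mu0` and the 300 bp / 24 CpG ancestor geometry. Tests and
examples run the same process at reduced census sizes (3e2–1e5 elements,
chosen so the whole suite completes on a laptop-class single core), with
`T1` re-derived from the growth curve at the reduced census so that the
duplication-vs-mutation balance — the quantity that sets `alpha(k)` — is
preserved.

Two finite-size facts matter when interpreting reduced-scale runs:

* The half-shift Hill formula under-measures steep tails (see above), and
  the sparse far tail at large `k` adds finite-size truncation; together
  they push the fitted ratio about 10–18% below the simulated truth at a
  1e4-element census. The estimated burst duration `T1` inherits that bias
  linearly (`T1_hat = log(N_hat) * ratio_hat / mu` at `delta = 1`); the
  pipeline's algebraic consistency between the two is exact and tested.
* The insensitivity of the spectra to `delta` at fixed `delta * gamma` is
  an asymptotic statement. At the full census (about 39000 active lineages
  for `delta = 0.05`) the curves collapse; at a 2e4-element census the
  `delta = 0.05` curve still sits visibly below the `delta = 1` curve
  because a small pool of active lineages leaves large-clone fluctuations
  un-averaged. The package's test suite asserts the desk-scale behaviour
  it can actually measure and documents this gap rather than widening
  tolerances.

## Numerical choices

* **Stopping rule** — exact hit of `target_n`; the event count is then
  deterministic (`target_n - 1`), which makes seeds fully reproducible.
* **Rescaling** — one multiplicative factor `T1 / (last event time)`
  applied to all edges.
* **Degenerate inputs** — a single-element "tree" is a bare founder edge of
  length `T1 + T2`; k longer than every sequence yields an empty mapping,
  not an error; windows containing non-ACGT letters are skipped.
* **Binning** — half-open integer bin edges `[ceil(lo), ceil(hi))`; empty
  integerised bins dropped; bin centre = abundance for unit bins, geometric
  mean of the edges for log bins.
* **Power-law sampling** — inverse CDF on an explicit 2e4-entry table, with
  draws beyond the table resolved exactly by bisecting the Hurwitz-zeta
  tail (the zeta itself via Euler–Maclaurin, ~1e-12 relative accuracy).
* **Randomness** — every stochastic entry point takes an explicit `seed`
  and restores the caller's RNG state; identical seed means byte-identical
  FASTA/Newick/TSV/JSON outputs.

## Known limitations

The model has no element death or excision, no time-varying or
sequence-dependent duplication rate, no indels, recombination or gene
conversion, no subfamily structure, and treats CpG context on one strand
only. The estimators inherit the model's assumptions: `estimate_N()`
assumes near-full-length elements, and `fit_T2()` requires the reference
and simulated spectra to be binned identically. Confidence intervals are
reported only as fit residuals and seed spread; a full parametric bootstrap
of the simulator is out of scope.
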