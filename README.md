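# repeatburst

Branching-process models of selfish DNA expansion and the power-law
statistics of k-mer abundances in repeat families.

## The problem

Large repeat families — the primate Alu SINEs being the canonical example —
arise from a **burst of duplication activity** followed by a long silent
period in which the copies only accumulate mutations. A signature of this
history survives in the present-day sequences: counting how often every
subsequence of length *k* (a *k-mer*) occurs across the family, the number
of distinct k-mers with abundance *s*, written *n<sub>k</sub>(s)*, has a
scale-free tail

&nbsp;&nbsp;&nbsp;&nbsp;*n<sub>k</sub>(s) ∝ s<sup>−α(k)</sup>*,

whose exponent starts at the Yule value *α = 2* for short k-mers and grows
with *k*. `repeatburst` is for researchers in molecular evolution who want
to simulate that process exactly, derive the spectra it predicts, and
invert the logic: estimate the duplication rate, the activity fraction and
the phase durations of a repeat family from its sequences alone.

## The model in brief

A single active element of length *L* appears at *t = 0*. During the burst
(*0 ≤ t ≤ T₁*) every active element duplicates at rate *γ*; each copy is
active with probability *δ*, silent otherwise. Afterwards all elements are
silent for a further *T₂*. Sites mutate at rate *μ₀* (the unit of time is
1/*μ₀*), except CpG dinucleotides, which mutate 6× faster; the effective
per-site rate for an Alu-like element (300 bp, 24 CpG) is *μ = 1.8 μ₀*.
Key closed forms, all implemented and tested:

* expected census: *N(t) = 1 + (e^{δγt} − 1)/δ*  (`expected_copies`,
  inverted by `estimate_T1`)
* k-mer survival over the silent phase: *p_k = e^{−μkT₂}* (`survival_prob`)
* abundance-tail exponent, valid while *μk < δγ*
  (`alpha_of_k`): *α(k) = 1 + δγ/(δγ − μk)*

Inference uses the discrete Hill (maximum-likelihood) estimator of the tail
exponent per *k* (`hill_exponent`, tail cutoff *s ≥ 3*), a one-parameter
Levenberg–Marquardt fit of *α(k)* over *35 ≤ k ≤ 75* that recovers the
ratio *μ/(δγ)* (`fit_ratio`), an element-count estimator (`estimate_N`) and
a grid fit for *T₂* by matching log-binned spectra (`fit_T2`).

## A worked example

Simulate an Alu-calibrated family at a reduced census of 10,000 elements,
profile the exponent curve and recover the rate ratio:

```r
library(repeatburst)

# delta*gamma = 200 mu0, T2 = 0.024/mu0, 300 bp / 24 CpG ancestor; at a
# reduced census, T1 is re-derived from the growth curve so the
# duplication-vs-mutation balance matches the full-size family
p   <- burst_params(gamma = 200, delta = 1,
                    T1 = estimate_T1(1e4, burst_params(gamma = 200)),
                    T2 = 0.024)
anc <- make_ancestral(300, 24, seed = 101)
els <- simulate_elements(p, 1e4, anc, seed = 102)

crv <- exponent_curve(els, k_values = seq(35, 75, by = 5))
head(crv, 3)
#> # A tibble: 3 × 4
#>       k alpha_hat n_tail      se
#>   <dbl>     <dbl>  <int>   <dbl>
#> 1    35      2.31 113526 0.00389
#> 2    40      2.41  93183 0.00460
#> 3    45      2.50  72843 0.00555
fit <- fit_ratio(crv)
glance(fit)
#> # A tibble: 1 × 6
#>   ratio_hat std.error residual_norm n_points  k_lo  k_hi
#>       <dbl>     <dbl>         <dbl>    <int> <dbl> <dbl>
#> 1   0.00791 0.0000679        0.0193        9    35    75
effective_rates(p)$ratio                 # the simulated truth
#> [1] 0.009
```

The fitted `ratio_hat` estimates *μ/(δγ)*, the single dimensionless number
that controls how fast the exponent curve rises; at a 10⁴-element census it
lands about 12% below the simulated truth 0.009, the expected finite-size
and Hill-estimator bias at this reduced scale (see the vignette). From it
and the census estimate the other parameters follow:

```r
estimate_N(els)                          # 10000  (exact for equal-length sets)
estimate_T1(776710, burst_params(gamma = 200, delta = 1))
#> [1] 0.06781411                         # burst duration, units 1/mu0
mu0_from_age(7.7e-2, 80e6)               # implied mu0 if the family is 80 My old
#> [1] 9.625e-10                          # per year
```

`autoplot()` methods draw spectra (`spectrum_from_counts`, `log_bin`) and
exponent curves with their analytic fit; `run_pipeline(pipeline_config())`
executes the whole workflow (simulate → count → bin → Hill → fit) and
writes FASTA/Newick/TSV/JSON artefacts reproducibly for a given seed. A
thin command-line wrapper with the same stages lives at
`inst/cli/repeatburst.R` (subcommands `make-ancestor`, `simulate-tree`,
`simulate-seqs`, `count`, `spectrum`, `hill`, `fit`, `predict`,
`pipeline`).

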