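---
title: "Screening mutational hotspots for survival association"
author: "survspot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening mutational hotspots for survival association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

`survspot` screens recurrently mutated amino-acid positions
("hotspots") for association with overall survival.  The pipeline is
built around one statistical difficulty: hotspot carriers are few
(often 4–30) inside cohorts of hundreds, and the χ²(1) approximation
behind the classical log-rank test is unreliable in that regime —
both its assumptions, large samples and comparable group sizes, are
violated at once.  The package therefore treats the *signed* log-rank
statistic

$$L = \sum_j \left( O_{1j} - d_j\,\frac{r_{1j}}{r_j} \right)$$

as the quantity of interest and tabulates its null distribution
*conditional on the observed times and censoring pattern*: under the
null hypothesis of no survival difference, every assignment of the
$n_1$ carrier labels to the $n$ patients is equally likely, and only
the labels are permuted.  This conditional construction needs no
distributional assumption about the survival times; what it assumes
is exchangeability of the group labels under the null, i.e. that
carriers are not systematically censored differently for reasons
unrelated to survival.

The signed statistic, not $L^2/V$, is tabulated: its null is visibly
asymmetric and often multimodal for rare carriers, and a signed axis
keeps the direction of the effect (more/fewer carrier deaths than
expected) interpretable.  The two-sided p-value is twice the smaller
tail area, capped at 1, with mass at the observed value counted in
both tails — the conservative convention for discrete distributions.

## Tabulating the null

`exact_null()` works in two modes.

**Enumeration.**  When $\binom{n}{n_1} \le$ `enum_limit` (default
100,000), all assignments are enumerated and the null is exact.  The
statistic is evaluated through its additive representation
$L(g) = \sum_{i \in g} c_i$ with $c_i = \delta_i - \hat H(T_i)$,
where $\hat H$ is the cumulative event-rate step function
$\sum_{t_j \le t} d_j/r_j$; this identity (the martingale-residual
form of the score) makes each assignment an $O(n_1)$ sum.  The test
suite verifies it against a naive per-event-time recomputation and
against full brute-force enumeration.

**Stratified sampling.**  Otherwise assignments are stratified by
$k$, the number of events that fall in the carrier group.  The
stratum probability is hypergeometric in closed form,
$w_k = \binom{d}{k}\binom{n-d}{n_1-k}/\binom{n}{n_1}$, and within
each stratum `n_perm_per_stratum` (default 10,000) random assignments
with exactly $k$ carrier events estimate the conditional law of $L$.
The mixture $\sum_k w_k \hat F_k$ estimates the null.  Stratification
is what makes the extreme tails usable: the rare-$k$ strata that
dominate small p-values get the same Monte Carlo effort as the bulk.
Strata beyond a cumulative weight of $1 - 10^{-10}$ are dropped and
the retained weights renormalized; the omitted mass is far below
every tolerance used anywhere in the package.  Subsets within a
stratum are drawn without replacement per draw; for small $k$ a
vectorized rejection sampler (draw with replacement, reject columns
with duplicate indices) is used, falling back to per-draw
`sample.int()` when the collision probability exceeds 0.3.

A seed is part of the public interface of every sampling entry point,
and the caller's RNG state is saved and restored, so screens are
reproducible end to end.

## Comparing tabulated nulls

`tv_distance()` reports total-variation distance.  Two exact
enumerations are compared on their atoms (merged within a relative
tolerance of $10^{-8}$).  When either side is a Monte Carlo estimate,
atom-level TV has a sampling-noise floor of order
$\sqrt{S/m}$ for $S$ support points — the atoms of a sample never
coincide with a continuum — so the comparison is made on a partition
of the line into intervals of equal reference mass (default 25).
Interval boundaries are placed halfway between adjacent support
values of the reference so that no atom sits on a boundary; without
this adjustment, floating-point jitter splits boundary atoms between
bins and biases the distance.

## The other statistics

The classical log-rank p uses the hypergeometric variance $V$ and the
$\chi^2_1$ upper tail at $L^2/V$ (`asymptotic_p()`; $p = 1$ when
$V = 0$).  The hazard ratio comes from a Cox proportional-hazards fit
of the binary carrier indicator via `survival::coxph()` with Breslow
tie handling (Efron available as an option) and a Wald p-value.  When
one group has no events the partial likelihood is monotone; the fit
is flagged degenerate and the HR reported qualitatively as `"<1"`
(no carrier events) or `">1"` (no comparison events) rather than as a
meaningless number.  Kaplan–Meier curves use the product-limit
estimator; median survival is the smallest time with
$S(t) \le 0.5$, absent when the curve never reaches 0.5.

Both Cox and KM are delegated to the `survival` package — the
standard tool for these fits — while the log-rank statistic and its
conditional null, the package's actual contribution, are implemented
here and cross-checked against `survival::survdiff()` and a
brute-force oracle in the tests.

## Input conventions and their rationale

* **Patient identity** is the 12-character barcode prefix; pooling
  and group construction are per *patient*, never per sample, and a
  patient counts once per position regardless of supporting calls.
* **Sample types**: the default whitelist keeps primary tumors
  (`"01"`); metastatic (`"06"`) can be added for melanoma-like
  cohorts.  Barcodes without a type field are kept.
* **Protein-change parsing** takes the *first* integer in the
  `HGVSp_Short` string: missense positions directly, range deletions
  their start, frameshifts the first altered residue.  This pools
  multi-residue events with substitutions at the start position,
  which is the behavior that aggregates e.g. exon-19-deletion-like
  events at one position.  Silent changes (`p.X123=`) are retained —
  they mark the same recurrent positions and may be functional.
* **Hypermutation rules**: a sample is flagged when (TMB > 500 and in
  the top decile, nearest-rank) *or* TMB > median + 4·MAD.  The MAD
  is the plain median of absolute deviations — no 1.4826 consistency
  constant — because the rule is a robust fence, not a normal-scale
  estimate; the scaled variant is available via `scale_mad = TRUE`.
  Ties at the 90th percentile are included.
* **Thresholds**: hotspots need ≥ 4 carriers with clinical data.  In
  the gene-, spots- and pairwise comparisons both sides must have
  ≥ 4 patients or the comparison is skipped (and logged); in the
  carriers-vs-all test only the carrier side is thresholded, since
  the comparison side is the rest of the cohort.
* **Overlapping carriers**: group disjointness is required by the
  statistics, so a carrier of X never enters X's comparison group,
  and patients carrying both hotspots of a pair are excluded from
  both sides.  Pairs are unordered, tested once, with X the
  lower position; the HR is oriented X relative to Y.
* **Significance** is `p_valorate <= alpha` (default 0.05) on the
  empirical p only.  No multiple-testing correction is applied across
  the screen: the per-case tabulated null already adapts to each
  comparison's size structure, and the output is a screening
  shortlist, not a confirmatory call.  The classical log-rank and Cox
  p-values are reported for reference and never used for calling.

## The synthetic generator

`generate_cohort()` emulates the statistical structure the screen
faces: exponential survival with baseline hazard 1/1500 per day
(median ≈ 1040 days), independent exponential censoring (rate 1/4000)
plus a 10-year administrative cutoff, a 5% hypermutated fraction at a
mean TMB of 1000 against a background of 50, per-gene background
mutation probabilities around 0.1, and planted hotspots with chosen
carrier counts and hazard ratios (defaults: HR 2.5 with 20 carriers,
HR 1 with 8, HR 0.5 with 12, in a 400-patient cohort).  Exponential
survival is chosen deliberately: it satisfies proportional hazards
exactly, so Cox recovery has a known truth.  Carriers of several
hotspots multiply their hazard ratios.  Planted carriers are drawn
among the non-hypermutated patients so that the filtering step leaves
the planted truth intact.  Protein-change strings are drawn from a
small grammar covering the parse cases real MAFs exercise (missense,
synonymous, frameshift, in-frame deletion).

What the generator does *not* emulate: mutational signatures,
copy-number events, subclonality, covariate structure (age, stage,
subtype), non-proportional hazards, or informative censoring.
Passing tests on synthetic cohorts therefore demonstrate the
correctness and calibration of the machinery under the stated
sampling model — not robustness to confounding in real cohorts,
which the screening design (raw p, no covariate adjustment)
explicitly leaves to downstream interpretation.

One consequence of the Poisson TMB model is worth noting: the
median + 4·MAD fence sits near the 99.8th percentile of a Poisson
background, so in a 400-sample cohort the filter occasionally flags a
legitimate background sample.  The tests assert complete recall of
the planted hypermutated samples and a false-positive rate at or
below 1%, which is the property the rule actually has.

## Numerical choices

* Tolerances: support values are compared within a relative
  $10^{-8}$; stratum weights must sum to 1 within $10^{-9}$.
* Degenerate inputs: no events gives $L = V = 0$ with a flag and
  $p = 1$; $n_1 \in \{0, n\}$ is an error; an all-censored group is
  handled by the degenerate Cox path.
* Tie handling: multiplicity-aware log-rank terms; Breslow ties in
  Cox (simplest consistent choice, Efron optional).
* Per-comparison sub-seeds in `run_screen()` are drawn once from the
  master seed after the (deterministic) comparison list is built, so
  adding or removing an unrelated cohort does not silently change the
  p-values of another comparison's seed only through ordering within
  the same cohort.

## Problem sizes used in the tests

The shipped test suite validates calibration at deliberately modest
sizes chosen to make the properties visible while keeping the suite
quick to run: oracle equivalence at $n \le 12$ against full
enumeration; sampler convergence at $n = 12$, $n_1 = 3$ across
100–10,000 draws per stratum; type-I error with 6 carriers among 300
patients over 2000 replicates; χ² agreement at $n_1 = n/2 = 100$ and
divergence at $n_1 = 4$, $n = 400$; Cox coverage at $n = 500$ over
200 replicates.  These are the package's reference operating points;
the same functions scale to cohort sizes in the thousands, where the
stratified sampler is the mode that matters.

## Known limitations

* The conditional-permutation null assumes exchangeable labels; it
  does not model carrier-dependent censoring.
* The empirical p's resolution is bounded by the per-stratum sample
  size; p-values far below $w_k/m$ are reported as the smallest
  attainable mass rather than extrapolated (no kernel smoothing of
  the strata is attempted).
* Transcript-level pooling means a gene annotated against several
  transcripts yields several hotspot series; no cross-transcript
  coordinate mapping is attempted.
* No covariate-adjusted models, no multiple-testing correction, no
  structural/3D hotspot clustering — the screen ranks candidates, it
  does not confirm them.
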