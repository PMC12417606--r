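---
title: "Registry-linked prevalence estimation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registry-linked prevalence estimation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prevalink)
```

prevalink estimates how common a clinically diagnosed condition is when the
only national data source is a school special-education registry that
undercounts it. The motivating setting is autism spectrum disorder (ASD,
ICD-10 F84.0-F84.9) among school-age children: a national registry records
ASD only for pupils enrolled in a special-education-needs (SEN) programme,
while one regional health service contributes an electronic-health-record
(EHR) extract of diagnosed patients. Linking the two in that one region
measures how much the registry misses; a Bayesian model then carries that
correction to every other region.

This vignette explains each stage's model, its assumptions, the tunable
parameters, and the numerical choices made where the design was open.

## 1. The synthetic registry generator

Real registry and EHR microdata of this kind cannot be redistributed, so the
package ships a generator (`sim_config()`, `simulate_registry()`) that
creates both sources from shared latent individuals with known ground truth.
Every downstream stage is tested against that truth table.

Per child, the generator draws sex, an age band (four 3-year bands, 6-18
years), a date of birth uniform over the integer ages-in-days compatible
with the band at the reference date, a commune within the health service
(rank-size skewed), a school consistent with the commune, a fee band,
ethnicity, immigration status, rurality, and an ordinal insurance band that
serves as the socioeconomic (SES) proxy shared by both sources. Condition
risk is multiplicative:

$$p_i = p_{s(i)} \cdot \frac{f_{\text{sex}(i)}}{E[f]} \cdot \frac{g_{\text{band}(i)}}{E[g]},$$

where $p_s$ is the service's true prevalence, $f_M/f_F$ is the
male-to-female risk ratio (default 6, the ratio observed in the registry
analyses this package is built around), and $g_k = \gamma^{k-1}$ a
multiplicative trend over the four bands (default $\gamma = 0.86$, matching
a prevalence that peaks at ages 6-8 and declines towards 15-18). The
normalisation keeps each service's marginal prevalence at $p_s$ exactly.

Affected children carry the registry flag with probability
`school_detection_prob` (default 0.30; in the clinical catchment the
package emulates, 488 of 1620 diagnosed children accessed school support)
and, in the designated clinical service only, appear in the EHR with
probability `clinical_capture_prob` (default 0.84). These two events are
drawn **independently**, which real data need not obey: in the motivating
study the observed overlap between school-flagged and clinically recorded
children was well below the independence expectation. Consequently the
synthetic "updated minus school" prevalence delta is smaller than the
published one; tests of the delta arithmetic therefore use the published
summary estimates as inputs, and synthetic runs validate machinery, not the
published magnitude.

Clinical field corruption is applied independently per field relative to
the registry truth: date of birth (default 2%) is day/month transposed when
that yields a valid distinct date, else shifted one day — this produces the
near-misses a date-tolerant comparator should catch; commune (3%) is
replaced by another commune of the service; the insurance band (5%) moves
off by one. A patient appears under a second commune with probability
`multi_commune_prob` (default 0.01, the order of magnitude implied by the
published row/unique-patient counts). `chile_sim_config()` instantiates the
29 published health services with their child populations, per-service
school-flag prevalence and clinically corrected prevalence; its `scale`
argument shrinks populations proportionally for fast experiments.

The generator does **not** emulate: school-level clustering beyond a school
label, the 28 distinct SEN categories (a single non-ASD SEN indicator is
kept so the SEN margin is realistic), name fields (the linkage schema has
none), or any correlation between SES and detection.

## 2. Crude and standardized prevalence

`crude_prevalence()` uses exact Poisson (chi-square) limits on the case
count. `direct_standardize()` computes
$100 \sum_i w_i r_i / \sum_i w_i$ over age-band x sex strata with external
weights. Confidence limits use the gamma construction of Fay and Feuer
(1997), `gamma_ci()`: with normalised per-capita weights $w_i$, the
weighted case sum $Y=\sum w_i x_i$ and its variance proxy
$v=\sum w_i^2 x_i$,

$$L = \frac{v}{2Y}\,\chi^2_{\alpha/2}(2Y^2/v), \qquad
  U = \frac{v+w_{max}^2}{2(Y+w_{max})}\,
      \chi^2_{1-\alpha/2}\!\big(2(Y+w_{max})^2/(v+w_{max}^2)\big).$$

This is the canonical chi-square-quantile gamma interval for a directly
standardized rate; in the single-stratum limit it reduces exactly to the
Poisson limits, which the tests assert. With zero cases the lower limit is
0 and the upper limit retains the maximal weight term.

The shipped standard population (`std_population()`) is a **synthetic**
age-sex table built from the registry's printed band and sex margins under
independence; real census projections are deliberately not reproduced.
Weights enter at band level (not single year of age) — the published
analysis is ambiguous on this point and band-level weights are the only
option the data schema supports. Prevalences are carried as proportions
internally and rendered as percent, 2 d.p., round-half-to-even, only at
report boundaries.

## 3. Fellegi-Sunter linkage

Candidate pairs are blocked on exact sex and date of birth (a `loose`
option blocks on year+month instead; it is off by default, matching the
blocked-pair behaviour of the motivating study). Within a block, each
field $f$ contributes

$$s_f \log_2 \frac{m_f}{u_f} + (1-s_f) \log_2 \frac{1-m_f}{1-u_f}$$

bits to the composite weight, where $s_f \in [0,1]$ is the comparator
similarity, and $m_f$, $u_f$ are the probabilities of agreement among true
matches and non-matches. Fractional similarities interpolate linearly
between the agreement and disagreement weights (Winkler-style); the
comparators are: exact (sex, commune — compared against every commune a
deduplicated patient was recorded under), date-tolerant (1 exact, 0.8 for
a day/month transposition, 0 otherwise), and ordinal
($1 - |\Delta \text{rank}|/(\text{max rank}-1)$) for the SES proxy.
Missing values score 0 and are counted.

Default m/u values (`default_field_specs()`) are conventional declared
starting points, not estimates: dob 0.95/0.001, sex 0.98/0.5, commune
0.9/(1/number of communes), SES 0.8/0.2. EM estimation of m/u is out of
scope. The default acceptance threshold of 9 bits was chosen by weight
arithmetic before any tuning: a blocked pair carries ~10.9 bits from
sex+dob, so 9 bits accepts a true pair that disagrees on commune provided
the SES band agrees (~9.6 bits), while requiring a chance candidate to
match on commune or SES beyond the blocked fields. Clerical review is
replaced by this threshold plus a "grey zone" export (pairs within 3 bits
below it) for human inspection.

Assignment is bijective and greedy: pairs are sorted by descending weight
with ties broken lexicographically by (student id, patient id), and a pair
is accepted iff neither side is taken — making the result invariant to
input row order, which property tests verify. `cohens_kappa()` supports
diagnostic-validation agreement reporting.

With exact-date blocking, recall is bounded above by one minus the dob
corruption rate; at the default error rates the 20-seed synthetic suite
achieves precision ~0.997 and recall ~0.96. At 5% corruption on every
field recall falls to ~0.94 — a structural consequence of blocking, not of
scoring.

## 4. Delta, bounded priors and MCMC projection

In the clinical service, the "updated" case set is the union of flagged
pupils and unmatched unique patients; both the school and updated counts
are standardized identically, and `compute_delta()` reports their
difference in percentage points. Although the motivating text calls this a
"ratio difference", the published per-service arithmetic is additive
(0.43 to 1.28, 0.75 to 1.60 under a delta of 0.85), so the delta is applied
additively; the delta's interval width is the wider of its two sources.

`build_priors()` gives each service $s$ a bounded uniform prior
$p_s \sim U(l_s, u_s)$ with $l_s$ its school-standardized prevalence and
$u_s = l_s + \delta$ (the clinical service keeps its directly observed
bounds). The likelihood couples the prior to the school observation:

$$y_s \sim \mathrm{Binomial}(n_s, \pi_s), \quad
  \mathrm{logit}(\pi_s) = \mathrm{logit}(p_s) + b_s, \quad
  b_s \sim N(0, \sigma^2), \quad \sigma \sim \text{Half-Normal}(1),$$

with $y_s$ the adjusted expected school case count
$\mathrm{round}(l_s n_s)$ by default (the observation the school data
actually contribute; a `y` column in the input overrides it). This
structure — adjusted case counts with a random effect on health service
under the bounded uniform priors — is a declared reconstruction consistent
with the published description; all of it sits behind `mcmc_config()` and
the prior table so alternatives can be slotted in.

The sampler (`run_mcmc()`) is Metropolis-within-Gibbs, written in the
package: a random-walk update of each $p_s$ on the prevalence scale with
proposals outside $[l_s,u_s]$ rejected (so support containment is exact, a
hard test assertion); an interweaving move that shifts $p_s$ while
absorbing the shift into $b_s$, leaving the likelihood unchanged — without
it the near-degenerate binomial likelihood makes $(p_s, b_s)$ a ridge the
plain walk traverses slowly (split R-hat up to 1.8; with it, below 1.02); a
random-walk update of $b_s$; and a log-scale walk for $\sigma$ with the
half-normal prior and Jacobian. Step sizes adapt toward a 20-50%
acceptance rate during burn-in only, so kept draws come from a fixed
kernel. Defaults follow the published sampler settings: 2000 burn-in and
2000 kept iterations without thinning; 4 chains (chain count is not
published; 4 is the convention for split R-hat), flagged non-converged
above 1.1. Setting `sigma_fixed = 0` removes the random effect, which is
how the test suite compares the sampler to an independent Riemann-grid
posterior (agreement within 0.02 percentage points in posterior mean);
`use_likelihood = FALSE` samples the priors alone (posterior mean then
recovers the prior midpoint). Degenerate priors ($l_s = u_s$) return the
point mass.

Reported credible bands for the projection follow the published
construction rather than the raw posterior quantiles: a band centred on
the projected prevalence whose width is the maximum of the service's
school-interval width and the delta-interval width, truncated to
$[0, 100]$. `national_projection()` applies the delta to the national
school estimate, converts to a posited case count, and subtracts support
accessors for the unmet need; an externally computed age-sex-adjusted
posited count can be supplied where the crude product is not the published
quantity.

## 5. Determinants of SEN access

`fit_poisson_robust()` is the standard modified-Poisson device for
prevalence ratios on a binary outcome: log-link Poisson IRLS fit, HC0
sandwich variance (via the sandwich package), Wald intervals on the
exponentiated coefficients, and a two-sided significance flag at
$p < 0.001$ (the multiplicity convention of the motivating analysis;
p-values are reported, never used for selection). Zero-variance and
aliased covariates fail with named errors. The two-level mixed-effects
logistic sensitivity model is deliberately out of scope; this module is
the Poisson arm only.

## 6. Pipeline, determinism and problem sizes

`run_pipeline()` chains simulate, impute, prevalence, link, delta, MCMC and
report stages, writing CSV artifacts and a JSON manifest of MD5 hashes. A
single global seed cascades to fixed per-stage seeds, so reruns are
hash-identical end to end (a test assertion). Stages re-read their inputs
from the artifact directory and fail naming the missing file when run out
of order.

Test and script problem sizes are chosen to exercise the estimators at
realistic rates while keeping the full suite under a minute of compute:
linkage experiments use a 30,000-child clinical service at 2% prevalence
over 20 seeds; the prevalence-ratio recovery uses 200,000 children per
replicate; coverage experiments use 8 services over 20 seeds with
shortened chains (400 burn-in, 800 kept, 2 chains), which the convergence
diagnostics show is sufficient for these small models. The full published
scale (3.06 million children) runs in well under a minute through
`chile_sim_config(scale = 1)` if needed.

## 7. Known limitations

* Detection and clinical capture are independent in the generator, so
  synthetic deltas understate real ones where school and clinic access
  correlate negatively.
* Exact-date blocking caps linkage recall at one minus the dob error rate;
  loose blocking recovers only same-month near-misses.
* m/u weights are declared, not estimated; badly misdeclared weights
  degrade ranking even though blocking keeps candidate sets small.
* The binomial denominator uses adjusted expected counts; raw counts can be
  supplied but change the posterior little at these prevalences.
* The credible band construction is a reporting convention around the
  projection; it is not the posterior quantile interval, which is also
  reported (`cri_low`, `cri_high`).
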