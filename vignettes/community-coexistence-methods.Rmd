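---
title: "Methods: coexistence and interaction analysis for model microbial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coexistence and interaction analysis for model microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcoex)
```

## The scientific problem

A model bacterial community is only useful for ecology and evolution
experiments if its members stably coexist under the culture regime. In
serial-transfer batch culture — here, weekly 1:100 dilutions into fresh
medium — an equilibrium is never observed directly, so coexistence is
tested by *invasion from rare*: each species is inoculated at a 100-fold
lower density than the resident community, and coexistence is supported
when every species, when rare, grows faster than the residents (negative
frequency dependence). `mcoex` implements that test, the pairwise and
indirect interaction calculus used to interpret it, the
supernatant/co-culture concordance statistics, morphotype identification
tallies, and the Sanger-read QC used to verify species identities — all
exercised against a synthetic data generator with known ground truth.

## The generative model

The simulator uses generalized Lotka–Volterra (gLV) batch dynamics with
an optional product-form higher-order term:

$$\frac{dN_i}{dt} = N_i\Big(r_i + \sum_j a_{ij} N_j +
  \sum_{j<k} b_{ijk} N_j N_k\Big)$$

with $N_i$ in cfu/mL, $r_i$ in day⁻¹, $a_{ij}$ in (cfu/mL)⁻¹ day⁻¹ and
$b_{ijk}$ in (cfu/mL)⁻² day⁻¹. This is the simplest generative model in
which multiplicative composition of pairwise effects can be switched on
($B = 0$) and off ($B \neq 0$), which is exactly the property the
indirect-interaction statistic is designed to detect. A serial transfer
divides all densities by the dilution factor and integrates one batch;
extinction is absorbing.

Assumptions worth keeping in mind: growth is logistic-like with fixed
carrying capacities (no death phase, so a culture left for weeks sits at
its equilibrium instead of declining), interactions are density- not
frequency-dependent, and there is no spatial structure, no evolution and
no explicit resource dynamics.

### The reference parameter set

`community_glv_params()` fixes the five-species ground truth used
throughout the tests:

* $r = (1.00, 1.02, 1.08, 0.98, 0.95)$ day⁻¹ — nearly equal rates. In
  dilute complex medium, fitness differences between co-isolated soil
  bacteria are small (an equalising mechanism); near-equal rates also
  make the invasion statistic reflect frequency dependence rather than
  intrinsic growth-rate differences.
* Carrying capacities $K = (5, 6, 8, 4, 3)\times 10^8$ cfu/mL, typical
  plate-count densities of dilute-broth batch cultures; $a_{ii} = -r_i/K_i$.
* Relative competition coefficients $c_{ij} = -a_{ij} K_i / r_i$ between
  0.15 and 0.30 — intraspecific competition well above interspecific (a
  stabilising mechanism). The *Variovorax* row carries negative
  coefficients (facilitation) from three species, mirroring the
  asymmetric positive interactions such communities show; its only
  symmetric competitor is *Stenotrophomonas*. The set was checked for
  feasibility (all equilibrium abundances positive) and mutual
  invasibility (every species has positive growth when rare against
  every resident subset) by linear algebra on the parameter set itself.
* Higher-order terms (`hoi_strength = 1`) are restricted to partner
  pairs $j, k$ both different from the focal $i$ — a true higher-order
  effect that needs two other species present and leaves pair cultures
  untouched — and are all negative with magnitude
  $\overline{|a_{i\cdot}|}/2.5\times10^8$, so their contribution at
  typical community densities matches the mean pairwise off-diagonal
  effect. Suppressive terms are used because positive quadratic
  per-capita terms can outrun linear self-limitation and diverge.
* The supernatant ground truth is a separate matrix $\sigma_{ij}$
  (multiplier on the focal's realised daily growth rate in species $j$'s
  spent medium; `community_sigma()`), not derived from $A$: diffusible
  effects need not match whole co-culture outcomes, and keeping them
  separate lets the concordance statistics be exercised under
  disagreement as well as agreement. Diagonal entries (own supernatant,
  0.08–0.25) sit far below the off-diagonal ones, and *Variovorax*
  exceeds 1 in three species' supernatants (cross-feeding).

### Assay emulation and noise

`generate_study_datasets()` reproduces the three assay designs:
persistence (every composition at $3\times10^6$ cfu/mL per species,
sampled at weeks 2–4 with 3 replicate plate counts; week 1 is excluded
because cultures have not equilibrated), invasion (residents at
$2.5\times10^7$ cfu/mL total in equal ratios — dense normalised cultures
diluted ~1:250 into fresh medium — invader 100-fold lower, one 7-day
batch, 6 replicates), and supernatant (2-day growth from
$2.5\times10^5$ cfu/mL, 3 technical replicates). Measured densities get
multiplicative lognormal noise (default `log_sd = 0.1`, a ~10%
coefficient of variation typical of plate counts; the validation studies
use 0.05, the low end of careful counting) and detection censoring at
1 cfu/mL. Replicates differ only in measurement noise: the generator
does not emulate biological replicate variation (true density
differences between replicate cultures), demography, contamination, or
day-to-day environmental variation, so passing tests demonstrate
correctness of the statistical machinery, not robustness to every noise
structure of real data. One master seed spawns fixed per-assay
substreams, so datasets are byte-reproducible.

The invasion inoculation density matters: both invader and residents
must be dense enough that the residents approach saturation within the
7-day batch, otherwise both grow near-exponentially and the ratio of
Malthusian parameters degenerates to a ratio of intrinsic rates. At the
chosen densities the deterministic relative invader growth rates of the
reference community span roughly 1.09–2.6 across the 75 treatments.

## The statistics

**Invasion.** $m = \ln(N_1/N_0)/t$; the relative invader growth rate is
$m_\text{focal} : m_\text{community}$ with the residents pooled by total
density before the log. Per treatment, a one-sample t-test against a
mean of 1; p-values adjusted by Benjamini–Hochberg jointly across all
treatments of a study (one family of 75 tests, not per focal species).
The t-test is two-sided — the conservative default, since only the null
(mean = 1) is specified by the assay logic. Choices for awkward cases:
a zero final plate count is censored at the detection limit before the
log (counts cannot distinguish absence from below-detection); a resident
community whose total declines makes the ratio uninterpretable (the
denominator changes sign), so such replicates are flagged `NA` and
excluded with a warning rather than returned as negative ratios;
zero-variance replicate sets are flagged degenerate instead of producing
infinite t statistics.

**Pairwise interactions.** $w_{1|2} = N_{1|2}/N_1$: per replicate, the
focal's co-culture density divided by the *week-matched* monoculture
mean, then averaged over weeks 2–4 (~9 ratios). Replicates are unpaired
across compositions, which is why the reference is the monoculture mean
rather than a paired count; week-matching (rather than pooling all
monoculture weeks) keeps slow monoculture drift from leaking into the
interaction estimate — the matching choice is this package's, as either
aggregation is defensible.

**Indirect interactions.** The prediction is multiplicative,
$\hat w_{1|23} = w_{1|2} \times w_{1|3}$, always built from pairwise
estimates only — never rescaled recursively through lower-order indirect
estimates — so estimates at all diversity levels share one null. The
deviation $d = w_\text{obs} - \hat w$ is synergistic when it pushes the
effect further from neutrality in the predicted direction
($\operatorname{sign}(d) = \operatorname{sign}(\hat w - 1)$), buffering
when it pulls back, additive at exactly zero. The sign-adjusted
statistic `ii_adj` negates $d$ for predicted-negative interactions so
synergism is always positive. A prediction of exactly 1 has no direction:
a nonzero deviation there is flagged indeterminate rather than forced
into either class (it does not arise in practice with continuous data).
Note that even with $B = 0$, gLV equilibria are not exactly
multiplicative, so the pairwise-null mean $|ii_\text{adj}|$ is small but
nonzero; the statistic's job is to be *larger* under genuine higher-order
structure, and the validation compares matched datasets accordingly.
The strength-vs-type comparison is a one-way ANOVA of $\hat w$ on the
two-level class factor, restricted to predicted-negative interactions
(predicted-positive ones are too few to test in a five-species pool
where only one species is facilitated).

**Supernatant assays.** Growth per day over $t = 2$ days; negative rates
are floored at 0.001 so relative growth stays positive; technical
replicates collapse by median before any ratio is formed; relative
growth divides by the focal's fresh-media rate. The intra-vs-inter
summary reports each species' own-supernatant value against the mean of
the others with a 95% t-interval.

**Concordance.** SMA regression on the raw ratio scale (no log
transform; a config switch is deliberately not provided because the two
scales answer different questions and the raw scale keeps
$w = 0$-adjacent estimates usable), with slope
$\operatorname{sign}(r)\, s_y/s_x$, the standard F-based CI, and the
rotation test of a hypothesised slope: $r^* = \operatorname{cor}(y - b_0
x,\; y + b_0 x)$, $t = r^*\sqrt{(n-2)/(1-r^{*2})}$. Data collinear at
$b_0$ make $y - b_0 x$ constant up to floating-point residue, which is
detected with a scale-aware tolerance ($s_u \le 10^{-10}(|\bar u| +
s_v)$) and returns $p = 1$ exactly. Sign agreement calls an estimate
positive above 1 and negative below; estimates exactly 1 are neutral and
excluded from the tally (forcing them into either class would
manufacture agreement or disagreement from nothing).

**Sanger QC.** Mott's modified trimming: per-base score
$s_i = 10^{-c/10} - 10^{-Q_i/10}$ with cutoff $c = 40$, retained segment
= the maximum-sum contiguous window, computed by a linear prefix-sum
scan and cross-checked in the tests against exhaustive $O(L^2)$ window
enumeration. Ties (same score) break to the leftmost start, then the
longest window — the tie rule is this package's fixed choice, made for
determinism. Reads whose every window scores $\le 0$ are discarded.
Secondary peaks count positions where the lower trace peak is at least
one third of the higher (boundary inclusive). The retention filters are
strict/inclusive exactly as stated: length > 100 (100 fails), secondary
peaks ≤ 5 (5 passes), mean quality > 30 (30 fails); mean quality is
computed on the *trimmed* read — filtering describes the sequence that
survives, so filtering the surviving bases is the choice documented
here. Binary chromatogram formats are not parsed: reads enter as
Phred+33 FASTQ with an optional TSV sidecar of peak heights.

## Numerical choices

* ODE integration: `deSolve::ode` (lsoda) at relative tolerance
  $10^{-8}$; state clamped nonnegative inside the derivative; species
  below $10^{-3}$ cfu/mL at batch end are set to exactly 0, making
  extinction reproducible and absorbing.
* The two-species integrator is validated against a fixed-step Euler
  oracle at $dt = 10^{-4}$ day (0.5% agreement); the one-species batch
  against the closed-form fixed point $-r/a_{11}$ (0.1%).
* BH-FDR delegates to `stats::p.adjust(method = "BH")` and is verified
  against a literal brute-force step-up implementation on 1000 random
  vectors; t-tests and ANOVA delegate to `stats::t.test`/`stats::lm`.
  SMA regression is implemented here from the standard formulas (no SMA
  package is a dependency) and verified through its analytic identities
  (slope product symmetry, sd-ratio identity, degenerate cases).

## Problem sizes in the test suite

The validation studies use the full five-species designs (31
compositions × weeks 2–4 × 3 replicates; 75 invasion treatments × 6
replicates; 20 supernatant combinations × 3 technical replicates) at
`log_sd = 0.05`, one seeded dataset per condition, plus matched
pairwise-null/higher-order dataset pairs for the indirect-interaction
contrast; property checks (Mott-window oracle, BH oracle, SMA
identities) run on 200–1000 randomized cases each under fixed seeds.

## Known limitations

* The gLV ground truth cannot represent death phases, lag phases, or
  resource-explicit mechanisms; "persistence without resource
  replenishment" therefore holds cultures at equilibrium rather than
  letting them decay, which is optimistic for weeks 3–4.
* Replicate variation is measurement noise only; estimates of the
  *variance* of downstream statistics from these data understate real
  biological replicate scatter.
* The intrinsic rates and interaction coefficients are illustrative (no
  growth-curve data exist to fit them); conclusions from the synthetic
  studies are about the correctness of the statistics, not about any
  real community's parameters.
* The indirect-interaction classification is relative to the
  multiplicative pairwise null; it cannot distinguish interaction chains
  (density-mediated) from true per-capita higher-order effects, and a
  different null (e.g. recursive rescaling through lower orders) would
  classify borderline cases differently.
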