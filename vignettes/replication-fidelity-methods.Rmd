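---
title: "Methods: fluctuation tests, gel-based ribonucleotide counting, and mutation spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fluctuation tests, gel-based ribonucleotide counting, and mutation spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replifid)
```

This vignette documents the statistical models implemented in **replifid**,
the assumptions behind them, the defaults and why they were chosen, the
numerical decisions that matter, and what the synthetic-data generators do
and do not emulate.

## 1. Fluctuation analysis

### Model

A fluctuation experiment grows many parallel cultures from tiny inocula and
plates each on selective medium. Because a mutation arising early founds a
large resistant clone, the per-culture mutant count is over-dispersed with a
heavy "jackpot" tail; its distribution identifies the expected number of
mutational events per culture, *m*, far better than the mean count would.

We use the Lea–Coulson formulation: events per culture are Poisson(*m*);
under deterministic exponential growth a clone founded when the population
was a fraction *u* of its final size has relative size ~1/*u*, giving the
clone-size law P(Y = y) = 1/[y(y + 1)] (equivalently Y = ⌊1/U⌋ with U
uniform). The count is the compound-Poisson sum of clone sizes, computed by
the standard recursion

$$p_0 = e^{-m}, \qquad
  p_n = \frac{m}{n}\sum_{i=0}^{n-1} \frac{p_i}{\,n-i+1\,}.$$

The test suite verifies this recursion two independent ways: term-by-term
against a plain-R reimplementation, and against Monte-Carlo frequencies
from the generator (the generator and the pmf code share no numerics; a
direct enumeration of P(X = 2) = e^{-m}(m/6 + m^2/8) pins the form of the
recursion).

**Partial plating.** When a fraction ε of each culture is plated, each
clone contributes Binomial(Y, ε) observed colonies. We thin the clone-size
law numerically, $h_k(\varepsilon) = \sum_y \frac{1}{y(y+1)}
\binom{y}{k}\varepsilon^k(1-\varepsilon)^{y-k}$, truncating the y-series
where a Hoeffding bound puts the neglected relative tail mass (over the
counts actually used) below ~1e-10, and apply the same compound-Poisson
recursion to *h*. Note h₀ > 0: a mutation can contribute no colonies, which
is what flattens the zero class at small ε. We deliberately avoid any
closed-form expression for the thinned law; the numerical route makes the
truncation error explicit and testable.

### Estimation and inference

- **MLE.** `ld_fit()` solves the score equation dℓ/dm = 0 using the
  analytic compound-Poisson identity dp_n/dm = (h∗p)_n − p_n, with
  safeguarded Brent root-finding started from m₀ = −ln(zero-count
  fraction) when defined, else 1. All-zero experiments return m̂ = 0 (the
  likelihood is monotone decreasing in m).
- **Confidence intervals.** Profile likelihood: the two solutions of
  ℓ(m) = ℓ(m̂) − qchisq(0.95, 1)/2 (= 1.9207). For all-zero data the lower
  bound is 0 and the upper bound has the closed form 1.9207/[n(1 − h₀)].
  The test suite measures empirical coverage at m = 2, 30 cultures over
  1,000 simulated experiments and requires it within 3 binomial standard
  errors of 95%.
- **Rates.** μ = m/N_t per cell per generation, with N_t the mean final
  viable count per culture supplied from CFU titers; CI bounds divide
  identically. This is the conventional normalization for reporting
  rifampicin-resistance rates.
- **Strain comparison.** `ld_lrt()` tests a shared rate (1 df). With equal
  N_t and ε the null model is simply the fit on pooled counts; otherwise
  the shared rate is profiled numerically. Its size is checked by
  simulation (rejection rate at α = 0.05 over 1,000 null pairs).
  `bh_adjust()` (stats::p.adjust, step-up) handles families of pairwise
  comparisons.

### Jackpot censoring

The 1/y² clone-size tail occasionally produces counts in the tens of
thousands, and the count recursion is O(n²) in the largest count needed.
`ld_fit(max_count = 1000)` treats counts above the threshold as
right-censored ("too numerous to count", exactly as saturated plates are
scored at the bench), contributing P(X ≥ cap) to the likelihood. The
likelihood remains exact for the censored observation scheme — coverage is
unaffected — while compute stays bounded. Set `max_count = Inf`-like large
values to fit extreme counts exactly; the suite checks that censored and
exact fits agree to ~2% on a jackpot dataset.

### Choice of ε

Plating volumes and dilutions vary between labs and are often not fully
specified; the plating fraction is therefore a free per-experiment
parameter (`epsilon` in the metadata table), defaulting to 1 (whole culture
plated). Mixed-dilution platings must be pre-converted by the caller to a
single effective ε.

## 2. Embedded-ribonucleotide quantification

### Pipeline

Alkaline electrophoresis denatures DNA and cleaves it at embedded
ribonucleotides (after RNase H2 treatment), so single-strand fragment sizes
measure the density of embedded rN. Per lane:

1. **Preprocess** (`preprocess_lane`): subtract one constant background from
   the whole lane — default the 2nd-percentile intensity, standing in for
   empty-lane staining; overridable per lane — clip negatives, and smooth
   with a cubic smoothing spline targeting 40 effective degrees of freedom
   (configurable; 40 df preserves band structure at typical profile
   resolutions while suppressing pixel noise). An all-zero lane after
   subtraction is an error: it cannot be quantified downstream.
2. **Calibrate** (`fit_calibration`): ladder peaks are local maxima with
   topographic prominence ≥ 5% of the lane maximum, paired to ladder sizes
   in order (largest size = smallest distance), averaged band-by-band
   across marker lanes, and fitted by least squares as
   d = a + b·log(sz), b < 0. When detection finds the wrong number of
   peaks the fit refuses and asks for manually supplied positions — the
   digital equivalent of supervised peak picking. Ladder band sizes come
   from the run configuration (they are a property of the commercial ladder
   used).
3. **Count fragments** (`fragment_count_profile`): sz = exp((d − a)/b) and
   n_sz = I_sz/sz, because staining intensity is proportional to deposited
   mass. The identity Σ(sz·n_sz) = ΣI holds algebraically and is asserted
   exactly in the tests.
4. **Cut-off.** Near the gel bottom, small intensity noise maps to large
   spurious counts of small fragments (I/sz blows up as sz → 0), so
   intervals beyond d_max are discarded. We parameterize by the minimum
   fragment size `sz_min` (default 500 nt, a typical resolution limit for
   genomic alkaline gels; always reported in outputs) and derive d_max
   through the calibration.
5. **Mean size and correction.** s̄z̄ = Σ(sz·n_sz)/Σn_sz over retained
   intervals; the correction s̄z̄_corr = s̄z̄·e^{−sz_min/s̄z̄} accounts for
   fragments below sz_min. For exponentially distributed fragment sizes
   observed above sz_min, the truncated mean is λ + sz_min and the
   correction returns λ to first order; the suite checks recovery of
   λ = 20,000 nt within 0.5% at sz_min = 500.
6. **Breakpoints and differencing.** N = G/s̄z̄_corr with G = 9.28×10⁶ nt
   (both strands of the 4.64-Mbp chromosome, since alkaline gels resolve
   single strands). N_ribo = N_ΔrnhB − mean(N of all RNase HII-proficient
   lanes on the same gel). Negative estimates are reported with a warning,
   never clamped — they are informative quality-control signals.
7. **Reporting** (`summarize_ribo`): per-Mb (= per-genome/(G/10⁶)) and
   kb-per-rN (= (G/10³)/per-genome) are computed per replicate then
   averaged; folds are ratios of strain means to the reference mean;
   Welch's unequal-variance t-test compares per-genome replicate values
   against the reference. Display rounding (integers for per-genome and
   per-Mb, 1 decimal for kb-per-rN, 2 for folds) lives in the print
   method; the underlying data frame keeps full precision.

## 3. Mutation spectra

Calls are 1-based coordinates in the *rpoB* gene; the reporting window is
the closed interval [1516, 1717] (the sequenced rifampicin
resistance-determining region). Substitutions are collapsed onto six
base-pair classes by complementing calls made at G or T references, with no
attempt to infer transcribed-strand asymmetry. Transitions are CG>TA and
AT>GC; conservation (transitions + transversions = total) and strand
symmetry are asserted exhaustively over all 12 ordered base changes.
Isolates with several in-window mismatches contribute several calls;
ambiguous bases are skipped at the calling step.

`find_hotspots()` needs a numeric rule where practice is usually visual: we
default to positions carrying ≥ 5% of all calls, sorted by count then
position (ascending position breaks ties). `spectrum_compare()` (Monte-Carlo
contingency test via stats::chisq.test) is auxiliary plumbing for
exploratory comparisons, not part of the core reporting.

## 4. What the generators emulate — and what they do not

`sim_config()` fixes the simulated study conditions:

| parameter | default | meaning |
|---|---|---|
| `m_true` | 2 | mutational events per culture — a realistic mid-range value at which the mutant-count distribution is informative |
| `epsilon` | 1 | whole culture plated |
| `n_cultures` | 30 | mid-range of the 15–57 cultures commonly used |
| `Nt` | 2×10⁸ | ~100 µl of a saturated overnight culture |
| `G` | 9.28×10⁶ nt | single-strand genome length |
| `rho` | 5×10⁻⁵ /nt | nick density giving ~465 breakpoints/genome, matching wild-type ΔrnhB levels |
| `calib_a`, `calib_b` | 450, −25 | maps 50 nt–10 Mnt onto a ~320-unit lane |
| `band_sd` | 2 | Gaussian band spread (distance units) |
| `background`, `noise_sd` | 200, 10 | constant lane background; additive Gaussian noise |
| `class_probs` | wild-type-like | six-class substitution probabilities |
| `position_weights` | mild peaks at 1547/1577/1687/1714/1715 | hotspot structure |

Generator realism notes:

- Fluctuation counts realize exactly the model the estimator assumes
  (deterministic growth, no phenotypic lag, no differential mutant fitness,
  no plating death). Passing tests therefore demonstrate *estimator*
  correctness, not robustness to those biological violations.
- Nicks are placed uniformly on a **linear** single-strand molecule
  (genomic DNA is sheared during preparation; end effects are negligible at
  G ≈ 9.28×10⁶), giving K+1 fragments whose sizes sum to G exactly.
- The lane renderer deposits mass-proportional intensity with a Gaussian
  band spread; it does not model diffusion-dependent band widths, lane
  smiling, partial RNase H2 digestion, or staining saturation. Ladder lanes
  are rendered with `counts = max(sizes)/sizes` molecules per band, because
  commercial ladders load roughly equal mass per band.
- Substitution calls draw class and position independently; real spectra
  couple them (a hotspot is usually hot for one class).

## 5. Numerical choices and degenerate inputs

- Clone-law thinning truncation: relative neglected tail below ~1e-10
  (Hoeffding-bounded), far below the 1e-8 documentation target.
- pmf entries are non-negative by construction; Σp ≤ 1 with deficit ~m/n_max
  (heavy tail), asserted in tests.
- The O(n²) recursions run in C++ (Rcpp); 1,000-replicate calibration
  studies complete in well under a minute.
- Root-finding brackets expand geometrically (score sign change; likelihood
  drop for CI bounds) and fail loudly if no bracket exists.
- `smooth.spline` reproduces linear profiles exactly (the penalty null
  space), asserted to 1e-6.
- Ties in hotspot ordering break by ascending position; `summarize_ribo`
  returns p = 1 for the reference strain by definition and NA when either
  strain has a single replicate.
- Simulation problem sizes used by the test suite — 10⁶ cultures for the
  Monte-Carlo pmf oracle, 1,000 replicates for coverage and test size, 20
  datasets for the grid-search oracle, 10 gels for end-to-end recovery —
  were chosen so Monte-Carlo error is small against each tolerance while
  the whole suite stays fast enough to run routinely.
- End-to-end gel recovery is judged two ways: per gel against that gel's
  *realized* nick difference (isolating densitometry error from binomial
  nick-sampling noise, whose SD is ~7% of the target difference), and
  averaged across gels against the expected value (ρ_mut − ρ_wt)·G.

## 6. Known limitations

- No phenotypic lag, cell death, or differential mutant fitness in the
  fluctuation model; no Bayesian estimation.
- One ε per experiment; mixed dilutions need pre-conversion.
- The gel pipeline starts from densitometry profiles; image → profile
  extraction is upstream. RNase H2 digestion efficiency is assumed
  complete, so incomplete digestion reads as fewer ribonucleotides.
- Spectra assume ungapped, pre-aligned windows (no indels) and do not
  annotate codon consequences.
- The printed reporting arithmetic (per-Mb, folds) is reproduced from
  summary inputs in the tests; raw densitometry beneath published tables
  is generally unpublished, so full-table regeneration depends on the
  cut-off (sz_min) chosen by the original analysts.

```{r}
# a compact end-to-end illustration
cfg <- sim_config(seed = 1, n_cultures = 30, m_true = 2, Nt = 2e8)
fit <- ld_fit(simulate_fluctuation_counts(cfg), Nt = 2e8)
coef(fit)
confint(fit)
```
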