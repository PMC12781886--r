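---
title: "Kinetic dissection of cold-induced FLC repression: models, inference, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic dissection of cold-induced FLC repression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldsplice)
```

# The scientific problem

During vernalization, weeks of cold progressively shut down transcription
of the Arabidopsis floral repressor *FLC* through a combination of
transcriptional repression and Polycomb-mediated epigenetic silencing.
Dissecting *which* step of the transcription cycle changes — productive
initiation, PolII elongation speed, splicing/intron processing, mRNA
turnover — is hard because several distinct changes produce similar
signatures in RNA abundance data. This package implements the
quantitative machinery needed to separate these contributions:

* closed-form steady-state models of RNA signal across a long intron
  (nascent plus lariat contributions) and of the spliced/unspliced
  transcript system;
* exponential mRNA-decay models with a correction for the equal-loading
  bias of qPCR after transcription inhibition;
* a single-ellipsoid nested-sampling engine providing posteriors *and*
  Bayesian evidences, hence Bayes-factor model comparison;
* NET-seq style termination-index analytics that convert PolII 3'-end
  coverage into elongation-rate fold changes and Polycomb-state
  fractions;
* synthetic-data generators that emulate each measurement type, so every
  stage of the pipeline is testable without any external download.

# The intron steady-state model

Consider an intron of length $L$ transcribed at productive initiation
rate $F$ with PolII speed $v$. Intronic sequence at offset $\ell$ from
the donor carries signal from two species:

* **Nascent transcripts.** A PolII that has passed $\ell$ carries the
  position until the intron is processed. Transit of the remaining
  $L - \ell$ nt takes $(L-\ell)/v$ and processing (a composite of the
  steps that convert intronic nascent RNA into a released lariat) adds a
  mean dwell $1/k_s$, giving
  $N(\ell) = F\left[(L - \ell)/v + 1/k_s\right]$.
  The slope along the intron is the PolII density $-F/v$ and the level
  at the acceptor is $F/k_s$.
* **Lariats.** The released lariat is degraded 5'→3' at speed $k_d$, so
  position $\ell$ survives for $\ell/k_d$ after excision:
  $\Lambda(\ell) = F\,\ell/k_d$, a rising gradient that vanishes at the
  donor.

Total RNA contains both components; chromatin-bound RNA contains the
nascent component plus a retained fraction $f_{\mathrm{lariat}}$ of the
lariat component:
$T(\ell) = N(\ell) + \Lambda(\ell)$,
$C(\ell) = N(\ell) + f_{\mathrm{lariat}}\Lambda(\ell)$.
The measured total profile rises towards the acceptor exactly when
$k_d < v$.

Between conditions we model fold changes $\alpha$ in initiation,
$\beta$ in speed and $\gamma$ in processing, with lariat degradation and
retention unchanged; the predicted fold-change profile is the ratio of
the fraction profile under $(\alpha F, \beta v, \gamma k_s)$ to the
baseline profile. Because the two RNA fractions come from separate
experiments with visibly variable *FLC* shutdown, the initiation fold
change is allowed to differ between them ($\alpha_T$, $\alpha_{CB}$)
while $\gamma$ and $f_{\mathrm{lariat}}$ are shared.

Two modelling choices deserve emphasis:

* **$\beta$ is fixed, never inferred here.** The tiling data cannot
  separate a speed change from an initiation change (both scale the
  nascent slope); the elongation fold change is measured independently
  from the NET-seq termination index and supplied to the fit (0.8 at
  two weeks of cold, 0.65 at four weeks, and 0.6/0.5/0.3 at the
  post-cold timepoints).
* **The lariat profile is a pure degradation gradient.** No
  debranching-delay constant is included; with such a term absorbed
  into $1/k_s$ the observable profile shapes are unchanged over the
  regimes considered.

Intron offsets are measured from the donor (5' splice site), the natural
frame for 5'→3' lariat degradation; conversion from genome/TSS
coordinates is the caller's responsibility at I/O time.

# The two-species splicing-ratio analysis

Unspliced transcripts $U$ are produced at rate $F$, spliced at rate
$k_s$, and optionally degraded at rate $d_U$ (e.g. by NMD); spliced
transcripts $S$ decay at rate $d_S$:
$U^* = F/(k_s + d_U)$, $S^* = F k_s /((k_s+d_U)\,d_S)$, so the
steady-state ratio is exactly
$$S^*/U^* = k_s / d_S,$$
independent of both $F$ and $d_U$. Consequently (i) a changed
spliced:unspliced ratio cannot be produced by changed degradation of the
unspliced form, and (ii) if $d_S$ is unchanged between conditions —
which the decay experiments test directly — the fold change of the ratio
*is* the fold change of the splicing rate. `splicing_fc()` implements
the ratio-of-ratios with first-order (delta-method) error propagation:
the relative variance of the fold change is the sum of the four relative
variances. The unchanged-$d_S$ assumption is recorded in the output.

# mRNA decay and model comparison

After transcription inhibition, abundance follows
$m(t) = (m_0 - a)e^{-\delta t} + a$; the asymptote $a$ (default 0)
captures residual transcription if shutdown is incomplete. Fits exclude
the untreated timepoint (inhibitor uptake is not instantaneous) and use
per-timepoint means with standard errors — for smFISH data, the mean
foci-per-cell-area across cells. Whether a cell-level likelihood would
sharpen the posterior is an open question; the summarized likelihood is
the more conservative choice and reproduces the targeted uncertainties.

qPCR decay courses carry a specific bias: equal total RNA is loaded per
sample while global RNA levels fall after inhibition. Using a
slow-decaying reference transcript with an independently known
half-life (about 24 h), `correct_decay_bias()` rescales every profile by
$c(t) = 2^{-t/t_{1/2}^{\mathrm{ref}}}/\mathrm{ref}(t)$; the corrected
reference then equals its assumed true decay exactly and the correction
is idempotent.

Condition comparisons use Bayesian evidences rather than point
estimates: `compare_decay()` computes the Bayes factor between a model
with separate decay rates and one with a shared rate. On the Jeffreys
scale, factors within $10^{\pm 1/2}$ of 1 are "barely worth
mentioning"; our reading of a "weak evidence" outcome for shared-rate
data is that the different-rates model gathers *no substantial support*
(BF $< 10^{1/2}$). With uniform rate priors over $[0.01, 2]\,h^{-1}$
the Occam penalty typically pushes the factor well below 1 on
shared-rate data — evidence actively favouring the simpler model — and
the acceptance check asserts the absence of spurious support for the
richer one.

# Nested sampling

The inference engine is a from-scratch single-ellipsoid nested sampler
over uniform box priors:

* live points start uniform in the unit cube; at each iteration the
  lowest-likelihood point is retired under deterministic volume
  shrinkage $X \to X e^{-1/n_{\mathrm{live}}}$ with trapezoidal weight
  $w_i = (X_{i-1} - X_{i+1})/2$;
* the replacement is drawn by rejection inside the minimum-covariance
  bounding ellipsoid of the live set, scaled so the farthest point is on
  the boundary and enlarged by 1.25 in volume (configurable); a stale
  ellipsoid is only conservative, so it is re-fitted at intervals of
  $n_{\mathrm{live}}/10$ iterations and immediately whenever $10^4$
  consecutive draws are rejected (with a progressively larger
  enlargement);
* termination follows the maximum-remaining-evidence criterion,
  $\log(1 + L_{\max} X / Z) < \texttt{dlogz}$ with default 0.5, after
  which the live points are absorbed with weight $X/n_{\mathrm{live}}$;
* the reported uncertainty is
  $\sqrt{H/n_{\mathrm{live}}}$ with $H$ the information.

**Plateau handling.** Exact likelihood ties (including the $-\infty$
region of a hard constraint, and degenerate but useful cases such as
top-hat likelihoods) violate the order-statistics argument behind
exponential shrinkage and would bias the evidence — a step likelihood
occupying half the prior would be estimated at volume $e^{-1/2}$
instead of $1/2$. Tied points are therefore retired as a block of $m$
with *linear* shrinkage $X \to X\,(n-m)/n$ and equal shares of the
retired interval. Replacement points must otherwise strictly exceed the
retired likelihood. Degenerate live-point clouds regularize the
ellipsoid shape matrix with a small diagonal jitter and a logged
warning.

Defaults: `n_live = 400` (large enough to stabilize Bayes factors;
tests and the calibration study use 100–200 where the posterior is easy
and runtime matters), `enlarge = 1.25`, `dlogz = 0.5`. Every run is
reproducible bit-for-bit under a fixed seed, and `n_live` must be at
least twice the dimension.

Prior bounds are configuration, not constants: fold changes default to
$[0.01, 20]$, $f_{\mathrm{lariat}}$ to $[0,1]$, decay rates to
$[0.01, 2]\,h^{-1}$, and $m_0$ to $[0, 3\max(\mathrm{data})]$. The
baseline kinetic rates ($v$, $k_s$, $k_d$) are likewise inputs with
documented provenance — they are constrained by published elongation
and splicing-rate ranges rather than fitted here.

# NET-seq termination index

plaNETseq maps the 3' end of PolII-associated nascent RNA at
single-nucleotide resolution. After removing read 3' ends that coincide
with annotated splice sites (splicing intermediates, not PolII
positions; matching is exact single-base by default with a configurable
width, strand-aware) and normalizing libraries to the geometric mean of
reference-gene totals, the termination index is
$$\mathrm{TI} = \frac{\text{counts in } [\mathrm{PAS}-150,\ \mathrm{PAS}+400)}
                      {\text{counts over the remaining gene body}},$$
in transcript orientation (the window is flipped for minus-strand
genes; both windows are half-open). Under a steady-state picture where
local density is $F/v$ with region-wise constant speed and the
termination-window speed unchanged, the TI is proportional to the
gene-body speed, so the TI ratio between conditions estimates the
elongation-rate fold change directly; initiation changes cancel. Signal
downstream of the 3'UTR end is excluded from the body. A dwell-time
model of the termination window itself is deliberately out of scope:
only ratios between conditions are interpreted, for which any constant
termination dwell cancels.

Post-cold speed fold changes are converted into Polycomb-state
fractions by a copy-weighted *arithmetic* speed mixture: if a fraction
$p$ of gene copies sit in an H3K27me3-spread state roughly 10-fold
slower than the active state, the population-average speed fold change
is $(1-p) + 0.1\,p$, so $p = (1 - \mathrm{FC})/0.9$. The arithmetic
mixture is the natural reading of a copy-averaged speed and reproduces
the reported fractions (0.6 → ~0.4, 0.5 → ~0.6, 0.3 → ~0.8); a harmonic
mixture would not.

# What the synthetic data emulate — and what they do not

The generators produce every input the pipeline consumes, with the
statistical structure the likelihoods assume, and attach the generating
parameters to each dataset:

* **Tiling profiles**: model fold changes at each primer position times
  multiplicative Gaussian replicate noise (`value * (1 + eps)`), so the
  replicate s.d. scales with the level as qPCR error approximately
  does; default three replicates, 10% relative noise.
* **Decay courses**: exponential means with additive Gaussian noise at
  timepoints 0/2/4/6 h; the smFISH variant draws log-normal cell areas
  (median 10 µm², log-s.d. 0.4 — the study reports no area
  distribution, so these are a plausible choice) and Poisson foci
  counts with mean density × area, collapsed to mean ± s.e.
* **Coverage**: piecewise-constant expected density per the TI model,
  an optional two-state active/Polycomb copy mixture, and per-base
  Poisson counts (the real count noise model is unstated; Poisson is
  the minimal choice).
* **Ratio time courses**: two-species steady states with the splicing
  rate scaled per condition.

A single replicate-noise term stands in for the unstated decomposition
into technical and biological qPCR variance. The generators do *not*
simulate raw reads, UMIs, images, antisense (*COOLAIR*) coverage, or
between-experiment batch effects — so passing recovery tests show that
the inference machinery is correct and calibrated under the assumed
noise model, not that the assumed noise model is a complete account of
real experiments.

# Numerical choices and degenerate inputs

* Per-datum s.d. from replicates uses the $n-1$ sample s.d. with a
  floor of 5% of the mean magnitude, preventing zero-s.d. degeneracy in
  noise-free or lucky draws.
* Positions outside $[0, L]$, negative timepoints, asymptotes outside
  $[0, m_0)$, termination windows outside the gene span, non-positive
  reference totals, and single-position tiling profiles are rejected
  with messages naming the offence.
* A zero gene-body count makes the TI undefined (`NA` with a warning)
  rather than infinite.
* `-Inf` log-likelihoods are legal (hard constraints) and carry zero
  quadrature weight.
* Weighted posterior quantiles invert the weighted empirical CDF
  without interpolation; credible intervals are central 95% intervals.
* Bayes factors refuse non-converged runs (`max_iter` exceeded flags
  the result instead of silently truncating).

# Problem sizes used by the test suite

The shipped tests run the full pipeline at sizes chosen to exercise the
statistics honestly while staying quick: 12 tiling positions × 2
fractions × 3 replicates per intron fit; 100 cells per smFISH
timepoint; depth-2 Poisson coverage over a 5.7-kb gene with 4 replicate
libraries per condition; 20 seeded repeats for the Bayes-factor band
and 50 synthetic datasets (200 credible intervals) for the calibration
study, run at `n_live = 100`; consistency checks that compare sample
means to printed densities use larger cell counts (500–5000) so that
sampling noise does not dominate a one-decimal comparison. Calibration
coverage is asserted within a three-standard-error binomial band around
0.95.

# Known limitations

* The single-ellipsoid proposal is adequate for the unimodal, low-
  dimensional posteriors here; strongly curved or multimodal targets
  would need multi-ellipsoid or slice sampling, which are out of scope.
* The intron processing rate $k_s$ is a composite; agreement between
  its fold change (intron 1) and the splicing-ratio fold change
  (intron 2/3 junction) is a consistency argument, not an identity.
* The splicing-rate interpretation of the ratio fold change leans on an
  unchanged $d_S$; the package tests this assumption on decay data but
  cannot enforce it for arbitrary user data.
* The TI-to-speed conversion assumes initiation and termination-window
  dwell are condition-invariant; violations bias the inferred $\beta$,
  which then propagates into the intron fit as a fixed input.
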