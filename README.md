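# coldsplice

Kinetic dissection of cold-induced transcriptional repression at the
Arabidopsis floral repressor *FLC*.

During vernalization, weeks of cold progressively silence *FLC*. Bulk
RNA measurements alone cannot tell *which* step of the transcription
cycle changed: reduced initiation, slower PolII, faster splicing and
altered mRNA turnover all leave similar fingerprints in abundance data.
`coldsplice` provides the models and Bayesian inference machinery to
separate them, for anyone analysing qPCR tiling profiles,
transcription-inhibition decay courses, smFISH counts, or NET-seq
style nascent-transcript coverage at this or similar loci.

## What is inside

* **Intron steady-state model** — signal at offset `l` from the intron
  donor is nascent plus lariat:
  `N(l) = F((L-l)/v + 1/k_s)`, `Lambda(l) = F l/k_d`, with total RNA
  `N + Lambda` and chromatin-bound RNA `N + f_lariat * Lambda`.
  Condition fold changes `alpha` (initiation), `beta` (PolII speed,
  fixed externally) and `gamma` (intron processing) are inferred from
  fold-change tiling profiles (`fit_intron`).
* **Two-species splicing analysis** — at steady state the
  spliced:unspliced ratio is exactly `k_s/d_S`, independent of
  unspliced degradation; with unchanged `d_S`, the fold change of the
  ratio is the fold change of the splicing rate (`splicing_fc`,
  delta-method errors).
* **mRNA decay** — exponential fits with optional asymptote,
  qPCR loading-bias correction against a slow reference transcript
  (`fit_decay`, `correct_decay_bias`), and shared-rate versus
  different-rate model comparison by Bayes factor (`compare_decay`).
* **Nested sampling** — a from-scratch single-ellipsoid sampler over
  uniform box priors returning log-evidence, weighted posteriors and
  Jeffreys-scale Bayes factors (`nested_sampling`, `bayes_factor`),
  with unbiased handling of likelihood plateaus.
* **NET-seq analytics** — splice-intermediate filtering, reference-gene
  normalization, the termination index
  `TI = counts[PAS-150, PAS+400) / remaining gene-body counts`, PolII
  speed fold changes `TI_cond/TI_ref`, and two-state Polycomb mixture
  fractions `p = (1 - FC)/(1 - 0.1)` (`termination_index`, `speed_fc`,
  `spread_fraction`).
* **Synthetic data** — seeded generators for every input type, with
  ground truth attached (`sim_tiling_profiles`, `sim_decay_course`,
  `sim_smfish_cells`, `sim_coverage`, `sim_ratio_timecourse`).

## Worked example

Simulate a 2-week-cold-like experiment and re-infer its parameters —
paired total and chromatin-bound tiling profiles across a 3-kb intron
(initiation fold changes 0.67 and 1.3, processing fold change 6.8,
lariat retention 0.17), with the elongation fold change fixed at 0.8:

```r
library(coldsplice)

base <- intron_params(init_rate = 1, pol_speed = 1500, proc_rate = 1/3,
                      lariat_speed = 500, intron_length = 3000,
                      f_lariat = 0.17)
truth <- fold_change_params(alpha_total = 0.67, alpha_cb = 1.3,
                            beta = 0.8, gamma = 6.8)
profiles <- sim_tiling_profiles(base, truth, sim_config(seed = 11))
fit <- fit_intron(profiles$total, profiles$chromatin, base = base,
                  beta = 0.8, cfg = ns_config(n_live = 200, seed = 5))
posterior_summary(fit)
#>     parameter   mean     sd median  q025   q975
#> 1 alpha_total  0.665 0.0265  0.671 0.601  0.706
#> 2    alpha_cb  1.362 0.0949  1.375 1.133  1.520
#> 3       gamma 11.867 4.6793 11.711 3.938 19.528
#> 4    f_lariat  0.201 0.0349  0.199 0.129  0.269
```

Every 95% credible interval covers its generating value; note how
weakly a single noisy tiling experiment pins down `gamma` compared to
the sharply identified initiation fold changes — the same asymmetry the
real data show.

Decay half-life from a simulated smFISH time course (1.4 foci/µm² at
t = 0, true half-life 4.1 h, 100 cells per timepoint, untreated
timepoint excluded):

```r
course <- exclude_untreated(
  sim_smfish_decay(1.4, 4.1, sim_config(seed = 301, n_cells = 100))$course)
f <- fit_decay(course, cfg = ns_config(n_live = 150, seed = 1))
sprintf("half-life: %.2f +/- %.2f h", f$halflife$mean, f$halflife$sd)
#> [1] "half-life: 4.56 +/- 0.44 h"
```

And the post-cold PolII speed fold changes (0.6, 0.5, 0.3) converted to
fractions of gene copies in the slow Polycomb state:

```r
round(spread_fraction(c(0.6, 0.5, 0.3)), 2)
#> [1] 0.44 0.56 0.78
```

A bundled end-to-end run (`run_pipeline(demo_config(seed = 9), out)`)
chains simulate → fit → report and writes a JSON bundle with posterior
summaries, the configuration hash and the seed.

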