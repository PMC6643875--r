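---
title: "Mixture-model analysis of colony-fitness screens: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture-model analysis of colony-fitness screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenmix)
```

# The model

An arrayed colony-fitness screen measures, for each strain, colony sizes
under an experimental condition and one or two control conditions, in a few
replicates (4 by default here; 16 in validation re-screens). Colony sizes
under equal conditions are treated as lognormal, so all modeling happens on
log sizes. The per-strain summary is the log growth ratio,

$$\mathrm{LGR} = \frac{1}{|C|}\sum_{c \in C}
  \ln\frac{\overline{\mathrm{size}}_c}{\overline{\mathrm{size}}_\mathrm{exp}},$$

positive when the experimental condition grows worse. With two controls the
per-control log-ratios are averaged (average of logs, not log of averages:
this keeps the statistic antisymmetric under swapping experimental and
control roles).

Screen-wide, the smoothed LGRs are modeled as a two-component Gaussian
mixture,
$$f(x) = (1-\rho_2)\,\mathcal N(x;\mu_1,\sigma_1^2)
       + \rho_2\,\mathcal N(x;\mu_2,\sigma_2^2),\qquad \mu_2 \ge \mu_1 .$$
Component 1 is an empirical null: strains unaffected by the perturbation,
spread purely by measurement noise. Component 2 collects the strains with
real growth defects; its shape mixes noise with the (unknown) distribution
of true effect strengths, which we assume Gaussian. The posterior
probability of being a hit given a measured LGR,
$$q(x) = \frac{\rho_2\,\mathcal N(x;\mu_2,\sigma_2^2)}{f(x)},$$
drives everything downstream: the cutoff $L_{q,0.5}$ solves $q(x)=0.5$, the
predicted validation probability is $p_V(x)=q(x)$, and the predicted
false-positive rate is $1-p_V(x)$. The classical $L_Z$ (LGR where the
Z-score reaches 2) is always reported alongside. When a screen has many
hits, the Z-denominator is inflated by the hit tail, so $L_{q,0.5}$ sits
below $L_Z$, increasingly so with more hits — which is precisely why hit
counts under the posterior cutoff have a wider dynamic range.

# Pipeline stages and their parameters

Stage order: plate normalization → LGR → spatial smoothing → duplicate
aggregation → Z-transformation → mixture fit → classification → cutoffs →
hit calls.

* **Plate normalization** (`plate_norm`): every physical plate (plate ×
  condition × replicate) is divided by the median of its nonzero colony
  sizes (primary screens), or by the median of its GFP-free reference
  colonies (validation screens). Unitless; idempotent. Note a real
  consequence: in a screen where a sizable fraction of colonies are small
  (many hits), the plate median itself is depressed, which shifts *all*
  LGRs by a small constant (about −0.07 LGR at 15% hits with unit-strength
  effects). We keep the conventional per-plate median because it needs no
  annotation of which strains are null.
* **Replicate summary**: arithmetic mean of nonzero sizes per condition;
  zero size means a dead colony, not a missing record. A strain with all
  experimental replicates dead is flagged `dead` (LGR = NA, never ±Inf);
  at least half dead → `sick`, still scored, because slow growers combine
  plate normalization with proportionally large measurement error and can
  masquerade as growth enhancers; an all-zero control → `control_failure`.
* **Spatial smoothing** (`smoothing_window` = 7 grid cells,
  `smoothing_min_neighbors` = 8): adjusted = raw − median of the
  surrounding window *excluding self*, then recentered so the plate-wide
  median is unchanged. Self-exclusion stops an isolated strong hit from
  being subtracted out of itself; the median (vs mean) background is
  robust to the hits that do fall inside a window. Positions with too few
  scored neighbors are left unadjusted and flagged `unsmoothed`. The 7×7
  default trades bias (artifact curvature within the window) against the
  sampling noise of a 48-cell median; both knobs are exposed.
* **Duplicate aggregation**: library copies of the same strain sit at
  different positions, so they are averaged *after* smoothing.
* **Mixture fit** (`fit_config`): EM with unequal variances, `n_starts` =
  10 initializations seeded by a random top-quantile split (top 5–30%
  assigned to Component 2), tolerance 1e-8 on the relative log-likelihood
  change, at most 1000 iterations. Variances are floored at 1e-4 × the
  sample variance to rule out singular collapse onto single points — a
  standard mixture pathology. Ties across starts break toward the smaller
  hit fraction. The per-iteration log-likelihood trace is stored and must
  be non-decreasing; the returned labels always satisfy $\mu_2 \ge \mu_1$.
* **Fit classification** (`classify_mu2_min` = 2.0, `classify_sigma2_max`
  = 4.0): a fit is `no_hit_peak` if the peaks are separated by less than
  2σ₁ or Component 2 carries less than 1/n of the mass — the screen has
  too few (or too weak) hits for the empirical-null machinery, and the
  Z-transformation is the appropriate tool, which is exactly what
  `analyze_screen` falls back to. `high_variance` (σ₂ > 4σ₁) marks fits
  whose validation predictions were unreliable in practice; cutoffs from
  such fits are withheld. The two thresholds are defaults calibrated only
  in the sense that clearly unimodal simulations classify `no_hit_peak`;
  both are configuration, not claims.
* **Hit calls**: closed comparisons (`z ≥ 2`, `q ≥ 0.5`). Growth
  enhancers (`z ≤ −2`) are annotated in their own column and never count
  as hits — they rarely reproduce on validation. Validation of a
  re-screened strain means its 16-replicate LGR exceeds mean + 2 sd of the
  GFP-free reference LGRs (a 95th-percentile option exists).

# What the simulator states, and what a green test means

`simulate_screen` generates log colony size as
`log(base_size) + plate offset + gradient(row, col) − θ·[experimental] +
N(0, σ_noise²)`, with θ = 0 for null genes and θ ~ N(μ₂_true, σ₂_true²)
truncated at zero for hits (growth defects only; enhancers are outside the
generator's world). Defaults: 4,000 genes on 16×24 plates, 4 replicates
(16 in validation), ρ₂ = 0.15, μ₂ = 1.0, per-colony noise σ = 0.33 (which
propagates to a null LGR sd near 0.2 — `lgr_noise_sd()` gives the closed
form, and `sim_params_for_lgr_mixture()` inverts it), plate offsets with
sd 0.15, gradient amplitude 0.2, 5% duplicated genes, 8 GFP-free
references per plate. Seeds are mandatory arguments; validation re-screens
derive their seed by a fixed offset.

One deliberate deviation from the obvious "paired plates" reading: the
*layout* is shared across conditions (a strain's controls sit at the same
coordinates), but the spatial gradient is drawn independently for every
physical plate copy. If controls shared the experimental plate's gradient
field exactly, the gradient would cancel term-for-term in the LGR and
spatial smoothing would be pointless by construction; independent per-copy
artifact fields are also how drying and incubator-position effects arise
in practice. Relatedly, the smoothing benefit is measured as the fraction
of the *gradient-attributable* degradation removed — smoothed-vs-raw MAE
compared against matched gradient-free baselines — so the smoother's
flat-plate overhead is not charged to the artifact.

The generator emulates: lognormal sizes, plate-scale offsets, smooth
linear tilts, replicate noise, duplicates, reference colonies, dead
colonies (off by default). It does not emulate batch effects between
growth days, growth-curve dynamics, colony-morphology artifacts, or
spatially correlated biology (neighboring library strains are related on
real plates). A green recovery test therefore establishes that the
estimator and cutoffs behave on data satisfying the model's own
assumptions — not that any particular laboratory screen does.

The "few-hit" fixture uses weak effects (μ₂_true = 0.3, under the 2σ₁
separation rule) rather than merely few strong hits: a 2% component at 5σ
separation is still genuinely detectable by EM, and the classification
rule is designed to catch *indistinct* hit peaks, which is the regime the
fixture is meant to represent.

# Numerical choices

* All posterior and likelihood computations run in log space
  (`log-sum-exp`, `plogis` on log-density differences), so q(x) is exact
  to machine precision 50σ beyond either mean.
* `lq_cutoff` brackets the first crossing of q(x) = 0.5 on a 512-point
  grid over [μ₁, μ₂] and bisects to |Δx| < 1e-9. With unequal variances
  q(x) is also large in the far-left tail (the wide component wins both
  tails); only the between-means crossing is a meaningful cutoff, and
  q(μ₁) ≥ 0.5 is reported as "components indistinguishable".
* UPGMA uses the Lance–Williams average-linkage update with deterministic
  lowest-index tie-breaking; heights are merge-average distances, Newick
  branch lengths are differences of half-heights (ultrametric). Distances
  are 1 − Pearson correlation over pairwise-complete entries (centered by
  default, uncentered optional); pairs sharing fewer than 10 strains and
  zero-variance profiles raise errors rather than being imputed.
* Tables are TSV with `#` comments, `NA` as the only missing token, and
  numeric columns at 15 significant digits: the write→read round-trip is
  the identity to well under 1e-12, which 6-digit formatting could not
  honor.

# Known limitations

* The Gaussian assumption for Component 2 is convenience, not biology;
  heavy-tailed effect distributions will leak tail mass into σ₂ and can
  push a screen into the `high_variance` class.
* Plate-median normalization biases all LGRs left in proportion to the
  hit fraction (see above); comparisons *within* a screen are unaffected,
  absolute μ₂ values across screens with very different hit loads are not
  perfectly comparable.
* `pV(x) = q(x)` ignores re-measurement noise around the validation
  threshold; the noise-aware variant (off by default) multiplies by the
  probability that a true hit's 16-replicate mean clears the threshold.
* No batch-effect correction across plates grown at different times; the
  validation re-screen is assumed exchangeable with the primary screen up
  to replicate count.
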