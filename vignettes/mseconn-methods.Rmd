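---
title: "Multiscale entropy and connectivity analysis of resting-state fMRI: models and design choices"
author: "mseconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale entropy and connectivity analysis of resting-state fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mseconn)
```

## What the package computes

mseconn implements a complete group-comparison pipeline for preprocessed
resting-state BOLD fMRI built around two per-subject measures:

* **signal complexity** — sample entropy (SampEn) of each region's BOLD
  time series, evaluated over multiple coarse-grained temporal scales and
  summarized as multiscale entropy (MSE);
* **functional connectivity (FC)** — pairwise Pearson correlation between
  region-mean time series, variance-stabilized as Fisher's
  $z = \operatorname{atanh}(r)$.

Group inference then proceeds through a factorial Group $\times$ Sex
analysis of covariance (ANCOVA) per region or edge, network-wise
Benjamini–Hochberg (BH) false-discovery-rate control, partial correlations
with a symptom score, and a two-group comparison of
complexity–connectivity "linkage" partial correlations.  A synthetic
cohort generator with known ground truth exercises every stage, because
the motivating cohort data (two 383-volume runs at TR = 0.8 s, 63 cases
vs. 92 controls across 4 scan sites) are access-restricted.

## Sample entropy and multiscale entropy

For a series $x_1,\dots,x_N$, pattern length $m$ and absolute tolerance
$r_{abs}$, SampEn is

$$\mathrm{SampEn}(m, r) = -\ln \frac{A}{B},$$

where $B$ counts pairs of length-$m$ templates (start indices $1..N-m$,
self-matches excluded) whose Chebyshev distance is at most $r_{abs}$, and
$A$ counts those whose length-$(m+1)$ extensions also match.  Both template
pools use start indices $1..N-m$ (the Richman–Moorman convention), which
guarantees $\mathrm{SampEn}=0$ for a constant series and for any signal of
period $p \le m$.  When $A$ or $B$ is zero the conditional probability is
undefined; the package returns `NA` rather than a ceiling value, excludes
such scales from the MSE mean, and records `n_valid_scales`.

Coarse-graining at scale $s$ replaces the series by non-overlapping block
means, giving length $\lfloor N/s \rfloor$ (trailing remainder dropped).
MSE is the arithmetic mean of SampEn over scales $1..a$.

Defaults: $m = 2$, $r = 0.3$ (as a fraction of SD), $a = 15$ scales.  At
TR = 0.8 s these scales span sampling frequencies $1/(s \cdot TR)$ from
1.25 Hz (scale 1) down to 0.083 Hz (scale 15).  One printed intermediate
frequency in the motivating work (0.111 Hz at scale 9) is inconsistent
with this formula ($1/(9 \times 0.8) = 0.139$ Hz); the package implements
the formulaic mapping and treats that print as an erratum.

### Numerical conventions

* **Tolerance reference.** By default $r_{abs} = r \times$ the population
  (divide-by-$N$) SD of the *original* (scale-1) series, held fixed across
  scales — the Costa convention, which makes the per-scale values
  comparable in signal units.  `tolerance_reference = "per_scale_sd"`
  recomputes the tolerance from each coarse-grained series instead.
* **Distance.** Chebyshev (maximum coordinate difference).
* **No internal detrending or normalization.**  The relative tolerance
  makes SampEn exactly invariant under positive affine transforms of the
  signal (asserted in the tests); any detrending belongs upstream.
* **Determinism.** The kernel is exact counting; identical inputs produce
  bit-identical profiles.  The compiled counter visits template pairs in
  first-coordinate order so the inner loop can stop early, but counts the
  identical pair set as a naive double loop (asserted exactly in tests).

### What fixed-tolerance MSE means for "complexity"

Under the fixed-tolerance convention, coarse-graining shrinks the SD of
white noise by $\sqrt{s}$, so its SampEn falls steeply with scale, whereas
temporally correlated (e.g. $1/f$-like) signals keep more variance at
coarse scales and so keep higher SampEn there.  Consequently a *lower*
15-scale MSE mean indicates *less* long-range temporal structure — a more
white-noise-like signal — not merely "more regularity".  This matters for
the synthetic generator (below): implanting a reduced-complexity group by
*raising* AR(1) autocorrelation at constant variance would lower scale-1
SampEn but raise the coarse-scale values and the MSE mean, the opposite of
the intended group difference.  We verified this numerically (MSE means of
roughly 1.15 / 1.30 / 1.37 for a composite signal whose AR component has
$\varphi$ = 0 / 0.3 / 0.6), and therefore implant reduced complexity as a
*negative* AR(1) increment.

## Functional connectivity

Region-mean series are correlated pairwise (Pearson), and $|r|$ is clipped
to $1-10^{-7}$ before $\operatorname{atanh}$ so that degenerate duplicated
columns yield a large finite $z$ instead of infinity.  Per-subject run
combination averages the $z$ matrices element-wise and back-transforms
$r = \tanh(\bar z)$; this "average-z" first-level rule is a documented
stand-in for an unspecified multi-run convention, and run concatenation
remains possible by concatenating panels upstream.  Edges belong to a
network family when *both* endpoints belong to that network; the anterior
cingulate (AC) belongs to both FPN and DMN, so its units enter both
families.

## Group statistics

* **Rankit transform.** Covariates with skew (pubertal development score,
  CBCL-like symptom score) are mapped through average ranks to
  $\Phi^{-1}((\text{rank}-0.5)/n)$ and z-scored (`pds_z`, `cbcl_z`).
* **ANCOVA.** A linear model with effect-coded (sum-to-zero) Group, Sex,
  their interaction, continuous `pds_z`, and sum-coded site dummies;
  Type-III $F$ tests (via `car::Anova`) and partial
  $\eta^2 = F\,df_1/(F\,df_1 + df_2)$.  For the 1-df effects under this
  coding the Type-III $F$ equals the squared coefficient $t$, which is how
  the batched many-units path computes it (one QR decomposition shared
  across regions/edges; asserted equal to the per-unit fit in tests).
* **Post-hoc t.** The default is the unadjusted pooled-variance
  case-minus-control $t$; a covariate-adjusted contrast $t$ (from the
  ANCOVA Group coefficient) is available by flag.  Both are reported
  because published per-region $t$ values cannot generally be reconciled
  with $\sqrt{F}$ of the same model, and the package does not attempt to
  emulate that inconsistency.
* **BH-FDR.** The classic step-up rule per declared family, one family per
  network at $q = 0.05$; dual-membership regions enter both families and a
  unit is flagged if any of its families rejects it.  Cross-network edges
  and linkages are reported but excluded from per-network families; an
  optional global-FDR mode corrects everything in one family.
* **Partial correlation.** Least-squares residualization of both variables
  on the covariates (with intercept; factors expand to dummies), Pearson
  correlation of residuals, $p$ from
  $t = r\sqrt{(n-2-k)/(1-r^2)}$ with $k$ the covariate column count.
* **Two-group comparison.** Fisher-z difference
  $z = (\operatorname{atanh} r_1 - \operatorname{atanh} r_2)\big/
  \sqrt{1/(n_1-k-3) + 1/(n_2-k-3)}$, two-sided normal reference.
* **Matching statistics.** Yates continuity-corrected $\chi^2$ for 2×2
  tables and the pooled two-sample $t$ from summary moments, for checking
  group matching against published tables.

Linkages are seed-anchored and directional: the partial correlation of a
seed region's MSE (or per-scale SampEn) with each of that seed's edges,
estimated within each group and compared between groups, giving
$R(R-1)$ linkages for $R$ regions.

## The synthetic cohort generator

Each ROI time series per run is

$$x_i(t) = \lambda_i\, g_{net(i)}(t) + \varepsilon^{AR}_i(t) +
\varepsilon^{white}_i(t),$$

with $g_{net}$ a fresh band-limited $1/f$-power-shaped ("pink") standard
signal shared by the regions of a network (multi-network regions load on
their first-listed network), an AR(1) noise term with marginal SD fixed at
`ar_sd` (innovations scaled by $\sqrt{1-\varphi^2}$, so changing $\varphi$
changes temporal structure, not variance), and white noise.  Per-subject
heterogeneity comes from drawing $\lambda_i \sim N(0.7, 0.1)$ and
$\varphi_i \sim N(0.45, 0.05)$ once per subject; the two runs are
independent draws sharing these parameters.

Implanted case-group effects:

* **complexity** — `complexity_effect` (default $-0.3$) is added to
  $\varphi$ in FPN regions, stripping temporal structure at constant
  variance and lowering the MSE mean (see the convention discussion
  above);
* **connectivity** — `fc_effect` (default $0.5$) loads two extra shared
  pink signals onto the AC–R.SFG and AC–L.MidFG pairs, raising exactly
  those edges' correlations (and, as a documented side effect of the
  added variance, slightly diluting the AC's other edges).

Covariates are drawn to match the published cohort description: group
sizes 63/92; per-group female proportions 25/63 and 29/92; per-group PDS
moments 1.665 ± 0.542 and 1.687 ± 0.522 clipped to [1, 4]; four scan
sites uniform; symptom scores normal with per-group moments 5.412 ± 2.152
and 1.228 ± 1.570 clipped at 0 (clipping perturbs the control-group mean
slightly upward); a Bernoulli(0.5) medication flag among cases.

The implanted effect sizes are deliberately *stronger* than the published
group effects ($\eta_p^2 \approx 0.03$–$0.05$): the generator's purpose is
parameter recovery — a sharp correctness check that the pipeline flags the
implanted locations in the implanted directions and nothing else — not
effect-size emulation.  What passing recovery shows is that the estimator
and the multiplicity logic are wired correctly; it does not show that
effects of the published magnitude would be detectable at these sample
sizes, nor does the generator model hemodynamics, head motion, scanner
drift, or spatially varying noise.  A further known limitation: because
reduced complexity is implanted as reduced autocorrelation, the case
group's scale-1 SampEn is slightly *higher* than controls', while the MSE
mean and mid/high scales carry the implanted negative direction; empirical
reports show the group difference largest at fine scales.

4D phantoms (ROI blocks on a small voxel grid carrying the panel series
plus voxel noise) exercise the voxel-wise entropy map and ROI-extraction
paths, including NIfTI round-trips.

## Validation suite and problem sizes

The package's checks, all runnable via `testthat`, include:

* exact agreement of the compiled SampEn counter with a naive double-loop
  oracle on random short series, and of the partial correlation with the
  precision-matrix formula to $10^{-10}$;
* the analytic iid-Gaussian limit
  $-\ln(2\Phi(r/\sqrt2)-1) \approx 1.784$ for $m=2$, $r=0.3\,\sigma$ at
  $N = 10^4$, within 0.05 over 20 seeds;
* published-table arithmetic (sex $\chi^2$, CBCL and PDS matching $t$,
  scale frequencies) recomputed from the printed inputs;
* type-I error of the Group ANCOVA and of the partial-correlation
  comparison within [0.035, 0.065] at $\alpha = .05$ (2000 null
  replicates each, with a 0.5 SD power check);
* full-pipeline recovery over 100 default-size synthetic cohorts:
  implanted FPN complexity reduction and both implanted AC edges
  recovered after network-wise BH in at least 80% of cohorts, the
  implanted edges carrying the largest FPN z differences in at least 90%,
  and each unaffected DMN/RMN region flagged in at most 10%.  (With a
  true AC effect inside the DMN family, BH being an FDR — not FWER —
  procedure makes the *aggregate* any-false-region rate per cohort
  structurally exceed 10%, so the per-region rate is the meaningful
  calibration quantity.)

Replicate counts (100 cohorts, 2000 calibration draws, $N=10^4$ limit
checks) were chosen so Monte-Carlo error is comfortably below each
acceptance margin while the whole suite stays desk-scale.

## Worked example

```{r example, eval = FALSE}
co  <- simulate_cohort(simulation_config(), seed = 1)
cfg <- analysis_config()
ent <- cohort_entropy(co$panels, cfg$entropy)
fcz <- cohort_fc(co$panels)

cx <- run_complexity_analysis(co, cfg, entropy = ent)
subset(cx, measure == "mse" & sig_fdr)[, c("label", "network", "F",
                                           "partial_eta_sq", "t_posthoc")]

fc <- run_fc_analysis(co, cfg, fcz = fcz)
subset(fc, sig_fdr)[, c("label_a", "label_b", "network", "F", "t_posthoc")]

lk <- run_linkage_analysis(co, cfg, entropy = ent, fcz = fcz)
head(lk[order(lk$p), ])
```
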