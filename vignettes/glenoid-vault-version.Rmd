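---
title: "Measuring glenoid vault version from 3D landmarks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring glenoid vault version from 3D landmarks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glenoidvault)
```

## The measurement model

Glenoid version is the orientation of the glenoid articular line in the
axial plane of the scapula, with posterior tilt (retroversion) positive.
`glenoidvault` computes it from seven named landmarks per shoulder, all in
world millimetres from any rigid scanner frame:

* `inferior_angle`, `glenoid_center`, `medial_point` — define the
  *scapular plane*;
* `anterior_rim`, `posterior_rim` — the *glenoid line* (optionally
  `anterior_rim_intermediate`/`posterior_rim_intermediate` for Walch B2
  biconcave glenoids, where the intermediate line between native and
  erosion surfaces is the accepted reference);
* `medial_border_tip` — origin of the conventional (Friedman) scapular
  axis;
* `vault_tip` — medial apex of the glenoid vault, origin of the vault
  axis.

The *three-dimensionally corrected slice* is the plane through
`glenoid_center` and `medial_point` perpendicular to the scapular plane.
Measuring in this slice removes two nuisance factors that plague raw axial
CT slices: scapular inclination (superior–inferior tilt of the scapula)
and gantry angle. Within the slice we use an anatomical 2D frame: the
u axis runs medial→lateral along `medial_point → glenoid_center`; the
v axis is the scapular-plane normal, oriented so the anterior rim has the
larger v coordinate. Because both axes are derived from landmark labels
rather than scanner axes, every angle the package reports is invariant
under rigid motions, uniform scaling, and reflections of the input — left
shoulders need no explicit mirroring step, and retroversion is positive
for both sides by construction.

Both methods share the identical glenoid line and its midpoint ("center of
the glenoid line"); they differ only in the axis:

* conventional: `medial_border_tip` → glenoid-line midpoint;
* vault: `vault_tip` → glenoid-line midpoint.

The signed angle between the glenoid line g (posterior→anterior) and the
perpendicular to the axis a is computed as
`sign(g·a) * atan2(|g × a⊥|, |g·a⊥|)`, in (−90°, 90°). The sign test
"posterior rim medial of the anterior rim ⇒ retroversion" is a pure dot
product in the 2D frame. The sign is carried by the anatomical labels:
swapping which rim is called anterior negates the angle, while a purely
geometric reflection of the rims across the axis (which leaves the
posterior rim the medial one) does not.

### Anatomical ambiguity of the medial reference

Published descriptions of this construction name the medial reference of
the scapular plane variously as the "medial pole of the scapula" and the
"root of the scapular spine", and the conventional axis origin as the "tip
of the medial border". The schema therefore keeps two separate landmarks:
`medial_point` (scapular plane and slice axis) and `medial_border_tip`
(conventional axis origin). Callers for whom the two coincide can simply
supply the same coordinates for both; nothing in the pipeline requires
them to differ.

## Statistical components

* **ICC(1,1)** (`icc(..., "oneway")`): one-way random-effects,
  single-measure — the right model for *intrarater* designs where the
  repeated sessions of one rater are exchangeable.
  `(BMS − WMS) / (BMS + (k−1) WMS)`.
* **ICC(2,1)** (`icc(..., "twoway")`): two-way random-effects, absolute
  agreement, single measure — for *interrater* designs where raters are a
  random sample and their systematic biases should count against
  agreement. `(BMS − EMS) / (BMS + (k−1) EMS + k(JMS − EMS)/n)`.
  Confidence intervals are F-based (Shrout–Fleiss), 95% by default.
  Negative estimates are reported as computed, with a warning, because
  truncation at zero biases reliability summaries upward.
* `reliability_report()` computes one ICC(1,1) per rater across sessions
  and a pooled ICC(2,1) across raters. The interrater table uses each
  rater's session mean by default (symmetric in the raters, uses all
  data); `interrater = "first_session"` restricts to session one for
  designs where later sessions are suspect.
* **Paired Wilcoxon** (`paired_wilcoxon()`): two-sided signed-rank on the
  paired differences. Zero differences are dropped before ranking —
  Wilcoxon's original treatment and the common default — rather than
  Pratt's method. The exact distribution is used for ≤ 25 untied non-zero
  differences, the tie-corrected normal approximation with continuity
  correction otherwise.
* **Variance-ratio F test** (`variance_f_test()`): larger sample variance
  over smaller, two-sided p from F(n₁−1, n₂−1); symmetric in its
  arguments. This is the classical two-sided fold of the variance-ratio
  test; it assumes approximate normality of the angle distributions.
* `compare_methods()` aggregates: per-method summaries, paired Wilcoxon
  vault vs conventional, F test of their spreads, mean signed difference.
  Repeated ratings should first be collapsed with `aggregate_ratings()`
  (mean over raters × sessions), the standard aggregation before
  cohort-level comparison. All tests use α = 0.05 and are reported to
  three decimals by the CLI.

## The synthetic scapula generator

`build_shoulder()` inverts the measurement: given a target vault version
and a body-shape offset it lays the landmark configuration out directly in
the corrected slice, tilts the medial landmarks by the requested scapular
inclination, optionally mirrors to a left shoulder, and applies an
arbitrary rigid placement. Measuring the result recovers the requested
angles to < 1e-6°, which is the generator's core guarantee (enforced by a
1,000-shoulder property test spanning vault version −20…60°, offset
−15…15°, inclination 0…30°).

The *body-shape offset* is the single angle between the vault axis and the
conventional scapular axis in the slice, so that
`conventional = vault − offset`. This is the minimal parametrisation of
the claim that scapular body shape biases the conventional method: a
flat-bodied scapula has a small offset, a round or waving body a large
one.

Cohort presets (`cohort_spec(preset = ...)`) are Gaussian, parametrised so
the marginal distributions of *both* measured methods match reported
reference cohorts simultaneously via the variance decomposition
`sd_conv² = sd_vault² + sd_offset²` (offset independent of vault version):

| preset | vault (°) | offset (°) | implied conventional (°) |
|---|---|---|---|
| `normal` | 8.9 ± 2.7 | 7.8 ± 1.72 | 1.1 ± 3.2 |
| `arthritic` | 18.2 ± 9.1 | 7.4 ± 1.92 | 10.8 ± 9.3 |
| `paired_dominance` | 8.2 ± 2.7 (nondominant), +1.4 shift | 7.8 ± 1.72 | — |

The paired preset splits the vault-version variance into a subject
baseline (SD 2.25°) and a within-subject component (SD 1.5°), preserving
the 2.7° marginal SD while giving bilateral shoulders a realistic
within-pair correlation (~0.7). The arthritic preset uses the standard
glenoid line for every synthetic shoulder; real arthritic cohorts mix
Walch types, with the intermediate line for B2 glenoids, and the preset
deliberately does not model that mixture.

Scapular dimensions default to a 28 mm glenoid width, 30 mm vault depth
and 100 mm medial-border distance — plausible adult values. Angles are
scale-invariant, so these matter only for how landmark noise propagates to
angle error.

### Observer noise

`simulate_raters()` perturbs every landmark with isotropic Gaussian noise
and re-runs the whole pipeline, so rater error propagates through the true
geometry rather than being added to angles. The default of 0.25 mm per
coordinate comes from first-order propagation: rim noise rotates the
glenoid line by ≈ σ√2/width and axis-endpoint noise rotates the axis by
≈ σ√1.5/depth, which at the default dimensions gives ≈ 0.9–1.0° of angle
SD — the level consistent with published intra-/interrater ICCs of ≈ 0.90
for this measurement. Against the normal preset's 2.7° between-shoulder
spread the variance-ratio closed form predicts ICC ≈ 2.7²/(2.7² + 1²) ≈
0.88 per single measurement, slightly higher for session means.

### What the simulation does and does not show

The generator emulates: controllable true version, scapular body-shape
variation, inclination, arbitrary patient pose, per-observer landmark
placement error, and paired dominance effects. It does not emulate:
segmentation or slice-reconstruction ambiguity (each synthetic measurement
starts from exact geometry, whereas real raters re-reconstruct the slice),
non-Gaussian or skewed version distributions, Walch-type-specific glenoid
morphology, or correlated (non-isotropic) landmark errors. Passing tests
therefore validate the computational pipeline and the statistical
machinery under the stated generative model — they do not certify
agreement with manual measurements on real CT data.

## Numerical choices

* Collinearity of the scapular-plane triangle is flagged below
  1e-6 mm² area; unit-vector and orthogonality tolerances are 1e-9 —
  comfortable margins for double precision at mm scale.
* Degenerate inputs (coincident axis endpoints, zero-length glenoid line,
  all-zero paired differences, zero-variance samples, constant rating
  tables) raise classed errors (`gv_degenerate_geometry`,
  `gv_degenerate_test`) rather than returning NaN.
* A glenoid line exactly perpendicular to the axis returns exactly 0°
  (the sign factor is zero); a line parallel to the axis would return
  ±90°, outside any anatomical range, and is left to the caller.
* Perfect-agreement rating tables collapse the ICC confidence interval to
  the point estimate rather than returning NaN from an ∞/∞ F bound.
* Validation problem sizes: the geometry round-trip property uses 1,000
  random shoulders; cohort-level checks use the presets' native 150
  shoulders; the F-test type-I simulation uses 10,000 replicates; these
  sizes keep every Monte-Carlo margin (3·SE) well clear of the effects
  being detected.

## Known limitations

* No imaging: landmarks are the contract. Landmark identification error
  in real data is likely structured (e.g. along bone surfaces), which the
  isotropic noise model understates or overstates depending on direction.
* The intermediate-line endpoints for B2 glenoids are caller-supplied;
  the package does not derive them from paleo-/neoglenoid geometry.
* ICC estimators assume complete, balanced designs; unbalanced or
  missing-data reliability studies are out of scope.
* The F test's normality assumption is inherited from standard practice
  for this comparison; heavy-tailed version distributions would call for
  a robust spread comparison instead.
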