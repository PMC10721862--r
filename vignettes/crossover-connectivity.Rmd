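---
title: "Crossover pharmaco-fMRI connectivity analysis with psiloconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crossover pharmaco-fMRI connectivity analysis with psiloconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The design and the scientific question

`psiloconn` analyses randomized, placebo-controlled crossover pharmaco-fMRI
experiments in rodents. Each subject is scanned twice — once under
psilocybin, once under saline, in randomized order — and each session is
split into a pre-injection baseline epoch (TP1, the first 340 frames at a
TR of 1.5 s) and a post-injection epoch (TP2, the last 340 frames). Every
outcome is a *delta response*, post minus pre, so that session-level
baseline differences cancel and the crossover contrast (psilocybin vs
saline) is a within-subject comparison.

The cohort mixes two groups: alcohol-experienced animals from a long-term
voluntary drinking model with repeated deprivation phases (the alcohol
deprivation effect, ADE — a relapse-like intake increase after renewed
access), and water-drinking controls. Besides the categorical
group-by-treatment question, the package supports a dimensional analysis:
does the intensity of the relapse phenotype (relapse intake as a percent
of baseline intake, `normalized_relapse()`) modulate the neural response
to the drug?

Because raw scans for such studies are generally not redistributable, the
package ships a seeded synthetic-cohort generator that emulates the design
end to end, providing ground truth for every stage.

## The synthetic generator

`simulate_session()` draws region time courses for the 44-region
bihemispheric parcellation (`region_labels()`) from a linear latent-factor
model with three band-limited (0.01–0.1 Hz) community factors:
cortical/DMN, sensory-motor, and subcortical. Each region loads 0.8 on its
community factor; the three DMN members of the sensory system (Aud1, Aud2,
V1) split their loading (0.55/0.55) between the sensory and cortical
factors so the 12-region DMN (`dmn_regions()`) is coherent. Idiosyncratic
white noise (SD 1) is added per region; the band-pass step of the
preprocessing chain later removes its out-of-band part, which sets the
realized connectivity scale.

Under psilocybin the generating model switches at the injection frame
(frame 400, minute 10 of a 1450-frame session):

* cortical/DMN factor loadings are multiplied by `1 - drop`, producing the
  post-injection hypoconnectivity of the cortical/DMN system;
* the dorsal raphe (DRN) and hypothalamus (HypR) gain a `hub_gain` = 0.4
  loading on the cortical factor, producing the focal hub-to-cortex
  hyperconnectivity.

The per-subject decrement is `drop = dmn_drop * max(0, 1 - beta *
(relapse_norm - 100)/100)` with `dmn_drop = 0.35`: controls (and ADE
animals with no relapse increase) get the full decrement, and the response
is attenuated linearly in the normalized relapse rate above 100%. The
slope `beta = 2` was calibrated once so that the generator reproduces the
magnitude of the reported relapse–response association (a Spearman rho
near -0.5 at n = 15 with fully independent session noise); with this
value a strong relapse phenotype (~150% of baseline) essentially abolishes
the drug response. ADE drinking values are drawn to match the reported
group statistics — baseline N(6.35, 1.75) g/kg and relapse = baseline plus
a truncated-normal increment (mean 1.75, SD 1.0, floor 0.1 g/kg), so
relapse always exceeds baseline and the group means land at 6.35 to
8.10 g/kg (128% mean normalized relapse). Because relapse is constructed
from baseline, the marginal relapse SD (about 2.0) slightly exceeds the
reported 1.74; the induced baseline–relapse correlation is the price of
guaranteeing relapse > baseline per animal.

Motion traces (`make_motion()`) superimpose rare step displacements
(default probability 0.02/frame, 0.1 mm) on low-amplitude drift, keeping
the flagged fraction well below the 10% exclusion rule. Voxel volumes
(`simulate_volume()`) assign contiguous blocks of a small grid (default
16 x 16 x 8 voxels at 0.3 mm) to the 44 regions; voxels inherit their
region's signal plus voxel noise. What the generator does *not* emulate:
hemodynamic convolution, scanner drift and physiological noise structure,
spatial autocorrelation within regions, anesthesia effects. Passing
recovery tests therefore demonstrates that the pipeline's inference is
correct under the assumed statistical structure, not that it is robust to
every artifact of real scans.

## Preprocessing

The desk-scale portion of the chain (upstream realignment, physiological
regression, slice timing and atlas registration are out of scope and
assumed done):

1. **Framewise displacement** — the sum of absolute frame-to-frame
   differentials of the three translations plus the three rotations
   converted to arc length at a 5 mm head radius (appropriate for the
   rat); FD of the first frame is 0.
2. **Scrubbing** (`scrub_interpolate()`) — frames with FD > 0.05 mm are
   replaced per region by a natural cubic spline through clean frames;
   boundary frames use nearest-neighbour extension because splines
   extrapolate poorly. More than 10% flagged frames raises a warning flag.
3. **Confound regression** (`regress_confounds()`) — least-squares
   projection on an intercept plus nuisance regressors (the six motion
   parameters; a CSF signal can be appended). Motion and CSF enter one
   joint design matrix.
4. **Band-pass** (`bandpass()`) — zero-phase forward–backward second-order
   Butterworth, 0.01–0.1 Hz at TR 1.5 s. The series is demeaned and
   padded by odd reflection before filtering; without padding,
   forward–backward filtering leaves visible transients at the series
   boundaries. Note that band-pass filtering is not strictly idempotent:
   content near the band edges is re-attenuated on a second pass (the
   squared magnitude response), so stability checks are phrased for
   band-center components.
5. **Epoch split** (`split_epochs()`) — positional: TP1 = first 340
   frames, TP2 = last 340 frames. The positional definition sidesteps the
   small inconsistency between the stated acquisition length (36 min 30 s)
   and 1450 x 1.5 s = 36.25 min.

## Connectivity

`fc_matrix()` computes Pearson correlations between region time courses
and Fisher-z transforms them, clipping |r| at 1 - 1e-7 so duplicated
signals stay finite; the diagonal is excluded (`NA`) everywhere
downstream. `diff_matrix()` forms the post-minus-pre difference per
session. `gbc_map()` is the voxel-wise analogue: for every voxel in the
gray-matter mask, the mean Fisher-z correlation to all other in-mask
voxels — signed, not absolute, and without global signal regression
(which manufactures negative correlations). Volumes are smoothed
beforehand with a 0.6 mm Gaussian kernel (`smooth_volume()`, separable
normalized convolution; at 0.3 mm voxels the kernel sigma is 0.85
voxels).

## Network-based statistic

`nbs_permutation_test()` performs family-wise-error-controlling inference
on connected components of suprathreshold edges. The GLM observations are
the 2n difference matrices (both sessions of every subject); the
treatment contrast is an edge-wise F test between conditions with df
(1, 2n - 2) — for 21 subjects, df (1, 40), whose upper-1% point is the
default primary threshold F_pt = 7.31. (Published threshold statements
sometimes attach this value to the ANOVA df (1, 19), but 7.31 is the
alpha = .01 critical value of F(1, 40); the df are therefore exposed
explicitly rather than matched silently.) Suprathreshold edges form a
graph; each connected component's extent (edge count) is compared with
the permutation null of the *maximum* component extent. Permutations
respect exchange blocks: condition labels are swapped only within a
subject's pair, honouring the paired crossover design (the group of
2^n swaps is sampled, not enumerated). The subgroup-by-treatment
interaction permutes group labels between subjects while keeping pairs
intact, with the F test applied to per-subject (psilocybin minus saline)
contrasts, df (1, n - 2). P-values use the add-one correction, so the
smallest attainable value is 1/(K + 1).

## Graph metrics

Weighted whole-brain graphs are built from correlation matrices with
negative weights zeroed (nonnegativity is required by the weighted
clustering and small-world definitions) and weights normalized by the
maximum. Proportional thresholds retain the 10–50% strongest edges in 1%
steps (41 graphs, deterministic tie-break, nested edge sets); metrics are
averaged across thresholds so conclusions do not hinge on one density.
Disconnected thresholded graphs are flagged and excluded from the
average, with the count reported.

Small-world propensity compares the observed mean Onnela weighted
clustering coefficient C and characteristic path length L (distance =
1/weight, Dijkstra) with two references sharing the node count, degree
sequence and density: degree-preserving connected rewired graphs with
reshuffled weights (default 20 per threshold, an accuracy/runtime
compromise), and a ring lattice carrying the sorted weights at the
shortest ranges. `dC = (C_latt - C)/(C_latt - C_rand)` and
`dL = (L - L_rand)/(L_latt - L_rand)` are clipped to [0, 1] and combined
as `SWP = 1 - sqrt((dC^2 + dL^2)/2)`; both pure lattices and pure random
graphs score 1 - sqrt(1/2) = 0.293, and genuinely small-world topologies
(e.g. Watts–Strogatz at 10% rewiring) score above 0.6.

Local metrics are nodal strength, Onnela clustering, and participation.
The module partition is obtained by Louvain modularity maximization (best
of 50 seeded restarts) — typically on a group-mean baseline graph and
then held fixed across conditions, so participation changes reflect
connectivity changes rather than partition changes. Because the phrase
"ratio of intermodule strength to total nodal strength" differs from the
standard participation coefficient `P_i = 1 - sum_s (kappa_is/k_i)^2`,
both are implemented behind the `participation` switch; the coefficient
is the default.

## DMN connectivity and sample entropy

`dmn_connectivity()` restricts a matrix to the 12 DMN regions and returns
the mean over the 66 unordered pairs plus each region's mean connectivity
to the other 11 (within-DMN strength); by the double-counting identity
the former is the mean of the latter.

`sample_entropy()` quantifies signal regularity: the negative log
conditional probability that templates matching for m = 3 points also
match for m + 1, self-matches excluded, tolerance r = 0.2. The series is
mean-subtracted and variance-standardized, and template distances are
standardized Euclidean (each embedding coordinate divided by its
across-template SD) with match criterion `distance <= r * sqrt(m)`, which
keeps r = 0.2 commensurate with the conventional per-coordinate rule.
Degenerate inputs (constant series, or no matching templates — which
genuinely happens for short white-noise series at these parameters) are
flagged `NA` rather than guessed. `regional_entropy()` averages
voxel-wise (or region-wise) entropy within labels and over the 12 DMN
regions; region means are averaged, not voxel-pooled.

## Inference layer

* **Mixed ANOVA** (`rm_anova()`): with two within-subject levels the
  between(group) x within(treatment) model collapses exactly onto the
  per-subject psilocybin-minus-saline contrast — the interaction is the
  one-way F between groups and the treatment effect tests the unweighted
  mean of the group means (Type III, appropriate for the unbalanced 15:6
  allocation), both with df (1, n - 2): df (1, 19) at n = 21.
* **Permutation ANOVA** (`permutation_anova()`, default 10000
  permutations): treatment by within-subject session swaps (sign flips of
  the contrast), interaction by group-label permutation — the concrete
  realization of permutation schemes for unbalanced between-within
  designs. Add-one p-values.
* **Assumption screens** (`assumption_checks()`): Shapiro–Wilk per cell,
  Bartlett across cells, via the standard `stats` routines.
* **FDR** (`fdr_adjust()`): Benjamini–Hochberg step-up, with `m`
  overridable (e.g. 44 regional tests, 12 within-DMN tests).
* **Correlation analysis** (`spearman_rho()`, `rho_to_t()`): Spearman
  with average ranks; p exact for small tie-free samples (via
  `cor.test`), t approximation otherwise; the absolute-value t-transform
  `t = |rho|/sqrt((1 - rho^2)/(N - 2))` feeds cluster-defining
  thresholds.
* **Cluster-extent correction** (`cluster_correct()`): suprathreshold
  voxels at a cluster-defining threshold form 6-connected components
  (configurable 18/26); FWE p-values come from the permutation null of
  the maximum extent — sign flips of subject maps for paired contrasts,
  covariate shuffles for correlation maps. Permutation was chosen over
  random-field theory as the reproducible desk-scale equivalent; the
  thresholds (t > 2.53 / 3.55 for df 20, t > 2.65 / 3.85 for df 13) are
  shared. On very small unsmoothed grids the integer-valued max-extent
  null is coarse and the test conservative; with the pipeline's 0.6 mm
  smoothing the null is rich enough to attain the nominal rate.
* **Sequence effects**: session order is carried in the cohort table and
  can be screened as an additional between factor; the baseline-drinking
  screen is implemented as a Spearman correlation check.

## Problem sizes and numerical choices

The test-suite and acceptance-script simulations run at desk scale,
chosen as the smallest sizes at which the statistical properties are
cleanly visible: null-calibration checks use 200–1000 replicates with
500–1000 permutations (10 subjects / 10 nodes for the NBS, 10 x 10 x 6
smoothed grids for cluster correction, the 15:6 allocation for the
ANOVA); effect-recovery runs use the full default cohort (21 subjects,
1450-frame sessions) and 100 cohort replicates for the correlation-sign
rate. Fisher z is clipped at |r| = 1 - 1e-7; proportional-threshold ties
break deterministically by weight then node pair; permutation p-values
are never zero by construction. All randomness flows through explicit
seeds; identical inputs and seeds reproduce results bit for bit.

## Known limitations

The generator's three-factor structure is the simplest model whose
correlation pattern matches the modular organization the analysis
assumes; it does not produce realistic spatial maps, hemodynamics, or
physiological confounds, and the voxel grids are far smaller than real
acquisitions. Full-resolution GBC group analysis is supported by the
same primitives (smoothing, GBC, cluster correction) but is exercised
here at desk-scale grid sizes. Real-data statistics from any particular
study are not
reproducible without the raw scans; the package's claim is that every
algorithmic component is verifiably correct and the full pipeline
recovers injected effects of the reported kind and size.
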