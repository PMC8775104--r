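---
title: "Regional tonic neuroelectric activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional tonic neuroelectric activity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

A referee-consensus source solver applied to MEG recordings emits a large
collection of probabilistically validated dipole current events, each with a
millimetre-scale location, a direction vector in the plane tangent to the
head-approximating sphere, and a parcellation region label. Two facts make
the raw per-region event counts unusable as a biomarker. First, the solver's
yield fluctuates with data quality and record length, so absolute counts are
not comparable between recordings. Second, the solver produces "dark counts":
falsely validated currents that appear even in empty-room recordings (no
subject in the scanner), whose regional profile correlates with that of
same-day human recordings and therefore contaminates any regional measure.

`megtonus` implements the analysis chain that turns these event collections
into reliable regional measures: geometric screening of individual currents
against the empty-room population, volume normalization to regional current
densities, a normative z-score atlas, test-retest reliability with a Welch
comparison between correction methods, jackknifed stepwise linear
discriminant classification of symptom presence/absence, and a
cortex-versus-adjacent-white-matter differential test.

## Regional current density

For each recording the count in region $r$ is normalized as

$$\rho_r = \frac{\mathrm{count}_r / \mathrm{count}_{\mathrm{total}}}
                {\mathrm{vol}_r / \mathrm{vol}_{\mathrm{total}}},$$

the region's share of validated currents divided by its share of brain
volume. Under spatially uniform currents $\rho_r = 1$ everywhere; dividing
by the total count removes global yield variation (any rescaling of all
counts leaves $\rho$ unchanged), and the volume ratio is unit-invariant.
`vol_total` defaults to the summed parcellation volume — the alternative
(whole-brain volume including unparcellated tissue) only rescales every
$\rho$ by a common factor and washes out of all downstream z-scores; it is
configurable in `count_events()`.

A normative atlas stores, per region, the sample mean and standard deviation
(denominator $n-1$) of $\rho$ across the normative cohort's baseline resting
recordings, and individuals are standardized as
$z = (\rho - \bar\rho)/s_\rho$. Scoring a cohort against its own atlas makes
each region's sample variance exactly 1, so composite measures built from
many regional z-scores weight regions approximately equally.

## The four geometric features and the dark-count screen

Each current is reduced to four local features: (1) the cosine between its
direction and the gray/white-interface normal at the nearest interface
point, (2) the cosine between the radial vector through its location and
that normal, (3) its distance to the nearest interface point, and (4) the
cortical thickness there (distance from that interface point to the nearest
pial point). Only feature 1 depends on the direction of current flow, so it
carries the brain-state signal (rest versus task), while all four separate
genuine brain currents from dark counts — a geometric asymmetry the screen
exploits and the feature-contribution comparison in the test suite checks.

Nearest-point queries operate on mesh vertices rather than interpolated
surface points: the features tolerate mesh-resolution error, and vertex
queries are exactly checkable against a brute-force scan (which the tests
do). Vertex normals are area-weighted averages of incident face normals;
distance ties break to the lowest vertex index, making every query
deterministic.

For every subject and each cortical / adjacent-white-matter region a random
forest (100 trees, majority vote, default `mtry` of 2 on 4 features) is
trained to distinguish the subject's resting currents from the same-day
empty-room currents in that region. Training subsets are capped at 5000
currents per class; when the smaller class is below the cap the larger is
further limited to 110% of the smaller — approximately balanced classes
remove a known failure mode of random-forest classification. Per-class
percentage accuracies are evaluated on the full populations (training plus
test, the optimistic convention) and also out-of-bag; the report carries
both. A screen is "successful" when both classes have at least
`min_class_size` (default 200) currents and both full-population accuracies
reach 55% — the success criterion is a package convention (the source
analyses report a 70% success rate without stating a criterion) and both
knobs are configurable in `training_spec()`.

Filtering drops a current when the forest's empty-class vote share exceeds
0.5 (ties retain). One numerical subtlety matters here: a current that was
itself in the training subset would be judged by trees that memorized it and
would essentially never be dropped, so training-set currents are judged by
their out-of-bag votes instead. Regions whose screen fails pass events
through unfiltered and are flagged, so downstream stages can restrict to
screen-successful subject/region pairs.

The legacy correction is also provided:
$\rho^{\mathrm{corr}}_r = \rho_r - \mathrm{corr}_r\,\rho^{\mathrm{empty}}_r$,
where $\mathrm{corr}_r$ is the across-subject correlation between densities
measured with the subject present and absent. It operates on densities, not
individual currents, and serves as the comparison baseline for the
reliability improvement.

## Test-retest reliability

Reliability is quantified per region as the Pearson correlation across
subjects between two measurement occasions (same-sitting rest versus task
for short-term; baseline versus follow-up rest for long-term), plus the
mean signed difference (occasion 2 minus occasion 1 — subtracting it
corrects a follow-up measure for comparison with baseline). Correlations
are computed on z-scores, both occasions scored against the baseline atlas;
a raw-density mode is available via the `value` argument. Regions with
fewer than 3 paired subjects are omitted. Correction methods are compared
by a Welch two-sample t-test (unequal variances, Welch–Satterthwaite df) on
the two vectors of per-region correlations.

## Stepwise linear discriminant classification

Symptom presence/absence is classified from the cortical and
adjacent-white-matter regional z-scores by textbook stepwise discriminant
analysis, implemented directly: at each step the candidate region with the
largest Wilks'-lambda partial $F$ enters if $p < p_{\mathrm{enter}}$
(default 0.05), any included region whose partial $p$ exceeds
$p_{\mathrm{remove}}$ (default 0.10) is removed, and ties break to the
lowest region id. The thresholds are package defaults — the textbook method
is cited without thresholds in the source analyses. The final model is a
two-class linear discriminant with equal priors (`MASS::lda`) over the
selected regions; the ↑/↓ sign table reports, for each selected region,
the sign of the group-mean difference on training data (with correlated
selected regions a discriminant weight can legitimately oppose the marginal
mean difference, so signs are defined from the means, which is what the
sign tables describe).

Accuracy is jackknifed (leave-one-out). The default protocol, `refit`,
re-runs the entire stepwise selection inside every fold, which is the
honest protocol; a `fixed` protocol (selection once on all data, weights
refit per fold) is provided because the original protocol is unstated.
Baseline and follow-up recordings are pooled as independent rows by
default; a subject-grouped jackknife (`groups =`) leaves whole subjects
out instead. One degenerate case needs care: when a fold's selection is
empty the model is constant, and predicting the *fold's* majority class
would anti-learn under a balanced null (leaving out a positive makes
negatives the fold majority), driving null accuracies far below chance.
Empty fold-models therefore fall back to the overall base rate, which
restores chance-level null behaviour; a standalone empty model from
`stepwise_train()` still predicts its own training majority.

Two p-values accompany each accuracy: the exact binomial tail
$\sum_{i\ge k} \binom{n}{i} 2^{-n}$ (the "at least $k$ heads in $n$ fair
flips" computation) and the goodness-of-fit chi-square against the
fair-classification null (half right per class; df 1 per class, df 2 for
the pooled confusion table). Both are reported because the source analyses
describe the coin-flip computation while stating chi-square was used; on
the published worked rows both satisfy the same printed bounds.

Cohort-level classification supports iterative region exclusion: each round
removes every region selected in prior rounds and re-runs selection and
jackknife on the remainder, mirroring the observation that accuracy decays
only gradually as informative regions are excluded (distributed signal).

## Cortex versus adjacent white matter

For each cortical region and its paired white-matter rim (thickness
≤ 5 mm), the observed counts are tested against expectations proportional
to the two volumes with a 1-df goodness-of-fit chi-square, no continuity
correction (counts are in the thousands). Significance uses $p < 10^{-8}$
to guard the large number of subject × pair comparisons, and summary
percentages are reported over evaluated pairs only (those whose screen
succeeded for both members). With two cells and 1 df this statistic
coincides with the one-cell binomial $z^2$, so the ambiguity between the
two formulations is immaterial.

## The synthetic cohort generator

Real inputs for this analysis are access-restricted, so the package carries
a first-class generator that emulates the solver's output at the level the
analysis consumes. Per recording, region counts are multinomial with
probabilities proportional to
$\mathrm{vol}_r \exp(s_r + y\,\delta_r + e_r)$: a subject-stable activation
field $s_r \sim N(0, \sigma_s^2)$, symptom shifts $\delta_r$ applied to
affected regions of labelled subjects, and per-recording session noise
$e_r \sim N(0, \sigma_e^2)$. Brain events are placed inside their region's
sector outside the 30 mm central exclusion sphere with tangent-plane
directions concentrated near the local interface normal's tangential
projection; task recordings rotate the preferred direction (default 60°),
so rest and task differ only through feature 1. Contaminant events follow a
separate dark log-rate profile (cohort-level SD 0.5) plus a per-subject,
per-day wobble (SD 0.3) shared between same-day recordings — which is
exactly what makes empty-room densities correlate with resting densities
across subjects — and carry broad radial spread and isotropic tangent
directions. The ground-truth `is_dark` column is emitted for oracle
evaluation of the screen and excluded from analysis inputs.

Default parameters are fixed once as study conditions: symptom cut-offs 15
(ISI) and 63 (BSI) with an inclusive boundary (score at the cut-off is
positive; the convention is configurable); `events_per_recording = 20000`
(a desk-scale stand-in — the solver's >600,000/min is a solver property,
not needed for the statistical structure); $\sigma_s = 0.30$ and
$\sigma_e = 0.15$, giving a latent reliability
$\sigma_s^2/(\sigma_s^2+\sigma_e^2) = 0.8$, between the short-term (~0.85)
and long-term (~0.67) correlation centers reported for the normative
cohort; `dark_fraction = 0.20` of brain-recording events; and an empty-room
yield equal to the brain-recording yield (with no true currents to
outcompete them, dark counts fill the empty-room yield). Seeding is
hierarchical: one master seed, with per-subject and per-recording streams
derived by a string-keyed hash (`derive_seed()`), so any subset of a cohort
regenerates identically without simulating the rest.

The toy geometry is a pair of concentric perturbed ellipsoids (gray/white
interface and pial, the pial strictly outside) with an azimuthal-sector
parcellation, cortical sectors paired with 5 mm white rims beneath them and
a deep subcortical band outside the exclusion sphere. The ellipsoid is
deliberately non-spherical: on a sphere the interface normal is everywhere
radial and feature 2 degenerates to 1. Sector volumes are computed by
deterministic solid-angle quadrature of the bounding radii, so stated
volumes and sampling geometry agree.

What the generator does *not* emulate: sensor-level time series, head
movement, the solver's validation statistics, spatially correlated
activation fields, non-Gaussian subject effects, or realistic
Desikan-Killiany region shapes. Passing tests therefore demonstrate that
the analysis chain is correct and well calibrated under its assumed
generative structure — not that real recordings satisfy those assumptions.

## Problem sizes and numerical choices

The test and acceptance workloads use desk-scale cohorts chosen to keep the
full suite fast while leaving Monte-Carlo margins comfortable: 8–24
subjects with 8 cortex/white-rim sector pairs and 3 subcortical regions for
screening and reliability (1,500–8,000 events per recording), and 120
subjects × 5,000 events with a 10-region planted effect of 1.5× the
between-subject SD for classifier parameter recovery. Meshes use a
subdivided icosahedron (642 vertices per surface; 162 in the smallest test
fixtures). Degenerate inputs are handled explicitly: zero-count recordings
are flagged invalid, zero-spread atlas regions z-score to missing with a
warning, screens with undersized or zero-variance classes report failure
rather than raising, and an event at the exact sphere center (undefined
radial vector) is an error.

## Known limitations

Densities are compositional (volume-weighted $\rho$ averages to 1), so
regional measures are not independent; the classifier does not model this.
The full-population screen accuracies are optimistic by construction (the
out-of-bag figures are the honest ones). The stepwise entry/removal
thresholds control greediness, not a family-wise error rate; selection
p-values should not be read as inferential. And the Welch comparison of
reliability between correction methods treats per-region correlations as
independent observations, which understates their coupling through the
shared cohort.
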