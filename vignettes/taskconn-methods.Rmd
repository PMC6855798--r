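---
title: "Task-dependent connectivity analysis: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-dependent connectivity analysis: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taskconn)
library(dplyr)
```

## The design and the question

taskconn analyses a two-group crossover neurostimulation experiment.
Each subject belongs to one stimulation-target group — parietal
stimulation of the posterior-medial network (PMN) or a prefrontal (PFC)
control site — and is scanned four times: after a week of real
stimulation and after a week of sham, each time both during an
autobiographical memory retrieval task and during rest.  The scientific
question is whether stimulation changes functional connectivity in a
*task-dependent* and *network-specific* way: the quantity of interest is
the three-way interaction

> (stim − sham during retrieval) − (stim − sham during rest),
> compared between the PMN-targeted and PFC-targeted groups,

measured on Fisher-z transformed correlations.  Everything in the
package exists to estimate, test, localise or exploit that contrast.

## Connectivity measures

**ROI networks.**  Regions are spheres (6 mm radius by default) around
a-priori coordinates; sphere membership is decided by voxel-centre
distance with an inclusive boundary — the simplest reproducible rule,
since sub-voxel partial membership conventions differ between tools.
A scan's `connectivity_matrix()` holds the pairwise Pearson correlations
of the spatially averaged region series, clamped to `|r| <= 1 - 1e-7`
(identical series would otherwise give an infinite z) and arctanh
transformed.  Network interconnectivity is the mean Fisher-z over all
distinct within-network pairs: each edge is transformed first and then
averaged, which keeps the network summary an unbiased average of the
variance-stabilised edges (averaging r first and transforming once is
the other defensible reading; the transform-then-average convention is
declared here once and used everywhere).

**Global connectedness.**  For each in-mask voxel the mean correlation
with every other in-mask voxel is stored back into the voxel and Fisher-z
transformed.  Two computation paths exist: an explicit correlation-matrix
path (each pairwise r clamped before averaging, identical to the
brute-force double loop, used up to 1024 voxels) and a row-sum path using
`sum_j r(i, j) = z_i . sum_j z_j` on unit-normalised series, which is
O(time x voxels) and clamps only the mean.  The two differ only when some
pairwise |r| exceeds the clamp, i.e. when series are numerically
identical; the test suite pins their equivalence at 1e-8 on instances up
to 200 voxels.

## The mixed-effects model

Network values (or per-voxel map values) are modelled with a linear mixed
model with a per-subject random intercept, REML estimation, and
Satterthwaite denominator degrees of freedom (`lmerTest`).  Factors are
coded as sum-to-zero ±1/2 contrasts (stim, retrieval, PMN-targeted at
+1/2), so the three-way beta *is* the difference-of-differences-of-
differences above, directly comparable to the generator's planted
increment.  The fixed-effect structure includes all main effects and all
two-way interactions alongside the three-way term: testing an
interaction without its lower-order terms confounds it with them, so the
hierarchy principle is followed even though a flat "mains + three-way"
reading of the analysis description is possible.  Mean whole-brain tSNR
enters as a mean-centred covariate of no interest (it differed
marginally between sessions in the motivating study); a constant
covariate is dropped with a message, which reproduces the no-covariate
fit exactly.  Condition-order terms (`include_order = TRUE`) are
available as a control analysis.

Edge-level tests apply the same model per region pair and control the
false-discovery rate with Benjamini–Hochberg separately within each
network's family of pairs, matching how per-network results are
reported.  Non-convergent edges are flagged and excluded from the FDR
family rather than silently contributing.

## Cluster-extent inference by label flipping

Voxelwise p-maps are thresholded two-tailed at p < 0.05 — a deliberately
lenient voxel threshold that is conventional for connectedness maps —
and false positives are controlled at the cluster level: only clusters
at least as large as a permutation-calibrated cutoff survive.

The null distribution of the maximum cluster size is built by refitting
the model under random flips of the factor labels.  Which labels the
original AFNI-era procedure permuted is not recoverable in detail, so
the scheme is explicit and configurable: per permutation, stim/sham are
swapped within each subject with probability 1/2, retrieval/rest are
swapped within each subject-condition with probability 1/2, and group
labels are permuted across subjects preserving group sizes.  This
respects the exchangeability structure of the design under the null:
within-subject factors are exchangeable within subject, group is
exchangeable across subjects.  The cutoff is the smallest size whose
exceedance probability across permutations is at most alpha ("the size
with only a 5% probability of finding any cluster that size or
larger"); with several effects tested, the most stringent per-term
cutoff is applied to all.  Cluster adjacency defaults to face
connectivity (6), the most conservative standard choice; 18 and 26 are
available.  Two-tailed clusters pool signs by default (`sign_split`
separates them).

**Fast refits.**  Refitting a REML mixed model at every voxel for every
permutation is needlessly slow in a balanced design: subtracting each
subject's mean from both sides removes the random intercept exactly,
after which ordinary least squares on the within-subject design columns
gives the interaction t-statistic in a handful of matrix products for
all voxels at once.  The same statistic is used for the observed map
and for every permuted map, so the cluster-level comparison is
like-with-like; the test suite checks that cutoffs from the fast path
and from full per-voxel REML refits agree within one voxel on a test
bed, and `voxelwise_lme(method = "lme")` remains available.  Residual
degrees of freedom for the centred OLS are `n - n_subjects - rank(X)`.

## Drivers and allegiance

Clusters surviving the whole-brain stage are used as seeds: each
cluster's mean series is correlated with every in-mask voxel
(`seed_driver_map()`), the per-group two-factor model is fit to the seed
maps, and driver regions are declared at the stricter fixed threshold of
voxelwise p < 0.001 two-tailed with >= 20 contiguous voxels (no
permutation at this stage).  Driver clusters are then classified:
overlap with any a-priori PMN/ATN sphere (one shared voxel suffices by
default; the minimum is configurable) assigns that network, with ties
going to the larger overlap and then to PMN, and both the tie and the
counts recorded; otherwise the cluster takes the reference-network label
with maximal overlap, or `unassigned`.  The resulting 2x2 counts
(stimulation target x network) are compared with a Yates
continuity-corrected chi-square, with the correction floored at zero so
cells with |O − E| < 0.5 contribute nothing.  Whether "overlap"
fractions count clusters or voxels is ambiguous in prose descriptions of
such analyses, so `overlap_fraction()` reports either; cluster counting
is the default.

## Behaviour and the brain–behaviour link

Memory assessments are 84-trial recognition tests (42 studied objects,
42 new).  Item recognition is the proportion of correct old/new
decisions; context recollection is the proportion of correct context
choices (one of six) among high-confidence hits — undefined when a
subject has none, in which case the subject is dropped pairwise from
contrasts with a message.  The post-stimulation vs post-sham contrast is
a directional paired t-test (the a-priori hypothesis is improvement);
baseline checks are two-tailed.

The per-subject connectivity interaction effect of a cluster —
(stim − sham, retrieval) − (stim − sham, rest) of its mean
connectedness — is regressed onto the memory change (post-stim minus
post-sham context recollection) by Huber M-estimation (tuning constant
1.345, IRLS to 1e-8; bisquare selectable).  Inference on the
connectivity coefficient is a Wald-type robust F: the squared robust t
referred to F(1, n − k).  No exact equivalence with any particular
published robust-F variant is claimed, and r² is reported as the squared
correlation between fitted and observed values (its definition under
M-estimation is not standardised, so the choice is stated).  Pooling
across the two groups' medial-temporal clusters concatenates subjects,
each with their own group's cluster effect.

## The synthetic-data generator

The generator is first-class, tested code; it defines the conditions
under which every statistical guarantee below is measured.

* **ROI level** (`simulate_roi_timeseries()`): per scan, a multivariate
  Gaussian whose population correlation is block structured — within a
  network, `tanh(baseline_z + subject intercept + planted increments)`,
  zero across networks.  This is exactly the data-generating process the
  Pearson + Fisher-z + mixed-model pipeline assumes, which is the point:
  parameter recovery is then a sharp test of the estimation chain.
* **Voxel level** (`simulate_voxel_dataset()`): voxels sharing a
  community label mix a latent signal with weight `w`
  (within-community correlation `w²`); planted cells raise coupling on
  the Fisher-z scale exactly as at ROI level.  Background voxels are
  independent noise.
* **Subject effects** enter as additive Fisher-z intercepts shared
  across a subject's four scans, mirroring the random-intercept model.
* **tSNR heterogeneity**: a per-scan log-normal noise-scale multiplier
  changes the marginal SD (not the correlations) and is recorded as the
  tSNR covariate, so the covariate behaves as a genuine
  nuisance variable.
* **Motion** (`simulate_motion()`): random-walk translations/rotations
  with occasional spikes, feeding the FD/censoring QC rules.
* **Behaviour** (`simulate_behavior()`): trial-level recognition tests
  whose generating context-recollection change is
  `behavior_slope x interaction_effect + N(0, behavior_sd)`, truncated
  to keep probabilities in [0, 1] (truncation is documented behaviour:
  recovered slopes attenuate if the line leaves the unit interval).

Defaults: `baseline_z = 0.2` and `subject_sd = 0.1` are typical
magnitudes for within-network Fisher-z connectivity and between-subject
spread; `delta_3way = 0.25` is the planted-effect magnitude used in the
recovery studies; behavioural parameters (`p_item = 0.85`,
`p_highconf = 0.7`, `p_context_base = 0.35`) are plausible levels for
this kind of 6-alternative source-memory task.  No effect size in
Fisher-z units is reported by the motivating study, so these are package
choices, stated once and not tuned.

What the generator does **not** emulate: hemodynamics, autocorrelated
noise, physiological confounds, anatomy, or spatial noise correlation
beyond the community structure.  Passing tests therefore demonstrate
the correctness and calibration of the *procedures* under their own
assumptions, not robustness to real fMRI noise.

## Numerical choices and degenerate inputs

* Correlations clamped at `1 - 1e-7` before arctanh; clamping only
  affects numerically identical series.
* FD is the Power convention: sum of absolute backward differences with
  rotations converted on a 50 mm sphere; first frame 0.  The exclusion
  boundary is strict (excluded iff censored fraction > 5%), because
  retained subjects are described as having under 5% censored.  Censored
  frames are flagged, not scrubbed, since scrubbing of retained scans is
  not part of the described pipeline.  Rotation units are configurable
  (radians default) because motion-file dialects differ.
* Bandpass is a hard DFT projection (bins with |f| in [0.01, 0.1] Hz
  kept), hence idempotent and mean-removing; tSNR is computed after
  motion regression but before the bandpass, which would null the mean
  and leave the ratio undefined.
* Smoothing uses a separable Gaussian truncated at 4 sigma,
  `sigma = FWHM / (2 sqrt(2 ln 2))` per axis.
* Ties in stimulation-target selection break by distance to the
  anatomical anchor, then lexicographic voxel index; the hippocampal
  seed search is a configurable radius (8 mm default) around the
  anatomical coordinate, since only the outcome distances, not the
  search rule, are reported.
* Zero-variance voxels are dropped from connectedness masks with a
  warning; zero-variance regions and seeds are errors naming the region.
* The permutation cutoff is well defined even when no permutation shows
  a cluster (`cutoff = max + 1` exceeds everything observed).

## Problem sizes used in validation

The statistical guarantees are measured at reduced scale chosen so the
full suite runs comfortably on a single CPU: familywise error on 100
null studies (16³ grid, 8 subjects per group, 60 frames, 200
permutations each); parameter recovery and type-I calibration on 200
replicate ROI-level studies (16 subjects per group, 300 frames); the
OLS-vs-REML permutation cross-check on a 27-voxel grid with 100
permutations.  These sizes give binomial Monte-Carlo error around ±4
percentage points on a 5% rate, matching the tolerances asserted.

## Known limitations

* Satterthwaite df from `lmerTest` need not reproduce the exact df
  conventions of other mixed-model front ends; df are reported, never
  forced.
* The robust F is a Wald-type analogue, not a finite-sample-exact test;
  its null calibration is verified by simulation at the study's n.
* The permutation scheme is one principled reading of "random flipping
  of factor labels"; alternatives are expressible through the
  `permute_scan_labels()` switches.
* Real-data ingestion assumes volumes already live in one common space;
  registration, despiking and slice-timing are out of scope.

## Reproducing the headline validation

```{r, eval = FALSE}
res <- cluster_fwe_simulation(n_studies = 100, n_per_group = 8,
                              grid_shape = c(16, 16, 16),
                              n_timepoints = 60, n_permutations = 200,
                              seed = 1)
mean(res$survived)  # empirical familywise error at nominal 0.05
```

The same computation, wrapped with JSON output, is
`scripts/acceptance.R`.
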