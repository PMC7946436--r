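---
title: "Methods: consensus parcellation, task decoding and connectivity testing of IPL subregions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus parcellation, task decoding and connectivity testing of IPL subregions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`iplparc` implements a multi-method analysis of functional specialization in
the inferior parietal lobe (IPL): a data-driven split of each hemisphere's
region of interest into subregions, decoding of task identity from
subregion-level activity, detection of task-specific functional-connectivity
shifts against a permutation baseline, and a second-level permutation test on
directed effective-connectivity modulations. Every stage consumes trial-wise
activity estimates ("betas"); nothing in the package fits hemodynamic models.
A synthetic-data module generates all inputs with planted ground truth so the
whole pipeline is testable without imaging data.

## The synthetic study conditions

The generator emulates a three-task, within-subject design. Each run contains
40 attentional-reorienting trials (8 *invalid*, 30 *valid*, 2 *catch*), 40
lexical-decision trials (20 *word*, 20 *pseudoword*) and 6 perspective-taking
trials (3 *false belief*, 3 *true belief*); sessions hold four runs. Task
blocks are administered consecutively within a run in pseudo-randomized order
with a 16 s rest between blocks, and onsets are jittered with task-specific
mean inter-trial intervals (3.2 s attention, 3.8 s otherwise; minimum 2 s).
Onsets are carried for completeness but no downstream stage consumes timing.

The randomized block order is not cosmetic. The decoding stage removes
variation explained by *run time* (the trial's position within its run). With
a fixed block order that regressor is collinear with task, and deconfounding
absorbs genuine task signal — in our simulations a fixed order capped
noiseless decoding accuracy near 80%, while randomized order restores perfect
separation. Blocked designs are intrinsically time-confounded within a run;
randomizing the block order across runs is what makes the confound removable.

Response correctness is Bernoulli with per-condition accuracy 0.95 (catch
trials carry no response), so downstream "correct-only" filters are always
exercised. Voxel activity is `baseline + subject offset + planted effect +
i.i.d. Gaussian noise`. The planted specialization pattern is qualitative:
the attention target condition raises activity in the right anterior
subregion, the semantics target in the left anterior subregion, and the
social target in both posterior subregions, by `effect_size` (default 1) beta
units against noise sd 1 and between-subject sd 0.5. The magnitudes are ours:
the source literature reports no effect sizes for these conditions, and the
defaults must not be read as estimates of real data. Noise is i.i.d. across
voxels and trials — no spatial autocorrelation, no temporal drift, no
hemodynamics — which keeps every oracle analytic but also means passing tests
certify the *statistics*, not realism of fMRI noise.

ROI masks are box grids per hemisphere (demo default 10 × 5 × 4 = 200 voxels)
with a planted anterior/posterior split perpendicular to the second
(anterior–posterior) axis; `drop_fraction` can carve irregular masks, and
mirrored generation makes the right hemisphere an exact left-right flip for
congruency identities. Parcel series (default 100 parcels in the demo
configuration, 400 in the full atlas convention) are unit Gaussian noise
except where a coupling entry plants `parcel = rho * standardized subregion
series + sqrt(1 - rho^2) * noise` on one task's trials (default rho 0.5).
Modulation matrices are subject-level draws around per-task 4 × 4 group
matrices with Gaussian between-subject sd 0.5; the default truth uses the
published table of significant task-specific modulations as its group-level
pattern.

## Parcellation

Features for clustering are per-voxel vectors of per-(subject, task) mean
betas of correct target-condition trials (a target-versus-rest contrast with
the synthetic rest baseline at zero). `kmeans_ensemble()` runs Lloyd's
squared-Euclidean k-means (via `stats::kmeans`, 300 iterations max) from
`n_init` random centroid initializations (default 1000). For each candidate
k in 2..7 the lowest within-cluster-sum-of-squares member is scored by a
battery of 12 validity indices: Calinski–Harabasz, mean silhouette,
Davies–Bouldin, Dunn, C-index, McClain–Rao, point-biserial, PBM,
Ratkowsky–Lance and Xie–Beni (each voting its own max/min optimum over k),
plus Hartigan and Krzanowski–Lai, which are defined on the sequence of
within-cluster sums of squares over successive k. Hartigan votes by the
successive-difference elbow of `H(k) = (W_k/W_{k+1} - 1)(n - k - 1)`: the
textbook `H <= 10` stopping rule never fires on continuous features at these
sample sizes, where adding a cluster always cuts W by more than a few
percent. Krzanowski–Lai maximizes `|DIFF_k|/|DIFF_{k+1}|` and abstains at the
top of the range where `W_{k+1}` is unavailable. Indices undefined on a
partition (zero diameters, coincident centroids, equal pair distances)
abstain and are logged in the vote table. The winning k is the modal vote
among non-abstaining indices, ties broken toward smaller k — a deliberate
parsimony bias — and the agreement percentage is reported over non-abstaining
indices only. Two caveats are worth stating: a 97-ish percent agreement over
an index battery is only meaningful relative to the battery's composition
(ours has 12 members, configurable, not the 25 of external batteries), and
the McClain–Rao minimum rule genuinely prefers large k on some well-separated
fixtures — the majority vote is robust to individual dissenters by design.

Consensus labelling aligns every ensemble member at the winning k to the
lowest-WSS member by exact maximum-overlap label matching (all k!
permutations are searched; k ≤ 7 keeps this trivial and avoids a dependency
on an assignment-problem solver). A voxel is *stable* iff its aligned label
agrees in at least `stability_threshold` of the members. The default
threshold is 1.0 — strict unanimity, the tightest reading of excluding voxels
with varying allocations — with a configurable override, since a tolerant
majority rule is equally defensible. Unstable voxels carry no subregion
membership downstream. For k = 2 the cluster whose center of mass lies
further along the anterior axis (second grid axis, orientation taken from the
mask affine) is named *anterior*; naming is ordinal for k > 2 and degenerate
ties are an error rather than an arbitrary choice.

Hemispheric congruency flips the right parcellation across the left-right
axis and reports (i) per hemisphere, the percentage of ROI voxels whose
mirrored position lies in the other mask, and (ii) over voxels present in
both masks and stably labelled on both sides, the percentage sharing a
subregion name, overall and per subregion. With no shared voxels the
concordance is reported as undefined (`NA`), never as 0.

## Task decoding

The classifier sees only the four subregion-averaged activities (L-ant,
L-post, R-ant, R-post) of correct target-condition trials. Within each
leave-one-subject-out fold: trials are balanced by subsampling every task to
the per-(subject, run) minimum (the design implies the social task is the
binding constraint, about 3 trials per run); numeric confounds — session
number, session time (run position within session) and run time (trial
position within run) — are regressed out with coefficients fitted on training
rows only; subject identity is handled by within-subject mean-centering from
each subject's own rows, because indicator regression cannot be applied to a
subject unseen at training time — this is the one deliberate deviation from a
plain confound regression, and its no-leakage property is tested; features
are then standardized per (subject, session, run) to mean 0 and unit
*population* variance (so a two-trial run maps (1, 3) to (−1, 1) exactly),
with zero-variance run-columns set to 0 and logged.

Balancing subsamples are seeded per (subject, run) group independently of
which other rows are present, which makes fold computations bit-reproducible
when a subject is removed — the property that the no-leakage test asserts
verbatim.

Three one-vs-rest logistic discriminants with L2 penalty are fitted via
`glmnet` (`alpha = 0`, `lambda = 1/(reg_strength * n)`, i.e. unit inverse
regularization strength in the loss-sum convention; `reg_strength` is
configurable because the upstream software default is not documented
anywhere). A held-out trial is assigned to the task with the maximal decision
value, ties broken in the fixed order attention < semantics < social. The
reported signature is the fold-average of the weight vectors; the confusion
matrix, overall and per-task accuracies, and the 33.33% chance level make up
the cross-validation report. (Subject, run) cells missing a task entirely —
possible when all of a run's few social trials are incorrect — are dropped
with a message before balancing rather than aborting the whole fit.

One behavior of the null configuration deserves a note: leave-one-subject-out
accuracy on data with no task effects scatters around chance with a spread
wider than a binomial interval for the test-trial count, because a
noise-fitted classifier's predictions are correlated across trials. Values a
few points either side of 33.33% on a ~2000-trial test set are the expected
null behavior, not a defect.

## Functional-connectivity shifts

For each task, Pearson correlations are computed across that task's correct
target-condition trials between each subregion mean series and each parcel
series (beta-series connectivity), then Fisher z-transformed after clipping r
to ±(1 − 1e−7) so z stays finite; cells with constant series are flagged
missing. The shift statistic per (subregion, parcel, task) is `z(task) -
mean over tasks of z` — a contrast against the pooled baseline of all three
conditions. Its null is built by shuffling task labels across trials *within
subject* (preserving per-task counts; a pooled-shuffle strategy switch exists
because the shuffling unit is a genuine interpretation choice), recomputing
the statistic `n_perm` times (default 5000). Two-tailed empirical p-values
use the add-one correction `p = (1 + #{|null| >= |obs|}) / (1 + n_perm)`; a
cell is flagged at `alpha = 0.05` with no correction across parcels by
default (an optional Benjamini–Hochberg flag is provided). Network summaries
average z per (subregion, network, task) over a parcel-to-network lookup of
the seven canonical large-scale systems, in all-cells and significant-only
variants.

## Effective-connectivity permutation test

The test consumes subject × task × 4 × 4 directed modulation matrices
(estimated upstream by external software, or synthesized here; the package
never inverts a causal model). Per task and directed connection the statistic
is the mean over subjects of (parameter under the task − mean of the same
parameter under the other two tasks). The null permutes the three task
assignments independently within each subject (default) or sign-flips each
subject's contrast (strategy switch; both respect subject exchangeability,
and the choice is recorded in the result's metadata). A connection is flagged
iff its absolute statistic exceeds the 99.9th percentile of the absolute
null over 10000 permutations; the add-one empirical p-value is reported
alongside because the published mapping of that percentile rule onto an alpha
level is not internally consistent, and users may prefer either decision
rule. Self-connections are excluded by default. The percentile rule requires
`n_perm >= 100/(100 - percentile)`; the check subtracts 1e−6 before the
ceiling so that floating-point noise in `100 - 99.9` does not demand 1001
permutations where 1000 is the honest minimum.

## Pipeline, seeding and numerical conventions

`run_pipeline()` executes simulate → parcellate → classify → connectivity →
ecperm, writing TSV/JSON/NIfTI artifacts plus a manifest (config and its MD5
hash, per-stage seeds and wall times). Stage seeds derive from one master
seed by a fixed Lehmer-style split (`stage_seed()`), so any stage is
reproducible in isolation; identical config and seed give byte-identical
stage outputs, and partial stage selections reload upstream artifacts from
disk, failing with the missing file's name. Configuration defaults: candidate
clusters 2..7, ensemble size 1000, stability threshold 1.0, alpha 0.05,
effective-connectivity percentile 99.9 with 10000 permutations; the demo
study conditions are 10 subjects × 4 runs, 200 voxels per hemisphere, 100
parcels, 1000 connectivity permutations.

Problem sizes used by the test suite were chosen so the full suite exercises
every calibration claim at desk scale: chance calibration runs 20 subjects ×
12 runs once; cluster recovery runs 20 seeds at ensemble size 50 (recovery at
these separations is insensitive to ensemble size beyond a few dozen members);
the connectivity type-I simulation uses 200 replicates × 199 permutations ×
30 parcels; the effective-connectivity calibration 200 replicates × 1999
permutations at 22 subjects. The stated permutation defaults (5000 / 10000)
remain the recommended analysis settings.

## Known limitations

* The generator's noise model is white; claims about real fMRI data (with
  autocorrelated, heteroscedastic noise and imperfect beta estimation) are
  outside what the tests certify.
* The validity battery is a documented 12-index subset, not a reproduction of
  any external 25-criterion battery; agreement percentages are comparable
  only within a fixed battery.
* Anatomical naming is defined for two clusters; larger k yields ordinal
  names with no anatomical semantics.
* The classifier's regularization and the exact permutation units of the
  published analyses are not documented upstream; both are exposed as
  parameters and the defaults are our choices.
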