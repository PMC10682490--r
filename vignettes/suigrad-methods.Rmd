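---
title: "Models and methods behind suigrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind suigrad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`suigrad` analyses resting-state functional connectomes across six ordered
clinical groups — healthy controls (HC) and five depression subgroups
graded by the HAMD suicide item (MDDNSI, MDDmSI, MDDmoSI, MDDSSI, MDDSB),
the "suicidality gradient". This vignette explains the statistical models
the package implements, the choices made where the design was genuinely
open, what the synthetic cohort generator does and does not emulate, and
the numerical details that matter when reproducing results.

## From time series to network summaries

Functional connectivity (FC) between two regions is the Pearson
correlation of their time series (`compute_fc()`); a constant series has
no defined correlation and is a hard error naming the node, never a
silent `NaN`. The connectome diagonal is stored as `NA` so no
self-connection can leak into a mean. Averaging is done on raw r by
default: an optional Fisher z-transform (`fisher_z()`) is provided
because variance stabilisation before averaging is the common
alternative, but it is not applied unless asked for, and all summaries
propagate whichever scale they are given.

For a K-network partition (`default_partition()` ships a synthetic but
structurally faithful 226-node, 10-network layout; it is not the true
ROI assignment of any published atlas), `summarize_networks()` computes

* **WNC(k)** — mean FC over the node pairs inside network k (K values);
* **BNC(k, l)** — mean FC over pairs spanning networks k and l
  (K(K−1)/2 values);
* **OVO(k)** — mean FC over *all* node pairs linking k to the other
  networks (K values).

OVO is defined as the pooled, pair-count-weighted mean, not the
unweighted mean of the K−1 BNC values; the two differ when network sizes
differ, and the pooled reading matches "one network versus all others".
The internal-consistency identity `OVO(k) = weighted.mean(BNC(k, ·),
pair counts)` is enforced by a property test. Negative correlations
enter every mean as-is: no thresholding, no absolute values. For the
10-network partition the metric family is 10 + 10 + 45 = 65, a count
the code always derives from the partition rather than hard-coding.

The FC index (FCI, `fci()`) of an edge set is the plain mean of the FC
values over its edges — the subject-level composite used both for
clinical correlations and as classifier features.

## Network roles and their trajectory

Each network, per group, gets one of four roles from its group-mean WNC
and OVO: *cohesive*/*incohesive* (WNC at or above / below a cohesion
cut) crossed with *connector*/*province* (OVO versus a connector cut).
No principled absolute cutoffs exist for these quantities, so the
default policy is the least-parameterised distribution-based one: each
cut is the median of the ten values within the group, with ties landing
on the cohesive/connector side; a fixed-cut policy is available, and the
cuts used are always recorded in the output. `role_trajectory()` orders
the roles along the gradient and flags networks whose role ever changes.

One consequence of a per-group median split worth knowing: exactly five
networks are cohesive and five are connectors in every group, so role
flips can only happen in pairs (one network crossing up while another
crosses down). A pattern with three divergent networks therefore
requires the divergent trio to swap rank among themselves around the
median, which is exactly how the synthetic design (below) produces a
seven-stable / three-divergent layout.

## Group inference

Each of the 65 metrics is tested with an ordinary least-squares model of
the metric on group indicators plus age, sex, education and study site
(site as categorical indicators) — the ANCOVA reading of a Gaussian GLM —
with the omnibus group effect assessed by the partial F against the
covariates-only model (`metric_group_test()`). With no covariates this
reduces exactly to one-way ANOVA, which the tests assert. Rank-deficient
designs (e.g. site perfectly confounded with group) fail naming the
collinear columns. The 65 p-values are adjusted together by
Benjamini–Hochberg FDR (`fdr_adjust()`, `stats::p.adjust` behind a
validated surface, cross-checked against a brute-force step-up oracle).

Demographic tables use one-way ANOVA with least-significant-difference
(LSD) post-hoc pairwise t-tests on the pooled error term — uncorrected,
because that is what LSD means, and labelled as such — and chi-squared
tests without continuity correction for categorical variables
(configurable for 2×2 tables).

Behaviour correlations (`partial_pearson()`) residualise both the metric
and the clinical score on the covariates and correlate the residuals,
with a t test on n − k − 2 degrees of freedom (k = covariate design
columns beyond the intercept). Whether such correlations should pool all
MDD subjects or run per subgroup is ambiguous in general; the function
takes whatever rows it is given, and the demo pools MDD subjects.

Heterogeneity screens (`heterogeneity_screen()`) run two-sided Wilcoxon
rank-sum tests of each variable between females and males, or between
younger (18–37) and older (38–65) subjects — 37 is the last "younger"
year. P-values come from exact enumeration when both strata have n ≤ 10
and there are no ties, and from the tie-corrected normal approximation
without continuity correction otherwise; results are reported as log10 p
with the significance line at log10(0.05) ≈ −1.301.

## Network-based statistic

`nbs_test()` computes, for every one of the 25,425 edges of a 226-node
connectome, the t statistic of the group indicator in a linear model of
edge FC on group + covariates. A single design matrix is shared across
all edges, so the whole map is one multi-response least-squares solve —
this is what makes permutation inference affordable. Edges at or above
the edge-forming threshold are collected and their connected components
(igraph, verified against a breadth-first-search oracle) form the
candidate clusters, sized in edges (the "extent" statistic; the
intensity variant is not implemented).

The component null is built by permuting group labels, recomputing the
edge map, and recording the maximal component size; component p-values
are `(1 + #[null ≥ observed]) / (1 + B)`, so they can never undercut the
permutation floor. Positive and negative directions (group A above or
below group B) are tested separately and Bonferroni-doubled when both
are requested, matching the practice of reporting increased and
decreased connections as separate families. The doubling makes the
two-direction test deliberately conservative; together with the
discreteness of component sizes at stringent edge-forming thresholds on
small graphs, its realised family-wise error can sit well below the
nominal level, which is why the calibration test in the suite exercises
the one-directional form at an edge-forming p of .05, where near-nominal
behaviour is the correct expectation. Label permutation is
unrestricted by default; a within-site stratified option and a
Freedman–Lane residual-permutation option are available for designs
where site exchangeability is a concern. The edge-forming threshold
defaults to the two-sided p = 0.001 t quantile at the model's residual
degrees of freedom — a deliberately stringent conventional choice, always
recorded in the result and overridable. `conjunction()` intersects edge
sets across contrasts to isolate shared differential connections.

## Classification

`evaluate_classifier()` implements the full protocol: ten (by default)
stratified 80/20 train/test splits; feature standardisation with
training statistics only; the soft-margin cost C of a linear SVM chosen
by stratified 10-fold cross-validation within the training set over
{0.01, 0.1, 1, 10, 100}; accuracy, sensitivity, specificity and AUC
(from decision values, by the rank/Mann–Whitney formula) on the held-out
set; mean ± SD across splits. The split ratio is a convention choice —
the companion of 10-fold inner CV — recorded in the report. The
permutation test permutes labels *before* the entire split-and-tune
procedure (the conservative reading) and compares mean permuted accuracy
with the observed mean. All study contrasts are binary, so no
multi-class machinery exists; `run_all_contrasts()` enumerates the three
contrast families (each MDD subgroup vs HC; each SI subgroup and MDDSB
vs MDDNSI; all pairs among the SI subgroups and MDDSB), 15 contrasts for
a full cohort, skipping and logging any contrast whose groups are
missing.

## The synthetic cohort generator

The generator is the package's stand-in for a multi-site clinical
cohort: it defines the study conditions under which everything else is
tested. Each subject's T × 226 time series is drawn from a zero-mean
multivariate normal whose correlation matrix is block-constant over the
networks: within-network blocks at `base_within[k] + shift`,
between-network blocks at `(base_between[a] + base_between[b]) / 2 +
shift`, with group shifts from the effect map and a small additive site
offset (two sites, +0.02 on site B) as nuisance structure. Defaults are
T = 200 timepoints and group sizes 50/30/30/25/20/15 — a deliberately
scaled-down cohort that one CPU simulates and analyses end to end in a
few minutes while keeping every group large enough for covariate-
adjusted inference.

The default effect map plants the qualitative gradient signature the
analysis is built to detect: within-network connectivity of AUD, SAN and
SUB rises from HC to a peak at MDDmoSI and falls into MDDSB (an
inverted U), and one-versus-others connectivity of DMN and VAN falls to
a valley at MDDmoSI and rises above baseline in MDDSB (a U). Peak
amplitudes (0.05–0.17 on r) are larger than typical clinical effect
sizes; they are chosen so that sign patterns are recoverable with high
probability at the scaled-down sample sizes, which is what the recovery
tests quantify. Baselines are arranged so the AUD/SAN/SUB trio straddles
the within-network median (their rank order among themselves changes
across groups) while four networks sit clearly below and three clearly
above it, and the one-versus-others tiers are separated by a wide gap at
the connector/province boundary — this yields the seven-stable /
three-divergent role pattern reproducibly.

Correlation targets assembled from block values need not be positive
definite; mild indefiniteness is repaired by clipping eigenvalues at
1e−4 and renormalising to unit diagonal. The repair slightly perturbs
the planted block values (≤ 0.03 under the defaults), so the ground
truth records the *post-repair* block means — the values the sampled data
actually follow — and `expected_group_summary()` re-derives every
expected summary from them (the closure property the recovery tests
use). A repair that would move any block mean by more than 0.05 is
refused with a pointer at `base_between`, since such a configuration no
longer means what it says.

Clinical scores are generated on top of connectivity: HAMD subfactors
are linear in the subject's planted FCI (the pooled within-network FC of
AUD/SAN/SUB, standardised over MDD subjects) plus noise — anxiety with a
negative slope, weight positive, retardation and sleep mildly positive —
then rounded and clipped to plausible integer ranges; the HAMD total
rises with the suicide-item score, and the suicide item is derived from
the group so the two are consistent by construction. Healthy controls
carry `NA` clinical scores, as in real ragged multi-site tables.

Reproducibility: one master seed fans out to per-subject substreams
keyed by (group, position), so enlarging one group never changes another
subject's data, and every stage of `run_demo()` derives its own stream
from the same master seed.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: hemodynamic autocorrelation and realistic
noise spectra, head-motion artefacts, node-level heterogeneity within
blocks (a single r per block), non-Gaussian tails, missingness, and
site effects beyond an additive offset. Results on synthetic cohorts
demonstrate that the *pipeline* is correct and calibrated, not that any
particular clinical effect exists.

## Numerical choices and scaled-down problem sizes

* Matrices are symmetrised on read only when asymmetry is below 1e−6;
  larger asymmetry is an error, as is a non-square file or a self-loop
  in an edge list. Edge files are 1-based with `node_i < node_j`.
* Degenerate (zero-variance) edges get statistic 0 rather than NaN.
* Permutation p-values are always `(1 + #extreme) / (1 + B)`.
* The demo and the test suite run deliberately scaled-down designs:
  NBS calibration uses 200 null datasets of 20 nodes with 200
  permutations; recovery uses a planted complete-K5 10-edge cluster at
  +1.5 SD with 1,000 permutations; trajectory recovery re-simulates the
  default cohort over 20 seeds; the demo uses 200 NBS permutations and
  5 splits / 5 folds / 50 permutations per classifier contrast. These
  sizes keep a full run on one CPU within minutes while leaving the
  Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* The cohesive/connector cuts are medians by construction, so absolute
  role labels are relative statements about a cohort, not calibrated
  physiological categories.
* The NBS intensity statistic, graph-theoretic node metrics
  (participation, modularity) and nonlinear classifiers are out of
  scope.
* The Bonferroni handling of the two NBS directions treats the family
  as exactly {positive, negative}; a wider family (e.g. across several
  contrasts) is the caller's responsibility.
* `fisher_z()` exists but no empirical claim in the package depends on
  the choice of scale; analyses default to raw r.
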