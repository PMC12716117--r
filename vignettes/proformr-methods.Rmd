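---
title: "Methods: post-identification proteoform analysis with proformr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-identification proteoform analysis with proformr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proformr)
library(dplyr)
```

proformr implements the downstream, post-identification half of a label-free
quantitative top-down proteomics experiment: the stages that turn
search-engine proteoform-spectrum matches (PSMs) from a set of LC-MS
acquisitions into a proteoform-by-sample abundance matrix and paired
differential-abundance calls. The motivating application is a paired
multi-donor pancreatic-islet study — six donors, each contributing a control
and a cytokine-treated sample, each sample acquired once with FAIMS gas-phase
fractionation over three compensation-voltage (CV) channels — but every stage
is parameterized and applies to any experiment with the same shape.

This vignette explains each stage's model and assumptions, the tunable
parameters with their defaults and units, the synthetic-data generator used
to verify the pipeline, and the numerical and design decisions that were
genuinely open.

## Input model

One row of the canonical PSM dialect is one spectrum-level match: dataset
(acquisition) id, scan number, retention time (minutes), observed
monoisotopic neutral mass (Da), the identification (accession, gene, first
and last residue, modification shifts), the search engine's E-value, a
target/decoy flag, the precursor feature intensity, and the CV channel
label. Residue coordinates are 1-based closed intervals on the full
precursor, with the first residue of the signal peptide as residue 1; the
insulin B chain is therefore `INS_25-54`, and a trailing `*` marks a
modified proteoform. Rows without an E-value are treated as unidentified
MS1 feature observations: they pass untouched through score-based filtering
and participate in clustering and quantification, which is what lets
identification transfer (below) extend identities onto them.

A proteoform's identity for cross-run matching is its *key*: gene,
accession, residue span, and a canonicalized modification signature in
which delta masses are rounded to two decimals. The rounding matches the
precision at which mass shifts are conventionally reported and avoids
float-identity fragility when the same modification is written with
different numbers of digits in different files.

## Filtering: E-value ceiling and target-decoy FDR

Scored records are first held to a maximum allowable E-value (default
0.05), then filtered to a 1% false discovery rate at PSM level by the
target-decoy construction: records are ranked by ascending E-value, the
running FDR at rank *i* is the decoy count divided by the target count at
or above that rank, and q-values are the cumulative minimum of the running
FDR taken from the worst rank upward. Targets with q at or below the
target are retained; decoys never survive. Ties in E-value rank targets
before decoys — the conservative convention, stated explicitly because
score ties do occur in exported tables. FDR is estimated globally across
acquisitions by default (`fdr_scope = "dataset"` filters each acquisition
separately); with twelve acquisitions of comparable depth the global and
per-dataset thresholds are close, and the global estimate is less noisy.

## Retention-time alignment

Chromatographic drift between acquisitions is corrected by aligning every
dataset to a reference — the acquisition with the most distinct identified
proteoform keys, ties broken lexicographically. For each other dataset,
anchors are the proteoform keys identified on both sides, each represented
by its best-E-value observation, and a locally weighted (loess) regression
of reference RT on local RT is fitted through them: degree 1, span 0.5,
with robustness reweighting (symmetric family) so a handful of wrongly
matched anchors cannot bend the curve. The span and the robustness
iterations are not dictated by any published value; 0.5 is wide enough to
be stable with ~100 anchors while still tracking gradient nonlinearity.
Outside the anchor range the fit is continued linearly from the boundary
slope rather than clamped: drift at the extremes of a gradient does not
flatten out, and a constant clamp would fold early- and late-eluting
features onto the boundary. Datasets with fewer than 10 anchors keep the
identity map, with a warning — too few anchors produce worse alignments
than none.

## Mass recalibration

Each acquisition's systematic mass error is estimated as the median ppm
error `(observed - theoretical) / theoretical * 1e6` over its confidently
identified records, and all masses in the acquisition are divided by
`(1 + median_ppm * 1e-6)`. The median is taken per dataset by default:
instrument calibration drifts between runs, and a single global median
would leave per-run biases in place (a `"global"` option exists for
instruments calibrated once per batch). Only post-FDR identified records
inform the estimate, but the correction applies to every record of the
dataset, including unidentified features. Theoretical masses come from the
identification: residue masses plus water, a fixed carbamidomethyl adduct
on every cysteine (the standard iodoacetamide alkylation), and the
declared variable-modification deltas; atomic monoisotopic masses are
fixed to five decimals so the arithmetic is bit-stable across platforms.

## Clustering and identification transfer

Observations are grouped into proteoform clusters on recalibrated mass and
aligned RT with complete-linkage agglomeration under the scaled distance

d(i, j) = max( |Δmass| / (mass × ppm_tol × 1e-6), |ΔRT| / rt_tol_min )

cut at d = 1, with defaults `ppm_tol = 10` and `rt_tol_min = 2`. Complete
linkage is the deliberate choice here: it bounds the *diameter* of every
cluster by the tolerances, whereas single linkage chains neighboring
features across the tolerance. The pair mass in the ppm term is the mean
of the two masses. For scalability the observations are first split at
sorted-neighbor mass gaps that no pair could bridge; linkage within the
resulting blocks is exact, so the partition is identical to a global
clustering and invariant to input order. One practical consequence of a
diameter bound worth knowing: per-observation mass errors whose spread
exceeds the tolerance will split a true proteoform's observations, so the
tolerance should be set to the instrument's worst-case error, not its
standard deviation.

Identification transfer then implements the match-between-runs idea at
cluster level: the most frequent identified key in a cluster becomes its
consensus (ties broken by best E-value, then lexicographically, flagged),
and all members — including unidentified feature observations — inherit
it. Clusters with no identified member remain unidentified; they are
retained in the outputs as unassigned rows for diagnostics but excluded
from gene-level statistics, since nothing scientifically interpretable can
be said about them. Transfer to wholly unidentified clusters by mass/RT
lookup against an external library is deliberately out of scope.

## Roll-up across compensation voltages and quantification

FAIMS CV channels partition the ion population, so a proteoform's signal
in one sample is spread across channels. The roll-up therefore *sums*
across CV channels; but within one (sample, channel) cell, multiple member
features most plausibly re-observe the same elution profile, so they
contribute their *maximum* rather than their sum, avoiding
double-counting. Both choices are exposed (`within_cv = "max"`/`"sum"`)
because the right behavior depends on how the upstream feature finder
reports co-eluting isotopologue envelopes. Abundances are log2-transformed;
the parallel spectral-count matrix (scored PSMs per cluster and sample)
supports the semi-quantitative per-gene rankings. Clusters that resolve to
the same consensus proteoform are merged by re-roll-up and flagged.

## Normalization and differential abundance

Sample-level intensity effects are removed by two-way median polish of the
log2 matrix (via `stats::medpolish`, missing cells skipped): the matrix is
decomposed into overall + row + column + residual, and the *column*
(sample) effects alone are subtracted from the data. Removing row effects
too would erase the between-proteoform structure that downstream tests
need. Two numerical caveats are documented because they are properties of
the algorithm, not bugs: convergence is declared on the change in the sum
of absolute residuals (default tolerance 1e-6, 50 iterations), and with an
even number of samples the midpoint median can leave residual row medians
slightly off zero at the fixed point; the additive reconstruction identity
holds to 1e-9 regardless, and the tests check exactly that.

The paired design is tested as a one-sample problem on per-donor
differences (treated minus control, log2 scale), which for complete pairs
is equivalent to a two-condition model with donor blocking. A proteoform
is quantifiable when it has at least two complete donor pairs; the rest
are excluded and counted. The moderated t-test shrinks each proteoform's
variance toward a pooled prior under the scaled chi-square model: with
`s_g^2` the sample variance on `d_g = n_pairs - 1` df, the posterior is

s̃²_g = (d0·s0² + d_g·s_g²) / (d0 + d_g),

and t̃ = mean / (s̃_g / √n) is referred to a t distribution on `d0 + d_g`
df. The hyperparameters `(d0, s0²)` are estimated by moment matching on
`log s_g²` using the digamma/trigamma moments of the log-F marginal, with
the trigamma inverted by Newton iteration and `d0` capped at 1e6 to
represent "effectively infinite". This estimator is implemented in the
package and cross-checked in the test suite against limma's
`squeezeVar`/`eBayes` on identical inputs, where it agrees to 1e-6; at
`d0 = 0` it reduces exactly to the classical one-sample t. Degenerate
panels in which no proteoform has positive variance disable moderation
with a warning rather than inventing a prior. P-values are two-sided and
Benjamini-Hochberg adjusted via `stats::p.adjust`. Volcano classes use the
conventional strict cutoffs, unadjusted p < 0.05 and |log2FC| > 1, both
configurable; classification on adjusted p-values is available
(`use_adjusted = TRUE`, threshold 0.05) and both views are reported.

## Presence/absence and regional trends

Proteoforms observed in only one condition cannot be tested for
differential abundance. For a proteoform seen in k samples all belonging
to one group of size n_g out of N, the hypergeometric presence probability
`choose(n_g, k) / choose(N, k)` is the chance that k samples drawn
uniformly without replacement all land in that group; group-unique
proteoforms with probability below 0.01 are flagged. The test is one-sided
per group and deliberately not multiplicity-adjusted — it is a screening
flag, matching field practice for condition-unique feature reporting.

Regional trends count tested proteoforms wholly contained (closed-interval
containment) in a named prohormone region, split by the sign of their
log2 fold change. The packaged region map covers the proglucagon products
(GRPP, glucagon, oxyntomodulin, glicentin, GLP-1, major proglucagon
fragment), the insulin chains, the chromogranin-A products (vasostatins,
EA-92, LF-19/catestatin, GR-44) and the somatostatins, with 1-based
full-precursor coordinates. Two mapping rules matter: nested containment
resolves to the *smallest* containing region, because the most specific
named product is the scientifically meaningful label (a 53-81 proteoform
is glucagon, not oxyntomodulin); and proteoforms that overlap regions
without being contained in any — precursors spanning several products —
are labelled "Other". The GRPP entry stores the wider 18-52 *region*
rather than the 21-50 mature product; the product is contained in the
region, so product-labelled proteoforms still map to GRPP, and trend
counting uses the region.

## The synthetic-data generator

`simulate_islet_study()` emulates the statistical structure of the paired
study so every stage is verifiable without raw mass-spectrometry data. Its
defaults are the study conditions: 6 donors × {control, treated} × 3 CV
channels; per-dataset ppm bias ~ Normal(0, 3 ppm) with 2 ppm observation
noise; per-dataset monotone cubic RT warps (offset ±2 min, slope
0.95-1.05, small quadratic/cubic terms, resampled until strictly
increasing); per-proteoform baseline log2 abundance ~ Normal(20, 2), donor
effects with sd 0.5 and residual sd 0.3; logistic abundance-dependent
missingness `P(observed) = plogis(2.5 + 0.8·(log2A - 20))`, which gives
high presence for abundant proteoforms and realistic dropout in the tail;
intensities split across CV channels by symmetric Dirichlet(2) weights;
5% decoy PSMs with Uniform(0,1) E-values against stretched-exponential
target E-values, so FDR filtering has signal; and a 20% identification
dropout that exports some observations without their identity, exercising
match-between-runs transfer.

Treatment effects are injected region-wise on the log2 scale — major
proglucagon fragment +1.5 and GRPP −1.5 on GCG, LF-19/catestatin −1.5 and
vasostatin-1/2 +1.0 on CHGA by default — mirroring the direction of the
regional shifts such a study reports; effect sizes are generator choices
on the order of one volcano fold-change cutoff. Proteoform truncations are
sampled with a 70% bias toward ragged inward trimming of the canonical
products (exopeptidase-style truncation ladders), the remainder uniform,
which reproduces the observed truncation landscape without claiming
biology. The precursor sequences are *synthetic*: deterministic
pseudorandom sequences of the canonical precursor lengths for INS, GCG,
CHGA, SST, IAPP and PPY with Lys-Arg dibasic sites placed at the true
processing-region boundaries. Region arithmetic, naming and mass
bookkeeping behave as with real sequences, but the residues between
cleavage sites are not the real ones and no biological conclusion
transfers. What passing tests on this generator show is that the
*pipeline* recovers what was injected — biases, warps, memberships,
effects — not that it would make the same calls on real islet data, whose
noise is neither Gaussian nor independent across proteoforms.

A `TruthManifest` accompanies every simulation (per-dataset warp
coefficients and ppm bias, per-cell true abundance and presence, injected
effects), and `expected_outputs()` recomputes oracle targets from it;
in the noiseless limit the pipeline's estimates must match these exactly,
and the test suite asserts that they do.

## Problem sizes and determinism

All randomness flows from a single integer seed passed explicitly; the
same seed reproduces the simulation byte for byte. The default study size
used throughout the tests and the acceptance script — 6 precursor genes ×
25 proteoforms × 12 acquisitions × 3 CV channels, roughly 4,700 PSMs, plus
a 2,000-proteoform null panel for hyperparameter recovery — was chosen so
that every recovery check has comfortable statistical power while a full
verification run completes in a couple of minutes on one core. Clustering
tie-breaks, consensus tie-breaks and reference selection are all
deterministic, so reruns with one seed are identical.

## Known limitations

The roll-up consumes feature intensities already present in the PSM
tables; there is no feature detection from raw MS1 data, no
isotope-envelope modeling, and no fragment-level (MS/MS) validation. The
recalibration applies one median per dataset, not a mass-dependent
calibration curve. Identification transfer never assigns identities to
clusters with zero identified members. Covariates (donor sex, age, BMI)
are not modeled; the paired design absorbs stable donor effects and
nothing more. Counts reported in the source study that depend on rerunning
a database search against the deposited raw data (total proteoform and
gene tallies) are outside what this package can recompute; the
`reproduce_reported_counts()` helper recomputes the downstream headline
counts whenever a per-proteoform differential table is supplied.
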