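---
title: "Methods: models, parameters, and design choices in saltomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in saltomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltomics)
```

This vignette documents the statistical machinery behind each pipeline
stage, the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the places where the design was
genuinely open and a choice had to be made.

## The experimental design being modeled

The package targets a salt-shock study layout in a euryhaline
cyanobacterium: a transcriptome time course at 0 (unstressed reference),
0.5, 2 and 24 h after raising the medium to 4 % NaCl, measured as log2
microarray signals in duplicate hybridizations per time point; a proteome
of salt-acclimated versus control cultures quantified absolutely (fmol on
column) in four fractions — total extract, soluble, membrane-enriched and
debris — with four biological replicates each (pooled triplicates for
debris); and an LC–MS/MS metabolome with a fixed amount of carnitine spiked
into every sample as internal standard, three replicates per condition.

Everything downstream assumes log2-scale signals for transcripts (noise is
treated as additive there) and linear fmol amounts for proteins (noise is
treated as lognormal there). Coordinates are 0-based half-open internally;
the GFF3 convention (1-based inclusive) is converted only at the I/O
boundary, which keeps all overlap arithmetic in a single convention.

## Differential transcript expression

Per feature and post-shock time point, the replicate-mean log2 fold change
is `mean(treated) − mean(reference)` and the p-value comes from a
two-sample test on the per-replicate log2 signals. A feature is *up* when
log2 FC ≥ 1 and raw p < 0.05, *down* symmetrically; BH-adjusted p-values
are always emitted alongside but the status gate uses the raw p, matching
the classic microarray cut-off pair.

**Choice of test.** With duplicate hybridizations each group has n = 2.
The Welch test's Satterthwaite degrees of freedom then fall between 1 and
2; whenever one group's sample variance dominates, df → 1 and the critical
t exceeds 12, so even a clean 4-fold change at realistic noise is called in
only ~85 % of cases. The pooled-variance t-test (equivalent to a two-group
one-way ANOVA, which is also exactly how the protein abundances are
tested — `oracle` checks in the test suite verify both equivalences) keeps
df = 2 and calls the same effect in > 99 % of cases. The default is
therefore `de_test = "pooled"`, with `"welch"` available in the
configuration; both reduce to the same decision in the noise-free limit.
Degenerate inputs: groups that are constant *and* equal get p = 1 (a tie
should never be significant); constant but different groups get p = 0
(perfect separation); fewer than two complete replicates give a missing p,
an `unchanged` status, and a one-time warning.

## Soft clustering of temporal profiles

Profiles entering the clustering are the log2 fold-change vectors with the
implicit 0 prepended for the reference time point (D = 4 dimensions for
the default design), restricted to features moving by |log2 FC| ≥ 1
somewhere, and row-standardized to mean 0 / sd 1 so that shapes, not
amplitudes, cluster. Flat (zero-variance) rows have no shape and are
excluded with a warning.

Fuzzy c-means minimizes J = Σ_i Σ_k u_ik^m ‖x_i − v_k‖² by alternating the
standard updates (centroids as membership-weighted means; memberships as
inverse-distance ratios with exponent 2/(m−1)). Numerical details:

* **Fuzzifier.** Default m is the closed-form estimate
  m(N, D) = 1 + (1418/N + 22.05)·D⁻² + (12.33/N + 0.243)·D^(−0.0406 ln N − 0.1134),
  which evaluates to 2.53 for N = 3831, D = 4. It is monotone decreasing
  in D and always > 1; m → 1 recovers hard k-means (verified as a property
  test at m = 1.05 against `stats::kmeans` from the same initialization).
* **Initialization.** Centroids start from c distinct rows drawn under the
  seed; 10 restarts are run and the lowest-objective fit kept, because FCM
  is sensitive to initialization and restarts make the tests stable.
* **Convergence.** Iteration stops when max |Δu| < 1e-9 (cap 1000); the
  objective trace is recorded and is non-increasing by construction of the
  alternating minimization, which the tests assert on random data.
* **Singularity rule.** A point coinciding with a centroid gets membership
  1 there (ties split equally), avoiding division by zero distances.

**Cluster count.** For each candidate c in 2..12 the minimum pairwise
centroid distance is recorded. When c exceeds the number of genuine
shapes, two centroids split one cluster and this distance collapses — the
elbow. The detection rule is deterministic: the second difference of the
curve is strongly negative at the last candidate before a flat-then-drop
kink; the chosen c is the dominant negative second difference (within half
the maximum magnitude, ties to the smaller c), accepted when the curve at
least halves across the kink. A curve that halves immediately after the
smallest candidate has its kink at the range boundary (this is what two
well-separated groups produce when the range starts at 2); if neither test
fires the data show no elbow and the smallest candidate is returned with a
low-confidence warning. The 0.5 relative-magnitude and the halving
constants were fixed from the three qualitative curve shapes (interior
kink, boundary kink, featureless decay) before the recovery experiments
were run.

**Membership filters.** Assignment needs max membership ≥ 0.5; below that,
a profile whose summed membership over the two same-direction clusters
(induced = the centroid entry of maximal absolute value is positive;
repressed otherwise) exceeds 0.6 is assigned to the larger of the pair.
"Same direction" is the natural reading of combining the two induced (and
the two repressed) clusters, and makes the rescue rule well-defined for
any even split of directions.

## asRNA:mRNA pair classification

Candidate pairs are all (asRNA, mRNA) duos overlapping on opposite strands
by ≥ 1 bp on the same replicon (half-open intervals; features without
strand cannot pair and are kept only for expression analyses). An asRNA
crossing several genes contributes one pair per mRNA — counts are of
pairs, not asRNAs.

The correlation is computed on the six per-replicate post-shock fold
changes (2 replicates × 3 time points) rather than the three replicate
means: three points make r nearly degenerate, and the per-replicate values
are what the underlying heatmaps display. This is switchable
(`pair_correlation_basis`). A pair is *eligible* when both members carry a
cluster assignment and each is differentially expressed at ≥ 1 time point
(the stricter, per-member reading of the eligibility requirement).
Eligible pairs with |r| ≥ 0.65 are classified by their members' cluster
directions, requiring the sign of r to agree (opposite directions need
r ≤ −0.65, same directions r ≥ +0.65); sign-inconsistent combinations stay
unclassified rather than being forced into a quadrant.

## Proteome quantification and fold changes

Hi3 absolute quantification: a protein's signal is the mean of its three
most intense peptides, and amounts scale as signal/standard-signal × 40
fmol, making them invariant to global intensity rescaling. Proteins with
fewer than three peptides are quantified from what they have and flagged;
proteins below two unique peptides per fraction are excluded unless
allow-listed by name (the escape hatch for biologically critical
single-peptide identifications).

The fraction-weighted fold change sums soluble + membrane + debris/10 per
condition and takes the salt/control ratio; the debris division by ten
reflects that fraction holding only ~10 % of total protein. Its design
point — proved as a property test — is that a protein moving between the
soluble and membrane fractions at constant total keeps the weighted ratio
within |Δlog2| < 0.1 of the total-extract ratio even when the
single-fraction ratios disagree by > 0.5. The combined fold change is the
arithmetic mean of the weighted and total ratios (the literal reading of
averaging two fold-change values; a geometric option exists via
`combined_fc_scale` for users who prefer log-scale symmetry), falling back
to whichever single value exists. Missing fractions contribute 0 to the
weighted sum — an undetected protein contributes no measured fmol — and
are flagged.

Significance tests run on log-transformed total-extract replicate amounts
(one-way ANOVA, two groups; `protein_test_fraction` and
`protein_test_log` are configurable since the original analysis does not
specify the scale or fraction), gated by the ≥ 1.5-fold combined change.

## Integration and enrichment

Transcript (24 h) and protein log2 fold changes join on locus tag;
asRNA records are excluded from the join since they share their host's
locus tag. |Δlog2| < log2(1.5) defines "similar". The consensus filter
uses strict inequalities (> 0.58 for each of three transcriptome datasets,
> 0.38 for the proteome) over the intersection universe — genes absent
from any table cannot pass and are reported separately. Enrichment is the
one-sided hypergeometric upper tail P(X ≥ k) per (cluster, term), with BH
across terms within a cluster; k = 0 terms are skipped. The test equals
exhaustive enumeration of draws to 1e-12 for every instance with N ≤ 30
(asserted in the suite).

## Metabolite normalization

normalized = intensity / standard-intensity per sample, which cancels the
per-sample injection factor exactly because the spiked standard rides the
same injection; fold change = mean(salt)/mean(control) of the normalized
values, so the control is 1 by construction. A ratio of replicate means
(not a mean of ratios) matches reporting mean values over three
replicates, and is switchable in principle. Samples with a zero or missing
standard are invalid and excluded with a warning; below-detection
metabolites stay missing, never 0.

## The synthetic-data generator

`simulate_all()` writes a complete input bundle with known ground truth:

* **Annotation.** One 200-kb pseudo-replicon; every feature sits in its own
  slot so that exactly the planted asRNA:mRNA pairs overlap on opposite
  strands (pair asRNAs are nested antisense within their host mRNA; free
  asRNAs and sRNAs occupy empty slots). Chromosome realism is irrelevant
  to the algorithms, so one replicon suffices.
* **Transcriptome.** Four temporal archetypes over (0, 0.5, 2, 24) h with
  amplitude A = 2 log2 units: peak at 0.5 h decaying by 24 h
  (0, A, 0.6A, 0.1A), peak at 2 h (0, 0.5A, A, 0.3A), and their repressed
  mirrors; flat profiles with probability 0.3. The intermediate values are
  set so every non-flat archetype crosses the |log2 FC| ≥ 1 DE gate at two
  sampling times — a planted regulated transcript is genuinely callable as
  regulated. Noise is additive Gaussian (sd 0.3 by default) per replicate
  on the log2 scale. Planted inverse pairs give the asRNA the sign-flipped
  archetype of its host; co-regulated pairs share it; pair hosts are never
  flat (a flat pair has no regulation to recover).
* **Proteome.** Control totals are lognormal around 50 fmol, split into
  soluble/membrane shares plus a 5–15 % debris share summing to 1; salt =
  control × planted fold change with lognormal noise at CV 0.1; a subset
  of proteins swaps half its soluble share into the membrane fraction
  under salt at constant total, reproducing the redistribution scenario
  the weighted fold change exists for. Called standalone, the generator
  plants the configured pattern (10 % at FC 2, 10 % at FC 0.5); inside
  `simulate_all()` the planted protein fold change is 2^(planted 24-h
  transcript log2 FC) of the same locus tag, so the omics layers correlate
  as they do in real acclimated cells. A small peptide table with a
  spiked standard encodes true amounts exactly for Hi3 testing.
* **Metabolome.** True abundances × per-sample injection factor
  (lognormal, sd 0.3 on the log scale) × measurement noise; the standard
  channel carries the identical injection factor, making the cancellation
  property exactly testable.
* **KO annotation.** Each gene gets 1–3 generic terms; one planted term
  per archetype cluster covers ~70 % of that cluster and ~2 % of the rest,
  so it is genuinely over-represented.

Determinism: each sub-generator seeds from the master seed plus a fixed
offset, so identical (config, seed) produce bit-identical files (the
manifest records checksums).

**What the generator does not emulate** — and hence what passing tests do
not show about real data: probe-level effects and array normalization
artifacts (inputs start at feature-level log2 signals), correlated noise
across time points or replicates, asRNAs partially overlapping several
genes, missing values, peptide misassignment and shared peptides,
condition-dependent fraction loss, and any real biological pathway
structure beyond the planted KO terms. Recovery results quantify the
pipeline's correctness under its stated model, not its robustness to
violations of that model.

## Problem sizes used in the validation suite

The recovery experiments run at the sizes the study structure implies
while staying desk-scale: 2000 transcript profiles × 5 seeds for cluster
recovery (mean adjusted Rand index and elbow hit rate), 100 planted pairs
× 5 seeds for quadrant recovery, 500 proteins × 10 seeds for differential
sensitivity and false-positive rate, and full enumeration to N = 30 for
the hypergeometric check. The default `simulation_config()` (600 mRNAs,
150 asRNAs with 50 + 50 planted pairs, 50 sRNAs, 500 proteins, 20
metabolites) is the bundle the end-to-end run and the worked example use.

## Known limitations

* With duplicate hybridizations any per-feature test is underpowered;
  the pooled test assumes equal group variances, and no moderated
  (information-sharing) variance estimator is provided.
* The elbow rule needs at least three candidate counts and can only
  return values inside the scanned range; data whose true structure lies
  at the upper boundary will be reported with low confidence rather than
  extended automatically.
* Multi-mRNA asRNAs are classified per pair; no attempt is made to pick a
  primary target.
* The consensus filter requires genes to be present in all four tables;
  genes regulated but undetected in the proteome are listed separately
  rather than ranked.
* Hi3 quantification assumes the standard behaves like the analytes
  within a run; no between-run normalization is implemented beyond the
  ratio to the standard.
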