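---
title: "Models and methods behind leukosplice"
author: "leukosplice maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind leukosplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leukosplice)
```

# Scope

leukosplice re-implements, as a tested and reusable pipeline, an
integrative blood-leukocyte transcriptomics workflow built around four
statistical components:

1. **isomiR-tolerant miRNA quantification** from adapter-flanked small-RNA
   reads;
2. **negative-binomial exact-test differential expression** with
   conditional dispersion estimation and empirical-Bayes posterior
   log-odds (B statistic) ranking;
3. **alternative-splicing detection** from splice-junction/exon probe-set
   intensity matrices, by reciprocal-junction regression and by the
   exon-level splicing index, with city-block hierarchical sample
   classification;
4. **downstream interpretation**: gene-set over-representation analysis,
   marker-based cell-lineage Z-scoring, and contrast-specific
   miRNA-to-spliced-target networks with seed-match verification.

The study design the pipeline models contrasts four blood-donor states —
healthy controls (HC), Parkinson's disease patients before deep brain
stimulation (PD), the same patients on stimulation (DBS_ON), and after one
hour of stimulation cessation (DBS_OFF) — with three tested contrasts:
HC vs PD (disease), PD vs DBS_ON (treatment), DBS_ON vs DBS_OFF
(stimulus dependence).

All inputs can be produced by the package's synthetic-data module with
planted ground truth, so every stage is validated end-to-end without any
external download. This vignette records the models, the parameter
choices, and the places where the design was genuinely open.

# Synthetic data: what is emulated, and what is not

`generateMiRNAReference()` builds a mature-miRNA reference with dominant
and passenger (star) strands and at least one group of two precursors
sharing one mature sequence, so that count merging by mature identity is
exercised. Sequences are uniform random RNA of 18-25 nt; real miRNA
sequence composition (GC bias, seed-family structure) is not modelled, so
cross-mapping between related family members is *not* stressed by these
data.

`simulateReads()` emits 50-base reads laid out as: a 6-8-base suffix of
the 5' adapter, the mature-derived insert, a prefix of the 3' adapter
filling to base 35, and a constant 15-base terminal tag. This mirrors a
ligation library in which sequencing runs from inside the 5' adapter
through the insert into the 3' adapter, with the instrument-specific tag
occupying the read end. IsomiR variation is 3'-biased (up to 2 bases
gained or lost at the 3' end, at most 1 at the 5' end), reflecting the
seed-constrained stability of real 5' ends; substitution noise plants 1-3
random mismatches per affected read. Counts are negative binomial with
dispersion `phi` (default 0.1, a typical biological-replicate value)
around per-condition means that carry the design's planted log2 fold
changes. Base-space FASTQ with constant Q30 qualities is written;
colourspace encoding, quality-score models and ligation bias are
deliberately out of scope.

Choosing the 5' fragment length from 6-8 bases (present on every read
unless the insert leaves no room) means every 5' adapter occurrence
clears the excision threshold; this is what makes exact count recovery a
meaningful oracle rather than a stochastic property.

`simulateProbeMatrix()` works directly at probe-set level (log2), the
level at which the detection statistics are defined: per gene it emits
two constitutive probe sets, one reciprocal inclusion/exclusion junction
pair, and one exon/PSR probe set. Planted reciprocal events move the two
junction probes in opposite directions by the planted effect in the
contrast's second group; planted exon events move only the PSR probe;
*decoy* genes move both junction probes in the same direction — a genuine
expression change that the reciprocity gate must reject. Probe-level
summarization artefacts (RMA/PLIER residuals, cross-hybridisation) are
not modelled.

`simulateTargetTable()` draws (miRNA, gene, region, offset) predictions
with regions sampled from a configurable simplex over (5'UTR, CDS,
3'UTR), default (0.19, 0.38, 0.43) — the region split observed in a
disease miRNA-target network. The demo bundle uses 40 predicted sites per
gene, emulating the density of a multi-program consensus predictor union.

`simulateLineageCompendium()` plants one marker block (default 100 genes,
within the conventional 50-150 range) per lineage, elevated by `shift`
(default 3 log2 units) over baseline; `simulateMixtureSamples()` mixes
noiseless lineage profiles (default 90/10) and records the dominant
label. `simulateLabeledMatrix()` provides the independent two-group
cohort used to exercise the classifier.

Because all generators are pure functions of (parameters, seed), every
downstream recovery rate in the tests and the acceptance report is
reproducible bit-for-bit.

# Small-RNA quantification

**Trimming** (`trimReads()`) applies, in order: removal of the last 15
bases (the tag end, taking 50-base reads to 35); adapter excision; removal
of the 5' terminal base; and a length filter keeping reads longer than 15
bases. Adapter location uses an *end-anchored, ungapped local alignment*:
because ligated adapters can only occur at the read termini, the scorer
evaluates exactly the anchored configurations of a local alignment —
read prefixes against 5'-adapter suffixes, read suffixes against
3'-adapter prefixes — scoring match +1 / mismatch -1 and excising
overlaps that reach `min_adapter_overlap` (default 6) while keeping
per-base identity at 90% or better. Short 3' overlaps below the score
threshold are excised only when exact, handling partial adapters that end
flush with the read. This restriction of the classical local-alignment
recursion is deterministic, which the exact-recovery oracle requires;
`sw_gap` is retained in `trimParams()` for interface completeness but
anchored configurations are gap-free.

**Matching** (`alignAndCount()`) assigns a read to a mature record if it
matches the mature sequence allowing up to 2 extra and 2 missing bases at
either end (isomiR tolerance) and at most 3 substitutions within the
overlap; extended non-templated bases are not compared. Each read gets
one best assignment — ties broken by fewest mismatches, then smallest end
shift, then lexicographic mature and precursor id — because digital
counts feeding an exact test should not be fractionally split. A
dictionary of trim-only variants provides an exact fast path; everything
else goes through a full scan over records and end offsets. Reads left
unmapped are returned for the secondary (filter-database) alignment,
which reuses the same matcher and reports mapped percentages and mismatch
histograms.

`mergeCounts()` sums precursors sharing a mature sequence into one mature
row (column totals are conserved), and `cpmFilter()` keeps features with
CPM at or above 1 in at least 3 libraries — both thresholds configurable.

# Differential expression

Counts are modelled as negative binomial. `normFactors()` computes
trimmed-mean-of-log-ratio factors against a reference library (upper
quartile closest to the mean), double-trimming log-ratios (30%) and
abundances (5%), rescaled to unit product; the unweighted trimmed mean
makes the factors exactly invariant to pure sequencing-depth changes.

Dispersion is estimated by conditional maximum likelihood: counts are
scaled to the geometric-mean effective library size (the
conditional-on-total argument needs equal sizes; the conditional
log-likelihood is a function of gamma terms and is well-defined for the
continuous scaled counts), and the summed conditional log-likelihood is
maximized over `phi` in [0, 10] by golden-section search (tolerance
1e-6). Tagwise dispersions maximize the weighted objective
`ll_g(phi) + prior_df * llbar(phi)` with `prior_df = 10`; `llbar` is the
average conditional log-likelihood, evaluated exactly while the
per-feature searches remain in lockstep and through a dense natural
spline once they diverge — so the infinite-prior limit reproduces the
common estimate exactly, and each estimate lies between the feature's own
conditional MLE and the common value.

`nbExactTest()` conditions each feature on the total count across both
groups; the group-1 sum then follows a beta-binomial whose tail
probabilities give the exact p-value, two-sided by doubling the smaller
tail (capped at 1; sidedness is a recorded choice). In the `phi = 0`
limit this is the conditional binomial test — the brute-force oracle the
acceptance suite checks to 1e-9. Display fold changes use a 0.5
small-count offset; testing never uses the offset.

`bStatistic()` ranks features by the log posterior odds of differential
expression computed on log2-CPM values: per-feature two-group residual
variances are moderated through a scaled-F prior fitted by the standard
log-variance moment equations (with a Newton trigamma inverse), and the
posterior odds use a two-component mixture with prior non-DE proportion
`pi0 = 0.9` and a fold-change variance ratio estimated by the method of
moments from the moderated t-statistics (clamped at or above 1, so the
odds can never be inflated by an ill-determined prior). Features are
called at `B >= 1`. No multiple-testing correction is applied to the
exact-test p-values: the workflow gates on the posterior odds, and this
is stated explicitly to avoid silent divergence.

# Splicing detection

`summarizeGeneExpression()` estimates gene-level expression as the mean
of the gene's constitutive probe sets. For a reciprocal pair (I, E),
gene-normalized values `nI = I - g` and `nE = E - g` are formed and the
baseline group defines a linear relation between them; the per-sample
deviation `d = nI - (a + b*nE)` scores splicing change as
`mean(d, group2) - mean(d, group1)`. The slope is a posterior mean under
a N(1, 0.5^2) prior: under expression-only (no-splicing) changes the two
gene-normalized junction measures co-move 1:1, so the prior centres
there, OLS information from the baseline samples updates it, and a
baseline with no variance collapses cleanly to the `d = nI - nE`
difference form. A free 6-sample OLS slope was rejected during design
because its sampling noise propagates multiplicatively into the score of
genuinely spliced pairs and makes the score scale inconsistent with the
difference form.

A pair is called when all three gates pass: `|score| >= 1` log2 unit (the
fold-change-2 threshold applied on the deviation scale), Welch two-sided
t-test on `d` with `p < 0.05`, and the *reciprocity gate* — the raw
group-mean changes of the inclusion and exclusion probes must be opposite
in sign, which is what distinguishes a splicing change from an expression
change. PSR-vs-exclusion pairs run through the same scorer with the PSR
in the inclusion role. Degenerate zero-variance groups define the t-test
deterministically (separated constants are certain, identical constants
carry no evidence), and threshold comparisons carry a 1e-9 numerical
slack so noiseless constructions at exactly the threshold are called.
Note the baseline-group fit makes group-swap antisymmetry exact only in
the degenerate path; under noise the swap is strongly anti-correlated but
not exactly negated.

`detectSplicingIndexEvents()` is the independent exon-level route:
`SI = x[p,] - g[gene,]`, called at `|dSI| >= 1` with `p < 0.05`.
Gene-wide expression shifts cancel in SI by construction.

`classifySamples()` clusters samples on the feature-restricted intensity
vectors with city-block (Manhattan) distance and average linkage (the
linkage is a recorded choice; only the distance is fixed by the
workflow), cuts at two clusters, and scores accuracy as the best matched
fraction over the two cluster-to-label assignments. Dendrograms export
as Newick.

# Enrichment, lineage, networks

**ORA** standardizes the overlap `r` between a gene set (size `R`) and
the changed list (size `n`) in a universe of `N` by the hypergeometric
mean and variance; sets are reported when `z >= 1.96` *and* at least 3
changed genes overlap, ranked by (z, overlap, name). Permutation
p-values resample the changed list (2000 draws, add-one estimator);
Benjamini-Hochberg q-values on the permutation p-values are reported
alongside but never used for gating, mirroring the workflow's z-and-count
gate.

**Lineage scoring** selects, per lineage, the genes most correlated with
the idealized binary membership profile (ties by gene name), computes
Pearson correlations between each sample and each lineage centroid over
the marker union, and standardizes per sample across lineages (unbiased
sd; a degenerate sd defines all z as 0, and z rows sum to zero
otherwise). Pearson invariance makes the scores immune to per-sample
affine transforms. Samples sharing fewer than half the marker genes are
rejected.

**Networks** connect a miRNA to a gene only when all three memberships
hold: DE-called in the contrast, a called splice event in the contrast,
and a predicted (miRNA, gene) pair. Multi-region predictions collapse to
one edge carrying the region set; region fractions are counted over
edge-region incidences, and both the incidence tally and the raw site
count are reported because "connections" can mean either. Seed
verification scans called junction probe sequences for the exact DNA
reverse complement of miRNA positions 2-8 (the canonical strict 7-mer
seed; start and length are configurable, wobble pairing is not
modelled). Exports are SIF and a canonical GraphML whose attribute order
is deterministic, so export–import–export round-trips are byte-identical.

# Pipeline, determinism and problem sizes

`makeDemo()` writes a complete synthetic bundle; `runAll()` executes
quantification, three DE contrasts, two splicing contrasts, enrichment,
lineage scoring, networks, and an independent-cohort classification, and
writes a manifest recording every threshold, the seed, record counts and
the MD5 of every output — two runs with one seed are byte-identical.
Demo problem sizes (120 + 20 reference miRNAs, 5000 reads per library
across 12 libraries, 300 genes with 30 + 15 planted events and 10 decoys
per contrast, 8 lineages x 100 markers, a 47-sample independent cohort)
were chosen once as desk-scale stand-ins that leave every stage with
non-trivial signal and noise; production depths are orders of magnitude
larger and only affect runtime, not code paths.

The validation suite measures, among others: exact-test agreement with
the enumerated binomial oracle (1e-9), null type-I error of the exact
test at the 5% level, recall and FDR of B >= 1 calls on planted two-fold
changes, exact count recovery and 99% read-assignment accuracy for the
quantifier, junction-caller recall / false-positive / decoy-rejection
rates, noiseless splicing-index exactness, hypergeometric-moment
agreement of the ORA z-score, dominant-lineage recovery in 90/10
mixtures, and two-cluster classification accuracy on the independent
cohort. The same quantities are recomputed from scratch by
`scripts/acceptance.R`.

# Known limitations

* Reference sequences, probe sequences and target predictions are random;
  none of the sequence-composition pathologies of real references
  (miRNA families, repeat-derived probes) are represented.
* The matcher resolves ties deterministically but does not model
  multi-mapping uncertainty; 1 read contributes 1 count.
* The exact test covers two-group contrasts only; multi-factor designs
  and batch correction are out of scope.
* The junction caller's baseline-group regression is not exactly
  antisymmetric under group swap (see above).
* Flat-set ORA only: no ontology-hierarchy pruning of redundant
  parent/child terms.
* GO-style annotations, protein-domain tables and prediction databases
  are consumed, never derived.
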