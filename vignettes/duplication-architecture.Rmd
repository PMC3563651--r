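---
title: "Gene-family duplication architecture: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-family duplication architecture: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syndup)
```

## The problem

Large plant gene families — the F-box family of SCF E3 ubiquitin-ligase
substrate adaptors is the motivating example — grow through a mixture of
whole-genome duplication (WGD), smaller segmental duplications, and local
(tandem) duplication. Two closely related genomes can take radically
different routes: one family may sit mostly in syntenic, segmentally
duplicated regions, while its counterpart in a sister species is dominated
by tandem arrays whose young duplicates then diverge transcriptionally.
`syndup` packages the full chain of inference needed to make that
comparison: call the family from domain evidence, locate it within the
genome's duplication architecture, test whether its placement could be
chance, and ask whether tandem duplicates kept or changed their expression.

Because the real inputs (proteomes, domain scans, all-vs-all BLAST,
transcriptomes) are large and version-dependent, the package also contains
a genome simulator with fully known duplication histories. Every detection
stage is validated as a round trip against that ground truth.

## Family calling from domain hits

Membership is decided from per-domain profile-HMM hits. A gene is a family
member iff it has at least one hit to a clan domain (for F-box proteins:
`F-box`, `F-box-like`, `F-box-like_2`) with

* e-value ≤ 1.0, and
* model coverage ≥ 0.5, where coverage is the aligned fraction of the HMM
  model, `(hmm_to − hmm_from + 1) / model_length`.

The permissive e-value is deliberate: fast-evolving family members are
easily missed at conventional cutoffs, and the coverage requirement does
the work of excluding spurious partial matches. Coverage is measured on
the *model* span, not the query sequence: "half of the domain aligned"
refers to the domain model. Both thresholds are arguments of
`call_family_members()`, and the filter is monotone — loosening either
never shrinks the member set (a property the tests assert).

When a gene has several qualifying hits, the evidence table keeps the
minimum-e-value hit; ties break toward larger coverage, then lexicographic
domain name, so the record is deterministic. Hits naming genes absent from
the annotation raise a validation error rather than being dropped —
silent drops hide identifier-mapping bugs.

"Potentially inactive" members (`detect_inactive_members()`) are genes
with no qualifying domain hit that nevertheless align to a called member
at e ≤ 0.01: the domain has degenerated but the family resemblance
remains. They are kept disjoint from members by construction.

## Collinearity by anchor chaining

Synteny detection works in *gene-rank space*: each gene's position is its
1-based index along its chromosome in start-coordinate order. Rank space
makes gap penalties independent of physical genome size and matches how
gene-model-based chainers (DAGchainer and its descendants) operate.

An *anchor* is a filtered homology hit (e ≤ 0.01) placed at
`(rank_a, rank_b)`, scored `min(50, −log10(max(e, 1e-50)))`. Within one
chromosome pair, `chain_anchors()` finds maximal-scoring chains by
longest-path dynamic programming over anchors sorted by rank: a chain must
increase strictly in `rank_a` and strictly increase (same orientation) or
decrease (inverted, found by negating `rank_b`) in `rank_b`; consecutive
anchors may skip at most `max_gap = 10` ranks per axis, each skipped rank
costing `gap_penalty = 1`. Chains are extracted greedily in descending
score order with anchors disjoint across chains, and chains with fewer
than `min_anchors = 4` anchors are discarded — four aligned gene pairs as
the minimum evidence for a block. On every random instance small enough to
enumerate (≤ 12 anchors), the DP optimum equals an exhaustive search over
all monotone chains; the test suite runs that oracle on 200 instances.

`max_gap` and `gap_penalty` are configurable stand-ins for chainer
defaults; `min_anchors = 4` is the setting this analysis is defined by.

### Tandem arrays

A tandem array (`detect_tandem_arrays()`) is a run of ≥ 2 family genes on
one chromosome in which consecutive members are separated by at most
`max_intervening = 5` non-member genes and are connected by homology at
e ≤ 0.01, transitively within the run (single linkage). Single linkage is
the right connectivity for duplication chains whose ends have diverged
past pairwise detectability. The positional-only mode (`homology = NULL`)
drops the homology requirement; the permutation null uses it, since
shuffled labels carry no homology structure. `max_intervening = 5` is an
explicit package default — tools differ here and the analysis this
implements did not publish its value — and it is shared between observed
and null detections so the comparison is like for like.

### Segmental duplications

Within-genome blocks are chained from self-homology anchors after removing
everything that reflects *local* duplication: self-hits, one direction of
each reciprocal pair, anchors joining two genes of the same tandem array,
and same-chromosome anchors within `max_intervening` ranks of the
diagonal. Same-chromosome blocks whose two rank windows overlap are also
discarded, so a region is never called duplicated against itself. What
remains — chromosome-scale collinear blocks — is the signature WGD leaves
behind, and on simulated WGD genomes at full retention the detector
returns exactly one block per chromosome/duplicate pair covering every
retained gene.

## The permutation null

Whether family genes concentrate inside syntenic blocks (or tandem
arrays) is tested by label shuffling. The key design reading: block
membership is a *fixed property of gene positions*. Shuffling moves the
family label over positions; homology search and chaining are not re-run
per replicate. Each replicate draws `|members|` genes uniformly without
replacement and recomputes the count of labelled genes at block positions.
This is both the only desk-scale-feasible reading of "shuffled synteny
maps" and the statistically conventional one (the architecture is the
conditioning event; the labels are exchangeable under the null).

Where blocks overlap, a gene occupying a position inside *k* blocks can be
counted once (`distinct`, the default — matching statements of the form
"N family genes are located in syntenic blocks") or *k* times
(`multiplicity`, distributing one-to-many relationships accordingly).
Both statistics are exposed.

P-values use the add-one estimator `p = (1 + #{null ≥ obs}) / (n_reps + 1)`,
which is never zero and is super-uniform under the null — the calibration
test draws families from the null itself 500 times and checks the
rejection rate at α = 0.05 stays within three standard errors of α. For
the tandem null, replicates re-detect positional runs only (see above); a
deliberate, documented approximation that makes the replicate arrays
slightly easier to form than homology-linked observed arrays.

The full analysis scale is 10,000 shuffles per comparison; tests and the
acceptance script use 500–2,000 replicates, which bounds the attainable
p-value at ~5 × 10⁻⁴ but leaves means and calibration unchanged.

## Expression divergence

Raw gene × tissue matrices are standardized per gene to zero mean and unit
*population* (divide-by-n) standard deviation — the profile-shape
convention, switchable to the n−1 estimator. Constant rows are set to zero
and flagged rather than producing NaNs.

Transcription is called from *raw* values: a gene counts as transcribed if
it exceeds 10.0 (strictly) in at least one tissue — the
normalized-intensity convention for microarray-style matrices. For data
already restricted to author-reported transcribed genes, a threshold of 0
reproduces "reported as transcribed".

Clustering is agglomerative with Pearson-correlation distance (1 − r) and
average linkage, the customary heatmap defaults, delegated to
`stats::hclust()`; the dendrogram exports as Newick. Tissue preference is
the argmax tissue of the z-profile when that z reaches `min_z = 1.5`
(ties and sub-threshold maxima yield no call). The threshold is an
operationalization of preference labels that were originally assigned
qualitatively from heatmaps; it is configurable and recorded in outputs.
Note a geometric constraint: with *t* tissues a one-hot profile peaks at
z = √(t−1), so preference calls need t ≥ 4 tissues to clear 1.5 — with
three tissues the ceiling is √2.

Within a tandem array, preferences classify the array as `divergent`
(≥ 2 members prefer different tissues), `concordant` (≥ 2 share the one
preferred tissue), `untranscribed` (no member has a preference) or
`indeterminate` (exactly one does).

## The simulator: what it emulates, and what it does not

`simulate_ancestor()` lays out uniform gene lengths (500–5,000 bp) and
intergenic gaps (200–2,000 bp); nothing downstream depends on base-pair
geometry beyond order, so simple distributions suffice. WGD
(`apply_wgd()`) duplicates every chromosome and retains each duplicated
copy independently with the given probability — fractionation bias between
subgenomes is not modelled, because the detection signal consumed
downstream (collinear blocks of retained pairs) does not require it.
Tandem events insert adjacent copies downstream of spaced source genes;
spacing (≥ 2 intervening genes between sources) guarantees distinct
ground-truth arrays never abut, so exact round-trip recovery is a
well-posed property. Domain-hit decoys fail *exactly one* of the two
filter criteria, exercising both branches; spurious homology e-values
straddle the 0.01 threshold. All generators take explicit seeds, restore
the caller's RNG state, and are bit-reproducible.

The simulator does not generate sequences, model selection or dating, or
produce phylogeny-aware ortholog structure. Consequently, passing
round-trip tests shows the detectors are correct with respect to the
stated definitions — not that those definitions capture every ambiguity of
real genomes (fragmented assemblies, nested duplications, allopolyploid
subgenome mixing).

## Problem sizes and numerical choices

Test and acceptance runs use: 200 random ≤ 12-anchor instances for the
chaining oracle; 500-gene genomes with 20 tandem events and 400-gene
chromosome sets at WGD retention 0.6 / 1.0 for round trips; a 1,000-gene,
4-chromosome genome with blocks covering exactly half the positions for
null calibration (500 experiments × 500 replicates; planted enrichment at
2,000 replicates); 90 genes × 6 tissues with a 10-sigma effect for
cluster recovery. These sizes keep every property sharply testable while
the whole suite runs in seconds. Floating-point comparisons use 1e-9
tolerances; percentage reporting rounds half away from zero (so 38.75
prints as 38.8), with per-quantity decimals.

## Interface decision

The package is an analysis toolkit driven from R: the exported functions,
the test suite and `scripts/acceptance.R` are the interface. A shell CLI
would add a dependency surface without adding capability; the writers
(`write_gff3()`, `write_blast_tab()`, `write_blocks_tsv()`,
`write_aligncoords()`, `write_arrays_bed()`, `write_summary()`,
`write_permutation_json()`) produce the standard text formats a
command-line ecosystem would consume.

## Known limitations

* The chainer's greedy chain extraction is optimal per chain but not
  globally across overlapping chain sets (the standard trade-off).
* The tandem null's positional-run approximation slightly inflates null
  array formation; enrichment p-values are therefore conservative.
* Distinct vs multiplicity counting can differ materially when blocks
  overlap heavily; both are computed, and reports state which was used.
* Expression preference is a single-threshold call; soft assignments or
  specificity indices (e.g. tau) are out of scope.
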