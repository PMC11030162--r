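---
title: "Methods: models, parameters and design choices in fbmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in fbmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbmeta)
```

`fbmeta` is a downstream pipeline for paired metagenome (MG) and
metatranscriptome (MT) gene tables from fungal fruiting bodies. This
vignette explains the statistical procedures, the tunable parameters and the
places where the design was genuinely open, so a reader can judge what a
green test suite does — and does not — establish.

## Quantification

All abundances are transcripts per kilobase million:

$$\mathrm{TPM}_i = \frac{c_i / L_i}{\sum_j c_j / L_j} \times 10^6$$

with counts $c$ and gene lengths $L$ in bp. Because the length enters only
as a ratio, converting to kilobases cancels; the implementation therefore
consumes bp directly and a regression test asserts that introducing a
$\times 1000$ factor anywhere would break the worked two-gene example
(counts 10,10 at 1000 and 2000 bp give 666666.67 / 333333.33). TPM is
computed over *all* predicted genes; taxonomic or functional filters apply
downstream. This was an open choice — the alternative, excluding
unassigned genes before normalization, changes every share — and the
all-genes convention was picked because it keeps one denominator per sample
across every analysis.

A sample with zero total counts keeps an all-zero row and raises a warning
rather than an error: dropout samples should stay visible in reports.

## KO adjudication and presence

KOfam-style rows are kept when `score > threshold` and `evalue < 1e-5`
(strict inequalities on both sides). A gene receives at most one KO: best
score, then lowest e-value, then the lexicographically smallest KO id. One
KO per gene keeps module evaluation unambiguous; multi-label assignment
would require a weighting convention that nothing downstream needs. A KO is
*present* in a sample when at least one in-scope gene carrying it has
TPM strictly greater than 0.

## Best-hit taxonomy

Each gene takes the lineage of its maximal-bitscore hit. Bitscore ties are
broken by lower e-value and then lexicographically smaller subject id —
the tie-break is not part of the method being reproduced, but BLAST output
order is unstable across runs and a deterministic rule is required for
byte-identical reruns. No lowest-common-ancestor computation is done on
near-ties: strict best hit only. Lineages are reported at family rank or
higher; requesting genus-level aggregation is an error by design, because
metagenomic best hits below the family rank are not trustworthy.

Genes whose lineage is truncated above the requested rank roll up to
`unclassified <nearest higher rank>`; genes with no hit become
`unassigned`. Aggregation conserves mass exactly, and the "Below 1%"
grouping merges taxa (or CAZyme targets) whose share of the *total* profile
mass — pseudo-categories included in the denominator — falls under the
threshold. `unassigned` itself is never merged: it is a statement about the
database, not a rare taxon.

## Sample status classification

Distances are Euclidean on the full-gene MG TPM matrix. Whether distances
should be computed on all genes or on a taxon-aggregated profile was open;
all genes is the default (an `aggregate_by_rank()` call can be interposed)
because aggregation discards the within-taxon signal that separates
conditions when taxon composition is similar.

PCA is the column-centered SVD (`prcomp`, no scaling). Component signs are
fixed so each loading vector's largest-magnitude entry is positive —
otherwise scores flip between BLAS builds.

Clustering is agglomerative Ward on unsquared Euclidean distances (the
`ward.D2` convention; the update rule squares internally). `k` is fixed at
2: the biological question is binary (healthy vs rotten), and automatic
model selection on ten samples mostly measures noise.

Bootstrap support resamples *gene columns* with replacement — at
$n \approx 10$ samples a sample-level bootstrap is degenerate. Each original
internal cluster scores 1 in an iteration when its exact leaf set appears
among the bootstrap dendrogram's internal nodes; support is the mean over
(default) 1000 iterations. Exact leaf-set matching is the simplest
well-defined notion of cluster identity. Columns are sorted by gene id
before resampling so support is invariant to input column order for a fixed
seed.

The final status rule generalizes a case-by-case narrative into thresholds,
which is why all four are exposed in configuration:

| parameter | default | meaning |
|---|---|---|
| `mg_low` | 0.01 | MG focal share below this: unambiguously rotten-like |
| `mg_high` | 0.50 | MG focal share at/above this: unambiguously healthy-like |
| `mt_rescue` | 0.10 | MT focal share that rescues an intermediate sample |
| `min_reads` | 3500 | MT library size below which the MT layer is unusable |

Precedence: (1) MT layers under `min_reads` are excluded from evidence;
(2) samples with MG focal share in `[mg_low, mg_high)` are decided by the
MT rescue rule (healthy iff MT focal share ≥ `mt_rescue`; with no usable MT
layer the sample is called rotten and tagged `excluded_low_reads`);
(3) everything else takes the majority putative label of its k = 2 cluster.
A within-cluster majority tie breaks toward healthy for the cluster with
the higher mean MG focal share. An intermediate sample without MT evidence
defaults to rotten rather than to its cluster because a fruiting body that
has lost most of its fungal DNA and shows no fungal transcription has, on
the available evidence, died — the cluster assignment at that composition
mostly reflects the bacterial background.

## KEGG module logic

DEFINITION strings are parsed with a recursive-descent parser over the
grammar: space separates AND-ed steps (weakest binder), `,` separates OR
alternatives, `+` joins obligatory complex subunits (tightest binder), `-`
prefixes an optional component, `--` is a wildcard step, parentheses group.
Whitespace is semantically significant: `K1 -K2` is an optional *step*,
`K1-K2` an optional *subunit*. Operator precedence (`+` > `,` > space) is
the standard KEGG convention; it is fixed here explicitly because changing
it changes completeness verdicts.

Completeness of a module against a present-KO set: leaves test membership,
AND/complex nodes need all children, OR nodes need one, optional nodes are
always satisfied. `satisfied_fraction` is the satisfied share of
*non-optional top-level steps* — optional subunits cannot block a pathway,
so they must not dilute the fraction either. `missing_kos` is the
minimal-cardinality completion, choosing the cheapest OR branch with
lexicographic tie-breaks for deterministic reports.

The `--` wildcard defaults to *satisfied* (KEGG uses it for steps with no
KO assigned, which cannot be tested from annotation data), with a switch to
count it unsatisfiable; under that switch a blocked module reports
`missing_kos = NA` since no KO addition can complete it. Both semantics are
offered because published completeness claims are generally not
reproducible without knowing which convention was used.

Community screening restricts to genes of superkingdom Bacteria, evaluates
per condition group (pooled presence across the group's samples) and,
per family, only for families contributing more than 1% of the bacterial
TPM. Per-group pooling was an open choice (per-sample and fully pooled are
both available through the `groups` argument); groups match how such
results are usually reported — one verdict per condition.

## CAZyme substrate profiling

The CAZy-family → substrate-target map is an explicit, editable TSV
resource (`inst/extdata/substrate_map.tsv`), not hidden code, and the md5
checksum of the map actually used is attached to every profile and recorded
in the run manifest. Unmapped families resolve to `unknown`; subfamily
labels (`GH5_5`) fall back to their base family.

A gene annotated with families mapping to several distinct targets has its
TPM divided *equally* among them. The alternative — counting the gene fully
under each target — double-counts mass; equal splitting keeps the profile
summing exactly to the sample's CAZyme TPM, which is the invariant every
aggregation here maintains.

Origin is `focal` iff the best-hit lineage matches the focal taxon at its
native ranks (default `family = Polyporaceae, genus = Fomes`), not merely
the same family: the contrast of interest is the focal organism against
everything else, including relatives. Share tables normalize over
*CAZyme TPM only* (not total sample TPM); the choice is recorded in the
output's `denominator` attribute.

## The synthetic community

The generator is a stated world, not a tuning dial. Defaults:

* one focal fungal lineage (Polyporaceae/Fomes) at **0.80** of expected
  healthy-MG reads and **0.001** of rotten-MG reads;
* 28 non-focal families (proteobacterial/actinobacterial families dominating
  the rotten community, a small Ascomycota contingent, beetle and mite
  families, one slime mould, one unassigned pseudo-family) with fixed
  per-condition mass weights;
* gene lengths log-normal (median 1 kb, log-sd 0.6) clipped to
  [150, 30000] bp; within-family gene weights log-normal;
* counts Dirichlet-multinomial at depth 1e5: gene probabilities proportional
  to family share × gene length × weight, perturbed by a Dirichlet draw with
  overdispersion 0.001 (concentration 1000). This value follows from the
  stated world itself: healthy samples are specified to sit within ±0.05 of
  the 0.80 focal share at depth 1e5, which bounds the admissible
  overdispersion (at concentration 100 the focal-share sd alone is ~0.04);
* nitrogenase KOs (K02588/K02586/K02591) blacklisted, with the
  nitrogen-fixation module nevertheless *planted* in one family — lifting
  the blacklist is the designed completeness flip;
* the denitrification KO set split across two families: community-complete,
  family-incomplete everywhere;
* arthropod chitinases GH18 at 13/1/1 genes in Tenebrionidae, Cerambycidae
  and Pyroglyphidae, plus beta-glucanases (GH16) in mites, beetles,
  actinobacteria and ascomycete families;
* rotten metatranscriptomes put 0.5 of reads on unassignable genes (a free
  choice — the source situation only states that most rotten transcription
  is unassigned), boost arthropod family shares ×15 and concentrate ×50 of
  each arthropod family's transcription on its CAZyme genes, so the
  decomposer fauna carries the majority of rotten CAZyme expression;
  healthy metatranscriptomes boost focal CAZyme expression ×5 and damp
  non-focal CAZyme expression ×0.2.

What the generator does *not* emulate: real sequence content (FASTA records
are random nucleotides of the right length), strain-level variation,
compositional correlations between families, length biases of assembly, or
database incompleteness beyond a single unassigned pool. A green
classification-recovery test therefore establishes that the pipeline
recovers a *large, planted* compositional contrast under realistic counting
noise — not that it would resolve subtle field gradients.

`make_transitional()` rewrites one sample with independent MG and MT focal
shares over the rotten background community — the construction used to test
the MT rescue rule in both directions.

## Numerical conventions

* TPM rows with any signal sum to 1e6 within 1e-9 relative; all-zero rows
  stay zero.
* Mass-conservation checks through aggregation and grouping use 1e-6
  relative tolerance.
* All RNG flows from one root seed; pipeline stages derive sub-seeds by
  fixed small offsets, and derived seeds stay below 2^31.
* Merge order in `hclust` and all tie-breaks (KO ids, subject ids, OR
  branches) are deterministic, so identical config + seed reproduce
  byte-identical output TSVs (the run manifest records md5 checksums to
  prove it).

## Known limitations

* The packaged KEGG module file is a curated offline stand-in written from
  the DEFINITION grammar (real module accessions, approximate definitions);
  swap in a real flat file via the `modules` config field for production
  use.
* The substrate map covers the major fungal-cell-wall and plant-cell-wall
  targets only; anything else reports `unknown`.
* Bootstrap support uses exact leaf-set identity; it does not credit
  near-matches, so support values are conservative for large, loose
  clusters.
* Module completeness is boolean per KO presence; it ignores abundance and
  cannot distinguish one organism carrying a pathway from a patchwork of
  partial carriers except through the per-family screen.
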