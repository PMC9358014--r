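---
title: "Methods: sex-determining region delineation and karyotype inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-determining region delineation and karyotype inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoregion)
```

This vignette documents the statistical procedures the package
implements, the assumptions behind them, the tunable parameters, what
the synthetic-data generators do and do not emulate, and the design
choices made where the methodology was genuinely open.

## 1. Evidence model and region delineation

The input to the delineation stage is a set of *evidence markers*: items
of heterogeneous provenance (sex-association QTLs mapped back to the
assembly, male-specific reduced-representation tags, male-specific
SSR/SCAR markers) each reduced to a class label and a genomic interval.
Point markers are 1 bp intervals; all coordinates are 0-based half-open
internally, BED in/out is 0-based half-open, GFF3 is 1-based closed, and
Mb figures are rounded half-up to two decimals only at the reporting
layer.

**Sex-chromosome prediction** (`majority_chromosome`) is by evidence
share: the chromosome carrying the most markers. Under an XX/XY system
with suppressed recombination around the sex locus, male-specific
markers co-localize on the X-homologous region, so a clear majority is
expected; an exact tie is reported as an error rather than resolved
arbitrarily.

**Per-class windows** (`minimal_covering_window`). The rule "the region
containing more than 90% of the segments" is operationalized as the
*shortest* window that fully contains at least ⌈f·n⌉ of the n markers of
one class on the majority chromosome, with f = 0.9 by default. A marker
counts only when its whole interval lies inside the window; markers with
identical positions count as distinct segments; strand is ignored.
The scan sorts candidate window ends and, for each end, takes the k-th
largest start among markers ending at or before it — the tightest
feasible window with that end — in O(n²) worst case, which is ample at
evidence scale (hundreds of markers). Among equal-length optima the
leftmost is returned, a deterministic tie-break. This minimal-window
reading is a declared interpretation: a visual-clustering choice would
be under-specified, while minimality is the unique parsimony-consistent
rule, and it is verified against an exhaustive-enumeration oracle in the
tests. Exact published window endpoints are therefore not claimed to be
recoverable from raw positions, only the rule's behaviour.

**Integration** (`integrate_evidence`) is the *bounding hull* — the
smallest single interval containing every per-class window and every
point marker — not the intersection. The hull is forced by the printed
behaviour of the analysis this package operationalizes, where the final
region equals the widest input window. Classes with fewer than
`min_class_n = 5` markers contribute their raw segments rather than a
window (a 90% rule on one or two markers is vacuous).

**Gene extraction** (`genes_in_region`) intersects gene models with the
region via `GenomicRanges::findOverlaps`, by ≥ 1 bp overlap by default
or full containment on request.

## 2. The QTL stand-in

Full interval mapping (MapQTL-style mixture models) is out of scope; the
package ships a desk-scale stand-in for a binary trait in an F1 family.
For one biallelic marker against sex, `binary_trait_lod` computes

* LOD = log10 of the likelihood ratio of the saturated 2×2 multinomial
  model against independence, i.e. G²/(2 ln 10);
* PVE = 100 · φ², the squared point-biserial correlation between 0/1
  genotype and sex codes.

This reproduces the operative semantics of "PVE = 100%": the marker
perfectly predicts sex in the family. Monomorphic markers are flagged,
not scored. Thresholds are configuration inputs (defaults 5.2
chromosome-wide and 7.0 genome-wide); an optional permutation routine
(`permutation_lod_threshold`, 1,000 label shuffles, 95th percentile) is
provided but off by default, since the fixed thresholds are part of the
study conditions. cM spans are reported to two decimals.

## 3. Candidate screening

`concordant_degs` intersects the two DEG tables (male vs female, male vs
pseudofemale) within the region gene set and keeps genes with the same
fold-change sign in both contrasts. The pseudofemale contrast separates
genetic from phenotypic sex: a gene tracking genetic sex keeps its
direction when genetic males are phenotypically female. Intersection is
restricted to region genes — whether the published analysis restricted
the second contrast before intersecting is implicit, and restricting is
the conservative reading. A fold-change of exactly 0 is ambiguous and
excluded.

GO terms are compared at the level supplied in the annotation (no
ontology traversal): a term is *sex-specific* when its concordant member
genes are unanimous in direction. Sex-related KEGG pathways are a
shipped, editable vocabulary (`sex_related_pathways()`, sixteen
pathways from TGF-beta signaling to cell cycle). Because the published
integration of GO and KEGG evidence into a final candidate list is not
fully specified (known candidate tables include genes with no
sex-related pathway), `select_candidates` exposes the rule —
`union` (default), `go_only`, `kegg_only` or an explicit `manual` list —
and always reports both component sets rather than guessing a single
irreproducible rule.

## 4. Synteny relationships and karyotype inference

`classify_relationships` aggregates alignment blocks per chromosome
pair. A partner chromosome is kept when its total aligned length reaches
`min_coverage` (default 0.2) of the shorter chromosome, counting only
blocks of at least `min_block_bp` (default 50 kb). The coverage filter
suppresses repeat-driven noise blocks; published analyses report only
the resulting labels, not a threshold, so both knobs are explicit
parameters. Labels follow partner multiplicity in both directions:
`one-to-one`, `one-to-two` (a fused chromosome), `two-to-one` (a
fissioned ancestral chromosome), `one-to-many` for more entangled
subgraphs, `unassigned` when nothing survives.

`find_evolution_clusters` takes connected components of the
(species, chromosome) homology graph; a component is an *evolution
cluster* only if it contains a non-bijective edge — pure one-to-one
chains are conserved groups and are reported separately. `infer_events`
is count-parsimony at cluster granularity against a designated ancestral
species: k fewer chromosomes than the ancestor ⇒ k fusions, k more ⇒ k
fissions. A species with an *equal* count but a non-bijective direct
relationship to the ancestral chromosomes is recorded as one fission
plus one fusion (a count-neutral rearrangement, e.g. a segment of an
ancestral chromosome splitting off and fusing elsewhere). When a species
has no direct synteny evidence against the ancestor inside the cluster —
as happens when only one species' pairwise comparisons are available and
homology is mediated through it — the count-neutral case cannot be
distinguished from conservation and is reported as no events; every
inferred chromosome number is unaffected, because count-neutral events
cancel by construction. No breakpoint-level reconstruction is attempted,
and Robertsonian versus tandem fusions are not discriminated.

`karyotype_inference` sums events over clusters:
n_inferred = n_ancestral − Σ fusions + Σ fissions. The ancestral species
and its haploid number are user inputs (the shipped catfish encoding
uses the Ictaluridae-like karyotype, n = 29); an optional `proto_n`
(e.g. 25) is reporting-only metadata for the trajectory string and is
never inferred.

The shipped `catfish_relationship_edges()` table encodes the published
pairwise relationships between *P. ussuriensis* and four other catfish
genomes. Only the non-bijective relationships are enumerated
chromosome-by-chromosome in the source material; the one-to-one edges
needed to complete the four cluster memberships are inferred from the
printed memberships, and one-to-one pairs outside the clusters are
omitted (they form no cluster by definition).

## 5. The synthetic-data generators

The generators produce every input with planted structure at the study's
own scale, under one root seed with fixed per-generator substream
offsets (adding a generator never perturbs another's output; identical
seed and configuration give byte-identical files).

* **Assembly**: the 26 chromosome lengths of the reference chromosome
  table (total 722.22 Mb) by default; optional random FASTA at a target
  GC fraction.
* **Evidence**: per class, exactly round(f·n) markers uniform inside the
  planted 6.90–23.73 Mb chr08 region and the rest uniform over the other
  chromosomes, so containment *on the sex chromosome* equals the
  configured fraction exactly (default 0.963, the tag-class figure) and
  the 90% rule's denominator is unambiguous. Default class sizes: 57
  QTLs, 326 tags, 1 SSR, 1 SCAR.
* **F1 genotypes**: a male-heterogametic family (female-heterogametic by
  flag), 100 offspring × 200 markers on a 108.52 cM group by default —
  the mapping-family design behind the original linkage map is not
  public, so this is a declared, realistic simplification. One marker is
  perfectly sex-linked; elsewhere the genotype flips from the sex-locus
  genotype with the Haldane recombination fraction
  r = (1 − e^(−2d/100))/2 of the cM distance d. Sexes are balanced to
  within one.
* **DEG tables**: category counts (concordant male/female, discordant,
  single-contrast per side) are realized exactly; defaults reproduce the
  181 → 150 → 135 (65/70) cascade with the 85/96 male/female split of
  the first contrast.
* **Synteny blocks**: the configured assembly acts as the ancestral
  karyotype; each derived species' fusion/fission events are applied
  sequentially and every resulting chromosome is tiled into 1 Mb blocks
  (sub-Mb remainders attach to the last tile), each block's two spans of
  equal length.

What the generators do *not* emulate: mapping error and genotyping
noise, marker clustering from local recombination suppression beyond the
planted containment, expression variance (DEG calls are taken as given),
inversions/translocations and block orientation, and repeat-driven
spurious alignments. Passing tests therefore demonstrate correctness of
the inference rules under their stated assumptions, not robustness to
every artefact of real data.

## 6. Numerical choices and degenerate inputs

* Half-up rounding (`round_half_up`) for all printed Mb, cM and
  percentage values, matching report conventions; an ulp-scale epsilon
  guards values stored just below a .5 boundary.
* Nx/Lx use the "first cumulative sum ≥ x% of total on descending
  lengths" convention; verified against a brute-force oracle.
* Ties: leftmost minimal window; chromosome-name order for density
  extremes; majority ties and mixed-chromosome integration are errors,
  not silent choices.
* Degenerate inputs (empty QTL tables, empty histories, single markers,
  zero DEG specs, all-bijective graphs) return well-defined empty or
  identity results and are covered by tests.

## 7. Problem sizes used by the test suite

The suite exercises the oracle comparisons at 500 random window
instances (n ≤ 30), 200–1,000 random length lists for assembly
statistics, 150 random graphs against a union-find oracle, 100 seeded
delineation replicates (planted chromosome recovered in all of them),
and 10–20 seeded synteny histories — sizes chosen to give the
property-based arguments real coverage while keeping a full run of the
suite around a minute.

## 8. Known limitations

* The LOD/PVE stand-in is a single-marker association score, not
  interval mapping; it matches the published screen's semantics at
  PVE = 100 but does not reproduce its LOD magnitudes.
* The minimal-window rule is an interpretation of an under-specified
  procedure; endpoints are reproducible only under that rule.
* Candidate selection exposes rules rather than reproducing an unstated
  one; the shipped pathway vocabulary is editable and deliberately
  small.
* Event inference is count-level; histories that cancel within a
  cluster (equal counts, no direct ancestral evidence) are reported
  conservatively as no events.
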