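---
title: "Applying the common cell type nomenclature with ccntax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Applying the common cell type nomenclature with ccntax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccntax)
```

## The model

A *taxonomy* is the output of one classification algorithm applied to one
dataset: a set of quantitatively derived clusters, usually organized as a
dendrogram whose terminal leaves are the *provisional cell types* and whose
internal nodes are groups of types with similar profiles. The nomenclature
layer adds no analysis on top of the clustering; it assigns stable,
machine-resolvable identity to every nameable group of cells so that
taxonomies from different labs, species, and modalities can be tracked and
linked.

The identity model has three tiers:

* **Taxonomy id** `CCN[YYYYMMDD][#]` — date of minting plus a same-day
  index. The index is a non-negative integer starting at 0; single digit in
  every id we have seen in the wild, but the grammar deliberately permits
  more digits, so `parse_taxonomy_id()` accepts them.
* **Cell set accession** `CS[YYYYMMDD][#]_[n]` — globally unique; the date
  and index digits always equal the owning taxonomy's, and `n` is a 1-based
  unpadded integer that is never reused, even if a cell set is later
  removed. Accessions are permanent tags, so `add_cell_set()` always
  extends by max + 1.
* **Cell set label** `<prefix> <numerals>` — the within-taxonomy membership
  language. A composite set's label compacts the numerals of its member
  leaves into range notation (`MTG 001-006`), which is what lets a label be
  *expanded* back into exactly its member provisional types, and what lets
  an alias like `"RNA-seq 040 in CCN201912131"` act as a machine-readable
  cross-taxonomy reference.

Each cell set additionally carries at most one preferred alias, at most one
aligned alias, any number of additional aliases, an anatomical structure
with an ontology CURIE, and alias provenance. Provenance (assignee,
citation) is stored per cell set, matching the columns of the published
nomenclature tables; an edit that changes an alias is expected to update
the provenance columns in the same row.

## Deriving cell sets

`build_taxonomy()` numbers leaves `1..L` in left-to-right dendrogram order
and internal nodes `L+1, ...` in depth-first pre-order. The published
examples fix only that leaves occupy the low numerals (the six-type node is
`MTG 001-006`, and a metadata set in a 75-leaf taxonomy has accession
number 154, far above the leaf count); the pre-order choice among internal
nodes is this package's own, made for determinism: two runs on the same
dendrogram must mint identical tables. Leaves keep their original cluster
name as preferred alias; internal nodes start blank, because a group of
types usually has no publication name until a curator gives it one.

Taxonomies without a dendrogram (non-hierarchical community structure,
morpho-electric panels) bypass the tree entirely: `build_taxonomy(types =
...)` makes leaf-only taxonomies, and composite sets are declared directly
through label expressions with `add_cell_set()`.

Membership of metadata cell sets (e.g. "all nuclei from neurosurgical
tissue") cannot be encoded in a label over leaf numerals. It is stored as a
predicate on the cell metadata table — `column == value` or an explicit
cell-id list — on the in-memory taxonomy. The fixed-column nomenclature CSV
cannot carry predicates, so they must be re-supplied after re-reading a
table; the CSV still records the set itself (`Metadata 1`, `Metadata 2`,
... with a running numeral).

## File formats and numerical conventions

* **Range separator.** Print typography uses an en dash (`001–006`);
  machine output uses ASCII hyphen-minus for CSV portability, and all
  parsers accept hyphen, en dash, and em dash.
* **Zero padding.** Published labels pad inconsistently (`MTG 001`, but
  `DNAm 12`, `ATAC-seq 08`). Padding is a per-taxonomy setting
  (`pad_width`, default 3); parsing is padding-agnostic and retains the
  observed width so that re-rendering reproduces the input.
* **Canonical JSON.** The annotated dendrogram is written with sorted keys,
  two-space indentation, and explicit `children` arrays, making read/write
  round trips byte-identical — important because the annotated tree is
  itself an archival output. A JSON-Schema document ships in
  `inst/extdata/dendrogram.schema.json`. Trees need not be binary; internal
  nodes require at least two children, and unary chains are rejected.
* **Edits semantics.** The manual annotation round trip is
  spreadsheet-mediated, so the edits table needs an explicit clear token: a
  blank cell means "leave unchanged", the literal `-` means "clear".
  Without this, a curator could never blank a field through a CSV. Reading
  tolerates a UTF-8 byte order mark and unknown extra columns (warned,
  dropped).
* **Membership matrix.** Binary calls, one row per cell, one column per
  cell set in accession-number order (the printed tables do not fix a
  column order; accession order is the deterministic choice). Leaf columns
  partition the cells, so each row sums to 1 over leaves and a composite
  column equals the max over its member leaf columns. The probabilistic
  variant (`map_cell_probabilities()`) keeps only the value contract:
  per-cell leaf probabilities sum to at most 1, and a composite's value is
  the clipped sum of its member leaves — the natural union measure for a
  partition. How such probabilities are estimated is out of scope.
* **Unclassified cells** are rejected by default; `keep_unmapped = TRUE`
  gives them all-zero rows instead, which keeps the row invariant
  restricted to classified cells.

## The aligned-alias grammar

Aligned aliases are the cross-taxonomy naming currency, so their grammar is
enforced rather than advisory: `[Layer] [Projection] #` for glutamatergic
types, `[Canonical gene(s)] #` for GABAergic, `[Cell class] #` for
non-neuronal, `[Historical name] #` for any class. The trailing ordinal is
optional (`Sst Chodl` has none). Published usage mixes `L6 CT_1` and
`L2/3 IT 4`; both are accepted and the canonical form uses a space. Gene
tokens match case-insensitively (mouse `Pvalb` vs human `PVALB`) but
canonicalize to the vocabulary's casing, so exact-string alias matching
across species-mixed registries behaves sensibly. The vocabulary is a JSON
config, not code — the convention is explicitly a starting point — and the
bundled file includes the projection alias map (`CF` → `ET`). Grammar
enforcement during annotation is opt-in (`strict_aligned`), since curators
legitimately stage drafts that fail it; the default is a warning.

## Cross-taxonomy linking

`build_link_graph()` joins cell sets across taxonomies by three kinds of
evidence, kept as typed edges so the user can weigh them:

* `alias` — identical non-empty aligned alias after whitespace
  normalization. Matching is exact by design: fuzzy matching would silently
  conflate `L6 CT 1` and `L6 CT_1` exactly when the curator has chosen not
  to canonicalize them.
* `reference` — a parsed additional alias of the form
  `<labels> in <taxonomy id>`. References resolve to the cell sets whose
  labels cover exactly the referenced numerals; a reference to a subset of
  a composite's span links the leaf sets, never the composite, because the
  reference names types, not groupings. References to taxonomies or labels
  not in the registry are skipped rather than fatal, so excerpt registries
  stay usable; whether a many-label reference means "matched" or merely
  "overlapping" is left to the reader — the graph records the edge, not an
  interpretation.
* `co_cell` (optional) — identical member cell-id sets across taxonomies
  over the same dataset, supplied externally.

Within-taxonomy alias duplication never creates an edge. Connected
components of the graph are the practical unit of interpretation ("all
cell sets associated with this type"), reported by `link_components()`.
`transfer_aligned_aliases()` copies aliases from a reference taxonomy along
an externally supplied correspondence and logs the provenance; it performs
no alignment itself.

## What the simulator models — and what it does not

`simulate_taxonomy()` generates the *structure* the workflow consumes: a
random tree over `n` provisional types (recursive random splits of the
ordered leaf range, optionally multifurcating up to a branching cap),
publication-style leaf names, and a cell table with per-leaf counts
(Poisson with a floor of one cell, or constant) and a `tissue` column
(neurosurgical fraction 0.1 by default, echoing the minority tissue class
in human cortical datasets). Everything is deterministic under a seed, and
the generator restores the caller's RNG state.

It does **not** model gene expression, doublets, ambiguous cluster
boundaries, or label noise. Passing tests therefore demonstrate that the
nomenclature machinery is correct on well-formed classifications — they say
nothing about the quality of any upstream clustering, which the
nomenclature deliberately treats as given.

Test and example problem sizes are the package's own choices, sized to the
scale of the published examples they mirror: 75-leaf trees with ~200 cells
per type for the MTG-shaped checks, 6-leaf/60-cell fixtures for membership
arithmetic, 100 random trees and ≥1000 random identifiers for the
round-trip property suites.

## Known limitations

* Uniqueness of taxonomy ids is checked locally (within a registry); the
  global uniqueness the convention ultimately wants requires a public
  registry service, which is a database problem, not a library one.
* The fixed nomenclature CSV cannot express metadata-set predicates (see
  above) or per-alias provenance beyond the assignee/citation pair.
* The cortical vocabulary ships with a defensible but small token set;
  non-cortical tissues need their own config.
* Dendrogram input must match the documented JSON schema; converters from
  other serializations (e.g. R `hclust`/`dendrogram` objects) are a thin
  exercise left to the caller via `dend_node()`.
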