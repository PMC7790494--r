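# ccntax

Common Cell Type Nomenclature (CCN) tooling for cell type taxonomies.

Single-cell and single-nucleus profiling produce cell type classifications
("taxonomies") at a pace that has outrun any naming convention: clusters get
ad hoc names like `Interneuron 1` or long marker-gene chains, and matching a
type in one study to a type in another is manual archaeology. The CCN
addresses this the way genomics handles transcripts across genome builds:
every taxonomy gets a permanent **taxonomy id** (`CCN[YYYYMMDD][#]`), every
**cell set** within it — a provisional cell type (a leaf of the taxonomy's
dendrogram), a group of types (an internal node or a custom union), or a
metadata-defined group — gets a globally unique **accession id**
(`CS[YYYYMMDD][#]_[number within taxonomy]`), a machine-readable **label**
in range notation over the leaf numerals it contains (`MTG 001-006`), and a
small set of curated descriptors: at most one **preferred alias** (the
publication name), at most one **aligned alias** (a controlled-vocabulary
name shared by matched cell sets across taxonomies, analogous to a gene
symbol), any number of additional aliases, an anatomical structure with its
UBERON ontology tag, and alias provenance (assignee, citation).

`ccntax` implements the full workflow for R, for anyone publishing or
curating a cell type classification:

* mint and validate the identifier grammars;
* derive cell sets from a dendrogram (JSON) or a flat cluster list, and
  emit the standard outputs — the nomenclature table (CSV), the annotated
  dendrogram (canonical JSON), and the cell × cell-set membership matrix;
* round-trip manual annotation through an editable CSV;
* validate aligned aliases against the cortical naming grammar
  (`[Layer] [Projection] #`, `[Canonical gene(s)] #`, `[Cell class] #`,
  `[Historical name] #`);
* link cell sets across taxonomies through shared aligned aliases and
  parsed cross-taxonomy label references (`"RNA-seq 040 in CCN201912131"`),
  reported as connected components of a link graph;
* simulate seeded synthetic taxonomies and cell tables for testing.

Computational cell set *alignment* is deliberately out of scope: the CCN
records the outcome of an upstream alignment, it does not perform one.

## Worked example

```r
library(ccntax)

# upstream inputs: a clustering result and the cell table (simulated here)
sim <- simulate_taxonomy(6, cells_per_leaf = 10, cells_dist = "constant",
                         seed = 2)

# taxonomy-wide defaults, then derivation of all cell sets
d   <- ccn_defaults("CCN201908210", assignee = "Trygve Bakken",
                    citation = "10.1038/s41586-019-1506-7",
                    structure = "middle temporal gyrus",
                    ontology_tag = "UBERON:0002771", prefix = "MTG")
tax <- build_taxonomy(d, sim$root)
tax
#> <ccn taxonomy> CCN201908210: 11 cell sets (6 leaf, 5 node, 0 custom, 0 metadata)

validate_taxonomy(tax)          # zero rows: all invariants hold
expand_label("MTG 001-006")
#> [1] "MTG 001" "MTG 002" "MTG 003" "MTG 004" "MTG 005" "MTG 006"

# metadata cell set + the membership matrix
tax <- add_cell_set(tax, kind = "metadata", preferred_alias = "Neurosurgical",
                    predicate = list(column = "tissue",
                                     value = "neurosurgical"))
m <- map_cells(tax, sim$cells)
dim(m)                          # 60 cells x 12 cell sets
sum(m[, "CS201908210_7"])       # the six-leaf union column: all 60 cells
#> [1] 60
```

Every cell scores 1 in its own leaf column, in every node column whose
label covers that leaf's numeral, and in each metadata column whose
predicate it satisfies; leaf columns sum to exactly 1 per cell.

Cross-taxonomy linking, on the bundled records of the Sst Chodl
interneuron class (rare long-range-projecting cortical interneurons traced
across eight taxonomies and three modalities):

```r
reg <- read_cell_set_records(system.file("extdata",
          "sst_chodl_cell_sets.csv", package = "ccntax"))
g <- build_link_graph(reg)
igraph::components(g)$no
#> [1] 1                         # all eight records form one component
```

The same steps are available from a shell via the thin wrapper:

```sh
CCN=$(Rscript -e 'cat(system.file("cli", "ccn.R", package = "ccntax"))')
Rscript $CCN build --dendrogram dend.json --taxonomy-id CCN202001010 \
    --prefix MTG --structure "middle temporal gyrus" \
    --ontology-tag UBERON:0002771 --out-dir out
#> [INFO] built CCN202001010: 6 leaves, 5 nodes, 11 cell sets
```

Commands: `build`, `annotate`, `map`, `validate`, `crosslink`, `simulate`;
exit codes 0 (ok), 1 (validation failure), 2 (usage error).

## Package layout

* `R/` — identifier/label grammars, dendrogram IO, taxonomy builder,
  annotation round trip, cell mapping, aligned-alias grammar, cross-taxonomy
  linking, simulator, CLI.
* `inst/extdata/` — cortical vocabulary config, dendrogram JSON-Schema, and
  the transcribed published records used as examples.
* `vignettes/ccn-workflow.Rmd` — the methods vignette: model, conventions,
  design choices, limitations.
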