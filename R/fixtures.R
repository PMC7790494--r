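# Synthetic study generators and bundled worked examples.
#
# simulate_taxonomy() emulates the inputs the nomenclature workflow
# assumes exist upstream: a hierarchical clustering result (random tree
# over provisional cell types with publication-style names) and a cell
# metadata table (one row per cell, cluster assignment, tissue metadata).
# It models taxonomy *structure* only — no gene expression.

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a cell type taxonomy and its cell metadata
#'
#' Generates a random tree with `n_leaves` provisional cell types by
#' recursive random splits of the ordered leaf range (so leaf order is
#' 1..n by construction), assigns each leaf a publication-style name
#' (class, layers, marker gene), and draws cells per leaf with the chosen
#' count distribution. Cells carry a `tissue` metadata column
#' (postmortem / neurosurgical) so that metadata cell sets can be
#' exercised. Fully deterministic for a fixed seed.
#'
#' @param n_leaves Number of provisional cell types (>= 1).
#' @param branching Maximum number of children per internal node (>= 2);
#'   2 gives a binary tree.
#' @param cells_per_leaf Mean cell count per leaf.
#' @param cells_dist `"poisson"` (counts drawn per leaf, minimum 1) or
#'   `"constant"`.
#' @param p_neurosurgical Probability a cell's tissue is neurosurgical.
#' @param seed Random seed.
#' @return A list with `root` (a `ccn_dend_node`) and `cells` (data.frame
#'   `cell_id`, `provisional_type`, `tissue`).
#' @examples
#' sim <- simulate_taxonomy(6, cells_per_leaf = 10,
#'                          cells_dist = "constant", seed = 2)
#' @export
simulate_taxonomy <- function(n_leaves, branching = 2L, cells_per_leaf = 100,
                              cells_dist = c("poisson", "constant"),
                              p_neurosurgical = 0.1, seed = 1L) {
  cells_dist <- match.arg(cells_dist)
  n_leaves <- as.integer(n_leaves)
  if (is.na(n_leaves) || n_leaves < 1L) {
    stop("`n_leaves` must be >= 1", call. = FALSE)
  }
  branching <- as.integer(branching)
  if (is.na(branching) || branching < 2L) {
    stop("`branching` must be >= 2", call. = FALSE)
  }
  if (!is.numeric(cells_per_leaf) || cells_per_leaf < 1) {
    stop("`cells_per_leaf` must be a positive mean count", call. = FALSE)
  }
  if (p_neurosurgical < 0 || p_neurosurgical > 1) {
    stop("`p_neurosurgical` must be a probability", call. = FALSE)
  }

  with_local_seed(seed, {
    # publication-style leaf names, unique by a per-leaf marker gene
    classes <- c("Inh", "Exc", "Astro", "Oligo", "Micro", "Endo")
    markers <- paste0(
      rep(c("GAD", "SLC", "PVB", "SSTR", "VIPR", "LMX", "RORA", "FEZ",
            "CUX", "TLE", "NTM", "CBL", "PDE", "KCN", "GRIK", "OPRK",
            "TSHZ", "ADAM", "COL", "SEMA"), each = 25),
      rep(1:25, times = 20)
    )
    genes <- sample(markers, n_leaves)
    leaf_names <- vapply(seq_len(n_leaves), function(i) {
      cl <- sample(classes, 1L)
      l1 <- sample(1:5, 1L)
      l2 <- min(6L, l1 + sample(0:2, 1L))
      lay <- if (l1 == l2) paste0("L", l1) else paste0("L", l1, "-", l2)
      paste(cl, lay, genes[i])
    }, character(1L))

    node_counter <- 0L
    build <- function(lo, hi) {
      if (lo == hi) {
        return(dend_node(paste0("leaf_", lo),
                         original_label = leaf_names[lo]))
      }
      node_counter <<- node_counter + 1L
      id <- paste0("node_", node_counter)
      n <- hi - lo + 1L
      k <- min(n, if (branching == 2L) 2L else sample(2:branching, 1L))
      pool <- seq.int(lo, hi - 1L)
      cuts <- sort(pool[sample.int(length(pool), k - 1L)])
      bounds <- c(lo - 1L, cuts, hi)
      children <- lapply(seq_len(k), function(j) {
        build(bounds[j] + 1L, bounds[j + 1L])
      })
      dend_node(id, children = children)
    }
    root <- if (n_leaves == 1L) {
      dend_node("leaf_1", original_label = leaf_names[1L])
    } else {
      build(1L, n_leaves)
    }

    counts <- switch(cells_dist,
      poisson = pmax(1L, stats::rpois(n_leaves, cells_per_leaf)),
      constant = rep(as.integer(round(cells_per_leaf)), n_leaves)
    )
    total <- sum(counts)
    cells <- data.frame(
      cell_id = sprintf("cell_%06d", seq_len(total)),
      provisional_type = rep(leaf_names, counts),
      tissue = sample(c("postmortem", "neurosurgical"), total,
                      replace = TRUE,
                      prob = c(1 - p_neurosurgical, p_neurosurgical))
    )
    list(root = root, cells = cells)
  })
}

#' Bundled worked examples
#'
#' The in-package transcriptions of published nomenclature records used
#' throughout the documentation and tests:
#' \describe{
#'   \item{`sst_chodl_records`}{The eight published Sst Chodl-associated
#'     cell set records spanning the motor-cortex taxonomies (RNA-seq,
#'     ATAC-seq, DNA methylation, and integrated), including the
#'     cross-taxonomy label references carried in their additional
#'     aliases.}
#'   \item{`registry_manifest`}{The 18-taxonomy registry of public
#'     taxonomies with applied nomenclature (mouse, human, marmoset,
#'     macaque, turtle; multiple modalities).}
#'   \item{`mtg_defaults`}{The taxonomy-wide defaults used for the human
#'     middle temporal gyrus (MTG) taxonomy CCN201908210.}
#' }
#'
#' @return A named list as described above.
#' @export
ccn_examples <- function() {
  ext <- function(f) system.file("extdata", f, package = "ccntax")
  list(
    sst_chodl_records = read_nomenclature_df(ext("sst_chodl_cell_sets.csv")),
    registry_manifest = utils::read.csv(ext("taxonomy_registry.csv"),
                                        colClasses = "character"),
    mtg_defaults = ccn_defaults(
      "CCN201908210",
      assignee = "Trygve Bakken",
      citation = "10.1038/s41586-019-1506-7",
      structure = "middle temporal gyrus",
      ontology_tag = "UBERON:0002771",
      prefix = "MTG"
    )
  )
}
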