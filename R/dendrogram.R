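# Hierarchical taxonomies: a dendrogram of provisional cell types (leaves)
# and groups of types with similar expression (internal nodes). Trees are
# plain nested lists serialized as canonical JSON (sorted keys, 2-space
# indent, UTF-8, explicit "children" arrays) so that the annotated tree
# round-trips byte-for-byte. Trees need not be binary; internal nodes have
# at least two children. Non-hierarchical taxonomies bypass this module and
# declare cell sets through label expressions directly.

.dend_fields <- c("cell_set_accession", "cell_set_aligned_alias",
                  "cell_set_label", "cell_set_preferred_alias",
                  "children", "node_id", "original_label")

#' Construct a dendrogram node
#'
#' @param node_id Identifier unique within the tree.
#' @param children List of child `ccn_dend_node`s; empty for a leaf.
#' @param original_label The publication's cluster name; required on leaves.
#' @param ... Optional annotation fields (`cell_set_accession`,
#'   `cell_set_label`, `cell_set_preferred_alias`,
#'   `cell_set_aligned_alias`).
#' @return A `ccn_dend_node`.
#' @export
dend_node <- function(node_id, children = list(), original_label = NULL, ...) {
  extra <- list(...)
  bad <- setdiff(names(extra), .dend_fields)
  if (length(bad)) {
    stop("unknown dendrogram field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  node <- c(list(node_id = node_id, children = children,
                 original_label = original_label), extra)
  node <- node[!vapply(node, is.null, logical(1L))]
  class(node) <- "ccn_dend_node"
  node
}

is_leaf <- function(node) length(node$children) == 0L

#' @export
print.ccn_dend_node <- function(x, ...) {
  leaves <- leaf_order(x)
  cat("<dendrogram> ", length(leaves), " leaves, root '", x$node_id, "'\n",
      sep = "")
  invisible(x)
}

check_tree <- function(root) {
  seen <- character(0)
  walk <- function(node) {
    if (is.null(node$node_id) || !nzchar(node$node_id)) {
      stop("dendrogram node without node_id", call. = FALSE)
    }
    if (node$node_id %in% seen) {
      stop("duplicate node_id '", node$node_id, "' in dendrogram",
           call. = FALSE)
    }
    seen <<- c(seen, node$node_id)
    if (is_leaf(node)) {
      if (is.null(node$original_label) || !nzchar(node$original_label)) {
        stop("leaf '", node$node_id, "' has no original_label",
             call. = FALSE)
      }
    } else {
      if (length(node$children) < 2L) {
        stop("internal node '", node$node_id,
             "' has fewer than two children", call. = FALSE)
      }
      for (ch in node$children) walk(ch)
    }
  }
  walk(root)
  invisible(root)
}

#' Read a dendrogram from JSON
#'
#' The on-disk schema is a nested object per node:
#' `{"node_id": ..., "original_label": ..., "children": [...]}` with
#' optional annotation fields; leaves omit `children` or carry an empty
#' array. Duplicate node ids, internal nodes with fewer than two children,
#' and leaves without an `original_label` are rejected. A JSON-Schema
#' document for this format ships in `inst/extdata/dendrogram.schema.json`.
#'
#' @param path Path to a JSON file, or a JSON string.
#' @return The root `ccn_dend_node`.
#' @seealso [write_dendrogram()]
#' @export
read_dendrogram <- function(path) {
  txt <- if (length(path) == 1L && file.exists(path)) {
    paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  } else {
    path
  }
  raw <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  build <- function(x) {
    children <- lapply(x$children, build)
    args <- x[setdiff(names(x), "children")]
    do.call(dend_node, c(args, list(children = children)))
  }
  root <- build(raw)
  check_tree(root)
  root
}

#' Serialize a dendrogram to canonical JSON
#'
#' Keys are written in sorted order with two-space indentation so that
#' read/write round-trips are byte-identical; leaf nodes carry an explicit
#' empty `children` array.
#'
#' @param root A `ccn_dend_node`.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_dendrogram <- function(root, path = NULL) {
  check_tree(root)
  strip <- function(node) {
    out <- node[intersect(.dend_fields, names(node))]
    out$children <- lapply(node$children, strip)
    out[order(names(out))]
  }
  json <- jsonlite::toJSON(strip(root), auto_unbox = TRUE, pretty = 2,
                           digits = NA)
  json <- as.character(json)
  if (!is.null(path)) {
    writeLines(json, path, useBytes = TRUE)
    return(invisible(json))
  }
  json
}

#' Leaves of a dendrogram in left-to-right order
#'
#' Depth-first traversal order; this order defines the leaf numerals used
#' for cell set labels and accession numbering.
#'
#' @param root A `ccn_dend_node`.
#' @return List of leaf `ccn_dend_node`s.
#' @export
leaf_order <- function(root) {
  out <- list()
  walk <- function(node) {
    if (is_leaf(node)) {
      out[[length(out) + 1L]] <<- node
    } else {
      for (ch in node$children) walk(ch)
    }
  }
  walk(root)
  out
}

#' Leaf positions spanned by every node
#'
#' Maps each `node_id` to the 1-based left-to-right positions of all
#' descendant leaves (a leaf maps to its own position). These spans are the
#' numerals that internal-node cell set labels compact into range notation.
#'
#' @param root A `ccn_dend_node`.
#' @return Named list: `node_id` to sorted integer vector of leaf
#'   positions.
#' @export
node_leaf_spans <- function(root) {
  spans <- list()
  pos <- 0L
  walk <- function(node) {
    if (is_leaf(node)) {
      pos <<- pos + 1L
      spans[[node$node_id]] <<- pos
      pos
    } else {
      child_spans <- lapply(node$children, walk)
      s <- sort(unlist(child_spans))
      spans[[node$node_id]] <<- s
      s
    }
  }
  walk(root)
  spans
}

#' Annotate a dendrogram with its taxonomy's cell set tags
#'
#' Attaches to every node the accession id, cell set label, and preferred /
#' aligned aliases of the cell set whose label expression covers exactly
#' that node's leaf span. Annotation is idempotent: re-annotating an already
#' annotated tree with the same taxonomy is a no-op.
#'
#' @param root A `ccn_dend_node`.
#' @param tax The `ccn_taxonomy` built from this dendrogram (see
#'   [build_taxonomy()]), possibly after manual annotation.
#' @return The annotated tree.
#' @export
annotate_dendrogram <- function(root, tax) {
  stopifnot(inherits(tax, "ccn_taxonomy"))
  spans <- node_leaf_spans(root)
  df <- tax$cell_sets
  hier <- df[df$cell_set_kind %in% c("leaf", "node"), , drop = FALSE]
  key_of <- function(nums) paste(sort(nums), collapse = ",")
  keys <- vapply(hier$cell_set_label,
                 function(l) key_of(label_numerals(l)),
                 character(1L), USE.NAMES = FALSE)
  lookup <- setNames(seq_len(nrow(hier)), keys)

  orphans <- character(0)
  walk <- function(node) {
    i <- lookup[key_of(spans[[node$node_id]])]
    if (is.na(i)) {
      orphans <<- c(orphans, node$node_id)
    } else {
      node$cell_set_accession <- hier$cell_set_accession_id[i]
      node$cell_set_label <- hier$cell_set_label[i]
      node$cell_set_preferred_alias <- hier$cell_set_preferred_alias[i]
      node$cell_set_aligned_alias <- hier$cell_set_aligned_alias[i]
    }
    node$children <- lapply(node$children, walk)
    node
  }
  out <- walk(root)
  if (length(orphans)) {
    stop("no cell set matches dendrogram node(s): ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  out
}

#' Plot an annotated dendrogram
#'
#' A simple base-graphics rendering of the taxonomy tree: leaves along the
#' x axis labelled by preferred alias, internal nodes drawn at their merge
#' height with filled circles where a preferred alias is assigned.
#' Cosmetic; intended for PDF/SVG export alongside the JSON output.
#'
#' @param x A `ccn_dend_node`.
#' @param cex Label character expansion.
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.ccn_dend_node <- function(x, cex = 0.6, ...) {
  spans <- node_leaf_spans(x)
  depth_of <- function(node, d = 0L) {
    if (is_leaf(node)) return(d)
    max(vapply(node$children, depth_of, integer(1L), d = d + 1L))
  }
  H <- depth_of(x)
  leaves <- leaf_order(x)
  L <- length(leaves)
  graphics::plot(NA, xlim = c(0.5, L + 0.5), ylim = c(-0.5, H),
                 xlab = "", ylab = "height", xaxt = "n", ...)
  draw <- function(node, h) {
    s <- spans[[node$node_id]]
    cx <- mean(range(s))
    if (!is_leaf(node)) {
      for (ch in node$children) {
        cs <- spans[[ch$node_id]]
        chh <- if (is_leaf(ch)) 0 else h - 1
        graphics::segments(cx, h, mean(range(cs)), chh)
        draw(ch, h - 1)
      }
      has_alias <- !is.null(node$cell_set_preferred_alias) &&
        nzchar(node$cell_set_preferred_alias)
      graphics::points(cx, h, pch = 21,
                       bg = if (has_alias) "darkcyan" else "white")
    }
  }
  draw(x, H)
  labs <- vapply(leaves, function(l) {
    if (!is.null(l$cell_set_preferred_alias)) l$cell_set_preferred_alias
    else l$original_label
  }, character(1L))
  graphics::axis(1, at = seq_len(L), labels = labs, las = 2, cex.axis = cex)
  invisible(x)
}
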