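# Mapping cells to cell sets: the membership matrix output. One row per
# cell, one column per cell set (accession-number order), binary calls
# (0 = excluded, 1 = included). A cell belongs to its assigned provisional
# type's leaf set, to every node/custom set whose label covers that leaf's
# numeral, and to every metadata set whose predicate its metadata
# satisfies. The value contract also admits probabilistic mappings with
# values in [0,1].

#' Map every cell to every cell set
#'
#' @param tax A `ccn_taxonomy`.
#' @param cells A data.frame with columns `cell_id` (unique) and
#'   `provisional_type` (matched against leaf preferred aliases, falling
#'   back to leaf labels), plus optional metadata columns used by metadata
#'   cell sets.
#' @param keep_unmapped Cells whose `provisional_type` resolves to no leaf
#'   get an all-zero row when `TRUE`; by default they are an error listing
#'   the offending cells.
#' @return An integer matrix (cells x cell sets) with `cell_id` rownames
#'   and accession colnames, values in {0, 1}.
#' @examples
#' tax <- build_taxonomy(ccn_defaults("CCN201908210", prefix = "MTG"),
#'                       types = c("a", "b"))
#' cells <- data.frame(cell_id = c("c1", "c2"),
#'                     provisional_type = c("a", "b"))
#' map_cells(tax, cells)
#' @export
map_cells <- function(tax, cells, keep_unmapped = FALSE) {
  stopifnot(inherits(tax, "ccn_taxonomy"), is.data.frame(cells))
  if (!all(c("cell_id", "provisional_type") %in% names(cells))) {
    stop("`cells` needs columns cell_id and provisional_type", call. = FALSE)
  }
  if (anyDuplicated(cells$cell_id)) {
    stop("duplicate cell_id(s): ",
         paste(unique(cells$cell_id[duplicated(cells$cell_id)]),
               collapse = ", "), call. = FALSE)
  }

  df <- tax$cell_sets
  ord <- order(accession_number(df$cell_set_accession_id))
  df <- df[ord, , drop = FALSE]
  accs <- df$cell_set_accession_id

  leaves <- df[df$cell_set_kind == "leaf", , drop = FALSE]
  leaf_num <- vapply(leaves$cell_set_label,
                     function(l) label_numerals(l)[1L], integer(1L),
                     USE.NAMES = FALSE)

  # resolve provisional types: preferred alias first, then leaf label
  hit <- match(cells$provisional_type, leaves$cell_set_preferred_alias)
  miss <- is.na(hit)
  hit[miss] <- match(cells$provisional_type[miss], leaves$cell_set_label)
  if (anyNA(hit) && !keep_unmapped) {
    bad <- cells$cell_id[is.na(hit)]
    stop("provisional type of cell(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) paste0(" (+", length(bad) - 5L, " more)"),
         " matches no leaf cell set", call. = FALSE)
  }
  cell_leaf_numeral <- leaf_num[hit]   # NA for unmapped

  m <- matrix(0L, nrow = nrow(cells), ncol = length(accs),
              dimnames = list(cells$cell_id, accs))

  for (j in seq_along(accs)) {
    kind <- df$cell_set_kind[j]
    if (kind %in% c("leaf", "node", "custom")) {
      nums <- label_numerals(df$cell_set_label[j])
      m[, j] <- as.integer(!is.na(cell_leaf_numeral) &
                             cell_leaf_numeral %in% nums)
    } else {  # metadata
      pred <- tax$predicates[[accs[j]]]
      if (is.null(pred)) {
        warning("metadata set ", accs[j],
                " has no membership predicate; column left all-zero",
                call. = FALSE)
        next
      }
      if (is.character(pred)) {
        m[, j] <- as.integer(cells$cell_id %in% pred)
      } else {
        if (!pred$column %in% names(cells)) {
          stop("metadata set ", accs[j], " predicates on unknown cell ",
               "metadata column '", pred$column, "'", call. = FALSE)
        }
        m[, j] <- as.integer(cells[[pred$column]] == pred$value)
      }
    }
  }
  m
}

#' Combine per-leaf assignment probabilities into all cell set columns
#'
#' The probabilistic counterpart of [map_cells()]: given a cells x leaf
#' matrix of assignment probabilities (each row summing to at most 1, since
#' leaf sets partition the cells), the value of a node/custom set is the
#' sum of its member leaves' probabilities, clipped to 1. Metadata sets are
#' not probabilistic and are excluded.
#'
#' @param tax A `ccn_taxonomy`.
#' @param leaf_probs Numeric matrix, rownames = cell ids, colnames = leaf
#'   accession ids, values in \[0, 1\] with row sums at most 1 (up to
#'   `tol`).
#' @param tol Tolerance on the row-sum check.
#' @return Numeric matrix over all leaf/node/custom cell sets.
#' @export
map_cell_probabilities <- function(tax, leaf_probs, tol = 1e-8) {
  stopifnot(inherits(tax, "ccn_taxonomy"), is.matrix(leaf_probs))
  df <- tax$cell_sets[tax$cell_sets$cell_set_kind != "metadata", ,
                      drop = FALSE]
  df <- df[order(accession_number(df$cell_set_accession_id)), , drop = FALSE]
  leaves <- df[df$cell_set_kind == "leaf", , drop = FALSE]
  if (!setequal(colnames(leaf_probs), leaves$cell_set_accession_id)) {
    stop("`leaf_probs` columns must be exactly the leaf accession ids",
         call. = FALSE)
  }
  if (any(leaf_probs < 0 | leaf_probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(rowSums(leaf_probs) > 1 + tol)) {
    stop("per-cell leaf probabilities must sum to at most 1", call. = FALSE)
  }
  leaf_num <- vapply(leaves$cell_set_label,
                     function(l) label_numerals(l)[1L], integer(1L),
                     USE.NAMES = FALSE)
  col_of_numeral <- setNames(leaves$cell_set_accession_id, leaf_num)

  out <- matrix(0, nrow = nrow(leaf_probs), ncol = nrow(df),
                dimnames = list(rownames(leaf_probs),
                                df$cell_set_accession_id))
  for (j in seq_len(nrow(df))) {
    nums <- label_numerals(df$cell_set_label[j])
    cols <- col_of_numeral[as.character(nums)]
    out[, j] <- pmin(1, rowSums(leaf_probs[, cols, drop = FALSE]))
  }
  out
}

#' Write / read a cell-to-cell-set mapping CSV
#'
#' Layout: header `cell_id,<accession>,...`, one row per cell, values `0`
#' and `1` (or decimals in \[0,1\] for probabilistic mappings). Reading
#' validates the value range and rejects ragged rows.
#'
#' @param m Membership matrix as returned by [map_cells()].
#' @param path CSV path.
#' @return `write_mapping()` returns `path` invisibly; `read_mapping()`
#'   returns the matrix.
#' @export
write_mapping <- function(m, path) {
  stopifnot(is.matrix(m))
  df <- data.frame(cell_id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_mapping
#' @export
read_mapping <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        fileEncoding = "UTF-8-BOM")
  if (names(df)[1L] != "cell_id") {
    stop("mapping file must start with a cell_id column", call. = FALSE)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    stop("mapping values must be numeric", call. = FALSE)
  }
  if (anyNA(m)) {
    stop("mapping file has missing values (ragged rows?)", call. = FALSE)
  }
  if (any(m < 0 | m > 1)) {
    stop("mapping values must lie in [0, 1]", call. = FALSE)
  }
  rownames(m) <- df$cell_id
  if (all(m == as.integer(m))) storage.mode(m) <- "integer"
  m
}
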