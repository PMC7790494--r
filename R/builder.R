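# Building a taxonomy: mint an accession id and a label for every cell set
# derived from the dendrogram (or from a flat list of provisional types),
# propagate the taxonomy-wide defaults, and write the intermediate
# nomenclature table for manual annotation.

#' Build a taxonomy from a dendrogram
#'
#' Leaves become `kind = "leaf"` cell sets numbered `1..L` in left-to-right
#' leaf order, each keeping its original cluster name as preferred alias.
#' Internal nodes become `kind = "node"` cell sets numbered `L+1, ...` in
#' depth-first pre-order, with a blank preferred alias. Every cell set
#' carries the default assignee, citation, structure, and ontology tag, and
#' a label of the form `<prefix> <compacted leaf numerals>`.
#'
#' @param defaults A [ccn_defaults()] object (taxonomy id, assignee,
#'   citation, structure, ontology tag, label prefix).
#' @param root A `ccn_dend_node`, or `NULL` when `types` is given.
#' @param types Optionally, a character vector of provisional cell type
#'   names for taxonomies without a dendrogram (non-hierarchical community
#'   structure); each becomes one leaf cell set, numbered in the given
#'   order.
#' @return A `ccn_taxonomy`.
#' @examples
#' d <- ccn_defaults("CCN201908210", prefix = "MTG")
#' tree <- dend_node("n1", list(
#'   dend_node("l1", original_label = "Inh L1-2 PAX6 CDH12"),
#'   dend_node("l2", original_label = "Inh L1 SST CHRNA4")))
#' build_taxonomy(d, tree)
#' @export
build_taxonomy <- function(defaults, root = NULL, types = NULL) {
  stopifnot(inherits(defaults, "ccn_defaults"))
  if (is.null(root) == is.null(types)) {
    stop("supply exactly one of `root` (dendrogram) or `types` (flat list)",
         call. = FALSE)
  }
  tid <- parse_taxonomy_id(defaults$taxonomy_id)

  if (!is.null(root)) {
    check_tree(root)
    leaves <- leaf_order(root)
    leaf_labels <- vapply(leaves, `[[`, character(1L), "original_label")
  } else {
    leaf_labels <- as.character(types)
  }
  if (anyDuplicated(leaf_labels)) {
    stop("duplicate provisional cell type name(s): ",
         paste(unique(leaf_labels[duplicated(leaf_labels)]), collapse = ", "),
         call. = FALSE)
  }
  L <- length(leaf_labels)

  mk_row <- function(n, numerals, preferred, kind) {
    data.frame(
      taxonomy_id = defaults$taxonomy_id,
      cell_set_accession_id = make_accession(tid, n),
      cell_set_label = compact_labels(defaults$prefix, numerals,
                                      defaults$pad_width),
      cell_set_preferred_alias = preferred,
      cell_set_aligned_alias = "",
      cell_set_additional_aliases = "",
      cell_set_alias_assignee = defaults$assignee,
      cell_set_alias_citation = defaults$citation,
      cell_set_structure = defaults$structure,
      cell_set_ontology_tag = defaults$ontology_tag,
      cell_set_level = "",
      cell_set_kind = kind
    )
  }

  rows <- lapply(seq_len(L), function(i) {
    mk_row(i, i, leaf_labels[i], "leaf")
  })

  if (!is.null(root)) {
    spans <- node_leaf_spans(root)
    # internal nodes in depth-first pre-order, numbered after the leaves
    internal_ids <- character(0)
    walk <- function(node) {
      if (!is_leaf(node)) {
        internal_ids <<- c(internal_ids, node$node_id)
        for (ch in node$children) walk(ch)
      }
    }
    walk(root)
    rows <- c(rows, lapply(seq_along(internal_ids), function(k) {
      mk_row(L + k, spans[[internal_ids[k]]], "", "node")
    }))
  }

  tax <- new_taxonomy(defaults$taxonomy_id, do.call(rbind, rows), defaults)
  tax
}

# next free accession number: max existing + 1 (never reuse)
next_accession_number <- function(tax) {
  if (nrow(tax$cell_sets) == 0L) return(1L)
  max(accession_number(tax$cell_sets$cell_set_accession_id)) + 1L
}

#' Add a custom or metadata cell set to a taxonomy
#'
#' Appends one cell set with the next free accession number (max existing
#' number + 1; numbers are never reused). Custom sets group provisional
#' cell types and define membership through their label expression;
#' metadata sets group cells by a cell-metadata predicate and get labels
#' `"Metadata 1"`, `"Metadata 2"`, ... with a running numeral.
#'
#' @param tax A `ccn_taxonomy`.
#' @param members For `kind = "custom"`: the member leaf numerals (integer
#'   vector) or a label expression string to take numerals from. Ignored
#'   for metadata sets.
#' @param kind `"custom"` or `"metadata"`.
#' @param preferred_alias,aligned_alias,additional_aliases Alias fields;
#'   additional aliases may be a character vector (stored `|`-delimited).
#' @param predicate For metadata sets: `list(column =, value =)` selecting
#'   cells whose metadata column equals the value, or a character vector of
#'   explicit cell ids.
#' @param label Optional label override for custom sets. Labels are unique
#'   within a taxonomy, so a custom set duplicating an existing set's
#'   membership (which is allowed) needs its own label text; its trailing
#'   numerals must still equal the member numerals, since the label is the
#'   membership encoding.
#' @param assignee,citation,structure,ontology_tag,level Per-set overrides
#'   of the taxonomy defaults.
#' @return The extended `ccn_taxonomy`.
#' @examples
#' d <- ccn_defaults("CCN201908210", prefix = "MTG")
#' tax <- build_taxonomy(d, types = c("t1", "t2", "t3"))
#' tax <- add_cell_set(tax, kind = "metadata",
#'                     preferred_alias = "Neurosurgical",
#'                     predicate = list(column = "tissue",
#'                                      value = "neurosurgical"))
#' @export
add_cell_set <- function(tax, members = NULL, kind = c("custom", "metadata"),
                         preferred_alias = "", aligned_alias = "",
                         additional_aliases = character(0), predicate = NULL,
                         label = NULL, assignee = NULL, citation = NULL,
                         structure = NULL, ontology_tag = NULL, level = "") {
  stopifnot(inherits(tax, "ccn_taxonomy"))
  kind <- match.arg(kind)
  d <- tax$defaults
  pick <- function(override, field) {
    if (!is.null(override)) override
    else if (!is.null(d)) d[[field]]
    else ""
  }

  if (kind == "custom") {
    if (is.null(members)) {
      stop("custom cell sets need `members` (numerals or a label expression)",
           call. = FALSE)
    }
    numerals <- if (is.character(members)) label_numerals(members)
                else as.integer(members)
    leaf_nums <- vapply(leaf_sets(tax)$cell_set_label,
                        function(l) label_numerals(l)[1L], integer(1L),
                        USE.NAMES = FALSE)
    unknown <- setdiff(numerals, leaf_nums)
    if (length(unknown)) {
      stop("member numeral(s) with no leaf cell set: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    prefix <- if (!is.null(d)) d$prefix else parse_label(tax$cell_sets$cell_set_label[1L])$prefix
    pad <- if (!is.null(d)) d$pad_width else 3L
    if (is.null(label)) {
      label <- compact_labels(prefix, numerals, pad)
    } else if (!identical(label_numerals(label), sort(unique(numerals)))) {
      stop("label '", label, "' does not encode the member numerals",
           call. = FALSE)
    }
  } else {
    n_meta <- sum(tax$cell_sets$cell_set_kind == "metadata")
    label <- paste("Metadata", n_meta + 1L)
    if (!is.null(predicate)) {
      if (is.list(predicate) &&
          !all(c("column", "value") %in% names(predicate))) {
        stop("`predicate` must be list(column =, value =) or a cell-id vector",
             call. = FALSE)
      }
    }
  }
  if (label %in% tax$cell_sets$cell_set_label) {
    stop("cell set label '", label, "' already in use", call. = FALSE)
  }

  n <- next_accession_number(tax)
  acc <- make_accession(tax$taxonomy_id, n)
  row <- data.frame(
    taxonomy_id = tax$taxonomy_id,
    cell_set_accession_id = acc,
    cell_set_label = label,
    cell_set_preferred_alias = preferred_alias,
    cell_set_aligned_alias = aligned_alias,
    cell_set_additional_aliases = paste(additional_aliases, collapse = "|"),
    cell_set_alias_assignee = pick(assignee, "assignee"),
    cell_set_alias_citation = pick(citation, "citation"),
    cell_set_structure = pick(structure, "structure"),
    cell_set_ontology_tag = pick(ontology_tag, "ontology_tag"),
    cell_set_level = level,
    cell_set_kind = kind
  )
  tax$cell_sets <- rbind(tax$cell_sets, row)
  if (kind == "metadata" && !is.null(predicate)) {
    tax$predicates[[acc]] <- predicate
  }
  tax
}

#' Write / read the nomenclature table
#'
#' The nomenclature table is the CSV a curator edits during manual
#' annotation: one row per cell set, the fixed column order of
#' [nomenclature_columns()], UTF-8, comma-separated, quoted where needed.
#' Reading tolerates unknown extra columns (with a warning), a UTF-8 byte
#' order mark, and en/em dashes inside label ranges; missing required
#' columns are an error.
#'
#' @param tax A `ccn_taxonomy`.
#' @param path Output (input) CSV path.
#' @return `write_nomenclature_table()` returns `path` invisibly;
#'   `read_nomenclature_table()` returns a `ccn_taxonomy`.
#' @export
write_nomenclature_table <- function(tax, path) {
  stopifnot(inherits(tax, "ccn_taxonomy"))
  df <- tax$cell_sets[, nomenclature_columns()]
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = TRUE)
  invisible(path)
}

#' @rdname write_nomenclature_table
#' @export
read_nomenclature_table <- function(path) {
  df <- read_nomenclature_df(path)
  ids <- unique(df$taxonomy_id)
  if (length(ids) != 1L) {
    stop("nomenclature table holds ", length(ids), " taxonomy ids; ",
         "use read_cell_set_records() for multi-taxonomy record files",
         call. = FALSE)
  }
  taxonomy_from_df(df)
}

# shared CSV reader: BOM-tolerant, checks/reorders columns, normalizes
# dash dialects in labels, coerces everything to character
read_nomenclature_df <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8-BOM", check.names = FALSE)
  req <- nomenclature_columns()
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("nomenclature table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), req)
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  df <- df[, req]
  df[is.na(df)] <- ""
  # canonicalize typographic dashes in label range notation
  df$cell_set_label <- gsub("–|—", "-", df$cell_set_label)
  df
}

# rebuild a taxonomy object (defaults inferred) from a one-taxonomy frame
taxonomy_from_df <- function(df) {
  leaves <- df[df$cell_set_kind == "leaf", , drop = FALSE]
  defaults <- NULL
  if (nrow(leaves) > 0L) {
    first <- tryCatch(parse_label(leaves$cell_set_label[1L]),
                      error = function(e) NULL)
    if (!is.null(first)) {
      defaults <- ccn_defaults(
        df$taxonomy_id[1L],
        assignee = stat_mode(leaves$cell_set_alias_assignee),
        citation = stat_mode(leaves$cell_set_alias_citation),
        structure = stat_mode(leaves$cell_set_structure),
        ontology_tag = stat_mode(leaves$cell_set_ontology_tag),
        prefix = first$prefix, pad_width = first$pad_width
      )
    }
  }
  new_taxonomy(df$taxonomy_id[1L], df, defaults)
}

stat_mode <- function(x) {
  if (length(x) == 0L) return("")
  names(sort(table(x), decreasing = TRUE))[1L]
}
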