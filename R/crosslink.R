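# Linking cell sets across taxonomies. Two mechanisms need no expression
# data at all: (a) two cell sets in different taxonomies sharing the same
# non-empty aligned alias are linked; (b) an additional alias of the form
# "<cell set labels> in <taxonomy id>" (e.g. "RNA-seq 040 in CCN201912131")
# is a machine-readable reference to cell sets of another taxonomy.
# Optionally, (c) cell sets over the same dataset whose member cell-id
# sets are identical can be linked. A registry holds the loaded
# taxonomies; the link graph is an undirected igraph over
# (taxonomy, accession) nodes.

#' Parse a cross-taxonomy alias reference
#'
#' Recognizes additional aliases of the form
#' `"<label expression> in <taxonomy id>"` and expands the label
#' expression. Other aliases (e.g. `"Long-range projecting Sst"`) are not
#' references and yield `NULL`; an alias that matches the pattern but
#' carries a malformed taxonomy id is an error.
#'
#' @param text One alias string.
#' @return `NULL`, or a list with `target_taxonomy` (id string) and
#'   `labels` (expanded member leaf labels).
#' @examples
#' parse_alias_reference("RNA-seq 040, 046-047, 050-052, 068 in CCN201912131")
#' parse_alias_reference("Long-range projecting Sst")  # NULL
#' @export
parse_alias_reference <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("alias must be a single string", call. = FALSE)
  }
  m <- regmatches(text, regexec("^(.*\\S)\\s+in\\s+(CCN\\S+)$", text))[[1L]]
  if (length(m) == 0L) return(NULL)
  tid <- parse_taxonomy_id(m[3L])        # malformed id -> error
  labels <- expand_label(m[2L])
  list(target_taxonomy = format(tid), labels = labels)
}

#' A registry of taxonomies
#'
#' Holds any number of taxonomies keyed by taxonomy id, with per-taxonomy
#' provenance (source file). Ingest enforces unique taxonomy ids and
#' globally unique accession ids.
#'
#' @param taxonomies Optional list of `ccn_taxonomy` objects to add.
#' @return A `ccn_registry`.
#' @export
ccn_registry <- function(taxonomies = list()) {
  reg <- structure(list(taxonomies = list(), provenance = character(0)),
                   class = "ccn_registry")
  for (tax in taxonomies) reg <- registry_add(reg, tax)
  reg
}

#' @export
print.ccn_registry <- function(x, ...) {
  n_sets <- sum(vapply(x$taxonomies, n_cell_sets, integer(1L)))
  cat("<ccn registry> ", length(x$taxonomies), " taxonomies, ", n_sets,
      " cell sets\n", sep = "")
  invisible(x)
}

#' Add a taxonomy to a registry
#'
#' @param reg A `ccn_registry`.
#' @param tax A `ccn_taxonomy`.
#' @param source Provenance note (e.g. the source file path).
#' @return The extended registry.
#' @export
registry_add <- function(reg, tax, source = NA_character_) {
  stopifnot(inherits(reg, "ccn_registry"), inherits(tax, "ccn_taxonomy"))
  if (tax$taxonomy_id %in% names(reg$taxonomies)) {
    stop("taxonomy id ", tax$taxonomy_id, " already registered",
         call. = FALSE)
  }
  existing <- unlist(lapply(reg$taxonomies,
                            function(t) t$cell_sets$cell_set_accession_id))
  clash <- intersect(existing, tax$cell_sets$cell_set_accession_id)
  if (length(clash)) {
    stop("accession id(s) already registered: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  reg$taxonomies[[tax$taxonomy_id]] <- tax
  reg$provenance[tax$taxonomy_id] <- source
  reg
}

#' Read a registry manifest
#'
#' The manifest CSV has columns `taxonomy_id,description,citation,file`.
#' Rows with a `file` entry load that nomenclature table (path relative to
#' the manifest); rows without one register the taxonomy id and its
#' description only.
#'
#' @param path Manifest CSV path.
#' @return A `ccn_registry`.
#' @export
read_registry <- function(path) {
  man <- utils::read.csv(path, colClasses = "character",
                         fileEncoding = "UTF-8-BOM")
  need <- c("taxonomy_id", "description", "citation", "file")
  missing <- setdiff(need, names(man))
  if (length(missing)) {
    stop("registry manifest is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  reg <- ccn_registry()
  for (i in seq_len(nrow(man))) {
    tid <- man$taxonomy_id[i]
    parse_taxonomy_id(tid)
    f <- man$file[i]
    if (!is.na(f) && nzchar(f)) {
      tab <- file.path(dirname(path), f)
      tax <- read_nomenclature_table(tab)
      if (tax$taxonomy_id != tid) {
        stop("manifest row ", i, ": file holds taxonomy ", tax$taxonomy_id,
             ", expected ", tid, call. = FALSE)
      }
      tax$description <- man$description[i]
      reg <- registry_add(reg, tax, source = f)
    } else {
      stub <- new_taxonomy(tid, empty_cell_sets(),
                           description = man$description[i])
      reg <- registry_add(reg, stub, source = NA_character_)
    }
  }
  reg
}

#' Read a multi-taxonomy cell set record file into a registry
#'
#' A nomenclature-format CSV whose rows span several taxonomies (an
#' excerpt, e.g. all cell sets matching one interneuron class across a
#' project's taxonomies) is split by taxonomy id into excerpt taxonomies.
#'
#' @param path Nomenclature-format CSV path.
#' @return A `ccn_registry` of excerpt taxonomies.
#' @export
read_cell_set_records <- function(path) {
  df <- read_nomenclature_df(path)
  reg <- ccn_registry()
  for (tid in unique(df$taxonomy_id)) {
    sub <- df[df$taxonomy_id == tid, , drop = FALSE]
    reg <- registry_add(reg, taxonomy_from_df(sub), source = path)
  }
  reg
}

# normalize an aligned alias for exact-match linking
squish <- function(x) trimws(gsub("\\s+", " ", x))

# resolve one alias reference against a registry: accessions of the cell
# sets whose labels cover exactly the referenced numerals; references to a
# strict subset of a composite set's span resolve to the leaf sets, never
# the composite. Unresolvable labels are dropped (dangling-ignore).
resolve_reference <- function(ref, reg) {
  tax <- reg$taxonomies[[ref$target_taxonomy]]
  if (is.null(tax)) return(character(0))
  want <- lapply(ref$labels, function(l) {
    p <- parse_label(l)
    list(prefix = p$prefix, numerals = p$numerals)
  })
  have <- lapply(tax$cell_sets$cell_set_label, function(l) {
    p <- tryCatch(parse_label(l), error = function(e) NULL)
    p
  })
  hits <- character(0)
  for (w in want) {
    for (j in seq_along(have)) {
      h <- have[[j]]
      if (is.null(h)) next
      if (identical(h$prefix, w$prefix) &&
          identical(h$numerals, w$numerals)) {
        hits <- c(hits, tax$cell_sets$cell_set_accession_id[j])
      }
    }
  }
  unique(hits)
}

#' Build the cross-taxonomy link graph
#'
#' Undirected graph over every cell set of every registered taxonomy.
#' Edges: `alias` edges between cell sets of different taxonomies sharing
#' an identical non-empty aligned alias (exact match after whitespace
#' normalization; no fuzzy matching); `reference` edges from a cell set to
#' each cell set its additional-alias references resolve to; and, when
#' `memberships` is given, `co_cell` edges between cell sets of different
#' taxonomies whose member cell-id sets are identical. References to
#' taxonomies or labels absent from the registry are skipped.
#'
#' @param reg A `ccn_registry`.
#' @param memberships Optional named list, accession id to character vector
#'   of member cell ids, enabling co-cell edges.
#' @return An `igraph` graph; vertices are named by accession id and carry
#'   `taxonomy_id`, `preferred_alias`, and `aligned_alias` attributes;
#'   edges carry a `type` attribute.
#' @export
build_link_graph <- function(reg, memberships = NULL) {
  stopifnot(inherits(reg, "ccn_registry"))
  if (length(reg$taxonomies) == 0L) {
    stop("registry is empty", call. = FALSE)
  }
  all_sets <- do.call(rbind, lapply(reg$taxonomies, `[[`, "cell_sets"))
  rownames(all_sets) <- NULL

  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(
    g, nrow(all_sets),
    name = all_sets$cell_set_accession_id,
    taxonomy_id = all_sets$taxonomy_id,
    preferred_alias = all_sets$cell_set_preferred_alias,
    aligned_alias = all_sets$cell_set_aligned_alias
  )

  edges <- character(0)
  types <- character(0)
  add_edge <- function(a, b, type) {
    edges <<- c(edges, a, b)
    types <<- c(types, type)
  }

  # (a) shared aligned aliases across taxonomies
  alias <- squish(all_sets$cell_set_aligned_alias)
  for (al in unique(alias[nzchar(alias)])) {
    idx <- which(alias == al)
    if (length(idx) < 2L) next
    for (i in idx) for (j in idx) {
      if (i < j && all_sets$taxonomy_id[i] != all_sets$taxonomy_id[j]) {
        add_edge(all_sets$cell_set_accession_id[i],
                 all_sets$cell_set_accession_id[j], "alias")
      }
    }
  }

  # (b) parsed additional-alias references
  for (i in seq_len(nrow(all_sets))) {
    for (al in split_aliases(all_sets$cell_set_additional_aliases[i])) {
      ref <- tryCatch(parse_alias_reference(al), error = function(e) {
        message("skipping unparseable alias reference: ", al)
        NULL
      })
      if (is.null(ref)) next
      for (acc in resolve_reference(ref, reg)) {
        if (acc != all_sets$cell_set_accession_id[i]) {
          add_edge(all_sets$cell_set_accession_id[i], acc, "reference")
        }
      }
    }
  }

  # (c) identical member cell-id sets across taxonomies
  if (!is.null(memberships)) {
    accs <- intersect(names(memberships), all_sets$cell_set_accession_id)
    tax_of <- setNames(all_sets$taxonomy_id, all_sets$cell_set_accession_id)
    if (length(accs) > 1L) {
      for (i in seq_along(accs)) for (j in seq_along(accs)) {
        if (i < j && tax_of[accs[i]] != tax_of[accs[j]] &&
            setequal(memberships[[accs[i]]], memberships[[accs[j]]])) {
          add_edge(accs[i], accs[j], "co_cell")
        }
      }
    }
  }

  if (length(edges)) {
    g <- igraph::add_edges(g, edges, type = types)
    g <- igraph::simplify(g, edge.attr.comb = "first")
  }
  g
}

#' Connected components of a link graph as a report table
#'
#' @param g Graph from [build_link_graph()].
#' @return A data.frame with columns `component_id`, `taxonomy_id`,
#'   `cell_set_accession_id`, `preferred_alias`, `aligned_alias`, ordered
#'   by component size (largest first), then accession.
#' @export
link_components <- function(g) {
  comp <- igraph::components(g)
  sizes <- comp$csize[comp$membership]
  ord <- order(-sizes, comp$membership,
               igraph::V(g)$name)
  # renumber components largest-first for a stable report
  old <- unique(comp$membership[ord])
  renum <- setNames(seq_along(old), old)
  data.frame(
    component_id = unname(renum[as.character(comp$membership[ord])]),
    taxonomy_id = igraph::V(g)$taxonomy_id[ord],
    cell_set_accession_id = igraph::V(g)$name[ord],
    preferred_alias = igraph::V(g)$preferred_alias[ord],
    aligned_alias = igraph::V(g)$aligned_alias[ord]
  )
}

#' Transfer aligned aliases from a reference taxonomy
#'
#' Given an externally supplied correspondence between target and
#' reference cell sets (from an upstream computational alignment — the
#' nomenclature itself performs no alignment), copies each reference cell
#' set's aligned alias onto the corresponding target cell set. The
#' transfer provenance (source taxonomy and accession per updated set) is
#' recorded in the returned taxonomy's `transfer_log`.
#'
#' @param source_tax Reference `ccn_taxonomy` (supplies the aliases).
#' @param target_tax Taxonomy to update.
#' @param correspondence Named character vector: target accession id to
#'   source accession id. May be empty (identity).
#' @return The updated target `ccn_taxonomy`.
#' @export
transfer_aligned_aliases <- function(source_tax, target_tax, correspondence) {
  stopifnot(inherits(source_tax, "ccn_taxonomy"),
            inherits(target_tax, "ccn_taxonomy"))
  if (length(correspondence) == 0L) return(target_tax)
  if (is.null(names(correspondence))) {
    stop("`correspondence` must be named: target accession -> source accession",
         call. = FALSE)
  }
  src_idx <- match(correspondence, source_tax$cell_sets$cell_set_accession_id)
  tgt_idx <- match(names(correspondence),
                   target_tax$cell_sets$cell_set_accession_id)
  if (anyNA(src_idx)) {
    stop("source accession(s) not found: ",
         paste(correspondence[is.na(src_idx)], collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(tgt_idx)) {
    stop("target accession(s) not found: ",
         paste(names(correspondence)[is.na(tgt_idx)], collapse = ", "),
         call. = FALSE)
  }
  target_tax$cell_sets$cell_set_aligned_alias[tgt_idx] <-
    source_tax$cell_sets$cell_set_aligned_alias[src_idx]
  log <- data.frame(
    target_accession = names(correspondence),
    source_accession = unname(correspondence),
    source_taxonomy = source_tax$taxonomy_id
  )
  prev <- target_tax$transfer_log
  target_tax$transfer_log <- if (is.null(prev)) log else {
    unique(rbind(prev, log))
  }
  target_tax
}
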