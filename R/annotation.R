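# The manual-annotation round trip: curators edit the exported
# nomenclature CSV in a spreadsheet (adding aliases from the literature,
# assignees, citations, structures), and the edited table is re-ingested
# here. Edits are full-row upserts keyed by accession id: a blank cell
# means "leave unchanged" and the literal token "-" means "clear".

.editable_columns <- c("cell_set_label", "cell_set_preferred_alias",
                       "cell_set_aligned_alias",
                       "cell_set_additional_aliases",
                       "cell_set_alias_assignee", "cell_set_alias_citation",
                       "cell_set_structure", "cell_set_ontology_tag",
                       "cell_set_level")

#' Apply a table of manual annotation edits to a taxonomy
#'
#' Each edit row is matched to an existing cell set by
#' `cell_set_accession_id`. Within a row, blank cells leave the current
#' value untouched and the token `"-"` clears it; anything else replaces
#' the stored value. Provenance travels with the edits through the
#' `cell_set_alias_assignee` and `cell_set_alias_citation` columns.
#' Applying the same edits table twice is a no-op the second time.
#'
#' @param tax A `ccn_taxonomy`.
#' @param edits A data.frame in nomenclature-table layout, or a path to an
#'   edits CSV (same header; tolerant of spreadsheet quirks, see
#'   [read_nomenclature_table()]).
#' @param strict_aligned When `TRUE`, an edited aligned alias that fails
#'   the cortical naming grammar (see [parse_aligned_alias()]) is an error;
#'   when `FALSE` (default) it only warns.
#' @param vocabulary Vocabulary used for the aligned-alias check; defaults
#'   to the bundled cortical vocabulary.
#' @return The updated `ccn_taxonomy`.
#' @export
apply_annotations <- function(tax, edits, strict_aligned = FALSE,
                              vocabulary = ccn_vocabulary()) {
  stopifnot(inherits(tax, "ccn_taxonomy"))
  if (is.character(edits)) edits <- read_nomenclature_df(edits)
  if (nrow(edits) == 0L) return(tax)
  if (!"cell_set_accession_id" %in% names(edits)) {
    stop("edits table has no cell_set_accession_id column", call. = FALSE)
  }

  df <- tax$cell_sets
  idx <- match(edits$cell_set_accession_id, df$cell_set_accession_id)
  if (anyNA(idx)) {
    stop("edit(s) reference unknown accession(s): ",
         paste(edits$cell_set_accession_id[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }

  cols <- intersect(.editable_columns, names(edits))
  for (k in seq_len(nrow(edits))) {
    i <- idx[k]
    for (col in cols) {
      val <- edits[[col]][k]
      if (is.na(val) || !nzchar(val)) next      # blank: keep
      df[[col]][i] <- if (identical(val, "-")) "" else val
    }
  }

  changed <- unique(idx)
  bad <- character(0)
  for (i in changed) {
    al <- df$cell_set_aligned_alias[i]
    if (!nzchar(al)) next
    res <- tryCatch(parse_aligned_alias(al, vocabulary),
                    error = function(e) NULL)
    if (is.null(res)) bad <- c(bad, al)
  }
  if (length(bad)) {
    msg <- paste0("aligned alias(es) outside the naming grammar: ",
                  paste(unique(bad), collapse = "; "))
    if (strict_aligned) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }

  tax$cell_sets <- df
  tax
}

#' Generalize the anatomical structure of selected cell sets
#'
#' Conserved cell types (e.g. most GABAergic and non-neuronal types) can be
#' re-tagged from the sampled region to a broader structure such as
#' "Neocortex" (UBERON:0001950). Only the listed accessions are touched.
#'
#' @param tax A `ccn_taxonomy`.
#' @param accessions Accession ids to update (may be empty: identity).
#' @param structure New anatomical structure text.
#' @param ontology_tag Matching ontology CURIE (`PREFIX:digits`).
#' @return The updated `ccn_taxonomy`.
#' @export
generalize_structure <- function(tax, accessions, structure, ontology_tag) {
  stopifnot(inherits(tax, "ccn_taxonomy"))
  if (!is_curie(ontology_tag)) {
    stop("'", ontology_tag, "' is not an ontology CURIE (expected ",
         "letters, a colon, then digits, e.g. UBERON:0001950)",
         call. = FALSE)
  }
  if (length(accessions) == 0L) return(tax)
  idx <- match(accessions, tax$cell_sets$cell_set_accession_id)
  if (anyNA(idx)) {
    stop("unknown accession(s): ",
         paste(accessions[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  tax$cell_sets$cell_set_structure[idx] <- structure
  tax$cell_sets$cell_set_ontology_tag[idx] <- ontology_tag
  tax
}
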