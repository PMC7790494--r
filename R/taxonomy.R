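# The in-memory taxonomy: one taxonomy id plus its cell sets, stored as a
# data.frame in the same column layout as the on-disk nomenclature table.
# This mirrors the spreadsheet-mediated workflow: what you see in the CSV is
# what the object holds. Multiple additional aliases share one column,
# "|"-delimited. Membership predicates of metadata/custom sets (which the
# CSV cannot express) live alongside in `predicates`.

#' Standard nomenclature table columns
#'
#' Fixed column order of the nomenclature CSV and of `$cell_sets` inside a
#' taxonomy object.
#' @return Character vector of column names.
#' @export
nomenclature_columns <- function() {
  c("taxonomy_id", "cell_set_accession_id", "cell_set_label",
    "cell_set_preferred_alias", "cell_set_aligned_alias",
    "cell_set_additional_aliases", "cell_set_alias_assignee",
    "cell_set_alias_citation", "cell_set_structure",
    "cell_set_ontology_tag", "cell_set_level", "cell_set_kind")
}

empty_cell_sets <- function() {
  df <- as.data.frame(
    setNames(rep(list(character(0)), length(nomenclature_columns())),
             nomenclature_columns())
  )
  df
}

#' Default metadata propagated to every cell set of a taxonomy
#'
#' Global values that propagate to each cell set as a starting point and can
#' be revised per set during manual annotation.
#'
#' @param taxonomy_id Taxonomy id string (`CCN...`) or `ccn_taxonomy_id`.
#' @param assignee Person responsible for the cell set aliases.
#' @param citation Permanent identifier (e.g. DOI) of the source taxonomy.
#' @param structure Anatomical structure the cells were collected from.
#' @param ontology_tag Ontology CURIE for the structure, e.g.
#'   `"UBERON:0002771"`.
#' @param prefix Cell set label prefix, e.g. `"MTG"`.
#' @param pad_width Zero-padding width for label numerals (default 3).
#' @return A list of class `ccn_defaults`.
#' @examples
#' ccn_defaults("CCN201908210", "Trygve Bakken",
#'              "10.1038/s41586-019-1506-7", "middle temporal gyrus",
#'              "UBERON:0002771", "MTG")
#' @export
ccn_defaults <- function(taxonomy_id, assignee = "", citation = "",
                         structure = "", ontology_tag = "", prefix = "CS",
                         pad_width = 3L) {
  if (inherits(taxonomy_id, "ccn_taxonomy_id")) {
    taxonomy_id <- format(taxonomy_id)
  }
  parse_taxonomy_id(taxonomy_id)  # validates
  if (nzchar(ontology_tag) && !is_curie(ontology_tag)) {
    stop("`ontology_tag` must be an ontology CURIE like 'UBERON:0002771'",
         call. = FALSE)
  }
  structure(
    list(taxonomy_id = taxonomy_id, assignee = assignee,
         citation = citation, structure = structure,
         ontology_tag = ontology_tag, prefix = prefix,
         pad_width = as.integer(pad_width)),
    class = "ccn_defaults"
  )
}

is_curie <- function(x) grepl("^[A-Za-z_]+:[0-9]+$", x)

new_taxonomy <- function(taxonomy_id, cell_sets, defaults = NULL,
                         predicates = list(), description = "") {
  structure(
    list(taxonomy_id = taxonomy_id,
         cell_sets = cell_sets,
         defaults = defaults,
         predicates = predicates,
         description = description),
    class = "ccn_taxonomy"
  )
}

#' @export
print.ccn_taxonomy <- function(x, ...) {
  kinds <- table(factor(x$cell_sets$cell_set_kind,
                        levels = c("leaf", "node", "custom", "metadata")))
  cat("<ccn taxonomy> ", x$taxonomy_id, ": ", nrow(x$cell_sets),
      " cell sets (", paste(sprintf("%d %s", kinds, names(kinds)),
                            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Number of cell sets in a taxonomy
#' @param tax A `ccn_taxonomy`.
#' @return Integer count.
#' @export
n_cell_sets <- function(tax) nrow(tax$cell_sets)

# split a "|"-delimited additional-alias cell into its aliases
split_aliases <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, "|", fixed = TRUE)[[1L]])
}

# leaf rows of a taxonomy, ordered by label numeral
leaf_sets <- function(tax) {
  df <- tax$cell_sets[tax$cell_sets$cell_set_kind == "leaf", , drop = FALSE]
  if (nrow(df) == 0L) return(df)
  num <- vapply(df$cell_set_label, function(l) label_numerals(l)[1L],
                integer(1L), USE.NAMES = FALSE)
  df[order(num), , drop = FALSE]
}

#' Validate a taxonomy against the nomenclature invariants
#'
#' Checks identifier grammars, accession/taxonomy digit agreement,
#' uniqueness of accessions and labels, alias cardinality (at most one
#' preferred and one aligned alias per cell set), and that leaf numerals
#' form the contiguous sequence `1..L`. Violations are returned as data,
#' never raised, so a taxonomy can be inspected mid-curation.
#'
#' @param tax A `ccn_taxonomy`.
#' @param check_leaf_numerals Require leaf numerals to cover `1..L` without
#'   gaps (default `TRUE`; disable for excerpt taxonomies that intentionally
#'   hold a subset of cell sets).
#' @return A data.frame with columns `code`, `accession`, `message`; zero
#'   rows if and only if the taxonomy is valid. Codes are machine-readable
#'   (e.g. `DUPLICATE_ACCESSION`, `MULTIPLE_ALIGNED_ALIAS`).
#' @export
validate_taxonomy <- function(tax, check_leaf_numerals = TRUE) {
  stopifnot(inherits(tax, "ccn_taxonomy"))
  df <- tax$cell_sets
  v <- list()
  add <- function(code, accession, message) {
    v[[length(v) + 1L]] <<- data.frame(code = code, accession = accession,
                                       message = message)
  }

  if (!is_taxonomy_id(tax$taxonomy_id)) {
    add("BAD_TAXONOMY_ID", "",
        paste0("taxonomy id '", tax$taxonomy_id, "' is malformed"))
  }

  for (i in seq_len(nrow(df))) {
    acc <- df$cell_set_accession_id[i]
    ok <- !inherits(tryCatch(parse_accession(acc), error = identity), "error")
    if (!ok) {
      add("BAD_ACCESSION_FORMAT", acc,
          paste0("accession '", acc, "' is malformed"))
    } else if (accession_taxonomy(acc) != tax$taxonomy_id) {
      add("ACCESSION_TAXONOMY_MISMATCH", acc,
          paste0("accession '", acc, "' does not carry the digits of ",
                 tax$taxonomy_id))
    }
    if (grepl("|", df$cell_set_preferred_alias[i], fixed = TRUE)) {
      add("MULTIPLE_PREFERRED_ALIAS", acc,
          "more than one preferred alias assigned")
    }
    if (grepl("|", df$cell_set_aligned_alias[i], fixed = TRUE)) {
      add("MULTIPLE_ALIGNED_ALIAS", acc,
          "more than one aligned alias assigned")
    }
  }

  dup_acc <- unique(df$cell_set_accession_id[duplicated(df$cell_set_accession_id)])
  for (acc in dup_acc) {
    add("DUPLICATE_ACCESSION", acc,
        paste0("accession '", acc, "' assigned to more than one cell set"))
  }
  dup_lab <- unique(df$cell_set_label[duplicated(df$cell_set_label)])
  for (lab in dup_lab) {
    add("DUPLICATE_LABEL", "",
        paste0("label '", lab, "' assigned to more than one cell set"))
  }

  leaves <- df[df$cell_set_kind == "leaf", , drop = FALSE]
  if (nrow(leaves) > 0L) {
    nums <- vapply(leaves$cell_set_label, function(l) {
      n <- tryCatch(label_numerals(l), error = function(e) NA_integer_)
      if (length(n) != 1L) NA_integer_ else n
    }, integer(1L), USE.NAMES = FALSE)
    bad <- which(is.na(nums))
    for (i in bad) {
      add("BAD_LEAF_LABEL", leaves$cell_set_accession_id[i],
          paste0("leaf label '", leaves$cell_set_label[i],
                 "' does not carry exactly one numeral"))
    }
    nums <- nums[!is.na(nums)]
    if (anyDuplicated(nums)) {
      add("DUPLICATE_LEAF_NUMERAL", "",
          "two leaf cell sets share a label numeral")
    }
    if (check_leaf_numerals && length(nums) > 0L &&
        !identical(sort(unique(nums)), seq_len(length(nums)))) {
      add("LEAF_NUMERAL_GAP", "",
          paste0("leaf numerals do not form 1..", length(nums)))
    }
  }

  if (length(v) == 0L) {
    data.frame(code = character(0), accession = character(0),
               message = character(0))
  } else {
    do.call(rbind, v)
  }
}
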