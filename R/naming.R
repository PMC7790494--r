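# The cortical aligned-alias grammar. Aligned aliases are the at-most-one
# controlled-vocabulary name linking matched cell sets across taxonomies
# (analogous to a gene symbol). Cortical names follow one of four shapes:
#
#   glutamatergic   [Layer] [Projection] #     e.g. "L2/3 IT 4"
#   GABAergic       [Canonical gene(s)] #      e.g. "Pvalb 3", "Sst Chodl"
#   non-neuronal    [Cell class] #             e.g. "Microglia 2"
#   historical      [Historical name] #        e.g. "Chandelier 1"
#
# The trailing ordinal is optional; "_" before the ordinal (as in
# "L6 CT_1") is accepted and canonicalized to a space. The vocabulary is a
# config file, not code: the convention is a starting point, expected to
# be extended.

#' Load an aligned-alias vocabulary
#'
#' @param path JSON config listing `layers`, `projections`,
#'   `projection_aliases` (map from accepted to canonical, e.g. CF -> ET),
#'   `genes`, `classes`, and `historical` tokens. Defaults to the bundled
#'   cortical vocabulary.
#' @return A list of class `ccn_vocabulary`.
#' @export
ccn_vocabulary <- function(path = system.file("extdata",
                                              "cortical_vocabulary.json",
                                              package = "ccntax")) {
  v <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  need <- c("layers", "projections", "genes", "classes", "historical")
  missing <- setdiff(need, names(v))
  if (length(missing)) {
    stop("vocabulary config is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(v$projection_aliases)) v$projection_aliases <- list()
  v$projection_aliases <- unlist(v$projection_aliases)
  class(v) <- "ccn_vocabulary"
  v
}

#' Parse an aligned alias against the cortical naming grammar
#'
#' @param text The alias string.
#' @param vocabulary A [ccn_vocabulary()].
#' @return A list of class `ccn_aligned_alias` with `class` (one of
#'   `"glutamatergic"`, `"GABAergic"`, `"non-neuronal"`, `"historical"`),
#'   the class-specific fields (`layer`, `projection`, `genes`, `base`),
#'   the optional `ordinal`, and `canonical`, the canonical rendering
#'   (single spaces, config casing), which re-parses to the same result.
#' @examples
#' parse_aligned_alias("L2/3 IT 4")
#' parse_aligned_alias("Sst Chodl")
#' @export
parse_aligned_alias <- function(text, vocabulary = ccn_vocabulary()) {
  stopifnot(inherits(vocabulary, "ccn_vocabulary"))
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("aligned alias must be a non-empty string", call. = FALSE)
  }
  s <- trimws(gsub("\\s+", " ", text))
  s <- sub("_([0-9]+)$", " \\1", s)      # "L6 CT_1" -> "L6 CT 1"
  tokens <- strsplit(s, " ", fixed = TRUE)[[1L]]

  ordinal <- NULL
  if (length(tokens) > 1L && grepl("^[0-9]+$", tokens[length(tokens)])) {
    ordinal <- as.integer(tokens[length(tokens)])
    tokens <- tokens[-length(tokens)]
  }
  if (length(tokens) == 0L) {
    stop("aligned alias '", text, "': ordinal without a name", call. = FALSE)
  }

  finish <- function(cls, canonical_tokens, layer = NULL, projection = NULL,
                     genes = NULL, base = NULL) {
    canonical <- paste(c(canonical_tokens, ordinal), collapse = " ")
    structure(list(class = cls, layer = layer, projection = projection,
                   genes = genes, base = base, ordinal = ordinal,
                   canonical = canonical),
              class = "ccn_aligned_alias")
  }

  v <- vocabulary
  ci_match <- function(token, pool) pool[match(tolower(token), tolower(pool))]

  # glutamatergic: layer then projection
  layer <- ci_match(tokens[1L], v$layers)
  if (!is.na(layer)) {
    if (length(tokens) < 2L) {
      stop("aligned alias '", text, "': layer '", tokens[1L],
           "' without a projection class", call. = FALSE)
    }
    proj <- ci_match(tokens[2L], v$projections)
    if (is.na(proj)) {
      alias_names <- names(v$projection_aliases)
      hit <- match(tolower(tokens[2L]), tolower(alias_names))
      if (!is.na(hit)) proj <- unname(v$projection_aliases[hit])
    }
    if (is.na(proj) || is.null(proj)) {
      stop("aligned alias '", text, "': unknown projection token '",
           tokens[2L], "'", call. = FALSE)
    }
    if (length(tokens) > 2L) {
      stop("aligned alias '", text, "': unexpected token '", tokens[3L],
           "'", call. = FALSE)
    }
    return(finish("glutamatergic", c(layer, proj),
                  layer = layer, projection = proj))
  }

  # GABAergic: every token a canonical gene symbol (case-insensitive)
  genes <- vapply(tokens, ci_match, character(1L), pool = v$genes)
  if (!anyNA(genes)) {
    return(finish("GABAergic", unname(genes), genes = unname(genes)))
  }

  rest <- paste(tokens, collapse = " ")
  cls_hit <- ci_match(rest, v$classes)
  if (!is.na(cls_hit)) {
    return(finish("non-neuronal", cls_hit, base = cls_hit))
  }
  hist_hit <- ci_match(rest, v$historical)
  if (!is.na(hist_hit)) {
    return(finish("historical", hist_hit, base = hist_hit))
  }

  first_bad <- tokens[which(is.na(genes))[1L]]
  stop("aligned alias '", text, "': unknown token '", first_bad, "'",
       call. = FALSE)
}

#' @export
print.ccn_aligned_alias <- function(x, ...) {
  cat("<aligned alias> ", x$canonical, " [", x$class, "]\n", sep = "")
  invisible(x)
}

#' Check every aligned alias in a taxonomy against the naming grammar
#'
#' @param tax A `ccn_taxonomy`.
#' @param vocabulary A [ccn_vocabulary()].
#' @return A data.frame with one row per cell set: `cell_set_accession_id`,
#'   `aligned_alias`, `status` (`"ok"`, `"unassigned"`, or `"fail"`),
#'   `class`, and `message` (the parse error for failures). The per-class
#'   summary counts are attached as attribute `"summary"`.
#' @export
check_taxonomy_aliases <- function(tax, vocabulary = ccn_vocabulary()) {
  stopifnot(inherits(tax, "ccn_taxonomy"))
  df <- tax$cell_sets
  rows <- lapply(seq_len(nrow(df)), function(i) {
    al <- df$cell_set_aligned_alias[i]
    if (!nzchar(al)) {
      return(data.frame(cell_set_accession_id = df$cell_set_accession_id[i],
                        aligned_alias = "", status = "unassigned",
                        class = "", message = ""))
    }
    res <- tryCatch(parse_aligned_alias(al, vocabulary), error = identity)
    if (inherits(res, "error")) {
      data.frame(cell_set_accession_id = df$cell_set_accession_id[i],
                 aligned_alias = al, status = "fail", class = "",
                 message = conditionMessage(res))
    } else {
      data.frame(cell_set_accession_id = df$cell_set_accession_id[i],
                 aligned_alias = al, status = "ok", class = res$class,
                 message = "")
    }
  })
  out <- do.call(rbind, rows)
  summary <- table(ifelse(out$status == "ok", out$class, out$status))
  attr(out, "summary") <- summary
  out
}
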