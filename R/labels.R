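# Cell set labels: the within-taxonomy membership language.
#
# A label is a prefix (e.g. "MTG", "RNA-seq", "Metadata") followed by a
# compact, zero-padded list of leaf numerals in range notation, e.g.
# "RNA-seq 040, 046-047, 050-052, 068". Labels are the machine-readable tie
# between composite cell sets and the provisional cell types they contain.
#
# Machine output uses the ASCII hyphen-minus as range separator; parsers
# additionally accept the typographic en and em dashes that appear in print.

.range_seps <- "[-–—]"

#' Compact a set of leaf numerals into a cell set label
#'
#' Collapses maximal runs of consecutive integers into `lo-hi` ranges,
#' leaves singletons as singletons, zero-pads numerals, and joins terms
#' with `", "` after the prefix.
#'
#' @param prefix Label prefix token(s), e.g. `"MTG"`.
#' @param numerals Non-empty set of positive integers (leaf numerals).
#' @param pad_width Zero-padding width for rendered numerals (default 3).
#' @return The label as a single string.
#' @examples
#' compact_labels("MTG", 1:6)                      # "MTG 001-006"
#' compact_labels("RNA-seq", c(40, 46, 47, 50:52, 68))
#' @seealso [expand_label()], [parse_label()]
#' @export
compact_labels <- function(prefix, numerals, pad_width = 3L) {
  numerals <- sort(unique(as.integer(numerals)))
  if (length(numerals) == 0L || anyNA(numerals)) {
    stop("`numerals` must be a non-empty set of integers", call. = FALSE)
  }
  if (any(numerals < 0L)) {
    stop("`numerals` must be non-negative", call. = FALSE)
  }
  pad_width <- as.integer(pad_width)
  if (is.na(pad_width) || pad_width < 1L) {
    stop("`pad_width` must be a positive integer", call. = FALSE)
  }
  pad <- function(n) formatC(n, width = pad_width, flag = "0")
  # maximal runs of consecutive integers
  run_id <- cumsum(c(1L, diff(numerals) != 1L))
  terms <- vapply(split(numerals, run_id), function(run) {
    if (length(run) == 1L) pad(run) else paste0(pad(run[1L]), "-", pad(run[length(run)]))
  }, character(1L))
  paste0(prefix, " ", paste(terms, collapse = ", "))
}

#' Parse a cell set label into prefix, numerals, and padding
#'
#' Parsing is padding-agnostic (`"MTG 001"` and `"MTG 1"` carry the same
#' numeral) and accepts hyphen-minus, en dash, or em dash as range
#' separator. The observed digit width is retained so that re-rendering
#' reproduces the input's padding.
#'
#' @param text A single label string.
#' @return A list of class `ccn_label` with `prefix`, `numerals` (expanded
#'   integer vector, sorted), `pad_width`, and `terms` (a data.frame of
#'   `lo`,`hi` range bounds).
#' @export
parse_label <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("label must be a single string", call. = FALSE)
  }
  term_re <- paste0("[0-9]+(\\s*", .range_seps, "\\s*[0-9]+)?")
  tail_re <- paste0("\\s+", term_re, "(\\s*,\\s*", term_re, ")*$")
  m <- regexpr(tail_re, text, perl = TRUE)
  if (m == -1L) {
    stop("label '", text, "': no numeral list found after prefix",
         call. = FALSE)
  }
  prefix <- substr(text, 1L, m - 1L)
  if (!nzchar(trimws(prefix))) {
    stop("label '", text, "': empty prefix", call. = FALSE)
  }
  numerals_part <- trimws(substring(text, m))
  raw_terms <- trimws(strsplit(numerals_part, ",")[[1L]])
  lo <- integer(0); hi <- integer(0); width <- 1L
  for (term in raw_terms) {
    bits <- trimws(strsplit(term, .range_seps)[[1L]])
    width <- max(width, nchar(bits))
    if (length(bits) == 1L) {
      a <- as.integer(bits); b <- a
    } else if (length(bits) == 2L) {
      a <- as.integer(bits[1L]); b <- as.integer(bits[2L])
      if (b < a) {
        stop("label '", text, "': malformed range '", term,
             "' (upper bound below lower)", call. = FALSE)
      }
    } else {
      stop("label '", text, "': malformed term '", term, "'", call. = FALSE)
    }
    lo <- c(lo, a); hi <- c(hi, b)
  }
  numerals <- sort(unique(unlist(mapply(seq.int, lo, hi, SIMPLIFY = FALSE))))
  structure(
    list(prefix = trimws(prefix), numerals = numerals,
         pad_width = as.integer(width),
         terms = data.frame(lo = lo, hi = hi)),
    class = "ccn_label"
  )
}

#' @export
format.ccn_label <- function(x, ...) {
  compact_labels(x$prefix, x$numerals, x$pad_width)
}

#' @export
print.ccn_label <- function(x, ...) {
  cat("<cell set label> ", format(x), " (", length(x$numerals),
      " provisional type", if (length(x$numerals) != 1L) "s", ")\n", sep = "")
  invisible(x)
}

#' Expand a cell set label into its member leaf labels
#'
#' Enumerates every provisional cell type covered by a composite label,
#' rendering each member as `<prefix> <zero-padded numeral>`.
#'
#' @param label A label string or a parsed `ccn_label`.
#' @param pad_width Optional override of the zero-padding width; defaults to
#'   the width observed in the label.
#' @return Character vector of member leaf labels, in ascending numeral
#'   order.
#' @examples
#' expand_label("MTG 001-006")
#' @export
expand_label <- function(label, pad_width = NULL) {
  if (is.character(label)) label <- parse_label(label)
  stopifnot(inherits(label, "ccn_label"))
  if (is.null(pad_width)) pad_width <- label$pad_width
  paste0(label$prefix, " ",
         formatC(label$numerals, width = pad_width, flag = "0"))
}

#' Leaf numerals covered by a cell set label
#' @param label A label string or parsed `ccn_label`.
#' @return Sorted integer vector.
#' @export
label_numerals <- function(label) {
  if (is.character(label)) label <- parse_label(label)
  label$numerals
}
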