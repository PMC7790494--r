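#' Mint a CCN taxonomy id
#'
#' A taxonomy id tags one classification result (one algorithm applied to one
#' dataset) and has the form `CCN[YYYYMMDD][#]`, where the trailing index
#' disambiguates multiple taxonomies minted on the same day.
#'
#' @param date A `Date`, or a string accepted by [as.Date()] (e.g.
#'   `"2019-08-21"`).
#' @param index Non-negative integer disambiguating taxonomies minted on the
#'   same day. Usually a single digit starting at 0, but larger indices are
#'   legal.
#' @return An object of class `ccn_taxonomy_id` with fields `date` and
#'   `index`; its [format()] method renders the `CCN...` string.
#' @examples
#' make_taxonomy_id("2019-08-21", 0)   # CCN201908210
#' @seealso [parse_taxonomy_id()], [make_accession()]
#' @export
make_taxonomy_id <- function(date, index = 0L) {
  if (!inherits(date, "Date")) {
    date <- tryCatch(as.Date(date), error = function(e) NA)
  }
  if (length(date) != 1L || is.na(date)) {
    stop("`date` is not a valid calendar date", call. = FALSE)
  }
  index <- as.integer(index)
  if (length(index) != 1L || is.na(index) || index < 0L) {
    stop("`index` must be a single non-negative integer", call. = FALSE)
  }
  structure(list(date = date, index = index), class = "ccn_taxonomy_id")
}

#' @export
format.ccn_taxonomy_id <- function(x, ...) {
  sprintf("CCN%s%d", format(x$date, "%Y%m%d"), x$index)
}

#' @export
print.ccn_taxonomy_id <- function(x, ...) {
  cat("<taxonomy id> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.ccn_taxonomy_id <- function(x, ...) format(x)

#' Parse a CCN taxonomy id string
#'
#' Inverse of [make_taxonomy_id()]'s rendering: splits `CCN[YYYYMMDD][#]`
#' into its calendar date and same-day index, rejecting malformed input with
#' an error that names the offending segment.
#'
#' @param text A single string such as `"CCN201912131"`.
#' @return A `ccn_taxonomy_id`.
#' @examples
#' parse_taxonomy_id("CCN201912131")
#' @export
parse_taxonomy_id <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("taxonomy id must be a single string", call. = FALSE)
  }
  if (!startsWith(text, "CCN")) {
    stop("taxonomy id '", text, "': prefix must be 'CCN'", call. = FALSE)
  }
  body <- substring(text, 4L)
  if (!grepl("^[0-9]+$", body)) {
    stop("taxonomy id '", text, "': digits expected after 'CCN'",
         call. = FALSE)
  }
  if (nchar(body) < 9L) {
    stop("taxonomy id '", text,
         "': needs 8 date digits (YYYYMMDD) plus an index", call. = FALSE)
  }
  date_str <- substr(body, 1L, 8L)
  date <- as.Date(date_str, format = "%Y%m%d")
  # as.Date() silently rolls some bad dates; re-render to catch them
  if (is.na(date) || format(date, "%Y%m%d") != date_str) {
    stop("taxonomy id '", text, "': impossible date segment '", date_str,
         "'", call. = FALSE)
  }
  index <- suppressWarnings(as.integer(substring(body, 9L)))
  if (is.na(index)) {
    stop("taxonomy id '", text, "': bad index segment", call. = FALSE)
  }
  make_taxonomy_id(date, index)
}

#' Test whether a string is a well-formed taxonomy id
#' @param text Character vector.
#' @return Logical vector.
#' @export
is_taxonomy_id <- function(text) {
  vapply(text, function(t) {
    !inherits(tryCatch(parse_taxonomy_id(t), error = identity), "error")
  }, logical(1L), USE.NAMES = FALSE)
}

#' Mint a cell set accession id
#'
#' Accession ids track cell sets across the entire universe of taxonomies:
#' `CS[YYYYMMDD][#]_[unique # within taxonomy]`. The date and index digits
#' always match the owning taxonomy id; the within-taxonomy number is
#' 1-based, unpadded, and never reused.
#'
#' @param taxonomy A `ccn_taxonomy_id` or a taxonomy id string.
#' @param n Positive integer, unique within the taxonomy.
#' @return The accession id as a string, e.g. `"CS201908210_154"`.
#' @examples
#' make_accession("CCN201912131", 40)
#' @export
make_accession <- function(taxonomy, n) {
  if (is.character(taxonomy)) taxonomy <- parse_taxonomy_id(taxonomy)
  stopifnot(inherits(taxonomy, "ccn_taxonomy_id"))
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) {
    stop("accession number must be a positive integer", call. = FALSE)
  }
  sprintf("CS%s%d_%d", format(taxonomy$date, "%Y%m%d"), taxonomy$index, n)
}

#' Parse a cell set accession id
#'
#' @param text A single accession string, e.g. `"CS201912131_40"`.
#' @return A list with `taxonomy` (a `ccn_taxonomy_id`) and `number`.
#' @export
parse_accession <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("accession must be a single string", call. = FALSE)
  }
  m <- regmatches(text, regexec("^CS([0-9]{8}[0-9]+)_([0-9]+)$", text))[[1L]]
  if (length(m) == 0L) {
    stop("accession '", text, "': expected CS[YYYYMMDD][#]_[#]",
         call. = FALSE)
  }
  taxonomy <- parse_taxonomy_id(paste0("CCN", m[2L]))
  number <- as.integer(m[3L])
  if (number < 1L) {
    stop("accession '", text, "': number must be >= 1", call. = FALSE)
  }
  list(taxonomy = taxonomy, number = number)
}

# taxonomy-id digits of an accession string, e.g. "CS201912131_40" -> "CCN201912131"
accession_taxonomy <- function(text) {
  sub("^CS([0-9]+)_[0-9]+$", "CCN\\1", text)
}

# within-taxonomy number of an accession string
accession_number <- function(text) {
  as.integer(sub("^CS[0-9]+_([0-9]+)$", "\\1", text))
}
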