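#' Parse AAIndex1 flat-file property records
#'
#' Reads the AAIndex1 format: records separated by `//`, with `H` (accession),
#' `D` (description) and `I` (values) sections. The `I` section header lists
#' the residues as ten `X/Y` pairs (A/L, R/K, ...) followed by two rows of
#' ten values; values are remapped to residue symbols so downstream code is
#' independent of that layout. Records containing `NA` values are kept but
#' flagged `has_na = TRUE` and excluded from screening.
#'
#' @param source Path to an AAIndex1 flat file, or the raw text (detected by
#'   embedded newlines).
#' @return A tibble with columns `accession`, `description`, `has_na` and a
#'   list-column `values` of named 20-vectors (named in alphabetical residue
#'   order; NA entries preserved).
#' @examples
#' f <- system.file("extdata", "aaindex_demo.txt", package = "scmpep")
#' read_aaindex(f)
#' @export
read_aaindex <- function(source) {
  lines <- read_source_lines(source)
  recs <- split(lines, cumsum(dplyr::lag(lines == "//", default = FALSE)))
  recs <- purrr::keep(recs, function(r) any(startsWith(r, "H ")))
  if (length(recs) == 0L) {
    abort("no AAIndex records found in input")
  }
  purrr::map_dfr(recs, parse_aaindex_record)
}

parse_aaindex_record <- function(rec) {
  grab <- function(key) {
    i <- which(startsWith(rec, paste0(key, " ")))
    if (length(i) == 0L) return("")
    # continuation lines are indented
    j <- i[1L]
    out <- sub(paste0("^", key, " +"), "", rec[j])
    while (j + 1L <= length(rec) && startsWith(rec[j + 1L], "  ")) {
      j <- j + 1L
      out <- paste(out, trimws(rec[j]))
    }
    out
  }
  acc <- grab("H")
  i_idx <- which(startsWith(rec, "I "))
  if (length(i_idx) == 0L) {
    abort(sprintf("record '%s': missing I (values) section", acc))
  }
  val_lines <- rec[(i_idx[1L] + 1L):min(i_idx[1L] + 2L, length(rec))]
  fields <- unlist(strsplit(trimws(val_lines), "[ \t]+"))
  fields <- fields[nzchar(fields)]
  if (length(fields) != 20L) {
    abort(sprintf("record '%s': I section has %d fields, expected 20",
                  acc, length(fields)))
  }
  vals <- suppressWarnings(as.numeric(fields))
  bad <- is.na(vals) & !(toupper(fields) %in% c("NA", "NA."))
  if (any(bad)) {
    abort(sprintf("record '%s': unparseable value '%s' in I section",
                  acc, fields[bad][1L]))
  }
  v <- setNames(vals, AAINDEX_ORDER)[AA_ALPHABET]
  tibble(
    accession = acc,
    description = grab("D"),
    has_na = anyNA(v),
    values = list(v)
  )
}

#' Pearson correlation between a score card and a property scale
#'
#' Pairs the 20 values by residue symbol and returns the standard Pearson
#' correlation. Returns `NA` (with a warning) when either side has zero
#' variance.
#'
#' @param card A `score_card`.
#' @param values Named numeric vector over the 20 residues, or a one-row
#'   slice of [read_aaindex()] output's `values` list-column.
#' @return Pearson r, or `NA` if undefined.
#' @examples
#' card <- scm_reference_card()
#' pcp_correlation(card, card$scores)
#' @export
pcp_correlation <- function(card, values) {
  stopifnot(inherits(card, "score_card"))
  if (is.list(values) && !is.data.frame(values)) values <- values[[1L]]
  if (is.null(names(values)) || !setequal(names(values), AA_ALPHABET)) {
    abort("`values` must be named with the 20 standard residues")
  }
  v <- values[AA_ALPHABET]
  if (anyNA(v)) {
    abort("property contains NA values; exclude it from correlation")
  }
  if (stats::sd(v) == 0 || stats::sd(card$scores) == 0) {
    warn("zero variance: correlation undefined, returning NA")
    return(NA_real_)
  }
  cor(card$scores, v)
}

#' Screen property scales by correlation with a score card
#'
#' Excludes NA-flagged records, computes the Pearson correlation of each
#' remaining property with the card, ranks by descending (signed) r and
#' flags candidates whose r strictly exceeds `min_r`. The convention that
#' r > 0.5 marks a property as informative about the positive class drives
#' the default.
#'
#' @param card A `score_card`.
#' @param pcps A tibble from [read_aaindex()], or any tibble with columns
#'   `accession` and `values` (list of named 20-vectors).
#' @param min_r Candidacy threshold (strict inequality).
#' @return A tibble with columns `accession`, `description`, `r`, `rank`,
#'   `candidate`, ordered by rank.
#' @export
screen_properties <- function(card, pcps, min_r = 0.5) {
  stopifnot(is.data.frame(pcps), all(c("accession", "values") %in% names(pcps)))
  if ("has_na" %in% names(pcps)) {
    pcps <- pcps[!pcps$has_na, , drop = FALSE]
  }
  if (nrow(pcps) == 0L) {
    abort("no usable (NA-free) property records to screen")
  }
  out <- tibble(
    accession = pcps$accession,
    description = if ("description" %in% names(pcps)) pcps$description else NA_character_,
    r = purrr::map_dbl(pcps$values, function(v) pcp_correlation(card, v))
  )
  out$rank <- rank(-out$r, ties.method = "first")
  out$candidate <- out$r > min_r
  dplyr::arrange(out, .data$rank)
}
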