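#' Round half away from zero
#'
#' Rounds to the nearest integer with ties at .5 resolved away from zero
#' (112.5 becomes 113), matching how printed integer THP scores are derived
#' from raw weighted-sum scores. Base `round()` rounds half to even and is
#' not suitable here.
#'
#' @param x Numeric vector.
#' @return Numeric vector of integers (as doubles).
#' @examples
#' round_half_away(c(112.5, -112.5, 683.57))
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Validate peptide sequences: uppercase, non-empty, 20-letter alphabet only.
# Errors name the offending record and character.
check_sequences <- function(seqs, ids = NULL) {
  if (length(seqs) == 0L) {
    abort("no sequences supplied")
  }
  ids <- ids %||% paste0("seq", seq_along(seqs))
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs))) {
    abort(sprintf("empty sequence in record '%s'", ids[!nzchar(seqs)][1L]))
  }
  pos <- regexpr(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), seqs)
  if (any(pos > 0L)) {
    i <- which(pos > 0L)[1L]
    abort(sprintf(
      "invalid residue '%s' in record '%s': sequences must use only the 20 standard amino acids",
      substr(seqs[i], pos[i], pos[i]), ids[i]
    ))
  }
  seqs
}

# Coerce a peptide input (character vector or data frame with a `seq` column)
# to a validated tibble with id / seq (/ label) columns.
as_peptide_tbl <- function(x, label = NULL) {
  if (is.character(x)) {
    x <- tibble(id = paste0("seq", seq_along(x)), seq = x)
  }
  if (!is.data.frame(x) || !"seq" %in% names(x)) {
    abort("expected a character vector of sequences or a data frame with a `seq` column")
  }
  x <- as_tibble(x)
  if (!"id" %in% names(x)) {
    x$id <- paste0("seq", seq_len(nrow(x)))
  }
  x$seq <- check_sequences(x$seq, x$id)
  if (!is.null(label)) {
    x$label <- as.integer(label)
  }
  x[, union(c("id", "seq"), names(x))]
}
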