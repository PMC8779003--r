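#' Create a propensity score card
#'
#' A score card assigns each of the 20 standard residues a propensity score,
#' conventionally on a 0–1000 scale, expressing its tendency to occur in the
#' positive (e.g., tumor-homing) class. A card may carry a decision cutoff:
#' peptides whose weighted-sum score strictly exceeds the cutoff are called
#' positive.
#'
#' @param scores Named numeric vector with exactly one entry per standard
#'   residue (names are one-letter codes, any order).
#' @param cutoff Optional decision threshold.
#' @param origin One of `"initial"`, `"optimized"`, `"literature"`.
#' @return An object of class `score_card`.
#' @examples
#' card <- scm_reference_card()
#' card
#' @export
score_card <- function(scores, cutoff = NULL, origin = "literature") {
  origin <- match.arg(origin, c("initial", "optimized", "literature"))
  if (is.data.frame(scores)) {
    scores <- setNames(scores$score, scores$residue)
  }
  if (is.null(names(scores)) || !setequal(names(scores), AA_ALPHABET) ||
      length(scores) != 20L) {
    abort("`scores` must be a named vector covering exactly the 20 standard residues")
  }
  scores <- scores[AA_ALPHABET]
  if (anyNA(scores)) {
    abort("score card contains missing values")
  }
  if (!is.null(cutoff)) {
    stopifnot(is.numeric(cutoff), length(cutoff) == 1L)
  }
  structure(
    list(scores = scores, cutoff = cutoff, origin = origin),
    class = "score_card"
  )
}

#' @export
print.score_card <- function(x, ...) {
  cat(sprintf("<score_card> origin: %s; cutoff: %s\n", x$origin,
              if (is.null(x$cutoff)) "none" else format(x$cutoff)))
  print(x$scores)
  invisible(x)
}

#' @rdname tidy.scm_fit
#' @method tidy score_card
#' @export
tidy.score_card <- function(x, ...) {
  tibble(
    residue = names(x$scores),
    score = unname(x$scores),
    rank = unname(rank(-x$scores, ties.method = "min"))
  ) |>
    dplyr::arrange(.data$rank)
}

#' @rdname tidy.scm_fit
#' @method glance score_card
#' @export
glance.score_card <- function(x, ...) {
  tibble(
    origin = x$origin,
    min_score = min(x$scores),
    max_score = max(x$scores),
    cutoff = if (is.null(x$cutoff)) NA_real_ else x$cutoff
  )
}

#' Read / write a score card as tab-separated text
#'
#' The on-disk format is a two-column TSV (residue, score) with an optional
#' `#cutoff=<value>` comment line.
#'
#' @param path File path.
#' @param card A `score_card`.
#' @param origin Origin recorded on the card read back.
#' @return `read_score_card()` returns a `score_card`; `write_score_card()`
#'   returns `path` invisibly.
#' @export
read_score_card <- function(path, origin = "literature") {
  lines <- readLines(path, warn = FALSE)
  cutoff <- NULL
  cut_line <- grep("^#cutoff=", lines, value = TRUE)
  if (length(cut_line) > 0L) {
    cutoff <- as.numeric(sub("^#cutoff=", "", cut_line[1L]))
  }
  lines <- lines[!startsWith(lines, "#")]
  dat <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                           col.names = c("residue", "score"),
                           colClasses = c("character", "numeric"))
  score_card(setNames(dat$score, dat$residue), cutoff = cutoff, origin = origin)
}

#' @rdname read_score_card
#' @export
write_score_card <- function(card, path) {
  stopifnot(inherits(card, "score_card"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(card$cutoff)) {
    writeLines(sprintf("#cutoff=%s", format(card$cutoff, digits = 15)), con)
  }
  writeLines(sprintf("%s\t%s", names(card$scores),
                     format(card$scores, digits = 15, trim = TRUE)), con)
  invisible(path)
}

#' Amino-acid composition of peptide sequences
#'
#' Computes, for each sequence, the fraction of each of the 20 standard
#' residues (count divided by length). Rows sum to 1.
#'
#' @param seqs Character vector of validated peptide sequences.
#' @return A numeric matrix with one row per sequence and 20 columns in
#'   alphabetical residue order.
#' @examples
#' aa_composition("CFWPNRC")
#' @export
aa_composition <- function(seqs) {
  seqs <- check_sequences(seqs)
  chars <- strsplit(seqs, "", fixed = TRUE)
  m <- t(vapply(chars, function(v) {
    tabulate(factor(v, levels = AA_ALPHABET), nbins = 20L) / length(v)
  }, numeric(20L)))
  colnames(m) <- AA_ALPHABET
  rownames(m) <- NULL
  m
}

#' Score peptides with a propensity card
#'
#' The weighted-sum score of a peptide is the dot product of its amino-acid
#' composition with the card's propensity scores — equivalently the mean
#' propensity over sequence positions. The reported integer score rounds the
#' raw score half away from zero. When a cutoff is available a strict-greater
#' classification is added: `prediction = 1` iff `raw_score > cutoff`.
#'
#' @param peptides Data frame with a `seq` column, or character vector of
#'   sequences.
#' @param card A `score_card`.
#' @param cutoff Optional cutoff overriding the card's own.
#' @return The input as a tibble with columns `raw_score`, `thp_score`
#'   (rounded integer) and, if a cutoff is available, `prediction`.
#' @examples
#' score_peptides(c("CFWPNRC", "IKIQD"), scm_reference_card())
#' @export
score_peptides <- function(peptides, card, cutoff = NULL) {
  stopifnot(inherits(card, "score_card"))
  out <- as_peptide_tbl(peptides)
  comp <- aa_composition(out$seq)
  out$raw_score <- as.numeric(comp %*% card$scores)
  out$thp_score <- round_half_away(out$raw_score)
  cutoff <- cutoff %||% card$cutoff
  if (!is.null(cutoff)) {
    out$prediction <- classify_scores(out$raw_score, cutoff)
  }
  out
}

#' Classify raw scores against a cutoff
#'
#' Strict inequality: a peptide scoring exactly the cutoff is classified
#' negative.
#'
#' @param raw_scores Numeric vector of raw weighted-sum scores.
#' @param cutoff Decision threshold.
#' @return Integer vector of 0/1 predictions.
#' @export
classify_scores <- function(raw_scores, cutoff) {
  stopifnot(is.numeric(raw_scores), is.numeric(cutoff), length(cutoff) == 1L)
  as.integer(raw_scores > cutoff)
}
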