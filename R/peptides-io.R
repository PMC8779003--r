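#' Read peptide sequences from FASTA or plain sequence-list text
#'
#' Reads peptides from a file path or a literal text string. Two dialects are
#' auto-detected: FASTA (any line beginning with `>`) and plain one-sequence-
#' per-line lists, the format in which peptide benchmark sets are commonly
#' distributed. Sequences are uppercased and validated against the 20-letter
#' amino-acid alphabet; ambiguous residues (B, J, O, U, X, Z), gaps and stop
#' characters are rejected with an error naming the record.
#'
#' @param source Path to a file, or a character string containing the raw
#'   text (detected by the presence of a newline or a `>`).
#' @param label Optional class label (1 = positive, 0 = negative) applied to
#'   every record read.
#' @return A tibble with columns `id`, `seq` and, when `label` is given,
#'   `label`.
#' @examples
#' read_peptides(">p1\nCFWPNRC", label = 1)
#' read_peptides("IKIQD\nWREWFL")
#' @export
read_peptides <- function(source, label = NULL) {
  lines <- read_source_lines(source)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    abort("empty input: no sequences found")
  }
  if (any(startsWith(lines, ">"))) {
    tf <- tempfile(fileext = ".fasta")
    on.exit(unlink(tf), add = TRUE)
    writeLines(lines, tf)
    recs <- seqinr::read.fasta(tf, seqtype = "AA", as.string = TRUE, seqonly = FALSE)
    out <- tibble(
      id = unname(vapply(recs, function(r) attr(r, "name"), character(1))),
      seq = toupper(unname(vapply(recs, function(r) as.character(r)[1L], character(1))))
    )
  } else {
    out <- tibble(id = paste0("seq", seq_along(lines)), seq = toupper(lines))
  }
  out$seq <- check_sequences(out$seq, out$id)
  if (!is.null(label)) {
    stopifnot(label %in% c(0L, 1L))
    out$label <- as.integer(label)
  }
  out
}

read_source_lines <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  if (!nzchar(trimws(source))) {
    return(character(0))
  }
  if (grepl("\n", source, fixed = TRUE) || startsWith(source, ">")) {
    return(strsplit(source, "\n", fixed = TRUE)[[1L]])
  }
  if (file.exists(source)) {
    return(readLines(source, warn = FALSE))
  }
  # a bare token that cannot be a path is taken as a single literal sequence
  if (grepl("^[A-Za-z*-]+$", source)) {
    return(source)
  }
  abort(sprintf("file not found: '%s'", source))
}

#' Write peptides to a FASTA file
#'
#' @param peptides A data frame with `id` and `seq` columns (as returned by
#'   [read_peptides()]), or a character vector of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(peptides, path) {
  peptides <- as_peptide_tbl(peptides)
  seqinr::write.fasta(
    sequences = as.list(peptides$seq),
    names = peptides$id,
    file.out = path,
    as.string = TRUE,
    nbchar = 10000L
  )
  invisible(path)
}

#' Assemble a labeled peptide dataset from positive and negative sets
#'
#' Combines positives (label forced to 1) and negatives (label forced to 0)
#' into one labeled tibble suitable for training and evaluation. Duplicate
#' sequences are permitted — published peptide benchmarks contain them — but
#' their count is reported via a message so repeated entries are visible.
#'
#' @param positives,negatives Data frames with a `seq` column, or character
#'   vectors of sequences. Both must be non-empty.
#' @param name Dataset name, stored in the `dataset` attribute.
#' @return A tibble with columns `id`, `seq`, `label`; positives first.
#' @examples
#' build_dataset(c("CFWPNRC", "WREWFL"), c("IKIQD"), name = "demo")
#' @export
build_dataset <- function(positives, negatives, name = "dataset") {
  if (length(positives) == 0L || (is.data.frame(positives) && nrow(positives) == 0L)) {
    abort("`positives` must be non-empty")
  }
  if (length(negatives) == 0L || (is.data.frame(negatives) && nrow(negatives) == 0L)) {
    abort("`negatives` must be non-empty")
  }
  pos <- as_peptide_tbl(positives, label = 1L)
  neg <- as_peptide_tbl(negatives, label = 0L)
  out <- dplyr::bind_rows(
    pos[, c("id", "seq", "label")],
    neg[, c("id", "seq", "label")]
  )
  out$id <- make.unique(out$id, sep = "_")
  ndup <- sum(duplicated(out$seq))
  if (ndup > 0L) {
    inform(sprintf("dataset '%s': %d duplicated sequence(s) retained", name, ndup))
  }
  attr(out, "dataset") <- name
  out
}

#' Write a dataset manifest as tab-separated text
#'
#' @param dataset A labeled peptide tibble from [build_dataset()].
#' @param path Output TSV path (columns id, sequence, label).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(dataset, path) {
  utils::write.table(
    data.frame(id = dataset$id, sequence = dataset$seq, label = dataset$label),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
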