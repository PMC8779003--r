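# Free amino-acid average molecular weights (Da), two-decimal convention.
# Peptide MW = sum of free residues minus 18.00 per peptide bond; this
# two-decimal table reproduces published peptide calculators to ~0.05 Da.
FREE_AA_MW <- c(
  A = 89.09, R = 174.20, N = 132.12, D = 133.10, C = 121.16, E = 147.13,
  Q = 146.15, G = 75.07, H = 155.15, I = 131.17, L = 131.17, K = 146.19,
  M = 149.21, F = 165.19, P = 115.13, S = 105.09, T = 119.12, V = 117.15,
  W = 204.23, Y = 181.19
)

residue_counts <- function(seqs, residues) {
  chars <- strsplit(check_sequences(seqs), "", fixed = TRUE)
  vapply(chars, function(v) sum(v %in% residues), numeric(1))
}

#' Molar extinction coefficient at 280 nm
#'
#' The chromophores at 280 nm are tryptophan (5500 M^-1 cm^-1), tyrosine
#' (1490) and cystine, the disulfide-bonded cysteine pair (125 per pair).
#' Cysteines are assumed maximally paired: `floor(n_Cys / 2)` pairs, so a
#' lone cysteine contributes nothing.
#'
#' @param seqs Character vector of peptide sequences.
#' @return Integer vector of extinction coefficients (M^-1 cm^-1).
#' @examples
#' extinction_coefficient(c("CFWPNRC", "IKIQD"))
#' @export
extinction_coefficient <- function(seqs) {
  5500 * residue_counts(seqs, "W") +
    1490 * residue_counts(seqs, "Y") +
    125 * (residue_counts(seqs, "C") %/% 2)
}

#' Net charge at neutral pH (integer counting rule)
#'
#' Counts Arg and Lys as +1 and Asp and Glu as -1; His is treated as
#' neutral, termini are ignored.
#'
#' @param seqs Character vector of peptide sequences.
#' @return Integer vector of net charges.
#' @examples
#' net_charge(c("HKNKGKKN", "DVGTTE"))
#' @export
net_charge <- function(seqs) {
  residue_counts(seqs, c("R", "K")) - residue_counts(seqs, c("D", "E"))
}

#' Peptide molecular weight (average masses)
#'
#' Sum of free amino-acid average masses minus 18.00 Da per peptide bond.
#'
#' @param seqs Character vector of peptide sequences.
#' @return Numeric vector of molecular weights in daltons.
#' @examples
#' molecular_weight("IKIQD")
#' @export
molecular_weight <- function(seqs) {
  chars <- strsplit(check_sequences(seqs), "", fixed = TRUE)
  vapply(chars, function(v) sum(FREE_AA_MW[v]) - 18.00 * (length(v) - 1L),
         numeric(1))
}

#' Physicochemical profile table of scored peptides
#'
#' Scores each peptide with the card, computes length, molecular weight,
#' 280 nm extinction coefficient and net charge, sorts by rounded THP score
#' (descending) and appends a summary row of column means (sequence
#' `"(mean)"`).
#'
#' @param peptides Data frame with a `seq` column or character vector; may
#'   be empty (returns an empty table).
#' @param card A `score_card`.
#' @return A tibble with columns `seq`, `thp_score`, `length`,
#'   `molecular_weight`, `extinction_coefficient`, `net_charge`.
#' @examples
#' profile_table(c("CFWPNRC", "WREWFL", "IKIQD"), scm_reference_card())
#' @export
profile_table <- function(peptides, card) {
  if (length(peptides) == 0L ||
      (is.data.frame(peptides) && nrow(peptides) == 0L)) {
    return(tibble(
      seq = character(), thp_score = numeric(), length = integer(),
      molecular_weight = numeric(), extinction_coefficient = numeric(),
      net_charge = numeric()
    ))
  }
  scored <- score_peptides(peptides, card)
  out <- tibble(
    seq = scored$seq,
    thp_score = scored$thp_score,
    length = nchar(scored$seq),
    molecular_weight = molecular_weight(scored$seq),
    extinction_coefficient = extinction_coefficient(scored$seq),
    net_charge = net_charge(scored$seq)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$thp_score))
  means <- dplyr::summarise(out, dplyr::across(dplyr::where(is.numeric), mean))
  dplyr::bind_rows(out, dplyr::bind_cols(tibble(seq = "(mean)"), means))
}
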