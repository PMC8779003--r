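# Independent brute-force oracles used to cross-check the vectorized
# implementations. These deliberately avoid the package's computation paths.

# position-sum scoring: mean propensity over sequence positions
oracle_score <- function(seq, scores) {
  mean(scores[strsplit(seq, "")[[1]]])
}

# pairwise Mann-Whitney AUC: enumerate all positive-negative pairs
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  pairs <- expand.grid(p = pos, n = neg)
  mean((pairs$p > pairs$n) + 0.5 * (pairs$p == pairs$n))
}

# MCC as the Pearson correlation of the 0/1 prediction and label vectors
oracle_mcc <- function(predictions, labels) {
  if (sd(predictions) == 0 || sd(labels) == 0) return(0)
  cor(predictions, labels)
}

random_peptides <- function(n, len_range = c(3, 30), seed = 1) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      L <- sample(seq(len_range[1], len_range[2]), 1)
      paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], L,
                   replace = TRUE), collapse = "")
    }, character(1))
  })
}
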