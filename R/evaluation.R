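#' Confusion counts for binary predictions
#'
#' @param predictions,labels Equal-length 0/1 vectors; `labels` are the truth.
#' @return A one-row tibble with columns `tp`, `tn`, `fp`, `fn`.
#' @examples
#' confusion_counts(c(1, 0, 1), c(1, 1, 0))
#' @export
confusion_counts <- function(predictions, labels) {
  if (length(predictions) != length(labels)) {
    abort("`predictions` and `labels` must have equal length")
  }
  if (length(labels) < 1L) {
    abort("need at least one observation")
  }
  predictions <- as.integer(predictions)
  labels <- as.integer(labels)
  stopifnot(all(predictions %in% 0:1), all(labels %in% 0:1))
  tibble(
    tp = sum(predictions == 1L & labels == 1L),
    tn = sum(predictions == 0L & labels == 0L),
    fp = sum(predictions == 1L & labels == 0L),
    fn = sum(predictions == 0L & labels == 1L)
  )
}

#' Classification metrics: accuracy, sensitivity, specificity, MCC, AUC
#'
#' Computes the standard confusion-matrix metrics
#' \deqn{ACC = (TP+TN)/(TP+TN+FP+FN)}
#' \deqn{Sn = TP/(TP+FN), \quad Sp = TN/(TN+FP)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' MCC is defined as 0 when any factor of its denominator is zero; Sn/Sp are
#' `NaN` when their class is absent. AUC is added when raw scores are
#' supplied.
#'
#' @param counts A one-row confusion tibble from [confusion_counts()], or
#'   `NULL` to derive it from `predictions` and `labels`.
#' @param predictions Optional 0/1 predictions (used when `counts` is NULL).
#' @param labels True 0/1 labels (required for AUC).
#' @param scores Optional raw scores for AUC computation.
#' @return A one-row tibble with columns `acc`, `sn`, `sp`, `mcc` and `auc`
#'   (`NA` when no scores are given).
#' @examples
#' classification_metrics(confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0)))
#' @export
classification_metrics <- function(counts = NULL, predictions = NULL,
                                   labels = NULL, scores = NULL) {
  if (is.null(counts)) {
    counts <- confusion_counts(predictions, labels)
  }
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  auc <- if (!is.null(scores) && !is.null(labels)) roc_auc(scores, labels) else NA_real_
  tibble(
    acc = (tp + tn) / (tp + tn + fp + fn),
    sn = tp / (tp + fn),
    sp = tn / (tn + fp),
    mcc = mcc,
    auc = auc
  )
}

#' Area under the ROC curve
#'
#' Rank-based (Mann–Whitney) estimator with midrank tie handling: the
#' probability that a random positive outscores a random negative, ties
#' counted one half. Identical to the trapezoidal area under the empirical
#' ROC curve.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(3, 2, 1, 0), c(1, 0, 1, 0))
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    abort("AUC requires both classes to be present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return A tibble with columns `threshold`, `fpr`, `tpr`, one row per
#'   distinct score plus the two end points.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pts <- purrr::map_dfr(thr, function(t) {
    pred <- as.integer(scores > t)
    tibble(
      threshold = t,
      fpr = sum(pred == 1L & labels == 0L) / sum(labels == 0L),
      tpr = sum(pred == 1L & labels == 1L) / sum(labels == 1L)
    )
  })
  dplyr::distinct(pts, .data$fpr, .data$tpr, .keep_all = TRUE)
}

# Stratified fold assignment: within each class, fold labels are dealt in a
# seeded random order so class balance is preserved per fold.
make_folds <- function(labels, k, seed) {
  labels <- as.integer(labels)
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k) {
        abort(sprintf("class %d has fewer members (%d) than folds (%d)",
                      cl, length(idx), k))
      }
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Stratified k-fold cross-validation of a card-building procedure
#'
#' Splits the labeled dataset into `k` stratified folds, refits the supplied
#' training procedure on each training portion, scores the held-out fold with
#' the resulting card, pools the out-of-fold scores and predictions, and
#' returns a single metric set.
#'
#' @param dataset Labeled peptide tibble (columns `seq`, `label`).
#' @param card_builder Function taking a training tibble and returning a
#'   `score_card` carrying a cutoff (e.g. `initial_propensity_scores`
#'   composed with [select_cutoff()], or a GA training wrapper).
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return A one-row metrics tibble (see [classification_metrics()]) with an
#'   added `k` column.
#' @export
cross_validate <- function(dataset, card_builder, k = 10, seed = 1) {
  stopifnot(k >= 2)
  fold <- make_folds(dataset$label, k, seed)
  oof_score <- numeric(nrow(dataset))
  oof_pred <- integer(nrow(dataset))
  for (f in seq_len(k)) {
    holdout <- fold == f
    card <- card_builder(dataset[!holdout, , drop = FALSE])
    stopifnot(inherits(card, "score_card"))
    scored <- score_peptides(dataset[holdout, , drop = FALSE], card)
    oof_score[holdout] <- scored$raw_score
    cut <- card$cutoff
    if (is.null(cut)) {
      abort("`card_builder` must return a card with a cutoff")
    }
    oof_pred[holdout] <- classify_scores(scored$raw_score, cut)
  }
  m <- classification_metrics(
    confusion_counts(oof_pred, dataset$label),
    labels = dataset$label, scores = oof_score
  )
  m$k <- k
  m
}
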