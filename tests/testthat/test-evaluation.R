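test_that("confusion counts follow the 2x2 contingency", {
  expect_equal(confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0)),
               tibble::tibble(tp = 2L, tn = 2L, fp = 0L, fn = 0L))
  expect_equal(confusion_counts(c(0, 0, 1, 1), c(1, 1, 0, 0)),
               tibble::tibble(tp = 0L, tn = 0L, fp = 2L, fn = 2L))
  expect_equal(confusion_counts(c(1, 0, 1), c(1, 1, 0)),
               tibble::tibble(tp = 1L, tn = 0L, fp = 1L, fn = 1L))
  expect_error(confusion_counts(c(1, 0), c(1)), "equal length")
})

test_that("metrics reproduce closed-form values and degenerate conventions", {
  perfect <- classification_metrics(tibble::tibble(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_equal(perfect[, c("acc", "sn", "sp", "mcc")],
               tibble::tibble(acc = 1, sn = 1, sp = 1, mcc = 1))

  chance <- classification_metrics(tibble::tibble(tp = 25, tn = 25, fp = 25, fn = 25))
  expect_equal(chance$acc, 0.5)
  expect_equal(chance$mcc, 0)

  m <- classification_metrics(tibble::tibble(tp = 40, tn = 45, fp = 5, fn = 10))
  expect_equal(m$acc, 0.85)
  expect_equal(m$sn, 0.80)
  expect_equal(m$sp, 0.90)
  expect_equal(m$mcc, (40 * 45 - 5 * 10) / sqrt(45 * 50 * 50 * 55))
  expect_equal(round(m$mcc, 4), 0.7035)

  # all-positive predictions zero two denominator factors -> MCC 0 by convention
  degen <- classification_metrics(tibble::tibble(tp = 5, tn = 0, fp = 5, fn = 0))
  expect_equal(degen$mcc, 0)
})

test_that("MCC equals the prediction/label correlation on random vectors", {
  withr::with_seed(21, {
    for (i in 1:20) {
      n <- sample(4:30, 1)
      pred <- rbinom(n, 1, 0.5)
      lab <- rbinom(n, 1, 0.5)
      m <- classification_metrics(confusion_counts(pred, lab))
      expect_equal(m$mcc, oracle_mcc(pred, lab), tolerance = 1e-12)
    }
  })
})

test_that("rank-based AUC equals the brute-force pairwise statistic", {
  expect_equal(roc_auc(c(10, 9, 2, 1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(roc_auc(c(3, 2, 1, 0), c(1, 0, 1, 0)), 0.75)

  # exhaustive-ish check on short vectors with heavy ties
  withr::with_seed(22, {
    for (i in 1:40) {
      n <- sample(3:8, 1)
      lab <- c(1, 0, rbinom(n - 2, 1, 0.5))  # both classes guaranteed
      sc <- sample(0:3, n, replace = TRUE)
      expect_equal(roc_auc(sc, lab), oracle_auc(sc, lab))
    }
  })
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC is invariant under strictly increasing score transforms", {
  withr::with_seed(23, {
    sc <- rnorm(40)
    lab <- rbinom(40, 1, 0.5)
    lab[1:2] <- c(0, 1)
    a <- roc_auc(sc, lab)
    expect_equal(roc_auc(exp(sc), lab), a)
    expect_equal(roc_auc(rank(sc), lab), a)
    expect_equal(roc_auc(100 + 3 * sc, lab), a)
  })
})

test_that("rank AUC agrees with pROC's trapezoidal estimate", {
  skip_if_not_installed("pROC")
  withr::with_seed(24, {
    sc <- c(rnorm(30, 1), rnorm(30))
    lab <- rep(c(1, 0), each = 30)
    expect_equal(
      roc_auc(sc, lab),
      as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE, direction = "<")))
    )
  })
})

test_that("roc_points trace the empirical ROC from (0,0) to (1,1)", {
  pts <- roc_points(c(3, 2, 1, 0), c(1, 0, 1, 0))
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
})

test_that("cross-validation is stratified, seeded and exact on separable data", {
  d <- synth_peptides(n_pos = 60, n_neg = 60, bias = 60, seed = 31)
  builder <- function(train) {
    card <- initial_propensity_scores(train)
    sc <- score_peptides(train, card)
    score_card(card$scores, cutoff = select_cutoff(sc$raw_score, train$label),
               origin = "initial")
  }
  m1 <- cross_validate(d, builder, k = 6, seed = 1)
  m2 <- cross_validate(d, builder, k = 6, seed = 1)
  expect_equal(m1, m2)
  expect_gte(m1$auc, 0.99)
  expect_gte(m1$acc, 0.95)

  # fold sizes are balanced per class
  f <- scmpep:::make_folds(d$label, 6, seed = 2)
  expect_equal(as.vector(table(f[d$label == 1])), rep(10L, 6))
  expect_error(cross_validate(d[1:8, ], builder, k = 10), "fewer members")
})
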