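test_that("initial propensity scores are composition ratios rescaled to 0-1000", {
  # positives pure CW repeats, negatives pure IK repeats: enriched residues
  # take the top of the scale, depleted ones the bottom
  d <- build_dataset(rep("CWCWCW", 10), rep("IKIKIK", 10))
  card <- initial_propensity_scores(d)
  expect_equal(card$origin, "initial")
  expect_equal(min(card$scores), 0)
  expect_equal(max(card$scores), 1000)
  expect_setequal(names(card$scores)[card$scores == 1000], c("C", "W"))
  expect_true(all(card$scores[c("I", "K")] == 0))

  # brute-force ratio oracle on a biased synthetic set
  d2 <- synth_peptides(n_pos = 80, n_neg = 80, bias = 6, seed = 41)
  card2 <- initial_propensity_scores(d2)
  cnt <- function(seqs) {
    v <- unlist(strsplit(seqs, ""))
    tab <- table(factor(v, levels = names(card2$scores)))
    comp <- as.numeric(tab) / length(v)
    comp[comp == 0] <- 1 / length(v)
    comp
  }
  ratio <- cnt(d2$seq[d2$label == 1]) / cnt(d2$seq[d2$label == 0])
  rescaled <- floor(1000 * (ratio - min(ratio)) / diff(range(ratio)) + 0.5)
  expect_equal(unname(card2$scores), rescaled)
})

test_that("identical class compositions yield a flagged degenerate card", {
  d <- build_dataset(c("ACDE", "FGHI"), c("ACDE", "FGHI"))
  expect_warning(card <- initial_propensity_scores(d), "degenerate")
  expect_equal(unname(card$scores), rep(500, 20))
  expect_error(initial_propensity_scores(tibble::tibble(seq = "AA", label = 1L)),
               "both classes")
})

test_that("fitness combines AUC and correlation with the stated weights", {
  d <- synth_peptides(n_pos = 40, n_neg = 40, bias = 10, seed = 42)
  init <- initial_propensity_scores(d)
  cfg <- ga_config()
  auc <- roc_auc(score_peptides(d, init)$raw_score, d$label)

  # the initial card correlates perfectly with itself
  expect_equal(scm_fitness(init, d, init, cfg), 0.9 * auc + 0.1)
  # negating the card flips both the ranking and the correlation
  neg <- score_card(-init$scores + 1000)
  expect_equal(scm_fitness(neg, d, init, cfg), 0.9 * (1 - auc) - 0.1)
  # a constant (all-zero) card gives identical raw scores: chance AUC, R forced to 0
  flat <- score_card(setNames(rep(0, 20), names(init$scores)))
  expect_warning(f <- scm_fitness(flat, d, init, cfg), "zero-variance")
  expect_equal(f, 0.9 * 0.5)
})

test_that("cutoff search maximizes accuracy and breaks ties at the smallest integer", {
  expect_equal(select_cutoff(c(600, 600, 100, 100), c(1, 1, 0, 0)), 100)
  # inverted labels: no cutoff beats chance, reported honestly
  acc_at <- function(ct, s, l) mean((s > ct) == l)
  ct <- select_cutoff(c(600, 600, 100, 100), c(0, 0, 1, 1))
  expect_equal(acc_at(ct, c(600, 600, 100, 100), c(0, 0, 1, 1)), 0.5)

  # the 40 reference peptides are perfectly separable (max non-THP 140 < min THP 571)
  peps <- scm_reference_peptides()
  sc <- score_peptides(peps, scm_reference_card())
  ct40 <- select_cutoff(sc$raw_score, peps$label)
  expect_equal(acc_at(ct40, sc$raw_score, peps$label), 1)
  expect_true(ct40 >= 140 && ct40 < 571)
  expect_error(select_cutoff(1:3, c(1, 1, 1)), "both classes")
})

test_that("zero generations passes the initial card through with a cutoff", {
  d <- synth_peptides(n_pos = 30, n_neg = 30, seed = 43)
  fit <- scm_train(d, ga_config(generations = 0, seed = 9))
  expect_equal(fit$optimized_card$scores, fit$initial_card$scores)
  expect_false(is.null(fit$optimized_card$cutoff))
  expect_equal(fit$best_fitness, fit$initial_fitness)
})

test_that("GA runs are reproducible, elitist-monotone, clamped and never worse than the start", {
  d <- synth_peptides(n_pos = 60, n_neg = 60, bias = 3, seed = 44)
  cfg <- ga_config(population_size = 16, generations = 25, elitism_count = 1,
                   seed = 45)
  fit1 <- scm_train(d, cfg)
  fit2 <- scm_train(d, cfg)
  expect_equal(fit1$optimized_card$scores, fit2$optimized_card$scores)
  expect_equal(fit1$fitness_history, fit2$fitness_history)

  expect_true(all(diff(fit1$fitness_history) >= 0))
  expect_gte(fit1$best_fitness, fit1$initial_fitness)
  expect_true(all(fit1$optimized_card$scores >= 0 &
                    fit1$optimized_card$scores <= 1000))
  expect_length(fit1$fitness_history, 26L)

  # a different seed explores a different trajectory
  fit3 <- scm_train(d, ga_config(population_size = 16, generations = 25,
                                 elitism_count = 1, seed = 46))
  expect_false(identical(fit1$optimized_card$scores, fit3$optimized_card$scores))
})

test_that("the optimized card recovers planted residue enrichment", {
  d <- synth_peptides(n_pos = 120, n_neg = 120, enriched = c("C", "W", "R"),
                      depleted = c("I", "K", "V"), bias = 8, seed = 47)
  init <- initial_propensity_scores(d)
  expect_gte(roc_auc(score_peptides(d, init)$raw_score, d$label), 0.95)

  fit <- scm_train(d, ga_config(population_size = 24, generations = 30, seed = 48))
  opt <- fit$optimized_card$scores
  expect_gt(mean(opt[c("C", "W", "R")]), mean(opt[c("I", "K", "V")]))
})

test_that("tidy/glance summarize a fit and experiments rank runs by CV accuracy", {
  d <- synth_peptides(n_pos = 40, n_neg = 40, bias = 6, seed = 49)
  cfg <- ga_config(population_size = 10, generations = 5, cv_folds = 4, seed = 50)
  fit <- scm_train(d, cfg, cv = TRUE)
  expect_false(is.null(fit$cv_metrics))
  g <- glance(fit)
  expect_true(all(c("cv_acc", "cv_auc", "best_fitness") %in% names(g)))
  td <- tidy(fit)
  expect_equal(nrow(td), 20L)
  expect_equal(sort(td$residue), sort(names(fit$optimized_card$scores)))

  runs <- run_experiments(d, n_runs = 3, config = cfg, cv = TRUE)
  expect_equal(nrow(runs), 3L)
  expect_setequal(runs$seed, 50:52)
  expect_true(all(diff(runs$cv_acc) <= 0))
  # identical seeds give identical optimized cards (determinism contract)
  again <- scm_train(d, cfg, cv = FALSE)
  ref <- runs$fit[[which(runs$seed == 50)]]
  expect_equal(again$optimized_card$scores, ref$optimized_card$scores)
})
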