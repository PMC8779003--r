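#' Genetic-algorithm configuration for score-card training
#'
#' Bundles the GA hyperparameters and the fitness weights. The fitness of a
#' candidate card is `w1 * AUC + w2 * R`, where AUC is that of the
#' weighted-sum scorer on the training data and R is the Pearson correlation
#' of the candidate's 20 scores with the initial (composition-ratio) scores —
#' the second term keeps the optimized card interpretable as a propensity
#' scale rather than an arbitrary weight vector.
#'
#' @param population_size Number of candidate cards per generation.
#' @param generations Number of GA generations (0 = return the initial card).
#' @param crossover_rate Probability a child is a uniform mix of two parents.
#' @param mutation_rate Per-gene mutation probability.
#' @param mutation_step Maximum absolute per-gene perturbation (uniform).
#' @param elitism_count Top individuals copied unchanged each generation.
#' @param tournament_size Tournament size for parent selection.
#' @param w1,w2 Fitness weights for AUC and initial-card correlation.
#' @param cv_folds Folds used when cross-validating the trained model.
#' @param seed Integer seed; the whole run is reproducible given the seed.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 50, generations = 100,
                      crossover_rate = 0.8, mutation_rate = 0.05,
                      mutation_step = 100, elitism_count = 2,
                      tournament_size = 3, w1 = 0.9, w2 = 0.1,
                      cv_folds = 10, seed = 1) {
  stopifnot(
    population_size >= 2, generations >= 0,
    crossover_rate >= 0, crossover_rate <= 1,
    mutation_rate >= 0, mutation_rate <= 1,
    mutation_step > 0, elitism_count >= 0,
    elitism_count < population_size, tournament_size >= 1,
    cv_folds >= 2
  )
  structure(
    list(
      population_size = as.integer(population_size),
      generations = as.integer(generations),
      crossover_rate = crossover_rate,
      mutation_rate = mutation_rate,
      mutation_step = mutation_step,
      elitism_count = as.integer(elitism_count),
      tournament_size = as.integer(tournament_size),
      w1 = w1, w2 = w2,
      cv_folds = as.integer(cv_folds),
      seed = as.integer(seed)
    ),
    class = "ga_config"
  )
}

#' Initial propensity scores from class compositions
#'
#' For each residue, the pooled composition in the positive class (residue
#' count over total residues) is divided by the pooled composition in the
#' negative class; the 20 ratios are then min–max rescaled to the 0–1000
#' integer scale. Residues absent from a class receive a pseudo-composition
#' of one count over the class residue total before the ratio, so the ratio
#' is always finite.
#'
#' @param dataset Labeled peptide tibble with both classes present.
#' @return A `score_card` with `origin = "initial"` (no cutoff).
#' @examples
#' d <- build_dataset(c("CWCW", "WCCW"), c("IKIK", "KIKI"))
#' initial_propensity_scores(d)
#' @export
initial_propensity_scores <- function(dataset) {
  stopifnot(all(c("seq", "label") %in% names(dataset)))
  if (!all(c(0L, 1L) %in% dataset$label)) {
    abort("both classes must be present to estimate propensity scores")
  }
  pooled_comp <- function(seqs) {
    v <- unlist(strsplit(seqs, "", fixed = TRUE))
    total <- length(v)
    if (total == 0L) abort("class has zero residues")
    cnt <- tabulate(factor(v, levels = AA_ALPHABET), nbins = 20L)
    comp <- cnt / total
    comp[comp == 0] <- 1 / total  # pseudocount for absent residues
    comp
  }
  p <- pooled_comp(dataset$seq[dataset$label == 1L])
  n <- pooled_comp(dataset$seq[dataset$label == 0L])
  ratio <- p / n
  if (diff(range(ratio)) < .Machine$double.eps^0.5) {
    warn("degenerate card: identical class compositions give all-equal ratios")
    scores <- rep(500, 20L)
  } else {
    scores <- round_half_away(1000 * (ratio - min(ratio)) / diff(range(ratio)))
  }
  score_card(setNames(scores, AA_ALPHABET), origin = "initial")
}

#' Fitness of a candidate score card
#'
#' `w1 * AUC + w2 * R`: AUC of the weighted-sum scorer over the training
#' peptides plus the Pearson correlation between the candidate's and the
#' initial card's 20 scores. A constant candidate has undefined correlation,
#' which is treated as 0 with a warning.
#'
#' @param card Candidate `score_card` (or bare named 20-vector).
#' @param dataset Labeled peptide tibble.
#' @param initial The initial `score_card` used as the correlation anchor.
#' @param config A [ga_config()] (only `w1`/`w2` are used).
#' @return The scalar fitness.
#' @export
scm_fitness <- function(card, dataset, initial, config = ga_config()) {
  scores <- if (inherits(card, "score_card")) card$scores else card[AA_ALPHABET]
  init <- if (inherits(initial, "score_card")) initial$scores else initial[AA_ALPHABET]
  comp <- aa_composition(dataset$seq)
  auc <- roc_auc(as.numeric(comp %*% scores), dataset$label)
  r <- if (stats::sd(scores) == 0 || stats::sd(init) == 0) {
    warn("zero-variance card: correlation with the initial card set to 0")
    0
  } else {
    cor(scores, init)
  }
  config$w1 * auc + config$w2 * r
}

#' Select the decision cutoff maximizing training accuracy
#'
#' Searches every integer from `floor(min(scores))` to `ceiling(max(scores))`
#' under the strict-greater classification rule and returns the smallest
#' cutoff achieving the highest accuracy.
#'
#' @param scores Raw weighted-sum scores.
#' @param labels 0/1 labels; both classes required.
#' @return The selected integer cutoff.
#' @examples
#' select_cutoff(c(600, 600, 100, 100), c(1, 1, 0, 0))
#' @export
select_cutoff <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    abort("cutoff selection requires both classes")
  }
  grid <- seq(floor(min(scores)), ceiling(max(scores)))
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  acc <- vapply(grid, function(ct) {
    (sum(scores > ct & labels == 1L) + sum(scores <= ct & labels == 0L)) /
      (npos + nneg)
  }, numeric(1))
  grid[which.max(acc)]  # which.max takes the first (smallest) maximizer
}

#' Train a score card by genetic-algorithm refinement
#'
#' Implements the full training procedure: (1) estimate initial propensity
#' scores from class compositions; (2) refine them with a GA whose fitness
#' rewards separation (AUC) while penalizing departure from the initial
#' scores; (3) select the decision cutoff maximizing training accuracy.
#' The GA population is seeded with the unperturbed initial card, so with
#' elitism the optimized fitness can never fall below the initial fitness.
#' Genes are integers clamped to \[0, 1000\].
#'
#' @param dataset Labeled peptide tibble (columns `seq`, `label`).
#' @param config A [ga_config()].
#' @param cv Logical: also estimate cross-validated performance of the whole
#'   procedure by refitting it on `config$cv_folds` stratified folds? (The
#'   per-fold refit repeats the GA, so this multiplies run time by ~k.)
#' @return An object of class `scm_fit` with elements `initial_card`,
#'   `optimized_card` (cutoff set), `fitness_history` (best fitness per
#'   generation, generation 0 first), `initial_fitness`, `best_fitness`,
#'   `cv_metrics` (or NULL), `config`.
#' @export
scm_train <- function(dataset, config = ga_config(), cv = FALSE) {
  stopifnot(inherits(config, "ga_config"))
  initial <- initial_propensity_scores(dataset)
  comp <- aa_composition(dataset$seq)
  labels <- as.integer(dataset$label)

  fit_of <- function(pop) {
    # pop: matrix individuals x 20; one matrix product scores all of them
    sc <- comp %*% t(pop)
    auc <- vapply(seq_len(ncol(sc)), function(j) roc_auc(sc[, j], labels),
                  numeric(1))
    sds <- apply(pop, 1L, stats::sd)
    r <- ifelse(sds == 0, 0,
                suppressWarnings(as.numeric(cor(t(pop), initial$scores))))
    config$w1 * auc + config$w2 * r
  }

  clamp <- function(m) pmin(pmax(m, 0), 1000)

  if (config$generations == 0L) {
    # degenerate run: no refinement, the initial card passes through
    f0 <- scm_fitness(initial, dataset, initial, config)
    result <- list(best = unname(initial$scores), history = f0, best_fit = f0)
  } else {
  result <- withr::with_seed(config$seed, {
    np <- config$population_size
    pop <- matrix(rep(initial$scores, each = np), nrow = np)
    if (np > 1L) {
      pert <- matrix(
        round_half_away(runif((np - 1L) * 20L, -config$mutation_step,
                              config$mutation_step)),
        nrow = np - 1L
      )
      pop[-1L, ] <- clamp(pop[-1L, , drop = FALSE] + pert)
    }
    fit <- fit_of(pop)
    history <- max(fit)

    for (gen in seq_len(config$generations)) {
      ord <- order(fit, decreasing = TRUE)
      elite <- pop[ord[seq_len(config$elitism_count)], , drop = FALSE]
      tournament <- function() {
        cand <- sample.int(np, config$tournament_size, replace = TRUE)
        cand[which.max(fit[cand])]
      }
      n_child <- np - config$elitism_count
      children <- matrix(0, nrow = n_child, ncol = 20L)
      for (i in seq_len(n_child)) {
        p1 <- pop[tournament(), ]
        if (runif(1) < config$crossover_rate) {
          p2 <- pop[tournament(), ]
          mask <- runif(20L) < 0.5
          child <- ifelse(mask, p1, p2)
        } else {
          child <- p1
        }
        mut <- runif(20L) < config$mutation_rate
        if (any(mut)) {
          child[mut] <- child[mut] +
            round_half_away(runif(sum(mut), -config$mutation_step,
                                  config$mutation_step))
        }
        children[i, ] <- clamp(child)
      }
      pop <- rbind(elite, children)
      fit <- fit_of(pop)
      history <- c(history, max(fit))
    }

    best <- pop[which.max(fit), ]
    list(best = best, history = history, best_fit = max(fit))
  })
  }

  best_scores <- setNames(result$best, AA_ALPHABET)
  raw <- as.numeric(comp %*% best_scores)
  cutoff <- select_cutoff(raw, labels)
  optimized <- score_card(best_scores, cutoff = cutoff, origin = "optimized")

  fit <- structure(
    list(
      initial_card = initial,
      optimized_card = optimized,
      fitness_history = result$history,
      initial_fitness = scm_fitness(initial, dataset, initial, config),
      best_fitness = result$best_fit,
      cv_metrics = NULL,
      config = config
    ),
    class = "scm_fit"
  )
  if (cv) {
    builder <- function(d) {
      f <- scm_train(d, config = config, cv = FALSE)
      f$optimized_card
    }
    fit$cv_metrics <- cross_validate(dataset, builder, k = config$cv_folds,
                                     seed = config$seed)
  }
  fit
}

#' @export
print.scm_fit <- function(x, ...) {
  cat(sprintf(
    "<scm_fit> %d generations; fitness %.4f -> %.4f; cutoff %s\n",
    x$config$generations, x$initial_fitness, x$best_fitness,
    format(x$optimized_card$cutoff)
  ))
  if (!is.null(x$cv_metrics)) {
    cat(sprintf("  %d-fold CV: ACC %.3f, AUC %.3f, MCC %.3f\n",
                x$cv_metrics$k, x$cv_metrics$acc, x$cv_metrics$auc,
                x$cv_metrics$mcc))
  }
  invisible(x)
}

#' Tidiers for score cards and fitted SCM models
#'
#' `tidy()` on an `scm_fit` returns one row per residue with the initial and
#' optimized scores; `glance()` returns a one-row model summary. The
#' `score_card` methods return the per-residue scores and a one-row summary.
#'
#' @param x A `scm_fit` or `score_card` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy scm_fit
#' @export
tidy.scm_fit <- function(x, ...) {
  tibble(
    residue = AA_ALPHABET,
    initial = unname(x$initial_card$scores),
    optimized = unname(x$optimized_card$scores),
    rank = unname(rank(-x$optimized_card$scores, ties.method = "min"))
  ) |>
    dplyr::arrange(.data$rank)
}

#' @rdname tidy.scm_fit
#' @method glance scm_fit
#' @export
glance.scm_fit <- function(x, ...) {
  out <- tibble(
    generations = x$config$generations,
    initial_fitness = x$initial_fitness,
    best_fitness = x$best_fitness,
    cutoff = x$optimized_card$cutoff,
    seed = x$config$seed
  )
  if (!is.null(x$cv_metrics)) {
    out <- dplyr::bind_cols(
      out,
      dplyr::rename_with(x$cv_metrics[, c("acc", "sn", "sp", "mcc", "auc")],
                         ~ paste0("cv_", .x))
    )
  }
  out
}

#' Repeat GA training over independent seeded runs
#'
#' Runs [scm_train()] `n_runs` times with seeds `config$seed + 0 .. n_runs-1`
#' and ranks the runs by cross-validated accuracy (descending), the basis on
#' which a final model is chosen.
#'
#' @param dataset Labeled peptide tibble.
#' @param n_runs Number of independent runs.
#' @param config Base [ga_config()]; each run gets its own seed.
#' @param cv Cross-validate each run (needed for the ranking; if `FALSE`,
#'   runs are ranked by training fitness instead).
#' @return A tibble with one row per run (`run`, `seed`, ranking metrics) and
#'   a list-column `fit` of `scm_fit` objects, best run first.
#' @export
run_experiments <- function(dataset, n_runs, config = ga_config(), cv = TRUE) {
  stopifnot(n_runs >= 1)
  runs <- purrr::map(seq_len(n_runs) - 1L, function(off) {
    cfg <- config
    cfg$seed <- config$seed + off
    scm_train(dataset, config = cfg, cv = cv)
  })
  out <- tibble(
    run = seq_len(n_runs),
    seed = config$seed + seq_len(n_runs) - 1L,
    best_fitness = purrr::map_dbl(runs, "best_fitness"),
    cv_acc = purrr::map_dbl(runs, function(f) {
      if (is.null(f$cv_metrics)) NA_real_ else f$cv_metrics$acc
    }),
    cv_auc = purrr::map_dbl(runs, function(f) {
      if (is.null(f$cv_metrics)) NA_real_ else f$cv_metrics$auc
    }),
    fit = runs
  )
  key <- if (cv) out$cv_acc else out$best_fitness
  out[order(key, decreasing = TRUE), ]
}
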