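#' Configuration for the in-silico gLV-vs-LSTM benchmark
#'
#' Desk-scale analogue of the canonical in-silico comparison: a synthetic
#' ground-truth community model generates low-richness training communities
#' (all monospecies, all pairs, random 3-/5-/6-member designs) and
#' high-richness hold-out communities; a pairwise gLV model and an LSTM are
#' trained on identical data and compared by hold-out accuracy. The default
#' scale (10 species, 150 training / 300 test communities, 6 time points
#' every 8 h) keeps a full run in CPU-minutes; see the methods vignette for
#' the rationale behind each value.
#'
#' @param pool_size Number of species in the ground-truth pool.
#' @param times Sampling grid (h).
#' @param n3,n5,n6 Random 3-/5-/6-member training designs.
#' @param n_test Hold-out designs.
#' @param test_min_richness Minimum hold-out richness.
#' @param n_augment_high Number of high-richness training designs added in
#'   the augmentation arm (split over `augment_richness`).
#' @param augment_richness Richness values of the augmentation designs.
#' @param lstm A [training_config()] for the LSTM.
#' @param glv_starts,glv_iters Multistart/iteration budget for [fit_glv()].
#' @param scenarios Ground-truth third-order levels to run.
#' @param seed Run-level seed.
#' @param ... Unused; supplying an unknown argument is an error.
#' @return List with class `"benchmark_config"`.
#' @export
benchmark_config <- function(pool_size = 12, times = seq(0, 40, by = 8),
                             n3 = 24, n5 = 24, n6 = 24,
                             n_test = 200, test_min_richness = 9,
                             n_augment_high = 40, augment_richness = c(9, 10),
                             lstm = training_config(hidden_dim = 192,
                                                    epochs = 200,
                                                    batch_size = 10,
                                                    lr_decay_every = 50),
                             glv_starts = 3, glv_iters = 300,
                             scenarios = c("none", "moderate"), seed = 1, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(names(extra), collapse = ", "),
         "; valid keys: pool_size, times, n3, n5, n6, n_test, ",
         "test_min_richness, n_augment_high, augment_richness, lstm, ",
         "glv_starts, glv_iters, scenarios, seed")
  structure(list(pool_size = pool_size, times = times, n3 = n3, n5 = n5,
                 n6 = n6, n_test = n_test,
                 test_min_richness = test_min_richness,
                 n_augment_high = n_augment_high,
                 augment_richness = augment_richness, lstm = lstm,
                 glv_starts = glv_starts, glv_iters = glv_iters,
                 scenarios = scenarios, seed = seed),
            class = "benchmark_config")
}

#' Load a benchmark configuration from YAML
#'
#' Unknown keys are a hard error (listing the valid ones).
#'
#' @param path YAML file.
#' @return A [benchmark_config()].
#' @export
load_benchmark_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!is.null(doc$lstm)) doc$lstm <- do.call(training_config, doc$lstm)
  do.call(benchmark_config, doc)
}

# Draw a ground truth whose dynamics stay bounded on all required designs;
# redraws with successive derived seeds when a draw blows up.
draw_stable_truth <- function(pool_size, level, seed, design_list, times,
                              max_tries = 20) {
  seeds <- derive_seeds(seed, max_tries)
  for (s in seeds) {
    truth <- generate_ground_truth(pool_size, level, seed = s)
    ok <- tryCatch({
      for (dm in design_list) invisible(simulate_glv(truth, dm, times))
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(list(truth = truth, seed = s))
  }
  stop("could not draw a bounded ground truth in ", max_tries, " attempts")
}

final_time_r2 <- function(pred_final, true_final) {
  pearson_r2(as.numeric(pred_final), as.numeric(true_final))
}

lstm_holdout_r2 <- function(model, test_tab) {
  K <- length(test_tab$times) - 1
  x0 <- matrix(test_tab$X[, 1, ], n_samples(test_tab), length(test_tab$species))
  pred <- rollout(model, x0, K)
  final_time_r2(pred[, K + 1, ], test_tab$X[, K + 1, ])
}

glv_holdout_r2 <- function(fitted, test_tab) {
  pred <- predict_glv(fitted, test_tab$designs, test_tab$times)
  k <- length(test_tab$times)
  final_time_r2(pred$X[, k, ], test_tab$X[, k, ])
}

#' Run the scaled-down gLV-vs-LSTM benchmark
#'
#' For each ground-truth scenario (pairwise-only, optionally mild/moderate
#' third-order) the benchmark: draws a bounded ground truth; simulates
#' noise-free training (low-richness) and hold-out (high-richness)
#' trajectories; fits a pairwise gLV by multistart optimization and trains a
#' teacher-forcing LSTM on the identical data; and scores both by the
#' squared Pearson correlation between predicted and true abundances at the
#' final time point, pooled over hold-out communities and species (absent
#' species included, as zero stays zero for both models). Under pairwise
#' truth the two models are expected to be comparable; under third-order
#' truth the structurally misspecified gLV degrades while the LSTM does not.
#' The pairwise scenario additionally re-trains the LSTM with high-richness
#' training communities added, quantifying the richness-extrapolation bias.
#'
#' @param config A [benchmark_config()].
#' @param out_dir Optional directory for a CSV summary and log.
#' @param assert If TRUE, error when the expected orderings (comparable
#'   under pairwise truth; LSTM ahead by >= `margin_third` under moderate
#'   third-order truth; augmentation gain >= `margin_augment`) fail.
#' @param margin_pair,margin_third,margin_augment Ordering margins (0.1,
#'   0.15, 0.05).
#' @return List with per-scenario hold-out R-squared values, the
#'   augmentation result and the ordering checks.
#' @export
run_insilico_benchmark <- function(config = benchmark_config(), out_dir = NULL,
                               assert = FALSE, margin_pair = 0.1,
                               margin_third = 0.15, margin_augment = 0.05) {
  pool <- make_pool_codes(config$pool_size)
  seeds <- derive_seeds(config$seed, 8)
  train_designs <- design_training_communities(pool, n3 = config$n3,
                                               n5 = config$n5, n6 = config$n6,
                                               seed = seeds[1])
  test_designs <- design_test_communities(pool, n = config$n_test,
                                          min_richness = config$test_min_richness,
                                          seed = seeds[2])
  n_aug_each <- ceiling(config$n_augment_high / length(config$augment_richness))
  aug_designs <- do.call(rbind, lapply(seq_along(config$augment_richness),
    function(i) {
      with_seed(seeds[3] + i, sample_distinct_designs(
        pool, config$augment_richness[i], n_aug_each,
        exclude_keys = design_key(test_designs)))
    }))
  results <- list()
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  for (sc_i in seq_along(config$scenarios)) {
    level <- config$scenarios[sc_i]
    say("scenario '", level, "': drawing ground truth")
    gt <- draw_stable_truth(config$pool_size, level, seeds[4] + sc_i,
                            list(train_designs, test_designs, aug_designs),
                            config$times)
    truth <- gt$truth
    train_tab <- simulate_glv(truth, train_designs, config$times)
    test_tab <- simulate_glv(truth, test_designs, config$times)
    say("scenario '", level, "': fitting pairwise gLV")
    fitted <- fit_glv(train_tab, n_starts = config$glv_starts,
                      iters = config$glv_iters, seed = seeds[5] + sc_i)
    r2_glv <- glv_holdout_r2(fitted, test_tab)
    say("scenario '", level, "': training LSTM")
    lstm_cfg <- config$lstm
    lstm_cfg$seed <- seeds[6] + sc_i
    model <- train_teacher_forcing(train_tab, lstm_cfg)
    r2_lstm <- lstm_holdout_r2(model, test_tab)
    say(sprintf("scenario '%s': hold-out R2 gLV = %.3f, LSTM = %.3f",
                level, r2_glv, r2_lstm))
    res <- list(level = level, r2_glv = r2_glv, r2_lstm = r2_lstm,
                truth_seed = gt$seed)
    if (level == "none") {
      aug_tab <- simulate_glv(truth, aug_designs, config$times)
      full_tab <- bind_trajectories(list(train_tab, aug_tab))
      say("scenario '", level, "': training LSTM with high-richness augmentation")
      lstm_cfg$seed <- seeds[7]
      model_aug <- train_teacher_forcing(full_tab, lstm_cfg)
      res$r2_lstm_augmented <- lstm_holdout_r2(model_aug, test_tab)
      say(sprintf("augmented LSTM hold-out R2 = %.3f", res$r2_lstm_augmented))
    }
    results[[level]] <- res
  }
  checks <- list()
  if ("none" %in% names(results)) {
    rp <- results[["none"]]
    checks$pairwise_comparable <- abs(rp$r2_lstm - rp$r2_glv) <= margin_pair
    if (!is.null(rp$r2_lstm_augmented))
      checks$augmentation_gain <-
        (rp$r2_lstm_augmented - rp$r2_lstm) >= margin_augment
  }
  if ("moderate" %in% names(results)) {
    rm_ <- results[["moderate"]]
    checks$third_order_advantage <- (rm_$r2_lstm - rm_$r2_glv) >= margin_third
  }
  report <- list(results = results, checks = checks, config = config,
                 log = log_lines)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    df <- do.call(rbind, lapply(results, function(r)
      data.frame(scenario = r$level, r2_glv = r$r2_glv, r2_lstm = r$r2_lstm,
                 r2_lstm_augmented = if (is.null(r$r2_lstm_augmented)) NA
                                     else r$r2_lstm_augmented)))
    write.csv(df, file.path(out_dir, "benchmark.csv"), row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "benchmark.log"))
  }
  if (assert && length(checks) && !all(unlist(checks)))
    stop("benchmark ordering check(s) failed: ",
         paste(names(checks)[!unlist(checks)], collapse = ", "))
  report
}
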