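# local surrogate explanations, gradient sensitivity, and the
# prediction-sensitivity statistics

test_that("local surrogate explanations recover exactly linear presence effects", {
  set.seed(2)
  d <- 8
  w_true <- c(5, -3, 0, 8, 1.5, 0, -6, 2)
  f <- function(Z) as.numeric(Z %*% w_true) + 10
  inst <- setNames(c(1L, 1L, 0L, 1L, 0L, 1L, 1L, 0L), paste0("S", 1:8))
  ex <- lime_explain(f, inst, n_perturbations = 5000, seed = 1)
  big <- abs(w_true) > 0
  expect_lt(max(abs(ex$weights[big] - w_true[big]) / abs(w_true[big])), 0.05)
  # null features get near-zero weight
  expect_lt(max(abs(ex$weights[!big])), 0.02 * max(abs(w_true)))
  # sign stability across seeds for the strong features
  ex2 <- lime_explain(f, inst, n_perturbations = 5000, seed = 99)
  strong <- abs(w_true) > max(abs(w_true)) / 2
  expect_identical(sign(ex$weights[strong]), sign(ex2$weights[strong]))
  # determinism and degenerate input
  ex3 <- lime_explain(f, inst, n_perturbations = 500, seed = 7)
  ex4 <- lime_explain(f, inst, n_perturbations = 500, seed = 7)
  expect_identical(ex3$weights, ex4$weights)
  expect_error(lime_explain(f, setNames(integer(8), paste0("S", 1:8))),
               "richness 0")
})

test_that("explanation networks threshold medians and gate on CV performance", {
  mk_ex <- function(target, weights) {
    structure(list(weights = weights, intercept = 0,
                   instance = NULL, target = target),
              class = "lime_explanation")
  }
  pool <- c("AC", "BT", "DP")
  w1 <- setNames(c(1, 0.1, -7), pool)
  # single instance: the median is that instance's weight
  net1 <- build_explanation_network(list(mk_ex("butyrate", w1)),
                                    cv_r2 = c(butyrate = 0.9))
  expect_equal(nrow(net1$edges), 1)
  expect_equal(net1$edges$source, "DP")
  expect_equal(net1$edges$weight, -7)
  expect_equal(net1$edges$sign, -1)

  # weights (1, 3, 5) mM across instances: median 3 < threshold 5, excluded
  exs <- lapply(c(1, 3, 5), function(v) mk_ex("butyrate", setNames(c(v, 0, 0), pool)))
  net2 <- build_explanation_network(exs, cv_r2 = c(butyrate = 0.9))
  expect_equal(nrow(net2$edges), 0)

  # the eligibility gate is strict: R2 <= 0.5 yields an empty network
  net3 <- build_explanation_network(list(mk_ex("butyrate", w1)),
                                    cv_r2 = c(butyrate = 0.5))
  expect_equal(nrow(net3$edges), 0)

  # species targets are normalized to the target's self-impact
  ws <- setNames(c(0.2, 2, -0.5), pool)
  net4 <- build_explanation_network(list(mk_ex("BT", ws)),
                                    cv_r2 = c(BT = 0.8))
  expect_setequal(net4$edges$source, c("BT", "DP"))   # 0.2/2 = 0.1 < 0.2 drops AC
  expect_equal(net4$edges$weight[net4$edges$source == "DP"], -0.25)
  w0 <- setNames(c(0.2, 0, -0.5), pool)
  expect_error(build_explanation_network(list(mk_ex("BT", w0)),
                                         cv_r2 = c(BT = 0.8)),
               "self-impact")

  # round trip through the edge-list CSV
  f <- tempfile(fileext = ".csv")
  write_explanation_network(net1, f)
  back <- read.csv(f)
  expect_equal(back$median_weight, net1$edges$weight)
  g <- tempfile(fileext = ".graphml")
  write_explanation_network(net1, g)
  expect_true(file.size(g) > 0)
})

test_that("gradient sensitivity is exact on linear maps and matches finite differences", {
  W <- matrix(rnorm(6), 2, 3)
  expect_identical(gradient_sensitivity(linear_map(W)), W)

  # a trained small model: reverse-mode derivatives vs central differences
  truth <- generate_ground_truth(5, "none", seed = 11)
  pool <- micos:::make_pool_codes(5)
  dm <- rbind(diag(1L, 5), make_pairs(5))
  colnames(dm) <- pool
  tab <- simulate_glv(truth, dm, times = seq(0, 40, 8))
  m <- train_teacher_forcing(tab, training_config(hidden_dim = 12, epochs = 30,
                                                  seed = 6))
  x0 <- rep(0.0066, 5)
  G <- gradient_sensitivity(m, x0, scale = "standardized")
  x0_std <- as.numeric(micos:::scaler_transform(m$scaler, matrix(x0, 1), k = 1))
  h <- 1e-4
  K <- m$n_steps
  fd_roll <- function(z) {
    fwd <- micos:::lstm_forward(m$weights, matrix(z, ncol = 1), K)
    vapply(fwd$Y, as.numeric, numeric(5))  # 5 outputs x K steps
  }
  for (i in 1:5) {
    zp <- x0_std; zp[i] <- zp[i] + h
    zm <- x0_std; zm[i] <- zm[i] - h
    fd <- (fd_roll(zp) - fd_roll(zm)) / (2 * h)   # outputs x steps
    for (k in 1:K) {
      denom <- pmax(abs(fd[, k]), 1e-3)
      expect_lt(max(abs(G[k, , i] - fd[, k]) / denom), 1e-4)
    }
  }

  # structural zero: an input whose weight columns are zeroed cannot matter
  m0 <- m
  for (g in c("Wii", "Wif", "Wig", "Wio")) m0$weights[[g]][, 3] <- 0
  G0 <- gradient_sensitivity(m0, x0, scale = "standardized")
  expect_true(all(G0[, , 3] == 0))
  expect_false(all(G0[, , 1] == 0))
})

test_that("subsampling curves separate planted signal from noise", {
  set.seed(14)
  n <- 120; d <- 6
  X <- matrix(rbinom(n * d, 1, 0.5), n, d)
  beta <- c(4, -2, 1, 0, 3, -1)
  Y <- cbind(signal = as.numeric(X %*% beta),
             noise = rnorm(n))
  curves <- subsample_sensitivity(X, Y, fractions = c(0.5, 0.75, 1),
                                  n_repeats = 8, cv_folds = 10, seed = 3)
  sig <- curves[curves$output == "signal", ]
  noi <- curves[curves$output == "noise", ]
  expect_true(all(sig$mean_r2 >= 0.99))
  expect_true(all(noi$mean_r2 <= 0.1))
  # at fraction 1 the spread reflects only fold randomness
  expect_lt(sig$sd_r2[sig$fraction == 1], 1e-6)
  expect_error(subsample_sensitivity(X, Y, fractions = 0.05, cv_folds = 10),
               "fewer than")
  expect_error(subsample_sensitivity(X[1:5, ], Y[1:5, ], cv_folds = 10),
               "smaller than")
})

test_that("pairwise sensitivity equals the printed formula and a brute-force loop", {
  # hand evaluation: 2 species, R2_1 = 0.5, R2_2 = 0.8, R2_12 = 0.6
  r2_i <- c(A = 0.5, B = 0.8)
  r2_ij <- matrix(c(NA, 0.6, 0.6, NA), 2, 2)
  hand <- pairwise_sensitivity_from_r2(r2_i, r2_ij)
  expect_equal(hand$value, 25 * ((0.6 - 0.5) / 0.5 + (0.6 - 0.8) / 0.8))  # -1.25
  expect_equal(hand$value, -1.25)

  # zero when every pair performs exactly like its singles
  r2_flat <- matrix(0.7, 2, 2); diag(r2_flat) <- NA
  expect_equal(pairwise_sensitivity_from_r2(c(A = 0.7, B = 0.7), r2_flat)$value, 0)

  # bit-exact agreement with an independently coded double loop, both
  # normalizer conventions
  set.seed(77)
  S <- 5
  r2i <- runif(S, 0.2, 0.9)
  r2ij <- matrix(runif(S * S, 0.2, 0.9), S, S); diag(r2ij) <- NA
  r2ij[1, 4] <- NA  # an undefined pair is skipped
  ours <- pairwise_sensitivity_from_r2(r2i, r2ij)
  expect_identical(ours$value, oracle_pairwise_sensitivity(r2i, r2ij, S^2))
  ours_p <- pairwise_sensitivity_from_r2(r2i, r2ij, normalizer = "pairs")
  expect_identical(ours_p$value, oracle_pairwise_sensitivity(r2i, r2ij, S * (S - 1)))
  expect_equal(ours$skipped, "1:4")

  # integrated path on data, with empty pairs warned about and skipped
  set.seed(5)
  n <- 80
  dm <- matrix(rbinom(n * 4, 1, 0.6), n, 4,
               dimnames = list(NULL, c("AC", "BT", "DP", "EL")))
  dm[, 4] <- c(rep(1L, 10), rep(0L, n - 10))
  dm[dm[, 4] == 1, 3] <- 0      # DP and EL never co-occur
  dm[rowSums(dm) == 0, 1] <- 1L
  true <- rnorm(n); pred <- true + rnorm(n, sd = 0.5)
  expect_warning(rep_ <- pairwise_sensitivity(pred, true, dm), "skipped")
  expect_true(is.finite(rep_$pairwise_sensitivity))
  expect_true("DP:EL" %in% rep_$skipped)
})
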