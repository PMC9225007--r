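test_that("ground-truth draws respect third-order bounds, support and determinism", {
  g0 <- generate_ground_truth(25, "none", seed = 1)
  expect_true(all(g0$B == 0))

  g1 <- generate_ground_truth(25, "mild", seed = 1)
  expect_lte(max(abs(g1$B)), 0.25 * max(abs(g1$A)))
  expect_identical(g1, generate_ground_truth(25, "mild", seed = 1))

  g2 <- generate_ground_truth(25, "moderate", seed = 1)
  expect_lte(max(abs(g2$B)), 0.50 * max(abs(g2$A)))
  # uniformity of admissible entries on their stated support
  offd <- abs(g2$A); diag(offd) <- 0
  bound <- 0.5 * max(offd)
  vals <- g2$B[!micos:::b_inadmissible_mask(25)]
  expect_gte(length(vals), 1e4)
  ks <- suppressWarnings(ks.test(vals, "punif", -bound, bound))
  expect_gt(ks$p.value, 0.01)

  # structural zeros of the tensor
  expect_true(all(g2$B[micos:::b_inadmissible_mask(25)] == 0))
  expect_error(generate_ground_truth(25, "wild", seed = 1))
})

test_that("gLV integration matches closed forms and an independent RK4 oracle", {
  # logistic fixed point -r/a
  p1 <- glv_params(r = 0.5, A = matrix(-1, 1, 1))
  tt <- simulate_glv(p1, matrix(1L, 1, 1), times = seq(0, 48, 8), x0_total = 0.1)
  expect_equal(tt$X[1, 7, 1], 0.5, tolerance = 1e-3)

  # decoupled pair equals its monocultures
  p2 <- glv_params(r = c(0.4, 0.6), A = diag(c(-1, -0.8)))
  tight <- list(rtol = 1e-12, atol = 1e-14)
  both <- simulate_glv(p2, matrix(1L, 1, 2), times = seq(0, 48, 8),
                       x0_total = 0.1, rtol = tight$rtol, atol = tight$atol)
  m1 <- simulate_glv(p2, matrix(c(1L, 0L), 1), times = seq(0, 48, 8),
                     x0_total = 0.05, rtol = tight$rtol, atol = tight$atol)
  m2 <- simulate_glv(p2, matrix(c(0L, 1L), 1), times = seq(0, 48, 8),
                     x0_total = 0.05, rtol = tight$rtol, atol = tight$atol)
  expect_equal(both$X[1, , 1], m1$X[1, , 1], tolerance = 1e-9)
  expect_equal(both$X[1, , 2], m2$X[1, , 2], tolerance = 1e-9)

  # 3 species with a third-order term vs the brute-force oracle
  set.seed(21)
  r <- runif(3, 0.3, 0.6)
  A <- matrix(rnorm(9, -0.1, 0.15), 3, 3); diag(A) <- c(-1, -0.9, -1.1)
  B <- array(0, dim = c(3, 3, 3)); B[1, 2, 3] <- 0.3
  p3 <- glv_params(r, A, B)
  times <- seq(0, 24, 8)
  sim <- simulate_glv(p3, matrix(1L, 1, 3), times = times, x0_total = 0.3)
  ref <- oracle_rk4_glv(r, A, B, rep(0.1, 3), times, dt = 1e-3)
  expect_lt(max(abs(sim$X[1, , ] - ref) / pmax(abs(ref), 1e-6)), 1e-4)

  # conservation of absence through simulation and noise
  p5 <- generate_ground_truth(5, "mild", seed = 3)
  des <- matrix(c(1L, 0L, 1L, 0L, 1L), 1)
  simd <- simulate_glv(p5, des, times = seq(0, 48, 8))
  expect_true(all(simd$X[1, , c(2, 4)] == 0))
  noisy <- add_observation_noise(simd, sigma = 0.2, seed = 9)
  expect_true(all(noisy$X[1, , c(2, 4)] == 0))
  expect_true(all(noisy$X[1, , c(1, 3, 5)] > 0))
  expect_identical(noisy$X, add_observation_noise(simd, sigma = 0.2, seed = 9)$X)

  # blow-up diagnostics name the offending species
  pb <- glv_params(r = c(1, 1), A = matrix(c(-0.01, 2, 2, -0.01), 2, 2),
                   strict = FALSE)
  expect_error(
    suppressWarnings(simulate_glv(pb, matrix(1L, 1, 2), times = seq(0, 48, 8),
                                  x0_total = 0.5)),
    "blew up")
})

test_that("passaging dilutes on schedule and matches the oracle in steady cycling", {
  # no growth: concentrations drop 20-fold at each passage
  p0 <- glv_params(r = 0, A = matrix(-1e-12, 1, 1), strict = FALSE)
  tt <- simulate_with_passaging(p0, matrix(1L, 1, 1), x0_total = 1,
                                horizon = 60, sample_every = 12)
  expect_equal(tt$X[1, , 1], c(1, 1, 1, 1 / 20, 1 / 20, 1 / 400),
               tolerance = 1e-9)

  expect_error(simulate_with_passaging(p0, matrix(1L, 1, 1), dilution_fold = 1),
               "dilution_fold")

  # logistic culture reaches a period-24h cycle; verify against the oracle
  p1 <- glv_params(r = 0.5, A = matrix(-1, 1, 1))
  long <- simulate_with_passaging(p1, matrix(1L, 1, 1), x0_total = 0.1,
                                  horizon = 24 * 8, sample_every = 8)
  cycle1 <- long$X[1, long$times %in% c(168, 176, 184), 1]
  cycle2 <- long$X[1, long$times %in% c(144, 152, 160), 1]
  expect_equal(cycle1, cycle2, tolerance = 1e-4)
  # one passage interval from the sampled post-dilution state, via the oracle
  x_start <- long$X[1, long$times == 168, 1] / 20
  ref <- oracle_rk4_glv(0.5, matrix(-1, 1, 1), NULL, x_start,
                        c(0, 8, 16, 24), dt = 1e-3)
  expect_equal(long$X[1, long$times %in% c(176, 184, 192), 1],
               ref[2:4, 1], tolerance = 1e-4)
})

test_that("training and test design generators hit the canonical counts", {
  tr <- design_training_communities(seed = 1)
  expect_equal(nrow(tr), 624)
  expect_equal(sum(richness(tr) == 1), 25)
  expect_equal(sum(richness(tr) == 2), 300)
  expect_equal(unname(c(table(richness(tr))[c("3", "5", "6")])),
               c(100L, 100L, 99L))
  expect_equal(anyDuplicated(micos:::design_key(tr)), 0)
  expect_identical(tr, design_training_communities(seed = 1))

  small <- design_training_communities(micos:::make_pool_codes(3),
                                       n3 = 1, n5 = 0, n6 = 0, seed = 2)
  expect_equal(nrow(small), 7)  # 3 singletons + 3 pairs + 1 triple

  expect_error(design_training_communities(micos:::make_pool_codes(4),
                                           n3 = 5, n5 = 0, n6 = 0, seed = 1),
               "only 4 exist")

  # richness property across seeds, disjointness from an exclusion set
  for (s in 1:30) {
    te <- design_test_communities(micos:::make_pool_codes(8), n = 10,
                                  min_richness = 5, seed = s)
    expect_true(all(richness(te) >= 5))
    expect_equal(anyDuplicated(micos:::design_key(te)), 0)
  }
  excl <- design_test_communities(micos:::make_pool_codes(6), n = 10,
                                  min_richness = 4, seed = 1)
  rest <- design_test_communities(micos:::make_pool_codes(6), n = 10,
                                  min_richness = 4, exclude = excl, seed = 2)
  expect_length(intersect(micos:::design_key(excl), micos:::design_key(rest)), 0)
  # pool of 5 with min_richness 5: the full community is the only candidate
  one <- design_test_communities(micos:::make_pool_codes(5), n = 1,
                                 min_richness = 5, seed = 1)
  expect_equal(unname(one[1, ]), rep(1L, 5))
  expect_error(design_test_communities(micos:::make_pool_codes(5), n = 2,
                                       min_richness = 5, seed = 1), "only 1")
})

test_that("trajectory tables and gLV parameters round-trip through disk", {
  p <- generate_ground_truth(4, "mild", seed = 6, metabolites = TRUE)
  tab <- simulate_glv(p, rbind(c(1L, 1L, 0L, 1L), c(0L, 1L, 1L, 1L)),
                      times = seq(0, 32, 8))
  csv <- tempfile(fileext = ".csv")
  write_trajectory_csv(tab, csv)
  back <- read_trajectory_csv(csv)
  expect_equal(back$X, tab$X, tolerance = 1e-12)
  expect_equal(back$C, tab$C, tolerance = 1e-12)
  expect_identical(back$species, tab$species)
  expect_identical(back$metabolites, tab$metabolites)

  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    write_glv_params(p, f)
    q <- read_glv_params(f)
    expect_equal(unname(q$r), unname(p$r), tolerance = 1e-10)
    expect_equal(unname(q$A), unname(p$A), tolerance = 1e-10)
    expect_equal(q$B, p$B, tolerance = 1e-10)
    expect_equal(unname(q$P), unname(p$P), tolerance = 1e-10)
  }

  df <- read.csv(csv)
  df$time_h <- NULL
  csv2 <- tempfile(fileext = ".csv")
  write.csv(df, csv2, row.names = FALSE)
  expect_error(read_trajectory_csv(csv2), "missing column")
})

test_that("the discrete gLV map is exactly the printed multiplicative update", {
  par2 <- list(r = c(1, 1), A = matrix(c(0, -1, -1, 0), 2, 2))
  expect_equal(step_glv_discrete(par2, c(0.2, 0.1)),
               c(0.2 * (1 - 0.1), 0.1 * (1 - 0.2)))  # (0.18, 0.08) by hand
  # r = 1, A = 0 is the identity map (no implicit "1 +")
  parI <- list(r = c(1, 1, 1), A = matrix(0, 3, 3))
  x <- c(0.3, 0.5, 0.9)
  expect_identical(step_glv_discrete(parI, x), x)
  # zero-initialized parameters send every state to zero
  par0 <- list(r = numeric(2), A = matrix(0, 2, 2))
  expect_equal(step_glv_discrete(par0, c(0.4, 0.2)), c(0, 0))
  expect_error(step_glv_discrete(parI, c(-0.1, 0, 0)), "non-negative")
})

test_that("the discretized gLV baseline trains and predicts on its own data", {
  # data generated by a known discrete map on [0,1]-scaled features
  set.seed(8)
  n <- 40; S <- 3; K <- 4
  r_true <- c(1.05, 0.95, 1.0)
  A_true <- matrix(c(0, -0.2, 0.1, -0.15, 0, 0, 0.05, -0.1, 0), S, S)
  X <- array(0, dim = c(n, K + 1, S))
  X[, 1, ] <- matrix(runif(n * S, 0.1, 0.9), n, S)
  for (k in 1:K)
    X[, k + 1, ] <- t(apply(X[, k, ], 1, function(x)
      pmax(step_glv_discrete(list(r = r_true, A = A_true), x), 0)))
  tab <- trajectory_table(X, 0:K, designs = matrix(1L, n, S))
  fit <- fit_glv_discrete(tab, training_config(epochs = 400, batch_size = 40,
                                               learning_rate = 0.05,
                                               lr_decay_every = 150,
                                               teacher_forcing_prob = 1, seed = 2))
  expect_lt(tail(fit$loss_history, 1), head(fit$loss_history, 1) / 10)
  pred <- predict_glv_discrete(fit, X[1:5, 1, ])
  expect_equal(dim(pred$X), c(5, K + 1, S))
  r2 <- pearson_r2(as.numeric(pred$X[, K + 1, ]), as.numeric(X[1:5, K + 1, ]))
  expect_gt(r2, 0.9)
})
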