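# slower, deeper training contracts: endpoint metabolite head, joint
# species+metabolite variant, and capacity on self-generated gLV data

# communities sampled with replacement: at 5 species only 26 distinct
# designs of richness >= 2 exist, so replicate designs are expected
sample_designs_replace <- function(pool, sizes, n, seed) {
  p <- length(pool)
  micos:::with_seed(seed, {
    out <- matrix(0L, n, p, dimnames = list(NULL, pool))
    for (i in seq_len(n)) {
      k <- if (length(sizes) == 1) sizes else sizes[sample.int(length(sizes), 1)]
      out[i, sample.int(p, k)] <- 1L
    }
    out
  })
}

make_endpoint_data <- function(n_species = 5, n_comm = 200, seed = 31) {
  truth <- generate_ground_truth(n_species, "none", seed = seed)
  pool <- micos:::make_pool_codes(n_species)
  dm <- sample_designs_replace(pool, 2:n_species, n_comm, seed + 1)
  tab <- simulate_glv(truth, dm, times = c(0, 48))
  list(truth = truth, designs = dm, tab = tab)
}

test_that("a linear metabolite head composes exactly with the rollout output", {
  d <- make_endpoint_data(n_comm = 30)
  cfg <- training_config(hidden_dim = 8, epochs = 2, n_steps = 3, seed = 1)
  m <- train_endpoint(d$tab, cfg)
  m <- attach_metabolite_head(m, head_layers = NULL, n_metabolites = 2, seed = 2)
  # force an identity-ish head: linear map, zero bias
  L <- matrix(rnorm(2 * 5), 2, 5)
  m$head[[1]]$W <- L
  m$head[[1]]$b[] <- 0
  m$met_scaler <- list(mu = c(0, 0), sigma = c(1, 1))
  m$metabolites <- c("m1", "m2")
  pe <- predict_endpoint(m, d$designs[1:4, ])
  # the head consumes the standardized final output
  x0 <- micos:::design_x0(d$designs[1:4, ], m$species, m$x0_per_species)
  fwd <- micos:::lstm_forward(m$weights,
                              t(micos:::scaler_transform(m$scaler, x0, k = 1)),
                              m$n_steps)
  expect_equal(pe$metabolites, t(L %*% fwd$Y[[m$n_steps]]),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("end-to-end training recovers a planted linear species-metabolite link", {
  d <- make_endpoint_data(n_species = 5, n_comm = 200, seed = 31)
  # ground truth: metabolites are a fixed linear function of endpoint abundance
  L <- matrix(c(8, 0, 0, 2, 0,
                0, 12, -3, 0, 0,
                3, 3, 3, 3, 3,
                0, 0, 6, 0, -2), 4, 5, byrow = TRUE)
  endX <- matrix(d$tab$X[, 2, ], nrow(d$designs), 5)
  C <- array(0, dim = c(nrow(d$designs), 2, 4))
  C[, 2, ] <- endX %*% t(L)
  tab <- trajectory_table(d$tab$X, d$tab$times, designs = d$tab$designs, C = C,
                          species = d$tab$species)
  cfg <- training_config(hidden_dim = 64, epochs = 600, batch_size = 20,
                         learning_rate = 0.01, lr_decay = 0.5,
                         lr_decay_every = 300, n_steps = 2, seed = 7)
  m <- train_endpoint(tab, cfg, head_layers = 16)
  hold <- 181:200
  pe <- predict_endpoint(m, tab$designs[hold, ])
  true_met <- C[hold, 2, ]
  for (j in 1:4)
    expect_gt(pearson_r2(pe$metabolites[, j], true_met[, j]), 0.9)
  # abundance endpoint is predicted jointly
  expect_gt(pearson_r2(as.numeric(pe$abundance), as.numeric(endX[hold, ])), 0.9)
})

test_that("metabolite loss back-propagates into the LSTM weights", {
  # gradient of the metabolite-only loss w.r.t. the recurrent weights is
  # nonzero: the head is trained end-to-end, not as a separate stage
  set.seed(13)
  w <- lstm_weights(3, 6, 3, seed = 2)
  head <- micos:::ffn_init(c(3, 4, 2), seed = 3)
  x0 <- matrix(rnorm(9), 3, 3)
  K <- 3
  fwd <- micos:::lstm_forward(w, x0, K)
  hf <- micos:::ffn_forward(head, fwd$Y[[K]])
  target <- matrix(rnorm(6), 2, 3)
  hb <- micos:::ffn_backward(head, hf, 2 * (hf$out - target))
  dY <- vector("list", K)
  dY[[K]] <- hb$dx                 # only the metabolite loss contributes
  grads <- micos:::lstm_backward(w, fwd, dY)$grads
  expect_gt(sqrt(sum(grads$Wii^2)), 0)
  expect_gt(sqrt(sum(grads$Whg^2)), 0)
  expect_gt(sqrt(sum(grads$Wyo^2)), 0)

  d <- make_endpoint_data(n_comm = 20, seed = 13)
  cfg <- training_config(hidden_dim = 8, epochs = 2, n_steps = 3, seed = 5)
  expect_error(train_endpoint(d$tab, cfg, head_layers = 8),
               "missing metabolite columns")
})

test_that("the joint species+metabolite variant propagates the concatenated block", {
  # full-scale constructor: 25 + 4 = 29 features at every step
  m29 <- build_joint_model(25, 4, hidden_dim = 4, seed = 1)
  expect_equal(attr(m29$weights, "dims")[["input"]], 29)
  expect_equal(attr(m29$weights, "dims")[["output"]], 29)

  # trainable desk-scale variant: gLV + linear metabolite dynamics
  truth <- generate_ground_truth(5, "none", seed = 41, metabolites = TRUE)
  pool <- micos:::make_pool_codes(5)
  dm <- sample_designs_replace(pool, 2:5, 150, seed = 42)
  tab <- simulate_glv(truth, dm, times = c(0, 16, 32, 48))
  expect_equal(dim(micos:::feature_array(tab))[3], 9)
  cfg <- training_config(hidden_dim = 48, epochs = 150, batch_size = 20,
                         lr_decay_every = 50, seed = 9)
  m <- train_teacher_forcing(tab, cfg, model = build_joint_model(5, 4, 48, seed = 9))
  hold <- 131:150
  x0 <- matrix(micos:::feature_array(tab)[hold, 1, ], length(hold), 9)
  pred <- rollout(m, x0, 3)
  expect_equal(dim(pred), c(20, 4, 9))
  # metabolite block recovered at every later time point
  for (k in 2:4) {
    for (j in 1:4) {
      r2 <- pearson_r2(pred[, k, 5 + j], tab$C[hold, k, j])
      expect_gt(r2, 0.8)
    }
  }
  # a model expecting metabolites rejects abundance-only tables
  ab_only <- trajectory_table(tab$X, tab$times, designs = tab$designs,
                              species = tab$species)
  expect_error(train_teacher_forcing(ab_only, cfg,
                                     model = build_joint_model(5, 4, 48)),
               "metabolite")
})

test_that("the LSTM learns 5-species pairwise gLV dynamics from low-richness data", {
  truth <- generate_ground_truth(5, "none", seed = 11)
  pool <- micos:::make_pool_codes(5)
  tr_designs <- rbind(diag(1L, 5), make_pairs(5),
                      micos:::with_seed(9, micos:::sample_distinct_designs(pool, 3, 10)))
  colnames(tr_designs) <- pool
  te_designs <- rbind(micos:::with_seed(10, micos:::sample_distinct_designs(pool, 4, 5)),
                      rep(1L, 5))
  tr <- simulate_glv(truth, tr_designs, times = seq(0, 40, 8))
  te <- simulate_glv(truth, te_designs, times = seq(0, 40, 8))
  m <- train_teacher_forcing(tr, training_config(hidden_dim = 48, epochs = 250,
                                                 batch_size = 10,
                                                 lr_decay_every = 50, seed = 4))
  pred <- rollout(m, matrix(te$X[, 1, ], 6, 5), 5)
  r2 <- pearson_r2(as.numeric(pred[, 6, ]), as.numeric(te$X[, 6, ]))
  expect_gt(r2, 0.8)
})
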