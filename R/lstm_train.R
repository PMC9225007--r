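#' Training configuration for LSTM community models
#'
#' Collects the optimizer hyperparameters. The historical full-scale settings
#' are a hidden dimension of 2048 (abundance-only) or 4096 (joint
#' species+metabolite) units, learning rates in \{0.005, 0.001, 0.0001\} each
#' decayed by a factor of 0.25 after every 25 epochs, an L2 weight decay of
#' 1e-5 and minibatches of 10 or 20 sequences; the package defaults are
#' scaled to desk-size problems but keep the same schedule.
#'
#' @param hidden_dim LSTM hidden units.
#' @param learning_rate Initial Adam learning rate.
#' @param lr_decay Multiplicative decay factor.
#' @param lr_decay_every Epoch interval between decays.
#' @param weight_decay L2 coefficient added to the loss.
#' @param batch_size Minibatch size (sequences).
#' @param epochs Training epochs.
#' @param teacher_forcing_prob Per-step probability of substituting the true
#'   observation for the fed-back prediction during training (in \[0, 1\]).
#' @param n_steps Rollout length used when only initial and final
#'   observations exist (endpoint mode).
#' @param seed Integer seed controlling initialization, shuffling and
#'   teacher-forcing draws.
#' @return A list with class `"training_config"`.
#' @export
training_config <- function(hidden_dim = 64, learning_rate = 0.005,
                            lr_decay = 0.25, lr_decay_every = 25,
                            weight_decay = 1e-5, batch_size = 20,
                            epochs = 100, teacher_forcing_prob = 0.5,
                            n_steps = 5, seed = 1) {
  cfg <- list(hidden_dim = hidden_dim, learning_rate = learning_rate,
              lr_decay = lr_decay, lr_decay_every = lr_decay_every,
              weight_decay = weight_decay, batch_size = batch_size,
              epochs = epochs, teacher_forcing_prob = teacher_forcing_prob,
              n_steps = n_steps, seed = seed)
  stopifnot(hidden_dim >= 1, learning_rate > 0, lr_decay > 0, batch_size >= 1,
            epochs >= 1, teacher_forcing_prob >= 0, teacher_forcing_prob <= 1)
  structure(cfg, class = "training_config")
}

new_lstm_model <- function(weights, scaler, species, metabolites = NULL,
                           mode = "trajectory", head = NULL, met_scaler = NULL,
                           times = NULL, n_steps = NULL, config = NULL,
                           loss_history = numeric(), x0_per_species = 0.0066) {
  structure(list(weights = weights, scaler = scaler, species = species,
                 metabolites = metabolites, mode = mode, head = head,
                 met_scaler = met_scaler, times = times, n_steps = n_steps,
                 config = config, loss_history = loss_history,
                 x0_per_species = x0_per_species),
            class = "lstm_model")
}

#' @export
print.lstm_model <- function(x, ...) {
  d <- attr(x$weights, "dims")
  cat("<lstm_model> ", x$mode, " mode; ", d[["input"]], " features, ",
      d[["hidden"]], " hidden units",
      if (!is.null(x$head)) "; metabolite head", "\n", sep = "")
  invisible(x)
}

#' Build an untrained joint species+metabolite LSTM
#'
#' The joint variant propagates a concatenated feature vector whose first
#' `n_species` components are abundances and whose remaining components are
#' metabolite concentrations (29-dimensional for the default 25-species,
#' 4-metabolite system); the rollout output splits back into the two blocks
#' on inverse transform.
#'
#' @param n_species,n_metabolites Block sizes.
#' @param hidden_dim Hidden units (historical full-scale default 4096).
#' @param seed Integer seed for weight initialization.
#' @return An untrained [new_lstm_model()]-style object (train with
#'   [train_teacher_forcing()] on tables that carry metabolites).
#' @export
build_joint_model <- function(n_species = 25, n_metabolites = 4,
                              hidden_dim = 64, seed = 1) {
  dim_in <- n_species + n_metabolites
  w <- lstm_weights(dim_in, hidden_dim, dim_in, seed = seed)
  new_lstm_model(w, scaler = NULL, species = make_pool_codes(n_species),
                 metabolites = metabolite_names()[seq_len(n_metabolites)],
                 mode = "trajectory")
}

#' Attach a feed-forward metabolite head to an endpoint model
#'
#' The head maps the model's final (standardized) species-abundance output to
#' metabolite concentrations through a feed-forward network with ReLU hidden
#' layers and a linear output, and is trained end-to-end together with the
#' LSTM weights.
#'
#' @param model An [train_endpoint()]-style LSTM model (or untrained model).
#' @param head_layers Integer vector of hidden-layer sizes (may be empty for
#'   a linear head).
#' @param n_metabolites Number of metabolite outputs.
#' @param seed Integer seed.
#' @return The model with a `head` component.
#' @export
attach_metabolite_head <- function(model, head_layers = 16, n_metabolites = 4,
                                   seed = 1) {
  d <- attr(model$weights, "dims")
  sizes <- c(d[["output"]], head_layers, n_metabolites)
  model$head <- ffn_init(sizes, seed = seed)
  if (is.null(model$metabolites))
    model$metabolites <- metabolite_names()[seq_len(n_metabolites)]
  model
}

# ---- Adam ------------------------------------------------------------------

flatten_params <- function(weights, head = NULL) {
  p <- unclass(weights)
  if (!is.null(head)) {
    for (l in seq_along(head)) {
      p[[paste0("head_W", l)]] <- head[[l]]$W
      p[[paste0("head_b", l)]] <- head[[l]]$b
    }
  }
  p
}

unflatten_params <- function(p, weights, head = NULL) {
  wn <- names(unclass(weights))
  for (nm in wn) weights[[nm]] <- p[[nm]]
  if (!is.null(head)) {
    for (l in seq_along(head)) {
      head[[l]]$W <- p[[paste0("head_W", l)]]
      head[[l]]$b <- p[[paste0("head_b", l)]]
    }
  }
  list(weights = weights, head = head)
}

adam_state <- function(params) {
  zero <- lapply(params, function(w) if (is.matrix(w)) matrix(0, nrow(w), ncol(w)) else numeric(length(w)))
  list(m = zero, v = zero, t = 0)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- training --------------------------------------------------------------

#' Train an LSTM on time-resolved community trajectories with teacher forcing
#'
#' Minimizes the mean squared error on standardized outputs at every observed
#' time point. At each step of each sequence, with probability
#' `teacher_forcing_prob` the true standardized observation replaces the
#' model's previous prediction as input (randomized teacher forcing, drawn
#' per step and per sequence); otherwise the prediction is fed back and
#' gradients flow through the feedback. Optimization is Adam with the
#' configured learning-rate schedule and L2 weight decay. If the tables carry
#' metabolites, the model is the joint species+metabolite variant and the
#' feature vector is the concatenated block.
#'
#' @param tables A [trajectory_table()] (or list of tables on one grid) with
#'   intermediate observations.
#' @param config A [training_config()].
#' @param model Optional pre-built model (e.g. [build_joint_model()]); built
#'   from the data dimensions when NULL.
#' @param normalize_all Optional table pooled into scaler statistics (the
#'   `normalize_all` toggle; default NULL = training statistics only).
#' @return A trained `lstm_model` with scaler and per-epoch loss history.
#' @export
train_teacher_forcing <- function(tables, config = training_config(),
                                  model = NULL, normalize_all = NULL) {
  if (is.list(tables) && !inherits(tables, "trajectory_table"))
    tables <- bind_trajectories(tables)
  nt <- length(tables$times)
  if (nt < 3)
    stop("teacher forcing requires intermediate observations (>= 3 time points); ",
         "use train_endpoint() for initial/final data")
  scaler <- fit_scaler(tables, normalize_all = normalize_all)
  arr <- scaler_transform(scaler, feature_array(tables))
  n_feat <- dim(arr)[3]
  if (is.null(model)) {
    w <- lstm_weights(n_feat, config$hidden_dim, n_feat, seed = config$seed)
    model <- new_lstm_model(w, scaler, tables$species, tables$metabolites)
  } else {
    d <- attr(model$weights, "dims")
    if (d[["input"]] != n_feat)
      stop(if (!is.null(model$metabolites) && is.null(tables$metabolites))
             "model expects metabolite columns but the tables carry none"
           else paste0("model input dimension ", d[["input"]],
                       " does not match the data's ", n_feat, " features"))
  }
  model$scaler <- scaler
  model$times <- tables$times
  model$config <- config
  fit <- run_training(model, arr, K = nt - 1, config,
                      endpoint_only = FALSE, met_targets = NULL)
  fit$n_steps <- nt - 1
  fit
}

#' Train an endpoint LSTM (initial state to final state, optional metabolite head)
#'
#' For datasets with only initial and final observations the model unrolls
#' `config$n_steps` LSTM units free-running (teacher forcing is impossible
#' without intermediate truths) and the loss is taken at the final output.
#' When `head_layers` is non-NULL (or the model already carries a head) and
#' the tables include endpoint metabolite concentrations, a feed-forward head
#' maps the final abundance output to metabolites and the whole network is
#' trained end-to-end with equal weight on the standardized abundance and
#' metabolite losses. Feature standardization is global per feature in this
#' mode.
#'
#' @inheritParams train_teacher_forcing
#' @param head_layers Hidden sizes for the metabolite head, or NULL for none.
#' @return A trained endpoint-mode `lstm_model`.
#' @export
train_endpoint <- function(tables, config = training_config(),
                           head_layers = NULL, model = NULL) {
  if (is.list(tables) && !inherits(tables, "trajectory_table"))
    tables <- bind_trajectories(tables)
  nt <- length(tables$times)
  scaler <- fit_scaler(trajectory_table(tables$X, tables$times,
                                        designs = tables$designs,
                                        sample_id = tables$sample_id,
                                        species = tables$species),
                       per_timepoint = FALSE)
  arr <- scaler_transform(scaler, tables$X)
  ns <- dim(arr)[3]
  if (is.null(model)) {
    w <- lstm_weights(ns, config$hidden_dim, ns, seed = config$seed)
    model <- new_lstm_model(w, scaler, tables$species, mode = "endpoint")
  }
  model$mode <- "endpoint"
  model$scaler <- scaler
  model$times <- tables$times
  model$config <- config
  model$n_steps <- config$n_steps
  met_targets <- NULL
  if (!is.null(head_layers) && is.null(model$head))
    model <- attach_metabolite_head(model, head_layers,
                                    n_metabolites = if (is.null(tables$C)) 4
                                                    else dim(tables$C)[3],
                                    seed = config$seed + 1)
  if (!is.null(model$head)) {
    if (is.null(tables$C))
      stop("a metabolite head requires endpoint metabolite observations (missing metabolite columns)")
    endC <- tables$C[, nt, , drop = TRUE]
    if (is.null(dim(endC))) endC <- matrix(endC, ncol = dim(tables$C)[3])
    mu <- colMeans(endC)
    sg <- pmax(sqrt(colMeans(sweep(endC, 2, mu)^2)), scaler$eps)
    model$met_scaler <- list(mu = mu, sigma = sg)
    met_targets <- t(sweep(sweep(endC, 2, mu), 2, sg, "/"))  # M x n
  }
  # endpoint training uses only x0 and the final observation
  arr2 <- arr[, c(1, nt), , drop = FALSE]
  run_training(model, arr2, K = config$n_steps, config,
               endpoint_only = TRUE, met_targets = met_targets)
}

run_training <- function(model, arr, K, config, endpoint_only, met_targets) {
  n <- dim(arr)[1]; n_feat <- dim(arr)[3]
  params <- flatten_params(model$weights, model$head)
  state <- adam_state(params)
  n_head <- if (is.null(model$head)) 0L else length(model$head)
  loss_history <- numeric(config$epochs)
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- config$learning_rate *
        config$lr_decay^((epoch - 1) %/% config$lr_decay_every)
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (idx in batches) {
        upd <- unflatten_params(params, model$weights, model$head)
        weights <- upd$weights; head <- upd$head
        B <- length(idx)
        x0 <- t(matrix(arr[idx, 1, ], B, n_feat))
        if (endpoint_only) {
          truth <- NULL
          tf_mask <- NULL
          final <- t(matrix(arr[idx, 2, ], B, n_feat))
        } else {
          truth <- lapply(seq_len(K), function(k) t(matrix(arr[idx, k + 1, ], B, n_feat)))
          tf_mask <- matrix(runif(K * B) < config$teacher_forcing_prob, K, B)
          tf_mask[1, ] <- FALSE
        }
        fwd <- lstm_forward(weights, x0, K, truth, tf_mask)
        dY <- vector("list", K)
        loss <- 0
        if (endpoint_only) {
          err <- fwd$Y[[K]] - final
          loss <- loss + mean(err^2)
          dY[[K]] <- 2 * err / length(err)
          hgrads <- NULL
          if (!is.null(head)) {
            hf <- ffn_forward(head, fwd$Y[[K]])
            merr <- hf$out - met_targets[, idx, drop = FALSE]
            loss <- loss + mean(merr^2)
            hb <- ffn_backward(head, hf, 2 * merr / length(merr))
            hgrads <- hb$grads
            dY[[K]] <- dY[[K]] + hb$dx
          }
        } else {
          denom <- K * n_feat * B
          for (k in seq_len(K)) {
            err <- fwd$Y[[k]] - truth[[k]]
            loss <- loss + sum(err^2) / denom
            dY[[k]] <- 2 * err / denom
          }
          hgrads <- NULL
        }
        if (!is.finite(loss))
          stop("training loss became non-finite at epoch ", epoch)
        bwd <- lstm_backward(weights, fwd, dY)
        grads <- bwd$grads
        if (n_head > 0) {
          if (is.null(hgrads))
            hgrads <- lapply(head, function(l)
              list(W = matrix(0, nrow(l$W), ncol(l$W)), b = numeric(length(l$b))))
          for (l in seq_len(n_head)) {
            grads[[paste0("head_W", l)]] <- hgrads[[l]]$W
            grads[[paste0("head_b", l)]] <- hgrads[[l]]$b
          }
        }
        # L2 weight decay on all parameters
        for (nm in names(params))
          grads[[nm]] <- grads[[nm]] + config$weight_decay * params[[nm]]
        up <- adam_update(params, grads, state, lr)
        params <- up$params
        state <- up$state
        ep_loss <- ep_loss + loss * B
      }
      loss_history[epoch] <- ep_loss / n
    }
  })
  upd <- unflatten_params(params, model$weights, model$head)
  model$weights <- upd$weights
  model$head <- upd$head
  model$loss_history <- loss_history
  model
}

# ---- prediction ------------------------------------------------------------

#' Free-running rollout of a trained LSTM
#'
#' Standardizes the initial state with the model's scaler, feeds each
#' prediction back as the next input, and returns the de-standardized
#' sequence (initial state included). `n_steps = 0` returns the input
#' unchanged.
#'
#' @param model A trained `lstm_model`.
#' @param x0 Initial state on the original scale: vector of length
#'   `n_features` or an `n_samples x n_features` matrix.
#' @param n_steps Number of steps; defaults to the model's training horizon.
#' @return Array `n_samples x (n_steps + 1) x n_features` on the original
#'   scale.
#' @export
rollout <- function(model, x0, n_steps = NULL) {
  if (is.null(model$scaler)) stop("model has no fitted scaler; train it first")
  if (is.null(n_steps)) n_steps <- model$n_steps
  if (!is.matrix(x0)) x0 <- matrix(x0, nrow = 1)
  n_feat <- attr(model$weights, "dims")[["input"]]
  if (ncol(x0) != n_feat) stop("x0 must have ", n_feat, " features")
  out <- array(0, dim = c(nrow(x0), n_steps + 1, n_feat))
  out[, 1, ] <- x0
  if (n_steps == 0) return(out)
  if (model$scaler$per_timepoint && n_steps + 1 > nrow(model$scaler$mu))
    stop("n_steps exceeds the per-timepoint scaler's training grid")
  x0_std <- scaler_transform(model$scaler, x0, k = 1)
  fwd <- lstm_forward(model$weights, t(x0_std), n_steps)
  for (k in seq_len(n_steps))
    out[, k + 1, ] <- scaler_inverse(model$scaler, t(fwd$Y[[k]]), k = k + 1)
  out
}

# initial raw state implied by a presence/absence design
design_x0 <- function(designs, species, x0_per_species = 0.0066) {
  dm <- as_design_matrix(designs, species)
  dm * x0_per_species
}

#' Predict endpoint abundances and metabolites from community designs
#'
#' Converts presence/absence designs to initial states (equal per-species
#' inoculum), rolls the endpoint model forward and returns the final
#' de-standardized species abundances plus, if a metabolite head is attached,
#' the predicted metabolite concentrations.
#'
#' @param model An endpoint-mode `lstm_model`.
#' @param designs A [community_design()] or binary design matrix.
#' @return List with `abundance` (`n x n_species`) and `metabolites`
#'   (`n x n_metabolites` or NULL).
#' @export
predict_endpoint <- function(model, designs) {
  x0 <- design_x0(designs, model$species, model$x0_per_species)
  K <- model$n_steps
  x0_std <- scaler_transform(model$scaler, x0, k = 1)
  fwd <- lstm_forward(model$weights, t(x0_std), K)
  ab <- scaler_inverse(model$scaler, t(fwd$Y[[K]]),
                       k = if (model$scaler$per_timepoint) K + 1 else 1)
  colnames(ab) <- model$species
  met <- NULL
  if (!is.null(model$head)) {
    m_std <- t(ffn_forward(model$head, fwd$Y[[K]])$out)
    met <- sweep(sweep(m_std, 2, model$met_scaler$sigma, "*"), 2,
                 model$met_scaler$mu, "+")
    colnames(met) <- model$metabolites
  }
  list(abundance = ab, metabolites = met)
}
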