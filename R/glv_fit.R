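# ---- differentiable RK4-unrolled pairwise gLV ------------------------------
#
# The fitted model is pairwise-only: dx_i/dt = (r_i + sum_j a_ij x_j) x_i.
# States are S x B matrices (B communities integrated simultaneously);
# absent species start at zero and remain exactly zero under the dynamics.

glv_pair_rhs <- function(x, r, A) (r + A %*% x) * x

# vector-Jacobian products of the pairwise RHS
glv_pair_vjp <- function(x, lam, r, A) {
  growth <- r + A %*% x
  list(dx = lam * growth + crossprod(A, x * lam),
       dr = rowSums(lam * x),
       dA = (lam * x) %*% t(x))
}

# forward fixed-step RK4 over the reporting grid; returns states at reports
# and the full substep cache for the backward pass
rk4_forward <- function(r, A, x0, times, nsub) {
  S <- nrow(x0); B <- ncol(x0)
  n_rep <- length(times)
  states <- vector("list", n_rep)
  states[[1]] <- x0
  cache <- list()
  x <- x0
  ci <- 0L
  for (seg in seq_len(n_rep - 1)) {
    h <- (times[seg + 1] - times[seg]) / nsub
    for (s in seq_len(nsub)) {
      k1 <- glv_pair_rhs(x, r, A)
      x2 <- x + h / 2 * k1; k2 <- glv_pair_rhs(x2, r, A)
      x3 <- x + h / 2 * k2; k3 <- glv_pair_rhs(x3, r, A)
      x4 <- x + h * k3;     k4 <- glv_pair_rhs(x4, r, A)
      ci <- ci + 1L
      cache[[ci]] <- list(x = x, x2 = x2, x3 = x3, x4 = x4, h = h)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    states[[seg + 1]] <- x
  }
  list(states = states, cache = cache, nsub = nsub)
}

# backward pass: dstates is a list of adjoints (S x B or NULL) at each report
rk4_backward <- function(r, A, fwd, dstates, times) {
  S <- length(r)
  dr <- numeric(S); dA <- matrix(0, S, S)
  lam <- NULL
  ci <- length(fwd$cache)
  n_rep <- length(times)
  add <- function(a, b) if (is.null(a)) b else a + b
  lam <- dstates[[n_rep]]
  if (is.null(lam)) lam <- fwd$states[[n_rep]] * 0
  for (seg in (n_rep - 1):1) {
    for (s in seq_len(fwd$nsub)) {
      cc <- fwd$cache[[ci]]; ci <- ci - 1L
      h <- cc$h
      dx <- lam
      dk1 <- h / 6 * lam; dk2 <- h / 3 * lam
      dk3 <- h / 3 * lam; dk4 <- h / 6 * lam
      v4 <- glv_pair_vjp(cc$x4, dk4, r, A)
      dk3 <- dk3 + h * v4$dx; dx <- dx + 0 * v4$dx
      v3 <- glv_pair_vjp(cc$x3, dk3, r, A)
      dk2 <- dk2 + h / 2 * v3$dx
      v2 <- glv_pair_vjp(cc$x2, dk2, r, A)
      dk1 <- dk1 + h / 2 * v2$dx
      v1 <- glv_pair_vjp(cc$x, dk1, r, A)
      dx <- dx + v1$dx + v2$dx + v3$dx + v4$dx
      dr <- dr + v1$dr + v2$dr + v3$dr + v4$dr
      dA <- dA + v1$dA + v2$dA + v3$dA + v4$dA
      lam <- dx
    }
    if (!is.null(dstates[[seg]])) lam <- lam + dstates[[seg]]
  }
  list(dr = dr, dA = dA)
}

glv_fit_loss <- function(r, A, x0, obs, times, nsub) {
  fwd <- rk4_forward(r, A, x0, times, nsub)
  n_rep <- length(times)
  denom <- (n_rep - 1) * length(x0)
  loss <- 0
  dstates <- vector("list", n_rep)
  for (k in 2:n_rep) {
    err <- fwd$states[[k]] - obs[[k]]
    if (!all(is.finite(err))) return(list(loss = Inf))
    loss <- loss + sum(err^2) / denom
    dstates[[k]] <- 2 * err / denom
  }
  g <- rk4_backward(r, A, fwd, dstates, times)
  list(loss = loss, dr = g$dr, dA = g$dA)
}

# Warm start from log-derivative regression: per-capita growth between
# consecutive samples is linear in the mean abundances, so each species' row
# of (r, A) solves an ordinary least-squares problem.
glv_warm_start <- function(x0, obs, times, tiny = 1e-8) {
  S <- nrow(x0)
  Xl <- list(); Zl <- list()
  n_rep <- length(times)
  for (k in seq_len(n_rep - 1)) {
    dt <- times[k + 1] - times[k]
    xa <- t(obs[[k]]); xb <- t(obs[[k + 1]])    # B x S
    Xl[[k]] <- (xa + xb) / 2
    z <- matrix(NA_real_, nrow(xa), S)
    ok <- xa > tiny & xb > tiny
    z[ok] <- (log(xb[ok]) - log(xa[ok])) / dt
    Zl[[k]] <- z
  }
  Xall <- do.call(rbind, Xl); Zall <- do.call(rbind, Zl)
  r <- runif(S, 0.1, 0.8); A <- matrix(0, S, S); diag(A) <- -1
  for (i in seq_len(S)) {
    keep <- is.finite(Zall[, i])
    if (sum(keep) >= S + 2) {
      co <- tryCatch(coef(lm.fit(cbind(1, Xall[keep, , drop = FALSE]), Zall[keep, i])),
                     error = function(e) NULL)
      if (!is.null(co) && all(is.finite(co))) {
        r[i] <- co[1]; A[i, ] <- co[-1]
      }
    }
  }
  list(r = r, A = A)
}

#' Fit a pairwise gLV model to observed trajectories
#'
#' Minimizes the mean squared error between simulated and observed abundances
#' with multistart Adam on a differentiable fixed-step RK4-unrolled loss.
#' The fitted model is pairwise-only (no third-order terms), which makes it
#' structurally misspecified when the data were produced with higher-order
#' interactions -- the benchmark exploits exactly that contrast. One start is
#' a log-derivative least-squares warm start; the rest are random.
#'
#' @param tables A [trajectory_table()] (or list) with >= 2 time points.
#' @param n_starts Number of optimization starts (default 8).
#' @param iters Adam iterations per start.
#' @param lr Adam learning rate.
#' @param nsub RK4 substeps per reporting interval.
#' @param seed Integer seed for the random starts.
#' @return A [glv_params()] object (strict diagonal check relaxed) with
#'   attributes `loss` (best training MSE) and `loss_per_start`.
#' @export
fit_glv <- function(tables, n_starts = 8, iters = 400, lr = 0.05, nsub = NULL,
                    seed = 1) {
  if (is.list(tables) && !inherits(tables, "trajectory_table"))
    tables <- bind_trajectories(tables)
  times <- tables$times
  if (length(times) < 2) stop("need at least 2 time points per table")
  S <- length(tables$species)
  obs <- lapply(seq_along(times), function(k) t(matrix(tables$X[, k, ], ncol = S)))
  x0 <- obs[[1]]
  if (is.null(nsub)) nsub <- max(1L, ceiling(max(diff(times)) / 0.5))
  starts <- list(glv_warm_start(x0, obs, times))
  with_seed(seed, {
    for (s in seq_len(max(0, n_starts - 1))) {
      starts[[s + 1]] <- list(r = runif(S, 0.1, 0.8),
                              A = {
                                A <- matrix(rnorm(S * S, 0, 0.2), S, S)
                                diag(A) <- runif(S, -1.5, -0.5); A
                              })
    }
  })
  best <- NULL
  loss_per_start <- numeric(length(starts))
  for (s in seq_along(starts)) {
    th <- list(r = starts[[s]]$r, A = starts[[s]]$A)
    mom <- list(r = 0 * th$r, A = 0 * th$A)
    vel <- list(r = 0 * th$r, A = 0 * th$A)
    cur_best <- list(loss = Inf)
    t_ad <- 0
    for (it in seq_len(iters)) {
      lr_it <- lr * 0.5^((it - 1) %/% max(1, iters %/% 3))
      g <- glv_fit_loss(th$r, th$A, x0, obs, times, nsub)
      if (!is.finite(g$loss)) break
      if (g$loss < cur_best$loss) cur_best <- list(loss = g$loss, r = th$r, A = th$A)
      t_ad <- t_ad + 1
      for (nm in c("r", "A")) {
        gr <- if (nm == "r") g$dr else g$dA
        mom[[nm]] <- 0.9 * mom[[nm]] + 0.1 * gr
        vel[[nm]] <- 0.999 * vel[[nm]] + 0.001 * gr^2
        th[[nm]] <- th[[nm]] - lr_it * (mom[[nm]] / (1 - 0.9^t_ad)) /
          (sqrt(vel[[nm]] / (1 - 0.999^t_ad)) + 1e-8)
      }
    }
    loss_per_start[s] <- cur_best$loss
    if (is.null(best) || cur_best$loss < best$loss) best <- cur_best
  }
  if (is.null(best) || !is.finite(best$loss))
    stop("gLV fit failed to converge from any start; best loss = ",
         if (is.null(best)) "Inf" else best$loss)
  out <- glv_params(best$r, best$A, species = tables$species, strict = FALSE)
  attr(out, "loss") <- best$loss
  attr(out, "loss_per_start") <- loss_per_start
  out
}

#' Predict trajectories from fitted gLV parameters
#'
#' Fast fixed-step RK4 prediction used to evaluate fitted pairwise models on
#' hold-out designs (the adaptive-step [simulate_glv()] is the ground-truth
#' path; fitted parameters need not satisfy its stability invariants).
#'
#' @inheritParams simulate_glv
#' @param nsub RK4 substeps per reporting interval.
#' @return A [trajectory_table()].
#' @export
predict_glv <- function(params, designs, times = seq(0, 48, by = 8),
                        x0_total = NULL, nsub = 16) {
  dm <- as_design_matrix(designs, params$species)
  S <- params$n_species
  x0 <- matrix(0, S, nrow(dm))
  for (s in seq_len(nrow(dm))) {
    pres <- dm[s, ] == 1
    tot <- if (is.null(x0_total)) 0.0066 * sum(pres) else x0_total
    x0[pres, s] <- tot / sum(pres)
  }
  fwd <- rk4_forward(params$r, params$A, x0, times, nsub)
  X <- array(0, dim = c(nrow(dm), length(times), S))
  for (k in seq_along(times)) X[, k, ] <- t(pmax(fwd$states[[k]], 0))
  bad <- !is.finite(X)
  if (any(bad)) X[bad] <- 0  # diverged fitted dynamics predict nothing useful
  trajectory_table(X, times, designs = dm, species = params$species)
}

# ---- discretized gLV baseline ----------------------------------------------

#' One step of the discretized gLV map
#'
#' The multiplicative update `x_i(t+1) = x_i(t) (r_i + sum_j a_ij x_j(t))`,
#' applied exactly as written -- note the absence of the `1 +` of a
#' forward-Euler step, so `r_i = 1, A = 0` is the identity map. Intended for
#' features scaled to \[0, 1\]; negative inputs are rejected.
#'
#' @param params List or [glv_params()] with `r` and `A`.
#' @param x_t Non-negative state vector (or matrix, species x batch).
#' @return The next state.
#' @export
step_glv_discrete <- function(params, x_t) {
  if (any(x_t < 0)) stop("discrete gLV requires non-negative inputs")
  x_t * as.vector(params$r + params$A %*% x_t)
}

#' Fit the discretized gLV baseline with a feed-forward metabolite head
#'
#' Trains the multiplicative discrete-time gLV map with the same stochastic
#' gradient machinery as the LSTM (Adam, randomized teacher forcing).
#' Features are scaled to \[0, 1\] by their per-timestep training maximum;
#' `r` and `A` are initialized to zero. Metabolite concentrations at step
#' t+1, when present, are predicted by a feed-forward network applied to the
#' abundance state x(t+1).
#'
#' @param tables A [trajectory_table()] with intermediate observations.
#' @param config A [training_config()].
#' @param head_layers Hidden sizes for the metabolite head (NULL = no head;
#'   requires metabolite columns when set).
#' @return Object of class `"dglv_model"` with `r`, `A`, optional `head`,
#'   scaling constants and loss history.
#' @export
fit_glv_discrete <- function(tables, config = training_config(), head_layers = NULL) {
  if (is.list(tables) && !inherits(tables, "trajectory_table"))
    tables <- bind_trajectories(tables)
  nt <- length(tables$times)
  if (nt < 2) stop("need at least 2 time points")
  S <- length(tables$species)
  n <- dim(tables$X)[1]
  xmax <- pmax(apply(tables$X, c(2, 3), max), 1e-8)
  if (!is.matrix(xmax)) xmax <- matrix(xmax, nt, S)
  arr <- tables$X
  for (k in seq_len(nt))
    arr[, k, ] <- sweep(matrix(arr[, k, ], n, S), 2, xmax[k, ], "/")
  has_met <- !is.null(head_layers)
  cmax <- NULL; carr <- NULL; head <- NULL
  if (has_met) {
    if (is.null(tables$C)) stop("head_layers set but the tables carry no metabolite columns")
    nm <- dim(tables$C)[3]
    cmax <- pmax(apply(tables$C, c(2, 3), max), 1e-8)
    if (!is.matrix(cmax)) cmax <- matrix(cmax, nt, nm)
    carr <- tables$C
    for (k in seq_len(nt))
      carr[, k, ] <- sweep(matrix(carr[, k, ], n, nm), 2, cmax[k, ], "/")
    head <- ffn_init(c(S, head_layers, dim(tables$C)[3]), seed = config$seed + 1)
  }
  r <- numeric(S); A <- matrix(0, S, S)   # zero initialization
  params <- c(list(r = r, A = A), if (has_met) flatten_head(head))
  state <- adam_state(params)
  K <- nt - 1
  loss_history <- numeric(config$epochs)
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- config$learning_rate * config$lr_decay^((epoch - 1) %/% config$lr_decay_every)
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (idx in batches) {
        B <- length(idx)
        r <- params$r; A <- params$A
        if (has_met) head <- unflatten_head(params, head)
        tf_mask <- matrix(runif(K * B) < config$teacher_forcing_prob, K, B)
        tf_mask[1, ] <- FALSE
        xs <- vector("list", K + 1)   # inputs actually used per step
        ys <- vector("list", K)
        hfs <- vector("list", K)
        fed_back <- vector("list", K)
        u <- t(matrix(arr[idx, 1, ], B, S))
        loss <- 0
        dY <- vector("list", K)
        denom <- K * S * B
        for (k in seq_len(K)) {
          if (k > 1) {
            fb <- rep(TRUE, B)
            u <- pmax(ys[[k - 1]], 0)
            truth_k <- t(matrix(arr[idx, k, ], B, S))
            use_true <- tf_mask[k, ]
            if (any(use_true)) { u[, use_true] <- truth_k[, use_true]; fb[use_true] <- FALSE }
            fed_back[[k]] <- fb
          } else fed_back[[k]] <- rep(FALSE, B)
          xs[[k]] <- u
          y <- u * as.vector(r + A %*% u)
          ys[[k]] <- y
          err <- y - t(matrix(arr[idx, k + 1, ], B, S))
          loss <- loss + sum(err^2) / denom
          dY[[k]] <- 2 * err / denom
          if (has_met) {
            hf <- ffn_forward(head, pmax(y, 0))
            hfs[[k]] <- hf
            merr <- hf$out - t(matrix(carr[idx, k + 1, ], B, nm))
            loss <- loss + sum(merr^2) / (K * B * nm)
            hb <- ffn_backward(head, hf, 2 * merr / (K * B * nm))
            dY[[k]] <- dY[[k]] + hb$dx * (y > 0)
            hfs[[k]]$grads <- hb$grads
          }
        }
        if (!is.finite(loss)) stop("training loss became non-finite at epoch ", epoch)
        dr <- 0 * r; dA <- 0 * A
        hgr <- if (has_met) lapply(head, function(l)
          list(W = 0 * l$W, b = 0 * l$b)) else NULL
        dcarry <- matrix(0, S, B)
        for (k in K:1) {
          dy <- dY[[k]] + dcarry
          u <- xs[[k]]
          growth <- as.vector(r + A %*% u)
          du <- dy * growth + crossprod(A, u * dy)
          dr <- dr + rowSums(dy * u)
          dA <- dA + (dy * u) %*% t(u)
          dcarry <- matrix(0, S, B)
          if (k > 1) {
            fb <- fed_back[[k]]
            if (any(fb)) {
              mask <- (ys[[k - 1]] > 0)
              dcarry[, fb] <- (du * mask)[, fb, drop = FALSE]
            }
          }
          if (has_met && !is.null(hfs[[k]]$grads)) {
            for (l in seq_along(head)) {
              hgr[[l]]$W <- hgr[[l]]$W + hfs[[k]]$grads[[l]]$W
              hgr[[l]]$b <- hgr[[l]]$b + hfs[[k]]$grads[[l]]$b
            }
          }
        }
        grads <- c(list(r = dr + config$weight_decay * params$r,
                        A = dA + config$weight_decay * params$A),
                   if (has_met) flatten_head_grads(hgr, config$weight_decay, params))
        up <- adam_update(params, grads, state, lr)
        params <- up$params; state <- up$state
        ep_loss <- ep_loss + loss * B
      }
      loss_history[epoch] <- ep_loss / n
    }
  })
  if (has_met) head <- unflatten_head(params, head)
  structure(list(r = params$r, A = params$A, head = head, xmax = xmax,
                 cmax = cmax, species = tables$species,
                 metabolites = tables$metabolites, times = tables$times,
                 config = config, loss_history = loss_history),
            class = "dglv_model")
}

flatten_head <- function(head) {
  out <- list()
  for (l in seq_along(head)) {
    out[[paste0("head_W", l)]] <- head[[l]]$W
    out[[paste0("head_b", l)]] <- head[[l]]$b
  }
  out
}

unflatten_head <- function(params, head) {
  for (l in seq_along(head)) {
    head[[l]]$W <- params[[paste0("head_W", l)]]
    head[[l]]$b <- params[[paste0("head_b", l)]]
  }
  head
}

flatten_head_grads <- function(hgr, wd, params) {
  out <- list()
  for (l in seq_along(hgr)) {
    out[[paste0("head_W", l)]] <- hgr[[l]]$W + wd * params[[paste0("head_W", l)]]
    out[[paste0("head_b", l)]] <- hgr[[l]]$b + wd * params[[paste0("head_b", l)]]
  }
  out
}

#' Free-running prediction with a fitted discretized gLV model
#'
#' @param model A `"dglv_model"` from [fit_glv_discrete()].
#' @param x0 Initial raw abundances (`n x n_species` matrix).
#' @return List with `X` (`n x n_times x n_species`, original scale) and,
#'   when the model has a head, `C` for metabolites.
#' @export
predict_glv_discrete <- function(model, x0) {
  if (!is.matrix(x0)) x0 <- matrix(x0, nrow = 1)
  S <- length(model$r); K <- length(model$times) - 1
  n <- nrow(x0)
  X <- array(0, dim = c(n, K + 1, S))
  X[, 1, ] <- x0
  has_met <- !is.null(model$head)
  C <- if (has_met) array(0, dim = c(n, K + 1, ncol(model$cmax))) else NULL
  u <- t(sweep(x0, 2, model$xmax[1, ], "/"))
  for (k in seq_len(K)) {
    y <- pmax(u * as.vector(model$r + model$A %*% u), 0)
    X[, k + 1, ] <- sweep(t(y), 2, model$xmax[k + 1, ], "*")
    if (has_met)
      C[, k + 1, ] <- sweep(t(ffn_forward(model$head, y)$out), 2, model$cmax[k + 1, ], "*")
    u <- y
  }
  list(X = X, C = C)
}
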