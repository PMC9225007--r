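# ---- LSTM core -------------------------------------------------------------
#
# A single shared-weight LSTM unit models the community state transition at
# each time step:
#
#   i_t = sigmoid(W_ii x_t + b_ii + W_hi h_{t-1} + b_hi)
#   f_t = sigmoid(W_if x_t + b_if + W_hf h_{t-1} + b_hf)
#   g_t = tanh   (W_ig x_t + b_ig + W_hg h_{t-1} + b_hg)
#   o_t = sigmoid(W_io x_t + b_io + W_ho h_{t-1} + b_ho)
#   c_t = f_t * c_{t-1} + i_t * g_t
#   h_t = o_t * tanh(c_t)
#
# and the output gate is mapped linearly to the next state prediction:
#
#   y_t = W_yo o_t + b_yo.
#
# During free-running rollout y_t is fed back as the next input; training
# backpropagates through that feedback path. All forward/backward passes are
# batched with features in rows and sequences in columns.

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Initialize LSTM weights
#'
#' Draws all gate weight matrices, biases and the output map uniformly on
#' `(-1/sqrt(hidden_dim), 1/sqrt(hidden_dim))` (fan-in scaling).
#'
#' @param input_dim,hidden_dim,output_dim Layer sizes.
#' @param seed Integer seed.
#' @return Named list of weight matrices/vectors with class `"lstm_weights"`.
#' @export
lstm_weights <- function(input_dim, hidden_dim, output_dim = input_dim, seed = 1) {
  s <- 1 / sqrt(hidden_dim)
  with_seed(seed, {
    rmat <- function(nr, nc) matrix(runif(nr * nc, -s, s), nr, nc)
    W <- list()
    for (g in c("i", "f", "g", "o")) {
      W[[paste0("Wi", g)]] <- rmat(hidden_dim, input_dim)
      W[[paste0("Wh", g)]] <- rmat(hidden_dim, hidden_dim)
      W[[paste0("bi", g)]] <- runif(hidden_dim, -s, s)
      W[[paste0("bh", g)]] <- runif(hidden_dim, -s, s)
    }
    W$Wyo <- rmat(output_dim, hidden_dim)
    W$byo <- runif(output_dim, -s, s)
    structure(W, class = "lstm_weights",
              dims = c(input = input_dim, hidden = hidden_dim, output = output_dim))
  })
}

#' Evaluate one LSTM unit
#'
#' Exact evaluation of the six gate/state equations for a single time step.
#' Inputs may be vectors or feature-by-batch matrices.
#'
#' @param x_t Input (length `input_dim`, or `input_dim x batch` matrix).
#' @param h_prev,c_prev Previous hidden and cell state (length `hidden_dim`
#'   or matrices).
#' @param weights An [lstm_weights()] list.
#' @return List with `h`, `c`, `o` (output gate), `y` (output-map
#'   prediction `W_yo o + b_yo`) and the gate cache used by backpropagation.
#' @export
lstm_cell_step <- function(x_t, h_prev, c_prev, weights) {
  d <- attr(weights, "dims")
  as_colmat <- function(v, nr, what) {
    if (!is.matrix(v)) v <- matrix(v, ncol = 1)
    if (nrow(v) != nr) stop("shape mismatch: ", what, " has ", nrow(v),
                            " rows, expected ", nr)
    v
  }
  x_t <- as_colmat(x_t, d[["input"]], "x_t")
  h_prev <- as_colmat(h_prev, d[["hidden"]], "h_prev")
  c_prev <- as_colmat(c_prev, d[["hidden"]], "c_prev")
  if (ncol(h_prev) != ncol(x_t) || ncol(c_prev) != ncol(x_t))
    stop("shape mismatch: batch sizes of x_t, h_prev, c_prev differ")
  pre <- function(g) {
    weights[[paste0("Wi", g)]] %*% x_t + weights[[paste0("bi", g)]] +
      weights[[paste0("Wh", g)]] %*% h_prev + weights[[paste0("bh", g)]]
  }
  i <- sigmoid(pre("i")); f <- sigmoid(pre("f"))
  g <- tanh(pre("g"));    o <- sigmoid(pre("o"))
  c_t <- f * c_prev + i * g
  tc <- tanh(c_t)
  h_t <- o * tc
  y <- weights$Wyo %*% o + weights$byo
  list(h = h_t, c = c_t, o = o, y = y,
       cache = list(x = x_t, h_prev = h_prev, c_prev = c_prev,
                    i = i, f = f, g = g, o = o, c = c_t, tc = tc))
}

# Forward pass over K steps. x0: D x B. truth: list of K matrices (D x B) of
# standardized observations at steps 2..K+1 (may be NULL in free-running
# prediction). tf_mask: K x B logical, TRUE = feed the true observation as
# input at that step (entry [1, ] is ignored: step 1 always takes x0).
lstm_forward <- function(weights, x0, n_steps, truth = NULL, tf_mask = NULL) {
  d <- attr(weights, "dims")
  B <- ncol(x0)
  h <- matrix(0, d[["hidden"]], B)
  cc <- matrix(0, d[["hidden"]], B)
  Y <- vector("list", n_steps)
  caches <- vector("list", n_steps)
  fed_back <- vector("list", n_steps)  # logical per column: input was y_{k-1}
  u <- x0
  for (k in seq_len(n_steps)) {
    if (k > 1) {
      fb <- rep(TRUE, B)
      u <- Y[[k - 1]]
      if (!is.null(tf_mask) && !is.null(truth)) {
        use_true <- tf_mask[k, ]
        if (any(use_true)) {
          u[, use_true] <- truth[[k - 1]][, use_true, drop = FALSE]
          fb[use_true] <- FALSE
        }
      }
      fed_back[[k]] <- fb
    } else fed_back[[k]] <- rep(FALSE, B)
    st <- lstm_cell_step(u, h, cc, weights)
    h <- st$h; cc <- st$c
    Y[[k]] <- st$y
    caches[[k]] <- st$cache
  }
  list(Y = Y, caches = caches, fed_back = fed_back)
}

# Backward pass. dY: list of K gradients (O x B) w.r.t. each y_k (loss
# terms only; feedback contributions are added internally). Returns weight
# gradients, the gradient w.r.t. x0, and optionally the gradient w.r.t. the
# input of step `input_grad_step`.
lstm_backward <- function(weights, fwd, dY, input_grad_step = NULL) {
  d <- attr(weights, "dims")
  K <- length(fwd$caches)
  B <- ncol(fwd$caches[[1]]$x)
  zero_like <- function(w) if (is.matrix(w)) matrix(0, nrow(w), ncol(w)) else numeric(length(w))
  grads <- lapply(weights, zero_like)
  dh <- matrix(0, d[["hidden"]], B)
  dc <- matrix(0, d[["hidden"]], B)
  dy_carry <- matrix(0, d[["output"]], B)
  dx0 <- NULL
  du_at <- NULL
  for (k in K:1) {
    cache <- fwd$caches[[k]]
    dy <- dy_carry
    if (!is.null(dY[[k]])) dy <- dy + dY[[k]]
    # y = Wyo o + byo
    grads$Wyo <- grads$Wyo + dy %*% t(cache$o)
    grads$byo <- grads$byo + rowSums(dy)
    do <- crossprod(weights$Wyo, dy)
    # h = o * tanh(c)
    do <- do + dh * cache$tc
    dc <- dc + dh * cache$o * (1 - cache$tc^2)
    # c = f * c_prev + i * g
    di <- dc * cache$g
    df <- dc * cache$c_prev
    dg <- dc * cache$i
    dc_prev <- dc * cache$f
    da <- list(i = di * cache$i * (1 - cache$i),
               f = df * cache$f * (1 - cache$f),
               g = dg * (1 - cache$g^2),
               o = do * cache$o * (1 - cache$o))
    du <- matrix(0, d[["input"]], B)
    dh_prev <- matrix(0, d[["hidden"]], B)
    for (gname in c("i", "f", "g", "o")) {
      a <- da[[gname]]
      grads[[paste0("Wi", gname)]] <- grads[[paste0("Wi", gname)]] + a %*% t(cache$x)
      grads[[paste0("Wh", gname)]] <- grads[[paste0("Wh", gname)]] + a %*% t(cache$h_prev)
      grads[[paste0("bi", gname)]] <- grads[[paste0("bi", gname)]] + rowSums(a)
      grads[[paste0("bh", gname)]] <- grads[[paste0("bh", gname)]] + rowSums(a)
      du <- du + crossprod(weights[[paste0("Wi", gname)]], a)
      dh_prev <- dh_prev + crossprod(weights[[paste0("Wh", gname)]], a)
    }
    if (!is.null(input_grad_step) && k == input_grad_step) du_at <- du
    dy_carry <- matrix(0, d[["output"]], B)
    if (k > 1) {
      fb <- fwd$fed_back[[k]]
      if (any(fb)) dy_carry[, fb] <- du[, fb, drop = FALSE]
    } else {
      dx0 <- du
    }
    dh <- dh_prev
    dc <- dc_prev
  }
  list(grads = grads, dx0 = dx0, du_at = du_at)
}

# ---- feed-forward metabolite head ------------------------------------------

# Head: list of layers (W, b); ReLU between layers, linear output.
ffn_init <- function(sizes, seed = 1) {
  with_seed(seed, {
    layers <- vector("list", length(sizes) - 1)
    for (l in seq_along(layers)) {
      s <- 1 / sqrt(sizes[l])
      layers[[l]] <- list(W = matrix(runif(sizes[l + 1] * sizes[l], -s, s),
                                     sizes[l + 1], sizes[l]),
                          b = runif(sizes[l + 1], -s, s))
    }
    layers
  })
}

ffn_forward <- function(layers, x) {
  acts <- list(x)
  for (l in seq_along(layers)) {
    z <- layers[[l]]$W %*% acts[[l]] + layers[[l]]$b
    acts[[l + 1]] <- if (l < length(layers)) pmax(z, 0) else z
  }
  list(out = acts[[length(acts)]], acts = acts)
}

ffn_backward <- function(layers, fwd, dout) {
  L <- length(layers)
  grads <- vector("list", L)
  dz <- dout
  for (l in L:1) {
    a_in <- fwd$acts[[l]]
    grads[[l]] <- list(W = dz %*% t(a_in), b = rowSums(dz))
    dx <- crossprod(layers[[l]]$W, dz)
    if (l > 1) dz <- dx * (fwd$acts[[l]] > 0)  # ReLU mask of the layer below's output
    else dz <- dx
  }
  list(grads = grads, dx = dz)
}
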