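# ---- local surrogate (LIME-style) explanations -----------------------------

#' Explain a prediction locally with a weighted linear surrogate
#'
#' Quantifies the impact of each species' presence on one model output for
#' one community instance: binary perturbations of the presence vector are
#' drawn, the model is queried on each, and an exponentially kernel-weighted
#' ridge regression is fit on the perturbation matrix. The returned
#' per-species coefficients are signed local effect estimates (in the target
#' variable's units).
#'
#' @param model Either an endpoint-mode `lstm_model` (queried through
#'   [predict_endpoint()]) or a function mapping a binary design matrix to a
#'   numeric prediction vector.
#' @param instance A [community_design()] (or binary vector) to explain.
#' @param target Output name (metabolite or species code) when `model` is an
#'   `lstm_model`; ignored for a function.
#' @param n_perturbations Number of perturbed designs (default 5000).
#' @param kernel_width Exponential kernel width on Hamming distance
#'   (default `0.75 * sqrt(d)`).
#' @param ridge Ridge penalty (default 1).
#' @param seed Integer seed.
#' @return Object of class `"lime_explanation"`: list with `weights` (named,
#'   one per pool species), `intercept`, `instance`, `target`.
#' @export
lime_explain <- function(model, instance, target = NULL, n_perturbations = 5000,
                         kernel_width = NULL, ridge = 1, seed = 1) {
  if (inherits(model, "lstm_model")) {
    pool <- model$species
    mdl <- model
    predict_fun <- function(Z) {
      pe <- predict_endpoint(mdl, Z)
      if (is.null(target)) stop("'target' must name a species or metabolite output")
      if (target %in% colnames(pe$abundance)) pe$abundance[, target]
      else if (!is.null(pe$metabolites) && target %in% colnames(pe$metabolites))
        pe$metabolites[, target]
      else stop("unknown target variable '", target, "'")
    }
  } else if (is.function(model)) {
    predict_fun <- model
    pool <- names(instance)
    if (is.null(pool)) pool <- make_pool_codes(length(instance))
  } else stop("'model' must be an lstm_model or a prediction function")
  z0 <- as.integer(instance)
  if (sum(z0) < 1) stop("cannot explain an empty community (richness 0)")
  d <- length(z0)
  if (is.null(kernel_width)) kernel_width <- 0.75 * sqrt(d)
  with_seed(seed, {
    Z <- matrix(rbinom(n_perturbations * d, 1, 0.5), n_perturbations, d)
    Z[rowSums(Z) == 0, sample.int(d, 1)] <- 1L  # keep designs non-empty
    colnames(Z) <- pool
    y <- predict_fun(Z)
    stopifnot(length(y) == n_perturbations)
    ham <- rowSums(Z != matrix(z0, n_perturbations, d, byrow = TRUE))
    w <- exp(-(ham^2) / kernel_width^2)
    # weighted ridge in closed form: (X'WX + lambda I)^{-1} X'Wy, intercept
    # unpenalized
    X <- cbind(1, Z)
    XtW <- t(X * w)
    pen <- diag(c(0, rep(ridge, d)))
    beta <- solve(XtW %*% X + pen, XtW %*% y)
  })
  weights <- setNames(as.numeric(beta[-1]), pool)
  structure(list(weights = weights, intercept = as.numeric(beta[1]),
                 instance = setNames(z0, pool), target = target),
            class = "lime_explanation")
}

#' @export
print.lime_explanation <- function(x, ...) {
  cat("<lime_explanation>", if (!is.null(x$target)) paste("target:", x$target),
      "\n")
  top <- sort(abs(x$weights), decreasing = TRUE)
  print(round(x$weights[names(head(top, 6))], 4))
  invisible(x)
}

#' Aggregate local explanations into a signed interaction network
#'
#' Edge weight between a source species and a target variable is the median
#' explanation weight across all explained instances. Targets must pass a
#' cross-validated predictability gate (CV R-squared > `r2_gate`); edges to
#' species targets are first normalized by the target species' self-impact
#' (its own median weight on itself) and metabolite edges are kept in
#' concentration units. Edges below the relevant absolute threshold are
#' dropped.
#'
#' @param explanations List of [lime_explain()] results (any mix of targets).
#' @param cv_r2 Named vector of cross-validated R-squared per target
#'   variable; targets absent from it are treated as failing the gate.
#' @param metabolite_threshold Minimum |median weight| for metabolite targets
#'   (units mM, default 5).
#' @param species_threshold Minimum |normalized median weight| for species
#'   targets (default 0.2).
#' @param r2_gate Eligibility cutoff on CV R-squared (default 0.5, strict).
#' @param metabolites Names treated as metabolite targets.
#' @return Object of class `"explanation_network"`: a data frame of edges
#'   (`source`, `target`, `weight`, `sign`) plus the thresholds and gate used.
#' @export
build_explanation_network <- function(explanations, cv_r2,
                                      metabolite_threshold = 5,
                                      species_threshold = 0.2, r2_gate = 0.5,
                                      metabolites = metabolite_names()) {
  targets <- vapply(explanations, function(e) e$target, "")
  if (anyNA(targets) || any(targets == ""))
    stop("every explanation must carry a target name")
  pool <- names(explanations[[1]]$weights)
  med_w <- function(tgt) {
    ws <- do.call(rbind, lapply(explanations[targets == tgt],
                                function(e) e$weights))
    apply(ws, 2, median)
  }
  edges <- list()
  for (tgt in unique(targets)) {
    eligible <- !is.na(cv_r2[tgt]) && cv_r2[tgt] > r2_gate
    if (!eligible) next
    m <- med_w(tgt)
    if (tgt %in% metabolites) {
      thr <- metabolite_threshold
    } else {
      self <- m[tgt]
      if (is.na(self) || self == 0)
        stop("species target '", tgt, "' has zero self-impact; cannot normalize")
      m <- m / abs(self)
      thr <- species_threshold
    }
    keep <- abs(m) >= thr
    if (any(keep))
      edges[[tgt]] <- data.frame(source = pool[keep], target = tgt,
                                 weight = unname(m[keep]),
                                 sign = sign(unname(m[keep])))
  }
  out <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(), target = character(),
               weight = numeric(), sign = numeric())
  rownames(out) <- NULL
  structure(list(edges = out,
                 thresholds = c(metabolite = metabolite_threshold,
                                species = species_threshold),
                 r2_gate = r2_gate),
            class = "explanation_network")
}

#' @export
print.explanation_network <- function(x, ...) {
  cat("<explanation_network> ", nrow(x$edges), " edge(s), R2 gate > ",
      x$r2_gate, "\n", sep = "")
  if (nrow(x$edges)) print(x$edges)
  invisible(x)
}

#' Export an explanation network
#'
#' Writes the edge list as CSV (`source,target,median_weight,sign,threshold`)
#' or GraphML.
#'
#' @param network An [build_explanation_network()] result.
#' @param path Output path; `.graphml` extension selects GraphML.
#' @export
write_explanation_network <- function(network, path) {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    g <- igraph::graph_from_data_frame(network$edges[, c("source", "target")],
                                       directed = TRUE)
    igraph::E(g)$weight <- network$edges$weight
    igraph::E(g)$sign <- network$edges$sign
    igraph::write_graph(g, path, format = "graphml")
  } else {
    df <- data.frame(source = network$edges$source,
                     target = network$edges$target,
                     median_weight = network$edges$weight,
                     sign = network$edges$sign,
                     threshold = ifelse(network$edges$target %in% metabolite_names(),
                                        network$thresholds["metabolite"],
                                        network$thresholds["species"]))
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

# ---- gradient sensitivity ---------------------------------------------------

#' A linear map as a trivially interpretable model
#'
#' Utility wrapper whose gradient sensitivity is its own coefficient matrix;
#' useful for validating interpretation code.
#'
#' @param W Coefficient matrix (outputs x inputs).
#' @return Object of class `"linear_map"`.
#' @export
linear_map <- function(W) structure(list(W = W), class = "linear_map")

#' Sensitivity of model outputs to initial inputs via backpropagation
#'
#' With the trained weights frozen, computes exact reverse-mode partial
#' derivatives of every model output at every rollout step with respect to
#' the inputs at a chosen time (default the initial state). The sign of
#' `d(output)/d(input)` indicates a positive or negative local contribution
#' and the magnitude its strength; derivatives are reported on the original
#' (de-standardized) scale by default.
#'
#' @param model A trained `lstm_model`, or a [linear_map()].
#' @param x0 Initial state on the original scale (vector of model features),
#'   e.g. the state implied by a community design; unused for a linear map.
#' @param at_time Index (1-based, on the rollout grid) of the input the
#'   derivatives are taken with respect to; default 1 (time zero).
#' @param scale `"original"` (chain the scaler through, default) or
#'   `"standardized"`.
#' @param n_steps Rollout length; defaults to the model's horizon.
#' @return For an `lstm_model`: array `n_steps x n_outputs x n_inputs`,
#'   where entry `[k, j, i]` is the derivative of output j at step k with
#'   respect to input i at `at_time`. For a `linear_map`: its matrix `W`.
#' @export
gradient_sensitivity <- function(model, x0 = NULL, at_time = 1,
                                 scale = c("original", "standardized"),
                                 n_steps = NULL) {
  scale <- match.arg(scale)
  if (inherits(model, "linear_map")) return(model$W)
  stopifnot(inherits(model, "lstm_model"))
  if (is.null(model$scaler)) stop("model has no fitted scaler")
  if (is.null(n_steps)) n_steps <- model$n_steps
  d <- attr(model$weights, "dims")
  n_feat <- d[["input"]]
  if (length(x0) != n_feat) stop("x0 must supply all ", n_feat, " model features")
  if (at_time > n_steps) stop("at_time must lie within the rollout")
  x0_std <- as.numeric(scaler_transform(model$scaler, matrix(x0, 1), k = 1))
  fwd <- lstm_forward(model$weights, matrix(x0_std, ncol = 1), n_steps)
  n_out <- d[["output"]]
  out <- array(0, dim = c(n_steps, n_out, n_feat),
               dimnames = list(NULL, feature_labels(model), feature_labels(model)))
  sig_at <- function(k) {
    if (model$scaler$per_timepoint) model$scaler$sigma[k, ] else model$scaler$sigma
  }
  for (k in at_time:n_steps) {
    for (j in seq_len(n_out)) {
      dY <- vector("list", n_steps)
      seedv <- matrix(0, n_out, 1); seedv[j, 1] <- 1
      dY[[k]] <- seedv
      bwd <- lstm_backward(model$weights, fwd, dY,
                           input_grad_step = if (at_time > 1) at_time else NULL)
      g <- if (at_time > 1) bwd$du_at else bwd$dx0
      g <- as.numeric(g)
      if (scale == "original")
        g <- g * sig_at(k + 1)[j] / sig_at(at_time)
      out[k, j, ] <- g
    }
  }
  out
}

feature_labels <- function(model) c(model$species, model$metabolites)

# ---- prediction-sensitivity statistics -------------------------------------

#' Prediction performance as a function of training-set size
#'
#' Randomly subsamples the dataset at several fractions, runs k-fold
#' cross-validation on each subsample, scores each output by the squared
#' Pearson correlation of pooled out-of-fold predictions against truth, and
#' reports the mean and standard deviation over repeats.
#'
#' @param X Feature matrix (rows = communities, e.g. presence bits).
#' @param Y Output matrix (rows matching `X`), one column per variable.
#' @param fractions Subsampling fractions (default 0.5 to 1 by 0.1).
#' @param n_repeats Repeats per fraction (default 30).
#' @param cv_folds Cross-validation folds (default 20).
#' @param fit_fun Function `(X_train, y_train)` returning a prediction
#'   function `(X_new) -> numeric`; default ordinary least squares.
#' @param seed Integer seed.
#' @return Data frame with columns `output`, `fraction`, `mean_r2`, `sd_r2`.
#' @export
subsample_sensitivity <- function(X, Y, fractions = seq(0.5, 1, by = 0.1),
                                  n_repeats = 30, cv_folds = 20,
                                  fit_fun = NULL, seed = 1) {
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1, dimnames = list(NULL, "y"))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  n <- nrow(X)
  if (n < cv_folds) stop("dataset smaller than the number of CV folds")
  if (is.null(fit_fun)) fit_fun <- ols_fit_fun
  seeds <- derive_seeds(seed, length(fractions) * n_repeats)
  res <- list()
  si <- 0L
  for (fr in fractions) {
    m <- floor(fr * n)
    if (m < cv_folds)
      stop("fraction ", fr, " yields ", m, " samples, fewer than ", cv_folds,
           " folds")
    r2s <- matrix(NA_real_, n_repeats, ncol(Y))
    for (rep_i in seq_len(n_repeats)) {
      si <- si + 1L
      with_seed(seeds[si], {
        idx <- if (m < n) sample.int(n, m) else seq_len(n)
        folds <- sample(rep(seq_len(cv_folds), length.out = m))
        preds <- matrix(NA_real_, m, ncol(Y))
        for (f in seq_len(cv_folds)) {
          tr <- idx[folds != f]; te <- idx[folds == f]
          for (j in seq_len(ncol(Y))) {
            pf <- fit_fun(X[tr, , drop = FALSE], Y[tr, j])
            preds[folds == f, j] <- pf(X[te, , drop = FALSE])
          }
        }
        for (j in seq_len(ncol(Y)))
          r2s[rep_i, j] <- tryCatch(pearson_r2(preds[, j], Y[idx, j]),
                                    error = function(e) NA_real_)
      })
    }
    for (j in seq_len(ncol(Y)))
      res[[length(res) + 1]] <- data.frame(output = colnames(Y)[j], fraction = fr,
                                           mean_r2 = mean(r2s[, j], na.rm = TRUE),
                                           sd_r2 = sd(r2s[, j]))
  }
  do.call(rbind, res)
}

ols_fit_fun <- function(Xtr, ytr) {
  # drop constant columns to keep the solve well posed
  keep <- apply(Xtr, 2, function(v) length(unique(v)) > 1)
  fit <- lm.fit(cbind(1, Xtr[, keep, drop = FALSE]), ytr)
  co <- fit$coefficients
  co[is.na(co)] <- 0
  function(Xn) as.numeric(cbind(1, Xn[, keep, drop = FALSE]) %*% co)
}

#' Pairwise prediction sensitivity of a metabolite
#'
#' Measures how much communities containing a species pair are predicted
#' better or worse than communities containing the single species: with
#' R2_i the squared Pearson correlation of out-of-fold predictions over the
#' subset of communities initially containing species i, and R2_ij over
#' communities containing both i and j,
#' \deqn{100 / N^2 \sum_i \sum_{j \ne i} (R^2_{ij} - R^2_i) / R^2_i.}
#' The normalizer is `N^2` exactly as conventionally printed;
#' `normalizer = "pairs"` divides by `N (N - 1)` instead.
#'
#' @param pred,true Out-of-fold predicted and true values, one per community.
#' @param designs Binary design matrix (rows matching `pred`).
#' @param normalizer `"n_squared"` (default) or `"pairs"`.
#' @param min_subset Minimum subset size for a defined R-squared (default 3).
#' @return Object of class `"sensitivity_report"`: list with the
#'   `pairwise_sensitivity` percentage, per-species `r2_i`, per-pair matrix
#'   `r2_ij`, subset sizes and any skipped pairs.
#' @export
pairwise_sensitivity <- function(pred, true, designs,
                                 normalizer = c("n_squared", "pairs"),
                                 min_subset = 3) {
  normalizer <- match.arg(normalizer)
  dm <- as_design_matrix(designs)
  S <- ncol(dm)
  stopifnot(length(pred) == nrow(dm), length(true) == nrow(dm))
  safe_r2 <- function(sel) {
    if (sum(sel) < min_subset) return(NA_real_)
    tryCatch(pearson_r2(pred[sel], true[sel]), error = function(e) NA_real_)
  }
  r2_i <- vapply(seq_len(S), function(i) safe_r2(dm[, i] == 1), 0)
  names(r2_i) <- colnames(dm)
  r2_ij <- matrix(NA_real_, S, S, dimnames = list(colnames(dm), colnames(dm)))
  n_ij <- matrix(0L, S, S)
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      if (j == i) next
      sel <- dm[, i] == 1 & dm[, j] == 1
      n_ij[i, j] <- sum(sel)
      r2_ij[i, j] <- safe_r2(sel)
    }
  }
  res <- pairwise_sensitivity_from_r2(r2_i, r2_ij, normalizer)
  if (length(res$skipped))
    warning(length(res$skipped),
            " species pair(s) skipped (undefined subset R2): ",
            paste(head(res$skipped, 5), collapse = ", "),
            if (length(res$skipped) > 5) ", ...")
  structure(list(pairwise_sensitivity = res$value,
                 r2_i = r2_i, r2_ij = r2_ij,
                 n_i = colSums(dm), n_ij = n_ij, skipped = res$skipped,
                 normalizer = normalizer),
            class = "sensitivity_report")
}

#' @rdname pairwise_sensitivity
#' @param r2_i Named vector of per-species subset R-squared values.
#' @param r2_ij Matrix of per-pair subset R-squared values (NA = undefined,
#'   skipped with the pair recorded).
#' @return `pairwise_sensitivity_from_r2()` returns a list with the
#'   sensitivity `value` (percent) and the `skipped` pairs.
#' @export
pairwise_sensitivity_from_r2 <- function(r2_i, r2_ij,
                                         normalizer = c("n_squared", "pairs")) {
  normalizer <- match.arg(normalizer)
  S <- length(r2_i)
  nms <- if (!is.null(names(r2_i))) names(r2_i) else as.character(seq_len(S))
  total <- 0
  skipped <- character()
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      if (j == i) next
      if (is.na(r2_ij[i, j]) || is.na(r2_i[i]) || r2_i[i] == 0) {
        skipped <- c(skipped, paste0(nms[i], ":", nms[j]))
        next
      }
      total <- total + (r2_ij[i, j] - r2_i[i]) / r2_i[i]
    }
  }
  denom <- if (normalizer == "n_squared") S^2 else S * (S - 1)
  list(value = unname(100 / denom * total), skipped = skipped)
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report> pairwise sensitivity = ",
      signif(x$pairwise_sensitivity, 4), "% (normalizer ", x$normalizer, ")\n",
      sep = "")
  invisible(x)
}
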