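# Stack species abundances and (when present) metabolite concentrations into
# one n_samples x n_times x n_features array; the model's feature order is
# species first, then metabolites.
feature_array <- function(table) {
  if (is.null(table$C)) return(table$X)
  n <- dim(table$X)[1]; nt <- dim(table$X)[2]
  out <- array(0, dim = c(n, nt, dim(table$X)[3] + dim(table$C)[3]))
  out[, , seq_len(dim(table$X)[3])] <- table$X
  out[, , dim(table$X)[3] + seq_len(dim(table$C)[3])] <- table$C
  out
}

feature_names <- function(table) c(table$species, table$metabolites)

#' Fit a per-feature, per-timepoint standardizer
#'
#' Computes means and standard deviations of every feature (species
#' abundance, metabolite concentration) at every time point over the training
#' samples, using the population (1/N) variance convention, and standardizes
#' to zero mean and unit variance. Standard deviations below `eps` are
#' floored at `eps`, so constant features map to 0. Statistics are computed
#' on training data only unless held-out tables are supplied through
#' `normalize_all` (a documented toggle; using hold-out statistics is
#' generally undesirable).
#'
#' @param table A [trajectory_table()] of training samples.
#' @param normalize_all Optional additional [trajectory_table()] (e.g. test
#'   data) pooled into the statistics when supplied.
#' @param per_timepoint If FALSE, one global mean/sd per feature over all
#'   times (used when intermediate observations are absent).
#' @param eps Standard-deviation floor (default 1e-8).
#' @return Object of class `"feature_scaler"`.
#' @export
fit_scaler <- function(table, normalize_all = NULL, per_timepoint = TRUE,
                       eps = 1e-8) {
  arr <- feature_array(table)
  if (!is.null(normalize_all)) {
    arr2 <- feature_array(normalize_all)
    stopifnot(identical(dim(arr)[-1], dim(arr2)[-1]))
    comb <- array(0, dim = c(dim(arr)[1] + dim(arr2)[1], dim(arr)[2], dim(arr)[3]))
    comb[seq_len(dim(arr)[1]), , ] <- arr
    comb[dim(arr)[1] + seq_len(dim(arr2)[1]), , ] <- arr2
    arr <- comb
  }
  if (dim(arr)[1] < 1) stop("cannot fit a scaler on an empty table")
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  if (per_timepoint) {
    mu <- apply(arr, c(2, 3), mean)
    sigma <- apply(arr, c(2, 3), pop_sd)
  } else {
    mu <- apply(arr, 3, mean)
    sigma <- apply(arr, 3, pop_sd)
  }
  sigma <- pmax(sigma, eps)
  structure(list(mu = mu, sigma = sigma, per_timepoint = per_timepoint,
                 eps = eps, features = feature_names(table),
                 times = table$times),
            class = "feature_scaler")
}

# Standardize / de-standardize an n x T x F array (or an F-vector / n x F
# matrix at a single time index k).
scaler_transform <- function(scaler, arr, k = NULL) {
  scale_op(scaler, arr, k, forward = TRUE)
}

scaler_inverse <- function(scaler, arr, k = NULL) {
  scale_op(scaler, arr, k, forward = FALSE)
}

scale_op <- function(scaler, arr, k, forward) {
  stats_at <- function(kk) {
    if (scaler$per_timepoint) list(mu = scaler$mu[kk, ], sigma = scaler$sigma[kk, ])
    else list(mu = scaler$mu, sigma = scaler$sigma)
  }
  if (!is.null(k)) {
    st <- stats_at(k)
    if (is.matrix(arr)) {
      mu <- matrix(st$mu, nrow(arr), ncol(arr), byrow = TRUE)
      sg <- matrix(st$sigma, nrow(arr), ncol(arr), byrow = TRUE)
    } else { mu <- st$mu; sg <- st$sigma }
    return(if (forward) (arr - mu) / sg else arr * sg + mu)
  }
  out <- arr
  for (kk in seq_len(dim(arr)[2])) {
    st <- stats_at(kk)
    mu <- matrix(st$mu, dim(arr)[1], dim(arr)[3], byrow = TRUE)
    sg <- matrix(st$sigma, dim(arr)[1], dim(arr)[3], byrow = TRUE)
    out[, kk, ] <- if (forward) (arr[, kk, ] - mu) / sg else arr[, kk, ] * sg + mu
  }
  out
}

#' @export
print.feature_scaler <- function(x, ...) {
  cat("<feature_scaler> ", length(x$features), " features, ",
      if (x$per_timepoint) paste0(length(x$times), " time points")
      else "global per-feature statistics", "\n", sep = "")
  invisible(x)
}

#' Squared Pearson correlation between predictions and truth
#'
#' The package's accuracy convention: the square of the Pearson correlation
#' coefficient between predicted and true values, always computed on the
#' original (de-standardized) scale.
#'
#' @param pred,true Equal-length numeric vectors (length >= 3).
#' @return Scalar in \[0, 1\].
#' @export
pearson_r2 <- function(pred, true) {
  if (length(pred) != length(true)) stop("pred and true must have equal length")
  if (length(pred) < 3) stop("need at least 3 observations")
  keep <- is.finite(pred) & is.finite(true)
  pred <- pred[keep]; true <- true[keep]
  if (length(pred) < 3) stop("need at least 3 finite observations")
  if (sd(pred) == 0 || sd(true) == 0)
    stop("Pearson correlation undefined for a constant vector")
  cor(pred, true)^2
}
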