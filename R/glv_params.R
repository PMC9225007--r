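#' Construct a set of generalized Lotka-Volterra parameters
#'
#' The ground-truth community model is
#' \deqn{dx_i/dt = (r_i + \sum_j a_{ij} x_j + \sum_{j \ne i} \sum_{k \ne i,j}
#'   b_{ijk} x_j(t) x_k(t)) \, x_i(t),}
#' with intrinsic growth rates `r` (1/h), a pairwise interaction matrix `A`
#' (rows = affected species) and an optional third-order tensor `B` encoding
#' the modification of pairwise interactions by a third species. Entries
#' `b[i,j,k]` with `j == i` or `k %in% c(i, j)` are structurally zero.
#'
#' An optional metabolite production matrix `P` (`n_metabolites x n_species`,
#' mM/(h*OD)) drives linear production/consumption dynamics
#' `dc_m/dt = sum_i P[m, i] x_i`, used by the synthetic-data generator to
#' emulate fermentation end-product trajectories.
#'
#' @param r Numeric vector of growth rates (1/h).
#' @param A Square interaction matrix; diagonal entries must be negative
#'   (self-limitation) unless `strict = FALSE`.
#' @param B Optional third-order array `n x n x n`; defaults to all zero.
#' @param P Optional metabolite production matrix with named rows.
#' @param species Optional species codes (defaults to the leading pool codes).
#' @param strict Enforce the negative-diagonal invariant (default TRUE).
#' @return Object of class `"glv_params"`.
#' @export
glv_params <- function(r, A, B = NULL, P = NULL, species = NULL, strict = TRUE) {
  n <- length(r)
  if (!is.matrix(A) || nrow(A) != n || ncol(A) != n)
    stop("A must be a square ", n, "x", n, " matrix")
  if (strict && any(diag(A) >= 0))
    stop("diagonal entries a_ii must be negative (self-limitation)")
  if (is.null(B)) B <- array(0, dim = c(n, n, n))
  if (!identical(dim(B), as.integer(c(n, n, n))))
    stop("B must be an n x n x n array")
  viol <- b_inadmissible_mask(n) & B != 0
  if (any(viol))
    stop("B entries with j == i or k in {i, j} must be exactly zero")
  if (is.null(species)) species <- make_pool_codes(n)
  if (!is.null(P)) {
    if (!is.matrix(P) || ncol(P) != n) stop("P must have one column per species")
    if (is.null(rownames(P))) rownames(P) <- metabolite_names()[seq_len(nrow(P))]
    colnames(P) <- species
  }
  names(r) <- species
  dimnames(A) <- list(species, species)
  structure(list(n_species = n, species = species, r = r, A = A, B = B, P = P),
            class = "glv_params")
}

#' @export
print.glv_params <- function(x, ...) {
  cat("<glv_params> ", x$n_species, " species; max|a| = ",
      signif(max(abs(x$A)), 3), "; max|b| = ", signif(max(abs(x$B)), 3),
      if (!is.null(x$P)) paste0("; ", nrow(x$P), " metabolites") else "",
      "\n", sep = "")
  invisible(x)
}

# logical mask of structurally-zero (inadmissible) b_ijk entries
b_inadmissible_mask <- function(n) {
  i <- slice.index(array(0, c(n, n, n)), 1)
  j <- slice.index(array(0, c(n, n, n)), 2)
  k <- slice.index(array(0, c(n, n, n)), 3)
  (j == i) | (k == i) | (k == j)
}

#' Draw a random ground-truth community model
#'
#' Samples gLV parameters for the in-silico benchmark. Growth rates are drawn
#' `r ~ U(0.1, 0.8)` 1/h, off-diagonal interactions
#' `a_ij ~ N(-0.15, 0.2)` (competition-dominated, as in empirical gut
#' community fits, which keeps random communities dynamically bounded) and
#' self-limitation `a_ii ~ U(-1.5, -0.5)`; all three distributions are
#' configurable. Third-order perturbations are drawn uniformly on a support
#' bounded by a fraction of the strongest pairwise *interaction*
#' coefficient (the largest off-diagonal `|a_ij|`; self-limitation terms
#' are not interactions): `mild` bounds each admissible `b_ijk` at 25% of
#' that maximum, `moderate` at 50%, and `none` leaves `B` identically
#' zero.
#'
#' @param n_species Number of species.
#' @param third_order One of `"none"`, `"mild"`, `"moderate"`.
#' @param seed Integer seed; the draw is a pure function of it.
#' @param r_range,a_mean,a_sd,diag_range Distribution controls (see above).
#' @param b_sparsity Fraction of admissible third-order entries set to zero
#'   (default 0, i.e. dense).
#' @param metabolites If TRUE, also draw a metabolite production matrix `P`
#'   (4 x n, mM/(h*OD)): each metabolite is produced by a random subset of
#'   species and consumed by a smaller subset, emulating cross-feeding of
#'   fermentation end products.
#' @return A [glv_params()] object.
#' @export
#' @examples
#' p <- generate_ground_truth(5, "mild", seed = 1)
#' max(abs(p$B)) <= 0.25 * max(abs(p$A))
generate_ground_truth <- function(n_species, third_order = c("none", "mild", "moderate"),
                                  seed = 1, r_range = c(0.1, 0.8),
                                  a_mean = -0.15, a_sd = 0.2,
                                  diag_range = c(-1.5, -0.5), b_sparsity = 0,
                                  metabolites = FALSE) {
  stopifnot(n_species >= 1)
  third_order <- match.arg(third_order)
  frac <- switch(third_order, none = 0, mild = 0.25, moderate = 0.5)
  with_seed(seed, {
    n <- n_species
    r <- runif(n, r_range[1], r_range[2])
    A <- matrix(rnorm(n * n, a_mean, a_sd), n, n)
    diag(A) <- runif(n, diag_range[1], diag_range[2])
    B <- array(0, dim = c(n, n, n))
    if (frac > 0 && n >= 3) {
      offdiag <- abs(A); diag(offdiag) <- 0
      bound <- frac * max(offdiag)
      admissible <- !b_inadmissible_mask(n)
      vals <- runif(sum(admissible), -bound, bound)
      if (b_sparsity > 0) vals[runif(length(vals)) < b_sparsity] <- 0
      B[admissible] <- vals
    }
    P <- NULL
    if (metabolites) {
      P <- matrix(0, 4, n, dimnames = list(metabolite_names(), NULL))
      for (m in 1:4) {
        producers <- sample.int(n, max(1L, rbinom_clamped(n)))
        P[m, producers] <- runif(length(producers), 2, 12)
        consumers <- setdiff(sample.int(n, max(1L, n %/% 4)), producers)
        P[m, consumers] <- -runif(length(consumers), 0.5, 4)
      }
    }
    glv_params(r, A, B, P = P)
  })
}

rbinom_clamped <- function(n) min(n, 1L + stats::rbinom(1, n - 1L, 0.3))

#' Serialize / deserialize gLV parameters
#'
#' Writes a single YAML (or JSON) document holding `r`, the full matrix `A`,
#' the third-order tensor as a sparse `(i, j, k, value)` list and, when
#' present, the metabolite production matrix.
#'
#' @param params A [glv_params()] object.
#' @param path Output (input) file; format chosen by extension
#'   (`.yaml`/`.yml` or `.json`).
#' @return `read_glv_params()` returns a [glv_params()] object;
#'   `write_glv_params()` returns `path` invisibly.
#' @export
write_glv_params <- function(params, path) {
  nz <- which(params$B != 0, arr.ind = TRUE)
  doc <- list(
    species = as.list(params$species),
    r = as.list(unname(params$r)),
    A = apply(unname(params$A), 1, as.list, simplify = FALSE),
    B_sparse = lapply(seq_len(nrow(nz)), function(row) {
      list(i = unname(nz[row, 1]), j = unname(nz[row, 2]),
           k = unname(nz[row, 3]), value = params$B[nz[row, , drop = FALSE]])
    })
  )
  if (!is.null(params$P)) {
    doc$metabolites <- as.list(rownames(params$P))
    doc$P <- apply(unname(params$P), 1, as.list, simplify = FALSE)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(doc, path, precision = 15)
  }
  invisible(path)
}

#' @rdname write_glv_params
#' @export
read_glv_params <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path)
  } else {
    yaml::read_yaml(path)
  }
  species <- unlist(doc$species)
  n <- length(species)
  r <- unlist(doc$r)
  A <- do.call(rbind, lapply(doc$A, unlist))
  B <- array(0, dim = c(n, n, n))
  for (e in doc$B_sparse) B[e$i, e$j, e$k] <- e$value
  P <- NULL
  if (!is.null(doc$P)) {
    P <- do.call(rbind, lapply(doc$P, unlist))
    rownames(P) <- unlist(doc$metabolites)
  }
  glv_params(r, A, B, P = P, species = species, strict = FALSE)
}
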