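# gLV right-hand side for the present-species subsystem; x and the returned
# derivative are vectors over present species only. Third-order terms use the
# subset tensor contracted against x twice.
glv_rhs <- function(x, r, A, B = NULL, P = NULL) {
  growth <- r + as.vector(A %*% x)
  if (!is.null(B)) {
    n <- length(x)
    # sum_{j,k} b_ijk x_j x_k over the admissible (pre-zeroed) tensor
    xx <- tcrossprod(x)  # n x n, x_j * x_k
    growth <- growth + as.vector(matrix(B, n, n * n) %*% as.vector(xx))
  }
  dx <- growth * x
  if (!is.null(P)) c(dx, as.vector(P %*% x)) else dx
}

#' Simulate community assembly under the gLV model
#'
#' Integrates the generalized Lotka-Volterra system (optionally with
#' third-order interaction terms and linear metabolite production) for one or
#' more community designs. Present species start from an equal split of
#' `x0_total` (default emulates a per-species inoculum of 0.0066 OD);
#' absent species are held at exactly zero. Integration uses adaptive
#' Runge-Kutta (deSolve `ode45`, rtol 1e-6, atol 1e-9) on the present-species
#' subsystem, with states clipped at zero at each reporting time.
#'
#' @param params A [glv_params()] object.
#' @param designs One [community_design()] or a binary design matrix.
#' @param times Reporting time grid (h), e.g. `seq(0, 48, by = 8)`.
#' @param x0_total Total initial abundance, split equally over present
#'   species. Default `0.0066 * richness`, i.e. 0.0066 per species.
#' @param c0 Initial metabolite concentrations (mM) when `params$P` is set.
#' @param rtol,atol Integrator tolerances (deSolve `ode45`).
#' @return A [trajectory_table()].
#' @export
#' @examples
#' p <- glv_params(r = 0.5, A = matrix(-1, 1, 1))
#' tt <- simulate_glv(p, matrix(1, 1, 1), times = seq(0, 48, 8), x0_total = 0.1)
#' tail(tt$X[1, , 1], 1)  # logistic fixed point -r/a = 0.5
simulate_glv <- function(params, designs, times = seq(0, 48, by = 8),
                         x0_total = NULL, c0 = NULL, rtol = 1e-6,
                         atol = 1e-9) {
  stopifnot(inherits(params, "glv_params"))
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  dm <- as_design_matrix(designs, params$species)
  n <- nrow(dm); ns <- params$n_species
  has_met <- !is.null(params$P)
  nm <- if (has_met) nrow(params$P) else 0L
  if (has_met && is.null(c0)) c0 <- rep(0, nm)
  X <- array(0, dim = c(n, length(times), ns))
  C <- if (has_met) array(0, dim = c(n, length(times), nm)) else NULL
  for (s in seq_len(n)) {
    pres <- which(dm[s, ] == 1)
    if (!length(pres)) stop("design row ", s, " has richness 0")
    tot <- if (is.null(x0_total)) 0.0066 * length(pres) else x0_total
    if (tot <= 0) stop("x0_total must be positive")
    x0 <- rep(tot / length(pres), length(pres))
    sub <- subset_glv(params, pres)
    sol <- integrate_glv(sub, x0, c0, times, params$species[pres], rtol, atol)
    X[s, , pres] <- pmax(sol$x, 0)
    if (has_met) C[s, , ] <- sol$c
  }
  trajectory_table(X, times, designs = dm, C = C, species = params$species,
                   metabolites = if (has_met) rownames(params$P))
}

subset_glv <- function(params, pres) {
  list(r = params$r[pres],
       A = params$A[pres, pres, drop = FALSE],
       B = if (any(params$B != 0)) params$B[pres, pres, pres, drop = FALSE],
       P = if (!is.null(params$P)) params$P[, pres, drop = FALSE])
}

integrate_glv <- function(sub, x0, c0, times, sp_names, rtol = 1e-6,
                          atol = 1e-9) {
  np <- length(x0)
  state <- c(x0, c0)
  rhs <- function(t, y, parms) {
    x <- pmax(y[seq_len(np)], 0)
    list(glv_rhs(x, sub$r, sub$A, sub$B, sub$P))
  }
  t_int <- times
  prepend <- FALSE
  if (t_int[1] > 0) { t_int <- c(0, t_int); prepend <- TRUE }
  sol <- deSolve::ode(y = state, times = t_int, func = rhs, parms = NULL,
                      method = "ode45", rtol = rtol, atol = atol)
  check_blowup(sol, t_int, np, sp_names)
  out <- unname(sol[, -1, drop = FALSE])
  if (prepend) out <- out[-1, , drop = FALSE]
  list(x = out[, seq_len(np), drop = FALSE],
       c = if (length(c0)) out[, np + seq_along(c0), drop = FALSE])
}

check_blowup <- function(sol, t_int, np, sp_names) {
  bad_rows <- nrow(sol) < length(t_int) || any(!is.finite(sol[, -1])) ||
    any(abs(sol[, 1 + seq_len(np)]) > 1e6)
  if (bad_rows) {
    vals <- sol[, 1 + seq_len(np), drop = FALSE]
    bad <- which(!is.finite(vals) | abs(vals) > 1e6, arr.ind = TRUE)
    if (nrow(bad) == 0) bad <- matrix(c(nrow(sol), 1L), 1)
    stop("gLV integration blew up: species ", sp_names[bad[1, 2]],
         " non-finite or unbounded near t = ", signif(sol[bad[1, 1], 1], 4), " h")
  }
  invisible(NULL)
}

#' Simulate serial passaging (periodic dilution) of a community
#'
#' Integrates gLV dynamics with a periodic external perturbation: every
#' `period` hours all abundances are divided by `dilution_fold` (transfer
#' into fresh medium), after which growth continues. Metabolites, when
#' modeled, are reset to their initial concentration at each passage (fresh
#' medium). The sampling grid is independent of the passage times.
#'
#' @inheritParams simulate_glv
#' @param horizon Total simulated time (h).
#' @param dilution_fold Fold-dilution at each passage (default 20).
#' @param period Passage interval (h, default 24).
#' @param sample_every Sampling interval (h, default 12).
#' @return A [trajectory_table()] sampled at `seq(0, horizon, sample_every)`.
#' @export
simulate_with_passaging <- function(params, designs, x0_total = NULL,
                                    horizon = 60, dilution_fold = 20,
                                    period = 24, sample_every = 12, c0 = NULL) {
  if (dilution_fold <= 1) stop("dilution_fold must be > 1")
  stopifnot(period > 0, horizon > 0)
  dm <- as_design_matrix(designs, params$species)
  times <- seq(0, horizon, by = sample_every)
  has_met <- !is.null(params$P)
  nm <- if (has_met) nrow(params$P) else 0L
  if (has_met && is.null(c0)) c0 <- rep(0, nm)
  passages <- seq(period, horizon, by = period)
  seg_bounds <- sort(unique(c(0, passages[passages < horizon], horizon)))
  X <- array(0, dim = c(nrow(dm), length(times), params$n_species))
  C <- if (has_met) array(0, dim = c(nrow(dm), length(times), nm)) else NULL
  for (s in seq_len(nrow(dm))) {
    pres <- which(dm[s, ] == 1)
    if (!length(pres)) stop("design row ", s, " has richness 0")
    tot <- if (is.null(x0_total)) 0.0066 * length(pres) else x0_total
    x <- rep(tot / length(pres), length(pres))
    cm <- c0
    sub <- subset_glv(params, pres)
    for (g in seq_len(length(seg_bounds) - 1)) {
      a <- seg_bounds[g]; b <- seg_bounds[g + 1]
      tt <- sort(unique(c(a, times[times >= a & times <= b], b)))
      sol <- integrate_glv(sub, x, cm, tt - a, params$species[pres])
      # map solved rows back onto the sampling grid; a sample falling exactly
      # on a passage time reports the pre-dilution state (the left boundary
      # belongs to the previous segment)
      keep <- which(if (g == 1) times >= a & times <= b else times > a & times <= b)
      idx <- match(times[keep], tt)
      X[s, keep, pres] <- pmax(sol$x[idx, , drop = FALSE], 0)
      if (has_met) C[s, keep, ] <- sol$c[idx, , drop = FALSE]
      x <- pmax(sol$x[nrow(sol$x), ], 0)
      if (has_met) cm <- sol$c[nrow(sol$c), ]
      if (b %in% passages) {           # dilute into fresh medium at t = b+
        x <- x / dilution_fold
        if (has_met) cm <- c0
      }
    }
  }
  trajectory_table(X, times, designs = dm, C = C, species = params$species,
                   metabolites = if (has_met) rownames(params$P))
}
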