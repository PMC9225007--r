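#' Construct a trajectory table
#'
#' The training/evaluation currency: per-sample, time-indexed species
#' abundances (OD units) and optional metabolite concentrations (mM) on a
#' shared time grid. Species absent from a sample's design have abundance
#' exactly zero at every time.
#'
#' @param X Abundance array `n_samples x n_times x n_species` (a single
#'   `n_times x n_species` matrix is promoted to one sample).
#' @param times Strictly increasing time grid (h).
#' @param designs Binary design matrix (rows match samples). Defaults to
#'   presence inferred from nonzero abundance.
#' @param C Optional metabolite array `n_samples x n_times x n_metabolites`.
#' @param sample_id Optional sample identifiers.
#' @param species,metabolites Variable names.
#' @return Object of class `"trajectory_table"`.
#' @export
trajectory_table <- function(X, times, designs = NULL, C = NULL,
                             sample_id = NULL, species = NULL,
                             metabolites = NULL) {
  if (is.matrix(X)) X <- array(X, dim = c(1, nrow(X), ncol(X)))
  stopifnot(length(dim(X)) == 3)
  n <- dim(X)[1]; nt <- dim(X)[2]; ns <- dim(X)[3]
  if (length(times) != nt || any(diff(times) <= 0))
    stop("'times' must be strictly increasing and match the abundance array")
  if (!all(is.finite(X)) || any(X < -1e-12))
    stop("abundances must be finite and non-negative")
  if (is.null(species)) species <- make_pool_codes(ns)
  if (is.null(designs)) {
    designs <- matrix(as.integer(apply(X, c(1, 3), max) > 0), n, ns)
    colnames(designs) <- species
  } else {
    designs <- as_design_matrix(designs, species)
    if (nrow(designs) != n) stop("designs must have one row per sample")
    for (s in seq_len(n)) {
      absent <- designs[s, ] == 0
      if (any(X[s, , absent] != 0))
        stop("sample ", s, ": absent species must have abundance exactly 0")
    }
  }
  if (!is.null(C)) {
    if (is.matrix(C)) C <- array(C, dim = c(1, nrow(C), ncol(C)))
    stopifnot(identical(dim(C)[1:2], dim(X)[1:2]))
    if (is.null(metabolites)) metabolites <- metabolite_names()[seq_len(dim(C)[3])]
  } else metabolites <- NULL
  if (is.null(sample_id)) sample_id <- sprintf("s%04d", seq_len(n))
  structure(list(sample_id = sample_id, designs = designs, times = times,
                 species = species, metabolites = metabolites, X = X, C = C),
            class = "trajectory_table")
}

#' @export
print.trajectory_table <- function(x, ...) {
  cat("<trajectory_table> ", n_samples(x), " sample(s), ",
      length(x$times), " time points (",
      paste(range(x$times), collapse = "-"), " h), ",
      length(x$species), " species",
      if (!is.null(x$C)) paste0(", ", length(x$metabolites), " metabolites"),
      "\n", sep = "")
  invisible(x)
}

#' Number of samples in a trajectory table
#' @param table A [trajectory_table()].
#' @export
n_samples <- function(table) dim(table$X)[1]

#' Concatenate trajectory tables sharing one grid
#' @param tables List of [trajectory_table()] objects on identical time grids.
#' @return A single [trajectory_table()].
#' @export
bind_trajectories <- function(tables) {
  stopifnot(length(tables) >= 1)
  t0 <- tables[[1]]
  for (tb in tables[-1]) {
    if (!isTRUE(all.equal(tb$times, t0$times)) ||
        !identical(tb$species, t0$species) ||
        !identical(tb$metabolites, t0$metabolites))
      stop("all trajectory tables must share time grid, species and metabolites")
  }
  abind3 <- function(xs) {
    d <- dim(xs[[1]])
    out <- array(0, dim = c(sum(vapply(xs, function(a) dim(a)[1], 0L)), d[2], d[3]))
    at <- 0L
    for (a in xs) { out[at + seq_len(dim(a)[1]), , ] <- a; at <- at + dim(a)[1] }
    out
  }
  C <- if (!is.null(t0$C)) abind3(lapply(tables, `[[`, "C")) else NULL
  trajectory_table(abind3(lapply(tables, `[[`, "X")), t0$times,
                   designs = do.call(rbind, lapply(tables, `[[`, "designs")),
                   C = C,
                   sample_id = make.unique(unlist(lapply(tables, `[[`, "sample_id"))),
                   species = t0$species, metabolites = t0$metabolites)
}

#' Read / write trajectory tables as tidy CSV
#'
#' One row per sample x time; columns `sample_id, time_h`, then one column
#' per species code and, when metabolites are present, one `<name>_mM` column
#' per metabolite (empty when missing).
#'
#' @param table A [trajectory_table()].
#' @param path CSV file path.
#' @return `read_trajectory_csv()` returns a [trajectory_table()].
#' @export
write_trajectory_csv <- function(table, path) {
  n <- n_samples(table); nt <- length(table$times)
  rows <- expand.grid(t = seq_len(nt), s = seq_len(n))
  df <- data.frame(sample_id = table$sample_id[rows$s],
                   time_h = table$times[rows$t])
  for (j in seq_along(table$species))
    df[[table$species[j]]] <- table$X[cbind(rows$s, rows$t, j)]
  if (!is.null(table$C)) {
    for (j in seq_along(table$metabolites))
      df[[paste0(table$metabolites[j], "_mM")]] <- table$C[cbind(rows$s, rows$t, j)]
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  need <- c("sample_id", "time_h")
  if (!all(need %in% names(df)))
    stop("malformed trajectory CSV '", path, "': missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  met_cols <- grep("_mM$", names(df), value = TRUE)
  sp_cols <- setdiff(names(df), c(need, met_cols))
  ids <- unique(df$sample_id)
  times <- sort(unique(df$time_h))
  n <- length(ids); nt <- length(times); ns <- length(sp_cols)
  X <- array(NA_real_, dim = c(n, nt, ns))
  C <- if (length(met_cols)) array(NA_real_, dim = c(n, nt, length(met_cols))) else NULL
  si <- match(df$sample_id, ids); ti <- match(df$time_h, times)
  for (j in seq_len(ns)) X[cbind(si, ti, j)] <- df[[sp_cols[j]]]
  if (any(is.na(X))) {
    bad <- which(is.na(X), arr.ind = TRUE)[1, ]
    stop("malformed trajectory CSV '", path, "': sample '", ids[bad[1]],
         "' missing time ", times[bad[2]], " for species ", sp_cols[bad[3]])
  }
  if (!is.null(C)) {
    for (j in seq_along(met_cols)) C[cbind(si, ti, j)] <- df[[met_cols[j]]]
    if (all(is.na(C))) C <- NULL
  }
  trajectory_table(X, times, C = C, sample_id = ids, species = sp_cols,
                   metabolites = sub("_mM$", "", met_cols))
}

#' Add multiplicative observation noise to sampled abundances
#'
#' Applies log-normal multiplicative noise `x * exp(sigma * z)`, `z ~ N(0,1)`,
#' to every nonzero sampled abundance; absent species remain exactly zero and
#' metabolites are left untouched.
#'
#' @param table A [trajectory_table()].
#' @param sigma Log-scale noise standard deviation (default 0.1).
#' @param seed Integer seed.
#' @return A noisy [trajectory_table()].
#' @export
add_observation_noise <- function(table, sigma = 0.1, seed = 1) {
  with_seed(seed, {
    noise <- array(exp(sigma * rnorm(length(table$X))), dim = dim(table$X))
    X <- table$X * noise  # zeros stay exactly zero
    trajectory_table(X, table$times, designs = table$designs, C = table$C,
                     sample_id = table$sample_id, species = table$species,
                     metabolites = table$metabolites)
  })
}
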