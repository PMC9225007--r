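#' Default 25-species synthetic gut community pool
#'
#' Two-letter codes for the 25 prevalent human gut bacterial strains that make
#' up the default species pool (e.g. AC = *Anaerostipes caccae*, a dedicated
#' butyrate producer; DP = *Desulfovibrio piger*; BT/BU/BO/... = *Bacteroides*
#' spp.).
#'
#' @return Character vector of length 25.
#' @export
#' @examples
#' gut_species_pool()
gut_species_pool <- function() {
  c("PC", "PJ", "BV", "BF", "BO", "BT", "BC", "BY", "BU", "DP",
    "BL", "BA", "BP", "CA", "EL", "FP", "CH", "AC", "BH", "CG",
    "ER", "RI", "CC", "DL", "DF")
}

#' Default fermentation end-product names
#'
#' The four health-relevant fermentation metabolites tracked by the models,
#' in the fixed column order used throughout the package (concentrations in
#' mM).
#'
#' @return Character vector `c("butyrate", "lactate", "acetate", "succinate")`.
#' @export
metabolite_names <- function() {
  c("butyrate", "lactate", "acetate", "succinate")
}

#' Construct a community design
#'
#' A community design is a binary presence/absence vector over an ordered
#' species pool: the unit of experimental planning.
#'
#' @param present Character vector of species codes to include, or a 0/1
#'   (logical or numeric) vector over the full pool.
#' @param pool Ordered character vector of species codes
#'   (default [gut_species_pool()]).
#' @return A named integer 0/1 vector over `pool` with class
#'   `"community_design"`.
#' @export
#' @examples
#' community_design(c("AC", "BT", "DP"))
community_design <- function(present, pool = gut_species_pool()) {
  if (anyDuplicated(pool)) stop("species pool entries must be unique")
  if (is.character(present)) {
    bad <- setdiff(present, pool)
    if (length(bad)) stop("unknown species code(s): ", paste(bad, collapse = ", "))
    vec <- as.integer(pool %in% present)
  } else {
    if (length(present) != length(pool))
      stop("presence vector length (", length(present),
           ") does not match pool size (", length(pool), ")")
    vec <- as.integer(as.logical(present))
  }
  if (sum(vec) < 1) stop("a community design must contain at least one species")
  names(vec) <- pool
  structure(vec, class = "community_design")
}

#' @export
print.community_design <- function(x, ...) {
  cat("<community_design> richness ", sum(x), ": ",
      paste(names(x)[x == 1], collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Species richness of designs
#'
#' @param designs A `community_design` or a binary design matrix
#'   (rows = designs, columns = pool).
#' @return Integer vector of richness values.
#' @export
richness <- function(designs) {
  if (is.matrix(designs)) as.integer(rowSums(designs)) else as.integer(sum(designs))
}

# Coerce a design / design list / matrix into a binary matrix with the pool
# as columns. Used internally by every operation that consumes designs.
as_design_matrix <- function(designs, pool = NULL) {
  if (inherits(designs, "community_design")) {
    m <- matrix(as.integer(designs), nrow = 1, dimnames = list(NULL, names(designs)))
  } else if (is.list(designs)) {
    pools <- unique(lapply(designs, names))
    if (length(pools) != 1) stop("all designs must share one species pool")
    m <- do.call(rbind, lapply(designs, as.integer))
    colnames(m) <- pools[[1]]
  } else if (is.matrix(designs)) {
    m <- designs
    storage.mode(m) <- "integer"
  } else {
    stop("cannot interpret 'designs' as community designs")
  }
  if (!is.null(pool)) {
    if (is.null(colnames(m))) {
      if (ncol(m) != length(pool)) stop("design matrix width does not match pool")
      colnames(m) <- pool
    } else if (!identical(colnames(m), pool)) {
      stop("design matrix columns do not match the species pool")
    }
  }
  m
}

# Draw `n` distinct random designs of the given richness values by rejection
# sampling (duplicates rejected; capped attempts).
sample_distinct_designs <- function(pool, sizes, n, exclude_keys = character(),
                                    max_attempts = 1e6) {
  p <- length(pool)
  out <- matrix(0L, nrow = n, ncol = p, dimnames = list(NULL, pool))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (k in exclude_keys) assign(k, TRUE, envir = seen)
  got <- 0L
  attempts <- 0L
  while (got < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("exhausted ", max_attempts, " attempts drawing ", n,
           " distinct designs; requested counts may exceed the number of unique combinations")
    size <- if (length(sizes) == 1) sizes else sample(sizes, 1)
    idx <- sort(sample.int(p, size))
    key <- paste(idx, collapse = ",")
    if (!exists(key, envir = seen, inherits = FALSE)) {
      assign(key, TRUE, envir = seen)
      got <- got + 1L
      out[got, idx] <- 1L
    }
  }
  out
}

design_key <- function(m) apply(m, 1, function(r) paste(which(r == 1), collapse = ","))

#' Generate the low-richness training community design set
#'
#' Builds the benchmark training set: all monospecies, all unique pairs, and
#' requested numbers of distinct random 3-, 5- and 6-member communities. With
#' the defaults on a 25-species pool this yields the canonical 624 training
#' communities (25 monospecies + 300 pairs + 100 + 100 + 99).
#'
#' @param pool Species pool (character) or pool size.
#' @param n3,n5,n6 Numbers of distinct random 3-, 5- and 6-member designs.
#' @param seed Integer seed; the result is a pure function of it.
#' @return Binary design matrix (rows = designs, columns = pool).
#' @export
#' @examples
#' nrow(design_training_communities(seed = 1))  # 624
design_training_communities <- function(pool = gut_species_pool(),
                                        n3 = 100, n5 = 100, n6 = 99, seed = 1) {
  if (is.numeric(pool)) pool <- make_pool_codes(pool)
  p <- length(pool)
  for (spec in list(c(3, n3), c(5, n5), c(6, n6))) {
    if (spec[2] > choose(p, spec[1]))
      stop("requested ", spec[2], " distinct ", spec[1], "-member designs but only ",
           choose(p, spec[1]), " exist")
  }
  mono <- diag(1L, p)
  colnames(mono) <- pool
  pairs <- t(combn(p, 2, function(ix) {
    v <- integer(p); v[ix] <- 1L; v
  }))
  colnames(pairs) <- pool
  with_seed(seed, {
    m3 <- sample_distinct_designs(pool, 3, n3)
    m5 <- sample_distinct_designs(pool, 5, n5)
    m6 <- sample_distinct_designs(pool, 6, n6)
  })
  rbind(mono, pairs, m3, m5, m6)
}

#' Generate a high-richness test community design set
#'
#' Draws `n` distinct uniform-random designs with richness at least
#' `min_richness`, disjoint from an optional exclusion set (e.g. the training
#' designs).
#'
#' @param pool Species pool (character) or pool size.
#' @param n Number of designs.
#' @param min_richness Minimum species richness.
#' @param exclude Optional design matrix whose rows must not reappear.
#' @param seed Integer seed.
#' @return Binary design matrix.
#' @export
design_test_communities <- function(pool = gut_species_pool(), n,
                                    min_richness = 10, exclude = NULL, seed = 1) {
  if (is.numeric(pool)) pool <- make_pool_codes(pool)
  p <- length(pool)
  if (min_richness > p) stop("min_richness exceeds pool size")
  sizes <- min_richness:p
  n_avail <- sum(choose(p, sizes))
  excl_keys <- character()
  if (!is.null(exclude)) {
    exclude <- as_design_matrix(exclude, pool)
    keep <- richness(exclude) >= min_richness
    excl_keys <- design_key(exclude[keep, , drop = FALSE])
    n_avail <- n_avail - length(unique(excl_keys))
  }
  if (n > n_avail)
    stop("requested ", n, " designs but only ", n_avail,
         " distinct designs with richness >= ", min_richness, " remain")
  # uniform over qualifying designs: richness drawn proportional to C(p, k)
  w <- choose(p, sizes)
  with_seed(seed, {
    out <- matrix(0L, nrow = n, ncol = p, dimnames = list(NULL, pool))
    seen <- new.env(hash = TRUE, parent = emptyenv())
    for (k in excl_keys) assign(k, TRUE, envir = seen)
    got <- 0L; attempts <- 0L
    while (got < n) {
      attempts <- attempts + 1L
      if (attempts > 1e6) stop("exhausted rejection-sampling attempts")
      size <- sizes[sample.int(length(sizes), 1, prob = w)]
      idx <- sort(sample.int(p, size))
      key <- paste(idx, collapse = ",")
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        got <- got + 1L
        out[got, idx] <- 1L
      }
    }
    out
  })
}

make_pool_codes <- function(p) {
  full <- gut_species_pool()
  if (p <= length(full)) full[seq_len(p)] else sprintf("S%02d", seq_len(p))
}
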