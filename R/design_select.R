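# ---- exhaustive enumeration -------------------------------------------------

#' Enumerate all community designs above a richness cutoff
#'
#' Returns the exact combinatorial count of designs with richness at least
#' `min_richness` (optionally constrained to contain `must_include`) together
#' with a streaming iterator that yields each qualifying design exactly once
#' without ever materializing the full set (the default 25-species pool has
#' 26,434,916 designs of richness >= 11).
#'
#' @param pool Species pool (character) or pool size.
#' @param min_richness Minimum richness.
#' @param must_include Character vector (or indices) of species every design
#'   must contain.
#' @return List with `count` (double), `pool`, and `next_batch(n)`, a
#'   closure returning up to `n` designs as a binary matrix or NULL when
#'   exhausted.
#' @export
#' @examples
#' enumerate_designs(25, 11)$count             # 26,434,916
#' enumerate_designs(25, 11, "AC")$count       # 14,198,086
enumerate_designs <- function(pool, min_richness, must_include = NULL) {
  if (is.numeric(pool)) pool <- make_pool_codes(pool)
  p <- length(pool)
  if (p > 30)
    stop("pool of ", p, " species is too large for exhaustive enumeration; ",
         "use design_test_communities() to sample instead")
  if (is.character(must_include)) {
    bad <- setdiff(must_include, pool)
    if (length(bad)) stop("must_include has unknown species: ", paste(bad, collapse = ", "))
    fixed <- match(must_include, pool)
  } else fixed <- as.integer(must_include)
  m <- length(fixed)
  free <- setdiff(seq_len(p), fixed)
  kmin <- max(min_richness - m, 0L)
  kmax <- length(free)
  count <- sum(choose(length(free), kmin:kmax))
  # iterator state: current free-subset size k and current combination (or
  # NULL before the first of each size)
  k_cur <- kmin
  comb <- NULL
  done <- FALSE
  next_one <- function() {
    if (done) return(NULL)
    repeat {
      if (is.null(comb)) {
        if (k_cur > kmax) { done <<- TRUE; return(NULL) }
        comb <<- seq_len(k_cur)  # first k-combination (empty when k=0)
        return(comb)
      }
      nxt <- next_combination(comb, length(free))
      if (is.null(nxt)) {
        k_cur <<- k_cur + 1L
        comb <<- NULL
      } else {
        comb <<- nxt
        return(comb)
      }
    }
  }
  next_batch <- function(n) {
    rows <- list()
    for (b in seq_len(n)) {
      cmb <- next_one()
      if (is.null(cmb)) break
      v <- integer(p)
      v[fixed] <- 1L
      if (length(cmb)) v[free[cmb]] <- 1L
      rows[[b]] <- v
    }
    if (!length(rows)) return(NULL)
    out <- do.call(rbind, rows)
    colnames(out) <- pool
    out
  }
  list(count = count, pool = pool, min_richness = min_richness,
       must_include = pool[fixed], next_batch = next_batch)
}

# lexicographic successor of a k-combination of 1..n, or NULL at the end
next_combination <- function(comb, n) {
  k <- length(comb)
  if (k == 0) return(NULL)
  i <- k
  while (i >= 1 && comb[i] == n - k + i) i <- i - 1
  if (i < 1) return(NULL)
  comb[i] <- comb[i] + 1L
  if (i < k) comb[(i + 1):k] <- comb[i] + seq_len(k - i)
  comb
}

# ---- prediction tables ------------------------------------------------------

#' Bundle community designs with predicted metabolite concentrations
#'
#' @param designs Binary design matrix.
#' @param metabolites Numeric matrix (rows matching `designs`) with columns
#'   named after the four metabolites (mM).
#' @return Object of class `"prediction_table"`.
#' @export
prediction_table <- function(designs, metabolites) {
  dm <- as_design_matrix(designs)
  stopifnot(nrow(metabolites) == nrow(dm))
  if (is.null(colnames(metabolites)))
    colnames(metabolites) <- metabolite_names()[seq_len(ncol(metabolites))]
  if (!all(is.finite(metabolites))) stop("metabolite predictions must be finite")
  structure(list(designs = dm, metabolites = metabolites),
            class = "prediction_table")
}

#' @export
print.prediction_table <- function(x, ...) {
  cat("<prediction_table> ", nrow(x$designs), " designs, metabolites: ",
      paste(colnames(x$metabolites), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# ---- distributed (k-means) selection ---------------------------------------

kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- numeric(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(X, 2, X[centers[1], ])^2)
  if (k > 1) {
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j] <- sample.int(n, 1, prob = prob)
      d2 <- pmin(d2, rowSums(sweep(X, 2, X[centers[j], ])^2))
    }
  }
  X[centers, , drop = FALSE]
}

#' Select communities spanning the predicted metabolite space
#'
#' Runs k-means (k-means++ initialization, several seeded restarts) on the
#' four-dimensional predicted metabolite concentrations and returns, for each
#' centroid, the unique nearest community in Euclidean distance (duplicates
#' resolved to the next nearest).
#'
#' @param predictions A [prediction_table()].
#' @param k Number of representative communities (default 100).
#' @param n_restarts k-means restarts (default 10).
#' @param seed Integer seed.
#' @return Binary design matrix of `k` selected designs, with the matched
#'   centroid index as attribute `"centroid"`.
#' @export
select_distributed <- function(predictions, k = 100, n_restarts = 10, seed = 1) {
  M <- predictions$metabolites
  n_distinct <- nrow(unique(M))
  if (k > n_distinct)
    stop("k = ", k, " exceeds the ", n_distinct, " distinct prediction rows")
  km <- with_seed(seed, {
    best <- NULL
    for (rs in seq_len(n_restarts)) {
      cc <- kmeanspp_centers(M, k)
      fit <- suppressWarnings(kmeans(M, centers = cc, iter.max = 50))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    best
  })
  chosen <- integer(k)
  used <- logical(nrow(M))
  for (j in seq_len(k)) {
    d2 <- rowSums(sweep(M, 2, km$centers[j, ])^2)
    ord <- order(d2)
    pick <- ord[!used[ord]][1]
    chosen[j] <- pick
    used[pick] <- TRUE
  }
  out <- predictions$designs[chosen, , drop = FALSE]
  attr(out, "centroid") <- seq_len(k)
  attr(out, "row") <- chosen
  out
}

# ---- corner selection -------------------------------------------------------

#' Specification of the two-level corner binning
#'
#' Corners are extreme tails of the predicted metabolite distribution:
#' four primary corners on the (lactate, butyrate) plane, each split into
#' four sub-corners on (acetate, succinate), all via sequential "take the
#' `percentile` most extreme, then the `percentile` most extreme of those"
#' binning. Each of the 16 sub-corner classes contributes
#' `per_subcorner` designs. With small prediction tables a strict percentile
#' bin can shrink below the number of designs to be picked, so bins are
#' floored at `min_bin` rows (ties at the percentile boundary are included on
#' the extreme side).
#'
#' @param percentile Tail fraction per binning step (default 0.05).
#' @param per_subcorner Designs selected per sub-corner (default 5).
#' @param primary,secondary Metabolite pairs for the two levels.
#' @param min_bin Minimum bin size (default `per_subcorner`).
#' @return List with class `"corner_spec"`.
#' @export
corner_spec <- function(percentile = 0.05, per_subcorner = 5,
                        primary = c("lactate", "butyrate"),
                        secondary = c("acetate", "succinate"),
                        min_bin = per_subcorner) {
  stopifnot(percentile > 0, percentile < 0.5)
  structure(list(percentile = percentile, per_subcorner = per_subcorner,
                 primary = primary, secondary = secondary, min_bin = min_bin),
            class = "corner_spec")
}

# indices of the `frac` lowest (or highest) values, floored at min_bin rows,
# boundary ties included on the extreme side
tail_bin <- function(values, frac, side, min_bin) {
  n <- length(values)
  need <- max(ceiling(frac * n), min_bin)
  need <- min(need, n)
  if (side == "low") {
    thr <- sort(values, partial = need)[need]
    which(values <= thr)
  } else {
    thr <- sort(values, decreasing = TRUE)[need]
    which(values >= thr)
  }
}

# the four sequential two-metabolite binning rules: (first axis, side),
# then (second axis, side) of those
corner_rules <- function(a, b) {
  list(list(c(a, "low"), c(b, "low")),
       list(c(a, "low"), c(b, "high")),
       list(c(b, "low"), c(a, "low")),
       list(c(b, "low"), c(a, "high")))
}

apply_rule <- function(M, idx, rule, frac, min_bin) {
  first <- tail_bin(M[idx, rule[[1]][1]], frac, rule[[1]][2], min_bin)
  idx <- idx[first]
  second <- tail_bin(M[idx, rule[[2]][1]], frac, rule[[2]][2], min_bin)
  idx[second]
}

#' Select extreme-tail ("corner") communities
#'
#' Builds the four primary corners on the (lactate, butyrate) plane and four
#' sub-corners each on (acetate, succinate) by sequential tail binning, then
#' picks `per_subcorner` designs from every sub-corner: one seed-random
#' design followed by designs greedily maximizing the minimum Hamming
#' distance (in species presence) to those already picked, ties broken by
#' lexicographic design order. With the defaults this yields 80 designs in
#' 16 groups of 5.
#'
#' @param predictions A [prediction_table()].
#' @param spec A [corner_spec()].
#' @param seed Integer seed.
#' @param exhaustive_max Sub-corners with at most this many candidates use
#'   exhaustive max-min search instead of the greedy (default 0 = always
#'   greedy).
#' @return Data-frame-like list: binary design matrix with attributes, plus
#'   a `corner` / `subcorner` label per selected design; class
#'   `"corner_selection"`.
#' @export
select_corners <- function(predictions, spec = corner_spec(), seed = 1,
                           exhaustive_max = 0) {
  M <- predictions$metabolites
  need <- c(spec$primary, spec$secondary)
  if (!all(need %in% colnames(M)))
    stop("prediction table lacks metabolite column(s): ",
         paste(setdiff(need, colnames(M)), collapse = ", "))
  rules1 <- corner_rules(spec$primary[1], spec$primary[2])
  rules2 <- corner_rules(spec$secondary[1], spec$secondary[2])
  seeds <- derive_seeds(seed, 16)
  picks <- list()
  labels <- data.frame(corner = integer(), subcorner = integer())
  ci <- 0L
  for (c1 in seq_along(rules1)) {
    idx1 <- apply_rule(M, seq_len(nrow(M)), rules1[[c1]], spec$percentile,
                       spec$min_bin)
    for (c2 in seq_along(rules2)) {
      ci <- ci + 1L
      idx2 <- apply_rule(M, idx1, rules2[[c2]], spec$percentile, spec$min_bin)
      if (!length(idx2))
        stop("sub-corner ", c1, ".", c2, " is empty after binning")
      cand <- predictions$designs[idx2, , drop = FALSE]
      sel <- pick_diverse(cand, spec$per_subcorner, seeds[ci], exhaustive_max)
      picks[[ci]] <- idx2[sel]
      labels <- rbind(labels, data.frame(corner = rep(c1, length(sel)),
                                         subcorner = rep(c2, length(sel))))
    }
  }
  rows <- unlist(picks)
  out <- list(designs = predictions$designs[rows, , drop = FALSE],
              metabolites = M[rows, , drop = FALSE],
              corner = labels$corner, subcorner = labels$subcorner,
              class_id = paste0(labels$corner, ".", labels$subcorner),
              rows = rows, spec = spec)
  class(out) <- "corner_selection"
  out
}

#' @export
print.corner_selection <- function(x, ...) {
  cat("<corner_selection> ", nrow(x$designs), " designs in ",
      length(unique(x$class_id)), " sub-corner classes\n", sep = "")
  invisible(x)
}

# One random pick then max-min Hamming diversification. Returns row indices
# into `cand`.
pick_diverse <- function(cand, n_pick, seed, exhaustive_max = 0) {
  n <- nrow(cand)
  if (n <= n_pick) return(seq_len(n))
  first <- with_seed(seed, sample.int(n, 1))
  if (n <= exhaustive_max) {
    return(c(first, pick_exhaustive(cand, first, n_pick - 1)))
  }
  chosen <- first
  # lexicographic order for deterministic tie-breaks
  lex <- do.call(order, as.data.frame(cand))
  rank_lex <- order(lex)
  while (length(chosen) < n_pick) {
    avail <- setdiff(seq_len(n), chosen)
    dmin <- vapply(avail, function(i) {
      min(vapply(chosen, function(j) sum(cand[i, ] != cand[j, ]), 0))
    }, 0)
    best <- avail[dmin == max(dmin)]
    chosen <- c(chosen, best[which.min(rank_lex[best])])
  }
  chosen
}

# exhaustive max-min complement search for small candidate sets
pick_exhaustive <- function(cand, first, n_more) {
  n <- nrow(cand)
  avail <- setdiff(seq_len(n), first)
  combos <- combn(avail, n_more)
  score <- function(set) {
    all_idx <- c(first, set)
    d <- as.matrix(dist(cand[all_idx, , drop = FALSE], method = "manhattan"))
    min(d[upper.tri(d)])
  }
  scores <- apply(combos, 2, score)
  combos[, which.max(scores)]
}

#' Classify measured communities into predicted corner classes
#'
#' Treats the 16 sub-corner groups as classes with centroids given by the
#' mean predicted metabolite profile per class. Each community's predicted
#' class is the centroid nearest its predicted profile and its measured
#' class the centroid nearest its measured profile; the confusion matrix
#' between the two and the misclassification rate as a function of
#' inter-class centroid distance (binned) quantify how well the predicted
#' extremes separate in measurement space.
#'
#' @param measured Matrix of measured metabolite concentrations (rows =
#'   communities in the selection order).
#' @param selection A `"corner_selection"` (provides predicted profiles and
#'   class labels), or a list with `metabolites` and `class_id`.
#' @param n_bins Number of centroid-distance bins (default 5).
#' @return List with `assigned`, `confusion` (table), `misclass_rate`, and
#'   `distance_table` (per ordered class pair: centroid distance, error
#'   rate) plus the binned rates.
#' @export
classify_corners <- function(measured, selection, n_bins = 5) {
  cls <- selection$class_id
  pred <- selection$metabolites
  if (is.null(colnames(measured))) colnames(measured) <- colnames(pred)
  if (!all(colnames(pred) %in% colnames(measured)))
    stop("measured table lacks metabolite column(s): ",
         paste(setdiff(colnames(pred), colnames(measured)), collapse = ", "))
  measured <- measured[, colnames(pred), drop = FALSE]
  stopifnot(nrow(measured) == length(cls))
  classes <- sort(unique(cls))
  cent <- t(vapply(classes, function(cl)
    colMeans(pred[cls == cl, , drop = FALSE]), numeric(ncol(pred))))
  nearest <- function(M) classes[apply(M, 1, function(v)
    which.min(colSums((t(cent) - v)^2)))]
  cls <- nearest(pred)        # predicted class: nearest centroid rule
  assigned <- nearest(measured)
  confusion <- table(true = factor(cls, classes), assigned = factor(assigned, classes))
  cd <- as.matrix(dist(cent))
  pairs <- expand.grid(true = classes, assigned = classes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$true != pairs$assigned, ]
  pairs$distance <- cd[cbind(match(pairs$true, classes), match(pairs$assigned, classes))]
  n_true <- table(factor(cls, classes))
  pairs$errors <- confusion[cbind(match(pairs$true, classes),
                                  match(pairs$assigned, classes))]
  pairs$rate <- pairs$errors / as.numeric(n_true[pairs$true])
  brk <- seq(0, max(pairs$distance) + 1e-9, length.out = n_bins + 1)
  pairs$bin <- cut(pairs$distance, brk, include.lowest = TRUE)
  binned <- do.call(rbind, lapply(split(pairs, pairs$bin), function(df) {
    if (!nrow(df)) return(NULL)
    data.frame(mid = mean(df$distance), rate = mean(df$rate))
  }))
  list(assigned = assigned,
       confusion = confusion,
       misclass_rate = mean(assigned != cls),
       distance_table = pairs[order(pairs$distance), ],
       binned = binned)
}
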