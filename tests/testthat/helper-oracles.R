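# Independent oracles used across the suite. These deliberately avoid the
# package's internal numerical paths: a plain fixed-step RK4 loop for the
# full (third-order) gLV system, a flood-fill re-implementation of divisive
# MST clustering, and a literal double-loop for the pairwise-sensitivity
# statistic.

# Brute-force fixed-step RK4 for dx_i/dt = (r_i + sum_j a_ij x_j +
# sum_{j,k} b_ijk x_j x_k) x_i, one community, explicit loops.
oracle_rk4_glv <- function(r, A, B, x0, times, dt = 1e-3) {
  n <- length(x0)
  rhs <- function(x) {
    g <- numeric(n)
    for (i in seq_len(n)) {
      gi <- r[i]
      for (j in seq_len(n)) gi <- gi + A[i, j] * x[j]
      if (!is.null(B)) {
        for (j in seq_len(n)) for (k in seq_len(n)) {
          if (B[i, j, k] != 0) gi <- gi + B[i, j, k] * x[j] * x[k]
        }
      }
      g[i] <- gi * x[i]
    }
    g
  }
  out <- matrix(NA_real_, length(times), n)
  x <- x0
  t_cur <- times[1]
  out[1, ] <- x
  for (ti in 2:length(times)) {
    n_steps <- ceiling((times[ti] - t_cur) / dt)
    h <- (times[ti] - t_cur) / n_steps
    for (s in seq_len(n_steps)) {
      k1 <- rhs(x)
      k2 <- rhs(x + h / 2 * k1)
      k3 <- rhs(x + h / 2 * k2)
      k4 <- rhs(x + h * k3)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    t_cur <- times[ti]
    out[ti, ] <- x
  }
  out
}

# Naive divisive MST clustering: builds the MST by Prim-style search on the
# dense distance matrix, then repeatedly deletes the largest edge whose
# removal (checked by flood fill) keeps all components >= min_size.
oracle_mst_cluster <- function(vectors, n_clusters, min_size) {
  n <- nrow(vectors)
  D <- as.matrix(dist(vectors))
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  edges <- list()
  while (sum(in_tree) < n) {
    best <- NULL
    for (a in which(in_tree)) for (b in which(!in_tree)) {
      if (is.null(best) || D[a, b] < best$w ||
          (D[a, b] == best$w && (min(a, b) < min(best$a, best$b) ||
            (min(a, b) == min(best$a, best$b) && max(a, b) < max(best$a, best$b)))))
        best <- list(a = a, b = b, w = D[a, b])
    }
    in_tree[best$b] <- TRUE
    edges[[length(edges) + 1]] <- best
  }
  active <- rep(TRUE, length(edges))
  flood <- function(active_edges) {
    lab <- rep(0L, n)
    cur <- 0L
    adj <- vector("list", n)
    for (ei in which(active_edges)) {
      e <- edges[[ei]]
      adj[[e$a]] <- c(adj[[e$a]], e$b)
      adj[[e$b]] <- c(adj[[e$b]], e$a)
    }
    for (v in seq_len(n)) {
      if (lab[v] == 0L) {
        cur <- cur + 1L
        stack <- v
        while (length(stack)) {
          u <- stack[[1]]; stack <- stack[-1]
          if (lab[u] == 0L) {
            lab[u] <- cur
            stack <- c(stack, adj[[u]])
          }
        }
      }
    }
    lab
  }
  n_comp <- 1L
  while (n_comp < n_clusters) {
    ord <- order(-vapply(edges, `[[`, 0, "w"),
                 vapply(edges, function(e) min(e$a, e$b), 0),
                 vapply(edges, function(e) max(e$a, e$b), 0))
    ord <- ord[active[ord]]
    done <- FALSE
    for (ei in ord) {
      active[ei] <- FALSE
      lab <- flood(active)
      if (min(tabulate(lab)) >= min_size) {
        n_comp <- max(lab)
        done <- TRUE
        break
      }
      active[ei] <- TRUE
    }
    if (!done) stop("oracle: infeasible")
  }
  lab <- flood(active)
  match(lab, unique(lab))
}

# Literal Eq.-style double loop over precomputed subset R^2 values.
oracle_pairwise_sensitivity <- function(r2_i, r2_ij, denom) {
  S <- length(r2_i)
  total <- 0
  for (i in seq_len(S)) for (j in seq_len(S)) {
    if (j == i || is.na(r2_ij[i, j]) || is.na(r2_i[i]) || r2_i[i] == 0) next
    total <- total + (r2_ij[i, j] - r2_i[i]) / r2_i[i]
  }
  100 / denom * total
}

# small helpers shared by several test files
make_pairs <- function(p) t(combn(p, 2, function(ix) { v <- integer(p); v[ix] <- 1L; v }))

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
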