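# ---- MST divisive clustering -----------------------------------------------

#' Flatten metabolite trajectories into clustering vectors
#'
#' Concatenates each community's metabolite trajectory (metabolites x time
#' points, e.g. 4 x 3 = 12 dimensions) into one vector for Euclidean
#' distance computation. Replicate samples of the same design are averaged
#' by default.
#'
#' @param table A [trajectory_table()] with metabolites.
#' @param times Optional subset of time points (values on the grid).
#' @param average_replicates Average samples sharing a design (default TRUE).
#' @return Numeric matrix (rows = communities) with attribute `"designs"`.
#' @export
trajectory_vectors <- function(table, times = NULL, average_replicates = TRUE) {
  if (is.null(table$C)) stop("trajectory table carries no metabolites")
  keep <- if (is.null(times)) seq_along(table$times) else match(times, table$times)
  if (anyNA(keep)) stop("requested times not on the table's grid")
  n <- n_samples(table)
  V <- matrix(0, n, length(keep) * dim(table$C)[3])
  for (s in seq_len(n)) V[s, ] <- as.numeric(table$C[s, keep, ])
  designs <- table$designs
  if (average_replicates) {
    key <- design_key(designs)
    grp <- split(seq_len(n), key)
    V <- do.call(rbind, lapply(grp, function(ix) colMeans(V[ix, , drop = FALSE])))
    designs <- designs[vapply(grp, `[`, 0L, 1), , drop = FALSE]
    rownames(V) <- NULL
  }
  attr(V, "designs") <- designs
  V
}

#' Cluster trajectories by divisive cuts of the minimum spanning tree
#'
#' Builds the complete Euclidean-distance graph over the trajectory vectors,
#' takes its minimum spanning tree, and divisively removes the largest
#' remaining edge whose removal leaves every component with at least
#' `min_cluster_size` members; an edge whose removal would create a
#' too-small component is returned and the next-largest edge is tried.
#' Removal continues until `n_clusters` components exist. Distance ties are
#' broken by the smaller (i, j) index pair, so the procedure is fully
#' deterministic.
#'
#' @param vectors Numeric matrix (rows = communities).
#' @param n_clusters Target number of clusters (default 6).
#' @param min_cluster_size Smallest admissible cluster (default 5).
#' @return Object of class `"mst_clusters"`: list with integer `labels`
#'   (1-based, ordered by first occurrence), `removed` / `skipped` edge
#'   logs, `sizes`, the `mst` (igraph) and the mean intracluster distance.
#' @export
mst_cluster <- function(vectors, n_clusters = 6, min_cluster_size = 5) {
  n <- nrow(vectors)
  if (n < n_clusters * min_cluster_size)
    stop("need at least n_clusters * min_cluster_size = ",
         n_clusters * min_cluster_size, " communities, got ", n)
  D <- as.matrix(dist(vectors))
  # complete graph as an explicit edge list (zero-weight edges between
  # duplicate trajectories must be kept); deterministic MST via Kruskal
  # with ties broken by the smaller (i, j) pair
  el <- t(combn(n, 2))
  w <- D[el]
  ord <- order(w, el[, 1], el[, 2])
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  mst_edges <- matrix(0L, n - 1, 2)
  mst_w <- numeric(n - 1)
  got <- 0L
  for (e in ord) {
    ra <- find(el[e, 1]); rb <- find(el[e, 2])
    if (ra != rb) {
      parent[ra] <- rb
      got <- got + 1L
      mst_edges[got, ] <- el[e, ]
      mst_w[got] <- w[e]
      if (got == n - 1L) break
    }
  }
  active <- rep(TRUE, n - 1L)
  removed <- integer(0)
  skipped_log <- list()
  comp_labels <- function() {
    gg <- igraph::graph_from_edgelist(mst_edges[active, , drop = FALSE],
                                      directed = FALSE)
    gg <- igraph::add_vertices(gg, max(0, n - igraph::vcount(gg)))
    igraph::components(gg)$membership
  }
  n_comp <- 1L
  while (n_comp < n_clusters) {
    cand <- which(active)
    cand <- cand[order(-mst_w[cand], pmin(mst_edges[cand, 1], mst_edges[cand, 2]),
                       pmax(mst_edges[cand, 1], mst_edges[cand, 2]))]
    cut_done <- FALSE
    for (e in cand) {
      active[e] <- FALSE
      mem <- comp_labels()
      if (min(tabulate(mem)) >= min_cluster_size) {
        removed <- c(removed, e)
        n_comp <- max(mem)
        cut_done <- TRUE
        break
      }
      active[e] <- TRUE    # too-small component: return the edge
      skipped_log[[length(skipped_log) + 1]] <-
        data.frame(i = mst_edges[e, 1], j = mst_edges[e, 2], weight = mst_w[e],
                   at_n_components = n_comp)
    }
    if (!cut_done) {
      partial <- relabel_first_occurrence(comp_labels())
      stop("cannot reach ", n_clusters, " clusters with min_cluster_size = ",
           min_cluster_size, "; stalled at ", n_comp,
           " components (partial labels attached)",
           call. = FALSE)
    }
  }
  labels <- relabel_first_occurrence(comp_labels())
  g_mst <- igraph::graph_from_edgelist(mst_edges, directed = FALSE)
  igraph::E(g_mst)$weight <- mst_w
  structure(list(labels = labels,
                 sizes = tabulate(labels),
                 removed = data.frame(i = mst_edges[removed, 1],
                                      j = mst_edges[removed, 2],
                                      weight = mst_w[removed]),
                 skipped = if (length(skipped_log)) do.call(rbind, skipped_log)
                           else NULL,
                 mst = g_mst,
                 mean_intracluster = mean_intracluster_distance(D, labels)),
            class = "mst_clusters")
}

relabel_first_occurrence <- function(mem) {
  match(mem, unique(mem))
}

#' @export
print.mst_clusters <- function(x, ...) {
  cat("<mst_clusters> ", length(x$sizes), " clusters, sizes: ",
      paste(x$sizes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# size-weighted mean of within-cluster average pairwise distances
mean_intracluster_distance <- function(D, labels, weighted = TRUE) {
  per <- vapply(sort(unique(labels)), function(cl) {
    ix <- which(labels == cl)
    if (length(ix) < 2) return(0)
    mean(D[ix, ix][upper.tri(D[ix, ix])])
  }, 0)
  sizes <- tabulate(labels)
  if (weighted) sum(per * sizes) / sum(sizes) else mean(per)
}

#' Elbow diagnostics for MST divisive clustering
#'
#' Runs [mst_cluster()] over a grid of cluster counts and minimum cluster
#' sizes and tabulates the mean intracluster distance (size-weighted mean of
#' within-cluster average pairwise Euclidean distances; set
#' `weighted = FALSE` for the unweighted variant). Infeasible grid cells are
#' recorded as NA.
#'
#' @param vectors Numeric matrix of trajectory vectors.
#' @param cluster_range Integer vector of cluster counts.
#' @param min_size_range Integer vector of minimum cluster sizes.
#' @param weighted Size-weight the per-cluster means (default TRUE).
#' @return Data frame `n_clusters`, `min_size`, `mean_intracluster`.
#' @export
elbow_curve <- function(vectors, cluster_range = 2:8, min_size_range = 5,
                        weighted = TRUE) {
  stopifnot(length(cluster_range) >= 1, length(min_size_range) >= 1)
  D <- as.matrix(dist(vectors))
  grid <- expand.grid(n_clusters = cluster_range, min_size = min_size_range)
  grid$mean_intracluster <- NA_real_
  for (rr in seq_len(nrow(grid))) {
    res <- tryCatch(mst_cluster(vectors, grid$n_clusters[rr], grid$min_size[rr]),
                    error = function(e) NULL)
    if (!is.null(res))
      grid$mean_intracluster[rr] <-
        mean_intracluster_distance(D, res$labels, weighted)
  }
  grid
}

#' Pick the elbow of a diagnostics curve
#'
#' The elbow is the cluster count with the largest second difference of the
#' mean intracluster distance.
#'
#' @param curve Output of [elbow_curve()] for a single `min_size`.
#' @return The `n_clusters` value at the elbow.
#' @export
elbow_point <- function(curve) {
  curve <- curve[order(curve$n_clusters), ]
  v <- curve$mean_intracluster
  if (length(v) < 3) return(curve$n_clusters[which.min(v)])
  sec <- diff(diff(v))
  curve$n_clusters[which.max(sec) + 1]
}

# ---- decision-tree design rules --------------------------------------------

#' Extract species presence/absence rules that explain clusters
#'
#' Fits an unpruned CART classification tree (Gini impurity, no depth limit,
#' deterministic feature order) on the presence bits and extracts, for each
#' cluster, the conjunction of split conditions along the path to the leaf
#' holding most of that cluster's communities. Reports per-cluster rule
#' coverage and the communities deviating from their cluster's rule.
#'
#' @param labels Cluster labels (one per design).
#' @param designs Binary design matrix.
#' @return Object of class `"design_rules"`: per-cluster list with `rule`
#'   (character conditions like `"AC+"`, `"DP-"`), `coverage`, and
#'   `deviating` (row indices of cluster members not matching the rule).
#' @export
decision_tree_rules <- function(labels, designs) {
  dm <- as_design_matrix(designs)
  stopifnot(length(labels) == nrow(dm))
  labels <- as.integer(factor(labels))
  clusters <- sort(unique(labels))
  if (length(clusters) == 1) {
    out <- list(`1` = list(rule = "always", coverage = 1,
                           deviating = integer(0)))
    return(structure(list(rules = out, tree = NULL), class = "design_rules"))
  }
  df <- as.data.frame(dm)
  df$.cluster <- factor(labels)
  fit <- rpart::rpart(.cluster ~ ., data = df, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(minsplit = 2, minbucket = 1,
                                                     cp = 0, xval = 0,
                                                     maxdepth = 30))
  frame <- fit$frame
  leaves <- which(frame$var == "<leaf>")
  out <- list()
  for (cl in clusters) {
    # majority leaf: the leaf containing most of this cluster's members
    counts <- frame$yval2[leaves, 1 + cl]
    leaf_row <- leaves[which.max(counts)]
    node_id <- as.integer(rownames(frame)[leaf_row])
    pth <- rpart::path.rpart(fit, node_id, print.it = FALSE)[[1]][-1]
    rule <- vapply(pth, condition_to_rule, "")
    rule <- unique(rule)
    match_rule <- rule_matcher(rule, dm)
    members <- which(labels == cl)
    deviating <- members[!match_rule[members]]
    out[[as.character(cl)]] <- list(rule = rule,
                                    coverage = mean(match_rule[members]),
                                    deviating = deviating)
  }
  structure(list(rules = out, tree = fit), class = "design_rules")
}

condition_to_rule <- function(cond) {
  # rpart splits binary 0/1 features as "X< 0.5" / "X>=0.5"
  m <- regmatches(cond, regexec("^([^<>=]+)(<|>=)\\s*([0-9.]+)$", cond))[[1]]
  if (length(m) != 4) return(cond)
  paste0(trimws(m[2]), if (m[3] == ">=") "+" else "-")
}

rule_matcher <- function(rule, dm) {
  ok <- rep(TRUE, nrow(dm))
  for (r in rule) {
    sp <- substr(r, 1, nchar(r) - 1)
    sgn <- substr(r, nchar(r), nchar(r))
    if (!sp %in% colnames(dm)) next
    ok <- ok & if (sgn == "+") dm[, sp] == 1 else dm[, sp] == 0
  }
  ok
}

#' @export
print.design_rules <- function(x, ...) {
  for (cl in names(x$rules)) {
    r <- x$rules[[cl]]
    cat("cluster ", cl, ": ", paste(r$rule, collapse = " & "),
        "  (coverage ", round(100 * r$coverage), "%",
        if (length(r$deviating)) paste0(", ", length(r$deviating), " deviating"),
        ")\n", sep = "")
  }
  invisible(x)
}

#' Export clustering results
#'
#' Writes labels as CSV, the removed-edge log as CSV, and the MST with
#' cluster annotations as GraphML.
#'
#' @param clusters An [mst_cluster()] result.
#' @param dir Output directory (created if needed).
#' @export
write_cluster_results <- function(clusters, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(community = seq_along(clusters$labels),
                       cluster = clusters$labels),
            file.path(dir, "labels.csv"), row.names = FALSE)
  write.csv(clusters$removed, file.path(dir, "removed_edges.csv"),
            row.names = FALSE)
  g <- clusters$mst
  igraph::V(g)$cluster <- clusters$labels
  igraph::write_graph(g, file.path(dir, "mst.graphml"), format = "graphml")
  invisible(dir)
}
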