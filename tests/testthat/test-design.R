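# exhaustive enumeration, representative (k-means) selection, corner
# selection, and corner classification

synthetic_predictions <- function(n, seed = 1, pool = 12) {
  micos:::with_seed(seed, {
    dm <- matrix(rbinom(n * pool, 1, 0.5), n, pool)
    dm[rowSums(dm) == 0, 1] <- 1L
    colnames(dm) <- micos:::make_pool_codes(pool)
    M <- cbind(butyrate = 20 * dm[, 1] + rnorm(n, 25, 6),
               lactate = -12 * dm[, 1] + rnorm(n, 30, 7),
               acetate = rnorm(n, 60, 12),
               succinate = rnorm(n, 15, 5))
    prediction_table(dm, M)
  })
}

test_that("enumeration counts are combinatorial and match brute force on small pools", {
  e <- enumerate_designs(25, 11)
  expect_equal(e$count, 26434916)
  expect_equal(enumerate_designs(25, 11, "AC")$count, 14198086)

  # pool 5, min richness 3: 16 designs, all yielded exactly once
  e5 <- enumerate_designs(5, 3)
  expect_equal(e5$count, 16)
  all5 <- e5$next_batch(100)
  expect_null(e5$next_batch(1))
  expect_equal(nrow(all5), 16)
  expect_true(all(richness(all5) >= 3))
  expect_equal(anyDuplicated(micos:::design_key(all5)), 0)
  # brute-force: all 2^5 subsets filtered by richness
  brute <- sum(vapply(0:31, function(m) sum(bitwAnd(m, 2^(0:4)) > 0) >= 3, TRUE))
  expect_equal(nrow(all5), brute)

  # must_include constrains every yielded design; batching is transparent
  e6 <- enumerate_designs(6, 3, must_include = "PC")
  got <- list()
  repeat {
    b <- e6$next_batch(7)
    if (is.null(b)) break
    got[[length(got) + 1]] <- b
  }
  got <- do.call(rbind, got)
  expect_equal(nrow(got), e6$count)
  expect_true(all(got[, "PC"] == 1))
  expect_equal(e6$count, sum(choose(5, 2:5)))

  expect_error(enumerate_designs(31, 11), "too large")
  expect_error(enumerate_designs(25, 11, "ZZ"), "unknown species")
})

test_that("distributed selection returns one nearest unique design per centroid", {
  # single row, k = 1
  p1 <- prediction_table(matrix(c(1L, 0L, 1L), 1),
                         matrix(c(10, 20, 30, 5), 1,
                                dimnames = list(NULL, metabolite_names())))
  s1 <- select_distributed(p1, k = 1, seed = 1)
  expect_equal(unname(s1[1, ]), c(1L, 0L, 1L))

  # planted well-separated blobs: one pick per blob
  set.seed(3)
  k <- 4; per <- 30
  centers <- matrix(c(0, 0, 0, 0, 100, 0, 0, 0, 0, 100, 0, 0, 0, 0, 100, 0),
                    k, 4, byrow = TRUE)
  M <- do.call(rbind, lapply(1:k, function(j)
    sweep(matrix(rnorm(per * 4, sd = 1), per, 4), 2, centers[j, ], "+")))
  dm <- matrix(rbinom(k * per * 6, 1, 0.5), k * per, 6)
  dm[rowSums(dm) == 0, 1] <- 1L
  pt <- prediction_table(dm, `colnames<-`(M, metabolite_names()))
  sel <- select_distributed(pt, k = k, seed = 2)
  blob <- rep(1:k, each = per)
  expect_setequal(blob[attr(sel, "row")], 1:k)

  # defaults on a larger synthetic table: exactly k unique designs
  pt2 <- synthetic_predictions(2000, seed = 5)
  sel2 <- select_distributed(pt2, k = 100, seed = 3)
  expect_equal(nrow(sel2), 100)
  expect_equal(anyDuplicated(attr(sel2, "row")), 0)

  expect_error(select_distributed(p1, k = 2), "exceeds")
})

test_that("corner selection returns 16 sub-corner groups of the requested size", {
  pt <- synthetic_predictions(10000, seed = 8)
  sel <- select_corners(pt, seed = 4)
  expect_equal(nrow(sel$designs), 80)
  expect_equal(length(unique(sel$class_id)), 16)
  expect_true(all(table(sel$class_id) == 5))
  # deterministic given the seed
  sel_b <- select_corners(pt, seed = 4)
  expect_identical(sel$rows, sel_b$rows)

  # primary corners live in the stated lactate/butyrate tails
  lact <- pt$metabolites[, "lactate"]; buty <- pt$metabolites[, "butyrate"]
  c1 <- sel$metabolites[sel$corner == 1, ]
  expect_true(all(c1[, "lactate"] <= quantile(lact, 0.06)))
  c2 <- sel$metabolites[sel$corner == 2, ]
  expect_true(all(c2[, "lactate"] <= quantile(lact, 0.06)))
  expect_gt(mean(c2[, "butyrate"]), mean(c1[, "butyrate"]))

  # a sub-corner with exactly the requested count returns all its designs
  few <- prediction_table(matrix(rbinom(5 * 4, 1, 0.8), 5, 4),
                          `colnames<-`(matrix(rnorm(20), 5, 4),
                                       metabolite_names()))
  self <- micos:::pick_diverse(few$designs, 5, seed = 1)
  expect_setequal(self, 1:5)

  expect_error(select_corners(prediction_table(
    matrix(1L, 3, 2), `colnames<-`(matrix(rnorm(6), 3, 2),
                                   c("butyrate", "lactate"))), corner_spec()),
    "lacks metabolite")
})

test_that("greedy Hamming diversification matches exhaustive max-min search on a toy", {
  # six designs engineered so the greedy choice is provably max-min optimal
  cand <- rbind(c(1, 1, 1, 1, 0, 0, 0, 0),
                c(0, 0, 0, 0, 1, 1, 1, 1),
                c(1, 1, 0, 0, 1, 1, 0, 0),
                c(0, 0, 1, 1, 0, 0, 1, 1),
                c(1, 0, 1, 0, 1, 0, 1, 0),
                c(1, 1, 1, 1, 1, 1, 1, 1))
  storage.mode(cand) <- "integer"
  g <- micos:::pick_diverse(cand, 5, seed = 2, exhaustive_max = 0)
  e <- micos:::pick_diverse(cand, 5, seed = 2, exhaustive_max = 10)
  min_pair <- function(rows) {
    d <- as.matrix(dist(cand[rows, ], method = "manhattan"))
    min(d[upper.tri(d)])
  }
  expect_equal(min_pair(g), min_pair(e))
  expect_equal(g[1], e[1])  # both anchored at the same random seed design
})

test_that("corner classification degrades with decreasing inter-class distance", {
  pt <- synthetic_predictions(10000, seed = 9)
  sel <- select_corners(pt, seed = 6)
  # measured exactly equal to predicted: zero misclassification
  perfect <- classify_corners(sel$metabolites, sel)
  expect_equal(perfect$misclass_rate, 0)
  expect_equal(sum(diag(perfect$confusion)), length(sel$class_id))

  # Gaussian measurement spread: errors concentrate between nearby classes
  set.seed(10)
  noisy <- sel$metabolites + matrix(rnorm(length(sel$metabolites), sd = 8),
                                    nrow(sel$metabolites))
  res <- classify_corners(noisy, sel)
  expect_gt(res$misclass_rate, 0)
  ct <- suppressWarnings(
    cor.test(res$distance_table$distance, res$distance_table$rate,
             method = "spearman"))
  expect_lt(ct$estimate, 0)

  expect_error(classify_corners(sel$metabolites[, 1:2], sel), "lacks")
})
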