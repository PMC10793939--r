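make_blob_panel <- function(centers, n_per, noise = 1, seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  lab <- rep(seq_len(k), each = n_per)
  x <- centers[lab, , drop = FALSE] +
    matrix(stats::rnorm(length(lab) * ncol(centers), 0, noise),
           ncol = ncol(centers))
  m <- matrix(0, nrow(x), 9)
  m[, seq_len(ncol(x))] <- x
  list(panel = as_indicator_panel(m), labels = lab)
}

test_that("well-separated blobs are recovered exactly", {
  blobs <- make_blob_panel(matrix(c(0, 0, 10, 10), 2, 2, byrow = TRUE),
                           n_per = 15, noise = 1, seed = 2)
  sol <- hkmeans_clubs(blobs$panel, 2, standardize = FALSE)
  expect_equal(adjusted_rand(sol$labels$cluster, blobs$labels), 1)
  expect_equal(sort(sol$sizes), c(15, 15))
})

test_that("three distant pairs attain the brute-force optimal within-SS", {
  pts <- rbind(c(0, 0), c(0.5, 0), c(20, 0), c(20.5, 0), c(10, 18), c(10, 18.5))
  m <- matrix(0, 6, 9); m[, 1:2] <- pts
  panel <- as_indicator_panel(m)
  sol <- hkmeans_clubs(panel, 3, standardize = FALSE)
  x <- m
  best <- min(vapply(all_partitions(6, 3), function(a) partition_wss(x, a),
                     numeric(1)))
  expect_equal(partition_wss(x, sol$labels$cluster), best, tolerance = 1e-9)
})

test_that("standardization makes labels invariant to column rescaling", {
  sim <- generate_panel(synthetic_config(countries_per_regime = 8L, seed = 5L))
  pan <- indicator_panel(sim$panel, 2000, "female")
  sol1 <- hkmeans_clubs(pan, 5)
  pan2 <- pan
  pan2$G0 <- pan2$G0 * 1000
  sol2 <- hkmeans_clubs(pan2, 5)
  expect_equal(adjusted_rand(sol1$labels$cluster, sol2$labels$cluster), 1)
})

test_that("cluster solutions satisfy their structural invariants", {
  sim <- generate_panel(synthetic_config(countries_per_regime = 10L, seed = 6L))
  pan <- indicator_panel(sim$panel, 1995, "male")
  sol <- hkmeans_clubs(pan, 5)
  expect_equal(sum(sol$sizes), nrow(pan))
  expect_true(all(sol$sizes > 0))
  # monotone descent of the Lloyd refinement
  expect_true(all(diff(sol$wss_trace) <= 1e-9))
  # centroid = mean of members in standardized space
  x <- scale(as.matrix(pan[, indicator_names]))
  for (cl in seq_len(sol$k)) {
    expect_equal(unname(sol$centroids[cl, ]),
                 unname(colMeans(x[sol$labels$cluster == cl, , drop = FALSE])),
                 tolerance = 1e-9)
  }
  # representative country attains the minimal distance, exhaustively
  for (cl in seq_len(sol$k)) {
    members <- sol$labels[sol$labels$cluster == cl, ]
    expect_equal(members$country[which.min(members$dist_to_centroid)],
                 unname(sol$representative[as.character(cl)]))
  }
  # cluster ids ordered by descending centroid e0
  expect_true(all(diff(sol$centroids_raw[, "e0"]) < 0))
  # shuffling row order only renames labels
  set.seed(9)
  perm <- sample(nrow(pan))
  sol_p <- hkmeans_clubs(pan[perm, ], 5)
  expect_equal(adjusted_rand(sol$labels$cluster[perm], sol_p$labels$cluster), 1)
})

test_that("lloyd refinement agrees with stats::kmeans from the same centers", {
  set.seed(11)
  for (i in 1:10) {
    x <- matrix(stats::rnorm(40), 20, 2)
    init <- stats::cutree(stats::hclust(stats::dist(x), "average"), 3)
    centers <- mortclubs:::centroid_matrix(x, init, 3)
    mine <- mortclubs:::lloyd_refine(x, centers, 100)
    km <- suppressWarnings(stats::kmeans(x, centers, iter.max = 100,
                                         algorithm = "Lloyd"))
    expect_equal(partition_wss(x, mine$labels), km$tot.withinss,
                 tolerance = 1e-9)
  }
})

test_that("index battery recovers planted k and flags weak structure", {
  sim <- generate_panel(synthetic_config(countries_per_regime = 12L, seed = 15L))
  pan <- indicator_panel(sim$panel, 2005, "female")
  ks <- select_k(pan, 2:8)
  expect_equal(ks$best_k, 5)
  # single Gaussian cloud: no structure; winning silhouette is low
  set.seed(16)
  cloud <- as_indicator_panel(matrix(stats::rnorm(40 * 9), 40, 9))
  ks2 <- select_k(cloud, 2:6)
  expect_lt(max(ks2$scores$silhouette), 0.3)
  expect_true(ks2$weak_structure)
  # a single-value range wins trivially
  ks3 <- select_k(pan, 4)
  expect_equal(ks3$best_k, 4)
})

test_that("transition tables count moves and recover permutations", {
  sim <- generate_panel(synthetic_config(countries_per_regime = 8L, seed = 18L))
  pan <- indicator_panel(sim$panel, 1990, "female")
  sol <- hkmeans_clubs(pan, 5)
  # identical solutions give a diagonal table
  tr <- cluster_transitions(sol, sol)
  expect_true(all(tr$counts[upper.tri(tr$counts)] == 0))
  expect_true(all(tr$counts[lower.tri(tr$counts)] == 0))
  expect_equal(unname(tr$alignment), seq_len(5))
  expect_equal(unname(rowSums(tr$counts)), unname(sol$sizes))
  # moving one country produces exactly one off-diagonal unit
  sol2 <- sol
  moved <- which(sol2$labels$cluster == 1)[1]
  sol2$labels$cluster[moved] <- 2L
  tr2 <- cluster_transitions(sol, sol2)
  off <- tr2$counts; diag(off) <- 0
  expect_equal(sum(off), 1)
  # a pure relabelling is recovered by the greedy alignment
  perm <- c(3L, 1L, 4L, 5L, 2L)
  sol3 <- sol
  sol3$labels$cluster <- perm[sol$labels$cluster]
  tr3 <- cluster_transitions(sol, sol3)
  expect_equal(unname(tr3$alignment[perm]), seq_len(5))
})

test_that("PCA projection matches an independent eigendecomposition", {
  sim <- generate_panel(synthetic_config(countries_per_regime = 8L, seed = 21L))
  pan <- indicator_panel(sim$panel, 2010, "male")
  pr <- project_pca(pan)
  x <- scale(as.matrix(pan[, indicator_names]))
  ev <- eigen(stats::cor(as.matrix(pan[, indicator_names])))
  expect_equal(pr$var_explained,
               (ev$values / sum(ev$values))[1:2], tolerance = 1e-9)
  for (j in 1:2) {
    v <- ev$vectors[, j]
    i <- which.max(abs(v))
    if (v[i] < 0) v <- -v
    expect_equal(unname(as.numeric(pr$scores[[c("PC1", "PC2")[j]]])),
                 unname(as.numeric(x %*% v)), tolerance = 1e-8)
  }
  expect_true(all(diff(pr$var_explained) <= 0))
  # orthogonality of the two component scores
  expect_equal(sum(pr$scores$PC1 * pr$scores$PC2), 0, tolerance = 1e-8)
  # duplicated rows project identically
  pan2 <- dplyr::bind_rows(pan, pan[1, ] |> dplyr::mutate(country = "Copy", code = "CPY"))
  pr2 <- project_pca(pan2)
  expect_equal(as.numeric(pr2$scores[pr2$scores$country == "Copy", c("PC1", "PC2")]),
               as.numeric(pr2$scores[1, c("PC1", "PC2")]), tolerance = 1e-9)
  # a rank-2 panel is fully explained by two components
  set.seed(23)
  b <- matrix(stats::rnorm(18), 2, 9)
  s <- matrix(stats::rnorm(30), 15, 2)
  pan3 <- as_indicator_panel(s %*% b)
  pr3 <- project_pca(pan3)
  expect_equal(sum(pr3$var_explained), 1, tolerance = 1e-9)
})

test_that("cluster recovery improves with regime separation", {
  aris <- vapply(c(0.1, 0.8), function(sep) {
    mean(vapply(1:5, function(s) {
      sim <- generate_panel(synthetic_config(countries_per_regime = 8L,
                                             regime_separation = sep,
                                             seed = 100L + s))
      pan <- indicator_panel(sim$panel, 2000, "female")
      sol <- hkmeans_clubs(pan, 5)
      truth <- sim$truth$regimes$regime[match(pan$country,
                                              sim$truth$regimes$country)]
      adjusted_rand(sol$labels$cluster, truth)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(aris[2], aris[1])
})
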