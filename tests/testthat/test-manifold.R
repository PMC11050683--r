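test_that("kNN graph structure on simple configurations", {
  pts <- cbind(c(0, 1, 2), 0, 0)  # equally spaced on a line
  g <- knn_graph(pts, k = 1)
  expect_equal(nrow(g$edges), 2L)
  expect_equal(g$edges$weight, c(1, 1))
  # k = n - 1 gives the complete graph
  pts2 <- random_points(6, seed = 5)
  gc <- knn_graph(pts2, k = 5)
  expect_equal(nrow(gc$edges), choose(6, 2))
})

test_that("disconnected graphs raise an error naming the components", {
  clouds <- rbind(random_points(4, seed = 6),
                  random_points(4, seed = 7) + 1000)
  expect_error(knn_graph(clouds, k = 2), "2 components")
})

test_that("geodesics match a Floyd-Warshall oracle on random graphs", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(5:12, 1)
    pts <- random_points(n, seed = seed + 200)
    k <- sample(2:(n - 2), 1)
    g <- tryCatch(knn_graph(pts, k), error = function(e) NULL)
    if (is.null(g)) next  # disconnected draw; contract covered elsewhere
    expect_equal(geodesic_distances(g),
                 floyd_warshall(g$n, g$edges),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # path graph: d(a, c) = 2
  gpath <- knn_graph(cbind(c(0, 1, 2), 0, 0), k = 1)
  expect_equal(geodesic_distances(gpath)[1, 3], 2)
  # complete graph: geodesic equals Euclidean
  pts <- random_points(7, seed = 8)
  gfull <- knn_graph(pts, k = 6)
  expect_equal(geodesic_distances(gfull), as.matrix(dist(pts)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("geodesics never undercut Euclidean distances and shrink with k", {
  pts <- random_points(15, seed = 9)
  eu <- as.matrix(dist(pts))
  g4 <- geodesic_distances(knn_graph(pts, 4))
  g8 <- geodesic_distances(knn_graph(pts, 8))
  expect_true(all(g4 - eu >= -1e-8))
  expect_true(all(g8 <= g4 + 1e-8))
})

test_that("classical MDS recovers line and planar configurations", {
  # 4 points on a line: 1D embedding reproduces pairwise distances
  x <- c(0, 1, 3, 7)
  d <- abs(outer(x, x, "-"))
  mds1 <- classical_mds(d, d = 1)
  expect_equal(as.matrix(dist(mds1$points)), d, tolerance = 1e-8,
               ignore_attr = TRUE)
  # planar point set: 2D embedding equals the set up to rigid motion
  set.seed(10)
  plane <- cbind(rnorm(9), rnorm(9))
  d2 <- as.matrix(dist(plane))
  mds2 <- classical_mds(d2, d = 2)
  expect_lt(procrustes_residual(mds2$points, plane), 1e-6)
  # asking for more dimensions than positive eigenvalues warns + truncates
  expect_warning(short <- classical_mds(d, d = 3), "positive eigenvalues")
  expect_lte(ncol(short$points), 2L)
  expect_error(classical_mds(matrix(1, 2, 3)), "symmetric")
})

test_that("MDS on Euclidean distances equals PCA scores up to sign", {
  g <- generate_ensemble(ensemble_spec(n_traces = 14, n_residues = 12,
                                       amplitudes = c(2, 1),
                                       noise_sigma = 0.15,
                                       pose_jitter = FALSE, seed = 101))
  mat <- g$ensemble$matrix
  sc <- predict(essential_dynamics(mat), mat, m = 2)
  mds <- classical_mds(as.matrix(dist(mat)), d = 2)
  for (j in 1:2) {
    dev <- min(max(abs(mds$points[, j] - sc[, j])),
               max(abs(mds$points[, j] + sc[, j])))
    expect_lt(dev, 1e-6)
  }
})

test_that("isomap is exact on flat manifolds and reduces to MDS at k = n - 1", {
  # points on a 2-plane embedded in 3R-space; with every pairwise edge
  # present the graph geodesics equal the Euclidean distances, so the 2D
  # embedding preserves them exactly
  set.seed(11)
  basis <- qr.Q(qr(matrix(rnorm(30 * 2), ncol = 2)))
  coords2d <- cbind(runif(12, 0, 5), runif(12, 0, 5))
  flat <- coords2d %*% t(basis)
  iso <- isomap(flat, k = 11, d = 2)
  expect_equal(as.matrix(dist(iso$embedding)), as.matrix(dist(flat)),
               tolerance = 1e-6, ignore_attr = TRUE)
  # a 1-flat sampled in order: consecutive-hop geodesics sum exactly, so
  # even k = 1 reproduces the line
  line <- outer(c(0, 1, 2.5, 4, 7), c(1, -2, 2) / 3)
  iso_line <- isomap(line, k = 1, d = 1)
  expect_equal(as.matrix(dist(iso_line$embedding)), as.matrix(dist(line)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # complete-graph reduction
  pts <- random_points(10, seed = 12)
  iso_full <- isomap(pts, k = 9, d = 2)
  mds <- classical_mds(as.matrix(dist(pts)), d = 2)
  expect_equal(iso_full$embedding, mds$points, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("isomap beats 2-PC PCA on a swiss-roll-style curve", {
  set.seed(13)
  t <- seq(0, 3 * pi, length.out = 40)
  roll <- cbind(t * cos(t), t * sin(t), runif(40, 0, 2))
  iso <- isomap(roll, k = 6, d = 2)
  pca_sc <- predict(essential_dynamics(roll), roll, m = 2)
  rv_iso <- residual_variance(iso$geodesic, iso$embedding)
  rv_pca <- residual_variance(iso$geodesic, pca_sc)
  expect_lt(rv_iso, rv_pca)
})

test_that("embedding is invariant (up to rigid motion) to input pose", {
  pts <- random_points(12, seed = 14)
  rot <- random_proper_rotation(15)
  moved <- sweep(pts %*% rot, 2, -c(4, -8, 2))
  e1 <- isomap(pts, k = 5, d = 2)$embedding
  e2 <- isomap(moved, k = 5, d = 2)$embedding
  expect_lt(procrustes_residual(e1, e2), 1e-6)
})
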