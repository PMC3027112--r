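fm_from <- function(x) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("p", seq_len(nrow(x)))
  structure(x, class = c("feature_matrix", "matrix", "array"),
            scaling = "standardized")
}

test_that("standardization centers, scales, drops constants, is idempotent", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 10, 20))
  expect_warning(s <- standardize_features(m), "zero-variance")
  expect_equal(colnames(s), c("a", "c"))
  expect_equal(unname(colMeans(s)), c(0, 0))
  expect_equal(unname(apply(s, 2, sd)), c(1, 1))
  s2 <- standardize_features(s)
  expect_equal(unclass(s2), unclass(s), tolerance = 1e-12)
  expect_error(standardize_features(cbind(x = c(1, 1, 1))), "zero variance")
})

test_that("feature distances are the stated L1/L2 metrics", {
  expect_equal(feature_dist(c(0, 0), c(3, 4), "euclidean"), 5)
  expect_equal(feature_dist(c(0, 0), c(3, 4), "manhattan"), 7)
  expect_equal(feature_dist(c(1, 2), c(1, 2)), 0)
  expect_equal(feature_dist(c(1, 2), c(5, -1)), feature_dist(c(5, -1), c(1, 2)))
  expect_error(feature_dist(1:2, 1:3), "dimension")
})

test_that("k-means recovers separated blobs and honors edge cases", {
  x <- fm_from(matrix(c(0, 0.1, 10, 10.1), ncol = 1))
  km <- st_kmeans(x, 2, seed = 1)
  expect_equal(km$assignments[["p1"]], km$assignments[["p2"]])
  expect_equal(km$assignments[["p3"]], km$assignments[["p4"]])
  expect_false(km$assignments[["p1"]] == km$assignments[["p3"]])
  kn <- st_kmeans(x, 4, seed = 1)
  expect_equal(kn$objective, 0)
  expect_equal(sort(unique(kn$assignments)), 1:4)
  dup <- fm_from(matrix(c(0, 0, 5, 5, 9), ncol = 1))
  kd <- st_kmeans(dup, 2, seed = 2)
  expect_equal(kd$assignments[["p1"]], kd$assignments[["p2"]])
  expect_equal(kd$assignments[["p3"]], kd$assignments[["p4"]])
  expect_error(st_kmeans(x, 5), "between 1")
  # deterministic under a fixed seed
  expect_identical(st_kmeans(x, 2, seed = 7), st_kmeans(x, 2, seed = 7))
})

test_that("PAM matches the exhaustive medoid optimum on small instances", {
  brute_pam <- function(dmat, k) {
    combs <- combn(nrow(dmat), k)
    min(apply(combs, 2, function(meds)
      sum(apply(dmat[, meds, drop = FALSE], 1, min))))
  }
  withr::with_seed(42, {
    for (i in 1:20) {
      n <- sample(5:10, 1); k <- sample(1:3, 1)
      x <- fm_from(matrix(rnorm(n * 2), ncol = 2))
      metric <- sample(c("euclidean", "manhattan"), 1)
      fit <- st_pam(x, k, metric)
      dmat <- as.matrix(dist(unclass(x), method = metric))
      expect_equal(fit$objective, brute_pam(dmat, k), tolerance = 1e-12,
                   info = sprintf("n=%d k=%d %s", n, k, metric))
    }
  })
})

test_that("PAM with k = 1 picks the distance-minimizing medoid", {
  withr::with_seed(9, {
    x <- fm_from(matrix(rnorm(14), ncol = 2))
    fit <- st_pam(x, 1)
    dmat <- as.matrix(dist(unclass(x)))
    expect_equal(fit$medoids, unname(which.min(colSums(dmat))))
    expect_equal(fit$objective, min(colSums(dmat)))
  })
})

test_that("silhouettes match the hand example and a naive reference", {
  x <- fm_from(matrix(c(0, 0.1, 10, 10.1), ncol = 1))
  cl <- c(1L, 1L, 2L, 2L)
  sil <- silhouette_widths(x, cl)
  expect_equal(sil$sil_width[1], 9.95 / 10.05)   # a = 0.1, b = 10.05
  expect_equal(sil$neighbor[1], 2L)
  # singleton cluster convention
  s3 <- silhouette_widths(x, c(1L, 1L, 1L, 2L))
  expect_equal(s3$sil_width[4], 0)
  # duplicates in a 2-point cluster: a = 0, s = 1
  xd <- fm_from(matrix(c(0, 0, 9), ncol = 1))
  sd_ <- silhouette_widths(xd, c(1L, 1L, 2L))
  expect_equal(sd_$sil_width[1], 1)
  withr::with_seed(21, {
    for (i in 1:10) {
      n <- sample(6:12, 1)
      xx <- fm_from(matrix(rnorm(n * 3), ncol = 3))
      cl <- sample(1:3, n, replace = TRUE)
      if (length(unique(cl)) < 2) next
      metric <- sample(c("euclidean", "manhattan"), 1)
      got <- silhouette_widths(xx, cl, metric)
      expect_equal(got$sil_width, naive_silhouette(unclass(xx), cl, metric),
                   tolerance = 1e-12)
      expect_true(all(got$sil_width >= -1 & got$sil_width <= 1))
    }
  })
  expect_error(silhouette_widths(x, rep(1L, 4)), "at least 2")
})

test_that("silhouettes agree with the cluster package on random data", {
  skip_if_not_installed("cluster")
  withr::with_seed(14, {
    x <- matrix(rnorm(40), ncol = 2)
    cl <- sample(1:3, 20, replace = TRUE)
    ref <- cluster::silhouette(cl, dist(x))
    got <- silhouette_widths(fm_from(x), cl)
    expect_equal(got$sil_width, unname(ref[, "sil_width"]),
                 tolerance = 1e-12)
  })
})

test_that("homogeneity and separation follow their definitions", {
  x <- fm_from(matrix(c(0, 2, 10, 12), ncol = 1))
  km <- st_kmeans(x, 2, seed = 1)
  expect_equal(cluster_homogeneity(x, km), 1)    # centroids 1 and 11
  expect_equal(cluster_separation(x, km), 10)
  # all singletons
  k4 <- st_kmeans(x, 4, seed = 1)
  expect_equal(cluster_homogeneity(x, k4), 0)
  # merging distant blobs loosens the single cluster
  pam1 <- st_pam(x, 1)
  expect_gt(cluster_homogeneity(x, pam1), cluster_homogeneity(x, km))
  # three equidistant representatives at distance d -> separation d
  x3 <- fm_from(matrix(c(0, 0, 1, 0, 0.5, sqrt(3) / 2), ncol = 2,
                       byrow = TRUE))
  km3 <- st_kmeans(x3, 3, seed = 1)
  expect_equal(cluster_separation(x3, km3), 1)
  expect_error(cluster_separation(x, st_pam(x, 1)), "at least 2")
})

test_that("objectives are non-increasing fixed points and row order is immaterial", {
  withr::with_seed(33, {
    x <- fm_from(matrix(rnorm(30), ncol = 2))
    fit <- st_pam(x, 3)
    # fixed point: reassigning to medoids changes nothing
    dmat <- as.matrix(dist(unclass(x)))
    reassigned <- apply(dmat[, fit$medoids], 1, which.min)
    expect_equal(unname(fit$assignments), unname(reassigned))
    # permuting rows relabels but does not change the partition
    perm <- sample(nrow(x))
    fit2 <- st_pam(fm_from(unclass(x)[perm, ]), 3)
    expect_equal(fit2$objective, fit$objective, tolerance = 1e-12)
    expect_equal(rand_index(fit$assignments[perm], fit2$assignments), 1)
    # scaling standardized features leaves assignments unchanged
    fit3 <- st_pam(fm_from(unclass(x) * 7), 3)
    expect_equal(unname(fit3$assignments), unname(fit$assignments))
  })
})

test_that("choose_k maximizes average silhouette with ties to smallest k", {
  withr::with_seed(55, {
    blobs <- rbind(matrix(rnorm(20, 0, 0.1), ncol = 2),
                   matrix(rnorm(20, 5, 0.1), ncol = 2),
                   matrix(rnorm(20, 10, 0.1), ncol = 2))
    x <- fm_from(blobs)
    ck <- choose_k(x, 2:6, algorithm = "pam")
    expect_equal(ck$best_k, 3L)
    ck1 <- choose_k(x, k_range = 2, algorithm = "kmeans")
    expect_equal(ck1$best_k, 2L)
  })
  # exact tie: four corners of a rectangle under kmeans
  expect_error(choose_k(fm_from(matrix(rnorm(8), ncol = 2)), integer()),
               "empty")
})
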