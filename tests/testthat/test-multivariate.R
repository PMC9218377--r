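test_that("Pearson correlation matches the explicit-formula oracle", {
  m <- cbind(x = c(1, 2, 3), y = c(2, 4, 6), z = c(6, 4, 2))
  cm <- correlation_matrix(m)
  expect_equal(cm$r["x", "y"], 1)
  expect_equal(cm$r["x", "z"], -1)
  expect_true(isSymmetric(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 3))

  set.seed(101)
  x <- stats::rnorm(50); y <- 0.6 * x + stats::rnorm(50)
  cm2 <- correlation_matrix(cbind(x = x, y = y))
  expect_equal(cm2$r["x", "y"], pearson_oracle(x, y), tolerance = 1e-12)
  # r(x, ax + b) = sign(a)
  for (a in c(-2, 0.5)) {
    r <- correlation_matrix(cbind(x = x, y = a * x + 3))$r["x", "y"]
    expect_equal(r, sign(a))
  }
  # constant trait flagged, r undefined
  cc <- suppressWarnings(correlation_matrix(cbind(x = x, k = rep(1, 50))))
  expect_true(is.na(cc$r["x", "k"]))
  expect_equal(cc$constant, "k")
})

test_that("PCA satisfies trace, rank-1 and closed-form 2x2 oracles", {
  set.seed(7)
  n <- 40
  base <- stats::rnorm(n)
  # two perfectly correlated traits -> eigenvalues (2, 0)
  m2 <- cbind(a = base, b = 2 * base + 1)
  pc2 <- trait_pca(m2)
  expect_equal(pc2$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_equal(pc2$proportion[1], 100)
  # 2x2 closed form: eigenvalues 1 +/- r, loadings (1,1)/sqrt(2)
  mr <- cbind(a = base, b = 0.5 * base + stats::rnorm(n))
  r <- stats::cor(mr)[1, 2]
  pcr <- trait_pca(mr)
  expect_equal(pcr$eigenvalues, c(1 + abs(r), 1 - abs(r)),
               tolerance = 1e-10)
  expect_equal(abs(unname(pcr$loadings[, 1])), rep(1 / sqrt(2), 2),
               tolerance = 1e-10)

  # trace identity and reconstruction of the correlation matrix
  m <- matrix(stats::rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("t", 1:5)))
  pc <- trait_pca(m)
  expect_equal(sum(pc$eigenvalues), 5, tolerance = 1e-10)
  expect_equal(sum(pc$proportion), 100, tolerance = 1e-10)
  recon <- pc$loadings %*% diag(pc$eigenvalues) %*% t(pc$loadings)
  expect_equal(unname(recon), unname(stats::cor(scale(m))),
               tolerance = 1e-10)
  # scores of distinct components are orthogonal
  cp <- crossprod(pc$scores)
  expect_equal(unname(cp - diag(diag(cp))), matrix(0, 5, 5),
               tolerance = 1e-8)
  # sign convention: largest-magnitude loading positive
  expect_true(all(apply(pc$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
})

test_that("important loadings use an inclusive threshold", {
  m <- matrix(stats::rnorm(120), 40, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  pc <- trait_pca(m)
  pc$loadings[1, 1] <- 0.46; pc$loadings[2, 1] <- 0.28
  pc$loadings[3, 1] <- -0.30
  flags <- important_loadings(pc)
  expect_true(flags[1, 1])
  expect_false(flags[2, 1])
  expect_true(flags[3, 1])  # |-0.30| at the threshold is flagged
})

test_that("UPGMA reproduces hand arithmetic and is ultrametric", {
  m <- matrix(c(0, 1, 5), 3, 1, dimnames = list(c("A", "B", "C"), "x"))
  up <- upgma_tree(m, standardize = FALSE)
  # merges: {A,B} at d = 1, then C at mean(d(A,C), d(B,C)) = 4.5
  expect_equal(up$heights, c(1, 4.5))
  expect_equal(sort(stats::cutree(up$tree, 2)[c("A", "B", "C")]),
               sort(c(A = 1, B = 1, C = 2)))
  # identical genotypes merge at height 0
  m2 <- rbind(m, D = 0)
  expect_equal(min(upgma_tree(m2, standardize = FALSE)$heights), 0)
  # monotone heights and the three-point ultrametric condition
  set.seed(33)
  mm <- matrix(stats::rnorm(10 * 3), 10, 3,
               dimnames = list(paste0("g", 1:10), c("a", "b", "c")))
  up2 <- upgma_tree(mm)
  expect_true(all(diff(up2$heights) >= -1e-10))
  cd <- as.matrix(cophenetic_distances(up2))
  for (i in 1:8) for (j in (i + 1):9) for (k in (j + 1):10) {
    d3 <- sort(c(cd[i, j], cd[i, k], cd[j, k]))
    expect_lt(d3[3] - d3[2], 1e-8)  # two largest equal: ultrametric
  }
})

test_that("k-means is seeded-deterministic and recovers separation", {
  set.seed(5)
  cloud <- rbind(matrix(stats::rnorm(40, 0), 20, 2),
                 matrix(stats::rnorm(40, 10), 20, 2))
  rownames(cloud) <- paste0("g", 1:40)
  colnames(cloud) <- c("a", "b")
  km1 <- kmeans_clusters(cloud, k = 2, seed = 99)
  km2 <- kmeans_clusters(cloud, k = 2, seed = 99)
  expect_identical(km1$assignments, km2$assignments)
  # 10-sigma separation: partition equals the generating labels
  expect_equal(length(unique(km1$assignments[1:20])), 1)
  expect_equal(length(unique(km1$assignments[21:40])), 1)
  expect_error(kmeans_clusters(cloud, k = 1, seed = 1), "at least 2")
  # total SS decomposition
  expect_equal(km1$totss, km1$tot_withinss + km1$betweenss,
               tolerance = 1e-8)
  # relabelling by a ranking trait: cluster 1 has the higher mean
  km3 <- kmeans_clusters(cloud, k = 2, seed = 99, rank_trait = "a")
  m1 <- mean(cloud[km3$assignments == 1, "a"])
  m2 <- mean(cloud[km3$assignments == 2, "a"])
  expect_gt(m1, m2)
})

test_that("cluster summaries are plain arithmetic on the assignments", {
  m <- matrix(c(1, 2, 9, 10,
                4, 4, 8, 8), 4, 2,
              dimnames = list(paste0("g", 1:4), c("a", "b")))
  res <- structure(list(assignments = setNames(c(1, 1, 2, 2),
                                               rownames(m)),
                        k = 2, method = "kmeans", labels = rownames(m)),
                   class = "cluster_result")
  cs <- cluster_summary(res, m,
                        origins = c(g1 = "KE", g2 = "KE", g3 = "TZ"))
  expect_equal(unname(cs$cluster_means[, "a"]), c(1.5, 9.5))
  expect_equal(unname(cs$cluster_means[, "b"]), c(4, 8))
  expect_equal(sum(cs$sizes), 4)
  expect_equal(as.numeric(cs$source_counts[, "unknown"]), c(0, 1))
  # single cluster: means equal grand means
  res1 <- res; res1$assignments[] <- 1
  expect_equal(unname(cluster_summary(res1, m)$cluster_means[1, ]),
               unname(colMeans(m)))
})
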