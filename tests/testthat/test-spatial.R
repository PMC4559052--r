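test_that("Edwards' distance follows its closed form", {
  fa <- list(loc1 = c(`1` = 1))
  fb <- list(loc1 = c(`1` = 0.5, `2` = 0.5))
  expect_equal(edwards_distance(fa, fa), 0)
  expect_equal(edwards_distance(fa, fb), sqrt(1 - sqrt(0.5)),
               tolerance = 1e-12)
  # fully disjoint alleles at every locus -> 1
  fc <- list(loc1 = c(`3` = 0.4, `4` = 0.6))
  expect_equal(edwards_distance(fa, fc), 1)
  # zero-copy locus dropped with a warning
  fd <- list(loc1 = c(`1` = 1), loc2 = c(`1` = 1))
  fe <- list(loc1 = c(`1` = 1), loc2 = numeric(0))
  expect_warning(d <- edwards_distance(fd, fe), "zero copies")
  expect_equal(d, 0)
})

test_that("Edwards' distance matrix is symmetric with zero diagonal", {
  sim <- sim_dataset(sim_config(colonies_per_cluster = c(4, 4), seed = 8))
  m <- edwards_dist_matrix(colony_allele_frequencies(sim$gt))
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  expect_true(all(m >= 0 & m <= 1))
})

test_that("Mantel test matches oracles and hits its trivial anchors", {
  set.seed(23)
  pts <- matrix(runif(24), ncol = 2)
  d1 <- as.matrix(dist(pts))
  expect_equal(mantel_test(d1, d1, n_perm = 99)$r, 1)
  expect_equal(mantel_test(d1, d1, n_perm = 99)$p_value, 1 / 100)
  expect_equal(mantel_test(max(d1) - d1, d1, n_perm = 9)$r, -1)

  d2 <- as.matrix(dist(matrix(runif(24), ncol = 2)))
  expect_equal(mantel_test(d1, d2, n_perm = 9)$r, oracle_mantel_r(d1, d2),
               tolerance = 1e-12)
  # cross-check against the independent ade4 implementation
  expect_equal(mantel_test(d1, d2, n_perm = 9)$r,
               ade4::mantel.rtest(as.dist(d1), as.dist(d2), nrepet = 9)$obs,
               tolerance = 1e-10)
  expect_error(mantel_test(d1, d2[1:10, 1:10]), "mismatch")
})

test_that("kernel density of the distance scatter is a proper density", {
  set.seed(24)
  n <- 18
  d_geo <- as.matrix(dist(runif(n)))
  d_gen <- as.matrix(dist(runif(n)))
  dens <- ibd_density(d_gen, d_geo, n = 60)
  expect_true(all(dens$z >= 0))
  dx <- diff(dens$x[1:2]); dy <- diff(dens$y[1:2])
  expect_equal(sum(dens$z) * dx * dy, 1, tolerance = 0.05)

  # two well-separated patches give two local maxima along the geo axis
  g1 <- runif(10, 0, 0.1); g2 <- runif(10, 10, 10.1)
  e1 <- runif(10, 0, 0.02); e2 <- runif(10, 0.8, 0.82)
  d_geo2 <- as.matrix(dist(c(g1, g2)))
  d_gen2 <- as.matrix(dist(c(e1, e2)))
  dens2 <- ibd_density(d_gen2, d_geo2, n = 50)
  marg <- rowSums(dens2$z)
  peaks <- sum(diff(sign(diff(marg))) == -2)
  expect_gte(peaks, 2)
})

test_that("KNN graph honours K, ties and row normalisation", {
  # 3 collinear equally spaced points, K = 1: middle joins the lower id
  geo <- tibble::tibble(colony_id = c("a", "b", "c"),
                        x = c(0, 1, 2), y = 0)
  g <- knn_graph(geo, k = 1)
  expect_equal(unname(g$adjacency["b", ]), c(1, 0, 0))
  expect_true(all(abs(rowSums(g$w) - 1) < 1e-12))
  expect_true(all(diag(g$adjacency) == 0))

  # K = n - 1: complete graph
  set.seed(25)
  geo2 <- tibble::tibble(colony_id = paste0("c", 1:7),
                         x = runif(7), y = runif(7))
  g2 <- knn_graph(geo2, k = 6)
  expect_true(all(g2$adjacency[upper.tri(g2$adjacency) |
                                 lower.tri(g2$adjacency)] == 1))

  # survey-scale layout: K = 10, every row of W sums to 1
  sim <- sim_dataset(sim_config(seed = 4))
  g3 <- knn_graph(sim$geo, k = 10)
  expect_equal(unname(rowSums(g3$w)), rep(1, 52))
  expect_error(knn_graph(geo, k = 5), "k \\+ 1")
})

test_that("Moran's I matches its null expectation and sign anchors", {
  set.seed(26)
  geo <- tibble::tibble(colony_id = paste0("c", 1:15),
                        x = runif(15), y = runif(15))
  w <- knn_graph(geo, 4)$w
  v <- rnorm(15)
  expect_equal(morans_i(v, w), oracle_moran(v, w), tolerance = 1e-12)
  null_mean <- mean(replicate(10000, morans_i(sample(v), w)))
  expect_lt(abs(null_mean - (-1 / 14)), 0.005)

  # two spatial blobs with distinct constant-ish values: strong positive I
  geo2 <- tibble::tibble(colony_id = paste0("c", 1:12),
                         x = c(runif(6), runif(6) + 10), y = 0)
  w2 <- knn_graph(geo2, 3)$w
  v2 <- c(rnorm(6, 0, 0.01), rnorm(6, 5, 0.01))
  expect_gt(morans_i(v2, w2), 0.8)

  # checkerboard on a 4x4 rook grid: negative I
  grid <- expand.grid(gx = 1:4, gy = 1:4)
  wr <- matrix(0, 16, 16)
  for (i in 1:16) for (j in 1:16) {
    if (abs(grid$gx[i] - grid$gx[j]) + abs(grid$gy[i] - grid$gy[j]) == 1) {
      wr[i, j] <- 1
    }
  }
  wr <- wr / rowSums(wr)
  chk <- (-1)^(grid$gx + grid$gy)
  expect_lt(morans_i(chk, wr), -0.9)
  expect_error(morans_i(rep(1, 16), wr), "constant")
})

test_that("sPCA satisfies the variance-times-autocorrelation identity", {
  set.seed(27)
  sim <- sim_dataset(sim_config(seed = 19))
  x <- freq_matrix(colony_allele_frequencies(sim$gt))[sim$geo$colony_id, ]
  net <- knn_graph(sim$geo, 10)
  fit <- spca(x, net)
  ident <- fit$axes$lambda - fit$axes$variance * fit$axes$moran_i
  expect_true(all(abs(ident[!is.na(ident)]) < 1e-10))
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  # loadings per axis sum to 1 (unit eigenvectors)
  expect_equal(unname(colSums(fit$loadings)), rep(1, ncol(fit$loadings)),
               tolerance = 1e-9)
})

test_that("sPCA separates spatially segregated clusters", {
  sim <- sim_dataset(sim_config(family_mix = c(1, 0, 0), seed = 31))
  x <- freq_matrix(colony_allele_frequencies(sim$gt))[sim$geo$colony_id, ]
  net <- knn_graph(sim$geo, 10)
  fit <- spca(x, net)
  expect_gt(fit$eigenvalues[1], 3 * abs(fit$eigenvalues[2]))
  sc <- fit$scores[, 1]
  conc <- max(mean((sc > 0) == (sim$geo$cluster == 1)),
              mean((sc > 0) == (sim$geo$cluster == 2)))
  expect_gte(conc, 0.9)
  tst <- spca_tests(x, net, n_perm = 499, seed = 1)
  expect_lte(tst$global$p_value, 0.01)
  expect_gt(tst$local$p_value, 0.05)
})

test_that("spatially random data yield a flat sPCA spectrum", {
  set.seed(28)
  sim <- sim_dataset(sim_config(n_clusters = 1, colonies_per_cluster = 30,
                                family_mix = c(1, 0, 0), seed = 9))
  x <- freq_matrix(colony_allele_frequencies(sim$gt))[sim$geo$colony_id, ]
  net <- knn_graph(sim$geo, 10)
  fit <- spca(x, net)
  # lambda1 is small relative to the total (non-spatial) variance
  expect_lt(fit$eigenvalues[1] / sum(fit$axes$variance), 0.25)
})

test_that("complete-graph sPCA degenerates to the PCA axes", {
  set.seed(29)
  n <- 25
  x <- matrix(rnorm(n * 8), n)
  w <- matrix(1 / (n - 1), n, n); diag(w) <- 0
  fit <- spca(x, w)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  # the most extreme sPCA axis carries the leading PCA axis (up to sign)
  extreme <- which.max(abs(fit$eigenvalues))
  r <- abs(cor(fit$scores[, extreme], pc$x[, 1]))
  expect_gte(r, 0.9)
})

test_that("loading reports rank planted high-divergence alleles first", {
  # two clusters differing mainly at locus 1
  set.seed(30)
  n <- 20
  x <- matrix(runif(n * 6, 0.3, 0.7), n)
  colnames(x) <- c(paste0("loc1.", 1:2), paste0("loc2.", 1:2),
                   paste0("loc3.", 1:2))
  x[1:10, 1] <- x[1:10, 1] + 0.8   # planted signal, spatially aligned
  geo <- tibble::tibble(colony_id = paste0("c", 1:n),
                        x = c(runif(10), runif(10) + 5), y = 0)
  rownames(x) <- geo$colony_id
  net <- knn_graph(geo, 4)
  fit <- spca(x, net)
  rep1 <- loading_report(fit, axes = 1, top_k = 3)
  expect_equal(rep1$allele[1], "loc1.1")
  # top_k larger than allele count: full list
  rep_all <- loading_report(fit, axes = 1, top_k = 99)
  expect_equal(nrow(rep_all), 6)
  expect_equal(sum(rep_all$loading), 1, tolerance = 1e-9)
})
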