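#' Edwards' angular genetic distance between two frequency profiles
#'
#' `D = sqrt(1 - (1/L) * sum_l sum_a sqrt(p_la * q_la))`: one minus the mean
#' per-locus Bhattacharyya overlap, square-rooted, so identical profiles are
#' at distance 0 and profiles with disjoint alleles at every locus are at
#' distance 1. Loci with zero gene copies in either group are dropped (with
#' a warning) and L reduced.
#'
#' @param freqs_a,freqs_b Lists of per-locus allele frequency vectors named
#'   by allele code (missing alleles count as frequency 0).
#' @return Distance in `[0, 1]`.
#' @export
edwards_distance <- function(freqs_a, freqs_b) {
  loci <- union(names(freqs_a), names(freqs_b))
  overlaps <- numeric(0)
  dropped <- character(0)
  for (lc in loci) {
    p <- freqs_a[[lc]]; q <- freqs_b[[lc]]
    if (is.null(p) || is.null(q) || !sum(p) > 0 || !sum(q) > 0) {
      dropped <- c(dropped, lc)
      next
    }
    al <- union(names(p), names(q))
    pv <- setNames(rep(0, length(al)), al); pv[names(p)] <- p
    qv <- setNames(rep(0, length(al)), al); qv[names(q)] <- q
    overlaps <- c(overlaps, sum(sqrt(pv * qv)))
  }
  if (length(dropped) > 0) {
    warning("dropping loci with zero copies: ", paste(dropped, collapse = ", "))
  }
  if (length(overlaps) == 0) stop("no usable loci for Edwards' distance")
  sqrt(max(0, 1 - mean(overlaps)))
}

#' Pairwise Edwards' distance matrix over groups
#'
#' @param freqs Long frequency tibble from [allele_frequencies()].
#' @return A symmetric matrix of Edwards' distances.
#' @export
edwards_dist_matrix <- function(freqs) {
  freqs <- dplyr::filter(freqs, !is.na(.data$allele))
  groups <- unique(freqs$group)
  flists <- lapply(groups, function(g) {
    d <- freqs[freqs$group == g, ]
    split(setNames(d$freq, d$allele), d$locus)
  })
  names(flists) <- groups
  n <- length(groups)
  m <- matrix(0, n, n, dimnames = list(groups, groups))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- edwards_distance(flists[[i]], flists[[j]])
    }
  }
  m
}

#' Mantel test of matrix association
#'
#' Pearson correlation between the lower triangles of two distance
#' matrices; the null is generated by simultaneous row/column permutation
#' of the second matrix. One-sided p for positive association,
#' `(1 + hits) / (1 + n_perm)`.
#'
#' @param d_gen,d_geo Square symmetric matrices of equal dimension.
#' @param n_perm Permutations (default 999).
#' @param seed Optional seed.
#' @return List `r`, `p_value`, `n_perm`.
#' @export
mantel_test <- function(d_gen, d_geo, n_perm = 999, seed = NULL) {
  if (!all(dim(d_gen) == dim(d_geo))) stop("matrix size mismatch")
  if (!is.null(seed)) set.seed(seed)
  lt <- lower.tri(d_gen)
  x <- d_gen[lt]
  r_obs <- cor(x, d_geo[lt])
  hits <- 0L
  n <- nrow(d_geo)
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    if (cor(x, d_geo[p, p][lt]) >= r_obs) hits <- hits + 1L
  }
  list(r = r_obs, p_value = (1 + hits) / (1 + n_perm), n_perm = n_perm)
}

#' Kernel density of the isolation-by-distance scatter
#'
#' Gaussian product-kernel density (via [MASS::kde2d()]) of the pairwise
#' (geographic distance, genetic distance) scatter, used to distinguish a
#' continuous cline (one cloud) from differentiated patches (several local
#' maxima).
#'
#' @param d_gen,d_geo Square symmetric distance matrices.
#' @param n Grid points per axis.
#' @param bandwidth Optional length-2 bandwidth; default normal-reference
#'   rule per axis.
#' @return List `x` (geographic grid), `y` (genetic grid), `z` (density
#'   matrix), `points` (tibble of the scatter).
#' @export
ibd_density <- function(d_gen, d_geo, n = 100, bandwidth = NULL) {
  lt <- lower.tri(d_gen)
  gx <- d_geo[lt]
  gy <- d_gen[lt]
  if (sd(gx) == 0 || sd(gy) == 0) stop("zero-variance axis in IBD scatter")
  if (is.null(bandwidth)) bandwidth <- c(MASS::bandwidth.nrd(gx),
                                         MASS::bandwidth.nrd(gy))
  # extend the grid beyond the data range so the kernel tails are captured
  # and the density integrates to ~1 over the grid
  lims <- c(range(gx) + c(-3, 3) * bandwidth[1] / 4,
            range(gy) + c(-3, 3) * bandwidth[2] / 4)
  kd <- MASS::kde2d(gx, gy, h = bandwidth, n = n, lims = lims)
  list(x = kd$x, y = kd$y, z = kd$z,
       points = tibble::tibble(geo = gx, gen = gy))
}

#' K-nearest-neighbour connection network
#'
#' Directed KNN adjacency on planar colony coordinates; distance ties are
#' broken by colony order (lower index first). The weight matrix `W` is the
#' row-normalised adjacency, so every row sums to 1. Adjacency need not be
#' symmetric.
#'
#' @param geo Colony metadata tibble with `colony_id`, `x`, `y`.
#' @param k Number of neighbours (default 10).
#' @return Object of class `knn_graph`: `nodes`, `adjacency` (0/1 matrix),
#'   `w` (row-normalised weights), `k`.
#' @export
knn_graph <- function(geo, k = 10) {
  n <- nrow(geo)
  if (n < k + 1) stop("need at least k + 1 colonies")
  d <- as.matrix(stats::dist(cbind(geo$x, geo$y)))
  adj <- matrix(0, n, n, dimnames = list(geo$colony_id, geo$colony_id))
  for (i in seq_len(n)) {
    ord <- order(d[i, -i], seq_len(n)[-i])   # ties broken by colony order
    nb <- (seq_len(n)[-i])[ord][seq_len(k)]
    adj[i, nb] <- 1
  }
  w <- adj / rowSums(adj)
  structure(list(nodes = geo$colony_id, adjacency = adj, w = w, k = k),
            class = "knn_graph")
}

#' Moran's I spatial autocorrelation
#'
#' `I = (n / sum(W)) * (z' W z) / (z' z)` with `z` the centred values. Null
#' expectation under random permutation is `-1 / (n - 1)`.
#'
#' @param values Numeric vector (one per node).
#' @param w Weight matrix (rows aligned with `values`) or a [knn_graph()].
#' @return Moran's I.
#' @export
morans_i <- function(values, w) {
  if (inherits(w, "knn_graph")) w <- w$w
  if (sd(values) == 0) stop("Moran's I undefined for a constant vector")
  z <- values - mean(values)
  n <- length(z)
  (n / sum(w)) * as.numeric(t(z) %*% w %*% z) / sum(z^2)
}

# internal: centred frequency matrix with NA cells replaced by column means
.center_freq_matrix <- function(x) {
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- mean(x[!nas, j])
  }
  sweep(x, 2, colMeans(x))
}

#' Spatial principal component analysis
#'
#' Eigenanalysis of `H = (1/n) * Xc' ((W + W') / 2) Xc`, where `Xc` is the
#' column-centred group-by-allele frequency matrix and `W` the
#' row-normalised connection-network weights. Each axis maximises the
#' product of the variance of its scores and their Moran's I (computed with
#' the symmetrised weights), so positive eigenvalues capture global
#' (neighbour-similar) structure and negative eigenvalues local
#' (neighbour-dissimilar) structure; the identity
#' `lambda_i = var(score_i) * I(score_i)` is exact.
#'
#' @param x Frequency matrix (groups x alleles, from [freq_matrix()]) or a
#'   long frequency tibble.
#' @param network A [knn_graph()] on the same groups (row order must match).
#' @return Object of class `spca`: `eigenvalues`, `scores`, `loadings`
#'   (squared eigenvector components per axis), `axes` tibble (lambda,
#'   variance, moran_i), `w_sym`.
#' @export
spca <- function(x, network) {
  if (!is.matrix(x)) x <- freq_matrix(x)
  if (nrow(x) < 3) stop("need at least 3 groups for sPCA")
  w <- if (inherits(network, "knn_graph")) network$w else network
  if (nrow(w) != nrow(x)) stop("network and frequency matrix disagree on groups")
  xc <- .center_freq_matrix(x)
  n <- nrow(xc)
  ws <- (w + t(w)) / 2
  h <- crossprod(xc, ws %*% xc) / n
  h <- (h + t(h)) / 2
  eig <- eigen(h, symmetric = TRUE)
  scores <- xc %*% eig$vectors
  lambda <- eig$values
  vr <- colSums(scores^2) / n
  mi <- vapply(seq_len(ncol(scores)), function(i) {
    if (vr[i] < 1e-14) return(NA_real_)
    morans_i(scores[, i], ws)
  }, numeric(1))
  loadings <- eig$vectors^2
  rownames(loadings) <- colnames(x)
  colnames(scores) <- paste0("axis", seq_along(lambda))
  structure(list(eigenvalues = lambda,
                 scores = scores,
                 vectors = eig$vectors,
                 loadings = loadings,
                 axes = tibble::tibble(axis = seq_along(lambda),
                                       lambda = lambda, variance = vr,
                                       moran_i = mi),
                 w_sym = ws, x_centered = xc),
            class = "spca")
}

#' Global and local permutation tests for spatial genetic structure
#'
#' The global statistic is the largest positive eigenvalue of the sPCA
#' matrix `H`, the local statistic the largest magnitude of its negative
#' eigenvalues; both null distributions come from permuting group rows over
#' locations. This extreme-eigenvalue statistic shares the null of the
#' classical global/local sPCA tests without claiming exact equivalence to
#' them. p-values are `(1 + hits) / (1 + n_perm)`.
#'
#' @param x Frequency matrix or long frequency tibble.
#' @param network A [knn_graph()].
#' @param n_perm Permutations (default 9999).
#' @param seed Optional seed.
#' @return List `global` (stat, p_value) and `local` (stat, p_value).
#' @export
spca_tests <- function(x, network, n_perm = 9999, seed = NULL) {
  if (!is.matrix(x)) x <- freq_matrix(x)
  if (!is.null(seed)) set.seed(seed)
  w <- if (inherits(network, "knn_graph")) network$w else network
  ws <- (w + t(w)) / 2
  xc <- .center_freq_matrix(x)
  n <- nrow(xc)
  stat_pair <- function(xm) {
    h <- crossprod(xm, ws %*% xm) / n
    ev <- eigen((h + t(h)) / 2, symmetric = TRUE, only.values = TRUE)$values
    c(global = max(ev, 0), local = max(-ev, 0))
  }
  obs <- stat_pair(xc)
  hits <- c(global = 0L, local = 0L)
  for (b in seq_len(n_perm)) {
    s <- stat_pair(xc[sample.int(n), , drop = FALSE])
    if (s["global"] >= obs["global"]) hits["global"] <- hits["global"] + 1L
    if (s["local"] >= obs["local"]) hits["local"] <- hits["local"] + 1L
  }
  list(global = list(stat = unname(obs["global"]),
                     p_value = unname((1 + hits["global"]) / (1 + n_perm))),
       local = list(stat = unname(obs["local"]),
                    p_value = unname((1 + hits["local"]) / (1 + n_perm))),
       n_perm = n_perm)
}

#' Ranked allele contributions to sPCA axes
#'
#' Loadings are squared eigenvector components, so per axis they sum to 1;
#' alleles are labelled `locus.alleleCode`.
#'
#' @param fit An [spca()] result.
#' @param axes Axes to report (default first two).
#' @param top_k Alleles per axis (clamped to the allele count).
#' @return Tibble `axis`, `allele`, `loading`, `rank`.
#' @export
loading_report <- function(fit, axes = 1:2, top_k = 10) {
  out <- lapply(axes, function(ax) {
    ld <- fit$loadings[, ax]
    ord <- order(ld, decreasing = TRUE)
    k <- min(top_k, length(ld))
    tibble::tibble(axis = ax, allele = rownames(fit$loadings)[ord][seq_len(k)],
                   loading = ld[ord][seq_len(k)], rank = seq_len(k))
  })
  dplyr::bind_rows(out)
}
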