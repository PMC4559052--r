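# Builders and independent brute-force oracles shared across test files.

# quick genotype-table builder from per-individual allele vectors
# geno: list of individuals, each a list of c(a1, a2) per locus (NA allowed)
make_gt <- function(geno, colony = NULL, loci = NULL) {
  n_loci <- length(geno[[1]])
  if (is.null(loci)) loci <- paste0("loc", seq_len(n_loci))
  if (is.null(colony)) colony <- rep("c1", length(geno))
  n <- length(geno)
  m <- do.call(rbind, lapply(geno, function(g) do.call(rbind, g)))
  gen_tbl(tibble::tibble(
    individual_id = rep(paste0("i", seq_len(n)), each = n_loci),
    colony_id = rep(colony, each = n_loci),
    locus = rep(loci, times = n),
    allele_1 = m[, 1], allele_2 = m[, 2]), loci = loci)
}

# random small dataset: n_col colonies x n_ind individuals x n_loci loci
random_gt <- function(n_col, n_ind, n_loci, n_alleles = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (ci in seq_len(n_col)) {
    for (ii in seq_len(n_ind)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        individual_id = sprintf("c%d_i%d", ci, ii),
        colony_id = paste0("c", ci),
        locus = paste0("loc", seq_len(n_loci)),
        allele_1 = sample.int(n_alleles, n_loci, replace = TRUE),
        allele_2 = sample.int(n_alleles, n_loci, replace = TRUE))
    }
  }
  gen_tbl(dplyr::bind_rows(rows))
}

# uniform allele-frequency template over the study's per-locus allele counts
uniform_freqs <- function(counts = c(13, 3, 3, 2, 3, 4)) {
  out <- lapply(counts, function(k) {
    p <- rep(1 / k, k)
    names(p) <- as.character(100 + 3 * seq_len(k))
    p
  })
  names(out) <- paste0("loc", seq_along(counts))
  out
}

# wrap sim_colony output as a gen_tbl for the classifier
colony_as_gt <- function(sim, colony_id = "c1") {
  gen_tbl(dplyr::mutate(
    sim$genotypes,
    individual_id = paste0(colony_id, "_w", .data$worker),
    colony_id = colony_id)[, c("individual_id", "colony_id", "locus",
                               "allele_1", "allele_2")])
}

# ---- oracles --------------------------------------------------------------

# Weir-Cockerham components by scalar loops, straight off the 1984 paper
oracle_wc <- function(gt, group_map) {
  loci <- loci_of(gt)
  tot <- c(a = 0, b = 0, c = 0)
  for (lc in loci) {
    d <- gt[gt$locus == lc & !is.na(gt$allele_1), ]
    grp <- group_map[d$colony_id]
    gl <- unique(grp)
    r <- length(gl)
    n_i <- sapply(gl, function(g) sum(grp == g))
    nbar <- mean(n_i)
    nsum <- sum(n_i)
    alleles <- unique(c(d$allele_1, d$allele_2))
    for (al in alleles) {
      p_i <- sapply(gl, function(g) {
        sel <- grp == g
        (sum(d$allele_1[sel] == al) + sum(d$allele_2[sel] == al)) / (2 * sum(sel))
      })
      h_i <- sapply(gl, function(g) {
        sel <- grp == g
        mean(xor(d$allele_1[sel] == al, d$allele_2[sel] == al))
      })
      pbar <- sum(n_i * p_i) / nsum
      hbar <- sum(n_i * h_i) / nsum
      if (r >= 2) {
        nc <- (nsum - sum(n_i^2) / nsum) / (r - 1)
        s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
        a <- (nbar / nc) *
          (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
        b <- (nbar / (nbar - 1)) *
          (pbar * (1 - pbar) - (r - 1) / r * s2 -
             (2 * nbar - 1) / (4 * nbar) * hbar)
      } else {
        a <- 0
        b <- (nbar / (nbar - 1)) *
          (pbar * (1 - pbar) - (2 * nbar - 1) / (4 * nbar) * hbar)
      }
      tot <- tot + c(a = a, b = b, c = hbar / 2)
    }
  }
  list(a = unname(tot["a"]), b = unname(tot["b"]), c = unname(tot["c"]),
       fis = 1 - tot[["c"]] / (tot[["b"]] + tot[["c"]]),
       fst = tot[["a"]] / sum(tot),
       fit = 1 - tot[["c"]] / sum(tot))
}

# AMOVA sums of squares from explicit gene-copy pair distances
oracle_amova <- function(gt) {
  loci <- loci_of(gt)
  sig <- c(a = 0, b = 0, c = 0)
  for (lc in loci) {
    d <- gt[gt$locus == lc & !is.na(gt$allele_1), ]
    copies <- c(d$allele_1, d$allele_2)
    owner <- rep(d$individual_id, 2)
    colony <- rep(d$colony_id, 2)
    M <- length(copies)
    dist2 <- outer(copies, copies, "!=") * 1
    ssd_of <- function(idx) {
      m <- length(idx)
      if (m < 2) return(0)
      s <- 0
      for (i in seq_len(m - 1)) for (j in (i + 1):m) s <- s + dist2[idx[i], idx[j]]
      s / m
    }
    ss_total <- ssd_of(seq_len(M))
    ss_wc <- sum(sapply(unique(colony), function(cc) ssd_of(which(colony == cc))))
    ss_wi <- sum(sapply(unique(owner), function(oo) ssd_of(which(owner == oo))))
    N <- nrow(d)
    I <- length(unique(d$colony_id))
    m_i <- sapply(unique(d$colony_id), function(cc) 2 * sum(d$colony_id == cc))
    ms_c <- ss_wi / N
    ms_b <- (ss_wc - ss_wi) / (N - I)
    ms_a <- (ss_total - ss_wc) / (I - 1)
    ncp <- (M - sum(m_i^2) / M) / (I - 1)
    sc <- ms_c
    sb <- (ms_b - sc) / 2
    sa <- (ms_a - ms_b) / ncp
    sig <- sig + c(a = sa, b = sb, c = sc)
  }
  sig
}

# Moran's I by double loop
oracle_moran <- function(values, w) {
  z <- values - mean(values)
  n <- length(z)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}

# Mantel r by explicit pair loop
oracle_mantel_r <- function(d1, d2) {
  n <- nrow(d1)
  x <- c(); y <- c()
  for (i in 2:n) for (j in seq_len(i - 1)) {
    x <- c(x, d1[i, j]); y <- c(y, d2[i, j])
  }
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# multinomial G by direct formula from counts and class probabilities
oracle_g <- function(obs_counts, probs) {
  n <- sum(unlist(obs_counts))
  g <- 0
  for (cls in names(obs_counts)) {
    o <- obs_counts[[cls]]
    if (o > 0) g <- g + 2 * o * log(o / (n * probs[[cls]]))
  }
  g
}

# exhaustive parental-pair compatibility from first principles: all pairs of
# genotypes over the given allele pool; a pair is compatible when every
# observed class is among its Mendelian offspring
oracle_parent_pairs <- function(a1, a2, extra_alleles = integer(0)) {
  obs <- paste0(pmin(a1, a2), "/", pmax(a1, a2))
  pool <- sort(unique(c(a1, a2, extra_alleles)))
  genos <- list()
  for (i in seq_along(pool)) for (j in i:length(pool)) {
    genos[[length(genos) + 1L]] <- c(pool[i], pool[j])
  }
  out <- list()
  for (x in seq_along(genos)) for (y in x:length(genos)) {
    p1 <- genos[[x]]; p2 <- genos[[y]]
    off <- character(0)
    for (u in p1) for (v in p2) off <- c(off, paste0(min(u, v), "/", max(u, v)))
    if (all(obs %in% off)) out[[length(out) + 1L]] <- list(p1 = p1, p2 = p2)
  }
  out
}

# one-sided heterozygote-deficiency p by enumeration over ALL pairings of the
# gene copies (distinct orderings collapse; feasible for n <= 5)
oracle_hwe_p <- function(a1, a2) {
  copies <- c(rbind(a1, a2))
  n <- length(a1)
  h_obs <- sum(a1 != a2)
  perms <- combinat_perms(length(copies))
  hets <- apply(perms, 1, function(idx) {
    s <- copies[idx]
    sum(s[seq(1, 2 * n, 2)] != s[seq(2, 2 * n, 2)])
  })
  mean(hets <= h_obs)
}

combinat_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- combinat_perms(n - 1)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- 0
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}
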