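#' Observed and Nei unbiased expected heterozygosity
#'
#' `H_O` is the fraction of heterozygous genotypes; `H_E` is Nei's unbiased
#' expected heterozygosity `(2n / (2n - 1)) * (1 - sum p_i^2)` with `n` the
#' number of genotyped individuals. A final `"all"` row carries the means
#' over loci.
#'
#' @param gt A genotype table.
#' @param group Optional grouping (as in [allele_frequencies()]); default
#'   pools the whole sample.
#' @return Tibble `group`, `locus`, `n`, `h_obs`, `h_exp`.
#' @export
observed_expected_het <- function(gt, group = NULL) {
  if (is.null(group)) {
    gt$.group <- "all"
  } else {
    gt$.group <- .group_of(gt, group)
  }
  typed <- dplyr::filter(gt, !is.na(.data$allele_1))
  per <- dplyr::summarise(
    dplyr::group_by(typed, group = .data$.group, locus = .data$locus),
    n = dplyr::n(),
    h_obs = mean(.data$allele_1 != .data$allele_2),
    h_exp = {
      p <- table(c(.data$allele_1, .data$allele_2))
      p <- p / sum(p)
      nn <- dplyr::n()
      if (nn > 1) (2 * nn / (2 * nn - 1)) * (1 - sum(p^2)) else NA_real_
    },
    .groups = "drop")
  per <- dplyr::arrange(per, .data$group, match(.data$locus, loci_of(gt)))
  overall <- dplyr::summarise(
    dplyr::group_by(per, .data$group),
    locus = "all", n = mean(.data$n), h_obs = mean(.data$h_obs),
    h_exp = mean(.data$h_exp), .groups = "drop")
  dplyr::bind_rows(per, overall)
}

# ---- Weir & Cockerham (1984) variance components -------------------------

# internal: per-locus W&C components summed over alleles.
# a1/a2 integer alleles (NA = missing), grp integer group index.
# Returns c(a, b, c) or NA when fewer than 2 typed individuals.
.wc_locus <- function(a1, a2, grp) {
  keep <- !is.na(a1)
  a1 <- a1[keep]; a2 <- a2[keep]; grp <- grp[keep]
  if (length(a1) < 2) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  gl <- sort(unique(grp))
  g <- match(grp, gl)
  r <- length(gl)
  n_i <- tabulate(g, r)
  nsum <- sum(n_i)
  nbar <- nsum / r
  if (nbar <= 1 && r == 1) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  alleles <- sort(unique(c(a1, a2)))
  A <- length(alleles)
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)
  # per-group allele copy counts (r x A)
  cnt <- matrix(tabulate(g + r * (i1 - 1L), r * A) +
                  tabulate(g + r * (i2 - 1L), r * A), r, A)
  p_i <- cnt / (2 * n_i)
  # per-group count of individuals heterozygous FOR each allele
  het <- i1 != i2
  hcnt <- matrix(tabulate(g[het] + r * (i1[het] - 1L), r * A) +
                   tabulate(g[het] + r * (i2[het] - 1L), r * A), r, A)
  h_i <- hcnt / n_i
  pbar <- colSums(n_i * p_i) / nsum
  hbar <- colSums(n_i * h_i) / nsum
  if (r >= 2) {
    nc <- (nsum - sum(n_i^2) / nsum) / (r - 1)
    s2 <- colSums(n_i * sweep(p_i, 2, pbar)^2) / ((r - 1) * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  } else {
    a <- rep(0, A)
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (2 * nbar - 1) / (4 * nbar) * hbar)
  }
  cc <- hbar / 2
  c(a = sum(a), b = sum(b), c = sum(cc))
}

# internal: assemble per-locus allele matrices once for fast permutation
.locus_arrays <- function(gt, grp_by_ind = NULL) {
  loci <- loci_of(gt)
  inds <- unique(gt$individual_id)
  colony <- gt$colony_id[match(inds, gt$individual_id)]
  arr <- lapply(loci, function(lc) {
    d <- gt[gt$locus == lc, ]
    i <- match(d$individual_id, inds)
    a1 <- rep(NA_integer_, length(inds)); a2 <- a1
    a1[i] <- d$allele_1; a2[i] <- d$allele_2
    cbind(a1, a2)
  })
  names(arr) <- loci
  list(arr = arr, inds = inds, colony = colony)
}

#' Weir-Cockerham F-statistics
#'
#' Per-locus and multi-locus estimates of F_IS, F_ST and F_IT from the
#' Weir & Cockerham (1984) variance components `a` (among groups), `b`
#' (among individuals within groups) and `c` (within individuals).
#' Multi-locus estimates are ratios of components summed over alleles and
#' loci, never means of per-locus ratios. With a single group only F_IS is
#' defined. Significance: F_IS by permuting gene copies among individuals
#' within groups (one-sided toward heterozygote deficiency, i.e. large
#' F_IS); F_ST by permuting individuals among groups (one-sided toward
#' differentiation). Permutation p-values use `(1 + hits) / (1 + n_perm)`.
#'
#' @param gt A genotype table.
#' @param group Grouping: `NULL` (single pooled group), `"colony"`, or a
#'   `colony_id`/`group` data frame.
#' @param n_perm Number of permutations (0 = no test).
#' @param seed Optional seed for the permutations.
#' @return An object of class `wc_fstats`: list with `per_locus` tibble,
#'   `overall` (components and F-statistics), `p_fis`, `p_fst`, `grouping`.
#' @export
wc_fstats <- function(gt, group = NULL, n_perm = 0, seed = NULL) {
  la <- .locus_arrays(gt)
  grp <- if (is.null(group)) rep(1L, length(la$inds)) else {
    gmap <- .group_of(tibble::tibble(colony_id = la$colony), group)
    match(gmap, unique(gmap))
  }
  compute <- function(arrs, grp) {
    comps <- t(vapply(arrs, function(m) .wc_locus(m[, 1], m[, 2], grp),
                      numeric(3)))
    tot <- colSums(comps, na.rm = TRUE)
    list(comps = comps, tot = tot,
         fis = 1 - tot[3] / (tot[2] + tot[3]),
         fst = tot[1] / sum(tot),
         fit = 1 - tot[3] / sum(tot))
  }
  obs <- compute(la$arr, grp)
  per_locus <- tibble::tibble(
    locus = names(la$arr),
    a = obs$comps[, 1], b = obs$comps[, 2], c = obs$comps[, 3],
    fis = 1 - obs$comps[, 3] / (obs$comps[, 2] + obs$comps[, 3]),
    fst = obs$comps[, 1] / rowSums(obs$comps),
    fit = 1 - obs$comps[, 3] / rowSums(obs$comps))
  p_fis <- NA_real_; p_fst <- NA_real_
  if (n_perm > 0 && !is.null(seed)) set.seed(seed)
  if (n_perm > 0) {
    hits_fis <- 0L
    hits_fst <- 0L
    r <- length(unique(grp))
    for (b in seq_len(n_perm)) {
      # F_IS null: shuffle gene copies among individuals within each group
      arrs_is <- lapply(la$arr, function(m) {
        out <- m
        for (gi in unique(grp)) {
          sel <- which(grp == gi & !is.na(m[, 1]))
          if (length(sel) < 2) next
          copies <- sample(c(m[sel, 1], m[sel, 2]))
          out[sel, 1] <- copies[seq_along(sel)]
          out[sel, 2] <- copies[length(sel) + seq_along(sel)]
        }
        out
      })
      pis <- compute(arrs_is, grp)
      if (!is.na(pis$fis) && pis$fis >= obs$fis) hits_fis <- hits_fis + 1L
      if (r >= 2) {
        gperm <- sample(grp)
        pst <- compute(la$arr, gperm)
        if (!is.na(pst$fst) && pst$fst >= obs$fst) hits_fst <- hits_fst + 1L
      }
    }
    p_fis <- (1 + hits_fis) / (1 + n_perm)
    if (r >= 2) p_fst <- (1 + hits_fst) / (1 + n_perm)
  }
  structure(list(
    per_locus = per_locus,
    overall = list(a = unname(obs$tot[1]), b = unname(obs$tot[2]),
                   c = unname(obs$tot[3]), fis = unname(obs$fis),
                   fst = unname(obs$fst), fit = unname(obs$fit)),
    p_fis = p_fis, p_fst = p_fst, n_perm = n_perm,
    grouping = if (is.null(group)) "pooled" else "grouped"),
    class = "wc_fstats")
}

#' Pairwise F_ST between groups with permutation significance
#'
#' @param gt A genotype table.
#' @param group A `colony_id`/`group` data frame or `"colony"`.
#' @param n_perm Randomizations for each pair (default 1000).
#' @param seed Optional seed.
#' @return Tibble `group_1`, `group_2`, `fst`, `p_value`.
#' @export
pairwise_fst <- function(gt, group, n_perm = 1000, seed = NULL) {
  gvec <- .group_of(gt, group)
  gt$.grp <- gvec
  groups <- unique(gvec)
  if (!is.null(seed)) set.seed(seed)
  pairs <- combn(groups, 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    sub <- gt[gt$.grp %in% pairs[, j], ]
    cg <- dplyr::distinct(tibble::tibble(colony_id = sub$colony_id,
                                         group = sub$.grp))
    fit <- wc_fstats(gen_tbl(sub[, 1:5], loci = loci_of(gt)), group = cg,
                     n_perm = n_perm)
    tibble::tibble(group_1 = pairs[1, j], group_2 = pairs[2, j],
                   fst = fit$overall$fst, p_value = fit$p_fst)
  })
  dplyr::bind_rows(out)
}

# ---- Exact / Monte-Carlo test of heterozygote deficiency -----------------

# internal: exact one-sided p by enumeration of genotype configurations
# conditional on allele counts. Returns NULL when the configuration count
# exceeds `bound`.
.hwe_enumerate <- function(allele_counts, h_obs, bound) {
  k <- length(allele_counts)
  n <- sum(allele_counts) / 2
  pairs <- combn(k, 2)
  # cheap overestimate of the configuration count; avoids paying for a
  # deep recursion only to discover the bound is exceeded
  est <- prod(pmin(allele_counts[pairs[1, ]], allele_counts[pairs[2, ]]) + 1)
  if (est > 50 * bound) return(NULL)
  lp_base <- lfactorial(n) + sum(lfactorial(allele_counts)) - lfactorial(2 * n)
  total <- 0
  hit <- 0
  count <- 0L
  overflow <- FALSE
  # recurse over heterozygote cells; homozygote counts are then determined
  rec <- function(idx, rem, h_acc, lp_het) {
    if (overflow) return(invisible(NULL))
    if (idx > ncol(pairs)) {
      if (any(rem %% 2 != 0)) return(invisible(NULL))
      count <<- count + 1L
      if (count > bound) { overflow <<- TRUE; return(invisible(NULL)) }
      homo <- rem / 2
      lp <- lp_base + h_acc * log(2) + lp_het - sum(lfactorial(homo))
      p <- exp(lp)
      total <<- total + p
      if (h_acc <= h_obs) hit <<- hit + p
      return(invisible(NULL))
    }
    i <- pairs[1, idx]; j <- pairs[2, idx]
    cmax <- min(rem[i], rem[j])
    for (cc in 0:cmax) {
      rem2 <- rem
      rem2[i] <- rem2[i] - cc
      rem2[j] <- rem2[j] - cc
      rec(idx + 1L, rem2, h_acc + cc, lp_het - lfactorial(cc))
      if (overflow) break
    }
    invisible(NULL)
  }
  rec(1L, allele_counts, 0L, 0)
  if (overflow) return(NULL)
  list(p = hit / total, n_configs = count)
}

#' Exact test of heterozygote deficiency
#'
#' Conditional on the observed allele counts, the one-sided p-value is the
#' probability (under random union of gametes, Levene's distribution) of a
#' genotype configuration with no more heterozygotes than observed. Small
#' tables are fully enumerated; larger ones fall back to Monte Carlo
#' shuffling of gene copies into diploid pairs, with
#' `p = (1 + hits) / (1 + reps)`.
#'
#' @param gt A genotype table.
#' @param group Optional grouping; default pools the sample.
#' @param mc_reps Monte Carlo replicates when enumeration is infeasible.
#' @param enum_bound Maximum number of genotype configurations enumerated.
#' @param seed Optional seed.
#' @return Tibble `group`, `locus`, `n`, `h_obs_count`, `p_value`, `method`,
#'   `reps`. Monomorphic loci get `p = 1`, method `"degenerate"`.
#' @export
hwe_deficiency_test <- function(gt, group = NULL, mc_reps = 10000,
                                enum_bound = 20000, seed = NULL) {
  gt$.group <- if (is.null(group)) "all" else .group_of(gt, group)
  if (!is.null(seed)) set.seed(seed)
  combos <- dplyr::distinct(gt, .data$.group, .data$locus)
  out <- lapply(seq_len(nrow(combos)), function(i) {
    d <- gt[gt$.group == combos$.group[i] & gt$locus == combos$locus[i], ]
    d <- d[!is.na(d$allele_1), ]
    n <- nrow(d)
    h_obs <- sum(d$allele_1 != d$allele_2)
    row <- tibble::tibble(group = combos$.group[i], locus = combos$locus[i],
                          n = n, h_obs_count = h_obs, p_value = 1,
                          method = "degenerate", reps = NA_integer_)
    copies <- c(d$allele_1, d$allele_2)
    ac <- as.integer(table(copies))
    if (n == 0 || length(ac) < 2) return(row)
    ex <- .hwe_enumerate(ac, h_obs, enum_bound)
    if (!is.null(ex)) {
      row$p_value <- ex$p
      row$method <- "enumeration"
      row$reps <- ex$n_configs
      return(row)
    }
    hits <- 0L
    for (b in seq_len(mc_reps)) {
      s <- sample(copies)
      h <- sum(s[seq_len(n)] != s[n + seq_len(n)])
      if (h <= h_obs) hits <- hits + 1L
    }
    row$p_value <- (1 + hits) / (1 + mc_reps)
    row$method <- "monte_carlo"
    row$reps <- as.integer(mc_reps)
    row
  })
  dplyr::bind_rows(out)
}

# ---- Genotypic linkage disequilibrium ------------------------------------

# internal: G statistic of an r x c count matrix built from index vectors
.g_stat_table <- function(fa, fb, ra, rb) {
  o <- tabulate(fa + ra * (fb - 1L), ra * rb)
  ca <- tabulate(fa, ra)
  cb <- tabulate(fb, rb)
  e <- as.vector(outer(ca, cb)) / length(fa)
  pos <- o > 0
  2 * sum(o[pos] * log(o[pos] / e[pos]))
}

#' Genotypic linkage disequilibrium test for one locus pair
#'
#' G statistic on the two-locus genotype contingency table; the null
#' distribution is generated by permuting one locus's genotypes across
#' individuals (within groups when a grouping is given).
#'
#' @param gt A genotype table.
#' @param locus_a,locus_b Locus names.
#' @param mc_reps Permutations.
#' @param group Optional grouping restricting the permutation.
#' @param seed Optional seed.
#' @return List `G`, `p_value`, `n`.
#' @export
ld_test <- function(gt, locus_a, locus_b, mc_reps = 10000, group = NULL,
                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grp <- if (is.null(group)) rep("all", nrow(gt)) else .group_of(gt, group)
  da <- gt[gt$locus == locus_a, ]
  db <- gt[gt$locus == locus_b, ]
  ids <- intersect(da$individual_id[!is.na(da$allele_1)],
                   db$individual_id[!is.na(db$allele_1)])
  if (length(ids) < 2) return(list(G = NA_real_, p_value = 1, n = length(ids)))
  ia <- match(ids, da$individual_id)
  ib <- match(ids, db$individual_id)
  ka <- paste0(da$allele_1[ia], "/", da$allele_2[ia])
  kb <- paste0(db$allele_1[ib], "/", db$allele_2[ib])
  g_ind <- grp[match(ids, gt$individual_id)]
  fa <- match(ka, unique(ka)); ra <- length(unique(ka))
  fb <- match(kb, unique(kb)); rb <- length(unique(kb))
  if (ra < 2 || rb < 2) return(list(G = NA_real_, p_value = 1, n = length(ids)))
  g_obs <- .g_stat_table(fa, fb, ra, rb)
  hits <- 0L
  for (b in seq_len(mc_reps)) {
    fb_p <- fb
    for (gi in unique(g_ind)) {
      sel <- which(g_ind == gi)
      fb_p[sel] <- fb[sel][sample.int(length(sel))]
    }
    if (.g_stat_table(fa, fb_p, ra, rb) >= g_obs) hits <- hits + 1L
  }
  list(G = g_obs, p_value = (1 + hits) / (1 + mc_reps), n = length(ids))
}

#' Linkage-disequilibrium scan over all locus pairs
#'
#' @param gt A genotype table.
#' @param mc_reps Permutations per pair.
#' @param alpha Nominal level; the decision threshold is Bonferroni-adjusted
#'   to `alpha / n_pairs`.
#' @param group Optional grouping for the permutations.
#' @param seed Optional seed.
#' @return Tibble `locus_a`, `locus_b`, `G`, `p_value`, `significant` plus
#'   attribute `alpha_adjusted`.
#' @export
ld_scan <- function(gt, mc_reps = 10000, alpha = 0.05, group = NULL,
                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  loci <- loci_of(gt)
  prs <- combn(loci, 2)
  out <- lapply(seq_len(ncol(prs)), function(j) {
    r <- ld_test(gt, prs[1, j], prs[2, j], mc_reps = mc_reps, group = group)
    tibble::tibble(locus_a = prs[1, j], locus_b = prs[2, j], G = r$G,
                   p_value = r$p_value)
  })
  out <- dplyr::bind_rows(out)
  thr <- alpha / ncol(prs)
  out$significant <- out$p_value < thr
  attr(out, "alpha_adjusted") <- thr
  out
}

# ---- Hierarchical AMOVA ---------------------------------------------------

# internal: per-locus AMOVA pieces from allele matrices and colony index
.amova_locus <- function(a1, a2, col_idx) {
  keep <- !is.na(a1)
  a1 <- a1[keep]; a2 <- a2[keep]; ci <- col_idx[keep]
  cols <- sort(unique(ci))
  g <- match(ci, cols)
  I <- length(cols)
  n_i <- tabulate(g, I)
  N <- sum(n_i)
  m_i <- 2 * n_i
  ncop <- 2 * N
  alleles <- sort(unique(c(a1, a2)))
  A <- length(alleles)
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)
  c_ia <- matrix(tabulate(g + I * (i1 - 1L), I * A) +
                   tabulate(g + I * (i2 - 1L), I * A), I, A)
  C_a <- colSums(c_ia)
  ss_total <- (ncop^2 - sum(C_a^2)) / (2 * ncop)
  ss_wc <- sum((m_i^2 - rowSums(c_ia^2)) / (2 * m_i))
  ss_wi <- sum(a1 != a2) / 2
  ss_a <- ss_total - ss_wc
  ss_b <- ss_wc - ss_wi
  df_a <- I - 1; df_b <- N - I; df_c <- N
  ms_a <- if (df_a > 0) ss_a / df_a else NA_real_
  ms_b <- if (df_b > 0) ss_b / df_b else NA_real_
  ms_c <- ss_wi / df_c
  ncp <- if (df_a > 0) (ncop - sum(m_i^2) / ncop) / df_a else NA_real_
  sig_c <- ms_c
  sig_b <- if (!is.na(ms_b)) (ms_b - sig_c) / 2 else NA_real_
  sig_a <- if (!is.na(ms_a) && !is.na(ms_b)) (ms_a - ms_b) / ncp else NA_real_
  c(ss_a = ss_a, ss_b = ss_b, ss_c = ss_wi,
    df_a = df_a, df_b = df_b, df_c = df_c,
    sig_a = sig_a, sig_b = sig_b, sig_c = sig_c)
}

#' Hierarchical AMOVA on gene-copy mismatch distances
#'
#' Partitions the molecular variance among colonies, among individuals
#' within colonies, and within individuals, using the allele-mismatch
#' distance (0/1 per locus, summed over loci) between gene copies; this is
#' the F_ST-analogue metric, not the allele-size (R_ST) one. Variance
#' components follow the nested-ANOVA expectations with unequal colony
#' sizes; loci are combined by summing components. Phi-statistics and
#' permutation p-values (individuals permuted among colonies for the
#' among-colony component; gene copies permuted among individuals within
#' colonies for the within-colony structure) are reported.
#'
#' @param gt A genotype table.
#' @param n_perm Permutations (0 = none).
#' @param seed Optional seed.
#' @return Object of class `amova`: `components` tibble (sigma, df, SS,
#'   percent), `phi` (phi_ST, phi_IS, phi_IT), `p_among_colonies`,
#'   `p_within_colonies`.
#' @export
amova <- function(gt, n_perm = 99, seed = NULL) {
  la <- .locus_arrays(gt)
  col_idx <- match(la$colony, unique(la$colony))
  compute <- function(arrs, ci) {
    pieces <- vapply(arrs, function(m) .amova_locus(m[, 1], m[, 2], ci),
                     numeric(9))
    rowSums(pieces, na.rm = TRUE)
  }
  obs <- compute(la$arr, col_idx)
  sig <- obs[c("sig_a", "sig_b", "sig_c")]
  tot <- sum(sig)
  phi_st <- sig[1] / tot
  phi_is <- sig[2] / (sig[2] + sig[3])
  phi_it <- (sig[1] + sig[2]) / tot
  p_a <- NA_real_; p_w <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    hits_a <- 0L; hits_w <- 0L
    for (b in seq_len(n_perm)) {
      ci_p <- sample(col_idx)
      pa <- compute(la$arr, ci_p)
      if (pa["sig_a"] >= sig[1]) hits_a <- hits_a + 1L
      arrs_w <- lapply(la$arr, function(m) {
        out <- m
        for (ck in unique(col_idx)) {
          sel <- which(col_idx == ck & !is.na(m[, 1]))
          if (length(sel) < 2) next
          copies <- sample(c(m[sel, 1], m[sel, 2]))
          out[sel, 1] <- copies[seq_along(sel)]
          out[sel, 2] <- copies[length(sel) + seq_along(sel)]
        }
        out
      })
      pw <- compute(arrs_w, col_idx)
      if (pw["sig_b"] >= sig[2]) hits_w <- hits_w + 1L
    }
    p_a <- (1 + hits_a) / (1 + n_perm)
    p_w <- (1 + hits_w) / (1 + n_perm)
  }
  components <- tibble::tibble(
    level = c("among_colonies", "among_individuals_within_colonies",
              "within_individuals"),
    ss = unname(obs[c("ss_a", "ss_b", "ss_c")]),
    df = unname(obs[c("df_a", "df_b", "df_c")]) / length(la$arr),
    sigma = unname(sig),
    percent = 100 * unname(sig) / tot)
  structure(list(components = components,
                 phi = list(phi_st = unname(phi_st), phi_is = unname(phi_is),
                            phi_it = unname(phi_it)),
                 p_among_colonies = p_a, p_within_colonies = p_w,
                 n_perm = n_perm),
            class = "amova")
}
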