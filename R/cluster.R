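# internal: genotype table -> integer allele-index matrix (n x 2L) plus
# per-locus allele dictionaries
.geno_matrix <- function(gt) {
  loci <- loci_of(gt)
  inds <- unique(gt$individual_id)
  dicts <- lapply(loci, function(lc) {
    d <- gt[gt$locus == lc, ]
    sort(unique(c(d$allele_1, d$allele_2)))
  })
  names(dicts) <- loci
  m <- matrix(0L, nrow = length(inds), ncol = 2 * length(loci))
  for (l in seq_along(loci)) {
    d <- gt[gt$locus == loci[l], ]
    i <- match(d$individual_id, inds)
    a1 <- match(d$allele_1, dicts[[l]]); a1[is.na(a1)] <- 0L
    a2 <- match(d$allele_2, dicts[[l]]); a2[is.na(a2)] <- 0L
    m[i, 2 * l - 1] <- a1
    m[i, 2 * l] <- a2
  }
  rownames(m) <- inds
  list(m = m, dicts = dicts,
       colony = gt$colony_id[match(inds, gt$individual_id)])
}

#' Admixture-model Bayesian clustering by Gibbs sampling
#'
#' The standard admixture model: each cluster is a panmictic unit with its
#' own allele frequencies (flat Dirichlet prior); each individual has
#' admixture proportions `q` (Dirichlet(alpha) prior, alpha fixed); the
#' origin of every allele copy is updated conditionally. The per-sweep
#' log-likelihood is recorded after burn-in and summarised as
#' `Lhat = mean(lnL) - var(lnL) / 2`, the usual model-choice estimator for
#' this sampler. Intended for one-individual-per-colony datasets so that
#' within-colony relatedness does not masquerade as structure.
#'
#' @param gt A genotype table (typically one worker per colony, see
#'   [make_resamples()]).
#' @param k Number of clusters (>= 1).
#' @param burn_in,sweeps Burn-in and retained MCMC sweeps. Defaults are the
#'   package's desk-scale settings; survey-scale runs use 50000 / 100000.
#' @param alpha_prior Fixed Dirichlet parameter of the admixture prior.
#' @param seed Optional seed.
#' @return Object of class `admix_fit`: `k`, `q` (individuals x k, rows sum
#'   to 1), `p` (list of per-locus cluster allele frequency matrices),
#'   `lnl` trace, `lhat`, `settings`.
#' @export
gibbs_admixture <- function(gt, k, burn_in = 5000, sweeps = 10000,
                            alpha_prior = 1, seed = NULL) {
  if (k < 1) stop("k must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  gm <- .geno_matrix(gt)
  n_alleles <- vapply(gm$dicts, length, integer(1))
  res <- gibbs_admixture_cpp(gm$m, as.integer(n_alleles), as.integer(k),
                             as.integer(burn_in), as.integer(sweeps),
                             alpha_prior)
  q <- res$q_mean
  rownames(q) <- rownames(gm$m)
  colnames(q) <- paste0("cluster", seq_len(k))
  off <- cumsum(c(0, n_alleles))
  p <- lapply(seq_along(gm$dicts), function(l) {
    sub <- res$p_mean[, (off[l] + 1):off[l + 1], drop = FALSE]
    colnames(sub) <- as.character(gm$dicts[[l]])
    rownames(sub) <- paste0("cluster", seq_len(k))
    sub
  })
  names(p) <- names(gm$dicts)
  lnl <- res$lnl
  structure(list(k = k, q = q, p = p, lnl = lnl,
                 lhat = mean(lnl) - var(lnl) / 2,
                 colony = gm$colony,
                 settings = list(burn_in = burn_in, sweeps = sweeps,
                                 alpha_prior = alpha_prior, seed = seed)),
            class = "admix_fit")
}

#' Evanno Delta-K model selection
#'
#' For replicate runs at consecutive K, `DeltaK(K) = |mean L(K-1) -
#' 2 mean L(K) + mean L(K+1)| / sd(L(K))`: the absolute second difference of
#' the mean model log-likelihood estimator, normalised by the
#' between-replicate standard deviation. Delta-K is defined only at
#' interior K with positive sd; the selected K maximises it. A log-
#' likelihood exactly linear in K leaves every second difference at zero
#' and no K is selected.
#'
#' @param lhat_tbl Tibble with columns `k`, `replicate`, `lhat` (the
#'   `lhat` of each [gibbs_admixture()] run).
#' @return Object of class `deltak`: `table` (per-K mean, sd, delta_k) and
#'   `selected_k` (`NA` when undefined or degenerate).
#' @export
evanno_deltak <- function(lhat_tbl) {
  stopifnot(all(c("k", "replicate", "lhat") %in% names(lhat_tbl)))
  s <- dplyr::summarise(dplyr::group_by(lhat_tbl, k = .data$k),
                        mean_l = mean(.data$lhat),
                        sd_l = sd(.data$lhat),
                        n_rep = dplyr::n(), .groups = "drop")
  s <- dplyr::arrange(s, .data$k)
  if (nrow(s) < 3) stop("Delta-K needs at least 3 consecutive K values")
  if (any(diff(s$k) != 1)) stop("K values must be consecutive")
  if (any(s$n_rep < 2)) stop("Delta-K needs >= 2 replicates per K")
  dk <- rep(NA_real_, nrow(s))
  for (i in 2:(nrow(s) - 1)) {
    if (is.na(s$sd_l[i]) || s$sd_l[i] == 0) next
    dk[i] <- abs(s$mean_l[i - 1] - 2 * s$mean_l[i] + s$mean_l[i + 1]) / s$sd_l[i]
  }
  s$delta_k <- dk
  selected <- if (all(is.na(dk)) || all(dk[!is.na(dk)] == 0)) NA_integer_ else
    s$k[which.max(dk)]
  structure(list(table = s, selected_k = selected), class = "deltak")
}

# internal: greedy cluster matching of run `fit` onto `ref` by correlation
# of concatenated allele-frequency vectors; returns the permutation such
# that fit cluster perm[k] corresponds to ref cluster k
.match_clusters <- function(ref, fit) {
  k <- ref$k
  # align allele dictionaries: runs on different resamples can observe
  # different allele sets at a locus; absent alleles have frequency 0
  loci <- names(ref$p)
  union_alleles <- lapply(loci, function(lc) {
    union(colnames(ref$p[[lc]]), colnames(fit$p[[lc]]))
  })
  fvec <- function(f, j) {
    unlist(lapply(seq_along(loci), function(li) {
      m <- f$p[[loci[li]]]
      v <- setNames(rep(0, length(union_alleles[[li]])), union_alleles[[li]])
      v[colnames(m)] <- m[j, ]
      v
    }))
  }
  s <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      a <- fvec(ref, i); b <- fvec(fit, j)
      s[i, j] <- if (sd(a) == 0 || sd(b) == 0) -sum((a - b)^2) else cor(a, b)
    }
  }
  perm <- integer(k)
  avail_i <- seq_len(k); avail_j <- seq_len(k)
  for (step in seq_len(k)) {
    sub <- s[avail_i, avail_j, drop = FALSE]
    best <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    perm[avail_i[best[1]]] <- avail_j[best[2]]
    avail_i <- avail_i[-best[1]]
    avail_j <- avail_j[-best[2]]
  }
  perm
}

#' Align replicate clustering runs and summarise assignments
#'
#' Cluster labels are arbitrary within each MCMC run; replicate runs are
#' aligned to the first by greedy matching of their cluster allele-
#' frequency vectors (highest correlation first), then summarised as the
#' per-individual mean admixture and modal cluster.
#'
#' @param runs List of [gibbs_admixture()] fits with equal `k` over the
#'   same individuals.
#' @return List `q_mean` (consensus admixture matrix), `assignments`
#'   (tibble `individual_id`, `colony_id`, `cluster`, `max_q`), `perms`.
#' @export
align_and_summarize <- function(runs) {
  if (length(runs) == 0) stop("no runs to align")
  k <- runs[[1]]$k
  if (!all(vapply(runs, function(r) r$k, numeric(1)) == k)) {
    stop("runs disagree on K")
  }
  perms <- vector("list", length(runs))
  perms[[1]] <- seq_len(k)
  q_acc <- runs[[1]]$q
  for (j in seq_along(runs)[-1]) {
    perm <- .match_clusters(runs[[1]], runs[[j]])
    perms[[j]] <- perm
    q_acc <- q_acc + runs[[j]]$q[, perm, drop = FALSE]
  }
  q_mean <- q_acc / length(runs)
  modal <- max.col(q_mean, ties.method = "first")
  assignments <- tibble::tibble(
    individual_id = rownames(q_mean),
    colony_id = runs[[1]]$colony,
    cluster = paste0("cluster", modal),
    max_q = q_mean[cbind(seq_len(nrow(q_mean)), modal)])
  list(q_mean = q_mean, assignments = assignments, perms = perms)
}
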