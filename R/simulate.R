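#' Simulation configuration
#'
#' Describes a synthetic study: clustered allele frequencies at a target
#' divergence, colony pedigrees (simple / extended / mixed families), a
#' spatial layout and colony-level mtDNA haplotypes. Defaults emulate a
#' regional social-insect survey: 52 colonies of 10 workers genotyped at 6
#' microsatellite loci with allele counts 13, 3, 3, 2, 3, 4, two spatial
#' clusters diverged at theta = 0.14, and a simple/extended family mixture
#' of 38.5% / 61.5%.
#'
#' @param n_clusters Number of genetic clusters.
#' @param colonies_per_cluster Integer vector (recycled) of colonies per
#'   cluster; defaults to 27 and 25.
#' @param workers_per_colony Workers sampled per colony.
#' @param allele_template Alleles per locus (length = number of loci).
#' @param theta Target F_ST-like divergence among clusters, in (0, 1).
#' @param family_mix Proportions of simple/extended/mixed colonies (sums to 1).
#' @param neotenic_g Generations of within-colony full-sib (neotenic)
#'   succession for extended families; `g = 0` degenerates to a simple family.
#' @param neotenic_pairs Sib pairs breeding in the final neotenic generation
#'   of extended families (see [sim_colony()]).
#' @param founders_m Number of unrelated founders in mixed families (>= 3).
#' @param layout `"clustered"` (Gaussian scatter around cluster centres) or
#'   `"gradient"` (colonies on a line with a frequency cline, for
#'   isolation-by-distance checks).
#' @param cluster_spread Standard deviation (m) of colony scatter around its
#'   cluster centre.
#' @param cluster_centers Optional matrix (n_clusters x 2) of centres in
#'   meters; default spaces clusters along a 395-km north-south axis.
#' @param haplotype_freqs Optional matrix (n_clusters x n_haplotypes) of
#'   per-cluster mtDNA haplotype frequencies; default gives a northern
#'   HT1/HT2 mix and adds the third haplotype only in the last (southern)
#'   cluster.
#' @param seed Root seed; every colony consumes an independent child stream
#'   derived from it, so changing the colony count does not reshuffle
#'   earlier colonies.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_clusters = 2,
                       colonies_per_cluster = c(27, 25),
                       workers_per_colony = 10,
                       allele_template = c(13, 3, 3, 2, 3, 4),
                       theta = 0.14,
                       family_mix = c(simple = 0.385, extended = 0.615, mixed = 0),
                       neotenic_g = 3,
                       neotenic_pairs = 3,
                       founders_m = 4,
                       layout = c("clustered", "gradient"),
                       cluster_spread = 30000,
                       cluster_centers = NULL,
                       haplotype_freqs = NULL,
                       seed = 1) {
  layout <- match.arg(layout)
  if (theta <= 0 || theta >= 1) stop("theta must lie strictly in (0, 1)")
  if (abs(sum(family_mix) - 1) > 1e-9) stop("family_mix must sum to 1")
  if (length(family_mix) != 3) stop("family_mix needs simple/extended/mixed proportions")
  if (founders_m < 3) stop("mixed families need founders_m >= 3")
  colonies_per_cluster <- rep_len(as.integer(colonies_per_cluster), n_clusters)
  if (is.null(cluster_centers)) {
    cluster_centers <- cbind(
      x = rep(0, n_clusters),
      y = seq(395000, 0, length.out = max(n_clusters, 2))[seq_len(n_clusters)])
  }
  if (is.null(haplotype_freqs)) {
    haplotype_freqs <- matrix(rep(c(0.65, 0.35, 0), n_clusters),
                              nrow = n_clusters, byrow = TRUE,
                              dimnames = list(NULL, c("HT1", "HT2", "HT3")))
    haplotype_freqs[n_clusters, ] <- c(0.50, 0.20, 0.30)
  }
  structure(list(
    n_clusters = n_clusters, colonies_per_cluster = colonies_per_cluster,
    workers_per_colony = workers_per_colony, allele_template = allele_template,
    theta = theta, family_mix = setNames(as.numeric(family_mix),
                                         c("simple", "extended", "mixed")),
    neotenic_g = neotenic_g, neotenic_pairs = neotenic_pairs,
    founders_m = founders_m, layout = layout,
    cluster_spread = cluster_spread, cluster_centers = cluster_centers,
    haplotype_freqs = haplotype_freqs, seed = as.integer(seed)),
    class = "sim_config")
}

# internal: one Dirichlet draw
.rdirichlet <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

# internal: child seed for colony k under root seed (kept below 2^31)
.child_seed <- function(root, k) {
  as.integer((as.numeric(root) * 48271 + 7919 * as.numeric(k)) %% 2147483629) + 1L
}

#' Clustered allele frequencies under the Balding-Nichols model
#'
#' Each cluster's per-locus frequency vector is drawn from a Dirichlet with
#' mean equal to the ancestral frequencies and concentration
#' `(1 - theta) / theta`, so that across clusters the frequency of an allele
#' with ancestral frequency p has variance `theta * p * (1 - p)` and a
#' multi-locus F_ST estimated over clusters recovers theta.
#'
#' With few clusters and loci, the divergence realised by one draw scatters
#' widely around theta (the between-cluster variance has only `n_clusters -
#' 1` degrees of freedom per allele), while the study design calls for
#' clusters *at* the target divergence. With `calibrate = TRUE` (the
#' default) the draw is therefore repeated until the realised parametric
#' divergence -- `sum(s2) / (sum(s2) / 2 + sum(pbar * (1 - pbar)))` over all loci and
#' alleles, with `s2` the between-cluster sample variance (this ratio is
#' the large-sample limit of the multi-locus Weir-Cockerham estimator for
#' the drawn frequencies) -- lies within
#' `tol` (relative) of theta, keeping the closest draw if the cap on
#' attempts is hit.
#'
#' @param ancestral List of per-locus ancestral frequency vectors.
#' @param theta Divergence parameter in (0, 1).
#' @param n_clusters Number of clusters to draw.
#' @param seed Optional seed.
#' @param calibrate Reject-and-redraw until the realised divergence matches
#'   theta (see Details).
#' @param tol Relative tolerance of the calibration band.
#' @param max_tries Attempt cap for the calibration loop.
#' @return A list (one element per cluster) of lists of per-locus frequency
#'   vectors, with attribute `realized_divergence`.
#' @export
sim_cluster_freqs <- function(ancestral, theta, n_clusters, seed = NULL,
                              calibrate = TRUE, tol = 0.05, max_tries = 500) {
  if (theta <= 0 || theta >= 1) stop("theta must lie strictly in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  scale <- (1 - theta) / theta
  draw <- function() {
    lapply(seq_len(n_clusters), function(k) {
      lapply(ancestral, function(p) {
        f <- .rdirichlet(p * scale)
        names(f) <- names(p)
        f
      })
    })
  }
  realized <- function(cf) {
    num <- 0; den <- 0
    for (l in seq_along(ancestral)) {
      pm <- do.call(rbind, lapply(cf, function(cl) cl[[l]]))
      pbar <- colMeans(pm)
      num <- num + sum(colSums(sweep(pm, 2, pbar)^2) / (n_clusters - 1))
      den <- den + sum(pbar * (1 - pbar))
    }
    num / (num / 2 + den)   # large-n limit of the W&C multi-locus estimator
  }
  out <- draw()
  if (!calibrate || n_clusters < 2) {
    attr(out, "realized_divergence") <- if (n_clusters >= 2) realized(out)
      else NA_real_
    return(out)
  }
  best <- out
  best_d <- realized(out)
  for (i in seq_len(max_tries)) {
    d <- realized(out)
    if (abs(d / theta - 1) <= tol) {
      attr(out, "realized_divergence") <- d
      return(out)
    }
    if (abs(d - theta) < abs(best_d - theta)) {
      best <- out
      best_d <- d
    }
    out <- draw()
  }
  attr(best, "realized_divergence") <- best_d
  best
}

# internal: draw a founder as a (alleles, tags) pair across loci
.draw_founder <- function(freqs, tag0) {
  lapply(seq_along(freqs), function(l) {
    codes <- as.integer(names(freqs[[l]]))
    a <- sample(codes, 2, replace = TRUE, prob = freqs[[l]])
    list(alleles = a, tags = c(tag0, tag0 + 1L))
  })
}

# internal: Mendelian offspring of two tagged parents
.cross <- function(pa, pb) {
  lapply(seq_along(pa), function(l) {
    i <- sample.int(2, 1)
    j <- sample.int(2, 1)
    list(alleles = c(pa[[l]]$alleles[i], pb[[l]]$alleles[j]),
         tags = c(pa[[l]]$tags[i], pb[[l]]$tags[j]))
  })
}

#' Simulate one colony
#'
#' Workers are produced by gene dropping from tagged founder alleles, so the
#' realised identity-by-descent inbreeding of every worker is observable.
#' `simple`: two unrelated founders drawn under Hardy-Weinberg from the local
#' frequencies; workers are their direct offspring. `extended`: a founder
#' pair followed by `g` generations in which two full sibs are chosen as the
#' next (neotenic) breeding pair; workers are offspring of the generation-g
#' pair, whose expected inbreeding follows the full-sib recurrence
#' `F_t = (1 + 2 F_(t-1) + F_(t-2)) / 4`. `mixed`: `founders_m` unrelated
#' founders; each worker's two parents are a uniformly drawn distinct pair.
#'
#' @param family_type `"simple"`, `"extended"` or `"mixed"`.
#' @param local_freqs List of per-locus allele frequency vectors (named by
#'   allele code).
#' @param workers_per_colony Number of workers to emit.
#' @param g Neotenic generations (extended families).
#' @param founders_m Number of founders (mixed families).
#' @param neotenic_pairs Number of sib pairs breeding in the final neotenic
#'   generation of an extended family. Real colonies hold many functional
#'   neotenics; several simultaneous sib pairs give worker genotype
#'   distributions that depart from any single parental pair (the signature
#'   extended-family classifiers test for) while leaving the expected
#'   worker inbreeding exactly on the full-sib recurrence, because all
#'   members of a brood are full sibs with identical kinship.
#' @return A list with `genotypes` (tibble `worker`, `locus`, `allele_1`,
#'   `allele_2`), `truth` (one-row tibble with the true family type, `g`,
#'   expected pedigree F and realised IBD F) .
#' @export
sim_colony <- function(family_type, local_freqs, workers_per_colony = 10,
                       g = 3, founders_m = 4, neotenic_pairs = 3) {
  if (!family_type %in% c("simple", "extended", "mixed")) {
    stop("unknown family type: ", family_type)
  }
  L <- length(local_freqs)
  locus_names <- names(local_freqs)
  if (is.null(locus_names)) locus_names <- paste0("loc", seq_len(L))

  workers <- vector("list", workers_per_colony)
  if (family_type == "mixed") {
    founders <- lapply(seq_len(founders_m),
                       function(i) .draw_founder(local_freqs, 2L * (i - 1L) + 1L))
    for (w in seq_len(workers_per_colony)) {
      pr <- sample.int(founders_m, 2, replace = FALSE)
      workers[[w]] <- .cross(founders[[pr[1]]], founders[[pr[2]]])
    }
    f_expected <- 0
  } else {
    pair <- list(.draw_founder(local_freqs, 1L), .draw_founder(local_freqs, 3L))
    g_eff <- if (family_type == "simple") 0L else as.integer(g)
    brood_n <- max(4L, workers_per_colony)
    if (g_eff > 0) {
      # single-pair succession up to the final neotenic generation
      brood <- lapply(seq_len(brood_n), function(i) .cross(pair[[1]], pair[[2]]))
      if (g_eff > 1) {
        for (t in 2:g_eff) {
          pick <- sample.int(brood_n, 2, replace = FALSE)
          pair <- brood[pick]
          brood <- lapply(seq_len(brood_n),
                          function(i) .cross(pair[[1]], pair[[2]]))
        }
      }
      # several sib pairs of the final brood breed simultaneously
      breeding <- lapply(seq_len(neotenic_pairs), function(j) {
        pick <- sample.int(brood_n, 2, replace = FALSE)
        brood[pick]
      })
      for (w in seq_len(workers_per_colony)) {
        pr <- breeding[[sample.int(neotenic_pairs, 1)]]
        workers[[w]] <- .cross(pr[[1]], pr[[2]])
      }
    } else {
      for (w in seq_len(workers_per_colony)) {
        workers[[w]] <- .cross(pair[[1]], pair[[2]])
      }
    }
    f_expected <- pedigree_f_recurrence(g_eff)
  }

  a1 <- matrix(0L, workers_per_colony, L)
  a2 <- matrix(0L, workers_per_colony, L)
  ibd <- matrix(FALSE, workers_per_colony, L)
  for (w in seq_len(workers_per_colony)) {
    for (l in seq_len(L)) {
      a1[w, l] <- workers[[w]][[l]]$alleles[1]
      a2[w, l] <- workers[[w]][[l]]$alleles[2]
      ibd[w, l] <- workers[[w]][[l]]$tags[1] == workers[[w]][[l]]$tags[2]
    }
  }
  genotypes <- tibble::tibble(
    worker = rep(seq_len(workers_per_colony), each = L),
    locus = rep(locus_names, workers_per_colony),
    allele_1 = as.integer(t(a1)), allele_2 = as.integer(t(a2)))
  truth <- tibble::tibble(
    family_type = family_type,
    g = if (family_type == "extended") as.integer(g) else 0L,
    pedigree_f = f_expected,
    realized_f = mean(ibd))
  list(genotypes = genotypes, truth = truth)
}

#' Expected inbreeding after g generations of full-sib mating
#'
#' Evaluates `F_t = (1 + 2 F_(t-1) + F_(t-2)) / 4` with `F_0 = F_(-1) = 0`,
#' giving 0.25, 0.375, 0.5, ... for g = 1, 2, 3, ...
#'
#' @param g Number of generations (>= 0).
#' @return The expected pedigree inbreeding coefficient.
#' @export
pedigree_f_recurrence <- function(g) {
  if (g <= 0) return(0)
  f <- numeric(g + 2)  # f[1] = F_{-1}, f[2] = F_0
  for (t in seq_len(g)) f[t + 2] <- (1 + 2 * f[t + 1] + f[t]) / 4
  f[g + 2]
}

#' Simulate a full study dataset
#'
#' Draws cluster allele frequencies under the Balding-Nichols model, places
#' colonies per the configured layout, simulates each colony's pedigree and
#' workers, and assigns colony-level mtDNA haplotypes from the cluster's
#' haplotype distribution. Fully reproducible from the root seed; each
#' colony consumes an independent child stream.
#'
#' @param config A [sim_config()].
#' @return A list with `gt` (a [gen_tbl()]), `geo` (colony metadata tibble
#'   with `colony_id`, `x`, `y`, `haplotype`, `cluster`) and `truth` (per
#'   colony: true family type, `g`, expected and realised inbreeding).
#' @export
sim_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- length(config$allele_template)
  locus_names <- paste0("loc", seq_len(L))
  ancestral <- lapply(seq_len(L), function(l) {
    k <- config$allele_template[l]
    p <- .rdirichlet(rep(1, k))
    names(p) <- as.character(100 + 3 * seq_len(k))  # fragment-size-like codes
    p
  })
  names(ancestral) <- locus_names
  cluster_freqs <- sim_cluster_freqs(ancestral, config$theta, config$n_clusters)
  for (k in seq_len(config$n_clusters)) names(cluster_freqs[[k]]) <- locus_names

  n_col <- sum(config$colonies_per_cluster)
  cluster_of <- rep(seq_len(config$n_clusters), config$colonies_per_cluster)
  total_span <- 395000

  geno_list <- vector("list", n_col)
  geo_list <- vector("list", n_col)
  truth_list <- vector("list", n_col)
  for (i in seq_len(n_col)) {
    set.seed(.child_seed(config$seed, i))
    k <- cluster_of[i]
    if (config$layout == "gradient") {
      t_frac <- (i - 1) / max(n_col - 1, 1)
      xy <- c(0, t_frac * total_span)
      k1 <- 1L
      k2 <- min(2L, config$n_clusters)
      freqs <- lapply(seq_len(L), function(l) {
        f <- (1 - t_frac) * cluster_freqs[[k1]][[l]] +
          t_frac * cluster_freqs[[k2]][[l]]
        f / sum(f)
      })
      names(freqs) <- locus_names
    } else {
      xy <- config$cluster_centers[k, ] + stats::rnorm(2, 0, config$cluster_spread)
      freqs <- cluster_freqs[[k]]
    }
    fam <- sample(c("simple", "extended", "mixed"), 1, prob = config$family_mix)
    colony <- sim_colony(fam, freqs, config$workers_per_colony,
                         g = config$neotenic_g, founders_m = config$founders_m,
                         neotenic_pairs = config$neotenic_pairs)
    hap <- sample(colnames(config$haplotype_freqs), 1,
                  prob = config$haplotype_freqs[k, ])
    cid <- sprintf("c%02d", i)
    geno_list[[i]] <- dplyr::mutate(
      colony$genotypes,
      individual_id = sprintf("%s_w%02d", cid, .data$worker),
      colony_id = cid)[, c("individual_id", "colony_id", "locus",
                           "allele_1", "allele_2")]
    geo_list[[i]] <- tibble::tibble(colony_id = cid, x = xy[1], y = xy[2],
                                    haplotype = hap, cluster = k)
    truth_list[[i]] <- dplyr::mutate(colony$truth, colony_id = cid,
                                     cluster = k, .before = 1)
  }
  gt <- gen_tbl(dplyr::bind_rows(geno_list), loci = locus_names)
  list(gt = gt, geo = dplyr::bind_rows(geo_list),
       truth = dplyr::bind_rows(truth_list))
}

#' Write a simulated dataset to disk
#'
#' Emits the GENEPOP genotype file, the colony metadata CSV and a truth CSV
#' (`colony_id`, `true_family_type`, `g`, `mean_pedigree_F`).
#'
#' @param sim Output of [sim_dataset()].
#' @param dir Output directory (created if needed).
#' @param stem File name stem.
#' @return Invisibly, the three file paths.
#' @export
write_sim_dataset <- function(sim, dir, stem = "sim") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gp <- file.path(dir, paste0(stem, ".gen"))
  cc <- file.path(dir, paste0(stem, "_colonies.csv"))
  tc <- file.path(dir, paste0(stem, "_truth.csv"))
  write_genepop(sim$gt, gp, title = "synthetic colony dataset")
  write_colony_table(sim$geo[, c("colony_id", "x", "y", "haplotype")], cc)
  truth <- data.frame(colony_id = sim$truth$colony_id,
                      true_family_type = sim$truth$family_type,
                      g = sim$truth$g,
                      mean_pedigree_F = sim$truth$pedigree_f)
  write.csv(truth, tc, row.names = FALSE, quote = FALSE)
  invisible(c(genepop = gp, colonies = cc, truth = tc))
}
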