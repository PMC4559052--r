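#' One-individual-per-colony resampling plan
#'
#' Within-colony relatedness biases sample-level statistics, so
#' population-level analyses run on datasets holding one randomly chosen
#' worker per colony, replicated (20 times by convention).
#'
#' @param gt A genotype table.
#' @param n_replicates Number of resampled datasets.
#' @param seed Seed for the uniform within-colony choices.
#' @return Tibble `replicate`, `colony_id`, `individual_id`.
#' @export
resample_plan <- function(gt, n_replicates = 20, seed = 1) {
  set.seed(seed)
  byc <- split(unique(gt[, c("individual_id", "colony_id")])$individual_id,
               unique(gt[, c("individual_id", "colony_id")])$colony_id)
  if (any(lengths(byc) == 0)) stop("empty colony in dataset")
  cols <- unique(gt$colony_id)
  out <- lapply(seq_len(n_replicates), function(r) {
    tibble::tibble(
      replicate = r, colony_id = cols,
      individual_id = vapply(cols, function(cid) {
        ids <- byc[[cid]]
        ids[sample.int(length(ids), 1)]
      }, character(1)))
  })
  dplyr::bind_rows(out)
}

#' Materialise one-per-colony resampled datasets
#'
#' @param gt A genotype table.
#' @param n_replicates Number of replicates (default 20).
#' @param seed Seed.
#' @param plan Optional precomputed [resample_plan()].
#' @return List of genotype tables, one individual per colony each.
#' @export
make_resamples <- function(gt, n_replicates = 20, seed = 1, plan = NULL) {
  if (is.null(plan)) plan <- resample_plan(gt, n_replicates, seed)
  lapply(split(plan, plan$replicate), function(p) {
    gen_tbl(gt[gt$individual_id %in% p$individual_id, ], loci = loci_of(gt))
  })
}

#' Aggregate per-replicate test results
#'
#' @param results Tibble with columns `replicate`, `locus`, `p_value` and
#'   optionally `estimate`.
#' @param alpha Significance level.
#' @return Per-locus tibble: fraction of replicates significant, mean and
#'   range of the estimate when present.
#' @export
aggregate_replicates <- function(results, alpha = 0.05) {
  g <- dplyr::group_by(results, locus = .data$locus)
  if ("estimate" %in% names(results)) {
    dplyr::summarise(g, n_replicates = dplyr::n(),
                     frac_significant = mean(.data$p_value < alpha),
                     mean_estimate = mean(.data$estimate, na.rm = TRUE),
                     min_estimate = suppressWarnings(min(.data$estimate, na.rm = TRUE)),
                     max_estimate = suppressWarnings(max(.data$estimate, na.rm = TRUE)),
                     .groups = "drop")
  } else {
    dplyr::summarise(g, n_replicates = dplyr::n(),
                     frac_significant = mean(.data$p_value < alpha),
                     .groups = "drop")
  }
}

#' Study configuration
#'
#' Bundles every setting of the end-to-end workflow. The survey-scale
#' convention is 20 resamples, K = 10 nearest neighbours, 999 Mantel and
#' 9999 sPCA permutations, 1000 F_ST randomizations and alpha 0.05;
#' MCMC defaults are the desk-scale 5000 / 10000 (survey scale:
#' 50000 / 100000).
#'
#' @param sim A [sim_config()] for synthetic mode (ignored when `gt` given).
#' @param gt,geo Optional observed genotype table and colony metadata.
#' @param n_resamples One-per-colony replicates.
#' @param knn_k Nearest neighbours of the connection network.
#' @param mantel_perm,spca_perm,fst_perm,amova_perm Permutation counts.
#' @param hwe_mc,hwe_enum_bound Heterozygote-deficiency test settings.
#' @param ld_reps LD permutations per locus pair.
#' @param alpha Significance level.
#' @param k_range Candidate cluster numbers (consecutive, for Delta-K).
#' @param cluster_replicates Clustering runs (each on its own resample).
#' @param burn_in,sweeps MCMC settings per run.
#' @param seed Root seed for the whole study.
#' @return A `study_config` list.
#' @export
study_config <- function(sim = sim_config(), gt = NULL, geo = NULL,
                         n_resamples = 20, knn_k = 10,
                         mantel_perm = 999, spca_perm = 9999,
                         fst_perm = 1000, amova_perm = 99,
                         hwe_mc = 10000, hwe_enum_bound = 20000,
                         ld_reps = 999, alpha = 0.05,
                         k_range = 1:4, cluster_replicates = 5,
                         burn_in = 5000, sweeps = 10000, seed = 1) {
  structure(as.list(environment()), class = "study_config")
}

# internal: run one stage, capturing failures into the report
.run_stage <- function(report, name, expr) {
  res <- tryCatch(expr, error = function(e) {
    structure(list(stage = name, message = conditionMessage(e)),
              class = "stage_error")
  })
  report[[name]] <- res
  report
}

#' Run the full study workflow
#'
#' Sequences the analyses end to end: simulate or ingest the dataset;
#' build 20 one-per-colony resamples; per-replicate heterozygote-
#' deficiency tests, F_IS and LD scans, aggregated across replicates;
#' AMOVA on all workers; isolation-by-distance (Edwards' distances, Mantel
#' test, kernel density) per replicate; sPCA on colony allele frequencies
#' with global/local tests; admixture clustering over `k_range` with one
#' resample per replicate run and Evanno Delta-K selection; per-cluster
#' F_IS / heterozygote-deficiency / pairwise F_ST / within-cluster Mantel;
#' and colony family classification with per-cluster proportions. Stage
#' failures are recorded by stage name and the partial report preserved.
#'
#' @param config A [study_config()].
#' @return Object of class `study_report` (a named list of stage results
#'   plus `provenance`).
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  report <- list()
  seed <- config$seed

  if (is.null(config$gt)) {
    config$sim$seed <- seed
    sim <- sim_dataset(config$sim)
    gt <- sim$gt; geo <- sim$geo
    report$truth <- sim$truth
  } else {
    gt <- config$gt; geo <- config$geo
  }
  report$data <- list(n_colonies = length(unique(gt$colony_id)),
                      n_individuals = length(unique(gt$individual_id)),
                      n_loci = length(loci_of(gt)))

  resamples <- make_resamples(gt, config$n_resamples, seed = seed + 101)
  report$resamples <- list(n = length(resamples))

  report <- .run_stage(report, "replicate_stats", {
    rows <- lapply(seq_along(resamples), function(r) {
      rg <- resamples[[r]]
      hwe <- hwe_deficiency_test(rg, mc_reps = config$hwe_mc,
                                 enum_bound = config$hwe_enum_bound,
                                 seed = seed + 200 + r)
      fis <- wc_fstats(rg, group = NULL, n_perm = 0)
      ld <- ld_scan(rg, mc_reps = config$ld_reps, alpha = config$alpha,
                    seed = seed + 300 + r)
      list(hwe = dplyr::mutate(hwe, replicate = r),
           fis = tibble::tibble(replicate = r,
                                locus = c(fis$per_locus$locus, "all"),
                                fis = c(fis$per_locus$fis, fis$overall$fis)),
           n_ld_significant = sum(ld$significant))
    })
    hwe_tbl <- dplyr::bind_rows(lapply(rows, `[[`, "hwe"))
    fis_tbl <- dplyr::bind_rows(lapply(rows, `[[`, "fis"))
    list(hwe = hwe_tbl, fis = fis_tbl,
         ld_significant = vapply(rows, `[[`, numeric(1), "n_ld_significant"),
         hwe_aggregate = aggregate_replicates(
           dplyr::rename(hwe_tbl, estimate = "h_obs_count"), config$alpha),
         fis_summary = dplyr::summarise(
           dplyr::group_by(fis_tbl, locus = .data$locus),
           mean_fis = mean(.data$fis, na.rm = TRUE),
           min_fis = min(.data$fis, na.rm = TRUE),
           max_fis = max(.data$fis, na.rm = TRUE), .groups = "drop"))
  })

  report <- .run_stage(report, "amova", {
    amova(gt, n_perm = config$amova_perm, seed = seed + 400)
  })

  report <- .run_stage(report, "ibd", {
    d_geo <- as.matrix(stats::dist(cbind(geo$x, geo$y)))
    per_rep <- lapply(seq_along(resamples), function(r) {
      fr <- colony_allele_frequencies(resamples[[r]])
      d_gen <- edwards_dist_matrix(fr)
      ord <- match(geo$colony_id, rownames(d_gen))
      mt <- mantel_test(d_gen[ord, ord], d_geo,
                        n_perm = config$mantel_perm, seed = seed + 500 + r)
      list(d_gen = d_gen[ord, ord], r = mt$r, p_value = mt$p_value)
    })
    dens <- ibd_density(per_rep[[1]]$d_gen, d_geo)
    list(per_replicate = tibble::tibble(
      replicate = seq_along(per_rep),
      r = vapply(per_rep, `[[`, numeric(1), "r"),
      p_value = vapply(per_rep, `[[`, numeric(1), "p_value")),
      mean_r = mean(vapply(per_rep, `[[`, numeric(1), "r")),
      frac_significant = mean(vapply(per_rep, `[[`, numeric(1), "p_value")
                              < config$alpha),
      density = dens)
  })

  report <- .run_stage(report, "spca", {
    freqs <- colony_allele_frequencies(gt)
    x <- freq_matrix(freqs)
    x <- x[geo$colony_id, , drop = FALSE]
    net <- knn_graph(geo, k = config$knn_k)
    fit <- spca(x, net)
    tests <- spca_tests(x, net, n_perm = config$spca_perm, seed = seed + 600)
    list(fit = fit, tests = tests,
         loadings = loading_report(fit, axes = 1:2, top_k = 10))
  })

  report <- .run_stage(report, "clustering", {
    runs_by_k <- list()
    lhat_rows <- list()
    for (rep_i in seq_len(config$cluster_replicates)) {
      rg <- resamples[[((rep_i - 1) %% length(resamples)) + 1]]
      for (k in config$k_range) {
        fit <- gibbs_admixture(rg, k, burn_in = config$burn_in,
                               sweeps = config$sweeps,
                               seed = seed + 700 + 17 * rep_i + k)
        lhat_rows[[length(lhat_rows) + 1]] <-
          tibble::tibble(k = k, replicate = rep_i, lhat = fit$lhat)
        key <- as.character(k)
        runs_by_k[[key]] <- c(runs_by_k[[key]], list(fit))
      }
    }
    lhat_tbl <- dplyr::bind_rows(lhat_rows)
    dk <- evanno_deltak(lhat_tbl)
    sel <- if (is.na(dk$selected_k)) config$k_range[2] else dk$selected_k
    cons <- align_and_summarize(runs_by_k[[as.character(sel)]])
    assign_tbl <- dplyr::distinct(cons$assignments[, c("colony_id", "cluster")])
    list(lhat = lhat_tbl, deltak = dk, selected_k = sel,
         consensus = cons,
         cluster_of = dplyr::rename(assign_tbl, group = "cluster"))
  })

  report <- .run_stage(report, "cluster_stats", {
    if (inherits(report$clustering, "stage_error")) stop("clustering failed")
    grp <- report$clustering$cluster_of
    rep1 <- resamples[[1]]
    fis_by <- lapply(split(grp$colony_id, grp$group), function(cids) {
      sub <- gen_tbl(rep1[rep1$colony_id %in% cids, ], loci = loci_of(gt))
      wc_fstats(sub, group = NULL, n_perm = 199)
    })
    pw <- pairwise_fst(rep1, group = grp, n_perm = config$fst_perm,
                       seed = seed + 800)
    d_geo_all <- as.matrix(stats::dist(cbind(geo$x, geo$y),
                                       diag = TRUE, upper = TRUE))
    rownames(d_geo_all) <- colnames(d_geo_all) <- geo$colony_id
    within_ibd <- lapply(split(grp$colony_id, grp$group), function(cids) {
      if (length(cids) < 5) return(NULL)
      sub <- gen_tbl(rep1[rep1$colony_id %in% cids, ], loci = loci_of(gt))
      d_gen <- edwards_dist_matrix(colony_allele_frequencies(sub))
      ids <- rownames(d_gen)
      mt <- mantel_test(d_gen, d_geo_all[ids, ids],
                        n_perm = config$mantel_perm, seed = seed + 900)
      list(r = mt$r, p_value = mt$p_value)
    })
    list(fis_by_cluster = tibble::tibble(
      cluster = names(fis_by),
      fis = vapply(fis_by, function(f) f$overall$fis, numeric(1)),
      p_value = vapply(fis_by, function(f) f$p_fis, numeric(1))),
      pairwise_fst = pw,
      within_cluster_ibd = within_ibd)
  })

  report <- .run_stage(report, "family", {
    calls <- classify_dataset(gt, alpha = config$alpha)
    grp <- if (!inherits(report$clustering, "stage_error"))
      report$clustering$cluster_of else NULL
    list(calls = calls, summary = family_summary(calls, group = grp))
  })

  report$provenance <- list(seed = seed, settings = config[
    setdiff(names(config), c("gt", "geo"))],
    package_version = as.character(utils::packageVersion("colonystruct")),
    timestamp = NULL)
  class(report) <- "study_report"
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Colony-structured population genetics study report\n")
  cat(sprintf("  %d colonies, %d individuals, %d loci\n",
              x$data$n_colonies, x$data$n_individuals, x$data$n_loci))
  if (!inherits(x$replicate_stats, "stage_error")) {
    fis <- x$replicate_stats$fis_summary
    cat(sprintf("  mean multi-locus F_IS over resamples: %.3f\n",
                fis$mean_fis[fis$locus == "all"]))
  }
  if (!inherits(x$amova, "stage_error")) {
    cat(sprintf("  AMOVA among-colony variance: %.1f%%\n",
                x$amova$components$percent[1]))
  }
  if (!inherits(x$ibd, "stage_error")) {
    cat(sprintf("  IBD Mantel mean r: %.3f (%.0f%% of replicates significant)\n",
                x$ibd$mean_r, 100 * x$ibd$frac_significant))
  }
  if (!inherits(x$spca, "stage_error")) {
    cat(sprintf("  sPCA lambda1 = %.4f (global p = %.4g)\n",
                x$spca$fit$eigenvalues[1], x$spca$tests$global$p_value))
  }
  if (!inherits(x$clustering, "stage_error")) {
    cat(sprintf("  Delta-K selected K = %s\n", x$clustering$selected_k))
  }
  if (!inherits(x$family, "stage_error")) {
    s <- x$family$summary
    s <- s[s$group == "all", ]
    cat("  family types: ",
        paste(sprintf("%s %.1f%%", s$verdict, 100 * s$proportion),
              collapse = ", "), "\n")
  }
  invisible(x)
}
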