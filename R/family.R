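#' Enumerate parental pairs compatible with observed worker genotypes
#'
#' A colony of workers descends from a single reproductive pair only if, at
#' every locus, some pair of diploid parental genotypes gives positive
#' Mendelian probability to every observed worker genotype class. This
#' enumerates all such pairs at one locus. Candidate parental genotypes are
#' built from the observed alleles plus at most one unobserved "wildcard"
#' allele per parent (wildcards, coded as negative integers, are never used
#' to explain an observed class -- they only complete a parental genotype).
#' Unobserved offspring classes never disqualify a pair: absence is
#' attributed to sampling.
#'
#' @param allele_1,allele_2 Integer vectors of worker alleles at one locus
#'   (missing genotypes removed or `NA`, which are dropped).
#' @return A tibble with one row per compatible pair: parental genotypes
#'   (`p1_a`, `p1_b`, `p2_a`, `p2_b`; negative codes are wildcards),
#'   `n_wildcards`, `loglik` (multinomial log-likelihood of the observed
#'   counts under the pair) and `dist` (list column: expected offspring
#'   class distribution, names `"a/b"`). Zero rows when no pair is
#'   compatible (e.g. more than 4 alleles, more than 4 genotype classes, or
#'   3+ homozygous classes).
#' @export
enumerate_parent_pairs <- function(allele_1, allele_2) {
  keep <- !is.na(allele_1) & !is.na(allele_2)
  a1 <- pmin(allele_1[keep], allele_2[keep])
  a2 <- pmax(allele_1[keep], allele_2[keep])
  empty <- tibble::tibble(p1_a = integer(0), p1_b = integer(0),
                          p2_a = integer(0), p2_b = integer(0),
                          n_wildcards = integer(0), loglik = numeric(0),
                          dist = list())
  if (length(a1) == 0) return(empty)
  obs_key <- paste0(a1, "/", a2)
  counts <- table(obs_key)
  obs_classes <- names(counts)
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) > 4) return(empty)

  genos_from <- function(extra) {
    pool <- c(alleles, extra)
    out <- list()
    for (i in seq_along(pool)) {
      for (j in i:length(pool)) {
        # no all-wildcard parents: they cannot transmit an observed allele
        if (pool[i] < 0 && pool[j] < 0) next
        out[[length(out) + 1L]] <- c(pool[i], pool[j])
      }
    }
    out
  }
  g1 <- genos_from(-1L)
  g2 <- genos_from(-2L)

  cross_dist <- function(p1, p2) {
    lo <- pmin(rep(p1, each = 2), rep(p2, times = 2))
    hi <- pmax(rep(p1, each = 2), rep(p2, times = 2))
    key <- paste0(lo, "/", hi)
    tapply(rep(0.25, 4), key, sum)
  }

  seen <- character(0)
  rows <- list()
  for (pa in g1) {
    for (pb in g2) {
      # canonical form: sorted genotypes, parents ordered, wildcards relabeled
      ga <- sort(pa); gb <- sort(pb)
      ord_key <- function(g) sum(ifelse(g < 0, 1e6, g) * c(2000, 1))
      if (ord_key(gb) < ord_key(ga)) { tmp <- ga; ga <- gb; gb <- tmp }
      both <- c(ga, gb)
      wc <- unique(both[both < 0])
      for (w in seq_along(wc)) both[both == wc[w]] <- -w
      ga <- both[1:2]; gb <- both[3:4]
      key <- paste(both, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      d <- cross_dist(ga, gb)
      if (!all(obs_classes %in% names(d))) next
      ll <- sum(counts * log(d[obs_classes]))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        p1_a = ga[1], p1_b = ga[2], p2_a = gb[1], p2_b = gb[2],
        n_wildcards = sum(both < 0), loglik = ll, dist = list(d))
    }
  }
  if (length(rows) == 0) return(empty)
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, dplyr::desc(.data$loglik), .data$n_wildcards,
                 ifelse(.data$p1_a < 0, 1e6, .data$p1_a),
                 ifelse(.data$p1_b < 0, 1e6, .data$p1_b),
                 ifelse(.data$p2_a < 0, 1e6, .data$p2_a),
                 ifelse(.data$p2_b < 0, 1e6, .data$p2_b))
}

# internal: G contribution of one locus under a given offspring distribution
.gtest_locus <- function(allele_1, allele_2, dist) {
  keep <- !is.na(allele_1) & !is.na(allele_2)
  key <- paste0(pmin(allele_1[keep], allele_2[keep]), "/",
                pmax(allele_1[keep], allele_2[keep]))
  counts <- table(key)
  n <- sum(counts)
  e <- n * dist
  o <- counts[names(dist)]
  o[is.na(o)] <- 0
  pos <- o > 0
  g <- 2 * sum(o[pos] * log(o[pos] / e[pos]))
  list(G = g, df = length(dist) - 1L, n = n)
}

#' Combined-locus G-test against the simple-family expectation
#'
#' For each locus the expected offspring genotype distribution under a
#' parental pair is compared with the observed counts by a multinomial
#' G-test: `G_l = 2 * sum O_g ln(O_g / E_g)` over classes with positive
#' expectation (zero observed counts contribute nothing), with
#' `df_l = (number of expected classes) - 1`. Loci are combined by summing G
#' and df; the p-value is the upper chi-square tail. When `pairs` is not
#' supplied the maximum-likelihood compatible pair per locus is used
#' (ties broken by fewer wildcards, then lexicographic order).
#'
#' @param gt_colony Genotype table rows for one colony.
#' @param pairs Optional named list (by locus) of expected offspring class
#'   distributions, as in the `dist` column of [enumerate_parent_pairs()].
#' @return A list `G`, `df`, `p_value`, `per_locus` (tibble), `best_pairs`.
#'   Errors if any locus has no compatible pair (the Mendelian screen must
#'   pass before a G-test is meaningful).
#' @export
gtest_simple_family <- function(gt_colony, pairs = NULL) {
  loci <- unique(gt_colony$locus)
  best_pairs <- list()
  per <- list()
  for (lc in loci) {
    d <- gt_colony[gt_colony$locus == lc, ]
    if (all(is.na(d$allele_1))) next
    if (is.null(pairs)) {
      cand <- enumerate_parent_pairs(d$allele_1, d$allele_2)
      if (nrow(cand) == 0) {
        stop("no compatible parental pair at locus ", lc,
             "; the Mendelian screen did not pass")
      }
      dist <- cand$dist[[1]]
      best_pairs[[lc]] <- cand[1, c("p1_a", "p1_b", "p2_a", "p2_b")]
    } else {
      dist <- pairs[[lc]]
      if (is.null(dist)) next
    }
    res <- .gtest_locus(d$allele_1, d$allele_2, dist)
    if (res$df > 0) {
      per[[lc]] <- tibble::tibble(locus = lc, G = res$G, df = res$df,
                                  n = res$n)
    }
  }
  per_locus <- if (length(per)) dplyr::bind_rows(per) else
    tibble::tibble(locus = character(0), G = numeric(0), df = integer(0),
                   n = integer(0))
  G <- sum(per_locus$G)
  df <- sum(per_locus$df)
  p <- if (df > 0) pchisq(G, df, lower.tail = FALSE) else 1
  list(G = G, df = df, p_value = p, per_locus = per_locus,
       best_pairs = best_pairs)
}

#' Classify one colony's breeding system
#'
#' Ordered decision rules on the worker genotype distribution:
#' 1. any locus with more than 4 alleles -> `mixed` (more than two unrelated
#'    reproductives must have contributed);
#' 2. any locus with no Mendelian-compatible parental pair (covers more than
#'    4 genotype classes and 3 or more homozygous classes) -> `extended`;
#' 3. combined-locus G-test p below `alpha` -> `extended`;
#' 4. otherwise `simple`.
#' Colonies with fewer than `min_workers` genotyped workers get verdict
#' `insufficient_data` rather than a silent `simple`.
#'
#' @param gt_colony Genotype table rows for one colony.
#' @param alpha Significance level of the G-test.
#' @param min_workers Minimum genotyped workers for a classification.
#' @return One-row tibble: `colony_id`, `verdict`, `rules` (comma-joined
#'   triggered rules), `G`, `df`, `p_value`, `n_workers`, `best_pairs`
#'   (list column).
#' @export
classify_colony <- function(gt_colony, alpha = 0.05, min_workers = 5) {
  cid <- unique(gt_colony$colony_id)
  if (length(cid) != 1) stop("classify_colony expects exactly one colony")
  by_ind <- dplyr::summarise(dplyr::group_by(gt_colony, .data$individual_id),
                             any_typed = any(!is.na(.data$allele_1)))
  n_workers <- sum(by_ind$any_typed)
  call <- function(verdict, rules, G = NA_real_, df = NA_integer_,
                   p = NA_real_, bp = list()) {
    tibble::tibble(colony_id = cid, verdict = verdict,
                   rules = paste(rules, collapse = ","),
                   G = G, df = df, p_value = p, n_workers = n_workers,
                   best_pairs = list(bp))
  }
  if (n_workers < min_workers) {
    return(call("insufficient_data", "too_few_workers"))
  }
  loci <- unique(gt_colony$locus)
  over4 <- character(0)
  inconsistent <- character(0)
  pair_dists <- list()
  best_pairs <- list()
  for (lc in loci) {
    d <- gt_colony[gt_colony$locus == lc, ]
    al <- c(d$allele_1, d$allele_2)
    al <- al[!is.na(al)]
    if (length(al) == 0) next
    if (length(unique(al)) > 4) {
      over4 <- c(over4, lc)
      next
    }
    cand <- enumerate_parent_pairs(d$allele_1, d$allele_2)
    if (nrow(cand) == 0) {
      inconsistent <- c(inconsistent, lc)
    } else {
      pair_dists[[lc]] <- cand$dist[[1]]
      best_pairs[[lc]] <- cand[1, c("p1_a", "p1_b", "p2_a", "p2_b")]
    }
  }
  if (length(over4) > 0) {
    return(call("mixed", paste0("gt4_alleles:", over4)))
  }
  if (length(inconsistent) > 0) {
    return(call("extended", paste0("mendelian_inconsistent:", inconsistent)))
  }
  gt_res <- gtest_simple_family(gt_colony, pairs = pair_dists)
  if (gt_res$p_value < alpha) {
    return(call("extended", "gtest_deviation", gt_res$G, gt_res$df,
                gt_res$p_value, best_pairs))
  }
  call("simple", "none", gt_res$G, gt_res$df, gt_res$p_value, best_pairs)
}

#' Classify every colony in a dataset
#'
#' @param gt A genotype table.
#' @param alpha Significance level of the combined G-test.
#' @param min_workers Minimum genotyped workers per colony.
#' @return A tibble of per-colony calls (see [classify_colony()]).
#' @export
classify_dataset <- function(gt, alpha = 0.05, min_workers = 5) {
  ids <- unique(gt$colony_id)
  dplyr::bind_rows(lapply(ids, function(cid) {
    classify_colony(gt[gt$colony_id == cid, ], alpha = alpha,
                    min_workers = min_workers)
  }))
}

#' Family-type proportions, overall and per group
#'
#' @param calls Output of [classify_dataset()].
#' @param group Optional `colony_id`/`group` data frame (e.g. inferred
#'   cluster assignments); adds per-group rows.
#' @return A tibble `group`, `verdict`, `n`, `proportion`; proportions are
#'   over classified colonies (verdict not `insufficient_data`).
#' @export
family_summary <- function(calls, group = NULL) {
  ok <- dplyr::filter(calls, .data$verdict != "insufficient_data")
  one <- function(d, g) {
    s <- dplyr::count(d, .data$verdict, name = "n")
    tibble::tibble(group = g, verdict = s$verdict, n = s$n,
                   proportion = s$n / sum(s$n))
  }
  out <- one(ok, "all")
  if (!is.null(group)) {
    m <- setNames(as.character(group$group), group$colony_id)
    ok$grp <- m[ok$colony_id]
    for (g in sort(unique(ok$grp))) {
      out <- dplyr::bind_rows(out, one(ok[!is.na(ok$grp) & ok$grp == g, ], g))
    }
  }
  out
}
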