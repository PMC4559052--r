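test_that("Nei unbiased heterozygosity follows the closed form", {
  # p = (0.5, 0.5), n = 10: H_E = (20/19) * 0.5
  gt <- make_gt(c(replicate(5, list(c(1, 1)), simplify = FALSE),
                  replicate(5, list(c(2, 2)), simplify = FALSE)))
  h <- observed_expected_het(gt)
  expect_equal(h$h_exp[h$locus == "loc1"], (20 / 19) * 0.5, tolerance = 1e-12)
  expect_equal(h$h_obs[h$locus == "loc1"], 0)

  # p = 4 x 0.25, n = 100: H_E = (200/199) * 0.75
  geno <- lapply(1:100, function(i) list(c((i %% 4) + 1, (i %% 4) + 1)))
  h2 <- observed_expected_het(make_gt(geno))
  expect_equal(h2$h_exp[h2$locus == "loc1"], (200 / 199) * 0.75,
               tolerance = 1e-12)

  # monomorphic locus
  h3 <- observed_expected_het(make_gt(replicate(6, list(c(3, 3)),
                                                simplify = FALSE)))
  expect_equal(h3$h_obs[1], 0)
  expect_equal(h3$h_exp[1], 0)
})

test_that("Weir-Cockerham components match the scalar-loop oracle", {
  set.seed(14)
  for (rep in 1:30) {
    gt <- random_gt(n_col = sample(2:5, 1), n_ind = sample(2:6, 1),
                    n_loci = sample(1:3, 1), n_alleles = sample(2:3, 1))
    gmap <- setNames(unique(gt$colony_id), unique(gt$colony_id))
    fit <- wc_fstats(gt, group = "colony")
    orc <- oracle_wc(gt, gmap)
    expect_equal(fit$overall$a, orc$a, tolerance = 1e-10)
    expect_equal(fit$overall$b, orc$b, tolerance = 1e-10)
    expect_equal(fit$overall$c, orc$c, tolerance = 1e-10)
    expect_equal(fit$overall$fst, orc$fst, tolerance = 1e-10)
    expect_equal(fit$overall$fis, orc$fis, tolerance = 1e-10)
  }
})

test_that("F-statistics hit their analytic anchors", {
  # all heterozygous A/B in one group: F_IS < 0, matches the oracle
  gt <- make_gt(replicate(10, list(c(1, 2)), simplify = FALSE))
  fit <- wc_fstats(gt)
  expect_lt(fit$overall$fis, 0)
  orc <- oracle_wc(gt, setNames("c1", "c1"))
  expect_equal(fit$overall$fis, orc$fis, tolerance = 1e-10)

  # two groups fixed for different alleles: F_ST = 1
  gt2 <- make_gt(c(replicate(6, list(c(1, 1)), simplify = FALSE),
                   replicate(6, list(c(2, 2)), simplify = FALSE)),
                 colony = rep(c("c1", "c2"), each = 6))
  expect_equal(wc_fstats(gt2, group = "colony")$overall$fst, 1)

  # large panmictic sample: F_IS ~ 0
  set.seed(15)
  geno <- lapply(1:5000, function(i) list(sample.int(4, 2, TRUE)))
  fit3 <- wc_fstats(make_gt(geno))
  expect_lt(abs(fit3$overall$fis), 0.02)
})

test_that("F_IS permutation test flags heterozygote deficiency", {
  set.seed(16)
  # inbred pool: pooled extended colonies
  rows <- lapply(1:25, function(i) {
    cl <- sim_colony("extended", uniform_freqs(), 4, g = 3)
    dplyr::mutate(colony_as_gt(cl, sprintf("c%02d", i)),
                  colony_id = sprintf("c%02d", i),
                  individual_id = sprintf("c%02d_%s", i, individual_id))
  })
  gt <- gen_tbl(dplyr::bind_rows(rows))
  fit <- wc_fstats(gt, n_perm = 99, seed = 1)
  expect_gt(fit$overall$fis, 0.2)
  expect_lte(fit$p_fis, 0.05)
})

test_that("heterozygote-deficiency exact test agrees with full pairing enumeration", {
  set.seed(17)
  for (rep in 1:12) {
    n <- sample(3:4, 1)
    a1 <- sample.int(3, n, TRUE); a2 <- sample.int(3, n, TRUE)
    if (length(unique(c(a1, a2))) < 2) next
    gt <- make_gt(lapply(seq_len(n), function(i) list(c(a1[i], a2[i]))))
    res <- hwe_deficiency_test(gt)
    expect_equal(res$method, "enumeration")
    expect_equal(res$p_value, oracle_hwe_p(a1, a2), tolerance = 1e-9)
  }
  # monomorphic convention
  gt1 <- make_gt(replicate(5, list(c(2, 2)), simplify = FALSE))
  r1 <- hwe_deficiency_test(gt1)
  expect_equal(r1$p_value, 1)
  expect_equal(r1$method, "degenerate")
})

test_that("heterozygote-deficiency p-values are valid and detect inbreeding", {
  set.seed(18)
  # null: never anti-conservative (empirical CDF below the diagonal + slack)
  ps <- replicate(300, {
    p <- runif(1, 0.25, 0.75)
    a1 <- sample(1:2, 40, TRUE, c(p, 1 - p))
    a2 <- sample(1:2, 40, TRUE, c(p, 1 - p))
    gt <- make_gt(lapply(1:40, function(i) list(c(a1[i], a2[i]))))
    hwe_deficiency_test(gt)$p_value
  })
  for (alpha in c(0.01, 0.05, 0.1, 0.25)) {
    expect_lte(mean(ps <= alpha), alpha + 2.5 * sqrt(alpha * (1 - alpha) / 300))
  }
  # power: pooled inbred colonies give small p at most loci
  rows <- lapply(1:20, function(i) {
    cl <- sim_colony("extended", uniform_freqs(), 3, g = 3)
    dplyr::mutate(colony_as_gt(cl, sprintf("c%02d", i)),
                  individual_id = sprintf("c%02d_%s", i, individual_id))
  })
  gt <- gen_tbl(dplyr::bind_rows(rows))
  res <- hwe_deficiency_test(gt, mc_reps = 2000, seed = 2)
  expect_gte(sum(res$p_value < 0.05), 4)
})

test_that("linkage disequilibrium test finds duplicated loci, not independent ones", {
  set.seed(19)
  # duplicated locus: maximal association
  geno <- lapply(1:30, function(i) {
    g <- sort(sample.int(3, 2, TRUE))
    list(g, g)
  })
  gt <- make_gt(geno)
  r <- ld_test(gt, "loc1", "loc2", mc_reps = 199)
  expect_lte(r$p_value, 1 / (1 + 199))

  # 6 loci -> 15 pairs, Bonferroni threshold alpha / 15
  sim <- sim_dataset(sim_config(n_clusters = 1, colonies_per_cluster = 10,
                                family_mix = c(1, 0, 0), seed = 41))
  one <- make_resamples(sim$gt, 1, seed = 3)[[1]]
  scan <- ld_scan(one, mc_reps = 99, seed = 4)
  expect_equal(nrow(scan), 15)
  expect_equal(attr(scan, "alpha_adjusted"), 0.05 / 15)
})

test_that("AMOVA components match the explicit pair-distance oracle", {
  set.seed(20)
  for (rep in 1:8) {
    gt <- random_gt(n_col = sample(2:4, 1), n_ind = sample(2:5, 1),
                    n_loci = sample(1:2, 1))
    fit <- amova(gt, n_perm = 0)
    orc <- oracle_amova(gt)
    expect_equal(fit$components$sigma, unname(orc), tolerance = 1e-10)
    expect_equal(sum(fit$components$percent), 100, tolerance = 1e-6)
  }
})

test_that("AMOVA behaves at its degenerate anchors", {
  # all individuals identical: zero everywhere
  gt <- make_gt(replicate(8, list(c(1, 1), c(2, 2)), simplify = FALSE),
                colony = rep(c("c1", "c2"), each = 4))
  fit <- amova(gt, n_perm = 0)
  expect_true(all(abs(fit$components$sigma) < 1e-12))

  # two colonies fixed for different alleles: 100% among colonies
  gt2 <- make_gt(c(replicate(5, list(c(1, 1)), simplify = FALSE),
                   replicate(5, list(c(2, 2)), simplify = FALSE)),
                 colony = rep(c("c1", "c2"), each = 5))
  fit2 <- amova(gt2, n_perm = 49, seed = 1)
  expect_equal(fit2$components$percent[1], 100, tolerance = 1e-9)
  expect_lte(fit2$p_among_colonies, 0.05)

  # permuting individuals leaves the total SS unchanged
  set.seed(21)
  gt3 <- random_gt(3, 4, 2)
  tot <- function(g) sum(amova(g, n_perm = 0)$components$ss)
  ids <- unique(gt3$individual_id)
  perm <- setNames(sample(unique(gt3$colony_id), length(ids), TRUE), ids)
  gt3p <- gen_tbl(dplyr::mutate(gt3, colony_id = perm[individual_id]),
                  loci = loci_of(gt3))
  expect_equal(tot(gt3), tot(gt3p), tolerance = 1e-9)
})

test_that("pairwise F_ST detects differentiation with permutation support", {
  set.seed(22)
  sim <- sim_dataset(sim_config(n_clusters = 2, colonies_per_cluster = 15,
                                family_mix = c(1, 0, 0), seed = 61))
  one <- make_resamples(sim$gt, 1, seed = 1)[[1]]
  grp <- tibble::tibble(colony_id = sim$geo$colony_id,
                        group = paste0("cl", sim$geo$cluster))
  pw <- pairwise_fst(one, grp, n_perm = 99, seed = 2)
  expect_equal(nrow(pw), 1)
  expect_gt(pw$fst, 0.05)
  expect_lte(pw$p_value, 0.05)
})
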