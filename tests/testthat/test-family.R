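test_that("parental-pair enumeration matches exhaustive first-principles search", {
  # canonical double-heterozygote brood {AC, AD, BC, BD}
  a1 <- c(1, 1, 2, 2); a2 <- c(3, 4, 3, 4)
  pairs <- enumerate_parent_pairs(a1, a2)
  expect_gt(nrow(pairs), 0)
  has_pair <- function(pairs, p1, p2) {
    any(vapply(seq_len(nrow(pairs)), function(i) {
      r <- c(pairs$p1_a[i], pairs$p1_b[i], pairs$p2_a[i], pairs$p2_b[i])
      (all(r[1:2] == p1) && all(r[3:4] == p2)) ||
        (all(r[1:2] == p2) && all(r[3:4] == p1))
    }, logical(1)))
  }
  expect_true(has_pair(pairs, c(1, 2), c(3, 4)))   # (A/B, C/D)
  expect_false(has_pair(pairs, c(1, 3), c(2, 4)))  # (A/C, B/D) cannot give AD

  # agreement with the exhaustive oracle over the observed-allele pool
  set.seed(8)
  for (rep in 1:25) {
    n_al <- sample(2:4, 1)
    n <- sample(3:8, 1)
    x1 <- sample.int(n_al, n, TRUE); x2 <- sample.int(n_al, n, TRUE)
    mine <- enumerate_parent_pairs(x1, x2)
    mine_obs <- mine[mine$n_wildcards == 0, ]
    orc <- oracle_parent_pairs(x1, x2)
    expect_equal(nrow(mine_obs), length(orc))
  }
})

test_that("single homozygous class admits any pair carrying that allele", {
  pairs <- enumerate_parent_pairs(rep(1, 6), rep(1, 6))
  # every compatible pair has allele 1 in both parents
  ok <- vapply(seq_len(nrow(pairs)), function(i) {
    (pairs$p1_a[i] == 1 || pairs$p1_b[i] == 1) &&
      (pairs$p2_a[i] == 1 || pairs$p2_b[i] == 1)
  }, logical(1))
  expect_true(all(ok))
  # (A/A, A/x) with an unobserved second allele (wildcard, coded negative)
  # is compatible: unobserved offspring classes never disqualify
  expect_true(any(pairs$p1_a == 1 & pairs$p1_b == 1 &
                    pairs$p2_b == 1 & pairs$p2_a < 0))
})

test_that("three homozygous classes are Mendelian-impossible", {
  pairs <- enumerate_parent_pairs(c(1, 2, 3), c(1, 2, 3))
  expect_equal(nrow(pairs), 0)
  # more than 4 genotype classes likewise
  a1 <- c(1, 1, 1, 2, 2); a2 <- c(1, 2, 3, 2, 3)
  expect_equal(nrow(enumerate_parent_pairs(a1, a2)), 0)
  # more than 4 alleles: empty by construction
  expect_equal(nrow(enumerate_parent_pairs(1:5, 1:5)), 0)
})

test_that("combined G-test reproduces hand-computed values", {
  # counts {AC:3, AD:2, BC:3, BD:2} under (A/B, C/D): G ~ 0.402, df 3
  gt1 <- make_gt(c(replicate(3, list(c(1, 3)), simplify = FALSE),
                   replicate(2, list(c(1, 4)), simplify = FALSE),
                   replicate(3, list(c(2, 3)), simplify = FALSE),
                   replicate(2, list(c(2, 4)), simplify = FALSE)))
  dist <- setNames(rep(0.25, 4), c("1/3", "1/4", "2/3", "2/4"))
  res <- gtest_simple_family(gt1, pairs = list(loc1 = dist))
  expect_equal(res$G, 0.4027, tolerance = 1e-3)
  expect_equal(res$df, 3)
  expect_equal(res$p_value, 0.9399, tolerance = 1e-3)
  expect_equal(res$G, oracle_g(as.list(table(paste0(
    pmin(gt1$allele_1, gt1$allele_2), "/",
    pmax(gt1$allele_1, gt1$allele_2)))), as.list(dist)), tolerance = 1e-12)

  # counts {AC:8, AD:2} under the same pair: G ~ 17.72
  gt2 <- make_gt(c(replicate(8, list(c(1, 3)), simplify = FALSE),
                   replicate(2, list(c(1, 4)), simplify = FALSE)))
  res2 <- gtest_simple_family(gt2, pairs = list(loc1 = dist))
  expect_equal(res2$G, 17.7178, tolerance = 1e-3)
  expect_equal(res2$df, 3)
  expect_lt(res2$p_value, 1e-3)

  # perfectly proportional counts: G = 0, p = 1
  gt3 <- make_gt(c(replicate(5, list(c(1, 3)), simplify = FALSE),
                   replicate(5, list(c(1, 4)), simplify = FALSE),
                   replicate(5, list(c(2, 3)), simplify = FALSE),
                   replicate(5, list(c(2, 4)), simplify = FALSE)))
  res3 <- gtest_simple_family(gt3, pairs = list(loc1 = dist))
  expect_equal(res3$G, 0)
  expect_equal(res3$p_value, 1)
})

test_that("G combines additively over loci", {
  set.seed(9)
  sim <- sim_colony("simple", uniform_freqs(), 10)
  gt <- colony_as_gt(sim)
  res <- gtest_simple_family(gt)
  expect_equal(res$G, sum(res$per_locus$G), tolerance = 1e-12)
  expect_equal(res$df, sum(res$per_locus$df))
})

test_that("classification rules fire in their stated order", {
  # rule 1: five alleles at a locus -> mixed
  gt5 <- make_gt(list(list(c(1, 2)), list(c(3, 4)), list(c(5, 5)),
                      list(c(1, 3)), list(c(2, 4))))
  call5 <- classify_colony(gt5)
  expect_equal(call5$verdict, "mixed")
  expect_match(call5$rules, "gt4_alleles")

  # rule 2: three homozygous classes, <= 4 alleles -> extended
  gth <- make_gt(c(replicate(2, list(c(1, 1)), simplify = FALSE),
                   replicate(2, list(c(2, 2)), simplify = FALSE),
                   replicate(2, list(c(3, 3)), simplify = FALSE)))
  callh <- classify_colony(gth)
  expect_equal(callh$verdict, "extended")
  expect_match(callh$rules, "mendelian_inconsistent")

  # canonical outcross family -> simple
  set.seed(10)
  sim <- sim_colony("simple", uniform_freqs(), 10)
  expect_equal(classify_colony(colony_as_gt(sim), alpha = 0.001)$verdict,
               "simple")

  # too few workers -> insufficient data, never a silent simple
  small <- make_gt(list(list(c(1, 2)), list(c(1, 2))))
  expect_equal(classify_colony(small)$verdict, "insufficient_data")
})

test_that("the Mendelian screen never rejects a true single-pair colony", {
  set.seed(11)
  freqs <- uniform_freqs()
  for (rep in 1:40) {
    sim <- sim_colony("simple", freqs, 10)
    gt <- colony_as_gt(sim)
    for (lc in unique(gt$locus)) {
      d <- gt[gt$locus == lc, ]
      expect_gt(nrow(enumerate_parent_pairs(d$allele_1, d$allele_2)), 0)
    }
  }
})

test_that("verdict mixed coincides exactly with a >4-allele locus", {
  set.seed(12)
  cfg <- sim_config(n_clusters = 1, colonies_per_cluster = 30,
                    family_mix = c(0.3, 0.3, 0.4), seed = 77)
  sim <- sim_dataset(cfg)
  calls <- classify_dataset(sim$gt)
  brute <- sapply(unique(sim$gt$colony_id), function(cid) {
    d <- sim$gt[sim$gt$colony_id == cid, ]
    any(sapply(unique(d$locus), function(lc) {
      al <- c(d$allele_1[d$locus == lc], d$allele_2[d$locus == lc])
      length(unique(al[!is.na(al)])) > 4
    }))
  })
  expect_equal(calls$verdict == "mixed", unname(brute))
})

test_that("dataset-level classification summarises proportions per group", {
  set.seed(13)
  sim <- sim_dataset(sim_config(colonies_per_cluster = c(4, 4), seed = 5))
  calls <- classify_dataset(sim$gt)
  expect_equal(nrow(calls), 8)
  grp <- tibble::tibble(colony_id = sim$geo$colony_id,
                        group = paste0("cl", sim$geo$cluster))
  s <- family_summary(calls, group = grp)
  all_row <- s[s$group == "all", ]
  expect_equal(sum(all_row$n), 8)
  expect_equal(sum(all_row$proportion), 1)
  expect_true(all(c("cl1", "cl2") %in% s$group))
})
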