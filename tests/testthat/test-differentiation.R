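test_that("theta hits its fixation and null anchors", {
  # pop1 all AA, pop2 all BB -> theta = 1
  gt <- genotype_table(tibble::tibble(
    id = sprintf("i%02d", 1:20),
    L1.1 = rep(c(100L, 104L), each = 10), L1.2 = rep(c(100L, 104L), each = 10)
  ))
  gr <- tibble::tibble(id = gt$id, stg = rep(c("p1", "p2"), each = 10))
  expect_equal(wc_theta(gt, gr)$theta, 1)
  # two samples from one random-mating pool: |theta| small in expectation
  thetas <- vapply(1:20, function(s) {
    pool <- hw_group(40, list(c(0.5, 0.3, 0.2), c(0.6, 0.4)), seed = 100 + s)
    gr2 <- tibble::tibble(id = pool$id, stg = rep(c("a", "b"), each = 20))
    wc_theta(pool, gr2)$theta
  }, numeric(1))
  expect_lt(abs(mean(thetas)), 0.02)
  # monomorphic everywhere is undefined
  gtm <- genotype_table(tibble::tibble(
    id = c("a", "b", "c", "d"), L1.1 = 100L, L1.2 = 100L
  ))
  grm <- tibble::tibble(id = gtm$id, stg = rep(c("x", "y"), 2))
  expect_error(wc_theta(gtm, grm), "monomorphic")
})

test_that("theta equals an independent ANOVA mean-squares computation", {
  withr::with_seed(8, {
    for (rep in 1:5) {
      sim <- two_deme_sim(seed = 200 + rep, n_sample = c(12, 18)[rep %% 2 + 1],
                          n_loci = 5, gens = 10)
      gt <- sim$table
      gr <- tibble::tibble(id = gt$id, stg = gt$region)
      expect_equal(wc_theta(gt, gr)$theta, wc_theta_anova(gt, gr),
                   tolerance = 1e-10)
    }
  })
})

test_that("theta permutation test is exact at the extremes and calibrated", {
  gt <- genotype_table(tibble::tibble(
    id = sprintf("i%02d", 1:20),
    L1.1 = rep(c(100L, 104L), each = 10), L1.2 = rep(c(100L, 104L), each = 10)
  ))
  gr <- tibble::tibble(id = gt$id, stg = rep(c("p1", "p2"), each = 10))
  out <- fst_permutation_test(gt, gr, n_perm = 99, seed = 4)
  expect_equal(out$p, 1 / 100)
  # under the null (one pool split arbitrarily), P(p <= 0.05) stays nominal
  rejections <- vapply(1:200, function(s) {
    pool <- hw_group(24, list(c(0.5, 0.5), c(0.4, 0.6), c(0.7, 0.3)), seed = 500 + s)
    gr2 <- tibble::tibble(id = pool$id, stg = rep(c("a", "b"), each = 12))
    fst_permutation_test(pool, gr2, n_perm = 99, seed = s)$p <= 0.05
  }, logical(1))
  ci <- stats::binom.test(sum(rejections), length(rejections), 0.05)$conf.int
  expect_lt(ci[1], 0.05)
})

test_that("pairwise theta table is symmetric and matches single-pair runs", {
  sim <- scenario_recovery_lag(seed = 21, record_truth = FALSE)
  gr <- assign_stgs(sim$table)
  gr14 <- gr[gr$time_point == "2014", ]
  pf <- pairwise_fst(sim$table, gr14, by = "region", n_perm = 49, seed = 2)
  expect_true(isSymmetric(pf$theta))
  expect_equal(unname(diag(pf$theta)), rep(0, nrow(pf$theta)))
  one <- pf$pairs[1, ]
  again <- wc_theta(sim$table,
                    gr14[gr14$region %in% c(one$group1, one$group2), ],
                    by = "region")
  expect_equal(one$theta, again$theta)
})

test_that("AMOVA Phi_ST spans its anchors and tracks theta", {
  # random split of one pool: Phi ~ 0
  pool <- hw_group(40, list(c(0.5, 0.3, 0.2), c(0.6, 0.4), c(0.3, 0.3, 0.4)),
                   seed = 77)
  gr <- tibble::tibble(id = pool$id, stg = rep(c("a", "b"), each = 20))
  am <- amova_global(pool, gr, n_perm = 49, seed = 1)
  expect_lt(abs(am$phi_st), 0.05)
  expect_gt(am$p, 0.05)
  # fixed difference: Phi = 1
  gt <- genotype_table(tibble::tibble(
    id = sprintf("i%02d", 1:20),
    L1.1 = rep(c(100L, 104L), each = 10), L1.2 = rep(c(100L, 104L), each = 10)
  ))
  gr2 <- tibble::tibble(id = gt$id, stg = rep(c("p1", "p2"), each = 10))
  am2 <- amova_global(gt, gr2, n_perm = 49, seed = 1)
  expect_equal(am2$phi_st, 1)
  expect_equal(am2$p, 1 / 50)
  # balanced two-deme design: AMOVA and Weir-Cockerham agree closely
  sim <- two_deme_sim(seed = 31, n_sample = 25, n_loci = 8)
  gts <- sim$table
  grs <- tibble::tibble(id = gts$id, stg = gts$region)
  expect_lt(abs(amova_global(gts, grs, n_perm = 9, seed = 1)$phi_st -
                wc_theta(gts, grs)$theta), 0.02)
  # undersized groups are dropped with a warning
  gr3 <- dplyr::bind_rows(grs, tibble::tibble(id = "ghost", stg = "tiny"))
  expect_warning(amova_global(gts, gr3, n_perm = 9, seed = 1), "excluded")
})

test_that("Hardy-Weinberg exact test enumeration matches the Levene formula", {
  # AA = 3, AB = 0, BB = 3: conditional probabilities over h in {0,2,4,6}
  # weight(h) = 6!/(nAA! h! nBB!) * 2^h -> {20, 360, 480, 64}, total 924
  gt <- cbind(c(rep(1, 3), rep(2, 3)), c(rep(1, 3), rep(2, 3)))
  out <- hwe_exact_test(gt)
  expect_equal(out$method, "enumeration")
  expect_equal(out$p, 20 / 924)
  # HW-proportional data at p = 0.5, large n: comfortably non-significant
  g <- withr::with_seed(5, replicate(2, sample(1:2, 400, TRUE)))
  expect_gt(hwe_exact_test(g)$p, 0.05)
  expect_equal(hwe_exact_test(cbind(rep(1, 10), rep(1, 10)))$method, "monomorphic")
})

test_that("HWE Markov chain agrees with enumeration on 2-allele tables", {
  tables <- list(
    c(nAA = 3, nAB = 0, nBB = 3),
    c(nAA = 10, nAB = 4, nBB = 2),
    c(nAA = 6, nAB = 14, nBB = 6),
    c(nAA = 1, nAB = 1, nBB = 8)
  )
  for (tb in tables) {
    g <- matrix(c(tb[1], tb[2], tb[2], tb[3]), 2, 2)
    g[1, 2] <- 0  # lower triangle only
    p_mc <- withr::with_seed(3, popgenmon:::.hwe_mcmc_cpp(g, 200000L, 20000L))
    p_en <- popgenmon:::hwe_enumerate_2allele(tb[1], tb[2], tb[3])
    expect_lt(abs(p_mc - p_en), 0.01)
  }
})

test_that("composite LD test flags duplicated loci and stays calibrated", {
  pool <- hw_group(30, list(c(0.5, 0.3, 0.2), c(0.5, 0.5)), seed = 12)
  dup <- dplyr::mutate(tibble::as_tibble(pool), L3.1 = .data$L1.1, L3.2 = .data$L1.2)
  gtd <- genotype_table(dup)
  out <- ld_permutation_test(gtd, "L1", "L3", n_perm = 99, seed = 1)
  expect_equal(out$p, 1 / 100)
  # independent loci: nominal rejection rate
  rej <- vapply(1:150, function(s) {
    g <- hw_group(25, list(c(0.5, 0.3, 0.2), c(0.6, 0.4)), seed = 900 + s)
    ld_permutation_test(g, "L1", "L2", n_perm = 99, seed = s)$p <= 0.05
  }, logical(1))
  ci <- stats::binom.test(sum(rej), length(rej), 0.05)$conf.int
  expect_lt(ci[1], 0.05)
})

test_that("pooling divergent demes inflates both LD and F_IS (Wahlund regime)", {
  hits <- vapply(1:25, function(s) {
    sim <- two_deme_sim(seed = 700 + s, n_sample = 20, n_loci = 2, gens = 25)
    gt <- sim$table
    ld_permutation_test(gt, "L01", "L02", n_perm = 99, seed = s)$p <= 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.1)  # well above the nominal 5% under true linkage equilibrium
})

test_that("F_IS spans its anchors", {
  # fully homozygous polymorphic group: f = 1
  gt <- genotype_table(tibble::tibble(
    id = sprintf("i%02d", 1:10),
    L1.1 = rep(c(100L, 104L), 5), L1.2 = rep(c(100L, 104L), 5)
  ))
  expect_equal(fis_estimate(gt)$fis, 1)
  # random-mating group: f near 0
  fis <- vapply(1:20, function(s) {
    fis_estimate(hw_group(40, list(c(0.5, 0.3, 0.2), c(0.6, 0.4)), seed = 40 + s))$fis
  }, numeric(1))
  expect_lt(abs(mean(fis)), 0.03)
})

test_that("within-group allele permutation gives a valid F_IS p-value", {
  # a strongly inbred group is detected
  gt <- genotype_table(tibble::tibble(
    id = sprintf("i%02d", 1:20),
    L1.1 = rep(c(100L, 104L), 10), L1.2 = rep(c(100L, 104L), 10),
    L2.1 = rep(c(110L, 112L), 10), L2.2 = rep(c(110L, 112L), 10)
  ))
  gr <- tibble::tibble(id = gt$id, stg = "g")
  out <- fis_significance(gt, gr, n_perm = 199, seed = 3)
  expect_lt(out$p, 0.05)
  # both routes agree qualitatively; t route returns a p too (the two
  # identical per-locus f values make its distribution degenerate)
  expect_warning(out_t <- fis_significance(gt, gr, method = "t"), "degenerate")
  expect_lt(out_t$p, 0.05)
  # null calibration
  rej <- vapply(1:100, function(s) {
    g <- hw_group(20, list(c(0.5, 0.3, 0.2), c(0.6, 0.4)), seed = 600 + s)
    fis_significance(g, tibble::tibble(id = g$id, stg = "g"),
                     n_perm = 99, seed = s)$p <= 0.05
  }, logical(1))
  ci <- stats::binom.test(sum(rej), length(rej), 0.05)$conf.int
  expect_lt(ci[1], 0.05)
})

test_that("Benjamini-Hochberg flags follow the step-up rule", {
  out <- fis_fdr(c(0.001, 0.02, 0.8))
  # by hand: sorted p (0.001, 0.02, 0.8) vs (0.05/3, 0.10/3, 0.15/3)
  expect_equal(out$significant, c(TRUE, TRUE, FALSE))
  expect_equal(fis_fdr(rep(1, 4))$significant, rep(FALSE, 4))
  # null FDR control
  withr::with_seed(15, {
    false_flags <- vapply(1:1000, function(i) {
      any(fis_fdr(runif(10))$significant)
    }, logical(1))
    expect_lte(mean(false_flags),
               0.05 + 2 * sqrt(0.05 * 0.95 / 1000) + 0.02)
  })
})

test_that("two-stage F_IS separates Wahlund pooling from true inbreeding", {
  # pooled pair of diverged random-mating demes -> "w"
  sim <- two_deme_sim(seed = 50, n_sample = 15, n_loci = 8, gens = 22)
  gt <- sim$table
  fit <- admixture_gibbs(gt, K = 2, burnin = 500, steps = 2000, seed = 2)
  res <- wahlund_two_stage(gt, gt$id, fit$Q, n_perm = 199, seed = 9)
  expect_equal(res$classification, "w")
  expect_gt(res$fis1, res$fis2)
  # a selfing deme -> "i"
  cfg <- sim_config(
    n_demes = 1, deme_names = "S", centroids = rbind(c(0, 0)),
    epochs = list(list(gens = 12, N = 60, m = 0)),
    n_loci = 8, founder_alleles = 6, founder_pool_size = 8,
    selfing_rate = 0.5,
    sampling = tibble::tibble(generation = 12, time_point = "t", year = 2000L,
                              n = list(30)),
    record_truth = FALSE
  )
  simi <- simulate_population(cfg, seed = 51)
  gti <- simi$table
  fiti <- admixture_gibbs(gti, K = 1)
  resi <- wahlund_two_stage(gti, gti$id, fiti$Q, n_perm = 199, seed = 9)
  expect_equal(resi$classification, "i")
  # tiny dominant cluster -> indeterminate
  Qsmall <- matrix(c(rep(c(0.9, 0.1), 3)), 3, 2, byrow = TRUE)
  res3 <- wahlund_two_stage(gt, gt$id[1:3], Qsmall, n_perm = 49, seed = 1)
  expect_equal(res3$classification, "indeterminate")
})
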