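test_that("observed heterozygosity counts heterozygotes among typed calls", {
  gt <- genotype_table(tibble::tibble(
    id = c("u", "v"), L1.1 = c(100L, 100L), L1.2 = c(100L, 102L)
  ))
  expect_equal(observed_heterozygosity(gt)$ho, 0.5)  # {AA, AB}
  gt2 <- genotype_table(tibble::tibble(
    id = c("u", "v"), L1.1 = c(100L, 102L), L1.2 = c(100L, 102L)
  ))
  expect_equal(observed_heterozygosity(gt2)$ho, 0)   # all homozygous
})

test_that("unbiased He matches the small-sample formula and its bounds", {
  # n = 2, alleles {A:3, B:1}: (4/3) * (1 - (9+1)/16) = 0.5
  gt <- genotype_table(tibble::tibble(
    id = c("u", "v"), L1.1 = c(100L, 100L), L1.2 = c(100L, 102L)
  ))
  he <- unbiased_expected_heterozygosity(allele_frequencies(gt))
  expect_equal(he$he, 0.5)
  # monomorphic locus has He = 0
  gtm <- genotype_table(tibble::tibble(
    id = c("u", "v"), L1.1 = 100L, L1.2 = 100L
  ))
  expect_equal(unbiased_expected_heterozygosity(allele_frequencies(gtm))$he, 0)
  # He_unbiased >= 1 - sum(p^2), converging as n grows
  withr::with_seed(42, {
    for (rep in 1:20) {
      k <- sample(2:6, 1)
      counts <- as.vector(stats::rmultinom(1, 2 * sample(3:30, 1), rep(1 / k, k)))
      counts <- counts[counts > 0]
      if (sum(counts) %% 2 == 1) counts[1] <- counts[1] + 1
      if (length(counts) < 2) next
      p <- counts / sum(counts)
      G <- sum(counts)
      he_u <- (G / (G - 1)) * (1 - sum(p^2))
      expect_gte(he_u, 1 - sum(p^2))
    }
  })
  G <- 2e4
  p <- c(0.3, 0.7)
  expect_lt(abs((G / (G - 1)) * (1 - sum(p^2)) - (1 - sum(p^2))), 1e-3)
})

test_that("rarefied richness equals the exhaustive-enumeration expectation", {
  expect_equal(rarefy_richness(c(2, 1, 1), 2), 11 / 6)
  expect_equal(rarefy_richness(c(2, 1, 1), 4), 3)  # g = G recovers the count
  withr::with_seed(7, {
    for (rep in 1:15) {
      k <- sample(2:5, 1)
      counts <- as.vector(stats::rmultinom(1, sample(4:12, 1), rep(1 / k, k)))
      counts <- counts[counts > 0]
      G <- sum(counts)
      if (G < 3 || length(counts) < 2) next
      g <- sample(2:(G - 1), 1)
      expect_equal(rarefy_richness(counts, g), ar_enum(counts, g),
                   tolerance = 1e-10)
    }
  })
  # monotone non-decreasing in g
  counts <- c(5, 3, 2, 1)
  ar <- vapply(2:11, function(g) rarefy_richness(counts, g), numeric(1))
  expect_true(all(diff(ar) >= 0))
  expect_error(rarefy_richness(c(2, 2), 5), "exceeds")
})

test_that("private allelic richness follows the multi-group expectation", {
  # two groups: focal {A:2, B:2}, other {A:4}; g = 2 -> only B contributes
  gt <- genotype_table(tibble::tibble(
    id = c("f1", "f2", "o1", "o2"),
    L1.1 = c(100L, 102L, 100L, 100L), L1.2 = c(100L, 102L, 100L, 100L)
  ))
  gr <- tibble::tibble(id = gt$id, stg = c("F", "F", "O", "O"))
  fr <- allele_frequencies(gt, gr)
  par <- rarefied_private_allelic_richness(fr, g = 2)
  q_b <- 1 - choose(2, 2) / choose(4, 2)  # P(B present in 2 of {A,A,B,B})
  expect_equal(par$par[par$group == "F"], q_b)
  expect_equal(q_b, 5 / 6)
  # the other direction: A is everywhere but can be missed in a rarefied
  # draw from F, so O retains (1 - Q_F,A) = 1/6
  expect_equal(par$par[par$group == "O"], 1 / 6)
  # an allele truly fixed in all groups contributes nothing anywhere
  gtf <- genotype_table(tibble::tibble(
    id = c("f1", "f2", "o1", "o2"), L1.1 = 100L, L1.2 = 100L
  ))
  frf <- allele_frequencies(gtf, gr)
  expect_equal(rarefied_private_allelic_richness(frf, g = 2)$par, c(0, 0))
  # single group: every allele is private, pA_r = A_r
  fr1 <- allele_frequencies(gt, gr[gr$stg == "F", ])
  expect_equal(rarefied_private_allelic_richness(fr1, g = 2)$par,
               rarefied_allelic_richness(fr1, g = 2)$ar)
})

test_that("private richness shrinks as comparison groups are added", {
  sim <- scenario_recovery_lag(seed = 5, record_truth = FALSE)
  gr <- assign_stgs(sim$table)
  gr14 <- gr[gr$time_point == "2014", ]
  regions <- unique(gr14$region)[1:4]
  pars <- vapply(2:4, function(k) {
    fr <- allele_frequencies(sim$table, gr14[gr14$region %in% regions[1:k], ],
                             by = "region")
    p <- rarefied_private_allelic_richness(fr, g = 12)
    p$par[p$group == regions[1]]
  }, numeric(1))
  expect_true(all(diff(pars) <= 1e-12))
  # and summed pA_r cannot exceed summed A_r
  fr <- allele_frequencies(sim$table, gr14, by = "region")
  expect_lte(sum(rarefied_private_allelic_richness(fr, g = 12)$par),
             sum(rarefied_allelic_richness(fr, g = 12)$ar))
})

test_that("null-allele estimators evaluate their closed forms", {
  est <- null_allele_estimates(he = c(0.5, 0.75), ho = c(0.5, 0.5))
  expect_equal(est$chakraborty, c(0, 0.2))
  expect_equal(est$brookfield1, c(0, 0.25 / 1.75))
  expect_true(is.na(null_allele_estimates(0, 0)$chakraborty))
  # majority flagging rule: > half the regions at a time point
  flags <- flag_null_loci(tibble::tibble(
    locus = "L1", time_point = "t",
    region = c("a", "b", "c", "d", "e"),
    estimate = c(0.1, 0.1, 0.1, 0.01, 0.01)
  ))
  expect_true(flags$flagged)
  flags2 <- flag_null_loci(tibble::tibble(
    locus = "L1", time_point = "t",
    region = c("a", "b", "c", "d", "e"),
    estimate = c(0.1, 0.1, 0.01, 0.01, 0.01)
  ))
  expect_false(flags2$flagged)
})

test_that("paired heterozygosity t test matches hand computation", {
  out <- paired_t_he_ho(he = c(0.3, 0.6), ho = c(0.2, 0.3))
  expect_equal(out$t, 2)           # diffs {0.1, 0.3}: mean .2, sd .1414
  expect_equal(out$df, 1)
  expect_warning(z <- paired_t_he_ho(c(0.5, 0.6), c(0.5, 0.6)), "zero variance")
  expect_equal(z$t, 0)
})

test_that("paired t keeps nominal type-I error on exchangeable noise", {
  reject <- withr::with_seed(31, vapply(1:2000, function(i) {
    he <- runif(10, 0.3, 0.8)
    ho <- he + rnorm(10, 0, 0.05)  # symmetric noise, no true difference
    paired_t_he_ho(he, ho)$p < 0.05
  }, logical(1)))
  ci <- stats::binom.test(sum(reject), length(reject), 0.05)$conf.int
  expect_lt(ci[1], 0.05)
  expect_gt(ci[2], 0.04)
})

test_that("Kendall tau-b handles ties and degenerate input", {
  expect_equal(kendall_tau_b(1:5, c(2, 4, 6, 8, 10))$tau, 1)
  expect_error(kendall_tau_b(rep(1, 5), 1:5), "all-tied")
  # tie-corrected value agrees with the classical formula on a tied example
  x <- c(1, 2, 2, 3, 4, 5)
  y <- c(2, 1, 3, 3, 5, 6)
  expect_equal(kendall_tau_b(x, y)$tau,
               unname(suppressWarnings(stats::cor.test(x, y, method = "kendall"))$estimate))
})

test_that("Kruskal-Wallis agrees with a first-principles computation", {
  withr::with_seed(9, {
    values <- c(rnorm(8, 0), rnorm(8, 1), rnorm(8, 0.5))
    groups <- rep(c("a", "b", "c"), each = 8)
    out <- kruskal_wallis(values, groups)
    expect_equal(out$h, kw_oracle(values, groups), tolerance = 1e-10)
    expect_equal(out$df, 2)
  })
  # a true shift is detected at n = 30 per group
  withr::with_seed(10, {
    v <- c(rnorm(30, 0), rnorm(30, 1))
    expect_lt(kruskal_wallis(v, rep(c("a", "b"), each = 30))$p, 0.05)
  })
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
})

test_that("rarefaction regime change preserves group ranking", {
  sim <- scenario_recovery_lag(seed = 13, record_truth = FALSE)
  gr <- assign_stgs(sim$table)
  gr14 <- gr[gr$time_point == "2014", ]
  fr <- allele_frequencies(sim$table, gr14, by = "region")
  ar_small <- rarefied_allelic_richness(fr, g = 12)      # fixed n = 6
  ar_min <- rarefied_allelic_richness(fr)                # per-year minimum
  merged <- dplyr::inner_join(ar_small, ar_min, by = "group")
  expect_gt(kendall_tau_b(merged$ar.x, merged$ar.y)$tau, 0)
})

test_that("diversity summary assembles the per-STG monitoring table", {
  sim <- scenario_recovery_lag(seed = 2, record_truth = FALSE)
  gr <- assign_stgs(sim$table)
  ds <- diversity_summary(sim$table, gr)
  expect_equal(nrow(ds), dplyr::n_distinct(gr$stg))
  expect_true(all(ds$he_mean >= 0 & ds$he_mean <= 1))
  expect_true(all(ds$ho_mean >= 0 & ds$ho_mean <= 1))
  expect_true(all(ds$ar_fixed <= ds$na_mean + 1e-9, na.rm = TRUE))
  expect_true(all(ds$par_fixed <= ds$ar_fixed + 1e-9, na.rm = TRUE))
  expect_equal(sum(ds$n), nrow(sim$table))
})
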