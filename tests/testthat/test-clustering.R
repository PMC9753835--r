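test_that("K = 1 fit is the closed-form pooled-frequency solution", {
  gt <- tiny_gt()
  fit <- admixture_gibbs(gt, K = 1)
  expect_equal(unname(fit$Q[, 1]), rep(1, nrow(gt)))
  fr <- allele_frequencies(gt)
  expect_equal(unname(fit$P$L1[1, ]), fr$freq[fr$locus == "L1"])
  expect_equal(unname(fit$P$L2[1, ]), fr$freq[fr$locus == "L2"])
})

test_that("Gibbs fits are seed-reproducible and recover two-deme structure", {
  sim <- two_deme_sim(seed = 7, n_sample = 25, n_loci = 8)
  gt <- sim$table
  f1 <- admixture_gibbs(gt, K = 2, burnin = 500, steps = 2000, seed = 11)
  f2 <- admixture_gibbs(gt, K = 2, burnin = 500, steps = 2000, seed = 11)
  expect_identical(f1$Q, f2$Q)
  expect_identical(f1$lnl, f2$lnl)
  # deme members are assigned almost entirely to one cluster each
  qa <- mean(f1$Q[gt$region == "A", 1])
  qb <- mean(f1$Q[gt$region == "B", 1])
  expect_gt(abs(qa - qb), 0.8)
  expect_gt(mean(apply(f1$Q, 1, max)), 0.9)
  # independent-frequency prior works too
  f3 <- admixture_gibbs(gt, K = 2, burnin = 500, steps = 2000, seed = 11,
                        prior = "independent")
  expect_gt(mean(apply(f3$Q, 1, max)), 0.9)
})

test_that("F1 crosses between demes get intermediate ancestry", {
  sim <- two_deme_sim(seed = 19, n_sample = 25, n_loci = 10, gens = 22)
  gt <- tibble::as_tibble(sim$table)
  loci <- gt_loci(sim$table)
  pa <- gt[gt$region == "A", ][1:10, ]
  pb <- gt[gt$region == "B", ][1:10, ]
  f1 <- pa
  f1$id <- paste0("f1_", seq_len(nrow(f1)))
  f1$region <- "F1"
  for (loc in loci) {
    # one gamete from each parental deme
    f1[[paste0(loc, ".2")]] <- pb[[paste0(loc, ".2")]]
  }
  all_gt <- genotype_table(dplyr::bind_rows(gt, f1), loci = loci)
  fit <- admixture_gibbs(all_gt, K = 2, burnin = 1000, steps = 4000, seed = 3)
  qf1 <- fit$Q[all_gt$region == "F1", ]
  expect_lt(max(abs(rowMeans(qf1) - 0.5)), 1e-9)  # rows sum to 1, K = 2
  expect_lt(abs(mean(qf1[, 1]) - 0.5), 0.1)
  expect_lt(abs(mean(qf1[, 2]) - 0.5), 0.1)
})

test_that("run alignment resolves label switching and finds modes", {
  sim <- two_deme_sim(seed = 23, n_sample = 15, n_loci = 6)
  gt <- sim$table
  fit <- admixture_gibbs(gt, K = 3, burnin = 300, steps = 1500, seed = 5)
  # a column-permuted copy aligns back perfectly
  perm <- c(3, 1, 2)
  fit_perm <- fit
  fit_perm$Q <- fit$Q[, perm]
  al <- align_runs(list(fit, fit_perm))
  expect_equal(al$aligned[[2]], fit$Q, ignore_attr = TRUE)
  expect_equal(al$similarity[1, 2], 1, tolerance = 1e-9)
  expect_equal(al$modes, c(1L, 1L))
  # invariance to arbitrary permutations of several runs
  perms <- list(1:3, c(2, 3, 1), c(3, 2, 1))
  fits <- purrr::map(perms, function(p) { f <- fit; f$Q <- fit$Q[, p]; f })
  al2 <- align_runs(fits)
  for (q in al2$aligned) expect_equal(q, fit$Q, ignore_attr = TRUE)
  # constructed bimodal ensemble separates into two modes
  Qa <- fit$Q
  Qb <- matrix(runif(nrow(Qa) * 3), ncol = 3)
  Qb <- Qb / rowSums(Qb)
  mk <- function(Q) { f <- fit; f$Q <- Q; f }
  al3 <- align_runs(list(mk(Qa), mk(Qa), mk(Qb)), mode_threshold = 0.9)
  expect_equal(sort(unique(al3$modes)), c(1L, 2L))
  expect_equal(sum(al3$modes == 1), 2)
})

test_that("replicate runs on well-separated demes form a single mode", {
  sim <- two_deme_sim(seed = 29, n_sample = 20, n_loci = 8)
  fits <- purrr::map(1:4, function(r) {
    admixture_gibbs(sim$table, K = 2, burnin = 300, steps = 1500, seed = 40 + r)
  })
  al <- align_runs(fits)
  expect_true(all(al$modes == 1L))
  expect_true(all(rowSums(al$Q_avg) - 1 < 1e-9))
})

test_that("Evanno delta-K picks out a likelihood elbow", {
  # linear lnL in K: second difference is zero everywhere
  lin <- tibble::tibble(K = 1:5, mean_lnl = -1000 + 50 * (1:5), sd_lnl = 2)
  expect_equal(evanno_delta_k(lin)$delta_k[2:4], rep(0, 3))
  # an elbow at K = 2
  elbow <- tibble::tibble(K = 1:5,
                          mean_lnl = c(-2000, -1500, -1450, -1400, -1350),
                          sd_lnl = c(1, 2, 2, 3, 3))
  dk <- evanno_delta_k(elbow)
  expect_equal(dk$K[which.max(dk$delta_k)], 2)
  # degenerate sd is NA, short or gappy ranges error
  elbow2 <- dplyr::mutate(elbow, sd_lnl = c(1, 0, 2, 3, 3))
  expect_true(is.na(evanno_delta_k(elbow2)$delta_k[2]))
  expect_error(evanno_delta_k(elbow[1:2, ]), ">= 3")
  expect_error(evanno_delta_k(elbow[c(1, 3, 5), ]), "contiguous")
})

test_that("admixture classification applies the assignment cutoff", {
  Q <- rbind(c(0.85, 0.15), c(0.7, 0.3), c(0.5, 0.5))
  rownames(Q) <- c("hi", "mid", "even")
  out <- classify_admixed(Q, cutoff = 0.8,
                          time_points = c("t1", "t1", "t2"))
  expect_equal(out$individuals$admixed, c(FALSE, TRUE, TRUE))
  expect_equal(out$by_time$pct_admixed, c(50, 100))
  # K = 1: never admixed
  Q1 <- matrix(1, 5, 1)
  expect_equal(sum(classify_admixed(Q1)$individuals$admixed), 0)
  # percentage admixed is monotone non-decreasing in the cutoff
  set.seed(4)
  Qr <- matrix(rexp(60), ncol = 3)
  Qr <- Qr / rowSums(Qr)
  pct <- vapply(seq(0.5, 0.95, by = 0.05), function(ct) {
    mean(classify_admixed(Qr, cutoff = ct)$individuals$admixed)
  }, numeric(1))
  expect_true(all(diff(pct) >= 0))
})

test_that("admixed fraction rises with the migration rate", {
  pcts <- vapply(c(0.0, 0.05, 0.15), function(m) {
    sim <- two_deme_sim(seed = 61, n_sample = 20, n_loci = 8, gens = 20, m = m)
    fit <- admixture_gibbs(sim$table, K = 2, burnin = 400, steps = 1600, seed = 2)
    mean(classify_admixed(fit$Q)$individuals$admixed)
  }, numeric(1))
  expect_gt(kendall_tau_b(c(0.0, 0.05, 0.15), pcts + c(1e-9, 0, 2e-9))$tau, 0)
})

test_that("progressive partitioning splits structured samples and stops on panmixia", {
  # one random-mating deme: the root stays a leaf
  cfg <- sim_config(n_demes = 1, deme_names = "P", centroids = rbind(c(0, 0)),
                    epochs = list(list(gens = 8, N = 60, m = 0)),
                    n_loci = 8, founder_alleles = 6, founder_pool_size = 8,
                    sampling = tibble::tibble(generation = 8, time_point = "t",
                                              year = 2000L, n = list(30)),
                    record_truth = FALSE)
  simp <- simulate_population(cfg, seed = 3)
  tree <- progressive_partition(simp$table, replicates = 3, burnin = 300,
                                steps = 1200, seed = 7)
  expect_true(tree$leaf)
  # two diverged demes: the top split recovers the demes
  sim2 <- two_deme_sim(seed = 37, n_sample = 15, n_loci = 8)
  tree2 <- progressive_partition(sim2$table, replicates = 5, burnin = 300,
                                 steps = 1200, seed = 7)
  expect_false(tree2$leaf)
  expect_gt(tree2$theta, 0.05)
  truth <- stats::setNames(tibble::as_tibble(sim2$table)$region, sim2$table$id)
  left_regions <- table(truth[tree2$left$ids])
  right_regions <- table(truth[tree2$right$ids])
  agreement <- (max(left_regions) + max(right_regions)) / length(truth)
  expect_gte(agreement, 0.95)
})

test_that("progressive partitioning recovers a two-pair hierarchy", {
  # four demes: high migration inside pairs, none between pairs
  M1 <- matrix(0, 4, 4)
  M1[1, 2] <- M1[2, 1] <- M1[3, 4] <- M1[4, 3] <- 0.15
  diag(M1) <- 1 - rowSums(M1)
  cfg <- sim_config(
    n_demes = 4, deme_names = c("A1", "A2", "B1", "B2"),
    centroids = cbind(c(0, 50, 300, 350), c(0, 50, 300, 350)),
    epochs = list(list(gens = 22, N = 40, m = M1),
                  list(gens = 16, N = 40, m = 0)),
    n_loci = 12, founder_alleles = 6, founder_pool_size = 8,
    sampling = tibble::tibble(generation = 38, time_point = "t", year = 2000L,
                              n = list(15)),
    record_truth = FALSE
  )
  sim <- simulate_population(cfg, seed = 101)
  tree <- progressive_partition(sim$table, replicates = 5, burnin = 400,
                                steps = 1600, seed = 5, min_n = 10)
  expect_false(tree$leaf)
  # first split separates the A pair from the B pair
  super <- function(ids) substr(ids, 1, 1)
  mis_left <- sum(super(tree$left$ids) != names(which.max(table(super(tree$left$ids)))))
  mis_right <- sum(super(tree$right$ids) != names(which.max(table(super(tree$right$ids)))))
  expect_lte(mis_left + mis_right, 6)
  # and the pairs split again into their demes
  leaves <- partition_leaves(tree)
  expect_gte(dplyr::n_distinct(leaves$leaf), 3)
})

test_that("BIC-guided discriminant clustering matches the admixture clusters", {
  # two demes with fixed differences at most loci: unambiguous K = 2
  withr::with_seed(6, {
    n <- 30
    cols <- list(id = sprintf("i%02d", 1:(2 * n)))
    for (l in 1:6) {  # fixed inter-deme difference
      cols[[paste0("F", l, ".1")]] <- rep(c(100L, 110L), each = n)
      cols[[paste0("F", l, ".2")]] <- rep(c(100L, 110L), each = n)
    }
    for (l in 1:8) {  # shared multi-allelic polymorphism (within-deme noise)
      a <- sample(c(120L, 122L, 124L, 126L), 2 * n, TRUE)
      b <- sample(c(120L, 122L, 124L, 126L), 2 * n, TRUE)
      cols[[paste0("P", l, ".1")]] <- pmin(a, b)
      cols[[paste0("P", l, ".2")]] <- pmax(a, b)
    }
    gt_fixed <- genotype_table(tibble::as_tibble(cols))
  })
  dl <- dapc_lite(gt_fixed, k_range = 1:6, seed = 2)
  expect_equal(dl$best_k, 2)
  # agreement with the admixture model's hard assignments on simulated demes
  sim <- two_deme_sim(seed = 43, n_sample = 25, n_loci = 8)
  gt <- sim$table
  dl2 <- dapc_lite(gt, k_range = 2, seed = 2)
  fit <- admixture_gibbs(gt, K = 2, burnin = 400, steps = 1600, seed = 2)
  hard_g <- max.col(fit$Q)
  hard_d <- dl2$assignments$cluster
  agreement <- max(mean(hard_g == hard_d), mean(hard_g == 3 - hard_d))
  expect_gte(agreement, 0.95)
  # extremes run without error
  expect_no_error(dapc_lite(gt, k_range = c(1, nrow(gt) - 1), seed = 2))
})

test_that("tidy and glance summarise admixture fits", {
  sim <- two_deme_sim(seed = 3, n_sample = 8, n_loci = 4)
  fit <- admixture_gibbs(sim$table, K = 2, burnin = 200, steps = 800, seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), nrow(sim$table) * 2)
  expect_true(all(c("id", "cluster", "q") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$K, 2L)
  expect_lt(gl$ln_pd, 0)
  # CLUMPP export writes one row per individual per run
  path <- withr::local_tempfile(fileext = ".txt")
  write_clumpp(list(fit, fit), path)
  expect_equal(sum(grepl(":", readLines(path))), 2 * nrow(sim$table))
})
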