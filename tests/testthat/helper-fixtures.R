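# Shared fixtures and independent oracles, all built in code.

# small deterministic genotype table
tiny_gt <- function() {
  genotype_table(tibble::tibble(
    id = c("a", "b", "c", "d"),
    year = c(1994L, 1999L, 2004L, 2004L),
    region = c("N", "N", "S", "S"),
    x = c(5, 25, 45, 46), y = c(5, 6, 7, 8),
    sex = c("M", "F", "M", "F"), age_class = "adult",
    L1.1 = c(100L, 100L, 102L, 104L), L1.2 = c(100L, 102L, 102L, 104L),
    L2.1 = c(120L, 122L, 120L, NA), L2.2 = c(120L, 122L, 124L, NA)
  ))
}

# one group of n individuals drawn at Hardy-Weinberg proportions
hw_group <- function(n, freqs_by_locus, seed, prefix = "i") {
  withr::with_seed(seed, {
    cols <- list(id = paste0(prefix, seq_len(n)))
    for (l in seq_along(freqs_by_locus)) {
      p <- freqs_by_locus[[l]]
      alleles <- as.integer(100 + 2 * seq_along(p))
      cols[[paste0("L", l, ".1")]] <- sample(alleles, n, TRUE, p)
      cols[[paste0("L", l, ".2")]] <- sample(alleles, n, TRUE, p)
    }
    genotype_table(tibble::as_tibble(cols))
  })
}

# quick two-deme divergence scenario with one sampling point
two_deme_sim <- function(seed, n_sample = 25, gens = 18, n_loci = 8, m = 0) {
  cfg <- sim_config(
    n_demes = 2, deme_names = c("A", "B"),
    centroids = rbind(c(100, 100), c(300, 300)),
    epochs = list(list(gens = gens, N = 40, m = m)),
    n_loci = n_loci, founder_alleles = 6, founder_pool_size = 8,
    sampling = tibble::tibble(generation = gens, time_point = "t1",
                              year = 2000L, n = list(n_sample)),
    record_truth = FALSE
  )
  simulate_population(cfg, seed)
}

# exhaustive-enumeration oracle for rarefied allelic richness: mean number
# of distinct alleles over all subsets of g gene copies
ar_enum <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2, function(ix) length(unique(copies[ix]))))
}

# independent Weir-Cockerham oracle via the nested ANOVA of allele
# indicator variables (mean-squares route, distinct from the
# variance-component formulas used in the package)
wc_theta_anova <- function(x, grouping, by = "stg") {
  tab <- tibble::as_tibble(x)
  key <- stats::setNames(grouping[[by]], grouping$id)
  num <- 0; den <- 0
  for (loc in gt_loci(x)) {
    a1 <- tab[[paste0(loc, ".1")]]; a2 <- tab[[paste0(loc, ".2")]]
    grp <- unname(key[tab$id])
    ok <- !is.na(a1) & !is.na(grp)
    if (!any(ok)) next
    alleles <- unique(c(a1[ok], a2[ok]))
    pops <- unique(grp[ok])
    n_i <- as.vector(table(factor(grp[ok], levels = pops)))
    r <- length(pops); ntot <- sum(n_i)
    if (r < 2) next
    n_c <- (ntot - sum(n_i^2) / ntot) / (r - 1)
    for (al in alleles) {
      y <- rbind(as.numeric(a1[ok] == al), as.numeric(a2[ok] == al))  # 2 x n
      ybar_ind <- colMeans(y)
      pop_f <- factor(grp[ok], levels = pops)
      ybar_pop <- tapply(ybar_ind, pop_f, mean)
      ybar_all <- mean(y)
      ss_g <- sum((t(y) - ybar_ind)^2)
      ss_i <- 2 * sum((ybar_ind - ybar_pop[pop_f])^2)
      ss_p <- 2 * sum(n_i * (ybar_pop - ybar_all)^2)
      msg <- ss_g / ntot
      msi <- ss_i / (ntot - r)
      msp <- ss_p / (r - 1)
      s2_g <- msg
      s2_i <- (msi - msg) / 2
      s2_p <- (msp - msi) / (2 * n_c)
      num <- num + s2_p
      den <- den + s2_p + s2_i + s2_g
    }
  }
  num / den
}

# tie-corrected Kruskal-Wallis statistic computed from first principles
kw_oracle <- function(values, groups) {
  rk <- rank(values)
  N <- length(values)
  h <- 12 / (N * (N + 1)) * sum(tapply(rk, groups, function(r) length(r) * mean(r)^2)) -
    3 * (N + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}
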