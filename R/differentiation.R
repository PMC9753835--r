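#' @useDynLib popgenmon, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data .env
NULL

# Per-locus encodings used by the F-statistic engines: for locus l,
# dosage D (n x k alleles, copies of each allele carried) and het-carrier
# indicator H (1 if the individual is heterozygous and carries the allele).
locus_codes <- function(x) {
  loci <- gt_loci(x)
  tab <- tibble::as_tibble(x)
  purrr::map(stats::setNames(loci, loci), function(loc) {
    a <- tab[[paste0(loc, ".1")]]; b <- tab[[paste0(loc, ".2")]]
    alleles <- sort(unique(stats::na.omit(c(a, b))))
    k <- length(alleles)
    n <- length(a)
    D <- matrix(0L, n, k, dimnames = list(NULL, alleles))
    ai <- match(a, alleles); bi <- match(b, alleles)
    ok <- which(!is.na(ai))
    for (i in ok) {
      D[i, ai[i]] <- D[i, ai[i]] + 1L
      D[i, bi[i]] <- D[i, bi[i]] + 1L
    }
    H <- matrix(0L, n, k)
    het <- ok[a[ok] != b[ok]]
    H[cbind(rep(het, 2), c(ai[het], bi[het]))] <- 1L
    list(D = D, H = H, typed = !is.na(a), alleles = alleles)
  })
}

# Weir-Cockerham (1984) variance components summed over alleles for one
# locus, given per-group size n_i, allele frequencies p (groups x alleles)
# and het-carrier frequencies h (groups x alleles). Returns c(a, b, c).
wc_locus_components <- function(n_i, p, h) {
  r <- length(n_i)
  nbar <- mean(n_i)
  if (nbar <= 1) return(c(0, 0, 0))
  n_c <- if (r > 1) (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1) else nbar
  w <- n_i / (r * nbar)
  pbar <- colSums(w * p)
  hbar <- colSums(w * h)
  s2 <- if (r > 1) colSums(n_i * (p - rep(pbar, each = r))^2) / ((r - 1) * nbar) else rep(0, ncol(p))
  if (r > 1) {
    a <- (nbar / n_c) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  } else {
    a <- rep(0, length(pbar))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - hbar * (2 * nbar - 1) / (4 * nbar))
  }
  cc <- hbar / 2
  c(sum(a), sum(b), sum(cc))
}

# components for every locus given integer group assignment z (NA = out)
wc_components <- function(codes, z) {
  groups <- sort(unique(z[!is.na(z)]))
  out <- matrix(0, length(codes), 3, dimnames = list(names(codes), c("a", "b", "c")))
  for (li in seq_along(codes)) {
    cd <- codes[[li]]
    use <- cd$typed & !is.na(z)
    if (!any(use)) next
    zi <- factor(z[use], levels = groups)
    n_i <- as.vector(table(zi))
    keep <- n_i > 0
    counts <- rowsum(cd$D[use, , drop = FALSE], zi)
    hets <- rowsum(cd$H[use, , drop = FALSE], zi)
    n_i <- n_i[keep]
    p <- counts[keep, , drop = FALSE] / (2 * n_i)
    h <- hets[keep, , drop = FALSE] / n_i
    if (length(n_i) == 0 || all(n_i < 1)) next
    out[li, ] <- wc_locus_components(n_i, p, h)
  }
  out
}

#' Weir-Cockerham multilocus theta between groups
#'
#' The 1984 analysis-of-variance estimator of F_ST: per-locus, per-allele
#' variance components for among-group (a), among-individual-within-group
#' (b) and within-individual (c) variation, combined across alleles and loci
#' as `theta = sum(a) / sum(a + b + c)`. Negative estimates are reported as
#' computed.
#'
#' @param x A [genotype_table()].
#' @param grouping Grouping tibble; only individuals assigned to the listed
#'   groups enter.
#' @param by Grouping column (default `"stg"`).
#' @return List with `theta` (multilocus), `per_locus` tibble and the summed
#'   components.
#' @export
wc_theta <- function(x, grouping, by = "stg") {
  codes <- locus_codes(x)
  key <- stats::setNames(grouping[[by]], grouping$id)
  z <- unname(key[tibble::as_tibble(x)$id])
  if (dplyr::n_distinct(z[!is.na(z)]) < 2) rlang::abort("wc_theta needs >= 2 groups")
  comp <- wc_components(codes, z)
  denom <- sum(comp)
  if (denom == 0) rlang::abort("all loci monomorphic across groups; theta undefined")
  list(
    theta = sum(comp[, "a"]) / denom,
    per_locus = tibble::tibble(
      locus = rownames(comp), a = comp[, "a"], b = comp[, "b"], c = comp[, "c"],
      theta = ifelse(rowSums(comp) == 0, NA_real_, comp[, "a"] / rowSums(comp))
    ),
    components = colSums(comp)
  )
}

#' Permutation test of differentiation between two groups
#'
#' Individuals are permuted between the two groups; the p-value is
#' `(1 + #{theta_perm >= theta_obs}) / (n_perm + 1)`.
#'
#' @param x A [genotype_table()].
#' @param grouping Grouping restricted to exactly two groups.
#' @param by Grouping column.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Tibble `theta`, `p`, `n_perm`.
#' @export
fst_permutation_test <- function(x, grouping, by = "stg", n_perm = 1000, seed = 1) {
  codes <- locus_codes(x)
  key <- stats::setNames(grouping[[by]], grouping$id)
  z <- unname(key[tibble::as_tibble(x)$id])
  groups <- unique(z[!is.na(z)])
  if (length(groups) != 2) rlang::abort("fst_permutation_test needs exactly 2 groups")
  if (any(table(z) < 2)) rlang::abort("groups of size < 2 cannot be permuted meaningfully")
  obs_comp <- wc_components(codes, z)
  theta_obs <- sum(obs_comp[, "a"]) / sum(obs_comp)
  idx <- which(!is.na(z))
  hits <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      zp <- z
      zp[idx] <- sample(z[idx])
      comp <- wc_components(codes, zp)
      sum(comp[, "a"]) / sum(comp) >= theta_obs
    }, logical(1)))
  })
  tibble::tibble(theta = theta_obs, p = (1 + hits) / (n_perm + 1), n_perm = n_perm)
}

#' Pairwise theta matrix with permutation p-values
#'
#' @inheritParams fst_permutation_test
#' @param grouping Grouping tibble with any number of groups.
#' @param min_n Groups smaller than this are skipped (reported `NA`).
#' @return List with `pairs` tibble (`group1`, `group2`, `theta`, `p`),
#'   symmetric matrices `theta` and `p`, and `n_perm`.
#' @export
pairwise_fst <- function(x, grouping, by = "stg", n_perm = 1000, seed = 1, min_n = 2) {
  sizes <- table(grouping[[by]])
  groups <- names(sizes)[sizes >= min_n]
  pairs <- utils::combn(groups, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    sub <- grouping[grouping[[by]] %in% c(g1, g2), ]
    pt <- fst_permutation_test(x, sub, by = by, n_perm = n_perm,
                               seed = seed + j)
    tibble::tibble(group1 = g1, group2 = g2, theta = pt$theta, p = pt$p)
  })
  th <- matrix(NA_real_, length(groups), length(groups), dimnames = list(groups, groups))
  pm <- th
  for (j in seq_len(nrow(res))) {
    th[res$group1[j], res$group2[j]] <- th[res$group2[j], res$group1[j]] <- res$theta[j]
    pm[res$group1[j], res$group2[j]] <- pm[res$group2[j], res$group1[j]] <- res$p[j]
  }
  diag(th) <- 0
  list(pairs = res, theta = th, p = pm, n_perm = n_perm)
}

# AMOVA sums of squares at one locus from per-group allele counts under the
# allele-identity ("number of different alleles") distance
amova_locus_ssd <- function(counts, het_by_group, n_by_group) {
  gp <- rowSums(counts)
  tot <- colSums(counts)
  Gt <- sum(gp)
  ssd_total <- (Gt^2 - sum(tot^2)) / (2 * Gt)
  ssd_wp <- sum((gp^2 - rowSums(counts^2)) / (2 * gp))
  ssd_wi <- sum(het_by_group) / 2
  c(ag = ssd_total - ssd_wp, ai = ssd_wp - ssd_wi, wi = ssd_wi)
}

amova_components <- function(codes, z) {
  groups <- sort(unique(z[!is.na(z)]))
  sig <- c(ag = 0, ai = 0, wi = 0)
  for (cd in codes) {
    use <- cd$typed & !is.na(z)
    zi <- factor(z[use], levels = groups)
    n_i <- as.vector(table(zi))
    keep <- n_i >= 1
    counts <- rowsum(cd$D[use, , drop = FALSE], zi)[keep, , drop = FALSE]
    hets <- rowSums(rowsum(cd$H[use, , drop = FALSE], zi)[keep, , drop = FALSE]) / 2
    n_i <- n_i[keep]
    P <- length(n_i)
    if (P < 2) next
    N <- sum(n_i)
    ssd <- amova_locus_ssd(counts, hets, n_i)
    df <- c(ag = P - 1, ai = N - P, wi = N)
    ms <- ssd / df
    n_c <- (N - sum(n_i^2) / N) / (P - 1)
    s_wi <- ms[["wi"]]
    s_ai <- (ms[["ai"]] - s_wi) / 2
    s_ag <- (ms[["ag"]] - ms[["ai"]]) / (2 * n_c)
    sig <- sig + c(ag = s_ag, ai = s_ai, wi = s_wi)
  }
  sig
}

#' Global AMOVA with individuals nested in groups
#'
#' Variance decomposition of allele-identity distances (0 if two gene copies
#' carry the same allele, 1 otherwise) into among-group, among-individual-
#' within-group and within-individual components. The reported global
#' fixation index is `Phi_ST = sigma_among / sigma_total`, with a
#' permutation p-value from shuffling individuals among groups.
#'
#' @inheritParams fst_permutation_test
#' @param min_n Groups with fewer individuals are excluded with a warning.
#' @return Tibble `phi_st`, `sigma_among`, `sigma_among_ind`,
#'   `sigma_within_ind`, `p`, `n_perm`, `n_groups`.
#' @export
amova_global <- function(x, grouping, by = "stg", n_perm = 1000, seed = 1, min_n = 2) {
  sizes <- table(grouping[[by]])
  small <- names(sizes)[sizes < min_n]
  if (length(small) > 0) {
    rlang::warn(paste0("groups excluded from AMOVA (n < ", min_n, "): ",
                       paste(small, collapse = ", ")))
    grouping <- grouping[!grouping[[by]] %in% small, ]
  }
  codes <- locus_codes(x)
  key <- stats::setNames(grouping[[by]], grouping$id)
  z <- unname(key[tibble::as_tibble(x)$id])
  if (dplyr::n_distinct(z[!is.na(z)]) < 2) rlang::abort("AMOVA needs >= 2 groups")
  sig <- amova_components(codes, z)
  phi <- sig[["ag"]] / sum(sig)
  idx <- which(!is.na(z))
  hits <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      zp <- z
      zp[idx] <- sample(z[idx])
      sp <- amova_components(codes, zp)
      sp[["ag"]] / sum(sp) >= phi
    }, logical(1)))
  })
  tibble::tibble(
    phi_st = phi, sigma_among = sig[["ag"]], sigma_among_ind = sig[["ai"]],
    sigma_within_ind = sig[["wi"]], p = (1 + hits) / (n_perm + 1),
    n_perm = n_perm, n_groups = dplyr::n_distinct(z[!is.na(z)])
  )
}

#' Exact test of Hardy-Weinberg proportions
#'
#' For loci with two alleles the p-value is computed by full enumeration of
#' the Levene conditional distribution of heterozygote counts; with more
#' alleles a Guo-Thompson Markov chain over genotype tables is used.
#'
#' @param genotypes Two-column matrix (or data frame) of the two allele
#'   sizes per individual; rows with missing values are dropped.
#' @param chain_steps,dememorisation Markov-chain lengths.
#' @param seed Integer seed for the chain.
#' @return Tibble `p`, `method` (`"enumeration"` or `"mcmc"`), `n`,
#'   `n_alleles`. Monomorphic input returns `p = 1` flagged as
#'   `"monomorphic"`.
#' @export
hwe_exact_test <- function(genotypes, chain_steps = 1e5, dememorisation = 1e4, seed = 1) {
  genotypes <- as.matrix(genotypes)
  ok <- stats::complete.cases(genotypes)
  genotypes <- genotypes[ok, , drop = FALSE]
  alleles <- sort(unique(as.vector(genotypes)))
  k <- length(alleles)
  n <- nrow(genotypes)
  if (k < 2) {
    return(tibble::tibble(p = 1, method = "monomorphic", n = n, n_alleles = k))
  }
  ai <- matrix(match(genotypes, alleles), ncol = 2)
  g <- matrix(0L, k, k)
  for (r in seq_len(n)) {
    i <- max(ai[r, ]); j <- min(ai[r, ])
    g[i, j] <- g[i, j] + 1L
  }
  if (k == 2) {
    p <- hwe_enumerate_2allele(nAA = g[1, 1], nAB = g[2, 1], nBB = g[2, 2])
    return(tibble::tibble(p = p, method = "enumeration", n = n, n_alleles = k))
  }
  p <- withr::with_seed(seed, .hwe_mcmc_cpp(g, as.integer(chain_steps),
                                            as.integer(dememorisation)))
  tibble::tibble(p = p, method = "mcmc", n = n, n_alleles = k)
}

# Levene conditional distribution of the heterozygote count for 2 alleles
hwe_enumerate_2allele <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- vapply(hs, function(h) {
    naa <- (nA - h) / 2
    nbb <- n - naa - h
    lgamma(n + 1) - lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(2 * n - nA + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(nAB, hs)] * (1 + 1e-9)])
}

#' Composite linkage-disequilibrium permutation test for a locus pair
#'
#' The statistic is a Burrows-type composite measure: the sum over allele
#' pairs of `n * r^2`, where `r` is the correlation across individuals of
#' allele dosages at the two loci (valid without assuming HWE). The null
#' distribution permutes one locus's genotypes across individuals.
#'
#' @param x A [genotype_table()].
#' @param locus1,locus2 Locus names.
#' @param ids Optional subset of individual ids (e.g. one group).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Tibble `statistic`, `p`, `n`, `n_perm`.
#' @export
ld_permutation_test <- function(x, locus1, locus2, ids = NULL, n_perm = 1000, seed = 1) {
  tab <- tibble::as_tibble(x)
  if (!is.null(ids)) tab <- tab[tab$id %in% ids, , drop = FALSE]
  a <- cbind(tab[[paste0(locus1, ".1")]], tab[[paste0(locus1, ".2")]])
  b <- cbind(tab[[paste0(locus2, ".1")]], tab[[paste0(locus2, ".2")]])
  ok <- stats::complete.cases(a) & stats::complete.cases(b)
  a <- a[ok, , drop = FALSE]; b <- b[ok, , drop = FALSE]
  n <- nrow(a)
  if (n < 5) rlang::warn("fewer than 5 individuals for LD test")
  dose <- function(m) {
    al <- sort(unique(as.vector(m)))
    if (length(al) < 2) rlang::abort("locus monomorphic in subset; LD undefined")
    sapply(al, function(s) rowSums(m == s))
  }
  da <- dose(a); db <- dose(b)
  stat <- function(da, db) {
    r <- suppressWarnings(stats::cor(da, db))
    r[is.na(r)] <- 0
    n * sum(r^2)
  }
  obs <- stat(da, db)
  hits <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) stat(da, db[sample.int(n), , drop = FALSE]) >= obs,
               logical(1)))
  })
  tibble::tibble(statistic = obs, p = (1 + hits) / (n_perm + 1), n = n, n_perm = n_perm)
}

#' Within-group inbreeding coefficient (Weir-Cockerham f)
#'
#' Single-group case of the 1984 variance components:
#' `f = 1 - sum(c) / sum(b + c)` over loci and alleles, measuring the
#' heterozygote deficit relative to Hardy-Weinberg proportions.
#'
#' @param x A [genotype_table()].
#' @param ids Ids of the group members (default: all rows).
#' @return Tibble `fis`, `n`, `n_loci_used`.
#' @export
fis_estimate <- function(x, ids = NULL) {
  tab <- tibble::as_tibble(x)
  if (is.null(ids)) ids <- tab$id
  z <- ifelse(tab$id %in% ids, "g", NA_character_)
  if (sum(!is.na(z)) < 2) rlang::abort("fis_estimate needs n >= 2")
  comp <- wc_components(locus_codes(x), z)
  denom <- sum(comp[, "b"] + comp[, "c"])
  if (denom == 0) rlang::abort("all loci monomorphic; F_IS undefined")
  tibble::tibble(fis = 1 - sum(comp[, "c"]) / denom, n = sum(!is.na(z)),
                 n_loci_used = sum(rowSums(comp) != 0))
}

# multilocus Weir-Cockerham f from per-locus allele-code vectors
# (a[i], b[i] = the two 1-based codes of individual i; NA = missing)
fis_from_codes <- function(a_list, b_list, k_list) {
  bsum <- 0; csum <- 0
  for (l in seq_along(a_list)) {
    a <- a_list[[l]]; b <- b_list[[l]]
    ok <- !is.na(a)
    a <- a[ok]; b <- b[ok]
    n <- length(a)
    if (n < 2) next
    k <- k_list[[l]]
    p <- tabulate(c(a, b), k) / (2 * n)
    het <- a != b
    h <- tabulate(c(a[het], b[het]), k) / n
    bl <- (n / (n - 1)) * (p * (1 - p) - h * (2 * n - 1) / (4 * n))
    bsum <- bsum + sum(bl)
    csum <- csum + sum(h / 2)
  }
  1 - csum / (bsum + csum)
}

#' Significance of F_IS per group
#'
#' Two testing routes: `"permutation"` shuffles alleles among individuals
#' within the group at each locus (destroying departures from random mating
#' while keeping allele frequencies), giving a two-sided p on `|f|`;
#' `"t"` treats per-locus f estimates as replicates in a one-sample t test
#' against zero.
#'
#' @param x A [genotype_table()].
#' @param grouping Grouping tibble.
#' @param by Grouping column.
#' @param method `"permutation"` (default) or `"t"`.
#' @param n_perm Permutations per group.
#' @param seed Integer seed.
#' @return Tibble `group`, `n`, `fis`, `p`.
#' @export
fis_significance <- function(x, grouping, by = "stg",
                             method = c("permutation", "t"),
                             n_perm = 1000, seed = 1) {
  method <- match.arg(method)
  tab <- tibble::as_tibble(x)
  loci <- gt_loci(x)
  groups <- split(grouping$id, grouping[[by]])
  purrr::imap_dfr(groups, function(ids, gname) {
    sub <- tab[tab$id %in% ids, , drop = FALSE]
    subx <- genotype_table(sub, loci = loci)
    if (method == "t") {
      comp <- wc_components(locus_codes(subx), rep("g", nrow(sub)))
      f_loc <- 1 - comp[, "c"] / (comp[, "b"] + comp[, "c"])
      f_loc <- f_loc[is.finite(f_loc)]
      p <- if (length(f_loc) < 2 || stats::sd(f_loc) == 0) {
        rlang::warn("degenerate per-locus f distribution; t test replaced by sign of mean")
        if (isTRUE(all.equal(mean(f_loc), 0))) 1 else 0
      } else {
        stats::t.test(f_loc, mu = 0)$p.value
      }
      return(tibble::tibble(group = gname, n = nrow(sub),
                            fis = fis_estimate(subx)$fis, p = p))
    }
    # precompute per-locus allele codes once; permutations shuffle codes only
    a_list <- list(); b_list <- list(); k_list <- list()
    for (loc in loci) {
      a <- sub[[paste0(loc, ".1")]]; b <- sub[[paste0(loc, ".2")]]
      alleles <- sort(unique(stats::na.omit(c(a, b))))
      a_list[[loc]] <- match(a, alleles)
      b_list[[loc]] <- match(b, alleles)
      k_list[[loc]] <- length(alleles)
    }
    obs <- fis_from_codes(a_list, b_list, k_list)
    hits <- withr::with_seed(seed + nrow(sub), {
      sum(vapply(seq_len(n_perm), function(i) {
        ap <- a_list; bp <- b_list
        for (loc in loci) {
          typed <- which(!is.na(a_list[[loc]]))
          pool <- sample(c(a_list[[loc]][typed], b_list[[loc]][typed]))
          nt <- length(typed)
          ap[[loc]][typed] <- pool[seq_len(nt)]
          bp[[loc]][typed] <- pool[nt + seq_len(nt)]
        }
        abs(fis_from_codes(ap, bp, k_list)) >= abs(obs)
      }, logical(1)))
    })
    tibble::tibble(group = gname, n = nrow(sub), fis = obs,
                   p = (1 + hits) / (n_perm + 1))
  })
}

#' Benjamini-Hochberg significance flags for a family of F_IS tests
#'
#' @param p Vector of per-group p-values.
#' @param q False-discovery rate (default 0.05).
#' @return Tibble `p`, `p_adj`, `significant`.
#' @export
fis_fdr <- function(p, q = 0.05) {
  adj <- stats::p.adjust(p, method = "BH")
  tibble::tibble(p = p, p_adj = adj, significant = adj < q)
}

#' Two-stage Wahlund-vs-inbreeding classification for one group
#'
#' A significant heterozygote deficit in a pooled sample can reflect either
#' inbreeding or the pooling of differentiated subgroups (the Wahlund
#' effect). The disambiguation recomputes F_IS using only members of the
#' group's dominant genetic cluster: if the deficit disappears the original
#' signal is attributed to substructure (`"w"`), if it persists to
#' inbreeding (`"i"`).
#'
#' @param x A [genotype_table()].
#' @param ids Group member ids.
#' @param Q Ancestry-proportion matrix for `ids` (rows in the same order),
#'   from [admixture_gibbs()] at the group's best K.
#' @param n_perm,seed Permutation settings for the significance tests.
#' @param alpha Significance level applied to both stages.
#' @return Tibble `fis1`, `p1`, `fis2`, `p2`, `n_dominant`, `classification`
#'   in `{"none", "w", "i", "indeterminate"}`.
#' @export
wahlund_two_stage <- function(x, ids, Q, n_perm = 500, seed = 1, alpha = 0.05) {
  stopifnot(nrow(Q) == length(ids))
  grouping_all <- tibble::tibble(id = ids, stg = "g")
  s1 <- fis_significance(x, grouping_all, n_perm = n_perm, seed = seed)
  hard <- max.col(Q)
  dominant <- as.integer(names(which.max(table(hard))))
  members <- ids[hard == dominant]
  if (length(members) < 4) {
    return(tibble::tibble(
      fis1 = s1$fis, p1 = s1$p, fis2 = NA_real_, p2 = NA_real_,
      n_dominant = length(members), classification = "indeterminate"
    ))
  }
  s2 <- fis_significance(x, tibble::tibble(id = members, stg = "g"),
                         n_perm = n_perm, seed = seed + 1)
  cls <- if (s1$p >= alpha) "none"
         else if (s2$p >= alpha) "w"
         else "i"
  tibble::tibble(fis1 = s1$fis, p1 = s1$p, fis2 = s2$fis, p2 = s2$p,
                 n_dominant = length(members), classification = cls)
}
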