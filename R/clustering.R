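#' Fit the Bayesian admixture model by Gibbs sampling
#'
#' A STRUCTURE-type model: each individual has ancestry proportions `Q`
#' over `K` clusters; each cluster has its own allele frequencies `P` at
#' every locus; each observed gene copy originates from a cluster drawn
#' from `Q` and an allele drawn from that cluster's frequencies. Origins,
#' `P` (Dirichlet full conditionals) and `Q` are Gibbs-updated; the shared
#' admixture parameter `alpha` (uniform(0,10) prior) and, under the
#' correlated-frequency prior, per-cluster drift parameters `F`
#' (uniform(0,1) prior) move by Metropolis steps. The correlated prior
#' shrinks cluster frequencies towards the pooled sample frequencies with
#' strength `(1-F)/F`, which helps at weak divergence. Missing genotypes
#' are skipped in the likelihood.
#'
#' @param x A [genotype_table()].
#' @param K Number of clusters (>= 1).
#' @param burnin,steps Chain lengths. The defaults are desk-scale; raise
#'   them (e.g. 1e5/1e6) for publication runs.
#' @param seed Integer seed; the fit is reproducible given the seed.
#' @param prior `"correlated"` (default) or `"independent"` allele
#'   frequency prior.
#' @param lambda Dirichlet parameter of the independent prior.
#' @param alpha_init Initial admixture parameter.
#' @return An `admixture_fit`: list with `K`, `Q` (N x K posterior means,
#'   rows named by id), `P` (per-locus cluster allele frequencies), `lnl`
#'   trace, `ln_pd` (model pseudo-evidence `mean(lnL) - var(lnL)/2` used
#'   for K selection), `alpha`, `F`, `seed`, `prior`.
#' @export
admixture_gibbs <- function(x, K, burnin = 1e4, steps = 5e4, seed = 1,
                            prior = c("correlated", "independent"),
                            lambda = 1, alpha_init = 1) {
  prior <- match.arg(prior)
  stopifnot(K >= 1)
  codes <- locus_codes(x)
  loci <- gt_loci(x)
  tab <- tibble::as_tibble(x)
  N <- nrow(tab)
  L <- length(loci)
  n_alleles <- vapply(codes, function(cd) length(cd$alleles), integer(1))
  maxA <- max(n_alleles)
  geno <- matrix(-1L, N, 2 * L)
  p_anc <- matrix(0, L, maxA)
  for (l in seq_len(L)) {
    cd <- codes[[l]]
    a <- tab[[paste0(loci[l], ".1")]]; b <- tab[[paste0(loci[l], ".2")]]
    geno[, 2 * l - 1] <- ifelse(is.na(a), -1L, match(a, cd$alleles) - 1L)
    geno[, 2 * l] <- ifelse(is.na(b), -1L, match(b, cd$alleles) - 1L)
    cnt <- colSums(cd$D)
    p_anc[l, seq_len(n_alleles[l])] <- (cnt + lambda) / (sum(cnt) + lambda * n_alleles[l])
  }
  if (K == 1) {
    # closed form: every copy originates from the single cluster
    P <- purrr::map(seq_len(L), function(l) {
      cnt <- colSums(codes[[l]]$D)
      matrix(cnt / sum(cnt), 1, dimnames = list(NULL, codes[[l]]$alleles))
    })
    lnl <- sum(purrr::map_dbl(seq_len(L), function(l) {
      cnt <- colSums(codes[[l]]$D)
      sum(cnt * log(cnt / sum(cnt)))
    }))
    fit <- list(K = 1L, Q = matrix(1, N, 1, dimnames = list(tab$id, NULL)),
                P = stats::setNames(P, loci), lnl = lnl, ln_pd = lnl,
                alpha = NA_real_, F = NA_real_, seed = seed, prior = prior)
    class(fit) <- "admixture_fit"
    return(fit)
  }
  res <- withr::with_seed(seed, .admixture_gibbs_cpp(
    geno, n_alleles, as.integer(K), as.integer(burnin), as.integer(steps),
    alpha_init, prior == "correlated", p_anc, lambda, 0.05, 0.05
  ))
  n_distinct_geno <- nrow(unique(as.data.frame(geno)))
  if (K > n_distinct_geno) {
    rlang::warn("K exceeds the number of distinct multilocus genotypes")
  }
  lnl <- res$lnl
  half <- length(lnl) %/% 2
  if (abs(mean(lnl[seq_len(half)]) - mean(lnl[-seq_len(half)])) > 2 * stats::sd(lnl)) {
    rlang::warn("log-likelihood trend between chain halves; consider longer burn-in")
  }
  rownames(res$Q) <- tab$id
  P <- purrr::map(seq_len(L), function(l) {
    pm <- res$P[[l]]
    colnames(pm) <- codes[[l]]$alleles
    pm
  })
  fit <- list(K = as.integer(K), Q = res$Q, P = stats::setNames(P, loci),
              lnl = lnl, ln_pd = mean(lnl) - stats::var(lnl) / 2,
              alpha = res$alpha, F = res$F, seed = seed, prior = prior)
  class(fit) <- "admixture_fit"
  fit
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("Admixture model fit: K =", x$K, ", N =", nrow(x$Q),
      ", prior =", x$prior, "\n")
  cat("ln P(D) ~", format(x$ln_pd, digits = 6), "; alpha =",
      format(x$alpha, digits = 3), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy ancestry proportions of an admixture fit
#'
#' @param x An `admixture_fit`.
#' @param ... Unused.
#' @return Tibble `id`, `cluster`, `q`.
#' @export
tidy.admixture_fit <- function(x, ...) {
  Q <- x$Q
  colnames(Q) <- paste0("V", seq_len(ncol(Q)))
  tibble::as_tibble(Q, rownames = "id") |>
    tidyr::pivot_longer(-"id", names_to = "cluster", values_to = "q") |>
    dplyr::mutate(cluster = as.integer(sub("^V", "", .data$cluster)))
}

#' One-row model summary of an admixture fit
#'
#' @param x An `admixture_fit`.
#' @param ... Unused.
#' @return Tibble `K`, `ln_pd`, `mean_lnl`, `sd_lnl`, `alpha`.
#' @export
glance.admixture_fit <- function(x, ...) {
  tibble::tibble(K = x$K, ln_pd = x$ln_pd, mean_lnl = mean(x$lnl),
                 sd_lnl = stats::sd(x$lnl), alpha = x$alpha)
}

# exact bipartite assignment maximizing total similarity (Hungarian for
# small K via exhaustive search, greedy beyond)
best_permutation <- function(sim) {
  K <- nrow(sim)
  if (K <= 8) {
    perms <- permutations_of(K)
    scores <- vapply(perms, function(p) sum(sim[cbind(seq_len(K), p)]), numeric(1))
    perms[[which.max(scores)]]
  } else {
    p <- integer(K)
    taken <- rep(FALSE, K)
    ord <- order(apply(sim, 1, max), decreasing = TRUE)
    for (i in ord) {
      j <- which.max(replace(sim[i, ], taken, -Inf))
      p[i] <- j; taken[j] <- TRUE
    }
    p
  }
}

permutations_of <- function(K) {
  if (K == 1) return(list(1L))
  sub <- permutations_of(K - 1L)
  out <- list()
  for (p in sub) for (pos in 0:(K - 1L)) {
    out[[length(out) + 1L]] <- append(p, K, after = pos)
  }
  out
}

#' Align replicate admixture runs and identify modes
#'
#' Replicate fits at the same K are label-switched; each run's cluster
#' labels are permuted to maximize the summed column-wise correlation of
#' its Q matrix with the first run's. Runs are then grouped into modes
#' (major/minor) by single-linkage on mean aligned Q correlation at
#' `mode_threshold`, and a per-mode average Q is returned.
#'
#' @param fits List of `admixture_fit` objects at the same K (>= 2).
#' @param mode_threshold Similarity threshold for two runs to share a mode.
#' @return List with `Q_avg` (average over the major mode), `modes`
#'   (integer mode id per run, 1 = major), `aligned` (list of permuted Q
#'   matrices), `similarity` (run x run mean aligned correlation).
#' @export
align_runs <- function(fits, mode_threshold = 0.9) {
  stopifnot(length(fits) >= 2)
  K <- fits[[1]]$K
  stopifnot(all(vapply(fits, function(f) f$K, integer(1)) == K))
  ref <- fits[[1]]$Q
  aligned <- purrr::map(fits, function(f) {
    if (K == 1) return(f$Q)
    sim <- suppressWarnings(stats::cor(ref, f$Q))
    sim[is.na(sim)] <- 0
    p <- best_permutation(t(sim))  # p[j]: reference column for run column j
    out <- f$Q
    out[, p] <- f$Q
    out
  })
  R <- length(fits)
  simmat <- matrix(1, R, R)
  for (i in seq_len(R - 1)) for (j in (i + 1):R) {
    cs <- vapply(seq_len(K), function(k) {
      suppressWarnings(stats::cor(aligned[[i]][, k], aligned[[j]][, k]))
    }, numeric(1))
    cs[is.na(cs)] <- 1  # constant columns (e.g. K = 1) count as agreeing
    simmat[i, j] <- simmat[j, i] <- mean(cs)
  }
  g <- igraph::graph_from_adjacency_matrix(simmat >= mode_threshold, mode = "undirected")
  comp <- igraph::components(g)$membership
  sizes <- table(comp)
  ranks <- rank(-as.vector(sizes), ties.method = "first")
  modes <- ranks[comp]
  major <- which(modes == 1)
  Q_avg <- Reduce(`+`, aligned[major]) / length(major)
  list(Q_avg = Q_avg, modes = as.integer(modes), aligned = aligned,
       similarity = simmat)
}

#' Evanno delta-K from replicate log-likelihoods
#'
#' The second-difference statistic
#' `deltaK = |L(K+1) - 2 L(K) + L(K-1)| / sd(L(K))` over a contiguous K
#' range, where `L(K)` is the mean and `sd(L(K))` the standard deviation of
#' the model log-probability across replicate runs at K.
#'
#' @param summaries Tibble with columns `K`, `mean_lnl`, `sd_lnl` (one row
#'   per K), e.g. built from `glance()` of replicate fits.
#' @return The input with a `delta_k` column (`NA` at the range ends and
#'   where `sd = 0`).
#' @export
evanno_delta_k <- function(summaries) {
  s <- dplyr::arrange(summaries, .data$K)
  if (nrow(s) < 3) rlang::abort("delta-K needs >= 3 contiguous K values")
  if (any(diff(s$K) != 1)) rlang::abort("K range must be contiguous")
  L <- s$mean_lnl
  dk <- rep(NA_real_, nrow(s))
  for (i in 2:(nrow(s) - 1)) {
    if (is.na(s$sd_lnl[i]) || s$sd_lnl[i] == 0) next
    dk[i] <- abs(L[i + 1] - 2 * L[i] + L[i - 1]) / s$sd_lnl[i]
  }
  dplyr::mutate(s, delta_k = dk)
}

#' Classify individuals as admixed from ancestry proportions
#'
#' An individual is admixed when its largest ancestry proportion falls
#' below `cutoff` (i.e. no single cluster explains at least that much of
#' its genome).
#'
#' @param Q Ancestry matrix (rows sum to 1), row names = ids.
#' @param cutoff Assignment threshold (default 0.8).
#' @param time_points Optional vector of time-point labels per row for a
#'   per-time-point percentage summary.
#' @return List with `individuals` tibble (`id`, `max_q`, `admixed`) and,
#'   if `time_points` given, `by_time` (`time_point`, `n`, `pct_admixed`).
#' @export
classify_admixed <- function(Q, cutoff = 0.8, time_points = NULL) {
  maxq <- unname(apply(Q, 1, max))
  ind <- tibble::tibble(
    id = if (is.null(rownames(Q))) as.character(seq_len(nrow(Q))) else rownames(Q),
    max_q = maxq, admixed = maxq < cutoff
  )
  out <- list(individuals = ind)
  if (!is.null(time_points)) {
    out$by_time <- tibble::tibble(time_point = time_points, admixed = ind$admixed) |>
      dplyr::group_by(.data$time_point) |>
      dplyr::summarise(n = dplyr::n(), pct_admixed = 100 * mean(.data$admixed),
                       .groups = "drop")
  }
  out
}

#' Progressive binary partitioning of a sample
#'
#' Recursively fits the admixture model at K = 2; a split is accepted when
#' it is decisive -- both child clusters have at least `min_child` members
#' and the run-averaged largest assignment is at least `decisive_q` -- and
#' each child is then partitioned again. Individuals are assigned to a
#' child by majority (> `threshold`) average assignment. Leaves are the
#' final subpopulations.
#'
#' @param x A [genotype_table()].
#' @param ids Ids to partition (default all).
#' @param replicates Replicate K = 2 runs per split.
#' @param threshold Assignment threshold for child membership.
#' @param min_child Minimum child size for a split to be accepted.
#' @param decisive_q Minimum mean largest assignment for a split.
#' @param min_n Groups smaller than this are not considered for splitting.
#' @param burnin,steps,seed Chain settings.
#' @param max_depth Safety cap on recursion depth.
#' @return A nested list (the partition tree): each node has `ids`, `n`,
#'   and either `leaf = TRUE` or children `left`/`right` plus the
#'   between-child `theta` and a `stable` flag (replicate agreement).
#' @export
progressive_partition <- function(x, ids = NULL, replicates = 5,
                                  threshold = 0.5, min_child = 4,
                                  decisive_q = 0.6, min_n = 8,
                                  burnin = 2000, steps = 8000, seed = 1,
                                  max_depth = 6) {
  tab <- tibble::as_tibble(x)
  if (is.null(ids)) ids <- tab$id
  recurse <- function(ids, depth, seed) {
    node <- list(ids = ids, n = length(ids))
    if (length(ids) < min_n || depth >= max_depth) {
      node$leaf <- TRUE
      return(node)
    }
    sub <- genotype_table(tab[tab$id %in% ids, , drop = FALSE], loci = gt_loci(x))
    fits <- purrr::map(seq_len(replicates), function(r) {
      admixture_gibbs(sub, K = 2, burnin = burnin, steps = steps,
                      seed = seed + r)
    })
    al <- align_runs(fits, mode_threshold = 0.9)
    Q <- al$Q_avg
    stable <- all(al$modes == 1)
    left <- ids[Q[, 1] > threshold]
    right <- setdiff(ids, left)
    decisive <- mean(apply(Q, 1, max)) >= decisive_q &&
      length(left) >= min_child && length(right) >= min_child
    if (!decisive) {
      node$leaf <- TRUE
      return(node)
    }
    gr <- tibble::tibble(id = c(left, right),
                         stg = rep(c("L", "R"), c(length(left), length(right))))
    node$leaf <- FALSE
    node$stable <- stable
    node$theta <- wc_theta(sub, gr)$theta
    node$left <- recurse(left, depth + 1, seed * 2 + 1)
    node$right <- recurse(right, depth + 1, seed * 2 + 2)
    node
  }
  recurse(ids, 0, seed)
}

#' Leaves of a progressive partition tree
#'
#' @param tree Output of [progressive_partition()].
#' @return Tibble `id`, `leaf` (integer label).
#' @export
partition_leaves <- function(tree) {
  leaves <- list()
  walk <- function(node) {
    if (isTRUE(node$leaf)) {
      leaves[[length(leaves) + 1L]] <<- node$ids
    } else {
      walk(node$left); walk(node$right)
    }
  }
  walk(tree)
  purrr::imap_dfr(leaves, function(ids, i) tibble::tibble(id = ids, leaf = i))
}

#' Discriminant-analysis clustering with BIC model choice
#'
#' A model-free companion to the admixture model: individuals are embedded
#' by PCA of their centred allele-dosage matrix, k-means is run over a K
#' range, the number of clusters is chosen by
#' `BIC(K) = n log(WSS/n) + K log(n)`, and linear discriminants are
#' computed on the chosen clustering.
#'
#' @param x A [genotype_table()].
#' @param k_range Candidate cluster numbers.
#' @param var_explained Fraction of dosage variance retained in the PCA.
#' @param n_da Number of discriminant axes (default `chosen K - 1`).
#' @param seed Integer seed for k-means restarts.
#' @return List with `bic` tibble (`K`, `bic`), `best_k`, `assignments`
#'   (tibble `id`, `cluster`, posterior matrix in `posterior`), `ld`
#'   (discriminant coordinates), `pca_dims`.
#' @export
dapc_lite <- function(x, k_range = 1:8, var_explained = 0.9, n_da = NULL, seed = 1) {
  codes <- locus_codes(x)
  tab <- tibble::as_tibble(x)
  D <- do.call(cbind, purrr::map(codes, function(cd) {
    m <- cd$D
    if (any(!cd$typed)) {
      # mean-impute missing dosages so PCA sees every individual
      mu <- colSums(m[cd$typed, , drop = FALSE]) / sum(cd$typed)
      m[!cd$typed, ] <- matrix(mu, sum(!cd$typed), length(mu), byrow = TRUE)
    }
    m
  }))
  stopifnot(nrow(D) > max(k_range))
  pc <- stats::prcomp(D, center = TRUE, scale. = FALSE)
  keep <- which(cumsum(pc$sdev^2) / sum(pc$sdev^2) >= var_explained)[1]
  keep <- max(keep, 2L)
  S <- pc$x[, seq_len(keep), drop = FALSE]
  n <- nrow(S)
  km <- withr::with_seed(seed, purrr::map(k_range, function(k) {
    if (k == 1) {
      list(cluster = rep(1L, n), tot.withinss = sum(scale(S, scale = FALSE)^2))
    } else {
      stats::kmeans(S, centers = k, nstart = 20, iter.max = 50)
    }
  }))
  bic <- tibble::tibble(
    K = k_range,
    bic = vapply(seq_along(k_range), function(i) {
      n * log(km[[i]]$tot.withinss / n) + k_range[i] * log(n)
    }, numeric(1))
  )
  best_i <- which.min(bic$bic)
  best_k <- k_range[best_i]
  cl <- km[[best_i]]$cluster
  out <- list(bic = bic, best_k = best_k, pca_dims = keep)
  if (best_k > 1) {
    nda <- if (is.null(n_da)) best_k - 1L else n_da
    ld <- suppressWarnings(MASS::lda(S, grouping = factor(cl)))
    pred <- stats::predict(ld, S)
    out$assignments <- tibble::tibble(id = tab$id, cluster = as.integer(cl),
                                      posterior = as.data.frame(pred$posterior))
    out$ld <- pred$x[, seq_len(min(nda, ncol(pred$x))), drop = FALSE]
  } else {
    out$assignments <- tibble::tibble(id = tab$id, cluster = 1L,
                                      posterior = as.data.frame(matrix(1, n, 1)))
    out$ld <- NULL
  }
  out
}

#' Export ancestry matrices in CLUMPP-compatible format
#'
#' @param fits List of `admixture_fit` objects at the same K.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_clumpp <- function(fits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in fits) {
    Q <- f$Q
    for (i in seq_len(nrow(Q))) {
      cat(sprintf("%d %d (0) 1 : %s\n", i, i,
                  paste(sprintf("%.4f", Q[i, ]), collapse = " ")), file = con)
    }
    cat("\n", file = con)
  }
  invisible(path)
}
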