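#' Configure a forward Wright-Fisher simulation
#'
#' The simulator models a set of regional demes that diverge by drift after a
#' bottleneck and are later reconnected by epoch-wise increasing migration --
#' the demographic history typical of a recovering, formerly fragmented
#' population. Generations are non-overlapping; within a deme mating is
#' random (with an optional selfing excess to emulate within-deme
#' inbreeding). Loci mutate under the stepwise model (SMM, +/- one repeat
#' unit, reflecting at the configured size bounds so alleles stay encodable)
#' or the K-allele model (KAM, uniform over states).
#'
#' @param n_demes Number of demes.
#' @param deme_names,centroids Region labels and planar centroid coordinates
#'   (km) attached to sampled individuals; `centroids` is an `n_demes` x 2
#'   matrix.
#' @param epochs List of epochs, each `list(gens, N, m)`: number of
#'   generations, per-deme sizes (scalar or vector) and migration. `m` may be
#'   a scalar (symmetric island-model rate: each individual emigrates with
#'   probability `m`, destination uniform among other demes) or a full
#'   `n_demes` x `n_demes` row-stochastic matrix.
#' @param n_loci Number of microsatellite loci.
#' @param mutation `"SMM"` or `"KAM"`.
#' @param mu Per-copy, per-generation mutation rate.
#' @param allele_range Allele size bounds in base pairs.
#' @param step Repeat-unit size in base pairs (SMM step).
#' @param founder_alleles Integer vector (recycled over demes) giving the
#'   number of founding allele states per locus in each deme; unequal values
#'   create the unequal diversity between demes seen in real fragmented
#'   populations.
#' @param founder_pool_size Number of allele states in the shared per-locus
#'   founder pool from which each deme draws its founding states; bounds the
#'   total allelic richness of the system.
#' @param selfing_rate Probability that a mating is a self-fertilisation
#'   (stand-in for within-deme consanguinity; 0 = random mating).
#' @param sampling Tibble with columns `generation`, `time_point`, `year` and
#'   `n` (scalar or list-column of per-deme sample sizes).
#' @param jitter_sd Spatial jitter (km) of sample coordinates around the deme
#'   centroid.
#' @param translocations Optional tibble `from`, `to`, `n`, `generation`.
#' @param record_truth Record per-generation allele frequencies?
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_demes = 5,
                       deme_names = paste0("deme", seq_len(n_demes)),
                       centroids = cbind(runif(n_demes, 0, 500), runif(n_demes, 0, 500)),
                       epochs = list(list(gens = 20, N = 50, m = 0)),
                       n_loci = 15,
                       mutation = c("SMM", "KAM"),
                       mu = 5e-4,
                       allele_range = c(100, 160),
                       step = 2,
                       founder_alleles = 8,
                       founder_pool_size = 10,
                       selfing_rate = 0,
                       sampling = NULL,
                       jitter_sd = 10,
                       translocations = NULL,
                       record_truth = TRUE) {
  mutation <- match.arg(mutation)
  cfg <- list(
    n_demes = n_demes, deme_names = deme_names, centroids = centroids,
    epochs = epochs, n_loci = n_loci, mutation = mutation, mu = mu,
    allele_range = allele_range, step = step,
    founder_alleles = rep_len(founder_alleles, n_demes),
    founder_pool_size = founder_pool_size, selfing_rate = selfing_rate,
    sampling = sampling, jitter_sd = jitter_sd,
    translocations = translocations, record_truth = record_truth
  )
  total_gens <- sum(vapply(cfg$epochs, function(e) e$gens, numeric(1)))
  if (!is.null(sampling) && any(sampling$generation > total_gens)) {
    rlang::abort("sampling generation beyond simulated span")
  }
  for (e in cfg$epochs) {
    if (is.matrix(e$m) && any(rowSums(e$m) - diag(e$m) > 1)) {
      rlang::abort("migration rows must sum to <= 1")
    }
    if (any(rep_len(e$N, n_demes) < 2)) rlang::abort("deme sizes must be >= 2")
  }
  structure(cfg, class = "sim_config")
}

migration_matrix <- function(m, n_demes) {
  if (is.matrix(m)) return(m)
  if (n_demes == 1L) return(matrix(1, 1, 1))
  mat <- matrix(m / (n_demes - 1), n_demes, n_demes)
  diag(mat) <- 1 - m
  mat
}

allele_states <- function(cfg) seq(cfg$allele_range[1], cfg$allele_range[2], by = cfg$step)

#' Run a forward Wright-Fisher simulation
#'
#' Each generation applies migration (multinomial moves between demes),
#' random mating with multinomial drift, and mutation, then draws any
#' scheduled samples without replacement. The returned truth ledger makes
#' every downstream estimator checkable against the simulated reality.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; output is fully reproducible given the seed.
#' @return List with `table` (a [genotype_table()] of sampled individuals
#'   with metadata) and `truth`: `freqs` (per-generation per-deme allele
#'   frequencies, if recorded), `migrants` (realized per-generation migrant
#'   counts), `ancestry` (per sampled individual, fractions of founding-deme
#'   ancestry), and `expected_fst` (island-model equilibrium reference
#'   `1/(1+4Nm)` per epoch).
#' @export
simulate_population <- function(config, seed) {
  withr::with_seed(seed, simulate_population_impl(config))
}

simulate_population_impl <- function(cfg) {
  nd <- cfg$n_demes
  L <- cfg$n_loci
  states <- allele_states(cfg)
  loci <- sprintf("L%02d", seq_len(L))

  # per-locus founder pool shared by all demes; each deme founds with a
  # subset of it, so demes overlap in common alleles but differ in rare ones
  founder_pool <- lapply(seq_len(L), function(l) {
    sample(states, min(cfg$founder_pool_size, length(states)))
  })
  geno <- vector("list", nd)      # per deme: N x 2L integer matrix
  anc <- vector("list", nd)       # per deme: N x nd ancestry fractions
  N0 <- rep_len(cfg$epochs[[1]]$N, nd)
  for (d in seq_len(nd)) {
    k <- cfg$founder_alleles[d]
    g <- matrix(0L, N0[d], 2 * L)
    for (l in seq_len(L)) {
      own <- founder_pool[[l]][sample.int(length(founder_pool[[l]]), min(k, cfg$founder_pool_size))]
      w <- as.vector(stats::rmultinom(1, 25, rep(1 / length(own), length(own)))) + 1
      g[, c(2 * l - 1, 2 * l)] <- sample(own, 2 * N0[d], replace = TRUE, prob = w)
    }
    geno[[d]] <- g
    anc[[d]] <- diag(nd)[rep(d, N0[d]), , drop = FALSE]
  }

  freqs_rec <- list(); migr_rec <- list(); samples <- list(); anc_rec <- list()
  expected_fst <- purrr::map_dfr(seq_along(cfg$epochs), function(i) {
    e <- cfg$epochs[[i]]
    mrate <- if (is.matrix(e$m)) mean(rowSums(e$m) - diag(e$m)) else e$m
    tibble::tibble(epoch = i, N = mean(rep_len(e$N, nd)), m = mrate,
                   fst = expected_island_fst(mean(rep_len(e$N, nd)), mrate))
  })

  gen <- 0L
  for (ei in seq_along(cfg$epochs)) {
    e <- cfg$epochs[[ei]]
    Ne <- rep_len(e$N, nd)
    M <- migration_matrix(e$m, nd)
    for (g_in_e in seq_len(e$gens)) {
      gen <- gen + 1L

      # migration: move whole individuals between demes
      if (nd > 1L) {
        dest <- vector("list", nd)
        for (d in seq_len(nd)) {
          dest[[d]] <- sample.int(nd, nrow(geno[[d]]), replace = TRUE, prob = M[d, ])
        }
        moved <- lapply(seq_len(nd), function(to) {
          list(
            g = do.call(rbind, lapply(seq_len(nd), function(fr) geno[[fr]][dest[[fr]] == to, , drop = FALSE])),
            a = do.call(rbind, lapply(seq_len(nd), function(fr) anc[[fr]][dest[[fr]] == to, , drop = FALSE]))
          )
        })
        mig_counts <- purrr::map_dfr(seq_len(nd), function(fr) {
          tb <- tabulate(dest[[fr]], nd)
          tibble::tibble(gen = gen, from = cfg$deme_names[fr], to = cfg$deme_names, n = tb)
        }) |> dplyr::filter(.data$from != .data$to, .data$n > 0)
        migr_rec[[length(migr_rec) + 1L]] <- mig_counts
        geno <- lapply(moved, `[[`, "g")
        anc <- lapply(moved, `[[`, "a")
        empty <- vapply(geno, nrow, integer(1)) == 0L
        if (any(empty)) rlang::abort("deme left empty by migration (extinction)")
      }

      # translocations: move n random individuals from source to sink
      if (!is.null(cfg$translocations)) {
        tr <- dplyr::filter(cfg$translocations, .data$generation == gen)
        for (i in seq_len(nrow(tr))) {
          fr <- match(tr$from[i], cfg$deme_names); to <- match(tr$to[i], cfg$deme_names)
          take <- sample.int(nrow(geno[[fr]]), min(tr$n[i], nrow(geno[[fr]]) - 2L))
          geno[[to]] <- rbind(geno[[to]], geno[[fr]][take, , drop = FALSE])
          anc[[to]] <- rbind(anc[[to]], anc[[fr]][take, , drop = FALSE])
          geno[[fr]] <- geno[[fr]][-take, , drop = FALSE]
          anc[[fr]] <- anc[[fr]][-take, , drop = FALSE]
        }
      }

      # reproduction with drift and mutation
      for (d in seq_len(nd)) {
        n_par <- nrow(geno[[d]])
        n_child <- Ne[d]
        mothers <- sample.int(n_par, n_child, replace = TRUE)
        fathers <- sample.int(n_par, n_child, replace = TRUE)
        if (cfg$selfing_rate > 0) {
          self <- stats::runif(n_child) < cfg$selfing_rate
          fathers[self] <- mothers[self]
        }
        child <- matrix(0L, n_child, 2 * L)
        for (l in seq_len(L)) {
          cm <- 2 * l - 1L + (stats::runif(n_child) < 0.5)
          cf <- 2 * l - 1L + (stats::runif(n_child) < 0.5)
          child[, 2 * l - 1L] <- geno[[d]][cbind(mothers, cm)]
          child[, 2 * l] <- geno[[d]][cbind(fathers, cf)]
        }
        mut <- which(stats::runif(length(child)) < cfg$mu)
        if (length(mut) > 0L) {
          if (cfg$mutation == "SMM") {
            stepv <- sample(c(-cfg$step, cfg$step), length(mut), replace = TRUE)
            v <- child[mut] + stepv
            v[v < cfg$allele_range[1]] <- cfg$allele_range[1] + cfg$step
            v[v > cfg$allele_range[2]] <- cfg$allele_range[2] - cfg$step
            child[mut] <- v
          } else {
            child[mut] <- sample(states, length(mut), replace = TRUE)
          }
        }
        geno[[d]] <- child
        anc[[d]] <- (anc[[d]][mothers, , drop = FALSE] + anc[[d]][fathers, , drop = FALSE]) / 2
      }

      if (cfg$record_truth) {
        freqs_rec[[length(freqs_rec) + 1L]] <- purrr::map_dfr(seq_len(nd), function(d) {
          purrr::map_dfr(seq_len(L), function(l) {
            tb <- table(geno[[d]][, c(2 * l - 1, 2 * l)])
            tibble::tibble(gen = gen, deme = cfg$deme_names[d], locus = loci[l],
                           allele = as.integer(names(tb)),
                           freq = as.vector(tb) / sum(tb))
          })
        })
      }

      # scheduled sampling at the end of this generation
      if (!is.null(cfg$sampling)) {
        sched <- dplyr::filter(cfg$sampling, .data$generation == gen)
        for (i in seq_len(nrow(sched))) {
          ns <- sched$n[[i]]
          ns <- rep_len(unlist(ns), nd)
          for (d in seq_len(nd)) {
            if (ns[d] == 0L) next
            if (ns[d] > nrow(geno[[d]])) rlang::abort("sampling n exceeds deme size")
            take <- sample.int(nrow(geno[[d]]), ns[d])
            ids <- sprintf("%s_%s_%03d", cfg$deme_names[d], sched$time_point[i], seq_along(take))
            gm <- geno[[d]][take, , drop = FALSE]
            tab <- tibble::tibble(
              id = ids,
              year = as.integer(sched$year[i]),
              time_point = as.character(sched$time_point[i]),
              region = cfg$deme_names[d],
              x = cfg$centroids[d, 1] + stats::rnorm(ns[d], 0, cfg$jitter_sd),
              y = cfg$centroids[d, 2] + stats::rnorm(ns[d], 0, cfg$jitter_sd),
              sex = sample(c("M", "F"), ns[d], replace = TRUE),
              age_class = sample(c("adult", "subadult", "juvenile"), ns[d],
                                 replace = TRUE, prob = c(0.55, 0.35, 0.10))
            )
            for (l in seq_len(L)) {
              tab[[paste0(loci[l], ".1")]] <- gm[, 2 * l - 1L]
              tab[[paste0(loci[l], ".2")]] <- gm[, 2 * l]
            }
            samples[[length(samples) + 1L]] <- tab
            anc_rec[[length(anc_rec) + 1L]] <- tibble::as_tibble(
              stats::setNames(as.data.frame(anc[[d]][take, , drop = FALSE]), cfg$deme_names)
            ) |> dplyr::mutate(id = ids, .before = 1)
          }
        }
      }
    }
  }

  table <- if (length(samples) > 0L) {
    genotype_table(dplyr::bind_rows(samples), loci = loci)
  } else NULL
  list(
    table = table,
    truth = list(
      freqs = if (cfg$record_truth) dplyr::bind_rows(freqs_rec) else NULL,
      migrants = if (length(migr_rec) > 0) dplyr::bind_rows(migr_rec) else NULL,
      ancestry = if (length(anc_rec) > 0) dplyr::bind_rows(anc_rec) else NULL,
      expected_fst = expected_fst
    )
  )
}

#' Island-model equilibrium differentiation
#'
#' Textbook reference value for the fixation index of an island model at
#' drift-migration equilibrium, used as an oracle for the simulator and the
#' Weir-Cockerham estimator.
#'
#' @param N Deme effective size.
#' @param m Per-generation migration rate.
#' @return `1 / (1 + 4 N m)`; 1 when `m = 0`.
#' @export
expected_island_fst <- function(N, m) 1 / (1 + 4 * N * m)

#' Canned recovery-with-lag scenario
#'
#' Five regional demes of unequal founding diversity diverge in isolation
#' after a bottleneck, then re-connect through epoch-wise increasing
#' migration across five sampling time points labelled 1994-2014 (about two
#' 3-year generations per 5-year sampling interval). Sample sizes mimic a
#' carcass-collection design (roughly 8-30 per deme per time point, ~400
#' total, 15 loci). The regime is "recovery lag": realized migration rises
#' across epochs while pairwise differentiation decays only marginally.
#'
#' @param seed Integer seed.
#' @param record_truth Record per-generation allele frequencies?
#' @return As [simulate_population()].
#' @export
scenario_recovery_lag <- function(seed, record_truth = TRUE) {
  centroids <- rbind(
    c(520, 260), c(420, 450), c(360, 230), c(250, 80), c(280, 290)
  )
  sampling <- tibble::tibble(
    generation = c(14, 16, 18, 20, 22),
    time_point = c("1994", "1999", "2004", "2009", "2014"),
    year = c(1994, 1999, 2004, 2009, 2014),
    n = list(c(8, 8, 10, 12, 16), c(16, 16, 24, 20, 26), c(10, 12, 18, 20, 14),
             c(22, 16, 12, 24, 16), c(18, 14, 12, 20, 16))
  )
  cfg <- sim_config(
    n_demes = 5,
    deme_names = c("Eastern", "Northern", "Severn", "South West", "Western Wales"),
    centroids = centroids,
    epochs = list(
      list(gens = 13, N = 40, m = 0),          # bottleneck + isolation: drift apart
      list(gens = 2, N = 80, m = 0.005),       # up to 1994
      list(gens = 2, N = 110, m = 0.012),      # 1994 -> 1999
      list(gens = 2, N = 140, m = 0.025),      # 1999 -> 2004
      list(gens = 2, N = 170, m = 0.05),       # 2004 -> 2009
      list(gens = 2, N = 200, m = 0.10)        # 2009 -> 2014
    ),
    n_loci = 15, mutation = "SMM", mu = 5e-4,
    allele_range = c(100, 160), step = 2,
    founder_alleles = c(8, 7, 4, 4, 3),
    founder_pool_size = 9,
    sampling = sampling,
    jitter_sd = 15,
    record_truth = record_truth
  )
  simulate_population(cfg, seed)
}
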