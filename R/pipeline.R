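#' Configure a monitoring analysis run
#'
#' @param pooling_rules Year -> time-point map ([default_pooling_rules()]).
#' @param exclude_regions Regions dropped from STG analyses.
#' @param n_perm Permutations for F_ST / AMOVA / F_IS tests.
#' @param burnin,steps Admixture chain lengths.
#' @param k_range K values fitted for the admixture K scan.
#' @param replicates Replicate admixture runs per K.
#' @param admixture_cutoff Q threshold below which an individual is admixed.
#' @param fixed_rarefaction_n Fixed rarefaction size in individuals.
#' @param min_group_n Groups smaller than this are excluded from trend
#'   tests.
#' @param nm_omit Time points omitted from the gene-flow series.
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(pooling_rules = default_pooling_rules(),
                       exclude_regions = "Other",
                       n_perm = 1000, burnin = 2000, steps = 10000,
                       k_range = 1:5, replicates = 3,
                       admixture_cutoff = 0.8, fixed_rarefaction_n = 6,
                       min_group_n = 6, nm_omit = "1994", seed = 1) {
  structure(
    list(pooling_rules = pooling_rules, exclude_regions = exclude_regions,
         n_perm = n_perm, burnin = burnin, steps = steps, k_range = k_range,
         replicates = replicates, admixture_cutoff = admixture_cutoff,
         fixed_rarefaction_n = fixed_rarefaction_n, min_group_n = min_group_n,
         nm_omit = nm_omit, seed = seed),
    class = "run_config"
  )
}

#' Run the full monitoring analysis and assemble report tables
#'
#' Executes, from one genotype table: STG assignment, the per-STG diversity
#' summary, pairwise Weir-Cockerham theta per time point with a global
#' AMOVA row, the private-alleles gene-flow series, an admixture K scan
#' with Evanno delta-K and per-time-point admixed percentages, and trend
#' tests. All numbers are produced by the exported module functions; the
#' report only assembles them.
#'
#' @param x A [genotype_table()].
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, every table is also
#'   written as TSV and a run log (seed, config hash) is recorded.
#' @return List of tibbles: `diversity`, `pairwise_fst`, `global_fst`,
#'   `nm`, `k_scan`, `admixed`, `trends`, plus `grouping` and `config_hash`.
#' @export
run_report <- function(x, config = run_config(), out_dir = NULL) {
  cfg <- config
  grouping <- assign_stgs(x, cfg$pooling_rules, exclude_regions = cfg$exclude_regions)
  keep_ids <- grouping$id
  tab <- tibble::as_tibble(x)
  xk <- genotype_table(tab[tab$id %in% keep_ids, , drop = FALSE], loci = gt_loci(x))

  diversity <- diversity_summary(xk, grouping, fixed_n = cfg$fixed_rarefaction_n)

  tps <- sort(unique(grouping$time_point))
  pw <- purrr::map_dfr(tps, function(tp) {
    gr <- grouping[grouping$time_point == tp, ]
    if (dplyr::n_distinct(gr$region) < 2) return(tibble::tibble())
    pf <- pairwise_fst(xk, gr, by = "region", n_perm = cfg$n_perm,
                       seed = cfg$seed + match(tp, tps))
    dplyr::mutate(pf$pairs, time_point = tp, .before = 1)
  })
  gl <- purrr::map_dfr(tps, function(tp) {
    gr <- grouping[grouping$time_point == tp, ]
    if (dplyr::n_distinct(gr$region) < 2) return(tibble::tibble())
    am <- amova_global(xk, gr, by = "region", n_perm = cfg$n_perm,
                       seed = cfg$seed + 100 + match(tp, tps))
    dplyr::mutate(am, time_point = tp, .before = 1)
  })

  nm <- nm_series(xk, grouping, omit = cfg$nm_omit)

  fits <- purrr::map(cfg$k_range, function(k) {
    purrr::map(seq_len(cfg$replicates), function(r) {
      admixture_gibbs(xk, K = k, burnin = cfg$burnin, steps = cfg$steps,
                      seed = cfg$seed + 1000 * k + r)
    })
  })
  k_scan <- purrr::map_dfr(fits, function(fl) {
    lp <- vapply(fl, function(f) f$ln_pd, numeric(1))
    tibble::tibble(K = fl[[1]]$K, mean_lnl = mean(lp), sd_lnl = stats::sd(lp))
  })
  k_scan <- if (nrow(k_scan) >= 3) evanno_delta_k(k_scan) else k_scan

  tp_of <- stats::setNames(grouping$time_point, grouping$id)
  admixed <- purrr::map_dfr(fits, function(fl) {
    if (fl[[1]]$K == 1) return(tibble::tibble())
    Q <- if (length(fl) >= 2) align_runs(fl)$Q_avg else fl[[1]]$Q
    rownames(Q) <- rownames(fl[[1]]$Q)
    ca <- classify_admixed(Q, cutoff = cfg$admixture_cutoff,
                           time_points = unname(tp_of[rownames(Q)]))
    dplyr::mutate(ca$by_time, K = fl[[1]]$K, .before = 1)
  })

  # per-individual observed heterozygosity feeds the trend tests
  ind_ho <- individual_heterozygosity(xk)
  ind_ho <- dplyr::left_join(ind_ho, grouping, by = "id")
  trends <- trend_tests(
    dplyr::transmute(ind_ho, value = .data$ho, region = .data$region,
                     time_point = .data$time_point),
    min_n = cfg$min_group_n
  )

  hash <- rlang::hash(list(cfg, tab$id))
  out <- list(diversity = diversity, pairwise_fst = pw, global_fst = gl,
              nm = nm$global, nm_pairwise = nm$pairwise, k_scan = k_scan,
              admixed = admixed, trends = trends, grouping = grouping,
              config_hash = hash)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nmv in c("diversity", "pairwise_fst", "global_fst", "nm",
                  "nm_pairwise", "k_scan", "admixed", "trends")) {
      readr::write_tsv(out[[nmv]], file.path(out_dir, paste0(nmv, ".tsv")))
    }
    writeLines(c(paste0("seed: ", cfg$seed), paste0("config_hash: ", hash),
                 paste0("package: popgenmon ",
                        as.character(utils::packageVersion("popgenmon")))),
               file.path(out_dir, "run_log.txt"))
  }
  out
}

#' Per-individual observed heterozygosity
#'
#' Fraction of typed loci at which the individual is heterozygous.
#'
#' @param x A [genotype_table()].
#' @return Tibble `id`, `n_typed`, `ho`.
#' @export
individual_heterozygosity <- function(x) {
  gt_alleles_long(x) |>
    tidyr::pivot_wider(names_from = "copy", values_from = "allele") |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(n_typed = dplyr::n(), ho = mean(.data$`1` != .data$`2`))
}

#' Temporal and regional trend tests on a monitoring series
#'
#' Within each region, a Kendall rank correlation of the values against
#' time tests for temporal trend; within each time point, a Kruskal-Wallis
#' test compares regions. Groups (region x time point) with fewer than
#' `min_n` values are excluded; p-values are reported unadjusted.
#'
#' @param series Tibble with columns `value`, `region`, `time_point`.
#' @param min_n Minimum group size.
#' @return Tibble `test` (`"temporal_kendall"` or `"regional_kw"`),
#'   `stratum` (region or time point), `statistic` (`tau` or `H`), `p`,
#'   `n`.
#' @export
trend_tests <- function(series, min_n = 6) {
  series <- series |>
    dplyr::group_by(.data$region, .data$time_point) |>
    dplyr::filter(dplyr::n() >= min_n) |>
    dplyr::ungroup()
  temporal <- series |>
    dplyr::group_by(.data$region) |>
    dplyr::group_modify(function(d, key) {
      if (dplyr::n_distinct(d$time_point) < 3) return(tibble::tibble())
      if (dplyr::n_distinct(d$value) < 2) {
        # a constant series carries no trend
        return(tibble::tibble(statistic = 0, p = 1, n = nrow(d)))
      }
      kt <- kendall_tau_b(as.numeric(d$time_point), d$value)
      tibble::tibble(statistic = kt$tau, p = kt$p, n = nrow(d))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(test = "temporal_kendall", .before = 1) |>
    dplyr::rename(stratum = "region")
  regional <- series |>
    dplyr::group_by(.data$time_point) |>
    dplyr::group_modify(function(d, key) {
      if (dplyr::n_distinct(d$region) < 2) return(tibble::tibble())
      kw <- kruskal_wallis(d$value, d$region)
      tibble::tibble(statistic = kw$h, p = kw$p, n = nrow(d))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(test = "regional_kw", .before = 1) |>
    dplyr::rename(stratum = "time_point")
  dplyr::bind_rows(temporal, regional)
}

#' Plot a gene-flow (Nm) series over time points
#'
#' @param nm_global The `global` tibble from [nm_series()].
#' @return A ggplot object.
#' @export
plot_nm_series <- function(nm_global) {
  ggplot2::ggplot(nm_global, ggplot2::aes(x = .data$time_point, y = .data$nm, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "Time point", y = "Effective migrants (Nm)") +
    ggplot2::theme_minimal()
}

#' Plot averaged ancestry proportions as a stacked bar chart
#'
#' @param Q Ancestry matrix (rows = individuals).
#' @param group Optional grouping vector (e.g. region) used to order and
#'   facet the bars.
#' @return A ggplot object.
#' @export
plot_admixture <- function(Q, group = NULL) {
  d <- tibble::as_tibble(Q, rownames = "id", .name_repair = "minimal")
  names(d)[-1] <- paste0("C", seq_len(ncol(Q)))
  d <- tidyr::pivot_longer(d, -"id", names_to = "cluster", values_to = "q")
  if (!is.null(group)) {
    d$group <- rep(group, each = ncol(Q))
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$id, y = .data$q, fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "Ancestry proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  if (!is.null(group)) {
    p <- p + ggplot2::facet_grid(~group, scales = "free_x", space = "free_x")
  }
  p
}

#' Reference summary tables from a long-term UK otter monitoring programme
#'
#' Published summary statistics from a 21-year genetic monitoring study of
#' Eurasian otters across Wales and England (five time points 1994-2014,
#' 15 microsatellite loci, five regions): per-locus variability, per-STG
#' diversity, region metadata and pairwise theta estimates. These serve as
#' worked-example inputs and as cross-checks of the statistical machinery.
#'
#' @param which One of `"locus_stats"`, `"stg_diversity"`, `"regions"`,
#'   `"pairwise_fst"`.
#' @return A tibble.
#' @export
otter_reference_table <- function(which = c("locus_stats", "stg_diversity",
                                            "regions", "pairwise_fst")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("uk_otter_", which, ".csv"),
                      package = "popgenmon")
  readr::read_csv(path, show_col_types = FALSE)
}
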