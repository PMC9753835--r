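#' Observed heterozygosity per locus and group
#'
#' @param x A [genotype_table()].
#' @param grouping Optional grouping tibble (see [assign_stgs()]); `NULL`
#'   treats the table as one group.
#' @param by Grouping column, as in [allele_frequencies()].
#' @return Tibble `group`, `locus`, `n` (non-missing individuals) and `ho`
#'   (heterozygote fraction). Loci with zero calls in a group are dropped
#'   with a warning.
#' @export
observed_heterozygosity <- function(x, grouping = NULL, by = "stg") {
  loci <- gt_loci(x)
  tab <- tibble::as_tibble(x)
  if (is.null(grouping)) {
    tab$..group <- "all"
  } else {
    key <- stats::setNames(grouping[[by]], grouping$id)
    tab$..group <- unname(key[tab$id])
    tab <- dplyr::filter(tab, !is.na(.data$..group))
  }
  out <- purrr::map_dfr(loci, function(loc) {
    a <- tab[[paste0(loc, ".1")]]; b <- tab[[paste0(loc, ".2")]]
    ok <- !is.na(a)
    tibble::tibble(group = tab$..group[ok], locus = loc, het = a[ok] != b[ok])
  }) |>
    dplyr::group_by(.data$group, .data$locus) |>
    dplyr::summarise(n = dplyr::n(), ho = mean(.data$het), .groups = "drop")
  expected <- tidyr::expand_grid(group = unique(tab$..group), locus = loci)
  dropped <- dplyr::anti_join(expected, out, by = c("group", "locus"))
  if (nrow(dropped) > 0L) {
    rlang::warn(paste0(nrow(dropped), " (group, locus) combination(s) with zero calls dropped"))
  }
  dplyr::arrange(out, .data$group, .data$locus)
}

#' Nei's unbiased expected heterozygosity per locus and group
#'
#' `He = 2n/(2n - 1) * (1 - sum(p^2))`, the small-sample-corrected gene
#' diversity, computed from the per-locus allele spectrum of each group.
#'
#' @param freqs Output of [allele_frequencies()].
#' @return Tibble `group`, `locus`, `n` (individuals), `he`.
#' @export
unbiased_expected_heterozygosity <- function(freqs) {
  out <- freqs |>
    dplyr::group_by(.data$group, .data$locus) |>
    dplyr::summarise(
      n = .data$gene_copies[1] / 2,
      he = (.data$gene_copies[1] / (.data$gene_copies[1] - 1)) * (1 - sum(.data$freq^2)),
      .groups = "drop"
    )
  if (any(out$n < 2)) rlang::abort("unbiased He requires n >= 2 individuals")
  out
}

#' Rarefied allelic richness of an allele spectrum
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies (hypergeometric expectation):
#' `A_r = sum_a (1 - choose(G - c_a, g) / choose(G, g))`.
#'
#' @param counts Integer vector of allele counts (one spectrum).
#' @param g Rarefaction size in gene copies (`2 * individuals`), `2 <= g <= G`.
#' @return The rarefied richness (a number).
#' @export
rarefy_richness <- function(counts, g) {
  G <- sum(counts)
  if (g > G) rlang::abort("rarefaction size g exceeds available gene copies")
  if (g < 2) rlang::abort("rarefaction size g must be >= 2")
  sum(1 - exp(lchoose(G - counts, g) - lchoose(G, g)))
}

# probability that each allele of a spectrum appears in a subsample of g copies
rarefied_presence <- function(counts, g) {
  G <- sum(counts)
  1 - exp(lchoose(G - counts, g) - lchoose(G, g))
}

#' Rarefied allelic richness per group
#'
#' Mean over loci of [rarefy_richness()] at a common rarefaction size, so
#' groups of unequal sample size are comparable.
#'
#' @param freqs Output of [allele_frequencies()].
#' @param g Rarefaction size in gene copies. `NULL` uses the largest size
#'   supported by every (group, locus), i.e. the minimum gene-copy count.
#' @return Tibble `group`, `g`, `ar` (mean over loci), plus per-locus values
#'   in the `per_locus` list-column.
#' @export
rarefied_allelic_richness <- function(freqs, g = NULL) {
  if (is.null(g)) {
    g <- freqs |>
      dplyr::group_by(.data$group, .data$locus) |>
      dplyr::summarise(G = .data$gene_copies[1], .groups = "drop") |>
      dplyr::pull(.data$G) |>
      min()
  }
  per_locus <- freqs |>
    dplyr::group_by(.data$group, .data$locus) |>
    dplyr::summarise(ar = rarefy_richness(.data$count, .env$g), .groups = "drop")
  per_locus |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(g = .env$g, ar = mean(.data$ar),
                     per_locus = list(dplyr::pick(dplyr::everything()))) |>
    dplyr::ungroup()
}

#' Rarefied private allelic richness per group
#'
#' Kalinowski's rarefied expectation of the number of alleles present in a
#' subsample of `g` gene copies from the focal group and absent from equal
#' subsamples of every other group:
#' `pA_r(f) = sum_a Q_{f,a} * prod_{j != f} (1 - Q_{j,a})`, with `Q_{j,a}`
#' the probability that allele `a` appears in `g` copies drawn from group `j`.
#'
#' @param freqs Output of [allele_frequencies()] covering all groups.
#' @param g Rarefaction size in gene copies; `NULL` as in
#'   [rarefied_allelic_richness()].
#' @return Tibble `group`, `g`, `par` (mean over loci).
#' @export
rarefied_private_allelic_richness <- function(freqs, g = NULL) {
  if (is.null(g)) {
    g <- min(dplyr::summarise(
      dplyr::group_by(freqs, .data$group, .data$locus),
      G = .data$gene_copies[1], .groups = "drop"
    )$G)
  }
  groups <- unique(freqs$group)
  loci <- unique(freqs$locus)
  per <- tidyr::expand_grid(group = groups, locus = loci)
  per$par <- purrr::map2_dbl(per$group, per$locus, function(gr, loc) {
    spectra <- dplyr::filter(freqs, .data$locus == loc)
    alleles <- unique(spectra$allele)
    Q <- matrix(0, length(groups), length(alleles),
                dimnames = list(groups, as.character(alleles)))
    for (gj in groups) {
      sp <- dplyr::filter(spectra, .data$group == gj)
      if (nrow(sp) == 0L) next
      cnt <- stats::setNames(rep(0L, length(alleles)), as.character(alleles))
      cnt[as.character(sp$allele)] <- sp$count
      Q[gj, ] <- rarefied_presence(cnt, g)
    }
    others <- setdiff(groups, gr)
    if (length(others) == 0L) return(sum(Q[gr, ]))
    not_elsewhere <- apply(1 - Q[others, , drop = FALSE], 2, prod)
    sum(Q[gr, ] * not_elsewhere)
  })
  per |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(g = .env$g, par = mean(.data$par)) |>
    dplyr::ungroup()
}

#' Closed-form null-allele frequency estimators
#'
#' Two moment estimators of the frequency of a non-amplifying (null) allele
#' from the heterozygote deficit: Chakraborty's `(He - Ho) / (He + Ho)` and
#' Brookfield's estimator 1, `(He - Ho) / (1 + He)`.
#'
#' @param he,ho Per-locus expected and observed heterozygosity (equal-length
#'   vectors in `[0, 1]`).
#' @return Tibble with `he`, `ho`, `chakraborty`, `brookfield1`; loci with
#'   `He + Ho = 0` get `NA` for the Chakraborty estimator (undefined).
#' @export
null_allele_estimates <- function(he, ho) {
  stopifnot(length(he) == length(ho), all(he >= 0 & he <= 1), all(ho >= 0 & ho <= 1))
  chak <- ifelse(he + ho == 0, NA_real_, (he - ho) / (he + ho))
  tibble::tibble(he = he, ho = ho, chakraborty = chak, brookfield1 = (he - ho) / (1 + he))
}

#' Flag loci with evidence of null alleles across regions
#'
#' A locus is flagged at a time point when its null-allele estimate exceeds
#' `threshold` in strictly more than half of the regions sampled there; the
#' removal rule for a monitoring panel then drops only loci flagged this way.
#'
#' @param estimates Tibble with columns `locus`, `region`, `time_point` and
#'   `estimate` (a per-locus, per-group null-allele frequency estimate).
#' @param threshold Flagging threshold on the estimate (default 0.05).
#' @return Tibble `locus`, `time_point`, `n_regions`, `n_exceeding`,
#'   `flagged`.
#' @export
flag_null_loci <- function(estimates, threshold = 0.05) {
  estimates |>
    dplyr::group_by(.data$locus, .data$time_point) |>
    dplyr::summarise(
      n_regions = dplyr::n_distinct(.data$region),
      n_exceeding = dplyr::n_distinct(.data$region[.data$estimate > threshold]),
      .groups = "drop"
    ) |>
    dplyr::mutate(flagged = .data$n_exceeding > .data$n_regions / 2)
}

#' Paired t test between per-locus expected and observed heterozygosity
#'
#' @param he,ho Per-locus values (equal length >= 2).
#' @return Tibble `t`, `df`, `p` (two-sided).
#' @export
paired_t_he_ho <- function(he, ho) {
  stopifnot(length(he) == length(ho), length(he) >= 2)
  d <- he - ho
  if (stats::sd(d) == 0) {
    rlang::warn("zero variance of He - Ho differences; t is infinite")
    return(tibble::tibble(t = ifelse(mean(d) == 0, 0, sign(mean(d)) * Inf),
                          df = length(d) - 1, p = ifelse(mean(d) == 0, 1, 0)))
  }
  ht <- stats::t.test(he, ho, paired = TRUE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Kendall rank correlation (tau-b) with tie correction
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Tibble `tau`, `p` (two-sided, normal approximation under ties).
#' @export
kendall_tau_b <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    rlang::abort("kendall_tau_b undefined for an all-tied vector")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  tibble::tibble(tau = unname(ct$estimate), p = ct$p.value)
}

#' Kruskal-Wallis test for differences in medians between groups
#'
#' @param values Numeric vector.
#' @param groups Group labels (>= 2 distinct, each with >= 1 value).
#' @return Tibble `h` (tie-corrected statistic), `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  if (dplyr::n_distinct(groups) < 2) rlang::abort("kruskal_wallis needs >= 2 groups")
  kt <- stats::kruskal.test(values, factor(groups))
  tibble::tibble(h = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Per-STG diversity summary table
#'
#' Assembles the standard monitoring summary: sample size, mean (+/- sd
#' across loci) expected and observed heterozygosity, mean alleles per
#' locus, and rarefied allelic and private allelic richness under two
#' regimes -- the per-time-point minimum sample size and a fixed
#' `n = fixed_n` individuals (`2 * fixed_n` gene copies).
#'
#' @param x A [genotype_table()].
#' @param grouping Grouping tibble from [assign_stgs()].
#' @param fixed_n Fixed rarefaction size in individuals (default 6).
#' @param min_n_rarefaction Groups smaller than this are excluded from the
#'   per-time-point rarefaction (default 5), mirroring the treatment of very
#'   small samples in monitoring reports.
#' @return Tibble with one row per STG.
#' @export
diversity_summary <- function(x, grouping, fixed_n = 6, min_n_rarefaction = 5) {
  freqs <- allele_frequencies(x, grouping, by = "stg")
  ho <- observed_heterozygosity(x, grouping, by = "stg")
  he <- unbiased_expected_heterozygosity(freqs)
  base <- grouping |>
    dplyr::count(.data$stg, .data$region, .data$time_point, name = "n")
  stats_tbl <- dplyr::full_join(he, ho, by = c("group", "locus")) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_loci = dplyr::n(),
      he_mean = mean(.data$he), he_sd = stats::sd(.data$he),
      ho_mean = mean(.data$ho), ho_sd = stats::sd(.data$ho),
      na_mean = NA_real_, .groups = "drop"
    )
  na_tbl <- freqs |>
    dplyr::group_by(.data$group, .data$locus) |>
    dplyr::summarise(k = dplyr::n(), .groups = "drop") |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(na_mean = mean(.data$k), na_sd = stats::sd(.data$k))
  stats_tbl$na_mean <- NULL
  out <- base |>
    dplyr::left_join(stats_tbl, by = c("stg" = "group")) |>
    dplyr::left_join(na_tbl, by = c("stg" = "group"))

  # rarefaction at the per-time-point minimum (groups >= min_n_rarefaction)
  ar_tp <- purrr::map_dfr(unique(base$time_point), function(tp) {
    stgs <- base$stg[base$time_point == tp & base$n >= min_n_rarefaction]
    fr <- dplyr::filter(freqs, .data$group %in% stgs)
    if (length(stgs) < 1L || nrow(fr) == 0L) return(tibble::tibble())
    ar <- rarefied_allelic_richness(fr)
    par <- rarefied_private_allelic_richness(fr, g = ar$g[1])
    dplyr::left_join(dplyr::select(ar, "group", "ar"),
                     dplyr::select(par, "group", "par"), by = "group")
  })
  out <- dplyr::left_join(out, ar_tp, by = c("stg" = "group"))

  # rarefaction at fixed n individuals across all STGs
  g_fixed <- 2 * fixed_n
  ok <- freqs |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(gmin = min(.data$gene_copies)) |>
    dplyr::filter(.data$gmin >= g_fixed) |>
    dplyr::pull(.data$group)
  fr <- dplyr::filter(freqs, .data$group %in% ok)
  if (nrow(fr) > 0L) {
    ar6 <- rarefied_allelic_richness(fr, g = g_fixed)
    par6 <- rarefied_private_allelic_richness(fr, g = g_fixed)
    out <- out |>
      dplyr::left_join(
        dplyr::select(ar6, "group", ar_fixed = "ar"), by = c("stg" = "group")
      ) |>
      dplyr::left_join(
        dplyr::select(par6, "group", par_fixed = "par"), by = c("stg" = "group")
      )
  }
  dplyr::arrange(out, .data$region, .data$time_point)
}
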