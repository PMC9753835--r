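# Regression of ln(mean private-allele frequency) on ln(Nm) at the three
# reference sample sizes (in gene copies): ln p(1) = a ln(Nm) + b.
barton_slatkin_coefs <- tibble::tibble(
  n = c(10, 25, 50),
  a = c(-0.505, -0.576, -0.612),
  b = c(-2.440, -2.519, -2.585)
)

#' Private alleles across groups
#'
#' An allele is private to a group when it is observed (count > 0) in that
#' group and in no other.
#'
#' @param freqs Output of [allele_frequencies()] for >= 2 groups.
#' @return Tibble `locus`, `allele`, `owner` (group), `freq` (within-owner
#'   frequency). Empty when no allele is private.
#' @export
private_alleles <- function(freqs) {
  if (dplyr::n_distinct(freqs$group) < 2) rlang::abort("need >= 2 groups")
  freqs |>
    dplyr::group_by(.data$locus, .data$allele) |>
    dplyr::filter(dplyr::n() == 1) |>
    dplyr::ungroup() |>
    dplyr::select("locus", "allele", owner = "group", "freq")
}

#' Effective number of migrants from the private-alleles method
#'
#' Inverts the published log-linear regression of the mean private-allele
#' frequency `p(1)` on `Nm`, with the regression coefficients interpolated
#' log-linearly between the tabulated reference sample sizes (10, 25 and 50
#' gene copies) to the observed mean sample size -- the standard
#' sample-size correction for this estimator.
#'
#' @param p1 Mean frequency of private alleles (in `(0, 1)`).
#' @param mean_n_genes Mean sample size in gene copies.
#' @return Tibble `p1`, `mean_n`, `nm` (corrected estimate).
#' @export
barton_slatkin_nm <- function(p1, mean_n_genes) {
  if (is.na(p1) || p1 <= 0) rlang::abort("no private alleles: p1 must be > 0")
  if (p1 >= 1) rlang::abort("p1 must be < 1")
  cf <- barton_slatkin_coefs
  if (mean_n_genes < min(cf$n) || mean_n_genes > max(cf$n)) {
    rlang::warn("mean sample size outside tabulated range; nearest regression used")
    mean_n_genes_c <- min(max(mean_n_genes, min(cf$n)), max(cf$n))
  } else {
    mean_n_genes_c <- mean_n_genes
  }
  a <- stats::approx(log(cf$n), cf$a, xout = log(mean_n_genes_c))$y
  b <- stats::approx(log(cf$n), cf$b, xout = log(mean_n_genes_c))$y
  tibble::tibble(p1 = p1, mean_n = mean_n_genes, nm = exp((log(p1) - b) / a))
}

# mean per-(group, locus) sample size in gene copies, and mean frequency of
# private alleles, the two summary inputs of the estimator
private_allele_summary <- function(freqs) {
  pa <- private_alleles(freqs)
  mean_n <- freqs |>
    dplyr::distinct(.data$group, .data$locus, .data$gene_copies) |>
    dplyr::pull(.data$gene_copies) |>
    mean()
  list(p1 = if (nrow(pa) == 0) NA_real_ else mean(pa$freq), mean_n = mean_n,
       n_private = nrow(pa))
}

#' Private-alleles Nm over time points, global and pairwise
#'
#' For every time point the estimator runs across all regions sampled then
#' (the global series) and for every pair of regions (using alleles private
#' to the pair). Time points listed in `omit` (e.g. one with inadequate
#' spatial coverage) are skipped.
#'
#' @param x A [genotype_table()].
#' @param grouping Grouping tibble from [assign_stgs()].
#' @param omit Time points to skip.
#' @return List with `global` tibble (`time_point`, `p1`, `mean_n`, `nm`,
#'   `n_private`, `n_regions`) and `pairwise` tibble (`time_point`,
#'   `region1`, `region2`, `nm`; `NA` when the pair has no private
#'   alleles).
#' @export
nm_series <- function(x, grouping, omit = character()) {
  tps <- setdiff(sort(unique(grouping$time_point)), omit)
  global <- purrr::map_dfr(tps, function(tp) {
    gr <- grouping[grouping$time_point == tp, ]
    regions <- unique(gr$region)
    if (length(regions) < 2) return(tibble::tibble())
    freqs <- allele_frequencies(x, gr, by = "region")
    s <- private_allele_summary(freqs)
    nm <- if (is.na(s$p1) || s$p1 <= 0) NA_real_ else
      barton_slatkin_nm(s$p1, s$mean_n)$nm
    tibble::tibble(time_point = tp, p1 = s$p1, mean_n = s$mean_n, nm = nm,
                   n_private = s$n_private, n_regions = length(regions))
  })
  pairwise <- purrr::map_dfr(tps, function(tp) {
    gr <- grouping[grouping$time_point == tp, ]
    regions <- sort(unique(gr$region))
    if (length(regions) < 2) return(tibble::tibble())
    pairs <- utils::combn(regions, 2)
    purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      sub <- gr[gr$region %in% pairs[, j], ]
      freqs <- allele_frequencies(x, sub, by = "region")
      s <- private_allele_summary(freqs)
      nm <- if (is.na(s$p1) || s$p1 <= 0) NA_real_ else
        suppressWarnings(barton_slatkin_nm(s$p1, s$mean_n)$nm)
      tibble::tibble(time_point = tp, region1 = pairs[1, j],
                     region2 = pairs[2, j], nm = nm)
    })
  })
  list(global = global, pairwise = pairwise)
}
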