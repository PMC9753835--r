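#' Build a binary land/sea grid
#'
#' @param mask Logical matrix, `TRUE` = land; rows index y (northing, row 1
#'   = top), columns index x (easting).
#' @param cell_km Cell size in km.
#' @param origin Coordinates (km) of the lower-left corner of the grid.
#' @return A `land_grid` object.
#' @export
land_grid <- function(mask, cell_km = 1, origin = c(0, 0)) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) rlang::abort("land grid has no land cells")
  structure(list(mask = mask, cell_km = cell_km, origin = origin),
            class = "land_grid")
}

#' Read an ASCII-grid raster as a land mask
#'
#' Standard ESRI ASCII grid (`ncols`/`nrows`/`xllcorner`/`yllcorner`/
#' `cellsize`/`nodata_value` header). Cells equal to the nodata value are
#' sea; everything else is land.
#'
#' @param path File path.
#' @return A [land_grid()].
#' @export
read_asc_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  land_grid(m != nodata, cell_km = hdr$cellsize,
            origin = c(hdr$xllcorner, hdr$yllcorner))
}

grid_cell_of <- function(grid, x, y) {
  nr <- nrow(grid$mask); nc <- ncol(grid$mask)
  col <- floor((x - grid$origin[1]) / grid$cell_km) + 1
  row <- nr - floor((y - grid$origin[2]) / grid$cell_km)
  cbind(row = row, col = col)
}

#' Least-cost distances between points over land
#'
#' Land cells form a lattice graph (8-connected by default: orthogonal
#' moves cost one cell size, diagonal moves `sqrt(2)` cell sizes; sea cells
#' are impassable) and pairwise distances are shortest paths on it.
#' Points are snapped to the nearest land cell within `snap_tolerance_km`.
#'
#' @param grid A [land_grid()].
#' @param points Data frame with `id`, `x`, `y` (km).
#' @param connectivity 8 (default) or 16 (adds knight moves at cost
#'   `sqrt(5)`).
#' @param snap_tolerance_km Maximum snap distance from a point to land.
#' @return Symmetric matrix of distances in km (dimnames = ids);
#'   unreachable pairs (disconnected land masses) are `NA`.
#' @export
least_cost_distances <- function(grid, points, connectivity = 8,
                                 snap_tolerance_km = 5) {
  mask <- grid$mask
  nr <- nrow(mask); nc <- ncol(mask)
  land <- which(mask)
  land_index <- matrix(NA_integer_, nr, nc)
  land_index[land] <- seq_along(land)
  land_rc <- arrayInd(land, dim(mask))

  moves <- rbind(
    cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1), w = 1),
    cbind(dr = c(-1, -1, 1, 1), dc = c(-1, 1, -1, 1), w = sqrt(2))
  )
  if (connectivity == 16) {
    kn <- expand.grid(dr = c(-2, -1, 1, 2), dc = c(-2, -1, 1, 2))
    kn <- kn[abs(kn$dr) != abs(kn$dc), ]
    moves <- rbind(moves, cbind(dr = kn$dr, dc = kn$dc, w = sqrt(5)))
  }
  edges <- list(); weights <- list()
  for (m in seq_len(nrow(moves))) {
    r2 <- land_rc[, 1] + moves[m, "dr"]
    c2 <- land_rc[, 2] + moves[m, "dc"]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    to <- rep(NA_integer_, length(ok))
    to[ok] <- land_index[cbind(r2[ok], c2[ok])]
    keep <- ok & !is.na(to)
    edges[[m]] <- rbind(land_index[land][keep], to[keep])
    weights[[m]] <- rep(moves[m, "w"] * grid$cell_km, sum(keep))
  }
  g <- igraph::graph_from_edgelist(t(do.call(cbind, edges)), directed = FALSE)
  igraph::E(g)$weight <- unlist(weights)

  rc <- grid_cell_of(grid, points$x, points$y)
  vertex <- integer(nrow(points))
  for (i in seq_len(nrow(points))) {
    r <- rc[i, 1]; c <- rc[i, 2]
    on_land <- r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]
    if (on_land) {
      vertex[i] <- land_index[r, c]
    } else {
      # snap to nearest land-cell centre
      cx <- grid$origin[1] + (land_rc[, 2] - 0.5) * grid$cell_km
      cy <- grid$origin[2] + (nr - land_rc[, 1] + 0.5) * grid$cell_km
      d2 <- (cx - points$x[i])^2 + (cy - points$y[i])^2
      j <- which.min(d2)
      if (sqrt(d2[j]) > snap_tolerance_km) {
        rlang::abort(paste0("point '", points$id[i], "' is in the sea beyond snap tolerance"))
      }
      vertex[i] <- j
    }
  }
  uv <- unique(vertex)
  Du <- igraph::distances(g, v = uv, to = uv, algorithm = "dijkstra")
  idx <- match(vertex, uv)
  D <- Du[idx, idx, drop = FALSE]
  D[is.infinite(D)] <- NA_real_
  dimnames(D) <- list(points$id, points$id)
  D
}

#' Shared-allele genetic distance between individuals
#'
#' For each co-typed locus the proportion of shared alleles is
#' `sum_a min(c_ia, c_ja) / 2` (counts out of the two gene copies each);
#' the distance is one minus the mean proportion over co-typed loci.
#'
#' @param x A [genotype_table()].
#' @return Symmetric matrix in `[0, 1]` (dimnames = ids); pairs with no
#'   co-typed loci are `NA` with a warning.
#' @export
shared_allele_distance <- function(x) {
  codes <- locus_codes(x)
  ids <- tibble::as_tibble(x)$id
  n <- length(ids)
  shared_sum <- matrix(0, n, n)
  cotyped <- matrix(0L, n, n)
  for (cd in codes) {
    D <- cd$D
    t_ok <- cd$typed
    # sum over alleles of min(dosage_i, dosage_j) via 0/1/2 decomposition:
    # min(a, b) = [a>=1][b>=1] + [a>=2][b>=2]
    G1 <- (D >= 1) + 0; G2 <- (D >= 2) + 0
    S <- tcrossprod(G1) + tcrossprod(G2)
    S[!t_ok, ] <- 0; S[, !t_ok] <- 0
    shared_sum <- shared_sum + S / 2
    cotyped <- cotyped + outer(t_ok, t_ok, `&`)
  }
  Dm <- 1 - shared_sum / cotyped
  if (any(cotyped[upper.tri(cotyped)] == 0)) {
    rlang::warn("individual pairs with no co-typed loci set to NA")
  }
  diag(Dm) <- 0
  dimnames(Dm) <- list(ids, ids)
  Dm
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal entries with a permutation null
#' (rows and columns permuted jointly).
#'
#' @param m1,m2 Symmetric matrices with identical dimnames; rows with
#'   missing values are dropped pairwise-complete with a warning.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return Tibble `r`, `p`, `n`, `n_perm`.
#' @export
mantel_test <- function(m1, m2, n_perm = 1000, seed = 1,
                        alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(identical(dim(m1), dim(m2)))
  bad <- apply(is.na(m1) | is.na(m2), 1, any)
  if (any(bad)) {
    rlang::warn(paste0(sum(bad), " row(s) with missing distances dropped"))
    m1 <- m1[!bad, !bad]; m2 <- m2[!bad, !bad]
  }
  if (stats::sd(m1[lower.tri(m1)]) == 0 || stats::sd(m2[lower.tri(m2)]) == 0) {
    rlang::abort("constant distance matrix; Mantel r undefined")
  }
  mt <- withr::with_seed(seed, vegan::mantel(stats::as.dist(m1), stats::as.dist(m2),
                                             method = "pearson",
                                             permutations = n_perm))
  r <- unname(mt$statistic)
  perm <- mt$perm
  p <- switch(alternative,
    greater = (1 + sum(perm >= r)) / (n_perm + 1),
    less = (1 + sum(perm <= r)) / (n_perm + 1),
    two.sided = (1 + sum(abs(perm) >= abs(r))) / (n_perm + 1)
  )
  tibble::tibble(r = r, p = p, n = nrow(m1), n_perm = n_perm)
}

#' Mantel correlogram over geographic distance classes
#'
#' Per-class Mantel correlations between geographic class membership and
#' genetic distance, reported in the ecological sign convention (positive
#' values = positive spatial autocorrelation, i.e. lower genetic distance
#' within the class), with Holm correction over classes.
#'
#' @param geo,gen Symmetric distance matrices with identical ids.
#' @param breaks Distance-class breakpoints in km.
#' @param n_perm Permutations per class.
#' @param seed Integer seed.
#' @param progressive Holm correction applied progressively (stopping at
#'   the first non-significant class) or over the full vector.
#' @param cutoff Restrict classes to those below half the maximum distance
#'   (the vegan convention); `FALSE` tests every non-empty class.
#' @return A `mantel_correlogram`: tibble `class_index`, `midpoint`,
#'   `n_pairs`, `r` (ecological sign), `p`, `p_adj`, `significant`.
#' @export
mantel_correlogram <- function(geo, gen, breaks = seq(0, 800, by = 50),
                               n_perm = 1000, seed = 1, progressive = FALSE,
                               cutoff = FALSE) {
  stopifnot(identical(dim(geo), dim(gen)))
  bad <- apply(is.na(geo) | is.na(gen), 1, any)
  if (any(bad)) {
    rlang::warn(paste0(sum(bad), " row(s) with missing distances dropped"))
    geo <- geo[!bad, !bad]; gen <- gen[!bad, !bad]
  }
  mc <- withr::with_seed(seed, suppressWarnings(vegan::mantel.correlog(
    D.eco = stats::as.dist(gen), D.geo = stats::as.dist(geo),
    break.pts = breaks, cutoff = cutoff, r.type = "pearson",
    nperm = n_perm, mult = "holm", progressive = progressive
  )))
  m <- as.data.frame(mc$mantel.res)
  out <- tibble::tibble(
    class_index = seq_len(nrow(m)),
    midpoint = m[[1]],
    n_pairs = as.integer(m[[2]]),
    r = m[[3]],
    r_raw = -m[[3]],  # untransformed indicator-vs-distance Mantel correlation
    p = m[[4]],
    p_adj = m[[5]]
  ) |>
    dplyr::filter(!is.na(.data$r)) |>
    dplyr::mutate(significant = !is.na(.data$p_adj) & .data$p_adj < 0.05)
  class(out) <- c("mantel_correlogram", class(out))
  out
}

#' Correlogram on a sex/age subset
#'
#' @param x A [genotype_table()] with `sex` and `age_class`.
#' @param grid A [land_grid()] for the geographic distances.
#' @param sex `"M"`, `"F"` or `NULL` (no sex filter).
#' @param age `"adult"` (default) or `NULL`.
#' @param ... Passed to [mantel_correlogram()].
#' @return As [mantel_correlogram()].
#' @export
sex_stratified_correlogram <- function(x, grid, sex = NULL, age = "adult", ...) {
  tab <- tibble::as_tibble(x)
  keep <- rep(TRUE, nrow(tab))
  if (!is.null(sex)) keep <- keep & tab$sex %in% sex
  if (!is.null(age)) keep <- keep & tab$age_class %in% age
  if (!any(keep)) rlang::abort("empty subset")
  if (sum(keep) < 20) rlang::warn("subset has fewer than 20 individuals")
  sub <- genotype_table(tab[keep, , drop = FALSE], loci = gt_loci(x))
  geo <- least_cost_distances(grid, tibble::as_tibble(sub)[, c("id", "x", "y")])
  gen <- shared_allele_distance(sub)
  mantel_correlogram(geo, gen, ...)
}

#' Plot a Mantel correlogram
#'
#' @param object A `mantel_correlogram`.
#' @param ... Unused.
#' @return A ggplot object (filled points = significant classes).
#' @export
autoplot.mantel_correlogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$midpoint, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(fill = .data$significant), shape = 21, size = 2.5) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "white"),
                               name = "Holm p < 0.05") +
    ggplot2::labs(x = "Distance class midpoint (km)", y = "Mantel correlation") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
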