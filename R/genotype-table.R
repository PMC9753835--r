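#' Build a validated genotype table
#'
#' A genotype table is a tibble with one row per individual, metadata columns
#' (`id`, `year`, `region`, `x`, `y`, `sex`, `age_class`, and optionally
#' `time_point`) and two integer allele columns per microsatellite locus named
#' `<locus>.1` and `<locus>.2` (allele sizes in base pairs; `NA` = missing).
#' Both gene copies of a locus call must be present or both missing:
#' half-calls are rejected, since a single scored allele usually indicates a
#' scoring failure rather than a haploid call.
#'
#' @param x A data frame with the columns described above.
#' @param loci Character vector of locus names. If `NULL`, loci are inferred
#'   from paired `<locus>.1`/`<locus>.2` columns.
#' @return A `genotype_tbl`: the validated tibble with a `loci` attribute.
#' @examples
#' gt <- genotype_table(tibble::tibble(
#'   id = c("a", "b"), year = 2014, region = "W", x = 10, y = 20,
#'   sex = "M", age_class = "adult",
#'   L1.1 = c(100L, 102L), L1.2 = c(100L, 104L)
#' ))
#' gt_loci(gt)
#' @export
genotype_table <- function(x, loci = NULL) {
  x <- tibble::as_tibble(x)
  if (is.null(loci)) {
    a1 <- stringr::str_subset(names(x), "\\.1$")
    loci <- stringr::str_remove(a1, "\\.1$")
    loci <- loci[paste0(loci, ".2") %in% names(x)]
  }
  if (length(loci) == 0L) {
    rlang::abort("no locus columns found (expected pairs named '<locus>.1' and '<locus>.2')")
  }
  missing_cols <- setdiff(c("id", allele_cols(loci)), names(x))
  if (length(missing_cols) > 0L) {
    rlang::abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(x$id)) {
    rlang::abort(paste0(
      "duplicate individual ids: ",
      paste(unique(x$id[duplicated(x$id)]), collapse = ", ")
    ))
  }
  for (loc in loci) {
    a <- x[[paste0(loc, ".1")]]
    b <- x[[paste0(loc, ".2")]]
    for (v in list(a, b)) {
      if (!is.numeric(v) || any(v[!is.na(v)] != as.integer(v[!is.na(v)]))) {
        rlang::abort(paste0("locus ", loc, ": alleles must be integers"))
      }
      if (any(v <= 0, na.rm = TRUE)) {
        rlang::abort(paste0("locus ", loc, ": allele sizes must be positive"))
      }
    }
    half <- xor(is.na(a), is.na(b))
    if (any(half)) {
      rlang::abort(paste0(
        "locus ", loc, ": half-calls (one allele missing) in rows ",
        paste(which(half), collapse = ", ")
      ))
    }
    if (all(is.na(a))) {
      rlang::abort(paste0("locus ", loc, ": no observed alleles in the table"))
    }
    x[[paste0(loc, ".1")]] <- as.integer(a)
    x[[paste0(loc, ".2")]] <- as.integer(b)
  }
  attr(x, "loci") <- loci
  class(x) <- c("genotype_tbl", class(x))
  x
}

#' @rdname genotype_table
#' @export
gt_loci <- function(x) attr(x, "loci")

allele_cols <- function(loci) as.vector(rbind(paste0(loci, ".1"), paste0(loci, ".2")))

#' Pivot a genotype table to one row per gene copy
#'
#' @param x A [genotype_table()].
#' @param drop_missing Drop missing calls?
#' @return Tibble with columns `id`, `locus`, `copy` (1 or 2) and `allele`.
#' @export
gt_alleles_long <- function(x, drop_missing = TRUE) {
  loci <- gt_loci(x)
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(x), "id", dplyr::all_of(allele_cols(loci))),
    cols = -"id",
    names_to = c("locus", "copy"),
    names_pattern = "^(.*)\\.([12])$",
    values_to = "allele"
  )
  long$copy <- as.integer(long$copy)
  if (drop_missing) long <- dplyr::filter(long, !is.na(.data$allele))
  long
}

#' Describe the column layout of a genotype CSV
#'
#' @param id,year,region,x,y,sex,age_class Column names in the file holding
#'   each metadata field; set to `NULL` if absent.
#' @param locus_columns How allele pairs are stored: `"pair"` (two columns per
#'   locus, `<locus>_1`/`<locus>_2` or given by `allele_suffixes`) or
#'   `"joined"` (a single `<locus>` column with alleles joined by `sep`).
#' @param loci Locus names (required for `"joined"`; inferred for `"pair"` if
#'   `NULL`).
#' @param allele_suffixes Suffixes of the two allele columns for `"pair"`.
#' @param sep Separator of the joined allele pair.
#' @param missing Values interpreted as a missing allele (besides empty cells).
#' @return A dialect object consumed by [read_genotype_csv()].
#' @export
csv_dialect <- function(id = "id", year = "year", region = "region",
                        x = "x", y = "y", sex = "sex", age_class = "age_class",
                        locus_columns = c("pair", "joined"), loci = NULL,
                        allele_suffixes = c("_1", "_2"), sep = "/",
                        missing = c("0", "NA", "")) {
  structure(
    list(
      id = id, year = year, region = region, x = x, y = y, sex = sex,
      age_class = age_class, locus_columns = match.arg(locus_columns),
      loci = loci, allele_suffixes = allele_suffixes, sep = sep,
      missing = missing
    ),
    class = "csv_dialect"
  )
}

#' Read a genotype CSV file
#'
#' Reads a table of diploid multilocus genotypes plus individual metadata and
#' validates it into a [genotype_table()]. Rows failing validation are
#' reported with their line numbers.
#'
#' @param path Path to the CSV file.
#' @param dialect A [csv_dialect()] mapping file columns to fields.
#' @return A `genotype_tbl`.
#' @export
read_genotype_csv <- function(path, dialect = csv_dialect()) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  d <- dialect
  take <- function(col, parse = identity) {
    if (is.null(col) || !col %in% names(raw)) return(NULL)
    parse(raw[[col]])
  }
  out <- tibble::tibble(id = take(d$id))
  if (is.null(out$id)) rlang::abort(paste0("id column '", d$id, "' not found"))
  out$year <- take(d$year, function(v) as.integer(v))
  out$region <- take(d$region)
  out$x <- take(d$x, as.numeric)
  out$y <- take(d$y, as.numeric)
  out$sex <- take(d$sex)
  out$age_class <- take(d$age_class)
  out <- out[!vapply(out, is.null, logical(1))]

  parse_allele <- function(v, locus) {
    v[v %in% d$missing] <- NA_character_
    bad <- !is.na(v) & is.na(suppressWarnings(as.integer(v)))
    if (any(bad)) {
      rlang::abort(paste0(
        "locus ", locus, ": non-integer allele in data row(s) ",
        paste(which(bad), collapse = ", ")
      ))
    }
    as.integer(v)
  }

  if (d$locus_columns == "pair") {
    loci <- d$loci
    if (is.null(loci)) {
      s1 <- d$allele_suffixes[1]
      cand <- stringr::str_subset(names(raw), paste0(stringr::str_escape(s1), "$"))
      loci <- stringr::str_remove(cand, paste0(stringr::str_escape(s1), "$"))
      loci <- loci[paste0(loci, d$allele_suffixes[2]) %in% names(raw)]
    }
    if (length(loci) == 0L) rlang::abort("no locus columns matched the dialect")
    for (loc in loci) {
      out[[paste0(loc, ".1")]] <- parse_allele(raw[[paste0(loc, d$allele_suffixes[1])]], loc)
      out[[paste0(loc, ".2")]] <- parse_allele(raw[[paste0(loc, d$allele_suffixes[2])]], loc)
    }
  } else {
    loci <- d$loci
    if (is.null(loci)) rlang::abort("dialect 'joined' requires explicit loci")
    for (loc in loci) {
      parts <- stringr::str_split_fixed(raw[[loc]], stringr::fixed(d$sep), 2)
      out[[paste0(loc, ".1")]] <- parse_allele(parts[, 1], loc)
      out[[paste0(loc, ".2")]] <- parse_allele(parts[, 2], loc)
    }
  }
  genotype_table(out, loci = loci)
}

#' Default pooling of sampling years into time points
#'
#' Early sampling years are pooled across three consecutive calendar years to
#' reach workable sample sizes; later time points are single years. Time
#' points are labelled by their shorthand year.
#'
#' @return Named integer-keyed lookup: calendar year -> time point label.
#' @export
default_pooling_rules <- function() {
  c(
    "1993" = "1994", "1994" = "1994", "1995" = "1994",
    "1998" = "1999", "1999" = "1999", "2000" = "1999",
    "2004" = "2004", "2009" = "2009", "2014" = "2014"
  )
}

#' Assign individuals to spatial-temporal groupings (STGs)
#'
#' An STG is the cross of a region label and a sampling time point. Sampling
#' years are mapped to time points through `pooling_rules`; regions are taken
#' from the table's `region` column.
#'
#' @param x A [genotype_table()] with `year` and `region` columns.
#' @param pooling_rules Named character vector mapping calendar years (as
#'   names) to time-point labels, e.g. [default_pooling_rules()].
#' @param exclude_regions Region labels dropped from the scheme (individuals
#'   in them are left unassigned), e.g. a catch-all "Other".
#' @return A `grouping_tbl`: tibble with `id`, `region`, `time_point` and
#'   `stg` (`"region_timepoint"`), one row per assigned individual.
#' @export
assign_stgs <- function(x, pooling_rules = default_pooling_rules(),
                        exclude_regions = character()) {
  stopifnot(all(c("year", "region") %in% names(x)))
  keep <- !(x$region %in% exclude_regions)
  tab <- tibble::as_tibble(x)[keep, c("id", "year", "region")]
  tp <- unname(pooling_rules[as.character(tab$year)])
  if (anyNA(tp)) {
    bad <- tab$id[is.na(tp)]
    rlang::abort(paste0(
      "years not covered by pooling rules for individuals: ",
      paste(bad, collapse = ", ")
    ))
  }
  out <- tibble::tibble(
    id = tab$id, region = tab$region, time_point = tp,
    stg = paste(tab$region, tp, sep = "_")
  )
  class(out) <- c("grouping_tbl", class(out))
  out
}

#' Thin a genotype table to one individual per grid cell and year
#'
#' Spatial pseudoreplication is avoided by retaining a single, uniformly
#' chosen individual from every `cell_km` x `cell_km` grid square per
#' sampling year. The grid is anchored at the coordinate origin with
#' half-open cells `[i*cell_km, (i+1)*cell_km)`.
#'
#' @param x A [genotype_table()] with `x`, `y` and `year`.
#' @param cell_km Cell size in km (default 20, around an otter home range).
#' @param seed Integer seed; the thinning is deterministic given the seed.
#' @return The thinned `genotype_tbl`.
#' @export
grid_subsample <- function(x, cell_km = 20, seed) {
  stopifnot(all(c("x", "y", "year") %in% names(x)))
  miss <- is.na(x$x) | is.na(x$y)
  if (any(miss)) {
    rlang::warn(paste0(
      sum(miss), " individual(s) without coordinates excluded from grid subsampling"
    ))
  }
  tab <- tibble::as_tibble(x)[!miss, , drop = FALSE]
  cell <- paste(floor(tab$x / cell_km), floor(tab$y / cell_km), tab$year, sep = ":")
  keep_ids <- withr::with_seed(seed, {
    split(tab$id, cell) |>
      purrr::map_chr(function(ids) ids[[sample.int(length(ids), 1L)]])
  })
  out <- tab[tab$id %in% keep_ids, , drop = FALSE]
  genotype_table(out, loci = gt_loci(x))
}

#' Per-group, per-locus allele counts and frequencies
#'
#' @param x A [genotype_table()].
#' @param grouping A grouping from [assign_stgs()], or `NULL` to treat the
#'   whole table as one group. Individuals absent from the grouping are
#'   dropped.
#' @param by Grouping column of `grouping` to use: `"stg"`, `"region"` or
#'   `"time_point"`.
#' @return Tibble with `group`, `locus`, `allele`, `count`, `gene_copies`
#'   (total non-missing gene copies for that group and locus) and `freq`.
#'   Loci with no data in a group get no rows (empty spectrum).
#' @export
allele_frequencies <- function(x, grouping = NULL, by = "stg") {
  long <- gt_alleles_long(x)
  if (is.null(grouping)) {
    long$group <- "all"
  } else {
    key <- grouping[[by]]
    names(key) <- grouping$id
    long$group <- unname(key[long$id])
    long <- dplyr::filter(long, !is.na(.data$group))
  }
  counts <- dplyr::count(long, .data$group, .data$locus, .data$allele, name = "count")
  counts |>
    dplyr::group_by(.data$group, .data$locus) |>
    dplyr::mutate(gene_copies = sum(.data$count), freq = .data$count / .data$gene_copies) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$group, .data$locus, .data$allele)
}

#' Write a genotype table as a Genepop file
#'
#' One `POP` block per group, individuals named `id`, alleles coded as
#' 3-digit numbers. Allele sizes up to 999 are written verbatim; larger sizes
#' are recoded to ranks, with the mapping recorded in the title line.
#' Missing calls are written as `000000`.
#'
#' @param x A [genotype_table()].
#' @param grouping A grouping tibble (see [assign_stgs()]); groups are its
#'   `stg` column.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(x, grouping, path) {
  loci <- gt_loci(x)
  groups <- split(grouping$id, grouping$stg)
  if (length(groups) == 0L || any(lengths(groups) == 0L)) {
    rlang::abort("empty group in grouping")
  }
  tab <- tibble::as_tibble(x)
  recodes <- list()
  for (loc in loci) {
    sizes <- sort(unique(stats::na.omit(c(tab[[paste0(loc, ".1")]], tab[[paste0(loc, ".2")]]))))
    if (length(sizes) > 999L) rlang::abort(paste0("locus ", loc, ": >999 distinct alleles"))
    if (length(sizes) > 0L && max(sizes) > 999L) {
      recodes[[loc]] <- stats::setNames(seq_along(sizes), sizes)
    }
  }
  code <- function(loc, v) {
    if (!is.null(recodes[[loc]])) v <- unname(recodes[[loc]][as.character(v)])
    ifelse(is.na(v), "000", formatC(v, width = 3, flag = "0"))
  }
  title <- "popgenmon genotype export"
  if (length(recodes) > 0L) {
    maps <- purrr::imap_chr(recodes, function(m, loc) {
      paste0(loc, "{", paste(names(m), m, sep = ">", collapse = ","), "}")
    })
    title <- paste0(title, " | recoded: ", paste(maps, collapse = " "))
  }
  lines <- c(title, loci)
  rows <- stats::setNames(seq_len(nrow(tab)), tab$id)
  for (g in names(groups)) {
    lines <- c(lines, "POP")
    for (ind in groups[[g]]) {
      i <- rows[[ind]]
      gcodes <- vapply(loci, function(loc) {
        paste0(code(loc, tab[[paste0(loc, ".1")]][i]), code(loc, tab[[paste0(loc, ".2")]][i]))
      }, character(1))
      lines <- c(lines, paste0(ind, " ,  ", paste(gcodes, collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a Genepop file written by [write_genepop()]
#'
#' @param path Path to a Genepop 4.x file (3-digit allele coding, loci listed
#'   one per line, `POP` separators).
#' @return A `genotype_tbl` with a `pop` column holding the POP block label
#'   (the first individual id of the block, Genepop convention aside: blocks
#'   are numbered `pop1`, `pop2`, ... and the label stored in `pop`).
#' @export
read_genepop <- function(path) {
  lines <- readLines(path)
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) rlang::abort("no POP line found")
  loci_lines <- lines[2:(first_pop - 1)]
  loci <- unlist(stringr::str_split(paste(loci_lines, collapse = ","), ","))
  loci <- trimws(loci[trimws(loci) != ""])
  ids <- character(); pops <- character(); mat <- list()
  pop_i <- 0L
  for (ln in lines[first_pop:length(lines)]) {
    if (toupper(trimws(ln)) == "POP") { pop_i <- pop_i + 1L; next }
    if (trimws(ln) == "") next
    parts <- stringr::str_split_fixed(ln, ",", 2)
    id <- trimws(parts[1])
    codes <- stringr::str_split_1(trimws(parts[2]), "\\s+")
    if (length(codes) != length(loci)) {
      rlang::abort(paste0("individual ", id, ": expected ", length(loci), " locus codes"))
    }
    ids <- c(ids, id); pops <- c(pops, paste0("pop", pop_i))
    mat[[length(mat) + 1L]] <- codes
  }
  out <- tibble::tibble(id = ids, pop = pops)
  for (j in seq_along(loci)) {
    codes <- vapply(mat, `[[`, character(1), j)
    a <- as.integer(substr(codes, 1, 3))
    b <- as.integer(substr(codes, 4, 6))
    a[a == 0L] <- NA_integer_; b[b == 0L] <- NA_integer_
    out[[paste0(loci[j], ".1")]] <- a
    out[[paste0(loci[j], ".2")]] <- b
  }
  genotype_table(out, loci = loci)
}
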