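#' Build a genomic window grid
#'
#' Tiles each chromosome with fixed-size windows (0-based, half-open). The
#' last window of a chromosome may be shorter than `window_size`. All
#' windowed statistics in the package (pairwise differences, within-individual
#' mismatches, IBD/ROH states) are indexed on this grid.
#'
#' @param chromosomes A data frame with columns `chrom` and `length` (bp), in
#'   the desired chromosome order.
#' @param window_size Window size in bp. Default 10 Mb.
#' @return A tibble of class `kin_grid` with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `window` (1..L, the global window index).
#' @examples
#' build_window_grid(data.frame(chrom = "chr1", length = 96e6))
#' @export
build_window_grid <- function(chromosomes, window_size = 1e7) {
  stopifnot(is.data.frame(chromosomes))
  if (nrow(chromosomes) == 0) stop("empty chromosome table")
  if (!all(c("chrom", "length") %in% names(chromosomes))) {
    stop("`chromosomes` needs columns `chrom` and `length`")
  }
  if (window_size <= 0) stop("`window_size` must be > 0")
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be > 0")
  if (anyDuplicated(chromosomes$chrom)) stop("duplicated chromosome names")

  grid <- purrr::map2_dfr(
    as.character(chromosomes$chrom), chromosomes$length,
    function(ch, len) {
      starts <- seq(0, len - 1, by = window_size)
      tibble::tibble(chrom = ch, start = starts,
                     end = pmin(starts + window_size, len))
    }
  )
  grid$window <- seq_len(nrow(grid))
  attr(grid, "window_size") <- window_size
  attr(grid, "chrom_lengths") <- stats::setNames(chromosomes$length,
                                                 as.character(chromosomes$chrom))
  class(grid) <- c("kin_grid", class(grid))
  grid
}

#' Infer a window grid from site-count tables
#'
#' Convenience constructor: chromosome lengths are taken as the largest
#' observed position per chromosome, rounded up to a full window.
#'
#' @param counts A site-count tibble (or list of them) with columns `chrom`,
#'   `pos`.
#' @inheritParams build_window_grid
#' @return A `kin_grid` tibble.
#' @export
grid_from_counts <- function(counts, window_size = 1e7) {
  if (is.data.frame(counts)) counts <- list(counts)
  all <- dplyr::bind_rows(lapply(counts, function(x) x[, c("chrom", "pos")]))
  lens <- all |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(length = ceiling(max(.data$pos) / window_size) * window_size,
                     .groups = "drop") |>
    dplyr::rename(chrom = "chrom")
  build_window_grid(as.data.frame(lens), window_size)
}

# Map 1-based positions to global window indices on a grid. Positions past the
# chromosome end fall into the last window of that chromosome.
window_index <- function(grid, chrom, pos) {
  ws <- attr(grid, "window_size")
  first <- tapply(grid$window, factor(grid$chrom, levels = unique(grid$chrom)), min)
  nwin <- tapply(grid$window, factor(grid$chrom, levels = unique(grid$chrom)), length)
  ch <- as.character(chrom)
  if (!all(ch %in% names(first))) {
    stop("chromosome names not present in grid: ",
         paste(utils::head(setdiff(unique(ch), names(first))), collapse = ", "))
  }
  off <- floor((pos - 1) / ws)           # 0-based within-chromosome window
  off <- pmin(off, nwin[ch] - 1)
  as.integer(first[ch] + off)
}

# Per-chromosome window index vector (for HMM chain restarts): integer factor of
# chromosome per window, in grid order.
grid_chrom_id <- function(grid) {
  as.integer(factor(grid$chrom, levels = unique(grid$chrom)))
}

#' Expected per-site pairwise difference
#'
#' The probability that one read sampled from each of two individuals carries
#' different alleles, given their derived-read proportions. Summed over sites
#' this averages over all possible single-read samplings instead of picking
#' one pseudo-haploid draw.
#'
#' @param nu_i,nu_j Derived-allele read proportions in `[0, 1]`.
#' @return Expected mismatch probability in `[0, 1]`.
#' @export
pair_site_difference <- function(nu_i, nu_j) {
  stopifnot(all(nu_i >= 0 & nu_i <= 1), all(nu_j >= 0 & nu_j <= 1))
  nu_i * (1 - nu_j) + (1 - nu_i) * nu_j
}

check_counts <- function(x, id = "individual") {
  need <- c("chrom", "pos", "derived", "total")
  if (!all(need %in% names(x))) {
    stop(id, ": site-count table needs columns ", paste(need, collapse = ", "))
  }
  if (any(x$derived > x$total)) stop(id, ": derived > total at some sites")
  if (any(x$derived < 0) || any(x$total < 0)) stop(id, ": negative counts")
  invisible(x)
}

#' Windowed pairwise differences for a pair of individuals
#'
#' Restricts to sites with at least one read in both individuals, computes the
#' expected per-site mismatch from the derived-read proportions, and sums it
#' within windows.
#'
#' @param a,b Site-count tibbles with columns `chrom`, `pos` (1-based),
#'   `derived`, `total`.
#' @param grid A `kin_grid` from [build_window_grid()].
#' @return A tibble with one row per window: `chrom`, `start`, `end`,
#'   `window`, `D` (expected pairwise differences) and `N` (overlapping site
#'   count). Windows without overlapping sites get `D = N = 0`.
#' @export
aggregate_pair_windows <- function(a, b, grid) {
  check_counts(a, "a"); check_counts(b, "b")
  if (!all(unique(a$chrom) %in% grid$chrom) ||
      !all(unique(b$chrom) %in% grid$chrom)) {
    stop("mismatched chromosome names between counts and grid")
  }
  ov <- dplyr::inner_join(
    dplyr::filter(a, .data$total >= 1)[, c("chrom", "pos", "derived", "total")],
    dplyr::filter(b, .data$total >= 1)[, c("chrom", "pos", "derived", "total")],
    by = c("chrom", "pos"), suffix = c("_a", "_b")
  )
  if (nrow(ov) == 0) {
    out <- grid[, c("chrom", "start", "end", "window")]
    out$D <- 0; out$N <- 0
    return(tibble::as_tibble(out))
  }
  nu_a <- ov$derived_a / ov$total_a
  nu_b <- ov$derived_b / ov$total_b
  d <- pair_site_difference(nu_a, nu_b)
  w <- window_index(grid, ov$chrom, ov$pos)
  L <- nrow(grid)
  out <- grid[, c("chrom", "start", "end", "window")]
  out$D <- as.numeric(rowsum(d, factor(w, levels = seq_len(L))))
  out$N <- as.numeric(rowsum(rep(1, length(w)), factor(w, levels = seq_len(L))))
  out$D[is.na(out$D)] <- 0; out$N[is.na(out$N)] <- 0
  tibble::as_tibble(out)
}

#' Windowed within-individual mismatch statistics
#'
#' Input for the ROH HMM. Only sites covered by at least two reads are used.
#' Each such site contributes its expected read-pair mismatch to `Delta` and 1
#' to `M`. The default `"pair"` estimator is the proportion of read pairs with
#' different alleles, `2*nu*(1-nu)*d/(d-1)` for depth `d`, which is unbiased
#' for half the site heterozygosity at any depth. The `"plugin"` estimator
#' `2*nu*(1-nu)` (sampling reads with replacement) is biased low at depth 2
#' and is provided for comparison only.
#'
#' @param a Site-count tibble (`chrom`, `pos`, `derived`, `total`).
#' @param grid A `kin_grid`.
#' @param estimator `"pair"` (default) or `"plugin"`.
#' @return A tibble with per-window `Delta` and `M`.
#' @export
within_individual_diffs <- function(a, grid, estimator = c("pair", "plugin")) {
  estimator <- match.arg(estimator)
  check_counts(a, "a")
  x <- dplyr::filter(a, .data$total >= 2)
  L <- nrow(grid)
  out <- grid[, c("chrom", "start", "end", "window")]
  if (nrow(x) == 0) {
    out$Delta <- 0; out$M <- 0
    return(tibble::as_tibble(out))
  }
  nu <- x$derived / x$total
  mis <- 2 * nu * (1 - nu)
  if (estimator == "pair") mis <- mis * x$total / (x$total - 1)
  w <- window_index(grid, x$chrom, x$pos)
  out$Delta <- as.numeric(rowsum(mis, factor(w, levels = seq_len(L))))
  out$M <- as.numeric(rowsum(rep(1, length(mis)), factor(w, levels = seq_len(L))))
  out$Delta[is.na(out$Delta)] <- 0; out$M[is.na(out$M)] <- 0
  tibble::as_tibble(out)
}

#' Estimate the background pairwise difference rate p0
#'
#' p0 is the expected per-site mismatch rate between unrelated individuals.
#' Following the pseudo-haploid mismatch tradition, it is estimated as the
#' median across pairs of each pair's genome-wide ratio `sum(D)/sum(N)`,
#' which is robust as long as most pairs are unrelated.
#'
#' @param pair_windows A tibble with columns `pair` (identifier), `D`, `N` —
#'   e.g. row-bound outputs of [aggregate_pair_windows()] with a `pair`
#'   column added.
#' @param override Optional user-supplied p0; returned unchanged (after range
#'   checking) when given.
#' @return A single proportion, guaranteed in (0, 0.5).
#' @export
estimate_p0 <- function(pair_windows, override = NULL) {
  if (!is.null(override)) {
    if (override <= 0 || override >= 0.5) stop("supplied p0 must be in (0, 0.5)")
    return(override)
  }
  stopifnot(all(c("pair", "D", "N") %in% names(pair_windows)))
  ratios <- pair_windows |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(D = sum(.data$D), N = sum(.data$N), .groups = "drop") |>
    dplyr::filter(.data$N > 0)
  if (nrow(ratios) == 0) stop("all pairs have zero overlapping sites")
  p0 <- stats::median(ratios$D / ratios$N)
  if (p0 <= 0 || p0 >= 0.5) {
    stop("estimated p0 = ", signif(p0, 4),
         " is outside (0, 0.5); supply p0 explicitly via `override`")
  }
  p0
}

#' Read a per-individual site-count table
#'
#' Expects a tab-separated file with header `chrom pos derived total`,
#' positions 1-based. Gzip-compressed files are handled transparently.
#'
#' @param path File path.
#' @return A site-count tibble sorted by chromosome (file order) and position.
#' @export
read_site_counts <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    pos = readr::col_double(),
    derived = readr::col_double(),
    total = readr::col_double()
  ), progress = FALSE)
  check_counts(x, basename(path))
  x |>
    dplyr::mutate(chrom = factor(.data$chrom, levels = unique(.data$chrom))) |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::mutate(chrom = as.character(.data$chrom))
}

#' Write a windowed pair table
#'
#' TSV with columns `chrom start end D N`, 0-based half-open coordinates.
#'
#' @param x Output of [aggregate_pair_windows()].
#' @param path File path.
#' @export
write_window_table <- function(x, path) {
  readr::write_tsv(x[, c("chrom", "start", "end", "D", "N")], path)
  invisible(path)
}
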