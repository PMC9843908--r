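test_that("window grids tile chromosomes correctly", {
  g <- build_window_grid(data.frame(chrom = "chr1", length = 96e6), 1e7)
  expect_equal(nrow(g), 10)
  expect_equal(g$end[10] - g$start[10], 6e6)

  g22 <- build_window_grid(data.frame(chrom = paste0("chr", 1:22),
                                      length = rep(96e6, 22)), 1e7)
  expect_equal(nrow(g22), 220)
  expect_equal(g22$window, seq_len(220))

  g1 <- build_window_grid(data.frame(chrom = "chr1", length = 1e7), 1e7)
  expect_equal(nrow(g1), 1)

  # windows tile without gaps or overlap
  by_chrom <- split(g22, g22$chrom)
  for (b in by_chrom) {
    expect_equal(b$start[-1], b$end[-nrow(b)])
  }
  expect_error(build_window_grid(data.frame(chrom = character(0),
                                            length = numeric(0))),
               "empty")
})

test_that("pair_site_difference follows the read-sampling expectation", {
  expect_equal(pair_site_difference(1, 0), 1)
  expect_equal(pair_site_difference(0.5, 0.5), 0.5)
  expect_equal(pair_site_difference(1, 1), 0)
  expect_error(pair_site_difference(1.2, 0))
})

test_that("pairwise aggregation matches the overlap rule", {
  g <- build_window_grid(data.frame(chrom = "chr1", length = 1e7), 1e7)
  a <- counts_tbl("chr1", c(100, 200, 300), c(2, 0, 1), c(2, 2, 2))
  b <- counts_tbl("chr1", c(100, 200, 300), c(2, 2, 0), c(2, 2, 2))
  pw <- aggregate_pair_windows(a, b, g)
  expect_equal(pw$N, 3)
  expect_equal(pw$D, 1.5)  # 0 + 1 + 0.5

  # site covered in a only is excluded
  a2 <- counts_tbl("chr1", c(100, 200), c(1, 1), c(1, 1))
  b2 <- counts_tbl("chr1", c(100, 200), c(1, 0), c(1, 0))
  pw2 <- aggregate_pair_windows(a2, b2, g)
  expect_equal(pw2$N, 1)

  # no overlap at all -> zeros, not dropped rows
  pw3 <- aggregate_pair_windows(
    counts_tbl("chr1", 1, 1, 1), counts_tbl("chr1", 2, 1, 1), g)
  expect_equal(pw3$N, 0)
  expect_equal(pw3$D, 0)

  expect_error(aggregate_pair_windows(
    counts_tbl("chrX", 1, 1, 1), counts_tbl("chr1", 1, 1, 1), g),
    "chromosome")
})

test_that("expected differences equal exhaustive single-read sampling for genotypes", {
  # oracle: enumerate the four chromosome draws per site
  enum_site <- function(ga, gb) {
    a <- c(rep(1, ga), rep(0, 2 - ga))
    b <- c(rep(1, gb), rep(0, 2 - gb))
    mean(outer(a, b, `!=`))
  }
  set.seed(11)
  ga <- sample(0:2, 20, replace = TRUE)
  gb <- sample(0:2, 20, replace = TRUE)
  g <- build_window_grid(data.frame(chrom = "chr1", length = 1e7), 1e7)
  a <- counts_tbl("chr1", 1:20 * 100, ga, rep(2, 20))
  b <- counts_tbl("chr1", 1:20 * 100, gb, rep(2, 20))
  pw <- aggregate_pair_windows(a, b, g)
  expect_equal(pw$D, sum(mapply(enum_site, ga, gb)), tolerance = 1e-12)

  # invariance under site permutation
  perm <- sample(20)
  pw2 <- aggregate_pair_windows(a[perm, ], b[perm, ], g)
  expect_equal(pw2$D, pw$D)
})

test_that("within-individual mismatch estimators behave at low depth", {
  g <- build_window_grid(data.frame(chrom = "chr1", length = 1e7), 1e7)
  x <- counts_tbl("chr1", c(100, 200, 300), c(2, 5, 1), c(4, 5, 1))
  # pair estimator: site1 2nu(1-nu)*d/(d-1) = 0.5*4/3; site2 hom -> 0;
  # site3 single read excluded
  r <- within_individual_diffs(x, g)
  expect_equal(r$M, 2)
  expect_equal(r$Delta, 2 * 0.5 * 0.5 * 4 / 3, tolerance = 1e-12)
  # plug-in option reproduces the uncorrected 2nu(1-nu) contribution
  r2 <- within_individual_diffs(x, g, estimator = "plugin")
  expect_equal(r2$Delta, 0.5, tolerance = 1e-12)
  # pair estimator is unbiased for het/2 at depth 2: E over read draws
  # of a het site: P(two reads differ) = 1/2
  probs <- dbinom(0:2, 2, 0.5)          # derived count among 2 reads
  vals <- 2 * (0:2) / 2 * (1 - (0:2) / 2) * 2  # 2nu(1-nu)*d/(d-1), d=2
  expect_equal(sum(probs * vals), 0.5)
})

test_that("p0 estimation takes the median pair ratio with sanity bounds", {
  mk <- function(ratios) {
    dplyr::bind_rows(lapply(seq_along(ratios), function(i) {
      tibble::tibble(pair = i, D = ratios[i] * 100, N = 100)
    }))
  }
  expect_equal(estimate_p0(mk(c(0.10, 0.20, 0.21, 0.22, 0.40))), 0.21)
  expect_equal(estimate_p0(mk(0.18)), 0.18)
  expect_equal(estimate_p0(mk(c(0.1, 0.2))), 0.15)
  expect_equal(estimate_p0(mk(0.3), override = 0.2), 0.2)
  expect_error(estimate_p0(mk(c(0.55, 0.6, 0.58))), "outside")
  expect_error(estimate_p0(tibble::tibble(pair = 1, D = 0, N = 0)), "zero")
  # robust to one outlier pair
  expect_equal(estimate_p0(mk(c(0.2, 0.2, 0.2, 0.2, 0.49))), 0.2)
})

test_that("site-count TSVs round-trip, including gzip", {
  x <- counts_tbl("chr1", c(10, 20), c(1, 0), c(2, 1))
  f <- tempfile(fileext = ".counts.tsv")
  readr::write_tsv(x, f)
  expect_equal(as.data.frame(read_site_counts(f)), as.data.frame(x))
  fgz <- tempfile(fileext = ".counts.tsv.gz")
  readr::write_tsv(x, fgz)
  expect_equal(as.data.frame(read_site_counts(fgz)), as.data.frame(x))
  bad <- counts_tbl("chr1", 10, 3, 2)
  fb <- tempfile(fileext = ".tsv")
  readr::write_tsv(bad, fb)
  expect_error(read_site_counts(fb), "derived")
})
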