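#' Emission mean parameters for the IBD/ROH beta-binomial model
#'
#' The expected pairwise difference rate between two individuals depends on
#' how many of the four possible chromosome comparisons are between identical
#' chromosomes: none (`p0`, unrelated background), one (`p1 = 3/4 p0`), two
#' (`p2 = p0/2`) or four (`p4 = p2/2`). `p4` would be 0 for a window entirely
#' inside shared homozygous tracts, but window boundaries rarely coincide with
#' tract boundaries, so it is set to `p2/2` as a deliberate compromise.
#'
#' The level used for a window is determined by the IBD state `Z` (0, 1, 2
#' shared chromosomes) and the ROH state `H` (0, 1, 2 individuals
#' homozygous): row `Z = 0` is always level 0 (ROH does not affect comparisons
#' between unrelated chromosomes), row `Z = 1` gives levels (1, 2, 4) and row
#' `Z = 2` gives (2, 4, 4).
#'
#' @param p0 Background pairwise difference rate, in (0, 1).
#' @return An object of class `kin_emission_params`: list with `p` (named
#'   vector of means for levels 0, 1, 2, 4) and `level_matrix` (3x3 matrix of
#'   level labels indexed by Z then H).
#' @export
build_p_matrix <- function(p0) {
  if (!is.numeric(p0) || length(p0) != 1 || p0 <= 0 || p0 >= 1) {
    stop("p0 must be a single value in (0, 1)")
  }
  p <- c("0" = p0, "1" = 0.75 * p0, "2" = 0.5 * p0, "4" = 0.25 * p0)
  lev <- matrix(c("0", "0", "0",
                  "1", "2", "4",
                  "2", "4", "4"),
                nrow = 3, byrow = TRUE,
                dimnames = list(Z = 0:2, H = 0:2))
  structure(list(p = p, level_matrix = lev), class = "kin_emission_params")
}

#' Beta-binomial log probability (Balding-Nichols parameterization)
#'
#' Log density of `D` differences among `N` comparisons where the per-window
#' difference rate is Beta-distributed with mean `p` and over-dispersion
#' `delta` (`alpha = p*delta`, `beta = (1-p)*delta`; variance of the rate is
#' `p(1-p)/(delta+1)`). All factorials are generalized with log-Gamma so
#' non-integer `D` and `N` (which arise from read-proportion averaging and
#' contamination correction) are accepted. `N = 0` returns 0 (probability 1).
#'
#' @param D,N Real-valued counts, `0 <= D <= N`.
#' @param p Mean difference rate in (0, 1).
#' @param delta Over-dispersion, > 0 (large `delta` approaches the binomial).
#' @return Log probability (vectorized over `D`, `N`).
#' @export
betabinom_logpmf <- function(D, N, p, delta) {
  if (any(delta <= 0)) stop("delta must be > 0")
  if (any(p <= 0) || any(p >= 1)) stop("p must be in (0, 1)")
  if (any(D < 0) || any(N < 0)) stop("negative counts")
  if (any(D > N + 1e-12)) stop("D > N")
  D <- pmin(D, N)
  out <- lgamma(N + 1) - lgamma(D + 1) - lgamma(N - D + 1) +
    lbeta(D + p * delta, N - D + delta * (1 - p)) -
    lbeta(p * delta, (1 - p) * delta)
  out[N == 0] <- 0
  out
}

#' Constraint interval for an over-dispersion parameter
#'
#' Unconstrained fitting of the per-level over-dispersions lets a
#' single-state model absorb multi-state data by inflating its variance. The
#' search space is therefore constrained so that each level's Beta
#' distribution stays within one standard deviation of its own mean before
#' reaching the nearest other level mean: with
#' `sd_i = sqrt(p_i (1 - p_i) / (delta_i + 1))` we require `sd_i <= gap_i`,
#' i.e. `delta_i >= p_i (1 - p_i) / gap_i^2 - 1`, where `gap_i` is the
#' distance from `p_i` to the nearest other mean.
#'
#' @param params A `kin_emission_params` object.
#' @param level Level label, one of `"0", "1", "2", "4"`.
#' @param floor,ceiling Numerical bounds for the optimizer.
#' @return Numeric vector `c(lower, upper)`.
#' @export
delta_constraint_interval <- function(params, level, floor = 1e-6,
                                      ceiling = 1e6) {
  stopifnot(inherits(params, "kin_emission_params"))
  level <- as.character(level)
  p <- params$p
  if (!level %in% names(p)) stop("unknown level: ", level)
  pi <- p[[level]]
  gap <- min(abs(p[names(p) != level] - pi))
  if (gap <= 0) stop("degenerate level means: two levels share the same mean")
  lower <- max(floor, pi * (1 - pi) / gap^2 - 1)
  c(lower = lower, upper = ceiling)
}
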