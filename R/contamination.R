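# --- Contamination correction ----------------------------------------------
#
# Present-day contaminant reads inflate apparent differences between
# individuals of the target population. With known (small) per-individual
# contamination rates and a known divergence phi between target and
# contaminant populations, the windowed counts are pre-corrected before any
# HMM sees them: each observed comparison is attributed to
# endogenous-endogenous vs endogenous-contaminant origin by Bayes' rule, and
# the expected endogenous counts are kept.

#' Endogenous difference rate under contamination
#'
#' Solves the genome-wide mixture `D/N = rho (1 - C) + C phi` for the
#' endogenous rate `rho`, where `C` is the probability that a random
#' cross-individual read comparison involves a contaminant read and `phi` the
#' difference rate against the contaminant population.
#'
#' @param sumD,sumN Genome-wide totals of differences and overlapping sites.
#' @param C_ij Combined contamination probability (sum of the two
#'   individuals' rates for pairwise data).
#' @param phi Target-contaminant divergence, in (0, 1).
#' @return The endogenous rate, clamped to (1e-9, 1 - 1e-9) with a warning
#'   if the plug-in estimate falls outside.
#' @export
estimate_rho <- function(sumD, sumN, C_ij, phi) {
  if (sumN <= 0) stop("sumN must be > 0")
  stopifnot(C_ij >= 0, C_ij < 1, phi > 0, phi < 1)
  rho <- (sumD / sumN - C_ij * phi) / (1 - C_ij)
  if (rho <= 0 || rho >= 1) {
    warning("endogenous rate estimate ", signif(rho, 4),
            " outside (0, 1); clamping")
    rho <- min(max(rho, 1e-9), 1 - 1e-9)
  }
  rho
}

#' Correct pairwise window counts for contamination
#'
#' Shrinks the per-window differences `D_w` and matches `S_w = N_w - D_w`
#' by the posterior probability that a comparison of the observed kind is
#' between endogenous reads:
#' `D'_w = D_w * rho(1-C) / (rho(1-C) + C phi)` and
#' `S'_w = S_w * (1-rho)(1-C) / ((1-rho)(1-C) + C(1-phi))`, with
#' `N'_w = D'_w + S'_w`. With `C = 0` the data are returned unchanged.
#'
#' @param data Window tibble with `D`, `N` columns.
#' @param C_i,C_j Contamination rates of the two individuals (each in
#'   `[0, 0.05)`; larger values warn but proceed).
#' @param phi Target-contaminant divergence.
#' @return The input tibble with corrected `D`, `N` (non-integer in general)
#'   and an attribute `rho` (the endogenous rate used).
#' @export
correct_pair_counts <- function(data, C_i, C_j, phi) {
  stopifnot(all(c("D", "N") %in% names(data)))
  if (C_i >= 0.05 || C_j >= 0.05) {
    warning("contamination rate >= 5%; the correction assumes small rates")
  }
  C <- C_i + C_j
  if (C == 0) return(data)
  rho <- estimate_rho(sum(data$D), sum(data$N), C, phi)
  S <- data$N - data$D
  wD <- rho * (1 - C) / (rho * (1 - C) + C * phi)
  wS <- (1 - rho) * (1 - C) / ((1 - rho) * (1 - C) + C * (1 - phi))
  out <- data
  out$D <- data$D * wD
  out$N <- data$D * wD + S * wS
  attr(out, "rho") <- rho
  out
}

#' Correct within-individual window counts for contamination
#'
#' Same functional form as [correct_pair_counts()], applied to the
#' ROH-HMM input. A comparison of two reads from one individual involves a
#' contaminant read with probability `2 C_i` (to first order), so the
#' combined contamination probability is `2 C_i` by default.
#'
#' @param input Window tibble with `Delta`, `M` columns.
#' @param C_i Contamination rate of the individual.
#' @param phi Target-contaminant divergence.
#' @param C_factor Multiplier turning `C_i` into the per-comparison
#'   contamination probability (default 2).
#' @return Corrected tibble (non-integer `Delta`, `M`).
#' @export
correct_roh_counts <- function(input, C_i, phi, C_factor = 2) {
  stopifnot(all(c("Delta", "M") %in% names(input)))
  if (C_i >= 0.05) {
    warning("contamination rate >= 5%; the correction assumes small rates")
  }
  C <- C_factor * C_i
  if (C == 0) return(input)
  rho <- estimate_rho(sum(input$Delta), sum(input$M), C, phi)
  S <- input$M - input$Delta
  wD <- rho * (1 - C) / (rho * (1 - C) + C * phi)
  wS <- (1 - rho) * (1 - C) / ((1 - rho) * (1 - C) + C * (1 - phi))
  out <- input
  out$Delta <- input$Delta * wD
  out$M <- input$Delta * wD + S * wS
  attr(out, "rho") <- rho
  out
}

#' Read a contamination table
#'
#' TSV with columns `individual` and `C` (contamination proportion).
#'
#' @param path File path.
#' @return Named numeric vector of rates.
#' @export
read_contamination_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    individual = readr::col_character(), C = readr::col_double()
  ), progress = FALSE)
  stats::setNames(x$C, x$individual)
}
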