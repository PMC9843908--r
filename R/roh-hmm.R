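# --- ROH-HMM: per-individual detection of long runs of homozygosity --------

#' Baum-Welch transition update
#'
#' Row-normalizes expected transition counts. Rows with no expected mass
#' keep the previous iterate's row.
#'
#' @param xi K x K matrix of expected transition counts.
#' @param prev Previous transition matrix (used for zero rows).
#' @return Row-stochastic matrix.
#' @export
baum_welch_transition_update <- function(xi, prev = NULL) {
  xi <- as.matrix(xi)
  if (any(xi < 0)) stop("negative expected counts")
  K <- nrow(xi)
  A <- matrix(0, K, K, dimnames = dimnames(xi))
  rs <- rowSums(xi)
  for (k in seq_len(K)) {
    if (rs[k] > 0) {
      A[k, ] <- xi[k, ] / rs[k]
    } else {
      if (is.null(prev)) stop("zero row in xi and no previous matrix")
      A[k, ] <- prev[k, ]
    }
  }
  A
}

#' Fit the two-state ROH HMM for one individual
#'
#' Hidden states are non-homozygous (`Y = 2`, two distinct chromosomes
#' compared) and homozygous (`Y = 4`), with beta-binomial emissions whose
#' means are fixed at `p2 = p0/2` and `p4 = p0/4` throughout fitting; the
#' over-dispersions and the transition matrix are estimated by EM
#' (Baum-Welch update for transitions, bounded scalar maximization for each
#' over-dispersion). Windows whose observed mismatch proportion exceeds `p2`
#' are forced into the non-homozygous state by zeroing their homozygous
#' emission, which keeps transition bookkeeping coherent. Chains restart at
#' each chromosome with the stationary distribution of the current
#' transition matrix.
#'
#' @param input Window tibble with columns `chrom`, `Delta`, `M` (from
#'   [within_individual_diffs()]).
#' @param p0 Background pairwise difference rate.
#' @param init_offdiag Initial off-diagonal transition probability.
#' @param max_iter,tol EM stopping rule.
#' @param n_starts Independent EM runs; the highest-likelihood one is kept
#'   (guards against collapsed optima, see [kin_fit()]).
#' @param seed Seed for the over-dispersion initializations.
#' @return An object of class `roh_fit` with the per-window posterior
#'   probability of homozygosity `q`, fitted transitions `A_hat`,
#'   over-dispersions, log-likelihood and convergence information.
#' @export
roh_fit <- function(input, p0, init_offdiag = 0.2, max_iter = 100,
                    tol = 1e-4, n_starts = 3, seed = NULL) {
  stopifnot(all(c("chrom", "Delta", "M") %in% names(input)))
  if (sum(input$M) == 0) stop("no sites with >= 2 reads")
  if (n_starts > 1) {
    fits <- lapply(seq_len(n_starts), function(s) {
      roh_fit(input, p0, init_offdiag = init_offdiag, max_iter = max_iter,
              tol = tol, n_starts = 1,
              seed = if (is.null(seed)) NULL else seed + (s - 1) * 999983)
    })
    return(fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]])
  }
  L <- nrow(input)
  params <- build_p_matrix(p0)
  p2 <- params$p[["2"]]; p4 <- params$p[["4"]]
  bounds <- list("2" = delta_constraint_interval(params, "2"),
                 "4" = delta_constraint_interval(params, "4"))
  if (!is.null(seed)) set.seed(seed)
  delta <- stats::runif(2, 0, 1000)
  delta[1] <- min(max(delta[1], bounds[["2"]][1]), bounds[["2"]][2])
  delta[2] <- min(max(delta[2], bounds[["4"]][1]), bounds[["4"]][2])
  names(delta) <- c("2", "4")
  A <- matrix(c(1 - init_offdiag, init_offdiag,
                init_offdiag, 1 - init_offdiag), 2, 2, byrow = TRUE)
  chrom_id <- as.integer(factor(input$chrom, levels = unique(input$chrom)))
  forced <- input$M > 0 & input$Delta / pmax(input$M, 1) > p2

  emissions <- function(delta) {
    e <- cbind(betabinom_logpmf(input$Delta, input$M, p2, delta[["2"]]),
               betabinom_logpmf(input$Delta, input$M, p4, delta[["4"]]))
    e[input$M == 0, ] <- 0
    e[forced, 2] <- -Inf
    e
  }

  loglik <- -Inf; converged <- FALSE; iter <- 0; fb <- NULL
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    pi <- stationary_distribution(A)
    fb <- forward_backward_core(emissions(delta), A, pi, chrom_id)
    trace <- c(trace, fb$loglik)
    if (is.finite(loglik) && abs(fb$loglik - loglik) < tol) {
      loglik <- fb$loglik
      converged <- TRUE
      break
    }
    loglik <- fb$loglik
    A <- baum_welch_transition_update(fb$xi_sum, prev = A)
    delta[["2"]] <- maximize_delta(input$Delta, input$M, fb$gamma[, 1], p2,
                                   bounds[["2"]], prev = delta[["2"]])
    delta[["4"]] <- maximize_delta(input$Delta, input$M, fb$gamma[, 2], p4,
                                   bounds[["4"]], prev = delta[["4"]])
  }
  structure(list(
    q = fb$gamma[, 2], Gamma = fb$gamma, A_hat = A, delta = delta,
    loglik = loglik, n_iter = iter, converged = converged, forced = forced,
    p0 = p0, loglik_trace = trace, data = tibble::as_tibble(input)
  ), class = "roh_fit")
}

#' @export
print.roh_fit <- function(x, ...) {
  cat("<roh_fit> windows:", length(x$q),
      " mean P(ROH):", format(mean(x$q), digits = 3), "\n")
  invisible(x)
}

#' @method tidy roh_fit
#' @export
tidy.roh_fit <- function(x, ...) {
  out <- x$data
  out$p_roh <- x$q
  out$forced <- x$forced
  out
}

#' @method glance roh_fit
#' @export
glance.roh_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n_iter = x$n_iter,
                 converged = x$converged,
                 delta2 = x$delta[["2"]], delta4 = x$delta[["4"]],
                 stay_nonroh = x$A_hat[1, 1], stay_roh = x$A_hat[2, 2])
}

#' Combine two individuals' ROH posteriors into pair weights
#'
#' Assuming independence of the two individuals' homozygosity, returns per
#' window the probability that 0, 1 or 2 of them are homozygous.
#'
#' @param fit_i,fit_j `roh_fit` objects or numeric vectors of per-window
#'   homozygosity probabilities. `NULL` stands for "no ROH" (probability 0).
#' @param L Number of windows (needed only when both inputs are `NULL`).
#' @return L x 3 matrix with rows summing to 1.
#' @export
pair_roh_prior <- function(fit_i = NULL, fit_j = NULL, L = NULL) {
  getq <- function(f) {
    if (is.null(f)) return(NULL)
    if (inherits(f, "roh_fit")) f$q else as.numeric(f)
  }
  qi <- getq(fit_i); qj <- getq(fit_j)
  if (is.null(qi) && is.null(qj)) {
    if (is.null(L)) stop("L required when both fits are NULL")
    qi <- qj <- rep(0, L)
  }
  if (is.null(qi)) qi <- rep(0, length(qj))
  if (is.null(qj)) qj <- rep(0, length(qi))
  if (length(qi) != length(qj)) stop("length mismatch between the two fits")
  cbind((1 - qi) * (1 - qj),
        qi * (1 - qj) + (1 - qi) * qj,
        qi * qj)
}

#' Window-level sensitivity and specificity of ROH calls
#'
#' A window is truly ROH when at least `truth_threshold` of it lies in a
#' homozygous tract, and called ROH when its posterior probability of
#' homozygosity is at least `post_threshold` (both default 20%).
#'
#' @param fit A `roh_fit` (or numeric posterior vector).
#' @param truth Per-window true ROH fraction.
#' @param post_threshold,truth_threshold Classification thresholds.
#' @return Tibble with `sensitivity` and `specificity` (`NA` when a class is
#'   absent).
#' @export
roh_eval <- function(fit, truth, post_threshold = 0.2,
                     truth_threshold = 0.2) {
  q <- if (inherits(fit, "roh_fit")) fit$q else as.numeric(fit)
  stopifnot(length(q) == length(truth))
  pos <- truth >= truth_threshold
  call <- q >= post_threshold
  se <- if (any(pos)) sum(call & pos) / sum(pos) else NA_real_
  sp <- if (any(!pos)) sum(!call & !pos) / sum(!pos) else NA_real_
  tibble::tibble(sensitivity = se, specificity = sp,
                 n_roh = sum(pos), n_nonroh = sum(!pos))
}

#' Write per-window ROH posteriors as bedGraph
#'
#' @param fit A `roh_fit` whose data carries `chrom`, `start`, `end`.
#' @param path Output file.
#' @export
write_roh_bedgraph <- function(fit, path) {
  d <- fit$data
  readr::write_tsv(tibble::tibble(chrom = d$chrom, start = d$start,
                                  end = d$end, p_roh = fit$q),
                   path, col_names = FALSE)
  invisible(path)
}
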