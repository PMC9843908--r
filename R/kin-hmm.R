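# --- Pairwise IBD HMM: inference for one relatedness model -----------------

# Log emission matrix (L x |states|) for a relatedness model: per window and
# IBD state Z, the ROH state H is marginalized in probability space with the
# per-window weights h:  e_w(z) = sum_H h_wH * BB(D_w; p(z,H), delta(z,H), N_w).
kin_log_emissions <- function(D, N, h, model, params, delta) {
  lev_names <- names(params$p)
  bb <- sapply(lev_names, function(l) {
    betabinom_logpmf(D, N, params$p[[l]], delta[[l]])
  })                                    # L x 4, columns are levels
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = length(D))
  colnames(bb) <- lev_names
  K <- length(model$states)
  out <- matrix(0, length(D), K)
  for (k in seq_len(K)) {
    z <- model$states[k]
    levs <- params$level_matrix[z + 1, ]     # levels for H = 0, 1, 2
    terms <- bb[, levs, drop = FALSE]        # L x 3
    m <- apply(terms, 1, max)
    out[, k] <- m + log(rowSums(h * exp(terms - m)))
  }
  out[N == 0, ] <- 0
  out
}

#' Mixture emission probability for one window
#'
#' Probability of observing `D_w` differences among `N_w` comparisons in IBD
#' state `z`, marginalizing the ROH state over the per-window distribution
#' `h_w`. Windows with `N_w = 0` are uninformative and emit probability 1.
#'
#' @param D_w,N_w Window counts.
#' @param h_w Length-3 probability vector over the ROH state (0, 1, or 2
#'   individuals homozygous).
#' @param z IBD state (0, 1, or 2).
#' @param params `kin_emission_params` from [build_p_matrix()].
#' @param delta Named over-dispersions for levels `"0","1","2","4"`.
#' @return A probability.
#' @export
window_emission <- function(D_w, N_w, h_w, z, params, delta) {
  stopifnot(abs(sum(h_w) - 1) < 1e-8, z %in% 0:2)
  model <- list(states = as.integer(z))
  exp(kin_log_emissions(D_w, N_w, matrix(h_w, 1), model, params, delta)[1, 1])
}

#' Level weights for the over-dispersion update
#'
#' Groups the joint (Z, H) posterior-by-prior weights by the number of
#' comparisons between identical chromosomes, the quantity that determines
#' which mean/over-dispersion level applies: level 0 collects Z=0; level 1 is
#' Z=1 without ROH; level 2 is Z=2 without ROH or Z=1 with one homozygous
#' individual; level 3 cannot occur; level 4 collects the remaining
#' ROH-inflated combinations.
#'
#' @param gamma L x 3 posterior over IBD states (columns Z = 0, 1, 2).
#' @param h L x 3 ROH state probabilities.
#' @return L x 5 matrix with columns `g0, g1, g2, g3, g4`; rows sum to 1.
#' @export
g_weights <- function(gamma, h) {
  gamma <- matrix(gamma, ncol = 3); h <- matrix(h, ncol = 3)
  cbind(g0 = gamma[, 1],
        g1 = gamma[, 2] * h[, 1],
        g2 = gamma[, 3] * h[, 1] + gamma[, 2] * h[, 2],
        g3 = 0,
        g4 = gamma[, 3] * (h[, 2] + h[, 3]) + gamma[, 2] * h[, 3])
}

#' Maximize one over-dispersion parameter
#'
#' Bounded scalar maximization (on the log scale) of the weighted
#' log-emission cost for one level: `sum_w g_w * log BB(D_w; p, delta, N_w)`.
#'
#' @param D,N Window count vectors.
#' @param g Non-negative weights per window.
#' @param p Level mean.
#' @param bounds `c(lower, upper)` from [delta_constraint_interval()].
#' @param prev Value returned unchanged when all weights are (near) zero.
#' @return The maximizing delta.
#' @export
maximize_delta <- function(D, N, g, p, bounds, prev = NULL) {
  if (sum(g) < 1e-10) {
    if (is.null(prev)) stop("all weights zero and no previous delta")
    return(prev)
  }
  keep <- g > 0 & N > 0
  if (!any(keep)) return(if (is.null(prev)) mean(bounds) else prev)
  D <- D[keep]; N <- N[keep]; g <- g[keep]
  f <- function(x) sum(g * betabinom_logpmf(D, N, p, exp(x)))
  opt <- stats::optimize(f, lower = log(bounds[1]), upper = log(bounds[2]),
                         maximum = TRUE, tol = 1e-3)
  # guard against a boundary beating the interior optimum
  cand <- c(opt$maximum, log(bounds))
  vals <- vapply(cand, f, numeric(1))
  exp(cand[which.max(vals)])
}

init_delta <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- stats::runif(4, 0, 1000)
  names(d) <- names(params$p)
  for (l in names(d)) {
    b <- delta_constraint_interval(params, l)
    d[[l]] <- min(max(d[[l]], b[1]), b[2])
  }
  d
}

#' Fit the pairwise IBD HMM for one relatedness model
#'
#' Expectation-maximization over the per-level over-dispersions: the E-step
#' runs the scaled forward-backward algorithm (restarting with the stationary
#' initial distribution at each chromosome), the M-step maximizes each
#' level's weighted log-emission independently within its variance
#' constraint. Transition matrices are fixed per model. After convergence the
#' Viterbi path is decoded.
#'
#' @param data Window tibble with columns `chrom`, `D`, `N` (output of
#'   [aggregate_pair_windows()], possibly contamination-corrected).
#' @param model A `kin_model` from [model_registry()].
#' @param p0 Background difference rate (see [estimate_p0()]).
#' @param h Optional L x 3 matrix of ROH-state probabilities per window
#'   (default: no ROH, i.e. rows `(1, 0, 0)`).
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood changes
#'   by less than `tol` or after `max_iter` iterations.
#' @param n_starts Number of independent EM runs (random over-dispersion
#'   initializations); the run with the highest log-likelihood is kept.
#'   Restarts guard against the occasional collapsed optimum in which one
#'   level's over-dispersion hits its lower bound and a single broad state
#'   absorbs all windows.
#' @param seed Seed for the random over-dispersion initializations.
#' @return An object of class `kin_fit`: log-likelihood, per-window posterior
#'   `gamma` (L x 3, padded with zeros for states outside the model), fitted
#'   `delta`, Viterbi `path` (IBD state values), iteration count and
#'   convergence flag.
#' @export
kin_fit <- function(data, model, p0, h = NULL, max_iter = 100, tol = 1e-4,
                    n_starts = 2, seed = NULL) {
  stopifnot(all(c("chrom", "D", "N") %in% names(data)))
  L <- nrow(data)
  if (L == 0 || sum(data$N) == 0) stop("no overlapping windows with data")
  if (is.null(h)) h <- matrix(rep(c(1, 0, 0), each = L), L, 3)
  h <- as.matrix(h)
  stopifnot(nrow(h) == L, ncol(h) == 3)
  if (n_starts > 1) {
    fits <- lapply(seq_len(n_starts), function(s) {
      kin_fit(data, model, p0, h = h, max_iter = max_iter, tol = tol,
              n_starts = 1,
              seed = if (is.null(seed)) NULL else seed + (s - 1) * 999983)
    })
    return(fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]])
  }
  params <- build_p_matrix(p0)
  chrom_id <- as.integer(factor(data$chrom, levels = unique(data$chrom)))
  delta <- init_delta(params, seed)
  bounds <- lapply(stats::setNames(nm = names(params$p)),
                   function(l) delta_constraint_interval(params, l))

  loglik <- -Inf; converged <- FALSE; iter <- 0; gamma_full <- NULL
  log_e <- NULL
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    log_e <- kin_log_emissions(data$D, data$N, h, model, params, delta)
    fb <- forward_backward_core(log_e, model$A, model$pi, chrom_id)
    trace <- c(trace, fb$loglik)
    gamma_full <- matrix(0, L, 3)
    gamma_full[, model$states + 1] <- fb$gamma
    if (is.finite(loglik) && abs(fb$loglik - loglik) < tol) {
      loglik <- fb$loglik
      converged <- TRUE
      break
    }
    loglik <- fb$loglik
    g <- g_weights(gamma_full, h)
    for (l in names(delta)) {
      col <- paste0("g", l)
      delta[[l]] <- maximize_delta(data$D, data$N, g[, col], params$p[[l]],
                                   bounds[[l]], prev = delta[[l]])
    }
  }
  path_idx <- viterbi_core(kin_log_emissions(data$D, data$N, h, model,
                                             params, delta),
                           model$A, model$pi, chrom_id)
  structure(list(
    model = model$label, states = model$states, loglik = loglik,
    gamma = gamma_full, delta = delta, path = model$states[path_idx],
    n_iter = iter, converged = converged, p0 = p0,
    loglik_trace = trace,
    data = tibble::as_tibble(data), h = h
  ), class = "kin_fit")
}

#' Viterbi IBD path for fixed over-dispersions
#'
#' Most likely IBD state sequence under a relatedness model, restarting with
#' the stationary initial distribution at each chromosome. Ties are broken
#' toward the lower IBD state.
#'
#' @inheritParams kin_fit
#' @param delta Named over-dispersions for levels `"0","1","2","4"`.
#' @return Integer vector of IBD state values per window.
#' @export
kin_viterbi <- function(data, model, p0, delta, h = NULL) {
  L <- nrow(data)
  if (is.null(h)) h <- matrix(rep(c(1, 0, 0), each = L), L, 3)
  params <- build_p_matrix(p0)
  chrom_id <- as.integer(factor(data$chrom, levels = unique(data$chrom)))
  log_e <- kin_log_emissions(data$D, data$N, as.matrix(h), model, params, delta)
  model$states[viterbi_core(log_e, model$A, model$pi, chrom_id)]
}

#' @export
print.kin_fit <- function(x, ...) {
  cat("<kin_fit>", x$model, "\n")
  cat(" loglik:", format(x$loglik), " iterations:", x$n_iter,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-window summary of a fitted pairwise HMM
#'
#' @param x A `kin_fit`.
#' @param ... Unused.
#' @return Tibble with one row per window: the data, the posterior
#'   probability of each IBD state and the Viterbi state.
#' @method tidy kin_fit
#' @export
tidy.kin_fit <- function(x, ...) {
  out <- x$data
  out$p_ibd0 <- x$gamma[, 1]
  out$p_ibd1 <- x$gamma[, 2]
  out$p_ibd2 <- x$gamma[, 3]
  out$viterbi <- x$path
  out
}

#' One-row summary of a fitted pairwise HMM
#'
#' @param x A `kin_fit`.
#' @param ... Unused.
#' @method glance kin_fit
#' @export
glance.kin_fit <- function(x, ...) {
  tibble::tibble(model = x$model, loglik = x$loglik, n_iter = x$n_iter,
                 converged = x$converged,
                 delta0 = x$delta[["0"]], delta1 = x$delta[["1"]],
                 delta2 = x$delta[["2"]], delta4 = x$delta[["4"]])
}

#' IBD tracts from a fitted model
#'
#' Merges runs of consecutive windows sharing a Viterbi state into tracts.
#'
#' @param fit A `kin_fit` whose `data` carries `chrom`, `start`, `end`.
#' @return BED-like tibble (0-based half-open): `chrom`, `start`, `end`,
#'   `state`, `mean_posterior` (mean posterior of the called state).
#' @export
ibd_tracts <- function(fit) {
  d <- fit$data
  stopifnot(all(c("chrom", "start", "end") %in% names(d)))
  post <- fit$gamma[cbind(seq_len(nrow(d)), fit$path + 1)]
  run <- cumsum(c(TRUE, diff(fit$path) != 0 |
                    d$chrom[-1] != d$chrom[-nrow(d)]))
  tibble::tibble(chrom = d$chrom, start = d$start, end = d$end,
                 state = fit$path, post = post, run = run) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(chrom = dplyr::first(.data$chrom),
                     start = min(.data$start), end = max(.data$end),
                     state = dplyr::first(.data$state),
                     mean_posterior = mean(.data$post), .groups = "drop") |>
    dplyr::select(!"run")
}

#' Write IBD tracts as BED
#'
#' @param fit A `kin_fit`.
#' @param path Output file.
#' @export
write_ibd_bed <- function(fit, path) {
  readr::write_tsv(ibd_tracts(fit), path, col_names = FALSE)
  invisible(path)
}
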