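#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of the row-stochastic matrix `A` for eigenvalue 1,
#' normalized to sum to 1. Used as the initial distribution at the start of
#' each chromosome.
#'
#' @param A Row-stochastic square matrix.
#' @return Numeric vector summing to 1.
#' @export
stationary_distribution <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("A must be square")
  if (any(A < -1e-12) || any(abs(rowSums(A) - 1) > 1e-9)) {
    stop("A is not row-stochastic")
  }
  if (nrow(A) == 1) return(1)
  e <- eigen(t(A))
  k <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, k])
  v <- v / sum(v)
  if (any(v < -1e-8)) stop("no non-negative stationary distribution found")
  pmax(v, 0) / sum(pmax(v, 0))
}

# Scaled forward-backward on log-emissions with independent chains per
# chromosome. log_emiss: L x K matrix; A: K x K; pi: length K; chrom_id:
# integer vector length L marking the chain each window belongs to.
# Returns gamma (L x K), total loglik, and xi_sum (K x K expected transition
# counts, summed within chromosomes) for Baum-Welch updates.
forward_backward_core <- function(log_emiss, A, pi, chrom_id) {
  L <- nrow(log_emiss); K <- ncol(log_emiss)
  stopifnot(length(chrom_id) == L, length(pi) == K)
  gamma <- matrix(0, L, K)
  xi_sum <- matrix(0, K, K)
  loglik <- 0
  # per-window scaling: subtract row max before exponentiation
  mx <- apply(log_emiss, 1, max)
  if (any(!is.finite(mx))) {
    stop("non-finite emission in all states at window ",
         which(!is.finite(mx))[1])
  }
  E <- exp(log_emiss - mx)
  for (ch in unique(chrom_id)) {
    idx <- which(chrom_id == ch)
    n <- length(idx)
    a <- matrix(0, n, K); b <- matrix(0, n, K); cc <- numeric(n)
    a[1, ] <- pi * E[idx[1], ]
    cc[1] <- sum(a[1, ])
    if (cc[1] <= 0) stop("zero forward probability at window ", idx[1])
    a[1, ] <- a[1, ] / cc[1]
    if (n > 1) {
      for (t in 2:n) {
        a[t, ] <- (a[t - 1, ] %*% A) * E[idx[t], ]
        cc[t] <- sum(a[t, ])
        if (cc[t] <= 0) stop("zero forward probability at window ", idx[t])
        a[t, ] <- a[t, ] / cc[t]
      }
    }
    b[n, ] <- 1
    if (n > 1) {
      for (t in (n - 1):1) {
        b[t, ] <- as.numeric(A %*% (b[t + 1, ] * E[idx[t + 1], ])) / cc[t + 1]
      }
      for (t in 1:(n - 1)) {
        x <- outer(a[t, ], b[t + 1, ] * E[idx[t + 1], ]) * A / cc[t + 1]
        xi_sum <- xi_sum + x
      }
    }
    g <- a * b
    g <- g / rowSums(g)
    gamma[idx, ] <- g
    loglik <- loglik + sum(log(cc)) + sum(mx[idx])
  }
  list(gamma = gamma, loglik = loglik, xi_sum = xi_sum)
}

# Viterbi decoding with per-chromosome restarts. Ties broken toward the
# lower state index. Returns integer vector of state indices (1..K).
viterbi_core <- function(log_emiss, A, pi, chrom_id) {
  L <- nrow(log_emiss); K <- ncol(log_emiss)
  logA <- log(A); logpi <- log(pi)
  path <- integer(L)
  for (ch in unique(chrom_id)) {
    idx <- which(chrom_id == ch)
    n <- length(idx)
    v <- matrix(-Inf, n, K)
    bp <- matrix(1L, n, K)
    v[1, ] <- logpi + log_emiss[idx[1], ]
    if (n > 1) {
      for (t in 2:n) {
        for (k in seq_len(K)) {
          cand <- v[t - 1, ] + logA[, k]
          j <- which.max(cand)   # which.max returns lowest index on ties
          bp[t, k] <- j
          v[t, k] <- cand[j] + log_emiss[idx[t], k]
        }
      }
    }
    s <- integer(n)
    s[n] <- which.max(v[n, ])
    if (n > 1) for (t in (n - 1):1) s[t] <- bp[t + 1, s[t + 1]]
    path[idx] <- s
  }
  path
}
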