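# Exhaustive-path oracles for HMM checks, independent of the package's
# forward-backward / Viterbi implementations.

# Joint probability of every state path for one chain; emissions in
# probability space (L x K), A transition matrix, pi initial distribution.
enumerate_paths <- function(emiss, A, pi) {
  L <- nrow(emiss); K <- ncol(emiss)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
  probs <- apply(paths, 1, function(s) {
    p <- pi[s[1]] * emiss[1, s[1]]
    if (L > 1) for (t in 2:L) p <- p * A[s[t - 1], s[t]] * emiss[t, s[t]]
    p
  })
  list(paths = paths, probs = probs)
}

brute_gamma <- function(emiss, A, pi) {
  en <- enumerate_paths(emiss, A, pi)
  L <- nrow(emiss); K <- ncol(emiss)
  g <- matrix(0, L, K)
  for (t in seq_len(L)) {
    for (k in seq_len(K)) {
      g[t, k] <- sum(en$probs[en$paths[, t] == k])
    }
  }
  list(gamma = g / sum(en$probs), loglik = log(sum(en$probs)))
}

brute_viterbi <- function(emiss, A, pi) {
  en <- enumerate_paths(emiss, A, pi)
  en$paths[which.max(en$probs), ]
}

# Site-count tibble helper
counts_tbl <- function(chrom, pos, derived, total) {
  tibble::tibble(chrom = chrom, pos = pos, derived = derived, total = total)
}
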