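test_that("stationary distributions are left eigenvectors", {
  expect_equal(stationary_distribution(matrix(1)), 1)
  A <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  expect_equal(stationary_distribution(A), c(0.5, 0.5))
  As <- analytic_transition("siblings", 1e-8, 1e7)
  expect_equal(unname(stationary_distribution(As)), c(0.25, 0.5, 0.25),
               tolerance = 1e-10)
  expect_error(stationary_distribution(matrix(c(0.5, 0.2, 0.5, 0.2), 2, 2)),
               "stochastic")
})

test_that("window emissions mix ROH states in probability space", {
  pm <- build_p_matrix(0.25)
  delta <- c("0" = 100, "1" = 100, "2" = 100, "4" = 100)
  # degenerate mixture reduces to a single beta-binomial
  e <- window_emission(5, 40, c(1, 0, 0), 0, pm, delta)
  expect_equal(log(e), betabinom_logpmf(5, 40, 0.25, 100), tolerance = 1e-12)
  # Z = 0 row is constant in H
  for (h in list(c(1, 0, 0), c(0, 1, 0), c(0.2, 0.3, 0.5))) {
    expect_equal(window_emission(5, 40, h, 0, pm, delta), e, tolerance = 1e-12)
  }
  # general mixture equals the weighted sum of level emissions
  h <- c(0.5, 0.3, 0.2)
  manual <- 0.5 * exp(betabinom_logpmf(5, 40, pm$p[["1"]], 100)) +
    0.3 * exp(betabinom_logpmf(5, 40, pm$p[["2"]], 100)) +
    0.2 * exp(betabinom_logpmf(5, 40, pm$p[["4"]], 100))
  expect_equal(window_emission(5, 40, h, 1, pm, delta), manual,
               tolerance = 1e-12)
  # no data -> probability 1
  expect_equal(window_emission(0, 0, c(1, 0, 0), 2, pm, delta), 1)
})

test_that("level weights implement the comparison-count grouping", {
  g <- g_weights(c(0.2, 0.5, 0.3), c(1, 0, 0))
  expect_equal(unname(g[1, ]), c(0.2, 0.5, 0.3, 0, 0))
  g2 <- g_weights(c(0.2, 0.5, 0.3), c(0, 0, 1))
  expect_equal(unname(g2[1, ]), c(0.2, 0, 0, 0, 0.8))
  g3 <- g_weights(c(1, 0, 0), c(0.3, 0.3, 0.4))
  expect_equal(unname(g3[1, ]), c(1, 0, 0, 0, 0))
  # rows always sum to 1 for normalized inputs
  set.seed(3)
  gam <- t(apply(matrix(runif(30), 10), 1, function(x) x / sum(x)))
  h <- t(apply(matrix(runif(30), 10), 1, function(x) x / sum(x)))
  expect_equal(rowSums(g_weights(gam, h)), rep(1, 10), tolerance = 1e-12)
})

test_that("forward-backward and Viterbi match exhaustive path enumeration", {
  set.seed(42)
  pm <- build_p_matrix(0.25)
  for (rep in 1:5) {
    L <- sample(3:8, 1)
    K <- sample(2:3, 1)
    emiss <- matrix(runif(L * K, 0.05, 1), L, K)
    A <- matrix(runif(K * K, 0.1, 1), K, K)
    A <- A / rowSums(A)
    pi <- stationary_distribution(A)
    fb <- kinfer:::forward_backward_core(log(emiss), A, pi, rep(1L, L))
    or <- brute_gamma(emiss, A, pi)
    expect_equal(fb$gamma, or$gamma, tolerance = 1e-9)
    expect_equal(fb$loglik, or$loglik, tolerance = 1e-9)
    vit <- kinfer:::viterbi_core(log(emiss), A, pi, rep(1L, L))
    expect_equal(vit, unname(brute_viterbi(emiss, A, pi)))
  }
  # two chromosomes: chains are independent, logliks add
  L <- 6
  emiss <- matrix(runif(L * 2, 0.05, 1), L, 2)
  A <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2, byrow = TRUE)
  pi <- stationary_distribution(A)
  cid <- c(1L, 1L, 1L, 2L, 2L, 2L)
  fb <- kinfer:::forward_backward_core(log(emiss), A, pi, cid)
  o1 <- brute_gamma(emiss[1:3, ], A, pi)
  o2 <- brute_gamma(emiss[4:6, ], A, pi)
  expect_equal(fb$loglik, o1$loglik + o2$loglik, tolerance = 1e-9)
  expect_equal(fb$gamma, rbind(o1$gamma, o2$gamma), tolerance = 1e-9)
})

test_that("Viterbi ties break toward the lower state and ignore scaling", {
  A <- matrix(0.5, 2, 2)
  pi <- c(0.5, 0.5)
  e <- matrix(1, 4, 2)   # fully degenerate
  expect_equal(kinfer:::viterbi_core(log(e), A, pi, rep(1L, 4)),
               rep(1L, 4))
  # scaling one window's emissions by a constant leaves the path unchanged
  set.seed(5)
  e2 <- matrix(runif(8, 0.1, 1), 4, 2)
  p1 <- kinfer:::viterbi_core(log(e2), A, pi, rep(1L, 4))
  e3 <- e2; e3[2, ] <- e3[2, ] * 17
  expect_equal(kinfer:::viterbi_core(log(e3), A, pi, rep(1L, 4)), p1)
})

test_that("over-dispersion maximization recovers a known delta", {
  set.seed(99)
  L <- 500; N <- 1000; p <- 0.2; delta_true <- 50
  rate <- rbeta(L, p * delta_true, (1 - p) * delta_true)
  D <- rbinom(L, N, rate)
  b <- c(1e-6, 1e6)
  dh <- maximize_delta(D, rep(N, L), rep(1, L), p, b)
  expect_gt(dh, 35); expect_lt(dh, 70)
  # grid-search oracle: no grid point beats the optimizer meaningfully
  cost <- function(d) sum(betabinom_logpmf(D, N, p, d))
  grid <- exp(seq(log(1), log(1e4), length.out = 200))
  expect_gte(cost(dh), max(vapply(grid, cost, 1)) - 1e-3)
  # single window: optimality certificate against both bounds
  d1 <- maximize_delta(30, 100, 1, 0.2, c(10, 1e5))
  expect_gte(cost2 <- betabinom_logpmf(30, 100, 0.2, d1),
             betabinom_logpmf(30, 100, 0.2, 10) - 1e-9)
  expect_gte(cost2, betabinom_logpmf(30, 100, 0.2, 1e5) - 1e-9)
  # data exactly at the mean pushes delta to the binomial limit (upper bound)
  dmean <- maximize_delta(20, 100, 1, 0.2, c(10, 1e5))
  expect_equal(dmean, 1e5, tolerance = 1e-2)
  # zero weights return the previous value
  expect_equal(maximize_delta(D, rep(N, L), rep(0, L), p, b, prev = 123), 123)
})

test_that("EM fits are monotone, deterministic and correct in easy cases", {
  set.seed(1)
  reg <- shipped_registry()
  pm <- build_p_matrix(0.25)
  # simulate window data from the siblings model (no ROH)
  L <- 60; N <- 800
  A <- reg[["siblings"]]$A
  z <- integer(L); z[1] <- sample(0:2, 1, prob = reg[["siblings"]]$pi)
  for (w in 2:L) z[w] <- sample(0:2, 1, prob = A[z[w - 1] + 1, ])
  p_lev <- pm$p[c("0", "1", "2")][z + 1]
  D <- rbinom(L, N, p_lev)
  dat <- tibble::tibble(chrom = rep(c("chr1", "chr2"), each = L / 2),
                        D = D, N = N)
  f <- kin_fit(dat, reg[["siblings"]], 0.25, seed = 7)
  # monotone log-likelihood (exact EM when the ROH mixture is degenerate)
  expect_true(all(diff(f$loglik_trace) > -1e-6))
  expect_true(f$converged)
  # posterior rows sum to 1; path states within the model
  expect_equal(rowSums(f$gamma), rep(1, L), tolerance = 1e-9)
  expect_true(all(f$path %in% 0:2))
  # viterbi recovers most of the true path in this high-information setting
  expect_gt(mean(f$path == z), 0.9)
  # determinism under the same seed
  f2 <- kin_fit(dat, reg[["siblings"]], 0.25, seed = 7)
  expect_identical(f$delta, f2$delta)
  expect_identical(f$loglik, f2$loglik)
  expect_identical(f$path, f2$path)

  # single-state model: loglik equals the direct emission sum at fitted delta
  fu <- kin_fit(dat, reg[["unrelated"]], 0.25, seed = 3)
  direct <- sum(betabinom_logpmf(dat$D, dat$N, 0.25, fu$delta[["0"]]))
  expect_equal(fu$loglik, direct, tolerance = 1e-8)
  expect_equal(unique(fu$path), 0L)
  expect_equal(fu$gamma[, 1], rep(1, L))

  # windows with N = 0 stay in the chain and are uninformative
  dat0 <- dat; dat0$N[5] <- 0; dat0$D[5] <- 0
  f0 <- kin_fit(dat0, reg[["siblings"]], 0.25, seed = 7)
  expect_true(all(is.finite(f0$gamma[5, ])))

  expect_error(kin_fit(dat[0, ], reg[["siblings"]], 0.25), "windows")
})

test_that("IBD tracts merge consecutive windows of one state", {
  reg <- shipped_registry()
  dat <- tibble::tibble(chrom = "chr1", start = 0:3 * 1e7,
                        end = 1:4 * 1e7,
                        D = c(200, 200, 150, 150), N = 1000)
  f <- kin_fit(dat, reg[["grandparent-grandchild"]], 0.2, seed = 1)
  tr <- ibd_tracts(f)
  expect_true(all(tr$end > tr$start))
  expect_equal(sum(tr$end - tr$start), 4e7)
  td <- tidy(f)
  expect_equal(nrow(td), 4)
  expect_true(all(c("p_ibd0", "p_ibd1", "viterbi") %in% names(td)))
  gl <- glance(f)
  expect_equal(gl$model, "grandparent-grandchild")
})
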