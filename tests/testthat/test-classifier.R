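fake_fit <- function(label, loglik, gamma = NULL) {
  if (is.null(gamma)) gamma <- matrix(c(1, 0, 0), 1, 3, byrow = TRUE)
  structure(list(model = label, loglik = loglik, gamma = gamma,
                 states = 0:2, path = 0L, n_iter = 1, converged = TRUE,
                 delta = c("0" = 1, "1" = 1, "2" = 1, "4" = 1)),
            class = "kin_fit")
}

fake_fits <- function(ll, gamma_best = NULL) {
  out <- lapply(names(ll), function(nm) {
    fake_fit(nm, ll[[nm]],
             if (!is.null(gamma_best) && ll[[nm]] == max(unlist(ll))) {
               gamma_best
             } else NULL)
  })
  names(out) <- names(ll)
  structure(out, class = "kin_fit_list")
}

test_that("classification picks the maximum-likelihood case with grouping", {
  r <- classify_pair(fake_fits(list("siblings" = -100, "parent-child" = -105)))
  expect_equal(r$best_case, "siblings")
  expect_equal(r$delta_LL, 5)
  expect_true(r$confident)

  # near-tie within second degree does not erode confidence
  r2 <- classify_pair(fake_fits(list("half-siblings" = -50,
                                     "avuncular" = -50.3,
                                     "unrelated" = -60)))
  expect_equal(r2$best_group, "second degree")
  expect_equal(r2$second_case, "avuncular")  # fine runner-up reported
  expect_equal(r2$second_group, "unrelated") # but confidence is cross-group
  expect_equal(r2$delta_LL, 10)
  expect_equal(r2$delta_LL_fine, 0.3, tolerance = 1e-12)
  expect_true(r2$confident)

  # posterior-mean IBD fractions and relatedness coefficient
  gpc <- matrix(c(0, 1, 0), 4, 3, byrow = TRUE)
  r3 <- classify_pair(fake_fits(list("parent-child" = -10,
                                     "unrelated" = -50), gamma_best = gpc))
  expect_equal(c(r3$k0, r3$k1, r3$k2), c(0, 1, 0))
  expect_equal(r3$r, 0.5)

  # exact ties resolve toward the less related category and are flagged
  r4 <- classify_pair(fake_fits(list("siblings" = -10, "unrelated" = -10)))
  expect_equal(r4$best_group, "unrelated")
  expect_true(r4$tie)

  # below-cutoff difference is not confident
  r5 <- classify_pair(fake_fits(list("siblings" = -10, "unrelated" = -10.5)))
  expect_false(r5$confident)

  # adding a strictly worse model never changes the call
  r6 <- classify_pair(fake_fits(list("siblings" = -100, "parent-child" = -105,
                                     "fifth-degree" = -500)))
  expect_equal(r6$best_case, r$best_case)
  expect_equal(r6$best_group, r$best_group)

  expect_error(classify_pair(fake_fits(list("siblings" = -1))), "two")
})

test_that("classification evaluation computes TP/FP under both groupings", {
  res <- tibble::tibble(
    relation = c("siblings", "parent-child", "unrelated", "third-degree",
                 "fourth-degree"),
    best_group = c("siblings", "parent-child", "unrelated", "third degree",
                   "unrelated"),
    confident = TRUE
  )
  ev <- evaluate_classification(res)
  std <- ev[ev$grouping == "standard", ]
  expect_true(all(std$tp == 1))
  expect_true(all(std$fp == 0, na.rm = TRUE))
  # merged grouping folds third degree into unrelated
  mg <- ev[ev$grouping == "merge_third", ]
  expect_equal(mg$tp[mg$category == "unrelated"], 1)

  # all pairs called unrelated: only the unrelated category scores
  res2 <- res
  res2$best_group <- "unrelated"
  ev2 <- evaluate_classification(res2)
  std2 <- ev2[ev2$grouping == "standard", ]
  expect_equal(std2$tp[std2$category == "unrelated"], 1)
  expect_equal(std2$tp[std2$category == "siblings"], 0)

  # unconfident calls never count as hits
  res3 <- res
  res3$confident <- FALSE
  ev3 <- evaluate_classification(res3)
  expect_true(all(ev3$tp == 0))
})

test_that("window-center IBD accuracy behaves at the extremes", {
  expect_equal(evaluate_ibd(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(evaluate_ibd(c(0, 0, 0), c(0, 1, 2)), 1 / 3)
  set.seed(2)
  pred <- sample(0:2, 3000, replace = TRUE)
  truth <- sample(0:2, 3000, replace = TRUE)
  expect_equal(evaluate_ibd(pred, truth), 1 / 3, tolerance = 0.05)
  expect_error(evaluate_ibd(0:1, 0:2))
})
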