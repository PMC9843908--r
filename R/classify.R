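# --- Model comparison and relatedness classification -----------------------

# Reporting order used for tie-breaks: lower coefficient of relatedness first.
group_order <- c("unrelated", "third degree", "second degree",
                 "parent-child", "siblings", "identical")

#' Fit every relatedness model for one pair
#'
#' @param data Pair window tibble (`chrom`, `D`, `N`), contamination-corrected
#'   if applicable.
#' @param registry Model list from [model_registry()].
#' @param p0 Background difference rate.
#' @param h Optional L x 3 ROH-state probabilities.
#' @param seed Optional seed; each model gets a derived seed so the whole
#'   table is reproducible.
#' @param ... Passed to [kin_fit()] (`max_iter`, `tol`).
#' @return Named list of `kin_fit` objects (class `kin_fit_list`). Models
#'   whose fit fails are dropped with a warning.
#' @export
fit_models <- function(data, registry = model_registry(), p0, h = NULL,
                       seed = NULL, ...) {
  if (sum(data$N) == 0) stop("pair has no overlapping windows")
  fits <- list()
  for (i in seq_along(registry)) {
    m <- registry[[i]]
    s <- if (is.null(seed)) NULL else seed + i
    f <- tryCatch(kin_fit(data, m, p0, h = h, seed = s, ...),
                  error = function(e) {
                    warning("model ", m$label, " failed: ",
                            conditionMessage(e))
                    NULL
                  })
    if (!is.null(f)) fits[[m$label]] <- f
  }
  structure(fits, class = "kin_fit_list")
}

#' @method glance kin_fit_list
#' @export
glance.kin_fit_list <- function(x, ...) {
  dplyr::bind_rows(lapply(unclass(x), glance))
}

#' Classify a pair from its fitted models
#'
#' Picks the maximum-likelihood model, maps fine cases to the reported
#' categories (4th/5th degree join unrelated; half-siblings, avuncular and
#' grandparent-grandchild join second degree), and computes the confidence
#' statistic `delta_LL` as the log-likelihood gap between the best model and
#' the best model of a *different* reported category, so near-ties within a
#' category (e.g. half-siblings vs avuncular) do not erode confidence. The
#' within-registry runner-up gap is reported alongside. Exact likelihood
#' ties resolve toward the less related category and are flagged.
#'
#' @param fits A `kin_fit_list` from [fit_models()].
#' @param cutoff Confidence cutoff in log-likelihood units (default 1).
#' @return One-row tibble: best/second case and group, `delta_LL` (cross
#'   group), `delta_LL_fine` (any model), `confident`, posterior-mean IBD
#'   fractions `k0, k1, k2`, relatedness coefficient `r`, `tie` flag.
#' @export
classify_pair <- function(fits, cutoff = 1) {
  if (length(fits) < 2) stop("need at least two fitted models to classify")
  ll <- vapply(unclass(fits), `[[`, numeric(1), "loglik")
  labels <- names(ll)
  groups <- relatedness_groups[labels]
  ord <- order(-ll, match(groups, group_order))
  tie <- sum(abs(ll - max(ll)) < 1e-12) > 1
  best <- ord[1]
  other <- ord[groups[ord] != groups[best]]
  if (length(other) == 0) stop("all fitted models are in one category")
  second_group_idx <- other[1]
  second_fine_idx <- ord[2]
  delta_LL <- ll[best] - ll[second_group_idx]
  bf <- fits[[labels[best]]]
  k_hat <- colMeans(bf$gamma)
  tibble::tibble(
    best_case = labels[best],
    best_group = unname(groups[best]),
    second_case = labels[second_fine_idx],
    second_group = unname(groups[second_group_idx]),
    delta_LL = unname(delta_LL),
    delta_LL_fine = unname(ll[best] - ll[second_fine_idx]),
    confident = unname(delta_LL > cutoff),
    tie = tie,
    k0 = k_hat[1], k1 = k_hat[2], k2 = k_hat[3],
    r = k_hat[2] / 2 + k_hat[3],
    loglik_best = unname(ll[best])
  )
}

truth_group <- function(relation, merge_third = FALSE) {
  g <- unname(relatedness_groups[relation])
  if (merge_third) g[g == "third degree"] <- "unrelated"
  g
}

#' Classification accuracy against simulation truth
#'
#' Computes per-category true- and false-positive rates of the confident
#' calls, under both the standard grouping (third degree separate) and the
#' coarser grouping in which 3rd/4th/5th-degree pairs count as unrelated
#' (comparable to pseudo-haploid distance classifiers that stop at second
#' degree).
#'
#' @param results Tibble with columns `relation` (true fine label),
#'   `best_group` and `confident` — e.g. classification rows joined to the
#'   simulator's relations table.
#' @return Tibble with `grouping`, `category`, `n_true`, `tp`, `fp`.
#' @export
evaluate_classification <- function(results) {
  stopifnot(all(c("relation", "best_group", "confident") %in% names(results)))
  out <- list()
  for (grouping in c("standard", "merge_third")) {
    truth <- truth_group(results$relation, grouping == "merge_third")
    called <- results$best_group
    if (grouping == "merge_third") called[called == "third degree"] <- "unrelated"
    hit <- results$confident & called == truth
    for (cat in unique(truth)) {
      pos <- truth == cat
      out[[length(out) + 1]] <- tibble::tibble(
        grouping = grouping, category = cat, n_true = sum(pos),
        tp = mean(hit[pos]),
        fp = if (any(!pos)) mean(results$confident[!pos] &
                                   called[!pos] == cat) else NA_real_
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Window-center IBD accuracy
#'
#' Fraction of windows whose predicted IBD state equals the true state at
#' the window's central position.
#'
#' @param path Predicted per-window states (e.g. `kin_fit$path`).
#' @param truth_center True states at window centers
#'   (`true_window_states()$Z_center`).
#' @return Proportion in `[0, 1]`.
#' @export
evaluate_ibd <- function(path, truth_center) {
  stopifnot(length(path) == length(truth_center))
  mean(path == truth_center)
}
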