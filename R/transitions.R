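#' Analytic IBD transition matrix
#'
#' For two relationships the window-to-window IBD transition matrix has a
#' closed form as the matrix exponential `expm(Q b)` of a per-bp rate matrix
#' scaled by the window size. For grandparent-grandchild (states 0, 1):
#' `Q = [-r r; r -r]`. For siblings (states 0, 1, 2):
#' `Q = [-4r 4r 0; 2r -4r 2r; 0 4r -4r]`, whose stationary distribution is
#' (0.25, 0.5, 0.25) for any window size.
#'
#' @param case `"grandparent-grandchild"` or `"siblings"`.
#' @param r Recombination rate per bp per generation.
#' @param b Window size in bp.
#' @return Row-stochastic transition matrix with state values as dimnames.
#' @export
analytic_transition <- function(case, r = 1e-8, b = 1e7) {
  stopifnot(r > 0, b >= 0)
  if (case == "grandparent-grandchild") {
    Q <- matrix(c(-r, r, r, -r), 2, 2, byrow = TRUE)
    states <- 0:1
  } else if (case == "siblings") {
    Q <- matrix(c(-4 * r, 4 * r, 0,
                  2 * r, -4 * r, 2 * r,
                  0, 4 * r, -4 * r), 3, 3, byrow = TRUE)
    states <- 0:2
  } else {
    stop("no analytic transition matrix for case: ", case)
  }
  A <- as.matrix(Matrix::expm(Q * b))
  A <- A / rowSums(A)
  dimnames(A) <- list(states, states)
  A
}

#' Empirical transition matrix from simulated IBD paths
#'
#' Counts transitions between consecutive window states along each path and
#' row-normalizes. Paths must be supplied per chromosome so that no
#' transition is counted across a chromosome boundary. Rows with no observed
#' transitions fall back to a self-transition of 1.
#'
#' @param paths List of integer vectors; each vector is the true IBD state at
#'   the centers of consecutive windows of one chromosome of one simulated
#'   pair.
#' @param states Vector of admissible state values (default: the sorted
#'   unique states observed).
#' @return Row-stochastic matrix with `states` as dimnames.
#' @export
empirical_transition <- function(paths, states = NULL) {
  if (length(paths) == 0) stop("no paths supplied")
  allv <- unlist(paths)
  if (is.null(states)) states <- sort(unique(allv))
  if (!all(allv %in% states)) stop("path contains states outside `states`")
  K <- length(states)
  counts <- matrix(0, K, K, dimnames = list(states, states))
  for (p in paths) {
    if (length(p) < 2) next
    from <- match(p[-length(p)], states)
    to <- match(p[-1], states)
    for (i in seq_along(from)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  }
  rs <- rowSums(counts)
  A <- counts
  for (k in seq_len(K)) {
    if (rs[k] == 0) {
      A[k, ] <- 0; A[k, k] <- 1
    } else {
      A[k, ] <- counts[k, ] / rs[k]
    }
  }
  A
}

#' @export
print.kin_model <- function(x, ...) {
  cat("<kin_model>", x$label, sprintf("(group: %s)", x$group), "\n")
  cat(" states:", paste(x$states, collapse = " "),
      " expected k:", paste(x$expected_k, collapse = "/"), "\n")
  invisible(x)
}

new_kin_model <- function(label, group, states, A, expected_k) {
  A <- as.matrix(A)
  pi <- stationary_distribution(A)
  structure(list(label = label, group = group, states = as.integer(states),
                 A = A, pi = pi, expected_k = expected_k),
            class = "kin_model")
}

relatedness_groups <- c(
  "unrelated" = "unrelated",
  "fifth-degree" = "unrelated",
  "fourth-degree" = "unrelated",
  "third-degree" = "third degree",
  "grandparent-grandchild" = "second degree",
  "avuncular" = "second degree",
  "half-siblings" = "second degree",
  "parent-child" = "parent-child",
  "siblings" = "siblings",
  "identical" = "identical"
)

empirical_cases <- c("fifth-degree", "fourth-degree", "third-degree",
                     "avuncular", "half-siblings")

expected_k_table <- list(
  "unrelated" = c(1, 0, 0),
  "fifth-degree" = c(0.9375, 0.0625, 0),
  "fourth-degree" = c(0.875, 0.125, 0),
  "third-degree" = c(0.75, 0.25, 0),
  "grandparent-grandchild" = c(0.5, 0.5, 0),
  "avuncular" = c(0.5, 0.5, 0),
  "half-siblings" = c(0.5, 0.5, 0),
  "parent-child" = c(0, 1, 0),
  "siblings" = c(0.25, 0.5, 0.25),
  "identical" = c(0, 0, 1)
)

default_matrix_store <- function() {
  system.file("extdata", "transition_matrices", package = "kinfer")
}

read_transition_file <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  A <- do.call(rbind, lapply(strsplit(body, "\\s+"), as.numeric))
  states <- as.integer(strsplit(meta$states, ",")[[1]])
  dimnames(A) <- list(states, states)
  list(A = A, states = states, r = as.numeric(meta$r), b = as.numeric(meta$b),
       source = meta$source, seed = meta$seed)
}

write_transition_file <- function(A, states, case, r, b, source, seed, path) {
  hdr <- c(paste0("# case = ", case),
           paste0("# r = ", format(r, digits = 15)),
           paste0("# b = ", format(b, digits = 15)),
           paste0("# source = ", source),
           paste0("# seed = ", seed),
           paste0("# states = ", paste(states, collapse = ",")))
  body <- apply(A, 1, function(row) paste(format(row, digits = 12), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Registry of relatedness models
#'
#' Builds the ten pairwise relatedness models: single-state models for
#' unrelated (Z = 0), parent-child (Z = 1) and identical (Z = 2); analytic
#' transition matrices for grandparent-grandchild and siblings; and
#' empirically estimated matrices (from simulated pedigrees) for avuncular,
#' half-siblings and 3rd/4th/5th-degree relatives. Initial probabilities are
#' the stationary distribution of each matrix.
#'
#' @param r Recombination rate per bp per generation.
#' @param b Window size in bp.
#' @param store Directory of shipped transition-matrix files (plain text).
#' @param regenerate If `TRUE`, re-estimate the empirical matrices by
#'   simulation instead of reading the store (required when `r` or `b` differ
#'   from the shipped values).
#' @param n_sims Number of simulated pairs per case when regenerating.
#' @param seed Seed for regeneration.
#' @param n_chromosomes,chrom_length Genome used when regenerating.
#' @return Named list of `kin_model` objects.
#' @export
model_registry <- function(r = 1e-8, b = 1e7, store = default_matrix_store(),
                           regenerate = FALSE, n_sims = 1000, seed = 1907,
                           n_chromosomes = 22, chrom_length = 96e6) {
  models <- list(
    "unrelated" = new_kin_model("unrelated", "unrelated", 0L, matrix(1),
                                expected_k_table[["unrelated"]]),
    "parent-child" = new_kin_model("parent-child", "parent-child", 1L,
                                   matrix(1), expected_k_table[["parent-child"]]),
    "identical" = new_kin_model("identical", "identical", 2L, matrix(1),
                                expected_k_table[["identical"]]),
    "grandparent-grandchild" = new_kin_model(
      "grandparent-grandchild", "second degree", 0:1,
      analytic_transition("grandparent-grandchild", r, b),
      expected_k_table[["grandparent-grandchild"]]),
    "siblings" = new_kin_model("siblings", "siblings", 0:2,
                               analytic_transition("siblings", r, b),
                               expected_k_table[["siblings"]])
  )
  for (case in empirical_cases) {
    path <- file.path(store, paste0(gsub("-", "_", case), ".txt"))
    use_file <- !regenerate && file.exists(path)
    if (use_file) {
      tf <- read_transition_file(path)
      if (!isTRUE(all.equal(tf$r, r)) || !isTRUE(all.equal(tf$b, b))) {
        stop("stored matrix for ", case, " was built for r = ", tf$r,
             ", b = ", tf$b, "; call model_registry(regenerate = TRUE) ",
             "to re-estimate for other settings")
      }
      A <- tf$A; states <- tf$states
    } else if (regenerate || !file.exists(path)) {
      if (!regenerate) {
        stop("missing empirical transition matrix for ", case,
             " and regeneration disabled")
      }
      paths <- sim_relation_paths(case, n_sims = n_sims, r = r, b = b,
                                  n_chromosomes = n_chromosomes,
                                  chrom_length = chrom_length,
                                  seed = seed + match(case, empirical_cases))
      states <- if (case %in% c("fifth-degree", "fourth-degree",
                                "third-degree", "avuncular",
                                "half-siblings")) 0:1 else 0:2
      A <- empirical_transition(paths, states = states)
    }
    models[[case]] <- new_kin_model(case, relatedness_groups[[case]],
                                    states, A, expected_k_table[[case]])
  }
  models[names(relatedness_groups)]
}
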