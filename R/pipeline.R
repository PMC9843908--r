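# --- End-to-end pipeline ----------------------------------------------------

#' Validate a directory (or list) of site-count tables
#'
#' Schema and consistency checks: required columns, derived <= total,
#' non-negative counts, sorted positions, shared site universe, and a
#' warning for individuals with very few covered sites.
#'
#' @param input Directory containing `*.counts.tsv` files, or a named list
#'   of site-count tibbles.
#' @return Tibble of issues (`individual`, `severity`, `message`); empty when
#'   everything checks out.
#' @export
validate_inputs <- function(input) {
  counts <- load_counts(input, validate = FALSE)
  issues <- list()
  note <- function(ind, sev, msg) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      individual = ind, severity = sev, message = msg)
  }
  for (nm in names(counts)) {
    x <- counts[[nm]]
    need <- c("chrom", "pos", "derived", "total")
    if (!all(need %in% names(x))) {
      note(nm, "error", paste("missing columns:",
                              paste(setdiff(need, names(x)), collapse = ", ")))
      next
    }
    bad <- which(x$derived > x$total)
    if (length(bad)) {
      note(nm, "error", paste0("derived > total at line ", bad[1] + 1))
    }
    if (any(x$derived < 0 | x$total < 0)) note(nm, "error", "negative counts")
    unsorted <- x |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(ok = !is.unsorted(.data$pos), .groups = "drop")
    if (any(!unsorted$ok)) {
      note(nm, "warning", "positions unsorted within chromosome; will be sorted")
    }
    if (anyDuplicated(paste(x$chrom, x$pos))) {
      note(nm, "error", "duplicated (chrom, pos)")
    }
    if (nrow(x) < 1000) {
      note(nm, "warning", paste0("only ", nrow(x), " covered sites"))
    }
  }
  if (length(counts) >= 2) {
    sets <- lapply(counts, function(x) paste(x$chrom, x$pos))
    common <- Reduce(intersect, sets)
    if (length(common) < 1000) {
      note("(cohort)", "warning",
           paste0("only ", length(common), " sites shared by all individuals"))
    }
  }
  if (length(issues) == 0) {
    return(tibble::tibble(individual = character(0), severity = character(0),
                          message = character(0)))
  }
  dplyr::bind_rows(issues)
}

load_counts <- function(input, validate = TRUE) {
  if (is.character(input) && length(input) == 1 && dir.exists(input)) {
    files <- list.files(input, pattern = "\\.counts\\.tsv(\\.gz)?$",
                        full.names = TRUE)
    if (length(files) == 0) stop("no *.counts.tsv files in ", input)
    counts <- lapply(files, function(f) {
      tryCatch(read_site_counts(f),
               error = function(e) stop("unreadable table ", f, ": ",
                                        conditionMessage(e)))
    })
    names(counts) <- sub("\\.counts\\.tsv(\\.gz)?$", "", basename(files))
  } else if (is.list(input) && !is.data.frame(input)) {
    counts <- input
    if (is.null(names(counts))) stop("count list must be named by individual")
  } else {
    stop("`input` must be a directory or a named list of count tables")
  }
  if (validate) for (nm in names(counts)) check_counts(counts[[nm]], nm)
  counts
}

#' Run the full relatedness pipeline
#'
#' Orchestrates the whole analysis on a cohort of site-count tables:
#' windowed pairwise differences, optional contamination correction,
#' background-rate estimation, per-individual ROH detection (for individuals
#' with sufficient coverage), pairwise model fitting across all ten
#' relatedness models, and classification.
#'
#' @param input Directory of `*.counts.tsv` files or a named list of
#'   site-count tibbles.
#' @param window_size Window size in bp.
#' @param p0 Optional user-supplied background difference rate (estimated
#'   from the data when `NULL`).
#' @param contamination Optional named vector of per-individual contamination
#'   rates; requires `phi`.
#' @param phi Target-contaminant divergence (used with `contamination`).
#' @param roh_mode `"auto"` (fit the ROH HMM for individuals with mean depth
#'   at least `min_roh_coverage`), `"off"` (assume no ROH), or `"file"`
#'   (use `h_tables`).
#' @param h_tables Named list of per-individual window homozygosity
#'   probabilities (numeric vectors on the pipeline grid), for
#'   `roh_mode = "file"`.
#' @param cutoff Confidence cutoff in log-likelihood units.
#' @param seed Seed controlling all stochastic initializations.
#' @param min_roh_coverage Mean-depth threshold for running the ROH HMM.
#' @param registry Model registry (defaults to [model_registry()] at
#'   `window_size`).
#' @param pairs Optional two-column data frame (`id_i`, `id_j`) restricting
#'   which pairs are classified; p0 is still estimated from all pairs.
#' @param n_target_sites Size of the target-site universe used for mean
#'   depth (default: number of distinct sites observed across the cohort).
#' @param output_dir Optional directory; when given, writes
#'   `results.tsv`, per-pair IBD BED files, per-individual ROH bedGraphs and
#'   a run log.
#' @param quiet Suppress progress messages.
#' @return A list of class `kin_run`: `results` (one row per pair),
#'   `p0`, `roh_fits`, `fits` (per pair `kin_fit_list`), `grid`.
#' @export
run_pipeline <- function(input, window_size = 1e7, p0 = NULL,
                         contamination = NULL, phi = NULL,
                         roh_mode = c("auto", "off", "file"),
                         h_tables = NULL, cutoff = 1, seed = NULL,
                         min_roh_coverage = 0.1, registry = NULL,
                         pairs = NULL, n_target_sites = NULL,
                         output_dir = NULL, quiet = TRUE) {
  roh_mode <- match.arg(roh_mode)
  if (!is.null(seed)) set.seed(seed)
  say <- function(...) if (!quiet) message(...)
  counts <- load_counts(input)
  ids <- names(counts)
  if (length(ids) < 2) stop("need at least two individuals")
  if (!is.null(contamination) && is.null(phi)) {
    stop("`phi` is required when contamination rates are given")
  }
  crate <- function(id) {
    if (is.null(contamination)) 0 else {
      v <- contamination[id]
      if (is.na(v)) 0 else unname(v)
    }
  }
  grid <- grid_from_counts(counts, window_size)
  if (is.null(registry)) registry <- model_registry(b = window_size)
  if (is.null(n_target_sites)) {
    n_target_sites <- dplyr::bind_rows(
      lapply(counts, function(x) x[, c("chrom", "pos")])) |>
      dplyr::distinct() |> nrow()
  }

  say("aggregating pairwise windows")
  all_pairs <- t(utils::combn(ids, 2))
  pair_windows <- vector("list", nrow(all_pairs))
  for (k in seq_len(nrow(all_pairs))) {
    i <- all_pairs[k, 1]; j <- all_pairs[k, 2]
    pw <- aggregate_pair_windows(counts[[i]], counts[[j]], grid)
    if (crate(i) + crate(j) > 0) {
      pw <- correct_pair_counts(pw, crate(i), crate(j), phi)
    }
    pair_windows[[k]] <- pw
  }
  names(pair_windows) <- paste(all_pairs[, 1], all_pairs[, 2], sep = "\r")

  pooled <- dplyr::bind_rows(pair_windows, .id = "pair")
  p0 <- estimate_p0(pooled, override = p0)
  say("p0 = ", signif(p0, 4))

  roh_fits <- list()
  h_ind <- list()
  if (roh_mode == "auto") {
    for (id in ids) {
      depth <- sum(counts[[id]]$total) / n_target_sites
      if (depth < min_roh_coverage) next
      ri <- within_individual_diffs(counts[[id]], grid)
      ci <- crate(id)
      if (ci > 0) ri <- correct_roh_counts(ri, ci, phi)
      if (sum(ri$M) == 0) next
      roh_fits[[id]] <- roh_fit(ri, p0,
                                seed = if (is.null(seed)) NULL
                                       else seed + match(id, ids))
      h_ind[[id]] <- roh_fits[[id]]$q
    }
  } else if (roh_mode == "file") {
    if (is.null(h_tables)) stop("roh_mode = 'file' needs `h_tables`")
    h_ind <- h_tables
  }
  qof <- function(id) if (id %in% names(h_ind)) h_ind[[id]] else rep(0, nrow(grid))

  if (is.null(pairs)) {
    pairs <- data.frame(id_i = all_pairs[, 1], id_j = all_pairs[, 2])
  }
  say("fitting ", nrow(pairs), " pairs x ", length(registry), " models")
  results <- list(); fits <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$id_i[k]; j <- pairs$id_j[k]
    key <- if (paste(i, j, sep = "\r") %in% names(pair_windows)) {
      paste(i, j, sep = "\r")
    } else paste(j, i, sep = "\r")
    pw <- pair_windows[[key]]
    h <- pair_roh_prior(qof(i), qof(j))
    fl <- fit_models(pw, registry, p0, h = h,
                     seed = if (is.null(seed)) NULL else seed + 1000 * k)
    cl <- classify_pair(fl, cutoff)
    cl <- tibble::add_column(cl, id_i = i, id_j = j,
                             n_overlap_sites = sum(pw$N), .before = 1)
    results[[k]] <- cl
    fits[[paste(i, j, sep = "-")]] <- fl
  }
  results <- dplyr::bind_rows(results)

  run <- structure(list(results = results, p0 = p0, roh_fits = roh_fits,
                        fits = fits, grid = grid, cutoff = cutoff,
                        seed = seed), class = "kin_run")
  if (!is.null(output_dir)) write_run(run, output_dir)
  run
}

#' @export
print.kin_run <- function(x, ...) {
  cat("<kin_run> p0 =", signif(x$p0, 4), "\n")
  print(x$results[, c("id_i", "id_j", "best_group", "best_case",
                      "delta_LL", "confident")])
  invisible(x)
}

write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(run$results, file.path(dir, "results.tsv"))
  for (nm in names(run$fits)) {
    best <- run$results$best_case[paste(run$results$id_i, run$results$id_j,
                                        sep = "-") == nm]
    write_ibd_bed(run$fits[[nm]][[best]],
                  file.path(dir, paste0(nm, ".ibd.bed")))
  }
  for (id in names(run$roh_fits)) {
    write_roh_bedgraph(run$roh_fits[[id]],
                       file.path(dir, paste0(id, ".roh.bedgraph")))
  }
  log <- c(paste0("kinfer version: ",
                  as.character(utils::packageVersion("kinfer"))),
           paste0("p0: ", format(run$p0, digits = 8)),
           paste0("cutoff: ", run$cutoff),
           paste0("seed: ", if (is.null(run$seed)) "NULL" else run$seed))
  writeLines(log, file.path(dir, "run.log"))
  invisible(dir)
}
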