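# --- Pedigree simulator -----------------------------------------------------
#
# Generates cohorts with known relatedness for transition-matrix estimation
# and method validation. Founder diversity comes from a frequency model:
# sites are independent, derived-allele frequencies follow a 1/x-weighted
# spectrum truncated below at `a`, with `a` calibrated so that the expected
# pairwise difference rate between two founders equals the target p0.
# Haplotypes of descendants are stored as mosaics of founder-haplotype
# segments, so true IBD and ROH states are known exactly everywhere.

#' Simulation configuration
#'
#' Defaults describe the reference scenario: 22 chromosomes of 96 Mb
#' (chromosome-13-sized), recombination rate 1e-8 per bp per generation,
#' 8 diploid founders, background difference rate 0.25 per polymorphic site,
#' contaminant divergence 0.4, per-individual contamination drawn from
#' 0.5-3%, and a per-bp ROH chain with entry rate 2/L and exit rate 10/L
#' (stationary ROH fraction 1/6, mean tract length L/10).
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param window_size Window size in bp.
#' @param r Recombination rate per bp per generation.
#' @param n_founders Number of diploid founders.
#' @param target_p0 Expected pairwise difference rate between founders at
#'   simulated polymorphic sites.
#' @param sites_per_Mb Density of polymorphic sites (default 1600/Mb,
#'   matching theta = 4 N mu = 4e-4 per bp and a sample of ~30 haplotypes).
#' @param window_cv Coefficient of variation of local (window-scale)
#'   diversity: each window's expected difference rate is the target `p0`
#'   times a lognormal multiplier with this CV, emulating the fluctuations
#'   in coalescent depth along real genomes that make windowed mismatch
#'   counts over-dispersed relative to the binomial. The default 0.07 is
#'   the coalescent expectation for the windowed pairwise TMRCA of a
#'   constant-size population at `4 N r L = 4000` per window; 0 disables.
#' @param phi Divergence between target and contaminant populations.
#' @param contamination_range Range the per-individual contamination rates
#'   are drawn from in contamination scenarios.
#' @param roh_entry,roh_exit Per-bp ROH chain rates, as multiples of 1/L.
#' @return A list of class `kin_sim_config`.
#' @export
sim_config <- function(n_chromosomes = 22, chrom_length = 96e6,
                       window_size = 1e7, r = 1e-8, n_founders = 8,
                       target_p0 = 0.25, sites_per_Mb = 1600, phi = 0.4,
                       contamination_range = c(0.005, 0.03),
                       roh_entry = 2, roh_exit = 10, window_cv = 0.07) {
  stopifnot(n_chromosomes >= 1, chrom_length > 0, r > 0, n_founders >= 2,
            target_p0 > 0, target_p0 < 0.5, phi > target_p0, phi < 1,
            window_cv >= 0)
  structure(list(
    n_chromosomes = n_chromosomes, chrom_length = chrom_length,
    window_size = window_size, r = r, n_founders = n_founders,
    target_p0 = target_p0, sites_per_Mb = sites_per_Mb, phi = phi,
    contamination_range = contamination_range,
    roh_entry = roh_entry, roh_exit = roh_exit, window_cv = window_cv
  ), class = "kin_sim_config")
}

sim_chrom_names <- function(config) paste0("chr", seq_len(config$n_chromosomes))

sim_chrom_table <- function(config) {
  data.frame(chrom = sim_chrom_names(config),
             length = rep(config$chrom_length, config$n_chromosomes))
}

#' @rdname sim_config
#' @param config A `kin_sim_config`.
#' @export
sim_grid <- function(config) {
  build_window_grid(sim_chrom_table(config), config$window_size)
}

# Lower truncation a of the 1/x frequency spectrum so that
# E[2 f (1-f)] = target; closed form E = (1-a)^2 / log(1/a), increasing in a
# on (0, ~0.28), so targets up to ~0.4 have a unique root there.
calibrate_spectrum <- function(target_p0) {
  if (target_p0 >= 0.40) stop("target rate out of the spectrum's range")
  f <- function(a) (1 - a)^2 / log(1 / a) - target_p0
  stats::uniroot(f, c(1e-12, 0.28), tol = 1e-12)$root
}

sample_spectrum <- function(n, a) {
  a^(1 - stats::runif(n))  # inverse CDF of density proportional to 1/f on (a, 1)
}

# --- haplotype mosaics ------------------------------------------------------
# A mosaic is list(ends, labels): segment i covers (ends[i-1], ends[i]] in bp
# with founder-haplotype label labels[i]; the last end equals the chromosome
# length.

full_mosaic <- function(label, len) list(ends = len, labels = as.integer(label))

# segment i covers (ends[i-1], ends[i]]; left-open matching avoids
# floating-point trouble at large coordinates
mosaic_labels_at <- function(m, pos) {
  m$labels[findInterval(pos, m$ends, left.open = TRUE) + 1L]
}

mosaic_slice <- function(m, from, to) {
  starts <- c(0, m$ends[-length(m$ends)])
  sel <- which(m$ends > from & starts < to)
  list(ends = pmin(m$ends[sel], to), labels = m$labels[sel])
}

# Recombine two parental mosaics at crossover positions, starting from
# haplotype `first`.
mosaic_splice <- function(m1, m2, xovers, first, len) {
  bounds <- c(0, xovers, len)
  ends <- numeric(0); labels <- integer(0)
  src <- first
  for (i in seq_len(length(bounds) - 1)) {
    s <- mosaic_slice(if (src == 1) m1 else m2, bounds[i], bounds[i + 1])
    ends <- c(ends, s$ends); labels <- c(labels, s$labels)
    src <- 3 - src
  }
  keep <- c(labels[-1] != labels[-length(labels)], TRUE)
  list(ends = ends[keep], labels = labels[keep])
}

make_founder <- function(id, hap_labels, config) {
  len <- config$chrom_length
  list(id = id, founder = TRUE,
       haps = list(
         lapply(seq_len(config$n_chromosomes), function(i)
           full_mosaic(hap_labels[1], len)),
         lapply(seq_len(config$n_chromosomes), function(i)
           full_mosaic(hap_labels[2], len))
       ))
}

gamete <- function(parent, config) {
  len <- config$chrom_length
  lapply(seq_len(config$n_chromosomes), function(ci) {
    k <- stats::rpois(1, config$r * len)
    xov <- sort(stats::runif(k, 0, len))
    first <- sample.int(2, 1)
    mosaic_splice(parent$haps[[1]][[ci]], parent$haps[[2]][[ci]],
                  xov, first, len)
  })
}

#' Mate two simulated individuals
#'
#' Each gamete draws a Poisson number of crossovers (mean `r * L`) at
#' uniform positions and alternates between the parent's two haplotypes from
#' a random start. Founder-haplotype labels propagate, so IBD against any
#' other individual remains exactly computable.
#'
#' @param parent_a,parent_b Individuals (founders from [simulate_founders()]
#'   or previous [mate()] calls).
#' @param config A `kin_sim_config`.
#' @param id Identifier for the child.
#' @return A child individual.
#' @export
mate <- function(parent_a, parent_b, config, id = "child") {
  list(id = id, founder = FALSE,
       haps = list(gamete(parent_a, config), gamete(parent_b, config)))
}

# --- founder genomes --------------------------------------------------------

#' Simulate founder genomes and the site table
#'
#' Draws the polymorphic-site positions, per-site derived-allele frequencies
#' from the calibrated spectrum, and Bernoulli haplotypes for the founders,
#' a 2-diploid ascertainment panel (stand-in for two outgroup populations)
#' and one contaminant diploid from a diverged population. The contaminant
#' haplotypes are founder-like draws with additional independent flips at
#' rate `kappa = (phi - p0) / (1 - 2 p0)`, which makes the expected mismatch
#' between a contaminant and an endogenous haplotype equal `phi`.
#'
#' @param config A `kin_sim_config`.
#' @param seed Optional seed.
#' @return A list of class `kin_sim`: `sites` (tibble `chrom`, `pos`, `f`),
#'   `founder_haps` (sites x 2*n_founders 0/1 matrix), `panel_haps`
#'   (sites x 4), `contaminant_haps` (sites x 2), `individuals` (named list
#'   of founders), `roh_masks` (empty), and the config.
#' @export
simulate_founders <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_per_chrom <- round(config$sites_per_Mb * config$chrom_length / 1e6)
  chroms <- sim_chrom_names(config)
  sites <- purrr::map_dfr(chroms, function(ch) {
    tibble::tibble(chrom = ch,
                   pos = sort(sample.int(config$chrom_length, n_per_chrom)))
  })
  n <- nrow(sites)
  # window-scale diversity fluctuations: lognormal rate multiplier per
  # window (mean 1, CV config$window_cv), realized by re-truncating the
  # frequency spectrum per window
  grid <- sim_grid(config)
  if (config$window_cv > 0) {
    sdlog <- sqrt(log(1 + config$window_cv^2))
    lambda <- stats::rlnorm(nrow(grid), -sdlog^2 / 2, sdlog)
    targets <- pmin(lambda * config$target_p0, 0.39)
    a_w <- vapply(targets, calibrate_spectrum, numeric(1))
    widx <- window_index(grid, sites$chrom, sites$pos)
    sites$f <- a_w[widx]^(1 - stats::runif(n))
  } else {
    a <- calibrate_spectrum(config$target_p0)
    sites$f <- sample_spectrum(n, a)
  }
  nh <- 2 * config$n_founders
  bern <- function(k, p) {
    matrix(stats::rbinom(n * k, 1L, rep(p, k)), n, k)
  }
  founder_haps <- bern(nh, sites$f)
  panel_haps <- bern(4, sites$f)
  kappa <- (config$phi - config$target_p0) / (1 - 2 * config$target_p0)
  base <- bern(2, sites$f)
  flips <- bern(2, rep(kappa, n))
  contaminant_haps <- (base + flips) %% 2L

  founders <- lapply(seq_len(config$n_founders), function(k) {
    make_founder(paste0("F", k), c(2 * k - 1, 2 * k), config)
  })
  names(founders) <- vapply(founders, `[[`, "", "id")
  structure(list(sites = sites, founder_haps = founder_haps,
                 panel_haps = panel_haps, contaminant_haps = contaminant_haps,
                 individuals = founders, roh_masks = list(),
                 config = config), class = "kin_sim")
}

# --- ROH in founders --------------------------------------------------------

# Alternating-tract realization of the two-state per-bp ROH chain.
sim_roh_mask_chrom <- function(len, entry_rate, exit_rate) {
  frac_roh <- entry_rate / (entry_rate + exit_rate)
  state <- stats::runif(1) < frac_roh
  pos <- 0
  out <- list()
  while (pos < len) {
    rate <- if (state) exit_rate else entry_rate
    seg <- stats::rexp(1, rate)
    end <- min(pos + seg, len)
    if (state) out[[length(out) + 1]] <- c(pos, end)
    pos <- end
    state <- !state
  }
  if (length(out) == 0) return(tibble::tibble(start = numeric(0), end = numeric(0)))
  m <- do.call(rbind, out)
  tibble::tibble(start = m[, 1], end = m[, 2])
}

#' Add runs of homozygosity to founder genomes
#'
#' Simulates ROH tracts per founder chromosome from the two-state per-bp
#' Markov chain (entry rate 2/L, exit rate 10/L by default: on average 1/6
#' of the genome in ROH, mean tract length L/10) and copies the first
#' haplotype's alleles over the second within each tract. Descendants
#' created afterwards inherit the homozygosity through the founder alleles;
#' true masks are recorded per founder.
#'
#' @param sim A `kin_sim`.
#' @param ids Founder ids to modify (default: all founders).
#' @param seed Optional seed.
#' @return The modified `kin_sim` with `roh_masks` filled in.
#' @export
apply_roh <- function(sim, ids = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  config <- sim$config
  if (is.null(ids)) {
    ids <- names(sim$individuals)[vapply(sim$individuals, `[[`, TRUE, "founder")]
  }
  len <- config$chrom_length
  entry <- config$roh_entry / len
  exit <- config$roh_exit / len
  chroms <- sim_chrom_names(config)
  for (id in ids) {
    ind <- sim$individuals[[id]]
    if (!isTRUE(ind$founder)) stop("ROH can only be applied to founders: ", id)
    h1 <- ind$haps[[1]][[1]]$labels[1]
    h2 <- ind$haps[[2]][[1]]$labels[1]
    masks <- purrr::map_dfr(chroms, function(ch) {
      m <- sim_roh_mask_chrom(len, entry, exit)
      if (nrow(m)) m$chrom <- ch
      m
    })
    if (nrow(masks)) {
      for (ci in seq_along(chroms)) {
        mm <- masks[masks$chrom == chroms[ci], , drop = FALSE]
        if (!nrow(mm)) next
        rows <- which(sim$sites$chrom == chroms[ci])
        pos <- sim$sites$pos[rows]
        inroh <- rep(FALSE, length(pos))
        for (k in seq_len(nrow(mm))) {
          inroh <- inroh | (pos > mm$start[k] & pos <= mm$end[k])
        }
        sim$founder_haps[rows[inroh], h2] <- sim$founder_haps[rows[inroh], h1]
      }
    }
    sim$roh_masks[[id]] <- masks
  }
  sim
}

# --- ascertainment ----------------------------------------------------------

#' Restrict sites to those polymorphic in the panel
#'
#' Emulates SNP-array ascertainment: keeps only sites polymorphic among the
#' four panel haplotypes (two outgroup diploids), which shifts the retained
#' frequency spectrum toward intermediate frequencies.
#'
#' @param sim A `kin_sim`.
#' @return A `kin_sim` on the reduced site set.
#' @export
ascertain_sites <- function(sim) {
  s <- rowSums(sim$panel_haps)
  keep <- s > 0 & s < 4
  sim$sites <- sim$sites[keep, ]
  sim$founder_haps <- sim$founder_haps[keep, , drop = FALSE]
  sim$panel_haps <- sim$panel_haps[keep, , drop = FALSE]
  sim$contaminant_haps <- sim$contaminant_haps[keep, , drop = FALSE]
  sim
}

# --- genotypes and reads ----------------------------------------------------

#' Diploid genotypes of a simulated individual
#'
#' @param sim A `kin_sim`.
#' @param ind An individual (or its id in `sim$individuals`).
#' @return Integer vector of derived-allele counts (0/1/2) over `sim$sites`.
#' @export
sim_genotypes <- function(sim, ind) {
  if (is.character(ind)) ind <- sim$individuals[[ind]]
  chroms <- sim_chrom_names(sim$config)
  g <- integer(nrow(sim$sites))
  for (ci in seq_along(chroms)) {
    rows <- which(sim$sites$chrom == chroms[ci])
    if (!length(rows)) next
    pos <- sim$sites$pos[rows]
    l1 <- mosaic_labels_at(ind$haps[[1]][[ci]], pos)
    l2 <- mosaic_labels_at(ind$haps[[2]][[ci]], pos)
    g[rows] <- sim$founder_haps[cbind(rows, l1)] +
      sim$founder_haps[cbind(rows, l2)]
  }
  g
}

#' Generate read counts for one individual
#'
#' Per-site depth is Poisson with the mean coverage; each read comes from a
#' random chromosome of the endogenous genome with probability
#' `1 - contamination`, otherwise from a random chromosome of the
#' contaminant diploid. No sequencing error is modeled. Sites with zero
#' depth are dropped from the output.
#'
#' @param sim A `kin_sim`.
#' @param ind Individual or id.
#' @param coverage Mean depth.
#' @param contamination Contaminant read fraction, in `[0, 1]`.
#' @param seed Optional seed.
#' @return Site-count tibble (`chrom`, `pos`, `derived`, `total`) with an
#'   attribute `n_target_sites` (the size of the site universe, needed for
#'   mean-depth computations).
#' @export
generate_reads <- function(sim, ind, coverage, contamination = 0,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(coverage > 0, contamination >= 0, contamination <= 1)
  g <- sim_genotypes(sim, ind)
  gc <- rowSums(sim$contaminant_haps)
  n <- length(g)
  depth <- stats::rpois(n, coverage)
  p <- (1 - contamination) * g / 2 + contamination * gc / 2
  derived <- stats::rbinom(n, depth, p)
  out <- tibble::tibble(chrom = sim$sites$chrom, pos = sim$sites$pos,
                        derived = derived, total = depth)
  out <- out[out$total > 0, ]
  attr(out, "n_target_sites") <- n
  out
}

# --- truth ------------------------------------------------------------------

multiset_shared <- function(a1, a2, b1, b2) {
  x <- c(a1, a2); y <- c(b1, b2)
  shared <- 0L
  for (u in unique(x)) {
    shared <- shared + min(sum(x == u), sum(y == u))
  }
  min(shared, 2L)
}

#' True IBD segments between two simulated individuals
#'
#' Intersects the founder-label mosaics of both individuals; within each
#' resulting segment the IBD state is the multiset overlap of the two label
#' pairs (0, 1 or 2 shared chromosomes).
#'
#' @param ind_i,ind_j Individuals.
#' @param config The `kin_sim_config` they were simulated under.
#' @return Tibble `chrom`, `start`, `end`, `Z`.
#' @export
true_ibd_segments <- function(ind_i, ind_j, config) {
  chroms <- sim_chrom_names(config)
  purrr::map_dfr(seq_along(chroms), function(ci) {
    ends <- sort(unique(c(ind_i$haps[[1]][[ci]]$ends,
                          ind_i$haps[[2]][[ci]]$ends,
                          ind_j$haps[[1]][[ci]]$ends,
                          ind_j$haps[[2]][[ci]]$ends)))
    starts <- c(0, ends[-length(ends)])
    mids <- (starts + ends) / 2
    a1 <- mosaic_labels_at(ind_i$haps[[1]][[ci]], mids)
    a2 <- mosaic_labels_at(ind_i$haps[[2]][[ci]], mids)
    b1 <- mosaic_labels_at(ind_j$haps[[1]][[ci]], mids)
    b2 <- mosaic_labels_at(ind_j$haps[[2]][[ci]], mids)
    z <- mapply(multiset_shared, a1, a2, b1, b2)
    tibble::tibble(chrom = chroms[ci], start = starts, end = ends, Z = z)
  })
}

#' Genome-wide IBD state fractions
#'
#' @param segments Output of [true_ibd_segments()].
#' @return Named vector `k0`, `k1`, `k2`.
#' @export
ibd_fractions <- function(segments) {
  tot <- sum(segments$end - segments$start)
  k <- vapply(0:2, function(z) {
    sum((segments$end - segments$start)[segments$Z == z]) / tot
  }, numeric(1))
  stats::setNames(k, c("k0", "k1", "k2"))
}

#' True per-window IBD state and occupancy
#'
#' @param segments Output of [true_ibd_segments()].
#' @param grid A `kin_grid`.
#' @return Tibble per window with `Z_center` (state at the window's central
#'   bp) and `frac0`, `frac1`, `frac2` (fractional occupancy).
#' @export
true_window_states <- function(segments, grid) {
  out <- grid[, c("chrom", "start", "end", "window")]
  centers <- (out$start + out$end) / 2
  zc <- integer(nrow(out))
  frac <- matrix(0, nrow(out), 3)
  for (ch in unique(out$chrom)) {
    seg <- segments[segments$chrom == ch, ]
    wi <- which(out$chrom == ch)
    idx <- findInterval(centers[wi], seg$end, left.open = TRUE) + 1L
    zc[wi] <- seg$Z[idx]
    for (k in seq_along(wi)) {
      w0 <- out$start[wi[k]]; w1 <- out$end[wi[k]]
      ov <- pmax(0, pmin(seg$end, w1) - pmax(seg$start, w0))
      for (z in 0:2) frac[wi[k], z + 1] <- sum(ov[seg$Z == z]) / (w1 - w0)
    }
  }
  out$Z_center <- zc
  out$frac0 <- frac[, 1]; out$frac1 <- frac[, 2]; out$frac2 <- frac[, 3]
  tibble::as_tibble(out)
}

#' True per-window ROH fraction for a founder
#'
#' @param sim A `kin_sim` after [apply_roh()].
#' @param id Founder id.
#' @param grid A `kin_grid`.
#' @return Numeric vector of per-window ROH fractions (0 when the individual
#'   has no recorded mask).
#' @export
true_window_roh <- function(sim, id, grid) {
  frac <- numeric(nrow(grid))
  mask <- sim$roh_masks[[id]]
  if (is.null(mask) || nrow(mask) == 0) return(frac)
  for (w in seq_len(nrow(grid))) {
    m <- mask[mask$chrom == grid$chrom[w], , drop = FALSE]
    if (!nrow(m)) next
    ov <- pmax(0, pmin(m$end, grid$end[w]) - pmax(m$start, grid$start[w]))
    frac[w] <- sum(ov) / (grid$end[w] - grid$start[w])
  }
  frac
}

# --- pedigree template ------------------------------------------------------

#' Build the 17-individual evaluation pedigree
#'
#' Mates the 8 founders into 9 descendants so that the cohort contains at
#' least one pair of every modeled relationship:
#' A, B = children of F1 x F2 (siblings; parent-child with F1);
#' C = child of F1 x F3 (half-sibling of A);
#' D = child of A x F4 (avuncular with B, grandparent-grandchild with F1);
#' E, J = children of B x F5 (D-E first cousins, 3rd degree);
#' G = child of D x F6 (E-G 4th degree); H = child of E x F7 (G-H 5th
#' degree); I = child of C x F8. The identical pair is realized as two
#' independent read sets from A's genome.
#'
#' @param sim A `kin_sim` with founders.
#' @param seed Optional seed.
#' @return The `kin_sim` with descendants added and a `relations` tibble
#'   (`id_i`, `id_j`, `relation`) of canonical evaluation pairs attached.
#' @export
build_pedigree <- function(sim, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  config <- sim$config
  if (config$n_founders < 8) stop("pedigree template needs 8 founders")
  ind <- sim$individuals
  ind$A <- mate(ind$F1, ind$F2, config, "A")
  ind$B <- mate(ind$F1, ind$F2, config, "B")
  ind$C <- mate(ind$F1, ind$F3, config, "C")
  ind$D <- mate(ind$A, ind$F4, config, "D")
  ind$E <- mate(ind$B, ind$F5, config, "E")
  ind$J <- mate(ind$B, ind$F5, config, "J")
  ind$G <- mate(ind$D, ind$F6, config, "G")
  ind$H <- mate(ind$E, ind$F7, config, "H")
  ind$I <- mate(ind$C, ind$F8, config, "I")
  sim$individuals <- ind
  sim$relations <- tibble::tribble(
    ~id_i, ~id_j, ~relation,
    "A", "A", "identical",
    "F1", "A", "parent-child",
    "A", "B", "siblings",
    "A", "C", "half-siblings",
    "B", "D", "avuncular",
    "F1", "D", "grandparent-grandchild",
    "D", "E", "third-degree",
    "E", "G", "fourth-degree",
    "G", "H", "fifth-degree",
    "F4", "F5", "unrelated",
    "F7", "F8", "unrelated",
    "F4", "H", "unrelated"
  )
  sim
}

# --- label-only paths for empirical transition matrices ---------------------

# Simulate minimal pedigrees for one relatedness case and return the true
# IBD state at window centers, one vector per chromosome per replicate.
# Only mosaics are simulated (no sites), so this is fast enough for 1000
# replicates.
sim_relation_paths <- function(case, n_sims, r = 1e-8, b = 1e7,
                               n_chromosomes = 22, chrom_length = 96e6,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  config <- sim_config(n_chromosomes = n_chromosomes,
                       chrom_length = chrom_length, window_size = b, r = r)
  grid <- sim_grid(config)
  founders <- lapply(1:6, function(k) {
    make_founder(paste0("F", k), c(2 * k - 1, 2 * k), config)
  })
  names(founders) <- paste0("F", 1:6)
  pair_fun <- switch(
    case,
    "half-siblings" = function(f) {
      list(mate(f$F1, f$F2, config), mate(f$F1, f$F3, config))
    },
    "avuncular" = function(f) {
      a <- mate(f$F1, f$F2, config); b2 <- mate(f$F1, f$F2, config)
      list(b2, mate(a, f$F3, config))
    },
    "third-degree" = function(f) {
      a <- mate(f$F1, f$F2, config); b2 <- mate(f$F1, f$F2, config)
      list(mate(a, f$F3, config), mate(b2, f$F4, config))
    },
    "fourth-degree" = function(f) {
      a <- mate(f$F1, f$F2, config); b2 <- mate(f$F1, f$F2, config)
      d <- mate(a, f$F3, config); e <- mate(b2, f$F4, config)
      list(e, mate(d, f$F5, config))
    },
    "fifth-degree" = function(f) {
      a <- mate(f$F1, f$F2, config); b2 <- mate(f$F1, f$F2, config)
      d <- mate(a, f$F3, config); e <- mate(b2, f$F4, config)
      list(mate(d, f$F5, config), mate(e, f$F6, config))
    },
    "grandparent-grandchild" = function(f) {
      a <- mate(f$F1, f$F2, config)
      list(f$F1, mate(a, f$F3, config))
    },
    "siblings" = function(f) {
      list(mate(f$F1, f$F2, config), mate(f$F1, f$F2, config))
    },
    stop("no simulated pedigree for case: ", case)
  )
  paths <- list()
  for (s in seq_len(n_sims)) {
    pr <- pair_fun(founders)
    seg <- true_ibd_segments(pr[[1]], pr[[2]], config)
    st <- true_window_states(seg, grid)
    for (ch in unique(st$chrom)) {
      paths[[length(paths) + 1]] <- st$Z_center[st$chrom == ch]
    }
  }
  paths
}

# --- cohort orchestration ---------------------------------------------------

#' Simulate a full evaluation cohort
#'
#' Runs founder simulation, optional ROH, pedigree construction, optional
#' ascertainment, and read generation at the requested coverage, with
#' optional contamination of a fixed subset of libraries. Two read sets are
#' generated from individual A's genome (`A` and `A2`) to realize the
#' identical pair.
#'
#' @param config A `kin_sim_config`.
#' @param coverage Mean sequencing depth.
#' @param seed Seed (drives everything; identical settings reproduce the
#'   cohort exactly).
#' @param roh,contamination,ascertainment Scenario switches.
#' @param libraries Optional character vector restricting which read sets are
#'   generated (defaults to all 17 individuals plus `A2`). Truth and genomes
#'   are always complete.
#' @return A list of class `kin_cohort`: `counts` (named list of site-count
#'   tibbles), `sim` (the `kin_sim` with individuals and masks), `relations`,
#'   `contamination` (named rates used), `grid`, `n_target_sites`.
#' @export
sim_cohort <- function(config = sim_config(), coverage = 1, seed = NULL,
                       roh = FALSE, contamination = FALSE,
                       ascertainment = FALSE, libraries = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_founders(config)
  if (roh) sim <- apply_roh(sim)
  sim <- build_pedigree(sim)
  if (ascertainment) sim <- ascertain_sites(sim)
  all_libs <- c(names(sim$individuals), "A2")
  if (is.null(libraries)) libraries <- all_libs
  stopifnot(all(libraries %in% all_libs))
  # fixed documented subset of contaminated libraries (8 of 17)
  contaminated <- c("F2", "F4", "F6", "F8", "A", "C", "E", "G")
  rates <- stats::setNames(rep(0, length(libraries)), libraries)
  if (contamination) {
    r <- stats::runif(length(contaminated), config$contamination_range[1],
                      config$contamination_range[2])
    names(r) <- contaminated
    hit <- intersect(libraries, contaminated)
    rates[hit] <- r[hit]
  }
  counts <- lapply(libraries, function(lib) {
    genome <- if (lib == "A2") "A" else lib
    generate_reads(sim, genome, coverage, contamination = rates[[lib]])
  })
  names(counts) <- libraries
  structure(list(counts = counts, sim = sim, relations = sim$relations,
                 contamination = rates, grid = sim_grid(config),
                 n_target_sites = nrow(sim$sites), config = config),
            class = "kin_cohort")
}

#' Write a simulated cohort to disk
#'
#' One site-count TSV per library plus truth tables (relations, per-pair
#' window states for the canonical pairs) and a manifest echoing seed and
#' configuration.
#'
#' @param cohort A `kin_cohort`.
#' @param dir Output directory (created if needed).
#' @param seed Seed to record in the manifest.
#' @export
write_cohort <- function(cohort, dir, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lib in names(cohort$counts)) {
    readr::write_tsv(cohort$counts[[lib]],
                     file.path(dir, paste0(lib, ".counts.tsv")))
  }
  readr::write_tsv(cohort$relations, file.path(dir, "relations.tsv"))
  cfg <- cohort$config
  manifest <- c(
    paste0("seed=", seed),
    paste0(names(cfg), "=", vapply(cfg, function(x)
      paste(format(x, digits = 12), collapse = ","), "")),
    paste0("contamination=", paste(names(cohort$contamination),
                                   format(cohort$contamination, digits = 4),
                                   sep = ":", collapse = ","))
  )
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
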