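test_that("founder diversity is calibrated to the target p0", {
  cfg <- test_config(n_chromosomes = 2, sites_per_Mb = 800, n_founders = 4,
                     target_p0 = 0.2)
  set.seed(5)
  sim <- simulate_founders(cfg)
  g1 <- sim_genotypes(sim, "F1") / 2
  g2 <- sim_genotypes(sim, "F2") / 2
  rate <- mean(g1 * (1 - g2) + (1 - g1) * g2)
  expect_equal(rate, 0.2, tolerance = 0.01)
  # same seed, same sites
  sim2 <- simulate_founders(cfg, seed = 123)
  sim3 <- simulate_founders(cfg, seed = 123)
  expect_identical(sim2$sites, sim3$sites)
  expect_identical(sim2$founder_haps, sim3$founder_haps)
})

test_that("mating implements Poisson recombination with label propagation", {
  cfg <- test_config(n_chromosomes = 1, sites_per_Mb = 10, n_founders = 4)
  set.seed(9)
  sim <- simulate_founders(cfg)
  # r = 0: child haplotypes are unrecombined parental haplotypes
  cfg0 <- test_config(n_chromosomes = 1, sites_per_Mb = 10, n_founders = 4,
                      r = 1e-300)
  child0 <- mate(sim$individuals$F1, sim$individuals$F2, cfg0)
  expect_length(child0$haps[[1]][[1]]$labels, 1)
  expect_true(child0$haps[[1]][[1]]$labels %in% 1:2)
  expect_true(child0$haps[[2]][[1]]$labels %in% 3:4)

  # breakpoint count over gametes is Poisson with mean r * L = 0.96
  nb <- replicate(1000, {
    g <- kinfer:::gamete(sim$individuals$F1, cfg)
    length(g[[1]]$labels) - 1
  })
  expect_equal(mean(nb), 0.96, tolerance = 0.1)

  # a child shares exactly one chromosome with each parent everywhere
  child <- mate(sim$individuals$F1, sim$individuals$F2, cfg)
  seg <- true_ibd_segments(sim$individuals$F1, child, cfg)
  expect_true(all(seg$Z == 1))
  expect_equal(unname(ibd_fractions(seg)), c(0, 1, 0))
})

test_that("the pedigree template yields the canonical relationships", {
  cfg <- test_config(n_chromosomes = 6, sites_per_Mb = 10)
  set.seed(17)
  sim <- build_pedigree(simulate_founders(cfg))
  expect_length(sim$individuals, 17)
  expect_true(all(c("identical", "parent-child", "siblings", "half-siblings",
                    "avuncular", "grandparent-grandchild", "third-degree",
                    "fourth-degree", "fifth-degree", "unrelated") %in%
                    sim$relations$relation))

  # genome-wide IBD fractions across replicate pedigrees match expectation
  reps <- 15
  ks <- array(0, c(reps, 3, 3))  # siblings, gp-gc, half-sibs
  for (r in seq_len(reps)) {
    s <- build_pedigree(simulate_founders(cfg, seed = 100 + r))
    ks[r, 1, ] <- ibd_fractions(true_ibd_segments(s$individuals$A,
                                                  s$individuals$B, cfg))
    ks[r, 2, ] <- ibd_fractions(true_ibd_segments(s$individuals$F1,
                                                  s$individuals$D, cfg))
    ks[r, 3, ] <- ibd_fractions(true_ibd_segments(s$individuals$A,
                                                  s$individuals$C, cfg))
  }
  se3 <- function(x) 3 * sd(x) / sqrt(reps) + 1e-9
  m <- apply(ks, c(2, 3), mean)
  expect_lt(abs(m[1, 1] - 0.25), max(se3(ks[, 1, 1]), 0.02))
  expect_lt(abs(m[1, 2] - 0.50), max(se3(ks[, 1, 2]), 0.02))
  expect_lt(abs(m[1, 3] - 0.25), max(se3(ks[, 1, 3]), 0.02))
  expect_lt(abs(m[2, 2] - 0.5), max(se3(ks[, 2, 2]), 0.02))
  expect_equal(m[2, 3], 0)   # grandparent-grandchild never shares 2
  expect_lt(abs(m[3, 2] - 0.5), max(se3(ks[, 3, 2]), 0.02))
  # unrelated founders share nothing
  seg0 <- true_ibd_segments(sim$individuals$F7, sim$individuals$F8, cfg)
  expect_true(all(seg0$Z == 0))
})

test_that("ROH tracts follow the two-state chain and silence heterozygosity", {
  cfg <- test_config(n_chromosomes = 8, sites_per_Mb = 200, n_founders = 2)
  fracs <- numeric(10); tract_means <- numeric(10)
  for (r in 1:10) {
    set.seed(300 + r)
    sim <- apply_roh(simulate_founders(cfg), ids = "F1")
    m <- sim$roh_masks$F1
    fracs[r] <- sum(m$end - m$start) / (cfg$n_chromosomes * cfg$chrom_length)
    tract_means[r] <- mean(m$end - m$start)
  }
  expect_lt(abs(mean(fracs) - 1 / 6), 0.04)
  # mean tract length ~ L/10 (geometric dwell), allowing edge truncation
  expect_lt(abs(mean(tract_means) - 9.6e6), 0.25 * 9.6e6)

  # zero heterozygosity inside true ROH
  set.seed(311)
  sim <- apply_roh(simulate_founders(cfg), ids = "F1")
  g <- sim_genotypes(sim, "F1")
  m <- sim$roh_masks$F1
  inroh <- rep(FALSE, nrow(sim$sites))
  for (k in seq_len(nrow(m))) {
    inroh <- inroh | (sim$sites$chrom == m$chrom[k] &
                        sim$sites$pos > m$start[k] &
                        sim$sites$pos <= m$end[k])
  }
  expect_true(all(g[inroh] %in% c(0L, 2L)))
  expect_error(apply_roh(sim, ids = "nope"))
})

test_that("panel ascertainment keeps polymorphic sites and shifts p0 up", {
  cfg <- test_config(n_chromosomes = 2, sites_per_Mb = 800, n_founders = 4)
  set.seed(41)
  sim <- simulate_founders(cfg)
  asc <- ascertain_sites(sim)
  s <- rowSums(sim$panel_haps)
  expect_equal(nrow(asc$sites), sum(s > 0 & s < 4))
  # fixed panel sites are gone
  sa <- rowSums(asc$panel_haps)
  expect_true(all(sa > 0 & sa < 4))
  # ascertainment enriches intermediate frequencies: founder mismatch grows
  rate_of <- function(x) {
    g1 <- sim_genotypes(x, "F1") / 2; g2 <- sim_genotypes(x, "F2") / 2
    mean(g1 * (1 - g2) + (1 - g1) * g2)
  }
  expect_gt(rate_of(asc), rate_of(sim))
})

test_that("read generation follows Poisson depth and the contamination mixture", {
  cfg <- test_config(n_chromosomes = 1, sites_per_Mb = 1100, n_founders = 2)
  set.seed(53)
  sim <- simulate_founders(cfg)
  n <- nrow(sim$sites)
  expect_gte(n, 1e5)
  reads <- generate_reads(sim, "F1", coverage = 4)
  expect_equal(sum(reads$total) / n, 4, tolerance = 0.02)
  expect_true(all(reads$derived <= reads$total))

  # no contamination: homozygous-derived sites yield only derived reads
  g <- sim_genotypes(sim, "F1")
  hom <- reads[match(sim$sites$pos[g == 2], reads$pos), ]
  hom <- hom[!is.na(hom$pos), ]
  expect_true(all(hom$derived == hom$total))

  # full contamination: counts reflect the contaminant genome only
  gc <- rowSums(sim$contaminant_haps)
  reads_c <- generate_reads(sim, "F1", coverage = 4, contamination = 1)
  idx <- match(reads_c$pos, sim$sites$pos)
  expect_true(all(reads_c$derived[gc[idx] == 0] == 0))
  expect_true(all(reads_c$derived[gc[idx] == 2] ==
                    reads_c$total[gc[idx] == 2]))
})

test_that("true window states and cohort generation are deterministic", {
  cfg <- test_config(n_chromosomes = 2, sites_per_Mb = 50)
  grid <- sim_grid(cfg)
  set.seed(61)
  sim <- build_pedigree(simulate_founders(cfg))
  # identical genomes: Z = 2 everywhere; founders: Z = 0
  segAA <- true_ibd_segments(sim$individuals$A, sim$individuals$A, cfg)
  expect_true(all(segAA$Z == 2))
  st <- true_window_states(true_ibd_segments(sim$individuals$F1,
                                             sim$individuals$A, cfg), grid)
  expect_true(all(st$Z_center == 1))
  expect_equal(st$frac1, rep(1, nrow(grid)))

  co1 <- sim_cohort(cfg, coverage = 0.5, seed = 99,
                    libraries = c("F1", "A", "B"))
  co2 <- sim_cohort(cfg, coverage = 0.5, seed = 99,
                    libraries = c("F1", "A", "B"))
  expect_identical(co1$counts, co2$counts)
  # written cohorts are byte-identical under the same seed
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(co1, d1, seed = 99); write_cohort(co2, d2, seed = 99)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
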