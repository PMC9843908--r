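# Small simulation configurations shared across tests. Generator parameters
# stay at their stated-world defaults; only the problem size (chromosome
# count/length, site density, replicate numbers) is scaled to the test
# budget.

test_config <- function(n_chromosomes = 4, chrom_length = 96e6,
                        sites_per_Mb = 400, ...) {
  sim_config(n_chromosomes = n_chromosomes, chrom_length = chrom_length,
             sites_per_Mb = sites_per_Mb, ...)
}

# Registry from the shipped transition-matrix store (fast; read once).
shipped_registry <- local({
  reg <- NULL
  function() {
    if (is.null(reg)) reg <<- model_registry()
    reg
  }
})

# Classify a set of canonical pairs of one simulated pedigree and join truth.
classify_pedigree <- function(seed, coverage, config = test_config(8),
                              libs = c("F1", "F4", "F7", "F8", "A", "A2",
                                       "B", "C", "D", "E", "G", "H"),
                              pairs = NULL, contamination = FALSE,
                              roh = FALSE, roh_mode = "auto", p0 = NULL) {
  co <- sim_cohort(config, coverage = coverage, seed = seed, roh = roh,
                   contamination = contamination, libraries = libs)
  rel <- co$relations
  rel$id_j[rel$relation == "identical"] <- "A2"
  rel <- rel[rel$id_i %in% libs & rel$id_j %in% libs, ]
  if (!is.null(pairs)) rel <- rel[rel$relation %in% pairs, ]
  run <- run_pipeline(co$counts, registry = shipped_registry(),
                      seed = seed + 1, p0 = p0,
                      contamination = if (contamination) co$contamination,
                      phi = if (contamination) config$phi,
                      roh_mode = roh_mode,
                      pairs = data.frame(id_i = rel$id_i, id_j = rel$id_j),
                      n_target_sites = co$n_target_sites)
  dplyr::left_join(run$results, rel, by = c("id_i", "id_j"))
}
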