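# shared fixture builders: everything is generated in code at test time

# calls table straight from a simulated dosage matrix (bypasses intensity
# calling; posterior 1)
h_calls <- function(sim, observed = FALSE) {
  dm <- if (observed) sim$dosage_obs else sim$dosage_true
  data.frame(marker_id = rep(rownames(dm), ncol(dm)),
             sample_id = rep(colnames(dm), each = nrow(dm)),
             dosage = as.vector(dm), posterior = 1)
}

# classification table from simulator truth (MSV3 offset from the fixed
# paralog's allele)
h_classifications <- function(sim) {
  off <- ifelse(sim$markers$klass == "MSV3",
                ifelse(sim$markers$allele_freq_locus2 >= 1, 2L, 0L),
                NA_integer_)
  data.frame(marker_id = sim$markers$id, klass = sim$markers$klass,
             msv3_offset = off, qc_flags = "")
}

# single-chromosome testcross simulation + grid, the workhorse of the
# linkage tests
h_testcross <- function(seed, n_markers = 20L, length_cM = 100,
                        n_families = 25L, offspring = 20L,
                        sex = "female", error_rate = 0,
                        male_length = length_cM, uniform_weight = 1,
                        male_telomere_weights = c(1, 1)) {
  cfg <- sim_config(
    chromosomes = data.frame(id = "c1", female_length = length_cM,
                             male_length = male_length),
    homeolog_pairs = data.frame(arm_a = character(), arm_b = character(),
                                divergence = numeric()),
    msv_fraction = 0, mono_fraction = 0, n_markers = n_markers,
    error_rate = error_rate, missing_rate = 0, marker_grid = TRUE,
    testcross = sex, n_sires = n_families, dams_per_sire = 1L,
    offspring_per_dam = offspring, uniform_weight = uniform_weight,
    male_telomere_weights = male_telomere_weights)
  sim <- simulate_dataset(cfg, seed)
  calls <- h_calls(sim, observed = error_rate > 0)
  cls <- h_classifications(sim)
  grid <- build_meiosis_grid(calls, cls, sim$pedigree)
  list(sim = sim, calls = calls, cls = cls, grid = grid)
}

# theta draws around class centers
h_theta <- function(centers, n_per, sd) {
  x <- rnorm(length(centers) * n_per, rep(centers, each = n_per), sd)
  pmin(pmax(x, 0), 1)
}

expect_same_order <- function(got, truth) {
  expect_true(identical(got, truth) || identical(got, rev(truth)),
              label = paste("order", paste(got, collapse = ",")))
}
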