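test_that("transmitted alleles are deduced exactly where determined", {
  # AB x AA, offspring AB: B came from the heterozygous parent
  dd <- tetramap:::.deduce_cells(1L, 0L, 1L)
  expect_equal(dd$value, 1L)
  # AB x AB, offspring AB: origin ambiguous
  dd2 <- tetramap:::.deduce_cells(1L, 1L, 1L)
  expect_true(is.na(dd2$value))
  # homozygous focal parent: never informative
  expect_true(is.na(tetramap:::.deduce_cells(0L, 1L, 1L)$value))
  # Mendelian impossibility flagged, not fatal
  dd3 <- tetramap:::.deduce_cells(1L, 0L, 2L)
  expect_true(is.na(dd3$value))
  expect_true(dd3$impossible)
})

test_that("grid cells match the simulator's gamete truth on clean data", {
  h <- h_testcross(3, n_markers = 10L, n_families = 4L, offspring = 10L)
  sim <- h$sim
  loci_by_chrom <- split(seq_len(nrow(sim$loci)), sim$loci$chrom)
  mism <- 0L; ninf <- 0L
  for (m in sim$markers$id) {
    li <- which(sim$loci$locus_id == m)
    col <- match(li, loci_by_chrom[[sim$loci$chrom[li]]])
    for (r in seq_len(nrow(h$grid$meioses))) {
      v <- h$grid$cells[r, m]
      if (is.na(v)) next
      role <- if (h$grid$meioses$parent_sex[r] == "M") "sire" else "dam"
      tr <- sim$gametes[[h$grid$meioses$offspring[r]]][[role]][[
        sim$loci$chrom[li]]][col]
      ninf <- ninf + 1L
      if (tr != v) mism <- mism + 1L
    }
  }
  expect_gt(ninf, 0L)
  expect_equal(mism, 0L)
})

test_that("two-point estimation matches closed forms and is symmetric", {
  # phase-known single parent: 10 meioses, 1 recombinant
  r1 <- tetramap:::.rf_ml(10L, 1L, phase_known = TRUE)
  expect_equal(r1$r, 0.1)
  expect_equal(r1$lod, log10(0.1 * 0.9^9 / 0.5^10), tolerance = 1e-9)
  # hidden phase converges to the same estimate here
  r1h <- tetramap:::.rf_ml(10L, 1L)
  expect_equal(r1h$r, 0.1, tolerance = 1e-6)
  expect_equal(r1h$lod, 1.60, tolerance = 0.01)
  # fully linked: r = 0, LOD = n log10 2
  r0 <- tetramap:::.rf_ml(c(10L, 10L), c(0L, 0L))
  expect_equal(r0$r, 0, tolerance = 1e-8)
  expect_equal(r0$lod, 20 * log10(2), tolerance = 1e-6)
  # phase-known EM equals the recombinant-count fraction
  set.seed(1)
  n <- rep(20L, 10); k <- rbinom(10, 20, 0.2)
  expect_equal(tetramap:::.rf_ml(n, k, phase_known = TRUE)$r,
               sum(k) / sum(n), tolerance = 1e-9)

  h <- h_testcross(5, n_markers = 6L, n_families = 5L, offspring = 10L)
  ab <- estimate_twopoint(h$grid, "M00001", "M00002")
  ba <- estimate_twopoint(h$grid, "M00002", "M00001")
  expect_equal(ab$r_female, ba$r_female)
  expect_equal(ab$lod_female, ba$lod_female)
})

test_that("unlinked markers give r near 0.5 and LOD near 0", {
  set.seed(8)
  # two independently transmitted markers, 200 meioses over 10 parents
  n_off <- 20L; n_par <- 10L
  cells <- cbind(a = rbinom(n_off * n_par, 1L, 0.5),
                 b = rbinom(n_off * n_par, 1L, 0.5))
  grid <- structure(list(
    cells = cells,
    conditional = matrix(FALSE, n_off * n_par, 2L,
                         dimnames = list(NULL, c("a", "b"))),
    meioses = data.frame(id = as.character(seq_len(n_off * n_par)),
                         parent = rep(paste0("P", 1:n_par), each = n_off),
                         offspring = as.character(seq_len(n_off * n_par)),
                         family = "F1",
                         parent_sex = rep(c("F", "M"),
                                          each = n_off)[seq_len(n_off * n_par)])),
    class = "tm_grid")
  colnames(grid$cells) <- c("a", "b")
  res <- estimate_twopoint(grid, "a", "b")
  se <- sqrt(0.25 / res$n_female)
  expect_lt(abs(res$r_female - 0.5), 3 * se + 0.05)
  expect_lt(res$lod_female, 1)
})

test_that("estimator converges to simulated r with small bias", {
  set.seed(99)
  for (r_true in c(0.05, 0.2, 0.4)) {
    # 2000 meioses over 100 parents, phase hidden
    est <- replicate(20, {
      k <- rbinom(100, 20, r_true)
      tetramap:::.rf_ml(rep(20L, 100), k)$r
    })
    expect_lt(abs(mean(est) - r_true), 0.01, label = paste("r", r_true))
  }
})

test_that("grouping recovers simulated chromosomes and honors anchors", {
  cfg <- sim_config(chromosomes = data.frame(id = c("c1", "c2"),
                                             female_length = c(80, 60),
                                             male_length = c(80, 60)),
                    homeolog_pairs = data.frame(arm_a = character(),
                                                arm_b = character(),
                                                divergence = numeric()),
                    msv_fraction = 0, mono_fraction = 0, n_markers = 40L,
                    error_rate = 0, missing_rate = 0, marker_grid = TRUE,
                    testcross = "female", n_sires = 25L, dams_per_sire = 1L,
                    offspring_per_dam = 20L, uniform_weight = 1)
  sim <- simulate_dataset(cfg, 23L)
  grid <- build_meiosis_grid(h_calls(sim), h_classifications(sim),
                             sim$pedigree)
  gr <- group_markers(grid)
  tab <- table(gr$groups$group,
               sim$markers$chromosome[match(gr$groups$marker,
                                            sim$markers$id)])
  expect_equal(nrow(tab), 2L)
  expect_true(all(rowSums(tab > 0) == 1L))  # groups are chromosome-pure

  # anchors label the recovered groups
  anchors <- setNames(sim$markers$chromosome[c(1, nrow(sim$markers))],
                      sim$markers$id[c(1, nrow(sim$markers))])
  gra <- group_markers(grid, anchors)
  lab <- gra$groups$anchor_label[match(sim$markers$id, gra$groups$marker)]
  expect_true(all(lab == sim$markers$chromosome, na.rm = TRUE))

  # infinite threshold: nothing links, all singletons
  gi <- group_markers(grid, lod_threshold = Inf)
  expect_equal(sort(gi$singletons), sort(sim$markers$id))
})

test_that("male-specific cross-pair association is detected and female-only is not", {
  cfg <- sim_config(chromosomes = data.frame(id = c("c1", "c2"),
                                             female_length = c(60, 60),
                                             male_length = c(60, 60)),
                    homeolog_pairs = data.frame(arm_a = "c1q", arm_b = "c2p",
                                                divergence = 0.05),
                    msv_fraction = 0, mono_fraction = 0, n_markers = 16L,
                    error_rate = 0, missing_rate = 0, marker_grid = TRUE,
                    maf_range = c(0.45, 0.55), n_sires = 20L,
                    dams_per_sire = 1L, offspring_per_dam = 25L,
                    uniform_weight = 1, pseudolinkage_coupling = 0.9)
  sim <- simulate_dataset(cfg, 41L)
  grid <- build_meiosis_grid(h_calls(sim), h_classifications(sim),
                             sim$pedigree)
  # pseudo-linkage itself can chain the homeologs into one group at lax
  # thresholds (the reason the study seeded groups with anchored markers),
  # so group stringently before scanning
  gr <- group_markers(grid, lod_threshold = 12)
  expect_gt(length(unique(gr$groups$group)), 1L)
  pl <- detect_pseudolinkage(grid, gr)
  expect_gt(nrow(pl$pairs), 0L)
  # supporting pairs span the two chromosomes
  chrom_of <- setNames(sim$markers$chromosome, sim$markers$id)
  expect_true(all(chrom_of[pl$support$marker_a] !=
                    chrom_of[pl$support$marker_b]))

  # without coupling the same design reports nothing
  cfg0 <- sim_config(chromosomes = data.frame(id = c("c1", "c2"),
                                              female_length = c(60, 60),
                                              male_length = c(60, 60)),
                     homeolog_pairs = data.frame(arm_a = "c1q", arm_b = "c2p",
                                                 divergence = 0.05),
                     msv_fraction = 0, mono_fraction = 0, n_markers = 16L,
                     error_rate = 0, missing_rate = 0, marker_grid = TRUE,
                     maf_range = c(0.45, 0.55), n_sires = 20L,
                     dams_per_sire = 1L, offspring_per_dam = 25L,
                     uniform_weight = 1, pseudolinkage_coupling = 0)
  sim0 <- simulate_dataset(cfg0, 41L)
  grid0 <- build_meiosis_grid(h_calls(sim0), h_classifications(sim0),
                              sim0$pedigree)
  gr0 <- group_markers(grid0, lod_threshold = 4)
  pl0 <- detect_pseudolinkage(grid0, gr0, lod_male_min = 5)
  expect_equal(nrow(pl0$pairs), 0L)
})

test_that("a female-linked male-independent pair is not reported", {
  # synthetic grid: two markers correlated in female meioses only
  set.seed(6)
  n <- 200L
  af <- rbinom(n, 1L, 0.5); bf <- af                    # female: fully linked
  am <- rbinom(n, 1L, 0.5); bm <- rbinom(n, 1L, 0.5)    # male: independent
  cells <- cbind(a = c(af, am), b = c(bf, bm))
  grid <- structure(list(
    cells = cells,
    conditional = matrix(FALSE, 2L * n, 2L,
                         dimnames = list(NULL, c("a", "b"))),
    meioses = data.frame(id = as.character(1:(2 * n)),
                         parent = rep(c("D1", "S1"), each = n),
                         offspring = as.character(1:(2 * n)), family = "F1",
                         parent_sex = rep(c("F", "M"), each = n))),
    class = "tm_grid")
  groups <- data.frame(marker = c("a", "b"), group = c("g1", "g2"),
                       anchor_label = NA_character_)
  pl <- detect_pseudolinkage(grid, list(groups = groups))
  expect_equal(nrow(pl$pairs), 0L)
})

test_that("MSV-5 pseudo-markers integrate into the grid and dual-place on the homeologous arm pair", {
  cfg <- sim_config(chromosomes = data.frame(id = c("c1", "c2"),
                                             female_length = c(60, 60),
                                             male_length = c(60, 60)),
                    homeolog_pairs = data.frame(arm_a = "c1q", arm_b = "c2p",
                                                divergence = 0.05),
                    msv_fraction = 0.25, msv5_fraction = 1,
                    mono_fraction = 0, n_markers = 30L,
                    error_rate = 0, missing_rate = 0,
                    maf_range = c(0.45, 0.55), n_sires = 10L,
                    dams_per_sire = 2L, offspring_per_dam = 25L,
                    uniform_weight = 1)
  sim <- simulate_dataset(cfg, 31L)
  calls <- h_calls(sim)
  cls <- h_classifications(sim)
  res5 <- resolve_msv5_all(calls, cls, sim$pedigree)
  expect_gt(length(res5), 0L)
  grid <- build_meiosis_grid(calls, cls, sim$pedigree, res5)
  expect_gt(length(grep("_L[12]$", colnames(grid$cells))), 0L)

  arms <- setNames(sim$markers$arm, sim$markers$id)
  snps <- sim$markers$id[sim$markers$klass == "SNP"]
  plc <- place_msv5_loci(grid, arms[snps], lod_min = 3)
  counts <- msv5_homeologies(plc)
  expect_gt(nrow(counts), 0L)
  top <- counts[which.max(counts$count), ]
  expect_equal(sort(c(top$arm_a, top$arm_b)), c("c1q", "c2p"))
  # single-placed MSV-5s contribute nothing
  single <- plc[!is.na(plc$arm_a) & is.na(plc$arm_b), ]
  if (nrow(single) > 0L)
    expect_false(any(single$marker_id %in% c(counts$arm_a, counts$arm_b)))
})
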