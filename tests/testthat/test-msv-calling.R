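test_that("cluster models are recovered from simulated theta data", {
  m1 <- fit_clusters(rep(0.5, 50))
  expect_equal(m1$k, 1L)
  expect_equal(m1$centers, 0.5, tolerance = 1e-6)

  set.seed(11)
  m5 <- fit_clusters(h_theta(c(0, .25, .5, .75, 1), 60, 0.02))
  expect_equal(m5$k, 5L)
  expect_true(all(abs(m5$centers - c(0, .25, .5, .75, 1)) < 0.02))

  m3 <- fit_clusters(h_theta(c(0, .5, 1), 100, 0.05))
  expect_equal(m3$k, 3L)
  expect_true(all(abs(m3$centers - c(0, .5, 1)) < 0.05))

  low <- fit_clusters(rep(0.5, 5))
  expect_equal(low$k, 0L)
  expect_equal(classify_marker(low)$qc_flags, "low_n")
})

test_that("cluster center recovery is within the parametric bound", {
  set.seed(21)
  for (rep in 1:20) {
    n_per <- 80L; sdv <- 0.03
    m <- fit_clusters(h_theta(c(0.25, 0.5, 0.75), n_per, sdv))
    if (m$k != 3L) next
    # interior centers are unaffected by boundary clamping
    expect_lt(abs(m$centers[2] - 0.5), 2 * sdv / sqrt(n_per) * 3)
  }
})

test_that("cluster patterns classify into SNP / MSV-3 / MSV-5 / MONO", {
  mod <- function(centers, sds) list(marker_id = "m", k = length(centers),
                                     centers = centers,
                                     sds = rep(sds, length(centers)),
                                     weights = rep(1 / length(centers),
                                                   length(centers)),
                                     flag = NULL)
  expect_equal(classify_marker(mod(c(0.01, 0.26, 0.49), 0.015))$klass, "MSV3")
  expect_equal(classify_marker(mod(c(0.02, 0.51, 0.98), 0.05))$klass, "SNP")
  expect_equal(classify_marker(mod(c(0, .25, .5, .75, 1), 0.02))$klass, "MSV5")
  expect_equal(classify_marker(mod(0.5, 0.02))$klass, "MONO")
  # tight-sd gate: wide three-cluster quarter-grid is not MSV3
  wide <- classify_marker(mod(c(0, 0.25, 0.5), 0.06))
  expect_equal(wide$klass, "FAIL")
  expect_true("pattern_mismatch" %in% wide$qc_flags)
  # upper-half MSV3 records the fixed paralog offset
  up <- classify_marker(mod(c(0.5, 0.76, 0.99), 0.02))
  expect_equal(up$klass, "MSV3")
  expect_equal(up$msv3_offset, 2L)
})

test_that("noise-free centers are classified without error for all classes", {
  cases <- list(SNP = c(0, .5, 1), MSV3 = c(0, .25, .5),
                MSV5 = c(0, .25, .5, .75, 1), MONO = 0.5)
  for (klass in names(cases)) {
    th <- rep(cases[[klass]], each = 30)
    got <- classify_marker(fit_clusters(th))$klass
    expect_equal(got, klass, label = klass)
  }
})

test_that("genotype calling maps clusters to dosages and drops weak posteriors", {
  set.seed(4)
  th5 <- h_theta(c(0, .25, .5, .75, 1), 200, 0.02)
  truth <- rep(0:4, each = 200)
  mod <- fit_clusters(th5)
  cl <- classify_marker(mod)
  calls <- call_genotypes(mod, cl, setNames(th5, paste0("s", seq_along(th5))))
  ok <- !is.na(calls$dosage)
  expect_lt(mean(calls$dosage[ok] != truth[ok]), 0.01)

  # theta exactly midway between two equal clusters is uncallable
  mid <- list(marker_id = "m", k = 2L, centers = c(0, 0.5),
              sds = c(0.05, 0.05), weights = c(0.5, 0.5), flag = NULL)
  cls <- list(marker_id = "m", klass = "SNP", qc_flags = character(),
              msv3_offset = NA_integer_)
  out <- call_genotypes(mid, cls, c(s1 = 0.25))
  expect_true(is.na(out$dosage))

  out0 <- call_genotypes(mid, cls, c(s1 = 0))
  expect_equal(out0$dosage, 0L)
  expect_gt(out0$posterior, 0.99)

  expect_error(call_genotypes(mod, list(marker_id = "m", klass = "FAIL"),
                              c(s1 = 0.1)), "FAIL")
})

test_that("SNP/MSV-3 confusion at sd 0.03 stays below 5%", {
  set.seed(31)
  n_mark <- 250L
  confusions <- 0L
  for (i in seq_len(n_mark)) {
    truth <- if (i %% 2 == 0) "SNP" else "MSV3"
    centers <- if (truth == "SNP") c(0, .5, 1) else c(0, .25, .5)
    got <- classify_marker(fit_clusters(h_theta(centers, 60, 0.03)))$klass
    if ((truth == "SNP" && got == "MSV3") ||
        (truth == "MSV3" && got == "SNP")) confusions <- confusions + 1L
  }
  expect_lt(confusions / n_mark, 0.05)
})

test_that("QC filtering applies call-rate and Mendelian thresholds", {
  ped <- sample_pedigree(list(n_sires = 1L, dams_per_sire = 1L,
                              offspring_per_dam = 10L))
  ids <- ped$id
  mk_calls <- function(marker, dosages) {
    data.frame(marker_id = marker, sample_id = ids, dosage = dosages,
               posterior = 1)
  }
  cls <- data.frame(marker_id = c("all_missing", "clean", "mendel_bad"),
                    klass = "SNP", msv3_offset = NA_integer_, qc_flags = "")
  clean <- c(2L, 0L, rep(1L, 10))          # sire BB x dam AA -> all AB
  bad <- c(2L, 0L, rep(c(0L, 1L), 5))      # half the offspring impossible
  calls <- rbind(mk_calls("all_missing", NA_integer_),
                 mk_calls("clean", clean),
                 mk_calls("mendel_bad", bad))
  qc <- qc_filter(calls, ped, cls)
  rep_ <- qc$report
  expect_false(rep_$pass[rep_$marker_id == "all_missing"])
  expect_equal(rep_$call_rate[rep_$marker_id == "all_missing"], 0)
  expect_true(rep_$pass[rep_$marker_id == "clean"])
  expect_false(rep_$pass[rep_$marker_id == "mendel_bad"])
  expect_equal(rep_$mendel_rate[rep_$marker_id == "mendel_bad"], 0.5)

  expect_error(qc_filter(data.frame(marker_id = "m", sample_id = "ghost",
                                    dosage = 1L, posterior = 1), ped, cls),
               "ghost")
})

test_that("one Mendelian error in 200 trios passes the threshold", {
  ped <- sample_pedigree(list(n_sires = 10L, dams_per_sire = 2L,
                              offspring_per_dam = 10L))
  off <- ped[ped$sire != "0", ]
  d <- setNames(rep(1L, nrow(ped)), ped$id)
  d[unique(off$sire)] <- 2L; d[unique(off$dam)] <- 0L
  d[off$id[1]] <- 0L  # single opposing transmission
  calls <- data.frame(marker_id = "m", sample_id = names(d), dosage = d,
                      posterior = 1)
  cls <- data.frame(marker_id = "m", klass = "SNP",
                    msv3_offset = NA_integer_, qc_flags = "")
  qc <- qc_filter(calls, ped, cls)
  expect_equal(qc$report$mendel_rate, 1 / 200)
  expect_true(qc$report$pass)
})

test_that("pedigree check flags a swapped sire but not true parents", {
  cfg <- sim_config(chromosomes = data.frame(id = "c1", female_length = 100,
                                             male_length = 100),
                    homeolog_pairs = data.frame(arm_a = character(),
                                                arm_b = character(),
                                                divergence = numeric()),
                    msv_fraction = 0, mono_fraction = 0, n_markers = 80L,
                    error_rate = 0.005, missing_rate = 0,
                    n_sires = 4L, dams_per_sire = 1L, offspring_per_dam = 10L)
  sim <- simulate_dataset(cfg, 17L)
  calls <- h_calls(sim, observed = TRUE)
  cls <- h_classifications(sim)
  ped <- sim$pedigree
  res0 <- check_pedigree(calls, ped, cls)
  off <- ped[ped$sire != "0", ]
  # swap one offspring's sire to an unrelated one
  victim <- off$id[1]
  wrong <- setdiff(unique(off$sire), off$sire[1])[1]
  ped2 <- ped
  ped2$sire[ped2$id == victim] <- wrong
  res1 <- check_pedigree(calls, ped2, cls)
  expect_true(any(res1$flagged[res1$offspring == victim &
                                 res1$parent == wrong]))
  expect_false(any(res0$flagged[res0$offspring == victim]))

  empty <- check_pedigree(calls, ped[ped$sire == "0", ], cls)
  expect_equal(nrow(empty), 0L)
})

test_that("MSV-5 resolution recovers parental configurations", {
  d <- setNames(c(2L, 0L, rep(1L, 20)), c("S", "D", paste0("O", 1:20)))
  r <- resolve_msv5(d, "S", "D", paste0("O", 1:20))
  expect_equal(r$status, "ok")
  best <- r$configs[which.max(r$configs$log10_lik), ]
  # sire homozygous B at exactly one locus; AB/AB alternative is
  # 20*log10(2) worse
  expect_equal(sort(c(best$sire_locus1, best$sire_locus2)), c(0, 2))
  alt <- r$configs$log10_lik[r$configs$sire_locus1 == 1]
  expect_equal(max(r$configs$log10_lik) - alt, 20 * log10(2),
               tolerance = 1e-9)
  expect_equal(unname(r$locus1[["S"]] + r$locus2[["S"]]), 2L)
  expect_equal(unname(r$locus1[["O1"]] + r$locus2[["O1"]]), 1L)

  d0 <- setNames(rep(0L, 8), c("S", "D", paste0("O", 1:6)))
  r0 <- resolve_msv5(d0, "S", "D", paste0("O", 1:6))
  expect_true(all(r0$locus1 == 0L & r0$locus2 == 0L))

  d4 <- setNames(rep(4L, 8), c("S", "D", paste0("O", 1:6)))
  r4 <- resolve_msv5(d4, "S", "D", paste0("O", 1:6))
  expect_true(all(r4$locus1 == 2L & r4$locus2 == 2L))

  # impossible segregation
  dbad <- setNames(c(0L, 0L, rep(3L, 6)), c("S", "D", paste0("O", 1:6)))
  rbad <- resolve_msv5(dbad, "S", "D", paste0("O", 1:6))
  expect_equal(rbad$status, "segregation_fail")
})

test_that("resolved locus genotypes always conserve the called dosage", {
  set.seed(55)
  for (rep in 1:20) {
    ds <- sample(0:4, 1); dd <- sample(0:4, 1)
    # draw offspring from a random true configuration
    sp <- tetramap:::.dosage_splits(ds); sp <- sp[sample(nrow(sp), 1), ]
    dp <- tetramap:::.dosage_splits(dd); dp <- dp[sample(nrow(dp), 1), ]
    kid <- function() {
      l1 <- rbinom(1, 1, sp[1] / 2) + rbinom(1, 1, dp[1] / 2)
      l2 <- rbinom(1, 1, sp[2] / 2) + rbinom(1, 1, dp[2] / 2)
      l1 + l2
    }
    d <- setNames(c(ds, dd, replicate(12, kid())),
                  c("S", "D", paste0("O", 1:12)))
    r <- resolve_msv5(d, "S", "D", paste0("O", 1:12))
    if (r$status != "ok") next
    both <- !is.na(r$locus1) & !is.na(r$locus2)
    expect_true(all((r$locus1 + r$locus2)[both] == d[names(r$locus1)][both]))
  }
})

test_that("MSV summaries aggregate per chromosome and genome-wide", {
  cls <- data.frame(marker_id = paste0("m", 1:10),
                    klass = c(rep("SNP", 5), rep("MSV3", 2), rep("MSV5", 3)),
                    msv3_offset = NA_integer_, qc_flags = "")
  chrom <- setNames(rep(c("c1", "c2"), each = 5), cls$marker_id)
  ms <- msv_summary(cls, chrom)
  expect_equal(ms$pct_msv[ms$chromosome == "ALL"], 50)
  expect_equal(ms$pct_msv[ms$chromosome == "c2"], 100)
  expect_equal(ms$pct_msv[ms$chromosome == "c1"], 0)

  all_snp <- msv_summary(data.frame(marker_id = names(chrom), klass = "SNP"),
                         chrom)
  expect_true(all(all_snp$pct_msv == 0))
})
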