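test_that("mapping functions match closed forms and round-trip", {
  expect_equal(rf_to_cM(0.25, "kosambi"), 25 * log(3), tolerance = 1e-12)
  expect_equal(rf_to_cM(0, "kosambi"), 0)
  d <- seq(0, 100, by = 0.5)
  for (fn in c("kosambi", "haldane")) {
    expect_equal(rf_to_cM(cM_to_rf(d, fn), fn), d, tolerance = 1e-9,
                 label = fn)
  }
})

test_that("build_order recovers the truth and agrees with brute force", {
  # 5 markers at 0/10/20/30/40 cM, 500 female meioses
  h <- h_testcross(61, n_markers = 5L, length_cM = 50, n_families = 25L,
                   offspring = 20L)
  ids <- h$sim$markers$id  # ids are in map order by construction
  bo <- build_order(h$grid, sample(ids))
  expect_equal(nrow(bo$unplaced), 0L)
  expect_same_order(bo$order, ids)

  # brute-force oracle: maximize the same adjacency criterion over all
  # 60 distinct orders
  fem <- h$grid$meioses$parent_sex == "F"
  fgrid <- structure(list(cells = h$grid$cells[fem, , drop = FALSE],
                          conditional = h$grid$conditional[fem, ,
                                                           drop = FALSE],
                          meioses = h$grid$meioses[fem, , drop = FALSE]),
                     class = "tm_grid")
  tp <- tetramap:::.tp_cache(fgrid)
  perms <- tetramap:::.perms(5L)
  scores <- vapply(perms, function(p)
    tetramap:::.order_score(ids[p], tp, "female"), 0)
  best <- ids[perms[[which.max(scores)]]]
  expect_same_order(bo$order, best)
})

test_that("20-marker order is recovered up to reversal at 500 meioses", {
  h <- h_testcross(62, n_markers = 20L, length_cM = 100, n_families = 25L,
                   offspring = 20L)
  ids <- h$sim$markers$id
  bo <- build_order(h$grid, sample(ids))
  ord <- improve_order(bo$order, h$grid)
  expect_equal(length(ord), 20L)
  expect_same_order(ord, ids)
})

test_that("degenerate order inputs are handled", {
  h <- h_testcross(63, n_markers = 2L, n_families = 5L, offspring = 10L)
  bo <- build_order(h$grid, h$sim$markers$id)
  expect_equal(sort(bo$order), sort(h$sim$markers$id))

  # duplicated column: one of the twins stays unplaced (tie)
  g <- h_testcross(64, n_markers = 6L, n_families = 10L, offspring = 10L)
  cells <- cbind(g$grid$cells, DUP = g$grid$cells[, "M00003"])
  cond <- cbind(g$grid$conditional, DUP = g$grid$conditional[, "M00003"])
  grid2 <- structure(list(cells = cells, conditional = cond,
                          meioses = g$grid$meioses), class = "tm_grid")
  bo2 <- build_order(grid2, colnames(cells))
  expect_true("DUP" %in% bo2$unplaced$marker ||
                "M00003" %in% bo2$unplaced$marker)
})

test_that("window refinement fixes a local swap and leaves optima alone", {
  h <- h_testcross(65, n_markers = 8L, length_cM = 80, n_families = 25L,
                   offspring = 20L)
  ids <- h$sim$markers$id
  swapped <- ids; swapped[4:5] <- swapped[5:4]
  expect_equal(improve_order(swapped, h$grid), ids)
  expect_equal(improve_order(ids, h$grid), ids)
  # window 2 on a reversed 3-marker order reaches an optimum
  expect_same_order(improve_order(rev(ids[1:3]), h$grid, window = 2L),
                    ids[1:3])
})

test_that("phase strings carry crossovers and handle uninformative cells", {
  h <- h_testcross(66, n_markers = 10L, length_cM = 60, n_families = 10L,
                   offspring = 15L)
  sim <- h$sim
  ph <- phase_strings(sim$markers$id, h$grid, sex = "F")
  u <- sim$markers$u
  # per-meiosis switch count equals the parity-relevant crossover count
  for (i in seq_len(nrow(ph$symbols))) {
    off <- ph$meioses$offspring[i]
    xo <- sim$crossovers[[off]][["dam"]][["c1"]]
    # crossovers between adjacent marker midpoints flip origin parity
    true_switches <- sum(vapply(seq_len(length(u) - 1L), function(j)
      sum(xo > u[j] & xo <= u[j + 1L]) %% 2L, 0L))
    expect_equal(tetramap:::.phase_switch_count(ph$symbols[i, ]),
                 true_switches)
  }
  # strings are over {0,1,-} with full informativeness here
  expect_true(all(nchar(ph$strings) == 10L))

  # all-uninformative column: male meioses in a female testcross
  phm <- phase_strings(sim$markers$id, h$grid, sex = "M")
  expect_true(all(grepl("^-+$", phm$strings)))
})

test_that("isolated phase islands are blanked, runs are kept", {
  # hand-built grid: one dam, 7 markers, 5 meioses
  mk <- paste0("m", 1:7)
  base <- rep(0L, 7)
  cells <- rbind(base, base, base, base, base)
  cells[1, 4] <- 1L              # isolated island -> error
  cells[2, 4:6] <- 1L            # genuine run -> keep
  rownames(cells) <- paste0("D1:o", 1:5)
  colnames(cells) <- mk
  meio <- data.frame(id = rownames(cells), parent = "D1",
                     offspring = paste0("o", 1:5), family = "F1",
                     parent_sex = "F")
  grid <- structure(list(cells = cells,
                         conditional = matrix(FALSE, 5, 7,
                                              dimnames = dimnames(cells)),
                         meioses = meio), class = "tm_grid")
  map <- data.frame(marker = mk, pos_female = seq(0, 12, by = 2),
                    pos_male = seq(0, 12, by = 2))
  calls <- data.frame(marker_id = rep(mk, each = 5),
                      sample_id = rep(paste0("o", 1:5), 7),
                      dosage = 1L, posterior = 1)
  cd <- correct_double_recombinants(mk, grid, map, calls)
  expect_equal(nrow(cd$changes), 1L)
  expect_equal(cd$changes$marker, "m4")
  expect_equal(cd$changes$sample, "o1")
  expect_true(is.na(cd$calls$dosage[cd$calls$marker_id == "m4" &
                                      cd$calls$sample_id == "o1"]))
  # the genuine run is untouched
  expect_equal(cd$grid$cells[2, 5], 1L)
  # far-apart flanks (span > max_span_cM) are not corrected
  map_wide <- map; map_wide$pos_female <- seq(0, 120, by = 20)
  map_wide$pos_male <- map_wide$pos_female
  cd2 <- correct_double_recombinants(mk, grid, map_wide, calls)
  expect_equal(nrow(cd2$changes), 0L)
})

test_that("correction brings the female map closer to truth at 1% error", {
  improved <- 0L
  inflations <- numeric(); residuals <- numeric()
  for (seed in 1:10) {
    h <- h_testcross(100 + seed, n_markers = 25L, length_cM = 100,
                     n_families = 15L, offspring = 20L, error_rate = 0.01)
    ord <- h$sim$markers$id
    map0 <- estimate_sex_maps(ord, h$grid, mapfn = "haldane")
    cd <- correct_double_recombinants(ord, h$grid, map0, h$calls)
    map1 <- estimate_sex_maps(ord, cd$grid, mapfn = "haldane")
    truth <- diff(range(h$sim$markers$pos_female))
    e0 <- abs(max(map0$pos_female) - truth)
    e1 <- abs(max(map1$pos_female) - truth)
    if (e1 < e0) improved <- improved + 1L
    inflations <- c(inflations, max(map0$pos_female) - truth)
    residuals <- c(residuals, max(map1$pos_female) - truth)
  }
  expect_gte(improved, 9L)
  # correction recovers at least half the inflation (median over reps)
  expect_gte(median(inflations - residuals), median(inflations) / 2)
})

test_that("map-length error grows with uncorrected genotyping error", {
  errs <- c(0, 0.01, 0.03)
  lens <- vapply(seq_along(errs), function(i) {
    h <- h_testcross(200 + i, n_markers = 25L, length_cM = 100,
                     n_families = 15L, offspring = 20L,
                     error_rate = errs[i])
    map <- estimate_sex_maps(h$sim$markers$id, h$grid, mapfn = "haldane")
    max(map$pos_female)
  }, 0)
  truth <- 100 * (24 / 25)
  devs <- abs(lens - truth)
  expect_true(devs[1] < devs[2] && devs[2] < devs[3])
})

test_that("sex map estimation matches closed forms and recovers truth", {
  # interval closed forms
  h <- h_testcross(70, n_markers = 20L, length_cM = 100, n_families = 40L,
                   offspring = 50L)
  map <- estimate_sex_maps(h$sim$markers$id, h$grid, mapfn = "haldane")
  expect_equal(map$pos_female[1], 0)
  expect_true(all(diff(map$pos_female) >= 0))
  truth <- diff(range(h$sim$markers$pos_female))
  expect_lt(abs(max(map$pos_female) - truth) / truth, 0.1)
  # additivity: total equals sum of interval lengths
  expect_equal(max(map$pos_female), sum(diff(map$pos_female)),
               tolerance = 1e-9)
  # male side of a female testcross has no information: imputed flat 0
  expect_equal(max(map$pos_male), 0)
  expect_gt(length(attr(map, "imputed_intervals")), 0L)
})

test_that("map summaries reproduce the published-table arithmetic", {
  t1 <- table1_fixture()
  ms <- summarize_maps(data.frame(chromosome = t1$chromosome,
                                  n_markers = t1$n_snps,
                                  female_length = t1$female_cM,
                                  male_length = t1$male_cM))
  tot <- ms[ms$chromosome == "Total", ]
  expect_equal(tot$n_markers, 5650L)
  expect_equal(tot$female_length, 2403)
  expect_equal(tot$male_length, 1752.9)
  expect_equal(tot$ratio, 1.37)
  expect_equal(max(ms$ratio[ms$chromosome != "Total"]), 7.39)

  eq <- summarize_maps(data.frame(chromosome = "c", n_markers = 5L,
                                  female_length = 50, male_length = 50))
  expect_equal(eq$ratio[1], 1.00)
})

test_that("male crossovers localize to the configured telomere end", {
  h <- h_testcross(71, n_markers = 20L, length_cM = 100, male_length = 70,
                   n_families = 20L, offspring = 25L, sex = "male",
                   uniform_weight = 0.2,
                   male_telomere_weights = c(1, 0))
  map <- data.frame(marker = h$sim$markers$id,
                    pos_female = h$sim$markers$pos_female -
                      min(h$sim$markers$pos_female),
                    pos_male = h$sim$markers$pos_male)
  loc <- recombination_localization(map, h$grid, sex = "M")
  expect_equal(loc$n_flagged, 1L)
  expect_true(loc$ends$flagged[loc$ends$end == "left"])

  # uniform male density: no flagged ends
  hu <- h_testcross(72, n_markers = 20L, length_cM = 100, male_length = 70,
                    n_families = 20L, offspring = 25L, sex = "male",
                    uniform_weight = 1)
  mapu <- data.frame(marker = hu$sim$markers$id,
                     pos_female = hu$sim$markers$pos_female -
                       min(hu$sim$markers$pos_female),
                     pos_male = hu$sim$markers$pos_male)
  locu <- recombination_localization(mapu, hu$grid, sex = "M")
  expect_equal(locu$n_flagged, 0L)
  expect_lt(abs(locu$ends$fraction[1] - 0.2), 0.1)
})
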