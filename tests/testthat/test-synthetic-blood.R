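test_that("default profile frequencies match the reported blood composition", {
  prof <- build_default_profile(seed = 1)
  f <- population_frequencies(prof)
  expect_equal(sum(f), 1, tolerance = 1e-9)
  expect_true(all(f >= 0 & f <= 1))
  nk <- f[c("NK1", "NK2", "NK3")]
  expect_gte(nk[["NK1"]] / sum(nk), 0.85)
  expect_lte(nk[["NK1"]] / sum(nk), 0.95)
  mo <- f[c("Mo1", "Mo2", "Mo3", "Mo4")]
  expect_gte(mo[["Mo1"]] / sum(mo), 0.80)
  expect_lte(mo[["Mo1"]] / sum(mo), 0.90)
  # major-type composition
  majors <- true_major_fractions(prof)
  expect_true(majors[["T"]] >= 0.20 && majors[["T"]] <= 0.30)
  expect_equal(majors[["B"]], 0.05, tolerance = 0.01)
  expect_true(majors[["NK"]] >= 0.03 && majors[["NK"]] <= 0.05)
  expect_true(majors[["Mo"]] >= 0.07 && majors[["Mo"]] <= 0.10)
  expect_lt(prof$dead_fraction, 0.01)
})

test_that("every panel marker is templated; unknown markers error", {
  prof <- build_default_profile()
  for (schema in diob_schemas[paste0("P", sprintf("%02d", 1:11))]) {
    expect_true(all(unname(schema$channels) %in%
                      immunogate:::known_markers(prof)))
  }
  fake <- diob_schemas$P03
  fake$channels[["FL2"]] <- "CD999"
  expect_error(simulate_panel_acquisition(prof, fake, 100, seed = 1),
               "configuration error.*CD999")
})

test_that("seeded simulations are bit-reproducible and panel-independent", {
  prof <- build_default_profile()
  a <- simulate_panel_acquisition(prof, diob_schemas$P05, 5000, seed = 3)
  b <- simulate_panel_acquisition(prof, diob_schemas$P05, 5000, seed = 3)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(event_truth(a), event_truth(b))
  # interleaving another panel's simulation does not perturb the stream
  invisible(simulate_panel_acquisition(prof, diob_schemas$P08, 1000, seed = 3))
  c_ <- simulate_panel_acquisition(prof, diob_schemas$P05, 5000, seed = 3)
  expect_identical(as.data.frame(a), as.data.frame(c_))
})

test_that("hidden labels partition events and converge to profile frequencies", {
  prof <- build_default_profile()
  tab <- simulate_panel_acquisition(prof, diob_schemas$P01, 100000, seed = 1)
  tr <- event_truth(tab)
  cells <- tr$artifact == "cell"
  expect_true(all(!is.na(tr$label[cells])))
  expect_true(all(is.na(tr$label[tr$artifact %in% c("debris", "doublet")])))
  f <- population_frequencies(prof)
  n <- sum(cells)
  counts <- table(factor(tr$label[cells], levels = names(f)))
  for (nm in names(f)) {
    sigma <- sqrt(n * f[[nm]] * (1 - f[[nm]]))
    expect_lte(abs(counts[[nm]] - n * f[[nm]]), 3 * sigma + 1e-9,
               label = sprintf("population %s count", nm))
  }
})

test_that("dead (reduced-FSC) events stay below one percent by default", {
  tab <- simulate_panel_acquisition(build_default_profile(),
                                    diob_schemas$P01, 100000, seed = 1)
  tr <- event_truth(tab)
  expect_lt(mean(tr$dead[tr$artifact == "cell"]), 0.01)
})

test_that("compensating a zero-spread simulation recovers template locations", {
  prof <- zero_noise_profile(keep_spillover = TRUE)
  tab <- simulate_panel_acquisition(prof, diob_schemas$P08, 2000, seed = 5)
  out <- compensate(tab, attr(tab, "spillover"))
  tr <- event_truth(out)
  loc <- prof$template$locations
  mo1 <- which(tr$label == "Mo1")
  expect_gt(length(mo1), 0)
  # Mo1 is CD14 hi / CD16 neg; FL1 = CD14, FL2 = CD16
  expect_lt(max(abs(out$FL1[mo1] - loc[["hi"]]) / loc[["hi"]]), 1e-6)
  expect_lt(max(abs(out$FL2[mo1] - loc[["neg"]]) / loc[["neg"]]), 1e-6)
})

test_that("acquiring the whole tube recovers the bead count exactly at zero doublets", {
  prof <- build_default_profile()
  cfg <- bead_config(beads_per_tube = 2000, doublet_rate = 0)
  tab <- simulate_trucount_acquisition(prof, cfg, acquired_fraction = 1,
                                       seed = 4)
  tr <- event_truth(tab)
  expect_equal(sum(tr$artifact == "bead"), 2000)
  expect_equal(sum(tr$artifact == "bead_doublet"), 0)
})

test_that("bead doublet bookkeeping conserves beads at the configured rate", {
  cfg <- bead_config(beads_per_tube = 10000, doublet_rate = 0.02)
  tab <- simulate_trucount_acquisition(build_default_profile(), cfg,
                                       acquired_fraction = 0.5, seed = 5)
  tr <- event_truth(tab)
  ns <- sum(tr$artifact == "bead")
  nd <- sum(tr$artifact == "bead_doublet")
  expect_equal(ns + 2 * nd, 5000)            # beads conserved
  expect_equal(nd / (ns + nd), 0.02, tolerance = 0.002)
})

test_that("the simulator records the true absolute counts of the profile", {
  prof <- build_default_profile(leukocytes_per_ul = 5500)
  tab <- simulate_trucount_acquisition(prof, bead_config(),
                                       acquired_fraction = 0.05, seed = 6)
  ta <- attr(tab, "true_abs")
  expect_equal(ta[["Leu"]], 5500)
  expect_equal(ta[["T"]], true_major_fractions(prof)[["T"]] * 5500)
})
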