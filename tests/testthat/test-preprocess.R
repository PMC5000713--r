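test_that("identity spillover leaves the table unchanged", {
  tab <- toy_table(data.frame(FL1 = c(10, 20), FL2 = c(5, 1)))
  out <- compensate(tab, identity_spillover(c("FL1", "FL2")))
  expect_equal(out$FL1, tab$FL1)
  expect_equal(out$FL2, tab$FL2)
})

test_that("compensation inverts a known spillover exactly", {
  true <- matrix(c(1000, 50, 2, 800, 30000, 4, 7, 7, 7), ncol = 3,
                 byrow = FALSE)
  sp <- spillover_matrix(matrix(c(1, 0.2, 0, 0.1, 1, 0, 0, 0, 1), 3, 3,
                                byrow = TRUE,
                                dimnames = list(paste0("FL", 1:3),
                                                paste0("FL", 1:3))))
  observed <- true %*% unclass(sp)
  tab <- toy_table(stats::setNames(as.data.frame(observed), paste0("FL", 1:3)))
  out <- compensate(tab, sp)
  expect_lt(max(abs(as.matrix(out[, paste0("FL", 1:3)]) - true)), 1e-9)
})

test_that("a singular spillover matrix is rejected", {
  m <- matrix(c(1, 1, 1, 1), 2, 2,
              dimnames = list(c("FL1", "FL2"), c("FL1", "FL2")))
  expect_error(spillover_matrix(m), "singular")
  fake <- structure(m, class = c("spillover_matrix", "matrix", "array"))
  tab <- toy_table(data.frame(FL1 = 1, FL2 = 2))
  expect_error(compensate(tab, fake), "singular")
})

test_that("flow gate keeps a uniform stream and excises a rate burst", {
  prof <- build_default_profile()
  tab <- simulate_panel_acquisition(prof, diob_schemas$P01, 30000, seed = 2)
  expect_gte(mean(flow_gate(tab)), 0.999)

  prof_b <- with_burst(prof, start = 40, duration = 2, rate = 5)
  tab_b <- simulate_panel_acquisition(prof_b, diob_schemas$P01, 50000, seed = 2)
  fg <- flow_gate(tab_b)
  in_burst <- tab_b$TIME >= 40 & tab_b$TIME < 42
  expect_lt(mean(fg[in_burst]), 0.05)
  expect_gte(mean(fg[!in_burst]), 0.99)
})

test_that("flow gate edge cases: empty table, short acquisition", {
  empty <- toy_table(data.frame(FL1 = numeric()))
  expect_identical(flow_gate(empty), logical(0))
  short <- toy_table(data.frame(FL1 = stats::runif(10)))
  short$TIME <- seq(0, 0.5, length.out = 10)
  expect_warning(mask <- flow_gate(short), "shorter than one flow window")
  expect_true(all(mask))
})

test_that("singlet gate keeps singlets and removes constructed doublets", {
  prof <- build_default_profile(doublet_fraction = 0.05)
  tab <- simulate_panel_acquisition(prof, diob_schemas$P01, 40000, seed = 6)
  tr <- event_truth(tab)
  sg <- singlet_gate(tab)
  singlets <- tr$artifact == "cell"
  doublets <- tr$artifact == "doublet"
  expect_gte(mean(sg[singlets]), 0.99)
  expect_gte(mean(!sg[doublets]), 0.95)
  expect_identical(singlet_gate(toy_table(data.frame(FL1 = numeric()))),
                   logical(0))
})

test_that("All Cells gate excludes debris and dying cells at the set rates", {
  prof <- build_default_profile(debris_fraction = 0.02, dead_fraction = 0.005)
  tab <- simulate_panel_acquisition(prof, diob_schemas$P01, 60000, seed = 3)
  ac <- all_cells_gate(tab)
  excluded <- 100 * mean(!ac$mask)
  expect_lt(abs(excluded - 2.5), 0.5)
  # the classification separates the two exclusion reasons; a small tail of
  # dying granulocytes stays above the FSC bound and is kept, as intended
  tr <- event_truth(tab)
  expect_gte(mean(ac$class[tr$artifact == "debris"] == "debris"), 0.99)
  expect_gte(mean(ac$class[which(tr$dead)] == "lowfsc"), 0.90)
})

test_that("a zero-artifact simulation retains every leukocyte", {
  prof <- zero_noise_profile()
  tab <- simulate_panel_acquisition(prof, diob_schemas$P01, 5000, seed = 4)
  ac <- all_cells_gate(tab)
  expect_true(all(ac$mask))
})

test_that("the scatter-shifted counting tube keeps leukocytes with scaled bounds", {
  prof <- build_default_profile()
  tab <- simulate_trucount_acquisition(prof, bead_config(),
                                       acquired_fraction = 0.05, seed = 8)
  ac <- all_cells_gate(tab, qc_config(fsc_scale = 1.15))
  tr <- event_truth(tab)
  live_cells <- tr$artifact == "cell" & !tr$dead
  expect_gte(mean(ac$mask[live_cells]), 0.99)
})

test_that("QC masks compose monotonically", {
  tab <- simulate_panel_acquisition(build_default_profile(),
                                    diob_schemas$P04, 20000, seed = 5)
  qc <- qc_gates(tab)
  expect_lte(sum(qc$mask), sum(qc$flow & qc$singlet))
  expect_lte(sum(qc$flow & qc$singlet), sum(qc$flow))
  expect_lte(sum(qc$flow), nrow(tab))
})
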