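# hand-built bead acquisitions with exact singlet/doublet/positivity layout
bead_table <- function(per_channel, fsc_singlet = 50000, fsc_doublet = 100000) {
  channels <- names(per_channel)
  n_dbl_max <- max(vapply(per_channel, `[[`, 0, "doublets"))
  n_sgl_max <- max(vapply(per_channel, `[[`, 0, "singlets"))
  n <- n_sgl_max + n_dbl_max
  fsc <- c(rep(fsc_singlet, n_sgl_max), rep(fsc_doublet, n_dbl_max))
  vals <- as.data.frame(lapply(per_channel, function(sd) {
    c(rep(200000, sd$singlets), rep(50, n_sgl_max - sd$singlets),
      rep(200000, sd$doublets), rep(50, n_dbl_max - sd$doublets))
  }))
  names(vals) <- channels
  df <- cbind(data.frame(TIME = seq_len(n) / 100, `FSC-INT` = fsc,
                         `FSC-TOF` = 60, `FSC-PEAK` = fsc, SSC = 400000,
                         check.names = FALSE), vals)
  event_table(df)
}

test_that("doublets are added twice and the five channels averaged", {
  pc <- list(FL1 = list(singlets = 970, doublets = 15),
             FL2 = list(singlets = 970, doublets = 15),
             FL3 = list(singlets = 970, doublets = 15),
             FL4 = list(singlets = 970, doublets = 15),
             FL8 = list(singlets = 970, doublets = 15))
  res <- count_beads(bead_table(pc))
  expect_true(all(res$per_channel$effective == 1000))
  expect_equal(res$mean_effective, 1000)
})

test_that("unequal channel splits still average to the common bead count", {
  sd_list <- list(c(1000, 0), c(998, 1), c(996, 2), c(994, 3), c(992, 4))
  pc <- stats::setNames(lapply(sd_list, function(x)
    list(singlets = x[1], doublets = x[2])),
    c("FL1", "FL2", "FL3", "FL4", "FL8"))
  res <- count_beads(bead_table(pc))
  expect_true(all(res$per_channel$effective == 1000))
  expect_equal(res$mean_effective, 1000)
})

test_that("simulated bead counting recovers the acquired bead number", {
  prof <- build_default_profile()
  cfg <- bead_config(beads_per_tube = 10000, doublet_rate = 0.02)
  tab <- simulate_trucount_acquisition(prof, cfg, acquired_fraction = 1,
                                       seed = 5)
  tab <- compensate(tab, attr(tab, "spillover"))
  res <- count_beads(tab, flow_mask = flow_gate(tab))
  expect_lt(abs(res$mean_effective - 10000) / 10000, 0.01)
  expect_gt(res$singlet_fraction, 97)
})

test_that("doublet correction removes the undercount across doublet rates", {
  prof <- build_default_profile()
  for (d in c(0, 0.01, 0.03)) {
    cfg <- bead_config(beads_per_tube = 10000, doublet_rate = d)
    tab <- simulate_trucount_acquisition(prof, cfg, acquired_fraction = 0.5,
                                         seed = 7)
    res <- count_beads(compensate(tab, attr(tab, "spillover")))
    uncorrected <- mean(res$per_channel$singlets + res$per_channel$doublets)
    expect_lt(abs(res$mean_effective - 5000) / 5000, 0.01,
              label = sprintf("corrected count at doublet rate %.2f", d))
    # uncorrected event counting underestimates by about the doublet rate
    expect_equal(uncorrected / 5000, 1 - d / (1 + d), tolerance = 0.005)
  }
})

test_that("an acquisition without beads in the gate refuses to count", {
  tab <- toy_table(data.frame(FL1 = rep(200000, 100)))  # cell-like scatter
  expect_error(count_beads(tab), "Beads gate")
})

test_that("the absolute-count formula is exact arithmetic", {
  expect_equal(absolute_count(5000, 2500, 50000, 50), 2000)
  expect_equal(absolute_count(0, 2500, 50000, 50), 0)
  # ratio invariance: doubling cells and beads together changes nothing
  expect_equal(absolute_count(5000, 2500, 50000, 50),
               absolute_count(10000, 5000, 50000, 50))
  expect_error(absolute_count(10, 0, 50000, 50), "beads_acquired")
  expect_error(absolute_count(10, 10, 50000, 0), "blood_volume")
})

test_that("absolute counts are invariant to the acquired fraction", {
  prof <- build_default_profile()
  cfg <- bead_config(beads_per_tube = 10000, doublet_rate = 0.02)
  abs_at <- function(af, seed) {
    tab <- simulate_trucount_acquisition(prof, cfg, acquired_fraction = af,
                                         seed = seed)
    tab <- compensate(tab, attr(tab, "spillover"))
    st <- classify_p12_majors(tab, diob_schemas$P12)
    qc <- attr(st, "qc")
    beads <- count_beads(tab, flow_mask = qc$flow)
    absolute_count(st$n_events[st$node == "leu"], beads$mean_effective,
                   cfg$beads_per_tube, cfg$blood_volume_ul)
  }
  a <- abs_at(0.10, 41)
  b <- abs_at(0.30, 41)
  expect_lt(abs(a - b) / b, 0.05)
})

test_that("absolute counts transfer onto subsets through their majors", {
  stats <- data.frame(
    population = c("T cells", "TH", "DC"), node = c("t", "th", "dc"),
    parent = c("root", "t", "root"), major = c(NA, "t", NA),
    n_events = c(1500, 900, 10), pct_parent = c(30, 60, 0.2),
    pct_major = c(NA, 60, NA), pct_all = c(30, 18, 0.2),
    abs_per_ul = NA_real_, valid = TRUE, stringsAsFactors = FALSE)
  p12 <- c(Leu = 6000, T = 1500)
  out <- propagate_absolute(stats, anchors = c(t = "T"), p12)
  expect_equal(out$abs_per_ul[out$node == "th"], 900)
  expect_equal(out$abs_per_ul[out$node == "t"], 6000 * 30 / 100)
  expect_equal(out$abs_per_ul[out$node == "dc"], 6000 * 0.2 / 100)
  expect_error(propagate_absolute(stats, anchors = c(t = "NK"), p12),
               "missing absolute-count anchor")
  expect_error(propagate_absolute(stats, anchors = c(t = "T"), c(T = 1500)),
               "all-leukocyte")
})

test_that("anchored subsets of one major sum to at most the major's absolute", {
  run <- run_pipeline(run_config(panels = c("P08", "P12"), seed = 9,
                                 n_events = 20000))
  mo_abs <- run$absolute[["Mo"]]
  subsets <- run$populations[run$populations$panel == "P08" &
                               grepl("^Mo[1-4]", run$populations$population), ]
  expect_equal(nrow(subsets), 4)
  expect_lte(sum(subsets$abs_per_ul), mo_abs * (1 + 1e-9))
})
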