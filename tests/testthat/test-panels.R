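test_that("every monitored subset is a report-flagged node of its panel", {
  defs <- subset_definitions()
  for (i in seq_len(nrow(defs))) {
    schema <- diob_schemas[[defs$panel[i]]]
    node <- schema$tree$nodes[[defs$node[i]]]
    expect_false(is.null(node), label = paste("node for", defs$subset[i]))
    expect_true(node$report, label = paste("report flag for", defs$subset[i]))
  }
})

test_that("NK gates are linked with identical geometry across both NK panels", {
  for (id in c("nk", "nk1", "nk2", "nk3")) {
    a <- diob_schemas$P06$tree$nodes[[id]]
    b <- diob_schemas$P07$tree$nodes[[id]]
    expect_identical(a$link, b$link)
    expect_identical(a$gate, b$gate)
  }
  # and they produce identical masks on the same events
  prof <- build_default_profile()
  tab <- simulate_panel_acquisition(prof, diob_schemas$P06, 5000, seed = 30)
  tab <- compensate(tab, attr(tab, "spillover"))
  m1 <- eval_geometric_gate(tab, diob_schemas$P06$tree$nodes$nk$gate,
                            diob_schemas$P06$transforms)
  m2 <- eval_geometric_gate(tab, diob_schemas$P07$tree$nodes$nk$gate,
                            diob_schemas$P06$transforms)
  expect_identical(m1, m2)
})

test_that("Boolean gates match independent set-algebra computation", {
  out <- gate_panel(build_default_profile(), "P04", 20000, seed = 31)
  m <- out$masks
  manual_rest <- m$b & !(m$prenaive | m$naive | m$memory |
                           m$transitional | m$plasmablast)
  expect_identical(m$restb, manual_rest)

  out6 <- gate_panel(build_default_profile(), "P06", 20000, seed = 31)
  m6 <- out6$masks
  expect_identical(m6$nkt, m6$t & (m6$nkt56 | m6$nkt16 | m6$nkt314))
  expect_identical(out6$masks$tc, NULL)  # tc lives in P01 only
})

test_that("removing a panel shrinks the enumeration by exactly its entries", {
  full <- list_reported_populations(diob_schemas)
  drop11 <- list_reported_populations(diob_schemas[setdiff(names(diob_schemas),
                                                           "P11")])
  n11 <- sum(full$panel == "P11")
  expect_gt(n11, 0)
  expect_equal(nrow(drop11), nrow(full) - n11)
  expect_identical(drop11, full[full$panel != "P11", ],
                   ignore_attr = "row.names")
})

test_that("config missing a threshold errors naming marker and panel", {
  cfg <- diob_config(marker_cuts = list(CD14 = list(pos = NA)))
  expect_error(build_diob_schema(cfg), "CD14.*P08|P08.*CD14")
})

test_that("P12 sequential majors partition the CD45+ leukocytes", {
  prof <- build_default_profile()
  tab <- simulate_trucount_acquisition(prof, bead_config(),
                                       acquired_fraction = 0.2, seed = 32)
  tab <- compensate(tab, attr(tab, "spillover"))
  st <- classify_p12_majors(tab, diob_schemas$P12)
  n <- stats::setNames(st$n_events, st$node)
  expect_equal(n[["t12"]] + n[["b12"]] + n[["mo12"]] + n[["gr12"]] +
                 n[["nk12"]] + n[["rest4"]], n[["leu"]])
  # majors are mutually disjoint by construction of the exclusion chain
  m <- attr(st, "masks")
  overlap <- (m$t12 & m$b12) | (m$b12 & m$mo12) | (m$mo12 & m$gr12) |
    (m$gr12 & m$nk12) | (m$nk12 & m$rest4) | (m$t12 & m$nk12)
  expect_false(any(overlap))
})

test_that("zero-noise P12 classification reproduces the profile composition", {
  prof <- zero_noise_profile()
  tab <- simulate_trucount_acquisition(prof, bead_config(doublet_rate = 0),
                                       acquired_fraction = 0.1, seed = 33)
  st <- classify_p12_majors(tab, diob_schemas$P12)
  n <- stats::setNames(st$n_events, st$node)
  tr <- event_truth(tab)
  majors <- vapply(prof$populations, `[[`, "", "major")
  lab <- tr$label[tr$artifact == "cell"]
  expect_identical(n[["t12"]], sum(majors[lab] == "T"))
  expect_identical(n[["b12"]], sum(majors[lab] == "B"))
  expect_identical(n[["mo12"]], sum(majors[lab] == "Mo"))
  expect_identical(n[["gr12"]], sum(majors[lab] == "Gr"))
  expect_identical(n[["nk12"]], sum(majors[lab] == "NK"))
  f <- true_major_fractions(prof)
  expect_equal(n[["t12"]] / n[["leu"]], f[["T"]], tolerance = 0.01)
})

test_that("the granulocyte CD16 split separates neutrophils from eosinophils", {
  prof <- zero_noise_profile()
  tab <- simulate_trucount_acquisition(prof, bead_config(doublet_rate = 0),
                                       acquired_fraction = 0.1, seed = 34)
  st <- classify_p12_majors(tab, diob_schemas$P12)
  m <- attr(st, "masks")
  tr <- event_truth(tab)
  neu <- !is.na(tr$label) & tr$label == "Neu"
  eos <- !is.na(tr$label) & tr$label == "Eos"
  expect_true(all(m$neu12[neu & m$gr12]))
  expect_false(any(m$neu12[eos]))
  expect_true(all(m$eos12[eos & m$gr12]))
})

test_that("activation readouts enumerate the configured determinations", {
  ar <- activation_readouts()
  expect_identical(sort(unique(ar$panel)),
                   c("P01", "P03", "P05", "P06", "P07", "P08", "P09", "P10"))
  expect_equal(sum(ar$panel == "P05"), 11)  # six on T, five on B
  expect_equal(sum(ar$cell_type == "Mo"), 4)
})
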