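test_that("a rectangle covering the whole display space selects all events", {
  set.seed(1)
  tab <- toy_table(data.frame(FL1 = stats::runif(200, 0, 1e6),
                              FL2 = stats::runif(200, 0, 1e6)))
  tr <- list(FL1 = diob_lp, FL2 = diob_lp)
  g <- gate_rectangle("FL1", "FL2", c(-1, 2), c(-1, 2))
  expect_true(all(eval_geometric_gate(tab, g, tr)))
})

test_that("threshold gates equal a direct per-event comparison", {
  set.seed(2)
  tab <- toy_table(data.frame(FL1 = stats::runif(500, -100, 1e6)))
  tr <- list(FL1 = diob_lp)
  g <- gate_threshold("FL1", lo = 0.5)
  expect_identical(eval_geometric_gate(tab, g, tr),
                   to_logicle(tab$FL1, diob_lp) >= 0.5)
})

test_that("the four quadrant cells partition their parent exactly", {
  set.seed(3)
  vals <- data.frame(FL1 = c(stats::runif(300, 0, 1e6), 800, 800, 55000),
                     FL2 = c(stats::runif(300, 0, 1e6), 800, 55000, 800))
  tab <- toy_table(vals)
  tr <- list(FL1 = diob_lp, FL2 = diob_lp)
  xs <- to_logicle(800, diob_lp); ys <- to_logicle(55000, diob_lp)
  masks <- lapply(c("++", "+-", "-+", "--"), function(cell)
    eval_geometric_gate(tab, gate_quadrant("FL1", "FL2", xs, ys, cell), tr))
  total <- Reduce(`+`, lapply(masks, as.integer))
  expect_true(all(total == 1L))  # disjoint and exhaustive, boundaries included
})

test_that("every gate kind matches a per-event brute-force oracle", {
  set.seed(4)
  for (rep in 1:5) {
    n <- sample(50:1000, 1)
    tab <- toy_table(data.frame(FL1 = stats::runif(n, -500, 1e6),
                                FL2 = stats::runif(n, -500, 1e6)))
    tr <- list(FL1 = diob_lp, FL2 = diob_lp)
    gates <- list(
      gate_threshold("FL1", lo = stats::runif(1, 0, 0.5),
                     hi = stats::runif(1, 0.5, 1.2)),
      gate_rectangle("FL1", "FL2", sort(stats::runif(2, 0, 1)),
                     sort(stats::runif(2, 0, 1))),
      gate_quadrant("FL1", "FL2", stats::runif(1, 0.2, 0.8),
                    stats::runif(1, 0.2, 0.8),
                    sample(c("++", "+-", "-+", "--"), 1)),
      gate_polygon("FL1", "FL2",
                   xs = c(0.1, 0.9, 0.9, 0.5, 0.1),
                   ys = c(0.1, 0.2, 0.9, 0.5, 0.8)))
    for (g in gates)
      expect_identical(eval_geometric_gate(tab, g, tr), brute_gate(tab, g, tr))
  }
})

test_that("gates reference markers through the channel map, unknowns error", {
  tab <- toy_table(data.frame(FL9 = c(100, 5000)), markers = c(FL9 = "CD3"))
  tr <- list(FL9 = diob_lp)
  g <- gate_threshold("CD3", lo = to_logicle(800, diob_lp))
  expect_identical(eval_geometric_gate(tab, g, tr), c(FALSE, TRUE))
  expect_error(eval_geometric_gate(tab, gate_threshold("CD99", lo = 0), tr),
               "unknown channel or marker")
})

test_that("Boolean union pools membership without double counting", {
  masks <- list(T8hi = c(TRUE, TRUE, FALSE, FALSE),
                T8lo = c(FALSE, FALSE, TRUE, FALSE))
  tc <- eval_boolean(bool_or("T8hi", "T8lo"), masks)
  expect_identical(tc, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(sum(tc), 3)
})

test_that("arbitrary three-gate expressions match exhaustive truth tables", {
  # all 8 membership patterns over gates A, B, C, one event per pattern
  patterns <- expand.grid(A = c(FALSE, TRUE), B = c(FALSE, TRUE),
                          C = c(FALSE, TRUE))
  masks <- as.list(patterns)
  exprs <- list(
    bool_and("A", bool_or("B", bool_not("C"))),
    bool_or(bool_and("A", "B"), bool_and(bool_not("A"), "C")),
    bool_not(bool_or("A", bool_or("B", "C"))))
  oracle <- list(
    with(patterns, A & (B | !C)),
    with(patterns, (A & B) | (!A & C)),
    with(patterns, !(A | B | C)))
  for (i in seq_along(exprs))
    expect_identical(eval_boolean(exprs[[i]], masks), oracle[[i]])
})

test_that("NOT of an empty gate within a parent returns every event", {
  masks <- list(empty = rep(FALSE, 10), parent = rep(TRUE, 10))
  out <- eval_boolean(bool_and("parent", bool_not("empty")), masks)
  expect_equal(sum(out), 10)
})

test_that("unresolved gate ids and unequal mask lengths are errors", {
  expect_error(eval_boolean(bool_or("a", "missing"),
                            list(a = c(TRUE, FALSE))),
               "unresolved gate id")
  expect_error(eval_boolean("a", list(a = c(TRUE), b = c(TRUE, FALSE))),
               "equal length")
})

test_that("gate trees evaluate hierarchically against hidden labels", {
  prof <- zero_noise_profile()
  out <- gate_panel(prof, "P01", 10000, seed = 21)
  tr <- out$truth
  kept <- out$qc$mask
  # two-level check: CD3+ then CD4hi
  t_truth <- sum(!is.na(tr$label[kept]) &
                   tr$label[kept] %in% c("TH", "TC8hi", "TC8lo", "DNT", "DPT",
                                         "T4lo", "T4hi8lo", "T8hi4lo", "NKT"))
  expect_identical(sum(out$masks[["t"]]), t_truth)
  th_truth <- sum(!is.na(tr$label[kept]) & tr$label[kept] == "TH")
  expect_identical(sum(out$masks[["th"]]), th_truth)
})

test_that("a root-only tree reports one population at 100 percent of parent", {
  tab <- toy_table(data.frame(FL1 = rep(5000, 50)))
  tree <- gate_tree(list(gate_node("all", "root",
                                   gate = gate_threshold("FL1", lo = -Inf),
                                   report = TRUE)))
  st <- apply_gate_tree(tab, tree, list(FL1 = diob_lp))
  expect_equal(nrow(st), 1)
  expect_equal(st$pct_parent, 100)
})

test_that("sibling quadrant cells report parent percentages summing to 100", {
  out <- gate_panel(build_default_profile(), "P01", 20000, seed = 22)
  mem <- out$stats[out$stats$node %in% c("th_naive", "th_eff", "th_em", "th_cm"), ]
  expect_equal(sum(mem$pct_parent), 100, tolerance = 1e-9)
})

test_that("schema errors are caught: cycles, orphans, duplicate ids", {
  g <- gate_threshold("FL1", lo = 0)
  expect_error(gate_tree(list(
    gate_node("a", "b", gate = g), gate_node("b", "a", gate = g))),
    "cycle or orphan")
  expect_error(gate_tree(list(gate_node("a", "nowhere", gate = g))),
    "unknown node")
  expect_error(gate_tree(list(gate_node("a", "root", gate = g),
                              gate_node("a", "root", gate = g))),
    "duplicate node ids")
})

test_that("population statistics flag fewer than 100 events as invalid", {
  out <- gate_panel(build_default_profile(), "P11", 5000, seed = 23)
  hsc <- out$stats[out$stats$node == "hsc", ]
  expect_false(hsc$valid)
  expect_lt(hsc$n_events, 100)
  allb <- out$stats[out$stats$node == "cd45dim", ]
  expect_true(allb$n_events <= sum(out$qc$mask))
})
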