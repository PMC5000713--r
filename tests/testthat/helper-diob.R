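# Shared fixtures: the schema is expensive enough to build once per session.
diob_schemas <- build_diob_schema()
diob_lp <- logicle_params()

# simulate + compensate + QC + gate one panel, returning everything the
# checks need
gate_panel <- function(profile, panel_id, n_events, seed,
                       schemas = diob_schemas) {
  schema <- schemas[[panel_id]]
  tab <- simulate_panel_acquisition(profile, schema, n_events, seed = seed)
  tab <- compensate(tab, attr(tab, "spillover"))
  qc <- qc_gates(tab, schema$qc)
  stats <- apply_gate_tree(tab, schema$tree, schema$transforms,
                           root_mask = qc$mask)
  list(table = tab, qc = qc, stats = stats, masks = attr(stats, "masks"),
       truth = event_truth(tab), schema = schema)
}

# brute-force per-event geometric gate oracle (independent of the engine)
brute_gate <- function(table, gate, transforms = list()) {
  disp <- function(ref) {
    col <- if (ref %in% colnames(table)) ref else {
      mk <- attr(table, "markers"); names(mk)[mk == ref]
    }
    tr <- transforms[[ref]]
    if (is.null(tr)) tr <- transforms[[col]]
    x <- table[[col]]
    if (is.null(tr) || identical(tr, "linear")) x else to_logicle(x, tr)
  }
  x <- disp(gate$channels[1])
  n <- nrow(table)
  out <- logical(n)
  if (gate$kind == "threshold") {
    for (i in seq_len(n)) out[i] <- x[i] >= gate$lo && x[i] < gate$hi
    return(out)
  }
  y <- disp(gate$channels[2])
  for (i in seq_len(n)) {
    out[i] <- switch(gate$kind,
      rectangle = x[i] >= gate$xlim[1] && x[i] < gate$xlim[2] &&
        y[i] >= gate$ylim[1] && y[i] < gate$ylim[2],
      quadrant = {
        xp <- x[i] >= gate$xsplit; yp <- y[i] >= gate$ysplit
        switch(gate$cell, "++" = xp && yp, "+-" = xp && !yp,
               "-+" = !xp && yp, "--" = !xp && !yp)
      },
      polygon = point_in_polygon(x[i], y[i], gate$xs, gate$ys))
  }
  out
}

# classic even-odd ray casting, written independently of mgcv
point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((ys[i] > py) != (ys[j] > py) &&
        px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
      inside <- !inside
    j <- i
  }
  inside
}

# a tiny event table with explicit values, for engine tests
toy_table <- function(values, markers = character()) {
  n <- nrow(values)
  base <- data.frame(TIME = seq_len(n) / 100, `FSC-INT` = rep(250000, n),
                     `FSC-TOF` = rep(60, n), `FSC-PEAK` = rep(250000, n),
                     SSC = rep(12000, n), check.names = FALSE)
  event_table(cbind(base, values), markers = markers)
}
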