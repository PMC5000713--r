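test_that("write then read round-trips events and metadata", {
  prof <- build_default_profile()
  tab <- simulate_panel_acquisition(prof, diob_schemas$P03, 500, seed = 9)
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(tab, path)
  back <- read_fcs(path)
  expect_equal(nrow(back), 500)
  expect_identical(colnames(back), colnames(tab))
  # float32 storage: relative error bounded by single precision
  for (cn in colnames(tab))
    expect_lt(max(abs(back[[cn]] - tab[[cn]]) / pmax(abs(tab[[cn]]), 1)), 1e-6)
  expect_identical(attr(back, "markers"), attr(tab, "markers"))
  expect_identical(attr(back, "panel_id"), "P03")
  expect_equal(unclass(attr(back, "spillover")),
               unclass(attr(tab, "spillover")), tolerance = 1e-9)
})

test_that("an empty acquisition writes a valid file with zero events", {
  df <- data.frame(TIME = numeric(), `FSC-INT` = numeric(),
                   `FSC-TOF` = numeric(), `FSC-PEAK` = numeric(),
                   SSC = numeric(), FL1 = numeric(), check.names = FALSE)
  tab <- event_table(df, markers = c(FL1 = "CD3"))
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(tab, path)
  raw <- readChar(path, file.info(path)$size, useBytes = TRUE)
  expect_match(raw, "\\$TOT\\|0\\|", fixed = FALSE)
  back <- read_fcs(path)
  expect_equal(nrow(back), 0)
  expect_identical(attr(back, "markers"), c(FL1 = "CD3"))
})

test_that("marker names ride in $PnS for mapped fluorescence channels", {
  tab <- toy_table(data.frame(FL1 = 1:3, FL9 = 4:6),
                   markers = c(FL1 = "CD8", FL9 = "CD3"))
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(tab, path)
  hdr <- readChar(path, 58L, useBytes = TRUE)
  text_end <- as.integer(substring(hdr, 19, 26))
  text <- readChar(path, text_end + 1L, useBytes = TRUE)
  expect_match(text, "\\$P6S\\|CD8\\|")
  expect_match(text, "\\$P7S\\|CD3\\|")
})

test_that("a table without spillover reads back with spillover absent", {
  tab <- toy_table(data.frame(FL1 = c(1, 2)))
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(tab, path)
  back <- read_fcs(path)
  expect_null(attr(back, "spillover"))
})

test_that("a truncated DATA segment is an error, not silent truncation", {
  tab <- toy_table(data.frame(FL1 = stats::runif(100)))
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(tab, path)
  raw <- readBin(path, "raw", file.info(path)$size)
  writeBin(raw[seq_len(length(raw) - 120)], path)
  expect_error(read_fcs(path), "truncated DATA segment")
})

test_that("spillover matrices round-trip through the plain-text format", {
  sp <- default_spillover()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spillover(sp, path)
  back <- read_spillover(path)
  expect_equal(unclass(back), unclass(sp), tolerance = 1e-12)
})
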