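# FCS 3.1 list-mode input/output.
#
# Dialect: single data set, $MODE L, $DATATYPE F (float32), little-endian
# ($BYTEORD 1,2,3,4), linear amplification ($PnE 0,0). Channel names follow
# the instrument convention TIME / FSC-INT / FSC-TOF / FSC-PEAK / SSC /
# FL1..FL10; marker names ride in $PnS. The TEXT delimiter is "|", which never
# occurs in the keywords or values this package writes.

FCS_DELIM <- "|"

#' Write an event table to an FCS 3.1 file
#'
#' Produces a single-dataset FCS 3.1 list-mode file with float32 data,
#' `$PnN` channel names, `$PnS` marker names for mapped fluorescence
#' channels, and a `$SPILLOVER` keyword when the table carries a spillover
#' matrix. Hidden simulator ground truth is not written.
#'
#' @param table an [event_table()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_fcs <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  cols <- colnames(table)
  p <- length(cols)
  n <- nrow(table)
  markers <- attr(table, "markers")
  spill <- attr(table, "spillover")

  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = "%BD%", "$ENDDATA" = "%ED%",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(p), "$TOT" = as.character(n)
  )
  for (i in seq_len(p)) {
    kw[sprintf("$P%dN", i)] <- cols[i]
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- "1048576"
    if (cols[i] %in% names(markers))
      kw[sprintf("$P%dS", i)] <- markers[[cols[i]]]
  }
  if (!is.null(spill)) {
    ch <- rownames(spill)
    vals <- as.vector(t(unclass(spill)))  # row-major
    kw["$SPILLOVER"] <- paste(c(length(ch), ch,
                                format(vals, trim = TRUE, digits = 12)),
                              collapse = ",")
  }
  meta <- c(PANEL = attr(table, "panel_id"), SAMPLE = attr(table, "sample_id"),
            DURATION = attr(table, "duration"), VOLUME_UL = attr(table, "volume_ul"))
  for (k in names(meta)) if (!is.na(meta[[k]])) kw[k] <- as.character(meta[[k]])

  build_text <- function(kw) {
    paste0(FCS_DELIM,
           paste0(names(kw), FCS_DELIM, unname(kw), FCS_DELIM, collapse = ""))
  }
  # fixed-width placeholders so TEXT length is independent of the offsets
  kw["$BEGINDATA"] <- "0000000000"
  kw["$ENDDATA"] <- "0000000000"
  text_start <- 58L
  text <- build_text(kw)
  text_end <- text_start + nchar(text, type = "bytes") - 1L
  nbytes <- 4L * p * n
  data_start <- text_end + 1L
  data_end <- if (nbytes > 0L) data_start + nbytes - 1L else 0L
  kw["$BEGINDATA"] <- sprintf("%010d", if (nbytes > 0L) data_start else 0L)
  kw["$ENDDATA"] <- sprintf("%010d", data_end)
  text <- build_text(kw)

  hdr <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d", text_start, text_end,
                 if (nbytes > 0L) data_start else 0L, data_end, 0L, 0L)
  stopifnot(nchar(hdr) == 58L)

  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  if (nbytes > 0L) {
    m <- t(as.matrix(as.data.frame(table)))  # interleave: event-major order
    writeBin(as.vector(m), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read an FCS 3.1 file into an event table
#'
#' Parses HEADER and TEXT segments, checks the DATA segment for truncation,
#' and returns an [event_table()]. A missing `$PnS` marker name is tolerated
#' (the marker map can then be supplied from a panel schema); a missing
#' `$SPILLOVER` keyword leaves the spillover attribute `NULL`.
#'
#' @param path path to an FCS file.
#' @return an [event_table()].
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sz <- file.info(path)$size
  con <- file(path, open = "rb")
  on.exit(close(con))
  hdr <- readChar(con, 58L, useBytes = TRUE)
  if (substr(hdr, 1, 3) != "FCS")
    stop("malformed header: file does not start with an FCS version string")
  offs <- suppressWarnings(as.integer(substring(hdr,
                                                c(11, 19, 27, 35), c(18, 26, 34, 42))))
  if (any(is.na(offs[1:2]))) stop("malformed header: unreadable TEXT offsets")
  text_start <- offs[1]; text_end <- offs[2]
  if (text_end > sz) stop("malformed header: TEXT segment extends past end of file")
  seek(con, text_start)
  text <- readChar(con, text_end - text_start + 1L, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  # trailing delimiter produces a final empty part; drop it
  if (length(parts) %% 2 == 1 && parts[length(parts)] == "")
    parts <- parts[-length(parts)]
  if (length(parts) %% 2 == 1)
    stop("malformed TEXT segment: odd number of delimited fields")
  kw <- as.list(stats::setNames(parts[seq(2, length(parts), 2)],
                                parts[seq(1, length(parts), 2)]))

  need <- function(key) {
    if (!key %in% names(kw)) stop("parse error: required keyword ", key, " missing")
    kw[[key]]
  }
  if (need("$DATATYPE") != "F")
    stop("parse error: unsupported $DATATYPE ", kw[["$DATATYPE"]])
  if (need("$MODE") != "L")
    stop("parse error: unsupported $MODE ", kw[["$MODE"]])
  endian <- if (need("$BYTEORD") == "4,3,2,1") "big" else "little"
  p <- as.integer(need("$PAR"))
  n <- as.integer(need("$TOT"))
  cols <- vapply(seq_len(p), function(i) need(sprintf("$P%dN", i)), "")
  bits <- vapply(seq_len(p), function(i) as.integer(need(sprintf("$P%dB", i))), 0L)
  if (any(bits != 32L)) stop("parse error: only 32-bit $PnB supported")

  if (n > 0L) {
    data_start <- as.integer(need("$BEGINDATA"))
    if (is.na(data_start) || data_start == 0L)
      data_start <- suppressWarnings(as.integer(substring(hdr, 27, 34)))
    nbytes <- 4 * p * n
    if (data_start + nbytes - 1 > sz)
      stop("truncated DATA segment: expected ", nbytes, " bytes at offset ",
           data_start, " but file has only ", sz)
    seek(con, data_start)
    vals <- readBin(con, what = "numeric", n = p * n, size = 4L, endian = endian)
    mat <- matrix(vals, nrow = n, ncol = p, byrow = TRUE)
  } else {
    mat <- matrix(numeric(0), nrow = 0, ncol = p)
  }
  df <- as.data.frame(mat)
  names(df) <- cols

  markers <- character()
  for (i in seq_len(p)) {
    s <- kw[[sprintf("$P%dS", i)]]
    if (!is.null(s)) markers[cols[i]] <- s
  }
  spill <- NULL
  if ("$SPILLOVER" %in% names(kw)) {
    f <- strsplit(kw[["$SPILLOVER"]], ",", fixed = TRUE)[[1]]
    k <- as.integer(f[1])
    ch <- f[2:(k + 1)]
    v <- as.numeric(f[(k + 2):(k + 1 + k * k)])
    m <- matrix(v, nrow = k, byrow = TRUE, dimnames = list(ch, ch))
    spill <- spillover_matrix(m)
  }
  num_or_na <- function(key) if (key %in% names(kw)) as.numeric(kw[[key]]) else NA_real_
  chr_or_na <- function(key) if (key %in% names(kw)) kw[[key]] else NA_character_
  event_table(df,
              panel_id = chr_or_na("PANEL"), sample_id = chr_or_na("SAMPLE"),
              markers = markers, duration = num_or_na("DURATION"),
              volume_ul = num_or_na("VOLUME_UL"), spillover = spill)
}
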