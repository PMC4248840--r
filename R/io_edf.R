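# Minimal European Data Format (EDF) reader/writer.
#
# Plain EDF only: 16-bit integer samples, ASCII headers, one-second data
# records.  Physical dimensions in the volt family (uV, mV, V) are
# honoured and converted to microvolts on read; anything else is
# rejected.  EDF+ annotations and vendor extensions are out of scope.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

edf_num <- function(x, width = 8) {
  s <- formatC(x, format = "g", digits = 7, width = -1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  pad_field(s, width)
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16-bit integers over each channel's physical
#' range; the physical dimension is written as "uV".  Requires a whole
#' number of seconds of data (records are one second long).
#'
#' @param recording [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  x <- recording$samples
  rate <- recording$rate_hz
  if (abs(rate - round(rate)) > 1e-9) {
    abort_invalid("EDF writer requires an integer sampling rate")
  }
  rate <- as.integer(round(rate))
  n <- ncol(x)
  if (n %% rate != 0) {
    abort_invalid("EDF writer requires whole seconds of data (%d samples at %d Hz)",
                  n, rate)
  }
  n_rec <- n %/% rate
  ns <- nrow(x)
  pmin <- apply(x, 1, min)
  pmax <- apply(x, 1, max)
  flat <- pmax - pmin < 1e-9
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(sprintf("subject %s", recording$subject_id), 80),
    pad_field(sprintf("day %d session %d", recording$day_index,
                      recording$session_index), 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 + 256 * ns, 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),
    pad_field(ns, 4),
    paste(vapply(recording$channels, pad_field, character(1), width = 16),
          collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(vapply(pmin, edf_num, character(1)), collapse = ""),
    paste(vapply(pmax, edf_num, character(1)), collapse = ""),
    paste(rep(pad_field(dmin, 8), ns), collapse = ""),
    paste(rep(pad_field(dmax, 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(rate, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * rate + 1):(r * rate)
    for (ch in seq_len(ns)) {
      d <- as.integer(round((x[ch, idx] - pmin[ch]) * scale[ch] + dmin))
      writeBin(d, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf_field <- function(raw, offset, width) {
  trimws(rawToChar(raw[(offset + 1):(offset + width)]))
}

#' Read an EDF file as a recording
#'
#' Honours the physical-dimension field: uV is taken as-is, mV scaled by
#' 1000 and V by 1e6 into microvolts; any other unit raises a unit error.
#'
#' @param path EDF file path.
#' @return [eeg_recording()] (identity fields default to 1; microvolts).
#' @export
read_edf <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 256) {
    abort_invalid("EDF parse error at byte %d: header truncated (%d bytes)",
                  length(raw), length(raw))
  }
  n_rec <- as.integer(read_edf_field(raw, 236, 8))
  rec_dur <- as.numeric(read_edf_field(raw, 244, 8))
  ns <- as.integer(read_edf_field(raw, 252, 4))
  hdr_len <- 256 + 256 * ns
  if (length(raw) < hdr_len) {
    abort_invalid("EDF parse error at byte %d: signal headers truncated",
                  length(raw))
  }
  fld <- function(block_off, width, i) {
    read_edf_field(raw, 256 + block_off * ns + (i - 1) * width, width)
  }
  labels <- vapply(seq_len(ns), function(i) fld(0, 16, i), character(1))
  units <- vapply(seq_len(ns), function(i) fld(96, 8, i), character(1))
  pmin <- vapply(seq_len(ns), function(i) as.numeric(fld(104, 8, i)),
                 numeric(1))
  pmax <- vapply(seq_len(ns), function(i) as.numeric(fld(112, 8, i)),
                 numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(fld(120, 8, i)),
                 numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(fld(128, 8, i)),
                 numeric(1))
  spr <- vapply(seq_len(ns), function(i) as.integer(fld(216, 8, i)),
                integer(1))
  unit_scale <- vapply(units, function(u) {
    switch(u, "uV" = 1, "µV" = 1, "mV" = 1000, "V" = 1e6,
           abort_invalid("EDF unit error: unsupported physical dimension '%s' (volt family required)", u))
  }, numeric(1))
  expected <- hdr_len + 2 * n_rec * sum(spr)
  if (length(raw) < expected) {
    abort_invalid("EDF parse error at byte %d: expected %d bytes of sample data",
                  length(raw), expected)
  }
  ints <- readBin(raw[(hdr_len + 1):expected], "integer",
                  n = n_rec * sum(spr), size = 2, endian = "little",
                  signed = TRUE)
  x <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      d <- ints[pos + seq_len(spr[ch])]
      pos <- pos + spr[ch]
      phys <- (d - dmin[ch]) * (pmax[ch] - pmin[ch]) /
        (dmax[ch] - dmin[ch]) + pmin[ch]
      x[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <- phys * unit_scale[ch]
    }
  }
  eeg_recording(x, rate_hz = spr[1] / rec_dur, channels = labels)
}
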