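# Internal compressed container, plain-text label intervals, study
# manifests and result tables.
#
# Unit conventions: all amplitudes are microvolts, all times are seconds
# from session start.

CONTAINER_MAGIC <- "WBC1"

#' Write a recording to the internal compressed container
#'
#' Gzip-compressed binary: a magic tag, a JSON metadata header (rate,
#' channels, identity fields, sample count) and the samples as doubles.
#' Lossless, unlike the 16-bit EDF quantization.
#'
#' @param recording [eeg_recording()].
#' @param path output path (conventionally `.wbci`).
#' @return `path`, invisibly.
#' @export
write_container <- function(recording, path) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  meta <- jsonlite::toJSON(list(
    rate_hz = recording$rate_hz, channels = recording$channels,
    subject_id = recording$subject_id, day_index = recording$day_index,
    session_index = recording$session_index,
    start_offset_s = recording$start_offset_s,
    n_samples = ncol(recording$samples)), auto_unbox = TRUE)
  writeChar(CONTAINER_MAGIC, con, eos = NULL)
  writeBin(nchar(meta, type = "bytes"), con, size = 4, endian = "little")
  writeChar(as.character(meta), con, eos = NULL)
  writeBin(as.numeric(t(recording$samples)), con, size = 8,
           endian = "little")
  invisible(path)
}

#' Read a recording from the internal container
#'
#' @param path container path.
#' @return [eeg_recording()].
#' @export
read_container <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  magic <- tryCatch(readChar(con, 4, useBytes = TRUE), error = function(e) "")
  if (!identical(magic, CONTAINER_MAGIC)) {
    abort_invalid("container parse error at byte 0: bad magic '%s'", magic)
  }
  mlen <- readBin(con, "integer", size = 4, endian = "little")
  if (length(mlen) == 0 || mlen <= 0 || mlen > 1e6) {
    abort_invalid("container parse error at byte 4: bad metadata length")
  }
  meta_raw <- readChar(con, mlen, useBytes = TRUE)
  if (nchar(meta_raw, type = "bytes") < mlen) {
    abort_invalid("container parse error at byte %d: metadata truncated",
                  8 + nchar(meta_raw, type = "bytes"))
  }
  meta <- jsonlite::fromJSON(meta_raw)
  nch <- length(meta$channels)
  want <- nch * meta$n_samples
  x <- readBin(con, "numeric", n = want, size = 8, endian = "little")
  if (length(x) < want) {
    abort_invalid(
      "container parse error at byte %d: expected %d samples, found %d",
      8 + mlen + 8 * length(x), want, length(x))
  }
  eeg_recording(matrix(x, nrow = nch, byrow = TRUE), meta$rate_hz,
                meta$channels, meta$subject_id, meta$day_index,
                meta$session_index, meta$start_offset_s)
}

#' Write a recording (format chosen by file extension)
#'
#' `.edf` files go through [write_edf()] (16-bit quantized); anything
#' else through the lossless internal container.
#'
#' @param recording [eeg_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    write_edf(recording, path)
  } else {
    write_container(recording, path)
  }
}

#' Read a recording (format chosen by file extension)
#'
#' @param path `.edf` or internal-container path.
#' @return [eeg_recording()] in microvolts.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) abort_invalid("no such file: %s", path)
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    read_edf(path)
  } else {
    read_container(path)
  }
}

#' Write label intervals as a delimited table
#'
#' Tab-separated columns `start_s`, `end_s`, `state`; half-open
#' `[start_s, end_s)` intervals.
#'
#' @param labels [label_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(labels$intervals, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read label intervals from a delimited table
#'
#' @param path label file path.
#' @return [label_track()] (validated: overlapping intervals raise an
#'   error naming the offending pair).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort_invalid("no such file: %s", path)
  if (file.info(path)$size == 0) {
    return(label_track(data.frame(start_s = numeric(0),
                                  end_s = numeric(0),
                                  state = character(0))))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    return(label_track(data.frame(start_s = numeric(0),
                                  end_s = numeric(0),
                                  state = character(0))))
  }
  label_track(df)
}

#' Write a study to disk with a manifest
#'
#' One container (or EDF) file and one label file per session plus a
#' `manifest.csv` listing (path, subject_id, day_index, session_index,
#' label_path).
#'
#' @param study [generate_study()] output.
#' @param dir output directory (created if needed).
#' @param format "wbci" (internal container) or "edf".
#' @return manifest path, invisibly.
#' @export
write_study <- function(study, dir, format = c("wbci", "edf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(study, function(s) {
    r <- s$recording
    base <- sprintf("sub%02d_day%02d_ses%02d", as.integer(r$subject_id),
                    r$day_index, r$session_index)
    rec_path <- file.path(dir, paste0(base, ".", format))
    lab_path <- file.path(dir, paste0(base, "_labels.tsv"))
    write_recording(r, rec_path)
    write_labels(s$labels, lab_path)
    data.frame(path = basename(rec_path), subject_id = r$subject_id,
               day_index = r$day_index, session_index = r$session_index,
               label_path = basename(lab_path))
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' Load a study from a manifest
#'
#' @param manifest_path path to a `manifest.csv` written by
#'   [write_study()]; entry paths are resolved relative to it.
#' @return list of sessions (`recording`, `labels`), in manifest order.
#' @export
read_study <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    abort_invalid("no such manifest: %s", manifest_path)
  }
  m <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  key <- paste(m$subject_id, m$day_index, m$session_index)
  if (anyDuplicated(key)) {
    abort_invalid("duplicate (subject, day, session) in manifest: %s",
                  key[duplicated(key)][1])
  }
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(m)), function(i) {
    rec_path <- file.path(base, m$path[i])
    lab_path <- file.path(base, m$label_path[i])
    for (p in c(rec_path, lab_path)) {
      if (!file.exists(p)) abort_invalid("manifest entry missing: %s", p)
    }
    rec <- read_recording(rec_path)
    rec$subject_id <- m$subject_id[i]
    rec$day_index <- m$day_index[i]
    rec$session_index <- m$session_index[i]
    list(recording = rec, labels = read_labels(lab_path))
  })
}
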