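# Reading ECG and annotation inputs, writing pipeline outputs.
#
# ECG comes in as EDF (single channel selected by label) or a WFDB
# record/annotation pair (format 16). Respiratory-event annotations use a
# plain CSV schema (kind, onset_s, duration_s, desaturation_pct, arousal);
# the hypnogram is one stage token per line. Timestamps are seconds from
# recording start, 0-based.

ANNOTATION_COLS <- c("kind", "onset_s", "duration_s", "desaturation_pct", "arousal")

# ---- EDF -------------------------------------------------------------------

read_edf_header <- function(con) {
  ascii <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  h <- list(
    version = ascii(8), patient = ascii(80), recording = ascii(80),
    startdate = ascii(8), starttime = ascii(8),
    header_bytes = as.integer(ascii(8)), reserved = ascii(44),
    n_records = as.integer(ascii(8)), record_duration = as.numeric(ascii(8)),
    n_signals = as.integer(ascii(4))
  )
  ns <- h$n_signals
  fields <- function(width) vapply(seq_len(ns), function(i) ascii(width), "")
  h$labels <- fields(16)
  h$transducer <- fields(80)
  h$units <- fields(8)
  h$phys_min <- as.numeric(fields(8))
  h$phys_max <- as.numeric(fields(8))
  h$dig_min <- as.numeric(fields(8))
  h$dig_max <- as.numeric(fields(8))
  h$prefilter <- fields(80)
  h$samples_per_record <- as.integer(fields(8))
  h$sig_reserved <- fields(32)
  h
}

#' Read a single channel from an EDF file
#'
#' Minimal European Data Format reader: parses the ASCII header, selects
#' one signal by label (or the first when `channel` is `NULL`) and
#' rescales the 16-bit samples to physical units.
#'
#' @param path Path to the `.edf` file.
#' @param channel Channel label to extract (exact match after trimming),
#'   or `NULL` for the first signal.
#' @return An `ecg_record` list: `samples`, `sampling_rate`, `duration`,
#'   `record_id`.
#' @export
read_edf <- function(path, channel = NULL) {
  if (!file.exists(path)) abort(sprintf("Cannot read EDF file '%s'.", path))
  con <- file(path, "rb")
  on.exit(close(con))
  h <- tryCatch(read_edf_header(con), error = function(e) {
    abort(sprintf("File '%s' is not a readable EDF file: %s", path, conditionMessage(e)))
  })
  sel <- if (is.null(channel)) 1L else match(channel, h$labels)
  if (is.na(sel)) {
    abort(sprintf(
      "Channel '%s' not found in '%s'; available: %s.",
      channel, path, paste(h$labels, collapse = ", ")
    ))
  }
  per_rec <- h$samples_per_record
  out <- vector("list", h$n_records)
  for (r in seq_len(h$n_records)) {
    for (s in seq_len(h$n_signals)) {
      raw16 <- readBin(con, "integer", n = per_rec[s], size = 2, endian = "little")
      if (s == sel) out[[r]] <- raw16
    }
  }
  dig <- unlist(out)
  gain <- (h$phys_max[sel] - h$phys_min[sel]) / (h$dig_max[sel] - h$dig_min[sel])
  phys <- (dig - h$dig_min[sel]) * gain + h$phys_min[sel]
  fs <- per_rec[sel] / h$record_duration
  structure(list(
    samples = phys, sampling_rate = fs,
    duration = length(phys) / fs,
    record_id = tools::file_path_sans_ext(basename(path))
  ), class = "ecg_record")
}

#' Write a single-channel EDF file
#'
#' Companion writer for [read_edf()], used to export simulated ECG and in
#' round-trip tests. Samples are scaled into the 16-bit digital range.
#'
#' @param ecg An `ecg_record` (see [render_ecg()]).
#' @param path Output path.
#' @param label Signal label written to the header.
#' @param units Physical dimension label.
#' @return `path`, invisibly.
#' @export
write_edf <- function(ecg, path, label = "ECG", units = "mV") {
  fs <- ecg$sampling_rate
  if (fs != round(fs)) abort("EDF export requires an integer sampling rate.")
  x <- ecg$samples
  n_rec <- as.integer(ceiling(length(x) / fs))
  x <- c(x, rep(0, n_rec * fs - length(x)))
  pmin_ <- min(x)
  pmax_ <- max(x)
  if (pmax_ <= pmin_) pmax_ <- pmin_ + 1
  dmin <- -32768
  dmax <- 32767
  dig <- as.integer(round((x - pmin_) / (pmax_ - pmin_) * (dmax - dmin) + dmin))
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(s, w) {
    s <- substr(format(s), 1, w)
    writeChar(formatC(s, width = -w), con, eos = NULL)
  }
  pad("0", 8)
  pad(ecg$record_id %||% "X", 80)
  pad("Startdate X", 80)
  pad("01.01.00", 8)
  pad("00.00.00", 8)
  pad(as.character(256 + 256), 8)
  pad("", 44)
  pad(as.character(n_rec), 8)
  pad("1", 8)
  pad("1", 4)
  pad(label, 16)
  pad("", 80)
  pad(units, 8)
  pad(format(pmin_, digits = 6), 8)
  pad(format(pmax_, digits = 6), 8)
  pad(as.character(dmin), 8)
  pad(as.character(dmax), 8)
  pad("", 80)
  pad(as.character(as.integer(fs)), 8)
  pad("", 32)
  writeBin(dig, con, size = 2, endian = "little")
  invisible(path)
}

# ---- WFDB (format 16) ------------------------------------------------------

#' Read a WFDB record (signal format 16)
#'
#' Minimal reader for WFDB record/header pairs: parses `<record>.hea` and
#' the interleaved 16-bit little-endian samples in the companion `.dat`
#' file, returning one channel scaled by its gain.
#'
#' @param record Path to the record without extension.
#' @param channel Signal index (1-based) or description string.
#' @return An `ecg_record`.
#' @export
read_wfdb <- function(record, channel = 1L) {
  hea <- paste0(record, ".hea")
  if (!file.exists(hea)) abort(sprintf("Cannot read WFDB header '%s'.", hea))
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  name <- top[1]
  n_sig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(top[3]) else 250
  n_samp <- if (length(top) >= 4) as.numeric(top[4]) else NA
  sig <- lines[1 + seq_len(n_sig)]
  parts <- strsplit(trimws(sig), "\\s+")
  dat_file <- parts[[1]][1]
  fmt <- sub("x.*", "", parts[[1]][2])
  if (fmt != "16") abort(sprintf("Only WFDB signal format 16 is supported, got '%s'.", fmt))
  gains <- vapply(parts, function(p) {
    g <- if (length(p) >= 3) as.numeric(sub("[(/].*", "", p[3])) else 200
    if (is.na(g) || g == 0) 200 else g
  }, 1)
  descs <- vapply(parts, function(p) {
    if (length(p) >= 9) paste(p[9:length(p)], collapse = " ") else ""
  }, "")
  sel <- if (is.character(channel)) match(channel, descs) else as.integer(channel)
  if (is.na(sel) || sel < 1 || sel > n_sig) {
    abort(sprintf("Channel '%s' not found in '%s'.", as.character(channel), hea))
  }
  dat_path <- file.path(dirname(record), dat_file)
  if (!file.exists(dat_path)) abort(sprintf("Cannot read WFDB signal file '%s'.", dat_path))
  raw16 <- readBin(dat_path, "integer",
    n = file.info(dat_path)$size / 2,
    size = 2, endian = "little"
  )
  m <- matrix(raw16, nrow = n_sig)
  x <- m[sel, ] / gains[sel]
  structure(list(
    samples = x, sampling_rate = fs, duration = length(x) / fs,
    record_id = name
  ), class = "ecg_record")
}

# ---- Annotations and hypnogram --------------------------------------------

#' Read respiratory-event annotations
#'
#' Reads the CSV schema `kind,onset_s,duration_s,desaturation_pct,arousal`
#' and validates event kinds, returning events sorted by onset.
#'
#' @param path Path to the annotation CSV.
#' @return Tibble of events.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("Cannot read annotation file '%s'.", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), ANNOTATION_COLS)) {
    abort(sprintf(
      "Annotation file '%s' must have header exactly '%s'.",
      path, paste(ANNOTATION_COLS, collapse = ",")
    ))
  }
  bad <- which(!df$kind %in% RE_EVENT_KINDS)
  if (length(bad)) {
    abort(sprintf(
      "Annotation file '%s' has unknown event kind(s) in row(s) %s: %s.",
      path, paste(bad, collapse = ", "),
      paste(unique(df$kind[bad]), collapse = ", ")
    ))
  }
  df$arousal <- as.logical(df$arousal)
  as_tibble(df) |> arrange(.data$onset_s)
}

#' Read a sleep/wake hypnogram
#'
#' One stage token (`wake` or `sleep`) per line, one line per 30-s epoch.
#'
#' @param path Path to the hypnogram file.
#' @return Character vector of stages.
#' @export
read_hypnogram <- function(path) {
  if (!file.exists(path)) abort(sprintf("Cannot read hypnogram file '%s'.", path))
  stages <- trimws(readLines(path, warn = FALSE))
  stages <- stages[nzchar(stages)]
  bad <- setdiff(unique(stages), c("wake", "sleep"))
  if (length(bad)) {
    abort(sprintf(
      "Hypnogram '%s' has unknown stage token(s): %s.",
      path, paste(bad, collapse = ", ")
    ))
  }
  stages
}

#' Read a recording: ECG, events and hypnogram
#'
#' Dispatches on the ECG path (`.edf` or a WFDB record stem), reads the
#' annotation CSV, and returns the triple the pipeline consumes. Without
#' a hypnogram all epochs are assumed asleep, with a warning.
#'
#' @param ecg_path EDF file or WFDB record stem.
#' @param annotation_path Respiratory-event CSV.
#' @param hypnogram_path Optional stage-per-line file.
#' @param channel Channel label (EDF) or index/description (WFDB).
#' @return List with `ecg`, `events` (sorted by onset) and `stages`
#'   (length `floor(duration / 30)`).
#' @export
read_recording <- function(ecg_path, annotation_path, hypnogram_path = NULL,
                           channel = NULL) {
  ecg <- if (grepl("\\.edf$", ecg_path, ignore.case = TRUE)) {
    read_edf(ecg_path, channel)
  } else {
    read_wfdb(ecg_path, channel %||% 1L)
  }
  events <- read_annotations(annotation_path)
  n_epochs <- as.integer(floor(ecg$duration / EPOCH_LEN))
  if (is.null(hypnogram_path)) {
    warn("No hypnogram given; assuming all epochs are sleep.")
    stages <- rep("sleep", n_epochs)
  } else {
    stages <- read_hypnogram(hypnogram_path)
    if (length(stages) != n_epochs) {
      abort(sprintf(
        "Hypnogram length (%d) does not match the recording's %d epochs.",
        length(stages), n_epochs
      ))
    }
  }
  list(ecg = ecg, events = events, stages = stages)
}

# ---- Dataset harmonisation -------------------------------------------------

#' Harmonise hypopnea scoring across datasets
#'
#' Drops hypopneas that have a desaturation below 4% and are not followed
#' by an arousal, aligning annotations scored with the 3%-desaturation
#' rule to the stricter 4% criterion. Apneas are never touched. Hypopneas
#' missing both the desaturation and arousal fields are handled by
#' `missing_policy` (default: kept, with a warning, since some datasets
#' provide no event detail).
#'
#' @param events Event tibble (see [read_annotations()]).
#' @param missing_policy `"keep"` or `"drop"` for hypopneas whose
#'   desaturation and arousal are both absent.
#' @param quiet Suppress the missing-detail warning.
#' @return Events with the failing hypopneas removed; order preserved.
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   kind = c("hypopnea", "hypopnea", "obstructive_apnea"),
#'   onset_s = c(0, 60, 120), duration_s = 15,
#'   desaturation_pct = c(3.5, 3.5, 2), arousal = c(FALSE, TRUE, NA)
#' )
#' harmonise_hypopneas(ev)
harmonise_hypopneas <- function(events, missing_policy = c("keep", "drop"),
                                quiet = FALSE) {
  missing_policy <- match.arg(missing_policy)
  check_df_cols(events, c("kind", "onset_s", "duration_s"), "events")
  if (!nrow(events)) return(events)
  desat <- events$desaturation_pct %||% rep(NA_real_, nrow(events))
  arousal <- events$arousal %||% rep(NA, nrow(events))
  is_hyp <- events$kind == "hypopnea"
  unknown <- is_hyp & is.na(desat) & is.na(arousal)
  if (any(unknown) && !quiet) {
    warn(sprintf(
      "%d hypopnea(s) lack both desaturation and arousal; policy '%s' applied.",
      sum(unknown), missing_policy
    ))
  }
  drop <- is_hyp & !is.na(desat) & desat < 4 & !is.na(arousal) & !arousal
  if (missing_policy == "drop") drop <- drop | unknown
  events[!drop, , drop = FALSE]
}

#' Split 60-second labels onto the 30-second grid
#'
#' Each minute-based binary label is duplicated into two 30-s epochs with
#' the same label, aligning minute-annotated datasets with the 30-s
#' scoring grid.
#'
#' @param labels60 Vector of per-60-s labels.
#' @return Vector of length `2 * length(labels60)`.
#' @export
#' @examples
#' split_minute_labels(c("A", "N"))
split_minute_labels <- function(labels60) {
  rep(labels60, each = 2)
}

# ---- Pipeline outputs ------------------------------------------------------

#' Write per-epoch labels or probabilities to CSV
#' @param labels Epoch label tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(labels, path) {
  write.csv(labels, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write an AHI report as JSON
#' @param estimate An AHI estimate tibble (see [estimate_ahi()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ahi_json <- function(estimate, path) {
  jsonlite::write_json(as.list(estimate), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write IBI series CSV
#'
#' Two-column schema `onset_s,ibi_s`, allowing the ECG processing stage to
#' be bypassed when inter-beat intervals come from another device.
#'
#' @param path CSV path.
#' @return For `read_ibis_csv`, a tibble `onset_s`, `ibi_s`.
#' @export
read_ibis_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("Cannot read IBI file '%s'.", path))
  df <- read.csv(path)
  check_df_cols(df, c("onset_s", "ibi_s"), "IBI file")
  as_tibble(df)
}

#' @rdname read_ibis_csv
#' @param ibis IBI tibble.
#' @export
write_ibis_csv <- function(ibis, path) {
  write.csv(ibis[, c("onset_s", "ibi_s")], path, row.names = FALSE)
  invisible(path)
}
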