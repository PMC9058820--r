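# Canonical CSV log schema: one row per packet with
# packet_number, timestamp, the 18 band responsivities keyed by wavelength,
# then ENDVI, EVI, NDVI. The dialect is fixed bit-exactly (column order,
# %.10g floats, quoted "MM/DD/YYYY,HH:MM:SS" timestamp) so that writing the
# same records twice yields byte-identical files.

LOG_INDEX_COLS <- c("ENDVI", "EVI", "NDVI")

log_columns <- function() {
  c("packet_number", "timestamp", band_keys(), LOG_INDEX_COLS)
}

#' Build log records from spectral readings
#'
#' Renders readings into the canonical log schema, computing the three
#' logged indices (ENDVI, EVI, NDVI) from the bands. Indices are kept in
#' double precision; formatting happens only at write time.
#'
#' @param readings List of [spectral_reading()]s.
#' @param packet_number Integer vector, strictly increasing, same length.
#' @param timestamp POSIXct vector, same length.
#' @return data.frame in log-record form: `packet_number`, `timestamp`,
#'   one column per band wavelength, `ENDVI`, `EVI`, `NDVI`.
#' @export
as_log_records <- function(readings, packet_number, timestamp) {
  stopifnot(length(readings) == length(packet_number),
            length(readings) == length(timestamp))
  bands <- do.call(rbind, lapply(readings, function(r)
    unclass(validate_reading(r))))
  out <- data.frame(packet_number = as.integer(packet_number),
                    timestamp = as.POSIXct(timestamp),
                    bands, check.names = FALSE)
  names(out)[3:20] <- band_keys()
  out$ENDVI <- vapply(readings, endvi, numeric(1))
  out$EVI   <- vapply(readings, evi, numeric(1))
  out$NDVI  <- vapply(readings, ndvi, numeric(1))
  out
}

# Internal: reconstruct the reading of one log-record row.
record_reading <- function(records, i) {
  spectral_reading(stats::setNames(as.numeric(records[i, band_keys()]),
                                   band_keys()))
}

#' Check stored indices against stored bands
#'
#' @param records Log-record data.frame.
#' @param tol Tolerance, absolute for indices of magnitude up to 1 and
#'   relative beyond (`tol * max(1, |stored|)`); the normalized-difference
#'   indices are bounded by 1, but EVI can blow up near its denominator
#'   zero. Default 1e-6.
#' @return Logical vector: TRUE where all three stored indices agree with
#'   recomputation from the stored bands within `tol`.
#' @export
check_log_consistency <- function(records, tol = 1e-6) {
  near <- function(stored, recomputed) {
    abs(stored - recomputed) <= tol * max(1, abs(stored))
  }
  vapply(seq_len(nrow(records)), function(i) {
    r <- record_reading(records, i)
    near(records$ENDVI[i], endvi(r)) &&
      near(records$EVI[i], evi(r)) &&
      near(records$NDVI[i], ndvi(r))
  }, logical(1))
}

validate_records <- function(records) {
  missing <- setdiff(log_columns(), names(records))
  if (length(missing) > 0L) {
    stop_schema(sprintf("log records missing column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  if (nrow(records) > 0L) {
    if (any(diff(records$packet_number) <= 0)) {
      stop_value("packet numbers must be strictly increasing")
    }
    if (any(records$packet_number < 1)) {
      stop_value("packet numbers must be >= 1")
    }
    b <- as.matrix(records[, band_keys()])
    if (any(!is.finite(b)) || any(b < 0)) {
      stop_value("band responsivities must be finite and >= 0")
    }
    ok <- check_log_consistency(records)
    if (!all(ok)) {
      stop_value(sprintf(
        "stored indices disagree with stored bands beyond 1e-6 at packet(s): %s",
        paste(records$packet_number[!ok], collapse = ", ")))
    }
  }
  invisible(records)
}

fmt_num <- function(x) sprintf("%.10g", x)

#' Write log records to CSV
#'
#' Writes the canonical 23-column log CSV. The timestamp field
#' `MM/DD/YYYY,HH:MM:SS` contains a comma and is therefore quoted. Output
#' is byte-stable: the same records always produce an identical file.
#'
#' @param records Log-record data.frame (see [as_log_records()]).
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_log <- function(records, path) {
  validate_records(records)
  header <- paste(log_columns(), collapse = ",")
  lines <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    ts <- format(records$timestamp[i], "%m/%d/%Y,%H:%M:%S")
    lines[i] <- paste(c(
      sprintf("%d", records$packet_number[i]),
      sprintf("\"%s\"", ts),
      fmt_num(as.numeric(records[i, band_keys()])),
      fmt_num(as.numeric(records[i, LOG_INDEX_COLS]))
    ), collapse = ",")
  }
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop_typed("gob_io_error",
                    sprintf("cannot open '%s' for writing", path)))
  on.exit(close(con))
  writeLines(c(header, lines), con, sep = "\n")
  invisible(path)
}

#' Read log records from CSV
#'
#' Reads a file in the canonical dialect, checks the schema, parses
#' timestamps, and verifies that stored indices are self-consistent with
#' the stored bands (a warning names any packet beyond tolerance).
#'
#' @param path Source file path.
#' @param tz Timezone for parsed timestamps. Default `"UTC"`.
#' @return Log-record data.frame.
#' @export
read_log <- function(path, tz = "UTC") {
  if (!file.exists(path)) {
    stop_typed("gob_io_error", sprintf("log file '%s' does not exist", path))
  }
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", strip.white = FALSE)
  missing <- setdiff(log_columns(), names(raw))
  if (length(missing) > 0L) {
    stop_schema(sprintf("log file missing column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  ts <- as.POSIXct(strptime(raw$timestamp, "%m/%d/%Y,%H:%M:%S", tz = tz))
  if (anyNA(ts) && nrow(raw) > 0) {
    bad <- which(is.na(ts))[1L]
    stop_format(sprintf("unparseable timestamp '%s' at data row %d",
                        raw$timestamp[bad], bad))
  }
  out <- data.frame(packet_number = as.integer(raw$packet_number),
                    timestamp = ts, check.names = FALSE)
  for (k in band_keys()) out[[k]] <- as.numeric(raw[[k]])
  for (k in LOG_INDEX_COLS) out[[k]] <- as.numeric(raw[[k]])
  b <- as.matrix(out[, band_keys()])
  if (nrow(out) > 0 && (any(!is.finite(b)) || any(b < 0))) {
    stop_value("log file contains negative or non-finite band responsivities")
  }
  if (nrow(out) > 0) {
    ok <- check_log_consistency(out)
    if (!all(ok)) {
      warning(sprintf(
        "stored indices disagree with stored bands beyond 1e-6 at packet(s): %s",
        paste(out$packet_number[!ok], collapse = ", ")), call. = FALSE)
    }
  }
  out
}

#' Re-derive a detection trace from logged raw bands
#'
#' Recomputes the chosen index from the stored band responsivities,
#' calibrates on a designated soil window of packets, and classifies every
#' remaining packet against the resulting threshold — the threshold-crossing
#' analysis of a field log, applicable to any log in the canonical schema.
#'
#' @param records Log-record data.frame (from [read_log()] or
#'   [as_log_records()]).
#' @param cfg A [detector_config()].
#' @param soil_window Integer vector of packet numbers forming the soil
#'   calibration window (e.g. `1:15`), or length-2 range `c(first, last)`.
#' @return List with `calibration` and `trace` (data.frame over packets
#'   outside the soil window: `packet_number`, `index_value`, `detected`,
#'   `relay_on`, `undefined_index`).
#' @export
reanalyze <- function(records, cfg, soil_window) {
  stopifnot(inherits(cfg, "detector_config"))
  if (length(soil_window) == 2L && soil_window[2] > soil_window[1] + 1) {
    soil_window <- seq(soil_window[1], soil_window[2])
  }
  in_window <- records$packet_number %in% soil_window
  if (!any(in_window)) {
    stop_calibration("soil window contains no packets of the log")
  }
  readings <- lapply(seq_len(nrow(records)), record_reading,
                     records = records)
  cal <- calibrate(readings[in_window], cfg)
  rest <- which(!in_window)
  trace <- do.call(rbind, lapply(seq_along(rest), function(j) {
    row <- detector_step(readings[[rest[j]]], cal, j)
    row$packet_number <- records$packet_number[rest[j]]
    row
  }))
  if (is.null(trace)) {
    trace <- detector_step(spectral_reading(rep(1, 18)), cal, 1L)[0L, ]
  }
  list(calibration = cal, trace = trace)
}
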