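# Soil-baseline calibration and the periodic sense -> index -> compare ->
# trigger loop. The relay mirrors detection every cycle; there is no
# hysteresis or minimum on-time. Recalibration is a new run.

#' Detector configuration
#'
#' @param index_name Index driving detection: `"endvi"` (default), `"ndvi"`,
#'   `"evi"`, `"psnd"`, or `"custom:<label>"` registered via
#'   [register_custom()].
#' @param offset Nonnegative index units added to the soil baseline to form
#'   the detection threshold; guards against false positives. Higher offsets
#'   demand a larger index excursion over soil before a plant registers.
#'   Default 0.05.
#' @param cycle_seconds Sensing cycle period in seconds. Default 2.
#' @param calibration_seconds Duration of the stationary soil calibration
#'   window in seconds. Default 30, giving `floor(30/2) = 15` soil samples.
#' @param aggregator Baseline statistic over the soil-sample index values:
#'   `"mean"` (default) or `"max"`.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(index_name = "endvi", offset = 0.05,
                            cycle_seconds = 2, calibration_seconds = 30,
                            aggregator = c("mean", "max")) {
  aggregator <- match.arg(aggregator)
  stopifnot(is.character(index_name), length(index_name) == 1L)
  if (!is.numeric(offset) || length(offset) != 1L || offset < 0) {
    stop_config("offset must be a single nonnegative number")
  }
  if (!is.numeric(cycle_seconds) || cycle_seconds <= 0) {
    stop_config("cycle_seconds must be > 0")
  }
  if (!is.numeric(calibration_seconds) || calibration_seconds < cycle_seconds) {
    stop_config("calibration_seconds must be >= cycle_seconds")
  }
  structure(list(index_name = index_name, offset = as.numeric(offset),
                 cycle_seconds = as.numeric(cycle_seconds),
                 calibration_seconds = as.numeric(calibration_seconds),
                 aggregator = aggregator),
            class = "detector_config")
}

#' Number of soil samples consumed by calibration
#' @param cfg A [detector_config()].
#' @return `floor(calibration_seconds / cycle_seconds)`, at least 1.
#' @export
calibration_samples <- function(cfg) {
  max(1L, as.integer(floor(cfg$calibration_seconds / cfg$cycle_seconds)))
}

#' Calibrate the detection threshold over bare soil
#'
#' Computes the configured index for every stationary soil reading,
#' aggregates them into a baseline (mean by default), and adds the
#' configured offset: `threshold = baseline + offset`, exactly.
#'
#' @param soil_readings List of [spectral_reading()]s taken over bare soil.
#' @param cfg A [detector_config()].
#' @return An object of class `calibration_result`: list with `index_name`,
#'   `baseline`, `offset`, `threshold`, `n_samples`, `aggregator`.
#' @examples
#' cfg <- detector_config(offset = 0.05)
#' soil <- replicate(15, spectral_reading(rep(0.3, 18)), simplify = FALSE)
#' calibrate(soil, cfg)$threshold  # flat soil -> ENDVI 0, threshold 0.05
#' @export
calibrate <- function(soil_readings, cfg) {
  if (length(soil_readings) < 1L) {
    stop_calibration("calibration requires at least one soil reading")
  }
  vals <- vapply(soil_readings, function(r) {
    tryCatch(evaluate_index(cfg$index_name, r),
             gob_undefined_index = function(e) {
               stop_calibration(paste0(
                 "undefined index among soil samples; the soil baseline ",
                 "must be well defined (", conditionMessage(e), ")"))
             })
  }, numeric(1))
  baseline <- switch(cfg$aggregator, mean = mean(vals), max = max(vals))
  structure(list(index_name = cfg$index_name, baseline = baseline,
                 offset = cfg$offset, threshold = baseline + cfg$offset,
                 n_samples = length(vals), aggregator = cfg$aggregator,
                 baseline_sd = stats::sd(vals)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration: %s baseline %.4f (%s of %d samples) + offset %.4f -> threshold %.4f\n",
              x$index_name, x$baseline, x$aggregator, x$n_samples, x$offset,
              x$threshold))
  invisible(x)
}

#' One detect/trigger cycle
#'
#' Computes the calibrated index for one reading and compares it to the
#' threshold. Detection requires the index to be *strictly* greater than the
#' threshold (a value exactly at the threshold does not trigger). An
#' undefined index (zero denominator) yields no detection plus a warning
#' flag rather than an error: fail safe while moving.
#'
#' @param r A [spectral_reading()].
#' @param cal A [calibrate()] result.
#' @param packet_number Positive integer packet counter.
#' @return A one-row data.frame: `packet_number`, `index_value` (NA if
#'   undefined), `detected`, `relay_on`, `undefined_index`.
#' @export
detector_step <- function(r, cal, packet_number) {
  stopifnot(inherits(cal, "calibration_result"), packet_number >= 1)
  value <- tryCatch(evaluate_index(cal$index_name, r),
                    gob_undefined_index = function(e) NA_real_)
  detected <- !is.na(value) && value > cal$threshold
  data.frame(packet_number = as.integer(packet_number),
             index_value = value,
             detected = detected,
             relay_on = detected,
             undefined_index = is.na(value))
}

#' Run the calibrate-then-detect loop over a reading stream
#'
#' Consumes the first `calibration_samples(cfg)` readings as the stationary
#' soil calibration window, then processes every remaining reading as one
#' detection cycle, numbering packets consecutively from 1. Deterministic
#' given the stream and configuration.
#'
#' @param stream List of [spectral_reading()]s; must be at least as long as
#'   the calibration window.
#' @param cfg A [detector_config()].
#' @return List with `calibration` (a `calibration_result`) and `packets`
#'   (data.frame, one row per operational reading, as in [detector_step()]).
#' @export
detector_run <- function(stream, cfg) {
  k <- calibration_samples(cfg)
  if (length(stream) < k) {
    stop_calibration(sprintf(
      "stream has %d readings but the calibration window needs %d",
      length(stream), k))
  }
  cal <- calibrate(stream[seq_len(k)], cfg)
  rest <- stream[-seq_len(k)]
  packets <- if (length(rest) == 0L) {
    detector_step(spectral_reading(rep(1, 18)), cal, 1L)[0L, ]
  } else {
    do.call(rbind, lapply(seq_along(rest), function(i) {
      detector_step(rest[[i]], cal, i)
    }))
  }
  list(calibration = cal, packets = packets)
}
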