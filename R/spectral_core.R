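# Band model and the spectral reading type consumed by every other module.

#' The canonical 18-band wavelength grid
#'
#' Returns the fixed wavelength grid of the 18-channel multispectral triad
#' sensor, from 410 nm to 940 nm, together with single-letter variable codes.
#' The letter codes are firmware-style metadata only; all computation in this
#' package is keyed by wavelength.
#'
#' @return An object of class `band_grid`: a list with
#'   `wavelengths_nm` (integer vector, length 18, strictly increasing) and
#'   `letter_codes` (character vector, length 18, paired 1:1).
#' @examples
#' g <- band_grid()
#' g$wavelengths_nm
#' @export
band_grid <- function() {
  structure(
    list(
      wavelengths_nm = c(410L, 435L, 460L, 485L, 510L, 535L, 560L, 585L,
                         610L, 645L, 680L, 705L, 730L, 760L, 810L, 860L,
                         900L, 940L),
      letter_codes = LETTERS[1:18]
    ),
    class = "band_grid"
  )
}

#' @export
print.band_grid <- function(x, ...) {
  cat("18-band grid:", paste0(x$wavelengths_nm, collapse = ", "), "nm\n")
  invisible(x)
}

# Internal: wavelengths as character keys ("410" ... "940")
band_keys <- function() as.character(band_grid()$wavelengths_nm)

#' Construct a spectral reading
#'
#' A spectral reading is one 18-band vector of relative responsivities, the
#' atomic sensor sample. Responsivity is a unitless, arbitrary-scale,
#' nonnegative quantity; no absolute radiometric calibration is modelled.
#'
#' @param values Numeric vector of length 18. If named, names must be the
#'   band wavelengths in nm (any order); if unnamed, values are taken in
#'   ascending wavelength order of [band_grid()].
#' @return An object of class `spectral_reading`: a named numeric vector of
#'   length 18, names `"410"` ... `"940"` in ascending order.
#' @examples
#' r <- spectral_reading(rep(1, 18))
#' r[["810"]]
#' @export
spectral_reading <- function(values) {
  keys <- band_keys()
  values <- unlist(values, use.names = TRUE)
  if (is.null(names(values)) || all(names(values) == "")) {
    if (length(values) != 18L) {
      stop_schema(sprintf(
        "a spectral reading needs 18 band values, got %d", length(values)))
    }
    names(values) <- keys
  }
  validate_reading(structure(as.numeric(values)[match(keys, names(values))],
                             names = keys, class = "spectral_reading"))
}

#' Validate a spectral reading
#'
#' Checks that all 18 bands of the canonical grid are present and that every
#' responsivity is finite and nonnegative. Returns the reading unchanged on
#' success; the function is idempotent.
#'
#' @param r A [spectral_reading()] or a named numeric vector keyed by
#'   wavelength in nm.
#' @return `r`, as a validated `spectral_reading`.
#' @export
validate_reading <- function(r) {
  keys <- band_keys()
  v <- unclass(r)
  missing <- setdiff(keys, names(v))
  if (length(missing) > 0L) {
    stop_schema(sprintf("reading is missing band(s): %s nm",
                        paste(missing, collapse = ", ")))
  }
  v <- v[keys]
  bad <- !is.finite(v) | v < 0
  if (any(bad)) {
    w <- keys[which(bad)[1L]]
    stop_value(sprintf("band %s nm has invalid responsivity %s (must be finite and >= 0)",
                       w, format(v[[w]])))
  }
  structure(as.numeric(v), names = keys, class = "spectral_reading")
}

#' Extract one band from a reading
#'
#' @param r A [spectral_reading()].
#' @param wavelength_nm Band wavelength in nm (must be on the grid).
#' @return The responsivity at that band.
#' @export
band <- function(r, wavelength_nm) {
  key <- as.character(wavelength_nm)
  if (!key %in% band_keys()) {
    stop_value(sprintf("%s nm is not a band of the 18-band grid", key))
  }
  unclass(r)[[key]]
}

#' Construct a pure-material endmember spectrum
#'
#' An endmember is a labelled pure-material responsivity spectrum under
#' reference illumination, used by the linear-mixing scene simulator
#' (e.g. bare soil, green vegetation).
#'
#' @param name Material label, e.g. `"soil"` or `"vegetation"`.
#' @param spectrum A [spectral_reading()] (or coercible vector).
#' @return An object of class `endmember`: list with `name` and `spectrum`.
#' @seealso [default_endmembers()]
#' @export
endmember <- function(name, spectrum) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, spectrum = spectral_reading(spectrum)),
            class = "endmember")
}

#' @export
print.endmember <- function(x, ...) {
  cat("endmember:", x$name, "\n")
  print(round(unclass(x$spectrum), 4))
  invisible(x)
}

# ---- typed condition helpers (shared across modules) -----------------------

stop_typed <- function(class, message, call. = FALSE) {
  stop(structure(
    class = c(class, "greenonbrown_error", "error", "condition"),
    list(message = message, call = if (call.) sys.call(-1) else NULL)
  ))
}

stop_schema      <- function(msg) stop_typed("gob_schema_error", msg)
stop_value       <- function(msg) stop_typed("gob_value_error", msg)
stop_undefined   <- function(msg) stop_typed("gob_undefined_index", msg)
stop_lookup      <- function(msg) stop_typed("gob_lookup_error", msg)
stop_calibration <- function(msg) stop_typed("gob_calibration_error", msg)
stop_config      <- function(msg) stop_typed("gob_config_error", msg)
stop_format      <- function(msg) stop_typed("gob_format_error", msg)
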