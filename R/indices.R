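# Vegetation indices computed from one 18-band spectral reading.
#
# ENDVI and NDVI are ratios of band sums/differences and are therefore
# invariant under uniform rescaling of the reading; EVI is not (the +1 term
# in its denominator fixes an absolute scale). A zero denominator raises a
# typed undefined-index condition rather than returning NaN, so the detector
# can fail safe (no detection + warning) while calibration fails loud.

#' Enhanced Normalized Difference Vegetation Index (ENDVI)
#'
#' `ENDVI = ((NIR + Green) - 2 Blue) / ((NIR + Green) + 2 Blue)` with the
#' band sums `NIR = R760 + R810 + R860`, `Green = R510 + R535 + R560` and
#' `Blue = R435 + R460 + R485`. Uses blue absorption by chlorophyll instead
#' of red; bounded in \[-1, 1\] for nonnegative readings.
#'
#' @param r A [spectral_reading()].
#' @return Unitless index value.
#' @examples
#' endvi(spectral_reading(rep(0.5, 18)))  # flat spectrum -> 0
#' @export
endvi <- function(r) {
  r <- validate_reading(r)
  nir   <- band(r, 760) + band(r, 810) + band(r, 860)
  green <- band(r, 510) + band(r, 535) + band(r, 560)
  blue  <- band(r, 435) + band(r, 460) + band(r, 485)
  den <- (nir + green) + 2 * blue
  if (den == 0) {
    stop_undefined("ENDVI undefined: NIR, green and blue bands are all zero")
  }
  ((nir + green) - 2 * blue) / den
}

#' Normalized Difference Vegetation Index (NDVI)
#'
#' `NDVI = (R810 - R680) / (R810 + R680)`; high for chlorophyll-bearing
#' vegetation, near zero for bare soil. Bounded in \[-1, 1\].
#'
#' @inheritParams endvi
#' @return Unitless index value.
#' @export
ndvi <- function(r) {
  r <- validate_reading(r)
  a <- band(r, 810); b <- band(r, 680)
  if (a + b == 0) stop_undefined("NDVI undefined: R810 + R680 = 0")
  (a - b) / (a + b)
}

#' Enhanced Vegetation Index (EVI)
#'
#' `EVI = 2.5 (R810 - R680) / (R810 + 6 R680 - 7.5 R435 + 1)`. Single-band
#' form; not invariant under rescaling of the reading because of the `+1`
#' term. The denominator can cross zero for nonphysical band combinations,
#' so it is guarded by `eps`.
#'
#' @inheritParams endvi
#' @param eps Denominator guard: |denominator| below this raises an
#'   undefined-index error. Default `1e-9`.
#' @return Unitless index value.
#' @export
evi <- function(r, eps = 1e-9) {
  r <- validate_reading(r)
  nir <- band(r, 810); red <- band(r, 680); blue <- band(r, 435)
  den <- nir + 6 * red - 7.5 * blue + 1
  if (abs(den) < eps) {
    stop_undefined(sprintf("EVI undefined: denominator %.3g within %g of 0",
                           den, eps))
  }
  2.5 * (nir - red) / den
}

#' Pigment-Specific Normalized Difference (PSND)
#'
#' An NDVI-style ratio pairing the 810 nm NIR band with a pigment-absorption
#' band: `PSND = (R810 - R_p) / (R810 + R_p)`. The default pigment band is
#' 645 nm (nearest grid band to the chlorophyll-b red absorption), which
#' keeps PSND distinct from NDVI's 680 nm; the pairing is configurable.
#'
#' @inheritParams endvi
#' @param pigment_nm Pigment-absorption band in nm (on the grid). Default 645.
#' @param nir_nm NIR band in nm. Default 810.
#' @return Unitless index value in \[-1, 1\].
#' @export
psnd <- function(r, pigment_nm = 645, nir_nm = 810) {
  r <- validate_reading(r)
  a <- band(r, nir_nm); b <- band(r, pigment_nm)
  if (a + b == 0) {
    stop_undefined(sprintf("PSND undefined: R%s + R%s = 0", nir_nm, pigment_nm))
  }
  (a - b) / (a + b)
}

# Registry for user-defined custom indices, keyed "custom:<label>".
.index_registry <- new.env(parent = emptyenv())

#' Register a custom vegetation index
#'
#' Registers `fn` under the name `custom:<label>` for use with
#' [evaluate_index()] and as a detector index choice.
#'
#' @param label Short label, e.g. `"greenness"`.
#' @param fn Function of one argument (a [spectral_reading()]) returning one
#'   unitless number.
#' @return The full index name `"custom:<label>"`, invisibly.
#' @examples
#' register_custom("greenness", function(r) band(r, 560) / band(r, 680))
#' @export
register_custom <- function(label, fn) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            is.function(fn))
  assign(label, fn, envir = .index_registry)
  invisible(paste0("custom:", label))
}

#' Names of available indices
#' @return Character vector: the built-in names plus registered
#'   `custom:<label>` entries.
#' @export
index_names <- function() {
  c("endvi", "ndvi", "evi", "psnd",
    paste0("custom:", ls(.index_registry)))
}

#' Evaluate a named vegetation index
#'
#' Dispatches on an index name: one of `"endvi"`, `"ndvi"`, `"evi"`,
#' `"psnd"`, or `"custom:<label>"` for a label previously passed to
#' [register_custom()].
#'
#' @param name Index name.
#' @param r A [spectral_reading()].
#' @return Unitless index value.
#' @export
evaluate_index <- function(name, r) {
  stopifnot(is.character(name), length(name) == 1L)
  if (startsWith(name, "custom:")) {
    label <- sub("^custom:", "", name)
    if (!exists(label, envir = .index_registry, inherits = FALSE)) {
      stop_lookup(sprintf("no custom index registered under label '%s'", label))
    }
    fn <- get(label, envir = .index_registry, inherits = FALSE)
    return(as.numeric(fn(validate_reading(r))))
  }
  switch(name,
    endvi = endvi(r),
    ndvi  = ndvi(r),
    evi   = evi(r),
    psnd  = psnd(r),
    stop_lookup(sprintf("unknown index '%s' (known: %s)",
                        name, paste(index_names(), collapse = ", ")))
  )
}

#' Compute the standard index set for one reading
#'
#' Convenience wrapper returning the three logged indices (ENDVI, NDVI, EVI)
#' plus any registered custom indices.
#'
#' @inheritParams endvi
#' @param extras Character vector of additional index names to evaluate
#'   (default: all registered custom indices).
#' @return A list with `endvi`, `ndvi`, `evi` and an `extras` named list.
#' @export
compute_indices <- function(r, extras = paste0("custom:", ls(.index_registry))) {
  r <- validate_reading(r)
  out <- list(endvi = endvi(r), ndvi = ndvi(r), evi = evi(r),
              extras = lapply(stats::setNames(as.list(extras), extras),
                              function(nm) evaluate_index(nm, r)))
  out
}
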