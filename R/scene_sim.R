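# Synthetic spectral-scene simulator: a 2-D soil surface with rectangular
# vegetation patches, sensed through a circular cone footprint while moving
# along a transect. Per band, the reading is a linear area-fraction mixture
# of the soil and vegetation endmembers with multiplicative Gaussian noise,
# clipped at zero. Illumination is constant within a run; changing light
# means a new run plus recalibration.

#' Built-in soil and vegetation endmember spectra
#'
#' Reference 18-band responsivity spectra for bare soil and green
#' vegetation. Vegetation shows the chlorophyll signature: low blue and red,
#' a moderate green peak at 560 nm, a steep red edge and high NIR peaking at
#' 810 nm. Soil is spectrally flat-ish, brighter than vegetation in the
#' visible (blue/red), with its gentle maximum at 860 nm. Both materials
#' respond most strongly in the 810/860 nm NIR bands, and the vegetation
#' ENDVI/NDVI/EVI exceed soil's by a wide margin.
#'
#' @return List with `soil` and `vegetation`, both [endmember()] objects.
#' @examples
#' em <- default_endmembers()
#' ndvi(em$vegetation$spectrum) - ndvi(em$soil$spectrum)
#' @export
default_endmembers <- function() {
  veg <- c(0.05, 0.05, 0.06, 0.07, 0.10, 0.13, 0.15, 0.12, 0.08,
           0.06, 0.05, 0.15, 0.45, 0.75, 0.95, 0.93, 0.85, 0.80)
  soil <- c(0.22, 0.24, 0.25, 0.26, 0.27, 0.28, 0.29, 0.30, 0.31,
            0.32, 0.33, 0.35, 0.37, 0.41, 0.44, 0.45, 0.43, 0.42)
  list(soil = endmember("soil", soil),
       vegetation = endmember("vegetation", veg))
}

#' Construct a synthetic scene
#'
#' A rectangular soil surface (origin at (0, 0)) carrying zero or more
#' axis-aligned rectangular vegetation patches.
#'
#' @param width_m,length_m Scene extent in metres (x in `[0, width_m]`,
#'   y in `[0, length_m]`).
#' @param patches data.frame with columns `x`, `y` (patch centre, m) and
#'   `width`, `height` (patch extent, m); may have zero rows.
#' @param soil,vegetation [endmember()] spectra for the background soil and
#'   the patch material. Defaults: [default_endmembers()].
#' @return An object of class `scene`.
#' @examples
#' sc <- scene(2.1, 1.5, data.frame(x = 1.2, y = 0.75,
#'                                  width = 0.076, height = 0.076))
#' @export
scene <- function(width_m, length_m,
                  patches = data.frame(x = numeric(), y = numeric(),
                                       width = numeric(), height = numeric()),
                  soil = default_endmembers()$soil,
                  vegetation = default_endmembers()$vegetation) {
  stopifnot(width_m > 0, length_m > 0,
            all(c("x", "y", "width", "height") %in% names(patches)),
            inherits(soil, "endmember"), inherits(vegetation, "endmember"))
  if (nrow(patches) > 0) {
    if (any(patches$width <= 0) || any(patches$height <= 0)) {
      stop_value("patch dimensions must be > 0")
    }
    inside <- patches$x - patches$width / 2 >= 0 &
      patches$x + patches$width / 2 <= width_m &
      patches$y - patches$height / 2 >= 0 &
      patches$y + patches$height / 2 <= length_m
    if (!all(inside)) stop_value("patches must lie within scene bounds")
  }
  structure(list(width_m = width_m, length_m = length_m,
                 patches = patches, soil = soil, vegetation = vegetation),
            class = "scene")
}

#' Sensor mounting geometry
#'
#' @param height_m Mounting height above ground, metres, > 0.
#' @param fov_half_angle_deg Field-of-view half-angle, degrees. Default 20.5
#'   (triad sensor datasheet).
#' @return An object of class `sensor_geometry` with the derived
#'   `footprint_radius_m = height_m * tan(half-angle)`.
#' @export
sensor_geometry <- function(height_m, fov_half_angle_deg = 20.5) {
  stopifnot(height_m > 0, fov_half_angle_deg > 0, fov_half_angle_deg < 90)
  structure(list(height_m = height_m,
                 fov_half_angle_deg = fov_half_angle_deg,
                 footprint_radius_m =
                   height_m * tan(fov_half_angle_deg * pi / 180)),
            class = "sensor_geometry")
}

#' Vegetation area fraction of the sensor footprint
#'
#' Fraction of the circular footprint disc covered by vegetation patches,
#' computed on a regular raster (default cell 2 mm). Cells are weighted by
#' their exact rectangular overlap with each patch and by an anti-aliased
#' disc-boundary weight, so the boundary quantization error is far below
#' the cell size. Footprint area outside the scene bounds counts as
#' background soil.
#'
#' @param scene A [scene()].
#' @param center Numeric length-2, footprint centre (x, y) in metres; must
#'   lie inside the scene.
#' @param radius Footprint radius in metres, > 0.
#' @param cell_m Raster cell size in metres. Default 0.002.
#' @return Fraction in \[0, 1\].
#' @export
footprint_fraction <- function(scene, center, radius, cell_m = 0.002) {
  stopifnot(inherits(scene, "scene"), length(center) == 2L, radius > 0,
            cell_m > 0)
  if (center[1] < 0 || center[1] > scene$width_m ||
      center[2] < 0 || center[2] > scene$length_m) {
    stop_value(sprintf("footprint centre (%.3f, %.3f) is outside the scene",
                       center[1], center[2]))
  }
  g <- seq(-radius - cell_m / 2, radius + cell_m / 2, by = cell_m)
  xs <- rep(center[1] + g, times = length(g))
  ys <- rep(center[2] + g, each = length(g))
  # disc weight: linear anti-aliasing of the circle boundary across one cell
  d <- sqrt((xs - center[1])^2 + (ys - center[2])^2)
  w_disc <- pmin(1, pmax(0, (radius - d) / cell_m + 0.5))
  keep <- w_disc > 0
  xs <- xs[keep]; ys <- ys[keep]; w_disc <- w_disc[keep]
  # patch weight: exact overlap of the square cell with each rectangle
  w_veg <- rep(0, length(xs))
  p <- scene$patches
  for (i in seq_len(nrow(p))) {
    ox <- pmax(0, pmin(xs + cell_m / 2, p$x[i] + p$width[i] / 2) -
                  pmax(xs - cell_m / 2, p$x[i] - p$width[i] / 2))
    oy <- pmax(0, pmin(ys + cell_m / 2, p$y[i] + p$height[i] / 2) -
                  pmax(ys - cell_m / 2, p$y[i] - p$height[i] / 2))
    cov <- pmin(1, ox * oy / cell_m^2)
    cov[cov > 1 - 1e-9] <- 1  # snap float round-off so pure cases are exact
    w_veg <- pmax(w_veg, cov)
  }
  min(1, max(0, sum(w_disc * w_veg) / sum(w_disc)))
}

#' Simulate one spectral reading at a position
#'
#' Per band: `reading = (f * vegetation + (1 - f) * soil) * (1 + eps)` with
#' `f` the vegetation area fraction of the footprint and
#' `eps ~ Normal(0, noise_sigma)` drawn once per band; negative results are
#' clipped to 0. Noise draws come from the current RNG state.
#'
#' @inheritParams footprint_fraction
#' @param geom A [sensor_geometry()].
#' @param noise_sigma Multiplicative noise standard deviation, >= 0.
#' @return A [spectral_reading()].
#' @export
sense <- function(scene, center, geom, noise_sigma = 0, cell_m = 0.002) {
  stopifnot(inherits(geom, "sensor_geometry"), noise_sigma >= 0)
  f <- footprint_fraction(scene, center, geom$footprint_radius_m, cell_m)
  mix_reading(scene, f, noise_sigma)
}

# Internal: linear mixture of the scene endmembers at vegetation fraction f,
# with per-band multiplicative Gaussian noise, clipped at 0.
mix_reading <- function(scene, f, noise_sigma) {
  mixed <- f * unclass(scene$vegetation$spectrum) +
    (1 - f) * unclass(scene$soil$spectrum)
  if (noise_sigma > 0) {
    mixed <- mixed * (1 + stats::rnorm(length(mixed), 0, noise_sigma))
  }
  spectral_reading(pmax(mixed, 0))
}

#' Plan a straight transect over a scene
#'
#' The sensor sits stationary at `start` for the calibration window, then
#' advances `speed_m_per_s * cycle_seconds` metres per packet towards `end`.
#'
#' @param start,end Numeric length-2 path endpoints (x, y) in metres.
#' @param speed_m_per_s Traverse speed, m/s, > 0. Default 0.10 (the
#'   validation roll speed; no faster than 10 cm/s).
#' @param cycle_seconds Packet cycle, seconds. Default 2.
#' @param noise_sigma Multiplicative spectral noise sd. Default 0.01.
#' @param seed Integer RNG seed for the run.
#' @param strict_speed If TRUE, [simulate_transect()] errors when the speed
#'   exceeds the no-overlap maximum for the geometry.
#' @return An object of class `transect_plan`.
#' @export
transect_plan <- function(start, end, speed_m_per_s = 0.10,
                          cycle_seconds = 2, noise_sigma = 0.01,
                          seed = 1L, strict_speed = FALSE) {
  stopifnot(length(start) == 2L, length(end) == 2L, speed_m_per_s > 0,
            cycle_seconds > 0, noise_sigma >= 0)
  structure(list(start = as.numeric(start), end = as.numeric(end),
                 speed_m_per_s = speed_m_per_s,
                 cycle_seconds = cycle_seconds,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 strict_speed = isTRUE(strict_speed)),
            class = "transect_plan")
}

#' Simulate a full calibrate-then-roll transect
#'
#' Reproduces the validation protocol in software: the sensor calibrates
#' while stationary over bare soil, then rolls along the transect sensing
#' one packet per cycle. Every packet carries its reading, vegetation
#' fraction and binary ground truth; the full packet sequence (calibration
#' plus operation) is also rendered as canonical log records. Fully
#' reproducible from the plan's seed (the global RNG state is preserved).
#'
#' @param scene A [scene()].
#' @param geom A [sensor_geometry()].
#' @param plan A [transect_plan()]; the calibration window is spent
#'   stationary at `plan$start`, which must be over bare soil.
#' @param cfg A [detector_config()]. Its `cycle_seconds` is taken from the
#'   plan's to keep the two clocks identical.
#' @param occupancy_threshold Vegetation area fraction at or above which a
#'   packet's ground truth is "vegetation present". Default 0.25.
#' @param cell_m Footprint raster cell, metres. Default 0.002.
#' @param start_time POSIXct timestamp of packet 1.
#' @return List with `trace` (operational packets: detector numbering,
#'   log numbering, position, `veg_fraction`, `ground_truth_present`,
#'   index value, `detected`, `relay_on`), `calibration`, `log`
#'   (canonical log records for all packets), `truth` (per-log-packet
#'   sidecar: `packet_number`, `veg_fraction`, `ground_truth_present`) and
#'   the echoed inputs.
#' @export
simulate_transect <- function(scene, geom, plan, cfg = detector_config(),
                              occupancy_threshold = 0.25, cell_m = 0.002,
                              start_time = as.POSIXct("2026-06-01 09:00:00",
                                                      tz = "UTC")) {
  stopifnot(inherits(scene, "scene"), inherits(geom, "sensor_geometry"),
            inherits(plan, "transect_plan"), inherits(cfg, "detector_config"),
            occupancy_threshold >= 0, occupancy_threshold <= 1)
  cfg$cycle_seconds <- plan$cycle_seconds
  if (plan$strict_speed) {
    vmax <- 2 * geom$footprint_radius_m / plan$cycle_seconds
    if (plan$speed_m_per_s > vmax) {
      stop_config(sprintf(
        "speed %.3f m/s exceeds the no-overlap maximum %.3f m/s",
        plan$speed_m_per_s, vmax))
    }
  }
  f0 <- footprint_fraction(scene, plan$start, geom$footprint_radius_m, cell_m)
  if (f0 > 0) {
    stop_calibration(paste0(
      "calibration window overlaps vegetation (footprint fraction ",
      format(f0), "); calibrate over a patch of soil with no vegetation"))
  }

  step_m <- plan$speed_m_per_s * plan$cycle_seconds
  delta <- plan$end - plan$start
  dist <- sqrt(sum(delta^2))
  n_op <- as.integer(floor(dist / step_m))
  if (n_op < 1L) stop_config("transect too short for a single moving packet")
  unit <- delta / dist
  pos <- cbind(plan$start[1] + unit[1] * step_m * seq_len(n_op),
               plan$start[2] + unit[2] * step_m * seq_len(n_op))
  if (any(pos[, 1] < 0 | pos[, 1] > scene$width_m |
          pos[, 2] < 0 | pos[, 2] > scene$length_m)) {
    stop_value("transect path leaves the scene")
  }

  n_cal <- calibration_samples(cfg)
  fracs <- vapply(seq_len(n_op), function(i) {
    footprint_fraction(scene, pos[i, ], geom$footprint_radius_m, cell_m)
  }, numeric(1))

  # Seeded run: preserve the caller's RNG state.
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(plan$seed)
  cal_readings <- replicate(n_cal, mix_reading(scene, 0, plan$noise_sigma),
                            simplify = FALSE)
  op_readings <- lapply(fracs, mix_reading, scene = scene,
                        noise_sigma = plan$noise_sigma)

  run <- detector_run(c(cal_readings, op_readings), cfg)
  trace <- cbind(run$packets,
                 data.frame(log_packet = n_cal + seq_len(n_op),
                            x = pos[, 1], y = pos[, 2],
                            veg_fraction = fracs,
                            ground_truth_present =
                              fracs >= occupancy_threshold))

  all_readings <- c(cal_readings, op_readings)
  n_all <- n_cal + n_op
  log <- as_log_records(
    all_readings,
    packet_number = seq_len(n_all),
    timestamp = start_time + (seq_len(n_all) - 1L) * plan$cycle_seconds)
  truth <- data.frame(packet_number = seq_len(n_all),
                      veg_fraction = c(rep(0, n_cal), fracs),
                      ground_truth_present =
                        c(rep(0, n_cal), fracs) >= occupancy_threshold,
                      phase = rep(c("calibration", "operation"),
                                  c(n_cal, n_op)))
  list(trace = trace, calibration = run$calibration, log = log,
       truth = truth, scene = scene, geom = geom, plan = plan, cfg = cfg,
       occupancy_threshold = occupancy_threshold)
}
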