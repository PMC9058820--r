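# Deployment geometry: the single-pixel "cone" footprint is a disc of
# radius h * tan(half-angle). Integer tables report the floor of the exact
# centimetre value; exact values are always exposed alongside so unit
# round-off never propagates into downstream computation.

#' Radius of detection for a given mounting height
#'
#' The sensor's ground footprint is a disc of radius
#' `h * tan(theta)` where `theta` is the field-of-view half-angle
#' (half pixel width). The default 20.5 degrees is the triad sensor's
#' datasheet value.
#'
#' @param height_m Mounting height(s) above ground, metres, > 0.
#' @param fov_half_angle_deg Field-of-view half-angle, degrees, in (0, 90).
#' @return data.frame with `height_m`, `radius_exact_cm` (100 h tan(theta))
#'   and `radius_cm` (integer floor of the exact value).
#' @examples
#' radius_of_detection(c(0.30, 0.41))  # 11 cm and 15 cm
#' @export
radius_of_detection <- function(height_m, fov_half_angle_deg = 20.5) {
  if (any(!is.finite(height_m)) || any(height_m <= 0)) {
    stop_value("height_m must be positive and finite")
  }
  if (length(fov_half_angle_deg) != 1L || !is.finite(fov_half_angle_deg) ||
      fov_half_angle_deg <= 0 || fov_half_angle_deg >= 90) {
    stop_value("fov_half_angle_deg must be in (0, 90)")
  }
  exact <- 100 * height_m * tan(fov_half_angle_deg * pi / 180)
  data.frame(height_m = height_m,
             radius_exact_cm = exact,
             radius_cm = as.integer(floor(exact)))
}

#' Maximum no-overlap traverse speed
#'
#' The fastest the sensor may move such that consecutive footprints do not
#' leave an unsensed gap: one footprint diameter per cycle,
#' `v = 2 r / T`. With the default 2-second cycle and radius in cm, the
#' speed in cm/s equals the radius magnitude.
#'
#' @param radius_cm Detection radius (cm), >= 0; use the *exact* radius for
#'   exact speeds.
#' @param cycle_seconds Sensing cycle period, seconds, > 0. Default 2.
#' @return data.frame with `speed_exact_cm_s` (2 r / T) and `speed_cm_s`
#'   (integer floor).
#' @examples
#' max_speed(radius_of_detection(0.30)$radius_exact_cm)  # 11 cm/s
#' @export
max_speed <- function(radius_cm, cycle_seconds = 2) {
  if (any(!is.finite(radius_cm)) || any(radius_cm < 0)) {
    stop_value("radius_cm must be nonnegative and finite")
  }
  if (length(cycle_seconds) != 1L || !is.finite(cycle_seconds) ||
      cycle_seconds <= 0) {
    stop_value("cycle_seconds must be > 0")
  }
  exact <- 2 * radius_cm / cycle_seconds
  data.frame(speed_exact_cm_s = exact, speed_cm_s = as.integer(floor(exact)))
}

#' Build a deployment plan
#'
#' Collects the geometry of one deployment (height, field of view, cycle
#' time) plus the optional crop parameters needed by the feasibility rules
#' of [check_deployment()].
#'
#' @inheritParams radius_of_detection
#' @param cycle_seconds Sensing cycle, seconds. Default 2.
#' @param plant_spacing_m Expected spacing between plants (optional).
#' @param plant_width_m Expected plant width (optional).
#' @param max_plant_height_m Tallest expected plant (optional).
#' @return An object of class `deployment_plan` with the derived
#'   `radius_exact_cm`, `radius_cm`, `max_speed_cm_s` fields.
#' @export
deployment_plan <- function(height_m, fov_half_angle_deg = 20.5,
                            cycle_seconds = 2, plant_spacing_m = NULL,
                            plant_width_m = NULL, max_plant_height_m = NULL) {
  stopifnot(length(height_m) == 1L)
  r <- radius_of_detection(height_m, fov_half_angle_deg)
  v <- max_speed(r$radius_exact_cm, cycle_seconds)
  structure(list(height_m = height_m,
                 fov_half_angle_deg = fov_half_angle_deg,
                 cycle_seconds = cycle_seconds,
                 radius_exact_cm = r$radius_exact_cm,
                 radius_cm = r$radius_cm,
                 max_speed_exact_cm_s = v$speed_exact_cm_s,
                 max_speed_cm_s = v$speed_cm_s,
                 plant_spacing_m = plant_spacing_m,
                 plant_width_m = plant_width_m,
                 max_plant_height_m = max_plant_height_m),
            class = "deployment_plan")
}

#' Check the three deployment feasibility rules
#'
#' Rule 1: double the detection radius must be smaller than the expected
#' plant spacing (so each plant triggers separately). Rule 2: the sensor
#' must clear the tallest expected plant. Rule 3: plant width must be at
#' least 50% of the detection radius (smaller fractions were not
#' validated). Rules whose crop parameter is absent are reported as not
#' evaluated.
#'
#' @param plan A [deployment_plan()].
#' @return data.frame with `rule`, `pass` (logical, NA if not evaluated)
#'   and `margin_m` (slack in metres; positive means pass).
#' @export
check_deployment <- function(plan) {
  stopifnot(inherits(plan, "deployment_plan"))
  r_m <- plan$radius_exact_cm / 100
  rules <- list(
    list(rule = "spacing_exceeds_footprint_diameter",
         value = plan$plant_spacing_m,
         margin = function(p) p - 2 * r_m),
    list(rule = "sensor_clears_tallest_plant",
         value = plan$max_plant_height_m,
         margin = function(p) plan$height_m - p),
    list(rule = "plant_width_at_least_half_radius",
         value = plan$plant_width_m,
         margin = function(p) p - 0.5 * r_m)
  )
  out <- lapply(rules, function(x) {
    if (is.null(x$value)) {
      data.frame(rule = x$rule, pass = NA, margin_m = NA_real_)
    } else {
      m <- x$margin(x$value)
      data.frame(rule = x$rule, pass = m > 0, margin_m = m)
    }
  })
  do.call(rbind, out)
}

#' Deployment geometry table over a set of heights
#'
#' @inheritParams radius_of_detection
#' @param cycle_seconds Sensing cycle, seconds. Default 2.
#' @return data.frame: `height_m`, `radius_cm`, `max_speed_cm_s` (integer,
#'   floor-reported) plus the exact values.
#' @examples
#' plan_table(c(0.30, 0.41))
#' @export
plan_table <- function(height_m, fov_half_angle_deg = 20.5, cycle_seconds = 2) {
  r <- radius_of_detection(height_m, fov_half_angle_deg)
  v <- max_speed(r$radius_exact_cm, cycle_seconds)
  data.frame(height_m = r$height_m,
             radius_cm = r$radius_cm,
             max_speed_cm_s = v$speed_cm_s,
             radius_exact_cm = r$radius_exact_cm,
             max_speed_exact_cm_s = v$speed_exact_cm_s)
}
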