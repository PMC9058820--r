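# Calibration arithmetic is exercised through a custom index that simply
# reads one band, so baseline/offset/threshold numbers can be set exactly.

local({
  register_custom("b410", function(r) band(r, 410))
})

reading_410 <- function(x) reading_from(`410` = x)

test_that("calibration aggregates soil index values and adds the offset exactly", {
  cfg <- detector_config(index_name = "custom:b410", offset = 0.05)
  cal <- calibrate(replicate(15, reading_410(0.20), simplify = FALSE), cfg)
  expect_identical(cal$threshold, cal$baseline + cal$offset)
  expect_equal(cal$threshold, 0.25, tolerance = 1e-15)
  expect_identical(cal$n_samples, 15L)

  three <- lapply(c(0.1, 0.2, 0.3), reading_410)
  cal_mean <- calibrate(three, detector_config("custom:b410", offset = 0))
  expect_equal(cal_mean$baseline, 0.2, tolerance = 1e-15)
  cal_max <- calibrate(three, detector_config("custom:b410", offset = 0.05,
                                              aggregator = "max"))
  expect_equal(cal_max$threshold, 0.35, tolerance = 1e-15)
})

test_that("calibration fails loud on empty input or undefined soil index", {
  cfg <- detector_config("ndvi")
  expect_error(calibrate(list(), cfg), class = "gob_calibration_error")
  # a soil sample with R810 = R680 = 0 makes NDVI undefined -> hard error
  bad <- reading_from(`810` = 0, `680` = 0)
  expect_error(calibrate(list(random_reading(), bad), cfg),
               class = "gob_calibration_error")
})

test_that("detection requires strictly exceeding the threshold; relay mirrors it", {
  cfg <- detector_config("custom:b410", offset = 0.05)
  cal <- calibrate(replicate(5, reading_410(0.20), simplify = FALSE), cfg)

  above <- detector_step(reading_410(0.30), cal, 1)
  expect_true(above$detected); expect_true(above$relay_on)

  at <- detector_step(reading_410(cal$threshold), cal, 2)
  expect_false(at$detected); expect_false(at$relay_on)

  below <- detector_step(reading_410(0.10), cal, 3)
  expect_false(below$detected); expect_false(below$relay_on)

  # undefined index while moving: no detection + warning flag, no error
  cfg_n <- detector_config("ndvi", offset = 0.05)
  cal_n <- calibrate(replicate(5, random_reading(), simplify = FALSE), cfg_n)
  und <- detector_step(reading_from(`810` = 0, `680` = 0), cal_n, 4)
  expect_false(und$detected)
  expect_true(und$undefined_index)
  expect_true(is.na(und$index_value))
})

test_that("the run loop splits calibration window from packets deterministically", {
  cfg <- detector_config("endvi", offset = 0.05)
  expect_identical(calibration_samples(cfg), 15L)

  run <- detector_run(soil_veg_stream(15, 5), cfg)
  expect_identical(nrow(run$packets), 5L)
  expect_identical(run$packets$packet_number, 1:5)
  expect_true(all(run$packets$detected))   # vegetation far above soil + 0.05

  soil_only <- detector_run(soil_veg_stream(20, 0), cfg)
  expect_false(any(soil_only$packets$detected))  # soil == baseline < threshold

  expect_error(detector_run(soil_veg_stream(10, 0), cfg),
               class = "gob_calibration_error")

  set.seed(99)
  stream <- replicate(25, noisy_soil_reading(0.05), simplify = FALSE)
  expect_identical(detector_run(stream, cfg), detector_run(stream, cfg))
})

test_that("run trace equals an independently coded calibrate-and-compare loop", {
  cfg <- detector_config("endvi", offset = 0.03)
  set.seed(123)
  stream <- c(replicate(15, noisy_soil_reading(0.05), simplify = FALSE),
              lapply(seq(0, 1, length.out = 10), function(f) {
                em <- default_endmembers()
                spectral_reading(f * unclass(em$vegetation$spectrum) +
                                 (1 - f) * unclass(em$soil$spectrum))
              }))
  run <- detector_run(stream, cfg)
  # oracle loop: positional-formula ENDVI, mean baseline, strict comparison
  vals <- vapply(stream, function(r) oracle_endvi(unname(unclass(r))),
                 numeric(1))
  thr <- mean(vals[1:15]) + 0.03
  expect_equal(run$calibration$threshold, thr, tolerance = 1e-12)
  expect_identical(run$packets$detected, vals[16:25] > thr)
  expect_equal(run$packets$index_value, vals[16:25], tolerance = 1e-12)
})

test_that("raising the offset only shrinks the detection set", {
  set.seed(5)
  stream <- c(replicate(15, noisy_soil_reading(0.05), simplify = FALSE),
              replicate(30, {
                f <- stats::runif(1)
                em <- default_endmembers()
                spectral_reading(pmax((f * unclass(em$vegetation$spectrum) +
                  (1 - f) * unclass(em$soil$spectrum)) *
                  (1 + stats::rnorm(18, 0, 0.05)), 0))
              }, simplify = FALSE))
  offsets <- c(0, 0.02, 0.05, 0.1, 0.3, 1)
  detected <- lapply(offsets, function(o) {
    run <- detector_run(stream, detector_config("endvi", offset = o))
    which(run$packets$detected)
  })
  for (i in seq_along(offsets)[-1]) {
    expect_true(all(detected[[i]] %in% detected[[i - 1]]))
  }
})

test_that("soil baseline converges to the noisy-index mean at the 1/sqrt(n) rate", {
  sigma <- 0.05
  cfg <- detector_config("endvi", offset = 0)
  set.seed(2026)
  # large-sample mean of the noisy soil ENDVI, via the vectorized oracle
  soil <- unclass(default_endmembers()$soil$spectrum)
  noise <- matrix(stats::rnorm(2e5 * 18, 0, sigma), ncol = 18)
  mu <- mean(oracle_endvi_mat(sweep(pmax(1 + noise, 0), 2, soil, `*`)))

  err <- function(n) {
    cal <- calibrate(replicate(n, noisy_soil_reading(sigma),
                               simplify = FALSE), cfg)
    cal$baseline - mu
  }
  reps <- 40
  e15 <- vapply(seq_len(reps), function(i) err(15), numeric(1))
  e1500 <- vapply(seq_len(reps), function(i) err(1500), numeric(1))
  rmse_ratio <- sqrt(mean(e15^2) / mean(e1500^2))
  expect_gt(rmse_ratio, 6)    # expected sqrt(1500/15) = 10
  expect_lt(rmse_ratio, 16)
})
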