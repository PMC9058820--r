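make_records <- function(n, seed = 1) {
  set.seed(seed)
  readings <- replicate(n, random_reading(), simplify = FALSE)
  as_log_records(readings, packet_number = seq_len(n),
                 timestamp = as.POSIXct("2026-06-01 09:00:00", tz = "UTC") +
                   2 * (seq_len(n) - 1))
}

test_that("one record serializes to exactly 23 columns in canonical order", {
  rec <- as_log_records(list(spectral_reading(rep(1, 18))), 1L,
                        as.POSIXct("2026-06-01 09:00:00", tz = "UTC"))
  path <- tempfile(fileext = ".csv")
  write_log(rec, path)
  lines <- readLines(path)
  expect_length(lines, 2L)  # header + one data row
  header <- strsplit(lines[1], ",")[[1]]
  expect_length(header, 23L)
  expect_identical(header[1:2], c("packet_number", "timestamp"))
  expect_identical(header[3:20], wl)
  expect_identical(header[21:23], c("ENDVI", "EVI", "NDVI"))
  # the quoted timestamp's internal comma must not add a column
  expect_identical(ncol(utils::read.csv(path, check.names = FALSE)), 23L)
})

test_that("an empty record set writes a header-only file", {
  path <- tempfile(fileext = ".csv")
  write_log(make_records(3)[0, ], path)
  expect_identical(readLines(path),
                   paste(c("packet_number", "timestamp", wl,
                           "ENDVI", "EVI", "NDVI"), collapse = ","))
})

test_that("write rejects non-monotone packet numbers and inconsistent indices", {
  rec <- make_records(3)
  rec$packet_number <- c(1L, 3L, 2L)
  expect_error(write_log(rec, tempfile()), class = "gob_value_error")
  rec2 <- make_records(3)
  rec2$NDVI[2] <- rec2$NDVI[2] + 0.01  # stored index no longer matches bands
  expect_error(write_log(rec2, tempfile()), class = "gob_value_error")
})

test_that("write -> read round-trips 100 records within tolerance", {
  rec <- make_records(100, seed = 42)
  path <- tempfile(fileext = ".csv")
  write_log(rec, path)
  back <- read_log(path)
  expect_identical(back$packet_number, rec$packet_number)
  expect_equal(as.numeric(back$timestamp), as.numeric(rec$timestamp))
  for (col in c(wl, "ENDVI", "EVI", "NDVI")) {
    expect_equal(back[[col]], rec[[col]], tolerance = 1e-6)
  }
  expect_true(all(check_log_consistency(back)))
})

test_that("writing the same records twice is byte-identical", {
  rec <- make_records(20, seed = 7)
  f1 <- tempfile(); f2 <- tempfile()
  write_log(rec, f1); write_log(rec, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("schema and timestamp problems are reported precisely", {
  rec <- make_records(10)
  path <- tempfile(fileext = ".csv")
  write_log(rec, path)

  # drop the 940 nm column -> schema error naming it
  lines <- readLines(path)
  crippled <- tempfile(fileext = ".csv")
  writeLines(sub("940", "941", lines), crippled)
  expect_error(read_log(crippled), "940", class = "gob_schema_error")

  # corrupt the timestamp of data row 7 -> format error citing row 7
  lines2 <- readLines(path)
  lines2[8] <- sub("\"[^\"]*\"", "\"not-a-time\"", lines2[8])
  corrupt <- tempfile(fileext = ".csv")
  writeLines(lines2, corrupt)
  expect_error(read_log(corrupt), "row 7", class = "gob_format_error")

  expect_error(read_log(tempfile()), class = "gob_io_error")
})

test_that("reading flags records whose stored indices disagree with bands", {
  rec <- make_records(5)
  path <- tempfile(fileext = ".csv")
  write_log(rec, path)
  lines <- readLines(path)
  row3 <- strsplit(lines[4], ",(?=(?:[^\"]*\"[^\"]*\")*[^\"]*$)", perl = TRUE)[[1]]
  row3[length(row3)] <- "0.999"  # tamper with stored NDVI of packet 3
  lines[4] <- paste(row3, collapse = ",")
  writeLines(lines, path)
  expect_warning(back <- read_log(path), "packet")
  expect_identical(which(!check_log_consistency(back)), 3L)
})

test_that("log reanalysis reproduces the live detector trace", {
  sc <- scene(2.1, 1.5, data.frame(x = 1.2, y = 0.75,
                                   width = 0.5, height = 0.5))
  sim <- simulate_transect(sc, sensor_geometry(0.30),
                           transect_plan(c(0.2, 0.75), c(2.0, 0.75),
                                         seed = 42))
  path <- tempfile(fileext = ".csv")
  write_log(sim$log, path)
  cfg <- detector_config("endvi", offset = 0.05)
  re <- reanalyze(read_log(path), cfg, soil_window = 1:15)
  expect_identical(re$trace$detected, sim$trace$detected)
  expect_equal(re$trace$index_value, sim$trace$index_value,
               tolerance = 1e-6)
  expect_equal(re$calibration$threshold, sim$calibration$threshold,
               tolerance = 1e-6)
  expect_identical(re$trace$packet_number, sim$trace$log_packet)
})

test_that("a contaminated soil window can only shrink the detection set", {
  sc <- scene(2.1, 1.5, data.frame(x = 1.2, y = 0.75,
                                   width = 0.5, height = 0.5))
  sim <- simulate_transect(sc, sensor_geometry(0.30),
                           transect_plan(c(0.2, 0.75), c(2.0, 0.75),
                                         seed = 42))
  cfg <- detector_config("endvi", offset = 0.05)
  clean <- reanalyze(sim$log, cfg, soil_window = 1:15)
  # extend the window over vegetation packets: the baseline rises
  dirty <- reanalyze(sim$log, cfg, soil_window = c(1:15, 19:20))
  expect_gt(dirty$calibration$threshold, clean$calibration$threshold)
  dirty_set <- dirty$trace$packet_number[dirty$trace$detected]
  clean_set <- clean$trace$packet_number[clean$trace$detected]
  expect_true(all(dirty_set %in% clean_set))

  huge <- reanalyze(sim$log, detector_config("endvi", offset = 1e6), 1:15)
  expect_false(any(huge$trace$detected))

  expect_error(reanalyze(sim$log, cfg, soil_window = 900:950),
               class = "gob_calibration_error")
})
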