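# Independent oracles and generators shared across tests.
#
# The oracle index functions below are hand-coded directly from the printed
# formulas, addressing bands by *position* in the ascending wavelength list
# (410=1, 435=2, 460=3, 485=4, 510=5, 535=6, 560=7, 585=8, 610=9, 645=10,
# 680=11, 705=12, 730=13, 760=14, 810=15, 860=16, 900=17, 940=18). They
# deliberately share no code with the package implementation.

oracle_endvi <- function(v) {
  nir <- v[14] + v[15] + v[16]
  green <- v[5] + v[6] + v[7]
  blue <- v[2] + v[3] + v[4]
  ((nir + green) - 2 * blue) / ((nir + green) + 2 * blue)
}

oracle_ndvi <- function(v) (v[15] - v[11]) / (v[15] + v[11])

oracle_evi <- function(v) {
  2.5 * (v[15] - v[11]) / (v[15] + 6 * v[11] - 7.5 * v[2] + 1)
}

oracle_psnd <- function(v) (v[15] - v[10]) / (v[15] + v[10])

# Matrix versions (rows = readings) for cheap large-sample statistics.
oracle_endvi_mat <- function(m) {
  nir <- m[, 14] + m[, 15] + m[, 16]
  green <- m[, 5] + m[, 6] + m[, 7]
  blue <- m[, 2] + m[, 3] + m[, 4]
  ((nir + green) - 2 * blue) / ((nir + green) + 2 * blue)
}

wl <- as.character(c(410, 435, 460, 485, 510, 535, 560, 585, 610, 645,
                     680, 705, 730, 760, 810, 860, 900, 940))

random_reading <- function() spectral_reading(stats::runif(18, 0.01, 1))

reading_from <- function(...) {
  # flat base 0.1 overridden by named wavelength values, e.g.
  # reading_from(`810` = 0.8, `680` = 0.1)
  v <- stats::setNames(rep(0.1, 18), wl)
  over <- c(...)
  v[names(over)] <- over
  spectral_reading(v)
}

# Noisy bare-soil reading: default soil endmember with multiplicative
# per-band Gaussian noise (test-side twin of the simulator's noise model).
noisy_soil_reading <- function(sigma) {
  s <- unclass(default_endmembers()$soil$spectrum)
  spectral_reading(pmax(s * (1 + stats::rnorm(18, 0, sigma)), 0))
}

# Monte-Carlo footprint-fraction oracle: uniform points in the disc,
# point-in-rectangle test written against the scene's patch table directly.
mc_footprint_fraction <- function(sc, center, radius, n = 1e5) {
  rr <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  x <- center[1] + rr * cos(th)
  y <- center[2] + rr * sin(th)
  hit <- rep(FALSE, n)
  p <- sc$patches
  for (i in seq_len(nrow(p))) {
    hit <- hit | (abs(x - p$x[i]) <= p$width[i] / 2 &
                  abs(y - p$y[i]) <= p$height[i] / 2)
  }
  mean(hit)
}

# A random 1 x 1 m scene with 1-3 patches kept inside the bounds.
random_scene <- function() {
  k <- sample(1:3, 1)
  cx <- stats::runif(k, 0.15, 0.85)
  cy <- stats::runif(k, 0.15, 0.85)
  w <- pmin(stats::runif(k, 0.05, 0.3), 2 * pmin(cx, 1 - cx))
  h <- pmin(stats::runif(k, 0.05, 0.3), 2 * pmin(cy, 1 - cy))
  scene(1, 1, data.frame(x = cx, y = cy, width = w, height = h))
}

# Simulator stream helpers used by several detector tests: n constant-soil
# readings followed by m constant-vegetation readings.
soil_veg_stream <- function(n_soil, n_veg) {
  em <- default_endmembers()
  c(replicate(n_soil, em$soil$spectrum, simplify = FALSE),
    replicate(n_veg, em$vegetation$spectrum, simplify = FALSE))
}
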