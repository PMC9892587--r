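# Preprocessing chain: SG smoothing, peak detection, centroiding,
# deisotoping, contaminant removal.

gaussian_profile <- function(centers, areas, mz_min, mz_max, step = 0.002,
                             sigma = 0.015) {
  grid <- seq(mz_min, mz_max, by = step)
  y <- numeric(length(grid))
  for (i in seq_along(centers)) {
    y <- y + areas[i] * dnorm(grid, centers[i], sigma)
  }
  data.frame(mz = grid, intensity = y)
}

test_that("SG smoothing preserves constants and linear ramps", {
  p <- prep_params()
  const <- data.frame(mz = seq(700, 701, by = 0.01), intensity = 5)
  expect_equal(smooth_profile(const, p)$intensity, const$intensity,
               tolerance = 1e-9)
  ramp <- data.frame(mz = seq(700, 701, by = 0.01),
                     intensity = seq(0, 1000, length.out = 101))
  expect_equal(smooth_profile(ramp, p)$intensity, ramp$intensity,
               tolerance = 1e-9)
  short <- data.frame(mz = 700 + 0:4 / 100, intensity = rep(1, 5))
  expect_error(smooth_profile(short, p), "window")
})

test_that("smoothing is linear on interior points", {
  p <- prep_params()
  set.seed(3)
  grid <- seq(800, 802, by = 0.01)
  x <- data.frame(mz = grid, intensity = runif(length(grid), 0, 100))
  y <- data.frame(mz = grid, intensity = runif(length(grid), 0, 100))
  combo <- data.frame(mz = grid, intensity = 2 * x$intensity -
                        0.5 * y$intensity)
  interior <- 10:(length(grid) - 10)
  expect_equal(smooth_profile(combo, p)$intensity[interior],
               (2 * smooth_profile(x, p)$intensity -
                  0.5 * smooth_profile(y, p)$intensity)[interior],
               tolerance = 1e-9)
})

test_that("peak detection thresholds apexes and separates valleys", {
  prof <- gaussian_profile(1000.5, 1000 * 0.015 * sqrt(2 * pi), 1000, 1001)
  reg <- detect_peaks(prof, threshold = 700)
  expect_equal(sum(reg$above_threshold), 1L)

  # apex below threshold is reported with intensity recorded as 0
  low <- gaussian_profile(1000.5, 699 * 0.015 * sqrt(2 * pi), 1000, 1001)
  reg_low <- detect_peaks(low, threshold = 700)
  expect_equal(nrow(reg_low), 1L)
  expect_false(reg_low$above_threshold)
  expect_identical(reg_low$apex_intensity, 0)

  two <- gaussian_profile(c(1000.3, 1000.8), rep(1e5, 2), 1000, 1001.2)
  reg2 <- detect_peaks(two, threshold = 700)
  expect_equal(sum(reg2$above_threshold), 2L)
})

test_that("centroiding matches the weighted-mean oracle and width filter", {
  p <- prep_params()
  prof <- gaussian_profile(1000.5, 1e5, 1000, 1001)
  reg <- detect_peaks(prof, 700)
  pk <- centroid_peaks(prof, reg, p)
  expect_equal(nrow(pk), 1L)
  apex_mz <- prof$mz[which.max(prof$intensity)]
  expect_lt(abs(pk$mz - apex_mz), 0.002)   # within one grid step

  # skewed peak: centroid equals the direct weighted mean over the top 80%
  grid <- seq(1000, 1001, by = 0.002)
  y <- 1e4 * dnorm(grid, 1000.5, 0.02) + 6e3 * dnorm(grid, 1000.53, 0.03)
  skew <- data.frame(mz = grid, intensity = y)
  regs <- detect_peaks(skew, 700)
  got <- centroid_peaks(skew, regs, p)
  r <- regs[which.max(regs$apex_intensity), ]
  idx <- r$left:r$right
  top <- idx[y[idx] >= 0.2 * max(y[idx])]
  expect_equal(got$mz[1L], round(sum(grid[top] * y[top]) / sum(y[top]), 3))
  apex <- grid[which.max(y)]
  expect_true(got$mz[1L] > apex)           # pulled toward the heavy tail

  # narrow spike: fewer than 5 points at half height is discarded
  spike <- data.frame(mz = seq(1000, 1001, by = 0.01),
                      intensity = c(rep(0, 48), 400, 1200, 400,
                                    rep(0, 50)))
  sreg <- detect_peaks(spike, 700)
  expect_equal(nrow(centroid_peaks(spike, sreg, p)), 0L)
})

test_that("deisotoping collapses charge-1 envelopes within 700-2000 Da", {
  p <- prep_params()
  chain <- data.frame(mz = c(1000.500, 1001.502, 1002.504),
                      intensity = c(100, 60, 25))
  expect_equal(deisotope(chain, p)$mz, 1000.500)

  pair <- data.frame(mz = c(1000.5, 1001.0), intensity = c(100, 50))
  expect_equal(nrow(deisotope(pair, p)), 2L)  # 0.5 Da is not isotopic

  outside <- data.frame(mz = c(2500.000, 2501.002), intensity = c(100, 60))
  expect_equal(deisotope(outside, p), outside)

  # rising intensity is not an envelope
  rising <- data.frame(mz = c(1000.500, 1001.502), intensity = c(50, 80))
  expect_equal(nrow(deisotope(rising, p)), 2L)
})

test_that("contaminant removal is ppm-bounded and labelled", {
  excl <- read_exclusion_list()
  peaks <- data.frame(mz = c(842.5094, 1000.5), intensity = c(10, 20))
  out <- remove_contaminants(peaks, excl, tol_ppm = 10)
  expect_equal(out$mz, 1000.5)
  expect_equal(attr(out, "removed")$label, "trypsin_autolysis")

  identity <- remove_contaminants(peaks, excl[0L, ], tol_ppm = 10)
  expect_equal(identity$mz, peaks$mz)

  near <- data.frame(mz = 842.5094 * (1 + 15e-6), intensity = 1)
  expect_equal(nrow(remove_contaminants(near, excl, tol_ppm = 10)), 1L)
})

test_that("the chain never increases peak count and recovers truth peaks", {
  truth <- data.frame(mz = c(905.432, 1205.617, 1514.772, 1807.911),
                      intensity = c(4000, 6000, 3500, 5000))
  prof <- render_profile(truth, mz_min = 900, mz_max = 1900,
                         grid_step = 0.002, peak_sigma = 0.015,
                         baseline_sd = 0)
  p <- prep_params()
  sm <- smooth_profile(prof, p)
  regions <- detect_peaks(sm, p$intensity_threshold)
  centroided <- centroid_peaks(sm, regions, p)
  deiso <- deisotope(centroided, p)
  cleaned <- remove_contaminants(deiso, read_exclusion_list(),
                                 p$contaminant_tol_ppm)
  expect_lte(nrow(centroided), sum(regions$above_threshold))
  expect_lte(nrow(deiso), nrow(centroided))
  expect_lte(nrow(cleaned), nrow(deiso))
  # monoisotopic set equals the truth set, positions within half a grid step
  expect_equal(nrow(cleaned), nrow(truth))
  expect_true(all(abs(cleaned$mz - truth$mz) <= 0.001))
})
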