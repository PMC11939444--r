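test_that("petri mask takes pixel centers strictly inside the circle", {
  map <- field_map(power = matrix(1, 5, 5), pixel_size_m = 1e-3,
                   petri_diameter_m = 4e-3)
  msk <- petri_mask(map)
  expect_equal(sum(msk), 9)  # center, 4 edges at r=1mm, 4 corners at sqrt(2)
  expect_false(msk[1, 3])    # r = 2 mm: on the circle, excluded
  expect_true(msk[2, 2])
})

test_that("inhomogeneity matches hand-computed population statistics", {
  expect_equal(inhomogeneity_percent(tiny_map(power = matrix(c(1, 3), 1))),
               50)  # sigma_pop = 1, mean = 2
  expect_equal(inhomogeneity_percent(tiny_map(power = matrix(5, 3, 3))), 0)
  # 16-pixel oracle: direct sums
  set.seed(11)
  p <- matrix(runif(16, 1, 4), 4, 4)
  v <- as.vector(p)
  oracle <- 100 * sqrt(mean((v - mean(v))^2)) / mean(v)
  expect_equal(inhomogeneity_percent(tiny_map(power = p)), oracle)
})

test_that("inhomogeneity is scale-invariant and guards degenerate input", {
  set.seed(4)
  p <- matrix(rlnorm(49), 7, 7)
  base <- inhomogeneity_percent(tiny_map(power = p))
  for (k in c(1e-6, 0.5, 3, 1e4)) {
    expect_equal(inhomogeneity_percent(tiny_map(power = k * p)), base)
  }
  expect_error(inhomogeneity_percent(tiny_map(power = matrix(0, 3, 3))),
               "all-zero")
  expect_error(
    inhomogeneity_percent(field_map(power = matrix(1, 3, 3),
                                    pixel_size_m = 1e-3,
                                    petri_diameter_m = 1e-9)),
    "fewer than 2")
})

test_that("polarization ratios recover constructed component ratios", {
  set.seed(5)
  ex <- cplx(matrix(runif(9, 1, 2), 3, 3))
  make <- function(ez_fac, ey_fac) {
    tiny_map(e = list(x = ex, y = ey_fac * ex, z = ez_fac * ex))
  }
  expect_equal(polarization_ratios(make(0.053, 0.015)),
               c(ez_ex = 0.053, ey_ex = 0.015))
  expect_equal(polarization_ratios(make(0, 0)), c(ez_ex = 0, ey_ex = 0))
  expect_equal(polarization_ratios(make(1, 1)), c(ez_ex = 1, ey_ex = 1))
  z <- cplx(matrix(0, 3, 3))
  expect_error(polarization_ratios(tiny_map(e = list(x = z, y = z, z = z))),
               "undefined")
})

test_that("plane-wave ratio is exact on constructed fields", {
  eta <- 377
  set.seed(6)
  amp <- matrix(runif(16, 0.5, 2), 4, 4)
  zero <- cplx(matrix(0, 4, 4))
  e <- list(x = cplx(amp), y = zero, z = zero)
  h_of <- function(scale) list(x = zero, y = cplx(amp / eta * scale),
                               z = zero)
  expect_equal(plane_wave_ratio(tiny_map(e = e, h = h_of(1))), 1,
               tolerance = 1e-12)
  expect_equal(plane_wave_ratio(tiny_map(e = e, h = h_of(1 / 1.01))), 1.01,
               tolerance = 1e-9)
  expect_error(plane_wave_ratio(tiny_map(e = e)), "without H")
})

test_that("standing-wave superposition departs from the plane-wave identity", {
  eta <- 377
  e1 <- 1.0; e2 <- 0.4  # counter-propagating amplitudes at the plane
  n <- 4
  zero <- cplx(matrix(0, n, n))
  e <- list(x = cplx(matrix(e1 + e2, n, n)), y = zero, z = zero)
  h <- list(x = zero, y = cplx(matrix((e1 - e2) / eta, n, n)), z = zero)
  r <- plane_wave_ratio(tiny_map(e = e, h = h))
  # brute-force both sides: |E|^2/2eta over |Re(0.5 E x H*)|
  oracle <- ((e1 + e2)^2 / (2 * eta)) / (0.5 * (e1 + e2) * (e1 - e2) / eta)
  expect_equal(r, oracle)
  expect_gt(r, 1.5)
})

test_that("field maps round-trip through CSV", {
  map <- gen_field_map(2.9e-3, 7, c(0.053, 0.015), grid_size = 11, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_field_map(map, f)
  back <- read_field_map(f)
  expect_equal(back$e$x, map$e$x)
  expect_equal(back$h$y, map$h$y)
  expect_equal(back$power, map$power)
  expect_equal(inhomogeneity_percent(back), inhomogeneity_percent(map))

  f2 <- tempfile(fileext = ".csv")
  write_power_map(map, f2)
  back2 <- read_power_map(f2)
  expect_equal(back2$power, map$power)
})
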