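test_that("decomposition of a constant series has no oscillatory content", {
  x <- rep(4.2, 64)
  d <- cwt_decompose(x, step = 1)
  expect_s3_class(d, "wavelet_decomposition")
  expect_equal(dim(d$coefficients), c(length(d$scales), 64))
  expect_lt(max(Mod(d$coefficients)), 1e-8 * 4.2)
})

test_that("a pure sinusoid localises at the matching scale", {
  n <- 128
  period <- 16
  x <- sin(2 * pi * (0:(n - 1)) / period) + 2
  d <- cwt_decompose(x, step = 1)
  power <- rowMeans(Mod(d$coefficients)^2)
  s_best <- d$scales[which.max(power)]
  # Morlet (omega0 = 6) Fourier period of scale s is 4*pi*s/(6 + sqrt(38))
  fourier_period <- 4 * pi * s_best / (6 + sqrt(38))
  expect_lt(abs(log(fourier_period / period)), log(1.1))
})

test_that("series shorter than 8 points are rejected", {
  expect_error(cwt_decompose(c(1, 2, 3, 1), step = 1), "too short")
  expect_error(smooth_curve(c(1, 2, 3, 1), step = 1), "too short")
})

test_that("smoothing preserves constant series at any tau", {
  x <- rep(3.7, 60)
  for (tau in c(0.1, 2, 50, 1e6)) {
    s <- smooth_curve(x, step = 1, config = smoothing_config(tau = tau))
    expect_lt(max(abs(s - 3.7)), 1e-6 * 3.7)
  }
})

test_that("large tau reproduces the raw series and tau = 2 smooths it", {
  x <- pulse_series(120, seed = 1)
  loose <- smooth_curve(x, config = smoothing_config(tau = 1e6))
  expect_lt(sqrt(sum((loose - x)^2) / sum(x^2)), 0.05)

  tight <- smooth_curve(x, config = smoothing_config(tau = 2))
  sign_changes <- function(y) sum(diff(sign(diff(y))) != 0)
  expect_lt(sign_changes(tight), sign_changes(x))
})

test_that("reconstruction is linear before the nonnegativity clip", {
  x <- pulse_series(96, seed = 2)
  y <- pulse_series(96, seed = 3)
  cfg <- smoothing_config(tau = 2)
  lhs <- smooth_curve(2.5 * x - 0.8 * y, config = cfg, clip = FALSE)
  rhs <- 2.5 * smooth_curve(x, config = cfg, clip = FALSE) -
    0.8 * smooth_curve(y, config = cfg, clip = FALSE)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("total intensity is approximately conserved at tau = 2", {
  for (seed in 1:5) {
    x <- pulse_series(120, seed = seed)
    s <- smooth_curve(x, config = smoothing_config(tau = 2))
    t <- 0:119
    expect_lt(abs(curve_integral(s, t) - curve_integral(x, t)) /
                curve_integral(x, t), 0.1)
  }
})

test_that("distance to the raw series is non-increasing in tau", {
  taus <- c(0.1, 0.5, 1, 2, 5, 10, 50, 1e3, 1e6)
  for (seed in 1:3) {
    x <- pulse_series(100, seed = seed)
    d <- vapply(taus, function(tau) {
      s <- smooth_curve(x, config = smoothing_config(tau = tau))
      sqrt(sum((s - x)^2))
    }, numeric(1))
    expect_true(all(diff(d) <= 1e-9 * d[1]))
  }
})

test_that("the mexican hat wavelet is supported and behaves sanely", {
  cfg <- smoothing_config("mexican_hat", tau = 1e6)
  x <- pulse_series(100, seed = 4)
  expect_lt(sqrt(sum((smooth_curve(x, config = cfg) - x)^2) / sum(x^2)), 0.05)
  expect_error(smoothing_config("haar"), "unsupported scaling function")
  expect_error(smoothing_config(tau = -1), "positive")
})

test_that("smooth_community smooths per species and drops silent ones", {
  set.seed(9)
  n <- 64
  m <- cbind(sp1 = rpois(n, 4), sp2 = rpois(n, 2), mute = rep(0, n))
  comm <- phenology_community(0:(n - 1), m)
  expect_warning(sm <- smooth_community(comm), "all-zero species: mute")
  expect_equal(sm$species, c("sp1", "sp2"))
  expect_equal(sm$stage, "smoothed")
  expect_true(all(sm$intensity >= 0))
  expect_equal(attr(sm, "dropped"), "mute")

  both_zero <- phenology_community(0:(n - 1),
                                   cbind(a = rep(0, n), b = rep(0, n),
                                         c = rpois(n, 3)))
  expect_warning(expect_error(smooth_community(both_zero),
                              "fewer than 2 species"))
  expect_error(suppressWarnings(smooth_community(sm)), "already smoothed")
})

test_that("a 40-species community yields 40 smoothed curves", {
  comm <- simulate_case("a", grid_length = 120, stage = "raw")
  sm <- smooth_community(comm)
  expect_equal(length(sm$species), 40)
  expect_equal(dim(sm$intensity), c(120, 40))
})
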