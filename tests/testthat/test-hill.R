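test_that("relative intensities are positive shares summing to one", {
  fx <- fixture_communities()
  p <- relative_intensities(fx$constants2)     # areas 40 vs 120
  expect_equal(unname(p), c(0.25, 0.75))
  expect_equal(sum(p), 1, tolerance = 1e-12)

  comm <- simulate_case("a", grid_length = 120)
  p40 <- relative_intensities(comm)
  expect_equal(unname(p40), rep(0.025, 40), tolerance = 1e-12)

  tg <- 0:20
  z <- phenology_community(tg, cbind(a = rep(1, 21), b = rep(0, 21)),
                           stage = "smoothed")
  expect_error(relative_intensities(z), "zero total intensity")
})

test_that("the Rao factor matches closed forms", {
  d2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(rao_factor(d2, c(0.5, 0.5)), 0.5)
  expect_equal(rao_factor(matrix(0, 3, 3), rep(1 / 3, 3)), 0)
  # S disjoint equal-weight species: Q = (S-1)/S
  for (S in c(2, 5, 40)) {
    d <- 1 - diag(S)
    expect_equal(rao_factor(d, rep(1 / S, S)), (S - 1) / S, tolerance = 1e-12)
  }
  expect_error(rao_factor(d2, c(1, 1, 1)), "does not match")
})

test_that("identical curves collapse to zero and disjoint equal curves to S", {
  for (S in c(2, 40)) {
    d <- 1 - diag(S)
    p <- rep(1 / S, S)
    expect_equal(hill_pd(d, p, c(0, 0.5, 1, 1.5, 2)), rep(S, 5),
                 tolerance = 1e-9)
  }
  expect_equal(hill_pd(matrix(0, 4, 4), rep(0.25, 4), c(0, 1, 2)),
               c(0, 0, 0))
})

test_that("package qPD agrees with the explicit-loop oracle on all
          step-curve fixtures", {
  for (comm in fixture_communities()) {
    d <- distance_matrix(comm)
    p <- relative_intensities(comm)
    Z <- lapply(seq_along(comm$species), function(j) comm$intensity[, j])
    for (q in c(0, 0.3, 0.7, 1, 1.4, 2, 3)) {
      expect_equal(pd_profile(d, p, 0, 4, 5)$PD[1], hill_pd(d, p, 0))
      expect_equal(hill_pd(d, p, q), oracle_qpd(comm$times, Z, q),
                   tolerance = 1e-9)
    }
  }
})

test_that("the q = 1 limit is continuous", {
  for (comm in fixture_communities()) {
    d <- distance_matrix(comm)
    p <- relative_intensities(comm)
    at1 <- hill_pd(d, p, 1)
    if (at1 == 0) next
    for (eps in c(1e-4, -1e-4)) {
      expect_lt(abs(hill_pd(d, p, 1 + eps) - at1) / at1, 1e-3)
    }
  }
})

test_that("profiles are non-increasing in q and invariant to common
          rescalings of intensity and time", {
  set.seed(101)
  for (i in 1:25) {
    comm <- simulate_random(S = sample(3:8, 1), grid_length = 96,
                            pattern = "random_pulse",
                            pulse_width = runif(1, 0.1, 0.5),
                            amplitudes = "unequal",
                            amp_ratio = runif(1, 0.5, 0.95), seed = i)
    d <- distance_matrix(comm)
    p <- relative_intensities(comm)
    prof <- pd_profile(d, p, 0, 2, 21)
    expect_true(all(diff(prof$PD) <= 1e-9 * max(prof$PD)))
    expect_true(all(prof$PD >= 0))
    # q = 0 never undershoots the high-q end of the profile
    expect_gte(prof$PD[1], max(prof$PD[prof$q >= 1]) - 1e-9)

    # common intensity rescaling: p, O, Q, qPD all unchanged
    scaled <- comm
    scaled$intensity <- comm$intensity * 7.3
    ds <- distance_matrix(scaled)
    ps <- relative_intensities(scaled)
    expect_equal(ds, d, tolerance = 1e-12)
    expect_equal(ps, p, tolerance = 1e-12)
    expect_equal(hill_pd(ds, ps, c(0, 1, 2)), hill_pd(d, p, c(0, 1, 2)),
                 tolerance = 1e-12)

    # uniform time rescaling changes nothing
    stretched <- phenology_community(comm$times * 4.5, comm$intensity,
                                     stage = "smoothed")
    expect_equal(hill_pd(distance_matrix(stretched),
                         relative_intensities(stretched), c(0, 1, 2)),
                 hill_pd(d, p, c(0, 1, 2)), tolerance = 1e-10)
  }
})

test_that("q = 0 diversity may exceed S when Q < 1", {
  comm <- simulate_case("b", grid_length = 120)
  d <- distance_matrix(comm)
  p <- relative_intensities(comm)
  expect_lt(rao_factor(d, p), 1)
  expect_gt(hill_pd(d, p, 0), 40)
})

test_that("invalid orders and profile ranges are rejected", {
  d <- 1 - diag(3)
  p <- rep(1 / 3, 3)
  expect_error(hill_pd(d, p, -0.5), "nonnegative")
  expect_error(pd_profile(d, p, 1, 1), "q_min < q_max")
  expect_error(pd_profile(d, p, 0, 2, steps = 1), "at least 2")
})

test_that("the phenohill fit object exposes the standard surface", {
  fit <- phenohill(simulate_case("b", grid_length = 120))
  expect_s3_class(fit, "phenohill")
  expect_equal(fit$S, 40)
  expect_named(coef(fit), c("qPD(q=0)", "qPD(q=1)", "qPD(q=2)"))
  expect_equal(unname(coef(fit)[1]), fit$profile$PD[fit$profile$q == 0])
  expect_equal(predict(fit, q = c(0, 1, 2)), unname(fit$hill))
  out <- capture.output(print(fit))
  expect_true(any(grepl("qPD", out)))
  s <- summary(fit)
  expect_s3_class(s, "summary.phenohill")
  expect_output(print(s), "diversity profile")
  pf <- tempfile(fileext = ".png")
  grDevices::png(pf); plot(fit); grDevices::dev.off()
  expect_true(file.exists(pf))

  # matrix + times entry point matches the community entry point
  fit2 <- phenohill(simulate_case("b", grid_length = 120)$intensity,
                    times = 0:119, smooth = FALSE)
  expect_equal(fit2$hill, fit$hill, tolerance = 1e-12)
})
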