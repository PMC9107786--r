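# Gaussian activity pulse on [0, period), truncated at 3 sd so that
# pulses spaced >= 6 sd apart have exactly disjoint support; optionally
# wrapped around the period (phenology treated as cyclical).
gaussian_pulse <- function(times, peak, sd, period, wrap = FALSE) {
  d <- times - peak
  if (wrap) d <- d - period * round(d / period)
  v <- exp(-d^2 / (2 * sd^2))
  v[abs(d) >= 3 * sd] <- 0
  v
}

# normalise each column to a prescribed trapezoidal integral
set_integrals <- function(m, times, target) {
  for (j in seq_len(ncol(m))) {
    m[, j] <- m[, j] * target[j] / pracma::trapz(times, m[, j])
  }
  m
}

#' Benchmark community scenarios
#'
#' Generates the nine reference scenarios used to characterise the
#' behaviour of phenological Hill numbers. Cases a-e are 40-species
#' communities, f-i two-species communities:
#'
#' * **a** 40 staggered Gaussian pulses, evenly spaced over the period,
#'   equal intensities. Pulses are narrow enough to be pairwise disjoint,
#'   so every `qPD` equals 40.
#' * **b** as a, but intensities decline geometrically (ratio 0.9):
#'   the profile decreases with q.
#' * **c** 40 identical constant curves: `qPD = 0` at every order.
#' * **d** 40 identical seasonally modulated curves
#'   (`1 + sin(2*pi*t/T)/2`): still identical, so `qPD = 0`.
#' * **e** 40 constant curves of geometrically unequal amplitude:
#'   distances are small but nonzero, so `qPD` is near (not exactly) 0.
#' * **f** 2 disjoint pulses, equal intensities (`qPD = 2`).
#' * **g** 2 partially overlapping pulses, equal intensities.
#' * **h** 2 disjoint pulses, intensities 1 and 0.5.
#' * **i** 2 partially overlapping pulses, intensities 1 and 0.5.
#'
#' Staggered pulses peak at `(k - 1/2) * T / S` with standard deviation
#' `T / (6 S)` (support exactly tiling the period); the "not equally
#' distributed" two-species cases shift the peaks to `0.35 T` and
#' `0.60 T` so the supports overlap. Each curve is rescaled to a
#' prescribed trapezoidal integral, so relative intensities are exact for
#' any grid length. All cases are deterministic.
#'
#' @param case_id One of `"a"` to `"i"`.
#' @param grid_length Number of time points (default 360, one period at
#'   unit spacing); at least 16.
#' @param seed Accepted for interface uniformity with
#'   [simulate_random()]; the benchmark cases involve no randomness.
#' @param stage Stage flag of the result. Simulated curves are already
#'   smooth, so they default to `"smoothed"` and can feed
#'   [distance_matrix()] directly; use `"raw"` to force them through
#'   wavelet smoothing in end-to-end runs.
#' @return A [phenology_community()] on times `0:(grid_length - 1)`.
#' @examples
#' comm <- simulate_case("f")
#' hill_pd(distance_matrix(comm), relative_intensities(comm), c(0, 1, 2))
#' @export
simulate_case <- function(case_id, grid_length = 360, seed = NULL,
                          stage = c("smoothed", "raw")) {
  stage <- match.arg(stage)
  cases <- c("a", "b", "c", "d", "e", "f", "g", "h", "i")
  if (length(case_id) != 1 || !case_id %in% cases) {
    stop("unknown case '", paste(case_id, collapse = ","),
         "'; valid cases: ", paste(cases, collapse = ", "), call. = FALSE)
  }
  grid_length <- as.integer(grid_length)
  if (is.na(grid_length) || grid_length < 16) {
    stop("'grid_length' must be an integer >= 16", call. = FALSE)
  }
  times <- as.numeric(0:(grid_length - 1))
  period <- as.numeric(grid_length)
  s_big <- 40L
  geo <- function(s) 0.9^(0:(s - 1))
  m <- switch(
    case_id,
    a = staggered(times, period, s_big, rep(1, s_big)),
    b = staggered(times, period, s_big, geo(s_big)),
    c = matrix(1, grid_length, s_big),
    d = matrix(1 + 0.5 * sin(2 * pi * times / period), grid_length, s_big),
    e = matrix(1, grid_length, s_big) %*% diag(geo(s_big)),
    f = two_pulses(times, period, c(0.25, 0.75), c(1, 1)),
    g = two_pulses(times, period, c(0.35, 0.60), c(1, 1)),
    h = two_pulses(times, period, c(0.25, 0.75), c(1, 0.5)),
    i = two_pulses(times, period, c(0.35, 0.60), c(1, 0.5))
  )
  colnames(m) <- paste0("sp", seq_len(ncol(m)))
  phenology_community(times, m, stage = stage)
}

staggered <- function(times, period, s, amps) {
  peaks <- (seq_len(s) - 0.5) * period / s
  sd <- period / (6 * s)
  m <- vapply(peaks, gaussian_pulse, numeric(length(times)),
              times = times, sd = sd, period = period)
  set_integrals(m, times, amps)
}

two_pulses <- function(times, period, at, amps) {
  sd <- period / 12    # support width T/2: disjoint at peaks T/4, 3T/4
  m <- vapply(at * period, gaussian_pulse, numeric(length(times)),
              times = times, sd = sd, period = period)
  set_integrals(m, times, amps)
}

#' Random pulse communities for property testing
#'
#' Draws a reproducible community of Gaussian activity pulses. Peak
#' times are uniform on the period (pulses wrap cyclically), pulse
#' standard deviations are log-normal around `pulse_width * T / 6`
#' (log-sd 0.2), and each curve is rescaled so its trapezoidal integral
#' equals its amplitude: amplitudes are all 1 for `amplitudes = "equal"`,
#' a geometric series with ratio `amp_ratio` for `"unequal"`, or any
#' user-supplied positive vector of length `S`.
#'
#' @param S Species count, at least 2.
#' @param grid_length Number of time points, at least 16.
#' @param pattern `"staggered_pulse"` (evenly spaced peaks),
#'   `"random_pulse"` (uniform random peaks), `"constant"` (flat curves)
#'   or `"constant_modulated"` (one shared seasonal curve).
#' @param pulse_width Pulse support as a fraction of the period, in
#'   (0, 1]; default `1/S` (pulses just tile the period).
#' @param amplitudes `"equal"`, `"unequal"`, or a positive numeric
#'   vector of length `S` of target curve integrals.
#' @param amp_ratio Ratio of the geometric amplitude series used by
#'   `amplitudes = "unequal"` (default 0.9).
#' @param seed Integer seed; identical seeds give identical communities.
#' @param stage As in [simulate_case()].
#' @return A [phenology_community()].
#' @examples
#' comm <- simulate_random(S = 5, grid_length = 120, seed = 7)
#' @export
simulate_random <- function(S = 10, grid_length = 120,
                            pattern = c("staggered_pulse", "random_pulse",
                                        "constant", "constant_modulated"),
                            pulse_width = 1 / S,
                            amplitudes = "equal", amp_ratio = 0.9,
                            seed = 1,
                            stage = c("smoothed", "raw")) {
  pattern <- match.arg(pattern)
  stage <- match.arg(stage)
  S <- as.integer(S)
  if (is.na(S) || S < 2) stop("invalid field 'S': need an integer >= 2",
                              call. = FALSE)
  grid_length <- as.integer(grid_length)
  if (is.na(grid_length) || grid_length < 16) {
    stop("invalid field 'grid_length': need an integer >= 16", call. = FALSE)
  }
  if (!is.numeric(pulse_width) || length(pulse_width) != 1 ||
      is.na(pulse_width) || pulse_width <= 0 || pulse_width > 1) {
    stop("invalid field 'pulse_width': need a value in (0, 1]", call. = FALSE)
  }
  if (is.numeric(amplitudes)) {
    if (length(amplitudes) != S || any(!is.finite(amplitudes)) ||
        any(amplitudes <= 0)) {
      stop("invalid field 'amplitudes': numeric amplitudes must be ", S,
           " positive values", call. = FALSE)
    }
    amps <- amplitudes
  } else if (identical(amplitudes, "equal")) {
    amps <- rep(1, S)
  } else if (identical(amplitudes, "unequal")) {
    amps <- amp_ratio^(0:(S - 1))
  } else {
    stop("invalid field 'amplitudes': use \"equal\", \"unequal\" or a ",
         "numeric vector", call. = FALSE)
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("invalid field 'seed': need an integer", call. = FALSE)
  set.seed(seed)
  times <- as.numeric(0:(grid_length - 1))
  period <- as.numeric(grid_length)
  m <- switch(
    pattern,
    constant = matrix(1, grid_length, S),
    constant_modulated = matrix(1 + 0.5 * sin(2 * pi * times / period),
                                grid_length, S),
    staggered_pulse = ,
    random_pulse = {
      peaks <- if (pattern == "staggered_pulse") {
        (seq_len(S) - 0.5) * period / S
      } else {
        stats::runif(S, 0, period)
      }
      sds <- pulse_width * period / 6 *
        exp(stats::rnorm(S, 0, if (pattern == "random_pulse") 0.2 else 0))
      vapply(seq_len(S),
             function(k) gaussian_pulse(times, peaks[k], sds[k], period,
                                        wrap = TRUE),
             numeric(grid_length))
    })
  m <- set_integrals(m, times, amps)
  colnames(m) <- paste0("sp", seq_len(S))
  phenology_community(times, m, stage = stage)
}
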