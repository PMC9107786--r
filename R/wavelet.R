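#' Wavelet smoothing configuration
#'
#' Settings for turning a discrete phenological series into a continuous
#' curve by continuous wavelet transform (CWT).
#'
#' @param scaling_function Mother wavelet: `"morlet"` (default, centre
#'   frequency 6; the usual choice for series with unknown frequency
#'   content) or `"mexican_hat"` (second-derivative-of-Gaussian).
#' @param tau Attenuation threshold, a positive real controlling how much
#'   fine-scale structure survives smoothing. Scales
#'   `s >= s_max / (1 + tau)` of the dyadic ladder are retained, where
#'   `s_max` is the largest analysed scale: `tau` near 0 keeps only the
#'   coarsest scales (a heavily smoothed curve) while `tau -> Inf` keeps
#'   the full ladder and reproduces the raw series. The conventional
#'   default is 2.
#' @param scales_per_octave Number of analysed scales per doubling of
#'   scale (default 12).
#' @return An object of class `smoothing_config`.
#' @seealso [smooth_curve()], [smooth_community()], [cwt_decompose()]
#' @export
smoothing_config <- function(scaling_function = c("morlet", "mexican_hat"),
                             tau = 2, scales_per_octave = 12) {
  if (is.character(scaling_function)) {
    scaling_function <- tolower(scaling_function)
  }
  scaling_function <- tryCatch(
    match.arg(scaling_function),
    error = function(e) stop("unsupported scaling function '",
                             scaling_function[1],
                             "'; available: morlet, mexican_hat",
                             call. = FALSE))
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau <= 0) {
    stop("'tau' must be a single positive number", call. = FALSE)
  }
  scales_per_octave <- as.integer(scales_per_octave)
  if (is.na(scales_per_octave) || scales_per_octave < 1) {
    stop("'scales_per_octave' must be a positive integer", call. = FALSE)
  }
  structure(list(scaling_function = scaling_function, tau = tau,
                 scales_per_octave = scales_per_octave),
            class = "smoothing_config")
}

#' @export
print.smoothing_config <- function(x, ...) {
  cat("Wavelet smoothing: ", x$scaling_function,
      ", tau = ", format(x$tau),
      ", ", x$scales_per_octave, " scales/octave\n", sep = "")
  invisible(x)
}

# Fourier transform of the mother wavelet at s*omega (omega >= 0).
# Morlet: Gaussian around the centre frequency omega0 = 6 (analytic part).
# Mexican hat (DOG, m = 2): (s w)^2 exp(-(s w)^2 / 2), suitably normalised.
wavelet_hat <- function(s_omega, family) {
  switch(family,
         morlet = pi^(-0.25) * exp(-(s_omega - 6)^2 / 2),
         mexican_hat = (s_omega)^2 * exp(-(s_omega)^2 / 2) / sqrt(gamma(2.5)),
         stop("unsupported scaling function '", family, "'", call. = FALSE))
}

# Dyadic scale ladder from 2*step up to (series length)*step.
scale_ladder <- function(n, step, scales_per_octave) {
  s0 <- 2 * step
  n_octaves <- log2(n * step / s0)
  j <- 0:floor(n_octaves * scales_per_octave)
  s0 * 2^(j / scales_per_octave)
}

check_series_length <- function(n) {
  if (n < 8) {
    stop("series of length ", n, " is too short for multi-scale analysis ",
         "(need at least 8 points; 25+ recommended)", call. = FALSE)
  }
}

#' Continuous wavelet transform of a phenological series
#'
#' Decomposes one raw series into a scales-by-time matrix of CWT
#' coefficients on a dyadic scale ladder spanning `2 * step` to
#' `length(x) * step`. The series is reflection-padded to three times its
#' length before the transform (edge-artifact control for short
#' phenology records) and the coefficients are cropped back.
#'
#' @param x Numeric vector of intensities (one species' raw series), or a
#'   [phenology_community()] with a single species.
#' @param step Grid spacing; ignored (taken from the grid) when `x` is a
#'   community.
#' @param config A [smoothing_config()].
#' @return An object of class `wavelet_decomposition`: list with complex
#'   `coefficients` (scales x time), `scales`, `step`, and
#'   `scaling_function`.
#' @examples
#' x <- sin(2 * pi * (0:63) / 16) + 2
#' d <- cwt_decompose(x, step = 1)
#' dim(d$coefficients)
#' @export
cwt_decompose <- function(x, step = 1, config = smoothing_config()) {
  if (inherits(x, "phenology_community")) {
    if (length(x$species) != 1) {
      stop("pass a single-species community or a numeric vector", call. = FALSE)
    }
    step <- time_step(x)
    x <- x$intensity[, 1]
  }
  stopifnot(inherits(config, "smoothing_config"))
  x <- as.numeric(x)
  n <- length(x)
  check_series_length(n)
  scales <- scale_ladder(n, step, config$scales_per_octave)
  xc <- x - mean(x)
  xp <- c(rev(xc), xc, rev(xc))
  np <- length(xp)
  k <- 0:(np - 1)
  omega <- 2 * pi * ifelse(k <= np / 2, k, k - np) / (np * step)
  fx <- stats::fft(xp)
  co <- matrix(0 + 0i, length(scales), n)
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi <- wavelet_hat(s * omega, config$scaling_function) * (omega > 0)
    w <- stats::fft(fx * sqrt(2 * pi * s / step) * psi, inverse = TRUE) / np
    co[j, ] <- w[(n + 1):(2 * n)]
  }
  structure(list(coefficients = co, scales = scales, step = step,
                 scaling_function = config$scaling_function),
            class = "wavelet_decomposition")
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat("Wavelet decomposition (", x$scaling_function, "): ",
      length(x$scales), " scales x ", ncol(x$coefficients),
      " time points; scales [", format(min(x$scales)), ", ",
      format(max(x$scales)), "]\n", sep = "")
  invisible(x)
}

# Scale-band smoother shared by smooth_curve()/smooth_community().
#
# Reconstruction sums the retained scale bands with the standard 1/sqrt(s)
# weights; since each band's frequency response is then proportional to
# the mother wavelet's spectrum at that scale, the retained-over-full
# ratio of responses gives the exact transfer function of the smoother.
# Normalising by the full-ladder response (rather than by a single global
# constant) makes reconstruction with every scale retained exact, which a
# truncated ladder cannot otherwise achieve on short series.
smooth_values <- function(x, step, config, clip = TRUE) {
  x <- as.numeric(x)
  n <- length(x)
  check_series_length(n)
  scales <- scale_ladder(n, step, config$scales_per_octave)
  keep <- scales >= max(scales) / (1 + config$tau)
  mu <- mean(x)
  xp <- c(rev(x - mu), x - mu, rev(x - mu))
  np <- length(xp)
  k <- 0:(np - 1)
  omega_abs <- 2 * pi * pmin(k, np - k) / (np * step)
  h_full <- rowSums(vapply(scales,
                           function(s) wavelet_hat(s * omega_abs,
                                                   config$scaling_function),
                           numeric(np)))
  h_keep <- rowSums(vapply(scales[keep],
                           function(s) wavelet_hat(s * omega_abs,
                                                   config$scaling_function),
                           numeric(np)))
  # frequencies outside the analysed band (response numerically zero)
  # belong to the trend and pass through unchanged
  g <- ifelse(h_full > 1e-10, h_keep / h_full, 1)
  rec <- Re(stats::fft(stats::fft(xp) * g, inverse = TRUE) / np)
  rec <- rec[(n + 1):(2 * n)] + mu
  if (clip) rec <- pmax(rec, 0)
  rec
}

#' Smooth one phenological series
#'
#' Wavelet-smooths a raw series into a continuous phenological curve:
#' the CWT scale bands at scales `>= s_max / (1 + tau)` are summed with
#' the standard `1/sqrt(s)` reconstruction weights (normalised in the
#' frequency domain, see [smoothing_config()]), the series mean is
#' restored, and negative reconstructed values are clipped to 0 so the
#' result is a valid intensity curve.
#'
#' @inheritParams cwt_decompose
#' @param clip Clip negative reconstructed values to 0 (default `TRUE`).
#'   Disable only for diagnostics of the linear reconstruction.
#' @return Numeric vector of smoothed intensities, same length as `x`.
#' @examples
#' set.seed(1)
#' x <- rpois(60, 3 * exp(-((0:59) - 30)^2 / 50))
#' s <- smooth_curve(x, step = 1, config = smoothing_config(tau = 2))
#' @export
smooth_curve <- function(x, step = 1, config = smoothing_config(),
                         clip = TRUE) {
  stopifnot(inherits(config, "smoothing_config"))
  if (inherits(x, "phenology_community")) {
    if (length(x$species) != 1) {
      stop("pass a single-species community or a numeric vector", call. = FALSE)
    }
    step <- time_step(x)
    x <- x$intensity[, 1]
  }
  smooth_values(x, step, config, clip = clip)
}

#' Smooth every species in a community
#'
#' Applies [smooth_curve()] independently to each species' series.
#' Species whose series is identically zero carry no phenological signal
#' and are dropped with a warning; the community must retain at least two
#' species.
#'
#' @param comm A raw [phenology_community()].
#' @param config A [smoothing_config()].
#' @return A `phenology_community` with `stage = "smoothed"`. Dropped
#'   species (if any) are recorded in the `"dropped"` attribute.
#' @export
smooth_community <- function(comm, config = smoothing_config()) {
  stopifnot(inherits(comm, "phenology_community"),
            inherits(config, "smoothing_config"))
  if (comm$stage != "raw") {
    stop("community is already smoothed; smooth_community() expects raw series",
         call. = FALSE)
  }
  zero <- colSums(comm$intensity) == 0
  if (any(zero)) {
    warning("dropping all-zero species: ",
            paste(comm$species[zero], collapse = ", "), call. = FALSE)
  }
  if (sum(!zero) < 2) {
    stop("fewer than 2 species with phenological signal remain; ",
         "cannot form a community", call. = FALSE)
  }
  step <- time_step(comm)
  sm <- apply(comm$intensity[, !zero, drop = FALSE], 2, smooth_values,
              step = step, config = config)
  out <- phenology_community(comm$times, sm, species = comm$species[!zero],
                             stage = "smoothed",
                             gaps = if (!is.null(comm$gaps))
                               comm$gaps[, !zero, drop = FALSE])
  attr(out, "dropped") <- comm$species[zero]
  out
}
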