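#' Phenological Hill numbers of a community
#'
#' One-stop estimator: takes raw or smoothed community phenology,
#' (optionally) wavelet-smooths each species' series, computes the
#' pairwise Morisita-Horn overlap distance matrix, the relative
#' intensities and the standardising factor Q, and evaluates the
#' diversity profile `qPD` over a range of orders.
#'
#' @param x A [phenology_community()], a numeric matrix (rows = times,
#'   columns = species; supply `times`), or a path to a wide-layout CSV.
#' @param q Orders at which the profile is evaluated (default 41 points
#'   on `[0, 2]`).
#' @param smooth Whether to wavelet-smooth the series first. Defaults to
#'   `TRUE` for raw input and `FALSE` for input already flagged as
#'   smoothed.
#' @param config A [smoothing_config()].
#' @param times Sampling times, used only when `x` is a bare matrix.
#' @return An object of class `phenohill` with elements `community`
#'   (smoothed), `distance`, `p`, `S`, `Q`, `profile` (data frame of
#'   `q`, `PD`), `hill` (named `qPD` at q = 0, 1, 2), `dropped`, `call`.
#' @examples
#' fit <- phenohill(simulate_case("b"))
#' fit
#' coef(fit)
#' @export
phenohill <- function(x, q = seq(0, 2, length.out = 41), smooth = NULL,
                      config = smoothing_config(), times = NULL) {
  cl <- match.call()
  if (is.character(x) && length(x) == 1) {
    x <- read_community(x)
  } else if (is.matrix(x) || is.data.frame(x)) {
    if (is.null(times)) {
      stop("supply 'times' when 'x' is a bare matrix", call. = FALSE)
    }
    x <- phenology_community(times, as.matrix(x))
  }
  stopifnot(inherits(x, "phenology_community"))
  if (is.null(smooth)) smooth <- x$stage == "raw"
  dropped <- character(0)
  if (smooth) {
    if (x$stage != "raw") x$stage <- "raw"
    x <- smooth_community(x, config)
    dropped <- attr(x, "dropped")
  } else if (x$stage == "raw") {
    x$stage <- "smoothed"   # caller vouches for the curves
  }
  zero <- apply(x$intensity, 2, curve_integral, times = x$times) <= 0
  if (any(zero)) {
    warning("dropping species with zero total intensity: ",
            paste(x$species[zero], collapse = ", "), call. = FALSE)
    dropped <- c(dropped, x$species[zero])
    x <- x[!zero]
  }
  if (length(x$species) < 2) {
    stop("fewer than 2 species remain; cannot compute diversity",
         call. = FALSE)
  }
  d <- distance_matrix(x)
  p <- relative_intensities(x)
  q <- sort(unique(as.numeric(q)))
  structure(
    list(community = x,
         distance = d,
         p = p,
         S = length(p),
         Q = rao_factor(d, p),
         profile = data.frame(q = q, PD = hill_pd(d, p, q)),
         hill = c("0" = pd_one(d, p, 0), "1" = pd_one(d, p, 1),
                  "2" = pd_one(d, p, 2)),
         dropped = dropped,
         call = cl),
    class = "phenohill")
}

#' @export
print.phenohill <- function(x, digits = 4, ...) {
  cat("Phenological Hill numbers\n")
  cat("  S =", x$S, "species,", length(x$community$times), "time points",
      if (length(x$dropped)) paste0("(", length(x$dropped), " dropped)"),
      "\n")
  cat("  Q =", format(x$Q, digits = digits), "\n")
  cat("  qPD:  q=0:", format(x$hill[["0"]], digits = digits),
      "  q=1:", format(x$hill[["1"]], digits = digits),
      "  q=2:", format(x$hill[["2"]], digits = digits), "\n")
  invisible(x)
}

#' @export
coef.phenohill <- function(object, ...) {
  stats::setNames(object$hill, paste0("qPD(q=", names(object$hill), ")"))
}

#' Evaluate a fitted phenohill object at new orders
#'
#' Re-evaluates the exact diversity (no interpolation) from the stored
#' distance matrix and weights.
#'
#' @param object A [phenohill()] fit.
#' @param q Vector of nonnegative orders (default: the fitted grid).
#' @param ... Unused.
#' @return Numeric vector of `qPD` values.
#' @export
predict.phenohill <- function(object, q = object$profile$q, ...) {
  hill_pd(object$distance, object$p, q)
}

#' @export
summary.phenohill <- function(object, ...) {
  off <- object$distance[upper.tri(object$distance)]
  structure(
    list(S = object$S, Q = object$Q, hill = object$hill,
         n_times = length(object$community$times),
         dropped = object$dropped,
         p_range = range(object$p),
         o_range = range(off),
         o_mean = mean(off),
         profile = object$profile),
    class = "summary.phenohill")
}

#' @export
print.summary.phenohill <- function(x, digits = 4, ...) {
  cat("Phenological Hill numbers\n")
  cat("  community: S =", x$S, "species on", x$n_times, "time points\n")
  if (length(x$dropped)) {
    cat("  dropped species:", paste(x$dropped, collapse = ", "), "\n")
  }
  cat("  relative intensities p: [",
      format(x$p_range[1], digits = digits), ", ",
      format(x$p_range[2], digits = digits), "]\n", sep = "")
  cat("  overlap distances O_ij: mean ", format(x$o_mean, digits = digits),
      ", range [", format(x$o_range[1], digits = digits), ", ",
      format(x$o_range[2], digits = digits), "]\n", sep = "")
  cat("  Q =", format(x$Q, digits = digits), "\n")
  cat("  diversity profile (effective phenological curves):\n")
  sel <- x$profile[x$profile$q %in% intersect(c(0, 0.5, 1, 1.5, 2),
                                              x$profile$q), ]
  if (nrow(sel) == 0) sel <- utils::head(x$profile, 5)
  print(sel, row.names = FALSE, digits = digits)
  invisible(x)
}

#' Plot a phenological diversity profile
#'
#' @param x A [phenohill()] fit.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.phenohill <- function(x, ...) {
  args <- list(x = x$profile$q, y = x$profile$PD, type = "l", lwd = 2,
               xlab = "order q",
               ylab = "qPD (effective phenological curves)",
               main = sprintf("Phenological Hill numbers (S = %d, Q = %.3g)",
                              x$S, x$Q))
  user <- list(...)
  args[names(user)] <- user
  do.call(graphics::plot, args)
  graphics::abline(h = x$S, lty = 3, col = "grey50")
  invisible(x)
}
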