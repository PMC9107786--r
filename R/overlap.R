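#' Integral of a phenological curve over the study interval
#'
#' Composite trapezoidal rule on the sampling grid — the curve is only
#' known at grid points, so higher-order rules add no information.
#'
#' @param values Numeric vector of intensities.
#' @param times Numeric vector of sampling times (same length).
#' @return The trapezoidal integral, a nonnegative real for nonnegative
#'   curves.
#' @examples
#' curve_integral(rep(1, 11), 0:10)   # 10
#' curve_integral(0:10, 0:10)         # 50
#' @export
curve_integral <- function(values, times) {
  if (length(values) != length(times)) {
    stop("'values' and 'times' differ in length", call. = FALSE)
  }
  pracma::trapz(as.numeric(times), as.numeric(values))
}

#' Pairwise overlap distance between two phenological curves
#'
#' The modified Morisita-Horn distance
#' \deqn{O_{ij} = 1 - \frac{2\int z_i(t) z_j(t)\,dt}
#'                        {\int z_i(t)^2 dt + \int z_j(t)^2 dt},}
#' with all integrals taken by the trapezoidal rule over the shared time
#' grid. For nonnegative curves \eqn{O_{ij} \in [0, 1]}: 0 when the two
#' curves are identical and 1 when their activity periods are disjoint.
#' The distance is invariant to multiplying both curves by a common
#' positive constant, but sensitive to relative intensity differences
#' between them.
#'
#' @param zi,zj Numeric intensity vectors on the same grid.
#' @param times Shared sampling times.
#' @return A distance in `[0, 1]`.
#' @examples
#' tg <- 0:10
#' overlap_distance(rep(1, 11), rep(3, 11), tg)   # 1 - 6/10 = 0.4
#' @export
overlap_distance <- function(zi, zj, times) {
  if (length(zi) != length(zj)) {
    stop("curves live on different grids (lengths ", length(zi), " and ",
         length(zj), ")", call. = FALSE)
  }
  cross <- curve_integral(zi * zj, times)
  ssq <- curve_integral(zi^2, times) + curve_integral(zj^2, times)
  if (ssq == 0) {
    stop("overlap distance is undefined: both curves are identically zero",
         call. = FALSE)
  }
  if (all(zi == 0) || all(zj == 0)) {
    warning("one curve is identically zero; distance is 1 by convention ",
            "(such species should normally be dropped upstream)",
            call. = FALSE)
  }
  o <- 1 - 2 * cross / ssq
  # guard against rounding just outside [0, 1] for (near-)identical curves
  min(max(o, 0), 1)
}

#' Community matrix of pairwise overlap distances
#'
#' Applies [overlap_distance()] to every unordered species pair of a
#' smoothed community and assembles the symmetric S x S matrix with a
#' zero diagonal.
#'
#' @param comm A smoothed [phenology_community()] with at least 2 species.
#' @return Square symmetric numeric matrix with species labels as
#'   dimnames; entries in `[0, 1]`, diagonal exactly 0.
#' @seealso [phenohill()] for the full pipeline.
#' @export
distance_matrix <- function(comm) {
  stopifnot(inherits(comm, "phenology_community"))
  s <- length(comm$species)
  if (s < 2) {
    stop("need at least 2 species for a distance matrix", call. = FALSE)
  }
  if (comm$stage != "smoothed") {
    warning("computing overlap distances on raw (unsmoothed) series",
            call. = FALSE)
  }
  z <- comm$intensity
  d <- matrix(0, s, s, dimnames = list(comm$species, comm$species))
  for (i in seq_len(s - 1)) {
    for (j in (i + 1):s) {
      o <- tryCatch(
        overlap_distance(z[, i], z[, j], comm$times),
        error = function(e) {
          stop("overlap distance failed for pair ('", comm$species[i],
               "', '", comm$species[j], "'): ", conditionMessage(e),
               call. = FALSE)
        })
      d[i, j] <- o
      d[j, i] <- o
    }
  }
  d
}
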