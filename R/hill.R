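#' Relative phenological intensities
#'
#' The weight of species *i* is its share of the community's total
#' phenological activity,
#' \eqn{p_i = \int z_i(t) dt / \sum_j \int z_j(t) dt},
#' with trapezoidal integrals over the study interval. Weights are
#' strictly positive and sum to 1.
#'
#' @param comm A smoothed [phenology_community()].
#' @return Named numeric vector of weights `p`, one per species.
#' @examples
#' comm <- simulate_case("f")
#' relative_intensities(comm)
#' @export
relative_intensities <- function(comm) {
  stopifnot(inherits(comm, "phenology_community"))
  ints <- apply(comm$intensity, 2, curve_integral, times = comm$times)
  if (any(ints <= 0)) {
    stop("species with zero total intensity: ",
         paste(comm$species[ints <= 0], collapse = ", "),
         "; drop them (see smooth_community()) before computing weights",
         call. = FALSE)
  }
  p <- ints / sum(ints)
  names(p) <- comm$species
  p
}

#' Rao-type standardising factor Q
#'
#' The mean pairwise overlap distance weighted by relative intensities,
#' \eqn{Q = \sum_i \sum_j O_{ij} p_i p_j}, taken over all ordered pairs
#' (the diagonal contributes 0 since \eqn{O_{ii} = 0}). With distances in
#' `[0, 1]` and a probability weight vector, `Q` lies in `[0, 1]`; it is
#' 0 exactly when all curves are identical.
#'
#' @param d Square distance matrix from [distance_matrix()].
#' @param w Weight vector from [relative_intensities()].
#' @return The scalar `Q`.
#' @export
rao_factor <- function(d, w) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("'d' must be a square matrix", call. = FALSE)
  }
  if (length(w) != nrow(d)) {
    stop("length of 'w' (", length(w), ") does not match matrix dimension (",
         nrow(d), ")", call. = FALSE)
  }
  as.numeric(w %*% d %*% w)
}

# Core order-q phenological Hill number for one q.
# Near q = 1 the exponent 1/(2(1-q)) has a removable singularity; inside
# a width-1e-6 window the Shannon-limit form is used instead.
pd_one <- function(d, w, q, q_window = 1e-6) {
  if (!is.finite(q) || q < 0) {
    stop("order q must be a nonnegative real, got ", format(q), call. = FALSE)
  }
  Q <- rao_factor(d, w)
  if (Q == 0) return(0)   # all curves identical
  pp <- outer(w, w)
  if (abs(q - 1) < q_window) {
    val <- exp(-0.5 * sum(d / Q * pp * log(pp)))
  } else {
    a <- sum(d / Q * pp^q)
    val <- a^(1 / (2 * (1 - q)))
  }
  if (!is.finite(val)) {
    stop("non-finite phenological Hill number at q = ", format(q),
         call. = FALSE)
  }
  val
}

#' Phenological Hill numbers of order q
#'
#' The order-q attribute diversity of a community's phenological curves:
#' \deqn{{}^q\!PD = \Big[\sum_i \sum_j \frac{O_{ij}}{Q} (p_i p_j)^q
#'       \Big]^{\frac{1}{2(1-q)}},}
#' with the Shannon-type limit
#' \deqn{{}^1\!PD = \exp\Big(-\tfrac12 \sum_i \sum_j \frac{O_{ij}}{Q}
#'       p_i p_j \log(p_i p_j)\Big)}
#' at `q = 1`. Units are effective phenological curves: the number of
#' equally weighted, temporally disjoint curves that would give the same
#' diversity. When all curves are identical (`Q = 0`) the measure is 0;
#' for S equally weighted, pairwise disjoint curves it equals S at every
#' order.
#'
#' @param d Distance matrix from [distance_matrix()].
#' @param w Weights from [relative_intensities()].
#' @param q Vector of nonnegative orders (q = 0 richness-like, q = 1
#'   Shannon-like, q = 2 dominance-weighted).
#' @return Numeric vector of `qPD` values, one per order.
#' @examples
#' comm <- simulate_case("a")
#' d <- distance_matrix(comm)
#' w <- relative_intensities(comm)
#' hill_pd(d, w, q = c(0, 1, 2))   # 40 40 40: disjoint, equally weighted
#' @export
hill_pd <- function(d, w, q) {
  vapply(q, function(qq) pd_one(d, w, qq), numeric(1))
}

#' Diversity profile over a range of orders
#'
#' Evaluates [hill_pd()] on an evenly spaced grid of orders. Profiles are
#' non-increasing in q; a flat profile signals equal intensities, a
#' decreasing one signals dominance of some curves.
#'
#' @inheritParams hill_pd
#' @param q_min,q_max Profile range, `0 <= q_min < q_max` (default 0 to 2,
#'   the range ecologists usually inspect).
#' @param steps Number of grid points (default 41).
#' @return A data frame with columns `q` and `PD`, with the species count
#'   `S` and factor `Q` attached as attributes.
#' @export
pd_profile <- function(d, w, q_min = 0, q_max = 2, steps = 41) {
  if (!is.numeric(q_min) || !is.numeric(q_max) || q_min < 0 ||
      q_min >= q_max) {
    stop("need 0 <= q_min < q_max", call. = FALSE)
  }
  if (steps < 2) {
    stop("'steps' must be at least 2", call. = FALSE)
  }
  qs <- seq(q_min, q_max, length.out = steps)
  out <- data.frame(q = qs, PD = hill_pd(d, w, qs))
  attr(out, "S") <- nrow(d)
  attr(out, "Q") <- rao_factor(d, w)
  out
}
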