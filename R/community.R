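#' Construct a community phenology object
#'
#' A `phenology_community` bundles the phenological time series of all
#' species in a community on one shared, evenly spaced time grid. Each
#' column of `intensity` is one species' activity curve (counts or any
#' nonnegative intensity); rows are sampling times.
#'
#' @param times Numeric vector of sampling times, strictly increasing and
#'   evenly spaced (relative tolerance `1e-9` on the step). Units are
#'   arbitrary and never interpreted: the diversity measure is invariant
#'   to a uniform rescaling of the time axis.
#' @param intensity Numeric matrix, `length(times)` rows by `S` columns,
#'   all values finite and nonnegative.
#' @param species Character vector of unique species labels; defaults to
#'   the column names of `intensity`.
#' @param stage Either `"raw"` (discrete field records) or `"smoothed"`
#'   (continuous curves, e.g. after [smooth_community()]).
#' @param gaps Optional logical matrix, same shape as `intensity`,
#'   marking cells that were missing in the source data (stored as 0).
#'
#' @return An object of class `phenology_community`: a list with
#'   elements `times`, `intensity`, `species`, `stage`, `gaps`.
#' @seealso [read_community()], [smooth_community()], [phenohill()]
#' @examples
#' tg <- 0:29
#' z <- cbind(sp1 = exp(-(tg - 10)^2 / 8), sp2 = exp(-(tg - 20)^2 / 8))
#' comm <- phenology_community(tg, z)
#' comm
#' @export
phenology_community <- function(times, intensity,
                                species = colnames(intensity),
                                stage = c("raw", "smoothed"),
                                gaps = NULL) {
  stage <- match.arg(stage)
  times <- as.numeric(times)
  if (is.data.frame(intensity)) intensity <- as.matrix(intensity)
  if (is.vector(intensity)) intensity <- matrix(intensity, ncol = 1)
  storage.mode(intensity) <- "double"
  validate_time_grid(times)
  if (nrow(intensity) != length(times)) {
    stop("'intensity' must have one row per sampling time (",
         length(times), " expected, got ", nrow(intensity), ")", call. = FALSE)
  }
  if (is.null(species)) species <- paste0("sp", seq_len(ncol(intensity)))
  species <- as.character(species)
  if (length(species) != ncol(intensity)) {
    stop("'species' must name every column of 'intensity'", call. = FALSE)
  }
  if (anyDuplicated(species)) {
    stop("duplicate species labels: ",
         paste(unique(species[duplicated(species)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(intensity) || any(!is.finite(intensity))) {
    stop("intensities must be finite (fill gaps with 0 and record them in 'gaps')",
         call. = FALSE)
  }
  if (any(intensity < 0)) {
    bad <- which(intensity < 0, arr.ind = TRUE)[1, ]
    stop("negative intensity at time ", times[bad[1]], ", species '",
         species[bad[2]], "': intensities must be nonnegative", call. = FALSE)
  }
  if (!is.null(gaps)) {
    gaps <- as.matrix(gaps)
    if (!identical(dim(gaps), dim(intensity))) {
      stop("'gaps' must match the shape of 'intensity'", call. = FALSE)
    }
  }
  colnames(intensity) <- species
  rownames(intensity) <- NULL
  structure(
    list(times = times, intensity = intensity, species = species,
         stage = stage, gaps = gaps),
    class = "phenology_community"
  )
}

# Shared time-grid validation: strictly increasing, constant spacing.
validate_time_grid <- function(times) {
  if (length(times) < 2) {
    stop("time grid must contain at least 2 sampling times", call. = FALSE)
  }
  if (anyNA(times) || any(!is.finite(times))) {
    stop("time grid contains non-finite values", call. = FALSE)
  }
  d <- diff(times)
  if (any(d <= 0)) {
    stop("time grid must be strictly increasing", call. = FALSE)
  }
  step <- d[1]
  if (any(abs(d - step) > 1e-9 * abs(step))) {
    stop("time grid is irregular: spacing varies by more than 1e-9 relative ",
         "tolerance (step ", format(step), ")", call. = FALSE)
  }
  invisible(step)
}

#' Spacing of a community's time grid
#' @param comm A `phenology_community`.
#' @return The (constant) spacing between consecutive sampling times.
#' @export
time_step <- function(comm) {
  stopifnot(inherits(comm, "phenology_community"))
  diff(comm$times[1:2])
}

#' @export
print.phenology_community <- function(x, ...) {
  cat("Community phenology (", x$stage, ")\n", sep = "")
  cat("  species:", length(x$species), "  time points:", length(x$times),
      "  step:", format(time_step(x)), "\n")
  cat("  time range: [", format(x$times[1]), ", ",
      format(x$times[length(x$times)]), "]\n", sep = "")
  if (!is.null(x$gaps) && any(x$gaps)) {
    per_sp <- colSums(x$gaps)
    cat("  gaps filled with 0:", sum(x$gaps), "cells in",
        sum(per_sp > 0), "species\n")
  }
  invisible(x)
}

#' @export
as.matrix.phenology_community <- function(x, ...) {
  x$intensity
}

#' Number of species in a community
#' @param comm A `phenology_community`.
#' @return Integer species count.
#' @export
n_species <- function(comm) {
  stopifnot(inherits(comm, "phenology_community"))
  length(comm$species)
}

#' Subset a community by species
#' @param x A `phenology_community`.
#' @param i Species selector (indices, labels or logical vector).
#' @param ... Unused.
#' @return A `phenology_community` with the selected species.
#' @export
`[.phenology_community` <- function(x, i, ...) {
  idx <- seq_along(x$species)
  names(idx) <- x$species
  keep <- idx[i]
  phenology_community(x$times, x$intensity[, keep, drop = FALSE],
                      species = x$species[keep], stage = x$stage,
                      gaps = if (!is.null(x$gaps)) x$gaps[, keep, drop = FALSE])
}
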