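#' Euclidean distance map of a surface image
#'
#' Computes, for every point of the shifted raster, the exact Euclidean
#' distance in mm (spacing-aware) to the nearest raster point carrying
#' strictly positive surface area. Uses the separable exact distance
#' transform, so anisotropic voxel grids are handled without chamfer
#' approximation error.
#'
#' @param surface a [extract_surface()] result with at least one nonzero
#'   point.
#' @return an object of class `distance_map` with elements `grid` (numeric
#'   array of distances in mm, same dims as the surface raster) and
#'   `spacing`.
#' @export
distance_map <- function(surface) {
  stopifnot(inherits(surface, "surface_image"))
  src <- surface$grid > 0
  if (!any(src))
    stop(surfdice_error("no_surface", "surface image has no nonzero points"))
  d <- dim(surface$grid)
  sq <- .edt3d_sq(src, as.integer(d), surface$spacing)
  structure(list(grid = array(sqrt(sq), d), spacing = surface$spacing),
            class = "distance_map")
}

surfdice_error <- function(class, message) {
  structure(class = c(class, "error", "condition"),
            list(message = message, call = NULL))
}

#' Achievable distances between points of a regular 3D raster
#'
#' On a raster with spacing (d1, d2, d3) only a discrete set of distances
#' D = { sqrt((i d1)^2 + (j d2)^2 + (k d3)^2) } can occur between points.
#' Enumerates this set up to `max_distance`.
#'
#' @param spacing voxel spacing in mm.
#' @param max_distance upper bound in mm (inclusive); must be >= 0.
#' @return sorted numeric vector of distinct achievable distances,
#'   starting at 0.
#' @examples
#' achievable_distances(c(1, 1, 1), 2)  # 0, 1, sqrt(2), sqrt(3), 2
#' @export
achievable_distances <- function(spacing, max_distance) {
  spacing <- grid_spacing(spacing)
  if (length(max_distance) != 1L || is.na(max_distance) || max_distance < 0)
    stop("max_distance must be a single non-negative length in mm",
         call. = FALSE)
  eps <- 1e-9 * (1 + max_distance)
  a <- (0:floor((max_distance + eps) / spacing[1])) * spacing[1]
  b <- (0:floor((max_distance + eps) / spacing[2])) * spacing[2]
  cc <- (0:floor((max_distance + eps) / spacing[3])) * spacing[3]
  sq <- outer(outer(a^2, b^2, `+`), cc^2, `+`)
  dd <- sqrt(sq[sq <= (max_distance + eps)^2])
  dd <- sort(dd)
  # collapse floating-point near-duplicates of the same achievable distance
  keep <- c(TRUE, diff(dd) > 1e-9 * pmax(1, dd[-1]))
  dd[keep]
}

#' Round a tolerance to the nearest achievable raster distance
#'
#' Distances between raster points are quantized, so a requested tolerance
#' is snapped to the nearest element of the achievable-distance set before
#' any surface-overlap decision. Exact midpoints resolve to the smaller
#' element (conservative: never enlarges the acceptance band). The
#' operation is idempotent.
#'
#' @param tau requested tolerance in mm, `0 <= tau <= max(dset)`.
#' @param dset sorted achievable distances from [achievable_distances()].
#' @return the element of `dset` nearest to `tau`.
#' @export
round_tolerance <- function(tau, dset) {
  if (length(tau) != 1L || is.na(tau) || tau < 0)
    stop("tau must be a single non-negative tolerance in mm", call. = FALSE)
  if (tau > dset[length(dset)] * (1 + 1e-9) + 1e-12)
    stop("tau exceeds the enumerated achievable-distance bound",
         call. = FALSE)
  i <- findInterval(tau, dset)
  if (i == 0L) return(dset[1])
  if (i >= length(dset)) return(dset[length(dset)])
  lo <- dset[i]; hi <- dset[i + 1L]
  if (tau - lo <= hi - tau) lo else hi
}
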