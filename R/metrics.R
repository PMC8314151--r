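#' Volumetric Dice similarity coefficient
#'
#' The standard overlap measure 2|A n B| / (|A| + |B|) on a shared voxel
#' grid (the common voxel-volume factor cancels). When both masks are empty
#' the ratio is 0/0; this is reported as an explicit undefined value (`NA`)
#' rather than a silent default.
#'
#' @param a,b [binary_mask()] objects on the same grid.
#' @return a value in \[0, 1\], or `NA` when both masks are empty.
#' @export
volumetric_dsc <- function(a, b) {
  assert_comparable(a, b)
  na <- sum(a$grid); nb <- sum(b$grid)
  if (na + nb == 0L) return(NA_real_)
  2 * sum(a$grid & b$grid) / (na + nb)
}

#' Bundle one sparsely labeled evaluation case
#'
#' A case pairs a sparse reference segmentation (ground truth available on
#' a subset of voxels, typically a few axial slices), the labeled region
#' marking which voxels carry annotation, and a dense predicted mask. The
#' reference foreground must lie inside the labeled region; the prediction
#' is restricted to the labeled region before any counting, so unlabeled
#' predicted voxels are neither penalized nor rewarded.
#'
#' @param reference sparse ground-truth [binary_mask()].
#' @param labeled a [labeled_region()] (or logical array) aligned with the
#'   masks.
#' @param prediction dense predicted [binary_mask()].
#' @return an object of class `sparse_case`.
#' @export
sparse_case <- function(reference, labeled, prediction) {
  if (!inherits(labeled, "labeled_region")) labeled <- labeled_region(labeled)
  assert_comparable(reference, prediction)
  if (!identical(dim(labeled$grid), dim(reference$grid)))
    stop("labeled region shape differs from the masks", call. = FALSE)
  if (any(reference$grid & !labeled$grid))
    stop("reference foreground must be contained in the labeled region",
         call. = FALSE)
  structure(list(reference = reference, labeled = labeled,
                 prediction = prediction), class = "sparse_case")
}

#' Aggregated volumetric DSC over sparsely labeled cases
#'
#' Estimates the volumetric DSC when ground truth is only available on
#' labeled voxels, pooling counts over scans and patients:
#' 2 sum_p |M1p n M2p n Lp| / sum_p (|M1p n Lp| + |M2p n Lp|).
#' With a fully labeled single case this reduces exactly to
#' [volumetric_dsc()].
#'
#' @param cases non-empty list of [sparse_case()] objects.
#' @return a value in \[0, 1\], or `NA` when the pooled denominator is 0.
#' @export
sparse_volumetric_dsc <- function(cases) {
  if (!is.list(cases) || length(cases) == 0L)
    stop("cases must be a non-empty list of sparse_case objects",
         call. = FALSE)
  num <- 0; den <- 0
  for (cs in cases) {
    stopifnot(inherits(cs, "sparse_case"))
    L <- cs$labeled$grid
    r <- cs$reference$grid & L
    p <- cs$prediction$grid & L
    num <- num + sum(r & p)
    den <- den + sum(r) + sum(p)
  }
  if (den == 0) return(NA_real_)
  2 * num / den
}

#' Surface Dice similarity coefficient at tolerance tau
#'
#' The fraction of the combined surface area of two masks that lies within
#' physical distance `tau` (mm) of the other mask's surface. Each mask's
#' surface is represented on the half-voxel-shifted raster with per-point
#' marching-cubes areas; a surface point is "acceptable" when its distance
#' map value against the other surface does not exceed the tolerance.
#' Because raster distances are quantized, the requested tolerance is first
#' rounded to the nearest achievable distance (see [round_tolerance()]).
#'
#' Both surfaces empty is 0/0 and flagged undefined; exactly one empty
#' surface gives 0.
#'
#' @param a,b [binary_mask()] objects on the same grid.
#' @param tau tolerance in mm, >= 0.
#' @param table optional [build_neighborhood_table()] for the shared
#'   spacing; built on the fly when omitted.
#' @return an object of class `surface_dsc_result`: a list with `value`
#'   (in \[0, 1\], or `NA` when undefined), `undefined`,
#'   `tolerance_requested`, `tolerance_used` (rounded, mm), `area_1`,
#'   `area_2`, `overlap_area_1`, `overlap_area_2` (mm^2).
#' @examples
#' m <- make_phantom(phantom_spec("sphere", radius_mm = 8,
#'                                shape = c(24, 24, 24)))
#' surface_dsc(m, m, tau = 1)$value  # identical masks: 1
#' @export
surface_dsc <- function(a, b, tau, table = NULL) {
  assert_comparable(a, b)
  if (length(tau) != 1L || is.na(tau) || tau < 0)
    stop("tau must be a single non-negative tolerance in mm", call. = FALSE)
  if (is.null(table)) table <- build_neighborhood_table(a$spacing)

  sa <- extract_surface(a, table)
  sb <- extract_surface(b, table)
  area_1 <- total_area(sa)
  area_2 <- total_area(sb)

  res <- list(value = NA_real_, undefined = FALSE,
              tolerance_requested = tau, tolerance_used = NA_real_,
              area_1 = area_1, area_2 = area_2,
              overlap_area_1 = NA_real_, overlap_area_2 = NA_real_)
  class(res) <- "surface_dsc_result"

  if (area_1 == 0 && area_2 == 0) {
    res$undefined <- TRUE
    return(res)
  }
  if (area_1 == 0 || area_2 == 0) {
    res$value <- 0
    res$overlap_area_1 <- 0
    res$overlap_area_2 <- 0
    return(res)
  }

  # tolerances beyond the grid's physical diagonal saturate; clamp before
  # enumerating the achievable-distance set
  diag_mm <- sqrt(sum((dim(a$grid) * a$spacing)^2))
  tau_eff <- min(tau, diag_mm)
  dset <- achievable_distances(a$spacing, tau_eff + max(a$spacing))
  tau_used <- round_tolerance(tau_eff, dset)
  res$tolerance_used <- tau_used

  da <- distance_map(sa)  # distance to surface of a
  db <- distance_map(sb)  # distance to surface of b
  tol <- tau_used * (1 + 1e-9) + 1e-12
  res$overlap_area_1 <- sum(sa$grid[db$grid <= tol])
  res$overlap_area_2 <- sum(sb$grid[da$grid <= tol])
  res$value <- (res$overlap_area_1 + res$overlap_area_2) / (area_1 + area_2)
  res
}

#' @export
print.surface_dsc_result <- function(x, ...) {
  if (x$undefined) {
    cat("<surface_dsc_result> undefined (both surfaces empty)\n")
  } else {
    cat(sprintf("<surface_dsc_result> value %.4f at tau %.4g mm (rounded %s mm)\n",
                x$value, x$tolerance_requested,
                if (is.na(x$tolerance_used)) "-" else
                  format(x$tolerance_used, digits = 6)))
    cat(sprintf("  surface areas %.2f / %.2f mm^2, within-tolerance %.2f / %.2f mm^2\n",
                x$area_1, x$area_2, x$overlap_area_1, x$overlap_area_2))
  }
  invisible(x)
}
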