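#' Validate a voxel spacing vector
#'
#' A spacing is the physical size of one voxel, in mm, along each of the
#' three array axes (positionally aligned: axis 1 has spacing `d1`, and so
#' on). World coordinates of voxel centers are `index * spacing`.
#'
#' @param spacing numeric vector of length 3, strictly positive and finite.
#' @return the validated spacing as a plain numeric vector.
#' @export
grid_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) ||
      !all(is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 strictly positive, finite lengths in mm",
         call. = FALSE)
  }
  unname(spacing)
}

#' Construct a binary mask on a regular voxel grid
#'
#' The fundamental object of the package: a 3D foreground/background grid
#' with physical voxel spacing in mm. Any numeric input is binarized by
#' "nonzero is foreground".
#'
#' @param grid a 3D array; logical, or numeric/integer (nonzero = foreground).
#' @param spacing voxel spacing in mm, see [grid_spacing()].
#' @return an object of class `binary_mask` with elements `grid` (logical
#'   array) and `spacing`.
#' @examples
#' m <- binary_mask(array(c(0, 1), c(2, 2, 2)), c(1, 1, 2.5))
#' foreground_count(m)
#' @export
binary_mask <- function(grid, spacing = c(1, 1, 1)) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("grid must be a 3D array", call. = FALSE)
  if (any(dim(grid) < 1L))
    stop("all grid dimensions must be >= 1", call. = FALSE)
  if (!is.logical(grid)) {
    if (!is.numeric(grid))
      stop("grid must be logical or numeric", call. = FALSE)
    grid <- array(grid != 0, dim(grid))
  }
  if (anyNA(grid)) stop("grid must not contain NA", call. = FALSE)
  structure(list(grid = grid, spacing = grid_spacing(spacing)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  foreground: %d voxels (%.2f mm^3)\n",
              foreground_count(x),
              foreground_count(x) * prod(x$spacing)))
  invisible(x)
}

#' Number of foreground voxels in a mask
#'
#' The discrete volume `|M|`; the physical volume in mm^3 is
#' `foreground_count(mask) * prod(mask$spacing)`.
#'
#' @param mask a [binary_mask()].
#' @return a non-negative integer count.
#' @export
foreground_count <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$grid)
}

#' Complement of a mask on its own grid
#' @param mask a [binary_mask()].
#' @return a `binary_mask` with foreground and background swapped.
#' @export
complement_mask <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  binary_mask(!mask$grid, mask$spacing)
}

#' Extract one label of an integer-labeled volume as a binary mask
#'
#' @param volume 3D array of integer label codes (0 = background by
#'   convention, but any value may be selected).
#' @param spacing voxel spacing in mm.
#' @param label the integer label to extract.
#' @return a [binary_mask()] that is foreground exactly where
#'   `volume == label`.
#' @export
extract_label <- function(volume, spacing, label) {
  if (!is.array(volume) || length(dim(volume)) != 3L)
    stop("volume must be a 3D array", call. = FALSE)
  if (!is.numeric(volume) || any(volume != round(volume), na.rm = TRUE))
    stop("volume must contain integer label codes", call. = FALSE)
  if (length(label) != 1L || !is.numeric(label) || label != round(label))
    stop("label must be a single integer", call. = FALSE)
  binary_mask(array(volume == label, dim(volume)), spacing)
}

#' Check that two masks live on the same grid
#'
#' Pairwise metrics require identical shape and (to relative 1e-6) identical
#' spacing; there is no implicit resampling. Shape and spacing mismatches
#' are reported distinctly.
#'
#' @param a,b [binary_mask()] objects.
#' @return invisibly `TRUE`; otherwise an error.
#' @export
assert_comparable <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!identical(dim(a$grid), dim(b$grid)))
    stop(sprintf("shape mismatch: (%s) vs (%s)",
                 paste(dim(a$grid), collapse = ","),
                 paste(dim(b$grid), collapse = ",")), call. = FALSE)
  rel <- abs(a$spacing - b$spacing) / pmax(a$spacing, b$spacing)
  if (any(rel > 1e-6))
    stop(sprintf("spacing mismatch: (%s) vs (%s) mm",
                 paste(format(a$spacing), collapse = ","),
                 paste(format(b$spacing), collapse = ",")), call. = FALSE)
  invisible(TRUE)
}

#' A region of labeled (annotated) voxels
#'
#' Marks which voxels of a grid carry ground-truth annotation, e.g. the
#' axial slices that were contoured when the reference segmentation is
#' sparse. Aligned voxel-for-voxel with the masks it annotates.
#'
#' @param grid 3D logical (or numeric, nonzero = labeled) array.
#' @return an object of class `labeled_region`.
#' @export
labeled_region <- function(grid) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("grid must be a 3D array", call. = FALSE)
  if (!is.logical(grid)) grid <- array(grid != 0, dim(grid))
  structure(list(grid = grid), class = "labeled_region")
}

#' Default organ-at-risk taxonomy
#'
#' The 21 head-and-neck organs at risk used throughout the package as the
#' default naming vocabulary for label maps and tolerance sets.
#'
#' @return character vector of 21 unique organ names.
#' @export
organ_taxonomy <- function() {
  c("Brain", "Brainstem",
    "Cochlea-left", "Cochlea-right",
    "Lacrimal-left", "Lacrimal-right",
    "Lens-left", "Lens-right",
    "Lung-left", "Lung-right",
    "Mandible",
    "Optic-nerve-left", "Optic-nerve-right",
    "Orbit-left", "Orbit-right",
    "Parotid-left", "Parotid-right",
    "Spinal-canal", "Spinal-cord",
    "Submandibular-left", "Submandibular-right")
}
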