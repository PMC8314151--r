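#' Build the 256-entry marching-cubes surface-area look-up table
#'
#' Every point of the half-voxel-shifted raster is surrounded by a 2x2x2
#' block of voxels, giving 2^8 = 256 possible binary neighbor
#' constellations. For each constellation this table stores the total area
#' (mm^2) of its marching-cubes triangles, with vertices at edge midpoints
#' scaled by the voxel spacing. Constellations 0 (all background) and 255
#' (all foreground) carry zero area.
#'
#' @param spacing voxel spacing in mm, see [grid_spacing()].
#' @return an object of class `neighborhood_table` with elements `areas`
#'   (numeric length 256, constellation code 0:255 maps to `areas[code + 1]`)
#'   and `spacing`.
#' @examples
#' tab <- build_neighborhood_table(c(1, 1, 1))
#' tab$areas[1 + 1]  # one corner voxel: an equilateral triangle, sqrt(3)/8
#' @export
build_neighborhood_table <- function(spacing) {
  spacing <- grid_spacing(spacing)
  areas <- vapply(mc_tri_table, function(tri) {
    if (length(tri) == 0L) return(0)
    v <- mc_edge_midpoints[tri, , drop = FALSE]
    v <- sweep(v, 2L, spacing, `*`)
    total <- 0
    for (t in seq_len(length(tri) %/% 3L)) {
      p <- v[3L * t - 2L, ]; q <- v[3L * t - 1L, ]; r <- v[3L * t, ]
      total <- total + triangle_area(p, q, r)
    }
    total
  }, numeric(1))
  structure(list(areas = areas, spacing = spacing),
            class = "neighborhood_table")
}

triangle_area <- function(p, q, r) {
  u <- q - p
  v <- r - p
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  0.5 * sqrt(sum(cr^2))
}

#' @export
print.neighborhood_table <- function(x, ...) {
  cat(sprintf(
    "<neighborhood_table> 256 constellations, spacing (%g, %g, %g) mm\n",
    x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  nonzero areas: %d, max %.4f mm^2\n",
              sum(x$areas > 0), max(x$areas)))
  invisible(x)
}

#' Convert a binary mask into a surface image on the shifted raster
#'
#' The surface of a mask lies between voxels. It is represented on a raster
#' shifted by half the voxel spacing on each axis: raster point (i,j,k) of
#' the (n1+1, n2+1, n3+1) grid sits at world position
#' ((i-1/2) d1, (j-1/2) d2, (k-1/2) d3) (1-based indices shown 0-based in
#' the stored array) and holds the look-up area of its 8 neighboring
#' voxels' constellation. Voxels outside the volume count as background, so
#' every foreground component has a closed surface. Points whose 8
#' neighbors are uniform hold zero.
#'
#' @param mask a [binary_mask()].
#' @param table a [build_neighborhood_table()] with matching spacing; built
#'   on the fly when omitted.
#' @return an object of class `surface_image` with elements `grid` (numeric
#'   array of local areas in mm^2, dims `dim(mask$grid) + 1`) and `spacing`.
#' @export
extract_surface <- function(mask, table = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  if (is.null(table)) table <- build_neighborhood_table(mask$spacing)
  stopifnot(inherits(table, "neighborhood_table"))
  rel <- abs(mask$spacing - table$spacing) / pmax(mask$spacing, table$spacing)
  if (any(rel > 1e-6))
    stop("spacing mismatch between mask and neighborhood table", call. = FALSE)
  d <- dim(mask$grid)
  codes <- .surface_codes(mask$grid, as.integer(d))
  grid <- array(table$areas[codes + 1L], d + 1L)
  structure(list(grid = grid, spacing = mask$spacing),
            class = "surface_image")
}

#' @export
print.surface_image <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<surface_image> %d x %d x %d raster points, area %.4f mm^2\n",
              d[1], d[2], d[3], total_area(x)))
  invisible(x)
}

#' Total surface area of a surface image
#'
#' @param surface a [extract_surface()] result.
#' @return the summed area `|S|` in mm^2.
#' @export
total_area <- function(surface) {
  stopifnot(inherits(surface, "surface_image"))
  sum(surface$grid)
}
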