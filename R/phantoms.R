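#' Specify a synthetic phantom mask
#'
#' Phantoms are simple geometric constructions with analytically known
#' properties (voxel counts, surface separations) used as test inputs and
#' worked examples in place of clinical contours. All phantoms are
#' deterministic given the spec (including its `seed` for randomized
#' variants).
#'
#' Kinds and their parameters (all geometric parameters in voxel units
#' unless suffixed `_mm`):
#' \describe{
#'   \item{`sphere`}{`radius_mm`, optional `center` (voxel index, may be
#'     fractional; defaults to the grid center). A voxel is foreground when
#'     its center is strictly inside the radius (world distance).}
#'   \item{`cuboid`}{`origin` (1-based corner voxel index) and `size`
#'     (extent in voxels).}
#'   \item{`slab`}{`axis` (1..3), `from`, `to` (inclusive 1-based slice
#'     range); full-width along the other two axes, so its broad faces are
#'     flat planes.}
#'   \item{`perturbed`}{`base` (another `phantom_spec`), `n_flip` voxels
#'     toggled at random positions, and `shift` (whole-voxel translation,
#'     length 3); uses `seed`.}
#' }
#'
#' @param kind one of `"sphere"`, `"cuboid"`, `"slab"`, `"perturbed"`.
#' @param ... kind-specific parameters, see Details.
#' @param shape grid dimensions in voxels.
#' @param spacing voxel spacing in mm.
#' @param seed integer seed for randomized variants.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind, ..., shape = c(64, 64, 64),
                         spacing = c(1, 1, 1), seed = 1L) {
  kind <- match.arg(kind, c("sphere", "cuboid", "slab", "perturbed"))
  structure(list(kind = kind, shape = as.integer(shape),
                 spacing = grid_spacing(spacing), seed = as.integer(seed),
                 params = list(...)),
            class = "phantom_spec")
}

#' Generate a phantom mask from its spec
#'
#' @param spec a [phantom_spec()].
#' @return a [binary_mask()]; bit-for-bit reproducible from the spec.
#' @examples
#' m <- make_phantom(phantom_spec("cuboid", origin = c(2, 2, 2),
#'                                size = c(4, 4, 4), shape = c(8, 8, 8)))
#' foreground_count(m)  # 64
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sh <- spec$shape; sp <- spec$spacing; p <- spec$params
  grid <- switch(spec$kind,
    sphere = {
      r <- p$radius_mm
      if (is.null(r)) stop("sphere needs radius_mm", call. = FALSE)
      center <- if (is.null(p$center)) (sh + 1) / 2 else p$center
      x <- ((seq_len(sh[1]) - center[1]) * sp[1])^2
      y <- ((seq_len(sh[2]) - center[2]) * sp[2])^2
      z <- ((seq_len(sh[3]) - center[3]) * sp[3])^2
      g <- outer(outer(x, y, `+`), z, `+`) < r^2
      array(g, sh)
    },
    cuboid = {
      o <- p$origin; s <- p$size
      if (is.null(o) || is.null(s))
        stop("cuboid needs origin and size", call. = FALSE)
      if (any(o < 1) || any(o + s - 1 > sh))
        stop("cuboid geometry exceeds the grid", call. = FALSE)
      g <- array(FALSE, sh)
      g[o[1]:(o[1] + s[1] - 1), o[2]:(o[2] + s[2] - 1),
        o[3]:(o[3] + s[3] - 1)] <- TRUE
      g
    },
    slab = {
      ax <- if (is.null(p$axis)) 3L else as.integer(p$axis)
      if (is.null(p$from) || is.null(p$to))
        stop("slab needs from and to", call. = FALSE)
      if (p$from < 1 || p$to > sh[ax] || p$from > p$to)
        stop("slab slice range exceeds the grid", call. = FALSE)
      g <- array(FALSE, sh)
      idx <- list(quote(expr = ), quote(expr = ), quote(expr = ))
      idx[[ax]] <- p$from:p$to
      do.call(`[<-`, c(list(g), idx, list(value = TRUE)))
    },
    perturbed = {
      if (is.null(p$base)) stop("perturbed needs a base spec", call. = FALSE)
      base <- make_phantom(p$base)
      g <- base$grid
      shift <- if (is.null(p$shift)) c(0L, 0L, 0L) else as.integer(p$shift)
      if (any(shift != 0L)) g <- shift_grid(g, shift)
      n_flip <- if (is.null(p$n_flip)) 0L else as.integer(p$n_flip)
      if (n_flip > 0L) {
        rng <- local({
          old <- if (exists(".Random.seed", .GlobalEnv))
            get(".Random.seed", .GlobalEnv) else NULL
          on.exit(if (is.null(old))
            rm(".Random.seed", envir = .GlobalEnv) else
            assign(".Random.seed", old, .GlobalEnv))
          set.seed(spec$seed)
          sample.int(length(g), n_flip)
        })
        g[rng] <- !g[rng]
      }
      g
    })
  binary_mask(grid, sp)
}

shift_grid <- function(g, shift) {
  sh <- dim(g)
  out <- array(FALSE, sh)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    s <- shift[a]
    if (abs(s) >= sh[a]) return(out)
    if (s >= 0) { src[[a]] <- 1:(sh[a] - s); dst[[a]] <- (1 + s):sh[a] }
    else        { src[[a]] <- (1 - s):sh[a]; dst[[a]] <- 1:(sh[a] + s) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- g[src[[1]], src[[2]], src[[3]]]
  out
}

#' Pair of multi-component cube masks with a known surface DSC
#'
#' Builds two masks that are each the union of `n_cubes` identical,
#' disjoint, axis-aligned cubes; the first `displaced` cubes of the second
#' mask are translated along the third axis by `displacement_mm`, far
#' beyond any intended tolerance. Because all components are congruent and
#' mutually separated by more than the tolerance, the surface DSC at any
#' tolerance `tau < gap_mm` equals exactly
#' `(n_cubes - displaced) / n_cubes`.
#'
#' @param n_cubes number of cube components per mask.
#' @param displaced how many cubes of the second mask to translate.
#' @param cube_vox cube edge length in voxels.
#' @param gap_mm in-arrangement gap between neighboring cubes, mm.
#' @param displacement_mm translation of the displaced cubes, mm; must
#'   exceed the intended tolerance plus the cube diagonal.
#' @param spacing voxel spacing in mm (isotropic layouts assumed for the
#'   voxel arithmetic; the default 1 mm grid keeps mm = voxels).
#' @return a list of two [binary_mask()] objects `a` and `b`.
#' @export
make_multi_cube_pair <- function(n_cubes = 20L, displaced = 1L,
                                 cube_vox = 4L, gap_mm = 10,
                                 displacement_mm = 50,
                                 spacing = c(1, 1, 1)) {
  stopifnot(n_cubes >= 1L, displaced >= 0L, displaced <= n_cubes)
  spacing <- grid_spacing(spacing)
  gap_vox <- ceiling(gap_mm / spacing[1])
  disp_vox <- ceiling(displacement_mm / spacing[3])
  pitch <- cube_vox + gap_vox
  nx <- ceiling(sqrt(n_cubes))
  ny <- ceiling(n_cubes / nx)
  sh <- c(1L + (nx - 1L) * pitch + cube_vox + 1L,
          1L + (ny - 1L) * pitch + cube_vox + 1L,
          1L + cube_vox + disp_vox + cube_vox + 1L)
  place <- function(g, o) {
    g[o[1]:(o[1] + cube_vox - 1L), o[2]:(o[2] + cube_vox - 1L),
      o[3]:(o[3] + cube_vox - 1L)] <- TRUE
    g
  }
  ga <- gb <- array(FALSE, sh)
  idx <- 0L
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    if (idx >= n_cubes) break
    idx <- idx + 1L
    o <- c(2L + (ix - 1L) * pitch, 2L + (iy - 1L) * pitch, 2L)
    ga <- place(ga, o)
    if (idx <= displaced) {
      gb <- place(gb, c(o[1], o[2], 2L + cube_vox + disp_vox))
    } else {
      gb <- place(gb, o)
    }
  }
  list(a = binary_mask(ga, spacing), b = binary_mask(gb, spacing))
}

#' Restrict a mask to a sparse axial labeling
#'
#' Emulates ground truth that was contoured only on a subset of axial
#' slices (third array axis): the reference keeps its foreground on the
#' listed slices only, and the labeled region marks those slices in full.
#'
#' @param mask dense reference [binary_mask()].
#' @param slice_indices non-empty vector of 1-based axial slice indices.
#' @return a list with `reference` (sparse [binary_mask()]) and `labeled`
#'   (a [labeled_region()]).
#' @export
make_sparse_labeling <- function(mask, slice_indices) {
  stopifnot(inherits(mask, "binary_mask"))
  slice_indices <- unique(as.integer(slice_indices))
  if (length(slice_indices) == 0L)
    stop("slice_indices must be non-empty", call. = FALSE)
  n3 <- dim(mask$grid)[3]
  if (any(slice_indices < 1L | slice_indices > n3))
    stop("slice_indices out of the axial extent", call. = FALSE)
  lab <- array(FALSE, dim(mask$grid))
  lab[, , slice_indices] <- TRUE
  ref <- mask$grid & lab
  list(reference = binary_mask(ref, mask$spacing),
       labeled = labeled_region(lab))
}
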