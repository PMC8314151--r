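# Independent brute-force oracles used to cross-check the fast paths.

# O(n^2) nearest-surface-point distances: for every raster point, the
# minimum spacing-aware Euclidean distance to any positive-area point.
brute_force_distance_map <- function(surface) {
  d <- dim(surface$grid)
  sp <- surface$spacing
  idx <- which(surface$grid > 0, arr.ind = TRUE)
  src <- sweep(idx - 1, 2, sp, `*`)
  all_idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                                   k = 0:(d[3] - 1)))
  pts <- sweep(all_idx, 2, sp, `*`)
  out <- apply(pts, 1, function(p) sqrt(min(colSums((t(src) - p)^2))))
  array(out, d)  # expand.grid varies the first index fastest
}

# On-the-fly marching-cubes triangulation of every 2x2x2 block: recompute
# each raster point's constellation code in R and sum the geometric areas
# of its triangles directly from edge-midpoint coordinates, independently
# of the compiled code path and the precomputed area look-up.
brute_force_surface_area <- function(mask) {
  g <- mask$grid
  sp <- mask$spacing
  d <- dim(g)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- g
  tri_table <- surfdice:::mc_tri_table
  mids <- surfdice:::mc_edge_midpoints
  tri_area <- function(v) {
    u <- v[2, ] - v[1, ]; w <- v[3, ] - v[1, ]
    cr <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
    0.5 * sqrt(sum(cr^2))
  }
  total <- 0
  for (k in 1:(d[3] + 1)) for (j in 1:(d[2] + 1)) for (i in 1:(d[1] + 1)) {
    block <- pad[i:(i + 1), j:(j + 1), k:(k + 1)]
    code <- sum(2^(0:7)[as.vector(block)])
    tri <- tri_table[[code + 1]]
    if (length(tri) == 0) next
    v <- sweep(mids[tri, , drop = FALSE], 2, sp, `*`)
    for (t in seq_len(length(tri) %/% 3))
      total <- total + tri_area(v[(3 * t - 2):(3 * t), , drop = FALSE])
  }
  total
}

random_mask <- function(shape, spacing = c(1, 1, 1), density = 0.4,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- array(stats::runif(prod(shape)) < density, shape)
  if (!any(g)) g[1] <- TRUE
  binary_mask(g, spacing)
}

# random smooth-ish phantom pair: a sphere and a perturbed/translated copy
random_phantom_pair <- function(seed, shape = c(20, 20, 20),
                                spacing = c(1, 1, 1)) {
  set.seed(seed)
  r <- stats::runif(1, 3, 6)
  base <- phantom_spec("sphere", radius_mm = r, shape = shape,
                       spacing = spacing)
  pert <- phantom_spec("perturbed", base = base,
                       shift = sample(-2:2, 3, replace = TRUE),
                       n_flip = sample(0:30, 1),
                       shape = shape, spacing = spacing,
                       seed = sample.int(1e6, 1))
  list(a = make_phantom(base), b = make_phantom(pert))
}
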