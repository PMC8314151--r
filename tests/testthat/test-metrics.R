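test_that("volumetric DSC matches hand-counted overlaps", {
  ga <- array(FALSE, c(6, 6, 6)); ga[2:3, 2:3, 2:3] <- TRUE
  a <- binary_mask(ga)
  expect_equal(volumetric_dsc(a, a), 1)

  gb <- array(FALSE, c(6, 6, 6)); gb[5:6, 5:6, 5:6] <- TRUE
  expect_equal(volumetric_dsc(a, binary_mask(gb)), 0)

  # 2x2x2 cube against itself shifted one voxel: 2*4/(8+8)
  gs <- array(FALSE, c(6, 6, 6)); gs[3:4, 2:3, 2:3] <- TRUE
  expect_equal(volumetric_dsc(a, binary_mask(gs)), 0.5)

  empty <- binary_mask(array(FALSE, c(6, 6, 6)))
  expect_true(is.na(volumetric_dsc(empty, empty)))
  expect_equal(volumetric_dsc(a, empty), 0)
  expect_error(volumetric_dsc(a, binary_mask(array(FALSE, c(5, 6, 6)))),
               "shape mismatch")
})

test_that("sparse aggregated DSC follows the pooled labeled-voxel formula", {
  # full labeling reduces exactly to the dense volumetric DSC
  set.seed(55)
  for (i in 1:5) {
    a <- random_mask(c(8, 8, 8), density = 0.3)
    b <- random_mask(c(8, 8, 8), density = 0.3)
    full <- labeled_region(array(TRUE, c(8, 8, 8)))
    expect_equal(sparse_volumetric_dsc(list(sparse_case(a, full, b))),
                 volumetric_dsc(a, b))
  }

  # constructed two-case fixture: per case one labeled slice, 10 reference
  # voxels, 10 predicted voxels inside L, intersection 5 -> 2*10/(20+20)
  mk_case <- function() {
    ref <- array(FALSE, c(6, 6, 4)); ref[1:5, 1:2, 2] <- TRUE  # 10 voxels
    prd <- array(FALSE, c(6, 6, 4))
    prd[1:5, 2:3, 2] <- TRUE   # 10 in slice 2, overlap 5
    prd[1:6, 1:6, 3] <- TRUE   # unlabeled slice, must not count
    lab <- array(FALSE, c(6, 6, 4)); lab[, , 2] <- TRUE
    sparse_case(binary_mask(ref), labeled_region(lab), binary_mask(prd))
  }
  expect_equal(sparse_volumetric_dsc(list(mk_case(), mk_case())), 0.5)

  # empty predictions inside L against nonempty references
  ref <- array(FALSE, c(4, 4, 4)); ref[2, 2, 2] <- TRUE
  lab <- array(FALSE, c(4, 4, 4)); lab[, , 2] <- TRUE
  cs <- sparse_case(binary_mask(ref), labeled_region(lab),
                    binary_mask(array(FALSE, c(4, 4, 4))))
  expect_equal(sparse_volumetric_dsc(list(cs)), 0)

  # all-empty denominator is undefined
  e <- binary_mask(array(FALSE, c(4, 4, 4)))
  cs0 <- sparse_case(e, labeled_region(array(TRUE, c(4, 4, 4))), e)
  expect_true(is.na(sparse_volumetric_dsc(list(cs0))))

  expect_error(sparse_volumetric_dsc(list()), "non-empty")
  expect_error(sparse_case(binary_mask(array(TRUE, c(2, 2, 2))),
                           labeled_region(array(FALSE, c(2, 2, 2))),
                           binary_mask(array(FALSE, c(2, 2, 2)))),
               "contained")
})

test_that("surface DSC reproduces its analytic anchor cases", {
  sph <- make_phantom(phantom_spec("sphere", radius_mm = 8,
                                   shape = c(24, 24, 24)))
  expect_equal(surface_dsc(sph, sph, 1)$value, 1)

  g1 <- array(FALSE, c(70, 12, 12)); g1[4:8, 4:8, 4:8] <- TRUE
  g2 <- array(FALSE, c(70, 12, 12)); g2[54:58, 4:8, 4:8] <- TRUE
  expect_equal(surface_dsc(binary_mask(g1), binary_mask(g2), 1)$value, 0)

  pair <- make_multi_cube_pair(n_cubes = 20, displaced = 1)
  res <- surface_dsc(pair$a, pair$b, 1)
  expect_equal(res$value, 0.95, tolerance = 1e-12)
  expect_equal(res$overlap_area_1 / res$area_1, 0.95)

  # slabs with flat faces offset 2 mm: everything lands inside tau = 2
  A <- make_phantom(phantom_spec("slab", axis = 3, from = 5, to = 10,
                                 shape = c(30, 30, 20)))
  B <- make_phantom(phantom_spec("slab", axis = 3, from = 7, to = 12,
                                 shape = c(30, 30, 20)))
  v1 <- surface_dsc(A, B, 1)$value
  v2 <- surface_dsc(A, B, 2)$value
  expect_equal(v2, 1)
  expect_gt(v2, v1)
})

test_that("surface DSC result bookkeeping is internally consistent", {
  pair <- make_multi_cube_pair(n_cubes = 5, displaced = 2)
  r <- surface_dsc(pair$a, pair$b, 1)
  expect_equal(r$value,
               (r$overlap_area_1 + r$overlap_area_2) / (r$area_1 + r$area_2))
  expect_true(r$overlap_area_1 >= 0 && r$overlap_area_1 <= r$area_1)
  expect_true(r$overlap_area_2 >= 0 && r$overlap_area_2 <= r$area_2)
  expect_equal(r$tolerance_used, 1)
})

test_that("empty masks follow the explicit undefined/zero conventions", {
  e <- binary_mask(array(FALSE, c(8, 8, 8)))
  f <- binary_mask(array(FALSE, c(8, 8, 8))); f$grid[4, 4, 4] <- TRUE
  both <- surface_dsc(e, e, 1)
  expect_true(both$undefined)
  expect_true(is.na(both$value))
  one <- surface_dsc(e, f, 1)
  expect_false(one$undefined)
  expect_equal(one$value, 0)
  expect_error(surface_dsc(f, f, -1), "non-negative")
})

test_that("surface DSC is symmetric, bounded, monotone in tau, and saturates", {
  taus <- c(0.5, 1, 2, 3)
  for (seed in 1:12) {
    p <- random_phantom_pair(seed)
    vals <- vapply(taus, function(t) surface_dsc(p$a, p$b, t)$value,
                   numeric(1))
    expect_true(all(vals >= 0 & vals <= 1))
    expect_true(all(diff(vals) >= -1e-12))
    expect_equal(surface_dsc(p$b, p$a, 1)$value,
                 surface_dsc(p$a, p$b, 1)$value)
    diag_mm <- sqrt(sum((dim(p$a$grid) * p$a$spacing)^2))
    expect_equal(surface_dsc(p$a, p$b, diag_mm)$value, 1)
  }
})

test_that("joint whole-voxel translation leaves both metrics unchanged", {
  base <- phantom_spec("sphere", radius_mm = 5, shape = c(24, 24, 24))
  a1 <- make_phantom(base)
  b1 <- make_phantom(phantom_spec("perturbed", base = base,
                                  shift = c(1, 0, 1), shape = c(24, 24, 24)))
  shift_spec <- function(s) phantom_spec("perturbed", base = s,
                                         shift = c(2, 3, 1),
                                         shape = c(24, 24, 24))
  a2 <- make_phantom(shift_spec(base))
  b2 <- binary_mask(surfdice:::shift_grid(b1$grid, c(2, 3, 1)))
  expect_equal(surface_dsc(a2, b2, 1)$value, surface_dsc(a1, b1, 1)$value)
  expect_equal(volumetric_dsc(a2, b2), volumetric_dsc(a1, b1))
})
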