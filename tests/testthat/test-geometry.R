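test_that("isovoxel resampling conserves foreground volume and passes isotropic input through", {
  iso <- phantom_cylinder(2, 10, 0.3)
  expect_identical(resample_isovoxel(iso), iso)
  aniso <- phantom_cylinder(2, 20, c(0.28, 0.28, 0.56))
  out <- resample_isovoxel(aniso)
  expect_equal(max(out$spacing) / min(out$spacing), 1, tolerance = 0.02)
  expect_lt(abs(foreground_mm3(out) / foreground_mm3(aniso) - 1), 0.05)
  empty <- vox_volume(array(FALSE, c(4, 4, 4)), c(0.3, 0.3, 0.6))
  expect_error(resample_isovoxel(empty), "empty")
})

test_that("isosurface area matches analytic phantoms", {
  sph <- extract_surface(phantom_sphere(5, 0.28))
  expect_lt(abs(sph$area / (4 * pi * 25) - 1), 0.10)
  cyl <- extract_surface(phantom_cylinder(2, 40, 0.28))
  expect_lt(abs(cyl$area / (2 * pi * 2 * 40 + 2 * pi * 4) - 1), 0.10)
  # single isolated voxel still produces a closed positive-area mesh
  arr <- array(FALSE, c(3, 3, 3)); arr[2, 2, 2] <- TRUE
  m <- extract_surface(vox_volume(arr, 0.3))
  expect_gt(m$area, 0)
  expect_true(all(m$faces >= 1 & m$faces <= nrow(m$vertices)))
  # closed mesh: every edge shared by exactly two faces
  ed <- rbind(m$faces[, 1:2], m$faces[, 2:3], m$faces[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  expect_true(all(table(key) == 2))
  expect_error(extract_surface(vox_volume(array(FALSE, c(3, 3, 3)), 0.3)),
               "empty")
})

test_that("skeleton of a straight cylinder is a single line with 2 endpoints", {
  fx <- cylinder_fixture()
  sk <- prune_skeleton(skeletonize(fx$vol), 2)
  s <- skeleton_summary(sk)
  expect_equal(s$n_endpoints, 2)
  expect_equal(s$n_junctions, 0)
  expect_equal(s$n_components, 1)
  # skeleton voxels lie on the axis (within one voxel) and inside foreground
  expect_lt(max(abs(sk$nodes$x)), 0.45)
  expect_lt(max(abs(sk$nodes$y)), 0.45)
  expect_true(all(fx$vol$occupancy[cbind(sk$nodes$i, sk$nodes$j, sk$nodes$k)]))
  # inscribed radius on the axis recovers the tube radius
  mid <- abs(sk$nodes$z) < 15
  expect_lt(abs(mean(sk$nodes$radius[mid]) - 2), 0.3)
})

test_that("Y phantom resolves 3 endpoints, 1 junction, 3 polylines", {
  fx <- y_fixture()
  s <- skeleton_summary(fx$sk)
  expect_equal(s$n_endpoints, 3)
  expect_equal(s$n_junctions, 1)
  expect_equal(length(unique(fx$cl$polyline_id)), 3)
})

test_that("torus skeleton has no endpoints and one cycle until broken", {
  sp <- 0.3; R <- 8; r <- 1.5
  ext <- c(2 * (R + r) + 3, 2 * (R + r) + 3, 2 * r + 3)
  dims <- as.integer(ceiling(ext / sp))
  occ <- array(FALSE, dims)
  xi <- ((seq_len(dims[1])) - 1) * sp - ext[1] / 2
  yi <- ((seq_len(dims[2])) - 1) * sp - ext[2] / 2
  zi <- ((seq_len(dims[3])) - 1) * sp - ext[3] / 2
  rr <- sqrt(outer(xi^2, yi^2, `+`))
  for (k in seq_len(dims[3])) occ[, , k] <- (rr - R)^2 + zi[k]^2 <= r^2
  vt <- vox_volume(occ, sp, -ext / 2)
  sk <- prune_skeleton(skeletonize(vt), 2)
  s <- skeleton_summary(sk)
  expect_equal(s$n_endpoints, 0)
  expect_equal(s$n_cycles, 1)
  tr <- build_tree(sk)
  expect_equal(tr$n_cut_edges, 1)
  expect_equal(skeleton_summary(tr)$n_cycles, 0)
})

test_that("pruning removes short spurs to a fixed point but keeps trunks", {
  fx <- cylinder_fixture()
  sk <- skeletonize(fx$vol)
  expect_identical(prune_skeleton(sk, 0), sk)  # threshold 0 = identity
  # huge threshold on a bare path must not delete the trunk
  pruned <- prune_skeleton(sk, 500)
  expect_equal(skeleton_summary(pruned)$n_endpoints, 2)
  # Y phantom with threshold larger than its arms degenerates to a path
  vy <- phantom_y(arm_length_mm = 15)
  py <- prune_skeleton(skeletonize(vy), 30)
  expect_equal(skeleton_summary(py)$n_endpoints, 2)
  expect_equal(skeleton_summary(py)$n_junctions, 0)
})

test_that("build_tree roots components on the lowest slice", {
  fx <- y_fixture()
  tr <- fx$tree
  expect_equal(length(tr$root), 1)
  expect_equal(tr$nodes$k[tr$root], min(tr$nodes$k))
  # two disjoint tubes -> two roots
  z <- seq(0, 10, by = 0.1)
  two <- dplyr::bind_rows(
    tibble::tibble(polyline_id = 1, branch_code = "a", x = 0, y = 0, z = z,
                   radius = 1.2),
    tibble::tibble(polyline_id = 2, branch_code = "b", x = 8, y = 0, z = z,
                   radius = 1.2))
  vx <- voxelize(two, spacing_mm = 0.35)
  t2 <- build_tree(skeletonize(vx$volume))
  expect_equal(length(t2$root), 2)
})

test_that("extracted centerlines recover radius, tangents and arc length", {
  fx <- cylinder_fixture()
  cl <- fx$cl
  expect_equal(length(unique(cl$polyline_id)), 1)
  # tip extension recovers the generating 40 mm within 2%
  arc <- sum(sqrt(diff(cl$x)^2 + diff(cl$y)^2 + diff(cl$z)^2))
  expect_lt(abs(arc - 40) / 40, 0.02)
  interior <- abs(cl$z) < 15
  expect_lt(abs(mean(cl$radius[interior]) - 2), 0.3)
  # tangents along the axis within 2 degrees
  ang <- acos(pmin(1, abs(cl$tz[interior]))) * 180 / pi
  expect_lt(max(ang), 2)
  # unit norm
  nrm <- sqrt(cl$tx^2 + cl$ty^2 + cl$tz^2)
  expect_true(all(abs(nrm - 1) < 1e-6))
})

test_that("component count is conserved volume -> skeleton -> forest", {
  for (s in c(21, 22)) {
    tr <- sample_tree(cow_template(), "control", seed = s)
    vx <- suppressWarnings(voxelize(realize_centerlines(tr), spacing_mm = 0.6))
    ncomp_vol <- max(cavlabel:::cpp_components26(
      as.logical(vx$volume$occupancy), dim(vx$volume$occupancy)))
    sk <- prune_skeleton(skeletonize(vx$volume), 2)
    expect_equal(skeleton_summary(sk)$n_components, ncomp_vol)
    tre <- build_tree(sk)
    expect_equal(length(tre$root), ncomp_vol)
  }
})
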