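test_that("spot sampling is exact in arc length", {
  # 2.801 mm polyline at the default interval: exactly 11 spots
  sp <- sample_spots(straight_polyline(2.801), 0.2801)
  expect_equal(nrow(sp), 11)
  expect_equal(diff(sp$s), rep(0.2801, 10), tolerance = 1e-9)
  # general polyline: all intra-polyline gaps equal the interval except the
  # terminal one, which is <= interval
  sp2 <- sample_spots(straight_polyline(10), 0.2801)
  gaps <- diff(sp2$s)
  expect_true(all(abs(gaps[-length(gaps)] - 0.2801) < 1e-6))
  expect_lte(gaps[length(gaps)], 0.2801 + 1e-9)
  expect_equal(max(sp2$s), 10)  # last point always included
  # shorter than one interval: both ends
  sp3 <- sample_spots(straight_polyline(0.1), 0.2801)
  expect_equal(nrow(sp3), 2)
  expect_equal(sp3$s, c(0, 0.1))
  expect_error(sample_spots(straight_polyline(5), 0), "interval")
})

test_that("cross-sections recover circular and elliptic analytic geometry", {
  fx <- cylinder_fixture()
  cs <- cross_section(fx$vol, c(0, 0, 0), c(0, 0, 1))
  expect_lt(abs(cs$area / (4 * pi) - 1), 0.07)
  expect_lt(abs(cs$min_diameter - 4), 0.3)
  expect_lt(abs(cs$max_diameter - 4), 0.3)
  # elliptic tube a=3, b=1.5: caliper ratio ~2
  sp <- rep(0.28, 3); ext <- c(8, 5, 12)
  dims <- as.integer(ceiling(ext / sp))
  xi <- (seq_len(dims[1]) - 1) * sp[1] - ext[1] / 2
  yi <- (seq_len(dims[2]) - 1) * sp[2] - ext[2] / 2
  msk <- outer(xi^2 / 9, yi^2 / 2.25, `+`) <= 1
  occ <- array(FALSE, dims)
  for (k in seq_len(dims[3])) occ[, , k] <- msk
  ev <- vox_volume(occ, sp, -ext / 2)
  ce <- cross_section(ev, c(0, 0, 0), c(0, 0, 1))
  expect_lt(abs(ce$max_diameter / ce$min_diameter - 2), 0.2)
  expect_lt(abs(ce$area / (pi * 3 * 1.5) - 1), 0.07)
  # background coordinate errors
  expect_error(cross_section(fx$vol, c(10, 10, 0), c(0, 0, 1)), "outside")
})

test_that("straight-tube features sit at their geometric limits", {
  fx <- cylinder_fixture()
  cfg <- cav_config()
  sp <- spot_features(fx$vol, fx$cl, sample_spots(fx$cl, 0.2801), cfg)
  interior <- sp$s > 4 & sp$s < max(sp$s) - 4
  expect_true(all(abs(sp$distortion[interior] - 1) <= 0.02))
  expect_true(all(sp$curvature[interior] <= 0.02))
  expect_true(all(sp$circularity[interior] >= 0.9 &
                    sp$circularity[interior] <= 1.05))
  expect_true(all(sp$radius_ratio[interior] >= 1))
  expect_lt(abs(mean(sp$radius_ratio[interior]) - 1), 0.1)
  expect_lt(abs(mean(sp$inscribed_radius[interior]) - 2), 0.3)
})

test_that("curvature matches the Frenet closed form on a circle", {
  # circle of radius 10 in the xy-plane as a polyline
  th <- seq(0, pi, length.out = 400)
  circ <- tibble::tibble(polyline_id = 1L, x = 10 * cos(th), y = 10 * sin(th),
                         z = 0, radius = 1)
  sp <- sample_spots(circ, 0.2801)
  sp$distortion <- NA; sp$curvature <- NA
  sp <- cavlabel:::spot_curve_features(sp, circ)
  interior <- sp$s > 3 & sp$s < max(sp$s) - 3
  expect_lt(abs(mean(sp$curvature[interior]) - 0.1), 0.01)
})

test_that("features are invariant to rigid translation of the volume", {
  fx <- y_fixture()
  cfg <- cav_config()
  tab1 <- {
    sp <- spot_features(fx$vol, fx$cl, sample_spots(fx$cl, 0.2801), cfg)
    assemble_feature_table(sp, frame = foreground_frame(fx$vol))
  }
  # translate by 10 voxels = 3 mm via the origin
  vol2 <- fx$vol; vol2$origin <- vol2$origin + 10 * vol2$spacing
  cl2 <- fx$cl
  cl2$x <- cl2$x + 10 * vol2$spacing[1]
  cl2$y <- cl2$y + 10 * vol2$spacing[2]
  cl2$z <- cl2$z + 10 * vol2$spacing[3]
  tab2 <- {
    sp <- spot_features(vol2, cl2, sample_spots(cl2, 0.2801), cfg)
    assemble_feature_table(sp, frame = foreground_frame(vol2))
  }
  feats <- cav_predictors()[-(1:3)]
  m1 <- as.matrix(as.data.frame(tab1)[, feats])
  m2 <- as.matrix(as.data.frame(tab2)[, feats])
  expect_equal(dim(m1), dim(m2))
  expect_lt(max(abs(m1 - m2)), 1e-6)
  frame1 <- attr(tab1, "frame")
  expect_lt(max(abs(as.matrix(tab1[, c("x", "y", "z")]) -
                      as.matrix(tab2[, c("x", "y", "z")]))),
            0.01 * frame1$diagonal)
})

test_that("feature table has exactly 12 predictors and logs drops", {
  fx <- subject_fixture()
  tab <- fx$tab
  expect_true(all(cav_predictors() %in% names(tab)))
  expect_equal(length(cav_predictors()), 12)
  expect_false(anyNA(tab[, cav_predictors()]))
  # circularity bounded by the isoperimetric inequality (+ discretisation)
  expect_true(all(tab$circularity <= 1.05))
  expect_true(all(tab$circularity > 0))
  expect_true(all(tab$radius_ratio >= 1))
  expect_true(all(tab$distortion >= 1 - 1e-9))
  # dropped-spot logging: inject one failed section
  sp <- spot_features(cylinder_fixture()$vol, cylinder_fixture()$cl,
                      sample_spots(cylinder_fixture()$cl, 0.2801),
                      cav_config())
  sp$cross_section_area[3] <- NA
  expect_message(out <- assemble_feature_table(sp), "dropping 1")
  expect_equal(nrow(out), nrow(sp) - 1)
  expect_equal(attr(out, "n_dropped"), 1)
  expect_error(assemble_feature_table(sp[0, ]), "empty")
})
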