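test_that("sample_tree is deterministic under a fixed seed", {
  tpl <- cow_template()
  a <- sample_tree(tpl, "control", seed = 1)
  b <- sample_tree(tpl, "control", seed = 1)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c2 <- sample_tree(tpl, "control", seed = 2)
  expect_false(identical(tibble::as_tibble(a), tibble::as_tibble(c2)))
  expect_error(sample_tree(tpl, "martian", 1), "unknown cohort")
})

test_that("control trees carry cohort-scale spot counts and icas loses chunks", {
  tpl <- cow_template()
  seeds <- 1:20
  spots <- vapply(seeds, function(s) {
    cl <- realize_centerlines(sample_tree(tpl, "control", seed = s))
    nrow(sample_spots(cl, 0.2801))
  }, 1)
  expect_gt(mean(spots), 3500)
  expect_lt(mean(spots), 6500)
  ch_control <- vapply(seeds, function(s)
    tree_summary(sample_tree(tpl, "control", seed = s))$n_chunks, 1L)
  ch_icas <- vapply(seeds, function(s)
    tree_summary(sample_tree(tpl, "icas", seed = s))$n_chunks, 1L)
  expect_gt(mean(ch_control), mean(ch_icas))
  br_control <- vapply(seeds, function(s)
    tree_summary(sample_tree(tpl, "control", seed = s))$n_branches, 1L)
  br_icas <- vapply(seeds, function(s)
    tree_summary(sample_tree(tpl, "icas", seed = s))$n_branches, 1L)
  expect_gt(mean(br_control), mean(br_icas))
})

test_that("trees are valid forests with parent-present consistency", {
  tpl <- cow_template()
  for (s in 1:5) {
    tr <- tibble::as_tibble(sample_tree(tpl, "icas", seed = s))
    pres <- tr[tr$present, ]
    par <- pres$parent_code[!is.na(pres$parent_code)]
    expect_true(all(par %in% pres$code))
    expect_true(all(pres$proximal_radius_mm > 0))
    expect_true(all(pres$distal_radius_mm <= pres$proximal_radius_mm + 1e-12))
    af <- pres$attach_fraction[!is.na(pres$parent_code)]
    expect_true(all(af >= 0 & af <= 1))
  }
})

test_that("apply_pathology implements stenosis arithmetic and subtree occlusion", {
  # stenosis on a constant-radius 2.0 mm branch, severity 0.6 -> 0.8 mm
  flat <- tibble::tibble(
    code = "B1", parent_code = NA_character_, attach_fraction = NA_real_,
    length_mm = 30, proximal_radius_mm = 2, distal_radius_mm = 2,
    tortuosity_amp_mm = 0, tortuosity_freq = 1,
    dir_x = 0, dir_y = 0, dir_z = 1, presence_p = 1,
    start_x = 0, start_y = 0, start_z = 0, present = TRUE)
  st0 <- apply_pathology(flat, "stenosis", "B1", severity = 0.6, seed = 5)
  rad0 <- realize_centerlines(st0)$radius
  expect_equal(min(rad0), 0.8, tolerance = 1e-9)
  expect_equal(max(rad0), 2, tolerance = 1e-9)

  tpl <- cow_template()
  tr <- sample_tree(tpl, "control", seed = 3)
  # occlusion of a leaf removes exactly one branch
  leaves <- tr$code[tr$present &
                      !tr$code %in% tr$parent_code[tr$present]]
  oc <- apply_pathology(tr, "occlusion", leaves[1])
  expect_equal(sum(tr$present) - sum(oc$present), 1)
  # occlusion of an internal branch removes its whole subtree
  oc2 <- apply_pathology(tr, "occlusion", "A3.01")
  gone <- tr$code[tr$present & !oc2$present]
  expect_true("A3.01" %in% gone)
  expect_true(all(c("A3.02", "A7.01") %in% gone))
  expect_error(apply_pathology(oc2, "stenosis", "A3.01"), "absent")
  expect_error(apply_pathology(tr, "stenosis", "A3.01", severity = 1.5),
               "severity")
})

test_that("realized polylines honour arc length and tortuosity", {
  # straight branch: arc/chord exactly 1
  tr <- tibble::tibble(
    code = "B1", parent_code = NA_character_, attach_fraction = NA_real_,
    length_mm = 40, proximal_radius_mm = 2, distal_radius_mm = 2,
    tortuosity_amp_mm = 0, tortuosity_freq = 1,
    dir_x = 0, dir_y = 0, dir_z = 1, presence_p = 1,
    start_x = 0, start_y = 0, start_z = 0)
  pl <- realize_centerlines(tr)
  arc <- max(pl$s)
  chord <- sqrt(sum((pl[nrow(pl), c("x", "y", "z")] - pl[1, c("x", "y", "z")])^2))
  expect_equal(arc, 40, tolerance = 0.01)
  expect_equal(arc / chord, 1, tolerance = 1e-6)

  # tortuous branch: arc/chord matches a dense numerical-integration oracle
  tr$tortuosity_amp_mm <- 2; tr$tortuosity_freq <- 2
  pl2 <- realize_centerlines(tr, step_mm = 0.05)
  arc2 <- max(pl2$s)
  chord2 <- sqrt(sum((pl2[nrow(pl2), c("x", "y", "z")] - pl2[1, c("x", "y", "z")])^2))
  expect_equal(arc2, 40, tolerance = 0.4)
  # oracle: integrate the generating curve x(t) = C t, y = 2 sin(2pi 2 t),
  # with C solved so total arc = 40
  arc_of <- function(C) {
    t <- seq(0, 1, length.out = 20001)
    x <- C * t; y <- 2 * sin(4 * pi * t)
    sum(sqrt(diff(x)^2 + diff(y)^2))
  }
  lo <- 8; hi <- 42
  for (i in 1:60) { mid <- (lo + hi) / 2
    if (arc_of(mid) < 40) lo <- mid else hi <- mid }
  C <- (lo + hi) / 2
  oracle_ratio <- 40 / C
  expect_equal(arc2 / chord2, oracle_ratio, tolerance = 0.01 * oracle_ratio)

  # absent branches emit no polyline
  tr2 <- dplyr::bind_rows(tr, tr)
  tr2$code <- c("B1", "B2"); tr2$present <- c(TRUE, FALSE)
  expect_equal(unique(realize_centerlines(tr2)$branch_code), "B1")
  # child of absent parent errors
  tr3 <- dplyr::bind_rows(tr, tr)
  tr3$code <- c("B1", "B2"); tr3$present <- c(FALSE, TRUE)
  tr3$parent_code <- c(NA, "B1"); tr3$attach_fraction <- c(NA, 0.5)
  expect_error(realize_centerlines(tr3), "absent parent")
})

test_that("collision-free topology trees reproduce their spec counts", {
  tr <- sample_topology_tree(8, seed = 99)
  expect_gte(nrow(tr), 6)
  exp <- expected_topology(tr, 0.4)
  # attachments are interior, so every branch tip stays an endpoint and the
  # root contributes its free start; one junction per non-root branch
  expect_equal(exp$n_endpoints, nrow(tr) + 1)
  expect_equal(exp$n_junctions, nrow(tr) - 1)
})
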