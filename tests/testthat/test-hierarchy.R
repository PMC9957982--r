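test_that("segments partition spots one polyline at a time", {
  fx <- y_fixture()
  spots <- sample_spots(fx$cl, 0.2801)
  seg <- segment_spots(fx$cl, spots)
  expect_equal(nrow(seg$segments), 3)          # Y phantom: 3 segments
  expect_equal(sum(seg$segments$n_spots), nrow(spots))
  expect_false(anyNA(seg$spots$segment_id))
  expect_equal(sort(unlist(seg$segments$spot_ids)), sort(spots$spot_id))
  # unbranched tube: a single segment holding every spot
  fc <- cylinder_fixture()
  sp1 <- sample_spots(fc$cl, 0.2801)
  seg1 <- segment_spots(fc$cl, sp1)
  expect_equal(nrow(seg1$segments), 1)
  expect_equal(seg1$segments$n_spots, nrow(sp1))
})

test_that("segment counts on synthetic subjects track the generating paths", {
  fx <- subject_fixture()
  n_seg <- length(unique(fx$tab$segment_id))
  # ideal junction-to-junction path count from the generating tree: one
  # path per branch plus one more per interior attachment
  spec <- tibble::as_tibble(fx$sim$tree)
  pres <- spec[spec$present, ]
  interior <- !is.na(pres$parent_code) &
    pres$attach_fraction > 0.05 & pres$attach_fraction < 0.95
  ideal <- nrow(pres) + sum(interior)
  expect_gt(n_seg, 0.7 * ideal)
  expect_lt(n_seg, 1.4 * ideal)
  # dimension-reduction ordering: chunks < segments < spots
  expect_lt(20, n_seg)
  expect_lt(n_seg, nrow(fx$tab))
})

test_that("gold labels transfer from the label volume with full hierarchy consistency", {
  fx <- subject_fixture()
  tab <- fx$tab
  nm <- nomenclature()
  expect_true(all(tab$true_branch %in% nm$branches$code))
  expect_identical(tab$true_chunk, chunk_of(tab$true_branch, nm))
  # spots lie within a voxel of the labelled foreground by construction
  expect_gt(nrow(tab), 3000)
})

test_that("label transfer reports unresolvable spots and catches grid mismatch", {
  z <- seq(0, 10, by = 0.1)
  cl <- tibble::tibble(polyline_id = 1, branch_code = "A1.01",
                       x = 0, y = 0, z = z, radius = 1.5)
  vx <- voxelize(cl, spacing_mm = 0.35)
  spots <- sample_spots(cl, 0.2801)
  lab <- label_spots_from_volume(spots, vx$labels)
  expect_equal(unique(lab$true_branch), "A1.01")
  expect_equal(unique(lab$true_chunk), "A1")
  # a spot far outside any labelled voxel is dropped with a message
  spots2 <- spots
  spots2$x[1] <- spots2$x[1] + 3.5   # > 2 voxels from the tube
  spots2$y[1] <- spots2$y[1] + 3.5
  expect_message(lab2 <- label_spots_from_volume(spots2, vx$labels),
                 "dropping 1")
  expect_equal(nrow(lab2), nrow(spots2) - 1)
  # grossly misaligned coordinates -> grid mismatch error
  spots3 <- spots
  spots3$x <- spots3$x + 500
  expect_error(label_spots_from_volume(spots3, vx$labels), "grid")
})

test_that("nearest-label tie-break is deterministic and lexicographic", {
  # constructed exact tie: a background voxel flanked by two labels at the
  # same distance; codes stored in non-alphabetical id order on purpose
  arr <- array(0L, c(3, 1, 1))
  arr[1, 1, 1] <- 1L   # id 1 = "B2"
  arr[3, 1, 1] <- 2L   # id 2 = "B1"
  lv <- label_volume(arr, codes = c("B2", "B1"), spacing = c(1, 1, 1),
                     origin = c(0, 0, 0))
  mid <- tibble::tibble(spot_id = 1, x = 1, y = 0, z = 0)  # centre voxel
  nm <- list(branches = tibble::tibble(code = c("B1", "B2"),
                                       chunk = c("C", "C")),
             chunks = tibble::tibble(code = "C"))
  out <- label_spots_from_volume(mid, lv, map = structure(nm,
    class = "cav_nomenclature"))
  expect_equal(out$true_branch, "B1")
  out2 <- label_spots_from_volume(mid, lv, map = structure(nm,
    class = "cav_nomenclature"))
  expect_identical(out$true_branch, out2$true_branch)
})
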