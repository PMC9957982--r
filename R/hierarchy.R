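#' Group spots into segments between bifurcations
#'
#' One segment per centerline polyline (junction-to-junction or
#' junction-to-endpoint path): the segments partition the spots with no
#' overlap.
#'
#' @param centerlines centerline tibble the spots were sampled from.
#' @param spots tibble from [sample_spots()].
#' @return list with `spots` (a `segment_id` column added) and `segments`
#'   (tibble: `segment_id`, `n_spots`, `start_kind`, `end_kind`, `spot_ids`
#'   list-column).
#' @export
segment_spots <- function(centerlines, spots) {
  spots$segment_id <- spots$polyline_id
  meta <- centerlines %>%
    group_by(.data$polyline_id) %>%
    summarise(
      start_kind = if ("start_kind" %in% names(centerlines))
        dplyr::first(.data$start_kind) else "endpoint",
      end_kind = if ("end_kind" %in% names(centerlines))
        dplyr::first(.data$end_kind) else "endpoint",
      .groups = "drop"
    )
  segs <- spots %>%
    group_by(.data$segment_id) %>%
    summarise(n_spots = n(), spot_ids = list(.data$spot_id), .groups = "drop") %>%
    left_join(meta, by = c(segment_id = "polyline_id"))
  stopifnot(sum(segs$n_spots) == nrow(spots))
  list(spots = spots, segments = segs)
}

#' Transfer gold-standard labels from a label volume onto spots
#'
#' Each spot adopts the branch code of the nearest labelled voxel within a
#' small search window (ties broken by distance then lexicographic code);
#' spots with no labelled voxel in range are dropped and reported.
#'
#' @param spots tibble with mm positions (`x`, `y`, `z` raw, or `pos_x` etc.
#'   if already normalised).
#' @param labels a [label_volume()].
#' @param map a [nomenclature()] for the branch-to-chunk lift.
#' @param max_dist_vox search window half-width in voxels.
#' @return `spots` with `true_branch` and `true_chunk` columns (unresolved
#'   spots removed; count in attribute `n_unlabelled`).
#' @export
label_spots_from_volume <- function(spots, labels, map = nomenclature(),
                                    max_dist_vox = 2) {
  cols <- if (all(c("pos_x", "pos_y", "pos_z") %in% names(spots))) {
    c("pos_x", "pos_y", "pos_z")
  } else c("x", "y", "z")
  pts <- as.matrix(spots[, cols])
  d <- dim(labels$labels)
  vox <- sweep(sweep(pts, 2, labels$origin, `-`), 2, labels$spacing, `/`)
  if (any(vox < -2) || any(vox > matrix(d, nrow(vox), 3, byrow = TRUE) + 1)) {
    abort("spot coordinates fall outside the label grid (grid mismatch?)")
  }
  # codes are passed in lexicographic order so integer tie-break = code tie-break
  ord <- order(labels$codes)
  relab <- match(seq_along(labels$codes), ord)  # old id -> rank
  arr <- array(0L, d)
  nz <- labels$labels > 0L
  arr[nz] <- relab[labels$labels[nz]]
  hit <- cpp_label_nearest(as.integer(arr), d, labels$origin, labels$spacing,
                           pts, as.integer(max_dist_vox))
  code <- ifelse(hit > 0, labels$codes[ord][pmax(hit, 1)], NA_character_)
  n_un <- sum(is.na(code))
  if (n_un > 0) {
    inform(paste0("dropping ", n_un, " spot(s) with no label within ",
                  max_dist_vox, " voxels"))
  }
  spots$true_branch <- code
  spots <- spots[!is.na(spots$true_branch), ]
  spots$true_chunk <- chunk_of(spots$true_branch, map)
  attr(spots, "n_unlabelled") <- n_un
  spots
}
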