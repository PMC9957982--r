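#' Names of the classifier predictor columns
#'
#' Three normalised spatial coordinates plus the nine geometric features
#' measured at every spot.
#'
#' @return character vector of length 12.
#' @export
cav_predictors <- function() {
  c("x", "y", "z",
    "cross_section_area", "inscribed_radius", "min_diameter", "max_diameter",
    "radius_ratio", "circumference", "distortion", "curvature", "circularity")
}

#' Sample spots along centerlines at a fixed arc-length interval
#'
#' Spots are placed at arc positions 0, d, 2d, ... along each polyline; the
#' final point of the polyline is always included. Polylines shorter than
#' one interval yield their two end spots.
#'
#' @param centerlines tibble from [extract_centerlines()] or
#'   [realize_centerlines()] (needs `polyline_id`, `x`, `y`, `z` and
#'   optionally `radius`, tangents, `branch_code`).
#' @param interval_mm spot spacing along the centerline (mm).
#' @return tibble: `spot_id`, `polyline_id`, `s` (arc position), `x`, `y`,
#'   `z`, `radius`, `tx`, `ty`, `tz` plus carried-over `branch_code`.
#' @export
sample_spots <- function(centerlines, interval_mm = 0.2801) {
  if (interval_mm <= 0) abort("spot interval must be > 0")
  ids <- unique(centerlines$polyline_id)
  out <- vector("list", length(ids))
  for (q in seq_along(ids)) {
    pl <- centerlines[centerlines$polyline_id == ids[q], ]
    if (nrow(pl) < 2) next
    seg <- sqrt(diff(pl$x)^2 + diff(pl$y)^2 + diff(pl$z)^2)
    cum <- c(0, cumsum(seg))
    L <- cum[length(cum)]
    if (L <= 0) next
    m <- floor(L / interval_mm + 1e-9)
    ss <- seq(0, by = interval_mm, length.out = m + 1)
    if (L - ss[length(ss)] > 1e-9) ss <- c(ss, L)
    ip <- function(v) approx(cum, v, ss, ties = "ordered")$y
    sp <- tibble(
      polyline_id = ids[q], s = ss,
      x = ip(pl$x), y = ip(pl$y), z = ip(pl$z),
      radius = if ("radius" %in% names(pl)) ip(pl$radius) else NA_real_
    )
    if (all(c("tx", "ty", "tz") %in% names(pl))) {
      tg <- cbind(ip(pl$tx), ip(pl$ty), ip(pl$tz))
    } else {
      tg <- polyline_tangents(as.matrix(sp[, c("x", "y", "z")]))
    }
    nn <- sqrt(rowSums(tg^2)); nn[nn == 0] <- 1
    sp$tx <- tg[, 1] / nn; sp$ty <- tg[, 2] / nn; sp$tz <- tg[, 3] / nn
    for (carry in c("branch_code", "start_node", "end_node")) {
      if (carry %in% names(pl)) sp[[carry]] <- pl[[carry]][1]
    }
    out[[q]] <- sp
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) abort("no spots sampled (empty centerlines)")
  res$spot_id <- seq_len(nrow(res))
  res %>% select("spot_id", dplyr::everything())
}

#' Perpendicular cross-section measurements at spots
#'
#' For each spot the binary volume is resampled on a plane normal to the
#' centerline tangent at sub-voxel pitch; the connected planar region
#' containing the spot yields the cross-sectional area, the surface
#' circumference (marching-squares contour length) and caliper diameters
#' through the region centroid (1 degree steps by default).
#'
#' @param volume a [vox_volume()].
#' @param spots tibble from [sample_spots()].
#' @param pitch_factor plane pitch as a fraction of the smallest voxel
#'   spacing.
#' @param n_angles caliper directions over 180 degrees.
#' @param max_extent_mm cap on the half-extent of the section plane.
#' @return `spots` with columns `cross_section_area`, `circumference`,
#'   `min_diameter`, `max_diameter` appended (NA where the section failed).
#' @export
spot_sections <- function(volume, spots, pitch_factor = 0.5, n_angles = 180,
                          max_extent_mm = 8) {
  pitch <- min(volume$spacing) * pitch_factor
  he <- pmin(pmax(2.5 * ifelse(is.na(spots$radius), 2, spots$radius),
                  8 * pitch), max_extent_mm)
  occ_num <- array(as.numeric(volume$occupancy), dim(volume$occupancy))
  sec <- cpp_sections(occ_num, dim(occ_num), volume$origin, volume$spacing,
                      as.matrix(spots[, c("x", "y", "z")]),
                      as.matrix(spots[, c("tx", "ty", "tz")]),
                      he, pitch, as.integer(n_angles))
  spots$cross_section_area <- sec[, 1]
  spots$circumference <- sec[, 2]
  spots$min_diameter <- sec[, 3]
  spots$max_diameter <- sec[, 4]
  spots
}

#' Single-spot cross-section
#'
#' Convenience wrapper measuring one perpendicular section; errors if the
#' spot lies outside the foreground.
#'
#' @param volume a [vox_volume()].
#' @param position mm coordinates (length 3).
#' @param tangent plane normal (length 3).
#' @inheritParams spot_sections
#' @return one-row tibble: `area`, `perimeter`, `min_diameter`,
#'   `max_diameter`.
#' @export
cross_section <- function(volume, position, tangent, pitch_factor = 0.5,
                          n_angles = 180, max_extent_mm = 8) {
  sp <- tibble(x = position[1], y = position[2], z = position[3],
               tx = tangent[1], ty = tangent[2], tz = tangent[3],
               radius = NA_real_)
  res <- spot_sections(volume, sp, pitch_factor, n_angles, max_extent_mm)
  if (is.na(res$cross_section_area)) {
    abort("cross-section failed: spot outside foreground")
  }
  tibble(area = res$cross_section_area, perimeter = res$circumference,
         min_diameter = res$min_diameter, max_diameter = res$max_diameter)
}

# distortion (arc/chord) and Menger curvature along each source polyline
spot_curve_features <- function(spots, centerlines, distortion_window_mm = 5,
                                curvature_window_mm = 2.5) {
  spots$distortion <- NA_real_
  spots$curvature <- NA_real_
  for (pid in unique(spots$polyline_id)) {
    pl <- centerlines[centerlines$polyline_id == pid, ]
    seg <- sqrt(diff(pl$x)^2 + diff(pl$y)^2 + diff(pl$z)^2)
    cum <- c(0, cumsum(seg))
    L <- cum[length(cum)]
    pos <- function(sv) cbind(approx(cum, pl$x, sv, ties = "ordered")$y,
                              approx(cum, pl$y, sv, ties = "ordered")$y,
                              approx(cum, pl$z, sv, ties = "ordered")$y)
    rows <- which(spots$polyline_id == pid)
    s0 <- spots$s[rows]
    h <- distortion_window_mm / 2
    s1 <- pmax(0, s0 - h); s2 <- pmin(L, s0 + h)
    dv <- pos(s2) - pos(s1)
    chord <- sqrt(rowSums(dv^2))
    spots$distortion[rows] <- ifelse(chord > 1e-9, (s2 - s1) / chord, 1)
    w <- curvature_window_mm
    a <- pmax(0, s0 - w); b <- pmin(L, s0 + w)
    cpt <- ifelse(s0 - a < 1e-6 | b - s0 < 1e-6, (a + b) / 2, s0)
    p1 <- pos(a); p2 <- pos(cpt); p3 <- pos(b)
    e1 <- p2 - p1; e2 <- p3 - p2; e3 <- p3 - p1
    la <- sqrt(rowSums(e1^2)); lb <- sqrt(rowSums(e2^2)); lc <- sqrt(rowSums(e3^2))
    crx <- e1[, 2] * e3[, 3] - e1[, 3] * e3[, 2]
    cry <- e1[, 3] * e3[, 1] - e1[, 1] * e3[, 3]
    crz <- e1[, 1] * e3[, 2] - e1[, 2] * e3[, 1]
    area2 <- sqrt(crx^2 + cry^2 + crz^2)
    kap <- ifelse(la < 1e-9 | lb < 1e-9 | lc < 1e-9, 0,
                  2 * area2 / (la * lb * lc))
    spots$curvature[rows] <- kap
  }
  spots
}

menger_curvature <- function(p1, p2, p3) {
  a <- sqrt(sum((p1 - p2)^2)); b <- sqrt(sum((p2 - p3)^2))
  cl <- sqrt(sum((p1 - p3)^2))
  if (a < 1e-9 || b < 1e-9 || cl < 1e-9) return(0)
  cr <- pracma_cross(p2 - p1, p3 - p1)
  area2 <- sqrt(sum(cr^2))  # twice the triangle area
  2 * area2 / (a * b * cl)
}

#' Compute the full nine-feature vector for every spot
#'
#' Combines perpendicular-section measurements ([spot_sections()]) with
#' centerline-derived features: inscribed radius (from the centerline
#' annotation), max/min diameter ratio, tortuosity-style distortion
#' (arc/chord over a centred window, one-sided at polyline ends), Menger
#' curvature, and luminal circularity (`4*pi*A/P^2` by default, or the
#' hydraulic-diameter form `4A/P`).
#'
#' @param volume a [vox_volume()].
#' @param centerlines source centerlines of the spots.
#' @param spots tibble from [sample_spots()].
#' @param config a [cav_config()] (controls windows, pitch, circularity
#'   form).
#' @return `spots` with the nine feature columns appended.
#' @export
spot_features <- function(volume, centerlines, spots, config = cav_config()) {
  spots <- spot_sections(volume, spots,
                         pitch_factor = config$section_pitch_factor,
                         n_angles = config$n_angles)
  spots <- spot_curve_features(spots, centerlines,
                               distortion_window_mm = config$distortion_window_mm,
                               curvature_window_mm = config$curvature_window_mm)
  spots$inscribed_radius <- spots$radius
  spots$radius_ratio <- spots$max_diameter / pmax(spots$min_diameter, 1e-9)
  spots$circularity <- if (config$circularity == "hydraulic") {
    4 * spots$cross_section_area / pmax(spots$circumference, 1e-9)
  } else {
    4 * pi * spots$cross_section_area / pmax(spots$circumference, 1e-9)^2
  }
  spots
}

#' Assemble the classifier feature table
#'
#' One row per retained spot with exactly 12 predictor columns (3 normalised
#' coordinates + 9 geometric features) plus bookkeeping (raw positions,
#' segment and label columns when present). Spots with failed sections are
#' dropped and reported. Coordinates are normalised by subtracting the
#' foreground centre of mass and dividing by the foreground bounding-box
#' diagonal, making the predictors invariant to rigid translation of the
#' scan.
#'
#' @param spots tibble from [spot_features()].
#' @param frame optional list with `com` and `diagonal` (from
#'   [foreground_frame()]); defaults to the spots' own cloud.
#' @return tibble with predictors [cav_predictors()], raw `pos_x/y/z` and
#'   any `segment_id` / label columns; attribute `n_dropped` records drops.
#' @export
assemble_feature_table <- function(spots, frame = NULL) {
  if (nrow(spots) == 0) abort("empty spot set")
  need <- c("cross_section_area", "circumference", "min_diameter",
            "max_diameter", "inscribed_radius", "radius_ratio",
            "distortion", "curvature", "circularity")
  ok <- complete.cases(spots[, need]) &
    spots$cross_section_area > 0 & spots$circumference > 0 &
    spots$min_diameter > 0
  n_drop <- sum(!ok)
  if (n_drop > 0) {
    inform(paste0("dropping ", n_drop, " spot(s) with failed sections"))
  }
  tab <- spots[ok, ]
  if (nrow(tab) == 0) abort("all spots dropped")
  if (is.null(frame)) {
    pts <- as.matrix(tab[, c("x", "y", "z")])
    rng <- apply(pts, 2, range)
    frame <- list(com = colMeans(pts),
                  diagonal = sqrt(sum((rng[2, ] - rng[1, ])^2)))
  }
  tab$pos_x <- tab$x; tab$pos_y <- tab$y; tab$pos_z <- tab$z
  tab$x <- (tab$pos_x - frame$com[1]) / frame$diagonal
  tab$y <- (tab$pos_y - frame$com[2]) / frame$diagonal
  tab$z <- (tab$pos_z - frame$com[3]) / frame$diagonal
  keep <- c("spot_id", "polyline_id", "segment_id", "s",
            cav_predictors(), "pos_x", "pos_y", "pos_z",
            "tx", "ty", "tz", "start_node", "end_node",
            "branch_code", "true_branch", "true_chunk",
            "subject_id", "cohort")
  tab <- tab[, intersect(keep, names(tab))]
  attr(tab, "n_dropped") <- n_drop
  attr(tab, "frame") <- frame
  tab
}
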