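#' Voxel volume containers
#'
#' A `vox_volume` is a binary occupancy grid with per-axis spacing (mm) and a
#' world origin: the mm coordinate of the centre of voxel `[1, 1, 1]`. Axis
#' order is fixed (x, y, z) and matches R array indexing; world coordinates
#' are right-handed millimetres.
#'
#' @param occupancy logical 3D array.
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin numeric length-3, mm coordinate of the first voxel centre.
#' @return A `vox_volume` object.
#' @export
vox_volume <- function(occupancy, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(occupancy), length(dim(occupancy)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (any(spacing <= 0)) abort("spacing must be positive on all axes")
  structure(
    list(occupancy = occupancy, spacing = spacing, origin = as.numeric(origin)),
    class = "vox_volume"
  )
}

#' @export
print.vox_volume <- function(x, ...) {
  cat("<vox_volume> ", paste(dim(x$occupancy), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm, ", sum(x$occupancy), " foreground\n", sep = "")
  invisible(x)
}

#' Labelled voxel volume
#'
#' Shares grid, spacing and origin with a paired [vox_volume()]; each
#' foreground voxel carries an integer index into `codes` (0 = background).
#'
#' @param labels integer 3D array (0 = background).
#' @param codes character vector mapping label index to branch code.
#' @param spacing,origin as in [vox_volume()].
#' @return A `label_volume` object.
#' @export
label_volume <- function(labels, codes, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(labels), length(dim(labels)) == 3)
  structure(
    list(labels = labels, codes = as.character(codes),
         spacing = as.numeric(spacing), origin = as.numeric(origin)),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$labels), collapse = " x "),
      " voxels, ", length(x$codes), " codes\n", sep = "")
  invisible(x)
}

#' Physical foreground volume in cubic millimetres
#' @param volume a [vox_volume()].
#' @return scalar mm^3.
#' @export
foreground_mm3 <- function(volume) {
  sum(volume$occupancy) * prod(volume$spacing)
}

#' Foreground centre of mass and bounding-box diagonal (mm)
#' @param volume a [vox_volume()].
#' @return list with `com` (length 3) and `diagonal` (scalar mm).
#' @export
foreground_frame <- function(volume) {
  w <- which(volume$occupancy, arr.ind = TRUE)
  if (nrow(w) == 0) abort("volume has empty foreground")
  mm <- sweep(sweep(w - 1, 2, volume$spacing, `*`), 2, volume$origin, `+`)
  rng <- apply(mm, 2, range)
  list(com = colMeans(mm), diagonal = sqrt(sum((rng[2, ] - rng[1, ])^2)))
}

#' Read / write volumes as NIfTI-1
#'
#' Volumes are stored with spacing in the NIfTI pixdim and the world origin
#' in the qform translation. Round-trips through these two functions are
#' lossless; files written by other tools are read back on a best-effort
#' basis (spacing from pixdim, origin from the stored affine translation).
#'
#' @param volume a [vox_volume()] or [label_volume()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `write_volume_nifti` returns `path` invisibly;
#'   `read_volume_nifti` returns a [vox_volume()].
#' @export
write_volume_nifti <- function(volume, path) {
  arr <- if (inherits(volume, "label_volume")) {
    array(as.integer(volume$labels), dim(volume$labels))
  } else {
    array(as.integer(volume$occupancy), dim(volume$occupancy))
  }
  aff <- diag(4)
  diag(aff)[1:3] <- volume$spacing
  aff[1:3, 4] <- volume$origin
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @param threshold values strictly above this are foreground.
#' @export
read_volume_nifti <- function(path, threshold = 0.5) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  spacing <- abs(diag(aff)[1:3])
  origin <- aff[1:3, 4]
  arr <- as.array(img)
  vox_volume(array(arr > threshold, dim(arr)), spacing = spacing, origin = origin)
}

#' Axis-aligned phantoms for validation
#'
#' Rasterised solid shapes used throughout the test-suite: voxel centres
#' inside the analytic shape are foreground.
#'
#' @param radius_mm,length_mm cylinder radius and axial length (mm).
#' @param spacing isotropic voxel spacing (mm) or length-3 vector.
#' @param axis cylinder axis, one of 1, 2, 3.
#' @param margin_mm background padding around the shape.
#' @return a [vox_volume()].
#' @export
phantom_cylinder <- function(radius_mm = 2, length_mm = 40, spacing = 0.28,
                             axis = 3, margin_mm = 2) {
  spacing <- if (length(spacing) == 1) rep(spacing, 3) else as.numeric(spacing)
  ext <- rep(2 * (radius_mm + margin_mm), 3)
  ext[axis] <- length_mm + 2 * margin_mm
  dims <- pmax(3L, as.integer(ceiling(ext / spacing)))
  cc <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * spacing[a] - ext[a] / 2)
  perp <- setdiff(1:3, axis)
  occ <- array(FALSE, dims)
  r2 <- outer(cc[[perp[1]]]^2, cc[[perp[2]]]^2, `+`)
  inside_ax <- abs(cc[[axis]]) <= length_mm / 2
  disk <- r2 <= radius_mm^2
  for (k in which(inside_ax)) {
    idx <- vector("list", 3)
    idx[[perp[1]]] <- seq_len(dims[perp[1]])
    idx[[perp[2]]] <- seq_len(dims[perp[2]])
    idx[[axis]] <- k
    occ[idx[[1]], idx[[2]], idx[[3]]] <- disk
  }
  vox_volume(occ, spacing, origin = -ext / 2)
}

#' @rdname phantom_cylinder
#' @export
phantom_sphere <- function(radius_mm = 5, spacing = 0.28, margin_mm = 2) {
  spacing <- if (length(spacing) == 1) rep(spacing, 3) else as.numeric(spacing)
  ext <- rep(2 * (radius_mm + margin_mm), 3)
  dims <- as.integer(ceiling(ext / spacing))
  cc <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * spacing[a] - ext[a] / 2)
  occ <- array(FALSE, dims)
  d2 <- outer(cc[[1]]^2, cc[[2]]^2, `+`)
  for (k in seq_len(dims[3])) occ[, , k] <- d2 + cc[[3]][k]^2 <= radius_mm^2
  vox_volume(occ, spacing, origin = -ext / 2)
}

#' @rdname phantom_cylinder
#' @param arm_length_mm,arm_radius_mm geometry of the three arms of a
#'   Y-shaped tube: a vertical trunk splitting into two oblique arms.
#' @export
phantom_y <- function(arm_length_mm = 15, arm_radius_mm = 1.5, spacing = 0.3,
                      margin_mm = 2.5) {
  trunk <- rbind(c(0, 0, 0), c(0, 0, arm_length_mm))
  s30 <- sin(pi / 5); c30 <- cos(pi / 5)
  armA <- rbind(c(0, 0, arm_length_mm),
                c(arm_length_mm * s30, 0, arm_length_mm + arm_length_mm * c30))
  armB <- rbind(c(0, 0, arm_length_mm),
                c(-arm_length_mm * s30, 0, arm_length_mm + arm_length_mm * c30))
  seg_pts <- function(m, step = spacing / 2) {
    L <- sqrt(sum((m[2, ] - m[1, ])^2))
    tt <- seq(0, 1, length.out = max(2, ceiling(L / step) + 1))
    cbind(m[1, 1] + tt * (m[2, 1] - m[1, 1]),
          m[1, 2] + tt * (m[2, 2] - m[1, 2]),
          m[1, 3] + tt * (m[2, 3] - m[1, 3]))
  }
  pts <- rbind(seg_pts(trunk), seg_pts(armA), seg_pts(armB))
  cl <- tibble(
    polyline_id = rep(1:3, times = c(nrow(seg_pts(trunk)), nrow(seg_pts(armA)),
                                     nrow(seg_pts(armB)))),
    branch_code = rep(c("T", "A", "B"), times = c(nrow(seg_pts(trunk)),
                                                  nrow(seg_pts(armA)), nrow(seg_pts(armB)))),
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    radius = arm_radius_mm
  )
  voxelize(cl, spacing_mm = spacing, margin_mm = margin_mm)$volume
}
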