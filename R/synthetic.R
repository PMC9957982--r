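#' Circle-of-Willis branch template
#'
#' A hand-crafted forest of the 62 nominal arterial branches used by the
#' simulator: two internal carotid roots plus a basilar root, with the
#' communicating arteries represented as branches of one side so the
#' structure remains a forest. Each row is a branch with its parent, the
#' arc-length fraction at which it sprouts, nominal length, proximal/distal
#' radii (linear taper), sinusoidal tortuosity parameters, a nominal unit
#' direction, and a baseline presence probability. World coordinates are mm:
#' +x left, +y anterior, +z superior; right-sided structures sit at negative
#' x. Anatomical dimensions follow typical adult calibres (ICA ~2.3 mm
#' proximal radius, distal pial branches tapering to ~0.6 mm).
#'
#' @return tibble, one row per branch (62 rows).
#' @export
cow_template <- function() {
  b <- function(code, parent, at, len, rp, rd, amp, freq, dx, dy, dz, p = 0.95,
                sx = NA, sy = NA, sz = NA) {
    tibble(code = code, parent_code = parent, attach_fraction = at,
           length_mm = len, proximal_radius_mm = rp, distal_radius_mm = rd,
           tortuosity_amp_mm = amp, tortuosity_freq = freq,
           dir_x = dx, dir_y = dy, dir_z = dz, presence_p = p,
           start_x = sx, start_y = sy, start_z = sz)
  }
  right <- bind_rows(
    # internal carotid root and its direct branches
    b("A1.01", NA, NA, 28, 2.3, 2.0, 1.0, 2.0, 0.05, 0.12, 1, 1, -12, 2, -14),
    b("A1.02", "A1.01", 0.55, 13, 0.9, 0.7, 0.4, 2, -0.25, 0.95, 0.15, 0.97),
    b("A1.03", "A1.01", 0.72, 11, 0.8, 0.65, 0.3, 1.5, -0.3, -0.55, 0.75, 0.97),
    b("P3.02", "A1.01", 0.62, 13, 0.9, 0.75, 0.4, 1.5, 0.1, -0.98, 0.1, 0.70),
    b("A5.01", "A1.01", 0.88, 15, 1.5, 1.3, 0.5, 1.5, 0.62, 0.5, 0.6, 1),
    b("A3.01", "A1.01", 0.95, 21, 1.9, 1.6, 0.7, 1.5, -0.95, 0.1, 0.12, 1),
    # sphenoidal MCA and its division
    b("A7.09", "A3.01", 0.45, 23, 1.0, 0.7, 0.8, 2, -0.55, 0.35, -0.75),
    b("A3.02", "A3.01", 0.93, 17, 1.5, 1.2, 0.6, 1.5, -0.75, -0.1, 0.65, 1),
    # pial MCA fan
    b("A7.01", "A3.02", 0.22, 24, 1.0, 0.7, 0.9, 2, -0.5, 0.85, 0.2),
    b("A7.02", "A3.02", 0.50, 27, 1.1, 0.75, 0.9, 2, -0.55, 0.35, 0.85),
    b("A7.03", "A3.02", 0.78, 28, 1.1, 0.75, 0.9, 2, -0.6, -0.05, 0.95),
    b("A7.06", "A3.02", 0.95, 33, 1.1, 0.8, 1.0, 2, -0.65, -0.9, 0.35),
    b("A7.04", "A7.03", 0.55, 24, 0.9, 0.65, 0.8, 2, -0.5, -0.5, 0.8),
    b("A7.05", "A7.04", 0.60, 22, 0.8, 0.6, 0.8, 2, -0.45, -0.85, 0.5),
    b("A7.07", "A7.06", 0.45, 24, 0.9, 0.65, 0.8, 2, -0.7, -0.8, -0.3),
    b("A7.08", "A7.07", 0.50, 21, 0.8, 0.6, 0.8, 2, -0.85, -0.3, -0.5),
    # anterior cerebral
    b("A0",    "A5.01", 0.93, 7, 0.7, 0.6, 0.2, 1, 1, 0.1, 0, 0.60),
    b("A5.02", "A5.01", 0.97, 16, 1.3, 1.1, 0.5, 1.5, 0.05, 0.3, 1, 1),
    b("A9.01", "A5.02", 0.30, 14, 0.9, 0.65, 0.5, 2, -0.15, 0.95, 0.3),
    b("A9.02", "A5.02", 0.70, 26, 1.0, 0.7, 0.9, 1.5, -0.12, 0.45, 0.9),
    b("A9.03", "A5.02", 0.95, 32, 1.0, 0.7, 1.5, 1, -0.05, -0.6, 0.8),
    # posterior cerebral (right)
    b("P3.01", "P0", 0.96, 19, 1.4, 1.15, 0.6, 1.5, -0.9, -0.45, 0.2, 1),
    b("P5.05", "P3.01", 0.35, 11, 0.75, 0.6, 0.3, 1.5, -0.25, -0.4, 0.85),
    b("P5.04", "P3.01", 0.60, 22, 0.9, 0.65, 0.8, 2, -0.85, -0.5, -0.15),
    b("P5.01", "P3.01", 0.97, 18, 1.1, 0.85, 0.6, 1.5, -0.3, -0.95, 0.25, 1),
    b("P5.02", "P5.01", 0.75, 21, 0.85, 0.6, 0.7, 2, -0.25, -0.65, 0.75),
    b("P5.03", "P5.01", 0.95, 23, 0.85, 0.6, 0.7, 2, -0.2, -0.95, 0.1),
    # cerebellar (right)
    b("P1", "P0", 0.04, 20, 1.6, 1.4, 0.8, 1.5, -0.3, -0.25, -1, 1),
    b("P7.03", "P1", 0.45, 18, 0.85, 0.6, 0.7, 2, -0.75, -0.55, -0.35),
    b("P7.02", "P0", 0.42, 15, 0.8, 0.6, 0.5, 2, -0.95, -0.3, -0.1),
    b("P7.01", "P0", 0.88, 16, 0.9, 0.65, 0.5, 2, -0.9, -0.35, 0.3)
  )
  # mirror the right-sided subtrees to the left; the basilar's left-side
  # children get their own attach fractions so sibling junctions stay apart
  mirror_code <- function(code) {
    out <- code
    do <- !is.na(code) & code != "P0"
    if (any(do)) {
      pb <- parse_branch_code(code[do])
      mc <- chunk_mirror(pb$chunk)
      out[do] <- ifelse(pb$segment_index == 0, mc,
                        sprintf("%s.%02d", mc, pb$segment_index))
    }
    out
  }
  left <- right %>%
    filter(!.data$code %in% c("A0", "P0")) %>%
    mutate(
      code = mirror_code(.data$code),
      parent_code = mirror_code(.data$parent_code),
      dir_x = -.data$dir_x, start_x = -.data$start_x,
      attach_fraction = ifelse(!is.na(.data$parent_code) & .data$parent_code == "P0",
                               .data$attach_fraction - 0.07, .data$attach_fraction)
    )
  mid <- b("P0", NA, NA, 25, 1.9, 1.7, 0.5, 1.5, 0, 0.12, 1, 1, 0, -16, -12)
  out <- bind_rows(right, left, mid)
  # global calibre: centre total centerline length so control trees carry
  # ~5000 spots at the 0.2801 mm interval
  out$length_mm <- out$length_mm * 1.15
  stopifnot(nrow(out) == 62, !anyDuplicated(out$code))
  out
}

# truncated normal draw (rejection; n small)
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- x < lo | x > hi
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- x < lo | x > hi
  }
  x
}

# chunks whose entire branch set can be congenitally absent, with baseline
# probabilities (pial posterior/ACA territories and fetal-type P1 variants)
.chunk_dropout <- c(P3 = 0.08, P4 = 0.08, P5 = 0.12, P6 = 0.12,
                    A9 = 0.08, A10 = 0.08)

#' Sample a subject-specific vascular tree
#'
#' Draws per-branch presence, lengths, radii, tortuosity and orientation from
#' cohort-specific distributions around the [cow_template()]. `control`
#' subjects get the baseline variation; `icas` subjects additionally receive
#' one or more intracranial stenosis (>50% radius reduction) or occlusion
#' lesions on major branches; `stroke` subjects are controls with elevated
#' branch dropout and an occasional mild lesion. Identical seeds reproduce
#' identical trees.
#'
#' @param template branch template tibble, see [cow_template()].
#' @param cohort one of `"control"`, `"stroke"`, `"icas"`.
#' @param seed integer RNG seed.
#' @param subject_id optional subject identifier string.
#' @return A `cav_tree`: the template with subject-specific columns
#'   (`present`, realized lengths/radii, perturbation state) and attributes
#'   `subject_id`, `cohort`, `seed`.
#' @export
sample_tree <- function(template = cow_template(), cohort = "control",
                        seed = 1L, subject_id = NULL) {
  if (!cohort %in% c("control", "stroke", "icas")) {
    abort(paste0("unknown cohort tag: ", cohort))
  }
  roots <- template$code[is.na(template$parent_code)]
  if (length(roots) < 3) abort("template missing ICA/BA root branches")
  if (is.null(subject_id)) subject_id <- sprintf("%s_%04d", cohort, seed)
  set.seed(seed)
  tr <- template
  n <- nrow(tr)

  # global subject anatomy: size, calibre, head pose
  gl_len <- rtrunc_norm(1, 1, 0.08, 0.88, 1.12)
  gl_rad <- rtrunc_norm(1, 1, 0.06, 0.8, 1.2)
  theta <- rnorm(1, 0, 3 * pi / 180)   # small axial rotation
  shift <- rnorm(3, 0, 2)

  dropout_mult <- if (cohort == "stroke") 1.5 else 1
  drop_chunk <- names(.chunk_dropout)[
    runif(length(.chunk_dropout)) < pmin(1, .chunk_dropout * dropout_mult)]

  tr$length_mm <- tr$length_mm * gl_len * rtrunc_norm(n, 1, 0.07, 0.85, 1.15)
  rad_jit <- rtrunc_norm(n, 1, 0.05, 0.8, 1.2)
  tr$proximal_radius_mm <- tr$proximal_radius_mm * gl_rad * rad_jit
  tr$distal_radius_mm <- pmin(tr$distal_radius_mm * gl_rad * rad_jit,
                              tr$proximal_radius_mm)
  tr$attach_fraction <- pmin(0.99, pmax(0.02,
    tr$attach_fraction + runif(n, -0.02, 0.02)))
  tr$tortuosity_amp_mm <- tr$tortuosity_amp_mm * runif(n, 0.7, 1.3)
  tr$tortuosity_freq <- tr$tortuosity_freq * runif(n, 0.85, 1.15)
  tr$phase <- runif(n, 0, 2 * pi)
  tr$perp_angle <- runif(n, 0, 2 * pi)

  # orientation jitter: rotate each nominal direction by a small random angle
  djit <- matrix(rnorm(3 * n, 0, 0.06), ncol = 3)
  dm <- as.matrix(tr[, c("dir_x", "dir_y", "dir_z")]) + djit
  dm <- dm / sqrt(rowSums(dm^2))
  # whole-head axial rotation + translation (applied to dirs and root starts)
  rz <- matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  dm <- dm %*% t(rz)
  tr$dir_x <- dm[, 1]; tr$dir_y <- dm[, 2]; tr$dir_z <- dm[, 3]
  isr <- is.na(tr$parent_code)
  sm <- as.matrix(tr[isr, c("start_x", "start_y", "start_z")]) %*% t(rz)
  tr$start_x[isr] <- sm[, 1] + shift[1]
  tr$start_y[isr] <- sm[, 2] + shift[2]
  tr$start_z[isr] <- sm[, 3] + shift[3]

  # presence draws, then enforce parent-present consistency top-down
  tr$present <- runif(n) < tr$presence_p
  tr$present[isr] <- TRUE
  tr$present[parse_branch_code(tr$code)$chunk %in% drop_chunk] <- FALSE
  tr$sten_at <- NA_real_; tr$sten_len_mm <- NA_real_; tr$sten_factor <- NA_real_
  tr <- propagate_presence(tr)

  out <- structure(tr, class = c("cav_tree", class(tr)),
                   subject_id = subject_id, cohort = cohort, seed = seed)

  if (cohort %in% c("icas", "stroke")) {
    n_les <- if (cohort == "icas") 1 + stats::rbinom(1, 2, 0.45) else
      stats::rbinom(1, 1, 0.35)
    targets <- intersect(
      c("A3.01", "A4.01", "A3.02", "A4.02", "A5.01", "A6.01",
        "P3.01", "P4.01", "P1", "P2"),
      out$code[out$present])
    n_les <- min(n_les, length(targets))
    if (n_les > 0) {
      picks <- sample(targets, n_les)
      for (i in seq_len(n_les)) {
        kind <- if (runif(1) < 0.55 && cohort == "icas") "occlusion" else "stenosis"
        out <- apply_pathology(out, kind, picks[i],
                               severity = runif(1, 0.5, 0.85),
                               seed = NULL)
      }
    }
  }
  out
}

# children of absent branches are absent
propagate_presence <- function(tr) {
  repeat {
    parent_present <- tr$present[match(tr$parent_code, tr$code)]
    bad <- tr$present & !is.na(tr$parent_code) & !parent_present
    if (!any(bad)) break
    tr$present[bad] <- FALSE
  }
  tr
}

# all descendants of a set of codes (excluding the codes themselves)
tree_descendants <- function(tr, codes) {
  out <- character(0)
  frontier <- codes
  repeat {
    kids <- tr$code[!is.na(tr$parent_code) & tr$parent_code %in% frontier]
    kids <- setdiff(kids, out)
    if (length(kids) == 0) break
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Apply a focal vascular pathology to a tree
#'
#' `stenosis` multiplies the radius over a contiguous arc-length window of
#' the target branch by `1 - severity`; `occlusion` removes the target branch
#' and all of its descendants.
#'
#' @param spec a `cav_tree` from [sample_tree()].
#' @param kind `"stenosis"` or `"occlusion"`.
#' @param target_code branch to lesion (must be present).
#' @param severity fraction in (0, 1]; radius multiplier is `1 - severity`.
#' @param seed optional seed controlling the stenosis window placement; with
#'   `NULL` the current RNG stream is used.
#' @param window_mm stenosis window length (mm).
#' @return the modified `cav_tree`.
#' @export
apply_pathology <- function(spec, kind = c("stenosis", "occlusion"),
                            target_code, severity = 0.6, seed = NULL,
                            window_mm = 5) {
  kind <- match.arg(kind)
  idx <- match(target_code, spec$code)
  if (is.na(idx) || !spec$present[idx]) {
    abort(paste0("pathology target absent: ", target_code))
  }
  if (severity <= 0 || severity > 1) abort("severity must be in (0, 1]")
  for (col in c("sten_at", "sten_len_mm", "sten_factor")) {
    if (!col %in% names(spec)) spec[[col]] <- NA_real_
  }
  if (!is.null(seed)) set.seed(seed)
  if (kind == "occlusion") {
    gone <- c(target_code, tree_descendants(spec, target_code))
    spec$present[spec$code %in% gone] <- FALSE
  } else {
    spec$sten_at[idx] <- runif(1, 0.25, 0.75)
    spec$sten_len_mm[idx] <- min(window_mm, 0.5 * spec$length_mm[idx])
    spec$sten_factor[idx] <- 1 - severity
  }
  spec
}

#' @export
print.cav_tree <- function(x, ...) {
  cat("<cav_tree> subject ", attr(x, "subject_id"), " (", attr(x, "cohort"),
      "): ", sum(x$present), "/", nrow(x), " branches present\n", sep = "")
  invisible(as_tibble(x))
}

#' Summaries of a sampled tree
#'
#' Present-branch, present-chunk counts and total present centerline length.
#'
#' @param spec a `cav_tree`.
#' @return one-row tibble.
#' @export
tree_summary <- function(spec) {
  pres <- spec[spec$present, ]
  tibble(
    subject_id = attr(spec, "subject_id") %||% NA_character_,
    cohort = attr(spec, "cohort") %||% NA_character_,
    n_branches = nrow(pres),
    n_chunks = length(unique(parse_branch_code(pres$code)$chunk)),
    total_length_mm = sum(pres$length_mm)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- centerline realization -------------------------------------------------

unit <- function(v) v / sqrt(sum(v^2))

perp_vector <- function(u, angle) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w1 <- unit(pracma_cross(a, u))
  w2 <- pracma_cross(u, w1)
  cos(angle) * w1 + sin(angle) * w2
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# generate one branch polyline: straight run of chord length C along u with a
# sinusoidal perpendicular displacement, scaled so total arc length equals
# length_mm, then resampled at equal arc steps.
branch_polyline <- function(start, u, length_mm, amp, freq, phase, w,
                            step_mm = 0.12) {
  nfine <- max(64, ceiling(length_mm / 0.05))
  tt <- seq(0, 1, length.out = nfine)
  sinterm <- sin(2 * pi * freq * tt + phase) - sin(phase)
  arc_of <- function(C) {
    px <- start[1] + C * tt * u[1] + amp * sinterm * w[1]
    py <- start[2] + C * tt * u[2] + amp * sinterm * w[2]
    pz <- start[3] + C * tt * u[3] + amp * sinterm * w[3]
    d <- sqrt(diff(px)^2 + diff(py)^2 + diff(pz)^2)
    list(arc = sum(d), x = px, y = py, z = pz, cum = c(0, cumsum(d)))
  }
  lo <- 0.2 * length_mm; hi <- 1.05 * length_mm
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (arc_of(mid)$arc < length_mm) lo <- mid else hi <- mid
  }
  g <- arc_of((lo + hi) / 2)
  s_out <- seq(0, g$arc, by = step_mm)
  if (g$arc - s_out[length(s_out)] > 1e-9) s_out <- c(s_out, g$arc)
  tibble(
    s = s_out,
    x = approx(g$cum, g$x, s_out)$y,
    y = approx(g$cum, g$y, s_out)$y,
    z = approx(g$cum, g$z, s_out)$y
  )
}

#' Realize a sampled tree as labelled centerline polylines
#'
#' Present branches become polylines (arc length equal to the branch length
#' within 1%), attached to their parent at the branch's arc-length fraction,
#' with sinusoidal tortuosity and linearly tapering per-point radii; stenosis
#' windows multiply the radius locally.
#'
#' @param spec a `cav_tree`.
#' @param step_mm sampling step along each polyline (mm).
#' @return tibble with columns `polyline_id`, `branch_code`, `s`, `x`, `y`,
#'   `z`, `radius`.
#' @export
realize_centerlines <- function(spec, step_mm = 0.12) {
  spec <- as_tibble(spec)
  if (!"present" %in% names(spec)) spec$present <- TRUE
  for (col in c("sten_at", "sten_len_mm", "sten_factor")) {
    if (!col %in% names(spec)) spec[[col]] <- NA_real_
  }
  if (!"phase" %in% names(spec)) spec$phase <- 0
  if (!"perp_angle" %in% names(spec)) spec$perp_angle <- 0
  pres <- spec[spec$present, ]
  orphan <- !is.na(pres$parent_code) & !pres$parent_code %in% pres$code
  if (any(orphan)) {
    abort(paste0("branch attaches to absent parent: ",
                 paste(pres$code[orphan], collapse = ", ")))
  }
  # topological order
  done <- character(0)
  order_idx <- integer(0)
  remaining <- seq_len(nrow(pres))
  while (length(remaining) > 0) {
    ready <- remaining[is.na(pres$parent_code[remaining]) |
                         pres$parent_code[remaining] %in% done]
    if (length(ready) == 0) abort("cycle in tree parent links")
    order_idx <- c(order_idx, ready)
    done <- c(done, pres$code[ready])
    remaining <- setdiff(remaining, ready)
  }
  polys <- vector("list", nrow(pres))
  names(polys) <- pres$code
  out <- vector("list", nrow(pres))
  for (ii in seq_along(order_idx)) {
    i <- order_idx[ii]
    code <- pres$code[i]
    if (is.na(pres$parent_code[i])) {
      start <- c(pres$start_x[i], pres$start_y[i], pres$start_z[i])
    } else {
      par <- polys[[pres$parent_code[i]]]
      s_at <- pres$attach_fraction[i] * max(par$s)
      start <- c(approx(par$s, par$x, s_at)$y,
                 approx(par$s, par$y, s_at)$y,
                 approx(par$s, par$z, s_at)$y)
    }
    u <- unit(c(pres$dir_x[i], pres$dir_y[i], pres$dir_z[i]))
    phase <- pres$phase[i]
    w <- perp_vector(u, pres$perp_angle[i])
    pl <- branch_polyline(start, u, pres$length_mm[i],
                          pres$tortuosity_amp_mm[i], pres$tortuosity_freq[i],
                          phase, w, step_mm)
    polys[[code]] <- pl
    L <- max(pl$s)
    rad <- pres$proximal_radius_mm[i] +
      (pres$distal_radius_mm[i] - pres$proximal_radius_mm[i]) * pl$s / L
    if (!is.na(pres$sten_factor[i])) {
      c0 <- pres$sten_at[i] * L
      inwin <- abs(pl$s - c0) <= pres$sten_len_mm[i] / 2
      rad[inwin] <- rad[inwin] * pres$sten_factor[i]
    }
    out[[ii]] <- tibble(polyline_id = ii, branch_code = code,
                        s = pl$s, x = pl$x, y = pl$y, z = pl$z, radius = rad)
  }
  bind_rows(out)
}

#' Sample a collision-free random tree for topology validation
#'
#' Builds a random vascular-tree specification whose tube embedding is
#' guaranteed (by rejection sampling) to be an embedded forest: no two
#' non-adjacent branches come within each other's tube radius, attachment
#' sites on a common parent stay well separated, and no branch attaches at a
#' parent tip. For such phantoms the raster skeleton's endpoint and junction
#' counts are exactly predictable from the specification (leaves + root
#' starts, and one junction per attachment), which the anatomical
#' Circle-of-Willis template deliberately is not: its communicating-artery
#' region and sibling trunks touch, as in real anatomy, altering raster
#' topology.
#'
#' @param n_branches number of branches (including the root).
#' @param seed RNG seed.
#' @param min_length_mm,max_length_mm branch length range.
#' @param radius_mm proximal radius scale.
#' @param clearance_mm extra clearance demanded between tube walls.
#' @return a tree tibble usable with [realize_centerlines()] /
#'   [expected_topology()].
#' @export
sample_topology_tree <- function(n_branches = 10, seed = 1L,
                                 min_length_mm = 18, max_length_mm = 30,
                                 radius_mm = 1.1, clearance_mm = 1.2) {
  set.seed(seed)
  mk <- function(code, parent, at, len, rp, rd, d) {
    tibble(code = code, parent_code = parent, attach_fraction = at,
           length_mm = len, proximal_radius_mm = rp, distal_radius_mm = rd,
           tortuosity_amp_mm = runif(1, 0.1, 0.5),
           tortuosity_freq = runif(1, 1, 2),
           dir_x = d[1], dir_y = d[2], dir_z = d[3], presence_p = 1,
           start_x = if (is.na(parent)) 0 else NA,
           start_y = if (is.na(parent)) 0 else NA,
           start_z = if (is.na(parent)) 0 else NA,
           present = TRUE)
  }
  tr <- mk("B01", NA, NA, runif(1, 28, 36), radius_mm * 1.4, radius_mm * 1.2,
           c(0, 0, 1))
  tube_clearance <- function(tr_new) {
    cl <- realize_centerlines(tr_new, step_mm = 0.5)
    codes <- unique(cl$branch_code)
    new_code <- tr_new$code[nrow(tr_new)]
    a <- cl[cl$branch_code == new_code, ]
    parent <- tr_new$parent_code[match(new_code, tr_new$code)]
    for (other in setdiff(codes, new_code)) {
      b <- cl[cl$branch_code == other, ]
      dm <- sqrt(outer(a$x, b$x, `-`)^2 + outer(a$y, b$y, `-`)^2 +
                   outer(a$z, b$z, `-`)^2)
      pen <- dm - outer(a$radius, b$radius, `+`) - clearance_mm
      if (other == parent) {
        # ignore the neighbourhood of the attachment itself (long enough
        # that a branch tilted >= ~37 degrees has cleared the parent wall)
        exempt <- (a$radius[1] + max(b$radius) + clearance_mm) / 0.6
        pen <- pen[a$s > exempt, , drop = FALSE]
        if (length(pen) == 0) next
      }
      if (min(pen) < 0) return(FALSE)
    }
    # junction sites (attachments) and free tips must stay well separated so
    # each bifurcation is individually resolvable in the raster
    att <- NULL
    for (i in seq_len(nrow(tr_new))) {
      if (is.na(tr_new$parent_code[i])) next
      par <- cl[cl$branch_code == tr_new$parent_code[i], ]
      s_at <- tr_new$attach_fraction[i] * max(par$s)
      att <- rbind(att, c(approx(par$s, par$x, s_at)$y,
                          approx(par$s, par$y, s_at)$y,
                          approx(par$s, par$z, s_at)$y))
    }
    if (!is.null(att) && nrow(att) > 1 && min(dist(att)) < 8) return(FALSE)
    tips <- do.call(rbind, lapply(codes, function(cd) {
      p <- cl[cl$branch_code == cd, ]
      as.numeric(p[nrow(p), c("x", "y", "z")])
    }))
    if (!is.null(att)) {
      dd <- apply(tips, 1, function(t)
        min(sqrt(rowSums(sweep(att, 2, t)^2))))
      if (min(dd) < 6) return(FALSE)
    }
    TRUE
  }
  while (nrow(tr) < n_branches) {
    placed <- FALSE
    for (try in 1:80) {
      pi_ <- sample.int(nrow(tr), 1)
      parent <- tr$code[pi_]
      Lp <- tr$length_mm[pi_]
      at <- runif(1, max(0.25, 6 / Lp), min(0.8, 1 - 6 / Lp))
      # attachments on one parent stay >= 8 mm apart
      sibs <- tr$attach_fraction[!is.na(tr$parent_code) &
                                   tr$parent_code == parent]
      if (length(sibs) > 0 && min(abs(at - sibs)) * Lp < 8) next
      u <- unit(c(tr$dir_x[pi_], tr$dir_y[pi_], tr$dir_z[pi_]))
      repeat {
        d <- unit(rnorm(3))
        dt <- sum(d * u)
        # tilt 45-100 degrees off the parent axis: acute forward angles hug
        # the parent tube, retrograde ones fold back along it
        if (dt < 0.7 && dt > -0.2) break
      }
      rp <- radius_mm * runif(1, 0.8, 1.1)
      cand <- bind_rows(tr, mk(sprintf("B%02d", nrow(tr) + 1), parent, at,
                               runif(1, min_length_mm, max_length_mm),
                               rp, rp * 0.75, d))
      if (tube_clearance(cand)) { tr <- cand; placed <- TRUE; break }
    }
    if (!placed) break
  }
  structure(tr, class = c("cav_tree", class(tr)),
            subject_id = sprintf("topo_%04d", seed), cohort = "phantom",
            seed = seed)
}

#' Voxelize labelled centerlines into paired occupancy and label volumes
#'
#' A voxel is foreground iff its centre lies within the local tube radius of
#' some centerline point; its label is the branch code of the nearest such
#' point. The two volumes share grid, spacing and origin exactly.
#'
#' @param centerlines tibble with `x`, `y`, `z`, `radius` and (optionally)
#'   `branch_code` columns, as from [realize_centerlines()].
#' @param spacing_mm voxel spacing, scalar (isotropic) or length 3.
#' @param margin_mm padding added around the tree bounding box.
#' @return list with elements `volume` ([vox_volume()]) and `labels`
#'   ([label_volume()]).
#' @export
voxelize <- function(centerlines, spacing_mm = 0.284, margin_mm = 2) {
  if (is.null(centerlines) || nrow(centerlines) == 0) {
    abort("empty centerline set")
  }
  spacing <- if (length(spacing_mm) == 1) rep(spacing_mm, 3) else as.numeric(spacing_mm)
  if (any(spacing <= 0)) abort("spacing must be positive")
  if (!"branch_code" %in% names(centerlines)) {
    centerlines$branch_code <- "V1"
  }
  thin_br <- centerlines %>%
    group_by(.data$branch_code) %>%
    summarise(rmax = max(.data$radius), .groups = "drop") %>%
    filter(.data$rmax < max(spacing) / 2)
  if (nrow(thin_br) > 0) {
    warn(paste0("spacing coarse relative to branch radius; branches may ",
                "vanish: ", paste(thin_br$branch_code, collapse = ", ")))
  }
  codes <- sort(unique(centerlines$branch_code))
  pad <- max(centerlines$radius) + margin_mm
  lo <- c(min(centerlines$x), min(centerlines$y), min(centerlines$z)) - pad
  hi <- c(max(centerlines$x), max(centerlines$y), max(centerlines$z)) + pad
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  lab <- cpp_voxelize(as.matrix(centerlines[, c("x", "y", "z")]),
                      centerlines$radius,
                      match(centerlines$branch_code, codes),
                      lo, spacing, dims)
  occ <- array(lab > 0L, dims)
  if (!any(occ)) abort("voxelization produced empty foreground")
  list(
    volume = vox_volume(occ, spacing, lo),
    labels = label_volume(array(lab, dims), codes, spacing, lo)
  )
}
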