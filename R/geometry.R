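#' Resample a volume to isotropic voxels
#'
#' Anisotropic grids are resampled axis-by-axis to the smallest input
#' spacing using cubic (Catmull-Rom) greyscale interpolation of the binary
#' occupancy, then re-binarised at 0.5. Already-isotropic input is returned
#' unchanged.
#'
#' @param volume a [vox_volume()].
#' @param tol relative spacing tolerance under which axes count as isotropic.
#' @return a [vox_volume()] with isotropic spacing.
#' @export
resample_isovoxel <- function(volume, tol = 0.01) {
  if (!any(volume$occupancy)) abort("volume has empty foreground")
  sp <- volume$spacing
  target <- min(sp)
  if (all(abs(sp / target - 1) <= tol)) return(volume)
  arr <- array(as.numeric(volume$occupancy), dim(volume$occupancy))
  new_sp <- sp
  for (a in 1:3) {
    if (abs(sp[a] / target - 1) <= tol) next
    n_old <- dim(arr)[a]
    n_new <- as.integer(round(n_old * sp[a] / target))
    arr <- cpp_resample_axis(arr, dim(arr), a - 1L, n_new)
    new_sp[a] <- sp[a] * n_old / n_new
  }
  # voxel centres of the resampled grid keep the same physical extent: the
  # first output centre sits at origin - sp/2 + new_sp/2
  new_origin <- volume$origin - sp / 2 + new_sp / 2
  vox_volume(array(arr >= 0.5, dim(arr)), new_sp, new_origin)
}

#' Extract an isosurface mesh of the vessel wall
#'
#' Marching tetrahedra over the (optionally Gaussian-smoothed) occupancy,
#' padded with a background shell so every component closes. Vertices are in
#' mm; faces index vertices (1-based).
#'
#' @param volume a [vox_volume()].
#' @param iso_level iso value in (0, 1); default 0.5.
#' @param smooth_sigma_vox Gaussian sigma in voxels applied before meshing
#'   (reduces staircase bias in surface area); if the smoothed field drops
#'   entirely below `iso_level` (very thin structures) the unsmoothed field
#'   is meshed instead.
#' @return A `surface_mesh`: list with `vertices` (n x 3), `faces` (m x 3),
#'   `area` (mm^2).
#' @export
extract_surface <- function(volume, iso_level = 0.5, smooth_sigma_vox = 1) {
  if (!any(volume$occupancy)) abort("volume has empty foreground")
  d <- dim(volume$occupancy)
  pad <- 2L
  arr <- array(0, d + 2L * pad)
  arr[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(volume$occupancy)
  origin <- volume$origin - pad * volume$spacing
  mesh_of <- function(a) {
    cpp_marching_tets(a, dim(a), origin, volume$spacing, iso_level)
  }
  m <- NULL
  if (smooth_sigma_vox > 0) {
    sm <- cpp_gauss3d(arr, dim(arr), rep(smooth_sigma_vox, 3))
    if (max(sm) >= iso_level) m <- mesh_of(sm)
  }
  if (is.null(m) || nrow(m$vertices) == 0) m <- mesh_of(arr)
  structure(list(vertices = m$vertices, faces = m$faces, area = m$area),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces, area ", signif(x$area, 5), " mm^2\n", sep = "")
  invisible(x)
}

#' Skeletonise a binary vessel volume
#'
#' Topology-preserving 3D thinning to a one-voxel-wide curve skeleton,
#' returned as a graph over skeleton voxels with 26-connected edges, degree
#' classes (endpoint = 1, regular = 2, junction >= 3) and the Euclidean
#' distance transform value (the maximally inscribed sphere radius) at every
#' node.
#'
#' @param volume a [vox_volume()].
#' @return A `skeleton_graph`: list with `nodes` (tibble: node, i, j, k
#'   voxel indices 1-based, x/y/z mm, radius mm, degree), `edges` (tibble:
#'   from, to, weight = mean endpoint radius), grid metadata, and the
#'   distance transform array (`edt`).
#' @export
skeletonize <- function(volume) {
  if (!any(volume$occupancy)) abort("volume has empty foreground")
  d <- dim(volume$occupancy)
  occ <- as.logical(volume$occupancy)
  edt <- cpp_edt3d(occ, d, volume$spacing)
  sk <- cpp_thin3d(occ, d)
  skeleton_graph_from_mask(array(sk, d), edt, volume)
}

skeleton_graph_from_mask <- function(mask, edt, volume) {
  d <- dim(mask)
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0) abort("skeleton is empty")
  ids <- array(0L, d)
  ids[mask] <- order(order(which(mask)))  # 1..n in linear index order
  # build 26-adjacency edges (each pair once)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  lin_idx <- which(mask)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    ii <- w[, 1] + o[1]; jj <- w[, 2] + o[2]; kk <- w[, 3] + o[3]
    ok <- ii >= 1 & jj >= 1 & kk >= 1 & ii <= d[1] & jj <= d[2] & kk <= d[3]
    if (!any(ok)) next
    nb <- ids[cbind(ii[ok], jj[ok], kk[ok])]
    me <- ids[w[ok, , drop = FALSE]]
    keep <- nb > 0 & nb > me
    from <- c(from, me[keep]); to <- c(to, nb[keep])
  }
  # drop redundant diagonal edges: an edge whose endpoints share a common
  # neighbour is a triangle shortcut of the 26-connectivity and would
  # inflate degrees at path corners; removal never disconnects
  if (length(from) > 0) {
    elen <- sqrt(((w[from, 1] - w[to, 1]) * volume$spacing[1])^2 +
                 ((w[from, 2] - w[to, 2]) * volume$spacing[2])^2 +
                 ((w[from, 3] - w[to, 3]) * volume$spacing[3])^2)
    ord <- order(-elen, from, to)
    nset <- vector("list", nrow(w))
    for (r in seq_along(from)) {
      nset[[from[r]]] <- c(nset[[from[r]]], to[r])
      nset[[to[r]]] <- c(nset[[to[r]]], from[r])
    }
    keep <- rep(TRUE, length(from))
    for (r in ord) {
      u <- from[r]; v <- to[r]
      if (length(intersect(nset[[u]], nset[[v]])) > 0) {
        keep[r] <- FALSE
        nset[[u]] <- setdiff(nset[[u]], v)
        nset[[v]] <- setdiff(nset[[v]], u)
      }
    }
    from <- from[keep]; to <- to[keep]
  }
  rad <- edt[lin_idx]
  mm <- sweep(sweep(w - 1, 2, volume$spacing, `*`), 2, volume$origin, `+`)
  nodes <- tibble(
    node = seq_len(nrow(w)),
    i = w[, 1], j = w[, 2], k = w[, 3],
    x = mm[, 1], y = mm[, 2], z = mm[, 3],
    radius = rad
  )
  deg <- tabulate(c(from, to), nbins = nrow(nodes))
  nodes$degree <- deg
  structure(
    list(nodes = nodes, edges = tibble(from = from, to = to,
                                       weight = (rad[from] + rad[to]) / 2),
         dims = d, spacing = volume$spacing, origin = volume$origin,
         edt = edt, root = integer(0)),
    class = "skeleton_graph"
  )
}

#' @export
print.skeleton_graph <- function(x, ...) {
  s <- skeleton_summary(x)
  cat("<skeleton_graph> ", nrow(x$nodes), " voxels, ", s$n_endpoints,
      " endpoints, ", s$n_junctions, " junctions, ", s$n_components,
      " components, ", s$n_cycles, " cycles\n", sep = "")
  invisible(x)
}

skeleton_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    data.frame(from = graph$edges$from, to = graph$edges$to),
    directed = FALSE,
    vertices = data.frame(name = graph$nodes$node)
  )
}

#' Topological summary of a skeleton graph
#'
#' Endpoint voxels have degree 1. Junction voxels (degree >= 3) belonging to
#' one physical bifurcation region are merged before counting: thinning
#' spreads a junction over a neighbourhood whose size scales with the local
#' vessel radius, so junction voxels closer than
#' `max(merge_factor * spacing, r_i + r_j)` count as one junction.
#'
#' @param graph a `skeleton_graph`.
#' @param merge_factor junction merge scale in voxel spacings.
#' @return one-row tibble: `n_endpoints`, `n_junctions`, `n_components`,
#'   `n_cycles`.
#' @export
skeleton_summary <- function(graph, merge_factor = 3) {
  g <- skeleton_igraph(graph)
  comp <- igraph::components(g)$no
  cyc <- nrow(graph$edges) - nrow(graph$nodes) + comp
  jn <- which(graph$nodes$degree >= 3)
  njc <- 0L
  if (length(jn) > 0) {
    pts <- as.matrix(graph$nodes[jn, c("x", "y", "z")])
    rr <- graph$nodes$radius[jn]
    dmat <- as.matrix(dist(pts))
    thr <- pmax(outer(rr, rr, `+`), merge_factor * max(graph$spacing))
    gj <- igraph::graph_from_adjacency_matrix(dmat <= thr, mode = "undirected")
    njc <- igraph::components(gj)$no
  }
  tibble(
    n_endpoints = sum(graph$nodes$degree == 1),
    n_junctions = njc,
    n_components = comp,
    n_cycles = cyc
  )
}

#' Prune short terminal skeleton branches
#'
#' Iteratively removes leaf paths shorter than `min_branch_mm` that end at a
#' junction, until a fixed point. Whole components that are bare paths
#' (trunks) are never removed.
#'
#' @param graph a `skeleton_graph`.
#' @param min_branch_mm threshold (mm); 0 is the identity.
#' @return the pruned `skeleton_graph`.
#' @export
prune_skeleton <- function(graph, min_branch_mm = 2) {
  if (min_branch_mm < 0) abort("pruning threshold must be >= 0")
  if (min_branch_mm == 0) return(graph)
  repeat {
    adj <- adjacency_list(graph)
    deg <- lengths(adj)
    leaves <- which(deg == 1)
    cand <- list()
    for (leaf in leaves) {
      path <- walk_chain(graph, adj, deg, leaf)
      if (path$end_kind == "junction" && path$length_mm < min_branch_mm) {
        cand[[length(cand) + 1]] <- path
      }
    }
    if (length(cand) == 0) break
    # remove one spur at a time, shortest first: when every leaf path of a
    # junction is below threshold this keeps the through-path (the trunk)
    lens <- vapply(cand, function(p) p$length_mm, 1)
    pick <- cand[[which.min(lens)]]
    graph <- drop_nodes(graph, pick$nodes[-length(pick$nodes)])
  }
  graph
}

adjacency_list <- function(graph) {
  n <- nrow(graph$nodes)
  adj <- vector("list", n)
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    adj[[e$from[r]]] <- c(adj[[e$from[r]]], e$to[r])
    adj[[e$to[r]]] <- c(adj[[e$to[r]]], e$from[r])
  }
  adj
}

# follow a degree-<=2 chain from a leaf until hitting a junction/another leaf
walk_chain <- function(graph, adj, deg, leaf) {
  nodes <- leaf
  prev <- 0L
  cur <- leaf
  len <- 0
  repeat {
    nxt <- setdiff(adj[[cur]], prev)
    if (length(nxt) == 0) return(list(nodes = nodes, end_kind = "leaf", length_mm = len))
    nxt <- nxt[1]
    len <- len + node_dist(graph, cur, nxt)
    nodes <- c(nodes, nxt)
    if (deg[nxt] >= 3) return(list(nodes = nodes, end_kind = "junction", length_mm = len))
    if (deg[nxt] == 1) return(list(nodes = nodes, end_kind = "leaf", length_mm = len))
    prev <- cur
    cur <- nxt
  }
}

node_dist <- function(graph, a, b) {
  sqrt((graph$nodes$x[a] - graph$nodes$x[b])^2 +
       (graph$nodes$y[a] - graph$nodes$y[b])^2 +
       (graph$nodes$z[a] - graph$nodes$z[b])^2)
}

drop_nodes <- function(graph, drop) {
  keep <- setdiff(seq_len(nrow(graph$nodes)), drop)
  remap <- integer(nrow(graph$nodes))
  remap[keep] <- seq_along(keep)
  nodes <- graph$nodes[keep, ]
  nodes$node <- seq_len(nrow(nodes))
  e <- graph$edges
  ok <- e$from %in% keep & e$to %in% keep
  edges <- tibble(from = remap[e$from[ok]], to = remap[e$to[ok]],
                  weight = e$weight[ok])
  deg <- tabulate(c(edges$from, edges$to), nbins = nrow(nodes))
  nodes$degree <- deg
  graph$nodes <- nodes
  graph$edges <- edges
  graph$root <- intersect(remap[graph$root], seq_len(nrow(nodes)))
  graph
}

#' Root the skeleton and break cycles into a forest
#'
#' Chooses one root per connected component on the lowest occupied slice
#' (minimum z index, ties by smallest x then y index) and breaks cycles with
#' a spanning tree that maximises retained inscribed radius, so cuts fall on
#' the thinnest vessels (typically communicating arteries).
#'
#' @param graph a (pruned) `skeleton_graph`.
#' @return the `skeleton_graph` with forest edges, `root` nodes, a `parent`
#'   column on nodes and `n_cut_edges` recording how many cycle edges were
#'   removed.
#' @export
build_tree <- function(graph) {
  g <- skeleton_igraph(graph)
  comp <- igraph::components(g)
  membership <- comp$membership[as.character(graph$nodes$node)]
  roots <- integer(comp$no)
  for (cc in seq_len(comp$no)) {
    cand <- which(membership == cc)
    ord <- order(graph$nodes$k[cand], graph$nodes$i[cand], graph$nodes$j[cand])
    roots[cc] <- cand[ord[1]]
  }
  n_edges_before <- nrow(graph$edges)
  mst <- igraph::mst(g, weights = -graph$edges$weight)
  em <- igraph::as_edgelist(mst)
  from <- as.integer(em[, 1]); to <- as.integer(em[, 2])
  # recover weights for retained edges
  key <- paste(pmin(from, to), pmax(from, to))
  key0 <- paste(pmin(graph$edges$from, graph$edges$to),
                pmax(graph$edges$from, graph$edges$to))
  wt <- graph$edges$weight[match(key, key0)]
  graph$edges <- tibble(from = from, to = to, weight = wt)
  graph$nodes$degree <- tabulate(c(from, to), nbins = nrow(graph$nodes))
  graph$root <- roots
  graph$n_cut_edges <- n_edges_before - nrow(graph$edges)
  graph$nodes$component <- membership
  # parent links by BFS from each root
  adj <- adjacency_list(graph)
  parent <- rep(NA_integer_, nrow(graph$nodes))
  for (r in roots) {
    queue <- r
    parent[r] <- 0L
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (is.na(parent[nb])) {
          parent[nb] <- cur
          queue <- c(queue, nb)
        }
      }
    }
  }
  graph$nodes$parent <- parent
  graph
}

#' Extract radius-annotated centerline polylines from a rooted skeleton
#'
#' Decomposes the forest into maximal paths between break nodes (junctions,
#' endpoints, roots), smooths point positions with a moving average,
#' annotates each point with the inscribed radius (distance transform,
#' trilinearly interpolated) and unit tangents (central differences).
#' Endpoint tips, which thinning retracts by roughly one vessel radius, are
#' extended along the local tangent to the foreground boundary.
#'
#' @param tree a rooted `skeleton_graph` from [build_tree()].
#' @param volume the originating [vox_volume()] (for tip extension).
#' @param smooth_window moving-average window (points, odd).
#' @param extend_tips extend terminal polylines to the vessel wall.
#' @param merge_mm junction-to-junction paths shorter than this are
#'   sub-resolution artefacts of one physical bifurcation region split into
#'   several skeleton junctions; they are absorbed into their longest
#'   neighbouring path.
#' @return tibble: `polyline_id`, `pt`, `x`, `y`, `z`, `radius`, `tx`, `ty`,
#'   `tz`, `start_kind`, `end_kind` (junction/endpoint/root), `start_node`,
#'   `end_node` (skeleton node ids of the path ends).
#' @export
extract_centerlines <- function(tree, volume, smooth_window = 5,
                                extend_tips = TRUE, merge_mm = 0) {
  adj <- adjacency_list(tree)
  deg <- lengths(adj)
  n <- nrow(tree$nodes)
  is_break <- deg != 2
  # isolated single nodes: emit nothing for them
  paths <- list()
  used <- new.env()
  edge_key <- function(a, b) paste(min(a, b), max(a, b))
  for (b0 in which(is_break)) {
    for (nb in adj[[b0]]) {
      k <- edge_key(b0, nb)
      if (!is.null(used[[k]])) next
      nodes <- c(b0, nb)
      used[[k]] <- TRUE
      prev <- b0; cur <- nb
      while (!is_break[cur]) {
        nxt <- setdiff(adj[[cur]], prev)
        if (length(nxt) == 0) break
        used[[edge_key(cur, nxt[1])]] <- TRUE
        nodes <- c(nodes, nxt[1])
        prev <- cur; cur <- nxt[1]
      }
      paths[[length(paths) + 1]] <- nodes
    }
  }
  # absorb sub-resolution junction-junction stubs into their longest
  # neighbouring path so one physical bifurcation yields one break point
  if (merge_mm > 0 && length(paths) > 1) {
    path_len <- function(nd) {
      sum(sqrt(diff(tree$nodes$x[nd])^2 + diff(tree$nodes$y[nd])^2 +
                 diff(tree$nodes$z[nd])^2))
    }
    repeat {
      lens <- vapply(paths, path_len, 1)
      ends1 <- vapply(paths, function(p) p[1], 1L)
      ends2 <- vapply(paths, function(p) p[length(p)], 1L)
      short <- which(lens < merge_mm &
                       deg[ends1] >= 3 & deg[ends2] >= 3)
      if (length(short) == 0) break
      i <- short[which.min(lens[short])]
      # neighbours share an endpoint node with the stub
      nbs <- setdiff(which(ends1 %in% paths[[i]][c(1, length(paths[[i]]))] |
                             ends2 %in% paths[[i]][c(1, length(paths[[i]]))]),
                     i)
      if (length(nbs) == 0) break
      j <- nbs[which.max(lens[nbs])]
      a <- paths[[i]]; b <- paths[[j]]
      # orient so that b's matching end meets a
      if (b[1] %in% c(a[1], a[length(a)])) {
        if (a[length(a)] != b[1]) a <- rev(a)
        merged <- c(a, b[-1])
      } else {
        if (a[1] != b[length(b)]) a <- rev(a)
        merged <- c(b, a[-1])
      }
      paths[[j]] <- merged
      paths[[i]] <- NULL
    }
  }
  # pure cycles with no break node (rare after MST): none remain in a forest
  kind_of <- function(nd) {
    if (nd %in% tree$root && deg[nd] <= 1) "root"
    else if (deg[nd] >= 3) "junction"
    else "endpoint"
  }
  occ_num <- array(as.numeric(volume$occupancy), dim(volume$occupancy))
  out <- vector("list", length(paths))
  for (p in seq_along(paths)) {
    nd <- paths[[p]]
    pts <- cbind(tree$nodes$x[nd], tree$nodes$y[nd], tree$nodes$z[nd])
    sk_start <- kind_of(nd[1])
    sk_end <- kind_of(nd[length(nd)])
    if (extend_tips) {
      if (sk_start %in% c("endpoint", "root")) {
        pts <- rbind(tip_extension(pts[2, ], pts[1, ], occ_num, volume), pts)
      }
      if (sk_end %in% c("endpoint", "root")) {
        m <- nrow(pts)
        pts <- rbind(pts, tip_extension(pts[m - 1, ], pts[m, ], occ_num, volume))
      }
    }
    sm <- smooth_polyline(pts, smooth_window)
    rad <- cpp_trilinear(tree$edt, tree$dims, tree$origin, tree$spacing, sm)
    rad <- pmax(rad, 0.25 * min(tree$spacing))
    tang <- polyline_tangents(sm)
    out[[p]] <- tibble(
      polyline_id = p, pt = seq_len(nrow(sm)),
      x = sm[, 1], y = sm[, 2], z = sm[, 3], radius = rad,
      tx = tang[, 1], ty = tang[, 2], tz = tang[, 3],
      start_kind = sk_start, end_kind = sk_end,
      start_node = nd[1], end_node = nd[length(nd)]
    )
  }
  bind_rows(out)
}

# march from `tip` along the (from -> tip) direction to the wall; returns the
# appended points (possibly none)
tip_extension <- function(from, tip, occ_num, volume, max_mm = 10) {
  u <- tip - from
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) return(NULL)
  u <- u / nu
  step <- min(volume$spacing) / 2
  added <- NULL
  t <- step
  while (t <= max_mm) {
    p <- tip + t * u
    v <- cpp_trilinear(occ_num, dim(occ_num), volume$origin, volume$spacing,
                       matrix(p, 1))
    if (v < 0.5) break
    added <- rbind(added, p)
    t <- t + step
  }
  added
}

smooth_polyline <- function(pts, window) {
  n <- nrow(pts)
  if (window <= 1 || n <= 2) return(pts)
  half <- floor(window / 2)
  out <- pts
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    out[i, ] <- colMeans(pts[lo:hi, , drop = FALSE])
  }
  out
}

polyline_tangents <- function(pts) {
  n <- nrow(pts)
  if (n == 1) return(matrix(c(1, 0, 0), 1))
  tg <- matrix(0, n, 3)
  tg[1, ] <- pts[2, ] - pts[1, ]
  tg[n, ] <- pts[n, ] - pts[n - 1, ]
  if (n > 2) tg[2:(n - 1), ] <- pts[3:n, ] - pts[1:(n - 2), ]
  nn <- sqrt(rowSums(tg^2))
  nn[nn == 0] <- 1
  tg / nn
}

#' Expected endpoint and junction counts of a sampled tree
#'
#' Computes, from the generating tree specification, how many skeleton
#' endpoints and junction clusters a voxelization at a given spacing should
#' resolve: attachment sites closer together than the merge tolerance (or
#' falling inside the same parent-calibre neighbourhood) coalesce into one
#' junction, exactly as the raster skeleton merges them.
#'
#' @param spec a `cav_tree`.
#' @param spacing_mm voxel spacing the tree will be rasterised at.
#' @param merge_factor junctions closer than `merge_factor * spacing` (or
#'   than the local vessel radius) merge.
#' @return one-row tibble: `n_endpoints`, `n_junctions`.
#' @export
expected_topology <- function(spec, spacing_mm, merge_factor = 3) {
  cl <- realize_centerlines(spec)
  spec_t <- as_tibble(spec)
  pres <- spec_t[spec_t$present, ]
  # attachment points in mm
  att <- list()
  for (i in seq_len(nrow(pres))) {
    if (is.na(pres$parent_code[i])) next
    par <- cl[cl$branch_code == pres$parent_code[i], ]
    s_at <- pres$attach_fraction[i] * max(par$s)
    att[[length(att) + 1]] <- c(
      approx(par$s, par$x, s_at)$y, approx(par$s, par$y, s_at)$y,
      approx(par$s, par$z, s_at)$y,
      approx(par$s, par$radius, s_at)$y)
  }
  tol <- merge_factor * max(spacing_mm)
  n_j <- 0L
  merged <- rep(FALSE, length(att))
  if (length(att) > 0) {
    am <- do.call(rbind, att)
    dmat <- as.matrix(dist(am[, 1:3, drop = FALSE]))
    thr <- outer(pmax(tol, am[, 4]), pmax(tol, am[, 4]), pmax)
    g <- igraph::graph_from_adjacency_matrix(dmat <= thr, mode = "undirected")
    n_j <- igraph::components(g)$no
  }
  # endpoints: root starts + branch tips that are not swallowed by a junction
  tips <- list()
  for (i in seq_len(nrow(pres))) {
    pl <- cl[cl$branch_code == pres$code[i], ]
    tips[[length(tips) + 1]] <- as.numeric(pl[nrow(pl), c("x", "y", "z")])
    if (is.na(pres$parent_code[i])) {
      tips[[length(tips) + 1]] <- as.numeric(pl[1, c("x", "y", "z")])
    }
  }
  n_e <- 0L
  if (length(tips) > 0) {
    tm <- do.call(rbind, tips)
    if (length(att) > 0) {
      am <- do.call(rbind, att)
      dd <- apply(tm, 1, function(p) {
        min(sqrt(colSums((t(am[, 1:3, drop = FALSE]) - p)^2)) -
              pmax(tol, am[, 4]))
      })
      n_e <- sum(dd > 0)
    } else {
      n_e <- nrow(tm)
    }
  }
  tibble(n_endpoints = n_e, n_junctions = n_j)
}
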