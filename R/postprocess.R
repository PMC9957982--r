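#' Anatomical rule-assisted post-processing of voted chunk labels
#'
#' Two configurable rules applied to segment-level chunk labels until a
#' fixed point (idempotent):
#'
#' * connectivity: a segment whose chunk label is not connected, through the
#'   segment adjacency graph, to any other segment of the same chunk adopts
#'   the modal chunk of its neighbours;
#' * laterality: right/left chunk pairs must lie on consistent sides of the
#'   labelled mass's mid-sagittal plane; segments contradicting the
#'   majority side convention are flipped to the mirrored chunk.
#'
#' Segment adjacency is inferred from the spot cloud: segments whose end
#' spots come within `adjacency_tol_mm` touch.
#'
#' @param table labelled feature table (needs `segment_id`, `pred_chunk`,
#'   raw positions `pos_x/y/z`, and arc position `s`).
#' @param ensemble the `cav_ensemble` (for the nomenclature and config
#'   toggles `rule_connectivity`, `rule_laterality`).
#' @param adjacency_tol_mm segment endpoints closer than this touch.
#' @param max_iter safety cap on rule iterations.
#' @return `table` with `pred_chunk` possibly relabelled; attribute
#'   `n_relabelled` counts changed segments.
#' @export
anatomical_postprocess <- function(table, ensemble, adjacency_tol_mm = 3,
                                   max_iter = 5) {
  map <- ensemble$nomenclature
  config <- ensemble$config
  if (!all(c("pos_x", "pos_y", "pos_z") %in% names(table))) {
    table$pos_x <- table$x; table$pos_y <- table$y; table$pos_z <- table$z
  }
  has_nodes <- all(c("start_node", "end_node") %in% names(table)) &&
    !anyNA(table$start_node)
  if (!".chunk_prob" %in% names(table)) table$.chunk_prob <- 0
  segs <- table %>%
    group_by(.data$segment_id) %>%
    summarise(
      chunk = dplyr::first(.data$pred_chunk),
      conf = mean(.data$.chunk_prob),
      mean_x = mean(.data$pos_x),
      x1 = .data$pos_x[which.min(.data$s)], y1 = .data$pos_y[which.min(.data$s)],
      z1 = .data$pos_z[which.min(.data$s)],
      x2 = .data$pos_x[which.max(.data$s)], y2 = .data$pos_y[which.max(.data$s)],
      z2 = .data$pos_z[which.max(.data$s)],
      n1 = if (has_nodes) dplyr::first(.data$start_node) else NA_integer_,
      n2 = if (has_nodes) dplyr::first(.data$end_node) else NA_integer_,
      .groups = "drop"
    )
  ns <- nrow(segs)
  adj <- matrix(FALSE, ns, ns)
  if (has_nodes) {
    # exact adjacency: segments sharing a skeleton junction node touch
    nodes <- c(segs$n1, segs$n2)
    seg_of2 <- rep(seq_len(ns), 2)
    for (nd in unique(nodes)) {
      mem <- unique(seg_of2[nodes == nd])
      if (length(mem) > 1) adj[t(utils::combn(mem, 2))] <- TRUE
    }
    adj <- adj | t(adj)
  } else {
    ends <- rbind(as.matrix(segs[, c("x1", "y1", "z1")]),
                  as.matrix(segs[, c("x2", "y2", "z2")]))
    seg_of <- rep(seq_len(ns), 2)
    dd <- as.matrix(dist(ends))
    touch <- which(dd <= adjacency_tol_mm, arr.ind = TRUE)
    adj[cbind(seg_of[touch[, 1]], seg_of[touch[, 2]])] <- TRUE
  }
  diag(adj) <- FALSE
  n_rel <- 0L
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    if (isTRUE(config$rule_connectivity %||% TRUE)) {
      new_chunk <- segs$chunk
      for (i in seq_len(ns)) {
        nbs <- which(adj[i, ])
        # one neighbour is no evidence: a correct leaf would be relabelled
        # whenever its single neighbour is itself mispredicted
        if (length(nbs) < 2) next
        same <- segs$chunk[nbs] == segs$chunk[i]
        if (any(same)) next
        # a segment with no same-chunk neighbour is legitimate when one of
        # its neighbours is an anatomically adjacent chunk (cerebellar
        # offshoots on the basilar, communicating arteries, ...); it is a
        # stray island only when even that fails
        legit <- map$adjacency[[segs$chunk[i]]]
        if (!is.null(legit) && any(segs$chunk[nbs] %in% legit)) next
        # act only on unanimous evidence against a low-confidence label
        if (length(unique(segs$chunk[nbs])) > 1) next
        if (segs$conf[i] >= 0.75) next
        # if the mirror chunk fits the neighbourhood this is a side error,
        # not a territory error
        mir <- chunk_mirror(segs$chunk[i], map)
        mir_legit <- map$adjacency[[mir]]
        if (mir != segs$chunk[i] &&
            any(segs$chunk[nbs] %in% c(mir, mir_legit))) {
          new_chunk[i] <- mir
        } else {
          new_chunk[i] <- segs$chunk[nbs][1]
        }
      }
      if (any(new_chunk != segs$chunk)) {
        n_rel <- n_rel + sum(new_chunk != segs$chunk)
        segs$chunk <- new_chunk
        changed <- TRUE
      }
    }
    if (isTRUE(config$rule_side_propagation %||% TRUE)) {
      # side consistency along the centerline forest: the spanning-tree
      # construction cuts cycles at the thinnest vessels (the communicating
      # arteries), so each lateral subtree hangs off one far-lateral trunk.
      # Far-lateral segments anchor the subject's physical side; the side
      # propagates along tree adjacency through lateral-labelled segments
      # (midline labels block, where the two sides meet), and lateral labels
      # contradicting their propagated physical side flip to the mirror
      # chunk. Resolves left/right ambiguity of midline-hugging territories
      # (pericallosal ACA) that coordinates alone cannot separate.
      x0 <- mean(table$pos_x)
      side <- chunk_side(segs$chunk, map)
      lat <- side %in% c("right", "left")
      far <- lat & abs(segs$mean_x - x0) > 8
      if (any(far)) {
        sgn0 <- ifelse(side[far] == "right", 1, -1) * sign(segs$mean_x[far] - x0)
        right_sign <- if (sum(sgn0, na.rm = TRUE) >= 0) 1 else -1
        phys_side <- ifelse(sign(segs$mean_x - x0) == right_sign,
                            "right", "left")
        prop <- rep(NA_character_, ns)
        prop[far] <- phys_side[far]
        queue <- which(far)
        while (length(queue) > 0) {
          cur <- queue[1]; queue <- queue[-1]
          for (nb in which(adj[cur, ])) {
            if (!is.na(prop[nb])) next
            if (side[nb] == "midline") { prop[nb] <- "midline"; next }
            prop[nb] <- prop[cur]
            queue <- c(queue, nb)
          }
        }
        flip <- lat & !is.na(prop) & prop %in% c("right", "left") &
          side != prop
        if (any(flip)) {
          segs$chunk[flip] <- chunk_mirror(segs$chunk[flip], map)
          n_rel <- n_rel + sum(flip)
          changed <- TRUE
        }
      }
    }
    if (isTRUE(config$rule_laterality %||% TRUE)) {
      x0 <- mean(table$pos_x)
      side <- chunk_side(segs$chunk, map)
      # learn the dataset's right-side sign from the labelled majority
      lat <- side %in% c("right", "left")
      if (any(lat)) {
        sgn <- ifelse(side[lat] == "right", 1, -1) * sign(segs$mean_x[lat] - x0)
        right_sign <- if (sum(sgn, na.rm = TRUE) >= 0) 1 else -1
        # scope: only segments the adjacency graph cannot adjudicate —
        # midline-hugging vessels legitimately cross the plane, so connected
        # segments are left to the connectivity rule
        isolated <- rowSums(adj) == 0
        wrong <- lat & isolated & abs(segs$mean_x - x0) > 5 &
          ifelse(side == "right", right_sign, -right_sign) *
            sign(segs$mean_x - x0) < 0
        if (any(wrong)) {
          segs$chunk[wrong] <- chunk_mirror(segs$chunk[wrong], map)
          n_rel <- n_rel + sum(wrong)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  if (n_rel > 0) inform(paste0("post-processing relabelled ", n_rel, " segment(s)"))
  table$pred_chunk <- segs$chunk[match(table$segment_id, segs$segment_id)]
  attr(table, "n_relabelled") <- n_rel
  table
}
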