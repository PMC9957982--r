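#' Per-class classification metrics
#'
#' One-vs-rest accuracy, precision, recall and F1 (percent) per class, with
#' the multiclass confusion matrix. Classes absent from the test truth are
#' excluded and listed.
#'
#' @param truth,pred aligned character vectors of true and predicted labels.
#' @param level `"chunk"` or `"branch"` (annotation only).
#' @param stage `"raw"`, `"voted"` or `"postprocessed"` (annotation only).
#' @return A `cav_metrics` object: `per_class` tibble, `confusion` matrix,
#'   `overall` list (micro accuracy %, macro F1 %), `excluded` classes.
#' @export
per_class_metrics <- function(truth, pred, level = "chunk", stage = "voted") {
  if (length(truth) != length(pred)) abort("label vectors differ in length")
  classes <- sort(union(unique(truth), unique(pred)))
  cm <- table(factor(truth, classes), factor(pred, classes))
  support <- rowSums(cm)
  excluded <- classes[support == 0]
  keep <- classes[support > 0]
  total <- sum(cm)
  rows <- lapply(keep, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    tn <- total - tp - fp - fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- tp / (tp + fn)
    f1 <- if (!is.na(prec) && prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    tibble(
      class = cl, support = tp + fn,
      accuracy = 100 * (tp + tn) / total,
      precision = 100 * prec, recall = 100 * rec, f1 = 100 * f1
    )
  })
  structure(
    list(
      per_class = bind_rows(rows),
      confusion = unclass(cm),
      overall = list(
        accuracy = 100 * sum(diag(cm)) / total,
        macro_f1 = mean(bind_rows(rows)$f1, na.rm = TRUE)
      ),
      excluded = excluded, level = level, stage = stage
    ),
    class = "cav_metrics"
  )
}

#' @export
print.cav_metrics <- function(x, ...) {
  cat("<cav_metrics> ", x$level, "/", x$stage, ": micro accuracy ",
      sprintf("%.1f%%", x$overall$accuracy), ", macro F1 ",
      sprintf("%.1f%%", x$overall$macro_f1), "\n", sep = "")
  if (length(x$excluded) > 0) {
    cat("  excluded (no test support): ", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.cav_metrics <- function(x, ...) x$per_class

#' @export
glance.cav_metrics <- function(x, ...) {
  tibble(level = x$level, stage = x$stage,
         accuracy = x$overall$accuracy, macro_f1 = x$overall$macro_f1,
         n_classes = nrow(x$per_class), n_excluded = length(x$excluded))
}

# rank-based one-vs-rest AUROC (equals the trapezoidal area with tie
# handling via midranks)
binary_auroc <- function(pos, score) {
  n1 <- as.numeric(sum(pos)); n0 <- as.numeric(sum(!pos))
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# average precision (step interpolation of the PR curve)
binary_auprc <- function(pos, score) {
  n1 <- sum(pos)
  if (n1 == 0 || all(pos)) return(NA_real_)
  ord <- order(-score, pos)  # ties: negatives first (conservative)
  pos <- pos[ord]
  tp <- cumsum(pos)
  prec <- tp / seq_along(pos)
  rec <- tp / n1
  dr <- diff(c(0, rec))
  sum(prec * dr)
}

#' Multiclass ROC and precision-recall areas
#'
#' One-vs-rest curves per class; micro-averaging pools all (spot, class)
#' decisions, macro-averaging takes the unweighted class mean over classes
#' present in the truth.
#'
#' @param truth character vector of true labels.
#' @param prob matrix of class probabilities (columns named by class, rows
#'   summing to 1).
#' @return list: `auroc_micro`, `auroc_macro`, `auprc_micro`,
#'   `auprc_macro`, `per_class` tibble.
#' @export
roc_pr <- function(truth, prob) {
  if (is.null(colnames(prob))) abort("probability matrix must have class columns")
  if (length(unique(truth)) < 2) abort("degenerate single-class input")
  if (any(abs(rowSums(prob) - 1) > 1e-6)) {
    warn("probability rows do not sum to 1")
  }
  classes <- colnames(prob)
  present <- intersect(classes, unique(truth))
  rows <- lapply(present, function(cl) {
    pos <- truth == cl
    tibble(class = cl,
           auroc = binary_auroc(pos, prob[, cl]),
           auprc = binary_auprc(pos, prob[, cl]))
  })
  per_class <- bind_rows(rows)
  pooled_pos <- as.vector(vapply(classes, function(cl) truth == cl,
                                 logical(length(truth))))
  pooled_score <- as.vector(prob)
  list(
    auroc_micro = binary_auroc(pooled_pos, pooled_score),
    auroc_macro = mean(per_class$auroc, na.rm = TRUE),
    auprc_micro = binary_auprc(pooled_pos, pooled_score),
    auprc_macro = mean(per_class$auprc, na.rm = TRUE),
    per_class = per_class
  )
}

#' Groupwise feature statistics per chunk
#'
#' Subject-level feature means per chunk are compared across cohorts:
#' two-sample t statistics for every cohort pair and a one-way ANOVA F
#' across all cohorts. Entries with p > `alpha` are masked (statistic set to
#' NA in `statistic_masked`), mirroring significance-gated reporting.
#'
#' @param table feature table with `subject_id`, `cohort`, `true_chunk` and
#'   feature columns.
#' @param features feature columns to test.
#' @param alpha significance threshold for the mask (default 0.001).
#' @return tibble: `chunk`, `feature`, `contrast`, `statistic`, `p_value`,
#'   `masked`, `statistic_masked`.
#' @export
groupwise_feature_stats <- function(table, features = cav_predictors()[-(1:3)],
                                    alpha = 0.001) {
  cohorts <- unique(table$cohort)
  if (length(cohorts) < 2) abort("need >= 2 cohorts")
  subj <- table %>%
    group_by(.data$subject_id, .data$cohort, .data$true_chunk) %>%
    summarise(across(all_of(features), mean), .groups = "drop")
  counts <- subj %>% count(.data$cohort) %>% pull(n)
  if (any(counts < 2)) abort("each cohort needs >= 2 subjects")
  pairs <- utils::combn(sort(cohorts), 2, simplify = FALSE)
  out <- list()
  for (ck in sort(unique(subj$true_chunk))) {
    sub <- subj[subj$true_chunk == ck, ]
    for (ft in features) {
      for (pr in pairs) {
        a <- sub[[ft]][sub$cohort == pr[1]]
        b <- sub[[ft]][sub$cohort == pr[2]]
        if (length(a) < 2 || length(b) < 2) next
        tt <- tryCatch(t.test(a, b), error = function(e) NULL)
        if (is.null(tt)) next
        out[[length(out) + 1]] <- tibble(
          chunk = ck, feature = ft,
          contrast = paste(pr, collapse = " vs "),
          statistic = unname(tt$statistic), p_value = tt$p.value)
      }
      if (length(cohorts) > 2) {
        sub2 <- sub[, c("cohort", ft)]
        names(sub2) <- c("cohort", "value")
        fit <- tryCatch(aov(value ~ cohort, data = sub2), error = function(e) NULL)
        if (!is.null(fit)) {
          an <- summary(fit)[[1]]
          out[[length(out) + 1]] <- tibble(
            chunk = ck, feature = ft, contrast = "ANOVA",
            statistic = an[["F value"]][1], p_value = an[["Pr(>F)"]][1])
        }
      }
    }
  }
  res <- bind_rows(out)
  res$masked <- res$p_value > alpha
  res$statistic_masked <- ifelse(res$masked, NA_real_, res$statistic)
  res
}

#' Cluster separability of the spot feature space at chunk vs branch level
#'
#' Embeds (a stratified subsample of) the 12-dimensional spot features into
#' two dimensions with a spectral neighbour embedding (Laplacian eigenmap of
#' the kNN graph) and reports the mean silhouette width per labelling level.
#' The anatomy-mirroring expectation is that the 20-chunk colouring
#' separates better than the 62-branch colouring.
#'
#' @param table feature table with `true_chunk` and `true_branch`.
#' @param n_max maximum spots embedded.
#' @param k neighbours for the kNN graph.
#' @param seed subsampling seed.
#' @return tibble: `level`, `silhouette`, `n_classes`, `n_spots`; 2-D
#'   embedding in attribute `embedding`.
#' @export
separability_check <- function(table, n_max = 1500, k = 15, seed = 1L) {
  for (col in c("true_chunk", "true_branch")) {
    if (length(unique(table[[col]])) < 2) {
      abort(paste0("need >= 2 classes at ", col))
    }
  }
  set.seed(seed)
  if (nrow(table) > n_max) {
    idx <- unlist(lapply(split(seq_len(nrow(table)), table$true_chunk),
                         function(ix) {
                           ns <- max(2, round(n_max * length(ix) / nrow(table)))
                           if (length(ix) <= ns) ix else sample(ix, ns)
                         }))
    table <- table[sort(idx), ]
  }
  emb <- spectral_embedding(scale(as.matrix(table[, cav_predictors()])), k = k)
  dmat <- dist(emb)
  out <- lapply(c(chunk = "true_chunk", branch = "true_branch"), function(col) {
    lab <- as.integer(factor(table[[col]]))
    sil <- cluster::silhouette(lab, dmat)
    tibble(silhouette = mean(sil[, "sil_width"]),
           n_classes = length(unique(lab)), n_spots = nrow(table))
  })
  res <- bind_rows(out, .id = "level")
  attr(res, "embedding") <- emb
  attr(res, "labels") <- table[, c("true_chunk", "true_branch")]
  res
}

#' Cluster-aware paired permutation test for an accuracy improvement
#'
#' Tests whether condition B is more accurate than condition A on paired
#' per-spot correctness indicators, permuting by sign-flips at the cluster
#' (segment) level so the within-segment correlation induced by voting does
#' not inflate significance.
#'
#' @param correct_a,correct_b logical vectors (per spot).
#' @param cluster cluster id per spot (segments).
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return list: `delta` (accuracy B - A), `p_value` (one-sided, B > A).
#' @export
paired_permutation_test <- function(correct_a, correct_b, cluster,
                                    n_perm = 5000, seed = 1L) {
  d <- tapply(as.numeric(correct_b) - as.numeric(correct_a), cluster, sum)
  w <- tapply(rep(1, length(cluster)), cluster, sum)
  obs <- sum(d) / sum(w)
  set.seed(seed)
  k <- length(d)
  hits <- 0L
  for (p in seq_len(n_perm)) {
    sgn <- sample(c(-1, 1), k, replace = TRUE)
    if (sum(sgn * d) / sum(w) >= obs - 1e-12) hits <- hits + 1L
  }
  list(delta = obs, p_value = (hits + 1) / (n_perm + 1))
}

# Laplacian eigenmap: symmetric-normalised graph Laplacian of the kNN graph
# (heat-kernel weights), two smallest non-trivial eigenvectors. A minimum
# spanning tree over the distances is merged in so the graph is always
# connected: otherwise well-separated clusters contribute extra null
# eigenvectors and the embedding degenerates.
spectral_embedding <- function(x, k = 15) {
  n <- nrow(x)
  k <- min(k, n - 1)
  dmat <- as.matrix(dist(x))
  sigma <- stats::median(dmat[dmat > 0])
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(dmat[i, ])[2:(k + 1)]
    W[i, nb] <- exp(-(dmat[i, nb] / sigma)^2)
  }
  W <- pmax(W, t(W))   # symmetrise (union kNN)
  g_full <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                                weighted = TRUE)
  mst <- igraph::as_edgelist(igraph::mst(g_full))
  storage.mode(mst) <- "integer"
  wmst <- pmax(exp(-(dmat[mst] / sigma)^2), 1e-4)
  W[mst] <- pmax(W[mst], wmst)
  W[mst[, 2:1]] <- pmax(W[mst[, 2:1]], wmst)
  dg <- pmax(rowSums(W), 1e-12)
  L <- diag(n) - diag(1 / sqrt(dg)) %*% W %*% diag(1 / sqrt(dg))
  ei <- eigen((L + t(L)) / 2, symmetric = TRUE)
  ord <- order(ei$values)
  emb <- ei$vectors[, ord[2:3], drop = FALSE] / sqrt(dg)
  # capped diffusion-map scaling: directions with smaller Laplacian
  # eigenvalues carry the coarser cluster structure and get more weight,
  # but the ratio is bounded so a single near-disconnected blob cannot
  # collapse the rest of the embedding
  lam <- pmax(ei$values[ord[2:3]], 1e-12)
  lam <- pmax(lam, 0.05 * max(lam))
  emb <- sweep(emb, 2, sqrt(lam), `/`)
  colnames(emb) <- c("dim1", "dim2")
  emb
}
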