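#' Subject-level train/test split
#'
#' Partitions subjects (never spots) into train and test sets, stratified by
#' cohort; per cohort `round(train_fraction * n)` subjects train.
#'
#' @param subjects tibble with `subject_id` and optionally `cohort`, or a
#'   character vector of subject ids.
#' @param train_fraction fraction of subjects used for training.
#' @param seed RNG seed.
#' @return tibble: `subject_id`, `cohort`, `split` ("train"/"test").
#' @export
split_subjects <- function(subjects, train_fraction = 0.70, seed = 1L) {
  if (is.character(subjects)) {
    subjects <- tibble(subject_id = subjects, cohort = "all")
  }
  subjects <- distinct(as_tibble(subjects)[, intersect(c("subject_id", "cohort"),
                                                       names(subjects))])
  if (!"cohort" %in% names(subjects)) subjects$cohort <- "all"
  if (nrow(subjects) < 4) abort("too few subjects to split (need >= 4)")
  set.seed(seed)
  subjects %>%
    group_by(.data$cohort) %>%
    mutate(split = {
      n <- n()
      ntr <- round(train_fraction * n)
      s <- rep("test", n)
      s[sample.int(n, ntr)] <- "train"
      s
    }) %>%
    ungroup()
}

fit_scaler <- function(x) {
  list(center = colMeans(x), scale = pmax(apply(x, 2, sd), 1e-8))
}

apply_scaler <- function(x, scaler) {
  scale(x, center = scaler$center, scale = scaler$scale)
}

fit_mlp <- function(x, y, config, seed_offset = 0, bag = NULL) {
  y <- factor(y)
  classes <- levels(y)
  if (length(classes) < 2) {
    return(list(kind = "constant", class = classes, classes = classes))
  }
  freq <- table(y)
  w <- as.numeric(1 / freq[y])
  w <- w * length(y) / sum(w)
  if (is.null(bag)) bag <- config$mlp_bag %||% 1
  models <- vector("list", bag)
  for (b in seq_len(bag)) {
    set.seed(config$seed + 101 * seed_offset + 7919 * (b - 1))
    if (bag > 1) {
      # true bagging: each replicate sees its own random subsample of the
      # full training pool, which adds diversity and bounds the cost
      rows <- sample.int(nrow(x), min(ceiling(nrow(x) / 2), 30000))
    } else {
      rows <- seq_len(nrow(x))
    }
    models[[b]] <- nnet::nnet(
      x = x[rows, , drop = FALSE],
      y = nnet::class.ind(y[rows])[, classes, drop = FALSE],
      weights = w[rows],
      size = config$mlp_hidden, decay = config$mlp_decay,
      maxit = config$mlp_maxit, softmax = TRUE,
      MaxNWts = 100000, trace = FALSE
    )
  }
  list(kind = "mlp", models = models, classes = classes)
}

predict_mlp <- function(fit, x) {
  if (fit$kind == "constant") {
    p <- matrix(1, nrow(x), 1, dimnames = list(NULL, fit$class))
    return(p)
  }
  p <- 0
  for (m in fit$models) p <- p + predict(m, x, type = "raw")
  p <- p / length(fit$models)
  colnames(p) <- fit$classes
  p
}

#' Train the step-1 spot-to-chunk model
#'
#' Standardises the 12 predictors on training subjects only, then fits a
#' multilayer perceptron (single hidden layer, softmax output,
#' inverse-frequency class weights) mapping each spot to one of the 20
#' chunks. Chunk classes absent from the training subjects are dropped with
#' a warning.
#'
#' @param table feature table ([assemble_feature_table()]) with
#'   `subject_id` and `true_chunk`.
#' @param split subject split from [split_subjects()].
#' @param config a [cav_config()].
#' @param map a [nomenclature()].
#' @return A `cav_ensemble` (step-1 part fitted; see
#'   [train_branch_models()] for step 2).
#' @export
train_chunk_model <- function(table, split, config = cav_config(),
                              map = nomenclature()) {
  check_predictors(table)
  train_ids <- split$subject_id[split$split == "train"]
  tr <- table[table$subject_id %in% train_ids, ]
  if (nrow(tr) == 0) abort("no training spots")
  if (nrow(tr) > config$max_train_spots) {
    set.seed(config$seed + 7)
    tr <- tr[sample.int(nrow(tr), config$max_train_spots), ]
  }
  missing_chunks <- setdiff(map$chunks$code, unique(tr$true_chunk))
  if (length(missing_chunks) > 0) {
    warn(paste0("chunk class(es) absent from training data, dropped: ",
                paste(missing_chunks, collapse = ", ")))
  }
  x <- as.matrix(tr[, cav_predictors()])
  scaler <- fit_scaler(x)
  fit <- fit_mlp(apply_scaler(x, scaler), tr$true_chunk, config)
  structure(
    list(chunk_model = fit, scaler = scaler, split = split, config = config,
         nomenclature = map, branch_models = NULL, branch_priors = NULL),
    class = "cav_ensemble"
  )
}

check_predictors <- function(table) {
  miss <- setdiff(cav_predictors(), names(table))
  if (length(miss) > 0) {
    abort(paste0("feature table missing predictor column(s): ",
                 paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Predict chunk membership per spot
#'
#' @param ensemble a trained `cav_ensemble`.
#' @param table feature table with the 12 predictor columns.
#' @return tibble: `spot_row` (row in `table`), `pred_chunk`, `prob` (max
#'   posterior); full probability matrix in attribute `prob_matrix`.
#' @export
predict_chunk <- function(ensemble, table) {
  check_predictors(table)
  x <- as.matrix(table[, cav_predictors()])
  if (anyNA(x) || any(!is.finite(x))) abort("non-finite predictor values")
  p <- predict_mlp(ensemble$chunk_model, apply_scaler(x, ensemble$scaler))
  lab <- colnames(p)[max.col(p, ties.method = "first")]
  out <- tibble(spot_row = seq_len(nrow(table)), pred_chunk = lab,
                prob = p[cbind(seq_len(nrow(p)), max.col(p, ties.method = "first"))])
  attr(out, "prob_matrix") <- p
  out
}

#' Segment-wise majority voting
#'
#' Every spot in a segment adopts the segment's modal label; ties are broken
#' by the larger summed predicted probability, then lexicographically.
#'
#' @param data tibble with one row per spot.
#' @param label_col,segment_col,prob_col column names (strings); `prob_col`
#'   may be `NULL`.
#' @param out_col name of the voted label column added.
#' @return `data` with `out_col` appended.
#' @export
vote_labels <- function(data, label_col, segment_col = "segment_id",
                        prob_col = NULL, out_col = "voted") {
  if (anyNA(data[[segment_col]])) abort("spots with missing segment")
  probs <- if (is.null(prob_col)) rep(1, nrow(data)) else data[[prob_col]]
  key <- tibble(seg = data[[segment_col]], lab = data[[label_col]], p = probs) %>%
    group_by(.data$seg, .data$lab) %>%
    summarise(n = n(), psum = sum(.data$p), .groups = "drop") %>%
    group_by(.data$seg) %>%
    arrange(desc(.data$n), desc(.data$psum), .data$lab, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
  data[[out_col]] <- key$lab[match(data[[segment_col]], key$seg)]
  data
}

#' Train step-2 spot-to-branch models
#'
#' For every chunk owning two or more branches, fits an MLP over the same 12
#' predictors restricted to training spots of that chunk; single-branch
#' chunks are assigned deterministically. Chunks without usable training
#' spots are skipped (logged) and fall back to their most frequent training
#' branch at prediction time.
#'
#' @param ensemble a `cav_ensemble` from [train_chunk_model()].
#' @param table the same feature table (needs `true_chunk`, `true_branch`).
#' @return the `cav_ensemble` with `branch_models` and `branch_priors`
#'   fitted.
#' @export
train_branch_models <- function(ensemble, table) {
  map <- ensemble$nomenclature
  config <- ensemble$config
  train_ids <- ensemble$split$subject_id[ensemble$split$split == "train"]
  tr <- table[table$subject_id %in% train_ids, ]
  models <- list()
  priors <- list()
  for (ck in map$chunks$code) {
    branches <- map$branches$code[map$branches$chunk == ck]
    sub <- tr[tr$true_chunk == ck, ]
    priors[[ck]] <- if (nrow(sub) > 0) {
      names(sort(table(sub$true_branch), decreasing = TRUE))[1]
    } else branches[1]
    if (length(branches) < 2) next
    if (nrow(sub) < 20 || length(unique(sub$true_branch)) < 2) {
      inform(paste0("step-2 model skipped for chunk ", ck,
                    " (insufficient training spots)"))
      next
    }
    # per-chunk problems are small; cap their size and iterations
    cap <- min(config$max_train_spots, 15000)
    if (nrow(sub) > cap) {
      set.seed(config$seed + 13)
      sub <- sub[sample.int(nrow(sub), cap), ]
    }
    cfg_b <- config
    cfg_b$mlp_maxit <- min(config$mlp_maxit, 200)
    x <- apply_scaler(as.matrix(sub[, cav_predictors()]), ensemble$scaler)
    models[[ck]] <- fit_mlp(x, sub$true_branch, cfg_b,
                            seed_offset = match(ck, map$chunks$code),
                            bag = 1)
  }
  ensemble$branch_models <- models
  ensemble$branch_priors <- priors
  ensemble
}

#' Predict branch labels given chunk assignments
#'
#' Spots are routed to their assigned chunk's branch model (or assigned
#' directly for single-branch chunks); emitted branch codes always belong to
#' the assigned chunk.
#'
#' @param ensemble a `cav_ensemble` with branch models.
#' @param table feature table.
#' @param chunk_assignments character vector (one chunk code per row of
#'   `table`).
#' @return tibble: `spot_row`, `pred_branch`, `prob`.
#' @export
predict_branch <- function(ensemble, table, chunk_assignments) {
  check_predictors(table)
  map <- ensemble$nomenclature
  x <- apply_scaler(as.matrix(table[, cav_predictors()]), ensemble$scaler)
  pred <- rep(NA_character_, nrow(table))
  prob <- rep(1, nrow(table))
  for (ck in unique(chunk_assignments)) {
    rows <- which(chunk_assignments == ck)
    branches <- map$branches$code[map$branches$chunk == ck]
    if (length(branches) == 1) {
      pred[rows] <- branches
    } else if (!is.null(ensemble$branch_models[[ck]])) {
      p <- predict_mlp(ensemble$branch_models[[ck]], x[rows, , drop = FALSE])
      pick <- max.col(p, ties.method = "first")
      pred[rows] <- colnames(p)[pick]
      prob[rows] <- p[cbind(seq_along(rows), pick)]
    } else {
      pred[rows] <- ensemble$branch_priors[[ck]] %||% branches[1]
    }
  }
  tibble(spot_row = seq_len(nrow(table)), pred_branch = pred, prob = prob)
}

#' Fit the full two-step labelling ensemble
#'
#' Convenience wrapper: step-1 chunk model plus step-2 branch models.
#'
#' @inheritParams train_chunk_model
#' @return a fitted `cav_ensemble`.
#' @export
fit_labeller <- function(table, split, config = cav_config(),
                         map = nomenclature()) {
  ensemble <- train_chunk_model(table, split, config, map)
  train_branch_models(ensemble, table)
}

#' Label spots with the trained ensemble
#'
#' Runs step 1 (chunk prediction), segment-wise chunk voting, step 2 (branch
#' prediction within the voted chunk), branch voting, and anatomical
#' post-processing, as enabled in the configuration.
#'
#' @param ensemble a fitted `cav_ensemble`.
#' @param table feature table with `segment_id` (and positions for the
#'   laterality rule).
#' @return `table` with columns `pred_chunk_raw`, `pred_chunk`,
#'   `pred_branch_raw`, `pred_branch` appended.
#' @export
label_spots <- function(ensemble, table) {
  config <- ensemble$config
  p1 <- predict_chunk(ensemble, table)
  table$pred_chunk_raw <- p1$pred_chunk
  table$.chunk_prob <- p1$prob
  # voting and anatomical rules are within-subject operations
  groups <- if ("subject_id" %in% names(table)) {
    split(seq_len(nrow(table)), table$subject_id)
  } else list(seq_len(nrow(table)))
  parts <- lapply(groups, function(rows) {
    sub <- table[rows, ]
    if (isTRUE(config$vote_chunk)) {
      sub <- vote_labels(sub, "pred_chunk_raw", "segment_id",
                         prob_col = ".chunk_prob", out_col = "pred_chunk_voted")
    } else {
      sub$pred_chunk_voted <- sub$pred_chunk_raw
    }
    sub$pred_chunk <- sub$pred_chunk_voted
    if (isTRUE(config$postprocess)) {
      sub <- anatomical_postprocess(sub, ensemble)
    }
    p2 <- predict_branch(ensemble, sub, sub$pred_chunk)
    sub$pred_branch_raw <- p2$pred_branch
    sub$.branch_prob <- p2$prob
    if (isTRUE(config$vote_branch)) {
      sub <- vote_labels(sub, "pred_branch_raw", "segment_id",
                         prob_col = ".branch_prob", out_col = "pred_branch")
    } else {
      sub$pred_branch <- sub$pred_branch_raw
    }
    sub
  })
  out <- bind_rows(parts)[order(unlist(groups)), ]   # restore input order
  out$.chunk_prob <- NULL
  out$.branch_prob <- NULL
  out
}

#' @export
print.cav_ensemble <- function(x, ...) {
  cat("<cav_ensemble> step-1 chunk model (",
      length(x$chunk_model$classes), " classes), ",
      length(x$branch_models), " step-2 branch models\n", sep = "")
  invisible(x)
}

#' @export
tidy.cav_ensemble <- function(x, ...) {
  map <- x$nomenclature
  rows <- lapply(map$chunks$code, function(ck) {
    tibble(
      chunk = ck,
      n_branches = sum(map$branches$chunk == ck),
      has_branch_model = !is.null(x$branch_models[[ck]])
    )
  })
  bind_rows(rows)
}

#' @export
glance.cav_ensemble <- function(x, ...) {
  tibble(
    n_chunk_classes = length(x$chunk_model$classes),
    n_branch_models = length(x$branch_models),
    n_train_subjects = sum(x$split$split == "train"),
    n_test_subjects = sum(x$split$split == "test"),
    hidden_units = x$config$mlp_hidden,
    seed = x$config$seed
  )
}
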