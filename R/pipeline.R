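#' Pipeline configuration
#'
#' Bundles every tunable of the simulation-to-evaluation pipeline. Defaults
#' reproduce the package's documented validation suite: 0.2801 mm spot
#' interval on the centerline, 2 mm skeleton pruning, a 70/30 subject-level
#' split, and cohort-scale voxelization at 0.5 mm isotropic (single-phantom
#' geometry checks use finer grids directly).
#'
#' @param spacing_mm voxel spacing for cohort simulation (mm, isotropic).
#' @param spot_interval_mm centerline spot sampling interval (mm).
#' @param prune_mm skeleton pruning threshold (mm).
#' @param smooth_window centerline smoothing window (points).
#' @param train_fraction subject-level training fraction.
#' @param seed root RNG seed; every stage derives its stream from it.
#' @param n_control,n_icas cohort sizes for [run_experiment()].
#' @param mlp_hidden,mlp_decay,mlp_maxit MLP hyperparameters.
#' @param mlp_bag bagged replicates of the step-1 chunk MLP whose softmax
#'   outputs are averaged (1 = single model).
#' @param max_train_spots training subsample cap.
#' @param vote_chunk,vote_branch,postprocess stage toggles.
#' @param rule_connectivity,rule_laterality,rule_side_propagation
#'   post-processing rule toggles.
#' @param circularity `"isoperimetric"` (4*pi*A/P^2) or `"hydraulic"` (4A/P).
#' @param distortion_window_mm,curvature_window_mm feature windows (mm).
#' @param section_pitch_factor plane pitch as fraction of voxel spacing.
#' @param n_angles caliper directions per half-turn.
#' @return a `cav_config` list.
#' @export
cav_config <- function(spacing_mm = 0.5, spot_interval_mm = 0.2801,
                       prune_mm = 2, smooth_window = 5,
                       train_fraction = 0.70, seed = 1L,
                       n_control = 30, n_icas = 10,
                       mlp_hidden = 48, mlp_decay = 5e-4, mlp_maxit = 350,
                       mlp_bag = 3, max_train_spots = 100000,
                       vote_chunk = TRUE, vote_branch = TRUE,
                       postprocess = TRUE,
                       rule_connectivity = TRUE, rule_laterality = TRUE,
                       rule_side_propagation = FALSE,
                       circularity = "isoperimetric",
                       distortion_window_mm = 5, curvature_window_mm = 2.5,
                       section_pitch_factor = 0.5, n_angles = 180) {
  structure(as.list(environment()), class = "cav_config")
}

# deterministic per-stage substream seeds, kept inside 32-bit range
derive_seed <- function(seed, stage, i = 0L) {
  base <- sum(utf8ToInt(stage)) * 2654435L
  as.integer((as.double(seed) * 1000003 + base + i * 7919) %% 2147483647)
}

#' Simulate one subject (tree, centerlines, volumes)
#'
#' @param cohort cohort tag.
#' @param seed subject seed.
#' @param config a [cav_config()].
#' @param template branch template.
#' @param subject_id optional id.
#' @return list: `tree`, `centerlines` (ground truth), `volume`, `labels`.
#' @export
simulate_subject <- function(cohort = "control", seed = 1L,
                             config = cav_config(), template = cow_template(),
                             subject_id = NULL) {
  tree <- sample_tree(template, cohort, seed, subject_id = subject_id)
  cl <- realize_centerlines(tree)
  vx <- voxelize(cl, spacing_mm = config$spacing_mm)
  list(tree = tree, centerlines = cl, volume = vx$volume, labels = vx$labels)
}

#' Run the geometry/feature half of the pipeline on one subject
#'
#' Binary volume to labelled feature table: isovoxel check, skeletonisation,
#' pruning, tree construction, centerline extraction, spot sampling at the
#' configured interval, nine-feature computation, segmentation between
#' bifurcations, and gold-label transfer from the paired label volume.
#'
#' @param sim output of [simulate_subject()], or a list with `volume` and
#'   (optionally) `labels`.
#' @param config a [cav_config()].
#' @param map a [nomenclature()].
#' @return labelled feature table (one row per retained spot).
#' @export
subject_feature_table <- function(sim, config = cav_config(),
                                  map = nomenclature()) {
  vol <- resample_isovoxel(sim$volume)
  sk <- skeletonize(vol)
  sk <- prune_skeleton(sk, config$prune_mm)
  tr <- build_tree(sk)
  cl <- extract_centerlines(tr, vol, smooth_window = config$smooth_window)
  spots <- sample_spots(cl, config$spot_interval_mm)
  spots <- spot_features(vol, cl, spots, config)
  seg <- segment_spots(cl, spots)
  spots <- seg$spots
  if (!is.null(sim$labels)) {
    spots <- label_spots_from_volume(spots, sim$labels, map)
  }
  tab <- assemble_feature_table(spots, frame = foreground_frame(vol))
  if (!is.null(sim$tree)) {
    tab$subject_id <- attr(sim$tree, "subject_id")
    tab$cohort <- attr(sim$tree, "cohort")
    # segment ids must be unique across subjects (voting groups by them)
    tab$segment_id <- paste0(tab$subject_id, "#", tab$segment_id)
  }
  tab
}

#' Simulate a cohort feature table
#'
#' @param n subjects.
#' @param cohort cohort tag.
#' @param config a [cav_config()].
#' @param map a [nomenclature()].
#' @param progress print per-subject progress.
#' @return feature table for all subjects (bind of per-subject tables).
#' @export
simulate_cohort_table <- function(n, cohort = "control",
                                  config = cav_config(),
                                  map = nomenclature(), progress = FALSE) {
  template <- cow_template()
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sprintf("%s_%03d", cohort, i)
    sim <- simulate_subject(cohort, derive_seed(config$seed, cohort, i),
                            config, template, subject_id = sid)
    out[[i]] <- suppressMessages(subject_feature_table(sim, config, map))
    if (progress) inform(paste0(sid, ": ", nrow(out[[i]]), " spots"))
  }
  bind_rows(out)
}

#' Run a full end-to-end experiment
#'
#' Simulate control (and optionally ICAS) cohorts, split subjects 70/30,
#' train the two-step ensemble on training subjects, label the held-out
#' subjects, and evaluate chunk/branch metrics at the raw and voted stages.
#' All artefacts (tables, metrics, resolved configuration) are written under
#' `out_dir` as CSV/JSON; per-subject tables are cached and reused when
#' re-run with the same directory.
#'
#' @param config a [cav_config()].
#' @param out_dir output directory (created); `NULL` for no artefacts.
#' @return list: `metrics` (tibble over level/stage), `tables`, `ensemble`,
#'   `split`.
#' @export
run_experiment <- function(config = cav_config(), out_dir = NULL) {
  map <- nomenclature()
  cache <- function(name, fn) {
    if (is.null(out_dir)) return(fn())
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f <- file.path(out_dir, paste0(name, ".csv"))
    if (file.exists(f)) {
      return(as_tibble(read.csv(f, stringsAsFactors = FALSE)))
    }
    x <- fn()
    write.csv(x, f, row.names = FALSE)
    x
  }
  control <- cache("spots_control", function()
    simulate_cohort_table(config$n_control, "control", config, map))
  icas <- if (config$n_icas > 0) {
    cache("spots_icas", function()
      simulate_cohort_table(config$n_icas, "icas", config, map))
  } else NULL

  split <- split_subjects(distinct(control[, c("subject_id", "cohort")]),
                          config$train_fraction,
                          derive_seed(config$seed, "split"))
  ensemble <- fit_labeller(control, split, config, map)
  test_tab <- control[control$subject_id %in%
                        split$subject_id[split$split == "test"], ]
  labelled <- label_spots(ensemble, test_tab)

  metrics <- bind_rows(
    glance(per_class_metrics(labelled$true_chunk, labelled$pred_chunk_raw,
                             "chunk", "raw")),
    glance(per_class_metrics(labelled$true_chunk, labelled$pred_chunk_voted,
                             "chunk", "voted")),
    glance(per_class_metrics(labelled$true_chunk, labelled$pred_chunk,
                             "chunk", "postprocessed")),
    glance(per_class_metrics(labelled$true_branch, labelled$pred_branch_raw,
                             "branch", "raw")),
    glance(per_class_metrics(labelled$true_branch, labelled$pred_branch,
                             "branch", "voted"))
  )
  icas_labelled <- NULL
  if (!is.null(icas)) {
    icas_labelled <- label_spots(ensemble, icas)
    metrics <- bind_rows(metrics,
      glance(per_class_metrics(icas_labelled$true_chunk,
                               icas_labelled$pred_chunk, "chunk", "voted")) %>%
        mutate(level = "chunk_icas"))
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(config = unclass(config), metrics = metrics,
           config_hash = config_hash(config)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    write.csv(labelled, file.path(out_dir, "labelled_test.csv"),
              row.names = FALSE)
  }
  list(metrics = metrics, ensemble = ensemble, split = split,
       tables = list(control = control, icas = icas),
       labelled = labelled, icas_labelled = icas_labelled)
}

# stable small hash of the resolved configuration (polynomial over its JSON)
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE)
  h <- 5381
  for (ch in utf8ToInt(as.character(s))) {
    h <- (h * 33 + ch) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
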