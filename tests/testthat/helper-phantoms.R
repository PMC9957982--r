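# shared fixtures, built once per test run and memoised
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

cylinder_fixture <- function() {
  fixture("cylinder", function() {
    vol <- phantom_cylinder(radius_mm = 2, length_mm = 40, spacing = 0.28)
    tree <- build_tree(prune_skeleton(skeletonize(vol), 2))
    cl <- extract_centerlines(tree, vol)
    list(vol = vol, tree = tree, cl = cl)
  })
}

y_fixture <- function() {
  fixture("y", function() {
    vol <- phantom_y()
    sk <- prune_skeleton(skeletonize(vol), 2)
    tree <- build_tree(sk)
    list(vol = vol, sk = sk, tree = tree,
         cl = extract_centerlines(tree, vol))
  })
}

# a small control subject processed through the full raster pipeline
subject_fixture <- function() {
  fixture("subject", function() {
    cfg <- cav_config(seed = 11)
    sim <- simulate_subject("control", seed = 11, config = cfg)
    tab <- suppressMessages(subject_feature_table(sim, cfg))
    list(sim = sim, tab = tab, cfg = cfg)
  })
}

# straight-tube polyline for spot sampling tests
straight_polyline <- function(length_mm, step = 0.05) {
  z <- seq(0, length_mm, by = step)
  if (z[length(z)] < length_mm) z <- c(z, length_mm)
  tibble::tibble(polyline_id = 1L, x = 0, y = 0, z = z, radius = 1.5)
}

# two well-separated Gaussian classes in the 12-predictor space
separable_table <- function(n_per = 1000, classes = c("A1", "A2"),
                            shift = 6, seed = 42) {
  set.seed(seed)
  preds <- cav_predictors()
  out <- lapply(seq_along(classes), function(i) {
    m <- matrix(rnorm(n_per * 12), n_per, 12)
    m[, 1] <- m[, 1] + shift * (i - 1)
    df <- tibble::as_tibble(as.data.frame(m))
    names(df) <- preds
    df$true_chunk <- classes[i]
    df$true_branch <- paste0(classes[i], ".0", (seq_len(n_per) %% 2) + 1)
    df
  })
  tab <- dplyr::bind_rows(out)
  tab$spot_id <- seq_len(nrow(tab))
  tab$segment_id <- paste0("s", ceiling(tab$spot_id / 10))
  tab$subject_id <- paste0("subj", (tab$spot_id %% 10) + 1)
  tab$pos_x <- tab$x; tab$pos_y <- tab$y; tab$pos_z <- tab$z
  tab$s <- 1
  tab
}
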