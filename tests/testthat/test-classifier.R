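test_that("subject splits are stratified, sized and reproducible", {
  subj <- tibble::tibble(subject_id = sprintf("s%02d", 1:42), cohort = "control")
  sp <- split_subjects(subj, 0.70, seed = 3)
  expect_equal(sum(sp$split == "train"), 29)  # round(0.7 * 42)
  expect_equal(sum(sp$split == "test"), 13)
  sp2 <- split_subjects(subj, 0.70, seed = 3)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_subjects(subj, 0.70, seed = 4)))
  # stratification by cohort
  subj2 <- tibble::tibble(subject_id = sprintf("s%02d", 1:20),
                          cohort = rep(c("control", "icas"), each = 10))
  sp3 <- split_subjects(subj2, 0.70, seed = 1)
  per <- table(sp3$cohort, sp3$split)
  expect_true(all(per[, "train"] == 7))
  expect_error(split_subjects(subj[1:2, ]), "too few")
})

test_that("the chunk MLP separates a Bayes-separable two-class toy", {
  tab <- separable_table(n_per = 1000)
  split <- split_subjects(dplyr::distinct(tab[, "subject_id"]), 0.7, seed = 1)
  cfg <- cav_config(mlp_hidden = 8, mlp_maxit = 200, seed = 1)
  ens <- suppressWarnings(train_chunk_model(tab, split, config = cfg,
                                            map = nomenclature()))
  test_rows <- tab$subject_id %in% split$subject_id[split$split == "test"]
  pr <- predict_chunk(ens, tab[test_rows, ])
  expect_gte(mean(pr$pred_chunk == tab$true_chunk[test_rows]), 0.99)
  # softmax contract: probability rows sum to 1
  pm <- attr(pr, "prob_matrix")
  expect_true(all(abs(rowSums(pm) - 1) < 1e-6))
  # statelessness: permuted rows give the same per-spot labels
  idx <- sample(which(test_rows))
  pr2 <- predict_chunk(ens, tab[idx, ])
  expect_identical(pr2$pred_chunk, pr$pred_chunk[match(idx, which(test_rows))])
  # NaN features error
  bad <- tab[test_rows, ]; bad$x[1] <- NA
  expect_error(predict_chunk(ens, bad), "finite")
})

test_that("shuffled labels give chance-level accuracy", {
  tab <- separable_table(n_per = 600)
  set.seed(9)
  tab$true_chunk <- sample(tab$true_chunk)
  split <- split_subjects(dplyr::distinct(tab[, "subject_id"]), 0.7, seed = 1)
  ens <- suppressWarnings(train_chunk_model(
    tab, split,
    config = cav_config(mlp_hidden = 8, mlp_maxit = 120, seed = 2),
    map = nomenclature()))
  test_rows <- tab$subject_id %in% split$subject_id[split$split == "test"]
  pr <- predict_chunk(ens, tab[test_rows, ])
  acc <- mean(pr$pred_chunk == tab$true_chunk[test_rows])
  n <- sum(test_rows)
  # within 3 SD of 1/2 for 2 balanced classes
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / n) + 0.02)
})

test_that("segment voting equals the exact binomial tail under iid errors", {
  # 10,000 segments of 15 spots, iid accuracy 0.7, binary confusion
  set.seed(123)
  n_seg <- 10000; m <- 15; p <- 0.7
  correct <- matrix(runif(n_seg * m) < p, n_seg, m)
  df <- tibble::tibble(
    segment_id = rep(seq_len(n_seg), each = m),
    label = ifelse(as.vector(t(correct)), "T", "F")
  )
  voted <- vote_labels(df, "label", "segment_id", out_col = "voted")
  seg_ok <- tapply(voted$voted == "T", voted$segment_id, all)
  oracle <- sum(choose(m, 8:m) * p^(8:m) * (1 - p)^(m - (8:m)))
  expect_equal(oracle, 0.9500, tolerance = 1e-4)
  expect_lt(abs(mean(seg_ok) - oracle), 0.01)
})

test_that("voting tie-breaks use summed probability then lexicographic code", {
  df <- tibble::tibble(segment_id = 1, label = c("A7", "A7", "A3"),
                       prob = c(0.5, 0.5, 0.9))
  v <- vote_labels(df, "label", "segment_id", prob_col = "prob")
  expect_equal(unique(v$voted), "A7")          # plain majority
  df2 <- tibble::tibble(segment_id = 1, label = c("A7", "A3"),
                        prob = c(0.6, 0.8))
  v2 <- vote_labels(df2, "label", "segment_id", prob_col = "prob")
  expect_equal(unique(v2$voted), "A3")         # tie -> higher probability
  df3 <- tibble::tibble(segment_id = 1, label = c("A7", "A3"),
                        prob = c(0.7, 0.7))
  v3 <- vote_labels(df3, "label", "segment_id", prob_col = "prob")
  expect_equal(unique(v3$voted), "A3")         # full tie -> lexicographic
})

test_that("voting never hurts segments when per-spot accuracy exceeds one half", {
  set.seed(5)
  for (p in c(0.6, 0.75, 0.9)) {
    n_seg <- 2000; m <- 9
    correct <- matrix(runif(n_seg * m) < p, n_seg, m)
    df <- tibble::tibble(segment_id = rep(seq_len(n_seg), each = m),
                         label = ifelse(as.vector(t(correct)), "T", "F"))
    voted <- vote_labels(df, "label", "segment_id")
    expect_gte(mean(voted$voted == "T"), mean(df$label == "T"))
  }
})

test_that("branch models respect the chunk restriction contract", {
  tab <- separable_table(n_per = 800)
  # give the branches structure inside each chunk so step 2 can learn
  tab$y <- tab$y + ifelse(parse_branch_code(tab$true_branch)$segment_index == 1,
                          3, -3)
  split <- split_subjects(dplyr::distinct(tab[, "subject_id"]), 0.7, seed = 1)
  cfg <- cav_config(mlp_hidden = 8, mlp_maxit = 200, seed = 1,
                    postprocess = FALSE)
  ens <- suppressWarnings(fit_labeller(tab, split, config = cfg,
                                       map = nomenclature()))
  test_tab <- tab[tab$subject_id %in% split$subject_id[split$split == "test"], ]
  out <- label_spots(ens, test_tab)
  nm <- nomenclature()
  expect_identical(chunk_of(out$pred_branch, nm), out$pred_chunk)
  expect_identical(chunk_of(out$pred_branch_raw, nm), out$pred_chunk)
  expect_gte(mean(out$pred_branch == test_tab$true_branch), 0.95)
  # single-branch chunks are assigned deterministically with probability 1
  pb <- predict_branch(ens, test_tab, rep("P0", nrow(test_tab)))
  expect_true(all(pb$pred_branch == "P0"))
  expect_true(all(pb$prob == 1))
})

test_that("anatomical post-processing fixes planted islands and is idempotent", {
  fx <- subject_fixture()
  cfg <- fx$cfg
  tab <- fx$tab
  ens <- structure(list(nomenclature = nomenclature(), config = cfg),
                   class = "cav_ensemble")
  # anatomically consistent toy: an M1 trunk feeding two pial branches
  toy <- tibble::tibble(
    segment_id = rep(c("s1", "s2", "s3"), each = 4),
    pred_chunk = rep(c("A3", "A7", "A7"), each = 4),
    pos_x = rep(c(-15, -20, -22), each = 4) + runif(12, -0.5, 0.5),
    pos_y = rnorm(12), pos_z = rnorm(12),
    s = rep(1:4, 3),
    start_node = rep(c(1L, 2L, 2L), each = 4),
    end_node = rep(c(2L, 3L, 4L), each = 4)
  )
  out_toy <- anatomical_postprocess(toy, ens)
  expect_identical(out_toy$pred_chunk, toy$pred_chunk)
  # segment-constant labels on the real subject
  modal <- tab %>%
    dplyr::group_by(.data$segment_id) %>%
    dplyr::summarise(lab = names(sort(table(.data$true_chunk),
                                      decreasing = TRUE))[1])
  tab$pred_chunk <- modal$lab[match(tab$segment_id, modal$segment_id)]
  # plant one mislabelled segment deep inside the A7 subtree: choose a
  # segment whose tree neighbours (shared junction nodes) are all A7
  segnodes <- tab %>%
    dplyr::group_by(.data$segment_id) %>%
    dplyr::summarise(chunk = dplyr::first(.data$true_chunk),
                     n1 = dplyr::first(.data$start_node),
                     n2 = dplyr::first(.data$end_node), .groups = "drop")
  victim <- NA
  for (i in seq_len(nrow(segnodes))) {
    if (segnodes$chunk[i] != "A7") next
    nb <- segnodes$segment_id[segnodes$segment_id != segnodes$segment_id[i] &
      (segnodes$n1 %in% c(segnodes$n1[i], segnodes$n2[i]) |
         segnodes$n2 %in% c(segnodes$n1[i], segnodes$n2[i]))]
    if (length(nb) >= 2 &&
        all(segnodes$chunk[segnodes$segment_id %in% nb] == "A7")) {
      victim <- segnodes$segment_id[i]
      break
    }
  }
  expect_false(is.na(victim))
  tab2 <- tab
  tab2$pred_chunk[tab2$segment_id == victim] <- "P6"
  out1 <- suppressMessages(anatomical_postprocess(tab2, ens))
  expect_true(all(out1$pred_chunk[out1$segment_id == victim] == "A7"))
  # idempotence: a second application is a fixed point
  out2 <- suppressMessages(anatomical_postprocess(out1, ens))
  expect_identical(out2$pred_chunk, out1$pred_chunk)
})

test_that("ensemble tidiers summarise models and split", {
  tab <- separable_table(n_per = 300)
  split <- split_subjects(dplyr::distinct(tab[, "subject_id"]), 0.7, seed = 1)
  ens <- suppressWarnings(fit_labeller(
    tab, split, config = cav_config(mlp_hidden = 4, mlp_maxit = 60),
    map = nomenclature()))
  td <- tidy(ens)
  expect_equal(nrow(td), 20)
  gl <- glance(ens)
  expect_equal(gl$n_train_subjects + gl$n_test_subjects, 10)
})
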