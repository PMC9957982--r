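test_that("per-class metrics match hand computation on a 2x2 confusion", {
  # confusion [[8,2],[1,9]]: class-1 precision 8/9, recall 8/10, F1 2pr/(p+r)
  truth <- c(rep("c1", 10), rep("c2", 10))
  pred <- c(rep("c1", 8), rep("c2", 2), "c1", rep("c2", 9))
  m <- per_class_metrics(truth, pred)
  c1 <- m$per_class[m$per_class$class == "c1", ]
  expect_equal(c1$precision, 100 * 8 / 9, tolerance = 1e-9)
  expect_equal(c1$recall, 80, tolerance = 1e-9)
  expect_equal(c1$f1, 100 * 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8), tolerance = 1e-9)
  expect_equal(m$overall$accuracy, 100 * 17 / 20, tolerance = 1e-9)
  # micro accuracy always equals trace / total
  expect_equal(m$overall$accuracy,
               100 * sum(diag(m$confusion)) / sum(m$confusion))
  # perfect predictions: all 100
  p <- per_class_metrics(truth, truth)
  expect_true(all(abs(p$per_class$precision - 100) < 1e-12))
  expect_true(all(abs(p$per_class$recall - 100) < 1e-12))
  expect_true(all(abs(p$per_class$f1 - 100) < 1e-12))
  # class absent from truth is excluded and reported
  m2 <- per_class_metrics(c("a", "a", "b"), c("a", "c", "b"))
  expect_true("c" %in% m2$excluded)
  expect_false("c" %in% m2$per_class$class)
  expect_error(per_class_metrics(c("a"), c("a", "b")), "length")
})

test_that("metrics agree with brute-force loops on random multiclass draws", {
  set.seed(77)
  for (rep in 1:3) {
    k <- sample(3:8, 1)
    n <- 400
    truth <- sample(letters[1:k], n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.6, truth, sample(letters[1:k], n, TRUE))
    m <- per_class_metrics(truth, pred)
    for (cl in unique(truth)) {
      tp <- sum(truth == cl & pred == cl)
      fp <- sum(truth != cl & pred == cl)
      fn <- sum(truth == cl & pred != cl)
      tn <- n - tp - fp - fn
      row <- m$per_class[m$per_class$class == cl, ]
      if (tp + fp > 0) expect_equal(row$precision, 100 * tp / (tp + fp),
                                    tolerance = 1e-9)
      expect_equal(row$recall, 100 * tp / (tp + fn), tolerance = 1e-9)
      expect_equal(row$accuracy, 100 * (tp + tn) / n, tolerance = 1e-9)
    }
  }
})

test_that("AUROC matches brute-force pair counting and pROC", {
  set.seed(42)
  n <- 300
  truth <- sample(c("pos", "neg"), n, replace = TRUE)
  score <- rnorm(n) + (truth == "pos") * 1.2
  prob <- cbind(neg = 1 - stats::plogis(score), pos = stats::plogis(score))
  r <- roc_pr(truth, prob)
  # brute force over all positive/negative pairs
  sp <- score[truth == "pos"]; sn <- score[truth == "neg"]
  brute <- mean(outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b)))
  auc_pos <- r$per_class$auroc[r$per_class$class == "pos"]
  expect_equal(auc_pos, brute, tolerance = 1e-9)
  if (requireNamespace("pROC", quietly = TRUE)) {
    expect_equal(auc_pos,
                 as.numeric(pROC::auc(pROC::roc(truth == "pos", score,
                                                quiet = TRUE))),
                 tolerance = 1e-9)
  }
  # macro equals the unweighted mean of per-class AUROCs
  expect_equal(r$auroc_macro, mean(r$per_class$auroc), tolerance = 1e-12)
})

test_that("AUROC is exactly 1 for separating scores and ~0.5 for random ones", {
  truth <- rep(c("a", "b"), each = 50)
  prob <- cbind(a = c(rep(0.9, 50), rep(0.1, 50)),
                b = c(rep(0.1, 50), rep(0.9, 50)))
  r <- roc_pr(truth, prob)
  expect_equal(r$auroc_macro, 1.0)
  expect_equal(r$auroc_micro, 1.0)
  set.seed(1)
  n <- 10000
  truth2 <- sample(c("a", "b"), n, replace = TRUE)
  p <- runif(n)
  r2 <- roc_pr(truth2, cbind(a = p, b = 1 - p))
  expect_lt(abs(r2$auroc_micro - 0.5), 0.02)
  expect_error(roc_pr(rep("a", 10), cbind(a = rep(1, 10))), "single-class")
})

test_that("groupwise statistics match the closed-form two-sample t", {
  a <- c(5.1, 4.8, 5.3, 5.0, 4.9)
  b <- c(6.0, 6.2, 5.8, 6.1, 6.4)
  tab <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:10),
    cohort = rep(c("control", "icas"), each = 5),
    true_chunk = "A1",
    inscribed_radius = c(a, b)
  )
  res <- groupwise_feature_stats(tab, features = "inscribed_radius")
  tt <- res[res$contrast != "ANOVA", ]
  # textbook Welch t
  tstat <- (mean(a) - mean(b)) / sqrt(var(a) / 5 + var(b) / 5)
  expect_equal(tt$statistic, tstat, tolerance = 1e-9)
  expect_false(tt$masked)   # a ~6 SD shift at n=5 clears p<0.001
  # identical cohorts: everything masked
  tab2 <- tab; tab2$inscribed_radius <- rep(a, 2)
  res2 <- groupwise_feature_stats(tab2, features = "inscribed_radius")
  expect_true(all(res2$masked))
  expect_true(all(is.na(res2$statistic_masked)))
  expect_error(groupwise_feature_stats(tab[1:5, ], "inscribed_radius"),
               "cohorts")
})

test_that("a planted large shift in one chunk's radius is detected and only there", {
  set.seed(31)
  mk <- function(cohort, shift) {
    tibble::tibble(
      subject_id = rep(sprintf("%s%02d", cohort, 1:20), each = 2),
      cohort = cohort,
      true_chunk = rep(c("A1", "A3"), 20),
      inscribed_radius = rnorm(40, 2, 0.2) +
        ifelse(rep(c(TRUE, FALSE), 20), shift, 0)
    )
  }
  tab <- dplyr::bind_rows(mk("control", 0), mk("icas", 3 * 0.2))
  res <- groupwise_feature_stats(tab, features = "inscribed_radius")
  shifted <- res[res$chunk == "A1" & res$contrast != "ANOVA", ]
  null_ck <- res[res$chunk == "A3" & res$contrast != "ANOVA", ]
  expect_false(shifted$masked)   # +3 SD at n=20/20: power ~1 at alpha 0.001
  expect_true(null_ck$masked)
})

test_that("separability silhouettes rank well-separated chunks above branches", {
  set.seed(8)
  # two far-apart chunk clouds, each mixing two overlapping branch clouds
  n <- 300
  mk <- function(center, chunk) {
    m <- matrix(rnorm(n * 12, sd = 0.5), n, 12)
    m[, 1] <- m[, 1] + center
    df <- tibble::as_tibble(as.data.frame(m))
    names(df) <- cav_predictors()
    df$true_chunk <- chunk
    df$true_branch <- paste0(chunk, ".0", (seq_len(n) %% 2) + 1)
    df
  }
  tab <- dplyr::bind_rows(mk(-4, "A1"), mk(4, "A2"))
  sep <- separability_check(tab, n_max = 400, seed = 1)
  sil_chunk <- sep$silhouette[sep$level == "chunk"]
  sil_branch <- sep$silhouette[sep$level == "branch"]
  # the spectral embedding's silhouette is conservative: even perfectly
  # separated pairs plateau near 0.5 because the second embedding
  # dimension carries within-cluster structure; the informative contrasts
  # are against the shuffled null (~0) and across levels
  expect_gt(sil_chunk, 0.35)
  expect_gt(sil_chunk, sil_branch)
  # shuffled labels give silhouette near zero
  tab2 <- tab
  set.seed(2)
  tab2$true_chunk <- sample(tab2$true_chunk)
  tab2$true_branch <- sample(tab2$true_branch)
  sep2 <- separability_check(tab2, n_max = 400, seed = 1)
  expect_lt(abs(sep2$silhouette[sep2$level == "chunk"]), 0.05)
  expect_error(separability_check(dplyr::mutate(tab, true_chunk = "A1",
                                                true_branch = "A1.01")),
               "classes")
})

test_that("paired permutation test flags a real improvement and not a null", {
  set.seed(12)
  n <- 600
  cluster <- rep(1:60, each = 10)
  base <- runif(n) < 0.7
  better <- base | (runif(n) < 0.15)
  res <- paired_permutation_test(base, better, cluster, n_perm = 2000)
  expect_lt(res$p_value, 0.001)
  expect_gt(res$delta, 0)
  null <- paired_permutation_test(base, base, cluster, n_perm = 500)
  expect_gt(null$p_value, 0.5)
})
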