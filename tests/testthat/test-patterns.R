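test_that("k-means degenerate cases behave analytically", {
  b <- make_blobs(20, rbind(c(0.2, 0.9, 1, 1), c(0.8, 0.2, 1, 1)), seed = 2)
  f1 <- fit_clusters(b$x, 1, seed = 1)
  expect_equal(unname(f1$centroids[1, ]), unname(colMeans(b$x)))
  expect_true(all(f1$assignments == 1))

  pts <- unique(round(b$x[1:6, ], 3))
  fn <- fit_clusters(pts, nrow(pts), seed = 1)
  expect_equal(fn$inertia, 0, tolerance = 1e-12)

  expect_error(fit_clusters(b$x[0, , drop = FALSE], 2), "empty")
  expect_error(fit_clusters(rbind(c(1, 1, 1, 1), c(1, 1, 1, 1)), 2), "distinct")
})

test_that("k-means matches stats::kmeans on well-separated blobs", {
  b <- make_blobs(40, rbind(c(0.2, 1, 1, 1), c(0.6, 1, 1, 1),
                            c(1, 0.3, 1, 1)), sd = 0.03, seed = 3)
  fit <- fit_clusters(b$x, 3, seed = 1, n_init = 10)
  ref <- stats::kmeans(b$x, 3, nstart = 10)
  expect_equal(fit$inertia, ref$tot.withinss, tolerance = 1e-8)
  expect_equal(adjusted_rand_index(fit$assignments, ref$cluster), 1)
  # every point sits with its nearest centroid
  d2 <- outer(rowSums(b$x^2), rowSums(fit$centroids^2), "+") -
    2 * b$x %*% t(fit$centroids)
  expect_equal(max.col(-d2, ties.method = "first"), fit$assignments)
})

test_that("mean silhouette agrees with a brute-force oracle", {
  b <- make_blobs(12, rbind(c(0.2, 1, 1, 1), c(0.9, 0.3, 1, 1)), seed = 4)
  fit <- fit_clusters(b$x, 2, seed = 1)
  d <- stats::dist(b$x)
  expect_equal(mean_silhouette(fit$assignments, d),
               brute_silhouette(b$x, fit$assignments), tolerance = 1e-12)
  sil <- mean_silhouette(fit$assignments, d)
  expect_true(sil >= -1 && sil <= 1)
})

test_that("silhouette selection recovers three planted blobs", {
  b <- make_blobs(60, rbind(c(0.15, 1, 1, 1), c(0.7, 1, 1, 1),
                            c(1, 0.3, 1, 1)), sd = 0.03, seed = 5)
  sel <- select_k(b$x, 2:6, seed = 1, n_init = 5)
  expect_equal(sel$k, 3)
  expect_true(all(sel$scores$mean_silhouette >= -1 &
                  sel$scores$mean_silhouette <= 1))
  expect_error(select_k(b$x[1:2, ], 2:3), "at least 3")
})

test_that("a single isotropic cloud triggers the low-separation warning", {
  set.seed(6)
  x <- matrix(runif(4 * 300, 0.2, 0.9), ncol = 4,
              dimnames = list(NULL, paste0("t_", tolower(cmd_codes()))))
  expect_warning(sel <- select_k(x, 2:4, seed = 1, n_init = 3),
                 "low cluster separation")
  expect_true(sel$k %in% 2:4)
})

test_that("cluster profiles match hand arithmetic on a 4-trajectory cluster", {
  tt <- traj_table(c(0.2, NA, NA, NA), c(0.4, 0.5, NA, NA),
                   c(NA, NA, NA, NA), c(0.3, NA, NA, 0.6))
  prof <- profile_clusters(list(assignments = rep(1L, 4)), tt)
  expect_length(prof, 1)
  p <- prof[[1]]
  expect_equal(p$n, 4)
  expect_equal(unname(p$incidence_pct), c(75, 25, 0, 25))
  expect_equal(unname(p$time_mean[["HYP"]]), 0.3)
  expect_equal(unname(p$time_sd[["HYP"]]), 0.1)
  expect_true(is.na(p$time_sd[["DM"]]))  # single occurrence
  expect_true(is.na(p$time_mean[["HD"]]))
  expect_equal(p$none_fraction, 0.25)
  expect_equal(as.integer(p$first_freq[["HYP"]]), 3)
  expect_setequal(p$patterns$pattern,
                  c("HYP", "HYP->DM", "HYP->STK", "None Disease"))
  expect_equal(sum(p$patterns$n), 4)
})

test_that("an all-healthy cluster profiles to zero incidence", {
  tt <- traj_table(c(NA, NA, NA, NA), c(NA, NA, NA, NA))
  p <- profile_clusters(list(assignments = c(1L, 1L)), tt)[[1]]
  expect_equal(unname(p$incidence_pct), rep(0, 4))
  expect_true(all(is.na(p$time_mean)))
  expect_equal(p$patterns$pattern, "None Disease")
})

test_that("labeling rules fire in precedence order with configurable thresholds", {
  mk <- function(times_mat) {
    tt <- do.call(traj_table, lapply(seq_len(nrow(times_mat)),
                                     function(i) times_mat[i, ]))
    profile_clusters(list(assignments = rep(1L, nrow(times_mat))), tt)[[1]]
  }
  # 25 members, all hypertension within 40% of follow-up, one with later DM
  early <- mk(cbind(seq(0.05, 0.38, length.out = 25),
                    c(0.6, rep(NA, 24)), NA, NA))
  expect_equal(unname(label_clusters(list(early))), "EarlyHyp")
  late <- mk(cbind(seq(0.41, 0.79, length.out = 25), NA, NA, NA))
  expect_equal(unname(label_clusters(list(late))), "LateHyp")
  dm <- mk(cbind(c(rep(NA, 12), rep(0.6, 8), rep(NA, 5)),
                 seq(0.1, 0.5, length.out = 25), NA, NA))
  expect_equal(unname(label_clusters(list(dm))), "FirstDM")
  hd <- mk(cbind(NA, NA, seq(0.1, 0.5, length.out = 25), NA))
  expect_equal(unname(label_clusters(list(hd))), "FirstHD")
  healthy <- mk(rbind(matrix(NA, 99, 4), c(0.9, NA, NA, NA)))
  expect_equal(unname(label_clusters(list(healthy))), "Healthy")
  stk <- mk(cbind(NA, NA, NA, seq(0.1, 0.9, length.out = 25)))
  expect_equal(unname(label_clusters(list(stk))), "Unlabeled")
  # duplicate labels are suffixed with a warning
  expect_warning(lab <- label_clusters(list(early, early)), "multiple")
  expect_setequal(unname(lab), c("EarlyHyp.1", "EarlyHyp.2"))
  # a tighter threshold can reject what the default accepts
  strict <- label_rules(healthy_none = 0.999)
  expect_equal(unname(label_clusters(list(healthy), strict)), "Unlabeled")
})

test_that("adjusted Rand index agrees with the mclust implementation", {
  skip_if_not_installed("mclust")
  set.seed(8)
  for (i in 1:10) {
    a <- sample(1:4, 60, TRUE)
    b <- sample(1:3, 60, TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 unname(mclust::adjustedRandIndex(a, b)), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 6)), 1)
})

test_that("cmc_patterns fits, labels, predicts and prints", {
  cfg <- study_emulation_config("uk", "female", n = 1200, seed = 21)
  coh <- generate_cohort(cfg)
  fit <- cmc_patterns(coh$trajectories, k = 5, seed = 1, n_init = 5)
  expect_s3_class(fit, "cmc_patterns")
  expect_equal(fit$k, 5)
  expect_length(fit$labels, 1200)
  expect_gt(adjusted_rand_index(fit$model$assignments, coh$labels), 0.9)
  # prediction on the training tuples reproduces the fitted labels
  expect_equal(predict(fit, coh$trajectories), fit$labels)
  expect_output(print(fit), "5 clusters")
  expect_output(summary(fit), "Cluster")
})
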