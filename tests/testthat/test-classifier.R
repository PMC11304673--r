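test_that("preprocessing imputes, scales and one-hot encodes from train statistics", {
  train <- data.frame(num = c(1, 2, 3, 4, 100), cat = c("a", "a", "b", "b", "b"))
  tr <- preprocess_fit(train)
  # test-set NA imputed with the train median (3), then standardised
  out <- preprocess_apply(tr, data.frame(num = NA, cat = "b"))
  vi <- c(1, 2, 3, 4, 100)
  expect_equal(unname(out[1, "num"]), (3 - mean(vi)) / sd(vi),
               tolerance = 1e-12)
  expect_equal(out[1, c("cat.a", "cat.b")], c(cat.a = 0, cat.b = 1))
  # unseen level maps to an all-zero indicator block
  out2 <- preprocess_apply(tr, data.frame(num = 2, cat = "zzz"))
  expect_equal(unname(out2[1, c("cat.a", "cat.b")]), c(0, 0))
  # categorical NA imputed with the train mode
  out3 <- preprocess_apply(tr, data.frame(num = 2, cat = NA))
  expect_equal(unname(out3[1, "cat.b"]), 1)
})

test_that("preprocessing guards zero variance and all-missing columns", {
  tr <- preprocess_fit(data.frame(const = rep(5, 4), x = 1:4))
  out <- preprocess_apply(tr, data.frame(const = c(5, 7), x = c(1, 2)))
  expect_equal(unname(out[, "const"]), c(0, 0))
  expect_error(preprocess_fit(data.frame(bad = c(NA_real_, NA_real_))),
               "'bad'")
})

test_that("SMOTE balances classes by convex combinations", {
  set.seed(3)
  x <- matrix(rnorm(220 * 2), ncol = 2)
  y <- rep(c("maj", "min"), c(200, 20))
  # already balanced input unchanged
  bal <- smote_balance(x[1:40, ], rep(c("a", "b"), each = 20), seed = 1)
  expect_equal(nrow(bal$x), 40)
  # 200/20 -> 200/200
  out <- smote_balance(x, y, k_neighbors = 5, seed = 1)
  expect_equal(unname(table(out$y)["min"]), 200)
  expect_equal(unname(table(out$y)["maj"]), 200)
  expect_equal(out$x[1:220, ], x)  # originals untouched, first

  # minority on a line segment: synthetic points stay on the segment
  seg <- cbind(seq(0, 1, length.out = 10), 2 * seq(0, 1, length.out = 10))
  xs <- rbind(matrix(rnorm(60, 10), ncol = 2), seg)
  ys <- rep(c("big", "line"), c(30, 10))
  o2 <- smote_balance(xs, ys, seed = 2)
  synth <- o2$x[o2$y == "line", ][-(1:10), , drop = FALSE]
  expect_true(all(abs(synth[, 2] - 2 * synth[, 1]) < 1e-10))
  expect_true(all(synth[, 1] >= 0 & synth[, 1] <= 1))

  # singleton class is skipped with a warning
  expect_warning(o3 <- smote_balance(x[1:21, ], rep(c("a", "b"), c(20, 1)),
                                     seed = 1), "single member")
  expect_equal(sum(o3$y == "b"), 1)
})

test_that("weighted metrics match hand-computed confusion-matrix values", {
  expect_equal(unname(weighted_metrics(c("a", "b"), c("a", "b"))),
               rep(1, 4))
  # rows (truth) x cols (pred): (5,1,0 / 0,4,2 / 1,0,7)
  true <- rep(c("c1", "c2", "c3"), c(6, 6, 8))
  pred <- c(rep("c1", 5), "c2",
            rep("c2", 4), "c3", "c3",
            "c1", rep("c3", 7))
  m <- weighted_metrics(true, pred)
  expect_equal(unname(m["accuracy"]), 0.8)
  expect_equal(unname(m["recall"]), 0.8)  # weighted recall == accuracy here
  expect_equal(unname(m["precision"]),
               (6 * 5 / 6 + 6 * 4 / 5 + 8 * 7 / 9) / 20, tolerance = 1e-12)
  f1 <- c(2 * (5 / 6) * (5 / 6) / (5 / 6 + 5 / 6),
          2 * (4 / 5) * (4 / 6) / (4 / 5 + 4 / 6),
          2 * (7 / 9) * (7 / 8) / (7 / 9 + 7 / 8))
  expect_equal(unname(m["f1"]), sum(c(6, 6, 8) / 20 * f1), tolerance = 1e-12)

  # single-class predictions on balanced truth: accuracy 0.5 + warning
  expect_warning(m2 <- weighted_metrics(rep(c("a", "b"), 10), rep("a", 20)),
                 "never predicted")
  expect_equal(unname(m2["accuracy"]), 0.5)
  expect_error(weighted_metrics(character(0), character(0)), "non-empty")
})

test_that("nested CV is deterministic, covers the data and learns a separable rule", {
  d <- make_separable(300, seed = 5)
  cvc <- quick_cv(seed = 2, outer = 5)
  cv1 <- run_nested_cv(d$covariates, d$labels, cvc)
  cv2 <- run_nested_cv(d$covariates, d$labels, cvc)
  expect_identical(cv1$metrics, cv2$metrics)
  expect_gt(cv1$metrics$mean[cv1$metrics$metric == "accuracy"], 0.9)
  # outer-test partitions within the repeat are a disjoint cover
  idx <- sort(unlist(lapply(cv1$fold_results, `[[`, "test_idx")))
  expect_equal(idx, 1:300)
  # transformer statistics come from the training partition only
  fr <- cv1$fold_results[[1]]
  expect_equal(fr$transformer$columns$x$median,
               median(d$covariates$x[fr$train_idx]))
})

test_that("nested CV metrics are invariant to row order", {
  d <- make_separable(240, seed = 6)
  cvc <- quick_cv(seed = 3, outer = 4)
  m1 <- run_nested_cv(d$covariates, d$labels, cvc)$metrics
  set.seed(99); perm <- sample.int(240)
  m2 <- run_nested_cv(d$covariates[perm, ], d$labels[perm], cvc)$metrics
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("inner tuning selects among grid rows", {
  d <- make_separable(200, seed = 7)
  cvc <- cv_config(outer_folds = 3, repeats = 1, inner_folds = 2, seed = 4,
                   grid = data.frame(num_trees = c(50, 60),
                                     max_depth = c(3, 0),
                                     min_node = c(10, 2)))
  cv <- run_nested_cv(d$covariates, d$labels, cvc)
  ps <- do.call(rbind, lapply(cv$fold_results, `[[`, "params"))
  expect_true(all(ps$num_trees %in% c(50, 60)))
})

test_that("classes smaller than the fold count are pooled with a warning", {
  d <- make_separable(120, seed = 8)
  lab <- d$labels
  lab[1:3] <- "rare"
  expect_warning(cv <- run_nested_cv(d$covariates, lab,
                                     quick_cv(seed = 5, outer = 5)),
                 "pooled")
  expect_s3_class(cv, "cmc_cv")
  expect_true("rare" %in% cv$classes)
})
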