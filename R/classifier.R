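#' Fit a fold-internal preprocessing transformer
#'
#' Learns, from a training partition only: per-numeric-column median (for
#' imputation), mean and SD (for standardisation), and per-categorical
#' column the mode (for imputation) and the set of observed levels (for
#' one-hot encoding). [preprocess_apply()] then maps any table through the
#' fitted transformer: numeric columns are imputed, centered and scaled by
#' the training statistics (zero-variance columns map to all zeros);
#' categorical columns are imputed with the training mode and one-hot
#' encoded over the training-observed levels, with levels unseen in
#' training mapping to an all-zero indicator block.
#'
#' @param train data.frame of covariates (numeric and character/factor
#'   columns; identifier columns should be dropped by the caller).
#' @return a `cmc_transformer`.
#' @export
preprocess_fit <- function(train) {
  train <- as.data.frame(train)
  if (!nrow(train)) abort("empty training partition")
  spec <- list()
  for (cn in names(train)) {
    v <- train[[cn]]
    if (is.numeric(v)) {
      if (all(is.na(v))) abort("column '%s' is all-missing in training", cn)
      med <- median(v, na.rm = TRUE)
      vi <- ifelse(is.na(v), med, v)
      s <- sd(vi)
      spec[[cn]] <- list(kind = "numeric", median = med, mean = mean(vi),
                         sd = s, zero_var = !is.finite(s) || s < 1e-12)
    } else {
      v <- as.character(v)
      if (all(is.na(v))) abort("column '%s' is all-missing in training", cn)
      tab <- sort(table(v), decreasing = TRUE)
      mode_lv <- names(tab)[tab == max(tab)]
      mode_lv <- sort(mode_lv)[1]  # deterministic tie-break
      spec[[cn]] <- list(kind = "categorical", mode = mode_lv,
                         levels = sort(unique(v[!is.na(v)])))
    }
  }
  structure(list(columns = spec), class = "cmc_transformer")
}

#' @rdname preprocess_fit
#' @param transformer a fitted `cmc_transformer`.
#' @param table data.frame with the same columns as the training partition.
#' @return `preprocess_apply`: a numeric matrix; one-hot columns are named
#'   `variable.level`.
#' @export
preprocess_apply <- function(transformer, table) {
  stopifnot(inherits(transformer, "cmc_transformer"))
  table <- as.data.frame(table)
  miss <- setdiff(names(transformer$columns), names(table))
  if (length(miss) > 0)
    abort("table lacks column(s): %s", paste(miss, collapse = ", "))
  n <- nrow(table)
  out <- list()
  for (cn in names(transformer$columns)) {
    sp <- transformer$columns[[cn]]
    if (sp$kind == "numeric") {
      v <- as.numeric(table[[cn]])
      v[is.na(v)] <- sp$median
      out[[cn]] <- if (sp$zero_var) rep(0, n) else (v - sp$mean) / sp$sd
    } else {
      v <- as.character(table[[cn]])
      v[is.na(v)] <- sp$mode
      for (lv in sp$levels)
        out[[paste(cn, lv, sep = ".")]] <- as.numeric(v == lv)
    }
  }
  m <- do.call(cbind, out)
  rownames(m) <- NULL
  m
}

#' SMOTE oversampling of minority classes
#'
#' Synthetic minority oversampling: each minority class is upsampled to the
#' majority-class count by convex combinations `x + u (x' - x)`, `u ~
#' U(0, 1)`, of a class member `x` and one of its `k` nearest same-class
#' neighbours `x'` (Euclidean). Applied strictly after preprocessing and
#' strictly on training partitions. Classes of size 1 cannot be
#' interpolated and are skipped with a warning; the effective neighbour
#' count is `min(k_neighbors, class size - 1)`.
#'
#' @param x numeric matrix (preprocessed training features).
#' @param y class labels, length `nrow(x)`.
#' @param k_neighbors nearest-neighbour pool size.
#' @param seed integer seed.
#' @return list with augmented `x` and `y` (original rows first).
#' @export
smote_balance <- function(x, y, k_neighbors = 5, seed = 1) {
  y <- as.character(y)
  if (!nrow(x) || length(y) != nrow(x)) abort("x / y size mismatch or empty")
  tab <- table(y)
  if (any(tab == 0)) abort("empty class")
  target <- max(tab)
  set.seed(seed)
  new_x <- list(); new_y <- character(0)
  for (cl in names(tab)) {
    need <- target - tab[[cl]]
    if (need == 0) next
    rows <- which(y == cl)
    if (length(rows) == 1) {
      warning(sprintf("class '%s' has a single member; SMOTE skipped", cl),
              call. = FALSE)
      next
    }
    xc <- x[rows, , drop = FALSE]
    k_eff <- min(k_neighbors, length(rows) - 1)
    d2 <- dist2_to_centers(xc, xc)
    diag(d2) <- Inf
    # k nearest same-class neighbours per member
    nn <- do.call(rbind, lapply(seq_len(nrow(xc)), function(i)
      order(d2[i, ])[seq_len(k_eff)]))
    base <- sample.int(length(rows), need, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k_eff, need, replace = TRUE))]
    u <- runif(need)
    synth <- xc[base, , drop = FALSE] +
      u * (xc[pick, , drop = FALSE] - xc[base, , drop = FALSE])
    new_x[[cl]] <- synth
    new_y <- c(new_y, rep(cl, need))
  }
  if (length(new_x) > 0) {
    x <- rbind(x, do.call(rbind, new_x))
    y <- c(y, new_y)
  }
  list(x = x, y = y)
}

#' Support-weighted classification metrics
#'
#' Accuracy (plain fraction correct) plus precision, recall and F1 computed
#' per class and averaged weighted by true-class support. A class present
#' in the truth but never predicted gets precision 0 with a warning.
#'
#' @param true,pred equal-length label vectors.
#' @return named numeric vector: `accuracy`, `precision`, `recall`, `f1`.
#' @export
weighted_metrics <- function(true, pred) {
  true <- as.character(true); pred <- as.character(pred)
  if (!length(true) || length(true) != length(pred))
    abort("true / pred must be equal-length and non-empty")
  classes <- sort(unique(true))
  support <- table(factor(true, levels = classes))
  prec <- rec <- f1 <- numeric(length(classes))
  unpredicted <- character(0)
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- sum(true == cl & pred == cl)
    np <- sum(pred == cl)
    nt <- sum(true == cl)
    if (np == 0) {
      prec[i] <- 0
      unpredicted <- c(unpredicted, cl)
    } else prec[i] <- tp / np
    rec[i] <- tp / nt
    f1[i] <- if (prec[i] + rec[i] > 0) 2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  if (length(unpredicted) > 0)
    warning(sprintf("class(es) never predicted: %s (precision set to 0)",
                    paste(unpredicted, collapse = ", ")), call. = FALSE)
  w <- as.numeric(support) / length(true)
  c(accuracy = mean(true == pred),
    precision = sum(w * prec), recall = sum(w * rec), f1 = sum(w * f1))
}

#' Cross-validation configuration
#'
#' Repeated stratified outer cross-validation with nested inner tuning.
#' The default mirrors the evaluation design: 10 outer folds repeated 5
#' times, 5 inner folds for hyperparameter selection by weighted F1, SMOTE
#' with 5 neighbours, median/mode imputation. The hyperparameter grid is a
#' package convention: trees in {200, 500}, depth in {unbounded, 10},
#' minimum leaf size in {1, 5}.
#'
#' @param outer_folds,repeats,inner_folds CV structure (`folds >= 2`,
#'   `repeats >= 1`).
#' @param seed master seed; repeat, fold, SMOTE and model seeds derive from
#'   it via [derive_seed()].
#' @param grid data.frame with columns `num_trees`, `max_depth` (0 =
#'   unbounded) and `min_node`.
#' @param smote_k_neighbors SMOTE neighbour count.
#' @return a `cv_config` list.
#' @export
cv_config <- function(outer_folds = 10, repeats = 5, inner_folds = 5,
                      seed = 1,
                      grid = expand.grid(num_trees = c(200, 500),
                                         max_depth = c(0, 10),
                                         min_node = c(1, 5)),
                      smote_k_neighbors = 5) {
  if (outer_folds < 2 || inner_folds < 2) abort("folds must be >= 2")
  if (repeats < 1) abort("repeats must be >= 1")
  grid <- as.data.frame(grid)
  if (!nrow(grid) || !all(c("num_trees", "max_depth", "min_node") %in% names(grid)))
    abort("grid must be non-empty with num_trees, max_depth, min_node")
  structure(list(outer_folds = as.integer(outer_folds),
                 repeats = as.integer(repeats),
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed), grid = grid,
                 smote_k_neighbors = smote_k_neighbors),
            class = "cv_config")
}

# internal: fit a probability forest on a preprocessed matrix
fit_forest <- function(x, y, params, seed) {
  ranger::ranger(x = as.data.frame(x), y = factor(y),
                 num.trees = params$num_trees,
                 max.depth = params$max_depth,
                 min.node.size = params$min_node,
                 probability = TRUE, seed = seed, num.threads = 1,
                 keep.inbag = FALSE)
}

# internal: predicted classes from a probability forest
predict_class <- function(fit, x) {
  pr <- predict(fit, as.data.frame(x), num.threads = 1)$predictions
  colnames(pr)[max.col(pr, ties.method = "first")]
}

#' Leakage-controlled nested cross-validated random forest
#'
#' Repeated stratified outer cross-validation of a multiclass probability
#' random forest predicting pattern labels from baseline covariates. In
#' every outer fold: hyperparameters are chosen by an inner stratified CV
#' run entirely on the outer-training partition (each inner fold refits the
#' preprocessing transformer and reapplies SMOTE on its own training part);
#' the winning parameters are refitted on the full outer-training partition
#' (preprocessed, then SMOTE-balanced); the held-out outer-test partition
#' is transformed with the outer-training transformer and never
#' oversampled. Metrics are support-weighted and aggregated as mean (SD)
#' over all `repeats x outer_folds` folds.
#'
#' Classes with fewer members than `outer_folds` are pooled into one
#' stratum for splitting only (true labels are kept for scoring), with a
#' warning.
#'
#' The `smote_timing = "pre_split"` variant deliberately applies
#' preprocessing and SMOTE to the full table before splitting. It exists
#' only to demonstrate the optimistic bias such leakage induces and must
#' not be used for evaluation.
#'
#' @param covariates data.frame of baseline covariates (no identifier
#'   columns).
#' @param labels outcome pattern labels, one per row.
#' @param config a [cv_config()].
#' @param keep_models keep fitted forests and training matrices per fold
#'   (required for SHAP explanation).
#' @param smote_timing `"fold_internal"` (correct) or `"pre_split"`
#'   (leakage diagnostic).
#' @return object of class `cmc_cv`: `metrics` (data.frame mean/sd for
#'   accuracy, precision, recall, f1), `fold_metrics`, `fold_results`
#'   (per-fold list: indices, chosen params, predictions, probabilities,
#'   and if `keep_models` the forest, transformer and training matrix),
#'   `config`, `classes`.
#' @export
run_nested_cv <- function(covariates, labels, config = cv_config(),
                          keep_models = FALSE,
                          smote_timing = c("fold_internal", "pre_split")) {
  smote_timing <- match.arg(smote_timing)
  covariates <- as.data.frame(covariates)
  labels <- as.character(labels)
  n <- nrow(covariates)
  if (n == 0 || length(labels) != n) abort("covariates / labels mismatch")
  tab <- table(labels)
  if (any(tab < config$outer_folds))
    warning(sprintf("class(es) smaller than outer_folds pooled for splitting: %s",
                    paste(names(tab)[tab < config$outer_folds], collapse = ", ")),
            call. = FALSE)

  leak <- NULL
  if (smote_timing == "pre_split") {
    tr_all <- preprocess_fit(covariates)
    x_all <- preprocess_apply(tr_all, covariates)
    sm <- smote_balance(x_all, labels, config$smote_k_neighbors,
                        derive_seed(config$seed, 66L))
    leak <- sm  # augmented pool; folds are drawn from it below
  }

  canon <- canonical_rank(covariates, labels)
  fold_results <- list()
  fold_metrics <- list()
  for (r in seq_len(config$repeats)) {
    rep_seed <- derive_seed(config$seed, 20L, r)
    if (is.null(leak)) {
      folds <- stratified_folds(labels, config$outer_folds, rep_seed, canon)
      pool_x <- NULL; pool_y <- labels
    } else {
      pool_y <- leak$y
      folds <- stratified_folds(pool_y, config$outer_folds, rep_seed)
      pool_x <- leak$x
    }
    for (f in seq_len(config$outer_folds)) {
      fold_seed <- derive_seed(rep_seed, 21L, f)
      test_idx <- which(folds == f)
      train_idx <- which(folds != f)
      if (is.null(leak)) {
        fit <- fit_outer_fold(covariates, labels, train_idx, test_idx,
                              config, fold_seed, keep_models, canon)
      } else {
        # leakage diagnostic: oversampled pool already transformed
        params <- config$grid[1, , drop = FALSE]
        model <- fit_forest(pool_x[train_idx, , drop = FALSE],
                            pool_y[train_idx], params,
                            derive_seed(fold_seed, 23L))
        pred <- predict_class(model, pool_x[test_idx, , drop = FALSE])
        fit <- list(params = params, pred = pred,
                    prob = predict(model, as.data.frame(
                      pool_x[test_idx, , drop = FALSE]),
                      num.threads = 1)$predictions,
                    true = pool_y[test_idx],
                    test_idx = test_idx, train_idx = train_idx)
      }
      fit$repeat_idx <- r; fit$fold <- f
      m <- suppressWarnings(weighted_metrics(fit$true, fit$pred))
      fold_metrics[[length(fold_metrics) + 1]] <-
        data.frame(repeat_idx = r, fold = f, t(m))
      fold_results[[length(fold_results) + 1]] <- fit
    }
  }
  fm <- do.call(rbind, fold_metrics)
  metr <- data.frame(
    metric = c("accuracy", "precision", "recall", "f1"),
    mean = c(mean(fm$accuracy), mean(fm$precision), mean(fm$recall),
             mean(fm$f1)),
    sd = c(sd(fm$accuracy), sd(fm$precision), sd(fm$recall), sd(fm$f1)))
  structure(list(metrics = metr, fold_metrics = fm,
                 fold_results = fold_results, config = config,
                 classes = sort(unique(labels)),
                 smote_timing = smote_timing),
            class = "cmc_cv")
}

# internal: one correctly leakage-controlled outer fold
fit_outer_fold <- function(covariates, labels, train_idx, test_idx, config,
                           fold_seed, keep_models, canon) {
  # order partitions canonically so every downstream draw (SMOTE, forest)
  # depends on row content, not storage order
  train_idx <- train_idx[order(canon[train_idx])]
  test_idx <- test_idx[order(canon[test_idx])]
  train_cov <- covariates[train_idx, , drop = FALSE]
  train_y <- labels[train_idx]
  # inner tuning (skipped for a single-point grid)
  params <- config$grid[1, , drop = FALSE]
  if (nrow(config$grid) > 1) {
    inner_folds <- stratified_folds(train_y, config$inner_folds,
                                    derive_seed(fold_seed, 22L),
                                    canon[train_idx])
    score <- numeric(nrow(config$grid))
    for (ifold in seq_len(config$inner_folds)) {
      itr <- which(inner_folds != ifold)
      ite <- which(inner_folds == ifold)
      tr <- preprocess_fit(train_cov[itr, , drop = FALSE])
      xi <- preprocess_apply(tr, train_cov[itr, , drop = FALSE])
      sm <- smote_balance(xi, train_y[itr], config$smote_k_neighbors,
                          derive_seed(fold_seed, 24L, ifold))
      xt <- preprocess_apply(tr, train_cov[ite, , drop = FALSE])
      for (gi in seq_len(nrow(config$grid))) {
        model <- fit_forest(sm$x, sm$y, config$grid[gi, , drop = FALSE],
                            derive_seed(fold_seed, 25L, 100 * ifold + gi))
        m <- suppressWarnings(weighted_metrics(train_y[ite],
                                               predict_class(model, xt)))
        score[gi] <- score[gi] + m[["f1"]]
      }
    }
    params <- config$grid[which.max(score), , drop = FALSE]
  }
  # refit on the full outer-training partition
  transformer <- preprocess_fit(train_cov)
  x_train <- preprocess_apply(transformer, train_cov)
  sm <- smote_balance(x_train, train_y, config$smote_k_neighbors,
                      derive_seed(fold_seed, 26L))
  model <- fit_forest(sm$x, sm$y, params, derive_seed(fold_seed, 23L))
  x_test <- preprocess_apply(transformer, covariates[test_idx, , drop = FALSE])
  prob <- predict(model, as.data.frame(x_test), num.threads = 1)$predictions
  pred <- colnames(prob)[max.col(prob, ties.method = "first")]
  out <- list(params = params, pred = pred, prob = prob,
              true = labels[test_idx],
              test_idx = test_idx, train_idx = train_idx,
              transformer = transformer)
  if (keep_models) {
    out$model <- model
    out$x_train_balanced <- sm$x
    out$x_test <- x_test
  }
  out
}

#' @export
print.cmc_cv <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Nested CV random forest: %d x %d-fold outer, %d-fold inner (%s)\n",
              cfg$repeats, cfg$outer_folds, cfg$inner_folds, x$smote_timing))
  m <- x$metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-9s %.3f (sd %.3f)\n", m$metric[i], m$mean[i], m$sd[i]))
  invisible(x)
}

#' @export
summary.cmc_cv <- function(object, ...) {
  print(object)
  cat("\nChosen hyperparameters by fold (top rows):\n")
  ps <- do.call(rbind, lapply(object$fold_results, function(fr)
    cbind(data.frame(repeat_idx = fr$repeat_idx, fold = fr$fold), fr$params)))
  print(head(ps, 10), row.names = FALSE)
  invisible(object)
}
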