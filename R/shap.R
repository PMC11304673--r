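# internal: flatten a ranger probability forest into the flat-array tree
# structure the C++ TreeSHAP kernel consumes. Node covers are the counts of
# the model's own training rows passing through each node.
extract_forest <- function(model, x_train, feature_names, classes) {
  n_trees <- model$num.trees
  term <- predict(model, as.data.frame(x_train), type = "terminalNodes",
                  num.threads = 1)$predictions
  lapply(seq_len(n_trees), function(t) {
    ti <- ranger::treeInfo(model, t)
    ti <- ti[order(ti$nodeID), , drop = FALSE]
    m <- nrow(ti)
    left <- ifelse(is.na(ti$leftChild), -1L, as.integer(ti$leftChild))
    right <- ifelse(is.na(ti$rightChild), -1L, as.integer(ti$rightChild))
    feat <- ifelse(is.na(ti$splitvarID), -1L, as.integer(ti$splitvarID))
    thr <- ifelse(is.na(ti$splitval), 0, ti$splitval)
    # leaf class probabilities, aligned to the global class set
    vals <- matrix(0, m, length(classes))
    pred_cols <- paste0("pred.", model$forest$levels)
    have <- intersect(pred_cols, names(ti))
    for (pc in have) {
      cls <- sub("^pred\\.", "", pc)
      j <- match(cls, classes)
      if (!is.na(j)) vals[, j] <- ifelse(is.na(ti[[pc]]), 0, ti[[pc]])
    }
    # covers: tabulate terminal nodes, then fold up (children have larger
    # node ids than their parent in ranger's storage)
    cover <- as.numeric(tabulate(term[, t] + 1L, nbins = m))
    for (j in rev(seq_len(m))) {
      if (left[j] >= 0)
        cover[j] <- cover[left[j] + 1L] + cover[right[j] + 1L]
    }
    if (cover[1] != nrow(x_train))
      abort("internal cover mismatch in tree %d", t)
    if (any(left >= 0 & (cover[pmax(left, 0) + 1L] == 0 |
                         cover[pmax(right, 0) + 1L] == 0)))
      abort("tree %d has an uncovered split; covers need the training matrix", t)
    list(left = left, right = right, feature = feat, threshold = thr,
         cover = cover, values = vals)
  })
}

#' TreeSHAP attributions on held-out CV folds
#'
#' Computes path-dependent TreeSHAP attributions, in predicted-probability
#' space, for every held-out row of every outer fold of a fitted
#' [run_nested_cv()] object (which must have been run with
#' `keep_models = TRUE`). Attributions are computed strictly on each fold's
#' own test partition with each fold's own model; no background data set is
#' involved (node covers come from the fold's training matrix). For every
#' row and class, base value plus the sum of attributions equals the
#' model's predicted probability to floating-point accuracy.
#'
#' One-hot encoded levels are attributed individually (e.g.
#' `education.Sec`); features missing from a fold's encoding (level never
#' seen in that training partition) pool with attribution 0.
#'
#' @param cv a `cmc_cv` fitted with `keep_models = TRUE`.
#' @param pool `"concatenate"` pools all held-out attributions (each row
#'   appears once per repeat); `"per_repeat_average"` averages a row's
#'   attributions across repeats.
#' @return object of class `cmc_shap`: list with `meta` (data.frame
#'   `repeat_idx`, `fold`, `row`, `true`), `features` (pooled feature
#'   names), `phi` (list per class: pooled rows x features attribution
#'   matrix), `base` (pooled rows x classes), `prob` (model probabilities
#'   for the same rows), `feature_values` (pooled encoded test features)
#'   and `classes`.
#' @export
compute_shap_cv <- function(cv, pool = c("concatenate", "per_repeat_average")) {
  pool <- match.arg(pool)
  stopifnot(inherits(cv, "cmc_cv"))
  if (is.null(cv$fold_results[[1]]$model))
    abort("run_nested_cv must be called with keep_models = TRUE for SHAP")
  classes <- cv$classes
  feats <- unique(unlist(lapply(cv$fold_results,
                                function(fr) colnames(fr$x_test))))
  metas <- list(); phis <- list(); bases <- list(); probs <- list()
  fvals <- list()
  for (fi in seq_along(cv$fold_results)) {
    fr <- cv$fold_results[[fi]]
    fn <- colnames(fr$x_test)
    trees <- extract_forest(fr$model, fr$x_train_balanced, fn, classes)
    res <- treeshap_forest(trees, fr$x_test, length(classes))
    nr <- nrow(fr$x_test)
    phi_full <- array(0, c(nr, length(feats), length(classes)))
    phi_full[, match(fn, feats), ] <- res$phi
    xv <- matrix(0, nr, length(feats))
    xv[, match(fn, feats)] <- fr$x_test
    metas[[fi]] <- data.frame(repeat_idx = fr$repeat_idx, fold = fr$fold,
                              row = fr$test_idx, true = fr$true,
                              stringsAsFactors = FALSE)
    phis[[fi]] <- phi_full
    bases[[fi]] <- matrix(res$base, nr, length(classes), byrow = TRUE)
    # model probabilities aligned to global classes
    pr <- matrix(0, nr, length(classes), dimnames = list(NULL, classes))
    pr[, colnames(fr$prob)] <- fr$prob
    probs[[fi]] <- pr
    fvals[[fi]] <- xv
  }
  meta <- do.call(rbind, metas)
  phi_all <- do.call(abind_rows, phis)
  base <- do.call(rbind, bases)
  prob <- do.call(rbind, probs)
  fv <- do.call(rbind, fvals)
  if (pool == "per_repeat_average") {
    key <- meta$row
    agg <- function(m) {
      out <- rowsum(m, key) / as.vector(table(key)[as.character(sort(unique(key)))])
      out
    }
    phi_all <- array(
      vapply(seq_along(classes),
             function(c) agg(phi_all[, , c, drop = TRUE]),
             matrix(0, length(unique(key)), length(feats))),
      c(length(unique(key)), length(feats), length(classes)))
    base <- agg(base); prob <- agg(prob); fv <- agg(fv)
    meta <- data.frame(repeat_idx = NA_integer_, fold = NA_integer_,
                       row = sort(unique(key)),
                       true = meta$true[match(sort(unique(key)), meta$row)])
  }
  phi <- setNames(lapply(seq_along(classes), function(c) {
    m <- phi_all[, , c, drop = FALSE]
    dim(m) <- dim(phi_all)[1:2]
    colnames(m) <- feats
    m
  }), classes)
  colnames(fv) <- feats
  colnames(base) <- classes
  structure(list(meta = meta, features = feats, phi = phi, base = base,
                 prob = prob, feature_values = fv, classes = classes,
                 pool = pool),
            class = "cmc_shap")
}

# internal: rbind 3-d arrays along the first dimension
abind_rows <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(0, c(sum(vapply(parts, function(p) dim(p)[1], 0L)), d[2], d[3]))
  at <- 0
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' @export
print.cmc_shap <- function(x, ...) {
  cat("TreeSHAP attributions:", nrow(x$meta), "pooled held-out rows,",
      length(x$features), "encoded features,",
      length(x$classes), "classes\n")
  invisible(x)
}

#' Global feature importance for one class
#'
#' Mean absolute attribution per encoded feature over all pooled held-out
#' rows, ranked descending — the per-class global importance that drives
#' top-10 importance plots.
#'
#' @param shap a `cmc_shap`.
#' @param class class label.
#' @param top_m how many features to flag as top (default 10).
#' @return data.frame `feature`, `mean_abs_shap`, `rank`, `top` (logical),
#'   ordered by rank. Ties keep the stable feature order.
#' @export
global_importance <- function(shap, class, top_m = 10) {
  stopifnot(inherits(shap, "cmc_shap"))
  if (!class %in% shap$classes) abort("unknown class '%s'", class)
  m <- shap$phi[[class]]
  if (!nrow(m)) abort("empty attribution pool")
  imp <- colMeans(abs(m))
  ord <- order(-imp, seq_along(imp))
  data.frame(feature = shap$features[ord], mean_abs_shap = imp[ord],
             rank = seq_along(ord), top = seq_along(ord) <= top_m,
             stringsAsFactors = FALSE)
}

#' Local directionality of one feature for one class
#'
#' Exports the beeswarm-style (feature value, attribution) pairs for one
#' encoded feature and class, plus a sign-concordance score: for a
#' continuous feature, the fraction of rows where the attribution's sign
#' matches the sign of the feature value minus its median (rows at the
#' median excluded); for a one-hot indicator, the fraction of indicator-1
#' rows with positive attribution. Constant features have no defined
#' direction and return `NA`.
#'
#' @param shap a `cmc_shap`.
#' @param feature encoded feature name.
#' @param class class label.
#' @return list with `data` (data.frame `value`, `attribution`) and
#'   `sign_concordance`.
#' @export
directionality_summary <- function(shap, feature, class) {
  stopifnot(inherits(shap, "cmc_shap"))
  if (!feature %in% shap$features) abort("unknown feature '%s'", feature)
  if (!class %in% shap$classes) abort("unknown class '%s'", class)
  v <- shap$feature_values[, feature]
  a <- shap$phi[[class]][, feature]
  is_indicator <- all(v %in% c(0, 1))
  if (length(unique(v)) < 2) {
    conc <- NA_real_
  } else if (is_indicator) {
    conc <- mean(a[v == 1] > 0)
  } else {
    med <- median(v)
    nz <- v != med
    conc <- if (any(nz)) mean(sign(a[nz]) == sign(v[nz] - med)) else NA_real_
  }
  list(data = data.frame(value = v, attribution = a),
       sign_concordance = conc)
}
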