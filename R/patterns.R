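#' k-means clustering of CMC trajectories
#'
#' Lloyd's algorithm on the raw (unscaled) 4-tuples of fractional occurrence
#' times; all four coordinates already share the (0, 1] scale so no feature
#' scaling is applied. The best of `n_init` seeded restarts by within-cluster
#' sum of squares (inertia) is kept, which makes the fit deterministic given
#' `seed`. A centroid left empty during an iteration is reinitialised at the
#' point currently farthest from its assigned centroid (deterministic).
#'
#' @param trajectories trajectory table (columns `t_hyp` .. `t_stk`) or
#'   numeric matrix with 4 columns.
#' @param k number of clusters, `>= 1`; must not exceed the number of
#'   distinct 4-tuples.
#' @param seed integer seed for the restarts.
#' @param n_init number of seeded restarts.
#' @param max_iter Lloyd iteration cap per restart.
#' @return an object of class `cmc_kmeans`: list with `k`, `centroids`
#'   (k x 4), `assignments` (1-based), `inertia`, `seed`, `n_init`,
#'   `iterations`.
#' @export
fit_clusters <- function(trajectories, k, seed = 1, n_init = 10,
                         max_iter = 100) {
  x <- traj_matrix(trajectories)
  n <- nrow(x)
  if (n == 0) abort("empty input: no trajectories to cluster")
  if (k < 1) abort("k must be >= 1")
  n_distinct <- nrow(unique(x))
  if (n_distinct < k)
    abort("only %d distinct 4-tuples for k = %d clusters", n_distinct, k)
  best <- NULL
  for (r in seq_len(n_init)) {
    set.seed(derive_seed(seed, 10L, r))
    fit <- lloyd_once(x, k, max_iter)
    if (is.null(best) || fit$inertia < best$inertia - 1e-12) best <- fit
  }
  structure(c(best, list(seed = seed, n_init = n_init)),
            class = "cmc_kmeans")
}

# internal: squared Euclidean distances of rows of x to rows of centers
dist2_to_centers <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
  pmax(d2, 0)
}

# internal: one Lloyd run from a random distinct-point initialisation
lloyd_once <- function(x, k, max_iter) {
  n <- nrow(x)
  # sample distinct starting points
  ux <- unique(x)
  centers <- ux[sample.int(nrow(ux), k), , drop = FALSE]
  assign_prev <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centers(x, centers)
    assign <- max.col(-d2, ties.method = "first")
    # empty-cluster repair: move the centroid to the point farthest from its
    # current centroid, then reassign
    repeat {
      sizes <- tabulate(assign, nbins = k)
      if (all(sizes > 0)) break
      cur <- d2[cbind(seq_len(n), assign)]
      far <- which.max(cur)
      empty <- which(sizes == 0)[1]
      centers[empty, ] <- x[far, ]
      d2 <- dist2_to_centers(x, centers)
      assign <- max.col(-d2, ties.method = "first")
    }
    for (j in seq_len(k))
      centers[j, ] <- colMeans(x[assign == j, , drop = FALSE])
    if (identical(assign, assign_prev)) break
    assign_prev <- assign
  }
  d2 <- dist2_to_centers(x, centers)
  assign <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(n), assign)])
  list(k = k, centroids = centers, assignments = assign, inertia = inertia,
       iterations = it)
}

#' Select the number of clusters by average silhouette
#'
#' Fits [fit_clusters()] for each candidate `k` and computes the mean
#' silhouette coefficient over all points (Euclidean distance, via
#' \pkg{cluster}); the `k` with the largest mean silhouette wins. Beyond
#' `max_silhouette_n` points a seeded uniform subsample is used for the
#' silhouette evaluation (the fits still use all points), a performance
#' convention for the quadratic distance matrix.
#'
#' @inheritParams fit_clusters
#' @param k_range candidate cluster counts (subset of `2 .. n-1`).
#' @param max_silhouette_n silhouette subsample cap.
#' @param warn_threshold mean-silhouette level below which a low-separation
#'   warning is raised for the winning `k`.
#' @return list with `k` (the argmax), `scores` (data.frame `k`,
#'   `mean_silhouette`), and `fits` (the fitted `cmc_kmeans` per k).
#' @export
select_k <- function(trajectories, k_range = 2:8, seed = 1, n_init = 10,
                     max_silhouette_n = 20000, warn_threshold = 0.25) {
  x <- traj_matrix(trajectories)
  n <- nrow(x)
  if (n < 3) abort("need at least 3 trajectories to select k")
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > n - 1))
    abort("k_range must lie within [2, n - 1]")
  sub <- seq_len(n)
  if (n > max_silhouette_n) {
    set.seed(derive_seed(seed, 11L))
    sub <- sort(sample.int(n, max_silhouette_n))
  }
  dsub <- stats::dist(x[sub, , drop = FALSE])
  fits <- list()
  scores <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- fit_clusters(x, k, seed = seed, n_init = n_init)
    fits[[as.character(k)]] <- fit
    scores[i] <- mean_silhouette(fit$assignments[sub], dsub)
  }
  best <- k_range[which.max(scores)]
  if (max(scores) < warn_threshold)
    warning(sprintf(paste("low cluster separation: best mean silhouette",
                          "%.3f (< %.2f) at k = %d"),
                    max(scores), warn_threshold, best), call. = FALSE)
  list(k = best,
       scores = data.frame(k = k_range, mean_silhouette = scores),
       fits = fits)
}

#' Mean silhouette coefficient of a clustering
#'
#' @param assignments integer cluster indices.
#' @param d a `dist` object over the same points.
#' @return mean silhouette width (in `[-1, 1]`); points in singleton
#'   clusters contribute 0, the \pkg{cluster} convention.
#' @export
mean_silhouette <- function(assignments, d) {
  if (length(unique(assignments)) < 2) abort("need >= 2 clusters")
  sil <- cluster::silhouette(assignments, d)
  mean(sil[, "sil_width"])
}

#' Per-cluster incidence, timing and ordered-pattern profiles
#'
#' For each cluster: size, per-disease incidence (percent of members), mean
#' and SD of the fractional occurrence time among members who developed the
#' disease, the first-disease frequency distribution, and the ordered
#' trajectory pattern frequency table (descending).
#'
#' @param model a `cmc_kmeans` fit (or any list with `assignments`).
#' @param trajectories the trajectory table the model was fitted on.
#' @return list of `cluster_profile` objects, one per cluster, each a list
#'   with `cluster`, `n`, `incidence_pct`, `time_mean`, `time_sd`,
#'   `none_fraction`, `first_freq`, `first_tie_n`, `patterns` (data.frame
#'   `pattern`, `n`, `pct`) and `times_occurred` (per-disease occurred
#'   times, kept for rule evaluation).
#' @export
profile_clusters <- function(model, trajectories) {
  x <- traj_matrix(trajectories)
  occ <- traj_occ(trajectories)
  assign <- model$assignments
  if (length(assign) != nrow(x))
    abort("assignments (%d) do not cover the %d trajectories",
          length(assign), nrow(x))
  lapply(sort(unique(assign)), function(j) {
    rows <- which(assign == j)
    tj <- x[rows, , drop = FALSE]
    oj <- occ[rows, , drop = FALSE]
    nn <- length(rows)
    inc <- 100 * colSums(oj) / nn
    times_occ <- lapply(seq_len(4), function(d) tj[oj[, d], d])
    names(times_occ) <- cmd_codes()
    tmean <- vapply(times_occ, function(v) if (length(v)) mean(v) else NA_real_, 0)
    tsd <- vapply(times_occ, function(v) if (length(v) > 1) sd(v) else NA_real_, 0)
    firsts <- character(nn); ties <- 0L
    pats <- character(nn)
    for (i in seq_len(nn)) {
      tr <- c(tj[i, ]); o <- c(oj[i, ])
      fd <- first_disease(make_pair(tr, o))
      firsts[i] <- if (is.null(fd)) "None" else fd$disease
      if (!is.null(fd) && fd$tie) ties <- ties + 1L
      pats[i] <- pattern_string(make_pair(tr, o))
    }
    ptab <- as.data.frame(table(pats), stringsAsFactors = FALSE)
    names(ptab) <- c("pattern", "n")
    ptab$pct <- 100 * ptab$n / nn
    ptab <- ptab[order(-ptab$n, ptab$pattern), , drop = FALSE]
    rownames(ptab) <- NULL
    structure(list(cluster = j, n = nn,
                   incidence_pct = setNames(inc, cmd_codes()),
                   time_mean = tmean, time_sd = tsd,
                   none_fraction = mean(firsts == "None"),
                   first_freq = table(factor(firsts,
                                             levels = c(cmd_codes(), "None"))),
                   first_tie_n = ties,
                   patterns = ptab,
                   times_occurred = times_occ),
              class = "cluster_profile")
  })
}

# internal: wrap a (times, occurred) pair as a minimal cmc_trajectory so the
# single-trajectory operations apply (needed because occurred may be TRUE at
# t = 1 for events at exactly end of follow-up)
make_pair <- function(times, occurred) {
  structure(list(participant_id = NA_character_,
                 times = setNames(times, cmd_codes()),
                 occurred = setNames(occurred, cmd_codes()),
                 follow_up = NA_real_),
            class = "cmc_trajectory")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat(sprintf("Cluster %d (n = %d): disease-free %.1f%%\n",
              x$cluster, x$n, 100 * x$none_fraction))
  inc <- sprintf("%s %.1f%% (t %.2f)", cmd_codes(), x$incidence_pct, x$time_mean)
  cat(" ", paste(inc, collapse = ", "), "\n")
  cat("  top patterns:",
      paste(sprintf("%s %d (%.1f%%)", head(x$patterns$pattern, 3),
                    head(x$patterns$n, 3), head(x$patterns$pct, 3)),
            collapse = "; "), "\n")
  invisible(x)
}

#' Default thresholds for rule-based pattern labeling
#'
#' The published pattern definitions are scenario-dependent (e.g. the
#' heart-disease-first rule requires HD first for at least 75% of members in
#' the Brazilian strata but 90% in the UK strata); the defaults here resolve
#' each rule to its weakest published bound so the same configuration labels
#' every stratum. All thresholds are fractions in `[0, 1]`.
#'
#' @param healthy_none Healthy: minimum disease-free fraction.
#' @param hd_first FirstHD: minimum fraction with HD first (HD incidence
#'   must be 100%).
#' @param dm_first FirstDM: minimum fraction with DM first (DM incidence
#'   must be 100%).
#' @param hyp_first Early/LateHyp: minimum fraction with HYP first (HYP
#'   incidence must be 100%).
#' @param hyp_window_frac Early/LateHyp: minimum fraction of hypertension
#'   times inside the pattern's window (`(0, 0.4]` early, `(0.4, 0.8]` late).
#' @return named list of thresholds.
#' @export
label_rules <- function(healthy_none = 0.88, hd_first = 0.75,
                        dm_first = 0.78, hyp_first = 0.92,
                        hyp_window_frac = 0.95) {
  list(healthy_none = healthy_none, hd_first = hd_first,
       dm_first = dm_first, hyp_first = hyp_first,
       hyp_window_frac = hyp_window_frac)
}

#' Rule-based labeling of discovered clusters
#'
#' Evaluates the pattern definitions in precedence order Healthy, FirstHD,
#' FirstDM, EarlyHyp, LateHyp; the first matching rule wins and a cluster
#' matching none is `Unlabeled`. If two clusters receive the same
#' non-Unlabeled label both are kept with numeric suffixes and a warning is
#' raised.
#'
#' @param profiles list of `cluster_profile` from [profile_clusters()].
#' @param rule_config thresholds from [label_rules()].
#' @return named character vector: cluster index -> label.
#' @export
label_clusters <- function(profiles, rule_config = label_rules()) {
  if (!length(profiles)) abort("no cluster profiles to label")
  rc <- rule_config
  one <- function(p) {
    ff <- p$first_freq / max(1, p$n)
    inc <- p$incidence_pct
    hyp_t <- p$times_occurred$HYP
    frac_in <- function(v, lo, hi) if (length(v)) mean(v > lo & v <= hi) else 0
    if (p$none_fraction >= rc$healthy_none) return("Healthy")
    if (inc["HD"] >= 100 - 1e-9 && ff[["HD"]] >= rc$hd_first) return("FirstHD")
    if (inc["DM"] >= 100 - 1e-9 && ff[["DM"]] >= rc$dm_first) return("FirstDM")
    if (inc["HYP"] >= 100 - 1e-9 && ff[["HYP"]] >= rc$hyp_first) {
      if (frac_in(hyp_t, 0, 0.4) >= rc$hyp_window_frac) return("EarlyHyp")
      if (frac_in(hyp_t, 0.4, 0.8) >= rc$hyp_window_frac) return("LateHyp")
    }
    "Unlabeled"
  }
  labels <- vapply(profiles, one, "")
  names(labels) <- vapply(profiles, `[[`, 0L, "cluster")
  dup <- labels[labels != "Unlabeled"]
  dup <- unique(dup[duplicated(dup)])
  if (length(dup) > 0) {
    warning(sprintf("label(s) %s assigned to multiple clusters; suffixed",
                    paste(dup, collapse = ", ")), call. = FALSE)
    for (d in dup) {
      at <- which(labels == d)
      labels[at] <- paste0(d, ".", seq_along(at))
    }
  }
  labels
}

#' Discover and label CMC patterns
#'
#' The front end of pattern discovery: selects the number of clusters by
#' average silhouette (unless `k` is given), fits k-means on the raw
#' 4-tuples, profiles each cluster and applies the rule-based pattern
#' labels. Returns a fitted-model object with `print`, `summary`, `plot`
#' and `predict` methods.
#'
#' @inheritParams fit_clusters
#' @param k fixed number of clusters, or `NULL` to select by silhouette
#'   over `k_range`.
#' @param k_range candidate cluster counts when `k` is `NULL`.
#' @param rules labeling thresholds from [label_rules()].
#' @param ... passed on to [select_k()].
#' @return object of class `cmc_patterns`: list with `model`
#'   (`cmc_kmeans`), `k`, `k_scores` (silhouette table or `NULL`),
#'   `profiles`, `cluster_labels`, `labels` (per-trajectory pattern label)
#'   and `call`.
#' @examples
#' cfg <- study_emulation_config("uk", "female", n = 800, seed = 42)
#' coh <- generate_cohort(cfg)
#' fit <- cmc_patterns(coh$trajectories, k_range = 2:6, seed = 1)
#' print(fit)
#' @export
cmc_patterns <- function(trajectories, k = NULL, k_range = 2:8, seed = 1,
                         n_init = 10, rules = label_rules(), ...) {
  k_scores <- NULL
  if (is.null(k)) {
    sel <- select_k(trajectories, k_range = k_range, seed = seed,
                    n_init = n_init, ...)
    k <- sel$k
    k_scores <- sel$scores
    model <- sel$fits[[as.character(k)]]
  } else {
    model <- fit_clusters(trajectories, k, seed = seed, n_init = n_init)
  }
  profiles <- profile_clusters(model, trajectories)
  cl_labels <- label_clusters(profiles, rules)
  structure(list(model = model, k = model$k, k_scores = k_scores,
                 profiles = profiles, cluster_labels = cl_labels,
                 labels = unname(cl_labels[as.character(model$assignments)]),
                 call = match.call()),
            class = "cmc_patterns")
}

#' @export
print.cmc_patterns <- function(x, ...) {
  cat("CMC pattern model:", x$k, "clusters over",
      length(x$model$assignments), "trajectories\n")
  if (!is.null(x$k_scores)) {
    best <- x$k_scores$mean_silhouette[x$k_scores$k == x$k]
    cat(sprintf("  k selected by average silhouette (%.3f)\n", best))
  }
  sizes <- table(x$labels)
  cat("  patterns:",
      paste(sprintf("%s (%d)", names(sizes), as.integer(sizes)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cmc_patterns <- function(object, ...) {
  cat("CMC pattern model (k =", object$k, ")\n")
  if (!is.null(object$k_scores)) {
    cat("\nSilhouette by k:\n")
    print(object$k_scores, row.names = FALSE)
  }
  cat("\n")
  for (i in seq_along(object$profiles)) {
    cat(sprintf("[%s] ", object$cluster_labels[i]))
    print(object$profiles[[i]])
  }
  invisible(object)
}

#' @export
predict.cmc_patterns <- function(object, newdata, ...) {
  x <- traj_matrix(newdata)
  d2 <- dist2_to_centers(x, object$model$centroids)
  cl <- max.col(-d2, ties.method = "first")
  unname(object$cluster_labels[as.character(cl)])
}

#' @export
plot.cmc_patterns <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if (!is.null(x$k_scores))
    graphics::plot(x$k_scores$k, x$k_scores$mean_silhouette, type = "b",
                   xlab = "k", ylab = "mean silhouette",
                   main = "k selection")
  inc <- t(vapply(x$profiles, `[[`, numeric(4), "incidence_pct"))
  rownames(inc) <- x$cluster_labels
  graphics::barplot(t(inc), beside = TRUE, legend.text = cmd_codes(),
                    ylab = "incidence (%)", main = "cluster incidences",
                    las = 2, ...)
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same points,
#' used for planted-cluster recovery checks. 1 means identical partitions
#' (up to label permutation), 0 the chance level.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("partitions differ in length")
  tab <- table(a, b)
  choose2 <- function(m) sum(m * (m - 1) / 2)
  sum_ij <- choose2(tab)
  sum_a <- choose2(rowSums(tab))
  sum_b <- choose2(colSums(tab))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
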