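# Shared fixture builders. Everything is generated in code at test time.

# n trajectories around k well-separated centers in the 4-d time space
make_blobs <- function(n_per, centers, sd = 0.02, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(j) {
    m <- matrix(rnorm(n_per * 4, mean = rep(centers[j, ], each = n_per),
                      sd = sd), n_per, 4)
    pmin(pmax(m, 1e-3), 1)
  }))
  colnames(x) <- paste0("t_", tolower(cmd_codes()))
  list(x = x, truth = rep(seq_len(nrow(centers)), each = n_per))
}

# trajectory table with given fractional times (NA = disease absent)
traj_table <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  df <- data.frame(participant_id = sprintf("P%03d", seq_len(nrow(m))))
  for (j in 1:4) {
    df[[paste0("t_", tolower(cmd_codes()[j]))]] <- ifelse(is.na(m[, j]), 1, m[, j])
    df[[paste0("occ_", tolower(cmd_codes()[j]))]] <- !is.na(m[, j])
  }
  df
}

# independent brute-force mean silhouette (plain loops, no cluster pkg)
brute_silhouette <- function(x, assign) {
  n <- nrow(x)
  dmat <- as.matrix(stats::dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(assign == assign[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(dmat[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(assign), assign[i]), function(cl)
      mean(dmat[i, assign == cl]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# small covariate table with a single informative covariate
make_separable <- function(n, seed = 1) {
  set.seed(seed)
  df <- data.frame(x = rnorm(n), noise = rnorm(n),
                   g = sample(c("u", "v", "w"), n, TRUE))
  y <- ifelse(df$x > 0.4, "A", ifelse(df$x < -0.4, "B", "C"))
  list(covariates = df, labels = y)
}

quick_cv <- function(seed = 1, outer = 5, repeats = 1, trees = 100) {
  cv_config(outer_folds = outer, repeats = repeats, inner_folds = 3,
            seed = seed,
            grid = data.frame(num_trees = trees, max_depth = 0, min_node = 5))
}
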