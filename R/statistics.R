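#' Incidence and average occurrence-time table
#'
#' For each group (e.g. sex, cluster, or a whole stratum) and each disease:
#' the number of members who developed the disease during follow-up, the
#' incidence as a percentage of the group size, and the mean and SD of the
#' fractional occurrence time among those who developed it. Percentages are
#' reported raw; use `digits` for the display-rounded column (half-up, the
#' convention of the printed tables).
#'
#' @param trajectories trajectory table.
#' @param group_labels one label per trajectory; a single value recycles.
#' @param digits decimals for the rounded percentage column.
#' @return data.frame with columns `group`, `N`, `disease`, `events`,
#'   `incidence_pct`, `incidence_pct_rounded`, `time_mean`, `time_sd`.
#' @export
incidence_table <- function(trajectories, group_labels = "all", digits = 1) {
  x <- traj_matrix(trajectories)
  occ <- traj_occ(trajectories)
  n <- nrow(x)
  if (length(group_labels) == 1) group_labels <- rep(group_labels, n)
  if (length(group_labels) != n)
    abort("need one group label per trajectory (%d vs %d)",
          length(group_labels), n)
  out <- list()
  for (g in unique(group_labels)) {
    rows <- which(group_labels == g)
    for (d in seq_len(4)) {
      hit <- rows[occ[rows, d]]
      tv <- x[hit, d]
      out[[length(out) + 1]] <- data.frame(
        group = g, N = length(rows), disease = cmd_codes()[d],
        events = length(hit),
        incidence_pct = if (length(rows)) 100 * length(hit) / length(rows) else 0,
        incidence_pct_rounded = if (length(rows))
          round_half_up(100 * length(hit) / length(rows), digits) else 0,
        time_mean = if (length(tv)) mean(tv) else NA_real_,
        time_sd = if (length(tv) > 1) sd(tv) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Participants by number of diseases developed
#'
#' Partition of the cohort by how many of the four diseases occurred during
#' follow-up (0 to 4), with percentages of the total.
#'
#' @param trajectories trajectory table.
#' @return data.frame with `n_diseases` (0..4), `n`, `pct`.
#' @export
disease_count_summary <- function(trajectories) {
  occ <- traj_occ(trajectories)
  counts <- rowSums(occ)
  tab <- table(factor(counts, levels = 0:4))
  data.frame(n_diseases = 0:4, n = as.integer(tab),
             pct = 100 * as.integer(tab) / max(1, nrow(occ)))
}

#' Group-comparison tests
#'
#' The three tests used for group differences: Pearson's chi-square
#' (uncorrected) for categorical data, one-way analysis of variance for
#' continuous data under normality, and Kruskal-Wallis (tie-corrected) as
#' its rank-based counterpart. Significance is flagged at `p < alpha`
#' (default .05). No multiple-testing adjustment is applied.
#'
#' For `test = "chi_square"`, `data` may alternatively be a pre-tabulated
#' contingency matrix, in which case `grouping` is ignored.
#'
#' @param data observations: a categorical vector (chi-square) or numeric
#'   vector (anova / kruskal_wallis), or a contingency matrix.
#' @param grouping group membership vector, `>= 2` groups.
#' @param test `"chi_square"`, `"anova"` or `"kruskal_wallis"`.
#' @param alpha significance level.
#' @return list with `statistic`, `df`, `p_value`, `significant`, `test`.
#' @export
compare_groups <- function(data, grouping = NULL,
                           test = c("chi_square", "anova", "kruskal_wallis"),
                           alpha = 0.05) {
  test <- match.arg(test)
  if (test == "chi_square") {
    tab <- if (is.matrix(data) || is.table(data)) as.matrix(data)
           else {
             check_groups(grouping)
             table(grouping, data)
           }
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      abort("contingency table has an empty row or column")
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 1))
      warning("chi-square expected cell count below 1; test may be unreliable",
              call. = FALSE)
    ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  } else {
    check_groups(grouping)
    if (!is.numeric(data)) abort("%s needs a numeric response", test)
    g <- factor(grouping)
    ht <- if (test == "anova")
      oneway.test(data ~ g, var.equal = TRUE)
    else kruskal.test(data, g)
  }
  stat <- unname(ht$statistic)
  p <- unname(ht$p.value)
  list(statistic = stat,
       df = unname(if (!is.null(ht$parameter)) ht$parameter else NA),
       p_value = p, significant = is.finite(p) && p < alpha, test = test)
}

# internal: >= 2 groups, none empty
check_groups <- function(grouping) {
  if (is.null(grouping)) abort("grouping is required")
  tab <- table(grouping)
  if (length(tab) < 2) abort("need at least 2 groups")
  if (any(tab == 0)) abort("group with zero observations")
  invisible(TRUE)
}
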