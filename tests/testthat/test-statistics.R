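# build a trajectory table with `events` occurrences of one disease among n
bulk_traj <- function(n, events, disease = "HYP", times = NULL) {
  df <- data.frame(participant_id = sprintf("P%07d", seq_len(n)))
  for (d in cmd_codes()) {
    tcol <- paste0("t_", tolower(d)); ocol <- paste0("occ_", tolower(d))
    df[[tcol]] <- 1; df[[ocol]] <- FALSE
  }
  if (events > 0) {
    if (is.null(times)) times <- rep(0.5, events)
    df[[paste0("t_", tolower(disease))]][seq_len(events)] <- times
    df[[paste0("occ_", tolower(disease))]][seq_len(events)] <- TRUE
  }
  df
}

test_that("incidence percentages reproduce printed count/N arithmetic", {
  # 1018 hypertension events among 8458 men -> 12.0%
  tab <- incidence_table(bulk_traj(8458, 1018))
  hyp <- tab[tab$disease == "HYP", ]
  expect_equal(hyp$events, 1018)
  expect_equal(hyp$incidence_pct_rounded, 12.0)
  # empty group: all zeros, times not available
  e <- incidence_table(bulk_traj(5, 0))
  expect_true(all(e$events == 0))
  expect_true(all(is.na(e$time_mean)))
})

test_that("incidence timing matches hand arithmetic on a 3-participant toy", {
  tab <- incidence_table(bulk_traj(3, 2, times = c(0.2, 0.4)))
  hyp <- tab[tab$disease == "HYP", ]
  expect_equal(hyp$events, 2)
  expect_equal(hyp$incidence_pct_rounded, 66.7)
  expect_equal(hyp$time_mean, 0.3)
  expect_equal(hyp$time_sd, sqrt(0.02), tolerance = 1e-12)  # 0.1414214
})

test_that("disease-count groups partition the cohort", {
  tt <- traj_table(c(NA, NA, NA, NA), c(NA, NA, NA, NA),
                   c(0.2, NA, NA, NA), c(0.2, 0.4, NA, NA),
                   c(0.2, 0.4, 0.6, NA))
  dc <- disease_count_summary(tt)
  expect_equal(dc$n, c(2, 1, 1, 1, 0))
  expect_equal(dc$pct, c(40, 20, 20, 20, 0))
  expect_equal(sum(dc$pct), 100)
  all_h <- disease_count_summary(traj_table(c(NA, NA, NA, NA)))
  expect_equal(all_h$pct[1], 100)
})

test_that("group tests match closed-form statistics", {
  # identical category proportions: statistic 0, p 1
  x <- rep(c("a", "b"), each = 30)
  g <- rep(c("g1", "g2"), 30)
  ht <- compare_groups(x, g, "chi_square")
  expect_equal(ht$statistic, 0)
  expect_equal(ht$p_value, 1)
  expect_false(ht$significant)

  # uncorrected Pearson on [[10,20],[20,10]]: X^2 = 20/3
  ht2 <- compare_groups(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
  expect_equal(ht2$statistic, 20 / 3, tolerance = 1e-12)

  # one-way ANOVA F on (1,2,3) vs (2,3,4): F = 1.5 with df (1, 4)
  ht3 <- compare_groups(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3),
                        "anova")
  expect_equal(ht3$statistic, 1.5, tolerance = 1e-12)
  expect_equal(unname(ht3$df), c(1, 4))

  # Kruskal-Wallis on identical samples: statistic 0
  ht4 <- compare_groups(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3),
                        "kruskal_wallis")
  expect_equal(ht4$statistic, 0, tolerance = 1e-12)
})

test_that("group tests validate their inputs", {
  expect_error(compare_groups(c(1, 2), c("a", "a"), "anova"), "2 groups")
  expect_error(compare_groups(c("x", "y"), NULL, "chi_square"), "required")
  expect_warning(compare_groups(matrix(c(1, 0, 0, 1), 2)), "below 1")
  expect_error(compare_groups(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "empty row or column")
})

test_that("display rounding is half away from zero", {
  expect_equal(cmctraj:::round_half_up(0.05, 1), 0.1)
  expect_equal(cmctraj:::round_half_up(12.25, 1), 12.3)
  expect_equal(cmctraj:::round_half_up(-0.05, 1), -0.1)
  expect_equal(cmctraj:::round_half_up(66.666, 1), 66.7)
})
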