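test_that("fractional-time encoding matches the worked example and edge cases", {
  tr <- encode_trajectory(data.frame(disease = c("HYP", "DM"), time = c(2, 4)),
                          follow_up = 10)
  expect_equal(unname(tr$times), c(0.2, 0.4, 1, 1))
  expect_equal(unname(tr$occurred), c(TRUE, TRUE, FALSE, FALSE))

  none <- encode_trajectory(NULL, follow_up = 10)
  expect_equal(unname(none$times), rep(1, 4))
  expect_false(any(none$occurred))

  stk <- encode_trajectory(data.frame(disease = "STK", time = 3), follow_up = 12)
  expect_equal(unname(stk$times), c(1, 1, 1, 0.25))

  # event at exactly end of follow-up: t = 1 but occurrence retained
  edge <- encode_trajectory(data.frame(disease = "HD", time = 10), follow_up = 10)
  expect_equal(unname(edge$times[3]), 1)
  expect_true(edge$occurred[["HD"]])
})

test_that("encoding rejects invalid events", {
  expect_error(encode_trajectory(data.frame(disease = c("HYP", "HYP"),
                                            time = c(1, 2)), 10), "HYP")
  expect_error(encode_trajectory(data.frame(disease = "DM", time = 0), 10),
               "baseline")
  expect_error(encode_trajectory(data.frame(disease = "DM", time = 11), 10),
               "beyond")
  expect_error(encode_trajectory(NULL, follow_up = 0), "positive")
  expect_error(encode_trajectory(data.frame(disease = "XX", time = 1), 10),
               "unknown")
})

test_that("encoding round-trips event times within 1e-12 relative error", {
  set.seed(11)
  for (i in 1:50) {
    fu <- runif(1, 5, 20)
    k <- sample(0:4, 1)
    dis <- sample(cmd_codes(), k)
    times <- runif(k, 1e-6, fu)
    ev <- if (k > 0) data.frame(disease = dis, time = times) else NULL
    tr <- encode_trajectory(ev, fu)
    if (k > 0) {
      back <- tr$times[dis] * fu
      expect_lt(max(abs(back - times) / times), 1e-12)
    }
    expect_equal(sum(tr$occurred), k)
  }
})

test_that("first_disease picks the earliest occurrence with canonical tie-break", {
  expect_equal(first_disease(c(0.2, 0.4, 1, 1))$disease, "HYP")
  expect_null(first_disease(c(1, 1, 1, 1)))
  tie <- first_disease(c(0.3, 0.3, 1, 1))
  expect_equal(tie$disease, "HYP")
  expect_true(tie$tie)
  expect_false(first_disease(c(0.2, 0.4, 1, 1))$tie)
})

test_that("pattern_string orders diseases by time and names the empty pattern", {
  expect_equal(pattern_string(c(0.43, 0.41, 1, 1)), "DM->HYP")
  expect_equal(pattern_string(c(1, 1, 1, 1)), "None Disease")
  expect_equal(pattern_string(c(0.3, 0.3, 0.3, 1)), "HYP->DM->HD")
})

test_that("pattern_string and first_disease agree and count occurrences", {
  set.seed(12)
  for (i in 1:40) {
    t <- runif(4, 0.05, 1)
    occ <- runif(4) < 0.5
    t[!occ] <- 1
    t[occ] <- pmin(t[occ], 0.999)
    ps <- pattern_string(t)
    fd <- first_disease(t)
    if (!any(t < 1)) {
      expect_equal(ps, "None Disease")
      expect_null(fd)
    } else {
      toks <- strsplit(ps, "->", fixed = TRUE)[[1]]
      expect_length(toks, sum(t < 1))
      expect_equal(toks[1], fd$disease)
    }
  }
})

test_that("cohort encoding and CSV round trip preserve the tables", {
  ev <- data.frame(participant_id = c("a", "b", "c"), sex = "female",
                   follow_up_years = c(10, 10, 12),
                   hyp_years = c(2, NA, NA), dm_years = c(4, NA, NA),
                   hd_years = c(NA, NA, 3), stk_years = c(NA, NA, NA))
  tj <- encode_cohort(ev)
  expect_equal(tj$t_hyp, c(0.2, 1, 1))
  expect_equal(tj$t_hd, c(1, 1, 0.25))
  expect_equal(tj$occ_dm, c(TRUE, FALSE, FALSE))

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_events_table(ev, f1)
  expect_equal(read_events_table(f1)$hyp_years, ev$hyp_years)
  write_trajectory_table(tj, f2)
  back <- read_trajectory_table(f2)
  expect_equal(back$t_stk, tj$t_stk)
  expect_error(encode_cohort(ev[, -3]), "missing column")
  ev$dm_years[2] <- 99
  expect_error(encode_cohort(ev), "outside")
})
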