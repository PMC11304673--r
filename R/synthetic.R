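#' Specification of one latent temporal pattern
#'
#' A pattern is the generative description of one cluster of CMC
#' trajectories: its mixing proportion, which disease strikes first and in
#' which window of the (fractional) follow-up, which further diseases may
#' follow and how soon, and the per-disease incidences.
#'
#' For a pattern with a designated `first_disease`, that disease occurs in
#' every member (incidence forced to 1) with occurrence fraction drawn
#' uniformly from `first_window`; each other disease occurs independently
#' with its incidence probability, at a strictly later fraction
#' `t_first + U(0, min(secondary_gap_max, 1 - t_first))`. A pattern without
#' a first disease (Healthy) draws each disease independently with its
#' (small) incidence at a time uniform in `first_window`.
#'
#' @param label pattern name (e.g. `"EarlyHyp"`).
#' @param mixing_proportion prior membership probability in `[0, 1]`.
#' @param incidence named probabilities for `HYP`, `DM`, `HD`, `STK`.
#' @param first_disease disease code or `NA` (no designated first disease).
#' @param first_window length-2 numeric `(lo, hi]`, a sub-interval of
#'   `(0, 1]`.
#' @param secondary_gap_max maximum fraction-of-follow-up delay between the
#'   first disease and any later one; default 1 (uniform on the rest of
#'   follow-up).
#' @return a `pattern_spec` list.
#' @export
pattern_spec <- function(label, mixing_proportion, incidence,
                         first_disease = NA, first_window = c(0, 1),
                         secondary_gap_max = 1) {
  if (mixing_proportion < 0 || mixing_proportion > 1)
    abort("mixing_proportion must lie in [0, 1]")
  inc <- setNames(rep(0, 4), cmd_codes())
  inc[names(incidence)] <- unlist(incidence)
  if (any(inc < 0 | inc > 1)) abort("incidences must lie in [0, 1]")
  if (!is.na(first_disease)) {
    cmd_index(first_disease)
    inc[first_disease] <- 1
  }
  fw <- as.numeric(first_window)
  if (length(fw) != 2 || fw[1] < 0 || fw[2] > 1 || fw[1] >= fw[2])
    abort("first_window must be (lo, hi] with 0 <= lo < hi <= 1")
  structure(list(label = as.character(label),
                 mixing_proportion = mixing_proportion,
                 incidence = inc,
                 first_disease = if (is.na(first_disease)) NA_character_ else first_disease,
                 first_window = fw,
                 secondary_gap_max = secondary_gap_max),
            class = "pattern_spec")
}

#' Specification of one baseline covariate
#'
#' Describes how a covariate is generated and how it shifts pattern
#' membership. Continuous covariates are Gaussian; their `effects` entry for
#' a pattern is the additive shift of that pattern's membership log-odds per
#' standard deviation of the covariate. Categorical covariates are sampled
#' from `probs` over `levels`; `effects` is then a list of per-level
#' log-odds shifts per pattern.
#'
#' @param name covariate name.
#' @param kind `"continuous"` or `"categorical"`.
#' @param levels,probs category labels and their marginal probabilities
#'   (categorical only; `probs` defaults to uniform).
#' @param mean,sd Gaussian parameters (continuous only).
#' @param effects named list: pattern label -> numeric shift (continuous,
#'   per SD) or named numeric vector over levels (categorical). Patterns not
#'   named get shift 0.
#' @return a `covariate_spec` list.
#' @export
covariate_spec <- function(name, kind = c("continuous", "categorical"),
                           levels = NULL, probs = NULL, mean = 0, sd = 1,
                           effects = list()) {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    if (is.null(levels) || length(levels) < 2)
      abort("categorical covariate '%s' needs >= 2 levels", name)
    if (is.null(probs)) probs <- rep(1 / length(levels), length(levels))
    if (length(probs) != length(levels) || any(probs < 0))
      abort("probs must be non-negative and match levels for '%s'", name)
    probs <- probs / sum(probs)
  } else if (sd <= 0) abort("sd must be > 0 for '%s'", name)
  if (!all(vapply(effects, function(e) all(is.finite(unlist(e))), TRUE)))
    abort("effects for '%s' must be finite", name)
  structure(list(name = name, kind = kind, levels = levels, probs = probs,
                 mean = mean, sd = sd, effects = effects),
            class = "covariate_spec")
}

#' Full generative specification of a synthetic cohort
#'
#' Bundles the pattern mixture, the covariate schema with membership
#' effects, the missingness rate and the follow-up distribution under one
#' master seed. Substream seeds for each generation stage are derived with
#' [derive_seed()], so stages are individually re-runnable.
#'
#' @param n number of participants (`>= 0`).
#' @param cohort_dialect `"uk"` or `"brasil"` (covariate schema family).
#' @param sex `"male"` or `"female"`.
#' @param seed master integer seed.
#' @param pattern_specs list of [pattern_spec()]; mixing proportions must
#'   sum to 1 (tolerance 1e-9).
#' @param covariate_specs list of [covariate_spec()].
#' @param missingness_rate MCAR cell-masking probability for covariates.
#' @param follow_up_mean,follow_up_sd follow-up duration (years), Gaussian,
#'   truncated below at 1 year.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n, cohort_dialect = c("uk", "brasil"),
                             sex = c("male", "female"), seed = 1,
                             pattern_specs, covariate_specs = list(),
                             missingness_rate = 0,
                             follow_up_mean = 10.9, follow_up_sd = 0.6) {
  cohort_dialect <- match.arg(cohort_dialect)
  sex <- match.arg(sex)
  if (n < 0) abort("n must be >= 0")
  if (missingness_rate < 0 || missingness_rate > 1)
    abort("missingness_rate must lie in [0, 1]")
  if (!length(pattern_specs)) abort("at least one pattern_spec required")
  mix <- vapply(pattern_specs, `[[`, 0, "mixing_proportion")
  if (abs(sum(mix) - 1) > 1e-9)
    abort("mixing proportions sum to %.12f, not 1", sum(mix))
  labs <- vapply(pattern_specs, `[[`, "", "label")
  if (anyDuplicated(labs)) abort("duplicate pattern labels")
  structure(list(n = as.integer(n), cohort_dialect = cohort_dialect,
                 sex = sex, seed = as.integer(seed),
                 pattern_specs = setNames(pattern_specs, labs),
                 covariate_specs = covariate_specs,
                 missingness_rate = missingness_rate,
                 follow_up_mean = follow_up_mean,
                 follow_up_sd = follow_up_sd),
            class = "synthetic_config")
}

#' Generate a synthetic cohort
#'
#' Draws, in order: baseline covariates from their marginals; pattern
#' membership from a per-participant softmax over
#' `log(mixing proportion) + covariate effects`; follow-up durations; and
#' disease occurrence fractions within each participant's pattern (see
#' [pattern_spec()]). Covariate missingness is then injected MCAR at the
#' configured rate. Fully reproducible given the config seed.
#'
#' @param config a [synthetic_config()].
#' @return list with `covariates` (data.frame: participant_id, sex,
#'   follow_up_years, covariates), `trajectories` (trajectory table, see
#'   [encode_cohort()]), `events` (participant-events table) and `labels`
#'   (character vector of true pattern labels).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n
  specs <- config$pattern_specs
  labs <- names(specs)
  K <- length(specs)
  empty <- function() {
    list(covariates = data.frame(participant_id = character(0)),
         trajectories = data.frame(participant_id = character(0)),
         events = data.frame(participant_id = character(0)),
         labels = character(0))
  }
  if (n == 0) return(empty())
  ids <- sprintf("P%06d", seq_len(n))

  # stage 1: covariates
  set.seed(derive_seed(config$seed, 1L))
  cov_df <- data.frame(participant_id = ids, sex = config$sex,
                       stringsAsFactors = FALSE)
  logodds <- matrix(rep(log(pmax(vapply(specs, `[[`, 0, "mixing_proportion"),
                                 1e-12)), each = n), n, K,
                    dimnames = list(NULL, labs))
  for (cs in config$covariate_specs) {
    if (cs$kind == "continuous") {
      x <- rnorm(n, cs$mean, cs$sd)
      z <- (x - cs$mean) / cs$sd
      for (p in names(cs$effects))
        if (p %in% labs) logodds[, p] <- logodds[, p] + cs$effects[[p]] * z
    } else {
      x <- sample(cs$levels, n, replace = TRUE, prob = cs$probs)
      for (p in names(cs$effects)) {
        if (!p %in% labs) next
        ev <- cs$effects[[p]]
        shift <- ifelse(x %in% names(ev), unlist(ev)[x], 0)
        shift[is.na(shift)] <- 0
        logodds[, p] <- logodds[, p] + shift
      }
    }
    cov_df[[cs$name]] <- x
  }

  # stage 2: membership via per-row softmax (inverse-CDF draw)
  set.seed(derive_seed(config$seed, 2L))
  pr <- exp(logodds - apply(logodds, 1, max))
  pr <- pr / rowSums(pr)
  u <- runif(n)
  cum <- t(apply(pr, 1, cumsum))
  memb <- 1L + rowSums(u > cum)
  memb[memb > K] <- K
  labels <- labs[memb]

  # stage 3: follow-up durations
  set.seed(derive_seed(config$seed, 3L))
  fu <- pmax(1, rnorm(n, config$follow_up_mean, config$follow_up_sd))

  # stage 4: occurrence fractions within pattern
  set.seed(derive_seed(config$seed, 4L))
  tfrac <- matrix(NA_real_, n, 4, dimnames = list(NULL, cmd_codes()))
  for (k in seq_len(K)) {
    sp <- specs[[k]]
    rows <- which(memb == k)
    if (!length(rows)) next
    m <- length(rows)
    if (!is.na(sp$first_disease)) {
      t1 <- sp$first_window[1] +
        runif(m) * (sp$first_window[2] - sp$first_window[1])
      tfrac[rows, sp$first_disease] <- t1
      for (d in setdiff(cmd_codes(), sp$first_disease)) {
        hit <- runif(m) < sp$incidence[d]
        gap <- pmin(sp$secondary_gap_max, 1 - t1)
        td <- t1 + runif(m) * gap
        tfrac[rows[hit], d] <- pmin(td[hit], 1)
      }
    } else {
      for (d in cmd_codes()) {
        hit <- runif(m) < sp$incidence[d]
        td <- sp$first_window[1] +
          runif(m) * (sp$first_window[2] - sp$first_window[1])
        tfrac[rows[hit], d] <- td[hit]
      }
    }
  }

  events <- data.frame(participant_id = ids, sex = config$sex,
                       follow_up_years = fu, stringsAsFactors = FALSE)
  for (j in seq_len(4)) events[[event_cols()[j]]] <- tfrac[, j] * fu
  trajectories <- encode_cohort(events)
  cov_df$follow_up_years <- fu
  cov_df <- cov_df[, c("participant_id", "sex", "follow_up_years",
                       setdiff(names(cov_df),
                               c("participant_id", "sex", "follow_up_years")))]
  if (config$missingness_rate > 0)
    cov_df <- inject_missingness(cov_df, config$missingness_rate,
                                 derive_seed(config$seed, 5L))
  list(covariates = cov_df, trajectories = trajectories, events = events,
       labels = labels)
}

#' Inject MCAR missingness into covariate cells
#'
#' Each maskable cell is independently set to `NA` with probability `rate`.
#' Identifier, sex, follow-up and outcome columns (event years, fractional
#' times, occurrence flags) are never masked.
#'
#' @param table data.frame.
#' @param rate masking probability in `[0, 1]`.
#' @param seed integer seed.
#' @return the table with cells masked.
#' @export
inject_missingness <- function(table, rate, seed = 1) {
  if (rate < 0 || rate > 1) abort("rate must lie in [0, 1]")
  if (rate == 0) return(table)
  protected <- c("participant_id", "sex", "follow_up_years",
                 event_cols(), time_cols(), occ_cols())
  maskable <- setdiff(names(table), protected)
  set.seed(seed)
  for (cn in maskable) {
    hit <- runif(nrow(table)) < rate
    table[[cn]][hit] <- NA
  }
  table
}

# ---- frozen study-emulation configurations -------------------------------

# Cluster sizes per stratum: EarlyHyp, FirstDM, FirstHD, Healthy, LateHyp.
emulation_sizes <- function(cohort_dialect, sex) {
  key <- paste(cohort_dialect, sex, sep = "_")
  sizes <- list(
    uk_male       = c(EarlyHyp = 370, FirstDM = 126, FirstHD = 199,
                      Healthy = 7313, LateHyp = 450),
    uk_female     = c(EarlyHyp = 241, FirstDM = 101, FirstHD = 71,
                      Healthy = 8490, LateHyp = 339),
    brasil_male   = c(EarlyHyp = 415, FirstDM = 81, FirstHD = 88,
                      Healthy = 1981, LateHyp = 305),
    brasil_female = c(EarlyHyp = 689, FirstDM = 167, FirstHD = 100,
                      Healthy = 2837, LateHyp = 499))
  if (!key %in% names(sizes)) abort("unknown stratum %s", key)
  sizes[[key]]
}

#' Frozen study-emulation configuration for one stratum
#'
#' Returns a [synthetic_config()] whose mixing proportions equal the
#' published per-stratum cluster-size fractions and whose time windows
#' follow the pattern definitions: EarlyHyp hypertension strikes within the
#' first 40% of follow-up, LateHyp between 40 and 80%, FirstDM and FirstHD
#' within stratum-specific early windows, and Healthy members mostly stay
#' disease-free with rare late isolated events. Secondary diseases
#' strike uniformly on the remainder of follow-up after the first disease.
#'
#' Covariate schemas follow the two cohort dialects (UK-style with Townsend
#' deprivation, past-smoking and coffee-type variables; Brazilian-style with
#' maternal education, family-history and income variables) plus the shared
#' anthropometric/clinical continuous block. Their means, SDs and default
#' membership effects are documented generator conventions, not published
#' values.
#'
#' @param cohort_dialect `"uk"` or `"brasil"`.
#' @param sex `"male"` or `"female"`.
#' @param n cohort size; defaults to the stratum's published size.
#' @param seed master seed.
#' @param missingness_rate MCAR covariate missingness (default 0.02).
#' @return a `synthetic_config`.
#' @export
study_emulation_config <- function(cohort_dialect = c("uk", "brasil"),
                                   sex = c("male", "female"),
                                   n = NULL, seed = 1,
                                   missingness_rate = 0.02) {
  cohort_dialect <- match.arg(cohort_dialect)
  sex <- match.arg(sex)
  sizes <- emulation_sizes(cohort_dialect, sex)
  if (is.null(n)) n <- sum(sizes)
  mix <- sizes / sum(sizes)
  uk <- cohort_dialect == "uk"

  # stratum-specific first-disease windows for the DM- and HD-first patterns
  dm_win <- if (!uk && sex == "male") c(0.10, 0.70)
            else if (!uk)             c(0.02, 0.60)
            else                      c(0.02, 0.70)
  hd_win <- if (uk && sex == "male")  c(0.02, 0.70) else c(0.02, 0.60)

  # Healthy: rare late isolated events; per-disease probabilities chosen so
  # the disease-free fraction matches the stratum's published share.
  healthy_inc <- switch(paste(cohort_dialect, sex, sep = "_"),
    uk_male       = c(HYP = 0.005, DM = 0.004, HD = 0.005, STK = 0.002),
    uk_female     = c(HYP = 0.0025, DM = 0.0025, HD = 0.002, STK = 0.001),
    brasil_male   = c(HYP = 0.055, DM = 0.030, HD = 0.027, STK = 0.010),
    brasil_female = c(HYP = 0.055, DM = 0.025, HD = 0.015, STK = 0.009))

  patterns <- list(
    pattern_spec("EarlyHyp", mix[["EarlyHyp"]],
                 incidence = c(DM = 0.04, HD = 0.03, STK = 0.005),
                 first_disease = "HYP", first_window = c(0.02, 0.40)),
    pattern_spec("FirstDM", mix[["FirstDM"]],
                 incidence = c(HYP = 0.50, HD = 0.02, STK = 0.01),
                 first_disease = "DM", first_window = dm_win),
    pattern_spec("FirstHD", mix[["FirstHD"]],
                 incidence = c(HYP = 0.45, DM = 0.02, STK = 0.01),
                 first_disease = "HD", first_window = hd_win),
    pattern_spec("Healthy", mix[["Healthy"]],
                 incidence = healthy_inc,
                 first_disease = NA, first_window = c(0.60, 1.0)),
    pattern_spec("LateHyp", mix[["LateHyp"]],
                 incidence = c(DM = 0.04, HD = 0.035, STK = 0.005),
                 first_disease = "HYP", first_window = c(0.40, 0.80)))

  synthetic_config(n = n, cohort_dialect = cohort_dialect, sex = sex,
                   seed = seed, pattern_specs = patterns,
                   covariate_specs = default_covariates(cohort_dialect),
                   missingness_rate = missingness_rate,
                   follow_up_mean = if (uk) 10.9 else 12.3,
                   follow_up_sd = if (uk) 0.6 else 0.7)
}

#' Default covariate schema for a cohort dialect
#'
#' The shared clinical/anthropometric continuous block plus the
#' dialect-specific socioeconomic and lifestyle variables. Means, SDs,
#' level frequencies and membership effects are plausible conventions for a
#' middle-aged cohort, exposed here so callers can replace or extend them.
#'
#' @param cohort_dialect `"uk"` or `"brasil"`.
#' @param effect_size reference log-odds shift used by the default effects.
#' @return list of [covariate_spec()].
#' @export
default_covariates <- function(cohort_dialect = c("uk", "brasil"),
                               effect_size = 0.5) {
  cohort_dialect <- match.arg(cohort_dialect)
  e <- effect_size
  uk <- cohort_dialect == "uk"
  common <- list(
    covariate_spec("age", "continuous", mean = if (uk) 55.1 else 50.8,
                   sd = if (uk) 7.6 else 7.4,
                   effects = list(EarlyHyp = e, LateHyp = e, FirstHD = e,
                                  FirstDM = 0.6 * e)),
    covariate_spec("bmi", "continuous", mean = 27, sd = 4.5,
                   effects = list(FirstDM = e, EarlyHyp = 0.5 * e)),
    covariate_spec("waist_hip", "continuous", mean = 0.88, sd = 0.09,
                   effects = list(FirstDM = 0.8 * e)),
    covariate_spec("sbp", "continuous", mean = 128, sd = 15,
                   effects = list(EarlyHyp = e, LateHyp = 0.8 * e)),
    covariate_spec("dbp", "continuous", mean = 79, sd = 10,
                   effects = list(EarlyHyp = 0.8 * e, LateHyp = 0.6 * e)),
    covariate_spec("heart_rate", "continuous", mean = 69, sd = 11),
    covariate_spec("cholesterol", "continuous", mean = 5.6, sd = 1.1,
                   effects = list(FirstHD = 0.5 * e)),
    covariate_spec("glucose", "continuous", mean = 5.1, sd = 1.0,
                   effects = list(FirstDM = 1.2 * e)),
    covariate_spec("ldl", "continuous", mean = 3.5, sd = 0.9,
                   effects = list(FirstHD = 0.5 * e)),
    covariate_spec("hdl", "continuous", mean = 1.45, sd = 0.38,
                   effects = list(FirstHD = -0.5 * e)),
    covariate_spec("hba1c", "continuous", mean = 36, sd = 6,
                   effects = list(FirstDM = e)),
    covariate_spec("triglycerides", "continuous", mean = 1.7, sd = 0.9,
                   effects = list(FirstDM = 0.4 * e)))
  dialect <- if (uk) list(
    covariate_spec("education", "categorical",
                   levels = c("None", "Sec", "Uni"),
                   probs = c(0.17, 0.45, 0.38),
                   effects = list(Healthy = c(Uni = 0.5 * e),
                                  FirstDM = c(Sec = 0.5 * e))),
    covariate_spec("ethnicity", "categorical",
                   levels = c("white", "not_white"), probs = c(0.91, 0.09)),
    covariate_spec("smoking", "categorical",
                   levels = c("never", "past", "current"),
                   probs = c(0.55, 0.34, 0.11),
                   effects = list(EarlyHyp = c(current = e),
                                  LateHyp = c(current = 0.8 * e),
                                  FirstHD = c(current = e))),
    covariate_spec("past_smoking", "categorical",
                   levels = c("never", "tried_twice", "occasionally",
                              "most_days"),
                   probs = c(0.45, 0.20, 0.15, 0.20),
                   effects = list(FirstHD = c(most_days = e))),
    covariate_spec("alcohol", "categorical",
                   levels = c("never", "past", "current"),
                   probs = c(0.04, 0.03, 0.93)),
    covariate_spec("sleep_problem", "categorical",
                   levels = c("never_rarely", "sometimes", "usually"),
                   probs = c(0.24, 0.47, 0.29),
                   effects = list(EarlyHyp = c(usually = 0.5 * e))),
    covariate_spec("coffee", "categorical", levels = c("yes", "no"),
                   probs = c(0.78, 0.22)),
    covariate_spec("live_with_others", "categorical",
                   levels = c("yes", "no"), probs = c(0.81, 0.19)),
    covariate_spec("townsend", "continuous", mean = -1.3, sd = 2.9,
                   effects = list(Healthy = -0.3 * e)),
    covariate_spec("physical_activity_min", "continuous", mean = 45, sd = 35,
                   effects = list(Healthy = 0.3 * e)),
    covariate_spec("fruit_intake", "continuous", mean = 3, sd = 2),
    covariate_spec("vegetable_intake", "continuous", mean = 4.8, sd = 2.3)
  ) else list(
    covariate_spec("education", "categorical",
                   levels = c("Ele", "Sec", "Uni"),
                   probs = c(0.12, 0.35, 0.53),
                   effects = list(Healthy = c(Uni = 0.6 * e),
                                  LateHyp = c(Uni = -0.5 * e),
                                  FirstHD = c(Uni = -0.5 * e))),
    covariate_spec("ethnicity", "categorical",
                   levels = c("white", "not_white"), probs = c(0.57, 0.43),
                   effects = list(Healthy = c(white = 0.4 * e),
                                  EarlyHyp = c(white = -0.4 * e))),
    covariate_spec("smoking", "categorical",
                   levels = c("never", "past", "current"),
                   probs = c(0.57, 0.30, 0.13),
                   effects = list(FirstHD = c(never = -e),
                                  Healthy = c(never = 0.4 * e))),
    covariate_spec("alcohol", "categorical",
                   levels = c("not_consuming", "moderate", "excessive"),
                   probs = c(0.28, 0.62, 0.10),
                   effects = list(EarlyHyp = c(not_consuming = 0.5 * e),
                                  FirstHD = c(not_consuming = 0.5 * e))),
    covariate_spec("physical_activity", "categorical",
                   levels = c("weak", "moderate", "strong"),
                   probs = c(0.65, 0.22, 0.13),
                   effects = list(FirstHD = c(weak = 0.4 * e,
                                              moderate = -0.4 * e))),
    covariate_spec("sleep_problem", "categorical",
                   levels = c("no", "yes"), probs = c(0.62, 0.38)),
    covariate_spec("coffee", "categorical",
                   levels = c("no", "yes_caffeinated", "yes_decaffeinated"),
                   probs = c(0.16, 0.77, 0.07),
                   effects = list(EarlyHyp = c(yes_caffeinated = 0.4 * e))),
    covariate_spec("mother_edu", "categorical",
                   levels = c("Never", "ElI", "ElC", "Sec", "Uni"),
                   probs = c(0.10, 0.32, 0.24, 0.20, 0.14)),
    covariate_spec("marital", "categorical",
                   levels = c("not_single", "single"), probs = c(0.73, 0.27)),
    covariate_spec("income", "continuous", mean = 1200, sd = 900,
                   effects = list(Healthy = 0.3 * e)),
    covariate_spec("diab_family", "categorical", levels = c("no", "yes"),
                   probs = c(0.62, 0.38),
                   effects = list(FirstDM = c(yes = e))),
    covariate_spec("hyp_family", "categorical", levels = c("no", "yes"),
                   probs = c(0.45, 0.55),
                   effects = list(EarlyHyp = c(yes = 0.5 * e))),
    covariate_spec("heartdis_family", "categorical", levels = c("no", "yes"),
                   probs = c(0.70, 0.30),
                   effects = list(FirstHD = c(yes = 0.5 * e))),
    covariate_spec("stroke_family", "categorical", levels = c("no", "yes"),
                   probs = c(0.78, 0.22)),
    covariate_spec("suddeath_family", "categorical", levels = c("no", "yes"),
                   probs = c(0.85, 0.15)),
    covariate_spec("fruit_intake", "categorical",
                   levels = c("high", "daily", "weekly", "rarely"),
                   probs = c(0.30, 0.33, 0.22, 0.15)),
    covariate_spec("vegetable_intake", "categorical",
                   levels = c("high", "daily", "weekly", "rarely"),
                   probs = c(0.28, 0.37, 0.22, 0.13)))
  c(common, dialect)
}

#' Read / write a synthetic-cohort configuration as YAML
#'
#' Serializes a [synthetic_config()] (including pattern and covariate
#' specs) to a YAML file and back.
#'
#' @param config a `synthetic_config`.
#' @param path file path.
#' @return `write_synthetic_config` returns `path` invisibly;
#'   `read_synthetic_config` returns the reconstructed `synthetic_config`.
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  raw <- unclass(config)
  raw$pattern_specs <- lapply(config$pattern_specs, function(p) {
    p <- unclass(p)
    p$incidence <- as.list(p$incidence)
    p
  })
  raw$covariate_specs <- lapply(config$covariate_specs, function(cs) {
    cs <- unclass(cs)
    cs$effects <- lapply(cs$effects, as.list)
    cs
  })
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  patterns <- lapply(raw$pattern_specs, function(p)
    pattern_spec(p$label, p$mixing_proportion, unlist(p$incidence),
                 first_disease = if (is.null(p$first_disease)) NA else p$first_disease,
                 first_window = unlist(p$first_window),
                 secondary_gap_max = p$secondary_gap_max))
  covs <- lapply(raw$covariate_specs, function(cs)
    covariate_spec(cs$name, cs$kind, levels = unlist(cs$levels),
                   probs = unlist(cs$probs),
                   mean = if (is.null(cs$mean)) 0 else cs$mean,
                   sd = if (is.null(cs$sd)) 1 else cs$sd,
                   effects = lapply(cs$effects, unlist)))
  synthetic_config(n = raw$n, cohort_dialect = raw$cohort_dialect,
                   sex = raw$sex, seed = raw$seed, pattern_specs = patterns,
                   covariate_specs = covs,
                   missingness_rate = raw$missingness_rate,
                   follow_up_mean = raw$follow_up_mean,
                   follow_up_sd = raw$follow_up_sd)
}
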