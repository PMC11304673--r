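#' Canonical cardiometabolic disease codes
#'
#' The four cardiometabolic diseases tracked along the continuum, in the
#' fixed canonical tuple order: hypertension (`HYP`), diabetes mellitus
#' (`DM`), heart disease (`HD`: angina, myocardial infarction or heart
#' failure), and stroke (`STK`). All 4-tuples, incidence tables and tie
#' breaks use this order.
#'
#' @return character vector of the four codes in canonical order.
#' @export
cmd_codes <- function() c("HYP", "DM", "HD", "STK")

# internal: validate a disease code, return its canonical index
cmd_index <- function(code) {
  i <- match(code, cmd_codes())
  if (anyNA(i)) abort("unknown disease code(s): %s",
                      paste(code[is.na(i)], collapse = ", "))
  i
}

#' Encode a participant's disease events as a fractional-time 4-tuple
#'
#' A participant's cardiometabolic-continuum (CMC) trajectory is the 4-tuple
#' `(t_HYP, t_DM, t_HD, t_STK)` where each component is the disease's
#' occurrence time divided by the follow-up duration, so `0 < t_i <= 1`,
#' with `t_i = 1` when the disease did not occur during follow-up. A
#' participant with hypertension after 2 years and diabetes after 4 years of
#' a 10-year follow-up encodes to `(0.2, 0.4, 1, 1)`.
#'
#' Events are given as (disease, time) pairs. Baseline-prevalent disease
#' (time 0) is an exclusion criterion upstream and is rejected here, as are
#' times beyond follow-up. An event at exactly the end of follow-up encodes
#' to `t_i = 1` but keeps `occurred = TRUE`, so profiling does not conflate
#' it with absence; clustering uses the times only.
#'
#' @param events a data.frame with columns `disease` (codes from
#'   [cmd_codes()]) and `time` (years from baseline), one row per event; or
#'   `NULL` / zero rows for a disease-free participant.
#' @param follow_up follow-up duration in years, `> 0`.
#' @param participant_id optional identifier carried through.
#' @return an object of class `cmc_trajectory`: a list with `participant_id`,
#'   `times` (named length-4 numeric), `occurred` (named length-4 logical)
#'   and `follow_up`.
#' @examples
#' tr <- encode_trajectory(data.frame(disease = c("HYP", "DM"), time = c(2, 4)),
#'                         follow_up = 10)
#' tr$times  # 0.2 0.4 1.0 1.0
#' @export
encode_trajectory <- function(events, follow_up, participant_id = NA_character_) {
  if (!is.numeric(follow_up) || length(follow_up) != 1 || is.na(follow_up) ||
      follow_up <= 0)
    abort("follow_up must be a single positive number of years")
  times <- setNames(rep(1, 4), cmd_codes())
  occurred <- setNames(rep(FALSE, 4), cmd_codes())
  if (!is.null(events) && nrow(as.data.frame(events)) > 0) {
    events <- as.data.frame(events)
    if (!all(c("disease", "time") %in% names(events)))
      abort("events needs columns 'disease' and 'time'")
    idx <- cmd_index(as.character(events$disease))
    if (anyDuplicated(idx))
      abort("duplicate event for disease %s",
            paste(unique(cmd_codes()[idx[duplicated(idx)]]), collapse = ", "))
    tt <- as.numeric(events$time)
    if (any(is.na(tt)) || any(tt <= 0))
      abort("event times must be > 0 (baseline-prevalent disease is excluded)")
    if (any(tt > follow_up))
      abort("event time beyond follow-up (%g > %g years)",
            max(tt), follow_up)
    times[idx] <- tt / follow_up
    occurred[idx] <- TRUE
  }
  structure(list(participant_id = as.character(participant_id),
                 times = times, occurred = occurred, follow_up = follow_up),
            class = "cmc_trajectory")
}

#' @export
print.cmc_trajectory <- function(x, ...) {
  cat("CMC trajectory", if (!is.na(x$participant_id)) x$participant_id else "",
      "\n  4-tuple: (", paste(signif(x$times, 4), collapse = ", "),
      ")\n  occurred:", paste(cmd_codes()[x$occurred], collapse = " "),
      "\n  follow-up:", x$follow_up, "years\n")
  invisible(x)
}

# internal: accept a cmc_trajectory, a length-4 times vector, or a 1-row
# slice of a trajectory table; return list(times, occurred)
as_traj_pair <- function(traj) {
  if (inherits(traj, "cmc_trajectory"))
    return(list(times = traj$times, occurred = traj$occurred))
  if (is.numeric(traj) && length(traj) == 4)
    return(list(times = setNames(as.numeric(traj), cmd_codes()),
                occurred = setNames(traj < 1, cmd_codes())))
  abort("expected a cmc_trajectory or a length-4 numeric 4-tuple")
}

#' First disease on the continuum
#'
#' Returns the disease with the smallest fractional occurrence time among
#' those that occurred. Ties at identical times are broken by canonical
#' disease order (HYP < DM < HD < STK) and flagged, since the data carry no
#' within-time ordering.
#'
#' @param traj a `cmc_trajectory`, or a length-4 numeric 4-tuple (times
#'   `< 1` are then taken as occurrences).
#' @return `NULL` if no disease occurred; otherwise a list with `disease`
#'   (code) and `tie` (logical: was the minimum time shared).
#' @export
first_disease <- function(traj) {
  p <- as_traj_pair(traj)
  if (!any(p$occurred)) return(NULL)
  t_occ <- ifelse(p$occurred, p$times, Inf)
  i <- which.min(t_occ)  # which.min takes the first index on ties
  list(disease = cmd_codes()[i], tie = sum(t_occ == t_occ[i]) > 1)
}

#' Ordered trajectory pattern string
#'
#' The occurred diseases sorted by ascending occurrence time (canonical
#' order on ties), joined by an arrow, e.g. `"DM->HYP"` for diabetes
#' followed by hypertension. A disease-free trajectory yields
#' `"None Disease"`.
#'
#' @inheritParams first_disease
#' @param arrow separator between successive diseases.
#' @return a single pattern string.
#' @export
pattern_string <- function(traj, arrow = "->") {
  p <- as_traj_pair(traj)
  if (!any(p$occurred)) return("None Disease")
  idx <- which(p$occurred)
  idx <- idx[order(p$times[idx], idx)]
  paste(cmd_codes()[idx], collapse = arrow)
}

#' Encode a participant-events table into a trajectory table
#'
#' The participant-events table has one row per participant: `participant_id`,
#' `sex`, `follow_up_years`, and one event-year column per disease
#' (`hyp_years`, `dm_years`, `hd_years`, `stk_years`), `NA` meaning the
#' disease did not occur. The returned trajectory table has columns `t_hyp`,
#' `t_dm`, `t_hd`, `t_stk` and `occ_hyp` .. `occ_stk`.
#'
#' @param events_df participant-events data.frame.
#' @return data.frame with one row per participant: `participant_id`,
#'   fractional times and occurrence flags.
#' @export
encode_cohort <- function(events_df) {
  need <- c("participant_id", "follow_up_years", event_cols())
  miss <- setdiff(need, names(events_df))
  if (length(miss) > 0) abort("missing column(s): %s", paste(miss, collapse = ", "))
  n <- nrow(events_df)
  tmat <- matrix(1, n, 4, dimnames = list(NULL, paste0("t_", tolower(cmd_codes()))))
  omat <- matrix(FALSE, n, 4, dimnames = list(NULL, paste0("occ_", tolower(cmd_codes()))))
  fu <- as.numeric(events_df$follow_up_years)
  if (any(is.na(fu)) || any(fu <= 0)) abort("follow_up_years must be positive")
  for (j in seq_len(4)) {
    ev <- as.numeric(events_df[[event_cols()[j]]])
    bad <- !is.na(ev) & (ev <= 0 | ev > fu)
    if (any(bad))
      abort("%s outside (0, follow_up] for participant(s) %s", event_cols()[j],
            paste(head(events_df$participant_id[bad], 5), collapse = ", "))
    has <- !is.na(ev)
    tmat[has, j] <- ev[has] / fu[has]
    omat[, j] <- has
  }
  data.frame(participant_id = as.character(events_df$participant_id),
             tmat, omat, stringsAsFactors = FALSE)
}

# internal: event-year column names in canonical disease order
event_cols <- function() paste0(tolower(cmd_codes()), "_years")

# internal: time / flag column names of a trajectory table
time_cols <- function() paste0("t_", tolower(cmd_codes()))
occ_cols <- function() paste0("occ_", tolower(cmd_codes()))

# internal: extract and validate the n x 4 time matrix from a trajectory
# table (or pass through a bare numeric matrix with 4 columns)
traj_matrix <- function(trajectories) {
  if (is.matrix(trajectories) && ncol(trajectories) == 4) {
    m <- trajectories
  } else {
    tdf <- as.data.frame(trajectories)
    if (!all(time_cols() %in% names(tdf)))
      abort("trajectory table needs columns %s", paste(time_cols(), collapse = ", "))
    m <- as.matrix(tdf[, time_cols()])
  }
  storage.mode(m) <- "double"
  if (any(is.na(m)) || any(m <= 0) || any(m > 1))
    abort("trajectory times must lie in (0, 1]")
  colnames(m) <- time_cols()
  m
}

# internal: occurrence flags of a trajectory table; falls back on t < 1
traj_occ <- function(trajectories) {
  tdf <- as.data.frame(trajectories)
  if (all(occ_cols() %in% names(tdf))) {
    m <- sapply(tdf[, occ_cols()], as.logical)
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(tdf))
  } else {
    m <- traj_matrix(trajectories) < 1
  }
  colnames(m) <- occ_cols()
  m
}

#' Read / write trajectory and participant-events tables
#'
#' Plain-CSV readers and writers for the two table formats used throughout:
#' the participant-events table (see [encode_cohort()]) and the trajectory
#' table (`t_hyp` .. `occ_stk`). Non-occurrence is an explicit `NA` in the
#' event-year columns.
#'
#' @param path file path.
#' @param x table to write.
#' @return the read data.frame, or (writers) `path` invisibly.
#' @export
read_events_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("participant_id", "follow_up_years", event_cols()), names(df))
  if (length(miss) > 0) abort("events table %s lacks column(s): %s",
                              path, paste(miss, collapse = ", "))
  df
}

#' @rdname read_events_table
#' @export
write_events_table <- function(x, path) {
  write.csv(x, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname read_events_table
#' @export
read_trajectory_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  traj_matrix(df)  # validates
  df
}

#' @rdname read_events_table
#' @export
write_trajectory_table <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}
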