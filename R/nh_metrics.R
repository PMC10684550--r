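#' @title Per-night nocturnal hypoglycemia metrics
#' @name nh_metrics
#' @description
#' The nocturnal window is the half-open interval \[00:00, 06:00) of the
#' night's date; at the 15-minute sensor cadence this holds exactly the 24
#' expected readings (00:00 to 05:45). Hypoglycemia is strictly below
#' threshold (< 3.9 mmol/L for Level 1+2, < 3.0 mmol/L for Level 2); a
#' reading of exactly 3.9 is in range. Each reading represents the
#' 15-minute interval starting at its timestamp, so a run of k consecutive
#' below-threshold readings is an episode of 15k minutes, and a single
#' below-threshold reading already satisfies the >= 15 min episode
#' definition. A gap in the data (successive readings more than 15 min
#' apart) breaks a run: unobserved time never counts as hypoglycemia.
NULL

THRESH_L1 <- 3.9
THRESH_L2 <- 3.0
TIR_RANGE <- c(3.9, 10.0)
CADENCE_MIN <- 15

#' Extract one participant-night's nocturnal window
#'
#' @param trace data frame with `timestamp` (POSIXct) and `glucose_mmol_l`,
#'   sorted by time (one participant's readings).
#' @param date the night's calendar date (`Date` or `"YYYY-MM-DD"`); the
#'   window is 00:00 (inclusive) to 06:00 (exclusive) of that date.
#' @param min_readings QC rule: at least this many in-window readings
#'   (default 20; 24 are expected at the 15-min cadence).
#' @return object of class `night_record`: list with `participant_id`,
#'   `date`, `readings` (data frame), `n_readings`, `qc_pass`.
#' @export
extract_night <- function(trace, date, min_readings = 20) {
  date <- as.Date(date)
  t0 <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  t1 <- t0 + 6 * 3600
  sel <- trace$timestamp >= t0 & trace$timestamp < t1
  readings <- trace[sel, c("timestamp", "glucose_mmol_l"), drop = FALSE]
  readings <- readings[order(readings$timestamp), , drop = FALSE]
  rownames(readings) <- NULL
  structure(list(
    participant_id = if (!is.null(trace$participant_id) && nrow(readings))
      trace$participant_id[sel][1] else trace$participant_id[1],
    date = date,
    readings = readings,
    n_readings = nrow(readings),
    qc_pass = nrow(readings) >= min_readings
  ), class = "night_record")
}

#' @export
print.night_record <- function(x, ...) {
  cat(sprintf("night %s / %s: %d readings, QC %s\n",
              x$participant_id, format(x$date), x$n_readings,
              if (x$qc_pass) "pass" else "FAIL"))
  invisible(x)
}

# Run-length episode scan on a glucose vector with timestamps.
# Returns integer matrix with columns start_idx, n_steps.
runs_below <- function(glucose, timestamp, threshold) {
  below <- glucose < threshold
  n <- length(glucose)
  if (!any(below)) return(matrix(integer(0), ncol = 2))
  # break runs at data gaps (> nominal cadence between successive readings)
  gap_before <- c(FALSE, diff(as.numeric(timestamp)) / 60 > CADENCE_MIN + 1e-9)
  run_break <- below & (c(TRUE, !below[-n]) | gap_before)
  run_id <- cumsum(run_break)
  run_id[!below] <- 0L
  starts <- which(run_break)
  lens <- tabulate(run_id[below])
  cbind(start_idx = starts, n_steps = lens)
}

#' Detect nocturnal hypoglycemia episodes
#'
#' Maximal runs of consecutive readings strictly below `threshold`;
#' "consecutive" requires adjacency in the observed sequence and a
#' time step of at most the nominal 15-min cadence. Each run of k
#' readings is one episode of duration 15k minutes.
#'
#' @param night a `night_record` with `qc_pass = TRUE`.
#' @param threshold mmol/L; 3.9 (Level 1+2) or 3.0 (Level 2).
#' @return data frame with one row per episode: `threshold`, `start`
#'   (timestamp of first below-threshold reading), `n_steps`,
#'   `duration_min`, `nadir`.
#' @export
detect_episodes <- function(night, threshold = THRESH_L1) {
  stopifnot(inherits(night, "night_record"))
  if (!night$qc_pass)
    stop("detect_episodes: night failed QC (", night$n_readings, " readings)")
  g <- night$readings$glucose_mmol_l
  ts <- night$readings$timestamp
  r <- runs_below(g, ts, threshold)
  if (!nrow(r)) {
    return(data.frame(threshold = numeric(0), start = as.POSIXct(character(0), tz = "UTC"),
                      n_steps = integer(0), duration_min = numeric(0), nadir = numeric(0)))
  }
  nadir <- vapply(seq_len(nrow(r)), function(i)
    min(g[r[i, 1] + seq_len(r[i, 2]) - 1L]), numeric(1))
  data.frame(threshold = threshold, start = ts[r[, 1]],
             n_steps = as.integer(r[, 2]),
             duration_min = CADENCE_MIN * as.numeric(r[, 2]),
             nadir = nadir)
}

#' Hypoglycemic area under the threshold curve for one night
#'
#' Sum over in-window readings g strictly below `threshold` of
#' (threshold - g) x 15 min; zero when no reading is below. Units
#' mmol/L.min. This incorporates both depth and duration of hypoglycemia.
#'
#' @inheritParams detect_episodes
#' @return scalar AUC in mmol/L.min.
#' @export
auc_below <- function(night, threshold = THRESH_L1) {
  stopifnot(inherits(night, "night_record"))
  if (!night$qc_pass)
    stop("auc_below: night failed QC (", night$n_readings, " readings)")
  g <- night$readings$glucose_mmol_l
  sum(pmax(threshold - g, 0) * CADENCE_MIN * (g < threshold))
}

# Fast internal metric computation on bare vectors; single definition
# shared by night_summary() and the synthetic generator so simulation
# truth and analysis can never disagree on a metric.
night_metric_vec <- function(glucose, timestamp) {
  r39 <- runs_below(glucose, timestamp, THRESH_L1)
  r30 <- runs_below(glucose, timestamp, THRESH_L2)
  below39 <- glucose < THRESH_L1
  below30 <- glucose < THRESH_L2
  n <- length(glucose)
  m <- mean(glucose)
  dur39 <- CADENCE_MIN * sum(below39)
  list(
    nh39_present = any(below39),
    nh39_episodes = nrow(r39),
    nh39_duration = dur39,
    nh39_auc = sum((THRESH_L1 - glucose[below39])) * CADENCE_MIN,
    nh30_present = any(below30),
    nh30_episodes = nrow(r30),
    nh30_duration = CADENCE_MIN * sum(below30),
    nh30_auc = sum((THRESH_L2 - glucose[below30])) * CADENCE_MIN,
    nocturnal_mean = m,
    nocturnal_cv = if (n > 1) 100 * sd(glucose) / m else 0,
    nocturnal_tir = 100 * sum(glucose >= TIR_RANGE[1] & glucose <= TIR_RANGE[2]) / n,
    level_class = if (any(below30)) "level2" else if (any(below39)) "level1_only" else "none",
    duration_quartile = duration_quartile(dur39)
  )
}

#' Bin a nightly NH<3.9 duration into the reporting quartiles
#'
#' Bins (minutes): Q0 = 0 (no NH), QI = 1--45, QII = 46--90,
#' QIII = 91--150, QIV = > 150.
#'
#' @param duration_min nightly NH<3.9 mmol/L duration in minutes.
#' @return character vector in `Q0, QI, QII, QIII, QIV`.
#' @export
duration_quartile <- function(duration_min) {
  cut(duration_min, breaks = c(-Inf, 0, 45, 90, 150, Inf),
      labels = c("Q0", "QI", "QII", "QIII", "QIV"), right = TRUE) |>
    as.character()
}

#' Summarise one night's glycemic metrics
#'
#' @inheritParams detect_episodes
#' @return one-row data frame with episode presence/count/duration/AUC at
#'   both thresholds, nocturnal mean (mmol/L), %CV (100 x SD/mean, sample
#'   SD), time-in-range 3.9--10.0 mmol/L inclusive (% of observed
#'   readings), night level class (`none`, `level1_only`, `level2`) and
#'   the NH<3.9 duration quartile bin. Denominators are observed readings,
#'   not the expected 24.
#' @export
night_summary <- function(night) {
  stopifnot(inherits(night, "night_record"))
  if (!night$qc_pass)
    stop("night_summary: night failed QC (", night$n_readings, " readings)")
  m <- night_metric_vec(night$readings$glucose_mmol_l, night$readings$timestamp)
  cbind(data.frame(participant_id = night$participant_id, date = night$date,
                   n_readings = night$n_readings, stringsAsFactors = FALSE),
        as.data.frame(m, stringsAsFactors = FALSE))
}

#' Build the analysis night table
#'
#' Pairs nocturnal windows with next-morning sleep scores
#' ([pair_by_night()]), computes per-night metrics ([night_summary()]) and
#' joins participant covariates. This is the input to every downstream
#' comparison and model.
#'
#' @inheritParams pair_by_night
#' @param participants optional participant data frame
#'   (see [read_participants_csv()]); when given, `age`, `sex_female`,
#'   `gold_score`, `dafne_score` and `treatment` are joined on.
#' @return data frame, one row per QC-passing score-matched night.
#' @export
night_metrics_table <- function(cgm, sleep, participants = NULL,
                                min_readings = 20, verbose = FALSE) {
  pairs <- pair_by_night(cgm, sleep, min_readings = min_readings, verbose = verbose)
  secs <- as.numeric(cgm$timestamp)
  in_window <- secs %% 86400 < 6 * 3600
  nsec <- secs[in_window]
  ng <- cgm$glucose_mmol_l[in_window]
  key <- paste(cgm$participant_id[in_window], floor(nsec / 86400))
  pk <- paste(pairs$participant_id, as.numeric(pairs$date))
  groups <- split(seq_along(nsec), key)
  mets <- lapply(groups[pk], function(idx) {
    idx <- idx[order(nsec[idx])]
    night_metric_vec(ng[idx], nsec[idx])
  })
  pull <- function(field, proto) vapply(mets, `[[`, proto, field)
  met_df <- data.frame(
    nh39_present = pull("nh39_present", logical(1)),
    nh39_episodes = pull("nh39_episodes", integer(1)),
    nh39_duration = pull("nh39_duration", numeric(1)),
    nh39_auc = pull("nh39_auc", numeric(1)),
    nh30_present = pull("nh30_present", logical(1)),
    nh30_episodes = pull("nh30_episodes", integer(1)),
    nh30_duration = pull("nh30_duration", numeric(1)),
    nh30_auc = pull("nh30_auc", numeric(1)),
    nocturnal_mean = pull("nocturnal_mean", numeric(1)),
    nocturnal_cv = pull("nocturnal_cv", numeric(1)),
    nocturnal_tir = pull("nocturnal_tir", numeric(1)),
    level_class = pull("level_class", character(1)),
    duration_quartile = pull("duration_quartile", character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- cbind(pairs, met_df)
  if (!is.null(participants)) {
    i <- match(out$participant_id, participants$participant_id)
    out$age <- participants$age[i]
    out$sex_female <- as.integer(participants$sex[i] == "female")
    out$gold_score <- participants$gold_score[i]
    out$dafne_score <- participants$dafne_score[i]
    out$treatment <- participants$treatment[i]
  }
  attr(out, "drops") <- attr(pairs, "drops")
  out
}
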