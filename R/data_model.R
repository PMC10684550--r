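#' @title CGM, sleep-diary, participant and capillary-meter file I/O
#' @name data_model
#' @description
#' All interchange is flat CSV with fixed column names:
#' \itemize{
#'   \item CGM / capillary: `participant_id,timestamp,glucose_mmol_l`
#'   \item sleep diary: `participant_id,date,score`
#'   \item participants: `participant_id,age,sex,gold_score,dafne_score,treatment`
#' }
#' Timestamps are ISO-8601 naive local time (no timezone arithmetic);
#' glucose is in mmol/L and must lie in the physiologic span 1.0--30.0.
NULL

GLUCOSE_RANGE <- c(1.0, 30.0)

parse_timestamp <- function(x) {
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
            "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M")
  best <- rep(NA_real_, length(x))
  for (f in fmts) {
    p <- as.numeric(strptime(x, f, tz = "UTC"))
    fill <- is.na(best) & !is.na(p)
    best[fill] <- p[fill]
  }
  as.POSIXct(best, origin = "1970-01-01", tz = "UTC")
}

#' Read a CGM (or capillary meter) CSV
#'
#' @param path path to a CSV with columns `participant_id`, `timestamp`
#'   (ISO-8601), `glucose_mmol_l`.
#' @return A data frame of class `cgm_data` with columns `participant_id`
#'   (character), `timestamp` (POSIXct), `glucose_mmol_l` (numeric), sorted
#'   by participant then time. One participant's rows form one trace.
#' @details Rows with unparseable timestamps, non-positive or
#'   non-physiologic glucose, or duplicate (participant, timestamp) keys
#'   are rejected with an error naming the offending row.
#' @export
read_cgm_csv <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(participant_id = "character",
                                 timestamp = "character"))
  need <- c("participant_id", "timestamp", "glucose_mmol_l")
  if (!all(need %in% names(raw)))
    stop("CGM CSV must have columns: ", paste(need, collapse = ", "))
  ts <- suppressWarnings(parse_timestamp(raw$timestamp))
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop(sprintf("unparseable timestamp '%s' at row %d of %s",
                 raw$timestamp[bad], bad, path))
  }
  g <- as.numeric(raw$glucose_mmol_l)
  if (anyNA(g) || any(g <= 0)) {
    bad <- which(is.na(g) | g <= 0)[1]
    stop(sprintf("non-positive or missing glucose at row %d of %s", bad, path))
  }
  if (any(g < GLUCOSE_RANGE[1] | g > GLUCOSE_RANGE[2])) {
    bad <- which(g < GLUCOSE_RANGE[1] | g > GLUCOSE_RANGE[2])[1]
    stop(sprintf("glucose %.2f mmol/L outside physiologic range [%g, %g] at row %d",
                 g[bad], GLUCOSE_RANGE[1], GLUCOSE_RANGE[2], bad))
  }
  out <- data.frame(participant_id = raw$participant_id,
                    timestamp = ts, glucose_mmol_l = g,
                    stringsAsFactors = FALSE)
  out <- out[order(out$participant_id, out$timestamp), , drop = FALSE]
  key <- paste(out$participant_id, format(out$timestamp, "%Y-%m-%dT%H:%M:%S"))
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (participant, timestamp) reading: ", d)
  }
  rownames(out) <- NULL
  class(out) <- c("cgm_data", "data.frame")
  out
}

#' @rdname read_cgm_csv
#' @param x a `cgm_data` data frame.
#' @export
write_cgm_csv <- function(x, path) {
  df <- data.frame(participant_id = x$participant_id,
                   timestamp = format(x$timestamp, "%Y-%m-%dT%H:%M:%S"),
                   glucose_mmol_l = x$glucose_mmol_l)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_cgm_csv
#' @export
read_capillary_csv <- read_cgm_csv

#' Read a daily sleep-diary CSV
#'
#' @param path CSV with columns `participant_id`, `date` (the morning the
#'   score was reported), `score` (5-point Likert, 1 = very poorly,
#'   5 = very well).
#' @return data frame with `participant_id` (character), `date` (Date),
#'   `score` (integer 1--5).
#' @export
read_sleep_csv <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(participant_id = "character", date = "character"))
  need <- c("participant_id", "date", "score")
  if (!all(need %in% names(raw)))
    stop("sleep CSV must have columns: ", paste(need, collapse = ", "))
  d <- suppressWarnings(as.Date(raw$date, tryFormats = c("%Y-%m-%d", "%Y/%m/%d")))
  if (anyNA(d)) {
    bad <- which(is.na(d))[1]
    stop(sprintf("unparseable date '%s' at row %d of %s", raw$date[bad], bad, path))
  }
  s <- suppressWarnings(as.integer(raw$score))
  if (anyNA(s) || any(s < 1L | s > 5L)) {
    bad <- which(is.na(s) | s < 1L | s > 5L)[1]
    stop(sprintf("sleep score '%s' outside 1-5 at row %d of %s",
                 raw$score[bad], bad, path))
  }
  data.frame(participant_id = raw$participant_id, date = d, score = s,
             stringsAsFactors = FALSE)
}

#' @rdname read_sleep_csv
#' @param x a sleep-record data frame.
#' @export
write_sleep_csv <- function(x, path) {
  df <- data.frame(participant_id = x$participant_id,
                   date = format(x$date, "%Y-%m-%d"), score = x$score)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the participant metadata CSV
#'
#' @param path CSV with columns `participant_id`, `age` (years),
#'   `sex` (`male`/`female`), `gold_score` (1--7 hypoglycemia-awareness
#'   scale, >= 4 impaired), `dafne_score` (1--3 symptomatic-threshold
#'   scale), `treatment` (`MDI`/`pump`).
#' @return validated data frame, one row per participant.
#' @export
read_participants_csv <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(participant_id = "character"))
  need <- c("participant_id", "age", "sex", "gold_score", "dafne_score", "treatment")
  if (!all(need %in% names(raw)))
    stop("participant CSV must have columns: ", paste(need, collapse = ", "))
  validate_participants(raw)
  raw
}

validate_participants <- function(p) {
  stopifnot(!anyDuplicated(p$participant_id))
  if (any(p$age <= 0)) stop("participant age must be positive")
  if (!all(p$sex %in% c("male", "female"))) stop("sex must be 'male' or 'female'")
  if (!all(p$gold_score %in% 1:7)) stop("gold_score must be an integer in 1-7")
  if (!all(p$dafne_score %in% 1:3)) stop("dafne_score must be an integer in 1-3")
  if (!all(p$treatment %in% c("MDI", "pump"))) stop("treatment must be 'MDI' or 'pump'")
  invisible(p)
}

#' @rdname read_participants_csv
#' @param x a participant data frame.
#' @export
write_participants_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pair nocturnal CGM windows with next-morning sleep scores
#'
#' The score reported on morning D refers to the night ending that morning,
#' i.e. the 00:00--06:00 window of date D. Nights failing quality control
#' (fewer than `min_readings` sensor readings in the window) and scores
#' without a qualifying night are dropped and logged, not errors.
#'
#' @param cgm a `cgm_data` data frame (see [read_cgm_csv()]).
#' @param sleep a sleep-record data frame (see [read_sleep_csv()]).
#' @param min_readings night QC threshold; nights with fewer readings in
#'   the nocturnal window are excluded (default 20 of the 24 expected).
#' @param verbose emit a message per dropped night/score.
#' @return data frame with one row per matched, QC-passing participant-night:
#'   `participant_id`, `date`, `score`, `n_readings`. The drops are recorded
#'   in `attr(, "drops")` with a reason each.
#' @export
pair_by_night <- function(cgm, sleep, min_readings = 20, verbose = FALSE) {
  # candidate nights: any date on which a participant has in-window readings
  secs <- as.numeric(cgm$timestamp)
  in_window <- secs %% 86400 < 6 * 3600
  noct <- cgm[in_window, , drop = FALSE]
  noct_date <- as.Date(floor(secs[in_window] / 86400), origin = "1970-01-01")
  key <- paste(noct$participant_id, noct_date)
  counts <- table(key)
  night_key <- names(counts)
  n_readings <- as.integer(counts)
  qc <- n_readings >= min_readings

  sleep_key <- paste(sleep$participant_id, sleep$date)
  matched <- sleep_key %in% night_key[qc]
  idx <- match(sleep_key[matched], night_key)

  out <- data.frame(participant_id = sleep$participant_id[matched],
                    date = sleep$date[matched],
                    score = sleep$score[matched],
                    n_readings = n_readings[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(out$participant_id, out$date), , drop = FALSE]
  rownames(out) <- NULL

  drop_rec <- function(ids, dates, reason)
    data.frame(participant_id = ids, date = dates,
               reason = rep_len(reason, length(ids)),
               stringsAsFactors = FALSE)
  unmatched_nights <- qc & !(night_key %in% sleep_key)
  drops <- rbind(
    drop_rec(sub(" .*", "", night_key[!qc]), sub(".* ", "", night_key[!qc]),
             "night failed QC (<min_readings)"),
    drop_rec(sleep$participant_id[!matched],
             format(sleep$date[!matched], "%Y-%m-%d"),
             "sleep score without qualifying night"),
    drop_rec(sub(" .*", "", night_key[unmatched_nights]),
             sub(".* ", "", night_key[unmatched_nights]),
             "night without sleep score"))
  if (verbose && nrow(drops))
    message(sprintf("pair_by_night: dropped %d night(s)/score(s)", nrow(drops)))
  attr(out, "drops") <- drops
  out
}
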