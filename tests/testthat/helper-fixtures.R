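# In-code fixtures shared across test files.

# one night's readings at the 15-min cadence starting 00:00 of `date`
make_night_df <- function(glucose, date = "2024-03-01", id = "P1",
                          start_hour = 0) {
  t0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + start_hour * 3600
  data.frame(participant_id = id,
             timestamp = t0 + 900 * (seq_along(glucose) - 1),
             glucose_mmol_l = glucose,
             stringsAsFactors = FALSE)
}

make_night <- function(glucose, date = "2024-03-01", id = "P1") {
  extract_night(make_night_df(glucose, date, id), date)
}

# independent O(n^2) episode oracle: enumerate all contiguous sub-runs and
# keep the maximal all-below runs (complete nights, no data gaps)
oracle_episodes <- function(glucose, threshold) {
  n <- length(glucose)
  runs <- list()
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (all(glucose[s:e] < threshold) &&
          (s == 1 || glucose[s - 1] >= threshold) &&
          (e == n || glucose[e + 1] >= threshold)) {
        runs[[length(runs) + 1]] <- data.frame(
          start_idx = s, n_steps = e - s + 1,
          nadir = min(glucose[s:e]))
      }
    }
  }
  if (!length(runs))
    return(data.frame(start_idx = integer(0), n_steps = integer(0),
                      nadir = numeric(0)))
  do.call(rbind, runs)
}

# small deterministic cohort for integration-style tests
small_cohort <- function(seed = 7, n = 6, nights = 10, ...) {
  generate_cohort(synthetic_config(n_participants = n,
                                   nights_per_participant = nights,
                                   seed = seed, ...))
}

tmpfile <- function(ext = ".csv") tempfile(fileext = ext)
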