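#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' 27 adults with type 1 diabetes contributing 28 nights each of blinded
#' CGM at 15-min cadence, with roughly 24% of nights containing nocturnal
#' hypoglycemia below 3.9 mmol/L, ordinal 5-point sleep scores generated
#' from a random-intercept proportional-odds model, and capillary meter
#' readings whose relative error is scaled to a target MARD of 13.6%.
#'
#' @param n_participants,nights_per_participant cohort dimensions.
#' @param seed one global integer seed; every stream (participants,
#'   intercepts, traces, scores, capillary error) is derived from it by a
#'   named substream, so one seed fixes the whole cohort bit-exactly.
#' @param baseline_mean_mu,baseline_mean_sd participant-level mean
#'   nocturnal glucose is drawn Normal(mu, sd) and clipped to
#'   \[4.5, 12\] mmol/L.
#' @param ar_rho,ar_sigma AR(1) autocorrelation (per 15-min step) and
#'   innovation SD (mmol/L) of the within-night glucose path.
#' @param hypo_night_prob probability a night receives an injected
#'   hypoglycemia excursion. Nights not selected are floored at
#'   4.0 mmol/L, so NH<3.9 presence is exactly Bernoulli with this rate.
#' @param hypo_duration_shape,hypo_duration_scale gamma distribution of
#'   excursion core length in 15-min steps (rounded, min 1, max 20);
#'   defaults give mean ~126 min, SD ~87 min.
#' @param hypo_nadir_min,hypo_nadir_max uniform range of excursion nadirs
#'   (mmol/L).
#' @param second_episode_prob probability a selected night carries a
#'   second, disjoint excursion (the study observed at most two episodes
#'   per night, ~8% of NH nights).
#' @param sleep_betas named log-odds effects on the latent sleep scale:
#'   `nh_presence`, `nh_episodes`, `nh_duration_per_15min`,
#'   `mean_glucose`, `age` (per year), `sex_female`.
#' @param sleep_cutpoints 4 strictly increasing cut-points of the 5-level
#'   proportional-odds model.
#' @param sigma_u SD of the participant random intercept.
#' @param mard_target percent mean absolute relative difference the
#'   capillary pair generator is scaled to.
#' @param n_capillary_pairs number of capillary/sensor pairs to generate.
#' @param gold_hypo_gamma log-odds shift of `hypo_night_prob` per
#'   gold-score point above the cohort mean (default 0: no planted
#'   awareness/NH association).
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_participants = 27,
                             nights_per_participant = 28,
                             seed = 1L,
                             baseline_mean_mu = 7.5,
                             baseline_mean_sd = 1.2,
                             ar_rho = 0.85,
                             ar_sigma = 0.45,
                             hypo_night_prob = 0.239,
                             hypo_duration_shape = 2.1,
                             hypo_duration_scale = 4.0,
                             hypo_nadir_min = 2.2,
                             hypo_nadir_max = 3.6,
                             second_episode_prob = 0.08,
                             sleep_betas = c(nh_presence = log(0.49),
                                             nh_episodes = 0,
                                             nh_duration_per_15min = 0,
                                             mean_glucose = 0,
                                             age = -0.02,
                                             sex_female = -0.2),
                             sleep_cutpoints = c(-4.3, -2.8, -1.0, 1.0),
                             sigma_u = 0.8,
                             mard_target = 13.6,
                             n_capillary_pairs = 518,
                             gold_hypo_gamma = 0) {
  cfg <- list(n_participants = as.integer(n_participants),
              nights_per_participant = as.integer(nights_per_participant),
              seed = as.integer(seed),
              baseline_mean_mu = baseline_mean_mu,
              baseline_mean_sd = baseline_mean_sd,
              ar_rho = ar_rho, ar_sigma = ar_sigma,
              hypo_night_prob = hypo_night_prob,
              hypo_duration_shape = hypo_duration_shape,
              hypo_duration_scale = hypo_duration_scale,
              hypo_nadir_min = hypo_nadir_min,
              hypo_nadir_max = hypo_nadir_max,
              second_episode_prob = second_episode_prob,
              sleep_betas = sleep_betas,
              sleep_cutpoints = sleep_cutpoints,
              sigma_u = sigma_u,
              mard_target = mard_target,
              n_capillary_pairs = as.integer(n_capillary_pairs),
              gold_hypo_gamma = gold_hypo_gamma)
  stopifnot(cfg$n_participants >= 1, cfg$nights_per_participant >= 1,
            cfg$ar_rho > 0, cfg$ar_rho < 1, cfg$ar_sigma >= 0,
            cfg$hypo_night_prob >= 0, cfg$hypo_night_prob <= 1,
            cfg$second_episode_prob >= 0, cfg$second_episode_prob <= 1,
            cfg$sigma_u >= 0, cfg$mard_target >= 0,
            all(diff(cfg$sleep_cutpoints) > 0),
            cfg$hypo_nadir_min <= cfg$hypo_nadir_max,
            cfg$hypo_nadir_max < 3.9)
  needed <- c("nh_presence", "nh_episodes", "nh_duration_per_15min",
              "mean_glucose", "age", "sex_female")
  stopifnot(all(needed %in% names(cfg$sleep_betas)))
  class(cfg) <- "synthetic_config"
  cfg
}

# glucose values are clipped to the span seen on the real sensor
SENSOR_SPAN <- c(1.1, 27.8)
NONHYPO_FLOOR <- 4.0

# times of the 24 expected nocturnal readings for a given date
night_times <- function(date) {
  as.POSIXct(paste(format(as.Date(date)), "00:00:00"), tz = "UTC") +
    60 * CADENCE_MIN * (0:23)
}

#' Generate one synthetic nocturnal CGM trace
#'
#' 24 readings at 00:00, 00:15, ..., 05:45 of `night_date`:
#' participant baseline plus a stationary AR(1) path, with (probability
#' `hypo_night_prob`) a smooth half-cosine hypoglycemia dip whose core
#' readings run from just under the 3.9 mmol/L threshold down to the drawn
#' nadir. Nights without an injected dip are floored at 4.0 mmol/L so the
#' nightly NH rate is exactly the configured probability. Uses the current
#' RNG state; seed management happens in [generate_cohort()].
#'
#' @param config a [synthetic_config()].
#' @param baseline participant mean nocturnal glucose (mmol/L).
#' @param night_date calendar date of the night.
#' @param participant_id id stamped on the rows.
#' @param force_hypo override the Bernoulli draw (TRUE/FALSE), or NULL.
#' @return data frame `participant_id`, `timestamp`, `glucose_mmol_l`
#'   (24 rows) with attribute `hypo` (logical: dip injected).
#' @export
generate_night_trace <- function(config, baseline, night_date,
                                 participant_id = "P1", force_hypo = NULL) {
  hypo <- if (is.null(force_hypo)) runif(1) < config$hypo_night_prob else isTRUE(force_hypo)
  g <- gen_night_glucose(config, baseline, hypo)
  out <- data.frame(participant_id = participant_id,
                    timestamp = night_times(night_date),
                    glucose_mmol_l = g,
                    stringsAsFactors = FALSE)
  attr(out, "hypo") <- hypo
  out
}

# glucose path for one night (numeric, length 24); uses current RNG state
gen_night_glucose <- function(config, baseline, hypo) {
  n <- 24L
  rho <- config$ar_rho
  sig <- config$ar_sigma
  sd_stat <- if (sig > 0) sig / sqrt(1 - rho^2) else 0
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd_stat)
  if (sig > 0) {
    innov <- rnorm(n - 1, 0, sig)
    for (t in 2:n) x[t] <- rho * x[t - 1] + innov[t - 1]
  }
  g <- baseline + x
  if (hypo) {
    n_dips <- 1L + (runif(1) < config$second_episode_prob)
    occupied <- rep(FALSE, n)
    for (d in seq_len(n_dips)) {
      len <- min(20L, max(1L, as.integer(round(
        rgamma(1, shape = config$hypo_duration_shape,
               scale = config$hypo_duration_scale)))))
      nadir <- runif(1, config$hypo_nadir_min, config$hypo_nadir_max)
      placed <- FALSE
      for (try in 1:20) {
        s <- sample.int(n - len + 1L, 1)
        span <- max(1L, s - 2L):min(n, s + len + 1L)  # keep a >=2-step gap
        if (!any(occupied[span])) { placed <- TRUE; break }
      }
      if (!placed) next
      idx <- s:(s + len - 1L)
      edge <- min(nadir + 0.4, 3.8)
      tt <- (seq_along(idx) - 0.5) / len
      prof <- (1 - cos(2 * pi * tt)) / 2
      g[idx] <- edge - (edge - nadir) * prof / max(prof)  # nadir attained
      occupied[idx] <- TRUE
    }
  } else {
    g <- pmax(g, NONHYPO_FLOOR)
  }
  round(pmin(pmax(g, SENSOR_SPAN[1]), SENSOR_SPAN[2]), 2)
}

#' Draw ordinal sleep scores from the proportional-odds model
#'
#' P(Y <= k) = logistic(cutpoint_k - eta) with
#' eta = sum_j beta_j x_j + u; a larger eta shifts mass toward higher
#' (better) scores, so a negative coefficient (OR < 1) lowers the score.
#'
#' @param config a [synthetic_config()].
#' @param covariates data frame (or named list, recycled) with columns
#'   matching the names of `config$sleep_betas`; one row per night.
#' @param u participant random intercept(s), one per row (recycled).
#' @return integer vector of scores in 1..5.
#' @export
generate_sleep_score <- function(config, covariates, u = 0) {
  covariates <- as.data.frame(covariates)
  betas <- config$sleep_betas
  eta <- rep(0, nrow(covariates))
  for (nm in names(betas)) {
    if (!nm %in% names(covariates))
      stop("covariates missing column '", nm, "'")
    eta <- eta + betas[[nm]] * as.numeric(covariates[[nm]])
  }
  eta <- eta + rep_len(u, length(eta))
  cum <- vapply(config$sleep_cutpoints, function(k) plogis(k - eta),
                numeric(length(eta)))
  if (length(eta) == 1L) cum <- matrix(cum, nrow = 1)
  uu <- runif(length(eta))
  as.integer(1L + rowSums(uu > cum))
}

#' Generate capillary meter readings paired to sensor readings
#'
#' Samples sensor readings from the cohort traces and sets
#' capillary = sensor / (1 + e), e ~ Normal(0, s) with
#' s = (mard_target/100) * sqrt(pi/2), so the expected mean absolute
#' relative difference |capillary - sensor| / capillary = |e| equals
#' `mard_target` percent. Draws violating the physiologic span are
#' redrawn. The meter timestamp is offset from the sensor time by a
#' uniform 0--3 min in either direction.
#'
#' @param cgm cohort CGM data frame.
#' @param config a [synthetic_config()].
#' @return list with `meter` (capillary CSV-shaped data frame) and
#'   `pairs` (data frame `capillary`, `sensor`, `time_gap` minutes).
#' @export
generate_capillary_pairs <- function(cgm, config) {
  n <- min(config$n_capillary_pairs, nrow(cgm))
  rows <- sample.int(nrow(cgm), n)
  sensor <- cgm$glucose_mmol_l[rows]
  s <- (config$mard_target / 100) * sqrt(pi / 2)
  cap <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      e <- if (s > 0) rnorm(1, 0, s) else 0
      v <- sensor[i] / (1 + e)
      if (e > -0.9 && v >= GLUCOSE_RANGE[1] && v <= GLUCOSE_RANGE[2]) break
    }
    cap[i] <- v
  }
  gap <- runif(n, 0, 3)
  sign <- sample(c(-1, 1), n, replace = TRUE)
  meter <- data.frame(participant_id = cgm$participant_id[rows],
                      timestamp = cgm$timestamp[rows] + round(sign * gap * 60),
                      glucose_mmol_l = round(cap, 1),
                      stringsAsFactors = FALSE)
  ord <- order(meter$participant_id, meter$timestamp)
  list(meter = meter[ord, , drop = FALSE],
       pairs = data.frame(capillary = cap, sensor = sensor, time_gap = gap))
}

#' Generate a full synthetic cohort with known ground truth
#'
#' Produces the four canonical inputs (CGM traces, sleep diary,
#' participant table, capillary meter download) plus the generative truth.
#' Night covariates entering the sleep-score model are computed with the
#' same metric code the analysis uses ([night_summary()] internals), so
#' simulation truth and analysis definitions cannot drift apart. The same
#' seed always yields a bit-identical cohort.
#'
#' @param config a [synthetic_config()].
#' @return list: `config`, `participants`, `cgm`, `sleep`, `capillary`
#'   (meter data frame), `capillary_pairs`, and `truth` (random
#'   intercepts, baselines, per-night hypo flags and covariates).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  np <- config$n_participants
  nn <- config$nights_per_participant

  set.seed(substream_seed(config$seed, "participants"))
  participants <- data.frame(
    participant_id = sprintf("P%02d", seq_len(np)),
    age = pmin(60L, pmax(21L, as.integer(round(rnorm(np, 30.6, 8.7))))),
    sex = ifelse(runif(np) < 18 / 27, "female", "male"),
    gold_score = sample(1:4, np, replace = TRUE, prob = c(0.28, 0.42, 0.22, 0.08)),
    dafne_score = sample(1:2, np, replace = TRUE, prob = c(0.704, 0.296)),
    treatment = ifelse(runif(np) < 14 / 27, "pump", "MDI"),
    stringsAsFactors = FALSE)
  baselines <- pmin(12, pmax(4.5, rnorm(np, config$baseline_mean_mu,
                                        config$baseline_mean_sd)))

  set.seed(substream_seed(config$seed, "random_intercepts"))
  u <- rnorm(np, 0, config$sigma_u)

  # per-participant hypo-night probability, optionally tilted by gold score
  pg <- plogis(qlogis(config$hypo_night_prob) +
                 config$gold_hypo_gamma *
                   (participants$gold_score - mean(participants$gold_score)))

  set.seed(substream_seed(config$seed, "traces"))
  dates <- as.Date("2024-03-01") + seq_len(nn) - 1
  night_secs <- as.numeric(as.POSIXct(paste(format(dates), "00:00:00"),
                                      tz = "UTC"))
  offsets <- 60 * CADENCE_MIN * (0:23)
  nnight <- np * nn
  gmat <- matrix(NA_real_, 24, nnight)
  hypo_flag <- matrix(FALSE, np, nn)
  k <- 0L
  for (i in seq_len(np)) {
    for (j in seq_len(nn)) {
      k <- k + 1L
      hypo <- runif(1) < pg[i]
      hypo_flag[i, j] <- hypo
      gmat[, k] <- gen_night_glucose(config, baselines[i], hypo)
    }
  }
  ts_all <- rep(night_secs, times = np)  # night blocks per participant
  cgm <- data.frame(
    participant_id = rep(participants$participant_id, each = nn * 24),
    timestamp = as.POSIXct(rep(ts_all, each = 24) + rep(offsets, nnight),
                           origin = "1970-01-01", tz = "UTC"),
    glucose_mmol_l = as.vector(gmat),
    stringsAsFactors = FALSE)
  class(cgm) <- c("cgm_data", "data.frame")

  # covariates from the analysis metric code, then ordinal scores
  set.seed(substream_seed(config$seed, "sleep"))
  uid <- rep(seq_len(np), each = nn)
  mets <- lapply(seq_len(nnight), function(k)
    night_metric_vec(gmat[, k], night_secs[(k - 1L) %% nn + 1L] + offsets))
  covs <- data.frame(
    participant_id = rep(participants$participant_id, each = nn),
    date = rep(dates, times = np),
    nh_presence = vapply(mets, function(m) as.integer(m$nh39_present), integer(1)),
    nh_episodes = vapply(mets, function(m) as.integer(m$nh39_episodes), integer(1)),
    nh_duration_per_15min = vapply(mets, function(m)
      m$nh39_duration / CADENCE_MIN, numeric(1)),
    mean_glucose = vapply(mets, function(m) m$nocturnal_mean, numeric(1)),
    age = participants$age[uid],
    sex_female = as.integer(participants$sex[uid] == "female"),
    stringsAsFactors = FALSE)
  score <- generate_sleep_score(config, covs[, names(config$sleep_betas)], u[uid])
  sleep <- data.frame(participant_id = covs$participant_id,
                      date = covs$date, score = score,
                      stringsAsFactors = FALSE)

  set.seed(substream_seed(config$seed, "capillary"))
  cp <- generate_capillary_pairs(cgm, config)

  list(config = config,
       participants = participants,
       cgm = cgm,
       sleep = sleep,
       capillary = cp$meter,
       capillary_pairs = cp$pairs,
       truth = list(u = u, baselines = baselines, hypo_night = hypo_flag,
                    covariates = covs))
}

#' Write the four canonical cohort CSVs
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort_csvs <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_cgm_csv(cohort$cgm, file.path(dir, "cgm.csv"))
  write_sleep_csv(cohort$sleep, file.path(dir, "sleep.csv"))
  write_participants_csv(cohort$participants, file.path(dir, "participants.csv"))
  write_cgm_csv(cohort$capillary, file.path(dir, "capillary.csv"))
  invisible(dir)
}
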