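#' @title Descriptive comparisons, smoothing and pipeline orchestration
#' @name association_analysis
NULL

strat_summary <- function(v) {
  q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(n = length(v), mean = mean(v), sd = sd(v),
       median = q[2], q1 = q[1], q3 = q[3])
}

#' Compare night-level metrics across strata
#'
#' For each continuous metric the two strata are summarised (mean/SD and
#' median/IQR) and compared with an independent-samples t test when a
#' Shapiro-Wilk check (alpha = 0.05, per stratum) supports normality in
#' both strata, otherwise with a Kruskal-Wallis test. Categorical
#' variables are compared as proportions with a chi-squared test. The
#' test actually used is always recorded.
#'
#' @param night_table a [night_metrics_table()] result.
#' @param strat_var stratifying column (default the night level class).
#' @param strata the two stratum labels to compare.
#' @param continuous,categorical metric columns to compare.
#' @return list of per-variable comparison records (`variable`, `groups`,
#'   `summaries`, `test`, `statistic`, `p_value`), class
#'   `night_comparisons`. Strata with fewer than 2 nights cause the
#'   variable to be skipped with a warning.
#' @export
compare_nights <- function(night_table, strat_var = "level_class",
                           strata = c("level1_only", "level2"),
                           continuous = c("nh39_duration", "nh39_auc",
                                          "nocturnal_mean", "nocturnal_cv",
                                          "nocturnal_tir"),
                           categorical = c("nh39_episodes")) {
  out <- list()
  grp <- night_table[[strat_var]]
  sel <- grp %in% strata
  tab <- night_table[sel, , drop = FALSE]
  grp <- factor(grp[sel], levels = strata)
  ns <- table(grp)
  for (v in continuous) {
    if (any(ns < 2)) {
      warning("stratum with n<2; skipping '", v, "'")
      next
    }
    vals <- split(as.numeric(tab[[v]]), grp)
    normal <- vapply(vals, function(x) {
      if (length(unique(x)) < 3 || length(x) < 3 || length(x) > 5000) return(FALSE)
      shapiro.test(x)$p.value >= 0.05
    }, logical(1))
    if (all(normal)) {
      tt <- t.test(vals[[1]], vals[[2]])
      rec <- list(test = "t", statistic = unname(tt$statistic),
                  p_value = tt$p.value)
    } else {
      kw <- kruskal.test(vals)
      rec <- list(test = "kruskal_wallis", statistic = unname(kw$statistic),
                  p_value = kw$p.value)
    }
    out[[v]] <- c(list(variable = v, groups = strata,
                       summaries = lapply(vals, strat_summary),
                       normal_by_stratum = as.list(normal)), rec)
  }
  for (v in categorical) {
    if (any(ns < 2)) {
      warning("stratum with n<2; skipping '", v, "'")
      next
    }
    ct <- table(factor(tab[[v]]), grp)
    if (nrow(ct) < 2) {
      out[[v]] <- list(variable = v, groups = strata, test = "chi_squared",
                       statistic = NA_real_, p_value = NA_real_,
                       note = "single observed category")
      next
    }
    cs <- suppressWarnings(chisq.test(ct))
    out[[v]] <- list(variable = v, groups = strata,
                     counts = lapply(strata, function(s) as.list(ct[, s])),
                     test = "chi_squared", statistic = unname(cs$statistic),
                     p_value = cs$p.value)
  }
  class(out) <- "night_comparisons"
  out
}

#' Spearman correlation of hypoglycemia-awareness (Gold) score with NH metrics
#'
#' @param night_table a [night_metrics_table()] built with participant
#'   covariates joined (must contain `gold_score`).
#' @param metrics NH parameters to correlate with the Gold score across
#'   nights.
#' @return data frame: `metric`, `rho`, `p_value`, `n`; `rho` is `NA`
#'   with a note when either input is constant.
#' @export
correlate_gold <- function(night_table,
                           metrics = c("nh39_episodes", "nh39_duration",
                                       "nh39_auc", "nh30_episodes",
                                       "nh30_duration", "nh30_auc")) {
  stopifnot("gold_score" %in% names(night_table))
  g <- as.numeric(night_table$gold_score)
  res <- lapply(metrics, function(v) {
    x <- as.numeric(night_table[[v]])
    if (length(unique(g)) < 2 || length(unique(x)) < 2)
      return(data.frame(metric = v, rho = NA_real_, p_value = NA_real_,
                        n = length(x), note = "constant input"))
    ct <- suppressWarnings(cor.test(g, x, method = "spearman", exact = FALSE))
    data.frame(metric = v, rho = unname(ct$estimate),
               p_value = ct$p.value, n = length(x), note = "")
  })
  do.call(rbind, res)
}

#' Locally weighted running-line smoother
#'
#' Single-pass LOWESS: at each distinct x value a degree-1 weighted
#' least-squares line is fitted over the nearest `ceiling(frac * n)`
#' observations with tricube weights scaled by the span radius, and
#' evaluated at that x. No robustness iterations.
#'
#' @param x,y observations (>= 10 points).
#' @param frac bandwidth as the fraction of points in each local fit,
#'   in (0, 1]; at least 3 points per local fit are required.
#' @return object of class `smooth_curve`: `x` (sorted distinct values),
#'   `fitted`, `frac`.
#' @export
lowess_curve <- function(x, y, frac = 0.8) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) stop("need at least 10 points")
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  q <- ceiling(frac * n)
  if (q < 3) stop("frac too small for a local linear fit (needs >= 3 points)")
  grid <- sort(unique(x))
  fitted <- vapply(grid, function(x0) {
    d <- abs(x - x0)
    h <- sort(d, partial = q)[q]
    if (h <= 0) {
      # all in-span points at x0 itself: weighted mean
      return(mean(y[d <= 0]))
    }
    w <- (1 - pmin(d / h, 1)^3)^3
    use <- w > 0
    if (sum(use) < 2 || length(unique(x[use])) < 2) return(sum(w * y) / sum(w))
    xw <- x[use]; yw <- y[use]; ww <- w[use]
    sw <- sum(ww)
    xm <- sum(ww * xw) / sw
    ym <- sum(ww * yw) / sw
    sxx <- sum(ww * (xw - xm)^2)
    b <- if (sxx > 0) sum(ww * (xw - xm) * (yw - ym)) / sxx else 0
    ym + b * (x0 - xm)
  }, numeric(1))
  structure(list(x = grid, fitted = fitted, frac = frac),
            class = "smooth_curve")
}

#' Locate slope sign changes on a fitted smooth curve
#'
#' Computes first differences of the fitted values over the x grid and
#' reports the grid x at which the slope sign flips. Sign changes whose
#' adjacent slope magnitudes are both below `noise_floor` are suppressed
#' so numerically flat stretches do not spawn spurious inflections.
#'
#' @param curve a [lowess_curve()] result.
#' @param noise_floor minimum |slope| (score units per mmol/L) for a sign
#'   change to count.
#' @return numeric vector of inflection x positions (possibly empty).
#' @export
find_inflections <- function(curve, noise_floor = 1e-3) {
  stopifnot(inherits(curve, "smooth_curve"))
  x <- curve$x; f <- curve$fitted
  if (length(x) < 3) return(numeric(0))
  sl <- diff(f) / diff(x)
  out <- numeric(0)
  last_sign <- 0
  for (i in seq_along(sl)) {
    s <- sign(sl[i])
    if (abs(sl[i]) < noise_floor) next
    if (last_sign != 0 && s != last_sign) out <- c(out, x[i])
    last_sign <- s
  }
  out
}

#' Mean sleep score by NH-duration quartile
#'
#' Reporting bins for nightly NH<3.9 duration: Q0 (no NH), QI 1--45 min,
#' QII 46--90, QIII 91--150, QIV > 150. Q0 equals the set of nights
#' without NH.
#'
#' @param night_table a [night_metrics_table()] result.
#' @return data frame with per-bin `n`, `mean_score`, `sd_score`.
#' @export
quartile_sleep_table <- function(night_table) {
  q <- factor(night_table$duration_quartile,
              levels = c("Q0", "QI", "QII", "QIII", "QIV"))
  sp <- split(night_table$score, q)
  data.frame(quartile = levels(q),
             n = vapply(sp, length, integer(1)),
             mean_score = vapply(sp, function(s) if (length(s)) mean(s) else NA_real_,
                                 numeric(1)),
             sd_score = vapply(sp, function(s) if (length(s) > 1) sd(s) else NA_real_,
                               numeric(1)),
             row.names = NULL)
}

PIPELINE_EXPOSURES <- c(nh39_presence = "nh39_present",
                        nh39_episodes = "nh39_episodes",
                        nh39_duration = "nh39_duration",
                        nh39_auc = "nh39_auc",
                        nh30_presence = "nh30_present",
                        nh30_episodes = "nh30_episodes",
                        nh30_duration = "nh30_duration",
                        nh30_auc = "nh30_auc",
                        mean_glucose = "nocturnal_mean",
                        cv = "nocturnal_cv",
                        tir = "nocturnal_tir")

#' Run the full analysis pipeline
#'
#' Orchestrates: night pairing and QC -> per-night metrics -> stratified
#' comparisons and Gold-score correlations -> one adjusted
#' proportional-odds mixed fit per glycemic exposure -> LOWESS of sleep
#' score on nocturnal mean glucose with inflection detection -> sensor
#' accuracy (MARD, Clarke and Parkes grids). Exposures that cannot be
#' fitted (zero variance, e.g. a cohort without any NH night) are skipped
#' with an explicit note, never silently.
#'
#' @param cgm,sleep,participants,capillary the four canonical inputs
#'   (data frames as returned by the readers / the synthetic generator).
#' @param lowess_frac LOWESS bandwidth fraction.
#' @param nq quadrature nodes for the ordinal fits.
#' @param exposures named vector mapping report labels to night-table
#'   columns; duration exposures are rescaled to 15-min steps for
#'   reporting.
#' @param out_dir if non-NULL, `nights.csv`, `results.json` and
#'   `report.md` are written there.
#' @return results bundle (list), invisibly the same if written.
#' @export
run_pipeline <- function(cgm, sleep, participants, capillary = NULL,
                         lowess_frac = 0.8, nq = 15,
                         exposures = PIPELINE_EXPOSURES, out_dir = NULL) {
  nights <- night_metrics_table(cgm, sleep, participants)
  drops <- attr(nights, "drops")

  comparisons <- if (sum(nights$level_class == "level1_only") >= 2 &&
                       sum(nights$level_class == "level2") >= 2)
    compare_nights(nights[nights$nh39_present, , drop = FALSE])
  else structure(list(), note = "insufficient NH nights for stratified comparison")

  gold <- correlate_gold(nights)
  quartiles <- quartile_sleep_table(nights)

  fits <- list()
  for (lab in names(exposures)) {
    col <- exposures[[lab]]
    scale_div <- if (grepl("duration", col)) CADENCE_MIN else 1
    dat <- nights
    dat$exposure_val <- as.numeric(dat[[col]]) / scale_div
    f <- tryCatch({
      fit <- fit_ordinal_mixed(dat, outcome = "score",
                               exposure = "exposure_val",
                               adjust = c("age", "sex_female"), nq = nq)
      orr <- odds_ratio(fit, "exposure_val")
      list(exposure = lab, or = orr$or, lo = orr$lo, hi = orr$hi,
           beta = unname(fit$betas[["exposure_val"]]),
           se = unname(fit$se[["exposure_val"]]),
           sigma_u = fit$sigma_u, loglik = fit$loglik,
           converged = fit$converged, n_obs = fit$n_obs,
           n_groups = fit$n_groups)
    }, error = function(e) list(exposure = lab, skipped = TRUE,
                                note = conditionMessage(e)))
    fits[[lab]] <- f
  }

  curve <- lowess_curve(nights$nocturnal_mean, nights$score, frac = lowess_frac)
  inflections <- find_inflections(curve)

  accuracy <- NULL
  if (!is.null(capillary)) {
    pairs <- pair_readings(capillary, cgm)
    accuracy <- list(clarke = zone_summary(pairs, grid = "clarke"),
                     parkes = zone_summary(pairs, grid = "parkes_t1"))
  }

  bundle <- list(
    n_nights = nrow(nights),
    n_participants = length(unique(nights$participant_id)),
    nh39_rate = mean(nights$nh39_present),
    n_dropped = if (is.null(drops)) 0L else nrow(drops),
    mean_score_nh = if (any(nights$nh39_present))
      mean(nights$score[nights$nh39_present]) else NA,
    mean_score_no_nh = mean(nights$score[!nights$nh39_present]),
    comparisons = comparisons,
    gold_correlations = gold,
    quartile_scores = quartiles,
    ordinal_fits = fits,
    lowess = list(x = curve$x, fitted = curve$fitted, frac = curve$frac,
                  inflections = inflections),
    accuracy = accuracy)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.csv(nights, file.path(out_dir, "nights.csv"), row.names = FALSE)
    jsonlite::write_json(strip_classes(bundle),
                         file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    writeLines(render_report(bundle), file.path(out_dir, "report.md"))
  }
  bundle$nights <- nights
  invisible(bundle)
}

# jsonlite serialises plain lists/frames predictably; drop S3 classes
strip_classes <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(unclass(x)))
  if (is.list(x)) {
    attributes(x) <- attributes(x)["names"]
    return(lapply(x, strip_classes))
  }
  x
}

render_report <- function(b) {
  l <- c("# Nocturnal hypoglycemia and sleep quality: analysis report", "",
         sprintf("- Nights analysed: %d from %d participants (%d dropped)",
                 b$n_nights, b$n_participants, b$n_dropped),
         sprintf("- Nights with NH < 3.9 mmol/L: %.1f%%", 100 * b$nh39_rate),
         sprintf("- Mean sleep score, NH vs no-NH nights: %.2f vs %.2f",
                 b$mean_score_nh, b$mean_score_no_nh), "",
         "## Adjusted odds ratios (per exposure, age/sex adjusted)", "")
  for (f in b$ordinal_fits) {
    l <- c(l, if (isTRUE(f$skipped))
      sprintf("- %s: skipped (%s)", f$exposure, f$note)
      else sprintf("- %s: OR %.3f (95%% CI %.3f, %.3f)%s",
                   f$exposure, f$or, f$lo, f$hi,
                   if (f$converged) "" else " [non-converged]"))
  }
  l <- c(l, "", "## Sleep score by NH duration quartile", "")
  q <- b$quartile_scores
  for (i in seq_len(nrow(q)))
    l <- c(l, sprintf("- %s: n=%d, mean %.2f (SD %.2f)", q$quartile[i],
                      q$n[i], q$mean_score[i], q$sd_score[i]))
  l <- c(l, "",
         sprintf("## LOWESS inflections (nocturnal mean glucose): %s",
                 if (length(b$lowess$inflections))
                   paste(sprintf("%.2f", b$lowess$inflections), collapse = ", ")
                 else "none"))
  if (!is.null(b$accuracy))
    l <- c(l, "", sprintf("## Sensor accuracy: MARD %.2f%% over %d pairs",
                          b$accuracy$clarke$mard, b$accuracy$clarke$n_pairs))
  l
}
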