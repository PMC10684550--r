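test_that("the running-line smoother is exact on linear data", {
  set.seed(71)
  x <- sort(runif(60, 0, 10))
  y <- 2 * x + 1
  for (frac in c(0.2, 0.5, 0.8, 1)) {
    cv <- lowess_curve(x, y, frac = frac)
    expect_lt(max(abs(cv$fitted - (2 * cv$x + 1))), 1e-8)
  }
  expect_error(lowess_curve(x[1:5], y[1:5]), "at least 10")
  expect_error(lowess_curve(x, y, frac = 0.02), "frac too small")
})

test_that("frac = 1 equals a pointwise global tricube-weighted least squares fit", {
  set.seed(72)
  x <- sort(runif(40, 0, 10))
  y <- sin(x) + rnorm(40, 0, 0.2)
  cv <- lowess_curve(x, y, frac = 1)
  for (i in seq_along(cv$x)) {
    d <- abs(x - cv$x[i])
    w <- (1 - (d / max(d))^3)^3
    fitw <- lm(y ~ x, weights = w)
    expect_equal(cv$fitted[i],
                 unname(predict(fitw, data.frame(x = cv$x[i]))),
                 tolerance = 1e-10)
  }
})

test_that("the smoother tracks stats::lowess on smooth data", {
  set.seed(73)
  x <- sort(runif(200, 0, 10))
  y <- sin(x) + rnorm(200, 0, 0.1)
  cv <- lowess_curve(x, y, frac = 0.3)
  ref <- lowess(x, y, f = 0.3, iter = 0, delta = 0)
  expect_lt(mean(abs(cv$fitted - ref$y[match(cv$x, ref$x)])), 0.02)
})

test_that("inflection detection finds planted slope sign changes", {
  # V shape: one sign change at the vertex
  x <- seq(0, 10, length.out = 80)
  v <- lowess_curve(x, abs(x - 5), frac = 0.2)
  inf_v <- find_inflections(v)
  expect_equal(length(inf_v), 1)
  expect_lt(abs(inf_v - 5), diff(range(x)) / 79 * 2)

  # monotone -> none
  m <- lowess_curve(x, x^1.5, frac = 0.3)
  expect_length(find_inflections(m), 0)

  # rise-fall with mode at 16.8 -> one inflection within one grid step
  xg <- seq(2, 25, by = 0.25)
  yg <- -(xg - 16.8)^2
  rf <- lowess_curve(xg, yg, frac = 0.2)
  infl <- find_inflections(rf)
  expect_equal(length(infl), 1)
  expect_lte(abs(infl - 16.8), 0.25 + 1e-9)

  # fall-rise-fall -> two inflections in order
  y3 <- sin(xg / 4)
  frf <- lowess_curve(xg, -y3, frac = 0.15)
  i3 <- find_inflections(frf)
  expect_equal(length(i3), 2)
  expect_true(all(diff(i3) > 0))

  # flat curve under the noise floor -> nothing
  flat <- lowess_curve(x, rep(1, 80) + rnorm(80, 0, 1e-6), frac = 0.5)
  expect_length(find_inflections(flat), 0)
})

fake_night_table <- function(n1, n2, dur1, dur2, seed = 1) {
  set.seed(seed)
  data.frame(
    participant_id = rep(c("A", "B", "C"), length.out = n1 + n2),
    level_class = c(rep("level1_only", n1), rep("level2", n2)),
    nh39_present = TRUE,
    nh39_duration = c(dur1, dur2),
    nh39_auc = c(dur1, dur2) * 0.3,
    nh39_episodes = rbinom(n1 + n2, 1, 0.1) + 1L,
    nocturnal_mean = rnorm(n1 + n2, 6, 1),
    nocturnal_cv = rnorm(n1 + n2, 30, 5),
    nocturnal_tir = pmin(100, pmax(0, rnorm(n1 + n2, 60, 15))),
    score = sample(1:5, n1 + n2, replace = TRUE),
    stringsAsFactors = FALSE)
}

test_that("stratified night comparisons pick tests by normality and detect planted effects", {
  set.seed(81)
  nt <- fake_night_table(120, 80,
                         dur1 = 15 * rpois(120, 5),
                         dur2 = 15 * rpois(80, 10))
  cmp <- compare_nights(nt)
  dur <- cmp$nh39_duration
  expect_true(dur$test %in% c("t", "kruskal_wallis"))
  expect_lt(dur$p_value, 0.001)
  expect_gt(dur$summaries[[2]]$median, dur$summaries[[1]]$median)
  # normally distributed metric with no effect: t test chosen, p not tiny
  cvr <- cmp$nocturnal_cv
  expect_equal(cvr$test, "t")
  # proportions compared by chi-squared
  expect_equal(cmp$nh39_episodes$test, "chi_squared")
  expect_true(cmp$nh39_episodes$p_value >= 0 && cmp$nh39_episodes$p_value <= 1)
})

test_that("null strata give approximately uniform p-values", {
  set.seed(82)
  pvals <- replicate(150, {
    nt <- fake_night_table(30, 30, dur1 = 15 * rpois(30, 6),
                           dur2 = 15 * rpois(30, 6), seed = sample.int(1e6, 1))
    suppressWarnings(compare_nights(nt))$nh39_duration$p_value
  })
  frac <- mean(pvals < 0.05)
  expect_gt(frac, 0.0)
  expect_lt(frac, 0.13)
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals), 0.65)
})

test_that("Gold-score correlations report Spearman rho with degenerate handling", {
  nt <- fake_night_table(50, 50, dur1 = 15 * (1:50), dur2 = 15 * (51:100))
  nt$gold_score <- nt$nh39_duration / 15  # perfectly monotone
  g <- correlate_gold(nt, metrics = "nh39_duration")
  expect_equal(g$rho, 1)

  nt$gold_score <- 2
  g2 <- correlate_gold(nt, metrics = "nh39_duration")
  expect_true(is.na(g2$rho))
  expect_equal(g2$note, "constant input")

  # independent draws: small rho, unremarkable p
  set.seed(83)
  nt$gold_score <- sample(1:4, 100, replace = TRUE)
  nt$nh39_duration <- 15 * rpois(100, 6)
  g3 <- correlate_gold(nt, metrics = "nh39_duration")
  expect_lt(abs(g3$rho), 0.3)
})

test_that("a planted weak Gold association near rho = 0.11 is detectable at study scale", {
  # generator knob tilts nightly NH probability with gold score
  co <- generate_cohort(synthetic_config(seed = 55, gold_hypo_gamma = 0.35,
                                         n_participants = 27,
                                         nights_per_participant = 28))
  nt <- night_metrics_table(co$cgm, co$sleep, co$participants)
  g <- correlate_gold(nt, metrics = "nh39_episodes")
  expect_gt(g$rho, 0.02)
  expect_lt(g$rho, 0.25)
})

test_that("quartile summary separates the no-NH bin from duration quartiles", {
  co <- small_cohort(seed = 19, n = 8, nights = 20)
  nt <- night_metrics_table(co$cgm, co$sleep, co$participants)
  q <- quartile_sleep_table(nt)
  expect_equal(q$quartile, c("Q0", "QI", "QII", "QIII", "QIV"))
  expect_equal(q$n[1], sum(!nt$nh39_present))
  expect_equal(sum(q$n), nrow(nt))
})

test_that("the pipeline produces all report sections and flags degenerate cohorts", {
  co <- small_cohort(seed = 23, n = 10, nights = 15)
  out <- run_pipeline(co$cgm, co$sleep, co$participants, co$capillary, nq = 5)
  expect_true(all(c("comparisons", "gold_correlations", "quartile_scores",
                    "ordinal_fits", "lowess", "accuracy") %in% names(out)))
  expect_equal(length(out$ordinal_fits), length(noctglu:::PIPELINE_EXPOSURES))
  expect_true(is.numeric(out$accuracy$clarke$mard))

  # zero-NH cohort: NH fits skipped with explicit notes
  co0 <- generate_cohort(synthetic_config(n_participants = 6,
                                          nights_per_participant = 10,
                                          hypo_night_prob = 0, seed = 2))
  out0 <- run_pipeline(co0$cgm, co0$sleep, co0$participants, nq = 5)
  expect_true(isTRUE(out0$ordinal_fits$nh39_presence$skipped))
  expect_match(out0$ordinal_fits$nh39_presence$note, "zero variance")
  expect_false(isTRUE(out0$ordinal_fits$mean_glucose$skipped))
})
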