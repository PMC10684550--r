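test_that("CGM CSV parsing validates, sorts and rejects duplicates", {
  df <- rbind(make_night_df(c(5.1, 6.2, 7.0), id = "A"),
              make_night_df(c(4.4, 4.5, 4.6), id = "B"))
  f <- tmpfile()
  write_cgm_csv(df, f)
  got <- read_cgm_csv(f)
  expect_equal(nrow(got), 6)
  expect_equal(sort(unique(got$participant_id)), c("A", "B"))
  expect_equal(got$glucose_mmol_l[got$participant_id == "B"], c(4.4, 4.5, 4.6))

  # unsorted rows come back sorted per participant
  write_cgm_csv(df[c(3, 1, 2, 6, 5, 4), ], f)
  got2 <- read_cgm_csv(f)
  expect_false(is.unsorted(got2$timestamp[got2$participant_id == "A"]))
  expect_equal(got2, got)

  # duplicate (participant, timestamp) named in the error
  write_cgm_csv(df[c(1, 1, 2), ], f)
  expect_error(read_cgm_csv(f), "duplicate.*A")

  # malformed timestamp names its row
  writeLines(c("participant_id,timestamp,glucose_mmol_l",
               "A,2024-03-01T00:00:00,5.0",
               "A,not-a-time,5.1"), f)
  expect_error(read_cgm_csv(f), "row 2")

  # non-positive and non-physiologic glucose rejected
  writeLines(c("participant_id,timestamp,glucose_mmol_l",
               "A,2024-03-01T00:00:00,-1"), f)
  expect_error(read_cgm_csv(f), "non-positive")
  writeLines(c("participant_id,timestamp,glucose_mmol_l",
               "A,2024-03-01T00:00:00,42"), f)
  expect_error(read_cgm_csv(f), "physiologic")
})

test_that("sleep diary parsing enforces the 1-5 score range and dates", {
  f <- tmpfile()
  ok <- data.frame(participant_id = "A",
                   date = as.Date("2024-03-01") + 0:4, score = c(1L, 2L, 3L, 4L, 5L))
  write_sleep_csv(ok, f)
  got <- read_sleep_csv(f)
  expect_equal(nrow(got), 5)
  expect_equal(got$score, 1:5)

  writeLines(c("participant_id,date,score", "A,2024-03-01,6"), f)
  expect_error(read_sleep_csv(f), "outside 1-5")
  writeLines(c("participant_id,date,score", "A,2024-03-01,0"), f)
  expect_error(read_sleep_csv(f), "outside 1-5")
  writeLines(c("participant_id,date,score", "A,2024-03-01,3",
               "A,03/2024/99,4"), f)
  expect_error(read_sleep_csv(f), "row 2")
})

test_that("participant table validation catches out-of-range fields", {
  p <- data.frame(participant_id = "A", age = 30L, sex = "female",
                  gold_score = 2L, dafne_score = 1L, treatment = "MDI",
                  stringsAsFactors = FALSE)
  f <- tmpfile()
  write_participants_csv(p, f)
  expect_equal(read_participants_csv(f)$age, 30L)
  for (mut in list(list(col = "age", val = 0),
                   list(col = "sex", val = "F"),
                   list(col = "gold_score", val = 8),
                   list(col = "dafne_score", val = 0),
                   list(col = "treatment", val = "pen"))) {
    bad <- p
    bad[[mut$col]] <- mut$val
    write_participants_csv(bad, f)
    expect_error(read_participants_csv(f))
  }
})

test_that("trace and diary CSV round-trips are exact", {
  co <- small_cohort(seed = 11, n = 3, nights = 4)
  f1 <- tmpfile(); f2 <- tmpfile()
  write_cgm_csv(co$cgm, f1)
  back <- read_cgm_csv(f1)
  expect_equal(back$glucose_mmol_l, co$cgm$glucose_mmol_l)
  expect_equal(as.numeric(back$timestamp), as.numeric(co$cgm$timestamp))
  write_cgm_csv(back, f2)
  expect_identical(readLines(f1), readLines(f2))

  fs <- tmpfile()
  write_sleep_csv(co$sleep, fs)
  sback <- read_sleep_csv(fs)
  expect_equal(sback$score, co$sleep$score)
  expect_equal(sback$date, co$sleep$date)
})

test_that("night/score pairing matches morning scores to the night ending then", {
  cgm <- do.call(rbind, lapply(0:2, function(d)
    make_night_df(rep(5.5, 24), date = as.Date("2024-03-01") + d)))
  sleep3 <- data.frame(participant_id = "P1",
                       date = as.Date("2024-03-01") + 0:2, score = c(3L, 4L, 5L))
  out <- pair_by_night(cgm, sleep3)
  expect_equal(nrow(out), 3)
  expect_equal(out$score, c(3L, 4L, 5L))
  expect_equal(out$n_readings, rep(24L, 3))

  # 3 nights, 2 scores -> 2 rows and a logged drop for the scoreless night
  out2 <- pair_by_night(cgm, sleep3[1:2, ])
  expect_equal(nrow(out2), 2)
  drops <- attr(out2, "drops")
  expect_true(any(drops$reason == "night without sleep score"))

  # a score whose night fails QC is dropped, not matched
  short <- make_night_df(rep(5.5, 19), date = "2024-03-04")
  out3 <- pair_by_night(rbind(cgm, short),
                        rbind(sleep3, data.frame(participant_id = "P1",
                                                 date = as.Date("2024-03-04"),
                                                 score = 2L)))
  expect_equal(nrow(out3), 3)
  expect_true(any(attr(out3, "drops")$reason ==
                    "sleep score without qualifying night"))
})

test_that("pairing row count never exceeds nights or scores available", {
  co <- small_cohort(seed = 3)
  out <- pair_by_night(co$cgm, co$sleep)
  n_nights <- length(unique(paste(co$cgm$participant_id,
                                  as.Date(co$cgm$timestamp))))
  expect_lte(nrow(out), min(n_nights, nrow(co$sleep)))
  expect_equal(nrow(out), nrow(co$sleep))  # complete synthetic cohort matches fully
})
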