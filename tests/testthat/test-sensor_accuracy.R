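cap_df <- function(times, values, id = "P1")
  data.frame(participant_id = id,
             timestamp = as.POSIXct(times, tz = "UTC"),
             glucose_mmol_l = values, stringsAsFactors = FALSE)

test_that("capillary readings pair to the nearest sensor reading within 3 min", {
  sen <- cap_df(c("2024-03-01 10:05:00", "2024-03-01 10:20:00"), c(5.0, 6.0))
  cap <- cap_df("2024-03-01 10:07:00", 5.5)
  p <- pair_readings(cap, sen)
  expect_equal(nrow(p), 1)
  expect_equal(p$sensor, 5.0)   # 2 min beats 13 min
  expect_equal(p$time_gap, 2)

  # nearest gap over the cutoff -> no pair
  cap2 <- cap_df("2024-03-01 10:09:00", 5.5)
  sen2 <- cap_df(c("2024-03-01 10:05:00", "2024-03-01 10:13:00"), c(5, 6))
  expect_equal(nrow(pair_readings(cap2, sen2)), 0)

  # pairing is within-participant
  capx <- cap_df("2024-03-01 10:06:00", 5.5, id = "P2")
  expect_equal(nrow(pair_readings(capx, sen)), 0)
})

test_that("pairing agrees with an exhaustive search oracle", {
  set.seed(91)
  t0 <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC")
  sen <- data.frame(participant_id = "P1",
                    timestamp = t0 + sort(sample.int(72 * 3600, 300)),
                    glucose_mmol_l = runif(300, 3, 15))
  cap <- data.frame(participant_id = "P1",
                    timestamp = t0 + sort(sample.int(72 * 3600, 80)),
                    glucose_mmol_l = runif(80, 3, 15))
  got <- pair_readings(cap, sen)
  # O(n*m) oracle
  st <- as.numeric(sen$timestamp)
  oracle <- lapply(seq_len(nrow(cap)), function(i) {
    d <- abs(as.numeric(cap$timestamp[i]) - st)
    j <- which.min(d)
    if (d[j] / 60 <= 3) data.frame(capillary = cap$glucose_mmol_l[i],
                                   sensor = sen$glucose_mmol_l[j],
                                   time_gap = d[j] / 60) else NULL
  })
  oracle <- do.call(rbind, oracle)
  expect_equal(nrow(got), nrow(oracle))
  expect_equal(got$sensor, oracle$sensor)
  expect_equal(got$time_gap, oracle$time_gap)
})

test_that("MARD follows the capillary-denominator formula", {
  expect_equal(mard(data.frame(capillary = c(5, 6), sensor = c(5, 6))), 0)
  expect_equal(mard(data.frame(capillary = 5.0, sensor = 4.5)), 10.0)
  expect_equal(mard(data.frame(capillary = 4.0, sensor = 5.0)), 25.0)
  expect_error(mard(data.frame(capillary = numeric(0), sensor = numeric(0))),
               "no pairs")
  expect_error(mard(data.frame(capillary = -1, sensor = 5)), "positive")
  # scale invariance
  set.seed(92)
  cp <- runif(50, 3, 12); sn <- cp * (1 + rnorm(50, 0, 0.1))
  m1 <- mard(data.frame(capillary = cp, sensor = sn))
  m2 <- mard(data.frame(capillary = 7 * cp, sensor = 7 * sn))
  expect_equal(m1, m2)
})

test_that("Clarke zones honor the published rules", {
  mgdl <- function(x) x / 18.016
  # identity diagonal -> A everywhere
  ref <- mgdl(seq(20, 500, by = 20))
  expect_true(all(clarke_zone(ref, ref) == "A"))
  # within 20% of reference -> A
  expect_equal(clarke_zone(mgdl(100), mgdl(115)), "A")
  expect_equal(clarke_zone(mgdl(100), mgdl(120)), "A")  # boundary tie favors A
  expect_equal(clarke_zone(mgdl(100), mgdl(125)), "B")
  # hypo reported during true hyperglycemia -> E
  expect_equal(clarke_zone(mgdl(200), mgdl(60)), "E")
  expect_equal(clarke_zone(mgdl(60), mgdl(200)), "E")
  # both under 70 mg/dL -> A regardless of error
  expect_equal(clarke_zone(mgdl(60), mgdl(30)), "A")
  # overcorrection region -> C
  expect_equal(clarke_zone(mgdl(150), mgdl(300)), "C")
  # dangerous failure-to-detect -> D
  expect_equal(clarke_zone(mgdl(250), mgdl(100)), "D")
  expect_error(clarke_zone(-1, 5), "positive")
})

test_that("Clarke severity never improves moving away from the diagonal", {
  sev <- function(z) match(z, c("A", "B", "C", "D", "E"))
  mgdl <- function(x) x / 18.016
  up_ray <- clarke_zone(mgdl(100), mgdl(seq(100, 350, by = 5)))
  expect_true(all(diff(sev(up_ray)) >= 0))
  down_ray <- clarke_zone(mgdl(300), mgdl(seq(300, 20, by = -5)))
  expect_true(all(diff(sev(down_ray)) >= 0))
})

test_that("Parkes type 1 zones follow the published boundary polygons", {
  mgdl <- function(x) x / 18.016
  ref <- mgdl(seq(20, 540, by = 20))
  expect_true(all(parkes_zone(ref, ref) == "A"))
  # point between the A-B and B-C boundaries
  expect_equal(parkes_zone(mgdl(200), mgdl(300)), "B")
  # beyond the B-C boundary
  expect_equal(parkes_zone(mgdl(200), mgdl(450)), "C")
  # top-left extreme: low reference, very high estimate
  expect_equal(parkes_zone(mgdl(30), mgdl(200)), "E")
  # lower-right: high reference, very low estimate
  expect_equal(parkes_zone(mgdl(450), mgdl(60)), "D")
  # just above / below the A-B upper boundary vertex (140, 170)
  expect_equal(parkes_zone(mgdl(140), mgdl(169)), "A")
  expect_equal(parkes_zone(mgdl(140), mgdl(171)), "B")
  # edge tie goes to the better zone
  expect_equal(parkes_zone(mgdl(140), mgdl(170)), "A")
  expect_error(parkes_zone(0, 5), "positive")
})

test_that("both grids partition the measurement plane with one zone per point", {
  g <- seq(0.15, 30, length.out = 200)
  lattice <- expand.grid(ref = g, est = g)
  for (fun in list(clarke_zone, parkes_zone)) {
    z <- fun(lattice$ref, lattice$est)
    expect_equal(length(z), nrow(lattice))
    expect_true(all(z %in% c("A", "B", "C", "D", "E")))
    expect_false(anyNA(z))
  }
})

test_that("zone summaries count every pair once and percentages sum to 100", {
  co <- small_cohort(seed = 29)
  pairs <- pair_readings(co$capillary, co$cgm)
  expect_gt(nrow(pairs), 400)
  for (grid in c("clarke", "parkes_t1")) {
    zs <- zone_summary(pairs, grid = grid)
    expect_equal(sum(unlist(zs$counts)), zs$n_pairs)
    expect_equal(sum(unlist(zs$percent)), 100)
    expect_gt(zs$percent$A, 50)  # well-calibrated synthetic sensor
  }
})
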