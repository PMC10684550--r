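#' @title Sensor accuracy: pairing, MARD and error grids
#' @name sensor_accuracy
#' @description
#' Capillary meter readings are matched to the nearest-in-time sensor
#' reading (within 3 min by default; a sensor reading may serve several
#' capillary readings). Accuracy is summarised as the mean absolute
#' relative difference (MARD, capillary in the denominator) and as Clarke
#' and Parkes (consensus, type 1 diabetes) error-grid zone distributions.
#' Grids are defined in mg/dL; mmol/L inputs are converted with the
#' factor 18.016 (glucose molar mass). Boundary ties are deterministic:
#' Parkes edge points go to the more favorable (earlier-letter) zone;
#' Clarke follows the canonical rule order (A checked first, then E, C,
#' D), so ties with zone A are always favorable.
NULL

MGDL_PER_MMOL <- 18.016

#' Pair capillary readings with the nearest sensor readings
#'
#' @param capillary,sensor data frames with `participant_id`, `timestamp`,
#'   `glucose_mmol_l` (sorted or not). Pairing is within participant.
#' @param max_gap_min maximum |time difference| in minutes (default 3).
#' @return data frame `participant_id`, `capillary`, `sensor`,
#'   `time_gap` (minutes); capillary readings with no sensor reading
#'   within the gap are dropped.
#' @export
pair_readings <- function(capillary, sensor, max_gap_min = 3) {
  out <- list()
  for (pid in unique(capillary$participant_id)) {
    cap <- capillary[capillary$participant_id == pid, , drop = FALSE]
    sen <- sensor[sensor$participant_id == pid, , drop = FALSE]
    if (!nrow(sen)) next
    sen <- sen[order(sen$timestamp), , drop = FALSE]
    st <- as.numeric(sen$timestamp)
    ct <- as.numeric(cap$timestamp)
    pos <- findInterval(ct, st)
    lo <- pmax(pos, 1L)
    hi <- pmin(pos + 1L, length(st))
    d_lo <- abs(ct - st[lo])
    d_hi <- abs(ct - st[hi])
    nearest <- ifelse(d_hi < d_lo, hi, lo)
    gap <- pmin(d_lo, d_hi) / 60
    keep <- gap <= max_gap_min
    if (any(keep))
      out[[pid]] <- data.frame(participant_id = pid,
                               capillary = cap$glucose_mmol_l[keep],
                               sensor = sen$glucose_mmol_l[nearest[keep]],
                               time_gap = gap[keep],
                               stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(participant_id = character(0), capillary = numeric(0),
                      sensor = numeric(0), time_gap = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean absolute relative difference (MARD)
#'
#' mean over pairs of |capillary - sensor| / capillary x 100. The
#' denominator is the capillary reference, so the measure is asymmetric
#' in its arguments and scale-invariant.
#'
#' @param pairs data frame with `capillary` and `sensor` columns
#'   (mmol/L), e.g. from [pair_readings()].
#' @return MARD in percent.
#' @export
mard <- function(pairs) {
  if (!nrow(pairs)) stop("mard: no pairs")
  if (any(pairs$capillary <= 0)) stop("mard: capillary values must be positive")
  mean(abs(pairs$capillary - pairs$sensor) / pairs$capillary) * 100
}

#' Clarke error grid zone
#'
#' Implements the published Clarke (1987) zone rules as recommended by
#' Clarke and Kovatchev: zone A when reference and estimate are both
#' below 70 mg/dL or the estimate is within 20% of the reference; zone E
#' for hypoglycemia reported during true hyperglycemia and vice versa;
#' zones C and D per the published boundary lines; everything else B.
#' Points exactly on a boundary are resolved deterministically by the
#' canonical rule order: the A condition is checked first (so ties with A
#' are favorable), then E, C, D, with B as the residual.
#'
#' @param reference,estimate glucose in mmol/L (vectors recycled).
#' @return character vector of zones `A`--`E`.
#' @export
clarke_zone <- function(reference, estimate) {
  if (any(reference <= 0) || any(estimate <= 0))
    stop("glucose values must be positive")
  r <- reference * MGDL_PER_MMOL
  e <- estimate * MGDL_PER_MMOL
  n <- max(length(r), length(e))
  r <- rep_len(r, n); e <- rep_len(e, n)
  zone <- character(n)
  inA <- (r <= 70 & e <= 70) | (abs(e - r) <= 0.2 * r)
  inE <- !inA & ((r >= 180 & e <= 70) | (r <= 70 & e >= 180))
  inC <- !inA & !inE &
    ((r >= 70 & r <= 290 & e >= r + 110) |
       (r >= 130 & r <= 180 & e <= (7 / 5) * r - 182))
  inD <- !inA & !inE & !inC &
    ((r >= 240 & e >= 70 & e <= 180) |
       (r <= 175 / 3 & e <= 180 & e >= 70) |
       (r >= 175 / 3 & r <= 70 & e >= (6 / 5) * r))
  zone[inA] <- "A"; zone[inE] <- "E"; zone[inC] <- "C"; zone[inD] <- "D"
  zone[zone == ""] <- "B"
  zone
}

# Parkes consensus error grid, type 1 diabetes: published boundary
# vertices in mg/dL (reference, estimate). Upper boundaries separate a
# zone from the zone above the diagonal; lower boundaries below it.
# Boundaries extend past the last vertex with the final segment's slope;
# lower boundaries are undefined (no region) left of their first vertex.
PARKES_T1 <- list(
  e_up = cbind(c(0, 35, 50),              c(150, 155, 550)),
  d_up = cbind(c(0, 25, 50, 80, 125),     c(100, 100, 125, 215, 550)),
  d_lo = cbind(c(250, 550),               c(40, 150)),
  c_up = cbind(c(0, 30, 50, 70, 260),     c(60, 60, 80, 110, 550)),
  c_lo = cbind(c(120, 260, 550),          c(30, 130, 250)),
  b_up = cbind(c(0, 30, 140, 280, 430),   c(50, 50, 170, 380, 550)),
  b_lo = cbind(c(50, 170, 385, 550),      c(30, 145, 300, 450))
)

# piecewise-linear boundary value at reference x; extended by final slope;
# -Inf (lower) / +Inf-like behaviour handled by caller via NA
parkes_boundary <- function(verts, x, lower = FALSE) {
  vx <- verts[, 1]; vy <- verts[, 2]
  nseg <- length(vx)
  y <- approx(vx, vy, xout = pmin(x, vx[nseg]), rule = 2)$y
  beyond <- x > vx[nseg]
  if (any(beyond)) {
    slope <- (vy[nseg] - vy[nseg - 1]) / (vx[nseg] - vx[nseg - 1])
    y[beyond] <- vy[nseg] + slope * (x[beyond] - vx[nseg])
  }
  if (lower) y[x < vx[1]] <- -Inf
  y
}

#' Parkes (consensus) error grid zone, type 1 diabetes
#'
#' Point-in-region test against the published type-1-diabetes consensus
#' grid boundaries. Edge ties go to the more favorable zone.
#'
#' @inheritParams clarke_zone
#' @return character vector of zones `A`--`E` (`E` exists only above the
#'   diagonal in the type 1 grid).
#' @export
parkes_zone <- function(reference, estimate) {
  if (any(reference <= 0) || any(estimate <= 0))
    stop("glucose values must be positive")
  r <- reference * MGDL_PER_MMOL
  e <- estimate * MGDL_PER_MMOL
  n <- max(length(r), length(e))
  r <- rep_len(r, n); e <- rep_len(e, n)
  B <- PARKES_T1
  zone <- rep("A", n)
  in_b <- e > parkes_boundary(B$b_up, r) | e < parkes_boundary(B$b_lo, r, TRUE)
  in_c <- e > parkes_boundary(B$c_up, r) | e < parkes_boundary(B$c_lo, r, TRUE)
  in_d <- e > parkes_boundary(B$d_up, r) | e < parkes_boundary(B$d_lo, r, TRUE)
  in_e <- e > parkes_boundary(B$e_up, r)
  zone[in_b] <- "B"; zone[in_c] <- "C"; zone[in_d] <- "D"; zone[in_e] <- "E"
  zone
}

#' Error-grid zone distribution and MARD for a set of pairs
#'
#' @param pairs data frame with `capillary` (reference) and `sensor`
#'   (estimate) in mmol/L.
#' @param grid `"clarke"` or `"parkes_t1"`.
#' @return list of class `zone_summary`: `grid`, `n_pairs`, `counts`,
#'   `percent` (A--E, summing to 100), `mard`.
#' @export
zone_summary <- function(pairs, grid = c("clarke", "parkes_t1")) {
  grid <- match.arg(grid)
  zfun <- if (grid == "clarke") clarke_zone else parkes_zone
  z <- factor(zfun(pairs$capillary, pairs$sensor), levels = c("A", "B", "C", "D", "E"))
  counts <- table(z)
  structure(list(grid = grid, n_pairs = nrow(pairs),
                 counts = as.list(as.integer(counts)) |> setNames(names(counts)),
                 percent = as.list(100 * as.integer(counts) / nrow(pairs)) |>
                   setNames(names(counts)),
                 mard = mard(pairs)),
            class = "zone_summary")
}

#' @export
print.zone_summary <- function(x, ...) {
  cat(sprintf("%s error grid, %d pairs, MARD %.2f%%\n", x$grid, x$n_pairs, x$mard))
  for (z in names(x$counts))
    cat(sprintf("  zone %s: %4d (%5.1f%%)\n", z, x$counts[[z]], x$percent[[z]]))
  invisible(x)
}
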