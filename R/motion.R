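#' 1-Hz sensor time series
#'
#' Validated container for a depth or tri-axial acceleration record
#' sampled at (nominally) 1 Hz: time must be strictly increasing and
#' value columns numeric. Axes follow the logger convention X = anterior
#' to posterior, Y = port to starboard, Z = top to bottom.
#'
#' @param t time in seconds since record start, strictly increasing.
#' @param ... named numeric value columns of the same length as `t`, e.g.
#'   `depth` (m) or `ax`, `ay`, `az` (m s^-2).
#' @return data.frame of class `"sensor_series"`.
#' @export
sensor_series <- function(t, ...) {
  vals <- list(...)
  if (!is.numeric(t) || anyNA(t)) stop("t must be numeric without NA",
                                       call. = FALSE)
  if (length(t) > 1 && any(diff(t) <= 0)) {
    stop("t must be strictly increasing", call. = FALSE)
  }
  for (nm in names(vals)) {
    if (length(vals[[nm]]) != length(t)) {
      stop("column ", nm, " must match length(t)", call. = FALSE)
    }
  }
  structure(data.frame(t = t, vals), class = c("sensor_series",
                                               "data.frame"))
}

#' Total acceleration
#'
#' Euclidean norm of the three per-axis accelerometer readings,
#' `TA = sqrt(X^2 + Y^2 + Z^2)`, per sample. Non-finite inputs propagate
#' into the result and raise a warning rather than an error.
#'
#' @param x,y,z per-axis acceleration (m s^-2), equal-length vectors.
#' @return Vector of total acceleration (m s^-2).
#' @export
total_acceleration <- function(x, y, z) {
  stopifnot(length(x) == length(y), length(y) == length(z))
  ta <- sqrt(x^2 + y^2 + z^2)
  if (any(!is.finite(ta))) {
    warning("non-finite acceleration samples propagate into TA",
            call. = FALSE)
  }
  ta
}

#' Detect alternating peaks and valleys in a 1-Hz record
#'
#' Local maxima and minima with topographic prominence at least
#' `min_prominence`, thinned so that same-type extrema closer than
#' `min_separation` keep only the more extreme one, and finally forced to
#' strictly alternate (between two retained peaks only the deepest valley
#' survives, and vice versa). Flat-topped extrema (plateaus of tied
#' values) are timed at the plateau midpoint, the average of the tied
#' sample times.
#'
#' @param t sample times (s), strictly increasing.
#' @param x signal values (e.g. depth in m).
#' @param min_prominence minimum prominence, in signal units (default
#'   0.02, the scale of the depth logger's resolution).
#' @param min_separation minimum spacing in seconds between same-type
#'   extrema (default 2).
#' @return data.frame with columns `time`, `value`, `type`
#'   (`"peak"`/`"valley"`), strictly alternating in time; zero rows if the
#'   record is monotone.
#' @export
detect_extrema <- function(t, x, min_prominence = 0.02,
                           min_separation = 2) {
  stopifnot(length(t) == length(x))
  if (length(t) < 3) stop("need at least 3 samples", call. = FALSE)
  # collapse tied runs to their midpoint time
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  rv <- r$values
  rt <- (t[starts] + t[ends]) / 2
  n <- length(rv)
  if (n < 3) return(empty_extrema())

  mid <- 2:(n - 1)
  is_peak <- c(FALSE, rv[mid] > rv[mid - 1] & rv[mid] > rv[mid + 1], FALSE)
  is_valley <- c(FALSE, rv[mid] < rv[mid - 1] & rv[mid] < rv[mid + 1], FALSE)

  keep_peak <- which(is_peak)
  keep_peak <- keep_peak[prominence(rv, keep_peak) >= min_prominence]
  keep_valley <- which(is_valley)
  keep_valley <- keep_valley[prominence(-rv, keep_valley) >= min_prominence]

  ex <- rbind(
    if (length(keep_peak)) data.frame(time = rt[keep_peak],
                                      value = rv[keep_peak], type = "peak"),
    if (length(keep_valley)) data.frame(time = rt[keep_valley],
                                        value = rv[keep_valley],
                                        type = "valley"))
  if (is.null(ex) || nrow(ex) == 0) return(empty_extrema())
  ex <- ex[order(ex$time), ]

  ex <- thin_separation(ex, "peak", min_separation, decreasing = TRUE)
  ex <- thin_separation(ex, "valley", min_separation, decreasing = FALSE)
  ex <- enforce_alternation(ex)
  rownames(ex) <- NULL
  ex
}

empty_extrema <- function() {
  data.frame(time = numeric(0), value = numeric(0), type = character(0))
}

# topographic prominence of candidate extrema at indices idx of v (peaks;
# pass -v for valleys): height above the higher of the two key saddles
prominence <- function(v, idx) {
  vapply(idx, function(i) {
    h <- v[i]
    j <- i - 1
    lmin <- h
    while (j >= 1 && v[j] <= h) {
      lmin <- min(lmin, v[j]); j <- j - 1
    }
    j <- i + 1
    rmin <- h
    while (j <= length(v) && v[j] <= h) {
      rmin <- min(rmin, v[j]); j <- j + 1
    }
    h - max(lmin, rmin)
  }, numeric(1))
}

# among same-type extrema closer than min_sep, keep the more extreme
thin_separation <- function(ex, type, min_sep, decreasing) {
  rows <- which(ex$type == type)
  if (length(rows) < 2) return(ex)
  keep <- rep(TRUE, length(rows))
  ord <- order(ex$value[rows], decreasing = decreasing)
  for (i in ord) {
    if (!keep[i]) next
    close <- which(keep & abs(ex$time[rows] - ex$time[rows[i]]) < min_sep)
    close <- setdiff(close, i)
    keep[close] <- FALSE
  }
  drop <- rows[!keep]
  if (length(drop)) ex[-drop, , drop = FALSE] else ex
}

# strict peak/valley alternation: within a run of same-type extrema keep
# the single most extreme one
enforce_alternation <- function(ex) {
  repeat {
    same <- which(ex$type[-1] == ex$type[-nrow(ex)])
    if (!length(same)) break
    i <- same[1]
    pick_second <- if (ex$type[i] == "peak") {
      ex$value[i + 1] > ex$value[i]
    } else {
      ex$value[i + 1] < ex$value[i]
    }
    ex <- ex[-(if (pick_second) i else i + 1), , drop = FALSE]
  }
  ex
}

#' Summarise codend oscillation from a depth record
#'
#' Runs [detect_extrema()] on a depth trace and derives the peak-to-peak
#' amplitudes (absolute depth difference between consecutive alternating
#' extrema, in cm), the amplitude ratios (amplitude divided by the side
#' panel length; zero excursions are dropped), and the oscillation periods
#' (differences between successive peak times, in s).
#'
#' @param t sample times (s).
#' @param depth depth (m).
#' @param panel_cm side-panel length in cm; the tested codend's panel
#'   measured 99.6 cm.
#' @inheritParams detect_extrema
#' @return An object of class `"oscillation_summary"`: list with
#'   `extrema`, `amplitudes_cm`, `ratios`, `periods_s`, `panel_cm`.
#' @export
oscillation_summary <- function(t, depth, panel_cm = 99.6,
                                min_prominence = 0.02, min_separation = 2) {
  if (!is.numeric(panel_cm) || length(panel_cm) != 1 || is.na(panel_cm) ||
      panel_cm <= 0) {
    stop("panel_cm must be a positive length in cm", call. = FALSE)
  }
  ex <- detect_extrema(t, depth, min_prominence, min_separation)
  amp <- if (nrow(ex) >= 2) abs(diff(ex$value)) * 100 else numeric(0)
  amp <- amp[amp > 0]
  pk <- ex$time[ex$type == "peak"]
  structure(list(extrema = ex, amplitudes_cm = amp,
                 ratios = amp / panel_cm,
                 periods_s = if (length(pk) >= 2) diff(pk) else numeric(0),
                 panel_cm = panel_cm),
            class = "oscillation_summary")
}

#' @export
print.oscillation_summary <- function(x, ...) {
  cat("Codend oscillation:", sum(x$extrema$type == "peak"), "peak(s),",
      sum(x$extrema$type == "valley"), "valley(s)\n")
  if (length(x$ratios)) {
    cat(sprintf("  amplitude ratio: mean %.3f (panel %.1f cm)\n",
                mean(x$ratios), x$panel_cm))
  }
  if (length(x$periods_s)) {
    cat(sprintf("  period: mean %.2f s (n = %d)\n", mean(x$periods_s),
                length(x$periods_s)))
  }
  invisible(x)
}

#' Amplitude ratios of an oscillation summary
#'
#' Peak-to-peak excursions (cm) divided by the side-panel length (cm).
#'
#' @param summary an `"oscillation_summary"` object.
#' @return Numeric vector of dimensionless ratios.
#' @export
amplitude_ratio <- function(summary) {
  stopifnot(inherits(summary, "oscillation_summary"))
  summary$ratios
}

#' Oscillation periods of an oscillation summary
#'
#' Differences between successive peak times.
#'
#' @param summary an `"oscillation_summary"` object.
#' @return Numeric vector of periods (s).
#' @export
periods <- function(summary) {
  stopifnot(inherits(summary, "oscillation_summary"))
  summary$periods_s
}

#' Stable-depth segments of a towing record
#'
#' Greedy left-to-right segmentation into maximal non-overlapping
#' intervals over which the depth range stays within `max_range` (the
#' at-sea analysis used 0.5 m, because bottom depth drifts continually
#' during a tow) and that last at least `min_duration` seconds (default
#' 30 s, long enough to hold two oscillations at the longest period
#' observed at sea).
#'
#' @param t sample times (s).
#' @param depth depth (m).
#' @param max_range maximum allowed depth range within a segment (m).
#' @param min_duration minimum segment duration (s).
#' @return data.frame with columns `start`, `end`, `duration` (s) and
#'   `depth_range` (m); zero rows if no interval qualifies.
#' @export
stable_segments <- function(t, depth, max_range = 0.5, min_duration = 30) {
  stopifnot(length(t) == length(depth))
  n <- length(t)
  out <- list()
  i <- 1L
  while (i < n) {
    lo <- depth[i]; hi <- depth[i]
    j <- i
    while (j < n) {
      lo2 <- min(lo, depth[j + 1]); hi2 <- max(hi, depth[j + 1])
      if (hi2 - lo2 > max_range) break
      lo <- lo2; hi <- hi2; j <- j + 1L
    }
    if (t[j] - t[i] >= min_duration) {
      out[[length(out) + 1L]] <- data.frame(start = t[i], end = t[j],
                                            duration = t[j] - t[i],
                                            depth_range = hi - lo)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0), depth_range = numeric(0)))
  }
  do.call(rbind, out)
}

#' Trim the unstable ends of a haul record
#'
#' Drops the leading and trailing portions of a sensor record: for sea
#' hauls the first and last 60 s (setting and haul-back), for flume-tank
#' runs the first 300 s (flow stabilisation) with no trailing trim. Use
#' `lead`/`trail` directly for other conventions.
#'
#' @param series a `"sensor_series"` (or data.frame with a `t` column).
#' @param mode `"sea"` (60 s both ends) or `"flume"` (300 s lead only);
#'   ignored when `lead`/`trail` are given.
#' @param lead,trail seconds to drop from each end.
#' @return The trimmed series (possibly with zero rows, with a warning).
#' @export
trim_haul <- function(series, mode = c("sea", "flume"), lead = NULL,
                      trail = NULL) {
  mode <- match.arg(mode)
  if (is.null(lead)) lead <- if (mode == "sea") 60 else 300
  if (is.null(trail)) trail <- if (mode == "sea") 60 else 0
  t <- series$t
  keep <- t >= min(t) + lead & t <= max(t) - trail
  out <- series[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("record shorter than the trimmed margins; nothing remains",
            call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Ordinary least-squares trend
#'
#' Linear trend of a response against flow velocity (or any single
#' predictor), via [stats::lm()].
#'
#' @param x predictor (e.g. flow velocity in kt), at least 3 points.
#' @param y response (e.g. moving angle in degrees).
#' @return List with `slope`, `intercept`, `se_slope`, `se_intercept`,
#'   `r_squared`, `p_value` (slope t-test) and the underlying `lm` fit.
#' @export
ols_trend <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance in x", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       se_slope = sm$coefficients[2, 2],
       se_intercept = sm$coefficients[1, 2],
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       fit = fit)
}

#' Mean, SD, SEM and range of a sample
#'
#' Convenience descriptive summary used for the haul-level oscillation and
#' operations tables: arithmetic mean, sample SD (n - 1), standard error
#' of the mean, and range.
#'
#' @param x numeric vector.
#' @return Named list `mean`, `sd`, `sem`, `min`, `max`, `n` (`sd`/`sem`
#'   are NA for a single value).
#' @export
sample_stats <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  s <- if (n > 1) stats::sd(x) else NA_real_
  list(mean = mean(x), sd = s, sem = s / sqrt(n), min = min(x),
       max = max(x), n = n)
}
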