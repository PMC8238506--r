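# Analysis statistics for click-evoked tuning data: smoothing, halfwidth,
# 20-80% slopes, ITD-SNR, summation ratios, PSP latency, theta effect size,
# cue-map coordinates, per-cell averaging.

#' Three-point Hanning smoothing
#'
#' Convolution with the normalized three-point Hanning window
#' `[0.25, 0.5, 0.25]`.  Endpoints use the truncated window renormalized to
#' unit sum, so constant curves are preserved exactly.
#'
#' @param x Numeric vector (>= 3 points).
#' @return Smoothed vector of the same length.
#' @examples
#' hanning3_smooth(c(0, 4, 0))   # middle point 2
#' @export
hanning3_smooth <- function(x) {
  n <- length(x)
  if (n < 3) stop("too short: need at least 3 points")
  y <- x
  y[1] <- (0.5 * x[1] + 0.25 * x[2]) / 0.75
  y[n] <- (0.25 * x[n - 1] + 0.5 * x[n]) / 0.75
  i <- 2:(n - 1)
  y[i] <- 0.25 * x[i - 1] + 0.5 * x[i] + 0.25 * x[i + 1]
  y
}

# Linear-interpolated crossing of `level` between samples i and i+1.
cross_at <- function(x, y, i, level) {
  x[i] + (level - y[i]) * (x[i + 1] - x[i]) / (y[i + 1] - y[i])
}

# The index of the tuning extremum (minimum for troughs, maximum for peaks).
extremum_index <- function(y, mode) {
  if (mode == "trough") which.min(y) else which.max(y)
}

#' Tuning-curve halfwidth
#'
#' Width of the ITD range over which the response is suppressed (trough
#' mode) or enhanced (peak mode) by at least 50% of the curve maximum.
#' Crossings of the 50% level bracketing the extremum are found by linear
#' interpolation between grid samples.  Returns `NA` when the 50% level is
#' not crossed on one side (e.g. a flat or monotone curve).
#'
#' The curve should already be smoothed ([hanning3_smooth()]); the reference
#' level is the maximum of the supplied curve.
#'
#' @param itd Condition axis (ms, ascending).
#' @param rate Response per condition (spikes/click or probability).
#' @param mode `"trough"` (suppression, LSO) or `"peak"` (enhancement, MSO).
#' @return Halfwidth in the units of `itd`, or `NA_real_` if undefined.
#' @export
halfwidth <- function(itd, rate, mode = c("trough", "peak")) {
  mode <- match.arg(mode)
  stopifnot(length(itd) == length(rate), !is.unsorted(itd))
  top <- max(rate)
  if (top <= 0) return(NA_real_)
  level <- 0.5 * top
  i0 <- extremum_index(rate, mode)
  crossed <- if (mode == "trough") rate <= level else rate >= level
  if (!crossed[i0]) return(NA_real_)
  # walk outward from the extremum to the first sample on the other side
  left <- NA_real_; right <- NA_real_
  for (i in rev(seq_len(i0 - 1))) {
    if (!crossed[i]) { left <- cross_at(itd, rate, i, level); break }
  }
  for (i in seq(i0 + 1, length.out = length(rate) - i0)) {
    if (!crossed[i]) { right <- cross_at(itd, rate, i - 1, level); break }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  right - left
}

#' 20--80% flank slopes of a tuning curve
#'
#' For each flank of the central trough (or peak), the slope between the
#' ITD values where the response crosses 20% and 80% of the curve maximum:
#' `slope = 0.6 * max / (itd_80 - itd_20)`, crossings by linear
#' interpolation, sign preserved (the left flank of a trough is negative).
#' A side is `NA` when a threshold is not reached on that side.
#'
#' @inheritParams halfwidth
#' @return Named numeric vector `c(left = , right = )` in response units per
#'   ms.
#' @export
slopes_20_80 <- function(itd, rate, mode = c("trough", "peak")) {
  mode <- match.arg(mode)
  stopifnot(length(itd) == length(rate), !is.unsorted(itd))
  top <- max(rate)
  if (top <= 0) return(c(left = NA_real_, right = NA_real_))
  lev20 <- 0.2 * top
  lev80 <- 0.8 * top
  i0 <- extremum_index(rate, mode)

  side_cross <- function(idx, level) {
    # first crossing of `level` when walking from the extremum outward
    below <- if (mode == "trough") rate <= level else rate >= level
    if (!below[i0]) return(NA_real_)
    for (i in idx) {
      if (!below[i]) {
        j <- if (i < i0) i else i - 1
        return(cross_at(itd, rate, j, level))
      }
    }
    NA_real_
  }
  left_idx <- rev(seq_len(i0 - 1))
  right_idx <- seq(i0 + 1, length.out = length(rate) - i0)

  l20 <- side_cross(left_idx, lev20); l80 <- side_cross(left_idx, lev80)
  r20 <- side_cross(right_idx, lev20); r80 <- side_cross(right_idx, lev80)

  left <- if (is.na(l20) || is.na(l80)) NA_real_ else
    (lev80 - lev20) / (l80 - l20)
  right <- if (is.na(r20) || is.na(r80)) NA_real_ else
    (lev80 - lev20) / (r80 - r20)
  c(left = left, right = right)
}

#' ITD signal-to-noise ratio of spike counts
#'
#' Fraction of the total spike-count variance that is attributable to the
#' ITD: `sigma_ITD^2 / sigma_tot^2` with
#' `sigma_ITD^2 = (1/Ns) * sum_s (Rbar_s - Rbar)^2` and
#' `sigma_tot^2 = (1/(Ns*NT)) * sum_{s,t} (R_st - Rbar)^2`, where `Rbar_s`
#' is the mean count at condition `s` and `Rbar` the grand mean of the
#' `Rbar_s`.  Returns 0 for a constant response (zero total variance).
#'
#' @param table A trial table: data frame with columns `condition_value` and
#'   `spike_count` (one row per trial), or a numeric matrix with one row per
#'   condition and one column per trial.
#' @param min_reps Minimum repetitions per condition (inclusion rule,
#'   default 10).  Set lower to override.
#' @param allow_ragged Accept unequal repetition counts across conditions;
#'   the total variance is then weighted by the per-condition `NT`.
#' @return ITD-SNR in `[0, 1]`.
#' @examples
#' m <- rbind(c(1, 1), c(0, 1))
#' itd_snr(m, min_reps = 2)   # 1/3
#' @export
itd_snr <- function(table, min_reps = 10, allow_ragged = FALSE) {
  if (is.matrix(table)) {
    counts <- split(table, row(table))
  } else {
    stopifnot(all(c("condition_value", "spike_count") %in% names(table)))
    counts <- split(table$spike_count, table$condition_value)
  }
  nt <- lengths(counts)
  if (any(nt < min_reps))
    stop(sprintf("conditions with fewer than %d repetitions (min %d found); lower min_reps to override",
                 min_reps, min(nt)))
  if (!allow_ragged && length(unique(nt)) > 1)
    stop("unequal repetitions per condition; set allow_ragged = TRUE to weight by per-condition NT")
  rbar_s <- vapply(counts, mean, numeric(1))
  rbar <- mean(rbar_s)
  sig_itd <- mean((rbar_s - rbar)^2)
  sig_tot <- sum(vapply(counts, function(x) sum((x - rbar)^2), numeric(1))) /
    sum(nt)
  if (sig_tot == 0) return(0)
  sig_itd / sig_tot
}

#' Monaural/binaural summation ratio
#'
#' Per sound level, the ratio of the summed monaural mean rates to the
#' binaural mean rate (LSO mode) or its inverse (MSO mode); the statistic is
#' the median ratio across levels.  Levels with a zero denominator are
#' excluded.  Both modes equal 1 in the absence of binaural interaction and
#' are much larger than 1 under strong binaural suppression (LSO) or
#' facilitation (MSO).
#'
#' @param rl Rate-level table: data frame with columns `spl`, `ipsi`,
#'   `contra`, `bin` (mean spikes/stimulus).
#' @param mode `"LSO"` or `"MSO"`.
#' @return The median ratio (unitless).
#' @examples
#' rl <- data.frame(spl = c(40, 50), ipsi = c(1, 1), contra = c(0, 0),
#'                  bin = c(0.5, 0.25))
#' summation_ratio(rl, "LSO")   # median(2, 4) = 3
#' @export
summation_ratio <- function(rl, mode = c("LSO", "MSO")) {
  mode <- match.arg(mode)
  stopifnot(all(c("spl", "ipsi", "contra", "bin") %in% names(rl)))
  num <- if (mode == "LSO") rl$ipsi + rl$contra else rl$bin
  den <- if (mode == "LSO") rl$bin else rl$ipsi + rl$contra
  ok <- den > 0
  if (!any(ok)) stop("no valid levels: all denominators are zero")
  if (any(!ok))
    message(sprintf("summation_ratio: excluded %d level(s) with zero denominator",
                    sum(!ok)))
  median(num[ok] / den[ok])
}

#' PSP latency by fractional-amplitude crossing
#'
#' Time (relative to stimulus onset `t0`) when the membrane potential first
#' deviates from rest by at least 20% of the reference IPSP amplitude, in the
#' required direction (depolarizing for the excitatory ear, hyperpolarizing
#' for the inhibitory ear).  The crossing is located by linear interpolation
#' between samples.
#'
#' @param t Time grid (ms).
#' @param v Membrane potential (mV), same length as `t`.
#' @param rest Resting potential (mV).
#' @param ipsp_amplitude Reference IPSP amplitude (mV, positive).
#' @param polarity `"depolarizing"` or `"hyperpolarizing"`.
#' @param t0 Stimulus onset (ms).
#' @param frac Fraction of the reference amplitude (default 0.2).
#' @return Latency in ms relative to `t0`, or `NA_real_` if never crossed.
#' @export
psp_latency <- function(t, v, rest, ipsp_amplitude,
                        polarity = c("depolarizing", "hyperpolarizing"),
                        t0 = 0, frac = 0.2) {
  polarity <- match.arg(polarity)
  stopifnot(ipsp_amplitude > 0, length(t) == length(v))
  keep <- t >= t0
  if (!any(keep)) stop("trace does not cover t0 onward")
  t <- t[keep]; v <- v[keep]
  dev <- if (polarity == "depolarizing") v - rest else rest - v
  level <- frac * ipsp_amplitude
  i <- which(dev >= level)
  if (length(i) == 0) return(NA_real_)
  i <- i[1]
  if (i == 1) return(t[1] - t0)
  cross_at(t, dev, i - 1, level) - t0
}

#' Theta effect size (Mann-Whitney)
#'
#' The Mann-Whitney U statistic divided by the product of the two sample
#' sizes, with ties counted as half: the probability that a random draw from
#' `x` exceeds one from `y`.  Equals 0.5 for identical samples, 1 for
#' complete separation with `x` above `y`.
#'
#' @param x,y Numeric samples (non-empty).
#' @return Theta in `[0, 1]`.
#' @examples
#' theta_effect_size(c(3, 4), c(1, 2))   # 1
#' theta_effect_size(c(1, 4), c(2, 3))   # 0.5
#' @export
theta_effect_size <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  r <- rank(c(x, y))
  u <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  u / (length(x) * length(y))
}

#' ITD/IID cue-map coordinates and nearest-site regions
#'
#' Places combined-cue measurements in a common plane by dividing ITD values
#' by an equivalence scale (ms of ITD per dB of IID, default 0.05) so that
#' the two axes are commensurate, then assigns query points to the nearest
#' site (Euclidean distance), which is Voronoi-cell membership.  Distance
#' ties break deterministically to the lower site index.
#'
#' @param itd,iid Site coordinates (ms, dB).
#' @param rate Optional response at each site.
#' @param scale ITD/IID equivalence scale (ms/dB).
#' @return An object of class `"lso_cuemap"`: data frame with columns `x`
#'   (`itd/scale`), `y` (`iid`), `itd`, `iid`, and `rate`.
#' @export
cue_map <- function(itd, iid, rate = NULL, scale = 0.05) {
  stopifnot(length(itd) == length(iid))
  if (length(itd) < 3) stop("degenerate geometry: need at least 3 sites")
  x <- itd / scale
  cross <- (x - x[1]) * (iid[2] - iid[1]) - (iid - iid[1]) * (x[2] - x[1])
  if (all(abs(cross) < 1e-12))
    message("cue_map: sites are collinear; region assignment degenerates to nearest site on a line")
  out <- data.frame(x = x, y = iid, itd = itd, iid = iid,
                    rate = if (is.null(rate)) NA_real_ else rate)
  attr(out, "scale") <- scale
  class(out) <- c("lso_cuemap", "data.frame")
  out
}

#' Assign query points to cue-map regions
#'
#' @param map An `"lso_cuemap"` from [cue_map()].
#' @param itd,iid Query coordinates (ms, dB), scaled with the map's scale.
#' @return Integer vector of site indices (ties to the lower index).
#' @export
cue_region <- function(map, itd, iid) {
  scale <- attr(map, "scale")
  qx <- itd / scale
  vapply(seq_along(qx), function(i) {
    d2 <- (map$x - qx[i])^2 + (map$y - iid[i])^2
    which.min(d2)  # ties: which.min takes the first (lowest index)
  }, integer(1))
}

#' Average a metric per cell
#'
#' Collapses repeated datasets from the same cell to one value per cell
#' (arithmetic mean), so each cell contributes a single point to downstream
#' population statistics.
#'
#' @param values Numeric metric values, one per dataset.
#' @param cell_id Grouping key, same length as `values`.
#' @return Named numeric vector, one element per cell.
#' @export
cell_average <- function(values, cell_id) {
  if (length(cell_id) != length(values) || any(is.na(cell_id)))
    stop("missing cell id")
  out <- tapply(values, cell_id, mean)
  structure(as.numeric(out), names = names(out))
}

#' All tuning metrics for one curve
#'
#' Convenience wrapper: smooths with [hanning3_smooth()] (optional), then
#' computes halfwidth and both flank slopes.
#'
#' @inheritParams halfwidth
#' @param smooth Apply three-point Hanning smoothing first (default TRUE,
#'   the convention used before measuring halfwidth and slopes).
#' @return List with `halfwidth`, `slopes`, and the (possibly smoothed)
#'   `rate`.
#' @export
tuning_metrics <- function(itd, rate, mode = c("trough", "peak"),
                           smooth = TRUE) {
  mode <- match.arg(mode)
  if (smooth) rate <- hanning3_smooth(rate)
  list(halfwidth = halfwidth(itd, rate, mode),
       slopes = slopes_20_80(itd, rate, mode),
       rate = rate)
}
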