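# Synthetic in-vivo-like recordings with closed-form ground truth: trial
# tables from parametric ITD tuning profiles, rate-level functions with a
# prescribed summation ratio, and PSP traces with level-dependent latency.

#' Specification for a synthetic recording
#'
#' Defines the generative ground truth: a U-shaped (LSO trough) or peaked
#' (MSO) ITD tuning profile built from two logistic flanks, trial counts,
#' and a PSP/latency model.  The profile is parameterized directly by
#' `(center, halfwidth, floor, ceiling)`; flank positions are obtained by
#' closed-form inversion so that (for well-separated flanks) the 50%-of-max
#' crossings sit exactly `halfwidth` apart.
#'
#' @param cell_class `"principal-LSO"` (Bernoulli single-spiking),
#'   `"non-principal-LSO"` or `"MSO"` (truncated-Poisson counts, peaked
#'   profile for MSO).
#' @param center Profile center (ms).
#' @param halfwidth Ground-truth halfwidth (ms, > 0).
#' @param floor,ceiling Response floor and ceiling (spikes/click),
#'   `floor <= ceiling`.  The 50%-of-max halfwidth is only defined when
#'   `floor < ceiling/2`; shallower (or flat) profiles are allowed and then
#'   position the flanks by their suppression midpoints instead.
#' @param steep_left,steep_right Logistic flank width parameters (ms);
#'   smaller is steeper.
#' @param n_reps Repetitions per ITD condition.
#' @param itd_grid Condition grid (ms).
#' @param latency_base Baseline PSP latency (ms) at the reference level.
#' @param latency_slope Latency decrease per dB (us/dB).
#' @param spl_ref Reference sound level (dB SPL).
#' @param psp_amp PSP amplitude (mV, positive).
#' @param psp_rise,psp_decay PSP kernel time constants (ms).
#' @param noise_sd Membrane noise SD (mV) for generated traces.
#' @param seed Master seed; all generators derive per-operation streams.
#' @return An object of class `"synth_spec"`.
#' @export
synth_spec <- function(cell_class = c("principal-LSO", "non-principal-LSO", "MSO"),
                       center = 0, halfwidth = 0.8, floor = 0, ceiling = 1,
                       steep_left = 0.08, steep_right = 0.08,
                       n_reps = 10, itd_grid = seq(-2, 2, by = 0.1),
                       latency_base = 4, latency_slope = 15, spl_ref = 50,
                       psp_amp = 5, psp_rise = 0.45, psp_decay = 2,
                       noise_sd = 0.2, seed = 1) {
  cell_class <- match.arg(cell_class)
  if (halfwidth <= 0) stop("invalid profile: halfwidth must be positive")
  if (floor > ceiling) stop("invalid profile: floor must not exceed ceiling")
  if (ceiling < 0) stop("invalid profile: ceiling must be non-negative")
  structure(as.list(environment()), class = "synth_spec")
}

#' Generative tuning profile
#'
#' The closed-form mean-response profile of a [synth_spec()]:
#' a product of two logistic flanks scaled between `floor` and `ceiling`.
#' Trough-shaped for LSO classes, peak-shaped for MSO.
#'
#' @param spec A `"synth_spec"`.
#' @return A vectorized function of ITD (ms) returning mean spikes/click.
#' @export
tuning_profile <- function(spec) {
  depth <- spec$ceiling - spec$floor
  if (depth == 0) {
    lvl <- spec$ceiling
    return(function(itd) rep(lvl, length(itd)))
  }
  # suppression fraction at the 50%-of-max level; when the profile is too
  # shallow to cross that level, fall back to the suppression midpoint
  g <- 0.5 * spec$ceiling / depth
  if (g >= 1) g <- 0.5
  lg <- log(g / (1 - g))
  aL <- spec$center - spec$halfwidth / 2 - spec$steep_left * lg
  aR <- spec$center + spec$halfwidth / 2 + spec$steep_right * lg
  mso <- spec$cell_class == "MSO"
  function(itd) {
    S <- plogis((itd - aL) / spec$steep_left) *
      plogis((aR - itd) / spec$steep_right)
    if (mso) spec$floor + depth * S else spec$ceiling - depth * S
  }
}

#' Exact ground-truth tuning metrics of a profile
#'
#' Numerically exact halfwidth and 20--80% chord slopes of the generative
#' profile (root-finding on the closed-form curve, not on sampled data).
#'
#' @param spec A `"synth_spec"`.
#' @return List with `halfwidth`, `slopes` (left/right), and `itd_snr`, the
#'   large-sample ITD-SNR on the spec's grid:
#'   `sigma_ITD^2 / (sigma_ITD^2 + mean(p(1-p)))` for Bernoulli trials.
#' @export
profile_truth <- function(spec) {
  f <- tuning_profile(spec)
  lo <- min(spec$itd_grid); hi <- max(spec$itd_grid)
  top <- max(f(seq(lo, hi, length.out = 4001)))
  cross <- function(level, interval) {
    tryCatch(uniroot(function(x) f(x) - level, interval, tol = 1e-10)$root,
             error = function(e) NA_real_)
  }
  c0 <- spec$center
  hw_l <- cross(0.5 * top, c(lo, c0)); hw_r <- cross(0.5 * top, c(c0, hi))
  l20 <- cross(0.2 * top, c(lo, c0)); l80 <- cross(0.8 * top, c(lo, c0))
  r20 <- cross(0.2 * top, c(c0, hi)); r80 <- cross(0.8 * top, c(c0, hi))
  # chord-slope convention: for a trough l80 < l20 (left slope negative);
  # for a peak l20 < l80 (left slope positive) -- the same formula covers both
  slopes <- c(left = (0.8 - 0.2) * top / (l80 - l20),
              right = (0.8 - 0.2) * top / (r80 - r20))
  p <- pmin(pmax(f(spec$itd_grid), 0), 1)
  sig_itd <- mean((p - mean(p))^2)
  list(halfwidth = hw_r - hw_l, slopes = slopes,
       itd_snr = sig_itd / (sig_itd + mean(p * (1 - p))))
}

#' Generate a synthetic trial table
#'
#' Per ITD condition, draws `n_reps` spike counts from the generative
#' profile: Bernoulli for principal LSO cells (which fire at most one spike
#' per click), truncated Poisson (at 5) otherwise.  Bit-reproducible for a
#' given seed; the ground-truth profile is retained as an attribute.
#'
#' @param spec A `"synth_spec"`.
#' @return A trial-table data frame (columns `cell_id`, `cell_class`,
#'   `condition_type`, `condition_value`, `trial_index`, `spike_count`,
#'   `spl_db`) with attribute `truth` ([profile_truth()]).
#' @export
gen_trial_table <- function(spec) {
  f <- tuning_profile(spec)
  p <- f(spec$itd_grid)
  counts <- with_stream(spec$seed, "gen_trial_table", {
    if (spec$cell_class == "principal-LSO") {
      pr <- pmin(pmax(p, 0), 1)
      vapply(pr, function(pp) rbinom(spec$n_reps, 1, pp),
             integer(spec$n_reps))
    } else {
      vapply(pmax(p, 0), function(lam) pmin(rpois(spec$n_reps, lam), 5L),
             integer(spec$n_reps))
    }
  })
  out <- data.frame(
    cell_id = "synth-1",
    cell_class = spec$cell_class,
    condition_type = "ITD",
    condition_value = rep(spec$itd_grid, each = spec$n_reps),
    trial_index = rep(seq_len(spec$n_reps), times = length(spec$itd_grid)),
    spike_count = as.integer(counts),
    spl_db = spec$spl_ref
  )
  attr(out, "truth") <- profile_truth(spec)
  out
}

#' Generate a rate-level table with a prescribed summation ratio
#'
#' Constructs ipsi/contra/binaural mean rates over sound levels whose
#' per-level ratios have median exactly `target_ratio`: the ratios are
#' `target_ratio * spread` with `median(spread) = 1`.
#'
#' @param spec A `"synth_spec"` (used for the level grid reference).
#' @param mode `"LSO"` or `"MSO"`.
#' @param target_ratio Desired [summation_ratio()] (>= 0).
#' @param spl Sound levels (dB), odd count recommended.
#' @param spread Per-level ratio multipliers with median 1.
#' @return A rate-level data frame (`spl`, `ipsi`, `contra`, `bin`).
#' @export
gen_rate_level <- function(spec, mode = c("LSO", "MSO"), target_ratio = 3,
                           spl = c(30, 40, 50),
                           spread = c(0.8, 1, 1.25)) {
  mode <- match.arg(mode)
  if (target_ratio < 0) stop("target_ratio must be >= 0")
  stopifnot(length(spl) == length(spread))
  if (median(spread) != 1) stop("spread must have median 1")
  ratios <- target_ratio * spread
  ipsi <- rep(1, length(spl))
  contra <- rep(0.2, length(spl))
  if (mode == "LSO") {
    bin <- (ipsi + contra) / ratios
  } else {
    bin <- (ipsi + contra) * ratios
  }
  data.frame(spl = spl, ipsi = ipsi, contra = contra, bin = bin)
}

#' Generate a synthetic PSP trace with level-dependent latency
#'
#' A double-exponential PSP (depolarizing for the ipsilateral ear,
#' hyperpolarizing for the contralateral ear) whose onset latency decreases
#' linearly with sound level at `latency_slope` us/dB, plus white membrane
#' noise.  The analytic 20%-amplitude crossing time is retained as ground
#' truth.
#'
#' @param spec A `"synth_spec"`.
#' @param ear `"ipsi"` (depolarizing) or `"contra"` (hyperpolarizing).
#' @param spl Sound level (dB).
#' @param dt Sample interval (ms).
#' @param t_end Trace length (ms).
#' @param rest Resting potential (mV).
#' @return Data frame `t`, `V` with attributes `onset`, `latency_truth`
#'   (the noise-free 20% crossing, ms relative to t = 0), and `polarity`.
#' @export
gen_psp_trace <- function(spec, ear = c("ipsi", "contra"), spl,
                          dt = 0.01, t_end = 30, rest = -60) {
  ear <- match.arg(ear)
  onset <- spec$latency_base - spec$latency_slope * 1e-3 * (spl - spec$spl_ref)
  if (onset < 0) stop("spl outside configured range: onset before trace start")
  k <- kernel_peak(spec$psp_rise, spec$psp_decay)
  t <- seq(0, t_end, by = dt)
  shape <- ifelse(t < onset, 0,
                  (exp(-(t - onset) / spec$psp_decay) -
                   exp(-(t - onset) / spec$psp_rise)) / k$norm)
  amp <- if (ear == "ipsi") spec$psp_amp else -spec$psp_amp
  noise <- with_stream(spec$seed, paste0("gen_psp_trace/", ear, "/", spl),
                       rnorm(length(t), 0, spec$noise_sd))
  v <- rest + amp * shape + noise
  # analytic 20% crossing on the rising edge of the kernel
  t20 <- uniroot(function(x) (exp(-x / spec$psp_decay) -
                                exp(-x / spec$psp_rise)) / k$norm - 0.2,
                 c(1e-9, k$t_peak), tol = 1e-12)$root
  out <- data.frame(t = t, V = v)
  attr(out, "onset") <- onset
  attr(out, "latency_truth") <- onset + t20
  attr(out, "polarity") <- if (ear == "ipsi") "depolarizing" else "hyperpolarizing"
  out
}
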