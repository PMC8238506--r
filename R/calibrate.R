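# Calibration procedures: maximal sodium conductance (spike threshold at a
# ~10 mV soma EPSP) and the inhibition-only IPSP statistics check.

# Peak soma EPSP of the largest just-subthreshold scaled excitatory drive,
# for a given g_Na.  The drive is a single excitatory-kernel-shaped
# conductance whose amplitude is scaled continuously; bisection finds the
# spike threshold amplitude.  The EPSP is measured at a drive 1% below
# threshold: exactly at the boundary the trajectory can ride the unstable
# manifold and produce an inflated graded response, so a small backoff keeps
# the measurement on the stable subthreshold branch.
threshold_epsp <- function(model, rel_tol = 1e-4, s_max = 3, backoff = 0.01) {
  ch <- channel_spec(model, itd = 0)
  full <- model$synapses$exc$n_max * ch$unit_amp[1]  # all inputs active
  spikes_at <- function(s) {
    out <- run_batch(model, cbind(s * full, 0, 0), itd = 0)
    out$spike[1]
  }
  lo <- 0
  hi <- s_max
  if (spikes_at(0)) return(list(epsp = 0, s_threshold = 0))  # spontaneous
  if (!spikes_at(hi)) return(list(epsp = NA_real_, s_threshold = NA_real_))
  while ((hi - lo) > rel_tol * hi) {
    mid <- (lo + hi) / 2
    if (spikes_at(mid)) hi <- mid else lo <- mid
  }
  out <- run_batch(model, cbind((1 - backoff) * lo * full, 0, 0), itd = 0)
  list(epsp = out$max1[1], s_threshold = hi)
}

#' Calibrate the maximal sodium conductance
#'
#' Sets `g_Na` so that the minimal scaled excitatory drive that elicits a
#' spike produces a just-subthreshold soma EPSP of `target` mV (default 10),
#' then sets `g_KHT = 0.1 * g_Na`.  The threshold EPSP amplitude decreases
#' monotonically as `g_Na` increases, so the outer search is a bisection.
#'
#' @param model An [lso_model()] object (passive parameters and synaptic
#'   kernels fixed).
#' @param target Target just-subthreshold soma EPSP (mV).
#' @param tol Absolute tolerance on the achieved EPSP (mV).
#' @param bracket Search bracket for `g_Na` (uS).
#' @return The model with calibrated `currents$g_Na`, `currents$g_KHT`, and a
#'   `calibration` record (`threshold_epsp`, `s_threshold`).
#' @export
calibrate_gna <- function(model, target = 10, tol = 0.02,
                          bracket = c(0.05, 10)) {
  f <- function(gna) {
    model$currents$g_Na <- gna
    model$currents$g_KHT <- 0.1 * gna
    threshold_epsp(model)$epsp - target
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo < 0 || fhi > 0)
    stop("calibration failure: no g_Na in the bracket reaches the target EPSP")
  for (i in 1:40) {
    mid <- sqrt(lo * hi)
    fm <- f(mid)
    if (is.na(fm)) stop("calibration failure: spike threshold not found")
    if (abs(fm) < tol) { lo <- hi <- mid; break }
    if (fm > 0) lo <- mid else hi <- mid
  }
  gna <- sqrt(lo * hi)
  model$currents$g_Na <- gna
  model$currents$g_KHT <- 0.1 * gna
  th <- threshold_epsp(model)
  model$calibration <- list(threshold_epsp = th$epsp,
                            s_threshold = th$s_threshold,
                            target = target)
  model$calibrated <- TRUE
  model
}

#' Monte-Carlo IPSP statistics
#'
#' Inhibition-only stimulus: per trial the number of active somatic
#' inhibitory inputs is drawn from `Binomial(n_max, p_release)`, the trial is
#' simulated, and the most negative soma deflection from rest is recorded.
#' Returns the sample mean and variance of the per-trial peak
#' hyperpolarizations.  Outcomes are deterministic given the active count
#' (inputs are synchronized), so simulation is memoized per unique count;
#' results are identical to simulating every trial.
#'
#' @param model An [lso_model()] object.
#' @param n_trials Number of Monte-Carlo trials (>= 1000 recommended).
#' @param seed Master seed for the binomial draws.
#' @param t_end Simulation length per trial (ms).
#' @return List with `mean` (mV), `variance` (mV^2), `peaks` (per-count
#'   peak deflections) and `counts` (the drawn active counts).
#' @export
ipsp_statistics <- function(model, n_trials = 10000, seed = 1, t_end = 10) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  inh <- model$synapses$inh
  nmax <- inh$n_max
  amps <- amps_for_counts(model, 0, 0:nmax, 0)
  out <- run_batch(model, amps, itd = 0, t_end = t_end)
  peak_by_count <- out$min1          # most negative soma deflection per count
  k <- with_stream(seed, "ipsp_statistics",
                   rbinom(n_trials, nmax, inh$p_release))
  x <- peak_by_count[k + 1]
  list(mean = mean(x), variance = var(x),
       peaks = peak_by_count, counts = k)
}
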