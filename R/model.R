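# The user-facing model object: constructor and S3 methods.

#' Two-compartment LSO neuron model
#'
#' Builds the complete model: passive parameters from the coupling constants
#' (via [passive_from_coupling()] and [fit_effective_capacitance()]),
#' spike-generating sodium and high-threshold potassium currents in the AIS
#' compartment, and the excitatory/inhibitory synapse populations of the
#' chosen preset.  With `calibrate = TRUE` the maximal sodium conductance is
#' immediately calibrated so that spike threshold corresponds to a ~10 mV
#' soma EPSP ([calibrate_gna()]), with `g_KHT = 0.1 * g_Na`.
#'
#' @param kappa_fwd,kappa_bwd Forward/backward coupling constants in (0, 1).
#' @param R1 Soma input resistance (MOhm).
#' @param tau_m Soma membrane time constant (ms).
#' @param alpha AIS/soma membrane-area ratio (see [ais_soma_area_ratio()]).
#' @param Cm Specific membrane capacitance (uF/cm^2), diagnostic only.
#' @param E_rest Resting potential (mV).
#' @param preset Synaptic preset name, see [synapse_preset()].
#' @param spike_threshold Absolute AIS voltage (mV) whose first upward
#'   crossing counts as a spike.
#' @param dt Default integration step (ms).
#' @param q Temperature scale factor dividing gating time constants.
#' @param E_Na,E_K Reversal potentials of the spike currents (mV).
#' @param calibrate Run [calibrate_gna()] on construction.
#' @param g_Na Initial/explicit maximal sodium conductance (uS); overwritten
#'   when `calibrate = TRUE`.
#'
#' @return An object of class `"lso_model"` with components `coupling`,
#'   `passive` (an `"lso_passive"`), `currents`, `synapses`, `spike_threshold`,
#'   `E_rest`, `dt` and (if calibrated) `calibration`.
#' @examples
#' \donttest{
#' m <- lso_model()                      # default: kappa = (0.95, 0.6)
#' coef(m)
#' curve_8_0 <- predict(m, arrangement = "8+0")
#' min(curve_8_0$p_spike)
#' }
#' @export
lso_model <- function(kappa_fwd = 0.95, kappa_bwd = 0.6, R1 = 40,
                      tau_m = 1, alpha = 0.12, Cm = 0.9, E_rest = -60,
                      preset = c("default_invitro", "mature_invivo"),
                      spike_threshold = -20, dt = 0.002, q = 6,
                      E_Na = 40, E_K = -70,
                      calibrate = TRUE, g_Na = 0.3) {
  preset <- match.arg(preset)
  if (spike_threshold <= E_rest)
    stop("spike_threshold must exceed the resting potential")
  passive <- passive_from_coupling(kappa_fwd, kappa_bwd, R1 = R1,
                                   tau_m = tau_m, alpha = alpha, Cm = Cm,
                                   E_rest = E_rest)
  model <- structure(list(
    coupling = list(kappa_fwd = kappa_fwd, kappa_bwd = kappa_bwd, R1 = R1,
                    tau_m = tau_m, alpha = alpha, Cm = Cm),
    passive = passive,
    currents = list(g_Na = g_Na, g_KHT = 0.1 * g_Na, E_Na = E_Na,
                    E_K = E_K, q = q, kinetics_id = "rm03_m3h_n2"),
    synapses = synapse_preset(preset),
    preset = preset,
    spike_threshold = spike_threshold,
    E_rest = E_rest,
    dt = dt,
    calibrated = FALSE
  ), class = "lso_model")
  if (calibrate) model <- calibrate_gna(model)
  model
}

#' @export
print.lso_model <- function(x, ...) {
  cat("Two-compartment LSO neuron model (soma + AIS)\n")
  cat(sprintf("  coupling: kappa_fwd = %.2f, kappa_bwd = %.2f; R1 = %g MOhm, R2 = %.2f MOhm\n",
              x$coupling$kappa_fwd, x$coupling$kappa_bwd,
              x$passive$R1, x$passive$R2))
  cat(sprintf("  passive: tau_m = %g ms, alpha = %g, c1 = %.4f nF\n",
              x$coupling$tau_m, x$coupling$alpha, x$passive$c1))
  cat(sprintf("  currents: g_Na = %.4f uS, g_KHT = %.4f uS (%s)\n",
              x$currents$g_Na, x$currents$g_KHT, x$currents$kinetics_id))
  cat(sprintf("  synapses (%s): %dE (%.1f nS, p=%.2f), %dI (%.1f nS, p=%.2f)\n",
              x$preset,
              x$synapses$exc$n_max, 1000 * x$synapses$exc$g_peak,
              x$synapses$exc$p_release,
              x$synapses$inh$n_max, 1000 * x$synapses$inh$g_peak,
              x$synapses$inh$p_release))
  if (isTRUE(x$calibrated))
    cat(sprintf("  calibrated: threshold EPSP = %.2f mV\n",
                x$calibration$threshold_epsp))
  else cat("  not calibrated\n")
  invisible(x)
}

#' @export
coef.lso_model <- function(object, ...) {
  p <- object$passive
  c(kappa_fwd = object$coupling$kappa_fwd,
    kappa_bwd = object$coupling$kappa_bwd,
    R1 = p$R1, R2 = p$R2, R12 = p$R12,
    g1 = p$g1, g2 = p$g2, gax = p$gax, c1 = p$c1, c2 = p$c2,
    g_Na = object$currents$g_Na, g_KHT = object$currents$g_KHT,
    spike_threshold = object$spike_threshold, E_rest = object$E_rest)
}

#' @export
summary.lso_model <- function(object, ...) {
  out <- list(coef = coef(object),
              effective_area_cm2 = object$passive$c1 * 1e-3 / object$coupling$Cm,
              calibration = object$calibration,
              preset = object$preset)
  class(out) <- "summary.lso_model"
  out
}

#' @export
print.summary.lso_model <- function(x, ...) {
  cat("Model parameters:\n")
  print(round(x$coef, 5))
  cat(sprintf("Effective soma area (c1/Cm): %.3g cm^2\n", x$effective_area_cm2))
  if (!is.null(x$calibration))
    cat(sprintf("Calibration: threshold EPSP %.2f mV (target %g mV)\n",
                x$calibration$threshold_epsp, x$calibration$target))
  invisible(x)
}

#' Predict ITD tuning from the model
#'
#' Computes the semi-analytic spike-probability tuning curve over a grid of
#' interaural time differences for one or more inhibitory arrangements.
#' Thin wrapper over [itd_curve()].
#'
#' @param object An `"lso_model"` object (calibrated).
#' @param itd ITD grid (ms); positive = inhibition leads.
#' @param arrangement Character vector of arrangements (`"8+0"`, `"6+2"`,
#'   `"0+2"`).
#' @param ... Unused.
#' @return A data frame of class `"lso_tuning"` with columns `itd`,
#'   `p_spike`, `arrangement`.
#' @export
predict.lso_model <- function(object, itd = seq(-2, 2, by = 0.05),
                              arrangement = "8+0", ...) {
  out <- do.call(rbind, lapply(arrangement, function(a)
    itd_curve(object, itd, arrangement = a)))
  class(out) <- c("lso_tuning", "data.frame")
  out
}

#' Simulate spike outcomes by Monte Carlo
#'
#' Draws per-trial active input counts from the populations' binomial
#' activation model and returns the (deterministic) spike outcome of each
#' trial at the given ITD.  This is the sampling estimator whose expectation
#' is the semi-analytic [spike_probability()].
#'
#' @param object An `"lso_model"` object.
#' @param nsim Number of trials.
#' @param seed Master seed.
#' @param itd ITD (ms).
#' @param arrangement Inhibitory arrangement label.
#' @param ... Unused.
#' @return A data frame with columns `n_exc`, `n_inh_soma`, `n_inh_ais`,
#'   `spike`.
#' @export
simulate.lso_model <- function(object, nsim = 1, seed = 1, itd = 0,
                               arrangement = "8+0", ...) {
  arr <- parse_arrangement(arrangement)
  ind <- build_indicator(object, itd, arrangement = arrangement)
  exc <- object$synapses$exc
  inh <- object$synapses$inh
  draws <- with_stream(seed, paste0("simulate/", itd, "/", arrangement), {
    data.frame(
      n_exc = rbinom(nsim, exc$n_max, exc$p_release),
      n_inh_soma = rbinom(nsim, arr["soma"], inh$p_release),
      n_inh_ais = rbinom(nsim, arr["ais"], inh$p_release)
    )
  })
  draws$spike <- ind$spike[cbind(draws$n_exc + 1L, draws$n_inh_soma + 1L,
                                 draws$n_inh_ais + 1L)]
  draws
}

#' Plot an ITD tuning curve
#'
#' @param x An `"lso_tuning"` data frame (from [predict.lso_model()] or
#'   [itd_curve()]).
#' @param ... Passed to [plot()].
#' @export
plot.lso_tuning <- function(x, ...) {
  arrs <- unique(x$arrangement)
  cols <- seq_along(arrs)
  plot(NA, xlim = range(x$itd), ylim = c(0, 1),
       xlab = "ITD (ms, positive = inhibition leads)",
       ylab = "spike probability", ...)
  for (i in seq_along(arrs)) {
    sub <- x[x$arrangement == arrs[i], ]
    lines(sub$itd, sub$p_spike, col = cols[i], lty = i)
  }
  legend("bottomright", legend = arrs, col = cols, lty = seq_along(arrs),
         bty = "n", title = "inhibition (soma+AIS)")
  invisible(x)
}
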