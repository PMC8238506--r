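# Single-trial simulation: R-side wrapper around the compiled
# exponential-Euler integrator.

# Synaptic channel layout used throughout: 1 = excitatory/soma,
# 2 = inhibitory/soma, 3 = inhibitory/AIS.  Onset convention: positive ITD
# means inhibition leads excitation; both populations share a common buffer
# onset `t_on`.
channel_spec <- function(model, itd, t_on = 2) {
  exc <- model$synapses$exc
  inh <- model$synapses$inh
  on_exc <- t_on + max(itd, 0)
  on_inh <- t_on + max(-itd, 0)
  kE <- kernel_peak(exc$tau_rise, exc$tau_decay)
  kI <- kernel_peak(inh$tau_rise, inh$tau_decay)
  list(
    on = c(on_exc, on_inh, on_inh),
    tr = c(exc$tau_rise, inh$tau_rise, inh$tau_rise),
    td = c(exc$tau_decay, inh$tau_decay, inh$tau_decay),
    Erel = c(exc$E_syn, inh$E_syn, inh$E_syn) - model$E_rest,
    comp = c(1L, 1L, 2L),
    unit_amp = c(exc$g_peak / kE$norm, inh$g_peak / kI$norm,
                 inh$g_peak / kI$norm)
  )
}

# Low-level batch run; `amps` is an n_combos x 3 matrix of *effective*
# conductance amplitudes (count * g_peak / kernel-normalizer, in uS).
run_batch <- function(model, amps, itd = 0, dt = model$dt, t_end = 10,
                      t_on = 2, record = FALSE) {
  ch <- channel_spec(model, itd, t_on)
  n_steps <- as.integer(round(t_end / dt))
  p <- model$passive
  cur <- model$currents
  out <- cpp_run_batch(p$g1, p$g2, p$gax, p$c1, p$c2,
                       cur$g_Na, cur$g_KHT, cur$E_Na, cur$E_K, cur$q,
                       model$E_rest, dt, n_steps,
                       model$spike_threshold - model$E_rest,
                       ch$on, ch$tr, ch$td, ch$Erel, ch$comp,
                       amps, record)
  if (any(out$unstable))
    stop("numerical instability: voltage exceeded +/-200 mV relative to rest")
  out
}

amps_for_counts <- function(model, n_exc, n_inh_soma, n_inh_ais, itd = 0) {
  ch <- channel_spec(model, itd)
  cbind(n_exc * ch$unit_amp[1], n_inh_soma * ch$unit_amp[2],
        n_inh_ais * ch$unit_amp[3])
}

#' Simulate a single trial
#'
#' Integrates both compartments with synchronized unitary conductances:
#' `n_exc` excitatory inputs on the soma, `n_inh_soma` / `n_inh_ais`
#' inhibitory inputs on soma / AIS.  Excitation onset is offset from
#' inhibition onset by the interaural time difference; positive `itd` means
#' inhibition leads.  A spike is the first upward crossing of the AIS voltage
#' through the model's spike threshold.
#'
#' @param model An [lso_model()] object.
#' @param n_exc,n_inh_soma,n_inh_ais Active input counts (within each
#'   population's maximum).
#' @param itd Interaural time difference (ms); positive = inhibition leads.
#' @param dt Integration step (ms), at most 0.005.
#' @param t_end Simulation length (ms).
#' @param t_on Stimulus buffer onset (ms).
#' @return A data frame of class `"lso_trace"` with columns `t`, `V1`
#'   (soma, mV, absolute) and `V2` (AIS), and attributes `spike` (logical),
#'   `t_spike`, `peaks` (soma/AIS extrema relative to rest) and `meta`.
#' @examples
#' \donttest{
#' m <- lso_model(calibrate = FALSE)
#' tr <- simulate_trial(m, n_exc = 0, n_inh_soma = 8, itd = 0)
#' min(tr$V1)   # peak soma hyperpolarization
#' }
#' @export
simulate_trial <- function(model, n_exc = 0, n_inh_soma = 0, n_inh_ais = 0,
                           itd = 0, dt = model$dt, t_end = 10, t_on = 2) {
  if (dt > 0.005) stop("dt must be <= 0.005 ms")
  if (n_exc > model$synapses$exc$n_max)
    stop("n_exc exceeds the excitatory population size")
  amps <- amps_for_counts(model, n_exc, n_inh_soma, n_inh_ais, itd)
  ch <- channel_spec(model, itd, t_on)
  n_steps <- as.integer(round(t_end / dt))
  p <- model$passive
  cur <- model$currents
  out <- cpp_run_batch(p$g1, p$g2, p$gax, p$c1, p$c2,
                       cur$g_Na, cur$g_KHT, cur$E_Na, cur$E_K, cur$q,
                       model$E_rest, dt, n_steps,
                       model$spike_threshold - model$E_rest,
                       ch$on, ch$tr, ch$td, ch$Erel, ch$comp,
                       amps, TRUE)
  if (any(out$unstable))
    stop("numerical instability: voltage exceeded +/-200 mV relative to rest")
  tr <- data.frame(t = seq(0, by = dt, length.out = n_steps + 1),
                   V1 = out$U1 + model$E_rest,
                   V2 = out$U2 + model$E_rest)
  class(tr) <- c("lso_trace", "data.frame")
  attr(tr, "spike") <- out$spike[1]
  attr(tr, "t_spike") <- out$t_spike[1]
  attr(tr, "peaks") <- c(max1 = out$max1[1], min1 = out$min1[1],
                         max2 = out$max2[1], min2 = out$min2[1])
  attr(tr, "meta") <- list(n_exc = n_exc, n_inh_soma = n_inh_soma,
                           n_inh_ais = n_inh_ais, itd = itd)
  tr
}

#' @export
print.lso_trace <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf(
    "Voltage trace: %d samples, dt = %g ms; nE = %d, nI = %d soma + %d AIS, ITD = %g ms\n",
    nrow(x), x$t[2] - x$t[1], m$n_exc, m$n_inh_soma, m$n_inh_ais, m$itd))
  cat(sprintf("  spike: %s; soma range [%.2f, %.2f] mV\n",
              attr(x, "spike"), min(x$V1), max(x$V1)))
  invisible(x)
}

#' Plot a voltage trace
#'
#' @param x An `"lso_trace"` object.
#' @param ... Passed to [plot()].
#' @export
plot.lso_trace <- function(x, ...) {
  plot(x$t, x$V1, type = "l", xlab = "time (ms)",
       ylab = "membrane potential (mV)",
       ylim = range(c(x$V1, x$V2)), ...)
  lines(x$t, x$V2, col = "grey50")
  legend("topright", c("soma", "AIS"), col = c("black", "grey50"),
         lty = 1, bty = "n")
  invisible(x)
}

#' Write a voltage trace to delimited text
#'
#' Columns `t_ms`, `V1_mV`, `V2_mV`.
#' @param trace An `"lso_trace"` object.
#' @param path Output file path.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(t_ms = trace$t, V1_mV = trace$V1, V2_mV = trace$V2)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
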