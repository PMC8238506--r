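# Double-exponential synaptic conductances and the named kinetic presets.

#' Define a synapse population
#'
#' A population of identical, perfectly synchronized unitary inputs.  Each
#' input is activated independently with probability `p_release` at a common
#' onset time; the unitary conductance is a peak-normalized double
#' exponential, so `g_peak` is the literal conductance maximum.
#'
#' @param n_max Number of unitary inputs in the population.
#' @param p_release Per-input activation probability in `[0, 1]`.
#' @param tau_rise,tau_decay Kernel time constants (ms), `tau_rise < tau_decay`.
#' @param g_peak Unitary peak conductance (uS).
#' @param E_syn Reversal potential (mV): 0 for excitation, -75 for inhibition.
#' @param compartment `"soma"` or `"AIS"`.
#' @param sign `"excitatory"` or `"inhibitory"`.
#' @return An object of class `"lso_synpop"`.
#' @export
synapse_population <- function(n_max, p_release, tau_rise, tau_decay,
                               g_peak, E_syn,
                               compartment = c("soma", "AIS"),
                               sign = c("excitatory", "inhibitory")) {
  compartment <- match.arg(compartment)
  sign <- match.arg(sign)
  if (tau_rise >= tau_decay)
    stop("invalid kinetics: tau_rise must be smaller than tau_decay")
  if (p_release < 0 || p_release > 1) stop("p_release must lie in [0, 1]")
  if (n_max < 0 || n_max != round(n_max)) stop("n_max must be a non-negative integer")
  structure(list(n_max = as.integer(n_max), p_release = p_release,
                 tau_rise = tau_rise, tau_decay = tau_decay,
                 g_peak = g_peak, E_syn = E_syn,
                 compartment = compartment, sign = sign),
            class = "lso_synpop")
}

#' Peak time and normalizer of a double-exponential kernel
#'
#' For `f(t) = exp(-t/tau_decay) - exp(-t/tau_rise)` the maximum is at
#' `t* = tau_rise*tau_decay/(tau_decay - tau_rise) * log(tau_decay/tau_rise)`.
#'
#' @param tau_rise,tau_decay Time constants (ms).
#' @return List with `t_peak` (ms) and `norm`, the unnormalized kernel value
#'   at `t_peak`.
#' @export
kernel_peak <- function(tau_rise, tau_decay) {
  if (tau_rise >= tau_decay)
    stop("invalid kinetics: tau_rise must be smaller than tau_decay")
  tp <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  list(t_peak = tp, norm = exp(-tp / tau_decay) - exp(-tp / tau_rise))
}

#' Unitary synaptic conductance waveform
#'
#' Peak-normalized double exponential
#' `g(t) = g_peak * (exp(-t/tau_decay) - exp(-t/tau_rise)) / norm`,
#' zero for `t < 0`, with maximum exactly `g_peak`.
#'
#' @param pop An `"lso_synpop"` object (or list with `tau_rise`, `tau_decay`,
#'   `g_peak`).
#' @param t Time grid (ms) relative to activation onset.
#' @return Conductance time course (uS).
#' @examples
#' pop <- synapse_population(20, 0.84, 0.1, 0.18, 0.0023, 0)
#' t <- seq(0, 2, by = 0.001)
#' max(synaptic_kernel(pop, t))   # ~0.0023
#' @export
synaptic_kernel <- function(pop, t) {
  k <- kernel_peak(pop$tau_rise, pop$tau_decay)
  g <- ifelse(t < 0, 0,
              (exp(-t / pop$tau_decay) - exp(-t / pop$tau_rise)) / k$norm)
  pop$g_peak * g
}

#' Named synaptic presets
#'
#' `"default_invitro"`: kinetics matched to juvenile in vitro conductance-clamp
#' waveforms -- excitation 0.1/0.18 ms, 2.3 nS, p = 0.84; inhibition
#' 0.45/2.0 ms, 3.1 nS, p = 0.92.
#' `"mature_invivo"`: a faster, mature-animal set -- excitation 0.25/0.4 ms,
#' 1.6 nS, p = 0.82; inhibition 0.35/0.7 ms, 3.9 nS, p = 0.92.
#'
#' The excitatory population (20 inputs) always contacts the soma; the 8
#' inhibitory inputs are divided between soma and AIS by the arrangement
#' chosen at simulation time.
#'
#' @param preset Preset name.
#' @return List with `exc` and `inh` `"lso_synpop"` templates.
#' @export
synapse_preset <- function(preset = c("default_invitro", "mature_invivo")) {
  preset <- match.arg(preset)
  if (preset == "default_invitro") {
    list(
      exc = synapse_population(20, 0.84, 0.1, 0.18, 0.0023, 0,
                               "soma", "excitatory"),
      inh = synapse_population(8, 0.92, 0.45, 2.0, 0.0031, -75,
                               "soma", "inhibitory")
    )
  } else {
    list(
      exc = synapse_population(20, 0.82, 0.25, 0.4, 0.0016, 0,
                               "soma", "excitatory"),
      inh = synapse_population(8, 0.92, 0.35, 0.7, 0.0039, -75,
                               "soma", "inhibitory")
    )
  }
}

#' Parse an inhibitory arrangement label
#'
#' Arrangements divide the 8 inhibitory inputs between soma and AIS:
#' `"8+0"` (all somatic), `"6+2"` (six somatic, two AIS), `"0+2"` (two AIS
#' inputs only).
#'
#' @param arrangement Label or length-2 integer vector `c(n_soma, n_ais)`.
#' @return Named integer vector with `soma` and `ais` counts.
#' @export
parse_arrangement <- function(arrangement) {
  if (is.numeric(arrangement) && length(arrangement) == 2) {
    n <- as.integer(arrangement)
  } else {
    parts <- strsplit(as.character(arrangement), "+", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("arrangement must look like \"6+2\"")
    n <- as.integer(parts)
  }
  if (any(is.na(n)) || any(n < 0)) stop("invalid arrangement counts")
  c(soma = n[1], ais = n[2])
}
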