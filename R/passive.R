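# Passive two-compartment skeleton: coupling-constant parameterization,
# input/transfer resistances, eigen-decomposition decay, and the effective
# soma capacitance fit.
#
# Unit system throughout: mV, ms, uS, nF, nA, MOhm (uS*mV = nA; MOhm*nF = ms).

#' Passive two-compartment parameters from coupling constants
#'
#' Inverts the pair of steady-state voltage-attenuation factors (coupling
#' constants) between soma (compartment 1) and axon initial segment
#' (compartment 2) into lumped leak and axial conductances.  A model of this
#' family is uniquely determined by `(kappa_fwd, kappa_bwd)` together with the
#' soma input resistance:
#' \deqn{g_{ax} = \frac{\kappa_{2\to1}}{R_1 (1 - \kappa_{1\to2}\kappa_{2\to1})},
#'  \quad g_1 = g_{ax}(1/\kappa_{2\to1} - 1), \quad
#'  g_2 = g_{ax}(1/\kappa_{1\to2} - 1).}
#'
#' @param kappa_fwd Forward (soma-to-AIS) coupling constant, in (0, 1).
#' @param kappa_bwd Backward (AIS-to-soma) coupling constant, in (0, 1).
#' @param R1 Soma input resistance (MOhm).
#' @param tau_m Target soma membrane time constant (ms) used by
#'   [fit_effective_capacitance()].
#' @param alpha AIS/soma membrane-area ratio in (0, 1); sets `c2 = alpha * c1`.
#' @param Cm Specific membrane capacitance (uF/cm^2); only used for the
#'   derived effective-area diagnostic `A = c1 / Cm`.
#' @param E_rest Resting potential (mV).
#' @param fit_c1 If `TRUE` (default) the effective soma capacitance is fitted
#'   immediately via [fit_effective_capacitance()].
#'
#' @return An object of class `"lso_passive"`: a list with conductances
#'   `g1`, `g2`, `gax` (uS), capacitances `c1`, `c2` (nF), resistances `R1`,
#'   `R2`, `R12` (MOhm), the coupling configuration, and `E_rest`.
#' @examples
#' p <- passive_from_coupling(0.95, 0.6, R1 = 40)
#' p$R12                      # transfer resistance = R1 * kappa_fwd = 38
#' p$R1 * p$kappa_fwd - p$R2 * p$kappa_bwd   # identity, ~0
#' @export
passive_from_coupling <- function(kappa_fwd, kappa_bwd, R1 = 40,
                                  tau_m = 1, alpha = 0.12, Cm = 0.9,
                                  E_rest = -60, fit_c1 = TRUE) {
  stopifnot(is.numeric(kappa_fwd), length(kappa_fwd) == 1L,
            is.numeric(kappa_bwd), length(kappa_bwd) == 1L)
  if (kappa_fwd <= 0 || kappa_fwd >= 1 || kappa_bwd <= 0 || kappa_bwd >= 1)
    stop("invalid configuration: coupling constants must lie strictly in (0, 1)")
  if (kappa_fwd * kappa_bwd >= 1)
    stop("invalid configuration: kappa_fwd * kappa_bwd must be < 1")
  if (R1 <= 0 || tau_m <= 0) stop("R1 and tau_m must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")

  gax <- kappa_bwd / (R1 * (1 - kappa_fwd * kappa_bwd))
  g1 <- gax * (1 / kappa_bwd - 1)
  g2 <- gax * (1 / kappa_fwd - 1)

  p <- structure(list(
    g1 = g1, g2 = g2, gax = gax,
    c1 = NA_real_, c2 = NA_real_,
    kappa_fwd = kappa_fwd, kappa_bwd = kappa_bwd,
    tau_m = tau_m, alpha = alpha, Cm = Cm, E_rest = E_rest
  ), class = "lso_passive")
  p[c("R1", "R2", "R12")] <- compartment_resistances(p)

  if (fit_c1) {
    p$c1 <- fit_effective_capacitance(p)
    p$c2 <- alpha * p$c1
  }
  p
}

#' Input and transfer resistances of the passive network
#'
#' Steady-state input resistances of the two compartments and the (symmetric)
#' transfer resistance, from the lumped conductances:
#' `R1 = (g2 + gax)/D`, `R2 = (g1 + gax)/D`, `R12 = gax/D` with
#' `D = (g1 + gax)(g2 + gax) - gax^2`.  The identity
#' `R1 * kappa_fwd = R2 * kappa_bwd = R12` holds exactly.
#'
#' @param params An `"lso_passive"` object (or any list with `g1`, `g2`, `gax`).
#' @return Named list with `R1`, `R2`, `R12` in MOhm.
#' @export
compartment_resistances <- function(params) {
  g1 <- params$g1; g2 <- params$g2; gax <- params$gax
  if (any(c(g1, g2, gax) <= 0)) stop("conductances must be positive")
  D <- (g1 + gax) * (g2 + gax) - gax^2
  if (D <= 0) stop("degenerate network: determinant of the conductance matrix is <= 0")
  list(R1 = (g2 + gax) / D, R2 = (g1 + gax) / D, R12 = gax / D)
}

#' Coupling constants from passive conductances
#'
#' Forward map `kappa_fwd = gax/(gax + g2)`, `kappa_bwd = gax/(gax + g1)`;
#' inverse of [passive_from_coupling()].
#'
#' @inheritParams compartment_resistances
#' @return Named list with `kappa_fwd`, `kappa_bwd`, `R1`.
#' @export
coupling_from_passive <- function(params) {
  r <- compartment_resistances(params)
  list(kappa_fwd = params$gax / (params$gax + params$g2),
       kappa_bwd = params$gax / (params$gax + params$g1),
       R1 = r$R1)
}

# Decay matrix M of u' = -M u for a candidate soma capacitance.
decay_matrix <- function(params, c1, alpha = params$alpha) {
  g1 <- params$g1; g2 <- params$g2; gax <- params$gax
  matrix(c((g1 + gax) / c1, -gax / c1,
           -gax / (alpha * c1), (g2 + gax) / (alpha * c1)),
         nrow = 2, byrow = TRUE)
}

#' Passive decay from an initial voltage deviation
#'
#' Solves `u' = -M u` by eigen-decomposition, with
#' `M = [[(g1+gax)/c1, -gax/c1], [-gax/(alpha c1), (g2+gax)/(alpha c1)]]`.
#' Both eigenvalues are real and positive for any valid parameter set (the
#' matrix is similar to a symmetric positive-definite one).
#'
#' @param params An `"lso_passive"` object.
#' @param c1 Soma capacitance (nF); defaults to the fitted value in `params`.
#' @param U0 Length-2 initial deviation from rest `(U1, U2)` in mV.  The
#'   default is the steady-state holding profile `(1, kappa_fwd)`.
#' @param t Time grid (ms, ascending).
#' @param alpha AIS/soma area ratio.
#' @return Matrix with columns `U1`, `U2`, one row per time point.
#' @export
passive_decay <- function(params, c1 = params$c1,
                          U0 = c(1, params$kappa_fwd),
                          t = seq(0, 10, by = 0.001),
                          alpha = params$alpha) {
  if (!is.numeric(c1) || is.na(c1) || c1 <= 0) stop("c1 must be positive")
  if (is.unsorted(t)) stop("t must be ascending")
  M <- decay_matrix(params, c1, alpha)
  e <- eigen(M)
  if (is.complex(e$values) || any(Re(e$values) <= 0))
    stop("numerical failure: decay matrix eigenvalues not real and positive")
  a <- solve(e$vectors, U0)
  U <- e$vectors %*% (a * exp(-outer(e$values, t)))
  out <- t(U)
  colnames(out) <- c("U1", "U2")
  out
}

# Squared-error functional E(c1) = int_0^T (exp(-t/tau_m) - U1(t))^2 dt,
# evaluated by composite Simpson quadrature at 1 us resolution.
capacitance_error <- function(params, c1, T = 10, dt = 0.001) {
  nt <- round(T / dt)
  if (nt %% 2 == 1) nt <- nt + 1
  t <- seq(0, T, length.out = nt + 1)
  U1 <- passive_decay(params, c1 = c1, t = t)[, "U1"]
  f <- (exp(-t / params$tau_m) - U1)^2
  w <- c(1, rep(c(4, 2), length.out = nt - 1), 1)
  sum(w * f) * dt / 3
}

# Golden-section search for a minimum of f over [lo, hi] (log-spaced domain).
golden_section <- function(f, lo, hi, tol = 1e-10) {
  gr <- (sqrt(5) - 1) / 2
  a <- log(lo); b <- log(hi)
  c_ <- b - gr * (b - a); d_ <- a + gr * (b - a)
  fc <- f(exp(c_)); fd <- f(exp(d_))
  while (b - a > tol) {
    if (fc < fd) {
      b <- d_; d_ <- c_; fd <- fc
      c_ <- b - gr * (b - a); fc <- f(exp(c_))
    } else {
      a <- c_; c_ <- d_; fc <- fd
      d_ <- a + gr * (b - a); fd <- f(exp(d_))
    }
  }
  exp((a + b) / 2)
}

#' Fit the effective soma capacitance
#'
#' The passive two-compartment model decays on two time scales; the effective
#' soma capacitance `c1` is chosen so that the soma trajectory `U1(t)`
#' (decaying from the steady-state holding profile `U(0) = (1, kappa_fwd)`)
#' best matches single-exponential decay `exp(-t/tau_m)` in the integrated
#' squared-error sense over `[0, T]`.  The match is approximate by design:
#' with a non-negligible area ratio there is no exact single time scale.
#'
#' Minimization is golden-section search on a log-spaced bracket; the error
#' integral is evaluated by composite Simpson quadrature at 1 us resolution.
#'
#' @param params An `"lso_passive"` object (conductances and `tau_m`, `alpha`).
#' @param T Upper integration limit (ms).
#' @return The fitted `c1` (nF).
#' @export
fit_effective_capacitance <- function(params, T = 10) {
  g_tot <- params$g1 + params$g2
  lo <- params$tau_m * g_tot / 100
  hi <- params$tau_m * g_tot * 100
  f <- function(c1) capacitance_error(params, c1, T = T)
  c1 <- golden_section(f, lo, hi)
  e_star <- f(c1)
  if (e_star > f(lo * 1.0001) || e_star > f(hi * 0.9999))
    stop("no interior minimum of the capacitance error over the search bracket")
  c1
}

#' @export
print.lso_passive <- function(x, ...) {
  cat("Passive two-compartment parameters (soma = 1, AIS = 2)\n")
  cat(sprintf("  coupling: kappa_fwd = %.3f, kappa_bwd = %.3f\n",
              x$kappa_fwd, x$kappa_bwd))
  cat(sprintf("  g1 = %.5f uS, g2 = %.5f uS, gax = %.5f uS\n",
              x$g1, x$g2, x$gax))
  cat(sprintf("  R1 = %.2f MOhm, R2 = %.2f MOhm, R12 = %.2f MOhm\n",
              x$R1, x$R2, x$R12))
  if (!is.na(x$c1))
    cat(sprintf("  c1 = %.4f nF, c2 = %.4f nF (tau_m target %.2f ms)\n",
                x$c1, x$c2, x$tau_m))
  invisible(x)
}
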