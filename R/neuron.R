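#' Morris-Lecar neuron parameters
#'
#' Returns the membrane parameters of the Morris-Lecar model used for every
#' neuron in the network. All parameters are shared between excitatory and
#' inhibitory neurons except the membrane capacitance, which is doubled for
#' inhibitory neurons (making them slower to charge).
#'
#' @param is_inhibitory logical; `TRUE` selects the inhibitory column
#'   (`C_m = 2`), `FALSE` (default) the excitatory one (`C_m = 1`).
#' @return A list with components `g_Ca`, `g_K`, `g_L` (conductance densities,
#'   mS/cm^2), `V_Ca`, `V_K`, `V_L` (reversal potentials, mV), `V1`--`V4`
#'   (gating half-activation and slope voltages, mV), `C_m` (uF/cm^2),
#'   `phi` (rate scale of the K+ gate) and `is_inhibitory`.
#' @export
#' @examples
#' neuron_params()$C_m               # 1 (excitatory)
#' neuron_params(TRUE)$C_m           # 2 (inhibitory)
neuron_params <- function(is_inhibitory = FALSE) {
  p <- list(
    g_Ca = 1, g_K = 2, g_L = 0.5,
    V_Ca = 100, V_K = -70, V_L = -50,
    V1 = -1, V2 = 15, V3 = 10, V4 = 14.5,
    C_m = if (is_inhibitory) 2 else 1,
    phi = 1 / 3,
    is_inhibitory = isTRUE(is_inhibitory)
  )
  validate_neuron_params(p)
  p
}

validate_neuron_params <- function(p) {
  stopifnot(p$g_Ca > 0, p$g_K > 0, p$g_L > 0, p$C_m > 0, p$phi > 0,
            p$V2 != 0, p$V4 != 0)
  invisible(p)
}

#' Steady-state gating variables of the Morris-Lecar model
#'
#' `M_SS` is the instantaneous Ca2+ activation (assumed to track the membrane
#' potential instantaneously) and `W_SS` the steady state of the slow K+ gate:
#' `M_SS = 0.5 (1 + tanh((V - V1)/V2))`, `W_SS = 0.5 (1 + tanh((V - V3)/V4))`.
#'
#' @param V membrane potential (mV); vectorised.
#' @param params a [neuron_params()] list.
#' @return A list with numeric components `M_SS` and `W_SS`, both in (0, 1).
#' @export
gating_steady_states <- function(V, params = neuron_params()) {
  validate_neuron_params(params)
  list(
    M_SS = 0.5 * (1 + tanh((V - params$V1) / params$V2)),
    W_SS = 0.5 * (1 + tanh((V - params$V3) / params$V4))
  )
}

#' Right-hand sides of the Morris-Lecar equations
#'
#' Evaluates the membrane and gate derivatives
#' `C_m dV/dt = I_ext - g_Ca M_SS(V) (V - V_Ca) - g_K W (V - V_K) - g_L (V - V_L)`
#' and `dW/dt = phi (W_SS(V) - W) cosh((V - V3) / (2 V4))`.
#'
#' @param state list with `V` (mV) and `W_gate` (K+ open fraction in `[0,1]`).
#' @param params a [neuron_params()] list.
#' @param I_ext externally applied current (uA/cm^2): synaptic plus noise.
#' @return list with `dV` (mV/ms) and `dW` (1/ms).
#' @export
neuron_derivatives <- function(state, params = neuron_params(), I_ext = 0) {
  validate_neuron_params(params)
  V <- state$V
  W <- state$W_gate
  ss <- gating_steady_states(V, params)
  dV <- (I_ext -
           params$g_Ca * ss$M_SS * (V - params$V_Ca) -
           params$g_K * W * (V - params$V_K) -
           params$g_L * (V - params$V_L)) / params$C_m
  dW <- params$phi * (ss$W_SS - W) * cosh((V - params$V3) / (2 * params$V4))
  list(dV = dV, dW = dW)
}
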