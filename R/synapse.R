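#' Tsodyks-Markram synapse parameters
#'
#' Parameters of the modified Tsodyks-Markram synapse. Excitatory synapses are
#' depressing with a constant utilization (`u = U0`); inhibitory synapses are
#' depressing-facilitating with a dynamic `u` that is incremented on each
#' presynaptic spike and decays with `tau_facil`. The recovery of depressed
#' resources is slowed near full depletion through a tangent nonlinearity (see
#' [synapse_step()]), which prevents run-away tonic firing of the network.
#'
#' The inhibitory strength and decay constant exist at two published levels;
#' `inhibition_level` selects among them: `"low"` (|A| = 10, tau_d = 6),
#' `"high_A"` (|A| = 20, tau_d = 6) and `"high_tau"` (|A| = 10, tau_d = 12).
#'
#' @param pre_type,post_type `"E"` or `"I"`: types of the pre- and
#'   post-synaptic neurons.
#' @param inhibition_level one of `"low"`, `"high_A"`, `"high_tau"`; ignored
#'   for excitatory synapses.
#' @return list with `A_nom` (nominal strength, mV; negative for inhibitory
#'   synapses), `U0` (baseline utilization), `u_dynamic` (logical),
#'   `tau_rec`, `tau_d`, `tau_facil` (ms; `tau_facil` is `NA` for static `u`).
#' @export
#' @examples
#' synapse_params("E", "E")$A_nom                      # 6.25
#' synapse_params("I", "E", "high_A")$A_nom            # -20
synapse_params <- function(pre_type = "E", post_type = "E",
                           inhibition_level = c("low", "high_A", "high_tau")) {
  pre_type <- match.arg(pre_type, c("E", "I"))
  post_type <- match.arg(post_type, c("E", "I"))
  inhibition_level <- match.arg(inhibition_level)
  if (pre_type == "E") {
    p <- list(
      A_nom = if (post_type == "E") 6.25 else 10,
      U0 = 0.2, u_dynamic = FALSE,
      tau_rec = 100, tau_d = 6, tau_facil = NA_real_
    )
  } else {
    A_mag <- if (inhibition_level == "high_A") 20 else 10
    tau_d <- if (inhibition_level == "high_tau") 12 else 6
    p <- list(
      A_nom = -A_mag,
      U0 = 0.06, u_dynamic = TRUE,
      tau_rec = 800, tau_d = tau_d, tau_facil = 1000
    )
  }
  p
}

#' Initial synapse state
#'
#' Synapses start fully recovered: all resources in the recovered pool
#' (`x = 1`, `y = z = 0`) and utilization at its baseline.
#'
#' @param params a [synapse_params()] list.
#' @return list with `x`, `y`, `z` (resource fractions on the simplex
#'   `x + y + z = 1`) and `u` (current utilization).
#' @export
synapse_state <- function(params = synapse_params()) {
  list(x = 1, y = 0, z = 0, u = params$U0)
}

#' Advance a Tsodyks-Markram synapse by one Euler step
#'
#' Integrates the resource kinetics
#' \deqn{\dot x = z\,(-\tan(1.2 z - 1.2))/\tau_{rec},\quad
#'       \dot y = -y/\tau_d,\quad
#'       \dot z = y/\tau_d - z\,(-\tan(1.2 z - 1.2))/\tau_{rec}}
#' by one forward-Euler step of length `dt`, and, if a presynaptic action
#' potential arrives at this step, applies the discrete jumps: for a dynamic
#' utilization first `u <- u + U0 (1 - u)`, then `x <- x - u x`,
#' `y <- y + u x` (with the pre-jump `x`). The tangent factor replaces the
#' linear recovery of the original model so that recovery stalls as the
#' inactive pool approaches full depletion (`z = 1` gives a zero rate).
#'
#' After the Euler step `x`, `y`, `z` are clamped to `[0, 1]` and renormalised
#' to the simplex; the tangent is only defined for `z` in `[0, 1]`.
#'
#' @param state a [synapse_state()] list.
#' @param params a [synapse_params()] list.
#' @param spike_arrived logical: did a presynaptic spike arrive at this step?
#' @param dt step length (ms).
#' @param tol tolerance for the `z` domain check.
#' @return the advanced state list.
#' @export
synapse_step <- function(state, params = synapse_params(),
                         spike_arrived = FALSE, dt = 0.1, tol = 1e-6) {
  x <- state$x; y <- state$y; z <- state$z; u <- state$u
  if (z < -tol || z > 1 + tol) {
    stop("synapse state outside the tangent domain: z = ", format(z))
  }
  zc <- min(max(z, 0), 1)
  rec <- zc * (-tan(1.2 * zc - 1.2)) / params$tau_rec
  x <- x + dt * rec
  y <- y + dt * (-y / params$tau_d)
  z <- z + dt * (y0_over_tau(state$y, params$tau_d) - rec)
  if (params$u_dynamic) {
    u <- u + dt * (-u / params$tau_facil)
  }
  if (isTRUE(spike_arrived)) {
    if (params$u_dynamic) u <- u + params$U0 * (1 - u)
    dx <- u * x
    x <- x - dx
    y <- y + dx
  }
  # clamp to the simplex (guards the tangent domain on the next step)
  x <- min(max(x, 0), 1)
  y <- min(max(y, 0), 1)
  z <- min(max(z, 0), 1)
  s <- x + y + z
  if (s > 0) {
    x <- x / s; y <- y / s; z <- z / s
  } else {
    x <- 1; y <- 0; z <- 0
  }
  list(x = x, y = y, z = z, u = min(max(u, 0), 1))
}

# decay flux out of the active pool, kept as a helper so the z update uses the
# same pre-step y as the y update (plain forward Euler, no operator splitting)
y0_over_tau <- function(y0, tau_d) y0 / tau_d
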