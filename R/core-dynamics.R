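#' Point-neuron parameters
#'
#' Parameters for the rate-coded point neuron used throughout the circuit.
#' Membrane potential integrates excitatory, inhibitory and leak currents,
#' each a conductance times a driving force toward its reversal potential.
#' All potentials live on a normalized 0-1 scale and must satisfy
#' \code{E_i < E_l < theta < E_e}: inhibition and leak pull the membrane
#' below the firing threshold, excitation pulls it above.
#'
#' @param Cm Membrane capacitance; sets the integration time constant.
#' @param E_e,E_i,E_l Excitatory, inhibitory and leak reversal potentials.
#' @param gbar_e,gbar_i,gbar_l Maximal conductances (dimensionless scales).
#' @param theta Firing threshold potential.
#' @param gamma Activation gain (> 0) of the thresholded sigmoid.
#' @param g_l Leak conductance fraction (always-open leak channels).
#' @return A list of class \code{neuron_params}.
#' @export
neuronParams <- function(Cm = 1, E_e = 1, E_i = 0.25, E_l = 0.3,
                         gbar_e = 1, gbar_i = 1, gbar_l = 1,
                         theta = 0.5, gamma = 100, g_l = 0.1) {
  stopifnot(Cm > 0, gamma > 0, g_l >= 0,
            gbar_e >= 0, gbar_i >= 0, gbar_l >= 0)
  if (!(E_i < E_l && E_l < theta && theta < E_e))
    stop("reversal potentials must satisfy E_i < E_l < theta < E_e")
  structure(list(Cm = Cm, E_e = E_e, E_i = E_i, E_l = E_l,
                 gbar_e = gbar_e, gbar_i = gbar_i, gbar_l = gbar_l,
                 theta = theta, gamma = gamma, g_l = g_l),
            class = "neuron_params")
}

#' Feedforward/feedback (FFFB) inhibition parameters
#'
#' Pooled lateral inhibition for a layer: a feedforward term driven by the
#' layer's mean net input and a leaky-integrated feedback term driven by its
#' mean firing rate. The overall gain \code{Gi} sets layer sparsity.
#'
#' @param Gi Overall inhibitory gain (>= 0).
#' @param ff_gain,fb_gain Feedforward / feedback coefficients (>= 0).
#' @param ff_floor Net-input offset below which feedforward inhibition is 0.
#' @param fb_tau Feedback integration time constant in cycles (>= 1).
#' @return A list of class \code{fffb_params}.
#' @export
fffbParams <- function(Gi = 2, ff_gain = 1, ff_floor = 0.1,
                       fb_gain = 1, fb_tau = 1.4) {
  stopifnot(Gi >= 0, ff_gain >= 0, fb_gain >= 0, fb_tau >= 1)
  structure(list(Gi = Gi, ff_gain = ff_gain, ff_floor = ff_floor,
                 fb_gain = fb_gain, fb_tau = fb_tau),
            class = "fffb_params")
}

#' Excitatory conductance from weighted sender groups
#'
#' Net excitatory input to each receiving neuron: for every projection the
#' mean over senders of activity times weight, multiplied by the
#' projection's relative scale, summed over projections. Relative scales are
#' how one pathway (e.g. bottom-up sensory input) is given a larger
#' influence than another (e.g. top-down PFC).
#'
#' @param sender_groups A list of groups, each a list with elements
#'   \code{x} (sender activities), \code{w} (weights: a vector for a single
#'   receiver, or a senders-by-receivers matrix) and \code{scale}
#'   (relative projection scale, >= 0; default 1).
#' @return Per-receiver conductance vector (scalar when all \code{w} are
#'   vectors); non-negative for non-negative activities and weights.
#' @export
excitatoryConductance <- function(sender_groups) {
  total <- NULL
  for (g in sender_groups) {
    scale <- if (is.null(g$scale)) 1 else g$scale
    stopifnot(scale >= 0)
    if (is.matrix(g$w)) {
      if (length(g$x) != nrow(g$w))
        stop("sender activities and weight rows differ in length")
      contrib <- scale * as.numeric(crossprod(g$w, g$x)) / length(g$x)
    } else {
      if (length(g$x) != length(g$w))
        stop("sender activities and weights differ in length")
      contrib <- scale * mean(g$x * g$w)
    }
    total <- if (is.null(total)) contrib else total + contrib
  }
  if (is.null(total)) 0 else total
}

#' Threshold excitatory conductance
#'
#' The excitatory conductance that would put the equilibrium membrane
#' potential exactly at the firing threshold, given the current inhibition
#' and leak: \code{(g_i (E_i - theta) + g_l (E_l - theta)) / (theta - E_e)}.
#'
#' @param g_i_val,g_l_val Inhibitory and leak conductances (>= 0).
#' @param params A \code{\link{neuronParams}} object.
#' @return The threshold conductance (non-negative under the parameter
#'   ordering invariant).
#' @export
thresholdConductance <- function(g_i_val, g_l_val, params) {
  stopifnot(all(g_i_val >= 0), all(g_l_val >= 0))
  if (params$theta == params$E_e)
    stop("theta equal to E_e leaves the threshold conductance undefined")
  (g_i_val * params$gbar_i * (params$E_i - params$theta) +
     g_l_val * params$gbar_l * (params$E_l - params$theta)) /
    ((params$theta - params$E_e) * params$gbar_e)
}

#' Rate-code activation
#'
#' Thresholded sigmoidal transfer: \code{y = 1 / (1 + 1/(gamma * d))} with
#' \code{d = max(ge - ge_theta, 0)}. Zero at or below threshold, strictly
#' increasing above it, asymptoting to 1.
#'
#' @param ge Excitatory conductance (vectorized).
#' @param ge_theta Threshold conductance from
#'   \code{\link{thresholdConductance}}.
#' @param gamma Gain (> 0).
#' @return Activation in [0, 1).
#' @export
rateActivation <- function(ge, ge_theta, gamma) {
  stopifnot(gamma > 0)
  d <- pmax(ge - ge_theta, 0)
  ifelse(d > 0, 1 / (1 + 1 / (gamma * d)), 0)
}

#' One explicit-Euler step of the membrane potential
#'
#' @param vm Membrane potential (vectorized).
#' @param ge,gi Excitatory and inhibitory conductances.
#' @param params A \code{\link{neuronParams}} object.
#' @param dt Step size divided by nothing; the effective rate is
#'   \code{dt / Cm} (default 0.3 per cycle).
#' @return Updated membrane potential; its fixed point is the
#'   conductance-weighted mean of the reversal potentials.
#' @export
integrateVm <- function(vm, ge, gi, params, dt = 0.3) {
  stopifnot(dt > 0)
  I <- ge * params$gbar_e * (params$E_e - vm) +
    gi * params$gbar_i * (params$E_i - vm) +
    params$g_l * params$gbar_l * (params$E_l - vm)
  vm + (dt / params$Cm) * I
}

#' FFFB pooled inhibition step
#'
#' Feedforward part: thresholded-linear in the layer's mean net input.
#' Feedback part: leaky integration of the layer's mean activation.
#'
#' @param mean_net_input Mean excitatory net input across the layer (>= 0).
#' @param mean_activation Mean activation across the layer (>= 0).
#' @param fb_state Current feedback integrator state.
#' @param params A \code{\link{fffbParams}} object.
#' @return List with \code{gi} (inhibitory conductance) and
#'   \code{fb_state} (updated integrator).
#' @export
fffbInhibition <- function(mean_net_input, mean_activation, fb_state,
                           params) {
  stopifnot(mean_net_input >= 0, mean_activation >= 0)
  ff <- params$ff_gain * max(0, mean_net_input - params$ff_floor)
  fb_state <- fb_state +
    (1 / params$fb_tau) * (params$fb_gain * mean_activation - fb_state)
  list(gi = params$Gi * (ff + fb_state), fb_state = fb_state)
}

#' Settle a ring layer under fixed excitatory drive
#'
#' Iterates activation and FFFB inhibition for a fixed number of synchronous
#' cycles under a constant excitatory conductance profile, approximating
#' attractor settling. Deterministic: no noise enters the dynamics.
#'
#' @param ge_input Per-neuron excitatory conductance (constant over cycles).
#' @param n_cycles Number of update cycles (>= 1, default 50).
#' @param neuron A \code{\link{neuronParams}} object.
#' @param fffb A \code{\link{fffbParams}} object.
#' @param fb_init Initial feedback-integrator state.
#' @return List with \code{y} (settled activations), \code{gi} and
#'   \code{fb_state}.
#' @export
settleRing <- function(ge_input, n_cycles = 50, neuron = neuronParams(),
                       fffb = fffbParams(), fb_init = 0) {
  stopifnot(n_cycles >= 1, all(ge_input >= 0))
  y <- numeric(length(ge_input))
  fb <- fb_init
  gi <- 0
  for (cyc in seq_len(n_cycles)) {
    inh <- fffbInhibition(mean(ge_input), mean(y), fb, fffb)
    gi <- inh$gi
    fb <- inh$fb_state
    ge_theta <- thresholdConductance(gi, neuron$g_l, neuron)
    y <- rateActivation(ge_input, ge_theta, neuron$gamma)
    if (any(!is.finite(y)))
      stop("layer dynamics diverged (non-finite activations)")
  }
  list(y = y, gi = gi, fb_state = fb)
}
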