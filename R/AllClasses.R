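#' GLIF3 point-neuron parameter set
#'
#' Membrane, threshold, reset, refractory and after-spike-current constants
#' of a generalized leaky integrate-and-fire neuron with two after-spike
#' currents. Units follow the conventions of point-neuron circuit models:
#' capacitance in pF, conductance in nS, potentials in mV, currents in pA,
#' times in ms. With these units pA/nS = mV, so currents divide by `g`
#' directly in the membrane update.
#'
#' @slot C membrane capacitance (pF), positive.
#' @slot g membrane conductance (nS), positive.
#' @slot EL resting membrane potential (mV).
#' @slot vth spiking threshold (mV).
#' @slot vr reset potential (mV).
#' @slot deltaR refractory period (ms), in \[2, 8\].
#' @slot k decay rates of the two after-spike currents (1/ms), positive.
#' @slot A after-spike additive constants (pA).
#' @slot R after-spike reset multipliers (dimensionless, typically 1).
#'
#' @seealso [GLIFParams()] for the constructor, [membraneTau()].
#' @export
setClass("GLIFParams",
  representation(
    C = "numeric", g = "numeric", EL = "numeric", vth = "numeric",
    vr = "numeric", deltaR = "numeric", k = "numeric", A = "numeric",
    R = "numeric"
  ),
  prototype(
    C = 100, g = 5, EL = -70, vth = -45, vr = -70, deltaR = 2,
    k = c(0.03, 0.003), A = c(0, 0), R = c(1, 1)
  )
)

setValidity("GLIFParams", function(object) {
  msg <- character()
  for (s in c("C", "g", "EL", "vth", "vr", "deltaR")) {
    if (length(slot(object, s)) != 1 || !is.finite(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  }
  if (length(msg) == 0) {
    if (object@C <= 0) msg <- c(msg, "'C' must be positive")
    if (object@g <= 0) msg <- c(msg, "'g' must be positive")
    if (object@deltaR < 2 || object@deltaR > 8)
      msg <- c(msg, "'deltaR' must lie in [2, 8] ms")
    if (length(object@k) != 2 || any(!is.finite(object@k)) ||
        any(object@k <= 0))
      msg <- c(msg, "'k' must be two positive decay rates")
    if (length(object@A) != 2 || any(!is.finite(object@A)))
      msg <- c(msg, "'A' must be two finite constants")
    if (length(object@R) != 2 || any(!is.finite(object@R)))
      msg <- c(msg, "'R' must be two finite multipliers")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic laminar cortical column
#'
#' A seeded realization of a cylindrical laminar microcircuit: neuron
#' placement and cell-type composition, recurrent synapses sampled from
#' distance-dependent Gaussian connection probabilities with like-to-like
#' excitatory weight modulation, LGN afferents restricted to the permitted
#' target classes, and per-neuron background weights for the shared 1 kHz
#' Poisson source.
#'
#' @slot neurons data.frame with one row per neuron: `id` (1-based),
#'   `type`, `layer`, `cellClass`, positions `x`, `y`, `z` (um) and tuning
#'   angle `theta` (degrees in \[0, 360)).
#' @slot recurrent data.frame of recurrent synapses: `pre`, `post`
#'   (neuron ids), `weight` (pA), `delay` (integer steps), `channel`
#'   (`"recE"` or `"recI"` by presynaptic class).
#' @slot lgn data.frame of thalamocortical synapses: `unit` (LGN unit id),
#'   `post`, `weight` (pA), `delay` (steps).
#' @slot background numeric vector, one non-negative weight (pA) per neuron.
#' @slot lgnUnits data.frame describing the LGN front-end units (positions
#'   in degrees, polarity, spatial phase, rates).
#' @slot glif named list of [GLIFParams-class] objects, one per neuron type.
#' @slot geometry list: `radius` (um) and `layerDepths` (named list of
#'   c(top, bottom) depth intervals, um).
#' @slot config the full configuration list the column was built from.
#' @slot seed integer seed of this realization.
#' @export
setClass("CorticalColumn",
  representation(
    neurons = "data.frame", recurrent = "data.frame", lgn = "data.frame",
    background = "numeric", lgnUnits = "data.frame", glif = "list",
    geometry = "list", config = "list", seed = "integer"
  )
)

setValidity("CorticalColumn", function(object) {
  msg <- character()
  nn <- nrow(object@neurons)
  need <- c("id", "type", "layer", "cellClass", "x", "y", "z", "theta")
  if (!all(need %in% names(object@neurons)))
    msg <- c(msg, "neuron table is missing required columns")
  if (length(object@background) != nn)
    msg <- c(msg, "background weight vector length must equal neuron count")
  if (any(object@background < 0))
    msg <- c(msg, "background weights must be non-negative")
  if (nrow(object@recurrent)) {
    if (any(object@recurrent$pre == object@recurrent$post))
      msg <- c(msg, "self-synapses are not allowed")
    if (any(object@recurrent$delay < 1))
      msg <- c(msg, "synaptic delays must be >= 1 step")
  }
  if (nn && "L1" %in% object@neurons$layer) {
    l1 <- object@neurons$cellClass[object@neurons$layer == "L1"]
    if (any(l1 != "Htr3a"))
      msg <- c(msg, "L1 may contain only Htr3a neurons")
  }
  if (nn && !is.null(object@geometry$radius)) {
    r2 <- object@neurons$x^2 + object@neurons$y^2
    if (any(r2 > object@geometry$radius^2 * (1 + 1e-9)))
      msg <- c(msg, "all neurons must lie inside the column cylinder")
  }
  if (nrow(object@lgn)) {
    tt <- object@neurons[match(object@lgn$post, object@neurons$id), ]
    ok <- (tt$cellClass %in% c("Exc", "Pvalb") & tt$layer != "L1") |
      (tt$cellClass == "Htr3a" & tt$layer == "L1")
    if (!all(ok))
      msg <- c(msg, paste(
        "LGN synapses may target only Exc/Pvalb outside L1",
        "and Htr3a in L1"
      ))
  }
  if (length(msg)) msg else TRUE
})

#' Simulation result of a visual-flow experiment
#'
#' Spike rasters and per-source input-current records for a set of trials
#' of one stimulus protocol. The warm-up trial used to flush the all-zero
#' initial condition is never included: `spikes$trial` runs over analyzed
#' trials only. Currents are decomposed by source: LGN (`in`), background
#' (`noise`), recurrent (`rec`) and after-spike (`asc`); the total input
#' current of a neuron is their sum.
#'
#' @slot spikes data.frame: `trial`, `neuron`, `step` (0-based time step).
#' @slot windowSums list, one element per analyzed trial; each a named list
#'   of `nWindow x nNeuron` matrices (`in`, `noise`, `rec`, `asc`) holding
#'   the per-window *sums* of each current source over the window steps.
#' @slot windows data.frame describing the recording windows: `label`,
#'   `start`, `end` (half-open step intervals).
#' @slot traces optional list (per trial) of full `T x nNeuron` trace
#'   matrices (`in`, `noise`, `rec`, `asc`, `v`); empty unless requested.
#' @slot protocol the [StimulusProtocol][gratingProtocol()] list simulated.
#' @slot dt integration step (ms).
#' @slot nSteps steps per trial.
#' @slot nTrials number of analyzed trials.
#' @slot seed master seed of the run.
#' @export
setClass("FlowSimResult",
  representation(
    spikes = "data.frame", windowSums = "list", windows = "data.frame",
    traces = "list", protocol = "list", dt = "numeric", nSteps = "integer",
    nTrials = "integer", seed = "integer"
  )
)

setValidity("FlowSimResult", function(object) {
  msg <- character()
  if (length(object@windowSums) != object@nTrials)
    msg <- c(msg, "one windowSums entry per analyzed trial is required")
  if (nrow(object@spikes) &&
      (min(object@spikes$step) < 0 || max(object@spikes$step) >= object@nSteps))
    msg <- c(msg, "spike steps must lie in [0, nSteps)")
  if (length(msg)) msg else TRUE
})
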