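# Discrete-time GLIF3 network simulation. The per-step integrator lives in
# src/glif.cpp; this file exposes the elementary update rules (useful for
# checking the dynamics against closed forms), the rheobase procedure, and
# the trial-level orchestrator.

#' Elementary GLIF3 update rules
#'
#' One integration step of each state variable, exposed as pure functions.
#' `membraneUpdate` applies the exponential-Euler membrane rule
#' `v <- alpha*v + (1 - alpha)*((Iext + Iint)/g + EL)` with
#' `alpha = exp(-dt/tau)`, `tau = C/g`. `ascUpdate` applies the
#' after-spike-current recursion `I <- exp(-k*dt)*I + spiked*A`.
#' `applyReset` applies the post-refractory reset `v <- vr`,
#' `I_m <- R_m*I_m + A_m`. `synapseUpdate` advances one alpha-function
#' channel: `I <- a*(I + dt*C)`, `C <- a*C + input*exp(1)/tau` with
#' `a = exp(-dt/tau)`; `input` is the summed weighted spike arrival
#' (sum of W*z, pA).
#'
#' @param v membrane potential(s), mV.
#' @param params a [GLIFParams-class] object.
#' @param Iext,Iint external and after-spike current sums (pA).
#' @param dt step (ms).
#' @param I,C alpha-channel state pair (pA).
#' @param k,A,R after-spike decay rate(s), additive constant(s) and reset
#'   multiplier(s).
#' @param spiked 0/1 spike indicator.
#' @param asc after-spike current vector (length 2).
#' @param input summed weighted arrivals at this step (pA).
#' @param tau synaptic time constant (ms), positive.
#' @return the updated state (a list for `applyReset` and
#'   `synapseUpdate`).
#' @name glif-updates
NULL

#' @rdname glif-updates
#' @export
membraneUpdate <- function(v, params, Iext, Iint, dt = 1) {
  if (any(!is.finite(c(v, Iext, Iint)))) stop("non-finite membrane inputs")
  alpha <- exp(-dt / membraneTau(params))
  alpha * v + (1 - alpha) * ((Iext + Iint) / params@g + params@EL)
}

#' @rdname glif-updates
#' @export
ascUpdate <- function(I, k, A, spiked = 0, dt = 1) {
  exp(-k * dt) * I + spiked * A
}

#' @rdname glif-updates
#' @export
applyReset <- function(v, asc, params) {
  list(v = params@vr, asc = params@R * asc + params@A)
}

#' @rdname glif-updates
#' @export
synapseUpdate <- function(I, C, input, tau, dt = 1) {
  if (tau <= 0) stop("synaptic time constant must be positive")
  a <- exp(-dt / tau)
  list(I = a * (I + dt * C), C = a * C + input * exp(1) / tau)
}

#' Alpha-function response to a spike-arrival train
#'
#' Iterates the discrete alpha-synapse recursion over a train of weighted
#' arrivals and returns the current trace. A single arrival of weight `W`
#' at entry `s` produces `I[s + 1 + n] = W*(n*dt/tau)*exp(1 - n*dt/tau)`
#' at grid points (current starts flowing one step after the arrival
#' enters the channel).
#'
#' @param arrivals numeric vector of summed weighted arrivals per step
#'   (pA).
#' @param tau synaptic time constant (ms).
#' @param dt step (ms).
#' @return numeric vector: the synaptic current at each step (pA), aligned
#'   with `arrivals` (entry `t` is the current at time `t*dt`, before the
#'   arrival at `t` acts).
#' @export
alphaTrace <- function(arrivals, tau, dt = 1) {
  n <- length(arrivals)
  out <- numeric(n)
  I <- 0
  C <- 0
  for (t in seq_len(n)) {
    out[t] <- I
    st <- synapseUpdate(I, C, arrivals[t], tau, dt)
    I <- st$I
    C <- st$C
  }
  out
}

#' Rheobase of a GLIF parameter set
#'
#' Minimum rectangular-pulse current eliciting at least one spike during a
#' 1000 ms pulse from rest, found by scanning pulses starting at 1 pA in
#' 0.01 pA increments with a full state reset between pulses.
#'
#' @param params a [GLIFParams-class] object.
#' @param start first pulse amplitude (pA).
#' @param increment pulse increment (pA).
#' @param pulse pulse duration (ms).
#' @param dt step (ms).
#' @param ceiling give up above this amplitude (pA).
#' @return rheobase current (pA).
#' @examples
#' rheobase(GLIFParams(g = 10, EL = -70, vth = -60)) # near 100 pA
#' @export
rheobase <- function(params, start = 1, increment = 0.01, pulse = 1000,
                     dt = 1, ceiling = 2000) {
  stopifnot(is(params, "GLIFParams"))
  out <- cpp_rheobase(
    params@C, params@g, params@EL, params@vth, dt,
    start, increment, ceiling, as.integer(round(pulse / dt))
  )
  if (is.na(out)) {
    stop("non-excitable: no spike elicited below the ceiling of ",
         ceiling, " pA")
  }
  out
}

# pack a CorticalColumn into flat arrays for the C++ integrator
packColumn <- function(column, dt, tauSyn) {
  nt <- column@neurons
  N <- nrow(nt)
  glif <- column@glif[nt$type]
  getp <- function(f) vapply(glif, f, numeric(1))
  Cap <- getp(function(p) p@C)
  g <- getp(function(p) p@g)
  pars <- list(
    alphaMem = exp(-dt / (Cap / g)), gmem = g,
    EL = getp(function(p) p@EL), vth = getp(function(p) p@vth),
    vr = getp(function(p) p@vr),
    refSteps = as.integer(round(getp(function(p) p@deltaR) / dt)),
    dk1 = exp(-getp(function(p) p@k[1]) * dt),
    dk2 = exp(-getp(function(p) p@k[2]) * dt),
    A1 = getp(function(p) p@A[1]), A2 = getp(function(p) p@A[2]),
    R1 = getp(function(p) p@R[1]), R2 = getp(function(p) p@R[2])
  )
  # synaptic time constants by (source E/I, target E/I); channels:
  # 1 = LGN, 2 = background (both excitatory sources), 3 = recE, 4 = recI
  exc <- isExcClass(nt$cellClass)
  tauE <- ifelse(exc, tauSyn[["EE"]], tauSyn[["EI"]])
  tauI <- ifelse(exc, tauSyn[["IE"]], tauSyn[["II"]])
  chanTau <- rbind(tauE, tauE, tauE, tauI)
  pars$chanTau <- chanTau
  pars$chanDecay <- exp(-dt / chanTau)

  rec <- column@recurrent
  ord <- order(rec$pre)
  rec <- rec[ord, , drop = FALSE]
  pars$recPtr <- c(0L, cumsum(tabulate(rec$pre, nbins = N)))
  pars$recPost <- as.integer(rec$post - 1L)
  pars$recDelay <- as.integer(rec$delay)
  pars$recChan <- ifelse(rec$channel == "recE", 2L, 3L)
  pars$recW <- rec$weight

  lgn <- column@lgn
  nUnits <- nrow(column@lgnUnits)
  ord <- order(lgn$unit)
  lgn <- lgn[ord, , drop = FALSE]
  pars$lgnPtr <- c(0L, cumsum(tabulate(lgn$unit, nbins = nUnits)))
  pars$lgnPost <- as.integer(lgn$post - 1L)
  pars$lgnDelay <- as.integer(lgn$delay)
  pars$lgnW <- lgn$weight
  pars$bkgW <- column@background
  pars
}

defaultWindows <- function(protocol, dt) {
  pt <- as.integer(round(protocol$perturbationTime / dt))
  base <- as.integer(round(min(500, protocol$perturbationTime) / dt))
  flowLen <- as.integer(round(protocol$epochs$duration[2] / dt))
  data.frame(
    label = c("baseline", "flow", "post500"),
    start = c(pt - base, pt, pt),
    end = c(pt, pt + flowLen, pt + min(flowLen, as.integer(500 / dt)))
  )
}

#' Simulate a column under a stimulus protocol
#'
#' Runs `nTrials + 1` trials of the protocol: all state variables start at
#' zero (or at rest, see `initAtRest`), the first trial absorbs the onset
#' transient and is discarded, and state carries over between trials.
#' Every trial re-draws the LGN Poisson spikes and the shared 1 kHz
#' background train from per-trial seeds derived deterministically from
#' the master seed. Per-source input currents (LGN, background, recurrent,
#' after-spike) are accumulated as sums over the recording windows; full
#' traces can be recorded for small networks.
#'
#' @param column a [CorticalColumn-class].
#' @param protocol a stimulus protocol ([gratingProtocol()],
#'   [flashProtocol()]).
#' @param nTrials number of analyzed trials (a discarded warm-up trial is
#'   always prepended).
#' @param seed master seed for the run.
#' @param dt integration step (ms).
#' @param windows data.frame (`label`, `start`, `end` in steps, half-open)
#'   of recording windows; defaults to a baseline window covering the
#'   500 ms before the perturbation, the full perturbation epoch
#'   (`"flow"`), and its first 500 ms (`"post500"`).
#' @param recordTraces record full per-step current and voltage traces per
#'   trial (memory scales with `T x nNeurons x nTrials`).
#' @param initAtRest start at `v = EL` instead of the literal all-zero
#'   initial state.
#' @param iInject optional constant per-neuron injected current (pA) added
#'   to the external current.
#' @param backgroundRate rate (1/s) of the shared background source.
#' @param warmup prepend the discarded warm-up trial (default). Disable
#'   only for controlled single-neuron experiments that must start from
#'   the exact initial state.
#' @return a [FlowSimResult-class] object.
#' @export
simulateColumn <- function(column, protocol, nTrials = 20, seed = 1,
                           dt = 1, windows = NULL, recordTraces = FALSE,
                           initAtRest = FALSE, iInject = NULL,
                           backgroundRate = NULL, warmup = TRUE) {
  stopifnot(is(column, "CorticalColumn"))
  cfg <- column@config
  tauSyn <- cfg$connectivity$tauSyn
  if (is.null(tauSyn)) {
    tauSyn <- c(EE = 5.5, IE = 8.5, EI = 2.8, II = 5.8)
  }
  if (is.null(backgroundRate)) {
    backgroundRate <- if (!is.null(cfg$background$rate)) {
      cfg$background$rate
    } else {
      1000
    }
  }
  lgnCfg <- cfg$lgn
  rates <- lgnRates(
    protocol, column@lgnUnits,
    dt = dt,
    temporalFilter = if (!is.null(lgnCfg$temporalFilter)) {
      lgnCfg$temporalFilter
    } else {
      "biphasic"
    },
    kernel = if (!is.null(lgnCfg$kernel)) {
      lgnCfg$kernel
    } else {
      list(tau1 = 10, tau2 = 30)
    }
  )
  T <- ncol(rates)
  N <- nNeurons(column)
  if (is.null(windows)) windows <- defaultWindows(protocol, dt)
  if (any(windows$start < 0) || any(windows$end > T))
    stop("recording windows must lie within the trial")
  if (is.null(iInject)) iInject <- numeric(N)

  pars <- packColumn(column, dt, tauSyn)

  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  nWarm <- if (warmup) 1L else 0L
  nRuns <- nTrials + nWarm
  trialSeeds <- matrix(
    sample.int(.Machine$integer.max - 1L, 2L * (nTrials + 1L)),
    nrow = nTrials + 1L
  )[seq_len(nRuns) + (1L - nWarm), , drop = FALSE]

  # mutable state, carried across trials
  v <- if (initAtRest) pars$EL + 0 else numeric(N)
  asc1 <- numeric(N)
  asc2 <- numeric(N)
  refr <- integer(N)
  synI <- matrix(0, 4, N)
  synC <- matrix(0, 4, N)

  spikes <- vector("list", nTrials)
  winSums <- vector("list", nTrials)
  traces <- if (recordTraces) vector("list", nTrials) else list()

  for (run in seq_len(nRuns)) {
    counts <- lgnSpikes(rates, dt, seed = trialSeeds[run, 1])
    bkg <- poissonSource(backgroundRate, T * dt, dt,
      seed = trialSeeds[run, 2]
    )
    res <- cpp_glif_trial(
      v, asc1, asc2, refr, synI, synC,
      pars$alphaMem, pars$gmem, pars$EL, pars$vth, pars$vr, pars$refSteps,
      pars$dk1, pars$dk2, pars$A1, pars$A2, pars$R1, pars$R2,
      pars$chanDecay, pars$chanTau,
      pars$recPtr, pars$recPost, pars$recDelay, pars$recChan, pars$recW,
      pars$lgnPtr, pars$lgnPost, pars$lgnDelay, pars$lgnW,
      pars$bkgW, counts, bkg, iInject,
      as.integer(T), dt,
      as.integer(windows$start), as.integer(windows$end),
      recordTraces
    )
    if (run > nWarm) {
      k <- run - nWarm
      spikes[[k]] <- data.frame(
        trial = rep(k, length(res$spikeNeuron)),
        neuron = res$spikeNeuron + 1L,
        step = res$spikeStep
      )
      winSums[[k]] <- res$windowSums
      if (recordTraces) traces[[k]] <- res$traces
    }
  }

  new("FlowSimResult",
    spikes = do.call(rbind, spikes), windowSums = winSums,
    windows = windows, traces = traces, protocol = protocol, dt = dt,
    nSteps = as.integer(T), nTrials = as.integer(nTrials),
    seed = as.integer(seed)
  )
}
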