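# Response analysis: baseline and flow-response currents, dVf/hVf
# classification, firing-rate smoothing, sweep sub-classification,
# effective synaptic weights and Ripley's K.

#' Baseline input current
#'
#' Mean total input current over the 500 ms (by default) preceding the
#' perturbation, averaged across trials.
#'
#' @param trace numeric vector (one trial, one neuron) or matrix
#'   (steps x trials) of total input current (pA).
#' @param onset perturbation step (0-based); the window is the half-open
#'   step interval `[onset - width/dt, onset)`.
#' @param dt step (ms).
#' @param width window width (ms).
#' @return baseline current (pA).
#' @export
baselineCurrent <- function(trace, onset, dt = 1, width = 500) {
  if (is.vector(trace)) trace <- matrix(trace, ncol = 1)
  w <- as.integer(round(width / dt))
  if (onset - w < 0 || onset > nrow(trace))
    stop("baseline window lies outside the trace")
  mean(trace[seq(onset - w + 1, onset), , drop = FALSE])
}

#' Visual-flow response with per-source decomposition
#'
#' Computes, for every neuron, the trial-averaged mean of each input
#' current source over the perturbation window and the response
#' `deltaI = <in> + <noise> + <rec> + <asc> - I0`, where `I0` is the
#' trial-averaged baseline of the total current.
#'
#' @param sim a [FlowSimResult-class] with `"baseline"` and `window`
#'   windows recorded.
#' @param window label of the response window (default `"flow"`).
#' @param I0 optional externally supplied baseline currents (pA, one per
#'   neuron); computed from the `"baseline"` window if `NULL`.
#' @return data.frame: `id`, `I0`, `dIn`, `dNoise`, `dRec`, `dAsc` (the
#'   window means per source, pA) and `deltaI`.
#' @export
deltaCurrent <- function(sim, window = "flow", I0 = NULL) {
  stopifnot(is(sim, "FlowSimResult"))
  flow <- windowMeans(sim, window)
  if (is.null(I0)) {
    basePer <- windowMeans(sim, "baseline", perTrial = TRUE)
    I0 <- Reduce(`+`, lapply(basePer, colSums)) / length(basePer)
  }
  if (length(I0) != ncol(flow))
    stop("I0 length must match the neuron count")
  data.frame(
    id = seq_len(ncol(flow)), I0 = I0,
    dIn = flow["in", ], dNoise = flow["noise", ], dRec = flow["rec", ],
    dAsc = flow["asc", ],
    deltaI = flow["in", ] + flow["noise", ] + flow["rec", ] +
      flow["asc", ] - I0
  )
}

#' Classify responses as dVf / hVf / unclassified
#'
#' A neuron is depolarized by visual flow (dVf) when its response exceeds
#' `+factor * thetaRheo`, hyperpolarized (hVf) when it falls below
#' `-factor * thetaRheo`, and unclassified otherwise. The inequalities are
#' strict: responses exactly at a threshold stay unclassified.
#'
#' @param deltaI response current(s), pA.
#' @param thetaRheo rheobase(s), pA, positive.
#' @param factor threshold factor (default 0.05).
#' @return factor with levels `dVf`, `hVf`, `unclassified`.
#' @export
classifyResponse <- function(deltaI, thetaRheo, factor = 0.05) {
  if (any(!is.finite(deltaI))) stop("non-finite response values")
  if (any(thetaRheo <= 0)) stop("rheobase must be positive")
  thr <- factor * thetaRheo
  out <- rep("unclassified", length(deltaI))
  out[deltaI > +thr] <- "dVf"
  out[deltaI < -thr] <- "hVf"
  factor(out, levels = c("dVf", "hVf", "unclassified"))
}

#' Per-neuron response summary of a visual-flow experiment
#'
#' Combines [deltaCurrent()], the per-type [rheobase()] and
#' [classifyResponse()] into the standard per-neuron summary table.
#'
#' @param sim a [FlowSimResult-class].
#' @param column the simulated [CorticalColumn-class].
#' @param factor classification threshold factor (times rheobase).
#' @param window response window label.
#' @param rheo optional named vector of rheobase currents per neuron type;
#'   computed with [rheobase()] defaults when `NULL`.
#' @return data.frame: neuron identity (`id`, `type`, `layer`,
#'   `cellClass`), `I0`, source means, `deltaI`, `thetaRheo`, `label`.
#' @export
responseSummary <- function(sim, column, factor = 0.05, window = "flow",
                            rheo = NULL) {
  nt <- neuronTable(column)
  if (is.null(rheo)) {
    rheo <- vapply(glifCatalog(column), rheobase, numeric(1))
  }
  dc <- deltaCurrent(sim, window = window)
  out <- cbind(
    nt[, c("id", "type", "layer", "cellClass")],
    dc[, c("I0", "dIn", "dNoise", "dRec", "dAsc", "deltaI")]
  )
  out$thetaRheo <- unname(rheo[nt$type])
  out$label <- classifyResponse(out$deltaI, out$thetaRheo, factor)
  out
}

#' Smoothed firing-rate trace
#'
#' Bins a spike train at the sampling rate and convolves with a Gaussian
#' kernel (standard deviation `kernelWidth`, truncated at three standard
#' deviations, normalized to unit mass so the total spike count is
#' preserved up to edge truncation).
#'
#' @param spikeTimes spike times (ms).
#' @param duration trace duration (ms).
#' @param sampleRate sampling rate (Hz).
#' @param kernelWidth Gaussian standard deviation (ms).
#' @return data.frame: `time` (ms, bin centres), `rate` (1/s).
#' @export
smoothFiringRate <- function(spikeTimes, duration, sampleRate = 60,
                             kernelWidth = 150) {
  binW <- 1000 / sampleRate
  nb <- ceiling(duration / binW)
  if (length(spikeTimes) &&
      (min(spikeTimes) < 0 || max(spikeTimes) > duration))
    stop("spike times must lie within [0, duration]")
  counts <- tabulate(pmin(floor(spikeTimes / binW) + 1, nb), nbins = nb)
  half <- ceiling(3 * kernelWidth / binW)
  kern <- exp(-0.5 * ((-half:half) * binW / kernelWidth)^2)
  kern <- kern / sum(kern)
  padded <- c(numeric(half), counts, numeric(half))
  sm <- vapply(seq_len(nb), function(i) {
    sum(padded[i:(i + 2 * half)] * rev(kern))
  }, numeric(1))
  data.frame(
    time = (seq_len(nb) - 0.5) * binW,
    rate = sm / binW * 1000
  )
}

#' Effective synaptic weights
#'
#' The effective weight of a synapse over a time window is the anatomical
#' weight gated by presynaptic firing: `(1/dt) * sum_t W * x_i(t)` with
#' `x_i(t)` the 0/1 firing state of the presynaptic neuron and the sum
#' over the `dt` window steps (`effectiveWeightPair`). Contributions of
#' all presynaptic neurons of one type to a target are summed
#' (`effectiveWeightType`).
#'
#' @param W synaptic weight (pA).
#' @param x 0/1 firing indicator over the window steps.
#' @param pairValues pairwise effective weights of the members of one
#'   presynaptic type.
#' @return effective weight (pA spikes per step).
#' @export
effectiveWeightPair <- function(W, x) {
  if (!length(x)) stop("window must contain at least one step")
  W * sum(x) / length(x)
}

#' @rdname effectiveWeightPair
#' @export
effectiveWeightType <- function(pairValues) sum(pairValues)

#' Windowed effective-weight table of a simulation
#'
#' Computes, for every target neuron and presynaptic neuron type, the
#' trial-averaged effective synaptic weight in the 500 ms windows before
#' and after the perturbation.
#'
#' @param sim a [FlowSimResult-class].
#' @param column the simulated [CorticalColumn-class].
#' @param windowLength window length (ms).
#' @return data.frame: `post` (target id), `preType`, `epoch`
#'   (`"pre"`/`"post"`), `weff` (pA spikes per step). Targets or types
#'   without active presynaptic partners get 0 rows.
#' @export
effectiveWeights <- function(sim, column, windowLength = 500) {
  stopifnot(is(sim, "FlowSimResult"), is(column, "CorticalColumn"))
  pt <- sim@windows$start[match("flow", sim@windows$label)]
  steps <- as.integer(round(windowLength / sim@dt))
  eps <- list(
    pre = c(pt - steps, pt),
    post = c(pt, pt + steps)
  )
  spk <- data.table::as.data.table(sim@spikes)
  syn <- data.table::as.data.table(column@recurrent)
  nt <- neuronTable(column)
  syn[, preType := nt$type[pre]]
  out <- lapply(names(eps), function(ep) {
    win <- eps[[ep]]
    # trial-averaged spike counts per presynaptic neuron in the window
    cnt <- spk[step >= win[1] & step < win[2], .N, by = neuron]
    x <- numeric(nrow(nt))
    if (nrow(cnt)) x[cnt$neuron] <- cnt$N / sim@nTrials
    syn2 <- syn[, .(weff = sum(weight * x[pre]) / steps),
      by = .(post, preType)
    ]
    syn2[, epoch := ep]
    syn2
  })
  res <- as.data.frame(data.table::rbindlist(out))
  res[, c("post", "preType", "epoch", "weff")]
}

#' Ripley's K function on a disk domain
#'
#' `K(t) = (A/n^2) * sum_i N_i(t)` with `A` the disk area and `N_i(t)` the
#' border-corrected neighbour count within planar distance `t` of point
#' `i`: counts are divided by the fraction of the search-circle area lying
#' inside the domain. Under complete spatial randomness K(t) scales as
#' `pi t^2`.
#'
#' @param xy two-column matrix of planar positions (um).
#' @param radii search-radius grid (um), increasing.
#' @param R domain (column) radius (um).
#' @param center domain centre.
#' @return data.frame: `t`, `K`, `csr` (`pi t^2`); the domain area is
#'   attached as attribute `"area"`.
#' @examples
#' pts <- cbind(c(0, 1, 3), c(0, 0, 0))
#' ripleyK(pts, radii = 1.5, R = 10) # K = (100 pi / 9) * 2
#' @export
ripleyK <- function(xy, radii, R, center = c(0, 0)) {
  xy <- as.matrix(xy)
  x <- xy[, 1] - center[1]
  y <- xy[, 2] - center[2]
  if (any(x^2 + y^2 > R^2 * (1 + 1e-12)))
    stop("all points must lie inside the domain disk")
  if (is.unsorted(radii)) stop("radii must be increasing")
  K <- cpp_ripley_k(x, y, as.numeric(radii), R)
  out <- data.frame(t = radii, K = K, csr = pi * radii^2)
  attr(out, "area") <- pi * R^2
  out
}

#' Sub-classification across a direction sweep
#'
#' A neuron keeping one non-unclassified label across all 8 directions is
#' perturbation-sensitive (of that sign); a neuron responding in exactly
#' one direction and unclassified in all others is direction-selective;
#' anything else is `other`.
#'
#' @param labels character/factor matrix (neurons x 8 directions) or a
#'   vector of 8 labels for a single neuron.
#' @return factor with levels `perturbation_dVf`, `perturbation_hVf`,
#'   `direction_dVf`, `direction_hVf`, `other`.
#' @export
classifyAcrossDirections <- function(labels) {
  if (is.null(dim(labels))) labels <- matrix(labels, nrow = 1)
  labels <- as.matrix(labels)
  if (ncol(labels) != 8)
    stop("one label per direction (8 directions) is required")
  one <- function(l) {
    if (all(l == "dVf")) return("perturbation_dVf")
    if (all(l == "hVf")) return("perturbation_hVf")
    resp <- l != "unclassified"
    if (sum(resp) == 1) {
      return(paste0("direction_", l[resp]))
    }
    "other"
  }
  factor(apply(labels, 1, one),
    levels = c(
      "perturbation_dVf", "perturbation_hVf", "direction_dVf",
      "direction_hVf", "other"
    )
  )
}

#' Preferred temporal frequency of a classified neuron
#'
#' The frequency at which a dVf neuron receives its highest (hVf: lowest)
#' response current during visual flow. Ties break toward the lower
#' frequency.
#'
#' @param deltaI responses over the frequency grid (pA).
#' @param label `"dVf"` or `"hVf"`.
#' @param tfs frequency grid (Hz), increasing.
#' @return preferred frequency (Hz).
#' @export
preferredFrequency <- function(deltaI, label, tfs = 1:9) {
  if (length(deltaI) != length(tfs))
    stop("a complete frequency sweep is required")
  label <- as.character(label)
  if (!label %in% c("dVf", "hVf"))
    stop("preferred frequency is defined only for dVf or hVf neurons")
  idx <- if (label == "dVf") which.max(deltaI) else which.min(deltaI)
  tfs[idx]
}

#' Row-normalized confusion matrix between two labelings
#'
#' @param labelsRef reference labels (rows).
#' @param labelsNew comparison labels (columns).
#' @param levels label levels; defaults to the union, in reference order.
#' @return matrix of row fractions (each row sums to 1).
#' @export
confusionMatrix <- function(labelsRef, labelsNew, levels = NULL) {
  if (length(labelsRef) != length(labelsNew))
    stop("labelings must cover the same neurons")
  if (is.null(levels))
    levels <- union(unique(as.character(labelsRef)),
                    unique(as.character(labelsNew)))
  tab <- table(
    factor(labelsRef, levels = levels),
    factor(labelsNew, levels = levels)
  )
  m <- as.matrix(tab)
  rs <- rowSums(m)
  m[rs > 0, ] <- m[rs > 0, , drop = FALSE] / rs[rs > 0]
  m
}
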