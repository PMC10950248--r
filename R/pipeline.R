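# Experiment orchestration: build -> simulate -> analyze under one master
# seed, plus direction/frequency sweeps and the onset-vs-halt comparison.

# deterministic sub-seeds from a master seed
deriveSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run a visual-flow experiment end to end
#'
#' Builds the column (unless one is supplied), simulates the protocol with
#' a discarded warm-up trial, and returns the simulation together with
#' the per-neuron response summary.
#'
#' @param config configuration list ([defaultColumnConfig()]).
#' @param protocol stimulus protocol; defaults to the 2 Hz visual-flow
#'   onset grating.
#' @param seed master seed (column and trials derive from it).
#' @param column optional pre-built [CorticalColumn-class] (skips
#'   building).
#' @param nTrials analyzed trials; defaults to `config$sim$nTrials`.
#' @param rheo optional per-type rheobase vector (computed if `NULL`).
#' @param ... passed to [simulateColumn()].
#' @return list: `column`, `sim` ([FlowSimResult-class]), `summary`
#'   (per-neuron data.frame from [responseSummary()]).
#' @export
runExperiment <- function(config = defaultColumnConfig(),
                          protocol = gratingProtocol(), seed = 1,
                          column = NULL, nTrials = NULL, rheo = NULL,
                          ...) {
  seeds <- deriveSeeds(seed, 2)
  if (is.null(column)) column <- buildColumn(config, seed = seeds[1])
  if (is.null(nTrials)) nTrials <- config$sim$nTrials
  sim <- simulateColumn(column, protocol,
    nTrials = nTrials,
    seed = seeds[2], dt = config$sim$dt,
    initAtRest = isTRUE(config$sim$initAtRest), ...
  )
  fac <- if (!is.null(config$classification$factor)) {
    config$classification$factor
  } else {
    0.05
  }
  summary <- responseSummary(sim, column, factor = fac, rheo = rheo)
  list(column = column, sim = sim, summary = summary)
}

#' Simulate a set of protocols on one column
#'
#' Runs [simulateColumn()] for each protocol in a sweep (same column,
#' distinct trial seeds derived from the master seed) and classifies each
#' run.
#'
#' @param column a [CorticalColumn-class].
#' @param protocols named list of protocols ([directionSweep()],
#'   [frequencySweep()]).
#' @param seed master seed.
#' @param nTrials analyzed trials per protocol.
#' @param factor classification threshold factor.
#' @param rheo optional per-type rheobase vector.
#' @param ... passed to [simulateColumn()].
#' @return list with `labels` (neurons x protocols factor matrix),
#'   `deltaI` (neurons x protocols numeric matrix) and `summaries`
#'   (per-protocol data.frames).
#' @export
runSweep <- function(column, protocols, seed = 1, nTrials = 20,
                     factor = 0.05, rheo = NULL, ...) {
  stopifnot(is(column, "CorticalColumn"))
  if (is.null(rheo)) {
    rheo <- vapply(glifCatalog(column), rheobase, numeric(1))
  }
  seeds <- deriveSeeds(seed, length(protocols))
  summaries <- vector("list", length(protocols))
  names(summaries) <- names(protocols)
  for (i in seq_along(protocols)) {
    sim <- simulateColumn(column, protocols[[i]],
      nTrials = nTrials,
      seed = seeds[i], ...
    )
    summaries[[i]] <- responseSummary(sim, column,
      factor = factor,
      rheo = rheo
    )
  }
  labels <- vapply(
    summaries, function(s) as.character(s$label),
    character(nNeurons(column))
  )
  deltaI <- vapply(
    summaries, function(s) s$deltaI,
    numeric(nNeurons(column))
  )
  list(labels = labels, deltaI = deltaI, summaries = summaries)
}

#' Analyze a completed visual-flow experiment
#'
#' Produces the population-level outputs for one classified run: class
#' counts by layer/class stratum, LGN in-degree comparison between dVf
#' and hVf neurons (one-sided Welch test, dVf > hVf), Ripley's K curves
#' per response class of the excitatory L2/3 population, and the
#' pre/post effective-weight table aggregated over target classes.
#'
#' @param experiment list from [runExperiment()].
#' @param stratum which neurons to sub-classify spatially; default
#'   excitatory L2/3.
#' @param radii Ripley search radii (um); default a grid up to 60%% of the
#'   column radius.
#' @return list: `classCounts`, `lgnTest` (htest), `ripley` (per-class
#'   data.frames), `effective` (aggregated effective weights), `stats`
#'   (baseline comparison between classes via [compareClasses()]).
#' @export
analyzeExperiment <- function(experiment, stratum = NULL, radii = NULL) {
  column <- experiment$column
  summ <- experiment$summary
  if (is.null(stratum)) {
    stratum <- summ$layer == "L2/3" & summ$cellClass == "Exc"
  }
  R <- column@geometry$radius
  if (is.null(radii)) radii <- seq(R / 20, 0.6 * R, length.out = 12)

  classCounts <- as.data.frame(table(
    layer = summ$layer, cellClass = summ$cellClass, label = summ$label
  ))
  classCounts <- classCounts[classCounts$Freq > 0, ]

  deg <- lgnInDegree(column)
  sub <- summ[stratum, ]
  degSub <- deg[stratum]
  lgnTest <- NULL
  if (sum(sub$label == "dVf") >= 2 && sum(sub$label == "hVf") >= 2) {
    lgnTest <- t.test(degSub[sub$label == "dVf"],
      degSub[sub$label == "hVf"],
      alternative = "greater", var.equal = FALSE
    )
  }

  nt <- neuronTable(column)
  ripley <- lapply(
    split(which(stratum), sub$label),
    function(idx) {
      if (length(idx) < 2) return(NULL)
      ripleyK(cbind(nt$x[idx], nt$y[idx]), radii, R)
    }
  )

  eff <- effectiveWeights(experiment$sim, column)
  eff$targetLabel <- summ$label[eff$post]
  effAgg <- stats::aggregate(
    weff ~ preType + epoch + targetLabel,
    data = eff[stratum[eff$post], ], FUN = mean
  )

  stats <- NULL
  if (all(table(sub$label) >= 2)) {
    stats <- compareClasses(sub$I0, sub$label)
  }

  list(
    classCounts = classCounts, lgnTest = lgnTest, ripley = ripley,
    effective = effAgg, stats = stats
  )
}

#' Onset versus halt comparison
#'
#' Classifies the same column under the flow-onset and flow-halt versions
#' of a grating protocol and reports the confusion matrix between the two
#' labelings and the fraction of perturbation responders whose response
#' sign reverses.
#'
#' @param column a [CorticalColumn-class].
#' @param seed master seed.
#' @param nTrials analyzed trials per protocol.
#' @param direction,tf grating parameters.
#' @param factor classification threshold factor.
#' @param rheo optional per-type rheobase vector.
#' @param stratum logical mask of neurons to compare; default excitatory
#'   L2/3.
#' @param ... passed to [simulateColumn()].
#' @return list: `onset`, `halt` (summaries), `confusion` (row-normalized
#'   matrix, onset classes as rows), `reversalFraction` (share of neurons
#'   classified under both protocols whose label flips dVf <-> hVf),
#'   `signReversalFraction` (share of onset-classified neurons whose halt
#'   deltaI has the opposite sign).
#' @export
runOnsetHalt <- function(column, seed = 1, nTrials = 20, direction = 0,
                         tf = 2, factor = 0.05, rheo = NULL,
                         stratum = NULL, ...) {
  protos <- list(
    onset = gratingProtocol(direction, tf, perturbation = "onset"),
    halt = gratingProtocol(direction, tf, perturbation = "halt")
  )
  sw <- runSweep(column, protos,
    seed = seed, nTrials = nTrials,
    factor = factor, rheo = rheo, ...
  )
  onset <- sw$summaries$onset
  halt <- sw$summaries$halt
  if (is.null(stratum)) {
    stratum <- onset$layer == "L2/3" & onset$cellClass == "Exc"
  }
  lo <- as.character(onset$label[stratum])
  lh <- as.character(halt$label[stratum])
  conf <- confusionMatrix(lo, lh,
    levels = c("dVf", "hVf", "unclassified")
  )
  both <- lo != "unclassified" & lh != "unclassified"
  reversal <- if (any(both)) mean(lo[both] != lh[both]) else NA_real_
  respOn <- lo != "unclassified"
  signRev <- if (any(respOn)) {
    mean(sign(halt$deltaI[stratum][respOn]) ==
           -sign(onset$deltaI[stratum][respOn]))
  } else {
    NA_real_
  }
  list(
    onset = onset, halt = halt, confusion = conf,
    reversalFraction = reversal, signReversalFraction = signRev
  )
}
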