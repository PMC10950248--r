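#' @name column-accessors
#' @title Accessors for CorticalColumn and FlowSimResult objects
#' @param object a [CorticalColumn-class] or [FlowSimResult-class] object.
#' @param which for [synapseTable()], `"recurrent"` or `"lgn"`.
NULL

#' @describeIn column-accessors neuron table (id, type, layer, class,
#'   position, tuning angle).
#' @export
setGeneric("neuronTable", function(object) standardGeneric("neuronTable"))
setMethod("neuronTable", "CorticalColumn", function(object) object@neurons)

#' @describeIn column-accessors number of neurons.
#' @export
setGeneric("nNeurons", function(object) standardGeneric("nNeurons"))
setMethod("nNeurons", "CorticalColumn", function(object) {
  nrow(object@neurons)
})

#' @describeIn column-accessors synapse table (recurrent or LGN).
#' @export
setGeneric("synapseTable", function(object, which = "recurrent") {
  standardGeneric("synapseTable")
})
setMethod("synapseTable", "CorticalColumn", function(object,
                                                     which = "recurrent") {
  which <- match.arg(which, c("recurrent", "lgn"))
  if (which == "recurrent") object@recurrent else object@lgn
})

#' @describeIn column-accessors per-neuron background weights (pA).
#' @export
setGeneric("backgroundWeights", function(object) {
  standardGeneric("backgroundWeights")
})
setMethod("backgroundWeights", "CorticalColumn", function(object) {
  object@background
})

#' @describeIn column-accessors named list of per-type [GLIFParams-class].
#' @export
setGeneric("glifCatalog", function(object) standardGeneric("glifCatalog"))
setMethod("glifCatalog", "CorticalColumn", function(object) object@glif)

#' @describeIn column-accessors LGN in-degree of every neuron (counting
#'   multiplicity), in neuron-id order.
#' @export
setGeneric("lgnInDegree", function(object) standardGeneric("lgnInDegree"))
setMethod("lgnInDegree", "CorticalColumn", function(object) {
  deg <- integer(nNeurons(object))
  if (nrow(object@lgn)) {
    tb <- table(factor(object@lgn$post, levels = object@neurons$id))
    deg <- as.integer(tb)
  }
  deg
})

setMethod("show", "CorticalColumn", function(object) {
  nn <- nNeurons(object)
  cat(sprintf(
    "CorticalColumn: %d neurons, radius %g um (seed %d)\n",
    nn, object@geometry$radius, object@seed
  ))
  tab <- table(object@neurons$layer, object@neurons$cellClass)
  print(tab)
  cat(sprintf(
    "  %d recurrent synapses, %d LGN synapses from %d units\n",
    nrow(object@recurrent), nrow(object@lgn), nrow(object@lgnUnits)
  ))
  invisible(NULL)
})

#' @describeIn column-accessors spike raster of a simulation
#'   (`trial`, `neuron`, `step`).
#' @export
setGeneric("spikeRaster", function(object) standardGeneric("spikeRaster"))
setMethod("spikeRaster", "FlowSimResult", function(object) object@spikes)

#' @describeIn column-accessors number of analyzed trials.
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))
setMethod("nTrials", "FlowSimResult", function(object) object@nTrials)

#' Per-window mean currents of a simulation
#'
#' Returns, for one recording window, the per-source mean input current of
#' every neuron, either per analyzed trial or averaged over them.
#'
#' @param object a [FlowSimResult-class].
#' @param window window label (see `object@windows$label`).
#' @param perTrial if `TRUE`, return a list of per-trial matrices
#'   (`source x neuron`); otherwise the trial average.
#' @return a `4 x nNeuron` matrix with rows `in`, `noise`, `rec`, `asc`
#'   (pA), or a list of such matrices.
#' @export
windowMeans <- function(object, window, perTrial = FALSE) {
  stopifnot(is(object, "FlowSimResult"))
  w <- match(window, object@windows$label)
  if (is.na(w)) stop("unknown window label: ", window)
  len <- object@windows$end[w] - object@windows$start[w]
  per <- lapply(object@windowSums, function(ws) {
    rbind(
      `in` = ws$`in`[w, ], noise = ws$noise[w, ],
      rec = ws$rec[w, ], asc = ws$asc[w, ]
    ) / len
  })
  if (perTrial) return(per)
  Reduce(`+`, per) / length(per)
}

setMethod("show", "FlowSimResult", function(object) {
  cat(sprintf(
    "FlowSimResult: %s, %d analyzed trials of %d steps (dt=%g ms)\n",
    object@protocol$kind, object@nTrials, object@nSteps, object@dt
  ))
  cat(sprintf(
    "  %d spikes; windows: %s\n", nrow(object@spikes),
    paste(object@windows$label, collapse = ", ")
  ))
  invisible(NULL)
})
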