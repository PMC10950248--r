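# Synthetic laminar column generator: neuron placement, distance-dependent
# stochastic recurrent wiring, like-to-like weight modulation, LGN and
# background afferents.

#' Place neurons uniformly in a laminar cylinder
#'
#' Each neuron receives an in-plane position drawn uniformly over the
#' column disk, a depth drawn uniformly within its layer interval, and an
#' independent uniform tuning angle in \[0, 360) degrees.
#'
#' @param catalog data.frame with columns `type`, `layer`, `cellClass`,
#'   `count` (one row per neuron type; L1 rows must be Htr3a).
#' @param geometry list with `radius` (um) and `layerDepths`, a named list
#'   of `c(top, bottom)` depth intervals (um) per layer.
#' @param seed integer seed; identical seeds give identical tables.
#' @return data.frame: `id`, `type`, `layer`, `cellClass`, `x`, `y`, `z`,
#'   `theta`.
#' @export
placeNeurons <- function(catalog, geometry, seed) {
  if (nrow(catalog) == 0) stop("neuron catalog is empty")
  if (is.null(geometry$radius) || geometry$radius <= 0)
    stop("geometry$radius must be positive")
  if (any(catalog$count <= 0)) stop("type counts must be positive")
  bad <- catalog$layer == "L1" & catalog$cellClass != "Htr3a"
  if (any(bad)) stop("L1 may contain only Htr3a neuron types")
  depths <- geometry$layerDepths
  if (!all(catalog$layer %in% names(depths)))
    stop("every catalog layer needs a depth interval in the geometry")

  withr_seed <- function(expr) { # local RNG scope
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    n <- sum(catalog$count)
    type <- rep(catalog$type, catalog$count)
    layer <- rep(catalog$layer, catalog$count)
    cellClass <- rep(catalog$cellClass, catalog$count)
    r <- geometry$radius * sqrt(runif(n))
    phi <- runif(n, 0, 2 * pi)
    zlo <- vapply(depths, `[`, numeric(1), 1)[layer]
    zhi <- vapply(depths, `[`, numeric(1), 2)[layer]
    data.frame(
      id = seq_len(n), type = type, layer = layer, cellClass = cellClass,
      x = r * cos(phi), y = r * sin(phi),
      z = runif(n, pmin(zlo, zhi), pmax(zlo, zhi)),
      theta = runif(n, 0, 360),
      stringsAsFactors = FALSE
    )
  })
}

#' Distance-dependent connection probability
#'
#' The pairwise connection probability is the base probability (defined at
#' the 75 um reference intersomatic distance) times a Gaussian scaling of
#' the planar distance, normalized to 1 at 75 um; the product is clamped
#' to \[0, 1\].
#'
#' @param pBase base connection probability at 75 um.
#' @param d planar intersomatic distance (um), vectorized.
#' @param sigma Gaussian width (um), positive.
#' @return probabilities in \[0, 1\].
#' @export
connectionProbability <- function(pBase, d, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(d < 0)) stop("distances must be non-negative")
  p <- pBase * exp(-(d^2 - 75^2) / (2 * sigma^2))
  pmin(pmax(p, 0), 1)
}

#' Like-to-like synaptic weight modulation
#'
#' Scales a mean synaptic weight by the similarity of the preferred motion
#' directions of the connected pair: `w = wBar * (1 + kappa * cos(dTheta))`.
#' The modulation is maximal for aligned preferences, minimal at 180
#' degrees, averages to `wBar` over uniform direction differences, and
#' preserves the sign of `wBar` for `kappa` in \[0, 1).
#'
#' @param wBar mean synaptic weight (pA).
#' @param dTheta circular difference of preferred directions, degrees in
#'   \[0, 180\], vectorized.
#' @param kappa modulation amplitude in \[0, 1).
#' @return modulated weights (pA).
#' @export
likeToLikeWeight <- function(wBar, dTheta, kappa) {
  if (any(kappa < 0 | kappa >= 1))
    stop("kappa must lie in [0, 1) to preserve the weight sign")
  if (any(dTheta < 0 | dTheta > 180))
    stop("dTheta must be a circular difference in [0, 180] degrees")
  wBar * (1 + kappa * cos(dTheta * pi / 180))
}

# circular difference of two direction preferences, in [0, 180]
circularDiff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Sample the recurrent synapse table
#'
#' Every ordered neuron pair is connected independently with the
#' distance-dependent probability of its type pair; connected pairs get a
#' like-to-like modulated weight, an integer delay drawn uniformly from
#' the configured range, and a receptor channel determined by the
#' presynaptic class (excitatory or inhibitory).
#'
#' @param neurons neuron table from [placeNeurons()].
#' @param rules list: `pBase` and `wBar` (type x type matrices, source
#'   rows), `sigma` (class x class matrix, um), `kappa`, `delayRange`
#'   (integer steps, within \[1, 4\]), and optional `likeToLikeProbE`
#'   (default `FALSE`) switching on a like-to-like bias of the E-to-E
#'   connection *probability* in addition to the weight.
#' @param seed integer seed.
#' @return data.frame: `pre`, `post`, `weight`, `delay`, `channel`.
#' @export
sampleRecurrentSynapses <- function(neurons, rules, seed) {
  types <- rownames(rules$pBase)
  stopifnot(
    !is.null(types), identical(types, rownames(rules$wBar)),
    all(neurons$type %in% types)
  )
  if (any(rules$pBase < 0 | rules$pBase > 1))
    stop("base probabilities must lie in [0, 1]")
  dr <- rules$delayRange
  if (length(dr) != 2 || dr[1] < 1 || dr[2] > 4 || dr[1] > dr[2])
    stop("delayRange must be an increasing integer pair within [1, 4]")
  classOf <- neurons$cellClass[match(types, neurons$type)]
  names(classOf) <- types
  # sign discipline of the mean-weight matrix
  for (ty in types) {
    row <- rules$wBar[ty, ]
    if (isExcClass(classOf[ty]) && any(row < 0))
      stop("excitatory source rows of wBar must be non-negative")
    if (!isExcClass(classOf[ty]) && any(row > 0))
      stop("inhibitory source rows of wBar must be non-positive")
  }
  probE <- isTRUE(rules$likeToLikeProbE)

  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  idx <- split(seq_len(nrow(neurons)), neurons$type)
  out <- vector("list", length(types)^2)
  k <- 0
  for (src in types) {
    si <- idx[[src]]
    if (is.null(si)) next
    for (trg in types) {
      ti <- idx[[trg]]
      pb <- rules$pBase[src, trg]
      if (is.null(ti) || pb == 0) next
      sg <- rules$sigma[classOf[src], classOf[trg]]
      # candidate ordered pairs (src block x trg block)
      pre <- rep(si, times = length(ti))
      post <- rep(ti, each = length(si))
      keepIdx <- pre != post
      pre <- pre[keepIdx]; post <- post[keepIdx]
      d <- sqrt((neurons$x[pre] - neurons$x[post])^2 +
                  (neurons$y[pre] - neurons$y[post])^2)
      p <- connectionProbability(pb, d, sg)
      dth <- circularDiff(neurons$theta[pre], neurons$theta[post])
      if (probE && isExcClass(classOf[src]) && isExcClass(classOf[trg])) {
        p <- pmin(p * (1 + rules$kappa * cos(dth * pi / 180)), 1)
      }
      conn <- runif(length(p)) < p
      if (!any(conn)) next
      pre <- pre[conn]; post <- post[conn]; dth <- dth[conn]
      w <- likeToLikeWeight(rules$wBar[src, trg], dth, rules$kappa)
      k <- k + 1
      out[[k]] <- data.frame(
        pre = pre, post = post, weight = w,
        delay = sample(dr[1]:dr[2], length(pre), replace = TRUE),
        channel = if (isExcClass(classOf[src])) "recE" else "recI",
        stringsAsFactors = FALSE
      )
    }
  }
  if (k == 0) {
    return(data.frame(
      pre = integer(), post = integer(), weight = numeric(),
      delay = integer(), channel = character(), stringsAsFactors = FALSE
    ))
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

#' Wire thalamocortical (LGN) afferents
#'
#' In-degrees are drawn per target type from an overdispersed negative
#' binomial law (variance above the mean, strictly positive mass at zero),
#' and each synapse is assigned a uniformly sampled LGN unit. Only
#' excitatory and Pvalb neurons outside L1 and Htr3a neurons in L1 may
#' receive LGN input; rules naming any other type are rejected.
#'
#' @param neurons neuron table.
#' @param nUnits number of LGN units.
#' @param rules named list (by neuron type) of lists with `mean` (mean
#'   in-degree), `size` (negative binomial dispersion; smaller is more
#'   overdispersed) and `weight` (pA per synapse, positive). Types absent
#'   from the list get no LGN input.
#' @param seed integer seed.
#' @param delayRange integer delay range in steps.
#' @return data.frame: `unit`, `post`, `weight`, `delay`.
#' @export
wireLGN <- function(neurons, nUnits, rules, seed, delayRange = c(1, 4)) {
  allowed <- function(layer, cellClass) {
    (cellClass %in% c("Exc", "Pvalb") & layer != "L1") |
      (cellClass == "Htr3a" & layer == "L1")
  }
  typeInfo <- unique(neurons[, c("type", "layer", "cellClass")])
  for (ty in names(rules)) {
    row <- typeInfo[typeInfo$type == ty, ]
    if (nrow(row) == 0) next
    if (!allowed(row$layer, row$cellClass))
      stop(
        "LGN input rule targets forbidden type '", ty,
        "': only Exc/Pvalb outside L1 and Htr3a in L1 may receive LGN input"
      )
    if (rules[[ty]]$weight < 0) stop("LGN weights must be non-negative")
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  out <- list()
  for (ty in names(rules)) {
    rows <- which(neurons$type == ty)
    if (!length(rows)) next
    rl <- rules[[ty]]
    deg <- rnbinom(length(rows), mu = rl$mean, size = rl$size)
    tot <- sum(deg)
    if (tot == 0) next
    out[[ty]] <- data.frame(
      unit = sample.int(nUnits, tot, replace = TRUE),
      post = rep(neurons$id[rows], deg),
      weight = rl$weight,
      delay = sample(delayRange[1]:delayRange[2], tot, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(
      unit = integer(), post = integer(), weight = numeric(),
      delay = integer(), stringsAsFactors = FALSE
    ))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Background-source weights per neuron
#'
#' Every neuron receives exactly one (excitatory, hence non-negative)
#' weight for the shared 1 kHz Poisson background source, looked up from
#' its type.
#'
#' @param neurons neuron table.
#' @param weights named numeric vector of weights (pA) per neuron type.
#' @return numeric vector, one weight per neuron (neuron-id order).
#' @export
wireBackground <- function(neurons, weights) {
  if (any(weights < 0)) stop("background weights must be non-negative")
  miss <- setdiff(unique(neurons$type), names(weights))
  if (length(miss))
    stop("missing background weights for types: ", paste(miss, collapse = ", "))
  unname(weights[neurons$type])
}

#' Build a synthetic cortical column
#'
#' Runs the full generator — placement, recurrent sampling, LGN wiring,
#' background weights and the LGN front-end unit mosaic — from a
#' configuration list (see [defaultColumnConfig()]) under a single seed.
#'
#' @param config configuration list; [defaultColumnConfig()] documents the
#'   required sections.
#' @param seed integer seed; defaults to `config$seed`.
#' @return a [CorticalColumn-class] object.
#' @examples
#' cfg <- defaultColumnConfig(scale = 0.05)
#' col <- buildColumn(cfg, seed = 1)
#' col
#' @export
buildColumn <- function(config, seed = config$seed) {
  required <- c("geometry", "types", "connectivity", "lgn", "background")
  miss <- setdiff(required, names(config))
  if (length(miss))
    stop("config is missing section(s): ", paste(miss, collapse = ", "))
  seed <- as.integer(seed)

  catalog <- do.call(rbind, lapply(names(config$types), function(ty) {
    tc <- config$types[[ty]]
    data.frame(
      type = ty, layer = tc$layer, cellClass = tc$cellClass,
      count = tc$count, stringsAsFactors = FALSE
    )
  }))
  neurons <- placeNeurons(catalog, config$geometry, seed)
  recurrent <- sampleRecurrentSynapses(
    neurons, config$connectivity,
    seed + 1L
  )
  lgnRules <- lapply(
    Filter(function(tc) !is.null(tc$lgn), config$types),
    function(tc) tc$lgn
  )
  lgn <- wireLGN(neurons, config$lgn$nUnits, lgnRules, seed + 2L,
    delayRange = config$connectivity$delayRange
  )
  bkgW <- vapply(config$types, function(tc) tc$bkgWeight, numeric(1))
  background <- wireBackground(neurons, bkgW)
  units <- makeLGNUnits(config$lgn, seed + 3L)

  glif <- lapply(config$types, function(tc) do.call(GLIFParams, tc$glif))
  new("CorticalColumn",
    neurons = neurons, recurrent = recurrent, lgn = lgn,
    background = background, lgnUnits = units, glif = glif,
    geometry = config$geometry, config = config, seed = seed
  )
}
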