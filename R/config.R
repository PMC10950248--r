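# Default configuration of the synthetic laminar column. The numeric
# wiring values (base probabilities, Gaussian widths, mean weights) are
# illustrative defaults chosen to preserve the qualitative structure of
# laminar V1 microcircuits — strong within-layer E-Pvalb reciprocity,
# L4->L2/3 feedforward excitation, dominant within-layer Pvalb
# inhibition, sparse overdispersed LGN input to L2/3 with dense input to
# L4 — not the released values of any published full-scale model.

# helper: empty type x type matrix
typeMatrix <- function(types) {
  matrix(0,
    length(types), length(types),
    dimnames = list(types, types)
  )
}

#' Default configuration of the synthetic column
#'
#' Returns the full configuration list consumed by [buildColumn()]: a
#' ~5,000-neuron laminar cylinder (radius 150 um) with one excitatory and
#' three inhibitory classes per layer (only Htr3a in L1), class-level GLIF
#' parameters, distance-dependent connection probability and mean-weight
#' matrices, like-to-like modulation, negative-binomial LGN in-degree laws
#' (sparse and overdispersed onto L2/3 excitatory cells, dense onto L4),
#' and the shared 1 kHz background source.
#'
#' @param scale multiplies all neuron counts (and leaves wiring rules
#'   unchanged); use small values for quick experiments.
#' @return a configuration list with sections `geometry`, `types`,
#'   `connectivity`, `lgn`, `background`, `sim`, `classification`, `seed`.
#' @export
defaultColumnConfig <- function(scale = 1) {
  geometry <- list(
    radius = 150,
    layerDepths = list(
      "L1" = c(0, 100), "L2/3" = c(100, 310), "L4" = c(310, 430),
      "L5" = c(430, 650), "L6" = c(650, 850)
    )
  )

  glifByClass <- list(
    Exc = list(
      C = 100, g = 5, EL = -70, vth = -45, vr = -70, deltaR = 3,
      k1 = 0.1, k2 = 0.01, A1 = -10, A2 = -5
    ),
    Pvalb = list(
      C = 60, g = 6, EL = -72, vth = -50, vr = -72, deltaR = 2,
      k1 = 0.2, k2 = 0.02, A1 = -5, A2 = -2
    ),
    Sst = list(
      C = 80, g = 4, EL = -70, vth = -50, vr = -70, deltaR = 2,
      k1 = 0.1, k2 = 0.01, A1 = -8, A2 = -4
    ),
    Htr3a = list(
      C = 70, g = 4, EL = -70, vth = -48, vr = -70, deltaR = 2,
      k1 = 0.1, k2 = 0.01, A1 = -8, A2 = -4
    )
  )

  counts <- list(
    "L1" = c(Htr3a = 90),
    "L2/3" = c(Exc = 1200, Pvalb = 80, Sst = 60, Htr3a = 90),
    "L4" = c(Exc = 1100, Pvalb = 120, Sst = 60, Htr3a = 50),
    "L5" = c(Exc = 750, Pvalb = 85, Sst = 85, Htr3a = 35),
    "L6" = c(Exc = 900, Pvalb = 70, Sst = 60, Htr3a = 35)
  )
  bkgWeight <- c(Exc = 6.4, Pvalb = 11.5, Sst = 8.5, Htr3a = 9.5)
  # LGN in-degree laws: negative binomial (mu, size) and synapse weight;
  # only permitted targets appear (Exc/Pvalb outside L1, Htr3a in L1).
  lgnLaw <- list(
    "L1-Htr3a" = list(mean = 3, size = 1.5, weight = 8),
    "L2/3-Exc" = list(mean = 3.5, size = 0.6, weight = 20),
    "L2/3-Pvalb" = list(mean = 6, size = 2, weight = 10),
    "L4-Exc" = list(mean = 15, size = 4, weight = 14),
    "L4-Pvalb" = list(mean = 12, size = 4, weight = 18),
    "L5-Exc" = list(mean = 9, size = 2, weight = 24),
    "L5-Pvalb" = list(mean = 3, size = 2, weight = 10),
    "L6-Exc" = list(mean = 9, size = 2, weight = 22),
    "L6-Pvalb" = list(mean = 2, size = 2, weight = 8)
  )

  types <- list()
  for (layer in names(counts)) {
    for (cl in names(counts[[layer]])) {
      ty <- paste0(layer, "-", cl)
      types[[ty]] <- list(
        layer = layer, cellClass = cl,
        count = max(1L, as.integer(ceiling(counts[[layer]][[cl]] * scale))),
        glif = glifByClass[[cl]],
        bkgWeight = bkgWeight[[cl]],
        lgn = lgnLaw[[ty]]
      )
    }
  }
  typeNames <- names(types)
  layerOf <- vapply(types, function(t) t$layer, character(1))
  classOf <- vapply(types, function(t) t$cellClass, character(1))

  # ---- connection probabilities at 75 um --------------------------------
  pBase <- typeMatrix(typeNames)
  wBar <- typeMatrix(typeNames)
  # within-layer class-pair rules: p at 75 um and mean weight (pA)
  within <- list(
    c("Exc", "Exc", 0.10, 2.0),
    c("Exc", "Pvalb", 0.35, 4.0),
    c("Exc", "Sst", 0.20, 1.5),
    c("Exc", "Htr3a", 0.10, 2.0),
    c("Pvalb", "Exc", 0.45, -18),
    c("Pvalb", "Pvalb", 0.35, -14),
    c("Pvalb", "Htr3a", 0.10, -6),
    c("Sst", "Exc", 0.25, -8),
    c("Sst", "Pvalb", 0.15, -8),
    c("Sst", "Htr3a", 0.10, -6),
    c("Htr3a", "Exc", 0.10, -6),
    c("Htr3a", "Sst", 0.25, -9),
    c("Htr3a", "Htr3a", 0.15, -6)
  )
  for (r in within) {
    src <- typeNames[classOf == r[1]]
    trg <- typeNames[classOf == r[2]]
    for (s in src) {
      for (t in trg) {
        if (layerOf[s] == layerOf[t]) {
          pBase[s, t] <- as.numeric(r[3])
          wBar[s, t] <- as.numeric(r[4])
        }
      }
    }
  }
  # layer-specific departures: within-layer Pvalb->Exc inhibition is
  # strongest in L4 and progressively weaker in L2/3 and the deep layers
  wBar["L2/3-Pvalb", "L2/3-Exc"] <- -13
  wBar["L5-Pvalb", "L5-Exc"] <- -11
  wBar["L6-Pvalb", "L6-Exc"] <- -10
  # cross-layer rules (src type, trg type, p, w)
  cross <- list(
    c("L4-Exc", "L2/3-Exc", 0.15, 3.0),
    c("L4-Exc", "L2/3-Pvalb", 0.20, 4.0),
    c("L4-Exc", "L2/3-Sst", 0.06, 1.5),
    c("L4-Pvalb", "L2/3-Exc", 0.12, -9),
    c("L2/3-Exc", "L4-Exc", 0.04, 1.5),
    c("L2/3-Exc", "L5-Exc", 0.10, 2.0),
    c("L2/3-Exc", "L5-Pvalb", 0.08, 3.0),
    c("L4-Exc", "L5-Exc", 0.08, 2.0),
    c("L5-Exc", "L2/3-Exc", 0.03, 1.5),
    c("L5-Exc", "L6-Exc", 0.06, 2.0),
    c("L5-Exc", "L4-Exc", 0.02, 1.5),
    c("L6-Exc", "L5-Exc", 0.04, 1.5),
    c("L6-Exc", "L4-Exc", 0.03, 1.5),
    c("L5-Pvalb", "L2/3-Exc", 0.04, -6),
    c("L1-Htr3a", "L2/3-Exc", 0.08, -5),
    c("L1-Htr3a", "L2/3-Sst", 0.08, -5),
    c("L1-Htr3a", "L5-Exc", 0.05, -4)
  )
  for (r in cross) {
    pBase[r[1], r[2]] <- as.numeric(r[3])
    wBar[r[1], r[2]] <- as.numeric(r[4])
  }

  classes <- c("Exc", "Pvalb", "Sst", "Htr3a")
  sigma <- matrix(100, 4, 4, dimnames = list(classes, classes))
  sigma["Exc", "Exc"] <- 160
  sigma["Exc", c("Pvalb", "Sst", "Htr3a")] <- 110
  sigma[c("Pvalb", "Sst", "Htr3a"), "Exc"] <- 100
  sigma[c("Pvalb", "Sst", "Htr3a"), c("Pvalb", "Sst", "Htr3a")] <- 85

  list(
    geometry = geometry,
    types = types,
    connectivity = list(
      pBase = pBase, wBar = wBar, sigma = sigma, kappa = 0.35,
      delayRange = c(1L, 4L),
      tauSyn = c(EE = 5.5, IE = 8.5, EI = 2.8, II = 5.8),
      likeToLikeProbE = FALSE
    ),
    lgn = list(
      nUnits = 400, fieldRadius = 60, r0 = 8, r1 = 55,
      kernel = list(tau1 = 20, tau2 = 60), temporalFilter = "biphasic"
    ),
    background = list(rate = 1000),
    sim = list(dt = 1, nTrials = 20, initAtRest = FALSE),
    classification = list(factor = 0.05),
    seed = 42L
  )
}
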