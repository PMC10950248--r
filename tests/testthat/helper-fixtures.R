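# Minimal hand-built columns for controlled simulator experiments.

emptyRecTable <- function() {
  data.frame(
    pre = integer(), post = integer(), weight = numeric(),
    delay = integer(), channel = character(), stringsAsFactors = FALSE
  )
}
emptyLgnTable <- function() {
  data.frame(
    unit = integer(), post = integer(), weight = numeric(),
    delay = integer(), stringsAsFactors = FALSE
  )
}

# n neurons at the column centre, optional synapse tables, inert LGN
# front-end unless configured otherwise
makeTinyColumn <- function(n = 1,
                           glif = list(Exc = GLIFParams(
                             C = 100, g = 10, EL = -70, vth = 0, vr = -70,
                             deltaR = 2, A1 = 0, A2 = 0
                           )),
                           types = rep("Exc", n),
                           classes = rep("Exc", n),
                           rec = emptyRecTable(),
                           lgn = emptyLgnTable(),
                           nUnits = 1,
                           bkg = rep(0, n),
                           lgnConfig = list(
                             nUnits = nUnits, fieldRadius = 1, r0 = 0,
                             r1 = 0, temporalFilter = "none"
                           ),
                           backgroundRate = 0) {
  neurons <- data.frame(
    id = seq_len(n), type = types, layer = "L2/3", cellClass = classes,
    x = 0, y = 0, z = 200, theta = 0, stringsAsFactors = FALSE
  )
  units <- data.frame(
    unit = seq_len(nUnits), xdeg = 0, ydeg = 0, polarity = 1, phase = 0,
    r0 = lgnConfig$r0, r1 = lgnConfig$r1
  )
  cfg <- list(
    lgn = lgnConfig,
    background = list(rate = backgroundRate),
    connectivity = list(tauSyn = c(EE = 5.5, IE = 8.5, EI = 2.8, II = 5.8))
  )
  new("CorticalColumn",
    neurons = neurons, recurrent = rec, lgn = lgn, background = bkg,
    lgnUnits = units, glif = glif,
    geometry = list(
      radius = 100,
      layerDepths = list("L2/3" = c(100, 310))
    ),
    config = cfg, seed = 1L
  )
}

# inert protocol: constant-zero drive, 500/1000/1000 epoch structure
inertProtocol <- function() gratingProtocol(contrast = 0)

# brute-force Ripley's K with border correction (independent oracle)
bruteRipley <- function(xy, radii, R) {
  n <- nrow(xy)
  A <- pi * R^2
  vapply(radii, function(t) {
    tot <- 0
    for (i in seq_len(n)) {
      cnt <- 0
      for (j in seq_len(n)) {
        if (i != j) {
          d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
          if (d <= t) cnt <- cnt + 1
        }
      }
      if (cnt > 0) {
        ri <- sqrt(sum(xy[i, ]^2))
        frac <- discFraction(ri, t, R)
        tot <- tot + cnt / frac
      }
    }
    A * tot / n^2
  }, numeric(1))
}

# fraction of a circle of radius t centred at distance r from the origin
# that lies inside the disk of radius R: standard two-circle lens area,
# written independently in R
discFraction <- function(r, t, R) {
  if (r + t <= R) return(1)
  d1 <- (r^2 + t^2 - R^2) / (2 * r * t)
  d2 <- (r^2 + R^2 - t^2) / (2 * r * R)
  s <- (-r + t + R) * (r + t - R) * (r - t + R) * (r + t + R)
  lens <- t^2 * acos(max(-1, min(1, d1))) +
    R^2 * acos(max(-1, min(1, d2))) - 0.5 * sqrt(max(0, s))
  lens / (pi * t^2)
}

# deterministic grid quadrature of the same in-domain fraction
quadFraction <- function(r, t, R, m = 400) {
  rho <- (seq_len(m) - 0.5) / m * t
  phi <- (seq_len(m) - 0.5) / m * 2 * pi
  g <- expand.grid(rho = rho, phi = phi)
  inside <- g$rho^2 + 2 * g$rho * r * cos(g$phi) + r^2 <= R^2
  # area element rho drho dphi
  sum(g$rho * inside) / sum(g$rho)
}

# finite-pulse-corrected analytic rheobase bound for ASC-free parameters
analyticRheobase <- function(g, vth, EL, Cap, pulse = 1000, dt = 1) {
  alpha <- exp(-dt / (Cap / g))
  g * (vth - EL) / (1 - alpha^(pulse / dt))
}
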