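# Visual stimulus protocols and the simplified LGN front-end that turns
# them into unit firing rates and Poisson spike trains.

#' Drifting-grating stimulus protocol
#'
#' Full-field sinusoidal grating with the standard perturbation epoch
#' structure: 500 ms static, 1000 ms drifting, 1000 ms static for a sudden
#' visual-flow *onset*; the epoch drift flags are reversed for a sudden
#' *halt* (drift, static, drift). Direction 0 means vertical gratings
#' moving rightward; 90 means horizontal gratings moving downward.
#'
#' @param direction drift direction, degrees in \[0, 360).
#' @param tf temporal frequency (Hz), non-negative.
#' @param sf spatial frequency (cycles/degree).
#' @param contrast contrast level in \[0, 1\].
#' @param perturbation `"onset"` (static then drifting) or `"halt"`
#'   (drifting then static).
#' @param epochDurations durations (ms) of the three epochs.
#' @return a protocol list with fields `kind`, `direction`, `tf`, `sf`,
#'   `contrast`, `epochs` (label, duration, drift flag), and
#'   `perturbationTime` (ms), the start of the middle epoch.
#' @examples
#' p <- gratingProtocol(direction = 0, tf = 2)
#' p$epochs
#' @export
gratingProtocol <- function(direction = 0, tf = 2, sf = 0.04,
                            contrast = 0.8,
                            perturbation = c("onset", "halt"),
                            epochDurations = c(500, 1000, 1000)) {
  perturbation <- match.arg(perturbation)
  if (direction < 0 || direction >= 360)
    stop("direction must lie in [0, 360)")
  if (tf < 0) stop("temporal frequency must be non-negative")
  if (any(epochDurations < 0)) stop("epoch durations must be non-negative")
  drift <- if (perturbation == "onset") c(FALSE, TRUE, FALSE) else
    c(TRUE, FALSE, TRUE)
  labels <- ifelse(drift, "drift", "static")
  list(
    kind = "grating", direction = direction, tf = tf, sf = sf,
    contrast = contrast, perturbation = perturbation,
    epochs = data.frame(
      label = paste0(labels, c("", "_mid", "_late")),
      duration = epochDurations, drift = drift, stringsAsFactors = FALSE
    ),
    perturbationTime = epochDurations[1]
  )
}

#' Full-field flash stimulus protocol
#'
#' Black for 500 ms, white for 1000 ms, black for 1000 ms by default.
#' Luminance is normalized so black is -1 and white is +1.
#'
#' @param epochDurations durations (ms) of the three epochs.
#' @param luminance normalized luminance levels per epoch.
#' @return a protocol list, as [gratingProtocol()].
#' @export
flashProtocol <- function(epochDurations = c(500, 1000, 1000),
                          luminance = c(-1, 1, -1)) {
  if (any(epochDurations < 0)) stop("epoch durations must be non-negative")
  list(
    kind = "flash",
    epochs = data.frame(
      label = c("pre", "flash", "post"), duration = epochDurations,
      luminance = luminance, stringsAsFactors = FALSE
    ),
    perturbationTime = epochDurations[1]
  )
}

#' Direction and temporal-frequency sweep builders
#'
#' `directionSweep()` returns the 8 grating protocols at 45-degree
#' spacing (0 to 315); `frequencySweep()` returns grating protocols over a
#' temporal-frequency grid (default 1 to 9 Hz in 1 Hz steps).
#'
#' @param tf,direction fixed parameter of the sweep.
#' @param tfs temporal-frequency grid (Hz).
#' @param ... passed to [gratingProtocol()].
#' @return named list of protocols.
#' @export
directionSweep <- function(tf = 2, ...) {
  dirs <- seq(0, 315, by = 45)
  stats::setNames(
    lapply(dirs, function(d) gratingProtocol(direction = d, tf = tf, ...)),
    paste0("dir", dirs)
  )
}

#' @rdname directionSweep
#' @export
frequencySweep <- function(tfs = 1:9, direction = 0, ...) {
  stats::setNames(
    lapply(tfs, function(f) {
      gratingProtocol(direction = direction, tf = f, ...)
    }),
    paste0("tf", tfs)
  )
}

#' Generate the LGN front-end unit mosaic
#'
#' Units are scattered uniformly over a disk of visual space; half are ON,
#' half OFF. Each unit is a spatio-temporally separable filter: a point
#' sample of the stimulus at its retinotopic position, passed through a
#' biphasic temporal kernel and rectified around the baseline rate.
#'
#' @param lgnConfig list: `nUnits`, `fieldRadius` (degrees), `r0` baseline
#'   rate (1/s), `r1` gain (1/s per unit contrast at the kernel's best
#'   frequency), `kernel` (list with `tau1`, `tau2` in ms),
#'   `temporalFilter` (`"biphasic"` or `"none"`).
#' @param seed integer seed.
#' @return data.frame: `unit`, `xdeg`, `ydeg`, `polarity` (+1 ON, -1 OFF),
#'   `phase` (degrees), `r0`, `r1`.
#' @export
makeLGNUnits <- function(lgnConfig, seed) {
  n <- lgnConfig$nUnits
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  r <- lgnConfig$fieldRadius * sqrt(runif(n))
  a <- runif(n, 0, 2 * pi)
  data.frame(
    unit = seq_len(n), xdeg = r * cos(a), ydeg = r * sin(a),
    polarity = rep(c(1, -1), length.out = n), phase = 0,
    r0 = lgnConfig$r0, r1 = lgnConfig$r1, stringsAsFactors = FALSE
  )
}

# Peak temporal-frequency gain of the difference-of-exponentials kernel
# |1/(1+i w tau1) - 1/(1+i w tau2)|, attained at w* = 1/sqrt(tau1*tau2).
biphasicPeakGain <- function(tau1, tau2) {
  w <- 1 / sqrt(tau1 * tau2)
  abs(1 / (1 + 1i * w * tau1) - 1 / (1 + 1i * w * tau2))
}

#' Instantaneous LGN firing rates for a stimulus protocol
#'
#' For gratings, each unit samples the grating luminance at its retinotopic
#' position: `sin(2 pi sf (x cos th + y sin th) + phase - 2 pi tf t)`, with
#' the temporal phase frozen during static epochs. For flashes the signal
#' is the normalized luminance level. The signal is passed through a
#' biphasic temporal filter (difference of two exponential low-passes,
#' zero DC gain, unit peak frequency gain) and rectified around the
#' baseline: `rate = max(0, r0 + polarity * r1 * contrast * y(t))`.
#' With `temporalFilter = "none"` the raw sinusoid drives the unit
#' directly (no onset transients; flash responses become sustained).
#'
#' @param protocol a protocol from [gratingProtocol()] or
#'   [flashProtocol()].
#' @param units LGN unit table from [makeLGNUnits()].
#' @param dt time step (ms); epoch durations must be multiples of `dt`.
#' @param temporalFilter `"biphasic"` (default) or `"none"`.
#' @param kernel list with `tau1`, `tau2` (ms) for the biphasic filter.
#' @return `nUnits x T` matrix of non-negative rates (1/s), `T` the total
#'   protocol duration in steps.
#' @export
lgnRates <- function(protocol, units, dt = 1,
                     temporalFilter = c("biphasic", "none"),
                     kernel = list(tau1 = 10, tau2 = 30)) {
  temporalFilter <- match.arg(temporalFilter)
  if (!protocol$kind %in% c("grating", "flash"))
    stop("unknown stimulus kind: ", protocol$kind)
  durs <- protocol$epochs$duration
  steps <- durs / dt
  if (any(abs(steps - round(steps)) > 1e-9))
    stop("epoch durations must be whole numbers of steps")
  steps <- as.integer(round(steps))
  T <- sum(steps)
  n <- nrow(units)

  # per-step stimulus signal per unit (n x T)
  if (protocol$kind == "grating") {
    th <- protocol$direction * pi / 180
    spatial <- 2 * pi * protocol$sf *
      (units$xdeg * cos(th) + units$ydeg * sin(th)) +
      units$phase * pi / 180
    # temporal phase advances only while drifting
    dphi <- 2 * pi * protocol$tf * dt / 1000
    driftStep <- rep(protocol$epochs$drift, steps)
    phase <- cumsum(c(0, ifelse(driftStep, dphi, 0)))[seq_len(T)]
    sig <- sin(outer(spatial, phase, `-`))
    amp <- protocol$contrast
  } else {
    lum <- rep(protocol$epochs$luminance, steps)
    sig <- matrix(lum, nrow = n, ncol = T, byrow = TRUE)
    amp <- 1
  }

  if (temporalFilter == "biphasic") {
    a1 <- exp(-dt / kernel$tau1)
    a2 <- exp(-dt / kernel$tau2)
    gmax <- biphasicPeakGain(kernel$tau1, kernel$tau2)
    u1 <- sig[, 1]
    u2 <- sig[, 1] # filters pre-adapted to the first epoch's signal
    y <- matrix(0, n, T)
    for (t in seq_len(T)) {
      u1 <- a1 * u1 + (1 - a1) * sig[, t]
      u2 <- a2 * u2 + (1 - a2) * sig[, t]
      y[, t] <- (u1 - u2) / gmax
    }
  } else {
    y <- sig
  }
  pmax(units$r0 + (units$polarity * units$r1 * amp) * y, 0)
}

#' Poisson spike trains from LGN rate traces
#'
#' Independent inhomogeneous Poisson counts per unit and step, with mean
#' `rate * dt`.
#'
#' @param rates `nUnits x T` rate matrix (1/s) from [lgnRates()].
#' @param dt time step (ms).
#' @param seed integer seed; identical seeds give identical trains.
#' @return integer `nUnits x T` matrix of spike counts.
#' @export
lgnSpikes <- function(rates, dt = 1, seed) {
  if (any(rates < 0)) stop("rates must be non-negative")
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  matrix(rpois(length(rates), rates * dt / 1000),
    nrow = nrow(rates), ncol = ncol(rates)
  )
}

#' Homogeneous Poisson source
#'
#' Spike-count train of a Poisson source with the given rate, one count
#' per step (mean `rate * dt`). Used for the shared 1 kHz background.
#'
#' @param rate firing rate (1/s), non-negative.
#' @param T duration (ms).
#' @param dt step (ms).
#' @param seed integer seed.
#' @return integer vector of length `T/dt`.
#' @export
poissonSource <- function(rate, T, dt = 1, seed) {
  if (rate < 0) stop("rate must be non-negative")
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rpois(as.integer(round(T / dt)), rate * dt / 1000)
}
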