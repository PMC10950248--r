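test_that("rheobase recovers the analytic bound across parameter sets", {
  # spec-default procedure on an ASC-free cell
  p <- GLIFParams(C = 100, g = 10, EL = -70, vth = -60)
  r <- rheobase(p)
  bound <- analyticRheobase(10, -60, -70, 100)
  expect_gte(r, bound)
  expect_lte(r, bound + 0.01)
  expect_true(r >= 100.00 && r <= 100.01)

  # degenerate threshold: the very first pulse fires
  expect_equal(rheobase(GLIFParams(vth = -70, EL = -70)), 1)

  # a coarser increment can only move the estimate upward
  expect_gte(rheobase(p, increment = 0.02), r - 1e-12)

  # sweep of 20 parameter sets
  set.seed(42)
  for (i in 1:20) {
    g <- runif(1, 3, 12)
    Cap <- runif(1, 60, 220)
    EL <- runif(1, -75, -65)
    vth <- EL + runif(1, 8, 30)
    pi_ <- GLIFParams(C = Cap, g = g, EL = EL, vth = vth)
    ri <- rheobase(pi_)
    bi <- analyticRheobase(g, vth, EL, Cap)
    expect_gte(ri, bi - 1e-9)
    expect_lte(ri, bi + 0.01)
  }
  expect_error(
    rheobase(GLIFParams(g = 10, EL = -70, vth = 60), ceiling = 100),
    "non-excitable"
  )
})

test_that("baseline currents use the half-open pre-onset window", {
  expect_equal(baselineCurrent(rep(10, 600), onset = 500), 10)
  tr <- matrix(c(rep(8, 600), rep(12, 600)), ncol = 2)
  expect_equal(baselineCurrent(tr, onset = 500), 10)
  # window arithmetic: onset at 500 uses steps 0..499 only
  x <- c(rep(1, 500), rep(100, 100))
  expect_equal(baselineCurrent(x, onset = 500), 1)
  expect_error(baselineCurrent(rep(1, 300), onset = 500), "outside")
})

# hand-built simulation result with known window sums
fakeSim <- function(perTrial) {
  nW <- 2L
  ws <- lapply(perTrial, function(m) {
    list(
      `in` = rbind(m$baseline["in"], m$flow["in"]),
      noise = rbind(m$baseline["noise"], m$flow["noise"]),
      rec = rbind(m$baseline["rec"], m$flow["rec"]),
      asc = rbind(m$baseline["asc"], m$flow["asc"])
    )
  })
  new("FlowSimResult",
    spikes = data.frame(trial = integer(), neuron = integer(),
                        step = integer()),
    windowSums = ws,
    windows = data.frame(
      label = c("baseline", "flow"), start = c(0L, 500L),
      end = c(500L, 1500L)
    ),
    traces = list(), protocol = gratingProtocol(), dt = 1,
    nSteps = 2500L, nTrials = length(perTrial), seed = 1L
  )
}
mkTrial <- function(base, flow) {
  list(
    baseline = c(`in` = 0, noise = base * 500, rec = 0, asc = 0),
    flow = c(`in` = 0, noise = flow * 1000, rec = 0, asc = 0)
  )
}

test_that("the flow response subtracts the baseline with exact bookkeeping", {
  # flow currents identical to baseline: zero response
  sim <- fakeSim(list(mkTrial(10, 10)))
  dc <- deltaCurrent(sim)
  expect_equal(dc$deltaI, 0)
  # 10 pA baseline then 15 pA during flow: +5 pA
  sim <- fakeSim(list(mkTrial(10, 15), mkTrial(10, 15)))
  dc <- deltaCurrent(sim)
  expect_equal(dc$deltaI, 5)
  expect_equal(dc$I0, 10)
  # decomposition identity at machine precision
  expect_lt(
    abs(dc$dIn + dc$dNoise + dc$dRec + dc$dAsc - dc$I0 - dc$deltaI),
    1e-12
  )
  expect_error(deltaCurrent(sim, I0 = c(1, 2)), "length")
})

test_that("classification uses strict rheobase-scaled thresholds", {
  expect_equal(as.character(classifyResponse(6, 100)), "dVf")
  expect_equal(as.character(classifyResponse(-5.2, 100)), "hVf")
  # boundary responses stay unclassified (strict inequalities)
  expect_equal(as.character(classifyResponse(-5, 100)), "unclassified")
  expect_equal(as.character(classifyResponse(5, 100)), "unclassified")
  expect_error(classifyResponse(NaN, 100), "non-finite")
  expect_error(classifyResponse(1, -3), "positive")

  # partition and exact dVf/hVf swap under sign flip
  set.seed(7)
  dI <- rnorm(500, 0, 8)
  lab <- classifyResponse(dI, rep(120, 500))
  expect_equal(sum(table(lab)), 500)
  flip <- classifyResponse(-dI, rep(120, 500))
  expect_equal(sum(lab == "dVf"), sum(flip == "hVf"))
  expect_equal(sum(lab == "hVf"), sum(flip == "dVf"))
  expect_equal(sum(lab == "unclassified"), sum(flip == "unclassified"))
})

test_that("firing-rate smoothing preserves spike counts", {
  z <- smoothFiringRate(numeric(0), duration = 1000)
  expect_true(all(z$rate == 0))

  one <- smoothFiringRate(500, duration = 1000)
  binW <- 1000 / 60
  expect_equal(sum(one$rate) * binW / 1000, 1, tolerance = 0.01)
  expect_equal(one$time[which.max(one$rate)], 500, tolerance = binW)

  set.seed(3)
  spikes <- cumsum(rexp(2000, rate = 20 / 1000))
  spikes <- spikes[spikes < 60000]
  sm <- smoothFiringRate(spikes, duration = 60000)
  expect_lt(abs(mean(sm$rate) - 20), 3 * sqrt(20 / 60))
  expect_error(smoothFiringRate(c(-5, 10), duration = 100), "within")
})

test_that("effective weights equal brute-force window sums", {
  expect_equal(effectiveWeightPair(2, numeric(100)), 0)
  x <- numeric(100); x[c(3, 10, 20, 50, 99)] <- 1
  expect_equal(effectiveWeightPair(2, x), 0.1)
  expect_error(effectiveWeightPair(2, numeric(0)), "at least one")

  set.seed(11)
  for (rep in 1:5) {
    W <- rnorm(1)
    x <- rbinom(200, 1, 0.2)
    brute <- sum(vapply(seq_along(x), function(t) W * x[t], numeric(1))) /
      length(x)
    expect_equal(effectiveWeightPair(W, x), brute, tolerance = 1e-12)
  }
  vals <- rnorm(7)
  expect_equal(effectiveWeightType(vals), sum(vals))
  expect_equal(effectiveWeightType(vals[1]), vals[1])
  # disjoint member partitions add
  expect_equal(
    effectiveWeightType(vals[1:3]) + effectiveWeightType(vals[4:7]),
    effectiveWeightType(vals)
  )
})

test_that("the windowed effective-weight table matches a direct loop", {
  cfg <- defaultColumnConfig(scale = 0.02)
  col <- buildColumn(cfg, seed = 13)
  sim <- simulateColumn(col, gratingProtocol(), nTrials = 2, seed = 17)
  eff <- effectiveWeights(sim, col)

  nt <- neuronTable(col)
  syn <- synapseTable(col)
  spk <- spikeRaster(sim)
  pt <- sim@windows$start[sim@windows$label == "flow"]
  for (ep in c("pre", "post")) {
    win <- if (ep == "pre") c(pt - 500, pt) else c(pt, pt + 500)
    cnt <- numeric(nrow(nt))
    sel <- spk$step >= win[1] & spk$step < win[2]
    tb <- table(spk$neuron[sel])
    cnt[as.integer(names(tb))] <- as.integer(tb) / sim@nTrials
    # brute force over a handful of (target, type) cells
    sub <- eff[eff$epoch == ep, ]
    some <- head(order(-abs(sub$weff)), 5)
    for (k in some) {
      row <- sub[k, ]
      mask <- syn$post == row$post & nt$type[syn$pre] == row$preType
      brute <- sum(syn$weight[mask] * cnt[syn$pre[mask]]) / 500
      expect_equal(row$weff, brute, tolerance = 1e-10)
    }
  }
})

test_that("Ripley's K matches brute force and the worked example", {
  # single point: no pairs
  expect_equal(ripleyK(cbind(0, 0), radii = c(1, 2), R = 5)$K, c(0, 0))

  # three collinear points, all search circles interior
  ex <- ripleyK(cbind(c(0, 1, 3), 0), radii = 1.5, R = 10)
  expect_equal(ex$K, (100 * pi / 9) * 2, tolerance = 1e-12)
  expect_equal(ex$csr, pi * 1.5^2)

  # randomized instances against the brute-force oracle
  set.seed(23)
  for (rep in 1:3) {
    n <- 150
    r <- 30 * sqrt(runif(n))
    a <- runif(n, 0, 2 * pi)
    xy <- cbind(r * cos(a), r * sin(a))
    radii <- c(2, 5, 9, 14)
    got <- ripleyK(xy, radii, R = 30)$K
    want <- bruteRipley(xy, radii, R = 30)
    expect_equal(got, want, tolerance = 1e-10)
    expect_true(all(diff(got) >= 0)) # K non-decreasing
  }
  expect_error(ripleyK(cbind(100, 0), radii = 1, R = 10), "inside")
})

test_that("the border-correction lens area agrees with quadrature", {
  for (case in list(c(25, 8, 30), c(29, 5, 30), c(15, 14, 20))) {
    expect_equal(
      discFraction(case[1], case[2], case[3]),
      quadFraction(case[1], case[2], case[3]),
      tolerance = 2e-3
    )
  }
  # the implementation applies exactly this correction: one boundary point
  xy <- cbind(c(29, 29.5), c(0, 0))
  got <- ripleyK(xy, radii = 2, R = 30)$K
  A <- pi * 30^2
  want <- A / 4 * (1 / discFraction(29, 2, 30) + 1 / discFraction(29.5, 2, 30))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("uniform points follow the CSR reference", {
  set.seed(31)
  R <- 30
  radii <- seq(2, 0.3 * R, length.out = 5)
  ks <- replicate(20, {
    n <- 2000
    r <- R * sqrt(runif(n))
    a <- runif(n, 0, 2 * pi)
    ripleyK(cbind(r * cos(a), r * sin(a)), radii, R)$K
  })
  expect_lt(max(abs(rowMeans(ks) / (pi * radii^2) - 1)), 0.05)
})

test_that("direction-sweep sub-classification follows its definitions", {
  expect_equal(
    as.character(classifyAcrossDirections(rep("dVf", 8))),
    "perturbation_dVf"
  )
  expect_equal(
    as.character(classifyAcrossDirections(rep("hVf", 8))),
    "perturbation_hVf"
  )
  one <- rep("unclassified", 8); one[3] <- "dVf"
  expect_equal(as.character(classifyAcrossDirections(one)), "direction_dVf")
  oneh <- rep("unclassified", 8); oneh[7] <- "hVf"
  expect_equal(as.character(classifyAcrossDirections(oneh)), "direction_hVf")
  expect_equal(
    as.character(classifyAcrossDirections(rep(c("dVf", "hVf"), 4))),
    "other"
  )
  expect_equal(
    as.character(classifyAcrossDirections(rep("unclassified", 8))),
    "other"
  )
  m <- rbind(rep("dVf", 8), one)
  expect_equal(
    as.character(classifyAcrossDirections(m)),
    c("perturbation_dVf", "direction_dVf")
  )
  expect_error(classifyAcrossDirections(rep("dVf", 5)), "8 directions")
})

test_that("preferred frequency is the signed extremum with low-tie break", {
  dI <- c(1, 3, 7, 9, 12, 8, 4, 2, 1)
  expect_equal(preferredFrequency(dI, "dVf"), 5)
  expect_equal(preferredFrequency(-dI, "hVf"), 5)
  expect_equal(preferredFrequency(seq(9, 1), "hVf"), 9)
  # ties break toward the lower frequency
  expect_equal(preferredFrequency(c(5, 9, 9, rep(0, 6)), "dVf"), 2)
  # sign flip swaps the dVf and hVf answers
  expect_equal(
    preferredFrequency(dI, "dVf"),
    preferredFrequency(-dI, "hVf")
  )
  expect_error(preferredFrequency(dI, "unclassified"), "only for")
  expect_error(preferredFrequency(dI[1:4], "dVf"), "complete")
})

test_that("confusion matrices are row-normalized fractions", {
  a <- c("dVf", "dVf", "hVf", "unclassified")
  cm <- confusionMatrix(a, a)
  expect_equal(unname(diag(cm)), rep(1, 3))
  set.seed(5)
  ref <- sample(c("dVf", "hVf"), 400, replace = TRUE)
  new <- sample(c("dVf", "hVf"), 400, replace = TRUE)
  cm <- confusionMatrix(ref, new)
  expect_equal(unname(rowSums(cm)), rep(1, 2), tolerance = 1e-12)
  # random relabeling: rows approach the marginal class frequencies
  expect_lt(max(abs(cm[, "dVf"] - mean(new == "dVf"))), 0.15)
  expect_error(confusionMatrix(a, a[1:2]), "same neurons")
})
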