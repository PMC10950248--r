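geom <- list(
  radius = 100,
  layerDepths = list("L2/3" = c(100, 310), "L4" = c(310, 430))
)
cat1 <- data.frame(
  type = "L2/3-Exc", layer = "L2/3", cellClass = "Exc", count = 1,
  stringsAsFactors = FALSE
)

test_that("neuron placement is uniform in the disk and deterministic", {
  one <- placeNeurons(cat1, geom, seed = 3)
  expect_equal(nrow(one), 1)
  expect_lte(one$x^2 + one$y^2, geom$radius^2)
  expect_true(one$z >= 100 && one$z <= 310)

  expect_identical(
    placeNeurons(cat1, geom, seed = 11),
    placeNeurons(cat1, geom, seed = 11)
  )

  big <- cat1
  big$count <- 10000
  nt <- placeNeurons(big, geom, seed = 5)
  # uniform-disk moments: E[x] = 0 with sd R/2 per coordinate
  se <- geom$radius / 2 / sqrt(10000)
  expect_lt(abs(mean(nt$x)), 3 * se)
  expect_lt(abs(mean(nt$y)), 3 * se)
  fracInner <- mean(nt$x^2 + nt$y^2 <= (geom$radius / 2)^2)
  expect_lt(abs(fracInner - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
  expect_true(all(nt$theta >= 0 & nt$theta < 360))

  expect_error(placeNeurons(cat1[0, ], geom, 1), "empty")
  expect_error(
    placeNeurons(cat1, list(radius = 0, layerDepths = geom$layerDepths), 1),
    "radius"
  )
  badL1 <- data.frame(
    type = "L1-Exc", layer = "L1", cellClass = "Exc", count = 1
  )
  expect_error(
    placeNeurons(badL1, list(
      radius = 10,
      layerDepths = list(L1 = c(0, 100))
    ), 1),
    "Htr3a"
  )
})

test_that("connection probability follows the normalized Gaussian", {
  expect_equal(connectionProbability(0.31, 75, 120), 0.31)
  expect_lt(connectionProbability(0.5, 6 * 80, 80), 1e-6 * 0.5)
  # algebraic ratio identity away from the clamp
  d1 <- 130; d2 <- 40; sg <- 90
  r <- connectionProbability(1e-3, d1, sg) / connectionProbability(1e-3, d2, sg)
  expect_equal(r, exp(-(d1^2 - d2^2) / (2 * sg^2)), tolerance = 1e-12)
  # clamped to [0, 1] below the reference distance
  expect_equal(connectionProbability(0.9, 0, 40), 1)
  expect_error(connectionProbability(0.5, 10, 0), "sigma")
  expect_error(connectionProbability(0.5, -1, 10), "non-negative")
})

test_that("like-to-like modulation is mean-preserving and sign-safe", {
  expect_equal(likeToLikeWeight(3, c(0, 90, 180), 0), c(3, 3, 3))
  expect_equal(likeToLikeWeight(2, 0, 0.5), 3)
  expect_equal(likeToLikeWeight(2, 180, 0.5), 1)
  # monotone non-increasing in the direction difference
  th <- seq(0, 180, by = 5)
  w <- likeToLikeWeight(2, th, 0.7)
  expect_true(all(diff(w) <= 1e-12))
  # uniform average over direction differences returns the mean weight
  grid <- seq(0, 180, length.out = 20001)
  expect_equal(mean(likeToLikeWeight(2, grid, 0.8)), 2, tolerance = 1e-3)
  # inhibitory weights stay inhibitory
  expect_true(all(likeToLikeWeight(-5, th, 0.99) < 0))
  expect_error(likeToLikeWeight(1, 90, 1), "kappa")
  expect_error(likeToLikeWeight(1, 200, 0.5), "circular")
})

twoClusterNeurons <- function(n1, n2, d) {
  data.frame(
    id = seq_len(n1 + n2),
    type = rep(c("A", "B"), c(n1, n2)),
    layer = "L2/3",
    cellClass = rep(c("Exc", "Pvalb"), c(n1, n2)),
    x = rep(c(0, d), c(n1, n2)), y = 0,
    z = 200, theta = runif(n1 + n2, 0, 360), stringsAsFactors = FALSE
  )
}

rulesAB <- function(pAB, wAB = 2, kappa = 0, delay = c(1L, 4L)) {
  types <- c("A", "B")
  pB <- matrix(0, 2, 2, dimnames = list(types, types))
  wB <- pB
  pB["A", "B"] <- pAB
  wB["A", "B"] <- wAB
  classes <- c("Exc", "Pvalb", "Sst", "Htr3a")
  sg <- matrix(120, 4, 4, dimnames = list(classes, classes))
  list(
    pBase = pB, wBar = wB, sigma = sg, kappa = kappa, delayRange = delay
  )
}

test_that("recurrent sampling matches the distance law and contracts", {
  set.seed(1)
  nn <- twoClusterNeurons(100, 100, d = 130)
  # Monte-Carlo connection frequency at fixed distance vs the formula
  p <- connectionProbability(0.25, 130, 120)
  syn <- sampleRecurrentSynapses(nn, rulesAB(0.25), seed = 9)
  phat <- nrow(syn) / (100 * 100)
  expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / 1e4))
  expect_true(all(syn$delay %in% 1:4))
  expect_true(all(syn$channel == "recE"))
  expect_true(all(nn$type[syn$pre] == "A" & nn$type[syn$post] == "B"))

  # empty when all probabilities vanish
  expect_equal(nrow(sampleRecurrentSynapses(nn, rulesAB(0), seed = 2)), 0)

  # complete digraph without self-loops when p = 1 and sigma is huge
  small <- twoClusterNeurons(8, 0, d = 0)
  ru <- rulesAB(1)
  ru$pBase["A", "A"] <- 1
  ru$wBar["A", "A"] <- 1
  ru$sigma[, ] <- 1e9
  synAA <- sampleRecurrentSynapses(small, ru, seed = 4)
  expect_equal(nrow(synAA), 8 * 7)
  expect_true(all(synAA$pre != synAA$post))

  # determinism
  expect_identical(
    sampleRecurrentSynapses(nn, rulesAB(0.2), seed = 31),
    sampleRecurrentSynapses(nn, rulesAB(0.2), seed = 31)
  )

  # sign discipline is rejected at the rule level
  bad <- rulesAB(0.2, wAB = -1) # excitatory source with negative weight
  expect_error(sampleRecurrentSynapses(nn, bad, seed = 1), "excitatory")
})

test_that("like-to-like weights appear on sampled synapses", {
  nn <- twoClusterNeurons(200, 200, d = 80)
  syn <- sampleRecurrentSynapses(nn, rulesAB(0.5, wAB = 2, kappa = 0.4),
    seed = 12
  )
  dth <- abs(nn$theta[syn$pre] - nn$theta[syn$post]) %% 360
  dth <- pmin(dth, 360 - dth)
  expect_equal(syn$weight, 2 * (1 + 0.4 * cos(dth * pi / 180)),
    tolerance = 1e-12
  )
})

lgnNeurons <- function() {
  data.frame(
    id = 1:4,
    type = c("L2/3-Exc", "L2/3-Sst", "L1-Htr3a", "L4-Htr3a"),
    layer = c("L2/3", "L2/3", "L1", "L4"),
    cellClass = c("Exc", "Sst", "Htr3a", "Htr3a"),
    x = 0, y = 0, z = 1, theta = 0, stringsAsFactors = FALSE
  )
}

test_that("LGN wiring respects the targeting rules", {
  nn <- lgnNeurons()
  # Sst may never receive LGN input
  expect_error(
    wireLGN(nn, 10, list("L2/3-Sst" = list(mean = 1, size = 1, weight = 1)),
      seed = 1
    ),
    "forbidden"
  )
  # Htr3a outside L1 may never receive LGN input
  expect_error(
    wireLGN(nn, 10, list("L4-Htr3a" = list(mean = 1, size = 1, weight = 1)),
      seed = 1
    ),
    "forbidden"
  )
  # L1 Htr3a and L2/3 Exc are permitted
  tab <- wireLGN(nn, 10, list(
    "L2/3-Exc" = list(mean = 5, size = 2, weight = 1),
    "L1-Htr3a" = list(mean = 5, size = 2, weight = 1)
  ), seed = 2)
  expect_true(all(tab$post %in% c(1L, 3L)))
  # degenerate law: zero mean gives an empty table
  expect_equal(
    nrow(wireLGN(nn, 10,
      list("L2/3-Exc" = list(mean = 0, size = 1, weight = 1)),
      seed = 3
    )), 0
  )
})

test_that("LGN in-degrees are overdispersed with mass at zero", {
  nn <- data.frame(
    id = 1:1000, type = "L2/3-Exc", layer = "L2/3", cellClass = "Exc",
    x = 0, y = 0, z = 1, theta = 0, stringsAsFactors = FALSE
  )
  tab <- wireLGN(nn, 50,
    list("L2/3-Exc" = list(mean = 3.5, size = 0.6, weight = 1)),
    seed = 8
  )
  deg <- tabulate(tab$post, nbins = 1000)
  expect_gt(var(deg), mean(deg)) # overdispersion
  expect_gt(mean(deg == 0), 0.1) # positive mass at zero
})

test_that("background wiring is a per-type lookup of non-negative weights", {
  nn <- lgnNeurons()
  w <- c("L2/3-Exc" = 2, "L2/3-Sst" = 3, "L1-Htr3a" = 0, "L4-Htr3a" = 1)
  expect_equal(wireBackground(nn, w), c(2, 3, 0, 1))
  expect_equal(wireBackground(nn, w * 0), rep(0, 4))
  expect_length(wireBackground(nn, w), nrow(nn))
  expect_error(wireBackground(nn, -w), "non-negative")
  expect_error(wireBackground(nn, w[1:2]), "missing")
})

test_that("full column builds are valid and bitwise reproducible", {
  cfg <- defaultColumnConfig(scale = 0.04)
  colA <- buildColumn(cfg, seed = 21)
  colB <- buildColumn(cfg, seed = 21)
  expect_true(validObject(colA))
  expect_identical(colA@neurons, colB@neurons)
  expect_identical(colA@recurrent, colB@recurrent)
  expect_identical(colA@lgn, colB@lgn)
  expect_identical(colA@background, colB@background)

  nt <- neuronTable(colA)
  # containment: inside the cylinder, depths within the layer intervals
  expect_true(all(nt$x^2 + nt$y^2 <= cfg$geometry$radius^2))
  for (L in names(cfg$geometry$layerDepths)) {
    zz <- nt$z[nt$layer == L]
    iv <- cfg$geometry$layerDepths[[L]]
    expect_true(all(zz >= iv[1] & zz <= iv[2]))
  }
  # sign discipline on every sampled synapse
  syn <- synapseTable(colA)
  exc <- nt$cellClass[syn$pre] == "Exc"
  expect_true(all(syn$weight[exc] >= 0))
  expect_true(all(syn$weight[!exc] <= 0))
  # LGN exclusion: nothing onto Sst, nothing onto Htr3a outside L1
  lg <- synapseTable(colA, "lgn")
  tcls <- nt$cellClass[lg$post]
  tlay <- nt$layer[lg$post]
  expect_true(all(tcls != "Sst"))
  expect_true(all(tcls != "Htr3a" | tlay == "L1"))
  # missing config section is reported by name
  expect_error(buildColumn(cfg[setdiff(names(cfg), "geometry")], 1),
    "geometry")
})
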