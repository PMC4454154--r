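test_that("the scale factor restores nearest-only coordination", {
  p <- interactionParams()
  expect_equal(p@scale * (6 + 12 / sqrt(2)), 6)
  expect_equal(p@scale, 1 / (1 + sqrt(2)))
  # substrate couplings default to the bulk-like convention
  expect_equal(p@epsLS, p@epsLL)
  expect_equal(p@epsNS, p@epsLN)
  expect_error(interactionParams(kT = 0), "kT")
})

test_that("total energy reproduces hand-evaluated configurations", {
  p <- interactionParams()

  # empty film: vapor couples to nothing, substrate-substrate excluded
  expect_equal(totalEnergy(stateFromGrid(emptyGrid(6, 4)), p, mu = -3.5), 0)
  expect_equal(
    totalEnergy(stateFromGrid(emptyGrid(6, 4)),
                interactionParams(epsLS = 50, epsNS = 50), mu = -3.5),
    0
  )

  # one isolated liquid cell in mid-film vacuum: only the -mu term
  g <- emptyGrid(8, 6)
  g[4, 4, 4] <- 1L
  expect_equal(totalEnergy(stateFromGrid(g), p, mu = -3), 3)

  # two nearest-adjacent liquid cells at mu = 0: one scaled bond
  g2 <- emptyGrid(8, 6)
  g2[4, 4, 4] <- 1L
  g2[5, 4, 4] <- 1L
  expect_equal(totalEnergy(stateFromGrid(g2), p, mu = 0), -(sqrt(2) - 1))
  expect_equal(totalEnergy(stateFromGrid(g2), p, mu = 0), -0.41421,
               tolerance = 1e-4)

  # pair across the periodic seam counts exactly once
  g3 <- emptyGrid(8, 6)
  g3[1, 4, 4] <- 1L
  g3[8, 4, 4] <- 1L
  expect_equal(totalEnergy(stateFromGrid(g3), p, mu = 0), -(sqrt(2) - 1))
})

test_that("flip energies match the closed forms at the defaults", {
  p <- interactionParams()
  allLiquid <- buildInitialState(8, 0.75, 0) # H = 6

  # bulk-interior liquid cell, all 18 in-grid neighbors liquid
  for (mu in c(-3.7, -3.6, -3, 0)) {
    expect_equal(deltaFlip(allLiquid, c(4, 4, 4), p, mu), 6 + mu)
  }
  # the coexistence point of the symmetric lattice gas: dE = 0 at mu = -6
  expect_equal(deltaFlip(allLiquid, c(4, 4, 4), p, -6), 0)

  # isolated liquid cell: no bonds broken, dE = mu
  g <- emptyGrid(8, 6)
  g[4, 4, 4] <- 1L
  iso <- stateFromGrid(g)
  expect_equal(deltaFlip(iso, c(4, 4, 4), p, -3.7), -3.7)

  # condensing vapor into a liquid-surrounded hole negates evaporation
  g2 <- latticeGrid(allLiquid)
  g2[4, 4, 4] <- 2L
  hole <- stateFromGrid(g2)
  expect_equal(deltaFlip(hole, c(4, 4, 4), p, -3), -3)

  expect_error(deltaFlip(allLiquid, c(4, 4, 1), p, -3), "liquid or vapor")
})

test_that("swap energies follow the stencil bookkeeping", {
  # lone particle fully surrounded by liquid: symmetric environment
  s <- buildInitialState(8, 0.75, 0)
  g <- latticeGrid(s)
  g[4, 4, 4] <- 3L
  lone <- stateFromGrid(g)
  p <- interactionParams()
  expect_equal(deltaSwap(lone, c(4, 4, 4), c(5, 4, 4), p), 0)

  # particle leaving a particle neighbor for bulk liquid: breaking the
  # nearest particle-particle contact and re-wetting the vacated cage
  # costs dE = c * (epsNN + epsLL - 2*epsLN) -- which vanishes at the
  # default epsLN = (epsNN + epsLL) / 2, so use an off-default coupling
  g2 <- latticeGrid(s)
  g2[3, 4, 4] <- 3L
  g2[4, 4, 4] <- 3L
  pairState <- stateFromGrid(g2)
  p2 <- interactionParams(epsNN = 2, epsLN = 1.2)
  dAway <- deltaSwap(pairState, c(4, 4, 4), c(5, 4, 4), p2)
  g2after <- g2
  g2after[4, 4, 4] <- 1L
  g2after[5, 4, 4] <- 3L
  refAway <- totalEnergy(stateFromGrid(g2after), p2, -3.5) -
    totalEnergy(pairState, p2, -3.5)
  expect_equal(dAway, refAway, tolerance = 1e-9)
  expect_equal(dAway, p2@scale * (2 + 1 - 2 * 1.2))

  # at the default couplings the same move is energy-neutral
  expect_equal(
    deltaSwap(pairState, c(4, 4, 4), c(5, 4, 4), interactionParams()), 0
  )

  # a sideways hop demotes the contact from nearest to next-nearest:
  # dE = c * (1 - 1/sqrt(2)) * (epsNN + epsLL - 2*epsLN)
  dSide <- deltaSwap(pairState, c(4, 4, 4), c(4, 5, 4), p2)
  g2side <- g2
  g2side[4, 4, 4] <- 1L
  g2side[4, 5, 4] <- 3L
  refSide <- totalEnergy(stateFromGrid(g2side), p2, -3.5) -
    totalEnergy(pairState, p2, -3.5)
  expect_equal(dSide, refSide, tolerance = 1e-9)
  expect_equal(dSide, p2@scale * (1 - 1 / sqrt(2)) * (2 + 1 - 2 * 1.2))

  expect_error(deltaSwap(lone, c(4, 4, 4), c(6, 4, 4), p), "nearest")
  expect_error(deltaSwap(lone, c(5, 4, 4), c(4, 4, 4), p), "particle")
})

test_that("swaps are reversible and independent of mu", {
  set.seed(7)
  s <- randomState(8, 4)
  g <- latticeGrid(s)
  # find a particle with a nearest liquid neighbor
  pc <- NULL
  near <- neighborTopology()$nearest
  for (i in sample(which(g == 3L))) {
    xyz <- arrayInd(i, dim(g))
    for (d in seq_len(6)) {
      q <- c(((xyz[1] - 1 + near[d, 1]) %% 8) + 1,
             ((xyz[2] - 1 + near[d, 2]) %% 8) + 1,
             xyz[3] + near[d, 3])
      if (q[3] >= 2 && q[3] <= 5 && g[q[1], q[2], q[3]] == 1L) {
        pc <- xyz
        lc <- q
        break
      }
    }
    if (!is.null(pc)) break
  }
  dE <- deltaSwap(s, pc, lc, interactionParams())
  # mu cancels: the full-Hamiltonian difference agrees under two mu values
  gAfter <- g
  gAfter[pc[1], pc[2], pc[3]] <- 1L
  gAfter[lc[1], lc[2], lc[3]] <- 3L
  after <- stateFromGrid(gAfter)
  p <- interactionParams()
  for (mu in c(-3.7, -1)) {
    expect_equal(totalEnergy(after, p, mu) - totalEnergy(s, p, mu), dE,
                 tolerance = 1e-9)
  }
  # reversibility: proposing the swap back negates the change
  expect_equal(deltaSwap(after, lc, pc, p), -dE, tolerance = 1e-12)
})

test_that("incremental energies agree with the full Hamiltonian on random moves", {
  # dual-route check: C++ stencil increments vs the vectorized R Hamiltonian
  set.seed(42)
  p <- interactionParams(epsLN = 1.3, epsNN = 1.9)
  nFlip <- 0L
  nSwap <- 0L
  near <- neighborTopology()$nearest
  while (nFlip + nSwap < 1000L) {
    s <- randomState(8, 4)
    g <- latticeGrid(s)
    mu <- runif(1, -4, -1)
    for (rep in seq_len(5)) {
      # random flip
      fluid <- which(g == 1L | g == 2L)
      i <- sample(fluid, 1)
      xyz <- arrayInd(i, dim(g))
      dE <- deltaFlip(s, xyz, p, mu)
      g2 <- g
      g2[i] <- if (g[i] == 1L) 2L else 1L
      ref <- totalEnergy(stateFromGrid(g2), p, mu) - totalEnergy(s, p, mu)
      expect_lt(abs(dE - ref), 1e-9)
      nFlip <- nFlip + 1L
      # random swap when a legal one exists at a sampled particle
      parts <- which(g == 3L)
      i <- sample(parts, 1)
      xyz <- arrayInd(i, dim(g))
      d <- near[sample.int(6, 1), ]
      q <- c(((xyz[1] - 1 + d[1]) %% 8) + 1, ((xyz[2] - 1 + d[2]) %% 8) + 1,
             xyz[3] + d[3])
      if (q[3] >= 2 && q[3] <= 5 && g[q[1], q[2], q[3]] == 1L) {
        dS <- deltaSwap(s, xyz, q, p)
        g3 <- g
        g3[xyz[1], xyz[2], xyz[3]] <- 1L
        g3[q[1], q[2], q[3]] <- 3L
        refS <- totalEnergy(stateFromGrid(g3), p, mu) - totalEnergy(s, p, mu)
        expect_lt(abs(dS - refS), 1e-9)
        nSwap <- nSwap + 1L
      }
    }
  }
  expect_gte(nFlip + nSwap, 1000L)
  expect_gt(nSwap, 100L)
})
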