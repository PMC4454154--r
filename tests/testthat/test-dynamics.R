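test_that("the Metropolis rule accepts exactly below the Boltzmann threshold", {
  # downhill and neutral moves always accepted
  expect_true(metropolisAccept(-1, 0.2, 0.9999))
  expect_true(metropolisAccept(0, 0.2, 0.9999))
  # dE = kT ln 2: acceptance probability exactly 1/2
  expect_true(metropolisAccept(0.2 * log(2), 0.2, 0.49))
  expect_false(metropolisAccept(0.2 * log(2), 0.2, 0.51))
  # threshold exactness and detailed balance across a (dE, kT) grid:
  # p(dE)/p(-dE) = exp(-dE/kT) since the smaller side is min(1, .)
  for (kT in c(0.17, 0.2, 0.25, 1)) {
    for (dE in c(0.05, 0.5, 2, 5)) {
      pAcc <- exp(-dE / kT)
      expect_true(metropolisAccept(dE, kT, pAcc * (1 - 1e-9)))
      expect_false(metropolisAccept(dE, kT, min(pAcc * (1 + 1e-9), 1 - 1e-15)))
      expect_true(metropolisAccept(-dE, kT, 1 - 1e-15))
    }
  }
  expect_error(metropolisAccept(1, 0, 0.5), "kT")
  expect_error(metropolisAccept(1, -1, 0.5), "kT")
  expect_error(metropolisAccept(1, 0.2, 1), "u")
})

test_that("fluid sweeps behave at the downhill and uphill extremes", {
  p <- interactionParams(kT = 0.2)

  # all-vapor film at mu = -4: condensation costs -mu = 4, acceptance
  # probability exp(-20) per visit; nothing condenses on a small lattice
  vap <- stateFromGrid(emptyGrid(8, 3))
  res <- sweepFluid(vap, p, mu = -4, seed = 1)
  expect_identical(res$accepted, 0L)
  expect_identical(latticeGrid(res$state), latticeGrid(vap))

  # a single liquid cell at mu = -3.7 evaporates on its visit (downhill)
  g <- emptyGrid(8, 3)
  g[4, 4, 3] <- 1L
  res2 <- sweepFluid(stateFromGrid(g), p, mu = -3.7, seed = 1)
  expect_gte(res2$accepted, 1L)
  expect_identical(sum(latticeGrid(res2$state) == 1L), 0L)
})

test_that("sweeps are reproducible from the seed and vary across seeds", {
  set.seed(3)
  s <- randomState(8, 4)
  p <- interactionParams(kT = 5) # hot: many random flips
  a <- sweepFluid(s, p, mu = -3, seed = 10)
  b <- sweepFluid(s, p, mu = -3, seed = 10)
  c <- sweepFluid(s, p, mu = -3, seed = 11)
  expect_identical(latticeGrid(a$state), latticeGrid(b$state))
  expect_false(identical(latticeGrid(a$state), latticeGrid(c$state)))
})

test_that("particle phases respect immobilization and particle conservation", {
  p <- interactionParams(kT = 0.2)

  # dried-in particle: no liquid anywhere, all attempts rejected
  g <- emptyGrid(8, 3)
  g[4, 4, 2] <- 3L
  dried <- stateFromGrid(g)
  res <- sweepParticles(dried, p, nMov = 50, seed = 1)
  expect_identical(res$accepted, 0L)
  expect_identical(latticeGrid(res$state), g)

  # particle-free film: the phase is a no-op
  s0 <- buildInitialState(8, 0.5, 0)
  res0 <- sweepParticles(s0, p, nMov = 20, seed = 1)
  expect_identical(res0$accepted, 0L)

  # particle count is conserved through busy phases
  set.seed(5)
  s <- randomState(8, 4, probs = c(0.7, 0.1, 0.2))
  res2 <- sweepParticles(s, p, nMov = 10, seed = 2)
  expect_identical(sum(latticeGrid(res2$state) == 3L),
                   sum(latticeGrid(s) == 3L))
})

test_that("a lone particle in bulk liquid performs an unbiased random walk", {
  p <- interactionParams(kT = 0.2)
  g0 <- latticeGrid(buildInitialState(9, 1, 0)) # 9x9x9 liquid block
  start <- c(5L, 5L, 5L)
  g0[start[1], start[2], start[3]] <- 3L
  s <- stateFromGrid(g0)
  disp <- matrix(0, 1000, 3)
  for (seed in seq_len(1000)) {
    res <- sweepParticles(s, p, nMov = 6, seed = seed)
    pos <- which(latticeGrid(res$state) == 3L, arr.ind = TRUE)[1, ]
    d <- as.numeric(pos) - start
    d[1:2] <- ((d[1:2] + 4) %% 9) - 4 # unwrap lateral displacement
    disp[seed, ] <- d
  }
  # every neutral attempt is accepted, so 6 unit steps per replicate:
  # component means ~ N(0, sqrt(2/1000)) -- assert within 5 sigma
  expect_gt(mean(rowSums(abs(disp))), 1) # the particle does move
  expect_true(all(abs(colMeans(disp)) < 5 * sqrt(2 / 1000)))
})

test_that("runs terminate on full evaporation and conserve invariants", {
  p <- interactionParams(kT = 0.2)
  s <- buildInitialState(16, 0.25, 0, seed = 1)
  res <- runSimulation(s, p, dynamicsConfig(
    nMov = 0, maxSteps = 10000, seed = 1,
    schedule = muSchedule("constant", -4)
  ))
  rec <- traceRecords(runTrace(res))
  expect_lt(nrow(rec), 10000) # terminated well before the budget
  expect_equal(liquidFraction(finalState(res)), 0)
  expect_equal(utils::tail(rec$liquidFraction, 1), 0)

  # with particles: conservation, substrate integrity, trace consistency
  s2 <- buildInitialState(16, 0.25, 0.02, seed = 3)
  sched <- muSchedule("sigmoidal", -3.45, 0.15, 0.01, 0.15)
  res2 <- runSimulation(s2, p, dynamicsConfig(
    nMov = 10, maxSteps = 300, seed = 3, schedule = sched
  ))
  expect_identical(particleCount(finalState(res2)), particleCount(s2))
  expect_true(all(latticeGrid(finalState(res2))[, , 1] == 0L))
  rec2 <- traceRecords(runTrace(res2))
  expect_equal(rec2$mu, muOfNu(sched, rec2$nu))
  expect_true(all(rec2$liquidFraction >= 0 & rec2$liquidFraction <= 1))
})

test_that("identical seeds replay to identical final grids and traces", {
  p <- interactionParams(kT = 0.2)
  cfg <- dynamicsConfig(
    nMov = 10, maxSteps = 150, seed = 9,
    schedule = muSchedule("constant", -3.7)
  )
  a <- runSimulation(buildInitialState(16, 0.25, 0.02, seed = 9), p, cfg)
  b <- runSimulation(buildInitialState(16, 0.25, 0.02, seed = 9), p, cfg)
  expect_identical(latticeGrid(finalState(a)), latticeGrid(finalState(b)))
  expect_identical(traceRecords(runTrace(a)), traceRecords(runTrace(b)))
})

test_that("a dried-in pattern is frozen: particle phases change nothing", {
  p <- interactionParams(kT = 0.2)
  s <- buildInitialState(12, 0.25, 0.05, seed = 2)
  res <- runSimulation(s, p, dynamicsConfig(
    nMov = 10, maxSteps = 2000, seed = 2,
    schedule = muSchedule("constant", -4.5)
  ))
  final <- finalState(res)
  if (liquidFraction(final) == 0) {
    after <- sweepParticles(final, p, nMov = 50, seed = 99)
    expect_identical(after$accepted, 0L)
    expect_identical(latticeGrid(after$state), latticeGrid(final))
  } else {
    succeed("trapped liquid remained; freezing not applicable")
  }
})

test_that("evaporation pressure dries the film monotonically on average", {
  # mu = -3.7, kT = 0.2, particle-free: ensemble-mean liquid fraction is
  # non-increasing in step index
  p <- interactionParams(kT = 0.2)
  nSteps <- 120L
  curves <- sapply(seq_len(10), function(seed) {
    s <- buildInitialState(32, 6 / 32, 0, seed = seed)
    res <- runSimulation(s, p, dynamicsConfig(
      nMov = 0, maxSteps = nSteps, seed = seed,
      schedule = muSchedule("constant", -3.7)
    ))
    lf <- traceRecords(runTrace(res))$liquidFraction
    c(lf, rep(0, nSteps - length(lf))) # terminated runs stay dry
  })
  ensemble <- rowMeans(curves)
  expect_true(all(diff(ensemble) <= 1e-12))
})

test_that("the liquid-favored side of coexistence keeps the film wet", {
  # mu = -2 is above the coexistence point -3: an all-liquid film stays
  # essentially full over 1000 steps at kT = 0.2
  p <- interactionParams(kT = 0.2)
  for (seed in 1:2) {
    s <- buildInitialState(16, 0.25, 0, seed = seed)
    res <- suppressWarnings(runSimulation(s, p, dynamicsConfig(
      nMov = 0, maxSteps = 1000, seed = seed,
      schedule = suppressWarnings(muSchedule("constant", -2))
    )))
    expect_gt(liquidFraction(finalState(res)), 0.9)
  }
})
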