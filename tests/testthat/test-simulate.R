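test_that("simulation is deterministic given the seed", {
  p <- simulationParams()
  a <- simulatePair(p, "P1", seed = 42)
  b <- simulatePair(p, "P1", seed = 42)
  expect_equal(mutations(a$catalog1), mutations(b$catalog1))
  expect_equal(mutations(a$catalog2), mutations(b$catalog2))
  expect_equal(probes(a$profile1), probes(b$profile1))
  expect_equal(a$counts, b$counts)
  expect_equal(a$truth@armStates2, b$truth@armStates2)
  # and actually random across seeds
  c <- simulatePair(p, "P1", seed = 43)
  expect_false(identical(mutations(a$catalog1), mutations(c$catalog1)))
})

test_that("rho = 1 forces the smaller catalog to be fully shared", {
  p <- simulationParams()
  for (seed in 1:5) {
    pr <- simulatePair(p, "P1", seed = seed, rho = 1, what = "mutations")
    m <- matchMutations(pr$catalog1, pr$catalog2)
    expect_equal(m@shared, min(m@n1, m@n2))
  }
})

test_that("independent pairs overlap at the chance rate n1*n2/N", {
  p <- simulationParams()
  set.seed(123)
  uni <- simulateUniverse(p)
  nrep <- 200
  obs <- exp <- numeric(nrep)
  for (i in seq_len(nrep)) {
    pr <- simulatePair(p, "P1", rho = 0, universe = uni, what = "mutations")
    m <- matchMutations(pr$catalog1, pr$catalog2)
    obs[i] <- m@shared
    exp[i] <- m@n1 * m@n2 / nrow(uni)
  }
  se <- sd(obs - exp) / sqrt(nrep)
  expect_lt(abs(mean(obs) - mean(exp)), 3 * se)
})

test_that("empirical Ti:Tv converges to the value implied by the weights", {
  u <- simulateUniverse(simulationParams(universeSize = 1e5), seed = 17)
  big <- MutationCatalog("big", u)
  expect_lt(abs(titvRatio(big) - 1.5) / 1.5, 0.05)
})

test_that("clonal shared fraction converges to rho", {
  p <- simulationParams()
  set.seed(31)
  uni <- simulateUniverse(p)
  frac <- replicate(100, {
    pr <- simulatePair(p, "P1", rho = 0.8, universe = uni, what = "mutations")
    m <- matchMutations(pr$catalog1, pr$catalog2)
    m@shared / min(m@n1, m@n2)
  })
  expect_lt(abs(mean(frac) - 0.8), 0.05)
})

test_that("arm-event frequencies match their configured probabilities", {
  p <- simulationParams()
  set.seed(57)
  states <- replicate(150, simulatePair(p, "P", rho = 0,
                                        what = "cnv")$truth@armStates1)
  gain1q <- mean(states["1q", ] == 1L)
  loss8p <- mean(states["8p", ] == -1L)
  gainBg <- mean(states["2p", ] == 1L)
  se25 <- sqrt(0.25 * 0.75 / 150)
  expect_lt(abs(gain1q - 0.25), 3.5 * se25)
  expect_lt(abs(loss8p - 0.25), 3.5 * se25)
  expect_lt(abs(gainBg - 0.02), 3.5 * sqrt(0.02 * 0.98 / 150))
})

test_that("a too-small universe is a parameter error", {
  p <- simulationParams()
  tiny <- simulateUniverse(p, seed = 1)[1:10, ]
  expect_error(simulatePair(p, "P1", seed = 1, universe = tiny),
               "universe")
})

test_that("cohorts have the declared design shape and reproduce exactly", {
  p <- simulationParams(nPatients = 6L, nClonal = 2L)
  co <- simulateCohort(p, seed = 9)
  expect_length(co$pairs, 6L)
  expect_equal(co$truth$isClonal, c(rep(FALSE, 4), rep(TRUE, 2)))
  expect_true(all(vapply(co$pairs[1:4], function(pr) !pr$truth@isClonal,
                         logical(1))))
  co2 <- simulateCohort(p, seed = 9)
  expect_equal(lapply(co$pairs, function(pr) mutations(pr$catalog1)),
               lapply(co2$pairs, function(pr) mutations(pr$catalog1)))

  empty <- simulateCohort(simulationParams(nPatients = 0L, nClonal = 0L),
                          seed = 1)
  expect_length(empty$pairs, 0L)
  expect_equal(nrow(empty$truth), 0L)
})

test_that("a written cohort can be read back from its manifest", {
  p <- simulationParams(nPatients = 2L, nClonal = 1L)
  co <- simulateCohort(p, seed = 4)
  dir <- withr::local_tempdir()
  manifestPath <- writeCohort(co, dir)
  manifest <- utils::read.delim(manifestPath, stringsAsFactors = FALSE)
  expect_equal(nrow(manifest), 2L)
  back <- readMutations(manifest$mutations1[1])
  expect_equal(mutations(back), mutations(co$pairs[[1]]$catalog1))
  prof <- readProbeProfile(manifest$probes2[2])
  expect_equal(probes(prof), probes(co$pairs[[2]]$profile2))
})
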