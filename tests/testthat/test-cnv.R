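test_that("dlrs matches closed forms and recovers i.i.d. noise", {
  expect_equal(dlrs(flatProfile(n = 50)), 0)
  # alternating +/-0.1: successive differences are -0.2, +0.2, ... so the
  # sample sd of 49 x (-0.2) and 48 x (+0.2) around their mean, over sqrt(2)
  x <- rep(c(0.1, -0.1), length.out = 98)
  d <- rep(c(-0.2, 0.2), length.out = 97)
  closedForm <- sqrt(sum((d - mean(d))^2) / 96) / sqrt(2)
  expect_equal(dlrs(x), closedForm)
  expect_equal(closedForm, 0.2 / sqrt(2), tolerance = 1e-2)

  set.seed(6)
  big <- rnorm(1e5, sd = 0.3)
  expect_lt(abs(dlrs(big) - 0.3) / 0.3, 0.02)

  expect_error(dlrs(c(0.1, 0.2)), "at least 3")
})

test_that("QC partitions profiles at the cutoff, boundary passing", {
  clean <- noisyProfile("clean", sd = 0.05, seed = 1)
  noisy <- noisyProfile("noisy", sd = 0.5, seed = 2)
  expect_message(qc <- qcFilter(list(clean, noisy)), "noisy")
  expect_equal(vapply(qc$passed, sampleId, character(1)), "clean")
  expect_equal(vapply(qc$failed, sampleId, character(1)), "noisy")
  # a score exactly at the cutoff passes ("above" excludes)
  boundary <- qcFilter(list(clean), cutoff = dlrs(clean))
  expect_length(boundary$passed, 1L)
})

test_that("aberration detection finds planted intervals and honors minProbes", {
  expect_equal(nrow(detectAberrations(flatProfile(n = 100))), 0L)

  set.seed(2)
  x <- rnorm(100, 0, 0.1)
  x[41:60] <- x[41:60] + 0.8
  prof <- CopyNumberProfile("S", data.frame(chrom = "1",
                                            pos = seq_len(100) * 10L,
                                            log2ratio = x))
  segs <- detectAberrations(prof)
  gains <- segs[segs$state == 1L, ]
  expect_equal(nrow(gains), 1L)
  overlap <- (min(gains$end, 600) - max(gains$start, 410) + 10) / (600 - 410 + 10)
  expect_gte(overlap, 0.9)

  # a 2-probe spike of +2.0 must not be called
  y <- rnorm(100, 0, 0.1)
  y[50:51] <- y[50:51] + 2.0
  spike <- CopyNumberProfile("S2", data.frame(chrom = "1",
                                              pos = seq_len(100) * 10L,
                                              log2ratio = y))
  segsY <- detectAberrations(spike, sigma = 0.1)
  expect_false(any(segsY$nProbes <= 2L))
  expect_false(any(segsY$start >= 490 & segsY$end <= 520 & segsY$state == 1L))
})

test_that("arm states reduce segments by signed coverage", {
  at <- defaultArmTable()
  none <- armStates(data.frame(sampleId = character(), chrom = character(),
                               start = integer(), end = integer(),
                               nProbes = integer(), meanLog2 = numeric(),
                               state = integer()), at, sampleId = "S")
  expect_true(all(armStatesOf(none) == 0L))

  arm1q <- at[at$arm == "1q", ]
  whole <- data.frame(sampleId = "S", chrom = "1", start = arm1q$start,
                      end = arm1q$end, nProbes = 22L, meanLog2 = 0.8,
                      state = 1L)
  expect_equal(armStatesOf(armStates(whole, at))[["1q"]], 1L)

  # exactly half coverage qualifies (>= convention)
  halfLen <- (arm1q$end - arm1q$start + 1) / 2
  half <- whole
  half$end <- arm1q$start + halfLen - 1
  expect_equal(armStatesOf(armStates(half, at))[["1q"]], 1L)

  # conflicting signs: larger covered fraction wins, ties go to normal
  loss <- data.frame(sampleId = "S", chrom = "1",
                     start = arm1q$start + halfLen, end = arm1q$end,
                     nProbes = 11L, meanLog2 = -0.7, state = -1L)
  both <- rbind(half, loss)
  expect_equal(armStatesOf(armStates(both, at))[["1q"]], 0L)
  lossBigger <- loss
  lossBigger$start <- arm1q$start + 5000
  expect_equal(armStatesOf(armStates(rbind(half, lossBigger), at))[["1q"]],
               -1L)
  # sub-threshold means do not qualify
  weak <- whole
  weak$meanLog2 <- 0.1
  expect_equal(armStatesOf(armStates(weak, at))[["1q"]], 0L)
})

test_that("marginal estimation floors and renormalizes", {
  cohort <- lapply(1:10, function(i) asv(paste0("S", i), rep(0L, 4)))
  m <- estimateMarginals(cohort, eps = 0.01)
  expect_equal(unname(m@freqs[1, ]), c(0.01, 0.98, 0.01))

  half <- lapply(1:10, function(i)
    asv(paste0("S", i), c(if (i <= 5) 1L else 0L, 0L)))
  m2 <- estimateMarginals(half, eps = 0.01)
  expect_equal(m2@freqs[1, "+1"], 0.5 * (1 - 0.01) / (0.5 + 0.5))
  expect_true(all(abs(rowSums(m2@freqs) - 1) < 1e-12))
})

test_that("LR2 is 1 without concordant aberrations and matches a grid oracle", {
  freqs <- rbind(c(0.01, 0.79, 0.2),
                 matrix(rep(c(0.02, 0.96, 0.02), 4), 4, byrow = TRUE))
  m <- marg(freqs)
  allNormal <- lr2Statistic(asv("A", rep(0L, 5)), asv("B", rep(0L, 5)), m)
  expect_equal(allNormal@lr2, 1)
  expect_equal(allNormal@cHat, 0)

  disjoint <- lr2Statistic(asv("A", c(1L, 0L, 0L, 0L, 0L)),
                           asv("B", c(0L, -1L, 0L, 0L, 0L)), m)
  expect_equal(disjoint@lr2, 1)

  # identical single gain on the pi(+1) = 0.2 arm: compare to brute force
  s1 <- asv("A", c(1L, 0L, 0L, 0L, 0L))
  s2 <- asv("B", c(1L, 0L, 0L, 0L, 0L))
  res <- lr2Statistic(s1, s2, m)
  grid <- seq(0, 1 - 1e-9, length.out = 1e4)
  lik <- vapply(grid, function(cc) {
    alpha1 <- freqs[1, 3] / (freqs[1, 1] + freqs[1, 3])
    t1 <- (1 - cc) * freqs[1, 3]^2 + cc * alpha1
    rest <- prod(((1 - cc) * freqs[2:5, 2]^2))
    t1 * rest
  }, numeric(1))
  oracleLr2 <- max(lik) / lik[1]
  expect_gt(res@lr2, 1)
  expect_equal(res@lr2, oracleLr2, tolerance = 1e-4)
  expect_equal(res@cHat, grid[which.max(lik)], tolerance = 1e-3)
})

test_that("LR2 never drops below 1 and grows with concordant aberrations", {
  freqs <- matrix(rep(c(0.05, 0.9, 0.05), 8), 8, byrow = TRUE)
  m <- marg(freqs)
  set.seed(14)
  for (i in 1:20) {
    s1 <- sample(c(-1L, 0L, 1L), 8, TRUE, prob = c(0.2, 0.6, 0.2))
    s2 <- sample(c(-1L, 0L, 1L), 8, TRUE, prob = c(0.2, 0.6, 0.2))
    expect_gte(lr2Statistic(asv("A", s1), asv("B", s2), m)@lr2, 1)
  }
  # adding one more concordant aberrant arm never decreases lr2
  base <- rep(0L, 8)
  lr2s <- vapply(0:4, function(k) {
    s <- base; if (k > 0) s[seq_len(k)] <- 1L
    lr2Statistic(asv("A", s), asv("B", s), m)@lr2
  }, numeric(1))
  expect_true(all(diff(lr2s) >= -1e-9))
})

test_that("LR2 p values are plug-in ranks against the reference null", {
  obs <- new("ClonalityResult", lr2 = 1, cHat = 0, p = NA_real_)
  ref <- rep(1, 30)
  expect_equal(lr2Pvalue(obs, ref)@p, 1)

  big <- new("ClonalityResult", lr2 = 50, cHat = 0.3, p = NA_real_)
  ref999 <- seq(1, 40, length.out = 999)
  expect_equal(lr2Pvalue(big, ref999)@p, 1 / 1000)
  expect_equal(lr2Pvalue(big, sample(ref999))@p, 1 / 1000)

  expect_error(lr2Pvalue(big, rep(1, 10)), "at least 20")
})
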