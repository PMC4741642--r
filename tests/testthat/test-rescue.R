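test_that("the superset is the key union with per-tumor counts attached", {
  c1 <- catalogFromKeys(c("1:1:C:T", "1:2:C:G", "1:3:T:A"), "S1")
  c2 <- catalogFromKeys(c("2:1:G:A", "2:2:G:C", "2:3:A:G", "2:4:C:T"), "S2",
                        tumorIndex = 2L)
  ss <- buildSuperset(list(c1, c2))
  expect_equal(nrow(ss), 7L)
  expect_equal(sum(ss$called1), 3L)
  expect_equal(sum(ss$called2), 4L)
  # without external counts, the other tumor's sites are unevaluable
  expect_true(all(!ss$evaluable2[ss$called1]))

  same <- buildSuperset(list(c1, catalogFromKeys(
    c("1:1:C:T", "1:2:C:G", "1:3:T:A"), "S1b", tumorIndex = 2L)))
  expect_equal(nrow(same), 3L)
  expect_true(all(same$called1 & same$called2))

  other <- catalogFromKeys("1:9:C:T", "X", patientId = "P2")
  expect_error(buildSuperset(list(c1, other)), "different patients")
})

test_that("superset of a simulated patient equals the brute-force key union", {
  pr <- simulatePair(simulationParams(), "P1", seed = 5, what = "mutations")
  ss <- buildSuperset(list(pr$catalog1, pr$catalog2), pr$counts)
  expected <- union(variantKey(pr$catalog1), variantKey(pr$catalog2))
  expect_setequal(variantKey(ss), expected)
  # counts table makes every site evaluable in both tumors
  expect_true(all(ss$evaluable1 & ss$evaluable2))
})

test_that("binomial rescue p values are exact error tails", {
  expect_equal(binomialRescueP(0, 400), 1.0)
  expect_equal(binomialRescueP(400, 400, e = 0.01), 0.01^400)
  oracle <- sum(stats::dbinom(10:400, 400, 0.01))
  expect_equal(binomialRescueP(10, 400, e = 0.01), oracle, tolerance = 1e-12)
  expect_warning(p0 <- binomialRescueP(0, 0), "depth of 0")
  expect_equal(p0, 1)
  # per-allele convention divides the error rate by 3
  expect_equal(binomialRescueP(10, 400, e = 0.03, perAllele = TRUE),
               binomialRescueP(10, 400, e = 0.01))
})

test_that("rescue calls planted misses and is monotone in the threshold", {
  p <- simulationParams(dropoutRate = 0.4)
  pr <- simulatePair(p, "P1", seed = 19, rho = 0.8, what = "mutations")
  expect_gt(length(pr$truth@droppedKeys), 0L)
  res <- rescueSnvs(list(pr$catalog1, pr$catalog2), pr$counts)
  rescued2 <- res$audit$key[res$audit$rescued & res$audit$tumor == 2]
  expect_gte(mean(pr$truth@droppedKeys %in% rescued2), 0.9)
  # rescued sites rejoin the catalog
  expect_equal(length(res$catalogs[[2]]),
               length(pr$catalog2) + sum(res$audit$rescued &
                                           res$audit$tumor == 2))
  # raising the threshold never un-rescues
  strict <- rescueSnvs(list(pr$catalog1, pr$catalog2), pr$counts,
                       recoveryParams(fdrThreshold = 0.02))
  loose <- rescueSnvs(list(pr$catalog1, pr$catalog2), pr$counts,
                      recoveryParams(fdrThreshold = 0.20))
  sKeys <- with(strict$audit, paste(key, tumor)[rescued])
  lKeys <- with(loose$audit, paste(key, tumor)[rescued])
  expect_true(all(sKeys %in% lKeys))
})

test_that("nothing is rescued from error-level or zero alt reads", {
  c1 <- catalogFromKeys(c("1:1:C:T", "1:2:C:G"), "S1")
  c2 <- catalogFromKeys("1:9:G:A", "S2", tumorIndex = 2L)
  counts <- data.frame(chrom = c("1", "1", "1"), pos = c(1L, 2L, 9L),
                       ref = c("C", "C", "G"), alt = c("T", "G", "A"),
                       altReads1 = c(100L, 90L, 0L), depth1 = rep(400L, 3),
                       altReads2 = c(0L, 0L, 120L), depth2 = rep(400L, 3))
  res <- rescueSnvs(list(c1, c2), counts)
  expect_false(any(res$audit$rescued))
  expect_equal(length(res$catalogs[[2]]), 1L)
})
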