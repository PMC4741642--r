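test_that("matching is exact-key intersection and symmetric", {
  keys <- c("1:100:C:T", "2:200:G:A", "3:300:T:G", "4:400:A:C", "5:500:C:G")
  c1 <- catalogFromKeys(keys, "S1")
  c2 <- catalogFromKeys(keys, "S2", tumorIndex = 2L)
  m <- matchMutations(c1, c2)
  expect_equal(c(m@n1, m@n2, m@shared), c(5L, 5L, 5L))

  d1 <- catalogFromKeys(c("1:1:C:T", "1:2:C:T", "1:3:C:T"), "S1")
  d2 <- catalogFromKeys(c("2:1:G:A", "2:2:G:A", "2:3:G:A", "2:4:G:A"), "S2",
                        tumorIndex = 2L)
  expect_equal(matchMutations(d1, d2)@shared, 0L)
  expect_equal(matchMutations(d2, d1)@shared, 0L)

  other <- catalogFromKeys(keys, "S3", patientId = "P2")
  expect_error(matchMutations(c1, other), "different patients")
  expect_silent(matchMutations(c1, other, allowPatientMismatch = TRUE))
})

test_that("matching agrees with brute-force intersection of written files", {
  pr <- simulatePair(simulationParams(), "P1", seed = 7, rho = 0.5,
                     what = "mutations")
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  writeMutations(pr$catalog1, f1)
  writeMutations(pr$catalog2, f2)
  keyOf <- function(path) {   # independent parse of the emitted VCF text
    lines <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
    parts <- do.call(rbind, strsplit(lines, "\t"))
    paste(parts[, 1], parts[, 2], parts[, 4], parts[, 5], sep = ":")
  }
  expected <- intersect(keyOf(f1), keyOf(f2))
  m <- matchMutations(pr$catalog1, pr$catalog2)
  expect_setequal(m@sharedKeys, expected)
  expect_equal(m@shared, length(expected))
})

test_that("contingency tables embed matches over the universe", {
  m <- new("MatchResult", n1 = 40L, n2 = 46L, shared = 3L,
           sharedKeys = paste0("k", 1:3))
  ct <- buildContingency(m, 874)
  expect_equal(c(ct@a, ct@b, ct@c, ct@d), c(3L, 37L, 43L, 791L))

  full <- new("MatchResult", n1 = 5L, n2 = 5L, shared = 5L,
              sharedKeys = paste0("k", 1:5))
  ct2 <- buildContingency(full, 10)
  expect_equal(c(ct2@a, ct2@b, ct2@c, ct2@d), c(5L, 0L, 0L, 5L))

  none <- new("MatchResult", n1 = 5L, n2 = 5L, shared = 0L,
              sharedKeys = character(0))
  expect_error(buildContingency(none, 9), "larger N")
})

test_that("one-sided Fisher matches direct hypergeometric tail sums", {
  expect_equal(fisherExactOneSided(rbind(c(1, 0), c(0, 1))), 0.5)
  expect_equal(fisherExactOneSided(rbind(c(0, 5), c(5, 90))), 1.0)

  ct <- buildContingency(new("MatchResult", n1 = 40L, n2 = 46L, shared = 3L,
                             sharedKeys = paste0("k", 1:3)), 874)
  oracle <- sum(stats::dhyper(3:40, 40, 874 - 40, 46))
  expect_equal(fisherExactOneSided(ct), oracle, tolerance = 1e-12)

  # log-space path agrees with the linear path
  expect_equal(exp(fisherExactOneSided(ct, log = TRUE)),
               fisherExactOneSided(ct))
})

test_that("Fisher tail equals the oracle over an exhaustive small sweep", {
  for (N in c(5L, 11L, 20L)) {
    for (n1 in 0:N) for (n2 in 0:N) {
      kmin <- max(0L, n1 + n2 - N)
      kmax <- min(n1, n2)
      a <- kmin:kmax
      ours <- exp(clonalPair:::.hyperTailLog(a, n1, n2, N))
      oracle <- vapply(a, function(ai)
        sum(stats::dhyper(ai:kmax, n1, N - n1, n2)), numeric(1))
      expect_equal(ours, oracle, tolerance = 1e-10)
    }
  }
})

test_that("the tail p value is monotone non-increasing in the shared count", {
  p <- exp(clonalPair:::.hyperTailLog(0:40, 40, 46, 874))
  expect_true(all(diff(p) <= 1e-15))
})

test_that("BH adjustment equals the textbook step-up oracle", {
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))^sample(1:3, 1)
    expect_equal(bhAdjust(p), bhOracle(p))
  }
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(rep(0.2, 7)), rep(0.2, 7))
  # stable against input order
  p <- c(0.9, 1e-5, 0.04, 0.5)
  perm <- c(3, 1, 4, 2)
  expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("concordance fractions follow their definitions", {
  m <- new("MatchResult", n1 = 70L, n2 = 95L, shared = 64L,
           sharedKeys = paste0("k", 1:64))
  fr <- concordanceFraction(m)
  expect_equal(fr$fMin, 64 / 70)
  expect_equal(fr$fUnion, 64 / (70 + 95 - 64))

  all5 <- new("MatchResult", n1 = 5L, n2 = 5L, shared = 5L,
              sharedKeys = paste0("k", 1:5))
  expect_equal(concordanceFraction(all5), list(fMin = 1, fUnion = 1))

  empty <- new("MatchResult", n1 = 0L, n2 = 3L, shared = 0L,
               sharedKeys = character(0))
  expect_warning(fr0 <- concordanceFraction(empty), "zero mutations")
  expect_true(is.na(fr0$fMin))
})

test_that("the per-patient report separates clonal from independent pairs", {
  co <- simulateCohort(simulationParams(), seed = 2)
  rep <- concordanceReport(co$pairs, universeSize = 900)
  expect_equal(rep$q, bhAdjust(rep$p))
  expect_true(all(rep$q[co$truth$isClonal] < 1e-6))
  expect_true(all(rep$q[!co$truth$isClonal] > 0.05))
  # superset universe reconstruction: N defaults to the union of all keys
  rep2 <- concordanceReport(co$pairs)
  expect_true(all(rep2$p[co$truth$isClonal] < 1e-6))
})
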