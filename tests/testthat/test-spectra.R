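test_that("strand collapse maps known examples correctly", {
  expect_equal(collapseContext("ACA", "C", "T"), "A[C>T]A")
  expect_equal(collapseContext("TGT", "G", "A"), "A[C>T]A")
  expect_equal(collapseContext("AGA", "G", "C"), "T[C>G]T")
  expect_true(is.na(collapseContext("ANA", "N", "T")))
  expect_true(is.na(collapseContext("NCA", "C", "T")))
})

test_that("strand collapse is exhaustive and strand-invariant", {
  bases <- c("A", "C", "G", "T")
  combos <- expand.grid(f5 = bases, ref = bases, f3 = bases, alt = bases,
                        stringsAsFactors = FALSE)
  combos <- combos[combos$ref != combos$alt, ]
  expect_equal(nrow(combos), 192L)
  ctx <- paste0(combos$f5, combos$ref, combos$f3)
  cat1 <- collapseContext(ctx, combos$ref, combos$alt)
  # the reverse-complement representation of each mutation collapses equally
  rc <- function(x) chartr("ACGT", "TGCA", sapply(strsplit(x, ""), function(b)
    paste(rev(b), collapse = "")))
  cat2 <- collapseContext(rc(ctx), chartr("ACGT", "TGCA", combos$ref),
                          chartr("ACGT", "TGCA", combos$alt))
  expect_equal(cat1, cat2)
  expect_true(all(cat1 %in% spectrumCategories()))
  expect_true(all(table(cat1) == 2L))  # every category from exactly 2 strands
})

test_that("spectra count usable SNVs and conserve totals", {
  one <- MutationCatalog("S", mutRow("1", 10L, "C", "T", "ACA"))
  sp <- buildSpectrum(one)
  expect_equal(sum(spectrumCounts(sp)), 1L)
  expect_equal(spectrumCounts(sp)[["A[C>T]A"]], 1L)

  # strand-flipped copy yields the identical spectrum
  flip <- MutationCatalog("Sf", mutRow("1", 10L, "G", "A", "TGT"))
  expect_equal(spectrumCounts(buildSpectrum(flip)), spectrumCounts(sp))

  # indels and context-less SNVs are skipped but tallied
  mixed <- MutationCatalog("M", rbind(
    mutRow("1", 1L, "C", "T", "ACA"),
    mutRow("1", 2L, "C", "G"),            # no context
    mutRow("1", 3L, "AT", "A"),           # indel: not an SNV at all
    mutRow("1", 4L, "T", "A", "CTG")))
  spM <- buildSpectrum(mixed)
  expect_equal(sum(spectrumCounts(spM)), 2L)
  expect_equal(spM@skipped, 1L)

  expect_warning(buildSpectrum(MutationCatalog("E")), "no SNVs")
})

test_that("spectrum of a simulated catalog equals a brute-force tally", {
  pr <- simulatePair(simulationParams(), "P1", seed = 11, what = "mutations")
  df <- mutations(pr$catalog1)
  # independent tally: loop + manual complementation, no shared code path
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  tally <- table(vapply(seq_len(nrow(df)), function(i) {
    r <- df$ref[i]; a <- df$alt[i]; ctx <- strsplit(df$context[i], "")[[1]]
    if (r %in% c("A", "G")) {
      ctx <- rev(unname(comp[ctx])); r <- unname(comp[r]); a <- unname(comp[a])
    }
    sprintf("%s[%s>%s]%s", ctx[1], r, a, ctx[3])
  }, character(1)))
  sp <- spectrumCounts(buildSpectrum(pr$catalog1))
  for (categ in names(tally))
    expect_equal(sp[[categ]], as.integer(tally[[categ]]))
  expect_equal(sum(sp), nrow(df))
})

test_that("scaling normalizes loads then standardizes columns", {
  raw <- rbind(S1 = rep(1L, 96), S2 = rep(3L, 96))
  colnames(raw) <- spectrumCategories()
  expect_equal(unname(scaleSpectra(raw)), matrix(0, 2, 96),
               ignore_attr = TRUE)

  set.seed(4)
  raw2 <- matrix(rpois(5 * 96, 3), 5, 96,
                 dimnames = list(paste0("S", 1:5), spectrumCategories()))
  sc <- scaleSpectra(raw2)
  expect_true(all(abs(colMeans(sc)) < 1e-12))
  sds <- apply(sc, 2, sd)
  expect_true(all(abs(sds[sds > 0] - 1) < 1e-12))

  expect_warning(one <- scaleSpectra(raw2[1, , drop = FALSE]), "fewer than 2")
  expect_equal(sum(one), 1)  # frequencies only
})

test_that("clustering adjacency identifies paired samples", {
  m <- rbind(A1 = c(rep(5, 48), rep(0, 48)), A2 = c(rep(5, 48), rep(0, 48)),
             B1 = c(rep(0, 48), rep(5, 48)), B2 = c(rep(0, 48), rep(5, 48)))
  m <- m + matrix(rnorm(4 * 96, 0, 0.01), 4)
  pats <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
  cl <- hierarchicalCluster(m, metric = "euclidean", patients = pats)
  expect_true(all(cl@adjacency))
  expect_equal(as.integer(sort(table(cl@membership))), c(2L, 2L))

  two <- hierarchicalCluster(m[c(1, 3), ], metric = "euclidean",
                             patients = pats[c(1, 3)])
  expect_s4_class(two, "ClusterResult")

  m[1, 1] <- NaN
  expect_error(hierarchicalCluster(m), "NA/NaN")
})

test_that("clustering trees export as Newick", {
  set.seed(2)
  m <- matrix(rnorm(5 * 96), 5, dimnames = list(paste0("S", 1:5), NULL))
  cl <- hierarchicalCluster(m)
  path <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(cl, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, paste0("S", 1:5))
})

test_that("Ti/Tv handles edge cases and the generator's default spectrum", {
  onlyTi <- MutationCatalog("t", rbind(mutRow("1", 1L, "C", "T"),
                                       mutRow("1", 2L, "G", "A"),
                                       mutRow("1", 3L, "A", "G")))
  expect_equal(titvRatio(onlyTi), Inf)
  even <- MutationCatalog("e", rbind(mutRow("1", 1L, "C", "A"),
                                     mutRow("1", 2L, "C", "T")))
  expect_equal(titvRatio(even), 1.0)
  expect_true(is.nan(titvRatio(MutationCatalog("z"))))
  # implied Ti:Tv of the default weights is exactly 1.5
  w <- defaultSpectrumWeights()
  ti <- sum(w[grepl("C>T|T>C", names(w))])
  expect_equal(ti / (1 - ti), 1.5)
})

test_that("nonsynonymous:synonymous right-tail test is exact", {
  res <- nsSynTest(493, 212)
  expect_equal(round(res$ratio, 2), 2.33)
  expect_equal(nsSynTest(0, 10)$p, 1)
  oracle <- sum(stats::dbinom(70:100, 100, 0.7))
  expect_equal(nsSynTest(70, 30, p0 = 0.7)$p, oracle, tolerance = 1e-12)
  noSyn <- nsSynTest(12, 0)
  expect_true(is.na(noSyn$ratio))
  expect_true(noSyn$p > 0 && noSyn$p <= 1)
})
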