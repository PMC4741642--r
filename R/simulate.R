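# Synthetic paired-tumor cohort generator. The defaults encode the study
# conditions the package is calibrated against: ~72.8 exonic mutations per
# tumor (over-dispersed, range ~28-185), a cohort-wide universe of 900
# candidate sites, C>T-dominated spectra with Ti:Tv = 1.5, ~428x depth with 1%
# sequencing error, breast-cancer hallmark arm events (gains 1q,3q,8q,20q,21q;
# losses 8p,11q,16q,Xq) and a scaled-down genome of 46 arms x 22 probes at
# 2.1 kb spacing.

#' SimulationParams: conditions for the synthetic cohort
#'
#' See [simulationParams()] for the meaning and defaults of every slot.
#'
#' @export
setClass("SimulationParams",
         representation(nPatients = "integer", nClonal = "integer",
                        rho = "numeric", mutationsMean = "numeric",
                        mutationsDispersion = "numeric",
                        universeSize = "integer",
                        spectrumWeights = "numeric", effectProbs = "numeric",
                        depthMean = "numeric", errorRate = "numeric",
                        vafShape1 = "numeric", vafShape2 = "numeric",
                        vafMin = "numeric", armTable = "data.frame",
                        armEventFreqs = "data.frame", noiseSd = "numeric",
                        gainLog2 = "numeric", lossLog2 = "numeric",
                        dropoutRate = "numeric"))

setValidity("SimulationParams", function(object) {
  if (object@rho < 0 || object@rho > 1) return("rho must lie in [0, 1]")
  if (object@errorRate <= 0 || object@errorRate >= 1)
    return("errorRate must lie in (0, 1)")
  if (object@dropoutRate < 0 || object@dropoutRate > 1)
    return("dropoutRate must lie in [0, 1]")
  if (length(object@spectrumWeights) != 96L)
    return("spectrumWeights must have length 96")
  if (any(object@spectrumWeights < 0)) return("spectrumWeights must be >= 0")
  if (object@universeSize < object@mutationsMean)
    return("universeSize must exceed the expected per-tumor mutation count")
  f <- object@armEventFreqs
  if (!all(c("arm", "pGain", "pLoss") %in% names(f)))
    return("armEventFreqs needs columns arm, pGain, pLoss")
  if (any(f$pGain < 0) || any(f$pLoss < 0) || any(f$pGain + f$pLoss > 1))
    return("arm event frequencies must be probabilities with pGain + pLoss <= 1")
  if (!setequal(f$arm, object@armTable$arm))
    return("armEventFreqs arms must match armTable arms")
  TRUE
})

#' Scaled-down genome arm table
#'
#' A synthetic genome of chromosomes 1-22 and X, each with a p and a q arm of
#' \code{probesPerArm} probes at \code{probeSpacing} bp (defaults give 46 arms
#' and 1012 probes, emulating a 2.1 kb-spaced array at desk scale). Arms are
#' laid out consecutively along each chromosome.
#'
#' @param probesPerArm probes per arm.
#' @param probeSpacing probe spacing in bp.
#' @return \code{data.frame} with columns \code{arm, chrom, start, end,
#'   nProbes}.
#' @export
defaultArmTable <- function(probesPerArm = 22L, probeSpacing = 2100L) {
  chroms <- c(as.character(1:22), "X")
  armLen <- as.integer(probesPerArm * probeSpacing)
  do.call(rbind, lapply(chroms, function(ch) {
    data.frame(arm = paste0(ch, c("p", "q")), chrom = ch,
               start = c(1L, armLen + 1L), end = c(armLen, 2L * armLen),
               nProbes = probesPerArm, stringsAsFactors = FALSE)
  }))
}

# default 6-class weights: C>T dominant, Ti:Tv = (wCT + wTC) / rest = 1.5
.defaultClassWeights <- c("C>A" = 0.10, "C>G" = 0.08, "C>T" = 0.45,
                          "T>A" = 0.07, "T>C" = 0.15, "T>G" = 0.15)

#' Default 96-category spectrum weights
#'
#' Class totals 0.10/0.08/0.45/0.07/0.15/0.15 for C>A/C>G/C>T/T>A/T>C/T>G: a
#' C>T-dominated spectrum whose implied transition:transversion ratio is
#' exactly 1.5. Within C>T, contexts with a 3' G (CpG sites) carry three-fold
#' weight; other classes are uniform over their 16 contexts.
#'
#' @return named numeric vector of length 96 summing to 1.
#' @export
defaultSpectrumWeights <- function() {
  w <- numeric(96L)
  names(w) <- spectrumCategories()
  for (cls in names(.defaultClassWeights)) {
    idx <- grepl(sprintf("[%s>%s]", substr(cls, 1, 1), substr(cls, 3, 3)),
                 names(w), fixed = TRUE)
    inner <- rep(1, 16L)
    if (cls == "C>T") inner[grepl("\\]G$", names(w)[idx])] <- 3
    w[idx] <- .defaultClassWeights[[cls]] * inner / sum(inner)
  }
  w
}

#' Simulation parameters with study-scale defaults
#'
#' @param nPatients patients in a cohort.
#' @param nClonal how many of the patients (the last ones) get clonal pairs;
#'   the rest are independent.
#' @param rho shared fraction for clonal pairs: the planted shared set has
#'   size \code{round(rho * min(n1, n2))}; independent pairs use 0.
#' @param mutationsMean,mutationsDispersion negative-binomial mean/size of the
#'   per-tumor exonic mutation count (defaults 72.8 and 8, over-dispersed to
#'   span roughly 28-185).
#' @param universeSize size N of the cohort-wide pool of candidate mutation
#'   sites (default 900, about 72.8 x 12 rounded up).
#' @param spectrumWeights 96-vector of category weights (default
#'   [defaultSpectrumWeights()], implied Ti:Tv 1.5).
#' @param effectProbs named probabilities of effect classes.
#' @param depthMean mean sequencing depth (default 428; depth is 1 + Poisson).
#' @param errorRate per-base sequencing error rate e (default 0.01).
#' @param vafShape1,vafShape2,vafMin true VAF ~ Beta(shape1, shape2)
#'   left-truncated at \code{vafMin} (defaults 2, 5, 0.05).
#' @param armTable scaled-down genome ([defaultArmTable()]).
#' @param armEventFreqs per-arm gain/loss probabilities; default 0.25 on the
#'   hallmark arms (gains 1q,3q,8q,20q,21q; losses 8p,11q,16q,Xq) and 0.02
#'   background per direction, about 3 events per tumor.
#' @param noiseSd per-probe Gaussian log-ratio noise sd (default 0.1, DLRS
#'   0.1, comfortably under the 0.20 QC cutoff).
#' @param gainLog2,lossLog2 planted segment means (defaults +0.5 / -0.6).
#' @param dropoutRate probability that a planted shared mutation's call is
#'   suppressed in tumor 2 while its reads are kept (for rescue experiments);
#'   default 0.
#' @return a validated [SimulationParams-class].
#' @export
simulationParams <- function(nPatients = 6L, nClonal = 2L, rho = 0.8,
                             mutationsMean = 72.8, mutationsDispersion = 8,
                             universeSize = 900L,
                             spectrumWeights = defaultSpectrumWeights(),
                             effectProbs = c(synonymous = 0.30,
                                             nonsynonymous = 0.645,
                                             stopgain = 0.03,
                                             splicing = 0.02, other = 0.005),
                             depthMean = 428, errorRate = 0.01,
                             vafShape1 = 2, vafShape2 = 5, vafMin = 0.05,
                             armTable = defaultArmTable(),
                             armEventFreqs = NULL,
                             noiseSd = 0.1, gainLog2 = 0.5, lossLog2 = -0.6,
                             dropoutRate = 0) {
  if (is.null(armEventFreqs)) {
    gains <- c("1q", "3q", "8q", "20q", "21q")
    losses <- c("8p", "11q", "16q", "Xq")
    armEventFreqs <- data.frame(arm = armTable$arm, pGain = 0.02,
                                pLoss = 0.02, stringsAsFactors = FALSE)
    armEventFreqs$pGain[armEventFreqs$arm %in% gains] <- 0.25
    armEventFreqs$pLoss[armEventFreqs$arm %in% losses] <- 0.25
  }
  new("SimulationParams", nPatients = as.integer(nPatients),
      nClonal = as.integer(nClonal), rho = rho,
      mutationsMean = mutationsMean,
      mutationsDispersion = mutationsDispersion,
      universeSize = as.integer(universeSize),
      spectrumWeights = spectrumWeights, effectProbs = effectProbs,
      depthMean = depthMean, errorRate = errorRate, vafShape1 = vafShape1,
      vafShape2 = vafShape2, vafMin = vafMin, armTable = armTable,
      armEventFreqs = armEventFreqs, noiseSd = noiseSd, gainLog2 = gainLog2,
      lossLog2 = lossLog2, dropoutRate = dropoutRate)
}

#' Generate the cohort-wide universe of candidate mutation sites
#'
#' Draws \code{universeSize} unique sites: positions uniform over the scaled
#' genome, substitution category by \code{spectrumWeights} (presented on the
#' reference or the reverse-complement strand with equal probability), effect
#' class by \code{effectProbs}.
#'
#' @param params a [SimulationParams-class].
#' @param seed optional integer seed; \code{NULL} continues the current RNG
#'   stream.
#' @return \code{data.frame} of sites with the canonical mutation columns.
#' @export
simulateUniverse <- function(params, seed = NULL) {
  stopifnot(is(params, "SimulationParams"))
  if (!is.null(seed)) set.seed(seed)
  N <- params@universeSize
  at <- params@armTable
  armIdx <- sample.int(nrow(at), N, replace = TRUE,
                       prob = at$end - at$start + 1)
  pos <- at$start[armIdx] +
    floor(stats::runif(N) * (at$end[armIdx] - at$start[armIdx] + 1L))
  chrom <- at$chrom[armIdx]
  # resolve positional collisions so (chrom, pos) is unique
  repeat {
    dup <- duplicated(paste(chrom, pos))
    if (!any(dup)) break
    pos[dup] <- at$start[armIdx[dup]] +
      floor(stats::runif(sum(dup)) * (at$end[armIdx[dup]] - at$start[armIdx[dup]] + 1L))
  }
  catIdx <- sample.int(96L, N, replace = TRUE, prob = params@spectrumWeights)
  cats <- spectrumCategories()[catIdx]
  ref <- substr(cats, 3L, 3L)
  alt <- substr(cats, 5L, 5L)
  context <- paste0(substr(cats, 1L, 1L), ref, substr(cats, 7L, 7L))
  flip <- stats::runif(N) < 0.5
  context[flip] <- .revcomp(context[flip])
  ref[flip] <- .complement(ref[flip])
  alt[flip] <- .complement(alt[flip])
  effect <- sample(names(params@effectProbs), N, replace = TRUE,
                   prob = params@effectProbs)
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             context = context, gene = sprintf("GENE%04d", seq_len(N)),
             effect = effect, stringsAsFactors = FALSE)
}

# truncated draws
.rnbinomMin <- function(n, mu, size, min = 5L) {
  out <- stats::rnbinom(n, mu = mu, size = size)
  while (any(out < min))
    out[out < min] <- stats::rnbinom(sum(out < min), mu = mu, size = size)
  out
}

.rvaf <- function(n, params) {
  out <- stats::rbeta(n, params@vafShape1, params@vafShape2)
  while (any(out < params@vafMin))
    out[out < params@vafMin] <- stats::rbeta(sum(out < params@vafMin),
                                             params@vafShape1, params@vafShape2)
  out
}

# depth ~ 1 + Poisson(depthMean - 1); alt ~ Binom(depth, vaf(1-e) + (1-vaf)e/3)
.drawReads <- function(vafTrue, params) {
  n <- length(vafTrue)
  depth <- 1L + stats::rpois(n, params@depthMean - 1)
  e <- params@errorRate
  p <- vafTrue * (1 - e) + (1 - vafTrue) * e / 3
  alt <- stats::rbinom(n, depth, p)
  data.frame(altReads = alt, depth = depth)
}

# background reads at a site not mutated in this tumor: errors toward the alt
# allele at rate e
.drawBackgroundReads <- function(n, params) {
  depth <- 1L + stats::rpois(n, params@depthMean - 1)
  alt <- stats::rbinom(n, depth, params@errorRate)
  data.frame(altReads = alt, depth = depth)
}

#' Simulate one tumor pair
#'
#' Draws per-tumor mutation counts n1, n2 from the negative binomial, plants a
#' shared set of size \code{round(rho * min(n1, n2))} drawn from the universe,
#' fills the remainders with independent draws (without replacement, outside
#' the shared set) so that independent pairs overlap only by chance
#' (expectation about \code{n1 n2 / N}), attaches true VAFs and read counts,
#' and generates per-arm copy-number events with probe-level log ratios. For
#' clonal pairs each tumor-1 arm event is inherited by tumor 2 with
#' probability \code{rho}. Deterministic given \code{seed}.
#'
#' @param params a [SimulationParams-class].
#' @param patientId patient identifier; samples are named
#'   \code{"<patient>-1"}/\code{"<patient>-2"}.
#' @param seed optional integer seed; \code{NULL} continues the current RNG
#'   stream (used by [simulateCohort()]).
#' @param rho overrides \code{params@rho} for this pair (0 = independent).
#' @param universe optional precomputed [simulateUniverse()] table shared
#'   across a cohort; generated from \code{params} when \code{NULL}.
#' @param what components to generate: subset of
#'   \code{c("mutations", "cnv")}.
#' @return list with \code{catalog1}, \code{catalog2}
#'   ([MutationCatalog-class]), \code{profile1}, \code{profile2}
#'   ([CopyNumberProfile-class] or \code{NULL}), \code{counts} (read counts of
#'   both tumors at every site of the pair's union, for superset rescue) and
#'   \code{truth} ([TumorPairTruth-class]).
#' @export
simulatePair <- function(params, patientId = "P1", seed = NULL,
                         rho = params@rho, universe = NULL,
                         what = c("mutations", "cnv")) {
  stopifnot(is(params, "SimulationParams"), rho >= 0, rho <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(universe)) universe <- simulateUniverse(params, seed = NULL)
  N <- nrow(universe)
  n12 <- .rnbinomMin(2L, params@mutationsMean, params@mutationsDispersion)
  n1 <- n12[1]; n2 <- n12[2]
  nShared <- as.integer(round(rho * min(n1, n2)))
  if (n1 > N || n2 > N || nShared > N)
    stop("universe too small for the requested mutation counts; increase ",
         "universeSize")
  sharedIdx <- if (nShared > 0) sample.int(N, nShared) else integer(0)
  pool <- setdiff(seq_len(N), sharedIdx)
  idx1 <- c(sharedIdx, sample(pool, n1 - nShared))
  idx2 <- c(sharedIdx, sample(pool, n2 - nShared))

  mkMutations <- function(idx) {
    df <- universe[idx, , drop = FALSE]
    vafTrue <- .rvaf(length(idx), params)
    cbind(df, .drawReads(vafTrue, params))
  }
  mut1 <- mkMutations(idx1)
  mut2 <- mkMutations(idx2)

  dropped <- logical(nrow(mut2))
  if (params@dropoutRate > 0 && nShared > 0) {
    inShared <- seq_len(nShared)  # shared sites lead idx2
    dropped[inShared] <- stats::runif(nShared) < params@dropoutRate
  }

  countsFor <- function(mut, idx, unionIdx) {
    m <- match(unionIdx, idx)
    out <- .drawBackgroundReads(length(unionIdx), params)
    hit <- !is.na(m)
    out$altReads[hit] <- mut$altReads[m[hit]]
    out$depth[hit] <- mut$depth[m[hit]]
    out
  }
  unionIdx <- union(idx1, idx2)
  uni <- universe[unionIdx, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  c1 <- countsFor(mut1, idx1, unionIdx)
  c2 <- countsFor(mut2, idx2, unionIdx)
  counts <- data.frame(uni, altReads1 = c1$altReads, depth1 = c1$depth,
                       altReads2 = c2$altReads, depth2 = c2$depth,
                       row.names = NULL, stringsAsFactors = FALSE)

  keys1 <- variantKey(mut1)
  keys2 <- variantKey(mut2)
  droppedKeys <- keys2[dropped]
  cat1 <- MutationCatalog(paste0(patientId, "-1"), mut1,
                          patientId = patientId, tumorIndex = 1L)
  cat2 <- MutationCatalog(paste0(patientId, "-2"),
                          mut2[!dropped, , drop = FALSE],
                          patientId = patientId, tumorIndex = 2L)

  profile1 <- profile2 <- NULL
  states1 <- states2 <- integer(0)
  sharedArms <- character(0)
  if ("cnv" %in% what) {
    f <- params@armEventFreqs
    drawStates <- function() {
      vapply(seq_len(nrow(f)), function(i)
        sample(c(1L, -1L, 0L), 1L,
               prob = c(f$pGain[i], f$pLoss[i], 1 - f$pGain[i] - f$pLoss[i])),
        integer(1))
    }
    states1 <- drawStates()
    inherit <- stats::runif(nrow(f)) < rho
    indep2 <- drawStates()
    states2 <- ifelse(inherit, states1, indep2)
    names(states1) <- names(states2) <- f$arm
    sharedArms <- f$arm[inherit & states1 != 0L]
    mkProfile <- function(states, sid) {
      at <- params@armTable
      rows <- lapply(seq_len(nrow(at)), function(i) {
        spacing <- (at$end[i] - at$start[i] + 1L) / at$nProbes[i]
        pos <- as.integer(at$start[i] + floor((seq_len(at$nProbes[i]) - 0.5) * spacing))
        mean <- if (states[[at$arm[i]]] == 1L) params@gainLog2 else
          if (states[[at$arm[i]]] == -1L) params@lossLog2 else 0
        data.frame(chrom = at$chrom[i], pos = pos,
                   log2ratio = mean + stats::rnorm(at$nProbes[i], 0, params@noiseSd),
                   stringsAsFactors = FALSE)
      })
      CopyNumberProfile(sid, do.call(rbind, rows))
    }
    profile1 <- mkProfile(states1, paste0(patientId, "-1"))
    profile2 <- mkProfile(states2, paste0(patientId, "-2"))
  }

  truth <- new("TumorPairTruth", patientId = patientId, isClonal = rho > 0,
               sharedKeys = intersect(keys1, keys2),
               droppedKeys = droppedKeys, sharedArms = sharedArms,
               armStates1 = states1, armStates2 = states2)
  list(catalog1 = cat1, catalog2 = cat2, profile1 = profile1,
       profile2 = profile2, counts = counts, truth = truth)
}

#' Simulate a cohort of tumor pairs
#'
#' Generates \code{nPatients} pairs sharing one universe: the first
#' \code{nPatients - nClonal} pairs are independent (rho 0), the last
#' \code{nClonal} are clonal at \code{params@rho} — mirroring a design of
#' independent bilateral pairs plus primary/metastasis control pairs.
#'
#' @param params a [SimulationParams-class].
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @return list with \code{params}, \code{universe}, \code{pairs} (named list
#'   of [simulatePair()] results) and \code{truth} (per-patient
#'   \code{data.frame}).
#' @export
simulateCohort <- function(params = simulationParams(), seed = 1L) {
  stopifnot(is(params, "SimulationParams"))
  set.seed(seed)
  universe <- simulateUniverse(params, seed = NULL)
  n <- params@nPatients
  if (n == 0L)
    return(list(params = params, universe = universe, pairs = list(),
                truth = data.frame(patientId = character(),
                                   isClonal = logical())))
  clonal <- seq_len(n) > n - params@nClonal
  ids <- paste0("P", seq_len(n))
  pairs <- lapply(seq_len(n), function(i)
    simulatePair(params, patientId = ids[i],
                 rho = if (clonal[i]) params@rho else 0,
                 universe = universe))
  names(pairs) <- ids
  list(params = params, universe = universe, pairs = pairs,
       truth = data.frame(patientId = ids, isClonal = clonal,
                          stringsAsFactors = FALSE))
}

#' Write a simulated cohort to disk
#'
#' Writes per-sample catalogs (chosen format), probe TSVs, per-pair read
#' counts, a truth table and a manifest, all as plain text.
#'
#' @param cohort result of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @param format catalog format, \code{"maf_tsv"} or \code{"vcf"}.
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir, format = c("maf_tsv", "vcf")) {
  format <- match.arg(format)
  ext <- if (format == "vcf") "vcf" else "tsv"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort$pairs, function(pair) {
    pid <- pair$truth@patientId
    paths <- c(mutations1 = file.path(dir, sprintf("%s-1.%s", pid, ext)),
               mutations2 = file.path(dir, sprintf("%s-2.%s", pid, ext)),
               counts = file.path(dir, sprintf("%s.counts.tsv", pid)))
    writeMutations(pair$catalog1, paths[["mutations1"]], format)
    writeMutations(pair$catalog2, paths[["mutations2"]], format)
    utils::write.table(pair$counts, paths[["counts"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    prof <- c(probes1 = NA_character_, probes2 = NA_character_)
    if (!is.null(pair$profile1)) {
      prof <- c(probes1 = file.path(dir, sprintf("%s-1.probes.tsv", pid)),
                probes2 = file.path(dir, sprintf("%s-2.probes.tsv", pid)))
      writeProbeProfile(pair$profile1, prof[["probes1"]])
      writeProbeProfile(pair$profile2, prof[["probes2"]])
    }
    data.frame(patient_id = pid, t(c(paths, prof)),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifestPath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, manifestPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifestPath)
}
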