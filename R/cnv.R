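# Copy-number clonality: profile QC by derivative log ratio spread, ADM-style
# aberration detection, reduction to per-arm gain/loss/normal states, and the
# arm-level clonality likelihood ratio (LR2) with a reference-null p value.

#' Derivative log ratio spread
#'
#' Noise metric of an aCGH-like profile: the standard deviation of successive
#' probe log-ratio differences divided by sqrt(2). For i.i.d. probe noise of
#' sd sigma the statistic estimates sigma.
#'
#' @param profile a [CopyNumberProfile-class] (differences are taken within
#'   chromosomes) or a numeric vector of log ratios.
#' @return the score.
#' @export
dlrs <- function(profile) {
  if (is(profile, "CopyNumberProfile")) {
    df <- probes(profile)
    if (nrow(df) < 3L) stop("need at least 3 probes to compute dlrs")
    diffs <- unlist(lapply(split(df$log2ratio, df$chrom), diff),
                    use.names = FALSE)
  } else {
    x <- as.numeric(profile)
    if (length(x) < 3L) stop("need at least 3 probes to compute dlrs")
    diffs <- diff(x)
  }
  stats::sd(diffs) / sqrt(2)
}

#' Quality-control filter on profile noise
#'
#' Partitions profiles by their [dlrs()] score against the cutoff. The cutoff
#' excludes profiles scoring strictly above it (a boundary score of exactly
#' 0.20 passes).
#'
#' @param profiles list of [CopyNumberProfile-class] objects.
#' @param cutoff maximum acceptable score (default 0.20).
#' @return list with \code{passed}, \code{failed} (profile lists) and
#'   \code{scores} (named numeric).
#' @export
qcFilter <- function(profiles, cutoff = 0.20) {
  scores <- vapply(profiles, dlrs, numeric(1))
  names(scores) <- vapply(profiles, sampleId, character(1))
  keep <- scores <= cutoff
  if (any(!keep))
    message("qcFilter: excluded ", sum(!keep), " profile(s): ",
            paste(sprintf("%s (%.3f)", names(scores)[!keep],
                          scores[!keep]), collapse = ", "))
  list(passed = profiles[keep], failed = profiles[!keep], scores = scores)
}

# greedy interval scan on one chromosome's log ratios: repeatedly take the
# interval maximizing |sum| / (sigma sqrt(len)) while it clears the
# threshold, then recurse into the flanks. An aberration narrower than
# minProbes is filtered out (its probes are not padded into a wider call).
.scanIntervals <- function(x, sigma, threshold, minProbes) {
  n <- length(x)
  if (n < 1L) return(NULL)
  S <- c(0, cumsum(x))
  starts <- seq_len(n)
  sums <- outer(S[1:n], S[2:(n + 1)], function(si, sj) sj - si)  # [i, j]
  len <- outer(starts, starts, function(i, j) j - i + 1)
  score <- abs(sums) / (sigma * sqrt(pmax(len, 1)))
  score[len < 1] <- -Inf
  best <- which(score == max(score), arr.ind = TRUE)[1, ]
  if (score[best[1], best[2]] < threshold) return(NULL)
  i <- best[[1]]; j <- best[[2]]
  left <- .scanIntervals(x[seq_len(i - 1L)], sigma, threshold, minProbes)
  right <- if (j < n) .scanIntervals(x[(j + 1L):n], sigma, threshold,
                                     minProbes) else NULL
  if (!is.null(right)) right[, c("i", "j")] <- right[, c("i", "j")] + j
  hit <- if (j - i + 1L >= minProbes) data.frame(i = i, j = j) else NULL
  rbind(left, hit, right)
}

#' Detect copy-number aberrations (ADM-style)
#'
#' Scans each chromosome for maximal non-overlapping probe intervals whose
#' score \code{|sum of log ratios| / (sigma * sqrt(n))} reaches the
#' sensitivity threshold with at least \code{minProbes} probes; \code{sigma}
#' is the profile's [dlrs()] noise estimate. Each reported interval becomes a
#' segment whose state is the sign of its mean.
#'
#' @param profile a QC-passed [CopyNumberProfile-class].
#' @param threshold sensitivity threshold (default 6.0).
#' @param minProbes minimum probes per aberration (default 3).
#' @param sigma noise sd; default \code{dlrs(profile)}, with
#'   \code{noiseFloor} substituted if the estimate is zero.
#' @param noiseFloor lower bound on sigma (default 1e-3).
#' @return segments \code{data.frame} (\code{sampleId, chrom, start, end,
#'   nProbes, meanLog2, state}); zero rows when the profile is flat.
#' @export
detectAberrations <- function(profile, threshold = 6.0, minProbes = 3L,
                              sigma = NULL, noiseFloor = 1e-3) {
  stopifnot(is(profile, "CopyNumberProfile"))
  df <- probes(profile)
  if (is.null(sigma)) sigma <- dlrs(profile)
  if (sigma <= 0) sigma <- noiseFloor
  segs <- lapply(split(df, df$chrom), function(ch) {
    hits <- .scanIntervals(ch$log2ratio, sigma, threshold, as.integer(minProbes))
    if (is.null(hits)) return(NULL)
    data.frame(sampleId = sampleId(profile), chrom = ch$chrom[1],
               start = ch$pos[hits$i], end = ch$pos[hits$j],
               nProbes = hits$j - hits$i + 1L,
               meanLog2 = vapply(seq_len(nrow(hits)), function(r)
                 mean(ch$log2ratio[hits$i[r]:hits$j[r]]), numeric(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, segs)
  if (is.null(out))
    out <- data.frame(sampleId = character(), chrom = character(),
                      start = integer(), end = integer(), nProbes = integer(),
                      meanLog2 = numeric(), stringsAsFactors = FALSE)
  out$state <- as.integer(sign(out$meanLog2))
  o <- order(.chromRank(out$chrom), out$start)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reduce segments to per-arm states
#'
#' An arm is called gained (+1) or lost (-1) when called segments of that
#' sign, with mean beyond the respective threshold, cover at least
#' \code{coverageFraction} of the arm (by bases); otherwise normal (0). When
#' both signs qualify the larger covered fraction wins; ties give 0.
#'
#' @param segments segment \code{data.frame} ([detectAberrations()] or
#'   [readSegments()]) of one sample.
#' @param armTable arm coordinates ([defaultArmTable()]).
#' @param coverageFraction minimum covered fraction (default 0.5; the boundary
#'   counts).
#' @param gainThr,lossThr segment-mean thresholds (defaults +0.25 / -0.25).
#' @param sampleId sample identifier for the result; defaults to the
#'   segments' own.
#' @return an [ArmStateVector-class] over all arms of \code{armTable}.
#' @export
armStates <- function(segments, armTable, coverageFraction = 0.5,
                      gainThr = 0.25, lossThr = -0.25, sampleId = NULL) {
  if (is.null(sampleId))
    sampleId <- if (nrow(segments)) segments$sampleId[1] else NA_character_
  states <- stats::setNames(integer(nrow(armTable)), armTable$arm)
  for (i in seq_len(nrow(armTable))) {
    arm <- armTable[i, ]
    armLen <- arm$end - arm$start + 1
    onArm <- segments[segments$chrom == arm$chrom &
                        segments$end >= arm$start &
                        segments$start <= arm$end, , drop = FALSE]
    covFor <- function(sel) {
      if (!any(sel)) return(0)
      s <- pmax(onArm$start[sel], arm$start)
      e <- pmin(onArm$end[sel], arm$end)
      sum(e - s + 1) / armLen
    }
    covGain <- covFor(onArm$state > 0L & onArm$meanLog2 >= gainThr)
    covLoss <- covFor(onArm$state < 0L & onArm$meanLog2 <= lossThr)
    qual <- c(gain = covGain >= coverageFraction,
              loss = covLoss >= coverageFraction)
    states[i] <- if (qual["gain"] && (!qual["loss"] || covGain > covLoss)) 1L
      else if (qual["loss"] && (!qual["gain"] || covLoss > covGain)) -1L
      else 0L
  }
  new("ArmStateVector", sampleId = as.character(sampleId), states = states)
}

#' Profile to arm states in one step
#'
#' Convenience composition of [detectAberrations()] and [armStates()].
#'
#' @param profile a [CopyNumberProfile-class].
#' @param armTable arm coordinates.
#' @param ... forwarded to [detectAberrations()] and [armStates()].
#' @return an [ArmStateVector-class].
#' @export
profileArmStates <- function(profile, armTable, ...) {
  dots <- list(...)
  detArgs <- dots[names(dots) %in% c("threshold", "minProbes", "sigma",
                                     "noiseFloor")]
  armArgs <- dots[names(dots) %in% c("coverageFraction", "gainThr", "lossThr")]
  segs <- do.call(detectAberrations, c(list(profile), detArgs))
  do.call(armStates, c(list(segs, armTable,
                            sampleId = sampleId(profile)), armArgs))
}

#' Estimate reference arm-state marginal frequencies
#'
#' Empirical per-arm frequencies of loss/normal/gain across a cohort of
#' samples, floored at \code{eps} and renormalized so that every state is
#' observable under the likelihood model.
#'
#' @param stateVectors list of [ArmStateVector-class] objects over a common
#'   arm set.
#' @param eps probability floor (default 0.01).
#' @return a [MarginalFrequencies-class].
#' @export
estimateMarginals <- function(stateVectors, eps = 0.01) {
  stopifnot(length(stateVectors) >= 2L)
  arms <- names(armStatesOf(stateVectors[[1]]))
  mat <- vapply(stateVectors, function(v) {
    s <- armStatesOf(v)
    stopifnot(identical(names(s), arms))
    s
  }, integer(length(arms)))
  freqs <- t(apply(mat, 1L, function(row) {
    f <- c(mean(row == -1L), mean(row == 0L), mean(row == 1L))
    low <- f < eps
    if (any(low)) {           # floored states get exactly eps, rest rescaled
      f[low] <- eps
      f[!low] <- f[!low] * (1 - eps * sum(low)) / sum(f[!low])
    }
    f
  }))
  dimnames(freqs) <- list(arms, c("-1", "0", "+1"))
  new("MarginalFrequencies", freqs = freqs)
}

# per-arm log likelihood terms of the clonality model at parameter c
.lr2LogLik <- function(c, s1, s2, freqs) {
  pi1 <- freqs[cbind(seq_len(nrow(freqs)), s1 + 2L)]
  pi2 <- freqs[cbind(seq_len(nrow(freqs)), s2 + 2L)]
  pAb <- freqs[, "-1"] + freqs[, "+1"]
  concordantAberrant <- s1 == s2 & s1 != 0L
  alpha <- ifelse(concordantAberrant, pi1 / pAb, 0)
  sum(log((1 - c) * pi1 * pi2 + c * alpha))
}

#' Arm-level clonality likelihood ratio (LR2)
#'
#' Generative model, independent across arms: with probability \code{c} a
#' shared clonal aberration occurs on arm k in both tumors, its sign drawn
#' from the arm's aberration frequencies renormalized over \{-1, +1\}; with
#' probability \code{1 - c} the two states are independent draws from the
#' arm's marginal distribution. \code{LR2 = max_c L(c) / L(0)} quantifies the
#' odds that the two tumors are clonal; \code{c_hat} is the maximizer (coarse
#' grid plus golden-section refinement, all in log space).
#'
#' @param states1,states2 [ArmStateVector-class] objects over the same arms.
#' @param marginals a [MarginalFrequencies-class] for those arms.
#' @param gridPoints coarse grid size on \code{[0, 1]} (default 101).
#' @return a [ClonalityResult-class] with \code{p = NA} (see [lr2Pvalue()]).
#' @export
lr2Statistic <- function(states1, states2, marginals, gridPoints = 101L) {
  stopifnot(is(states1, "ArmStateVector"), is(states2, "ArmStateVector"),
            is(marginals, "MarginalFrequencies"))
  s1 <- armStatesOf(states1)
  s2 <- armStatesOf(states2)
  freqs <- marginals@freqs
  stopifnot(identical(names(s1), rownames(freqs)),
            identical(names(s2), rownames(freqs)))
  # c = 1 has likelihood 0 unless every arm is concordant-aberrant; cap the
  # search just inside the boundary
  hi <- 1 - 1e-9
  grid <- seq(0, hi, length.out = gridPoints)
  ll <- vapply(grid, .lr2LogLik, numeric(1), s1 = s1, s2 = s2, freqs = freqs)
  best <- which.max(ll)
  lo <- grid[max(1L, best - 1L)]
  up <- grid[min(length(grid), best + 1L)]
  opt <- stats::optimize(.lr2LogLik, interval = c(lo, up), maximum = TRUE,
                         s1 = s1, s2 = s2, freqs = freqs)
  ll0 <- .lr2LogLik(0, s1, s2, freqs)
  cand <- rbind(c(0, ll0), c(opt$maximum, opt$objective),
                c(grid[best], ll[best]))
  top <- cand[which.max(cand[, 2]), ]
  if (top[2] <= ll0 + 1e-12) {
    cHat <- 0; lr2 <- 1
  } else {
    cHat <- top[1]; lr2 <- exp(top[2] - ll0)
  }
  new("ClonalityResult", lr2 = max(1, lr2), cHat = cHat, p = NA_real_)
}

#' Reference-null p value for LR2
#'
#' Plug-in permutation-style p value against a declared null set of reference
#' (independent) pairs: \code{p = (1 + #\{reference LR2 >= observed\}) /
#' (1 + #reference)}.
#'
#' @param observed a [ClonalityResult-class].
#' @param reference list of [ClonalityResult-class] objects or a numeric
#'   vector of reference LR2 values; at least 20 required.
#' @return the observed result with its \code{p} slot filled.
#' @export
lr2Pvalue <- function(observed, reference) {
  stopifnot(is(observed, "ClonalityResult"))
  refLr2 <- if (is.numeric(reference)) reference else
    vapply(reference, function(r) r@lr2, numeric(1))
  if (length(refLr2) < 20L)
    stop("need at least 20 reference pairs; simulate more independent pairs ",
         "to build the null")
  p <- (1 + sum(refLr2 >= observed@lr2)) / (1 + length(refLr2))
  new("ClonalityResult", lr2 = observed@lr2, cHat = observed@cHat, p = p)
}
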