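# Mutation-concordance clonality test: exact-key matching, the 2x2
# shared/specific contingency table over a finite universe of candidate
# sites, a one-sided (right-tail) Fisher exact test computed in log space,
# and Benjamini-Hochberg control across patients.

#' Match mutations between the two tumors of a patient
#'
#' Sharing is exact identity of the (chrom, pos, ref, alt) key; no positional
#' fuzziness. Symmetric in its arguments.
#'
#' @param cat1,cat2 [MutationCatalog-class] objects of the same patient.
#' @param allowPatientMismatch set \code{TRUE} to match catalogs whose
#'   \code{patientId}s differ (used when building between-patient reference
#'   pairs).
#' @return a [MatchResult-class].
#' @export
matchMutations <- function(cat1, cat2, allowPatientMismatch = FALSE) {
  stopifnot(is(cat1, "MutationCatalog"), is(cat2, "MutationCatalog"))
  p1 <- patientId(cat1); p2 <- patientId(cat2)
  if (!allowPatientMismatch && !is.na(p1) && !is.na(p2) && p1 != p2)
    stop("catalogs belong to different patients ('", p1, "' vs '", p2,
         "'); set allowPatientMismatch = TRUE to override")
  k1 <- variantKey(cat1)
  k2 <- variantKey(cat2)
  shared <- intersect(k1, k2)
  new("MatchResult", n1 = length(cat1), n2 = length(cat2),
      shared = length(shared), sharedKeys = shared)
}

#' Embed a match in the 2x2 shared/specific contingency table
#'
#' Cells: shared \code{a}, tumor-1-specific \code{b = n1 - a},
#' tumor-2-specific \code{c = n2 - a}, and \code{d = N - n1 - n2 + a} universe
#' sites mutated in neither tumor.
#'
#' @param match a [MatchResult-class].
#' @param N universe size; must satisfy \code{N >= n1 + n2 - shared}.
#' @return a [ContingencyTable-class].
#' @examples
#' m <- new("MatchResult", n1 = 40L, n2 = 46L, shared = 3L,
#'          sharedKeys = as.character(1:3))
#' buildContingency(m, 874)  # cells 3, 37, 43, 791
#' @export
buildContingency <- function(match, N) {
  stopifnot(is(match, "MatchResult"))
  N <- as.integer(N)
  d <- N - match@n1 - match@n2 + match@shared
  if (d < 0L)
    stop("universe size N = ", N, " is too small: the union of the two ",
         "catalogs has ", match@n1 + match@n2 - match@shared,
         " sites; supply a larger N")
  new("ContingencyTable", a = match@shared, b = match@n1 - match@shared,
      c = match@n2 - match@shared, d = d, N = N)
}

# log right tail P(X >= a) of Hypergeometric(N, K = n1, draws = n2),
# vectorized over a; lchoose + logsumexp so p ~ 1e-44 stays exact in log space
.hyperTailLog <- function(a, n1, n2, N) {
  stopifnot(n1 >= 0, n2 >= 0, N >= n1, N >= n2)
  kmin <- max(0L, n1 + n2 - N)
  kmax <- min(n1, n2)
  k <- kmin:kmax
  logpmf <- lchoose(n1, k) + lchoose(N - n1, n2 - k) - lchoose(N, n2)
  # running logsumexp from the top of the support downwards
  tails <- numeric(length(k))
  acc <- -Inf
  for (i in rev(seq_along(k))) {
    acc <- .logsumexp(c(acc, logpmf[i]))
    tails[i] <- acc
  }
  tails <- pmin(tails, 0)
  vapply(a, function(ai) {
    if (ai <= kmin) return(0)
    if (ai > kmax) return(-Inf)
    tails[match(ai, k)]
  }, numeric(1))
}

#' One-sided Fisher exact test for excess sharing
#'
#' Right-tail test of whether the two tumors share more mutations than
#' expected by chance given their per-tumor counts and the universe:
#' \code{p = P(X >= a)} with \code{X ~ Hypergeometric(N, n1, n2)}. The tail is
#' accumulated in log space, so p values far below double-precision
#' denormals away from 1 (e.g. 1e-44) are exact.
#'
#' @param table a [ContingencyTable-class], or a 2x2 matrix
#'   \code{rbind(c(a, b), c(c, d))}.
#' @param log return the natural-log p value.
#' @return the p value (or its log).
#' @examples
#' fisherExactOneSided(rbind(c(1, 0), c(0, 1)))  # 0.5
#' @export
fisherExactOneSided <- function(table, log = FALSE) {
  if (is.matrix(table)) {
    stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0))
    table <- new("ContingencyTable", a = as.integer(table[1, 1]),
                 b = as.integer(table[1, 2]), c = as.integer(table[2, 1]),
                 d = as.integer(table[2, 2]), N = as.integer(sum(table)))
  }
  stopifnot(is(table, "ContingencyTable"))
  lp <- .hyperTailLog(table@a, n1 = table@a + table@b, n2 = table@a + table@c,
                      N = table@N)
  if (log) lp else exp(lp)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (monotone in rank, capped at 1, stable
#' against input order), with input validation.
#'
#' @param pvalues numeric vector of p values in \code{[0, 1]}.
#' @return adjusted values in input order.
#' @examples
#' bhAdjust(c(0.46, 0.05, 0.99, 0.56, 8.80e-44, 7.36e-29))
#' @export
bhAdjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p values must lie in [0, 1] and contain no NA")
  stats::p.adjust(pvalues, method = "BH")
}

#' Concordance fractions of a match
#'
#' \code{fMin = shared / min(n1, n2)} and
#' \code{fUnion = shared / (n1 + n2 - shared)}.
#'
#' @param match a [MatchResult-class].
#' @return list with \code{fMin} and \code{fUnion}; both \code{NA} (with a
#'   warning) when either tumor has no mutations.
#' @export
concordanceFraction <- function(match) {
  stopifnot(is(match, "MatchResult"))
  if (match@n1 == 0L || match@n2 == 0L) {
    warning("a tumor has zero mutations; concordance fractions undefined")
    return(list(fMin = NA_real_, fUnion = NA_real_))
  }
  list(fMin = match@shared / min(match@n1, match@n2),
       fUnion = match@shared / (match@n1 + match@n2 - match@shared))
}

#' Per-patient concordance report
#'
#' Runs [matchMutations()], [buildContingency()], [fisherExactOneSided()] for
#' every pair, then [bhAdjust()] across patients — the mutation-concordance
#' arm of the clonality analysis.
#'
#' @param pairs named list; each element either a [simulatePair()] result or
#'   a list with \code{catalog1}, \code{catalog2}.
#' @param universeSize the universe N for the 2x2 fourth cell; \code{NULL}
#'   (default) uses the superset reconstruction: the size of the union of all
#'   variant keys across all catalogs in \code{pairs}.
#' @return \code{data.frame} with columns \code{patientId, n1, n2, shared, p,
#'   q, fMin, fUnion}.
#' @export
concordanceReport <- function(pairs, universeSize = NULL) {
  if (length(pairs) == 0L)
    return(data.frame(patientId = character(), n1 = integer(),
                      n2 = integer(), shared = integer(), p = numeric(),
                      q = numeric(), fMin = numeric(), fUnion = numeric()))
  if (is.null(universeSize)) {
    allKeys <- unique(unlist(lapply(pairs, function(pr)
      c(variantKey(pr$catalog1), variantKey(pr$catalog2)))))
    universeSize <- length(allKeys)
  }
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    m <- matchMutations(pr$catalog1, pr$catalog2)
    p <- fisherExactOneSided(buildContingency(m, universeSize))
    fr <- concordanceFraction(m)
    data.frame(patientId = names(pairs)[i] %||% patientId(pr$catalog1),
               n1 = m@n1, n2 = m@n2, shared = m@shared, p = p,
               fMin = fr$fMin, fUnion = fr$fUnion, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bhAdjust(out$p)
  out[, c("patientId", "n1", "n2", "shared", "p", "q", "fMin", "fUnion")]
}
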