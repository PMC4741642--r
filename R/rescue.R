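# Superset rescue: every candidate SNV seen anywhere in a patient is
# re-examined in each of the patient's tumors with an exact binomial test
# against the background sequencing error rate; sites passing BH FDR control
# are called, recovering variants the caller under-sampled.

#' RecoveryParams: rescue thresholds
#'
#' @slot errorRate background sequencing error rate e (default 0.01).
#' @slot fdrThreshold BH q-value calling threshold (default 0.10).
#' @slot alpha nominal per-test binomial level retained for provenance
#'   (default 0.05); the operative rule is the FDR threshold.
#' @export
setClass("RecoveryParams",
         representation(errorRate = "numeric", fdrThreshold = "numeric",
                        alpha = "numeric"))

setValidity("RecoveryParams", function(object) {
  if (object@errorRate <= 0 || object@errorRate >= 1)
    return("errorRate must lie in (0, 1)")
  if (object@fdrThreshold <= 0 || object@fdrThreshold >= 1)
    return("fdrThreshold must lie in (0, 1)")
  TRUE
})

#' @rdname RecoveryParams-class
#' @param errorRate,fdrThreshold,alpha see slots.
#' @return a validated \code{RecoveryParams}.
#' @export
recoveryParams <- function(errorRate = 0.01, fdrThreshold = 0.10,
                           alpha = 0.05) {
  new("RecoveryParams", errorRate = errorRate, fdrThreshold = fdrThreshold,
      alpha = alpha)
}

#' Exact binomial rescue p value
#'
#' \code{p = P(X >= altReads)} with \code{X ~ Binomial(depth, e)}: the
#' probability that sequencing error alone produces at least the observed
#' alt-allele support. Vectorized; \code{altReads = 0} gives 1, and
#' \code{depth = 0} gives 1 with a warning.
#'
#' @param altReads,depth observed alt-supporting reads and total depth.
#' @param e background error rate toward the specific alt allele. By the
#'   package's convention e is the total error probability toward that allele;
#'   set \code{perAllele = TRUE} to divide by 3.
#' @param perAllele divide \code{e} by 3 (errors spread over three alternate
#'   bases).
#' @return p values.
#' @export
binomialRescueP <- function(altReads, depth, e = 0.01, perAllele = FALSE) {
  stopifnot(all(altReads >= 0, na.rm = TRUE),
            all(depth >= altReads, na.rm = TRUE), e > 0, e < 1)
  if (perAllele) e <- e / 3
  if (any(depth == 0, na.rm = TRUE))
    warning("depth of 0 at some site(s); p set to 1 there")
  p <- stats::pbinom(altReads - 1, size = depth, prob = e, lower.tail = FALSE)
  p[!is.na(depth) & depth == 0] <- 1
  p[!is.na(altReads) & altReads == 0] <- 1
  p
}

#' Build the patient-level SNV superset
#'
#' Concatenates all variants detected in any of the patient's tumors into one
#' candidate list and attaches each tumor's read counts at every candidate
#' site. Sites already called in a tumor are marked called there
#' unconditionally; sites without counts in a tumor are flagged unevaluable
#' there.
#'
#' @param catalogs list of two or more [MutationCatalog-class] objects of one
#'   patient.
#' @param counts optional \code{data.frame} of per-site read counts with
#'   columns \code{chrom, pos, ref, alt, altReads<i>, depth<i>} for tumor i
#'   (as emitted by [simulatePair()]); catalogs' own counts are used where the
#'   table has none.
#' @return \code{data.frame} with one row per superset site: the variant key
#'   columns plus, per tumor i, \code{altReads<i>}, \code{depth<i>},
#'   \code{called<i>}, \code{evaluable<i>}.
#' @export
buildSuperset <- function(catalogs, counts = NULL) {
  stopifnot(length(catalogs) >= 2L,
            all(vapply(catalogs, is, logical(1), "MutationCatalog")))
  pids <- unique(stats::na.omit(vapply(catalogs, patientId, character(1))))
  if (length(pids) > 1L)
    stop("catalogs belong to different patients: ",
         paste(pids, collapse = ", "))
  keyTabs <- lapply(catalogs, function(cat) mutations(cat))
  allKeys <- unique(unlist(lapply(keyTabs, variantKey)))
  first <- do.call(rbind, keyTabs)
  first <- first[match(allKeys, variantKey(first)),
                 c("chrom", "pos", "ref", "alt", "context", "gene", "effect")]
  rownames(first) <- NULL
  out <- first
  countKeys <- if (!is.null(counts)) variantKey(counts) else character(0)
  for (i in seq_along(catalogs)) {
    df <- keyTabs[[i]]
    m <- match(allKeys, variantKey(df))
    alt <- df$altReads[m]
    dep <- df$depth[m]
    if (!is.null(counts)) {
      cm <- match(allKeys, countKeys)
      altCol <- counts[[paste0("altReads", i)]]
      depCol <- counts[[paste0("depth", i)]]
      if (!is.null(altCol)) {
        use <- is.na(alt) & !is.na(cm)
        alt[use] <- altCol[cm[use]]
        dep[use] <- depCol[cm[use]]
      }
    }
    out[[paste0("altReads", i)]] <- as.integer(alt)
    out[[paste0("depth", i)]] <- as.integer(dep)
    out[[paste0("called", i)]] <- !is.na(m)
    out[[paste0("evaluable", i)]] <- !is.na(dep)
  }
  out
}

#' Rescue under-sampled SNVs from the superset
#'
#' For every (site, tumor) combination not already called but evaluable, the
#' exact binomial p value against the error rate is computed; BH adjustment is
#' applied across all such tests jointly, and tests with \code{q <
#' fdrThreshold} are called. Returns the augmented catalogs and an audit
#' trail. Rescue is monotone in the threshold: raising \code{fdrThreshold}
#' never un-rescues a site.
#'
#' @param catalogs list of the patient's [MutationCatalog-class] objects.
#' @param counts optional counts table (see [buildSuperset()]).
#' @param params a [RecoveryParams-class].
#' @return list with \code{catalogs} (augmented), \code{audit}
#'   (\code{data.frame} of all evaluated tests: key, tumor, reads, p, q,
#'   rescued) and \code{superset}.
#' @export
rescueSnvs <- function(catalogs, counts = NULL, params = recoveryParams()) {
  stopifnot(is(params, "RecoveryParams"))
  superset <- buildSuperset(catalogs, counts)
  keys <- variantKey(superset)
  tests <- do.call(rbind, lapply(seq_along(catalogs), function(i) {
    eligible <- !superset[[paste0("called", i)]] &
      superset[[paste0("evaluable", i)]]
    if (!any(eligible)) return(NULL)
    data.frame(row = which(eligible), tumor = i,
               altReads = superset[[paste0("altReads", i)]][eligible],
               depth = superset[[paste0("depth", i)]][eligible],
               stringsAsFactors = FALSE)
  }))
  if (is.null(tests) || nrow(tests) == 0L) {
    return(list(catalogs = catalogs,
                audit = data.frame(key = character(), tumor = integer(),
                                   altReads = integer(), depth = integer(),
                                   p = numeric(), q = numeric(),
                                   rescued = logical()),
                superset = superset))
  }
  tests$p <- binomialRescueP(tests$altReads, tests$depth,
                             e = params@errorRate)
  tests$q <- bhAdjust(tests$p)
  tests$rescued <- tests$q < params@fdrThreshold
  augmented <- catalogs
  for (i in seq_along(catalogs)) {
    hit <- tests[tests$tumor == i & tests$rescued, , drop = FALSE]
    if (nrow(hit) == 0L) next
    add <- superset[hit$row, c("chrom", "pos", "ref", "alt", "context",
                               "gene", "effect"), drop = FALSE]
    add$altReads <- hit$altReads
    add$depth <- hit$depth
    augmented[[i]] <- MutationCatalog(
      sampleId(catalogs[[i]]),
      rbind(mutations(catalogs[[i]]), .coerceMutations(add)),
      patientId = patientId(catalogs[[i]]),
      tumorIndex = tumorIndex(catalogs[[i]]))
  }
  audit <- data.frame(key = keys[tests$row], tumor = tests$tumor,
                      altReads = tests$altReads, depth = tests$depth,
                      p = tests$p, q = tests$q, rescued = tests$rescued,
                      stringsAsFactors = FALSE)
  list(catalogs = augmented, audit = audit, superset = superset)
}
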