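#' MutationCatalog: somatic mutations of one tumor sample
#'
#' Holds the validated somatic-variant catalog of a single tumor: one row per
#' variant with genomic key (\code{chrom}, \code{pos}, \code{ref}, \code{alt}),
#' optional reference-strand trinucleotide \code{context}, \code{gene} symbol,
#' functional \code{effect} class, and read support (\code{altReads},
#' \code{depth}). Variant keys are unique within a catalog; indels are accepted
#' but are ignored by SNV-only summaries (spectra, Ti/Tv).
#'
#' @slot sampleId sample identifier, conventionally \code{"<patient>-<1|2>"}.
#' @slot patientId patient identifier (may be \code{NA}).
#' @slot tumorIndex 1 or 2, the tumor's index within the patient (may be
#'   \code{NA}).
#' @slot mutations \code{data.frame} with the canonical mutation columns.
#'
#' @seealso [readMutations()], [matchMutations()], [buildSpectrum()]
#' @export
setClass("MutationCatalog",
         representation(sampleId = "character", patientId = "character",
                        tumorIndex = "integer", mutations = "data.frame"))

setValidity("MutationCatalog", function(object) {
  df <- object@mutations
  missing <- setdiff(.MUTATION_COLS, names(df))
  if (length(missing))
    return(sprintf("mutation table lacks columns: %s",
                   paste(missing, collapse = ", ")))
  if (length(object@sampleId) != 1L) return("sampleId must be length 1")
  ti <- object@tumorIndex
  if (length(ti) != 1L || (!is.na(ti) && !ti %in% c(1L, 2L)))
    return("tumorIndex must be 1, 2 or NA")
  probs <- .mutationProblems(df)
  if (any(nzchar(probs)))
    return(sprintf("invalid mutation rows: %s",
                   paste(sprintf("row %d (%s)", which(nzchar(probs)),
                                 probs[nzchar(probs)]), collapse = "; ")))
  if (anyDuplicated(variantKey(df)))
    return("duplicate variant keys (chrom,pos,ref,alt) in catalog")
  TRUE
})

#' Construct a MutationCatalog
#'
#' @param sampleId sample identifier.
#' @param mutations \code{data.frame} with at least \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}; optional \code{context}, \code{gene},
#'   \code{effect}, \code{altReads}, \code{depth}.
#' @param patientId,tumorIndex optional provenance.
#' @return a [MutationCatalog-class] object.
#' @examples
#' MutationCatalog("S1", data.frame(chrom = "1", pos = 100, ref = "C", alt = "T"))
#' @export
MutationCatalog <- function(sampleId, mutations = NULL,
                            patientId = NA_character_,
                            tumorIndex = NA_integer_) {
  if (is.null(mutations)) mutations <- .emptyMutations()
  df <- .coerceMutations(mutations)
  if (nrow(df)) {
    o <- order(.chromRank(df$chrom), df$pos, df$ref, df$alt)
    df <- df[o, , drop = FALSE]
    rownames(df) <- NULL
  }
  new("MutationCatalog", sampleId = as.character(sampleId),
      patientId = as.character(patientId),
      tumorIndex = as.integer(tumorIndex), mutations = df)
}

#' @rdname accessors
#' @export
setMethod("sampleId", "MutationCatalog", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("patientId", "MutationCatalog", function(x) x@patientId)
#' @rdname accessors
#' @export
setMethod("tumorIndex", "MutationCatalog", function(x) x@tumorIndex)
#' @rdname accessors
#' @export
setMethod("mutations", "MutationCatalog", function(x) x@mutations)

#' @describeIn MutationCatalog number of mutations in the catalog.
#' @param x a \code{MutationCatalog}.
#' @export
setMethod("length", "MutationCatalog", function(x) nrow(x@mutations))

#' @rdname accessors
#' @export
setMethod("vaf", "MutationCatalog", function(x) {
  df <- x@mutations
  ifelse(!is.na(df$depth) & df$depth > 0L, df$altReads / df$depth, NA_real_)
})

setMethod("show", "MutationCatalog", function(object) {
  df <- object@mutations
  nSnv <- sum(.isSnv(df$ref, df$alt))
  cat(sprintf("MutationCatalog '%s' (patient %s, tumor %s)\n",
              object@sampleId, object@patientId, object@tumorIndex))
  cat(sprintf("  %d mutations (%d SNVs, %d indels/other)\n",
              nrow(df), nSnv, nrow(df) - nSnv))
})

#' CopyNumberProfile: probe-level log2 ratios of one sample
#'
#' An ordered probe-level aCGH-like profile: per probe the chromosome, 1-based
#' position and log2 tumor/normal ratio. Probes are sorted by (chrom, pos) and
#' unique.
#'
#' @slot sampleId sample identifier.
#' @slot probes \code{data.frame} with columns \code{chrom}, \code{pos},
#'   \code{log2ratio}.
#' @seealso [readProbeProfile()], [dlrs()], [detectAberrations()]
#' @export
setClass("CopyNumberProfile",
         representation(sampleId = "character", probes = "data.frame"))

setValidity("CopyNumberProfile", function(object) {
  df <- object@probes
  need <- c("chrom", "pos", "log2ratio")
  if (!all(need %in% names(df)))
    return(sprintf("probes must have columns %s", paste(need, collapse = ", ")))
  if (nrow(df)) {
    if (any(is.na(df$pos)) || any(df$pos < 1L)) return("probe pos must be >= 1")
    if (any(!is.finite(df$log2ratio))) return("log2ratio must be finite")
    o <- order(.chromRank(df$chrom), df$pos)
    if (!identical(o, seq_len(nrow(df)))) return("probes must be sorted by (chrom, pos)")
    if (anyDuplicated(paste(df$chrom, df$pos))) return("duplicate (chrom, pos) probes")
  }
  TRUE
})

#' Construct a CopyNumberProfile
#'
#' Probes are sorted by (chrom, pos); duplicated positions are an error.
#'
#' @param sampleId sample identifier.
#' @param probes \code{data.frame} with \code{chrom}, \code{pos},
#'   \code{log2ratio}.
#' @return a [CopyNumberProfile-class].
#' @export
CopyNumberProfile <- function(sampleId, probes) {
  df <- data.frame(chrom = normalizeChrom(probes$chrom),
                   pos = as.integer(probes$pos),
                   log2ratio = as.numeric(probes$log2ratio),
                   stringsAsFactors = FALSE)
  o <- order(.chromRank(df$chrom), df$pos)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  if (anyDuplicated(paste(df$chrom, df$pos)))
    stop("duplicate (chrom, pos) probes in profile '", sampleId, "'")
  new("CopyNumberProfile", sampleId = as.character(sampleId), probes = df)
}

#' @rdname accessors
#' @export
setMethod("sampleId", "CopyNumberProfile", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("probes", "CopyNumberProfile", function(x) x@probes)
#' @describeIn CopyNumberProfile number of probes.
#' @param x a \code{CopyNumberProfile}.
#' @export
setMethod("length", "CopyNumberProfile", function(x) nrow(x@probes))

setMethod("show", "CopyNumberProfile", function(object) {
  cat(sprintf("CopyNumberProfile '%s': %d probes on %d chromosomes\n",
              object@sampleId, nrow(object@probes),
              length(unique(object@probes$chrom))))
})

#' Spectrum96: strand-collapsed trinucleotide mutation spectrum
#'
#' Counts of SNVs in the 96 canonical pyrimidine-reference trinucleotide
#' categories (6 substitution classes x 16 flanking-base combinations).
#' \code{skipped} tallies SNVs whose context was absent or ambiguous.
#'
#' @slot sampleId sample identifier.
#' @slot counts named integer vector of length 96 in canonical order.
#' @slot skipped number of SNVs excluded for missing/ambiguous context.
#' @seealso [buildSpectrum()], [spectrumCategories()]
#' @export
setClass("Spectrum96",
         representation(sampleId = "character", counts = "integer",
                        skipped = "integer"))

setValidity("Spectrum96", function(object) {
  if (length(object@counts) != 96L) return("counts must have length 96")
  if (!identical(names(object@counts), spectrumCategories()))
    return("counts must be named by the 96 canonical categories, in order")
  if (any(object@counts < 0L)) return("counts must be non-negative")
  if (object@skipped < 0L) return("skipped must be non-negative")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("sampleId", "Spectrum96", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("spectrumCounts", "Spectrum96", function(x) x@counts)

setMethod("show", "Spectrum96", function(object) {
  top <- names(sort(object@counts, decreasing = TRUE))[1:3]
  cat(sprintf("Spectrum96 '%s': %d SNVs (%d skipped); top categories: %s\n",
              object@sampleId, sum(object@counts), object@skipped,
              paste(top, collapse = ", ")))
})

#' SpectraMatrix: raw and scaled spectra of several samples
#'
#' Rows are samples, columns the 96 categories. \code{scaled} is derived from
#' \code{raw} by per-sample frequency normalization followed by per-column
#' z-scoring (see [scaleSpectra()]).
#'
#' @slot raw sample x 96 count matrix.
#' @slot scaled matrix of identical shape.
#' @export
setClass("SpectraMatrix",
         representation(raw = "matrix", scaled = "matrix"))

setValidity("SpectraMatrix", function(object) {
  if (ncol(object@raw) != 96L) return("raw must have 96 columns")
  if (!identical(dim(object@raw), dim(object@scaled)))
    return("raw and scaled must have identical dimensions")
  if (is.null(rownames(object@raw))) return("raw must have sample row names")
  TRUE
})

setMethod("show", "SpectraMatrix", function(object) {
  cat(sprintf("SpectraMatrix: %d samples x 96 categories (total %d SNVs)\n",
              nrow(object@raw), sum(object@raw)))
})

#' ClusterResult: hierarchical clustering of mutation spectra
#'
#' @slot tree the \code{hclust} tree.
#' @slot leafOrder integer leaf order of the tree.
#' @slot membership named integer cluster memberships (one cluster index per
#'   sample; \code{cutree} at the number of patients when known).
#' @slot patients named character vector mapping sample id to patient id (may
#'   be empty).
#' @slot adjacency named logical per patient: are the patient's two samples
#'   mutual nearest neighbors under the cophenetic distance of the tree?
#' @export
setClass("ClusterResult",
         representation(tree = "ANY", leafOrder = "integer",
                        membership = "integer", patients = "character",
                        adjacency = "logical"))

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: %d samples", length(object@leafOrder)))
  if (length(object@adjacency))
    cat(sprintf("; %d/%d patient pairs mutually adjacent",
                sum(object@adjacency), length(object@adjacency)))
  cat("\n")
})

#' MatchResult: shared-mutation summary for a tumor pair
#'
#' @slot n1,n2 per-tumor mutation counts.
#' @slot shared number of identical (chrom,pos,ref,alt) keys.
#' @slot sharedKeys the matched keys.
#' @seealso [matchMutations()]
#' @export
setClass("MatchResult",
         representation(n1 = "integer", n2 = "integer", shared = "integer",
                        sharedKeys = "character"))

setValidity("MatchResult", function(object) {
  if (object@shared != length(object@sharedKeys))
    return("shared must equal length(sharedKeys)")
  if (object@shared > min(object@n1, object@n2))
    return("shared cannot exceed min(n1, n2)")
  TRUE
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult: n1 = %d, n2 = %d, shared = %d\n",
              object@n1, object@n2, object@shared))
})

#' ContingencyTable: 2x2 embedding of a tumor-pair match
#'
#' Cells: \code{a} shared mutations, \code{b} tumor-1-specific, \code{c}
#' tumor-2-specific, \code{d} universe sites mutated in neither tumor;
#' \code{a + b + c + d = N}.
#'
#' @slot a,b,c,d non-negative integer cells.
#' @slot N universe size.
#' @seealso [buildContingency()], [fisherExactOneSided()]
#' @export
setClass("ContingencyTable",
         representation(a = "integer", b = "integer", c = "integer",
                        d = "integer", N = "integer"))

setValidity("ContingencyTable", function(object) {
  cells <- c(object@a, object@b, object@c, object@d)
  if (any(cells < 0L)) return("all cells must be >= 0")
  if (sum(cells) != object@N) return("cells must sum to N")
  TRUE
})

setMethod("show", "ContingencyTable", function(object) {
  m <- matrix(c(object@a, object@b, object@c, object@d), 2, 2, byrow = TRUE)
  dimnames(m) <- list(c("tumor1 +", "tumor1 -"), c("tumor2 +", "tumor2 -"))
  cat(sprintf("ContingencyTable (N = %d):\n", object@N))
  print(m)
})

#' ArmStateVector: per-arm copy-number states of one sample
#'
#' @slot sampleId sample identifier.
#' @slot states named integer vector over the configured arm list with values
#'   -1 (loss), 0 (normal), +1 (gain).
#' @seealso [armStates()], [lr2Statistic()]
#' @export
setClass("ArmStateVector",
         representation(sampleId = "character", states = "integer"))

setValidity("ArmStateVector", function(object) {
  if (is.null(names(object@states))) return("states must be named by arm")
  if (!all(object@states %in% c(-1L, 0L, 1L)))
    return("states must be -1, 0 or +1")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("sampleId", "ArmStateVector", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("armStatesOf", "ArmStateVector", function(x) x@states)

setMethod("show", "ArmStateVector", function(object) {
  g <- names(object@states)[object@states == 1L]
  l <- names(object@states)[object@states == -1L]
  cat(sprintf("ArmStateVector '%s': %d arms; gains: %s; losses: %s\n",
              object@sampleId, length(object@states),
              if (length(g)) paste(g, collapse = ",") else "none",
              if (length(l)) paste(l, collapse = ",") else "none"))
})

#' MarginalFrequencies: reference arm-state frequencies
#'
#' Per-arm probabilities of loss/normal/gain estimated from a cohort, floored
#' at a small epsilon and renormalized so every observable state has positive
#' probability.
#'
#' @slot freqs arms x 3 matrix with columns \code{"-1"}, \code{"0"},
#'   \code{"+1"}; rows sum to 1.
#' @seealso [estimateMarginals()]
#' @export
setClass("MarginalFrequencies", representation(freqs = "matrix"))

setValidity("MarginalFrequencies", function(object) {
  f <- object@freqs
  if (!identical(colnames(f), c("-1", "0", "+1")))
    return('freqs must have columns "-1", "0", "+1"')
  if (is.null(rownames(f))) return("freqs must have arm row names")
  if (any(f <= 0)) return("all frequencies must be positive (flooring)")
  if (any(abs(rowSums(f) - 1) > 1e-8)) return("rows must sum to 1")
  TRUE
})

setMethod("show", "MarginalFrequencies", function(object) {
  cat(sprintf("MarginalFrequencies over %d arms (mean P(gain) = %.3f, P(loss) = %.3f)\n",
              nrow(object@freqs), mean(object@freqs[, "+1"]),
              mean(object@freqs[, "-1"])))
})

#' ClonalityResult: copy-number clonality likelihood ratio
#'
#' @slot lr2 likelihood ratio \code{max_c L(c) / L(0)}, always \code{>= 1}.
#' @slot cHat maximizing clonality parameter in \code{[0, 1]}.
#' @slot p reference-null p value (\code{NA} until [lr2Pvalue()] is applied).
#' @seealso [lr2Statistic()], [lr2Pvalue()]
#' @export
setClass("ClonalityResult",
         representation(lr2 = "numeric", cHat = "numeric", p = "numeric"))

setValidity("ClonalityResult", function(object) {
  if (object@lr2 < 1) return("lr2 must be >= 1")
  if (object@cHat < 0 || object@cHat > 1) return("cHat must lie in [0, 1]")
  if (!is.na(object@p) && (object@p <= 0 || object@p > 1))
    return("p must lie in (0, 1]")
  TRUE
})

setMethod("show", "ClonalityResult", function(object) {
  cat(sprintf("ClonalityResult: LR2 = %.4g, c_hat = %.3f, p = %s\n",
              object@lr2, object@cHat,
              if (is.na(object@p)) "NA" else format(object@p, digits = 3)))
})

#' TumorPairTruth: ground truth of one simulated pair
#'
#' @slot patientId patient identifier.
#' @slot isClonal whether the pair was generated under the clonal model.
#' @slot sharedKeys realized shared variant keys (for independent pairs these
#'   arise only by chance collisions within the universe).
#' @slot droppedKeys shared variants whose call was suppressed in tumor 2
#'   (caller-miss planting for rescue experiments); reads are still emitted.
#' @slot sharedArms arms whose aberration was planted as a shared clonal event.
#' @slot armStates1,armStates2 true per-arm states of the two tumors.
#' @export
setClass("TumorPairTruth",
         representation(patientId = "character", isClonal = "logical",
                        sharedKeys = "character", droppedKeys = "character",
                        sharedArms = "character", armStates1 = "integer",
                        armStates2 = "integer"))

setMethod("show", "TumorPairTruth", function(object) {
  cat(sprintf("TumorPairTruth '%s': %s; %d shared mutations (%d dropped), %d shared arm events\n",
              object@patientId,
              if (object@isClonal) "clonal" else "independent",
              length(object@sharedKeys), length(object@droppedKeys),
              length(object@sharedArms)))
})
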