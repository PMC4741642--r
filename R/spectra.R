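# 96-context mutational spectra: strand collapse, spectrum construction,
# scaling, hierarchical clustering, and the descriptive statistics reported
# alongside them (Ti/Tv, nonsynonymous:synonymous right-tail test).

.SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

.spectrumCategoriesBuild <- function() {
  out <- character(0)
  for (cls in .SUBSTITUTION_CLASSES) {
    ref <- substr(cls, 1L, 1L)
    for (f5 in .BASES) for (f3 in .BASES)
      out <- c(out, sprintf("%s[%s]%s", f5, cls, f3))
  }
  out
}

.SPECTRUM_CATEGORIES <- .spectrumCategoriesBuild()

#' Canonical 96 spectrum categories
#'
#' The canonical order of the strand-collapsed trinucleotide categories:
#' substitution class major (\code{C>A}, \code{C>G}, \code{C>T}, \code{T>A},
#' \code{T>C}, \code{T>G}), then 5' flank, then 3' flank, e.g.
#' \code{"A[C>T]G"}.
#'
#' @return character vector of length 96.
#' @export
spectrumCategories <- function() .SPECTRUM_CATEGORIES

#' Collapse an SNV to its strand-collapsed 96-context category
#'
#' SNVs with a purine reference (A or G) are mapped to the reverse-complement
#' strand so every category has a pyrimidine (C or T) reference. Vectorized.
#'
#' @param context 3-mer reference-strand context; middle base must equal
#'   \code{ref}.
#' @param ref,alt single reference/alternate bases, \code{ref != alt}.
#' @return character vector of categories (e.g. \code{"A[C>T]A"}); \code{NA}
#'   where the context or alleles contain ambiguous bases (such SNVs are
#'   excluded from spectra and counted as skipped).
#' @examples
#' collapseContext("ACA", "C", "T")  # "A[C>T]A"
#' collapseContext("TGT", "G", "A")  # same category, opposite strand
#' @export
collapseContext <- function(context, ref, alt) {
  context <- toupper(as.character(context))
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  n <- max(length(context), length(ref), length(alt))
  context <- rep_len(context, n); ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  ok <- !is.na(context) & !is.na(ref) & !is.na(alt) &
    nchar(context) == 3L & ref %in% .BASES & alt %in% .BASES & ref != alt &
    substr(context, 2L, 2L) == ref &
    !grepl("[^ACGT]", context)
  out <- rep(NA_character_, n)
  if (!any(ok)) return(out)
  ctx <- context[ok]; r <- ref[ok]; a <- alt[ok]
  purine <- r %in% c("A", "G")
  ctx[purine] <- .revcomp(ctx[purine])
  r[purine] <- .complement(r[purine])
  a[purine] <- .complement(a[purine])
  out[ok] <- sprintf("%s[%s>%s]%s", substr(ctx, 1L, 1L), r, a,
                     substr(ctx, 3L, 3L))
  out
}

#' Build the 96-context spectrum of a catalog
#'
#' Uses only single-nucleotide variants that carry a usable 3-mer context;
#' everything else (indels, missing or ambiguous context) is tallied in the
#' \code{skipped} slot so that \code{sum(counts) + skipped} equals the
#' catalog's SNV-plus-context-less count.
#'
#' @param catalog a [MutationCatalog-class].
#' @return a [Spectrum96-class].
#' @export
buildSpectrum <- function(catalog) {
  stopifnot(is(catalog, "MutationCatalog"))
  df <- mutations(catalog)
  snv <- df[.isSnv(df$ref, df$alt), , drop = FALSE]
  cat96 <- collapseContext(snv$context, snv$ref, snv$alt)
  skipped <- sum(is.na(cat96))
  counts <- table(factor(cat96[!is.na(cat96)], levels = .SPECTRUM_CATEGORIES))
  counts <- stats::setNames(as.integer(counts), .SPECTRUM_CATEGORIES)
  if (sum(counts) == 0L)
    warning("catalog '", sampleId(catalog), "' has no SNVs with usable context; ",
            "spectrum is all zero")
  new("Spectrum96", sampleId = sampleId(catalog), counts = counts,
      skipped = as.integer(skipped))
}

#' Assemble spectra of several catalogs into a matrix
#'
#' @param catalogs list of [MutationCatalog-class] objects (or of
#'   [Spectrum96-class] objects).
#' @return a [SpectraMatrix-class] with raw counts and the scaled matrix from
#'   [scaleSpectra()].
#' @export
spectraMatrix <- function(catalogs) {
  specs <- lapply(catalogs, function(x)
    if (is(x, "Spectrum96")) x else buildSpectrum(x))
  raw <- do.call(rbind, lapply(specs, spectrumCounts))
  rownames(raw) <- vapply(specs, sampleId, character(1))
  colnames(raw) <- .SPECTRUM_CATEGORIES
  new("SpectraMatrix", raw = raw, scaled = scaleSpectra(raw))
}

#' Scale a spectra count matrix
#'
#' Each row (sample) is first converted to frequencies so that heterogeneous
#' mutation loads become comparable; each of the 96 columns is then
#' standardized to mean zero and unit variance across samples. Zero-variance
#' columns are left at zero. With a single sample only the frequency step is
#' applied (with a warning), since column standardization is undefined.
#'
#' @param raw sample x 96 count matrix.
#' @return matrix of identical shape.
#' @export
scaleSpectra <- function(raw) {
  if (is(raw, "SpectraMatrix")) raw <- raw@raw
  stopifnot(is.matrix(raw), ncol(raw) == 96L)
  tot <- rowSums(raw)
  freq <- raw / ifelse(tot > 0, tot, 1)
  if (nrow(raw) < 2L) {
    warning("fewer than 2 samples: returning per-sample frequencies without ",
            "column standardization")
    return(freq)
  }
  mu <- colMeans(freq)
  sdv <- apply(freq, 2L, stats::sd)
  scaled <- sweep(freq, 2L, mu, "-")
  pos <- sdv > 0
  scaled[, pos] <- sweep(scaled[, pos, drop = FALSE], 2L, sdv[pos], "/")
  scaled[, !pos] <- 0
  scaled
}

#' Hierarchically cluster samples on their scaled spectra
#'
#' @param x a [SpectraMatrix-class] (its scaled slot is used) or a numeric
#'   matrix of samples x features.
#' @param linkage one of \code{"average"}, \code{"complete"}, \code{"ward"}.
#' @param metric \code{"correlation"} (\code{1 - Pearson r} between scaled
#'   rows; the default, matching the field's practice of comparing spectra by
#'   cosine-type similarity) or \code{"euclidean"}.
#' @param patients optional named character vector mapping sample id to
#'   patient id; when given, the per-patient mutual-nearest-neighbor adjacency
#'   (under the cophenetic distance of the tree) is computed and cluster
#'   membership is cut at the number of patients.
#' @return a [ClusterResult-class].
#' @export
hierarchicalCluster <- function(x, linkage = c("average", "complete", "ward"),
                                metric = c("correlation", "euclidean"),
                                patients = NULL) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  m <- if (is(x, "SpectraMatrix")) x@scaled else as.matrix(x)
  if (nrow(m) < 2L) stop("need at least 2 samples to cluster")
  if (anyNA(m) || any(!is.finite(m))) stop("matrix contains NA/NaN values")
  d <- switch(metric,
              euclidean = stats::dist(m),
              correlation = stats::as.dist(1 - stats::cor(t(m))))
  method <- if (linkage == "ward") "ward.D2" else linkage
  tree <- stats::hclust(d, method = method)
  membership <- integer(0)
  adjacency <- logical(0)
  pats <- character(0)
  if (!is.null(patients)) {
    stopifnot(!is.null(names(patients)), all(rownames(m) %in% names(patients)))
    pats <- patients[rownames(m)]
    k <- length(unique(pats))
    membership <- stats::cutree(tree, k = max(1L, min(k, nrow(m))))
    coph <- as.matrix(stats::cophenetic(tree))
    diag(coph) <- Inf
    nn <- rownames(m)[apply(coph, 1L, which.min)]
    names(nn) <- rownames(m)
    adjacency <- vapply(split(rownames(m), pats), function(ids) {
      length(ids) == 2L && nn[[ids[1]]] == ids[2] && nn[[ids[2]]] == ids[1]
    }, logical(1))
  }
  new("ClusterResult", tree = tree, leafOrder = as.integer(tree$order),
      membership = membership, patients = as.character(pats),
      adjacency = adjacency)
}

#' Write a clustering tree as Newick
#'
#' @param cluster a [ClusterResult-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeNewick <- function(cluster, path) {
  stopifnot(is(cluster, "ClusterResult"))
  ape::write.tree(ape::as.phylo(cluster@tree), file = path)
  invisible(path)
}

#' Transition:transversion ratio of a catalog
#'
#' Transitions are \code{A<->G} and \code{C<->T}; everything else among SNVs
#' is a transversion. Indels are ignored.
#'
#' @param catalog a [MutationCatalog-class].
#' @return the ratio; \code{Inf} when there are transversion-free SNVs, and
#'   \code{NaN} for a catalog without SNVs.
#' @export
titvRatio <- function(catalog) {
  df <- mutations(catalog)
  snv <- df[.isSnv(df$ref, df$alt), , drop = FALSE]
  if (nrow(snv) == 0L) return(NaN)
  pair <- paste0(snv$ref, snv$alt)
  ti <- sum(pair %in% c("AG", "GA", "CT", "TC"))
  tv <- nrow(snv) - ti
  if (tv == 0L) return(Inf)
  ti / tv
}

#' Right-tail test of the nonsynonymous:synonymous ratio
#'
#' Tests whether the observed number of nonsynonymous coding mutations exceeds
#' the count expected by chance: with \code{n = nNonsyn + nSyn} coding point
#' mutations and expected nonsynonymous proportion \code{p0}, the p value is
#' the exact binomial right tail \code{P(X >= nNonsyn)},
#' \code{X ~ Binomial(n, p0)}.
#'
#' @param nNonsyn,nSyn non-negative counts.
#' @param p0 expected nonsynonymous proportion under no selection; the default
#'   0.715 approximates the genome-wide nonsynonymous fraction under uniform
#'   substitution.
#' @return list with \code{ratio} (\code{NA} when \code{nSyn == 0}) and
#'   \code{p}.
#' @examples
#' nsSynTest(493, 212)$ratio  # 2.325...
#' @export
nsSynTest <- function(nNonsyn, nSyn, p0 = 0.715) {
  stopifnot(nNonsyn >= 0, nSyn >= 0, p0 > 0, p0 < 1)
  n <- nNonsyn + nSyn
  ratio <- if (nSyn > 0) nNonsyn / nSyn else NA_real_
  p <- if (nNonsyn == 0) 1 else
    stats::pbinom(nNonsyn - 1, size = n, prob = p0, lower.tail = FALSE)
  list(ratio = ratio, p = p)
}
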