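# Readers/writers for the formats the pipeline touches: VCF 4.x and MAF-like
# TSV for mutation catalogs, plain TSV for probe-level log ratios, SEG for
# segments. All coordinates are 1-based inclusive at the file interface.

.MAF_HEADER <- c("sample_id", "patient_id", "tumor_index", "chrom", "pos",
                 "ref", "alt", "context", "gene", "effect", "alt_reads",
                 "depth")

.guessFormat <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "maf_tsv"
}

# drop invalid rows with a warning naming their (file) line numbers; duplicate
# keys are a hard error
.validateRows <- function(df, lineNumbers, what) {
  probs <- .mutationProblems(df)
  bad <- nzchar(probs)
  if (any(bad)) {
    warning(sprintf("%s: rejected %d record(s) failing validation: %s", what,
                    sum(bad),
                    paste(sprintf("line %d (%s)", lineNumbers[bad], probs[bad]),
                          collapse = "; ")), call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  dup <- duplicated(variantKey(df))
  if (any(dup))
    stop(sprintf("%s: duplicate variant key(s): %s", what,
                 paste(unique(variantKey(df)[dup]), collapse = ", ")))
  df
}

#' Read a somatic mutation catalog
#'
#' Supports VCF 4.x (read counts taken from the \code{AD}/\code{DP} FORMAT
#' fields; \code{CTX}, \code{GENE}, \code{EFF} INFO keys carry context, gene
#' and effect class) and a MAF-like TSV with header columns
#' \code{chrom,pos,ref,alt} plus optional
#' \code{context,gene,effect,alt_reads,depth} and sample provenance columns.
#' Records violating the catalog invariants are rejected with a warning naming
#' their line numbers; duplicate variant keys are an error.
#'
#' @param path input file.
#' @param format \code{"auto"} (by extension), \code{"vcf"} or
#'   \code{"maf_tsv"}.
#' @param sampleId,patientId,tumorIndex override provenance when the file does
#'   not carry it.
#' @return a [MutationCatalog-class].
#' @seealso [writeMutations()]
#' @export
readMutations <- function(path, format = c("auto", "vcf", "maf_tsv"),
                          sampleId = NULL, patientId = NULL,
                          tumorIndex = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- .guessFormat(path)
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- if (format == "vcf") .readVcfCatalog(path) else .readMafCatalog(path)
  df <- .validateRows(.coerceMutations(parsed$df), parsed$lines,
                      basename(path))
  MutationCatalog(
    sampleId = sampleId %||% parsed$sampleId %||% sub("\\.[^.]*$", "", basename(path)),
    mutations = df,
    patientId = patientId %||% parsed$patientId %||% NA_character_,
    tumorIndex = tumorIndex %||% parsed$tumorIndex %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

.readMafCatalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA", "."),
                          colClasses = "character", check.names = FALSE)
  required <- c("chrom", "pos", "ref", "alt")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("MAF-like TSV lacks required column(s): ",
         paste(missing, collapse = ", "))
  for (col in c("pos", "alt_reads", "depth"))
    if (col %in% names(df)) {
      val <- suppressWarnings(as.numeric(df[[col]]))
      badNum <- !is.na(df[[col]]) & is.na(val)
      if (any(badNum))
        stop(sprintf("non-numeric '%s' at line(s) %s", col,
                     paste(which(badNum) + 1L, collapse = ", ")))
      df[[col]] <- val
    }
  names(df)[names(df) == "alt_reads"] <- "altReads"
  list(df = df, lines = seq_len(nrow(df)) + 1L,
       sampleId = if ("sample_id" %in% names(df) && nrow(df)) df$sample_id[1] else NULL,
       patientId = if ("patient_id" %in% names(df) && nrow(df)) df$patient_id[1] else NULL,
       tumorIndex = if ("tumor_index" %in% names(df) && nrow(df))
         as.integer(df$tumor_index[1]) else NULL)
}

.readVcfCatalog <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  info <- function(key) {
    if (n == 0L) return(character(0))
    m <- regmatches(fix$INFO, regexec(sprintf("(?:^|;)%s=([^;]+)", key),
                                      fix$INFO))
    out <- vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
                  character(1))
    out[out == "."] <- NA_character_
    out
  }
  altReads <- depth <- rep(NA_integer_, n)
  gt <- v@gt
  if (!is.null(gt) && ncol(gt) >= 2L && n > 0L) {
    ad <- vcfR::extract.gt(v, element = "AD")[, 1L]
    dp <- suppressWarnings(as.integer(vcfR::extract.gt(v, element = "DP")[, 1L]))
    adSplit <- strsplit(ad, ",", fixed = TRUE)
    altReads <- vapply(adSplit, function(x)
      if (length(x) >= 2L) suppressWarnings(as.integer(x[2])) else NA_integer_,
      integer(1))
    refReads <- vapply(adSplit, function(x)
      if (length(x) >= 2L) suppressWarnings(as.integer(x[1])) else NA_integer_,
      integer(1))
    depth <- ifelse(!is.na(dp), dp, refReads + altReads)
  }
  df <- data.frame(chrom = fix$CHROM, pos = fix$POS, ref = fix$REF,
                   alt = fix$ALT, context = info("CTX"), gene = info("GENE"),
                   effect = info("EFF"), altReads = altReads, depth = depth,
                   stringsAsFactors = FALSE)
  meta <- v@meta
  sampleLine <- grep("^##SAMPLE=", meta, value = TRUE)
  getAttr <- function(key) {
    if (!length(sampleLine)) return(NULL)
    m <- regmatches(sampleLine[1],
                    regexec(sprintf("%s=([^,>]+)", key), sampleLine[1]))[[1]]
    if (length(m) == 2L) m[2] else NULL
  }
  sid <- getAttr("ID")
  if (is.null(sid) && !is.null(gt) && ncol(gt) >= 2L) sid <- colnames(gt)[2]
  ti <- getAttr("TumorIndex")
  list(df = df, lines = seq_len(n), sampleId = sid,
       patientId = getAttr("Patient"),
       tumorIndex = if (is.null(ti)) NULL else as.integer(ti))
}

#' Write a somatic mutation catalog
#'
#' Emits VCF 4.2 (with \code{AD}/\code{DP} FORMAT fields and \code{CTX},
#' \code{GENE}, \code{EFF} INFO keys) or the MAF-like TSV; both round-trip
#' through [readMutations()] preserving every field, with missing optional
#' fields written as empty/\code{.} tokens.
#'
#' @param catalog a [MutationCatalog-class].
#' @param path output file.
#' @param format \code{"auto"} (by extension), \code{"vcf"} or
#'   \code{"maf_tsv"}.
#' @return the path, invisibly.
#' @export
writeMutations <- function(catalog, path, format = c("auto", "vcf", "maf_tsv")) {
  stopifnot(is(catalog, "MutationCatalog"))
  format <- match.arg(format)
  if (format == "auto") format <- .guessFormat(path)
  if (format == "vcf") .writeVcfCatalog(catalog, path) else
    .writeMafCatalog(catalog, path)
  invisible(path)
}

.writeMafCatalog <- function(catalog, path) {
  df <- mutations(catalog)
  out <- data.frame(sample_id = rep(sampleId(catalog), nrow(df)),
                    patient_id = rep(patientId(catalog), nrow(df)),
                    tumor_index = rep(tumorIndex(catalog), nrow(df)),
                    chrom = df$chrom, pos = df$pos, ref = df$ref,
                    alt = df$alt, context = df$context, gene = df$gene,
                    effect = df$effect, alt_reads = df$altReads,
                    depth = df$depth, stringsAsFactors = FALSE)
  if (nrow(out) == 0L)
    out <- stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(.MAF_HEADER))),
                           .MAF_HEADER)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

.writeVcfCatalog <- function(catalog, path) {
  df <- mutations(catalog)
  tok <- function(x) ifelse(is.na(x), ".", as.character(x))
  info <- sprintf("CTX=%s;GENE=%s;EFF=%s", tok(df$context), tok(df$gene),
                  tok(df$effect))
  hasAd <- !is.na(df$altReads) & !is.na(df$depth)
  ad <- ifelse(hasAd, sprintf("%d,%d", df$depth - df$altReads, df$altReads), ".")
  dp <- tok(df$depth)
  sid <- sampleId(catalog)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##SAMPLE=<ID=%s,Patient=%s,TumorIndex=%s>", sid,
            tok(patientId(catalog)), tok(tumorIndex(catalog))),
    '##INFO=<ID=CTX,Number=1,Type=String,Description="Reference-strand trinucleotide context">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=EFF,Number=1,Type=String,Description="Effect class">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sid), collapse = "\t"))
  body <- if (nrow(df)) sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tAD:DP\t%s:%s",
                                df$chrom, df$pos, df$ref, df$alt, info, ad, dp)
          else character(0)
  writeLines(c(header, body), path)
}

#' Read a probe-level copy-number profile
#'
#' TSV with header columns \code{chrom}, \code{pos}, \code{log2ratio}. Probes
#' are sorted by (chrom, pos) on read; duplicated positions and non-numeric
#' log ratios are errors reporting line numbers.
#'
#' @param path input file.
#' @param sampleId sample identifier (defaults to the file's base name).
#' @return a [CopyNumberProfile-class].
#' @export
readProbeProfile <- function(path, sampleId = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  need <- c("chrom", "pos", "log2ratio")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("probe TSV lacks required column(s): ", paste(missing, collapse = ", "))
  lr <- suppressWarnings(as.numeric(df$log2ratio))
  bad <- is.na(lr)
  if (any(bad))
    stop("non-numeric log2ratio at line(s) ",
         paste(which(bad) + 1L, collapse = ", "))
  CopyNumberProfile(sampleId %||% sub("\\.[^.]*$", "", basename(path)),
                    data.frame(chrom = df$chrom, pos = as.integer(df$pos),
                               log2ratio = lr, stringsAsFactors = FALSE))
}

#' Write a probe-level profile TSV
#'
#' @param profile a [CopyNumberProfile-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeProbeProfile <- function(profile, path) {
  stopifnot(is(profile, "CopyNumberProfile"))
  utils::write.table(probes(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.SEG_COLS <- c("sample", "chrom", "start", "end", "n_probes", "mean_log2")

#' Read called segments (SEG)
#'
#' Tab-separated SEG with columns
#' \code{sample, chrom, start, end, n_probes, mean_log2} and optionally
#' \code{state}; coordinates 1-based inclusive. Segments with \code{end <
#' start} or \code{n_probes < 1} are rejected; overlapping segments on one
#' chromosome of one sample are accepted with a warning. When the \code{state}
#' column is absent it is derived as the sign of \code{mean_log2}.
#'
#' @param path input file.
#' @return \code{data.frame} with columns \code{sampleId, chrom, start, end,
#'   nProbes, meanLog2, state}.
#' @export
readSegments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(.SEG_COLS, names(df))
  if (length(missing))
    stop("SEG file lacks required column(s): ", paste(missing, collapse = ", "))
  out <- data.frame(sampleId = as.character(df$sample),
                    chrom = normalizeChrom(df$chrom),
                    start = as.integer(df$start), end = as.integer(df$end),
                    nProbes = as.integer(df$n_probes),
                    meanLog2 = as.numeric(df$mean_log2),
                    stringsAsFactors = FALSE)
  out$state <- if ("state" %in% names(df)) as.integer(df$state) else
    sign(out$meanLog2)
  bad <- out$end < out$start | out$nProbes < 1L
  if (any(bad))
    stop("invalid segment(s) (end < start or n_probes < 1) at line(s) ",
         paste(which(bad) + 1L, collapse = ", "))
  .warnOverlaps(out)
  o <- order(out$sampleId, .chromRank(out$chrom), out$start)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.warnOverlaps <- function(seg) {
  for (grp in split(seg, paste(seg$sampleId, seg$chrom))) {
    if (nrow(grp) < 2L) next
    grp <- grp[order(grp$start), ]
    if (any(grp$start[-1L] <= grp$end[-nrow(grp)]))
      warning("overlapping segments for sample '", grp$sampleId[1],
              "' on chromosome ", grp$chrom[1], call. = FALSE)
  }
}

#' Write segments as SEG
#'
#' @param segments segment \code{data.frame} as produced by
#'   [detectAberrations()] or [readSegments()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSegments <- function(segments, path) {
  out <- data.frame(sample = segments$sampleId, chrom = segments$chrom,
                    start = segments$start, end = segments$end,
                    n_probes = segments$nProbes, mean_log2 = segments$meanLog2,
                    state = segments$state, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
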