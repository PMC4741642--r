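# Internal helpers shared across modules.

.CHROM_LEVELS <- c(as.character(1:22), "X", "Y")

.EFFECT_LEVELS <- c("synonymous", "nonsynonymous", "stopgain", "stoploss",
                    "splicing", "other", "unknown")

.BASES <- c("A", "C", "G", "T")

#' Normalize chromosome names
#'
#' Strips a leading \code{"chr"} prefix so that \code{"chr1"} and \code{"1"}
#' compare equal everywhere in the package.
#'
#' @param x character vector of chromosome names.
#' @return character vector without the \code{"chr"} prefix.
#' @export
normalizeChrom <- function(x) sub("^chr", "", as.character(x))

# rank used for (chrom, pos) sorting; unknown contigs sort after Y, alphabetically
.chromRank <- function(x) {
  r <- match(x, .CHROM_LEVELS)
  extra <- is.na(r)
  if (any(extra)) {
    lev <- sort(unique(x[extra]))
    r[extra] <- length(.CHROM_LEVELS) + match(x[extra], lev)
  }
  r
}

#' Variant keys
#'
#' Builds the exact-match identifier \code{chrom:pos:ref:alt} used for all
#' mutation matching in the package.
#'
#' @param x a \code{data.frame} with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, or a [MutationCatalog-class].
#' @return character vector of keys.
#' @export
variantKey <- function(x) {
  if (is(x, "MutationCatalog")) x <- mutations(x)
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

# log(sum(exp(x))) without overflow; -Inf for empty input
.logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# vectorized reverse complement of short DNA strings
.revcomp <- function(x) {
  out <- vapply(strsplit(chartr("ACGT", "TGCA", x), ""),
                function(b) paste(rev(b), collapse = ""), character(1))
  out[is.na(x)] <- NA_character_
  out
}

.complement <- function(x) chartr("ACGT", "TGCA", x)

.isSnv <- function(ref, alt) {
  !is.na(ref) & !is.na(alt) & ref %in% .BASES & alt %in% .BASES & ref != alt
}

# canonical column template for a mutation table
.MUTATION_COLS <- c("chrom", "pos", "ref", "alt", "context", "gene", "effect",
                    "altReads", "depth")

.emptyMutations <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), context = character(), gene = character(),
             effect = character(), altReads = integer(), depth = integer(),
             stringsAsFactors = FALSE)
}

# coerce an arbitrary data.frame to the canonical mutation table layout,
# filling absent optional columns with NA
.coerceMutations <- function(df) {
  if (nrow(df) == 0L && ncol(df) == 0L) return(.emptyMutations())
  out <- .emptyMutations()[seq_len(nrow(df)), , drop = FALSE]
  rownames(out) <- NULL
  out$chrom <- normalizeChrom(df$chrom)
  out$pos <- as.integer(df$pos)
  out$ref <- toupper(as.character(df$ref))
  out$alt <- toupper(as.character(df$alt))
  for (col in c("context", "gene", "effect")) {
    if (col %in% names(df)) out[[col]] <- as.character(df[[col]])
  }
  if (!is.null(df$context)) out$context <- toupper(out$context)
  for (col in c("altReads", "depth")) {
    if (col %in% names(df)) out[[col]] <- as.integer(df[[col]])
  }
  out
}

# per-row invariant check; returns a character vector of problems, "" when ok
.mutationProblems <- function(df) {
  n <- nrow(df)
  probs <- character(n)
  add <- function(bad, msg) {
    bad <- which(bad)
    probs[bad] <<- ifelse(nzchar(probs[bad]), paste(probs[bad], msg, sep = "; "),
                          msg)
  }
  add(is.na(df$chrom) | !nzchar(df$chrom), "missing chrom")
  add(is.na(df$pos) | df$pos < 1L, "pos must be a positive integer")
  add(is.na(df$ref) | !nzchar(df$ref), "missing ref")
  add(is.na(df$alt) | !nzchar(df$alt), "missing alt")
  add(!is.na(df$ref) & !is.na(df$alt) & df$ref == df$alt, "ref equals alt")
  ctx <- !is.na(df$context)
  add(ctx & nchar(df$context) != 3L, "context must be a 3-mer")
  snvCtx <- ctx & nchar(df$context) == 3L & !is.na(df$ref) & nchar(df$ref) == 1L
  add(snvCtx & substr(df$context, 2L, 2L) != df$ref,
      "context middle base must equal ref")
  add(!is.na(df$effect) & !(df$effect %in% .EFFECT_LEVELS),
      sprintf("effect must be one of %s", paste(.EFFECT_LEVELS, collapse = ", ")))
  add(!is.na(df$altReads) & df$altReads < 0L, "altReads must be >= 0")
  add(!is.na(df$altReads) & !is.na(df$depth) & df$depth < df$altReads,
      "depth must be >= altReads")
  probs
}

# seeds derived from a master seed stay below 2^31
.deriveSeed <- function(seed, k = 1L) {
  (as.integer(seed) + 7919L * as.integer(k)) %% 2147483611L
}
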