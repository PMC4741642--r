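# shared fixture builders; everything is generated in code

mutRow <- function(chrom, pos, ref, alt, context = NA, gene = NA,
                   effect = NA, altReads = NA, depth = NA) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             context = context, gene = gene, effect = effect,
             altReads = altReads, depth = depth, stringsAsFactors = FALSE)
}

tinyCatalog <- function(sampleId = "S1", patientId = "P1", tumorIndex = 1L) {
  MutationCatalog(sampleId, rbind(
    mutRow("1", 100L, "C", "T", "ACA", "TP53", "nonsynonymous", 40L, 400L),
    mutRow("2", 200L, "G", "A", "TGT", "PIK3CA", "synonymous", 30L, 380L),
    mutRow("X", 300L, "T", "G", "CTG", NA, "unknown", 25L, 410L)),
    patientId = patientId, tumorIndex = tumorIndex)
}

# random valid catalog for round-trip property tests; mixes SNVs, an indel,
# and missing optional fields
randomCatalog <- function(seed, sampleId = paste0("S", seed)) {
  set.seed(seed)
  n <- sample(3:25, 1)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  ctx <- paste0(sample(c("A", "C", "G", "T"), n, TRUE), ref,
                sample(c("A", "C", "G", "T"), n, TRUE))
  ctx[sample(n, ceiling(n / 4))] <- NA
  depth <- sample(100:500, n, TRUE)
  alt_reads <- rbinom(n, depth, 0.3)
  eff <- sample(c("synonymous", "nonsynonymous", NA), n, TRUE)
  df <- mutRow(sample(c(as.character(1:5), "X"), n, TRUE),
               sample(1e6, n), ref, alt, ctx,
               gene = sample(c("G1", "G2", NA), n, TRUE), effect = eff,
               altReads = alt_reads, depth = depth)
  df <- df[!duplicated(paste(df$chrom, df$pos)), , drop = FALSE]
  # one indel row, no context / no counts
  df <- rbind(df, mutRow("7", 999L, "AT", "A"))
  MutationCatalog(sampleId, df, patientId = "P9", tumorIndex = 2L)
}

catalogFromKeys <- function(keys, sampleId = "S", patientId = "P1",
                            tumorIndex = 1L) {
  parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  MutationCatalog(sampleId,
                  data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                             ref = parts[, 3], alt = parts[, 4],
                             stringsAsFactors = FALSE),
                  patientId = patientId, tumorIndex = tumorIndex)
}

flatProfile <- function(sampleId = "CN1", n = 50, value = 0, chrom = "1") {
  CopyNumberProfile(sampleId,
                    data.frame(chrom = chrom, pos = seq_len(n) * 10L,
                               log2ratio = rep(value, n)))
}

noisyProfile <- function(sampleId = "CN1", n = 200, sd = 0.05, seed = 1,
                         chrom = "1") {
  set.seed(seed)
  CopyNumberProfile(sampleId,
                    data.frame(chrom = chrom, pos = seq_len(n) * 10L,
                               log2ratio = rnorm(n, 0, sd)))
}

# arm-state vector over a small synthetic arm set
asv <- function(sampleId, states, arms = paste0("a", seq_along(states))) {
  new("ArmStateVector", sampleId = sampleId,
      states = stats::setNames(as.integer(states), arms))
}

# marginals matrix built directly
marg <- function(freqs) {
  colnames(freqs) <- c("-1", "0", "+1")
  if (is.null(rownames(freqs))) rownames(freqs) <- paste0("a", seq_len(nrow(freqs)))
  new("MarginalFrequencies", freqs = freqs)
}

# textbook step-up BH, the independent oracle for bhAdjust
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
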