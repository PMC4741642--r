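# Orchestration: per-patient clonality report joining the three lines of
# evidence (mutation concordance, spectrum clustering adjacency, copy-number
# LR2) into a verdict, plus the diagnostic figures.

#' Run the full per-patient clonality report
#'
#' For every patient: superset rescue (optional), mutation-concordance Fisher
#' test with BH control across patients, spectrum-clustering
#' mutual-nearest-neighbor adjacency, and the copy-number LR2 with a
#' reference-null p value built from all between-patient tumor pairings
#' (augmented with simulated independent pairs when the cohort yields fewer
#' than \code{minReference}). The verdict rule (configurable via
#' \code{alpha}): clonal iff the concordance q value or the LR2 p value falls
#' below \code{alpha}; the spectrum adjacency is reported but not decisive;
#' patients with neither component evaluable are indeterminate.
#'
#' @param cohort a [simulateCohort()] result, or any list with \code{pairs}
#'   (each pair holding \code{catalog1}, \code{catalog2} and optionally
#'   \code{profile1}, \code{profile2}, \code{counts}) and optionally
#'   \code{params}.
#' @param universeSize universe N for the 2x2 tables; defaults to the
#'   cohort's generating universe size when known, otherwise the superset
#'   reconstruction.
#' @param alpha significance threshold of the verdict rule (default 0.05).
#' @param useRescue apply superset rescue before concordance when counts are
#'   available (default TRUE).
#' @param minReference minimum size of the LR2 reference null (default 20).
#' @param outDir optional directory: report tables (TSV), spectra heatmap and
#'   dendrogram (PNG/Newick) and per-pair VAF concordance scatters (PNG) are
#'   written there.
#' @param seed seed for any augmentation simulations (default 1).
#' @return list with \code{verdicts}, \code{concordance}, \code{cnv}
#'   (data.frames), \code{cluster} ([ClusterResult-class] or NULL) and
#'   \code{thresholds}.
#' @export
runReport <- function(cohort, universeSize = NULL, alpha = 0.05,
                      useRescue = TRUE, minReference = 20L, outDir = NULL,
                      seed = 1L) {
  pairs <- cohort$pairs
  params <- cohort$params
  if (is.null(universeSize) && !is.null(params))
    universeSize <- params@universeSize
  if (length(pairs) == 0L) {
    out <- list(verdicts = data.frame(patientId = character(),
                                      verdict = character()),
                concordance = concordanceReport(list()),
                cnv = data.frame(), cluster = NULL,
                thresholds = c(alpha = alpha))
    if (!is.null(outDir)) .writeReport(out, outDir)
    return(out)
  }

  usedPairs <- lapply(pairs, function(pr) {
    if (useRescue && !is.null(pr$counts)) {
      res <- rescueSnvs(list(pr$catalog1, pr$catalog2), pr$counts)
      pr$catalog1 <- res$catalogs[[1]]
      pr$catalog2 <- res$catalogs[[2]]
      pr$superset <- res$superset
      pr$audit <- res$audit
    }
    pr
  })
  conc <- concordanceReport(usedPairs, universeSize = universeSize)

  catalogs <- unlist(lapply(usedPairs, function(pr)
    list(pr$catalog1, pr$catalog2)), recursive = FALSE)
  patients <- stats::setNames(
    vapply(catalogs, patientId, character(1)),
    vapply(catalogs, sampleId, character(1)))
  cluster <- NULL
  if (length(catalogs) >= 3L)
    cluster <- hierarchicalCluster(spectraMatrix(catalogs),
                                   patients = patients)

  cnv <- NULL
  haveCnv <- vapply(usedPairs, function(pr) !is.null(pr$profile1) &&
                      !is.null(pr$profile2), logical(1))
  if (any(haveCnv)) {
    armTable <- if (!is.null(params)) params@armTable else defaultArmTable()
    cnvPairs <- usedPairs[haveCnv]
    qc <- qcFilter(unlist(lapply(cnvPairs, function(pr)
      list(pr$profile1, pr$profile2)), recursive = FALSE))
    passedIds <- vapply(qc$passed, sampleId, character(1))
    states <- lapply(qc$passed, profileArmStates, armTable = armTable)
    names(states) <- passedIds
    if (length(states) >= 2L) {
      marg <- estimateMarginals(states)
      refLr2 <- .betweenPatientLr2(states, patients, marg)
      if (length(refLr2) < minReference) {
        set.seed(.deriveSeed(seed, 1L))
        simParams <- if (!is.null(params)) params else simulationParams()
        extra <- replicate(minReference - length(refLr2), {
          pr <- simulatePair(simParams, patientId = "ref", rho = 0,
                             what = "cnv")
          lr2Statistic(profileArmStates(pr$profile1, armTable),
                       profileArmStates(pr$profile2, armTable), marg)@lr2
        })
        refLr2 <- c(refLr2, extra)
      }
      cnv <- do.call(rbind, lapply(names(cnvPairs), function(pid) {
        pr <- cnvPairs[[pid]]
        s1 <- states[[sampleId(pr$profile1)]]
        s2 <- states[[sampleId(pr$profile2)]]
        if (is.null(s1) || is.null(s2))
          return(data.frame(patientId = pid, lr2 = NA_real_,
                            cHat = NA_real_, p = NA_real_))
        res <- lr2Pvalue(lr2Statistic(s1, s2, marg), refLr2)
        data.frame(patientId = pid, lr2 = res@lr2, cHat = res@cHat,
                   p = res@p, stringsAsFactors = FALSE)
      }))
    }
  }

  verdicts <- do.call(rbind, lapply(names(pairs), function(pid) {
    qv <- conc$q[conc$patientId == pid]
    qv <- if (length(qv)) qv[1] else NA_real_
    cp <- if (!is.null(cnv)) cnv$p[cnv$patientId == pid] else NA_real_
    cp <- if (length(cp)) cp[1] else NA_real_
    adj <- if (!is.null(cluster) && pid %in% names(cluster@adjacency))
      cluster@adjacency[[pid]] else NA
    verdict <- if (is.na(qv) && is.na(cp)) "indeterminate"
      else if ((!is.na(qv) && qv < alpha) || (!is.na(cp) && cp < alpha))
        "clonal" else "independent"
    data.frame(patientId = pid, concordanceQ = qv, spectrumAdjacent = adj,
               cnvP = cp, verdict = verdict, stringsAsFactors = FALSE)
  }))

  out <- list(verdicts = verdicts, concordance = conc, cnv = cnv,
              cluster = cluster, pairs = usedPairs,
              thresholds = c(alpha = alpha, universeSize = universeSize))
  if (!is.null(outDir)) .writeReport(out, outDir)
  out
}

# lr2 of every between-patient tumor pairing (the self-contained reference
# null: such pairings are independent by construction)
.betweenPatientLr2 <- function(states, patients, marginals) {
  ids <- names(states)
  out <- numeric(0)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    if (patients[[ids[i]]] == patients[[ids[j]]]) next
    out <- c(out, lr2Statistic(states[[i]], states[[j]], marginals)@lr2)
  }
  out
}

.writeReport <- function(report, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) utils::write.table(
    df, file.path(outDir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(report$verdicts, "verdicts.tsv")
  wt(report$concordance, "concordance.tsv")
  if (!is.null(report$cnv)) wt(report$cnv, "cnv_clonality.tsv")
  hdr <- file.path(outDir, "thresholds.tsv")
  utils::write.table(data.frame(key = names(report$thresholds),
                                value = unname(report$thresholds)),
                     hdr, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$cluster)) {
    writeNewick(report$cluster, file.path(outDir, "spectra_tree.nwk"))
    sm <- spectraMatrix(unlist(lapply(report$pairs, function(pr)
      list(pr$catalog1, pr$catalog2)), recursive = FALSE))
    grDevices::png(file.path(outDir, "spectra_heatmap.png"), width = 1400,
                   height = 600)
    pheatmap::pheatmap(sm@scaled, cluster_cols = FALSE,
                       cluster_rows = report$cluster@tree, show_colnames = FALSE)
    grDevices::dev.off()
    grDevices::png(file.path(outDir, "spectra_dendrogram.png"), width = 800,
                   height = 600)
    graphics::plot(report$cluster@tree, xlab = "", sub = "",
                   main = "Hierarchical clustering of mutation spectra")
    grDevices::dev.off()
  }
  if (!is.null(report$pairs)) {
    for (pid in names(report$pairs)) {
      pr <- report$pairs[[pid]]
      if (is.null(pr$counts)) next
      fig <- plotVafConcordance(pr$counts, title = pid)
      ggplot2::ggsave(file.path(outDir, sprintf("vaf_%s.png", pid)), fig,
                      width = 5, height = 5, dpi = 120)
    }
  }
  invisible(outDir)
}

#' VAF concordance scatter for a tumor pair
#'
#' Plots each superset site's variant allele fraction in tumor 1 against
#' tumor 2. Sites private to one tumor hug that tumor's axis; shared sites
#' sit away from both axes, so clonal pairs show off-axis mass and
#' independent pairs do not.
#'
#' @param counts per-site read counts of both tumors: columns
#'   \code{altReads1, depth1, altReads2, depth2} (as in [simulatePair()]'s
#'   \code{counts}), or a [buildSuperset()] table.
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plotVafConcordance <- function(counts, title = NULL) {
  v1 <- ifelse(counts$depth1 > 0, counts$altReads1 / counts$depth1, NA_real_)
  v2 <- ifelse(counts$depth2 > 0, counts$altReads2 / counts$depth2, NA_real_)
  df <- data.frame(vaf1 = v1, vaf2 = v2)
  ggplot2::ggplot(df, ggplot2::aes(x = vaf1, y = vaf2)) +
    ggplot2::geom_point(alpha = 0.6, size = 1.5) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "VAF, tumor 1", y = "VAF, tumor 2", title = title) +
    ggplot2::theme_bw()
}
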