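#' Run the full analysis chain from a configuration
#'
#' Orchestrates simulation (or loading), QC, structure analyses, f3
#' admixture tests and the selection scan in fixed order. The
#' configuration is a YAML file or an equivalent nested list with
#' blocks:
#'
#' \describe{
#'   \item{simulate}{arguments for [simConfig()] (seed mandatory), or}
#'   \item{input}{`vcf` and `sample_table` paths (exactly one of
#'     `simulate` / `input` must be present),}
#'   \item{qc}{arguments for [runQc()],}
#'   \item{structure}{`n_perm`, `seed` for the Procrustes test,}
#'   \item{selscan}{`cluster1`, `cluster2`, `n_tests`, window/binning
#'     parameters,}
#'   \item{stages}{character vector of stages to run (default all).}
#' }
#'
#' Stages consume only prior-stage results; reruns with the same
#' config are bit-reproducible. When `outdir` is given, per-stage TSV
#' artifacts and a JSON run report are written with deterministic
#' ordering.
#'
#' @param config path to a YAML file, or a list
#' @param outdir optional output directory
#' @return list of per-stage results plus a `report` entry
#' @export
runPipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$input)
  if (has_sim == has_inp)
    stop("config error: exactly one of 'simulate' or 'input' must be present")
  stages <- config$stages %||% c("qc", "structure", "f3", "selscan")
  res <- list()
  report <- list()

  if (has_sim) {
    if (is.null(config$simulate$seed))
      stop("config error: simulate block requires a seed")
    cfg <- do.call(simConfig, config$simulate)
    sim <- simulateDataset(cfg)
    G <- sim$genotypes
    res$simulate <- sim
    report$simulate <- list(n_samples = nSamples(G), n_markers = nMarkers(G),
                            seed = cfg@seed)
  } else {
    st <- readSampleTable(config$input$sample_table)
    x <- readGenoVcf(config$input$vcf, st)
    G <- if (is(x, "HaplotypeSet")) asGenotypes(x) else x
    if (is(x, "HaplotypeSet")) res$haplotypes <- x
    report$input <- list(n_samples = nSamples(G), n_markers = nMarkers(G))
  }

  if ("qc" %in% stages) {
    qc <- do.call(runQc, c(list(G), config$qc))
    res$qc <- qc
    G <- qc$data
    report$qc <- qc$report
  }
  ld_keep <- res$qc$ld_keep %||% seq_len(nMarkers(G))

  if ("structure" %in% stages) {
    pca <- pcaGenotypes(G, n_components = config$structure$n_pc %||% 10,
                        loci = ld_keep)
    st <- samples(G)
    cent <- provinceCentroids(pca, st)
    geo <- provinceGeography(st)
    pro <- procrustesPermTest(cent, geo,
                              n_perm = config$structure$n_perm %||% 999,
                              seed = config$structure$seed %||% 1)
    dp <- dapc(G, loci = ld_keep)
    res$structure <- list(pca = pca, procrustes = pro, dapc = dp)
    report$structure <- list(
      t0 = pro@t0, perm_p = pro@perm_p,
      mean_own_posterior = mean(dp@posteriors[cbind(
        seq_len(nrow(dp@posteriors)),
        match(dp@assignments, colnames(dp@posteriors)))]))
  }

  if ("f3" %in% stages) {
    gf <- groupFreqs(G, "cluster")
    f3 <- f3AllTrios(gf$freq, gf$n, markers(G),
                     block_bp = config$f3$block_bp %||% 5e6)
    f3 <- rankTrios(f3, config$f3$top_fraction %||% 0.01)
    res$f3 <- f3
    report$f3 <- list(n_trios = nrow(f3), min_z = suppressWarnings(min(f3$z)))
  }

  if ("selscan" %in% stages) {
    cls <- unique(samples(G)$cluster)
    c1 <- config$selscan$cluster1 %||% cls[1L]
    c2 <- config$selscan$cluster2 %||% cls[min(2L, length(cls))]
    fst <- pairwiseFst(G, c1, c2)
    fst <- mafBinOutliers(fst,
                          bin_width = config$selscan$maf_bin_width %||% 0.05,
                          top_fraction = config$selscan$top_fraction %||% 0.01)
    sel <- list(fst = fst)
    haps <- res$simulate$haplotypes %||% res$haplotypes
    if (!is.null(haps)) {
      ih <- ihsScan(haps, cluster = c1,
                    ehh_cutoff = config$selscan$ehh_cutoff %||% 0.05,
                    max_gap = config$selscan$max_gap %||% 20000,
                    min_daf = 0.05)
      ihs <- ihsStandardize(ih,
                            min_daf = config$selscan$min_daf %||% 0.2,
                            top_fraction = config$selscan$top_fraction %||% 0.01)
      win <- jointWindowScan(fst, ihs,
                             window_bp = config$selscan$window_bp %||% 2e5,
                             step_bp = config$selscan$step_bp %||% 5e4,
                             min_snps = config$selscan$min_snps %||% 10)
      sel$ihs <- ihs
      sel$windows <- win
    }
    if (!is.null(config$selscan$n_tests)) {
      daf <- deltaDafScan(G, c1, c2, n_tests = config$selscan$n_tests,
                          loci = which(fst$outlier))
      sel$daf <- daf
      sel$daf_report <- dafReport(daf)
    }
    res$selscan <- sel
    report$selscan <- list(
      n_fst_outliers = sum(fst$outlier, na.rm = TRUE),
      n_candidate_windows = if (!is.null(sel$windows))
        sum(sel$windows$candidate) else NA_integer_,
      n_daf_significant = if (!is.null(sel$daf_report))
        nrow(sel$daf_report) else NA_integer_)
  }

  if (has_sim)
    report$truth_validation <- validateAgainstTruth(res, res$simulate$truth,
                                                    markers(G))
  res$report <- report
  if (!is.null(outdir)) .write_artifacts(res, outdir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_artifacts <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    write.table(df, file.path(outdir, paste0(name, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$structure)) {
    wr(data.frame(sample_id = rownames(res$structure$pca@scores),
                  res$structure$pca@scores), "pca_scores")
    wr(data.frame(province = names(res$structure$procrustes@residuals),
                  residual = res$structure$procrustes@residuals),
       "procrustes_residuals")
    wr(data.frame(sample_id = rownames(res$structure$dapc@posteriors),
                  res$structure$dapc@posteriors), "dapc_posteriors")
  }
  if (!is.null(res$f3)) wr(res$f3, "f3_trios")
  if (!is.null(res$selscan)) {
    wr(res$selscan$fst, "fst_records")
    if (!is.null(res$selscan$ihs)) wr(res$selscan$ihs, "ihs_records")
    if (!is.null(res$selscan$windows)) wr(res$selscan$windows, "window_scores")
    if (!is.null(res$selscan$daf)) wr(res$selscan$daf, "daf_tests")
  }
  jsonlite::write_json(res$report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(outdir)
}

#' Score detector output against simulation ground truth
#'
#' Computes recall and precision of the binned-Fst outlier scan against
#' planted differentiated loci, of the joint window scan against
#' planted sweep intervals (a window is a true positive when it
#' overlaps a planted interval; a sweep is recalled when any candidate
#' window overlaps it), and of the delta-DAF report against planted
#' loci. Detectors with empty output get recall 0 and `NA` precision.
#'
#' @param res pipeline result list (needs `selscan`)
#' @param truth a [GroundTruth-class]
#' @param marker_table marker table of the analysed dataset
#' @return nested list of recall/precision per detector
#' @export
validateAgainstTruth <- function(res, truth, marker_table) {
  out <- list()
  planted_ids <- marker_table$id[truth@outlier_loci$locus]
  if (!is.null(res$selscan$fst)) {
    got <- res$selscan$fst$id[which(res$selscan$fst$outlier)]
    tp <- sum(planted_ids %in% got)
    out$fst <- list(
      recall = if (length(planted_ids)) tp / length(planted_ids) else NA_real_,
      precision = if (length(got)) sum(got %in% planted_ids) / length(got)
                  else NA_real_)
  }
  if (!is.null(res$selscan$windows) && nrow(truth@sweep_windows)) {
    w <- res$selscan$windows[res$selscan$windows$candidate, , drop = FALSE]
    sw <- truth@sweep_windows
    overlaps <- function(a1, a2, b1, b2) a1 <= b2 & a2 >= b1
    rec <- vapply(seq_len(nrow(sw)), function(i) {
      any(overlaps(w$start, w$end, sw$start[i], sw$end[i]))
    }, logical(1))
    prec <- if (nrow(w)) vapply(seq_len(nrow(w)), function(i) {
      any(overlaps(sw$start, sw$end, w$start[i], w$end[i]))
    }, logical(1)) else logical()
    out$windows <- list(
      recall = mean(rec),
      precision = if (nrow(w)) mean(prec) else NA_real_,
      n_candidates = nrow(w))
  }
  if (!is.null(res$selscan$daf_report)) {
    got <- res$selscan$daf_report$id
    tp <- sum(planted_ids %in% got)
    out$daf <- list(
      recall = if (length(planted_ids)) tp / length(planted_ids) else NA_real_,
      precision = if (length(got)) sum(got %in% planted_ids) / length(got)
                  else NA_real_)
  }
  out
}
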