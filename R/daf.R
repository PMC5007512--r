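#' Derived-allele-frequency difference with Fisher exact test
#'
#' From derived/ancestral allele counts in two clusters, computes
#' `delta = |p1 - p2|` and the two-sided Fisher exact p (sum of table
#' probabilities no larger than the observed one, via
#' [stats::fisher.test]). An empty margin gives p = 1 and an undefined
#' delta flag.
#'
#' @param d1,a1 derived/ancestral allele counts in cluster 1
#' @param d2,a2 derived/ancestral allele counts in cluster 2
#' @return list: delta, direction (+1 if p1 > p2), p, defined
#' @export
deltaDafFisher <- function(d1, a1, d2, a2) {
  stopifnot(d1 >= 0, a1 >= 0, d2 >= 0, a2 >= 0)
  n1 <- d1 + a1; n2 <- d2 + a2
  if (n1 == 0 || n2 == 0 || (d1 + d2) == 0 || (a1 + a2) == 0)
    return(list(delta = if (n1 == 0 || n2 == 0) NA_real_
                        else abs(d1 / n1 - d2 / n2),
                direction = NA_real_, p = 1, defined = FALSE))
  p1 <- d1 / n1; p2 <- d2 / n2
  p <- fisher.test(matrix(c(d1, a1, d2, a2), nrow = 2))$p.value
  list(delta = abs(p1 - p2), direction = sign(p1 - p2), p = min(p, 1),
       defined = TRUE)
}

#' Drift-corrected test of allele-frequency differentiation
#'
#' Tests whether an observed frequency difference exceeds what genetic
#' drift at the genome-wide background differentiation would produce.
#' Under the null, `Var(p1 - p2) = pbar (1 - pbar) (2 F + 1/(2 n1) +
#' 1/(2 n2))` with `pbar` the pooled frequency and `F` the genome-wide
#' mean pairwise Weir-Cockerham theta for the cluster pair; the
#' statistic `(p1 - p2)^2 / Var` is referred to chi-square with 1 df.
#' With `background_F = 0` this reduces to the two-proportion
#' chi-square test. Negative `background_F` is truncated to 0; a pooled
#' frequency of 0 or 1 is undefined.
#'
#' @param p1,p2 derived-allele frequencies in the two clusters
#' @param n1,n2 diploid sample sizes
#' @param background_F genome-wide mean pairwise theta (see
#'   [meanPairwiseTheta()])
#' @return list: statistic, p, defined
#' @export
driftCorrectedTest <- function(p1, p2, n1, n2, background_F) {
  if (background_F < 0) {
    message("negative background_F truncated to 0")
    background_F <- 0
  }
  pbar <- (2 * n1 * p1 + 2 * n2 * p2) / (2 * n1 + 2 * n2)
  defined <- pbar > 0 & pbar < 1
  v <- pbar * (1 - pbar) * (2 * background_F + 1 / (2 * n1) + 1 / (2 * n2))
  stat <- ifelse(defined, (p1 - p2)^2 / v, NA_real_)
  list(statistic = stat,
       p = ifelse(defined, pchisq(stat, df = 1, lower.tail = FALSE),
                  NA_real_),
       defined = defined)
}

#' Genome scan of delta-DAF between two clusters
#'
#' For every marker with ancestral annotation, computes derived-allele
#' counts per cluster, the Fisher exact p, the Bonferroni significance
#' flag at `alpha / n_tests`, and the drift-corrected p at the supplied
#' (or estimated) background theta.
#'
#' @param G a [GenotypeData-class]
#' @param cluster1,cluster2 cluster labels
#' @param n_tests Bonferroni denominator; the implied genome-wide test
#'   count is study-specific, so it must be supplied explicitly
#' @param alpha family-wise error rate
#' @param background_F background differentiation; NULL estimates it as
#'   the mean pairwise theta of this cluster pair
#' @param loci optional marker subset to test
#' @return data.frame: id, chrom, pos, p1, p2, delta, fisher_p,
#'   bonferroni, drift_p, background_F
#' @export
deltaDafScan <- function(G, cluster1, cluster2, n_tests, alpha = 0.05,
                         background_F = NULL, loci = NULL) {
  mk <- markers(G)
  if (is.null(background_F))
    background_F <- meanPairwiseTheta(pairwiseFst(G, cluster1, cluster2))
  gf <- groupDerivedFreqs(G, "cluster")
  if (is.null(loci)) loci <- which(!is.na(mk$ancestral))
  thr <- bonferroniThreshold(alpha, n_tests)
  rows <- lapply(loci, function(j) {
    n1 <- gf$n[cluster1, j]; n2 <- gf$n[cluster2, j]
    p1 <- gf$freq[cluster1, j]; p2 <- gf$freq[cluster2, j]
    if (is.na(p1) || is.na(p2)) return(NULL)
    d1 <- round(2 * n1 * p1); d2 <- round(2 * n2 * p2)
    fis <- deltaDafFisher(d1, 2 * n1 - d1, d2, 2 * n2 - d2)
    dr <- driftCorrectedTest(p1, p2, n1, n2, background_F)
    data.frame(id = mk$id[j], chrom = mk$chrom[j], pos = mk$pos[j],
               p1 = p1, p2 = p2, delta = fis$delta, fisher_p = fis$p,
               bonferroni = fis$p < thr, drift_p = dr$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$background_F <- background_F
  rownames(out) <- NULL
  out
}

#' Report of significantly differentiated loci
#'
#' Loci passing the Bonferroni threshold on the Fisher exact p, sorted
#' by (chrom, pos), with delta-DAF, raw and drift-corrected p-values
#' and a flag marking loci at or above the 0.25 delta-DAF reference
#' threshold conventionally used to call highly differentiated loci
#' within a continent.
#'
#' @param records data.frame from [deltaDafScan()]
#' @param daf_reference reference delta-DAF threshold (default 0.25)
#' @return the significant subset, sorted, with column
#'   `above_reference`
#' @export
dafReport <- function(records, daf_reference = 0.25) {
  out <- records[!is.na(records$bonferroni) & records$bonferroni, ,
                 drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  out$above_reference <- out$delta >= daf_reference
  rownames(out) <- NULL
  out
}
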