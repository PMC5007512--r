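#' Two-population Weir-Cockerham variance components and theta
#'
#' Computes the 1984 variance components for two populations per locus
#' from allele frequencies, observed heterozygote proportions and
#' diploid sample sizes: `a` (among populations), `b` (among
#' individuals within populations), `c` (within individuals), and
#' `theta = a / (a + b + c)`. Loci where the denominator is zero
#' (monomorphic in both populations) are flagged undefined, never
#' returned as 0/0.
#'
#' All arguments are vectorised over loci.
#'
#' @param p1,p2 allele frequencies per population
#' @param h1,h2 observed heterozygote proportions per population
#' @param n1,n2 diploid sample sizes per population (>= 2)
#' @return data.frame with columns a, b, c, theta, defined
#' @export
wcFst <- function(p1, p2, h1, h2, n1, n2) {
  stopifnot(all(n1 >= 2, na.rm = TRUE), all(n2 >= 2, na.rm = TRUE))
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  den <- a + b + cc
  defined <- !is.na(den) & den != 0
  theta <- ifelse(defined, a / den, NA_real_)
  data.frame(a = a, b = b, c = cc, theta = theta, defined = defined)
}

#' Per-locus Weir-Cockerham Fst between two clusters
#'
#' Extracts per-cluster allele frequency, observed heterozygosity and
#' non-missing sample size from a genotype panel and applies [wcFst()].
#' Also reports the pooled minor-allele frequency used downstream for
#' binning.
#'
#' @param G a [GenotypeData-class]
#' @param cluster1,cluster2 cluster labels
#' @return data.frame: id, chrom, pos, a, b, c, theta, defined, maf
#' @export
pairwiseFst <- function(G, cluster1, cluster2) {
  g <- genotypes(G)
  mk <- markers(G)
  cl <- samples(G)$cluster
  stat <- function(rows) {
    sub <- g[rows, , drop = FALSE]
    n <- colSums(!is.na(sub))
    p <- ifelse(n > 0, colSums(sub, na.rm = TRUE) / (2 * n), NA_real_)
    h <- ifelse(n > 0, colSums(sub == 1L, na.rm = TRUE) / n, NA_real_)
    list(p = p, h = h, n = n)
  }
  s1 <- stat(which(cl == cluster1))
  s2 <- stat(which(cl == cluster2))
  ok <- s1$n >= 2 & s2$n >= 2
  res <- data.frame(id = mk$id, chrom = mk$chrom, pos = mk$pos,
                    a = NA_real_, b = NA_real_, c = NA_real_,
                    theta = NA_real_, defined = FALSE,
                    stringsAsFactors = FALSE)
  if (any(ok)) {
    w <- wcFst(s1$p[ok], s2$p[ok], s1$h[ok], s2$h[ok], s1$n[ok], s2$n[ok])
    res$a[ok] <- w$a; res$b[ok] <- w$b; res$c[ok] <- w$c
    res$theta[ok] <- w$theta; res$defined[ok] <- w$defined
  }
  ntot <- s1$n + s2$n
  pbar <- (s1$n * s1$p + s2$n * s2$p) / ntot
  res$maf <- pmin(pbar, 1 - pbar)
  res
}

#' Genome-wide mean pairwise theta
#'
#' The genome-wide background differentiation between two clusters,
#' summarised as the mean of defined per-locus theta values. Used as
#' `background_F` in [driftCorrectedTest()].
#'
#' @param fst data.frame from [pairwiseFst()]
#' @return mean theta over defined loci
#' @export
meanPairwiseTheta <- function(fst) {
  mean(fst$theta[fst$defined], na.rm = TRUE)
}

#' MAF-binned top-fraction Fst outliers
#'
#' Records with defined theta are grouped into minor-allele-frequency
#' bins of `bin_width` over [0, 0.5]; within each bin, loci are ranked
#' by descending theta (ties: higher MAF first, then id) and the top
#' `ceiling(top_fraction x bin size)` are flagged as outliers.
#'
#' @param fst data.frame from [pairwiseFst()] (columns theta, maf, id,
#'   defined)
#' @param bin_width MAF bin width (default 0.05)
#' @param top_fraction flagged fraction per bin (default 0.01)
#' @return the input with columns `maf_bin`, `bin_rank`, `outlier`
#' @export
mafBinOutliers <- function(fst, bin_width = 0.05, top_fraction = 0.01) {
  fst$maf_bin <- NA_integer_
  fst$bin_rank <- NA_integer_
  fst$outlier <- FALSE
  use <- which(fst$defined & !is.na(fst$maf) & fst$maf > 0)
  if (!length(use)) return(fst)
  bin <- pmin(floor(fst$maf[use] / bin_width), ceiling(0.5 / bin_width) - 1L)
  fst$maf_bin[use] <- as.integer(bin)
  for (b in unique(bin)) {
    rows <- use[bin == b]
    ord <- rows[order(-fst$theta[rows], -fst$maf[rows], fst$id[rows])]
    fst$bin_rank[ord] <- seq_along(ord)
    k <- ceiling(top_fraction * length(ord))
    fst$outlier[ord[seq_len(k)]] <- TRUE
  }
  fst
}
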