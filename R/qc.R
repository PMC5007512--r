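#' Call-rate filtering
#'
#' Removes loci with call rate below `locus_threshold` first, then
#' samples with call rate (over the surviving loci) below
#' `sample_threshold`.
#'
#' @param G a [GenotypeData-class]
#' @param locus_threshold,sample_threshold minimum call-rate fractions
#' @return list with filtered `data`, `loci_removed` and
#'   `samples_removed` (ids), and the thresholds used
#' @export
callRateFilter <- function(G, locus_threshold = 0.95,
                           sample_threshold = 0.95) {
  stopifnot(locus_threshold >= 0, locus_threshold <= 1,
            sample_threshold >= 0, sample_threshold <= 1)
  g <- genotypes(G)
  cr_loc <- colMeans(!is.na(g))
  keep_l <- cr_loc >= locus_threshold
  g2 <- g[, keep_l, drop = FALSE]
  cr_smp <- rowMeans(!is.na(g2))
  keep_s <- cr_smp >= sample_threshold
  out <- GenotypeData(g2[keep_s, , drop = FALSE],
                      markers(G)[keep_l, , drop = FALSE],
                      samples(G)[keep_s, , drop = FALSE])
  list(data = out,
       loci_removed = markers(G)$id[!keep_l],
       samples_removed = samples(G)$sample_id[!keep_s],
       locus_threshold = locus_threshold,
       sample_threshold = sample_threshold)
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Two-sided conditional exact test: given the allele counts, the
#' probability of every possible heterozygote count is enumerated and
#' the p-value is the sum of probabilities no larger than that of the
#' observed count. Monomorphic loci return 1 by convention.
#'
#' @param nAA,nAa,naa genotype counts (AA homozygote, heterozygote, aa
#'   homozygote)
#' @return exact two-sided p-value
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  stopifnot(nAA >= 0, nAa >= 0, naa >= 0)
  n <- nAA + nAa + naa
  if (n < 1) stop("need at least one genotype")
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1)
  rare <- min(nA, na)
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(nAa = h | allele counts), up to a shared constant
  lp <- vapply(hets, function(h) {
    hom1 <- (nA - h) / 2
    hom2 <- (na - h) / 2
    h * log(2) - lfactorial(h) - lfactorial(hom1) - lfactorial(hom2)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(nAa, hets)]
  sum(p[p <= obs + 1e-12 * obs])
}

#' Per-test Bonferroni threshold
#'
#' @param alpha family-wise error rate in (0, 1)
#' @param m number of tests (>= 1)
#' @return `alpha / m`
#' @export
bonferroniThreshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1)
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Hardy-Weinberg filter over all loci
#'
#' Applies [hweExactTest()] per locus and removes loci with p below the
#' Bonferroni threshold. By default the test runs within each province
#' (pooling structured populations inflates homozygosity — the Wahlund
#' effect — and masks genotyping artefacts confined to one batch); a
#' locus is removed when its smallest per-province p falls below
#' `alpha / (loci x provinces)`. `by = "pooled"` tests the whole panel
#' at `alpha / loci`.
#'
#' @param G a [GenotypeData-class]
#' @param alpha family-wise error rate (default 0.01)
#' @param by `"province"` (default) or `"pooled"`
#' @return list with filtered `data`, `loci_removed` ids, per-locus
#'   `p` (minimum over groups) and the `threshold` used
#' @export
hweFilter <- function(G, alpha = 0.01, by = c("province", "pooled")) {
  by <- match.arg(by)
  g <- genotypes(G)
  groups <- if (by == "province") split(seq_len(nrow(g)),
                                        samples(G)$province)
            else list(seq_len(nrow(g)))
  p_one <- function(rows, j) {
    gj <- g[rows, j]
    hweExactTest(sum(gj == 0L, na.rm = TRUE), sum(gj == 1L, na.rm = TRUE),
                 sum(gj == 2L, na.rm = TRUE))
  }
  p <- vapply(seq_len(ncol(g)), function(j) {
    min(vapply(groups, p_one, numeric(1), j = j))
  }, numeric(1))
  thr <- bonferroniThreshold(alpha, ncol(g) * length(groups))
  keep <- p >= thr
  out <- GenotypeData(g[, keep, drop = FALSE],
                      markers(G)[keep, , drop = FALSE], samples(G))
  list(data = out, loci_removed = markers(G)$id[!keep], p = p,
       threshold = thr)
}

#' LD pruning by pairwise genotype correlation
#'
#' Slides a `window_snps`-marker window along the map in `step_snps`
#' increments. Within a window, each marker pair with squared genotype
#' correlation above `r2_threshold` loses its lower-MAF member (tie:
#' later position removed). Monomorphic loci are skipped from the r2
#' computation (their correlation is undefined) and always retained.
#'
#' @param G a [GenotypeData-class]
#' @param window_snps window width in markers (>= 2)
#' @param step_snps window advance in markers
#' @param r2_threshold maximum tolerated r2
#' @return integer indices of retained markers
#' @export
ldPrune <- function(G, window_snps = 50, step_snps = 5,
                    r2_threshold = 0.2) {
  stopifnot(window_snps >= 2)
  g <- genotypes(G)
  M <- ncol(g)
  v <- apply(g, 2, var, na.rm = TRUE)
  poly <- !is.na(v) & v > 0
  maf <- pmin(colMeans(g, na.rm = TRUE) / 2,
              1 - colMeans(g, na.rm = TRUE) / 2)
  alive <- rep(TRUE, M)
  starts <- seq(1L, max(1L, M - 1L), by = step_snps)
  for (s in starts) {
    idx <- s:min(s + window_snps - 1L, M)
    idx <- idx[alive[idx] & poly[idx]]
    if (length(idx) < 2L) next
    r2 <- suppressWarnings(
      cor(g[, idx, drop = FALSE], use = "pairwise.complete.obs"))^2
    for (ii in seq_along(idx)[-length(idx)]) {
      if (!alive[idx[ii]]) next
      for (jj in (ii + 1L):length(idx)) {
        if (!alive[idx[jj]]) next
        if (!is.na(r2[ii, jj]) && r2[ii, jj] > r2_threshold) {
          pair <- c(idx[ii], idx[jj])
          drop <- if (maf[pair[1L]] < maf[pair[2L]]) pair[1L]
                  else if (maf[pair[2L]] < maf[pair[1L]]) pair[2L]
                  else pair[2L]   # tie: later position
          alive[drop] <- FALSE
          if (drop == idx[ii]) break
        }
      }
    }
  }
  which(alive)
}

#' Full QC chain
#'
#' Call-rate filter, HWE exact filter with Bonferroni, relatedness
#' pruning at the pi-hat cutoff, and LD pruning, in that order,
#' mirroring a standard array-QC protocol. LD pruning produces a
#' separate pruned marker index; the returned dataset keeps all
#' HWE/call-rate-passing loci.
#'
#' @param G a [GenotypeData-class]
#' @param callrate_loci,callrate_samples call-rate thresholds
#' @param hwe_alpha family-wise alpha for the HWE filter
#' @param ibd_cutoff pi-hat above which one of a pair is dropped
#' @param ld_window,ld_step,ld_r2 LD-pruning parameters
#' @return list with `data` (filtered [GenotypeData-class]),
#'   `ld_keep` (marker indices of the LD-pruned subset), `kinship`
#'   (pairwise records) and `report` (counts and thresholds)
#' @export
runQc <- function(G, callrate_loci = 0.95, callrate_samples = 0.95,
                  hwe_alpha = 0.01, ibd_cutoff = 0.125,
                  ld_window = 50, ld_step = 5, ld_r2 = 0.2) {
  cr <- callRateFilter(G, callrate_loci, callrate_samples)
  hw <- hweFilter(cr$data, hwe_alpha)
  kin <- ibdMoments(hw$data)
  callrates <- rowMeans(!is.na(genotypes(hw$data)))
  names(callrates) <- samples(hw$data)$sample_id
  drop <- pruneRelated(kin, cutoff = ibd_cutoff, callrates = callrates)
  keep <- !(samples(hw$data)$sample_id %in% drop)
  dat <- GenotypeData(genotypes(hw$data)[keep, , drop = FALSE],
                      markers(hw$data), samples(hw$data)[keep, , drop = FALSE])
  ld_keep <- ldPrune(dat, ld_window, ld_step, ld_r2)
  report <- list(
    loci_removed_callrate = length(cr$loci_removed),
    samples_removed_callrate = length(cr$samples_removed),
    loci_removed_hwe = length(hw$loci_removed),
    samples_removed_ibd = length(drop),
    loci_after_ld_prune = length(ld_keep),
    thresholds = list(callrate_loci = callrate_loci,
                      callrate_samples = callrate_samples,
                      hwe_alpha = hwe_alpha, hwe_threshold = hw$threshold,
                      ibd_cutoff = ibd_cutoff, ld_window = ld_window,
                      ld_step = ld_step, ld_r2 = ld_r2))
  list(data = dat, ld_keep = ld_keep, kinship = kin, report = report)
}
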