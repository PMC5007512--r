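#' Moments-based IBD estimation from identity-by-state counts
#'
#' For every sample pair, counts loci by IBS class (0, 1, 2 shared
#' alleles over non-missing calls) and solves the method-of-moments
#' system: expected IBS-class counts given the allele frequencies under
#' IBD = 0 / 1 / 2 are accumulated over loci, and P(IBD = 0), P(IBD = 1),
#' P(IBD = 2) are obtained sequentially from the observed IBS0, IBS1 and
#' IBS2 counts, truncated to [0, 1] and renormalised.
#' `pi_hat = P(IBD=1)/2 + P(IBD=2)`. Pairs with fewer than
#' `min_informative` jointly called loci are flagged low-confidence.
#'
#' Frequencies default to the sample-wide allele frequencies; an
#' LD-pruned marker set is recommended (not enforced).
#'
#' @param G a [GenotypeData-class]
#' @param loci optional marker indices to use (e.g. an LD-pruned set)
#' @param min_informative minimum jointly called loci per pair
#' @return data.frame with one row per pair: sample1, sample2, ibs0,
#'   ibs1, ibs2, p_ibd0, p_ibd1, p_ibd2, pi_hat, n_loci,
#'   low_confidence
#' @export
ibdMoments <- function(G, loci = NULL, min_informative = 100) {
  g <- genotypes(G)
  if (!is.null(loci)) g <- g[, loci, drop = FALSE]
  ids <- samples(G)$sample_id
  n <- nrow(g)
  p <- colMeans(g, na.rm = TRUE) / 2
  q <- 1 - p
  ok <- !is.na(p) & p > 0 & p < 1
  g <- g[, ok, drop = FALSE]; p <- p[ok]; q <- q[ok]
  M <- ncol(g)

  # per-locus IBS-class probabilities conditional on IBD state
  e0_ibd0 <- 2 * p^2 * q^2
  e1_ibd0 <- 4 * p^3 * q + 4 * p * q^3
  e2_ibd0 <- p^4 + q^4 + 4 * p^2 * q^2
  e1_ibd1 <- 2 * p^2 * q + 2 * p * q^2
  e2_ibd1 <- p^3 + q^3 + p^2 * q + p * q^2
  S0_0 <- sum(e0_ibd0); S1_0 <- sum(e1_ibd0); S2_0 <- sum(e2_ibd0)
  S1_1 <- sum(e1_ibd1); S2_1 <- sum(e2_ibd1)

  A0 <- (!is.na(g) & g == 0L); A1 <- (!is.na(g) & g == 1L)
  A2 <- (!is.na(g) & g == 2L)
  storage.mode(A0) <- storage.mode(A1) <- storage.mode(A2) <- "double"
  V <- !is.na(g); storage.mode(V) <- "double"
  ibs0 <- A0 %*% t(A2); ibs0 <- ibs0 + t(ibs0)
  ibs2 <- A0 %*% t(A0) + A1 %*% t(A1) + A2 %*% t(A2)
  valid <- V %*% t(V)
  ibs1 <- valid - ibs0 - ibs2

  pairs <- which(upper.tri(valid), arr.ind = TRUE)
  res <- data.frame(
    sample1 = ids[pairs[, 1L]], sample2 = ids[pairs[, 2L]],
    ibs0 = ibs0[pairs], ibs1 = ibs1[pairs], ibs2 = ibs2[pairs],
    n_loci = valid[pairs], stringsAsFactors = FALSE)
  fr <- res$n_loci / M   # scale expectations to each pair's call set
  P0 <- res$ibs0 / (S0_0 * fr)
  P1 <- (res$ibs1 - P0 * S1_0 * fr) / (S1_1 * fr)
  P2 <- (res$ibs2 - P0 * S2_0 * fr - P1 * S2_1 * fr) / res$n_loci
  cl <- function(x) pmin(pmax(x, 0), 1)
  P0 <- cl(P0); P1 <- cl(P1); P2 <- cl(P2)
  tot <- P0 + P1 + P2
  res$p_ibd0 <- P0 / tot; res$p_ibd1 <- P1 / tot; res$p_ibd2 <- P2 / tot
  res$pi_hat <- res$p_ibd1 / 2 + res$p_ibd2
  res$low_confidence <- res$n_loci < min_informative
  res
}

#' Greedy pruning of related samples
#'
#' Repeatedly drops the sample involved in the most pairs with
#' `pi_hat > cutoff` (ties broken by lower call rate, then by
#' lexicographically larger id) until no pair exceeds the cutoff, so
#' exactly one member of an isolated related pair is removed.
#'
#' @param records pairwise table from [ibdMoments()]
#' @param cutoff pi-hat threshold (0.125 = third-degree relatives)
#' @param callrates optional named per-sample call rates for
#'   tie-breaking
#' @return character vector of sample ids to drop
#' @export
pruneRelated <- function(records, cutoff = 0.125, callrates = NULL) {
  over <- records[records$pi_hat > cutoff, c("sample1", "sample2")]
  drop <- character()
  while (nrow(over) > 0L) {
    cnt <- table(c(over$sample1, over$sample2))
    cand <- names(cnt)[cnt == max(cnt)]
    if (length(cand) > 1L && !is.null(callrates)) {
      cr <- callrates[cand]
      cand <- cand[order(cr, cand)]
      cand <- cand[1L]
    } else {
      cand <- sort(cand)[1L]
    }
    drop <- c(drop, cand)
    over <- over[over$sample1 != cand & over$sample2 != cand, , drop = FALSE]
  }
  sort(drop)
}
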