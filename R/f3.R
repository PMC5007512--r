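#' Per-locus f3 admixture terms
#'
#' For target c and sources a, b, the per-locus term is
#' `(c - a)(c - b) - h_c`, with the finite-sample correction
#' `h_c = c(1 - c) / (2 n_c - 1)` (toggleable). A significantly
#' negative mean indicates the target is admixed between the sources.
#' Loci with undefined frequency in any population, or with
#' `n_c <= 0`, are skipped (`NA` term).
#'
#' @param freq populations x markers frequency matrix (any consistent
#'   allele orientation)
#' @param n populations x markers diploid sample-size matrix
#' @param target,s1,s2 population labels (rows of `freq`)
#' @param correction apply the h_c finite-sample correction
#' @return numeric vector of per-locus terms (`NA` where skipped)
#' @export
f3PerLocus <- function(freq, n, target, s1, s2, correction = TRUE) {
  c_ <- freq[target, ]; a <- freq[s1, ]; b <- freq[s2, ]
  nc <- n[target, ]
  term <- (c_ - a) * (c_ - b)
  if (correction) term <- term - c_ * (1 - c_) / (2 * nc - 1)
  term[is.na(c_) | is.na(a) | is.na(b) | nc <= 0] <- NA_real_
  term
}

#' Weighted block jackknife over contiguous genomic blocks
#'
#' Loci are grouped into contiguous blocks of `block_bp` (default 5 Mb)
#' per chromosome; the estimate is the mean of the per-locus terms, and
#' the standard error comes from delete-one-block pseudovalues with
#' block weights proportional to the loci per block. `Z = mean / SE`.
#' A single non-empty block is an error; identical terms everywhere
#' give SE 0 and an infinite Z (flagged).
#'
#' @param terms per-locus values (`NA` skipped)
#' @param pos per-locus bp positions
#' @param chrom per-locus chromosome labels
#' @param block_bp block size in bp
#' @return list with `estimate`, `se`, `z`, `n_blocks`, `n_loci`,
#'   `degenerate` (TRUE when SE = 0)
#' @export
blockJackknife <- function(terms, pos, chrom = NULL, block_bp = 5e6) {
  keep <- !is.na(terms)
  terms <- terms[keep]; pos <- pos[keep]
  if (is.null(chrom)) chrom <- rep("1", length(pos)) else chrom <- chrom[keep]
  n <- length(terms)
  block <- paste(chrom, floor(pos / block_bp), sep = ":")
  blocks <- unique(block)
  g <- length(blocks)
  if (g < 2L) stop("only one non-empty block; use a smaller block size")
  est <- mean(terms)
  tot <- sum(terms)
  m <- as.numeric(table(block)[blocks])
  bs <- vapply(blocks, function(b) sum(terms[block == b]), numeric(1))
  theta_j <- (tot - bs) / (n - m)       # delete-one-block means
  h <- n / m
  # weighted jackknife (Busing et al.): pseudovalues with unequal block sizes
  if (var(terms) == 0) {
    return(list(estimate = est, se = 0, z = sign(est) * Inf,
                n_blocks = g, n_loci = n, degenerate = TRUE))
  }
  theta_J <- g * est - sum((1 - m / n) * theta_j)
  var_J <- sum((h * est - (h - 1) * theta_j - theta_J)^2 / (h - 1)) / g
  se <- sqrt(var_J)
  z <- if (se > 0) est / se else sign(est) * Inf
  list(estimate = est, se = se, z = z, n_blocks = g, n_loci = n,
       degenerate = se == 0)
}

#' f3 statistic over all population trios
#'
#' Computes the admixture f3 statistic with block-jackknife Z-scores
#' for every (target; source1, source2) combination of the populations
#' in the frequency table; the sources are unordered.
#'
#' @inheritParams f3PerLocus
#' @param marker_table marker table giving chrom and pos per locus
#' @param block_bp jackknife block size (bp)
#' @return data.frame: target, source1, source2, f3, se, z, n_blocks,
#'   n_loci
#' @export
f3AllTrios <- function(freq, n, marker_table, block_bp = 5e6,
                       correction = TRUE) {
  pops <- rownames(freq)
  out <- list()
  for (tgt in pops) {
    src <- setdiff(pops, tgt)
    if (length(src) < 2L) next
    cmb <- combn(sort(src), 2L)
    for (i in seq_len(ncol(cmb))) {
      terms <- f3PerLocus(freq, n, tgt, cmb[1L, i], cmb[2L, i], correction)
      bj <- blockJackknife(terms, marker_table$pos, marker_table$chrom,
                           block_bp)
      out[[length(out) + 1L]] <- data.frame(
        target = tgt, source1 = cmb[1L, i], source2 = cmb[2L, i],
        f3 = bj$estimate, se = bj$se, z = bj$z,
        n_blocks = bj$n_blocks, n_loci = bj$n_loci,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Rank trios by Z-score and flag the most negative
#'
#' Ascending Z (ties broken by f3); the lowest `top_fraction` are
#' flagged as admixture candidates regardless of sign (the ranking is
#' relative).
#'
#' @param results data.frame from [f3AllTrios()]
#' @param top_fraction fraction to flag (default 1%)
#' @return the input sorted by (z, f3) with columns `rank` and
#'   `candidate`
#' @export
rankTrios <- function(results, top_fraction = 0.01) {
  if (!nrow(results)) {
    results$rank <- integer(); results$candidate <- logical()
    return(results)
  }
  ord <- order(results$z, results$f3)
  results <- results[ord, , drop = FALSE]
  results$rank <- seq_len(nrow(results))
  k <- ceiling(top_fraction * nrow(results))
  results$candidate <- results$rank <= k
  rownames(results) <- NULL
  results
}
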