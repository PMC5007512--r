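#' Joint sliding-window scan of Fst and |iHS| outliers
#'
#' Slides `window_bp` windows (closed intervals, 1-based) in `step_bp`
#' increments over the shared locus universe of the two scans. Per
#' window it counts SNPs and SNPs flagged outlier in BOTH scans,
#' excludes windows below `min_snps`, assigns the survivors to
#' SNP-count classes (deciles by default), ranks within class by
#' descending joint-outlier fraction and flags the top `top_fraction`
#' per class as candidates.
#'
#' @param fst output of [mafBinOutliers()] (columns id, pos, outlier)
#' @param ihs output of [ihsStandardize()] (columns id, pos, outlier)
#' @param window_bp window span (default 200 kb)
#' @param step_bp window advance (default 50 kb)
#' @param min_snps minimum SNPs per window
#' @param n_classes number of SNP-count classes
#' @param top_fraction flagged fraction per class
#' @return data.frame: chrom, start, end, n_snps, n_joint, fraction,
#'   class, class_rank, candidate; empty (with a warning) when no
#'   window passes the floor
#' @export
jointWindowScan <- function(fst, ihs, window_bp = 200000, step_bp = 50000,
                            min_snps = 10, n_classes = 10,
                            top_fraction = 0.01) {
  common <- intersect(fst$id[!is.na(fst$theta)], ihs$id[!is.na(ihs$std)])
  f <- fst[match(common, fst$id), ]
  i <- ihs[match(common, ihs$id), ]
  pos <- f$pos
  joint <- f$outlier & i$outlier
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_snps = integer(),
                      n_joint = integer(), fraction = numeric(),
                      class = integer(), class_rank = integer(),
                      candidate = logical())
  if (!length(pos)) { warning("no shared loci between the scans"); return(empty) }
  starts <- seq(1, max(pos), by = step_bp)
  ord <- order(pos)
  pos <- pos[ord]; joint <- joint[ord]
  cum_joint <- cumsum(joint)
  n_snps <- findInterval(starts + window_bp - 1, pos) - findInterval(starts - 1, pos)
  lo <- findInterval(starts - 1, pos)
  hi <- findInterval(starts + window_bp - 1, pos)
  n_joint <- c(0, cum_joint)[hi + 1] - c(0, cum_joint)[lo + 1]
  win <- data.frame(chrom = "1", start = starts,
                    end = starts + window_bp - 1,
                    n_snps = as.integer(n_snps),
                    n_joint = as.integer(n_joint))
  win <- win[win$n_snps >= min_snps, , drop = FALSE]
  if (!nrow(win)) {
    warning("no window passes the SNP floor")
    return(empty)
  }
  win$fraction <- win$n_joint / win$n_snps
  qs <- unique(quantile(win$n_snps, probs = seq(0, 1, length.out = n_classes + 1)))
  win$class <- as.integer(cut(win$n_snps, breaks = qs, include.lowest = TRUE))
  win$class_rank <- NA_integer_
  win$candidate <- FALSE
  for (cl in unique(win$class)) {
    rows <- which(win$class == cl)
    ord <- rows[order(-win$fraction[rows], win$start[rows])]
    win$class_rank[ord] <- seq_along(ord)
    k <- ceiling(top_fraction * length(ord))
    flag <- ord[seq_len(k)]
    win$candidate[flag] <- win$fraction[flag] > 0
  }
  rownames(win) <- NULL
  win
}

#' Write candidate windows as BED
#'
#' BED uses 0-based half-open coordinates; the package's closed 1-based
#' intervals [start, end] become `start - 1, end`.
#'
#' @param windows data.frame from [jointWindowScan()]
#' @param path output file
#' @param candidates_only write only flagged candidate windows
#' @return `path`, invisibly
#' @export
writeWindowsBed <- function(windows, path, candidates_only = TRUE) {
  w <- if (candidates_only) windows[windows$candidate, , drop = FALSE]
       else windows
  bed <- data.frame(w$chrom, w$start - 1, w$end,
                    sprintf("win_%d", seq_len(nrow(w))),
                    round(1000 * w$fraction))
  write.table(bed, path, quote = FALSE, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
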