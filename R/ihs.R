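#' Extended haplotype homozygosity curve
#'
#' For carriers of `allele` at the `core` marker within one group of
#' haplotypes, partitions the carriers by identity of their extended
#' haplotype at each successive marker outward and returns
#' `EHH = sum_groups C(size, 2) / C(n_carriers, 2)`. EHH at the core is
#' 1 and the curve is monotone non-increasing outward. Needs at least
#' two carriers.
#'
#' @param haps a [HaplotypeSet-class]
#' @param core marker index of the core SNP
#' @param allele 0 (ancestral-coded allele_a) or 1 (allele_b)
#' @param direction `"right"` or `"left"` of the core
#' @param which_samples optional sample subset (e.g. one cluster)
#' @return data.frame with columns pos and ehh, ordered outward from
#'   the core (the core itself, EHH = 1, is the first row)
#' @export
ehhCurve <- function(haps, core, allele, direction = c("right", "left"),
                     which_samples = NULL) {
  direction <- match.arg(direction)
  H <- haplotypes(haps)
  if (!is.null(which_samples)) {
    if (is.logical(which_samples)) which_samples <- which(which_samples)
    H <- H[.hap_rows(which_samples), , drop = FALSE]
  }
  carriers <- which(H[, core] == allele)
  if (length(carriers) < 2L) stop("core allele must have >= 2 carriers")
  pos <- markers(haps)$pos
  cols <- if (direction == "right") seq(core + 1L, ncol(H))
          else rev(seq_len(core - 1L))
  if (direction == "right" && core == ncol(H)) cols <- integer()
  if (direction == "left" && core == 1L) cols <- integer()
  e <- .ehh_curve_cpp(H, carriers - 1L, as.integer(cols - 1L))
  data.frame(pos = c(pos[core], pos[cols]), ehh = c(1, e))
}

#' Unstandardized integrated haplotype score for one locus
#'
#' Integrates (trapezoid, physical bp) the EHH curves of the ancestral
#' and derived carrier sets in both directions from the core, stopping
#' when EHH drops below `ehh_cutoff`, at inter-marker gaps above
#' `max_gap` (integration truncated before the gap) or at the
#' chromosome end (flagged). The score is
#' `ln(iHH_A / iHH_D)`; a sweep on the derived allele inflates iHH_D
#' and drives the score negative.
#'
#' @param haps a [HaplotypeSet-class]
#' @param locus core marker index (must have known ancestral allele)
#' @param which_samples optional sample subset
#' @param ehh_cutoff EHH level at which integration stops
#' @param max_gap maximum tolerated inter-marker gap (bp)
#' @return list: ihh_a, ihh_d, unstd, daf, truncated (logical),
#'   defined
#' @export
ihsUnstandardized <- function(haps, locus, which_samples = NULL,
                              ehh_cutoff = 0.05, max_gap = 20000) {
  mk <- markers(haps)
  anc <- mk$ancestral[locus]
  if (is.na(anc)) return(list(ihh_a = NA_real_, ihh_d = NA_real_,
                              unstd = NA_real_, daf = NA_real_,
                              truncated = NA, defined = FALSE))
  H <- haplotypes(haps)
  if (!is.null(which_samples)) {
    if (is.logical(which_samples)) which_samples <- which(which_samples)
    H <- H[.hap_rows(which_samples), , drop = FALSE]
  }
  anc_code <- if (anc == mk$allele_a[locus]) 0L else 1L
  der_code <- 1L - anc_code
  pos <- as.numeric(mk$pos)
  a_rows <- which(H[, locus] == anc_code)
  d_rows <- which(H[, locus] == der_code)
  daf <- length(d_rows) / nrow(H)
  if (length(a_rows) < 2L || length(d_rows) < 2L)
    return(list(ihh_a = NA_real_, ihh_d = NA_real_, unstd = NA_real_,
                daf = daf, truncated = NA, defined = FALSE))
  ihh <- function(rows) {
    r <- .ihh_one_side_cpp(H, rows - 1L, locus - 1L, pos, 1L,
                           ehh_cutoff, max_gap)
    l <- .ihh_one_side_cpp(H, rows - 1L, locus - 1L, pos, -1L,
                           ehh_cutoff, max_gap)
    c(area = r[1L] + l[1L], trunc = max(r[2L], l[2L]))
  }
  ia <- ihh(a_rows); id <- ihh(d_rows)
  if (is.na(ia[1L]) || is.na(id[1L]) || ia[1L] == 0 || id[1L] == 0)
    return(list(ihh_a = unname(ia[1L]), ihh_d = unname(id[1L]),
                unstd = NA_real_, daf = daf,
                truncated = any(c(ia[2L], id[2L]) > 0), defined = FALSE))
  list(ihh_a = unname(ia[1L]), ihh_d = unname(id[1L]),
       unstd = log(ia[[1L]] / id[[1L]]), daf = daf,
       truncated = any(c(ia[2L], id[2L]) > 0), defined = TRUE)
}

#' Genome scan of unstandardized iHS within one cluster
#'
#' Applies [ihsUnstandardized()] to every marker with known ancestral
#' allele and at least `min_carriers` carriers of each allele in the
#' chosen cluster.
#'
#' @param haps a [HaplotypeSet-class]
#' @param cluster cluster label (NULL = all samples)
#' @param loci optional marker indices to scan
#' @param min_daf skip loci whose derived-allele frequency in the
#'   cluster is below this (they are excluded from standardization
#'   anyway); set to 0 to scan everything
#' @inheritParams ihsUnstandardized
#' @return data.frame: id, pos, daf, ihh_a, ihh_d, unstd, truncated,
#'   defined
#' @export
ihsScan <- function(haps, cluster = NULL, loci = NULL, ehh_cutoff = 0.05,
                    max_gap = 20000, min_daf = 0) {
  mk <- markers(haps)
  which_samples <- if (is.null(cluster)) NULL
                   else which(samples(haps)$cluster == cluster)
  if (is.null(loci)) loci <- seq_len(nMarkers(haps))
  daf <- derivedFreq(haps, which_samples)
  scan <- loci[!is.na(daf[loci]) & daf[loci] >= min_daf &
               daf[loci] < 1 & daf[loci] > 0]
  H <- haplotypes(haps)
  if (!is.null(which_samples)) H <- H[.hap_rows(which_samples), , drop = FALSE]
  pos <- as.numeric(mk$pos)
  n <- length(scan)
  ihh_a <- ihh_d <- unstd <- rep(NA_real_, n)
  truncated <- defined <- rep(FALSE, n)
  der_code <- ifelse(mk$ancestral == mk$allele_a, 1L, 0L)
  ihh_both <- function(rows, j) {
    r <- .ihh_one_side_cpp(H, rows - 1L, j - 1L, pos, 1L, ehh_cutoff, max_gap)
    l <- .ihh_one_side_cpp(H, rows - 1L, j - 1L, pos, -1L, ehh_cutoff, max_gap)
    c(r[1L] + l[1L], max(r[2L], l[2L]))
  }
  for (k in seq_len(n)) {
    j <- scan[k]
    d_rows <- which(H[, j] == der_code[j])
    if (length(d_rows) < 2L || nrow(H) - length(d_rows) < 2L) next
    a_rows <- seq_len(nrow(H))[-d_rows]
    ia <- ihh_both(a_rows, j)
    id <- ihh_both(d_rows, j)
    ihh_a[k] <- ia[1L]; ihh_d[k] <- id[1L]
    truncated[k] <- any(c(ia[2L], id[2L]) > 0)
    if (!is.na(ia[1L]) && !is.na(id[1L]) && ia[1L] > 0 && id[1L] > 0) {
      unstd[k] <- log(ia[1L] / id[1L])
      defined[k] <- TRUE
    }
  }
  out <- data.frame(id = mk$id[scan], pos = mk$pos[scan], daf = daf[scan],
                    ihh_a = ihh_a, ihh_d = ihh_d, unstd = unstd,
                    truncated = truncated, defined = defined,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Standardize iHS in derived-allele-frequency bins
#'
#' Loci with DAF below `min_daf` (default 0.2) are excluded; within
#' each DAF bin of `bin_width` (default 10%), scores are centered and
#' scaled to mean 0, SD 1. Bins with fewer than `min_bin` loci are
#' merged with their nearest neighbour (with a message); a bin with
#' zero score variance is flagged degenerate and emits no scores.
#' Finally the top `top_fraction` of |standardized iHS| genome-wide is
#' flagged as outliers.
#'
#' @param records data.frame from [ihsScan()]
#' @param bin_width DAF bin width
#' @param min_daf minimum DAF retained
#' @param min_bin minimum loci per bin before merging
#' @param top_fraction outlier fraction on |std|
#' @return the retained records with columns `daf_bin`, `std`,
#'   `outlier`
#' @export
ihsStandardize <- function(records, bin_width = 0.10, min_daf = 0.2,
                           min_bin = 20, top_fraction = 0.01) {
  rec <- records[records$defined & !is.na(records$unstd) &
                 records$daf >= min_daf, , drop = FALSE]
  if (!nrow(rec)) {
    rec$daf_bin <- integer(); rec$std <- numeric(); rec$outlier <- logical()
    return(rec)
  }
  bin <- pmin(floor(rec$daf / bin_width), ceiling(1 / bin_width) - 1L)
  # merge sparse bins with their nearest non-sparse neighbour
  repeat {
    tab <- table(bin)
    small <- names(tab)[tab < min_bin]
    if (!length(small) || length(tab) == 1L) break
    b <- as.integer(small[1L])
    others <- as.integer(setdiff(names(tab), small[1L]))
    nb <- others[which.min(abs(others - b))]
    message(sprintf("iHS bin %d has < %d loci; merged into bin %d",
                    b, min_bin, nb))
    bin[bin == b] <- nb
  }
  rec$daf_bin <- as.integer(bin)
  rec$std <- NA_real_
  for (b in unique(bin)) {
    i <- which(bin == b)
    s <- sd(rec$unstd[i])
    if (is.na(s) || s == 0) {
      warning(sprintf("iHS bin %d has zero score variance; flagged degenerate", b))
      next
    }
    rec$std[i] <- (rec$unstd[i] - mean(rec$unstd[i])) / s
  }
  rec$outlier <- FALSE
  ok <- which(!is.na(rec$std))
  k <- ceiling(top_fraction * length(ok))
  if (k > 0 && length(ok)) {
    thr <- sort(abs(rec$std[ok]), decreasing = TRUE)[k]
    rec$outlier[ok] <- abs(rec$std[ok]) >= thr
  }
  rownames(rec) <- NULL
  rec
}
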