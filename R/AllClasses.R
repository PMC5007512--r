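#' @import methods
#' @importFrom stats rbeta rbinom runif rnorm cor quantile var sd
#'   pchisq fisher.test dhyper setNames complete.cases prcomp predict
#'   residuals
#' @importFrom utils read.table write.table combn head
#' @useDynLib popgenscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.valid_marker_table <- function(m) {
  msg <- character()
  need <- c("id", "chrom", "pos", "allele_a", "allele_b", "ancestral")
  if (!all(need %in% names(m)))
    return(paste("marker table must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(m$id)) msg <- c(msg, "marker ids must be unique")
  if (any(m$pos < 1, na.rm = TRUE)) msg <- c(msg, "positions are 1-based (>= 1)")
  for (ch in unique(m$chrom)) {
    p <- m$pos[m$chrom == ch]
    if (is.unsorted(p)) msg <- c(msg, sprintf("positions not sorted on chrom %s", ch))
  }
  ok <- is.na(m$ancestral) | m$ancestral == m$allele_a | m$ancestral == m$allele_b
  if (!all(ok)) msg <- c(msg, "ancestral must equal allele_a, allele_b or NA")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
}

.valid_sample_table <- function(s) {
  msg <- character()
  need <- c("sample_id", "province", "cluster", "lat", "lon")
  if (!all(need %in% names(s)))
    return(paste("sample table must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(s$sample_id)) msg <- c(msg, "sample ids must be unique")
  if (!all(is.finite(s$lat)) || !all(is.finite(s$lon)))
    msg <- c(msg, "coordinates must be finite")
  pc <- unique(s[, c("province", "cluster")])
  if (anyDuplicated(pc$province))
    msg <- c(msg, "each province must belong to exactly one cluster")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
}

#' Diploid genotype container
#'
#' Holds a samples x markers matrix of allele-b dosages (0, 1, 2 or `NA`
#' for missing), a marker table (id, chrom, 1-based pos, alleles,
#' ancestral-allele annotation) and a sample table (sample_id, province,
#' cluster, lat, lon). Provinces partition into clusters; marker
#' positions are sorted within chromosome.
#'
#' @slot geno integer matrix, samples x markers; `NA` = missing call.
#' @slot markers data.frame with columns id, chrom, pos, allele_a,
#'   allele_b, ancestral (one of the alleles, or `NA` if unknown).
#' @slot samples data.frame with columns sample_id, province, cluster,
#'   lat, lon.
#' @export
setClass("GenotypeData", representation(
  geno = "matrix", markers = "data.frame", samples = "data.frame"
))

setValidity("GenotypeData", function(object) {
  msg <- character()
  g <- object@geno
  if (nrow(g) != nrow(object@samples))
    msg <- c(msg, "nrow(geno) != nrow(samples)")
  if (ncol(g) != nrow(object@markers))
    msg <- c(msg, "ncol(geno) != nrow(markers)")
  if (!all(g %in% c(0L, 1L, 2L, NA)))
    msg <- c(msg, "genotypes must be 0, 1, 2 or NA")
  v <- .valid_marker_table(object@markers); if (!isTRUE(v)) msg <- c(msg, v)
  v <- .valid_sample_table(object@samples); if (!isTRUE(v)) msg <- c(msg, v)
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Phased haplotype container
#'
#' Binary haplotype matrix (2 rows per sample: `<id>_1`, `<id>_2`) over
#' the same marker/sample metadata as [GenotypeData-class]. Entry 1 means
#' the haplotype carries allele_b. Collapsing the two rows of a sample
#' reproduces its genotype dosage.
#'
#' @slot haps integer 0/1 matrix, (2 x samples) x markers.
#' @slot markers marker table as in [GenotypeData-class].
#' @slot samples sample table as in [GenotypeData-class].
#' @export
setClass("HaplotypeSet", representation(
  haps = "matrix", markers = "data.frame", samples = "data.frame"
))

setValidity("HaplotypeSet", function(object) {
  msg <- character()
  h <- object@haps
  if (nrow(h) != 2L * nrow(object@samples))
    msg <- c(msg, "nrow(haps) must be 2 * nrow(samples)")
  if (ncol(h) != nrow(object@markers))
    msg <- c(msg, "ncol(haps) != nrow(markers)")
  if (!all(h %in% c(0L, 1L)))
    msg <- c(msg, "haplotypes must be binary")
  v <- .valid_marker_table(object@markers); if (!isTRUE(v)) msg <- c(msg, v)
  v <- .valid_sample_table(object@samples); if (!isTRUE(v)) msg <- c(msg, v)
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Ground truth of a simulated dataset
#'
#' Records every planted feature of a simulation so detector output can
#' be scored: indices of planted differentiated loci (per target
#' cluster), planted sweep intervals (closed, bp), planted related
#' sample pairs, planted Hardy-Weinberg violator loci, planted low
#' call-rate loci, and the per-locus ancestral allele frequencies.
#'
#' @export
setClass("GroundTruth", representation(
  outlier_loci = "data.frame",   # locus, cluster, shift
  sweep_windows = "data.frame",  # chrom, start, end, cluster, center_locus
  related_pairs = "data.frame",  # sample1, sample2, relation
  hwe_violators = "integer",
  lowcall_loci = "integer",
  ancestral_freqs = "numeric"
))

# ---- generics ----------------------------------------------------------

#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))
#' @export
setGeneric("asGenotypes", function(x, ...) standardGeneric("asGenotypes"))

#' @describeIn GenotypeData-class number of samples
#' @param x a `GenotypeData` or `HaplotypeSet`
#' @export
setMethod("nSamples", "GenotypeData", function(x) nrow(x@samples))
#' @export
setMethod("nSamples", "HaplotypeSet", function(x) nrow(x@samples))
#' @describeIn GenotypeData-class number of markers
#' @export
setMethod("nMarkers", "GenotypeData", function(x) nrow(x@markers))
#' @export
setMethod("nMarkers", "HaplotypeSet", function(x) nrow(x@markers))
#' @describeIn GenotypeData-class marker metadata table
#' @export
setMethod("markers", "GenotypeData", function(x) x@markers)
#' @export
setMethod("markers", "HaplotypeSet", function(x) x@markers)
#' @describeIn GenotypeData-class sample metadata table
#' @export
setMethod("samples", "GenotypeData", function(x) x@samples)
#' @export
setMethod("samples", "HaplotypeSet", function(x) x@samples)
#' @describeIn GenotypeData-class the dosage matrix
#' @export
setMethod("genotypes", "GenotypeData", function(x) x@geno)
#' @describeIn HaplotypeSet-class the binary haplotype matrix
#' @param x a `HaplotypeSet`
#' @export
setMethod("haplotypes", "HaplotypeSet", function(x) x@haps)

#' @describeIn HaplotypeSet-class collapse haplotype pairs into dosages
#' @param ... unused
#' @export
setMethod("asGenotypes", "HaplotypeSet", function(x, ...) {
  n <- nSamples(x)
  g <- x@haps[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
       x@haps[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  storage.mode(g) <- "integer"
  rownames(g) <- x@samples$sample_id
  colnames(g) <- x@markers$id
  new("GenotypeData", geno = g, markers = x@markers, samples = x@samples)
})

setMethod("show", "GenotypeData", function(object) {
  cat(sprintf(
    "GenotypeData: %d samples x %d markers (%.2f%% missing)\n",
    nSamples(object), nMarkers(object),
    100 * mean(is.na(object@geno))))
  cat("  clusters:", paste(unique(object@samples$cluster), collapse = ", "), "\n")
})

setMethod("show", "HaplotypeSet", function(object) {
  cat(sprintf("HaplotypeSet: %d haplotypes (%d samples) x %d markers\n",
              2L * nSamples(object), nSamples(object), nMarkers(object)))
  cat("  clusters:", paste(unique(object@samples$cluster), collapse = ", "), "\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:",
      nrow(object@outlier_loci), "planted outlier loci,",
      nrow(object@sweep_windows), "sweeps,",
      nrow(object@related_pairs), "related pairs,",
      length(object@hwe_violators), "HWE violators,",
      length(object@lowcall_loci), "low-call loci\n")
})

#' Construct a GenotypeData object
#'
#' @param geno samples x markers dosage matrix (0/1/2/NA).
#' @param markers marker table (id, chrom, pos, allele_a, allele_b,
#'   ancestral).
#' @param samples sample table (sample_id, province, cluster, lat, lon).
#' @return a validated [GenotypeData-class] object.
#' @export
GenotypeData <- function(geno, markers, samples) {
  storage.mode(geno) <- "integer"
  rownames(geno) <- samples$sample_id
  colnames(geno) <- markers$id
  new("GenotypeData", geno = geno,
      markers = as.data.frame(markers), samples = as.data.frame(samples))
}

#' Construct a HaplotypeSet object
#'
#' @param haps (2 x samples) x markers binary matrix, sample-major
#'   (rows 2i-1 and 2i are the two haplotypes of sample i).
#' @inheritParams GenotypeData
#' @return a validated [HaplotypeSet-class] object.
#' @export
HaplotypeSet <- function(haps, markers, samples) {
  storage.mode(haps) <- "integer"
  rownames(haps) <- paste0(rep(samples$sample_id, each = 2L), c("_1", "_2"))
  colnames(haps) <- markers$id
  new("HaplotypeSet", haps = haps,
      markers = as.data.frame(markers), samples = as.data.frame(samples))
}

# rows of the haplotype matrix belonging to given sample indices
.hap_rows <- function(sample_idx) {
  as.vector(rbind(2L * sample_idx - 1L, 2L * sample_idx))
}

#' Derived-allele frequency per marker
#'
#' Frequency of the annotated derived (non-ancestral) allele, computed
#' from haplotypes or genotypes over a subset of samples. Markers with
#' unknown ancestral allele get `NA`.
#'
#' @param x a [HaplotypeSet-class] or [GenotypeData-class]
#' @param which_samples integer or logical index into samples (default
#'   all)
#' @return numeric vector of derived-allele frequencies
#' @export
derivedFreq <- function(x, which_samples = NULL) {
  m <- markers(x)
  if (is.null(which_samples)) which_samples <- seq_len(nSamples(x))
  if (is.logical(which_samples)) which_samples <- which(which_samples)
  if (is(x, "HaplotypeSet")) {
    fb <- colMeans(x@haps[.hap_rows(which_samples), , drop = FALSE])
  } else {
    fb <- colMeans(x@geno[which_samples, , drop = FALSE], na.rm = TRUE) / 2
  }
  daf <- ifelse(is.na(m$ancestral), NA_real_,
                ifelse(m$ancestral == m$allele_a, fb, 1 - fb))
  unname(daf)
}
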