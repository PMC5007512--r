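#' Write genotypes or haplotypes to VCF 4.2
#'
#' Emits one biallelic SNP record per marker, sorted by (chrom, pos),
#' with the ancestral allele in the `AA` INFO tag when known.
#' [HaplotypeSet-class] input is written phased (`0|1`),
#' [GenotypeData-class] unphased (`0/1`, missing as `./.`). REF is
#' allele_a, ALT allele_b.
#'
#' @param x a [HaplotypeSet-class] or [GenotypeData-class]
#' @param path output file (plain text)
#' @return `path`, invisibly
#' @export
writeGenoVcf <- function(x, path) {
  mk <- markers(x)
  smp <- samples(x)
  phased <- is(x, "HaplotypeSet")
  n <- nSamples(x)
  if (phased) {
    h <- x@haps
    gt <- matrix(paste(h[seq(1L, 2L * n, 2L), , drop = FALSE],
                       h[seq(2L, 2L * n, 2L), , drop = FALSE], sep = "|"),
                 nrow = n)
  } else {
    g <- x@geno
    code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- matrix("./.", nrow = n, ncol = ncol(g))
    ok <- !is.na(g)
    gt[ok] <- code[as.character(g[ok])]
  }
  info <- ifelse(is.na(mk$ancestral), ".", paste0("AA=", mk$ancestral))
  ord <- order(mk$chrom, mk$pos)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", smp$sample_id), collapse = "\t"))
  body <- vapply(ord, function(j) {
    paste(c(mk$chrom[j], mk$pos[j], mk$id[j], mk$allele_a[j], mk$allele_b[j],
            ".", "PASS", info[j], "GT", gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a VCF of biallelic SNPs
#'
#' Parses with `vcfR`. Fully phased files (`|` separators throughout)
#' yield a [HaplotypeSet-class]; otherwise a [GenotypeData-class].
#' The `AA` INFO tag populates the ancestral-allele column. Records
#' that are multi-allelic or not SNPs are skipped with a message.
#'
#' @param path VCF file
#' @param sample_table optional sample table (as from
#'   [readSampleTable()]); defaults to one province/cluster for all
#'   samples at coordinate 0.
#' @return [HaplotypeSet-class] or [GenotypeData-class]
#' @export
readGenoVcf <- function(path, sample_table = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  snp <- !is.na(fix$ALT) & nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE)
  if (any(!snp))
    message(sum(!snp), " non-SNP or multi-allelic records skipped")
  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  aa <- sub(".*AA=([^;]+).*", "\\1", fix$INFO)
  aa[!grepl("AA=", fix$INFO)] <- NA_character_
  aa[!(aa == fix$REF | aa == fix$ALT)] <- NA_character_
  mk <- data.frame(id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
                   allele_a = fix$REF, allele_b = fix$ALT, ancestral = aa,
                   stringsAsFactors = FALSE)
  ord <- order(mk$chrom, mk$pos)
  mk <- mk[ord, , drop = FALSE]
  gt <- gt[ord, , drop = FALSE]
  rownames(mk) <- NULL
  ids <- colnames(gt)
  if (is.null(sample_table)) {
    sample_table <- data.frame(sample_id = ids, province = "P1",
                               cluster = "CL1", lat = 0, lon = 0,
                               stringsAsFactors = FALSE)
  } else {
    sample_table <- sample_table[match(ids, sample_table$sample_id), ,
                                 drop = FALSE]
    if (anyNA(sample_table$sample_id))
      stop("sample table does not cover all VCF samples")
    rownames(sample_table) <- NULL
  }
  phased <- all(grepl("|", gt, fixed = TRUE) | is.na(gt))
  if (phased && !anyNA(gt)) {
    M <- nrow(mk); n <- length(ids)
    a1 <- substr(gt, 1L, 1L); a2 <- substr(gt, 3L, 3L)
    H <- matrix(0L, nrow = 2L * n, ncol = M)
    H[seq(1L, 2L * n, 2L), ] <- as.integer(t(matrix(as.integer(a1), M, n)))
    H[seq(2L, 2L * n, 2L), ] <- as.integer(t(matrix(as.integer(a2), M, n)))
    return(HaplotypeSet(H, mk, sample_table))
  }
  g <- matrix(NA_integer_, nrow = length(ids), ncol = nrow(mk))
  known <- !is.na(gt) & !grepl(".", gt, fixed = TRUE)
  dose <- (substr(gt, 1L, 1L) == "1") + (substr(gt, 3L, 3L) == "1")
  g[t(known)] <- as.integer(t(dose)[t(known)])
  GenotypeData(g, mk, sample_table)
}

#' Write PLINK-style text files (.ped/.map)
#'
#' @param x a [GenotypeData-class]
#' @param prefix output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`
#' @return `prefix`, invisibly
#' @export
writePlinkText <- function(x, prefix) {
  mk <- markers(x)
  g <- genotypes(x)
  smp <- samples(x)
  map <- data.frame(mk$chrom, mk$id, 0, mk$pos)
  write.table(map, paste0(prefix, ".map"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  al <- matrix("0", nrow = nrow(g), ncol = 2L * ncol(g))
  for (j in seq_len(ncol(g))) {
    a <- mk$allele_a[j]; b <- mk$allele_b[j]
    gj <- g[, j]
    first <- ifelse(is.na(gj), "0", ifelse(gj >= 1L, b, a))
    second <- ifelse(is.na(gj), "0", ifelse(gj == 2L, b, a))
    al[, 2L * j - 1L] <- first
    al[, 2L * j] <- second
  }
  ped <- cbind(smp$province, smp$sample_id, 0, 0, 0, -9, al)
  write.table(ped, paste0(prefix, ".ped"), quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK-style text files (.ped/.map)
#'
#' Allele coding is resolved per locus from the observed alleles
#' (lexicographically first allele becomes allele_a); `0 0` means
#' missing. More than two observed alleles at a locus is an error.
#'
#' @param ped,map file paths
#' @param sample_table optional sample table keyed by sample_id
#' @return a [GenotypeData-class] (ancestral alleles unknown)
#' @export
readPlinkText <- function(ped, map, sample_table = NULL) {
  mp <- read.table(map, header = FALSE, stringsAsFactors = FALSE)
  pd <- read.table(ped, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  M <- nrow(mp)
  if (ncol(pd) != 6L + 2L * M)
    stop(sprintf("ped has %d allele columns but map lists %d markers",
                 ncol(pd) - 6L, M))
  ids <- pd[[2]]
  g <- matrix(NA_integer_, nrow = nrow(pd), ncol = M)
  allele_a <- allele_b <- character(M)
  for (j in seq_len(M)) {
    a1 <- pd[[6L + 2L * j - 1L]]
    a2 <- pd[[6L + 2L * j]]
    obs <- setdiff(sort(unique(c(a1, a2))), "0")
    if (length(obs) > 2L)
      stop(sprintf("more than 2 alleles at marker %s", mp[[2]][j]))
    if (length(obs) == 0L) obs <- c("A", "A")
    if (length(obs) == 1L) obs <- c(obs, obs)
    allele_a[j] <- obs[1L]; allele_b[j] <- obs[2L]
    miss <- a1 == "0" | a2 == "0"
    g[, j] <- (a1 == obs[2L]) + (a2 == obs[2L])
    if (obs[1L] == obs[2L]) g[, j] <- 0L  # monomorphic: zero copies of allele_b
    g[miss, j] <- NA_integer_
  }
  mk <- data.frame(id = mp[[2]], chrom = as.character(mp[[1]]),
                   pos = as.integer(mp[[4]]), allele_a = allele_a,
                   allele_b = allele_b, ancestral = NA_character_,
                   stringsAsFactors = FALSE)
  ord <- order(mk$chrom, mk$pos)
  mk <- mk[ord, , drop = FALSE]; rownames(mk) <- NULL
  g <- g[, ord, drop = FALSE]
  if (is.null(sample_table))
    sample_table <- data.frame(sample_id = ids, province = pd[[1]],
                               cluster = pd[[1]], lat = 0, lon = 0,
                               stringsAsFactors = FALSE)
  GenotypeData(g, mk, sample_table)
}

#' Write / read the sample table as TSV
#'
#' Columns: sample_id, province, cluster, lat, lon.
#'
#' @param s sample table data.frame
#' @param path TSV path
#' @return `path` invisibly / the data.frame
#' @export
writeSampleTable <- function(s, path) {
  write.table(s[, c("sample_id", "province", "cluster", "lat", "lon")],
              path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname writeSampleTable
#' @export
readSampleTable <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Per-group allele frequencies and sample counts
#'
#' Frequency of allele_b per group = allele_b count / (2 x non-missing
#' samples). Groups with zero non-missing calls at a locus get `NA`
#' frequency (flagged, never silently 0).
#'
#' @param G a [GenotypeData-class]
#' @param grouping `"cluster"` or `"province"`
#' @return list with `freq` (groups x markers), `n` (non-missing
#'   diploid counts, groups x markers) and `undefined` (logical matrix)
#' @export
groupFreqs <- function(G, grouping = c("cluster", "province")) {
  grouping <- match.arg(grouping)
  fac <- samples(G)[[grouping]]
  g <- genotypes(G)
  labs <- unique(fac)
  freq <- nmat <- matrix(NA_real_, nrow = length(labs), ncol = ncol(g),
                         dimnames = list(labs, colnames(g)))
  for (k in seq_along(labs)) {
    sub <- g[fac == labs[k], , drop = FALSE]
    n <- colSums(!is.na(sub))
    cnt <- colSums(sub, na.rm = TRUE)
    nmat[k, ] <- n
    freq[k, ] <- ifelse(n > 0, cnt / (2 * n), NA_real_)
  }
  list(freq = freq, n = nmat, undefined = nmat == 0)
}

#' Per-group derived-allele frequencies
#'
#' Like [groupFreqs()] but oriented to the annotated derived allele;
#' markers without ancestral annotation get `NA`.
#'
#' @inheritParams groupFreqs
#' @return list with `freq` (derived-allele frequency) and `n`
#' @export
groupDerivedFreqs <- function(G, grouping = c("cluster", "province")) {
  gf <- groupFreqs(G, grouping)
  mk <- markers(G)
  flip <- !is.na(mk$ancestral) & mk$ancestral == mk$allele_b
  unknown <- is.na(mk$ancestral)
  f <- gf$freq
  f[, flip] <- 1 - f[, flip]
  f[, unknown] <- NA_real_
  list(freq = f, n = gf$n)
}
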