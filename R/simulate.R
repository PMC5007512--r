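#' Simulation configuration
#'
#' Parameters of the structured-genotype simulator. Populations are
#' organised as `n_clusters` geographic clusters on a north-south line,
#' each split into `provinces_per_cluster` provinces. Allele frequencies
#' drift from a common ancestral frequency under the Balding-Nichols
#' model, first to the cluster level (drift `cluster_F`), then to the
#' province level (drift `province_F`). On top of the neutral
#' background, highly differentiated loci and selective sweeps can be
#' planted, and QC defects (missing calls, low-call loci, HWE violator
#' loci, related sample pairs) injected.
#'
#' @slot n_clusters,provinces_per_cluster,n_per_province design counts.
#' @slot n_snps number of SNPs on the single simulated chromosome.
#' @slot chrom_length_bp chromosome length in bp.
#' @slot cluster_F,province_F Balding-Nichols drift parameters in
#'   [0, 0.5]; 0 means no drift at that level.
#' @slot planted_daf_loci data.frame (locus, cluster, shift): at marker
#'   index `locus`, the target cluster's derived-allele frequency is
#'   moved `shift` above the mean of the other clusters.
#' @slot planted_sweeps data.frame (center_bp, cluster, freq,
#'   length_bp): a haplotype-copying sweep of the given derived-allele
#'   frequency and extent planted in the target cluster.
#' @slot missing_rate per-call missing probability.
#' @slot n_lowcall_loci loci forced below 95% call rate.
#' @slot n_hwe_violators loci overwritten as all-heterozygote in one
#'   province.
#' @slot n_related_pairs parent-child pairs appended to the panel.
#' @slot seed RNG seed (mandatory; every run is bit-reproducible).
#' @slot topology `"star"` (independent cluster drift), `"serial"`
#'   (stepping-stone along the north-south chain) or `"cline"`
#'   (admixture gradient between two drifted endpoint pools).
#' @export
setClass("SimConfig", representation(
  n_clusters = "integer", provinces_per_cluster = "integer",
  n_per_province = "integer", n_snps = "integer",
  chrom_length_bp = "numeric", cluster_F = "numeric",
  province_F = "numeric", planted_daf_loci = "data.frame",
  planted_sweeps = "data.frame", missing_rate = "numeric",
  n_lowcall_loci = "integer", n_hwe_violators = "integer",
  n_related_pairs = "integer", seed = "integer", topology = "character"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@cluster_F < 0 || object@cluster_F > 0.5)
    msg <- c(msg, "cluster_F must be in [0, 0.5]")
  if (object@province_F < 0 || object@province_F > 0.5)
    msg <- c(msg, "province_F must be in [0, 0.5]")
  if (object@chrom_length_bp <= 0) msg <- c(msg, "chrom_length_bp must be > 0")
  if (object@missing_rate < 0 || object@missing_rate > 1)
    msg <- c(msg, "missing_rate must be in [0, 1]")
  pd <- object@planted_daf_loci
  if (nrow(pd)) {
    if (anyDuplicated(pd$locus)) msg <- c(msg, "planted loci indices must be distinct")
    if (any(pd$locus < 1 | pd$locus > object@n_snps))
      msg <- c(msg, "planted locus index out of range")
  }
  ps <- object@planted_sweeps
  if (nrow(ps)) {
    if (any(ps$freq <= 0 | ps$freq >= 1))
      msg <- c(msg, "sweep frequency must be in (0, 1)")
    if (any(ps$center_bp - ps$length_bp / 2 < 1 |
            ps$center_bp + ps$length_bp / 2 > object@chrom_length_bp))
      msg <- c(msg, "sweep interval outside chromosome")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Build a simulation configuration
#'
#' Defaults emulate a peninsular sampling design: 4 clusters of 5
#' provinces, 37 diploids per province (185 per cluster, 740 total),
#' cluster-level drift F = 0.005 and province-level F = 0.001 (realised
#' pairwise cluster Fst of a few per mille), 10,000 SNPs on a 200-Mb
#' chromosome.
#'
#' @param n_clusters,provinces_per_cluster,n_per_province design counts
#' @param n_snps,chrom_length_bp marker panel size and chromosome span
#' @param cluster_F,province_F Balding-Nichols drift at each level
#' @param planted_daf_loci data.frame (locus, cluster, shift) or NULL
#' @param planted_sweeps data.frame (center_bp, cluster, freq,
#'   length_bp) or NULL
#' @param missing_rate,n_lowcall_loci,n_hwe_violators,n_related_pairs
#'   QC-defect intensities
#' @param seed mandatory integer RNG seed
#' @param topology `"star"`: every cluster drifts independently from
#'   the ancestor (isotropic differentiation); `"serial"`:
#'   stepping-stone drift along the north-south cluster chain;
#'   `"cline"`: an admixture gradient between two endpoint pools
#'   drifted from the ancestor, the sharpest realisation of a
#'   latitudinal cline (genetic structure mirrors the geographic
#'   layout exactly, up to sampling noise)
#' @return a [SimConfig-class]
#' @export
simConfig <- function(n_clusters = 4, provinces_per_cluster = 5,
                      n_per_province = 37, n_snps = 10000,
                      chrom_length_bp = 2e8, cluster_F = 0.005,
                      province_F = 0.001, planted_daf_loci = NULL,
                      planted_sweeps = NULL, missing_rate = 0,
                      n_lowcall_loci = 0, n_hwe_violators = 0,
                      n_related_pairs = 0, seed,
                      topology = c("star", "serial", "cline")) {
  if (missing(seed)) stop("seed is mandatory")
  topology <- match.arg(topology)
  if (is.null(planted_daf_loci))
    planted_daf_loci <- data.frame(locus = integer(), cluster = character(),
                                   shift = numeric())
  if (is.null(planted_sweeps))
    planted_sweeps <- data.frame(center_bp = numeric(), cluster = character(),
                                 freq = numeric(), length_bp = numeric())
  new("SimConfig",
      n_clusters = as.integer(n_clusters),
      provinces_per_cluster = as.integer(provinces_per_cluster),
      n_per_province = as.integer(n_per_province),
      n_snps = as.integer(n_snps),
      chrom_length_bp = as.numeric(chrom_length_bp),
      cluster_F = as.numeric(cluster_F),
      province_F = as.numeric(province_F),
      planted_daf_loci = as.data.frame(planted_daf_loci),
      planted_sweeps = as.data.frame(planted_sweeps),
      missing_rate = as.numeric(missing_rate),
      n_lowcall_loci = as.integer(n_lowcall_loci),
      n_hwe_violators = as.integer(n_hwe_violators),
      n_related_pairs = as.integer(n_related_pairs),
      seed = as.integer(seed), topology = topology)
}

.cluster_labels <- function(k) {
  if (k == 4L) c("N_ITA", "C_ITA", "S_ITA", "SARD") else paste0("CL", seq_len(k))
}

# Balding-Nichols draw around parent frequency p with drift F.
# F = 0 returns p exactly (degenerate Beta).
.bn_draw <- function(p, F) {
  if (F == 0) return(p)
  rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

#' Simulate cluster and province allele frequencies
#'
#' Ancestral frequencies are uniform on [0.05, 0.95]; each cluster
#' drifts from the ancestor under Balding-Nichols with `cluster_F`, and
#' each province drifts from its cluster with `province_F`. Frequencies
#' refer to allele b, the derived allele.
#'
#' @param cfg a [SimConfig-class]
#' @return list with `ancestral` (length n_snps), `cluster`
#'   (n_clusters x n_snps), `province` (provinces x n_snps, rownames
#'   province labels) and `province_cluster` (province -> cluster map)
#' @export
simulateFrequencies <- function(cfg) {
  validObject(cfg)
  set.seed(cfg@seed)
  M <- cfg@n_snps
  K <- cfg@n_clusters
  P <- cfg@provinces_per_cluster
  anc <- runif(M, 0.05, 0.95)
  clabs <- .cluster_labels(K)
  if (cfg@topology == "cline") {
    # latitudinal admixture gradient: two endpoint pools drift from the
    # ancestor, and cluster k mixes them in proportion to its position
    # on the north-south line -- cluster centroids are exactly collinear
    # in frequency space, the explicit geography == structure truth
    p_n <- .bn_draw(anc, cfg@cluster_F)
    p_s <- .bn_draw(anc, cfg@cluster_F)
    w <- if (K > 1) (seq_len(K) - 1) / (K - 1) else 0.5
    cl <- matrix(NA_real_, K, M, dimnames = list(clabs, NULL))
    for (i in seq_len(K)) cl[i, ] <- (1 - w[i]) * p_n + w[i] * p_s
  } else if (cfg@topology == "serial") {
    # stepping-stone drift along the north-south cluster chain: each
    # cluster drifts from its northern neighbour, producing a cline
    cl <- matrix(NA_real_, K, M, dimnames = list(clabs, NULL))
    parent <- anc
    for (i in seq_len(K)) {
      cl[i, ] <- .bn_draw(parent, cfg@cluster_F)
      parent <- cl[i, ]
    }
  } else {
    cl <- t(vapply(seq_len(K), function(i) .bn_draw(anc, cfg@cluster_F),
                   numeric(M)))
    rownames(cl) <- clabs
  }
  provs <- as.vector(t(outer(clabs, seq_len(P),
                             function(c, j) paste0(c, "_P", j))))
  pc <- rep(clabs, each = P)
  pr <- t(vapply(seq_along(provs), function(i) {
    .bn_draw(cl[pc[i], ], cfg@province_F)
  }, numeric(M)))
  rownames(pr) <- provs
  list(ancestral = anc, cluster = cl, province = pr,
       province_cluster = setNames(pc, provs))
}

.geo_layout <- function(cfg) {
  K <- cfg@n_clusters
  P <- cfg@provinces_per_cluster
  clabs <- .cluster_labels(K)
  # cluster anchors on a north-south line (lat 45.5 -> 39, lon 9 -> 16)
  lat0 <- seq(45.5, 39.0, length.out = K)
  lon0 <- seq(9.0, 16.0, length.out = K)
  provs <- as.vector(t(outer(clabs, seq_len(P),
                             function(c, j) paste0(c, "_P", j))))
  i <- rep(seq_len(K), each = P)
  data.frame(province = provs, cluster = clabs[i],
             lat = lat0[i] + runif(K * P, -0.5, 0.5),
             lon = lon0[i] + runif(K * P, -0.5, 0.5))
}

#' Simulate phased haplotypes from province frequencies
#'
#' Each province contributes `2 * n_per_province` haplotypes with loci
#' drawn independently Bernoulli(province frequency). Allele a ("A") is
#' ancestral by construction and annotated as such; allele b is "G".
#' Marker positions are distinct, sorted, 1-based on one chromosome.
#' Province geographic coordinates are cluster anchors jittered by
#' +/- 0.5 degrees.
#'
#' @param freqs output of [simulateFrequencies()]
#' @param cfg the same [SimConfig-class]
#' @return a [HaplotypeSet-class]
#' @export
simulateHaplotypes <- function(freqs, cfg) {
  stopifnot(all(freqs$province >= 0 & freqs$province <= 1))
  M <- cfg@n_snps
  pos <- sort(sample.int(cfg@chrom_length_bp, M))
  mk <- data.frame(
    id = sprintf("snp%06d", seq_len(M)), chrom = "1", pos = pos,
    allele_a = "A", allele_b = "G", ancestral = "A",
    stringsAsFactors = FALSE)
  geo <- .geo_layout(cfg)
  n <- cfg@n_per_province
  smp <- do.call(rbind, lapply(seq_len(nrow(geo)), function(i) {
    data.frame(sample_id = sprintf("%s_S%03d", geo$province[i], seq_len(n)),
               province = geo$province[i], cluster = geo$cluster[i],
               lat = geo$lat[i], lon = geo$lon[i],
               stringsAsFactors = FALSE)
  }))
  H <- matrix(0L, nrow = 2L * nrow(smp), ncol = M)
  for (i in seq_len(nrow(geo))) {
    rows <- .hap_rows(which(smp$province == geo$province[i]))
    f <- freqs$province[geo$province[i], ]
    H[rows, ] <- matrix(rbinom(length(rows) * M, 1L, rep(f, each = length(rows))),
                        nrow = length(rows))
  }
  HaplotypeSet(H, mk, smp)
}

#' Plant a selective sweep by haplotype copying
#'
#' Within the target cluster, a fraction `freq` of haplotypes is
#' replaced, over the closed interval `center_bp +/- length_bp/2`, by
#' copies of one core haplotype carrying the derived allele at the
#' marker nearest `center_bp`. Each copy then receives per-site
#' mutations with probability rising linearly from 0 at the center to
#' `edge_mut` at the interval edge, and a single crossover onto a
#' random background haplotype at a distance drawn uniformly over the
#' interval half-length, so extended haplotype homozygosity decays with
#' distance from the core.
#'
#' @param haps a [HaplotypeSet-class]
#' @param center_bp sweep center (bp)
#' @param cluster target cluster label
#' @param freq sweep frequency in (0, 1); if the derived allele is
#'   absent at the core, a warning is issued and one carrier is created
#' @param length_bp sweep extent (bp)
#' @param edge_mut per-site mutation probability at the interval edge
#' @param crossover logical; disable to keep copies intact
#' @return list with the modified `haps`, the `center_locus` index and
#'   the closed `interval` (bp)
#' @export
plantSweep <- function(haps, center_bp, cluster, freq, length_bp,
                       edge_mut = 0.05, crossover = TRUE) {
  mk <- markers(haps)
  if (center_bp - length_bp / 2 < 1)
    stop("sweep interval outside chromosome")
  core <- which.min(abs(mk$pos - center_bp))
  half <- length_bp / 2
  cols <- which(mk$pos >= center_bp - half & mk$pos <= center_bp + half)
  tgt_samples <- which(samples(haps)$cluster == cluster)
  rows <- .hap_rows(tgt_samples)
  H <- haps@haps
  derived <- 1L   # allele_b is derived (ancestral = allele_a)
  carriers <- rows[H[rows, core] == derived]
  if (!length(carriers)) {
    warning("no derived carrier at sweep core; creating one")
    carriers <- rows[1L]
    H[carriers, core] <- derived
  }
  # non-replaced haplotypes keep their background center allele, so the
  # number of copies is chosen to land the final derived frequency on
  # `freq`: n_copy/n + p_bg (1 - n_copy/n) = freq
  p_bg <- length(carriers) / length(rows)
  if (freq <= p_bg) {
    # impossible to hit `freq` exactly: replaced haplotypes all carry
    # the derived core allele, so the realized frequency is raised to
    # about freq + p_bg (1 - freq)
    warning(sprintf(
      "sweep frequency %.2f not above current derived frequency %.2f; raised",
      freq, p_bg))
    n_copy <- round(freq * length(rows))
  } else {
    n_copy <- round(length(rows) * (freq - p_bg) / (1 - p_bg))
  }
  if (n_copy < 1L) n_copy <- 1L
  core_row <- carriers[sample.int(length(carriers), 1L)]
  core_hap <- H[core_row, cols]
  copy_rows <- sample(rows, n_copy)
  dist_frac <- abs(mk$pos[cols] - mk$pos[core]) / half
  dist_frac[dist_frac > 1] <- 1
  for (r in copy_rows) {
    hap <- core_hap
    mut <- runif(length(cols)) < edge_mut * dist_frac
    hap[mut] <- 1L - hap[mut]
    if (crossover) {
      d <- runif(1, 0, half)
      side <- sample(c(-1, 1), 1L)
      bg <- sample(setdiff(rows, r), 1L)
      far <- if (side < 0) mk$pos[cols] < mk$pos[core] - d
             else mk$pos[cols] > mk$pos[core] + d
      hap[far] <- H[bg, cols[far]]
    }
    hap[which(cols == core)] <- derived
    H[r, cols] <- hap
  }
  haps@haps <- H
  list(haps = haps, center_locus = core,
       interval = c(floor(center_bp - half), ceiling(center_bp + half)))
}

#' Plant highly differentiated loci
#'
#' At each specified marker, target-cluster haplotypes are resampled so
#' that the cluster's derived-allele frequency differs from the mean of
#' the other clusters by `shift` (to within half a haplotype count),
#' shifted upward when that stays in [0, 1] and downward otherwise (the
#' differentiation signal is an absolute difference). Other clusters
#' are untouched.
#'
#' @param haps a [HaplotypeSet-class]
#' @param specs data.frame with columns locus, cluster, shift
#' @return the modified [HaplotypeSet-class]
#' @export
plantDafOutliers <- function(haps, specs) {
  if (!nrow(specs)) return(haps)
  H <- haps@haps
  smp <- samples(haps)
  for (i in seq_len(nrow(specs))) {
    j <- specs$locus[i]
    tgt <- .hap_rows(which(smp$cluster == specs$cluster[i]))
    oth <- .hap_rows(which(smp$cluster != specs$cluster[i]))
    # the shift is a target |delta|: applied upward when realizable,
    # otherwise downward
    target_f <- mean(H[oth, j]) + specs$shift[i]
    if (target_f > 1 || target_f < 0)
      target_f <- mean(H[oth, j]) - specs$shift[i]
    if (target_f < 0 || target_f > 1)
      stop(sprintf("shift at locus %d pushes frequency outside [0, 1]", j))
    if (specs$shift[i] == 0) next
    k <- round(target_f * length(tgt))
    H[tgt, j] <- 0L
    H[sample(tgt, k), j] <- 1L
  }
  haps@haps <- H
  haps
}

#' Pair haplotypes into genotypes and inject QC defects
#'
#' Genotypes are the sum of each sample's two haplotypes. Defects, in
#' order: `n_related_pairs` children appended (one transmitted
#' haplotype from each of two existing samples of one province);
#' `n_hwe_violators` loci overwritten as all-heterozygote within one
#' province; `n_lowcall_loci` loci dropped below 95% call rate; then
#' uniform missingness at `missing_rate`. Defect loci avoid planted
#' outliers and sweeps so ground truths stay separable.
#'
#' @param haps a [HaplotypeSet-class] (post planting)
#' @param cfg the [SimConfig-class]
#' @param avoid_loci marker indices exempt from defect planting
#' @return list with `geno` (a [GenotypeData-class], possibly with
#'   appended child samples), `hwe_violators`, `lowcall_loci` (integer
#'   indices) and `related_pairs` (data.frame sample1, sample2)
#' @export
addQcDefects <- function(haps, cfg, avoid_loci = integer()) {
  G <- asGenotypes(haps)
  g <- G@geno
  smp <- G@samples
  M <- ncol(g)
  free <- setdiff(seq_len(M), avoid_loci)

  rel <- data.frame(sample1 = character(), sample2 = character(),
                    relation = character())
  if (cfg@n_related_pairs > 0L) {
    prov <- smp$province[1L]
    cand <- which(smp$province == prov)
    # distinct parents across pairs, so each pair stays an isolated
    # relatedness component and pruning removes exactly one member
    pool <- sample(cand, 2L * cfg@n_related_pairs)
    for (k in seq_len(cfg@n_related_pairs)) {
      par <- pool[c(2L * k - 1L, 2L * k)]
      h1 <- haps@haps[.hap_rows(par[1L])[sample.int(2L, 1L)], ]
      h2 <- haps@haps[.hap_rows(par[2L])[sample.int(2L, 1L)], ]
      child <- as.integer(h1 + h2)
      cid <- sprintf("%s_CH%02d", prov, k)
      g <- rbind(g, child)
      smp <- rbind(smp, data.frame(
        sample_id = cid, province = prov, cluster = smp$cluster[cand[1L]],
        lat = smp$lat[cand[1L]], lon = smp$lon[cand[1L]]))
      rel <- rbind(rel, data.frame(
        sample1 = smp$sample_id[par[1L]], sample2 = cid,
        relation = "parent-child"))
    }
  }

  hwe <- integer()
  if (cfg@n_hwe_violators > 0L) {
    hwe <- sort(sample(free, cfg@n_hwe_violators))
    free <- setdiff(free, hwe)
    prov_rows <- which(smp$province == smp$province[1L])
    g[prov_rows, hwe] <- 1L
  }

  lowcall <- integer()
  if (cfg@n_lowcall_loci > 0L) {
    lowcall <- sort(sample(free, cfg@n_lowcall_loci))
    n <- nrow(g)
    for (j in lowcall) {
      # force call rate strictly below 0.95
      nmiss <- ceiling(0.05 * n) + sample(2:5, 1L)
      g[sample.int(n, min(nmiss, n)), j] <- NA_integer_
    }
  }

  if (cfg@missing_rate > 0) {
    mask <- matrix(runif(length(g)) < cfg@missing_rate, nrow = nrow(g))
    # keep planted low-call loci as designed, leave them out of the mask
    mask[, lowcall] <- FALSE
    g[mask] <- NA_integer_
  }
  rownames(g) <- smp$sample_id
  list(geno = GenotypeData(g, G@markers, smp),
       hwe_violators = hwe, lowcall_loci = lowcall, related_pairs = rel)
}

#' Simulate a complete structured dataset with ground truth
#'
#' Runs the whole generator: Balding-Nichols frequencies, phased
#' haplotypes, planted differentiated loci, planted sweeps, genotype
#' pairing with QC defects. The RNG is seeded once from `cfg@seed`, so
#' identical configs give bit-identical output.
#'
#' @param cfg a [SimConfig-class]
#' @return list with `haplotypes` ([HaplotypeSet-class], defect-free,
#'   post planting), `genotypes` ([GenotypeData-class] with defects),
#'   `truth` ([GroundTruth-class]) and `freqs` (the frequency layers)
#' @export
simulateDataset <- function(cfg) {
  freqs <- simulateFrequencies(cfg)      # seeds the RNG
  haps <- simulateHaplotypes(freqs, cfg)
  haps <- plantDafOutliers(haps, cfg@planted_daf_loci)
  mk <- markers(haps)
  sweeps <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), cluster = character(),
                       center_locus = integer())
  sweep_loci <- integer()
  ps <- cfg@planted_sweeps
  for (i in seq_len(nrow(ps))) {
    r <- plantSweep(haps, ps$center_bp[i], ps$cluster[i], ps$freq[i],
                    ps$length_bp[i])
    haps <- r$haps
    sweeps <- rbind(sweeps, data.frame(
      chrom = "1", start = r$interval[1L], end = r$interval[2L],
      cluster = ps$cluster[i], center_locus = r$center_locus))
    sweep_loci <- c(sweep_loci,
                    which(mk$pos >= r$interval[1L] & mk$pos <= r$interval[2L]))
  }
  avoid <- unique(c(cfg@planted_daf_loci$locus, sweep_loci))
  def <- addQcDefects(haps, cfg, avoid_loci = avoid)
  ol <- cfg@planted_daf_loci
  truth <- new("GroundTruth",
               outlier_loci = ol, sweep_windows = sweeps,
               related_pairs = def$related_pairs,
               hwe_violators = def$hwe_violators,
               lowcall_loci = def$lowcall_loci,
               ancestral_freqs = freqs$ancestral)
  list(haplotypes = haps, genotypes = def$geno, truth = truth, freqs = freqs)
}
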