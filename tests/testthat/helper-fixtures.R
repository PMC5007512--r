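# Small programmatic fixtures shared across test files.

mk_markers <- function(M, chrom = "1", spacing = 1000L, ancestral = "A") {
  data.frame(id = sprintf("m%04d", seq_len(M)), chrom = chrom,
             pos = seq_len(M) * spacing,
             allele_a = "A", allele_b = "G", ancestral = ancestral,
             stringsAsFactors = FALSE)
}

mk_samples <- function(n, province = "P1", cluster = "CL1") {
  data.frame(sample_id = sprintf("%s_s%03d", province, seq_len(n)),
             province = province, cluster = cluster, lat = 0, lon = 0,
             stringsAsFactors = FALSE)
}

# genotype container from a raw samples x markers matrix
mk_geno <- function(g, markers = NULL, samples_df = NULL) {
  g <- as.matrix(g)
  if (is.null(markers)) markers <- mk_markers(ncol(g))
  if (is.null(samples_df)) samples_df <- mk_samples(nrow(g))
  GenotypeData(g, markers, samples_df)
}

# haplotype container from a raw (2n) x markers binary matrix
mk_haps <- function(h, markers = NULL, samples_df = NULL) {
  h <- as.matrix(h)
  if (is.null(markers)) markers <- mk_markers(ncol(h))
  if (is.null(samples_df)) samples_df <- mk_samples(nrow(h) / 2)
  HaplotypeSet(h, markers, samples_df)
}

# two-cluster genotype simulation straight from Balding-Nichols
# frequencies (no haplotype machinery), for structure/fst tests
sim_two_cluster_geno <- function(M, n_per, F, seed) {
  set.seed(seed)
  p <- runif(M, 0.05, 0.95)
  draw <- function(pp) rbeta(length(pp), pp * (1 - F) / F,
                             (1 - pp) * (1 - F) / F)
  p1 <- draw(p); p2 <- draw(p)
  g1 <- matrix(rbinom(M * n_per, 2, rep(p1, each = n_per)), n_per, M)
  g2 <- matrix(rbinom(M * n_per, 2, rep(p2, each = n_per)), n_per, M)
  smp <- rbind(mk_samples(n_per, "P1", "CL1"), mk_samples(n_per, "P2", "CL2"))
  mk_geno(rbind(g1, g2), mk_markers(M), smp)
}

# three-population frequency fixture for f3 tests: two drifted sources
# and a target that is either independently drifted or their mixture
freq_fixture <- function(M = 5000, F = 0.02, n = 100, admixed = FALSE,
                         alpha = 0.5, seed = 1) {
  set.seed(seed)
  p <- runif(M, 0.05, 0.95)
  bn <- function(pp) rbeta(length(pp), pp * (1 - F) / F,
                           (1 - pp) * (1 - F) / F)
  pa <- bn(p); pb <- bn(p)
  pt <- if (admixed) alpha * pa + (1 - alpha) * pb else bn(p)
  samp <- function(pp) rbinom(length(pp), 2 * n, pp) / (2 * n)
  freq <- rbind(A = samp(pa), B = samp(pb), C = samp(pt))
  nmat <- matrix(n, 3, M, dimnames = list(c("A", "B", "C"), NULL))
  list(freq = freq, n = nmat,
       mk = data.frame(id = seq_len(M), chrom = "1",
                       pos = sort(sample.int(2e8, M))))
}

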