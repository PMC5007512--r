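test_that("Balding-Nichols drift has the right degenerate case and moments", {
  cfg <- simConfig(n_clusters = 2, provinces_per_cluster = 1,
                   n_per_province = 5, n_snps = 200, cluster_F = 0,
                   province_F = 0, seed = 1)
  fr <- simulateFrequencies(cfg)
  expect_identical(unname(fr$cluster[1, ]), fr$ancestral)
  expect_identical(unname(fr$province[1, ]), unname(fr$cluster[1, ]))

  set.seed(99)
  draws <- popgenscan:::.bn_draw(rep(0.5, 1e5), 0.01)
  expect_lt(abs(mean(draws) - 0.5), 0.005)
  expect_lt(abs(var(draws) / (0.01 * 0.25) - 1), 0.10)
})

test_that("seeded simulation is bit-reproducible", {
  cfg <- simConfig(n_snps = 300, n_per_province = 5, seed = 31,
                   missing_rate = 0.01, n_hwe_violators = 2,
                   n_related_pairs = 1, n_lowcall_loci = 2)
  a <- simulateDataset(cfg)
  b <- simulateDataset(cfg)
  expect_identical(haplotypes(a$haplotypes), haplotypes(b$haplotypes))
  expect_identical(genotypes(a$genotypes), genotypes(b$genotypes))
  expect_identical(a$truth@hwe_violators, b$truth@hwe_violators)
})

test_that("haplotype sampling respects frequencies, positions sorted unique", {
  cfg <- simConfig(n_clusters = 1, provinces_per_cluster = 1,
                   n_per_province = 500, n_snps = 2000,
                   chrom_length_bp = 1e7, cluster_F = 0.01,
                   province_F = 0.001, seed = 8)
  fr <- simulateFrequencies(cfg)
  haps <- simulateHaplotypes(fr, cfg)
  pos <- markers(haps)$pos
  expect_true(all(diff(pos) > 0))

  f_in <- fr$province[1, ]
  f_out <- colMeans(haplotypes(haps))
  sdv <- sqrt(f_in * (1 - f_in) / 1000)
  expect_gte(mean(abs(f_out - f_in) <= 3 * sdv), 0.99)

  # frequency 1 forces fixation
  fr$province[1, 1] <- 1
  haps2 <- simulateHaplotypes(fr, cfg)
  expect_true(all(haplotypes(haps2)[, 1] == 1L))
})

test_that("planted sweeps fix the target cluster and leave others intact", {
  cfg <- simConfig(n_clusters = 2, provinces_per_cluster = 2,
                   n_per_province = 25, n_snps = 1500,
                   chrom_length_bp = 1e7, seed = 5)
  fr <- simulateFrequencies(cfg)
  haps <- simulateHaplotypes(fr, cfg)
  before <- haplotypes(haps)
  smp <- samples(haps)
  # plant at a core whose background derived frequency leaves the
  # requested sweep frequencies realizable
  tgt0 <- popgenscan:::.hap_rows(which(smp$cluster == "CL1"))
  mk0 <- markers(haps)
  mid <- which(mk0$pos > 3e6 & mk0$pos < 7e6)
  core0 <- mid[which.min(abs(colMeans(before[tgt0, mid]) - 0.2))]
  center <- mk0$pos[core0]

  full <- plantSweep(haps, center, "CL1", freq = 0.999, length_bp = 1e6,
                     edge_mut = 0, crossover = FALSE)
  H <- haplotypes(full$haps)
  mk <- markers(full$haps)
  cols <- which(mk$pos >= full$interval[1] & mk$pos <= full$interval[2])
  tgt <- popgenscan:::.hap_rows(which(smp$cluster == "CL1"))
  expect_true(all(apply(H[tgt, cols], 2, function(x) length(unique(x)) == 1)))
  crv <- ehhCurve(full$haps, full$center_locus, 1,
                  which_samples = smp$cluster == "CL1")
  expect_true(all(crv$ehh[crv$pos <= full$interval[2]] == 1))

  oth <- popgenscan:::.hap_rows(which(smp$cluster != "CL1"))
  expect_identical(H[oth, ], before[oth, ])

  part <- plantSweep(haps, center, "CL1", freq = 0.6, length_bp = 1e6)
  dafc <- mean(haplotypes(part$haps)[tgt, part$center_locus])
  expect_lt(abs(dafc - 0.6), 0.05)
})

test_that("planted DAF outliers hit the requested shift and are recorded once", {
  specs <- data.frame(locus = c(50, 200), cluster = "N_ITA", shift = 0.25)
  cfg <- simConfig(n_snps = 400, n_per_province = 30, seed = 17,
                   planted_daf_loci = specs)
  sim <- simulateDataset(cfg)
  smp <- samples(sim$haplotypes)
  H <- haplotypes(sim$haplotypes)
  for (j in specs$locus) {
    tgt <- popgenscan:::.hap_rows(which(smp$cluster == "N_ITA"))
    oth <- popgenscan:::.hap_rows(which(smp$cluster != "N_ITA"))
    expect_lt(abs(mean(H[tgt, j]) - (mean(H[oth, j]) + 0.25)), 0.02)
  }
  expect_identical(sort(sim$truth@outlier_loci$locus), sort(specs$locus))
  expect_identical(anyDuplicated(sim$truth@outlier_loci$locus), 0L)

  haps0 <- plantDafOutliers(sim$haplotypes,
                            data.frame(locus = 10, cluster = "N_ITA",
                                       shift = 0))
  expect_identical(haplotypes(haps0)[, 10], H[, 10])
  expect_error(plantDafOutliers(sim$haplotypes,
                                data.frame(locus = 11, cluster = "N_ITA",
                                           shift = 0.999)),
               "outside")
})

test_that("QC defects are injected as designed", {
  cfg <- simConfig(n_snps = 500, n_per_province = 50,
                   provinces_per_cluster = 2, n_clusters = 2, seed = 23)
  sim <- simulateDataset(cfg)
  # no defects: genotypes equal haplotype pairing exactly
  expect_identical(genotypes(sim$genotypes),
                   genotypes(asGenotypes(sim$haplotypes)))

  cfg2 <- simConfig(n_snps = 500, n_per_province = 100,
                    provinces_per_cluster = 1, n_clusters = 2, seed = 24,
                    n_hwe_violators = 3, n_related_pairs = 2,
                    n_lowcall_loci = 4)
  sim2 <- simulateDataset(cfg2)
  g <- genotypes(sim2$genotypes)
  # planted all-heterozygote loci fail the exact HWE test hard
  for (j in sim2$truth@hwe_violators) {
    gj <- g[, j]
    p <- hweExactTest(sum(gj == 0, na.rm = TRUE), sum(gj == 1, na.rm = TRUE),
                      sum(gj == 2, na.rm = TRUE))
    expect_lt(p, 1e-8)
  }
  # planted low-call loci fall below the 95% call-rate bar
  cr <- colMeans(!is.na(g))
  expect_true(all(cr[sim2$truth@lowcall_loci] < 0.95))
  # planted relatives look like first-degree pairs downstream
  kin <- ibdMoments(sim2$genotypes)
  key <- paste(kin$sample1, kin$sample2)
  tr <- sim2$truth@related_pairs
  ph <- kin$pi_hat[match(paste(tr$sample1, tr$sample2), key)]
  expect_true(all(!is.na(ph)))
  expect_gt(mean(ph), 0.40)
  expect_lt(mean(ph), 0.60)
})
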