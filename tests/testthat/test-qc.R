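test_that("call-rate filter keeps 96% loci, drops 94%, is inert at 0", {
  set.seed(1)
  g <- matrix(1L, nrow = 100, ncol = 3)
  g[1:4, 1] <- NA   # 96/100
  g[1:6, 2] <- NA   # 94/100
  G <- mk_geno(g)
  r <- callRateFilter(G, 0.95, 0)
  expect_identical(r$loci_removed, "m0002")
  expect_identical(nMarkers(r$data), 2L)
  r0 <- callRateFilter(G, 0, 0)
  expect_identical(nMarkers(r0$data), 3L)
  expect_identical(nSamples(r0$data), 100L)
})

test_that("HWE exact test matches enumeration oracle and edge cases", {
  expect_equal(hweExactTest(0, 0, 50), 1)
  expect_lt(hweExactTest(0, 100, 0), 1e-25)
  expect_equal(hweExactTest(25, 50, 25), oracle_hwe(25, 50, 25),
               tolerance = 1e-12)
  set.seed(42)
  for (i in 1:50) {
    n <- sample(5:200, 1)
    nAA <- sample(0:n, 1)
    nAa <- sample(0:(n - nAA), 1)
    naa <- n - nAA - nAa
    expect_equal(hweExactTest(nAA, nAa, naa), oracle_hwe(nAA, nAa, naa),
                 tolerance = 1e-12)
  }
})

test_that("Bonferroni threshold arithmetic", {
  expect_equal(signif(bonferroniThreshold(0.01, 524738), 2), 1.9e-8)
  expect_equal(bonferroniThreshold(0.037, 1), 0.037)
  expect_equal(bonferroniThreshold(0.05, 100), 5e-4)
  expect_error(bonferroniThreshold(0.05, 0), ">= 1")
})

test_that("moments IBD: duplicates, parent-child and unrelated pairs", {
  cfg <- simConfig(n_clusters = 1, provinces_per_cluster = 1,
                   n_per_province = 60, n_snps = 2000, cluster_F = 0.01,
                   province_F = 0, seed = 12, n_related_pairs = 3)
  sim <- simulateDataset(cfg)
  G <- sim$genotypes
  # append an exact duplicate of sample 1
  g <- rbind(genotypes(G), genotypes(G)[1, ])
  smp <- rbind(samples(G), samples(G)[1, ])
  smp$sample_id[nrow(smp)] <- "DUP"
  kin <- ibdMoments(GenotypeData(g, markers(G), smp))
  key <- paste(kin$sample1, kin$sample2)
  dup <- kin$pi_hat[match(paste(samples(G)$sample_id[1], "DUP"), key)]
  expect_gte(dup, 0.95)

  tr <- sim$truth@related_pairs
  ph <- kin$pi_hat[match(paste(tr$sample1, tr$sample2), key)]
  expect_gt(mean(ph), 0.40); expect_lt(mean(ph), 0.60)

  founders <- samples(G)$sample_id[1:60]
  unrel <- kin[kin$sample1 %in% founders & kin$sample2 %in% founders, ]
  expect_lte(mean(unrel$pi_hat), 0.05)
})

test_that("relatedness pruning drops exactly one of a pair, two of a triangle", {
  rec <- data.frame(sample1 = c("a", "x"), sample2 = c("b", "y"),
                    pi_hat = c(0.3, 0.05))
  expect_identical(length(pruneRelated(rec)), 1L)
  expect_true(pruneRelated(rec) %in% c("a", "b"))
  expect_identical(pruneRelated(data.frame(sample1 = "a", sample2 = "b",
                                           pi_hat = 0.1)), character(0))
  tri <- data.frame(sample1 = c("a", "a", "b"), sample2 = c("b", "c", "c"),
                    pi_hat = 0.4)
  expect_identical(length(pruneRelated(tri)), 2L)   # minimal vertex cover
})

test_that("LD pruning removes duplicates and spares independent loci", {
  set.seed(3)
  base <- rbinom(500, 2, 0.4)
  g <- cbind(base, base, rbinom(500, 2, 0.4))
  storage.mode(g) <- "integer"
  keep <- ldPrune(mk_geno(g), window_snps = 3, step_snps = 1,
                  r2_threshold = 0.2)
  expect_identical(length(keep), 2L)

  M <- 200L
  g2 <- matrix(rbinom(500 * M, 2, 0.4), 500, M)
  keep2 <- ldPrune(mk_geno(g2), 50, 5, 0.2)
  expect_gte(length(keep2) / M, 0.95)
  keep3 <- ldPrune(mk_geno(g2), 50, 5, 1.0)
  expect_identical(length(keep3), M)

  # exhaustive: surviving pairs inside any original-index window
  # satisfy the r2 bound
  for (s in seq(1L, M - 1L, by = 5L)) {
    idx <- intersect(s:(s + 49L), keep2)
    if (length(idx) < 2L) next
    r2 <- cor(g2[, idx, drop = FALSE])^2
    expect_lte(max(r2[upper.tri(r2)]), 0.2 + 1e-12)
  }
})

test_that("planted QC defects are removed at the standard thresholds", {
  cfg <- simConfig(n_snps = 2000, n_per_province = 50,
                   provinces_per_cluster = 2, n_clusters = 2, seed = 77,
                   n_hwe_violators = 5, n_lowcall_loci = 5,
                   n_related_pairs = 2, missing_rate = 0.002)
  sim <- simulateDataset(cfg)
  qc <- runQc(sim$genotypes)
  mk <- markers(sim$genotypes)
  removed <- setdiff(mk$id, markers(qc$data)$id)
  planted <- mk$id[c(sim$truth@hwe_violators, sim$truth@lowcall_loci)]
  expect_true(all(planted %in% removed))                  # full recall
  expect_lt((length(removed) - length(planted)) / nrow(mk), 0.01)
  # each related pair loses exactly one member
  kept <- samples(qc$data)$sample_id
  tr <- sim$truth@related_pairs
  n_kept <- (tr$sample1 %in% kept) + (tr$sample2 %in% kept)
  expect_true(all(n_kept == 1))
})
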