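test_that("delta-DAF Fisher: null, complete separation, enumeration oracle", {
  eq <- deltaDafFisher(10, 10, 10, 10)
  expect_equal(eq$p, 1)
  expect_equal(eq$delta, 0)

  sep <- deltaDafFisher(0, 10, 10, 0)
  expect_equal(sep$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(sep$delta, 1)

  set.seed(27)
  for (i in 1:60) {
    d1 <- sample(0:12, 1); a1 <- sample(0:12, 1)
    d2 <- sample(0:12, 1); a2 <- sample(0:12, 1)
    if ((d1 + a1) == 0 || (d2 + a2) == 0) next
    mine <- deltaDafFisher(d1, a1, d2, a2)
    if (mine$defined)
      expect_equal(mine$p, oracle_fisher(d1, a1, d2, a2), tolerance = 1e-9)
  }
  # empty margin
  em <- deltaDafFisher(0, 10, 0, 10)
  expect_equal(em$p, 1)
  expect_false(em$defined)
})

test_that("delta-DAF arithmetic reproduces printed cluster frequencies", {
  # frequency pairs as printed for the four significant loci, realised
  # as exact allele counts over 1000 chromosomes
  freqs <- list(c(0.038, 0.202, 0.164), c(0.080, 0.275, 0.195),
                c(0.234, 0.462, 0.228), c(0.122, 0.336, 0.214))
  for (f in freqs) {
    r <- deltaDafFisher(1000 * f[1], 1000 * (1 - f[1]),
                        1000 * f[2], 1000 * (1 - f[2]))
    expect_equal(r$delta, f[3], tolerance = 1e-12)
  }
})

test_that("drift correction reduces to the two-proportion test at F = 0", {
  p1 <- 0.31; p2 <- 0.4; n1 <- 150; n2 <- 210
  d <- driftCorrectedTest(p1, p2, n1, n2, 0)
  pbar <- (2 * n1 * p1 + 2 * n2 * p2) / (2 * n1 + 2 * n2)
  z2 <- (p1 - p2)^2 / (pbar * (1 - pbar) * (1 / (2 * n1) + 1 / (2 * n2)))
  expect_equal(d$statistic, z2, tolerance = 1e-10)
  expect_equal(d$p, pchisq(z2, 1, lower.tail = FALSE), tolerance = 1e-10)

  expect_equal(driftCorrectedTest(0.3, 0.3, 100, 100, 0.01)$p, 1)
  expect_false(driftCorrectedTest(0, 0, 100, 100, 0.01)$defined)
  expect_message(driftCorrectedTest(0.3, 0.4, 100, 100, -0.01), "truncated")
})

test_that("drift-corrected test is calibrated on neutral drifted data", {
  set.seed(28)
  M <- 10000; Fd <- 0.01; n <- 200
  p <- runif(M, 0.1, 0.9)
  bn <- function(pp) rbeta(length(pp), pp * (1 - Fd) / Fd,
                           (1 - pp) * (1 - Fd) / Fd)
  c1 <- rbinom(M, 2 * n, bn(p)); c2 <- rbinom(M, 2 * n, bn(p))
  p1 <- c1 / (2 * n); p2 <- c2 / (2 * n)
  keep <- (p1 + p2) > 0 & (p1 + p2) < 2
  # background F estimated from the data itself, as in the pipeline
  h1 <- 2 * p1 * (1 - p1); h2 <- 2 * p2 * (1 - p2)  # HWE-expected het
  bg <- mean(wcFst(p1[keep], p2[keep], h1[keep], h2[keep], n, n)$theta,
             na.rm = TRUE)
  dr <- driftCorrectedTest(p1[keep], p2[keep], n, n, bg)
  t1 <- mean(dr$p < 0.05, na.rm = TRUE)
  expect_gte(t1, 0.03); expect_lte(t1, 0.07)
  # the uncorrected Fisher test is anticonservative on the same data
  fp <- vapply(which(keep)[1:2000], function(j) {
    fisher.test(matrix(c(c1[j], 2 * n - c1[j], c2[j], 2 * n - c2[j]),
                       2))$p.value
  }, numeric(1))
  expect_gt(mean(fp < 0.05), 0.07)
})

test_that("delta-DAF report lists planted strong shifts, sorted", {
  cfg <- simConfig(n_clusters = 2, provinces_per_cluster = 4,
                   n_per_province = 50, n_snps = 2000, cluster_F = 0.005,
                   province_F = 0.001, seed = 29,
                   planted_daf_loci = data.frame(
                     locus = c(1500, 300, 900), cluster = "CL1",
                     shift = 0.25))
  sim <- simulateDataset(cfg)
  daf <- deltaDafScan(sim$genotypes, "CL1", "CL2", n_tests = 2000)
  rep <- dafReport(daf)
  planted <- markers(sim$genotypes)$id[sim$truth@outlier_loci$locus]
  expect_true(all(planted %in% rep$id))
  expect_identical(rep$pos, sort(rep$pos))

  none <- dafReport(daf[daf$fisher_p > 0.5, ])
  expect_identical(nrow(none), 0L)
  expect_true("delta" %in% names(none))
})
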