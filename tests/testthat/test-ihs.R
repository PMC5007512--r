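test_that("EHH: identity, pair-count enumeration, monotone decay", {
  # all carriers identical over the interval
  h <- matrix(rep(c(1L, 0L, 1L, 0L), 6), nrow = 4)
  hp <- mk_haps(h)
  crv <- ehhCurve(hp, core = 1, allele = 1)
  expect_true(all(crv$ehh == 1))

  # 4 carriers splitting into groups {2,2} then {2,1,1}:
  # EHH = 2/C(4,2) = 1/3, then C(2,2)/C(4,2) = 1/6
  h2 <- rbind(c(1L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L), c(1L, 1L, 1L),
              c(0L, 0L, 0L), c(0L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  hp2 <- mk_haps(h2)
  crv2 <- ehhCurve(hp2, core = 1, allele = 1)
  expect_equal(crv2$ehh[2], 1 / 3)
  expect_equal(crv2$ehh[3], 1 / 6)
  # brute-force pair counting agrees on random data
  set.seed(19)
  H <- matrix(rbinom(30 * 12, 1, 0.5), nrow = 30)
  storage.mode(H) <- "integer"
  hp3 <- mk_haps(H, mk_markers(12), mk_samples(15))
  carriers <- which(H[, 4] == 1L)
  crv3 <- ehhCurve(hp3, core = 4, allele = 1)
  for (k in 2:nrow(crv3)) {
    j <- 4 + (k - 1)
    expect_equal(crv3$ehh[k], oracle_ehh(H, carriers, 4, j))
  }
  expect_true(all(diff(crv3$ehh) <= 1e-12))

  expect_error(ehhCurve(hp3, core = 4, allele = 1,
                        which_samples = integer(0)), "carriers")
})

test_that("iHS symmetry: mirror-identical allele classes score zero", {
  # derived and ancestral carriers with identical internal structure
  blockA <- matrix(rbinom(10 * 9, 1, 0.5), nrow = 10)
  H <- rbind(cbind(blockA[, 1:4], 0L, blockA[, 5:9]),
             cbind(blockA[, 1:4], 1L, blockA[, 5:9]))
  storage.mode(H) <- "integer"
  hp <- mk_haps(H, mk_markers(10), mk_samples(10))
  r <- ihsUnstandardized(hp, locus = 5, max_gap = 1e9)
  expect_true(r$defined)
  expect_equal(r$unstd, 0, tolerance = 1e-12)
  expect_equal(r$ihh_a, r$ihh_d, tolerance = 1e-12)
})

test_that("degenerate cutoff gives undefined, flagged scores", {
  set.seed(20)
  H <- matrix(rbinom(40 * 20, 1, 0.5), nrow = 40)
  storage.mode(H) <- "integer"
  hp <- mk_haps(H, mk_markers(20), mk_samples(20))
  r <- ihsUnstandardized(hp, locus = 10, ehh_cutoff = 1.0, max_gap = 1e9)
  expect_false(r$defined)
})

test_that("planted sweep drives strongly negative iHS at the core", {
  cfg <- simConfig(n_clusters = 2, provinces_per_cluster = 2,
                   n_per_province = 50, n_snps = 4000,
                   chrom_length_bp = 2e7, seed = 25,
                   planted_sweeps = data.frame(center_bp = 1e7,
                                               cluster = "CL1", freq = 0.6,
                                               length_bp = 4e5))
  sim <- simulateDataset(cfg)
  core <- sim$truth@sweep_windows$center_locus[1]
  ih <- ihsScan(sim$haplotypes, cluster = "CL1", min_daf = 0.05)
  ihs <- suppressMessages(suppressWarnings(ihsStandardize(ih)))
  core_id <- markers(sim$haplotypes)$id[core]
  core_std <- ihs$std[ihs$id == core_id]
  expect_lt(core_std, 0)
  bg <- ihs$std[!(ihs$pos >= sim$truth@sweep_windows$start[1] &
                  ihs$pos <= sim$truth@sweep_windows$end[1])]
  expect_gt(abs(core_std), quantile(abs(bg), 0.99, na.rm = TRUE))
})

test_that("standardization: bin moments, DAF floor, degenerate bins", {
  set.seed(26)
  rec <- data.frame(id = sprintf("s%04d", 1:600),
                    pos = sort(sample.int(1e8, 600)),
                    daf = runif(600, 0.05, 0.95),
                    ihh_a = 1, ihh_d = 1,
                    unstd = rnorm(600), truncated = FALSE, defined = TRUE)
  std <- suppressMessages(ihsStandardize(rec))
  expect_true(all(std$daf >= 0.2))
  expect_false(any(rec$id[rec$daf < 0.2] %in% std$id))
  for (b in unique(std$daf_bin)) {
    x <- std$std[std$daf_bin == b]
    expect_equal(mean(x), 0, tolerance = 1e-10)
    expect_equal(sd(x), 1, tolerance = 1e-10)
  }
  expect_identical(sum(std$outlier), as.integer(ceiling(0.01 * nrow(std))))

  flat <- rec[rec$daf >= 0.4 & rec$daf < 0.5, ]
  flat$unstd <- 0.7
  expect_warning(ihsStandardize(flat, min_bin = 2), "degenerate")
})
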