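test_that("VCF round trip preserves haplotypes, genotypes and metadata", {
  cfg <- simConfig(n_snps = 120, n_per_province = 4, seed = 2,
                   missing_rate = 0)
  sim <- simulateDataset(cfg)
  f <- tempfile(fileext = ".vcf")

  writeGenoVcf(sim$haplotypes, f)
  back <- readGenoVcf(f, samples(sim$haplotypes))
  expect_s4_class(back, "HaplotypeSet")
  expect_identical(unname(haplotypes(back)), unname(haplotypes(sim$haplotypes)))
  expect_identical(markers(back)$pos, markers(sim$haplotypes)$pos)
  expect_identical(markers(back)$ancestral, markers(sim$haplotypes)$ancestral)

  g <- genotypes(sim$genotypes)
  g[1, 1] <- NA_integer_
  G <- GenotypeData(g, markers(sim$genotypes), samples(sim$genotypes))
  writeGenoVcf(G, f)
  back2 <- readGenoVcf(f, samples(G))
  expect_s4_class(back2, "GenotypeData")
  expect_identical(unname(genotypes(back2)), unname(g))
  expect_true(is.na(genotypes(back2)[1, 1]))
})

test_that("ancestral ALT flips the derived orientation", {
  mk <- mk_markers(2)
  mk$ancestral <- c("A", "G")      # second marker: ALT is ancestral
  h <- matrix(c(1L, 1L, 0L, 1L,
                1L, 0L, 0L, 0L), nrow = 4)
  hp <- mk_haps(h, mk, mk_samples(2))
  daf <- derivedFreq(hp)
  expect_equal(daf[1], 0.75)       # derived = allele_b
  expect_equal(daf[2], 1 - 0.25)   # derived = allele_a = 1 - ALT freq
  gf <- groupDerivedFreqs(asGenotypes(hp), "cluster")
  expect_equal(unname(gf$freq[1, ]), daf)
})

test_that("PLINK text I/O: hand fixture, round trip, mismatch error", {
  ped <- tempfile(fileext = ".ped")
  map <- tempfile(fileext = ".map")
  writeLines(c("1\tm1\t0\t100", "1\tm2\t0\t200"), map)
  writeLines(c("F1 s1 0 0 0 -9 A A A G",
               "F1 s2 0 0 0 -9 A G 0 0"), ped)
  G <- readPlinkText(ped, map)
  expect_identical(unname(genotypes(G)),
                   matrix(c(0L, 1L, 1L, NA), nrow = 2))
  expect_identical(markers(G)$allele_b, c("G", "G"))

  cfg <- simConfig(n_snps = 80, n_per_province = 4, seed = 3)
  sim <- simulateDataset(cfg)
  pre <- tempfile()
  writePlinkText(sim$genotypes, pre)
  back <- readPlinkText(paste0(pre, ".ped"), paste0(pre, ".map"),
                        samples(sim$genotypes))
  poly <- apply(genotypes(sim$genotypes), 2, function(x) length(unique(x)) > 1)
  expect_identical(unname(genotypes(back))[, poly],
                   unname(genotypes(sim$genotypes))[, poly])

  writeLines("1\tm1\t0\t100", map)   # now one marker vs two in ped
  expect_error(readPlinkText(ped, map), "map lists")
})

test_that("VCF and PLINK loaders agree on the same exported dataset", {
  cfg <- simConfig(n_snps = 60, n_per_province = 3, seed = 4,
                   missing_rate = 0.05)
  sim <- simulateDataset(cfg)
  vf <- tempfile(fileext = ".vcf"); pre <- tempfile()
  writeGenoVcf(sim$genotypes, vf)
  writePlinkText(sim$genotypes, pre)
  a <- readGenoVcf(vf, samples(sim$genotypes))
  b <- readPlinkText(paste0(pre, ".ped"), paste0(pre, ".map"),
                     samples(sim$genotypes))
  poly <- apply(genotypes(sim$genotypes), 2,
                function(x) length(unique(x[!is.na(x)])) > 1)
  expect_identical(unname(genotypes(a))[, poly], unname(genotypes(b))[, poly])
})

test_that("group frequencies handle missingness and empty groups", {
  g <- matrix(c(0L, 1L, 2L,
                2L, NA, NA,
                NA, NA, NA), nrow = 3)
  G <- mk_geno(g)
  gf <- groupFreqs(G, "cluster")
  expect_equal(unname(gf$freq[1, 1]), 0.5)
  expect_equal(unname(gf$freq[1, 2]), 1.0)
  expect_equal(unname(gf$n[1, 2]), 1)
  expect_true(is.na(gf$freq[1, 3]))
  expect_true(gf$undefined[1, 3])
})

test_that("derived plus ancestral frequency is one where annotated", {
  cfg <- simConfig(n_snps = 100, n_per_province = 5, seed = 6)
  sim <- simulateDataset(cfg)
  daf <- derivedFreq(sim$haplotypes)
  aaf <- 1 - colMeans(haplotypes(sim$haplotypes))
  expect_equal(daf + unname(aaf), rep(1, 100), tolerance = 1e-12)
})

test_that("sample table round-trips through TSV", {
  cfg <- simConfig(n_snps = 10, n_per_province = 3, seed = 9)
  sim <- simulateDataset(cfg)
  f <- tempfile(fileext = ".tsv")
  writeSampleTable(samples(sim$genotypes), f)
  back <- readSampleTable(f)
  expect_equal(back, samples(sim$genotypes), ignore_attr = TRUE)
})
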