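# Independent oracles used to pin expected values. Each is a separate,
# deliberately naive transcription of the underlying definition, kept
# apart from the package's implementation path.

# Exact HWE p by direct enumeration of the conditional distribution of
# heterozygote counts given allele counts, using plain choose() ratios.
oracle_hwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  if (nA == 0 || nA == 2 * n) return(1)
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  # P(het = h | nA, n) = C(n; (nA-h)/2, h, n-(nA+h)/2) 2^h / C(2n, nA)
  pr <- vapply(hets, function(h) {
    exp(lchoose(n, (nA - h) / 2) + lchoose(n - (nA - h) / 2, h) +
        h * log(2) - lchoose(2 * n, nA))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(nAa, hets)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Weir & Cockerham (1984) two-population variance components, written
# as explicit per-population loops following the general-r equations.
oracle_wc <- function(p_list, h_list, n_list) {
  r <- length(p_list)
  nbar <- mean(unlist(n_list))
  nc <- (r * nbar - sum(unlist(n_list)^2) / (r * nbar)) / (r - 1)
  pbar <- 0
  for (i in seq_len(r)) pbar <- pbar + n_list[[i]] * p_list[[i]]
  pbar <- pbar / (r * nbar)
  s2 <- 0
  for (i in seq_len(r)) s2 <- s2 + n_list[[i]] * (p_list[[i]] - pbar)^2
  s2 <- s2 / ((r - 1) * nbar)
  hbar <- 0
  for (i in seq_len(r)) hbar <- hbar + n_list[[i]] * h_list[[i]]
  hbar <- hbar / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - (1 / 4) * hbar))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
    ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# Two-sided Fisher exact p by hypergeometric enumeration: sum of
# probabilities of all tables with the same margins whose probability
# does not exceed the observed table's.
oracle_fisher <- function(d1, a1, d2, a2) {
  m <- d1 + a1          # row 1 total
  n <- d2 + a2          # row 2 total
  k <- d1 + d2          # first-column total
  x <- max(0, k - n):min(k, m)
  pr <- dhyper(x, m, n, k)
  obs <- dhyper(d1, m, n, k)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# EHH by brute-force pair counting: fraction of carrier pairs identical
# over all markers from the core out to column j inclusive.
oracle_ehh <- function(H, carriers, core, j) {
  cols <- if (j >= core) core:j else j:core
  cols <- setdiff(cols, core)
  n <- length(carriers)
  if (!length(cols)) return(1)
  same <- 0
  for (i1 in seq_len(n - 1)) for (i2 in (i1 + 1):n) {
    if (all(H[carriers[i1], cols] == H[carriers[i2], cols])) same <- same + 1
  }
  same / choose(n, 2)
}
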