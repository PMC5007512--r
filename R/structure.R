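#' Result containers for the structure analyses
#'
#' `PcaResult` holds Patterson-scaled PC scores, eigenvalues and
#' variance-explained fractions. `ProcrustesResult` holds the
#' similarity transform fitted between PC centroids and geography, the
#' t0 score, the permutation p (when computed) and per-province
#' residual distances. `DapcResult` holds retained-PC count,
#' discriminant functions and posterior cluster memberships.
#'
#' @name structure-classes
NULL

#' @rdname structure-classes
#' @export
setClass("PcaResult", representation(
  scores = "matrix", eigenvalues = "numeric", var_explained = "numeric",
  loci_used = "integer", n_dropped_monomorphic = "integer"
))

setValidity("PcaResult", function(object) {
  ev <- object@eigenvalues
  if (any(ev < -1e-8)) return("eigenvalues must be non-negative")
  if (is.unsorted(rev(ev))) return("eigenvalues must be sorted descending")
  if (sum(object@var_explained) > 1 + 1e-8)
    return("variance fractions must sum to <= 1")
  TRUE
})

#' @rdname structure-classes
#' @export
setClass("ProcrustesResult", representation(
  rotation = "matrix", scale = "numeric", translation = "numeric",
  t0 = "numeric", perm_p = "numeric", residuals = "numeric",
  degenerate = "logical"
))

setValidity("ProcrustesResult", function(object) {
  if (object@t0 < -1e-10 || object@t0 > 1 + 1e-10)
    return("t0 must lie in [0, 1]")
  r <- object@rotation
  if (max(abs(crossprod(r) - diag(2))) > 1e-6)
    return("rotation must be orthogonal")
  TRUE
})

#' @rdname structure-classes
#' @export
setClass("DapcResult", representation(
  n_pc = "integer", discriminants = "matrix", posteriors = "matrix",
  province_posteriors = "matrix", assignments = "character"
))

setMethod("show", "PcaResult", function(object) {
  cat(sprintf("PcaResult: %d samples x %d PCs, %d loci (%d monomorphic dropped)\n",
              nrow(object@scores), ncol(object@scores),
              length(object@loci_used), object@n_dropped_monomorphic))
  cat("  variance explained:",
      paste(sprintf("%.2f%%", 100 * head(object@var_explained, 5)),
            collapse = ", "), "\n")
})

setMethod("show", "ProcrustesResult", function(object) {
  cat(sprintf("ProcrustesResult: t0 = %.4f", object@t0))
  if (!is.na(object@perm_p)) cat(sprintf(", permutation p = %.3g", object@perm_p))
  cat("\n")
})

setMethod("show", "DapcResult", function(object) {
  cat(sprintf("DapcResult: %d PCs retained, %d clusters, mean own-cluster posterior %.3f\n",
              object@n_pc, ncol(object@posteriors),
              mean(object@posteriors[cbind(seq_along(object@assignments),
                                           match(object@assignments,
                                                 colnames(object@posteriors)))])))
})

#' Principal component analysis of genotypes
#'
#' Each locus is mean-centered by twice its allele frequency and scaled
#' by `sqrt(p(1-p))` (Patterson scaling); missing entries contribute
#' zero after centering. Scores are the left singular vectors scaled by
#' the singular values of the scaled matrix; eigenvalues are singular
#' values squared over (samples - 1), and variance fractions are
#' relative to the total variance over all components. Monomorphic loci
#' are dropped with a count.
#'
#' @param G a [GenotypeData-class] (LD-pruned loci recommended)
#' @param n_components number of PCs to return
#' @param loci optional marker indices to use
#' @return a [PcaResult][structure-classes]
#' @export
pcaGenotypes <- function(G, n_components = 10, loci = NULL) {
  g <- genotypes(G)
  if (!is.null(loci)) g <- g[, loci, drop = FALSE] else loci <- seq_len(ncol(g))
  n <- nrow(g)
  if (n_components > min(dim(g)))
    stop("n_components exceeds the rank of the data")
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  n_drop <- sum(!poly)
  g <- g[, poly, drop = FALSE]; p <- p[poly]
  X <- sweep(g, 2L, 2 * p, `-`)
  X <- sweep(X, 2L, sqrt(p * (1 - p)), `/`)
  X[is.na(X)] <- 0
  sv <- svd(X, nu = n_components, nv = 0)
  ev <- sv$d^2 / (n - 1)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  rownames(scores) <- samples(G)$sample_id
  colnames(scores) <- paste0("PC", seq_len(n_components))
  new("PcaResult", scores = scores,
      eigenvalues = ev[seq_len(n_components)],
      var_explained = (ev / sum(ev))[seq_len(n_components)],
      loci_used = as.integer(loci[poly]),
      n_dropped_monomorphic = as.integer(n_drop))
}

#' Per-province centroids of PC scores
#'
#' Averages individuals' scores on the chosen PCs within sampling
#' province, returning one 2D point per province.
#'
#' @param pca a [PcaResult][structure-classes]
#' @param sample_table sample table aligned with the score rows
#' @param pcs which two PCs to use
#' @return matrix provinces x 2, rownames = province
#' @export
provinceCentroids <- function(pca, sample_table, pcs = c(1, 2)) {
  sc <- pca@scores[, pcs, drop = FALSE]
  provs <- sort(unique(sample_table$province))
  out <- t(vapply(provs, function(p) {
    colMeans(sc[sample_table$province == p, , drop = FALSE])
  }, numeric(2)))
  rownames(out) <- provs
  out
}

#' Province geographic configuration
#'
#' One (lon, lat) point per province, in plain degrees (no map
#' projection), ordered to match [provinceCentroids()].
#'
#' @param sample_table sample table
#' @return matrix provinces x 2 (lon, lat)
#' @export
provinceGeography <- function(sample_table) {
  provs <- sort(unique(sample_table$province))
  out <- t(vapply(provs, function(p) {
    r <- sample_table[sample_table$province == p, ][1L, ]
    c(r$lon, r$lat)
  }, numeric(2)))
  colnames(out) <- c("lon", "lat")
  out
}

#' Symmetric Procrustes fit of genetic structure onto geography
#'
#' Both configurations are centered and scaled to unit sum of squares;
#' the optimal rotation (reflections allowed) comes from the singular
#' decomposition of the cross-product. The similarity score is
#' `t0 = sqrt(1 - D)` with D the symmetric Procrustes sum of squared
#' residuals. Collinear configurations are flagged degenerate but still
#' fitted; a constant configuration is an error (scaling is undefined).
#'
#' @param X province points in PC space (provinces x 2), e.g. from
#'   [provinceCentroids()]
#' @param Y province geography (provinces x 2, same row order)
#' @return a [ProcrustesResult][structure-classes] with `perm_p = NA`
#' @export
procrustesFit <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) < 3L) stop("need at least 3 provinces")
  if (!all(dim(X) == dim(Y))) stop("X and Y must match in dimension")
  if (all(apply(X, 2, sd) < 1e-12) || all(apply(Y, 2, sd) < 1e-12))
    stop("degenerate (constant) configuration: scaling undefined")
  fit <- vegan::procrustes(Y, X, symmetric = TRUE)
  D <- fit$ss
  t0 <- sqrt(max(0, 1 - D))
  res <- residuals(fit)
  names(res) <- rownames(Y)
  degen <- min(svd(scale(Y, scale = FALSE))$d) < 1e-10 ||
    min(svd(scale(X, scale = FALSE))$d) < 1e-10
  if (degen) warning("collinear configuration: fit is rank-deficient")
  new("ProcrustesResult", rotation = fit$rotation,
      scale = fit$scale, translation = as.numeric(fit$translation),
      t0 = t0, perm_p = NA_real_, residuals = res, degenerate = degen)
}

#' Permutation test of the Procrustes similarity
#'
#' Rows of X are permuted `n_perm` times; the p-value is
#' `(count of permuted t >= observed t0 + 1) / (n_perm + 1)`.
#'
#' @inheritParams procrustesFit
#' @param n_perm number of permutations
#' @param seed RNG seed (the test is deterministic given a seed)
#' @return a [ProcrustesResult][structure-classes] with `perm_p` filled
#' @export
procrustesPermTest <- function(X, Y, n_perm = 999, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  fit <- procrustesFit(X, Y)
  set.seed(seed)
  Xc <- .pr_norm(as.matrix(X))
  Yc <- .pr_norm(as.matrix(Y))
  hits <- 0L
  n <- nrow(Xc)
  for (i in seq_len(n_perm)) {
    tp <- sum(svd(crossprod(Yc, Xc[sample.int(n), , drop = FALSE]))$d)
    if (tp >= fit@t0 - 1e-12) hits <- hits + 1L
  }
  fit@perm_p <- (hits + 1) / (n_perm + 1)
  fit
}

# center and scale a configuration to unit sum of squares; for two such
# configurations t0 = sum of singular values of their cross-product
.pr_norm <- function(M) {
  M <- scale(M, scale = FALSE)
  M / sqrt(sum(M^2))
}

#' Discriminant analysis of principal components
#'
#' Genotypes are PCA-reduced (Patterson scaling) to `n_pc` scores;
#' linear discriminant analysis with a shared within-class covariance
#' is fitted on the scores, and Gaussian posterior membership
#' probabilities per cluster are computed for every individual and
#' averaged per province. The default `n_pc` is the smallest number of
#' components explaining at least 80% of the PC-space variance.
#'
#' @param G a [GenotypeData-class]
#' @param labels cluster label per sample (default the sample table's
#'   cluster column)
#' @param n_pc number of retained PCs (NULL = 80% rule)
#' @param n_df number of discriminant functions (NULL = K - 1)
#' @param loci optional marker subset (e.g. LD-pruned)
#' @return a [DapcResult][structure-classes]
#' @export
dapc <- function(G, labels = NULL, n_pc = NULL, n_df = NULL, loci = NULL) {
  if (is.null(labels)) labels <- samples(G)$cluster
  K <- length(unique(labels))
  if (K < 2L) stop("need at least 2 clusters")
  if (any(table(labels) < 2L)) stop("every cluster needs >= 2 members")
  max_pc <- min(nrow(genotypes(G)) - 1L, 50L)
  pca <- pcaGenotypes(G, n_components = max_pc, loci = loci)
  if (is.null(n_pc)) {
    cum <- cumsum(pca@var_explained) / sum(pca@var_explained)
    n_pc <- which(cum >= 0.8)[1L]
  }
  n_pc <- as.integer(n_pc)
  sc <- pca@scores[, seq_len(n_pc), drop = FALSE]
  if (is.null(n_df)) n_df <- K - 1L
  fit <- MASS::lda(sc, grouping = factor(labels))
  pr <- predict(fit, as.data.frame(sc))
  post <- pr$posterior
  rownames(post) <- samples(G)$sample_id
  provs <- sort(unique(samples(G)$province))
  pp <- t(vapply(provs, function(p) {
    colMeans(post[samples(G)$province == p, , drop = FALSE])
  }, numeric(ncol(post))))
  rownames(pp) <- provs
  new("DapcResult", n_pc = n_pc,
      discriminants = fit$scaling[, seq_len(min(n_df, ncol(fit$scaling))),
                                  drop = FALSE],
      posteriors = post, province_posteriors = pp,
      assignments = labels)
}
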