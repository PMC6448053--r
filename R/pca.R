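#' Principal components of the standardized genotype matrix
#'
#' Each SNP column is centered by `2p` and scaled by `sqrt(2p(1-p))` (sample
#' frequencies), and the top-`k` principal-component scores of the resulting
#' matrix are returned. These are the usual fixed covariates for population
#' stratification in GREML: subpopulation structure with non-zero Fst shows up
#' as dominant components, while a panmictic sample has none. The sign of each
#' component is fixed so that its largest-magnitude SNP loading is positive.
#'
#' @param genotypes a QC'd [genotype_matrix()].
#' @param k number of components, `k < min(n, m)` (20 in the emulated
#'   analyses; for small simulated cohorts the command-line interface warns
#'   when `k > n/100`).
#' @param grm optional precomputed [grm()] or [grm_eigen()] of the same
#'   genotypes with `diagonal = "simple"` semantics; when supplied, scores are
#'   taken from its eigenvectors instead of redecomposing.
#' @return An object of class `pc_scores`: list with `scores` (`n x k`),
#'   `varprop` (explained-variance fractions of all positive eigenvalues,
#'   non-increasing), `k`.
#' @export
compute_pcs <- function(genotypes, k = 20L, grm = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  n <- nrow(genotypes$dosages); m <- ncol(genotypes$dosages)
  if (k >= min(n, m)) {
    stop("invalid config: k must be smaller than min(n individuals, m SNPs)",
         call. = FALSE)
  }
  z <- standardize_dosages(genotypes$dosages)
  if (is.null(grm)) {
    kmat <- tcrossprod(z) / m
    ed <- eigen(kmat, symmetric = TRUE)
  } else {
    ge <- grm_eigen(grm)
    ed <- list(vectors = ge$vectors, values = ge$values)
  }
  lam <- pmax(ed$values, 0)
  u <- ed$vectors[, seq_len(k), drop = FALSE]
  scores <- sweep(u, 2L, sqrt(lam[seq_len(k)] * m), `*`)
  # sign convention: largest-magnitude SNP loading positive
  loadings <- crossprod(z, u) # m x k, proportional to right singular vectors
  flip <- vapply(seq_len(k), function(j) {
    l <- loadings[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(scores, 2L, flip, `*`)
  structure(list(scores = scores, varprop = lam / sum(lam), k = k),
            class = "pc_scores")
}

#' @export
print.pc_scores <- function(x, ...) {
  cat(sprintf("<pc_scores> %d samples x %d components; leading variance fractions: %s\n",
              nrow(x$scores), x$k,
              paste(sprintf("%.3f", utils::head(x$varprop, 4)), collapse = ", ")))
  invisible(x)
}
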