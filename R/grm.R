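#' Construct a GRM object
#'
#' @param values symmetric `n x n` matrix of relatedness estimates.
#' @param pair_snp_counts `n x n` matrix of non-missing SNP counts per pair
#'   (scalar recycled).
#' @param sample_ids data frame with `fid`, `iid` matching the rows.
#' @return An object of class `grm`.
#' @export
grm <- function(values, pair_snp_counts, sample_ids) {
  values <- as.matrix(values)
  n <- nrow(values)
  stopifnot(ncol(values) == n)
  if (max(abs(values - t(values))) > 1e-6 * max(1, max(abs(values)))) {
    stop("GRM values must be symmetric", call. = FALSE)
  }
  if (length(pair_snp_counts) == 1L) {
    pair_snp_counts <- matrix(pair_snp_counts, n, n)
  }
  pair_snp_counts <- as.matrix(pair_snp_counts)
  if (any(pair_snp_counts < 1)) {
    stop("every retained pair must share at least one non-missing SNP", call. = FALSE)
  }
  sample_ids <- tibble::as_tibble(sample_ids)
  stopifnot(nrow(sample_ids) == n)
  if (anyDuplicated(paste(sample_ids$fid, sample_ids$iid))) {
    stop("sample ids must be unique", call. = FALSE)
  }
  structure(list(values = values, pair_snp_counts = pair_snp_counts,
                 sample_ids = sample_ids),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  n <- nrow(x$values)
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("<grm> %d samples; diag mean %.4f; off-diag mean %.2e (sd %.2e)\n",
              n, mean(diag(x$values)), mean(off), stats::sd(off)))
  invisible(x)
}

#' @export
dim.grm <- function(x) dim(x$values)

#' Compute the genetic relatedness matrix
#'
#' Off-diagonal entries are the average over SNPs non-missing in both
#' individuals of \eqn{(x_{ij} - 2p_i)(x_{ik} - 2p_i) / (2 p_i (1 - p_i))}.
#' The diagonal uses, by default, the within-individual estimator
#' \eqn{A_{jj} = 1 + \frac{1}{m}\sum_i \frac{x^2 - (1+2p)x + 2p^2}{2p(1-p)}}
#' (`diagonal = "gcta"`); `diagonal = "simple"` uses the plain
#' \eqn{(x - 2p)^2 / (2p(1-p))} average. Missing dosages are excluded
#' pairwise and per-pair SNP counts recorded. Frequencies are estimated from
#' the sample unless `freq` is supplied.
#'
#' @param genotypes a [genotype_matrix()]; run [qc_filter()] first so that no
#'   SNP is monomorphic.
#' @param freq optional vector of effect-allele frequencies to standardize by
#'   (defaults to sample frequencies).
#' @param diagonal `"gcta"` (default) or `"simple"`.
#' @return A [grm()].
#' @examples
#' g <- simulate_genotypes(sim_config(n_individuals = 100, n_snps = 500,
#'                                    n_causal = 0, seed = 11))
#' A <- compute_grm(g)
#' mean(diag(A$values))
#' @export
compute_grm <- function(genotypes, freq = NULL, diagonal = c("gcta", "simple")) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  diagonal <- match.arg(diagonal)
  dos <- genotypes$dosages
  n <- nrow(dos); m <- ncol(dos)
  if (is.null(freq)) freq <- allele_frequencies(genotypes)
  if (any(freq <= 0) || any(freq >= 1)) {
    bad <- which(freq <= 0 | freq >= 1)[1]
    stop(sprintf("monomorphic SNP %s: frequency must be strictly inside (0, 1); run QC first",
                 genotypes$snp_meta$id[bad]), call. = FALSE)
  }
  het <- 2 * freq * (1 - freq)
  z <- sweep(dos, 2L, 2 * freq, `-`)
  z <- sweep(z, 2L, sqrt(het), `/`)
  has_missing <- anyNA(dos)
  if (has_missing) {
    obs <- !is.na(dos)
    z[!obs] <- 0
    counts <- tcrossprod(obs * 1)
    if (any(counts < 1)) {
      stop("a pair of individuals shares no non-missing SNP", call. = FALSE)
    }
    a <- tcrossprod(z) / counts
  } else {
    counts <- matrix(m, n, n)
    a <- tcrossprod(z) / m
  }
  if (diagonal == "gcta") {
    num <- dos * dos - sweep(dos, 2L, 1 + 2 * freq, `*`)
    num <- sweep(num, 2L, 2 * freq^2, `+`)
    num <- sweep(num, 2L, het, `/`)
    if (has_missing) {
      num[is.na(num)] <- 0
      diag(a) <- 1 + rowSums(num) / diag(counts)
    } else {
      diag(a) <- 1 + rowMeans(num)
    }
  }
  a <- (a + t(a)) / 2
  grm(values = a, pair_snp_counts = counts, sample_ids = genotypes$sample_ids)
}

#' Greedy relatedness pruning
#'
#' While any off-diagonal relatedness exceeds `cutoff`, drops the sample
#' participating in the most offending pairs (ties broken towards the larger
#' row index). The retained set has no off-diagonal above `cutoff`. The default
#' 0.05 is the usual GREML convention for "unrelated" (second cousins share
#' about 0.03); the identity-by-descent screening threshold 0.1 can be passed
#' instead.
#'
#' @param grm a [grm()].
#' @param cutoff positive relatedness threshold.
#' @return Integer vector of retained sample indices (increasing).
#' @export
prune_related <- function(grm, cutoff = 0.05) {
  stopifnot(inherits(grm, "grm"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop("invalid config: cutoff must be a positive number", call. = FALSE)
  }
  a <- grm$values
  diag(a) <- 0
  keep <- rep(TRUE, nrow(a))
  repeat {
    offending <- (abs(a) * outer(keep, keep)) > cutoff
    deg <- rowSums(offending)
    if (all(deg == 0L)) break
    worst <- max(deg)
    drop <- max(which(deg == worst)) # ties -> larger row index
    keep[drop] <- FALSE
    a[drop, ] <- 0
    a[, drop] <- 0
  }
  which(keep)
}

#' Eigendecomposition of a GRM for repeated REML fits
#'
#' `fit_greml()` and friends work in the eigenbasis of the GRM, where the
#' covariance `V = sigma_g^2 A + sigma_e^2 I` is diagonal; decomposing once and
#' reusing the result makes repeated fits on the same cohort cheap.
#'
#' @param grm a [grm()] or symmetric matrix.
#' @return An object of class `grm_eigen` with `vectors`, `values`,
#'   `sample_ids`.
#' @export
grm_eigen <- function(grm) {
  if (inherits(grm, "grm_eigen")) return(grm)
  if (inherits(grm, "grm")) {
    a <- grm$values
    ids <- grm$sample_ids
  } else {
    a <- as.matrix(grm)
    ids <- tibble::tibble(fid = as.character(seq_len(nrow(a))),
                          iid = as.character(seq_len(nrow(a))))
  }
  if (max(abs(a - t(a))) > 1e-8 * max(1, max(abs(a)))) {
    stop("GRM must be symmetric", call. = FALSE)
  }
  ed <- eigen(a, symmetric = TRUE)
  structure(list(vectors = ed$vectors, values = ed$values, sample_ids = ids),
            class = "grm_eigen")
}
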