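#' Harmonize polygenic-score weights with the genotype coding
#'
#' Matches weights to SNPs by identifier and aligns alleles: when the weight's
#' effect allele equals the dosage-coded allele the weight is kept; when the
#' allele pair is swapped the contribution becomes `w * (2 - x)`, handled as a
#' negated weight plus a per-variant constant `2w`; variants whose alleles
#' match neither orientation are dropped with a warning, never silently
#' scored.
#'
#' @param weights a tibble with `id`, `effect_allele`, `other_allele`, `weight`
#'   (see [read_pgs_weights()]).
#' @param snp_meta the `snp_meta` of a [genotype_matrix()].
#' @return A tibble with `id`, `col` (genotype column), `weight` (signed),
#'   `offset` (additive constant per variant), `flipped`; the match report
#'   (`n_matched`, `n_flipped`, `n_dropped`, `dropped_ids`) in
#'   `attr(, "report")`.
#' @export
align_weights <- function(weights, snp_meta) {
  need <- c("id", "effect_allele", "other_allele", "weight")
  stopifnot(all(need %in% names(weights)))
  idx <- match(weights$id, snp_meta$id)
  found <- !is.na(idx)
  ea <- snp_meta$effect_allele[idx]
  oa <- snp_meta$other_allele[idx]
  same <- found & weights$effect_allele == ea & weights$other_allele == oa
  flip <- found & weights$effect_allele == oa & weights$other_allele == ea
  drop <- !(same | flip)
  if (any(drop)) {
    warning(sprintf("%d variant(s) dropped (unresolvable id or allele pair): %s",
                    sum(drop),
                    paste(utils::head(weights$id[drop], 5), collapse = ", ")),
            call. = FALSE)
  }
  keep <- which(!drop)
  out <- tibble::tibble(
    id = weights$id[keep],
    col = idx[keep],
    weight = ifelse(flip[keep], -weights$weight[keep], weights$weight[keep]),
    offset = ifelse(flip[keep], 2 * weights$weight[keep], 0),
    flipped = flip[keep]
  )
  attr(out, "report") <- list(n_matched = length(keep), n_flipped = sum(flip),
                              n_dropped = sum(drop),
                              dropped_ids = weights$id[drop])
  out
}

#' Compute a weighted allelic score
#'
#' `score_j = sum_i w_i x_ij` over harmonized variants, plus the flip offsets.
#' A missing dosage contributes its expectation `2 p_i w_i` (mean imputation,
#' the standard allelic-scoring behaviour); `impute_missing = FALSE` instead
#' propagates `NA` for individuals with any missing scored variant.
#'
#' @param genotypes a [genotype_matrix()].
#' @param weights raw weights (harmonized internally via [align_weights()]) or
#'   the output of [align_weights()].
#' @param impute_missing mean-impute missing dosages (default `TRUE`).
#' @return A tibble `sample_id`, `pgs`.
#' @export
compute_pgs <- function(genotypes, weights, impute_missing = TRUE) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!"col" %in% names(weights)) {
    weights <- align_weights(weights, genotypes$snp_meta)
  }
  if (nrow(weights) == 0L) {
    stop("no weight variant matches the genotype panel", call. = FALSE)
  }
  x <- genotypes$dosages[, weights$col, drop = FALSE]
  if (anyNA(x)) {
    if (impute_missing) {
      p <- colMeans(x, na.rm = TRUE) / 2
      for (j in seq_len(ncol(x))) {
        x[is.na(x[, j]), j] <- 2 * p[j]
      }
    }
  }
  score <- as.vector(x %*% weights$weight) + sum(weights$offset)
  tibble::tibble(sample_id = genotypes$sample_ids$iid, pgs = score)
}

#' Incremental variance explained by a polygenic score
#'
#' `R^2(covariates + pgs) - R^2(covariates)` from ordinary least squares on
#' the inverse-normal transformed phenotype, reported as a percentage.
#'
#' @param phenotype numeric outcome.
#' @param pgs polygenic score vector.
#' @param covariates optional data frame / matrix of covariates.
#' @param int inverse-normal transform the phenotype first (default `TRUE`).
#' @return Incremental R-squared in percent (a scalar).
#' @export
incremental_r2 <- function(phenotype, pgs, covariates = NULL, int = TRUE) {
  stopifnot(length(phenotype) == length(pgs))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(phenotype))
    cc <- is.finite(phenotype) & is.finite(pgs) & stats::complete.cases(covariates)
    xr <- stats::model.matrix(~ ., data = covariates[cc, , drop = FALSE])
  } else {
    cc <- is.finite(phenotype) & is.finite(pgs)
    xr <- matrix(1, sum(cc), 1)
  }
  y <- if (int) int_transform(phenotype[cc]) else phenotype[cc]
  xf <- cbind(xr, pgs = pgs[cc])
  if (qr(xf)$rank < ncol(xf)) {
    stop("polygenic score is collinear with the covariates", call. = FALSE)
  }
  r2 <- function(xm) {
    res <- qr.resid(qr(xm), y)
    1 - sum(res^2) / sum((y - mean(y))^2)
  }
  100 * (r2(xf) - r2(xr))
}

#' Synthetic GWAS weight table for the simulated cohort
#'
#' The real discovery-GWAS weight table is external to any simulation, so this
#' builds the synthetic stand-in: the `n_variants` causal SNPs with the
#' largest absolute true effects, converted to the per-allele scale, plus
#' Gaussian estimation noise emulating discovery/replication error.
#'
#' @param genotypes a [genotype_matrix()].
#' @param effects causal-effect table from [draw_causal_effects()].
#' @param n_variants number of index variants (default 74).
#' @param noise_sd standard deviation of the estimation noise, as a multiple
#'   of the per-allele weight SD (default 0.5).
#' @param seed integer seed.
#' @return A weight tibble (`id`, `effect_allele`, `other_allele`, `weight`).
#' @export
synthetic_gwas_weights <- function(genotypes, effects, n_variants = 74L,
                                   noise_sd = 0.5, seed = 1L) {
  stopifnot(nrow(effects) > 0L)
  n_variants <- min(n_variants, nrow(effects))
  idx <- match(effects$id, genotypes$snp_meta$id)
  p <- allele_frequencies(genotypes)[idx]
  per_allele <- effects$beta / sqrt(2 * p * (1 - p))
  top <- order(abs(per_allele), decreasing = TRUE)[seq_len(n_variants)]
  withr::with_seed(seed, {
    w <- per_allele[top]
    w <- w + stats::rnorm(n_variants, 0, noise_sd * stats::sd(w))
    tibble::tibble(
      id = effects$id[top],
      effect_allele = genotypes$snp_meta$effect_allele[idx[top]],
      other_allele = genotypes$snp_meta$other_allele[idx[top]],
      weight = w
    )
  })
}
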