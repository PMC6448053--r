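#' Construct a genotype matrix object
#'
#' A thin container for an `n x m` dosage matrix (counts of the effect allele,
#' values 0/1/2 with `NA` for missing), per-sample identifiers and per-SNP
#' metadata, mirroring what a PLINK bed/bim/fam triplet stores.
#'
#' @param dosages integer/numeric matrix, individuals in rows, SNPs in columns.
#' @param sample_ids data frame with columns `fid`, `iid` (unique).
#' @param snp_meta data frame with columns `id`, `chr`, `pos`, `effect_allele`,
#'   `other_allele` and optionally `freq` (ancestral effect-allele frequency).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, sample_ids, snp_meta) {
  dosages <- as.matrix(dosages)
  ok <- is.na(dosages) | dosages == 0 | dosages == 1 | dosages == 2
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  sample_ids <- tibble::as_tibble(sample_ids)
  snp_meta <- tibble::as_tibble(snp_meta)
  stopifnot(nrow(sample_ids) == nrow(dosages), nrow(snp_meta) == ncol(dosages))
  if (anyDuplicated(paste(sample_ids$fid, sample_ids$iid))) {
    stop("sample ids must be unique", call. = FALSE)
  }
  if (anyDuplicated(snp_meta$id)) stop("SNP ids must be unique", call. = FALSE)
  dimnames(dosages) <- list(sample_ids$iid, snp_meta$id)
  structure(list(dosages = dosages, sample_ids = sample_ids, snp_meta = snp_meta),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Simulate independent biallelic SNP genotypes
#'
#' Ancestral effect-allele frequencies are drawn uniformly on
#' `config$maf_range`. With a single subpopulation, dosages are
#' `Binomial(2, p)` draws. With `n_subpops > 1`, subpopulation frequencies are
#' drawn from the Balding-Nichols distribution
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` around the ancestral frequency
#' with differentiation `F = config$fst`, and individuals are split evenly
#' across subpopulations; this creates the allele-frequency structure that the
#' principal-component covariates are meant to absorb. SNPs are independent
#' (no linkage disequilibrium). Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A [genotype_matrix()]; the subpopulation label of each individual is
#'   stored in `sample_ids$subpop`, the ancestral frequency in `snp_meta$freq`.
#' @examples
#' g <- simulate_genotypes(sim_config(n_individuals = 50, n_snps = 20,
#'                                    n_causal = 5, seed = 7))
#' dim(g)
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  m <- config$n_snps
  withr::with_seed(config$seed, {
    p_anc <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    subpop <- rep_len(seq_len(config$n_subpops), n)
    if (config$n_subpops > 1L) {
      f <- config$fst
      # m x n_subpops matrix of drifted frequencies
      p_sub <- matrix(stats::rbeta(m * config$n_subpops,
                                   rep(p_anc, config$n_subpops) * (1 - f) / f,
                                   rep(1 - p_anc, config$n_subpops) * (1 - f) / f),
                      nrow = m)
      p_sub <- pmin(pmax(p_sub, 1e-6), 1 - 1e-6)
      dos <- matrix(stats::rbinom(n * m, 2L, t(p_sub)[subpop, , drop = FALSE]),
                    nrow = n, ncol = m)
    } else {
      dos <- matrix(stats::rbinom(n * m, 2L, rep(p_anc, each = n)), nrow = n, ncol = m)
    }
    if (config$missing_rate > 0) {
      dos[stats::runif(n * m) < config$missing_rate] <- NA_integer_
    }
    genotype_matrix(
      dosages = dos,
      sample_ids = tibble::tibble(
        fid = sprintf("F%05d", seq_len(n)),
        iid = sprintf("I%05d", seq_len(n)),
        subpop = subpop
      ),
      snp_meta = tibble::tibble(
        id = sprintf("snp%05d", seq_len(m)),
        chr = 1L,
        pos = seq_len(m) * 1000L,
        effect_allele = "A",
        other_allele = "G",
        freq = p_anc
      )
    )
  })
}

#' Draw causal SNP effects for the polygenic ability component
#'
#' Chooses `config$n_causal` polymorphic SNPs without replacement and draws
#' their effect sizes i.i.d. normal on the standardized-dosage scale. Betas are rescaled so
#' that the genetic value `G = Z beta` (with `Z` the frequency-standardized
#' dosages) has unit sample variance; stage-specific heritability shares are
#' applied later by [simulate_cohort()]. Deterministic given `config$seed`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param config a [sim_config()] with `n_causal <= n_snps`.
#' @return A tibble with one row per causal SNP: `id`, `effect_allele`,
#'   `beta` (standardized scale); the realized genetic values are attached as
#'   attribute `"g_value"`.
#' @export
draw_causal_effects <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(config, "sim_config"))
  m <- ncol(genotypes$dosages)
  if (config$n_causal > m) {
    stop("invalid config: n_causal exceeds the number of SNPs", call. = FALSE)
  }
  n <- nrow(genotypes$dosages)
  withr::with_seed(config$seed + 1L, {
    if (config$n_causal == 0L) {
      out <- tibble::tibble(id = character(), effect_allele = character(),
                            beta = numeric())
      attr(out, "g_value") <- rep(0, n)
      return(out)
    }
    p_hat <- colMeans(genotypes$dosages, na.rm = TRUE) / 2
    poly <- which(p_hat > 0 & p_hat < 1)
    if (config$n_causal > length(poly)) {
      stop("invalid config: fewer polymorphic SNPs than n_causal", call. = FALSE)
    }
    idx <- sort(sample(poly, config$n_causal))
    beta <- stats::rnorm(config$n_causal)
    z <- standardize_dosages(genotypes$dosages[, idx, drop = FALSE])
    g <- as.vector(z %*% beta)
    s <- stats::sd(g)
    if (s > 0) {
      beta <- beta / s
      g <- g / s
    }
    out <- tibble::tibble(
      id = genotypes$snp_meta$id[idx],
      effect_allele = genotypes$snp_meta$effect_allele[idx],
      beta = beta
    )
    attr(out, "g_value") <- g
    out
  })
}

# Center by 2p and scale by sqrt(2p(1-p)) using sample frequencies; missing
# dosages become 0 (i.e. the mean) after standardization.
standardize_dosages <- function(dosages, freq = NULL) {
  if (is.null(freq)) freq <- colMeans(dosages, na.rm = TRUE) / 2
  denom <- sqrt(2 * freq * (1 - freq))
  if (any(!is.finite(denom)) || any(denom <= 0)) {
    bad <- which(!is.finite(denom) | denom <= 0)[1]
    stop(sprintf("monomorphic SNP (column %d): cannot standardize", bad),
         call. = FALSE)
  }
  z <- sweep(dosages, 2L, 2 * freq, `-`)
  z <- sweep(z, 2L, denom, `/`)
  z[is.na(z)] <- 0
  z
}
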