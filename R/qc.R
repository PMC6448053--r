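#' Per-SNP effect-allele frequencies
#'
#' `p = (sum of non-missing dosages) / (2 * non-missing count)` per SNP.
#'
#' @param genotypes a [genotype_matrix()].
#' @return Named numeric vector of frequencies.
#' @export
allele_frequencies <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  nn <- colSums(!is.na(genotypes$dosages))
  if (any(nn == 0L)) {
    stop(sprintf("SNP %s has no non-missing calls",
                 genotypes$snp_meta$id[which(nn == 0L)[1]]), call. = FALSE)
  }
  colSums(genotypes$dosages, na.rm = TRUE) / (2 * nn)
}

# Hardy-Weinberg chi-square goodness-of-fit p-value (1 df) per SNP, from
# genotype counts n0/n1/n2 of the effect allele.
hwe_pvalues <- function(dosages) {
  n0 <- colSums(dosages == 0, na.rm = TRUE)
  n1 <- colSums(dosages == 1, na.rm = TRUE)
  n2 <- colSums(dosages == 2, na.rm = TRUE)
  nn <- n0 + n1 + n2
  p <- (n1 + 2 * n2) / (2 * nn)
  e0 <- nn * (1 - p)^2
  e1 <- nn * 2 * p * (1 - p)
  e2 <- nn * p^2
  stat <- (n0 - e0)^2 / pmax(e0, .Machine$double.eps) +
    (n1 - e1)^2 / pmax(e1, .Machine$double.eps) +
    (n2 - e2)^2 / pmax(e2, .Machine$double.eps)
  # monomorphic SNPs carry no HWE information
  stat[p <= 0 | p >= 1] <- 0
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Genotype quality control
#'
#' Removes SNPs with minor allele frequency below `maf_min`, call rate below
#' `call_rate_min`, or Hardy-Weinberg equilibrium violation (chi-square
#' goodness of fit, 1 df) at `P < hwe_p_min`; then removes samples whose
#' missingness across the retained SNPs exceeds `sample_missing_max`. The
#' default thresholds are the conventional ones for GREML input (MAF < 1%,
#' call rate < 95%, HWE P < 5e-7, individual missingness > 3%). Order of the
#' retained rows and columns is preserved.
#'
#' @param genotypes a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency.
#' @param call_rate_min minimum per-SNP call rate.
#' @param hwe_p_min HWE p-value threshold below which a SNP is removed.
#' @param sample_missing_max maximum per-sample missingness.
#' @return A list with elements `genotypes` (filtered [genotype_matrix()]) and
#'   `report` (a `qc_report`: thresholds, per-filter removal counts, removed
#'   SNP/sample ids).
#' @export
qc_filter <- function(genotypes, maf_min = 0.01, call_rate_min = 0.95,
                      hwe_p_min = 5e-7, sample_missing_max = 0.03) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  stopifnot(maf_min >= 0, maf_min < 0.5, call_rate_min >= 0, call_rate_min <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1,
            sample_missing_max >= 0, sample_missing_max <= 1)
  dos <- genotypes$dosages
  n <- nrow(dos)

  call_rate <- colMeans(!is.na(dos))
  informative <- call_rate > 0
  p <- rep(NA_real_, ncol(dos))
  p[informative] <- colSums(dos[, informative, drop = FALSE], na.rm = TRUE) /
    (2 * colSums(!is.na(dos[, informative, drop = FALSE])))
  maf <- pmin(p, 1 - p)
  hwe_p <- hwe_pvalues(dos)

  fail_call <- call_rate < call_rate_min
  fail_maf <- !fail_call & (is.na(maf) | maf < maf_min)
  fail_hwe <- !fail_call & !fail_maf & !is.na(hwe_p) & hwe_p < hwe_p_min
  keep_snp <- !(fail_call | fail_maf | fail_hwe)

  dos2 <- dos[, keep_snp, drop = FALSE]
  sample_miss <- if (ncol(dos2)) rowMeans(is.na(dos2)) else rep(1, n)
  keep_sample <- sample_miss <= sample_missing_max

  if (!any(keep_snp) || !any(keep_sample)) {
    stop("QC removed every SNP or every sample: degenerate result", call. = FALSE)
  }

  out <- genotype_matrix(
    dosages = dos2[keep_sample, , drop = FALSE],
    sample_ids = genotypes$sample_ids[keep_sample, , drop = FALSE],
    snp_meta = genotypes$snp_meta[keep_snp, , drop = FALSE]
  )
  report <- structure(list(
    thresholds = list(maf_min = maf_min, call_rate_min = call_rate_min,
                      hwe_p_min = hwe_p_min, sample_missing_max = sample_missing_max),
    n_snps_in = ncol(dos), n_snps_out = ncol(dos2),
    n_samples_in = n, n_samples_out = sum(keep_sample),
    removed_call_rate = sum(fail_call),
    removed_maf = sum(fail_maf),
    removed_hwe = sum(fail_hwe),
    removed_samples = sum(!keep_sample),
    removed_snp_ids = genotypes$snp_meta$id[!keep_snp],
    removed_sample_ids = genotypes$sample_ids$iid[!keep_sample]
  ), class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  SNPs: %d -> %d (call rate: -%d, MAF: -%d, HWE: -%d)\n",
              x$n_snps_in, x$n_snps_out, x$removed_call_rate, x$removed_maf,
              x$removed_hwe))
  cat(sprintf("  samples: %d -> %d (missingness: -%d)\n",
              x$n_samples_in, x$n_samples_out, x$removed_samples))
  invisible(x)
}
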