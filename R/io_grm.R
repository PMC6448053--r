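#' Write / read a GRM in the GCTA binary dialect
#'
#' `prefix.grm.bin` holds the lower triangle including the diagonal, row-major
#' (pair (j,k), k <= j, ordered by j then k), as 4-byte little-endian floats;
#' `prefix.grm.N.bin` the matching per-pair non-missing SNP counts (also
#' 4-byte floats, as GCTA writes them); `prefix.grm.id` two tab-separated ID
#' columns (FID, IID). Read of a written triplet reproduces the GRM at 4-byte
#' float precision, and re-writing what was read is byte-identical.
#'
#' @param grm a [grm()].
#' @param prefix path prefix.
#' @return `write_grm_binary()` returns `prefix` invisibly; `read_grm_binary()`
#'   returns a [grm()].
#' @export
write_grm_binary <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  n <- nrow(grm$values)
  j <- rep(seq_len(n), seq_len(n))
  k <- sequence(seq_len(n))
  idx <- cbind(j, k)
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(grm$values[idx]), con, size = 4L, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(grm$pair_snp_counts[idx]), con, size = 4L, endian = "little")
  close(con)
  utils::write.table(grm$sample_ids[, c("fid", "iid")],
                     paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_grm_binary
#' @export
read_grm_binary <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"), header = FALSE,
                           stringsAsFactors = FALSE, col.names = c("fid", "iid"))
  n <- nrow(ids)
  n_tri <- n * (n + 1) / 2
  read_tri <- function(path) {
    sz <- file.size(path)
    if (is.na(sz) || sz != 4 * n_tri) {
      stop(sprintf("corrupt GRM file %s: expected %d bytes for %d samples, found %s",
                   path, 4 * n_tri, n, ifelse(is.na(sz), "none", sz)), call. = FALSE)
    }
    readBin(path, "numeric", n = n_tri, size = 4L, endian = "little")
  }
  vals <- read_tri(paste0(prefix, ".grm.bin"))
  cnts <- read_tri(paste0(prefix, ".grm.N.bin"))
  j <- rep(seq_len(n), seq_len(n))
  k <- sequence(seq_len(n))
  a <- matrix(0, n, n); cc <- matrix(0, n, n)
  a[cbind(j, k)] <- vals; a[cbind(k, j)] <- vals
  cc[cbind(j, k)] <- cnts; cc[cbind(k, j)] <- cnts
  grm(values = a, pair_snp_counts = cc, sample_ids = ids)
}

#' Read / write GCTA-style phenotype and covariate text files
#'
#' Whitespace-separated files with columns `FID IID value(s)` and no header;
#' missing values coded `NA` or `-9` are both read as missing.
#'
#' @param path file path.
#' @param n_values number of value columns expected (default: all present).
#' @return A tibble with `fid`, `iid` and value columns `v1`, `v2`, ...
#' @export
read_pheno <- function(path, n_values = NULL) {
  d <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         na.strings = c("NA", "-9"))
  if (ncol(d) < 3L) stop("phenotype/covariate file needs FID IID value(s)", call. = FALSE)
  if (!is.null(n_values)) d <- d[, seq_len(2L + n_values), drop = FALSE]
  names(d) <- c("fid", "iid", paste0("v", seq_len(ncol(d) - 2L)))
  tibble::as_tibble(d)
}

#' @rdname read_pheno
#' @param x tibble/data frame whose first two columns are FID and IID.
#' @export
write_pheno <- function(x, path) {
  utils::write.table(x, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a polygenic-score weight table
#'
#' Tab-separated with header columns `id`, `effect_allele`, `other_allele`,
#' `weight` (per-allele effect size).
#'
#' @param path file path.
#' @return A tibble of weights.
#' @export
read_pgs_weights <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("id", "effect_allele", "other_allele", "weight")
  if (!all(need %in% names(d))) {
    stop("weight file must have columns id, effect_allele, other_allele, weight",
         call. = FALSE)
  }
  tibble::as_tibble(d[, need])
}

#' @rdname read_pgs_weights
#' @param weights a weight tibble.
#' @export
write_pgs_weights <- function(weights, path) {
  utils::write.table(weights, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
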