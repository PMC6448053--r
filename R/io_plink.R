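#' Write genotypes as a PLINK bed/bim/fam triplet
#'
#' Variant-major bed (magic bytes `0x6C 0x1B`, mode `0x01`), two bits per
#' genotype packed four per byte from the least significant bits. Coding:
#' the `.bim` fifth column (allele 1) is the effect allele; dosage 2 (two
#' effect alleles) is stored as code `00`, heterozygote as `10`, dosage 0 as
#' `11`, missing as `01`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param prefix output path prefix (files `prefix.bed/.bim/.fam`).
#' @return `prefix`, invisibly.
#' @export
write_plink_bed <- function(genotypes, prefix) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  dos <- genotypes$dosages
  n <- nrow(dos); m <- ncol(dos)
  # dosage -> 2-bit code
  code <- matrix(3L, n, m)
  code[dos == 2] <- 0L
  code[dos == 1] <- 2L
  code[is.na(dos)] <- 1L
  n_pad <- ceiling(n / 4) * 4
  if (n_pad > n) code <- rbind(code, matrix(0L, n_pad - n, m))
  dim(code) <- c(4L, n_pad / 4 * m)
  bytes <- as.raw(colSums(code * c(1L, 4L, 16L, 64L)))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)

  sm <- genotypes$snp_meta
  utils::write.table(
    data.frame(sm$chr, sm$id, 0L, sm$pos, sm$effect_allele, sm$other_allele),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  ids <- genotypes$sample_ids
  utils::write.table(
    data.frame(ids$fid, ids$iid, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK bed/bim/fam triplet
#'
#' @param prefix path prefix of the triplet.
#' @return A [genotype_matrix()] (dosages count the `.bim` allele-1).
#' @export
read_plink_bed <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chr", "id", "cm", "pos",
                                         "effect_allele", "other_allele"))
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"))
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK bed file: bad magic bytes", call. = FALSE)
  }
  if (raw[3] != as.raw(0x01)) {
    stop("unsupported bed mode: only variant-major (0x01) is handled", call. = FALSE)
  }
  bpf <- ceiling(n / 4)
  payload <- raw[-(1:3)]
  if (length(payload) != bpf * m) {
    stop(sprintf("bed payload size %d does not match %d samples x %d SNPs from fam/bim",
                 length(payload), n, m), call. = FALSE)
  }
  v <- as.integer(payload)
  codes <- rbind(v %% 4L, (v %/% 4L) %% 4L, (v %/% 16L) %% 4L, (v %/% 64L) %% 4L)
  dim(codes) <- c(4L * bpf, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  map <- c(2L, NA_integer_, 1L, 0L) # codes 0..3
  dos <- matrix(map[codes + 1L], n, m)
  genotype_matrix(
    dosages = dos,
    sample_ids = tibble::as_tibble(fam[, c("fid", "iid")]),
    snp_meta = tibble::as_tibble(bim[, c("id", "chr", "pos", "effect_allele",
                                         "other_allele")])
  )
}
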