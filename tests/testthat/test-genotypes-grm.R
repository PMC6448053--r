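toy_genotypes <- function(dos) {
  n <- nrow(dos); m <- ncol(dos)
  genotype_matrix(
    dosages = dos,
    sample_ids = tibble::tibble(fid = paste0("F", 1:n), iid = paste0("I", 1:n)),
    snp_meta = tibble::tibble(id = paste0("s", 1:m), chr = 1L, pos = 1:m,
                              effect_allele = "A", other_allele = "G")
  )
}

test_that("allele frequencies match the counting definition", {
  g <- toy_genotypes(matrix(c(0, 1, 2), ncol = 1))
  expect_equal(unname(allele_frequencies(g)), 0.5)
  g2 <- toy_genotypes(matrix(2, 3, 1))
  expect_equal(unname(allele_frequencies(g2)), 1.0)

  # loop oracle on a seeded matrix with missingness
  withr::with_seed(5, {
    dos <- matrix(sample(c(0:2, NA), 20 * 50, TRUE, prob = c(.3, .3, .3, .1)),
                  20, 50)
  })
  dos[, 1] <- c(rep(NA, 19), 1) # nearly all-missing but defined
  g3 <- toy_genotypes(dos)
  oracle <- vapply(1:50, function(j) {
    x <- dos[, j]; sum(x, na.rm = TRUE) / (2 * sum(!is.na(x)))
  }, numeric(1))
  expect_equal(unname(allele_frequencies(g3)), oracle)

  dos[, 2] <- NA
  expect_error(allele_frequencies(toy_genotypes(dos)), "s2")
})

test_that("qc_filter removes exactly the planted violations", {
  withr::with_seed(9, {
    n <- 200
    p <- runif(6, 0.2, 0.4)
    dos <- sapply(p, function(pp) rbinom(n, 2, pp))
  })
  dos[, 3] <- c(rep(0L, 199), 1L) # MAF = 1/400, below the 1% threshold
  g <- toy_genotypes(dos)
  res <- qc_filter(g)
  expect_identical(res$report$removed_maf, 1L)
  expect_identical(res$genotypes$snp_meta$id, paste0("s", c(1, 2, 4, 5, 6)))

  # clean matrix passes through untouched
  clean <- toy_genotypes(dos[, -3])
  res2 <- qc_filter(clean)
  expect_identical(res2$genotypes$dosages, clean$dosages)
  expect_identical(res2$report$n_snps_out, 5L)

  # planted violations of each filter vs a per-SNP oracle
  withr::with_seed(10, {
    dos <- sapply(runif(40, 0.15, 0.45), function(pp) rbinom(300, 2, pp))
    dos[sample(length(dos), 600)] <- NA
    na_rows <- sample(300, 40)
  })
  dos[, 1] <- c(rep(0L, 298), 1L, 1L)          # MAF = 2/600, low
  dos[na_rows, 2] <- NA                        # low call rate
  dos[, 3] <- rep(c(0, 2), each = 150)         # extreme HWE violation
  dos[1, ] <- NA; dos[1, 1:10] <- 0            # high sample missingness
  g <- toy_genotypes(dos)
  res <- qc_filter(g)
  rep <- res$report

  # oracle: first failed filter in order call-rate, MAF, HWE
  cr <- colMeans(!is.na(dos))
  p_hat <- colSums(dos, na.rm = TRUE) / (2 * colSums(!is.na(dos)))
  maf <- pmin(p_hat, 1 - p_hat)
  hwe <- vapply(seq_len(ncol(dos)), function(j) {
    x <- dos[, j][!is.na(dos[, j])]
    nn <- length(x); pj <- mean(x) / 2
    if (pj <= 0 || pj >= 1) return(1)
    obs <- c(sum(x == 0), sum(x == 1), sum(x == 2))
    ex <- nn * c((1 - pj)^2, 2 * pj * (1 - pj), pj^2)
    pchisq(sum((obs - ex)^2 / ex), 1, lower.tail = FALSE)
  }, numeric(1))
  o_call <- cr < 0.95
  o_maf <- !o_call & maf < 0.01
  o_hwe <- !o_call & !o_maf & hwe < 5e-7
  expect_identical(rep$removed_call_rate, sum(o_call))
  expect_identical(rep$removed_maf, sum(o_maf))
  expect_identical(rep$removed_hwe, sum(o_hwe))
  keep <- !(o_call | o_maf | o_hwe)
  o_samp <- rowMeans(is.na(dos[, keep])) > 0.03
  expect_identical(rep$removed_samples, sum(o_samp))
  expect_identical(rep$n_snps_in - rep$n_snps_out,
                   rep$removed_call_rate + rep$removed_maf + rep$removed_hwe)

  expect_error(qc_filter(toy_genotypes(matrix(0L, 20, 2))),
               "degenerate")
})

test_that("GRM matches hand values and the triple-loop oracle", {
  # identical homozygous-alternate pair at p = 0.5: each SNP contributes
  # (2-1)(2-1)/0.5 = 2
  g <- toy_genotypes(matrix(2, 2, 4))
  A <- compute_grm(g, freq = rep(0.5, 4))
  expect_equal(A$values[1, 2], 2)
  # opposite homozygotes: (2-1)(0-1)/0.5 = -2
  g2 <- toy_genotypes(rbind(rep(2, 4), rep(0, 4)))
  expect_equal(compute_grm(g2, freq = rep(0.5, 4))$values[1, 2], -2)

  # sample frequencies on monomorphic data must error
  expect_error(compute_grm(g), "monomorphic")

  # brute-force oracle, 5 x 8, including the GCTA diagonal
  withr::with_seed(21, dos <- matrix(rbinom(40, 2, runif(8, 0.2, 0.8)), 5, 8,
                                     byrow = FALSE))
  dos[2, 3] <- NA
  g3 <- toy_genotypes(dos)
  A3 <- compute_grm(g3)
  p <- colSums(dos, na.rm = TRUE) / (2 * colSums(!is.na(dos)))
  oracle <- matrix(0, 5, 5); counts <- matrix(0, 5, 5)
  for (j in 1:5) for (k in 1:5) {
    s <- 0; cnt <- 0
    for (i in 1:8) {
      xj <- dos[j, i]; xk <- dos[k, i]
      if (is.na(xj) || is.na(xk)) next
      cnt <- cnt + 1
      s <- s + if (j == k) {
        (xj^2 - (1 + 2 * p[i]) * xj + 2 * p[i]^2) / (2 * p[i] * (1 - p[i]))
      } else {
        (xj - 2 * p[i]) * (xk - 2 * p[i]) / (2 * p[i] * (1 - p[i]))
      }
    }
    oracle[j, k] <- if (j == k) 1 + s / cnt else s / cnt
    counts[j, k] <- cnt
  }
  expect_lt(max(abs(A3$values - oracle)), 1e-12)
  expect_equal(unname(A3$pair_snp_counts), counts)
})

test_that("GRM is invariant to SNP order and equivariant to sample order", {
  fx <- small_cohort_fixture()
  g <- fx$g
  perm_snp <- sample(ncol(g$dosages))
  g_s <- genotype_matrix(g$dosages[, perm_snp], g$sample_ids,
                         g$snp_meta[perm_snp, ])
  expect_equal(compute_grm(g_s)$values, fx$grm$values, tolerance = 1e-12)

  perm <- sample(nrow(g$dosages))
  g_p <- genotype_matrix(g$dosages[perm, ], g$sample_ids[perm, ], g$snp_meta)
  expect_equal(compute_grm(g_p)$values, fx$grm$values[perm, perm],
               tolerance = 1e-12)
})

test_that("GRM of clean simulated data is calibrated and QC is a no-op", {
  fx <- small_cohort_fixture()
  A <- fx$grm$values
  n <- nrow(A)
  expect_lt(abs(mean(diag(A)) - 1), 0.05)
  off <- A[upper.tri(A)]
  # sample-frequency centering forces a small negative mean of order -1/n
  expect_lt(abs(mean(off)), 2 / n)
  # approximately 1/m off-diagonal variance for independent SNPs
  expect_equal(var(off), 1 / ncol(fx$g$dosages), tolerance = 0.3)

  res <- qc_filter(fx$g)
  expect_equal(compute_grm(res$genotypes)$values, A, tolerance = 1e-12)
})

test_that("greedy relatedness pruning matches the exhaustive optimum", {
  base <- diag(12) * 0 + 0.01
  diag(base) <- 1
  # planted cliques {1,2,3} and {5,6,7,8} above the cutoff
  for (p in list(c(1, 2), c(1, 3), c(2, 3), c(5, 6), c(5, 7), c(5, 8),
                 c(6, 7), c(6, 8), c(7, 8))) {
    base[p[1], p[2]] <- base[p[2], p[1]] <- 0.2
  }
  gm <- grm(base, 100, tibble::tibble(fid = paste0("F", 1:12),
                                      iid = paste0("I", 1:12)))
  kept <- prune_related(gm, cutoff = 0.05)
  # no offending pair remains
  sub <- base[kept, kept]; diag(sub) <- 0
  expect_true(all(abs(sub) <= 0.05))

  # exhaustive maximum independent set on the threshold graph
  adj <- abs(base) > 0.05; diag(adj) <- FALSE
  best <- 0
  for (mask in 0:(2^12 - 1)) {
    set <- which(bitwAnd(mask, 2^(0:11)) > 0)
    if (length(set) <= best) next
    if (!any(adj[set, set])) best <- length(set)
  }
  expect_identical(length(kept), best)

  # trivial cases
  low <- base * 0 + 0.02; diag(low) <- 1
  gm_low <- grm(low, 100, gm$sample_ids)
  expect_identical(prune_related(gm_low, 0.05), 1:12)
  one <- low; one[1, 2] <- one[2, 1] <- 0.2
  expect_identical(length(prune_related(grm(one, 100, gm$sample_ids), 0.05)), 11L)
  expect_error(prune_related(gm, cutoff = 0), "cutoff")
})

test_that("PLINK bed round-trip is exact and malformed files are rejected", {
  # 4 individuals x 1 SNP occupy exactly one payload byte
  g4 <- toy_genotypes(matrix(c(0, 1, 2, NA), 4, 1))
  prefix <- withr::local_tempfile()
  write_plink_bed(g4, prefix)
  expect_identical(file.size(paste0(prefix, ".bed")), 4) # 3 magic + 1 payload
  back4 <- read_plink_bed(prefix)
  expect_identical(back4$dosages[, 1], c(I1 = 0L, I2 = 1L, I3 = 2L, I4 = NA))

  fx <- small_cohort_fixture()
  g <- fx$g
  g$dosages[sample(length(g$dosages), 500)] <- NA_integer_
  prefix2 <- withr::local_tempfile()
  write_plink_bed(g, prefix2)
  back <- read_plink_bed(prefix2)
  expect_identical(unname(back$dosages), unname(g$dosages))
  expect_identical(back$sample_ids$iid, g$sample_ids$iid)
  expect_identical(back$snp_meta$effect_allele, g$snp_meta$effect_allele)

  # corrupt the magic
  raw <- readBin(paste0(prefix2, ".bed"), "raw", 10)
  con <- file(paste0(prefix2, ".bed"), "r+b")
  writeBin(as.raw(0), con); close(con)
  expect_error(read_plink_bed(prefix2), "magic")
})

test_that("GCTA GRM binary round-trip is exact at float precision", {
  fx <- small_cohort_fixture()
  sub <- 1:3
  gm3 <- grm(fx$grm$values[sub, sub], fx$grm$pair_snp_counts[sub, sub],
             fx$grm$sample_ids[sub, ])
  prefix <- withr::local_tempfile()
  write_grm_binary(gm3, prefix)
  expect_identical(file.size(paste0(prefix, ".grm.bin")), 6 * 4) # n(n+1)/2 floats

  back <- read_grm_binary(prefix)
  expect_equal(back$values, unname(gm3$values), tolerance = 1e-6) # float32
  # re-writing what was read is bit-identical
  prefix2 <- withr::local_tempfile()
  write_grm_binary(back, prefix2)
  expect_identical(readBin(paste0(prefix, ".grm.bin"), "raw", 1e4),
                   readBin(paste0(prefix2, ".grm.bin"), "raw", 1e4))
  expect_identical(readBin(paste0(prefix, ".grm.N.bin"), "raw", 1e4),
                   readBin(paste0(prefix2, ".grm.N.bin"), "raw", 1e4))

  # truncated triplet member
  writeBin(readBin(paste0(prefix, ".grm.bin"), "raw", 10),
           paste0(prefix, ".grm.bin"))
  expect_error(read_grm_binary(prefix), "corrupt")
})

test_that("phenotype files accept NA and -9 as missing", {
  path <- withr::local_tempfile()
  writeLines(c("F1 I1 1.5", "F2 I2 -9", "F3 I3 NA"), path)
  d <- read_pheno(path)
  expect_identical(d$v1, c(1.5, NA, NA))
})
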