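test_that("reml_loglik matches a literal dense-formula oracle", {
  inst <- random_greml_instance(40, seed = 3)
  for (th in list(c(0.5, 0.5), c(0.2, 1.1), c(1.3, 0.05))) {
    expect_equal(reml_loglik(th[1], th[2], inst$y, inst$X, inst$A),
                 dense_reml_loglik(th[1], th[2], inst$y, inst$X, inst$A),
                 tolerance = 1e-8)
  }
  expect_error(reml_loglik(0.5, 0.5, inst$y, cbind(inst$X, inst$X[, 1]),
                           inst$A), "rank-deficient")
})

test_that("with A = I the components are non-identifiable along sums", {
  withr::with_seed(4, { y <- rnorm(30); X <- matrix(1, 30, 1) })
  A <- diag(30)
  lls <- sapply(seq(0.1, 0.9, length.out = 10), function(sg) {
    reml_loglik(sg, 1 - sg, y, X, A)
  })
  expect_lt(max(lls) - min(lls), 1e-8)
})

test_that("REML likelihood is invariant to phenotype translation", {
  inst <- random_greml_instance(50, seed = 5)
  expect_equal(reml_loglik(0.4, 0.6, inst$y, inst$X, inst$A),
               reml_loglik(0.4, 0.6, inst$y + 7, inst$X, inst$A),
               tolerance = 1e-9)
})

test_that("AI-REML optimum matches a dense grid-search maximizer", {
  # independent oracle: coarse-to-fine grid over (sigma_g2, sigma_e2) using the
  # literal dense formula only
  grid_oracle <- function(y, X, A) {
    vp <- var(y)
    gr <- seq(vp * 1e-3, 1.6 * vp, length.out = 60)
    ll <- outer(gr, gr, Vectorize(function(a, b) dense_reml_loglik(a, b, y, X, A)))
    ix <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    ctr <- c(gr[ix[1]], gr[ix[2]])
    span <- (gr[2] - gr[1]) * 1.5
    g1 <- seq(max(vp * 1e-6, ctr[1] - span), ctr[1] + span, length.out = 60)
    g2 <- seq(max(vp * 1e-6, ctr[2] - span), ctr[2] + span, length.out = 60)
    ll2 <- outer(g1, g2, Vectorize(function(a, b) dense_reml_loglik(a, b, y, X, A)))
    ix2 <- which(ll2 == max(ll2), arr.ind = TRUE)[1, ]
    c(g1[ix2[1]], g2[ix2[2]])
  }
  for (s in 1:5) {
    inst <- random_greml_instance(80, h2 = 0.5, seed = 100 + s)
    fit <- fit_greml(inst$y, inst$X, inst$A)
    opt <- grid_oracle(inst$y, inst$X, inst$A)
    expect_lt(max(abs(c(fit$sigma_g2, fit$sigma_e2) - opt)), 1e-3)
    expect_true(fit$converged)
    # the returned likelihood dominates the whole oracle grid
    expect_gte(fit$loglik + 1e-6,
               dense_reml_loglik(opt[1], opt[2], inst$y, inst$X, inst$A))
  }
})

test_that("estimates are invariant to simultaneous sample permutation", {
  inst <- random_greml_instance(60, seed = 8)
  fit <- fit_greml(inst$y, inst$X, inst$A)
  perm <- sample(60)
  fit_p <- fit_greml(inst$y[perm], inst$X[perm, ], inst$A[perm, perm])
  expect_equal(fit_p$sigma_g2, fit$sigma_g2, tolerance = 1e-5)
  expect_equal(fit_p$h2, fit$h2, tolerance = 1e-5)
})

test_that("heritability SE follows the closed-form delta method", {
  inst <- random_greml_instance(60, seed = 9)
  fit <- fit_greml(inst$y, inst$X, inst$A)
  # sigma_g2 = sigma_e2 = 0.5 with C = diag(0.01): grad = (0.5, -0.5),
  # SE = sqrt(0.25 * 0.01 * 2) = sqrt(0.005)
  fit0 <- fit
  fit0$sigma_g2 <- 0.5; fit0$sigma_e2 <- 0.5
  expect_equal(heritability_se(fit0, diag(c(0.01, 0.01))), sqrt(0.005),
               tolerance = 1e-12)
  # C -> 0 => SE -> 0
  expect_equal(heritability_se(fit0, diag(c(1e-12, 1e-12))), 0, tolerance = 1e-5)
  expect_error(heritability_se(fit0, matrix(c(1, 2, 2, 1), 2)), "positive definite")

  # scale invariance: y -> c y scales components by c^2, h2 and SE unchanged
  fit_c <- fit_greml(3 * inst$y, inst$X, inst$A)
  expect_equal(fit_c$sigma_g2, 9 * fit$sigma_g2, tolerance = 1e-3)
  expect_equal(fit_c$h2, fit$h2, tolerance = 1e-6)
  expect_equal(fit_c$h2_se, fit$h2_se, tolerance = 1e-4)
})

test_that("h2 is identical for any monotone transform after rank normalization", {
  fx <- small_cohort_fixture()
  y <- fx$cohort$ks3_score
  f1 <- fit_greml(int_transform(y), A = fx$ge)
  f2 <- fit_greml(int_transform(exp(y / 2)), A = fx$ge)
  expect_identical(int_transform(y), int_transform(exp(y / 2)))
  expect_equal(f1$h2, f2$h2, tolerance = 1e-12)
})

test_that("unconstrained fits can go negative on null data; constrained flag boundary", {
  fx <- small_cohort_fixture()
  n <- nrow(fx$ge$vectors)
  h2_unc <- h2_con <- numeric(8)
  withr::with_seed(11, {
    for (i in 1:8) {
      y <- rnorm(n) # no genetic signal
      h2_unc[i] <- fit_greml(y, A = fx$ge, constrain = FALSE)$h2
      fc <- fit_greml(y, A = fx$ge, constrain = TRUE)
      h2_con[i] <- fc$h2
      if (fc$constrained[["sigma_g2"]]) expect_lt(fc$sigma_g2, 1e-5)
    }
  })
  expect_lt(min(h2_unc), 0) # mirrors the constrained-to-zero phenomenon
  expect_true(all(h2_con >= 0))
  expect_lt(mean(abs(h2_unc)), 0.15)
})

test_that("boundary LRT behaves as a 50:50 chi-square mixture under the null", {
  fx <- small_cohort_fixture()
  n <- nrow(fx$ge$vectors)
  stats <- numeric(150)
  withr::with_seed(13, {
    for (i in seq_along(stats)) {
      res <- lrt_genetic_variance(rnorm(n), A = fx$ge)
      stats[i] <- res$stat
      expect_gte(res$stat, 0)
    }
  })
  frac_zero <- mean(stats < 1e-6)
  expect_gt(frac_zero, 0.33)
  expect_lt(frac_zero, 0.67)

  # strong signal: p below 0.001 throughout
  cfg <- sim_config(n_individuals = 500, n_snps = 800, n_causal = 200,
                    h2_target = 0.8, school_var_share = 0,
                    covariate_var_share = 0, baseline_error_var = 0)
  for (s in 1:5) {
    cfg_s <- sim_config(n_individuals = 500, n_snps = 800, n_causal = 200,
                        h2_target = 0.8, school_var_share = 0,
                        covariate_var_share = 0, baseline_error_var = 0,
                        seed = 200 + s)
    g <- simulate_genotypes(cfg_s)
    co <- simulate_cohort(g, cfg_s)
    res <- lrt_genetic_variance(int_transform(co$ks3_score), A = compute_grm(g))
    expect_lt(res$p, 0.001)
  }
})

test_that("power approximation is calibrated and monotone", {
  # size equals level at h2 = 0
  expect_equal(greml_power(5000, 2e-4, h2 = 0, alpha = 0.05)$power, 0.05,
               tolerance = 1e-12)
  # strictly increasing in n and h2
  pw_n <- sapply(c(1, 2, 4, 8) * 1000, function(n) {
    greml_power(n, 2e-5, 0.2)$power
  })
  expect_true(all(diff(pw_n) > 0))
  pw_h <- sapply(c(0.05, 0.1, 0.2, 0.4), function(h) {
    greml_power(4000, 2e-5, h)$power
  })
  expect_true(all(diff(pw_h) > 0))
  # the genome-wide-panel regime: well powered for h2 > 0.15 at n ~ 6.5k
  expect_gt(greml_power(6518, 2e-5, 0.15)$power, 0.9)

  # the SE formula itself against a Monte-Carlo spread of estimates
  fx <- small_cohort_fixture()
  n <- nrow(fx$ge$vectors)
  v_off <- var(fx$grm$values[upper.tri(fx$grm$values)])
  h2s <- numeric(20)
  withr::with_seed(17, {
    g_latent <- fx$cohort$g_value
    for (i in seq_along(h2s)) {
      y <- sqrt(0.5) * g_latent + sqrt(0.5) * rnorm(n)
      h2s[i] <- fit_greml(y, A = fx$ge)$h2
    }
  })
  se_formula <- greml_power(n, v_off, 0.5)$se
  expect_gt(sd(h2s) / se_formula, 0.55)
  expect_lt(sd(h2s) / se_formula, 1.6)
})

test_that("tidy and glance expose the fit in broom style", {
  inst <- random_greml_instance(60, seed = 20)
  fit <- fit_greml(inst$y, inst$X, inst$A)
  td <- tidy(fit)
  expect_identical(td$term, c("sigma_g2", "sigma_e2", "h2"))
  expect_equal(td$estimate[3], fit$h2)
  gl <- glance(fit)
  expect_equal(gl$conf.high - gl$conf.low, 2 * 1.96 * fit$h2_se)
  expect_identical(gl$nobs, 60L)
})
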