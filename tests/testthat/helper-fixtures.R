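# Shared fixtures, built once per test run.
.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_individuals = 120L, n_snps = 80L, n_causal = 30L,
                   school_count = 12L, seed = 42L)
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}

small_cohort_fixture <- function() {
  cached("small_cohort", {
    cfg <- sim_config(n_individuals = 600, n_snps = 800, n_causal = 200,
                      school_count = 30, seed = 7)
    g <- simulate_genotypes(cfg)
    eff <- draw_causal_effects(g, cfg)
    cohort <- simulate_cohort(g, cfg, eff)
    grmA <- compute_grm(g)
    ge <- grm_eigen(grmA)
    pcs <- suppressWarnings(compute_pcs(g, k = 10, grm = ge))$scores
    list(cfg = cfg, g = g, eff = eff, cohort = cohort, grm = grmA, ge = ge,
         pcs = pcs)
  })
}

# Literal dense REML log-likelihood: the independent oracle used against the
# eigenbasis implementation (solve/determinant, no shared code path).
dense_reml_loglik <- function(sg, se, y, X, A) {
  V <- sg * A + se * diag(nrow(A))
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  XtViX <- XtVi %*% X
  beta <- solve(XtViX, XtVi %*% y)
  r <- y - X %*% beta
  ypy <- as.numeric(crossprod(r, Vi %*% r))
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus + ypy))
}

# Random small GREML instance with known structure.
random_greml_instance <- function(n, h2 = 0.5, m = 2 * n, seed = 1) {
  withr::with_seed(seed, {
    Z <- matrix(stats::rbinom(n * m, 2, 0.4), n, m)
    Zs <- scale(Z)
    A <- tcrossprod(Zs) / m
    A <- (A + t(A)) / 2
    u <- as.vector(Zs %*% stats::rnorm(m)) / sqrt(m)
    g <- sqrt(h2) * u / stats::sd(u)
    y <- g + sqrt(1 - h2) * stats::rnorm(n)
    X <- cbind(1, stats::rnorm(n))
    list(y = y, X = X, A = A)
  })
}
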