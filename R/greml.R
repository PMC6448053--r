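#' Restricted log-likelihood of the GREML variance-component model
#'
#' For the model `y = X beta + g + e` with `g ~ N(0, sigma_g2 * A)` and
#' `e ~ N(0, sigma_e2 * I)`, evaluates the restricted log-likelihood
#' \deqn{\ell_R = -\tfrac12\left[\log|V| + \log|X'V^{-1}X| + y'Py\right]}
#' (up to an additive constant), with `V = sigma_g2 A + sigma_e2 I` and
#' `P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}`.
#'
#' @param sigma_g2,sigma_e2 variance components (V must be positive definite).
#' @param y phenotype vector.
#' @param X fixed-effect design matrix (full column rank); default intercept.
#' @param A GRM: a [grm()], symmetric matrix, or [grm_eigen()].
#' @return The restricted log-likelihood (finite scalar).
#' @export
reml_loglik <- function(sigma_g2, sigma_e2, y, X = NULL, A) {
  ge <- grm_eigen(A)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  stopifnot(nrow(ge$vectors) == n, nrow(X) == n)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient fixed-effect design X", call. = FALSE)
  }
  w <- sigma_g2 * ge$values + sigma_e2
  if (any(w <= 0)) {
    stop("singular V: sigma_g2 * A + sigma_e2 * I is not positive definite",
         call. = FALSE)
  }
  yt <- crossprod(ge$vectors, y)
  xt <- crossprod(ge$vectors, X)
  wi <- 1 / w
  xtwx <- crossprod(xt, xt * wi)
  ch <- tryCatch(chol(xtwx),
                 error = function(e) stop("singular X'V^{-1}X", call. = FALSE))
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(xt, yt * wi)))
  r <- yt - xt %*% beta
  ypy <- sum(r * wi * r)
  as.numeric(-0.5 * (sum(log(w)) + 2 * sum(log(diag(ch))) + ypy))
}

# One evaluation of the REML pieces in the eigenbasis; returns loglik, Py,
# projection helper, and fixed effects.
reml_pieces <- function(theta, yt, xt, d) {
  w <- theta[1] * d + theta[2]
  wi <- 1 / w
  xtw <- xt * wi
  xtwx <- crossprod(xt, xtw)
  ch <- chol(xtwx)
  cinv <- chol2inv(ch)
  beta <- cinv %*% crossprod(xtw, yt)
  r <- yt - xt %*% beta
  py <- wi * r
  loglik <- as.numeric(-0.5 * (sum(log(w)) + 2 * sum(log(diag(ch))) + sum(r * py)))
  pmat <- function(v) { # P %*% v in the eigenbasis
    wv <- wi * v
    wv - xtw %*% (cinv %*% crossprod(xt, wv))
  }
  list(loglik = loglik, py = py, pmat = pmat, wi = wi, xtw = xtw, cinv = cinv,
       beta = beta)
}

#' Fit the GREML model by average-information REML
#'
#' Estimates `(sigma_g2, sigma_e2)` of `y = X beta + g + e`,
#' `g ~ N(0, sigma_g2 A)`, by restricted maximum likelihood: the GRM is
#' eigendecomposed once, then expectation-maximization warm-up steps are
#' followed by average-information (AI) updates with step-halving whenever a
#' step would decrease the likelihood. In constrained mode (the default) a
#' component crossing zero is clamped to `1e-6 * var(y)` and flagged;
#' unconstrained mode may return a negative `sigma_g2` (and hence a negative
#' heritability estimate, as GCTA reports before constraining). Convergence is
#' declared when the relative change in restricted log-likelihood falls below
#' `tol`.
#'
#' @param y phenotype vector (inverse-normal transform it first for the
#'   analyses emulated here; see [int_transform()]).
#' @param X fixed-effect design (default intercept only). An intercept column
#'   is *not* added automatically.
#' @param A a [grm()], symmetric matrix, or [grm_eigen()].
#' @param constrain keep components non-negative (default `TRUE`).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap; non-convergence is flagged, never silent.
#' @param em_iter number of EM warm-up iterations before AI steps.
#' @param lrt also fit the `sigma_g2 = 0` null and report the boundary
#'   likelihood-ratio test (see [lrt_genetic_variance()]).
#' @return A `greml_fit` object: list with `sigma_g2`, `sigma_e2`, `h2`,
#'   `h2_se`, `beta`, `loglik`, `n_iter`, `converged`, `constrained` (named
#'   logical), `vcov_components` (inverse AI matrix), `n`, and optionally
#'   `lrt_stat`, `lrt_p`.
#' @examples
#' cfg <- sim_config(n_individuals = 300, n_snps = 400, n_causal = 100,
#'                   h2_target = 0.5, school_var_share = 0,
#'                   covariate_var_share = 0, baseline_error_var = 0, seed = 5)
#' g <- simulate_genotypes(cfg)
#' cohort <- simulate_cohort(g, cfg)
#' fit <- fit_greml(int_transform(cohort$ks3_score), A = compute_grm(g))
#' fit$h2
#' @export
fit_greml <- function(y, X = NULL, A, constrain = TRUE, tol = 1e-8,
                      max_iter = 100L, em_iter = 2L, lrt = FALSE) {
  ge <- grm_eigen(A)
  n <- length(y)
  stopifnot(nrow(ge$vectors) == n)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient fixed-effect design X", call. = FALSE)

  yt <- as.vector(crossprod(ge$vectors, y))
  xt <- crossprod(ge$vectors, X)
  d <- ge$values
  vp <- stats::var(y)
  floor_val <- 1e-6 * vp
  theta <- c(vp / 2, vp / 2)
  clamped <- c(FALSE, FALSE)

  pieces <- reml_pieces(theta, yt, xt, d)
  ll <- pieces$loglik
  converged <- FALSE
  iter <- 0L

  grad_and_ai <- function(pieces, theta) {
    py <- pieces$py
    # trace(P D_k): D_1 = diag(d), D_2 = I
    tr1 <- sum(pieces$wi * d) -
      sum(pieces$cinv * crossprod(pieces$xtw, pieces$xtw * d))
    tr2 <- sum(pieces$wi) -
      sum(pieces$cinv * crossprod(pieces$xtw, pieces$xtw))
    q1 <- d * py
    q2 <- py
    ypd <- c(sum(py * q1), sum(py * q2))
    grad <- 0.5 * (ypd - c(tr1, tr2))
    p1 <- pieces$pmat(q1)
    p2 <- pieces$pmat(q2)
    ai <- 0.5 * matrix(c(sum(q1 * p1), sum(q1 * p2),
                         sum(q2 * p1), sum(q2 * p2)), 2, 2)
    ai <- (ai + t(ai)) / 2
    list(grad = grad, ai = ai, ypd = ypd, tr = c(tr1, tr2))
  }

  ga <- grad_and_ai(pieces, theta)
  while (iter < max_iter) {
    iter <- iter + 1L
    if (iter <= em_iter) {
      step <- theta^2 / n * ga$grad * 2 # EM: theta + theta^2/n (y'PDPy - tr(PD))
      prop <- theta + step
    } else {
      delta <- tryCatch(solve(ga$ai, ga$grad), error = function(e) NULL)
      if (is.null(delta)) delta <- ga$grad / max(abs(ga$grad), 1)
      prop <- theta + delta
      if (constrain) {
        hit <- prop < floor_val
        if (any(hit) && !all(hit)) {
          # active set: clamp the offending component and take a conditional
          # Newton step on the free one (the joint step would keep dragging
          # it through the AI cross term)
          free <- which(!hit)
          prop[hit] <- floor_val
          prop[free] <- theta[free] + ga$grad[free] / ga$ai[free, free]
        }
      }
    }
    # keep V positive definite / apply constraint
    fix_prop <- function(p) {
      if (constrain) {
        p <- pmax(p, floor_val)
      } else {
        # keep w = p1 * d + p2 positive
        wmin <- min(p[1] * d + p[2])
        if (wmin <= 0) return(NULL)
      }
      p
    }
    prop_ok <- fix_prop(prop)
    new_pieces <- NULL
    if (!is.null(prop_ok)) {
      new_pieces <- tryCatch(reml_pieces(prop_ok, yt, xt, d), error = function(e) NULL)
    }
    # step-halving towards the current point on likelihood decrease
    halvings <- 0L
    while ((is.null(new_pieces) || new_pieces$loglik < ll - 1e-12) && halvings < 12L) {
      halvings <- halvings + 1L
      prop <- theta + (prop - theta) / 2
      prop_ok <- fix_prop(prop)
      new_pieces <- if (is.null(prop_ok)) NULL else
        tryCatch(reml_pieces(prop_ok, yt, xt, d), error = function(e) NULL)
    }
    if (is.null(new_pieces)) break
    rel <- abs(new_pieces$loglik - ll) / (abs(ll) + 1)
    theta <- prop_ok
    pieces <- new_pieces
    ll <- pieces$loglik
    ga <- grad_and_ai(pieces, theta)
    if (iter > em_iter && rel < tol) { converged <- TRUE; break }
  }
  clamped <- constrain & (theta <= floor_val * (1 + 1e-8))

  vcov <- tryCatch(solve(ga$ai), error = function(e) matrix(NA_real_, 2, 2))
  h2 <- theta[1] / (theta[1] + theta[2])
  h2_se <- tryCatch(
    heritability_se_value(theta[1], theta[2], vcov),
    error = function(e) NA_real_)

  fit <- structure(list(
    sigma_g2 = theta[1], sigma_e2 = theta[2], h2 = h2, h2_se = h2_se,
    beta = as.vector(pieces$beta),
    beta_names = colnames(X) %||% paste0("x", seq_len(ncol(X))),
    loglik = ll, n_iter = iter, converged = converged,
    constrained = stats::setNames(clamped, c("sigma_g2", "sigma_e2")),
    vcov_components = vcov, n = n, constrain_mode = constrain
  ), class = "greml_fit")

  if (lrt) {
    null_ll <- reml_null_loglik(yt, xt)
    stat <- max(0, 2 * (max(ll, null_ll) - null_ll))
    fit$lrt_stat <- stat
    fit$lrt_p <- if (stat <= 0) 1 else 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE)
  }
  fit
}

# REML loglik of the sigma_g2 = 0 null, maximized in closed form over
# sigma_e2 (same additive-constant convention as reml_pieces).
reml_null_loglik <- function(yt, xt) {
  n <- length(yt)
  p <- ncol(xt)
  qrx <- qr(xt)
  rss <- sum(qr.resid(qrx, yt)^2)
  s2 <- rss / (n - p)
  xtx <- crossprod(xt)
  as.numeric(-0.5 * (n * log(s2) + determinant(xtx)$modulus - p * log(s2) + (n - p)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.greml_fit <- function(x, ...) {
  cat("<greml_fit>\n")
  cat(sprintf("  sigma_g2 = %.6g%s, sigma_e2 = %.6g%s\n",
              x$sigma_g2, if (x$constrained[1]) " (constrained)" else "",
              x$sigma_e2, if (x$constrained[2]) " (constrained)" else ""))
  cat(sprintf("  h2 = %.4f (SE %.4f), n = %d\n", x$h2, x$h2_se, x$n))
  cat(sprintf("  logLik = %.4f after %d iterations (%s)\n", x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  if (!is.null(x$lrt_stat)) {
    cat(sprintf("  LRT(sigma_g2 = 0): stat = %.3f, p = %.3g\n", x$lrt_stat, x$lrt_p))
  }
  invisible(x)
}

heritability_se_value <- function(sigma_g2, sigma_e2, vcov) {
  tot <- sigma_g2 + sigma_e2
  grad <- c(sigma_e2, -sigma_g2) / tot^2
  v <- as.numeric(t(grad) %*% vcov %*% grad)
  sqrt(v)
}

#' Delta-method standard error of the heritability ratio
#'
#' For `h2 = sigma_g2 / (sigma_g2 + sigma_e2)` with component covariance `C`,
#' the gradient is `(sigma_e2, -sigma_g2) / (sigma_g2 + sigma_e2)^2` and
#' `SE = sqrt(g' C g)`.
#'
#' @param fit a converged [fit_greml()] result.
#' @param ai_inverse 2x2 positive-definite covariance of
#'   `(sigma_g2, sigma_e2)`; defaults to the fit's inverse AI matrix.
#' @return Standard error of `h2`.
#' @export
heritability_se <- function(fit, ai_inverse = fit$vcov_components) {
  stopifnot(inherits(fit, "greml_fit"))
  ai_inverse <- as.matrix(ai_inverse)
  ev <- eigen(ai_inverse, symmetric = TRUE, only.values = TRUE)$values
  if (any(!is.finite(ev)) || any(ev <= 0)) {
    stop("component covariance matrix is not positive definite", call. = FALSE)
  }
  heritability_se_value(fit$sigma_g2, fit$sigma_e2, ai_inverse)
}

#' Likelihood-ratio test for genetic variance
#'
#' Twice the gap between the restricted log-likelihood of the full model and
#' of the `sigma_g2 = 0` null. Because the null sits on the parameter
#' boundary, the reference distribution is a 50:50 mixture of a point mass at
#' zero and chi-square with 1 df.
#'
#' @inheritParams fit_greml
#' @return A list with `stat`, `p`, and the two fits' log-likelihoods.
#' @export
lrt_genetic_variance <- function(y, X = NULL, A) {
  fit <- fit_greml(y, X, A, constrain = TRUE, lrt = TRUE)
  list(stat = fit$lrt_stat, p = fit$lrt_p, loglik_full = fit$loglik,
       loglik_null = fit$loglik - fit$lrt_stat / 2, fit = fit)
}

#' A-priori power of a GREML heritability analysis
#'
#' Standard approximation: `SE(h2) ~ sqrt(2 / (n^2 var_offdiag))` where
#' `var_offdiag` is the variance of the GRM off-diagonal entries (about `1/m`
#' for `m` independent SNPs; about `2e-5` for genome-wide panels of unrelated
#' individuals). Power is the one-sided normal tail probability that the
#' estimate exceeds the level-`alpha` critical value.
#'
#' @param n sample size.
#' @param var_offdiag variance of GRM off-diagonals.
#' @param h2 true heritability in `(0, 1)` (0 allowed: power equals `alpha`).
#' @param alpha test level.
#' @return A list with `power` and `se`.
#' @examples
#' greml_power(6518, 2e-5, 0.15)$power
#' @export
greml_power <- function(n, var_offdiag = 2e-5, h2, alpha = 0.05) {
  stopifnot(n > 0, var_offdiag > 0, h2 >= 0, h2 < 1, alpha > 0, alpha < 1)
  se <- sqrt(2 / (n^2 * var_offdiag))
  power <- stats::pnorm(h2 / se - stats::qnorm(1 - alpha))
  list(power = power, se = se)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a GREML fit
#'
#' @param x a `greml_fit`.
#' @param ... unused.
#' @return A tibble with one row per variance component plus the heritability
#'   ratio: `term`, `estimate`, `std.error`, `constrained`.
#' @method tidy greml_fit
#' @export
tidy.greml_fit <- function(x, ...) {
  se_comp <- sqrt(pmax(diag(x$vcov_components), 0))
  tibble::tibble(
    term = c("sigma_g2", "sigma_e2", "h2"),
    estimate = c(x$sigma_g2, x$sigma_e2, x$h2),
    std.error = c(se_comp, x$h2_se),
    constrained = c(x$constrained, any(x$constrained))
  )
}

#' Glance at a GREML fit
#'
#' @param x a `greml_fit`.
#' @param ... unused.
#' @return One-row tibble: `h2`, `h2_se`, `conf.low`, `conf.high` (Wald 95%),
#'   `logLik`, `n_iter`, `converged`, `nobs`.
#' @method glance greml_fit
#' @export
glance.greml_fit <- function(x, ...) {
  tibble::tibble(
    h2 = x$h2, h2_se = x$h2_se,
    conf.low = x$h2 - 1.96 * x$h2_se, conf.high = x$h2 + 1.96 * x$h2_se,
    logLik = x$loglik, n_iter = x$n_iter, converged = x$converged, nobs = x$n
  )
}
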