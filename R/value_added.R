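#' Rank-based inverse normal transform
#'
#' Maps ranks (ties to average rank) through the standard normal quantile of
#' `(rank - 3/8) / (n + 1/4)` (Blom offsets). Any strictly monotone transform
#' of the input yields the identical output; `NA`s are passed through and the
#' effective `n` counts finite values only.
#'
#' @param x numeric vector with at least 3 finite, non-constant values.
#' @return Numeric vector of normal scores.
#' @examples
#' int_transform(c(5, 1, 9))
#' @export
int_transform <- function(x) {
  ok <- is.finite(x)
  n <- sum(ok)
  if (n < 3L) stop("int_transform needs at least 3 finite values", call. = FALSE)
  if (max(x[ok]) == min(x[ok])) {
    stop("int_transform is undefined for a constant vector", call. = FALSE)
  }
  out <- rep(NA_real_, length(x))
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

new_va_scores <- function(sample_id, score, measure, from, to, diagnostics = NULL) {
  out <- tibble::tibble(sample_id = sample_id, measure = measure,
                        from = from, to = to, score = score)
  attr(out, "diagnostics") <- diagnostics
  class(out) <- c("va_scores", class(out))
  out
}

#' Raw value-added scores
#'
#' Difference between cohort-standardized later and earlier point scores:
#' `VA = s(score_t2) - s(score_t1)`, where `s()` is the rank-based inverse
#' normal transform by default (the child's cohort rank at each occasion is
#' what enters), or mean/SD z-scoring with `method = "zscore"`. Complete cases
#' only: rows with a missing score at either occasion get `NA`.
#'
#' @param score_t1,score_t2 paired numeric vectors (earlier, later).
#' @param sample_id optional ids (defaults to position).
#' @param method `"int"` (default) or `"zscore"`.
#' @param from,to stage labels for bookkeeping.
#' @return A `va_scores` tibble (`sample_id`, `measure = "raw"`, `from`, `to`,
#'   `score`).
#' @export
raw_va <- function(score_t1, score_t2, sample_id = NULL,
                   method = c("int", "zscore"), from = "ks2", to = "ks3") {
  method <- match.arg(method)
  if (length(score_t1) != length(score_t2)) {
    stop("score vectors must have the same length", call. = FALSE)
  }
  if (is.null(sample_id)) sample_id <- seq_along(score_t1)
  cc <- is.finite(score_t1) & is.finite(score_t2)
  std <- function(v) {
    out <- rep(NA_real_, length(v))
    if (method == "int") {
      out[cc] <- int_transform(v[cc])
    } else {
      out[cc] <- as.vector(scale(v[cc]))
    }
    out
  }
  new_va_scores(sample_id, std(score_t2) - std(score_t1), "raw", from, to)
}

#' Contextual value-added from a two-level model
#'
#' Fits, by restricted maximum likelihood with a school random intercept
#' (`lme4`), the model
#' `s(score_t2) = b0 + b1 s(score_t1) + gamma' covariates + u_school + e`,
#' and returns each child's deviation from the *fixed-effects* prediction
#' (so the score retains the school contribution plus the child residual,
#' which is what a school/teacher effectiveness measure is meant to capture).
#' `mode = "residual"` additionally subtracts the shrunken school effect.
#' Continuous scores are inverse-normal transformed first (as in the emulated
#' pipeline); categorical covariates are expanded to indicators (month of
#' birth as 11 indicators). Complete cases only.
#'
#' @param score_t2,score_t1 later / earlier (baseline) point scores.
#' @param covariates data frame of contextual covariates; character/factor
#'   columns are treated as categorical.
#' @param school_id school identifier per child.
#' @param sample_id optional ids.
#' @param mode `"fixed"` (default) or `"residual"`.
#' @param int inverse-normal transform the scores first (default `TRUE`).
#' @param from,to stage labels.
#' @return A `va_scores` tibble with `measure = "contextual"`; model
#'   diagnostics (fixed effects, school variance, residual variance) in
#'   `attr(, "diagnostics")`.
#' @export
fit_cva <- function(score_t2, score_t1, covariates, school_id, sample_id = NULL,
                    mode = c("fixed", "residual"), int = TRUE,
                    from = "ks2", to = "ks3") {
  mode <- match.arg(mode)
  n <- length(score_t2)
  stopifnot(length(score_t1) == n, length(school_id) == n)
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == n)
  if (anyNA(school_id)) stop("every child needs a school", call. = FALSE)
  if (is.null(sample_id)) sample_id <- seq_len(n)

  cc <- is.finite(score_t2) & is.finite(score_t1) & stats::complete.cases(covariates)
  y2 <- if (int) int_transform(score_t2[cc]) else score_t2[cc]
  y1 <- if (int) int_transform(score_t1[cc]) else score_t1[cc]

  cov_cc <- covariates[cc, , drop = FALSE]
  for (j in names(cov_cc)) {
    if (is.character(cov_cc[[j]])) cov_cc[[j]] <- factor(cov_cc[[j]])
  }
  xmat <- stats::model.matrix(~ ., data = cov_cc)
  fixed <- cbind(`(Intercept)` = 1, baseline = y1, xmat[, -1, drop = FALSE])
  qrf <- qr(fixed)
  if (qrf$rank < ncol(fixed)) {
    bad <- colnames(fixed)[qrf$pivot[(qrf$rank + 1):ncol(fixed)]]
    stop("singular fixed-effect design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  df <- data.frame(.y2 = y2, .school = factor(school_id[cc]))
  pred <- fixed[, -1, drop = FALSE]
  colnames(pred) <- make.names(colnames(pred), unique = TRUE)
  df <- cbind(df, as.data.frame(pred))
  fml <- stats::as.formula(paste(".y2 ~", paste(colnames(pred), collapse = " + "),
                                 "+ (1 | .school)"))
  fit <- lme4::lmer(fml, data = df, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  beta <- lme4::fixef(fit)
  yhat <- as.vector(stats::model.matrix(fit) %*% beta)
  resid_fixed <- y2 - yhat
  if (mode == "residual") {
    blup <- lme4::ranef(fit)$.school[, 1]
    resid_fixed <- resid_fixed - blup[as.integer(df$.school)]
  }
  score <- rep(NA_real_, n)
  score[cc] <- resid_fixed

  vc <- as.data.frame(lme4::VarCorr(fit))
  diagnostics <- list(
    fixed_effects = beta,
    school_var = vc$vcov[vc$grp == ".school"],
    resid_var = vc$vcov[vc$grp == "Residual"],
    n_complete = sum(cc)
  )
  new_va_scores(sample_id, score, "contextual", from, to, diagnostics)
}

#' Teacher-assessed value-added
#'
#' Difference between the mean teacher-assigned level over the three subjects
#' (English, Mathematics, Science) at the two occasions.
#'
#' @param levels_t1,levels_t2 integer matrices/data frames (`n x 3`) of levels
#'   in `1..n_levels`.
#' @param n_levels size of the rating scale (default 8).
#' @param sample_id optional ids.
#' @param from,to stage labels.
#' @return A `va_scores` tibble with `measure = "teacher"`; values lie in
#'   `[-(n_levels - 1), n_levels - 1]`.
#' @export
tava <- function(levels_t1, levels_t2, n_levels = 8L, sample_id = NULL,
                 from = "ks2", to = "ks3") {
  l1 <- as.matrix(levels_t1); l2 <- as.matrix(levels_t2)
  stopifnot(ncol(l1) == 3L, ncol(l2) == 3L, nrow(l1) == nrow(l2))
  check <- function(l) {
    v <- l[!is.na(l)]
    if (any(v != round(v)) || any(v < 1) || any(v > n_levels)) {
      stop(sprintf("teacher levels must be integers in [1, %d]", n_levels),
           call. = FALSE)
    }
  }
  check(l1); check(l2)
  if (is.null(sample_id)) sample_id <- seq_len(nrow(l1))
  new_va_scores(sample_id, rowMeans(l2) - rowMeans(l1), "teacher", from, to)
}
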