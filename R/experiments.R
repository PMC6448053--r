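#' Covariates entering the contextual value-added model
#'
#' Selects the contextual covariates from a cohort tibble and encodes the
#' categorical ones (ethnicity; month of birth as 11 indicators) as factors.
#'
#' @param cohort a [simulate_cohort()] tibble.
#' @return A data frame ready for [fit_cva()].
#' @export
cva_covariates <- function(cohort) {
  data.frame(
    sex = cohort$sex, fsm = cohort$fsm, sen = cohort$sen,
    first_language = cohort$first_language, mobility = cohort$mobility,
    in_care = cohort$in_care,
    ethnicity = factor(cohort$ethnicity),
    birth_month = factor(cohort$birth_month, levels = 1:12),
    area_deprivation = cohort$area_deprivation
  )
}

# GREML h2 of a measure with intercept + PC fixed effects, on the
# inverse-normal transformed values. Returns a one-row tibble.
greml_h2_row <- function(values, ge, pcs, label, from, to, metric = "h2",
                         constrain = TRUE) {
  x <- cbind(`(Intercept)` = 1, pcs)
  fit <- fit_greml(int_transform(values), X = x, A = ge, constrain = constrain)
  tibble::tibble(
    metric = metric, measure = label, from = from, to = to,
    estimate = fit$h2, se = fit$h2_se,
    ci_lo = fit$h2 - 1.96 * fit$h2_se, ci_hi = fit$h2 + 1.96 * fit$h2_se,
    n = fit$n, converged = fit$converged,
    constrained = any(fit$constrained)
  )
}

#' Measurement-error simulation study
#'
#' The package's analogue of the published simulation: for each baseline
#' measurement-error variance in `error_grid` and each replicate, a cohort is
#' generated, raw and contextual value-added measures for the KS2 to KS3 pair
#' are built on the noisy baseline, and the GREML heritability of each measure
#' (with `n_pcs` principal-component covariates) is estimated.
#'
#' With `paired = TRUE` (default) each replicate simulates one cohort and one
#' GRM and shares them across the error grid, scaling a common standard-normal
#' error draw by `sqrt(error variance)`: common random numbers make the
#' *differences* between grid points far more precise at a given replicate
#' budget, which is what the monotonicity-in-error property needs.
#' `paired = FALSE` draws an independent cohort per grid point and replicate
#' with seeds `seed + 1000 * grid_index + replicate`.
#'
#' @param config a [sim_config()]; its `baseline_error_var` is overridden by
#'   the grid.
#' @param error_grid numeric vector of baseline error variances.
#' @param replicates number of replicates per grid point.
#' @param n_pcs number of principal-component covariates (default 20).
#' @param paired share cohorts across the grid (default `TRUE`).
#' @param measures which measures to fit: subset of `c("raw", "contextual")`.
#' @param constrain constrain variance components to be non-negative (default
#'   `TRUE`). Near-zero heritabilities are censored at the boundary by the
#'   constraint, which masks small trends in grid means at modest sample
#'   sizes; pass `FALSE` to study the unbiased unconstrained estimates.
#' @return A tibble of class `vaherit_me_experiment`: one row per
#'   `(error_var, replicate, measure)` with `h2`, `se`, `ci_lo`, `ci_hi`,
#'   `n`, `seed`, `converged`. The config is attached as attribute `"config"`.
#' @export
run_measurement_error_experiment <- function(config,
                                             error_grid = c(0, 0.1, 0.25, 0.5),
                                             replicates = 20L,
                                             n_pcs = 20L,
                                             paired = TRUE,
                                             measures = c("raw", "contextual"),
                                             constrain = TRUE) {
  stopifnot(inherits(config, "sim_config"), replicates >= 1L)
  measures <- match.arg(measures, several.ok = TRUE)
  rows <- list()

  fit_one <- function(cohort, y1_obs, ge, pcs, err, rep_i, seed_i) {
    out <- list()
    if ("raw" %in% measures) {
      va <- raw_va(y1_obs, cohort$ks3_score)
      out$raw <- greml_h2_row(va$score, ge, pcs, "raw", "ks2", "ks3",
                              constrain = constrain)
    }
    if ("contextual" %in% measures) {
      cva <- fit_cva(cohort$ks3_score, y1_obs, cva_covariates(cohort),
                     cohort$school_id)
      out$contextual <- greml_h2_row(cva$score, ge, pcs, "contextual", "ks2",
                                     "ks3", constrain = constrain)
    }
    dplyr::bind_rows(out) |>
      dplyr::mutate(error_var = err, replicate = rep_i, seed = seed_i,
                    .before = 1)
  }

  if (paired) {
    for (r in seq_len(replicates)) {
      seed_r <- config$seed + r
      cfg_r <- modify_config(config, seed = seed_r, baseline_error_var = 0)
      g <- simulate_genotypes(cfg_r)
      cohort <- simulate_cohort(g, cfg_r)
      ge <- grm_eigen(compute_grm(g))
      pcs <- compute_pcs(g, k = n_pcs, grm = ge)$scores
      err_unit <- withr::with_seed(seed_r + 500000L,
                                   stats::rnorm(config$n_individuals))
      for (gi in seq_along(error_grid)) {
        v <- error_grid[gi]
        y1_obs <- cohort$ks2_score_true + sqrt(v) * err_unit
        rows[[length(rows) + 1L]] <- fit_one(cohort, y1_obs, ge, pcs, v, r, seed_r)
      }
      rm(g, ge, pcs); gc(FALSE)
    }
  } else {
    for (gi in seq_along(error_grid)) {
      for (r in seq_len(replicates)) {
        seed_gr <- config$seed + 1000L * gi + r
        cfg_gr <- modify_config(config, seed = seed_gr,
                                baseline_error_var = error_grid[gi])
        g <- simulate_genotypes(cfg_gr)
        cohort <- simulate_cohort(g, cfg_gr)
        ge <- grm_eigen(compute_grm(g))
        pcs <- compute_pcs(g, k = n_pcs, grm = ge)$scores
        rows[[length(rows) + 1L]] <- fit_one(cohort, cohort$ks2_score, ge, pcs,
                                             error_grid[gi], r, seed_gr)
        rm(g, ge, pcs); gc(FALSE)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  class(out) <- c("vaherit_me_experiment", class(out))
  out
}

# A sim_config copy with some fields replaced (re-validated).
modify_config <- function(config, ...) {
  lst <- unclass(config)
  repl <- list(...)
  lst[names(repl)] <- repl
  lst$h2_target <- unlist(lst$h2_target)
  do.call(sim_config, lst)
}

#' Summarize a measurement-error experiment
#'
#' Means and Monte-Carlo standard errors of the heritability estimates per
#' (error variance, measure), excluding (and counting) non-converged fits.
#'
#' @param object a [run_measurement_error_experiment()] result.
#' @param ... unused.
#' @return A tibble with `error_var`, `measure`, `mean_h2`, `mc_se`,
#'   `mean_se`, `n_reps`, `n_nonconverged`.
#' @export
summary.vaherit_me_experiment <- function(object, ...) {
  object |>
    dplyr::group_by(.data$error_var, .data$measure) |>
    dplyr::summarise(
      mean_h2 = mean(.data$estimate[.data$converged]),
      mc_se = stats::sd(.data$estimate[.data$converged]) /
        sqrt(sum(.data$converged)),
      mean_se = mean(.data$se[.data$converged]),
      n_reps = dplyr::n(),
      n_nonconverged = sum(!.data$converged),
      .groups = "drop"
    )
}

#' Full heritability and polygenic-score analysis of one synthetic cohort
#'
#' Reproduces the shape of the emulated study on a single generated cohort:
#' GREML heritability (with `n_pcs` PC covariates) of the three key-stage
#' attainment scores, three raw VA measures, three contextual VA measures and
#' the KS2-KS3 teacher-assessed VA; plus, for each of the ten measures, the
#' incremental variance explained by a synthetic 74-variant polygenic score
#' (percentage points, PC-adjusted).
#'
#' @param config a [sim_config()].
#' @param n_pcs number of principal components.
#' @param include_pgs also compute polygenic-score increments (default `TRUE`).
#' @return A tibble of class `vaherit_full_analysis`: rows `metric = "h2"`
#'   (estimate on the 0-1 scale with SE and Wald CI) and `metric = "pgs_r2"`
#'   (percentage points), one per measure; the generated cohort and scores are
#'   attached as attributes `"cohort"` and `"scores"`.
#' @export
run_full_analysis <- function(config, n_pcs = 20L, include_pgs = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  g <- simulate_genotypes(config)
  effects <- draw_causal_effects(g, config)
  cohort <- simulate_cohort(g, config, effects)
  ge <- grm_eigen(compute_grm(g))
  pcs <- compute_pcs(g, k = n_pcs, grm = ge)$scores

  stages <- c("ks2", "ks3", "ks4")
  pairs <- list(c("ks2", "ks3"), c("ks2", "ks4"), c("ks3", "ks4"))
  covs <- cva_covariates(cohort)

  scores <- list()
  for (s in stages) {
    scores[[paste0("attainment_", s)]] <- cohort[[paste0(s, "_score")]]
  }
  for (p in pairs) {
    lab <- paste(p, collapse = "_")
    scores[[paste0("raw_", lab)]] <-
      raw_va(cohort[[paste0(p[1], "_score")]], cohort[[paste0(p[2], "_score")]],
             from = p[1], to = p[2])$score
    scores[[paste0("contextual_", lab)]] <-
      fit_cva(cohort[[paste0(p[2], "_score")]], cohort[[paste0(p[1], "_score")]],
              covs, cohort$school_id, from = p[1], to = p[2])$score
  }
  scores[["teacher_ks2_ks3"]] <- tava(
    cohort[, paste0("tlevel_ks2_", c("en", "ma", "sc"))],
    cohort[, paste0("tlevel_ks3_", c("en", "ma", "sc"))],
    n_levels = config$n_levels)$score

  meta <- tibble::tibble(
    name = names(scores),
    measure = sub("_ks.*$", "", names(scores)),
    from = sub("^.*?_(ks[0-9]).*$", "\\1", names(scores)),
    to = sub("^.*(ks[0-9])$", "\\1", names(scores))
  )

  rows <- purrr::pmap(meta, function(name, measure, from, to) {
    greml_h2_row(scores[[name]], ge, pcs, measure, from, to)
  })
  out <- dplyr::bind_rows(rows)

  if (include_pgs && nrow(effects) > 0L) {
    weights <- synthetic_gwas_weights(g, effects, seed = config$seed + 9L)
    pgs <- compute_pgs(g, weights)$pgs
    pgs_rows <- purrr::pmap(meta, function(name, measure, from, to) {
      tibble::tibble(
        metric = "pgs_r2", measure = measure, from = from, to = to,
        estimate = incremental_r2(scores[[name]], pgs, covariates = pcs),
        se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
        n = sum(is.finite(scores[[name]])), converged = NA, constrained = NA
      )
    })
    out <- dplyr::bind_rows(out, dplyr::bind_rows(pgs_rows))
  }
  out$seed <- config$seed
  attr(out, "config") <- config
  attr(out, "cohort") <- cohort
  attr(out, "scores") <- scores
  class(out) <- c("vaherit_full_analysis", class(out))
  out
}

#' Pairwise correlations between measures
#'
#' Product-moment correlations on pairwise-complete cases, with the paired
#' sample size.
#'
#' @param ... named numeric vectors, or a single named list of them (e.g. the
#'   `"scores"` attribute of [run_full_analysis()]); `va_scores` tibbles are
#'   accepted and their `score` column used.
#' @return A tibble `measure1`, `measure2`, `r`, `n` for every unordered pair.
#' @export
measure_correlations <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && !is.data.frame(args[[1]])) {
    args <- args[[1]]
  }
  args <- lapply(args, function(a) {
    if (inherits(a, "va_scores")) a$score else as.numeric(a)
  })
  if (length(args) < 2L) stop("need at least two measures", call. = FALSE)
  if (is.null(names(args)) || any(names(args) == "")) {
    names(args) <- paste0("m", seq_along(args))
  }
  nm <- names(args)
  combs <- utils::combn(length(args), 2L)
  rows <- vector("list", ncol(combs))
  for (k in seq_len(ncol(combs))) {
    i <- combs[1, k]; j <- combs[2, k]
    cc <- is.finite(args[[i]]) & is.finite(args[[j]])
    if (!any(cc)) stop(sprintf("no overlapping complete cases for %s and %s",
                               nm[i], nm[j]), call. = FALSE)
    rows[[k]] <- tibble::tibble(measure1 = nm[i], measure2 = nm[j],
                                r = stats::cor(args[[i]][cc], args[[j]][cc]),
                                n = sum(cc))
  }
  dplyr::bind_rows(rows)
}
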