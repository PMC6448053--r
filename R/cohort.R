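#' Simulate a school cohort with key-stage attainment and teacher ratings
#'
#' Builds per-child observed point scores at the three key stages (ages 11, 14
#' and 16), contextual covariates partially confounded with the polygenic
#' component, school clustering, teacher-assigned subject levels, and the
#' latent components needed for oracle testing.
#'
#' Generating model, per child and key stage `s`:
#' \deqn{y_s = \sqrt{h^2_s}\,G + \sqrt{v_L - h^2_s}\,E_s
#'       + \sqrt{v_u}\,U_{school} + \sqrt{v_c}\,C^{\perp}}
#' where `G` is the standardized genetic value from [draw_causal_effects()],
#' `E_s` is a unit-variance environmental component following a Markov chain
#' across stages with stage-pair loadings solved so that the latent-ability
#' correlation between adjacent stages equals `persistence`, `U` is a school
#' random effect, and `C⊥` is the contextual-covariate effect orthogonalized
#' against `G` (so configured variance shares are exact and `h2_target = 0`
#' yields a genuinely non-heritable score). The observed covariates themselves
#' *are* correlated with `G` via `covariate_confounding` (e.g. free-school-meal
#' probability decreases in `G`), which is what lets a contextual value-added
#' adjustment re-introduce genetic variance. The observed KS2 score receives
#' additional independent Gaussian noise of variance `baseline_error_var`
#' (the error-free value is kept in `ks2_score_true`).
#'
#' Teacher levels at KS2 and KS3 come from [coarsen_teacher_levels()]: the
#' rated quantity is the child's realized (error-free) score, plus a shared
#' rater-bias term of variance `teacher_bias_var` that is *heritable but
#' occasion-specific* - each occasion's raters key on a different heritable
#' "appeal" trait (an independent combination of the causal SNPs), emulating
#' bias from heritable characteristics other than attainment, assessed by
#' different teachers at ages 11 and 14. A bias proportional to the attainment
#' genetic value itself would cancel in the between-stage difference; an
#' occasion-specific heritable bias is what makes teacher-assessed progress
#' measures genetically loaded.
#'
#' @param genotypes a [genotype_matrix()] with `n_individuals` rows.
#' @param config the [sim_config()] used to generate `genotypes`.
#' @param effects optional effect table from [draw_causal_effects()]; computed
#'   from `genotypes` and `config` when omitted.
#' @return A tibble (one row per child) with ids, `school_id`, covariates,
#'   observed scores `ks2_score`/`ks3_score`/`ks4_score`, teacher levels
#'   `tlevel_ks2_en` ... `tlevel_ks3_sc`, and latent columns (`g_value`,
#'   `ability_ks2/3/4`, `school_effect`, `covariate_effect`,
#'   `ks2_score_true`).
#' @examples
#' cfg <- sim_config(n_individuals = 300, n_snps = 200, n_causal = 50, seed = 3)
#' cohort <- simulate_cohort(simulate_genotypes(cfg), cfg)
#' cor(cohort$ability_ks2, cohort$ability_ks3)
#' @export
simulate_cohort <- function(genotypes, config, effects = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(config, "sim_config"))
  n <- nrow(genotypes$dosages)
  if (n != config$n_individuals) {
    stop("genotypes and config disagree on the number of individuals", call. = FALSE)
  }
  if (is.null(effects)) effects <- draw_causal_effects(genotypes, config)
  g <- attr(effects, "g_value")
  if (is.null(g)) {
    g <- genetic_values(genotypes, effects)
  }

  v_u <- config$school_var_share
  v_c <- config$covariate_var_share
  v_l <- 1 - v_u - v_c
  h2 <- pmin(config$h2_target, v_l)
  kap <- persistence_loadings(config)

  withr::with_seed(config$seed + 2L, {
    # environmental Markov chain across stages
    e1 <- stats::rnorm(n)
    e2 <- kap[1] * e1 + sqrt(max(0, 1 - kap[1]^2)) * stats::rnorm(n)
    e3 <- kap[2] * e2 + sqrt(max(0, 1 - kap[2]^2)) * stats::rnorm(n)
    env <- cbind(e1, e2, e3)

    # contextual covariates, confounded with g via logistic/linear loadings
    conf <- config$covariate_confounding
    sex <- stats::rbinom(n, 1, 0.5)
    fsm <- stats::rbinom(n, 1, stats::plogis(stats::qlogis(0.15) - 1.2 * conf * g))
    sen <- stats::rbinom(n, 1, stats::plogis(stats::qlogis(0.12) - 1.2 * conf * g))
    first_language <- stats::rbinom(n, 1, stats::plogis(stats::qlogis(0.06) - 0.4 * conf * g))
    mobility <- stats::rbinom(n, 1, stats::plogis(stats::qlogis(0.08) - 0.6 * conf * g))
    in_care <- stats::rbinom(n, 1, stats::plogis(stats::qlogis(0.01) - 0.8 * conf * g))
    ethnicity <- sample(c("white", "asian", "black", "mixed", "other"), n,
                        replace = TRUE, prob = c(0.85, 0.06, 0.04, 0.03, 0.02))
    birth_month <- sample.int(12L, n, replace = TRUE)
    area_deprivation <- -0.7 * conf * g +
      sqrt(max(0, 1 - (0.7 * conf)^2)) * stats::rnorm(n)

    eth_eff <- c(white = 0, asian = 0.05, black = -0.05, mixed = 0, other = -0.02)
    c_raw <- 0.1 * sex - 0.35 * fsm - 0.5 * sen - 0.2 * first_language -
      0.15 * mobility - 0.4 * in_care + eth_eff[ethnicity] +
      0.15 * (6.5 - birth_month) / 3.45 - 0.35 * area_deprivation
    c_std <- as.vector(scale(c_raw))
    # effect on attainment enters through the G-orthogonal part of the composite
    if (stats::sd(g) > 0) {
      c_perp <- c_std - (stats::cov(c_std, g) / stats::var(g)) * g
    } else {
      c_perp <- c_std
    }
    c_perp <- as.vector(scale(c_perp))

    school_id <- sprintf("S%04d", sample.int(config$school_count, n, replace = TRUE))
    u <- stats::rnorm(config$school_count)
    school_effect <- u[as.integer(substring(school_id, 2L))]

    ability <- sapply(1:3, function(s) {
      sqrt(h2[s]) * g + sqrt(max(0, v_l - h2[s])) * env[, s]
    })
    score_true <- ability + sqrt(v_u) * school_effect + sqrt(v_c) * c_perp
    baseline_error <- sqrt(config$baseline_error_var) * stats::rnorm(n)

    # occasion-specific heritable rater-appeal traits for the teacher model
    g_bias <- matrix(0, n, 2)
    if (nrow(effects) > 0L) {
      idx <- match(effects$id, genotypes$snp_meta$id)
      zc <- standardize_dosages(genotypes$dosages[, idx, drop = FALSE])
      for (s in 1:2) {
        bb <- stats::rnorm(nrow(effects))
        gb <- as.vector(zc %*% bb)
        sdg <- stats::sd(gb)
        if (sdg > 0) g_bias[, s] <- gb / sdg
      }
    }

    cohort <- tibble::tibble(
      fid = genotypes$sample_ids$fid,
      iid = genotypes$sample_ids$iid,
      school_id = school_id,
      sex = sex, fsm = fsm, sen = sen,
      first_language = first_language, mobility = mobility, in_care = in_care,
      ethnicity = ethnicity, birth_month = birth_month,
      area_deprivation = area_deprivation,
      ks2_score = score_true[, 1] + baseline_error,
      ks3_score = score_true[, 2],
      ks4_score = score_true[, 3],
      g_value = g,
      ability_ks2 = ability[, 1],
      ability_ks3 = ability[, 2],
      ability_ks4 = ability[, 3],
      school_effect = school_effect,
      covariate_effect = sqrt(v_c) * c_perp,
      ks2_score_true = score_true[, 1],
      ks3_score_true = score_true[, 2],
      g_bias_ks2 = g_bias[, 1],
      g_bias_ks3 = g_bias[, 2]
    )
  })

  for (s in c("ks2", "ks3")) {
    bias <- sqrt(config$teacher_bias_var) * cohort[[paste0("g_bias_", s)]]
    lv <- coarsen_teacher_levels(cohort[[paste0(s, "_score_true")]], config,
                                 bias = bias, stage = s)
    colnames(lv) <- paste0("tlevel_", s, "_", c("en", "ma", "sc"))
    cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(lv))
  }
  cohort
}

#' Genetic values from an effect table
#'
#' @param genotypes a [genotype_matrix()].
#' @param effects tibble with `id` and `beta` (standardized-dosage scale).
#' @return Numeric vector of per-individual genetic values.
#' @export
genetic_values <- function(genotypes, effects) {
  if (nrow(effects) == 0L) return(rep(0, nrow(genotypes$dosages)))
  idx <- match(effects$id, genotypes$snp_meta$id)
  if (anyNA(idx)) stop("effect table contains SNPs absent from the genotypes", call. = FALSE)
  z <- standardize_dosages(genotypes$dosages[, idx, drop = FALSE])
  as.vector(z %*% effects$beta)
}

#' Coarsen continuous ability into teacher-assigned subject levels
#'
#' Emulates teachers grading each child in English, Mathematics and Science on
#' an integer scale of 1 to `n_levels`: three subject-specific noisy copies of
#' ability (noise variance `teacher_noise_var`), plus a shared rater-bias term
#' passed by the caller (heritable when built from the genetic value), each
#' binned into `n_levels` equal-probability bands by sample quantiles. With
#' zero noise and zero bias the binning is a deterministic monotone function of
#' ability.
#'
#' @param ability numeric vector of latent ability.
#' @param config a [sim_config()] (uses `n_levels`, `teacher_noise_var`, `seed`).
#' @param bias shared rater-bias vector (default 0); [simulate_cohort()] passes
#'   `sqrt(teacher_bias_var) * g`.
#' @param stage label ("ks2"/"ks3") used only to decorrelate the noise streams
#'   between stages.
#' @return Integer matrix `length(ability) x 3` with values in `1..n_levels`.
#' @export
coarsen_teacher_levels <- function(ability, config, bias = 0, stage = "ks2") {
  stopifnot(inherits(config, "sim_config"))
  n <- length(ability)
  l <- config$n_levels
  offset <- 3L + match(stage, c("ks2", "ks3", "ks4"), nomatch = 1L)
  withr::with_seed(config$seed + offset, {
    noise_sd <- sqrt(config$teacher_noise_var)
    out <- sapply(1:3, function(j) {
      rating <- ability + bias + noise_sd * stats::rnorm(n)
      brk <- stats::quantile(rating, probs = seq_len(l - 1L) / l, names = FALSE)
      as.integer(findInterval(rating, unique(brk)) + 1L)
    })
    storage.mode(out) <- "integer"
    out
  })
}

#' Write / read a cohort table as tab-separated text
#'
#' Plain TSV with a header row; the column set is documented in
#' [simulate_cohort()].
#'
#' @param cohort a cohort tibble.
#' @param path file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` a tibble.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}
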