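#' Simulation configuration for a synthetic school cohort
#'
#' Collects every parameter of the synthetic-cohort generator: genotype
#' dimensions and allele-frequency model, the per-key-stage heritability of
#' attainment, the persistence of ability across stages, school clustering,
#' gene-covariate confounding, baseline measurement error, and the teacher
#' rating model. All downstream generators (`simulate_genotypes()`,
#' `simulate_cohort()`) are deterministic functions of a config.
#'
#' Variance model: each observed key-stage score has unit variance built from
#' shares `h2_target[s]` (additive genetic), `school_var_share` (school random
#' effect), `covariate_var_share` (contextual covariates, entering through
#' their genetically orthogonal component so shares are exact), and the
#' remainder as persistent-plus-specific environment. `baseline_error_var` is
#' additive noise (in phenotype-variance units, so 0.25 means 25% of the unit
#' score variance) applied to the observed KS2 score only: it is the baseline
#' of the age 11-14 progress measures that the measurement-error study varies.
#'
#' Default values are calibrated so that, at baseline error 0.25, the implied
#' population-level heritability of raw VA is close to 10% and of contextual
#' VA close to 17%, with realized attainment heritability rising across key
#' stages; see the methods vignette for the calibration.
#'
#' @param n_individuals number of children (default 5000).
#' @param n_snps number of independent biallelic SNPs (default 5000).
#' @param n_causal number of causal SNPs behind the polygenic ability
#'   component (default 1000; 0 gives a phenotype with no genetic component).
#' @param maf_range length-2 numeric in (0, 0.5], range of ancestral minor
#'   allele frequencies, drawn uniformly.
#' @param n_subpops number of subpopulations (1 = panmictic).
#' @param fst Wright's differentiation coefficient in `[0, 1)` for the
#'   Balding-Nichols subpopulation frequency model; must be > 0 when
#'   `n_subpops > 1`.
#' @param h2_target named numeric (`ks2`, `ks3`, `ks4`) or scalar: share of
#'   unit score variance that is additive genetic at each key stage.
#' @param persistence correlation of latent ability between adjacent key
#'   stages (genetic plus persistent environment), in `[0, 1]`.
#' @param school_count number of schools; children are assigned uniformly.
#' @param school_var_share share of score variance from the school effect.
#' @param covariate_var_share share of score variance from contextual
#'   covariates (sex, FSM, SEN, ethnicity, month of birth, first language,
#'   mobility, in-care, area deprivation).
#' @param covariate_confounding loading of the covariates on the standardized
#'   genetic value, in `[-1, 1]`: e.g. free-school-meal probability decreases
#'   in the genetic value. 0 means covariates are independent of genotype.
#' @param baseline_error_var variance of additive Gaussian measurement error
#'   added to the observed KS2 (baseline) score.
#' @param teacher_bias_var variance of the heritable, occasion-specific
#'   rater-bias component shared across the three subject ratings (see
#'   [simulate_cohort()]).
#' @param teacher_noise_var variance of the subject-specific rater noise.
#' @param n_levels size of the teacher rating scale (National Curriculum
#'   levels; 8 in the emulated data).
#' @param missing_rate missing-at-random dosage rate (default 0; only used to
#'   exercise the QC filters).
#' @param seed integer seed governing all randomness downstream.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_individuals = 200, n_snps = 100, n_causal = 20, seed = 1)
#' cfg$h2_target
#' @export
sim_config <- function(n_individuals = 5000,
                       n_snps = 5000,
                       n_causal = 1000,
                       maf_range = c(0.05, 0.5),
                       n_subpops = 1,
                       fst = 0,
                       h2_target = c(ks2 = 0.35, ks3 = 0.55, ks4 = 0.60),
                       persistence = 0.82,
                       school_count = 200,
                       school_var_share = 0.10,
                       covariate_var_share = 0.10,
                       covariate_confounding = 0.7,
                       baseline_error_var = 0.25,
                       teacher_bias_var = 0.10,
                       teacher_noise_var = 0.25,
                       n_levels = 8,
                       missing_rate = 0,
                       seed = 1L) {
  if (length(h2_target) == 1L) {
    h2_target <- stats::setNames(rep(h2_target, 3L), c("ks2", "ks3", "ks4"))
  }
  stages <- c("ks2", "ks3", "ks4")
  if (is.null(names(h2_target)) || !all(stages %in% names(h2_target))) {
    stop("`h2_target` must be a scalar or named with ks2, ks3, ks4", call. = FALSE)
  }
  h2_target <- h2_target[stages]

  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_snps = as.integer(n_snps),
    n_causal = as.integer(n_causal),
    maf_range = as.numeric(maf_range),
    n_subpops = as.integer(n_subpops),
    fst = as.numeric(fst),
    h2_target = h2_target,
    persistence = as.numeric(persistence),
    school_count = as.integer(school_count),
    school_var_share = as.numeric(school_var_share),
    covariate_var_share = as.numeric(covariate_var_share),
    covariate_confounding = as.numeric(covariate_confounding),
    baseline_error_var = as.numeric(baseline_error_var),
    teacher_bias_var = as.numeric(teacher_bias_var),
    teacher_noise_var = as.numeric(teacher_noise_var),
    n_levels = as.integer(n_levels),
    missing_rate = as.numeric(missing_rate),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_individuals < 1L || n_snps < 1L) {
      stop("invalid config: non-positive genotype dimensions", call. = FALSE)
    }
    if (n_causal < 0L || n_causal > n_snps) {
      stop("invalid config: n_causal must be in [0, n_snps]", call. = FALSE)
    }
    if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
          maf_range[1] > maf_range[2]) {
      stop("invalid config: maf_range must be within (0, 0.5]", call. = FALSE)
    }
    if (n_subpops < 1L) stop("invalid config: n_subpops must be >= 1", call. = FALSE)
    if (n_subpops > 1L && fst <= 0) {
      stop("invalid config: fst must be > 0 when n_subpops > 1", call. = FALSE)
    }
    if (fst < 0 || fst >= 1) stop("invalid config: fst must be in [0, 1)", call. = FALSE)
    if (any(h2_target < 0) || any(h2_target > 1)) {
      stop("invalid config: h2_target values must be in [0, 1]", call. = FALSE)
    }
    if (persistence < 0 || persistence > 1) {
      stop("invalid config: persistence must be in [0, 1]", call. = FALSE)
    }
    if (school_count < 1L) stop("invalid config: school_count must be >= 1", call. = FALSE)
    if (school_var_share < 0 || school_var_share >= 1 ||
          covariate_var_share < 0 || covariate_var_share >= 1) {
      stop("invalid config: variance shares must be in [0, 1)", call. = FALSE)
    }
    v_latent <- 1 - school_var_share - covariate_var_share
    if (any(h2_target > v_latent + 1e-12)) {
      stop("invalid config: variance shares sum above 1 ",
           "(h2_target + school_var_share + covariate_var_share > 1)", call. = FALSE)
    }
    if (baseline_error_var < 0 || teacher_bias_var < 0 || teacher_noise_var < 0) {
      stop("invalid config: variances must be >= 0", call. = FALSE)
    }
    if (n_levels < 2L) stop("invalid config: n_levels must be >= 2", call. = FALSE)
    if (missing_rate < 0 || missing_rate >= 1) {
      stop("invalid config: missing_rate must be in [0, 1)", call. = FALSE)
    }
  })
  # persistence must be attainable given the shared genetic component
  kap <- persistence_loadings(cfg)
  if (any(!is.finite(kap)) || any(kap < -1e-12) || any(kap > 1 + 1e-12)) {
    stop("invalid config: persistence is not attainable for the given h2_target ",
         "profile (adjacent-stage genetic covariance exceeds or falls short of ",
         "the persistence budget)", call. = FALSE)
  }
  invisible(cfg)
}

# Markov loadings of the environmental component: kap[s] is the correlation
# between the environmental parts of stages s and s+1 needed so that
# corr(latent ability s, s+1) == persistence.
persistence_loadings <- function(cfg) {
  v_l <- 1 - cfg$school_var_share - cfg$covariate_var_share
  h2 <- cfg$h2_target
  ve <- v_l - h2
  kap <- numeric(2L)
  for (s in 1:2) {
    num <- cfg$persistence * v_l - sqrt(h2[s] * h2[s + 1])
    den <- sqrt(ve[s] * ve[s + 1])
    kap[s] <- if (den <= .Machine$double.eps) {
      if (abs(num) < 1e-10) 0 else NaN
    } else {
      num / den
    }
  }
  kap
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  individuals: %d, SNPs: %d (causal: %d), subpops: %d (Fst %.3g)\n",
              x$n_individuals, x$n_snps, x$n_causal, x$n_subpops, x$fst))
  cat(sprintf("  h2 target: ks2 %.2f / ks3 %.2f / ks4 %.2f, persistence %.2f\n",
              x$h2_target[["ks2"]], x$h2_target[["ks3"]], x$h2_target[["ks4"]],
              x$persistence))
  cat(sprintf("  shares: school %.2f, covariates %.2f (confounding %.2f)\n",
              x$school_var_share, x$covariate_var_share, x$covariate_confounding))
  cat(sprintf("  baseline error var: %.3g, teacher bias/noise var: %.3g/%.3g (%d levels)\n",
              x$baseline_error_var, x$teacher_bias_var, x$teacher_noise_var, x$n_levels))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Write / read a simulation config as YAML
#'
#' @param config a [sim_config()] object.
#' @param path file path.
#' @return `write_sim_config()` returns `path` invisibly; `read_sim_config()`
#'   returns a validated `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  lst <- unclass(config)
  lst$h2_target <- as.list(lst$h2_target)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$h2_target <- unlist(lst$h2_target)
  do.call(sim_config, lst)
}
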