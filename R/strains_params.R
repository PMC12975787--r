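# Strain definitions, cytoplasmic-incompatibility structure, fitness
# parameters and configuration validation.

KNOWN_STRAINS <- c("wAlbAB", "ARwP", "cleared")
INFECTED_STRAINS <- c("wAlbAB", "ARwP")

#' Derive the female death rate from the feasibility constraint
#'
#' The model is biologically feasible when `mu_F / (0.5 * lambda * p_mated) <
#' 1`, i.e. when a female produces more than one daughter over her lifetime.
#' The female death rate is set to the largest feasible value satisfying
#' `mu_F / (0.5 * lambda * p_mated) = ratio` for a ratio strictly below 1.
#'
#' @param lambda_birth base per-mated-female birth rate of future adults
#'   (day^-1).
#' @param p_mated steady-state proportion of wild-type females that are mated.
#' @param ratio target feasibility ratio, strictly in (0, 1); 0.999 by default.
#' @return the female death rate `mu_F` (day^-1).
#' @export
derive_female_death_rate <- function(lambda_birth, p_mated, ratio = 0.999) {
  if (!is.numeric(lambda_birth) || length(lambda_birth) != 1L || lambda_birth <= 0)
    stop("invalid parameter: lambda_birth must be a positive scalar")
  if (!is.numeric(p_mated) || length(p_mated) != 1L || p_mated <= 0 || p_mated > 1)
    stop("invalid parameter: p_mated must be in (0, 1]")
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio >= 1)
    stop("invalid parameter: ratio must be in (0, 1)")
  ratio * 0.5 * lambda_birth * p_mated
}

#' Report the biological feasibility of a fitness parameter set
#'
#' @param fitness a fitness list with at least `lambda_birth`, `mu_F` and
#'   either `p_mated` or `mating_rate` (from which `p_mated = eta/(eta+mu_F)`
#'   is computed).
#' @return list with elements `ratio` (the value of
#'   `mu_F / (0.5 lambda p_mated)`) and `ok` (`TRUE` iff ratio < 1).
#' @export
check_feasibility <- function(fitness) {
  p <- fitness$p_mated
  if (is.null(p)) {
    eta <- fitness$mating_rate
    p <- eta / (eta + fitness$mu_F)
  }
  ratio <- fitness$mu_F / (0.5 * fitness$lambda_birth * p)
  list(ratio = ratio, ok = ratio < 1)
}

#' Build the cytoplasmic-incompatibility efficacy profile
#'
#' Efficacy is the fraction of a cross's offspring rendered non-viable, as a
#' function of (female strain, male strain, male CI-age class k = 1..K).
#' Rules: same-strain crosses and any cross with an uninfected (`cleared`)
#' male are fully compatible (efficacy 0).  Crosses with an infected male of
#' a different strain than the female are incompatible; for `wAlbAB` males
#' the efficacy decays with CI-age class (100% in classes 1..`decay_breaks[1]`,
#' an intermediate level up to `decay_breaks[2]`, then 0), reflecting the loss
#' of Wolbachia titre in ageing wild-type males.  `ARwP` male incompatibility
#' does not decay.
#'
#' @param strain_names character vector of strain labels (subset of
#'   `wAlbAB`, `ARwP`, `cleared`).
#' @param K number of male CI-age classes.
#' @param decay_enabled when `FALSE` every cross has a constant efficacy in k
#'   (the class-1 value).
#' @param decay_breaks last CI class of the full-efficacy and of the
#'   intermediate-efficacy band for `wAlbAB` males.
#' @param decay_levels efficacies in the three bands (default 1, 0.67, 0).
#' @return list of class `iit_ci` with the efficacy array and its settings.
#' @export
default_ci_profile <- function(strain_names, K = 20, decay_enabled = TRUE,
                               decay_breaks = c(14, 19),
                               decay_levels = c(1, 0.67, 0)) {
  stopifnot(K >= 1, length(decay_breaks) == 2, length(decay_levels) == 3,
            decay_breaks[1] <= decay_breaks[2], decay_breaks[2] <= K,
            all(decay_levels >= 0), all(decay_levels <= 1))
  ns <- length(strain_names)
  eff <- array(0, dim = c(ns, ns, K),
               dimnames = list(strain_names, strain_names, NULL))
  walbab_profile <- function(k) {
    if (!decay_enabled) return(decay_levels[1])
    ifelse(k <= decay_breaks[1], decay_levels[1],
           ifelse(k <= decay_breaks[2], decay_levels[2], decay_levels[3]))
  }
  for (f in strain_names) for (m in strain_names) {
    if (m == f || m == "cleared") next  # compatible
    if (m == "wAlbAB") eff[f, m, ] <- walbab_profile(seq_len(K))
    else eff[f, m, ] <- 1  # ARwP male CI does not decay
  }
  structure(list(K = K, decay_enabled = decay_enabled,
                 decay_breaks = decay_breaks, decay_levels = decay_levels,
                 efficacy = eff),
            class = "iit_ci")
}

#' Look up CI efficacy for a cross
#'
#' @param ci an `iit_ci` profile.
#' @param female_strain,male_strain strain labels.
#' @param male_class male CI-age class, 1..K.
#' @return fraction of the cross's offspring that are non-viable.
#' @export
ci_efficacy <- function(ci, female_strain, male_strain, male_class) {
  dn <- dimnames(ci$efficacy)[[1]]
  if (!(female_strain %in% dn)) stop("unknown strain: ", female_strain)
  if (!(male_strain %in% dn)) stop("unknown strain: ", male_strain)
  if (any(male_class < 1) || any(male_class > ci$K))
    stop("male_class out of range 1..", ci$K)
  ci$efficacy[female_strain, male_strain, male_class]
}

# Fixed-point derivation of mu_F.  p_mated depends on mu_F through the
# steady-state mated fraction eta/(eta + mu_F), and mu_F is in turn derived
# from p_mated; iterate from a 9.5-day-lifespan initial guess.
derive_fitness <- function(fitness) {
  eta <- fitness$mating_rate
  lam <- fitness$lambda_birth
  ratio <- fitness$feasibility_ratio
  if (is.null(fitness$mu_F)) {
    mu <- 1 / 9.5
    for (it in 1:200) {
      p <- eta / (eta + mu)
      mu_new <- derive_female_death_rate(lam, p, ratio)
      if (abs(mu_new - mu) <= 1e-14 * mu) { mu <- mu_new; break }
      mu <- mu_new
    }
    # final sync so (mu_F, p_mated) satisfy the target ratio to the ulp
    p <- eta / (eta + mu)
    fitness$mu_F <- derive_female_death_rate(lam, p, ratio)
    fitness$p_mated <- p
    fitness$feas_ratio <- check_feasibility(fitness)$ratio
    return(fitness)
  }
  fitness$p_mated <- eta / (eta + fitness$mu_F)
  fitness$feas_ratio <- check_feasibility(fitness)$ratio
  fitness
}

strain_defaults <- function(entry) {
  out <- list(wild_type = FALSE, lambda_mult = 1, mu_F_mult = 1,
              mu_M_mult = 1, eta_mult = 1, frieds_index = 1)
  modifyList(out, entry[!vapply(entry, is.null, logical(1))])
}

#' Load and validate a model configuration
#'
#' Reads a YAML document with sections `strains`, `ci`,
#' `fitness.expected|low|high`, `population`, `migration`, `policy` and
#' `cage`, fills defaults, derives the female death rate from the
#' feasibility constraint, and validates every range invariant.  The package
#' ships a default document (`system.file("extdata", "default.yaml", package
#' = "iitsim")`) and a small `tiny.yaml` used for fast tests.
#'
#' @param path path to the YAML document; `NULL` for the packaged default.
#' @param parameter_set one of `expected`, `low`, `high`.
#' @param overrides named list merged over the top-level config fields
#'   (e.g. `list(migration_total = 2, policy = "naive")`).
#' @return a validated list of class `iit_config`.
#' @export
load_config <- function(path = NULL, parameter_set = "expected",
                        overrides = list()) {
  if (is.null(path))
    path <- system.file("extdata", "default.yaml", package = "iitsim")
  doc <- yaml::read_yaml(path)
  if (!parameter_set %in% names(doc$fitness))
    stop("configuration error: unknown parameter_set '", parameter_set, "'")

  strains <- lapply(doc$strains, strain_defaults)
  if (is.null(names(strains)) || anyDuplicated(names(strains)))
    stop("configuration error: strain names must be unique")
  bad <- setdiff(names(strains), KNOWN_STRAINS)
  if (length(bad))
    stop("configuration error: unknown strain name '", bad[1], "'")
  if (sum(vapply(strains, `[[`, logical(1), "wild_type")) != 1L)
    stop("configuration error: exactly one strain must have wild_type: true")

  fit <- doc$fitness[[parameter_set]]
  fit_defaults <- list(ci_aging_rate = 1, feasibility_ratio = 0.999,
                       immature_shape = 5)
  fit <- modifyList(fit_defaults, fit)

  cfg <- list(
    strains = strains,
    parameter_set = parameter_set,
    fitness = fit,
    ci_settings = modifyList(
      list(K = 20, decay_enabled = TRUE, decay_breaks = c(14, 19),
           decay_levels = c(1, 0.67, 0)),
      if (is.null(doc$ci)) list() else doc$ci),
    N0 = if (is.null(doc$population$N0)) 420 else doc$population$N0,
    migration_total = if (is.null(doc$migration$migration_total)) 0
                      else doc$migration$migration_total,
    policy = "maintain", contamination_rate = 0.01, overflooding_ratio = 5,
    release_interval = 7, omega_star = 0.4, resume_factor = 0.8,
    suppression_fraction = 0.10, horizon_days = 920, max_release_days = 730,
    min_release_days = 100, contamination_deterministic = FALSE,
    cage_max_days = 500, cage_runout_days = 180,
    cage_male_placement = "class1"
  )
  if (!is.null(doc$policy)) cfg <- modifyList(cfg, doc$policy)
  if (!is.null(doc$cage)) {
    if (!is.null(doc$cage$max_days)) cfg$cage_max_days <- doc$cage$max_days
    if (!is.null(doc$cage$runout_days)) cfg$cage_runout_days <- doc$cage$runout_days
  }
  if (length(overrides)) cfg <- modifyList(cfg, overrides)

  cfg$ci <- default_ci_profile(names(strains),
                               K = cfg$ci_settings$K,
                               decay_enabled = cfg$ci_settings$decay_enabled,
                               decay_breaks = unlist(cfg$ci_settings$decay_breaks),
                               decay_levels = unlist(cfg$ci_settings$decay_levels))
  cfg$fitness <- derive_fitness(cfg$fitness)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  fit <- cfg$fitness
  pos <- c("lambda_birth", "mu_M", "mating_rate", "immature_mean_duration",
           "ci_aging_rate", "mu_F")
  for (key in pos)
    if (is.null(fit[[key]]) || !is.numeric(fit[[key]]) || fit[[key]] <= 0)
      stop("configuration error: fitness parameter '", key,
           "' must be a positive number")
  if (fit$immature_shape < 1 || fit$immature_shape != round(fit$immature_shape))
    stop("configuration error: immature_shape must be a positive integer")
  if (cfg$contamination_rate < 0 || cfg$contamination_rate >= 1)
    stop("configuration error: contamination_rate must be in [0, 1)")
  if (!(cfg$suppression_fraction > 0 && cfg$suppression_fraction < cfg$omega_star &&
        cfg$omega_star < 1))
    stop("configuration error: need 0 < suppression_fraction < omega_star < 1")
  if (!(cfg$min_release_days <= cfg$max_release_days &&
        cfg$max_release_days <= cfg$horizon_days))
    stop("configuration error: need min_release_days <= max_release_days <= horizon_days")
  if (cfg$migration_total < 0)
    stop("configuration error: migration_total must be non-negative")
  if (!cfg$policy %in% c("naive", "complete_stop", "maintain"))
    stop("configuration error: unknown policy '", cfg$policy, "'")
  for (g in vapply(cfg$strains, `[[`, numeric(1), "frieds_index"))
    if (g < 0) stop("configuration error: frieds_index must be >= 0")
  feas <- check_feasibility(fit)
  if (!feas$ok)
    stop("configuration error: infeasible parameters, mu_F/(0.5 lambda p_mated) = ",
         format(feas$ratio), " >= 1")
  structure(cfg, class = "iit_config")
}

#' Reconfigure strains and CI for a cage experiment arm
#'
#' `bi` keeps the natural wAlbAB wild type against ARwP (bi-directional CI
#' with age decay), `bi_nodecay` switches off the age decay, and `uni`
#' replaces the wild type by a Wolbachia-cleared strain, giving the classic
#' uni-directional CI control (only cleared-female x ARwP-male crosses are
#' incompatible).
#'
#' @param config an `iit_config`.
#' @param arm one of `bi`, `bi_nodecay`, `uni`.
#' @return a new validated `iit_config`.
#' @export
arm_config <- function(config, arm = c("bi", "bi_nodecay", "uni")) {
  arm <- match.arg(arm)
  wild <- if (arm == "uni") "cleared" else "wAlbAB"
  strains <- list()
  strains[[wild]] <- strain_defaults(list(wild_type = TRUE))
  strains[["ARwP"]] <- modifyList(config$strains[["ARwP"]] %||%
                                    strain_defaults(list()),
                                  list(wild_type = FALSE))
  config$strains <- strains
  config$ci_settings$decay_enabled <- arm != "bi_nodecay"
  config$ci <- default_ci_profile(names(strains),
                                  K = config$ci_settings$K,
                                  decay_enabled = config$ci_settings$decay_enabled,
                                  decay_breaks = unlist(config$ci_settings$decay_breaks),
                                  decay_levels = unlist(config$ci_settings$decay_levels))
  validate_config(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
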