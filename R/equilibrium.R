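# Deterministic (mean-field) counterpart of the event set: calibration of the
# immature-pool capacity to the target steady state, the mated-female
# fraction, and net-zero immigration/emigration.

#' Calibrate the wild-type steady state
#'
#' Solves the wild-type-only mean-field balance equations for the positive
#' steady state with a prescribed adult total `N0`, and returns the implied
#' immature-pool capacity `C`.  At equilibrium the density factor must equal
#' the feasibility ratio `mu_F / (0.5 lambda p_mated)`, which pins down
#' `C = I_total / (1 - d*)`; the compartment composition follows from the
#' per-recruit balance of each stage, CI class, and mating state.
#'
#' @param config an `iit_config`.
#' @param N0 target steady-state adult population (default from the config).
#' @return list of class `iit_equilibrium` with the continuous steady state
#'   (full compartment layout), `p_mated`, `C`, the equilibrium density
#'   factor `d_star`, the adult recruitment rate `R`, and the adult
#'   composition shares used for the immigration split.
#' @export
calibrate_wildtype_equilibrium <- function(config, N0 = config$N0) {
  comp <- compartment_map(config)
  W <- wild_strain(config)
  sr <- strain_rates(config, W)
  fit <- config$fitness
  feas <- check_feasibility(list(lambda_birth = sr$lambda, mu_F = sr$mu_F,
                                 mating_rate = sr$eta))
  if (!feas$ok)
    stop("calibration error: no positive equilibrium, feasibility ratio ",
         format(feas$ratio), " >= 1")
  a <- fit$ci_aging_rate
  r_stage <- fit$immature_shape / fit$immature_mean_duration
  K <- comp$K

  # per unit adult-recruitment rate R (day^-1):
  m <- numeric(K)
  m[1] <- 0.5 / (a + sr$mu_M)
  if (K > 2) for (k in 2:(K - 1)) m[k] <- m[k - 1] * a / (a + sr$mu_M)
  if (K > 1) m[K] <- m[K - 1] * a / sr$mu_M
  U <- 0.5 / (sr$eta + sr$mu_F)
  M <- sr$eta * U / sr$mu_F
  adults_per_R <- sum(m) + U + M
  R <- N0 / adults_per_R

  p_mated <- M / (U + M)
  d_star <- sr$mu_F / (0.5 * sr$lambda * p_mated)
  I_tot <- R * fit$immature_mean_duration
  C <- I_tot / (1 - d_star)

  state <- setNames(numeric(comp$n_comp), comp$names)
  state[comp$imm[[W]]] <- R / r_stage
  state[comp$males[[W]]] <- R * m
  state[comp$unmated[[W]]] <- R * U
  # mated inflow allocated across the male CI-class groups of the wild x wild
  # cross in proportion to the male compartment totals
  rows <- comp$mated[comp$mated$f == W & comp$mated$m == W, ]
  shares <- vapply(seq_len(nrow(rows)), function(j)
    sum(m[rows$k_lo[j]:rows$k_hi[j]]) / sum(m), numeric(1))
  state[rows$idx] <- R * M * shares

  adult_idx <- adult_indices(comp, W)
  adult_share <- setNames(state[adult_idx] / sum(state[adult_idx]),
                          comp$names[adult_idx])
  structure(list(state_continuous = state, p_mated = p_mated, C = C,
                 d_star = d_star, R = R, N_adults = sum(state[adult_idx]),
                 adult_share = adult_share, wild = W,
                 epsilon = 0, immigration = NULL),
            class = "iit_equilibrium")
}

#' Calibrate immigration and emigration for net-zero drift
#'
#' Total wild-type inflow `migration_total/7` per day is split across the
#' wild adult compartments in proportion to their equilibrium shares, and the
#' per-capita emigration rate is set so that expected outflow at the
#' steady state equals the inflow exactly.
#'
#' @param eq an `iit_equilibrium` from [calibrate_wildtype_equilibrium()]
#'   (computed migration-free).
#' @param migration_total adult immigrants per week.
#' @return the equilibrium object with `epsilon` (day^-1) and the named
#'   per-compartment immigration rates filled in.
#' @export
calibrate_migration <- function(eq, migration_total) {
  if (migration_total < 0)
    stop("invalid parameter: migration_total must be non-negative")
  daily <- migration_total / 7
  eq$epsilon <- daily / eq$N_adults
  eq$immigration <- daily * eq$adult_share
  eq
}

#' Mean-field right-hand side
#'
#' Derivative of the continuous-state relaxation, obtained by summing
#' `rate x stoichiometry` over the same event list the stochastic engine
#' uses (never hand-coded separately).
#'
#' @param state non-negative real-valued state vector.
#' @param model an `iit_model`.
#' @return derivative vector (per day).
#' @export
mean_field_rhs <- function(state, model) {
  rates <- event_rates(pmax(state, 0), model)
  as.vector(model$delta %*% rates)
}

#' Integrate the mean-field system
#'
#' @param model an `iit_model`.
#' @param x0 initial continuous state.
#' @param times output times (days).
#' @return matrix of states (rows = times), as returned by [deSolve::ode()]
#'   without the time column.
#' @export
mean_field_trajectory <- function(model, x0, times) {
  out <- deSolve::ode(y = as.numeric(x0), times = times,
                      func = function(t, y, p) list(mean_field_rhs(y, model)))
  unname(out[, -1, drop = FALSE])
}

# Largest-remainder rounding of non-negative values to integers summing to
# `total`; ties broken by index order so results are reproducible.
largest_remainder <- function(v, total) {
  fl <- floor(v)
  rem <- total - sum(fl)
  if (rem > 0) {
    ord <- order(v - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  fl
}

#' Integer initial state for the open-patch scenarios
#'
#' Rounds the continuous wild-type equilibrium with largest-remainder
#' rounding, preserving the adult total at exactly `N0` and the immature
#' total at its rounded equilibrium value; released-strain compartments start
#' at zero.
#'
#' @param model an `iit_model`.
#' @return named integer-valued state vector.
#' @export
initial_state_patch <- function(model) {
  eq <- model$eq
  comp <- model$comp
  x <- setNames(numeric(comp$n_comp), comp$names)
  cs <- eq$state_continuous
  ai <- adult_indices(comp, eq$wild)
  x[ai] <- largest_remainder(cs[ai], round(sum(cs[ai])))
  ii <- comp$imm[[eq$wild]]
  x[ii] <- largest_remainder(cs[ii], round(sum(cs[ii])))
  x
}

#' Integer initial state for the cage experiments
#'
#' Half males, half females; within each sex a fraction `p_arwp` (rounded
#' half-up) carries the released strain and the rest are wild type.  All
#' females start unmated, all males in CI class 1 (freshly emerged, matching
#' colony-reared adults) unless `cage_male_placement = "stationary"` places
#' them at the equilibrium CI-class distribution.  The immature pool starts
#' at the wild equilibrium level split by the strain shares, so cage dynamics
#' do not begin with a recruitment gap.
#'
#' @param model an `iit_model` whose strains are the wild type and `ARwP`.
#' @param p_arwp initial proportion infected with the released strain.
#' @return named integer-valued state vector.
#' @export
initial_state_cage <- function(model, p_arwp) {
  if (!is.numeric(p_arwp) || p_arwp < 0 || p_arwp > 1)
    stop("invalid parameter: p_arwp must be in [0, 1]")
  comp <- model$comp
  eq <- model$eq
  cfg <- model$config
  W <- eq$wild
  half <- cfg$N0 / 2
  n_ar <- floor(p_arwp * half + 0.5)  # round half up
  n_w <- round(half) - n_ar
  x <- setNames(numeric(comp$n_comp), comp$names)
  if (cfg$cage_male_placement == "stationary") {
    mdist <- eq$state_continuous[comp$males[[W]]]
    mdist <- mdist / sum(mdist)
    x[comp$males[[W]]] <- largest_remainder(n_w * mdist, n_w)
    x[comp$males[["ARwP"]]] <- largest_remainder(n_ar * mdist, n_ar)
  } else {
    x[comp$males[[W]][1]] <- n_w
    x[comp$males[["ARwP"]][1]] <- n_ar
  }
  x[comp$unmated[[W]]] <- n_w
  x[comp$unmated[["ARwP"]]] <- n_ar
  imm_eq <- eq$state_continuous[comp$imm[[W]]]
  share <- c(n_w, n_ar) / (n_w + n_ar)
  x[comp$imm[[W]]] <- largest_remainder(imm_eq * share[1],
                                        round(sum(imm_eq) * share[1]))
  x[comp$imm[["ARwP"]]] <- largest_remainder(imm_eq * share[2],
                                             round(sum(imm_eq) * share[2]))
  x
}

#' Assemble a ready-to-simulate model
#'
#' Validates the configuration, calibrates the wild-type equilibrium and the
#' migration rates, and compiles the event set.
#'
#' @param config an `iit_config` from [load_config()].
#' @return list of class `iit_model` with the config, compartment map,
#'   equilibrium, event table, stoichiometry matrix and the flattened arrays
#'   used by the compiled engine.
#' @export
iit_model <- function(config) {
  if (!inherits(config, "iit_config")) config <- validate_config(config)
  eq <- calibrate_wildtype_equilibrium(config)
  eq <- calibrate_migration(eq, config$migration_total)
  comp <- compartment_map(config)
  events <- build_event_set(config, eq)
  model <- list(config = config, comp = comp, eq = eq, events = events)
  model$delta <- delta_matrix(comp, events)
  model$cpp <- model_to_cpp(config, comp, events, eq$C)
  structure(model, class = "iit_model")
}

#' @export
print.iit_model <- function(x, ...) {
  cfg <- x$config
  cat("iit_model:", paste(x$comp$strains, collapse = " vs "),
      sprintf("(%s parameters)\n", cfg$parameter_set))
  cat(sprintf("  compartments: %d, event channels: %d\n",
              x$comp$n_comp, nrow(x$events)))
  cat(sprintf("  N0 = %g adults, C = %.1f, p_mated = %.4f, mu_F = %.5f (1/mu_F = %.2f d)\n",
              cfg$N0, x$eq$C, x$eq$p_mated, cfg$fitness$mu_F,
              1 / cfg$fitness$mu_F))
  cat(sprintf("  feasibility ratio = %.4f, migration = %g/week (epsilon = %.3g/d)\n",
              cfg$fitness$feas_ratio, cfg$migration_total, x$eq$epsilon))
  invisible(x)
}
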