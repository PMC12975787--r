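# Release events (overflooding + female contamination), the three stopping
# policies, and the cage-protocol monitor.

#' Initial policy state
#'
#' @param config an `iit_config`.
#' @return list of class `iit_policy`: `releasing`, `policy_name`,
#'   `release_stopped_at`, `last_decision_time`, `resumed_at`.
#' @export
new_policy_state <- function(config) {
  structure(list(releasing = TRUE, policy_name = config$policy,
                 release_stopped_at = NA_real_,
                 last_decision_time = NA_real_,
                 resumed_at = numeric(0)),
            class = "iit_policy")
}

#' Size one release event
#'
#' Released males total `round(overflooding_ratio x current wild-type male
#' count)`; the number of contaminating females is a Binomial draw at the
#' contamination rate (or its rounded expectation in deterministic mode).
#' Released males enter the released strain's CI class 1, females enter its
#' unmated pool.
#'
#' @param state current state vector.
#' @param model an `iit_model`.
#' @return list with `males`, `females`, `total`.
#' @export
compute_release <- function(state, model) {
  cfg <- model$config
  comp <- model$comp
  wild_males <- sum(state[comp$males[[wild_strain(cfg)]]])
  total <- round(cfg$overflooding_ratio * wild_males)
  females <- if (total == 0 || cfg$contamination_rate == 0) 0L
  else if (cfg$contamination_deterministic)
    as.integer(round(total * cfg$contamination_rate))
  else rbinom(1L, total, cfg$contamination_rate)
  list(males = total - females, females = as.integer(females), total = total)
}

# Add a release to the state.
apply_release <- function(state, model, rel) {
  comp <- model$comp
  state[comp$males[["ARwP"]][1]] <- state[comp$males[["ARwP"]][1]] + rel$males
  state[comp$unmated[["ARwP"]]] <- state[comp$unmated[["ARwP"]]] + rel$females
  state
}

#' Evaluate the release policy at a decision instant
#'
#' Decisions are taken immediately before the release at the same instant.
#' No stopping condition is considered before `min_release_days`; all
#' policies force releases off from `max_release_days`.  Stopping: the naive
#' policy stops when wild-type adults drop below `suppression_fraction x N0`;
#' complete-stop and maintain additionally stop when released-strain adults
#' exceed `omega_star x N0`.  Only the maintain policy can resume, when the
#' wild type rebounds above `suppression_fraction x N0` AND the released
#' strain falls below `resume_factor x omega_star x N0`.  Proportions use the
#' initial steady-state adult count `N0` as denominator.
#'
#' @param state current state vector.
#' @param policy an `iit_policy`.
#' @param model an `iit_model`.
#' @param t decision time (days).
#' @return the updated `iit_policy`.
#' @export
policy_step <- function(state, policy, model, t) {
  cfg <- model$config
  if (!policy$policy_name %in% c("naive", "complete_stop", "maintain"))
    stop("configuration error: unknown policy '", policy$policy_name, "'")
  N0 <- cfg$N0
  adults <- strain_adults(state, model)
  wild <- adults[[wild_strain(cfg)]]
  arwp <- adults[["ARwP"]]
  if (t >= cfg$max_release_days) {
    if (policy$releasing) {
      policy$releasing <- FALSE
      policy$release_stopped_at <- t
    }
  } else if (t >= cfg$min_release_days) {
    supp <- wild < cfg$suppression_fraction * N0
    over <- arwp > cfg$omega_star * N0
    if (policy$releasing) {
      stop_now <- switch(policy$policy_name,
                         naive = supp,
                         complete_stop = supp || over,
                         maintain = supp || over)
      if (stop_now) {
        policy$releasing <- FALSE
        policy$release_stopped_at <- t
      }
    } else if (policy$policy_name == "maintain") {
      rebound <- wild > cfg$suppression_fraction * N0
      low_arwp <- arwp < cfg$resume_factor * cfg$omega_star * N0
      if (rebound && low_arwp) {
        policy$releasing <- TRUE
        policy$resumed_at <- c(policy$resumed_at, t)
      }
    }
  }
  policy$last_decision_time <- t
  policy
}

#' Cage stopping monitor
#'
#' Scans a daily trajectory for the first time either stopping condition
#' holds -- released-strain adults reach zero, or the wild-type adult
#' population is suppressed (strictly below `suppression_fraction x N0`) --
#' and schedules the end of the run `runout_days` later, capped at the cage
#' maximum duration.
#'
#' @param times sample times (days).
#' @param states state matrix (rows = times).
#' @param model an `iit_model`.
#' @return list with `trigger_time` (`NA` if never met) and `end_time`.
#' @export
cage_monitor <- function(times, states, model) {
  cfg <- model$config
  comp <- model$comp
  W <- wild_strain(cfg)
  wild <- rowSums(states[, adult_indices(comp, W), drop = FALSE])
  arwp <- rowSums(states[, adult_indices(comp, "ARwP"), drop = FALSE])
  hit <- which(arwp == 0 | wild < cfg$suppression_fraction * cfg$N0)
  trigger <- if (length(hit)) times[hit[1]] else NA_real_
  end <- if (is.na(trigger)) cfg$cage_max_days
         else min(cfg$cage_max_days, trigger + cfg$cage_runout_days)
  list(trigger_time = trigger, end_time = end)
}

#' Run one release-scenario replicate
#'
#' Weekly releases from day 0 while the policy allows, a 920-day horizon,
#' daily sampling, and policy decisions evaluated immediately before each
#' release instant.
#'
#' @param model an `iit_model` (strains: wild type and `ARwP`; policy and
#'   migration set in the config).
#' @param seed integer seed for this replicate.
#' @param method `"tau"` or `"exact"`.
#' @param tau leap step (days).
#' @return `iit_trajectory` with the release log and stop flags
#'   (`release_stopped` = time releases permanently ceased).
#' @export
run_scenario_rep <- function(model, seed, method = "tau", tau = 0.1) {
  cfg <- model$config
  set.seed(seed)
  x <- initial_state_patch(model)
  pol <- new_policy_state(cfg)
  instants <- seq(0, cfg$max_release_days - 1e-9, by = cfg$release_interval)
  horizon <- cfg$horizon_days
  times <- 0:horizon
  states <- matrix(NA_real_, nrow = length(times), ncol = length(x),
                   dimnames = list(NULL, model$comp$names))
  logs <- list()
  mcode <- if (method == "exact") 0L else 1L
  t_cur <- 0
  for (ti in instants) {
    if (ti > t_cur) {
      seg <- (t_cur + 1):ti
      res <- cpp_simulate(x, model$cpp, t_cur, ti, seg, mcode, tau)
      x <- res$state
      states[seg + 1L, ] <- res$record
      t_cur <- ti
    }
    pol <- policy_step(x, pol, model, ti)
    if (pol$releasing) {
      rel <- compute_release(x, model)
      if (rel$total > 0) {
        x <- apply_release(x, model, rel)
        logs[[length(logs) + 1L]] <- data.frame(time = ti, males = rel$males,
                                                females = rel$females)
      }
    }
    states[ti + 1L, ] <- x
  }
  if (horizon > t_cur) {
    seg <- (t_cur + 1):horizon
    res <- cpp_simulate(x, model$cpp, t_cur, horizon, seg, mcode, tau)
    states[seg + 1L, ] <- res$record
  }
  release_end <- if (!is.na(pol$release_stopped_at)) pol$release_stopped_at
                 else cfg$max_release_days
  rl <- if (length(logs)) do.call(rbind, logs) else
    data.frame(time = numeric(0), males = numeric(0), females = numeric(0))
  structure(list(times = times, states = states, release_log = rl,
                 stop_flags = c(release_stopped = release_end,
                                simulation_end = horizon),
                 policy = pol, seed = seed, method = method),
            class = "iit_trajectory")
}

#' Run one cage replicate
#'
#' No releases and no migration; the run ends `runout_days` after a stopping
#' condition first holds (checked on the daily grid) or at the cage maximum.
#'
#' @param model an `iit_model` built from a cage arm configuration.
#' @param p_arwp initial released-strain proportion.
#' @param seed integer seed.
#' @param method,tau engine settings.
#' @return list: truncated `times`/`states`, `trigger_time`, `end_time`, and
#'   final adult counts per strain.
#' @export
run_cage_rep <- function(model, p_arwp, seed, method = "tau", tau = 0.1) {
  cfg <- model$config
  set.seed(seed)
  x0 <- initial_state_cage(model, p_arwp)
  t_max <- cfg$cage_max_days
  mcode <- if (method == "exact") 0L else 1L
  chunk <- 50
  x <- as.numeric(x0)
  states <- matrix(x0, nrow = 1, dimnames = list(NULL, model$comp$names))
  t_cur <- 0
  end_t <- t_max
  trigger <- NA_real_
  while (t_cur < end_t) {
    t_next <- min(t_cur + chunk, end_t)
    seg <- (t_cur + 1):t_next
    res <- cpp_simulate(x, model$cpp, t_cur, t_next, seg, mcode, tau)
    x <- res$state
    states <- rbind(states, res$record)
    t_cur <- t_next
    if (is.na(trigger)) {
      mon <- cage_monitor(0:t_cur, states, model)
      if (!is.na(mon$trigger_time)) {
        trigger <- mon$trigger_time
        end_t <- mon$end_time
      }
    }
  }
  times <- 0:end_t
  states <- states[seq_len(end_t + 1), , drop = FALSE]
  final <- strain_adults(states[nrow(states), ], model)
  list(times = times, states = states, trigger_time = trigger,
       end_time = end_t, final_adults = final, seed = seed)
}
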