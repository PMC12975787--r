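# The two simulation studies: cage threshold sweeps and IIT release-scenario
# batches, with outcome classification, success/reversibility statistics and
# the released-mosquito cost proxy.

#' Classify establishment of a strain
#'
#' A strain counts as established when its adult total strictly exceeds 10%
#' of the initial population at the end of the run.
#'
#' @param state final state vector.
#' @param model an `iit_model`.
#' @param strain strain label.
#' @param N0 initial steady-state adult population.
#' @param fraction establishment fraction of `N0` (default 0.10).
#' @return logical flag.
#' @export
classify_establishment <- function(state, model, strain, N0 = model$config$N0,
                                   fraction = 0.10) {
  sum(state[adult_indices(model$comp, strain)]) > fraction * N0
}

#' Cage threshold sweep
#'
#' Runs `n_reps` cage replicates at each initial released-strain proportion
#' and reports the percentage establishing per strain, together with two
#' estimators of the unstable equilibrium threshold: the smallest grid
#' proportion with any released-strain establishment, and the smallest with
#' at least 50% of replicates establishing.
#'
#' @param config an `iit_config` (the cage uses no migration or releases).
#' @param arm cage arm: `bi`, `bi_nodecay` or `uni` (see [arm_config()]).
#' @param proportions initial proportion grid.
#' @param n_reps replicates per grid point.
#' @param master_seed master seed.
#' @param method,tau engine settings.
#' @return data frame (proportion x strain establishment percentages with
#'   binomial standard errors) with attributes `threshold_any` and
#'   `threshold_50` for the released strain, and `n_reps`.
#' @export
run_cage_sweep <- function(config, arm = "bi",
                           proportions = seq(0.05, 0.50, by = 0.05),
                           n_reps = 200, master_seed = 20260310,
                           method = "tau", tau = 0.1) {
  cfg <- arm_config(config, arm)
  cfg$migration_total <- 0
  model <- iit_model(cfg)
  strains <- model$comp$strains
  out <- list()
  for (j in seq_along(proportions)) {
    p <- proportions[j]
    reps <- run_batch(n_reps, master_seed + 1000 * j, function(seed, i) {
      r <- run_cage_rep(model, p, seed, method = method, tau = tau)
      vapply(strains, function(s)
        classify_establishment(r$states[nrow(r$states), ], model, s),
        logical(1))
    })
    est <- do.call(rbind, reps)
    for (s in strains) {
      phat <- mean(est[, s])
      out[[length(out) + 1L]] <- data.frame(
        proportion = p, strain = s, pct_established = 100 * phat,
        se_pct = 100 * sqrt(phat * (1 - phat) / n_reps), n = n_reps)
    }
  }
  res <- do.call(rbind, out)
  ar <- res[res$strain == "ARwP", ]
  attr(res, "threshold_any") <-
    if (any(ar$pct_established > 0)) min(ar$proportion[ar$pct_established > 0]) else NA_real_
  attr(res, "threshold_50") <-
    if (any(ar$pct_established >= 50)) min(ar$proportion[ar$pct_established >= 50]) else NA_real_
  attr(res, "n_reps") <- n_reps
  res
}

# Success flags and release accounting for one scenario trajectory.  The
# release program ends at its permanent stop for naive/complete_stop; the
# maintain strategy stays active (pauses included) until max_release_days,
# so it is evaluated there.  The 6-month evaluation is 183 days after the
# program end, capped at the simulation horizon.
classify_scenario <- function(traj, model) {
  cfg <- model$config
  N0 <- cfg$N0
  W <- wild_strain(cfg)
  stop_t <- if (cfg$policy == "maintain") cfg$max_release_days
            else unname(traj$stop_flags["release_stopped"])
  eval6 <- min(stop_t + 183, cfg$horizon_days)
  at <- function(t) traj$states[which.min(abs(traj$times - t)), ]
  flags <- function(t) {
    ad <- strain_adults(at(t), model)
    c(wild_ok = unname(ad[W] < cfg$suppression_fraction * N0),
      arwp_ok = unname(ad["ARwP"] < cfg$omega_star * N0))
  }
  fs <- flags(stop_t)
  f6 <- flags(eval6)
  rl <- traj$release_log
  tot <- rl$males + rl$females
  bins <- seq(0, 700, by = 100)
  per_bin <- vapply(seq_len(length(bins) - 1), function(b)
    sum(tot[rl$time >= bins[b] & rl$time < bins[b + 1]]), numeric(1))
  names(per_bin) <- sprintf("rel_%d_%d", bins[-length(bins)], bins[-1])
  final <- at(cfg$horizon_days)
  data.frame(
    stop_time = stop_t, eval6_time = eval6,
    success_wild_at_stop = fs[["wild_ok"]],
    success_arwp_at_stop = fs[["arwp_ok"]],
    success_at_stop = fs[["wild_ok"]] && fs[["arwp_ok"]],
    success_wild_at_6mo = f6[["wild_ok"]],
    success_arwp_at_6mo = f6[["arwp_ok"]],
    success_at_6mo = f6[["wild_ok"]] && f6[["arwp_ok"]],
    wild_established_end = classify_establishment(final, model, W),
    arwp_established_end = classify_establishment(final, model, "ARwP"),
    suppressed_wild_end =
      sum(final[adult_indices(model$comp, W)]) < cfg$suppression_fraction * N0,
    total_released = sum(tot),
    released_to_700 = sum(per_bin),
    t(per_bin))
}

#' Release-scenario batch
#'
#' Runs `n_reps` replicates of one policy x migration cell, classifies each
#' replicate at release stop and six months (183 days) later, and summarises
#' success percentages and the released-insect cost proxy.
#'
#' @param config an `iit_config` whose `policy` and `migration_total` define
#'   the cell.
#' @param n_reps number of replicates.
#' @param master_seed master seed.
#' @param method,tau engine settings.
#' @param keep_trajectories keep the first `keep_trajectories` trajectories
#'   (0 by default; summaries only).
#' @return list of class `iit_batch`: `records` (one row per replicate),
#'   `summary` (success percentages with binomial standard errors), `cost`
#'   (from [cost_summary()]), and the cell settings.
#' @export
run_scenario_batch <- function(config, n_reps = 200, master_seed = 20260310,
                               method = "tau", tau = 0.1,
                               keep_trajectories = 0) {
  model <- iit_model(config)
  kept <- list()
  reps <- run_batch(n_reps, master_seed, function(seed, i) {
    traj <- run_scenario_rep(model, seed, method = method, tau = tau)
    if (i <= keep_trajectories) kept[[i]] <<- traj
    cbind(replicate = i, seed = seed, classify_scenario(traj, model))
  })
  records <- do.call(rbind, reps)
  pct <- function(v) 100 * mean(v)
  se <- function(v) 100 * sqrt(mean(v) * (1 - mean(v)) / length(v))
  summary <- data.frame(
    timing = rep(c("within_stopping_time", "after_6_months"), each = 2),
    criterion = rep(c("wAlbAB", "ARwP"), 2),
    pct_success = c(pct(records$success_wild_at_stop),
                    pct(records$success_arwp_at_stop),
                    pct(records$success_wild_at_6mo),
                    pct(records$success_arwp_at_6mo)),
    se = c(se(records$success_wild_at_stop),
           se(records$success_arwp_at_stop),
           se(records$success_wild_at_6mo),
           se(records$success_arwp_at_6mo)))
  structure(list(records = records, summary = summary,
                 cost = cost_summary(records),
                 policy = config$policy,
                 migration_total = config$migration_total,
                 parameter_set = config$parameter_set,
                 n_reps = n_reps, master_seed = master_seed,
                 trajectories = kept),
            class = "iit_batch")
}

#' Released-insect cost proxy
#'
#' Median and interquartile band of releases per 100-day bin (bins anchored
#' at day 0, last bin ending day 700) and of the cumulative total to day 700.
#'
#' @param records replicate table from [run_scenario_batch()].
#' @return data frame with one row per bin plus a `cumulative_700` row.
#' @export
cost_summary <- function(records) {
  bin_cols <- grep("^rel_", names(records), value = TRUE)
  rows <- lapply(bin_cols, function(cl) {
    q <- quantile(records[[cl]], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(bin = sub("^rel_", "", cl), q25 = q[1], median = q[2], q75 = q[3],
               mean = mean(records[[cl]]))
  })
  q <- quantile(records$released_to_700, c(0.25, 0.5, 0.75), names = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    bin = "cumulative_700", q25 = q[1], median = q[2], q75 = q[3],
    mean = mean(records$released_to_700))
  do.call(rbind, rows)
}

#' @export
print.iit_batch <- function(x, ...) {
  cat(sprintf("iit_batch: policy %s, migration %g/week, %s parameters, %d reps\n",
              x$policy, x$migration_total, x$parameter_set, x$n_reps))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
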