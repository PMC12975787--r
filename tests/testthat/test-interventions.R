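model0 <- iit_model(default_config())

test_that("release size follows the overflooding ratio and contamination", {
  m <- model0
  x <- state_with(m, M_wAlbAB_3 = 30, M_wAlbAB_15 = 20)
  set.seed(8)
  draws <- replicate(400, {
    r <- compute_release(x, m)
    expect_equal(r$males + r$females, 250)  # 5 x 50 wild males
    r$females
  })
  # Binomial(250, 0.01) mean 2.5
  expect_lt(abs(mean(draws) - 2.5), 3 * sqrt(250 * 0.01 * 0.99 / 400))
  # no wild males, nothing to release
  expect_equal(compute_release(state_with(m), m)$total, 0)
  # contamination off
  m2 <- iit_model(default_config(contamination_rate = 0))
  expect_equal(compute_release(x, m2)$females, 0L)
  # deterministic contamination
  m3 <- iit_model(default_config(contamination_deterministic = TRUE))
  expect_equal(compute_release(x, m3)$females, 2L)  # round(250 * 0.01)
})

test_that("policies respect the minimum-days guard and their stop rules", {
  m <- model0
  N0 <- 420
  mk_state <- function(wild, arwp) {
    x <- state_with(m)
    x[m$comp$unmated[["wAlbAB"]]] <- wild
    x[m$comp$unmated[["ARwP"]]] <- arwp
    x
  }
  # before 100 days no stopping is considered
  for (pn in c("naive", "complete_stop", "maintain")) {
    pol <- new_policy_state(default_config(policy = pn))
    pol <- policy_step(mk_state(10, 0), pol, m, 50)
    expect_true(pol$releasing)
  }
  # naive stops on suppression only, permanently
  pol <- new_policy_state(default_config(policy = "naive"))
  pol <- policy_step(mk_state(41, 0), pol, m, 105)
  expect_false(pol$releasing)
  expect_equal(pol$release_stopped_at, 105)
  pol <- policy_step(mk_state(400, 0), pol, m, 112)  # rebound: no resume
  expect_false(pol$releasing)
  # naive ignores the threshold breach that stops complete_stop
  pol_n <- policy_step(mk_state(300, 200), new_policy_state(default_config(policy = "naive")), m, 105)
  expect_true(pol_n$releasing)
  pol_c <- policy_step(mk_state(300, 200), new_policy_state(default_config(policy = "complete_stop")), m, 105)
  expect_false(pol_c$releasing)  # 200 > 0.4 x 420
  # maintain resumes when the wild type rebounds and the released strain falls
  pol <- new_policy_state(default_config(policy = "maintain"))
  pol <- policy_step(mk_state(41, 0), pol, m, 105)
  expect_false(pol$releasing)
  pol <- policy_step(mk_state(50, 140), pol, m, 112)  # ARwP above 0.8 w* N0
  expect_false(pol$releasing)
  pol <- policy_step(mk_state(50, 120), pol, m, 119)  # 120 < 134.4 and 50 > 42
  expect_true(pol$releasing)
  expect_equal(pol$resumed_at, 119)
  # forced off from the maximum release duration
  pol <- policy_step(mk_state(400, 0), pol, m, 730)
  expect_false(pol$releasing)
})

test_that("cage monitor schedules the run-out and respects the boundary", {
  m <- model0
  n <- m$comp$n_comp
  wild_u <- m$comp$unmated[["wAlbAB"]]
  ar_u <- m$comp$unmated[["ARwP"]]
  mk_traj <- function(wild, arwp) {
    st <- matrix(0, nrow = length(wild), ncol = n)
    st[, wild_u] <- wild
    st[, ar_u] <- arwp
    st
  }
  # released strain extinct at day 90: end at 270
  wild <- rep(300, 501); arwp <- c(rep(5, 90), rep(0, 411))
  mon <- cage_monitor(0:500, mk_traj(wild, arwp), m)
  expect_equal(mon$trigger_time, 90)
  expect_equal(mon$end_time, 270)
  # no condition ever met: full 500 days
  mon <- cage_monitor(0:500, mk_traj(rep(300, 501), rep(50, 501)), m)
  expect_true(is.na(mon$trigger_time))
  expect_equal(mon$end_time, 500)
  # exactly 42 wild adults is not suppressed (strictly below)
  mon <- cage_monitor(0:500, mk_traj(rep(42, 501), rep(50, 501)), m)
  expect_true(is.na(mon$trigger_time))
  mon <- cage_monitor(0:500, mk_traj(rep(41, 501), rep(50, 501)), m)
  expect_equal(mon$trigger_time, 0)
})

test_that("clean releases leave released-strain female compartments empty", {
  cfg <- default_config(contamination_rate = 0, migration_total = 0,
                        policy = "naive")
  m <- iit_model(cfg)
  tr <- run_scenario_rep(m, seed = 21, method = "tau")
  comp <- m$comp
  fem_cols <- c(comp$unmated[["ARwP"]], comp$mated$idx[comp$mated$f == "ARwP"])
  expect_true(all(tr$states[, fem_cols] == 0))
  expect_true(all(tr$release_log$females == 0))
})
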