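test_that("identical seeds give identical trajectories in both modes", {
  m <- iit_model(tiny_config())
  x0 <- initial_state_patch(m)
  for (method in c("exact", "tau")) {
    a <- simulate_ctmc(m, x0, 30, seed = 11, method = method)
    b <- simulate_ctmc(m, x0, 30, seed = 11, method = method)
    expect_identical(a$states, b$states)
  }
  c1 <- simulate_ctmc(m, x0, 30, seed = 12, method = "tau")
  expect_false(identical(c1$states,
                         simulate_ctmc(m, x0, 30, seed = 11, method = "tau")$states))
})

test_that("a state with zero propensities stays constant", {
  m <- iit_model(tiny_config())
  x0 <- numeric(m$comp$n_comp)
  tr <- simulate_ctmc(m, x0, 10, seed = 1, method = "exact")
  expect_true(all(tr$states == 0))
})

test_that("pure-death ensemble mean matches exponential decay", {
  mu <- 0.3; n0 <- 50; t_end <- 3
  tm <- toy_model(1, data.frame(from = 1, to = NA, rate = mu))
  set.seed(2024)
  finals <- replicate(1000, toy_final(tm, n0, t_end))
  p <- exp(-mu * t_end)
  se <- sqrt(n0 * p * (1 - p) / 1000)
  expect_lt(abs(mean(finals) - n0 * p), 3 * se)
  # tau mode agrees too
  set.seed(2025)
  finals_tau <- replicate(1000, toy_final(tm, n0, t_end, method = 1L))
  expect_lt(abs(mean(finals_tau) - n0 * p), 4 * se)
})

test_that("SSA state distribution matches the matrix-exponential CTMC solution", {
  # one particle hopping on three states
  rates <- rbind(c(NA, 1.0, 0.2), c(0.5, NA, 0.7), c(0.1, 0.3, NA))
  trans <- do.call(rbind, lapply(1:3, function(i) do.call(rbind, lapply(1:3, function(j)
    if (i != j) data.frame(from = i, to = j, rate = rates[i, j]) else NULL))))
  tm <- toy_model(3, trans)
  t_obs <- 5
  Q <- rates; diag(Q) <- 0; diag(Q) <- -rowSums(Q)
  P <- as.matrix(Matrix::expm(Q * t_obs))
  target <- P[1, ]
  set.seed(31415)
  n <- 10000
  where <- replicate(n, which(toy_final(tm, c(1, 0, 0), t_obs) == 1))
  emp <- tabulate(where, nbins = 3) / n
  tv <- 0.5 * sum(abs(emp - target))
  expect_lt(tv, 0.02)
})

test_that("tau-leaping reproduces exact-mode ensemble means", {
  m <- iit_model(tiny_config())
  x0 <- initial_state_patch(m)
  mean_adults <- function(method) {
    finals <- run_batch(300, 55, function(seed, i) {
      set.seed(seed)
      r <- iitsim:::cpp_simulate(x0, m$cpp, 0, 100, numeric(0),
                                 if (method == "exact") 0L else 1L, 0.1)
      sum(strain_adults(r$state, m))
    })
    mean(unlist(finals))
  }
  me <- mean_adults("exact")
  mt <- mean_adults("tau")
  expect_lt(abs(me - mt) / me, 0.03)
})

test_that("replicate seed streams are distinct and reproducible", {
  s1 <- replicate_seeds(20260310, 500)
  expect_equal(length(unique(s1)), 500)
  expect_identical(s1, replicate_seeds(20260310, 500))
  expect_true(all(s1 > 0 & s1 < 2^31))
  out <- run_batch(3, 9, function(seed, i) { set.seed(seed); rpois(1, 100) })
  out2 <- run_batch(3, 9, function(seed, i) { set.seed(seed); rpois(1, 100) })
  expect_identical(out, out2)
})

test_that("callbacks fire exactly on schedule and alter the state", {
  m <- iit_model(tiny_config())
  x0 <- numeric(m$comp$n_comp)  # frozen population; only the callback acts
  kick <- list(times = c(3, 7), fn = function(state, t) {
    state[m$comp$males[["ARwP"]][1]] <- state[m$comp$males[["ARwP"]][1]] + 5
    list(state = state, log = data.frame(time = t, males = 5, females = 0))
  })
  tr <- simulate_ctmc(m, x0, 10, seed = 4, method = "exact", callbacks = list(kick))
  i3 <- which(tr$times == 3); i7 <- which(tr$times == 7)
  cls1 <- m$comp$males[["ARwP"]][1]
  all_m <- m$comp$males[["ARwP"]]
  expect_equal(unname(tr$states[i3, cls1]), 5)   # post-callback sample
  expect_true(all(tr$states[tr$times < 3, ] == 0))
  # the second injection lands on top of the (aging, dying) survivors
  expect_gte(unname(tr$states[i7, cls1]), 5)
  expect_lte(sum(tr$states[i7, all_m]), 10)
  expect_equal(tr$release_log$time, c(3, 7))
  expect_true(all(diff(tr$times) > 0))
})

test_that("no trajectory contains a negative count", {
  m <- iit_model(default_config(migration_total = 10, policy = "maintain"))
  tr <- run_scenario_rep(m, seed = 3, method = "tau")
  expect_true(all(tr$states >= 0))
  expect_true(all(tr$states == floor(tr$states)))
})
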