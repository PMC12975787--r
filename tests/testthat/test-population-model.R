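model_default <- iit_model(default_config())

test_that("compartment grid matches the strain/class arithmetic", {
  comp <- model_default$comp
  expect_equal(length(unlist(comp$males)), 2 * 20)
  ev <- model_default$events
  expect_equal(sum(ev$type == "aging"), 2 * 19)
  # wAlbAB-male crosses carry the three distinct efficacy classes of the
  # decay profile; every other cross collapses to one mated compartment
  md <- comp$mated
  expect_equal(nrow(md[md$f == "ARwP" & md$m == "wAlbAB", ]), 3)
  expect_equal(nrow(md[md$f == "wAlbAB" & md$m == "wAlbAB", ]), 1)
  expect_equal(nrow(md[md$m == "ARwP", ]), 2)
  expect_equal(comp$n_comp,
               2 * 5 + 2 * 20 + 2 + nrow(md))
})

test_that("density factor is the linear-logistic form", {
  expect_equal(density_factor(0, 100), 1)
  expect_equal(density_factor(100, 100), 0)
  expect_equal(density_factor(50, 100), 0.5)
  expect_equal(density_factor(150, 100), 0)  # clamped
  expect_error(density_factor(10, 0), "invalid")
})

test_that("propensities follow CI viability and vanish on empty compartments", {
  m <- model_default
  lam <- m$config$fitness$lambda_birth
  # empty state, no migration: nothing can happen
  x <- state_with(m)
  expect_true(all(propensity_vector(x, m) == 0))
  # a fully incompatible mated female produces no offspring
  x <- state_with(m, F_wAlbABxARwP_c1 = 1)
  ev <- m$events
  expect_equal(propensity_vector(x, m)[ev$name == "birth_wAlbABxARwP_c1"],
               0)
  # partial CI: viable births at (1 - 0.67) lambda with an empty pool
  x <- state_with(m, F_ARwPxwAlbAB_c2 = 1)
  expect_equal(propensity_vector(x, m)[ev$name == "birth_ARwPxwAlbAB_c2"],
               (1 - 0.67) * lam)
  expect_error(propensity_vector(rep(-1, m$comp$n_comp), m), "negative")
})

test_that("R and compiled propensities agree on random states", {
  m <- model_default
  set.seed(77)
  for (i in 1:15) {
    x <- rpois(m$comp$n_comp, 10)
    expect_equal(propensity_vector(x, m),
                 as.numeric(iitsim:::cpp_propensities(x, m$cpp)),
                 tolerance = 1e-12)
  }
  # and with migration-bearing event sets
  m2 <- iit_model(default_config(migration_total = 2))
  x <- rpois(m2$comp$n_comp, 5)
  expect_equal(propensity_vector(x, m2),
               as.numeric(iitsim:::cpp_propensities(x, m2$cpp)),
               tolerance = 1e-12)
})

test_that("every event moves the total population by its category's amount", {
  m <- iit_model(default_config(migration_total = 2))
  net <- colSums(m$delta)
  expected <- ifelse(m$events$type %in% c("birth", "immigration"), 1,
              ifelse(m$events$type %in% c("death", "emigration"), -1, 0))
  expect_equal(unname(net), expected)
})

test_that("mating moves one unmated female and leaves males untouched", {
  m <- model_default
  x <- state_with(m, U_ARwP = 3, M_wAlbAB_16 = 5)
  e <- which(m$events$name == "mate_ARwPxwAlbAB_c2")
  y <- apply_event(x, m, e)
  expect_equal(y[["U_ARwP"]], 2)
  expect_equal(y[["F_ARwPxwAlbAB_c2"]], 1)
  expect_equal(y[["M_wAlbAB_16"]], 5)
  expect_equal(sum(y), sum(x))
  # mating allocation: only the compatible class group's males drive its rate
  pr <- propensity_vector(x, m)
  eta <- m$config$fitness$mating_rate
  expect_equal(pr[e], eta * 3)  # all males are in class group 2
  expect_error(apply_event(state_with(m), m, e), "negative")
})

test_that("the released strain never arises spontaneously", {
  for (mig in c(0, 2)) {
    m <- iit_model(default_config(migration_total = mig))
    x0 <- initial_state_patch(m)
    tr <- simulate_ctmc(m, x0, 60, seed = 99, method = "tau")
    ar_cols <- adult_indices(m$comp, "ARwP")
    imm_ar <- m$comp$imm[["ARwP"]]
    expect_true(all(tr$states[, c(ar_cols, imm_ar)] == 0))
  }
})

test_that("male CI-class residence times follow the truncated Erlang law", {
  # a = 1/day aging chain without death: the occupied class at time t is
  # 1 + min(Pois(a t), K - 1)
  K <- 20
  trans <- data.frame(from = 1:(K - 1), to = 2:K, rate = 1)
  tm <- toy_model(K, trans)
  t_obs <- 10
  set.seed(424)
  cls <- replicate(3000, which(toy_final(tm, c(1, rep(0, K - 1)), t_obs) == 1))
  emp <- tabulate(cls, nbins = K) / 3000
  theo <- c(dpois(0:(K - 2), t_obs), ppois(K - 2, t_obs, lower.tail = FALSE))
  expect_lt(0.5 * sum(abs(emp - theo)), 0.05)
})
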