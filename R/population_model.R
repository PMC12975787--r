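# Integer state space and the full Markov event set: density-dependent
# recruitment, CI-dependent offspring viability, male CI-class progression,
# mating with Fried's-index allocation, and migration.

# Compartment layout (fixed, stable column order for serialization):
#   immatures by strain x stage, males by strain x CI class, unmated females
#   by strain, mated females by (female strain x male strain x CI class
#   group).  Male CI classes with identical efficacy for a given cross are
#   collapsed into one mated compartment (the efficacy is frozen at mating).
compartment_map <- function(config) {
  strains <- names(config$strains)
  K <- config$ci$K
  n_st <- config$fitness$immature_shape
  nm <- character(0)
  imm <- males <- list()
  unmated <- integer(0)
  idx <- 0L
  for (s in strains) {
    imm[[s]] <- idx + seq_len(n_st)
    idx <- idx + n_st
    nm <- c(nm, sprintf("I_%s_%d", s, seq_len(n_st)))
  }
  imm_range <- c(1L, idx)
  for (s in strains) {
    males[[s]] <- idx + seq_len(K)
    idx <- idx + K
    nm <- c(nm, sprintf("M_%s_%d", s, seq_len(K)))
  }
  for (s in strains) {
    unmated[s] <- idx + 1L
    idx <- idx + 1L
    nm <- c(nm, sprintf("U_%s", s))
  }
  mated <- NULL
  for (f in strains) for (m in strains) {
    runs <- rle(as.vector(config$ci$efficacy[f, m, ]))
    hi <- cumsum(runs$lengths)
    lo <- c(1L, head(hi, -1L) + 1L)
    for (g in seq_along(runs$values)) {
      idx <- idx + 1L
      mated <- rbind(mated, data.frame(
        f = f, m = m, grp = g, k_lo = lo[g], k_hi = hi[g],
        eff = runs$values[g], idx = idx, stringsAsFactors = FALSE))
      nm <- c(nm, sprintf("F_%sx%s_c%d", f, m, g))
    }
  }
  list(n_comp = idx, names = nm, strains = strains, imm = imm, males = males,
       unmated = unmated, mated = mated, imm_range = imm_range,
       n_stages = n_st, K = K)
}

# Adult compartment indices, overall or for one strain (female strain for
# mated compartments: a mated female belongs to her own strain).
adult_indices <- function(comp, strain = NULL) {
  strains <- if (is.null(strain)) comp$strains else strain
  unlist(lapply(strains, function(s) {
    c(comp$males[[s]], comp$unmated[[s]], comp$mated$idx[comp$mated$f == s])
  }), use.names = FALSE)
}

#' Adult counts per strain
#'
#' @param state numeric state vector in the model's compartment layout.
#' @param model an `iit_model`.
#' @return named vector of adult totals (males + unmated + mated females) per
#'   strain.
#' @export
strain_adults <- function(state, model) {
  comp <- model$comp
  vapply(comp$strains, function(s) sum(state[adult_indices(comp, s)]),
         numeric(1))
}

#' Density-dependent birth modifier
#'
#' Linear-logistic factor `max(0, 1 - I_total / C)` applied to every birth
#' rate; both strains contribute to the same immature pool.
#'
#' @param I_total total immature count across strains and stages.
#' @param C immature-pool capacity (calibrated to the target steady state).
#' @return fraction in `[0, 1]`, monotone non-increasing in `I_total`.
#' @export
density_factor <- function(I_total, C) {
  if (!is.numeric(C) || length(C) != 1L || C <= 0)
    stop("invalid parameter: capacity C must be positive")
  pmax(0, 1 - I_total / C)
}

# Per-strain effective rates (base rate times the strain's multiplier).
strain_rates <- function(config, s) {
  st <- config$strains[[s]]
  fit <- config$fitness
  list(lambda = fit$lambda_birth * st$lambda_mult,
       mu_F = fit$mu_F * st$mu_F_mult,
       mu_M = fit$mu_M * st$mu_M_mult,
       eta = fit$mating_rate * st$eta_mult,
       gamma = st$frieds_index)
}

#' Build the complete Markov event set
#'
#' Returns one row per event channel: immature stage progression, emergence
#' with a 50/50 sex split (two competing events at half the stage rate), male
#' CI-class aging (class K absorbing until death), per-capita deaths, mating
#' with Fried's-index allocation across male compartments, CI- and
#' density-modified births with maternal strain inheritance, wild-type
#' immigration split by the equilibrium composition, and per-capita
#' emigration from every adult compartment.
#'
#' @param config an `iit_config`.
#' @param eq an `iit_equilibrium` (required when `migration_total > 0`; used
#'   for the immigration split and emigration rate).
#' @return data frame of event definitions with rate-formula codes
#'   (`cat`: 1 linear, 2 constant, 3 birth, 4 mating), rate constants,
#'   sparse deltas and mating male-group ranges.
#' @export
build_event_set <- function(config, eq = NULL) {
  comp <- compartment_map(config)
  fit <- config$fitness
  a <- fit$ci_aging_rate
  r_stage <- fit$immature_shape / fit$immature_mean_duration
  ev <- list()
  add <- function(name, type, cat, cc, src = NA_integer_,
                  d1i, d1v, d2i = NA_integer_, d2v = NA_integer_,
                  grp_lo = NA_integer_, grp_hi = NA_integer_, gma = NA_real_) {
    ev[[length(ev) + 1L]] <<- data.frame(
      name = name, type = type, cat = cat, cc = cc, src = src,
      d1i = d1i, d1v = d1v, d2i = d2i, d2v = d2v,
      grp_lo = grp_lo, grp_hi = grp_hi, gma = gma, stringsAsFactors = FALSE)
  }
  for (s in comp$strains) {
    sr <- strain_rates(config, s)
    im <- comp$imm[[s]]; ml <- comp$males[[s]]; u <- comp$unmated[[s]]
    n_st <- comp$n_stages; K <- comp$K
    if (n_st > 1)
      for (i in seq_len(n_st - 1))
        add(sprintf("dev_%s_%d", s, i), "development", 1, r_stage,
            src = im[i], d1i = im[i], d1v = -1L, d2i = im[i + 1], d2v = 1L)
    add(sprintf("emerge_M_%s", s), "emergence", 1, r_stage / 2,
        src = im[n_st], d1i = im[n_st], d1v = -1L, d2i = ml[1], d2v = 1L)
    add(sprintf("emerge_F_%s", s), "emergence", 1, r_stage / 2,
        src = im[n_st], d1i = im[n_st], d1v = -1L, d2i = u, d2v = 1L)
    for (k in seq_len(K - 1))
      add(sprintf("age_%s_%d", s, k), "aging", 1, a,
          src = ml[k], d1i = ml[k], d1v = -1L, d2i = ml[k + 1], d2v = 1L)
    for (k in seq_len(K))
      add(sprintf("death_M_%s_%d", s, k), "death", 1, sr$mu_M,
          src = ml[k], d1i = ml[k], d1v = -1L)
    add(sprintf("death_U_%s", s), "death", 1, sr$mu_F,
        src = u, d1i = u, d1v = -1L)
    rows <- comp$mated[comp$mated$f == s, ]
    for (j in seq_len(nrow(rows))) {
      rw <- rows[j, ]
      gm <- config$strains[[rw$m]]$frieds_index
      mm <- comp$males[[rw$m]]
      add(sprintf("mate_%sx%s_c%d", s, rw$m, rw$grp), "mating", 4, sr$eta,
          src = u, d1i = u, d1v = -1L, d2i = rw$idx, d2v = 1L,
          grp_lo = mm[rw$k_lo], grp_hi = mm[rw$k_hi], gma = gm)
      add(sprintf("death_F_%sx%s_c%d", s, rw$m, rw$grp), "death", 1, sr$mu_F,
          src = rw$idx, d1i = rw$idx, d1v = -1L)
      add(sprintf("birth_%sx%s_c%d", s, rw$m, rw$grp), "birth", 3,
          sr$lambda * (1 - rw$eff),
          src = rw$idx, d1i = im[1], d1v = 1L)
    }
  }
  if (config$migration_total > 0) {
    if (is.null(eq) || is.null(eq$epsilon))
      stop("configuration error: migration requires a calibrated equilibrium")
    wild <- wild_strain(config)
    inflow <- eq$immigration  # named per-compartment rates (day^-1)
    for (nm in names(inflow)) {
      if (inflow[[nm]] <= 0) next
      i <- match(nm, comp$names)
      add(sprintf("immigrate_%s", nm), "immigration", 2, inflow[[nm]],
          d1i = i, d1v = 1L)
    }
    for (i in adult_indices(comp))
      add(sprintf("emigrate_%s", comp$names[i]), "emigration", 1, eq$epsilon,
          src = i, d1i = i, d1v = -1L)
  }
  do.call(rbind, ev)
}

wild_strain <- function(config) {
  names(config$strains)[vapply(config$strains, `[[`, logical(1), "wild_type")]
}

# Flat 0-based arrays consumed by the C++ engine.
model_to_cpp <- function(config, comp, events, capacity) {
  list(cat = as.integer(events$cat),
       cc = as.numeric(events$cc),
       src = as.integer(ifelse(is.na(events$src), 1L, events$src)) - 1L,
       d1i = as.integer(events$d1i) - 1L,
       d1v = as.integer(events$d1v),
       d2i = as.integer(ifelse(is.na(events$d2i), 0L, events$d2i)) - 1L,
       d2v = as.integer(ifelse(is.na(events$d2v), 0L, events$d2v)),
       grp_lo = as.integer(ifelse(is.na(events$grp_lo), 1L, events$grp_lo)) - 1L,
       grp_hi = as.integer(ifelse(is.na(events$grp_hi), 1L, events$grp_hi)) - 1L,
       gma = as.numeric(ifelse(is.na(events$gma), 0, events$gma)),
       imm_lo = comp$imm_range[1] - 1L,
       imm_hi = comp$imm_range[2] - 1L,
       capacity = as.numeric(capacity),
       male_lo = vapply(comp$males, function(v) v[1], integer(1)) - 1L,
       male_hi = vapply(comp$males, function(v) v[length(v)], integer(1)) - 1L,
       male_gamma = vapply(comp$strains, function(s)
         config$strains[[s]]$frieds_index, numeric(1)))
}

# R-side mirror of the C++ rate formulas; used by propensity_vector and the
# mean-field right-hand side so both routes share one event list.
event_rates <- function(state, model) {
  ev <- model$events
  comp <- model$comp
  itot <- sum(state[comp$imm_range[1]:comp$imm_range[2]])
  dens <- density_factor(itot, model$eq$C)
  wm <- 0
  for (s in comp$strains)
    wm <- wm + model$config$strains[[s]]$frieds_index * sum(state[comp$males[[s]]])
  n <- nrow(ev)
  rates <- numeric(n)
  for (e in seq_len(n)) {
    rates[e] <- switch(ev$cat[e],
      ev$cc[e] * state[ev$src[e]],
      ev$cc[e],
      ev$cc[e] * state[ev$src[e]] * dens,
      if (wm <= 0) 0 else
        ev$cc[e] * state[ev$src[e]] * ev$gma[e] *
          sum(state[ev$grp_lo[e]:ev$grp_hi[e]]) / wm)
  }
  rates
}

#' Propensity vector of the Markov chain at a state
#'
#' @param state numeric state vector (non-negative integer counts).
#' @param model an `iit_model`.
#' @return vector of event rates (day^-1), one per event channel.
#' @export
propensity_vector <- function(state, model) {
  if (length(state) != model$comp$n_comp)
    stop("state has wrong length")
  if (any(state < 0) || any(!is.finite(state)))
    stop("internal consistency error: negative or non-finite state")
  rates <- event_rates(state, model)
  if (any(rates < 0) || any(!is.finite(rates)))
    stop("internal consistency error: negative or non-finite propensity")
  rates
}

#' Apply one event's state change
#'
#' @param state numeric state vector.
#' @param model an `iit_model`.
#' @param event_index row index into `model$events`.
#' @return the new state; errors if any count would become negative.
#' @export
apply_event <- function(state, model, event_index) {
  ev <- model$events[event_index, ]
  state[ev$d1i] <- state[ev$d1i] + ev$d1v
  if (!is.na(ev$d2i)) state[ev$d2i] <- state[ev$d2i] + ev$d2v
  if (any(state < 0))
    stop("internal consistency error: event '", ev$name,
         "' produced a negative count")
  state
}

# Dense stoichiometry matrix (n_comp x n_events).
delta_matrix <- function(comp, events) {
  D <- matrix(0, nrow = comp$n_comp, ncol = nrow(events))
  for (e in seq_len(nrow(events))) {
    D[events$d1i[e], e] <- D[events$d1i[e], e] + events$d1v[e]
    if (!is.na(events$d2i[e]))
      D[events$d2i[e], e] <- D[events$d2i[e], e] + events$d2v[e]
  }
  D
}
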