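# Shared fixtures: configs built from the packaged documents and hand-built
# toy chains fed straight to the compiled engine.

tiny_config <- function(...) {
  ov <- list(...)
  load_config(system.file("extdata", "tiny.yaml", package = "iitsim"),
              overrides = ov)
}

default_config <- function(...) {
  load_config(overrides = list(...))
}

# A bare linear-transition model for the engine: `trans` has columns
# from, to (NA = removal), rate; `inflow` adds constant-rate arrivals.
toy_model <- function(n_comp, trans, inflow = NULL) {
  ne <- nrow(trans) + if (is.null(inflow)) 0L else nrow(inflow)
  cat <- c(rep(1L, nrow(trans)), rep(2L, if (is.null(inflow)) 0L else nrow(inflow)))
  cc <- c(trans$rate, inflow$rate)
  src <- c(trans$from, rep(1L, ne - nrow(trans)))
  d1i <- c(trans$from, inflow$to)
  d1v <- c(rep(-1L, nrow(trans)), rep(1L, ne - nrow(trans)))
  d2i <- c(ifelse(is.na(trans$to), 0L, trans$to), rep(0L, ne - nrow(trans)))
  d2v <- c(ifelse(is.na(trans$to), 0L, 1L), rep(0L, ne - nrow(trans)))
  cpp <- list(cat = cat, cc = as.numeric(cc), src = as.integer(src) - 1L,
              d1i = as.integer(d1i) - 1L, d1v = as.integer(d1v),
              d2i = as.integer(d2i) - 1L, d2v = as.integer(d2v),
              grp_lo = rep(0L, ne), grp_hi = rep(0L, ne), gma = rep(0, ne),
              imm_lo = -1L, imm_hi = -1L, capacity = 1,
              male_lo = integer(0), male_hi = integer(0),
              male_gamma = numeric(0))
  list(comp = list(n_comp = n_comp, names = paste0("c", seq_len(n_comp))),
       cpp = cpp)
}

# Final state after simulating a toy model, one compiled call.
toy_final <- function(model, x0, t_end, method = 0L, tau = 0.1) {
  iitsim:::cpp_simulate(as.numeric(x0), model$cpp, 0, t_end, numeric(0),
                        method, tau)$state
}

# State vector helper: zero state with named compartments set.
state_with <- function(model, ...) {
  x <- setNames(numeric(model$comp$n_comp), model$comp$names)
  vals <- list(...)
  for (nm in names(vals)) {
    stopifnot(nm %in% model$comp$names)
    x[nm] <- vals[[nm]]
  }
  x
}
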