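# Serialization: trajectory and summary CSVs, run manifests.

#' Write a trajectory to CSV
#'
#' One row per sample time; columns are `time`, every compartment in the
#' stable layout order (immatures by strain x stage, males by strain x CI
#' class, unmated females by strain, mated females by cross x class), and the
#' cumulative release counters.  The release log is written to a sibling
#' `<file>_releases.csv` with columns (time, males, females).
#'
#' @param traj an `iit_trajectory`.
#' @param file destination CSV path.
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(traj, file) {
  rl <- traj$release_log
  cum_m <- vapply(traj$times, function(t) sum(rl$males[rl$time <= t]), numeric(1))
  cum_f <- vapply(traj$times, function(t) sum(rl$females[rl$time <= t]), numeric(1))
  df <- data.frame(time = traj$times, traj$states, check.names = FALSE,
                   cumulative_released_males = cum_m,
                   cumulative_released_females = cum_f)
  write.csv(df, file, row.names = FALSE)
  write.csv(rl, sub("\\.csv$", "_releases.csv", file), row.names = FALSE)
  invisible(file)
}

#' Read back a trajectory CSV
#'
#' @param file path written by [write_trajectory()].
#' @return list with `times`, `states` and the cumulative release counters.
#' @export
read_trajectory <- function(file) {
  df <- read.csv(file, check.names = FALSE)
  cc <- c("time", "cumulative_released_males", "cumulative_released_females")
  states <- as.matrix(df[, setdiff(names(df), cc), drop = FALSE])
  list(times = df$time, states = states,
       cumulative_released_males = df$cumulative_released_males,
       cumulative_released_females = df$cumulative_released_females)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-for-bit in exact mode:
#' the resolved configuration, master seed, package version, command line and
#' wall times.
#'
#' @param file destination JSON path.
#' @param config the resolved `iit_config`.
#' @param master_seed master seed of the run.
#' @param command free-form command description.
#' @param started,finished POSIXct wall times.
#' @return `file`, invisibly.
#' @export
write_manifest <- function(file, config, master_seed, command = "",
                           started = Sys.time(), finished = Sys.time()) {
  snap <- unclass(config)
  snap$ci <- NULL  # rebuilt from ci_settings on load
  manifest <- list(
    package = "iitsim",
    version = as.character(utils::packageVersion("iitsim")),
    master_seed = master_seed,
    command = command,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
    config = snap)
  jsonlite::write_json(manifest, file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(file)
}
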