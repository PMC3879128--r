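# Result writers, run manifests, and the command surface behind the
# motor-ensemble command-line script.

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  path
}

# every command writes a manifest describing the resolved run
.write_manifest <- function(outdir, p, extra = list(), outputs = character(0),
                            seed = NULL, started = NULL) {
  n <- max_extent(p)
  manifest <- c(list(
    package = "motorensemble",
    parameters = unclass(p),
    extent_n = as.integer(n),
    truncated = isTRUE(attr(n, "truncated")),
    n_states = count_states(p$m_bar, as.integer(n)),
    seed = seed,
    elapsed_s = if (is.null(started)) NULL else as.numeric(Sys.time()) - started,
    outputs = as.list(outputs)
  ), extra)
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, null = "null")
  path
}

#' Enumerate the state space and write it to CSV
#'
#' @param p A `motor_params` object.
#' @param outdir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
run_enumerate <- function(p, outdir) {
  started <- as.numeric(Sys.time())
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  n <- max_extent(p)
  space <- enumerate_states(p$m_bar, as.integer(n))
  f <- .write_csv(as.data.frame(space), file.path(outdir, "states.csv"))
  invisible(.write_manifest(outdir, p, outputs = basename(f), started = started))
}

#' Solve the master equation and write time series
#'
#' Writes the probability vector at each requested time plus a time series
#' of survival, engaged-motor mean, and velocity (both unconditional and
#' conditioned on the cargo not being lost).
#'
#' @param p A `motor_params` object.
#' @param times Numeric vector of times, s.
#' @param outdir Output directory.
#' @return The manifest path, invisibly.
#' @export
run_solve <- function(p, times, outdir) {
  started <- as.numeric(Sys.time())
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mod <- build_model(p)
  times <- sort(unique(times))
  probs <- matrix(0, mod$space$N, length(times))
  Pt <- mod$P0
  t_prev <- 0
  for (i in seq_along(times)) {
    Pt <- propagate(Pt, times[i] - t_prev, mod$G)
    t_prev <- times[i]
    probs[, i] <- Pt
  }
  pdf <- data.frame(index = seq_len(mod$space$N), configuration = mod$space$strings,
                    probs, check.names = FALSE)
  names(pdf)[-(1:2)] <- sprintf("t_%g", times)
  f1 <- .write_csv(pdf, file.path(outdir, "probabilities.csv"))
  series <- data.frame(
    time_s = times,
    p_lost = probs[mod$space$N, ],
    mean_engaged = apply(probs, 2, expected_engaged, space = mod$space),
    velocity_nm_s = apply(probs, 2, mean_velocity, table = mod$table, space = mod$space),
    mean_engaged_conditional = apply(probs, 2, function(P)
      expected_engaged(conditional_not_lost(P), mod$space))
  )
  f2 <- .write_csv(series, file.path(outdir, "series.csv"))
  invisible(.write_manifest(outdir, p, outputs = basename(c(f1, f2)), started = started))
}

#' Run-length/velocity load sweep command
#'
#' @param p A `motor_params` object.
#' @param loads Load grid in nN.
#' @param outdir Output directory.
#' @return The manifest path, invisibly.
#' @export
run_sweep <- function(p, loads, outdir) {
  started <- as.numeric(Sys.time())
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  curve <- run_length_curve(loads, p)
  # flag interior local maxima of the run-length curve
  rl <- curve$runlength_nm
  peak <- rep(FALSE, length(rl))
  if (length(rl) >= 3) {
    interior <- 2:(length(rl) - 1)
    peak[interior] <- rl[interior] > rl[interior - 1] & rl[interior] > rl[interior + 1]
  }
  curve$runlength_peak <- peak
  f <- .write_csv(curve, file.path(outdir, "sweep.csv"))
  invisible(.write_manifest(outdir, p, outputs = basename(f), started = started))
}

#' Steady-state (quasi-stationary) distribution command
#'
#' @param p A `motor_params` object.
#' @param outdir Output directory.
#' @return The manifest path, invisibly.
#' @export
run_steadystate <- function(p, outdir) {
  started <- as.numeric(Sys.time())
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mod <- build_model(p)
  df <- data.frame(index = seq_len(mod$space$N - 1L),
                   configuration = mod$space$strings[-mod$space$N],
                   probability = mod$qsd$pi)
  f <- .write_csv(df, file.path(outdir, "steadystate.csv"))
  invisible(.write_manifest(
    outdir, p, extra = list(decay_rate_per_s = mod$qsd$decay_rate),
    outputs = basename(f), started = started))
}

#' Step-size distribution command
#'
#' @param p A `motor_params` object.
#' @param outdir Output directory.
#' @return The manifest path, invisibly.
#' @export
run_stepdist <- function(p, outdir) {
  started <- as.numeric(Sys.time())
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mod <- build_model(p)
  dist <- step_size_distribution(mod$qsd$pi, mod$table, mod$space)
  f1 <- .write_csv(dist$support, file.path(outdir, "stepdist.csv"))
  attr_df <- dist$attribution
  attr_df$from <- mod$space$strings[attr_df$from]
  attr_df$to <- mod$space$strings[attr_df$to]
  f2 <- .write_csv(attr_df, file.path(outdir, "stepdist_attribution.csv"))
  invisible(.write_manifest(outdir, p, outputs = basename(c(f1, f2)), started = started))
}

#' Gillespie simulation command
#'
#' @param p A `motor_params` object.
#' @param n_traj Number of trajectories.
#' @param t_end Horizon, s (`Inf` runs to absorption).
#' @param seed Integer seed.
#' @param outdir Output directory.
#' @return The manifest path, invisibly.
#' @export
run_simulate <- function(p, n_traj, t_end, seed, outdir) {
  started <- as.numeric(Sys.time())
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  n <- max_extent(p)
  space <- enumerate_states(p$m_bar, as.integer(n))
  table <- transition_table(space, p)
  batch <- simulate_batch(n_traj, t_end, table, space, seed = seed)
  f1 <- .write_csv(batch, file.path(outdir, "trajectories.csv"))
  emp <- empirical_distribution(batch, space)
  f2 <- .write_csv(
    data.frame(index = seq_len(space$N), configuration = space$strings,
               frequency = emp),
    file.path(outdir, "empirical.csv"))
  invisible(.write_manifest(
    outdir, p,
    extra = list(n_traj = n_traj, t_end = t_end,
                 mean_runlength_nm = mean(batch$runlength_nm)),
    outputs = basename(c(f1, f2)), seed = seed, started = started))
}

#' Export the event-level transition table to CSV
#'
#' @param table Event table from [transition_table()].
#' @param space The matching `state_space`.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
export_transitions <- function(table, space, path) {
  out <- table
  out$from <- space$strings[out$from]
  out$to <- space$strings[out$to]
  invisible(.write_csv(out, path))
}
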