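# Stochastic simulation of the unprojected lattice model: the independent
# oracle for every exact result. Rates come from the same mechanics and
# kinetics code as the exact solver, so discrepancies isolate
# projection/solver defects.

#' Simulate one trajectory of the lattice model
#'
#' Event-driven stochastic simulation on absolute configurations:
#' exponential waiting times from the total outflow rate of
#' [absolute_transitions()], events chosen proportionally to their rates.
#' Stops when the cargo is lost (empty configuration) or at `t_end`.
#'
#' @param Z0 Initial non-empty `abs_config`.
#' @param t_end Time horizon, s (may be `Inf` to run to absorption).
#' @param p A `motor_params` object.
#' @param seed Integer seed; the trajectory is fully reproducible from it.
#' @param max_events Safety cap on the number of events.
#' @return Object of class `motor_trajectory`: list with `events` (data
#'   frame: `time`, `kind`, `site`, `displacement`, `x_eq`), `Z_final`,
#'   `lost`, `loss_time` (NA if the horizon was reached), `seed`.
#' @export
simulate_ensemble <- function(Z0, t_end, p, seed = NULL, max_events = 1e6) {
  if (length(Z0$sites) == 0L) stop("Z0 must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  Z <- Z0
  t <- 0
  x <- cargo_equilibrium(Z, p)$x_eq
  rows <- vector("list", 256L)
  nrow_ <- 0L
  lost <- FALSE
  loss_time <- NA_real_
  while (t < t_end && nrow_ < max_events) {
    ev <- absolute_transitions(Z, p)
    rates <- vapply(ev, `[[`, 0, "rate")
    tot <- sum(rates)
    dt <- stats::rexp(1, tot)
    if (t + dt > t_end) {
      t <- t_end
      break
    }
    t <- t + dt
    j <- findInterval(stats::runif(1) * tot, cumsum(rates)) + 1L
    e <- ev[[j]]
    x <- x + e$displacement
    nrow_ <- nrow_ + 1L
    if (nrow_ > length(rows)) rows <- c(rows, vector("list", length(rows)))
    rows[[nrow_]] <- data.frame(time = t, kind = e$kind, site = e$site,
                                displacement = e$displacement, x_eq = x,
                                stringsAsFactors = FALSE)
    Z <- e$target
    if (length(Z$sites) == 0L) {
      lost <- TRUE
      loss_time <- t
      break
    }
  }
  events <- if (nrow_ > 0L) do.call(rbind, rows[seq_len(nrow_)]) else
    data.frame(time = numeric(0), kind = character(0), site = integer(0),
               displacement = numeric(0), x_eq = numeric(0))
  structure(list(events = events, Z_final = Z, lost = lost,
                 loss_time = loss_time, t_end = t_end, seed = seed),
            class = "motor_trajectory")
}

#' @export
print.motor_trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d events, %s\n", nrow(x$events),
              if (x$lost) sprintf("cargo lost at t = %.4g s", x$loss_time)
              else sprintf("horizon t = %g s reached", x$t_end)))
  invisible(x)
}

# per-state event cache over the projected chain (translation invariance
# makes absolute simulation reducible to relative state + displacement)
.gillespie_cache <- function(table, space) {
  N <- space$N
  by_from <- split(seq_len(nrow(table)), table$from)
  cache <- vector("list", N)
  for (s in names(by_from)) {
    i <- by_from[[s]]
    cache[[as.integer(s)]] <- list(
      cum = cumsum(table$rate[i]),
      tot = sum(table$rate[i]),
      to = table$to[i],
      disp = table$displacement[i],
      row = i
    )
  }
  cache
}

#' Simulate many trajectories of the lattice model (vectorized)
#'
#' Batch Gillespie simulation over the event table. Translation invariance
#' lets every trajectory be tracked as a relative state plus the cargo
#' displacement accumulated event by event, with rates identical to the
#' full lattice simulation. All trajectories advance in lock-step, one
#' event per iteration.
#'
#' @param n_traj Number of trajectories.
#' @param t_end Horizon, s (`Inf` runs every trajectory to absorption).
#' @param table Event table from [transition_table()].
#' @param space The matching `state_space`.
#' @param seed Integer seed.
#' @param init Initial state: a configuration string (default `"M"`) or a
#'   full-length probability vector to sample starting states from.
#' @param record_steps If `TRUE`, tally how often each event of `table`
#'   fired (for empirical step-size histograms).
#' @return Data frame with one row per trajectory: `state` (index at the
#'   earlier of `t_end` and loss; the empty state if lost), `runlength_nm`
#'   (accumulated displacement), `lost`, `loss_time`, `n_events`. With
#'   `record_steps`, attribute `event_counts` holds per-table-row counts.
#' @export
simulate_batch <- function(n_traj, t_end, table, space, seed = NULL, init = "M",
                           record_steps = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  N <- space$N
  cache <- .gillespie_cache(table, space)
  tot <- vapply(seq_len(N), function(i) if (is.null(cache[[i]])) 0 else cache[[i]]$tot, 0)
  if (is.character(init)) {
    st <- rep.int(state_index(space, init), n_traj)
  } else {
    st <- sample.int(N, n_traj, replace = TRUE, prob = init)
  }
  t <- numeric(n_traj)
  x <- numeric(n_traj)
  nev <- integer(n_traj)
  counts <- if (record_steps) integer(nrow(table)) else NULL
  loss_time <- rep(NA_real_, n_traj)
  active <- st != N
  while (any(active)) {
    ia <- which(active)
    s_a <- st[ia]
    dt <- stats::rexp(length(ia), tot[s_a])
    tnew <- t[ia] + dt
    over <- tnew > t_end
    if (any(over)) {
      # the next event would fall beyond the horizon: freeze at t_end
      io <- ia[over]
      t[io] <- t_end
      active[io] <- FALSE
      ia <- ia[!over]
      if (length(ia) == 0L) next
      s_a <- st[ia]
      tnew <- tnew[!over]
    }
    t[ia] <- tnew
    u <- stats::runif(length(ia))
    for (s in unique(s_a)) {
      sel <- which(s_a == s)
      cs <- cache[[s]]
      j <- findInterval(u[sel] * cs$tot, cs$cum) + 1L
      j[j > length(cs$to)] <- length(cs$to)
      idx <- ia[sel]
      x[idx] <- x[idx] + cs$disp[j]
      st[idx] <- cs$to[j]
      if (record_steps) {
        tb <- tabulate(j, nbins = length(cs$row))
        counts[cs$row] <- counts[cs$row] + tb
      }
    }
    nev[ia] <- nev[ia] + 1L
    lost_now <- ia[st[ia] == N]
    if (length(lost_now) > 0L) {
      loss_time[lost_now] <- t[lost_now]
      active[lost_now] <- FALSE
    }
  }
  out <- data.frame(state = st, runlength_nm = x, lost = st == N,
                    loss_time = loss_time, n_events = nev)
  if (record_steps) attr(out, "event_counts") <- counts
  out
}

#' Empirical distribution over relative configurations
#'
#' Frequency of each relative configuration (including the empty one)
#' across a batch of simulated trajectories.
#'
#' @param batch Result of [simulate_batch()].
#' @param space The `state_space`.
#' @return Probability vector of length N.
#' @export
empirical_distribution <- function(batch, space) {
  tabulate(batch$state, nbins = space$N) / nrow(batch)
}
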