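# Force-dependent single-motor kinetics, thermal averaging over the cargo
# position, enumeration of elementary transitions, and projection onto
# relative-configuration rates.

#' Binding efficiency of the free motor head under load
#'
#' `1` for assisting or zero load, `(1 - F/F_s)^2` between zero and stall,
#' `0` at or above stall.
#'
#' @param F Load on the motor, nN (positive opposes motion); vectorized.
#' @param p A `motor_params` object.
#' @return Probability in `[0, 1]`.
#' @export
binding_efficiency <- function(F, p) {
  ifelse(F <= 0, 1, ifelse(F < p$F_s, (1 - F / p$F_s)^2, 0))
}

#' Stepping rate of a single motor under constant load
#'
#' Michaelis-Menten ATP turnover with a load-dependent Michaelis constant
#' (the hydrolysis back-rate grows as `exp(F*d_l/kB*T)`), multiplied by the
#' binding efficiency; zero at or above stall.
#'
#' @inheritParams binding_efficiency
#' @return Rate in 1/s.
#' @export
step_rate_at_force <- function(F, p) {
  kBT <- thermal_energy(p)
  k_off <- p$k0_off * exp(F * p$d_l / kBT)
  km <- (p$k_cat + k_off) / p$k_on
  p$k_cat * p$atp / (p$atp + km) * binding_efficiency(F, p)
}

#' Processivity of a single motor under constant load
#'
#' Mean distance a motor travels before detaching:
#' `L(F) = d_s * [ATP] * A * e / ([ATP] + B*(1+A)*e)` with
#' `e = exp(-F*delta_l/(kB*T))`.
#'
#' @inheritParams binding_efficiency
#' @return Length in nm.
#' @export
processivity <- function(F, p) {
  kBT <- thermal_energy(p)
  e <- exp(-F * p$delta_l / kBT)
  p$d_s * p$atp * p$proc_A * e / (p$atp + p$proc_B * (1 + p$proc_A) * e)
}

#' Detachment rate of a single motor under constant load
#'
#' Below stall the stepping and detachment rates are tied by the
#' processivity, `P_step/P_detach = L/d_s`; at or above stall the rate is
#' the constant `P_back`.
#'
#' @inheritParams binding_efficiency
#' @return Rate in 1/s.
#' @export
detach_rate_at_force <- function(F, p) {
  ifelse(F < p$F_s, step_rate_at_force(F, p) * p$d_s / processivity(F, p), p$P_back)
}

# cached Gauss-Legendre nodes/weights on [-1, 1]
.quad_cache <- new.env(parent = emptyenv())
.gauss_legendre <- function(order) {
  key <- as.character(order)
  gl <- get0(key, envir = .quad_cache, inherits = FALSE)
  if (is.null(gl)) {
    gl <- pracma::gaussLegendre(order, -1, 1)
    assign(key, gl, envir = .quad_cache)
  }
  gl
}

# thermal average of rate_fun(force on a motor at a_k) over the truncated
# Gaussian cargo position centered at eq$x_eq. The integrand is only
# piecewise smooth (slack boundaries of the force law, the stall switch of
# the detachment law), so the interval is split at those breakpoints and
# Gauss-Legendre is applied per smooth piece.
.thermal_avg <- function(rate_fun, a_k, eq, p,
                         order = getOption("motorensemble.quad_order", 41L)) {
  if (p$sigma_th == 0) {
    return(rate_fun(motor_load(a_k, eq$x_eq, p), p))
  }
  gl <- .gauss_legendre(order)
  lo <- eq$x_eq - 3 * p$sigma_th
  hi <- eq$x_eq + 3 * p$sigma_th
  # cargo positions where the motor's force law changes branch
  cuts <- a_k + c(-p$l0, p$l0,
                  -p$l0 - p$F_s / p$k_el,   # stall boundary, motor ahead
                  p$l0 + p$F_s / p$k_el)
  cuts <- sort(unique(c(lo, cuts[cuts > lo & cuts < hi], hi)))
  total <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    h <- (cuts[i + 1] - cuts[i]) / 2
    x <- (cuts[i + 1] + cuts[i]) / 2 + h * gl$x
    f <- rate_fun(linkage_force(a_k - x, p), p)
    total <- total + h * sum(gl$w * f * thermal_density(x - eq$x_eq, p))
  }
  total
}

#' Stepping rate out of a lattice site
#'
#' Total rate of a forward step from site `k` of configuration `Z`:
#' `z_k` times the thermal average of the single-motor stepping rate over
#' the cargo position. With `sigma_th = 0` the average collapses to a
#' point evaluation at the equilibrium.
#'
#' @param Z A non-empty `abs_config`.
#' @param k Site index (must be occupied).
#' @param p A `motor_params` object.
#' @param eq Optional precomputed [cargo_equilibrium()] of `Z`.
#' @return Rate in 1/s.
#' @export
site_step_rate <- function(Z, k, p, eq = NULL) {
  i <- match(as.integer(k), Z$sites)
  if (is.na(i)) stop("site k is not occupied")
  if (is.null(eq)) eq <- cargo_equilibrium(Z, p)
  Z$counts[i] * .thermal_avg(step_rate_at_force, k * p$d_s, eq, p)
}

#' Detachment rate out of a lattice site
#'
#' As [site_step_rate()] with the detachment kinetics; inside the thermal
#' average the integrand switches to the above-stall constant `P_back`
#' wherever the instantaneous load reaches the stall force.
#'
#' @inheritParams site_step_rate
#' @return Rate in 1/s.
#' @export
site_detach_rate <- function(Z, k, p, eq = NULL) {
  i <- match(as.integer(k), Z$sites)
  if (is.na(i)) stop("site k is not occupied")
  if (is.null(eq)) eq <- cargo_equilibrium(Z, p)
  Z$counts[i] * .thermal_avg(detach_rate_at_force, k * p$d_s, eq, p)
}

# admissible attachment sites: lattice sites within l0 of the cargo
.admissible_sites <- function(x_eq, p) {
  eps <- 1e-9
  lo <- ceiling((x_eq - p$l0) / p$d_s - eps)
  hi <- floor((x_eq + p$l0) / p$d_s + eps)
  if (hi < lo) integer(0) else seq.int(lo, hi)
}

#' Attachment transitions from a configuration
#'
#' An unattached motor can only bind at lattice sites within `l0` of the
#' cargo (it attaches without stretching its linkage), all equally likely.
#' The total attachment rate is `(m_bar - engaged) * P_att`, split
#' uniformly over the admissible sites.
#'
#' @inheritParams site_step_rate
#' @return List of events, each a list with `kind = "attach"`, `site`,
#'   `rate`, `displacement`, and `target` (an `abs_config`).
#' @export
attachment_events <- function(Z, p, eq = NULL) {
  if (length(Z$sites) == 0L) stop("attachment from the empty configuration is not modeled")
  engaged <- sum(Z$counts)
  if (engaged >= p$m_bar) return(list())
  if (is.null(eq)) eq <- cargo_equilibrium(Z, p)
  sites <- .admissible_sites(eq$x_eq, p)
  if (length(sites) == 0L) return(list())
  rate <- (p$m_bar - engaged) * p$P_att / length(sites)
  lapply(sites, function(k) {
    i <- match(k, Z$sites)
    target <- if (is.na(i)) {
      abs_config(c(Z$sites, k), c(Z$counts, 1L))
    } else {
      abs_config(Z$sites, Z$counts + (Z$sites == k))
    }
    list(kind = "attach", site = as.integer(k), rate = rate,
         displacement = as.numeric(displacement(Z, target, p)),
         target = target)
  })
}

#' All elementary transitions from an absolute configuration
#'
#' Union of one step and one detachment event per occupied site plus the
#' admissible attachments. Events whose rate is exactly zero (stalled
#' steps) are omitted. Each event carries the change in the cargo
#' equilibrium position.
#'
#' @inheritParams site_step_rate
#' @return List of events as in [attachment_events()], with
#'   `kind` in `step`, `detach`, `attach` and a `rearguard` flag marking
#'   events at the rearmost occupied site.
#' @export
absolute_transitions <- function(Z, p) {
  if (length(Z$sites) == 0L) stop("no transitions from the empty configuration")
  eq <- cargo_equilibrium(Z, p)
  rear <- Z$sites[1]
  ev <- list()
  for (i in seq_along(Z$sites)) {
    k <- Z$sites[i]
    # forward step: one motor k -> k+1
    r_step <- site_step_rate(Z, k, p, eq)
    if (r_step > 0) {
      tgt <- .move_motor(Z, i)
      ev[[length(ev) + 1L]] <- list(
        kind = "step", site = k, rate = r_step,
        displacement = as.numeric(displacement(Z, tgt, p)),
        target = tgt, rearguard = (k == rear))
    }
    # detachment: remove one motor at k
    r_det <- site_detach_rate(Z, k, p, eq)
    if (r_det > 0) {
      tgt <- .remove_motor(Z, i)
      ev[[length(ev) + 1L]] <- list(
        kind = "detach", site = k, rate = r_det,
        displacement = as.numeric(displacement(Z, tgt, p)),
        target = tgt, rearguard = (k == rear))
    }
  }
  att <- attachment_events(Z, p, eq)
  for (e in att) {
    e$rearguard <- (e$site == rear)
    ev[[length(ev) + 1L]] <- e
  }
  ev
}

.move_motor <- function(Z, i) {
  k <- Z$sites[i]
  counts <- Z$counts
  counts[i] <- counts[i] - 1L
  j <- match(k + 1L, Z$sites)
  if (!is.na(j)) {
    counts[j] <- counts[j] + 1L
    keep <- counts > 0L
    abs_config(Z$sites[keep], counts[keep])
  } else {
    keep <- counts > 0L
    abs_config(c(Z$sites[keep], k + 1L), c(counts[keep], 1L))
  }
}

.remove_motor <- function(Z, i) {
  counts <- Z$counts
  counts[i] <- counts[i] - 1L
  keep <- counts > 0L
  abs_config(Z$sites[keep], counts[keep])
}

#' Projected transition rates out of one relative configuration
#'
#' Enumerates the elementary transitions of the canonical representative
#' and groups them by the relative configuration of the target. By
#' translation invariance any representative yields the same rates, so the
#' projected rate is simply the sum of absolute rates into each target
#' class, and the class displacement is their rate-weighted mean.
#' Self-transitions (e.g. a lone motor stepping) are retained: they carry
#' displacement for the observables even though they cancel in the
#' generator.
#'
#' @param sigma Non-empty relative configuration (count vector or string).
#' @param space A `state_space` containing `sigma`.
#' @param p A `motor_params` object.
#' @return A data frame with one row per elementary event: `from`, `to`
#'   (state indices; the empty state maps to index `N`), `kind`, `site`,
#'   `rearguard`, `rate` (1/s), `displacement` (nm), and `target_shift`
#'   (new rearguard position in the source canonical frame; `NA` into the
#'   empty state).
#' @export
relative_rates <- function(sigma, space, p) {
  if (is.character(sigma)) sigma <- parse_config(sigma)
  from <- state_index(space, sigma)
  ev <- absolute_transitions(canonical_representative(sigma), p)
  allow_drop <- !is.null(p$n_cap)
  n_ev <- length(ev)
  keep <- logical(n_ev)
  to <- integer(n_ev); shift <- integer(n_ev)
  for (j in seq_len(n_ev)) {
    tgt_sigma <- project(ev[[j]]$target)
    if (length(tgt_sigma) > space$n) {
      if (allow_drop) next
      stop(sprintf("transition target exceeds the extent bound n = %d (state '%s')",
                   space$n, render_config(sigma)))
    }
    keep[j] <- TRUE
    to[j] <- if (length(tgt_sigma) == 0L) space$N else state_index(space, tgt_sigma)
    shift[j] <- if (length(tgt_sigma) == 0L) NA_integer_ else ev[[j]]$target$sites[1]
  }
  dropped <- sum(!keep)
  ev <- ev[keep]
  out <- data.frame(
    from = rep.int(from, length(ev)),
    to = to[keep],
    kind = vapply(ev, `[[`, "", "kind"),
    site = vapply(ev, `[[`, 0L, "site"),
    rearguard = vapply(ev, `[[`, NA, "rearguard"),
    rate = vapply(ev, `[[`, 0, "rate"),
    displacement = vapply(ev, `[[`, 0, "displacement"),
    target_shift = shift[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "dropped") <- dropped
  out
}

#' Event-level transition table for a whole state space
#'
#' Binds [relative_rates()] over every non-empty state. This is the single
#' source the generator, the observables, and the Gillespie oracle consume.
#'
#' @param space A `state_space`.
#' @param p A `motor_params` object.
#' @return A data frame of elementary events (columns as in
#'   [relative_rates()]) with attributes `m_bar`, `n`, and `dropped` (count
#'   of events discarded under an `n_cap` truncation).
#' @export
transition_table <- function(space, p) {
  if (p$m_bar != space$m_bar) {
    stop("p$m_bar does not match the state space")
  }
  rows <- vector("list", space$N - 1L)
  dropped <- 0L
  for (i in seq_len(space$N - 1L)) {
    r <- relative_rates(space$configs[[i]], space, p)
    dropped <- dropped + attr(r, "dropped")
    rows[[i]] <- r
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "m_bar") <- space$m_bar
  attr(out, "n") <- space$n
  attr(out, "dropped") <- dropped
  if (dropped > 0L) {
    message(sprintf("transition_table: %d event(s) dropped by the n_cap truncation", dropped))
  }
  out
}

#' Aggregate the event table to class-to-class rates
#'
#' Collapses elementary events to the projected chain: total rate
#' `lambda_rel(to, from)` and rate-weighted mean displacement `d_av`.
#'
#' @param table An event table from [transition_table()].
#' @return Data frame with columns `from`, `to`, `rate`, `d_av`.
#' @export
aggregate_rates <- function(table) {
  key <- paste(table$from, table$to)
  rate <- rowsum(table$rate, key, reorder = FALSE)
  wdisp <- rowsum(table$rate * table$displacement, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- data.frame(
    from = table$from[first], to = table$to[first],
    rate = as.numeric(rate[match(key[first], rownames(rate)), 1]),
    d_av = NA_real_
  )
  out$d_av <- as.numeric(wdisp[match(key[first], rownames(wdisp)), 1]) / out$rate
  out[order(out$from, out$to), , drop = FALSE]
}
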