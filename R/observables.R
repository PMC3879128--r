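# Biologically relevant quantities: engaged-motor statistics, velocity,
# run length, the exact step-size distribution, and load sweeps.

#' Expected number of engaged motors
#'
#' `E[m] = sum_i M(sigma_i) P_i` where `M` counts the motors in a
#' configuration; the empty state contributes zero.
#'
#' @param P Probability vector over the full space (length N) or over the
#'   non-empty states (length N-1, e.g. a quasi-stationary distribution).
#' @param space The `state_space`.
#' @return Mean engaged-motor count.
#' @export
expected_engaged <- function(P, space) {
  M <- space$engaged
  if (length(P) == space$N) sum(M * P)
  else if (length(P) == space$N - 1L) sum(M[-space$N] * P)
  else stop("P length matches neither N nor N-1")
}

# recycle a non-empty-states vector to full length
.full_vector <- function(P, space) {
  if (length(P) == space$N) P
  else if (length(P) == space$N - 1L) c(P, 0)
  else stop("P length matches neither N nor N-1")
}

#' Mean cargo velocity
#'
#' `v = sum over events of d * lambda * P(from)`, including
#' self-transition classes (a lone stepping motor advances the cargo by a
#' full lattice period without changing its relative configuration).
#'
#' @param P Probability vector (length N or N-1).
#' @param table Event table from [transition_table()].
#' @param space The `state_space`.
#' @return Velocity in nm/s.
#' @export
mean_velocity <- function(P, table, space) {
  Pf <- .full_vector(P, space)
  sum(table$rate * table$displacement * Pf[table$from])
}

#' Average run length
#'
#' Expected distance traveled by the cargo before all motors detach.
#' Computed in closed form as the time integral of the mean velocity:
#' with expected state occupancy times `tau = -Q^{-1} P0`, the run length
#' is `sum over events of d * lambda * tau(from)`.
#'
#' @param P0 Initial probability vector (length N, typically
#'   [initial_distribution()]).
#' @param G The `generator`.
#' @param table Event table from [transition_table()].
#' @return Run length in nm.
#' @export
average_run_length <- function(P0, G, table) {
  N <- G$N
  tau <- as.numeric(Matrix::solve(G$Q, -P0[-N]))
  if (any(tau < -1e-9)) stop("negative occupancy time; Q is not a proper substochastic restriction")
  sum(table$rate * table$displacement * tau[table$from])
}

#' Exact step-size distribution
#'
#' Probability of each distinct nonzero displacement of the cargo
#' equilibrium position per transition event. Event weights are
#' `rate * P(from)`; displacements are grouped within 1e-6 nm, the
#' zero-displacement class (e.g. slack attachments) is excluded from the
#' support, and the remainder is normalized. Each support point carries an
#' attribution over the transition kinds and configuration pairs that
#' produce it — this is how displacements beyond one lattice period are
#' traced to rearguard detachments.
#'
#' @param P Probability vector (length N or N-1, e.g. quasi-stationary).
#' @param table Event table from [transition_table()].
#' @param space The `state_space`.
#' @param tol Grouping tolerance in nm.
#' @return Object of class `step_size_distribution`: list with `support`
#'   (data frame: `length_nm`, `probability`, `rate_weight`,
#'   `dominant_mechanism`) and `attribution` (data frame per contributing
#'   `(length_nm, kind, rearguard, from, to)` tuple with its weight share).
#' @export
step_size_distribution <- function(P, table, space, tol = 1e-6) {
  Pf <- .full_vector(P, space)
  w <- table$rate * Pf[table$from]
  keep <- abs(table$displacement) > tol / 2 & w > 0
  if (!any(keep)) stop("empty step-size support")
  tb <- table[keep, , drop = FALSE]
  w <- w[keep]
  ki <- as.character(round(tb$displacement / tol))
  mu <- rowsum(w, ki, reorder = FALSE)
  lens <- as.numeric(rownames(mu)) * tol
  prob <- mu[, 1] / sum(mu[, 1])
  o <- order(lens)
  attribution <- stats::aggregate(
    list(weight = w),
    by = list(key = ki, kind = tb$kind, rearguard = tb$rearguard,
              from = tb$from, to = tb$to),
    FUN = sum
  )
  attribution$length_nm <- as.numeric(attribution$key) * tol
  attribution$share <- attribution$weight / mu[match(attribution$key, rownames(mu)), 1]
  attribution$key <- NULL
  dominant <- vapply(rownames(mu), function(k) {
    sub_i <- ki == k
    agg <- tapply(w[sub_i], paste0(tb$kind[sub_i],
                                   ifelse(tb$rearguard[sub_i], " (rearguard)", "")), sum)
    names(agg)[which.max(agg)]
  }, "")
  support <- data.frame(length_nm = lens[o], probability = as.numeric(prob)[o],
                        rate_weight = as.numeric(mu[, 1])[o],
                        dominant_mechanism = dominant[o],
                        stringsAsFactors = FALSE)
  structure(list(support = support,
                 attribution = attribution[order(attribution$length_nm), ]),
            class = "step_size_distribution")
}

#' @export
print.step_size_distribution <- function(x, ...) {
  cat("exact step-size distribution (nonzero cargo displacements):\n")
  print(x$support, row.names = FALSE)
  invisible(x)
}

#' Full exact pipeline for one parameter set
#'
#' Convenience wrapper: extent bound, state space, event table, generator,
#' initial distribution, and quasi-stationary distribution.
#'
#' @param p A `motor_params` object.
#' @return List with `params`, `n`, `space`, `table`, `G`, `P0`, `qsd`.
#' @export
build_model <- function(p) {
  n <- max_extent(p)
  space <- enumerate_states(p$m_bar, as.integer(n))
  table <- transition_table(space, p)
  G <- build_generator(space, table)
  P0 <- initial_distribution(G, space)
  qsd <- quasi_stationary(G, table, space)
  list(params = p, n = as.integer(n), truncated = isTRUE(attr(n, "truncated")),
       space = space, table = table, G = G, P0 = P0, qsd = qsd)
}

#' Run-length and velocity load sweep
#'
#' Rebuilds the rates and the generator at every load (the equilibrium and
#' every force-dependent rate change with `F_load`) and evaluates the run
#' length from the reference initialization plus steady-state velocity and
#' engaged-motor statistics from the quasi-stationary distribution.
#'
#' @param loads Numeric vector of loads in nN.
#' @param p A `motor_params` object (its `F_load` is overridden per point).
#' @return Data frame with `load_nN`, `load_pN`, `runlength_nm`,
#'   `velocity_nm_s`, `mean_engaged`.
#' @export
run_length_curve <- function(loads, p) {
  rows <- lapply(loads, function(f) {
    pf <- p
    pf$F_load <- f
    mod <- build_model(pf)
    data.frame(
      load_nN = f,
      load_pN = f * 1e3,
      runlength_nm = average_run_length(mod$P0, mod$G, mod$table),
      velocity_nm_s = mean_velocity(mod$qsd$pi, mod$table, mod$space),
      mean_engaged = expected_engaged(mod$qsd$pi, mod$space)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
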