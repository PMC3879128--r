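# Linkage force law, cargo force balance, equilibrium displacements, and
# the truncated-Gaussian thermal density of the cargo position.

#' Elastic force of a motor-cargo linkage
#'
#' The linkage is a Hookean spring of stiffness `k_el` with rest length
#' `l0` that offers no resistance when shorter than `l0`:
#' `F(l) = k_el*(l - l0)` for `l >= l0`, `0` for `|l| < l0`, and
#' `k_el*(l + l0)` for `l <= -l0`. Continuous, odd, non-decreasing.
#'
#' @param l Signed extension (nm); vectorized.
#' @param p A `motor_params` object.
#' @return Force in nN.
#' @export
linkage_force <- function(l, p) {
  ifelse(l >= p$l0, p$k_el * (l - p$l0),
         ifelse(l <= -p$l0, p$k_el * (l + p$l0), 0))
}

#' Load on a motor from the cargo
#'
#' Force the cargo exerts on a motor at lattice position `a_k` when the
#' cargo sits at `x`. Positive when it opposes the motor's forward motion
#' (motor ahead of the cargo, taut linkage); negative when it assists.
#'
#' @param a_k Motor position, nm; vectorized.
#' @param x Cargo position, nm.
#' @param p A `motor_params` object.
#' @return Force on the motor in nN.
#' @export
motor_load <- function(a_k, x, p) {
  linkage_force(a_k - x, p)
}

#' Cargo mechanical equilibrium
#'
#' Solves the force balance `sum_k z_k * F_spring_k(x) = F_load` for the
#' cargo position. The net spring force is piecewise linear and
#' non-increasing in `x` with breakpoints at `a_k +/- l0`, so the root is
#' found exactly by scanning breakpoints and inverting the active linear
#' piece. When the balance holds on a whole interval (only possible if the
#' required net spring force is exactly zero) the midpoint is returned and
#' flagged.
#'
#' @param Z A non-empty `abs_config`.
#' @param p A `motor_params` object.
#' @return List with `x_eq` (nm), `motor_force` (nN, the load on a motor at
#'   each occupied site, positive = opposing), `flat_interval` (logical),
#'   and `residual` (net-force residual in nN).
#' @export
cargo_equilibrium <- function(Z, p) {
  if (length(Z$sites) == 0L) stop("cargo equilibrium undefined for the empty configuration")
  a <- Z$sites * p$d_s
  z <- Z$counts
  # net forward spring force on the cargo at position x
  G <- function(x) sum(z * linkage_force(a - x, p))
  bp <- sort(unique(c(a - p$l0, a + p$l0)))
  gb <- vapply(bp, G, 0)
  target <- p$F_load
  ktot <- p$k_el * sum(z)
  flat <- FALSE
  if (target > gb[1]) {
    # root left of all breakpoints: every spring taut pulling forward
    x_eq <- bp[1] - (target - gb[1]) / ktot
  } else if (target < gb[length(gb)]) {
    # root right of all breakpoints: every spring taut pulling backward
    x_eq <- bp[length(bp)] + (gb[length(gb)] - target) / ktot
  } else {
    i <- findInterval(-target, -gb)           # last index with gb[i] >= target
    if (gb[i] == target) {
      j0 <- which(gb == target)[1]
      if (j0 < i) {
        # zero-slope piece held exactly at the target level
        x_eq <- (bp[j0] + bp[i]) / 2
        flat <- TRUE
      } else {
        x_eq <- bp[i]
      }
    } else {
      # gb[i] > target > gb[i+1]: invert the active linear piece
      g1 <- gb[i]; g2 <- gb[i + 1]
      x_eq <- bp[i] + (g1 - target) * (bp[i + 1] - bp[i]) / (g1 - g2)
    }
  }
  list(x_eq = x_eq,
       motor_force = motor_load(a, x_eq, p),
       flat_interval = flat,
       residual = G(x_eq) - target)
}

#' Equilibrium displacement between two absolute configurations
#'
#' `d(Z2, Z) = x_eq(Z2) - x_eq(Z)`. Transitions into the empty (cargo
#' lost) configuration carry zero displacement: the run terminates through
#' the absorbing state rather than through a final jump.
#'
#' @param Z,Z2 `abs_config` objects (before and after).
#' @param p A `motor_params` object.
#' @return Displacement in nm; attribute `lost = TRUE` if either
#'   configuration is empty.
#' @export
displacement <- function(Z, Z2, p) {
  if (length(Z$sites) == 0L || length(Z2$sites) == 0L) {
    return(structure(0, lost = TRUE))
  }
  cargo_equilibrium(Z2, p)$x_eq - cargo_equilibrium(Z, p)$x_eq
}

#' Thermal density of the cargo position
#'
#' Gaussian with standard deviation `sigma_th`, truncated to
#' `[-3*sigma_th, 3*sigma_th]` and renormalized; zero outside.
#'
#' @param x Offset from the equilibrium position, nm; vectorized.
#' @param p A `motor_params` object with `sigma_th > 0`.
#' @return Density in 1/nm.
#' @export
thermal_density <- function(x, p) {
  s <- p$sigma_th
  if (s <= 0) stop("thermal_density requires sigma_th > 0; use the point-mass path")
  z <- 2 * stats::pnorm(3) - 1
  ifelse(abs(x) <= 3 * s, stats::dnorm(x, 0, s) / z, 0)
}
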