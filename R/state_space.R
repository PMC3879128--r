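# Absolute and relative configurations, the extent bound, and enumeration
# of the finite relative-configuration space.

#' Absolute configuration on the microtubule lattice
#'
#' Occupancy of integer lattice sites: site `k` sits at `a_k = k * d_s`.
#' The empty configuration (no engaged motor, cargo lost) is allowed.
#'
#' @param sites Integer vector of occupied site indices (any integers).
#' @param counts Integer vector of motor counts per site (all >= 1).
#' @return An object of class `abs_config` with sorted `sites` and `counts`.
#' @examples
#' abs_config(c(0, 3, 6), c(1, 2, 1))
#' @export
abs_config <- function(sites = integer(0), counts = integer(0)) {
  if (length(sites) != length(counts)) stop("sites and counts differ in length")
  sites <- as.integer(sites); counts <- as.integer(counts)
  if (any(counts < 1)) stop("all occupancy counts must be >= 1")
  if (anyDuplicated(sites)) stop("duplicate site indices")
  o <- order(sites)
  structure(list(sites = sites[o], counts = counts[o]), class = "abs_config")
}

#' @export
print.abs_config <- function(x, ...) {
  if (length(x$sites) == 0L) {
    cat("<empty absolute configuration>\n")
  } else {
    cat(sprintf("absolute configuration: %s\n",
                paste(sprintf("site %d: %d", x$sites, x$counts), collapse = ", ")))
  }
  invisible(x)
}

#' Shift an absolute configuration along the lattice
#'
#' @param Z An `abs_config`.
#' @param alpha Integer number of sites to shift by.
#' @return The shifted `abs_config`.
#' @export
shift_config <- function(Z, alpha) {
  abs_config(Z$sites + as.integer(alpha), Z$counts)
}

#' Render a relative configuration as a string
#'
#' A relative configuration is an integer vector of per-site motor counts
#' starting at the rearguard site; its string form writes `M` per motor and
#' `|` between consecutive sites, e.g. `c(1, 0, 2)` is `"M||MM"`.
#'
#' @param sigma Integer vector of counts (possibly empty).
#' @return A single string; the empty configuration renders as `""`.
#' @export
render_config <- function(sigma) {
  if (length(sigma) == 0L) return("")
  paste(vapply(sigma, function(k) strrep("M", k), ""), collapse = "|")
}

#' Parse a relative-configuration string
#'
#' Inverse of [render_config()].
#'
#' @param s A string of `M` and `|` symbols; `""` is the empty configuration.
#' @return Integer vector of counts.
#' @export
parse_config <- function(s) {
  if (!is.character(s) || length(s) != 1L) stop("expected a single string")
  if (identical(s, "")) return(integer(0))
  if (grepl("[^M|]", s)) stop("configuration strings contain only 'M' and '|'")
  sigma <- nchar(strsplit(s, "|", fixed = TRUE)[[1]])
  # trailing separators denote trailing empty sites, which are not allowed
  n_sep <- nchar(gsub("M", "", s, fixed = TRUE))
  if (n_sep >= length(sigma)) sigma <- c(sigma, rep(0L, n_sep - length(sigma) + 1L))
  sigma <- as.integer(sigma)
  if (sigma[1] < 1L || sigma[length(sigma)] < 1L) {
    stop("rearguard and vanguard sites must be occupied")
  }
  sigma
}

#' Maximum extent of a relative configuration
#'
#' Upper bound, in lattice sites, on the distance between the rearguard and
#' vanguard motors that the dynamics can ever produce when started inside
#' the bound. It follows from the stall condition: a configuration can only
#' spread while the vanguard motor is below stall, which caps the total
#' elastic stretch at `m_bar * F_s - F_load`; slack linkages contribute up
#' to `2*l0` of unstretched separation, and attachment near a trailing
#' cargo up to `F_load/k_el + 2*l0`. Thermal fluctuation of the cargo lets
#' a motor step while its mean load is up to `3*sigma_th*k_el` above
#' stall; since every assisting motor's force is bounded by the
#' vanguard's, the allowance is `3*sigma_th` per motor. Both branches
#' carry the slack and thermal allowances.
#'
#' @param p A `motor_params` object.
#' @return Integer site count `n` (>= 1), with attribute `truncated = TRUE`
#'   when an `n_cap` below the theoretical bound was applied.
#' @examples
#' max_extent(motor_params(m_bar = 2, l0 = 0, sigma_th = 0))  # 6
#' @export
max_extent <- function(p) {
  validate_params(p)
  slack <- 2 * p$l0 / p$d_s + 3 * p$m_bar * p$sigma_th / p$d_s
  n_stall <- ceiling((p$m_bar * p$F_s - p$F_load) / (p$k_el * p$d_s) + slack) + 1
  n_attach <- ceiling(p$F_load / (p$k_el * p$d_s) + slack) + 1
  n <- as.integer(max(n_stall, n_attach))
  if (n < 1L) stop("extent bound is non-positive; check parameters")
  truncated <- FALSE
  if (!is.null(p$n_cap) && p$n_cap < n) {
    n <- p$n_cap
    truncated <- TRUE
  }
  structure(n, truncated = truncated)
}

#' Number of relative configurations
#'
#' Closed-form count of relative configurations of up to `m_bar`
#' indistinguishable motors whose extent is at most `n` sites, plus the
#' empty (cargo-lost) configuration:
#' `N = 1 + sum_{m=1..m_bar} choose(n + m - 2, m - 1)`.
#'
#' @param m_bar Ensemble size (>= 1).
#' @param n Maximum extent in sites (>= 1).
#' @return The state count `N` as a double (exact for all practical sizes).
#' @examples
#' count_states(2, 3)  # 5
#' @export
count_states <- function(m_bar, n) {
  stopifnot(m_bar >= 1, n >= 1)
  m <- seq_len(m_bar)
  1 + sum(choose(n + m - 2, m - 1))
}

#' Enumerate the relative-configuration space
#'
#' Generates every relative configuration with 1..`m_bar` motors, rearguard
#' and vanguard sites occupied, and extent at most `n` sites, plus the
#' empty configuration which by convention is last (index `N`). The order
#' is graded: by motor count, then by extent, then lexicographically by the
#' occupancy vector, so generator matrices are bit-reproducible.
#'
#' @param m_bar Ensemble size.
#' @param n Maximum extent in sites.
#' @param max_states Memory guard; enumeration refuses to build more states
#'   than this (suggesting `n_cap`).
#' @return An object of class `state_space`: list with `configs` (list of
#'   integer count vectors; the last is `integer(0)`), `strings`, `m_bar`,
#'   `n`, `N`, `engaged` (motor count per state), and `index` (fast
#'   string-to-index lookup).
#' @export
enumerate_states <- function(m_bar, n, max_states = 5e6) {
  m_bar <- as.integer(m_bar); n <- as.integer(n)
  N <- count_states(m_bar, n)
  if (N > max_states) {
    stop(errorCondition(
      sprintf("state space has %.3g states (> %g); set n_cap to truncate", N, max_states),
      class = c("motorensemble_budget_exceeded", "error")
    ))
  }
  configs <- vector("list", N)
  i <- 0L
  for (m in seq_len(m_bar)) {
    spans <- if (m == 1L) 1L else seq_len(n)
    for (span in spans) {
      for (cfg in .compositions_span(m, span)) {
        i <- i + 1L
        configs[[i]] <- cfg
      }
    }
  }
  configs[[N]] <- integer(0)
  stopifnot(i == N - 1)
  strings <- vapply(configs, render_config, "")
  index <- new.env(parent = emptyenv())
  # environments cannot hold a zero-length name; key the empty state as ".empty"
  keys <- ifelse(strings == "", ".empty", strings)
  for (j in seq_len(N)) assign(keys[j], j, envir = index)
  structure(list(
    configs = configs, strings = strings, m_bar = m_bar, n = n, N = as.integer(N),
    engaged = vapply(configs, sum, 0L), index = index
  ), class = "state_space")
}

# All occupancy vectors of m motors over exactly `span` sites with first and
# last site occupied, in lexicographic order.
.compositions_span <- function(m, span) {
  if (span == 1L) return(list(as.integer(m)))
  if (m < 2L) return(list())
  out <- list()
  rec <- function(prefix, left, pos) {
    if (pos == span) {
      if (left >= 1L) out[[length(out) + 1L]] <<- as.integer(c(prefix, left))
      return(invisible())
    }
    lo <- if (pos == 1L) 1L else 0L
    # keep at least one motor for the vanguard site
    for (k in lo:(left - 1L)) rec(c(prefix, k), left - k, pos + 1L)
  }
  rec(integer(0), m, 1L)
  out
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("state space: m_bar = %d, extent n = %d, N = %d states (incl. empty)\n",
              x$m_bar, x$n, x$N))
  invisible(x)
}

#' @export
as.data.frame.state_space <- function(x, ...) {
  extent <- vapply(x$configs, length, 0L)
  data.frame(index = seq_len(x$N), configuration = x$strings,
             motors = x$engaged, extent_sites = extent,
             stringsAsFactors = FALSE)
}

#' Look up the index of a relative configuration
#'
#' @param space A `state_space`.
#' @param sigma Integer count vector or configuration string.
#' @return The state index, or an error if absent.
#' @export
state_index <- function(space, sigma) {
  s <- if (is.character(sigma)) sigma else render_config(sigma)
  if (s == "") s <- ".empty"
  i <- get0(s, envir = space$index, inherits = FALSE)
  if (is.null(i)) stop(sprintf("configuration '%s' not in state space", s))
  i
}

#' Project an absolute configuration to its relative configuration
#'
#' Drops the absolute position: the occupancy list is read from the
#' rearguard (lowest occupied) site. Translation invariant.
#'
#' @param Z An `abs_config`.
#' @return Integer count vector (empty for the empty configuration).
#' @examples
#' project(abs_config(c(0, 3, 6), c(1, 2, 1)))  # "M||MM||M"
#' @export
project <- function(Z) {
  if (length(Z$sites) == 0L) return(integer(0))
  span <- Z$sites[length(Z$sites)] - Z$sites[1] + 1L
  sigma <- integer(span)
  sigma[Z$sites - Z$sites[1] + 1L] <- Z$counts
  sigma
}

#' Canonical absolute representative of a relative configuration
#'
#' Places the rearguard motor at lattice site 0, so that
#' `project(canonical_representative(sigma))` recovers `sigma`.
#'
#' @param sigma Non-empty integer count vector (or string).
#' @return An `abs_config`.
#' @export
canonical_representative <- function(sigma) {
  if (is.character(sigma)) sigma <- parse_config(sigma)
  if (length(sigma) == 0L) stop("the empty configuration has no representative")
  occ <- which(sigma > 0L)
  abs_config(occ - 1L, sigma[occ])
}
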