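# Generator assembly, master-equation propagation, and the
# quasi-stationary (conditional steady-state) distribution.

#' Build the master-equation generator
#'
#' Assembles the sparse rate matrix `A` of the projected chain in the
#' column convention `dP/dt = A P`: `A[j, i]` is the rate from state `i`
#' to state `j`, and each diagonal balances its column so every column
#' sums to zero. The empty (cargo-lost) state is absorbing: its column is
#' zero. Self-transition events in the table cancel and do not enter `A`.
#'
#' @param space A `state_space`.
#' @param table An event table from [transition_table()].
#' @return An object of class `generator`: list with `A` (N x N sparse
#'   Matrix), `Q` (restriction of `A` to the non-empty states,
#'   substochastic), `space`, and `N`.
#' @export
build_generator <- function(space, table) {
  N <- space$N
  if (any(table$rate < 0)) stop("negative transition rate")
  off <- table[table$from != table$to, , drop = FALSE]
  A <- Matrix::sparseMatrix(i = off$to, j = off$from, x = off$rate,
                            dims = c(N, N))
  outflow <- numeric(N)
  agg <- rowsum(off$rate, off$from)
  outflow[as.integer(rownames(agg))] <- agg[, 1]
  A <- A - Matrix::Diagonal(N, outflow)
  structure(list(A = A, Q = A[-N, -N, drop = FALSE], space = space, N = N),
            class = "generator")
}

#' @export
print.generator <- function(x, ...) {
  cat(sprintf("master-equation generator: %d states, %d non-zero rates\n",
              x$N, Matrix::nnzero(x$A)))
  invisible(x)
}

# action of expm(M * t) on a vector: dense matrix exponential for moderate
# sizes, uniformization (stable for generator/substochastic matrices) above
.expm_action <- function(M, v, t, dense_limit = 2000L) {
  n <- nrow(M)
  if (t == 0) return(v)
  if (n <= dense_limit) {
    return(as.numeric(Matrix::expm(M * t) %*% v))
  }
  lambda <- max(-Matrix::diag(M)) * (1 + 1e-12)
  if (lambda <= 0) return(v)
  lt <- lambda * t
  kmax <- stats::qpois(1e-14, lt, lower.tail = FALSE) + 10L
  u <- v
  out <- stats::dpois(0, lt) * u
  for (k in seq_len(kmax)) {
    u <- u + as.numeric(M %*% u) / lambda
    w <- stats::dpois(k, lt)
    out <- out + w * u
  }
  pmax(out, 0)
}

#' Propagate a probability vector
#'
#' Solves `P(t0 + dt) = exp(A dt) P(t0)` for the projected chain.
#' Probability is conserved (columns of `A` sum to zero) and the semigroup
#' property holds to solver precision.
#'
#' @param P0 Probability vector over the state order of `G` (length N).
#' @param dt Time increment, s (>= 0).
#' @param G A `generator` (or a square generator Matrix).
#' @return The propagated probability vector.
#' @export
propagate <- function(P0, dt, G) {
  if (dt < 0) stop("dt must be >= 0")
  A <- if (inherits(G, "generator")) G$A else G
  if (length(P0) != nrow(A)) stop("P0 length does not match the generator")
  .expm_action(A, P0, dt)
}

#' Initial distribution: one motor engaged, cargo not yet lost
#'
#' The reference initialization: a single engaged motor one second before
#' time zero, evolved for that second under the loss-free restriction
#' (i.e. conditioned on the cargo surviving to time zero), then
#' renormalized. For `m_bar = 1` this is exactly the point mass on `"M"`.
#'
#' @param G A `generator`.
#' @param space The `state_space` of `G`.
#' @param warm_time Conditioning interval in s (default 1).
#' @return Probability vector of length N with zero mass on the empty state.
#' @export
initial_distribution <- function(G, space, warm_time = 1) {
  iM <- state_index(space, "M")
  d0 <- numeric(space$N - 1L)
  d0[iM] <- 1
  Pt <- .expm_action(G$Q, d0, warm_time)
  Pt <- pmax(Pt, 0)
  Pt <- Pt / sum(Pt)
  c(Pt, 0)
}

#' Condition a distribution on the cargo not being lost
#'
#' @param P Probability vector over the full state order (empty state last).
#' @return Vector of length N-1 over the non-empty states, summing to 1.
#' @export
conditional_not_lost <- function(P) {
  N <- length(P)
  surv <- 1 - P[N]
  if (surv <= 0) stop("all probability mass is on the lost-cargo state")
  P[-N] / surv
}

#' States reachable from the single-motor configuration
#'
#' Breadth-first search over the directed transition graph restricted to
#' non-empty states, starting from `"M"`.
#'
#' @param table An event table from [transition_table()].
#' @param space The matching `state_space`.
#' @return Integer vector of reachable state indices (sorted).
#' @export
reachable_states <- function(table, space) {
  N <- space$N
  edges <- table[table$rate > 0 & table$to != N & table$from != table$to, c("from", "to")]
  adj <- split(edges$to, edges$from)
  start <- state_index(space, "M")
  seen <- logical(N - 1L)
  seen[start] <- TRUE
  frontier <- start
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}

#' Quasi-stationary distribution of the surviving chain
#'
#' The conditional distribution over non-empty configurations that the
#' chain approaches when conditioned on the cargo not having been lost.
#' It is the eigenvector of the substochastic restriction `Q` (on the
#' class reachable from `"M"`) for the eigenvalue of largest real part,
#' normalized to a probability vector; unreachable states carry exactly
#' zero mass. A dense eigendecomposition is used for moderate sizes and
#' sparse inverse iteration above that.
#'
#' @param G A `generator`.
#' @param table The event table used to build `G` (for reachability).
#' @param space The matching `state_space`.
#' @param dense_limit Size threshold for the dense eigen route.
#' @return List with `pi` (length N-1 probability vector over non-empty
#'   states), `decay_rate` (absorption rate `-lambda_1`, 1/s), and
#'   `reachable` (indices).
#' @export
quasi_stationary <- function(G, table, space, dense_limit = 1500L) {
  reach <- reachable_states(table, space)
  Qr <- G$Q[reach, reach, drop = FALSE]
  nr <- length(reach)
  if (nr == 1L) {
    v <- 1
    lam <- as.numeric(Qr[1, 1])
  } else if (nr <= dense_limit) {
    es <- eigen(as.matrix(Qr))
    i1 <- which.max(Re(es$values))
    lam <- Re(es$values[i1])
    v <- Re(es$vectors[, i1])
    if (sum(v) < 0) v <- -v
    if (any(v < -1e-8 * max(abs(v)))) {
      stop("leading eigenvector is not sign-definite; eigen solve failed")
    }
    v <- pmax(v, 0)
  } else {
    # inverse iteration: the quasi-stationary eigenvalue is the one of
    # smallest magnitude for an absorbing substochastic restriction
    set_v <- rep(1 / nr, nr)
    lu <- Matrix::lu(Qr)
    v <- set_v
    for (it in seq_len(200L)) {
      w <- as.numeric(Matrix::solve(lu, v))
      w <- w / sum(abs(w))
      if (sum(w) < 0) w <- -w
      delta <- sum(abs(w - v))
      v <- w
      if (delta < 1e-14) break
    }
    if (any(v < -1e-8)) stop("inverse iteration failed to produce a nonnegative vector")
    v <- pmax(v, 0)
    lam <- sum(v * as.numeric(Qr %*% v)) / sum(v * v)
  }
  v <- v / sum(v)
  pi_full <- numeric(space$N - 1L)
  pi_full[reach] <- v
  list(pi = pi_full, decay_rate = -lam, reachable = reach)
}

#' Total-variation distance between two distributions
#'
#' @param p,q Probability vectors of equal length.
#' @return `sum(abs(p - q)) / 2`.
#' @export
tv_distance <- function(p, q) {
  if (length(p) != length(q)) stop("length mismatch")
  sum(abs(p - q)) / 2
}
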