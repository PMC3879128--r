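test_that("engaged-motor expectation counts symbols under any distribution", {
  sp <- enumerate_states(3, 6)
  P <- numeric(sp$N); P[state_index(sp, "M|MM")] <- 1
  expect_equal(expected_engaged(P, sp), 3)
  P2 <- numeric(sp$N); P2[sp$N] <- 1
  expect_equal(expected_engaged(P2, sp), 0)
  set.seed(1)
  for (i in 1:20) {
    P <- stats::runif(sp$N); P <- P / sum(P)
    e <- expected_engaged(P, sp)
    expect_gte(e, 0); expect_lte(e, 3)
  }
})

test_that("a lone unloaded motor moves at the full stepping speed", {
  mod <- model_m1()
  v <- mean_velocity(c(1, 0), mod$table, mod$space)
  expect_equal(v, 8 * 100.96154, tolerance = 1e-6)
  expect_equal(mean_velocity(c(0, 1), mod$table, mod$space), 0)
})

test_that("noiseless single-motor run length equals the processivity at every load", {
  for (f_pN in 0:5) {
    p <- motor_params(m_bar = 1, sigma_th = 0, F_load = f_pN * 1e-3)
    mod <- build_model(p)
    rl <- average_run_length(mod$P0, mod$G, mod$table)
    expect_equal(rl, processivity(p$F_load, p), tolerance = 1e-6,
                 info = sprintf("load %d pN", f_pN))
  }
})

test_that("the linear-solve run length matches independent eigen-mode time integration", {
  mod <- model_m2f0()
  rl <- average_run_length(mod$P0, mod$G, mod$table)
  # independent route: v(t) integrated analytically through the eigenmodes
  # of the substochastic restriction
  Q <- as.matrix(mod$G$Q)
  es <- eigen(Q)
  P0r <- mod$P0[-mod$space$N]
  coef <- solve(es$vectors, P0r)
  tau_modes <- es$vectors %*% (coef / (-es$values))   # integral of exp(Q t) P0
  tau <- Re(tau_modes)
  c_from <- rowsum(mod$table$rate * mod$table$displacement, mod$table$from)
  rl_eig <- sum(c_from[, 1] * tau[as.integer(rownames(c_from))])
  expect_equal(rl, rl_eig, tolerance = 1e-3)
})

test_that("step-size distribution is a probability law on nonzero displacements", {
  mod <- model_m2()
  dist <- step_size_distribution(mod$qsd$pi, mod$table, mod$space)
  expect_equal(sum(dist$support$probability), 1, tolerance = 1e-12)
  expect_true(all(dist$support$probability >= 0))
  expect_true(all(abs(dist$support$length_nm) > 1e-7))
  # attribution shares sum to one within each step size
  shares <- rowsum(dist$attribution$share, as.character(dist$attribution$length_nm))
  expect_true(all(abs(shares - 1) < 1e-9))
})

test_that("two-motor step statistics show full and shared-load steps as the top modes", {
  mod <- model_m2()   # reference sub-stall load, defaults otherwise
  dist <- step_size_distribution(mod$qsd$pi, mod$table, mod$space)
  top2 <- dist$support$length_nm[order(-dist$support$probability)][1:2]
  expect_setequal(round(top2, 6), c(8, 4))
})

test_that("every step beyond one lattice period stems from rearguard detachment", {
  # under load the equilibrium is unique and only the loss of a taut
  # opposing rearguard can advance the cargo beyond one period
  mod <- model_m2()
  dist <- step_size_distribution(mod$qsd$pi, mod$table, mod$space)
  big <- dist$attribution[dist$attribution$length_nm > mod$params$d_s + 1e-9, ]
  expect_gt(nrow(big), 0)
  expect_true(all(big$kind == "detach"))
  expect_true(all(big$rearguard))
})

test_that("run-length curves decrease with load for a single motor", {
  p <- motor_params(m_bar = 1, sigma_th = 0)
  curve <- run_length_curve(seq(0, 0.005, by = 0.001), p)
  expect_true(all(diff(curve$runlength_nm) < 0))
  expect_equal(curve$runlength_nm[1], processivity(0, p), tolerance = 1e-6)
  expect_equal(curve$load_pN, 0:5)
})

test_that("exact velocity matches the Gillespie displacement slope under survival", {
  mod <- model_m2f0()
  v_ex <- mean_velocity(mod$qsd$pi, mod$table, mod$space)
  b5 <- simulate_batch(4000, 5, mod$table, mod$space, seed = 31, init = mod$P0)
  b10 <- simulate_batch(4000, 10, mod$table, mod$space, seed = 32, init = mod$P0)
  x5 <- b5$runlength_nm[!b5$lost]
  x10 <- b10$runlength_nm[!b10$lost]
  slope <- (mean(x10) - mean(x5)) / 5
  se <- sqrt(stats::var(x10) / length(x10) + stats::var(x5) / length(x5)) / 5
  expect_lt(abs(slope - v_ex), 3 * se)
})

test_that("exact step-size law matches the empirical event histogram", {
  mod <- model_m2()
  qsd_full <- c(mod$qsd$pi, 0)
  b <- simulate_batch(3000, 2, mod$table, mod$space, seed = 5,
                      init = qsd_full, record_steps = TRUE)
  counts <- attr(b, "event_counts")
  expect_gt(sum(counts), 20000)
  keep <- abs(mod$table$displacement) > 5e-7
  l_key <- as.character(round(mod$table$displacement[keep] / 1e-6))
  emp <- rowsum(counts[keep], l_key)
  emp_p <- emp[, 1] / sum(emp[, 1])
  dist <- step_size_distribution(mod$qsd$pi, mod$table, mod$space)
  ex_key <- as.character(round(dist$support$length_nm / 1e-6))
  ex_p <- dist$support$probability[match(rownames(emp), ex_key)]
  expect_true(!anyNA(ex_p))
  tv <- (sum(abs(emp_p - ex_p)) + (1 - sum(ex_p))) / 2
  expect_lt(tv, 0.03)
})
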