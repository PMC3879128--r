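p_def <- motor_params()

test_that("binding efficiency follows the quadratic stall law", {
  expect_equal(binding_efficiency(-1e-3, p_def), 1)
  expect_equal(binding_efficiency(p_def$F_s / 2, p_def), 0.25)
  expect_equal(binding_efficiency(p_def$F_s, p_def), 0)
  expect_equal(binding_efficiency(1, p_def), 0)
})

test_that("stepping rate matches the Michaelis-Menten evaluation and stalls", {
  # kM(0) = (105 + 55) / 2e6 = 8e-5 M; rate = 105 * 2e-3 / 2.08e-3
  expect_equal(step_rate_at_force(0, p_def), 100.96154, tolerance = 1e-6)
  expect_equal(step_rate_at_force(p_def$F_s, p_def), 0)
  F <- seq(0, p_def$F_s, length.out = 200)
  expect_true(all(diff(step_rate_at_force(F, p_def)) <= 1e-12))
})

test_that("processivity evaluates the published load dependence", {
  expect_equal(processivity(0, p_def), 854.6616, tolerance = 0.5 / 854)
  F <- seq(0, 0.02, length.out = 100)
  L <- processivity(F, p_def)
  expect_true(all(diff(L) < 0))
  expect_lt(processivity(0.2, p_def), 1e-6)
})

test_that("detachment rate ties to the processivity below stall, constant above", {
  expect_equal(detach_rate_at_force(0, p_def), 0.9450434, tolerance = 1e-5)
  expect_equal(detach_rate_at_force(p_def$F_s + 1e-6, p_def), 2)
  expect_equal(detach_rate_at_force(p_def$F_s, p_def), 2)
  F <- seq(0, p_def$F_s - 1e-9, length.out = 50)
  expect_equal(step_rate_at_force(F, p_def) / detach_rate_at_force(F, p_def),
               processivity(F, p_def) / p_def$d_s, tolerance = 1e-12)
})

test_that("site rates reduce to point evaluations without noise and scale with occupancy", {
  p0 <- motor_params(m_bar = 1, sigma_th = 0, F_load = 0.002)
  Z <- abs_config(0, 1)
  # a lone motor bears the full load
  expect_equal(site_step_rate(Z, 0, p0), step_rate_at_force(0.002, p0), tolerance = 1e-12)
  expect_equal(site_detach_rate(Z, 0, p0), detach_rate_at_force(0.002, p0), tolerance = 1e-12)
  p2 <- motor_params(m_bar = 2, sigma_th = 0, F_load = 0.002)
  Z2 <- abs_config(0, 2)
  expect_equal(site_step_rate(Z2, 0, p2), 2 * step_rate_at_force(0.001, p2), tolerance = 1e-12)

  p00 <- motor_params(m_bar = 1, sigma_th = 0)
  expect_equal(site_detach_rate(abs_config(0, 1), 0, p00), 0.9450434, tolerance = 1e-5)
})

test_that("fixed-order quadrature agrees with adaptive integration and the noiseless limit", {
  p <- motor_params(m_bar = 2, F_load = 0.004)
  Z <- abs_config(c(0, 30), c(1, 1))
  eq <- cargo_equilibrium(Z, p)
  for (k in c(0, 30)) {
    r_gl <- site_step_rate(Z, k, p, eq)
    f <- function(x) {
      step_rate_at_force(linkage_force(k * p$d_s - x, p), p) * thermal_density(x - eq$x_eq, p)
    }
    r_ad <- stats::integrate(f, eq$x_eq - 3 * p$sigma_th, eq$x_eq + 3 * p$sigma_th,
                             rel.tol = 1e-12, abs.tol = 0)$value
    expect_equal(r_gl, r_ad, tolerance = 1e-8)
  }
  # vanishing noise recovers the point evaluation
  p_small <- motor_params(m_bar = 2, F_load = 0.004, sigma_th = 1e-7)
  p_zero <- motor_params(m_bar = 2, F_load = 0.004, sigma_th = 0)
  eq_s <- cargo_equilibrium(Z, p_small)
  expect_equal(site_step_rate(Z, 30, p_small, eq_s),
               site_step_rate(Z, 30, p_zero), tolerance = 1e-6)
})

test_that("thermal averaging interpolates across the stall boundary", {
  # a lone motor loaded just below stall: the fluctuating cargo pushes the
  # instantaneous load across F_s, so the detachment rate must lie strictly
  # between the below-stall law and P_back
  p <- motor_params(m_bar = 1, F_load = 0.005)
  Z <- abs_config(0, 1)
  r <- site_detach_rate(Z, 0, p)
  expect_gt(r, detach_rate_at_force(0.005, p))
  expect_lt(r, p$P_back)
})

test_that("attachment spreads the per-motor rate uniformly over admissible sites", {
  # lone engaged motor of two, slack cargo on the motor: sites within +-l0
  p <- motor_params(m_bar = 2, l0 = 20, F_load = 0)
  Z <- abs_config(0, 1)
  ev <- attachment_events(Z, p)
  expect_length(ev, 5)   # sites -2..2 lie within 20 nm of the plateau midpoint
  rates <- vapply(ev, `[[`, 0, "rate")
  expect_equal(sum(rates), (2 - 1) * p$P_att, tolerance = 1e-12)
  expect_true(all(abs(rates - p$P_att / 5) < 1e-12))
  # fully engaged ensemble: no attachment
  expect_length(attachment_events(abs_config(0, 2), p), 0)
})

test_that("elementary transition census and displacement ranges hold", {
  p <- motor_params(m_bar = 2, F_load = 0.001)
  ev <- absolute_transitions(abs_config(0, 1), p)
  kinds <- vapply(ev, `[[`, "", "kind")
  expect_equal(sum(kinds == "step"), 1)
  expect_equal(sum(kinds == "detach"), 1)
  expect_gt(sum(kinds == "attach"), 0)
  expect_gt(sum(vapply(ev, `[[`, 0, "rate")), 0)

  # steps advance the cargo by at most one lattice period
  mod <- model_m2()
  steps <- mod$table[mod$table$kind == "step", ]
  expect_true(all(steps$displacement > -1e-12))
  expect_true(all(steps$displacement <= p$d_s + 1e-9))

  # a taut opposing rearguard that detaches lets the cargo jump forward
  Zop <- abs_config(c(0, 33), c(1, 1))   # opposed pair, both taut
  evd <- absolute_transitions(Zop, p)
  det_rear <- Filter(function(e) e$kind == "detach" && isTRUE(e$rearguard), evd)
  expect_length(det_rear, 1)
  expect_gt(det_rear[[1]]$displacement, p$d_s)
})

test_that("projected rates group events by target class", {
  sp <- model_m2()$space
  p <- model_m2()$params
  # a lone stepping motor maps to its own class with an 8 nm mean displacement
  rr <- relative_rates("M", sp, p)
  self <- rr[rr$to == rr$from & rr$kind == "step", ]
  expect_equal(nrow(self), 1)
  expect_equal(self$displacement, p$d_s, tolerance = 1e-12)

  # either detachment from "M|M" reaches "M": the class rate sums both
  rr2 <- relative_rates("M|M", sp, p)
  toM <- rr2[rr2$to == state_index(sp, "M") & rr2$kind == "detach", ]
  expect_equal(nrow(toM), 2)
  agg <- aggregate_rates(rr2)
  row <- agg[agg$to == state_index(sp, "M"), ]
  expect_equal(row$rate, sum(toM$rate), tolerance = 1e-12)

  # partition of events: class rates sum to the representative's outflow
  ev <- absolute_transitions(canonical_representative(parse_config("M|M")), p)
  expect_equal(sum(rr2$rate), sum(vapply(ev, `[[`, 0, "rate")), tolerance = 1e-12)
})

test_that("rates are independent of the absolute representative", {
  mod <- model_m2()
  p <- mod$params
  set.seed(7)
  picks <- sample(mod$space$N - 1L, 20)
  for (i in picks) {
    Z <- canonical_representative(mod$space$configs[[i]])
    ev0 <- absolute_transitions(Z, p)
    for (alpha in sample(c(-40:-1, 1:40), 2)) {
      evs <- absolute_transitions(shift_config(Z, alpha), p)
      expect_equal(vapply(evs, `[[`, 0, "rate"), vapply(ev0, `[[`, 0, "rate"),
                   tolerance = 1e-12)
      expect_equal(vapply(evs, `[[`, 0, "displacement"),
                   vapply(ev0, `[[`, 0, "displacement"), tolerance = 1e-9)
    }
  }
})

test_that("slack attachments carry zero displacement into self or new classes", {
  mod <- model_m2()
  att <- mod$table[mod$table$kind == "attach" & mod$table$from == mod$table$to, ]
  if (nrow(att) > 0) expect_true(all(abs(att$displacement) < 1e-9))
  expect_true(all(mod$table$rate >= 0))
})
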