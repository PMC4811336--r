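test_that("DAGL activation matches its clamped-calcium fixed point", {
  ps <- ps_default
  expect_identical(dagl_activation_rhs(0, 0, ps), 0)
  expect_identical(dagl_activation_rhs(1, 0.7, ps), -ps$r_p)
  Ca <- 1.8
  phi_ss <- ps$r_k * Ca^ps$n_c / (ps$r_k * Ca^ps$n_c + ps$r_p)
  expect_near(dagl_activation_rhs(phi_ss, Ca, ps), 0)
  # clamped-calcium simulation relaxes onto the analytic fixed point
  out <- deSolve::lsoda(c(phi = 0), seq(0, 10, by = 0.5),
                        function(t, y, p) list(dagl_activation_rhs(y, Ca, ps)),
                        NULL, rtol = 1e-10, atol = 1e-12)
  expect_near(out[nrow(out), "phi"], phi_ss, tol = 1e-6)
})

test_that("DAG / 2-AG bookkeeping balances synthesis and degradation", {
  ps <- ps_default
  d0 <- dag_2ag_rhs(DAG = 0, AG2 = 0.4, phi = 0.5, R_P = 0, ps)
  expect_identical(d0$dDAG, 0)
  expect_near(d0$dAG2, -ps$r_MAGL * 0.4)
  # with DAGK and MAGL off, total mass grows exactly at the production rate
  ps0 <- ps; ps0$r_DAGK <- 0; ps0$r_MAGL <- 0
  d <- dag_2ag_rhs(0.3, 0.2, 0.6, R_P = 0.8, ps0)
  expect_near(d$dDAG + d$dAG2, 0.8)
  # full MAGL block: 2-AG is non-decreasing whenever phi * DAG > 0
  dm <- dag_2ag_rhs(0.3, 5, 0.6, R_P = 0, ps0)
  expect_gt(dm$dAG2, 0)
})

test_that("anandamide has the derived clamped-calcium steady state", {
  ps <- ps_default
  expect_lt(aea_rhs(0.5, 0, ps), 0)
  Ca <- 1.2   # nu_AT * Ca < r_FAAH: finite steady state exists
  stopifnot(ps$nu_AT * Ca < ps$r_FAAH)
  aea_ss <- ps$nu_AT * Ca * ps$K_FAAH / (ps$r_FAAH - ps$nu_AT * Ca)
  expect_near(aea_rhs(aea_ss, Ca, ps), 0)
  out <- deSolve::lsoda(c(a = 0), c(0, 50, 200),
                        function(t, y, p) list(aea_rhs(y, Ca, ps)), NULL,
                        rtol = 1e-10, atol = 1e-12)
  expect_near(out[nrow(out), "a"], aea_ss, tol = 1e-5)
  # saturated degradation: above the capacity there is no finite fixed point
  Ca_hi <- 1.1 * ps$r_FAAH / ps$nu_AT
  for (aea in c(1, 10, 1000)) expect_gt(aea_rhs(aea, Ca_hi, ps), 0)
})

test_that("CB1R three-state kinetics conserve mass and match the fixed point", {
  ps <- ps_default
  z <- cb1r_rhs(0, 0, AG2 = 0, AEA = 0, ps)
  expect_identical(z$dx, 0)
  expect_identical(z$dd, 0)
  expect_identical(z$eCB, 0)
  # partial agonism factor enters the drive
  expect_near(cb1r_rhs(0, 0, 0, AEA = 1, ps)$eCB, ps$A_endo)

  # clamped agonist: analytic simultaneous fixed point of x and d
  E <- 0.15
  a <- ps$alpha_CB1R * E
  x_ss <- a / (a * (1 + ps$gamma_CB1R / ps$epsilon_CB1R) +
                 ps$beta_CB1R + ps$gamma_CB1R)
  d_ss <- ps$gamma_CB1R * x_ss / ps$epsilon_CB1R
  fx <- cb1r_rhs(x_ss, d_ss, E, 0, ps)
  expect_near(fx$dx, 0)
  expect_near(fx$dd, 0)

  # x + d + i = 1 along a full-model trajectory (i recovered as 1 - x - d)
  tr <- short_run()$trajectory
  expect_true(all(tr$x_CB1R >= 0 & tr$d_CB1R >= 0))
  expect_true(all(tr$x_CB1R + tr$d_CB1R <= 1 + 10 * ps_default$rtol))
})

test_that("desensitization grows over the first pairings, post-pre leads pre-post", {
  simA <- short_run()
  d <- simA$trajectory$d_CB1R
  tt <- simA$trajectory$time
  d_s <- stats::approx(tt, d, xout = 1:10)$y
  expect_true(all(diff(d_s) > 0))

  # timing selectivity of the cascade: DAGL activation and the CB1R drive
  # are larger for post-pre than pre-post pairings, and the drive fades for
  # long positive timings where glutamate precedes the depolarization
  ps <- ps_default
  peaks <- function(dt) {
    sim <- run_protocol(ps, build_stdp_protocol(12, dt, 1, delta = ps$delta),
                        settle_time = 2)
    c(phi = max(sim$trajectory$phi_DAGL), x = max(sim$trajectory$x_CB1R))
  }
  p_neg <- peaks(-15); p_pos <- peaks(15); p_far <- peaks(40)
  expect_gt(p_neg[["phi"]], p_pos[["phi"]])
  expect_gt(p_neg[["x"]], p_pos[["x"]])
  expect_gt(p_pos[["x"]], p_far[["x"]])
})
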