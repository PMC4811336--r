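test_that("rapid-buffer factor has the analytic limits", {
  ps <- ps_default
  ps0 <- ps; ps0$B_T <- 1e-300
  expect_near(buffer_factor(c(0, 0.5, 10), ps0), rep(1, 3), tol = 1e-250)
  expect_near(buffer_factor(0, ps), 1 + ps$B_T / ps$K_dB)
  expect_near(buffer_factor(1e9, ps), 1, tol = 1e-6)
  # decreasing in calcium, always >= 1
  x <- seq(0, 20, by = 0.5)
  tf <- buffer_factor(x, ps)
  expect_true(all(diff(tf) < 0) && all(tf >= 1))
})

test_that("CICR fluxes vanish without gradients or calcium", {
  ps <- ps_default
  fl <- cicr_fluxes(Ca = 0.5, Ca_ER = 0.5, IP3 = 0.3, h_IP3R = 0.6, ps)
  expect_identical(fl$J_IP3R, 0)
  expect_identical(fl$J_leak, 0)
  expect_identical(cicr_fluxes(0, 100, 0.3, 0.6, ps)$J_SERCA, 0)
})

test_that("the unstimulated steady state balances the ER fluxes", {
  ss <- rest_state()
  fl <- cicr_fluxes(ss[["Ca"]], ss[["Ca_ER"]], ss[["IP3"]], ss[["h_IP3R"]],
                    ps_default)
  expect_near(fl$J_IP3R - fl$J_SERCA + fl$J_leak, 0, tol = 1e-6)
})

test_that("IP3 turnover reduces to its production term at the origin", {
  ps <- ps_default
  expect_identical(ip3_rhs(Ca = 0, IP3 = 0, G = 0, camkii_act = 0, ps),
                   plc_production(0, 0, 0, ps))
  # doubling the IP-5P rate doubles the linear degradation branch
  ps2 <- ps; ps2$r_5P <- 2 * ps$r_5P
  d1 <- ip3_rhs(0.2, 0.5, 0.1, 0, ps)
  d2 <- ip3_rhs(0.2, 0.5, 0.1, 0, ps2)
  expect_near(d1 - d2, ps$r_5P * 0.5)
})

test_that("cytosol-ER exchange conserves buffered calcium", {
  ps <- ps_default
  # zero influx and extrusion: T_C dC + (1/rho) T_ER dC_ER must vanish
  ps0 <- ps
  ps0$tau_Cab <- 1e12                 # no extrusion
  zero <- list(I_NMDA = 0, I_VSCC = 0, I_TRPV1 = 0)
  for (st in list(c(0.3, 40, 0.4, 0.7), c(1.5, 120, 0.1, 0.5))) {
    d <- calcium_rhs(st[1], st[2], st[3], st[4], zero, ps0)
    lhs <- buffer_factor(st[1], ps0) * d$dCa +
      buffer_factor(st[2], ps0) * d$dCa_ER / ps0$rho_ER
    expect_near(lhs, 0, tol = 1e-8)
  }
})

test_that("inward NMDAR current raises cytosolic calcium", {
  ps <- ps_default
  base <- calcium_rhs(0.2, 50, 0.1, 0.7,
                      list(I_NMDA = 0, I_VSCC = 0, I_TRPV1 = 0), ps)
  inw <- calcium_rhs(0.2, 50, 0.1, 0.7,
                     list(I_NMDA = -5, I_VSCC = 0, I_TRPV1 = 0), ps)
  expect_gt(inw$dCa, base$dCa)
})

test_that("calcium peaks are biphasic and the ER store depletes at 1 Hz", {
  # 100 post-pre pairings: amplitude envelope rises over the first pairings
  # then decays to a roughly constant level; the ER store only depletes
  # while the pairing protocol lasts
  sim <- run_protocol(ps_default,
                      build_stdp_protocol(100, -15, 1,
                                          delta = ps_default$delta),
                      settle_time = 10)
  pk <- sim$peaks$Ca_peak
  i_max <- which.max(pk)
  expect_gt(i_max, 3)
  expect_lt(i_max, 35)
  expect_gt(max(pk), 2 * pk[1])                 # rising phase
  expect_lt(mean(pk[85:100]), 0.6 * max(pk))    # decayed plateau
  late_sd <- stats::sd(pk[85:100])
  expect_lt(late_sd, 0.15 * max(pk))            # roughly constant amplitude

  tr <- sim$trajectory
  er <- tr$Ca_ER[tr$time < 100]
  tt <- tr$time[tr$time < 100]
  er_s <- stats::approx(tt, er, xout = seq(2, 98, by = 4))$y
  expect_true(all(diff(er_s) < 1e-3))           # monotone depletion
  expect_lt(min(er_s), 0.5 * er_s[1])
})
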