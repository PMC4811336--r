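test_that("the resting state is stationary with unit weights", {
  ps <- ps_default
  ss <- rest_state()
  expect_lt(abs(ss[["V"]] - ps$V_L), 3)          # near the leak potential
  expect_lt(abs(ss[["Ca"]] - ps$Ca_b), 0.06)     # near basal calcium
  expect_gt(ss[["Ca_ER"]], ss[["Ca"]])           # loaded store
  expect_near(ss[["W_pre"]], 1, tol = 1e-6)

  # integrating 100 s without stimulation moves nothing by more than 0.1 %
  sim <- run_protocol(ps, NULL, settle_time = 100)
  end <- as.numeric(sim$trajectory[nrow(sim$trajectory), -1])
  rel <- abs(end - ss) / pmax(abs(ss), 1e-3)
  expect_lt(max(rel), 1e-3)
  expect_near(sim$W_total, 1)
})

test_that("compiled and reference right-hand sides agree at random states", {
  ps <- ps_default
  pr <- build_stdp_protocol(3, -15, 1, delta = ps$delta)
  parms <- ecbstdp:::.pack_parms(ps, pr)
  set.seed(42)
  y0 <- ecbstdp:::.initial_guess(ps)
  for (k in 1:5) {
    y <- y0
    y["V"] <- runif(1, -80, 10)
    y["Ca"] <- runif(1, 0.05, 4)
    y["Ca_ER"] <- runif(1, 1, 300)
    y["IP3"] <- runif(1, 0, 1)
    y["DAG"] <- runif(1, 0, 0.5); y["AG2"] <- runif(1, 0, 0.5)
    y["AEA"] <- runif(1, 0, 0.5)
    y["r_NMDA"] <- runif(1); y["r_AMPA"] <- runif(1)
    y["x_CB1R"] <- runif(1, 0, 0.5); y["d_CB1R"] <- runif(1, 0, 0.4)
    y["W_pre"] <- runif(1, 0.6, 2.9)
    y[paste0("B", 1:13)] <- runif(13, 0, ps$CaMKII_T / 20)
    tt <- runif(1, 0, 4)
    dR <- model_rhs(tt, y, ps, pr)
    dC <- deSolve::DLLfunc(y = y, dllname = "ecbstdp",
                           func = "ecbstdp_derivs",
                           initfunc = "ecbstdp_init", parms = parms,
                           times = tt, nout = 1)$dy
    expect_near(dC, unname(dR), tol = 1e-10)
  }
})

test_that("identical runs are bitwise reproducible", {
  ps <- ps_default
  pr <- build_stdp_protocol(3, -15, 1, delta = ps$delta)
  a <- run_protocol(ps, pr, settle_time = 10)
  b <- run_protocol(ps, pr, settle_time = 10)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$W_total, b$W_total)
})

test_that("weights are robust to tighter tolerances and denser restarts", {
  ps <- ps_default
  pr <- build_stdp_protocol(5, -15, 1, delta = ps$delta)
  base <- run_protocol(ps, pr, settle_time = 60, keep_trajectory = FALSE)
  tight <- ps; tight$rtol <- 1e-9; tight$atol <- 1e-9
  ref <- run_protocol(tight, pr, settle_time = 60, keep_trajectory = FALSE)
  expect_lt(abs(base$W_total - ref$W_total) / ref$W_total, 0.005)
  # halving the recording step (densifying segment grids) changes nothing
  dense <- run_protocol(ps, pr, settle_time = 60, record_dt = 0.001,
                        keep_trajectory = FALSE)
  expect_lt(abs(base$W_total - dense$W_total) / base$W_total, 0.005)
})

test_that("weight change reporting follows the percent-of-baseline convention", {
  sim <- short_run()
  wc <- weight_change(sim)
  expect_named(wc, c("dW_pre", "dW_post", "dW_total"))
  expect_near(wc[["dW_total"]], 100 * sim$W_total)
  fake <- sim; fake$settled <- FALSE
  expect_error(weight_change(fake), "settled")
})

test_that("empty protocols leave the synapse untouched and exports round-trip", {
  sim <- run_protocol(ps_default, NULL, settle_time = 5)
  expect_near(sim$W_total, 1)
  base <- file.path(tempdir(), "simexport")
  paths <- export_simulation(short_run(), base)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::fromJSON(paste0(base, ".json"))
  expect_near(js$W_total, short_run()$W_total)
  traj <- utils::read.csv(paste0(base, ".csv"))
  expect_identical(colnames(traj), c("time", state_names()))
})
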