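test_that("ring automaton lumps into 14 conserving necklace classes", {
  m <- camkii_transition_matrices()
  expect_identical(dim(m$A6), c(14L, 14L))
  # phospho-counts per class: 1 class each for 0,1,5,6; 3 for 2 and 4; 4 for 3
  expect_identical(as.integer(table(m$nphos)),
                   c(1L, 1L, 3L, 4L, 3L, 1L, 1L))
  # every flux matrix conserves total holoenzyme (columns sum to zero)
  expect_near(colSums(m$A6), rep(0, 14))
  expect_near(colSums(m$A7), rep(0, 14))
  expect_near(colSums(m$A12), rep(0, 14))
  # the unphosphorylated ring offers 6 initiation sites and no k7 targets
  expect_identical(m$A6[1, 1], -6)
  expect_identical(m$A7[1, 1], 0)
  # the full ring loses phospho-groups at 6 sites and gains none
  expect_identical(m$A12[14, 14], -6)
  expect_identical(m$A6[, 14], rep(0, 14))
})

test_that("subsystem derivative conserves pools and rests in the down state", {
  ps <- ps_default
  st <- list(B = rep(0, 13), I1P = 0.1, PP1 = 0.05)
  d <- camkii_subsystem_rhs(st, ps$Ca_b, ps)
  expect_identical(d$CaMKII_act, 0)
  # no initiation flux reaches beyond B1 from an empty ring ensemble
  expect_true(all(d$dB[2:13] == 0))
  expect_gte(d$dB[1], 0)
})

test_that("the switch is bistable at basal calcium and monostable when saturated", {
  ps <- ps_default
  bi <- find_bistable_states(ps, ps$Ca_b)
  expect_true(bi$bistable)
  expect_lt(bi$down, 0.05 * 6 * ps$CaMKII_T)
  expect_gt(bi$up, 0.5 * 6 * ps$CaMKII_T)
  # saturating clamped calcium: monostable up
  hi <- find_bistable_states(ps, 25, t_end = 4000)
  expect_false(hi$bistable)
  expect_gt(hi$down, 0.5 * 6 * ps$CaMKII_T)
  # the original Hill exponent of the PKA calcium activation preserves
  # the bistable structure
  ps8 <- ps; ps8$n_PKA <- 8
  bi8 <- find_bistable_states(ps8, ps$Ca_b)
  expect_true(bi8$bistable)
})

test_that("a sub-threshold calcium transient decays back over more than 1 s", {
  ps <- ps_default
  rest <- ecbstdp:::.camkii_rest_i1(ps, ps$Ca_b)
  rhs <- function(t, y, p) {
    Ca <- if (t < 0.1) 3 else ps$Ca_b
    d <- camkii_subsystem_rhs(list(B = y[1:13], I1P = y[14], PP1 = y[15]),
                              Ca, ps)
    list(c(d$dB, d$dI1P, d$dPP1))
  }
  y0 <- c(rep(0, 13), rest$I1P, rest$PP1)
  out <- deSolve::lsoda(y0, c(0, 0.1, 1.1, 5, 60, 400), rhs, NULL,
                        rtol = 1e-8, atol = 1e-10)
  m <- camkii_transition_matrices()
  act <- as.matrix(out[, 2:14]) %*% m$nphos[-1]
  expect_gt(act[2], 0)              # the pulse phosphorylates something
  expect_gt(act[3], 0.5 * act[2])   # less than half lost within 1 s
  expect_lt(act[6], 0.1 * act[2])   # eventually back toward the down state
})

test_that("postsynaptic weight readout is linear with the stated ceiling", {
  ps <- ps_default
  act_max <- 6 * ps$CaMKII_T
  expect_identical(w_post(0, ps), 1)
  expect_near(w_post(act_max, ps), 4.5)
  expect_near(w_post(act_max / 2, ps), 2.75)
  expect_error(w_post(act_max * 1.01, ps), "CaMKII_act_max")
})
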