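test_that("parameter sampling is uniform on [0.1, 1.9] x reference and seeded", {
  ps <- ps_default
  s1 <- sample_parameter_vectors(ps, c("tau_G", "g_NMDA"), 500, seed = 7)
  s2 <- sample_parameter_vectors(ps, c("tau_G", "g_NMDA"), 500, seed = 7)
  expect_identical(s1, s2)
  expect_true(all(s1[, "tau_G"] >= 0.1 * ps$tau_G &
                    s1[, "tau_G"] <= 1.9 * ps$tau_G))
  # empirical variance approaches the design value 0.27 * ref^2
  expect_lt(abs(var(s1[, "g_NMDA"]) / (0.27 * ps$g_NMDA^2) - 1), 0.2)
  expect_error(sample_parameter_vectors(ps, "no_such_knob", 5), "no_such_knob")
})

test_that("SRC recovers a known linear model and its scale invariance", {
  set.seed(11)
  n <- 300
  X <- cbind(p1 = runif(n, 0.1, 1.9), p2 = runif(n, 1, 19),
             p3 = runif(n, 0.01, 0.19))
  D <- 5 * X[, "p1"] + rnorm(n, sd = 0.02)
  rep1 <- compute_src(X, D, seed = 11)
  expect_identical(rep1$parameter[1], "p1")
  expect_near(abs(rep1$src[rep1$parameter == "p1"]), 1, tol = 0.02)
  expect_lt(max(abs(rep1$src[rep1$parameter != "p1"])), 0.1)
  expect_identical(sort(rep1$rank), 1:3)

  # rescaling a parameter's units leaves its SRC unchanged
  X2 <- X; X2[, "p1"] <- X2[, "p1"] * 1000
  rep2 <- compute_src(X2, D)
  expect_near(rep2$src[rep2$parameter == "p1"],
              rep1$src[rep1$parameter == "p1"], tol = 1e-8)

  # constant response degenerates to an all-zero report with a warning
  expect_warning(rep0 <- compute_src(X, rep(2, n)), "constant")
  expect_true(all(rep0$src == 0))

  # failed samples are dropped; too few valid samples abort
  D_na <- D; D_na[1:295] <- NA
  expect_error(compute_src(X, D_na), "valid samples")
})

test_that("map distance is zero against itself and flags failures", {
  ps <- ps_default
  grid <- data.frame(dt = -15, n = 2)
  ref <- ecbstdp:::.grid_weights(ps, grid, 1, settle_time = 10)
  self <- map_distance(setNames(ps$tau_G, "tau_G"), ps, grid,
                       settle_time = 10, reference = ref)
  expect_near(self, 0, tol = 1e-9)
  # the stated arithmetic of the distance on a hand-built two-point grid
  cand <- list(W_pre = ref$W_pre + c(0.1, 0), W_post = ref$W_post + c(0.2, 0))
  grid2 <- data.frame(dt = c(-15, 15), n = c(2, 2))
  D <- sqrt(mean((cand$W_pre - ref$W_pre)^2 + (cand$W_post - ref$W_post)^2))
  expect_near(D, sqrt((0.1^2 + 0.2^2) / 2))
})

test_that("an end-to-end miniature sensitivity run ranks a live parameter", {
  ps <- ps_default
  rep <- run_sensitivity(ps, free_list = c("tau_G", "kappa_delta"),
                         n = 6, seed = 3,
                         grid = data.frame(dt = -15, n = 3),
                         settle_time = 10)
  expect_s3_class(rep, "src_report")
  expect_identical(attr(rep, "seed"), 3)
  expect_gte(attr(rep, "n_valid"), 4)
  # glutamate clearance shapes the map; the PLCdelta product-inhibition
  # constant is inert on this grid
  expect_identical(rep$parameter[1], "tau_G")
  expect_gt(abs(rep$src[1]), abs(rep$src[2]))
})
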