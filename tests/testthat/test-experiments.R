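# build a synthetic map object without running the ODE model
synthetic_map <- function(W_pre, W_post, dt_grid, n_grid) {
  ecbstdp:::.finish_map(W_pre, W_post, dt_grid, n_grid,
                        axis2 = "n_pairings", frequency = 1,
                        variant = NULL, ps = ps_default, blur = TRUE)
}

test_that("the timing blur is normalized, exact on constants and symmetric", {
  dt <- seq(-40, 40, by = 2)
  expect_near(gaussian_blur(rep(1.7, length(dt)), dt, 3), rep(1.7, length(dt)))
  # an interior unit spike spreads as a normalized Gaussian: mass preserved
  w <- rep(0, length(dt)); w[21] <- 1
  b <- gaussian_blur(w, dt, 3)
  expect_near(sum(b), 1)
  expect_lt(max(b), 1)
  expect_near(b[20], b[22])                      # symmetric kernel
  # reversing the axis reverses the output
  expect_near(rev(gaussian_blur(rev(w), dt, 3)), b)
  expect_error(gaussian_blur(w, cumsum(seq_along(dt)), 3), "uniformly")
})

test_that("domain extraction labels connected LTP and LTD regions", {
  dt <- seq(-20, 20, by = 2); n <- c(5, 10, 25, 50, 100)
  Wpre <- matrix(1, length(dt), length(n), dimnames = list(dt, n))
  Wpost <- Wpre
  Wpre[dt < 0, n <= 10] <- 1.6                   # an LTP island
  Wpre[dt > 5, n >= 50] <- 0.7                   # an LTD island
  m <- synthetic_map(Wpre, Wpost, dt, n)
  dom <- extract_domain_boundaries(m, blurred = FALSE)
  expect_identical(sort(dom$type), c("LTD", "LTP"))
  ltp <- dom[dom$type == "LTP", ]
  expect_identical(c(ltp$dt_min, ltp$dt_max), c(-20, -2))
  expect_identical(c(ltp$axis2_min, ltp$axis2_max), c(5, 10))
  ltd <- dom[dom$type == "LTD", ]
  expect_identical(c(ltd$axis2_min, ltd$axis2_max), c(50, 100))

  # an all-baseline map yields no domains
  none <- synthetic_map(Wpost, Wpost, dt, n)
  expect_identical(nrow(extract_domain_boundaries(none)), 0L)
  expect_error(extract_domain_boundaries(m, ltp_threshold = 90), "straddle")
})

test_that("blur acts on the weight components before their product", {
  dt <- seq(-10, 10, by = 2); n <- c(10, 100)
  Wpre <- matrix(1, length(dt), length(n), dimnames = list(dt, n))
  Wpost <- Wpre
  Wpre[6, 1] <- 2                                # single potentiated column
  Wpost[6, 2] <- 3
  m <- synthetic_map(Wpre, Wpost, dt, n)
  expect_near(m$W_total_blur[, 1], gaussian_blur(Wpre[, 1], dt, 3))
  expect_near(m$W_total_blur[, 2], gaussian_blur(Wpost[, 2], dt, 3))
  # and the product map recombines blurred components, not blurred totals
  mix <- m$W_pre_blur * m$W_post_blur
  expect_near(m$W_total_blur, mix)
})

test_that("small simulated maps carry both layers and export to disk", {
  ps <- ps_default
  m <- compute_map(ps, NULL, dt_grid = c(-18, -15, -12), n_grid = c(5, 10),
                   settle_time = 30)
  expect_s3_class(m, "stdp_map")
  expect_identical(dim(m$W_total), c(3L, 2L))
  expect_true(all(m$W_total > 1))                # inside the eCB-LTP domain
  expect_near(m$W_total, m$W_pre * m$W_post)
  base <- file.path(tempdir(), "mapexport")
  paths <- export_map(m, base)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[1], row.names = 1)
  expect_near(as.matrix(back), m$W_total, tol = 1e-12)
})
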