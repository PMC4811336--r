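# shared fixtures: default parameters and a few short cached simulations
ps_default <- default_parameters()

# short post-pre run reused by several property tests (10 pairings,
# trajectory kept); computed lazily once per session
.fixture_env <- new.env()

short_run <- function() {
  if (is.null(.fixture_env$sim10))
    .fixture_env$sim10 <- run_protocol(
      ps_default, build_stdp_protocol(10, -15, 1, delta = ps_default$delta),
      settle_time = 30)
  .fixture_env$sim10
}

rest_state <- function() steady_state(ps_default)

# numeric all-equal with a tolerance that suits ODE outputs
expect_near <- function(object, expected, tol = 1e-6) {
  expect_equal(object, expected, tolerance = tol,
               ignore_attr = c("names", "dimnames"))
}
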