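# Shared fixtures and lazily cached long simulations (computed once per
# test run; several acceptance and property tests reuse them).

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# 20 simulated minutes of default 2D motion at dt = 0.01 s, fixed seed.
default_run_20min <- function() {
  cached("run20", {
    set.seed(20240101)
    simulate_agent(Agent(Arena()), duration = 1200, dt = 0.01)$history
  })
}

expect_all_close <- function(actual, expected, tol = 1e-8) {
  expect_lt(max(abs(actual - expected)), tol)
}
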