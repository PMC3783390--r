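test_that("competing strength and environmental restriction follow the model", {
  C <- cycle_matrix(2)
  expect_equal(competing_strength(c(50, 50), C, a = 100), c(5000, 5000))
  # an unsupported occupation has zero competing strength
  expect_equal(competing_strength(c(3, 4), matrix(0L, 2, 2), a = 100), c(0, 0))
  # inactive supporters hold zero productivity and contribute nothing
  expect_equal(competing_strength(c(50, 0), C, a = 100)[1], 0)
  expect_error(competing_strength(c(1, 2, 3), C, a = 100), "dimensions")

  expect_equal(environmental_restriction(100, b = 1), 100)
  expect_equal(environmental_restriction(0, b = 2), 0)
  expect_equal(environmental_restriction(40, b = 1),
               environmental_restriction(20, b = 1) * 2)
  expect_error(environmental_restriction(-1, b = 1), "nonnegative")
})

test_that("the change rate vanishes at equilibrium and has the closed single-occupation form", {
  env <- environment_params(a = 100, b = 1)
  C1 <- matrix(1L, 1, 1)
  # single self-supporter: dx/dt = a - b x
  g <- derivative(society_state(50), C1, env)
  expect_equal(g, 50)
  expect_equal(derivative(society_state(100), C1, env), 0)

  sm <- random_irreducible(6, 0.6, seed = 2)
  xstar <- equilibrium_productivity(sm, env$a, env$b)
  for (form in c("ratio", "mass")) {
    g <- derivative(society_state(xstar), sm, env, rate_form = form)
    expect_lt(max(abs(g)), 1e-5)
  }

  # an unsupported active occupation always declines
  C <- cycle_matrix(2); C[2, 1] <- 0L
  g <- derivative(society_state(c(5, 5)), C, env)
  expect_lt(g[2], 0)

  st <- society_state(c(5, 0)); st$active <- c(TRUE, TRUE)
  expect_error(derivative(st, C, env), "zero productivity")
})

test_that("develop relaxes to the Perron equilibrium on irreducible structures", {
  env <- environment_params(a = 100, b = 1)
  cfg <- tiny_cfg(2, 1)

  out <- develop(society_state(1), matrix(1L, 1, 1), env, cfg)
  expect_equal(out$x, 100, tolerance = 1e-6)

  out <- develop(society_state(c(1, 1)), cycle_matrix(2), env, cfg)
  expect_equal(out$x, c(50, 50), tolerance = 1e-6)

  # oracle equivalence on random irreducible fixtures, both rate forms
  set.seed(12)
  sizes <- sample(3:15, 5, replace = TRUE)
  for (s in 1:5) {
    n <- sizes[s]
    sm <- random_irreducible(n, 0.5, seed = 100 + s)
    xstar <- equilibrium_productivity(sm, env$a, env$b)
    for (form in c("ratio", "mass")) {
      cfgf <- tiny_cfg(n, 0.5, rate_form = form)
      out <- develop(society_state(rep(2, n)), sm, env, cfgf)
      expect_equal(out$x, xstar, tolerance = 1e-6)
    }
  }
})

test_that("develop eliminates unsupported occupations and the rest re-equilibrate", {
  env <- environment_params(a = 100, b = 1)
  cfg <- tiny_cfg(3, 1)
  # occupation 3 is supported by nobody; 1 and 2 form a 2-cycle
  C <- matrix(0L, 3, 3)
  C[1, 2] <- C[2, 1] <- 1L
  out <- develop(society_state(c(10, 10, 10)), C, env, cfg)
  expect_equal(out$active, c(TRUE, TRUE, FALSE))
  expect_equal(out$x, c(50, 50, 0), tolerance = 1e-6)

  # nothing viable: everyone is eliminated, flagged extinct, no error
  out <- develop(society_state(c(5, 5)), matrix(0L, 2, 2), env, cfg)
  expect_true(is_extinct(out))
  expect_equal(out$x, c(0, 0))

  # an extinct state passes through unchanged
  ext <- society_state(c(0, 0))
  expect_identical(develop(ext, cycle_matrix(2), env, cfg), ext)
})

test_that("eligible targets are the occupations supported by active ones", {
  # occupation 1 supports 2 and 3; nothing else
  C <- matrix(0L, 4, 4)
  C[2, 1] <- C[3, 1] <- 1L
  C[1, 1] <- 1L
  st <- society_state(c(5, 0, 0, 0))
  expect_equal(eligible_targets(st, C, source = 1), c(2L, 3L))

  # nobody active supports anything
  C0 <- matrix(0L, 3, 3); C0[2, 3] <- 1L
  st <- society_state(c(5, 0, 0))
  expect_length(eligible_targets(st, C0, source = 1), 0)

  # fully active complete society: every other occupation is a target
  st <- society_state(rep(5, 4))
  expect_equal(eligible_targets(st, complete_matrix(4), source = 2),
               c(1L, 3L, 4L))

  expect_error(eligible_targets(society_state(c(0, 1)), complete_matrix(2), 1),
               "not active")
})

test_that("mutation conserves productivity and respects the limina rules", {
  sm <- random_irreducible(12, 0.4, seed = 5)
  cfg <- tiny_cfg(12, 0.4, p_m = 0.5)
  env <- config_environment(cfg)

  set.seed(1)
  for (k in 1:20) {
    x <- ifelse(runif(12) < 0.7, runif(12, 1, 30), 0)
    if (!any(x > 0)) x[1] <- 5
    st <- society_state(x)
    res <- mutate(st, sm, cfg)
    expect_equal(sum(res$state$x), sum(st$x), tolerance = 1e-12)
    # phase-boundary invariant: zero or at least limina
    xs <- res$state$x
    expect_true(all(xs == 0 | xs >= cfg$limina))
    expect_true(all(xs[!res$state$active] == 0))
    if (nrow(res$events) > 0) {
      expect_true(all(res$events$amount == cfg$limina))
      expect_true(all(res$events$source != res$events$target))
      # sources held more than 2 limina before firing
      expect_true(all(st$x[res$events$source[1]] > 2 * cfg$limina))
    }
  }

  # a source at 1.5 limina (or exactly 2 limina) can never fire
  cfg1 <- tiny_cfg(2, 1, p_m = 1)
  for (xv in c(1.5, 2)) {
    res <- mutate(society_state(c(xv, 0)), support_matrix(complete_matrix(2)),
                  cfg1)
    expect_equal(nrow(res$events), 0)
  }

  # a firing source creates the target at exactly limina
  res <- mutate(society_state(c(10, 0)), support_matrix(complete_matrix(2)),
                cfg1)
  expect_equal(nrow(res$events), 1)
  expect_equal(res$state$x, c(9, 1))
  expect_true(res$state$active[2])
})

test_that("steps are deterministic and reduce to develop when p_m = 0", {
  sm <- random_irreducible(8, 0.5, seed = 6)
  env <- environment_params(a = 100, b = 1)
  cfg0 <- tiny_cfg(8, 0.5, p_m = 0)
  xstar <- equilibrium_productivity(sm, env$a, env$b)

  st <- society_state(rep(2, 8))
  for (k in 1:3) st <- step(st, sm, env, cfg0)
  expect_equal(st$x, xstar, tolerance = 1e-6)
  expect_equal(st$phase_index, 3L)

  # extinct states pass through
  ext <- society_state(numeric(8))
  expect_identical(step(ext, sm, env, cfg0), ext)

  # fixed seed => bit-identical trajectories, and the R-level step loop
  # matches the compiled multi-phase loop
  cfg <- tiny_cfg(8, 0.5, p_m = 0.3, n_phases = 25)
  run_loop <- function() {
    st <- society_state(rep(2, 8))
    for (k in 1:25) st <- step(st, sm, env, cfg)
    st
  }
  set.seed(99); s1 <- run_loop()
  set.seed(99); s2 <- run_loop()
  expect_identical(s1, s2)
  set.seed(99)
  ch <- evosoc:::phase_chunk(sm, society_state(rep(2, 8)), cfg, 25)
  expect_equal(ch$state$x, s1$x)
  expect_identical(ch$state$active, s1$active)
})

test_that("non-interacting blocks sharing an environment exclude competitively", {
  env <- environment_params(a = 100, b = 1)
  # complete-3 block (radius 3) against a 2-cycle (radius 1)
  C <- matrix(0L, 5, 5)
  C[1:3, 1:3] <- 1L
  C[4, 5] <- C[5, 4] <- 1L
  cfg <- tiny_cfg(5, 1)
  st <- society_state(c(1, 1, 1, 50, 50))  # weak block at its equilibrium
  out <- develop(st, C, env, cfg)
  expect_equal(out$active, c(rep(TRUE, 3), rep(FALSE, 2)))
  expect_equal(sum(out$x), 100 * 3, tolerance = 1e-5)

  # identical blocks: the established mass persists, the limina squad dies
  C2 <- matrix(0L, 6, 6)
  C2[1:3, 1:3] <- 1L
  C2[4:6, 4:6] <- 1L
  st <- society_state(c(100, 100, 100, 1, 1, 1))
  out <- develop(st, C2, env, cfg)
  expect_equal(out$active, c(rep(TRUE, 3), rep(FALSE, 3)))
  expect_equal(out$x[1:3], rep(100, 3), tolerance = 1e-5)
})
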