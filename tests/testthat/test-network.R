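test_that("irreducibility is strong connectivity of the support digraph", {
  # legal societies: cycles and complete graphs of any size, and a
  # self-supporting singleton
  expect_true(is_irreducible(cycle_matrix(2)))
  expect_true(is_irreducible(cycle_matrix(3)))
  expect_true(is_irreducible(complete_matrix(3)))
  expect_true(is_irreducible(matrix(1L, 1, 1)))

  # illegal structures, mirroring the canonical counterexamples:
  # two occupations with no connection at all
  expect_false(is_irreducible(matrix(0L, 2, 2)))
  expect_false(is_irreducible(diag(1L, 2)))
  # an occupation nobody supports (zero row)
  E <- complete_matrix(3); E[1, ] <- 0L
  expect_false(is_irreducible(E))
  # an occupation that supports nobody (zero column)
  F_ <- complete_matrix(4); F_[, 4] <- 0L; F_[4, ] <- 1L
  expect_false(is_irreducible(F_))
  # two occupations that support nobody
  G <- complete_matrix(6); G[, 5] <- 0L; G[, 6] <- 0L
  expect_false(is_irreducible(G))
  # one-way support between two occupations
  expect_false(is_irreducible(matrix(c(1L, 1L, 0L, 0L), 2)))
  # a non-self-supporting singleton is not a legal society
  expect_false(is_irreducible(matrix(0L, 1, 1)))

  expect_error(is_irreducible(matrix(0L, 2, 3)), "square")
})

test_that("random generation respects p_c, seeds and the self-supporter guarantee", {
  sm <- generate_support_matrix(3, 1)
  expect_true(all(as.matrix(sm) == 1L))
  expect_true(is_irreducible(sm))

  expect_error(generate_support_matrix(3, 0, max_attempts = 10),
               "irreducible")
  expect_error(generate_support_matrix(3, 1.5), "probability")
  expect_error(generate_support_matrix(0, 0.5), "n must be")

  a <- generate_support_matrix(20, 0.3, seed = 42, require_irreducible = FALSE)
  b <- generate_support_matrix(20, 0.3, seed = 42, require_irreducible = FALSE)
  expect_identical(as.matrix(a), as.matrix(b))
  # Bernoulli mean over 400 entries
  expect_gt(mean(as.matrix(a)), 0.2)
  expect_lt(mean(as.matrix(a)), 0.4)

  set.seed(9)
  for (k in 1:20) {
    sm <- generate_support_matrix(5, 0.05, require_irreducible = FALSE,
                                  ensure_self_supporter = TRUE)
    expect_gte(sum(diag(as.matrix(sm))), 1L)
  }
})

test_that("two-society generation fills the specified blocks", {
  # forced probabilities pin every entry: both originals support the single
  # derived occupation, which supports nothing
  spec <- inter_society_spec(n_o = 2, n_d = 1, p_c_oo = 1, p_c_od = 1,
                             p_c_do = 0, p_c_dd = 0)
  sm <- generate_two_society_matrix(spec, seed = 1)
  C <- as.matrix(sm)
  expect_identical(sm$labels, c("original", "original", "derived"))
  expect_equal(C[3, 1:2], c(1L, 1L))   # derived row supported by originals
  expect_equal(C[1:2, 3], c(0L, 0L))   # no back-support
  expect_equal(C[3, 3], 0L)

  # invader block only: block-diagonal, overall reducible
  spec <- inter_society_spec(n_o = 2, n_i = 2, p_c_oo = 1, p_c_ii = 1)
  sm <- generate_two_society_matrix(spec, seed = 1)
  C <- as.matrix(sm)
  expect_true(all(C[1:2, 3:4] == 0L) && all(C[3:4, 1:2] == 0L))
  expect_false(is_irreducible(sm))
  expect_true(is_irreducible(C[3:4, 3:4]))

  # mutual support in both directions makes the merged matrix irreducible
  spec <- inter_society_spec(n_o = 2, n_d = 2, p_c_oo = 1, p_c_od = 1,
                             p_c_do = 1, p_c_dd = 1)
  sm <- generate_two_society_matrix(spec, seed = 1)
  expect_true(is_irreducible(sm))

  expect_warning(inter_society_spec(n_o = 2, p_c_oo = 1, p_c_od = 1.5),
                 "capped")
})

test_that("power iteration agrees with the dense eigen oracle", {
  e <- spectral_radius_and_perron(matrix(1, 1, 1))
  expect_equal(e$lambda_pf, 1)
  expect_equal(e$perron_vector, 1)

  e <- spectral_radius_and_perron(cycle_matrix(2))
  expect_equal(e$lambda_pf, 1, tolerance = 1e-10)
  expect_equal(e$perron_vector, c(0.5, 0.5), tolerance = 1e-10)

  e <- spectral_radius_and_perron(complete_matrix(2))
  expect_equal(e$lambda_pf, 2, tolerance = 1e-10)
  expect_equal(e$perron_vector, c(0.5, 0.5), tolerance = 1e-10)

  set.seed(31)
  sizes <- sample(3:20, 10, replace = TRUE)
  for (s in 1:10) {
    n <- sizes[s]
    sm <- random_irreducible(n, 0.5, seed = s)
    e <- spectral_radius_and_perron(sm)
    expect_equal(e$lambda_pf, eigen_radius(sm), tolerance = 1e-8)
    expect_true(all(e$perron_vector > 0))
    resid <- as.matrix(sm) %*% e$perron_vector - e$lambda_pf * e$perron_vector
    expect_lt(max(abs(resid)), 1e-10)
    expect_gte(e$lambda_pf, 1)  # binary irreducible matrices
  }
})

test_that("eliminating occupations never raises the spectral radius", {
  set.seed(11)
  for (s in 1:10) {
    sm <- generate_support_matrix(12, 0.4, require_irreducible = FALSE)
    C <- as.matrix(sm)
    keep <- sort(sample(12, sample(2:11, 1)))
    expect_lte(eigen_radius(C[keep, keep, drop = FALSE]),
               spectral_radius_and_perron(C)$lambda_pf + 1e-8)
  }
})

test_that("equilibrium productivity is the scaled Perron vector", {
  expect_equal(equilibrium_productivity(matrix(1, 1, 1), 100, 1), 100)
  expect_equal(equilibrium_productivity(cycle_matrix(2), 100, 1), c(50, 50))
  expect_equal(equilibrium_productivity(complete_matrix(2), 100, 1),
               c(100, 100))

  # stationarity: the rate vector vanishes at x*
  sm <- random_irreducible(8, 0.5, seed = 3)
  env <- environment_params(a = 100, b = 1)
  xstar <- equilibrium_productivity(sm, env$a, env$b)
  g <- derivative(society_state(xstar), sm, env)
  expect_lt(max(abs(g)), 1e-8)

  # only the ratio a/b matters, and x* is proportional to it
  expect_equal(equilibrium_productivity(sm, 200, 2),
               equilibrium_productivity(sm, 100, 1))
  expect_equal(equilibrium_productivity(sm, 300, 1),
               3 * equilibrium_productivity(sm, 100, 1))

  expect_error(equilibrium_productivity(diag(1L, 2), 100, 1), "reducible")
  expect_error(equilibrium_productivity(matrix(1, 1, 1), -1, 1), "positive")
})

test_that("average reserve is mean active productivity above limina", {
  expect_equal(average_reserve(rep(10, 100), limina = 1), 9)
  expect_equal(average_reserve(rep(2, 5), limina = 2), 0)
  expect_equal(average_reserve(society_state(c(4, 0, 2)), limina = 1), 2)
  expect_error(average_reserve(numeric(3), limina = 1), "extinct")
})

test_that("wipeout threshold matches brute-force pulses on a uniform society", {
  expect_equal(wipeout_threshold(1000, 100, 1), 10)
  expect_equal(wipeout_threshold(100, 1, 1), 100)
  expect_equal(wipeout_threshold(1000, 100, 2),
               wipeout_threshold(1000, 100, 1) / 2)
  expect_error(wipeout_threshold(-1, 100, 1), "positive")

  # a complete graph gives a uniformly distributed society: pulses just
  # below/above the predicted threshold decide survival
  C <- complete_matrix(5)
  cfg <- tiny_cfg(5, 1)
  env <- config_environment(cfg)
  st <- society_state(equilibrium_productivity(C, env$a, env$b))
  rstar <- wipeout_threshold(sum(st$x), 5, cfg$limina)
  expect_equal(rstar, 100)
  below <- apply_disturbance(st, C, env, rstar * 0.98, cfg)
  expect_false(is_extinct(below))
  above <- apply_disturbance(st, C, env, rstar * 1.02, cfg)
  expect_true(is_extinct(above))
})

test_that("support matrices round-trip through adjacency CSV and edge-list TSV", {
  sm <- generate_two_society_matrix(
    inter_society_spec(n_o = 4, n_d = 3, p_c_oo = 0.6, p_c_od = 0.5),
    seed = 8)
  adj <- tempfile(fileext = ".csv")
  lab <- tempfile(fileext = ".csv")
  write_support_matrix(sm, adj, format = "adjacency", labels_path = lab)
  back <- read_support_matrix(adj, format = "adjacency", labels_path = lab)
  expect_identical(as.matrix(back), as.matrix(sm))
  expect_identical(back$labels, sm$labels)

  edg <- tempfile(fileext = ".tsv")
  write_support_matrix(sm, edg, format = "edgelist", labels_path = lab)
  back <- read_support_matrix(edg, format = "edgelist", labels_path = lab)
  expect_identical(as.matrix(back), as.matrix(sm))
  expect_identical(back$labels, sm$labels)
})
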