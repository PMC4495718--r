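test_that("cross-section placement honours spacing, jitter and determinism", {
  ## degenerate bundle
  cs1 <- generate_cross_section(fiber_spec(n_mts = 1, rng_seed = 7))
  expect_equal(nrow(cs1), 1)
  expect_equal(c(cs1$x_nm, cs1$y_nm), c(0, 0))

  ## jitter-free triple sits at exactly the lattice spacing
  cs3 <- generate_cross_section(
    fiber_spec(n_mts = 3, mean_nn_spacing_nm = 56.1, spacing_jitter_nm = 0,
               rng_seed = 1))
  d <- as.matrix(dist(cbind(cs3$x_nm, cs3$y_nm)))
  expect_equal(min(d[upper.tri(d)]), 56.1, tolerance = 1e-9)

  ## seeded determinism
  sp <- fiber_spec(n_mts = 30, rng_seed = 1)
  expect_identical(generate_cross_section(sp), generate_cross_section(sp))

  ## no-overlap invariant and median-spacing accuracy over seeds
  for (seed in 1:10) {
    sp <- fiber_spec(n_mts = 30, mean_nn_spacing_nm = 56.1,
                     spacing_jitter_nm = 4, rng_seed = seed)
    cs <- generate_cross_section(sp)
    dm <- as.matrix(dist(cbind(cs$x_nm, cs$y_nm)))
    expect_gte(min(dm[upper.tri(dm)]), 25)
    nn <- nearest_neighbor_stats(cs)
    expect_lt(abs(nn$median_nn_nm - 56.1), 4)
  }
})

test_that("over-dense packing requests fail rather than overlap", {
  ## the constructor already rejects spacings below one MT diameter, so the
  ## generator guard is exercised by corrupting a spec after validation
  sp <- fiber_spec(n_mts = 40, mean_nn_spacing_nm = 30, rng_seed = 2)
  sp$mean_nn_spacing_nm <- 2
  expect_error(generate_cross_section(sp), "over-dense|could not place")
  expect_error(fiber_spec(n_mts = 10, mean_nn_spacing_nm = 20),
               "MTs would overlap")
})

test_that("MT vectors carry the bundle tilt and planted deviants", {
  ## perfectly parallel fiber
  sp <- fiber_spec(n_mts = 8, rng_seed = 3)
  vec <- generate_mt_vectors(generate_cross_section(sp), sp)
  expect_true(all(abs(vec$dir_x) < 1e-12 & abs(vec$dir_y) < 1e-12))
  expect_equal(vec$top_z_nm - vec$bot_z_nm,
               rep(sp$slab_thickness_nm, 8), tolerance = 1e-9)

  ## rigid tilt: all directions parallel, each at the planted polar angle
  sp <- fiber_spec(n_mts = 8, fiber_tilt = c(0.3, 1.0), rng_seed = 3)
  vec <- generate_mt_vectors(generate_cross_section(sp), sp)
  dirs <- cbind(vec$dir_x, vec$dir_y, vec$dir_z)
  gram <- dirs %*% t(dirs)
  expect_equal(max(abs(gram - 1)), 0, tolerance = 1e-9)   # pairwise angles 0
  expect_equal(acos(dirs[, 3]), rep(0.3, 8), tolerance = 1e-9)
  expect_equal(vec$top_z_nm - vec$bot_z_nm,
               rep(sp$slab_thickness_nm, 8), tolerance = 1e-9)

  ## planted deviant count is exact
  sp <- fiber_spec(n_mts = 9, deviant_fraction = 0.5,
                   deviant_polar_max_rad = 0.2, rng_seed = 11)
  vec <- generate_mt_vectors(generate_cross_section(sp), sp)
  polar <- acos(cbind(vec$dir_x, vec$dir_y, vec$dir_z)[, 3])
  expect_equal(sum(polar > 1e-12), ceiling(9 / 2))
  expect_equal(sum(vec$is_deviant), ceiling(9 / 2))
  expect_true(all(polar <= 0.2 + 1e-12))
})

test_that("connector generation respects polarity mix and proximity", {
  ## forced bipolar mix
  sp <- fiber_spec(n_mts = 12, connector_polarity_mix = c("2" = 1, "3" = 0, "4" = 0),
                   connectors_per_mt = 0.8, rng_seed = 5)
  sf <- simulate_fiber(sp)
  expect_true(all(sf$connectors$edges$polarity == 2))

  ## two MTs: the single possible pair, chained together
  sp2 <- fiber_spec(n_mts = 2, connectors_per_mt = 1, rng_seed = 5)
  sf2 <- simulate_fiber(sp2)
  expect_equal(nrow(sf2$connectors$edges), 1)
  expect_equal(sf2$connectors$edges$polarity, 2)
  expect_equal(sf2$chain_partition$sizes, 2L)

  ## member sets stay mutually proximal
  xy <- cbind(sf$fiber$mts$mid_x_nm, sf$fiber$mts$mid_y_nm)
  dm <- as.matrix(dist(xy))
  for (m in sf$connectors$edges$members) {
    expect_true(all(dm[m, m] <= 105 + 1e-9))
  }

  ## polarity proportions track the mix within binomial 99% bounds (pooled)
  pol <- integer(0)
  for (seed in 1:6) {
    spb <- fiber_spec(n_mts = 40, connectors_per_mt = 1.5,
                      connector_polarity_mix = c("2" = .8, "3" = .15, "4" = .05),
                      rng_seed = seed)
    pol <- c(pol, simulate_fiber(spb)$connectors$edges$polarity)
  }
  n <- length(pol)
  for (k in c(2, 3, 4)) {
    p0 <- c("2" = .8, "3" = .15, "4" = .05)[[as.character(k)]]
    half <- 2.576 * sqrt(p0 * (1 - p0) / n)
    expect_lt(abs(mean(pol == k) - p0), half + 0.02)
  }

  ## no connectable geometry signals
  far <- fiber_model(
    tibble::tibble(mt_id = 1:2,
                   mid_x_nm = c(0, 500), mid_y_nm = c(0, 0),
                   bot_x_nm = c(0, 500), bot_y_nm = c(0, 0), bot_z_nm = c(0, 0),
                   top_x_nm = c(0, 500), top_y_nm = c(0, 0), top_z_nm = c(40, 40)),
    fiber_spec(n_mts = 2, rng_seed = 1))
  expect_error(generate_connector_graph(far, fiber_spec(n_mts = 2, rng_seed = 1)),
               "no connectable geometry")
})

test_that("planted chain partitions match an independent union-find oracle", {
  for (seed in 1:20) {
    sp <- fiber_spec(n_mts = 25, connectors_per_mt = 1.2, rng_seed = seed)
    sf <- simulate_fiber(sp)
    expect_true(all(unlist(sf$connectors$edges$members) %in% sf$fiber$mts$mt_id))
    oracle <- oracle_chain_partition(sf$connectors$nodes,
                                     sf$connectors$edges$members)
    expect_identical(unname(sf$chain_partition$membership), oracle)
  }
})
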