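test_that("chain detection is transitive over shared connectors", {
  g <- connector_graph("f", nodes = 1:4, members = list(c(1, 2), c(2, 3)))
  p <- chains_from_connectors(g)
  expect_equal(p$table$chain_size, c(3L, 3L, 3L, 1L))
  expect_equal(p$singles, 4L)

  gq <- connector_graph("f", nodes = 1:4, members = list(c(1, 2, 3, 4)))
  expect_equal(chains_from_connectors(gq)$sizes, 4L)
})

test_that("chain partitions equal the union-find oracle on random hypergraphs", {
  set.seed(99)
  for (i in 1:100) {
    h <- random_hypergraph(n_nodes = 50, n_edges = 40)
    g <- connector_graph("f", nodes = h$nodes, members = h$members)
    p <- chains_from_connectors(g)
    expect_identical(unname(p$membership),
                     oracle_chain_partition(h$nodes, h$members))
  }
})

test_that("chain-size histogram excludes singles", {
  g <- connector_graph("f", nodes = 1:8,
                       members = list(c(1, 2), c(3, 4), c(5, 6, 7)))
  h <- chain_size_histogram(chains_from_connectors(g))
  expect_equal(h$chain_size, c(2L, 3L))
  expect_equal(h$count, c(2L, 1L))

  ## all singles: empty histogram
  g0 <- connector_graph("f", nodes = 1:5, members = list())
  expect_equal(nrow(chain_size_histogram(chains_from_connectors(g0))), 0)
})

test_that("polarity proportions are conserved and sum to one", {
  g <- connector_graph("f", nodes = 1:8,
                       members = list(c(1, 2), c(3, 4), c(5, 6, 7), c(1, 3, 5, 7)))
  pp <- polarity_proportions(g)
  expect_equal(pp$proportion, c(0.5, 0.25, 0.25))
  expect_equal(sum(pp$count), 4)
  expect_equal(sum(pp$proportion), 1)

  gb <- connector_graph("f", nodes = 1:4, members = list(c(1, 2), c(3, 4)))
  expect_equal(polarity_proportions(gb)$proportion, 1)

  ## planted mix recovered on a large synthetic graph
  pol <- integer(0)
  for (seed in 1:5) {
    sp <- fiber_spec(n_mts = 40, connectors_per_mt = 1.5,
                     connector_polarity_mix = c("2" = .6, "3" = .3, "4" = .1),
                     rng_seed = seed)
    pol <- c(pol, simulate_fiber(sp)$connectors$edges$polarity)
  }
  pp <- polarity_proportions(connector_graph("f", nodes = 1:40,
                                             members = lapply(pol, function(k) seq_len(k))))
  expect_lt(max(abs(pp$proportion - c(.6, .3, .1))), 0.1)
})

test_that("rank-sum test matches exact enumeration and stats::wilcox.test", {
  ## the textbook extreme case: C(6,3) = 20 arrangements, two-sided p = 0.1
  ts <- rank_sum_test(c(1, 2, 3), c(101, 102, 103))
  expect_equal(ts$p_value, 0.1)
  expect_equal(ts$statistic, sum(rank(c(1, 2, 3, 101, 102, 103))[1:3]))
  expect_equal(ts$method, "exact")

  ## identical multisets carry no evidence
  expect_equal(rank_sum_test(c(3, 5, 5, 8), c(3, 5, 5, 8))$p_value, 1)

  ## tie-free small samples agree with wilcox.test's exact p
  set.seed(5)
  for (i in 1:25) {
    x <- sample(1:1000, sample(2:8, 1))
    y <- sample(2000:3000, sample(2:8, 1))
    expect_equal(rank_sum_test(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }

  ## tied small samples agree with the enumeration oracle
  for (i in 1:25) {
    x <- sample(1:4, sample(2:8, 1), replace = TRUE)
    y <- sample(2:6, sample(2:8, 1), replace = TRUE)
    expect_equal(rank_sum_test(x, y)$p_value, oracle_ranksum_p(x, y),
                 tolerance = 1e-12)
  }

  ## large samples agree with the tie- and continuity-corrected normal
  ## approximation of wilcox.test
  for (i in 1:10) {
    x <- sample(1:10, 25, replace = TRUE)
    y <- sample(3:12, 30, replace = TRUE)
    expect_equal(rank_sum_test(x, y)$p_value,
                 wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("chained-vs-single test behaves at the no-effect and planted-effect poles", {
  ## identical count multisets (two twin pairs, one chained + one single
  ## MT in each): p = 1 at every radius
  sym <- tibble::tibble(mt_id = 1:4, x_nm = c(0, 50, 1000, 1050), y_nm = 0)
  res <- chained_vs_single_test(sym, c(TRUE, FALSE, TRUE, FALSE),
                                radii_nm = c(60, 105))
  expect_equal(res$p_value, c(1, 1))

  ## p-values are undefined when one group is empty
  res0 <- chained_vs_single_test(sym, rep(TRUE, 4), radii_nm = 60)
  expect_true(is.na(res0$p_value))

  ## planted effect: chained MTs packed tightly, singles spread out;
  ## p decreases as the planted contrast grows (seeded sweep)
  set.seed(31)
  p_at_gap <- function(gap) {
    x_ch <- runif(15, 0, 200)
    x_si <- runif(15, 0, 200 * gap)
    pts <- tibble::tibble(mt_id = 1:30, x_nm = c(x_ch, x_si),
                          y_nm = c(runif(15, 0, 200), runif(15, 0, 200 * gap)))
    ch <- rep(c(TRUE, FALSE), each = 15)
    median(chained_vs_single_test(pts, ch, radii_nm = c(80, 100, 120))$p_value)
  }
  ps <- vapply(c(1, 2.5, 6), p_at_gap, numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_lt(ps[3], 0.05)
})

test_that("membership randomization preserves group sizes and kills planted effects", {
  set.seed(77)
  x_ch <- runif(20, 0, 150); x_si <- runif(20, 0, 900)
  pts <- tibble::tibble(mt_id = 1:40, x_nm = c(x_ch, x_si),
                        y_nm = c(runif(20, 0, 150), runif(20, 0, 900)))
  ch <- rep(c(TRUE, FALSE), each = 20)

  obs <- chained_vs_single_test(pts, ch, radii_nm = 100)
  rnd <- randomize_membership(pts, ch, radii_nm = 100,
                              n_permutations = 99, seed = 4)
  expect_gt(rnd$median_p[["100"]], 10 * obs$p_value)

  ## determinism of a single permutation
  r1 <- randomize_membership(pts, ch, radii_nm = 100, n_permutations = 1, seed = 8)
  r2 <- randomize_membership(pts, ch, radii_nm = 100, n_permutations = 1, seed = 8)
  expect_identical(r1$p_matrix, r2$p_matrix)

  ## null p-values approximately uniform on symmetric data (KS at alpha 0.01)
  set.seed(123)
  pts0 <- tibble::tibble(mt_id = 1:30, x_nm = runif(30, 0, 400),
                         y_nm = runif(30, 0, 400))
  ch0 <- sample(rep(c(TRUE, FALSE), each = 15))
  rnd0 <- randomize_membership(pts0, ch0, radii_nm = 120,
                               n_permutations = 500, seed = 21)
  ks <- suppressWarnings(ks.test(rnd0$p_matrix[, 1], "punif"))
  expect_gt(ks$p.value, 0.01)
})
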