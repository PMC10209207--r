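test_that("saturated constraints force certain links", {
  m <- fit_link_probabilities(c("a", "b"), c(a = 1, b = 1))
  expect_equal(link_probability(m, "a", "b"), 1)
  # triangle as its own negative model: all degrees 2 on K3 -> all p = 1
  nm <- negative_model(triangle())
  expect_equal(link_probability(nm, c("a", "a", "b"), c("b", "c", "c")),
               c(1, 1, 1))
})

test_that("symmetric complete-graph constraint gives the symmetric solution", {
  m <- fit_link_probabilities(letters[1:4], stats::setNames(rep(1, 4), letters[1:4]))
  p <- link_probability(m, c("a", "a", "a", "b", "b", "c"),
                        c("b", "c", "d", "c", "d", "d"))
  expect_equal(p, rep(1 / 3, 6), tolerance = 1e-6)
})

test_that("fixed point matches closed form and brute-force oracle on a triangle", {
  tri <- triangle()
  k <- c(a = 1.2, b = 1.0, c = 0.8)
  fp <- fit_link_probabilities(tri, k, mode = "negative")
  bf <- brute_force_maxent(tri, k)
  pairs_a <- c("a", "a", "b"); pairs_b <- c("b", "c", "c")
  p_fp <- link_probability(fp, pairs_a, pairs_b)
  p_bf <- link_probability(bf, pairs_a, pairs_b)
  # on a triangle the equations solve in closed form: p_ij = (k_i+k_j-k_l)/2
  expect_equal(p_fp, c(0.7, 0.5, 0.3), tolerance = 1e-5)
  expect_equal(max(abs(p_fp - p_bf)), 0, tolerance = 1e-5)
})

test_that("fixed point agrees with the root-finding oracle on small fixtures", {
  # sparse constraints
  for (s in 1:4) {
    fx <- interior_fixture(8, 0.6, seed = s)
    fp <- fit_link_probabilities(fx$constraint, fx$targets, mode = "negative")
    bf <- brute_force_maxent(fx$constraint, fx$targets)
    pairs <- fx$constraint$edges
    dif <- abs(link_probability(fp, pairs[, 1], pairs[, 2]) -
                 link_probability(bf, pairs[, 1], pairs[, 2]))
    expect_lt(max(dif), 1e-5)
  }
  # complete-graph constraints
  for (s in 5:8) {
    nodes <- sprintf("n%d", 1:7)
    k <- stats::setNames(with_seed_(s, stats::runif(7, 1, 4)), nodes)
    fp <- fit_link_probabilities(nodes, k, mode = "negative")
    bf <- brute_force_maxent(nodes, k)
    idx <- utils::combn(nodes, 2)
    dif <- abs(link_probability(fp, idx[1, ], idx[2, ]) -
                 link_probability(bf, idx[1, ], idx[2, ]))
    expect_lt(max(dif), 1e-5)
  }
})

test_that("fitted models reproduce their target degrees", {
  for (s in 1:5) {
    g <- er_graph(40, 0.12, seed = s)
    nm <- negative_model(g)
    expect_lt(max_degree_relerr(nm), 1e-3)
    m <- er_graph(40, 0.08, seed = s + 50)
    pm <- positive_model(g, m)
    expect_lt(max_degree_relerr(pm), 1e-3)
  }
})

test_that("infeasible targets fail fast with a constraint error", {
  expect_error(fit_link_probabilities(c("a", "b"), c(a = 2, b = 1)),
               "infeasible", class = "normlap_input_error")
  expect_error(
    fit_link_probabilities(triangle(), c(a = 2.5, b = 1, c = 1)),
    "infeasible", class = "normlap_input_error")
})

test_that("positive model zeroes pairs of nodes absent from the reference", {
  g <- net_from(c("a", "b"), c("b", "c"), name = "G")
  m <- net_from(c("a", "b"), c("c", "d"), c("d", "e"), name = "M")
  pm <- positive_model(g, m)
  expect_equal(link_probability(pm, c("c", "d"), c("d", "e")), c(0, 0))
  bm <- benchmark_moments(pm, m)
  # only the shared edge {a,b} can carry probability
  expect_equal(bm$mean, link_probability(pm, "a", "b"))
})

test_that("subgraph saturation: positive benchmark is exact with zero variance", {
  g <- er_graph(30, 0.2, seed = 3, name = "G")
  keep <- with_seed_(4, sample(nrow(g$edges), 20))
  m <- network(g$edges[keep, , drop = FALSE], name = "M")
  pm <- positive_model(g, m)
  bm <- benchmark_moments(pm, m)
  expect_equal(bm$mean, nrow(m$edges), tolerance = 1e-6)
  expect_equal(bm$variance, 0, tolerance = 1e-6)
})

test_that("benchmark moments are the Bernoulli-sum mean and variance", {
  # all p = 1 on m's edges
  nm <- negative_model(triangle())
  bm <- benchmark_moments(nm, triangle())
  expect_equal(bm$mean, 3)
  expect_equal(bm$variance, 0)
  # hand-built model with p = 0.5 on 4 edges
  sq <- net_from(c("a", "b"), c("b", "c"), c("c", "d"), c("a", "d"))
  m05 <- fit_link_probabilities(sq, c(a = 1, b = 1, c = 1, d = 1),
                                mode = "negative")
  bm2 <- benchmark_moments(m05, sq)
  expect_equal(bm2$mean, 2, tolerance = 1e-5)
  expect_equal(bm2$variance, 1, tolerance = 1e-4)
  expect_equal(bm2$sd, sqrt(bm2$variance))
})

test_that("sampling respects degenerate probabilities and the seed", {
  nm <- negative_model(triangle())
  s1 <- sample_network(nm, seed = 9)
  expect_equal(nrow(s1$edges), 3L)  # all p = 1
  g <- er_graph(25, 0.15, seed = 6)
  mod <- negative_model(g)
  a <- sample_network(mod, seed = 42)
  b <- sample_network(mod, seed = 42)
  expect_identical(a$edges, b$edges)
  c_ <- sample_network(mod, seed = 43)
  expect_false(identical(a$edges, c_$edges))
})

test_that("sampled edge counts follow the Bernoulli-sum distribution", {
  sq <- net_from(c("a", "b"), c("b", "c"), c("c", "d"), c("a", "d"))
  mod <- fit_link_probabilities(sq, c(a = 1, b = 1, c = 1, d = 1),
                                mode = "negative")  # p = 1/2 each
  counts <- vapply(1:400, function(s) nrow(sample_network(mod, s)$edges), 0L)
  # mean 2, variance 1 per draw -> SE of the mean = 1/20
  expect_lt(abs(mean(counts) - 2), 4 / sqrt(400))
})

test_that("analytic moments match Monte-Carlo sampling", {
  g <- er_graph(25, 0.15, seed = 21, name = "G")
  m <- er_graph(25, 0.12, seed = 22, name = "M")
  nm <- negative_model(g)
  an <- benchmark_moments(nm, m)
  mc <- monte_carlo_overlap(nm, m, n_samples = 4000, seed = 77)
  expect_lt(abs(an$mean - mc$mean), 3 * an$sd / sqrt(4000))
  expect_lt(abs(an$sd - mc$sd), 3 * an$sd / sqrt(2 * 4000))
})

test_that("solver reports non-convergence instead of silently stopping", {
  fx <- interior_fixture(12, 0.5, seed = 2)
  expect_error(
    fit_link_probabilities(fx$constraint, fx$targets, mode = "negative",
                           max_iter = 3),
    "convergence", class = "normlap_solver_error")
})

test_that("model serialization round-trips through JSON", {
  g <- er_graph(12, 0.3, seed = 8)
  mod <- negative_model(g)
  js <- jsonlite::fromJSON(model_to_json(mod))
  expect_equal(js$mode, "negative")
  expect_equal(unlist(js$alphas[names(mod$alpha)]), mod$alpha,
               tolerance = 1e-12)
})
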