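test_that("precision is TP/D with an error on empty selections", {
  expect_equal(precision(5, 10), 0.5)
  expect_equal(precision(7, 7), 1)
  expect_equal(precision(0, 4), 0)
  expect_error(precision(0, 0), class = "normlap_input_error")
})

# candidate = top 60% of the reference scored high, the remaining 40% of
# links rewired (degree-matched garbage) and scored low: corruption sets in
# below score 0.5
planted_scored <- function(seed, n = 45, p = 0.13, good_frac = 0.6) {
  ref <- er_graph(n, p, seed = seed, name = "reference")
  e <- nrow(ref$edges)
  good <- with_seed_(seed + 1, sample(e, floor(good_frac * e)))
  noise <- degree_shuffled_decoy(ref, seed = seed + 2)
  bad_edges <- noise$edges[!(paste(noise$edges[, 1], noise$edges[, 2]) %in%
                               paste(ref$edges[, 1], ref$edges[, 2])), ,
                           drop = FALSE]
  scored <- network(rbind(ref$edges[good, , drop = FALSE], bad_edges),
                    scores = c(with_seed_(seed + 3,
                                          stats::runif(length(good), 0.55, 1)),
                               with_seed_(seed + 4,
                                          stats::runif(nrow(bad_edges), 0, 0.45))),
                    name = "candidate")
  list(ref = ref, scored = scored, n_good = length(good))
}

test_that("thresholding recovers the planted corruption onset", {
  hits <- 0L
  for (s in 1:8) {
    fx <- planted_scored(1000 + 7 * s)
    tc <- threshold_scored_network(fx$scored, fx$ref, grid = c(0.01, 0.5))
    # curve is sorted strict -> loose; link counts never decrease downwards
    expect_true(all(diff(tc$curve$link_count) >= 0))
    if (!is.na(tc$selected_threshold) && tc$selected_threshold == 0.5) {
      hits <- hits + 1L
    }
    # above the onset the candidate is a clean subset of the reference
    top <- tc$curve[tc$curve$threshold == 0.5, ]
    expect_equal(top$observed, fx$n_good)
    expect_equal(top$precision, 1)
    expect_equal(top$normlap, 1, tolerance = 0.01)
  }
  expect_gte(hits, 7L)
})

test_that("a never-compatible candidate yields no selected threshold", {
  ref <- er_graph(40, 0.12, seed = 55, name = "reference")
  decoy <- degree_shuffled_decoy(ref, seed = 56)
  scored <- network(decoy$edges,
                    scores = with_seed_(57, stats::runif(nrow(decoy$edges))),
                    name = "noise")
  tc <- threshold_scored_network(scored, ref, grid = c(0.25, 0.5, 0.75))
  expect_true(is.na(tc$selected_threshold))
  expect_false(any(tc$curve$classification == "compatible"))
})

test_that("threshold curve errors when every grid point empties the candidate", {
  s <- network(rbind(c("a", "b")), scores = 0.3)
  expect_error(threshold_scored_network(s, triangle("ref"), grid = c(2, 3)),
               class = "normlap_input_error")
})

test_that("validation against a thresholded scored network", {
  g <- er_graph(40, 0.15, seed = 71, name = "base")
  keep <- with_seed_(72, sample(nrow(g$edges), floor(nrow(g$edges) * 0.6)))
  new <- network(g$edges[keep, , drop = FALSE], name = "new")
  scored <- network(g$edges, scores = rep(1, nrow(g$edges)), name = "scored")
  tc <- validate_with_scored_network(new, scored, grid = c(1))
  row <- tc$curve[1, ]
  # new is a subgraph of the reference at the only cutoff
  expect_equal(row$classification, "compatible")
  expect_equal(row$normlap, 1, tolerance = 0.01)
  expect_equal(row$positive_fraction, row$observed / row$testable)
  expect_equal(tc$selected_threshold, 1)
})

test_that("validation of a disjoint dataset is undefined everywhere", {
  new <- net_from(c("p", "q"), c("q", "r"), name = "new")
  scored <- network(er_graph(20, 0.2, seed = 73)$edges,
                    scores = rep(0.5, nrow(er_graph(20, 0.2, seed = 73)$edges)),
                    name = "scored")
  tc <- validate_with_scored_network(new, scored, grid = c(0.5))
  expect_true(all(tc$curve$classification == "undefined"))
  expect_true(is.na(tc$selected_threshold))
})

test_that("a random decoy validates at zero positive fraction", {
  g <- er_graph(45, 0.12, seed = 74, name = "base")
  keep <- with_seed_(75, sample(nrow(g$edges), floor(nrow(g$edges) * 0.6)))
  good <- network(g$edges[keep, , drop = FALSE], name = "good")
  decoy <- degree_shuffled_decoy(g, seed = 76)
  decoy$name <- "decoy"
  scored <- network(g$edges, scores = rep(1, nrow(g$edges)), name = "scored")
  tc_good <- validate_with_scored_network(good, scored, grid = c(1))
  tc_decoy <- validate_with_scored_network(decoy, scored, grid = c(1))
  expect_equal(tc_good$curve$classification[1], "compatible")
  expect_gt(tc_good$curve$positive_fraction[1], 0.9)
  expect_lt(tc_decoy$curve$positive_fraction[1],
            tc_good$curve$positive_fraction[1])
})

test_that("agreement matrix of identical networks is a complete graph", {
  g <- er_graph(30, 0.15, seed = 90)
  nets <- list(g, g, g)
  am <- agreement_matrix(nets, labels = c("n1", "n2", "n3"))
  expect_equal(nrow(am$agreement_edges), 3L)
  expect_true(all(am$pairs$classification == "compatible"))
  expect_equal(am$pairs$normlap, rep(1, 3), tolerance = 1e-4)
  expect_equal(am$pairs$overlap_fraction, rep(1, 3))
  # pair-symmetric matrices
  expect_equal(am$normlap, t(am$normlap))
})

test_that("agreement matrix marks disjoint pairs undefined with no edge", {
  a <- er_graph(20, 0.2, seed = 91, name = "A")
  b <- network(cbind(sprintf("x%02d", 1:10), sprintf("y%02d", 1:10)),
               name = "B")
  am <- agreement_matrix(list(a, b))
  expect_equal(am$pairs$classification, "undefined")
  expect_equal(nrow(am$agreement_edges), 0L)
  expect_true(is.na(am$pairs$normlap))
})

test_that("agreement matrix separates shared-union pairs from a decoy", {
  ok <- 0L
  for (s in 1:6) {
    base <- er_graph(40, 0.18, seed = 9000 + s, name = "base")
    pair <- sampled_pair_from_union(base, seed = 9100 + s)
    decoy <- degree_shuffled_decoy(base, seed = 9200 + s)
    decoy$name <- "decoy"
    am <- agreement_matrix(list(pair$a, pair$b, decoy))
    cls <- am$pairs
    good <- cls$classification[cls$labelA == "sample_a" &
                                 cls$labelB == "sample_b"]
    bad <- cls$classification[cls$labelA == "decoy" | cls$labelB == "decoy"]
    if (good == "compatible" && all(bad %in% c("no_signal", "incompatible"))) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok, 5L)
})

test_that("agreement matrix requires at least two networks", {
  expect_error(agreement_matrix(list(triangle())),
               class = "normlap_input_error")
})

test_that("threshold curve and agreement matrix write clean TSV", {
  fx <- planted_scored(4321)
  tc <- threshold_scored_network(fx$scored, fx$ref, grid = c(0.1, 1.0))
  path <- tempfile(fileext = ".tsv")
  write_threshold_curve(tc, path)
  back <- utils::read.delim(path)
  expect_equal(nrow(back), 2L)
  expect_true(all(c("threshold", "link_count", "precision", "normlap",
                    "classification") %in% names(back)))
})
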