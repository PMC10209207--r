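# shared builders for small test networks

net_from <- function(..., name = NULL) {
  pairs <- list(...)
  network(do.call(rbind, pairs), name = name)
}

triangle <- function(name = NULL) {
  net_from(c("a", "b"), c("b", "c"), c("a", "c"), name = name)
}

# random strictly-interior targets on a small random constraint graph: one
# shared scaling fraction c of the degrees, so p_e = c realizes the targets
# and they are guaranteed to lie inside the feasible expected-degree region
interior_fixture <- function(n, p_edge, seed, lo = 0.3, hi = 0.7) {
  g <- er_graph(n, p_edge, seed)
  deg <- degrees(g)
  keep <- names(deg)[deg > 0]
  g2 <- network(g$edges, nodes = keep)
  deg <- degrees(g2)
  frac <- with_seed_(seed + 1000L, stats::runif(1, lo, hi))
  list(constraint = g2, targets = stats::setNames(deg * frac, names(deg)))
}

with_seed_ <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

max_degree_relerr <- function(model) {
  act <- names(model$targets)[model$targets > 0]
  pairs <- normlap:::model_pairs(model)
  p <- link_probability(model, pairs[, 1L], pairs[, 2L])
  expk <- stats::setNames(numeric(length(act)), act)
  for (side in 1:2) {
    s <- rowsum(p, pairs[, side])
    hit <- intersect(rownames(s), act)
    expk[hit] <- expk[hit] + s[hit, 1L]
  }
  max(abs(expk - model$targets[act]) / pmax(model$targets[act], 1))
}
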