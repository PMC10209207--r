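#' Seedable Erdos-Renyi random graph
#'
#' G(n, p) over nodes `v001 ... v<n>`; each of the `n(n-1)/2` pairs is included
#' independently with probability `p`. A pure function of `(n, p, seed)`.
#'
#' @param n number of nodes (`>= 2`).
#' @param p edge probability in \[0, 1\].
#' @param seed integer seed.
#' @param name optional label.
#' @return a `normlap_network` with all `n` nodes present.
#' @export
er_graph <- function(n, p, seed, name = NULL) {
  if (n < 2 || p < 0 || p > 1) stop_input("need n >= 2 and p in [0, 1]")
  ids <- sprintf("v%03d", seq_len(n))
  g <- with_seed(seed, igraph::sample_gnp(n, p))
  el <- igraph::as_edgelist(g, names = FALSE)
  network(cbind(ids[el[, 1L]], ids[el[, 2L]]), nodes = ids, name = name)
}

#' Sample a compatible network pair from a common underlying network
#'
#' Emulates the best-case scenario: both networks are draws from the same
#' underlying `base` network. Each side is sampled from the maximum-entropy
#' ensemble constrained to the edges of `base` with target degrees equal to
#' the base degrees scaled by the given fraction, so the pair is by
#' construction a draw from the positive-benchmark ensemble of their union.
#'
#' The positive benchmark of a later comparison conditions on the realized
#' union of the pair, which at sampling fraction `f` covers about `f * (2 - f)`
#' of the base's edges. The pair therefore tests as compatible only in the
#' joint-coverage regime (fractions around 0.8 and above); deeply incomplete
#' samples (0.5 and below) are flagged incompatible because the union misses
#' too much of the common truth — the default of 0.8 reflects the former,
#' which is the scenario the best-case ensemble models.
#'
#' @param base a `normlap_network` underlying "truth".
#' @param degree_fraction_a,degree_fraction_b fractions in (0, 1] scaling the
#'   base degrees of each sample (default 0.8).
#' @param seed integer seed (the two draws use `seed` and `seed + 1`).
#' @param ... solver options passed to [fit_link_probabilities()].
#' @return list of two `normlap_network`s named `a` and `b`.
#' @export
sampled_pair_from_union <- function(base, degree_fraction_a = 0.8,
                                    degree_fraction_b = 0.8, seed, ...) {
  stopifnot(is_network(base))
  if (degree_fraction_a <= 0 || degree_fraction_a > 1 ||
      degree_fraction_b <= 0 || degree_fraction_b > 1) {
    stop_input("degree fractions must lie in (0, 1]")
  }
  draw <- function(frac, s, nm) {
    if (frac == 1) {
      out <- base; out$name <- nm
      return(out)
    }
    model <- fit_link_probabilities(base, degrees(base) * frac,
                                    mode = "positive", overlap_edges = base, ...)
    sample_network(model, s, name = nm)
  }
  list(a = draw(degree_fraction_a, seed, "sample_a"),
       b = draw(degree_fraction_b, seed + 1L, "sample_b"))
}

#' Degree-matched randomized decoy of a network
#'
#' A draw from the negative-benchmark model of `net`: same expected degree
#' sequence over the complete graph on its nodes, structure destroyed.
#'
#' @param net a `normlap_network` with at least one edge.
#' @param seed integer seed.
#' @param ... solver options passed to [negative_model()].
#' @return a `normlap_network`.
#' @export
degree_shuffled_decoy <- function(net, seed, ...) {
  sample_network(negative_model(net, ...), seed, name = "decoy")
}

#' Monte-Carlo overlap statistics of a fitted ensemble
#'
#' Draws full networks from the model and counts their overlap with `m`; the
#' empirical mean and SD are an independent check of the analytic
#' Bernoulli-sum moments of [benchmark_moments()].
#'
#' @param model a fitted `normlap_model`.
#' @param m network of interest.
#' @param n_samples number of draws (`>= 100`).
#' @param seed integer seed.
#' @return list with `mean`, `sd`, `n_samples`.
#' @export
monte_carlo_overlap <- function(model, m, n_samples, seed) {
  stopifnot(inherits(model, "normlap_model"), is_network(m), n_samples >= 100)
  pairs <- model_pairs(model)
  p <- link_probability(model, pairs[, 1L], pairs[, 2L])
  key <- paste(pmin(pairs[, 1L], pairs[, 2L]),
               pmax(pairs[, 1L], pairs[, 2L]), sep = "\t")
  in_m <- as.numeric(key %in% edge_keys(m))
  counts <- with_seed(seed, {
    out <- numeric(n_samples)
    chunk <- max(1L, min(n_samples, floor(2e6 / max(length(p), 1L))))
    done <- 0L
    while (done < n_samples) {
      take <- min(chunk, n_samples - done)
      u <- matrix(stats::runif(take * length(p)), nrow = take)
      out[done + seq_len(take)] <-
        as.numeric((u < rep(p, each = take)) %*% in_m)
      done <- done + take
    }
    out
  })
  list(mean = mean(counts), sd = stats::sd(counts), n_samples = n_samples)
}

#' Brute-force maximum-entropy fit by generic root-finding
#'
#' Independent oracle for [fit_link_probabilities()]: solves the coupled
#' expected-degree equations `sum_j 1/(1 + alpha_i alpha_j) = k_i` in
#' log-multiplier space with a generic multivariate root-finder
#' ([pracma::fsolve()]) from several starts. Shares no code with the
#' fixed-point solver. Intended for small problems (<= 12 constrained nodes)
#' away from saturation.
#'
#' @param constraint a `normlap_network` of allowed pairs, or a character
#'   vector of nodes meaning the complete graph.
#' @param targets named numeric target degrees (positive, non-saturating).
#' @return a `normlap_model` (with `convergence$rule = "brute_force"`),
#'   usable with [link_probability()] and [benchmark_moments()].
#' @export
brute_force_maxent <- function(constraint, targets) {
  if (is_network(constraint)) {
    universe <- constraint$nodes
    sparse <- TRUE
  } else {
    universe <- sort(unique(as.character(constraint)), method = "radix")
    sparse <- FALSE
  }
  tg <- stats::setNames(numeric(length(universe)), universe)
  known <- intersect(names(targets), universe)
  tg[known] <- as.numeric(targets[known])
  active <- names(tg)[tg > 0]
  n <- length(active)
  if (n > 12L) stop_input("brute-force oracle limited to <= 12 constrained nodes")
  k <- tg[active]
  if (sparse) {
    ei <- match(constraint$edges[, 1L], active)
    ej <- match(constraint$edges[, 2L], active)
    ok <- !is.na(ei) & !is.na(ej)
    adj <- matrix(FALSE, n, n)
    adj[cbind(ei[ok], ej[ok])] <- TRUE
    adj[cbind(ej[ok], ei[ok])] <- TRUE
  } else {
    adj <- matrix(TRUE, n, n); diag(adj) <- FALSE
  }
  resid <- function(beta) {
    pm <- 1 / (1 + exp(outer(beta, beta, "+")))
    pm[!adj] <- 0
    rowSums(pm) - k
  }
  starts <- c(list(rep(0, n), rep(1, n), rep(-1, n)),
              lapply(1:6, function(s) with_seed(7L + s, stats::rnorm(n))))
  sol <- NULL
  for (x0 in starts) {
    fit <- tryCatch(
      suppressWarnings(pracma::fsolve(resid, x0, maxiter = 500, tol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && max(abs(resid(fit$x))) < 1e-8) { sol <- fit$x; break }
    # least-squares fallback for starts where Broyden stalls
    obj <- function(beta) sum(resid(beta)^2)
    ls <- stats::optim(x0, obj, method = "BFGS",
                       control = list(maxit = 2000, reltol = 1e-16))
    if (max(abs(resid(ls$par))) < 1e-8) { sol <- ls$par; break }
  }
  if (is.null(sol)) {
    stop(structure(class = c("normlap_oracle_error", "error", "condition"),
                   list(message = "brute-force oracle did not converge",
                        call = sys.call())))
  }
  structure(list(
    alpha = stats::setNames(exp(sol), active),
    targets = tg,
    nodes = universe,
    constraint_mode = if (sparse) "sparse" else "complete",
    constraint_edges = if (sparse) constraint$edges,
    forced_edges = matrix(character(0), 0, 2),
    mode = "negative",
    convergence = list(iterations = NA_integer_,
                       residual = max(abs(resid(sol))), rule = "brute_force")
  ), class = "normlap_model")
}
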