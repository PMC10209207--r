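ALPHA_MIN <- 1e-12
ALPHA_MAX <- 1e12

stop_solver <- function(msg, residual = NA_real_, iterations = NA_integer_) {
  stop(structure(class = c("normlap_solver_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1),
                      residual = residual, iterations = iterations)))
}

#' Fit the maximum-entropy link-probability model
#'
#' Solves for the Lagrange multipliers `alpha` of the soft configuration model
#' in which each allowed node pair `(i, j)` carries an independent link with
#' probability `p_ij = 1 / (1 + alpha_i alpha_j)` and the expected degree of
#' every constrained node matches its target. The fixed point is reached by
#' synchronous sweeps of the multiplicative update
#' `alpha_i' = alpha_i * <k_i> / k_i` (equivalently
#' `alpha_i' = (1/k_i) * sum_j 1 / (alpha_j + 1/alpha_i)` over allowed
#' partners), starting from `alpha_i = 1`.
#'
#' Two stopping rules are used. The fit always stops once the maximum relative
#' change of any `alpha_i` in a sweep falls below `tol` (the rule used for the
#' negative benchmark). In `mode = "positive"` the fit additionally stops once
#' the mean overlap evaluated on `overlap_edges` has changed by less than
#' `overlap_tol` over the last `overlap_window` sweeps, the cheaper criterion
#' appropriate for the slower-converging union-graph constraint.
#'
#' Nodes with target degree 0 are excluded from the fit and their incident
#' pairs carry probability 0 (the `alpha -> Inf` limit). Multipliers are
#' clamped to `[1e-12, 1e12]`; a node whose target equals its number of
#' allowed partners is saturated and is driven to the lower clamp, `p -> 1`.
#'
#' @param constraint either a `normlap_network` (the sparse graph of allowed
#'   pairs, e.g. the union Q of the two networks) or a character vector of node
#'   identifiers meaning the complete graph on those nodes (held implicitly;
#'   all-pairs bookkeeping is never materialized per sweep beyond one
#'   `n x n` probability evaluation).
#' @param targets named non-negative numeric vector of target expected degrees;
#'   nodes of the constraint absent from `targets` get target 0.
#' @param mode `"negative"` or `"positive"`; selects the default iteration cap
#'   and, for `"positive"`, enables the mean-overlap stopping rule.
#' @param overlap_edges a `normlap_network` whose edges define the mean overlap
#'   monitored by the positive-mode stopping rule (ignored otherwise).
#' @param max_iter iteration cap; defaults to 1e5 (negative) or 5e5 (positive).
#' @param tol maximum relative change of `alpha` at which the fit is declared
#'   converged (default 1e-6).
#' @param overlap_tol,overlap_window positive-mode rule: stop when the mean
#'   overlap changes by less than `overlap_tol` (default 1 link) over the last
#'   `overlap_window` (default 1000) sweeps.
#' @param degree_tol maximum relative error of the fitted expected degrees
#'   accepted post-fit (default 1e-3); a larger error raises a solver error,
#'   which happens when the targets lie on or outside the feasible region.
#' @return an object of class `normlap_model`: `alpha` (named vector over
#'   constrained nodes with positive target), `targets`, `nodes` (the full
#'   constraint universe), `constraint_mode` (`"sparse"` or `"complete"`),
#'   `constraint_edges` (for sparse mode), and `convergence` (iterations,
#'   final residual, which rule stopped the fit).
#' @seealso [negative_model()], [positive_model()], [benchmark_moments()],
#'   [link_probability()]
#' @export
fit_link_probabilities <- function(constraint, targets,
                                   mode = c("negative", "positive"),
                                   overlap_edges = NULL,
                                   max_iter = NULL, tol = 1e-6,
                                   overlap_tol = 1, overlap_window = 1000L,
                                   degree_tol = 1e-3) {
  mode <- match.arg(mode)
  if (is.null(max_iter)) max_iter <- if (mode == "negative") 1e5 else 5e5
  stopifnot(max_iter > 0)
  if (is_network(constraint)) {
    constraint_mode <- "sparse"
    universe <- constraint$nodes
  } else {
    constraint_mode <- "complete"
    universe <- sort(unique(as.character(constraint)), method = "radix")
  }
  tg <- stats::setNames(numeric(length(universe)), universe)
  known <- intersect(names(targets), universe)
  tg[known] <- as.numeric(targets[known])
  if (any(tg < 0)) stop_input("target degrees must be non-negative")

  peel <- peel_forced_nodes(universe, tg, constraint_mode,
                            if (constraint_mode == "sparse") constraint$edges)
  active <- peel$active
  k <- peel$k
  n <- length(active)

  if (constraint_mode == "sparse") {
    ei <- match(peel$edges[, 1L], active)
    ej <- match(peel$edges[, 2L], active)
    # incidence: edges x nodes, to accumulate per-node expected degrees
    if (length(ei) > 0L) {
      inc <- Matrix::sparseMatrix(i = c(seq_along(ei), seq_along(ej)),
                                  j = c(ei, ej), x = 1,
                                  dims = c(length(ei), n))
    } else {
      inc <- NULL
    }
  } else {
    ei <- ej <- NULL
    inc <- NULL
  }

  mon <- NULL
  if (mode == "positive" && !is.null(overlap_edges) && n > 0L) {
    mi <- match(overlap_edges$edges[, 1L], active)
    mj <- match(overlap_edges$edges[, 2L], active)
    ok <- !is.na(mi) & !is.na(mj)
    if (constraint_mode == "sparse") {
      # only pairs that are allowed by Q can carry probability
      allowed <- paste(pmin(ei, ej), pmax(ei, ej))
      ok <- ok & (paste(pmin(mi, mj), pmax(mi, mj)) %in% allowed)
    }
    mon <- cbind(mi[ok], mj[ok])
    if (nrow(mon) == 0L) mon <- NULL
  }

  alpha <- rep(1, n)
  iter <- 0L
  residual <- Inf
  rule <- "alpha"
  mean_hist <- numeric(0)
  if (n > 0L) {
    repeat {
      iter <- iter + 1L
      if (constraint_mode == "sparse") {
        if (is.null(inc)) { expk <- numeric(n) } else {
          pe <- 1 / (1 + alpha[ei] * alpha[ej])
          expk <- as.numeric(Matrix::crossprod(inc, pe))
        }
      } else {
        pm <- 1 / (1 + outer(alpha, alpha))
        expk <- rowSums(pm) - diag(pm)
      }
      alpha_new <- pmin(pmax(alpha * expk / k, ALPHA_MIN), ALPHA_MAX)
      residual <- max(abs(alpha_new - alpha) / alpha)
      alpha <- alpha_new
      if (residual < tol) { rule <- "alpha"; break }
      if (!is.null(mon)) {
        mean_hist[iter] <- sum(1 / (1 + alpha[mon[, 1L]] * alpha[mon[, 2L]]))
        if (iter > overlap_window &&
            abs(mean_hist[iter] - mean_hist[iter - overlap_window]) < overlap_tol) {
          rule <- "overlap"; break
        }
      }
      if (iter >= max_iter) {
        stop_solver(sprintf(
          "no convergence after %d iterations (residual %.3g)", iter, residual),
          residual = residual, iterations = iter)
      }
    }
  }

  # post-fit validation: clamped multipliers can freeze the iteration at a
  # residual below tol without satisfying the constraints (targets on or
  # outside the feasible boundary); expected degrees are re-checked explicitly
  if (n > 0L) {
    if (constraint_mode == "sparse") {
      expk <- if (is.null(inc)) numeric(n) else
        as.numeric(Matrix::crossprod(inc, 1 / (1 + alpha[ei] * alpha[ej])))
    } else {
      pm <- 1 / (1 + outer(alpha, alpha))
      expk <- rowSums(pm) - diag(pm)
    }
    degree_err <- max(abs(expk - k) / pmax(k, 1))
    if (degree_err > degree_tol) {
      stop_solver(sprintf(
        "fitted expected degrees miss their targets (max relative error %.3g): targets lie on or outside the feasible region",
        degree_err), residual = residual, iterations = iter)
    }
  } else {
    degree_err <- 0
  }

  structure(list(
    alpha = stats::setNames(alpha, active),
    targets = tg,
    nodes = universe,
    constraint_mode = constraint_mode,
    constraint_edges = if (constraint_mode == "sparse") constraint$edges,
    forced_edges = peel$forced,
    mode = mode,
    convergence = list(iterations = iter, residual = residual, rule = rule,
                       degree_error = degree_err)
  ), class = "normlap_model")
}

# Exact preprocessing of the expected-degree equations: nodes with target 0
# carry p = 0 on all incident pairs (alpha -> Inf limit) and are removed;
# nodes whose target equals their current number of allowed partners are
# saturated, their incident pairs carry p = 1 exactly (alpha -> 0 limit),
# and each partner's target drops by 1. Removal can saturate or zero further
# nodes, so the peel iterates to a fixed point; the remaining interior
# problem has 0 < k_i < (number of partners) for every node and is solved
# iteratively. Returns the interior (active nodes, residual targets, residual
# sparse edges) plus the forced p = 1 edge list.
peel_forced_nodes <- function(universe, tg, constraint_mode, edges) {
  active <- names(tg)[tg > 1e-12]
  k <- tg[active]
  forced <- list()
  if (constraint_mode == "sparse") {
    keep <- edges[, 1L] %in% active & edges[, 2L] %in% active
    ea <- edges[keep, 1L]; eb <- edges[keep, 2L]
  }
  repeat {
    n <- length(active)
    if (constraint_mode == "sparse") {
      np <- stats::setNames(numeric(n), active)
      if (length(ea) > 0L) {
        tab <- table(c(ea, eb))
        np[names(tab)] <- as.numeric(tab)
      }
    } else {
      np <- stats::setNames(rep(n - 1, n), active)
    }
    bad <- which(k > np + 1e-9)
    if (length(bad) > 0L) {
      stop_input(sprintf(
        "infeasible target for node '%s': degree %g exceeds %g allowed partners",
        active[bad[1L]], k[bad[1L]], np[bad[1L]]))
    }
    sat <- which(k > np - 1e-9)  # saturated: target equals partner count
    if (length(sat) > 0L) {
      i <- active[sat[1L]]
      if (constraint_mode == "sparse") {
        hit <- ea == i | eb == i
        partners <- ifelse(ea[hit] == i, eb[hit], ea[hit])
        if (length(partners) > 0L) {
          forced[[length(forced) + 1L]] <- cbind(pmin(i, partners),
                                                 pmax(i, partners))
        }
        ea <- ea[!hit]; eb <- eb[!hit]
      } else {
        partners <- setdiff(active, i)
        if (length(partners) > 0L) {
          forced[[length(forced) + 1L]] <- cbind(pmin(i, partners),
                                                 pmax(i, partners))
        }
      }
      k[partners] <- k[partners] - 1
      drop <- match(i, active)
      active <- active[-drop]; k <- k[-drop]
    }
    zero <- which(k < 1e-12)
    if (length(zero) > 0L) {
      rm_nodes <- active[zero]
      if (any(k[zero] < -1e-9)) {
        stop_input("inconsistent targets: residual degree below zero after peeling")
      }
      active <- active[-zero]; k <- k[-zero]
      if (constraint_mode == "sparse") {
        keep <- !(ea %in% rm_nodes) & !(eb %in% rm_nodes)
        ea <- ea[keep]; eb <- eb[keep]
      }
    } else if (length(sat) == 0L) {
      break
    }
  }
  forced <- if (length(forced) > 0L) do.call(rbind, forced) else
    matrix(character(0), 0, 2)
  list(active = active, k = k, forced = forced,
       edges = if (constraint_mode == "sparse") cbind(ea, eb))
}

#' @export
print.normlap_model <- function(x, ...) {
  cat(sprintf(
    "<normlap %s-benchmark model: %s constraint, %d nodes (%d constrained), %d iterations, residual %.2e (%s rule)>\n",
    x$mode, x$constraint_mode, length(x$nodes), length(x$alpha),
    x$convergence$iterations, x$convergence$residual, x$convergence$rule))
  invisible(x)
}

#' Negative-benchmark model: degree-preserving randomization of a network
#'
#' Fits the maximum-entropy model on the complete graph over the nodes of `g`
#' with the degrees of `g` as soft constraints — the null model in which only
#' the expected degree sequence of `g` is retained and all structure is
#' destroyed.
#'
#' @param g a `normlap_network` with at least one edge.
#' @param ... passed to [fit_link_probabilities()].
#' @return a `normlap_model`.
#' @export
negative_model <- function(g, ...) {
  stopifnot(is_network(g))
  if (n_edges(g) == 0L) stop_input("network has no edges")
  fit_link_probabilities(g$nodes, degrees(g), mode = "negative", ...)
}

#' Positive-benchmark model: resampling the reference from the union
#'
#' Fits the maximum-entropy model whose allowed pairs are the edges of the
#' union Q of `g` and `m`, with the degrees of `g` as soft constraints. Samples
#' from this ensemble are the best-case versions of `g`: they live on the
#' combined support of both maps and carry `g`'s degree sequence on average.
#' Nodes of `m` absent from `g` get target degree 0, so their incident pairs
#' carry probability 0.
#'
#' @param g reference network (the side being randomized); at least one edge.
#' @param m network of interest; overlap moments are later evaluated on its
#'   edges, and its edge set is used by the positive-mode stopping rule.
#' @param ... passed to [fit_link_probabilities()].
#' @return a `normlap_model`.
#' @export
positive_model <- function(g, m, ...) {
  stopifnot(is_network(g), is_network(m))
  if (n_edges(g) == 0L) stop_input("reference network has no edges")
  q <- union_graph(g, m)
  fit_link_probabilities(q, degrees(g), mode = "positive", overlap_edges = m, ...)
}

#' Link probabilities of a fitted model on given node pairs
#'
#' @param model a `normlap_model`.
#' @param a,b character vectors of endpoints (recycled to equal length).
#' @return numeric vector of probabilities; 0 for pairs not allowed by the
#'   constraint, for pairs involving nodes outside the model, and for pairs
#'   with a zero-target endpoint.
#' @export
link_probability <- function(model, a, b) {
  stopifnot(inherits(model, "normlap_model"))
  if (length(a) != length(b)) {
    len <- max(length(a), length(b))
    a <- rep_len(a, len); b <- rep_len(b, len)
  }
  ai <- model$alpha[a]; bj <- model$alpha[b]
  p <- ifelse(is.na(ai) | is.na(bj) | a == b, 0, 1 / (1 + ai * bj))
  key <- paste(pmin(a, b), pmax(a, b), sep = "\t")
  if (model$constraint_mode == "sparse") {
    ekey <- paste(model$constraint_edges[, 1L], model$constraint_edges[, 2L],
                  sep = "\t")
    p[!(key %in% ekey)] <- 0
  }
  if (nrow(model$forced_edges) > 0L) {
    fkey <- paste(model$forced_edges[, 1L], model$forced_edges[, 2L],
                  sep = "\t")
    p[key %in% fkey] <- 1
  }
  unname(p)
}

#' Analytic overlap moments of a benchmark ensemble
#'
#' The overlap between a sample from the fitted ensemble and the network `m`
#' is a sum of independent Bernoulli links over the edges of `m`, so its mean
#' is `sum(p_ij)` and its variance `sum(p_ij (1 - p_ij))` over those edges —
#' no sampling needed.
#'
#' @param model a fitted `normlap_model`.
#' @param m the network of interest whose edges are scored.
#' @param kind `"negative"` or `"positive"` label carried into reports;
#'   defaults to the model's mode.
#' @param randomized_side optional label of the network whose degrees were the
#'   soft constraints.
#' @return an object of class `normlap_benchmark` with fields `mean`,
#'   `variance`, `sd`, `kind`, `randomized_side`, `n_edges`.
#' @export
benchmark_moments <- function(model, m, kind = NULL, randomized_side = NULL) {
  stopifnot(inherits(model, "normlap_model"), is_network(m))
  p <- link_probability(model, m$edges[, 1L], m$edges[, 2L])
  v <- sum(p * (1 - p))
  structure(list(mean = sum(p), variance = v, sd = sqrt(v),
                 kind = if (is.null(kind)) model$mode else kind,
                 randomized_side = randomized_side,
                 n_edges = n_edges(m)),
            class = "normlap_benchmark")
}

#' @export
print.normlap_benchmark <- function(x, ...) {
  cat(sprintf("<%s benchmark: mean %.3f, sd %.3f over %d edges%s>\n",
              x$kind, x$mean, x$sd, x$n_edges,
              if (is.null(x$randomized_side)) "" else
                paste0(", randomized side: ", x$randomized_side)))
  invisible(x)
}

model_pairs <- function(model) {
  # all pairs that can carry positive probability, as a 2-column name matrix:
  # forced p = 1 pairs plus pairs between fitted (interior) nodes
  act <- names(model$alpha)
  if (model$constraint_mode == "sparse") {
    ok <- model$constraint_edges[, 1L] %in% act &
      model$constraint_edges[, 2L] %in% act
    free <- model$constraint_edges[ok, , drop = FALSE]
  } else {
    n <- length(act)
    if (n >= 2L) {
      idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      free <- cbind(act[idx[, 1L]], act[idx[, 2L]])
    } else {
      free <- matrix(character(0), 0, 2)
    }
  }
  unname(rbind(model$forced_edges, free))
}

#' Draw one network from a fitted ensemble
#'
#' Each allowed pair is included independently with its model probability.
#'
#' @param model a fitted `normlap_model`.
#' @param seed integer seed; the draw is a pure function of (model, seed).
#' @param name optional label for the sample.
#' @return a `normlap_network` over the model's node universe.
#' @export
sample_network <- function(model, seed, name = NULL) {
  stopifnot(inherits(model, "normlap_model"))
  pairs <- model_pairs(model)
  p <- link_probability(model, pairs[, 1L], pairs[, 2L])
  keep <- with_seed(seed, stats::runif(length(p)) < p)
  network(pairs[keep, , drop = FALSE], nodes = model$nodes, name = name)
}

#' Serialize a fitted model to JSON
#'
#' @param model a `normlap_model`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
model_to_json <- function(model, path = NULL) {
  doc <- list(mode = model$mode,
              constraint_mode = model$constraint_mode,
              alphas = as.list(model$alpha),
              targets = as.list(model$targets),
              convergence = model$convergence)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

# run code with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
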