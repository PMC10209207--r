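stop_degenerate <- function(msg) {
  stop(structure(class = c("normlap_degenerate_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Absolute z-score of an observed overlap against a benchmark
#'
#' `z = |benchmark mean - observed| / benchmark SD`. When the benchmark SD is
#' 0 the score is 0 if the observed overlap equals the mean exactly and `Inf`
#' otherwise.
#'
#' @param benchmark a `normlap_benchmark` (or any list with `mean` and `sd`).
#' @param observed integer observed overlap.
#' @return non-negative numeric (possibly `Inf`).
#' @export
z_score <- function(benchmark, observed) {
  if (benchmark$sd == 0) {
    if (benchmark$mean == observed) 0 else Inf
  } else {
    abs(benchmark$mean - observed) / benchmark$sd
  }
}

#' One-sided p-value from an absolute z-score
#'
#' Upper tail of the standard normal: `p = 1 - Phi(z)`, in `(0, 0.5]` for
#' finite `z >= 0` and 0 for the `Inf` sentinel.
#'
#' @param z non-negative numeric.
#' @return p-value.
#' @export
one_sided_p <- function(z) {
  if (any(z < 0)) stop_input("z must be non-negative")
  stats::pnorm(z, lower.tail = FALSE)
}

#' Normlap score and its standard deviation
#'
#' The observed overlap rescaled between the two benchmark means:
#' `(observed - negative mean) / (positive mean - negative mean)`, so 0 sits at
#' the null expectation and 1 at the best-case expectation. The SD is obtained
#' by first-order (delta-method) propagation of the two analytic benchmark
#' variances, treating the benchmarks as independent and the observed overlap
#' as fixed:
#' `sd^2 = ((observed - pos.mean)^2 * neg.var + (observed - neg.mean)^2 * pos.var)
#'         / (pos.mean - neg.mean)^4`.
#' The score is not clipped to \[0, 1\]; values outside the range flag
#' anomalies.
#'
#' @param observed integer observed overlap.
#' @param negative,positive `normlap_benchmark` objects (means must differ).
#' @return list with `score` and `sd`.
#' @export
normlap_score <- function(observed, negative, positive) {
  span <- positive$mean - negative$mean
  if (span == 0) {
    stop_degenerate("positive and negative benchmark means coincide; score undefined")
  }
  score <- (observed - negative$mean) / span
  var <- ((observed - positive$mean)^2 * negative$variance +
            (observed - negative$mean)^2 * positive$variance) / span^4
  list(score = score, sd = sqrt(var))
}

#' Classify a comparison as compatible, incompatible, no-signal or undefined
#'
#' Two networks are *compatible* when the observed overlap is significantly
#' above the negative benchmark and not significantly below the positive one:
#' all remaining disagreement is accounted for by degree inconsistency. If the
#' overlap does not beat the null there is *no signal*; if it does but falls
#' significantly short of the best case the pair is *incompatible*. When the
#' two networks have no common support (observed overlap and positive mean
#' both 0) no conclusion is drawn.
#'
#' @param observed integer observed overlap.
#' @param positive_mean positive-benchmark mean.
#' @param p_above_negative one-sided p for "observed above the null".
#' @param p_below_positive one-sided p for "observed below the best case".
#' @param alpha significance level (default 0.05).
#' @return one of `"undefined"`, `"no_signal"`, `"compatible"`,
#'   `"incompatible"`.
#' @export
classify <- function(observed, positive_mean, p_above_negative,
                     p_below_positive, alpha = 0.05) {
  if (observed == 0 && positive_mean == 0) return("undefined")
  if (p_above_negative >= alpha) return("no_signal")
  if (p_below_positive >= alpha) return("compatible")
  "incompatible"
}

# one side of a comparison: randomize `ref`, evaluate moments on `other`
benchmark_side <- function(ref, other, side_label, ...) {
  neg <- benchmark_moments(negative_model(ref, ...), other,
                           randomized_side = side_label)
  pos <- benchmark_moments(positive_model(ref, other, ...), other,
                           randomized_side = side_label)
  list(negative = neg, positive = pos)
}

#' Compare two networks: benchmarks, Normlap score, significance, class
#'
#' Computes the observed overlap, the negative (degree-preserving null) and
#' positive (union-resampling best case) benchmark moments, the Normlap score
#' with its SD, one-sided significance against both benchmarks, and the
#' compatibility classification.
#'
#' When `reference` names one of the networks, only that side is randomized
#' (its degrees are the soft constraints) and the moments are evaluated on the
#' other network's edges. Without a reference, both directions are computed
#' and, independently for each benchmark, the direction with the lower
#' absolute z-score is kept; on a tie the direction randomizing the larger
#' network (more edges) wins, then the first argument.
#'
#' One-sided bookkeeping: the overlap is tested as *above* the negative
#' benchmark only when it exceeds the negative mean (otherwise `p = 1`), and
#' as *below* the positive benchmark only when it falls short of the positive
#' mean (otherwise `p = 1`).
#'
#' @param a,b `normlap_network` objects with at least one edge each.
#' @param reference `NULL`, `"a"`, `"b"`, or the `name` of one of the two
#'   networks: the side to randomize.
#' @param alpha significance level for the classification (default 0.05).
#' @param ... solver options passed to [fit_link_probabilities()] (e.g.
#'   `max_iter`, `tol`).
#' @return an object of class `normlap_comparison`: `observed`, `negative`,
#'   `positive` (the selected `normlap_benchmark`s), `normlap`, `normlap_sd`,
#'   `z_negative`, `z_positive`, `p_above_negative`, `p_below_positive`,
#'   `classification`, `labels`.
#' @export
compare_networks <- function(a, b, reference = NULL, alpha = 0.05, ...) {
  stopifnot(is_network(a), is_network(b))
  if (n_edges(a) == 0L || n_edges(b) == 0L) {
    stop_input("both networks must have at least one edge")
  }
  la <- if (is.null(a$name)) "a" else a$name
  lb <- if (is.null(b$name)) "b" else b$name
  observed <- observed_overlap(a, b)

  if (!is.null(reference)) {
    side <- if (identical(reference, "a") || identical(reference, la)) "a"
            else if (identical(reference, "b") || identical(reference, lb)) "b"
            else stop_input(sprintf("unknown reference '%s'", reference))
    bm <- if (side == "a") benchmark_side(a, b, la, ...)
          else benchmark_side(b, a, lb, ...)
    negative <- bm$negative; positive <- bm$positive
  } else {
    bm_a <- benchmark_side(a, b, la, ...)
    bm_b <- benchmark_side(b, a, lb, ...)
    pick <- function(x, y) {
      zx <- z_score(x, observed); zy <- z_score(y, observed)
      if (zx < zy) return(x)
      if (zy < zx) return(y)
      if (n_edges(a) >= n_edges(b)) x else y  # tie: randomize the larger side
    }
    negative <- pick(bm_a$negative, bm_b$negative)
    positive <- pick(bm_a$positive, bm_b$positive)
  }

  z_neg <- z_score(negative, observed)
  z_pos <- z_score(positive, observed)
  p_above <- if (observed > negative$mean) one_sided_p(z_neg) else 1
  p_below <- if (observed < positive$mean) one_sided_p(z_pos) else 1

  if (positive$mean == negative$mean) {
    if (observed == 0 && positive$mean == 0) {
      nl <- list(score = NA_real_, sd = NA_real_)
    } else {
      stop_degenerate(sprintf(
        "benchmark means coincide (%g) with nonzero support; score undefined",
        positive$mean))
    }
  } else {
    nl <- normlap_score(observed, negative, positive)
  }

  structure(list(
    observed = observed,
    negative = negative,
    positive = positive,
    normlap = nl$score,
    normlap_sd = nl$sd,
    z_negative = z_neg,
    z_positive = z_pos,
    p_above_negative = p_above,
    p_below_positive = p_below,
    classification = classify(observed, positive$mean, p_above, p_below, alpha),
    alpha = alpha,
    labels = c(a = la, b = lb)
  ), class = "normlap_comparison")
}

#' @export
print.normlap_comparison <- function(x, ...) {
  cat(sprintf("Comparison of '%s' vs '%s'\n", x$labels["a"], x$labels["b"]))
  cat(sprintf("  observed overlap : %d\n", x$observed))
  cat(sprintf("  negative benchmark: %.2f +/- %.2f (randomized: %s, z = %.2f, p = %.3g)\n",
              x$negative$mean, x$negative$sd, x$negative$randomized_side,
              x$z_negative, x$p_above_negative))
  cat(sprintf("  positive benchmark: %.2f +/- %.2f (randomized: %s, z = %.2f, p = %.3g)\n",
              x$positive$mean, x$positive$sd, x$positive$randomized_side,
              x$z_positive, x$p_below_positive))
  if (is.na(x$normlap)) {
    cat("  Normlap score    : undefined (no common support)\n")
  } else {
    cat(sprintf("  Normlap score    : %.1f%% +/- %.1f%%\n",
                100 * x$normlap, 100 * x$normlap_sd))
  }
  cat(sprintf("  classification   : %s\n", x$classification))
  invisible(x)
}

#' Serialize a comparison result to JSON
#'
#' @param x a `normlap_comparison`.
#' @param path optional output path.
#' @return JSON string (invisibly when written to a file).
#' @export
comparison_to_json <- function(x, path = NULL) {
  strip <- function(b) list(mean = b$mean, sd = b$sd, variance = b$variance,
                            randomized_side = b$randomized_side)
  doc <- list(
    labels = as.list(x$labels),
    observed = x$observed,
    negative = strip(x$negative),
    positive = strip(x$positive),
    normlap = x$normlap,
    normlap_sd = x$normlap_sd,
    z_negative = x$z_negative,
    z_positive = x$z_positive,
    p_above_negative = x$p_above_negative,
    p_below_positive = x$p_below_positive,
    classification = x$classification,
    alpha = x$alpha
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
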