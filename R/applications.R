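#' Precision of a thresholded candidate network
#'
#' `TP / D`, where `TP` is the overlap with the reference and `D` the number of
#' candidate links above the threshold.
#'
#' @param tp true positives (overlap), `0 <= tp <= d`.
#' @param d total retained links; must be positive.
#' @return precision in \[0, 1\].
#' @export
precision <- function(tp, d) {
  if (d == 0) stop_input("precision undefined for an empty selection (d = 0)")
  stopifnot(tp >= 0, tp <= d)
  tp / d
}

# default grid: unique scores coarsened to <= grid_size points by quantiles
score_grid <- function(scores, grid_size = 50L) {
  u <- sort(unique(scores))
  if (length(u) <= grid_size) return(u)
  qs <- stats::quantile(scores, probs = seq(0, 1, length.out = grid_size),
                        type = 1, names = FALSE)
  sort(unique(qs))
}

# walk thresholds from strictest down; the selected threshold is the loosest
# cutoff in the first contiguous compatible run (where the filtered network
# "becomes" compatible before losing compatibility again)
select_threshold <- function(thresholds, classification) {
  ord <- order(thresholds, decreasing = TRUE)
  cls <- classification[ord]
  first <- which(cls == "compatible")[1L]
  if (is.na(first)) return(NA_real_)
  run_end <- first
  while (run_end < length(cls) && cls[run_end + 1L] == "compatible") {
    run_end <- run_end + 1L
  }
  thresholds[ord][run_end]
}

threshold_curve_row <- function(threshold, cmp, link_count, extra = NULL) {
  data.frame(
    threshold = threshold,
    link_count = link_count,
    observed = cmp$observed,
    precision = if (link_count > 0) cmp$observed / link_count else NA_real_,
    neg_mean = cmp$negative$mean, neg_sd = cmp$negative$sd,
    pos_mean = cmp$positive$mean, pos_sd = cmp$positive$sd,
    normlap = cmp$normlap, normlap_sd = cmp$normlap_sd,
    z_neg = cmp$z_negative, z_pos = cmp$z_positive,
    p_neg = cmp$p_above_negative, p_pos = cmp$p_below_positive,
    classification = cmp$classification,
    stringsAsFactors = FALSE
  )
}

#' Threshold a scored candidate network against a reference network
#'
#' Scans score cutoffs from strict to loose; at each cutoff the candidate links
#' at or above the cutoff form a network that is compared to the reference
#' (the reference is the randomized side). The selected threshold is the
#' loosest cutoff at which the filtered network is still compatible with the
#' reference before compatibility is first lost — the point where the ranked
#' candidate list stops being explainable as a degree-inconsistent sample of
#' the reference's support.
#'
#' @param s a `normlap_scored` candidate network.
#' @param reference a `normlap_network` with at least one edge.
#' @param grid optional numeric vector of cutoffs; default: unique scores
#'   coarsened to at most `grid_size` quantile points.
#' @param grid_size maximum number of default grid points (default 50).
#' @param alpha significance level (default 0.05).
#' @param ... solver options passed down to [compare_networks()].
#' @return an object of class `normlap_threshold_curve`: a `curve` data frame
#'   (one row per cutoff: link count, observed overlap, precision = TP/D,
#'   benchmark moments, Normlap score +/- SD, classification) and
#'   `selected_threshold` (`NA` when never compatible).
#' @export
threshold_scored_network <- function(s, reference, grid = NULL, grid_size = 50L,
                                     alpha = 0.05, ...) {
  if (!inherits(s, "normlap_scored")) stop_input("`s` must be a scored network")
  stopifnot(is_network(reference))
  if (n_edges(s) == 0L || n_edges(reference) == 0L) {
    stop_input("scored network and reference must be non-empty")
  }
  if (is.null(grid)) grid <- score_grid(s$score, grid_size)
  rows <- vector("list", length(grid))
  any_nonempty <- FALSE
  for (i in seq_along(grid)) {
    t <- grid[i]
    filt <- filter_by_threshold(s, t, name = sprintf("filtered@%g", t))
    lc <- n_edges(filt)
    if (lc == 0L) {
      rows[[i]] <- data.frame(
        threshold = t, link_count = 0L, observed = 0L, precision = NA_real_,
        neg_mean = NA_real_, neg_sd = NA_real_, pos_mean = NA_real_,
        pos_sd = NA_real_, normlap = NA_real_, normlap_sd = NA_real_,
        z_neg = NA_real_, z_pos = NA_real_, p_neg = NA_real_, p_pos = NA_real_,
        classification = "undefined", stringsAsFactors = FALSE)
      next
    }
    any_nonempty <- TRUE
    cmp <- compare_networks(filt, reference, reference = "b", alpha = alpha, ...)
    rows[[i]] <- threshold_curve_row(t, cmp, lc)
  }
  if (!any_nonempty) {
    stop_input("no grid point leaves a non-empty filtered network")
  }
  curve <- do.call(rbind, rows)
  curve <- curve[order(curve$threshold, decreasing = TRUE), , drop = FALSE]
  rownames(curve) <- NULL
  structure(list(curve = curve,
                 selected_threshold =
                   select_threshold(curve$threshold, curve$classification)),
            class = "normlap_threshold_curve")
}

#' Validate a new network against a score-ranked existing network
#'
#' For each cutoff the existing scored network is filtered to its links at or
#' above the cutoff and used as the reference; the new dataset is compared to
#' that reference (the reference is the randomized side). Alongside the
#' Normlap score the curve reports the *positive fraction*: the overlap
#' divided by the number of testable links of the new dataset (those with both
#' endpoints among the reference's nodes). The selected threshold is the
#' loosest cutoff at which the new dataset is compatible with the thresholded
#' reference before compatibility is first lost.
#'
#' @param new the network to validate; at least one edge.
#' @param scored the score-ranked existing network.
#' @param grid,grid_size,alpha,... as in [threshold_scored_network()].
#' @return a `normlap_threshold_curve` whose curve additionally carries
#'   `testable` and `positive_fraction` columns.
#' @export
validate_with_scored_network <- function(new, scored, grid = NULL,
                                         grid_size = 50L, alpha = 0.05, ...) {
  stopifnot(is_network(new))
  if (!inherits(scored, "normlap_scored")) {
    stop_input("`scored` must be a scored network")
  }
  if (n_edges(new) == 0L || n_edges(scored) == 0L) {
    stop_input("both networks must be non-empty")
  }
  if (is.null(grid)) grid <- score_grid(scored$score, grid_size)
  rows <- vector("list", length(grid))
  any_nonempty <- FALSE
  for (i in seq_along(grid)) {
    t <- grid[i]
    ref <- filter_by_threshold(scored, t, name = sprintf("reference@%g", t))
    lc <- n_edges(ref)
    testable <- if (lc > 0L) {
      sum(new$edges[, 1L] %in% ref$nodes & new$edges[, 2L] %in% ref$nodes)
    } else 0L
    if (lc == 0L) {
      rows[[i]] <- data.frame(
        threshold = t, link_count = 0L, observed = 0L, testable = 0L,
        positive_fraction = NA_real_, precision = NA_real_,
        neg_mean = NA_real_, neg_sd = NA_real_, pos_mean = NA_real_,
        pos_sd = NA_real_, normlap = NA_real_, normlap_sd = NA_real_,
        z_neg = NA_real_, z_pos = NA_real_, p_neg = NA_real_, p_pos = NA_real_,
        classification = "undefined", stringsAsFactors = FALSE)
      next
    }
    any_nonempty <- TRUE
    cmp <- compare_networks(new, ref, reference = "b", alpha = alpha, ...)
    row <- threshold_curve_row(t, cmp, lc)
    row$testable <- testable
    row$positive_fraction <- if (testable > 0L) cmp$observed / testable else NA_real_
    rows[[i]] <- row[, c("threshold", "link_count", "observed", "testable",
                         "positive_fraction", "precision", "neg_mean", "neg_sd",
                         "pos_mean", "pos_sd", "normlap", "normlap_sd",
                         "z_neg", "z_pos", "p_neg", "p_pos", "classification")]
  }
  if (!any_nonempty) {
    stop_input("no grid point leaves a non-empty reference network")
  }
  curve <- do.call(rbind, rows)
  curve <- curve[order(curve$threshold, decreasing = TRUE), , drop = FALSE]
  rownames(curve) <- NULL
  structure(list(curve = curve,
                 selected_threshold =
                   select_threshold(curve$threshold, curve$classification)),
            class = "normlap_threshold_curve")
}

#' @export
print.normlap_threshold_curve <- function(x, ...) {
  cat(sprintf("<threshold curve: %d cutoffs, selected threshold: %s>\n",
              nrow(x$curve),
              if (is.na(x$selected_threshold)) "none (never compatible)"
              else format(x$selected_threshold)))
  print(utils::head(x$curve, 10))
  invisible(x)
}

#' Write a threshold curve as TSV
#'
#' @param x a `normlap_threshold_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_threshold_curve <- function(x, path) {
  utils::write.table(x$curve, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' All-pairs agreement matrix over a collection of networks
#'
#' Runs [compare_networks()] (no fixed reference: lower absolute-z rule) on
#' every unordered pair and assembles: the Normlap score matrix, the overlap
#' fraction matrix (observed overlap divided by the smaller network's edge
#' count, the conventional display normalization), the classification matrix,
#' a per-pair table, and the agreement edges — the compatible pairs, which
#' form the agreement network. Pairs with no common support are `undefined`
#' and carry no edge.
#'
#' @param nets list of at least two `normlap_network` objects.
#' @param labels optional character labels; defaults to network names or
#'   `net1`, `net2`, ...
#' @param alpha significance level (default 0.05).
#' @param ... solver options passed to [compare_networks()].
#' @return an object of class `normlap_agreement`: `labels`, `pairs` (data
#'   frame, lexicographic label order), matrices `normlap`, `normlap_sd`,
#'   `overlap_fraction`, `classification`, and `agreement_edges` (two-column
#'   character matrix of compatible pairs).
#' @export
agreement_matrix <- function(nets, labels = NULL, alpha = 0.05, ...) {
  if (!is.list(nets) || length(nets) < 2L) {
    stop_input("need at least two networks")
  }
  stopifnot(all(vapply(nets, is_network, TRUE)))
  if (is.null(labels)) {
    labels <- vapply(seq_along(nets), function(i) {
      if (!is.null(nets[[i]]$name)) nets[[i]]$name else sprintf("net%d", i)
    }, "")
  }
  if (anyDuplicated(labels)) stop_input("network labels must be unique")
  n <- length(nets)
  m_score <- m_sd <- m_frac <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  m_cls <- matrix(NA_character_, n, n, dimnames = list(labels, labels))
  diag(m_cls) <- "compatible"; diag(m_score) <- 1; diag(m_frac) <- 1
  rows <- list()
  edges <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      cmp <- compare_networks(nets[[i]], nets[[j]], alpha = alpha, ...)
      frac <- cmp$observed / min(n_edges(nets[[i]]), n_edges(nets[[j]]))
      m_score[i, j] <- m_score[j, i] <- cmp$normlap
      m_sd[i, j] <- m_sd[j, i] <- cmp$normlap_sd
      m_frac[i, j] <- m_frac[j, i] <- frac
      m_cls[i, j] <- m_cls[j, i] <- cmp$classification
      li <- labels[i]; lj <- labels[j]
      if (li > lj) { tmp <- li; li <- lj; lj <- tmp }
      rows[[length(rows) + 1L]] <- data.frame(
        labelA = li, labelB = lj, observed = cmp$observed,
        overlap_fraction = frac,
        neg_mean = cmp$negative$mean, neg_sd = cmp$negative$sd,
        pos_mean = cmp$positive$mean, pos_sd = cmp$positive$sd,
        normlap = cmp$normlap, normlap_sd = cmp$normlap_sd,
        z_neg = cmp$z_negative, z_pos = cmp$z_positive,
        p_neg = cmp$p_above_negative, p_pos = cmp$p_below_positive,
        classification = cmp$classification, stringsAsFactors = FALSE)
      if (cmp$classification == "compatible") {
        edges[[length(edges) + 1L]] <- c(li, lj)
      }
    }
  }
  pairs <- do.call(rbind, rows)
  pairs <- pairs[order(pairs$labelA, pairs$labelB), , drop = FALSE]
  rownames(pairs) <- NULL
  agreement_edges <- if (length(edges) > 0L) do.call(rbind, edges) else
    matrix(character(0), 0, 2)
  colnames(agreement_edges) <- c("labelA", "labelB")
  structure(list(labels = labels, pairs = pairs, normlap = m_score,
                 normlap_sd = m_sd, overlap_fraction = m_frac,
                 classification = m_cls, agreement_edges = agreement_edges),
            class = "normlap_agreement")
}

#' @export
print.normlap_agreement <- function(x, ...) {
  cat(sprintf("<agreement matrix over %d networks: %d compatible pairs>\n",
              length(x$labels), nrow(x$agreement_edges)))
  print(x$pairs[, c("labelA", "labelB", "observed", "normlap",
                    "classification")])
  invisible(x)
}

#' Write an agreement matrix: pairwise TSV and agreement edge list
#'
#' @param x a `normlap_agreement`.
#' @param pairs_path path for the per-pair table (TSV, one row per unordered
#'   pair).
#' @param edges_path optional path for the agreement network's edge list
#'   (two-column TSV of compatible pairs).
#' @return `pairs_path`, invisibly.
#' @export
write_agreement_matrix <- function(x, pairs_path, edges_path = NULL) {
  utils::write.table(x$pairs, pairs_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(edges_path)) {
    utils::write.table(x$agreement_edges, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(pairs_path)
}
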