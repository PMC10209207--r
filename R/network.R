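#' Construct an undirected simple network from an edge table
#'
#' A `normlap_network` is a set of string node identifiers plus a set of
#' undirected edges stored canonically (lexicographically smaller endpoint
#' first). Self-loops and duplicate edges are dropped; the dropped counts are
#' kept as attributes. Nodes may be isolated (degree 0).
#'
#' @param edges two-column character matrix or data.frame of endpoints, or
#'   `NULL` for an edgeless network.
#' @param nodes optional character vector of node identifiers to include even
#'   when isolated; endpoints of `edges` are always included.
#' @param scores optional numeric vector, one finite score per row of `edges`;
#'   when given the result is also a `normlap_scored` network. Duplicate edges
#'   keep the highest score.
#' @param name optional label used in reports.
#' @return an object of class `normlap_network` (and `normlap_scored` when
#'   scores are supplied) with fields `nodes` (sorted character), `edges`
#'   (two-column character matrix, canonical, sorted), optionally `score`,
#'   and attributes `n_self_loops`, `n_duplicates`.
#' @export
network <- function(edges = NULL, nodes = NULL, scores = NULL, name = NULL) {
  if (is.null(edges) || NROW(edges) == 0L) {
    a <- character(0); b <- character(0)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) < 2L) stop("`edges` must have two columns")
    a <- as.character(edges[, 1L]); b <- as.character(edges[, 2L])
  }
  if (!is.null(scores)) {
    scores <- as.numeric(scores)
    if (length(scores) != length(a)) stop("one score per edge is required")
    if (any(!is.finite(scores))) stop("scores must be finite")
  }
  loop <- a == b
  n_loops <- sum(loop)
  if (n_loops > 0L) {
    a <- a[!loop]; b <- b[!loop]
    if (!is.null(scores)) scores <- scores[!loop]
  }
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b, sep = "\t")
  if (!is.null(scores) && anyDuplicated(key)) {
    # keep the highest-confidence score for a repeated pair
    ord <- order(key, -scores)
    keep <- ord[!duplicated(key[ord])]
    keep <- sort(keep)
  } else {
    keep <- which(!duplicated(key))
  }
  n_dup <- length(key) - length(keep)
  a <- a[keep]; b <- b[keep]
  if (!is.null(scores)) scores <- scores[keep]
  ord <- order(a, b, method = "radix")
  a <- a[ord]; b <- b[ord]
  if (!is.null(scores)) scores <- scores[ord]
  all_nodes <- sort(unique(c(as.character(nodes), a, b)), method = "radix")
  obj <- list(
    nodes = all_nodes,
    edges = cbind(a = a, b = b),
    name = name
  )
  if (!is.null(scores)) obj$score <- scores
  structure(obj,
            n_self_loops = n_loops, n_duplicates = n_dup,
            class = c(if (!is.null(scores)) "normlap_scored", "normlap_network"))
}

#' @export
print.normlap_network <- function(x, ...) {
  lbl <- if (is.null(x$name)) "" else paste0(" '", x$name, "'")
  kind <- if (inherits(x, "normlap_scored")) "scored network" else "network"
  cat(sprintf("<normlap %s%s: %d nodes, %d edges>\n",
              kind, lbl, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

n_edges <- function(net) nrow(net$edges)

edge_keys <- function(net) {
  if (nrow(net$edges) == 0L) return(character(0))
  paste(net$edges[, 1L], net$edges[, 2L], sep = "\t")
}

is_network <- function(x) inherits(x, "normlap_network")

stop_input <- function(msg) {
  stop(structure(class = c("normlap_input_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Read an undirected edge list from a TSV file
#'
#' Expects UTF-8 lines `nodeA<TAB>nodeB[<TAB>score]` (any whitespace accepted
#' as separator); lines starting with `#` and blank lines are ignored.
#' Self-interactions and duplicate pairs are dropped and counted; a one-line
#' summary is emitted via [message()].
#'
#' @param path file path.
#' @param scored if `TRUE`, require a numeric third column and return a scored
#'   network.
#' @param name optional label; defaults to the file name.
#' @param id_map optional named character vector, or path to a two-column TSV,
#'   mapping raw identifiers to harmonized ones; unmapped identifiers are kept
#'   as-is.
#' @param quiet suppress the summary message.
#' @return a `normlap_network` (or `normlap_scored`).
#' @export
read_edge_list <- function(path, scored = FALSE, name = NULL, id_map = NULL,
                           quiet = FALSE) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop_input(sprintf("line %d of %s: expected at least 2 fields, got %d",
                       idx[which(nf < 2L)[1L]], path, nf[nf < 2L][1L]))
  }
  if (scored && any(nf < 3L)) {
    stop_input(sprintf("line %d of %s: scored input requires a third column",
                       idx[which(nf < 3L)[1L]], path))
  }
  a <- vapply(fields, `[`, "", 1L)
  b <- vapply(fields, `[`, "", 2L)
  sc <- NULL
  if (scored) {
    raw <- vapply(fields, `[`, "", 3L)
    sc <- suppressWarnings(as.numeric(raw))
    if (any(is.na(sc))) {
      stop_input(sprintf("line %d of %s: score '%s' is not numeric",
                         idx[which(is.na(sc))[1L]], path, raw[is.na(sc)][1L]))
    }
  }
  if (!is.null(id_map)) {
    if (is.character(id_map) && length(id_map) == 1L && file.exists(id_map)) {
      mp <- utils::read.table(id_map, sep = "\t", header = FALSE,
                              colClasses = "character", comment.char = "#")
      id_map <- stats::setNames(mp[[2L]], mp[[1L]])
    }
    a <- ifelse(a %in% names(id_map), unname(id_map[a]), a)
    b <- ifelse(b %in% names(id_map), unname(id_map[b]), b)
  }
  net <- network(cbind(a, b), scores = sc,
                 name = if (is.null(name)) basename(path) else name)
  if (!quiet) {
    message(sprintf(
      "read %s: %d nodes, %d edges (%d self-loops dropped, %d duplicates dropped)",
      basename(path), length(net$nodes), n_edges(net),
      attr(net, "n_self_loops"), attr(net, "n_duplicates")))
  }
  net
}

#' Write a network as a canonical TSV edge list
#'
#' Edges are written in canonical order (smaller endpoint first, rows sorted),
#' so reading the file back reproduces the object exactly.
#'
#' @param net a `normlap_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(is_network(net))
  if (inherits(net, "normlap_scored")) {
    out <- sprintf("%s\t%s\t%s", net$edges[, 1L], net$edges[, 2L],
                   format(net$score, trim = TRUE, digits = 15))
  } else {
    out <- sprintf("%s\t%s", net$edges[, 1L], net$edges[, 2L])
  }
  writeLines(out, path)
  invisible(path)
}

#' Node degrees
#'
#' @param net a `normlap_network`.
#' @return named integer vector over all nodes of `net` (isolated nodes have
#'   degree 0); the degrees sum to twice the edge count.
#' @export
degrees <- function(net) {
  stopifnot(is_network(net))
  d <- stats::setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(net$edges) > 0L) {
    tab <- table(c(net$edges[, 1L], net$edges[, 2L]))
    d[names(tab)] <- as.integer(tab)
  }
  d
}

#' Union of two networks
#'
#' Combines G and M into Q with the union of the node sets and the union of the
#' canonical edge sets. Q is the constraint graph of the positive benchmark.
#'
#' @param g,m `normlap_network` objects.
#' @param name optional label for the union.
#' @return a `normlap_network`.
#' @export
union_graph <- function(g, m, name = NULL) {
  stopifnot(is_network(g), is_network(m))
  network(rbind(g$edges, m$edges), nodes = c(g$nodes, m$nodes), name = name)
}

#' Observed overlap between two networks
#'
#' Number of undirected edges present in both networks; symmetric in its
#' arguments.
#'
#' @param g,m `normlap_network` objects.
#' @return non-negative integer.
#' @export
observed_overlap <- function(g, m) {
  stopifnot(is_network(g), is_network(m))
  sum(edge_keys(g) %in% edge_keys(m))
}

#' Naive upper bound on the overlap of two networks
#'
#' Half the sum, over all nodes of either network, of the smaller of the node's
#' two degrees (0 for a node absent from one network), floored to an integer.
#' An exact but not always achievable cap: each shared link is counted once
#' from each endpoint, and a node cannot take part in more shared links than
#' its smaller degree.
#'
#' @param g,m `normlap_network` objects.
#' @return non-negative integer, always `>= observed_overlap(g, m)`.
#' @export
naive_upper_bound <- function(g, m) {
  dg <- degrees(g); dm <- degrees(m)
  all_nodes <- union(names(dg), names(dm))
  kg <- ifelse(all_nodes %in% names(dg), dg[all_nodes], 0L)
  km <- ifelse(all_nodes %in% names(dm), dm[all_nodes], 0L)
  floor(sum(pmin(kg, km)) / 2)
}

#' Keep edges of a scored network at or above a score threshold
#'
#' @param s a `normlap_scored` network.
#' @param threshold numeric cutoff; edges with `score >= threshold` are kept.
#' @param name optional label for the filtered network.
#' @return an unscored `normlap_network`; monotone in `threshold` (higher
#'   cutoff gives a subset of edges).
#' @export
filter_by_threshold <- function(s, threshold, name = NULL) {
  if (!inherits(s, "normlap_scored")) stop_input("`s` must be a scored network")
  keep <- s$score >= threshold
  network(s$edges[keep, , drop = FALSE], name = name)
}
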