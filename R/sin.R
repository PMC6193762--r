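# Social interaction network construction and day-to-day persistence.

#' Fisher z-test of a correlation against zero
#'
#' `z = atanh(r) * sqrt(n - 3)`; two-tailed p from the standard normal.
#'
#' @param r Pearson correlation coefficient.
#' @param n Number of pairs (>= 3; at the degenerate n = 3 the statistic is
#'   0 and p is 1).
#' @return List with `z` and `p`.
#' @export
fisher_z_test <- function(r, n) {
  stopifnot(is.finite(r), abs(r) <= 1, n >= 3)
  z <- atanh(r) * sqrt(n - 3)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Day-to-day persistence of dyad interactivity
#'
#' Correlates per-dyad interactivity indices between two days (averaging
#' over sessions within a day when a dyad was assayed more than once), and
#' tests the correlation with the Fisher z transform. Only dyads measured
#' on both days enter; the count used is reported.
#'
#' @param table A [dyad_metric_table()] data frame.
#' @param day_i,day_j The two day indices to compare.
#' @param use_abs Correlate absolute indices instead of signed (signed is
#'   the default).
#' @return Object of class `persistence_result`: `day_i`, `day_j`, `r`,
#'   `n_dyads`, `z`, `p`.
#' @export
day_persistence <- function(table, day_i, day_j, use_abs = FALSE) {
  stopifnot(is.data.frame(table),
            all(c("dyad_id", "day", "interactivity_index") %in% names(table)))
  tbl <- table[is.finite(table$interactivity_index), , drop = FALSE]
  if (!is.null(tbl$excluded)) tbl <- tbl[!tbl$excluded, , drop = FALSE]
  per_day <- function(d) {
    sub <- tbl[tbl$day == d, , drop = FALSE]
    tapply(sub$interactivity_index, sub$dyad_id, mean)
  }
  vi <- per_day(day_i); vj <- per_day(day_j)
  common <- intersect(names(vi), names(vj))
  n <- length(common)
  if (n < max(length(vi), length(vj))) {
    message(sprintf("day_persistence: %d of %d/%d dyads matched across days",
                    n, length(vi), length(vj)))
  }
  if (n < 3) stop("need at least 3 dyads measured on both days", call. = FALSE)
  a <- vi[common]; b <- vj[common]
  if (use_abs) { a <- abs(a); b <- abs(b) }
  r <- stats::cor(a, b)
  zt <- if (abs(r) < 1) fisher_z_test(r, n) else list(z = sign(r) * Inf, p = 0)
  structure(list(day_i = day_i, day_j = day_j, r = r, n_dyads = n,
                 z = zt$z, p = zt$p, use_abs = use_abs),
            class = "persistence_result")
}

#' @export
print.persistence_result <- function(x, ...) {
  cat(sprintf("<persistence day %s vs %s: r = %.3f (n = %d), z = %.3f, p = %.4g>\n",
              format(x$day_i), format(x$day_j), x$r, x$n_dyads, x$z, x$p))
  invisible(x)
}

#' Average dyad indices over early and late session windows
#'
#' For each dyad, orders its sessions chronologically and returns the mean
#' interactivity index over the first two and (separately) the last two
#' phenotyping sessions. Dyads with fewer than two sessions are excluded
#' with a warning.
#'
#' @param table A [dyad_metric_table()] data frame.
#' @return Data frame with columns `dyad_id`, `early_index`, `late_index`,
#'   `n_sessions`.
#' @export
aggregate_sessions <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("dyad_id", "day", "session", "interactivity_index") %in% names(table)))
  tbl <- table[is.finite(table$interactivity_index), , drop = FALSE]
  if (!is.null(tbl$excluded)) tbl <- tbl[!tbl$excluded, , drop = FALSE]
  parts <- split(tbl, tbl$dyad_id)
  ns <- vapply(parts, nrow, integer(1))
  if (any(ns < 2)) {
    warning(sprintf("%d dyad(s) with < 2 sessions excluded", sum(ns < 2)),
            call. = FALSE)
    parts <- parts[ns >= 2]
  }
  if (length(parts) == 0) stop("no dyad has >= 2 sessions", call. = FALSE)
  rows <- lapply(parts, function(g) {
    g <- g[order(g$day, g$session), , drop = FALSE]
    v <- g$interactivity_index
    data.frame(dyad_id = g$dyad_id[1],
               early_index = mean(v[1:2]),
               late_index = mean(v[(length(v) - 1):length(v)]),
               n_sessions = length(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Network connection threshold from the index population
#'
#' The threshold is the mean of the first and third quartiles of all dyads'
#' absolute interactivity indices, with quartiles by linear interpolation
#' between order statistics (quantile type 7).
#'
#' @param indices Numeric interactivity indices (>= 4 values).
#' @return Scalar threshold.
#' @examples
#' sin_threshold(c(0.1, 0.2, 0.3, 0.4))  # 0.25
#' @export
sin_threshold <- function(indices) {
  indices <- indices[is.finite(indices)]
  if (length(indices) < 4) stop("need at least 4 dyads", call. = FALSE)
  q <- stats::quantile(abs(indices), c(0.25, 0.75), type = 7, names = FALSE)
  mean(q)
}

#' Build a social interaction network
#'
#' Nodes are flies (isolates included); an edge connects a measured dyad
#' whose absolute interactivity index strictly exceeds the threshold.
#'
#' @param indices Data frame with columns `fly_a`, `fly_b`,
#'   `interactivity_index` (one row per measured dyad, typically one day's
#'   slice of a [dyad_metric_table()]).
#' @param threshold Edge threshold (see [sin_threshold()]).
#' @param nodes Node universe; defaults to all flies appearing in `indices`.
#' @param day Day label stored on the graph.
#' @param threshold_rule Free-text record of how the threshold was derived
#'   (e.g. reusing day 1's threshold for day 2).
#' @return Object of class `sin_graph` wrapping an [igraph::graph] plus the
#'   threshold metadata.
#' @export
build_sin <- function(indices, threshold, nodes = NULL, day = NA,
                      threshold_rule = "mean of Q1 and Q3 of |index| (type 7)") {
  stopifnot(is.data.frame(indices),
            all(c("fly_a", "fly_b", "interactivity_index") %in% names(indices)))
  idx <- indices[is.finite(indices$interactivity_index), , drop = FALSE]
  if (is.null(nodes)) nodes <- sort(unique(c(idx$fly_a, idx$fly_b)))
  nodes <- as.character(nodes)
  keep <- abs(idx$interactivity_index) > threshold
  edges <- idx[keep, c("fly_a", "fly_b", "interactivity_index"), drop = FALSE]
  names(edges)[3] <- "index"
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  structure(list(graph = g, threshold = threshold,
                 threshold_rule = threshold_rule, day = day),
            class = "sin_graph")
}

#' @export
print.sin_graph <- function(x, ...) {
  cat(sprintf("<sin_graph day %s: %d flies, %d edges, |index| > %.4g (%s)>\n",
              format(x$day), igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$threshold, x$threshold_rule))
  invisible(x)
}

.sin_edge_keys <- function(g) {
  e <- igraph::as_edgelist(g$graph)
  if (nrow(e) == 0) return(character(0))
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "--")
}

#' Edge overlap of two interaction networks
#'
#' @param g1,g2 [build_sin()] graphs over the same node universe.
#' @return List with `shared` (edge count in both), `jaccard`
#'   (`|E1 n E2| / |E1 u E2|`; 1 with `degenerate = TRUE` if both edge sets
#'   are empty), and `degenerate`.
#' @export
sin_overlap <- function(g1, g2) {
  stopifnot(inherits(g1, "sin_graph"), inherits(g2, "sin_graph"))
  n1 <- sort(igraph::V(g1$graph)$name); n2 <- sort(igraph::V(g2$graph)$name)
  if (!identical(n1, n2)) stop("node universes differ", call. = FALSE)
  e1 <- .sin_edge_keys(g1); e2 <- .sin_edge_keys(g2)
  shared <- length(intersect(e1, e2))
  uni <- length(union(e1, e2))
  if (uni == 0) {
    return(list(shared = 0L, jaccard = 1, degenerate = TRUE))
  }
  list(shared = shared, jaccard = shared / uni, degenerate = FALSE)
}

#' Export a network as GraphML
#'
#' @param g A [build_sin()] graph.
#' @param path Output path.
#' @export
write_sin_graphml <- function(g, path) {
  stopifnot(inherits(g, "sin_graph"))
  igraph::write_graph(g$graph, path, format = "graphml")
  invisible(path)
}

#' Export a network as an edge-list CSV
#'
#' @param g A [build_sin()] graph.
#' @param path Output path.
#' @param header_lines Optional `#`-prefixed provenance lines.
#' @export
write_sin_edgelist <- function(g, path, header_lines = NULL) {
  stopifnot(inherits(g, "sin_graph"))
  e <- igraph::as_edgelist(g$graph)
  df <- data.frame(fly_a = e[, 1], fly_b = e[, 2],
                   index = if (igraph::ecount(g$graph) > 0)
                     igraph::E(g$graph)$index else numeric(0))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# threshold=%.6g rule=%s day=%s", g$threshold,
                     g$threshold_rule, format(g$day)), con)
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
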