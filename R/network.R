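# Cluster co-occurrence networks: Spearman correlation of daily cluster
# activity within one (site, month), thresholded into an undirected graph
# whose node degrees identify hub clusters.

#' Daily cluster activity matrix for one site and month
#'
#' Counts minute-rows per (day, cluster) in the stratum. Clusters of the
#' fitted model never observed that month keep zero columns, so the matrix
#' is always days x K.
#'
#' @param table a minute table with a `cluster` column (see [apply_map()]).
#' @param site site id.
#' @param month calendar month 1-12.
#' @param clusters cluster id universe (default `0:max(table$cluster)`);
#'   pass `seq_len(model$K) - 1` to pin it to the fitted model.
#' @return Integer matrix (days x clusters) with dimnames (dates, cluster
#'   ids). Errors when the stratum has fewer than 3 days of data.
#' @export
cluster_timeseries <- function(table, site, month,
                               clusters = 0:max(table$cluster)) {
  if (!"cluster" %in% names(table))
    stop("table has no `cluster` column: run apply_map() first", call. = FALSE)
  tb <- table[table$site == site & table$month == month, , drop = FALSE]
  days <- sort(unique(as.character(tb$date)))
  if (length(days) < 3L)
    stopf("site %s month %d has %d day(s) of data; need >= 3 for correlation",
          site, month, length(days))
  M <- table(factor(as.character(tb$date), levels = days),
             factor(tb$cluster, levels = clusters))
  M <- matrix(as.integer(M), nrow = length(days),
              dimnames = list(days, as.character(clusters)))
  M
}

#' Build a Spearman co-occurrence network over clusters
#'
#' Computes pairwise Spearman rank correlations (average ranks on ties)
#' between the daily activity series of every cluster pair and keeps an
#' undirected edge where the correlation passes the threshold:
#' `rho >= threshold` when `positive_only` (default, the co-occurrence
#' reading), else `|rho| >= threshold`. Zero-variance columns yield no
#' edges; an all-zero-variance matrix gives an empty graph with a warning.
#'
#' @param mat days x clusters matrix from [cluster_timeseries()].
#' @param threshold correlation cutoff tau (default 0.5).
#' @param positive_only keep only positive correlations (default `TRUE`).
#' @param components optional named vector mapping cluster id to component,
#'   carried onto the nodes.
#' @param site,month optional stratum annotations.
#' @return Object of class `cluster_network`: `nodes` (cluster, component,
#'   degree), `edges` (i, j, rho with i < j), `threshold`, `site`, `month`.
#' @export
spearman_network <- function(mat, threshold = 0.5, positive_only = TRUE,
                             components = NULL, site = NA, month = NA) {
  if (nrow(mat) < 3L) stop("need at least 3 days of data", call. = FALSE)
  ids <- colnames(mat) %||% as.character(seq_len(ncol(mat)) - 1L)
  variable <- apply(mat, 2L, function(x) stats::var(x) > 0)
  edges <- data.frame(i = character(), j = character(), rho = numeric())
  if (!any(variable)) {
    warnf("all cluster series are constant; returning an empty graph")
  } else {
    sub <- mat[, variable, drop = FALSE]
    rho <- suppressWarnings(stats::cor(sub, method = "spearman"))
    idx <- which(upper.tri(rho), arr.ind = TRUE)
    r <- rho[idx]
    keep <- if (positive_only) !is.na(r) & r >= threshold
            else !is.na(r) & abs(r) >= threshold
    edges <- data.frame(i = ids[variable][idx[keep, 1L]],
                        j = ids[variable][idx[keep, 2L]],
                        rho = r[keep])
  }
  deg <- stats::setNames(integer(length(ids)), ids)
  if (nrow(edges)) {
    t1 <- table(edges$i); t2 <- table(edges$j)
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  nodes <- data.frame(cluster = ids,
                      component = if (is.null(components)) NA_character_
                                  else unname(components[ids]),
                      degree = as.integer(deg))
  structure(list(nodes = nodes, edges = edges, threshold = threshold,
                 positive_only = positive_only, site = site, month = month),
            class = "cluster_network")
}

#' @export
print.cluster_network <- function(x, ...) {
  cat(sprintf("<cluster_network> site=%s month=%s: %d nodes, %d edges (|rho| >= %g%s)\n",
              x$site, x$month, nrow(x$nodes), nrow(x$edges), x$threshold,
              if (x$positive_only) ", positive only" else ""))
  invisible(x)
}

#' Node degree table and hub clusters
#'
#' @param net a `cluster_network`.
#' @param top_k number of hub clusters to flag (default 5).
#' @return The node table sorted by decreasing degree with a logical `hub`
#'   column on the `top_k` highest-degree nodes.
#' @export
network_degrees <- function(net, top_k = 5L) {
  stopifnot(inherits(net, "cluster_network"))
  out <- net$nodes[order(-net$nodes$degree, net$nodes$cluster), , drop = FALSE]
  out$hub <- seq_len(nrow(out)) <= top_k & out$degree > 0
  rownames(out) <- NULL
  out
}

#' Convert a cluster network to an igraph object
#'
#' @param net a `cluster_network`.
#' @return An [igraph::graph_from_data_frame()] undirected graph with
#'   `component` vertex attributes and `rho` edge weights.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cluster_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Export a cluster network as GraphML and edge-list CSV
#'
#' @param net a `cluster_network`.
#' @param stem output path stem; writes `<stem>.graphml`, `<stem>_edges.csv`
#'   and `<stem>_nodes.csv`.
#' @return `stem`, invisibly.
#' @export
write_network <- function(net, stem) {
  g <- as_igraph(net)
  igraph::write_graph(g, paste0(stem, ".graphml"), format = "graphml")
  utils::write.csv(net$edges, paste0(stem, "_edges.csv"), row.names = FALSE)
  utils::write.csv(net$nodes, paste0(stem, "_nodes.csv"), row.names = FALSE)
  invisible(stem)
}

#' Plot a cluster network
#'
#' Dot size scales with node degree (hubs are large), colours follow the
#' component taxonomy.
#'
#' @param x a `cluster_network`.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.cluster_network <- function(x, ...) {
  g <- as_igraph(x)
  tax <- component_taxonomy()
  comp <- igraph::vertex_attr(g, "component")
  cols <- grDevices::hcl.colors(length(tax), "Dark 3")[match(comp, tax)]
  cols[is.na(cols)] <- "grey70"
  deg <- igraph::degree(g)
  igraph::plot.igraph(g, vertex.size = 4 + 2 * deg, vertex.color = cols,
                      vertex.label.cex = 0.6, ...)
  invisible(x)
}
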