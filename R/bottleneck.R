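#' TOM subgraph over a set of modules
#'
#' Extracts the complete weighted graph on the union of the chosen modules'
#' members: every pair of member proteins is connected by an edge weighted
#' with its TOM value; no self loops. Proteins not assigned to one of the
#' chosen modules are excluded even if topologically adjacent.
#'
#' @param tom TOM similarity matrix (or a \code{\link{CoexpressionNetwork}}).
#' @param labels named integer module labels (ignored when \code{tom} is a
#'   network object).
#' @param module_set integer module numbers (at least 2).
#' @return a \code{tomGraph}: list with \code{nodes} (protein ids),
#'   \code{weights} (TOM submatrix), \code{edges} (logical adjacency, all
#'   TRUE off-diagonal before thresholding) and \code{module} (named member
#'   module per node).
#' @export
tomSubgraph <- function(tom, labels = NULL, module_set) {
  if (is(tom, "CoexpressionNetwork")) {
    labels <- moduleLabels(tom)
    tom <- tomMatrix(tom)
  }
  module_set <- as.integer(module_set)
  if (length(module_set) < 2L)
    stop("module_set must contain at least 2 modules")
  missing_mods <- setdiff(module_set, unique(labels))
  if (length(missing_mods))
    stop("module(s) not present in labels: ",
         paste0("M", missing_mods, collapse = ", "))
  nodes <- names(labels)[labels %in% module_set]
  if (!length(nodes)) stop("empty module set")
  w <- tom[nodes, nodes]
  e <- matrix(TRUE, length(nodes), length(nodes),
              dimnames = dimnames(w))
  diag(e) <- FALSE
  structure(list(nodes = nodes, weights = w, edges = e,
                 module = setNames(labels[nodes], nodes),
                 threshold = NA_real_),
            class = "tomGraph")
}

#' Threshold subgraph edges at the mean edge weight
#'
#' Computes the mean weight over all current edges and removes edges whose
#' weight is strictly less than that mean (ties at the mean are kept); the
#' node set is unchanged. The resulting graph may be disconnected, which is
#' permitted and reported.
#'
#' @param graph a \code{tomGraph}.
#' @param edge_rule currently \code{"mean"}.
#' @return the thresholded \code{tomGraph} with \code{threshold} set and
#'   attribute fields \code{n_edges_kept} / \code{n_edges_total}.
#' @export
thresholdEdges <- function(graph, edge_rule = c("mean")) {
  edge_rule <- match.arg(edge_rule)
  stopifnot(inherits(graph, "tomGraph"))
  ut <- upper.tri(graph$weights)
  current <- graph$edges & ut
  if (!any(current)) stop("graph has no edges")
  m <- mean(graph$weights[current])
  keep <- graph$edges & graph$weights >= m
  diag(keep) <- FALSE
  graph$edges <- keep | t(keep)
  graph$threshold <- m
  graph$n_edges_total <- sum(current)
  graph$n_edges_kept <- sum(graph$edges & ut)
  comp <- .graphComponents(graph$edges)
  if (max(comp) > 1L)
    message("thresholded graph has ", max(comp), " connected components")
  graph
}

.graphComponents <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Source/target-restricted betweenness centrality
#'
#' \deqn{g(v) = \sum_{s \in S, t \in T, s \ne t}
#'   \frac{\sigma_{st}(v)}{\sigma_{st}}}
#' where \eqn{\sigma_{st}} counts the shortest s-to-t paths (hop-count paths
#' in unweighted mode; \code{1 - TOM} edge lengths in \code{tom_distance}
#' mode) and \eqn{\sigma_{st}(v)} those passing through \eqn{v \notin \{s,
#' t\}}. Pairs with no connecting path contribute 0. When
#' \code{normalized}, the sum is divided by the number of valid (s, t)
#' pairs. Computed by Brandes-style dependency accumulation with the target
#' set restricting which endpoints contribute.
#'
#' A node in both sets is removed from the target set with a warning,
#' except when the two sets are identical: sources = targets = all nodes is
#' the classical (ordered-pair) betweenness, which this function then
#' reproduces; only pairs with \eqn{s \ne t} contribute.
#'
#' @param graph a (thresholded) \code{tomGraph}.
#' @param sources,targets character vectors of node ids.
#' @param path_mode \code{"unweighted"} (default) or \code{"tom_distance"}.
#' @param normalized divide by the number of (s, t) pairs (default TRUE).
#' @return named numeric g per node.
#' @export
subsetBetweenness <- function(graph, sources, targets,
                              path_mode = c("unweighted", "tom_distance"),
                              normalized = TRUE) {
  stopifnot(inherits(graph, "tomGraph"))
  path_mode <- match.arg(path_mode)
  sources <- intersect(sources, graph$nodes)
  targets <- intersect(targets, graph$nodes)
  both <- intersect(sources, targets)
  if (length(both) && !setequal(sources, targets)) {
    # identical sets are the classical all-pairs case and are allowed;
    # a partial overlap is almost certainly a labelling mistake
    warning(length(both), " node(s) in both sources and targets removed ",
            "from targets")
    targets <- setdiff(targets, both)
  }
  if (!length(sources) || !length(targets))
    stop("sources and targets must be non-empty")
  n <- length(graph$nodes)
  idx <- setNames(seq_len(n), graph$nodes)
  s_idx <- idx[sources]
  t_set <- logical(n)
  t_set[idx[targets]] <- TRUE
  nbrs <- apply(graph$edges, 1L, which, simplify = FALSE)
  len <- 1 - graph$weights        # only used in tom_distance mode
  g <- numeric(n)
  for (s in s_idx) {
    sp <- if (path_mode == "unweighted") .bfsPaths(s, nbrs, n)
    else .dijkstraPaths(s, nbrs, len, n)
    delta <- numeric(n)
    for (w in rev(sp$order)) {
      contrib <- (if (t_set[w] && w != s) 1 else 0) + delta[w]
      if (contrib != 0 && length(sp$preds[[w]])) {
        for (v in sp$preds[[w]])
          delta[v] <- delta[v] + sp$sigma[v] / sp$sigma[w] * contrib
      }
    }
    delta[s] <- 0
    g <- g + delta
  }
  if (normalized) {
    n_pairs <- length(s_idx) * sum(t_set) - sum(t_set[s_idx])
    g <- g / n_pairs
  }
  setNames(g, graph$nodes)
}

.bfsPaths <- function(s, nbrs, n) {
  dist <- rep(Inf, n)
  sigma <- numeric(n)
  preds <- vector("list", n)
  dist[s] <- 0
  sigma[s] <- 1
  order <- integer(0)
  frontier <- s
  while (length(frontier)) {
    order <- c(order, frontier)
    nxt <- integer(0)
    for (v in frontier) {
      for (w in nbrs[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    frontier <- unique(nxt)
  }
  list(order = order, sigma = sigma, preds = preds)
}

.dijkstraPaths <- function(s, nbrs, len, n, eps = 1e-12) {
  dist <- rep(Inf, n)
  sigma <- numeric(n)
  preds <- vector("list", n)
  done <- logical(n)
  dist[s] <- 0
  sigma[s] <- 1
  order <- integer(0)
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    v <- cand[which.min(dist[cand])]
    done[v] <- TRUE
    order <- c(order, v)
    for (w in nbrs[[v]]) {
      if (done[w]) next
      d_new <- dist[v] + len[v, w]
      if (d_new < dist[w] - eps) {
        dist[w] <- d_new
        sigma[w] <- sigma[v]
        preds[[w]] <- v
      } else if (abs(d_new - dist[w]) <= eps) {
        sigma[w] <- sigma[w] + sigma[v]
        preds[[w]] <- c(preds[[w]], v)
      }
    }
  }
  list(order = order, sigma = sigma, preds = preds)
}

#' Rank a source module's proteins by bottleneck centrality
#'
#' Sorts the source module's proteins by betweenness centrality, rank 1
#' being the strongest bottleneck. Ties are broken by higher own-module kME
#' (when supplied), then lexicographic protein id; an all-zero centrality
#' vector is flagged as carrying no bottleneck signal.
#'
#' @param g named betweenness values from \code{\link{subsetBetweenness}}.
#' @param labels named integer module labels.
#' @param source_module the source module number.
#' @param kme optional named own-module kME for tie-breaking.
#' @return data.frame (protein, module, g, rank) with attribute
#'   \code{"no_signal"}.
#' @export
rankBottlenecks <- function(g, labels, source_module, kme = NULL) {
  ids <- intersect(names(g), names(labels)[labels == source_module])
  if (!length(ids)) stop("no source-module proteins in the graph")
  gv <- g[ids]
  kv <- if (is.null(kme)) setNames(rep(0, length(ids)), ids) else kme[ids]
  kv[!is.finite(kv)] <- 0
  ord <- order(-gv, -kv, ids)
  out <- data.frame(protein = ids[ord],
                    module = unname(source_module),
                    g = unname(gv[ord]),
                    rank = seq_along(ids),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "no_signal") <- all(gv == 0)
  out
}

#' End-to-end bottleneck analysis
#'
#' Runs the full procedure on a built network: extract the TOM subgraph
#' over the chosen modules, drop edges below the mean edge weight, compute
#' source/target-restricted betweenness with the source module's members as
#' sources and the remaining modules' members as targets, and rank the
#' source module's proteins. The order (subgraph, then threshold, then
#' betweenness) is fixed: thresholding before extraction is not equivalent.
#'
#' @param net a \code{\link{CoexpressionNetwork}}.
#' @param module_set integer module numbers forming the subgraph.
#' @param source_module one of \code{module_set}.
#' @param path_mode,normalized see \code{\link{subsetBetweenness}}.
#' @return data.frame of ranked source-module proteins with attributes
#'   \code{"graph_summary"} (nodes, edges kept, mean-weight threshold) and
#'   \code{"g"} (centrality for every subgraph node).
#' @export
bottleneckAnalysis <- function(net, module_set, source_module,
                               path_mode = c("unweighted", "tom_distance"),
                               normalized = TRUE) {
  stopifnot(is(net, "CoexpressionNetwork"))
  path_mode <- match.arg(path_mode)
  if (!source_module %in% module_set)
    stop("source_module must be one of module_set")
  labels <- moduleLabels(net)
  graph <- tomSubgraph(tomMatrix(net), labels, module_set)
  graph <- thresholdEdges(graph)
  sources <- names(labels)[labels == source_module]
  targets <- setdiff(graph$nodes, sources)
  g <- subsetBetweenness(graph, sources, targets, path_mode = path_mode,
                         normalized = normalized)
  kme_own <- setNames(net@kme[cbind(seq_along(labels),
                                    match(paste0("M", labels),
                                          colnames(net@kme)))],
                      names(labels))
  res <- rankBottlenecks(g, labels, source_module, kme = kme_own)
  attr(res, "graph_summary") <- list(
    n_nodes = length(graph$nodes),
    n_edges_kept = graph$n_edges_kept,
    n_edges_total = graph$n_edges_total,
    threshold = graph$threshold,
    path_mode = path_mode,
    normalized = normalized)
  attr(res, "g") <- g
  res
}
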