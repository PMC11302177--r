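# Shared fixtures, built lazily once per test run.

suppressPackageStartupMessages({
  library(SummarizedExperiment)
})

.fixture_env <- new.env(parent = emptyenv())

# small 5-module cohort: 301 proteins, CTL/DLB 40+40, no batch effects
smallConfig <- function(seed = 42L, ...) {
  args <- list(n_proteins = 301L,
               module_sizes = c(60L, 50L, 40L, 30L, 25L),
               groups = c(CTL = 40L, DLB = 40L), n_batches = 6L,
               channels_per_batch = 15L, batch_sd = 0,
               bottleneck_targets = c(1L, 2L, 5L),
               bottleneck_weights = c(2, 2, 2), seed = seed)
  do.call(simConfig, utils::modifyList(args, list(...)))
}

smallCohort <- function() {
  if (is.null(.fixture_env$small)) {
    se <- simulateCohort(smallConfig())
    cd <- as.data.frame(colData(se))
    x <- filterMissingness(assay(se, "log2")[, !cd$is_gis])
    .fixture_env$small <- list(
      se = se, truth = metadata(se)$truth,
      samples = cd[!cd$is_gis, , drop = FALSE],
      x = x
    )
  }
  .fixture_env$small
}

# planted labels as integers over a filtered matrix
plantedLabels <- function(truth, ids) {
  memb <- truth@membership[ids]
  mods <- rownames(truth@groupEffects)
  lab <- setNames(integer(length(ids)), ids)
  for (k in seq_along(mods)) lab[memb == mods[k]] <- k
  lab
}

# small-cohort network, built once
smallNetwork <- function() {
  if (is.null(.fixture_env$small_net)) {
    fx <- smallCohort()
    .fixture_env$small_net <- buildNetwork(fx$x, min_module_size = 20L)
  }
  .fixture_env$small_net
}

# match each recovered module to the planted latent score it best tracks
eigenTruthCor <- function(net, truth) {
  E <- eigenproteins(net)
  if (!nrow(E)) return(numeric(0))
  scores <- truth@moduleScores[, colnames(E), drop = FALSE]
  apply(E, 1L, function(e)
    max(abs(cor(e, t(scores), use = "pairwise.complete.obs"))))
}

# bicor matrix across protein rows with undefined entries zeroed
networkCorrelationOf <- function(x) {
  r <- bicorMatrix(t(x))
  r[is.na(r)] <- 0
  attr(r, "n") <- NULL
  attr(r, "pearson_fallback") <- NULL
  r
}

# brute-force subset betweenness by exhaustive path enumeration (<= 8 nodes)
bruteSubsetBetweenness <- function(adj, w, sources, targets,
                                   weighted = FALSE, normalized = TRUE) {
  n <- nrow(adj)
  all_paths <- function(s, t) {
    out <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        out[[length(out) + 1L]] <<- path
        return()
      }
      for (u in which(adj[v, ])) {
        if (!u %in% path) walk(c(path, u))
      }
    }
    walk(s)
    out
  }
  plen <- function(p) {
    if (!weighted) return(length(p) - 1L)
    sum(vapply(seq_len(length(p) - 1L),
               function(i) 1 - w[p[i], p[i + 1L]], numeric(1L)))
  }
  g <- numeric(n)
  n_pairs <- 0L
  for (s in sources) {
    for (t in targets) {
      if (s == t) next
      n_pairs <- n_pairs + 1L
      paths <- all_paths(s, t)
      if (!length(paths)) next
      lens <- vapply(paths, plen, numeric(1L))
      sp <- paths[lens <= min(lens) + 1e-9]
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        thru <- sum(vapply(sp, function(p) v %in% p, logical(1L)))
        g[v] <- g[v] + thru / length(sp)
      }
    }
  }
  if (normalized) g <- g / n_pairs
  g
}

# random tomGraph on n nodes with edge probability p_edge
randomTomGraph <- function(n, p_edge = 0.5) {
  w <- matrix(runif(n * n), n)
  w <- (w + t(w)) / 2
  diag(w) <- 1
  adj <- matrix(runif(n * n) < p_edge, n)
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  ids <- sprintf("N%02d", seq_len(n))
  dimnames(w) <- dimnames(adj) <- list(ids, ids)
  structure(list(nodes = ids, weights = w, edges = adj,
                 module = setNames(rep(1L, n), ids),
                 threshold = NA_real_),
            class = "tomGraph")
}
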