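#' Soft-threshold power diagnostics
#'
#' For each candidate power, computes the signed adjacency, the connectivity
#' distribution, the model fit R^2 of the log-log scale-free degree
#' regression (signed by the slope, as is conventional), and the mean
#' connectivity. Advisory only: the network build always uses the configured
#' power.
#'
#' @param x proteins x samples matrix.
#' @param powers candidate soft powers.
#' @param cor_method \code{"bicor"} or \code{"pearson"}.
#' @param n_bins histogram bins for the scale-free fit.
#' @return data.frame (power, scale_free_R2, mean_k, median_k, max_k).
#' @export
pickSoftThreshold <- function(x, powers = c(1:10, seq(12, 20, 2)),
                              cor_method = c("bicor", "pearson"),
                              n_bins = 10L) {
  .checkAbundanceMatrix(x)
  if (nrow(x) < 20L) stop("need at least 20 proteins")
  cor_method <- match.arg(cor_method)
  r <- .networkCorrelation(x, cor_method)
  out <- lapply(powers, function(b) {
    a <- signedAdjacency(r, b)
    k <- rowSums(a) - 1
    data.frame(power = b,
               scale_free_R2 = .scaleFreeFit(k, n_bins),
               mean_k = mean(k), median_k = median(k), max_k = max(k))
  })
  do.call(rbind, out)
}

.scaleFreeFit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(unique(k)) < 3L) return(NA_real_)
  br <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmid <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3L) return(NA_real_)
  fit <- lm(log10(freq[ok]) ~ log10(kmid[ok]))
  r2 <- summary(fit)$r.squared
  -sign(coef(fit)[2L]) * r2
}

.networkCorrelation <- function(x, cor_method) {
  r <- if (cor_method == "bicor") bicorMatrix(t(x))
  else suppressWarnings(cor(t(x), use = "pairwise.complete.obs"))
  n_na <- sum(is.na(r))
  if (n_na > 0) {
    message(n_na, " undefined correlations set to 0")
    r[is.na(r)] <- 0
  }
  r
}

#' Signed soft-thresholded adjacency
#'
#' \eqn{a_{ij} = ((1 + r_{ij}) / 2)^\beta}, the signed-network convention:
#' perfectly anti-correlated proteins get adjacency 0 rather than being
#' conflated with positive correlation. Diagonal is set to 1.
#'
#' @param corr symmetric correlation matrix with entries in [-1, 1].
#' @param beta soft power (> 0); 11.0 is the pipeline default, with 12.0 and
#'   7.5 used for stiffer or looser cohorts.
#' @return adjacency matrix in [0, 1].
#' @export
signedAdjacency <- function(corr, beta = 11) {
  if (!isSymmetric(unname(corr), tol = 1e-10))
    stop("correlation matrix must be symmetric")
  if (beta <= 0) stop("beta must be positive")
  if (any(corr < -1 - 1e-8 | corr > 1 + 1e-8, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]")
  a <- ((1 + pmin(pmax(corr, -1), 1)) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' \deqn{TOM_{ij} = \frac{\ell_{ij} + a_{ij}}{f(k_i, k_j) + 1 - a_{ij}}, \quad
#' \ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}, \quad k_i = \sum_{u \ne i} a_{iu}}
#' with \eqn{f} the mean (default) or the minimum of the two connectivities.
#' The mean denominator damps the inflation of overlap between a low- and a
#' high-connectivity protein. Diagonal is 1.
#'
#' @param adjacency adjacency matrix in [0, 1] with unit diagonal.
#' @param denominator \code{"mean"} or \code{"min"}.
#' @return TOM matrix in [0, 1].
#' @export
tomSimilarity <- function(adjacency, denominator = c("mean", "min")) {
  denominator <- match.arg(denominator)
  if (any(adjacency < 0 | adjacency > 1))
    stop("adjacency must lie in [0, 1]")
  if (!isSymmetric(unname(adjacency), tol = 1e-10))
    stop("adjacency must be symmetric")
  a0 <- adjacency
  diag(a0) <- 0
  L <- a0 %*% a0                       # l_ij = sum_u a_iu a_uj, u != i,j
  k <- rowSums(a0)
  f <- if (denominator == "mean") outer(k, k, function(a, b) (a + b) / 2)
  else outer(k, k, pmin)
  tom <- (L + a0) / (f + 1 - a0)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Hybrid dynamic dendrogram cut with PAM-style assignment
#'
#' Average-linkage hierarchical clustering on \code{1 - TOM} followed by a
#' dynamic, shape-respecting cut: branches below a static cut height are
#' split recursively where both sub-branches are large enough
#' (\code{min_module_size}), separated by a height gap exceeding the
#' deep-split-dependent minimum, and internally tight (core scatter below
#' the deep-split maximum). Deep split 0-4 maps to progressively more
#' aggressive splitting via the conventional (maxCoreScatter, minGap)
#' schedule. Clusters smaller than \code{min_module_size} are dissolved to
#' unassigned. An optional PAM stage then assigns each unassigned protein to
#' the nearest module medoid -- restricted, when
#' \code{pam_respect_dendro}, to modules within the protein's own static
#' branch -- and only when the protein lies within the module's own radius
#' (its maximal member-to-medoid dissimilarity).
#'
#' @param tom TOM similarity matrix.
#' @param deep_split integer 0-4 (default 2).
#' @param min_module_size smallest allowed module (default 25).
#' @param cut_height static cut height on the dendrogram; default 99% of the
#'   way from the 5th percentile to the maximum of the joining heights.
#' @param pam_stage run the PAM assignment stage (default TRUE).
#' @param pam_respect_dendro restrict PAM assignment to the protein's
#'   dendrogram branch (default TRUE).
#' @param method \code{"hybrid"} (default) or \code{"static"} (plain
#'   fixed-height cut, debugging aid).
#' @return list with \code{labels} (named integer, 0 = unassigned, numbered
#'   by decreasing size) and \code{tree} (the \code{hclust} object).
#' @export
cutModules <- function(tom, deep_split = 2L, min_module_size = 25L,
                       cut_height = NULL, pam_stage = TRUE,
                       pam_respect_dendro = TRUE,
                       method = c("hybrid", "static")) {
  method <- match.arg(method)
  if (deep_split < 0L || deep_split > 4L) stop("deep_split must be in 0..4")
  if (min_module_size < 3L) stop("min_module_size must be at least 3")
  diss <- 1 - tom
  tree <- hclust(as.dist(diss), method = "average")
  h <- tree$height
  if (diff(range(h)) < 1e-12) {
    message("degenerate TOM: all joining heights equal")
    labels <- rep(if (length(tree$order) >= min_module_size) 1L else 0L,
                  length(tree$order))
    names(labels) <- rownames(tom)
    return(list(labels = labels, tree = tree))
  }
  if (is.null(cut_height)) {
    h5 <- quantile(h, 0.05)
    cut_height <- h5 + 0.99 * (max(h) - h5)
  }
  base <- cutree(tree, h = cut_height)

  if (method == "static") {
    labels <- base
  } else {
    # higher deep_split -> tighter required core -> deeper splitting
    max_core_scatter <- c(0.95, 0.91, 0.82, 0.73, 0.64)[deep_split + 1L]
    hmin <- min(h)
    hrange <- max(h) - hmin
    info <- .treeNodeInfo(tree)
    labels <- integer(length(base))
    next_lab <- 0L
    for (cl in unique(base)) {
      leaves <- which(base == cl)
      if (length(leaves) == 1L) {
        labels[leaves] <- (next_lab <- next_lab + 1L)
        next
      }
      node <- info$node_of_set[[paste(sort(leaves), collapse = ",")]]
      if (is.null(node)) {                # should not happen; keep whole
        labels[leaves] <- (next_lab <- next_lab + 1L)
        next
      }
      parts <- .splitBranch(node, info, diss,
                            hmin + max_core_scatter * hrange,
                            min_module_size,
                            (1 - c(0.64, 0.73, 0.82, 0.91, 0.95)
                             [deep_split + 1L]) * 3 / 4 * hrange)
      for (p in parts)
        labels[p] <- (next_lab <- next_lab + 1L)
    }
  }

  labels <- .dissolveSmall(labels, min_module_size)

  if (pam_stage && any(labels == 0L) && any(labels > 0L)) {
    medoid <- vapply(sort(unique(labels[labels > 0L])), function(m) {
      rows <- which(labels == m)
      rows[which.min(rowMeans(diss[rows, rows, drop = FALSE]))]
    }, integer(1L))
    names(medoid) <- sort(unique(labels[labels > 0L]))
    radius <- vapply(names(medoid), function(m) {
      rows <- which(labels == as.integer(m))
      max(diss[rows, medoid[[m]]])
    }, numeric(1L))
    for (u in which(labels == 0L)) {
      allowed <- names(medoid)
      if (pam_respect_dendro)
        allowed <- allowed[base[medoid[allowed]] == base[u]]
      if (!length(allowed)) next
      d <- diss[u, medoid[allowed]]
      best <- allowed[which.min(d)]
      if (min(d) <= radius[[best]])
        labels[u] <- as.integer(best)
    }
  }

  labels <- .renumberBySize(labels)
  names(labels) <- rownames(tom)
  list(labels = labels, tree = tree)
}

# per-internal-node leaf sets and heights for the dendrogram walk
.treeNodeInfo <- function(tree) {
  n <- length(tree$order)
  leaves <- vector("list", n - 1L)
  for (j in seq_len(n - 1L)) {
    ch <- tree$merge[j, ]
    leaves[[j]] <- c(
      if (ch[1] < 0) -ch[1] else leaves[[ch[1]]],
      if (ch[2] < 0) -ch[2] else leaves[[ch[2]]]
    )
  }
  node_of_set <- vector("list", 0L)
  keys <- vapply(leaves, function(v) paste(sort(v), collapse = ","), "")
  node_of_set <- as.list(seq_len(n - 1L))
  names(node_of_set) <- keys
  list(leaves = leaves, heights = tree$height, merge = tree$merge,
       node_of_set = node_of_set)
}

# Recursive hybrid split of one branch; returns a list of leaf index
# vectors. Phase 1: a branch looser than the deep-split scatter threshold
# is "glue" (chained background proteins joining near the top) and is
# split into its children recursively; fragments that never reach
# coherence fall below the minimum module size and dissolve to unassigned.
# Phase 2: a scatter-coherent branch may still be a mixture of two tight
# modules bridged by spurs, so it is probed for a strong internal split
# before being accepted whole.
.splitBranch <- function(node, info, diss, max_scatter_abs, min_size,
                         min_gap_abs) {
  leaves <- info$leaves[[node]]
  if (.branchScatter(leaves, diss) <= max_scatter_abs)
    return(.probeSplit(node, info, diss, min_size, min_gap_abs))
  ch <- info$merge[node, ]
  out <- list()
  for (c in ch) {
    out <- c(out, if (c < 0) list(-c)
             else .splitBranch(c, info, diss, max_scatter_abs, min_size,
                               min_gap_abs))
  }
  out
}

# Descend a coherent branch, peeling sub-min_size spurs, to the first node
# whose two children are both large. If the joining height clearly exceeds
# both children's internal scatter (gap >= min_gap_abs) the branch is two
# clusters: the spurs become loose glue and each child is probed again.
# Otherwise the original branch is one cluster and is kept whole (spurs
# included).
.probeSplit <- function(start_node, info, diss, min_size, min_gap_abs) {
  whole <- list(info$leaves[[start_node]])
  node <- start_node
  loose <- list()
  repeat {
    ch <- info$merge[node, ]
    sets <- lapply(ch, function(c) if (c < 0) -c else info$leaves[[c]])
    sizes <- lengths(sets)
    if (min(sizes) >= min_size) {
      scatters <- vapply(sets, .branchScatter, numeric(1L), diss = diss)
      gap <- info$heights[node] - max(scatters)
      if (gap < min_gap_abs) return(whole)
      return(c(loose,
               .probeSplit(ch[1L], info, diss, min_size, min_gap_abs),
               .probeSplit(ch[2L], info, diss, min_size, min_gap_abs)))
    }
    if (max(sizes) < min_size) return(whole)
    small <- which.min(sizes)
    if (ch[3L - small] < 0) return(whole)
    loose <- c(loose, list(sets[[small]]))
    node <- ch[3L - small]
  }
}

# mean pairwise dissimilarity within a branch
.branchScatter <- function(leaves, diss, max_n = 200L) {
  if (length(leaves) <= 1L) return(0)
  if (length(leaves) > max_n)          # subsample very large branches
    leaves <- leaves[seq(1L, length(leaves), length.out = max_n)]
  d <- diss[leaves, leaves]
  mean(d[upper.tri(d)])
}

.dissolveSmall <- function(labels, min_module_size) {
  tab <- table(labels[labels > 0L])
  small <- as.integer(names(tab)[tab < min_module_size])
  labels[labels %in% small] <- 0L
  labels
}

.renumberBySize <- function(labels) {
  tab <- sort(table(labels[labels > 0L]), decreasing = TRUE)
  map <- setNames(seq_along(tab), names(tab))
  out <- labels
  pos <- labels > 0L
  out[pos] <- map[as.character(labels[pos])]
  as.integer(out)
}

#' Module eigenproteins
#'
#' The eigenprotein of a module is the first right singular vector of the
#' standardised member x sample matrix -- the first principal component of
#' the module across samples. Member rows are centred and scaled on their
#' observed values; residual missing cells are imputed at the protein mean
#' (zero after standardisation). The sign is aligned so that the mean
#' correlation of members with their eigenprotein is positive. Samples with
#' no observed member values get a missing eigenprotein entry.
#'
#' @param x proteins x samples matrix.
#' @param labels named integer module labels (0 = unassigned).
#' @return list with \code{E} (modules x samples, rows named "M<k>") and
#'   \code{varExplained} (fraction of member variance captured).
#' @export
moduleEigenproteins <- function(x, labels) {
  mods <- sort(unique(labels[labels > 0L]))
  if (!length(mods)) stop("no modules to summarise")
  E <- matrix(NA_real_, nrow = length(mods), ncol = ncol(x),
              dimnames = list(paste0("M", mods), colnames(x)))
  ve <- setNames(numeric(length(mods)), paste0("M", mods))
  for (i in seq_along(mods)) {
    rows <- which(labels == mods[i])
    xm <- x[rows, , drop = FALSE]
    mu <- rowMeans(xm, na.rm = TRUE)
    sdv <- .rowSdsNA(xm)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    xs <- (xm - mu) / sdv
    empty <- colSums(is.finite(xs)) == 0L
    xs[!is.finite(xs)] <- 0
    sv <- svd(xs)
    e <- sv$v[, 1L]
    memb_cor <- as.numeric(xs %*% e)
    if (mean(memb_cor) < 0) e <- -e
    e[empty] <- NA_real_
    E[i, ] <- e
    ve[i] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  list(E = E, varExplained = ve)
}

#' kME module membership
#'
#' Signed biweight midcorrelation between every protein profile and every
#' module eigenprotein, on pairwise-complete samples, with Student-t
#' p-values.
#'
#' @param x proteins x samples matrix.
#' @param E modules x samples eigenprotein matrix.
#' @return list with \code{kme} and \code{p} (proteins x modules).
#' @export
moduleKME <- function(x, E) {
  r <- bicorMatrix(t(x), t(E))
  n <- attr(r, "n")
  p <- matrix(bicorPValue(as.numeric(r), as.numeric(n)),
              nrow = nrow(r), dimnames = dimnames(r))
  list(kme = r, p = p)
}

#' Iterative kME-based module clean-up
#'
#' Repeats until a fixed point (or \code{max_rounds}): a protein whose kME
#' to a foreign module exceeds its own-module kME with significance below
#' \code{reassign_p} moves to that module; a protein whose own-module kME is
#' not significant becomes unassigned. Eigenproteins and kME are recomputed
#' every round and the minimum module size is re-enforced.
#'
#' @param x proteins x samples matrix.
#' @param labels named integer labels (0 = unassigned).
#' @param reassign_p significance threshold for moves (default 0.05).
#' @param max_rounds round cap (default 30); hitting it raises a warning and
#'   keeps the last state.
#' @param min_module_size minimum module size re-enforced per round.
#' @return named integer labels, renumbered by decreasing size, with
#'   attribute \code{"rounds"}.
#' @export
reassignModules <- function(x, labels, reassign_p = 0.05, max_rounds = 30L,
                            min_module_size = 25L) {
  rounds <- 0L
  repeat {
    if (!any(labels > 0L)) break
    rounds <- rounds + 1L
    el <- moduleEigenproteins(x, labels)
    km <- moduleKME(x, el$E)
    mods <- as.integer(sub("^M", "", colnames(km$kme)))
    changed <- FALSE
    new_labels <- labels
    for (i in seq_along(labels)) {
      if (labels[i] == 0L) next
      own_col <- match(labels[i], mods)
      own_k <- km$kme[i, own_col]
      own_p <- km$p[i, own_col]
      foreign <- setdiff(seq_along(mods), own_col)
      if (length(foreign)) {
        fb <- foreign[which.max(km$kme[i, foreign])]
        if (is.finite(km$kme[i, fb]) && (!is.finite(own_k) ||
            km$kme[i, fb] > own_k) && km$p[i, fb] < reassign_p) {
          new_labels[i] <- mods[fb]
          changed <- TRUE
          next
        }
      }
      if (!is.finite(own_p) || own_p >= reassign_p) {
        new_labels[i] <- 0L
        changed <- TRUE
      }
    }
    dl <- .dissolveSmall(new_labels, min_module_size)
    changed <- changed || !identical(dl, labels)
    labels <- dl
    if (!changed) break
    if (rounds >= max_rounds) {
      warning("reassignment did not reach a fixed point in ", max_rounds,
              " rounds; keeping last state")
      break
    }
  }
  out <- .renumberBySize(labels)
  names(out) <- names(labels)
  attr(out, "rounds") <- rounds
  out
}

#' Merge modules with near-identical eigenproteins
#'
#' Clusters module eigenproteins on \code{1 - cor(E)} and merges any set of
#' modules whose dissimilarity falls below \code{merge_cut_height} (i.e.
#' eigenprotein correlation above \code{1 - merge_cut_height}), repeating
#' until no pair qualifies. Order-independent by construction (the merge
#' groups come from a dendrogram cut, not from pairwise sweeps).
#'
#' @param x proteins x samples matrix.
#' @param labels named integer labels.
#' @param merge_cut_height eigenprotein dissimilarity threshold, default
#'   0.07 (merge when correlation exceeds 0.93).
#' @return named integer labels, renumbered by decreasing size.
#' @export
mergeModules <- function(x, labels, merge_cut_height = 0.07) {
  if (merge_cut_height <= 0 || merge_cut_height >= 1)
    stop("merge_cut_height must be in (0, 1)")
  repeat {
    mods <- sort(unique(labels[labels > 0L]))
    if (length(mods) < 2L) break
    el <- moduleEigenproteins(x, labels)
    d <- 1 - cor(t(el$E), use = "pairwise.complete.obs")
    tr <- hclust(as.dist(d), method = "average")
    grp <- cutree(tr, h = merge_cut_height)
    if (max(table(grp)) == 1L) break
    for (g in unique(grp)) {
      members <- mods[grp == g]
      if (length(members) < 2L) next
      sizes <- table(factor(labels, levels = members))
      target <- members[which.max(sizes)]
      labels[labels %in% members] <- target
    }
  }
  out <- .renumberBySize(labels)
  names(out) <- names(labels)
  out
}

#' Build a signed co-expression network end to end
#'
#' Orchestrates the full build on a preprocessed matrix: robust correlation,
#' signed adjacency at the configured power, mean-denominator TOM,
#' average-linkage clustering with the hybrid dynamic cut and PAM stage,
#' eigenprotein-based module merging, iterative kME clean-up, and the final
#' eigenprotein / kME tables. Deterministic given the input.
#'
#' @param x proteins x samples analysis-ready matrix.
#' @param beta signed soft power (default 11).
#' @param cor_method \code{"bicor"} (default) or \code{"pearson"}.
#' @param tom_denominator \code{"mean"} (default) or \code{"min"}.
#' @param deep_split,min_module_size,cut_height,pam_stage,pam_respect_dendro
#'   dynamic-cut parameters, see \code{\link{cutModules}}.
#' @param merge_cut_height eigenprotein merge threshold (default 0.07).
#' @param reassign_p clean-up significance threshold (default 0.05).
#' @param max_rounds clean-up round cap (default 30).
#' @return a \code{\link{CoexpressionNetwork}}.
#' @examples
#' cfg <- simConfig(n_proteins = 150, module_sizes = c(50, 45, 35),
#'                  groups = c(CTL = 20, DLB = 20), n_batches = 4,
#'                  channels_per_batch = 11, missing_rate = 0,
#'                  batch_sd = 0, seed = 11)
#' se <- simulateCohort(cfg)
#' x <- assay(se)[, !colData(se)$is_gis]
#' net <- buildNetwork(x, min_module_size = 20)
#' net
#' @export
buildNetwork <- function(x, beta = 11, cor_method = c("bicor", "pearson"),
                         tom_denominator = c("mean", "min"),
                         deep_split = 2L, min_module_size = 25L,
                         cut_height = NULL, pam_stage = TRUE,
                         pam_respect_dendro = TRUE,
                         merge_cut_height = 0.07, reassign_p = 0.05,
                         max_rounds = 30L) {
  .checkAbundanceMatrix(x)
  cor_method <- match.arg(cor_method)
  tom_denominator <- match.arg(tom_denominator)
  r <- .networkCorrelation(x, cor_method)
  a <- signedAdjacency(r, beta)
  tom <- tomSimilarity(a, tom_denominator)
  cut <- cutModules(tom, deep_split = deep_split,
                    min_module_size = min_module_size,
                    cut_height = cut_height, pam_stage = pam_stage,
                    pam_respect_dendro = pam_respect_dendro)
  labels <- cut$labels
  if (any(labels > 0L))
    labels <- mergeModules(x, labels, merge_cut_height)
  if (any(labels > 0L))
    labels <- reassignModules(x, labels, reassign_p = reassign_p,
                              max_rounds = max_rounds,
                              min_module_size = min_module_size)
  rounds <- attr(labels, "rounds")
  if (any(labels > 0L)) {
    el <- moduleEigenproteins(x, labels)
    km <- moduleKME(x, el$E)
  } else {
    el <- list(E = matrix(numeric(0), 0L, ncol(x),
                          dimnames = list(NULL, colnames(x))),
               varExplained = numeric(0))
    km <- list(kme = matrix(numeric(0), nrow(x), 0L,
                            dimnames = list(rownames(x), NULL)),
               p = matrix(numeric(0), nrow(x), 0L,
                          dimnames = list(rownames(x), NULL)))
  }
  labels <- setNames(as.integer(labels), rownames(x))
  new("CoexpressionNetwork",
      corr = r, adjacency = a, tom = tom, tree = cut$tree,
      labels = labels,
      colors = setNames(moduleColorOf(labels), rownames(x)),
      eigenproteins = el$E, varExplained = el$varExplained,
      kme = km$kme, kmeP = km$p,
      config = list(beta = beta, corMethod = cor_method,
                    tomDenominator = tom_denominator,
                    deepSplit = deep_split, minModuleSize = min_module_size,
                    mergeCutHeight = merge_cut_height,
                    reassignP = reassign_p, pamStage = pam_stage,
                    pamRespectDendro = pam_respect_dendro),
      provenance = list(package = as.character(packageVersion("wpcna")),
                        date = format(Sys.time(), "%Y-%m-%d"),
                        cleanupRounds = rounds,
                        nProteins = nrow(x), nSamples = ncol(x)))
}
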