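#' Permutation module preservation (Z summary)
#'
#' Assesses whether modules defined in a reference cohort retain their
#' density and connectivity pattern in an independent test cohort. For each
#' reference module, over the shared protein universe:
#' \itemize{
#'   \item density statistics in the test data: mean intramodular adjacency
#'     and the proportion of member variance explained by the module
#'     eigenprotein;
#'   \item connectivity statistics: the correlation between intramodular
#'     connectivity vectors (kIM) in reference vs test, and the correlation
#'     between the intramodular correlation-matrix entries in reference vs
#'     test.
#' }
#' The null distribution of each statistic comes from \code{n_perm} seeded
#' permutations of module labels over the shared universe (size-matched
#' random member sets). Each statistic's Z is (observed - null mean) / null
#' SD; the density and connectivity composites are the medians of their
#' component Zs, and \deqn{Z_{summary} = (Z_{density} + Z_{connectivity})/2.}
#' Modules at \eqn{Z_{summary} \ge 1.96} are called preserved and at
#' \eqn{\ge 10} highly preserved (inclusive boundaries).
#'
#' @param ref_x reference proteins x samples matrix.
#' @param ref_labels named integer module labels from the reference network.
#' @param test_x test-cohort proteins x samples matrix.
#' @param beta signed soft power used for the adjacency (default 11).
#' @param n_perm label permutations (default 200; below 50 raises a
#'   warning).
#' @param seed integer seed for the permutation null.
#' @param cor_method \code{"bicor"} or \code{"pearson"}.
#' @param min_shared modules with fewer shared proteins are flagged
#'   (default 30) but still evaluated.
#' @return data.frame per module: shared size, component Zs,
#'   \code{Z_density}, \code{Z_connectivity}, \code{Z_summary},
#'   \code{category}, \code{flagged}; attributes \code{"n_perm"} and
#'   \code{"seed"}.
#' @export
modulePreservation <- function(ref_x, ref_labels, test_x, beta = 11,
                               n_perm = 200L, seed = 1L,
                               cor_method = c("bicor", "pearson"),
                               min_shared = 30L) {
  cor_method <- match.arg(cor_method)
  if (n_perm < 50L)
    warning("fewer than 50 permutations gives unstable Z estimates")
  shared <- intersect(rownames(ref_x), rownames(test_x))
  if (!length(shared)) stop("no shared proteins between cohorts")
  lab <- ref_labels[shared]
  ref_r <- .networkCorrelation(ref_x[shared, , drop = FALSE], cor_method)
  test_r <- .networkCorrelation(test_x[shared, , drop = FALSE], cor_method)
  ref_a <- signedAdjacency(ref_r, beta)
  test_a <- signedAdjacency(test_r, beta)
  xs_test <- .standardizeRows(test_x[shared, , drop = FALSE])

  mods <- sort(unique(lab[lab > 0L]))
  set.seed(seed)
  out <- list()
  for (m in mods) {
    members <- which(lab == m)
    nm <- length(members)
    if (nm < 3L) next
    obs <- .preservationStats(members, ref_r, test_r, ref_a, test_a, xs_test)
    null <- matrix(NA_real_, nrow = n_perm, ncol = 4L)
    for (b in seq_len(n_perm)) {
      perm <- sample(length(shared), nm)
      null[b, ] <- .preservationStats(perm, ref_r, test_r, ref_a, test_a,
                                      xs_test)
    }
    mu <- colMeans(null, na.rm = TRUE)
    sdv <- apply(null, 2L, sd, na.rm = TRUE)
    z <- (obs - mu) / sdv
    # a (near-)degenerate null carries no information: flag the Z missing
    degenerate <- !is.finite(sdv) | sdv < 1e-8 * pmax(1, abs(mu))
    z[degenerate] <- NA_real_
    z_density <- median(z[1:2], na.rm = TRUE)
    z_conn <- median(z[3:4], na.rm = TRUE)
    z_summary <- mean(c(z_density, z_conn), na.rm = TRUE)
    out[[as.character(m)]] <- data.frame(
      module = paste0("M", m), n_shared = nm,
      Z_meanAdj = z[1L], Z_propVar = z[2L],
      Z_cor_kIM = z[3L], Z_cor_cor = z[4L],
      Z_density = z_density, Z_connectivity = z_conn,
      Z_summary = z_summary,
      category = classifyPreservation(z_summary),
      flagged = nm < min_shared,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_perm") <- n_perm
  attr(res, "seed") <- seed
  res
}

# (meanAdj, propVar, cor.kIM, cor.cor) for one member index set
.preservationStats <- function(members, ref_r, test_r, ref_a, test_a,
                               xs_test) {
  off <- upper.tri(matrix(0, length(members), length(members)))
  ta <- test_a[members, members]
  ra <- ref_a[members, members]
  mean_adj <- mean(ta[off])
  prop_var <- .propVarExplained(xs_test[members, , drop = FALSE])
  kim_ref <- rowSums(ra) - 1
  kim_test <- rowSums(ta) - 1
  cor_kim <- if (sd(kim_ref) > 0 && sd(kim_test) > 0)
    cor(kim_ref, kim_test) else NA_real_
  rr <- ref_r[members, members][off]
  tr <- test_r[members, members][off]
  cor_cor <- if (sd(rr) > 0 && sd(tr) > 0) cor(rr, tr) else NA_real_
  c(mean_adj, prop_var, cor_kim, cor_cor)
}

.standardizeRows <- function(x) {
  mu <- rowMeans(x, na.rm = TRUE)
  sdv <- .rowSdsNA(x)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  xs <- (x - mu) / sdv
  xs[!is.finite(xs)] <- 0
  xs
}

# leading-eigenvalue share of total variance for a standardised submatrix
.propVarExplained <- function(xs) {
  tot <- sum(xs^2)
  if (tot == 0) return(NA_real_)
  cp <- if (nrow(xs) <= ncol(xs)) tcrossprod(xs) else crossprod(xs)
  ev <- eigen(cp, symmetric = TRUE, only.values = TRUE)$values[1L]
  ev / tot
}

#' Classify a preservation Z summary score
#'
#' Inclusive boundaries: below 1.96 not preserved; 1.96 up to (but not
#' including) 10 preserved; 10 and above highly preserved.
#'
#' @param z_summary numeric vector of Z summary scores.
#' @return character vector in \{"not", "preserved", "highly preserved"\}.
#' @export
classifyPreservation <- function(z_summary) {
  if (any(!is.finite(z_summary)))
    stop("Z_summary must be finite")
  ifelse(z_summary >= 10, "highly preserved",
         ifelse(z_summary >= 1.96, "preserved", "not"))
}

#' Synthetic eigenproteins of reference modules in a test cohort
#'
#' For each reference module, assembles a synthetic module in the test
#' cohort from the top \code{pct} (default 20th percentile) of the module's
#' members ranked by own-module kME, computes its eigenprotein in the test
#' data (same SVD and sign rules as the network build), and tests the
#' eigenprotein across test diagnosis groups by one-way ANOVA, with the
#' direction of each group's shift relative to the first (reference) group.
#'
#' @param ref_labels named integer reference module labels.
#' @param ref_kme proteins x modules reference kME matrix.
#' @param test_x test-cohort proteins x samples matrix.
#' @param test_groups factor (or coercible) per test sample.
#' @param pct top kME fraction defining the synthetic module (default 0.2;
#'   1.0 reproduces the full module).
#' @param min_members modules with fewer shared top members are skipped with
#'   a flag (default 4).
#' @return data.frame (module, n_top, n_shared, p_anova, skipped, one
#'   \code{dir_<group>} column per non-reference group); attribute
#'   \code{"eigenproteins"} holds the synthetic eigenprotein matrix.
#' @export
syntheticEigenproteins <- function(ref_labels, ref_kme, test_x, test_groups,
                                   pct = 0.2, min_members = 4L) {
  if (pct <= 0 || pct > 1) stop("pct must be in (0, 1]")
  test_groups <- factor(test_groups)
  if (length(test_groups) != ncol(test_x))
    stop("test_groups must have one label per test sample")
  mods <- sort(unique(ref_labels[ref_labels > 0L]))
  lev <- levels(test_groups)
  E <- matrix(NA_real_, nrow = length(mods), ncol = ncol(test_x),
              dimnames = list(paste0("M", mods), colnames(test_x)))
  rows <- list()
  for (i in seq_along(mods)) {
    m <- mods[i]
    ids <- names(ref_labels)[ref_labels == m]
    k <- ref_kme[ids, paste0("M", m)]
    top <- ids[order(-k, ids)][seq_len(ceiling(pct * length(ids)))]
    shared <- intersect(top, rownames(test_x))
    row <- data.frame(module = paste0("M", m), n_top = length(top),
                      n_shared = length(shared), p_anova = NA_real_,
                      skipped = length(shared) < min_members,
                      stringsAsFactors = FALSE)
    for (g in lev[-1L]) row[[paste0("dir_", g)]] <- NA_integer_
    if (!row$skipped) {
      e <- .singleEigenprotein(test_x[shared, , drop = FALSE])
      E[i, ] <- e
      ok <- is.finite(e)
      fit <- aov(e[ok] ~ test_groups[ok])
      row$p_anova <- summary(fit)[[1L]][["Pr(>F)"]][1L]
      mref <- mean(e[ok & test_groups == lev[1L]])
      for (g in lev[-1L])
        row[[paste0("dir_", g)]] <-
          as.integer(sign(mean(e[ok & test_groups == g]) - mref))
    }
    rows[[i]] <- row
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "eigenproteins") <- E
  res
}

.singleEigenprotein <- function(xm) {
  mu <- rowMeans(xm, na.rm = TRUE)
  sdv <- .rowSdsNA(xm)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  xs <- (xm - mu) / sdv
  empty <- colSums(is.finite(xs)) == 0L
  xs[!is.finite(xs)] <- 0
  sv <- svd(xs)
  e <- sv$v[, 1L]
  if (mean(as.numeric(xs %*% e)) < 0) e <- -e
  e[empty] <- NA_real_
  e
}

#' Hypergeometric overlap between two module partitions
#'
#' Cross-tabulates two module assignments over their shared protein
#' universe and computes, per module pair, the one-tailed hypergeometric
#' (Fisher exact) overlap p-value, with BH correction across the grid.
#'
#' @param labelsA,labelsB named integer module labels from two networks.
#' @return list with matrices \code{p}, \code{q}, \code{neg_log10_q},
#'   \code{overlap} and a \code{stars} character matrix (on q).
#' @export
moduleOverlap <- function(labelsA, labelsB) {
  shared <- intersect(names(labelsA), names(labelsB))
  if (!length(shared)) stop("no shared proteins between the partitions")
  a <- labelsA[shared]
  b <- labelsB[shared]
  modsA <- sort(unique(a[a > 0L]))
  modsB <- sort(unique(b[b > 0L]))
  N <- length(shared)
  p <- ov <- matrix(NA_real_, length(modsA), length(modsB),
                    dimnames = list(paste0("A.M", modsA),
                                    paste0("B.M", modsB)))
  for (i in seq_along(modsA)) {
    inA <- a == modsA[i]
    for (j in seq_along(modsB)) {
      inB <- b == modsB[j]
      k <- sum(inA & inB)
      ov[i, j] <- k
      p[i, j] <- phyper(k - 1, sum(inB), N - sum(inB), sum(inA),
                        lower.tail = FALSE)
    }
  }
  q <- matrix(bhCorrect(as.numeric(p)), nrow = nrow(p), dimnames = dimnames(p))
  list(p = p, q = q, neg_log10_q = -log10(q), overlap = ov,
       stars = matrix(.stars(q), nrow = nrow(q), dimnames = dimnames(q)))
}
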