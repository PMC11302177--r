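#' Filter proteins by missingness
#'
#' Retains exactly the proteins observed in at least \code{min_present_frac}
#' of samples; proteins with more missing values are removed from the matrix.
#' The sample set is unchanged and no values are imputed.
#'
#' @param x proteins x samples log2 abundance matrix (NAs allowed).
#' @param min_present_frac minimum fraction of samples with an observed
#'   value, default 0.5 (a protein missing in more than 50% of samples is
#'   dropped).
#' @return the filtered matrix, with attribute \code{"removed"} listing the
#'   dropped protein ids.
#' @export
filterMissingness <- function(x, min_present_frac = 0.5) {
  .checkAbundanceMatrix(x)
  if (min_present_frac <= 0 || min_present_frac > 1)
    stop("min_present_frac must be in (0, 1]")
  frac <- rowMeans(is.finite(x))
  keep <- frac >= min_present_frac
  if (!any(keep))
    warning("no proteins pass the missingness filter")
  out <- x[keep, , drop = FALSE]
  attr(out, "removed") <- rownames(x)[!keep]
  out
}

#' TAMPOR: two-factor iterative median-polish batch correction
#'
#' Removes inter-batch technical variance from a log2 abundance matrix by
#' alternating two median centrings until convergence: (factor 1) for each
#' protein and batch, subtract the median log2 abundance of that batch's
#' pooled global-internal-standard (GIS) samples for that protein; (factor 2)
#' for each sample, subtract that sample's median over proteins. The result
#' is a twice-centred log2 ratio matrix (abundance relative to the batch GIS
#' and to the sample's central tendency). Missing cells stay missing; the
#' procedure tolerates up to 50% missingness. When a protein has no observed
#' GIS value in a batch, the median of all that batch's samples stands in
#' for that protein/batch denominator.
#'
#' @param x proteins x samples log2 abundance matrix.
#' @param batch batch label per sample (length \code{ncol(x)}).
#' @param is_gis logical per sample; \code{TRUE} marks GIS channels. Required
#'   when \code{use_gis = TRUE} (every batch must contain at least one).
#' @param use_gis use GIS channels as the factor-1 denominators (default);
#'   \code{FALSE} falls back to the median over all intra-batch samples.
#' @param tol convergence tolerance on the maximum absolute cell change
#'   between successive iterations.
#' @param max_iter iteration cap; non-convergence raises a warning carrying
#'   the final delta.
#' @return corrected matrix with attributes \code{"iterations"},
#'   \code{"delta"} and \code{"converged"}.
#' @export
tampor <- function(x, batch, is_gis = NULL, use_gis = TRUE,
                   tol = 1e-8, max_iter = 250L) {
  .checkAbundanceMatrix(x)
  batch <- as.character(batch)
  if (length(batch) != ncol(x))
    stop("batch must have one label per sample")
  if (use_gis) {
    if (is.null(is_gis) || length(is_gis) != ncol(x))
      stop("is_gis flags are required in GIS mode")
    missing_gis <- setdiff(unique(batch), unique(batch[is_gis]))
    if (length(missing_gis))
      stop("batch(es) without a GIS sample: ",
           paste(missing_gis, collapse = ", "))
  }
  batches <- unique(batch)
  iter <- 0L
  delta <- Inf
  while (iter < max_iter && delta >= tol) {
    prev <- x
    for (b in batches) {
      cols <- batch == b
      ref <- if (use_gis) cols & is_gis else cols
      med <- .rowMediansNA(x[, ref, drop = FALSE])
      nofix <- is.na(med)
      if (any(nofix))
        med[nofix] <- .rowMediansNA(x[nofix, cols, drop = FALSE])
      med[is.na(med)] <- 0
      x[, cols] <- x[, cols] - med
    }
    smed <- .colMediansNA(x)
    smed[is.na(smed)] <- 0
    x <- sweep(x, 2L, smed, "-")
    delta <- max(abs(x - prev), na.rm = TRUE)
    iter <- iter + 1L
  }
  converged <- delta < tol
  if (!converged)
    warning(sprintf("TAMPOR did not converge in %d iterations (delta %.3g)",
                    max_iter, delta))
  attr(x, "iterations") <- iter
  attr(x, "delta") <- delta
  attr(x, "converged") <- converged
  x
}

#' Bootstrap regression of covariates with a protected diagnosis term
#'
#' Removes covariate-driven variance per protein while protecting the
#' diagnosis signal. For each protein, \code{n_boot} bootstrap resamples of
#' the samples are drawn (with replacement, stratified by the protected
#' group so every level stays represented); on each resample an ordinary
#' least squares fit of abundance on [protected dummies + covariates] is
#' computed from that protein's non-missing samples, and the per-covariate
#' median coefficient across resamples is retained. The correction subtracts
#' \eqn{\sum_c \hat\beta_{c,med} (covariate_c - \bar{covariate_c})} from each
#' sample's value; mean-centring preserves the grand mean, and
#' protected-variable coefficients are never subtracted.
#'
#' Proteins with fewer complete samples than (number of parameters + 2) are
#' left unregressed and flagged, as are proteins observed in fewer than two
#' protected levels.
#'
#' @param x proteins x samples matrix.
#' @param samples data.frame aligned to \code{colnames(x)}.
#' @param covariates column names of the numeric covariates to remove.
#' @param protected column name of the protected categorical variable.
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed integer seed for the resampling.
#' @return corrected matrix with attributes \code{"coefficients"} (proteins x
#'   covariates median bootstrap coefficients), \code{"unregressed"}
#'   (flagged protein ids) and \code{"seed"}.
#' @export
regressCovariates <- function(x, samples, covariates = c("age", "sex", "pmi"),
                              protected = "diagnosis", n_boot = 1000L,
                              seed = 1L) {
  .checkAbundanceMatrix(x)
  samples <- as.data.frame(samples)
  if (!all(colnames(x) %in% rownames(samples)) &&
      "sample_id" %in% colnames(samples))
    rownames(samples) <- samples$sample_id
  samples <- samples[colnames(x), , drop = FALSE]
  if (n_boot < 1L) stop("n_boot must be at least 1")
  covs <- as.matrix(samples[, covariates, drop = FALSE])
  if (anyNA(covs) || anyNA(samples[[protected]]))
    stop("covariates and the protected variable must be complete; subset ",
         "to biological samples first")
  if (any(apply(covs, 2L, function(v) length(unique(v)) < 2L)))
    stop("constant covariate")
  g <- factor(samples[[protected]])
  if (nlevels(g) < 2L)
    stop("protected variable needs at least 2 levels")

  set.seed(seed)
  cov_means <- colMeans(covs)
  cov_centered <- sweep(covs, 2L, cov_means, "-")
  beta_med <- matrix(NA_real_, nrow = nrow(x), ncol = length(covariates),
                     dimnames = list(rownames(x), covariates))
  unregressed <- character(0)

  for (i in seq_len(nrow(x))) {
    obs <- which(is.finite(x[i, ]))
    gi <- droplevels(g[obs])
    if (nlevels(gi) < 2L) {
      unregressed <- c(unregressed, rownames(x)[i])
      next
    }
    Xi <- cbind(`(Intercept)` = 1,
                stats::model.matrix(~gi)[, -1L, drop = FALSE],
                covs[obs, , drop = FALSE])
    q <- ncol(Xi)
    if (length(obs) < q + 2L) {
      unregressed <- c(unregressed, rownames(x)[i])
      next
    }
    # stratified bootstrap weights: multinomial resampling counts per level
    W <- matrix(0, nrow = length(obs), ncol = n_boot)
    for (lvl in levels(gi)) {
      idx <- which(gi == lvl)
      W[idx, ] <- rmultinom(n_boot, length(idx), rep(1, length(idx)))
    }
    # weighted normal equations, all bootstraps at once
    Z <- Xi[, rep(seq_len(q), q), drop = FALSE] *
      Xi[, rep(seq_len(q), each = q), drop = FALSE]        # n x q^2
    XtWX <- crossprod(Z, W)                                # q^2 x n_boot
    XtWy <- crossprod(Xi * x[i, obs], W)                   # q   x n_boot
    betas <- matrix(NA_real_, nrow = q, ncol = n_boot)
    for (b in seq_len(n_boot)) {
      A <- matrix(XtWX[, b], q, q)
      bb <- tryCatch(solve(A, XtWy[, b]), error = function(e) rep(NA_real_, q))
      betas[, b] <- bb
    }
    rownames(betas) <- colnames(Xi)
    beta_med[i, ] <- apply(betas[covariates, , drop = FALSE], 1L, median,
                           na.rm = TRUE)
    x[i, ] <- x[i, ] - as.numeric(cov_centered %*% beta_med[i, ])
  }
  attr(x, "coefficients") <- beta_med
  attr(x, "unregressed") <- unregressed
  attr(x, "seed") <- seed
  x
}

#' Remove network-connectivity outlier samples
#'
#' Computes each sample's total connectivity \eqn{k_j = \sum_{j' \ne j}
#' cor(sample_j, sample_{j'})} over standardised protein profiles
#' (pairwise-complete Pearson), standardises \eqn{k}, and removes samples
#' whose connectivity Z-score exceeds \code{z_cut} in either direction. The
#' removal is a single pass.
#'
#' @param x proteins x samples matrix.
#' @param z_cut Z-score threshold, default 3.
#' @return list with \code{matrix} (samples retained), \code{removed}
#'   (sample ids) and \code{z} (named connectivity Z-scores).
#' @export
removeConnectivityOutliers <- function(x, z_cut = 3) {
  .checkAbundanceMatrix(x)
  if (ncol(x) < 4L)
    stop("need at least 4 samples for connectivity outlier detection")
  xs <- (x - rowMeans(x, na.rm = TRUE)) / .rowSdsNA(x)
  C <- suppressWarnings(cor(xs, use = "pairwise.complete.obs"))
  k <- colSums(C, na.rm = TRUE) - 1
  z <- (k - mean(k)) / sd(k)
  names(z) <- colnames(x)
  drop <- abs(z) > z_cut
  if (all(drop))
    stop("all samples flagged as connectivity outliers")
  list(matrix = x[, !drop, drop = FALSE],
       removed = colnames(x)[drop],
       z = z)
}

#' Run the full preprocessing chain on a cohort
#'
#' Applies, in order: the missingness filter, TAMPOR batch correction (GIS
#' denominators), removal of GIS channels, bootstrap covariate regression
#' with the diagnosis protected, and single-pass connectivity outlier
#' removal.
#'
#' @param se a \code{SummarizedExperiment} with assay \code{"log2"} and
#'   colData columns \code{batch}, \code{is_gis}, \code{diagnosis} and the
#'   covariates.
#' @param min_present_frac,tampor_tol,tampor_max_iter,covariates,protected,n_boot,outlier_z,seed
#'   stage parameters; see the stage functions.
#' @param run_tampor,run_regression logical switches for the two heavier
#'   stages (both default \code{TRUE}).
#' @return a \code{SummarizedExperiment} of the analysis-ready matrix
#'   (biological samples only) whose \code{metadata(se)$preprocess} holds a
#'   report: proteins filtered, TAMPOR iterations and final delta, covariate
#'   coefficient summary, removed outlier samples, and the seed.
#' @export
preprocessCohort <- function(se, min_present_frac = 0.5,
                             tampor_tol = 1e-8, tampor_max_iter = 250L,
                             covariates = c("age", "sex", "pmi"),
                             protected = "diagnosis", n_boot = 1000L,
                             outlier_z = 3, seed = 1L,
                             run_tampor = TRUE, run_regression = TRUE) {
  x <- assay(se, "log2")
  cd <- as.data.frame(colData(se))
  report <- list(seed = seed)

  xf <- filterMissingness(x, min_present_frac)
  report$proteins_removed <- attr(xf, "removed")
  report$n_proteins <- nrow(xf)

  if (run_tampor) {
    xt <- tampor(xf, batch = cd$batch, is_gis = cd$is_gis,
                 tol = tampor_tol, max_iter = tampor_max_iter)
    report$tampor <- list(iterations = attr(xt, "iterations"),
                          delta = attr(xt, "delta"),
                          converged = attr(xt, "converged"))
  } else xt <- xf

  bio <- !cd$is_gis
  xb <- xt[, bio, drop = FALSE]
  cdb <- cd[bio, , drop = FALSE]

  if (run_regression) {
    xr <- regressCovariates(xb, cdb, covariates = covariates,
                            protected = protected, n_boot = n_boot,
                            seed = seed)
    report$regression <- list(
      coefficients = apply(attr(xr, "coefficients"), 2L, median, na.rm = TRUE),
      unregressed = attr(xr, "unregressed"),
      n_boot = n_boot)
  } else xr <- xb

  out <- removeConnectivityOutliers(xr, z_cut = outlier_z)
  report$outliers_removed <- out$removed

  md <- metadata(se)
  md$preprocess <- report
  SummarizedExperiment(
    assays = list(log2 = out$matrix),
    colData = colData(se)[colnames(out$matrix), , drop = FALSE],
    rowData = rowData(se)[rownames(out$matrix), , drop = FALSE],
    metadata = md
  )
}
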