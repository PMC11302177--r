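#' Per-protein one-way ANOVA with Tukey (or Bonferroni) post-hoc contrasts
#'
#' For every protein, fits a one-way ANOVA of abundance on the diagnosis
#' group using non-missing values, and computes adjusted pairwise p-values
#' for every group contrast: Tukey HSD via the studentized range
#' distribution, with the Tukey-Kramer generalisation for unequal group
#' sizes, or a Bonferroni-scaled pooled t-test. Log2 differences are
#' reported as (second level minus first level) for each contrast, so with
#' the control group as first factor level the contrasts read disease minus
#' control. Proteins with any tested group below 2 non-missing values are
#' flagged, not dropped; contrasts involving a group entirely missing for a
#' protein are \code{NA}.
#'
#' @param x proteins x samples matrix.
#' @param groups factor (or coercible) of length \code{ncol(x)}.
#' @param posthoc \code{"tukey"} (default) or \code{"bonferroni"}.
#' @return data.frame: per protein the per-group means and n, ANOVA F and p,
#'   and per contrast \code{log2fc_<a>_vs_<b>} (mean a minus mean b, a being
#'   the later factor level) and \code{p_<a>_vs_<b>}, plus a \code{flag}
#'   column.
#' @export
anovaTukey <- function(x, groups, posthoc = c("tukey", "bonferroni")) {
  .checkAbundanceMatrix(x)
  posthoc <- match.arg(posthoc)
  groups <- factor(groups)
  if (length(groups) != ncol(x))
    stop("groups must have one label per sample")
  lev <- levels(groups)
  k <- length(lev)
  if (k < 2L) stop("need at least 2 groups")

  fin <- is.finite(x)
  ns <- ms <- ss <- matrix(NA_real_, nrow(x), k, dimnames = list(rownames(x), lev))
  for (g in lev) {
    cols <- which(groups == g)
    xg <- x[, cols, drop = FALSE]
    fg <- fin[, cols, drop = FALSE]
    ns[, g] <- rowSums(fg)
    sums <- rowSums(xg, na.rm = TRUE)
    ms[, g] <- ifelse(ns[, g] > 0, sums / ns[, g], NA_real_)
    ss[, g] <- rowSums((xg - ms[, g])^2, na.rm = TRUE)
  }
  N <- rowSums(ns)
  k_used <- rowSums(ns >= 1)
  grand <- rowSums(ns * ms, na.rm = TRUE) / N
  ssb <- rowSums(ns * (ms - grand)^2, na.rm = TRUE)
  ssw <- rowSums(ss, na.rm = TRUE)
  df1 <- k_used - 1
  df2 <- N - k_used
  msw <- ssw / df2
  Fstat <- (ssb / df1) / msw
  p_anova <- ifelse(df1 >= 1 & df2 >= 1 & msw > 0,
                    pf(Fstat, df1, df2, lower.tail = FALSE),
                    ifelse(msw == 0 & ssb == 0, 1, NA_real_))

  out <- data.frame(protein = rownames(x), n = N, F = Fstat, p = p_anova,
                    stringsAsFactors = FALSE)
  for (g in lev) {
    out[[paste0("mean_", g)]] <- ms[, g]
    out[[paste0("n_", g)]] <- ns[, g]
  }
  pairs <- utils::combn(lev, 2L)
  n_pairs <- ncol(pairs)
  for (j in seq_len(n_pairs)) {
    a <- pairs[2L, j]; b <- pairs[1L, j]       # later level minus earlier
    diff <- ms[, a] - ms[, b]
    se2 <- msw * (1 / ns[, a] + 1 / ns[, b])
    valid <- ns[, a] >= 2 & ns[, b] >= 2 & msw > 0 & df2 >= 1
    if (posthoc == "tukey") {
      qstat <- abs(diff) / sqrt(se2 / 2)
      pp <- ifelse(valid,
                   ptukey(qstat, nmeans = k_used, df = df2,
                          lower.tail = FALSE),
                   NA_real_)
    } else {
      tstat <- abs(diff) / sqrt(se2)
      pp <- ifelse(valid,
                   pmin(1, 2 * pt(tstat, df2, lower.tail = FALSE) * n_pairs),
                   NA_real_)
    }
    pp[valid & se2 == 0 & diff == 0] <- 1
    out[[paste0("log2fc_", a, "_vs_", b)]] <- diff
    out[[paste0("p_", a, "_vs_", b)]] <- pp
  }
  out$flag <- apply(ns, 1L, function(v) any(v < 2))
  out
}

#' Per-protein two-group Welch t-test
#'
#' Welch (unequal-variance) t-test of every protein between two sample
#' groups, e.g. the CERAD-defined low (0-1) versus high (2-3) amyloid
#' stratification. Uses non-missing values per protein.
#'
#' @param x proteins x samples matrix.
#' @param labels two-level factor (or coercible) per sample.
#' @param ref the reference level; log2 differences are (other - ref).
#' @return data.frame with \code{log2fc}, \code{t}, \code{df}, \code{p},
#'   group means and ns, and BH-adjusted \code{q}.
#' @export
twoGroupTest <- function(x, labels, ref = NULL) {
  .checkAbundanceMatrix(x)
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("labels must have exactly two levels")
  if (!is.null(ref)) labels <- stats::relevel(labels, ref = ref)
  lev <- levels(labels)
  fin <- is.finite(x)
  stat <- lapply(lev, function(g) {
    cols <- which(labels == g)
    xg <- x[, cols, drop = FALSE]
    n <- rowSums(fin[, cols, drop = FALSE])
    m <- ifelse(n > 0, rowSums(xg, na.rm = TRUE) / n, NA_real_)
    v <- rowSums((xg - m)^2, na.rm = TRUE) / pmax(n - 1, 1)
    list(n = n, m = m, v = v)
  })
  n1 <- stat[[1]]$n; n2 <- stat[[2]]$n
  ok <- n1 >= 2 & n2 >= 2
  delta <- stat[[2]]$m - stat[[1]]$m
  se2 <- stat[[1]]$v / n1 + stat[[2]]$v / n2
  t <- delta / sqrt(se2)
  df <- se2^2 / ((stat[[1]]$v / n1)^2 / (n1 - 1) +
                   (stat[[2]]$v / n2)^2 / (n2 - 1))
  p <- ifelse(ok, 2 * pt(-abs(t), df), NA_real_)
  p[ok & se2 == 0 & delta == 0] <- 1
  out <- data.frame(
    protein = rownames(x),
    log2fc = delta, t = t, df = df, p = p,
    stringsAsFactors = FALSE
  )
  out[[paste0("mean_", lev[1])]] <- stat[[1]]$m
  out[[paste0("mean_", lev[2])]] <- stat[[2]]$m
  out[[paste0("n_", lev[1])]] <- n1
  out[[paste0("n_", lev[2])]] <- n2
  out$q <- p.adjust(out$p, method = "BH")
  out
}

#' Correlate every protein to a seed protein's abundance
#'
#' Volcano-style table of the biweight midcorrelation (and Student-t p) of
#' each protein against a chosen seed protein, with counts of significant
#' positive and negative correlators. The seed's self-correlation is
#' excluded from the counts.
#'
#' @param x proteins x samples matrix.
#' @param seed_protein row name of the seed.
#' @param p_threshold significance threshold for the correlator counts
#'   (default unadjusted 0.05).
#' @return data.frame (protein, r, p, n, is_seed) with attributes
#'   \code{"n_positive"} and \code{"n_negative"}.
#' @export
correlateToSeed <- function(x, seed_protein, p_threshold = 0.05) {
  .checkAbundanceMatrix(x)
  if (!seed_protein %in% rownames(x)) {
    near <- utils::head(agrep(seed_protein, rownames(x), value = TRUE,
                              max.distance = 0.3), 5L)
    stop("seed protein '", seed_protein, "' not found",
         if (length(near)) paste0("; nearest ids: ",
                                  paste(near, collapse = ", ")))
  }
  r <- bicorMatrix(t(x), t(x[seed_protein, , drop = FALSE]))
  n <- attr(r, "n")
  out <- data.frame(
    protein = rownames(x),
    r = as.numeric(r),
    p = bicorPValue(as.numeric(r), as.numeric(n)),
    n = as.numeric(n),
    is_seed = rownames(x) == seed_protein,
    stringsAsFactors = FALSE
  )
  sig <- !out$is_seed & !is.na(out$p) & out$p < p_threshold
  attr(out, "n_positive") <- sum(sig & out$r > 0)
  attr(out, "n_negative") <- sum(sig & out$r < 0)
  out
}

#' Correlate profiles to a sample trait
#'
#' Pearson or biweight midcorrelation of one or many protein (or
#' eigenprotein) profiles against a numeric trait, on pairwise-complete
#' observations.
#'
#' @param x numeric vector, or a matrix with profiles in rows.
#' @param trait numeric trait per sample.
#' @param method \code{"pearson"} or \code{"bicor"}.
#' @return data.frame (profile, r, p, n, flag); \code{flag} marks an
#'   undefined correlation (e.g. constant trait).
#' @export
traitCorrelation <- function(x, trait, method = c("bicor", "pearson")) {
  method <- match.arg(method)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L,
                                   dimnames = list("profile", names(x)))
  if (ncol(x) != length(trait))
    stop("trait must have one value per sample")
  if (method == "bicor") {
    r <- bicorMatrix(t(x), cbind(trait = as.numeric(trait)))
    n <- attr(r, "n")
    r <- as.numeric(r); n <- as.numeric(n)
  } else {
    r <- n <- numeric(nrow(x))
    for (i in seq_len(nrow(x))) {
      ok <- is.finite(x[i, ]) & is.finite(trait)
      n[i] <- sum(ok)
      r[i] <- if (n[i] >= 3 && sd(trait[ok]) > 0 && sd(x[i, ok]) > 0)
        cor(x[i, ok], trait[ok]) else NA_real_
    }
  }
  data.frame(
    profile = rownames(x) %||% paste0("row", seq_len(nrow(x))),
    r = r,
    p = bicorPValue(r, n),
    n = n,
    flag = !is.finite(r),
    stringsAsFactors = FALSE
  )
}
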