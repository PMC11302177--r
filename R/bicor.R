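#' Biweight midcorrelation
#'
#' Robust correlation based on median/MAD biweights. Each observation is
#' weighted by \eqn{w_i = (1 - u_i^2)^2} with \eqn{u_i = (x_i -
#' \mathrm{med}(x)) / (9\,\mathrm{MAD}(x))} and weight zero where
#' \eqn{|u_i| \ge 1}, so values far from the median cannot dominate the
#' estimate. Medians and MADs are computed per variable from all of its
#' observed values; sums run over pairwise-complete observations only, and no
#' values are imputed. Variables with \code{MAD = 0} fall back to Pearson
#' weighting (mean centring, unit weights) and are flagged.
#'
#' @param x numeric vector.
#' @param y numeric vector of the same length.
#' @return A one-row \code{data.frame} with columns \code{r}, \code{p}
#'   (two-sided Student-t transform, \code{NA} when fewer than 3 complete
#'   pairs), \code{n} (pairwise-complete count) and \code{fallback}
#'   (\code{TRUE} when either variable used the Pearson fallback).
#' @examples
#' x <- rnorm(50); y <- x + rnorm(50)
#' bicor(x, y)
#' @seealso \code{\link{bicorMatrix}} for all-pairs computation.
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have the same length")
  m <- cbind(x = as.numeric(x), y = as.numeric(y))
  r <- bicorMatrix(m)
  fb <- attr(r, "pearson_fallback")
  n <- sum(is.finite(x) & is.finite(y))
  data.frame(
    r = r["x", "y"],
    p = bicorPValue(r["x", "y"], n),
    n = n,
    fallback = any(fb)
  )
}

#' Two-sided p-value for a correlation via the Student-t transform
#'
#' @param r correlation estimate(s).
#' @param n number(s) of pairwise-complete observations.
#' @return p-values; \code{NA} where \code{n < 3} or \code{r} is \code{NA}.
#' @export
bicorPValue <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- is.finite(r) & n >= 3
  rr <- pmin(pmax(r[ok], -1), 1)
  t <- rr * sqrt((n[ok] - 2) / pmax(1 - rr^2, .Machine$double.eps))
  p[ok] <- 2 * pt(-abs(t), df = n[ok] - 2)
  p
}

#' All-pairs biweight midcorrelation matrix
#'
#' Computes \code{bicor} between every pair of columns of \code{x} (and
#' optionally between columns of \code{x} and \code{y}), using
#' pairwise-complete observations. Vectorised: weighted centred values are
#' zeroed at missing cells so that cross-products automatically sum over the
#' common support, and per-pair denominators are recovered from masked sums of
#' squares.
#'
#' @param x numeric matrix, observations in rows, variables in columns.
#' @param y optional second matrix with the same number of rows.
#' @return correlation matrix with attributes \code{pearson_fallback}
#'   (logical per column of \code{x}; and \code{pearson_fallback_y}) and
#'   \code{n} (pairwise-complete counts).
#' @export
bicorMatrix <- function(x, y = NULL) {
  x <- as.matrix(x)
  px <- .bicorPrepare(x)
  if (is.null(y)) {
    num <- crossprod(px$U)
    d <- crossprod(px$U^2, px$M)             # d[a, b] = sum_common U_a^2
    den <- sqrt(d * t(d))
    r <- num / den
    r[den == 0] <- NA_real_
    diag(r) <- ifelse(colSums(px$M) > 0, 1, NA_real_)
    dimnames(r) <- list(colnames(x), colnames(x))
    attr(r, "pearson_fallback") <- px$fallback
    attr(r, "n") <- crossprod(px$M)
    return(r)
  }
  y <- as.matrix(y)
  if (nrow(y) != nrow(x))
    stop("x and y must have the same number of rows")
  py <- .bicorPrepare(y)
  num <- crossprod(px$U, py$U)
  dx <- crossprod(px$U^2, py$M)              # sum over common of U_x^2
  dy <- crossprod(px$M, py$U^2)
  den <- sqrt(dx * dy)
  r <- num / den
  r[den == 0] <- NA_real_
  dimnames(r) <- list(colnames(x), colnames(y))
  attr(r, "pearson_fallback") <- px$fallback
  attr(r, "pearson_fallback_y") <- py$fallback
  attr(r, "n") <- crossprod(px$M, py$M)
  r
}

# weighted, centred, NA-zeroed column matrix for bicor cross-products
.bicorPrepare <- function(x) {
  M <- is.finite(x)
  xw <- x
  xw[!M] <- NA_real_
  med <- apply(xw, 2L, median, na.rm = TRUE)
  madv <- apply(xw, 2L, function(v) median(abs(v - median(v, na.rm = TRUE)),
                                           na.rm = TRUE))
  fallback <- !is.na(madv) & madv == 0
  center <- med
  if (any(fallback))
    center[fallback] <- colMeans(xw[, fallback, drop = FALSE], na.rm = TRUE)
  ctr <- sweep(xw, 2L, center, "-")
  u <- sweep(ctr, 2L, 9 * madv, "/")
  w <- (1 - u^2)^2
  w[abs(u) >= 1] <- 0
  if (any(fallback))
    w[, fallback] <- 1
  U <- ctr * w
  U[!M] <- 0
  list(U = U, M = M * 1, fallback = fallback)
}
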