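mkmat <- function(v, nr, nc, ids = NULL, samples = NULL) {
  m <- matrix(v, nr, nc)
  rownames(m) <- ids %||% sprintf("P%03d", seq_len(nr))
  colnames(m) <- samples %||% sprintf("S%03d", seq_len(nc))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("missingness filter keeps exactly the sufficiently observed", {
  m <- mkmat(rnorm(100), 10, 10)
  m[1, 1:6] <- NA      # present in 4 of 10 -> dropped at 0.5
  m[2, 1:5] <- NA      # present in 5 of 10 -> retained (boundary)
  f <- filterMissingness(m, 0.5)
  expect_false("P001" %in% rownames(f))
  expect_true("P002" %in% rownames(f))
  expect_equal(attr(f, "removed"), "P001")
  # monotone: a stricter threshold never retains more proteins
  for (fr in c(0.3, 0.5, 0.7, 0.9)) {
    expect_lte(nrow(filterMissingness(m, fr + 0.1)),
               nrow(filterMissingness(m, fr)))
  }
})

test_that("fully observed matrix passes the filter unchanged", {
  m <- mkmat(rnorm(60), 6, 10)
  expect_equal(filterMissingness(m, 0.5)[, ], m[, ])
})

test_that("tampor reaches a fixed point on pre-centred data", {
  # 3 proteins x (2 batches x {2 biological + 1 GIS}); GIS rows already 0
  # and sample medians 0
  m <- mkmat(0, 3, 6)
  m[, c(1, 4)] <- c(1, -1, 0)     # biological contrasts, median 0 per sample
  m[, c(2, 5)] <- c(-1, 1, 0)
  batch <- rep(c("b1", "b2"), each = 3)
  is_gis <- rep(c(FALSE, FALSE, TRUE), 2)
  out <- tampor(m, batch, is_gis)
  expect_equal(attr(out, "iterations"), 1L)
  expect_equal(out[, ], m[, ], tolerance = 1e-12)
})

test_that("tampor removes an additive batch offset (hand median polish)", {
  set.seed(10)
  base <- mkmat(rnorm(18), 3, 6)
  batch <- rep(c("b1", "b2"), each = 3)
  is_gis <- rep(c(FALSE, FALSE, TRUE), 2)
  shifted <- base
  shifted[, batch == "b2"] <- shifted[, batch == "b2"] + 0.8
  out_base <- tampor(base, batch, is_gis)
  out_shift <- tampor(shifted, batch, is_gis)
  # the +0.8 batch shift is annihilated: both inputs give the same result
  expect_equal(out_shift[, ], out_base[, ], tolerance = 1e-7)
  b_means <- tapply(colMeans(out_shift), batch, mean)
  expect_lt(abs(b_means["b1"] - b_means["b2"]),
            abs(diff(tapply(colMeans(shifted), batch, mean))))
})

test_that("tampor is idempotent and preserves within-batch contrasts", {
  cfg <- smallConfig(seed = 13L, batch_sd = 0.5)
  se <- simulateCohort(cfg)
  cd <- as.data.frame(colData(se))
  x <- filterMissingness(assay(se, "log2"))
  out <- tampor(x, cd$batch, cd$is_gis)
  again <- tampor(out[, ], cd$batch, cd$is_gis)
  expect_lt(max(abs(again[, ] - out[, ]), na.rm = TRUE), 1e-6)
  # factor structure: within-batch sample contrasts survive up to the
  # sample-median offsets
  b1 <- which(cd$batch == "b01" & !cd$is_gis)[1:2]
  d_in <- x[, b1[1]] - x[, b1[2]]
  d_out <- out[, b1[1]] - out[, b1[2]]
  expect_equal(sd(d_in - d_out, na.rm = TRUE), 0, tolerance = 1e-6)
})

test_that("tampor demands GIS coverage and reports non-convergence", {
  m <- mkmat(rnorm(40), 4, 10)
  expect_error(tampor(m, rep(c("b1", "b2"), each = 5),
                      is_gis = c(TRUE, rep(FALSE, 9))),
               "without a GIS")
  cfg <- smallConfig(seed = 14L, batch_sd = 0.5)
  se <- simulateCohort(cfg)
  cd <- as.data.frame(colData(se))
  x <- filterMissingness(assay(se, "log2"))
  expect_warning(tampor(x, cd$batch, cd$is_gis, max_iter = 1L),
                 "did not converge")
})

test_that("batch-explained variance collapses after tampor", {
  # signal-light cohort so batch variance dominates the planted biology
  cfg <- simConfig(n_proteins = 200L, module_sizes = c(30L, 25L, 25L),
                   groups = c(CTL = 20L, DLB = 20L),
                   n_batches = 4L, channels_per_batch = 11L,
                   batch_sd = 0.5, noise_sd = 0.5,
                   bottleneck_targets = 1:3,
                   bottleneck_weights = c(2, 2, 2), seed = 15L)
  se <- simulateCohort(cfg)
  cd <- as.data.frame(colData(se))
  x <- filterMissingness(assay(se, "log2"))
  out <- tampor(x, cd$batch, cd$is_gis)
  bio <- !cd$is_gis
  frac <- function(m) {
    b <- factor(cd$batch[bio])
    mean(apply(m[, bio], 1L, function(v) {
      ok <- is.finite(v)
      summary(lm(v[ok] ~ b[ok]))$adj.r.squared   # unbiased under the null
    }))
  }
  expect_gt(frac(x), 0.20)
  expect_lt(frac(out), 0.02)
})

test_that("regression leaves a null covariate essentially untouched", {
  set.seed(16)
  n <- 120
  x <- mkmat(rnorm(20 * n), 20, n)
  samples <- data.frame(sample_id = colnames(x),
                        diagnosis = rep(c("CTL", "DLB"), each = n / 2),
                        age = rnorm(n, 75, 8), sex = rbinom(n, 1, 0.5),
                        pmi = rnorm(n, 12, 3), row.names = colnames(x))
  out <- regressCovariates(x, samples, n_boot = 200L, seed = 1L)
  # null covariates: correction is sampling noise only
  expect_gt(cor(as.numeric(out), as.numeric(x)), 0.97)
  expect_lt(median(abs(out[, ] - x[, ])), 0.2)
})

test_that("regression removes a planted age slope, protecting diagnosis", {
  fx <- smallCohort()
  out <- regressCovariates(fx$x, fx$samples, n_boot = 300L, seed = 2L)
  planted <- fx$truth@membership[rownames(fx$x)] %in% paste0("M", 1:5)
  age <- fx$samples$age
  r_after <- traitCorrelation(out[, ], age)$r
  expect_lt(median(abs(r_after[planted])), 0.05)
  # diagnosis contrast preserved: pooled over planted proteins, the
  # post-regression log2FCs regress on the pre-regression ones with a
  # slope within 10% of 1
  grp <- fx$samples$diagnosis
  fc <- function(m) rowMeans(m[planted, grp == "DLB"], na.rm = TRUE) -
    rowMeans(m[planted, grp == "CTL"], na.rm = TRUE)
  slope <- coef(lm(fc(out[, ]) ~ 0 + fc(fx$x)))[[1L]]
  expect_lt(abs(slope - 1), 0.1)
  # coefficient estimates centred on the planted slope; background
  # proteins have independent errors, so their median pins it tightly
  # (module proteins share their latent's sampling error and scatter more)
  coefs <- attr(out, "coefficients")
  bg <- fx$truth@membership[rownames(fx$x)] == "unassigned"
  expect_equal(median(coefs[bg, "age"], na.rm = TRUE), 0.02,
               tolerance = 0.005)
})

test_that("proteins with too few complete cases are flagged unregressed", {
  set.seed(17)
  x <- mkmat(rnorm(5 * 30), 5, 30)
  x[1, 6:30] <- NA                        # 5 complete values only
  samples <- data.frame(sample_id = colnames(x),
                        diagnosis = rep(c("CTL", "DLB"), 15),
                        age = rnorm(30, 75, 8), sex = rbinom(30, 1, 0.5),
                        pmi = rnorm(30, 12, 3), row.names = colnames(x))
  out <- regressCovariates(x, samples, n_boot = 50L, seed = 3L)
  expect_true("P001" %in% attr(out, "unregressed"))
  expect_equal(out[1, ], x[1, ])
})

test_that("connectivity outlier removal behaves under null and planted", {
  fx <- smallCohort()
  res <- removeConnectivityOutliers(fx$x, z_cut = 3)
  expect_lte(length(res$removed), 2L)     # homogeneous cohort: ~0-1
  # replace one sample with independent noise -> removed
  x2 <- fx$x
  x2[, 5] <- rnorm(nrow(x2), sd = 2)
  res2 <- removeConnectivityOutliers(x2, z_cut = 3)
  expect_true(colnames(x2)[5] %in% res2$removed)
  expect_lt(res2$z[5], -3)
  expect_error(removeConnectivityOutliers(fx$x[, 1:3]), "at least 4")
})

test_that("preprocessCohort chains the stages and reports", {
  cfg <- smallConfig(seed = 18L, batch_sd = 0.3)
  se <- simulateCohort(cfg)
  out <- preprocessCohort(se, n_boot = 50L, seed = 4L)
  rep <- metadata(out)$preprocess
  expect_true(rep$tampor$converged)
  expect_false(any(colData(out)$is_gis))
  expect_equal(rep$n_proteins, nrow(out))
  expect_true(all(c("age", "sex", "pmi") %in%
                    names(rep$regression$coefficients)))
})
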