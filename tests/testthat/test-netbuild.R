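test_that("signed adjacency endpoints and monotonicity", {
  r <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(signedAdjacency(r, 11)[1, 2], 1)
  r[1, 2] <- r[2, 1] <- -1
  expect_equal(signedAdjacency(r, 11)[1, 2], 0)
  r[1, 2] <- r[2, 1] <- 0
  expect_equal(signedAdjacency(r, 11)[1, 2], 2^-11)
  set.seed(30)
  m <- matrix(rnorm(100), 10)
  rr <- cor(m)
  a <- signedAdjacency(rr, 6)
  ut <- upper.tri(rr)
  ord <- order(rr[ut])
  expect_true(all(diff(a[ut][ord]) >= 0))      # increasing in r
  bad <- rr; bad[1, 2] <- 0.5; bad[2, 1] <- -0.5
  expect_error(signedAdjacency(bad, 6), "symmetric")
})

test_that("TOM matches brute-force triple loops and handles edge cases", {
  # clique: all adjacency 1 -> TOM 1
  a1 <- matrix(1, 3, 3)
  expect_true(all(tomSimilarity(a1) == 1))
  # empty graph: off-diagonal 0
  a0 <- diag(3)
  t0 <- tomSimilarity(a0)
  expect_true(all(t0[upper.tri(t0)] == 0))
  # brute-force oracle on random matrices, both denominators
  set.seed(31)
  for (rep in 1:10) {
    n <- 10
    a <- matrix(runif(n * n), n)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    for (denom in c("mean", "min")) {
      tom <- tomSimilarity(a, denom)
      ref <- diag(n)
      for (i in 1:n) for (j in 1:n) {
        if (i == j) next
        l <- sum(a[i, -c(i, j)] * a[-c(i, j), j])
        ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
        f <- if (denom == "mean") (ki + kj) / 2 else min(ki, kj)
        ref[i, j] <- (l + a[i, j]) / (f + 1 - a[i, j])
      }
      expect_lt(max(abs(tom - ref)), 1e-12)
      expect_true(all(tom >= 0 & tom <= 1))
      expect_true(isSymmetric(unname(tom)))
    }
  }
})

test_that("soft-threshold diagnostics behave with power", {
  fx <- smallCohort()
  st <- pickSoftThreshold(fx$x[1:150, ], powers = c(2, 6, 11, 16))
  expect_true(all(diff(st$mean_k) < 0))        # mean k strictly decreasing
  # power = 1 on an all-r=1 block: mean connectivity = size - 1
  blk <- matrix(rep(rnorm(30), times = 21), nrow = 21, byrow = TRUE)
  rownames(blk) <- sprintf("B%02d", 1:21)
  colnames(blk) <- sprintf("S%02d", 1:30)
  st1 <- pickSoftThreshold(blk, powers = 1)
  expect_equal(st1$mean_k, 20, tolerance = 1e-6)
})

test_that("perfectly separated blocks are cut into exactly their modules", {
  set.seed(32)
  s1 <- rnorm(40); s2 <- rnorm(40)
  x <- rbind(matrix(rep(s1, each = 50), 50, byrow = FALSE) * 0 +
               outer(runif(50, 0.8, 1), s1),
             outer(runif(50, 0.8, 1), s2))
  rownames(x) <- sprintf("P%03d", 1:100)
  colnames(x) <- sprintf("S%03d", 1:40)
  tom <- tomSimilarity(signedAdjacency(cor(t(x)), 11))
  cut <- cutModules(tom, min_module_size = 25)
  expect_equal(length(unique(cut$labels[cut$labels > 0])), 2L)
  expect_equal(sum(cut$labels == 0), 0L)
  # labels align perfectly with the two blocks
  expect_equal(length(unique(cut$labels[1:50])), 1L)
  expect_equal(length(unique(cut$labels[51:100])), 1L)
})

test_that("modules below the minimum size dissolve to unassigned", {
  set.seed(33)
  s1 <- rnorm(40); s2 <- rnorm(40)
  x <- rbind(outer(runif(40, 0.8, 1), s1),      # size 40: kept
             outer(runif(10, 0.8, 1), s2),      # size 10: dissolved
             matrix(rnorm(50 * 40), 50))        # background
  rownames(x) <- sprintf("P%03d", 1:100)
  colnames(x) <- sprintf("S%03d", 1:40)
  x <- x + rnorm(length(x), sd = 0.4)
  tom <- tomSimilarity(signedAdjacency(cor(t(x)), 11))
  cut <- cutModules(tom, min_module_size = 25)
  expect_true(all(cut$labels[41:50] == 0))
  expect_equal(length(unique(cut$labels[1:40])), 1L)
  expect_true(unique(cut$labels[1:40]) > 0)
})

test_that("eigenproteins: duplicates, sign symmetry and planted latents", {
  # module of 2 identical proteins: E equals the standardised profile
  v <- rnorm(30)
  x <- rbind(P1 = v, P2 = v)
  colnames(x) <- sprintf("S%02d", 1:30)
  lab <- setNames(c(1L, 1L), rownames(x))
  el <- moduleEigenproteins(x, lab)
  expect_equal(el$varExplained[["M1"]], 1, tolerance = 1e-12)
  std <- (v - mean(v)) / sd(v)
  expect_equal(abs(cor(el$E["M1", ], std)), 1, tolerance = 1e-10)
  expect_gt(cor(el$E["M1", ], std), 0)          # sign-aligned to members
  # flipping member values flips E but not |kME|
  el2 <- moduleEigenproteins(-x, lab)
  expect_equal(el2$E["M1", ], -el$E["M1", ], tolerance = 1e-10)
  km <- moduleKME(x, el$E)
  km2 <- moduleKME(-x, el2$E)
  expect_equal(abs(km$kme), abs(km2$kme), tolerance = 1e-10)
  # planted module latent recovered
  fx <- smallCohort()
  labp <- plantedLabels(fx$truth, rownames(fx$x))
  elp <- moduleEigenproteins(fx$x, labp)
  cc <- abs(cor(elp$E["M1", ], fx$truth@moduleScores["M1", colnames(fx$x)]))
  expect_gte(cc, 0.9)
})

test_that("kME separates hubs from noise and the planted bottleneck", {
  fx <- smallCohort()
  labp <- plantedLabels(fx$truth, rownames(fx$x))
  el <- moduleEigenproteins(fx$x, labp)
  km <- moduleKME(fx$x, el$E)
  memb <- fx$truth@membership[rownames(fx$x)]
  lam <- fx$truth@loadings[rownames(fx$x)]
  hub <- names(which.max(lam * (memb == "M1")))
  expect_gt(km$kme[hub, "M1"], 0.75)
  # noise proteins: small kME, p roughly uniform
  bg <- memb == "unassigned"
  expect_lt(median(abs(km$kme[bg, "M1"])), 0.2)
  expect_gt(ks.test(km$p[bg, "M1"], "punif")$p.value, 0.001)
  # bottleneck: moderate membership in all of its target modules,
  # well below hub strength (population value ~0.6; wide sampling window)
  kb <- km$kme[fx$truth@bottleneckId, names(fx$truth@bottleneckWeights)]
  expect_true(all(kb > 0.4 & kb < 0.8))
  expect_true(all(kb < km$kme[hub, "M1"]))
})

test_that("reassignment fixes a planted mislabel and reaches fixed points", {
  fx <- smallCohort()
  labp <- plantedLabels(fx$truth, rownames(fx$x))
  moved <- names(labp)[labp == 1L][1:2]
  wrong <- labp
  wrong[moved] <- 2L                      # mislabel two M1 proteins as M2
  fixed <- reassignModules(fx$x, wrong, min_module_size = 20L)
  expect_equal(unname(fixed[moved]), unname(labp[moved]))
  # clean planted labels: (near) fixed point, nothing moves between modules
  clean <- reassignModules(fx$x, labp, min_module_size = 20L)
  agree <- mean(clean[labp > 0] == labp[labp > 0])
  expect_gt(agree, 0.98)
})

test_that("merging collapses split modules but respects the cut height", {
  fx <- smallCohort()
  labp <- plantedLabels(fx$truth, rownames(fx$x))
  # artificially split M1 into two labels -> eigenproteins correlate ~1
  split <- labp
  ids1 <- names(labp)[labp == 1L]
  split[ids1[1:30]] <- 6L
  merged <- mergeModules(fx$x, split, merge_cut_height = 0.07)
  expect_equal(length(unique(merged[ids1])), 1L)
  # distinct planted modules (eigenprotein corr << 0.93) stay separate
  merged2 <- mergeModules(fx$x, labp, merge_cut_height = 0.07)
  expect_equal(length(unique(merged2[merged2 > 0])), 5L)
})

test_that("merge decisions use the 0.07 dissimilarity boundary", {
  # two synthetic eigen-profiles with controlled correlation
  set.seed(34)
  n <- 200
  base <- rnorm(n)
  mk2 <- function(r_target) {
    e2 <- r_target * base + sqrt(1 - r_target^2) * rnorm(n)
    x <- rbind(outer(runif(30, 0.9, 1), base), outer(runif(30, 0.9, 1), e2))
    x <- x + rnorm(length(x), sd = 0.05)
    rownames(x) <- sprintf("P%03d", 1:60)
    colnames(x) <- sprintf("S%03d", 1:n)
    lab <- setNames(rep(c(1L, 2L), each = 30), rownames(x))
    length(unique(mergeModules(x, lab, 0.07)[mergeModules(x, lab, 0.07) > 0]))
  }
  expect_equal(mk2(0.98), 1L)             # dissimilarity 0.02 < 0.07: merged
  expect_equal(mk2(0.80), 2L)             # dissimilarity 0.20 > 0.07: kept
})

test_that("network build is deterministic and order-invariant", {
  fx <- smallCohort()
  x <- fx$x[1:150, ]
  net1 <- buildNetwork(x, min_module_size = 20L)
  net2 <- buildNetwork(x, min_module_size = 20L)
  expect_identical(moduleLabels(net1), moduleLabels(net2))
  # permuting protein rows and sample columns does not change the partition
  set.seed(35)
  perm <- sample(nrow(x)); cperm <- sample(ncol(x))
  net3 <- buildNetwork(x[perm, cperm], min_module_size = 20L)
  l1 <- moduleLabels(net1)
  l3 <- moduleLabels(net3)[names(l1)]
  expect_gt(mclust::adjustedRandIndex(l1, l3), 0.95)
})

test_that("a structure-free matrix yields no sizeable modules", {
  set.seed(36)
  x <- matrix(rnorm(300 * 50), 300)
  rownames(x) <- sprintf("P%03d", 1:300)
  colnames(x) <- sprintf("S%03d", 1:50)
  net <- buildNetwork(x)
  expect_lte(length(unique(moduleLabels(net)[moduleLabels(net) > 0])), 1L)
})

test_that("full build recovers the planted partition", {
  fx <- smallCohort()
  net <- smallNetwork()
  lab <- moduleLabels(net)
  memb <- fx$truth@membership[names(lab)]
  expect_equal(length(unique(lab[lab > 0])), 5L)
  expect_gte(mclust::adjustedRandIndex(memb, paste0("L", lab)), 0.75)
  # each planted module lands on a single recovered label, near-completely
  for (m in paste0("M", 1:5)) {
    tab <- table(lab[memb == m])
    expect_gte(max(tab) / sum(tab), 0.9)
    expect_true(names(which.max(tab)) != "0")
  }
  expect_gte(min(eigenTruthCor(net, fx$truth)), 0.9)
  # unassigned fraction in a plausible band
  expect_gt(mean(lab == 0), 0.02)
  expect_lt(mean(lab == 0), 0.35)
})
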