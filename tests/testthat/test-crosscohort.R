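test_that("preservation categories use inclusive 1.96 / 10 boundaries", {
  expect_equal(classifyPreservation(c(0, 1.95, 1.96, 2.5, 9.99, 10, 11)),
               c("not", "not", "preserved", "preserved", "preserved",
                 "highly preserved", "highly preserved"))
  expect_error(classifyPreservation(NA_real_), "finite")
})

test_that("planted modules are highly preserved in a replication cohort", {
  fx <- smallCohort()
  rep_se <- simulateReplication(fx$truth, seed = 51L)
  test_x <- assay(rep_se, "log2")[, !colData(rep_se)$is_gis]
  labp <- plantedLabels(fx$truth, rownames(fx$x))
  pres <- modulePreservation(fx$x, labp, test_x, n_perm = 100L, seed = 1L)
  expect_equal(nrow(pres), 5L)
  # modules above the evaluation floor: highly preserved; the smallest
  # (below min_shared, flagged) still clears the preserved boundary
  expect_true(all(pres$Z_summary[!pres$flagged] >= 10))
  expect_true(all(pres$Z_summary >= 1.96))
  expect_true(all(pres$Z_density >= 10))
})

test_that("scrambled or random modules show no preservation", {
  fx <- smallCohort()
  rep_se <- simulateReplication(fx$truth, scramble_modules = "M2",
                                seed = 52L)
  test_x <- assay(rep_se, "log2")[, !colData(rep_se)$is_gis]
  labp <- plantedLabels(fx$truth, rownames(fx$x))
  pres <- modulePreservation(fx$x, labp, test_x, n_perm = 100L, seed = 2L)
  # the destroyed module is called not preserved; it can score below the
  # mixed-set null, so the assertion is one-sided
  expect_lt(pres$Z_summary[pres$module == "M2"], 1.96)
  expect_equal(pres$category[pres$module == "M2"], "not")
  expect_true(all(pres$Z_summary[pres$module != "M2"] >= 1.96))
  expect_true(all(pres$Z_density[pres$module != "M2" & !pres$flagged] >= 10))
  # size-matched random "modules" against an honest test cohort
  set.seed(53)
  rand <- setNames(sample(rep(c(0:3), length.out = nrow(fx$x))),
                   rownames(fx$x))
  pres_r <- modulePreservation(fx$x, rand, test_x, n_perm = 100L, seed = 3L)
  expect_lt(mean(abs(pres_r$Z_summary)), 2)
})

test_that("the permutation null is seed-reproducible", {
  fx <- smallCohort()
  rep_se <- simulateReplication(fx$truth, seed = 54L)
  test_x <- assay(rep_se, "log2")[, !colData(rep_se)$is_gis]
  labp <- plantedLabels(fx$truth, rownames(fx$x))
  a <- modulePreservation(fx$x, labp, test_x, n_perm = 60L, seed = 9L)
  b <- modulePreservation(fx$x, labp, test_x, n_perm = 60L, seed = 9L)
  expect_equal(a$Z_summary, b$Z_summary, tolerance = 1e-12)
  expect_warning(
    modulePreservation(fx$x, labp, test_x, n_perm = 20L, seed = 1L),
    "permutations")
})

test_that("synthetic eigenproteins replicate planted module behaviour", {
  fx <- smallCohort()
  net <- smallNetwork()
  rep_se <- simulateReplication(fx$truth, seed = 55L)
  cdr <- as.data.frame(colData(rep_se))
  test_x <- assay(rep_se, "log2")[, !cdr$is_gis]
  test_groups <- cdr$diagnosis[!cdr$is_gis]
  km <- attr(kmeTable(net), "kme")
  syn <- syntheticEigenproteins(moduleLabels(net), km, test_x, test_groups)
  E <- attr(syn, "eigenproteins")
  truth_rep <- metadata(rep_se)$truth
  # each synthetic eigenprotein tracks the replication cohort's latent
  for (i in seq_len(nrow(syn))) {
    if (syn$skipped[i]) next
    cc <- max(abs(cor(E[syn$module[i], ],
                      t(truth_rep@moduleScores[, colnames(E)]),
                      use = "pairwise.complete.obs")))
    expect_gte(cc, 0.85)
  }
  # modules with planted DLB shifts are detected with the planted direction
  m1 <- syn[syn$module == paste0("M", 1L), ]
  expect_lt(m1$p_anova, 0.05)
  expect_equal(m1$dir_DLB, 1L)
  m3 <- syn[syn$module == paste0("M", 3L), ]
  expect_equal(m3$dir_DLB, -1L)
})

test_that("pct = 1 on the reference cohort reproduces module eigenproteins", {
  fx <- smallCohort()
  net <- smallNetwork()
  km <- attr(kmeTable(net), "kme")
  syn <- syntheticEigenproteins(moduleLabels(net), km, fx$x,
                                fx$samples$diagnosis, pct = 1)
  E_syn <- attr(syn, "eigenproteins")
  E_ref <- eigenproteins(net)
  for (m in rownames(E_ref)) {
    expect_gte(abs(cor(E_syn[m, ], E_ref[m, ],
                       use = "pairwise.complete.obs")), 0.99)
  }
})

test_that("opposite-signed test-cohort effects flip the direction call", {
  fx <- smallCohort()
  flipped <- -fx$truth@groupEffects
  rep_se <- simulateReplication(fx$truth, group_effects = flipped,
                                seed = 56L)
  cdr <- as.data.frame(colData(rep_se))
  test_x <- assay(rep_se, "log2")[, !cdr$is_gis]
  labp <- plantedLabels(fx$truth, names(fx$truth@membership))
  el <- moduleEigenproteins(fx$x, labp[rownames(fx$x)])
  km <- moduleKME(fx$x, el$E)$kme
  syn <- syntheticEigenproteins(labp[rownames(fx$x)], km, test_x,
                                cdr$diagnosis[!cdr$is_gis])
  expect_equal(syn$dir_DLB[syn$module == "M1"], -1L)
  expect_lt(syn$p_anova[syn$module == "M1"], 0.05)
})

test_that("module overlap grids detect identity, splits and independence", {
  fx <- smallCohort()
  labp <- plantedLabels(fx$truth, names(fx$truth@membership))
  ov <- moduleOverlap(labp, labp)
  expect_true(all(diag(ov$p) <= apply(ov$p, 1, min)))
  expect_true(all(diag(ov$stars) == "***"))
  # split construction: one module divided across two labels in B
  labB <- labp
  ids1 <- names(labp)[labp == 1L]
  labB[ids1[seq_len(30)]] <- 6L
  ov2 <- moduleOverlap(labp, labB)
  expect_lt(ov2$q["A.M1", "B.M1"], 0.01)
  expect_lt(ov2$q["A.M1", "B.M6"], 0.01)
  # independent random partitions: p roughly uniform
  set.seed(57)
  labR <- setNames(sample(rep(1:5, length.out = length(labp))), names(labp))
  ovr <- moduleOverlap(labp, labR)
  expect_gt(suppressWarnings(ks.test(as.numeric(ovr$p), "punif"))$p.value,
            0.01)
})
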