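test_that("pair building filters by quantification and missingness", {
  co <- small_cohort(seed = 50, missing_rate = 0)
  # toy overlay: 10 relations, 2 with a kinase that has >= 6 missing values
  ks <- co$ks_table[1:10, ]
  kinA <- unique(ks$kinase)[1]
  kinB <- unique(ks$kinase)[2]
  global <- co$global
  global[kinA, 1:6] <- NA   # 6 missing -> dropped ("fewer than 6")
  global[kinB, 1:5] <- NA   # 5 missing -> retained
  paired <- build_pairs(ks, global, co$phospho, max_missing = 6)
  miss <- rowSums(is.na(global[unique(ks$kinase), , drop = FALSE]))
  expected <- sum(miss[ks$kinase] < 6)  # brute-force filter
  expect_equal(nrow(paired$pairs), expected)
  expect_false(kinA %in% paired$pairs$kinase)
  expect_true(kinB %in% paired$pairs$kinase)
  expect_equal(unname(paired$stats["relations"]), 10)
})

test_that("non-phosphorylation relations and unquantified features are excluded", {
  co <- small_cohort(seed = 51)
  ks <- co$ks_table
  ks$modification[1:5] <- "acetylation"
  ks2 <- rbind(ks, data.frame(kinase = "GHOST", substrate = "NOPE",
                              residue = "S", position = 1,
                              modification = "phosphorylation"))
  paired <- build_pairs(ks2, co$global, co$phospho)
  expect_equal(unname(paired$stats["phosphorylation"]),
               nrow(ks2) - 5)
  expect_false("GHOST" %in% paired$pairs$kinase)
  empty <- build_pairs(ks[0, ], co$global, co$phospho)
  expect_equal(nrow(empty$pairs), 0L)
})

test_that("Z scores are computed per feature and planted pairs rank on top", {
  co <- small_cohort(seed = 52, n_samples = 30)
  paired <- build_pairs(co$ks_table, co$global, co$phospho)
  zp <- compute_z(paired, co$groups[colnames(co$global)], co$purity)
  expect_true(all(sign(zp$Zk) == sign(zp$lfc_k) | zp$lfc_k == 0))
  expect_true(all(sign(zp$Zs) == sign(zp$lfc_s) | zp$lfc_s == 0))
  planted <- zp$pair %in% co$truth$planted_pairs
  expect_gt(mean(zp$Zk[planted] > stats::quantile(zp$Zk[!planted], 0.9)), 0.9)
  expect_gt(mean(zp$Zs[planted] > stats::quantile(zp$Zs[!planted], 0.9)), 0.9)
  # duplicated relation rows yield identical pair statistics (per-feature)
  paired2 <- build_pairs(rbind(co$ks_table, co$ks_table[1, ]), co$global,
                         co$phospho)
  zp2 <- compute_z(paired2, co$groups[colnames(co$global)], co$purity)
  expect_equal(zp2[match(zp$pair, zp2$pair), -1], zp[, -1],
               ignore_attr = TRUE)
})

test_that("permutation null is seeded, pooled and roughly centered", {
  co <- small_cohort(seed = 53, n_kinases = 20, substrates_per_kinase = 3)
  paired <- build_pairs(co$ks_table, co$global, co$phospho)
  g <- co$groups[colnames(co$global)]
  n1 <- permutation_null(paired, g, co$purity, n_perm = 12, seed = 5)
  n2 <- permutation_null(paired, g, co$purity, n_perm = 12, seed = 5)
  expect_identical(n1, n2)
  n3 <- permutation_null(paired, g, co$purity, n_perm = 12, seed = 6)
  expect_false(identical(n1, n3))
  expect_equal(nrow(n1), 12 * nrow(paired$pairs))  # pooled bookkeeping
  expect_lt(abs(mean(n1[, "Zk"])), 0.15)
  expect_lt(abs(mean(n1[, "Zs"])), 0.15)
  # symmetric tails
  expect_lt(abs(stats::quantile(n1[, "Zs"], 0.95) +
                stats::quantile(n1[, "Zs"], 0.05)), 0.4)
})

test_that("mixture identities hold: p0 + p1 = 1, p1(Z) + fdr(Z) = 1, fdr(0) = 1", {
  co <- small_cohort(seed = 54, n_samples = 30)
  fit <- ksa2d(co$ks_table, co$global, co$phospho,
               co$groups[colnames(co$global)], co$purity,
               n_perm = 30, seed = 4)
  expect_equal(fit$p0 + fit$p1, 1, tolerance = 1e-12)
  expect_equal(fit$pairs$p1 + fit$pairs$fdr, rep(1, nrow(fit$pairs)),
               tolerance = 1e-12)
  expect_true(all(fit$pairs$fdr >= 0 & fit$pairs$fdr <= 1))
  # when p0 was not clipped, the local fdr at the origin is exactly 1
  if (fit$p0_raw <= 1) {
    at0 <- predict(fit, data.frame(Zk = 0, Zs = 0))
    expect_equal(at0$fdr, 1, tolerance = 1e-10)
    expect_equal(at0$p1, 0, tolerance = 1e-10)
  }
})

test_that("a pure-null cohort yields p0 near 1 and almost no calls", {
  co <- small_cohort(seed = 55, n_samples = 30, n_kinases = 60,
                     substrates_per_kinase = 5, planted_fraction = 0)
  fit <- ksa2d(co$ks_table, co$global, co$phospho,
               co$groups[colnames(co$global)], co$purity,
               n_perm = 40, seed = 9)
  expect_gt(fit$p0, 0.85)
  expect_lte(nrow(fit$significant), ceiling(0.02 * nrow(fit$pairs)))
})

test_that("planted co-regulation is detected with high posterior probability", {
  co <- small_cohort(seed = 56, n_samples = 30, n_kinases = 40,
                     substrates_per_kinase = 5)
  fit <- ksa2d(co$ks_table, co$global, co$phospho,
               co$groups[colnames(co$global)], co$purity,
               n_perm = 40, seed = 2)
  planted <- fit$pairs$pair %in% co$truth$planted_pairs
  expect_gt(mean(fit$pairs$p1[planted]), 0.8)
  expect_lt(mean(fit$pairs$p1[!planted]), 0.35)
  called <- fit$significant$pair
  eligible <- intersect(co$truth$planted_pairs, fit$pairs$pair)
  expect_gt(length(intersect(called, eligible)) / length(eligible), 0.6)
})

test_that("swapping group labels negates Z and leaves p0 nearly unchanged", {
  co <- small_cohort(seed = 57, n_samples = 26)
  paired <- build_pairs(co$ks_table, co$global, co$phospho)
  g <- co$groups[colnames(co$global)]
  g_swap <- factor(as.character(g), levels = c("high", "low"))
  zp <- compute_z(paired, g, co$purity)
  zs <- compute_z(paired, g_swap, co$purity)
  expect_equal(zs$Zk, -zp$Zk, tolerance = 1e-10)
  expect_equal(zs$Zs, -zp$Zs, tolerance = 1e-10)
  n1 <- permutation_null(paired, g, co$purity, n_perm = 30, seed = 3)
  n2 <- permutation_null(paired, g_swap, co$purity, n_perm = 30, seed = 3)
  f1 <- fit_mixture(zp, n1)
  f2 <- fit_mixture(zs, n2)
  expect_lt(abs(f1$p0 - f2$p0), 0.1)
})

test_that("significance filtering applies all three thresholds and sorts by fdr", {
  co <- small_cohort(seed = 58, n_samples = 30)
  fit <- ksa2d(co$ks_table, co$global, co$phospho,
               co$groups[colnames(co$global)], co$purity,
               n_perm = 25, seed = 8)
  sig <- fit$significant
  expect_true(all(sig$fdr < 0.05))
  expect_true(all(abs(sig$lfc_k) > 0.05))
  expect_true(all(abs(sig$lfc_s) > 0.5))
  expect_true(!is.unsorted(sig$fdr))
  all_pairs <- significant_pairs(fit, fdr_max = 1.0000001, lfc_k_min = 0,
                                 lfc_s_min = 0)
  expect_equal(nrow(all_pairs), nrow(fit$pairs))
  kc <- attr(sig, "kinase_counts")
  expect_equal(sum(kc), nrow(sig))
})

test_that("degenerate Z sets are rejected", {
  zp <- data.frame(pair = c("a", "b", "c"), Zk = c(1, 1, 1), Zs = c(1, 2, 3),
                   lfc_k = 0.1, lfc_s = 0.1)
  nullz <- cbind(Zk = stats::rnorm(100), Zs = stats::rnorm(100))
  expect_error(fit_mixture(zp, nullz), class = "gicoreg_estimation_error")
})
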