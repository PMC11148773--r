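make_design <- function(n = 20, seed = 1) {
  set.seed(seed)
  g <- factor(rep(c("low", "high"), each = n / 2), levels = c("low", "high"))
  design_spec(group = g, purity = stats::runif(n, 0.3, 0.9))
}

test_that("per-feature OLS matches a brute-force normal-equations solve", {
  d <- make_design(24, 3)
  set.seed(4)
  m <- matrix(stats::rnorm(30 * 24), 30,
              dimnames = list(sprintf("f%02d", 1:30), NULL))
  m[sample(length(m), 40)] <- NA
  fit <- fit_linear_model(m, d)
  X <- d$X
  for (i in sample(nrow(fit), 10)) {
    y <- m[fit$feature[i], ]
    cc <- !is.na(y)
    beta <- solve(crossprod(X[cc, ]), crossprod(X[cc, ], y[cc]))
    expect_equal(fit$coefficient[i], as.numeric(beta[2, 1]), tolerance = 1e-10)
    res <- y[cc] - X[cc, ] %*% beta
    expect_equal(fit$sigma2[i], sum(res^2) / (sum(cc) - 3), tolerance = 1e-10)
    expect_equal(fit$stdev_unscaled[i],
                 sqrt(solve(crossprod(X[cc, ]))[2, 2]), tolerance = 1e-10)
  }
})

test_that("noiseless group shift is recovered exactly; label swap flips sign", {
  g <- factor(rep(c("low", "high"), each = 6), levels = c("low", "high"))
  pur <- rep(c(0.4, 0.6), 6)
  d <- design_spec(group = g, purity = pur)
  y <- matrix(2.5 * (g == "high"), 1, dimnames = list("f", NULL))
  fit <- fit_linear_model(y + 0, d)
  expect_equal(fit$coefficient, 2.5, tolerance = 1e-12)
  d_swap <- design_spec(group = factor(g, levels = c("high", "low")),
                        purity = pur)
  fit_swap <- fit_linear_model(y + 0, d_swap)
  expect_equal(fit_swap$coefficient, -2.5, tolerance = 1e-12)
})

test_that("purity adjustment removes a planted purity confounder", {
  set.seed(9)
  n <- 60
  g <- factor(rep(c("low", "high"), each = n / 2), levels = c("low", "high"))
  purity <- ifelse(g == "high", stats::runif(n, 0.6, 0.9),
                   stats::runif(n, 0.3, 0.6))
  m <- matrix(rep(2 * purity, each = 50), 50, byrow = FALSE) +
    matrix(stats::rnorm(50 * n, 0, 0.3), 50)
  rownames(m) <- sprintf("f%02d", 1:50)
  adj <- fit_linear_model(m, design_spec(group = g, purity = purity))
  # naive fit: purity ignored (constant regressor replaced by intercept-only
  # group model via tumor-vs-normal-free design)
  naive <- fit_linear_model(m, design_spec(
    group = g, purity = rep(0.5, n))) # purity constant -> rank-deficient
  expect_equal(nrow(naive), 0L)  # dropped: cannot separate
  t_adj <- adj$coefficient / (sqrt(adj$sigma2) * adj$stdev_unscaled)
  expect_lt(mean(abs(t_adj) > 2), 0.15)
  # without adjustment the confounder masquerades as a group effect
  d0 <- mean(m[1, g == "high"]) - mean(m[1, g == "low"])
  expect_gt(d0, 0.3)
})

test_that("tumor-vs-normal mode regresses on purity alone", {
  set.seed(10)
  n <- 30
  purity <- c(rep(0, 10), stats::runif(20, 0.4, 0.9))
  m <- matrix(1.8 * purity + stats::rnorm(n, 0, 0.01), 1,
              dimnames = list("f", NULL))
  d <- design_spec(purity = purity, mode = "tumor-vs-normal")
  fit <- fit_linear_model(m, d)
  expect_equal(fit$coefficient, 1.8, tolerance = 0.05)
})

test_that("moderation limits: d0 = 0 is the ordinary t, d0 = Inf pools", {
  d <- make_design(20, 5)
  set.seed(6)
  m <- matrix(stats::rnorm(200 * 20), 200,
              dimnames = list(sprintf("f%03d", 1:200), NULL))
  fit <- fit_linear_model(m, d)
  m0 <- moderate(fit, df_prior = 0)
  t_ord <- fit$coefficient / (sqrt(fit$sigma2) * fit$stdev_unscaled)
  expect_equal(m0$t_mod, t_ord, tolerance = 1e-10)
  expect_equal(m0$p_mod, 2 * stats::pt(-abs(t_ord), fit$df_residual),
               tolerance = 1e-12)
  mInf <- moderate(fit, df_prior = Inf, s2_prior = 0.9)
  expect_equal(mInf$t_mod, fit$coefficient / (sqrt(0.9) * fit$stdev_unscaled),
               tolerance = 1e-12)
})

test_that("moderation agrees with the limma empirical-Bayes machinery", {
  d <- make_design(16, 7)
  set.seed(8)
  sigma2 <- 0.05 * 4 / stats::rchisq(300, 4)  # scaled inverse chi-square
  m <- matrix(stats::rnorm(300 * 16, 0, rep(sqrt(sigma2), 16)), 300,
              dimnames = list(sprintf("f%03d", 1:300), NULL))
  fit <- fit_linear_model(m, d)
  mod <- moderate(fit)
  sq <- limma::squeezeVar(fit$sigma2, fit$df_residual)
  expect_equal(attr(mod, "df_prior"), sq$df.prior, tolerance = 1e-6)
  expect_equal(attr(mod, "s2_prior"), sq$var.prior, tolerance = 1e-6)
  s2_post <- (sq$df.prior * sq$var.prior + fit$df_residual * fit$sigma2) /
    (sq$df.prior + fit$df_residual)
  expect_equal(mod$t_mod,
               fit$coefficient / (sqrt(s2_post) * fit$stdev_unscaled),
               tolerance = 1e-8)
})

test_that("moderation recovers known variance hyperparameters", {
  set.seed(15)
  nfeat <- 5000; df <- 10
  sigma2 <- 0.05 * 4 / stats::rchisq(nfeat, 4)
  s2 <- sigma2 * stats::rchisq(nfeat, df) / df
  fake <- structure(data.frame(
    feature = sprintf("f%05d", seq_len(nfeat)), coefficient = 0,
    sigma2 = s2, df_residual = df, stdev_unscaled = 1, n_obs = df + 3),
    class = c("feature_fit", "data.frame"))
  mod <- moderate(fake)
  expect_lt(abs(attr(mod, "df_prior") - 4) / 4, 0.25)
  expect_lt(abs(attr(mod, "s2_prior") - 0.05) / 0.05, 0.25)
})

test_that("moderated p-values are uniform under a pure null", {
  d <- make_design(20, 11)
  set.seed(12)
  m <- matrix(stats::rnorm(5000 * 20, 0, 0.5), 5000,
              dimnames = list(sprintf("f%04d", 1:5000), NULL))
  mod <- moderate(fit_linear_model(m, d))
  expect_gt(stats::ks.test(mod$p_mod, "punif")$p.value, 0.01)
})

test_that("identical variances trigger the complete-pooling branch", {
  fake <- structure(data.frame(
    feature = sprintf("f%02d", 1:50), coefficient = stats::rnorm(50),
    sigma2 = 0.25, df_residual = 10, stdev_unscaled = 0.5, n_obs = 13),
    class = c("feature_fit", "data.frame"))
  mod <- moderate(fake)
  expect_true(is.infinite(attr(mod, "df_prior")))
  expect_equal(attr(mod, "s2_prior"), 0.25, tolerance = 1e-12)
})

test_that("BH adjustment matches the hand-evaluated step-up rule", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # worked example: q_i = min_{j >= i} m p_(j) / j
  p <- c(0.005, 0.011, 0.02, 0.04, 0.9)
  expect_equal(adjust_bh(p), c(0.025, 0.0275, 0.0333333333333333, 0.05, 0.9),
               tolerance = 1e-10)
  set.seed(3)
  p2 <- stats::runif(50)
  ord <- sample(50)
  expect_equal(adjust_bh(p2)[ord], adjust_bh(p2[ord]))
  expect_error(adjust_bh(c(0.5, 0)), class = "gicoreg_invalid_input")
  expect_error(adjust_bh(c(0.5, 1.2)), class = "gicoreg_invalid_input")
})

test_that("PTM normalization residualizes against the parent protein", {
  co <- small_cohort(seed = 20, missing_rate = 0.1)
  site_map <- stats::setNames(sub("_[STY][0-9]+$", "", rownames(co$phospho)),
                              rownames(co$phospho))
  # identical matrices -> zero residuals
  fake_global <- co$phospho
  rownames(fake_global) <- unname(site_map)
  res0 <- normalize_ptm(co$phospho, fake_global, site_map)
  expect_lt(max(abs(res0), na.rm = TRUE), 1e-10)
  # orthogonality: residuals uncorrelated with the predictor
  set.seed(1)
  glob <- matrix(stats::rnorm(5 * 30), 5, dimnames = list(sprintf("P%d", 1:5),
                                                          sprintf("S%03d", 1:30)))
  ptm <- 0.7 * glob[rep(1:5, 2), ] + matrix(stats::rnorm(10 * 30), 10)
  rownames(ptm) <- sprintf("P%d_S%d", rep(1:5, 2), 1:10)
  map2 <- stats::setNames(sprintf("P%d", rep(1:5, 2)), rownames(ptm))
  res <- normalize_ptm(ptm, glob, map2)
  for (i in 1:10) {
    r <- stats::cor(res[i, ], glob[map2[[i]], ])
    expect_lt(abs(r), 1e-10)
  }
  # invariance to shifting the predictor by a constant
  res_shift <- normalize_ptm(ptm, glob + 5, map2)
  expect_equal(res, res_shift, tolerance = 1e-10)
})

test_that("PTM sites without a parent protein pass through flagged", {
  set.seed(2)
  glob <- matrix(stats::rnorm(2 * 10), 2, dimnames = list(c("A", "B"),
                                                          sprintf("S%02d", 1:10)))
  ptm <- matrix(stats::rnorm(3 * 10), 3,
                dimnames = list(c("A_S1", "B_S2", "C_S3"), colnames(glob)))
  map <- c(A_S1 = "A", B_S2 = "B", C_S3 = "C")
  res <- normalize_ptm(ptm, glob, map)
  expect_identical(attr(res, "flagged"), "C_S3")
  expect_equal(res["C_S3", ], ptm["C_S3", ])
  # independence: slope ~ 0 so residuals ~ centered values
  ptm_i <- matrix(stats::rnorm(1 * 10), 1, dimnames = list("A_S9", colnames(glob)))
  r <- normalize_ptm(ptm_i, glob, c(A_S9 = "A"))
  expect_equal(unname(drop(r)), unname(drop(ptm_i) - mean(ptm_i)),
               tolerance = 0.8, ignore_attr = TRUE)
})

test_that("metagene scores equal the standardized-submatrix column means", {
  set.seed(30)
  m <- matrix(stats::rnorm(20 * 12), 20,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:12)))
  gs <- sprintf("g%02d", c(2, 5, 9, 11, 17))
  sc <- metagene_score(m, gs)
  z <- t(scale(t(m[gs, ])))
  expect_equal(sc, colMeans(z), tolerance = 1e-12)
  # single gene: its own z-scores
  expect_equal(metagene_score(m, "g03"), drop(scale(m["g03", ]))[],
               tolerance = 1e-12, ignore_attr = TRUE)
  # column permutation equivariance
  perm <- sample(12)
  expect_equal(metagene_score(m[, perm], gs), sc[perm], tolerance = 1e-12)
  expect_error(metagene_score(m, c("zz1", "zz2")), class = "gicoreg_empty_input")
})
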