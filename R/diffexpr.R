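#' Design specification for per-feature linear models
#'
#' Two modes of tumor-purity adjustment are supported. In `between-groups`
#' mode the per-feature model is `value ~ group + purity` and the group
#' coefficient is the log2 fold change between the two groups. In
#' `tumor-vs-normal` mode purity is the only regressor (`value ~ purity`),
#' because normal tissue has purity zero the purity coefficient captures the
#' tumor effect.
#'
#' @param group per-sample two-level factor (ignored in tumor-vs-normal mode,
#'   where it may be NULL).
#' @param purity per-sample tumor purity in \[0, 1\].
#' @param mode `"between-groups"` or `"tumor-vs-normal"`.
#' @return a `design_spec` list with the model matrix and the name of the
#'   target coefficient.
#' @export
design_spec <- function(group = NULL, purity, mode = c("between-groups", "tumor-vs-normal")) {
  mode <- match.arg(mode)
  check_number(purity, "purity", lower = 0, upper = 1, len = NULL)
  n <- length(purity)
  if (mode == "between-groups") {
    group <- as.factor(group)
    if (nlevels(droplevels(group)) != 2L) {
      stop_invalid("group must have exactly two levels")
    }
    if (length(group) != n) stop_invalid("group and purity lengths differ")
    X <- stats::model.matrix(~ group + purity)
    target <- colnames(X)[2L]  # the group contrast
  } else {
    X <- stats::model.matrix(~ purity)
    target <- "purity"
  }
  structure(list(X = X, target = target, mode = mode, group = group,
                 purity = purity), class = "design_spec")
}

#' Per-feature ordinary least squares on observed samples
#'
#' Fits the design of [design_spec()] to every feature (row) of the matrix by
#' OLS on that feature's observed samples (complete-case per feature).
#' Features with fewer than 3 observations per model term, or with a group
#' level unrepresented among observed samples, are dropped and reported.
#' Features sharing a missingness pattern share one QR decomposition, so the
#' fit is fast even with thousands of features.
#'
#' @param matrix numeric matrix, features x samples; NA = missing.
#' @param design a [design_spec()]; its rows must align with `ncol(matrix)`.
#' @param min_obs_per_term minimum observations required per model column
#'   (default 3).
#' @return object of class `feature_fit`: data.frame with per-feature
#'   `coefficient` (the target-coefficient estimate), `sigma2` (residual
#'   variance), `df_residual`, `stdev_unscaled`, `n_obs`; dropped features in
#'   `attr(, "dropped")`.
#' @export
fit_linear_model <- function(matrix, design, min_obs_per_term = 3L) {
  stopifnot(inherits(design, "design_spec"), is.matrix(matrix))
  X <- design$X
  n <- nrow(X)
  if (ncol(matrix) != n) stop_invalid("matrix columns and design rows differ")
  p <- ncol(X)
  ti <- match(design$target, colnames(X))
  obs <- !is.na(matrix)
  pattern <- apply(obs, 1L, function(z) paste(which(z), collapse = ","))
  feats <- rownames(matrix)
  if (is.null(feats)) feats <- as.character(seq_len(nrow(matrix)))

  nf <- nrow(matrix)
  coefficient <- rep(NA_real_, nf)
  sigma2 <- rep(NA_real_, nf)
  df_residual <- rep(NA_real_, nf)
  stdev_unscaled <- rep(NA_real_, nf)
  n_obs_v <- rep(NA_integer_, nf)
  grp_col <- if (design$mode == "between-groups") as.integer(design$group) else NULL

  pat_groups <- split(seq_len(nf), pattern)
  for (pat in names(pat_groups)) {
    idx <- pat_groups[[pat]]
    cols <- as.integer(strsplit(pat, ",", fixed = TRUE)[[1L]])
    n_obs <- length(cols)
    valid <- n_obs >= min_obs_per_term * p && n_obs > p
    if (valid && !is.null(grp_col)) {
      valid <- length(unique(grp_col[cols])) == 2L
    }
    if (!valid) next
    Xp <- X[cols, , drop = FALSE]
    qrX <- qr(Xp)
    if (qrX$rank < p) next
    Yp <- t(matrix[idx, cols, drop = FALSE])      # n_obs x f
    beta <- qr.coef(qrX, Yp)                      # p x f
    rss <- colSums((Yp - Xp %*% beta)^2)
    xtx_inv <- chol2inv(qr.R(qrX))
    coefficient[idx] <- beta[ti, ]
    sigma2[idx] <- rss / (n_obs - p)
    df_residual[idx] <- n_obs - p
    stdev_unscaled[idx] <- sqrt(xtx_inv[ti, ti])
    n_obs_v[idx] <- n_obs
  }
  keep <- !is.na(coefficient)
  dropped <- feats[!keep]
  out <- data.frame(feature = feats[keep], coefficient = coefficient[keep],
                    sigma2 = sigma2[keep], df_residual = df_residual[keep],
                    stdev_unscaled = stdev_unscaled[keep],
                    n_obs = n_obs_v[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, dropped = dropped, target = design$target,
            class = c("feature_fit", "data.frame"))
}

# Newton inversion of the trigamma function (solve trigamma(y) = x, x > 0).
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderation of per-feature variances
#'
#' Shrinks each feature's residual variance toward a common prior estimated
#' across features, assuming residual variances follow a scaled inverse
#' chi-square distribution with prior degrees of freedom `d0` and prior
#' variance `s0^2`. The hyperparameters are estimated by method of moments on
#' the log residual variances (digamma/trigamma matching). The posterior
#' variance is `(d0*s0^2 + d*s^2) / (d0 + d)`; the moderated t-statistic is
#' the coefficient over its posterior standard error, referred to a
#' t-distribution with `d + d0` degrees of freedom. `df_prior = 0` recovers
#' the ordinary t-test; `df_prior = Inf` pools all features to one variance.
#'
#' @param fit a [fit_linear_model()] result.
#' @param df_prior optional fixed prior df, overriding estimation.
#' @param s2_prior optional fixed prior variance, overriding estimation.
#' @return object of class `moderated_result`: data.frame with `feature`,
#'   `log2fc`, `t_mod`, `p_mod`, `q_mod`, `df_residual`, `df_total`; scalars
#'   in `attr(, "df_prior")` and `attr(, "s2_prior")`.
#' @export
moderate <- function(fit, df_prior = NULL, s2_prior = NULL) {
  stopifnot(inherits(fit, "feature_fit"))
  s2 <- fit$sigma2
  d <- fit$df_residual
  if (length(s2) < 2L) stop_invalid("moderation needs at least 2 fitted features")
  pos <- s2 > 0
  if (sum(pos) < 2L) stop_invalid("not enough positive residual variances")

  if (is.null(df_prior) || is.null(s2_prior)) {
    z <- log(s2[pos])
    e <- z - digamma(d[pos] / 2) + log(d[pos] / 2)
    emean <- mean(e)
    nn <- length(e)
    evar <- sum((e - emean)^2) / (nn - 1L) - mean(trigamma(d[pos] / 2))
    if (is.finite(evar) && evar > 0) {
      d0_hat <- 2 * trigamma_inverse(evar)
      s20_hat <- exp(emean + digamma(d0_hat / 2) - log(d0_hat / 2))
    } else {
      # variances indistinguishable from a common value: complete pooling
      d0_hat <- Inf
      s20_hat <- mean(s2[pos])
    }
    if (is.null(df_prior)) df_prior <- d0_hat
    if (is.null(s2_prior)) s2_prior <- s20_hat
  }
  check_number(df_prior, "df_prior", lower = 0)
  check_number(s2_prior, "s2_prior", lower = 0)

  if (is.infinite(df_prior)) {
    s2_post <- rep(s2_prior, length(s2))
  } else if (df_prior == 0) {
    s2_post <- s2
  } else {
    s2_post <- (df_prior * s2_prior + d * s2) / (df_prior + d)
  }
  df_total <- d + df_prior
  t_mod <- fit$coefficient / (sqrt(s2_post) * fit$stdev_unscaled)
  p_mod <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- data.frame(feature = fit$feature, log2fc = fit$coefficient,
                    t_mod = t_mod, p_mod = p_mod,
                    q_mod = adjust_bh(p_mod),
                    df_residual = d, df_total = df_total,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, df_prior = df_prior, s2_prior = s2_prior,
            dropped = attr(fit, "dropped"),
            class = c("moderated_result", "data.frame"))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validating wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param p p-values in (0, 1\].
#' @return q-values, same order as `p`.
#' @export
adjust_bh <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p <= 0) || any(p > 1)) {
    stop_invalid("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Normalize PTM intensities against parent protein abundance
#'
#' For every PTM site, fits a simple linear regression of the site's log2
#' ratios on the parent protein's global log2 ratios across samples and
#' returns the residuals as the normalized PTM intensity: the component of
#' PTM variation not explained by protein abundance. Samples missing either
#' value stay missing. Sites whose parent protein is absent from the global
#' matrix, or with fewer than `min_pairs` complete sample pairs, are passed
#' through unnormalized and listed in `attr(, "flagged")`.
#'
#' @param ptm numeric matrix, sites x samples (log2 ratios).
#' @param global numeric matrix, proteins x samples, same sample columns.
#' @param site_to_protein named character vector mapping site ids (rownames
#'   of `ptm`) to protein ids (rownames of `global`).
#' @param min_pairs minimum complete pairs to fit the regression (default 3).
#' @return matrix of residuals, same shape as `ptm`.
#' @export
normalize_ptm <- function(ptm, global, site_to_protein, min_pairs = 3L) {
  stopifnot(is.matrix(ptm), is.matrix(global))
  common <- intersect(colnames(ptm), colnames(global))
  if (length(common) < min_pairs) stop_invalid("matrices share too few samples")
  out <- ptm
  flagged <- character(0)
  for (site in rownames(ptm)) {
    prot <- site_to_protein[[site]]
    if (is.null(prot) || is.na(prot) || !(prot %in% rownames(global))) {
      flagged <- c(flagged, site)
      next
    }
    y <- ptm[site, common]
    x <- global[prot, common]
    cc <- !is.na(x) & !is.na(y)
    if (sum(cc) < min_pairs) {
      flagged <- c(flagged, site)
      next
    }
    b <- stats::cov(x[cc], y[cc]) / stats::var(x[cc])
    a <- mean(y[cc]) - b * mean(x[cc])
    r <- rep(NA_real_, length(common))
    r[cc] <- y[cc] - (a + b * x[cc])
    out[site, common] <- r
    out[site, setdiff(colnames(ptm), common)] <- NA_real_
  }
  structure(out, flagged = flagged)
}

#' Metagene score of a gene set
#'
#' Standardizes each gene of the set across samples (mean 0, SD 1, computed
#' over observed values) and averages the z-scores per sample.
#'
#' @param matrix numeric matrix, features x samples.
#' @param gene_set character vector of feature ids.
#' @return named per-sample score vector.
#' @export
metagene_score <- function(matrix, gene_set) {
  genes <- intersect(gene_set, rownames(matrix))
  if (length(genes) == 0L) {
    stop_invalid("no gene of the set is present in the matrix",
                 class = "gicoreg_empty_input")
  }
  sub <- matrix[genes, , drop = FALSE]
  mu <- rowMeans(sub, na.rm = TRUE)
  sd <- apply(sub, 1L, stats::sd, na.rm = TRUE)
  z <- (sub - mu) / sd
  colMeans(z, na.rm = TRUE)
}
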