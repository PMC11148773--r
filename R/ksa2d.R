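#' Join a kinase-substrate relation table to quantified omics data
#'
#' Keeps phosphorylation relations whose kinase protein is quantified in the
#' global proteome and whose substrate site (id `PROT_<residue><position>`)
#' is quantified in the phosphoproteome, then applies the missingness filter:
#' a feature (kinase protein or substrate site) is retained only if it is
#' missing in fewer than `max_missing` samples. Join and filter statistics
#' are recorded for auditing.
#'
#' @param ks_table data.frame with columns `kinase`, `substrate`, `residue`,
#'   `position`, and optionally `modification` (rows not marked
#'   `phosphorylation` are discarded).
#' @param global numeric matrix, proteins x samples.
#' @param phospho numeric matrix, phosphosites x samples; rownames must
#'   encode protein, residue and position as `PROT_S123`.
#' @param max_missing retain features with missing count strictly below this
#'   (default 6).
#' @return object of class `paired_data`: list with `pairs` (data.frame
#'   `pair`, `kinase`, `site`), `global`, `phospho` (subset to used
#'   features), and `stats` (per-filter counts).
#' @export
build_pairs <- function(ks_table, global, phospho, max_missing = 6L) {
  stopifnot(is.data.frame(ks_table), is.matrix(global), is.matrix(phospho))
  check_number(max_missing, "max_missing", lower = 1, integer = TRUE)
  common <- intersect(colnames(global), colnames(phospho))
  if (length(common) < 4L) stop_invalid("matrices share too few samples")
  global <- global[, common, drop = FALSE]
  phospho <- phospho[, common, drop = FALSE]

  n0 <- nrow(ks_table)
  if ("modification" %in% names(ks_table)) {
    ks_table <- ks_table[ks_table$modification == "phosphorylation", , drop = FALSE]
  }
  n_phos <- nrow(ks_table)
  stats_out <- c(relations = n0, phosphorylation = n_phos)
  if (n_phos == 0L) {
    return(structure(list(pairs = data.frame(pair = character(0),
                                             kinase = character(0),
                                             site = character(0),
                                             stringsAsFactors = FALSE),
                          global = global, phospho = phospho,
                          stats = c(stats_out, quantified = 0, retained = 0)),
                     class = "paired_data"))
  }
  site <- paste0(ks_table$substrate, "_", ks_table$residue, ks_table$position)
  quant <- ks_table$kinase %in% rownames(global) & site %in% rownames(phospho)
  ks_table <- ks_table[quant, , drop = FALSE]
  site <- site[quant]
  stats_out <- c(stats_out, quantified = sum(quant))

  miss_g <- rowSums(is.na(global))
  miss_p <- rowSums(is.na(phospho))
  keep <- miss_g[ks_table$kinase] < max_missing & miss_p[site] < max_missing
  ks_table <- ks_table[keep, , drop = FALSE]
  site <- site[keep]
  stats_out <- c(stats_out, retained = sum(keep))
  if (sum(keep) == 0L && stats_out[["quantified"]] > 0L) {
    stop_invalid(sprintf(
      "no kinase-substrate pair survived filtering (relations=%d, phosphorylation=%d, quantified=%d, missingness-retained=0)",
      stats_out[["relations"]], stats_out[["phosphorylation"]],
      stats_out[["quantified"]]), class = "gicoreg_empty_result")
  }
  pairs <- data.frame(pair = paste0(ks_table$kinase, "|", site),
                      kinase = ks_table$kinase, site = site,
                      stringsAsFactors = FALSE)
  pairs <- pairs[!duplicated(pairs$pair), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 global = global[unique(pairs$kinase), , drop = FALSE],
                 phospho = phospho[unique(pairs$site), , drop = FALSE],
                 stats = stats_out),
            class = "paired_data")
}

#' Two-dimensional Z scores for kinase-substrate pairs
#'
#' Regresses kinase protein abundance and substrate-site intensity
#' separately against the sample grouping with tumor purity as a covariate
#' ([fit_linear_model()] + [moderate()]), once per unique feature, and
#' assigns each pair the moderated t-statistics of its kinase (Zk) and
#' substrate site (Zs) together with the log2 fold changes.
#'
#' @param paired a [build_pairs()] result.
#' @param groups per-sample two-level factor, aligned with the matrix
#'   columns.
#' @param purity per-sample tumor purity.
#' @return data.frame with `pair`, `kinase`, `site`, `Zk`, `Zs`, `lfc_k`,
#'   `lfc_s`; pairs whose kinase or site failed the fit are dropped (ids in
#'   `attr(, "dropped_pairs")`).
#' @export
compute_z <- function(paired, groups, purity) {
  stopifnot(inherits(paired, "paired_data"))
  design <- design_spec(group = groups, purity = purity, mode = "between-groups")
  mod_k <- moderate(fit_linear_model(paired$global, design))
  mod_s <- moderate(fit_linear_model(paired$phospho, design))
  ik <- match(paired$pairs$kinase, mod_k$feature)
  is <- match(paired$pairs$site, mod_s$feature)
  ok <- !is.na(ik) & !is.na(is)
  out <- data.frame(pair = paired$pairs$pair[ok],
                    kinase = paired$pairs$kinase[ok],
                    site = paired$pairs$site[ok],
                    Zk = mod_k$t_mod[ik[ok]], Zs = mod_s$t_mod[is[ok]],
                    lfc_k = mod_k$log2fc[ik[ok]], lfc_s = mod_s$log2fc[is[ok]],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, dropped_pairs = paired$pairs$pair[!ok])
}

#' Permutation null for the two-dimensional Z scores
#'
#' Builds the empirical null by repeatedly permuting the group labels over
#' samples — one shared permutation applied to both matrices per iteration,
#' preserving the kinase-substrate dependence structure under the null —
#' and recomputing all pair Z scores. Purity stays attached to its sample
#' and is never permuted. All permuted (Zk, Zs) points are pooled.
#'
#' @param paired a [build_pairs()] result.
#' @param groups,purity as in [compute_z()].
#' @param n_perm number of permutations (default 200).
#' @param seed integer seed.
#' @return numeric matrix with columns `Zk`, `Zs` (pooled across
#'   permutations).
#' @export
permutation_null <- function(paired, groups, purity, n_perm = 200L, seed = 1L) {
  check_number(n_perm, "n_perm", lower = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  set.seed(derive_seed(seed, 17L))
  n <- length(groups)
  acc <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    gp <- groups[sample.int(n)]  # labels shuffled; purity stays put
    z <- compute_z(paired, gp, purity)
    acc[[b]] <- cbind(Zk = z$Zk, Zs = z$Zs)
  }
  do.call(rbind, acc)
}

# Product-Gaussian kernel density estimate evaluated at arbitrary points,
# chunked to bound memory at large null-sample sizes.
kde2d_points <- function(points, data, h, chunk = 64L) {
  m <- nrow(points)
  n <- nrow(data)
  out <- numeric(m)
  norm <- n * 2 * pi * h[1] * h[2]
  for (s in seq(1L, m, by = chunk)) {
    e <- min(s + chunk - 1L, m)
    z1 <- outer(points[s:e, 1L], data[, 1L], "-") / h[1]
    z1 <- z1 * z1
    z2 <- outer(points[s:e, 2L], data[, 2L], "-") / h[2]
    z1 <- z1 + z2 * z2
    out[s:e] <- rowSums(exp(-0.5 * z1)) / norm
  }
  out
}

#' Fit the two-dimensional empirical-Bayes mixture of co-regulation
#'
#' Models the observed pair statistics Z = (Zk, Zs) as a mixture
#' `f(Z) = p0 f0(Z) + p1 f1(Z)` of non-co-regulated pairs (density f0,
#' estimated from the permutation null) and co-regulated pairs. Both
#' densities are product-Gaussian kernel density estimates. The null
#' proportion is read off at the origin, `p0 = f(Z00)/f0(Z00)` with
#' `Z00 = (0, 0)` (clipped into (0, 1\]), the point where the alternative
#' density is assumed negligible. Each pair then receives a local false
#' discovery rate `fdr(Z) = p0 f0(Z)/f(Z)` and posterior co-regulation
#' probability `p1(Z) = 1 - fdr(Z)` (both clipped to \[0, 1\] consistently,
#' so they sum to one exactly).
#'
#' One shared per-dimension bandwidth — Scott's rule with the null sample's
#' robust scale (MAD) at the observed sample size, widened by `adjust` — is
#' used for both f and f0, so kernel-smoothing bias cancels in the density
#' ratio at the origin. Oversmoothing relative to Scott's optimum (default
#' `adjust = 2`) is deliberate: p0 is a ratio of two densities at one point,
#' where shared-kernel bias cancels but estimation variance does not, and
#' the co-regulated component sits far from the origin so its leakage stays
#' negligible.
#'
#' @param zpairs observed pair statistics from [compute_z()].
#' @param null_z pooled null sample from [permutation_null()].
#' @param bandwidth `"scott"` or a numeric length-2 bandwidth (Zk, Zs).
#' @param adjust multiplier on the Scott bandwidth (ignored when `bandwidth`
#'   is numeric).
#' @param eps density floor applied to f before division (default 1e-12).
#' @return object of class `mixture_fit`: list with `p0`, `p0_raw`, `p1`,
#'   `pairs` (zpairs plus `p1`, `fdr` columns), `bandwidth`, `f_origin`,
#'   `f0_origin`, and the samples needed to evaluate the densities at new
#'   points.
#' @export
fit_mixture <- function(zpairs, null_z, bandwidth = "scott", adjust = 2,
                        eps = 1e-12) {
  obs <- cbind(zpairs$Zk, zpairs$Zs)
  if (nrow(obs) < 2L) stop_invalid("too few observed pairs for density estimation")
  null_z <- as.matrix(null_z)
  if (nrow(null_z) < 10L) stop_invalid("null sample too small")
  if (any(apply(obs, 2L, stats::sd) == 0) || any(apply(null_z, 2L, stats::sd) == 0)) {
    stop_invalid("degenerate (zero-variance) Z sample",
                 class = "gicoreg_estimation_error")
  }
  if (identical(bandwidth, "scott")) {
    check_number(adjust, "adjust", lower = 1e-12)
    sig <- apply(null_z, 2L, stats::mad)
    sig[sig == 0] <- apply(null_z, 2L, stats::sd)[sig == 0]
    h <- adjust * sig * nrow(obs)^(-1 / 6)
  } else {
    check_number(bandwidth, "bandwidth", lower = 1e-12, len = 2L)
    h <- bandwidth
  }
  origin <- matrix(0, 1L, 2L)
  f_origin <- kde2d_points(origin, obs, h)
  f0_origin <- kde2d_points(origin, null_z, h)
  p0_raw <- f_origin / max(f0_origin, eps)
  p0 <- min(1, max(p0_raw, eps))
  f_obs <- pmax(kde2d_points(obs, obs, h), eps)
  f0_obs <- kde2d_points(obs, null_z, h)
  fdr <- pmin(1, pmax(0, p0 * f0_obs / f_obs))
  pairs <- zpairs
  pairs$p1 <- 1 - fdr
  pairs$fdr <- fdr
  structure(list(p0 = p0, p0_raw = p0_raw, p1 = 1 - p0, pairs = pairs,
                 bandwidth = h, f_origin = f_origin, f0_origin = f0_origin,
                 eps = eps, obs_sample = obs, null_sample = null_z),
            class = "mixture_fit")
}

#' Filter significantly co-regulated kinase-substrate pairs
#'
#' Retains pairs with local fdr below `fdr_max` and absolute kinase /
#' substrate log2 fold changes above `lfc_k_min` / `lfc_s_min` (defaults
#' 0.05, 0.05 and 0.5), sorted by fdr then by combined |Zk| + |Zs|
#' descending; per-kinase substrate counts are attached for network
#' rendering.
#'
#' @param fit a [fit_mixture()] result.
#' @param fdr_max,lfc_k_min,lfc_s_min significance thresholds.
#' @return data.frame of significant pairs; per-kinase counts in
#'   `attr(, "kinase_counts")`.
#' @export
significant_pairs <- function(fit, fdr_max = 0.05, lfc_k_min = 0.05,
                              lfc_s_min = 0.5) {
  stopifnot(inherits(fit, "mixture_fit"))
  p <- fit$pairs
  sel <- p$fdr < fdr_max & abs(p$lfc_k) > lfc_k_min & abs(p$lfc_s) > lfc_s_min
  out <- p[sel, , drop = FALSE]
  out <- out[order(out$fdr, -(abs(out$Zk) + abs(out$Zs))), , drop = FALSE]
  rownames(out) <- NULL
  counts <- if (nrow(out) > 0L) table(out$kinase) else table(character(0))
  structure(out, kinase_counts = counts,
            thresholds = c(fdr_max = fdr_max, lfc_k_min = lfc_k_min,
                           lfc_s_min = lfc_s_min))
}

#' Kinase-substrate co-regulation analysis
#'
#' The full two-dimensional empirical-Bayes co-regulation model in one call:
#' joins the relation table to the quantified matrices ([build_pairs()]),
#' computes purity-adjusted moderated statistics per pair ([compute_z()]),
#' simulates the permutation null ([permutation_null()]), deconvolves the
#' 2D mixture ([fit_mixture()]) and filters significant pairs
#' ([significant_pairs()]).
#'
#' @param ks_table,global,phospho,max_missing as in [build_pairs()].
#' @param groups,purity as in [compute_z()].
#' @param n_perm,seed as in [permutation_null()].
#' @param bandwidth,adjust as in [fit_mixture()].
#' @param fdr_max,lfc_k_min,lfc_s_min as in [significant_pairs()].
#' @return object of class `ksa2d`: the [fit_mixture()] result plus
#'   `significant`, `filter_stats`, `n_perm`, `seed` and the call.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 20, n_kinases = 15,
#'                                      substrates_per_kinase = 4, seed = 7))
#' fit <- ksa2d(cohort$ks_table, cohort$global, cohort$phospho,
#'              cohort$groups, cohort$clinical$purity, n_perm = 20, seed = 7)
#' print(fit)
ksa2d <- function(ks_table, global, phospho, groups, purity,
                  max_missing = 6L, n_perm = 200L, seed = 1L,
                  bandwidth = "scott", adjust = 2, fdr_max = 0.05,
                  lfc_k_min = 0.05, lfc_s_min = 0.5) {
  cl <- match.call()
  paired <- build_pairs(ks_table, global, phospho, max_missing = max_missing)
  zp <- compute_z(paired, groups, purity)
  null_z <- permutation_null(paired, groups, purity, n_perm = n_perm, seed = seed)
  fit <- fit_mixture(zp, null_z, bandwidth = bandwidth, adjust = adjust)
  fit$significant <- significant_pairs(fit, fdr_max = fdr_max,
                                       lfc_k_min = lfc_k_min,
                                       lfc_s_min = lfc_s_min)
  fit$filter_stats <- paired$stats
  fit$n_perm <- n_perm
  fit$seed <- seed
  fit$call <- cl
  class(fit) <- c("ksa2d", "mixture_fit")
  fit
}

#' @export
print.ksa2d <- function(x, ...) {
  cat("Two-dimensional kinase-substrate co-regulation model\n")
  cat(sprintf("  pairs analyzed: %d (of %d relations; %d permutations)\n",
              nrow(x$pairs), x$filter_stats[["relations"]], x$n_perm))
  cat(sprintf("  estimated null proportion p0 = %.3f (p1 = %.3f)\n",
              x$p0, 1 - x$p0))
  th <- attr(x$significant, "thresholds")
  cat(sprintf("  significant pairs: %d (fdr < %g, |lfc_k| > %g, |lfc_s| > %g)\n",
              nrow(x$significant), th["fdr_max"], th["lfc_k_min"], th["lfc_s_min"]))
  invisible(x)
}

#' @export
summary.ksa2d <- function(object, ...) {
  kc <- attr(object$significant, "kinase_counts")
  out <- list(n_pairs = nrow(object$pairs), p0 = object$p0,
              p0_raw = object$p0_raw, bandwidth = object$bandwidth,
              n_perm = object$n_perm, seed = object$seed,
              n_significant = nrow(object$significant),
              kinase_counts = sort(kc, decreasing = TRUE),
              filter_stats = object$filter_stats,
              fdr_quartiles = stats::quantile(object$pairs$fdr,
                                              c(0, 0.25, 0.5, 0.75, 1)))
  class(out) <- "summary.ksa2d"
  out
}

#' @export
print.summary.ksa2d <- function(x, ...) {
  cat(sprintf("KSA2D fit: %d pairs, p0 = %.3f, %d significant\n",
              x$n_pairs, x$p0, x$n_significant))
  cat(sprintf("  bandwidths (Zk, Zs): %.3f, %.3f; %d permutations, seed %d\n",
              x$bandwidth[1], x$bandwidth[2], x$n_perm, x$seed))
  cat("  filter counts:", paste(names(x$filter_stats), x$filter_stats,
                                sep = "=", collapse = ", "), "\n")
  cat("  local fdr quartiles:",
      paste(sprintf("%.3f", x$fdr_quartiles), collapse = " "), "\n")
  if (length(x$kinase_counts) > 0) {
    top <- utils::head(x$kinase_counts, 5L)
    cat("  top kinases:", paste(names(top), top, sep = ":", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Evaluate the fitted mixture at new points of the Z plane
#'
#' @param object a [ksa2d()] / [fit_mixture()] result.
#' @param newdata data.frame or matrix with columns `Zk`, `Zs`.
#' @param ... unused.
#' @return data.frame with `Zk`, `Zs`, `f`, `f0`, `p1`, `fdr`.
#' @export
predict.mixture_fit <- function(object, newdata, ...) {
  nd <- as.matrix(as.data.frame(newdata)[, c("Zk", "Zs")])
  f <- pmax(kde2d_points(nd, object$obs_sample, object$bandwidth), object$eps)
  f0 <- kde2d_points(nd, object$null_sample, object$bandwidth)
  fdr <- pmin(1, pmax(0, object$p0 * f0 / f))
  data.frame(Zk = nd[, 1L], Zs = nd[, 2L], f = f, f0 = f0,
             p1 = 1 - fdr, fdr = fdr)
}

#' Plot the Z plane of a co-regulation fit
#'
#' Scatter of (Zk, Zs) for all pairs, shaded by local fdr, with significant
#' pairs highlighted.
#'
#' @param x a [ksa2d()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ksa2d <- function(x, ...) {
  p <- x$pairs
  shade <- grDevices::gray(pmin(0.85, p$fdr))
  graphics::plot(p$Zk, p$Zs, col = shade, pch = 16, cex = 0.6,
                 xlab = "Zk (kinase moderated t)",
                 ylab = "Zs (substrate-site moderated t)", ...)
  graphics::abline(h = 0, v = 0, col = "gray70", lty = 3)
  sig <- x$significant
  if (!is.null(sig) && nrow(sig) > 0) {
    graphics::points(sig$Zk, sig$Zs, col = "firebrick", pch = 1, cex = 0.9)
  }
  graphics::legend("topleft", legend = c("pair (dark = low fdr)", "significant"),
                   col = c("gray40", "firebrick"), pch = c(16, 1), bty = "n",
                   cex = 0.8)
  invisible(x)
}
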