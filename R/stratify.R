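#' Two-group log-rank test
#'
#' Standard log-rank chi-square test (1 df) for a survival difference between
#' two groups, computed via [survival::survdiff()].
#'
#' @param times non-negative event/censoring times.
#' @param events event indicators (0 = censored, 1 = event).
#' @param groups two-level grouping vector.
#' @return list with `statistic` (chi-square, 1 df) and `p`.
#' @export
logrank_test <- function(times, events, groups) {
  check_number(times, "times", lower = 0, len = NULL)
  check_number(events, "events", lower = 0, upper = 1, len = NULL, integer = TRUE)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L) {
    stop_invalid("groups must have exactly two non-empty levels",
                 class = "gicoreg_degenerate_design")
  }
  if (sum(events) < 1L) {
    stop_invalid("at least one event is required",
                 class = "gicoreg_degenerate_design")
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  stat <- unname(sd$chisq)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Multivariate Cox regression maximizing the partial likelihood with Efron
#' handling of tied event times (via [survival::coxph()]). Returns per-
#' covariate Wald statistics plus the global score test, which for a single
#' binary covariate without ties equals the log-rank statistic.
#'
#' @param times,events as in [logrank_test()].
#' @param covariates data.frame (or matrix) of covariates; factors allowed.
#' @return list with `coefficients`, `se`, `wald_p` (named per coefficient),
#'   `score_test` (global score chi-square), `loglik`, and the underlying
#'   `fit`.
#' @export
cox_fit <- function(times, events, covariates) {
  check_number(times, "times", lower = 0, len = NULL)
  check_number(events, "events", lower = 0, upper = 1, len = NULL, integer = TRUE)
  covariates <- as.data.frame(covariates)
  const <- vapply(covariates, function(x) length(unique(x[!is.na(x)])) < 2L, logical(1))
  if (any(const)) {
    stop_invalid(sprintf("covariate(s) %s constant across samples",
                         paste(names(covariates)[const], collapse = ", ")),
                 class = "gicoreg_degenerate_design")
  }
  if (sum(events) < 1L) {
    stop_invalid("at least one event is required",
                 class = "gicoreg_degenerate_design")
  }
  df <- cbind(data.frame(.time = times, .event = events), covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  if (any(is.na(stats::coef(fit)))) {
    stop(structure(class = c("gicoreg_convergence", "gicoreg_error", "error", "condition"),
                   list(message = "Cox model did not yield estimable coefficients",
                        call = sys.call())))
  }
  s <- summary(fit)
  list(coefficients = stats::coef(fit),
       se = stats::setNames(s$coefficients[, "se(coef)"],
                            rownames(s$coefficients)),
       wald_p = stats::setNames(s$coefficients[, "Pr(>|z|)"],
                                rownames(s$coefficients)),
       score_test = unname(s$sctest["test"]),
       loglik = fit$loglik,
       fit = fit)
}

#' Assign high/low genome-instability groups at a wGII cutoff
#'
#' A sample is `high` iff its wGII strictly exceeds the cutoff; a sample
#' exactly at the cutoff is `low`.
#'
#' @param wgii per-sample wGII values.
#' @param cutoff finite cutoff.
#' @return factor with levels `low`, `high`, named like `wgii`.
#' @export
assign_groups <- function(wgii, cutoff) {
  check_number(cutoff, "cutoff")
  stats::setNames(factor(ifelse(wgii > cutoff, "high", "low"),
                         levels = c("low", "high")), names(wgii))
}

#' Survival-driven wGII cutoff search
#'
#' Scans a grid of candidate wGII cutoffs, dichotomizes the cohort at each,
#' and records the Cox p-value of the high/low group indicator (optionally
#' adjusted for clinical covariates). The chosen cutoff minimizes this
#' p-value; ties are broken toward the more balanced grouping. Because the
#' minimal p-value over a grid is anti-conservative by construction, the full
#' p-curve is returned and should be reported alongside the choice (or the
#' cutoff validated on an independent cohort).
#'
#' @param wgii named per-sample wGII values.
#' @param clinical data.frame with columns `sample`, `time`, `event`, and any
#'   adjustment covariates.
#' @param grid_step spacing of candidate cutoffs (default 0.01).
#' @param min_group_fraction minimum fraction of samples in each group for a
#'   candidate to be admissible (default 0.1).
#' @param adjust character vector of clinical columns to adjust for (e.g.
#'   `c("age", "gender", "stage", "purity")`); default none (univariate).
#' @return object of class `cutoff_search`: list with `grid`, `p_curve`,
#'   `chosen_cutoff`, `group_sizes`, `n`.
#' @export
find_wgii_cutoff <- function(wgii, clinical, grid_step = 0.01,
                             min_group_fraction = 0.1, adjust = character(0)) {
  stopifnot(is.data.frame(clinical),
            all(c("sample", "time", "event") %in% names(clinical)))
  if (is.null(names(wgii))) stop_invalid("wgii must be named by sample id")
  common <- intersect(names(wgii), clinical$sample)
  if (length(common) < 4L) stop_invalid("wgii and clinical share too few samples")
  clinical <- clinical[match(common, clinical$sample), , drop = FALSE]
  wgii <- wgii[common]
  n <- length(wgii)
  check_number(grid_step, "grid_step", lower = 1e-6)
  check_number(min_group_fraction, "min_group_fraction", lower = 0, upper = 0.5)

  rng <- range(wgii)
  grid <- seq(ceiling(rng[1] / grid_step) * grid_step, rng[2], by = grid_step)
  grid <- grid[grid > rng[1] & grid < rng[2]]
  admissible <- vapply(grid, function(cc) {
    nh <- sum(wgii > cc)
    min(nh, n - nh) >= min_group_fraction * n
  }, logical(1))
  grid <- grid[admissible]
  if (length(grid) < 1L) {
    stop_invalid("no admissible cutoff candidate", class = "gicoreg_search_failure")
  }
  p_curve <- vapply(grid, function(cc) {
    g <- assign_groups(wgii, cc)
    covs <- data.frame(group = g)
    if (length(adjust) > 0) covs <- cbind(covs, clinical[, adjust, drop = FALSE])
    fit <- tryCatch(cox_fit(clinical$time, clinical$event, covs),
                    gicoreg_error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    unname(fit$wald_p[grep("^group", names(fit$wald_p))[1L]])
  }, numeric(1))
  ok <- which(!is.na(p_curve))
  if (length(ok) == 0L) {
    stop_invalid("no candidate cutoff admitted a Cox fit",
                 class = "gicoreg_search_failure")
  }
  best_p <- min(p_curve[ok])
  cand <- ok[p_curve[ok] <= best_p + 1e-15]
  if (length(cand) > 1L) {  # tie-break: most balanced grouping
    imbalance <- vapply(grid[cand], function(cc) abs(sum(wgii > cc) - sum(wgii <= cc)),
                        numeric(1))
    cand <- cand[which.min(imbalance)]
  }
  chosen <- grid[cand[1L]]
  g <- assign_groups(wgii, chosen)
  structure(list(grid = grid, p_curve = p_curve, chosen_cutoff = chosen,
                 group_sizes = c(n_high = sum(g == "high"), n_low = sum(g == "low")),
                 n = n),
            class = "cutoff_search")
}

#' @export
print.cutoff_search <- function(x, ...) {
  cat(sprintf("wGII cutoff search over %d candidates (n = %d)\n",
              length(x$grid), x$n))
  cat(sprintf("  chosen cutoff: %.3f (p = %.3g; %d high / %d low)\n",
              x$chosen_cutoff, min(x$p_curve, na.rm = TRUE),
              x$group_sizes["n_high"], x$group_sizes["n_low"]))
  cat("  note: the minimized p-value is anti-conservative; inspect p_curve\n")
  invisible(x)
}

#' Kaplan-Meier step-function table per group
#'
#' @param times,events,groups as in [logrank_test()].
#' @return data.frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `surv`.
#' @export
km_table <- function(times, events, groups) {
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  strata <- if (is.null(fit$strata)) rep("all", length(fit$time)) else {
    rep(sub("^groups=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv, stringsAsFactors = FALSE)
}
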