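#' Simulation configuration for synthetic cohorts
#'
#' Bundles and validates every knob of the synthetic-data generator. Defaults
#' describe a small renal-cohort-like study: 30 tumors, a genome of 22
#' autosome-like chromosomes, diploid baseline, survival hazard that triples
#' above a wGII of 0.3, and a phosphoproteomics experiment in which 30% of
#' kinase-substrate pairs are co-regulated between the instability groups
#' with kinase shifts of 1 and substrate-site shifts of 1.5 on the log2
#' scale over measurement noise of SD 0.5.
#'
#' @param n_samples number of tumor samples.
#' @param chrom_sizes named vector of chromosome lengths in bp. Default: 22
#'   chromosomes of 10 kb (small so that per-base oracles stay cheap; wGII is
#'   scale-free in chromosome length).
#' @param baseline_ploidy integer baseline copy number, recycled per sample.
#' @param aberrant_fraction per-sample target fraction of the genome at a
#'   non-baseline copy number, recycled; may be a single value, a vector of
#'   length `n_samples`, or `"uniform"` to draw from U(0.05, 0.6).
#' @param hazard_ratio hazard multiplier for samples above `true_cutoff`.
#' @param true_cutoff wGII threshold at which the hazard changes.
#' @param baseline_hazard exponential event rate (per month) below the cutoff.
#' @param censor_frac approximate fraction of samples censored.
#' @param n_features number of global-proteome features (>= `n_kinases`; the
#'   first `n_kinases` rows are the kinases, the rest null background).
#' @param n_kinases number of kinase proteins.
#' @param substrates_per_kinase substrate phosphosites per kinase.
#' @param planted_fraction fraction of kinase-substrate pairs that are truly
#'   co-regulated (planted at whole-kinase granularity).
#' @param effect_size_kinase,effect_size_substrate log2 mean shift of planted
#'   kinase proteins / substrate sites in the high-instability group.
#' @param purity_effect log2 shift per unit tumor purity added to planted
#'   features (purity confounding, making purity adjustment necessary).
#' @param noise_sd residual SD of log2 ratios.
#' @param purity_range length-2 interval in (0, 1\] for tumor purity.
#' @param missing_rate completely-at-random missingness rate of the matrices.
#' @param seed integer seed; every generator is deterministic given it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 30L,
                       chrom_sizes = stats::setNames(rep(10000L, 22), as.character(1:22)),
                       baseline_ploidy = 2L,
                       aberrant_fraction = "uniform",
                       hazard_ratio = 3,
                       true_cutoff = 0.3,
                       baseline_hazard = 0.015,
                       censor_frac = 0.3,
                       n_features = NULL,
                       n_kinases = 50L,
                       substrates_per_kinase = 10L,
                       planted_fraction = 0.3,
                       effect_size_kinase = 1,
                       effect_size_substrate = 1.5,
                       purity_effect = 1,
                       noise_sd = 0.5,
                       purity_range = c(0.4, 0.9),
                       missing_rate = 0.05,
                       seed = 1L) {
  check_number(n_samples, "n_samples", lower = 1, integer = TRUE)
  if (length(chrom_sizes) == 0L || is.null(names(chrom_sizes))) {
    stop_invalid("chrom_sizes must be a non-empty named vector")
  }
  check_number(chrom_sizes, "chrom_sizes", lower = 1, integer = TRUE, len = NULL)
  check_number(baseline_ploidy, "baseline_ploidy", lower = 0, integer = TRUE, len = NULL)
  if (!identical(aberrant_fraction, "uniform")) {
    check_number(aberrant_fraction, "aberrant_fraction", lower = 0, upper = 1, len = NULL)
    if (!length(aberrant_fraction) %in% c(1L, n_samples)) {
      stop_invalid("aberrant_fraction must be scalar, length n_samples, or \"uniform\"")
    }
  }
  check_number(hazard_ratio, "hazard_ratio", lower = 1e-12)
  check_number(true_cutoff, "true_cutoff", lower = 0, upper = 1)
  check_number(baseline_hazard, "baseline_hazard", lower = 1e-12)
  check_number(censor_frac, "censor_frac", lower = 0, upper = 0.95)
  check_number(n_kinases, "n_kinases", lower = 1, integer = TRUE)
  check_number(substrates_per_kinase, "substrates_per_kinase", lower = 1, integer = TRUE)
  if (is.null(n_features)) n_features <- n_kinases
  check_number(n_features, "n_features", lower = n_kinases, integer = TRUE)
  check_number(planted_fraction, "planted_fraction", lower = 0, upper = 1)
  check_number(effect_size_kinase, "effect_size_kinase")
  check_number(effect_size_substrate, "effect_size_substrate")
  check_number(purity_effect, "purity_effect")
  check_number(noise_sd, "noise_sd", lower = 1e-12)
  check_number(purity_range, "purity_range", lower = 0, upper = 1, len = 2L)
  if (purity_range[1] >= purity_range[2]) stop_invalid("purity_range must be increasing")
  check_number(missing_rate, "missing_rate", lower = 0, upper = 0.99)
  check_number(seed, "seed", integer = TRUE)
  structure(list(
    n_samples = as.integer(n_samples), chrom_sizes = chrom_sizes,
    baseline_ploidy = rep_len(as.integer(baseline_ploidy), n_samples),
    aberrant_fraction = aberrant_fraction, hazard_ratio = hazard_ratio,
    true_cutoff = true_cutoff, baseline_hazard = baseline_hazard,
    censor_frac = censor_frac, n_features = as.integer(n_features),
    n_kinases = as.integer(n_kinases),
    substrates_per_kinase = as.integer(substrates_per_kinase),
    planted_fraction = planted_fraction,
    effect_size_kinase = effect_size_kinase,
    effect_size_substrate = effect_size_substrate,
    purity_effect = purity_effect, noise_sd = noise_sd,
    purity_range = purity_range, missing_rate = missing_rate,
    seed = as.integer(seed)), class = "sim_config")
}

sample_ids <- function(n) sprintf("S%03d", seq_len(n))

#' Generate per-sample copy-number segment profiles
#'
#' Each chromosome receives 1-4 aberrant blocks whose total length is exactly
#' `round(target * chromosome length)` base pairs, placed at random positions
#' with baseline-copy-number gaps between them, so the realized per-
#' chromosome aberrant fraction matches the target at base-pair resolution.
#' Aberrant blocks receive an integer copy number differing from the
#' baseline by 1 or 2 (never below 0).
#'
#' @param config a [sim_config()].
#' @return list with `segments` (long data.frame: sample, chrom, start, end,
#'   copy_number) and `true_wgii` (named per-sample realized wGII, which by
#'   construction equals the wGII recomputed from the emitted segments).
#' @export
gen_segments <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_samples
  ids <- sample_ids(n)
  targets <- config$aberrant_fraction
  if (identical(targets, "uniform")) {
    targets <- stats::runif(n, 0.05, 0.6)
  } else {
    targets <- rep_len(targets, n)
  }
  chroms <- names(config$chrom_sizes)
  out <- vector("list", n)
  true_wgii <- numeric(n)
  for (i in seq_len(n)) {
    base <- config$baseline_ploidy[i]
    per_chr <- vector("list", length(chroms))
    chr_frac <- numeric(length(chroms))
    for (j in seq_along(chroms)) {
      L <- config$chrom_sizes[[j]]
      A <- as.integer(round(targets[i] * L))  # aberrant bases, exact
      if (A == 0L) {
        len <- L
        aberr <- FALSE
      } else if (A == L) {
        m <- sample(1:4, 1L)
        len <- as.vector(stats::rmultinom(1L, L - m, rep(1 / m, m))) + 1L
        aberr <- rep(TRUE, m)
      } else {
        m <- min(sample(1:4, 1L), A)
        block <- as.vector(stats::rmultinom(1L, A - m, rep(1 / m, m))) + 1L
        gap <- as.vector(stats::rmultinom(1L, L - A, rep(1 / (m + 1L), m + 1L)))
        len <- integer(0)
        aberr <- logical(0)
        for (b in seq_len(m)) {
          if (gap[b] > 0L) { len <- c(len, gap[b]); aberr <- c(aberr, FALSE) }
          len <- c(len, block[b]); aberr <- c(aberr, TRUE)
        }
        if (gap[m + 1L] > 0L) { len <- c(len, gap[m + 1L]); aberr <- c(aberr, FALSE) }
      }
      end <- cumsum(len)
      start <- c(1L, utils::head(end, -1L) + 1L)
      cn <- rep(base, length(len))
      if (any(aberr)) {
        delta <- sample(c(-2L, -1L, 1L, 2L), sum(aberr), replace = TRUE)
        cn_ab <- base + delta
        cn_ab[cn_ab < 0L] <- base + abs(delta[cn_ab < 0L])  # reflect below zero
        cn[aberr] <- cn_ab
      }
      per_chr[[j]] <- data.frame(sample = ids[i], chrom = chroms[j],
                                 start = start, end = end, copy_number = cn,
                                 stringsAsFactors = FALSE)
      chr_frac[j] <- A / L
    }
    out[[i]] <- do.call(rbind, per_chr)
    true_wgii[i] <- mean(chr_frac)
  }
  segments <- do.call(rbind, out)
  rownames(segments) <- NULL
  names(true_wgii) <- ids
  list(segments = segments, true_wgii = true_wgii)
}

#' Generate survival and clinical covariates from true wGII
#'
#' Event times are exponential with rate `baseline_hazard`, multiplied by
#' `hazard_ratio` for samples whose true wGII exceeds `true_cutoff`.
#' Censoring is independent uniform on (0, b) with b chosen so that roughly
#' `censor_frac` of samples are censored. Tumor purity is drawn within
#' `purity_range`, shifted toward its upper half for high-instability samples
#' so that purity is a genuine confounder downstream.
#'
#' @param true_wgii named per-sample wGII vector (e.g. from [gen_segments()]).
#' @param config a [sim_config()].
#' @return clinical data.frame: sample, time (months), event, age, gender,
#'   race, stage, purity.
#' @export
gen_survival <- function(true_wgii, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 2L))
  n <- length(true_wgii)
  high <- true_wgii > config$true_cutoff
  rate <- config$baseline_hazard * ifelse(high, config$hazard_ratio, 1)
  t_event <- stats::rexp(n, rate)
  # uniform censoring horizon calibrated for the baseline-rate group:
  # P(censored) = (1 - exp(-lambda b)) / (lambda b) = censor_frac
  f <- function(x) (1 - exp(-x)) / x - config$censor_frac
  xb <- stats::uniroot(f, c(1e-6, 500))$root
  b <- xb / config$baseline_hazard
  t_cens <- stats::runif(n, 0, b)
  pr <- config$purity_range
  mid <- mean(pr)
  purity <- unname(ifelse(high, stats::runif(n, mid, pr[2]),
                          stats::runif(n, pr[1], mid)))
  out <- data.frame(
    sample = names(true_wgii),
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    age = pmin(90, pmax(30, round(stats::rnorm(n, 60, 10)))),
    gender = sample(c("M", "F"), n, replace = TRUE),
    race = sample(c("white", "black", "asian", "other"), n, replace = TRUE,
                  prob = c(0.7, 0.15, 0.1, 0.05)),
    stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE),
    purity = purity,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Generate global-proteome and phosphoproteome matrices with planted
#' kinase-substrate co-regulation
#'
#' The global matrix holds kinase-protein log2 ratios, null substrate-protein
#' ratios (planting acts at the PTM-site level) and optional extra background
#' features; the phospho matrix holds substrate-site log2 ratios,
#' one site per substrate protein, with site ids `PROT_S<pos>`. A
#' `planted_fraction` share of kinases is planted: their proteins are shifted
#' by `effect_size_kinase` and all their substrate sites by
#' `effect_size_substrate` in the high group, plus `purity_effect * purity`
#' (the purity confounder). Noise is i.i.d. Gaussian; missingness is MCAR.
#'
#' @param config a [sim_config()].
#' @param groups per-sample factor with levels `low`, `high` (names = sample
#'   ids).
#' @param purity per-sample tumor purity aligned with `groups`; defaults to a
#'   fresh draw in `purity_range` shifted upward for the high group.
#' @return list with `global`, `phospho` (matrices, features x samples),
#'   `ks_table` (kinase, substrate, residue, position, modification),
#'   `truth` (planted pair ids and effects), `purity`.
#' @export
gen_omics <- function(config, groups, purity = NULL) {
  stopifnot(inherits(config, "sim_config"))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop_invalid("groups must have exactly two levels")
  groups <- factor(groups, levels = c("low", "high"))
  if (anyNA(groups)) stop_invalid("groups must use labels 'low' and 'high'")
  set.seed(derive_seed(config$seed, 3L))
  n <- length(groups)
  ids <- names(groups)
  if (is.null(ids)) ids <- sample_ids(n)
  if (is.null(purity)) {
    pr <- config$purity_range
    mid <- mean(pr)
    purity <- ifelse(groups == "high", stats::runif(n, mid, pr[2]),
                     stats::runif(n, pr[1], mid))
    names(purity) <- ids
  }
  nk <- config$n_kinases
  spk <- config$substrates_per_kinase
  kin_ids <- sprintf("KIN%04d", seq_len(nk))
  n_bg <- config$n_features - nk
  bg_ids <- if (n_bg > 0) sprintf("PRO%04d", seq_len(n_bg)) else character(0)
  n_sites <- nk * spk
  sub_prot <- sprintf("SUB%05d", seq_len(n_sites))
  residue <- sample(c("S", "T", "Y"), n_sites, replace = TRUE, prob = c(0.8, 0.15, 0.05))
  position <- sample(5:1500, n_sites, replace = TRUE)
  site_ids <- paste0(sub_prot, "_", residue, position)
  ks_table <- data.frame(
    kinase = rep(kin_ids, each = spk),
    substrate = sub_prot,
    residue = residue,
    position = position,
    modification = "phosphorylation",
    stringsAsFactors = FALSE)

  n_planted_kin <- round(config$planted_fraction * nk)
  planted_kin <- if (n_planted_kin > 0) sample(kin_ids, n_planted_kin) else character(0)
  planted <- ks_table$kinase %in% planted_kin
  hi <- as.numeric(groups == "high")

  mk_matrix <- function(feat_ids, effect_feat, effect_size) {
    m <- matrix(stats::rnorm(length(feat_ids) * n, 0, config$noise_sd),
                nrow = length(feat_ids), dimnames = list(feat_ids, ids))
    if (any(effect_feat)) {
      shift <- outer(rep(effect_size, sum(effect_feat)), hi) +
        outer(rep(config$purity_effect, sum(effect_feat)), purity)
      m[effect_feat, ] <- m[effect_feat, , drop = FALSE] + shift
    }
    if (config$missing_rate > 0) {
      m[stats::runif(length(m)) < config$missing_rate] <- NA_real_
    }
    m
  }
  # global proteome quantifies kinases (planted ones shifted), the substrate
  # proteins (null at protein level: planting acts on the PTM site), and any
  # extra background features
  global <- mk_matrix(c(kin_ids, sub_prot, bg_ids),
                      c(kin_ids %in% planted_kin, rep(FALSE, n_sites + n_bg)),
                      config$effect_size_kinase)
  phospho <- mk_matrix(site_ids, planted, config$effect_size_substrate)

  planted_ids <- paste0(ks_table$kinase, "|", site_ids)[planted]
  truth <- list(
    planted_kinases = planted_kin,
    planted_pairs = planted_ids,
    true_effects = data.frame(
      pair = planted_ids,
      d_kinase = rep(config$effect_size_kinase, length(planted_ids)),
      d_substrate = rep(config$effect_size_substrate, length(planted_ids)),
      stringsAsFactors = FALSE))
  list(global = global, phospho = phospho, ks_table = ks_table,
       truth = truth, purity = purity)
}

#' Simulate a full synthetic cohort
#'
#' Runs [gen_segments()], [gen_survival()] and [gen_omics()] in sequence with
#' consistent sample ids, grouping samples by their true wGII against
#' `config$true_cutoff`.
#'
#' @param config a [sim_config()].
#' @return list with `segments`, `true_wgii`, `clinical`, `groups`, `global`,
#'   `phospho`, `ks_table`, `truth`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  seg <- gen_segments(config)
  clinical <- gen_survival(seg$true_wgii, config)
  groups <- factor(ifelse(seg$true_wgii > config$true_cutoff, "high", "low"),
                   levels = c("low", "high"))
  names(groups) <- names(seg$true_wgii)
  om <- gen_omics(config, groups, purity = stats::setNames(clinical$purity, clinical$sample))
  list(segments = seg$segments, true_wgii = seg$true_wgii,
       clinical = clinical, groups = groups,
       global = om$global, phospho = om$phospho, ks_table = om$ks_table,
       truth = c(om$truth, list(true_wgii = seg$true_wgii,
                                true_group = as.character(groups))))
}
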