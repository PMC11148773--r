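# Independent brute-force oracles and small fixture builders.

# Per-base-pair wGII recomputation: expand every chromosome to a base-wise
# copy-number vector and count aberrant bases directly.
brute_force_wgii <- function(profile, baseline, chromosomes = NULL) {
  if (is.null(chromosomes)) chromosomes <- unique(profile$chrom)
  fracs <- vapply(chromosomes, function(ch) {
    s <- profile[profile$chrom == ch, , drop = FALSE]
    per_base <- unlist(lapply(seq_len(nrow(s)), function(i) {
      rep(s$copy_number[i], s$end[i] - s$start[i] + 1)
    }))
    mean(per_base != baseline)
  }, numeric(1))
  mean(fracs)
}

# Per-base modal copy number (ties toward smaller value).
brute_force_baseline <- function(profile) {
  per_base <- unlist(lapply(seq_len(nrow(profile)), function(i) {
    rep(profile$copy_number[i], profile$end[i] - profile$start[i] + 1)
  }))
  tab <- table(per_base)
  cands <- as.integer(names(tab)[tab == max(tab)])
  min(cands)
}

# Random valid segment profile over small chromosomes.
random_profile <- function(seed, n_chrom = 3, chrom_len = 2000) {
  set.seed(seed)
  segs <- do.call(rbind, lapply(seq_len(n_chrom), function(ch) {
    k <- sample(2:8, 1)
    cuts <- sort(sample(seq_len(chrom_len - 1), k - 1))
    data.frame(chrom = as.character(ch),
               start = c(1L, cuts + 1L), end = c(cuts, chrom_len),
               copy_number = sample(0:5, k, replace = TRUE))
  }))
  segment_profile(segs)
}

# Hand expansion of the two-group log-rank test: hypergeometric expectation
# and variance summed over distinct event times.
logrank_by_hand <- function(times, events, groups) {
  groups <- as.factor(groups)
  g1 <- levels(groups)[1]
  obs_minus_exp <- 0
  var_sum <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & groups == g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & groups == g1)
    obs_minus_exp <- obs_minus_exp + (d1 - d * n1 / n)
    if (n > 1) {
      var_sum <- var_sum + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  obs_minus_exp^2 / var_sum
}

# Purity gap between groups (planted features carry purity_effect * purity,
# so the raw group difference exceeds the planted shift by this gap).
attr_purity_gap <- function(co) {
  grp <- co$groups[names(co$purity)]
  mean(co$purity[grp == "high"]) - mean(co$purity[grp == "low"])
}

# Small co-regulation cohort used by several ksa2d tests.
small_cohort <- function(seed = 42, n_samples = 24, n_kinases = 30,
                         substrates_per_kinase = 4, planted_fraction = 0.3,
                         ...) {
  co <- simulate_cohort(sim_config(
    n_samples = n_samples, n_kinases = n_kinases,
    substrates_per_kinase = substrates_per_kinase,
    planted_fraction = planted_fraction, seed = seed, ...))
  co$purity <- stats::setNames(co$clinical$purity,
                               co$clinical$sample)[colnames(co$global)]
  co
}
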