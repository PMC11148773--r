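#' Segment profiles: per-sample absolute copy-number segments
#'
#' A segment profile is a `data.frame` with columns `chrom` (character),
#' `start`, `end` (1-based inclusive base-pair coordinates) and `copy_number`
#' (non-negative integer), describing one sample's absolute copy-number
#' landscape. Segments within a chromosome must be non-overlapping.
#'
#' @param segments data.frame with columns `chrom`, `start`, `end`,
#'   `copy_number`.
#' @param sample_id sample identifier attached as an attribute.
#' @return A validated `segment_profile` (a `data.frame`, sorted by chromosome
#'   then start).
#' @export
segment_profile <- function(segments, sample_id = NA_character_) {
  req <- c("chrom", "start", "end", "copy_number")
  if (!is.data.frame(segments) || !all(req %in% names(segments))) {
    stop_invalid("segments must be a data.frame with columns chrom, start, end, copy_number")
  }
  if (nrow(segments) == 0L) {
    stop_invalid("segment profile is empty", class = "gicoreg_empty_input")
  }
  segments$chrom <- sub("^chr", "", as.character(segments$chrom))
  check_number(segments$start, "start", lower = 1, len = NULL, integer = TRUE)
  check_number(segments$end, "end", lower = 1, len = NULL, integer = TRUE)
  check_number(segments$copy_number, "copy_number", lower = 0, len = NULL,
               integer = TRUE)
  if (any(segments$end < segments$start)) {
    bad <- which(segments$end < segments$start)[1L]
    stop_invalid(sprintf("segment %d has end < start", bad))
  }
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1L] <= s$end[-nrow(s)])) {
      stop_invalid(sprintf("overlapping segments on chromosome %s", ch))
    }
  }
  rownames(segments) <- NULL
  structure(segments, sample_id = sample_id, class = c("segment_profile", "data.frame"))
}

#' Infer the baseline (reference) copy number of a sample
#'
#' The baseline is the length-weighted modal integer copy number across all
#' segments of the profile: the copy-number state covering the largest share
#' of the profiled genome. Ties are broken toward the smaller copy number.
#' Aberration in [compute_wgii()] is defined relative to this baseline; a
#' known ploidy can be supplied there instead.
#'
#' @param profile a [segment_profile()].
#' @return integer scalar baseline copy number.
#' @export
#' @examples
#' p <- segment_profile(data.frame(chrom = "1", start = c(1, 61),
#'                                 end = c(60, 100), copy_number = c(4, 3)))
#' infer_baseline(p)  # 4: covers 60% of profiled length
infer_baseline <- function(profile) {
  profile <- as_profile(profile)
  len <- profile$end - profile$start + 1
  tot <- tapply(len, profile$copy_number, sum)
  cn <- as.integer(names(tot))
  # ties toward the smaller copy number
  best <- cn[tot == max(tot)]
  min(best)
}

as_profile <- function(profile) {
  if (inherits(profile, "segment_profile")) return(profile)
  segment_profile(profile)
}

#' Weighted genome instability index (wGII)
#'
#' For each chromosome, the fraction of its covered segment length whose copy
#' number differs from the sample baseline; wGII is the unweighted mean of
#' these per-chromosome fractions, so every chromosome contributes equally
#' regardless of its physical size. The denominator is the covered (profiled)
#' length of the chromosome, not its nominal size, so incomplete segment
#' coverage does not deflate the score.
#'
#' @param profile a [segment_profile()].
#' @param baseline integer baseline copy number; default infers the
#'   length-weighted modal copy number via [infer_baseline()].
#' @param chromosomes chromosomes to include; default all chromosomes present
#'   in the profile. Conventional usage restricts to autosomes.
#' @return object of class `wgii_result`: list with `sample_id`, `baseline`,
#'   `per_chromosome_fraction` (named numeric) and `wgii`.
#' @export
#' @examples
#' p <- segment_profile(data.frame(
#'   chrom = c("1", "1", "2"), start = c(1, 41, 1), end = c(40, 100, 100),
#'   copy_number = c(3, 2, 2)))
#' compute_wgii(p, baseline = 2)$wgii  # chr1: 0.4 aberrant, chr2: 0 -> 0.2
compute_wgii <- function(profile, baseline = NULL, chromosomes = NULL) {
  profile <- as_profile(profile)
  if (is.null(baseline)) baseline <- infer_baseline(profile)
  check_number(baseline, "baseline", lower = 0, integer = TRUE)
  if (is.null(chromosomes)) {
    chromosomes <- unique(profile$chrom)
  } else {
    chromosomes <- sub("^chr", "", as.character(chromosomes))
  }
  missing_chr <- setdiff(chromosomes, unique(profile$chrom))
  if (length(missing_chr) > 0L) {
    stop_invalid(sprintf("chromosome(s) %s absent from profile",
                         paste(missing_chr, collapse = ", ")),
                 class = "gicoreg_missing_chromosome")
  }
  frac <- vapply(chromosomes, function(ch) {
    s <- profile[profile$chrom == ch, , drop = FALSE]
    len <- s$end - s$start + 1
    sum(len[s$copy_number != baseline]) / sum(len)
  }, numeric(1))
  names(frac) <- chromosomes
  structure(list(sample_id = attr(profile, "sample_id"),
                 baseline = as.integer(baseline),
                 per_chromosome_fraction = frac,
                 wgii = mean(frac)),
            class = "wgii_result")
}

#' @export
print.wgii_result <- function(x, ...) {
  cat(sprintf("wGII = %.4f (baseline CN = %d, %d chromosomes)\n",
              x$wgii, x$baseline, length(x$per_chromosome_fraction)))
  invisible(x)
}

#' wGII for a table of segments covering many samples
#'
#' @param segments data.frame with columns `sample`, `chrom`, `start`, `end`,
#'   `copy_number` (as read by [read_segments()]).
#' @param baseline `"auto"` (per-sample modal baseline) or a single integer
#'   applied to every sample.
#' @param chromosomes passed to [compute_wgii()].
#' @return data.frame with columns `sample`, `baseline`, `wgii`.
#' @export
wgii_table <- function(segments, baseline = "auto", chromosomes = NULL) {
  stopifnot(is.data.frame(segments), "sample" %in% names(segments))
  samples <- unique(segments$sample)
  rows <- lapply(samples, function(sid) {
    p <- segment_profile(segments[segments$sample == sid,
                                  c("chrom", "start", "end", "copy_number")],
                         sample_id = sid)
    b <- if (identical(baseline, "auto")) NULL else as.integer(baseline)
    r <- compute_wgii(p, baseline = b, chromosomes = chromosomes)
    data.frame(sample = sid, baseline = r$baseline, wgii = r$wgii,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' RNA in situ hybridization H-score
#'
#' Percentage-weighted sum of staining intensity bins 0-4:
#' `0*A + 1*B + 2*C + 3*D + 4*E` for bin percentages (A, B, C, D, E) summing
#' to 100. Range 0 (all cells negative) to 400 (all cells in the top bin).
#'
#' @param percentages numeric vector of length 5, percentages of cells in
#'   score bins 0,1,2,3,4; must sum to 100 (tolerance 1e-6).
#' @return H-score in \[0, 400\].
#' @export
#' @examples
#' h_score(c(10, 20, 30, 25, 15))  # 215
h_score <- function(percentages) {
  check_number(percentages, "percentages", lower = 0, upper = 100, len = 5L)
  if (abs(sum(percentages) - 100) > 1e-6) {
    stop_invalid("percentages must sum to 100")
  }
  sum(percentages * 0:4)
}

#' Classify an N-glycan composition into a glycoform category
#'
#' Intact-glycopeptide glycan compositions are binned into five categories by
#' monosaccharide content. Sialic-acid content is NeuAc + NeuGc. Precedence:
#' fuco-sialylated (both fucose and sialic acid) is checked before the
#' single-feature sialylated / fucosylated classes; oligomannose requires the
#' chitobiose core (HexNAc = 2) and at least `oligomannose_min_hex` hexoses;
#' anything else is neutral.
#'
#' @param hexnac,hex,fuc,neuac,neugc non-negative monosaccharide counts.
#' @param oligomannose_min_hex minimum Hex count for the oligomannose class
#'   (default 5, the Man5 convention).
#' @return one of `"fuco-sialylated"`, `"sialylated"`, `"fucosylated"`,
#'   `"oligomannose"`, `"neutral"`.
#' @export
#' @examples
#' classify_glycoform(hexnac = 2, hex = 9)                       # oligomannose
#' classify_glycoform(hexnac = 4, hex = 5, fuc = 1, neuac = 2)   # fuco-sialylated
#' classify_glycoform(hexnac = 4, hex = 5)                       # neutral
classify_glycoform <- function(hexnac, hex = 0, fuc = 0, neuac = 0, neugc = 0,
                               oligomannose_min_hex = 5) {
  for (nm in c("hexnac", "hex", "fuc", "neuac", "neugc")) {
    check_number(get(nm), nm, lower = 0, integer = TRUE)
  }
  if (hexnac + hex + fuc + neuac + neugc == 0) {
    stop_invalid("glycan composition is all zero")
  }
  sialic <- neuac + neugc
  if (fuc > 0 && sialic > 0) return("fuco-sialylated")
  if (sialic > 0) return("sialylated")
  if (fuc > 0) return("fucosylated")
  if (hexnac == 2 && hex >= oligomannose_min_hex) return("oligomannose")
  "neutral"
}
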