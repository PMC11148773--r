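#' Read a SEG-like copy-number segment table
#'
#' Expects a TSV with header `sample, chrom, start, end, copy_number` and
#' 1-based inclusive coordinates; `chr` prefixes are tolerated and stripped.
#' Rows with `end < start` or overlapping segments within a sample and
#' chromosome are rejected with the offending line number.
#'
#' @param path file path.
#' @return data.frame with the five columns, validated and sorted.
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample", "chrom", "start", "end", "copy_number")
  if (!all(req %in% names(df))) {
    stop_invalid(sprintf("%s: expected columns %s", path,
                         paste(req, collapse = ", ")),
                 class = "gicoreg_parse_error")
  }
  df$chrom <- sub("^chr", "", as.character(df$chrom))
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- which(df$end < df$start)
  if (length(bad) > 0L) {
    stop_invalid(sprintf("%s line %d: end < start", path, line[bad[1L]]),
                 class = "gicoreg_parse_error")
  }
  ord <- order(df$sample, df$chrom, df$start)
  for (key in unique(paste(df$sample, df$chrom))) {
    idx <- ord[paste(df$sample, df$chrom)[ord] == key]
    if (length(idx) > 1L) {
      ov <- which(df$start[idx][-1L] <= df$end[idx][-length(idx)])
      if (length(ov) > 0L) {
        stop_invalid(sprintf("%s line %d: segment overlaps previous segment",
                             path, line[idx[ov[1L] + 1L]]),
                     class = "gicoreg_parse_error")
      }
    }
  }
  df <- df[ord, req, drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_segments
#' @param segments data.frame as returned by [read_segments()] or
#'   [gen_segments()].
#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write an expression matrix TSV
#'
#' First column = feature id, remaining columns = samples; empty cells and
#' `NA` are missing values. Duplicate feature ids are rejected.
#'
#' @param path file path.
#' @return numeric matrix, features x samples.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop_invalid(sprintf("%s: no sample columns", path),
                                  class = "gicoreg_parse_error")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop_invalid(sprintf("%s: duplicate feature id '%s'", path,
                         ids[duplicated(ids)][1L]),
                 class = "gicoreg_parse_error")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    suppressWarnings(storage.mode(m) <- "double")
  }
  rownames(m) <- ids
  m
}

#' @rdname read_matrix
#' @param matrix numeric matrix with feature rownames and sample colnames.
#' @param feature_col name of the feature id column on disk.
#' @export
write_matrix <- function(matrix, path, feature_col = "feature") {
  # %.17g preserves doubles exactly across a write/read round trip
  chr <- apply(matrix, 2L, function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x)))
  df <- data.frame(rownames(matrix), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- feature_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table TSV
#'
#' Requires columns `sample`, `time`, `event`; other covariate columns
#' (age, gender, race, stage, purity, ...) pass through.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample", "time", "event")
  if (!all(req %in% names(df))) {
    stop_invalid(sprintf("%s: expected columns %s", path,
                         paste(req, collapse = ", ")),
                 class = "gicoreg_parse_error")
  }
  df
}

#' Read a kinase-substrate relation table TSV
#'
#' OmniPath-export-style columns: `kinase` (or `enzyme`), `substrate`,
#' `residue`, `position`, optional `modification`.
#'
#' @param path file path.
#' @return data.frame with canonical column names.
#' @export
read_ks_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if ("enzyme" %in% names(df) && !("kinase" %in% names(df))) {
    names(df)[names(df) == "enzyme"] <- "kinase"
  }
  req <- c("kinase", "substrate", "residue", "position")
  if (!all(req %in% names(df))) {
    stop_invalid(sprintf("%s: expected columns %s", path,
                         paste(req, collapse = ", ")),
                 class = "gicoreg_parse_error")
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
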