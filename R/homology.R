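# Import of precomputed profile-HMM homology hits (nhmmer tabular output).
# The pipeline itself never runs the homology search; any external run in
# the standard tblout dialect can feed the downstream screening steps.

#' Parse nhmmer tblout homology hits into SINE candidates
#'
#' Reads the whitespace-separated tabular output dialect of nhmmer
#' (comment lines start with \code{#}). Hits with E-value at or below
#' \code{e_cutoff} become candidates with \code{source = "homology"}.
#' Coordinates are converted from the 1-based inclusive \code{alifrom}/
#' \code{ali to} convention (reversed on the minus strand) to internal
#' 0-based half-open forward-strand intervals. Overlapping hits from
#' different family models are merged when they overlap reciprocally by
#' more than \code{merge_overlap}, keeping the lowest E-value.
#'
#' @param path tblout file.
#' @param e_cutoff maximum E-value (default 1.0).
#' @param config a \code{\link{sine_config}} (supplies \code{merge_overlap}).
#' @return A \code{sine_candidates} data.frame with status \code{"raw"}.
#' @export
parse_hmm_hits <- function(path, e_cutoff = 1.0, config = sine_config()) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) return(empty_candidates())
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 13L)
      stop("malformed tblout row at line ", lineno[i], ": expected >= 13 columns")
    ali_from <- suppressWarnings(as.integer(f[7]))
    ali_to <- suppressWarnings(as.integer(f[8]))
    ev <- suppressWarnings(as.numeric(f[13]))
    if (is.na(ali_from) || is.na(ali_to) || is.na(ev) || ev <= 0)
      stop("malformed tblout row at line ", lineno[i],
           ": bad coordinates or E-value")
    strand <- f[12]
    if (!strand %in% c("+", "-"))
      strand <- if (ali_from > ali_to) "-" else "+"
    data.frame(seqid = f[1], model = f[3],
               start = min(ali_from, ali_to) - 1L,
               end = max(ali_from, ali_to),
               strand = strand, evalue = ev, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[df$evalue <= e_cutoff, , drop = FALSE]
  if (!nrow(df)) return(empty_candidates())
  df <- merge_reciprocal(df, config$merge_overlap)
  df <- df[order(df$seqid, df$start, df$end), , drop = FALSE]
  out <- data.frame(
    id = sprintf("hm_%04d", seq_len(nrow(df))),
    seqid = df$seqid, start = df$start, end = df$end, strand = df$strand,
    source = "homology", status = "raw", filter_reason = NA_character_,
    stringsAsFactors = FALSE)
  new_candidates(out)
}

merge_reciprocal <- function(df, frac) {
  # collapse hits overlapping > frac reciprocally, keeping the lowest E-value
  df <- df[order(df$seqid, df$evalue), , drop = FALSE]
  kept <- df[0, , drop = FALSE]
  for (i in seq_len(nrow(df))) {
    merged <- FALSE
    if (nrow(kept)) {
      same <- kept$seqid == df$seqid[i]
      if (any(same)) {
        ov <- pmin(kept$end[same], df$end[i]) - pmax(kept$start[same], df$start[i])
        w1 <- kept$end[same] - kept$start[same]
        w2 <- df$end[i] - df$start[i]
        merged <- any(ov > frac * w1 & ov > frac * w2)
      }
    }
    if (!merged) kept <- rbind(kept, df[i, , drop = FALSE])
  }
  kept
}
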