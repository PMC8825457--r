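# Candidate tables are plain data.frames (class "sine_candidates") with one
# row per putative element. All coordinates are forward-strand, 0-based,
# half-open, regardless of the candidate's strand.

CANDIDATE_COLS <- c("id", "seqid", "start", "end", "strand", "source",
                    "status", "filter_reason",
                    "box_a_start", "box_a_end", "box_b_start", "box_b_end",
                    "spacing", "tail_start", "tail_end", "tail_kind",
                    "tsd_len", "tsd_mismatches",
                    "tsd_left_start", "tsd_left_end",
                    "tsd_right_start", "tsd_right_end")

empty_candidates <- function() {
  df <- data.frame(
    id = character(0), seqid = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    source = character(0), status = character(0), filter_reason = character(0),
    box_a_start = integer(0), box_a_end = integer(0),
    box_b_start = integer(0), box_b_end = integer(0), spacing = integer(0),
    tail_start = integer(0), tail_end = integer(0), tail_kind = character(0),
    tsd_len = integer(0), tsd_mismatches = integer(0),
    tsd_left_start = integer(0), tsd_left_end = integer(0),
    tsd_right_start = integer(0), tsd_right_end = integer(0),
    stringsAsFactors = FALSE)
  class(df) <- c("sine_candidates", "data.frame")
  df
}

new_candidates <- function(df) {
  out <- empty_candidates()
  if (nrow(df) == 0L) return(out)
  for (col in CANDIDATE_COLS) if (is.null(df[[col]])) df[[col]] <- out[[col]][NA][seq_len(nrow(df))]
  df <- df[, CANDIDATE_COLS]
  if (is.null(df$id) || anyNA(df$id))
    df$id <- sprintf("cand_%04d", seq_len(nrow(df)))
  class(df) <- c("sine_candidates", "data.frame")
  rownames(df) <- NULL
  df
}

validate_intervals <- function(df, genome) {
  if (nrow(df) == 0L) return(invisible(TRUE))
  lens <- genome$lengths[df$seqid]
  ok <- !is.na(lens) & df$start >= 0L & df$start < df$end & df$end <= lens
  if (!all(ok)) stop("interval out of bounds for sequence(s): ",
                     paste(unique(df$seqid[!ok]), collapse = ", "))
  invisible(TRUE)
}

candidate_seq <- function(genome, cand_row) {
  genome_subseq(genome, cand_row$seqid, cand_row$start, cand_row$end,
                cand_row$strand)
}

#' @export
print.sine_candidates <- function(x, ...) {
  cat("sine_candidates:", nrow(x), "candidate(s)\n")
  if (nrow(x)) print(table(status = x$status))
  invisible(x)
}
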