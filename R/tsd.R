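# Target site duplication (TSD) search. A genuine retrotransposition event
# duplicates a short target site on both flanks of the insertion, so an
# exact-or-nearly-exact duplicated pair in the two flanking windows is
# strong evidence for a real element. Windows are asymmetric because tail
# length varies: by default 30 nt upstream of the 5' terminus and 50 nt
# downstream of the 3' terminus.

best_tsd_pair <- function(up, down, config) {
  # exhaustive over all (position, position, length) pairs within bounds;
  # returns the highest-scoring pair (score = matches - penalty * mismatches,
  # mismatches <= budget) or NULL. Ties: longer, then leftmost up, then
  # leftmost down.
  nu <- nchar(up); nd <- nchar(down)
  uch <- strsplit(up, "", fixed = TRUE)[[1]]
  dch <- strsplit(down, "", fixed = TRUE)[[1]]
  best <- NULL
  for (l in seq(config$tsd_max_len, config$tsd_min_len)) {
    if (l > nu || l > nd) next
    us <- seq_len(nu - l + 1L)
    ds <- seq_len(nd - l + 1L)
    M <- matrix(0L, length(us), length(ds))
    for (j in seq_len(l))
      M <- M + outer(uch[us + j - 1L], dch[ds + j - 1L], "!=")
    ok <- which(M <= config$tsd_max_mismatch, arr.ind = TRUE)
    if (!nrow(ok)) next
    mism <- M[ok]
    score <- (l - mism) - config$tsd_mismatch_penalty * mism
    ord <- order(-score, ok[, 1L], ok[, 2L])
    top <- ord[1L]
    cand <- list(up_start = us[ok[top, 1L]] - 1L, down_start = ds[ok[top, 2L]] - 1L,
                 length = l, mismatches = mism[top], score = score[top])
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  best
}

#' Find the target site duplication flanking a candidate
#'
#' Enumerates all substring pairs (one per flanking window) with length in
#' \code{[tsd_min_len, tsd_max_len]} and at most \code{tsd_max_mismatch}
#' mismatches, and returns the highest-scoring pair (score = matches minus
#' \code{tsd_mismatch_penalty} per mismatch). Windows are clipped at
#' sequence ends. For minus-strand candidates the 30/50 window sizes attach
#' to the element's 5'/3' termini, i.e. they are mirrored in forward
#' coordinates.
#'
#' @param candidate one-row \code{sine_candidates} data.frame (or list with
#'   \code{seqid, start, end, strand}).
#' @param genome a \code{sine_genome}.
#' @param config a \code{\link{sine_config}}.
#' @return \code{NULL}, or a list with forward-strand 0-based half-open
#'   fields \code{left_start, left_end, right_start, right_end} plus
#'   \code{length, mismatches, score}.
#' @export
find_tsd <- function(candidate, genome, config = sine_config()) {
  n <- seq_len0(genome, candidate$seqid)
  if (candidate$strand == "+") {
    wleft <- config$tsd_up_window; wright <- config$tsd_down_window
  } else {
    wleft <- config$tsd_down_window; wright <- config$tsd_up_window
  }
  ls <- max(0L, candidate$start - wleft)
  re <- min(n, candidate$end + wright)
  if (candidate$start - ls < config$tsd_min_len ||
      re - candidate$end < config$tsd_min_len) return(NULL)
  up <- genome_subseq(genome, candidate$seqid, ls, candidate$start)
  down <- genome_subseq(genome, candidate$seqid, candidate$end, re)
  hit <- best_tsd_pair(up, down, config)
  if (is.null(hit)) return(NULL)
  list(left_start = ls + hit$up_start,
       left_end = ls + hit$up_start + hit$length,
       right_start = candidate$end + hit$down_start,
       right_end = candidate$end + hit$down_start + hit$length,
       length = hit$length, mismatches = hit$mismatches, score = hit$score)
}

#' Verify candidates by TSD presence
#'
#' Candidates without a qualifying TSD are removed
#' (\code{filter_reason = "no_tsd"}); kept candidates get status
#' \code{"tsd_verified"} and their boundaries are refined to the inner edges
#' of the two TSD copies.
#'
#' @param candidates \code{sine_candidates} with raw status.
#' @param genome a \code{sine_genome}.
#' @param config a \code{\link{sine_config}}.
#' @return list with elements \code{kept} and \code{removed}.
#' @export
verify_candidates <- function(candidates, genome, config = sine_config()) {
  if (nrow(candidates) == 0L)
    return(list(kept = empty_candidates(), removed = empty_candidates()))
  keep <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    hit <- find_tsd(candidates[i, ], genome, config)
    if (is.null(hit)) next
    keep[i] <- TRUE
    candidates$start[i] <- hit$left_end
    candidates$end[i] <- hit$right_start
    candidates$status[i] <- "tsd_verified"
    candidates$tsd_len[i] <- hit$length
    candidates$tsd_mismatches[i] <- hit$mismatches
    candidates$tsd_left_start[i] <- hit$left_start
    candidates$tsd_left_end[i] <- hit$left_end
    candidates$tsd_right_start[i] <- hit$right_start
    candidates$tsd_right_end[i] <- hit$right_end
  }
  removed <- candidates[!keep, , drop = FALSE]
  if (nrow(removed)) {
    removed$status <- "filtered_out"
    removed$filter_reason <- "no_tsd"
  }
  kept <- candidates[keep, , drop = FALSE]
  # distinct box pairings of one element refine to the same TSD-delimited
  # interval; collapse them
  kept <- kept[!duplicated(paste(kept$seqid, kept$start, kept$end,
                                 kept$strand)), , drop = FALSE]
  list(kept = kept, removed = removed)
}
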