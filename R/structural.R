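# De novo structural SINE candidate discovery: RNA-polymerase-III internal
# promoter motifs (box A "[GA][CGA]TGG", box B "CTTA[AG]A"), 25-50 nt
# spacing, and a downstream poly-A / poly-T / low-complexity tail 20-500 nt
# past box B. Matching is exact against the degenerate patterns; the
# patterns themselves carry the degeneracy.

BOX_A_PATTERN <- "[GA][CGA]TGG"
BOX_A_LEN <- 5L
BOX_B_PATTERN <- "CTTA[AG]A"
BOX_B_LEN <- 6L

pattern_starts <- function(seq, pattern) {
  # overlapping matches via lookahead; returns 0-based starts
  m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  as.integer(m) - 1L
}

#' Find box A / box B promoter motif pairs
#'
#' Returns every pair of box A and box B occurrences whose spacing (bases
#' strictly between the motifs) lies in \code{[min_spacing, max_spacing]}.
#'
#' @param seq DNA character scalar (upper case).
#' @param config a \code{\link{sine_config}}.
#' @param window optional 0-based half-open \code{c(start, end)} restricting
#'   the box A search (box B and spacing may extend past it).
#' @return data.frame with 0-based half-open columns \code{box_a_start,
#'   box_a_end, box_b_start, box_b_end, spacing}.
#' @export
find_head_boxes <- function(seq, config = sine_config(), window = NULL) {
  a <- pattern_starts(seq, BOX_A_PATTERN)
  b <- pattern_starts(seq, BOX_B_PATTERN)
  if (!is.null(window)) a <- a[a >= window[1] & a + BOX_A_LEN <= window[2]]
  out <- data.frame(box_a_start = integer(0), box_a_end = integer(0),
                    box_b_start = integer(0), box_b_end = integer(0),
                    spacing = integer(0))
  if (!length(a) || !length(b)) return(out)
  pairs <- expand.grid(a = a, b = b)
  pairs$spacing <- pairs$b - (pairs$a + BOX_A_LEN)
  keep <- pairs$spacing >= config$min_spacing & pairs$spacing <= config$max_spacing
  pairs <- pairs[keep, , drop = FALSE]
  data.frame(box_a_start = pairs$a, box_a_end = pairs$a + BOX_A_LEN,
             box_b_start = pairs$b, box_b_end = pairs$b + BOX_B_LEN,
             spacing = pairs$spacing, row.names = NULL)
}

qualifying_run_at <- function(chars, p, n, config) {
  # poly-A / poly-T run of >= tail_min_run with >= tail_min_purity majority
  # base starting at 0-based p, else a low-complexity window (dinucleotide
  # entropy < lc_max_entropy over lc_window). Only true starts qualify: a
  # run or low-complexity region that began before p is not reported at p.
  # Returns NULL or list(start, end, kind, purity).
  r <- config$tail_min_run
  if (p + r <= n) {
    w <- chars[(p + 1L):(p + r)]
    for (base in c("A", "T")) {
      cnt <- sum(w == base)
      if (cnt / r >= config$tail_min_purity && w[1] == base &&
          (p == 0L || chars[p] != base)) {
        q <- p + r
        nmatch <- cnt
        miss_run <- 0L
        while (q < n) {
          is_base <- chars[q + 1L] == base
          nxt <- nmatch + is_base
          if (nxt / (q - p + 1L) < config$tail_min_purity) break
          # more than 2 consecutive foreign bases ends the run even when
          # the overall purity budget would absorb them
          miss_run <- if (is_base) 0L else miss_run + 1L
          if (miss_run > 2L) break
          nmatch <- nxt
          q <- q + 1L
        }
        # trim trailing non-majority bases
        while (q > p + r && chars[q] != base) q <- q - 1L
        return(list(start = p, end = q, kind = if (base == "A") "polyA" else "polyT",
                    purity = sum(chars[(p + 1L):q] == base) / (q - p)))
      }
    }
  }
  wlen <- config$lc_window
  if (p + wlen <= n) {
    s <- paste(chars[(p + 1L):(p + wlen)], collapse = "")
    prev_lc <- p > 0L && p - 1L + wlen <= n &&
      dinucleotide_entropy(paste(chars[p:(p - 1L + wlen)],
                                 collapse = "")) < config$lc_max_entropy
    if (!prev_lc && dinucleotide_entropy(s) < config$lc_max_entropy) {
      q <- p
      while (q + wlen < n &&
             dinucleotide_entropy(paste(chars[(q + 2L):(q + 1L + wlen)],
                                        collapse = "")) < config$lc_max_entropy)
        q <- q + 1L
      return(list(start = p, end = q + wlen, kind = "low_complexity",
                  purity = NA_real_))
    }
  }
  NULL
}

#' Detect the 3' tail downstream of box B
#'
#' Scans positions \code{search_from + tail_min_offset} to
#' \code{search_from + tail_max_offset} (0-based) for the nearest qualifying
#' tail: a poly-A or poly-T run (length >= \code{tail_min_run}, purity >=
#' \code{tail_min_purity}) or a low-complexity window (dinucleotide Shannon
#' entropy below \code{lc_max_entropy} bits over \code{lc_window} bases).
#'
#' @param seq DNA character scalar.
#' @param search_from 0-based position of the end of box B (exclusive end).
#' @param config a \code{\link{sine_config}}.
#' @details When a low-complexity window at position p merely leads into a
#' poly-A/T run starting within that window, the poly run is reported
#' instead: the run is the more specific call and its end (trimmed back to
#' the majority base) does not spill over into the flanking sequence.
#' @return \code{NULL}, or list with \code{start, end} (0-based half-open),
#'   \code{kind}, \code{purity}.
#' @export
detect_tail <- function(seq, search_from, config = sine_config()) {
  n <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  lo <- search_from + config$tail_min_offset
  hi <- min(search_from + config$tail_max_offset, n - config$tail_min_run)
  if (lo > hi) return(NULL)
  for (p in lo:hi) {
    hit <- qualifying_run_at(chars, p, n, config)
    if (is.null(hit)) next
    if (hit$kind == "low_complexity") {
      for (p2 in (p + 1L):min(p + config$lc_window, hi)) {
        h2 <- qualifying_run_at(chars, p2, n, config)
        if (!is.null(h2) && h2$kind != "low_complexity") return(h2)
      }
    }
    return(hit)
  }
  NULL
}

scan_one_strand <- function(seqchar, seqid, strand, rec_len, config) {
  frag <- config$fragment
  ov <- config$overlap
  n <- nchar(seqchar)
  step <- max(frag - ov, 1L)
  starts <- if (is.finite(frag) && n > frag) seq(0L, n - 1L, by = step) else 0L
  rows <- list()
  seen <- character(0)
  for (f0 in starts) {
    f1 <- min(f0 + frag, n)
    fragseq <- substr(seqchar, f0 + 1L, f1)
    pairs <- find_head_boxes(fragseq, config)
    if (!nrow(pairs)) next
    pairs$box_a_start <- pairs$box_a_start + f0
    pairs$box_a_end <- pairs$box_a_end + f0
    pairs$box_b_start <- pairs$box_b_start + f0
    pairs$box_b_end <- pairs$box_b_end + f0
    for (i in seq_len(nrow(pairs))) {
      key0 <- paste(pairs$box_a_start[i], pairs$box_b_start[i])
      if (key0 %in% seen) next
      seen <- c(seen, key0)
      tail <- detect_tail(seqchar, pairs$box_b_end[i], config)
      if (is.null(tail)) next
      len <- tail$end - pairs$box_a_start[i]
      if (len < config$sine_min_len || len > config$sine_max_len) next
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = seqid, strand = strand,
        s_start = pairs$box_a_start[i], s_end = tail$end,
        box_a_start = pairs$box_a_start[i], box_a_end = pairs$box_a_end[i],
        box_b_start = pairs$box_b_start[i], box_b_end = pairs$box_b_end[i],
        spacing = pairs$spacing[i],
        tail_start = tail$start, tail_end = tail$end,
        tail_kind = tail$kind, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  df <- do.call(rbind, rows)
  if (strand == "-") {
    # map scan coordinates (on the reverse complement) back to forward strand
    flip <- function(st, en) list(start = rec_len - en, end = rec_len - st)
    iv <- flip(df$s_start, df$s_end)
    ba <- flip(df$box_a_start, df$box_a_end)
    bb <- flip(df$box_b_start, df$box_b_end)
    tl <- flip(df$tail_start, df$tail_end)
    df$s_start <- iv$start; df$s_end <- iv$end
    df$box_a_start <- ba$start; df$box_a_end <- ba$end
    df$box_b_start <- bb$start; df$box_b_end <- bb$end
    df$tail_start <- tl$start; df$tail_end <- tl$end
  }
  df
}

#' Scan a genome for structural SINE candidates
#'
#' Records are sliced into \code{fragment}-sized pieces with \code{overlap}
#' overlap for the motif-pair search (tails are sought in the full record so
#' fragmentation never truncates an element); both strands are scanned and
#' minus-strand hits are reported in forward-strand coordinates. Duplicate
#' intervals from overlapping fragments are removed; candidates sharing a
#' tail keep the box pair whose spacing is closest to the centre of the
#' allowed range (ties to the leftmost start). The candidate 5' boundary is
#' provisionally placed at box A; TSD verification later refines both
#' boundaries.
#'
#' @param genome a \code{sine_genome}.
#' @param config a \code{\link{sine_config}}.
#' @return A \code{sine_candidates} data.frame with status \code{"raw"}.
#' @export
scan_structural_candidates <- function(genome, config = sine_config()) {
  all <- list()
  for (sid in seq_ids(genome)) {
    fwd <- genome$seqs[[sid]]
    n <- nchar(fwd)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else revcomp(fwd)
      df <- scan_one_strand(s, sid, strand, n, config)
      if (!is.null(df)) all[[length(all) + 1L]] <- df
    }
  }
  if (!length(all)) return(empty_candidates())
  df <- do.call(rbind, all)
  # deduplicate identical intervals (fragment-overlap duplicates); distinct
  # box pairs sharing a tail are all kept here -- TSD verification refines
  # their boundaries and collapses the survivors to one interval, which is
  # more robust than guessing the true box pair from spacing alone
  key <- paste(df$seqid, df$s_start, df$s_end, df$strand)
  df <- df[!duplicated(key), , drop = FALSE]
  df <- df[order(df$seqid, df$s_start, df$s_end, df$strand), , drop = FALSE]
  out <- data.frame(
    id = sprintf("st_%04d", seq_len(nrow(df))),
    seqid = df$seqid, start = df$s_start, end = df$s_end, strand = df$strand,
    source = "structural", status = "raw", filter_reason = NA_character_,
    box_a_start = df$box_a_start, box_a_end = df$box_a_end,
    box_b_start = df$box_b_start, box_b_end = df$box_b_end,
    spacing = df$spacing,
    tail_start = df$tail_start, tail_end = df$tail_end,
    tail_kind = df$tail_kind,
    tsd_len = NA_integer_, tsd_mismatches = NA_integer_,
    tsd_left_start = NA_integer_, tsd_left_end = NA_integer_,
    tsd_right_start = NA_integer_, tsd_right_end = NA_integer_,
    stringsAsFactors = FALSE)
  new_candidates(out)
}
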