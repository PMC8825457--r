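# False-positive filters applied after profile screening:
# superfamily classification with ncRNA-gene exclusion, tandem-repeat
# fraction, and terminal inverted repeat (MITE) detection.

#' Read a labelled ncRNA reference set
#'
#' FASTA headers must carry a \code{type=tRNA|7SL|5S} tag in the
#' description, e.g. \code{>trna1 type=tRNA}.
#'
#' @param path FASTA file.
#' @return data.frame with columns \code{id, type, sequence}.
#' @export
read_ncrna_refs <- function(path) {
  set <- Biostrings::readBStringSet(path)
  hdr <- names(set)
  id <- sub("\\s.*$", "", hdr)
  type <- rep(NA_character_, length(hdr))
  has <- grepl("type=(tRNA|7SL|5S)", hdr)
  type[has] <- sub(".*type=(tRNA|7SL|5S).*", "\\1", hdr[has])
  data.frame(id = id, type = type, sequence = toupper(as.character(set)),
             stringsAsFactors = FALSE)
}

superfamily_label <- function(type) {
  switch(type, tRNA = "tRNA", `7SL` = "7SL_RNA", `5S` = "5S_rRNA", "unknown")
}

#' Classify the superfamily of a candidate and screen out ncRNA genes
#'
#' The 5' half of the candidate (the head, which derives from an
#' RNA-polymerase-III transcript) is aligned locally against each labelled
#' reference; the best hit passing the reporting threshold gives the
#' superfamily label. Independently, if the full candidate is nearly
#' identical to a reference -- surrogate significance at or below
#' \code{exclusion_evalue} with the alignment covering at least
#' \code{exclusion_coverage} of the candidate length -- the candidate is
#' judged to be an ncRNA gene itself and is excluded.
#'
#' @param seq candidate sequence (element orientation), character scalar.
#' @param refs data.frame from \code{\link{read_ncrna_refs}}.
#' @param config a \code{\link{sine_config}}.
#' @param report_evalue reporting threshold for labelling (default 1e-3).
#' @return list: \code{label}, \code{best_identity}, \code{best_evalue},
#'   \code{keep}.
#' @export
classify_superfamily <- function(seq, refs, config = sine_config(),
                                 report_evalue = 1e-3) {
  if (is.null(refs) || nrow(refs) == 0L || anyNA(refs$type)) {
    warning("missing or unlabelled ncRNA reference set; classification skipped")
    return(list(label = "unknown", best_identity = NA_real_,
                best_evalue = NA_real_, keep = TRUE))
  }
  n <- nchar(seq)
  head_seq <- substr(seq, 1L, max(1L, floor(n / 2)))
  total_ref <- sum(nchar(refs$sequence))
  best <- list(label = "unknown", best_identity = NA_real_,
               best_evalue = NA_real_)
  keep <- TRUE
  best_score <- -Inf
  for (i in seq_len(nrow(refs))) {
    h <- align_pair(head_seq, refs$sequence[i], type = "local", config = config)
    ev <- ka_evalue(h$score, nchar(head_seq), total_ref)
    if (ev <= report_evalue && h$score > best_score) {
      best_score <- h$score
      best <- list(label = superfamily_label(refs$type[i]),
                   best_identity = h$identity, best_evalue = ev)
    }
    f <- align_pair(seq, refs$sequence[i], type = "local", config = config)
    fev <- ka_evalue(f$score, n, total_ref)
    cov <- (f$q_end - f$q_start) / n
    if (fev <= config$exclusion_evalue && cov >= config$exclusion_coverage)
      keep <- FALSE
  }
  c(best, list(keep = keep))
}

#' Fraction of a sequence covered by short-period tandem arrays
#'
#' Internal tandem detector: for each period p in 1..\code{tandem_max_period}
#' the sequence is compared against itself shifted by p; any window of
#' \code{max((tandem_min_copies - 1) * p, tandem_min_span)} consecutive
#' comparisons with at least \code{tandem_min_identity} matches marks the
#' spanned positions (window plus one period) as tandem. The fraction is
#' the union coverage over all periods.
#'
#' @param seq DNA character scalar.
#' @param config a \code{\link{sine_config}}.
#' @return fraction in [0, 1].
#' @export
tandem_fraction <- function(seq, config = sine_config()) {
  n <- nchar(seq)
  if (n < 1L) stop("empty sequence")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  covered <- logical(n)
  for (p in seq_len(config$tandem_max_period)) {
    if (n <= p) break
    m <- ch[seq_len(n - p)] == ch[(p + 1L):n]
    w <- max((config$tandem_min_copies - 1L) * p, config$tandem_min_span)
    if (length(m) < w) next
    cs <- c(0L, cumsum(m))
    wins <- which((cs[(w + 1L):length(cs)] - cs[seq_len(length(cs) - w)]) >=
                    config$tandem_min_identity * w)
    for (j in wins) covered[j:min(n, j + w - 1L + p)] <- TRUE
  }
  mean(covered)
}

#' Find a terminal inverted repeat within the element's terminal zones
#'
#' Searches the two terminal zones (\code{tir_zone} nt inward from the
#' refined 5' and 3' boundaries) for the longest pair of
#' reverse-complementary arms of at least \code{tir_min_arm} nt with at
#' most \code{tir_max_mismatch} mismatches. SINEs lack TIRs, so a hit marks
#' the candidate as a putative MITE.
#'
#' @param candidate one-row \code{sine_candidates} with refined boundaries.
#' @param genome a \code{sine_genome}.
#' @param config a \code{\link{sine_config}}.
#' @return \code{NULL}, or list with genome-forward 0-based half-open
#'   \code{left_start, left_end, right_start, right_end} plus
#'   \code{arm_length, mismatches}.
#' @export
find_tir <- function(candidate, genome, config = sine_config()) {
  s <- candidate$start; e <- candidate$end
  zl_end <- min(e, s + config$tir_zone)
  zr_start <- max(s, e - config$tir_zone)
  left <- genome_subseq(genome, candidate$seqid, s, zl_end)
  right <- genome_subseq(genome, candidate$seqid, zr_start, e)
  hit <- best_tir_pair(left, right, config)
  if (is.null(hit)) return(NULL)
  list(left_start = s + hit$l_start, left_end = s + hit$l_start + hit$arm,
       right_start = zr_start + hit$r_start,
       right_end = zr_start + hit$r_start + hit$arm,
       arm_length = hit$arm, mismatches = hit$mismatches)
}

best_tir_pair <- function(left, right, config) {
  # longest reverse-complementary arm pair within the mismatch budget;
  # scanned from the longest arm down, ties to leftmost positions
  nl <- nchar(left); nr <- nchar(right)
  if (nl < config$tir_min_arm || nr < config$tir_min_arm) return(NULL)
  lch <- strsplit(left, "", fixed = TRUE)[[1]]
  rch <- strsplit(revcomp(right), "", fixed = TRUE)[[1]]
  # rch[i] corresponds to right-zone position nr - i (0-based start nr - i)
  for (l in seq(min(nl, nr), config$tir_min_arm)) {
    ls <- seq_len(nl - l + 1L)
    rs <- seq_len(nr - l + 1L)
    M <- matrix(0L, length(ls), length(rs))
    for (j in seq_len(l))
      M <- M + outer(lch[ls + j - 1L], rch[rs + j - 1L], "!=")
    ok <- which(M <= config$tir_max_mismatch, arr.ind = TRUE)
    if (nrow(ok)) {
      ok <- ok[order(ok[, 1L], ok[, 2L]), , drop = FALSE]
      li <- ls[ok[1L, 1L]] - 1L        # 0-based in left zone
      ri_rc <- rs[ok[1L, 2L]] - 1L     # 0-based in revcomp(right)
      ri <- nr - (ri_rc + l)           # 0-based in right zone
      return(list(l_start = li, r_start = ri, arm = l,
                  mismatches = M[ok[1L, 1L], ok[1L, 2L]]))
    }
  }
  NULL
}
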