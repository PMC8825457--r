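# Internal local alignment machinery: exact k-mer seeding on diagonals,
# followed by banded local alignment of the query against a small subject
# window (Biostrings pairwiseAlignment does the extension). Significance is
# a Karlin-Altschul-style surrogate E = K * m * n * exp(-lambda * S) with
# the ungapped +1/-1 uniform-composition parameters (lambda = ln 3,
# K = 0.333). Ambiguity codes other than ACGT always score as mismatches.

ALPHABET15 <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
                "B", "D", "H", "V")

sub_matrix <- function(match, mismatch) {
  m <- matrix(mismatch, 15L, 15L, dimnames = list(ALPHABET15, ALPHABET15))
  diag(m)[1:4] <- match
  m
}

ka_evalue <- function(score, m, n, lambda = log(3), K = 0.333) {
  K * m * n * exp(-lambda * score)
}

seed_clusters <- function(qs, subject_dna, k, band = 30L) {
  L <- nchar(qs)
  if (L < k) return(list())
  starts <- seq_len(L - k + 1L)
  kmers <- substring(qs, starts, starts + k - 1L)
  ok <- grepl("^[ACGT]+$", kmers)
  if (!any(ok)) return(list())
  uq <- unique(kmers[ok])
  pd <- Biostrings::PDict(uq)
  mi <- Biostrings::matchPDict(pd, subject_dna)
  qpos_by_kmer <- split(starts[ok] - 1L, kmers[ok])
  seeds_q <- integer(0); seeds_s <- integer(0)
  hits <- Biostrings::startIndex(mi)  # list of subject starts per unique kmer
  for (i in seq_along(uq)) {
    sp <- hits[[i]]
    if (is.null(sp) || !length(sp)) next
    qp <- qpos_by_kmer[[uq[i]]]
    grid <- expand.grid(q = qp, s = sp - 1L)
    seeds_q <- c(seeds_q, grid$q)
    seeds_s <- c(seeds_s, grid$s)
  }
  if (!length(seeds_q)) return(list())
  diag <- seeds_s - seeds_q
  ord <- order(diag, seeds_s)
  seeds_q <- seeds_q[ord]; seeds_s <- seeds_s[ord]; diag <- diag[ord]
  # band by diagonal, then split bands where subject positions jump
  newband <- c(TRUE, diff(diag) > band)
  bid <- cumsum(newband)
  clusters <- list()
  for (b in unique(bid)) {
    sel <- which(bid == b)
    sel <- sel[order(seeds_s[sel])]
    brk <- c(TRUE, diff(seeds_s[sel]) > L)
    cid <- cumsum(brk)
    for (cc in unique(cid)) {
      s2 <- sel[cid == cc]
      clusters[[length(clusters) + 1L]] <-
        list(qmin = min(seeds_q[s2]), qmax = max(seeds_q[s2]) + 1L,
             smin = min(seeds_s[s2]), smax = max(seeds_s[s2]) + 1L)
    }
  }
  clusters
}

#' Seeded local alignment of a query against a genome
#'
#' Finds all significant local alignments of \code{query} in the genome
#' (both strands), using exact k-mer seeds grouped on diagonals and local
#' alignment extension within a window around each seed cluster. Hits with
#' surrogate E-value above \code{e_cutoff} or aligned query span below
#' \code{min_len} are dropped; hits overlapping >50% on the subject keep
#' the best score.
#'
#' @param query DNA character scalar.
#' @param genome a \code{sine_genome}.
#' @param config a \code{\link{sine_config}} (scoring and k-mer size).
#' @param e_cutoff significance cutoff.
#' @param min_len minimum aligned query span in nt.
#' @return data.frame: \code{seqid, s_start, s_end, strand, q_start, q_end,
#'   length, identity, score, evalue} (0-based half-open; \code{q_*} on the
#'   original query orientation).
#' @export
find_local_hits <- function(query, genome, config = sine_config(),
                            e_cutoff = config$e_cutoff, min_len = 0) {
  L <- nchar(query)
  total_n <- sum(genome$lengths)
  mat <- sub_matrix(config$match, config$mismatch)
  k <- config$kmer
  out <- list()
  for (sid in seq_ids(genome)) {
    subject_chr <- genome$seqs[[sid]]
    ns <- nchar(subject_chr)
    subject_dna <- Biostrings::DNAString(subject_chr)
    for (strand in c("+", "-")) {
      qs <- if (strand == "+") query else revcomp(query)
      clusters <- seed_clusters(qs, subject_dna, k)
      for (cl in clusters) {
        w0 <- max(0L, cl$smin - cl$qmin - 30L)
        w1 <- min(ns, cl$smax + (L - cl$qmax) + 30L)
        win <- substr(subject_chr, w0 + 1L, w1)
        aln <- Biostrings::pairwiseAlignment(
          pattern = qs, subject = win, type = "local",
          substitutionMatrix = mat,
          gapOpening = config$gap_open, gapExtension = config$gap_ext)
        score <- Biostrings::score(aln)
        ev <- ka_evalue(score, L, total_n)
        if (ev > e_cutoff) next
        p0 <- BiocGenerics::start(Biostrings::pattern(aln))
        p1 <- BiocGenerics::end(Biostrings::pattern(aln))
        s0 <- BiocGenerics::start(Biostrings::subject(aln))
        s1 <- BiocGenerics::end(Biostrings::subject(aln))
        q0 <- p0 - 1L; q1 <- p1
        if (strand == "-") { tmp <- q0; q0 <- L - q1; q1 <- L - tmp }
        span <- p1 - p0 + 1L
        if (span < min_len) next
        out[[length(out) + 1L]] <- data.frame(
          seqid = sid, s_start = w0 + s0 - 1L, s_end = w0 + s1,
          strand = strand, q_start = q0, q_end = q1,
          length = span,
          identity = Biostrings::pid(aln) / 100,
          score = score, evalue = ev, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(seqid = character(0), s_start = integer(0),
                      s_end = integer(0), strand = character(0),
                      q_start = integer(0), q_end = integer(0),
                      length = integer(0), identity = numeric(0),
                      score = numeric(0), evalue = numeric(0),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  dedup_subject_hits(df)
}

dedup_subject_hits <- function(df) {
  df <- df[order(-df$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    if (i == nrow(df)) break
    j <- (i + 1L):nrow(df)
    same <- keep[j] & df$seqid[j] == df$seqid[i] & df$strand[j] == df$strand[i]
    jj <- j[same]
    if (!length(jj)) next
    ov <- pmin(df$s_end[jj], df$s_end[i]) - pmax(df$s_start[jj], df$s_start[i])
    wmin <- pmin(df$s_end[jj] - df$s_start[jj], df$s_end[i] - df$s_start[i])
    keep[jj[ov > 0.5 * wmin]] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$seqid, df$s_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Pairwise alignment of two sequences
#'
#' Thin wrapper over \code{Biostrings::pairwiseAlignment} with the package's
#' scoring conventions (+1 match, -1 mismatch, gap open 2, extend 1 by
#' default; ambiguity codes score as mismatches).
#'
#' @param a,b DNA character scalars (\code{a} is the pattern/query).
#' @param type \code{"local"} or \code{"global"}.
#' @param config a \code{\link{sine_config}}.
#' @return list: \code{score}, \code{nmatch}, \code{identity} (matches over
#'   alignment columns), \code{q_start, q_end, s_start, s_end} (0-based
#'   half-open on \code{a} and \code{b}).
#' @export
align_pair <- function(a, b, type = c("local", "global"),
                       config = sine_config()) {
  type <- match.arg(type)
  mat <- sub_matrix(config$match, config$mismatch)
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = type, substitutionMatrix = mat,
    gapOpening = config$gap_open, gapExtension = config$gap_ext)
  list(score = Biostrings::score(aln),
       nmatch = Biostrings::nmatch(aln),
       identity = Biostrings::pid(aln) / 100,
       q_start = BiocGenerics::start(Biostrings::pattern(aln)) - 1L,
       q_end = BiocGenerics::end(Biostrings::pattern(aln)),
       s_start = BiocGenerics::start(Biostrings::subject(aln)) - 1L,
       s_end = BiocGenerics::end(Biostrings::subject(aln)))
}
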