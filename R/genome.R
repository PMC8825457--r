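#' @importFrom Biostrings DNAStringSet readBStringSet writeXStringSet
#'   reverseComplement pairwiseAlignment nmatch matchPDict PDict DNAString
#' @importFrom IRanges IRanges reduce width start end findOverlaps
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<-
NULL

IUPAC_OK <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V")

#' Construct a genome object from in-memory sequences
#'
#' Internal coordinates are 0-based half-open everywhere in this package;
#' conversions to 1-based conventions happen only at format boundaries.
#'
#' @param seqs named character vector of DNA sequences (IUPAC letters; case
#'   is preserved as a soft-mask flag, residues are stored upper-cased).
#' @return An object of class \code{"sine_genome"}: fields \code{seqs}
#'   (upper-case character vector), \code{softmask} (named list of
#'   \code{IRanges} of soft-masked runs, 1-based as IRanges requires), and
#'   \code{lengths}.
#' @export
sine_genome <- function(seqs) {
  if (is.null(names(seqs)) || any(names(seqs) == "") || anyDuplicated(names(seqs)))
    stop("sequences must have unique non-empty ids")
  softmask <- lapply(seqs, lowercase_runs)
  up <- toupper(seqs)
  bad <- vapply(up, function(s) {
    ch <- unique(strsplit(s, "", fixed = TRUE)[[1]])
    any(!ch %in% IUPAC_OK)
  }, logical(1))
  if (any(bad))
    stop("non-IUPAC residues in sequence(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  structure(list(seqs = up, softmask = softmask, lengths = nchar(up)),
            class = "sine_genome")
}

lowercase_runs <- function(s) {
  low <- gregexpr("[a-z]+", s)[[1]]
  if (low[1] == -1L) return(IRanges::IRanges())
  IRanges::IRanges(start = as.integer(low),
                   width = attr(low, "match.length"))
}

#' Read a genome assembly from FASTA
#'
#' @param path FASTA file. Lower-case (soft-masked) residues are recorded in
#'   the \code{softmask} field and upper-cased for analysis.
#' @return A \code{sine_genome}.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(sine_genome(stats::setNames(character(0), character(0))))
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not readable as FASTA: ", path,
                                           " (", conditionMessage(e), ")"))
  if (length(set) == 0L) {
    warning("FASTA file contains no records: ", path)
    return(sine_genome(stats::setNames(character(0), character(0))))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate sequence ids in ", path)
  seqs <- stats::setNames(as.character(set), ids)
  if (!all(grepl("^[ACGTNRYSWKMBDHVacgtnryswkmbdhv]*$", seqs)))
    stop("non-FASTA or non-DNA content in ", path)
  sine_genome(seqs)
}

#' @export
print.sine_genome <- function(x, ...) {
  cat("sine_genome:", length(x$seqs), "sequence(s),",
      format(sum(x$lengths), big.mark = ","), "bp total\n")
  invisible(x)
}

seq_ids <- function(genome) names(genome$seqs)

seq_len0 <- function(genome, seqid) unname(genome$lengths[[seqid]])

#' Extract a subsequence in internal coordinates
#'
#' @param genome a \code{sine_genome}.
#' @param seqid sequence id.
#' @param start,end 0-based half-open bounds.
#' @param strand if \code{"-"}, the reverse complement is returned.
#' @return character scalar.
#' @export
genome_subseq <- function(genome, seqid, start, end, strand = "+") {
  s <- substr(genome$seqs[[seqid]], start + 1L, end)
  if (strand == "-") s <- revcomp(s)
  s
}

#' Reverse complement of a DNA string
#' @param s character scalar (IUPAC DNA).
#' @return character scalar.
#' @export
revcomp <- function(s) {
  if (nchar(s) == 0L) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

dinucleotide_entropy <- function(s) {
  n <- nchar(s)
  if (n < 2L) return(0)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  di <- paste0(ch[-n], ch[-1L])
  p <- table(di) / (n - 1L)
  -sum(p * log2(p))
}
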