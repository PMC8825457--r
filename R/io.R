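#' Write annotation records to GFF3 or BED
#'
#' Annotation records are data.frames with columns \code{seqid, start, end,
#' strand, seed_id, divergence, family} in internal 0-based half-open
#' coordinates. GFF3 output is 1-based inclusive; BED output is 0-based
#' half-open. GFF3 preserves all metadata on round trip; BED preserves
#' coordinates, name and strand (the BED score carries divergence in
#' per-mille, capped at 1000).
#'
#' @param records annotation data.frame.
#' @param path output file; dialect inferred from extension unless given.
#' @param dialect \code{"gff3"} or \code{"bed"}.
#' @param genome optional \code{sine_genome} for bounds validation.
#' @return \code{path}, invisibly.
#' @export
write_annotation <- function(records, path, dialect = NULL, genome = NULL) {
  if (is.null(dialect))
    dialect <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  dialect <- match.arg(dialect, c("gff3", "bed"))
  if (!is.null(genome)) validate_intervals(records, genome)
  if (is.null(records$seed_id)) records$seed_id <- records$id
  if (is.null(records$divergence)) records$divergence <- NA_real_
  if (is.null(records$family)) records$family <- NA_character_
  gr <- GenomicRanges::GRanges(
    seqnames = records$seqid,
    ranges = IRanges::IRanges(start = records$start + 1L, end = records$end),
    strand = records$strand)
  if (dialect == "gff3") {
    S4Vectors::mcols(gr)$source <- "sinescout"
    S4Vectors::mcols(gr)$type <- "dispersed_repeat"
    S4Vectors::mcols(gr)$ID <- sprintf("ann%06d", seq_along(gr))
    S4Vectors::mcols(gr)$seed_id <- records$seed_id
    S4Vectors::mcols(gr)$divergence <- records$divergence
    S4Vectors::mcols(gr)$family <- records$family
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    S4Vectors::mcols(gr)$name <- records$seed_id
    score <- ifelse(is.na(records$divergence), 0,
                    pmin(1000, round(records$divergence * 1000)))
    S4Vectors::mcols(gr)$score <- score
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}

#' Read annotation records from GFF3 or BED
#'
#' @param path input file.
#' @return data.frame with columns \code{seqid, start, end, strand, seed_id,
#'   divergence, family} (0-based half-open).
#' @export
read_annotation <- function(path) {
  fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  df <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand,
    stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  if (fmt == "gff3") {
    df$seed_id <- if (!is.null(mc$seed_id)) as.character(mc$seed_id) else NA_character_
    df$divergence <- if (!is.null(mc$divergence)) as.numeric(mc$divergence) else NA_real_
    df$family <- if (!is.null(mc$family)) as.character(mc$family) else NA_character_
    if (!is.null(mc$class)) df$class <- as.character(mc$class)
  } else {
    df$seed_id <- if (!is.null(mc$name)) as.character(mc$name) else NA_character_
    df$divergence <- if (!is.null(mc$score)) as.numeric(mc$score) / 1000 else NA_real_
    df$family <- NA_character_
  }
  df[order(df$seqid, df$start), , drop = FALSE] -> df
  rownames(df) <- NULL
  df
}

#' Write a seed library to FASTA
#'
#' Headers encode the seed id, superfamily, source locus, cluster and
#' representative status, so that \code{read_library()} recovers all
#' metadata. Records are ordered deterministically by (seqid, start).
#'
#' @param library a \code{seed_library} (see \code{\link{cluster_seeds}}) or a
#'   seed data.frame.
#' @param path output FASTA.
#' @param which \code{"nonredundant"} (default) or \code{"redundant"}.
#' @return \code{path}, invisibly.
#' @export
write_library <- function(library, path, which = c("nonredundant", "redundant")) {
  which <- match.arg(which)
  seeds <- if (inherits(library, "seed_library")) library[[which]] else library
  if (is.null(seeds) || nrow(seeds) == 0L) {
    warning("writing empty seed library to ", path)
    writeLines(character(0), path)
    return(invisible(path))
  }
  seeds <- seeds[order(seeds$seqid, seeds$start), , drop = FALSE]
  hdr <- sprintf("%s superfamily=%s;locus=%s:%d-%d(%s);cluster=%d;representative=%s",
                 seeds$id, seeds$superfamily, seeds$seqid, seeds$start,
                 seeds$end, seeds$strand,
                 ifelse(is.na(seeds$cluster_id), -1L, seeds$cluster_id),
                 ifelse(is.na(seeds$is_representative), TRUE,
                        seeds$is_representative))
  set <- Biostrings::DNAStringSet(seeds$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a seed library written by \code{write_library}
#'
#' @param path FASTA file.
#' @return seed data.frame (columns \code{id, sequence, seqid, start, end,
#'   strand, superfamily, cluster_id, is_representative}).
#' @export
read_library <- function(path) {
  if (file.size(path) == 0L)
    return(empty_seeds())
  set <- Biostrings::readBStringSet(path)
  hdr <- names(set)
  id <- sub("\\s.*$", "", hdr)
  meta <- sub("^\\S+\\s*", "", hdr)
  field <- function(key) {
    m <- regmatches(meta, regexpr(paste0(key, "=[^;]*"), meta))
    ifelse(lengths(regmatches(meta, gregexpr(paste0(key, "="), meta))) > 0,
           sub(paste0("^", key, "="), "", m), NA_character_)
  }
  locus <- field("locus")
  lm <- regmatches(locus, regexec("^(.*):(\\d+)-(\\d+)\\(([+-])\\)$", locus))
  seeds <- data.frame(
    id = id,
    sequence = toupper(as.character(set)),
    seqid = vapply(lm, `[`, "", 2L),
    start = as.integer(vapply(lm, `[`, "", 3L)),
    end = as.integer(vapply(lm, `[`, "", 4L)),
    strand = vapply(lm, `[`, "", 5L),
    superfamily = field("superfamily"),
    cluster_id = as.integer(field("cluster")),
    is_representative = as.logical(field("representative")),
    stringsAsFactors = FALSE)
  seeds$cluster_id[seeds$cluster_id == -1L] <- NA_integer_
  rownames(seeds) <- NULL
  seeds
}

empty_seeds <- function() {
  data.frame(id = character(0), sequence = character(0), seqid = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             superfamily = character(0), cluster_id = integer(0),
             is_representative = logical(0), stringsAsFactors = FALSE)
}

#' Write a genome to FASTA
#' @param genome a \code{sine_genome}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_genome <- function(genome, path) {
  seqs <- genome$seqs
  for (i in seq_along(seqs)) {
    sm <- genome$softmask[[i]]
    if (length(sm)) {
      ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
      idx <- unlist(lapply(seq_along(sm), function(j)
        seq(IRanges::start(sm)[j], IRanges::end(sm)[j])))
      ch[idx] <- tolower(ch[idx])
      seqs[[i]] <- paste(ch, collapse = "")
    }
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
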