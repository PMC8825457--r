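# Seed-library construction (redundancy removal at 80% identity, longest
# member as cluster representative) and genome-wide annotation of all
# copies -- including fragmented and TSD-less family members -- against the
# nonredundant library under a divergence cap.

#' Merge the structural and homology candidate tracks
#'
#' Takes the union of the two filtered candidate sets; pairs with
#' reciprocal overlap > 50% are collapsed to the longer element with
#' provenance \code{"both"}.
#'
#' @param structural,homology \code{sine_candidates} (post-filtering).
#' @return merged \code{sine_candidates}.
#' @export
merge_tracks <- function(structural, homology) {
  df <- rbind(as.data.frame(structural), as.data.frame(homology))
  if (nrow(df) == 0L) return(empty_candidates())
  df <- df[order(-(df$end - df$start)), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i] || i == nrow(df)) next
    j <- (i + 1L):nrow(df)
    same <- keep[j] & df$seqid[j] == df$seqid[i]
    jj <- j[same]
    if (!length(jj)) next
    ov <- pmin(df$end[jj], df$end[i]) - pmax(df$start[jj], df$start[i])
    w1 <- df$end[i] - df$start[i]
    w2 <- df$end[jj] - df$start[jj]
    # overlap measured on the shorter element, so nested pairs collapse
    hit <- ov > 0.5 * pmin(w1, w2)
    if (any(hit)) {
      if (any(df$source[jj[hit]] != df$source[i])) df$source[i] <- "both"
      keep[jj[hit]] <- FALSE
    }
  }
  out <- df[keep, , drop = FALSE]
  out <- out[order(out$seqid, out$start), , drop = FALSE]
  class(out) <- c("sine_candidates", "data.frame")
  rownames(out) <- NULL
  out
}

#' Build seed records from surviving candidates
#'
#' @param candidates filtered \code{sine_candidates} (with an optional
#'   \code{superfamily} column).
#' @param genome a \code{sine_genome}.
#' @return seed data.frame (element-orientation sequences).
#' @export
candidates_to_seeds <- function(candidates, genome) {
  if (nrow(candidates) == 0L) return(empty_seeds())
  seqs <- vapply(seq_len(nrow(candidates)), function(i)
    candidate_seq(genome, candidates[i, ]), character(1))
  data.frame(
    id = paste0("seed_", candidates$id),
    sequence = seqs,
    seqid = candidates$seqid, start = candidates$start,
    end = candidates$end, strand = candidates$strand,
    superfamily = if (!is.null(candidates$superfamily))
      candidates$superfamily else "unknown",
    cluster_id = NA_integer_, is_representative = NA,
    stringsAsFactors = FALSE)
}

#' Cluster seeds into a nonredundant library
#'
#' Greedy incremental clustering: seeds are sorted by length (descending,
#' stable); each seed joins the first cluster whose representative aligns
#' globally at identity >= \code{cluster_identity}, where identity is
#' matched bases over the length of the shorter sequence; otherwise it
#' founds a new cluster. Because processing is longest-first, each cluster
#' founder is its longest member and becomes the representative.
#'
#' @param seeds seed data.frame (see \code{\link{candidates_to_seeds}}).
#' @param config a \code{\link{sine_config}}.
#' @return object of class \code{"seed_library"}: list with
#'   \code{redundant} (all seeds, cluster-labelled) and \code{nonredundant}
#'   (representatives only).
#' @export
cluster_seeds <- function(seeds, config = sine_config()) {
  if (nrow(seeds) == 0L)
    return(structure(list(redundant = empty_seeds(),
                          nonredundant = empty_seeds()),
                     class = "seed_library"))
  ord <- order(-nchar(seeds$sequence))
  seeds <- seeds[ord, , drop = FALSE]
  reps <- integer(0)  # row indices of representatives
  cluster <- integer(nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    assigned <- FALSE
    for (ci in seq_along(reps)) {
      ident <- seed_identity(seeds$sequence[i], seeds$sequence[reps[ci]], config)
      if (ident >= config$cluster_identity) {
        cluster[i] <- ci
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      cluster[i] <- length(reps)
    }
  }
  seeds$cluster_id <- cluster
  seeds$is_representative <- seq_len(nrow(seeds)) %in% reps
  seeds <- seeds[order(seeds$seqid, seeds$start), , drop = FALSE]
  rownames(seeds) <- NULL
  structure(list(redundant = seeds,
                 nonredundant = seeds[seeds$is_representative, , drop = FALSE]),
            class = "seed_library")
}

seed_identity <- function(a, b, config) {
  # global-alignment matches over the shorter sequence (the convention of
  # greedy redundancy removers). Gaps are priced so that scattering
  # single-base gaps can never buy a match (open + extend > 2 * match);
  # otherwise a short seed aligned against a much longer unrelated one
  # accumulates LCS-like spurious matches and inflates the identity.
  mat <- sub_matrix(config$match, config$mismatch)
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global", substitutionMatrix = mat,
    gapOpening = config$cluster_gap_open,
    gapExtension = config$cluster_gap_ext)
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

#' @export
print.seed_library <- function(x, ...) {
  cat("seed_library:", nrow(x$redundant), "seed(s) in",
      nrow(x$nonredundant), "cluster(s)\n")
  invisible(x)
}

#' Annotate a genome against a seed library
#'
#' Each nonredundant seed is searched against the genome (both strands);
#' hits with divergence (1 - identity) at most \code{max_divergence} and
#' aligned seed span at least \code{min_hit_frac} of the seed length are
#' reported, so fragmented and TSD-less family members are recovered.
#' Overlapping hits (> 50% of the shorter) from different seeds resolve to
#' the lowest divergence, then the longer hit, then the leftmost.
#'
#' @param genome a \code{sine_genome}.
#' @param library a \code{seed_library} (or seed data.frame used as the
#'   nonredundant set).
#' @param config a \code{\link{sine_config}}.
#' @return annotation data.frame: \code{seqid, start, end, strand, seed_id,
#'   divergence, family} (0-based half-open).
#' @export
annotate_genome <- function(genome, library, config = sine_config()) {
  seeds <- if (inherits(library, "seed_library")) library$nonredundant else library
  empty <- data.frame(seqid = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      seed_id = character(0), divergence = numeric(0),
                      family = character(0), stringsAsFactors = FALSE)
  if (is.null(seeds) || nrow(seeds) == 0L) {
    warning("empty seed library; no annotation produced")
    return(empty)
  }
  recs <- list()
  for (i in seq_len(nrow(seeds))) {
    slen <- nchar(seeds$sequence[i])
    hits <- find_local_hits(seeds$sequence[i], genome, config,
                            e_cutoff = config$e_cutoff,
                            min_len = ceiling(config$min_hit_frac * slen))
    if (!nrow(hits)) next
    hits <- hits[1 - hits$identity <= config$max_divergence, , drop = FALSE]
    if (!nrow(hits)) next
    recs[[length(recs) + 1L]] <- data.frame(
      seqid = hits$seqid, start = hits$s_start, end = hits$s_end,
      strand = hits$strand, seed_id = seeds$id[i],
      divergence = round(1 - hits$identity, 4),
      family = seeds$superfamily[i], stringsAsFactors = FALSE)
  }
  if (!length(recs)) return(empty)
  df <- do.call(rbind, recs)
  # overlap resolution: lowest divergence, then longer, then leftmost
  df <- df[order(df$divergence, -(df$end - df$start), df$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i] || i == nrow(df)) next
    j <- (i + 1L):nrow(df)
    same <- keep[j] & df$seqid[j] == df$seqid[i]
    jj <- j[same]
    if (!length(jj)) next
    ov <- pmin(df$end[jj], df$end[i]) - pmax(df$start[jj], df$start[i])
    wmin <- pmin(df$end[jj] - df$start[jj], df$end[i] - df$start[i])
    keep[jj[ov > 0.5 * wmin]] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$seqid, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}
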