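# Position-specific copy-number profiles. Each TSD-verified candidate is
# extended by `extension` bases on both sides; the extended window is
# searched against the whole genome for copies; retained alignments are
# tallied per window position. The profile shape separates real SINEs
# (a block of uniformly high counts at the element) from joined/truncated
# repeats (interior gaps), long repeats (alignments running into the window
# edges) and shifted repeat structures.

#' Collect genome-wide copies of a candidate
#'
#' The candidate is extended by \code{extension} nt on both sides (clipped
#' at sequence ends); the extended query of length L is aligned against all
#' genome records on both strands. Hits must reach significance
#' \code{e_cutoff} and aligned length at least \code{alpha * L}. The self
#' hit is retained and flagged.
#'
#' @param candidate one-row \code{sine_candidates} (TSD-verified).
#' @param genome a \code{sine_genome}.
#' @param config a \code{\link{sine_config}}.
#' @return list with \code{hits} (see \code{\link{find_local_hits}}, plus a
#'   \code{self} flag), \code{window} (seqid, 0-based half-open start/end),
#'   \code{L}, and \code{s_pos}, \code{e_pos} (original candidate boundaries
#'   in window coordinates).
#' @export
collect_copies <- function(candidate, genome, config = sine_config()) {
  n <- seq_len0(genome, candidate$seqid)
  ws <- max(0L, candidate$start - config$extension)
  we <- min(n, candidate$end + config$extension)
  L <- we - ws
  query <- genome_subseq(genome, candidate$seqid, ws, we, "+")
  hits <- find_local_hits(query, genome, config,
                          e_cutoff = config$e_cutoff,
                          min_len = ceiling(config$alpha * L))
  if (nrow(hits)) {
    ov <- ifelse(hits$seqid == candidate$seqid,
                 pmin(hits$s_end, we) - pmax(hits$s_start, ws), 0L)
    hits$self <- hits$strand == "+" & ov >= 0.9 * L
    if (sum(hits$self) > 1L) {
      # keep only the best-scoring hit flagged as self
      sf <- which(hits$self)
      hits$self[sf[-which.max(hits$score[sf])]] <- FALSE
    }
  } else {
    hits$self <- logical(0)
  }
  list(hits = hits,
       window = list(seqid = candidate$seqid, start = ws, end = we),
       L = L, s_pos = candidate$start - ws, e_pos = candidate$end - ws)
}

#' Build the position-specific copy-number profile
#'
#' @param copies result of \code{\link{collect_copies}} (or a compatible
#'   list with \code{hits}, \code{L}, \code{s_pos}, \code{e_pos}).
#' @param config a \code{\link{sine_config}}.
#' @return object of class \code{"copy_profile"}: \code{counts} (integer
#'   vector of length L; \code{counts[p]} = number of retained alignments
#'   covering window position p), \code{T} (number of retained alignments),
#'   plus the window bookkeeping. \code{profile_class} is \code{"low_copy"}
#'   when \code{T < min_copies}, otherwise unset until
#'   \code{\link{classify_profile}}.
#' @export
build_profile <- function(copies, config = sine_config()) {
  L <- copies$L
  counts <- integer(L)
  hits <- copies$hits
  for (i in seq_len(nrow(hits))) {
    a <- hits$q_start[i] + 1L
    b <- hits$q_end[i]
    if (b >= a) counts[a:b] <- counts[a:b] + 1L
  }
  cls <- if (nrow(hits) < config$min_copies) "low_copy" else NA_character_
  structure(list(counts = counts, T = nrow(hits), L = L,
                 window = copies$window, s_pos = copies$s_pos,
                 e_pos = copies$e_pos, hits = hits,
                 i_start = NA_integer_, i_end = NA_integer_,
                 profile_class = cls),
            class = "copy_profile")
}

#' Refine element boundaries from the copy-number profile
#'
#' The refined 5' boundary is the first window position with count strictly
#' above \code{tau * T}; the refined 3' boundary is the last such position.
#' Both are stored 0-based inclusive in \code{i_start}/\code{i_end}; the
#' refined half-open interval is \code{[i_start, i_end + 1)} in window
#' coordinates.
#'
#' @param profile a \code{copy_profile}.
#' @param config a \code{\link{sine_config}}.
#' @return the profile with \code{i_start}, \code{i_end} filled in;
#'   \code{NULL} when no position exceeds the threshold (degenerate
#'   profile: the candidate is removed).
#' @export
refine_boundaries <- function(profile, config = sine_config()) {
  thr <- config$tau * profile$T
  above <- profile$counts > thr
  if (!any(above)) return(NULL)
  profile$i_start <- which(above)[1L] - 1L
  profile$i_end <- which(above)[sum(above)] - 1L
  profile
}

#' Classify a copy-number profile
#'
#' Classes, checked in order after boundary refinement:
#' \describe{
#'   \item{low_copy}{fewer than \code{min_copies} retained alignments.}
#'   \item{truncated}{an interior run of positions with counts below
#'     \code{tau * T} longer than \code{gap_max} bp between the refined
#'     boundaries (joined/nested repeat halves).}
#'   \item{extended}{more than \code{extend_frac} of the non-self alignments
#'     run into the first or last base of the extended window, i.e. the
#'     repeat continues beyond it (long repeats such as LINEs). Checked
#'     before the shift rule because such profiles saturate the window and
#'     would otherwise always trip it.}
#'   \item{shifted}{\code{max(|i_start - s|, |i_end - e|)} exceeds
#'     \code{shift_max} nt, with s, e the pre-refinement boundaries.}
#'   \item{clean}{none of the above; the candidate is a credible SINE.}
#' }
#'
#' @param profile a \code{copy_profile} with refined boundaries.
#' @param config a \code{\link{sine_config}}.
#' @return character scalar, one of \code{"low_copy", "truncated",
#'   "extended", "shifted", "clean"}.
#' @export
classify_profile <- function(profile, config = sine_config()) {
  if (profile$T < config$min_copies) return("low_copy")
  if (is.na(profile$i_start)) stop("boundaries not refined")
  thr <- config$tau * profile$T
  inner <- profile$counts[(profile$i_start + 1L):(profile$i_end + 1L)]
  r <- rle(inner < thr)  # gap: interior positions with counts below tau * T
  gaps <- r$lengths[r$values]
  if (length(gaps) && max(gaps) > config$gap_max) return("truncated")
  hits <- profile$hits
  ns <- hits[!hits$self, , drop = FALSE]
  if (nrow(ns)) {
    touches <- ns$q_start == 0L | ns$q_end == profile$L
    if (mean(touches) > config$extend_frac) return("extended")
  }
  shift <- max(abs(profile$i_start - profile$s_pos),
               abs(profile$i_end - (profile$e_pos - 1L)))
  if (shift > config$shift_max) return("shifted")
  "clean"
}

#' @export
print.copy_profile <- function(x, ...) {
  cat("copy_profile: L =", x$L, ", T =", x$T,
      ", class =", ifelse(is.na(x$profile_class), "<unclassified>",
                          x$profile_class), "\n")
  invisible(x)
}

#' Profile-based screening of TSD-verified candidates
#'
#' Runs copy collection, profile construction, boundary refinement and
#' classification for each candidate. Candidates with a clean profile get
#' status \code{"profile_passed"} and their interval is updated to the
#' refined boundaries; all others are removed with the profile class as
#' \code{filter_reason} (\code{"degenerate_profile"} when no position
#' clears the threshold).
#'
#' @param candidates TSD-verified \code{sine_candidates}.
#' @param genome a \code{sine_genome}.
#' @param config a \code{\link{sine_config}}.
#' @return list: \code{kept}, \code{removed}, \code{profiles} (one per
#'   input candidate, named by candidate id).
#' @export
profile_screen <- function(candidates, genome, config = sine_config()) {
  profiles <- list()
  keep <- logical(nrow(candidates))
  reason <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    copies <- collect_copies(candidates[i, ], genome, config)
    prof <- build_profile(copies, config)
    if (prof$T >= config$min_copies) {
      ref <- refine_boundaries(prof, config)
      if (is.null(ref)) {
        reason[i] <- "degenerate_profile"
        profiles[[candidates$id[i]]] <- prof
        next
      }
      prof <- ref
    }
    cls <- if (prof$T < config$min_copies) "low_copy"
           else classify_profile(prof, config)
    prof$profile_class <- cls
    profiles[[candidates$id[i]]] <- prof
    if (cls == "clean") {
      keep[i] <- TRUE
      candidates$start[i] <- prof$window$start + prof$i_start
      candidates$end[i] <- prof$window$start + prof$i_end + 1L
      candidates$status[i] <- "profile_passed"
    } else {
      reason[i] <- cls
    }
  }
  removed <- candidates[!keep, , drop = FALSE]
  if (nrow(removed)) {
    removed$status <- "filtered_out"
    removed$filter_reason <- reason[!keep]
  }
  list(kept = candidates[keep, , drop = FALSE], removed = removed,
       profiles = profiles)
}
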