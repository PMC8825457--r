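# End-to-end driver: structural (and optional homology) candidate
# discovery -> TSD verification -> copy-number profile screening ->
# superfamily / ncRNA, tandem and TIR filters -> track merging -> seed
# clustering -> genome-wide annotation.

ncrna_screen <- function(candidates, genome, refs, config) {
  candidates$superfamily <- rep("unknown", nrow(candidates))
  if (nrow(candidates) == 0L)
    return(list(kept = candidates, removed = candidates[0, , drop = FALSE]))
  if (is.null(refs)) {
    return(list(kept = candidates, removed = candidates[0, , drop = FALSE]))
  }
  keep <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    call <- classify_superfamily(candidate_seq(genome, candidates[i, ]),
                                 refs, config)
    candidates$superfamily[i] <- call$label
    keep[i] <- call$keep
  }
  removed <- candidates[!keep, , drop = FALSE]
  if (nrow(removed)) {
    removed$status <- "filtered_out"
    removed$filter_reason <- "ncrna_gene"
  }
  list(kept = candidates[keep, , drop = FALSE], removed = removed)
}

tandem_screen <- function(candidates, genome, config) {
  if (nrow(candidates) == 0L)
    return(list(kept = candidates, removed = candidates))
  frac <- vapply(seq_len(nrow(candidates)), function(i)
    tandem_fraction(candidate_seq(genome, candidates[i, ]), config),
    numeric(1))
  keep <- frac < config$tandem_max_fraction
  removed <- candidates[!keep, , drop = FALSE]
  if (nrow(removed)) {
    removed$status <- "filtered_out"
    removed$filter_reason <- "tandem_repeat"
  }
  list(kept = candidates[keep, , drop = FALSE], removed = removed)
}

tir_screen <- function(candidates, genome, config) {
  if (nrow(candidates) == 0L)
    return(list(kept = candidates, removed = candidates))
  keep <- vapply(seq_len(nrow(candidates)), function(i)
    is.null(find_tir(candidates[i, ], genome, config)), logical(1))
  removed <- candidates[!keep, , drop = FALSE]
  if (nrow(removed)) {
    removed$status <- "filtered_out"
    removed$filter_reason <- "tir_mite"
  }
  list(kept = candidates[keep, , drop = FALSE], removed = removed)
}

screen_track <- function(candidates, genome, config, ncrna_refs) {
  removed <- list()
  v <- verify_candidates(candidates, genome, config)
  removed$tsd <- v$removed
  p <- profile_screen(v$kept, genome, config)
  removed$profile <- p$removed
  n <- ncrna_screen(p$kept, genome, ncrna_refs, config)
  removed$ncrna <- n$removed
  t <- tandem_screen(n$kept, genome, config)
  removed$tandem <- t$removed
  r <- tir_screen(t$kept, genome, config)
  removed$tir <- r$removed
  rem_list <- lapply(removed, function(d) {
    d <- as.data.frame(d)
    d$superfamily <- NULL
    d
  })
  rem <- do.call(rbind, rem_list)
  rownames(rem) <- NULL
  list(kept = r$kept, removed = rem, profiles = p$profiles)
}

#' Run the full SINE annotation pipeline
#'
#' @param genome a \code{sine_genome} (or path to a FASTA file).
#' @param config a \code{\link{sine_config}}.
#' @param hmm_hits optional path to an nhmmer tblout file supplying the
#'   homology candidate track.
#' @param ncrna_refs optional ncRNA reference set
#'   (\code{\link{read_ncrna_refs}} data.frame or FASTA path) for
#'   superfamily classification and ncRNA-gene exclusion.
#' @return object of class \code{"sine_annotation"}: \code{seeds} (a
#'   \code{seed_library}), \code{annotation} (data.frame of genome-wide
#'   records), \code{candidates} (surviving, with provenance),
#'   \code{removed} (screened-out candidates with \code{filter_reason}),
#'   and \code{config}.
#' @examples
#' sim <- generate_genome(synthetic_spec(genome_length = 60000,
#'   n_families = 2, copies_per_family = 5,
#'   decoy_counts = c(mite = 0, tandem_array = 0, line_fragment = 0,
#'                    joined_pair = 0), seed = 7))
#' res <- sine_annotate(sim$genome)
#' summary(res)
#' @export
sine_annotate <- function(genome, config = sine_config(), hmm_hits = NULL,
                          ncrna_refs = NULL) {
  if (is.character(genome)) genome <- read_genome(genome)
  if (is.character(ncrna_refs)) ncrna_refs <- read_ncrna_refs(ncrna_refs)
  structural <- scan_structural_candidates(genome, config)
  st <- screen_track(structural, genome, config, ncrna_refs)
  if (!is.null(hmm_hits)) {
    homology <- parse_hmm_hits(hmm_hits, config$hmm_evalue, config)
    hm <- screen_track(homology, genome, config, ncrna_refs)
  } else {
    hm <- list(kept = empty_candidates(), removed = NULL)
  }
  sup_of <- function(track) {
    s <- track$superfamily
    if (is.null(s)) s <- rep("unknown", nrow(track))
    stats::setNames(s, track$id)
  }
  sup <- c(sup_of(st$kept), sup_of(hm$kept))
  st_kept <- st$kept; st_kept$superfamily <- NULL
  hm_kept <- hm$kept; hm_kept$superfamily <- NULL
  merged <- merge_tracks(st_kept, hm_kept)
  merged$superfamily <- unname(sup[merged$id])
  seeds <- candidates_to_seeds(merged, genome)
  library <- cluster_seeds(seeds, config)
  annotation <- if (nrow(library$nonredundant))
    annotate_genome(genome, library, config)
  else
    data.frame(seqid = character(0), start = integer(0), end = integer(0),
               strand = character(0), seed_id = character(0),
               divergence = numeric(0), family = character(0),
               stringsAsFactors = FALSE)
  removed <- rbind(if (!is.null(st$removed)) st$removed,
                   if (!is.null(hm$removed)) hm$removed)
  structure(list(seeds = library, annotation = annotation,
                 candidates = merged, removed = removed, config = config),
            class = "sine_annotation")
}

#' @export
print.sine_annotation <- function(x, ...) {
  cat("sine_annotation:\n")
  cat("  intact seeds:      ", nrow(x$seeds$redundant),
      "(", nrow(x$seeds$nonredundant), "nonredundant )\n")
  cat("  annotation records:", nrow(x$annotation), "\n")
  invisible(x)
}

#' @export
summary.sine_annotation <- function(object, ...) {
  print(object)
  if (!is.null(object$removed) && nrow(object$removed)) {
    cat("  removed candidates by reason:\n")
    tab <- table(object$removed$filter_reason)
    for (nm in names(tab)) cat(sprintf("    %-20s %d\n", nm, tab[[nm]]))
  }
  if (nrow(object$annotation)) {
    cat("  mean divergence of annotated copies:",
        sprintf("%.3f", mean(object$annotation$divergence)), "\n")
  }
  invisible(object)
}
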