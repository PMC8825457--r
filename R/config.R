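#' Pipeline configuration
#'
#' Builds the full set of tunable parameters for the SINE annotation pipeline,
#' with the defaults used throughout. Any subset can be overridden by name.
#'
#' Key parameters (units are nucleotides unless noted):
#' \describe{
#'   \item{min_spacing, max_spacing}{Allowed number of bases strictly between
#'     the box A and box B promoter motifs (default 25--50).}
#'   \item{tail_min_offset, tail_max_offset}{Distance from the end of box B to
#'     the start of the 3' tail (default 20--500).}
#'   \item{tail_min_run, tail_min_purity}{A poly-A/poly-T tail is a run of at
#'     least \code{tail_min_run} bases with at least \code{tail_min_purity}
#'     majority-base content (defaults 6 and 0.8).}
#'   \item{lc_window, lc_max_entropy}{Other low-complexity tails: window of
#'     \code{lc_window} bases whose dinucleotide Shannon entropy is below
#'     \code{lc_max_entropy} bits (defaults 10 and 1.2).}
#'   \item{sine_min_len, sine_max_len}{Accepted element length range
#'     (default 100--700).}
#'   \item{fragment, overlap}{Genome slicing for the structural scan
#'     (default 10 kb fragments, 2 kb overlap).}
#'   \item{tsd_min_len, tsd_max_len}{Accepted TSD length range (10--20).}
#'   \item{tsd_up_window, tsd_down_window}{Flanking search windows upstream of
#'     the 5' terminus and downstream of the 3' terminus (30 and 50).}
#'   \item{tsd_max_mismatch, tsd_mismatch_penalty}{Mismatch budget between the
#'     two TSD copies and the per-mismatch score penalty (1 and 1).}
#'   \item{extension}{Bases added to both ends of a candidate before the
#'     genome-wide copy search (100).}
#'   \item{alpha}{Length factor: a copy alignment must cover at least
#'     \code{alpha * L} of the extended query of length L (0.3).}
#'   \item{tau}{Copy-number factor: profile positions with counts strictly
#'     above \code{tau * T} (T = retained copies) lie inside the element (0.5).}
#'   \item{min_copies}{Minimum retained alignments (including the self hit)
#'     for a profile to be usable; fewer is classed \code{low_copy} (3).}
#'   \item{e_cutoff}{Significance cutoff for copy alignments (1e-10).}
#'   \item{gap_max}{Maximum interior run of sub-threshold positions before a
#'     profile is classed truncated (10 bp).}
#'   \item{shift_max}{Maximum refined-boundary shift before a profile is
#'     classed shifted (50).}
#'   \item{extend_frac}{Fraction of non-self copies running into the window
#'     edges above which a profile is classed extended (0.5).}
#'   \item{exclusion_evalue, exclusion_coverage}{A candidate nearly identical
#'     to a reference ncRNA (significance at or below \code{exclusion_evalue}
#'     over at least \code{exclusion_coverage} of its length) is excluded as an
#'     ncRNA gene rather than a SINE (1e-15 and 0.9).}
#'   \item{tandem_max_fraction}{Candidates with at least this fraction of their
#'     length in tandem arrays are removed (0.7).}
#'   \item{tir_min_arm, tir_max_mismatch, tir_zone}{Terminal inverted repeat
#'     filter: minimum arm length, arm mismatch budget, and terminal zone
#'     width searched at each end (10, 1, 50).}
#'   \item{cluster_identity}{Greedy clustering identity cutoff for the
#'     nonredundant library (0.80).}
#'   \item{max_divergence}{Maximum divergence from a library seed for a
#'     genome-wide annotation hit (0.40).}
#'   \item{min_hit_frac}{Minimum annotation hit length as a fraction of the
#'     seed length (0.5).}
#' }
#'
#' @param ... named overrides of any default.
#' @return A named list with class \code{"sine_config"}.
#' @examples
#' cfg <- sine_config(tau = 0.6)
#' cfg$tau
#' @export
sine_config <- function(...) {
  cfg <- list(
    # structural search
    min_spacing = 25L, max_spacing = 50L,
    tail_min_offset = 20L, tail_max_offset = 500L,
    tail_min_run = 6L, tail_min_purity = 0.8,
    lc_window = 10L, lc_max_entropy = 1.2,
    sine_min_len = 100L, sine_max_len = 700L,
    fragment = 10000L, overlap = 2000L,
    # TSD
    tsd_min_len = 10L, tsd_max_len = 20L,
    tsd_up_window = 30L, tsd_down_window = 50L,
    tsd_max_mismatch = 1L, tsd_mismatch_penalty = 1,
    # copy-number profile
    extension = 100L, alpha = 0.3, tau = 0.5,
    min_copies = 3L, e_cutoff = 1e-10,
    gap_max = 10L, shift_max = 50L, extend_frac = 0.5,
    # homology import
    hmm_evalue = 1.0, merge_overlap = 0.5,
    # filters
    exclusion_evalue = 1e-15, exclusion_coverage = 0.9,
    tandem_max_fraction = 0.7, tandem_max_period = 6L,
    tandem_min_copies = 3L, tandem_min_identity = 0.8, tandem_min_span = 8L,
    tir_min_arm = 10L, tir_max_mismatch = 1L, tir_zone = 50L,
    # library / annotation
    cluster_identity = 0.80, max_divergence = 0.40, min_hit_frac = 0.5,
    cluster_gap_open = 10, cluster_gap_ext = 4,
    # internal aligner
    kmer = 12L, match = 1, mismatch = -1, gap_open = 2, gap_ext = 1,
    # evaluation
    min_overlap = 0.5, min_sw_score = 225, min_coverage = 0.5
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  if (cfg$alpha <= 0 || cfg$alpha > 1) stop("alpha must be in (0, 1]")
  if (cfg$tau <= 0 || cfg$tau > 1) stop("tau must be in (0, 1]")
  structure(cfg, class = "sine_config")
}
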