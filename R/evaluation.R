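# Three-level evaluation of a predicted annotation against a reference:
# base level (per-nucleotide four-way classification), element level
# (per known element, requiring > 50% overlap with a prediction), and seed
# level (library-vs-library local alignment with a Smith-Waterman score and
# coverage threshold).

#' Compute sensitivity, precision, FDR and F1 from confusion counts
#'
#' sensitivity = TP/(TP+FN); precision = TP/(TP+FP); FDR = FP/(TP+FP);
#' F1 = 2TP/(2TP+FP+FN). Metrics with an undefined (zero) denominator are
#' returned as \code{NA}. Values are reported to 3 decimals.
#'
#' @param counts list or data.frame with \code{TP}, \code{FP}, \code{FN}
#'   (and optionally \code{TN}, \code{level}).
#' @return object of class \code{"metric_report"}: list with
#'   \code{sensitivity, precision, fdr, f1} and the input counts.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  sens <- if (tp + fn > 0) round(tp / (tp + fn), 3) else NA_real_
  prec <- if (tp + fp > 0) round(tp / (tp + fp), 3) else NA_real_
  fdr <- if (tp + fp > 0) round(fp / (tp + fp), 3) else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) round(2 * tp / (2 * tp + fp + fn), 3)
        else NA_real_
  structure(list(sensitivity = sens, precision = prec, fdr = fdr, f1 = f1,
                 counts = counts),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("sensitivity %.3f  precision %.3f  FDR %.3f  F1 %.3f\n",
              x$sensitivity, x$precision, x$fdr, x$f1))
  invisible(x)
}

coverage_ranges <- function(df) {
  if (nrow(df) == 0L) return(list())
  sp <- split(df, df$seqid)
  lapply(sp, function(d)
    IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end)))
}

#' Base-level evaluation counts
#'
#' Overlapping records within each set are unioned first; every genome
#' position is then classified TP (covered by both), FP (prediction only),
#' FN (reference only) or TN (neither).
#'
#' @param pred,truth annotation data.frames (\code{seqid, start, end}).
#' @param genome_length total genome length in bases (or a
#'   \code{sine_genome}).
#' @return list with \code{level = "base"}, \code{TP, FP, FN, TN}.
#' @export
count_base_level <- function(pred, truth, genome_length) {
  if (inherits(genome_length, "sine_genome"))
    genome_length <- sum(genome_length$lengths)
  pr <- coverage_ranges(pred)
  tr <- coverage_ranges(truth)
  pcov <- sum(vapply(pr, function(r) sum(IRanges::width(r)), numeric(1)))
  tcov <- sum(vapply(tr, function(r) sum(IRanges::width(r)), numeric(1)))
  tp <- 0
  for (sid in intersect(names(pr), names(tr)))
    tp <- tp + sum(IRanges::width(BiocGenerics::intersect(pr[[sid]], tr[[sid]])))
  list(level = "base", TP = tp, FP = pcov - tp, FN = tcov - tp,
       TN = genome_length - pcov - tcov + tp)
}

#' Element-level evaluation counts
#'
#' A reference element is TP when a single prediction covers strictly more
#' than \code{min_overlap} of its length (one prediction may validate
#' several elements it spans), else FN. A prediction is FP when no
#' reference element covers strictly more than \code{min_overlap} of the
#' prediction's length. Matching is strand-agnostic.
#'
#' @param pred,truth annotation data.frames.
#' @param min_overlap overlap fraction threshold (default 0.5, strict).
#' @return list with \code{level = "element"}, \code{TP, FP, FN}.
#' @export
count_element_level <- function(pred, truth, min_overlap = 0.5) {
  np <- nrow(pred); nt <- nrow(truth)
  tp <- 0L
  pred_matched <- rep(FALSE, np)
  for (i in seq_len(nt)) {
    ok <- FALSE
    if (np) {
      same <- pred$seqid == truth$seqid[i]
      ov <- pmax(0L, pmin(pred$end, truth$end[i]) -
                       pmax(pred$start, truth$start[i]))
      ov[!same] <- 0L
      tw <- truth$end[i] - truth$start[i]
      ok <- any(ov > min_overlap * tw)
      pw <- pred$end - pred$start
      pred_matched <- pred_matched | (ov > min_overlap * pw)
    }
    if (ok) tp <- tp + 1L
  }
  list(level = "element", TP = tp, FP = sum(!pred_matched), FN = nt - tp)
}

#' Seed-level library comparison
#'
#' A test seed is TP when it aligns locally to some reference seed with
#' score at least \code{min_sw_score} and aligned query coverage at least
#' \code{min_coverage} of the test seed; otherwise it is FP. Reference
#' seeds not matched by any test seed under the same criterion are FN.
#'
#' @param test_lib,standard_lib \code{seed_library} objects or seed
#'   data.frames (nonredundant sets are compared).
#' @param config a \code{\link{sine_config}} (scoring, \code{min_sw_score},
#'   \code{min_coverage}).
#' @return list with \code{level = "seed"}, \code{TP, FP, FN}.
#' @export
compare_seeds <- function(test_lib, standard_lib, config = sine_config()) {
  test <- if (inherits(test_lib, "seed_library")) test_lib$nonredundant else test_lib
  std <- if (inherits(standard_lib, "seed_library")) standard_lib$nonredundant
         else standard_lib
  if (nrow(test) == 0L || nrow(std) == 0L)
    return(list(level = "seed", TP = 0L, FP = nrow(test), FN = nrow(std)))
  match_mat <- matrix(FALSE, nrow(test), nrow(std))
  for (i in seq_len(nrow(test))) {
    for (j in seq_len(nrow(std))) {
      hit <- best_strand_local(test$sequence[i], std$sequence[j], config)
      cov <- (hit$q_end - hit$q_start) / nchar(test$sequence[i])
      match_mat[i, j] <- hit$score >= config$min_sw_score &&
        cov >= config$min_coverage
    }
  }
  tp <- sum(apply(match_mat, 1L, any))
  fp <- nrow(test) - tp
  fn <- sum(!apply(match_mat, 2L, any))
  list(level = "seed", TP = tp, FP = fp, FN = fn)
}

best_strand_local <- function(a, b, config) {
  h1 <- align_pair(a, b, type = "local", config = config)
  h2 <- align_pair(a, revcomp(b), type = "local", config = config)
  if (h2$score > h1$score) h2 else h1
}

#' Evaluate a predicted annotation against a reference
#'
#' @param pred predicted annotation data.frame.
#' @param truth reference annotation data.frame (rows with a \code{class}
#'   column not equal to \code{"sine"} are dropped from the positive set).
#' @param genome_length genome length (base level only).
#' @param level \code{"base"} or \code{"element"}.
#' @param config a \code{\link{sine_config}}.
#' @return a \code{metric_report}.
#' @export
evaluate_annotation <- function(pred, truth, genome_length = NULL,
                                level = c("element", "base"),
                                config = sine_config()) {
  level <- match.arg(level)
  if (!is.null(truth$class))
    truth <- truth[is.na(truth$class) | truth$class == "sine" |
                     grepl("^sine", truth$class), , drop = FALSE]
  counts <- if (level == "base") {
    if (is.null(genome_length)) stop("genome_length required at base level")
    count_base_level(pred, truth, genome_length)
  } else {
    count_element_level(pred, truth, config$min_overlap)
  }
  compute_metrics(counts)
}
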