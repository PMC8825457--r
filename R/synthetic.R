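# Synthetic plant-like genomes with planted SINE families and the decoy
# repeat classes the screening cascade targets: MITEs (TIR-flanked),
# tandem-dominated elements, long repeated blocks that embed a SINE-like
# core (LINE-fragment geometry), and joined halves of two unrelated repeats
# (truncated-profile geometry). Background is i.i.d. with configurable GC;
# per-copy divergence is substitution-only so that oracle alignments stay
# exact. Box motifs, TSDs, TIR arms, tandem arrays and poly-A tails are
# excluded from mutation so that structural re-detection is well defined at
# moderate divergence.

#' Specification for a synthetic genome
#'
#' @param genome_length total genome length in bp.
#' @param gc_content background GC fraction.
#' @param n_families number of planted SINE families.
#' @param copies_per_family copies planted per family.
#' @param sine_length_range allowed family canonical length range (nt).
#' @param divergence_range per-copy substitution divergence range.
#' @param tsd_length_range TSD length range (nt).
#' @param decoy_counts named integer vector: copies planted per decoy class
#'   (\code{mite}, \code{tandem_array}, \code{line_fragment},
#'   \code{joined_pair}).
#' @param n_records number of FASTA records to split the genome across.
#' @param seed RNG seed; generation is fully reproducible given the spec.
#' @return list of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(genome_length = 200000L, gc_content = 0.4,
                           n_families = 5L, copies_per_family = 8L,
                           sine_length_range = c(100L, 700L),
                           divergence_range = c(0, 0.15),
                           tsd_length_range = c(10L, 20L),
                           decoy_counts = c(mite = 3L, tandem_array = 3L,
                                            line_fragment = 3L,
                                            joined_pair = 1L),
                           n_records = 1L, seed = 1L) {
  spec <- list(genome_length = as.integer(genome_length),
               gc_content = gc_content,
               n_families = as.integer(n_families),
               copies_per_family = as.integer(copies_per_family),
               sine_length_range = as.integer(sine_length_range),
               divergence_range = divergence_range,
               tsd_length_range = as.integer(tsd_length_range),
               decoy_counts = decoy_counts,
               n_records = as.integer(n_records),
               seed = as.integer(seed))
  stopifnot(spec$genome_length > 0, all(decoy_counts >= 0),
            spec$n_families >= 0, spec$copies_per_family >= 0)
  structure(spec, class = "synthetic_spec")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

random_dna <- function(n, gc = 0.4) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# regenerate any stretch that the tail detector itself would call a tail,
# so bodies/spacers never pre-empt the planted tail
sanitize_no_tail <- function(s, config, gc = 0.4) {
  n <- nchar(s)
  if (n < config$tail_min_run) return(s)
  for (iter in 1:50) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- NULL
    for (p in 0:(n - config$tail_min_run)) {
      hit <- qualifying_run_at(chars, p, n, config)
      if (!is.null(hit)) { bad <- hit; break }
    }
    if (is.null(bad)) return(s)
    i <- bad$start + 1L
    j <- min(n, bad$end)
    # balanced shuffled fill cannot form an 80%-majority run or a
    # low-entropy window
    substr(s, i, j) <- paste(sample(rep(c("A", "C", "G", "T"),
                                        length.out = j - i + 1L)),
                             collapse = "")
  }
  s
}

make_tsd <- function(len_range) {
  len <- sample(len_range[1]:len_range[2], 1L)
  head4 <- sample(c("C", "G", "T"), min(4L, len), replace = TRUE)
  rest <- if (len > 4L) sample(c("A", "C", "G", "T"), len - 4L, replace = TRUE)
          else character(0)
  paste(c(head4, rest), collapse = "")
}

random_box_a <- function() paste0(sample(c("G", "A"), 1L),
                                  sample(c("C", "G", "A"), 1L), "TGG")
random_box_b <- function() paste0("CTTA", sample(c("A", "G"), 1L), "A")

mutate_seq <- function(s, rate, protect = integer(0)) {
  if (rate <= 0) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  free <- setdiff(seq_along(chars), protect)
  hit <- free[stats::runif(length(free)) < rate]
  for (i in hit)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  paste(chars, collapse = "")
}

# part-based element assembly: parts is a named-list of c(sequence, protect)
assemble_parts <- function(parts) {
  seqs <- vapply(parts, `[[`, "", 1L)
  prot <- vapply(parts, function(p) isTRUE(p[[2]]), logical(1))
  offs <- cumsum(c(0L, nchar(seqs)))[seq_along(seqs)]
  protect <- unlist(lapply(which(prot), function(i)
    offs[i] + seq_len(nchar(seqs[i]))))
  ranges <- lapply(seq_along(seqs), function(i)
    c(offs[i], offs[i] + nchar(seqs[i])))  # 0-based half-open
  names(ranges) <- names(parts)
  list(seq = paste(seqs, collapse = ""), protect = as.integer(protect),
       ranges = ranges)
}

# after mutation, regenerate any tail-like run the substitutions created in
# the mutable region between box B and the planted tail, so the tail
# detector always lands on the planted tail
resanitize_body <- function(s, body_range, config) {
  if (is.null(body_range) || body_range[2] <= body_range[1]) return(s)
  body <- substr(s, body_range[1] + 1L, body_range[2])
  body2 <- sanitize_no_tail(body, config)
  if (!identical(body, body2))
    substr(s, body_range[1] + 1L, body_range[2]) <- body2
  s
}

has_chance_tir <- function(el, config) {
  # a planted SINE must not carry the defining MITE feature: a pair of
  # reverse-complementary arms in its terminal zones would (correctly) send
  # every copy into the TIR filter
  n <- nchar(el)
  z <- min(config$tir_zone, n)
  left <- substr(el, 1L, z)
  right <- substr(el, max(1L, n - z + 1L), n)
  !is.null(best_tir_pair(left, right, config))
}

build_sine_family <- function(fid, spec, config) {
  lo <- max(spec$sine_length_range[1], 160L)
  hi <- min(spec$sine_length_range[2], 600L)
  dl <- sample(5:10, 1L)
  sp <- sample(config$min_spacing:config$max_spacing, 1L)
  dt <- sample(12:20, 1L)
  target <- sample(lo:hi, 1L)
  db <- max(config$tail_min_offset,
            min(450L, target - (dl + 5L + sp + 6L + dt)))
  gc <- spec$gc_content
  for (attempt in 1:50) {
    parts <- list(
      leader = list(sanitize_no_tail(random_dna(dl, gc), config), FALSE),
      box_a = list(random_box_a(), TRUE),
      spacer = list(sanitize_no_tail(random_dna(sp, gc), config), FALSE),
      box_b = list(random_box_b(), TRUE),
      body = list(sanitize_no_tail(random_dna(db, gc), config), FALSE),
      tail = list(strrep("A", dt), TRUE))
    el <- assemble_parts(parts)
    span <- c(el$ranges$box_b[2], el$ranges$tail[1])
    el$seq <- resanitize_body(el$seq, span, config)
    if (!has_chance_tir(el$seq, config)) break
  }
  list(id = sprintf("fam%02d", fid), canonical = el$seq,
       protect = el$protect, body_range = span, leader_len = dl)
}

plant_copy <- function(fam, spec, class, rate = NULL,
                       tsd_range = spec$tsd_length_range) {
  if (is.null(rate))
    rate <- stats::runif(1, spec$divergence_range[1], spec$divergence_range[2])
  mut <- mutate_seq(fam$canonical, rate, fam$protect)
  mut <- resanitize_body(mut, fam$body_range, sine_config())
  tsd <- make_tsd(tsd_range)
  list(seq = paste0(tsd, mut, tsd),
       inner_start = nchar(tsd), inner_end = nchar(tsd) + nchar(mut),
       family = fam$id, class = class)
}

build_mite_family <- function(spec, config) {
  gc <- spec$gc_content
  arm <- sanitize_no_tail(random_dna(14L, gc), config)
  parts <- list(
    arm_l = list(arm, TRUE),
    leader = list(sanitize_no_tail(random_dna(4L, gc), config), FALSE),
    box_a = list(random_box_a(), TRUE),
    spacer = list(sanitize_no_tail(random_dna(30L, gc), config), FALSE),
    box_b = list(random_box_b(), TRUE),
    body = list(sanitize_no_tail(random_dna(60L, gc), config), FALSE),
    tail = list(strrep("A", 14L), TRUE),
    arm_r = list(revcomp(arm), TRUE))
  el <- assemble_parts(parts)
  span <- c(el$ranges$box_b[2], el$ranges$tail[1])
  el$seq <- resanitize_body(el$seq, span, config)
  list(id = "mite01", canonical = el$seq, protect = el$protect,
       body_range = span)
}

build_tandem_family <- function(spec, config) {
  gc <- spec$gc_content
  unit <- paste(sample(c("A", "C", "G", "T"), 3L), collapse = "")
  array <- strrep(unit, 70L)
  parts <- list(
    leader = list(sanitize_no_tail(random_dna(5L, gc), config), FALSE),
    box_a = list(random_box_a(), TRUE),
    spacer = list(sanitize_no_tail(random_dna(28L, gc), config), FALSE),
    box_b = list(random_box_b(), TRUE),
    body = list(sanitize_no_tail(random_dna(20L, gc), config), FALSE),
    array = list(array, TRUE),
    tail = list(strrep("A", 14L), TRUE))
  el <- assemble_parts(parts)
  span <- c(el$ranges$box_b[2], el$ranges$body[2])
  el$seq <- resanitize_body(el$seq, span, config)
  list(id = "tand01", canonical = el$seq, protect = el$protect,
       body_range = span)
}

build_line_block <- function(spec, config) {
  gc <- spec$gc_content
  itsd <- make_tsd(c(12L, 12L))
  parts <- list(
    flank_l = list(random_dna(380L, gc), FALSE),
    itsd_l = list(itsd, TRUE),
    leader = list(sanitize_no_tail(random_dna(5L, gc), config), FALSE),
    box_a = list(random_box_a(), TRUE),
    spacer = list(sanitize_no_tail(random_dna(30L, gc), config), FALSE),
    box_b = list(random_box_b(), TRUE),
    body = list(sanitize_no_tail(random_dna(120L, gc), config), FALSE),
    tail = list(strrep("A", 15L), TRUE),
    itsd_r = list(itsd, TRUE),
    flank_r = list(random_dna(380L, gc), FALSE))
  el <- assemble_parts(parts)
  span <- c(el$ranges$box_b[2], el$ranges$tail[1])
  el$seq <- resanitize_body(el$seq, span, config)
  list(id = "line01", canonical = el$seq, protect = el$protect,
       body_range = span)
}

build_joined_family <- function(spec, config) {
  gc <- spec$gc_content
  x_block <- sanitize_no_tail(random_dna(240L, gc), config)
  y_core <- sanitize_no_tail(random_dna(225L, gc), config)
  y_block <- paste0(y_core, strrep("A", 15L))
  parts <- list(
    leader = list(sanitize_no_tail(random_dna(6L, gc), config), FALSE),
    box_a = list(random_box_a(), TRUE),
    spacer = list(sanitize_no_tail(random_dna(30L, gc), config), FALSE),
    box_b = list(random_box_b(), TRUE),
    x_half = list(x_block, TRUE),
    linker = list(sanitize_no_tail(random_dna(30L, gc), config), FALSE),
    y_half = list(y_block, TRUE))
  el <- assemble_parts(parts)
  span <- c(el$ranges$box_b[2], el$ranges$y_half[2] - 15L)
  el$seq <- resanitize_body(el$seq, span, config)
  list(joined = list(id = "join01", canonical = el$seq, protect = el$protect,
                     body_range = span),
       x_block = x_block, y_block = y_block)
}

#' Generate a synthetic genome with planted SINEs and decoys
#'
#' Each SINE family has a canonical sequence (box A, 25--50 nt spacer,
#' box B, body, poly-A tail, short leader before box A); copies carry
#' substitution divergence drawn from \code{divergence_range} and are
#' flanked by fresh exact TSDs. Decoy classes: MITEs (14-nt TIR arms plus
#' SINE-like interior and TSDs), tandem-dominated elements (period-3 array
#' covering > 70%), repeated >1 kb blocks embedding a SINE-like core, and
#' joined halves of two unrelated repeats (supporting copies of each half
#' are planted as plain repeat blocks). Elements never overlap; strands are
#' random; placement and gaps are drawn from the seeded RNG, so the same
#' spec always yields a byte-identical genome.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param config a \code{\link{sine_config}} (structural parameters used by
#'   the element builders).
#' @return list of class \code{"sine_sim"}: \code{genome} (a
#'   \code{sine_genome}), \code{truth} (data.frame \code{seqid, start, end,
#'   strand, family, class}), and \code{spec}.
#' @export
generate_genome <- function(spec, config = sine_config()) {
  with_seed(spec$seed, {
    inserts <- list()
    add <- function(x) inserts[[length(inserts) + 1L]] <<- x
    if (spec$n_families > 0L) {
      for (f in seq_len(spec$n_families)) {
        fam <- build_sine_family(f, spec, config)
        for (k in seq_len(spec$copies_per_family))
          add(plant_copy(fam, spec, "sine"))
      }
    }
    dc <- spec$decoy_counts
    n_of <- function(k) if (!is.na(dc[k])) as.integer(dc[k]) else 0L
    if (n_of("mite") > 0L) {
      fam <- build_mite_family(spec, config)
      for (k in seq_len(n_of("mite")))
        add(plant_copy(fam, spec, "decoy:mite", tsd_range = c(10L, 12L)))
    }
    if (n_of("tandem_array") > 0L) {
      fam <- build_tandem_family(spec, config)
      for (k in seq_len(n_of("tandem_array")))
        add(plant_copy(fam, spec, "decoy:tandem_array"))
    }
    if (n_of("line_fragment") > 0L) {
      fam <- build_line_block(spec, config)
      for (k in seq_len(n_of("line_fragment"))) {
        mut <- mutate_seq(fam$canonical, 0.01, fam$protect)
        mut <- resanitize_body(mut, fam$body_range, config)
        add(list(seq = mut, inner_start = 0L, inner_end = nchar(mut),
                 family = fam$id, class = "decoy:line_fragment"))
      }
    }
    if (n_of("joined_pair") > 0L) {
      jf <- build_joined_family(spec, config)
      for (k in seq_len(n_of("joined_pair")))
        add(plant_copy(jf$joined, spec, "decoy:joined_pair", rate = 0))
      for (k in 1:3) {
        for (blk in list(c("x", jf$x_block), c("y", jf$y_block))) {
          mut <- mutate_seq(blk[2], 0.01)
          add(list(seq = mut, inner_start = 0L, inner_end = nchar(mut),
                   family = paste0("join01_", blk[1]),
                   class = "decoy:repeat_block"))
        }
      }
    }
    # random strand per insert
    for (i in seq_along(inserts)) {
      strand <- sample(c("+", "-"), 1L)
      inserts[[i]]$strand <- strand
      if (strand == "-") {
        n <- nchar(inserts[[i]]$seq)
        is0 <- inserts[[i]]$inner_start
        ie0 <- inserts[[i]]$inner_end
        inserts[[i]]$seq <- revcomp(inserts[[i]]$seq)
        inserts[[i]]$inner_start <- n - ie0
        inserts[[i]]$inner_end <- n - is0
      }
    }
    # distribute across records and place with random gaps (min 150 bp)
    nrec <- spec$n_records
    rec_len <- spec$genome_length %/% nrec
    rec_of <- rep(seq_len(nrec), length.out = length(inserts))
    if (length(inserts)) rec_of <- rec_of[sample(length(inserts))]
    seqs <- character(nrec)
    truth <- list()
    for (r in seq_len(nrec)) {
      idx <- which(rec_of == r)
      ins <- inserts[idx]
      if (length(ins) > 1L) ins <- ins[sample(length(ins))]
      total_ins <- sum(vapply(ins, function(x) nchar(x$seq), numeric(1)))
      min_gap <- 150L
      k <- length(ins)
      slack <- rec_len - total_ins - min_gap * (k + 1L)
      if (slack < 0L)
        stop("infeasible spec: planted elements exceed genome length")
      cuts <- sort(stats::runif(k, 0, slack))
      extra <- diff(c(0, cuts, slack))
      sid <- sprintf("chr%d", r)
      pos <- 0L
      pieces <- character(0)
      for (j in seq_len(k)) {
        gap <- min_gap + as.integer(round(extra[j]))
        pieces <- c(pieces, random_dna(gap, spec$gc_content))
        pos <- pos + gap
        pieces <- c(pieces, ins[[j]]$seq)
        truth[[length(truth) + 1L]] <- data.frame(
          seqid = sid,
          start = pos + ins[[j]]$inner_start,
          end = pos + ins[[j]]$inner_end,
          strand = ins[[j]]$strand,
          family = ins[[j]]$family, class = ins[[j]]$class,
          stringsAsFactors = FALSE)
        pos <- pos + nchar(ins[[j]]$seq)
      }
      tail_gap <- rec_len - pos
      if (tail_gap > 0L)
        pieces <- c(pieces, random_dna(tail_gap, spec$gc_content))
      seqs[r] <- paste(pieces, collapse = "")
    }
    names(seqs) <- sprintf("chr%d", seq_len(nrec))
    truth_df <- if (length(truth)) do.call(rbind, truth) else
      data.frame(seqid = character(0), start = integer(0), end = integer(0),
                 strand = character(0), family = character(0),
                 class = character(0), stringsAsFactors = FALSE)
    truth_df <- truth_df[order(truth_df$seqid, truth_df$start), , drop = FALSE]
    rownames(truth_df) <- NULL
    structure(list(genome = sine_genome(seqs), truth = truth_df, spec = spec),
              class = "sine_sim")
  })
}

#' @export
print.sine_sim <- function(x, ...) {
  cat("sine_sim:", sum(x$genome$lengths), "bp,",
      sum(x$truth$class == "sine"), "planted SINEs,",
      sum(x$truth$class != "sine"), "decoy elements\n")
  invisible(x)
}

#' Write a truth set to GFF3
#'
#' One record per planted element, with \code{family} and \code{class}
#' attributes; readable by \code{\link{read_annotation}}.
#'
#' @param truth truth data.frame from \code{\link{generate_genome}}.
#' @param path output GFF3 file.
#' @return \code{path}, invisibly.
#' @export
write_truth <- function(truth, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = truth$seqid,
    ranges = IRanges::IRanges(start = truth$start + 1L, end = truth$end),
    strand = truth$strand)
  S4Vectors::mcols(gr)$source <- "sinescout_sim"
  S4Vectors::mcols(gr)$type <- "dispersed_repeat"
  S4Vectors::mcols(gr)$ID <- sprintf("el%05d", seq_along(gr))
  S4Vectors::mcols(gr)$family <- truth$family
  S4Vectors::mcols(gr)$class <- truth$class
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a truth set written by \code{write_truth}
#' @param path GFF3 file.
#' @return truth data.frame.
#' @export
read_truth <- function(path) {
  df <- read_annotation(path)
  out <- df[, c("seqid", "start", "end", "strand", "family", "class")]
  rownames(out) <- NULL
  out
}
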