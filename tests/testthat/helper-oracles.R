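# Independent brute-force oracles, written as plain nested loops so they
# share no code path with the package implementation.

rand_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# all box A / box B pairs with spacing (bases strictly between) in
# [min_sp, max_sp]; naive character checks, no regex
bf_box_pairs <- function(seq, min_sp = 25, max_sp = 50) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  is_a <- function(i) {
    i + 4 <= n &&
      ch[i] %in% c("G", "A") && ch[i + 1] %in% c("C", "G", "A") &&
      ch[i + 2] == "T" && ch[i + 3] == "G" && ch[i + 4] == "G"
  }
  is_b <- function(i) {
    i + 5 <= n &&
      ch[i] == "C" && ch[i + 1] == "T" && ch[i + 2] == "T" &&
      ch[i + 3] == "A" && ch[i + 4] %in% c("A", "G") && ch[i + 5] == "A"
  }
  a_pos <- Filter(is_a, seq_len(n))
  b_pos <- Filter(is_b, seq_len(n))
  out <- NULL
  for (a in a_pos) {
    for (b in b_pos) {
      sp <- (b - 1) - (a - 1 + 5)  # 0-based: b0 - (a0 + 5)
      if (sp >= min_sp && sp <= max_sp)
        out <- rbind(out, data.frame(a0 = a - 1, b0 = b - 1, spacing = sp))
    }
  }
  out
}

count_mismatch <- function(x, y) {
  cx <- strsplit(x, "", fixed = TRUE)[[1]]
  cy <- strsplit(y, "", fixed = TRUE)[[1]]
  sum(cx != cy)
}

# best TSD pair by exhaustive triple loop; returns best score (and the
# length achieving it) or NULL
bf_tsd_best <- function(up, down, min_len = 10, max_len = 20,
                        max_mism = 1, penalty = 1) {
  best <- NULL
  for (l in min_len:max_len) {
    if (l > nchar(up) || l > nchar(down)) next
    for (i in seq_len(nchar(up) - l + 1)) {
      for (j in seq_len(nchar(down) - l + 1)) {
        mm <- count_mismatch(substr(up, i, i + l - 1),
                             substr(down, j, j + l - 1))
        if (mm <= max_mism) {
          sc <- (l - mm) - penalty * mm
          if (is.null(best) || sc > best$score)
            best <- list(score = sc, length = l, mismatches = mm)
        }
      }
    }
  }
  best
}

rc_naive <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

# longest reverse-complementary arm pair across two zones, mismatch budget
bf_tir_best <- function(left, right, min_arm = 10, max_mism = 1) {
  best <- 0L
  for (l in min_arm:min(nchar(left), nchar(right))) {
    for (i in seq_len(nchar(left) - l + 1)) {
      for (j in seq_len(nchar(right) - l + 1)) {
        mm <- count_mismatch(substr(left, i, i + l - 1),
                             rc_naive(substr(right, j, j + l - 1)))
        if (mm <= max_mism && l > best) best <- l
      }
    }
  }
  if (best == 0L) NULL else best
}

# per-position tally of coverage from (q_start, q_end) half-open ranges
bf_tally <- function(q_start, q_end, L) {
  counts <- integer(L)
  for (p in seq_len(L)) {
    for (i in seq_along(q_start)) {
      if (p - 1 >= q_start[i] && p - 1 < q_end[i])
        counts[p] <- counts[p] + 1L
    }
  }
  counts
}

# naive tandem coverage: for each period, every window of comparisons with
# >= 80% matches marks the spanned positions (window plus one period)
bf_tandem_cover <- function(s, max_period = 6, min_copies = 3,
                            min_span = 8, min_ident = 0.8) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  cov <- logical(n)
  for (p in 1:max_period) {
    if (n <= p) next
    w <- max((min_copies - 1) * p, min_span)
    if (n - p < w) next
    for (j in 1:(n - p - w + 1)) {
      matches <- 0
      for (k in 0:(w - 1))
        if (ch[j + k] == ch[j + k + p]) matches <- matches + 1
      if (matches >= min_ident * w)
        cov[j:min(n, j + w - 1 + p)] <- TRUE
    }
  }
  mean(cov)
}

# build a copy_profile object directly from a counts layout
make_profile <- function(counts, hits = NULL, s_pos = NULL, e_pos = NULL) {
  L <- length(counts)
  if (is.null(hits))
    hits <- data.frame(seqid = character(0), s_start = integer(0),
                       s_end = integer(0), strand = character(0),
                       q_start = integer(0), q_end = integer(0),
                       length = integer(0), identity = numeric(0),
                       score = numeric(0), evalue = numeric(0),
                       self = logical(0))
  structure(list(counts = as.integer(counts), T = nrow(hits), L = L,
                 window = list(seqid = "chr1", start = 0L, end = L),
                 s_pos = if (is.null(s_pos)) 100L else s_pos,
                 e_pos = if (is.null(e_pos)) L - 100L else e_pos,
                 hits = hits, i_start = NA_integer_, i_end = NA_integer_,
                 profile_class = NA_character_),
            class = "copy_profile")
}

# hits table row helper
hit_row <- function(q_start, q_end, self = FALSE, identity = 0.95) {
  data.frame(seqid = "chr1", s_start = 0L, s_end = q_end - q_start,
             strand = "+", q_start = q_start, q_end = q_end,
             length = q_end - q_start, identity = identity,
             score = q_end - q_start, evalue = 1e-20, self = self)
}

# one-row candidate helper
cand_row <- function(seqid, start, end, strand = "+", id = "c1") {
  data.frame(id = id, seqid = seqid, start = start, end = end,
             strand = strand, source = "structural", status = "raw",
             filter_reason = NA_character_,
             box_a_start = NA_integer_, box_a_end = NA_integer_,
             box_b_start = NA_integer_, box_b_end = NA_integer_,
             spacing = NA_integer_, tail_start = NA_integer_,
             tail_end = NA_integer_, tail_kind = NA_character_,
             tsd_len = NA_integer_, tsd_mismatches = NA_integer_,
             tsd_left_start = NA_integer_, tsd_left_end = NA_integer_,
             tsd_right_start = NA_integer_, tsd_right_end = NA_integer_,
             stringsAsFactors = FALSE)
}

# a canonical SINE-like element assembled from explicit parts
toy_element <- function(spacing = 35, body = 120, tail = 15, leader = 6,
                        gc = 0.4) {
  paste0(rand_dna(leader, gc), "GATGG", rand_dna(spacing, gc), "CTTAAA",
         gsub("A{4,}|T{4,}", "GCGC", rand_dna(body, gc)), strrep("A", tail))
}
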