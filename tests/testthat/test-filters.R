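toy_trna <- function() {
  set.seed(1234)
  rand_dna(75, gc = 0.55)
}

test_that("superfamily labelling keeps SINEs but drops ncRNA genes", {
  trna <- toy_trna()
  refs <- data.frame(id = "trna1", type = "tRNA", sequence = trna,
                     stringsAsFactors = FALSE)
  set.seed(9)
  # candidate whose 75-nt head is ~85% identical to the reference
  head_mut <- trna
  pos <- sample(75, 11)
  ch <- strsplit(head_mut, "")[[1]]
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  head_mut <- paste(ch, collapse = "")
  cand_seq <- paste0(head_mut, rand_dna(150))
  call <- classify_superfamily(cand_seq, refs)
  expect_equal(call$label, "tRNA")
  expect_true(call$keep)

  # a candidate that IS the reference is an ncRNA gene, not a SINE
  call2 <- classify_superfamily(trna, refs)
  expect_false(call2$keep)

  # no similarity at all
  call3 <- classify_superfamily(rand_dna(250), refs)
  expect_equal(call3$label, "unknown")
  expect_true(call3$keep)

  # missing reference set: warn, keep
  expect_warning(call4 <- classify_superfamily(cand_seq, NULL), "skipped")
  expect_true(call4$keep)
})

test_that("stricter ncRNA exclusion thresholds never remove more candidates", {
  trna <- toy_trna()
  refs <- data.frame(id = "trna1", type = "tRNA", sequence = trna,
                     stringsAsFactors = FALSE)
  set.seed(41)
  cands <- c(trna, paste0(trna, rand_dna(20)), paste0(trna, rand_dna(150)),
             rand_dna(250), rand_dna(80))
  keep_loose <- vapply(cands, function(s)
    classify_superfamily(s, refs, sine_config(exclusion_evalue = 1e-15))$keep,
    logical(1))
  keep_strict <- vapply(cands, function(s)
    classify_superfamily(s, refs, sine_config(exclusion_evalue = 1e-40))$keep,
    logical(1))
  expect_true(all(keep_strict >= keep_loose))
})

test_that("tandem fraction matches planted array extent", {
  expect_equal(tandem_fraction(strrep("AC", 100)), 1.0)

  # 300-nt candidate with a 60-nt microsatellite: ~20%, kept at the 70% rule
  set.seed(66)
  s <- paste0(rand_dna(120), strrep("AGT", 20), rand_dna(120))
  f <- tandem_fraction(s)
  expect_gt(f, 0.15)
  expect_lt(f, 0.30)

  # planted arrays of known extent across 50 random sequences: the fraction
  # matches an exhaustive small-period autocorrelation oracle exactly, and
  # tracks the planted extent (boundary windows can only over-extend into
  # the flanks, by a bounded amount)
  set.seed(14)
  for (trial in 1:50) {
    n <- 1200L
    alen <- sample(c(240L, 360L, 600L, 960L), 1)
    unit <- paste(sample(c("A", "C", "G", "T"),
                         sample(2:4, 1)), collapse = "")
    array <- substr(strrep(unit, alen), 1, alen)
    pre <- sample(0:(n - alen), 1)
    s <- paste0(rand_dna(pre), array, rand_dna(n - alen - pre))
    f <- tandem_fraction(s)
    expect_equal(f, bf_tandem_cover(s))
    expect_gte(f, alen / n - 0.01)
    expect_lte(f, alen / n + 0.08)
  }
})

test_that("tandem fraction is invariant under reversal and complementation", {
  set.seed(8)
  for (trial in 1:10) {
    s <- paste0(rand_dna(80), strrep("A", 30), rand_dna(40),
                strrep("GT", 25), rand_dna(80))
    f <- tandem_fraction(s)
    rev <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(tandem_fraction(rev), f)
    expect_equal(tandem_fraction(revcomp(s)), f)
  }
})

test_that("terminal inverted repeats are detected and brute-force optimal", {
  set.seed(19)
  arm <- "GATTACCGGTAGCA"  # 14 nt
  interior <- rand_dna(150)
  el <- paste0(arm, interior, revcomp(arm))
  g <- sine_genome(c(chr1 = paste0(rand_dna(300), el, rand_dna(300))))
  cand <- cand_row("chr1", 300L, 300L + nchar(el))
  hit <- find_tir(cand, g)
  expect_false(is.null(hit))
  expect_gte(hit$arm_length, 14L)

  # a SINE-like element without inverted termini
  el2 <- toy_element()
  g2 <- sine_genome(c(chr1 = paste0(rand_dna(300), el2, rand_dna(300))))
  expect_null(find_tir(cand_row("chr1", 300L, 300L + nchar(el2)), g2))

  # maximal arm equals brute-force enumeration over zone substring pairs
  cfg <- sine_config()
  for (trial in 1:100) {
    left <- rand_dna(50)
    right <- rand_dna(50)
    if (trial %% 2 == 0) {
      l <- sample(10:16, 1)
      a <- rand_dna(l)
      i <- sample(1:(50 - l + 1), 1); j <- sample(1:(50 - l + 1), 1)
      substr(left, i, i + l - 1) <- a
      substr(right, j, j + l - 1) <- revcomp(a)
    }
    gz <- sine_genome(c(chr1 = paste0(left, strrep("C", 60), right)))
    got <- find_tir(cand_row("chr1", 0L, 160L), gz)
    want <- bf_tir_best(left, right)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$arm_length, want)
    }
  }
})

test_that("TIR detection is symmetric under reverse complement", {
  set.seed(27)
  arm <- rand_dna(12)
  el <- paste0(arm, rand_dna(140), revcomp(arm))
  g1 <- sine_genome(c(chr1 = paste0(rand_dna(200), el, rand_dna(200))))
  g2 <- sine_genome(c(chr1 = paste0(rand_dna(200), revcomp(el),
                                    rand_dna(200))))
  h1 <- find_tir(cand_row("chr1", 200L, 200L + nchar(el)), g1)
  h2 <- find_tir(cand_row("chr1", 200L, 200L + nchar(el)), g2)
  expect_equal(h1$arm_length, h2$arm_length)
})
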