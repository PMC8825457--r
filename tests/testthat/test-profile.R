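test_that("profile counts are a per-position coverage tally", {
  hits <- do.call(rbind, lapply(1:3, function(i) hit_row(50L, 150L)))
  hits$self <- c(TRUE, FALSE, FALSE)
  prof <- build_profile(list(hits = hits, L = 400L, s_pos = 100L,
                             e_pos = 300L,
                             window = list(seqid = "chr1", start = 0L,
                                           end = 400L)))
  expect_equal(prof$T, 3L)
  expect_equal(prof$counts[51:150], rep(3L, 100))
  expect_equal(sum(prof$counts), 300L)

  # oracle equivalence on random layouts
  set.seed(88)
  for (trial in 1:100) {
    n <- sample(1:10, 1)
    q0 <- sample(0:350, n, replace = TRUE)
    q1 <- pmin(400L, q0 + sample(10:100, n, replace = TRUE))
    hits <- do.call(rbind, lapply(seq_len(n), function(i)
      hit_row(q0[i], q1[i])))
    prof <- build_profile(list(hits = hits, L = 400L, s_pos = 100L,
                               e_pos = 300L,
                               window = list(seqid = "chr1", start = 0L,
                                             end = 400L)))
    expect_equal(prof$counts, bf_tally(q0, q1, 400L))
  }
})

test_that("low-copy profiles are flagged by the copy threshold", {
  prof <- build_profile(list(hits = hit_row(0L, 400L, self = TRUE),
                             L = 400L, s_pos = 100L, e_pos = 300L,
                             window = list(seqid = "chr1", start = 0L,
                                           end = 400L)),
                        sine_config(min_copies = 2))
  expect_equal(prof$profile_class, "low_copy")
  expect_equal(classify_profile(prof, sine_config(min_copies = 2)),
               "low_copy")
})

test_that("boundary refinement applies the strict tau*T rule", {
  counts <- integer(400)
  counts[21:150] <- 6L   # above 0.5 * 10 = 5, strictly
  counts[c(1:20, 151:400)] <- 3L
  prof <- make_profile(counts, hits = do.call(rbind, lapply(1:10, function(i)
    hit_row(20L, 150L, self = i == 1))))
  ref <- refine_boundaries(prof, sine_config(tau = 0.5))
  expect_equal(ref$i_start, 20L)
  expect_equal(ref$i_end, 149L)

  # counts exactly at tau*T are not above it
  counts5 <- counts
  counts5[21:150] <- 5L
  prof5 <- make_profile(counts5, hits = prof$hits)
  expect_null(refine_boundaries(prof5, sine_config(tau = 0.5)))

  # copies extending past the original 3' end pull the boundary outward
  counts2 <- integer(400)
  counts2[101:360] <- 8L  # 60 nt beyond e_pos = 300
  prof2 <- make_profile(counts2, s_pos = 100L, e_pos = 300L,
                        hits = do.call(rbind, lapply(1:10, function(i)
                          hit_row(100L, 360L, self = i == 1))))
  ref2 <- refine_boundaries(prof2, sine_config(tau = 0.5))
  expect_equal(ref2$i_end, 359L)
})

test_that("profile classes follow the gap, extension and shift rules", {
  cfg <- sine_config()
  base_hits <- do.call(rbind, lapply(1:10, function(i)
    hit_row(100L, 300L, self = i == 1)))

  # interior sub-threshold run of 12 bp -> truncated
  counts <- integer(400)
  counts[101:300] <- 8L
  counts[181:192] <- 2L
  prof <- make_profile(counts, hits = base_hits, s_pos = 100L, e_pos = 300L)
  prof <- refine_boundaries(prof, cfg)
  expect_equal(classify_profile(prof, cfg), "truncated")

  # gap of exactly 10 bp is tolerated
  counts10 <- integer(400)
  counts10[101:300] <- 8L
  counts10[181:190] <- 2L
  prof10 <- refine_boundaries(make_profile(counts10, hits = base_hits,
                                           s_pos = 100L, e_pos = 300L), cfg)
  expect_equal(classify_profile(prof10, cfg), "clean")

  # boundary shifted by 60 nt -> shifted; by 50 -> clean
  counts_sh <- integer(400)
  counts_sh[41:300] <- 8L  # i_start = 40, s_pos = 100
  prof_sh <- refine_boundaries(make_profile(counts_sh, hits = base_hits,
                                            s_pos = 100L, e_pos = 300L), cfg)
  expect_equal(classify_profile(prof_sh, cfg), "shifted")
  counts_ok <- integer(400)
  counts_ok[51:300] <- 8L  # shift exactly 50: tolerated
  prof_ok <- refine_boundaries(make_profile(counts_ok, hits = base_hits,
                                            s_pos = 100L, e_pos = 300L), cfg)
  expect_equal(classify_profile(prof_ok, cfg), "clean")

  # 7 of 10 non-self copies running into the window edge -> extended
  ext_hits <- rbind(hit_row(100L, 300L, self = TRUE),
                    do.call(rbind, lapply(1:7, function(i) hit_row(0L, 400L))),
                    do.call(rbind, lapply(1:3, function(i)
                      hit_row(100L, 300L))))
  counts_ext <- bf_tally(ext_hits$q_start, ext_hits$q_end, 400L)
  prof_ext <- refine_boundaries(make_profile(counts_ext, hits = ext_hits,
                                             s_pos = 100L, e_pos = 300L), cfg)
  expect_equal(classify_profile(prof_ext, cfg), "extended")
})

test_that("copy collection finds planted copies and applies the length factor", {
  set.seed(17)
  unit <- rand_dna(300)
  pieces <- c(rand_dna(1500))
  starts <- integer(0)
  for (k in 1:6) {
    pieces <- c(pieces, unit, rand_dna(1200))
    starts <- c(starts, sum(nchar(pieces)) - 1200L - 300L)
  }
  # one extra locus sharing only a 20% fragment
  frag <- substr(unit, 1, 100)
  pieces <- c(pieces, frag, rand_dna(800))
  g <- sine_genome(c(chr1 = paste(pieces, collapse = "")))
  cand <- cand_row("chr1", starts[1], starts[1] + 300L)
  cfg <- sine_config(alpha = 0.3)
  copies <- collect_copies(cand, g, cfg)
  expect_equal(sum(copies$hits$self), 1L)
  expect_equal(nrow(copies$hits), 6L)  # 5 planted copies incl. self + nothing else at alpha 0.3
  # the 100-nt fragment (0.2 * L) is excluded by the alpha rule
  expect_false(any(abs(copies$hits$s_start - (sum(nchar(pieces)) - 800L - 100L)) < 50))

  # a unique sequence yields exactly the self hit
  g2 <- sine_genome(c(chr1 = paste0(rand_dna(2000), rand_dna(300),
                                    rand_dna(2000))))
  cand2 <- cand_row("chr1", 2000L, 2300L)
  copies2 <- collect_copies(cand2, g2, cfg)
  expect_equal(nrow(copies2$hits), 1L)
  expect_true(copies2$hits$self)
})

test_that("profile screening keeps clean planted families end to end", {
  set.seed(23)
  sim <- generate_genome(synthetic_spec(
    genome_length = 40000, n_families = 2, copies_per_family = 5,
    divergence_range = c(0, 0.08),
    decoy_counts = c(mite = 0, tandem_array = 0, line_fragment = 0,
                     joined_pair = 0), seed = 23))
  cands <- scan_structural_candidates(sim$genome)
  v <- verify_candidates(cands, sim$genome)
  p <- profile_screen(v$kept, sim$genome)
  expect_gt(nrow(p$kept), 0)
  expect_true(all(p$kept$status == "profile_passed"))
  cls <- vapply(p$profiles, function(x) x$profile_class, character(1))
  expect_true(all(cls[p$kept$id] == "clean"))
})
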