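mut_exact <- function(s, k) {
  # exactly k substitutions at distinct positions
  ch <- strsplit(s, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

test_that("track merging unions candidates and collapses overlaps", {
  a <- do.call(rbind, lapply(1:3, function(i)
    cand_row("chr1", i * 1000L, i * 1000L + 300L, id = paste0("a", i))))
  b <- do.call(rbind, lapply(1:2, function(i)
    cand_row("chr1", 10000L + i * 1000L, 10000L + i * 1000L + 300L,
             id = paste0("b", i))))
  b$source <- "homology"
  m <- merge_tracks(a, b)
  expect_equal(nrow(m), 5L)

  # identical interval in both tracks -> one candidate, provenance both
  b2 <- a[1, ]; b2$source <- "homology"; b2$id <- "bx"
  m2 <- merge_tracks(a[1, ], b2)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$source, "both")

  # nested: 200 nt inside 400 nt -> the longer kept
  long <- cand_row("chr1", 1000L, 1400L, id = "L")
  short <- cand_row("chr1", 1100L, 1300L, id = "S")
  short$source <- "homology"
  m3 <- merge_tracks(long, short)
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$end - m3$start, 400L)
})

test_that("greedy clustering follows the 80% identity rule exactly", {
  set.seed(7)
  A <- rand_dna(300)
  B <- mut_exact(A, 45)   # identity 0.85
  C <- rand_dna(300)
  seeds <- data.frame(id = c("A", "B", "C"), sequence = c(A, B, C),
                      seqid = "chr1", start = c(0L, 1000L, 2000L),
                      end = c(300L, 1300L, 2300L), strand = "+",
                      superfamily = "unknown", cluster_id = NA_integer_,
                      is_representative = NA, stringsAsFactors = FALSE)
  lib <- cluster_seeds(seeds)
  red <- lib$redundant
  expect_equal(red$cluster_id[red$id == "A"], red$cluster_id[red$id == "B"])
  expect_false(red$cluster_id[red$id == "C"] == red$cluster_id[red$id == "A"])
  expect_equal(nrow(lib$nonredundant), 2L)

  # identities straddling the cutoff: 75% no, 80% yes, 85% yes
  for (k in c(75L, 60L, 45L)) {
    other <- mut_exact(A, k)
    seeds2 <- seeds[1:2, ]
    seeds2$sequence <- c(A, other)
    lib2 <- cluster_seeds(seeds2)
    same <- lib2$redundant$cluster_id[1] == lib2$redundant$cluster_id[2]
    expect_equal(same, (300 - k) / 300 >= 0.80, info = paste("k =", k))
  }

  # five identical sequences -> one cluster
  seeds5 <- do.call(rbind, lapply(1:5, function(i) {
    s <- seeds[1, ]; s$id <- paste0("s", i); s$start <- i * 1000L
    s$end <- i * 1000L + 300L; s
  }))
  lib5 <- cluster_seeds(seeds5)
  expect_equal(length(unique(lib5$redundant$cluster_id)), 1L)
  expect_equal(nrow(lib5$nonredundant), 1L)
})

test_that("cluster representatives are the longest members and nonredundant", {
  set.seed(70)
  A <- rand_dna(400)
  shorter <- substr(mut_exact(A, 20), 51, 400)  # high identity, shorter
  C <- rand_dna(350)
  seeds <- data.frame(id = c("short", "long", "C"),
                      sequence = c(shorter, A, C), seqid = "chr1",
                      start = c(0L, 1000L, 2000L),
                      end = c(350L, 1400L, 2350L), strand = "+",
                      superfamily = "unknown", cluster_id = NA_integer_,
                      is_representative = NA, stringsAsFactors = FALSE)
  lib <- cluster_seeds(seeds)
  reps <- lib$nonredundant
  expect_true("long" %in% reps$id)
  expect_false("short" %in% reps$id)
  # all representative pairs are below the cutoff
  cfg <- sine_config()
  if (nrow(reps) > 1) {
    for (i in 1:(nrow(reps) - 1)) {
      for (j in (i + 1):nrow(reps)) {
        ident <- sinescout:::seed_identity(reps$sequence[i],
                                           reps$sequence[j], cfg)
        expect_lt(ident, cfg$cluster_identity)
      }
    }
  }
})

test_that("genome annotation honours the divergence cap", {
  set.seed(33)
  seed_seq <- rand_dna(300)
  divs <- seq(0, 0.27, by = 0.03)  # ten copies at 0-30% divergence
  pieces <- rand_dna(1000)
  loci <- integer(0)
  for (d in divs) {
    copy <- mut_exact(seed_seq, round(d * 300))
    loci <- c(loci, nchar(pieces))
    pieces <- paste0(pieces, copy, rand_dna(1000))
  }
  far <- mut_exact(seed_seq, round(0.45 * 300))
  far_at <- nchar(pieces)
  pieces <- paste0(pieces, far, rand_dna(1000))
  g <- sine_genome(c(chr1 = pieces))
  seeds <- data.frame(id = "seed1", sequence = seed_seq, seqid = "chr1",
                      start = loci[1], end = loci[1] + 300L, strand = "+",
                      superfamily = "unknown", cluster_id = 1L,
                      is_representative = TRUE, stringsAsFactors = FALSE)
  ann <- annotate_genome(g, seeds)
  expect_equal(nrow(ann), length(divs))
  # the self locus is annotated at divergence 0
  self <- ann[abs(ann$start - loci[1]) < 20, ]
  expect_equal(self$divergence, 0)
  # the 45%-divergent copy is not annotated
  expect_false(any(ann$start > far_at - 50 & ann$start < far_at + 50))
  expect_true(all(ann$divergence <= 0.40))

  expect_warning(empty <- annotate_genome(g, structure(
    list(redundant = seeds[0, ], nonredundant = seeds[0, ]),
    class = "seed_library")), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("annotation is idempotent on the masked genome", {
  set.seed(77)
  seed_seq <- rand_dna(250)
  g <- sine_genome(c(chr1 = paste0(rand_dna(800), seed_seq, rand_dna(800),
                                   mut_exact(seed_seq, 25), rand_dna(800))))
  seeds <- data.frame(id = "s", sequence = seed_seq, seqid = "chr1",
                      start = 800L, end = 1050L, strand = "+",
                      superfamily = "unknown", cluster_id = 1L,
                      is_representative = TRUE, stringsAsFactors = FALSE)
  ann <- annotate_genome(g, seeds)
  expect_gte(nrow(ann), 2L)
  chars <- strsplit(g$seqs[["chr1"]], "")[[1]]
  for (i in seq_len(nrow(ann)))
    chars[(ann$start[i] + 1):ann$end[i]] <- "N"
  g_masked <- sine_genome(c(chr1 = paste(chars, collapse = "")))
  ann2 <- annotate_genome(g_masked, seeds)
  expect_equal(nrow(ann2), 0L)
})
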