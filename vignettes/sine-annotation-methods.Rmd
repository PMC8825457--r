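---
title: "Annotating SINEs from structure: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating SINEs from structure: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinescout)
```

## The annotation problem

Short interspersed nuclear elements (SINEs) are non-LTR retrotransposons,
typically 100–700 bp, built from an RNA-polymerase-III-derived head (most
often tRNA-related, sometimes 7SL RNA or 5S rRNA), a body of variable
origin, and a low-complexity 3' tail. In plants they are rarely more than
a percent of the genome, yet they sit near genes and matter for
regulation, so accurate genome-scale annotation is worth having. The
difficulty is that none of the SINE features is individually reliable:
the box A/B promoter motifs are short and degenerate, the tail is generic
low-complexity sequence, and sequence conservation decays quickly across
species. A scan for structural features alone therefore produces mostly
false positives, while a library-based homology search alone misses novel
families.

`sinescout` follows a discover-then-screen design. Candidate discovery is
deliberately permissive (structural scan, or imported profile-HMM homology
hits, or both); a cascade of filters then removes false positives, with
each filter targeting a specific class of non-SINE repeat that mimics some
SINE features. The one feature that is nearly diagnostic of a true
retrotransposition event — the target site duplication (TSD) — anchors the
screen; the rest of the cascade exploits how genome-wide *copies* of a
candidate align back to it, and the terminal/compositional features that
distinguish MITEs, tandem arrays and ncRNA genes from real SINEs. Finally,
only verified intact elements ("seeds") enter the library; every other
family member, including fragmented and TSD-less copies, is recovered by
aligning the library back to the genome. This is why losing an individual
intact copy to a conservative filter is cheap: one surviving seed per
family annotates all of its relatives.

## Pipeline stages and their parameters

All coordinates are 0-based and half-open internally; conversions to GFF3
(1-based inclusive) and BED happen only at format boundaries.

### Structural discovery

Box A is matched as `[GA][CGA]TGG` (5 nt) and box B as `CTTA[AG]A`
(6 nt), exactly — the degeneracy lives in the patterns, so no mismatch
budget is layered on top. A legal pair has 25–50 bases strictly between
the motifs (`min_spacing`, `max_spacing`). The tail must begin 20–500 nt
after box B (`tail_min_offset`, `tail_max_offset`) and is either a
poly(A)/poly(T) run (≥ 6 nt at ≥ 80% majority base; `tail_min_run`,
`tail_min_purity`) or an "other low complexity" stretch (a 10 nt window
with dinucleotide Shannon entropy < 1.2 bits; `lc_window`,
`lc_max_entropy`). The poly thresholds accept textbook tails while a
qualifying window arises in < 5% of uniform random scans; the entropy
cutoff corresponds to roughly two effective dinucleotides.

Three behaviours of the tail detector deserve note, because each was a
deliberate choice:

* **Run starts only.** A run that began before the legal offset window is
  not reported mid-run; the detector requires the previous base (or
  previous window, for low-complexity) not to qualify. A tail closer than
  20 nt to box B therefore disqualifies, rather than being picked up at
  its 20th base.
* **Bounded absorption.** Run extension tolerates interior foreign bases
  within the purity budget but stops after more than two consecutive
  foreign bases, then trims back to the last majority base. Without the
  cap, a 16-A tail followed by a TSD containing an A at its fifth
  position would absorb the start of the TSD and shift the candidate's 3'
  terminus into it.
* **Poly over low-complexity.** When a low-complexity window merely leads
  into a poly run starting inside it, the poly run is reported: it is the
  more specific call and its trimmed end does not spill into the flank.

Records are sliced into 10 kb fragments with 2 kb overlap for the motif
search (tails are sought in the whole record), so fragmentation never
truncates an element shorter than the overlap; duplicate intervals from
overlapping fragments are removed. Both strands are scanned and
minus-strand hits are reported in forward coordinates.

When several box pairs share one tail, all are kept at this stage. An
earlier design picked a single "best" pair per tail, but every in-range
pair is equally legal a priori, and any positional tie-break systematically
prefers chance flank motifs over the true pair, which then misplaces the
TSD search window. TSD verification is the natural arbiter: the pairs that
survive it refine to the same TSD-delimited interval and collapse to one
candidate.

The provisional 5' boundary sits at box A (the true start, including any
short leader, lies within the TSD search window upstream); both boundaries
are refined twice downstream, first to the TSD inner edges, then by the
copy-number profile.

### TSD verification

Windows of 30 nt upstream of the 5' terminus and 50 nt downstream of the
3' terminus (`tsd_up_window`, `tsd_down_window`; the asymmetry reflects
tail-length uncertainty) are searched exhaustively over all substring
pairs of length 10–20 (`tsd_min_len`, `tsd_max_len`) with at most one
mismatch (`tsd_max_mismatch`), scoring matches minus one per mismatch and
keeping the best pair; ties go to the longer pair, then the leftmost. The
length bounds follow the operative method description; an alternative
8–16 nt convention exists in the literature and both are exposed in
`sine_config()`. Indels inside the TSD are not modelled — with a small
mismatch budget the exhaustive search is exact and cheap, and decayed TSDs
beyond that budget are deliberately given up (their family is recovered at
the annotation step). Windows are clipped at record ends, and candidates
at a boundary are still processed.

### Copy-number profiles

The candidate is extended by 100 bp per side (`extension`); the extended
window of length L becomes the query of a genome-wide local alignment
search (internal k-mer-seeded aligner, below). Alignments must reach a
significance of 1e-10 (`e_cutoff`) and a length of at least α·L
(`alpha` = 0.3, the low end of the recommended 0.3–0.8 range — see
Limitations). Each retained alignment adds one count to every window
position it covers; with T retained alignments (the self-hit included),
boundaries are refined to the first and last positions with counts
strictly above τ·T (`tau` = 0.5: a mid-range default; raise it for
precision, lower it for sensitivity — the passing set is monotone in τ).
Profiles are then classified, in order:

* `low_copy`: T < 3 (`min_copies`, counted including the self-hit, i.e.
  at least two non-self copies) — single-copy sequence is not usable
  evidence either way, and SINEs are by definition interspersed repeats;
* `truncated`: an interior run of positions below τ·T longer than 10 bp
  (`gap_max`) between the refined boundaries — the signature of two
  unrelated repeat halves joined by chance or nesting;
* `extended`: more than half (`extend_frac`) of the non-self alignments
  run into the first or last base of the window — the candidate sits
  inside a longer repeat (e.g. a LINE). The criterion is whether the
  alignment touches the window edge; the self-hit always covers the whole
  window and is excluded from the fraction. This check precedes the shift
  rule because window-saturating profiles would otherwise always trip it;
* `shifted`: the refined boundary moved more than 50 nt
  (`shift_max`) from the pre-refinement boundary — repeat structure in
  the flanks rather than at the candidate;
* `clean` otherwise: the candidate's interval is updated to the refined
  boundaries and it moves on.

Short simple repeats contributed by the flanks appear as sub-threshold
bumps outside the refined boundaries and are trimmed implicitly by the
refinement; no separate rule is needed. A profile in which no position
clears τ·T is degenerate and the candidate is removed.

### ncRNA, tandem-repeat and TIR filters

*Superfamily / ncRNA.* The 5' half of the candidate (the head region has
no canonical extent, and half the element comfortably covers tRNA-sized
heads) is aligned locally against labelled tRNA/7SL/5S references; the
best hit past a mild reporting threshold (1e-3) labels the superfamily.
Separately, a candidate whose *full length* is nearly identical to a
reference — significance ≤ 1e-15 (`exclusion_evalue`) over ≥ 90% of the
candidate (`exclusion_coverage`) — is an ncRNA gene rather than a SINE and
is excluded. The coverage guard is essential: a true tRNA-derived SINE
*should* match a tRNA over its head, and without the guard the exclusion
would throw away exactly the candidates it is meant to protect. Stricter
(smaller) exclusion thresholds never remove more candidates. With no
reference set the classification is skipped with a warning and everything
is kept.

*Tandem fraction.* An internal detector covers positions by comparing the
sequence against itself shifted by each period p = 1…6: any window of
max(2p, 8) consecutive comparisons with ≥ 80% matches marks the spanned
positions (window plus one period) as tandem. The window floor of 8
comparisons keeps the false coverage on random DNA below 1% (a bare 2p
window at p = 1 would mark every chance triplet). Candidates with ≥ 70%
tandem coverage (`tandem_max_fraction`) are removed.

*Terminal inverted repeats.* MITEs — the classic SINE impostor of similar
size, with TSDs of their own — carry reverse-complementary termini.
The two terminal zones (50 nt inward from each refined boundary,
`tir_zone`) are searched for the longest arm pair of ≥ 10 nt
(`tir_min_arm`) with ≤ 1 mismatch; any hit disqualifies the candidate.
The search is exact (longest-first enumeration) and symmetric under
reverse complement.

### Library construction and genome-wide annotation

Surviving candidates from the structural and homology tracks are merged
(pairs overlapping > 50% of the shorter element collapse to the longer,
with provenance "both" — measuring on the shorter makes nested pairs
collapse). Seeds are clustered greedily, longest first: a seed joins the
first cluster whose representative aligns globally at ≥ 80% identity
(`cluster_identity`), identity being matched bases over the shorter
sequence; otherwise it founds a cluster, and — processing being
longest-first — every founder is its cluster's longest member and
representative. The clustering alignment prices gaps at open 10 / extend 4
(`cluster_gap_open`, `cluster_gap_ext`): with cheap gaps, globally
aligning a short seed against a much longer unrelated one scatters
single-base gaps to harvest coincidental matches (an LCS effect) and
unrelated families merge; pricing a gap above twice the match reward makes
that impossible while leaving substitution-only comparisons — where the
80% boundary semantics live — bit-exact.

Each nonredundant seed is then aligned genome-wide; hits with divergence
(1 − identity) ≤ 40% (`max_divergence`) and length ≥ 50% of the seed
(`min_hit_frac`, chosen to match the element-level evaluation convention)
become annotation records. Overlapping hits from different seeds resolve
to the lowest divergence, then the longer hit, then the leftmost.
Annotation is idempotent: masking the annotated intervals and re-running
yields nothing new.

### The internal aligner

BLAST-style steps are served by an internal seeded aligner: exact 12-mers
(`kmer`) of the query are located in the subject (both strands), grouped
on diagonals (band 30, split on subject gaps longer than the query), and
each cluster's window is aligned with `Biostrings::pairwiseAlignment`
(local; +1 match, −1 mismatch, gap open 2, extend 1; IUPAC codes other
than ACGT always score as mismatches — a conservative reading since the
sources are silent on ambiguity handling). Significance is a
Karlin–Altschul-style surrogate E = K·m·n·e^(−λS) with the ungapped
uniform-composition parameters for ±1 scoring (λ = ln 3, K = 0.333). It is
a surrogate, not a calibrated BLAST E-value; the contract that matters
downstream is the α·L length rule plus a stringent cutoff, and 1e-10
keeps random-window alignments out by a wide margin. Exact 12-mer seeding
bounds detectable divergence: the chance that a 300 nt copy at 30%
divergence retains no exact 12-mer is a few percent, which is adequate for
copy collection (profiles need several copies anyway) and for annotation
up to the 40% cap in combination with the 50% length rule; a smaller k
trades speed for sensitivity and is exposed in the configuration.

### Evaluation

`compute_metrics()` reports sensitivity TP/(TP+FN), precision TP/(TP+FP),
FDR FP/(TP+FP) and F1 2TP/(2TP+FP+FN) to three decimals, with undefined
ratios returned as `NA` rather than 0 or 1. Base-level counting unions
overlapping records first and classifies every nucleotide; element-level
counting scores a known element as recovered when a *single* prediction
covers strictly more than half of it (one prediction may validate several
elements it spans — the definition is per known element, not per matched
pair), and a prediction as a false positive when no known element covers
more than half of *it*; matching is strand-agnostic. Seed-level
comparison aligns each test seed locally against each reference seed
(±1/−1, gap 2/1 — the reference masking engine's matrix is not public, so
the threshold is exposed) and requires score ≥ 225 with ≥ 50% query
coverage. Specificity is deliberately not reported: at base level TN
dwarfs FP by orders of magnitude and the ratio is always ≈ 1 regardless of
annotation quality.

## The synthetic genome generator

`generate_genome()` plants what the pipeline is designed to find, and what
its filters are designed to reject, in an i.i.d. background of
configurable GC (default 0.4, plant-like):

* **SINE families** (default 5 × 8 copies on a 200 kb genome): canonical
  elements of 160–600 nt with a 5–10 nt leader, box A, 25–50 nt spacer,
  box B, body, and a 12–20 nt poly-A tail. Copies carry substitution-only
  divergence drawn uniformly from 0–15% and fresh exact TSDs of 10–20 nt.
* **Decoys**, each engineered to be *discovered* (boxes, spacer, tail,
  TSDs, and enough copies to clear the low-copy rule) so that its
  designated filter is what removes it: MITEs (14 nt TIR arms), tandem
  elements (period-3 array covering > 70%), LINE-like blocks (> 1 kb
  repeated blocks embedding a SINE-like core with inner TSDs — their
  copies saturate the profile window, the extended-profile signature),
  and joined pairs (halves of two unrelated repeats, each half with its
  own supporting copies elsewhere, abutted across a linker — the
  truncated-profile signature).

Generation is fully deterministic given the seed. Several constructive
constraints keep the truth labels *true*:

* Mutable regions between box B and the tail are re-sanitised after
  mutation so substitutions never create a qualifying tail-like run that
  would pre-empt the planted tail (sanitisation spans part boundaries,
  where runs otherwise slip through).
* TSDs never start with A (first four bases drawn from C/G/T), so a
  poly-A tail cannot silently annex the start of its right TSD.
* Box motifs, TSDs, TIR arms, tandem arrays *and poly-A tails* are
  excluded from mutation. Protecting the tail goes beyond protecting
  motifs and TSDs, but homopolymer tails are not on a substitution clock
  comparable to unique sequence, and an eroded tail would make structural
  re-detection ill-defined rather than realistically hard.
* A family canonical whose terminal zones contain a chance ≥ 10 nt
  reverse-complementary arm pair is redrawn: such an element carries the
  defining MITE feature, so labelling it "sine" would be wrong and the
  TIR filter would (correctly) remove all its copies.

What the generator does *not* emulate: indels (substitution-only keeps
oracle alignments exact), nested or fragmented insertions, isochore
structure, 7SL/5S-headed families beyond labels, and element ages beyond
a uniform divergence draw. Passing the end-to-end recovery test therefore
demonstrates that the machinery implements its rules correctly and works
under clean repeat geometry — not that real-genome performance matches it;
real assemblies add decayed elements, indels and nesting that this fixture
deliberately omits.

## Problem sizes and determinism in the tests

The test-suite uses 25–100 kb genomes with 2–4 families for unit and
property tests, and the standard 200 kb / 5 × 8 condition (full decoy mix,
fixed seed) for end-to-end recovery; oracle-equivalence properties run 100
seeded trials per operation on ≤ 2 kb inputs against independent
brute-force enumerators. All stochastic fixtures fix their seeds, so every
reported number is reproducible.

## Known limitations

* **Upper end of the α range.** With TSD-exact boundaries and
  substitution-only copies in random flanks, a copy alignment can span at
  most the element itself, while the length rule demands α·(element +
  200). At α = 0.8 this requires elements of ≥ 800 nt — beyond the
  100–700 nt SINE range — so no copy can be retained and the profile
  stage empties. The oft-quoted robustness of performance across
  α ∈ 0.3–0.8 presupposes real-genome geometry (homology hits that
  underestimate boundaries, copies sharing flanking repeat context). With
  this package's exact-boundary candidates, keep α at or near 0.3; the
  passing set is stable in practice between 0.3 and 0.5 for elements
  longer than ~200 nt, and the relevant regression test documents the
  collapse at 0.8 rather than hiding it.
* **Low-complexity tail ends.** For genuinely low-complexity (non-poly)
  tails, the reported tail end is the end of the last qualifying window
  and can overshoot the element by a few bases; the TSD and profile
  refinements correct the element boundaries, but the tail annotation
  itself is approximate.
* **Surrogate significance.** E-values from the internal aligner are a
  Karlin–Altschul-style surrogate with ungapped parameters; they order
  hits sensibly and gate noise at 1e-10, but are not comparable to BLAST
  E-values in absolute terms.
* **Exact-seed sensitivity.** 12-mer exact seeding begins to miss
  individual copies beyond ~30% divergence; families are still recovered
  through their less-diverged members, but single very old copies can
  escape both collection and annotation.
* **Ambiguity codes** are retained but always score as mismatches, and
  soft-mask information is preserved through I/O but ignored by all
  search stages by default.
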