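---
title: "Closing scaffold gaps with paired reads: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closing scaffold gaps with paired reads: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapmender)
```

## The problem and the model

A scaffold is an ordered set of contigs joined by runs of `N` whose length
is the scaffolder's estimate of the missing sequence. The estimate comes
from insert-size information, so it is informative but imperfect. Paired
reads give two independent handles on a gap: a pair whose first mate maps
to sequence near a gap *predicts*, through its insert size, that the second
mate lies inside the gap — even though that mate itself has nothing to map
to. Collecting those predicted-in-gap mates yields a local read pool highly
enriched for the missing sequence, without any whole-genome reassembly.

`gapmender` turns that pool into sequence by greedy k-mer extension with
voting. Each recruited read (and its reverse complement — strand symmetry
means we never need to know which strand a mate came from) is decomposed
into k-mers. A gap edge is the last $m = k - 1$ confirmed bases; every
k-mer equal to that edge plus one more base votes for its overhang base.
The vote must clear two independent thresholds:

* **coverage** $o$: the winning base's support count, so that a single
  spurious read cannot extend the assembly; and
* **majority ratio** $r$: the winner's fraction of all overhang support, so
  that near-ties (allelic differences, repeat branch points, recurrent
  sequencing errors) stop extension instead of guessing.

A tie for the winning base always stops extension, whatever $r$ is: the
algorithm is deterministic by construction and prefers leaving a gap open
to closing it wrongly.

Closure is accepted only on two further conditions: the left and right
extensions must overlap by at least $n$ bases (suffix of one equals prefix
of the other), and the implied insertion must be within $d$ bases of the
expected gap length. The second condition is what makes the scaffolder's
size estimate an active safety check: a candidate insertion that is
consistent sequence-wise but 60 bases shorter than the estimate is
rejected as `SIZE_MISMATCH` rather than accepted on faith.

## Parameters

| symbol | meaning | unit | default | rationale |
|---|---|---|---|---|
| `t` | gap-edge trim | nt | 10 | contig ends near gaps are error-prone; trimming converts them back to unknowns and enlarges the expected insertion accordingly |
| `m` | edge overlap; k-mer size is `m+1` | nt | 29 (k = 30) | long enough to be specific in non-repetitive sequence, short enough to be covered by 70–100 nt reads |
| `o` | minimum overhang coverage | count | 2 | one read never suffices; raise on deep data, lower to 1 only with relaxed expectations |
| `r` | majority voting ratio | fraction | 0.7 | winner must dominate; 0.5 is the permissive low-coverage mode |
| `n` | minimum merge overlap | nt | 10 | chance suffix/prefix agreement of 10 bases is ~1e-6 per comparison |
| `d` | size tolerance | nt | 50 | absorbs normal scaffolder error while rejecting gross misestimates; applied symmetrically |
| `i` | global iterations | count | 10 | later rounds re-anchor reads onto newly confirmed sequence; the loop stops early once an iteration inserts nothing |
| `seed_len` | anchoring seed | nt | 30 | exact-match seed for the built-in mapper |
| `max_mismatch_frac` | verification budget | fraction | 0.04 | ~3 mismatches on a 70 nt read, no indels |

Insert-size windows use the library's stated mean and fractional deviation
(`deviation = 0.25` by default): an anchor on the forward strand at
position $s$ predicts its mate within
$[s + (1-v)I - \ell_m,\; s + (1+v)I - 1]$ (1-based, inclusive; $\ell_m$ the
mate length), mirrored for reverse-strand anchors. Mate-pair (RF)
libraries are normalized to FR on input by reverse-complementing both
mates, so one window formula serves both layouts.

## Design choices where the design was open

* **Coordinates are 1-based inclusive throughout.** This package lives in
  the R/Bioconductor ecosystem, where IRanges-style 1-based closed
  intervals are the convention; SAM `POS` values are likewise 1-based and
  are used as-is.
* **Built-in anchorer.** Alignment is a seed-and-verify exact-first mapper:
  candidate loci are found by exact lookup of the read's (or its reverse
  complement's) first `seed_len` bases and verified full-length with a
  mismatch budget and no indels. Only a *unique* best placement anchors a
  pair; multi-mapping anchors are discarded rather than assigned randomly,
  because recruiting from the wrong repeat copy is precisely how gaps get
  closed with the wrong sequence. SAM ingestion is provided for users who
  prefer an external aligner; those placements are used on the first
  iteration (they refer to input coordinates) and re-anchoring takes over
  afterwards.
* **A recruited mate may serve several gaps** when its ±25% window spans
  more than one; downstream coverage and ratio thresholds absorb the noise.
* **Voting semantics.** `o` applies to the winning base's count, not to the
  column total, and `r` is the winner's share of the column; this keeps the
  two thresholds independent, and makes the permissive mode (`o = 1`,
  `r = 0.5`) meaningful.
* **Removal on use, one restore.** The k-mers used for an incorporation are
  removed (all copies), so a handful of reads cannot be recycled
  indefinitely; when both edges stall, the pool is rebuilt once per gap per
  iteration and extension resumes, which lets legitimately repeated context
  be traversed a second time.
* **Overlap is sought between the extensions only**, not between extension
  and untouched flank: flanks are part of the assembly being corrected, and
  the trim step exists precisely because they are unreliable near gaps.
* **The closure check runs after every incorporated base.** This matters
  more than it may seem: the suffix/prefix overlap between the two
  extensions exists only while both tips lie inside each other's span.
  Extensions that grow past the gap into the opposite flank (they may: the
  per-side growth cap is `expected_len + d`, anything longer necessarily
  fails the size test) destroy the textual overlap. A size-rejected overlap
  observed mid-growth is therefore remembered and reported as
  `SIZE_MISMATCH` even if the final state shows no overlap; the diagnosis
  is conclusive, so later iterations do not overwrite it.
* **Strict left/right alternation** (skipping a stalled side) prevents one
  edge from exhausting shared k-mers before the other starts.
* **Edge trimming runs in the first iteration only**; re-trimming would
  erode sequence the tool itself confirmed in earlier rounds. A flank
  shared by two nearby gaps is split between them and never fully consumed,
  so distinct gaps remain distinct; a flank at a scaffold end may be
  consumed entirely (such terminal gaps are unfillable anyway, having only
  one flank, and are reported but left alone).
* **Expected length counts trimmed bases.** The size test compares the full
  replacement of the enlarged interval with `N-count + trimmed bases`, so a
  size-exact closure conserves scaffold length.

## What the simulator emulates — and what it does not

`simulate_genome` draws i.i.d. bases at a chosen GC content;
`make_gapped_scaffolds` masks stated intervals with `N`, optionally
misreporting the run length to emulate imperfect scaffolder estimates, and
records the masked truth; `simulate_read_pairs` draws uniform fragment
starts with normal fragment lengths (truncated below at two read lengths),
takes read 1 as the fragment prefix and read 2 as the reverse-complemented
suffix, and applies i.i.d. substitution errors. This mirrors a wgsim-style
simulation with substitution-only errors.

Real data differ in ways the simulator deliberately ignores: read indels
and quality-dependent error profiles, GC-coverage bias, chimeric fragments,
heterozygosity, and genome-scale repeat structure beyond what is injected
explicitly. Passing the simulated suites therefore demonstrates the
correctness of the machinery — recruitment geometry, voting, merging, size
control, determinism — not performance on any particular organism. The
evaluator's repertoire is likewise per-gap: it aligns each realized
insertion to its truth and counts SNPs and indel events (≤ 5 bp vs > 5 bp
— events are contiguous inserted/deleted blocks from an affine-gap global
alignment, while the reported edit distance is the plain unit-cost
Levenshtein distance); structural misjoins are out of scope, as detecting
them needs whole-assembly alignment rather than per-gap comparison.

## Numerical and degenerate-input behaviour

* Ambiguity codes and the gap characters `-`/`.` normalize to `N`; only
  A/C/G/T can seed or extend k-mers. Unknown characters are a hard error
  naming the record.
* Reads shorter than `k` contribute no k-mers; k-mer windows containing `N`
  are skipped; an edge whose last `m` bases contain `N` cannot seed
  extension and stops with `NO_COVERAGE`.
* Ties anywhere are refused, never broken randomly: the winning overhang
  base must be unique, and among equally size-accurate merge candidates the
  larger overlap wins (a deterministic tie-break).
* Per-side extension is capped at `expected_len + d`; with k-mer removal
  this bounds work even on adversarial periodic k-mer sets.
* A zero-gap assembly passes through unchanged; a gap with no recruited
  pairs is reported `OPEN`/`NO_READS`; partially filled gaps always retain
  at least one `N` so they remain detectable as gaps.

## Problem sizes used by the test and acceptance suites

The reference study is a 100 kb genome with 20 gaps of 20–250 bp and one
2×70 bp FR library (insert 300 ± 30) at 40× — comfortably bacterial-like
recruitment geometry while keeping a full pipeline run in seconds. The
size-constraint suite uses 50 gaps misreported by `d + 10` = 60 nt; the
threshold-monotonicity comparison runs at 10×; property checks (voting,
merging, anchoring) use 1,000 random instances each against brute-force
oracles. Unit tests run the same machinery at 5–15 kb.

## Known limitations

* Extension is strictly greedy with local voting; it does not build a
  de Bruijn graph, so content whose resolution requires global path
  reasoning (long repeats at comparable coverage) ends `AMBIGUOUS` or
  `SIZE_MISMATCH` by design rather than being resolved.
* The built-in anchorer allows mismatches but not indels; reads with an
  error in their first `seed_len` bases do not anchor (at 1% error and
  70 nt reads, ~26% of reads are lost this way — the windows are wide
  enough that this costs coverage, not correctness).
* Base qualities are read but unused.
* Gap-size estimates more than `d` off cannot be closed (by design); the
  remedy on real data is re-scaffolding or raising `d` deliberately.
* Processing is serial; the thread flag exists for interface compatibility
  and results are identical for any value.
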