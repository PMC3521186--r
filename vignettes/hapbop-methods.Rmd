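---
title: "Balanced optimal partition haplotype assembly: model, algorithm and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balanced optimal partition haplotype assembly: model, algorithm and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(hapbop)
```

## The problem

A diploid individual carries two copies of each chromosome. At a
heterozygous SNP locus the two copies carry different alleles, coded `0`
(major) and `1` (minor). Sequencing reads ("fragments") sample one copy at
a time; after alignment and restriction to heterozygous loci, the data are
an `m x n` SNP matrix over `{0, 1, -}`: fragment `i` calls allele
`M[i, j]` at locus `j`, or `-` where it has no call. Single-individual
haplotyping reconstructs the two complementary haplotypes
`H = (H1, H2)`, `H1[j] != H2[j]`, from the conflicts among overlapping
fragments. Sequencing errors make exact reconstruction impossible, so the
problem is cast as combinatorial optimization.

## The model

Two classical objectives operate on opposite sides of a fragment
bipartition `P = (G1, G2)` (fragments believed to come from the same
chromosome copy share a group):

* **Errors corrected (MEC side).** Let `N[g, v](j)` count the fragments of
  group `g` calling allele `v` at locus `j`. The majority haplotype of `P`
  sets `H1[j] = 0` when `N[1,1](j) + N[2,0](j) <= N[1,0](j) + N[2,1](j)`
  and `1` otherwise. The errors-corrected measure of the partition is

  `sc(P) = sum_j min(N[1,1](j) + N[2,0](j), N[1,0](j) + N[2,1](j))`,

  the number of allele calls that must be flipped so every fragment
  matches its own group's haplotype.

* **Fragments cut (MFC side).** Two alleles score `d(a, b) = -1` when both
  are called and equal, `+1` when both are called and unequal, `0` when
  either is a gap; the fragment weight `d(f1, f2)` sums `d` over loci. The
  fragments-cut measure `sd(P)` sums `d(f1, f2)` over all cross-group
  pairs — the cut value of `P` in the weighted conflict graph.

The balanced objective combines them with a weight factor `w >= 0`:

`sp(P) = sc(P) - w * sd(P)`,

to be minimized. `w = 0` is exactly MEC; a sufficiently large `w` makes
the cut term dominate and the model approaches MFC (no finite `w` is
claimed to make it MFC-exact; `w` is simply exposed). The blend matters at
realistic error rates: pure MEC happily "corrects" many errors to slightly
shorten its count, producing partitions that disagree with the truth over
long stretches, while the cut term rewards partitions that separate
genuinely conflicting fragments.

A subtlety worth stating explicitly: the MEC literature also defines an
errors-corrected measure of a *haplotype pair*, in which each fragment is
matched against whichever haplotype fits it better
(`errors_corrected()`). Our `partition_score()` instead charges every
fragment to its own group's haplotype — the columnwise count above — which
is the quantity the incremental recurrences of the solver telescope to.
The two agree except on partitions holding a fragment that fits the other
group's haplotype better (then the partition measure is larger); at
`w = 0` their minima over partitions coincide with the MEC optimum, since
any optimal haplotype pair induces a partition whose columnwise measure is
no larger. Tests assert both the exact equality of the incremental and
from-scratch partition measures and the MEC reduction against an
exhaustive haplotype enumeration.

## The H-BOP solver

Enumerating the `2^(m-1)` bipartitions is hopeless, but fragments are
local: after sorting rows by `(l(i), r(i))` (first/last called column;
stable on ties), only the *active set* `R(i)` — rows among the first `i`
spanning column `l(i)` — can still interact with later rows. The solver
sweeps rows left to right, maintaining candidate partitions of `R(i)`
together with their best-so-far full extensions and scores:

1. **Project.** Moving to row `i + 1`, restrict each candidate to the
   carried-over set `Rc = R(i) ∩ R(i+1)`; candidates that collide after
   restriction are merged keeping the smaller score (the optimal-extension
   semantics of the recurrence).
2. **Extend.** Each candidate spawns two children (row `i + 1` in either
   group). The score changes only over the new row's span: `delta_ec()`
   re-evaluates the per-column minority counts over the `Rc` rows covering
   each column, `delta_fc()` adds the signed agreement of the new row
   against cross-group overlaps. Sorting guarantees every row covering a
   column at or past `l(i+1)` is in `Rc` (asserted as a test), so the
   local update is exact.
3. **Select.** At most `k` candidates with the smallest scores survive —
   the counterpart of a capacity-`k` max-heap whose root is replaced only
   by a strictly smaller score; accordingly, the earlier-generated
   candidate wins ties, making runs deterministic.

The answer is the stored extension of the best final candidate. Work per
row is `O(k * k1 * k2)` (`k1` = max span length, `k2` = max active-set
size), so total time `O(m * k * k1 * k2)` — linear in each of the
parameters at fixed others; the exported `ops` counter empirically doubles
when `k` doubles. With `k >= 2^(q-1)` for every active-set size `q` the
beam holds all canonical states and the algorithm is exact, which is how
the tests tie it to the brute-force `exact_bop()`.

Partitions of the active set are stored canonically — the smallest-indexed
active row is fixed to group 0, halving the state space — and
re-canonicalized (by complementing the whole extension) after projection.
If the carried-over set ever becomes empty (possible only between
connected components when phasing a whole matrix), the beam collapses to
the single best candidate, whose extension is carried forward; the scores
of the disconnected parts add.

### Parameters

* `w` (weight factor, dimensionless, default **0.1**): 0 is pure MEC;
  around 0.01–0.1 the switch-error behaviour is best at realistic error
  rates, and 0.1 is the operating point used throughout.
* `k` (beam width, default **8**): accuracy saturates around `k = 8` on
  simulated data while time grows linearly in `k`, so 8 is the default
  operating point; raise it (or call `exact_bop()`) on small hard
  instances.

### Per-block solving

Phase is only determinable within a *block*: a connected component of the
site graph joining two loci whenever one fragment calls both
(`snp_blocks()`). Because no fragment crosses blocks, the objective
decomposes exactly, and `phase_blocks()` solves each block's submatrix
independently (tested: per-block scores sum to the whole-matrix score on
disconnected instances). Singleton blocks are reported unphased.
`hbop_phase()` remains available for whole-matrix runs.

### Which sites count as phased

A locus is reported *determined* when it is covered and its majority vote
is strict; a tied vote (`N[1,1] + N[2,0] == N[1,0] + N[2,1]`, e.g. a
two-fragment column whose calls disagree after grouping) carries no
evidence for either orientation and is flagged unphased by the solver
pipeline, though the `<=` rule still fixes its allele deterministically
for anyone who wants it (`ties = "phase"` in
`haplotype_from_partition()`). This convention is what makes the phased
haplotype length respond to the sequencing error rate — with more errors,
more columns tie — matching the behaviour of the published simulation
table; flagging only uncovered sites would make phased length a function
of coverage alone.

## The simulator

`simulate_fragments(n, m, l, e, g, seed)` emulates the standard study
design: a uniform random haplotype `h1` of `n` heterozygous SNPs and its
complement `h2`; half the `m` fragments from each copy (odd `m`: the extra
one from `h1`); fragment length drawn from `Normal(l, 1)`, rounded to the
nearest integer and clamped to `[2, min(4l, n)]` (the clamp at 2 preserves
the every-fragment-covers-two-loci assumption; the upper clamp only rules
out absurd draws); start uniform over positions where the fragment fits;
every allele flipped with probability `e`; every allele except the
fragment's first and last deleted with probability `g`. Ends are never
deleted, so no fragment degenerates below two calls. The draw order is
fixed (haplotype; then per fragment: length, start, flips left to right,
deletions left to right) and the RNG is scoped, so a seed reproduces a
dataset bit for bit. Call coverage `c` is the total number of called
alleles divided by `n`; at the reference setting `(n = 100, m = 140,
l = 3, g = 0.1)` our conventions give `c ≈ 4.15`, close to the published
4.25 — the original generator's rounding/clamping conventions are not
documented, so coverage is reported rather than asserted.

What the simulator does **not** emulate: base-quality variation (the model
is unweighted, and quality strings in fragment files are parsed but
ignored), indels and multi-allelic sites, non-uniform coverage along real
chromosomes, mate-pair insert-size structure, and correlated
(non-independent) sequencing errors. Passing simulation tests therefore
demonstrates correctness of the algorithmics and faithful behaviour under
the stated generative model, not performance on any particular real
dataset.

## Evaluation metrics

Within each block, orientation is relative: the reconstruction is compared
with the truth through the per-site agreement bit, and a **switch error**
is a flip of that bit between two consecutive phased sites (a complemented
block is error-free; blocks are never compared across boundaries).
**Phased haplotype length** counts determined sites in blocks of two or
more sites, and the **switch error rate** divides total switch errors by
it. **QAN50** summarizes completeness and accuracy together: blocks are
broken at switch errors into clean segments; each segment's span (first to
last phased SNP, in reference coordinates when a coordinate map is given,
else site index) is adjusted by the fraction of phased SNPs among all SNPs
inside its extent; segments are walked in decreasing adjusted span,
accumulating phased SNPs, and the adjusted span of the segment at which
the count first exceeds half of all SNPs is reported.

Two conventions the definition leaves open are fixed as: spans are
inclusive (a one-SNP segment has span 1), and "half of the total number of
SNPs" means the whole evaluated input, with a strict `>` threshold. The
Hamming-distance accuracy metric is deliberately omitted — it
over-penalizes single switch errors; switch errors are the standard
alternative.

## Numerical and degenerate-input choices

* Scores are kept as the integer pair `(sc, sd)`; for rational
  `w = p/q` (any `w` with at most six decimals), candidates are compared
  through the exact integer `q*sc - p*sd`, so float round-off can never
  reorder ties. Irrational `w` falls back to float comparison.
* All ties anywhere (sorting, beam insertion, final argmin, merged
  projections) resolve to the earlier item, so every code path is
  deterministic.
* Empty matrices phase to empty results; uncovered columns are singleton
  blocks; fragments with fewer than two calls are removed by
  `preprocess_fragments()` (and by `phase_blocks()` internally), with an
  old-to-new column index map kept when empty columns are dropped.
* `exact_bop()`/`exact_mec()` refuse instances beyond a size cap (default
  20) instead of silently truncating.

## Problem sizes used by the test suite

The suite ties the beam solver to exhaustive enumeration on ~100
instances with up to 8 fragments and 10 loci (where `2^(m-1)` partitions
and `2^(n-1)` haplotypes are enumerable in milliseconds), checks the
incremental scores against from-scratch recomputation at every step of
smaller sweeps, and reproduces four cells of the published
phased-haplotype-length table at the study's own scale — 100 replicates
of `n = 100` — which completes in well under a minute per cell. These
sizes were chosen as the smallest at which each property is
non-trivially exercised.

## Known limitations

* The beam is a heuristic: for `k` below the exact threshold no optimality
  guarantee exists, and widening the beam, while never worse on any tested
  instance, has no worst-case monotonicity proof.
* The model assumes all loci heterozygous and bi-allelic; genotyping
  errors that violate this upstream are out of scope.
* Runtime scales with call coverage through `k1 * k2`; extremely deep
  coverage would call for subsampling upstream.
* QAN50 on simulated data uses SNP indices as coordinates; real-data use
  should pass genomic positions via `coords`.
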