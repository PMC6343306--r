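---
title: "bsmeth: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bsmeth: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsmeth)
```

This vignette is the package's own account of what it computes and why the
open design choices were made the way they were. It states no empirical
result that the test suite does not itself compute.

# The alignment model

## Three-letter conversion

Bisulfite converts unmethylated cytosine to uracil, sequenced as T;
methylated cytosine is protected. After conversion the two genomic strands
are no longer reverse complements, so `convert_genome()` keeps two views
in a single plus-strand coordinate system: C→T for the plus strand and
G→A for the minus strand (a C→T conversion of the minus strand, read back
on plus coordinates, turns every G into A). Keeping the minus view in plus
coordinates — rather than as a physically reverse-complemented string —
means every hit from either view is natively a plus-strand position and no
coordinate flipping ever happens downstream.

A directional library yields two search tasks per read (`convert_read()`):
the C→T read against the C→T view, and the G→A conversion of the reverse
complement against the G→A view. A non-directional library adds the two
complementary-strand conversions. The original read is retained: search
happens in converted space, *scoring* happens on the original sequences
under the asymmetric matching rule (read T over reference C is a match in
C→T space; read C over reference T is not — the conversion is one-way).

## Long seeds

Candidate loci come from a 75-bp leading seed allowing 5 mismatches and
one gap, with a gap charged like 1.5 mismatches when ranking hits. The
long high-tolerance seed is the point: a 2-error 25-bp seed misses its
locus, while a 75-bp seed with budget 5+gap still anchors it. Candidates
are generated by exact k-mer sub-seed lookups (k = 12 by default, a plain
sorted k-mer table — the contract is exact substring lookup, and nothing
at desk scale justifies an FM-index) and verified by a single-gap scan
that considers every gap length up to `max_gap_len` (10) and every
placement. Reads shorter than 75 bp use the whole read as the seed with
the mismatch budget scaled as `floor(5 · len/75)`; reads longer than
150 bp search every nonoverlapping 75-bp window and merge the implied
read starts.

Pigeonhole caveat: with k = 12 a 75-bp seed has six disjoint sub-seeds,
so an adversarial placement of 6 edits can evade candidate generation.
At the simulated error process (≤ 2 substitutions plus rarely one indel
per read) at least three sub-seeds stay clean, and the acceptance suite
measures the realized recovery directly (≥ 95% mapping, ≥ 90% indel
recovery).

## Affine-gap extension and the indel gate

Extension is a banded, global-in-read affine-gap dynamic program
(`extend_hit()`, Rcpp): match `+Q`, mismatch `−Q` (Q = Phred quality of
the read base), gap open 40, gap extension 6, first gap base 46. The
"band" is implemented as a reference window of `band` extra bases
(default `2·max_gap_len + 8` = 28) on both sides of the implied read
span; if the optimum touches the window edge the window is doubled once,
then the hit fails. With soft clipping enabled, a read prefix or suffix
whose inclusion drives the score negative is replaced by S operations
(the DP allows a free restart, i.e. Smith–Waterman-style prefix clipping,
and a free stop).

The **indel gate**: for each candidate the ungapped diagonal alignment is
computed first; if it has fewer than `mismatch_threshold` (default 2)
bisulfite-aware mismatches, the gapped DP is skipped entirely — when a
low-mismatch ungapped alignment exists it beats an indel alignment, and
skipping the DP is pure speed. Otherwise (or when no acceptable ungapped
alignment exists at all) the gapped DP runs and the better score wins.
Disabling indels (`indels = FALSE`) suppresses gapped alignment and falls
back to clipped ungapped alignment.

### The gap-event cap

One numerical choice deserves emphasis. Under the prescribed scoring
(±Q vs open 40/extend 6 at Q ≈ 30) the *unrestricted* optimal affine DP
will profitably chain short gaps across unrelated sequence: a one-base
gap costs 46 while a lucky shifted diagonal of two or three chance
matches earns 60–90, so a read whose tail belongs elsewhere (a chimera)
gets a contorted gapped tail instead of a soft clip. The pipeline
therefore caps the number of gap *openings* in extension at the seed
model's allowance (one), via the `max_gap_events` argument. The
unrestricted exhaustive DP remains `extend_hit()`'s default and is the
behaviour verified exactly against an independent DP oracle in the
acceptance suite; the cap is applied only where the aligner itself calls
the extension. Reads genuinely carrying two indels (≈ `(100·3·10⁻⁴)² ≈
10⁻³` per 100-bp read at the simulated indel rate) lose one of them to a
mismatch or clip representation.

## Best hit, MAPQ, clips, pairs

All candidates across conversion spaces are extended, deduplicated by
(chromosome, position, strand) and ordered by score with deterministic
ties (chromosome order, position, strand). MAPQ is artifact-defined — the
method only requires *a* mapping-quality report: a hit with no scoring
alternative gets 60, co-optimal hits get 0 (the "ambiguous" marker used
by the evaluator and excluded from pileup), otherwise
`min(60, round(0.4·(s₁−s₂)/mean Q))`. Soft clips longer than 20 bp are
realigned with 0 mismatches; a unique occurrence becomes a supplementary
record so primary + auxiliary represent the complete read.

Paired ends use deep-scan selection (`deep_scan_pair()`): all retained
candidates of both mates are paired jointly, requiring same chromosome,
opposite strands, forward–reverse orientation and outer insert ≤ 500 bp,
and the pair maximizing the summed score wins — the individually best
hits are *not* privileged. FR-only orientation is an assumption of this
implementation (the common library layout); with no proper pair the
individual bests are reported improper.

# Methylation calling

`pileup()` walks each primary alignment's CIGAR: M consumes read and
reference, I and S consume read only, D consumes reference only, so bases
under a deletion contribute nothing. At a plus-strand cytosine (reference
C), C2T-space reads contribute C (methylated) or T (unmethylated);
G2A-space reads at the same position show, in reference-forward SAM
orientation, C for a bottom-strand G (`rev_G`) and T for a bottom-strand
A (`rev_A`, the C→T SNP signal). The minus-strand case is the mirror
image. Three conservative filters are applied, all adjustable: base
quality ≥ 20, MAPQ ≥ 1 (ambiguous placements corrupt counts), and
overlapping proper-pair mates counted once with mate 1 winning (whether
the original counts overlaps once or twice is unstated; double counting
overstates coverage, so we do not).

The level is the reverse-strand-corrected estimator with its capped form
and low-coverage fallback (threshold 10), as shown in the README. The
edge the formula leaves open: sufficient reverse coverage with
`rev_G = 0` makes the corrected formula divide by zero, and the capped
value (100%) would be maximally wrong at what looks like a homozygous
C→T SNP — such sites are flagged (`snp_flag`) and get no level. Depth
filtering is strict (`C+T > 5` by default), matching the stated "more
than" wording; context (CpG/CHG/CHH) is read from the reference strand
alone, with insufficient downstream sequence or N falling into CHH as
the catch-all.

# Regions and differential methylation

Region level is the pooled-count statistic `100·ΣC/Σ(C+T)` over
qualifying cytosines — deep sites weigh more, and the statistic is
additive over disjoint regions. Sliding windows default to 100 kb/50 kb
(the chromosome-density view, per strand); gene meta-profiles use 2-kb
flanks and a length-normalized body, 50 bins per segment (the bin count
is unstated upstream; 50 is configurable), assigning each 1-bp site to
bins by fractional overlap; minus-strand genes are flipped as whole
intervals so mirror symmetry is exact. The five-category partition reads
the stated ranges with inclusive upper bounds (M > 80, Mh (60,80],
H (40,60], hU [20,40], U < 20), the only reading that makes the
categories exhaustive and disjoint. Promoters, where needed, are 2 kb
upstream of the TSS, strand-aware — matching the profile flank.

DMC/DMR testing: windows (or predefined regions, or single sites for
DMCs) are tested only if both samples have ≥ m = 5 valid sites, a site
being valid at coverage ≥ n = 5 ("at least", non-strict). Without
replicates, pooled counts go into a two-sided Fisher's exact test (sum of
hypergeometric probabilities ≤ observed, with the conventional 1e−7
relative tolerance). With replicates, a beta-binomial likelihood-ratio
test: the null fits one beta-binomial (mean μ, dispersion φ in the
ICC parametrization `a = μ(1−φ)/φ`, `b = (1−μ)(1−φ)/φ`) to all
replicates; the alternative fits separate means with a shared, profiled
dispersion; `2·ΔlogL` is referred to χ²₁. μ is estimated by bounded
one-dimensional likelihood maximization, φ profiled on a logit grid over
(10⁻⁶, 1−10⁻⁶). The upstream description names only the distribution, so
the LRT-with-shared-dispersion formulation is this package's choice:
standard, simple, and testable by simulation (type-I error and parameter
recovery are both in the acceptance suite). BH adjustment is the step-up
formula, and a unit is significant iff q < 0.05 (strict) and
|Δmethylation| ≥ 0.6 (inclusive) on the 0–1 scale, with the window
difference taken between pooled-count levels. Genome-wide DMR scans
default to 1 kb windows with 500 bp steps — the upstream scan size is
never stated; 1 kb is a conventional methylation-block scale and it is a
CLI flag.

# The simulator: what a green test establishes

`simulate_genome()` draws i.i.d. bases (default GC 0.42, human-like);
`simulate_methylome()` methylates each cytosine independently per context
(defaults 0.8 CpG / 0.02 CHG / 0.02 CHH, a mammalian-like bimodal
methylome); `simulate_reads()` draws uniform loci and strands of a
directional protocol, converts unmethylated Cs with probability
`conversion_rate` (default 0.99, a realistic conversion efficiency;
evaluation scenarios use 0.5 where specified), injects substitution
errors at 1% capped at 2 per read — mirroring the stated evaluation
protocol — and indels at 3·10⁻⁴ per base. Planted-indel reads
(`force_indel`) place exactly one indel of length 1–10 at a read offset
uniform on [10, len−10]: an indel within 10 bp of a read end leaves too
little anchor to be located even in principle, so including terminal
offsets would measure a floor effect, not the aligner. This range was
fixed before any measurement. Per-read truth records position, strand,
protocol, the indel list (in reference-forward read coordinates, matching
CIGAR), the injected error count and the methylated-C count; per-site
methylation truth lives in the methylome table rather than being
duplicated per read.

What the simulator does **not** emulate: non-uniform coverage, quality
decay along reads, PCR duplicates, repeats/low-complexity structure
(genomes are i.i.d., so mapping here is *easier* than in a real genome's
repeat space), CpG islands, methylation spatial correlation, M-bias, or
incomplete-conversion clustering. A green mapping-recovery test
establishes the machinery is correct at the stated error process, not
that real-genome mapping rates would match.

The evaluator applies the three correctness criteria in order (unique
strand-matched mapping with MAPQ > 0; start within 10 bp; similar
indels/mismatches). "Similar" is operationalized — the source never
quantifies it — as: every truth indel matched by a called indel of the
same type within ±1 length and ±5 read offset and vice versa, and the
reported mismatch count within ±2 of the injected error count. Paired
concordance counts mate pairs mapped within 500 bp of each other,
cumulatively from high to low MAPQ. For the concordance experiment the
mates are aligned single-end in non-directional mode, since mate 2 of a
directional library derives from the complementary strand and is
invisible to a directional single-end search.

# Numerical and boundary conventions

* All internal coordinates are 0-based half-open; SAM emission converts
  to 1-based at the boundary, and bedGraph stays 0-based half-open with
  levels on the 0–1 scale.
* Determinism everywhere: candidate ties break by (chromosome order,
  position, strand); the DP traceback prefers the leftmost maximal end
  column and drops to the fewest-gap layer on ties; identical seeds give
  byte-identical FASTQ, truth tables and SAM (asserted in the suite).
* RRBS digestion cuts at `C^CGG` (offset 1 into the MspI site) on the
  undigested plus strand and keeps fragments ≤ 600 bp. Chromosome-end
  (terminal) fragments are retained subject to the same length filter —
  whether the original keeps them is unstated; discarding them would
  silently drop real fragments at contig boundaries.
* `fisher_dmc` returns 1 on any zero margin (the table carries no
  information); `betabinom_test` returns 1 on all-zero coverage; the LRT
  statistic is floored at 0 against profiling jitter.
* N never matches anything: not in the index (k-mers overlapping N are
  unindexed), not in seed verification, not in extension scoring.
* Best-hit selection ("a set of predefined criteria" upstream, never
  enumerated) is: score, then fewer mismatches via the score itself,
  then deterministic coordinate order; this is noted as this package's
  rule, not claimed as the original's.

# Known limitations

* The aligner is desk-scale by design: the k-mer table and R
  orchestration handle megabase genomes comfortably but are not
  engineered for a whole human genome in RAM.
* Only substitution-style MAPQ calibration is provided; the formula is
  artifact-defined and not comparable across aligners.
* The beta-binomial model assumes a shared dispersion between groups;
  strongly heteroscedastic designs would need a free-dispersion
  alternative.
* SNP handling stops at the `snp_flag` heuristic; genotype-aware
  methylation calling is out of scope.
* bigWig and HTML reporting are intentionally replaced by bedGraph and a
  JSON/text summary; plotting is left to the emitted matrices.
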