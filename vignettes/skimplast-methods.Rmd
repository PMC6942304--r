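---
title: "Methods: plastome skimming drafts, QC and alignment-free identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plastome skimming drafts, QC and alignment-free identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`skimplast` models the computational half of a herbarium genome-skimming
workflow: degraded plant DNA is shotgun-sequenced shallowly, the high-copy
plastome is assembled de novo, drafts are finished against a related
reference, scored for quality, and identified against a sequence database.
This vignette explains the models and procedures the package implements,
the parameters that matter, the numerical choices at the corners, and what
the synthetic data generator does and does not emulate.

## The pipeline model

The package follows a fixed stage order, mirrored by `runDemo()` and the
`skimplast.R` command-line wrapper:

1. **Read preparation.** 3' adapter trimming (`trimAdapters`), two-pass
   digital normalization on canonical k-mer counts (`normalizeKmerDepth`),
   and overlap merging of pairs (`mergePairs`).
2. **Assembly sweep.** An external de novo assembler is treated as a
   callback; `runParameterSweep` tries paired (k-mer, coverage cut-off)
   rounds — defaults k = 51, 71, 91, 111 with cut-offs 10, 7, 15, 20 — and
   stops at the first round whose contigs reach a minimum total
   plastid-matching length and median read depth. If no round qualifies, the
   best round is handed to the reference-guided path. The package
   deliberately does not re-implement an assembler; `stubAssembler()` is a
   documented stand-in seam that fragments a known genome so the sweep,
   alignment and scaffolding logic stay exercised end to end.
3. **Reference-guided drafting.** Contigs are anchored to every database
   reference by maximal exact matches and colinear chaining
   (`alignContigs`), the reference covering the most sequence with the
   fewest contigs is chosen (`selectReference`), and contigs are ordered,
   oriented and joined (`scaffoldContigs`).
4. **QC.** Length-ratio error against the top-ranked database match,
   good/poor classification at 0.1, GC, repeat diagnostics, depth
   (`assemblyReport`), and Welch t-test screening of per-sample parameters
   between good and poor groups (`compareGoodPoor`).
5. **Identification.** Average-common-substring ranking (`rankDatabase`,
   `evaluateIdentification`) and barcode extraction by simulated PCR
   (`extractBarcode`).

## Assembly error

`assemblyError(La, Lr)` returns |ln(La/Lr)|; `classifyAssembly` labels an
assembly poor at error ≥ 0.1, inclusive. The natural log is a deliberate
choice: at error exactly 0.1 the assembly is either 10.52% longer or 9.52%
shorter than its match — "about ±10%" — whereas a base-10 log would imply
±26%. The asymmetry means missing sequence is penalised slightly more than
the same proportion of extra sequence, and the statistic is invariant to
rescaling both lengths. The error is a rough screen, not an alignment-based
measure: it trusts that the closest database match has a comparable genome
length, which is also its main failure mode when no close relative exists.

## Exact-match machinery

Matching statistics (`matchingStatistics`) are computed by streaming the
reversed query over a suffix automaton of the reversed subject (with the
complement strand concatenated behind a separator when both strands are
searched). This gives O(|A|+|B|) per pair and exact results; ambiguity codes
never match anything, so N-gaps silently partition matches. MEMs
(`findMEMs`) and maximal repeat pairs (`findMaximalRepeats`) are enumerated
by hashing subject seeds of the minimum length and extending only
left-maximal seed hits, which visits each maximal match exactly once. All
three operations are verified in the test suite against quadratic
brute-force oracles built on a longest-common-extension table — exact array
and set equality, not tolerances.

Chaining maximises total anchored length over anchors that strictly increase
in both coordinates with per-step gaps bounded by `maxGap` (default 5 kb);
the dynamic program is exact and is checked against exhaustive subset search
in the tests. MEMs rather than unique matches are used deliberately:
plastomes carry two identical inverted-repeat (IR) copies, so uniqueness
fails exactly where anchoring is needed. A fragment falling wholly inside
one IR copy ties between two placements; `alignContigs` reports all tied
chains and `scaffoldContigs` resolves them greedily, placing unambiguous
contigs first and giving a tied contig the placement least covered by
already-placed contigs. This is what lets fragmentation round trips
reconstruct the genome byte-for-byte even when cuts land inside the IR.

## Scaffolding policies

Contigs are sorted by subject start and oriented by strand. Neighbouring
placements can overlap on the reference (the lower-identity contig's
overlapping bases are trimmed), abut (joined directly), or leave a gap. The
default gap policy inserts an N-run sized to the reference gap net of the
contigs' unaligned tails, which preserves coordinate fidelity for downstream
barcode extraction; `gapPolicy = "direct"` concatenates instead, for
workflows that prefer a gapless single sequence and accept coordinate
distortion. Contigs whose subject interval is contained in another's are
dropped with a warning. Every draft base traces to exactly one contig base
or one N, an invariant enforced by the `Draft` validity method.

## Average common substring identification

The ACS distance uses the mean matching statistic L(A,B) with zeros floored
at 1 (so sequences over disjoint alphabets yield a finite, large distance),
the log-length normalisation log|B|/L(A,B), and subtraction of the
self-match baseline 2·log|A|/(|A|+1), which makes D(A,A) = 0 exactly.
The symmetrised form is the default because database genomes and queries
differ in length; the one-directional form is available via
`mode = "directed"`. Ties in ranking break lexicographically by subject id
for determinism. No "no-match" threshold is applied: the top hit is always
reported with its distance, and callers can threshold downstream.

## Simulated PCR

Primer sites match by IUPAC possibility-set intersection on the primer side;
a fully ambiguous template base (N) binds nothing, so N-filled gaps never
amplify. Up to `maxMismatch` (default 2) mismatches are tolerated per
primer, except in the 3 bases at the primer's 3' end, which must match
exactly — a standard approximation of polymerase extension chemistry. Both
template strands are scanned and the amplicon spans the forward primer's 5'
end to the reverse primer's 5' end. The bundled primer table
(`extdata/primers_synthetic.tsv`) is synthetic: the pairs exist so the
simulator can plant recoverable loci, and they are clearly labelled as such
rather than curated barcoding primers.

## The synthetic data generator

`SimConfig()` defaults define the study conditions used throughout the
tests and the acceptance script:

* a 30 kb genome with 3 kb IRs and a 3.6 kb SSC at 37% GC — a deliberately
  desk-scale plastome (real plastomes are ~120–160 kb with ~25 kb IRs; all
  algorithms are length-agnostic, and 30 kb keeps the full suite inside a
  few minutes);
* divergence dials of 5% between genera, 2% within a genus, and 0.3% within
  a species, giving a clean genus/species signal for identification
  experiments;
* 2 × 125 nt reads from fragments with a 350 bp mean and 120 bp sd
  (log-normal, the standard model for degraded DNA), 0.2% per-base error,
  and an 80% plastome read fraction, with the remainder drawn from a random
  same-GC background genome as a contamination model.

Marker loci (rbcL-, matK- and rdna-like) are planted with literal primer
sites; when genomes are evolved, the 35 bp at each marker end are held
substitution-free — the conserved flanks that real barcoding primers target —
while the marker interior and the rest of the genome mutate freely, and
indels are kept out of marker loci so annotations remap exactly. The bases
flanking the SSC/IR boundaries are constrained so the planted IR pair is
exactly maximal, which is what lets `detectInvertedRepeat` recover the
annotated intervals precisely and makes that recovery testable as an
equality.

What the generator does **not** emulate: codon or gene structure,
instrument-specific error and quality profiles, PCR duplicates, real
contaminant taxa, heteroplasmy, and the rDNA's actual nuclear (not plastid)
location — the rdna locus is planted in the simulated genome purely to give
ranking and extraction a ground truth. Passing tests therefore demonstrate
algorithmic correctness and the qualitative behaviour of the pipeline
(e.g. that identification accuracy decays from whole plastome to short
barcode fragments), not calibrated performance on real herbarium libraries.

## Digital normalization and depth

Normalization is two-pass: canonical k-mer counts (k = 31, odd to avoid
palindromic self-canonical k-mers) are built over all pairs, then each pair
is kept, dropped (median below the low cut-off 10 or above the high cut-off
500), or kept with probability target/median above the target. The target
(default 100) is configurable since only the 10/500 cut-offs are pinned by
the workflow the package models. Depth estimation is pseudo-mapping: per
read, the union of assembly bases covered by the read's uniquely-occurring
k-mers gains one unit, so an error-free read contributes 1× across its span
and reads from unrelated genomes contribute essentially nothing (a chance
31-mer collision has probability ~4^-31). Bases inside the IR are covered by
non-unique k-mers and report zero — medians over whole plastomes remain
accurate because the IR is a minority of the genome, which is also why the
acceptance checks use the median.

## Statistical screen

`welchTTest` delegates to `stats::t.test(var.equal = FALSE)` and reports the
Welch statistic, Welch–Satterthwaite degrees of freedom, and a two-sided
p-value; the tests verify it against an independent closed-form
implementation to 1e-10 and confirm the empirical size under the null
(rejection rate ≈ 5% at α = 0.05 over 1000 replicates of n = 20 per group).
`compareGoodPoor` runs one test per parameter without multiple-testing
correction, mirroring a per-parameter presentation; `holm = TRUE` adds
Holm-adjusted p-values for users who want family-wise control.

## Numerical and design choices

* Coordinates are 1-based closed intervals (`IRanges` convention) in all
  R-facing objects and reports; 0-based coordinates exist only inside the
  compiled code.
* Ambiguity codes: exact-match operations treat them as matching nothing
  (conservative anchoring); `gcContent` weights them by expected GC so the
  statistic is deterministic and length-preserving.
* `repeatContent` sums the union of non-IR repeat-covered bases by default;
  a per-pair sum (both copies of every pair) is available via
  `sumMode = "pairs"` since either reading of "summed repeat lengths" is
  defensible.
* The sweep's acceptance criteria ("desired length and coverage") are made
  explicit and configurable: 0.8 × the median database reference length, and
  median depth 10 (the lowest assembler cut-off).
* The sweep pairs k-mer values with coverage cut-offs positionally
  (51↔10, 71↔7, 91↔15, 111↔20) rather than as a cross product; a cross
  product can be expressed by enumerating pairs in a `SweepPlan`.
* Adapter trimming and pair merging use no-indel overlap models scored by
  matching bases, with ambiguous best-overlap ties left unmerged; this keeps
  both operations brute-force verifiable and suits short-read data.
* References are treated as linear; a contig spanning the circular origin
  chains on one side only. Drafts are not rotated.

## Problem sizes

The test suite and acceptance script run at the generator's desk scale:
30 kb genomes, 20-genome databases (5 × 4), 30-query identification worlds
replicated 10 times, 6 000–40 000 read pairs per simulation, and 200-instance
oracle-equivalence sweeps with sequences up to 500 bp. These sizes were
chosen so the whole suite completes in a few minutes while every statistic
(agreement fractions, medians, retention rates) is estimated from hundreds
of independent draws.

## Known limitations

The assembler seam means de novo assembly quality is out of scope by
construction. The error statistic inherits the closest-match caveat above.
ACS identification is whole-sequence: it does not model partial drafts with
large N-gaps beyond the fact that Ns contribute matching statistic 0 (the
floor at 1 bounds their influence). The simulator's divergence model is
substitutions plus small indels without rearrangements, so structural
variation between query and reference — a real cause of poor herbarium
assemblies — is only represented indirectly through fragmentation and loss.
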