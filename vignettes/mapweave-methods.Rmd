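---
title: "Methods: map-guided assembly improvement at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: map-guided assembly improvement at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mapweave rebuilds, end to end and at a size a laptop can handle, a genome
improvement strategy in which a draft plant assembly and an F8 recombinant
inbred line (RIL) genetic map improve each other: the map orders and orients
draft scaffolds into chromosome-scale pseudomolecules, long reads fill gaps
and connect scaffolds, and a reconciliation step resolves the conflicts that
arise because a read-based gap filler cannot place whole scaffolds into
map-introduced joins.  This vignette documents the models, parameters,
numerical choices and known limitations; the README shows a worked run.

## The synthetic study system

Real data of this kind (a ~200-Mbp genome, hundreds of thousands of
genotyping-by-sequencing reads) is neither redistributable nor tractable in a
test suite, so every input is simulated with the statistical structure the
analysis relies on, and with the ground truth retained so that results can be
verified byte-exactly.

* **Reference genome.** `simulate_reference()` draws i.i.d. sequence at a
  configurable GC fraction (default 0.38, a typical crucifer value). The
  default study shape is 11 chromosomes — the karyotype of the system the
  workflow targets — of 120 kbp each, a deliberate ~1/150 linear scale-down.
* **Parental divergence.** `simulate_parents()` places biallelic SNPs
  uniformly (default 1.4 × 10⁻³ per bp, ≈170 per chromosome). This marker
  budget mirrors the real study's *per-linkage-group marker count* at the
  grouping stage (≈165 markers/LG), which is what determines whether a
  linkage group holds together; the per-bp rate itself is a scale artifact.
* **RIL population.** `simulate_ril_population()` makes each line descend
  from a heterozygous F1 through single-seed descent (default 7 selfing
  rounds → F8, 216 lines, as in the study design). Each meiosis places
  crossovers as a Poisson process with mean equal to the chromosome map
  length in Morgans — the Haldane model, with no interference, because no
  interference model is stated for the source system. The map length
  defaults to 1.625 Morgans per chromosome (the study's average linkage
  group spans 162.5 cM). F8 is simulated explicitly rather than by the RIL∞
  shortcut, so residual heterozygosity (≈0.5⁷ ≈ 0.8% per locus) exists as in
  real data. Genotypes are then degraded GBS-style: calls flip to a random
  other state at `error_rate` (default 1%) and are masked at `missing_rate`
  (default 5%). The source study does not report its GBS error rate, so
  these are configurable defaults, not calibrated values.
* **Draft fragmentation.** `fragment_assembly()` cuts chromosomes at
  Poisson points (mean scaffold 15 kbp), replaces one internal stretch per
  scaffold (probability `gap_rate`) with the same number of Ns — recording
  the removed bytes — and shuffles and randomly flips the scaffolds. The
  removed-byte record is what lets the test suite check gap fills exactly.
* **Long reads.** `simulate_long_reads()` samples both strands uniformly,
  truncated-geometric lengths (default mean 4 kbp), substitutions and
  indels at a configurable total rate. No chimeras, homopolymer bias or
  quality decay are modelled; "error-free reads" results therefore bound
  what real long reads can achieve, they do not predict it.
* **Contamination.** `simulate_contamination()` appends short bacterial-like
  scaffolds and emits a per-1-kbp-fragment taxon hit table, so the screening
  rule (flag a scaffold when >50% of its length hits bacteria at bit score
  ≥50 and it has no Viridiplantae hit) can be exercised against known truth.

Every generator expands one global seed into per-stage substreams by hashing
the stage name, so any stage can be re-run independently and reproducibly.

## Marker reduction

GBS produces SNP "islands" — many markers with the same segregation pattern —
whose redundancy both slows mapping and inflates map length once genotyping
errors accumulate. The reduction pipeline applies, in this order:

1. `filter_missing()` — drop markers missing in more than 30% of lines.
2. `collapse_window()` — within 10-kbp windows, merge runs of markers whose
   call vectors are identical on pairwise non-missing entries; the leftmost
   marker represents the group and missing entries are filled from members.
   The identity-on-shared-entries reading is a deliberate choice: with GBS
   missingness, demanding literal identity would leave nothing to collapse.
3. `collapse_similar()` — merge markers whose pairwise similarity (matching
   calls over shared non-missing entries, heterozygous calls counting as a
   third state) exceeds 90%.

The 90% step uses **complete-linkage** clustering, iterated to a fixpoint,
rather than single linkage. This was a design decision forced by
implementation evidence: similarity between markers d cM apart is roughly
1 − R(d), so at a RIL recombinant fraction of 10% the merge radius is ≈5–6 cM,
and single linkage chains every marker run denser than that — in trials it
collapsed entire linkage groups to a handful of markers and fragmented the
LOD-9 grouping. Complete linkage bounds the cluster diameter, so clusters
remain groups of near-duplicates and the retained markers stay dense enough
(≈3–5 cM spacing) to group correctly; iterating to a fixpoint restores
idempotence. Representatives are the least-missing member (ties: leftmost).

Segregation distortion is tested per marker with a 1-df chi-square against
the 1:1 A:B RIL expectation among homozygous calls (heterozygotes excluded),
Bonferroni-corrected at α = 0.05 by default. The source analysis reports
distortion without naming a test; the chi-square choice is ours and is
configurable.

## Linkage map construction

For each marker pair, lines homozygous at both loci are informative; the
observed RIL recombinant fraction R is corrected to the meiotic fraction by
inverting R = 2r/(1+2r) (selfing-RIL at F∞; residual F8 heterozygotes are
excluded, and the F8-vs-F∞ bias is far below the method's resolution). The
LOD score is a binomial likelihood ratio against free recombination,

LOD = k·log₁₀(R̂) + (n−k)·log₁₀(1−R̂) − n·log₁₀(½),  R̂ = max(R, 1/(2n)),

floored at zero; pairs with fewer than 10 doubly informative lines are
untestable. Grouping is the transitive closure over pairs with LOD ≥ 9.0
(the study's threshold). Ordering replaces the interactive regression/ML
duality of desktop mapping software with one deterministic algorithm:
greedy nearest-neighbour seriation on r seeded at the marker most distant
from any other, refined by 2-opt until no swap reduces the sum of adjacent
r, with the orientation canonicalised so the lexicographically smaller end
comes first. Distances use the Kosambi function by default (the convention
of the mapping software the study used), Haldane optionally; an adjacent r
of 0.5 is capped at 50 cM with a warning. Finally markers closer than 0.1 cM
to the last kept marker are pruned, keeping the leftmost of each run (the
source rule does not say which member is kept; leftmost is our deterministic
choice).

## Map integration

`place_scaffolds()` assigns each scaffold the majority linkage group of its
markers (ties: larger summed pairwise LOD, then smaller group number), the
median marker cM as anchor (median, not mean, so one mis-mapped marker
cannot drag a scaffold), and the sign of the Spearman correlation between
marker bp and cM as orientation. Single-marker scaffolds get "?" and are
treated as forward — the orientation is genuinely undetermined and forward
is the convention. `build_pseudomolecules()` concatenates each group's
scaffolds in anchor order (ties: longer scaffold first, then name), joined
by exactly 100 Ns recorded as `map_join` gaps — 100 N being the conventional
"gap of unknown length" marker — and emits a lift chain mapping every source
base to its new coordinate.

## Gap filling and reconciliation

The long-read stage replaces an external gap-filling pipeline with a
desk-scale equivalent that keeps the two properties the reconciliation
depends on: reads map uniquely (ties leave a read unanchored) and gaps are
filled by read sequence anchored on both flanks.

Anchoring indexes every assembly k-mer that occurs exactly once (default
k = 17, read k-mers sampled at stride 3), chains read hits colinearly per
scaffold and strand by longest increasing subsequence, and keeps chains with
at least 3 k-mers. A gap of ≥10 Ns (the minimal gap size convention) closes
when at least `min_support` reads anchor on both flanks; the inserted bytes
are the plurality among the spanning reads' inferred fill sequences (a full
partial-order alignment would be overkill at the error rates simulated).
One-sided reads shorten a gap from the reachable side, always leaving at
least one N. Reads whose anchor path exits one scaffold end and enters
another create connection events; an end with conflicting partners stays
unjoined and the conflict is logged. Scaffold-end extension beyond
connections is not performed — it adds unverifiable sequence and nothing
downstream consumes it.

Reconciliation handles the structural conflict between the two improvement
routes: a connection discovered on the *base* assembly is impossible on the
*integrated* assembly when the map already joined one of its ends to a
different neighbour, because a read-based filler cannot insert a whole
scaffold into a join. `reconcile()` therefore (1) fills the base assembly
and records its connections, (2) fills the integrated assembly, (3) splits
the integrated assembly at exactly the map-join junctions that block base
connections — original intra-scaffold gaps are never split — (4) re-fills
the split assembly so the connections can form, (5) reconnects with exactly
100 Ns any split junction the reads did not re-join, and (6) restores every
map-join gap that was only partially filled back to exactly 100 Ns, keeping
the filled flanking bytes. The composed lift chain (integrated → final) is
returned so annotations and markers can follow.

## Annotation migration

The source workflow ran two external lifters and preferred the
nucleotide-level one on disagreement. Here both candidate sets are produced
by the internal chain under two strictness settings — exact block-wise
lifting versus lifting plus neighbour-offset rescue — so the merge logic
(`both` / `primary only` / `secondary only`, primary wins on disagreement)
is exercised without those tools. Rescue infers a candidate interval for an
unlifted exon/CDS from the offset of its nearest lifted sibling and accepts
it only when the target bytes equal the source bytes exactly
(reverse-complemented across flipped regions). Classification marks a gene
`pseudo` when any of four defects holds: spliced CDS not starting with ATG;
no terminal stop — after first attempting the 3-base CDS extension
correction; some CDS feature with no stop-free reading frame (the annotated
terminal stop codon is excluded from the scan, otherwise every valid gene
would flag its own stop); or spliced length not divisible by 3. Duplicate
genes (same scaffold, strand, start, end) keep the lexicographically
smallest id; genes strictly contained in another gene are removed. Renaming
numbers genes 1..n from the 5' end per scaffold as `Aa3<type><n>G<i>` with
isoforms `.1`, `.2`, …, and preserves the prior id in the `note` attribute.

## Numerical conventions

* Internal coordinates are 0-based half-open everywhere; conversion to
  1-based inclusive happens only when writing GFF3/AGP.
* Percentages round half away from zero to one decimal (`format_pct()`),
  matching the reporting convention of the tables this mirrors.
* N50 includes N bases; L50 is the rank of the N50 scaffold.
* All ties anywhere resolve deterministically (documented per function), so
  a fixed seed reproduces every output byte.

## Problem sizes used by the tests

The default simulated study is 11 × 120 kbp chromosomes, 216 RIL lines,
≈1,850 raw markers, ≈90 draft scaffolds and ≈2,200 long reads at ≈6×
coverage; the test suite runs most modules on 1–3 chromosome reductions of
the same conditions. These sizes were chosen so the statistical behaviour
that matters (LOD-9 group integrity, ordering accuracy, spanning-read
availability) is preserved while a full run stays in the minutes range.

## Limitations

* Sequence is i.i.d.: no repeats, so unique-k-mer anchoring is easier than
  on a real genome; centromeric marker pile-ups and repeat-driven
  mis-joins are out of reach of these tests.
* Parents differ only by SNPs — no structural variation — so colinearity
  between map and assembly is perfect in truth.
* Read errors are uniform substitutions/indels; consensus from plurality of
  spanning reads, adequate here, would need a real consensus algorithm at
  PacBio/ONT error profiles.
* The RIL correction assumes selfing at F∞; acceptable at F8, wrong for
  sib-mated designs.
* Organellar genomes, QTL mapping and expression-based triage of unlifted
  genes are out of scope.
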