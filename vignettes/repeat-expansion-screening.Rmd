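---
title: "Screening exome cohorts for repeat expansions: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening exome cohorts for repeat expansions: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exrepeat)
```

## The problem

Short tandem repeat (STR) expansions — a 1–12 bp motif repeated in tandem
beyond a locus-specific threshold — are the most common cause of inherited
neurological disease (Huntington disease, myotonic dystrophy, the
spinocerebellar ataxias, CANVAS, and many others). Short-read exome
sequencing was not designed to genotype them: a 100–150 bp read cannot span
an allele longer than itself, and exome capture kits differ in whether they
target a given repeat at all. Modern callers classify the reads at a repeat
locus as *spanning* (whole tract plus flank on both sides: exact allele
size), *flanking* (one boundary: a lower bound) or *in-repeat* (entirely
inside the tract: the allele is at least a read length long), and genotype
from that evidence.

`exrepeat` packages that workflow for cohort-scale screening: a catalogued
set of repeat expansion disease (RED) loci with unit and bp cutoffs, a
seeded synthetic cohort generator, an evidence-based repeat genotyper, a
deterministic pass/borderline/fail triage of predicted expansions with
interruption screening, and cohort metrics (genotyping rate and locus
coverage by capture kit and read length).

## The locus catalogue

The shipped catalogue (`default_catalogue()`) has 26 RED loci spanning
coding, intronic and UTR repeats. Each row carries the repeat motif, the
pathogenicity cutoff in repeat units and in bp, a region class, optional
interruption motifs, a zygosity requirement, and a motif-change flag.

Design choices worth knowing:

* **Cutoff inclusivity.** A single cutoff per locus is interpreted as the
  minimal abnormal size: `allele_units >= cutoff_units` is expanded. We do
  not model separate premutation bands; the single boundary separates
  normal from "pathogenic or premutation range".
* **Counting discrepancy.** Published summaries of this locus set sometimes
  count 27 loci (12 coding, 7 intronic, 8 UTR); the tabulated set we ship
  resolves to 26 rows (12 coding, 7 intronic, 7 UTR). The loader reports its
  actual per-class counts rather than the irreproducible total.
* **No-threshold loci.** PHOX2B, NIPA1 and PABN1 are catalogued with `NA`
  cutoffs (their motifs are the degenerate GCN/GCG class). They are loaded
  and included in coverage metrics but excluded from expansion calling;
  threshold arithmetic on them raises a typed `exrepeat_no_threshold`
  condition rather than returning a number.
* **Motif change (RFC1).** The CANVAS locus is pathogenic through an AAGGG
  motif absent from the reference allele, catalogued as 0 units / 5 bp.
  The bp-consistency invariant (`cutoff_bp == cutoff_units x motif length`)
  is enforced for every row except such whitelisted motif-change loci, whose
  catalogued bp value is returned verbatim; any allele carrying at least one
  pathogenic-motif unit is classified expanded.
* **Interruptions and zygosity.** ATXN1 carries `CAT` as its catalogued
  interruption motif (interrupted CAG tracts are non-pathogenic there); GLS
  is marked `biallelic` because only biallelic expansions cause disease.
* **Coordinates.** Shipped intervals are synthetic placeholders (consistent
  chrom/start/end per locus, interval length equal to a typical normal
  tract) sufficient for depth aggregation; users with real GRCh38
  coordinates supply their own columns. Intervals are 0-based half-open
  internally and converted to 1-based only in VCF output.

A locus is *spanning-resolvable* at read length `L` with minimum anchoring
flank `f` when `cutoff_bp + 2f <= L` (`detectability()`); otherwise normal
and expanded alleles can only be separated through lower-bound evidence.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure of a heterogeneous
diagnostic exome cohort; it does not simulate sequences through alignment.
Per sample x locus:

1. **Depth.** The per-base coverage is the kit's on-target depth (default
   60x) at targeted loci and its off-target depth (default 3x; 0 for the
   Nextera-like profile) elsewhere. Each haplotype contributes
   `Poisson(depth/2 x (tract_bp + L - 1)/L)` reads, so the expected pileup
   depth over the tract equals the configured coverage — `depth` means what
   `samtools depth` would report, not a raw read count.
2. **Genotypes.** Normal alleles are discretised Gaussians around the
   locus's reference tract (SD 3 units), truncated below the cutoff. With
   per-allele probability 0.005 (enriched to 0.02 at DMPK, HTT, GLS and
   ATXN1, the loci that dominate predicted expansions in practice) an
   allele is drawn instead from a uniform expanded range
   `[cutoff, 10 x cutoff]` units — truncation that keeps simulated tract
   strings small. Motif-change loci use 100–400 units. These rates are
   deliberately enriched relative to clinical reality (~0.3% of samples per
   locus) so that a 1,000-sample synthetic cohort contains enough
   expansions to measure recovery; they are conditions of the synthetic
   study, not population estimates.
3. **Read placement.** Read starts are uniform over the
   `tract_bp + L - 1` placements overlapping the tract. A read is
   *spanning* if it covers the tract with at least `min_flank` (default
   10 bp) anchoring on both sides, *in-repeat* if entirely inside the
   tract, else *flanking*. In-tract sequence is reported frame-aligned to
   motif boundaries, as a realigning caller reports it, so in-repeat
   sequences are within one motif length of the read length.
4. **Lower-bound bookkeeping.** Every non-spanning read records the
   minimum allele it witnesses: its full in-tract units, plus one only when
   a read edge strictly inside the tract cuts a unit mid-motif (the partial
   unit proves one more unit exists). A naive "observed + 1" rule over-calls
   whenever a read edge coincides with a tract boundary — for example a read
   covering the whole tract with sub-`min_flank` anchoring — and that
   over-call would masquerade as a lower-bound genotype at perfectly
   spannable loci.
5. **Interruptions.** Expanded alleles at loci with catalogued interruption
   motifs carry, with probability 0.25, one interior interruption unit at a
   uniformly chosen interior position; it propagates into every read
   covering it. The real prevalence of interrupted ATXN1 expansions is far
   lower (~3%); the enrichment makes interruption handling measurable at
   cohort size 10^3.
6. **Quality.** Read quality is a Bernoulli flag (`base_quality_ok`,
   failure rate 0.02/read); no base-level error model. Reads are never
   mutated, so "high-quality" evidence in the simulation is clean — one
   consequence is that synthetic cohorts produce very few `fail` triage
   verdicts, unlike real pileups where degraded evidence dominates. Tests of
   the fail rules therefore use constructed fixtures.

The default kit preset (`default_kits()`) mirrors four common capture
designs (SureSelect V6/V4, TruSeq, Nextera-like) with read lengths
150/125/100/75 bp and illustrative target maps: ATXN2, HTT and CACNA1A
untargeted on some kits, most intronic repeats untargeted except NOP56 and
CSTB, and the Nextera profile contributing zero off-target depth (it is the
kind of focused design that can miss an intronic FXN expansion entirely).
These maps are plausibility presets, not vendor BED files.

Everything is driven by one integer seed; equal seeds reproduce the
manifest, truth table and evidence byte for byte.

## The repeat genotyper

`genotype_locus()` / `call_cohort()` implement a deliberately simple
evidence-based genotyper in the style of ExpansionHunter-class callers
(graph realignment itself is out of scope — the generator already outputs
classified reads):

* Spanning reads are tabulated by implied unit count. As a stutter
  surrogate, a unit value is absorbed into an adjacent (±1 unit) value only
  when the neighbour holds at least 4x its read count. A symmetric ±1 merge
  would collapse genuine adjacent-allele heterozygotes (e.g. 20/21 units,
  common under an SD-3 allele model), which is why absorption is
  asymmetric.
* The two largest clusters (ties towards smaller alleles) give the exact
  genotype; one cluster with no longer-allele signal is homozygous.
* If flanking/in-repeat evidence implies a minimum allele above the largest
  spanning allele, the long allele becomes that minimum with a lower-bound
  flag (rendered `"23/>81"`-style): in-repeat reads imply
  `floor(L / motif_length)` units; flanking reads their witnessed minimum.
* Caller locus coverage (LC) is the mean per-base depth of the caller's
  working set over the catalogued interval; the filter is `NoCall` (zero
  reads), `LowDepth` (LC below 10, a conventional minimum, configurable),
  else `PASS`.

In the pipeline the caller works on quality-passing reads while pileup LC
(`pileup_lc()`, the `samtools depth` analogue) is computed over all reads,
so caller LC is bounded above by pileup LC — the package's model of why
caller-reported coverage consistently under-reads BAM-derived coverage.
Confidence intervals are not modelled; the lower-bound flag is the only
uncertainty encoding.

## Triage of predicted expansions

Predicted expansions (long allele at or above the cutoff) are classified by
a stateless rule engine. With `L` true when the sample's read length
strictly exceeds the locus cutoff in bp, `n_hq` the number of high-quality
reads supporting the expanded genotype (reads whose implied units or
witnessed minimum reach the cutoff), and `n_max` the number of in-repeat
reads of clean motif content:

| category | rule |
|---|---|
| `pass` | `L` and (`n_hq >= 2` or `n_max > 10`) |
| `borderline` | (`L` and `n_hq == 1`) or (not `L` and `n_hq >= 2`) |
| `fail` | anything else |
| `discard_interruption` | catalogued interruption on a supporting read |

Boundary readings are deliberate and tested: "longer than" is strict (read
length equal to the cutoff falls into the short-read branch), "a large
number (>10)" is strictly greater than ten, and the cells the prose rules
leave unspecified (one supporting read at a short-read kit; no support but
ten maximum-expansion reads) are `fail`. Interruption discard applies only
when the interruption lies on reads supporting the expanded allele;
interruptions seen on normal-allele reads are reported but do not discard.
Whether "supporting" reads must span or may be flanking/in-repeat is
ambiguous in the source procedure; we count any read whose evidence is
consistent with the expanded allele and document the choice here. At
biallelic-requirement loci (GLS) a monoallelic expansion is flagged
(`monoallelic_at_biallelic_locus`) for follow-up rather than reclassified.

Note a structural consequence: at a kit whose read length cannot make any
read imply the cutoff (e.g. ATXN1's 117 bp cutoff at 100 bp reads, where an
in-repeat read implies at most 33 units), no expanded call exists at all —
interrupted or not — so interruption discard is only observable at kits
that can predict the expansion in the first place.

## Cohort metrics

* **Genotyping rate** is operationalised as the percentage of a kit's
  samples whose call carries the caller's `PASS` filter (the source
  procedure conflates the caller filter with review "pass"; we use the
  filter and say so). Loci with no call count as rate 0.
* **Rounding** follows printed precision: percentages to one decimal,
  diagnostic yield to the nearest integer; a yield over zero confirmations
  is `NA`, never a division error.
* **Validation bookkeeping** enforces that only `pass`/`borderline` calls
  are PCR-dispatched; diagnostic yield is diagnoses per confirmed
  expansion.
* **Read-length trend.** `readlength_trend()` averages genotyping rate per
  (region class, read length) and reports per-class non-decreasing
  monotonicity. The packaged experiment holds *sequencing effort* fixed —
  equal expected read counts, so per-base coverage scales with read length
  (10x/12.5x/15x at 100/125/150 bp), as when one library is sequenced
  longer. At fixed per-base coverage an LC-threshold filter is
  read-length-invariant by construction and no trend exists; the effort
  parameterisation is the physically meaningful comparison.

## Problem sizes and numerical checks

The test suite exercises a study-scale synthetic cohort of 4 kits x 250
samples x 26 loci (~1,000 exomes, ~1.8M reads), simulated once and shared.
On it the suite verifies: 100% of spanning-resolvable, well-covered
(target, 60x) simulated expansions triage pass/borderline; every
interrupted ATXN1 expansion that yielded an expanded call is discarded;
exact diploid genotypes are recovered in >= 99% of sample-locus pairs where
both alleles have at least two spanning reads; calls never contradict the
truth table (exact alleles are always true alleles, lower bounds never
overshoot); and caller LC never exceeds pileup LC. The read-length trend
experiment uses 3 x 150 samples. The triage engine is checked against an
independently written brute-force truth table over 160 enumerated rule
inputs.

What passing these tests does *not* show: performance on real exomes. The
generator has no capture bias beyond the binary target map, no GC or
fragment-length structure, no base-level errors, no somatic or stutter
mosaicism, and clean frame-aligned evidence; real genotyping rates (e.g.
the very low rates of ATXN2 under some kits) are properties of real capture
chemistry that the presets only gesture at. The package reproduces the
*procedural* behaviour of a screening pipeline — cutoff arithmetic, triage
logic, bookkeeping, stratified metrics — under controlled conditions.

## Degenerate inputs and edge behaviour

Empty evidence yields `NoCall` and renders `"./."`; empty verdict sets
yield all-zero summaries; a header-only catalogue loads as an empty
catalogue; zero samples simulate to empty outputs without error. Unknown
region classes, duplicate genes, bp-inconsistent non-whitelisted rows,
orphan sample ids and mismatched LC key sets are all named validation
errors. Seeds fix every random draw; two runs of any pipeline stage with
equal inputs produce identical files.
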