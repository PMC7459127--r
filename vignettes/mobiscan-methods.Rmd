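---
title: "Methods: TE insertion-polymorphism discovery, genotyping and population analysis"
author: "mobiscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE insertion-polymorphism discovery, genotyping and population analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `mobiscan`, and what the synthetic-data validation
does and does not demonstrate.

## The detection model

`mobiscan` detects TE insertion polymorphisms (TIPs) purely from
*junction reads*: reads that span the boundary between a TE terminus
and its flanking genomic sequence. The model is count-based — base
qualities are carried through I/O but never enter a score — and
deliberately uses only split-read evidence; discordant read-pair
spacing is not modelled.

**End library.** The terminal `end_len = 150` bp of each curated TE
element are extracted from both ends (elements shorter than 150 bp
contribute a single `whole` end; elements under 300 bp yield
overlapping ends). Redundancy between ends is decided by an explicit
criterion — an optimal Smith–Waterman local alignment with identity
≥ 0.90 over ≥ 75 aligned columns, with both strands tested — applied
greedily after sorting ends by (length descending, id): the first
non-redundant end becomes a representative, later redundant ends are
dropped and record their representative. The sort makes the result
independent of input order. The scoring scheme is BLASTN-like
(match +1, mismatch −2, gap open −4, gap extend −1) and configurable;
the alignment itself is exact dynamic programming with a deterministic
tie-break (lowest end coordinates, diagonal-first traceback), not a
heuristic, so the collapse is reproducible to the base.

**Junction reads.** Each read (both orientations) is searched against
the representative ends by exact 15-mer seeding followed by ungapped,
score-maximising extension along each seeded diagonal (match +1,
mismatch −2; the best-scoring contiguous segment is kept). A read
qualifies when the TE segment covers ≥ `min_te_match` = 20 read bases
at ≥ 0.95 identity, reaches the junction-forming terminus of the end
(within 2 bp of slack), and leaves ≥ `min_flank` = 30 unaligned bases
on exactly the flank side. The ungapped engine is a deliberate choice:
the evidence model is substitution-only (as is the simulator's error
model), which makes the diagonal segment the exact optimum while
keeping cohort-scale scanning fast; the engine sits behind the module
surface and can be swapped for a gapped aligner without changing any
contract. The thresholds 20/30 make a 100-bp read informative on both
sides of the junction while keeping flank placement specific.

**Flank mapping and breakpoints.** Flanks are placed on the reference
by the same seed-and-extend search over both strands; a flank maps only
if a single location attains the best segment score and no second
seeded location scores within 95% of it — multi-mapping flanks are
discarded rather than guessed. The breakpoint is recorded as the
0-based insertion offset `b` (the TE sits between reference bases
`b − 1` and `b`) together with the side of the insertion point on which
the TE body lies; emitted tables print the 1-based index of the base
left of the insertion point. Internally *all* coordinates are 0-based
half-open and are converted exactly once, at the I/O boundary.

**Clustering.** Candidate breakpoints pooled over all accessions are
clustered by single linkage within a 15-bp window, keyed by
(chromosome, TE id, element end side, TE direction); the locus position
is the member median (lower middle on even counts). The 15-bp window
absorbs breakpoint jitter from alignment-end trimming while staying far
below the spacing of distinct insertions.

**Ref/nonRef classification.** A locus is `Ref` (present in the
reference assembly) when the reference sequence adjacent to the
breakpoint, on the TE side, aligns to the corresponding TE terminus at
≥ 0.90 identity over ≥ 50 bp and the alignment starts at the junction;
the reference TE span is then delimited by locating the opposite
terminus within twice the element length.

## Genotyping

For every locus two allele templates are built with 150-bp genomic
flanks. For nonRef loci the presence template joins the reference flank
to the TE terminus and the absence template is the contiguous reference
across the empty site. For Ref loci the presence junction is read
directly from the reference; the absence template is the *excision
joint* — the reference with the TE span and one copy of the target-site
duplication (TSD) removed. The TSD is detected by comparing the
sequence immediately left of the span with the sequence immediately
right of it (largest match up to 20 bp): without this correction the
joint would retain a duplicated target site and absence reads would no
longer align across it. A spurious TSD detection requires an exact
coincidental repeat and shifts the joint by at most a few bases.

A read supports an allele when it crosses that allele's junction with
≥ `min_overlap` = 20 matched bases on both sides at ≥ 0.95 identity;
reads supporting both alleles of one locus are discarded as
uninformative. Calls are made from ≥ 1 supporting read — `(0,0) → M`,
`(p>0,0) → P`, `(0,a>0) → A`, both `→ H` — with stringency deferred to
the filter stage's singleton rule; there is no binomial test because
the intended cohorts are near-homozygous inbred accessions, so `H`
calls are themselves a quality signal. Ref loci whose span could not be
delimited get no absence template and are genotyped
presence-versus-missing only (a documented limitation).

## The filter cascade

Applied in order, with every threshold strict exactly as stated:
missing fraction > 0.5; heterozygosity > 0.41 computed over non-missing
calls (the denominator choice is ours; computing over all accessions
would conflate missingness with heterozygosity); single-carrier loci
with < 3 presence reads; end-pair merging. Two loci merge when they
come from the same TE *family* on the same chromosome with opposite end
sides and opposite TE directions and either (nonRef) their breakpoints
differ by ≤ 25 bp — the two sides of one insertion are separated by the
TSD only, typically 2–10 bp — or (Ref) they flank the same reference TE
span. Merging on the family rather than on an identical element id is
deliberate: after redundancy collapse the left and right junctions of
one insertion generally match representative ends donated by
*different* copies of the same family, so id equality would almost
never hold. Genotype joining: agreeing calls stand, `H` dominates, `M`
defers to the other end, and a P/A conflict becomes `M` with its read
counts zeroed — a true heterozygote should agree across ends, so a
cross-end conflict signals an artifact rather than heterozygosity. When
more than two loci are mutually mergeable, the closest pair is merged
and a warning raised.

## Population analytics

Frequencies are *carrier* frequencies — `H` counts as a carrier — not
allele frequencies; this matches a presence/absence marker reading of
the data and is the package's documented convention. Classes implement
the integer-percent bins on exact fractions: `low` (≤ 0.30, boundary
inclusive), `median` (0.30–0.70, upper inclusive), `high`
(0.70–1 exclusive), `fixed` (exactly 1). Differential fixation between
groups uses inclusive ≥ 0.90 / ≤ 0.10 thresholds; heterogeneity uses a
strict > 0.5 difference. Gene-proximity annotation resolves one
category per locus by the precedence CDS > intron > upstream >
downstream > intergenic, with strand-aware 500-bp windows inclusive at
the window edge and nearest-gene tie-breaking; a breakpoint at offset
`p` disrupts an interval `[a, b)` iff `a < p < b`. Report tables round
densities to integers and averages/percentages to one decimal, half
away from zero, matching how such tables are conventionally printed.

## Population genetics

Loci with carrier frequency in the inclusive band [0.2, 0.8] are
encoded as a binary matrix (`H → 1`; a flagged alternative is to treat
`H` as 0.5-dosage, which the FST path does). The distance is the mean
pairwise character difference over mutually called loci, which adjusts
for missing calls pair by pair. The NJ implementation is standard
Saitou–Nei (Q criterion, usual branch-length formulas) with two
determinism rules: ties in Q break towards the lexicographically
smallest label pair, and negative branch lengths are clamped to zero
with the deficit moved to the sister branch (at the final trifurcation,
to the largest remaining branch). Branch lengths are plain NJ lengths;
least-squares refitting is out of scope. PCA imputes missing cells by
the locus mean, centres, scales by `sqrt(p(1 − p))` (the SNP-style
normalisation; a no-scaling flag exists), eigen-decomposes the
accession covariance, reports percent variance over positive
eigenvalues, and fixes each component's sign by making its
largest-magnitude loading positive. FST is Weir & Cockerham (1984) with
observed heterozygosity, computed per locus from presence dosages
(P = 2, H = 1, A = 0, missing excluded; ≥ 2 called accessions per group
required) and combined as a ratio of sums — our diploidisation
convention, since a binary matrix alone does not define one.

## The simulator: what it emulates and what it does not

`sim_config()` defaults define the validation conditions, chosen once:

* 20 accessions in four morphotype groups of five; a 100-kb
  two-chromosome backbone of i.i.d. uniform bases, post-processed so no
  15-mer occurs twice genome-wide (guaranteeing unique flank mapping);
* a 24-element TE library over seven superfamilies (TIR, Helitron,
  LTR, SINE, LINE representatives, 200–600 bp) with within-family
  copies diverged by 2% substitutions — enough that family copies
  always collapse to one representative end (> 90% identity) while
  junction reads from any copy still pass the 0.95 read-identity gate;
* 50 planted loci: 10 fixed Ref insertions, 32 segregating nonRef loci
  at target frequencies 0.15/0.50/0.85 (Bernoulli per accession), and 8
  differential-fixed nonRef loci at 0.95 versus 0.05 realised by exact
  carrier counts. Exact-count realisation for the differential class is
  deliberate: with five accessions per group a Bernoulli draw at 0.95
  frequently realises 4/5 = 0.8 and no method could then call the locus
  differentially fixed, so the planted condition would not be the
  tested condition;
* TSDs of 0–10 bp fixed per superfamily (0 for the Helitron-like
  family, which biologically inserts without target duplication);
* 10× expected coverage of 100-bp single-end reads drawn uniformly
  from both haplotypes, 1% substitution errors by default (0 where a
  test's contract is exact recovery), 5% heterozygous carriers, and 2%
  accession-locus coverage dropout to emulate missing calls.

Each stage draws from its own RNG stream derived from the master seed,
so changing one stage's parameters does not perturb another's draws,
and identical configs give byte-identical outputs.

The simulator does **not** model indels or quality-profile errors, GC
or coverage bias, nested or truncated insertions, segmental
duplications (a repeat-free backbone guarantees unique mapping), or
genome-scale references. Passing the recovery tests therefore shows the
pipeline's logic is correct under its own evidence model — split reads
with substitution noise on a mappable genome — not that it matches
tools tuned for real repeat-rich genomes at scale.

## Validation sizes and determinism

The test suite and the acceptance script run the full pipeline on five
cohorts (seeds varied) at the default 20 accessions × 100 kb × 10×,
about ten seconds per cohort on one CPU — a deliberate desk-scale
problem size; estimator-level checks (alignment, NJ, FST, PCA) use
independent pure-R oracles, closed forms or published formulas at small
n. Floating-point values in emitted tables are rounded to six
significant digits at I/O so that reruns are byte-identical across
platforms.

## Known limitations

* Split-read evidence only; no insert-size or read-pair signal.
* Ungapped read-level matching: an indel inside a junction read loses
  that read (not the locus, at realistic coverage).
* Locus strand is inferred but not reported in the profile tables.
* Heterozygote detection needs reads on both alleles; at 10× a true
  heterozygote is occasionally called `P` or `A` (the dominant error
  mode in the accuracy tests).
* The 0.41 heterozygosity threshold is taken as given, not re-derived.
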