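---
title: "Discovering repeat insertion domains of lncRNAs: models and methods"
author: "ridlscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering repeat insertion domains of lncRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ridlscan)
```

## The problem

Transposable elements (TEs) litter mammalian genomes, and lncRNA exons are
no exception: a large fraction of lncRNA nucleotides derive from repeats.
If a TE fragment retained in a mature lncRNA contributes to the
transcript's function — say, as a nuclear-retention element or a
protein-binding platform — it should carry signatures of selection that
neutral insertions lack. `ridlscan` operationalizes three such signatures
at the level of the *repeat type* (RepeatMasker `repName`, e.g. MIRb),
then maps type-level evidence back to individual *instances* to build a
repeat-insertion-domain (RIDL) annotation, and finally asks what RIDLs do
to their host transcripts.

The central difficulty is that exons and introns differ in base
composition, length and conservation for reasons that have nothing to do
with RNA function. Each screen therefore either normalizes by an internal
control (intronic TEs of the same type, which share insertion and decay
history with the exonic copies) or compares against an explicit positional
randomization.

## Exonic TE curation

Exons of all transcripts of a gene are unioned (bookended intervals merge,
distance 0); introns are the gene span minus the merged exons, keeping
only introns contained in exactly one gene span so every intronic
nucleotide has an unambiguous host. Every (TE instance, merged exon
interval) overlap becomes one record with one of six structural
categories: `TSS` (covers the gene's first exonic nucleotide), `TTS`
(covers the last), `encompassing` (exon strictly inside the TE),
`acceptor`/`donor` (crosses the exon's 5'/3' boundary, strand-aware),
`inside` (TE within the exon). Where several definitions hold the
precedence is TSS > TTS > encompassing > acceptor > donor > inside; the
terminal categories win deliberately, because downstream filters treat
boundary-crossing TEs (possible splice-signal donors) differently from
internal ones. A TE overlapping the merged exons of two genes yields one
record per gene, since both category and relative strand are only defined
relative to a host. Unstranded (`.`) TEs keep their coverage contribution
but are excluded from strand statistics.

## The three screens

**Enrichment.** For each type, the exonic and intronic per-nucleotide
coverage fractions (same-type overlaps counted once) form the ratio
`exonic_fraction / intronic_fraction`; a type is a candidate when the
ratio is *strictly* greater than the twofold cutoff. The ratio is
undefined when intronic coverage is zero; such types are flagged and never
candidates — treating them as infinitely enriched would promote rare
types on no evidence. A minimum-data filter (at least one exonic and one
intronic instance) gates entry into all screens for the same reason.

**Strand bias.** Functional RNA domains should sit preferentially on the
sense strand of their host. Restricted to noSJ records (categories
`inside` and `encompassing`, so splice-site-donating boundary TEs cannot
masquerade as sense-enriched), the statistic is the sense/antisense
nucleotide-coverage ratio per type. Whether coverage or instance counts is
the better statistic is genuinely ambiguous; nucleotide coverage is the
default, with `statistic = "count"` available. The null rigidly
repositions every gene structure — exon/intron architecture and strand
preserved — uniformly on a chromosome drawn proportional to length, then
re-intersects against the full TE annotation. Antisense-significant types
are flagged but never become candidates: antisense excess is more
parsimoniously explained by selection *against* sense insertions (as for
LINE-1) than by RNA function, and excluding them controls false positives.
Infinite ratios (zero antisense nucleotides) rank as maximal with no
pseudocount, since significance comes from the empirical null rather than
the magnitude.

**Conservation.** The relative exonic–intronic conservation,
`REIC = (Ce/(Ce+Ne)) / (Ci/(Ci+Ni))`, is the conserved fraction of a
type's exonic TE nucleotides over the intronic one; because both terms are
fractions, total exon and intron lengths cancel. The null shuffles the
*conserved elements* (lengths preserved, uniform per chromosome
proportional to length, overlaps permitted), not the TEs: conserved
elements are themselves enriched in exons, so shuffling TEs would inflate
the background estimate of exonic conservation and hide real signal. The
TE-shuffling alternative is available behind `shuffleTes = TRUE` for
comparison only. The screen runs once per conserved-element set, each set
contributing an independent evidence label. REIC is undefined when a type
has no exonic or no intronic TE nucleotides or zero conserved intronic
nucleotides (`Ci = 0`); such types are flagged and skipped. Depleted types
(observed below all null values) are reported but excluded from candidacy.

**Empirical p-values and FDR.** `P = rank / (1 + n_sim)`, with rank the
1-based position of the observed value among observed-plus-null in the
tested direction. A statistic beating all replicates is conservatively
assigned `P = 1/n_sim` (0.001 at the default 1000 simulations) — rounded
up from 1/(n_sim+1), never 0 — and candidacy requires exactly this floor,
i.e. the observed value must exceed every null replicate. P-values are
converted to FDR with Benjamini–Hochberg within each screen, matching the
per-screen interpretation of the q-values reported alongside.

## From candidate types to the RIDL annotation

Type-level evidence filters instances: enrichment admits all exonic
instances of the type; strand bias only instances in sense orientation to
a host transcript; conservation only instances intersecting (≥ 1 nt) an
element of the specific set that flagged the type. Selected fragments are
merged genome-wide ignoring strand; evidence labels, host genes and source
instances are unioned across the merge; the te_type of the largest
contributing fragment labels the merged record (merge semantics across
types are otherwise undefined — the contributors remain listed in
`source_instances`); merged fragments shorter than 10 nt are discarded,
with length exactly 10 surviving. Re-assembly of an assembled set is a
no-op. Whether merging should be per-gene or genome-wide is not decidable
from first principles; genome-wide was chosen because exons of distinct
genes can overlap and a nucleotide-level annotation should be disjoint,
with host genes kept as a list column.

## Insertion profiles

For types with suspicious histories, the package compares where along the
TE consensus the RIDL instances fall versus intronic instances of the same
type: `profile[pos]` is the fraction of instances whose consensus interval
covers position `pos`, and the two profiles are compared by Spearman
correlation, flagging CC < 0.9. Selection for a specific sub-domain of
the consensus shows up as a profile mismatch; rank correlation makes the
comparison insensitive to the overall abundance difference.

## Localization analyses

`RCI = log2(nuclear/cytoplasmic RPKM)` per transcript and cell line, for
transcripts with nonzero RPKM in both fractions (no additional expression
floor). One representative transcript per gene — the one with most exons,
ties broken by lexicographically smallest id for determinism — enters the
screen. Per (RIDL type, cell line), RIDL-carrying versus non-carrying
representative transcripts are compared by a two-sided Wilcoxon rank-sum
test; a type must have at least three RIDL transcripts with defined RCI in
some cell line to be tested at all; p-values are BH-adjusted globally
across all tests and called significant at q < 0.01, with direction read
from the medians. Cytoplasmic-shifting types (e.g. GC-rich repeats) are
covered by the same two-sided screen, not special-cased.

Three complementary analyses guard against confounding by transcript
length and expression: a Spearman dose–response of RCI on RIDL copy
number; an OLS fit `RCI ~ copies + length + expression` (expression in
untransformed RPKM by default, `logExpression = TRUE` available) with
variance inflation factors reported per term; and a rank-based partial
correlation of RCI and copy number given length and expression, computed
from the inverse of the rank-scale correlation matrix with a t
approximation on n − 2 − k degrees of freedom. Finally, the intra-gene
isoform contrast removes locus-level confounding entirely: within genes
expressing both a RIDL and a non-RIDL isoform in a cell line, Δ = mean
RCI(RIDL isoforms) − mean RCI(non-RIDL isoforms), summarized per cell line
by the median and a one-sided t-test of Δ > 0.

## Host-gene statistics

The clustering test asks whether RIDLs concentrate in few genes: the null
reassigns each RIDL independently to a gene with probability proportional
to merged exonic length (the expectation of a positional shuffle across
the lncRNA annotation; a uniform-per-gene option exists), and the observed
per-gene count histogram is compared to the empirical 95% band over
replicates. Functional-association tests compare RIDL-hosting genes to
exonic-length-matched controls (20 log-spaced bins, sampling without
replacement, exhausted bins capped and reported) by Fisher's exact test;
the logistic model `outcome ~ ridl_count + exonic_length +
exonic_conservation` controls both covariates simultaneously, reports
VIFs, and falls back to a ridge-penalized fit (coefficients only, p-values
NA, flagged) under complete separation. The DAF module bins derived allele
frequencies into deciles per region class and reports the rare fraction
(DAF < 0.1); elevated rare fractions in RIDLs relative to other exonic or
intronic TE nucleotides indicate ongoing purifying selection.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture: it emits every
file shape the pipeline reads, with planted effects whose recovery the
test suite checks end to end. Default study conditions: a 2 × 1 Mb genome
carrying 300 non-overlapping multi-exon genes (2–5 exons of 150–400 nt,
introns 300–1500 nt, 1–3 transcripts per gene built as sub-chains of a
master exon chain); a 30-type TE catalog with 150 instances per background
type and 600 per planted type, fragments of 60–180 nt, giving ~40% TE
coverage, comparable to the human genome; planted effects of fourfold
exonic enrichment (TE001–TE002), 90/10 sense bias (TE003–TE004), exonic
conservation 0.5 versus an intronic baseline of 0.25 (TE005–TE006, REIC 2
in expectation), a +0.5 log2 per-copy nuclear shift (TE001, TE005), and a
0.6-versus-0.4 rare-allele excess in the RIDL SNP class.

Placement realizes the effects by construction: an instance chooses
exon/intron/intergenic space with weights (fold × exonic nt, intronic nt,
intergenic nt) and lands uniformly within an interval of that compartment,
so the expected exon/intron coverage ratio equals the planted fold (the
measured ratio runs slightly below fold 4, ≈ 3.6, because fragments are
truncated to fit short exons more often than long introns). Conserved
elements arise by tiling every TE instance with short windows (12 nt for
the phastCons-like set, 15 nt for the ECS-like set), each independently
becoming an element with probability equal to its compartment's target
conserved fraction, plus 300 TE-independent background elements. The
window-level construction matters: it makes the granularity of the
planted conservation match what a positional shuffle resamples, so the
empirical null is calibrated; planting whole-instance conserved blocks
would give the observed statistic instance-level clumping variance that
the shuffle null cannot reproduce. Planted types are deliberately
abundant, as real exapted repeat families are — with only a handful of
exonic instances per type, a shuffle null over a 2 Mb genome is too noisy
for any fixed effect size to clear it.

Expression is generated as whole-cell lognormal RPKM with a baseline RCI
drawn from N(0, 1) per transcript and cell line (the symmetric null is a
free design choice, not an estimate of any real RCI distribution), shifted
additively by copies × δ; nuclear and cytoplasmic RPKM are back-computed
so `log2(N/C)` equals the intended RCI exactly before per-fraction
lognormal noise (σ = 0.25 log2 units), with an optional dropout rate
(default 0). Consensus coordinates are sampled uniformly along the
consensus, with a power-transform bias knob to exercise the
insertion-profile analysis.

What the generator does *not* emulate: nucleotide sequences, TE
phylogenies and age structure, read-level noise or mappability,
overlapping genes (placement forbids overlap, isolating the single-gene
intron filter to hand-built fixtures), chromosome-scale heterogeneity in
gene or repeat density, and correlated conservation across neighbouring
elements. Passing tests therefore demonstrate that the statistical
machinery is correct and calibrated under its stated model — not that any
particular biological dataset will yield the same candidates.

## Numerical choices and edge cases

* Internal containers are GRanges (1-based, closed); GTF is parsed at the
  boundary and BED output is 0-based half-open, sorted (chrom, start, end)
  for byte-identical reruns.
* Equal-boundary TEs (TE exactly spanning an exon) classify as `inside`,
  not `encompassing`; `encompassing` requires the TE to extend strictly
  beyond both exon boundaries.
* Shuffles may place elements on top of each other; only capacity is
  checked (an element longer than every chromosome is an error).
* The shuffle nulls run on plain integer vectors in a concatenated
  coordinate axis for speed; a testthat case pins the fast path to the
  reference GRanges implementation on a seeded shuffle.
* NA/NaN null values (e.g. REIC with `Ci = 0` in a shuffle replicate)
  count as "not more extreme", which can only make p-values larger.
* Representative-transcript ties, BED sort order, and matched-control
  sampling are all deterministic given the seed.
* Test and acceptance runs use n_sim = 100–200 with candidacy at the
  corresponding floor (1/n_sim), and 20-replicate Monte-Carlo checks; the
  default for real analyses remains n_sim = 1000.

## Known limitations

Type-level screens cannot see selection acting on a single instance of an
otherwise neutral family. The enrichment screen has no significance
machinery — it is a descriptive cutoff, as published. Conservation
evidence inherits the ascertainment of the conserved-element sets
supplied. The localization model treats RPKM linearly by default, and the
Wilcoxon screen's background (transcripts lacking the tested type) still
contains RIDLs of other types. Orthology-based dating of insertions and
cross-assembly coordinate conversion are out of scope.
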