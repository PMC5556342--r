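---
title: "Measuring copy number of highly duplicated domain families from read depth"
author: "dupdepth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring copy number of highly duplicated domain families from read depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Some protein-coding domains occur in dozens to hundreds of near-identical
copies in a genome.  The motivating case is the DUF1220 (Olduvai) domain of
the human NBPF gene family: roughly 300 haploid copies, most of them in the
1q21 region, falling into six sequence clades (CON1-CON3, conserved across
primates; HLS1-HLS3, human-lineage-specific), with copy-number variation
that has been associated with brain-size and neurodevelopmental phenotypes.
Arrays and exome capture measure such families poorly, and most CNV callers
mask segmental duplications outright.  Whole-genome sequencing read depth
can measure them - *if* the read-mapping ambiguity between near-identical
copies is characterised and handled rather than ignored.

`dupdepth` implements that programme end to end: annotate the family on a
reference, simulate truth-tagged reads from it, align them under competing
strategies, quantify copy number from weighted fragment coverage, measure
the residual ambiguity, and use those measurements to decide at which
resolution the family can honestly be quantified.

## The measurement model

Let a *domain* be an annotated interval of the reference (here: the exon
doublet encoding one domain copy plus a bounded flank).  For a sample
sequenced at haploid depth $h$, the copy number of domain $d$ is estimated
from weighted fragment coverage:

$$\widehat{c}_d \;=\; \frac{1}{h\,L_d} \sum_{f}\, w_f \cdot
  \mathrm{overlap}(f, d),$$

where the sum runs over aligned fragments $f$, $L_d$ is the region length,
and $w_f$ is the fragment weight.  Proper read pairs are joined into one
fragment spanning both mates; discordant mates are extended 3'-ward to half
the sample mean insert size; a read reported at $k$ loci carries weight
$1/k$ (the *multiread correction*).  In simulations $h$ is the configured
haploid coverage (15x, i.e. 30x diploid); in real samples $h$ is half the
mean coverage of background regions (uniquely mappable, ultra-conserved,
CNV-free), and each region's coverage is additionally multiplied by a GC
correction factor obtained by loess regression of 1 kb-window depth on
window GC content.

Four alignment strategies are implemented and compared:

* **best** - one best placement per read, ties chosen at random.  Emulates a
  sensitive end-to-end aligner (bowtie2 `--very-sensitive -X 800`).
* **best_ties** - all tied best placements kept, weights $1/k$ (bowtie
  `--best --strata --all -v 2`): the multiread-correction strategy.
* **all_crop36** - reads cropped to 36 bp, every placement within 2
  mismatches reported (mrsFast `--crop 36 -e 2`): the classic align-all
  protocol for duplicated sequence.
* **all** - every full-length placement within 2 mismatches (bowtie
  `--all -v 2 -X 800`).

Under the align-all strategies each landing counts fully and clade totals
are divided by the clade's reference domain count; this is the published
arithmetic for those protocols and is applied uniformly across levels so
that aggregation totals still add up.  (The package default elsewhere is
the $1/k$ weighting, which conserves one read-unit per read regardless of
strategy.)

## Four levels of measurement

Read ambiguity is summarised in a *source x target* matrix: simulate
truth-tagged reads from every domain, align, and record the percentage of
each source's aligned reads landing in each target unit.  The same matrix
is computed at four resolutions - domain, gene-clade (all copies of a clade
within one gene), group-clade, and clade - and the off-target rate can only
fall as units coarsen.  *Groups* are derived from the gene-clade matrix:
genes sharing at least a threshold percentage of reads (5% by default, in
either direction) are connected, and groups are the connected components,
computed per clade.  Copy numbers at every level are sums of domain-level
copies, so totals are conserved exactly across levels.

Gene copy number (as opposed to intragenic domain gains/losses) is measured
separately, from regions around each gene to which reads map back uniquely
within one mismatch, excluding the domain-coding intervals; the estimate is
twice the length-weighted mean normalized depth of those regions.  Comparing
gene-level and clade-level estimates distinguishes whole-gene dosage events
from intragenic expansions.

## The read simulator

Reads are sampled so that the *fragment* depth over a region is
$\text{copies} \times h$ in expectation: fragment start positions are
uniform over the region extended by one buffer length upstream, fragments
not overlapping the region are discarded, and the draw count is
$D\,W/\bar f$ for window size $W$ and mean fragment length $\bar f$.
Paired-end fragment lengths are Normal(350 bp, 50 bp), matching short-insert
WGS libraries; single-end fragments equal the read length.  Sampling at
fragment depth (rather than read-base depth) is what makes
$\widehat c = \text{coverage}/h$ come out unbiased under the fragment-based
coverage accounting above; the two conventions differ by the ratio of insert
to read length.

Substitution errors follow a mate-specific mean rate (0.0026 for mate 1,
0.004 for mate 2) with a linear positional ramp from $0.5\times$ the mean
rate at the first base to $1.5\times$ at the last (so the end/start ratio is
exactly 3 and the mean is exact by construction).  Quality strings come from
a per-position profile: either fitted to observed per-position mean
qualities by loess and extended along the fitted tail trend (clamped to
Phred 2-41), or the documented default - a mild linear decline, Phred 38 to
32 over 100 bp for mate 1, two points lower for mate 2, since second reads
run lower in practice.  Empirical quality data are a pluggable input, not a
built-in; the profile affects quality-based filtering, not the error
process, which is parameterised separately.  Indels, PCR duplicates and
chastity filtering are out of scope.  Every read name encodes its origin
(`origin|domain|chrom:start-end|copy|serial`), which is what later makes
off-target alignment measurable.

## The oracle mapper

External aligners are driven through their published command lines, but the
package also carries its own exhaustive mapper for small references (up to
a few Mbp): every substitution-only placement of a read on either strand
with at most $m$ mismatches is enumerated by pigeonhole seeding - a
placement with $\le m$ mismatches must contain an exact match of one of
$m+1$ disjoint read segments; segment hits (via `matchPDict`) propose
candidate placements, which are verified by vectorised mismatch counting.
`N` counts as a mismatch on either side.  Tie-breaking for the best
strategy hashes the read id together with the run seed (with avalanche
mixing), so results are reproducible and independent of read order.

The mismatch cap follows the published protocols: 2 for the align-all and
best-ties strategies (`-v 2`).  For the best strategy the emulated aligner
has no hard cap, so the oracle scales the cap with read length
($2 + \lceil L/75\rceil$); a fixed cap of 2 would discard about 15% of
300 bp pairs through accumulated sequencing errors and reverse the
read-length accuracy trend that motivates long reads.

## Evaluation: spike-ins, RMSE, off-target

The spike-in driver simulates every domain at 1-10 copies across read
lengths (36/100/150/300 bp, single- and paired-end) and strategies, and
reports RMSE per level and clade.  The error for a source unit is
*measured minus expected*, where the expected value is the copy number the
same reads yield under perfect truth-tag placement.  This "relative ratio"
convention cancels Monte-Carlo sampling noise (which at fixed depth grows
with read length as reads get fewer) so the RMSE isolates misalignment
error.  RMSE is reported in both the summed convention
($\sqrt{\sum e_i^2}$, as printed in the original protocol) and the mean
convention ($\sqrt{\overline{e_i^2}}$), since accumulation across
replicates is a convention choice.

The worked example makes the arithmetic concrete: a single 30 kb focal
domain has a central segment duplicated once elsewhere, sized so that with
the Normal(350, 50) insert model the expected coverage lost to off-target
ties is exactly 10% ($E[f\,(s+1-f)] = 0.2\,M\,\mu$ determines the shared
length $s$; pairs falling wholly inside the shared segment tie and land
off-target half the time, i.e. 20% of pairs tie).  Measured copies are then
$0.9\times$ the simulated copies in expectation: 0.9 for one copy, 4.5 for
five.  The 30 kb region size is chosen so that depth noise (relative SD
$\approx\sqrt{\mu/(M\,D)}$) is small against the 10% effect at both 1 and 5
copies; the scenario is an idealisation of the ambiguity structure, not a
realistically sized domain.

## The synthetic genome generator

`family_spec()`/`make_toy_genome()` build references with a controlled
version of the family's similarity structure: per-clade ancestral domains
(short exon + intron + long exon, with clade-specific amino-acid motifs
embedded codon-aligned and held immutable), gene clusters whose members
diverge by a target within-cluster rate (default 1%), clusters separated by
a larger rate (default 10%), and unique random intergenic sequence
providing per-gene flanks for gene-level copy number.  Per-branch
substitution rates are solved numerically from the pairwise-divergence
target ($d = 2r(1-r) + \tfrac23 r^2$ over the mutable fraction), and each
branch applies an *exact* substitution count (rate x mutable length, with
unbiased rounding) at uniformly sampled positions: realised identities then
land within half a percent of the request for every pair, where a binomial
per-site draw would occasionally produce near-identical pairs whose
read-sharing does not decay with read length.  Defaults -
2 Mb, 6 genes x 6 domains (one per clade in the canonical CON1, CON2,
HLS1, HLS2, HLS3, CON3 order), 600 bp domains - run the full pipeline in
minutes on one CPU.

What the generator does *not* emulate: indel divergence, the real 1q21
haplotype structure, interspersed repeats, GC heterogeneity at biological
scale, and reference errors.  Passing tests on these fixtures demonstrate
the correctness of the measurement machinery under the stated similarity
structure, not performance on real human data.

## Numerical and design choices

* **Coordinates.**  All in-memory intervals are `GRanges` (1-based closed),
  the standard container of the R genomics stack; BED's 0-based half-open
  and HMMER's 1-based inclusive conventions are converted exactly once, at
  the I/O boundary.
* **Quantification regions.**  A domain's region spans its exon doublet;
  where the gap to the nearest neighbour exceeds 1 kb, the facing boundary
  is extended by up to 250 bp, capped at half the gap excess so extended
  regions always remain at least the gap threshold apart (hence disjoint,
  which the coverage accounting assumes).
* **Discordant extension.**  Exactly half the mean insert, 3'-ward,
  deterministic.  A stochastic extension would break run-to-run
  reproducibility for no accuracy gain.  Genuinely single-end reads are not
  extended - no insert exists for them, and extending them would inflate
  single-end coverage by the insert/read-length ratio.
* **Short-exon pairing.**  The nearest upstream exon (transcription order)
  with length in 50-111 bp; absence is flagged rather than fatal.  When two
  exon models disagree, the one with more intact doublets wins, then the
  one with more annotated UTR exons.
* **Clade assignment.**  Exact amino-acid motif substrings (configurable
  mismatch allowance, default 0).  A short-exon motif of one clade with a
  long-exon motif of another yields `HYBRID`; no match yields `UNASSIGNED`;
  both are annotated but excluded from quantification by default, as are
  the non-canonical CON4-CON8 clades.
* **Degenerate inputs.**  A GC model over fewer than three distinct GC
  values returns an identity correction with a warning; zero background
  coverage is an error; a gene without unique regions is reported
  unmeasurable rather than imputed.
* **Determinism.**  Every stochastic step takes a seed; library code
  restores the caller's RNG state.  Per-domain and per-read seeds are
  derived by hashing names, so results do not depend on iteration order.

## Problem sizes used by the test suite

The shipped tests run the complete pipeline on 600 kb (six genes) and 2 Mb
(parameter recovery) synthetic genomes, with 20-replicate averages where a
mean over seeds is asserted, and the read-length/pairing trend on a
600 kb genome at 36/100/150/300 bp in both single- and paired-end mode.
These sizes keep a full run in the minutes range on one CPU while leaving
the Monte-Carlo error well below the asserted tolerances.

## Known limitations

* The oracle mapper is exhaustive and substitution-only; it is the
  reference implementation for small genomes and the cross-check for
  external aligners, not a production aligner for hg38.
* Align-all absolute copy numbers depend on a normalization convention
  (clade domain counts) that only summarises well for clades whose members
  are nearly interchangeable; the package reports them for comparison, as
  in the original protocol, while the best strategy carries the headline
  estimates.
* Unique-region discovery probes single-end reads at a fixed stride;
  paired-end uniqueness is slightly more permissive, so the discovered
  regions are conservative.
* Sequencing-centre batch effects and population structure in real cohort
  data are out of scope; the package emits per-sample tables on which such
  analyses can be built.
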