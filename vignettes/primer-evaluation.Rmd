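---
title: "Evaluating degenerate SSU rRNA primers against metagenomic reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating degenerate SSU rRNA primers against metagenomic reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primerscope)
```

## The problem

Amplicon surveys of small-subunit (SSU) rRNA genes are only quantitative if
the PCR primers perfectly match the rRNA of the organisms present: even a
single primer-template mismatch can severely depress amplification of the
affected taxon and distort its apparent relative abundance. Shotgun
metagenomes, which carry rRNA fragments untouched by any primer, offer an
independent way to measure how often each primer actually matches naturally
occurring sequences. `primerscope` implements that evaluation as a reusable
library with a thin command-line front end: it extracts primer-binding-region
fragments from reads aligned to group-specific SSU rRNA references, scores
them against degenerate primers with full IUPAC arithmetic, summarises
perfect- and near-match coverage per sample, organismal category and primer
pair, enumerates the naturally occurring primer-site variants, designs
minimal explicit oligonucleotide mixtures, and quantifies the concordance of
amplicon- and metagenome-derived community composition.

## Degenerate-primer arithmetic

A degenerate primer is shorthand for a mixture of concrete oligonucleotides:
each IUPAC code denotes a set of bases (Y = {C,T}, H = {A,C,T}, N =
{A,C,G,T}, ...), and the number of distinct oligos synthesised is the product
of the per-position set sizes (`degeneracy_count()`). Internally every code
is a 4-bit mask, so set membership is a bitwise AND and mismatch counting
vectorises over whole fragment collections.

A fragment *matches* a primer at position *i* when its (concrete) base is a
member of the primer's IUPAC set at *i*; `count_mismatches()` counts the
positions where it is not. For nondegenerate fragments this per-position
membership rule is provably equal to the minimum Hamming distance between
the fragment and any oligo in the primer's expansion, and the test suite
asserts that equivalence against a brute-force oracle on thousands of random
primer/fragment pairs. We chose membership rather than set intersection
between two degenerate strings because fragments here are concrete sequencer
reads; reads containing any ambiguity code (including N) are excluded before
matching rather than counted either way, since an uninformative base should
inflate neither the matched nor the mismatched tally.

```{r}
degeneracy_count("GTGYCAGCMGCCGCGGTAA")   # 515Y: 4 oligos
degeneracy_count("CCGYCAATTYMTTTRAGTTT")  # 926R: 16 oligos
count_mismatches("GTGYCAGCMGCCGCGGTAA", "GTGCCAGCAGCCGCGGTAA")
```

## Fragment extraction

`extract_fragments()` takes reads aligned to a single SSU rRNA reference
(SAM/BAM, read through Rsamtools/GenomicAlignments) and a primer whose
binding site is given as 1-based inclusive coordinates on that reference.
A read qualifies when its alignment covers the full primer window and at
least 5 reference bases of flank on at least one side. The flank language
admits two readings (flank on one side versus both); we default to the
one-sided rule, which retains reads anchored well on either flank while
still guaranteeing a complete, length-matched fragment, and expose
`both_sides = TRUE` for the stricter reading. Reads with an insertion or
deletion *inside* the window are skipped rather than gap-resolved:
length-changing variants cannot be scored by positional mismatch counting.
Indels outside the window are fine; the read is projected into reference
space before the window is sliced.

Fragments are kept in reference orientation and reverse primers are
compared via their reverse complement (`binding_site_sequence()`), so one
extraction pass serves both primers of a pair.

The filter chain is fixed and tallied: extract, then mean-quality filter
(default Phred 30 over the window -- a conventional threshold, configurable,
since no specific value is canonical), then removal of non-ACGT fragments,
then an exclusion filter that discards fragments with more than 6 mismatches
as likely misalignments or distantly related sequences (boundary inclusive).
`evaluate_primer()` asserts read conservation: extracted = emitted + removed
at each stage.

## Coverage statistics

Coverage at *k* mismatches is the fraction of scored fragments within *k*
mismatches of the primer; the 0-mismatch ("perfect match") fraction is the
headline statistic, tabulated per sample and per organismal category
(Archaea; Bacteria; Cyanobacteria plus plastidal 16S rRNA, which proxies
eukaryotic phytoplankton; Eukarya). Coverage over zero fragments is `NA`,
never 0/0 -- absence of evidence is not zero coverage.

For a primer pair, statistics are restricted to the categories targeted by
*both* primers (declared per primer in the config). This taxonomic-overlap
correction matters: a reverse primer with no 18S rRNA binding site cannot
amplify Eukarya regardless of the forward primer's match, so the pair
reports no Eukarya coverage at all. Within shared categories three
combination rules are computed:

* `worst_case` = max(0, 1 − (missed_fwd + missed_rev)) — the lower bound
  attained when the organisms missed by the two primers are disjoint sets;
* `min` — the bound attained when one missed set contains the other;
* `product` — independence of the two missed sets.

Because forward and reverse windows are observed on different short reads
and cannot be linked per template molecule, no per-molecule pair statistic
is observable; we default to the product rule (and always emit all three,
with the rule recorded in the output) rather than presenting any one as
the true pair coverage.

## Variant tables and minimal mixtures

`tabulate_variants()` counts the distinct window sequences per dataset, in
the primer's own 5'→3' orientation so each row is directly a synthesis
candidate. The "overall" abundance across datasets is the unweighted mean of
per-dataset relative abundances — each environment counts equally regardless
of sequencing depth — with pooled-read weighting available behind a flag.
Variants seen fewer than `min_count` (default 2) times in every dataset are
flagged as possible sequencing errors: they remain in the table but are
excluded from design, reflecting the long tail of rare variants in real
data.

`design_mixture()` builds an explicit oligo mixture: a nondegenerate seed
(defaulting to the most abundant perfectly matched variant) plus every
variant above an overall-abundance threshold (default >2%) plus curated
additions supplied as sequences or FASTA — curation is an input, never a
database lookup inside the tool. The achieved coverage is recomputed from
the variant table (summed abundance of variants exactly present in the
mixture), never cached. `compare_mixture_vs_degenerate()` then contrasts the
mixture with the minimal single degenerate sequence covering it
(`degenerate_union()`): the union's expansion is typically several-fold
larger, and the expansions never observed in the data are the redundant
oligos a fully degenerate redesign would synthesise while diluting its
perfect matches.

`suggest_degeneracies()` addresses the converse question — how far a single
added degeneracy can take an existing primer — by ranking, per position, the
minimal IUPAC widening that rescues the variants whose only mismatch lies
there. Applying the top edit increases matched abundance by exactly the
reported gain (an invariant the tests recompute).

## Amplicon–metagenome concordance

`concordance()` compares a taxon-by-sample table derived from amplicon ASVs
with one derived from metagenomic rRNA fragments. Because a 150-base
metagenomic read can often be attributed only to a broader clade, both
tables are first aggregated through a user-supplied taxon→group mapping;
groups observed by only one method get explicit zeros (a taxon one method
misses should count against concordance, not vanish). After renormalisation,
amplicon relative abundance is regressed on metagenome relative abundance by
ordinary least squares per sample, and R² is reported along with slope and
intercept so either convention (through-origin or not, which the literature
leaves open) can be audited. We regress untransformed relative abundances by
default — "linear least squares" at face value — with a log10 option off by
default. A fit needs at least 3 groups and non-degenerate variance;
otherwise the sample reports `NA` with a reason. `depth_summary()`
stratifies the per-sample R² about a depth boundary (default 150 m,
threshold 0.95), the comparison of interest across the
surface–mesopelagic transition.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions under which the package validates itself: 150-base reads
(the short-read regime in which the two primer windows are unlinked),
2000 reads per sample and group, a 1600-base reference (the scale of an SSU
rRNA gene), uniform read starts, and a two-level quality model — passing
reads at Q40, a planted 10% of reads at Q2 — that makes quality-filter
outcomes exactly predictable. Reads spanning a primer window draw their
window sequence from a planted variant pool; `variant_pool()` builds pools
whose i-th mismatched variant carries exactly i mismatches at positions
outside the primer's IUPAC sets. Everything is deterministic given the seed
(byte-identical FASTQ/SAM across runs), the truth table records every read's
variant and qualification status, and the caller's RNG state is restored.

What the generator does *not* emulate — realistic taxonomic abundance
curves, GC or coverage bias, chimeras, PCR bias, correlated sequencing
errors — bounds what passing tests show: they demonstrate that the
machinery recovers planted parameters exactly or within binomial error,
not that any particular field primer achieves any particular coverage in
nature. Real-survey medians require the real metagenome corpus.

Problem sizes used in the tests were chosen to make binomial tolerances
meaningful at desk scale: parameter recovery uses 10 samples x 2000 reads
with a planted perfect-match frequency of 0.75 and a 3-standard-error
band; the demo pipeline runs 3 samples x 4 groups x 2000 reads.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere (config, reports), the
  convention of the E. coli 16S reference positions primer names derive
  from; conversions are internal.
* Variant-table ties at equal abundance break lexicographically, making
  every report deterministic.
* The expansion cap (4096 by default) guards against enumerating
  near-random degenerate strings; the most degenerate mixture union
  discussed in practice expands to 144, far below it.
* U is normalised to T and lowercase to uppercase on input; any other
  non-IUPAC character is rejected with its position.
* The mean-quality threshold (Phred 30) and the exclusion threshold
  (6 mismatches) are configurable; the exclusion boundary is inclusive.
* `NA` coverage (no fragments) propagates through summaries rather than
  being coerced to zero.

## Known limitations

* Melting temperature, self-dimerisation and hairpin screening of designed
  oligos are out of scope; a designed mixture is a coverage object, not a
  validated PCR protocol.
* Taxonomic classification of fragments is an input (sidecar labels or
  per-group files), not something the package performs.
* The exclusion filter cannot distinguish a genuinely divergent rRNA from
  a misalignment; at the default threshold both are removed.
* Indel variants of a primer site are invisible to positional mismatch
  counting and are excluded at extraction.
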