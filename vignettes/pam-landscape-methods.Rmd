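---
title: "Methods: PAM landscapes, depletion statistics, and base-editing scope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PAM landscapes, depletion statistics, and base-editing scope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamscape)
```

`pamscape` implements the computational machinery used to characterise a
CRISPR-Cas9 nuclease with a degenerate, internally palindromic PAM — the
motivating system is FrCas9 with its 5'-NNTA-3' PAM and 22-nt spacer — and
to quantify what such a PAM buys in practice: target density, back-to-back
guide pairs, TATA-box access, base-editing scope, and cleavage read-outs
from depletion assays and amplicon sequencing. This vignette records the
models, conventions and design choices behind each module.

## Coordinates and the site model

All genomic coordinates are 0-based, half-open, reported on the plus strand
(BED convention). A target site consists of a protospacer of `spacer_len`
nt with the PAM immediately 3' of it *on the site strand*; minus-strand
sites therefore carry their PAM to the left of the protospacer in
plus-strand coordinates. On circular records (plasmids, viral episomes)
features may wrap the origin: interval starts are reduced modulo the record
length and the end may exceed it. Scanning a circular record doubles the
sequence and keeps one canonical representative per locus; a site whose
protospacer plus PAM would exceed the record length cannot be placed and
yields an empty result.

The inferred blunt cut is placed `cut_offset = 3` nt 5' of the PAM on the
site strand. Double-strand-break mapping for this nuclease family (dsODN
incorporation) localises cuts to the 3rd *or* 4th base upstream of the PAM;
we fix 3, the convention shared with SpCas9, and expose the offset as a
parameter because the ambiguity is real.

Sites whose protospacer or PAM overlaps an assembly `N` are dropped by
default (`drop_n = TRUE`). This matters for statistics on real assemblies
with N-gaps; the flag retains protospacer-N sites when a permissive count
is wanted, but an `N` inside the PAM never matches a concrete motif
position.

## Palindromic cores and back-to-back pairs

The full NNTA motif is *not* closed under reverse complement (the reverse
complement of `xxTA` is `TAyy`); the palindrome is the `TA` core.
`pam_is_palindromic()` tests the strict full-motif closure; back-to-back
pairing instead requires a motif of the shape `N^j TA N^k`, for which every
plus-strand TA dinucleotide with full flanks anchors exactly one site per
strand. The two protospacers are divergent and separated by `2j + 2` bp —
6 bp for NNTA, the `NNTANN` box between the two PAM-proximal ends. Pair
enumeration joins plus and minus sites on the plus-strand coordinate of the
shared TA, so truncated loci (flank missing on one side) drop out
naturally.

This geometry is what gives a TA-core PAM its double editing windows: each
site of a pair carries its own base-editing window on opposite sides of the
shared TA (`double_window()`), and what makes TATA boxes (core
`TATAAATAAT`, holding TA dinucleotides at offsets 0, 2 and 6) dense
targets (`tata_box_targets()`).

## Landscape statistics

**Coverage** is the fraction of genome positions overlapped by at least one
protospacer (union over strands). PAM bases are excluded by default because
"target coverage" is read as *editable* sequence; `include_pam = TRUE` is
provided since the alternative definition is equally defensible.

**Spacing** summarises gaps between consecutive anchors — cut positions for
site sets, word start positions for dinucleotide scans. On circular records
the wrap-around gap is included, so gaps sum exactly to the record length
and the mean is exactly `L / n_anchors`. For dinucleotide scans with
`count_both_strands = TRUE`, a non-palindromic word pools the occurrences
of its reverse complement (GG also counts CC), while a palindromic word
(TA) contributes two anchors per locus — one per orientation — which makes
duplicated loci explicit as zero-length gaps and yields a circular mean of
`L / (2 #TA)`. Whether published genome-wide distributions were computed on
one strand or two is rarely stated, so the orientation policy is explicit
and switchable; means are the statistic we calibrate against (on i.i.d.
uniform sequence the single-orientation TA mean is the renewal expectation
`1/p = 16` bp, which the tests verify at 1 Mb), medians are reported but
convention-sensitive. Spacing never crosses record boundaries; per-record
summaries can be combined with `pool_spacing()`.

Fewer than two anchors on a linear record gives an empty gap set with the
mean flagged undefined rather than an error, so record-wise pipelines do
not fall over on sparse contigs.

## Depletion-assay statistics

A randomized-PAM depletion assay exposes a `4^k` PAM library (k = 6: 4096
members) to the nuclease; functional PAMs drop out. For each PAM the
post-selection PAM depletion value is the frequency ratio

\[ \mathrm{PPDV}(p) = \frac{(\,\mathrm{sel}_p + c\,)/\sum(\mathrm{sel}+c)}
                          {(\,\mathrm{ctl}_p + c\,)/\sum(\mathrm{ctl}+c)} \]

with pseudocount `c = 0` by default — the raw-ratio definition — so a PAM
unobserved in the control is flagged undefined rather than silently
smoothed; `c = 0.5` is suggested for noisy libraries. Depletion efficacy is
inversely related to PPDV and reported as an ascending rank. The top-decile
depleted set (size `floor(0.1 * 4096) = 409`; floor and lexicographic
tie-break are our choices, the convention being otherwise unstated) feeds
the depletion logo: a position frequency matrix and its
`log2(freq / 0.25)` enrichment against the uniform background. The PAM
wheel restricts to "positive depleted" PAMs, interpreted as PPDV < 1, and
accumulates weight `1 - PPDV` onto the 3-mer at PAM positions 2-4,
normalised to sum 1; no published formula exists for wheel weights, so this
linear-depletion weighting is declared rather than inferred. Per-position
log2 fold-changes are computed within the depleted subset; exact equality
with published panels is not claimed because their aggregation is unstated.

Pooled-screen utilities follow the standard definitions: the sgRNA evenness
index `total / (N * reads_i)` (which satisfies
`sum 1/(N * index) = 1` identically and corrects per-guide indel rates by
multiplication, capped at 1), and the GUIDE-seq on:off ratio
`on / sum(off)` with denominator 1 when no off-targets were detected, so
fully specific guides stay rankable.

## Base-editing scope

A base editor is `(from, to, window)` with window positions counted 1-based
from the PAM-distal 5' end of the protospacer — the standard convention for
"6th-10th base" style statements. Bundled models: the TA-PAM CBE
(BE4Gam-style, C→T, window 6-10) and ABE (ABE7.10-style, A→G, window 6-8)
with 22-nt spacers, and NGG comparators with the canonical literature
window 4-8 on 20-nt spacers (the comparator windows are a configurable
default, not a measured quantity).

Correctability is evaluated on the *patient* sequence — the genome carrying
the pathogenic `alt` allele — because that is the molecule the editor must
revert; this is the only chemically coherent reading. A variant is
correctable when some site places it in the window with the site-strand
base equal to the substrate (`alt = C, ref = T` on either strand for a CBE;
`alt = A, ref = G` for an ABE), and *precise* when at least one supporting
site's window contains no bystander substrate base. Both the any-site and
bystander-free tallies are emitted per variant, since published scope
counts do not always state which was used. PAM-disrupting edits and
synonymous-bystander reasoning are out of scope. Scope comparisons between
editors use `scope_difference(A, B) = |A \ B| / |A|`.

## Amplicon indel quantification

Merged reads are aligned to the amplicon reference by global affine-gap
alignment (Gotoh, implemented in C++): a gap of length `k` costs
`open + k * extend`, defaults match +2, mismatch −4, open −8, extend −1.
The heavy gap penalties relative to substitutions guarantee that sequencing
substitution errors (≤ 1%) never surface as indel operations, and
discourage spurious terminal gaps on amplicons. Traceback is deterministic:
at equal score, match/mismatch is preferred over deletion over insertion,
so tied optima (homopolymer indels) are always placed the same way. A read
is indel-positive when an insertion or deletion overlaps the ±10 bp window
around the cut; the site rate is the indel-positive fraction, and a
no-nuclease control rate is subtracted and clamped at zero to remove
PCR/sequencing background. Reads whose best alignment exceeds 40%
mismatches are discarded as unalignable and counted — a QC default we
declare rather than take from any published pipeline. Read merging is
upstream of this package.

## Synthetic data and what it does (not) show

Every generator takes an explicit seed and runs in its own RNG scope
(identical configs are byte-identical; the global RNG stream is untouched).

* `random_genome()` draws i.i.d. bases at a chosen GC content. Real genomes
  have dinucleotide structure, repeats and N-gaps that i.i.d. sequence does
  not; landscape numbers on synthetic genomes therefore demonstrate the
  *machinery*, not any particular organism's values.
* `simulate_depletion()` draws the control library from a uniform
  multinomial and the selected library with rule-matching PAMs down-weighted
  to `retention` (1 = no selection, 0 = complete depletion). It models no
  PCR bias or bottlenecking, so it shows rule *recovery*, not assay noise.
* `simulate_amplicon()` plants at most one indel per read (sizes ±1..±10,
  weight `0.6^(|s|-1)` so single-base events dominate, placed within ±3 bp
  of the cut to mimic NHEJ clustering) plus uniform substitution errors —
  no quality scores, chimeras or multi-indel reads.
* `simulate_variants()` constructs variants of known correctability class
  from enumerated sites (the healthy base is the editor's product base, the
  pathogenic allele its substrate) and certifies each planted class by
  direct evaluation on the constructed sequence, retrying placement up to a
  bound. Truth tables are first-class outputs. The *independent* check of
  the scoper is a brute-force site-by-window oracle in the test suite, not
  the generator.

## Numerical and testing choices

Problem sizes used by the test suite and acceptance script are chosen to
make the statistics sharp at interactive scale: 1000 random genomes of
50-2000 bp for scanner/oracle equivalence, depletion libraries at depth
10^6 over 4096 PAMs, 200 genomes for scoping/oracle equivalence, 1000
reads for indel-rate recovery (checked against exact binomial 99% bounds),
and 1 Mb for the TA renewal-spacing check. Logos computed from a depleted
set report `-Inf` log2 enrichment for absent bases (a true zero frequency),
and PFM rows sum to 1 within 1e-12. Alignment scores are exact doubles; the
aligner is checked against an independent R Gotoh implementation, an
exhaustive alignment enumeration on tiny strings, and a third-party
affine-gap implementation.

## Known limitations

No sgRNA efficacy scoring, off-target search, thermodynamics, promoter
discovery, per-base conversion tallies for base-editing outcomes, or
per-PAM kinetic rate fitting. Anti-repeat search (`find_antirepeats()`) is
ungapped with fixed defaults (identity ≥ 0.8 over the full repeat length,
minimum repeat 15 nt) — a screening aid, not an aligner. ClinVar-scale
scope *counts* are database-version-dependent and deliberately not
reproduced; the package reproduces the statistics, not the snapshot.
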