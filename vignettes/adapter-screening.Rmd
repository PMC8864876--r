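---
title: "Screening HiFi reads for residual PacBio adapter sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening HiFi reads for residual PacBio adapter sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hifiscrub)
```

## Why screen HiFi reads at all

PacBio circular consensus (HiFi) reads are widely treated as
assembly-ready, but a small fraction of reads in public datasets carry
residual library artifacts: the 45 bp SMRTbell blunt adapter
(`r builtin_adapters()$sequence[1]`) and the 35 bp C2 sequencing primer.
These artifacts occur at rates on the order of a tenth of a percent of
reads, most often as the reverse complement of the adapter, and most often
near the 5′ end of the read. Left in the pool they can be incorporated into
contigs by any of the common HiFi assemblers, producing mis-joins and
vector-screen failures at submission time.

Because contaminated reads are so rare, `hifiscrub` removes each one whole
instead of trimming it. A read containing adapter sequence is plausibly a
chimeric molecule; trimming would retain its flanks, and the cost of
discarding the entire read is negligible at these rates. Survivors are
copied through byte-identically — filtering is record selection on the
original file, never re-serialization.

## The detector

Each adapter, in both orientations, is aligned against each read with
Smith–Waterman local alignment under affine gap costs (the Gotoh
recurrences, implemented in C++). The scoring scheme is the strict one used
for vector screening:

* match reward **+1**
* mismatch penalty **−5**
* a gap of length $k$ costs **3 + 3k** (so a single-base gap costs 6)

`N` — and any other non-ACGT letter — scores as a mismatch against
everything, including itself; no low-complexity masking of any kind is
performed. Under this scheme a local alignment only scores highly when it is
nearly exact, which is what makes a 45-mer findable inside a 20 kb read
without any significance statistics: the length-and-identity acceptance
thresholds below strictly dominate any practical E-value cut at these
settings, so no E-value machinery is implemented.

The best hit's read interval is masked and the search repeated until the
best remaining score falls below a reporting floor (default 20). This
iterate-and-mask loop recovers multiple adapter copies per read (tandem
copies included) with non-overlapping intervals per adapter and orientation.
Because a masked column costs −5, an optimal local alignment can never begin
or end inside a masked interval, and bridging across one would cost far more
than any adapter match can earn, so masking cannot create artifact hits.
When the stringency knobs are relaxed far enough that a passing hit could
score below 20, the floor is lowered automatically to the worst score a
passing hit can have (`7·⌈L·M/100⌉ − 6·L`), which keeps the blocklist
monotone in both knobs.

### Determinism and tie-breaking

All outputs are deterministic. Among equal-scoring alignments the one
ending leftmost on the read (then leftmost on the adapter) is reported, and
traceback prefers substitution columns over gaps, then gap extension over
opening a new gap. The implementation runs a score-only sweep over the whole
read (O(adapter) memory) and then a full traceback on a short window ending
at the best cell; a window of three adapter lengths is provably sufficient
because, with a mismatch costing five matches and each gapped base at least
three, no positive-scoring alignment can span more than about 1.6 adapter
lengths of the read.

## Acceptance thresholds

A hit counts as contamination when it spans at least `L` alignment columns
at percent identity at least `M`:

| adapter | length | default L | default M |
|---|---|---|---|
| SMRTbell blunt adapter | 45 bp | 44 | 97 % |
| C2 sequencing primer | 35 bp | 34 | 97 % |

Both defaults allow exactly one missing or mismatched base. The boundary
behavior is sharp: a full-length blunt-adapter alignment with one
substitution has identity $44/45 = 97.8\,\%$ and passes; with two
substitutions, $43/45 = 95.6\,\%$, it fails; a perfect 43-column fragment
fails on length. The `min_match_length` / `min_identity` overrides (the
`-l` / `-m` command-line options) replace the per-adapter defaults
*uniformly* for every adapter, including user-supplied ones; when unset,
each adapter keeps its own defaults. User adapters loaded from FASTA get the
same one-missing-base convention: `L = length − 1`, `M = 97`.

## Positional classification

Contaminated reads are categorized by where their passing hits fall. A hit
starting in the first 10 % of the read is `five_prime`; ending in the last
10 %, `three_prime`; otherwise `internal` (a hit qualifying for both ends,
possible only on very short reads, counts as `five_prime`). Reads whose hits
all share one zone take that category; otherwise `distributed`. Reads whose
passing hits cover more than 80 % of their length are set aside as `other` —
adapter-dimer-like artifacts that fit none of the four positional patterns.
The 10 % end-zone fraction is a tunable (`end_zone_fraction` in
`filter_config()`): no published quantitative boundary exists for "at the
5′ end", and 10 % of a typical 10–15 kb read leaves a 45 bp hit at the read
tip unambiguous. Classification is reported only; filtering depends solely
on the thresholds above.

## The simulator

`generate_dataset()` produces a HiFi-like FASTQ plus a truth table with one
row per spiked adapter copy. Its defaults are the study conditions the
package is evaluated under:

* `n_reads = 1000`, lengths Gaussian (mean 10 kb, sd 2.5 kb, truncated at
  500 bp) — typical HiFi length scale;
* `contamination_rate = 0.0025` — the highest per-dataset proportion
  observed in surveyed public data;
* `reverse_orientation_fraction = 0.896` — the observed orientation bias;
* `category_weights = (0.45, 0.25, 0.20, 0.10)` for 5′ / 3′ / internal /
  distributed — the observed abundance *ordering*; the exact weights are a
  design choice since only the ordering is published;
* `adapter_error_rate = 0`, background GC 40 %, constant quality `U` (Q52).

Spiked copies **replace** read bases rather than inserting, so the length
distribution is independent of contamination and length-profile summaries
are easy to reason about. Orientation is assigned by stratification —
exactly `round(total_copies × fraction)` copies are reverse, their positions
randomized — so the realized share is deterministic at the configured value;
categories and offsets remain random draws. The RNG is consumed in a fixed,
documented order (read lengths, read bases, then spike decisions), the
caller's RNG state is saved and restored, and identical configurations give
byte-identical outputs.

What the simulator does **not** emulate: real CCS error profiles (indels,
pass-number-dependent quality), repeat structure in the background (i.i.d.
bases only), and the empirical enrichment of contamination in ~10 kb and
very short reads. Passing recall/specificity tests on simulated pools
therefore demonstrates the detector's behavior on near-exact adapter copies
in neutral sequence — which is the regime the thresholds target — not its
behavior in low-complexity or repetitive genomic context.

## Contig screening

`screen_contigs()` applies the identical detector and thresholds to each
contig of an assembly, scanning long contigs in 1 Mb windows with 100 bp
overlap (at least twice the longest adapter, so a boundary-straddling hit is
always contained whole in the next window); coordinates are mapped back and
duplicates from the overlap removed. The contract is exact consistency with
the read path: an assembly is reported clean if and only if no contig yields
a passing hit under the same configuration. Findings are reported as advice;
no automatic excision or masking is performed, since no post-assembly fix is
clearly optimal — the right remedy is filtering the reads and reassembling.

## Numerical and interface conventions

* Coordinates are 0-based half-open in R objects, 1-based inclusive in the
  TSV outputs (BLAST-tabular convention).
* Medians use the lower-median convention for even counts.
* GC content excludes `N` from numerator and denominator.
* The contamination proportion is printed with six decimals so rates of
  10⁻³ remain visible.
* Duplicate read ids are a fatal error: blocklist removal matches ids
  exactly and completely, never as prefixes, and duplicate ids would make
  whole-read removal ambiguous.
* BAM input uses primary, non-supplementary records only (HiFi BAMs are
  unaligned; secondary records should not occur, and are skipped if they
  do). Reads shorter than an adapter are scanned like any other and
  trivially pass through.
* The `threads` option is accepted for interface compatibility and recorded
  in the run manifest, but processing is sequential; outputs are identical
  for any value.
* Lowercase bases are preserved in all pass-through output and uppercased
  only for alignment.

## Problem sizes in the test suite

The shipped tests exercise the aligner against an exhaustive
enumeration oracle on 2,000 random string pairs (lengths ≤ 8, including
`N`), verify perfect recall and zero false positives on five seeded
1,000-read pools spiked at 20 %, check threshold monotonicity on a
60-read degraded-spike fixture over a 3 × 4 stringency grid, and recover
the 89.6 % orientation share from a 500-spike pool. These sizes were chosen
to make every property measurable with comfortable statistical margins
while keeping the default suite fast on a laptop.

## Known limitations

* Only substitutions are simulated in spiked copies; real residual adapters
  may carry indels. The aligner handles indels (affine gaps), but simulated
  recall does not measure that regime.
* The detector is exhaustive dynamic programming per (read × adapter ×
  orientation); it is fast because adapters are short, but it is not a
  seeded heuristic and will not scale to screening against large vector
  databases.
* Adapters with IUPAC ambiguity codes are not supported; `N` in reads is
  treated conservatively as a universal mismatch.
* The positional categories depend on the 10 % end-zone convention; other
  defensible boundaries would shift counts between `five_prime`/`internal`
  without affecting which reads are removed.
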