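---
title: "spacertrace: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spacertrace: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacertrace)
```

## What the package models

`spacertrace` analyses naive CRISPR–Cas adaptation read out through a
reading-frame reporter. The biological object is a type I-E CRISPR array
whose leader–repeat junction runs into a frame-shifted *lacZ*; insertion
of one repeat–spacer unit (61 bp = 29 bp repeat + 32 bp spacer by
default) restores the frame. PCR amplicons spanning that junction are
sequenced on a long-read instrument, and the package answers four
questions per amplicon pool:

1. which new spacers were acquired (extraction),
2. where each came from — chromosome or plasmid, strand, locus, PAM
   (mapping),
3. whether source sampling is biased once DNA abundance is accounted for
   (bias/hotspots),
4. whether highly duplicated spacers are enriched for in-frame start
   codons, as expected when the assay selects for functional LacZ
   fusions (frame statistics).

Coordinates throughout are 0-based, half-open, forward-strand, with an
explicit strand field; both replicons are treated as circular by default
(coordinate wrap is implemented by appending a short prefix copy before
scanning). `N` is allowed in reads but never in references; `N` matches
nothing, and counts as a mismatch in approximate comparisons.

## Extraction model

A read is first oriented by the best approximate occurrence of the
leader anchor in the read versus its reverse complement (ties go to
forward; neither orientation within `ceiling(0.2 × anchor length)` edits
flags the read unparseable). All approximate repeat occurrences within
`ceiling(max_edit_fraction × repeat length)` edits are then located by a
semi-global edit-distance scan and selected greedily — best edit
distance first, leftmost on ties, non-overlapping. Each inter-repeat
segment whose length falls in `spacer_length_window` (expected length
± 3 bp by default) is a spacer, reported leader-proximal first. Reads
with two or more expansions yield multiple spacers.

`max_edit_fraction = 0.2` is our own default: the source protocols for
this kind of data do not publish matching thresholds, so the threshold is
explicit configuration, logged with every run. At 20% of a 29-mer the
chance of a spurious repeat hit in random sequence is negligible while
realistic per-read error (a few percent) is tolerated.

Spacers are *not* error-corrected or consensus-polished. Exact-duplicate
collapse therefore slightly undercounts duplications at non-zero error
rate; this mirrors the exact-duplicate rule of the original analysis and
keeps the duplication count interpretable as "reads carrying this exact
sequence".

## Mapping model

Each unique spacer is scanned against both replicons on both strands.
An exact substring pass runs first (if any 0-edit hit exists, the global
best is 0 and nothing else can tie it); otherwise a Myers bit-parallel
scan finds the best edit distance up to `max_edits = 2`. Decision rule
for equal-best hits: one replicon → that source, lowest (start, strand)
wins and the multiplicity is recorded; both replicons → `ambiguous`;
nothing within `max_edits` → `unmapped`. Ambiguous and unmapped spacers
are excluded from the plasmid fraction (numerator and denominator) and
reported separately — how the original analysis treated multi-mappers is
unstated, so we chose the conservative exclusion and made it visible.

The PAM is read 5'→3' on the protospacer strand at offsets −2..0
relative to the protospacer start: two genomic upstream bases plus the
first protospacer base, which yields the canonical three-letter AAG.
A "−2 to +1" logo window can also be read as four bases; both are
supported (`pam_offset`, `pam_width`), three is the default because it
reproduces the canonical AAG reading.

Spacers matching the reporter cassette itself map as chromosomal, since
the cassette is chromosomally integrated in the simulated references.

## Two deduplication rules, deliberately

Source *ratios* use **all** spacers (duplicates included); hotspot maps
and PAM matrices use **unique** spacers. Both rules come from the
original analysis protocol and are enforced by separate code paths
(`classify_sources(hits, weights = duplication_count)` versus unique-hit
binning), with a regression test that distinguishes them.

## Bias normalisation

For genome length $g$, plasmid length $p$ and copy number $c$ (default
40), chromosomal DNA is in molar excess $g/(cp)$ and the neutral plasmid
share under proportional sampling is $s = cp/(cp+g)$. The bias index is
the odds ratio $[f/(1-f)]/[s/(1-s)]$ for the observed all-spacer plasmid
fraction $f$; 1 means source sampling proportional to DNA content. At
*E. coli* scale ($g = 4{,}641{,}652$, $p = 5{,}300$, $c = 40$) the
excess is ≈ 21.9-fold and $s ≈ 0.044$, so a ~9% plasmid share is
near-neutral. The true reporter-plasmid length is fixed only in
unpublished supplementary material; 5,300 bp is our stated working value
for a pBAD-family vector carrying *cas1–cas2*, and every function takes
the length explicitly.

PAM-site saturation counts perfect motif occurrences with a pinned
convention: both strands of the circular sequence, overlapping
occurrences and origin-spanning occurrences included
(`count_pam_sites()`). The convention is validated against a brute-force
enumeration oracle and exercised on a synthetic stand-in plasmid built to
carry a known motif count; the real reporter plasmid sequence is not
distributed with the package, so its printed motif count cannot be
checked directly here.

## Frame statistics

Only the first `atg_window = 30` bp of a spacer can contribute an
in-frame ATG before translation runs into the downstream repeat, i.e.
$k = 10$ codons; `frame_offset` (default 0) sets the codon grid. Under a
uniform base model:

* detection limit — probability a spacer introduces no in-frame stop:
  $(61/64)^k$, ≈ 61.9% at $k = 10$;
* ATG baseline — probability of an in-frame ATG with no downstream
  in-frame stop: reading codons right-to-left, ATG (1/64 per codon) must
  precede any stop (3/64), giving
  $\sum_{i=1}^{k} (60/64)^{i-1}(1/64) = \tfrac14\,(1-(60/64)^k)$,
  ≈ 11.9% at $k = 10$.

Both closed forms are verified in the tests by exhaustive enumeration
over all $64^k$ codon sequences for $k \le 3$ (to $10^{-12}$) and by
Monte-Carlo at $k = 10$. The "no downstream stop" qualifier is the
definition that reproduces the ~12% baseline; a looser any-ATG mode
exists but is not the default. `annotate_frame()` applies the same
definition to real spacers; codons containing `N` are skipped and
flagged, and spacers shorter than the window are annotated over their
full length and flagged.

The duplication-frequency analysis groups unique spacers by exact
duplication count (one bin per observed count — published figures of
this kind do not state their bin edges, so no merging is the default)
and computes each bin's ATG fraction. The original description of this
analysis reports "a strong correlation" without naming a statistic; we
chose the least parametric option and label it as our own: the rank
correlation between duplication count and bin ATG fraction, weighted by
bin size, with a permutation null (duplication counts permuted against
annotations at the spacer level, default 10,000 permutations, seeded,
two-sided p). Its type-I error is calibrated in the test suite
(≤ 0.07 at nominal 0.05 over 200 null simulations).

## The synthetic-data generator: what it does and does not emulate

The generator is a stated world, not a tuning knob. Defaults:

| parameter | default | why |
|---|---|---|
| chromosome / plasmid length | 100 kb / 5.3 kb | desk-scale chromosome; plasmid at the working length used for normalisation |
| plasmid_source_prob π | 0.64 | the liquid-culture plasmid share, used as a planted parameter |
| pam_bias w | 20 | AAG-site weighting strong enough to dominate the PAM matrix while leaving non-AAG PAMs observable |
| duplication distribution | geometric, mean 3 | PCR + clonal amplification modelled jointly; heavy right tail matches duplication counts reaching ≥ 19 |
| error model | 1% sub + 0.5% ins + 0.5% del | plain proxy for post-basecalling long-read noise |
| parental_read_fraction | 0.9 | expansion is rare in real amplicon pools; most reads are unexpanded |

Reads are synthesised as
`upstream + repeat + spacer + repeat + downstream` (expanded) or without
the spacer unit (parental), half reverse-complemented, independently
corrupted per base (substitution, then deletion, then insertion-after).
A single RNG stream keyed by `seed` with a documented draw order makes
the whole run — references, events, reads, truth table — byte
reproducible.

Not emulated: homopolymer-specific error profiles, chimeric reads,
quality-score information (qualities are constant placeholders; no stage
consumes them), barcodes, and multi-unit pre-existing arrays (the
reporter starts with a single repeat). A green simulation test therefore
establishes correctness of the algorithms under idealised noise, not
performance on any particular real flow cell.

## Numerical and degenerate-input choices

* Edit-distance ties in repeat selection: ascending edit distance, then
  leftmost start, then shortest match.
* Mapping ties within a replicon: lowest start, then strand "+" before
  "−"; multiplicity recorded in `n_equal_best`.
* `plasmid_fraction` with zero mapped spacers is an explicit error, not
  NaN; bias index at f ∈ {0, 1} is reported as 0/Inf with a degenerate
  flag.
* PAM matrices use pseudocount 0 by default (none is published for the
  logos this mirrors); information content is `2 − H` bits per column
  and a uniform pseudocount can only lower it.
* Permutation p-values use the add-one estimator `(1 + #extreme)/(1 + B)`
  and are two-sided.
* The trend statistic is NA (p NA) when fewer than two duplication bins
  exist or a ranking is constant.

## Acceptance-scale choices

The parameter-recovery check plants π = 0.64 at n = 2000 events and
re-estimates it end-to-end at error rates 0 and 2%, five seeds each.
Because the ratio rule weights spacers by duplication count, the correct
binomial-oracle standard error of the recovered fraction is
$\sqrt{\pi(1-\pi)\sum d_i^2}/\sum d_i$ (about 1.3× the unweighted
binomial SE under the geometric duplication default); the test uses
3 of these SEs. The run uses `parental_read_fraction = 0.1` rather than
the generator default 0.9: parental reads contain no spacer and cannot
move the ratio, they only multiply runtime.

## Known limitations

* The mapper is exhaustive within `max_edits` but reports a single best
  site; it is not a seeded aligner and produces no E-values.
* Spacer orientation is kept as extracted (spacers are directional in
  the array); palindromic or strand-duplicated protospacers therefore
  count as distinct sites per strand.
* Duplication counts conflate PCR and clonal amplification; the data
  cannot distinguish them and neither does the model.
* Real-data headline ratios (liquid ~64%, solid ~9% plasmid share)
  require the deposited sequencing data and are out of desk-scale scope;
  the package's evidence for correctness is truth-table recovery on the
  synthetic world.
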