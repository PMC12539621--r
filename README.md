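# spacertrace

Analysis of naive CRISPR–Cas spacer acquisition from long-read amplicon
sequencing of a reading-frame reporter array.

## The problem

In the *E. coli* type I-E system, Cas1–Cas2 captures short DNA fragments
(prespacers) and inserts them at the leader-proximal end of a CRISPR
array, duplicating the direct repeat. A reporter strain couples this to a
visible phenotype: a constitutive promoter reads through the leader–repeat
region into a frame-shifted *lacZ*, and acquisition of one 61 bp
repeat–spacer unit restores the reading frame. Sequencing PCR amplicons of
the leader–repeat junction with a nanopore instrument then reveals, for
every acquisition event, the new spacer, its protospacer locus on the
chromosome or the Cas1–Cas2 expression plasmid, its PAM, and how often the
same spacer was amplified (its duplication count).

`spacertrace` re-implements that computational pipeline as a tested,
reusable R package for anyone studying spacer-source bias, protospacer
hotspots, PAM preferences, or reading-frame selection effects:

* **Synthetic data** (`sim_config()`, `simulate_run()`) — seeded generator
  of chromosome/plasmid references with an embedded reporter cassette,
  planted acquisition events (configurable plasmid share π, AAG-PAM bias
  weight w, duplication distribution) and nanopore-style noisy reads, plus
  a ground-truth table.
* **Spacer extraction** (`parse_reads()`, `collapse_duplicates()`) —
  orientation by leader anchor, error-tolerant repeat location by
  semi-global edit distance (Myers bit-parallel + DP kernels in C++),
  inter-repeat spacer extraction, exact-duplicate tallying.
* **Mapping** (`map_spacers()`, `extract_pam()`) — best edit-distance hit
  across both replicons and strands with circular wrap; sources
  chromosome / plasmid / ambiguous / unmapped; PAM window −2..+1 (two
  upstream bases + first protospacer base) by default.
* **Bias & hotspots** (`bias_summary()`, `bin_hits()`,
  `build_pam_matrix()`, `count_pam_sites()`) — all-spacer
  chromosome:plasmid ratios, molar-excess normalisation
  `g / (c·p)`, neutral share `s = c·p/(c·p+g)`, bias index
  `[f/(1−f)]/[s/(1−s)]`, 10 kb / 50 bp hotspot bins from unique spacers,
  PAM position-frequency matrices with per-column information
  `2 − H` bits.
* **Frame statistics** (`p_no_inframe_stop()`, `p_inframe_atg_no_stop()`,
  `annotate_frames()`, `atg_fraction_by_duplication()`) — under a uniform
  base model over k in-frame codons, the reporter's detection limit is
  `(61/64)^k` (≈ 62% at k = 10) and the baseline chance of an in-frame ATG
  with no downstream in-frame stop is `(1/4)(1 − (60/64)^k)` (≈ 12% at
  k = 10); spacers are annotated accordingly and tested for a
  duplication-count × ATG-fraction trend with a weighted rank correlation
  and permutation p-value.
* **Pipeline/CLI** (`run_pipeline()`, `spacertrace_cli()`) — simulate →
  extract → map → analyze with TSV + JSON reports, deterministic under a
  seed.

## Worked example

```r
library(spacertrace)

cfg <- pipeline_config(
  out_dir = "demo_out",
  sim = sim_config(seed = 7, n_events = 300, plasmid_source_prob = 0.64,
                   pam_bias = 20, parental_read_fraction = 0.2,
                   chromosome_length = 100000L, plasmid_length = 5300L),
  n_perm = 1000, seed = 7)
s <- run_pipeline(cfg)
s$bias
#> BiasSummary
#>   spacers: 296 chromosome, 543 plasmid (plasmid fraction 0.647)
#>   molar excess (chromosome:plasmid DNA): 0.5-fold
#>   neutral plasmid share: 0.6795; bias index: 0.87
s$pam_consensus
#> [1] "AAG"
round(s$analytic_constants$detection_limit_percent, 1)
#> [1] 61.9
```

The simulated pool planted 64% plasmid-derived events; the pipeline
recovers a plasmid fraction of 0.647 from the reads alone. Note the molar
excess: this *test-scale* world has a 100 kb chromosome against 40 copies
of a 5.3 kb plasmid, so plasmid DNA is actually in excess (0.5-fold) and a
64% plasmid share is *near-neutral* sampling (bias index 0.86 ≈ 1). At
real *E. coli* scale (`molar_excess(4641652, 5300, 40)` ≈ 21.9) the same
machinery shows a ~9% plasmid share to be near-neutral too. The PAM
consensus recovered from mapped protospacers is the canonical 5′-AAG, and
the analytic detection limit of the reporter is 61.9% ≈ 62%.

All per-stage outputs (spacers.tsv, tally.tsv, hits.tsv, bin maps,
pam_matrix.tsv, bias_summary.json, frame annotations, duplication bins,
run_summary.json) are written to `demo_out/`.

The same analysis is available from the shell:

```sh
Rscript inst/cli/spacertrace run --seed 7 --out demo_out --n-events 300
```

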