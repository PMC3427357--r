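# enhansr

Screening strand-specific RNA-seq coverage for novel enhancer-associated
antisense RNAs, and quantifying the sense isoform shift they correlate with.

## The problem

Active enhancers inside protein-coding genes can drive polyadenylated
antisense transcripts in a cell-state-specific way, and when the antisense
RNA is expressed, the host gene often switches to a shorter isoform ending
near the antisense transcript's 3' end — a signature of *cis*-acting
transcriptional interference. Finding such loci from stranded RNA-seq takes
four bespoke computations that this package packages up for reuse:

1. **RPKM-percentile-calibrated merging** of fragmented transcript
   assemblies. Features are ranked by RPKM percentile
   (`RPKM = count · 10⁹ / (length · N)`, percentile = empirical
   fraction-at-or-below over expressed features); two same-strand fragments
   are merged iff their gap is ≤ `max_gap` (default 11 kb, treated as an
   intron) **and** their percentile difference is ≤ `chosen_d` (default 10;
   5 as a conservative preset). Thresholds are calibrated from annotated
   genes, contrasting adjacent *internal* exon pairs (per-gene mean |Δp|)
   against adjacent *outer* pairs.
2. **A rule-based antisense screen**: candidates must be novel (same-strand
   exonic overlap with known transcripts < 10%), expressed
   (RPKM ≥ 1) in a condition where an associated enhancer peak is active,
   and the peak must lie within or just upstream (≤ 2 kb, strand-aware) of
   the transcript. Candidates are written as a six-column table
   (Region, Strand, Nearest Gene, Description, Expression, Enhancer).
3. **An isoform-shift statistic** at the antisense 3' boundary *b*:
   per condition, `r_c = (mean exonic coverage downstream of b + ε) /
   (mean upstream + ε)`; the score is `log2(r_off) − log2(r_on)` (positive
   ⇒ the long isoform is favoured when the antisense RNA is off), with a
   permutation p-value from random interior boundaries.
4. **ORF heuristics**: longest ATG→stop ORF (stop-inclusive length, so a
   243-nt ORF encodes `243/3 − 1 = 80` aa) and a simple noncoding-like flag
   (ORF covers < 50% of the transcript and encodes < 100 aa).

A synthetic-data generator plants all of this structure — two conditions,
condition-specific antisense loci under enhancer peaks, correlated isoform
shifts, fragmented assemblies — with machine-readable ground truth, so the
whole pipeline is exercised end to end without any external data.

## Worked example

```r
library(enhansr)

sim <- simulate_dataset(sim_config(noise_model = "none", seed = 1))
res <- run_pipeline(sim, out_dir = "enhansr_run",
                    config = pipeline_config(seed = 1))

evaluate_screen(res$candidates, sim$truth)
#>   n_candidates n_truth    tp    fp    fn precision recall
#> 1            6       6     6     0     0         1      1

glance(res$calibration)[, c("median_internal", "median_outer", "q90", "q95", "q99")]
#>   median_internal median_outer   q90   q95   q99
#> 1            1.08         11.1  8.86  9.54  11.1

res$shift[, c("gene_id", "boundary", "r_on", "r_off", "score", "pvalue")]
#>   gene_id boundary  r_on r_off score pvalue
#> 1 gene01     21035 0.196 0.911  2.22  0.001
#> 2 gene02     59189 0.124 0.903  2.86  0.003
#> 3 gene03     98566 0.120 0.902  2.91  0.003
#> 4 gene04    140202 0.124 0.903  2.86  0.001
#> 5 gene05    186748 0.177 0.909  2.36  0.001
#> 6 gene06    233616 0.121 0.902  2.90  0.002
```

Reading the output: the screen recovered all six planted antisense loci
with no false positives. Calibration shows the expected contrast — adjacent
internal exons differ by ~1 percentile point at the median while outer
(terminal) pairs differ by ~11, so a merge cap of 5–10 points bridges
within-transcript fragmentation without fusing genes. Every planted locus
has a positive shift score (the planted truth is 90% of sense signal
stopping at the boundary when the antisense RNA is on, vs 10% when off,
i.e. a true log-ratio of `log2(0.9/0.1) ≈ 3.17`; the pseudocount shrinks
estimates slightly toward 0) and a permutation p ≤ 0.003 at the true
boundary. `res$orf` flags five of the six random-sequence antisense
transcripts noncoding-like. All intermediates (calibration report, merged
BED12 models per condition, candidate/shift/ORF tables, run log with
parameter values and output checksums) are written under `enhansr_run/`.

A thin CLI over the same functions lives at `inst/cli/enhansr-cli.R`
(subcommands `simulate`, `coverage`, `calibrate`, `merge`, `evaluate`,
`screen`, `shift`, `orf`, `run-all`; exit code 2 on validation errors, 1 on
runtime errors):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","enhansr-cli.R",package="enhansr"))')" \
    simulate --out dataset_dir --seed 1
Rscript .../enhansr-cli.R run-all --dataset dataset_dir --out run_dir
```

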