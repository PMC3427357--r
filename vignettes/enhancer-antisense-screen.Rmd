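---
title: "Methods: screening stranded RNA-seq coverage for enhancer-associated antisense RNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening stranded RNA-seq coverage for enhancer-associated antisense RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhansr)
```

# The biological setting

Some protein-coding genes harbour an active enhancer inside one of their
introns. When such an enhancer drives a polyadenylated antisense RNA in one
cell state but not another, two things can be observed in strand-specific
RNA-seq: condition-specific coverage on the strand opposite the gene,
originating at the enhancer, and a correlated change in the gene's own 3'
end — the major sense isoform terminates near the antisense transcript's 3'
end when the antisense RNA is on, consistent with transcriptional
interference acting in cis. `enhansr` turns that observation into a
reusable, testable pipeline:

1. **Expression and calibration** — RPKM and transcriptome-wide RPKM
   percentiles per feature; calibration of merge thresholds from
   adjacent-exon percentile differences in annotated genes.
2. **Fragment merging** — reassembly of fragmented transcript calls under a
   percentile-difference/gap rule.
3. **Antisense screen** — novel transcripts, expressed when an associated
   enhancer peak is active, within or just upstream of the mature
   transcript.
4. **Isoform shift** — a log-ratio statistic for short- vs long-isoform
   preference at the antisense 3' boundary, with a permutation test.
5. **ORF heuristics** — longest-ORF scanning and a simple coding-potential
   flag for the candidates.

All coordinates inside the package are 0-based half-open (BED-native);
1-based formats (GTF) are converted at the file boundary only, so interval
arithmetic is uniformly gap- and length-safe.

# Expression: RPKM and percentiles

A coverage track is dense per-base depth for one strand, one condition,
plus the library's total mapped read count $N$. Read counts are recovered
from coverage as $\text{count} = \sum_{\text{exonic bases}} d_i / L$ with a
read-length equivalent $L$ (default 50 nt, matching 50-bp single-end
reads), and

$$\mathrm{RPKM} = \frac{\text{count} \cdot 10^9}{\text{exonic length} \cdot N}.$$

Percentiles are the empirical "fraction at or below" CDF over *expressed*
features only (RPKM > 0), scaled to $[0, 100]$: ties share one value, zeros
are reported as percentile 0 and excluded from the denominator. This
estimator was chosen because it is exact on small feature sets, monotone in
RPKM, and makes the rank interpretation of a threshold $d$ ("merge when two
fragments are within $d$ percentile points") transparent. Percentiles are
computed per track (per condition and strand); pooling across library types
is possible but not the default.

# Merge calibration from adjacent exons

Within a genuinely single transcript, adjacent exons should have similar
expression; their percentile differences measure how much apparent
expression difference is compatible with "same transcript". For each gene
(the longest isoform of multi-isoform genes), every consecutive exon pair in
which both exons are non-terminal is an *internal* pair; the gene
contributes the mean $|\Delta p|$ of its internal pairs. The (first, second)
and (last−1, last) pairs are *outer* pairs and are pooled without averaging
— terminal exons carry UTRs, alternative ends and assembly edge effects, so
their differences are systematically larger and serve as the contrast. The
calibration reports the empirical 90/95/99th percentiles of the internal
distribution and the fraction of outer pairs at or below each.

The merge rule itself uses a chosen cap `chosen_d` (default 10 percentile
points, with 5 as a conservative preset) and a maximum bridged gap
`max_gap` (default 11,000 bp), treating the bridged gap as an intron.

# Fragment merging

Two adjacent fragments on the same chromosome and strand are joined iff
their gap is at most `max_gap` *and* their percentile difference is at most
`chosen_d`. Joining concatenates exon lists, unions provenance, recomputes
RPKM as the length-weighted combination of the parts, and re-looks-up the
merged percentile **against the unchanged pre-merge percentile map**. The
scan is left-to-right per chromosome/strand and iterates to a fixpoint.

Numerical and design notes:

* Keeping the percentile reference fixed during a run makes the operation
  deterministic and order-stable; re-ranking against a shrinking model set
  would make results depend on scan order.
* On the study conditions the pipeline is built for — fragments of a
  transcript with near-uniform internal expression, neighbouring genes
  separated by more than `max_gap` — the final partition is provably
  order-independent (all within-transcript differences are ties or near
  ties, nothing can bridge between genes), and the test suite verifies the
  left-to-right fixpoint against an all-orders brute-force oracle on such
  chains. For arbitrary percentile patterns the join relation is genuinely
  order-dependent, which is why a deterministic scan order is part of the
  method definition.
* "Bad joins" are counted as models whose exons overlap exonic bases of two
  or more distinct genes on the same strand. Because the count is over
  models, it is monotone in `d` only while joins do not chain: at very
  permissive `d` two separate 2-gene fusions can merge into a single 4-gene
  fusion, lowering the count by one while making the assembly worse. The
  per-model count is retained because it matches the reported quantity the
  audit mirrors; interpret it alongside the model list, not alone.

# The antisense screen

A merged model becomes a candidate iff

1. it is **novel**: same-strand exonic overlap with any known transcript is
   below `novelty_max_overlap` (default 10% of the model's exonic length) —
   opposite-strand overlap, i.e. the antisense configuration itself, does
   not count against novelty;
2. it is **expressed with an active enhancer**: there is a condition where
   its RPKM is at least `expression_threshold` (default 1 RPKM) *and* an
   associated peak is annotated for that condition;
3. a peak is **associated**: it overlaps the model span or lies within
   `upstream_window` (default 2,000 bp) 5' of the transcription start,
   strand-aware. Peaks are strandless, as ChIP peaks are.

The defaults for the novelty fraction, expression threshold and upstream
window are package choices: the source observations ("do not appear to be
part of a known transcript", "within or just upstream") are qualitative, so
each is exposed as a single tunable with a conservative default. Candidates
are reported with their best opposite-strand partner gene (maximal span
overlap) and written in a six-column table (Region, Strand, Nearest Gene,
Description, Expression, Enhancer).

# The isoform-shift statistic

Let $b$ be a boundary inside the sense gene — by default the antisense
model's 3' end projected onto the gene. For each condition $c$,

$$r_c = \frac{\overline{d}_{\text{downstream}} + \epsilon}
             {\overline{d}_{\text{upstream}} + \epsilon},$$

where the means are taken over `flank` (default 1,000) *exonic* bases of
the gene's longest isoform on each side of $b$ in the sense direction, and
$\epsilon$ is a pseudocount (default 1 depth unit). The score is
$\log_2 r_{\text{off}} - \log_2 r_{\text{on}}$: positive when the long
isoform is relatively favoured with the antisense RNA off. Exonic-only
means avoid intronic dilution; the pseudocount guarantees finite scores but
biases them toward 0 when window means are comparable to $\epsilon$ (i.e.
for weakly expressed genes) — the score recovers the planted log-ratio
within a few tenths only when mean exonic depth is well above the
pseudocount.

The permutation null recomputes the score at `n_perm` (default 999)
boundaries drawn uniformly from the gene's interior exonic positions
(excluding a `flank` margin at each end), and reports the add-one estimator
$p = (1 + \#\{|s_\pi| \ge |s_{obs}|\}) / (n_\text{perm} + 1)$, which is
never 0 and is deterministic given a seed. Window means are computed from
prefix sums over the sense-ordered exonic depth vector, so the full null
costs $O(\text{gene length} + n_\text{perm})$.

No score threshold is imposed for declaring a shift: continuous scores and
p-values are reported and the decision is left to the analyst.

# ORF scanning and the coding flag

`longest_orf()` scans the three frames of the given strand (candidate
transcripts are already oriented) for the longest ATG→stop stretch, stop
codon included in the length; ties go to the smallest start, and codons
containing N match neither ATG nor a stop. ORFs without an in-frame stop
inside the sequence are not reported — the stop-inclusive convention is
what makes a 243-nt ORF correspond to an 80-aa protein
($243 = 3\times(80+1)$). The coding flag is deliberately minimal: a
transcript is noncoding-like iff its longest ORF covers less than half the
transcript *and* encodes fewer than 100 aa. It stands in for nothing more
sophisticated (no Kozak-context scoring, no homology search, no
conservation) and is labelled a heuristic in the output.

# The synthetic-data generator

`simulate_dataset()` builds one toy chromosome with the statistical
structure the analysis assumes, plus machine-readable truth:

* `n_genes` (default 20) multi-exon sense genes on the minus strand,
  10–14 exons of 250–500 bp with introns of 0.8–2.5 kb, spaced 20 kb apart
  so the 11-kb merge gap cannot bridge neighbouring genes unless a fixture
  plants it deliberately;
* per-gene mean exonic depth uniform in 5–50; optional per-base Poisson
  noise around the planted mean (coverage-level simulation — the pipeline
  consumes coverage, not alignments, so individual reads are never
  simulated);
* `n_antisense_loci` (default 6) genes additionally carry an unspliced
  plus-strand antisense transcript of 0.8–1.8 kb ending at the gene's
  exonic midpoint, with depth `antisense_depth` (default 10) in the ON
  condition ("UN") and zero in the OFF condition ("NP"), and a 300-bp
  enhancer peak over its 5' end annotated only in the ON condition;
* the sense isoform shift is planted by multiplying sense coverage
  downstream (in the sense direction) of the antisense 3' boundary by
  $1 - f_c$, with $f_{\text{on}} = 0.9$ and $f_{\text{off}} = 0.1$ —
  i.e. 90% of sense signal stops at the boundary when the antisense RNA is
  on;
* terminal-exon attenuation: the first and last exon's mean depth is
  multiplied by a factor drawn uniformly from
  `terminal_attenuation_range` (default 0.4–1). This models the
  systematically deviating coverage of terminal exons in real libraries
  (UTR structure, alternative starts/ends, edge effects of assembly),
  which is precisely the contrast the merge calibration measures: with
  strictly uniform expression plus noise, internal and outer differences
  are draws from the same distribution and their medians are not reliably
  ordered. Setting the range to `c(1, 1)` gives fully within-gene-uniform
  expression, which the merge-recovery analyses use;
* fragmentation: each expressed transcript is split at
  `n_breaks_per_transcript` break points (chosen among exonic positions)
  with gaps of 50–200 bp, emulating fragmented assembler output. The gaps
  exist at the annotation level only — coverage keeps the full planted
  signal, since zeroing it would corrupt the shift statistic's flank
  windows with artefacts the real phenomenon does not have;
* library size per condition is derived from the planted coverage
  (`sum(depth)/read_length`) by default, so planted depths are honoured
  exactly in the no-noise limit; a fixed
  `library_size_per_condition` instead rescales the planted means so the
  realised read count matches it within Poisson tolerance;
* seeding: one master seed; each locus derives a child seed from its index,
  so enlarging a simulation leaves earlier loci byte-identical.

What the generator does **not** emulate: spliced antisense transcripts,
sequencing error, mappability and multi-mapping, nuclear/cytoplasmic
compartments, biological replicates, and chromatin data beyond labelled
peak intervals. Passing tests on this generator therefore demonstrate the
pipeline's logic — recovery of planted structure under Poisson counting
noise — not robustness to alignment artefacts or biological variability in
real libraries.

# Problem sizes and runtime choices

The bundled analyses run the default design (20 genes, 6 antisense loci,
one ~900-kb chromosome, two conditions, 999 permutations per candidate) in
seconds on one CPU; unit tests use a 6-gene version of the same design.
These sizes were chosen because every statistic involved (percentile ranks
over ~260 exons, merge decisions over ~70 fragments, 6-locus
precision/recall) is already stable at that scale — the pipeline's
complexity is linear in chromosome length and fragment count, so larger
designs change cost, not behaviour.

# Degenerate inputs and tie-breaking

* Percentile assignment refuses inputs with no expressed feature; all-zero
  tracks yield zero fragments rather than errors.
* Merging with equal percentiles and in-range gaps joins everything
  reachable; exon lists are union-reduced, so overlapping fragment calls
  cannot produce invalid models.
* `find_antisense_partner()` breaks exact overlap ties by gene id;
  `longest_orf()` breaks length ties by smallest start.
* `shift_score()` errors (rather than truncating) when a flank window does
  not fit inside the gene's exonic sequence, naming the offending window;
  the permutation test refuses genes with fewer than two eligible
  boundaries.
* The fragment caller's bridging rule is exact: an internal sub-threshold
  run of exactly `max_zero_run` bases is bridged, one base more splits.

# Known limitations

* The screen is coverage-driven: antisense transcripts overlapping their
  host gene on the *same* strand (rare, but real) are invisible by
  construction, and novelty is judged against the provided annotation only.
* RPKM from coverage assumes unspliced, uniquely mapped reads; spliced
  alignments would need exon-aware counting upstream of this package.
* The shift statistic conditions on a single boundary; genes with several
  alternative 3' ends produce composite scores.
* The coding flag is a heuristic and should not be treated as a coding
  potential call of record; it exists to triage candidates.

# A worked run

```{r, eval = FALSE}
sim <- simulate_dataset(sim_config(noise_model = "none", seed = 1))
res <- run_pipeline(sim, out_dir = "enhansr_run",
                    config = pipeline_config(seed = 1))
evaluate_screen(res$candidates, sim$truth)
glance(res$calibration)
res$shift
autoplot(res$calibration)
plot_locus(sim, locus = 1)
```
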