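---
title: "Models and methods behind tnfitness"
author: "tnfitness authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tnfitness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnfitness)
```

# The experiment being modeled

Transposon-directed insertion-site sequencing (TraDIS) starts from a dense
library of mutants, each carrying a mini-Tn5 insertion at a random genomic
position. Sequencing outward from the transposon end yields *junction reads*
whose first genomic base marks the insertion site; counting reads per site
and sites per gene quantifies how well each mutant tolerates a condition.
Two statistics carry the analysis:

* the **insertion index** of a gene, unique insertion sites divided by gene
  length in bp — near zero for genes whose disruption is lethal on the
  selective medium used to build the library;
* the **log2 fold change** of per-gene read counts between a treated and an
  untreated (control) aliquot of the same library — negative when mutants of
  the gene die faster than average under treatment (a conditional-fitness
  *loss*), positive when they are relatively enriched (*gain*).

`tnfitness` implements the full desk side of such a screen — simulation with
known ground truth, read processing, per-gene statistics, essentiality
calling, fitness testing, enrichment, and the competition-assay selection
rate used for single-mutant validation — so that every stage can be tested
against a truth it is supposed to recover.

# The synthetic-data generator

`generate_genome()` draws a random linear replicon and packs
non-overlapping genes with gamma-distributed lengths (mean 900 bp by
default, a typical bacterial CDS; CV 0.25, floor 100 bp), separated by gaps
of at least 1 bp. Coordinates are 1-based and inclusive throughout.

`simulate_library()` turns each base into a unique insertion site with
probability `insertions_per_bp` (default 1/10.3, the density of a saturated
mini-Tn5 library in *E. coli*), assigns a uniform random strand, and draws a
zero-truncated negative-binomial read count per site (mean 20, dispersion
`alpha = 0.3`, variance `mu + alpha*mu^2`) — realistic overdispersion for a
PCR-amplified junction library. Bases strictly inside genes marked
*essential* in the effect map never receive insertions; tolerance of
insertions in the terminal portion of essential genes is not simulated
(a downstream `end_trim_fraction` exists instead). Two further conventions
matter:

* **End margin.** The first and last 100 bp (about one read length) carry no
  simulated insertions. A real chromosome is circular, so junctions never
  run off an end; on the linear simulated replicon the margin plays the same
  role without modeling wraparound. Junction reads from sites near an end
  would otherwise be truncated below the length filter and make exact
  profile round-trips impossible.
* **Replicates.** Biological replicates of a screen are aliquots of *one*
  physical library, not independent libraries. Replicate profiles are
  therefore produced by `apply_selection()` — multinomial resampling of the
  master library's reads, with per-site weight `count * 2^(scale *
  fitness_log2)` of the containing gene — using `scale = 0` for control
  replicates. This is what makes per-gene insertion indices of replicate
  pairs highly correlated (the r² ≥ 0.95 regime the tests check, matching
  the 0.97–0.98 observed in real screens); independent libraries would show
  no correlation across genes at all, since every gene has the same
  expected index. Selection conserves `total_reads` exactly and can only
  lose sites, mirroring a sequencing budget split across surviving mutants.
  A `fitness_log2` of `-Inf` is a hard kill (zero weight).

`emit_reads()` writes `barcode + tag + junction` reads with constant Q30
qualities. Substitution errors at `error_rate` are applied to the genomic
junction only: the inline barcode and transposon tag are synthetic handles
ligated after the error-prone template, and modeling errors there would
conflate demultiplexing loss with mapping loss. Reads near a replicon end
are truncated, never wrapped. No PCR bias, indels, quality decay or
paired-end structure is modeled — passing tests therefore say nothing about
adapter contamination or quality trimming on real data.

All randomness flows from one master seed through `derive_seed(seed, stage,
index)`, so each stage is independently reproducible.

# Read processing

Demultiplexing is exact prefix matching against a prefix-free barcode table
(violations are configuration errors). The transposon tag must match with at
most `max_mismatch` substitutions (default 2); the remainder is the
junction, and junctions shorter than `min_junction_len` (default 20 bp —
short enough to keep, long enough for essentially unique placement in a
multi-Mb genome) are removed with a distinct counter, since short-read
removal is a standard step in these pipelines.

Mapping is seed-and-verify: a 20-mer seed must match a two-strand k-mer
index exactly, at one of up to three non-overlapping offsets into the
junction; each candidate placement is then verified over the full junction
with at most `max_mismatch` substitutions and no gaps. The offset retry and
the mismatch budget exist because a 1% per-base error rate leaves barely
60% of 44-bp junctions error-free: exact full-length matching would discard
a third of the data, while the budgeted verification recovers well over 95%
of reads from unique-sequence sites. Ties on the minimal mismatch count are
reported *ambiguous* and discarded, never randomly assigned — random
assignment would fabricate insertion sites inside repeats. The reported
position is the first genomic base of the junction on the matched strand
(for a minus-strand junction, its rightmost genomic coordinate); site
uniqueness is per (position, strand) by default, with a `collapse_strands`
flag because published screens rarely state their convention. An external
mapper can substitute for the built-in one via `read_sam_sites()`, which
ingests SAM records (RNAME/POS/FLAG only) under the same position
convention.

# Per-gene statistics and essentiality

`summarize_genes()` credits a site to every gene whose (optionally
end-trimmed) interval covers its position; `end_trim_fraction` defaults to
0 because no trimming rule is standard, and the flag exists for
essentiality-style analyses where gene ends tolerate insertions.

Essentiality calling fits a two-component gamma mixture to the insertion
indices by EM (`fit_essentiality_mixture()`), the standard approach for
saturated libraries. Numerical choices:

* every index gets a small pseudo-index before fitting — the pipeline uses
  `1/(2 * max gene length)`, half the smallest index a single insertion
  could produce — so insertion-free genes have a proper support point in
  the left component;
* weighted gamma MLE with the shape solved by Newton iteration; the shape is
  capped at `1e4` because it diverges when a component collapses onto a
  single value (exactly what happens when the left component absorbs the
  all-zero essential genes);
* initialization splits the data at the geometric midpoint of the index
  range, making the fit deterministic; components are reported in
  increasing-mean order;
* convergence is declared when the log-likelihood improves by less than
  1e-8 for three consecutive iterations;
* a fit whose component means are separated by less than a factor of 5 (or
  whose weight runs to 0 or 1) raises a degenerate-fit error. Genuinely
  bimodal index data separate the modes by around two orders of magnitude,
  so this guard fires on unimodal data, where a mixture split would be
  arbitrary. `run_pipeline()` then falls back to a fixed threshold
  (`essentiality_fallback_threshold`, default 0.005 insertions/bp, far
  below the 1/10.3 library density), which is also used for screens with
  fewer than the 100 genes the mixture needs.

Calls use the log2 likelihood ratio of the two weighted components with an
*ambiguous* band between log2-odds −2 and +2, so that borderline genes are
neither excluded from fitness testing silently nor counted as essential.

# Fitness testing

The treated-versus-control comparison re-implements the classical exact
test for overdispersed counts rather than calling an external package, so
that its behavior is fully specified and testable:

1. **Normalization.** Size factors are library sizes (optionally a
   trimmed-mean-of-ratios variant). A common dispersion φ is estimated by
   method of moments on within-condition replicates, with an unbiased
   denominator (`m² − v/n`) and a floor at zero.
2. **Pooling.** Replicates are mapped to a common library size by mid-p
   quantile-to-quantile matching under NB(φ) and summed per condition —
   the classical exact-test construction for replicated counts.
3. **Exact test.** Conditional on the pooled total *t*, the split between
   conditions is free of the unknown gene abundance (binomial at φ = 0, its
   negative-binomial analogue otherwise). The two-sided p-value sums the
   probabilities of all splits no more probable than the observed one,
   computed in log space; a relative tie tolerance of 1e-9 keeps equal-mass
   splits on the rejection side regardless of rounding.
4. **Fold change.** `log2((mean normalized treated + 0.5) / (mean
   normalized control + 0.5))`; the 0.5 prior keeps zero-count genes finite
   without materially moving well-covered genes.
5. **Correction and gate.** Bonferroni over the genes actually tested
   (non-essential genes with at least one read anywhere). The gate is
   `loss` when `log2fc < -1` and `adj_p < 0.005`, `gain` when `log2fc > 1`
   and `adj_p < 0.005`, else `ns` — both inequalities strict, because
   published usage treats a magnitude of 0.961 as "fractionally below" a
   threshold of 1 while a p of 0.0041 passes 0.005. The enrichment
   threshold below is inclusive (≤), deliberately; the two constants are
   independent.

Dispersion shrinkage (tagwise/trended), GLMs, FDR procedures other than
Bonferroni and operon-polarity corrections are out of scope.

# Enrichment and validation statistics

`enrich()` is a plain one-sided hypergeometric upper tail per term against
a user-supplied background (default in the pipeline: all annotated genes —
whether published analyses used all genes or only non-essential ones is
usually unstated, so it is configurable). It deliberately replaces
web-service annotation tools with an explicit, reproducible test on a
two-column gene→term table; no GO-graph propagation and no multiplicity
correction is applied, matching common practice for these screens.

`selection_rate()` computes the competition-assay fitness index
`r = ln(Rt/R0) − ln(Vt/V0)` from mutant (R) and wild-type (V) colony
counts. Zero counts at time t leave r undefined; the default policy flags
the replicate (a mutant eradicated below the detection limit is a
qualitative outcome, not a number), and a 0.5-pseudocount policy exists for
users who prefer a finite estimate. Zero baselines are data errors. The
statistic is invariant to common dilution factors and antisymmetric under
swapping the two competitors.

# Orchestration and problem sizes

`run_pipeline()` chains the stages deterministically from a validated
config (`tn_config()`; unknown keys rejected; a frozen copy written next to
the outputs). Two treated time points are modeled as two selection
strengths against one control pool (defaults 1.0 and 1.6), reflecting a
design where the same stress acts longer in the second sample. When ground
truth is attached — always, for simulated runs — a recovery report gives
the confusion table, essentiality sensitivity/specificity, fold-change RMSE
over well-covered true-effect genes, and replicate r².

The packaged checks run at sizes chosen to finish in minutes on one CPU
while keeping sampling error well inside the asserted margins: a 50 kb /
40-gene screen for round-trips and replicate agreement, a 900 kb /
1,000-gene screen (30 loss genes at log2 effect −3, 10 gain genes at +2,
50 essential, ≥ 200 reads per gene) for effect recovery, and a 1.8 Mb /
4,000-gene screen for the null false-positive rate (10 seeds) and
essentiality recovery (400 insertion-free genes). These are scaled-down
study conditions, not the multi-Mb genome of a real screen; nothing in the
statistics depends on genome size beyond sampling depth.

# Known limitations

* The generator does not model PCR bias, positional coverage waves,
  polar effects on downstream operon genes, or insertion hot/cold spots;
  real replicate correlation and dispersion structure are messier.
* The mapper is exact-seed based and gap-free; structural variants between
  the clone and its reference would defeat it (use an external mapper and
  `read_sam_sites()` in that case).
* The essentiality mixture assumes a bimodal index distribution; genomes
  with many ambiguous, low-coverage genes will land in the ambiguous band
  or trip the degeneracy guard.
* Bonferroni is conservative; with thousands of genes, genuine small
  effects below roughly one log2 unit are invisible by design of the gate.
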