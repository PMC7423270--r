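---
title: "Detecting copy-number displacement from pooled paired-end sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting copy-number displacement from pooled paired-end sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When two classes of populations differ in a derived trait — here, two
*Choosy* populations showing assortative mate preference inside a hybrid
zone versus two *Non-Choosy* populations outside it — loci contributing to
the trait are expected to mirror the phenotypic pattern of character
displacement: the derived allele at high frequency only where the derived
trait occurs. `cnvdisplace` implements this scan for copy-number variants
(multi-nucleotide deletions and tandem duplications, collectively CNVs)
detected from pooled whole-genome sequencing (Pool-Seq), where allele
frequencies must be inferred from read evidence rather than genotypes.

Two read-pair signatures carry the signal. A read pair spanning a deletion
maps to the reference with an unusually large outer insert (a *distant*
pair); a pair spanning the junction between the two copies of a tandem
duplication maps with outward-facing mates (an *everted* pair). Two proxies
stand in for allele frequency at a called locus: the number of discordant
pairs supporting the call, and the local read depth normalized by the
pool's genome-wide median.

## The procedure

1. **Insert-size profile** (`fit_insert_profile`). Per pool, the mean, sd
   and the upper first percentile of the outer insert sizes of
   inward-facing pairs (nearest-rank, no interpolation). Only inward pairs
   enter the fit, so variant signal cannot inflate the threshold.
2. **Classification** (`classify_pairs`). Everted orientation is
   duplication evidence regardless of insert; inward pairs with insert
   strictly greater than the upper-1% threshold are distant (deletion
   evidence); same-strand pairs are set aside.
3. **Calling** (`cluster_discordant`, `estimate_interval`, `call_pool`).
   Single-linkage clustering of one class of discordant pairs: two pairs
   join when their implied CNV intervals overlap by at least 1 bp and
   corresponding endpoints each differ by at most the insert threshold
   (pairs from one event scatter by at most about one fragment length).
   Clusters need at least five supporting pairs; event coordinates are
   lower-middle medians of member endpoints with a fragment-geometry bias
   correction (below); calls below 50 bp are dropped, since below one read
   length pair geometry cannot resolve an event.
4. **Pairwise divergence** (`compare_pools`). Calls from two pools are
   comparable when both coordinates differ by less than half their mean
   size. A locus diverges significantly only if (i) its
   coverage-normalized support difference exceeds the empirical 95th
   percentile cutoff, (ii) its depth log2 ratio falls outside empirical
   per-length-bin 5th/95th cutoffs estimated from random unmasked regions
   of matched length (bins 50, 100, 150, 200, 500, 1000, 2000, 5000,
   8000 bp), and (iii) the depth deviation implicates the same carrier
   pool as the support imbalance (deletion carriers lose depth,
   duplication carriers gain it).
5. **Replicate consistency and candidates** (`match_across_comparisons`,
   `enforce_direction`, `subtract_control`, `classify_candidates`). Loci
   significant in both focal (between-class) comparisons are matched as
   identical by state (equal coordinates) or non-identical by state (≥1 bp
   overlap, sizes within 5% of their mean), must diverge toward the same
   behavioural class in both, and are removed if a same-type locus repeats
   in the within-class control comparisons. Survivors are
   Choosiness-associated (non-reference allele high in both Choosy pools;
   the reference genome is treated as the ancestral state by assumption,
   not inference) or Non-Choosiness-associated, and parallel-fixed if they
   are presence/absence differences in both comparisons.
6. **Genomic context** (`clustering_test`, `overlap_enrichment`,
   `summarize_sizes`). Masked-aware permutation tests: candidates are
   re-placed uniformly among all positions where they fit entirely in
   unmasked sequence, lengths preserved, placements independent and
   cross-chromosome. Statistics: 10-kb bins holding ≥2 candidate starts,
   and candidates intersecting a track extended by a flank (1 kb for
   genes; 0 for recombination cold-/hot-spot tracks). Empirical p-values
   use the add-one rule, so p ≥ 1/(n_perm + 1); two-sided p doubles the
   smaller tail, capped at 1; a null with zero variance is flagged
   degenerate rather than given a z-score.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `min_support` | 5 | pairs | minimum discordant pairs per call |
| insert threshold | upper 1% | bp | distant-pair cutoff, per pool |
| `min_size` | 50 | bp | below one read length geometry is uninformative |
| support percentile | 95th | — | two-sided extremeness of normalized support differences |
| depth percentiles | 5th/95th | — | literal top-and-bottom-5% empirical cutoffs |
| `n_random` | 10,000 | regions/bin | ±0.5% percentile stability |
| match fraction | 1/2 | of mean size | between-pool comparability |
| `ibs_tol` | 0.05 | of mean size | non-identical-by-state tolerance |
| `eps` | 0.01 | — | pseudocount keeping zero-depth deletions representable in log2 ratios |
| `gene_flank` | 1000 | bp | gene proximity criterion |
| `n_perm` | 10,000 | permutations | context tests |

## What the simulator emulates — and what it does not

`simulate_pool_reads` emulates mapping by coordinate transformation rather
than synthesizing and aligning sequence. Each pool samples
2 × `n_individuals` haplotypes; each haplotype carries each planted CNV
independently at that pool's allele frequency (no linkage). Fragments are
drawn uniformly along each haplotype with truncated-normal lengths
(defaults 480 ± 50 bp on [2 × 100, 480 + 6 × 50] bp), at a rate giving the
target 30X pooled read-base depth. A fragment spanning a deletion maps
inward with the insert inflated by the deletion size; a fragment spanning
a tandem-duplication junction maps everted; fragments inside a deleted
segment on a carrier haplotype produce nothing, and both copies of a
duplicated segment pile onto the single reference locus. Mates that would
straddle a breakpoint are dropped as unmappable rather than soft-clipped.

Not modelled: sequencing error, base/mapping qualities, SNPs, inversions
and transpositions, repeat-induced mismapping, GC bias, and the two-library
insert mixture of real data (one truncated-normal component is used; the
upper-percentile threshold adapts to whatever distribution is present, so
the detection layer does not depend on normality). Passing tests therefore
demonstrate that the *inference chain* — from alignment geometry to
candidate classification — is correct under clean mapping; they do not
certify performance under alignment artefacts, which real data would add
on top.

A consequence of the method worth stating plainly: the distant-pair
threshold is a percentile, so roughly 1% of all pairs are distant by
construction and per-pool catalogues contain hundreds of spurious
deletion clusters per 10 Mb at 30X. This matches the scale of raw
per-population cluster counts the approach produces on real data. Noise is
removed downstream — by the dual significance criteria, replicate
consistency and control subtraction — not at the calling stage; the
variant-free demonstration genome ends with zero candidates.

## Numerical choices

* **Nearest-rank percentiles** everywhere (insert threshold, support
  cutoff, depth cutoffs): reproducible integer-friendly thresholds, no
  interpolation; identical to `quantile(type = 1)`.
* **Lower-middle medians** for interval estimation: even-sized clusters
  take the lower middle member, keeping estimates on observed coordinates
  and deterministic.
* **Fragment-geometry bias correction.** A distant pair's implied interval
  `[left_end, right_start)` over-spans the deletion by the sequenced-free
  part of the fragment — on average `(mean_insert − 2 × read_length)/2`
  per side (~140 bp at 480/100 geometry); everted intervals under-span a
  duplication by the same amount. `call_pool` shrinks deletion estimates
  and expands duplication estimates by that constant per side. Without it,
  1-kb deletions are recovered with only ~72% reciprocal overlap; with it,
  recovered intervals sit within a few tens of bp of the truth.
  `estimate_interval` keeps plain medians as its default (`adjust = 0`).
* **Support-cutoff basis.** The 95th percentile of normalized support
  differences is taken over loci present in both pools when at least 20
  such loci exist. On small genomes two independent pools share few
  chance loci, so the cutoff falls back to the percentile over all matched
  loci; the basis is recorded in the thresholds object. On data with
  realistic amounts of shared polymorphism the primary definition applies.
* **Degenerate inputs.** Fully masked call intervals are flagged unusable
  and can never be significant; permutation nulls with zero variance are
  flagged rather than z-scored; empty candidate sets short-circuit the
  context stage and report zeros.
* **Determinism.** Every stochastic stage derives its seed from the run's
  master seed via a fixed string hash (`derive_seed`), so one config fully
  determines all outputs; two runs from one config are byte-identical.

## Open design decisions

* *Insert size* is the outer span (leftmost mapped base to rightmost
  mapped base), consistent with deletion-size inflation arithmetic.
* *Control-test direction.* Within-class comparisons have no behavioural
  polarity; "same direction" is positional (the carrier is the
  first-listed pool of its pair in both comparisons). This is a
  convention, flagged as such.
* *Control subtraction is type-restricted*: a deletion and a duplication
  at the same locus are different alleles and never cancel.
* *Mixed fixity* across the two focal comparisons (fixed in one,
  quantitative in the other) classifies as quantitative.
* *BOTH-locus interval.* A locus called in both pools is reported with
  the higher-support (carrier) side's coordinates; candidates report the
  union across the two comparisons.
* *One-to-one matching* resolves competing partners by minimal endpoint
  distance with leftmost tie-break, symmetric under catalogue exchange.

## Problem sizes used

The packaged demonstration scenario runs four pools of 30 diploids at 30X
on a 2 × 10 Mb genome with 5% masked sequence (~3 million read pairs per
pool), 10 + 3 planted displacement variants, 5 mirror-pattern deletions,
5 single-pool decoys and 5 shared neutral deletions, with 10,000 random
regions per depth bin and 10,000 permutations for context tests. These
sizes exercise every stage at full library realism while a complete run
stays under a minute per pool end to end. The same generator scales to
larger genomes linearly in genome size × depth.

## Known limitations

* Breakpoints are resolved to tens of bp, not single-base precision; no
  split-read refinement is attempted.
* Multi-copy amplifications are not distinguished from single tandem
  duplications, and only tandem (not dispersed) duplications are
  detectable from everted pairs.
* Duplications shorter than about one fragment length leave no everted
  pairs with both mates mappable and are invisible to the method.
* Individuals within a pool are not genotyped; frequencies are proxies.
* No multiple-testing correction is applied across loci at the divergence
  stage; the replicate-and-control design is the error-control mechanism.

## A minimal run

```{r example}
library(cnvdisplace)
run <- run_pipeline(demo_config(seed = 1), verbose = TRUE)
run$report        # count ledger, Venn-style splits, identity checks
run$candidates    # confirmed candidates with association and fixity
write_run(run, "results/demo")
```
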