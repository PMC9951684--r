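---
title: "Models and methods behind rohdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rohdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohdiv)
```

`rohdiv` packages the diversity-partitioning, conservation-priority and
runs-of-homozygosity (ROH) workflow used in livestock conservation
genomics. This vignette explains the models, the parameters that matter,
the conventions we had to pin down where the field's descriptions are
loose, and what the synthetic-data validation does and does not establish.

## Molecular coancestry and the gene-diversity partition

All gene-diversity quantities derive from identity-by-state molecular
coancestry: for dosages $x_i, x_j \in \{0,1,2\}$,
$f_{ij} = (x_i x_j + (2-x_i)(2-x_j))/4$ averaged over loci called in both
individuals, with self-coancestry $s_i = (1+\text{hom}_i)/2$ on the
diagonal. Missing data are handled pairwise-complete per locus.

The partition uses breed-block means $\bar f_{bb'}$ of this matrix, with
the within-breed mean taken **over the full block including the diagonal**.
This convention is not cosmetic: it makes the block means reduce
algebraically to $\hat p_b^2 + \hat q_b^2$ (within) and
$\hat p_b \hat p_{b'} + \hat q_b \hat q_{b'}$ (between), so

* $H_T = H_S + D_G$ holds to machine precision on every dataset, and
* the coancestry-based between-breed distance equals the frequency-based
  Nei minimum distance $(\hat p_b - \hat p_{b'})^2$ **exactly** on complete
  data (the test suite asserts equality at $10^{-12}$ at sample sizes 10,
  50 and 200; with missing calls the two drift apart only through
  pairwise-complete averaging).

Breeds are weighted equally ($1/B$) throughout; census weighting is
available via `breed_weights` but is not the default, since conservation
comparisons are breed-level, not head-count-level.

Within-breed indices follow the same algebra: `fii` over ordered pairs of
distinct individuals, `dii` from $d_{ij} = (s_i+s_j)/2 - f_{ij}$, and
$G_i = d_{ii}/(d_{ii} + (1-s_i))$, read as the between-individual share of
the within-breed diversity $(1-s_i) + d_{ii}$. One subtlety we document
rather than hide: duplicating every individual does *not* leave `fii` and
`dii` unchanged at finite $n$, because a clone pair has $f = s$ exactly;
the replication closed forms are pinned in the tests.

## Allelic diversity and rarefaction

Allelic richness per breed and locus is the El Mousadik–Petit rarefied
expectation $\sum_a [1 - \binom{n-N_a}{g}/\binom{n}{g}]$. The automatic
rarefaction size is per locus the smallest per-breed called allele count,
floored at 2; loci uncallable in any breed at size $g$ are dropped from
all averages and counted. For the between-breed component `DA`, "presence"
of an allele under rarefaction is defined as an expected rarefied count
above 0.5 — a cutoff we chose because it reduces to plain observed
presence for balanced samples; the pooled rarefied richness is reported as
a diagnostic so users can compare conventions. `AT = AS + DA` holds by
construction.

## Conservation priority

`leave_one_out()` *is* its own oracle: it recomputes both partitions on
every reduced breed set (coancestry sub-blocks are reused, allelic
rarefaction is redone because the automatic $g$ can change). Percentages
are relative to the full-set value, which reproduces the loss(+)/gain(−)
reading of sequential-removal analyses.

`optimize_pool()` maximizes over integer compositions $c$ of a pool of
$N$ individuals (default 1000):

* **H**: expected heterozygosity of the pooled frequencies
  $\sum_b (c_b/N) p_{b,l}$, mean over loci of $2p(1-p)$, times the
  finite-pool factor $N/(N-1)$;
* **K**: expected number of distinct alleles per locus in a sample of $2N$
  allele draws from the pooled frequencies (the $2N$ gametes of $N$
  diploids).

Both objectives are concave in the proportions, so the search — simulated
annealing over single-individual transfers with geometric cooling and
restarts, followed by a deterministic steepest-ascent polish, with every
pure-breed and the uniform composition always evaluated — is exact on
two-breed instances (verified against exhaustive search up to $N = 200$)
and never returns less than any pure or uniform pool. A flat landscape
(e.g. identical breeds) is flagged and the uniform composition returned.

One modelling fact worth stating plainly: under Balding–Nichols, a breed's
divergence and its gene diversity are inversely coupled through the single
drift parameter $F_b$ (the within-breed block mean is
$J_{anc} + 2F_b\,\overline{pq}$ in expectation, and autozygosity does not
move breed frequencies at all). A simulated breed therefore cannot be both
the most divergent and the most heterozygous; the priority-recovery test
engineers the low-drift, high-diversity breed, which is the intra-breed
route to a top $\Delta H_T$ ranking. Real breeds, with independent
demographic histories, can realize both routes.

## ROH detection

Detection is a direct maximal-interval scan rather than a sliding-window
heuristic, so every constraint is exact and brute-force checkable:

1. split each chromosome where consecutive SNPs are more than `max_gap_bp`
   (1 Mb) apart;
2. enumerate all maximal intervals containing at most `max_het` (1)
   heterozygous and `max_missing` (2) missing calls (two-pointer scan);
3. select non-overlapping intervals greedily, longest first, ties to the
   leftmost start;
4. keep those with at least `min_snps` (100) SNPs, `min_length_bp` (1 Mb)
   and density `n_snps/(length/1000)` of at least 0.01 SNP/kb.

Coordinates are 1-based inclusive at SNP positions and
`length = end − start + 1`. An $O(n^2)$ subinterval enumerator in the test
suite reproduces the scan exactly on 200 random instances.

Monotonicity needs care. Raising `min_snps`, `min_length_bp` or the
density floor only strengthens step 4, so the result is always a subset.
Tightening the *allowances* (`max_het`, `max_missing`, `max_gap_bp`)
shrinks every candidate to a subinterval — which the tests assert — but
can split one long candidate into two that the greedy packing both keeps,
so segment count and even total covered length may grow; we found concrete
random instances of this and therefore do not claim segment-level
monotonicity for the allowance parameters.

`call_islands()` uses the strict rule: maximal runs of consecutive SNPs
whose ROH incidence (fraction of all individuals covered, by bp inclusion)
exceeds 0.30 strictly, within one chromosome, without gap merging. Runs
shorter than `min_island_snps` (default 50, configurable) are discarded
and counted; published chicken islands contain several hundred SNPs each,
so this floor only suppresses speckle. Incidence exactly at the threshold
is excluded. The per-breed summary reports `SROH`, `NROH` and
`MNROH ± SD` (sample SD), and the aggregation path reports the mean ROH
length under both conventions — the mean of per-breed `MNROH` and the
pooled total-length/total-count ratio — because published tables are
ambiguous between them.

## Annotation overlap

Islands (1-based inclusive) and BED-like annotation tables (0-based
half-open) are harmonized to 1-based closed intervals and intersected with
`GenomicRanges::findOverlaps()`; a record counts when the intersection is
at least `min_overlap_bp` (default 1 bp). Records on chromosomes outside
the genotype map's vocabulary are listed, excluded and warned about.
Trait classification is a user-supplied two-column mapping; unmapped
labels route to `"other"` with a warning, each distinct QTL record counts
once, and percentages are rounded to two decimals.

## LD decay and the Ne trajectory

Pairwise LD is the composite (Rogers–Huff style) genotype correlation:
squared Pearson correlation of dosage vectors over pairwise-complete
samples, computed without phasing. Monomorphic pairs have undefined $r^2$
and are excluded with a count — never treated as 0 in the decay curve,
though in LD *pruning* they are treated as unlinked (r² = 0) so they can
never be pruned or cause division by zero. Distances are binned at
500 (kb) below the 2000 breakpoint and 1100 above it; the unit of the
scheme is a config switch recorded in the output metadata.

The Ne trajectory inverts Sved's relation $E[r^2] = 1/(1+4N_ec)$ per bin:
$c$ comes from the bin midpoint via the 1 Mb = 3 cM chicken map scaling,
the sample-size offset $1/n$ is subtracted, bins with $r^2_{adj} \le
\varepsilon = 10^{-6}$ are skipped with a reason, and the bin is
attributed to generation $t = 1/(2c)$. This is a deliberately simple,
closed-form stand-in for genetic-algorithm Ne-history fitters: it produces
the same qualitative object (Ne per generation bin) and round-trips
exactly — $r^2$ generated from the formula at Ne 50, 500 or 5000 inverts
back to machine precision — but it has no confidence intervals and no
within-bin recombination modelling.

## The synthetic-data generator

`simulate_dataset()` emulates a multi-breed SNP-array panel: the default
configuration is eight breeds of 18–20 birds (157 total), 28 autosomes of
approximately chicken lengths (~1 Gb), 450,000 markers placed uniformly,
ancestral frequencies uniform on (0.05, 0.95), per-breed Balding–Nichols
divergence chosen so pairwise Nei distances span ~0.035–0.10, per-breed
autozygosity targets spanning 0.01–0.15 (a 15-fold ROH burden range), and
0.2% missing calls. Autozygosity is a two-state Markov mosaic along the
genetic map (3 cM/Mb): stationary probability `froh`, mean autozygous
tract length $100/(2g)$ cM with $g = 8$ generations, i.e. ~2.1 Mb tracts
with exponential lengths, matching pedigree expectations. Inside a tract
genotypes are homozygous with one allele drawn per locus; outside they are
Hardy–Weinberg draws. Identical configuration and seed give byte-identical
output.

What the generator recovers, with the calibration the tests verify:

* realized mean Nei distance between two breeds at common $F$ approaches
  $2F\,E[p(1-p)] \approx 0.365F$ (the Balding–Nichols expectation,
  evaluated on the generator's stored true frequencies — sample
  frequencies from 20 birds carry a known $+\,p(1-p)/2n$ inflation that
  belongs to the estimator, not the generator);
* detected ROH genome fraction tracks `froh` within ±0.05 at array-like
  density: detection loses sub-megabase tracts (~8% of autozygous mass at
  $g=8$) and splits tracts at clusters of >2 missing calls, and gains
  homozygous flank extensions.

What it does **not** emulate: inter-locus linkage disequilibrium. Breed
frequencies are drawn independently per locus and genotypes are
Hardy–Weinberg given the mosaic state, so within-breed $E[\hat r^2]$ is
the finite-sample floor $1/(n-1)$ regardless of drift (the autozygosity
mosaic changes variances, not cross-locus means, and therefore creates no
dosage covariance). Consequently, passing tests establish the LD/Ne
machinery against Sved-model-generated curves — including the monotone
ordering of inferred Ne across drift intensities — not against
genotype-level LD; real-data LD decay contrasts between breeds are outside
what this generator can certify. Likewise there is no genotyping-error
model, no batch structure in missingness, and no sex chromosomes.

## File-format conventions

PLINK text (PED/MAP) carries no allele metadata, so the alternate allele
is fixed deterministically as the lexicographically larger allele observed
at the marker; a marker showing a single allele therefore decodes as
dosage 2 for every called sample, and a dataset whose markers all show
both alleles round-trips exactly. The binary BED/BIM/FAM dialect stores
both allele names and round-trips every dataset bit-exactly (2-bit
SNP-major codes: `00` hom-A1, `10` het, `11` hom-A2, `01` missing). QC
stages run in a pinned order — duplicates, non-autosomes (integer codes
1–28), individual call rate ≥ 0.95, marker call rate ≥ 0.99, each
computed on the axis surviving the previous stage, thresholds inclusive —
because the retained counts depend on the order. LD pruning removes, per
50-SNP window advanced by 5, the lower-MAF member of the worst pair above
$r^2 = 0.2$ (ties: the later map position). Exported BED intervals are
0-based half-open; MAP/BIM coordinates 1-based.

## Problem sizes and runtime choices

The test suite and the acceptance script run on scaled panels chosen to
keep the whole validation in minutes on one core while leaving every
statistic in its asymptotic regime: partition identities on 50 random
12-sample datasets, ROH oracle equivalence on 200 instances of up to 200
SNPs, autozygosity recovery on 8 individuals × 100 Mb × 25,000 markers
(4 kb spacing, array-like), divergence recovery on 50,000 markers, and
optimizer exactness up to pool size 200 against exhaustive search. The
full-size default configuration (450k markers × 157 birds) runs through
the same code paths unchanged.

## Known limitations

* The pipeline is breed-label driven; there is no admixture or
  individual-assignment modelling, and a mislabelled individual simply
  contributes to its labelled breed.
* `Gi` is one reading of "proportion of diversity between individuals";
  the decomposition $(1-s_i) + d_{ii}$ is stated so users can derive
  alternatives.
* The Ne stand-in shares Sved's assumptions (equilibrium, no mutation,
  unstructured population) and inherits the usual caveat that adjacent
  bins are not independent estimates.
* Interval annotation reproduces overlap mechanics only; gene/QTL content
  depends entirely on the user-supplied table and its database snapshot.
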