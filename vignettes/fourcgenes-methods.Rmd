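---
title: "Methods: binary 4C-seq interaction calling and candidate-gene filtering"
author: "fourcgenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binary 4C-seq interaction calling and candidate-gene filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourcgenes)
```

# Scope and model

`fourcgenes` analyzes viewpoint-based 4C-seq experiments in which each
viewpoint is a GWAS tag-SNP region and the goal is to nominate the genes
its regulatory element contacts. The pipeline works on a deliberately
reduced representation of the data: every DpnII fragend of the viewpoint
chromosome is either covered by at least one uniquely mapped read or not.
This binary reduction trades dynamic range for robustness — PCR efficiency
differences between fragends inflate read counts multiplicatively, but they
cannot change covered into uncovered — and it makes the natural null model
a Bernoulli coverage process.

## Fragend library

The genome is digested in silico at every `GATC` occurrence on the forward
strand (the site is palindromic, so a reverse-strand search would be
redundant). Each site contributes an upstream and a downstream fragend. The
mapping key of a fragend is the 16 bases reading *away* from the cut on its
side of the site, excluding the site itself; for the upstream fragend that
read direction is the minus strand, so its 16-mer is stored
reverse-complemented. An alternative convention would include the `GATC`
itself in the mapped bases; either is internally consistent, and the choice
only has to match between library construction and read trimming, which it
does here by construction (the synthetic read emitter uses the library's
own 16-mers).

Two flags qualify a fragend:

* **mappable** — the flank holds 16 unambiguous bases. Sites within 16 bp
  of a chromosome end or of the adjacent site yield shorter fragends, which
  cannot be mapped by a 16-base read.
* **unique** — the 16-mer occurs at exactly one fragend genome-wide.
  Because mapping is exact, pre-computing uniqueness at the library level
  is equivalent to per-read multi-hit detection and much cheaper; reads
  whose 16-mer matches a non-unique fragend are discarded and counted as
  multi-hit.

Coverage profiles are defined over unique-mappable fragends, in coordinate
order, per chromosome. All coordinates in the package are 0-based
half-open; BED output conforms.

## Adaptive window statistic

Coverage decays with genomic distance from the viewpoint, and absolute
coverage differs between libraries, so a fixed window width would compare
poorly across viewpoints. The window size \(k\) (in fragends) is calibrated
per viewpoint so that an average window near the viewpoint holds 20 covered
fragends:

\[ k = \mathrm{round}\!\left(\frac{20}{r}\right),\qquad
   r = \frac{\text{covered fragends within} \pm 100\ \text{kbp}}
            {\text{total fragends within} \pm 100\ \text{kbp}} \]

with rounding half away from zero (the worked case, 100 covered of 150,
gives exactly \(k = 30\) under any rounding convention). Since \(r \le 1\),
\(k \ge 20\). A viewpoint with no covered fragend in its flank cannot be
calibrated and fails QC with an error.

Windows of \(k\) consecutive unique-mappable fragends slide one fragend at
a time — a running window in the literal sense — across the whole viewpoint
chromosome. Each window's covered count \(x\) is scored against the upper
binomial tail \(P(X \ge x)\), \(X \sim \mathrm{Binomial}(k, p_0)\), with
\(P = 1\) at \(x = 0\). Windows with \(p < 10^{-8}\) count as significant
4C signal; the stringent fixed cutoff takes the place of an explicit
multiple-testing correction (at \(10^4\) windows the family-wise false-call
expectation is \(\sim 10^{-4}\)). Overlapping or adjacent significant
windows (index gap \(\le k\)) merge into interaction segments; a segment
spans from the first fragend of its first window to the last fragend of its
last window and carries the minimum member-window p-value.

Numerical choices:

* **Background \(p_0\)** is the covered fraction over all unique-mappable
  fragends of the chromosome *excluding* the viewpoint ±100 kbp, where
  decay-dominated coverage would inflate the null. It is clamped to
  \([1/(n+2), (n+1)/(n+2)]\) (the add-one posterior-mean bounds) so the
  binomial tail is always defined, even for all-zero or all-one profiles.
  Fewer than 1000 eligible fragends trigger a warning, not an error.
* **Self-circle exclusion.** Windows lying wholly inside the viewpoint
  fragend ± 2 fragends are excluded from calling, to avoid scoring
  self-ligation signal in isolation. With the default \(k \ge 20\) this
  exclusion is almost always vacuous — deliberately minimal, because
  viewpoint-proximal contact signal is real signal. It is configurable and
  can be disabled (`self_circle = NA`).
* **Degenerate inputs.** A chromosome with fewer than \(k\) fragends yields
  no windows (warning); an empty read set yields an all-uncovered profile
  (warning); empty BED exports carry a comment header and round-trip to
  empty objects.

## Candidate-gene criteria

Per cell type, a gene is a candidate for a locus when all three hold:

1. **Chromatin interaction** — some TSS of the gene lies within 5 kbp
   (inclusive: exactly 5000 bp qualifies, 5001 does not) of a significant
   segment; distance is measured to the nearest covered base of the merged
   segment, 0 inside. Segment boundaries, not individual significant
   fragends, define the distance — the merged segment is the called object.
   Genes may carry multiple TSS records; any qualifying TSS qualifies the
   gene, which then carries the minimum p among its qualifying segments.
2. **Enhancer activity** — the tag SNP or any variant in LD with it
   overlaps an H3K27ac peak of that cell type (point-in-interval). LD
   arrives as a precomputed variant table; a SNP missing from it is
   assessed on the tag SNP alone, with a warning.
3. **Expression** — log₂(RPKM) strictly greater than −0.5; a value exactly
   at the cutoff fails. Genes absent from the expression table count as not
   expressed (warned). When raw counts are supplied,
   `rpkm()` = count / (length/1000) / (library/10⁶); a zero count maps to
   log₂ = −∞ and fails the filter.

Novelty is defined against a user-supplied known-gene list rather than by
re-deriving GWAS gene assignments. Candidate distance summaries use
|TSS − viewpoint position|. These filters are monotone: relaxing any cutoff
(larger distance, lower expression cutoff, larger p threshold) can only add
candidates — a property the test suite checks on simulated studies.

## Downstream statistics

* **TSS occupancy**: mean track signal over TSS ± 2 kbp, normalized by the
  covered width when the window is truncated at a chromosome edge; the
  detected-vs-other contrast uses group medians and a Wilcoxon rank-sum
  test (the upstream work shows this contrast graphically without naming a
  test; the rank-sum choice is ours).
* **CTCF bypass**: number of CTCF peak midpoints strictly between the
  viewpoint position and the TSS (exclusive endpoints, symmetric,
  additive under splitting).
* **eQTL concordance**: per SNP, its eQTL genes — restricted first to the
  annotation universe — are split into those among the SNP's 4C candidates
  and those among non-interacting genes within ±2 Mb of the viewpoint.
* **Gene-set concordance**: \(|A \cap B| / |A|\), used for replicate and
  Hi-C-style comparisons.
* **GSEA**: the classic weighted Kolmogorov–Smirnov running sum. Hits
  increment by \(|m|^w\) normalized over set members (\(w = 1\) by
  default), misses decrement by \(1/(N - N_{set})\); ES is the signed
  extremum, so \(|ES| \le 1\) and ES is invariant under positive rescaling
  of the metric.

**GSEA permutation scheme.** Ranked fold changes arrive pre-computed, so no
per-sample phenotype labels exist at this stage; the null is therefore
built by *gene-set* permutation — `n_perm` random same-size sets drawn
without replacement from the ranked genes — rather than phenotype
permutation. Significance is assessed against the same-signed portion of
the null: for positive ES, \(p = (1 + \#\{ES_{null}^{+} \ge ES\}) /
(1 + \#ES_{null}^{+})\), mirrored for negative ES. We chose this
sign-conditional convention (standard for the signed running-sum statistic)
because comparing each tail against the full null would double the
realized type-I error; as implemented, a random gene set rejects at the
nominal rate, which the acceptance suite verifies by simulation. One
consequence: the smallest attainable p is \(1/(\#\text{same-signed nulls}
+ 1)\), not \(1/(n_{perm}+1)\). NES is ES divided by the mean magnitude of
the same-signed null scores.

# The synthetic-data generator

The generator produces every input the pipeline consumes, with known ground
truth. Its defaults encode the emulated study design: **92 viewpoints × 3
cell types** (monocytes, lymphocytes, DLD-1 intestinal epithelial cells),
per-cell-type enhancer-active locus fractions of **68/92, 73/92, 52/92**,
and a DpnII site density of 4/kbp (random sequence carries one GATC per
256 bp in expectation).

* **Genome**: site positions are drawn first (Poisson count, uniform
  placement, ≥ 4 bp apart), the background is sampled GATC-free (accidental
  sites are removed by flipping their `A`, which provably cannot create a
  new site), then `GATC` is injected at the chosen positions. The site
  count is therefore controllable and the residual background rate is
  exactly zero — with `gatc_density = 0` the sequence contains no site at
  all.
* **Coverage**: each unique-mappable fragend is one Bernoulli draw with
  probability \(\max(\text{background},\ 2^{-d/h},\ \text{planted})\) —
  background 0.05 by default, \(d\) the distance to the viewpoint, \(h\)
  the decay halflife, and the planted probability (0.8 by default) applying
  inside planted contact intervals. The max, rather than a sum, keeps each
  fragend a single draw with a well-defined per-stratum probability that
  the tests can check against empirical fractions.
* **Decay halflife** (default 20 kbp) is a modeling choice, not an
  empirical value: the emulated study does not report its coverage-decay
  profile. It was chosen once so that the ±100 kbp calibration flank spans
  the transition from near-certain proximal coverage to background, giving
  realistic window sizes (k of order 50–80 at the default background).
* **Determinism**: one master seed fans out arithmetically into
  per-chromosome, per-viewpoint and per-cell-type substreams, so adding a
  viewpoint or cell type never perturbs the data of existing ones, and
  identical configurations regenerate byte-identical studies.
* **Annotations**: true target genes get a TSS inside each planted contact;
  decoy TSS are kept ≥ 50 kbp away from every *expected-signal region* —
  planted contacts plus each viewpoint's decay zone (out to
  \(h \log_2(1/\text{background})\), where the decay meets background).
  Expression values span the −0.5 boundary from both sides; eQTL tables
  are drawn from true targets; the ranked DE table elevates true targets
  by a configurable effect; a configurable fraction of targets is
  "already known" for novelty flagging.

## What the generator does and does not emulate

It reproduces the *structure* the caller relies on: binary coverage, decay
around the viewpoint, sparse background, contiguous planted contacts, and
annotation tables consistent with a planted truth. It does **not** model
PCR duplication, ligation bias, read quality, trans-chromosomal contacts,
non-uniform restriction-site spacing beyond Poisson placement, or realistic
LD structure. Passing tests therefore demonstrate the correctness of the
algorithms under the stated coverage model — not the sensitivity of the
method on real sequencing data, where background is structured and decay is
heavier-tailed.

A consequence of honest emulation: the viewpoint-proximal decay zone *is*
genuine 4C signal, and the caller rightly reports segments there. Recovery
tests therefore score planted contacts for sensitivity, and accept segments
inside planted contacts *or* the viewpoint zone (each ± one window span)
for specificity; a segment anywhere else counts as a false call.

# Problem sizes and verification

The test and acceptance suites run at desk scale, chosen as the package's
own verification design: chromosomes of 0.3–2 Mbp (4 sites/kbp, so roughly
2–16 k fragends per chromosome), the full 92 × 3 study on eight 2-Mbp
chromosomes (276 datasets), planted-recovery sweeps over 20 independent
coverage seeds, false-call control over 100 null chromosomes of 10⁴
fragends, and GSEA calibration over 500 replicates of 199 permutations on
200-gene lists (1000 permutations for planted-set checks, matching the
default). The binomial tail is verified against exhaustive summation for
every \(x\), \(k \le 25\), \(p_0 \in \{0.01, 0.1, 0.5, 0.9\}\) at relative
error below \(10^{-10}\), and the enrichment score against an independent
dense running-sum computation and `fgsea::calcGseaStat`.

# Known limitations

* Cis-only: interactions are called on the viewpoint chromosome;
  trans-chromosomal contacts are out of scope.
* Binary coverage discards quantitative contact strength and, as with any
  such reduction, can overestimate distal relative to proximal interaction
  strength.
* Exact 16-mer matching does not tolerate sequencing errors; the mapped
  fraction on real error-prone reads would be lower than on synthetic
  reads.
* The binomial null assumes exchangeable background fragends; real 4C
  background varies with chromatin environment, and a structured background
  would require a position-dependent null (e.g. monotone-regression
  backgrounds), which this package intentionally does not implement.
* Whether the emulated study excluded a viewpoint-proximal zone from
  calling is unknown; the minimal self-circle default here is our choice,
  documented rather than inferred.
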