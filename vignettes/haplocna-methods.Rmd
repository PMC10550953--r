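---
title: "Haplotype-specific SCNA evolution: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-specific SCNA evolution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplocna)
```

This vignette explains the models behind `haplocna`: what the simulator
generates and why, what each analysis stage assumes, which parameters
matter, and where the methods' limits are.

## The measurement model

A bulk sample is a mixture of a tumor clone (fraction *p*, "purity") and
diploid normal cells. For a genomic position with allelic copy numbers
(c_A, c_B) in the clone, the expected normalized coverage of homolog A is

    a_A = (p * c_A + (1 - p)) / D,     D = p * psi + 2 * (1 - p),

where psi is the clone's average total copy number ("ploidy"). The
denominator D is fixed by the centering convention: normalized total
coverage averages 1 over the genome, so the implied average total copy
number always equals psi. Purity and ploidy are therefore estimated by a
grid search (p in [0.05, 1] by 0.01; psi in [1.2, 6] by 0.05) over the
length-weighted distance of implied allelic copy numbers to non-negative
integers, computed on segments of at least 2 Mb.

Two exact degeneracies limit what coverage ratios alone can determine:

* **halving/doubling** — if every allelic copy number is even, dividing
  all states by two (with a matching purity) fits equally well;
* **one-copy shift** — if no homolog is ever at zero copies, subtracting
  one copy from every homolog (again with a matching purity) also maps
  integers to integers.

Odd-copy states break the first alias; a stretch of LOH (one homolog at
zero) breaks the second. The automatic pick among near-optimal candidates
(objective within 0.005 of the best) is the one with the fewest subclonal
states, ties resolved toward lower ploidy; the full ranked candidate list
is returned for inspection. Samples without allelic imbalance are reported
`indeterminate` rather than forced — such samples cannot anchor a
purity/ploidy solution. The recovery study (`study_purity_ploidy()`)
consequently admits only clones with at least 10 Mb of odd-copy states in
segments of 5 Mb or more and at least 5 Mb of LOH; clones without these
anchors are genuinely ratio-degenerate, the regime that in practice is
resolved with orthogonal information (mutation allele fractions,
histology), which is out of scope here.

## What the simulator emulates — and what it does not

`simulate_genome()` builds a 4-chromosome genome (150/120/90/60 Mb,
centromere at 40% of each chromosome) with het sites as a Poisson process
at 1/3 kb; this keeps whole-pipeline simulations in seconds while
preserving the scale separation that matters (bins 25 kb, het spacing 3
kb, switch errors 250 kb, segments megabases). GC content varies at the
tens-of-kb scale (isochore-like moving-average noise, sd ~0.04), far below
segment scale, so per-sample GC correction cannot absorb copy-number
signal; the recurrent FFPE coverage bias is a smooth low-frequency field
shared by all samples of a patient, which is exactly what reference-panel
normalization removes. Depth is negative-binomial (size 60 by default, a
FFPE-like variance inflation); allelic depths are beta-binomial (rho =
0.01); statistical phasing is emulated by flipping the reported phase at
Poisson switch points (rate 1/250 kb). The rendered mean coverage is
unbiased for the purity-weighted copy-number expectation (verified to 2%
over 200 replicates in the test suite).

Not modeled: read-level artifacts (mappability, alignment), replication
timing, sequence-resolved rearrangement junctions, and real haplotype
reference panels. Passing tests therefore demonstrate correctness of the
algorithms under calibrated noise, not robustness to every artifact of
FFPE libraries.

Event rates in `simulate_clone_tree()` are order-of-magnitude choices
(Poisson 2 events per branch; WGD probability 0.2 per post-TP53-loss
branch, so that roughly half of small trees' post-loss lineages carry a
WGD, echoing the prevalence reported in patient cohorts). TP53 gating
restricts pre-loss branches to copy-neutral or focal events; both the
gating and the rates are configuration, not biology claims.

## Switch-error correction

Within regions where enough samples show windowed allelic imbalance
(50 kb windows, minimum total allele count 50, |imbalance| >= 0.15 in at
least 2 samples — or 1 when the cohort has a single sample, since
cross-sample consensus is then impossible), per-site phased depth
differences are aggregated across samples after aligning each sample's
imbalance direction by its sign correlation with the strongest sample.
The aggregated signal is segmented by penalized changepoints and each
segment keeps or flips its orientation by majority vote toward the
region's dominant sign; sites whose aggregated evidence is individually
confident (|sum of depth differences| >= 10 reads) follow their own sign,
which places flip boundaries at het-site resolution. Correction never
touches depths, only orientations, and is idempotent. Ties in the majority
vote keep the statistical-phasing orientation. The residual switch rate
inside imbalanced regions drops more than 10-fold from the simulated
1/250 kb input (about 30-40x in the studies here); outside imbalanced
regions the phase is — by construction — uncorrectable and left as is.
One caveat: when switch errors cover more than half of a small imbalanced
region, the dominant orientation itself can be the flipped one; copy
numbers are unaffected, but the homolog labels of that region may be
swapped relative to the rest of the chromosome.

In single cells the same machinery runs in two passes
(`two_pass_correct_cells()`): pass 1 aggregates all cells; cells that then
show a run of at least 10 Mb with |imbalance| > 0.25 are called aneuploid,
and only those (with their cleaner, integer-state imbalance) drive pass 2.
With no aneuploid cell the pass-1 result is returned with a warning.

## Segmentation and calling parameters

Joint penalized least-squares changepoints on the two homolog tracks;
the penalty is `penalty_factor * 2 * d * log(n)` on difference-based
noise-normalized signals, with `penalty_factor = 1.8` — a deliberately
conservative setting against over-segmentation of noisy coverage (1.0
reproduces a BIC-like criterion). Minimum segment length 2 bins;
haplotype fractions are smoothed over +-2 bins (125 kb), well under
segment scale; bins without informative het sites inherit the nearest
informative fraction and are flagged. Integer calls flag residuals above
0.3 copies as subclonal (the threshold that separates clonal integer
states from mixtures in the burden summaries; configurable).

## Classification rules and tie-breaks

The per-homolog baseline is the length-weighted modal copy number across
the genome (ties to the lower state) — with four or more chromosomes this
is robust even to whole-chromosome events. Decision order: oscillation
(chromothripsis) first, then amplification, then per-run classification
(whole-chromosome / arm within 1 Mb of centromere or telomere / UPD /
terminal / focal under 5 Mb / paracentric / pericentric). Two thresholds
are declared choices where no quantitative rule exists in the literature:
the oscillation threshold (>= 8 alternating switches between two states)
and the focal-size boundary (5 Mb). Oscillation chains are bounded by a
maximum fragment length of 10 Mb so that adjacent large SCNAs remain
separate events — without the bound, a terminal loss flanking a shattered
region is swallowed into the oscillation. Chromothripsis footprints
(`direct-bridge` when the oscillation abuts a large SCNA boundary within
1 Mb, `downstream-micronucleus` when it spans an arm or reaches a
telomere/centromere, `regional` otherwise) are best-effort annotations:
the underlying mechanisms are not strictly distinguishable from copy
number alone.

Sloping copy number — the population-level signature of progressive
subclonal terminal erosion — is detected on purity-corrected allelic
copy number by scanning sub-spans anchored at each arm end (erosion always
runs into a telomere or centromere): a call needs a robust monotone trend
(Spearman |rho| >= 0.4 and an MASS::rlm fit) with attenuation >= 0.3
copies over >= 5 Mb, a flat other homolog (attenuation <= 0.2 copies,
the internal control), and a better linear than single-step fit (which
rejects clonal terminal losses). Calibration: sensitivity 1.0 at 0.5
copies over 10 Mb at purity 0.5 and 20x, with 0 false calls in 100 flat
genomes in the bundled studies.

## Phylogeny, WGD and timing

Breakpoints are matched at 0.1 Mb tolerance (segmentation inaccuracy),
direction-aware: same-direction matches are identical, opposite-direction
matches complementary (reciprocal daughters of one bridge break — evidence
of branching, not sharing). Characters (clusters of pairwise-shared
events) are accepted greedily by support into a laminar family; a
character conflicting with the accepted set is dropped and reported, never
silently — the deterministic replacement for manual review. Branch length
is the number of altered chromosomes. WGD placement: each maximal clade
whose samples are all WGD goes on one stem branch; the germline root never
carries WGD, so an all-WGD cohort without a truncal character receives
independent placements per top-level clade, logged. Timing uses the copy
difference across changepoints (>= 2 pre-duplication, 1 post) and, for
whole-chromosome states, the final-copy-number rules (1 -> duplicated then
lost; odd >= 3 -> duplicated to nearest even then +-1; even != 2 ->
altered before duplication). A known erasure caveat is inherited from the
marker model itself: whole-chromosome or arm-level deletions can remove
ancestral breakpoints, which surfaces as logged conflicts rather than
wrong trees.

## Problem sizes in the bundled studies

The validation studies run at the sizes reported by
`scripts/acceptance.R`: 500 single-event chromosomes for the classifier;
20 simulated samples (4-chromosome genome, 25 kb bins, ~3000 reads per
neutral bin, i.e. about 20x) for purity/ploidy; 20 three-sample patients
for switch correction; 20 patients of 4-8 samples for phylogeny; 30
positive and 100 flat renders for sloping; 1000 random events for the
conservation audit. These sizes put the whole suite within a few minutes
on one CPU; all of them scale linearly if larger studies are wanted.

## Known limitations

* Homolog orientation within an imbalanced region is only defined up to
  the dominant phase of that region (see above).
* A uniformly balanced duplicated genome — (2,2) everywhere — is
  indistinguishable from (1,1) by coverage ratios; the single-cell
  half-integer rule and the tetraploid criterion (an arm with median
  allelic CN in [0.2, 0.8] and allelic-coverage SD < 0.25) only fire when
  at least one chromosome deviates.
* Purity/ploidy estimation needs odd-copy and LOH anchors; without them
  the ranked candidate list, not the automatic pick, is the honest output.
* The sloping detector reports at most one call per arm (the strongest);
  co-occurring telomeric and centromeric slopes on one arm are not
  separated.
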