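---
title: "Mapping type-IIA topoisomerase cleavage sites from strand-specific fragment ends"
author: "toposeqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping type-IIA topoisomerase cleavage sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toposeqr)
```

## The measurement model

Type-IIA topoisomerases (DNA gyrase, topoisomerase IV) cut both strands of
their "gate" DNA duplex with a 4-nt stagger, leaving 4-nt 5'-overhangs whose
5' ends are covalently bound to the enzyme's catalytic tyrosines.
Fluoroquinolone poisons (ciprofloxacin, norfloxacin) freeze this covalent
cleavage complex. Affinity purification of a tagged enzyme subunit followed
by strand-specific sequencing of the attached DNA recovers fragments whose
ends trace the cut with single-nucleotide precision.

`toposeqr` works in the coordinate system of the top strand, 0-based and
half-open. Writing `c` for the first base of the overhang, one trapped
complex defines:

* a top-strand scissile bond between `c - 1` and `c`, and
* a bottom-strand bond between `c + 3` and `c + 4`,

that is, a wall offset (`stagger`) of 5 coordinates between the two
strand-specific cut marks. Counting sequenced fragments' 3'-ends per
position and strand (the N3E track; N5E for 5'-ends) turns each site into a
bimodal signature: a forward-strand N3E spike at `c - 1`, a reverse-strand
N3E spike at `c + 4` (in top-strand coordinates the reverse-strand 3'-end
is the *leftmost* fragment coordinate — forced by the staggered-cut
geometry), and exactly `stagger - 1 = 4` interior positions between the
walls. The free-3'-OH fragments leave that interior uncovered; fragments on
the covalent 5' side would cover it, which is why their capture efficiency
is a separate simulator parameter (below).

Three derived patterns matter downstream:

* **Canonical site** — walls in the order forward < reverse, interior gap
  4 bp, inclusive wall-to-wall span 6 bp. Because "separated by" is
  ambiguous between these readings, `wall_geometry()` reports all three
  (coordinate difference 5, interior gap 4, inclusive span 6) rather than
  collapsing them into one number.
* **Composite site** — the superposition of two independent *single-strand*
  cleavage events with inverted strand roles (the pattern seen at
  dif-like loci): forward-strand 3'-ends pile up at a position `f`,
  reverse-strand 3'-ends at `f - stagger`, and instead of a gap the two
  fragment populations co-cover `stagger + 1 = 6` positions between the
  walls.
* **Repair-extension counterfactual** — if repair polymerases filled in the
  3' ends across the overhang of a *canonical* cut, the walls would shift
  inward: overlap `stagger - 1 = 4` bp and signal separation `stagger - 3 =
  2` bp (`predict_repair_extension()`). A genuine composite locus (overlap
  6) is therefore distinguishable from a repair-extended canonical one
  (overlap 4).

## The simulator and what it does (not) emulate

`simulate_sample()` emits, per sample:

* **Background**: `background_fragments` uniform intervals with lengths
  uniform in `[fragment_length_min, fragment_length_max]` (default 200–800
  bp, the sonication range), on both strands, in every condition.
* **Site fragments** (+drug conditions only): per site, a Poisson number of
  trapping events with the site's strength as mean. Each event can emit
  four fragments — free-3'-OH side forward `[s, c)` and reverse
  `[c + 4, s')` with probability `capture_efficiency_3p`, covalent-5' side
  forward `[c, s'')` and reverse `[s''', c + 4)` with probability
  `capture_efficiency_5p`. Fragment lengths are uniform sonication draws;
  the wall-side coordinate is exact, so wall-side truncation is the only
  way a fragment can be shorter than the sonication minimum.
* **Mock (−IP) samples** keep site fragments at `mock_dilution = 1/20` of
  the +IP rate — mock libraries are total lysate DNA, enriched rather than
  devoid of signal. −drug samples carry none.

Defaults are fixed once as the emulated study conditions: triplicates, a
±drug × ±IP design, 200–800 bp fragments, stagger 5. Two parameters are not
dictated by the emulated protocol and are set by this package's own
judgment:

* `capture_efficiency_5p = 0.5`: the 5'-phosphotyrosine adduct plausibly
  impairs library entry of covalent-side fragments; since the caller uses
  N3E only, this parameter affects N5E/coverage realism, not calling.
  `capture_efficiency_3p = 0.8` reflects efficient but imperfect recovery
  of the annealed free-3'-OH fragments.
* Site strengths are log-normal with `meanlog = log(100)`, `sdlog = 0.5`:
  strong drug-trapped sites in deep libraries show wall spikes of order
  10^2 fragment ends, and with the caller's default stringency
  (`alpha = 1e-5`) a wall needs roughly 20+ counts to reach significance,
  so ~100-event sites represent confidently detectable cleavage sites with
  a realistic spread down to marginal ones.

Site centers are placed by drawing order statistics in the "slack" space
and re-inflating by the minimum separation, which guarantees non-overlap
(including across the origin on circular genomes) for any feasible density;
the marginal center distribution is exchangeable but not exactly uniform —
irrelevant for geometry and calling tests, worth knowing for density
statistics at extreme packing.

Not emulated: sequencing errors, base qualities, adapter artifacts, PCR
duplicates, mappability, replication-associated copy-number gradients, or
any sequence preference of sonication. Passing tests on this generator
demonstrate that the *computational* pipeline recovers what the cleavage
model puts in; they do not validate the wet-lab assumptions themselves.

## Calling sites

`call_strand_spikes()` compares treatment vs control N3E counts
per position and strand with the one-sided Audic–Claverie test,

\[
p(x \mid y) = \sum_{k \ge x} \left(\frac{N_1}{N_2}\right)^{k}
\frac{(y+k)!}{y!\,k!\,(1 + N_1/N_2)^{y+k+1}},
\]

where `x`, `y` are the counts at the position and `N1`, `N2` the library
totals (total N3E counts of each sample — the compared statistic is scaled
in its own units). The tail is evaluated through its negative-binomial
closed form and is pinned in the test suite against an independent
brute-force series summation to 1e-10 relative error. Both a significance
threshold (`alpha`, default 1e-5) and a minimal wall height (`min_height`,
default 5 counts) are exposed, since protocols of this family threshold on
either; the defaults apply both.

Significant spikes are paired by `pair_spikes()`: a forward spike at `f`
and reverse spike at `r` with `r - f = stagger` (± `jitter`, default 0 —
strict single-nucleotide geometry; 2 bp is a reasonable setting for noisy
data) form a canonical site with center `f + 1`; the inverted order forms a
composite site with center `r`. Pairing is greedy by descending summed
height with leftmost-center tie-breaks, each spike used once; unpaired
significant spikes go to an orphan table rather than being promoted to
sites. A site's score is the mean of its two walls' fold enrichments
`(x + pseudocount) / (scale \cdot y + pseudocount)` (pseudocount 1 count,
which keeps ratios finite at zero-coverage positions).

`reconcile_replicates()` keeps sites supported by `min_support` replicates
within `tolerance` (default 0 bp — single-nucleotide reproducibility;
200 bp is the sensible setting when comparing against region-scale
methods), taking the highest-score supporting replicate's coordinate as
consensus. `classify_primary_satellite()` marks, within each
transitive-closure cluster of nearby sites, the top-scoring site as primary
and the rest as satellites. Ties anywhere resolve to the leftmost
coordinate, making every step deterministic.

## Motif analysis

Windows around oriented centers use a frame with no position 0: position
+1 is the base at `c`, so a halfwidth-`W` matrix spans `-W..-1, +1..+(W+4)`
and the dyad axis of the staggered cut falls between +2 and +3 — position
`i` pairs with `j = 4 - i`. The published logo of this enzyme family spans
roughly −13..+17, hence the default `halfwidth = 13`; it is configurable.
`build_pfm()` weights windows by site score by default (stronger sites
contribute proportionally; an unweighted mode is available since published
logos do not always state their weighting), computes per-column information
content `2 + \sum_b f_b \log_2 f_b` (uniform background) and GC content.
`dyad_check()` calls a position's modal base only when its frequency
reaches 0.3 — barely above the 0.25 background, because this motif family
is weak — and flags dyad pairs whose modal bases are Watson–Crick
complements. `gc_profile()` extends the per-column GC view to ±2 kb and
attaches an autocorrelation scan of the mean-subtracted profile: a
DNA-wrapping enzyme leaves ~10-bp periodic flanks, and the scan reports
(rather than thresholds) any such periodicity.

## Genome statistics

`region_enrichment()` tests observed site counts in a region against the
uniform expectation `n \cdot \text{len}/L` with an exact binomial test,
two-sided by doubling the smaller tail (capped at 1) — sidedness is a
package decision since protocols often leave it unstated; the direction is
reported separately. Regions may wrap the origin. `bin_density()` counts
centers in fixed half-open bins (partial last bin kept, so bins always sum
to the site count). `compare_region_means()` runs a Welch two-tailed t-test
on per-site scores in two region groups (per-site scores, not per-position
FE — the site is the experimental unit, and per-position values are
strongly autocorrelated). `metagene()` orients each transcription unit
5'→3', keeps flanks at native resolution, length-normalizes bodies into
bins, and averages mean-of-means so long TUs do not dominate; strata are
expression deciles (HETU/LETU) with a minimum stratum size, and TUs
shorter than 2 bp per body bin are skipped with a message.
`downstream_correlation()` reduces each track to per-TU means over the
strand-aware downstream window before correlating, so the TU — not the
base pair — is again the unit of correlation.

## Numerical and reproducibility choices

* Coordinates are 0-based half-open internally; BED/bedGraph outputs stay
  0-based, WIG and SAM are 1-based, and the writer/reader pairs round-trip
  exactly.
* One global seed drives everything: per-sample and per-stage seeds derive
  from it via a documented hash (`derive_seed()`), so each stage is
  independently reproducible and two runs with the same config produce
  byte-identical outputs (the pipeline manifest records MD5 checksums).
* Degenerate inputs fail loudly: zero-length genomes, even smoothing
  windows, empty site sets for motif/enrichment work, zero-variance
  t-test inputs, and malformed SAM records (reported with line numbers)
  are errors, not NaNs.
* Problem sizes in the test suite are chosen to exercise the asymptotics
  that matter while staying desk-sized: geometry and calling on 20-kb
  genomes, null calibration on 50-kb × 2 × 10^5-fragment mocks, and the
  flagship recovery experiment — 500 sites planted on a 1-Mb genome at the
  default strength distribution and background density, simulated in
  triplicate — where ≥95% of planted centers must be recovered at exactly
  0 bp error by the 2-of-3 replicate consensus.

## Known limitations

* The Audic–Claverie test conditions on the control count; with shallow
  control libraries a single coincidental control end at a wall noticeably
  weakens the call. Calibration is verified on mock-vs-mock splits, but
  power at fixed `alpha` depends on the treatment/control library ratio
  because the test penalizes globally enriched treatment libraries.
* Composite detection is exactly inverted-order pairing; loci that are
  partially composite (one strand canonical, one shifted) surface as
  orphan spikes instead.
* Replicate reconciliation with `tolerance > 0` uses chain clustering,
  which can merge a dense run of distinct sites; at the default tolerance
  of 0 this cannot happen.
* Enrichment statistics assume sites are exchangeable across the genome;
  on real chromosomes, replication-associated coverage gradients violate
  this and would need a position-dependent expectation.
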