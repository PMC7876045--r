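---
title: "Calling and characterizing sigma70-dependent promoter-proximal pauses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterizing sigma70-dependent promoter-proximal pauses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigmapause)
```

## The biological problem

In *E. coli*, the housekeeping initiation factor sigma70 can remain
bound to RNA polymerase after transcription initiation. When it does,
the enzyme pauses 10–20 bp downstream of many promoters, frequently
backtracking, until the transcript-cleavage factors GreA/GreB rescue
it. RNET-seq — NET-seq combined with RNase I footprinting of the
nascent transcript — reports, for each transcription-engaged
polymerase, both the genomic position of the nascent RNA 3' end (the
active-site register) and the length of the RNase-protected fragment
(the translocation state). `sigmapause` implements the downstream
analysis of such data: pause calling, TSS-relative classification,
promoter-element annotation, footprint-state summaries, cross-strain
comparison, and a simulator that provides planted ground truth.

## The pause score and the calling rule

For a strand-specific track of read-3'-end counts \(c_p\), the pause
score at position \(p\) is

\[ S_p = \frac{c_p}{\mathrm{median}(c_{p-25}, \ldots, c_{p+25})} \]

and a position is called a pause site when \(S_p \ge 20\) **and**
\(c_p \cdot 10^6 / N \ge 10\) (N the library-wide read total over both
strands). The 51-nt window is centered at the position and includes
it; including the center makes the score slightly conservative, and an
`exclude_center` flag preserves the alternative reading (the two differ
negligibly at 20-fold enrichment). Tunables and defaults:

* `min_fold = 20`, `min_cpm = 10` — the published dual threshold.
* `window = 51` nt, odd; at contig edges the window is truncated to
  the available positions rather than discarding the position. A
  `circular` flag applies wrap-around windows for circular
  chromosomes; linear truncation is the default because it composes
  with multi-contig references.
* `median_floor = 1` read — the divisor is
  \(\max(\mathrm{median}, 1)\). Deep libraries make this moot (the
  median under a real peak is far above 0), but sparse synthetic or
  subsampled tracks would otherwise divide by zero. The floor is a
  flag, not a constant.

Masked intervals (rRNA, tRNA, repeats — sources of false-positive
spikes from multi-mapping artifacts) are excluded strandlessly: a
repetitive locus contaminates the statistics of both strands.
Adjacent qualifying positions are reported individually; the analysis
treats single 3'-end coordinates as pause sites, not merged peaks.

The interior of each track uses `stats::runmed` (an exact running
median); edge positions are computed directly on the truncated
windows. The test suite keeps an independent naive
sort-and-pick-middle oracle and checks equality at every position of a
\(10^5\)-nt random track.

## TSS-relative classification

Distances are signed along the TSS strand, with \(d = 0\) meaning the
pause 3' end sits on the TSS base. Groups are inclusive integer
windows: G0 \([-2, 3]\), G1p \([10, 15]\), G1d \([16, 20]\), G2
\([31, 39]\); distances in the gaps are reported as `other` rather
than force-assigned. Under this convention the nascent RNA of a pause
whose 5' end is at the TSS has length \(d + 1\); whether the published
distances equal RNA length or length − 1 is not fully determined by
the source material, so the package fixes one convention everywhere
instead of guessing per figure.

A pause equidistant from two same-strand TSSs is assigned to the
upstream one (the one for which the pause is downstream): pauses are
products of transcription initiated upstream. When several pauses map
to one TSS, `strongest_per_tss()` keeps the maximal-score one (ties:
smaller |distance|, then smaller coordinate) so that promoter-level
statistics are not dominated by multi-pause promoters.

Feature categories use the precedence rRNA > tRNA > ncRNA > CDS > UTR
on the same strand (the source material states no precedence; ours
puts structural RNAs first because they motivate the exclusion mask),
then Antisense for opposite-strand-only overlap, else intergenic. UTRs
are taken from explicit `five_prime_UTR` records when the GFF3 has
them, and otherwise derived as TSS-to-CDS-start spans within 300 nt —
a pragmatic bound covering bacterial 5' UTRs.

`region_matrix()` reproduces the TSS-anchored heatmap normalization:
each −50..+200 region is scaled by its own maximum to \([0, 1]\)
(sense) and \([0, -1]\) (antisense), and duplicate regions (several
pauses sharing one TSS) are counted once.

## The −10 element information model

The sigma70 −10 hexamer is scored by individual information: from an
aligned training set, \(f(b, l)\) are per-position base frequencies
(pseudocount 0.25 per base by default) and

\[ w(b, l) = 2 + \log_2 f(b, l), \qquad
   R_i(s) = \sum_l w(s_l, l). \]

\(R_\mathrm{sequence} = \sum_l \sum_b f\,w\) is the training-set mean
information; at pseudocount 0 the mean \(R_i\) over the training set
equals \(R_\mathrm{sequence}\) exactly (an algebraic identity the
acceptance suite verifies to \(10^{-6}\)), and 0 bits is the
conventional threshold for a recognizable site. The small-sample
correction used with very small alignments is omitted: training sets
here are either large or synthetic, and omitting it keeps the
identities exact. Only the −10 hexamer is modeled; −35 and extended
−10 scoring are out of scope.

Element annotation per TSS:

* **−10R**: the maximal-\(R_i\) hexamer among placements with spacer
  (bases strictly between hexamer and TSS) in 3–9 nt. The range
  brackets the observed 6–8-nt spacers with margin. Ties prefer
  spacer 6, then 7 (the spacers characteristic of strong pause-prone
  promoters), then spacers outward from 6.
* **tssR**: the triplet at TSS−1..TSS+1; `is_yry` tests
  pyrimidine/purine/pyrimidine (`[CT][AG][CT]`).
* **−10LR**: the maximal-\(R_i\) hexamer whose *second* base sits at
  TSS offsets −1..+2. The second-base anchor follows the stated
  convention of the source analysis; an `anchor = "start"` switch
  preserves the alternative reading. The \(R_i\) is reported even when
  ≤ 0, with a `weak` flag.

## Footprint lengths and translocation states

Protected-fragment lengths map to translocation registers: 16–17 nt
post-translocated, 18 nt pre-translocated, >18 nt backtracked; <16-nt
reads arise so close to the promoter that the nuclease cannot resolve
the state and are binned as indeterminate, never backtrack-classified.
The bin edges are arguments (`post`, `pre`), not constants, so the
in vitro RNase T1 14-nt bound can be explored.

## Comparison utilities

`overlap_sets()` counts shared pauses with exact coordinate matching
by default (tolerance 0; each B pause matches at most one A pause,
greedy nearest in position order) — whether the published sharing used
a window is unstated, so exact matching is the default and a ±2 nt
tolerance is available. `pause_strength()` implements
\(I_\mathrm{paused} / (I_\mathrm{paused} + I_\mathrm{runoff})\), with
relative strength against a reference condition set to 1.
`group_summary()` reports boxplot statistics (median, mean, quartiles,
1.5×IQR whiskers) and two-sided Mann-Whitney U tests (exact for
n ≤ 10 without ties, normal approximation with tie correction
otherwise).

## What the simulator states, and what a green test establishes

The generator's defaults are the stated world of the analysis:
Poisson background at \(\lambda = 2\) 3' ends per transcribed position
(0.05 intergenic), 250-nt transcribed spans, planted spikes of fold 30
over \(\lambda\) (spike count is the deterministic
\(\mathrm{round}(30 \times 2) = 60\) so threshold behavior is exact),
50 G1p and 50 G1d promoters on a 120-kb genome (spacing > 1 kb,
comfortably beyond the ±300-nt non-overlap requirement), consensus
TATAAT −10 at spacer 6, YRY start-site triplets at G1p promoters, and
for G1d promoters a −10-like hexamer starting 11 nt downstream of the
−10 start — one helical turn, which places its second base at the TSS.
G1p pause reads are capped at offset + 1 (their 5' ends cannot precede
the TSS); G1d pause reads keep their drawn 16–20-nt mixture with the
configured >18-nt backtracked mass. The cap is *not* applied to G1d
reads: at 16–17-nt offsets it would contradict the configured mixture,
and the module contract treats the mixture as authoritative — the
geometric violation is at most 4 nt and does not affect any 3'-end
statistic.

The background is Poisson, not negative-binomial: real NET-seq
libraries are overdispersed, but the overdispersion-free null keeps
the oracle math closed-form, and overdispersion would only make the
planted-recovery criteria harder in ways the stated world does not
model. Consequently a green recovery test establishes that the caller
implements its definition correctly and recovers truth under the
stated noise model — not that the thresholds are optimal for real,
overdispersed, biased libraries. Likewise the simulated genome has
i.i.d. background composition; real promoter regions are AT-rich, so
real −10 scans face a harder discrimination problem than the synthetic
one.

All randomness flows from the single config seed (`seed` for the
genome stage, `seed + 1` for the read stage, with a documented draw
order), so every dataset is byte-reproducible.

## Numerical and degenerate-input choices

* Window medians of even-sized truncated edge windows are midpoint
  averages (can be half-integers); scores divide by
  \(\max(\mathrm{median}, \mathrm{floor})\).
* `build_ri_model` at pseudocount 0 yields \(-\infty\) weights for
  unseen bases; \(R_i\) of a sequence containing one is \(-\infty\),
  which orders correctly below every finite score.
* Empty inputs return empty, typed results with warnings (empty read
  file, empty track, empty histogram) rather than errors, except where
  the operation is undefined (both gel intensities zero, zero-read
  simulation).
* Tie-breaks are total and documented (spacer preference order;
  leftmost −10LR anchor; strongest-per-TSS ordering), so all outputs
  are deterministic for identical inputs.

## Known limitations

* No BAM input; alignment, deduplication and trimming are upstream of
  this package's scope.
* The caller models background only through the local window median —
  no smoothing, no replicate pooling.
* TSSs are imported, not called; operon structure is not
  reconstructed.
* Footprint analysis summarizes read lengths; it does not model RNase
  digestion kinetics or gel quantification.
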