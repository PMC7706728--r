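---
title: "Dissecting promoter architecture: methods and design notes"
author: "promarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting promoter architecture: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promarch)
```

# Scope

`promarch` characterizes promoter chromatin architecture from three kinds of
evidence: the positions and lengths of paired-end ATAC-seq fragments, the
DNA sequence itself, and nucleosome occupancy probability tracks computed
upstream. It targets the architecture that distinguishes constitutively
active (ubiquitous and germline-active) promoters from somatic
tissue-specific promoters in small non-mammalian genomes: well-positioned
-1/+1 nucleosomes around a short nucleosome-depleted region (NDR), a 10-bp
periodic WW (W = A/T) dinucleotide signal over the +1 nucleosome, and a
stereotyped distance between the transcription start site (TSS) and the +1
nucleosome edge. A rule-based classifier assigns accessible sites and genes
to tissue-specificity classes from pairwise differential statistics
computed by standard count-based tools upstream.

Differential testing, occupancy-probability inference, read alignment and
peak calling are deliberately out of scope: their outputs are inputs here.

# Spectral periodicity scoring

For a set of same-oriented sequences, every occurrence of a member
dinucleotide (overlapping occurrences included, so `AAA` contains two `AA`)
is located, and all within-sequence pairwise distances up to `d_max`
(default 300 bp, matching a -50..+300 TSS-anchored analysis window) are
accumulated into one histogram. Pairs are never formed across sequences.
The histogram is scaled to unit sum, a distance-decay baseline is
subtracted, the residual is smoothed with a centered moving average of
window three, and the power spectral density (PSD) is computed by FFT. The
score reported for a period `p` is the PSD at the grid frequency `1/p`.

Numerical choices:

* **Decay baseline.** The monotone decay of the pair-distance distribution
  is estimated as a centered moving average of window `w_decay = 15` bp and
  subtracted. The window must cover more than one period so the oscillation
  survives detrending; 15 bp covers 1.5 periods of the 10-bp target. It is
  a tunable argument; any window in roughly 11-25 bp behaves equivalently
  on planted signals.
* **Zero padding.** The normalized distribution is zero-padded to the next
  multiple of 10 at or above `max(length, 500)` before the FFT, so 0.1 bp^-1
  lies exactly on the frequency grid and the 10-bp score needs no
  interpolation. The PSD is normalized as `|DFT|^2 / L`, with `L` the padded
  length.
* **Edges.** All moving averages shrink their window at the vector edges
  rather than dropping positions.
* **Degenerate input.** An all-zero histogram (no pairs) yields an all-zero
  normalized distribution, flagged, and a zero PSD.

The running track variant scores one 100-bp window every 2 bp across each
region, assigning the score to the window center (floored). Windows
containing `N` score zero and are flagged. No post-smoothing is applied to
the track; consumers can smooth as they see fit.

# V-plots and flanking-nucleosome enrichment

A V-plot is the 2D histogram of (fragment midpoint offset from anchor
center, fragment length), accumulated over every anchor whose window
contains the midpoint; offsets are sign-flipped for minus-strand anchors.
Midpoints of even-length fragments take the floor of the true center so
counts are exactly reproducible. A fragment overlapping several anchor
windows counts once per anchor (per-anchor density semantics). The default
extent is +/-500 bp by 30-250 bp; the density scale is
`counts * 1e6 / (n_fragments * n_anchors)` ("per million fragments per
anchor"), with raw counts always retained.

The flanking-nucleosome enrichment score is the mean density over two
symmetric boxes capturing nucleosome-length fragments on either side of the
anchor (|offset| in 70-180 bp, length 150-250 bp) divided by the mean over
matched background boxes further out (|offset| in 250-400 bp). A uniform
plot scores exactly 1. The box geometry is a documented, configurable
default; the score is undefined (flagged) when the background is empty.

# Nucleosome calling and architecture metrics

Given a promoter's forward and reverse TSS modes, the +1 dyad is the argmax
of the occupancy track over the 200 bp strictly downstream of the forward
mode, and the -1 dyad the argmax over the 200 bp strictly upstream of the
reverse mode. "Local maximum" is implemented as the window argmax; ties are
broken toward the TSS, the conservative choice (smallest TSS-to-nucleosome
distance). Edges are dyad +/- 73 bp (the 147-bp core particle); the
half-width is configurable because occupancy estimators do not report
edges. Each side is called independently; a flat-zero window yields no call
on that side and flags the promoter.

The metrics follow directly: `d1` = forward TSS mode to +1 nucleosome 5'
edge, `d2` = separation of the divergent TSS modes, `w` = NDR width from
the -1 nucleosome's TSS-proximal edge to the +1 nucleosome's 5' edge.
Overlapping calls give negative `w` and are flagged rather than dropped.

To relate positioning to sequence, +1 calls are sorted by occupancy and
chunked into bins of ~20 calls; each bin's 200-bp dyad-centered sequences
are scored for 10-bp WW periodicity and the bin-level Pearson correlation
between mean occupancy and periodicity is reported.

# Phasing of nucleosomal dinucleotide matrices

The 400-bp dyad-centered sequences are converted to a binary occurrence
matrix, clustered by k-means (default `k = 6`, 10 restarts, fixed seed; the
choice of `k` only controls the granularity of the rephasing), and each
cluster is shifted by the lag in -5..+5 bp that maximizes the
cross-correlation between the cluster mean profile and the global mean
profile; the mean product is taken over the overlap so no lag is favored by
window length alone, and ties break toward zero lag. Positions shifted out
of range are dropped before summing the phased profile.

One identifiability limitation is worth stating: if the input is an
equal-weight mixture of copies of one template at several phases, the
global mean profile has no preferred phase, and every assignment of lags
consistent with the pairwise phase differences maximizes the
cross-correlation — recovered lags are then arbitrary up to a common
rotation. Recovery is well-posed as soon as one phase dominates the
mixture, which is the biologically expected situation (a consensus
rotational frame with minority offsets) and is what the packaged fixtures
emulate. When there are fewer distinct occurrence rows than clusters
(e.g. literally identical sequences), each distinct row forms its own
cluster and all lags are zero.

# Specificity classification

Inputs are a replicate-averaged signal matrix (RPM for accessible sites,
TPM for genes) over the five-tissue panel (germline, neurons, muscle,
hypodermis, intestine) and a table of pairwise fold changes and adjusted
P-values from upstream differential testing. Detection thresholds are 8 RPM
for sites and 5 TPM for genes; a pair is significant toward a tissue when
its fold change exceeds 3 in that tissue's favor with adjusted P < 0.01.
The decision tree, applied in order:

1. below detection everywhere — *unclassified*;
2. the maximum-signal tissue is significant over every other tissue —
   *specific* to that tissue;
3. the detected set has 2-4 members, every member is significant over every
   outsider, and no member is significant over all other members —
   *restricted* to that set;
4. detected in all five with spread `max/min < 3` and no significant pair —
   *ubiquitous-uniform*;
5. detected in all five otherwise — *ubiquitous-biased*;
6. anything else — *unclassified*.

This tree reconstructs the published constraints (detection thresholds,
FC > 3 with adjusted P < 0.01, "less than threefold difference between any
two tissues" for the uniform class) and is the documented contract of this
package; the original study's full conservative rule set lives in
supplemental material and may differ in borderline restricted-vs-specific
handling. CV-based grouping cuts genes at the 20% lowest and 20% highest
coefficients of variation (broad vs regulated); the cut is rank-based so
the extreme groups have exactly `floor(0.2 n)` members, with ties broken
stably by input order, and zero-mean genes are excluded and flagged.

# What the generators emulate — and what they do not

All fixtures are produced by seeded generators so every analysis can be
exercised, with ground truth, without external data:

* `gen_periodic_sequences()`: i.i.d. backgrounds at 36% GC (worm-like) with
  W pairs planted every 10 bp, 10% jitter by default, in a chosen fraction
  of sequences.
* `gen_fragments()`: a germline-like architecture (short fragments over a
  narrow NDR, 140-200-bp fragments at dyads planted +/-110 bp) and a
  somatic-like architecture (wide NDR, diffuse nucleosome-length
  fragments), both over a 10% uniform background floor such as real
  libraries show.
* `gen_occupancy_track()`: Gaussian bumps (sigma 20 bp) at planted dyads;
  noiseless by default so dyad recovery is exact.
* `gen_class_matrix()`: per-class design means scaled off the detection
  threshold with a 10-fold planted effect, multiplicative Gaussian noise of
  chosen CV, and a differential table derived from the design means
  (emulating well-powered upstream testing).
* `gen_coupled_nucleosomes()`: 400-bp blocks whose central 200 bp carry
  planted periodic sites retained with probability equal to the planted
  occupancy, giving a monotone occupancy-periodicity coupling.

These fixtures establish correctness of the computations, not biological
truth: they contain no mappability or GC artifacts, no replicate structure,
no overdispersed counts, no mixed promoter classes within an anchor set,
and their differential statistics are noiseless functions of the design.
Passing tests therefore demonstrate that the methods recover what was
planted under realistic geometry — not that any particular biological claim
holds in new data.

Problem sizes used throughout the packaged tests and the acceptance script
(100-350-bp sequences in sets of 20-100, 2 x 10^4 fragments over five
anchors, 100 promoters, 400 nucleosome calls in 20 occupancy bins, 120
classified IDs) were chosen as the smallest sets on which the planted
effects are unambiguous.

# Known limitations

* The classifier's restricted/biased borderline logic is a reconstruction
  (see above), and operon handling is a simple keep-first filter.
* `d1` uses the 5' edge at dyad - 73 bp; occupancy estimators that report
  model-based edges may differ by a few bp systematically.
* The phasing lag is only identifiable up to a common rotation for
  perfectly balanced phase mixtures.
* Periodicity scores are comparable within one parameterization only;
  changing `d_max`, the decay window or the padding length rescales the
  PSD.
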