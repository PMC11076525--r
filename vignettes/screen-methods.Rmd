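---
title: "Models and methods behind splicescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind splicescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicescreen)
```

## The screen and its readout

A dCas13d/gRNA complex binds, but does not cleave, a target pre-mRNA.
Parked on a splicing-regulatory element (SRE), it competes with the
RNA-binding proteins that normally read that element, so a tiling library
of guides across a cassette exon and its flanking introns turns into a
per-nucleotide perturbation map of splicing regulation. The readout is a
dual-fluorescence reporter: eGFP is expressed constitutively while
tdTomato comes into frame only when the monitored exon is included
(Dual-IN) or only when it is skipped (Dual-EX). Cells expressing the
effector (high BFP) are sorted into the top and bottom 5% by
tdTomato/eGFP ratio, the guide cassettes in each bin are amplified and
sequenced, and guides that shift splicing become enriched in one bin and
depleted in the other.

On the log2 scale the reporter gives `log2(PSI) = log2(tdTomato) -
log2(eGFP) + c` with an unknown, sample-independent constant `c` (PSI:
percent spliced in). The package therefore treats per-event
`M = log2(tdtomato) - log2(egfp)` as a *relative* inclusion readout only:
summaries are median-based, comparisons are always against a
non-targeting control so that `c` cancels, and absolute PSI is never
reported from fluorescence.

## Library design

`tile_guides()` enumerates every window of each requested spacer length
(22 and 25 nt by default) at a 1-nt step; the spacer is the reverse
complement of the target window. An 835-nt region yields 814 22-nt and
811 25-nt on-target guides. Internally all coordinates are 0-based
half-open; displayed guide names are 1-based inclusive and
splice-site-relative: `E[a,b]` inside the exon, `A[a,b]` around the 3'
splice site (exon position 1 is the first exonic base, upstream-intron
positions count back as -1, -2, ... with no zero), and `D[a,b]` around
the 5' splice site (intron position 1 is the first intronic base, exonic
positions negative). Guides outside that window fall back to absolute
coordinates. The convention makes names like `D[10,34]` directly readable
as "intron positions 10-34".

Non-targeting controls are uniform random spacers rejection-sampled so
that neither the spacer nor its reverse complement occurs in the reporter
(10,000 retries per control before erroring). A genome-scale exclusion
list is the caller's responsibility: the package accepts any list of
forbidden sequences but does not ship an alignment step. Windows that
contain `N` are emitted but flagged, keeping the tiling count law exact.

## Enrichment statistics

For guide $g$, with read counts $n_{x,g}$ in bin $x \in \{u, t, b\}$
(unsorted, top, bottom) and bin totals $N_x$, each sorted bin is compared
against the unsorted sample:

$$e_{t,g} = \frac{r - r_0}{\sqrt{r(1-r)/(n_{t,g}+n_{u,g})}}, \qquad
r = \frac{n_{t,g}}{n_{t,g}+n_{u,g}}, \quad
r_0 = \frac{N_t}{N_t+N_u}.$$

This is the default `per_guide` mode: the guide's reads in the two
compared samples form a two-sample binomial, and $e$ is the standardized
departure of the guide's share from the share implied by the totals. A
second mode, `as_printed`, uses the library-wide denominator
($r = n_{t,g}/(N_t+N_u)$, $s = \sqrt{r(1-r)/(N_t+N_u)}$) throughout. The
two modes differ by a guide-independent offset and scale that the
subsequent centering removes, so downstream ranking is essentially
unchanged; `per_guide` is the statistically conventional reading and is
the default, `as_printed` is kept for audits against legacy analyses.
Degenerate proportions ($r \in \{0, 1\}$, including zero-count guides)
yield a missing score and make the guide unquantifiable in that
comparison rather than producing an infinite statistic.

Raw $e$ scores carry library-wide scale from whatever overdispersion the
experiment has (cell sampling into bins, PCR, pipetting), so they are
standardized robustly:

$$z = \frac{e - m}{\sigma}, \qquad \sigma = \mathrm{MAD}(e)/0.6745,$$

with median and MAD taken across *all* guides with a defined score,
controls included (`mad()` is called with constant $1/0.6745$, matching
the definition rather than R's rounded default). Because the bulk of a
tiling library is effect-free, the median/MAD pool is dominated by null
guides and the standardization is self-calibrating: extra biological or
technical dispersion inflates $e$ and $\sigma$ together. A zero MAD is an
error, not an epsilon — it means the score distribution is degenerate and
the screen (or simulation) is misconfigured.

Guides with fewer than 5 reads in either compared sample, or RPM below 20
in both, give unstable outlier Z-scores; they are flagged unquantifiable
($w = 0$) *after* Z computation, so the filter affects the Stouffer
combination but not the normalization pool. Thresholds are inclusive
($\geq$).

Within a replicate the two sorted bins are combined by Stouffer's method
with opposite signs (enrichment on top and depletion on bottom are
concordant): $z_g = (z_t w_t - z_b w_b)/\sqrt{w_t + w_b}$. Across
replicates the final score generalizes to any replicate set:

$$Z_g = \frac{\sum_{\text{bins}} \mathrm{sign}(x, \text{reporter})\, z\, w}{\sqrt{W}},
\qquad W = \sum w,$$

with $\mathrm{sign}(t, \text{IN}) = +1$,
$\mathrm{sign}(b, \text{IN}) = -1$ and both flipped for the Dual-EX
reporter, whose readout is inverted. The canonical design is four
replicates (two per reporter), giving $W \le 8$. Positive $Z$ means
splicing activation. Two exact symmetries follow and are tested:
swapping top and bottom counts negates $Z$; relabeling a replicate's
reporter while swapping its bins leaves $Z$ unchanged.

Guides with $W \ge 4$ are converted to two-sided normal p-values and
Benjamini-Hochberg FDR computed over exactly that filtered set. The hit
threshold is $\mathrm{FDR} \le 0.01$ (inclusive) by default; hits are
classified activator ($Z > 0$) or inhibitor ($Z < 0$).

## Spacer counting

Reads are matched exactly (no mismatch tolerance, sequenced strand only —
amplicon orientation is fixed by the PCR primers). The default `anchored`
mode locates the direct repeat in the read, extracts the sequence up to
the 3' backbone anchor and requires exact equality to a library spacer,
which tolerates untrimmed reads. The `substring` mode, for pre-trimmed
data, assigns a read to a guide whose spacer occurs as a substring, with
longest-match tie-breaking so a read carrying a 25-nt spacer is never
credited to its nested 22-nt sub-spacer; a read matching several distinct
spacers of the same longest length is ambiguous and left unassigned
(each read is assigned to at most one guide). Note that on a 1-nt tiling
library, untrimmed cassette context makes same-length neighbours collide
about half the time — anchored mode exists precisely to avoid this, and
is the default.

## The synthetic screen generator

The generator exists so that every stage is testable with known ground
truth; its defaults are the package's canonical study conditions and are
not tuned per test. The demo reporter is an 835-nt region laid out as
exon6 (81 nt), intron6 (200 nt), exon7 (54 nt), intron7 (444 nt), exon8
(56 nt), with two planted 25-nt SREs in the downstream intron: a proximal
silencer at intron positions 10-34 (effect -2.5 on the logit scale,
emulating the ISS-N1 class of elements) and a distal enhancer at
positions 333-357 (+2.5, emulating a distal intronic enhancer). Baseline
PSI is 0.4 for Dual-IN, so both directions of change are observable.

Blocking is modeled on the logit scale so PSI stays in (0, 1):
$\mathrm{logit}(\psi_g) = \mathrm{logit}(\psi_0) - \sum_{\text{SRE}}
\text{effect} \times \text{overlap} \times \text{potency}(L)$, linear in
the overlap fraction (a modeling choice, not a mechanistic claim).
Potency is 1.0 for 25-nt and 0.7 for 22-nt spacers — longer spacers
modulate splicing more strongly. The *effective footprint* is the 22
target bases adjacent to the target interval's 3' end, i.e. anchored at
the spacer 5' end, which together with the upstream stem-loop positions
the protein; this is what makes 22-nt guides with a matching spacer 5'
end (shift 0) behave most like their covering 25-nt guide, and it is the
property the shift analysis tests. Setting `footprint_anchor = "full"`
disables the anchoring.

Cells follow a single-integration model (one guide per cell, as under
low-MOI transduction): 1,000 cells per guide, 40% BFP-positive, 95%
viable, eGFP lognormal (log2 mean 10, sd 0.8), tdTomato proportional to
$\psi$ (Dual-IN) or $1-\psi$ (Dual-EX) times eGFP with 0.5 log2 units of
Gaussian ratio noise. Sorting takes the strict top and bottom 5%
empirical quantiles of M among gated cells with deterministic tie-breaks
by event index; the unsorted sample is the whole gated population.
Sequencing draws 1e6 reads per bin from a multinomial over the bin's
guide composition, and can optionally emit FASTQ with each spacer
embedded in the full cassette, which round-trips exactly through the
counter.

What the simulator does *not* model: PCR amplification bias, cell growth
and dropout between transduction and sort, multi-integration events,
effector silencing beyond the static BFP-positive fraction, and spectral
spillover between channels. Passing tests therefore demonstrate the
correctness and calibration of the statistics under realistic sampling
noise, not robustness to every artifact of real screens.

## Numerical and design choices

- Missing values are explicit `NA` sentinels propagated through every
  stage; no NaN comparisons, no silent drops. Output TSVs write missing
  as `.`.
- Degenerate inputs error early with the offending field named:
  zero-total bins, empty gates, malformed FASTQ, manifest schema
  violations.
- The anchor position reported for plotting is the guide's 5'-most target
  coordinate (the base paired by the spacer 3' end).
- Per-shift concordance uses squared Pearson correlation on the combined
  Z (not per replicate, switchable by passing any per-replicate table),
  with pairs dropped — not imputed — when either Z is filtered, and at
  least 3 complete pairs required per shift.
- The 22/25 pairing rule in target coordinates: a 25-mer footprint
  $[s, s+25)$ pairs at shift $k$ with the 22-mer $[s+3-k, s+25-k)$;
  shift 0 shares the target 3' end (spacer 5' end), shift 3 the target
  5' end.
- Control generation, cell simulation and read sampling are all
  reproducible under explicit integer seeds; `simulate_screen()` derives
  per-replicate seeds as `seed + 1000 * replicate_index`.

## Problem sizes used by the test suite

The end-to-end validations run the full canonical library (1,937 guides)
with 1,000 cells per guide and 1e6 reads per bin: 20 seeds of no-effect
screens for null calibration (control hit rate at FDR 0.01 stays below
2%), 3 seeds for hit recovery (sensitivity at least 0.9 for guides with
at least 80% SRE overlap, all signs correct, control FPR at most 0.02),
and 20 seeds for the shift property (R² at shift 0 exceeds shift 3 in at
least 18). Unit tests use a 110-nt miniature of the same layout so that
every arithmetic path is also checked at a size where brute-force oracles
are feasible.

## Known limitations

- Exact matching only; real screens lose reads with sequencing errors in
  the spacer, which the counter reports as unassigned rather than
  rescuing.
- The per-guide binomial treats reads as independent given the bin
  composition; true replicate-to-replicate dispersion enters only through
  the robust standardization, not an explicit overdispersion model
  (no negative-binomial or rank-aggregation alternative is provided).
- No segmentation of per-guide scores into discrete SRE calls; the
  product is the per-guide landscape.
- FACS input is a plain event table; FCS binary parsing and
  compensation/spillover correction are out of scope.
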