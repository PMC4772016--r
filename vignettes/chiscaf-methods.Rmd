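---
title: "Likelihood-based scaffolding with in vitro proximity-ligation pairs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood-based scaffolding with in vitro proximity-ligation pairs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiscaf)
```

## The data and the model

Chicago-style libraries are proximity-ligation read pairs produced from
chromatin reconstituted *in vitro* on high-molecular-weight (HMW) input DNA.
Because ligation happens within one chromatin aggregate assembled on a single
input fragment, the genomic separation of a true pair is bounded by the input
fragment length (about 150 kbp for standard HMW preparations), and there is
no biological contact signal (no telomere clustering, no loops) to confound
assembly. The separation distribution of real libraries decays smoothly over
four orders of magnitude and is well approximated by a mixture of
exponentials; a small fraction of pairs are chimeric ligations between
unrelated fragments whose two ends sample the genome essentially
independently.

chiscaf models the separation `x` of a mapped pair as

$$ f(x) \;=\; \frac{p_n}{G} \;+\; (1 - p_n) \sum_k a_k\,
   \frac{\lambda_k e^{-\lambda_k x}}{1 - e^{-\lambda_k M}},
   \qquad 0 \le x \le M, $$

where `G` is the effective genome size, `p_n` the noise fraction, and `M`
(`max_span`) the input fragment length that truncates the exponential part;
each truncated component is renormalised. Truncation is the simplest
mechanism consistent with libraries showing no linking signal beyond the
input DNA size. The noise floor `p_n/G` extends to the genome size, so the
density integrates to one.

Given two contigs of lengths $l_1, l_2$ at a hypothesised gap $g$ and
orientation $o$, the likelihood of observing $n$ spanning pairs with implied
separations $d_i$ among $N$ total pairs is

$$ L(l_1, l_2, g, o) \;=\; \frac{N!}{(N-n)!}\,(1 - P_0)^{N-n}
   \prod_{i=1}^{n} f(d_i), $$

with $P_0$ the probability that a single random pair spans the join,

$$ P_0 = \frac{1}{G} \int f(x)\, c(x)\, dx, \qquad
   c(x) = \max\{0,\ \min(l_1,\, l_2,\, x - g,\, l_1 + l_2 + g - x)\}, $$

evaluated in closed form per exponential component ($c$ is piecewise
linear). We drop the combinatorial prefactor $N!/(N-n)!$ everywhere: every
comparison the pipeline makes (gap against gap, orientation against
orientation, join against no join) holds $n$ fixed, so the prefactor cancels
in all ratios and omitting it avoids large-factorial arithmetic. We read
$P_0$ as the per-pair spanning probability, which makes $(1-P_0)^{N-n}$ the
likelihood of the $N-n$ non-spanning pairs; the source material never defines
$P_0$ explicitly, so this reading is our own.

All join decisions use the log-likelihood ratio against the unlinked
hypothesis ($g = \infty$), under which every observed pair is scored as noise
and the spanning term vanishes:

$$ \mathrm{LLR} = (N - n)\log(1 - P_0) +
   \sum_i \left[\log f(d_i) - \log(p_n/G)\right]. $$

A pair whose implied separation exceeds `M` sits on the noise floor and
contributes zero, so irrelevant long-range pairs neither help nor hurt.
Densities are floored at `1e-300` before logs; all arithmetic is in natural
log.

An important subtlety: with offset-resolved scoring, flipping every contig
orientation at a *fixed* left-to-right order is not a symmetry — it inverts
each contig in place, which changes the implied separations. The true mirror
symmetry reverses the order *and* flips the orientations (reading the
scaffold from the other strand), and that invariance is what the test suite
asserts.

## Fitting the model to mapped pairs

The noise product $N p_n$ is estimated first, from the link counts of a
random sample of contig pairs: an unrelated pair $(i, j)$ expects
$2 N p_n\, l_i l_j / G^2$ links, so after dropping the top and bottom `trim`
quantiles of the densities $n_{ij}/(l_i l_j)$ (removing genuine neighbours
and repeat-inflated outliers) the estimator inverts this expectation on the
retained pairs. Two desk-scale adaptations were necessary. First, the
fraction of contig pairs that are genuinely linked grows as assemblies get
smaller (neighbours are ~1% of all pairs at a few hundred contigs, versus
~0.01% at tens of thousands), so the pipeline widens the trim to twice the
observed linked fraction. Second, when the noise is so sparse that the
trimmed sample retains no links at all, the estimator switches to
value-based exclusion over the full contig-pair population: counts
incompatible with the current Poisson noise expectation (above its 0.999
quantile) are excluded and the estimate is iterated to a fixed point, with
the all-zero pairs entering the denominator in closed form. Weakly linked
non-adjacent contig pairs (one or two long-range links) are not separable
from noise by any truth-free estimator, so the noise product carries an
upward bias of a small factor at desk scale; downstream scores depend on it
only through the (log) noise floor and tolerate this.

Separation histograms are corrected for finite-contig edge bias: a
separation `x` can only be observed from $\max(0, l_i - x)$ start positions
within contig $i$, so width-normalised counts are multiplied by
$G \,/\, \sum_i \max(0, l_i - x)$. (The corresponding printed expression uses
$\min(0, l_i - x)$, which is non-positive and cannot be a count denominator;
we treat it as a typo for $\max$.) Bins are log-spaced with edges snapped to
whole bp — separations are integers, and sub-bp bins otherwise corrupt the
density estimate at small `x`. The mixture is then fitted by least squares
in raw-count space (each bin weighted by width over correction factor, so
dense short-range bins and sparse tail bins count equitably): rates are
selected greedily on a log-spaced grid with amplitudes solved by nonnegative
least squares, then polished by box-constrained quasi-Newton on the log
rates; rates within 1% merge. The number of components is a free parameter
(default 3); the source material does not state the number used originally.

## The simulator and its calibration

The synthetic library generator is first-class, tested code: it emulates the
statistical structure the scaffolder assumes, with exact truth tracking.
Genomes are uniform random sequence (content never matters — pairs are
coordinates); contigs tile chromosomes under a configurable length law
separated by unassembled gaps (default 100 bp); placements get uniform
random strands. Signal pairs place one end uniformly and draw the
separation from the truncated mixture by inverse CDF (draws leaving the
chromosome are rejected); noise pairs place both ends independently; read
strands are independent coin flips, because Chicago pair geometry carries no
strand information. Map quality is a fixed high value with an optional
degraded fraction, and duplicates are exact coordinate repeats at a
configurable rate, so the filters can be exercised.

The default mixture was calibrated once, by least squares, so that its
per-separation-bin physical coverage (bp of pair span per genome bp over the
bins 0–1, 1–5, 5–10, 10–25, 25–50, 50–150 kbp) reproduces the published
single-lane profile of two 150-kbp-input libraries — 3.8, 8.4, 8.6, 18.6,
13.5, 6.5× — essentially exactly (residual ~1e-17). The result is rates
(1.711e-3, 1.796e-4, 6.167e-5)/bp with weights (0.686, 0.188, 0.126) and a
mean truncated separation of ≈ 3.49 kbp. The noise level is calibrated from
the published rate of about one spurious link per unrelated 500-kbp window
pair: $p_n = s\,G^2 / (2\,w^2\,N)$. Together these fix the simulated pair
count at `sum(coverage) * G / E[separation]` plus the implied noise pairs.
Six bin aggregates cannot pin down the within-bin shape of the real
distribution; this mattered for one acceptance target (below).

What the generator does *not* emulate: sequencing errors and base
qualities, restriction-site placement and junction masking (an
alignment-time concern), mappability and coverage heterogeneity of real
genomes, and biological repeat structure (repeats are emulated only through
the depth-masking and promiscuity filters' inputs, and chimeric joins are
injected explicitly). Passing tests therefore demonstrate correctness of
the algorithms under the model's own assumptions, not performance on real
libraries, where overdispersion and mapping artifacts will erode the
operating points.

## The scaffolding pipeline

`run_hirise()` executes: pair filtering → model fit → pre-pass contig
breaking → link graph → components → edge filtering → spanning-forest
linearization → orientation DP → within-component merging → local
refinement → iterative joining → post-pass join breaking → final refinement
→ gap estimation. Determinism: candidate moves are processed in decreasing
score order with lexicographic tie-breaks; the only randomised step (the
contig-pair sample of the noise estimate) uses a seed derived from the
config.

**Filtering.** Pairs are dropped when either end has map quality below 20,
is a flagged duplicate, lies in a masked high-depth interval (double
threshold $t_1 = t_2/2$, searched on the observed depth grid so the masked
fraction is the largest value at or below the 0.5% target), or lies in a
fixed 1-kbp window linked to more than four other contigs by at least two
links. Each pair is tallied under the first rule that rejects it, so the
tallies reconstruct the input count exactly.

**Graph and seeds.** Contigs are nodes; each linked pair of contigs is one
edge carrying all read offsets; intra-contig pairs feed the break-support
profiles. The link threshold $t_L$ is the smallest integer such that
components of the at-least-$t_L$-links subgraph stay below the cluster cap
(5% of contigs by default — a parallelisation guard designed for assemblies
of tens of thousands of contigs; on small simulated assemblies a larger cap
keeps chromosomes intact and the iterative joiner stitches across component
boundaries either way). Promiscuous contigs (degree per bp, or fanout at
$t_L$ links, in the top 5% tail) lose their edges; the maximum-support
spanning forest of the remainder (Kruskal on negated LLRs — the published
"minimum" forest is minimal cost under negated support) is linearized by
three rounds of deleting degree-1 then degree->2 nodes, and surviving
simple paths become seeds. Each pruning round trims the path ends; the
trimmed contigs re-enter as singletons at the merge stage, so nothing is
lost.

**Orientation.** For each seed path, orientations maximise the summed join
LLR over pairs within `k` positions (default 2), with gaps implied by
intervening lengths plus one standard gap `g_o` (default 1 kbp) per step.
The `k`-step structure admits an exact DP over the orientations of the last
`k` contigs; the acceptance suite checks exact score equality against
$2^n$ enumeration. Lookback beyond adjacent pairs matters because a small
intercalated contig may carry orientation information only through links
that jump over it.

**Moves.** Candidate contig-end pairs are scored at the standard gap and
processed in decreasing order. Depending on whether ends are free or buried
and co-scaffolded, the implied move is an end-to-end join, an insertion into
the gap adjacent to a buried end, an inversion of the segment between two
same-scaffold ends, or the best of the four end-to-end joinings. A move is
accepted iff the summed LLR change over all affected contig pairs is
positive; the change is computed by rescoring the layout window within the
model's span of the edit (pairs further away are unaffected), which the test
suite verifies against full-chain rescoring. Within components the pool
updates live; the pool-wide iterative joiner instead runs rounds in which a
scaffold participates in at most one accepted move (both behaviours are
exposed). Local refinement slides a `w`-contig window (default 4, capped at
5 since cost grows as $w!\,2^w$) and enumerates all orderings and
orientations, sharing pair evaluations across the $2^w$ orientation sets of
each permutation; for layouts of at most `w` contigs this is a single
exhaustive enumeration and hence exact, which the acceptance suite checks
against $n!\,2^n$ search. Refinement scores pairs within a 60-kbp reach:
beyond that, link terms are too weak to inform local order, and the shorter
horizon keeps the enumeration affordable.

**Breaking.** The support score at position $i$ of a contig is the join LLR
of the two fragments $[0, i)$ and $[i, \mathrm{len})$ at gap 0, evaluated on
a 500-bp grid; at gap 0 a straddling pair's implied separation is just its
observed separation, independent of $i$, so the profile accumulates by
difference arrays. The robust score virtually masks up to `n_mask` bins of
`w_mask` bp (defaults 3 × 1 kbp) on the left or right of the candidate
breakpoint — whichever masking lowers the score more — removing the bins
whose straddling pairs contribute the largest positive terms; masked pairs
leave both the spanning count and the total, so the change is exactly the
removed contribution. This exposes misjoins propped up by a single repeat
cluster.

Two numerical choices here were genuinely open and we record the reasoning.
(1) *Thresholds.* A raw score below 0 marks a position where breaking is
likelier than keeping. The robust score, however, is somewhat negative even
on perfectly clean contigs near their ends, where all genuine support sits
within the masking footprint of one side: at calibrated coverage, clean
contigs bottom out around −25 nats while true junctions sit at the full
no-support penalty (≈ −49 nats for 30-kbp flanks). The default robust
threshold therefore auto-calibrates to 90% of the model's no-support
spanning penalty at a nominal 25-kbp junction (≈ −41 nats): the masked
support must fall essentially to the no-information floor. (2) *Segment
cuts.* Below-threshold positions form segments (merged within 300 bp;
segments within 1 kbp of a contig end are discarded). A single junction
produces a robust-score dip up to about $(n_\mathrm{mask}+1) w_\mathrm{mask}$
wide on each side, so only segments longer than twice that footprint are
treated as extended weak regions and cut at both ends; shorter segments
break once, at the midpoint, which localises a point junction to within the
grid stride. The published 1,000-bp rule for double cuts presumes masking
parameters that were not stated. Breaking runs once on the input contigs
(pre-pass, full profiles) and once on the assembled scaffolds (post-pass,
evaluated at the junctions between adjacent contigs); the number of
iterations is configurable.

**Gaps.** Each junction's gap is the argmax of the join LLR over a
log-spaced grid with local refinement, floored at 0, with an LLR-drop-of-2
interval. At calibrated coverage (~30–50 spanning pairs over a 5-kbp gap)
the estimate is unbiased with a median relative error around 22% — the
information about the gap is carried almost entirely by the two slow
mixture components, which bounds the achievable precision.

## The inversion discriminator

A heterozygous inversion $[b_1, b_2)$ puts half of the molecules on a
haplotype whose interior coordinates map reflected
($x \mapsto b_1 + b_2 - 1 - x$) against the reference. The discriminator
scores known candidate breakpoints (detection, not discovery) by

$$ \mathrm{LLR} = \sum_i \log\left[\tfrac12 f(d_{\mathrm{ref},i}) +
   \tfrac12 f(d_{\mathrm{inv},i})\right] - \log f(d_{\mathrm{ref},i}), $$

where $d_\mathrm{inv}$ is the separation after reflecting in-interval read
coordinates. Pairs with both or neither end inside contribute exactly zero
(reflection preserves their separations); only breakpoint-straddling pairs
are informative. The 0.5/0.5 per-pair mixture mirrors the simulation
protocol, which assigns each pair independently at random to a haplotype;
the original method's details are not published, so this construction is
ours and is validated against the published sensitivity/specificity table.
Classification at threshold 0 calls an inversion iff LLR > 0 (ties go to
reference). The evaluation harness simulates matched heterozygous and null
trials over a region with 100-kbp flanks (the same underlying pair draw,
differing only in the coordinate editing), applies the breakpoint-flank
masking `W` to both arms, and reports Wilson confidence intervals.

Under the calibrated library the harness reproduces the published unmasked
operating points closely (sensitivity ≈ 0.97 at L = 5 kbp and ≈ 0.76–0.77
at L = 1 kbp against published 0.97 and 0.76). Two deviations are expected
and observed. The simulated null trials are cleaner than real data — no
mappability structure, no coverage heterogeneity — so specificity runs a few
points above the published 0.94. And with 1-kbp masked breakpoint flanks
the simulated sensitivity (~0.6) falls short of the published 0.81: masking
removes every pair within 1 kbp of a breakpoint, so the evidence comes from
pairs spanning at least ~2–2.5 kbp, and the bin-calibrated mixture — which
is all that six published bin aggregates can determine — appears to place
less mass at those separations than the real library did. We deliberately
did not tune the within-bin shape toward the published table.

## Truth-based QC

Markers are planted every 1 kbp of scaffold coordinate and mapped to
reference coordinates through the truth map (synthetic coordinates, not
literal k-mers: on simulated data every base has a known source, so k-mer
uniqueness machinery is unnecessary). A scaffold is anchored to a
chromosome when some tiling window of 5, 10 or 50 kbp contains markers that
all map there; scaffolds anchored to two or more chromosomes are misjoined,
reported as the fraction of assembly span. Orientation accuracy is the
density of consecutive same-chromosome marker pairs with incongruent
reference orientation (internal switches only — globally flipping a scaffold
changes nothing). Gap accuracy takes marker pairs 49.5–50 kbp apart in the
assembly and reports the 95th percentile of |assembly − reference|
separation. Window placement for anchoring is tiling (the published
definition leaves it open).

## Problem sizes and what the checks show

The test and acceptance workloads are sized for a single CPU: discriminator
operating points at 500 trials per arm; DP-versus-enumeration equivalence at
50 random instances each; parameter recovery at 1e5–2e5 pairs; misjoin
breaking on 50 planted chimeras over a 20-Mbp two-chromosome genome; and
end-to-end scaffolding of a 50-Mbp four-chromosome genome fragmented into
~1,800 contigs of ~30-kbp N50 at the full calibrated coverage (~850,000
pairs), which completes in about three minutes and yields scaffold N50 over
100× the input with zero truth-misjoins and zero orientation switches. The
published genome-scale results (human 20-Mbp scaffold N50 and its Table-1
error profile) require the original sequencing data and are out of scope;
the synthetic-truth metrics above are the desk-scale analogues.

## Known limitations

* The noise-product estimator is upward-biased at desk scale (see above);
  p_n enters only the noise floor, so the effect on decisions is a few nats.
* The robust break criterion cannot distinguish a repeat-supported misjoin
  from a clean region whose entire support lies within the masking footprint
  of one side; junctions between pieces shorter than ~15 kbp are therefore
  caught only by the raw criterion.
* Local refinement is a hill climber over sliding windows (exact only for
  scaffolds of at most `w` contigs); order errors spanning more than `w`
  contigs that survive the merge stage are not guaranteed to be repaired.
* The discriminator assumes known breakpoints; genome-wide breakpoint
  discovery, and deletion/duplication models, are out of scope.
* Gap estimates have ~20% relative error at calibrated coverage; AGP output
  floors gaps at 10 bp per the format's convention.
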