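---
title: "Methods: intrinsic nucleosome occupancy at regulatory sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intrinsic nucleosome occupancy at regulatory sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nucoccupancy)
```

This vignette records the models, numerical choices and known limitations
behind `nucoccupancy`. The package asks a single scientific question of a
genome sequence: how strongly does the DNA itself invite nucleosome
formation, base by base — and how does that intrinsic signal relate to an
(observed or simulated) in vivo nucleosome map, particularly over
regulatory sequence such as promoters, CpG islands and transcription-factor
binding sites?

## The binding-energy model

A nucleosome footprint covers `L` bases (default `L = 147`, the core
particle). A candidate footprint starting at position $i$ is scored by the
log-likelihood ratio of its $L-1$ dinucleotides under a position-specific
nucleosome model versus a position-free background:

$$\mathrm{llr}(i) = \sum_{p=1}^{L-1} \left[\log P_{\mathrm{nuc}}(d_p \mid p)
 - \log P_{\mathrm{bg}}(d_p)\right]$$

and the binding energy is the strand-symmetrized negative score,
$E(i) = -\tfrac12(\mathrm{llr}_{\mathrm{fwd}} + \mathrm{llr}_{\mathrm{rc}})$,
so favourable sequence means low energy. Nucleosomes are strand-agnostic;
symmetry is also enforced at fitting time by counting every training window
together with its reverse complement, so the model is symmetric regardless
of how training data are oriented. Dinucleotides are the established
resolution for this class of model: they capture the ~10 bp bendability
periodicity and the rigidity of poly(dA:dT), which are the dominant
sequence determinants of nucleosome formation. Published models of this
lineage add a k-mer term (e.g. 5-mers) on top of the dinucleotide
component; that term is deliberately omitted here — the dinucleotide
component carries all the behaviour this pipeline studies, and keeping the
model trainable from small window sets keeps every result reproducible
without external weight files. The background is a single position-free
dinucleotide distribution fit on background sequence; its simplicity is a
documented assumption, not an oversight.

`fit_nucleosome_model()` adds a pseudocount to every (position,
dinucleotide) cell, so degenerate training sets stay finite; `fit_gc_model()`
is the pipeline's default trainer, taking the top G+C quintile of randomly
sampled genomic windows as the bound set. This stands in for an in
vitro-trained model and transparently encodes the empirical fact the
pipeline needs: G+C-rich sequence is occupancy-prone, poly-A is
occupancy-averse.

## From energies to per-base occupancy

Footprints exclude one another ("hard-core" exclusion). The ensemble of all
legal footprint configurations on a chromosome is a one-dimensional
grand-canonical lattice gas: a configuration with footprint starts $S$ has
weight $\prod_{i \in S} e^{\mu - E(i)}$, the empty configuration has weight
1, and the chemical potential $\mu$ sets the overall density.
`occupancy_from_energies()` computes exact marginal start probabilities with
forward/backward recursions over the partition function in $O(n)$ time
(compiled code), entirely in log space — the documented contract is no
overflow for $|E| \le 50$ on chromosome-scale inputs. Per-base occupancy is
the windowed sum of start probabilities over the $L$ covering windows.
Correctness is pinned by an exhaustive-enumeration oracle on short
sequences (every configuration listed explicitly) and by two conservation
properties: $\sum_j \mathrm{occ}(j) = L \sum_i P(\mathrm{start}\ i)$ and
$\mathrm{occ} \in [0, 1]$.

Two plausible-sounding properties are *false*, and the test suite documents
both with enumeration counterexamples rather than asserting them:

* **Per-base monotonicity in $\mu$.** Mean occupancy is monotone in $\mu$
  (that is what makes the calibration below well-posed), but occupancy at a
  *specific* base can drop as $\mu$ rises: denser packing can reroute
  footprints away from a base whose only covering windows are weak.
* **Flat plateaus on uniform landscapes.** A uniform-energy chromosome does
  not give constant interior occupancy at finite length; open boundaries
  induce the classic Tonks-gas density oscillation. The profile is exactly
  mirror-symmetric and matches enumeration; it is not flat.

Bases inside windows containing ambiguous (N) bases get weight 0; bases
coverable by no valid footprint have occupancy exactly 0 but remain
*defined*, so downstream masks stay explicit.

**Choosing $\mu$.** The absolute occupancy level is removed by the log2
normalization, so $\mu$ mainly sets the dynamic range. `calibrate_mu()`
root-finds $\mu$ so the genome-mean occupancy hits a target, default 0.8 —
dense, chromatin-like packing. The calibration is global per genome, not
per chromosome.

## Track normalization

Both occupancy tracks are placed on the scale
$x''(i) = \log_2(x(i)/\bar{x}) - \overline{\log_2(x/\bar{x})}$: a log2 ratio
over the genomic mean, re-centred so the genomic average is exactly zero
(`normalize_track()` guarantees $|\text{mean}| < 10^{-12}$ over defined
bases). The mean is global across chromosomes. Count-like tracks contain
zeros, which the log cannot take; `floor_track()` lifts values to a
configurable pseudo-floor, default half the smallest positive defined
value. The floor preserves rank order and is reported when applied; whether
the original analyses floored or dropped zero-read bases is not knowable
from the outside, so the choice is exposed as a parameter rather than
hidden.

## Region machinery

* Proximal promoters are the window $[-150, 0]$ around the TSS with *both*
  endpoints included — 151 bases. A plus-strand TSS at 0-based $t$ maps to
  $[t-150, t+1)$; minus-strand windows mirror; everything clips to
  chromosome bounds. The one-base difference against a 150-base reading is
  immaterial to every downstream statistic and is documented here once.
* CpG islands follow the classic criteria — length $\ge 200$, G+C $\ge 0.5$,
  observed/expected CpG $\ge 0.6$ with expected $= \#C \cdot \#G /
  \mathrm{len}$ — with one sharpening: at least one observed CpG is
  required, so all-G or all-C stretches (expected $= 0$, ratio $0/0$) fail
  rather than pass vacuously. The caller emits disjoint maximal intervals
  by a leftmost-start, longest-extent greedy over all criteria-passing
  intervals. Sequences up to 5 kb get the exact global search; longer
  sequences are first seeded on passing 200-bp windows, and the greedy runs
  inside adaptively widened seeded neighbourhoods. A passing interval that
  contains no passing 200-bp window can be missed on long sequences — the
  standard seeding assumption, irrelevant for island-like composition
  blocks. Note a consequence of literal maximality worth knowing: islands
  may absorb a few flanking non-island bases when the flank keeps the
  aggregate criteria true (a 199-bp CpG block plus one flanking A is a
  legitimate 200-bp island).
* Promoters are `CpG` iff they share at least one base with an island
  (half-open adjacency is not overlap). Non-promoter filtering removes
  regions overlapping $[-1000, 0]$ TSS windows. Restriction to designated
  study regions keeps an item iff its midpoint lies inside — midpoint
  containment avoids double-keeping straddlers.

## Profiles and windowed sequence statistics

`meta_profile()` averages a track at each relative offset across anchors,
flipping orientation on minus-strand anchors so upstream is always left.
Undefined bases and offsets beyond chromosome ends contribute nothing; the
per-offset `support` count is reported so thin edges can be masked in
plots, and no imputation ever happens. `window_stat()` computes G+C
fraction and AAAA frequency in 150-base windows $[i-75, i+75)$; the even
width forces a half-base registration choice, resolved left-heavy (the
value sits at offset +75 of its window). AAAA occurrences are counted with
overlaps allowed and normalized by the $\mathrm{width}-3$ window start
positions, giving a value in $[0,1]$; windows touching an N are undefined.

## Correlation, subsampling, quadrants

`correlate_tracks()` works over jointly defined bases only; Spearman uses
average ranks for ties; p-values use the standard t approximation and are
clipped at the smallest positive double, so "vanishingly small" is reported
as a floor rather than 0. Because per-base tracks are strongly
autocorrelated at the nucleosome scale, naive p-values overstate
significance; `subsample_positions()` draws a fixed number of jointly
defined positions per chromosome with all pairwise distances $\ge 150$
bases (rejection sampling with a retry cap, then a deterministic greedy
fill that is flagged in the result). Feasibility is checked exactly via
maximum packing of the eligible positions. `quadrant_fractions()` assigns
every jointly defined base to a quadrant around configurable splits —
default 0/0, the genomic means of normalized tracks — with ties going to
the lower/left side; optional finite box limits measure genome fractions
inside dashed-box-style regions instead. The pipeline orients the plane the
way this scatter is conventionally drawn: in vivo on x, intrinsic on y, so
the upper left collects bases whose DNA invites nucleosomes but whose in
vivo coverage is depleted by trans-acting factors.

## What the synthetic genome emulates — and what it does not

`generate_genome()` produces, reproducibly from one seed: a two-state
(isochore-like) regional G+C process (defaults 0.37/0.48, mean segment
lengths 30/10 kb); genome-wide CpG depletion (retention 0.15, matching the
~0.2 observed/expected of mammalian genomes) imposed by replacing the G of
a CpG with A/T; promoters (100 per Mb — denser than a real mammalian
genome, a deliberate choice so promoter-level statistics are stable on a
1 Mb study genome) with G+C-elevated surroundings and, for 37% of them (the
human CpG-promoter share), an embedded CpG-island-like segment (G+C 0.72,
no CpG suppression) overlapping the proximal window; poly-A tracts in the
low-G+C background; and TFBS annotations in two classes ("TF" and a
CTCF-like minority) whose neighbourhoods are G+C-elevated like real
regulatory sites.

`simulate_invivo()` builds latent occupancy
$\lambda = [\alpha I + (1-\alpha)\varepsilon] \cdot d_{\mathrm{class}}$,
with $\varepsilon$ block-constant log-normal noise (blocks of 200 bases —
trans-acting influences are regional, not per-base white noise; the
log-normal keeps coverage positive and right-skewed) scaled to the
intrinsic mean, and class-wise multiplicative depletion (default: CTCF-like
sites $\times 0.2$) applied to latent occupancy, *not* to reads — so
depletion and the low-coverage quantal artifact interact as they do in real
maps. Reads then start as Poisson draws with per-base expectation
proportional to $c\,\lambda$ and are smoothed into coverage by the read
length; at low $c$ the output takes few distinct values (the quantal
pattern visible in log-scale scatters of real low-coverage data).

Noise calibration is analytic: for a target latent correlation $\rho$
between $\lambda$ and $I$,
$\alpha = \rho\,\sigma_\varepsilon / (\sigma_I \sqrt{1-\rho^2} +
\rho\,\sigma_\varepsilon)$ (`alpha_for_rho()`), with $\sigma_I$ measured on
the realized intrinsic track and $\sigma_\varepsilon = \bar{I}\sqrt{e^{s^2}-1}$
for log-normal sdlog $s$ (`invivo_noise_sd()`).

One subtlety matters when validating this calibration end to end: the
coverage operator is a running sum over the read length, i.e. a low-pass
filter. At mean occupancy 0.8 the intrinsic track's variance is dominated
by nucleosome-scale positioning ripple (autocorrelation falls to ~0.14 by
lag 50), so 50-base fragments filter away a large part of the very signal
being correlated, and the measured coverage-vs-intrinsic correlation
understates the latent $\rho$ — by up to ~0.2 at $\rho = 0.5$. The recovery
validation therefore uses 5-base fragments, where the identity holds to
within ~0.03; the default configuration keeps 50-base fragments for
realism everywhere the latent correlation is not the quantity under test.
The same mechanism is a real feature of fragment-based maps, worth
remembering when comparing per-base correlations across experiments with
different fragment sizes.

Not emulated, by design: sequencing G+C bias, MNase digestion sequence
preference and fragment-length variability, rotational positioning, linker
length distributions, replication timing, and any cell-type-specific
trans-factor program beyond one multiplicative depletion per annotation
class. Consequently, passing recovery tests show that the *pipeline*
measures what the generator encodes; they do not show that real chromatin
obeys the generator.

## Problem sizes and reproducibility

The study genome is 1 Mb (two 500 kb chromosomes) — large enough that
genome-wide correlations stabilize to two decimals and 100 promoters give
tight region means, small enough that the full analysis re-runs in minutes
on one core. The test suite's exhaustive DP oracle covers every DNA
sequence up to length 5 and hundreds of random landscapes up to length 12
for $L \in \{2,3,4\}$; island calling is checked against a global
$O(n^2)$ exhaustive search on constructed sequences up to 2 kb.

Every stochastic stage derives its own seed from one master seed and a
stage label (`derive_seed()`), so stages are individually reproducible and
identical configurations regenerate byte-identical artifacts, which the
tests assert. Tracks round-trip through run-length-collapsed bedGraph at 9
significant digits; regions through BED6; the genome through FASTA.

## Known limitations

* The dinucleotide model is a stand-in trained on G+C-rich windows of the
  genome at hand; its absolute energies are not comparable across genomes,
  and it omits the k-mer refinements of published models.
* The position-free background makes the model's zero point composition
  dependent; only normalized (relative) occupancy is interpretable.
* The island caller's seeding assumption (above) on sequences beyond 5 kb.
* `quadrant_fractions` with default splits is sensitive to the marginal
  shape of each track near its mean; quantile mismatch between two
  differently skewed tracks moves near-origin mass between quadrants. Tail
  statements are robust; near-origin ones are not.
* Correlations between per-base tracks depend on the fragment length that
  produced them (see above); cross-experiment comparisons should match
  smoothing scales first.
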