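---
title: "Joint depth and mate-pair HMM for CNV calling: model, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint depth and mate-pair HMM for CNV calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvhmm)
```

## The generative model

`cnvhmm` treats a chromosome as a sequence of hidden copy-number
states visited position by position. A state carries a copy number
$C \in \{0,1,2,3,4\}$ and an outer-distance shift $\delta$, and emits
two kinds of observations at position $t$:

* the read-start count $n_t$, Poisson with mean
  $\max\!\big(\tfrac{C}{2}\,\lambda\,G_t,\ \varepsilon\,\lambda\,G_t\big)$,
  where $\lambda$ is the genome-wide mean read-start rate per position
  and $G_t$ the GC depth-adjustment factor of the position's bin;
* every outer-distance $d$ whose pair has its leftmost (forward) mate
  starting at $t$, with probability $\Pr(d \mid D, \delta)$. For
  $\delta = 0$ this is the Laplace-smoothed empirical distribution of
  all retained pairs; for flanking states it is the heterozygous
  mixture $w\,\mathrm{pmf}(d-\delta) + (1-w)\,\mathrm{pmf}(d)$.

The joint log emission is the sum of the depth term and the distance
terms; attaching each pair's distance exactly once (at its leftmost
mate) keeps the product from double-counting pair evidence.

The state space contains the five copy-number states (Normal,
Del1/Del2, Dup1/Dup2) plus a grid of deletion rows. Row $k$ targets
deletions of size $k$ and consists of a 5' flank ($C=2$,
$\delta = k$), an interior deletion state ($C = 1$ by default), and a
3' flank ($C=2$, $\delta=k$). Pairs whose insert contains the deletion
have their leftmost mate in the 5' flank, which is where the shifted
mixture pays off; the interior state contributes the depth deficit.
Duplication states carry $\delta = 0$: tandem-duplication junction
pairs map everted or shortened and are excluded by the distance
filter, so duplications are detected from depth alone.

### Transitions as duration heuristics

Every state's self-transition probability is $1 - 1/\mathrm{duration}$,
so run lengths are geometric with the stated mean, and the exit mass
$1/\mathrm{duration}$ is split equally among the permitted
destinations. (A literal reading of "self-transition equals the inverse
of the expected duration" would give mean run lengths of about one
base, contradicting the stated duration targets; the geometric
convention is the standard reconciliation and is what the duration
numbers imply.) The topology is sparse: Normal exchanges with
Del1/Del2/Dup1/Dup2 and every 5' flank; within a row, f5 → interior →
f3 → Normal; nothing else.

Durations: flanks last one insert mean (the span over which shifted
pairs attach), a row's interior lasts its targeted size, large-CNV
states last `cnv_duration` (default 10 kbp — the scale at which
depth alone is well powered at these coverages), and Normal lasts
`genome_len / expected_events` with a default prior of one CNV per
3 Mbp. Decoding is plain Viterbi (no posterior smoothing), with ties
broken toward the lowest state index so runs are reproducible
bit-for-bit; the initial distribution is a point mass on Normal.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `grid_sizes` | 200–1600 by 200 | bp | medium-size range where mate-pair evidence dominates |
| `het_mix_weight` | 0.5 | – | carrier haplotype contributes half the spanning pairs of a het deletion; 1.0 models purely shifted flanks (hom) |
| `expected_events_per_bp` | 1/3 Mbp | 1/bp | prior CNV rate; sets the Normal duration and hence the entry cost of any call |
| `cnv_duration` | 10 000 | bp | duration of the depth-only CNV states |
| `eps_frac` | 0.01 | – | Poisson-mean floor for $C=0$; tolerates mismapped reads inside homozygous deletions |
| `dist_cutoff` | 6000 | bp | distances beyond it contribute depth but no pair evidence |
| `pseudocount` | 1 | counts/cell | Laplace smoothing so shifted lookups never hit zero |
| `gc_window`, `gc_bins` | 100 bp, 20 | | windowed GC binning; bins under 1000 positions fall back to $G=1$; $G$ clipped to $[0.1, 10]$ |
| `mapq_min` | 0 | | no mapping-quality filter by default (none is implied by the method) |
| `merge_gap` | 0 | bp | call merging off; available for smoothing fragmented calls on real data |
| `edge_mask` | `D + 4σ` | bp | chromosome ends cannot receive minus-strand read starts within one insert length, which mimics a deletion; both ends are masked from calling |

`sigma` is floored at 1 bp so power formulas and smoothed pmfs stay
defined on degenerate inputs. Coverage can be stated either as a fold
coverage $c$ or a per-position rate $\lambda = c/S$ (read length $S$);
all formulas use the rate.

## Power calculators

* **Depth only.** In a region of size $\delta$ the copy-neutral count
  is Poisson with mean $\mu_0 = \delta\lambda/S$; a 1-copy loss halves
  it, a gain multiplies by 1.5. The test is one-sided with an exact
  discrete critical value (no normal approximation), so the achieved
  size is at most $\alpha$ — and exactly 0 when $\mu_0 = 0$, which is
  why the depth calculator returns 0 rather than $\alpha$ at
  $\delta = 0$.
* **Single pair.** Reject when $d$ exceeds the $(1-\alpha)$ quantile
  $Q$ of the null; power is $1 - \mathrm{CDF}(Q \mid D + \delta)$ with
  the shifted distribution sharing the null's shape. On the discrete
  support the size at $\delta = 0$ is within one pmf cell below
  $\alpha$.
* **Multiple pairs.** With $m$ spanning inserts, the mean distance has
  standard error $\sigma/\sqrt{m}$ under a Gaussian approximation of
  the null, giving power $1 - \Phi(z_{1-\alpha} - \delta\sqrt{m}/\sigma)$.
  The expected spanning count is $m = (\lambda/2) D$, halved for
  heterozygous deletions because only carrier-haplotype pairs shift.
  We deliberately define $m$ as the number of *shifted* pairs and let
  the test run on those: the matching Monte-Carlo oracle draws $m$
  shifted pairs and applies the Z test. (Pooling shifted and unshifted
  pairs and testing the pooled mean would instead give noncentrality
  $\delta\sqrt{m}/(\sqrt2\sigma)$; the two conventions differ by
  $\sqrt2$ and cannot both match one formula. The shifted-pairs
  convention is the self-consistent reading of the halved-$m$
  formula.) $m$ is kept continuous in the formula; the oracle rounds.

## The simulator: what it emulates, what it does not

The generator builds a uniform-GC random reference, plants
non-overlapping heterozygous (one haplotype, fair coin) or homozygous
deletions and tandem duplications, and samples fragments uniformly per
haplotype with Gaussian insert outer spans (rounded, clamped at twice
the read length). Each haplotype receives
`coverage · hap_len / (2 · read_len)` pairs split equally across
libraries, i.e. `coverage` is per-haplotype fold coverage and the
diploid sample maps $2c/S$ read starts per reference position. Reads
map back to reference coordinates through the haplotype's block
lift-over — this, not an aligner, is what shifts spanning pairs by the
deletion size. A read crossing a breakpoint junction is unmappable
unless its minor-side overhang is under `min_anchor` (5 bp), in which
case it maps to its major block, as an aligner would tolerate a few
mismatched tail bases. Events keep at least twice the largest insert
mean apart (so neighbouring flank evidence stays disjoint) and one
margin (largest insert mean + largest event) from the ends; size
assignment cycles through the size list in balanced rotation before
shuffling, so requested counts per size are exact. An optional
`gc_bias` mode thins fragments by local GC to exercise the adjustment
model.

Not modelled: sequencing errors and base qualities, chimeric pairs,
duplicate reads, repeat-driven mismapping, real aligner behaviour
beyond the `min_anchor` rule, and hemizygous states. Passing tests on
these simulations therefore demonstrate the statistical machinery —
aggregation of depth and distance evidence, size-resolved decoding,
calibration of the power formulas — not robustness to alignment
artifacts on real genomes.

## Numerical choices and degenerate inputs

* All decoding is in log space; forbidden transitions are $-\infty$
  and never enter the sparse predecessor lists.
* Poisson log-pmfs are table lookups per (state, GC bin, count) with a
  direct `lgamma` fallback for counts above 64.
* Positions whose reference base is N emit 0 for every state (no
  evidence), and calls wholly inside masked runs are suppressed; the
  same mechanism masks chromosome ends (`edge_mask`).
* Zero-length tracks decode to empty paths; an empty grid yields a
  valid depth-only model; an all-N reference or an insert fit with
  fewer than 100 distances is a fatal, explained error.
* Chunked decoding (optional) processes windows with 10 kbp overlap —
  larger than any grid size plus the insert mean — keeps calls whose
  start lies in the chunk core, and deduplicates by coordinates;
  away from chunk edges it reproduces the unchunked calls.
* Coordinates are 1-based at the mapview boundary, 0-based internally,
  0-based half-open (BED) on output; the conversion happens once, at
  parse time.

## Problem sizes in the shipped tests

The test suite exercises the headline experiment at a 2 Mbp genome
with 200 planted heterozygous deletions at 3×, ten 1 Mbp event-free
replicates at 4× for specificity, a five-coverage power curve
(0.5–4×, 100 events per size per cell), Monte-Carlo power oracles at
$10^5$–$2\times10^5$ replicates, and exhaustive-enumeration Viterbi
oracles on instances with up to 4 states and length 8. These sizes
were chosen so the whole suite runs in a few minutes while keeping
binomial error bands (≈±4 % at $n=100$) narrow enough for the
monotonicity and sensitivity assertions to be meaningful.

## Known limitations

* Hemizygous deletions are not modelled as distinct states.
* Duplication distance signatures are ignored by design; duplication
  power rests on depth and is weak below `cnv_duration` scales.
* The empirical insert distribution is fit from *all* retained pairs,
  so a genome very dense in deletions inflates its tail and slightly
  depresses sensitivity for the smallest grid sizes; on genome-scale
  data the contamination fraction is negligible, but at
  benchmark-scale densities (hundreds of events in a few Mbp) the
  effect is visible for 400 bp events.
* Viterbi reports the single best path; no per-call posterior
  probability is provided (the score column is an emission
  log-likelihood ratio, not a calibrated probability).
* A single sample is processed at a time; no joint multi-sample
  calling or genotype likelihoods.
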