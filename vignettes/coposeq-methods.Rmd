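---
title: "Simulating parallel-successive copolymer sequences and their selective digestion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating parallel-successive copolymer sequences and their selective digestion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coposeq)
library(dplyr)
```

## The problem

Degradable polyesters such as PLGA analogs have properties — degradation
rate above all — that depend not only on composition but on monomer
*sequence*. Parallel-successive (P-S) copolymerization gives coarse-grained
sequence control in a scalable way: two telechelic oligomer pools are made
separately (a diacid-ended pool from B-type diacid monomers S and U
alternating with the A-type diol G, and a diol-ended pool), and then coupled
into long chains in a second step. The cleavable monomer U carries an
olefin that selective cross-metathesis digestion severs; the molecular
weight distribution of the digestion fragments therefore reads out where
the U units sat in the chain.

`coposeq` is a Monte Carlo model of that whole pipeline: pool construction,
alternating assembly, in-silico digestion at every U, and block-length
statistics. It answers the design question: *given a total U budget, how
does splitting it between the short and long oligomer pools shape the
postdigestion block-length distribution?*

## The model

**Oligomer pools.** Each pool is described by its end-group type, a length
law, and a U fraction (`oligomer_pool()`). In disperse mode, oligomer
monomer counts follow the Flory most-probable distribution under
stoichiometric imbalance: because the excess monomer caps both chain ends,
only odd monomer counts occur,

$$P_x = (1-r)\,r^{(x-1)/2}, \quad x = 1, 3, 5, \dots$$

whose mean is Carothers' $\overline{DP} = (1+r)/(1-r)$. The imbalance ratio
targeting a mean DP is the inverse, $r = (\overline{DP}-1)/(\overline{DP}+1)$
(`imbalance_for_mean_dp()`). Discrete mode instead fixes every oligomer at
one odd monomer count, useful for exposing combinatorially forbidden block
lengths. Diacid oligomers run B G B … G B, so a DP-$x$ oligomer carries
$(x+1)/2$ B positions; diol oligomers run G B G … B G with $(x-1)/2$
internal B positions. Each B position is independently U with the pool's
`u_fraction` — feed ratios are met in expectation, as in statistical
incorporation, not as an exact quota.

**Assembly.** The coupling step treats the pools as macromonomers reacting
in alternating AA/BB fashion at 1:1 functional-group stoichiometry, stopped
at extent of reaction $p$; the number of oligomers per chain is then the
standard Flory law $P_y = (1-p)\,p^{y-1}$ with mean $1/(1-p)$. The working
conditions throughout are $p = 0.9$ (10 oligomers per chain on average)
with pool mean DPs 5 (diacid) and 10 (diol), which gives a mean chain
length of $\tfrac{1}{1-p}\cdot\tfrac{5+10}{2} = 75$ monomers. The starting
pool of each chain is chosen uniformly — the symmetric choice for an AA/BB
step growth, and the one under which that 75-monomer closed form holds
exactly. Junction chemistry guarantees strict A/B alternation across
oligomer boundaries, so no chain ever contains U-U adjacencies.

**Composition algebra.** At fixed overall U content $u$ the per-pool
fractions satisfy the B-count-weighted constraint
$f_\mathrm{acid}\frac{dp_a+1}{2} + f_\mathrm{diol}\frac{dp_d-1}{2}
 = u\left(\frac{dp_a+1}{2}+\frac{dp_d-1}{2}\right)$;
`solve_feed_fractions()` solves it for any split of the U budget and
reports infeasible splits (a pool that would need more than 100% U) by
name. At DPs 5/10 and 20% overall U this spans `(U50)_5-alt-(U0)_10`
(all U in the short pool) through the balanced `(U20)_5-alt-(U20)_10` to
`(U0)_5-alt-(U33)_10`, where "(U33)" is exactly 1/3, the value the budget
forces.

**Digestion.** `digest_chain()` / `simulate_digest()` cleave at every U;
the U monomer is destroyed, so $k$ U's give $k+1$ fragments. The two
flanking fragments carry a chain end (a terminal U leaves a zero-length end
stub), interior fragments are bounded by two cleavage sites, and U-free
chains persist as intact fragments. In an alternating chain an internal
fragment is G-flanked on both sides and hence always odd in monomer count;
only end fragments can be even. Zero-length stubs *are* counted as
fragments in all number statistics: fragment count and surviving monomer
count are then conserved exactly, which is what makes the number-average
postdigestion block length composition-independent at fixed overall U —
$\left(\frac{75 - 7.5}{7.5 + 1}\right)/2 = 3.97$ repeat units under the
working conditions, regardless of the split.

**Statistics.** With $N_i$ fragments of length $DP_i$,
$\overline{DP} = \sum DP_i N_i / \sum N_i$,
$\overline{DP}_l = \sum DP_i^2 N_i / \sum DP_i N_i$, and the block-length
dispersity is their ratio ($\text{Đ}_{DP} = 2$ for the most probable
distribution, larger for blockier microstructures). All averages are
computed on monomer counts and only divided by 2 for repeat-unit reporting;
binning monomer counts $2k$ and $2k+1$ into repeat-unit bin $k$ is applied
only when building histograms (`digest_histogram()`), which removes the
even/odd secondary distribution contributed by end fragments without
touching the averages. `sec_like_export()` presents the number-weighted
distribution on a log abscissa as SEC data are drawn; zero- and
sub-repeat-unit fragments are excluded there because their log size is
undefined, and a trace can be normalized to the maximum of a reference
trace for overlays.

## A worked comparison

```{r example}
ps <- simulate_digest(copolymer_spec(
  oligomer_pool("diacid", mean_dp = 5, u_fraction = 0.5),
  oligomer_pool("diol", mean_dp = 10),
  extent_p = 0.9, n_chains = 1e5, seed = 1
))
rand <- simulate_digest(random_analog_spec(0.2, 5, 10, p = 0.9,
                                           n_chains = 1e5, seed = 2))
bind_rows(glance(ps), glance(rand))
```

Both ensembles share the number-average block length; concentrating U in
the short diacid oligomers inflates the length-weighted average and the
dispersity (about 11.9 and 3.0 versus 8.0 and 2.0), because a typical
repeat unit then sits either in a very short block (between two nearby U's
of one diacid oligomer) or in a long U-free stretch.

## Parameters that matter

* `extent_p` (unitless, default 0.9 in the canned suites): sets oligomers
  per chain at $1/(1-p)$; 0.9 keeps molecular weight modest while leaving
  the block statistics converged.
* pool `mean_dp` / `discrete_dp` (monomers): 5/10 disperse reproduces the
  reference composition series; 5/11 discrete is the idealized case where
  confining U to the short pool makes repeat-unit lengths 3–4, 11–12,
  19–20 strictly impossible and 2, 10, 18 reachable only as end fragments.
* `u_fraction` per pool (fraction of B positions): set directly or via
  `solve_feed_fractions()` from an overall budget and a split.
* `n_chains`: the reference tables use $10^6$ chains; the package's own
  test suite runs the same pipelines at $10^4$–$10^5$ chains with
  correspondingly widened Monte Carlo tolerances, and examples here use
  $10^5$. `seed` is mandatory in every spec and echoed in every output.

## Numerical and design choices

* Lengths are sampled by closed-form inverse transform (geometric draws),
  not by materializing finite scaled-count pools; oligomers are drawn
  i.i.d. with replacement. At ensemble sizes of $10^5$ and up, pool
  depletion effects would be negligible, and the sampler is exact for the
  target laws.
* Chains are generated in chunks (default $10^5$ chains) so that
  million-chain runs hold only fragment histograms in memory. The
  sequence-materializing path (`simulate_ensemble()` →
  `digest_ensemble()`) and the streaming path (`simulate_digest()`) share
  one draw order, so the same seed and chunk size give exactly identical
  fragments — this equality is asserted in the tests.
* Degenerate inputs are defined, not special-cased: `r = 0` or `p = 0`
  give single-monomer / single-oligomer chains; a DP-1 diol oligomer is a
  bare G with zero B positions; a U at a chain terminus yields a
  zero-length end fragment that still counts.
* Dispersity is undefined (an error) when every fragment has zero length;
  in practice that requires an ensemble of bare-U chains.
* The optional `mass_map` of `sec_like_export()` assigns fragment masses
  assuming the alternating fragment starts with G — exact for internal
  fragments, at most half a monomer off for end fragments; the default
  abscissa is repeat units and involves no mass model.

## What the generator does and does not emulate

The simulator reproduces ideal step-growth statistics: equal end-group
reactivity, complete oligomerization, no cyclization, and full digestion at
every U. It deliberately does not model precipitation losses of
low-molecular-weight chains, the N-acylurea side reaction that consumes
diacid end groups in the real coupling step, partial digestion, or
SEC calibration/band-broadening. Passing tests therefore validate the
combinatorics and statistics of sequence placement and cleavage — not
quantitative agreement with experimental SEC traces, which the excluded
effects shift systematically (most visibly by depleting the low-MW region).

## Known limitations

* Finite-pool (without-replacement) oligomer consumption is not modeled.
* Only two pools are supported — the canonical P-S design; three-stream
  generalizations would need a different assembly rule.
* Fragment composition beyond length (e.g. exact G/S counts of end
  fragments) is not retained in the streaming path; use the materialized
  path when per-fragment sequences matter.
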