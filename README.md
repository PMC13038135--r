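# coposeq

Monte Carlo simulation of **parallel-successive (P-S) step-growth
copolymerization** with a cleavable comonomer, plus **in-silico selective
digestion** and block-length-distribution statistics.

## The problem

Semirandom degradable polyesters (PLGA analogs and relatives) can be made
by a parallel-successive strategy: two telechelic oligomer pools — a
diacid-terminated pool built from diacid monomers (inert **S** or cleavable
**U**) alternating with a diol **G**, and a diol-terminated pool — are
synthesized separately and then coupled into long chains. Cleaving the
finished copolymer at every **U** (experimentally, by cross-metathesis at
the olefin inside U) releases (GS)<sub>n</sub> fragments whose length
distribution is a direct readout of where the cleavable units sat. The
design question for anyone tuning such materials: *how does splitting a
fixed U budget between the short and long oligomer pools shape that
block-length distribution?*

`coposeq` models the whole pipeline for chemists and simulation folk
working on sequence-controlled step-growth polymers:

* **Pools** — oligomer lengths follow the Flory most-probable law under
  stoichiometric imbalance (odd monomer counts only),
  P<sub>x</sub> = (1−r)·r<sup>(x−1)/2</sup>, with Carothers mean
  DP̄ = (1+r)/(1−r); or exact discrete lengths. Each B position is U with
  the pool's feed fraction.
* **Assembly** — pools couple in strict alternation; oligomers per chain
  follow the standard Flory law P<sub>y</sub> = (1−p)·p<sup>y−1</sup> at
  extent of reaction p.
* **Digestion** — every U is severed (and destroyed): k U's → k+1
  fragments, classified internal / end / intact; internal fragments are
  always odd in monomer count.
* **Statistics** — number-average block length DP̄ = ΣDP·N / ΣN,
  length-weighted average DP̄<sub>l</sub> = ΣDP²·N / ΣDP·N, and block-length
  dispersity Đ<sub>DP</sub> = DP̄<sub>l</sub>/DP̄ (2 for the most probable
  distribution, higher for blockier chains), in monomer or repeat-unit
  (GS-pair) scale; number- and length-weighted histograms and SEC-like
  log-scale traces.

Everything is tibble-in / tibble-out with `tidy()` / `glance()` /
`autoplot()` methods, and a thin CLI (`exec/coposeq`) wraps the suites.

## Worked example

Concentrate all of a 20% U budget in the short diacid pool
(`(U50)_5-alt-(U0)_10`) and compare with the balanced, statistically random
split:

```r
library(coposeq)

spec <- copolymer_spec(
  oligomer_pool("diacid", mean_dp = 5, u_fraction = 0.5),
  oligomer_pool("diol",   mean_dp = 10),
  extent_p = 0.9, n_chains = 1e5, seed = 1
)
simulate_digest(spec)
#> <digest_result> 1e+05 chains, 750,425 cleavages, 850,425 fragments
#>   spec: (U50)_5-alt-(U0)_10 seed 1
#>   block length (repeat units): dp_n 3.983, dp_l 11.982, dispersity 3.008

glance(simulate_digest(random_analog_spec(0.2, 5, 10, p = 0.9,
                                          n_chains = 1e5, seed = 2)))
#> # A tibble: 1 × 9
#>   label     scale        dp_n  dp_l dispersity n_fragments n_chains n_cleavages  seed
#>   <chr>     <chr>       <dbl> <dbl>      <dbl>       <int>    <dbl>       <dbl> <int>
#> 1 Rand(U20) repeat_unit  3.98  8.00       2.01      851955   100000      751955     2
```

Both compositions share the number-average block length (≈3.97 repeat
units — a conservation identity at fixed overall U), but confining U to the
short oligomers fattens both distribution tails: the length-weighted
average rises from ≈8.0 to ≈12.0 repeat units and the dispersity from
≈2.0 to ≈3.0. `run_usplit_series(n_chains, seed)` sweeps all twelve
published U-splits at once; `run_blocklength_panels("discrete", ...)` shows the
discrete-pool case where whole bands of block lengths (3–4, 11–12, 19–20
repeat units) are combinatorially impossible.

Single objects are just as inspectable:

```r
digest_chain("SGSGUGSGS")
#> # A tibble: 2 × 5
#>   fragment sequence monomer_count repeat_units origin
#>      <int> <chr>            <int>        <int> <chr>
#> 1        1 SGSG                 4            2 end
#> 2        2 GSGS                 4            2 end
```

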