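# gameticsel

Competition among pollen or sperm — *gametic selection* — depends on who
competes against whom, and that is set by the mating system: monandry versus
polyandry, selfing versus outcrossing.  Monandry and selfing both shrink the
competitive arena to a single male's gametes, blunting gametic selection;
conversely, by changing offspring fitness, mutation load, and inbreeding
depression, gametic selection feeds back on how mating systems themselves
evolve.  `gameticsel` is a toolkit for population geneticists and
evolutionary biologists to analyse this two-way interaction quantitatively.

It implements the same model at three mutually validating levels:

1. **Per-locus fitness** (`fitness_scheme()`): adult fitness `1 + s_g^h` by
   genotype `g ∈ {AA, Aa, aa}` and sex role `h`, plus gametic selection of
   strength `σ` under any expression pattern `d` from haploid (`d = 0`) to
   diploid (`d = 1`), with masking `γ(x) = 1 − (1 − x^H)^(1/H)`.
2. **Weak-selection analytics**: compound selection terms and invasion
   coefficients `I_α = s̄_α^f/2 + (s̄_α^{m,d} + s̄_α^{m,g})/2`; equilibria
   `q̂_μ = μ/(−I_a)` (mutation–selection balance) and
   `q̂_B = I_a/(I_A + I_a)` (balancing selection); spread rates `λ` of
   mating-system modifier alleles on both axes; genome-wide mutation load,
   inbreeding depression `δ̄`, and net modifier selection
   `s_tot = Σ(λ_l − 1)`, including the selfing transmission advantage
   `(1 − c)/2` under pollen discounting `c`.
3. **Exact machinery**: deterministic two-locus recursions over the full
   diploid genotype distribution (`find_equilibrium()`,
   `numerical_invasion()`) and an individual-based multilocus Wright–Fisher
   simulator of hermaphrodites with explicit gamete competition
   (`simulate_population()`).

All user-facing functions take plain inputs or data frames and return
tibbles; fitted objects support `tidy()`, `glance()`, and `autoplot()`.

## A worked example

How strongly does a genome full of deleterious mutations select for
polyandry in a monandrous population?  Take partially recessive deleterious
alleles (`s_Aa = −0.01`, `s_aa = −0.05`, `H = 2`) under gametic selection
`σ = 0.12` with haploid expression, a genome-wide deleterious mutation rate
`U = 1`, and a modifier that makes its carriers fully polyandrous:

```r
library(gameticsel)

sch <- scheme_deleterious()           # σ = 0.12, d = 0
invasion_coefficients(sch, "polyandry", level = 0)
#> # A tibble: 1 × 5
#>     I_A   I_a mode      level     F
#>   <dbl> <dbl> <chr>     <dbl> <dbl>
#> 1  0.07 -0.04 polyandry     0     0

genome_spec(sch, "polyandry", level = 0, U = 1, k = 1) |>
  genome_summary(delta_mod = 0.5) |>
  dplyr::select(load, delta_bar, s_tot)
#> # A tibble: 1 × 3
#>    load delta_bar  s_tot
#>   <dbl>     <dbl>  <dbl>
#> 1 0.393     0.303 0.0150
```

A rare allele of the deleterious class is removed at rate `I_a = −0.04` per
generation, so mutation maintains it at frequency `μ/0.04` per locus; summed
over the genome the polyandry modifier gains `s_tot = 0.015` — a 1.5%
per-generation advantage, and an upper bound on the direct cost polyandry
could bear.  The same pipeline shows a dominant full-selfing allele gains
`(1 − c)/2 = 50%` per generation without pollen discounting
(`lambda_selfing_leading(-1, c = 0, level = 1)`), so outcrossing is stable
only when genome-wide inbreeding depression exceeds `selfing_threshold(0) =
0.5` — and gametic selection, by purging deleterious alleles, can pull `δ̄`
below that threshold and open the door to selfing.

Every analytic claim can be cross-checked against the exact recursions:

```r
mod <- modifier_scheme("polyandry", level_MM = 0, level_Mm = 0.2)
glance(numerical_invasion(sch, mod, mu = 1e-4))   # measured λ of the rare modifier
```

Experiment-level sweeps (load and `δ̄` across mating systems, the
`s_tot` surface over `U` and the number of balancing-selection loci, the
direction-of-evolution matrix, optional simulator overlays) are available
through `run_experiment()` and from the shell:

```sh
Rscript scripts/arena.R load_sweep --mode outcrossing --out results/
Rscript scripts/arena.R invasion_check --numerical
Rscript scripts/arena.R validate
```

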