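---
title: "Gametic selection and the evolution of mating systems: the model behind gameticsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gametic selection and the evolution of mating systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gameticsel)
```

## The model

Males (or the male function of hermaphrodites) produce far more gametes than
can fertilise, so pollen and sperm compete.  Who competes against whom is set
by the mating system: under **polyandry** or **outcrossing** a female gamete
samples from a population-wide pool of male gametes, whereas under
**monandry** the pool comes from a single mate and under **selfing** from the
same individual.  `gameticsel` models a single biallelic locus **A** whose
alleles affect fitness at three life-cycle stages — female adults, male
adults, and male gametes — together with a modifier locus **M** that sets the
mating system, and then extrapolates to a genome of such loci.

Per-locus fitness is held in a `fitness_scheme`: adult fitnesses are
$1 + s^{\,h}_g$ for genotype $g \in \{AA, Aa, aa\}$ and sex role
$h \in \{f, m\}$.  Gamete fitness depends on how much of the
gamete's own haploid genotype is expressed.  With expression pattern
$d \in [0, 1]$ ($d = 0$ fully haploid, $d = 1$ fully diploid), an $A$ gamete
from an $Aa$ male expresses a proportion $d/2$ of the deleterious allele and
has fitness $1 - \gamma(d/2)\,\sigma$, an $a$ gamete $1 - \gamma(1 - d/2)\,
\sigma$, with $\gamma(x) = 1 - (1 - x^H)^{1/H}$; $aa$ males make $a$ gametes
of fitness $1 - \sigma$ and $AA$ males set the reference of 1.  The gametic
dominance $H$ defaults to 2 (the fitter allele dominant), so partially
diploid expression masks deleterious alleles in gametes just as diploidy
masks them in adults.  At $d = 1$ both gamete types from a heterozygote are
equally fit: combined with monandry this removes gametic selection entirely,
because a single male's pool then has no fitness variation.

### Weak-selection analytics

Writing $\Pi$ for the proportion of polyandry and $\Omega$ for the
proportion of outcrossing (with inbreeding coefficient
$F = (1-\Omega)/(1+\Omega)$ at neutral equilibrium), the fate of a rare
allele $\alpha$ is governed by three compound terms — selection through
females $\bar s^{\,f}_\alpha$, through diploid males
$\bar s^{\,m,d}_\alpha$, and through male gametes
$\bar s^{\,m,g}_\alpha$ (`selection_terms()`) — combining into the
invasion coefficient

$$I_\alpha \approx \tfrac12 \bar s^{\,f}_\alpha +
  \tfrac12 \left(\bar s^{\,m,d}_\alpha + \bar s^{\,m,g}_\alpha\right).$$

Deleterious alleles ($I_a < 0$) equilibrate at mutation–selection balance
$\hat q_\mu = \mu / (-I_a)$; when both alleles are favoured while rare
($I_A, I_a > 0$; overdominance, sexually or ploidally antagonistic
selection) a protected polymorphism sits at
$\hat q_B = I_a / (I_A + I_a)$.  The `lambda_*()` functions give the
per-generation spread rate of a rare mating-system modifier: polyandry is
favoured by loci at mutation–selection balance, monandry by balancing
selection (unless expression is diploid, which makes the modifier neutral),
and the selfing–outcrossing axis is dominated by the automatic transmission
advantage of selfing, $(1-c)/2$ for pollen discounting $c$, against which
genome-wide inbreeding depression $\bar\delta$ competes: outcrossing is
stable when $\bar\delta > (1-c)/2$ (`selfing_threshold()`).

Genome-wide quantities assume unlinked loci with multiplicative,
non-epistatic fitness, so per-locus equilibria compose:
$\text{load} = 1 - \prod_l \bar w_l$,
$\bar\delta = 1 - \prod_l (1 - \delta_l)$, and net modifier selection
$s_{tot} = \sum_l (\lambda_l - 1)$ (`genome_summary()`).
Mutation–selection-balance sums depend on the per-locus rate $\mu$ and the
number of loci $l_\mu$ only through $U = \mu\, l_\mu$, because each
per-locus contribution is proportional to $\hat q_\mu \propto \mu$; the
nominal `mu` in `genome_spec()` (default $10^{-6}$) only controls
higher-order terms and results are insensitive to it (this is asserted by a
test).

### Exact two-locus recursions

Every approximation above is checked against exact deterministic recursions
(`step_two_locus()`, `find_equilibrium()`, `numerical_invasion()`).  The
state is the full unordered diploid distribution over the four haplotypes
{AM, Am, aM, am} — ten genotypes, with cis and trans double heterozygotes
kept apart because they recombine differently.  A haplotype-frequency state
would not suffice: selfing generates departures from Hardy–Weinberg that
only a diploid state can carry.  One generation applies, in order:
sex-specific fecundity weighting of mothers and fathers; gametogenesis with
recombination $r$, gametic-fitness weighting of male gametes, then one-way
$A \to a$ mutation; and fertilisation.  Monandrous mothers average over
fathers drawn by male fitness with each father's pool normalised
internally; polyandrous/outcross mothers draw from the global pool
normalised once (so a male's mean gametic fitness affects his siring
share); selfing mothers use their own pool; an individual's contribution to
the outcross pool is scaled by $1 - c(1 - \Omega_i)$, which is what makes
the transmission advantage come out as $(1-c)/2$ and vanish at $c = 1$.

## Numerical choices

* **Mutation after gametic selection.**  The gamete fitness table defines
  fitness for gametes whose allele is consistent with their father;
  applying selection to the pre-mutation gamete and mutating afterwards
  avoids inventing fitnesses for mutant–father mismatches and differs from
  the opposite order only at $O(\mu\sigma)$.
* **Equilibria** iterate to a per-genotype change below `tol = 1e-12`
  (cap `max_gen = 5e5`, with geometric progress checks that abort
  non-contracting runs).  Convergence is geometric at the leading selection
  rate, so typical solves take hundreds to thousands of generations.
* **Invasion growth rates** are measured as
  $(\log q_m(T) - \log q_m(T - W))/W$ after a burn-in that lets the mutant
  lineage's genotype structure equilibrate; the mutant is injected at
  $q_{init} \le 10^{-6}$ in linkage equilibrium and must stay below
  $10^{-3}$ throughout, otherwise the fit aborts with advice to lower
  $q_{init}$.  Because the recursion is deterministic, growth rates are
  resolvable to ~$10^{-12}$, which is what makes oracle tests of
  $\lambda - 1$ values as small as $10^{-7}$ meaningful.
* **Convergence order.**  The analytic $\lambda$ formulas are leading-order
  in the selection scale $\epsilon$ (adult $s$, $\sigma$, and the modifier
  effect $\Delta$ are all of order $\epsilon$).  Halving all of them
  shrinks the numerical-minus-analytic discrepancy at least ~4-fold
  (some corrections are cubic and shrink ~8-fold); the test suite asserts
  the at-least-quadratic behaviour.
* **Degenerate limits.**  At $\Omega = 0$ the leading-order equilibrium is
  independent of $\sigma$ and $d$, but the exact recursions retain an
  $O(\mu)$ heterozygote inflow whose gametic purging shifts $\hat q$ by a
  relative $\sim 0.2\sigma$ (a few percent, independent of $\mu$); tests
  bound this correction rather than pretending exactness.  The
  $(\Pi = 0, d = 1)$ degeneracy is exact and tested at $10^{-10}$.

## The simulator: what it emulates and what it does not

`simulate_population()` is an individual-based Wright–Fisher model of
$N$ diploid hermaphrodites with $L$ unlinked loci (free recombination),
multiplicative fitness, soft selection (mothers drawn with replacement by
female fitness, constant $N$).  Locus classes (gametic-selected
mutation–selection balance, non-gametic, balancing) are placed uniformly at
random using the configuration seed — dynamically irrelevant under free
recombination, retained for protocol fidelity.  Each fertilisation event
draws `gamete_ratio` (default 10) candidate male gametes from the source
the mating system dictates — the population (fathers by male fitness),
the mother's single designated mate under monandry (that mate drawn by male
fitness, consistent with fitness-based mate sampling elsewhere), or the
mother herself under selfing — and the pool competes by multiplicative
gametic fitness.  Drawing a fresh pool per event (rather than one large
per-father pool consumed without replacement) leaves the marginal offspring
distribution unchanged while keeping memory bounded.  Inbreeding depression
is measured by building a parallel selfed cohort from the same mothers and
comparing mean offspring fitness, mirroring the analytic definition.

The simulator deliberately omits: linked loci and recombination maps,
pollen discounting (simulations compare fixed mating systems; modifier
invasion is the analytics' and engine's job), distributions of fitness
effects across loci (uniform effects per class), and ecological forces such
as reproductive assurance.  Passing simulation tests therefore validate the
population-genetic machinery, not those omitted processes; in real data,
linkage, effect-size variation, and ecology will all loosen the
correspondence.

### Default study conditions and problem sizes

The reference conditions are a genome-wide deleterious mutation rate
$U = 1/2$, partially recessive deleterious alleles
($s_{Aa} = -0.01$, $s_{aa} = -0.05$, $H = 2$) with gametic selection up to
$\sigma = 0.12$ under haploid-like expression, and ploidally antagonistic
or overdominant schemes for balancing selection
(`scheme_deleterious()`, `scheme_antagonistic()`, `scheme_overdominant()`).
Full-scale simulations use $N = 5000$, $L = 100$, 50,000 generations and
three replicates; the package's default *desk scale*
($N = 500$, $L = 50$, 5,000 generations, statistics over the final ~1,500
generations) keeps a full cross-validation sweep in the minutes range while
preserving every qualitative contrast, at the price of a larger per-locus
$\mu = U/L$ (the weak-mutation approximation is then visibly strained for
weakly selected, non-gametic loci) and more drift noise.  The
`scale = "paper"` switch in `run_experiment()` restores the full protocol.

## Known limitations

The genome-wide composition ignores linkage disequilibrium and identity
disequilibrium between loci, so it is least accurate at intermediate
selfing rates, where associations among loci matter most — the
cross-validation tests encode exactly this expectation.  The analytic
spread rates are leading-order: modifiers of large effect (e.g. a jump from
full selfing to full outcrossing) are handled by the exact engine, not the
formulas.  Two alleles per locus, one-way mutation, and a single modifier
locus are structural assumptions throughout.

## A worked example

```{r example, eval = FALSE}
library(gameticsel)

# how strongly does a mutation-loaded genome select for polyandry?
sch <- scheme_deleterious()                       # sigma = 0.12, d = 0
genome_spec(sch, "polyandry", level = 0, U = 1) |>
  genome_summary(delta_mod = 0.5)                 # s_tot = 0.015

# cross-check a spread-rate formula against the exact recursions
mod <- modifier_scheme("polyandry", level_MM = 0, level_Mm = 0.2, c = 1)
fit <- numerical_invasion(sch, mod, mu = 1e-4)
glance(fit)

ic <- invasion_coefficients(sch, "polyandry", 0)
lambda_polyandry_msb(sch, 0, modifier_delta(mod), q_hat_msb(1e-4, ic$I_a))
```
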