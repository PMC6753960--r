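---
title: "Managing genetic diversity in subdivided populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing genetic diversity in subdivided populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Conservation programs for structured populations (zoos, germplasm
collections, fragmented wild populations) must decide, every generation,
which parents reproduce, how often, with whom, and which offspring move
between subpopulations. Two currencies of neutral genetic diversity compete
for attention: *expected heterozygosity*, which tracks short-term additive
variance, and *allelic diversity* (the number of alleles per locus), which
is more sensitive to bottlenecks and tracks long-term adaptive potential.
`metapopman` implements, as a reusable and tested package, a simulation
study that compares management strategies maximising one or the other in a
subdivided population genotyped at multiallelic SNP-haplotype markers.

## The simulated system

The base population is produced by a forward neutral Wright--Fisher
simulator over a 10 kb diploid binary sequence:

* per-site flip mutation at rate $\mu = 5\times10^{-5}$ per generation,
* per-boundary recombination at rate $c = 10^{-6}$ (a variant at
  $10^{-5}$ is supported),
* an ancestral monoecious deme of $N = 4{,}000$ run for 5,000 generations
  towards mutation--drift equilibrium,
* five demes (2,000; 100; 100; 100; 100) founded from it by sampling
  without replacement and drifting independently for 25 generations,
* founder samples of 40 individuals (20 of each sex) per deme.

**Mutation model.** Sites are binary (ancestral/derived) with a symmetric
flip. This keeps every SNP biallelic, so a 5-SNP marker window has at most
$2^5 = 32$ alleles -- the marker construct the management study is built
on. A consequence worth stating precisely: the equilibrium gene diversity
of a binary site under symmetric two-way mutation is

$$ H = \frac{\theta}{1 + 2\theta}, \qquad \theta = 4N\mu, $$

(derived from the exact two-lineage identity-in-state recursion
$F = a\,(c + (1-c)F) + b\,(1-c)(1-F)$ with $a = (1-\mu)^2 + \mu^2$,
$b = 2\mu(1-\mu)$, $c = 1/2N$), *not* the infinite-alleles form
$\theta/(1+\theta)$: a binary site saturates at $H = 1/2$. At the study's
$\theta = 0.8$ the equilibrium is $H \approx 0.308$, and the calibration
tests assert exactly this closed form. At these parameters essentially
every 5-site window segregates in the pooled founder sample, so the
package's base populations expose about 2,000 segregating marker loci
rather than the circa 1,200 a 4-state nucleotide simulator can produce;
all diversity statistics and optimisers are unaffected by this difference
in marker supply.

**Scaling.** Full-scale ancestral runs are expensive, but every
population-genetic expectation involved depends on the compound parameters
$\theta = 4N\mu$, $4Nc$ and time in units of $N$. `scaled_setup()` and the
`"desk"` study profile therefore multiply $\mu$ and $c$ by a factor and
divide $N$ and generation counts by it. The desk profile uses scale 10
($N = 400$, 500 ancestral generations), demes of (200, 40, 40, 40, 40)
drifting 10 generations (about the same drift time in units of $2N$ as 25
generations at size 100), and a full-sized management phase. Tests use
these desk sizes; the `"paper"` profile runs the full design.

## Markers

Marker loci are fixed, consecutive 5-site windows (`build_locus_map()`),
polymorphic or not, so a 10 kb map has exactly 2,000 candidate loci; the
5-bit window haplotype is the allele, leftmost site as the most significant
bit (an arbitrary but round-trip-tested convention). The managed panel
takes every 100th (or 10th) segregating locus starting from the first; at
$c = 10^{-6}$ the two panels correspond to densities of roughly 1,200 and
12,000 markers per Morgan. Monomorphic windows are excluded from management
but included in whole-genome measurement.

## Diversity partitions

All statistics weight demes equally and average over loci. For allele
frequencies $p_{i,a}$ in deme $i$:

* $H_S$ = mean over demes of $1 - \sum_a p_{i,a}^2$;
* $D_G$ = Nei's minimum distance $\sum_a (p_{i,a}-p_{j,a})^2/2$ averaged
  over all $n^2$ *ordered* deme pairs (self-pairs contribute zero);
* $H_T = H_S + D_G$.

The ordered-pair convention is chosen because it makes the decomposition
exact: $H_T$ then equals the heterozygosity of the equally weighted pooled
frequencies, which the tests assert to $10^{-12}$. For allelic diversity,
with $a_i$ the allele count of deme $i$:

* $A_S$ = mean over demes of $a_i$, minus one;
* $D_A$ = the symmetrised private-allele count
  $\tfrac12(|i \setminus j| + |j \setminus i|)$ averaged over unordered
  pairs;
* $A_T = A_S + D_A$, which equals the mean pair-union allele count minus
  one -- again an exact, tested identity.

$K$ counts distinct alleles in the pooled population (reported per locus,
with the raw sum as a secondary column). Molecular inbreeding $F$ is the
observed fraction of homozygous marker loci per individual (identity by
descent plus identity in state). `VarFreq` is the population variance of
pooled frequencies across each locus's *management-start* allele set, lost
alleles entering as zeros -- the denominators and the baseline set are
conventions fixed here and recorded in the output metadata.

## The optimiser

A contribution plan assigns each offspring slot (40 per destination deme) a
natal deme and a sire and dam from that deme; offspring whose natal deme
differs from their destination are migrants. The migration level $m$
(migrants per deme per generation; 0.4, 1 or 2) is enforced as a fixed
population-wide total of $\mathrm{round}(m \times n_\text{demes})$ migrant
slots -- a mean constraint, not a per-deme cap, since the study reports a
nonzero variance of migrant numbers across subpopulations. Plans therefore
realise the budget exactly in every generation.

Objectives evaluated on the expected progeny:

* **maxHT**: $D_G + \lambda H_S$ of the expected progeny frequencies
  $p' = \sum_k g_{k,s}\,x_{k,a}/2N_s$, with $x_{k,a}$ the parent's
  Mendelian transmission probability;
* **maxAT**: $E[D_A] + \lambda E[A_S]$ built from per-allele retention
  probabilities $R = 1 - P_\text{loss}$, where
  $P_\text{loss}(a,s) = \prod_k (1/2)^{g_{k,s}}$ over heterozygous
  carriers (0 with any homozygous carrier, 1 with none). Expected allelic
  components treat alleles and demes as independent -- the exact joint law
  is combinatorial, and this is the standard expected-loss approximation;
* **maxK**: minus the expected number of global losses,
  $-\sum_{l,a} \prod_s P_\text{loss}(a,s)$ over the parental allele set;
* **RND**: the unmanaged control -- uniform random parents, no migration.
  (Isolated-deme RND matches the control's fast inbreeding rise; a random-
  migration variant can be built by passing an explicit plan.)

The search is simulated annealing with Metropolis acceptance and geometric
cooling. Default schedule: initial temperature calibrated on 100 probe
moves so a typical worsening move is accepted with probability one half,
cooling 0.95, 200 moves per temperature, 30,000 iterations (the desk
profile uses 3,000/100). Ties keep the incumbent best plan and the best
plan visited is returned, so the final score never falls below the initial
one; identical seeds give identical plans.

**Move set.** Moves preserve per-destination totals, within-deme matings
and the migrant total: (a) a slot adopts another same-destination mating of
equal migrant status; (b) one parent of a mating is replaced within its
natal deme; (c) two offspring in different destinations swap destinations
when that preserves the migrant count; (d) a migrant is re-sourced from a
different natal deme; (e) a migrant is demoted to a resident while a
resident elsewhere is promoted to a migrant. Moves (d) and (e) are
essential and easy to overlook: with (a)-(c) alone both the per-natal-deme
contribution totals and the per-destination migrant counts are invariants,
so the search could never redistribute migration -- the plan graph is
disconnected. With all five kinds a random walk reaches every feasible
canonical plan of a small instance, which the tests verify by exhaustive
enumeration, and annealed plans match brute-force optima for all three
objectives.

## The management loop and study harness

Each generation: optimise contributions on the managed panel, realise
progeny by Mendelian sampling of whole locus alleles (no recombination
within a 5-SNP locus, free recombination between loci, no new mutation
during the 25 managed generations -- making "no locus ever gains alleles"
a testable invariant), fill each deme's 20/20 sex quota at random, record
statistics. Generations are discrete. When the measurement scope is the
managed panel itself, unmanaged loci are dropped internally for speed; the
whole-genome scenario carries and measures all 2,000 loci while optimising
only the panel.

`run_study()` replicates the design (10 base replicates x 10 samplings at
full scale; 5 x 5 on the desk profile) over the factorial of methods,
lambdas, migration levels and scenarios, with one derived seed per stage so
results are independent of execution order, and reports per-cell means and
standard errors.

## What the tests do and do not show

The synthetic-data generator emulates neutral, constant-size,
discrete-generation demes with known history. It does not emulate
selection, variable deme sizes, overlapping generations, genotyping error
or real marker ascertainment, so passing tests demonstrate correctness of
the algorithms and the internal consistency of the study -- not that any
particular wild population will show the same trajectories. Monte-Carlo
tests run at desk scale under fixed seeds: equilibrium calibration uses
$N = 200$, $\theta = 0.8$, 800 generations and 20 replicates; ordering
checks use 50 desk-profile runs per method at generation 25; optimality
checks use 2-deme instances small enough for exhaustive search. Numerical
conventions worth restating: population (biased) variances throughout;
equal deme weights; allele universes fixed at the 32 codes; degenerate
inputs (single deme, zero migrants, monomorphic loci, zero generations)
are exercised explicitly in the unit tests.

## Known limitations

* The binary mutation model caps per-site diversity at 0.5 and saturates
  marker supply at these parameter values (see above); studies needing a
  literal 4-state nucleotide sequence should treat the simulator's sites
  as SNP states, not nucleotides.
* Expected allelic objectives use the independence approximation across
  alleles and demes; exact joint retention is enumerated only in tests on
  tiny instances.
* The annealer is stochastic: on large instances it returns a good plan,
  not a certified optimum.
* Genealogical coancestry, linear-programming contribution solvers and
  overlapping generations are out of scope.
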