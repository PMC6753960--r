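# metapopman

Optimal management of genetic diversity in subdivided populations.

Conservation programs for structured populations must choose, each
generation, the parental contributions, matings and migrations that best
preserve genetic diversity. Two standard but competing targets exist:
**expected heterozygosity** (short-term additive variance) and **allelic
diversity** (long-term adaptive potential, sensitive to bottlenecks).
`metapopman` implements the full simulation machinery to compare such
strategies in a subdivided population genotyped at multiallelic
SNP-haplotype markers, for population geneticists and conservation-program
designers:

* a forward neutral **Wright–Fisher simulator** (binary 10 kb sequence,
  per-site flip mutation, per-boundary recombination) that builds a
  five-deme base population from a mutation–drift-equilibrium ancestor;
* **marker construction**: haplotypes of five consecutive SNPs as loci,
  each 5-bit window haplotype an allele (at most 32 per locus);
* **diversity partitions**, per locus and averaged over equally weighted
  demes:

  H<sub>T</sub> = H<sub>S</sub> + D<sub>G</sub> — within-deme gene
  diversity plus Nei's minimum distance averaged over ordered deme pairs
  (exactly the pooled-frequency heterozygosity);

  A<sub>T</sub> = A<sub>S</sub> + D<sub>A</sub> — mean within-deme allele
  count (−1) plus the mean symmetrised private-allele count over deme
  pairs (exactly the mean pair-union allele count −1);

  plus K (total alleles), molecular inbreeding F, VarFreq, and the plan
  statistics nMates, VarContFem, VarMigrants;
* a **simulated-annealing optimiser** of contribution/mating/migration
  plans under the objectives maxH<sub>T</sub> (maximise
  D<sub>G</sub> + λH<sub>S</sub> of the expected progeny),
  maxA<sub>T</sub> (maximise D<sub>A</sub> + λA<sub>S</sub> from
  per-allele Mendelian retention probabilities), maxK (minimise expected
  global allele losses), and an RND unmanaged control, with a fixed
  migrant budget of `round(m × n_demes)` offspring per generation;
* a **management loop** (optimise → Mendelian reproduction → measure, 25
  generations) and a **replication harness** with `"paper"` (full-scale)
  and `"desk"` (scaled, θ- and drift-preserving) profiles.

## Worked example

```r
library(metapopman)
set.seed(2024)

cfg      <- study_profile("desk")          # scaled study conditions
base     <- simulate_base(cfg)             # ancestor + five demes
founders <- sample_founders(base, 40)      # 40 per deme, 20 of each sex
gm       <- encode_genotypes(founders)     # 5-SNP haplotype alleles

panel <- select_managed(segregating_loci(gm), every_nth = 100)
diversity_report(gm, panel$loci)[, 1:10]
#>    H_S    D_G    H_T    A_S   D_A   A_T     K  K_total      F VarFreq
#> 0.7033 0.0585 0.7619 5.2600 2.120 7.380 11.35      227 0.2908  0.0145

run <- run_management(gm, objective("maxAT", lambda = 1, migrants = 1),
                      gens = 25, managed = panel, schedule = cfg$schedule)
run$report[c(1, 6, 26), c("generation", "H_T", "A_T", "K", "F", "VarMigrants")]
#>    generation    H_T  A_T     K      F VarMigrants
#> 1           0 0.7619 7.38 11.35 0.2908          NA
#> 6           5 0.7800 8.42 10.95 0.2470         1.2
#> 26         25 0.8107 9.09 10.55 0.2262         0.4
```

Reading the numbers: managing for total allelic diversity raised
A<sub>T</sub> from 7.38 to 9.09 and *lowered* molecular inbreeding
(F: 0.291 → 0.226) over 25 generations, while keeping ~10.6 of the
baseline 11.35 alleles per locus — the behaviour that makes
maxA<sub>T</sub> attractive for structured populations. Every plan carries
exactly one migrant per deme per generation (the budget), with the
reported variance across demes.

A whole replicated comparison is one call:

```r
res <- run_study(study_profile("desk"))   # 5 x 5 replicates, 4 methods
plot_trajectories(res)                    # H_T, A_T, K, F vs generation
write_outputs(res, "study_out")           # summary.csv, runs.csv, config.json
```

A thin CLI over the same functions lives in `inst/cli/metapopman.R`
(`simulate-base`, `optimize`, `evaluate`, `manage`, `study`).

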