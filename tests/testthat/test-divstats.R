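make_ft <- function(...) {
  # build a frequency table from per-deme frequency vectors (one locus)
  rows <- list(...)
  p <- array(0, c(length(rows), 32, 1))
  for (d in seq_along(rows))
    p[d, seq_along(rows[[d]]), 1] <- rows[[d]]
  freq_table(p)
}

test_that("allele frequencies are copy counts over 2N", {
  gm <- geno_matrix(matrix(c(0L, 0L, 1L), 3, 1),
                    matrix(c(1L, 0L, 1L), 3, 1),
                    deme = rep(1L, 3), sex = c("F", "M", "F"))
  ft <- allele_freqs(gm)
  expect_equal(ft$p[1, 1, 1], 0.5)  # AA, AB, BB -> p_A = 3/6
  expect_equal(ft$p[1, 2, 1], 0.5)
  one <- geno_matrix(matrix(4L), matrix(7L), deme = 1L, sex = "F")
  expect_equal(allele_freqs(one)$p[1, c(5, 8), 1], c(0.5, 0.5))
  hom <- geno_matrix(matrix(2L, 2, 1), matrix(2L, 2, 1),
                     deme = c(1L, 1L), sex = c("F", "M"))
  expect_equal(allele_freqs(hom)$p[1, 3, 1], 1)
})

test_that("the Nei heterozygosity partition matches hand-computed cases", {
  r <- het_partition(make_ft(c(1, 0), c(0, 1)))
  expect_equal(c(r$H_S, r$D_G, r$H_T), c(0, 0.5, 0.5))
  r <- het_partition(make_ft(c(0.5, 0.5), c(0.5, 0.5)))
  expect_equal(c(r$H_S, r$D_G, r$H_T), c(0.5, 0, 0.5))
  r <- het_partition(make_ft(c(0.75, 0.25), c(0.25, 0.75)))
  expect_equal(c(r$H_S, r$D_G, r$H_T), c(0.375, 0.125, 0.5))
})

test_that("H_T equals pooled-frequency heterozygosity on random tables", {
  set.seed(31)
  for (r in 1:50) {
    ft <- rand_ft(D = sample(1:5, 1), L = sample(1:6, 1))
    expect_equal(het_partition(ft)$H_T, pooled_het(ft), tolerance = 1e-12)
  }
})

test_that("the allelic partition matches hand-computed cases and its identity", {
  r <- allelic_partition(make_ft(c(0.5, 0.5, 0), c(0, 0.5, 0.5)))
  expect_equal(c(r$A_S, r$D_A, r$A_T), c(1, 1, 2))  # {A,B} vs {B,C}
  r <- allelic_partition(make_ft(c(0.5, 0.5), c(0.5, 0.5)))
  expect_equal(c(r$A_S, r$D_A, r$A_T), c(1, 0, 1))
  r <- allelic_partition(make_ft(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  expect_equal(c(r$A_S, r$D_A, r$A_T), c(0, 1, 1))
  set.seed(32)
  for (i in 1:50) {
    ft <- rand_ft(D = sample(2:5, 1), L = sample(1:6, 1))
    expect_equal(allelic_partition(ft)$A_T, pair_union_alleles(ft),
                 tolerance = 1e-12)
  }
})

test_that("K counts pooled distinct alleles and never grows by dropping a deme", {
  expect_equal(total_alleles(make_ft(c(0.5, 0.5, 0, 0), c(0, 0, 0.5, 0.5)))$K, 4)
  expect_equal(total_alleles(make_ft(1))$K, 1)  # monomorphic locus counts 1
  set.seed(33)
  for (i in 1:20) {
    ft <- rand_ft(D = 4, L = 3)
    k_all <- total_alleles(ft)$K
    sub <- freq_table(ft$p[-sample(1:4, 1), , , drop = FALSE])
    expect_lte(total_alleles(sub)$K, k_all)
    # K is at least the largest per-deme allele count
    per_deme <- apply(ft$p > 0, 1, function(m) mean(colSums(matrix(m, 32))))
    expect_gte(k_all, max(per_deme))
  }
})

test_that("statistics are invariant to deme and individual order", {
  set.seed(34)
  gm <- rand_gm(D = 3, n = 6, L = 5, K = 5)
  ft <- allele_freqs(gm)
  base <- c(unlist(het_partition(ft)[1:3]), unlist(allelic_partition(ft)[1:3]),
            total_alleles(ft)$K, molecular_F(gm))
  # permute demes (relabel) and individuals within demes
  perm <- c(3, 1, 2)
  ord <- order(perm[gm$deme], sample(18))
  gm2 <- geno_matrix(gm$a1[ord, ], gm$a2[ord, ], deme = sort(perm[gm$deme]),
                     sex = gm$sex[ord])
  ft2 <- allele_freqs(gm2)
  again <- c(unlist(het_partition(ft2)[1:3]), unlist(allelic_partition(ft2)[1:3]),
             total_alleles(ft2)$K, molecular_F(gm2))
  expect_equal(again, base, tolerance = 1e-12)
})

test_that("molecular inbreeding is the fraction of homozygous loci", {
  a1 <- matrix(c(1L, 1L, 2L, 3L), 1)
  a2 <- matrix(c(1L, 1L, 5L, 7L), 1)
  gm <- geno_matrix(a1, a2, deme = 1L, sex = "F")
  expect_equal(molecular_F(gm), 0.5)
  gm_hom <- geno_matrix(a1, a1, deme = 1L, sex = "F")
  expect_equal(molecular_F(gm_hom), 1)
  gm_het <- geno_matrix(a1, a1 + 10L, deme = 1L, sex = "F")
  expect_equal(molecular_F(gm_het), 0)
})

test_that("frequency variance uses the baseline allele set with lost alleles at zero", {
  expect_equal(freq_variance(make_ft(c(0.5, 0.5))), 0)
  expect_equal(freq_variance(make_ft(c(1, 0)),
                             baseline = matrix(c(TRUE, TRUE, rep(FALSE, 30)))),
               0.25)
  expect_equal(freq_variance(make_ft(rep(0.25, 4))), 0)
  # an allele lost since baseline still enters with frequency zero:
  # variance of (0.5, 0.5, 0) is 1/18
  base <- matrix(FALSE, 32, 1); base[1:3, 1] <- TRUE
  ft <- make_ft(c(0.5, 0.5))  # third baseline allele now absent
  expect_equal(freq_variance(ft, base), 1 / 18)
})

test_that("plan statistics match their definitions", {
  set.seed(35)
  gm <- rand_gm(D = 5, n = 4, L = 2)
  # every female contributes exactly 2 offspring, no migration
  females <- which(gm$sex == "F")
  males <- which(gm$sex == "M")
  dest <- rep(1:5, each = 4)
  dams <- unlist(lapply(split(females, gm$deme[females]),
                        function(f) rep(f, each = 2)))
  sires <- unlist(lapply(split(males, gm$deme[males]),
                         function(m) rep(m, each = 2)))
  plan <- metapopman:::new_plan(dest, dest, sires, dams, gm, 4, 0)
  ps <- plan_stats(plan)
  expect_equal(ps$VarContFem, 0)
  expect_equal(ps$VarMigrants, 0)
  expect_equal(ps$nMates, 10)

  # migrant dispersion: one migrant into each of 5 demes -> VarMigrants = 0;
  # all migrants into one deme -> the population variance of the counts
  mk <- function(natal_override) {
    natal <- dest
    sire <- sires; dam <- dams
    for (i in seq_along(natal_override)) {
      s <- natal_override[[i]][1]; nd <- natal_override[[i]][2]
      natal[s] <- nd
      sire[s] <- males[gm$deme[males] == nd][1]
      dam[s] <- females[gm$deme[females] == nd][1]
    }
    metapopman:::new_plan(dest, natal, sire, dam, gm, 4, length(natal_override))
  }
  even <- mk(list(c(1, 2), c(5, 3), c(9, 4), c(13, 5), c(17, 1)))
  expect_equal(plan_stats(even)$VarMigrants, 0)
  # slots 1-4 (destination deme 1) all sourced from deme 2: counts (4,0,0,0,0),
  # population variance 2.56
  skewed <- mk(list(c(1, 2), c(2, 2), c(3, 2), c(4, 2)))
  expect_equal(plan_stats(skewed)$VarMigrants, 2.56)
})
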