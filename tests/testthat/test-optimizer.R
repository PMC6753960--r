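# a fixed tiny instance: 2 demes, 2 males + 2 females each, 3 loci
tiny_gm <- function(seed = 41, K = 3) {
  set.seed(seed)
  rand_gm(D = 2, n = 4, L = 3, K = K)
}

test_that("expected progeny frequencies follow gamete-dosage weighting", {
  # one destination deme: sire A/B x dam A/A, 40 offspring -> p_A = 0.75
  gm <- geno_matrix(matrix(c(0L, 0L)), matrix(c(1L, 0L)),
                    deme = c(1L, 1L), sex = c("M", "F"))
  dest <- rep(1L, 40)
  plan <- metapopman:::new_plan(dest, dest, rep(1L, 40), rep(2L, 40), gm, 40, 0)
  ft <- expected_progeny_freqs(plan, gm)
  expect_equal(ft$p[1, 1, 1], 0.75)
  expect_equal(ft$p[1, 2, 1], 0.25)

  # sole heterozygous contributor -> 0.5 / 0.5; sole homozygote -> 1
  gm1 <- geno_matrix(matrix(c(3L, 3L)), matrix(c(5L, 3L)),
                     deme = c(1L, 1L), sex = c("M", "F"))
  plan1 <- metapopman:::new_plan(rep(1L, 2), rep(1L, 2), c(1L, 1L), c(2L, 2L),
                                 gm1, 2, 0)
  ft1 <- expected_progeny_freqs(plan1, gm1)
  expect_equal(ft1$p[1, 4, 1], 0.75)  # het sire 3/5 + hom dam 3/3
  expect_equal(ft1$p[1, 6, 1], 0.25)

  # frequencies sum to one per deme and locus
  set.seed(42)
  gm <- tiny_gm()
  for (r in 1:10) {
    plan <- initial_plan(gm, n_migrants = 2, deme_size = 2)
    ft <- expected_progeny_freqs(plan, gm)
    expect_equal(apply(ft$p, c(1, 3), sum),
                 matrix(1, 2, 3), tolerance = 1e-12)
  }
})

test_that("allele-loss probabilities match exhaustive Mendelian enumeration", {
  # one heterozygous carrier with g = 2 -> (1/2)^2
  gm <- geno_matrix(matrix(c(0L, 0L)), matrix(c(1L, 0L)),
                    deme = c(1L, 1L), sex = c("M", "F"))
  plan <- metapopman:::new_plan(rep(1L, 2), rep(1L, 2), c(1L, 1L), c(2L, 2L),
                                gm, 2, 0)
  expect_equal(allele_loss_prob(plan, gm, locus = 1, allele = 1, dest = 1), 0.25)
  expect_equal(enum_loss(list(c(0, 1), c(0, 0)), c(2, 2), 1), 0.25)
  # homozygous carrier with g >= 1 -> 0
  expect_equal(allele_loss_prob(plan, gm, locus = 1, allele = 0, dest = 1), 0)

  # two heterozygous carriers with g = 1 and g = 3 -> 1/16, by enumeration
  gm2 <- geno_matrix(matrix(c(2L, 2L, 0L, 0L)), matrix(c(7L, 7L, 2L, 0L)),
                     deme = rep(1L, 4), sex = c("M", "M", "F", "F"))
  # sire 3 (het 0/2) gives 1 gamete, dam 4... build with slots: deme size 2
  plan2 <- metapopman:::new_plan(rep(1L, 2), rep(1L, 2), c(1L, 1L), c(3L, 4L),
                                 gm2, 2, 0)
  # carriers of allele 2: parent 1 (hom? 2/7 het), counts: sire1 g=2, dam3 g=1
  p_pkg <- allele_loss_prob(plan2, gm2, locus = 1, allele = 2, dest = 1)
  p_enum <- enum_loss(list(c(2, 7), c(2, 7), c(0, 2), c(0, 0)),
                      c(1, 1, 1, 1), 2)
  expect_equal(p_pkg, enum_loss(list(c(2, 7), c(0, 2), c(0, 0)), c(2, 1, 1), 2))
  # direct spec case: carriers with gamete counts 1 and 3
  expect_equal(enum_loss(list(c(2, 7), c(2, 9)), c(1, 3), 2), 0.0625)

  # monotonicity: loss is non-increasing in a carrier's gamete count
  set.seed(43)
  gm3 <- tiny_gm(43)
  for (g in 1:4) {
    dest <- rep(1:2, each = g)
    sire <- rep(which(gm3$deme == 1 & gm3$sex == "M")[1], 2 * g)
    sire[dest == 2] <- which(gm3$deme == 2 & gm3$sex == "M")[1]
    dam <- rep(which(gm3$deme == 1 & gm3$sex == "F")[1], 2 * g)
    dam[dest == 2] <- which(gm3$deme == 2 & gm3$sex == "F")[1]
    plan <- metapopman:::new_plan(dest, dest, sire, dam, gm3, g, 0)
    l <- metapopman:::loss_probs(plan, gm3)
    if (g > 1) expect_true(all(l <= prev + 1e-12))
    prev <- l
  }
})

test_that("R and C++ objective evaluations agree on random plans", {
  set.seed(44)
  gm <- rand_gm(D = 3, n = 6, L = 4, K = 5)
  for (r in 1:15) {
    M <- sample(0:4, 1)
    plan <- initial_plan(gm, n_migrants = M, deme_size = 4)
    for (m in c("maxHT", "maxAT", "maxK")) {
      obj <- objective(m, lambda = sample(c(0, 0.5, 1, 1000), 1),
                       migrants = M / 3)
      r_val <- objective_value(plan, gm, obj)
      c_val <- metapopman:::plan_score_cpp(gm$a1, gm$a2, gm$deme,
                                           gm$sex == "F", 4L, M, m,
                                           obj$lambda, plan$natal,
                                           plan$sire, plan$dam)
      expect_equal(r_val, c_val, tolerance = 1e-10)
    }
  }
})

test_that("lambda = 0 scores ignore the within-deme component", {
  set.seed(45)
  gm <- tiny_gm(45)
  plan <- initial_plan(gm, n_migrants = 2, deme_size = 2)
  hp <- het_partition(expected_progeny_freqs(plan, gm))
  expect_equal(objective_value(plan, gm, objective("maxHT", lambda = 0)),
               hp$D_G)
  # single deme: D_G = 0, so the maxHT score at lambda = 1 is the expected
  # Hardy-Weinberg heterozygosity of the progeny
  gm1 <- geno_matrix(gm$a1[1:4, ], gm$a2[1:4, ], deme = rep(1L, 4),
                     sex = gm$sex[1:4])
  plan1 <- random_plan(gm1, deme_size = 4)
  hp1 <- het_partition(expected_progeny_freqs(plan1, gm1))
  expect_equal(objective_value(plan1, gm1, objective("maxHT", lambda = 1)),
               hp1$H_S)
  expect_equal(hp1$D_G, 0)
})

test_that("plan moves preserve feasibility and reach the whole plan space", {
  set.seed(46)
  gm <- rand_gm(D = 3, n = 6, L = 2, K = 3)
  plan <- initial_plan(gm, n_migrants = 3, deme_size = 4)
  for (i in 1:300) {
    plan <- propose_move(plan, gm)  # validate_plan() runs inside new_plan()
    expect_equal(sum(plan$natal != plan$dest), 3)
    expect_equal(tabulate(plan$dest, 3), rep(4L, 3))
  }

  # connectivity: random walk visits every feasible canonical plan of a
  # tiny instance (2 demes x (2M + 2F), deme size 2, 1 migrant)
  set.seed(47)
  gm2 <- rand_gm(D = 2, n = 4, L = 1, K = 2)
  all_states <- unique(vapply(enum_plans(gm2, N = 2, M = 1), canon_plan,
                              character(1)))
  plan <- initial_plan(gm2, n_migrants = 1, deme_size = 2)
  seen <- character(0)
  for (i in 1:4000) {
    plan <- propose_move(plan, gm2)
    seen <- union(seen, canon_plan(plan))
    if (length(seen) == length(all_states)) break
  }
  expect_setequal(seen, all_states)
})

test_that("annealing is deterministic, monotone, and beats random plans", {
  set.seed(48)
  gm <- rand_gm(D = 2, n = 6, L = 4, K = 4)
  obj <- objective("maxAT", lambda = 1, migrants = 1)
  set.seed(100)
  p1 <- anneal_plan(gm, obj, schedule = tiny_schedule(), deme_size = 4)
  set.seed(100)
  p2 <- anneal_plan(gm, obj, schedule = tiny_schedule(), deme_size = 4)
  expect_identical(p1$natal, p2$natal)
  expect_identical(p1$sire, p2$sire)
  expect_identical(p1$dam, p2$dam)
  expect_identical(attr(p1, "score"), attr(p2, "score"))
  expect_gte(attr(p1, "score"), attr(p1, "score0"))

  # annealed score beats the average random-plan score for every method
  for (m in c("maxHT", "maxAT", "maxK")) {
    obj <- objective(m, lambda = 1, migrants = 0)
    ann <- anneal_plan(gm, obj, schedule = tiny_schedule(), deme_size = 4)
    rnd <- replicate(20, {
      pl <- random_plan(gm, deme_size = 4)
      objective_value(pl, gm, obj)
    })
    expect_gt(attr(ann, "score"), mean(rnd))
  }
})

test_that("annealed plans attain the exhaustive optimum on tiny instances", {
  set.seed(49)
  gm <- tiny_gm(49, K = 4)
  plans <- enum_plans(gm, N = 2, M = 2)
  expect_gt(length(plans), 100)
  for (m in c("maxHT", "maxAT", "maxK")) {
    obj <- objective(m, lambda = 1, migrants = 1)
    best <- max(vapply(plans, objective_value, numeric(1), gm = gm, obj = obj))
    hits <- vapply(1:10, function(i) {
      ann <- anneal_plan(gm, obj, schedule = tiny_schedule(), deme_size = 2)
      attr(ann, "score") >= best - 1e-9
    }, logical(1))
    expect_gte(mean(hits), 0.9)
  }
})

test_that("random plans have the right structure", {
  set.seed(50)
  gm <- rand_gm(D = 5, n = 40, L = 3, K = 4)
  plan <- random_plan(gm)
  expect_equal(tabulate(plan$dest, 5), rep(40L, 5))
  expect_equal(sum(plan$natal != plan$dest), 0)
  ps <- plan_stats(plan)
  expect_gt(ps$VarContFem, 0)  # multinomial contributions are unequal a.s.
  # expected contribution per female is 2 offspring
  expect_equal(length(plan$dam) / sum(gm$sex == "F"), 2)
})
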