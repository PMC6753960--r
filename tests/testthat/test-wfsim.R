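test_that("meiosis without mutation or recombination copies a parental haplotype", {
  set.seed(11)
  p <- sim_params(seq_len = 50, mu = 0, rec = 0)
  ind <- list(hap1 = rep(1L, 50), hap2 = rep(0L, 50))
  hits <- replicate(200, {
    g <- as.integer(meiosis(ind, p))
    expect_true(all(g == 1L) || all(g == 0L))
    all(g == 1L)
  })
  # both strands are used, each about half the time
  expect_gt(mean(hits), 0.35)
  expect_lt(mean(hits), 0.65)
})

test_that("mutation and crossover counts follow their binomial laws", {
  set.seed(12)
  L <- 10000
  # mutations: parent monomorphic 0, so derived sites = mutations
  p <- sim_params(seq_len = L, mu = 5e-5, rec = 0)
  ind <- list(hap1 = rep(0L, L), hap2 = rep(0L, L))
  nmut <- replicate(4000, sum(as.integer(meiosis(ind, p))))
  m_expect <- L * 5e-5                     # Binomial(L, mu) mean = 0.5
  se <- sqrt(m_expect / 4000)              # Poisson-scale SE of the mean
  expect_lt(abs(mean(nmut) - m_expect), 3 * se)

  # strand switches: haplotypes differ everywhere so switches are visible
  p <- sim_params(seq_len = L, mu = 0, rec = 5e-4)
  ind <- list(hap1 = rep(1L, L), hap2 = rep(0L, L))
  nsw <- replicate(2000, {
    g <- as.integer(meiosis(ind, p))
    sum(g[-1] != g[-L])
  })
  s_expect <- (L - 1) * 5e-4               # Binomial(L-1, rec) mean
  se <- sqrt(s_expect / 2000)
  expect_lt(abs(mean(nsw) - s_expect), 3 * se)
})

test_that("ancestral runs preserve sizes and zero generations change nothing", {
  set.seed(13)
  p <- sim_params(seq_len = 100, mu = 1e-3, rec = 1e-4)
  pop0 <- run_ancestral(p, 20, 0)
  expect_identical(pop0$demes[[1]],
                   matrix(as.raw(0), nrow = 100, ncol = 40))
  pop <- run_ancestral(p, 20, 50)
  expect_equal(ncol(pop$demes[[1]]), 40)
  expect_equal(pop$generation, 50)
  expect_lte(segregating_sites(pop), 100)
})

test_that("without mutation no new segregating sites arise and gametes are parental", {
  set.seed(14)
  p <- sim_params(seq_len = 200, mu = 2e-3, rec = 1e-3)
  pop <- run_ancestral(p, 30, 80)
  seg_before <- which(site_is_seg(pop))
  p0 <- sim_params(seq_len = 200, mu = 0, rec = 1e-3)
  pop$params <- p0
  evolved <- found_demes(pop, sizes = 30, generations = 20)
  seg_after <- which(site_is_seg(evolved))
  expect_true(all(seg_after %in% seg_before))

  # mu = 0, rec = 0: every gamete equals one parental haplotype exactly
  p00 <- sim_params(seq_len = 200, mu = 0, rec = 0)
  ind <- get_individual(pop, 1, 1)
  for (i in 1:20) {
    g <- meiosis(ind, p00)
    expect_true(identical(g, ind$hap1) || identical(g, ind$hap2))
  }
})

test_that("scaled runs reach the two-state mutation-drift equilibrium", {
  set.seed(15)
  # theta = 4*N*u = 0.8 at desk scale; oracle: exact identity-in-state
  # recursion for a binary site (closed form)
  N <- 100
  u <- 2e-3
  target <- eq_het_two_state(N, u)
  p <- sim_params(seq_len = 2000, mu = u, rec = 4e-5)
  hets <- replicate(4, mean_site_het(run_ancestral(p, N, 1200)))
  expect_lt(abs(mean(hets) - target) / target, 0.2)
})

test_that("founding demes samples without replacement and drifts faster when small", {
  set.seed(16)
  p <- sim_params(seq_len = 300, mu = 1e-3, rec = 0)
  src <- run_ancestral(p, 60, 150)
  expect_error(found_demes(src, sizes = c(50, 20)), "exceed")

  mp0 <- found_demes(src, sizes = c(20, 10, 10), generations = 0)
  expect_equal(deme_sizes(mp0), c(20L, 10L, 10L))
  # generations = 0: founders are drawn from the source, unchanged
  src_cols <- apply(src$demes[[1]], 2, paste, collapse = "")
  for (d in 1:3) {
    cols <- apply(mp0$demes[[d]], 2, paste, collapse = "")
    expect_true(all(cols %in% src_cols))
  }

  # E[H_t] = H_0 (1 - 1/2N)^t: the small deme loses heterozygosity faster
  h_small <- h_big <- numeric(12)
  for (r in 1:12) {
    mp <- found_demes(src, sizes = c(40, 8), generations = 15)
    h_big[r] <- mean_site_het(mp, demes = 1)
    h_small[r] <- mean_site_het(mp, demes = 2)
  }
  expect_lt(mean(h_small), mean(h_big))
})

test_that("founder sampling is sexed half-and-half and unbiased", {
  set.seed(17)
  p <- sim_params(seq_len = 100, mu = 2e-3, rec = 0)
  pop <- run_ancestral(p, 40, 100)
  mp <- found_demes(pop, sizes = c(30, 10), generations = 0)
  expect_error(sample_founders(mp, 7), "even")
  expect_error(sample_founders(mp, 12), "at least")

  f <- sample_founders(mp, 10)
  for (d in 1:2) {
    expect_equal(sum(f$sexes[[d]] == "F"), 5)
    expect_equal(sum(f$sexes[[d]] == "M"), 5)
  }
  # sampling a whole deme keeps the same haplotype multiset
  f2 <- sample_founders(mp, 10)
  all10 <- sort(apply(mp$demes[[2]], 2, paste, collapse = ""))
  expect_identical(sort(apply(f2$demes[[2]], 2, paste, collapse = "")), all10)

  # resampled allele frequencies are unbiased for the deme frequency
  cnt <- site_counts_per_deme(mp, 1)
  site <- which(cnt > 5 & cnt < 55)[1]
  p_deme <- cnt[site] / 60
  p_hat <- replicate(1000, {
    s <- sample_founders(mp, 10)
    sum(as.integer(s$demes[[1]][site, ])) / 20
  })
  se <- sd(p_hat) / sqrt(1000)
  expect_lt(abs(mean(p_hat) - p_deme), 3 * se + 1e-9)
})
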