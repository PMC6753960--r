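# Shared fixtures and independent oracles, all built in code.

# genotype matrix with D equal demes of n individuals (half F, half M) and
# random allele codes drawn from the first K codes
rand_gm <- function(D, n, L, K = 4) {
  a1 <- matrix(sample(0:(K - 1), D * n * L, replace = TRUE), D * n, L)
  a2 <- matrix(sample(0:(K - 1), D * n * L, replace = TRUE), D * n, L)
  geno_matrix(a1, a2, deme = rep(seq_len(D), each = n),
              sex = rep(rep(c("F", "M"), each = n / 2), D))
}

# frequency table with random support and Dirichlet-ish frequencies
rand_ft <- function(D, L, K = 6) {
  p <- array(0, c(D, 32, L))
  for (d in seq_len(D))
    for (l in seq_len(L)) {
      k <- sample(seq_len(K), 1)
      sup <- sample(seq_len(K), k)
      w <- stats::rgamma(k, 1)
      p[d, sup, l] <- w / sum(w)
    }
  freq_table(p)
}

# pooled-frequency heterozygosity: the oracle identity for H_T
pooled_het <- function(ft) {
  p <- ft$p
  L <- dim(p)[3]
  pbar <- matrix(apply(p, c(2, 3), mean), 32, L)
  mean(1 - colSums(pbar^2))
}

# mean pair-union allele count minus one: the oracle identity for A_T
pair_union_alleles <- function(ft) {
  pres <- ft$p > 0
  D <- dim(pres)[1]
  L <- dim(pres)[3]
  if (D == 1) {
    return(mean(colSums(matrix(pres[1, , ], 32, L)) - 1))
  }
  tot <- 0
  npairs <- 0
  for (i in seq_len(D - 1))
    for (j in (i + 1):D) {
      u <- matrix(pres[i, , ] | pres[j, , ], 32, L)
      tot <- tot + mean(colSums(u) - 1)
      npairs <- npairs + 1
    }
  tot / npairs
}

# exact equilibrium gene diversity of one binary site under symmetric flip
# mutation (rate u per generation each way) in a Wright-Fisher deme of N
# diploids: identity-in-state recursion for two lineages,
# F = a (c + (1-c) F) + b (1-c)(1-F), a = (1-u)^2 + u^2, b = 2u(1-u),
# c = 1/(2N); solved in closed form.
eq_het_two_state <- function(N, u) {
  a <- (1 - u)^2 + u^2
  b <- 2 * u * (1 - u)
  cc <- 1 / (2 * N)
  Fhat <- (a * cc + b * (1 - cc)) / (1 - (1 - cc) * (a - b))
  1 - Fhat
}

# enumerate every feasible plan of a tiny instance: D demes, N offspring
# per destination, exactly M migrants
enum_plans <- function(gm, N, M) {
  D <- max(gm$deme)
  males <- lapply(seq_len(D), function(d) which(gm$deme == d & gm$sex == "M"))
  females <- lapply(seq_len(D), function(d) which(gm$deme == d & gm$sex == "F"))
  opts <- do.call(rbind, lapply(seq_len(D), function(nd)
    expand.grid(natal = nd, sire = males[[nd]], dam = females[[nd]])))
  dest <- rep(seq_len(D), each = N)
  slots <- nrow(opts)
  grid <- expand.grid(rep(list(seq_len(slots)), D * N))
  plans <- list()
  for (r in seq_len(nrow(grid))) {
    ch <- opts[as.integer(grid[r, ]), ]
    if (sum(ch$natal != dest) != M) next
    plans[[length(plans) + 1]] <-
      metapopman:::new_plan(dest, ch$natal, ch$sire, ch$dam, gm, N, M)
  }
  plans
}

# exact allele-loss probability by enumerating every Mendelian outcome:
# genos = list of c(allele1, allele2) per contributing parent, g = gamete
# counts, allele = the allele whose loss is assessed
enum_loss <- function(genos, g, allele) {
  total <- sum(g)
  ids <- rep(seq_along(g), g)
  combos <- as.matrix(expand.grid(rep(list(1:2), total)))
  lost <- apply(combos, 1, function(ch)
    all(vapply(seq_len(total),
               function(t) genos[[ids[t]]][ch[t]], numeric(1)) != allele))
  mean(lost)
}

# canonical form of a plan: destinations with sorted slot tuples
canon_plan <- function(plan) {
  D <- attr(plan, "n_demes")
  paste(vapply(seq_len(D), function(d) {
    rows <- which(plan$dest == d)
    paste(sort(paste(plan$natal[rows], plan$sire[rows], plan$dam[rows],
                     sep = "-")), collapse = ",")
  }, character(1)), collapse = ";")
}

# per-site segregation indicator / derived counts over pooled demes
site_is_seg <- function(mp, demes = seq_along(mp$demes)) {
  haps <- do.call(cbind, mp$demes[demes])
  cnt <- metapopman:::site_counts_cpp(haps)
  cnt > 0 & cnt < ncol(haps)
}

site_counts_per_deme <- function(mp, d) {
  metapopman:::site_counts_cpp(mp$demes[[d]])
}

# tiny annealing schedule for unit tests
tiny_schedule <- function(iterations = 2000)
  anneal_schedule(cooling = 0.9, steps_per_temp = 50, iterations = iterations)
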