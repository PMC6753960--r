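#' Simulation parameters for the neutral sequence
#'
#' Bundles the per-site mutation and recombination probabilities of the
#' simulated diploid sequence. Defaults reproduce the base-population
#' conditions of the subdivided-population management study: a 10 kb
#' sequence with mutation probability 5e-5 per nucleotide per generation
#' and recombination probability 1e-6 between consecutive nucleotides.
#'
#' @param seq_len number of nucleotide sites; must be a multiple of 5 so the
#'   sequence tiles exactly into 5-SNP marker windows.
#' @param mu per-site, per-generation probability that a site flips between
#'   its ancestral and derived state.
#' @param rec per-meiosis probability of a strand switch at each boundary
#'   between consecutive sites.
#' @param scale optional down-scaling factor for desk-size runs; see
#'   [scaled_setup()]. `scale = 1` is the full-size model.
#' @return An object of class `sim_params`.
#' @examples
#' p <- sim_params(seq_len = 100, mu = 1e-3, rec = 0)
#' @export
sim_params <- function(seq_len = 10000, mu = 5e-5, rec = 1e-6, scale = 1) {
  stopifnot(is_count(seq_len), seq_len >= 5, seq_len %% 5 == 0,
            is.numeric(mu), mu >= 0, mu <= 1,
            is.numeric(rec), rec >= 0, rec <= 0.5,
            is.numeric(scale), scale >= 1)
  structure(list(seq_len = as.integer(seq_len), mu = mu, rec = rec,
                 scale = scale),
            class = "sim_params")
}

#' Rescale a simulation design for desk-size runs
#'
#' Multiplies the mutation and recombination probabilities by
#' `params$scale` and divides the population size and generation count by
#' it, holding the compound parameters theta = 4*N*mu and 4*N*c and the
#' drift time T/N fixed. Population-genetic expectations (equilibrium
#' heterozygosity, rates of diversity loss) are functions of these compound
#' parameters, so a scaled run probes the same regime at a fraction of the
#' cost.
#'
#' @param params a [sim_params()] object whose `scale` is applied.
#' @param n population size (diploid individuals) at full scale.
#' @param generations number of generations at full scale.
#' @return A list with elements `params` (rescaled, `scale = 1`), `n`, and
#'   `generations`.
#' @export
scaled_setup <- function(params, n, generations) {
  s <- params$scale
  list(params = sim_params(params$seq_len, min(params$mu * s, 1),
                           min(params$rec * s, 0.5), scale = 1),
       n = max(2L, as.integer(round(n / s))),
       generations = as.integer(round(generations / s)))
}

new_metapop <- function(demes, sexes = NULL, params = NULL, generation = 0L) {
  structure(list(demes = demes, sexes = sexes, params = params,
                 generation = as.integer(generation)),
            class = "metapop")
}

#' @export
print.metapop <- function(x, ...) {
  sizes <- vapply(x$demes, function(h) ncol(h) / 2, numeric(1))
  cat("Metapopulation: ", length(x$demes), " deme(s) of size ",
      paste(sizes, collapse = ", "), "; ", nrow(x$demes[[1]]),
      " sites; generation ", x$generation,
      if (is.null(x$sexes)) "" else "; sexed", "\n", sep = "")
  invisible(x)
}

deme_sizes <- function(metapop) {
  vapply(metapop$demes, function(h) ncol(h) %/% 2L, integer(1))
}

#' Initialise a monomorphic population
#'
#' All haplotypes carry the ancestral state (0) at every site.
#'
#' @param n number of diploid individuals.
#' @param params a [sim_params()] object.
#' @return A `metapop` with a single deme.
#' @export
init_population <- function(n, params) {
  stopifnot(is_count(n), n >= 1)
  haps <- matrix(as.raw(0), nrow = params$seq_len, ncol = 2 * n)
  new_metapop(list(haps), params = params)
}

#' Form one gamete by meiosis
#'
#' Starts on a uniformly chosen parental haplotype, switches strands
#' independently with probability `rec` at each of the `seq_len - 1`
#' boundaries between consecutive sites, then flips each site independently
#' with probability `mu`.
#'
#' @param parent a list with raw or 0/1 components `hap1` and `hap2`, as
#'   returned by [get_individual()].
#' @param params a [sim_params()] object (only `mu` and `rec` are used).
#' @return A raw 0/1 vector of length `seq_len`: the gamete.
#' @examples
#' p <- sim_params(seq_len = 10, mu = 0, rec = 0)
#' ind <- list(hap1 = rep(1L, 10), hap2 = rep(0L, 10))
#' meiosis(ind, p)  # one of the two parental haplotypes, unchanged
#' @export
meiosis <- function(parent, params) {
  h1 <- as.raw(parent$hap1)
  h2 <- as.raw(parent$hap2)
  stopifnot(length(h1) == length(h2), all(as.integer(h1) <= 1),
            all(as.integer(h2) <= 1))
  meiosis_cpp(h1, h2, params$mu, params$rec)
}

#' Extract one individual from a metapopulation
#'
#' @param metapop a `metapop` object.
#' @param deme deme index.
#' @param i individual index within the deme.
#' @return A list with `hap1`, `hap2` (raw 0/1 vectors) and `sex`
#'   (`"F"`/`"M"`, or `NA` before sexes are assigned).
#' @export
get_individual <- function(metapop, deme, i) {
  haps <- metapop$demes[[deme]]
  stopifnot(i >= 1, i <= ncol(haps) / 2)
  sex <- if (is.null(metapop$sexes)) NA_character_ else metapop$sexes[[deme]][i]
  list(hap1 = haps[, 2 * i - 1], hap2 = haps[, 2 * i], sex = sex)
}

#' Evolve an ancestral deme to mutation-drift equilibrium
#'
#' Non-overlapping Wright-Fisher generations: each offspring is formed from
#' two parents drawn uniformly with replacement (monoecious random mating,
#' selfing allowed), one gamete from each via [meiosis()]. The study design
#' runs N = 4,000 individuals for 5,000 generations to accumulate neutral
#' variation before the subpopulations are founded.
#'
#' @param params a [sim_params()] object.
#' @param n deme size (diploid individuals), at least 2.
#' @param generations number of generations (0 returns the monomorphic
#'   population unchanged).
#' @return A `metapop` with one deme.
#' @export
run_ancestral <- function(params, n, generations) {
  stopifnot(is_count(n), n >= 2, is_count(generations), generations >= 0)
  pop <- init_population(n, params)
  pop$demes[[1]] <- wf_evolve_cpp(pop$demes[[1]], as.integer(generations),
                                  params$mu, params$rec)
  pop$generation <- as.integer(generations)
  pop
}

#' Found subpopulations from an ancestral deme
#'
#' Each deme is founded by uniform sampling of individuals without
#' replacement from the source (draws are disjoint across demes), then
#' evolved independently -- no migration -- by Wright-Fisher reproduction at
#' constant size, with mutation and recombination still acting. The study
#' founds five demes of sizes 2,000 and 4 x 100 and maintains them for 25
#' generations.
#'
#' @param source a one-deme `metapop`.
#' @param sizes deme sizes to found.
#' @param generations number of generations of independent evolution.
#' @return A `metapop` with `length(sizes)` demes.
#' @export
found_demes <- function(source, sizes = c(2000, 100, 100, 100, 100),
                        generations = 25) {
  stopifnot(length(source$demes) == 1, all(sizes >= 1),
            is_count(generations), generations >= 0)
  params <- source$params
  n_src <- ncol(source$demes[[1]]) %/% 2
  if (sum(sizes) > n_src)
    stop("founder draws (", sum(sizes), ") exceed source population size (",
         n_src, ")")
  picks <- sample.int(n_src, sum(sizes))
  offsets <- c(0, cumsum(sizes))
  src <- source$demes[[1]]
  demes <- vector("list", length(sizes))
  for (d in seq_along(sizes)) {
    ids <- picks[(offsets[d] + 1):offsets[d + 1]]
    cols <- as.vector(rbind(2 * ids - 1, 2 * ids))
    demes[[d]] <- wf_evolve_cpp(src[, cols, drop = FALSE],
                                as.integer(generations), params$mu, params$rec)
  }
  new_metapop(demes, params = params,
              generation = source$generation + generations)
}

#' Sample sexed founders for management
#'
#' Draws `n_per_deme` individuals uniformly without replacement from every
#' deme and assigns sexes at random so that exactly half are female and half
#' male (the managed population holds 40 individuals, 20 of each sex, per
#' deme).
#'
#' @param metapop a `metapop` object.
#' @param n_per_deme even number of individuals to sample per deme.
#' @return A sexed `metapop` with demes of size `n_per_deme`.
#' @export
sample_founders <- function(metapop, n_per_deme = 40) {
  stopifnot(is_count(n_per_deme), n_per_deme >= 2)
  if (n_per_deme %% 2 != 0)
    stop("n_per_deme must be even (equal numbers of each sex)")
  sizes <- deme_sizes(metapop)
  if (any(sizes < n_per_deme))
    stop("every deme needs at least n_per_deme individuals")
  demes <- vector("list", length(metapop$demes))
  sexes <- vector("list", length(metapop$demes))
  for (d in seq_along(metapop$demes)) {
    ids <- sample.int(sizes[d], n_per_deme)
    cols <- as.vector(rbind(2 * ids - 1, 2 * ids))
    demes[[d]] <- metapop$demes[[d]][, cols, drop = FALSE]
    sexes[[d]] <- sample(rep(c("F", "M"), each = n_per_deme / 2))
  }
  new_metapop(demes, sexes = sexes, params = metapop$params,
              generation = metapop$generation)
}

#' Mean per-site expected heterozygosity
#'
#' For each site, the expected heterozygosity 2*p*(1-p) of the derived-allele
#' frequency p in the pooled haplotypes of the selected demes; returns the
#' mean over sites. Used to check mutation-drift calibration against the
#' two-state equilibrium H = theta / (1 + 2*theta), theta = 4*N*mu.
#'
#' @param metapop a `metapop` object.
#' @param demes deme indices to pool (default: all).
#' @return Mean per-site expected heterozygosity, a number in \[0, 0.5\].
#' @export
mean_site_het <- function(metapop, demes = seq_along(metapop$demes)) {
  haps <- do.call(cbind, metapop$demes[demes])
  p <- site_counts_cpp(haps) / ncol(haps)
  mean(2 * p * (1 - p))
}

#' Number of segregating sites
#'
#' @param metapop a `metapop` object.
#' @param demes deme indices to pool (default: all).
#' @return Count of sites with both states present in the pooled haplotypes.
#' @export
segregating_sites <- function(metapop, demes = seq_along(metapop$demes)) {
  haps <- do.call(cbind, metapop$demes[demes])
  cnt <- site_counts_cpp(haps)
  sum(cnt > 0 & cnt < ncol(haps))
}
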