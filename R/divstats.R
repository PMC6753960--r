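#' Per-deme allele frequencies
#'
#' Counts allele copies per deme and locus: p(allele | deme, locus) =
#' copies / (2 * deme size). Frequencies are stored densely over the 32
#' possible codes so downstream partitions vectorise over a
#' demes x alleles x loci array.
#'
#' @param gm a `geno_matrix`.
#' @param loci integer vector of locus indices (default: all loci).
#' @return A `freq_table`: list with array `p` (demes x 32 x loci), integer
#'   `n` (deme sizes) and `loci` (the locus indices used).
#' @export
allele_freqs <- function(gm, loci = NULL) {
  loci <- loci %||% seq_len(n_loci(gm))
  D <- n_demes(gm)
  L <- length(loci)
  p <- array(0, c(D, 32L, L))
  n <- integer(D)
  for (d in seq_len(D)) {
    rows <- which(gm$deme == d)
    if (length(rows) == 0)
      stop("deme ", d, " is empty")
    n[d] <- length(rows)
    A <- rbind(gm$a1[rows, loci, drop = FALSE], gm$a2[rows, loci, drop = FALSE])
    idx <- as.vector(A) + 1L + 32L * rep(seq_len(L) - 1L, each = nrow(A))
    p[d, , ] <- tabulate(idx, 32L * L) / (2 * n[d])
  }
  structure(list(p = p, n = n, loci = as.integer(loci)), class = "freq_table")
}

#' Frequency table constructor
#'
#' Wraps a demes x 32 x loci array of allele frequencies; mainly useful for
#' building small examples by hand. [allele_freqs()] is the usual entry
#' point.
#'
#' @param p array with dimensions (demes, 32, loci).
#' @param n optional deme sizes.
#' @param loci optional locus indices.
#' @return An object of class `freq_table`.
#' @export
freq_table <- function(p, n = NULL, loci = NULL) {
  stopifnot(length(dim(p)) == 3, dim(p)[2] == 32)
  structure(list(p = p, n = n, loci = loci %||% seq_len(dim(p)[3])),
            class = "freq_table")
}

#' Nei partition of total heterozygosity
#'
#' Per locus, the within-subpopulation gene diversity H_S is the mean over
#' demes of 1 - sum(p^2); the between component D_G is Nei's minimum
#' genetic distance D_ij = sum((p_i - p_j)^2) / 2 averaged over all n^2
#' ordered deme pairs (self-pairs contribute 0); and H_T = H_S + D_G. With
#' this averaging convention H_T equals, exactly, the expected
#' heterozygosity of the equally weighted pooled allele frequencies. Demes
#' are weighted equally regardless of census size. Reported values are
#' means over loci.
#'
#' @param ft a `freq_table`.
#' @return List with scalars `H_S`, `D_G`, `H_T` and a matrix `per_locus`.
#' @examples
#' # two demes fixed for alternative alleles: H_S = 0, D_G = 0.5, H_T = 0.5
#' p <- array(0, c(2, 32, 1)); p[1, 1, 1] <- 1; p[2, 2, 1] <- 1
#' het_partition(freq_table(p))
#' @export
het_partition <- function(ft) {
  p <- ft$p
  D <- dim(p)[1]
  L <- dim(p)[3]
  s2 <- apply(p^2, c(1, 3), sum)          # D x L: per-deme sum of p^2
  hs <- 1 - colMeans(matrix(s2, D, L))
  dg <- numeric(L)
  for (i in seq_len(D)) {
    pi <- matrix(p[i, , ], 32, L)
    for (j in seq_len(D)) {
      if (i == j) next
      pj <- matrix(p[j, , ], 32, L)
      dg <- dg + colSums((pi - pj)^2) / 2
    }
  }
  dg <- dg / D^2
  list(H_S = mean(hs), D_G = mean(dg), H_T = mean(hs + dg),
       per_locus = cbind(H_S = hs, D_G = dg, H_T = hs + dg))
}

#' Partition of allelic diversity
#'
#' Per locus, the within component A_S is the mean over demes of the number
#' of alleles segregating in the deme, minus one. The between component
#' D_A is, for each unordered deme pair, the symmetrised count of alleles
#' private to one member, d_ij = (|i \ j| + |j \ i|) / 2, averaged over
#' pairs. Their sum A_T = A_S + D_A equals the mean number of alleles in
#' the union of a deme pair, minus one. With a single deme D_A = 0.
#' Reported values are means over loci.
#'
#' @param ft a `freq_table`.
#' @return List with scalars `A_S`, `D_A`, `A_T` and a matrix `per_locus`.
#' @export
allelic_partition <- function(ft) {
  pres <- ft$p > 0
  D <- dim(pres)[1]
  L <- dim(pres)[3]
  a_s <- matrix(apply(pres, c(1, 3), sum), D, L)
  as_l <- colMeans(a_s) - 1
  da_l <- numeric(L)
  if (D > 1) {
    for (i in seq_len(D - 1)) {
      qi <- matrix(pres[i, , ], 32, L)
      for (j in (i + 1):D) {
        qj <- matrix(pres[j, , ], 32, L)
        da_l <- da_l + (colSums(qi & !qj) + colSums(qj & !qi)) / 2
      }
    }
    da_l <- da_l / (D * (D - 1) / 2)
  }
  list(A_S = mean(as_l), D_A = mean(da_l), A_T = mean(as_l + da_l),
       per_locus = cbind(A_S = as_l, D_A = da_l, A_T = as_l + da_l))
}

#' Total number of alleles in the pooled population
#'
#' @param ft a `freq_table`.
#' @return List with `K` (mean distinct alleles per locus), `K_total` (raw
#'   sum over loci) and `per_locus`.
#' @export
total_alleles <- function(ft) {
  pres <- ft$p > 0
  L <- dim(pres)[3]
  pooled <- apply(pres, c(2, 3), any)
  k_l <- colSums(matrix(pooled, 32, L))
  list(K = mean(k_l), K_total = sum(k_l), per_locus = k_l)
}

#' Molecular inbreeding coefficient
#'
#' The observed marker homozygosity of an individual: the fraction of
#' in-scope loci at which its two allele codes are equal (identity by
#' descent plus identity in state). F is the mean over all individuals in
#' all demes.
#'
#' @param gm a `geno_matrix`.
#' @param loci integer vector of locus indices (default: all).
#' @return F, a number in \[0, 1\].
#' @export
molecular_F <- function(gm, loci = NULL) {
  loci <- loci %||% seq_len(n_loci(gm))
  mean(rowMeans(gm$a1[, loci, drop = FALSE] == gm$a2[, loci, drop = FALSE]))
}

#' Variance of allele frequencies within loci
#'
#' Per locus, the population variance of the pooled (equally deme-weighted)
#' allele frequencies across the locus's baseline allele set -- the alleles
#' recorded at management start; alleles since lost count as frequency 0.
#' Maximising heterozygosity drives frequencies towards equality, i.e.
#' towards zero variance.
#'
#' @param ft a `freq_table`.
#' @param baseline 32 x loci logical matrix marking the baseline allele set,
#'   as from [baseline_presence()]; defaults to the presence set of `ft`
#'   itself.
#' @return Mean over loci of the per-locus frequency variance.
#' @export
freq_variance <- function(ft, baseline = NULL) {
  L <- dim(ft$p)[3]
  pbar <- matrix(apply(ft$p, c(2, 3), mean), 32, L)
  baseline <- baseline %||% (matrix(apply(ft$p > 0, c(2, 3), any), 32, L))
  v <- vapply(seq_len(L), function(l) pop_var(pbar[baseline[, l], l]),
              numeric(1))
  mean(v)
}

#' Baseline allele presence per locus
#'
#' Records which alleles are present anywhere in the metapopulation, per
#' locus -- the reference set against which later allele loss and
#' [freq_variance()] are measured.
#'
#' @param ft a `freq_table`.
#' @return A 32 x loci logical matrix.
#' @export
baseline_presence <- function(ft) {
  L <- dim(ft$p)[3]
  matrix(apply(ft$p > 0, c(2, 3), any), 32, L)
}

#' Mating and migration statistics of a contribution plan
#'
#' @param plan a `contribution_plan`.
#' @return List with `nMates` (count of sire-dam pairs with at least one
#'   offspring), `VarContFem` (population variance of per-female total
#'   offspring counts, zero-contribution females included), `VarMigrants`
#'   (population variance across demes of incoming migrant counts) and
#'   `migrants` (total migrant offspring).
#' @export
plan_stats <- function(plan) {
  par <- attr(plan, "parents")
  D <- attr(plan, "n_demes")
  females <- which(par$sex == "F")
  contrib <- tabulate(match(plan$dam, females), length(females))
  mig_in <- vapply(seq_len(D), function(d) sum(plan$dest == d & plan$natal != d),
                   numeric(1))
  list(nMates = nrow(unique(data.frame(plan$sire, plan$dam))),
       VarContFem = pop_var(contrib),
       VarMigrants = pop_var(mig_in),
       migrants = sum(plan$natal != plan$dest))
}

#' One-row diversity report
#'
#' Assembles every per-generation statistic of a management run: the
#' heterozygosity partition (H_S, D_G, H_T), the allelic-diversity
#' partition (A_S, D_A, A_T), allele counts (K, K_total), molecular
#' inbreeding F, the within-locus frequency variance VarFreq, and -- when a
#' plan produced this generation -- nMates, VarContFem and VarMigrants.
#'
#' @param gm a `geno_matrix` (the current generation).
#' @param loci measurement scope: locus indices.
#' @param baseline baseline allele presence from [baseline_presence()]
#'   (management-start allele set), or `NULL` to use the current set.
#' @param plan the `contribution_plan` that produced this generation, or
#'   `NULL` for the baseline row.
#' @return A one-row data frame.
#' @export
diversity_report <- function(gm, loci = NULL, baseline = NULL, plan = NULL) {
  loci <- loci %||% seq_len(n_loci(gm))
  ft <- allele_freqs(gm, loci)
  hp <- het_partition(ft)
  ap <- allelic_partition(ft)
  ta <- total_alleles(ft)
  ps <- if (is.null(plan)) list(nMates = NA_real_, VarContFem = NA_real_,
                                VarMigrants = NA_real_, migrants = NA_real_)
        else plan_stats(plan)
  data.frame(H_S = hp$H_S, D_G = hp$D_G, H_T = hp$H_T,
             A_S = ap$A_S, D_A = ap$D_A, A_T = ap$A_T,
             K = ta$K, K_total = ta$K_total,
             F = molecular_F(gm, loci),
             VarFreq = freq_variance(ft, baseline),
             nMates = as.numeric(ps$nMates),
             VarContFem = as.numeric(ps$VarContFem),
             VarMigrants = as.numeric(ps$VarMigrants),
             migrants = as.numeric(ps$migrants))
}
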