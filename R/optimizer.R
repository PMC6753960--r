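#' Management objective
#'
#' The optimisation criteria of the conservation scheme:
#' * `maxHT` maximises D_G + lambda * H_S on the expected progeny allele
#'   frequencies (total expected heterozygosity at lambda = 1);
#' * `maxAT` maximises D_A + lambda * A_S where the expected allelic
#'   components are built from per-allele retention probabilities;
#' * `maxK` minimises the expected number of global allele losses in the
#'   progeny (maximises the total allele count K);
#' * `RND` is the unmanaged control: random contributions, no migration.
#'
#' `lambda` weights the within-subpopulation component (study values 0,
#' 0.5, 1, 1000). `migrants` is the mean number of migrants per deme per
#' generation (study values 0.4, 1, 2); plans carry exactly
#' `round(migrants * n_demes)` migrant offspring in total.
#'
#' @param method one of `"maxHT"`, `"maxAT"`, `"maxK"`, `"RND"`.
#' @param lambda non-negative finite weight of the within component.
#' @param migrants mean migrants per deme per generation.
#' @return An object of class `objective`.
#' @export
objective <- function(method = c("maxHT", "maxAT", "maxK", "RND"),
                      lambda = 1, migrants = 1) {
  method <- match.arg(method)
  stopifnot(is.numeric(lambda), is.finite(lambda), lambda >= 0,
            is.numeric(migrants), migrants >= 0)
  structure(list(method = method, lambda = lambda, migrants = migrants),
            class = "objective")
}

#' Annealing schedule
#'
#' Geometric-cooling schedule for the plan search. With `t0 = NA` the
#' initial temperature is calibrated from 100 probe moves so that a typical
#' worsening move is accepted with probability about one half.
#'
#' @param t0 initial temperature, or `NA` to calibrate.
#' @param cooling geometric cooling factor in (0, 1).
#' @param steps_per_temp moves evaluated at each temperature.
#' @param iterations total moves evaluated.
#' @return An object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(t0 = NA_real_, cooling = 0.95,
                            steps_per_temp = 200, iterations = 30000) {
  stopifnot(cooling > 0, cooling < 1, steps_per_temp >= 1, iterations >= 1)
  structure(list(t0 = t0, cooling = cooling,
                 steps_per_temp = as.integer(steps_per_temp),
                 iterations = as.integer(iterations)),
            class = "anneal_schedule")
}

# slot-level plan constructor; one row per offspring, grouped by destination
new_plan <- function(dest, natal, sire, dam, gm, deme_size, migrants) {
  plan <- structure(list(dest = as.integer(dest), natal = as.integer(natal),
                         sire = as.integer(sire), dam = as.integer(dam)),
                    class = "contribution_plan")
  attr(plan, "n_demes") <- n_demes(gm)
  attr(plan, "deme_size") <- as.integer(deme_size)
  attr(plan, "migrants") <- as.integer(migrants)
  attr(plan, "parents") <- list(deme = gm$deme, sex = gm$sex)
  validate_plan(plan)
  plan
}

validate_plan <- function(plan) {
  par <- attr(plan, "parents")
  D <- attr(plan, "n_demes")
  N <- attr(plan, "deme_size")
  if (length(plan$dest) != D * N)
    stop("plan must assign exactly deme_size offspring per destination deme")
  if (any(tabulate(plan$dest, D) != N))
    stop("per-destination offspring totals violated")
  if (any(par$deme[plan$sire] != plan$natal) ||
      any(par$deme[plan$dam] != plan$natal))
    stop("sire and dam must belong to the natal deme")
  if (any(par$sex[plan$sire] != "M") || any(par$sex[plan$dam] != "F"))
    stop("sires must be male and dams female")
  m <- sum(plan$natal != plan$dest)
  if (m != attr(plan, "migrants"))
    stop("plan carries ", m, " migrants, budget is ", attr(plan, "migrants"))
  invisible(plan)
}

#' @export
print.contribution_plan <- function(x, ...) {
  cat("Contribution plan: ", length(x$dest), " offspring, ",
      attr(x, "n_demes"), " demes, ", sum(x$natal != x$dest),
      " migrants\n", sep = "")
  sc <- attr(x, "score")
  if (!is.null(sc)) cat("objective score: ", format(sc), "\n", sep = "")
  invisible(x)
}

#' Aggregate a plan into mating entries
#'
#' @param x a `contribution_plan`.
#' @param ... unused.
#' @return Data frame with one row per (natal deme, sire, dam, destination)
#'   mating and its offspring count `n_offspring`.
#' @export
as.data.frame.contribution_plan <- function(x, ...) {
  df <- data.frame(natal = x$natal, sire = x$sire, dam = x$dam, dest = x$dest)
  agg <- stats::aggregate(list(n_offspring = rep(1L, nrow(df))),
                          df, FUN = sum)
  agg[order(agg$natal, agg$sire, agg$dam, agg$dest), , drop = FALSE]
}

deme_members <- function(gm, d, sex = NULL) {
  idx <- which(gm$deme == d & (if (is.null(sex)) TRUE else gm$sex == sex))
  if (length(idx) == 0) stop("deme ", d, " has no ", sex %||% "", " parents")
  idx
}

#' Random contribution plan (unmanaged control)
#'
#' For every offspring slot the dam and sire are drawn uniformly with
#' replacement from the females and males of the natal deme; the
#' destination equals the natal deme (no migration).
#'
#' @param gm the parental `geno_matrix` (sexed).
#' @param deme_size offspring per deme; defaults to the current deme sizes.
#' @return A `contribution_plan`.
#' @export
random_plan <- function(gm, deme_size = NULL) {
  D <- n_demes(gm)
  deme_size <- deme_size %||% (nrow(gm$a1) %/% D)
  dest <- rep(seq_len(D), each = deme_size)
  sire <- dam <- integer(length(dest))
  for (d in seq_len(D)) {
    rows <- which(dest == d)
    sire[rows] <- sample(deme_members(gm, d, "M"), deme_size, replace = TRUE)
    dam[rows] <- sample(deme_members(gm, d, "F"), deme_size, replace = TRUE)
  }
  new_plan(dest, dest, sire, dam, gm, deme_size, migrants = 0L)
}

#' Random feasible plan with a fixed migrant total
#'
#' Starting point of the annealing search: random within-deme matings per
#' destination, then `n_migrants` uniformly chosen slots are re-sourced
#' from a random foreign deme.
#'
#' @param gm the parental `geno_matrix` (sexed).
#' @param n_migrants total migrant offspring.
#' @param deme_size offspring per deme; defaults to the current deme sizes.
#' @return A `contribution_plan`.
#' @export
initial_plan <- function(gm, n_migrants, deme_size = NULL) {
  D <- n_demes(gm)
  deme_size <- deme_size %||% (nrow(gm$a1) %/% D)
  if (n_migrants > D * deme_size)
    stop("migrant budget exceeds total offspring")
  if (n_migrants > 0 && D < 2)
    stop("migration requires at least two demes")
  plan <- random_plan(gm, deme_size)
  natal <- plan$natal
  sire <- plan$sire
  dam <- plan$dam
  mig <- sample.int(D * deme_size, n_migrants)
  for (s in mig) {
    foreign <- setdiff(seq_len(D), plan$dest[s])
    nd <- foreign[sample.int(length(foreign), 1)]
    natal[s] <- nd
    sire[s] <- sample(deme_members(gm, nd, "M"), 1)
    dam[s] <- sample(deme_members(gm, nd, "F"), 1)
  }
  new_plan(plan$dest, natal, sire, dam, gm, deme_size, migrants = n_migrants)
}

#' Propose one elementary plan move
#'
#' Draws uniformly among the feasibility-preserving move kinds of the
#' annealing search (offspring reassignment within a destination, parent
#' replacement, destination swap, migrant re-sourcing, migrant relocation).
#' Per-destination totals and the total migrant count are invariant; if no
#' feasible move is found the plan is returned unchanged.
#'
#' @param plan a `contribution_plan`.
#' @param gm the parental `geno_matrix`.
#' @return A `contribution_plan`.
#' @export
propose_move <- function(plan, gm) {
  res <- propose_move_cpp(gm$deme, gm$sex == "F",
                          attr(plan, "deme_size"), attr(plan, "migrants"),
                          plan$natal, plan$sire, plan$dam)
  new_plan(plan$dest, res$natal, res$sire, res$dam, gm,
           attr(plan, "deme_size"), attr(plan, "migrants"))
}

# per-parent gamete counts into each destination deme
gamete_counts <- function(plan, n_parents) {
  D <- attr(plan, "n_demes")
  g <- matrix(0L, n_parents, D)
  for (d in seq_len(D)) {
    rows <- which(plan$dest == d)
    tab <- tabulate(c(plan$sire[rows], plan$dam[rows]), n_parents)
    g[, d] <- tab
  }
  g
}

#' Expected progeny allele frequencies under a plan
#'
#' For destination deme s and allele a, p' = sum over parents k of
#' g(k, s) * x(k, a) / (2 * N_s), where g(k, s) is the parent's gamete
#' count into s and x(k, a) its transmission probability of allele a
#' (1 if homozygous for a, 1/2 if a heterozygous carrier, 0 otherwise).
#'
#' @param plan a `contribution_plan`.
#' @param gm the parental `geno_matrix`.
#' @param loci locus indices (default: all).
#' @return A `freq_table` over the destination demes.
#' @export
expected_progeny_freqs <- function(plan, gm, loci = NULL) {
  validate_plan(plan)
  loci <- loci %||% seq_len(n_loci(gm))
  D <- attr(plan, "n_demes")
  N <- attr(plan, "deme_size")
  L <- length(loci)
  p <- array(0, c(D, 32L, L))
  for (d in seq_len(D)) {
    rows <- which(plan$dest == d)
    par <- c(plan$sire[rows], plan$dam[rows])  # one gamete per entry
    A <- rbind(gm$a1[par, loci, drop = FALSE], gm$a2[par, loci, drop = FALSE])
    idx <- as.vector(A) + 1L + 32L * rep(seq_len(L) - 1L, each = nrow(A))
    p[d, , ] <- 0.5 * tabulate(idx, 32L * L) / (2 * N)
  }
  freq_table(p, n = rep(N, D), loci = loci)
}

# array (demes x 32 x loci) of allele-loss probabilities
loss_probs <- function(plan, gm, loci = NULL) {
  loci <- loci %||% seq_len(n_loci(gm))
  D <- attr(plan, "n_demes")
  L <- length(loci)
  g <- gamete_counts(plan, nrow(gm$a1))
  loss <- array(1, c(D, 32L, L))
  for (d in seq_len(D)) {
    for (k in which(g[, d] > 0)) {
      c1 <- gm$a1[k, loci]
      c2 <- gm$a2[k, loci]
      hom <- c1 == c2
      if (any(hom))
        loss[cbind(d, c1[hom] + 1L, which(hom))] <- 0
      if (any(!hom)) {
        w <- 0.5^g[k, d]
        i1 <- cbind(d, c1[!hom] + 1L, which(!hom))
        i2 <- cbind(d, c2[!hom] + 1L, which(!hom))
        loss[i1] <- loss[i1] * w
        loss[i2] <- loss[i2] * w
      }
    }
  }
  loss
}

#' Probability that an allele is lost in a destination deme
#'
#' Under independent Mendelian transmission, a parent contributing g
#' gametes fails to transmit an allele it carries heterozygously with
#' probability (1/2)^g, always transmits an allele it is homozygous for,
#' and never transmits an allele it lacks; the loss probability is the
#' product over contributing parents.
#'
#' @param plan a `contribution_plan`.
#' @param gm the parental `geno_matrix`.
#' @param locus locus index.
#' @param allele allele code in 0-31.
#' @param dest destination deme.
#' @return P(allele absent from the progeny of `dest`), in \[0, 1\].
#' @export
allele_loss_prob <- function(plan, gm, locus, allele, dest) {
  stopifnot(allele >= 0, allele <= 31)
  loss_probs(plan, gm, locus)[dest, allele + 1L, 1]
}

#' Objective score of a plan
#'
#' Evaluates the management criterion on the expected progeny:
#' * `maxHT`: D_G + lambda * H_S of [expected_progeny_freqs()];
#' * `maxAT`: E\[D_A\] + lambda * E\[A_S\] from per-allele retention
#'   probabilities R = 1 - P_loss, with E\[a_s\] = sum(R) per deme and
#'   deme pairs treated as independent;
#' * `maxK`: minus the expected number of global allele losses,
#'   -sum over loci and parental alleles of prod over demes P_loss.
#'
#' @param plan a `contribution_plan`.
#' @param gm the parental `geno_matrix`.
#' @param obj an [objective()] with method other than `"RND"`.
#' @param loci locus indices (default: all).
#' @return The scalar score (larger is better).
#' @export
objective_value <- function(plan, gm, obj, loci = NULL) {
  if (obj$method == "RND")
    stop("the RND control has no objective score")
  loci <- loci %||% seq_len(n_loci(gm))
  if (obj$method == "maxHT") {
    hp <- het_partition(expected_progeny_freqs(plan, gm, loci))
    return(hp$D_G + obj$lambda * hp$H_S)
  }
  loss <- loss_probs(plan, gm, loci)
  D <- dim(loss)[1]
  L <- dim(loss)[3]
  if (obj$method == "maxAT") {
    R <- 1 - loss
    A_S <- sum(R) / D / L - 1
    D_A <- 0
    if (D > 1) {
      for (i in seq_len(D - 1)) {
        Ri <- matrix(R[i, , ], 32, L)
        for (j in (i + 1):D) {
          Rj <- matrix(R[j, , ], 32, L)
          D_A <- D_A + sum(0.5 * (Ri * (1 - Rj) + Rj * (1 - Ri)))
        }
      }
      D_A <- D_A / (D * (D - 1) / 2) / L
    }
    return(D_A + obj$lambda * A_S)
  }
  # maxK: restrict to alleles present among the parents
  pres <- array(FALSE, c(32L, L))
  for (l in seq_len(L)) {
    a <- c(gm$a1[, loci[l]], gm$a2[, loci[l]])
    pres[unique(a) + 1L, l] <- TRUE
  }
  prod_loss <- matrix(apply(loss, c(2, 3), prod), 32, L)
  -sum(prod_loss[pres])
}

#' Search a contribution/mating/migration plan by simulated annealing
#'
#' Metropolis search over feasible plans: worse moves are accepted with
#' probability exp(delta / T) under a geometrically cooled temperature T;
#' the best plan visited is returned, so the final score is never below the
#' initial one. Identical seeds give bitwise-identical plans.
#'
#' @param gm the parental `geno_matrix` (sexed, equal-sized demes).
#' @param obj an [objective()] (`maxHT`, `maxAT` or `maxK`).
#' @param managed a `managed_set` from [select_managed()], or an integer
#'   vector of locus indices to optimise on.
#' @param schedule an [anneal_schedule()].
#' @param deme_size offspring per destination deme; defaults to the
#'   parental deme size.
#' @param initial optional feasible starting `contribution_plan`; defaults
#'   to [initial_plan()].
#' @return The best `contribution_plan` found, with attributes `score`
#'   (its objective value), `score0` (the initial plan's) and `t0` (the
#'   calibrated initial temperature).
#' @export
anneal_plan <- function(gm, obj, managed = NULL, schedule = anneal_schedule(),
                        deme_size = NULL, initial = NULL) {
  if (obj$method == "RND")
    stop("use random_plan() for the unmanaged control")
  loci <- if (inherits(managed, "managed_set")) managed$loci
          else managed %||% seq_len(n_loci(gm))
  D <- n_demes(gm)
  deme_size <- deme_size %||% (nrow(gm$a1) %/% D)
  M <- as.integer(round(obj$migrants * D))
  plan0 <- initial %||% initial_plan(gm, M, deme_size)
  stopifnot(attr(plan0, "migrants") == M)
  res <- anneal_cpp(gm$a1[, loci, drop = FALSE], gm$a2[, loci, drop = FALSE],
                    gm$deme, gm$sex == "F", deme_size, M,
                    obj$method, obj$lambda,
                    plan0$natal, plan0$sire, plan0$dam,
                    schedule$t0, schedule$cooling, schedule$steps_per_temp,
                    schedule$iterations)
  plan <- new_plan(plan0$dest, res$natal, res$sire, res$dam, gm,
                   deme_size, M)
  attr(plan, "score") <- res$score
  attr(plan, "score0") <- res$score0
  attr(plan, "t0") <- res$t0
  plan
}
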