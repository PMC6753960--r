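#' Realise the progeny of a contribution plan
#'
#' Mendelian sampling at whole-locus resolution: each offspring receives,
#' at every locus independently, one of its sire's two locus alleles with
#' probability 1/2 and likewise one of its dam's -- no recombination within
#' a 5-SNP locus, free recombination between loci, and no new mutation
#' during management. Offspring are placed in their destination demes and
#' sexes fill each deme's half-female, half-male quota uniformly at random.
#'
#' @param plan a `contribution_plan`.
#' @param gm the parental `geno_matrix`; all its loci are transmitted.
#' @return The offspring `geno_matrix`.
#' @export
make_progeny <- function(plan, gm) {
  validate_plan(plan)
  if (max(plan$sire, plan$dam) > nrow(gm$a1))
    stop("plan references parents absent from the genotype matrix")
  n_off <- length(plan$dest)
  L <- n_loci(gm)
  N <- attr(plan, "deme_size")
  if (N %% 2 != 0)
    stop("destination deme size must be even to fill the sex quota")
  off1 <- gm$a1[plan$sire, , drop = FALSE]
  alt <- gm$a2[plan$sire, , drop = FALSE]
  pick <- matrix(runif(n_off * L) < 0.5, n_off, L)
  off1[pick] <- alt[pick]
  off2 <- gm$a1[plan$dam, , drop = FALSE]
  alt <- gm$a2[plan$dam, , drop = FALSE]
  pick <- matrix(runif(n_off * L) < 0.5, n_off, L)
  off2[pick] <- alt[pick]
  sex <- unlist(lapply(seq_len(attr(plan, "n_demes")),
                       function(d) sample(rep(c("F", "M"), each = N / 2))))
  geno_matrix(off1, off2, deme = plan$dest, sex = sex, map = gm$map)
}

#' Run the multi-generation management loop
#'
#' Per generation: search the optimal plan on the managed loci (or draw a
#' random unmanaged plan for `RND`), realise the progeny by Mendelian
#' sampling, and record a [diversity_report()] on the measurement scope --
#' the managed panel itself (loci-of-interest scenario) or all loci
#' (whole-genome scenario). Generations are discrete: parents are discarded
#' after reproducing. The baseline (generation 0) report is always first.
#'
#' @param gm the founder `geno_matrix` (sexed, equal-sized demes with equal
#'   sex counts).
#' @param obj an [objective()].
#' @param gens number of managed generations (study: 25).
#' @param managed a `managed_set` from [select_managed()]; required unless
#'   `obj$method == "RND"`.
#' @param scope `"managed"` to measure statistics on the managed panel,
#'   `"all"` for the whole genome; defaults to the panel's own scope flag.
#' @param schedule an [anneal_schedule()].
#' @param keep_plans if `TRUE`, the per-generation plans are returned.
#' @return A `management_run`: list with `report` (data frame, one row per
#'   generation 0..gens), `final` (the last `geno_matrix`), and the run
#'   settings.
#' @export
run_management <- function(gm, obj, gens = 25, managed = NULL,
                           scope = NULL, schedule = anneal_schedule(),
                           keep_plans = FALSE) {
  stopifnot(inherits(obj, "objective"), is_count(gens), gens >= 0)
  if (is.null(managed) && obj$method != "RND")
    stop("managed loci are required for an optimising method")
  scope <- scope %||% (if (inherits(managed, "managed_set")) managed$scope
                       else "managed")
  scope <- match.arg(scope, c("managed", "all"))
  loci <- if (scope == "all") seq_len(n_loci(gm))
          else if (inherits(managed, "managed_set")) managed$loci
          else as.integer(managed)
  if (scope == "managed") {
    # unmanaged, unmeasured loci play no role: drop them for speed
    gm <- subset_loci(gm, loci)
    managed <- seq_along(loci)
    loci <- seq_along(loci)
  }
  baseline <- baseline_presence(allele_freqs(gm, loci))
  reports <- vector("list", gens + 1)
  reports[[1]] <- cbind(generation = 0L,
                        diversity_report(gm, loci, baseline, plan = NULL))
  plans <- if (keep_plans) vector("list", gens) else NULL
  for (t in seq_len(gens)) {
    plan <- if (obj$method == "RND") random_plan(gm)
            else anneal_plan(gm, obj, managed, schedule)
    gm <- make_progeny(plan, gm)
    reports[[t + 1]] <- cbind(generation = t,
                              diversity_report(gm, loci, baseline, plan))
    if (keep_plans) plans[[t]] <- plan
  }
  structure(list(report = do.call(rbind, reports), final = gm,
                 objective = obj, managed = managed, scope = scope,
                 plans = plans),
            class = "management_run")
}

#' @export
print.management_run <- function(x, ...) {
  cat("Management run: ", x$objective$method,
      " (lambda = ", x$objective$lambda,
      ", migrants = ", x$objective$migrants, "), ",
      max(x$report$generation), " generations, scope = ", x$scope,
      "\n", sep = "")
  last <- x$report[nrow(x$report), ]
  cat(sprintf("generation %d: H_T = %.4f, A_T = %.3f, K = %.3f, F = %.4f\n",
              last$generation, last$H_T, last$A_T, last$K, last$F))
  invisible(x)
}
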