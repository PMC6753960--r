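#' Study configuration profiles
#'
#' `"paper"` is the full design: 10 kb sequence, mu = 5e-5, c = 1e-6, an
#' ancestral deme of 4,000 run 5,000 generations, five demes of sizes
#' 2,000 and 4 x 100 for 25 generations, samples of 40 (20 per sex) per
#' deme, 25 managed generations, 10 base replicates x 10 samplings, and
#' both marker scenarios (every 100th segregating locus measured on
#' itself; every 10th measured genome-wide).
#'
#' `"desk"` is a down-scaled profile for interactive work and tests: the
#' ancestral phase is scaled by 10 (N = 400, 500 generations, mu and c
#' times 10, preserving theta = 4*N*mu and 4*N*c), demes of 200 and
#' 4 x 40 drift for 10 generations (about the same drift time in units of
#' 2N as the full design's 25 at size 100), management itself is
#' full-sized (5 demes x 40 over 25 generations) with a lighter annealing
#' schedule, and 5 x 5 replicates.
#'
#' @param profile `"paper"` or `"desk"`.
#' @param ... named overrides of any configuration field.
#' @return A `study_config` list.
#' @export
study_profile <- function(profile = c("paper", "desk"), ...) {
  profile <- match.arg(profile)
  cfg <- if (profile == "paper") {
    list(seq_len = 10000L, mu = 5e-5, rec = 1e-6,
         ancestral_N = 4000L, ancestral_gens = 5000L,
         deme_sizes = c(2000L, 100L, 100L, 100L, 100L), split_gens = 25L,
         sample_size = 40L, manage_gens = 25L,
         methods = c("maxHT", "maxAT", "maxK", "RND"),
         lambdas = 1, migration = 1,
         scenarios = list(
           managed = list(every_nth = 100L, scope = "managed"),
           genome = list(every_nth = 10L, scope = "all")),
         n_replicates = 10L, n_samplings = 10L,
         schedule = anneal_schedule(), seed = 1L)
  } else {
    list(seq_len = 10000L, mu = 5e-4, rec = 1e-5,
         ancestral_N = 400L, ancestral_gens = 500L,
         deme_sizes = c(200L, 40L, 40L, 40L, 40L), split_gens = 10L,
         sample_size = 40L, manage_gens = 25L,
         methods = c("maxHT", "maxAT", "maxK", "RND"),
         lambdas = 1, migration = 1,
         scenarios = list(
           managed = list(every_nth = 100L, scope = "managed")),
         n_replicates = 5L, n_samplings = 5L,
         schedule = anneal_schedule(iterations = 3000, steps_per_temp = 100),
         seed = 1L)
  }
  cfg$profile <- profile
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "study_config")
}

#' Simulate the subdivided base population of a study
#'
#' Ancestral mutation-drift phase followed by the founding and independent
#' drift of the subpopulations.
#'
#' @param cfg a `study_config`.
#' @return An unsexed `metapop` with `length(cfg$deme_sizes)` demes.
#' @export
simulate_base <- function(cfg) {
  params <- sim_params(cfg$seq_len, cfg$mu, cfg$rec)
  anc <- run_ancestral(params, cfg$ancestral_N, cfg$ancestral_gens)
  found_demes(anc, cfg$deme_sizes, cfg$split_gens)
}

# grid of management settings; maxK and RND ignore lambda
setting_grid <- function(cfg) {
  rows <- list()
  for (sc in names(cfg$scenarios))
    for (m in cfg$methods)
      for (mi in cfg$migration) {
        lams <- if (m %in% c("maxHT", "maxAT")) cfg$lambdas else NA_real_
        for (la in lams)
          rows[[length(rows) + 1]] <-
            data.frame(scenario = sc, method = m, lambda = la, migration = mi)
      }
  do.call(rbind, rows)
}

#' Run the replicated management study
#'
#' Reproduces the full factorial design: for every base-population
#' replicate and every sampling event, founders are drawn and encoded, the
#' managed panel of each scenario is selected, and every
#' (method, lambda, migration) setting is run for `manage_gens`
#' generations. Per-generation statistics are averaged over all
#' replicate x sampling runs; standard errors are sample SD / sqrt(runs)
#' (0 for a single run). The whole study is deterministic given
#' `cfg$seed`: every stage draws from its own pre-derived seed, so run
#' order is immaterial.
#'
#' @param cfg a `study_config` from [study_profile()].
#' @return A `study_result`: list with `summary` (mean and SE per setting
#'   and generation), `runs` (every per-run, per-generation report row),
#'   `seeds` and `config`.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  R <- cfg$n_replicates
  S <- cfg$n_samplings
  grid <- setting_grid(cfg)
  G <- nrow(grid)
  set.seed(cfg$seed)
  seeds <- list(base = draw_seeds(R),
                samp = matrix(draw_seeds(R * S), R, S),
                run = array(draw_seeds(R * S * G), c(R, S, G)))
  rows <- list()
  for (r in seq_len(R)) {
    set.seed(seeds$base[r])
    base <- simulate_base(cfg)
    for (s in seq_len(S)) {
      set.seed(seeds$samp[r, s])
      founders <- sample_founders(base, cfg$sample_size)
      gm <- encode_genotypes(founders)
      seg <- segregating_loci(gm)
      panels <- lapply(cfg$scenarios, function(sc)
        select_managed(seg, sc$every_nth, sc$scope))
      for (g in seq_len(G)) {
        st <- grid[g, ]
        set.seed(seeds$run[r, s, g])
        obj <- objective(st$method,
                         lambda = if (is.na(st$lambda)) 1 else st$lambda,
                         migrants = st$migration)
        run <- run_management(gm, obj, gens = cfg$manage_gens,
                              managed = panels[[st$scenario]],
                              schedule = cfg$schedule)
        rows[[length(rows) + 1]] <-
          cbind(replicate = r, sampling = s, st, run$report,
                row.names = NULL)
      }
    }
  }
  runs <- do.call(rbind, rows)
  structure(list(summary = summarise_runs(runs), runs = runs,
                 seeds = seeds, config = cfg),
            class = "study_result")
}

# mean and standard error of every statistic per setting cell and generation
summarise_runs <- function(runs) {
  stats <- setdiff(names(runs),
                   c("replicate", "sampling", "scenario", "method", "lambda",
                     "migration", "generation"))
  key <- paste(runs$scenario, runs$method, runs$lambda, runs$migration,
               runs$generation)  # NA lambda (maxK, RND) keeps its group
  groups <- split(seq_len(nrow(runs)), key)
  out <- lapply(groups, function(idx) {
    cell <- runs[idx, ]
    means <- vapply(stats, function(s) mean(cell[[s]]), numeric(1))
    ses <- vapply(stats, function(s) {
      if (length(idx) < 2 || all(is.na(cell[[s]]))) return(0)
      sd(cell[[s]]) / sqrt(length(idx))
    }, numeric(1))
    cbind(cell[1, c("scenario", "method", "lambda", "migration", "generation")],
          n_runs = length(idx),
          as.data.frame(as.list(means)),
          as.data.frame(as.list(setNames(ses, paste0("se_", stats)))))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$scenario, out$method, out$lambda, out$migration,
                   out$generation), ]
  rownames(out) <- NULL
  out
}

#' @export
print.study_result <- function(x, ...) {
  cat("Study: ", x$config$n_replicates, " replicate(s) x ",
      x$config$n_samplings, " sampling(s), ",
      length(unique(x$summary$method)), " methods, generations 0..",
      max(x$summary$generation), "\n", sep = "")
  invisible(x)
}

#' Write study outputs
#'
#' Writes `summary.csv` (one row per setting cell per generation, in a
#' deterministic column order), `runs.csv` (per-run trajectories) and
#' `config.json` (the resolved configuration and derived seeds).
#'
#' @param result a `study_result`.
#' @param dir output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(summary = file.path(dir, "summary.csv"),
             runs = file.path(dir, "runs.csv"),
             config = file.path(dir, "config.json"))
  write.csv(result$summary, paths["summary"], row.names = FALSE)
  write.csv(result$runs, paths["runs"], row.names = FALSE)
  cfg <- result$config
  cfg$schedule <- unclass(cfg$schedule)
  jsonlite::write_json(list(config = unclass(cfg), seeds = result$seeds),
                       paths["config"], auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(paths)
}

#' Plot diversity trajectories
#'
#' One panel per statistic: mean trajectories over generations, one line
#' per management method (base graphics).
#'
#' @param result a `study_result`.
#' @param stats statistics to plot.
#' @param scenario scenario name (default: first).
#' @export
plot_trajectories <- function(result, stats = c("H_T", "A_T", "K", "F"),
                              scenario = NULL) {
  sm <- result$summary
  scenario <- scenario %||% sm$scenario[1]
  sm <- sm[sm$scenario == scenario, ]
  methods <- unique(sm$method)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(stats)))
  on.exit(graphics::par(old))
  for (st in stats) {
    rng <- range(sm[[st]], na.rm = TRUE)
    graphics::plot(NULL, xlim = range(sm$generation), ylim = rng,
                   xlab = "generation", ylab = st, main = st)
    for (i in seq_along(methods)) {
      mm <- sm[sm$method == methods[i], ]
      graphics::lines(mm$generation, mm[[st]], col = i,
                      lty = if (methods[i] == "RND") 3 else 1)
    }
    graphics::legend("bottomleft", legend = methods, col = seq_along(methods),
                     lty = ifelse(methods == "RND", 3, 1), cex = 0.7)
  }
  invisible(result)
}
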