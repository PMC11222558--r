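#' Experiment configuration
#'
#' Bundles and validates the parameters of a full simulation experiment:
#' genome, breeding scheme, variance targets, effect-simulation method and
#' replication structure.  Unsupported combinations (plot-phenotype targets
#' with SS_NOIA, or with by-locus scaling) are rejected here: the backward
#' NOIA transform would give two functional additive effects per QTL in the
#' plot setting, and by-locus scaling admits no plot-setting solution.
#'
#' @param example 1 (individual phenotypes, unlinked genome), 2 (individual
#'   phenotypes, linked genome) or 3 (three-way hybrid plots).
#' @param targets a \code{variance_targets} object matching the example.
#' @param method \code{"ss_noia"} or \code{"sf_ga"}.
#' @param mode \code{"by_locus"} or \code{"by_individual"}.
#' @param n_effect_reps outer replicates (effect simulation).
#' @param n_scheme_reps inner replicates (breeding + phenotypes) per effect
#'   set.
#' @param genome list of genome parameters (see Details).
#' @param scheme list of breeding-scheme parameters.
#' @param estimate run AI-REML re-estimation per scheme replicate.
#' @param covariate anchor covariate form for statistical calculations.
#' @param ga a \code{\link{ga_control}} list (SF_GA only).
#' @param seed master seed; all replicate streams derive from it.
#'
#' @details Genome parameters: example 1 uses \code{n_qtl} (default 2000);
#' examples 2-3 use \code{n_chr}, \code{chr_length}, \code{loci_per_chr},
#' \code{n_qtl}, \code{maf_min}, \code{historical_generations},
#' \code{historical_n} (and \code{divergence_generations} for example 3).
#' Scheme parameters: example 1-2 use \code{generations}, \code{n_parents},
#' \code{n_matings}, \code{offspring_per_mating}, \code{n_base}; example 3
#' takes the arguments of \code{\link{run_threeway_scheme}} plus
#' \code{n_base_lines} and \code{selfing_generations}.
#' @return list of class \code{experiment_config}.
#' @export
experiment_config <- function(example, targets, method = c("ss_noia", "sf_ga"),
                              mode = c("by_locus", "by_individual"),
                              n_effect_reps = 10L, n_scheme_reps = 2L,
                              genome = list(), scheme = list(),
                              estimate = FALSE, covariate = "genofreq",
                              ga = ga_control(), seed = 1L) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  if (!example %in% 1:3) stop("example must be 1, 2 or 3")
  if (n_effect_reps < 1L || n_scheme_reps < 1L)
    stop("replicate counts must be >= 1")
  if (example == 3L) {
    if (targets$type != "ppg")
      stop("example 3 requires variance_targets_ppg()")
    if (method != "sf_ga")
      stop("unsupported combination: the plot setting requires SF_GA ",
           "(the backward transform would give two functional additive ",
           "effects per QTL)")
    if (mode != "by_individual")
      stop("unsupported combination: plot-setting effects can only be ",
           "scaled by individual")
  } else if (targets$type != "ipg") {
    stop("examples 1-2 require variance_targets()")
  }
  g_def <- if (example == 1L) list(n_qtl = 2000L)
  else if (example == 2L)
    list(n_chr = 7L, chr_length = 230, loci_per_chr = 800L,
         n_qtl = 2000L, maf_min = 0.05, historical_generations = 200L,
         historical_n = 100L)
  else list(n_chr = 7L, chr_length = 230, loci_per_chr = 300L,
            n_qtl = 800L, maf_min = 0.05, historical_generations = 100L,
            historical_n = 200L, divergence_generations = 20L)
  s_def <- if (example < 3L)
    list(generations = 4L, n_parents = 150L, n_matings = 150L,
         offspring_per_mating = 5L, n_base = 100L)
  else list(generations = 4L, n_base_lines = 100L, selfing_generations = 4L,
            lines1_per_gen = 200L, lines2_per_gen = 100L,
            seeds_per_cross = 5L, n_twoway = 100L, plots_per_line1 = 5L,
            plots_per_twoway = 10L, base_plots_per_line1 = 5L,
            first_plot_generation = 2L)
  genome <- utils::modifyList(g_def, genome)
  scheme <- utils::modifyList(s_def, scheme)
  structure(list(example = example, targets = targets, method = method,
                 mode = mode, n_effect_reps = n_effect_reps,
                 n_scheme_reps = n_scheme_reps, genome = genome,
                 scheme = scheme, estimate = estimate,
                 covariate = covariate, ga = ga, seed = seed),
            class = "experiment_config")
}

# derive independent child seeds from a master seed
.child_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(master)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  s
}

# one iPG base population per the config
.ex_base_ipg <- function(cfg) {
  if (cfg$example == 1L) {
    gm <- le_genome(cfg$genome$n_qtl)
    sample_base_le(cfg$scheme$n_base, gm)
  } else {
    gm <- ld_genome(cfg$genome$n_chr, cfg$genome$chr_length,
                    cfg$genome$loci_per_chr)
    base <- simulate_ld_base(cfg$scheme$n_base, gm,
                             cfg$genome$historical_generations,
                             cfg$genome$historical_n)
    keep_qtl(draw_qtl(base, cfg$genome$n_qtl, cfg$genome$maf_min))
  }
}

# calculated variance rows for one iPG scheme replicate
.ipg_replicate_rows <- function(cfg, fx, base, seed) {
  set.seed(seed)
  mode_scheme <- if (cfg$example == 1L) "le" else "ld"
  pop <- run_ipg_scheme(base, cfg$scheme$generations, cfg$scheme$n_parents,
                        cfg$scheme$n_matings,
                        cfg$scheme$offspring_per_mating, mode = mode_scheme)
  ph <- simulate_phenotypes_ipg(pop, fx, cfg$targets$residual)
  desc <- which(pop$generation >= 1L)
  sx_d <- reanchor_statistical(fx, pop, subset = desc,
                               covariate = cfg$covariate)
  pop_d <- subset_population(pop, desc)
  ve <- stats::var(ph$e[desc])
  r_ind <- variance_by_individual(genetic_values(pop_d, sx_d))
  r_loc <- variance_by_locus(sx_d)
  f_ind <- variance_by_individual(genetic_values(pop_d, fx),
                                  basis = "functional")
  rows <- rbind(
    data.frame(measure = "calc_stat_by_individual",
               as.data.frame(t(r_ind$components)), residual = ve),
    data.frame(measure = "calc_stat_by_locus",
               as.data.frame(t(r_loc$components)), residual = ve),
    data.frame(measure = "calc_func_by_individual",
               as.data.frame(t(f_ind$components)), residual = ve))
  if (cfg$estimate) {
    grms <- build_grms_ipg(pop, subset = desc)
    fit <- aireml(ph$y[desc], component_covariances(grms))
    est <- fit$estimates
    rows <- rbind(data.frame(measure = "estimated_stat",
                             additive = est[["additive"]],
                             dominance = est[["dominance"]],
                             epistasis = est[["epistasis"]],
                             residual = est[["residual"]]), rows)
  }
  rows
}

.ppg_replicate_rows <- function(cfg, fx, base1, base2, seed) {
  set.seed(seed)
  sc <- cfg$scheme
  sw <- run_threeway_scheme(base1, base2, sc$generations, sc$lines1_per_gen,
                            sc$lines2_per_gen, sc$seeds_per_cross,
                            sc$selfing_generations, sc$n_twoway,
                            sc$plots_per_line1, sc$plots_per_twoway,
                            sc$base_plots_per_line1,
                            sc$first_plot_generation, mode = "ld")
  ph <- simulate_phenotypes_ppg(sw, fx, cfg$targets$residual)
  # re-anchor statistical effects and covariates at the descendant line
  # populations' frequencies (the pPG analog of the generations-1-4
  # re-anchoring used for individual data)
  q1d <- allele_frequencies(sw$lines1, subset = sort(unique(sw$plots$i1)))$q
  q2d <- allele_frequencies(sw$lines2,
                            subset = sort(unique(c(sw$plots$i2a,
                                                   sw$plots$i2b))))$q
  swd <- sw; swd$anchor_q1 <- q1d; swd$anchor_q2 <- q2d
  sx <- noia_forward_ppg(fx, q1d, q2d)
  ve <- stats::var(ph$e)
  r_ind <- variance_ppg(swd, sx, mode = "by_individual")
  r_loc <- variance_ppg(swd, sx, mode = "by_locus")
  f_ind <- variance_ppg(swd, fx, mode = "by_individual")
  pack <- function(measure, vc) {
    data.frame(measure = measure, as.data.frame(t(vc$components)),
               residual = ve)
  }
  rows <- rbind(pack("calc_stat_by_individual", r_ind),
                pack("calc_stat_by_locus", r_loc),
                pack("calc_func_by_individual", f_ind))
  if (cfg$estimate) {
    grms <- build_grms_ppg(sw)
    fit <- aireml(ph$y, component_covariances(grms))
    est <- fit$estimates
    rows <- rbind(data.frame(measure = "estimated_stat",
                             additive1 = est[["additive1"]],
                             additive2 = est[["additive2"]],
                             dominance3 = est[["dominance3"]],
                             epistasis3 = est[["epistasis3"]],
                             residual = est[["residual"]]), rows)
  }
  rows
}

#' Run a replicated simulation experiment
#'
#' Outer replicates simulate a base population (or populations) and a
#' functional-effect set meeting the variance targets; inner replicates run
#' the breeding scheme, simulate phenotypes and compute the calculated (and
#' optionally REML-estimated) statistical and functional variances over the
#' descendant generations.  Results are aggregated as mean and SD (divisor
#' n - 1) per measure and component.
#'
#' @param config an \code{\link{experiment_config}}.
#' @param verbose print progress.
#' @return list of class \code{experiment_result} with \code{per_replicate}
#'   and \code{summary} data.frames and the per-replicate achieved fitness
#'   (SF_GA).
#' @export
run_experiment <- function(config, verbose = FALSE) {
  cfg <- config
  seeds <- .child_seeds(cfg$seed, cfg$n_effect_reps * (cfg$n_scheme_reps + 1L))
  si <- 0L
  out <- list(); fitness <- numeric(0)
  for (er in seq_len(cfg$n_effect_reps)) {
    si <- si + 1L
    set.seed(seeds[si])
    if (cfg$example < 3L) {
      base <- .ex_base_ipg(cfg)
      fx <- if (cfg$method == "ss_noia")
        ss_noia(base, cfg$targets, cfg$mode, covariate = cfg$covariate)
      else {
        fit <- sf_ga_ipg(base, cfg$targets, cfg$mode, control = cfg$ga,
                         covariate = cfg$covariate)
        fitness <- c(fitness, fit$fitness)
        fit$effects
      }
    } else {
      gm <- ld_genome(cfg$genome$n_chr, cfg$genome$chr_length,
                      cfg$genome$loci_per_chr)
      hist_pop <- simulate_ld_base(cfg$genome$historical_n, gm,
                                   cfg$genome$historical_generations,
                                   cfg$genome$historical_n)
      dv <- diverge_populations(hist_pop, cfg$scheme$n_base_lines,
                                cfg$scheme$n_base_lines,
                                cfg$genome$divergence_generations,
                                cfg$genome$historical_n)
      both <- bind_populations(dv$pop1, dv$pop2)
      both <- draw_qtl(both, cfg$genome$n_qtl, cfg$genome$maf_min)
      both <- keep_qtl(both)
      n1 <- n_ind(dv$pop1)
      base1 <- make_inbred_lines(subset_population(both, seq_len(n1)),
                                 cfg$scheme$selfing_generations)
      base2 <- make_inbred_lines(
        subset_population(both, n1 + seq_len(n_ind(dv$pop2))),
        cfg$scheme$selfing_generations)
      sc <- cfg$scheme
      base_scheme <- run_threeway_scheme(base1, base2, generations = 0L,
                                         sc$lines1_per_gen,
                                         sc$lines2_per_gen,
                                         sc$seeds_per_cross,
                                         sc$selfing_generations, sc$n_twoway,
                                         sc$plots_per_line1,
                                         sc$plots_per_twoway,
                                         sc$base_plots_per_line1)
      fit <- sf_ga_ppg(base_scheme, cfg$targets, control = cfg$ga)
      fitness <- c(fitness, fit$fitness)
      fx <- fit$effects
    }
    for (sr in seq_len(cfg$n_scheme_reps)) {
      si <- si + 1L
      rows <- if (cfg$example < 3L)
        .ipg_replicate_rows(cfg, fx, base, seeds[si])
      else .ppg_replicate_rows(cfg, fx, base1, base2, seeds[si])
      rows <- cbind(effect_rep = er, scheme_rep = sr, rows)
      out[[length(out) + 1L]] <- rows
      if (verbose)
        message("effect rep ", er, " scheme rep ", sr, " done")
    }
  }
  per_rep <- do.call(rbind, out)
  comp_cols <- setdiff(names(per_rep),
                       c("effect_rep", "scheme_rep", "measure"))
  agg_mean <- stats::aggregate(per_rep[comp_cols],
                               by = list(measure = per_rep$measure), mean)
  agg_sd <- stats::aggregate(per_rep[comp_cols],
                             by = list(measure = per_rep$measure),
                             stats::sd)
  long <- do.call(rbind, lapply(comp_cols, function(cc) {
    data.frame(measure = agg_mean$measure, component = cc,
               mean = agg_mean[[cc]], sd = agg_sd[[cc]])
  }))
  structure(list(per_replicate = per_rep, summary = long,
                 fitness = fitness, config = cfg),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, digits = 1, ...) {
  cat("Experiment result (example ", x$config$example, ", ",
      x$config$method, ", ", x$config$mode, "):\n", sep = "")
  s <- x$summary
  s$mean <- round(s$mean, digits); s$sd <- round(s$sd, digits)
  print(s, row.names = FALSE)
  invisible(x)
}
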