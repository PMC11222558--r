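#' Statistical variance targets
#'
#' The simulator's contract: the statistical variance components a simulated
#' base population must realize.  Single-population targets carry additive,
#' dominance and epistasis components; three-way-hybrid targets carry the two
#' population-specific additive components plus plot dominance and epistasis.
#'
#' @param additive,dominance,epistasis target statistical variances (>= 0).
#' @param residual residual variance used at phenotype simulation.
#' @return An object of class \code{variance_targets}.
#' @export
variance_targets <- function(additive, dominance, epistasis, residual = 0) {
  v <- c(additive = additive, dominance = dominance, epistasis = epistasis)
  if (any(v < 0) || residual < 0) stop("variance targets must be >= 0")
  structure(list(components = v, residual = residual, type = "ipg"),
            class = "variance_targets")
}

#' @rdname variance_targets
#' @param additive1,additive2 plot additive variances explained by the two
#'   parental populations.
#' @param dominance3,epistasis3 plot dominance and epistasis variances.
#' @export
variance_targets_ppg <- function(additive1, additive2, dominance3,
                                 epistasis3, residual = 0) {
  v <- c(additive1 = additive1, additive2 = additive2,
         dominance3 = dominance3, epistasis3 = epistasis3)
  if (any(v < 0) || residual < 0) stop("variance targets must be >= 0")
  structure(list(components = v, residual = residual, type = "ppg"),
            class = "variance_targets")
}

#' @export
print.variance_targets <- function(x, ...) {
  cat("Variance targets (", x$type, "):\n", sep = "")
  print(c(x$components, residual = x$residual))
  invisible(x)
}

#' Rescale an effect vector to a target variance
#'
#' Multiplies by sqrt(target/prior) so a variance that is quadratic in the
#' effects lands exactly on the target.  A zero target returns the zero
#' vector; a zero prior with a nonzero target is an error.
#'
#' @param x effect vector.
#' @param prior current (prior) variance implied by \code{x}.
#' @param target desired variance.
#' @export
rescale_to_target <- function(x, prior, target) {
  if (target == 0) return(x * 0)
  if (prior <= 0) stop("prior variance is 0 but target is > 0")
  x * sqrt(target / prior)
}

# prior statistical variances of an iPG statistical-effects object in a mode
.ipg_prior_var <- function(pop, sx, mode) {
  if (mode == "by_locus") variance_by_locus(sx)$components
  else variance_by_individual(genetic_values(pop, sx))$components
}

#' Simulate functional effects by sampling statistical effects (SS_NOIA)
#'
#' Samples prior statistical effects (substitution effects from
#' N(0, additive target); dominance degrees from N(dd_mean, dd_var) giving
#' delta = dd * |alpha|; epistatic effects from N(0, epistasis target)),
#' rescales each class so the base population's statistical variance in the
#' requested mode equals the target exactly, and back-transforms to
#' functional effects with the NOIA model at the base-population frequencies.
#' Single-population (iPG) targets only: in the plot setting the backward
#' transform would return two different functional additive effects per QTL,
#' contradicting the assumption that functional effects are
#' population-independent, so pPG targets are rejected.
#'
#' @param pop base \code{population} with designated QTL and pairs.
#' @param targets a \code{variance_targets} object (type "ipg").
#' @param mode \code{"by_locus"} or \code{"by_individual"} scaling.
#' @param covariate anchor covariate form (general genotype-frequency form by
#'   default).
#' @param dd_mean,dd_var mean and variance of the dominance-degree
#'   distribution (defaults 0.19 and 0.097).
#' @param seed optional integer seed.
#' @return A \code{functional_effects} object; the exactly scaled statistical
#'   effects are attached as attribute \code{"statistical"}.
#' @export
ss_noia <- function(pop, targets, mode = c("by_locus", "by_individual"),
                    covariate = "genofreq", dd_mean = 0.19, dd_var = 0.097,
                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mode <- match.arg(mode)
  if (targets$type != "ipg")
    stop("unsupported setting: SS_NOIA backward transformation would give ",
         "two functional additive effects per QTL in the plot setting; ",
         "use sf_ga_ppg()")
  gm <- pop$genome
  nq <- length(gm$qtl)
  np <- if (is.null(gm$pairs)) 0L else nrow(gm$pairs)
  anchor <- freq_anchor(pop, covariate = covariate)
  tg <- targets$components
  alpha <- stats::rnorm(nq, 0, sqrt(tg[["additive"]]))
  dd <- stats::rnorm(nq, dd_mean, sqrt(dd_var))
  delta <- dd * abs(alpha)
  aa <- stats::rnorm(np, 0, sqrt(tg[["epistasis"]]))
  fx0 <- functional_effects(a = alpha, d = delta, aa = aa, genome = gm)
  sx <- new_statistical_effects(alpha, delta, aa, fx0, anchor)
  prior <- .ipg_prior_var(pop, sx, mode)
  sx$alpha <- rescale_to_target(alpha, prior[["additive"]], tg[["additive"]])
  sx$delta <- rescale_to_target(delta, prior[["dominance"]], tg[["dominance"]])
  if (np) sx$aa <- rescale_to_target(aa, prior[["epistasis"]],
                                     tg[["epistasis"]])
  fx <- noia_backward_ipg(sx, gm)
  fx$dd <- dd
  attr(fx, "statistical") <- sx
  attr(fx, "mode") <- mode
  fx
}

# --- fitness ----------------------------------------------------------------

# precomputed base-population quantities for fast repeated fitness evaluation
.ipg_precomp <- function(pop, covariate = "genofreq") {
  anchor <- freq_anchor(pop, covariate = covariate)
  gm <- pop$genome
  fx0 <- functional_effects(a = numeric(length(gm$qtl)),
                            d = numeric(length(gm$qtl)),
                            aa = numeric(if (is.null(gm$pairs)) 0L
                                         else nrow(gm$pairs)),
                            genome = gm)
  cf <- .anchor_coef(anchor, gm$qtl)
  pm <- .partner_map(fx0)
  lv <- .locus_covariate_var(anchor, gm$qtl)
  cv <- .ipg_covariates(pop, fx0, "statistical", anchor)
  list(anchor = anchor, genome = gm, B = cf$B, m = cf$m,
       partner = pm$partner, pair_id = pm$pair_id,
       pairs_q = fx0$pairs_q, va = lv$va, vd = lv$vd,
       A = cv$A, D = cv$D, EP = cv$EP)
}

.ipg_alpha <- function(a, d, aa, pre) {
  ep <- rep(0, length(a))
  ok <- !is.na(pre$partner)
  ep[ok] <- pre$m[pre$partner[ok]] * aa[pre$pair_id[ok]]
  a - pre$B * d + ep
}

.ipg_candidate_var <- function(a, dd, aa, pre, mode) {
  d <- dd * abs(a)
  alpha <- .ipg_alpha(a, d, aa, pre)
  if (mode == "by_locus") {
    c(additive = sum(pre$va * alpha^2),
      dominance = sum(pre$vd * d^2),
      epistasis = if (length(aa))
        sum(aa^2 * pre$va[pre$pairs_q[, 1L]] * pre$va[pre$pairs_q[, 2L]])
      else 0)
  } else {
    c(additive = .pvar(drop(pre$A %*% alpha)),
      dominance = .pvar(drop(pre$D %*% d)),
      epistasis = if (is.null(pre$EP)) 0 else .pvar(drop(pre$EP %*% aa)))
  }
}

#' Fitness of a candidate functional-effect set (single population)
#'
#' Converts the candidate (a, dd, aa) with d = dd * |a| to statistical
#' effects by the forward NOIA transform at the base-population frequencies,
#' computes the statistical variances in the requested mode, and returns the
#' negative sum of absolute deviations from the targets (0 at a perfect
#' match).
#'
#' @param candidate list with numeric \code{a}, \code{dd}, \code{aa}.
#' @param pop base \code{population}.
#' @param targets a \code{variance_targets} (type "ipg").
#' @param mode variance calculation mode.
#' @param covariate anchor covariate form.
#' @return fitness (<= 0) with the achieved variances as attribute
#'   \code{"variances"}.
#' @export
fitness_ipg <- function(candidate, pop, targets,
                        mode = c("by_locus", "by_individual"),
                        covariate = "genofreq") {
  mode <- match.arg(mode)
  pre <- .ipg_precomp(pop, covariate)
  v <- .ipg_candidate_var(candidate$a, candidate$dd, candidate$aa, pre, mode)
  f <- -sum(abs(v - targets$components))
  attr(f, "variances") <- v
  f
}

# precomputed plot covariates for the pPG fitness (base plot set)
.ppg_precomp <- function(scheme, plots = NULL) {
  if (is.null(plots)) plots <- scheme$base_plots
  gm <- scheme$lines1$genome
  q1 <- scheme$anchor_q1
  q2 <- scheme$anchor_q2
  fx0 <- functional_effects(a = numeric(length(gm$qtl)),
                            d = numeric(length(gm$qtl)),
                            aa = numeric(if (is.null(gm$pairs)) 0L
                                         else nrow(gm$pairs)),
                            genome = gm)
  pm <- .partner_map(fx0)
  cv <- .ppg_covariates(scheme, plots, gm$qtl, fx0$pairs_q, "statistical",
                        q1 = q1, q2 = q2)
  list(genome = gm, qq1 = q1[gm$qtl], qq2 = q2[gm$qtl],
       partner = pm$partner, pair_id = pm$pair_id, pairs_q = fx0$pairs_q,
       A1 = cv$A1, A2 = rbind(cv$A2a, cv$A2b), D = cv$D, EP = cv$EP)
}

.ppg_candidate_var <- function(a, dd, aa, pre) {
  d <- dd * abs(a)
  ep <- rep(0, length(a))
  ok <- !is.na(pre$partner)
  csum <- pre$qq1 + pre$qq2
  ep[ok] <- csum[pre$partner[ok]] * aa[pre$pair_id[ok]]
  alpha1 <- a + (1 - 2 * pre$qq2) * d + ep
  alpha2 <- a + (1 - 2 * pre$qq1) * d + ep
  c(additive1 = .pvar(drop(pre$A1 %*% alpha1)),
    additive2 = .pvar(drop(pre$A2 %*% alpha2)),
    dominance3 = .pvar(drop(pre$D %*% d)),
    epistasis3 = if (is.null(pre$EP)) 0 else .pvar(drop(pre$EP %*% aa)))
}

#' Fitness of a candidate functional-effect set (three-way hybrid plots)
#'
#' Computes plot statistical effects from the candidate via the pPG forward
#' transform at the two base populations' allele frequencies, then plot-level
#' variances by individual over the base plot set.  Only by-individual mode
#' is supported: with by-locus scaling no functional-effect set reproduces
#' the population-specific additive variances, so the setting is rejected.
#'
#' @param candidate list with \code{a}, \code{dd}, \code{aa}.
#' @param scheme a three-way scheme (provides base plots and anchors).
#' @param targets a \code{variance_targets} (type "ppg").
#' @param mode must be \code{"by_individual"}.
#' @return fitness (<= 0) with achieved variances attached.
#' @export
fitness_ppg <- function(candidate, scheme, targets, mode = "by_individual") {
  if (mode != "by_individual")
    stop("unsupported setting: by-locus scaling admits no functional-effect ",
         "solution in the plot setting; use by_individual")
  pre <- .ppg_precomp(scheme)
  v <- .ppg_candidate_var(candidate$a, candidate$dd, candidate$aa, pre)
  f <- -sum(abs(v - targets$components))
  attr(f, "variances") <- v
  f
}

# --- genetic algorithm ------------------------------------------------------

#' Genetic-algorithm control parameters
#'
#' @param pop_size number of candidate solutions per GA generation.
#' @param max_generations GA generation budget.
#' @param p_crossover probability a pair of parents is recombined (blend
#'   crossover, BLX-alpha) rather than copied.
#' @param blend_alpha blend-crossover expansion factor.
#' @param p_mutation per-gene Gaussian mutation probability.
#' @param mutation_sd_frac mutation standard deviation as a fraction of the
#'   class prior standard deviation.
#' @param elitism_frac fraction of top candidates copied unchanged.
#' @param tournament_k tournament size for parent selection.
#' @param tolerance absolute fitness tolerance for convergence; default
#'   0.1 percent of the summed variance targets.
#' @param local_search apply the variance-rescaling repair operator (scales
#'   each effect class toward its target variance; a memetic local-search
#'   step).
#' @param local_search_prob per-offspring probability of the repair step.
#' @return list of class \code{ga_control}.
#' @export
ga_control <- function(pop_size = 200L, max_generations = 2000L,
                       p_crossover = 0.8, blend_alpha = 0.5,
                       p_mutation = 0.1, mutation_sd_frac = 0.1,
                       elitism_frac = 0.05, tournament_k = 3L,
                       tolerance = NULL, local_search = TRUE,
                       local_search_prob = 0.25) {
  stopifnot(p_crossover >= 0, p_crossover <= 1, p_mutation >= 0,
            p_mutation <= 1, is.null(tolerance) || tolerance > 0)
  structure(as.list(environment()), class = "ga_control")
}

# scale x so that a variance quadratic in x hits the target exactly
.scale_class <- function(x, cur, target) {
  if (target == 0) return(x * 0)
  if (cur <= 0) return(x)
  x * sqrt(target / cur)
}

# repair operator, iPG: epistasis and dominance classes scale exactly;
# the additive class scale solves a quadratic because alpha is affine in it
.repair_ipg <- function(g, pre, targets, mode, nq, np) {
  a <- g[seq_len(nq)]; dd <- g[nq + seq_len(nq)]
  aa <- if (np) g[2L * nq + seq_len(np)] else numeric(0)
  tg <- targets$components
  if (np) {
    cur <- if (mode == "by_locus")
      sum(aa^2 * pre$va[pre$pairs_q[, 1L]] * pre$va[pre$pairs_q[, 2L]])
    else .pvar(drop(pre$EP %*% aa))
    aa <- .scale_class(aa, cur, tg[["epistasis"]])
  }
  d <- dd * abs(a)
  cur <- if (mode == "by_locus") sum(pre$vd * d^2)
         else .pvar(drop(pre$D %*% d))
  if (cur > 0) {
    s <- sqrt(tg[["dominance"]] / cur)
    dd <- dd * s; d <- d * s
  }
  # alpha(s) = s * a + e with d, aa held fixed (dd is divided by |s| after)
  ep <- rep(0, nq); ok <- !is.na(pre$partner)
  ep[ok] <- pre$m[pre$partner[ok]] * aa[pre$pair_id[ok]]
  e <- -pre$B * d + ep
  if (mode == "by_locus") {
    A2 <- sum(pre$va * a^2); A1 <- sum(pre$va * a * e)
    A0 <- sum(pre$va * e^2)
  } else {
    x <- drop(pre$A %*% a); y <- drop(pre$A %*% e)
    A2 <- .pvar(x); A1 <- mean(x * y) - mean(x) * mean(y); A0 <- .pvar(y)
  }
  disc <- A1^2 - A2 * (A0 - tg[["additive"]])
  if (A2 > 0) {
    s <- if (disc >= 0) {
      r1 <- (-A1 + sqrt(disc)) / A2; r2 <- (-A1 - sqrt(disc)) / A2
      if (abs(r1 - 1) <= abs(r2 - 1)) r1 else r2
    } else -A1 / A2
    if (is.finite(s) && abs(s) > 1e-12) {
      a <- s * a
      dd <- dd / abs(s)
    }
  }
  c(a, dd, aa)
}

# repair operator, pPG: dominance/epistasis classes exact; additive scale
# chosen by 1-D search over the two additive deviation terms
.repair_ppg <- function(g, pre, targets, nq, np) {
  a <- g[seq_len(nq)]; dd <- g[nq + seq_len(nq)]
  aa <- if (np) g[2L * nq + seq_len(np)] else numeric(0)
  tg <- targets$components
  if (np) {
    cur <- .pvar(drop(pre$EP %*% aa))
    aa <- .scale_class(aa, cur, tg[["epistasis3"]])
  }
  d <- dd * abs(a)
  cur <- .pvar(drop(pre$D %*% d))
  if (cur > 0) {
    s <- sqrt(tg[["dominance3"]] / cur)
    dd <- dd * s; d <- d * s
  }
  ep <- rep(0, nq); ok <- !is.na(pre$partner)
  csum <- pre$qq1 + pre$qq2
  ep[ok] <- csum[pre$partner[ok]] * aa[pre$pair_id[ok]]
  e1 <- (1 - 2 * pre$qq2) * d + ep
  e2 <- (1 - 2 * pre$qq1) * d + ep
  x1 <- drop(pre$A1 %*% a); y1 <- drop(pre$A1 %*% e1)
  x2 <- drop(pre$A2 %*% a); y2 <- drop(pre$A2 %*% e2)
  vfun <- function(x, y, s) .pvar(s * x + y) # small n of evals; keep simple
  obj <- function(s) abs(vfun(x1, y1, s) - tg[["additive1"]]) +
    abs(vfun(x2, y2, s) - tg[["additive2"]])
  opt <- stats::optimize(obj, c(0, 10))
  s <- opt$minimum
  if (is.finite(s) && s > 1e-12) {
    a <- s * a
    dd <- dd / s
  }
  c(a, dd, aa)
}

#' Optimize functional effects with a real-valued genetic algorithm (SF_GA)
#'
#' Searches for functional effects (a, dd, aa) whose implied statistical
#' variances in the base population match the targets, maximizing the
#' negative-absolute-deviation fitness.  The candidate population evolves by
#' tournament selection, blend crossover, Gaussian mutation and elitism; a
#' variance-rescaling repair operator (local search) can be applied to
#' offspring.  Initial candidates are drawn from the same priors as SS_NOIA.
#'
#' @param pop base \code{population} (single-population setting).
#' @param targets a \code{variance_targets} (type "ipg").
#' @param mode variance calculation mode.
#' @param control a \code{\link{ga_control}} list.
#' @param covariate anchor covariate form.
#' @param dd_mean,dd_var dominance-degree prior parameters.
#' @param seed optional integer seed.
#' @return An object of class \code{sf_ga_fit}: the best
#'   \code{functional_effects} (element \code{effects}), achieved fitness and
#'   variances, convergence flag and per-generation best-fitness trajectory.
#' @export
sf_ga_ipg <- function(pop, targets, mode = c("by_locus", "by_individual"),
                      control = ga_control(), covariate = "genofreq",
                      dd_mean = 0.19, dd_var = 0.097, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mode <- match.arg(mode)
  if (targets$type != "ipg") stop("iPG targets required; use sf_ga_ppg()")
  pre <- .ipg_precomp(pop, covariate)
  gm <- pop$genome
  nq <- length(gm$qtl)
  np <- if (is.null(gm$pairs)) 0L else nrow(gm$pairs)
  tg <- targets$components
  prior_sd <- c(rep(sqrt(tg[["additive"]]), nq),
                rep(sqrt(dd_var), nq),
                rep(sqrt(max(tg[["epistasis"]], 1e-12)), np))
  init <- function() c(stats::rnorm(nq, 0, sqrt(tg[["additive"]])),
                       stats::rnorm(nq, dd_mean, sqrt(dd_var)),
                       stats::rnorm(np, 0, sqrt(tg[["epistasis"]])))
  fit_fun <- function(g) {
    v <- .ipg_candidate_var(g[seq_len(nq)], g[nq + seq_len(nq)],
                            if (np) g[2L * nq + seq_len(np)] else numeric(0),
                            pre, mode)
    -sum(abs(v - tg))
  }
  repair <- function(g) .repair_ipg(g, pre, targets, mode, nq, np)
  res <- .run_ga(init, fit_fun, repair, prior_sd, control, sum(tg))
  best <- res$best
  a <- best[seq_len(nq)]; dd <- best[nq + seq_len(nq)]
  aa <- if (np) best[2L * nq + seq_len(np)] else numeric(0)
  fx <- functional_effects(a = a, d = dd * abs(a), aa = aa, genome = gm,
                           dd = dd)
  structure(list(effects = fx, fitness = res$fitness,
                 variances = .ipg_candidate_var(a, dd, aa, pre, mode),
                 targets = targets, mode = mode,
                 converged = res$converged, trajectory = res$trajectory),
            class = "sf_ga_fit")
}

#' @rdname sf_ga_ipg
#' @param scheme a three-way scheme (plot setting); fitness is evaluated by
#'   individual over its base plot set.
#' @export
sf_ga_ppg <- function(scheme, targets, control = ga_control(),
                      dd_mean = 0.19, dd_var = 0.097, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (targets$type != "ppg") stop("pPG targets required")
  pre <- .ppg_precomp(scheme)
  gm <- scheme$lines1$genome
  nq <- length(gm$qtl)
  np <- if (is.null(gm$pairs)) 0L else nrow(gm$pairs)
  tg <- targets$components
  a_sd <- sqrt(tg[["additive1"]] + tg[["additive2"]])
  prior_sd <- c(rep(a_sd, nq), rep(sqrt(dd_var), nq),
                rep(sqrt(max(tg[["epistasis3"]], 1e-12)), np))
  init <- function() c(stats::rnorm(nq, 0, a_sd),
                       stats::rnorm(nq, dd_mean, sqrt(dd_var)),
                       stats::rnorm(np, 0, sqrt(tg[["epistasis3"]])))
  fit_fun <- function(g) {
    v <- .ppg_candidate_var(g[seq_len(nq)], g[nq + seq_len(nq)],
                            if (np) g[2L * nq + seq_len(np)] else numeric(0),
                            pre)
    -sum(abs(v - tg))
  }
  repair <- function(g) .repair_ppg(g, pre, targets, nq, np)
  res <- .run_ga(init, fit_fun, repair, prior_sd, control, sum(tg))
  best <- res$best
  a <- best[seq_len(nq)]; dd <- best[nq + seq_len(nq)]
  aa <- if (np) best[2L * nq + seq_len(np)] else numeric(0)
  fx <- functional_effects(a = a, d = dd * abs(a), aa = aa, genome = gm,
                           dd = dd)
  structure(list(effects = fx, fitness = res$fitness,
                 variances = .ppg_candidate_var(a, dd, aa, pre),
                 targets = targets, mode = "by_individual",
                 converged = res$converged, trajectory = res$trajectory),
            class = "sf_ga_fit")
}

#' @export
print.sf_ga_fit <- function(x, ...) {
  cat("SF_GA fit (", x$mode, "): fitness ", format(x$fitness, digits = 4),
      if (x$converged) " (converged)" else " (budget exhausted)", "\n",
      sep = "")
  cat("  achieved: ", paste(names(x$variances),
                            round(x$variances, 2), sep = "=",
                            collapse = ", "), "\n")
  invisible(x)
}

# generic real-valued GA engine
.run_ga <- function(init, fit_fun, repair, prior_sd, control, target_sum) {
  tol <- control$tolerance
  if (is.null(tol)) tol <- 0.001 * target_sum
  P <- vapply(seq_len(control$pop_size), function(i) init(),
              FUN.VALUE = init())
  P <- t(P)                      # candidates in rows
  if (control$local_search) P <- t(apply(P, 1L, repair))
  fit <- apply(P, 1L, fit_fun)
  n_elite <- max(1L, round(control$elitism_frac * control$pop_size))
  traj <- numeric(0)
  ngene <- ncol(P)
  mut_sd <- control$mutation_sd_frac * prior_sd
  gen <- 0L
  repeat {
    best_i <- which.max(fit)
    traj <- c(traj, fit[best_i])
    if (fit[best_i] >= -tol || gen >= control$max_generations) break
    gen <- gen + 1L
    ord <- order(fit, decreasing = TRUE)
    elites <- P[ord[seq_len(n_elite)], , drop = FALSE]
    n_off <- control$pop_size - n_elite
    tournament <- function() {
      cand <- sample.int(control$pop_size, control$tournament_k)
      cand[which.max(fit[cand])]
    }
    OFF <- matrix(0, n_off, ngene)
    for (i in seq_len(n_off)) {
      p1 <- P[tournament(), ]; p2 <- P[tournament(), ]
      child <- if (stats::runif(1) < control$p_crossover) {
        lo <- pmin(p1, p2); hi <- pmax(p1, p2)
        rg <- hi - lo
        stats::runif(ngene, lo - control$blend_alpha * rg,
                     hi + control$blend_alpha * rg)
      } else p1
      mut <- stats::runif(ngene) < control$p_mutation
      if (any(mut))
        child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, mut_sd[mut])
      if (control$local_search &&
          stats::runif(1) < control$local_search_prob)
        child <- repair(child)
      OFF[i, ] <- child
    }
    P <- rbind(elites, OFF)
    fit <- c(fit[ord[seq_len(n_elite)]], apply(OFF, 1L, fit_fun))
  }
  best_i <- which.max(fit)
  list(best = P[best_i, ], fitness = fit[best_i],
       converged = fit[best_i] >= -tol, trajectory = traj)
}
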