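#' Variance components container
#' @keywords internal
new_variance_components <- function(components, mode, basis,
                                    residual = NA_real_) {
  structure(list(components = components, residual = residual,
                 mode = mode, basis = basis),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, digits = 3, ...) {
  cat("Variance components (", x$basis, ", ", x$mode, "):\n", sep = "")
  v <- c(x$components, residual = x$residual)
  print(round(v[!is.na(v)], digits))
  invisible(x)
}

#' @export
as.data.frame.variance_components <- function(x, ...) {
  data.frame(component = c(names(x$components), "residual"),
             value = unname(c(x$components, x$residual)),
             basis = x$basis, mode = x$mode, row.names = NULL)
}

# covariate matrices (individuals x QTL / x pairs) for a population
.ipg_covariates <- function(pop, effects, basis, anchor = NULL) {
  d <- dosage(pop)[, effects$qtl, drop = FALSE]
  if (basis == "functional") {
    tc <- t_covariates(d)
    A <- tc$t_a; D <- tc$t_d
  } else {
    if (is.null(anchor)) stop("statistical basis requires anchoring frequencies")
    if (anchor$covariate == "freq") {
      hc <- h_covariates_freq(d, anchor$q[effects$qtl])
    } else {
      hc <- h_covariates_genofreq(d, anchor$geno[effects$qtl, , drop = FALSE])
    }
    A <- hc$h_a; D <- hc$h_d
  }
  EP <- NULL
  if (!is.null(effects$pairs_q) && nrow(effects$pairs_q) > 0L) {
    EP <- A[, effects$pairs_q[, 1L], drop = FALSE] *
      A[, effects$pairs_q[, 2L], drop = FALSE]
  }
  list(A = A, D = D, EP = EP)
}

#' Per-individual genetic values
#'
#' Sums covariate-weighted effects over loci and pairs: additive value u,
#' dominance value v and epistatic value uu for every individual, in the
#' functional basis (t covariates with a, d, aa) or the statistical basis
#' (h covariates with alpha, delta, alpha-alpha at the effects' anchor).
#'
#' @param pop a \code{population}.
#' @param effects a \code{functional_effects} (basis "functional") or
#'   \code{statistical_effects_ipg} (basis "statistical") object.
#' @param basis which model the values belong to; defaults to the effect
#'   object's natural basis.
#' @return data.frame with columns \code{u}, \code{v}, \code{uu}.
#' @export
genetic_values <- function(pop, effects,
                           basis = c("auto", "functional", "statistical")) {
  basis <- match.arg(basis)
  if (basis == "auto")
    basis <- if (inherits(effects, "functional_effects")) "functional"
             else "statistical"
  if (basis == "functional") {
    cv <- .ipg_covariates(pop, effects, "functional")
    eff <- list(a = effects$a, d = effects$d, aa = effects$aa)
  } else {
    if (!inherits(effects, "statistical_effects_ipg"))
      stop("statistical basis requires statistical_effects_ipg")
    cv <- .ipg_covariates(pop, effects, "statistical", effects$anchor)
    eff <- list(a = effects$alpha, d = effects$delta, aa = effects$aa)
  }
  u <- drop(cv$A %*% eff$a)
  v <- drop(cv$D %*% eff$d)
  uu <- if (is.null(cv$EP)) rep(0, n_ind(pop)) else drop(cv$EP %*% eff$aa)
  data.frame(u = u, v = v, uu = uu)
}

# population variance, divisor n
.pvar <- function(x) mean((x - mean(x))^2)

#' Genetic variance by individual
#'
#' Population variance (divisor n) of the per-individual genetic values; the
#' by-individual calculation automatically absorbs between-locus covariances.
#'
#' @param values data.frame from \code{\link{genetic_values}} (columns u, v,
#'   uu), or a population plus effects via \code{...} passed on.
#' @param basis label recorded in the result.
#' @return A \code{variance_components} object (mode "by_individual").
#' @export
variance_by_individual <- function(values, basis = "statistical") {
  if (nrow(values) < 2L) stop("need at least 2 individuals")
  new_variance_components(
    c(additive = .pvar(values$u), dominance = .pvar(values$v),
      epistasis = .pvar(values$uu)),
    mode = "by_individual", basis = basis)
}

# per-locus covariate variances at an anchor (statistical coding):
# E[h_a] = E[h_d] = 0 under the anchoring genotype distribution, so the
# variances are plain second moments
.locus_covariate_var <- function(anchor, loci) {
  if (anchor$covariate == "freq") {
    q <- anchor$q[loci]; p <- 1 - q
    list(va = 2 * p * q, vd = 4 * p^2 * q^2)
  } else {
    g <- anchor$geno[loci, , drop = FALSE]
    mean_dos <- g[, 2L] + 2 * g[, 3L]
    va <- g[, 2L] + 4 * g[, 3L] - mean_dos^2
    cls <- .hd_geno_classes(g)
    vd <- rowSums(g * cls^2)
    list(va = va, vd = vd)
  }
}

#' Genetic variance by locus
#'
#' Sum of per-locus variances, assuming linkage equilibrium (no between-locus
#' covariance).  In the statistical basis the additive term is
#' alpha_j^2 Var(h_a) (2 p q alpha^2 under HWE), the dominance term
#' delta_j^2 Var(h_d) (4 p^2 q^2 delta^2 under HWE) and each pair contributes
#' (alpha-alpha)^2 Var(h_a,k) Var(h_a,l).  Outside HWE the genotype-frequency
#' covariate moments are used.  In the functional basis the t-covariate
#' moments at the anchor play the same role.
#'
#' @param effects a \code{statistical_effects_ipg} or (with \code{anchor})
#'   a \code{functional_effects} object.
#' @param anchor anchor for functional effects; ignored for statistical
#'   effects (their own anchor is used).
#' @return A \code{variance_components} object (mode "by_locus").
#' @export
variance_by_locus <- function(effects, anchor = NULL) {
  if (inherits(effects, "statistical_effects_ipg")) {
    anchor <- effects$anchor
    cv <- .locus_covariate_var(anchor, effects$qtl)
    add <- sum(cv$va * effects$alpha^2)
    dom <- sum(cv$vd * effects$delta^2)
    epi <- if (length(effects$aa))
      sum(effects$aa^2 * cv$va[effects$pairs_q[, 1L]] *
            cv$va[effects$pairs_q[, 2L]]) else 0
    basis <- "statistical"
  } else {
    if (is.null(anchor)) stop("functional by-locus variance needs an anchor")
    # t-covariate moments under the anchoring genotype distribution
    g <- if (anchor$covariate == "freq") {
      p <- 1 - anchor$q
      cbind(p^2, 2 * p * anchor$q, anchor$q^2)[effects$qtl, , drop = FALSE]
    } else anchor$geno[effects$qtl, , drop = FALSE]
    m_ta <- g[, 3L] - g[, 1L]
    v_ta <- (g[, 1L] + g[, 3L]) - m_ta^2
    v_td <- g[, 2L] - g[, 2L]^2
    add <- sum(v_ta * effects$a^2)
    dom <- sum(v_td * effects$d^2)
    epi <- 0
    if (length(effects$aa)) {
      k <- effects$pairs_q[, 1L]; l <- effects$pairs_q[, 2L]
      e2 <- (v_ta + m_ta^2)   # E[t_a^2]
      v_ep <- e2[k] * e2[l] - (m_ta[k] * m_ta[l])^2
      epi <- sum(v_ep * effects$aa^2)
    }
    basis <- "functional"
  }
  new_variance_components(c(additive = add, dominance = dom, epistasis = epi),
                          mode = "by_locus", basis = basis)
}

# --- three-way hybrid plot variances ----------------------------------------

# covariate matrices (plots x QTL / pairs) for a plot set
# scheme: list with lines1, lines2 (populations) and plots (data.frame with
# i1, i2a, i2b row indices); anchor frequencies from the two base populations
.ppg_covariates <- function(scheme, plots, qtl, pairs_q, basis,
                            q1 = NULL, q2 = NULL) {
  t1 <- dosage(scheme$lines1)[plots$i1, qtl, drop = FALSE] - 1
  d2a <- dosage(scheme$lines2)[plots$i2a, qtl, drop = FALSE] - 1
  d2b <- dosage(scheme$lines2)[plots$i2b, qtl, drop = FALSE] - 1
  t2 <- 0.5 * (d2a + d2b)
  if (basis == "functional") {
    A1 <- 0.5 * (t1 + t2)            # combined additive covariate
    A2 <- NULL
    A2a <- A2b <- NULL
    D <- t_d3(t1, t2)
    Acomb <- A1
  } else {
    if (is.null(q1) || is.null(q2))
      stop("statistical basis requires base-population allele frequencies")
    h1 <- sweep(t1, 2L, 2 * q1[qtl])
    h2 <- sweep(t2, 2L, 2 * q2[qtl])
    A1 <- 0.5 * h1
    A2 <- 0.5 * h2
    # per-grandparent-slot covariates: each plot receives two population-2
    # line contributions (summed incidence in the plot model), so the
    # model-scale additive-2 variance is the per-slot (line-level) variance
    A2a <- 0.25 * sweep(d2a, 2L, 2 * q2[qtl])
    A2b <- 0.25 * sweep(d2b, 2L, 2 * q2[qtl])
    D <- h_d3(t1, t2,
              matrix(q1[qtl], nrow(t1), ncol(t1), byrow = TRUE),
              matrix(q2[qtl], nrow(t1), ncol(t1), byrow = TRUE))
    Acomb <- A1 + A2
  }
  EP <- NULL
  if (!is.null(pairs_q) && nrow(pairs_q) > 0L) {
    EP <- Acomb[, pairs_q[, 1L], drop = FALSE] *
      Acomb[, pairs_q[, 2L], drop = FALSE]
  }
  list(A1 = A1, A2 = A2, A2a = A2a, A2b = A2b, D = D, EP = EP)
}

#' Per-plot genetic values for three-way hybrids
#'
#' Functional basis: combined additive value from (t1 + t2)/2 with a, plot
#' dominance from t_d3 with d, epistasis from the product covariate with aa.
#' Statistical basis: separate population-1 and population-2 additive values
#' (u1, u2) from the halved h covariates with alpha1/alpha2, dominance from
#' h_d3 with delta3 and epistasis from the product of combined h covariates.
#'
#' @param scheme a three-way scheme (see \code{\link{run_threeway_scheme}}).
#' @param plots data.frame of plot records (columns i1, i2a, i2b); defaults
#'   to all plots in the scheme.
#' @param effects \code{functional_effects} or \code{statistical_effects_ppg}.
#' @return data.frame with columns \code{u1}, \code{u2}, \code{v}, \code{uu}
#'   (functional basis puts the combined additive value in \code{u1} and 0 in
#'   \code{u2}).
#' @export
genetic_values_ppg <- function(scheme, effects, plots = NULL) {
  if (is.null(plots)) plots <- scheme$plots
  if (inherits(effects, "functional_effects")) {
    cv <- .ppg_covariates(scheme, plots, effects$qtl, effects$pairs_q,
                          "functional")
    u1 <- drop(cv$A1 %*% effects$a)
    u2 <- rep(0, nrow(plots))
    v <- drop(cv$D %*% effects$d)
    uu <- if (is.null(cv$EP)) rep(0, nrow(plots)) else drop(cv$EP %*% effects$aa)
  } else {
    an <- effects$anchor
    cv <- .ppg_covariates(scheme, plots, effects$qtl, effects$pairs_q,
                          "statistical", q1 = an$q1, q2 = an$q2)
    u1 <- drop(cv$A1 %*% effects$alpha1)
    u2 <- drop(cv$A2 %*% effects$alpha2)
    v <- drop(cv$D %*% effects$delta3)
    uu <- if (is.null(cv$EP)) rep(0, nrow(plots)) else drop(cv$EP %*% effects$aa3)
  }
  data.frame(u1 = u1, u2 = u2, v = v, uu = uu)
}

#' Plot-phenotype variance components
#'
#' By individual: population variances of the per-plot genetic values.  By
#' locus: per-locus covariate variances are taken over the supplied plot set
#' (columnwise, divisor n) and multiplied by squared effects, ignoring
#' between-locus covariance.
#'
#' The additive-2 component is reported on the scale of the plot prediction
#' model, in which each plot receives the breeding values of both
#' population-2 grandparental lines through a summed incidence matrix: the
#' reported variance is the per-line-slot variance (half the plot-level
#' population-2 additive variance).  This is what makes the additive-1 to
#' additive-2 ratio about four for equal substitution effects and equal
#' frequencies (per-slot regression coefficients 1 vs 1/2, squared), the
#' relationship-coefficient factor of the three-way design.
#'
#' @param scheme a three-way scheme.
#' @param effects \code{statistical_effects_ppg} or \code{functional_effects}.
#' @param plots plot records; defaults to all plots in the scheme.
#' @param mode \code{"by_individual"} or \code{"by_locus"}.
#' @return A \code{variance_components} object with components
#'   \code{additive1}, \code{additive2}, \code{dominance3}, \code{epistasis3}
#'   (functional basis: combined additive in \code{additive1}).
#' @export
variance_ppg <- function(scheme, effects, plots = NULL,
                         mode = c("by_individual", "by_locus")) {
  mode <- match.arg(mode)
  if (is.null(plots)) plots <- scheme$plots
  functional <- inherits(effects, "functional_effects")
  if (mode == "by_individual") {
    gv <- genetic_values_ppg(scheme, effects, plots)
    add2 <- if (functional) .pvar(gv$u2) else {
      an <- effects$anchor
      cv <- .ppg_covariates(scheme, plots, effects$qtl, effects$pairs_q,
                            "statistical", q1 = an$q1, q2 = an$q2)
      .pvar(c(drop(cv$A2a %*% effects$alpha2),
              drop(cv$A2b %*% effects$alpha2)))
    }
    comps <- c(additive1 = .pvar(gv$u1), additive2 = add2,
               dominance3 = .pvar(gv$v), epistasis3 = .pvar(gv$uu))
  } else {
    if (functional) {
      cv <- .ppg_covariates(scheme, plots, effects$qtl, effects$pairs_q,
                            "functional")
      eff <- list(a1 = effects$a, a2 = NULL, d = effects$d, aa = effects$aa)
    } else {
      an <- effects$anchor
      cv <- .ppg_covariates(scheme, plots, effects$qtl, effects$pairs_q,
                            "statistical", q1 = an$q1, q2 = an$q2)
      eff <- list(a1 = effects$alpha1, a2 = effects$alpha2,
                  d = effects$delta3, aa = effects$aa3)
    }
    colvar <- function(M) colMeans(M^2) - colMeans(M)^2
    slotvar <- function(Ma, Mb) {       # per-slot covariate variance
      m2 <- (colMeans(Ma^2) + colMeans(Mb^2)) / 2
      m1 <- (colMeans(Ma) + colMeans(Mb)) / 2
      m2 - m1^2
    }
    comps <- c(
      additive1 = sum(colvar(cv$A1) * eff$a1^2),
      additive2 = if (is.null(cv$A2a)) 0
                  else sum(slotvar(cv$A2a, cv$A2b) * eff$a2^2),
      dominance3 = sum(colvar(cv$D) * eff$d^2),
      epistasis3 = if (is.null(cv$EP)) 0 else sum(colvar(cv$EP) * eff$aa^2))
  }
  new_variance_components(comps, mode = mode,
                          basis = if (functional) "functional" else "statistical")
}
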