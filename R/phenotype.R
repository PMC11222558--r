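#' Simulate individual phenotypes from functional effects
#'
#' y_i = mu + sum t_a a + sum t_d d + sum t_ep aa + e with e ~ N(0, sigma2_e).
#' The functional genetic components are stored alongside the phenotype so
#' downstream estimation bias can be measured against the simulated truth;
#' they sum to y - mu - e exactly.
#'
#' @param pop a \code{population}.
#' @param effects a \code{functional_effects} object.
#' @param sigma2_e residual variance (>= 0).
#' @param mu population mean.
#' @param seed optional integer seed.
#' @return data.frame (class \code{phenotype_table}): id, generation, y, e,
#'   u, v, uu.
#' @export
simulate_phenotypes_ipg <- function(pop, effects, sigma2_e, mu = 0,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (sigma2_e < 0) stop("sigma2_e must be >= 0")
  gv <- genetic_values(pop, effects, basis = "functional")
  e <- stats::rnorm(n_ind(pop), 0, sqrt(sigma2_e))
  out <- data.frame(id = pop$id, generation = pop$generation,
                    y = mu + gv$u + gv$v + gv$uu + e, e = e,
                    u = gv$u, v = gv$v, uu = gv$uu)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Simulate three-way hybrid plot phenotypes
#'
#' y_i3 = mu + sum (t1+t2)/2 a + sum t_d3 d + sum t_ep3 aa + e.  The two-way
#' parent code is t2 = (t_i2a + t_i2b)/2 and the plot is treated as an
#' infinite set of plants, so no within-plot genotype sampling noise enters
#' beyond the residual e.
#'
#' @param scheme a three-way scheme (see \code{\link{run_threeway_scheme}}).
#' @param effects a \code{functional_effects} object.
#' @param sigma2_e residual plot variance.
#' @param mu population mean.
#' @param plots plot records; defaults to the scheme's descendant plots.
#' @param seed optional integer seed.
#' @return data.frame (class \code{phenotype_table}): plot, generation, i1,
#'   i2a, i2b, y, e, u, v, uu (u holds the combined additive value).
#' @export
simulate_phenotypes_ppg <- function(scheme, effects, sigma2_e, mu = 0,
                                    plots = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (sigma2_e < 0) stop("sigma2_e must be >= 0")
  if (is.null(plots)) plots <- scheme$plots
  if (any(plots$i1 > n_ind(scheme$lines1)) ||
      any(c(plots$i2a, plots$i2b) > n_ind(scheme$lines2)))
    stop("plot pedigree references ungenotyped parents")
  gv <- genetic_values_ppg(scheme, effects, plots)
  e <- stats::rnorm(nrow(plots), 0, sqrt(sigma2_e))
  out <- data.frame(plot = seq_len(nrow(plots)),
                    generation = plots$generation,
                    i1 = plots$i1, i2a = plots$i2a, i2b = plots$i2b,
                    y = mu + gv$u1 + gv$v + gv$uu + e, e = e,
                    u = gv$u1, v = gv$v, uu = gv$uu)
  class(out) <- c("phenotype_table", "data.frame")
  out
}
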