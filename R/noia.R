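#' Functional genotype covariates
#'
#' Codes a b-allele dosage as the functional (genotypic) covariates of the
#' NOIA framework: \code{t_a} = -1/0/1 and \code{t_d} = 0/1/0 for genotypes
#' BB/Bb/bb.
#'
#' @param dos dosage (0, 1 or 2); vector or matrix.
#' @return list with \code{t_a} and \code{t_d}, same shape as \code{dos}.
#' @export
t_covariates <- function(dos) {
  if (any(!dos %in% 0:2)) stop("dosage must be 0, 1 or 2")
  list(t_a = dos - 1, t_d = (dos == 1L) + 0)
}

#' Statistical covariates from allele frequencies (HWE form)
#'
#' Additive covariate \code{h_a} = dosage - 2q; dominance covariate
#' \code{h_d} = -2q^2 / 2pq / -2p^2 for BB/Bb/bb.  The dominance form is
#' orthogonal to the additive one only under Hardy-Weinberg proportions; use
#' \code{\link{h_covariates_genofreq}} otherwise.
#'
#' @param dos dosage vector or matrix (individuals by loci).
#' @param q b-allele frequency; scalar or per-locus vector.
#' @return list with \code{h_a} and \code{h_d}.
#' @export
h_covariates_freq <- function(dos, q) {
  p <- 1 - q
  if (is.matrix(dos)) {
    h_a <- sweep(dos, 2L, 2 * q)
    hd_bb <- -2 * q^2; hd_het <- 2 * p * q; hd_BB <- -2 * p^2
    h_d <- matrix(0, nrow(dos), ncol(dos))
    for (jcase in 0:2) {
      v <- switch(jcase + 1L, hd_bb, hd_het, hd_BB)
      h_d <- h_d + sweep((dos == jcase) + 0, 2L, v, `*`)
    }
    list(h_a = h_a, h_d = h_d)
  } else {
    h_a <- dos - 2 * q
    h_d <- ifelse(dos == 0, -2 * q^2, ifelse(dos == 1, 2 * p * q, -2 * p^2))
    list(h_a = h_a, h_d = h_d)
  }
}

# dominance-covariate class values under observed genotype frequencies;
# rows: value for BB, Bb, bb carriers; degenerate loci (zero denominator,
# e.g. fixed or a pure BB/bb mixture) get h_d = 0 and are flagged
.hd_geno_classes <- function(geno) {
  pBB <- geno[, 1L]; pBb <- geno[, 2L]; pbb <- geno[, 3L]
  den <- pBB + pbb - (pBB - pbb)^2
  bad <- den <= .Machine$double.eps
  den[bad] <- 1
  cls <- cbind(BB = -2 * pBb * pbb / den,
               Bb = 4 * pBB * pbb / den,
               bb = -2 * pBB * pBb / den)
  cls[bad, ] <- 0
  attr(cls, "degenerate") <- bad
  cls
}

#' Statistical covariates from genotype frequencies (general form)
#'
#' The general NOIA covariates, valid in and out of Hardy-Weinberg
#' equilibrium: \code{h_a} = dosage - p_Bb - 2 p_bb and the three-case
#' dominance covariate with denominator p_BB + p_bb - (p_BB - p_bb)^2.
#' Degenerate loci (zero denominator) get \code{h_d} = 0 and are reported in
#' the \code{"degenerate"} attribute.
#'
#' @param dos dosage vector or matrix (individuals by loci).
#' @param geno genotype frequencies: a 3-vector (BB, Bb, bb) for a single
#'   locus or a loci-by-3 matrix.
#' @return list with \code{h_a} and \code{h_d}.
#' @export
h_covariates_genofreq <- function(dos, geno) {
  if (!is.matrix(geno)) geno <- matrix(geno, 1L, 3L)
  if (any(geno < -1e-9) || any(abs(rowSums(geno) - 1) > 1e-8))
    stop("genotype frequencies must be >= 0 and sum to 1")
  mean_dos <- geno[, 2L] + 2 * geno[, 3L]
  cls <- .hd_geno_classes(geno)
  if (is.matrix(dos)) {
    h_a <- sweep(dos, 2L, mean_dos)
    h_d <- matrix(0, nrow(dos), ncol(dos))
    for (jcase in 0:2)
      h_d <- h_d + sweep((dos == jcase) + 0, 2L, cls[, jcase + 1L], `*`)
  } else {
    # one locus for all dosages, or one locus per dosage
    row_idx <- if (nrow(geno) == 1L) rep(1L, length(dos))
               else seq_along(dos)
    if (nrow(geno) != 1L && nrow(geno) != length(dos))
      stop("geno must have 1 row or one row per dosage value")
    h_a <- dos - mean_dos[row_idx]
    h_d <- cls[cbind(row_idx, dos + 1L)]
  }
  out <- list(h_a = h_a, h_d = h_d)
  attr(out, "degenerate") <- attr(cls, "degenerate")
  out
}

#' Epistatic covariate of a locus pair
#'
#' The additive-by-additive covariate is the product of the two loci's
#' additive covariates, for functional (\code{t}) and statistical (\code{h})
#' codings alike.
#'
#' @param cov_k,cov_l additive covariates at loci k and l (same shape).
#' @return elementwise product.
#' @export
epistasis_covariates <- function(cov_k, cov_l) cov_k * cov_l

# --- frequency anchors ------------------------------------------------------

#' Frequency anchor of a population subset
#'
#' Statistical effects and covariates are defined relative to reference
#' frequencies.  An anchor records the allele frequencies, the observed
#' genotype frequencies and which covariate form (\code{"genofreq"}, the
#' general form, or \code{"freq"}, the HWE form) to use.
#'
#' @param pop a \code{population}.
#' @param subset optional individual subset.
#' @param covariate \code{"genofreq"} or \code{"freq"}.
#' @return An object of class \code{noia_anchor}.
#' @export
freq_anchor <- function(pop, subset = NULL,
                        covariate = c("genofreq", "freq")) {
  covariate <- match.arg(covariate)
  af <- allele_frequencies(pop, subset)
  anchor_from_freq(af$q, af$geno, covariate)
}

#' Build an anchor directly from frequencies
#' @param q per-locus b-allele frequencies.
#' @param geno loci-by-3 genotype frequency matrix; defaults to HWE
#'   proportions computed from \code{q}.
#' @param covariate covariate form, see \code{\link{freq_anchor}}.
#' @export
anchor_from_freq <- function(q, geno = NULL,
                             covariate = c("genofreq", "freq")) {
  covariate <- match.arg(covariate)
  if (is.null(geno)) {
    p <- 1 - q
    geno <- cbind(BB = p^2, Bb = 2 * p * q, bb = q^2)
  }
  structure(list(q = q, geno = geno, covariate = covariate),
            class = "noia_anchor")
}

# per-locus closed-form transform coefficients at an anchor:
#   m = E[t_a]               (mean additive functional covariate)
#   B = coefficient of t_a when h_d is written as A + B t_a + t_d
# under HWE both reduce to 2q - 1.
.anchor_coef <- function(anchor, loci = NULL) {
  if (anchor$covariate == "freq") {
    q <- anchor$q
    m <- 2 * q - 1
    B <- 2 * q - 1
  } else {
    g <- anchor$geno
    m <- g[, 2L] + 2 * g[, 3L] - 1
    den <- g[, 1L] + g[, 3L] - (g[, 1L] - g[, 3L])^2
    bad <- den <= .Machine$double.eps
    den[bad] <- 1
    B <- g[, 2L] * (g[, 3L] - g[, 1L]) / den
    B[bad] <- 0
  }
  if (!is.null(loci)) {
    m <- m[loci]; B <- B[loci]
  }
  list(m = m, B = B)
}

# 3-class covariate vectors for one locus at an anchor
.locus_class_covariates <- function(anchor, locus) {
  dos <- 0:2
  t_ <- t_covariates(dos)
  if (anchor$covariate == "freq") {
    h <- h_covariates_freq(dos, anchor$q[locus])
  } else {
    h <- h_covariates_genofreq(dos, anchor$geno[locus, , drop = FALSE])
  }
  list(t_a = t_$t_a, t_d = t_$t_d, h_a = h$h_a, h_d = h$h_d)
}

# --- effect containers ------------------------------------------------------

#' Functional QTL effects
#'
#' Per-QTL additive (\code{a}) and dominance (\code{d}) functional effects and
#' per-pair additive-by-additive effects (\code{aa}).  Functional effects are
#' frequency-free: they simulate the phenotype of any genotype without
#' reference frequencies, which is what makes them inheritable through a
#' breeding scheme.
#'
#' @param a,d numeric vectors, one value per QTL of \code{genome}.
#' @param aa numeric vector, one value per epistatic pair (NULL if none).
#' @param genome the \code{genome_map} the effects refer to.
#' @param dd optional dominance degrees (d = dd * |a|), kept for provenance.
#' @return An object of class \code{functional_effects}.
#' @export
functional_effects <- function(a, d, aa, genome, dd = NULL) {
  nq <- length(genome$qtl)
  np <- if (is.null(genome$pairs)) 0L else nrow(genome$pairs)
  stopifnot(length(a) == nq, length(d) == nq)
  if (np == 0L) aa <- numeric(0) else stopifnot(length(aa) == np)
  if (any(!is.finite(c(a, d, aa)))) stop("effects must be finite")
  structure(list(a = a, d = d, aa = aa, dd = dd, qtl = genome$qtl,
                 pairs = genome$pairs,
                 pairs_q = if (np) matrix(match(genome$pairs, genome$qtl),
                                          ncol = 2L)),
            class = "functional_effects")
}

#' @export
print.functional_effects <- function(x, ...) {
  cat("Functional effects:", length(x$a), "QTL,", length(x$aa),
      "epistatic pair(s)\n")
  cat(sprintf("  sd(a) = %.3f, sd(d) = %.3f, sd(aa) = %.3f\n",
              stats::sd(x$a), stats::sd(x$d),
              if (length(x$aa) > 1) stats::sd(x$aa) else NA))
  invisible(x)
}

new_statistical_effects <- function(alpha, delta, aa, fx_like, anchor,
                                    class2 = "statistical_effects_ipg") {
  structure(list(alpha = alpha, delta = delta, aa = aa,
                 qtl = fx_like$qtl, pairs = fx_like$pairs,
                 pairs_q = fx_like$pairs_q, anchor = anchor),
            class = c(class2, "statistical_effects"))
}

#' @export
print.statistical_effects <- function(x, ...) {
  cat("Statistical effects (", class(x)[1L], "): ", length(x$alpha %||% x$alpha1),
      " QTL\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# partner locus index (within the QTL vector) and pair id for each QTL;
# NA when unpaired
.partner_map <- function(fx) {
  nq <- length(fx$qtl)
  partner <- rep(NA_integer_, nq)
  pair_id <- rep(NA_integer_, nq)
  if (!is.null(fx$pairs_q)) {
    pq <- fx$pairs_q
    partner[pq[, 1L]] <- pq[, 2L]
    partner[pq[, 2L]] <- pq[, 1L]
    pair_id[pq[, 1L]] <- seq_len(nrow(pq))
    pair_id[pq[, 2L]] <- seq_len(nrow(pq))
  }
  list(partner = partner, pair_id = pair_id)
}

# --- single-population (iPG) transforms -------------------------------------

#' NOIA design matrices for a locus pair (single population)
#'
#' Builds the 9-by-6 functional (\code{W_f}) and statistical (\code{W_s})
#' design matrices over the joint genotype classes of loci k and l.  Rows are
#' ordered with the locus-k genotype varying fastest (BB, Bb, bb).  Columns:
#' intercept, additive k, additive l, dominance k, dominance l, epistasis.
#'
#' @param anchor a \code{noia_anchor} covering both loci.
#' @param k,l locus indices into the anchor.
#' @return list with \code{W_f} and \code{W_s}.
#' @export
build_W_ipg <- function(anchor, k, l) {
  ck <- .locus_class_covariates(anchor, k)
  cl <- .locus_class_covariates(anchor, l)
  J <- rep(1, 3)
  kf <- function(a, b) kronecker(a, b)   # b varies fastest
  W_f <- cbind(1, kf(J, ck$t_a), kf(cl$t_a, J), kf(J, ck$t_d),
               kf(cl$t_d, J), kf(cl$t_a, J) * kf(J, ck$t_a))
  W_s <- cbind(1, kf(J, ck$h_a), kf(cl$h_a, J), kf(J, ck$h_d),
               kf(cl$h_d, J), kf(cl$h_a, J) * kf(J, ck$h_a))
  list(W_f = W_f, W_s = W_s)
}

.left_solve <- function(W, rhs, what) {
  XtX <- crossprod(W)
  out <- tryCatch(solve(XtX, crossprod(W, rhs)),
                  error = function(e)
                    stop("singular ", what,
                         " cross-product (degenerate frequencies): ",
                         conditionMessage(e)))
  drop(out)
}

#' Functional-to-statistical transform for one locus pair (matrix route)
#'
#' E_s = (W_s' W_s)^{-1} W_s' W_f E_f, the unweighted left-inverse transform;
#' a diagonal class-frequency weight matrix cancels out of this expression
#' because W_f E_f lies in the column space of W_s.
#'
#' @param E_f length-6 functional vector (mu, a_k, a_l, d_k, d_l, aa).
#' @param W list with \code{W_f}, \code{W_s} from \code{\link{build_W_ipg}}.
#' @return length-6 statistical vector (mu, alpha_k, alpha_l, delta_k,
#'   delta_l, alpha-alpha).
#' @export
functional_to_statistical_ipg <- function(E_f, W) {
  .left_solve(W$W_s, W$W_f %*% E_f, "W_s")
}

#' Statistical-to-functional transform for one locus pair (matrix route)
#' @param E_s length-6 statistical vector.
#' @param W list with \code{W_f}, \code{W_s}.
#' @return length-6 functional vector.
#' @export
statistical_to_functional_ipg <- function(E_s, W) {
  .left_solve(W$W_f, W$W_s %*% E_s, "W_f")
}

#' Additive substitution contribution of a pair's epistasis
#'
#' The term the pair's additive-by-additive effect contributes to each locus'
#' substitution effect; at an anchor it equals \code{m_l * aa} for locus k
#' (and \code{m_k * aa} for locus l), where m is the mean functional additive
#' covariate of the partner locus (2q - 1 under HWE).
#'
#' @param aa the pair's additive-by-additive effect.
#' @param anchor a \code{noia_anchor}.
#' @param k,l locus indices.
#' @return named vector with components \code{k} and \code{l}.
#' @export
epistatic_additive_contribution <- function(aa, anchor, k, l) {
  cf <- .anchor_coef(anchor)
  c(k = cf$m[l] * aa, l = cf$m[k] * aa)
}

#' Forward NOIA transform, whole genome (single population)
#'
#' Vectorised closed form of the per-pair matrix transform: delta = d,
#' alpha-alpha = aa, and alpha_j = a_j - B_j d_j + m_partner aa.  Identical to
#' applying \code{\link{functional_to_statistical_ipg}} pair by pair.
#'
#' @param fx a \code{functional_effects} object.
#' @param anchor a \code{noia_anchor} on the same loci.
#' @return A \code{statistical_effects_ipg} object.
#' @export
noia_forward_ipg <- function(fx, anchor) {
  cf <- .anchor_coef(anchor, fx$qtl)
  pm <- .partner_map(fx)
  ep <- ifelse(is.na(pm$partner), 0, cf$m[pm$partner] *
                 ifelse(is.na(pm$pair_id), 0, fx$aa[pm$pair_id]))
  ep[is.na(ep)] <- 0
  alpha <- fx$a - cf$B * fx$d + ep
  new_statistical_effects(alpha, fx$d, fx$aa, fx, anchor)
}

#' Backward NOIA transform, whole genome (single population)
#'
#' Recovers functional effects from statistical effects anchored at
#' \code{sx$anchor} (or a supplied anchor): d = delta, aa = alpha-alpha,
#' a_j = alpha_j + B_j d_j - m_partner aa.
#'
#' @param sx a \code{statistical_effects_ipg} object.
#' @param anchor optional anchor overriding \code{sx$anchor}.
#' @param genome the \code{genome_map} (for the returned object).
#' @return A \code{functional_effects} object.
#' @export
noia_backward_ipg <- function(sx, genome, anchor = NULL) {
  if (is.null(anchor)) anchor <- sx$anchor
  cf <- .anchor_coef(anchor, sx$qtl)
  pm <- .partner_map(sx)
  ep <- ifelse(is.na(pm$partner), 0, cf$m[pm$partner] *
                 ifelse(is.na(pm$pair_id), 0, sx$aa[pm$pair_id]))
  ep[is.na(ep)] <- 0
  a <- sx$alpha + cf$B * sx$delta - ep
  functional_effects(a = a, d = sx$delta, aa = sx$aa, genome = genome)
}

#' Re-anchor statistical effects at new frequencies
#'
#' Statistical effects are tied to reference frequencies; when a descendant
#' population's frequencies are used, the fixed functional effects imply new
#' statistical effects.  This recomputes them via the forward transform.
#'
#' @param fx a \code{functional_effects} object.
#' @param pop a \code{population} (or an anchor via \code{anchor =}).
#' @param subset individual subset defining the frequencies.
#' @param covariate covariate form for the new anchor.
#' @param anchor optional explicit \code{noia_anchor}.
#' @return A \code{statistical_effects_ipg} at the new anchor.
#' @export
reanchor_statistical <- function(fx, pop = NULL, subset = NULL,
                                 covariate = "genofreq", anchor = NULL) {
  if (is.null(anchor)) anchor <- freq_anchor(pop, subset, covariate)
  noia_forward_ipg(fx, anchor)
}

# --- three-way hybrid (pPG) transforms --------------------------------------

#' Plot dominance covariate from parental genotype codes
#'
#' Expected heterozygosity of a plot's plants given the inbred parent's code
#' t1 (-1/0/1) and the two-way parent's code t2 (-1/-0.5/0/0.5/1):
#' (1 - t1 t2)/2, equivalently the quarter-sum form of the four parental
#' allele combinations.
#'
#' @param t1 population-1 parent genotype code(s).
#' @param t2 two-way parent mean genotype code(s).
#' @return numeric, same shape.
#' @export
t_d3 <- function(t1, t2) {
  0.25 * ((1 - t1) * (t2 + 1) + (t1 + 1) * (1 - t2))
}

#' Statistical plot dominance covariate
#'
#' The generalized dominance element for a hybrid plot, anchored at the
#' allele frequencies of the two inbred base populations.
#'
#' @param t1,t2 parental genotype codes as in \code{\link{t_d3}}.
#' @param q1,q2 b-allele frequencies in populations 1 and 2 (p = 1 - q).
#' @return numeric, same shape.
#' @export
h_d3 <- function(t1, t2, q1, q2) {
  p1 <- 1 - q1; p2 <- 1 - q2
  0.5 * (1 - t1) * (t2 + 1) * q1 * p2 +
    0.5 * (t1 + 1) * (1 - t2) * p1 * q2 -
    0.5 * (1 - t1) * (1 - t2) * q1 * q2 -
    0.5 * (t1 + 1) * (t2 + 1) * p1 * p2
}

# 15-class covariate vectors at one locus for the plot setting:
# classes = 3 inbred-parent codes x 5 two-way codes (two-way fastest)
.ppg_locus_classes <- function(q1, q2) {
  t1 <- kronecker(c(-1, 0, 1), rep(1, 5))
  t2 <- kronecker(rep(1, 3), c(-1, -0.5, 0, 0.5, 1))
  list(t1 = t1, t2 = t2,
       h1 = t1 - 2 * q1, h2 = t2 - 2 * q2,
       td3 = t_d3(t1, t2), hd3 = h_d3(t1, t2, q1, q2))
}

#' NOIA design matrices for a locus pair (three-way hybrid plots)
#'
#' Joint-class design matrices over the 15 x 15 = 225 combinations of plot
#' classes at loci k and l (locus-k class varying fastest).  Effect layout:
#' E_f = (1, a_k, a_l, a_k, a_l, d_k, d_l, aa) with the additive functional
#' effect repeated for the two parental origins, and E_s = (mu, alpha_k1,
#' alpha_l1, alpha_k2, alpha_l2, delta_k3, delta_l3, alpha-alpha_3).
#' Additive columns carry the factor 1/2.  Anchoring uses the allele
#' frequencies of the two inbred base populations.
#'
#' @param q_k1,q_l1 b-allele frequencies of loci k, l in population 1.
#' @param q_k2,q_l2 b-allele frequencies in population 2.
#' @return list with \code{W_f} and \code{W_s} (225 x 8).
#' @export
build_W_ppg <- function(q_k1, q_k2, q_l1, q_l2) {
  ck <- .ppg_locus_classes(q_k1, q_k2)
  cl <- .ppg_locus_classes(q_l1, q_l2)
  J <- rep(1, 15)
  kf <- function(a, b) kronecker(a, b)   # b varies fastest
  Tk <- 0.5 * (ck$t1 + ck$t2); Tl <- 0.5 * (cl$t1 + cl$t2)
  Hk <- 0.5 * (ck$h1 + ck$h2); Hl <- 0.5 * (cl$h1 + cl$h2)
  W_f <- cbind(1,
               kf(J, 0.5 * ck$t1), kf(0.5 * cl$t1, J),
               kf(J, 0.5 * ck$t2), kf(0.5 * cl$t2, J),
               kf(J, ck$td3), kf(cl$td3, J),
               kf(Tl, J) * kf(J, Tk))
  W_s <- cbind(1,
               kf(J, 0.5 * ck$h1), kf(0.5 * cl$h1, J),
               kf(J, 0.5 * ck$h2), kf(0.5 * cl$h2, J),
               kf(J, ck$hd3), kf(cl$hd3, J),
               kf(Hl, J) * kf(J, Hk))
  list(W_f = W_f, W_s = W_s)
}

#' Functional-to-statistical transform for one pair (plot setting)
#' @param E_f length-8 functional vector (see \code{\link{build_W_ppg}}).
#' @param W list with \code{W_f}, \code{W_s}.
#' @return length-8 statistical vector.
#' @export
functional_to_statistical_ppg <- function(E_f, W) {
  .left_solve(W$W_s, W$W_f %*% E_f, "W_s")
}

#' Forward NOIA transform, whole genome (three-way hybrid plots)
#'
#' Vectorised closed form: delta3 = d, alpha-alpha3 = aa,
#' alpha_{j,1} = a_j + (1 - 2 q_{j,2}) d_j + (q_{partner,1} + q_{partner,2}) aa
#' and symmetrically for alpha_{j,2} (with q_{j,1}).  The dominance term uses
#' the opposite population's frequency because the heterozygosity of the
#' hybrid depends on the mate's allele.  Identical to the per-pair matrix
#' transform.
#'
#' @param fx a \code{functional_effects} object.
#' @param q1,q2 per-locus b-allele frequencies of the two inbred base
#'   populations (full-genome vectors).
#' @return An object of class \code{statistical_effects_ppg}.
#' @export
noia_forward_ppg <- function(fx, q1, q2) {
  qq1 <- q1[fx$qtl]; qq2 <- q2[fx$qtl]
  pm <- .partner_map(fx)
  csum <- qq1 + qq2
  ep <- ifelse(is.na(pm$partner), 0,
               csum[pm$partner] * ifelse(is.na(pm$pair_id), 0,
                                         fx$aa[pm$pair_id]))
  ep[is.na(ep)] <- 0
  alpha1 <- fx$a + (1 - 2 * qq2) * fx$d + ep
  alpha2 <- fx$a + (1 - 2 * qq1) * fx$d + ep
  structure(list(alpha1 = alpha1, alpha2 = alpha2, delta3 = fx$d,
                 aa3 = fx$aa, qtl = fx$qtl, pairs = fx$pairs,
                 pairs_q = fx$pairs_q,
                 anchor = list(q1 = q1, q2 = q2)),
            class = c("statistical_effects_ppg", "statistical_effects"))
}
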