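#' Genomic relationship matrices for individual data
#'
#' G_A = H_a H_a' / (tr(H_a H_a')/n) with H_a the additive statistical
#' covariates (dosage - 2q); G_D likewise from the general genotype-frequency
#' dominance covariates; G_AA is the Hadamard product G_A * G_A with its own
#' trace normalization.  Anchor frequencies default to the observed
#' frequencies of the analyzed individuals (standard GBLUP practice); a
#' different anchor can be supplied for truth tracking.
#'
#' @param pop a \code{population} (QTL serve as the marker panel).
#' @param subset optional individual subset.
#' @param anchor optional \code{noia_anchor}; default observed frequencies.
#' @return An object of class \code{grm_set}: list of matrices \code{G_A},
#'   \code{G_D}, \code{G_AA}.
#' @export
build_grms_ipg <- function(pop, subset = NULL, anchor = NULL) {
  d <- dosage(pop, subset)[, pop$genome$qtl, drop = FALSE]
  if (nrow(d) < 2L) stop("need at least 2 individuals")
  if (is.null(anchor)) {
    n <- nrow(d)
    q <- colMeans(d) / 2
    het <- colMeans(d == 1L); bb <- colMeans(d == 2L)
    geno <- cbind(1 - het - bb, het, bb)
  } else {
    q <- anchor$q[pop$genome$qtl]
    geno <- anchor$geno[pop$genome$qtl, , drop = FALSE]
  }
  keep <- q > 0 & q < 1
  if (!any(keep)) stop("degenerate: all marker loci are monomorphic")
  Ha <- sweep(d[, keep, drop = FALSE], 2L, 2 * q[keep])
  hd <- h_covariates_genofreq(d[, keep, drop = FALSE],
                              geno[keep, , drop = FALSE])
  Hd <- hd$h_d
  norm_cp <- function(H) {
    G <- tcrossprod(H)
    G / (sum(diag(G)) / nrow(G))
  }
  G_A <- norm_cp(Ha)
  G_D <- norm_cp(Hd)
  G_AA <- G_A * G_A
  G_AA <- G_AA / (sum(diag(G_AA)) / nrow(G_AA))
  structure(list(G_A = G_A, G_D = G_D, G_AA = G_AA),
            class = "grm_set")
}

#' Genomic relationship matrices for three-way hybrid plot data
#'
#' G_A1 and G_A2 are built from the genotypes of the population-1 and
#' population-2 parental lines (anchored at their own base frequencies);
#' G_D3 from the generalized plot dominance covariates h_d3; G_A3 from the
#' parental-line genotype means h_a3 = (t1 - 2 q1)/2 + (t2a + t2b - 4 q2)/4,
#' and G_AA3 as the trace-normalized Hadamard square of G_A3.  Incidence
#' matrices link each plot to its population-1 parent (\code{Z1}) and to both
#' population-2 grandparents (\code{Z2}, the summed two-slot incidence).
#'
#' @param scheme a three-way scheme.
#' @param plots plot records (defaults to the scheme's descendant plots).
#' @param lines1_rows,lines2_rows rows of the line populations to carry in
#'   G_A1/G_A2 (defaults: all lines referenced by the plots).
#' @return An object of class \code{grm_set_ppg} with matrices G_A1, G_A2,
#'   G_D3, G_AA3 and incidence matrices Z1, Z2.
#' @export
build_grms_ppg <- function(scheme, plots = NULL, lines1_rows = NULL,
                           lines2_rows = NULL) {
  if (is.null(plots)) plots <- scheme$plots
  if (is.null(lines1_rows)) lines1_rows <- sort(unique(plots$i1))
  if (is.null(lines2_rows))
    lines2_rows <- sort(unique(c(plots$i2a, plots$i2b)))
  qtl <- scheme$lines1$genome$qtl
  d1 <- dosage(scheme$lines1)[lines1_rows, qtl, drop = FALSE]
  d2 <- dosage(scheme$lines2)[lines2_rows, qtl, drop = FALSE]
  q1 <- colMeans(d1) / 2
  q2 <- colMeans(d2) / 2
  keep1 <- q1 > 0 & q1 < 1; keep2 <- q2 > 0 & q2 < 1
  norm_cp <- function(H) {
    G <- tcrossprod(H)
    G / (sum(diag(G)) / nrow(G))
  }
  G_A1 <- norm_cp(sweep(d1[, keep1, drop = FALSE], 2L, 2 * q1[keep1]))
  G_A2 <- norm_cp(sweep(d2[, keep2, drop = FALSE], 2L, 2 * q2[keep2]))

  t1 <- dosage(scheme$lines1)[plots$i1, qtl, drop = FALSE] - 1
  t2a <- dosage(scheme$lines2)[plots$i2a, qtl, drop = FALSE] - 1
  t2b <- dosage(scheme$lines2)[plots$i2b, qtl, drop = FALSE] - 1
  t2 <- 0.5 * (t2a + t2b)
  np <- nrow(plots); nq <- ncol(t1)
  Q1 <- matrix(q1, np, nq, byrow = TRUE)
  Q2 <- matrix(q2, np, nq, byrow = TRUE)
  Hd3 <- h_d3(t1, t2, Q1, Q2)
  Ha3 <- 0.5 * (t1 - 2 * Q1) + 0.25 * (t2a + t2b - 4 * Q2)
  G_D3 <- norm_cp(Hd3)
  G_A3 <- norm_cp(Ha3)
  G_AA3 <- G_A3 * G_A3
  G_AA3 <- G_AA3 / (sum(diag(G_AA3)) / nrow(G_AA3))

  Z1 <- matrix(0, np, length(lines1_rows))
  Z1[cbind(seq_len(np), match(plots$i1, lines1_rows))] <- 1
  Z2 <- matrix(0, np, length(lines2_rows))
  ia <- match(plots$i2a, lines2_rows); ib <- match(plots$i2b, lines2_rows)
  Z2[cbind(seq_len(np), ia)] <- Z2[cbind(seq_len(np), ia)] + 1
  Z2[cbind(seq_len(np), ib)] <- Z2[cbind(seq_len(np), ib)] + 1
  structure(list(G_A1 = G_A1, G_A2 = G_A2, G_D3 = G_D3, G_AA3 = G_AA3,
                 Z1 = Z1, Z2 = Z2),
            class = "grm_set_ppg")
}

#' Average-information REML for dense multi-GRM mixed models
#'
#' Maximizes the restricted log-likelihood of y = 1 mu + sum_c Z_c g_c + e,
#' g_c ~ N(0, G_c sigma2_c), e ~ N(0, I sigma2_e), by average-information
#' updates with step halving and a boundary constraint at zero (estimates are
#' clamped to a small positive floor; the log-likelihood never decreases
#' across accepted iterations).  Dense algebra throughout, intended for
#' moderate n.
#'
#' @param y numeric response vector.
#' @param K named list of n-by-n covariance structures Z_c G_c Z_c' (built
#'   with \code{\link{component_covariances}} or supplied directly).
#' @param start optional named start values (components then residual);
#'   default splits var(y) equally.
#' @param max_iter maximum iterations.
#' @param tol convergence tolerance on the change in restricted logL.
#' @param bend diagonal bending added to a structure whose Cholesky fails.
#' @param n_max guard for the dense algebra: record counts above this are
#'   rejected (raise deliberately for bigger machines).
#' @param verbose print the trajectory.
#' @return An object of class \code{reml_fit}: estimates, asymptotic
#'   standard errors from the inverse average-information matrix,
#'   convergence flag and logL trajectory.
#' @export
aireml <- function(y, K, start = NULL, max_iter = 60L, tol = 1e-6,
                   bend = 1e-6, n_max = 5000L, verbose = FALSE) {
  n <- length(y)
  if (n > n_max)
    stop("n = ", n, " exceeds the dense-algebra cap (n_max = ", n_max, ")")
  nc <- length(K)
  if (is.null(names(K))) names(K) <- paste0("g", seq_len(nc))
  for (j in seq_len(nc)) {
    ev_ok <- tryCatch({ chol(K[[j]] + diag(1e-8, n)); TRUE },
                      error = function(e) FALSE)
    if (!ev_ok)
      K[[j]] <- K[[j]] + diag(bend * mean(diag(K[[j]])), n)
  }
  vy <- stats::var(y)
  theta <- if (is.null(start)) rep(vy / (nc + 1L), nc + 1L) else start
  names(theta) <- c(names(K), "residual")
  floor_ <- 1e-6 * vy
  X <- matrix(1, n, 1L)

  loglik_parts <- function(theta) {
    V <- diag(theta[nc + 1L], n)
    for (j in seq_len(nc)) V <- V + theta[j] * K[[j]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    Py <- Vi %*% y - ViX %*% solve(XtViX, crossprod(ViX, y))
    ll <- -0.5 * (2 * sum(log(diag(ch))) + log(XtViX[1L, 1L]) +
                    sum(y * Py))
    list(ll = ll, Vi = Vi, ViX = ViX, XtViX = XtViX, Py = Py)
  }

  cur <- loglik_parts(theta)
  if (is.null(cur)) stop("initial variance matrix not positive definite")
  traj <- cur$ll
  converged <- FALSE
  AI <- NULL
  for (iter in seq_len(max_iter)) {
    # tr(P Kc) via explicit V^{-1} and the rank-1 fixed-effect correction
    Py <- cur$Py
    KPy <- vector("list", nc + 1L)
    for (j in seq_len(nc)) KPy[[j]] <- K[[j]] %*% Py
    KPy[[nc + 1L]] <- Py
    w <- cur$ViX / cur$XtViX[1L, 1L]   # V^{-1} X (X' V^{-1} X)^{-1}
    score <- numeric(nc + 1L)
    for (j in seq_len(nc + 1L)) {
      Kj <- if (j <= nc) K[[j]] else NULL
      trPK <- if (j <= nc)
        sum(cur$Vi * Kj) - sum(w * (Kj %*% cur$ViX))
      else sum(diag(cur$Vi)) - sum(w * cur$ViX)
      score[j] <- -0.5 * (trPK - sum(Py * KPy[[j]]))
    }
    Pv <- function(v) cur$Vi %*% v - cur$ViX %*%
      solve(cur$XtViX, crossprod(cur$ViX, v))
    PKPy <- lapply(KPy, Pv)
    AI <- matrix(0, nc + 1L, nc + 1L)
    for (j in seq_len(nc + 1L))
      for (k in j:(nc + 1L))
        AI[j, k] <- AI[k, j] <- 0.5 * sum(KPy[[j]] * PKPy[[k]])
    step <- tryCatch(solve(AI, score),
                     error = function(e) score / diag(AI))
    accepted <- FALSE
    for (h in 0:12) {
      prop <- pmax(theta + step / 2^h, floor_)
      nxt <- loglik_parts(prop)
      if (!is.null(nxt) && nxt$ll >= cur$ll - 1e-10) {
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break
    delta <- nxt$ll - cur$ll
    theta <- prop
    cur <- nxt
    traj <- c(traj, cur$ll)
    if (verbose)
      cat(sprintf("iter %d logL %.6f  %s\n", iter, cur$ll,
                  paste(sprintf("%.3f", theta), collapse = " ")))
    if (abs(delta) < tol) {
      converged <- TRUE
      break
    }
  }
  se <- rep(NA_real_, nc + 1L)
  if (!is.null(AI)) {
    AIi <- tryCatch(solve(AI), error = function(e) NULL)
    if (!is.null(AIi)) se <- sqrt(pmax(diag(AIi), 0))
  }
  structure(list(estimates = theta, se = stats::setNames(se, names(theta)),
                 logLik = cur$ll, trajectory = traj, converged = converged,
                 n = n, ai = AI),
            class = "reml_fit")
}

#' Covariance structures Z G Z' for \code{\link{aireml}}
#'
#' @param grms a \code{grm_set} or \code{grm_set_ppg}.
#' @param Z optional named list of incidence matrices (defaults: identity for
#'   individual models; the stored Z1/Z2 and plot-level identity for plot
#'   models).
#' @return named list of n-by-n matrices.
#' @export
component_covariances <- function(grms, Z = NULL) {
  if (inherits(grms, "grm_set")) {
    list(additive = grms$G_A, dominance = grms$G_D, epistasis = grms$G_AA)
  } else {
    list(additive1 = grms$Z1 %*% grms$G_A1 %*% t(grms$Z1),
         additive2 = grms$Z2 %*% grms$G_A2 %*% t(grms$Z2),
         dominance3 = grms$G_D3, epistasis3 = grms$G_AA3)
  }
}

#' @export
print.reml_fit <- function(x, digits = 3, ...) {
  cat("AI-REML fit (n = ", x$n, ")",
      if (!x$converged) " [not converged]", ":\n", sep = "")
  print(round(cbind(estimate = x$estimates, se = x$se), digits))
  cat("logLik:", format(x$logLik, digits = 7), "in",
      length(x$trajectory) - 1L, "iterations\n")
  invisible(x)
}

#' @export
summary.reml_fit <- function(object, ...) object

#' @export
coef.reml_fit <- function(object, ...) object$estimates

#' @export
logLik.reml_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$estimates), class = "logLik")
}

#' @export
vcov.reml_fit <- function(object, ...) {
  if (is.null(object$ai)) return(NULL)
  solve(object$ai)
}
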