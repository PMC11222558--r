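test_that("genotype covariates take the canonical values", {
  tc <- t_covariates(c(0, 1, 2))
  expect_equal(tc$t_a, c(-1, 0, 1))
  expect_equal(tc$t_d, c(0, 1, 0))
  expect_error(t_covariates(3), "dosage")

  hc <- h_covariates_freq(1, 0.5)
  expect_equal(c(hc$h_a, hc$h_d), c(0, 0.5))
  hc2 <- h_covariates_freq(0, 0.3)
  expect_equal(c(hc2$h_a, hc2$h_d), c(-0.6, -0.18))
  hc3 <- h_covariates_freq(0, 0)      # fixed locus, no variation
  expect_equal(c(hc3$h_a, hc3$h_d), c(0, 0))

  expect_equal(epistasis_covariates(-1, 1), -1)
  expect_equal(epistasis_covariates(0, 1), 0)
})

test_that("genotype-frequency covariates generalize the HWE form", {
  q <- 0.4; p <- 1 - q
  hw <- h_covariates_freq(0:2, q)
  gf <- h_covariates_genofreq(0:2, c(p^2, 2 * p * q, q^2))
  expect_equal(gf$h_a, hw$h_a, tolerance = 1e-12)
  expect_equal(gf$h_d, hw$h_d, tolerance = 1e-12)
  # pure BB/bb mixture: numerators vanish for the observed classes and the
  # dominance covariate of the absent heterozygote class is flagged finite
  gfm <- h_covariates_genofreq(c(0, 2), c(0.5, 0, 0.5))
  expect_equal(gfm$h_d, c(0, 0))
  # population-weighted mean of h_a is zero by construction
  geno <- c(0.2, 0.5, 0.3)
  ha <- h_covariates_genofreq(0:2, geno)$h_a
  expect_equal(sum(ha * geno), 0, tolerance = 1e-12)
  # degenerate (fixed) locus: h_d defined as 0 and flagged
  gfd <- h_covariates_genofreq(c(2, 2), c(0, 0, 1))
  expect_equal(gfd$h_d, c(0, 0))
  expect_true(attr(gfd, "degenerate"))
})

test_that("single-population W matrices have the documented structure", {
  an <- hwe_anchor(c(0.3, 0.7))
  W <- build_W_ipg(an, 1, 2)
  expect_equal(dim(W$W_f), c(9, 6))
  expect_equal(W$W_f[, 1], rep(1, 9))
  expect_equal(W$W_s[, 1], rep(1, 9))
  # column 2 varies with locus k fastest
  expect_equal(W$W_f[, 2], rep(c(-1, 0, 1), 3))
  # left-inverse property
  LI <- solve(crossprod(W$W_s)) %*% t(W$W_s)
  expect_equal(LI %*% W$W_s, diag(6), tolerance = 1e-10)
})

test_that("class-frequency weights cancel out of the transform", {
  set.seed(10)
  for (i in 1:20) {
    qk <- runif(1, 0.05, 0.95); ql <- runif(1, 0.05, 0.95)
    an <- hwe_anchor(c(qk, ql), covariate = "freq")
    W <- build_W_ipg(an, 1, 2)
    E_f <- c(rnorm(1), rnorm(5))
    plain <- functional_to_statistical_ipg(E_f, W)
    # weighted left inverse with the joint HWE class-frequency matrix
    fk <- c((1 - qk)^2, 2 * qk * (1 - qk), qk^2)
    fl <- c((1 - ql)^2, 2 * ql * (1 - ql), ql^2)
    Fw <- diag(kronecker(fl, fk))
    weighted <- solve(t(W$W_s) %*% Fw %*% W$W_s,
                      t(W$W_s) %*% Fw %*% W$W_f %*% E_f)
    expect_equal(drop(weighted), unname(plain), tolerance = 1e-10)
  }
})

test_that("forward and backward transforms are mutual inverses", {
  set.seed(11)
  gm <- le_genome(40)
  # property loop over random anchors and effects, closed-form route
  for (i in 1:25) {
    an <- hwe_anchor(runif(40, 0.05, 0.95),
                     covariate = if (i %% 2) "freq" else "genofreq")
    fx <- random_fx(gm)
    sx <- noia_forward_ipg(fx, an)
    fx2 <- noia_backward_ipg(sx, gm)
    expect_equal(fx2$a, fx$a, tolerance = 1e-10)
    expect_equal(fx2$d, fx$d, tolerance = 1e-10)
    expect_equal(fx2$aa, fx$aa, tolerance = 1e-10)
    # the model restriction holds in every output
    expect_identical(sx$delta, fx$d)
    expect_identical(sx$aa, fx$aa)
  }
  # matrix route round trip on one pair
  an <- hwe_anchor(runif(40, 0.05, 0.95))
  fx <- random_fx(gm)
  W <- build_W_ipg(an, gm$pairs[1, 1], gm$pairs[1, 2])
  E_f <- ef_pair(fx, 1)
  E_s <- functional_to_statistical_ipg(E_f, W)
  expect_equal(statistical_to_functional_ipg(E_s, W), E_f,
               tolerance = 1e-10)
  # statistical round trip: backward then forward recovers E_s
  sx <- noia_forward_ipg(noia_backward_ipg(noia_forward_ipg(fx, an), gm), an)
  expect_equal(sx$alpha, noia_forward_ipg(fx, an)$alpha, tolerance = 1e-10)
})

test_that("closed-form substitution effects match the matrix transform", {
  set.seed(12)
  gm <- le_genome(20)
  an <- hwe_anchor(runif(20, 0.05, 0.95), covariate = "freq")
  fx <- random_fx(gm)
  sx <- noia_forward_ipg(fx, an)
  for (pi in seq_len(nrow(gm$pairs))) {
    k <- gm$pairs[pi, 1]; l <- gm$pairs[pi, 2]
    W <- build_W_ipg(an, k, l)
    E_s <- functional_to_statistical_ipg(ef_pair(fx, pi), W)
    ki <- fx$pairs_q[pi, 1]; li <- fx$pairs_q[pi, 2]
    expect_equal(E_s[2], sx$alpha[ki], tolerance = 1e-10)
    expect_equal(E_s[3], sx$alpha[li], tolerance = 1e-10)
    # alpha decomposition: a + (1-2q)d + epistatic contribution
    contrib <- epistatic_additive_contribution(fx$aa[pi], an, k, l)
    expect_equal(sx$alpha[ki],
                 fx$a[ki] + (1 - 2 * an$q[k]) * fx$d[ki] + contrib[["k"]],
                 tolerance = 1e-10)
  }
  # no dominance/epistasis: alpha equals a at any frequency
  fx0 <- functional_effects(a = rnorm(20), d = rep(0, 20),
                            aa = rep(0, 10), genome = gm)
  expect_equal(noia_forward_ipg(fx0, an)$alpha, fx0$a)
  # a = 1, d = 0.5, q = 0.3, no epistasis: alpha = 1.2
  gm1 <- le_genome(1, paired = FALSE)
  fx1 <- functional_effects(a = 1, d = 0.5, aa = numeric(0), genome = gm1)
  expect_equal(noia_forward_ipg(fx1, hwe_anchor(0.3, "freq"))$alpha, 1.2)
})

test_that("epistatic additive contributions follow the partner frequency", {
  an <- hwe_anchor(c(0.3, 0.7), covariate = "freq")
  # aa = 1, q_l = 0.7: contribution to alpha_k is q_l - p_l = 0.4
  expect_equal(epistatic_additive_contribution(1, an, 1, 2)[["k"]], 0.4)
  expect_equal(epistatic_additive_contribution(0, an, 1, 2),
               c(k = 0, l = 0))
  an5 <- hwe_anchor(c(0.2, 0.5), covariate = "freq")
  expect_equal(epistatic_additive_contribution(2, an5, 1, 2)[["k"]], 0)
  # matches the matrix transform with E_f = (1,0,0,0,0,aa)
  W <- build_W_ipg(an, 1, 2)
  E_s <- functional_to_statistical_ipg(c(1, 0, 0, 0, 0, 1), W)
  expect_equal(E_s[2], 0.4, tolerance = 1e-10)
  expect_equal(E_s[6], 1, tolerance = 1e-10)
})

test_that("additive and dominance covariates are orthogonal per locus", {
  set.seed(13)
  for (i in 1:15) {
    geno <- as.vector(stats::rmultinom(1, 60, runif(3, 0.05, 1)))
    geno <- geno / sum(geno)
    h <- h_covariates_genofreq(0:2, geno)
    expect_equal(sum(geno * h$h_a * h$h_d), 0, tolerance = 1e-10)
    expect_equal(sum(geno * h$h_d), 0, tolerance = 1e-10)
  }
  # HWE-form covariates are orthogonal under HWE weights only
  q <- 0.37; p <- 1 - q
  h <- h_covariates_freq(0:2, q)
  expect_equal(sum(c(p^2, 2 * p * q, q^2) * h$h_a * h$h_d), 0,
               tolerance = 1e-10)
})

test_that("joint-class row order is immaterial to the transform", {
  an <- hwe_anchor(c(0.25, 0.6))
  W <- build_W_ipg(an, 1, 2)
  perm <- sample(9)
  Wp <- list(W_f = W$W_f[perm, ], W_s = W$W_s[perm, ])
  E_f <- c(0, rnorm(5))
  expect_equal(functional_to_statistical_ipg(E_f, Wp),
               functional_to_statistical_ipg(E_f, W), tolerance = 1e-10)
})

test_that("plot covariates reproduce expected heterozygosity", {
  expect_equal(t_d3(-1, 1), 1)      # BB line x bb two-way: all heterozygous
  expect_equal(t_d3(-1, -1), 0)
  expect_equal(t_d3(-1, 0), 0.5)
  expect_equal(t_d3(1, -0.5), 0.75)
  # statistical plot dominance covariate, spec substitution cases
  expect_equal(h_d3(-1, -1, 0.5, 0.5), -0.5)
  expect_equal(h_d3(-1, 1, 0.5, 0.5), 0.5)
  expect_equal(h_d3(-1, 1, 0.3, 0.2), 2 * 0.3 * 0.8)
  # expectation of h_d3 over random-mating plots is ~0 at the anchor
  set.seed(14)
  gm <- le_genome(1, paired = FALSE)
  q1 <- 0.35; q2 <- 0.6
  t1 <- 2 * rbinom(4000, 1, q1) - 1          # inbred pop-1 parent codes
  t2 <- (rbinom(4000, 1, q2) + rbinom(4000, 1, q2)) - 1  # two inbred lines
  hv <- h_d3(t1, t2 / 1, q1, q2)
  expect_lt(abs(mean(hv)), 4 * sd(hv) / sqrt(4000))
})

test_that("plot-setting W matrices transform like the closed form", {
  set.seed(15)
  gm <- le_genome(8)
  q1 <- runif(8, 0.1, 0.9); q2 <- runif(8, 0.1, 0.9)
  fx <- random_fx(gm)
  sp <- noia_forward_ppg(fx, q1, q2)
  for (pi in 1:2) {
    k <- gm$pairs[pi, 1]; l <- gm$pairs[pi, 2]
    W <- build_W_ppg(q1[k], q2[k], q1[l], q2[l])
    expect_equal(W$W_f[, 1], rep(1, nrow(W$W_f)))
    expect_equal(qr(W$W_s)$rank, 8)
    ki <- fx$pairs_q[pi, 1]; li <- fx$pairs_q[pi, 2]
    E_f <- c(0, fx$a[ki], fx$a[li], fx$a[ki], fx$a[li], fx$d[ki], fx$d[li],
             fx$aa[pi])
    E_s <- functional_to_statistical_ppg(E_f, W)
    expect_equal(E_s[2], sp$alpha1[ki], tolerance = 1e-9)
    expect_equal(E_s[4], sp$alpha2[ki], tolerance = 1e-9)
    expect_equal(E_s[6], fx$d[ki], tolerance = 1e-9)   # delta3 = d
    expect_equal(E_s[8], fx$aa[pi], tolerance = 1e-9)  # (alpha alpha)3 = aa
  }
  # equal frequencies in both populations: alpha1 = alpha2
  sp2 <- noia_forward_ppg(fx, q1, q1)
  expect_equal(sp2$alpha1, sp2$alpha2, tolerance = 1e-12)
})
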