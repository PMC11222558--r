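# small in-code fixtures shared across test files

# population with prescribed dosage matrix (phase chosen deterministically)
pop_from_dosage <- function(d, genome = NULL) {
  d <- as.matrix(d)
  if (is.null(genome)) genome <- le_genome(ncol(d), paired = FALSE)
  noiasim:::new_population(h1 = pmin(d, 1L), h2 = pmax(d - 1L, 0L),
                           genome = genome)
}

# HWE anchor at given allele frequencies using the general covariate form
hwe_anchor <- function(q, covariate = "genofreq") {
  anchor_from_freq(q, covariate = covariate)
}

# random functional effects on a genome
random_fx <- function(genome, sd_a = 1, sd_d = 0.5, sd_aa = 0.5) {
  np <- if (is.null(genome$pairs)) 0L else nrow(genome$pairs)
  functional_effects(a = rnorm(length(genome$qtl), 0, sd_a),
                     d = rnorm(length(genome$qtl), 0, sd_d),
                     aa = rnorm(np, 0, sd_aa), genome = genome)
}

# E_f vector for pair pi of fx, iPG layout (mu, a_k, a_l, d_k, d_l, aa)
ef_pair <- function(fx, pi, mu = 0) {
  ki <- fx$pairs_q[pi, 1L]; li <- fx$pairs_q[pi, 2L]
  c(mu, fx$a[ki], fx$a[li], fx$d[ki], fx$d[li], fx$aa[pi])
}
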