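#' Forward Wright-Fisher history and linked base population
#'
#' Simulates standing variation with linkage disequilibrium by forward
#' Wright-Fisher drift: all loci start at allele frequency 0.5 (heterozygous
#' founder haplotypes randomised across individuals), and each historical
#' generation is formed by random union of recombinant gametes (Haldane model)
#' from the previous one.  No mutation or selection acts, so linked loci build
#' up drift-generated LD while unlinked loci stay near equilibrium.  After the
#' historical phase \code{n} base individuals are drawn as offspring of the
#' final historical generation.
#'
#' @param n number of base individuals to return.
#' @param genome a \code{genome_map} (QTL not yet designated).
#' @param historical_generations number of historical generations; 0 returns
#'   a founder population with every locus exactly at frequency 0.5.
#' @param historical_n historical population size per generation.
#' @param seed optional integer seed.
#' @return A \code{population} at generation 0.
#' @export
simulate_ld_base <- function(n, genome, historical_generations = 200L,
                             historical_n = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (historical_generations < 0L) stop("historical_generations must be >= 0")
  if (historical_generations == 0L) historical_n <- n
  m <- n_loci(genome)
  # founder haplotypes: every locus exactly at frequency 0.5 across the 2N
  # haplotypes, allele order randomised per locus to avoid initial LD
  nh <- 2L * historical_n
  H <- matrix(0L, nh, m)
  half <- nh %/% 2L
  for (j in seq_len(m)) H[sample.int(nh, half), j] <- 1L
  h1 <- H[seq_len(historical_n), , drop = FALSE]
  h2 <- H[historical_n + seq_len(historical_n), , drop = FALSE]
  pop <- new_population(h1, h2, genome)
  if (historical_generations == 0L) return(pop)
  for (g in seq_len(historical_generations)) {
    sires <- sample.int(historical_n, historical_n, replace = TRUE)
    dams <- sample.int(historical_n, historical_n, replace = TRUE)
    pop <- .make_offspring(pop, sires, dams, mode = "ld", generation = 0L)
  }
  sires <- sample.int(historical_n, n, replace = TRUE)
  dams <- sample.int(historical_n, n, replace = TRUE)
  .make_offspring(pop, sires, dams, mode = "ld", generation = 0L)
}

#' Split a population's history into two diverged populations
#'
#' Continues Wright-Fisher drift separately from a common population, giving
#' two populations whose allele-frequency differences reflect
#' \code{divergence_generations} of independent drift.
#'
#' @param pop common ancestral \code{population}.
#' @param n1,n2 base sizes of the two resulting populations.
#' @param divergence_generations generations of separate drift.
#' @param historical_n size of each diverged line during drift.
#' @param seed optional integer seed.
#' @return list of two \code{population}s.
#' @export
diverge_populations <- function(pop, n1, n2, divergence_generations = 50L,
                                historical_n = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  branch <- function(nf) {
    cur <- pop
    for (g in seq_len(divergence_generations)) {
      sires <- sample.int(n_ind(cur), historical_n, replace = TRUE)
      dams <- sample.int(n_ind(cur), historical_n, replace = TRUE)
      cur <- .make_offspring(cur, sires, dams, mode = "ld", generation = 0L)
    }
    sires <- sample.int(n_ind(cur), nf, replace = TRUE)
    dams <- sample.int(n_ind(cur), nf, replace = TRUE)
    .make_offspring(cur, sires, dams, mode = "ld", generation = 0L)
  }
  list(pop1 = branch(n1), pop2 = branch(n2))
}

#' Designate QTL among segregating loci
#'
#' Draws \code{n_qtl} QTL uniformly from loci whose minor allele frequency in
#' \code{pop} is at least \code{maf_min}, and (optionally) groups them into
#' epistatic pairs by random permutation, one pair per QTL.
#'
#' @param pop a \code{population}.
#' @param n_qtl number of QTL to designate (even when \code{paired}).
#' @param maf_min minimum minor allele frequency, in (0, 0.5).
#' @param paired create the epistatic pairing.
#' @param seed optional integer seed.
#' @return The population with its genome's \code{qtl} and \code{pairs} set.
#' @export
draw_qtl <- function(pop, n_qtl, maf_min = 0.05, paired = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  af <- allele_frequencies(pop)
  maf <- pmin(af$q, 1 - af$q)
  eligible <- which(maf >= maf_min)
  if (length(eligible) < n_qtl)
    stop("insufficient segregation: only ", length(eligible),
         " loci with MAF >= ", maf_min)
  qtl <- sort(sample(eligible, n_qtl))
  pairs <- NULL
  if (paired) {
    if (n_qtl %% 2L != 0L) stop("n_qtl must be even to pair all QTL")
    pairs <- matrix(sample(qtl), ncol = 2L)
  }
  gm <- pop$genome
  gm$qtl <- qtl
  gm$pairs <- pairs
  pop$genome <- gm
  pop
}

#' Restrict a population to its QTL loci
#'
#' Drops non-QTL loci, renumbering QTL and pairs onto the reduced scaffold.
#' Useful after \code{\link{draw_qtl}} when only QTL are carried forward.
#'
#' @param pop a \code{population} whose genome has designated QTL.
#' @return A \code{population} on the reduced genome (all loci QTL).
#' @export
keep_qtl <- function(pop) {
  gm <- pop$genome
  if (length(gm$qtl) == 0L) stop("no QTL designated")
  idx <- gm$qtl
  remap <- match(gm$pairs, idx)
  pairs <- if (is.null(gm$pairs)) NULL else matrix(remap, ncol = 2L)
  gm2 <- genome_map(chr = gm$chr[idx], pos = gm$pos[idx],
                    chr_length = gm$chr_length, qtl = seq_along(idx),
                    pairs = pairs)
  new_population(pop$h1[, idx, drop = FALSE], pop$h2[, idx, drop = FALSE],
                 gm2, id = pop$id, sire = pop$sire, dam = pop$dam,
                 generation = pop$generation)
}
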