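#' Genome map
#'
#' A genome map holds the marker scaffold of the simulator: chromosome
#' assignment and genetic-map position (cM) of every locus, the subset of loci
#' that act as QTL, and the list of additive-by-additive interaction pairs.
#' Each QTL belongs to at most one pair and pair members are distinct.
#'
#' @param chr integer vector, chromosome id per locus (non-decreasing).
#' @param pos numeric vector, position in cM per locus; strictly increasing
#'   within chromosome.
#' @param chr_length named numeric vector of chromosome lengths in cM; defaults
#'   to the largest position per chromosome.
#' @param qtl integer vector of locus indices designated as QTL.
#' @param pairs two-column integer matrix of locus indices (both columns QTL)
#'   defining epistatic pairs.
#' @return An object of class \code{genome_map}.
#' @export
genome_map <- function(chr, pos, chr_length = NULL, qtl = seq_along(chr),
                       pairs = NULL) {
  chr <- as.integer(chr)
  pos <- as.numeric(pos)
  if (length(chr) != length(pos)) stop("chr and pos must have equal length")
  if (length(chr) == 0L) stop("empty genome")
  if (is.unsorted(chr)) stop("loci must be grouped by chromosome")
  for (c_ in unique(chr)) {
    pc <- pos[chr == c_]
    if (length(pc) > 1L && any(diff(pc) <= 0))
      stop("positions must be strictly increasing within chromosome ", c_)
  }
  if (is.null(chr_length)) {
    chr_length <- tapply(pos, chr, max)
  }
  qtl <- sort(unique(as.integer(qtl)))
  if (any(qtl < 1L) || any(qtl > length(chr))) stop("qtl indices out of range")
  if (!is.null(pairs)) {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
    if (any(pairs[, 1L] == pairs[, 2L])) stop("pair members must be distinct")
    if (!all(pairs %in% qtl)) stop("pair members must be QTL")
    if (anyDuplicated(as.vector(pairs)))
      stop("every QTL may appear in at most one pair")
  }
  structure(list(chr = chr, pos = pos, chr_length = chr_length,
                 qtl = qtl, pairs = pairs,
                 chr_index = split(seq_along(chr), chr)),
            class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat("Genome map:", length(x$chr), "loci on", length(x$chr_index),
      "chromosome(s);", length(x$qtl), "QTL,",
      if (is.null(x$pairs)) 0L else nrow(x$pairs), "epistatic pair(s)\n")
  invisible(x)
}

n_loci <- function(genome) length(genome$chr)

#' Linkage-equilibrium genome of unlinked QTL
#'
#' Convenience constructor for the unlinked setting: \code{n_qtl} loci, each a
#' QTL, inherited independently (map positions are nominal).  When
#' \code{paired} is TRUE the QTL are grouped into \code{n_qtl/2} epistatic
#' pairs by random permutation, so that every QTL sits in exactly one pair.
#'
#' @param n_qtl number of QTL (even when \code{paired}).
#' @param paired logical; create the one-pair-per-QTL epistatic pairing.
#' @return A \code{genome_map}.
#' @export
le_genome <- function(n_qtl, paired = TRUE) {
  pairs <- NULL
  if (paired) {
    if (n_qtl %% 2L != 0L) stop("n_qtl must be even to pair all QTL")
    perm <- sample.int(n_qtl)
    pairs <- matrix(perm, ncol = 2L)
  }
  genome_map(chr = rep(1L, n_qtl), pos = seq_len(n_qtl),
             chr_length = n_qtl, qtl = seq_len(n_qtl), pairs = pairs)
}

#' Multi-chromosome genome scaffold for linked simulation
#'
#' Loci positions are drawn uniformly along each chromosome (sorted), before
#' any QTL are designated; QTL are typically assigned later from segregating
#' loci with \code{\link{draw_qtl}}.
#'
#' @param n_chr number of chromosomes.
#' @param chr_length chromosome length in cM (recycled).
#' @param loci_per_chr number of loci per chromosome (recycled).
#' @return A \code{genome_map} with no QTL designated (\code{qtl} empty).
#' @export
ld_genome <- function(n_chr = 7L, chr_length = 230, loci_per_chr = 1000L) {
  chr_length <- rep_len(chr_length, n_chr)
  loci_per_chr <- rep_len(loci_per_chr, n_chr)
  chr <- rep(seq_len(n_chr), loci_per_chr)
  pos <- unlist(lapply(seq_len(n_chr), function(c_) {
    sort(stats::runif(loci_per_chr[c_], 0, chr_length[c_]))
  }))
  genome_map(chr = chr, pos = pos, chr_length = chr_length,
             qtl = integer(0))
}

#' Population of haplotype-resolved genotypes
#'
#' Internal constructor.  Haplotypes are 0/1 integer matrices (individuals by
#' loci) counting copies of allele b; dosage is their sum.  Pedigree is stored
#' as sire/dam ids (NA for founders) and an integer generation label.
#'
#' @keywords internal
new_population <- function(h1, h2, genome, id = NULL, sire = NA_integer_,
                           dam = NA_integer_, generation = 0L) {
  n <- nrow(h1)
  stopifnot(identical(dim(h1), dim(h2)), ncol(h1) == n_loci(genome))
  if (is.null(id)) id <- seq_len(n)
  structure(list(h1 = h1, h2 = h2, genome = genome,
                 id = as.integer(id),
                 sire = rep_len(as.integer(sire), n),
                 dam = rep_len(as.integer(dam), n),
                 generation = rep_len(as.integer(generation), n)),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  gen <- table(x$generation)
  cat("Population:", nrow(x$h1), "individuals x", ncol(x$h1), "loci\n")
  cat("  generations:", paste0(names(gen), " (n=", gen, ")", collapse = ", "),
      "\n")
  invisible(x)
}

n_ind <- function(pop) nrow(pop$h1)

#' Allele-b dosage matrix (0/1/2)
#' @param pop a \code{population}.
#' @param subset optional row subset (indices or logical).
#' @return integer matrix, individuals by loci.
#' @export
dosage <- function(pop, subset = NULL) {
  if (is.null(subset)) pop$h1 + pop$h2
  else pop$h1[subset, , drop = FALSE] + pop$h2[subset, , drop = FALSE]
}

#' Subset a population by individuals
#' @param pop a \code{population}.
#' @param i row indices (or logical mask).
#' @export
subset_population <- function(pop, i) {
  new_population(pop$h1[i, , drop = FALSE], pop$h2[i, , drop = FALSE],
                 pop$genome, id = pop$id[i], sire = pop$sire[i],
                 dam = pop$dam[i], generation = pop$generation[i])
}

#' Combine populations sharing a genome
#' @param ... \code{population} objects on the same genome.
#' @export
bind_populations <- function(...) {
  pops <- list(...)
  if (length(pops) == 1L && is.list(pops[[1L]]) &&
      !inherits(pops[[1L]], "population")) pops <- pops[[1L]]
  new_population(do.call(rbind, lapply(pops, `[[`, "h1")),
                 do.call(rbind, lapply(pops, `[[`, "h2")),
                 pops[[1L]]$genome,
                 id = unlist(lapply(pops, `[[`, "id")),
                 sire = unlist(lapply(pops, `[[`, "sire")),
                 dam = unlist(lapply(pops, `[[`, "dam")),
                 generation = unlist(lapply(pops, `[[`, "generation")))
}

#' Allele and genotype frequencies
#'
#' Per-locus frequency of allele b (\code{q}) and the observed genotype
#' frequencies (columns BB, Bb, bb, summing to 1 per locus).
#'
#' @param pop a \code{population}.
#' @param subset optional individual subset.
#' @return list with \code{q} (numeric vector) and \code{geno} (matrix, loci by
#'   3, columns \code{BB}, \code{Bb}, \code{bb}).
#' @export
allele_frequencies <- function(pop, subset = NULL) {
  d <- dosage(pop, subset)
  if (nrow(d) == 0L) stop("empty subset")
  n <- nrow(d)
  q <- colMeans(d) / 2
  het <- colMeans(d == 1L)
  bb <- colMeans(d == 2L)
  geno <- cbind(BB = 1 - het - bb, Bb = het, bb = bb)
  list(q = q, geno = geno, n = n)
}

#' Sample a linkage-equilibrium base population
#'
#' Per-locus target allele-b frequencies are drawn uniformly on
#' \code{freq_range} and haplotype alleles sampled independently
#' Bernoulli(q_j), so loci are mutually independent and genotypes are in
#' Hardy-Weinberg proportions in expectation.
#'
#' @param n number of individuals (>= 2).
#' @param genome a \code{genome_map}.
#' @param freq_range length-2 numeric in (0,1), bounds of the uniform
#'   distribution of target allele frequencies.
#' @param seed optional integer seed.
#' @return A \code{population} (generation 0).
#' @export
sample_base_le <- function(n, genome, freq_range = c(0.05, 0.95),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n < 2L) stop("invalid configuration: n must be >= 2")
  m <- n_loci(genome)
  if (m == 0L) stop("invalid configuration: empty genome")
  if (freq_range[1L] <= 0 || freq_range[2L] >= 1 ||
      freq_range[1L] > freq_range[2L])
    stop("invalid configuration: freq_range must satisfy 0 < low <= high < 1")
  q <- stats::runif(m, freq_range[1L], freq_range[2L])
  h1 <- matrix(stats::rbinom(n * m, 1L, rep(q, each = n)), n, m)
  h2 <- matrix(stats::rbinom(n * m, 1L, rep(q, each = n)), n, m)
  pop <- new_population(h1, h2, genome)
  attr(pop, "target_freq") <- q
  pop
}

# one recombinant gamete under the Haldane model (Poisson crossovers,
# uniform positions, no interference; chromosome-start haplotype by fair coin)
.gamete_ld <- function(h1, h2, genome) {
  g <- integer(length(h1))
  for (ci in seq_along(genome$chr_index)) {
    idx <- genome$chr_index[[ci]]
    len <- genome$chr_length[[ci]]
    nco <- stats::rpois(1L, len / 100)
    start <- sample.int(2L, 1L)
    if (nco == 0L) {
      g[idx] <- if (start == 1L) h1[idx] else h2[idx]
    } else {
      xo <- sort(stats::runif(nco, 0, len))
      seg <- findInterval(genome$pos[idx], xo)
      use1 <- (seg + start) %% 2L == 1L
      g[idx] <- ifelse(use1, h1[idx], h2[idx])
    }
  }
  g
}

# independent per-locus inheritance (unlinked loci)
.gamete_le <- function(h1, h2) {
  pick <- stats::runif(length(h1)) < 0.5
  ifelse(pick, h1, h2)
}

#' Simulate one meiosis
#'
#' In \code{"ld"} mode the crossover count per chromosome is Poisson(length in
#' Morgan) with uniform crossover positions (Haldane map function, no
#' interference) and the starting haplotype is chosen by fair coin.  In
#' \code{"le"} mode every locus inherits one of the two parental alleles
#' independently with probability 1/2.
#'
#' @param pop a \code{population}.
#' @param parent index of the parent within \code{pop}.
#' @param mode \code{"ld"} (recombination along the map) or \code{"le"}
#'   (independent inheritance).
#' @param seed optional integer seed.
#' @return integer vector: one gamete haplotype over all loci.
#' @export
meiosis <- function(pop, parent, mode = c("ld", "le"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mode <- match.arg(mode)
  h1 <- pop$h1[parent, ]
  h2 <- pop$h2[parent, ]
  if (mode == "ld") .gamete_ld(h1, h2, pop$genome) else .gamete_le(h1, h2)
}

# batch of offspring: one gamete from each listed sire and dam
.make_offspring <- function(pop, sires, dams, mode, generation) {
  m <- n_loci(pop$genome)
  k <- length(sires)
  if (mode == "le") {
    s1 <- pop$h1[sires, , drop = FALSE]; s2 <- pop$h2[sires, , drop = FALSE]
    d1 <- pop$h1[dams, , drop = FALSE];  d2 <- pop$h2[dams, , drop = FALSE]
    ps <- matrix(stats::runif(k * m) < 0.5, k, m)
    pd <- matrix(stats::runif(k * m) < 0.5, k, m)
    h1 <- ifelse(ps, s1, s2)
    h2 <- ifelse(pd, d1, d2)
  } else {
    h1 <- matrix(0L, k, m); h2 <- matrix(0L, k, m)
    for (i in seq_len(k)) {
      h1[i, ] <- .gamete_ld(pop$h1[sires[i], ], pop$h2[sires[i], ], pop$genome)
      h2[i, ] <- .gamete_ld(pop$h1[dams[i], ], pop$h2[dams[i], ], pop$genome)
    }
  }
  new_population(h1, h2, pop$genome, id = seq_len(k),
                 sire = pop$id[sires], dam = pop$id[dams],
                 generation = generation)
}

#' Mate two individuals
#'
#' Each offspring receives one independent meiosis from each parent.  Selfing
#' is only permitted through \code{\link{self_pollinate}}.
#'
#' @param pop a \code{population}.
#' @param sire,dam parent indices within \code{pop} (distinct).
#' @param n_offspring number of offspring.
#' @param mode inheritance mode, see \code{\link{meiosis}}.
#' @param seed optional integer seed.
#' @return A \code{population} of offspring.
#' @export
mate <- function(pop, sire, dam, n_offspring = 1L, mode = c("ld", "le"),
                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mode <- match.arg(mode)
  if (sire == dam) stop("selfing only permitted via self_pollinate()")
  .make_offspring(pop, rep(sire, n_offspring), rep(dam, n_offspring), mode,
                  generation = max(pop$generation[c(sire, dam)]) + 1L)
}

#' Self-pollinate a line
#'
#' Repeated self-fertilization; with \code{single_seed} (single seed descent)
#' exactly one descendant is kept at each step.  Pedigree-expected inbreeding
#' after t generations from a non-inbred founder is 1 - (1/2)^t.
#'
#' @param pop a \code{population}.
#' @param line index of the founder line within \code{pop}.
#' @param generations number of selfing generations (>= 1).
#' @param single_seed keep a single descendant per step (currently the only
#'   supported scheme).
#' @param mode inheritance mode, see \code{\link{meiosis}}.
#' @param seed optional integer seed.
#' @return A \code{population} of one inbred individual; its \code{sire}/
#'   \code{dam} record the founder id.
#' @export
self_pollinate <- function(pop, line, generations = 4L, single_seed = TRUE,
                           mode = c("ld", "le"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mode <- match.arg(mode)
  if (generations < 1L) stop("generations must be >= 1")
  if (!single_seed) stop("only single seed descent is implemented")
  h1 <- pop$h1[line, ]; h2 <- pop$h2[line, ]
  gm <- pop$genome
  for (t in seq_len(generations)) {
    if (mode == "ld") {
      g1 <- .gamete_ld(h1, h2, gm); g2 <- .gamete_ld(h1, h2, gm)
    } else {
      g1 <- .gamete_le(h1, h2); g2 <- .gamete_le(h1, h2)
    }
    h1 <- g1; h2 <- g2
  }
  new_population(matrix(h1, 1L), matrix(h2, 1L), gm, id = pop$id[line],
                 sire = pop$id[line], dam = pop$id[line],
                 generation = pop$generation[line] + 1L)
}

# self every line of a population once-through t generations (vectorised loop)
.self_all <- function(pop, generations, mode) {
  k <- n_ind(pop); m <- n_loci(pop$genome)
  h1 <- pop$h1; h2 <- pop$h2
  for (t in seq_len(generations)) {
    if (mode == "le") {
      p1 <- matrix(stats::runif(k * m) < 0.5, k, m)
      p2 <- matrix(stats::runif(k * m) < 0.5, k, m)
      g1 <- ifelse(p1, h1, h2); g2 <- ifelse(p2, h1, h2)
    } else {
      g1 <- matrix(0L, k, m); g2 <- matrix(0L, k, m)
      for (i in seq_len(k)) {
        g1[i, ] <- .gamete_ld(h1[i, ], h2[i, ], pop$genome)
        g2[i, ] <- .gamete_ld(h1[i, ], h2[i, ], pop$genome)
      }
    }
    h1 <- g1; h2 <- g2
  }
  new_population(h1, h2, pop$genome, id = pop$id, sire = pop$id,
                 dam = pop$id, generation = pop$generation + generations)
}

#' Run the random-mating breeding scheme for individual phenotypes
#'
#' Per generation, \code{n_parents} parents are sampled uniformly (no
#' selection) from the previous generation and paired at random into
#' \code{n_matings} matings of \code{offspring_per_mating} offspring each.
#' With the defaults this yields 4 generations of 750 offspring (3000
#' descendants).
#'
#' @param base base \code{population} (generation 0).
#' @param generations number of descendant generations.
#' @param n_parents parents sampled per generation.
#' @param n_matings matings per generation.
#' @param offspring_per_mating offspring per mating.
#' @param mode inheritance mode, see \code{\link{meiosis}}.
#' @param seed optional integer seed.
#' @return A \code{population} containing the base and all descendant
#'   generations (generation labels 0..\code{generations}).
#' @export
run_ipg_scheme <- function(base, generations = 4L, n_parents = 150L,
                           n_matings = 150L, offspring_per_mating = 5L,
                           mode = c("ld", "le"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mode <- match.arg(mode)
  if (n_ind(base) == 0L) stop("invalid configuration: empty base population")
  gens <- list(base)
  current <- base
  next_id <- max(base$id) + 1L
  for (g in seq_len(generations)) {
    n_avail <- n_ind(current)
    if (n_avail < 2L)
      stop("invalid configuration: fewer than 2 mating candidates")
    # the first generation may offer fewer candidates than n_parents (e.g.
    # 150 matings drawn from a base of 100); use all candidates then
    parents <- sample.int(n_avail, min(n_parents, n_avail))
    sires <- integer(n_matings); dams <- integer(n_matings)
    for (k in seq_len(n_matings)) {
      pr <- sample(parents, 2L)
      sires[k] <- pr[1L]; dams[k] <- pr[2L]
    }
    off <- .make_offspring(current,
                           rep(sires, each = offspring_per_mating),
                           rep(dams, each = offspring_per_mating),
                           mode, generation = g)
    off$id <- seq.int(next_id, length.out = n_ind(off))
    next_id <- next_id + n_ind(off)
    gens[[g + 1L]] <- off
    current <- off
  }
  bind_populations(gens)
}
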