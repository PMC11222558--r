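#' Fix a population into inbred lines by repeated selfing
#'
#' Applies \code{generations} rounds of self-fertilization with single seed
#' descent to every individual; after t = 4 rounds the pedigree-expected
#' inbreeding coefficient of a non-inbred founder is 1 - (1/2)^4 = 0.9375.
#'
#' @param pop a \code{population}.
#' @param generations selfing generations.
#' @param mode inheritance mode, see \code{\link{meiosis}}.
#' @param seed optional integer seed.
#' @return A \code{population} of inbred lines (one per input individual).
#' @export
make_inbred_lines <- function(pop, generations = 4L, mode = c("ld", "le"),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mode <- match.arg(mode)
  .self_all(pop, generations, mode)
}

# cross random pairs within a line population and return selfed seed lines:
# n_crosses random pairs, seeds_per_cross offspring each, then selfing with
# single seed descent
.line_generation <- function(lines, idx, n_crosses, seeds_per_cross,
                             selfing_generations, mode, generation) {
  if (length(idx) < 2L)
    stop("invalid configuration: need at least 2 lines to cross")
  sires <- integer(n_crosses); dams <- integer(n_crosses)
  for (k in seq_len(n_crosses)) {
    pr <- sample(idx, 2L)
    sires[k] <- pr[1L]; dams[k] <- pr[2L]
  }
  off <- .make_offspring(lines, rep(sires, each = seeds_per_cross),
                         rep(dams, each = seeds_per_cross), mode,
                         generation = generation)
  .self_all(off, selfing_generations, mode)
}

# balanced random assignment: each of n1 items used r1 times, each of n2
# items r2 times, n1*r1 == n2*r2 matings
.balanced_matings <- function(n1, r1, n2, r2) {
  if (n1 * r1 != n2 * r2)
    stop("invalid configuration: mating design counts do not balance")
  data.frame(a = sample(rep(seq_len(n1), r1)),
             b = sample(rep(seq_len(n2), r2)))
}

#' Run the three-way hybrid crop breeding scheme
#'
#' Two inbred-line populations are bred in parallel for \code{generations}
#' discrete generations: new lines arise by random within-population crosses
#' (\code{seeds_per_cross} seeds per cross) followed by
#' \code{selfing_generations} rounds of single-seed-descent selfing.  Two-way
#' hybrids are made by random mating of population-2 lines of generation t
#' with lines of generation t-1; three-way plots by random mating of
#' population-1 lines with two-way hybrids, each line contributing
#' \code{plots_per_line1} matings and each hybrid \code{plots_per_twoway},
#' one plot per mating.  All selection is random.  A base plot set (label
#' \code{generation = 0}) is built from the base lines and base two-way
#' hybrids for effect simulation.
#'
#' @param base1,base2 base \code{population}s of inbred lines on the same
#'   genome (use \code{\link{make_inbred_lines}}).
#' @param generations number of breeding generations (plots arise in
#'   generations \code{first_plot_generation}..\code{generations}).
#' @param lines1_per_gen,lines2_per_gen new lines per generation.
#' @param seeds_per_cross seeds kept per within-population cross.
#' @param selfing_generations selfing rounds per new line.
#' @param n_twoway two-way hybrids per generation.
#' @param plots_per_line1,plots_per_twoway matings per population-1 line and
#'   per two-way hybrid (their products with the line counts must agree).
#' @param base_plots_per_line1 matings per base population-1 line for the
#'   base plot set.
#' @param first_plot_generation first generation producing plots.
#' @param mode inheritance mode.
#' @param seed optional integer seed.
#' @return An object of class \code{threeway_scheme}: stacked line
#'   populations \code{lines1}, \code{lines2}, two-way pedigree
#'   \code{twoway}, plot records \code{plots} (generation, i1, i2a, i2b row
#'   indices), base plot records \code{base_plots}, and the base anchoring
#'   allele frequencies \code{anchor_q1}, \code{anchor_q2}.
#' @export
run_threeway_scheme <- function(base1, base2, generations = 4L,
                                lines1_per_gen = 200L, lines2_per_gen = 100L,
                                seeds_per_cross = 5L,
                                selfing_generations = 4L, n_twoway = 100L,
                                plots_per_line1 = 5L, plots_per_twoway = 10L,
                                base_plots_per_line1 = 5L,
                                first_plot_generation = 2L,
                                mode = c("ld", "le"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mode <- match.arg(mode)
  if (lines1_per_gen %% seeds_per_cross != 0L ||
      lines2_per_gen %% seeds_per_cross != 0L)
    stop("invalid configuration: lines per generation must be a multiple ",
         "of seeds_per_cross")
  anchor_q1 <- allele_frequencies(base1)$q
  anchor_q2 <- allele_frequencies(base2)$q

  l1 <- list(base1); l2 <- list(base2)
  idx1 <- list(seq_len(n_ind(base1)))       # row ranges per generation
  idx2 <- list(seq_len(n_ind(base2)))
  off1 <- n_ind(base1); off2 <- n_ind(base2)
  for (t in seq_len(generations)) {
    stack1 <- bind_populations(l1)
    stack2 <- bind_populations(l2)
    g1 <- .line_generation(stack1, idx1[[t]],
                           lines1_per_gen %/% seeds_per_cross,
                           seeds_per_cross, selfing_generations, mode, t)
    g2 <- .line_generation(stack2, idx2[[t]],
                           lines2_per_gen %/% seeds_per_cross,
                           seeds_per_cross, selfing_generations, mode, t)
    g1$generation[] <- t; g2$generation[] <- t
    l1[[t + 1L]] <- g1; l2[[t + 1L]] <- g2
    idx1[[t + 1L]] <- off1 + seq_len(n_ind(g1)); off1 <- off1 + n_ind(g1)
    idx2[[t + 1L]] <- off2 + seq_len(n_ind(g2)); off2 <- off2 + n_ind(g2)
  }
  lines1 <- bind_populations(l1); lines1$id <- seq_len(n_ind(lines1))
  lines2 <- bind_populations(l2); lines2$id <- seq_len(n_ind(lines2))

  # base two-way hybrids: pair base-2 lines with equal contribution (each
  # line in 2 of the 2 * n_twoway parent slots), avoiding self-pairs
  tw_base <- .twoway_pairs(idx2[[1L]], idx2[[1L]], n_twoway)
  twoway <- data.frame(generation = 0L, a = tw_base$a, b = tw_base$b)
  plots <- list()
  bm <- .balanced_matings(length(idx1[[1L]]), base_plots_per_line1,
                          n_twoway,
                          (length(idx1[[1L]]) * base_plots_per_line1) %/%
                            n_twoway)
  base_plots <- data.frame(generation = 0L,
                           i1 = idx1[[1L]][bm$a],
                           i2a = twoway$a[bm$b], i2b = twoway$b[bm$b])
  plot_gens <- if (generations >= first_plot_generation)
    seq.int(first_plot_generation, generations) else integer(0)
  for (t in plot_gens) {
    tw <- .twoway_pairs(idx2[[t + 1L]], idx2[[t]], n_twoway)
    twoway <- rbind(twoway, data.frame(generation = t, a = tw$a, b = tw$b))
    tw_rows <- which(twoway$generation == t)
    bm <- .balanced_matings(length(idx1[[t + 1L]]), plots_per_line1,
                            n_twoway, plots_per_twoway)
    plots[[length(plots) + 1L]] <-
      data.frame(generation = t, i1 = idx1[[t + 1L]][bm$a],
                 i2a = twoway$a[tw_rows[bm$b]],
                 i2b = twoway$b[tw_rows[bm$b]])
  }
  structure(list(lines1 = lines1, lines2 = lines2, twoway = twoway,
                 plots = if (length(plots)) do.call(rbind, plots),
                 base_plots = base_plots,
                 anchor_q1 = anchor_q1, anchor_q2 = anchor_q2,
                 line1_gen_rows = idx1, line2_gen_rows = idx2),
            class = "threeway_scheme")
}

# n_twoway hybrid matings between two line sets (lines used as equally as
# possible); identical-parent pairs (possible when the sets overlap) are
# resolved by swapping the second parent with another mating's
.twoway_pairs <- function(rows_a, rows_b, n_twoway) {
  ra <- sample(rep(rows_a, length.out = n_twoway))
  rb <- sample(rep(rows_b, length.out = n_twoway))
  for (i in which(ra == rb)) {
    j <- which(rb != ra[i] & ra != rb[i])
    if (length(j)) {
      j <- j[[sample.int(length(j), 1L)]]
      tmp <- rb[i]; rb[i] <- rb[j]; rb[j] <- tmp
    }
  }
  list(a = ra, b = rb)
}

#' @export
print.threeway_scheme <- function(x, ...) {
  cat("Three-way hybrid breeding scheme:\n")
  cat("  population-1 lines:", n_ind(x$lines1), " population-2 lines:",
      n_ind(x$lines2), "\n")
  cat("  two-way hybrids:", nrow(x$twoway), " plots:", nrow(x$plots),
      "(+", nrow(x$base_plots), "base plots)\n")
  invisible(x)
}
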