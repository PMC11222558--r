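test_that("genome map enforces its invariants", {
  expect_s3_class(genome_map(c(1, 1, 2), c(1, 2, 1)), "genome_map")
  expect_error(genome_map(c(1, 1), c(2, 2)), "strictly increasing")
  expect_error(genome_map(c(1, 1), c(1, 2), pairs = cbind(1, 1)), "distinct")
  expect_error(genome_map(c(1, 1, 1), c(1, 2, 3),
                          pairs = rbind(c(1, 2), c(1, 3))),
               "at most one pair")
  gm <- le_genome(10)
  expect_length(gm$qtl, 10)
  expect_equal(sort(as.vector(gm$pairs)), 1:10)  # every QTL in one pair
})

test_that("LE base sampling respects target frequencies", {
  gm <- le_genome(6, paired = FALSE)
  expect_error(sample_base_le(1, gm), "invalid configuration")
  expect_error(sample_base_le(10, gm, freq_range = c(0, 0.5)),
               "invalid configuration")
  set.seed(1)
  # degenerate uniform: all target frequencies 0.5
  pop <- sample_base_le(4000, gm, freq_range = c(0.5, 0.5))
  q <- allele_frequencies(pop)$q
  expect_true(all(abs(q - 0.5) < 4 * sqrt(0.25 / 8000)))
  # fixed q = 0.3: empirical frequency within 4 binomial SE
  pop2 <- sample_base_le(10000, gm, freq_range = c(0.3, 0.3))
  q2 <- allele_frequencies(pop2)$q
  expect_true(all(abs(q2 - 0.3) < 4 * sqrt(0.3 * 0.7 / 20000)))
  # LE: pairwise dosage correlation ~ 0
  d <- dosage(pop2)
  cors <- cor(d)[upper.tri(diag(6))]
  expect_true(all(abs(cors) < 4 / sqrt(10000)))
})

test_that("allele and genotype frequencies are consistent", {
  pop <- pop_from_dosage(rbind(c(0, 2), c(0, 2)))           # all BB / all bb
  af <- allele_frequencies(pop)
  expect_equal(af$q, c(0, 1))
  expect_equal(af$geno[1, ], c(BB = 1, Bb = 0, bb = 0))
  # 50/50 BB and bb: q = 0.5 with no heterozygotes (non-HWE)
  pop2 <- pop_from_dosage(cbind(c(0, 2, 0, 2)))
  af2 <- allele_frequencies(pop2)
  expect_equal(af2$q, 0.5)
  expect_equal(af2$geno[1, ], c(BB = 0.5, Bb = 0, bb = 0.5))
  expect_error(allele_frequencies(pop2, integer(0)), "empty")
  # HWE population at q = 0.5 has about half heterozygotes
  set.seed(2)
  pop3 <- sample_base_le(5000, le_genome(2, paired = FALSE),
                         freq_range = c(0.5, 0.5))
  expect_true(all(abs(allele_frequencies(pop3)$geno[, "Bb"] - 0.5) < 0.03))
})

test_that("meiosis follows the Haldane model and Mendelian segregation", {
  gm <- genome_map(c(1, 1), c(0, 10), chr_length = 10)
  # doubly heterozygous parent in coupling
  par <- noiasim:::new_population(h1 = matrix(c(1L, 1L), 1),
                                  h2 = matrix(c(0L, 0L), 1), genome = gm)
  set.seed(3)
  n <- 25000
  rec <- 0
  for (i in seq_len(n)) {
    g <- meiosis(par, 1, mode = "ld")
    rec <- rec + (g[1] != g[2])
  }
  r_expect <- 0.5 * (1 - exp(-0.2))   # Haldane map function, 10 cM
  expect_lt(abs(rec / n - r_expect),
            4 * sqrt(r_expect * (1 - r_expect) / n))
  # fully homozygous parent: gamete equals either haplotype exactly
  hom <- pop_from_dosage(matrix(c(0L, 2L), 1))
  expect_equal(meiosis(hom, 1, mode = "ld"), c(0L, 1L))
  expect_equal(meiosis(hom, 1, mode = "le"), c(0L, 1L))
  # LE mode transmits the b allele of a heterozygote with frequency 1/2
  het <- noiasim:::new_population(h1 = matrix(1L, 1), h2 = matrix(0L, 1),
                                  genome = le_genome(1, paired = FALSE))
  b <- mean(replicate(20000, meiosis(het, 1, mode = "le")))
  expect_lt(abs(b - 0.5), 4 * sqrt(0.25 / 20000))
})

test_that("mating produces Mendelian offspring with recorded pedigree", {
  gm <- le_genome(3, paired = FALSE)
  pop <- pop_from_dosage(rbind(c(0, 0, 1), c(2, 2, 1)), gm)
  off <- mate(pop, 1, 2, n_offspring = 50, mode = "le")
  d <- dosage(off)
  expect_true(all(d[, 1:2] == 1L))   # opposite homozygotes -> heterozygous
  expect_equal(n_ind(off), 50)
  expect_true(all(off$sire == 1L & off$dam == 2L))
  expect_error(mate(pop, 1, 1), "self_pollinate")
  # offspring dosage mean tends to the midparent mean
  set.seed(4)
  off2 <- mate(pop, 1, 2, n_offspring = 8000, mode = "le")
  expect_lt(abs(mean(dosage(off2)[, 3]) - 1), 4 * sqrt(0.5 / 8000))
  # dosage conservation: no allele appears that no parent carries
  expect_true(all(dosage(off2)[, 1] <= 2) && all(d >= 0))
})

test_that("selfing halves heterozygosity per generation", {
  expect_equal(1 - 0.5^4, 0.9375)   # pedigree-expected F after 4 selfings
  gm <- le_genome(400, paired = FALSE)
  set.seed(5)
  founder <- pop_from_dosage(matrix(1L, 1, 400), gm)  # all heterozygous
  lines <- replicate(250, {
    l <- self_pollinate(founder, 1, generations = 4, mode = "le")
    mean(dosage(l) == 1L)
  })
  expect_lt(abs(mean(lines) - 0.5^4), 0.01)
  # one generation: half the loci stay heterozygous in expectation
  l1 <- replicate(200, mean(dosage(
    self_pollinate(founder, 1, generations = 1, mode = "le")) == 1L))
  expect_lt(abs(mean(l1) - 0.5), 0.02)
  expect_error(self_pollinate(founder, 1, generations = 0), ">= 1")
})

test_that("the random-mating scheme reproduces the replication counts", {
  gm <- le_genome(50, paired = FALSE)
  set.seed(6)
  base <- sample_base_le(30, gm)
  pop <- run_ipg_scheme(base, generations = 1, n_parents = 10,
                        n_matings = 150, offspring_per_mating = 5,
                        mode = "le")
  expect_equal(sum(pop$generation == 1), 750)  # 150 matings x 5 offspring
  pop2 <- run_ipg_scheme(base, generations = 1, n_parents = 2,
                         n_matings = 1, offspring_per_mating = 1,
                         mode = "le")
  expect_equal(n_ind(pop2), n_ind(base) + 1)
  # neutral drift: mean frequency change centred on zero
  set.seed(7)
  basep <- sample_base_le(200, gm, freq_range = c(0.4, 0.6))
  popd <- run_ipg_scheme(basep, generations = 4, n_parents = 100,
                         n_matings = 100, offspring_per_mating = 3,
                         mode = "le")
  dq <- allele_frequencies(popd, popd$generation == 4)$q -
    allele_frequencies(popd, popd$generation == 0)$q
  expect_lt(abs(mean(dq)), 3 * sd(dq) / sqrt(length(dq)))
})

test_that("Wright-Fisher history produces LD that decays with distance", {
  # zero historical generations: all frequencies exactly 0.5
  gm0 <- genome_map(rep(1, 4), 1:4, chr_length = 200)
  pop0 <- simulate_ld_base(40, gm0, historical_generations = 0)
  expect_true(all(allele_frequencies(pop0)$q == 0.5))
  # tightly linked loci end up with higher r^2 than distant loci
  gm <- genome_map(rep(1, 4), c(10, 10.01, 100, 199.9), chr_length = 200)
  set.seed(8)
  r2 <- replicate(24, {
    p <- simulate_ld_base(50, gm, historical_generations = 40,
                          historical_n = 40)
    d <- dosage(p)
    ok <- apply(d, 2, sd) > 0
    c(close = if (ok[1] && ok[2]) cor(d[, 1], d[, 2])^2 else NA,
      far = if (ok[1] && ok[4]) cor(d[, 1], d[, 4])^2 else NA)
  })
  expect_gt(mean(r2["close", ], na.rm = TRUE),
            mean(r2["far", ], na.rm = TRUE))
})

test_that("QTL are drawn from segregating loci and the map can be reduced", {
  gm <- genome_map(rep(1, 30), 1:30, chr_length = 100)
  set.seed(9)
  pop <- simulate_ld_base(50, gm, historical_generations = 60,
                          historical_n = 30)
  expect_error(draw_qtl(pop, 30, maf_min = 0.05), "insufficient segregation")
  pop <- draw_qtl(pop, 10, maf_min = 0.05)
  maf <- pmin(allele_frequencies(pop)$q, 1 - allele_frequencies(pop)$q)
  expect_true(all(maf[pop$genome$qtl] >= 0.05))
  red <- keep_qtl(pop)
  expect_equal(n_loci(red$genome), 10)
  expect_equal(dosage(red), dosage(pop)[, pop$genome$qtl])
  expect_equal(sort(as.vector(red$genome$pairs)), 1:10)
})
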