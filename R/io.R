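#' Write and read genotype tables
#'
#' Tab-separated genotype matrix: one row per individual with id, generation,
#' sire, dam followed by per-locus b-allele dosages (0/1/2).  Haplotype phase
#' is not preserved by this format.
#'
#' @param pop a \code{population}.
#' @param path output file.
#' @export
write_genotypes <- function(pop, path) {
  d <- dosage(pop)
  colnames(d) <- paste0("L", seq_len(ncol(d)))
  df <- data.frame(id = pop$id, generation = pop$generation,
                   sire = pop$sire, dam = pop$dam, d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @param genome a \code{genome_map} for the loci in the file.
#' @return \code{read_genotypes}: a \code{population} whose haplotypes split
#'   the dosage arbitrarily (heterozygotes phased at random coin order is
#'   avoided by a deterministic split: allele b on haplotype 1).
#' @export
read_genotypes <- function(path, genome) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  meta <- c("id", "generation", "sire", "dam")
  if (!all(meta %in% names(df)))
    stop("malformed genotype file: missing columns ",
         paste(setdiff(meta, names(df)), collapse = ", "))
  d <- as.matrix(df[setdiff(names(df), meta)])
  if (ncol(d) != n_loci(genome))
    stop("genotype file has ", ncol(d), " loci; genome has ",
         n_loci(genome))
  if (any(!d %in% 0:2)) stop("malformed genotype file: dosages must be 0/1/2")
  h1 <- pmin(d, 1L)
  h2 <- pmax(d - 1L, 0L)
  new_population(h1, h2, genome, id = df$id, sire = df$sire, dam = df$dam,
                 generation = df$generation)
}

#' Write and read a genome map
#' @param genome a \code{genome_map}.
#' @param path file path.
#' @export
write_genome <- function(genome, path) {
  pair_id <- rep(NA_integer_, n_loci(genome))
  if (!is.null(genome$pairs)) {
    pair_id[genome$pairs[, 1L]] <- seq_len(nrow(genome$pairs))
    pair_id[genome$pairs[, 2L]] <- seq_len(nrow(genome$pairs))
  }
  df <- data.frame(chr = genome$chr, locus = seq_len(n_loci(genome)),
                   pos_cM = genome$pos,
                   is_qtl = seq_len(n_loci(genome)) %in% genome$qtl,
                   pair_id = pair_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  pairs <- NULL
  if (any(!is.na(df$pair_id))) {
    sp <- split(df$locus[!is.na(df$pair_id)], df$pair_id[!is.na(df$pair_id)])
    pairs <- do.call(rbind, sp)
  }
  genome_map(chr = df$chr, pos = df$pos_cM, qtl = df$locus[df$is_qtl],
             pairs = pairs)
}

#' Write and read effect tables
#'
#' QTL effects as TSV: locus, a, d, dd, pair id and aa (pair effect repeated
#' on both members); optional statistical columns when a statistical-effects
#' object is attached.
#'
#' @param fx a \code{functional_effects} object.
#' @param path file path.
#' @export
write_effects <- function(fx, path) {
  pm <- .partner_map(fx)
  aa_col <- rep(NA_real_, length(fx$a))
  if (length(fx$aa)) {
    ok <- !is.na(pm$pair_id)
    aa_col[ok] <- fx$aa[pm$pair_id[ok]]
  }
  df <- data.frame(locus = fx$qtl, a = fx$a, d = fx$d,
                   dd = if (is.null(fx$dd)) NA_real_ else fx$dd,
                   pair_id = pm$pair_id, aa = aa_col)
  sx <- attr(fx, "statistical")
  if (inherits(sx, "statistical_effects_ppg")) {
    df$alpha1 <- sx$alpha1; df$alpha2 <- sx$alpha2; df$delta3 <- sx$delta3
    df$anchor_q1 <- sx$anchor$q1[fx$qtl]
    df$anchor_q2 <- sx$anchor$q2[fx$qtl]
  } else if (!is.null(sx)) {
    df$alpha <- sx$alpha; df$delta <- sx$delta
    df$anchor_q <- sx$anchor$q[fx$qtl]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_effects
#' @param genome the \code{genome_map} the effects belong to.
#' @export
read_effects <- function(path, genome) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  if (!all(c("locus", "a", "d") %in% names(df)))
    stop("malformed effects file")
  aa <- numeric(0)
  if (!is.null(genome$pairs)) {
    first <- match(genome$pairs[, 1L], df$locus)
    aa <- df$aa[first]
  }
  functional_effects(a = df$a, d = df$d, aa = aa, genome = genome,
                     dd = if (all(is.na(df$dd))) NULL else df$dd)
}

#' Write a phenotype table
#' @param ph a \code{phenotype_table}.
#' @param path file path.
#' @export
write_phenotypes <- function(ph, path) {
  utils::write.table(as.data.frame(ph), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Write a variance report
#' @param x a \code{variance_components} object or a list of them.
#' @param path file path.
#' @param label optional label column (e.g. generation subset).
#' @export
write_variance_report <- function(x, path, label = NA_character_) {
  if (inherits(x, "variance_components")) x <- list(x)
  df <- do.call(rbind, lapply(x, as.data.frame))
  df$label <- label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export genotypes as VCF
#'
#' Minimal VCF 4.2 export: loci become pseudo-markers CHROM/POS with the
#' genetic-map position stored in INFO (CM=), REF=A (allele B) and ALT=T
#' (allele b), and unphased diploid GT built from the dosage (dosage 2 ->
#' "1/1").
#'
#' @param pop a \code{population}.
#' @param path output file (plain text).
#' @export
write_vcf <- function(pop, path) {
  gm <- pop$genome
  d <- t(dosage(pop))        # loci x individuals
  gt <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow(d), ncol(d))
  ids <- paste0("ind", pop$id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=noiasim",
               "##INFO=<ID=CM,Number=1,Type=Float,Description=\"Map position in cM\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  pos_int <- as.integer(round(gm$pos * 1e4)) + 1L  # unique integer positions
  body <- paste(gm$chr, pos_int, paste0("locus", seq_len(n_loci(gm))),
                "A", "T", ".", ".", sprintf("CM=%.6f", gm$pos), "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read an experiment configuration from a DCF file
#'
#' Plain-text configuration: a Debian-control-format file with fields
#' \code{example}, \code{method}, \code{mode}, the variance targets
#' (\code{additive}, \code{dominance}, \code{epistasis}, \code{residual}, or
#' the pPG names), replicate counts and optional genome/scheme overrides
#' given as \code{name=value} pairs separated by commas.
#'
#' @param path configuration file.
#' @return An \code{\link{experiment_config}}.
#' @export
read_experiment_config <- function(path) {
  dcf <- read.dcf(path)
  fld <- function(name, default = NULL) {
    if (name %in% colnames(dcf)) dcf[1L, name] else default
  }
  num <- function(name, default = NULL) {
    v <- fld(name); if (is.null(v)) default else as.numeric(v)
  }
  example <- as.integer(num("example"))
  targets <- if (!is.null(fld("additive1")))
    variance_targets_ppg(num("additive1"), num("additive2"),
                         num("dominance3"), num("epistasis3"),
                         num("residual", 0))
  else variance_targets(num("additive"), num("dominance"),
                        num("epistasis"), num("residual", 0))
  parse_kv <- function(name) {
    v <- fld(name)
    if (is.null(v)) return(list())
    parts <- strsplit(strsplit(v, ",")[[1L]], "=")
    vals <- lapply(parts, function(p) as.numeric(trimws(p[2L])))
    names(vals) <- vapply(parts, function(p) trimws(p[1L]), "")
    vals
  }
  experiment_config(example = example, targets = targets,
                    method = fld("method", "ss_noia"),
                    mode = fld("mode", "by_locus"),
                    n_effect_reps = as.integer(num("n_effect_reps", 10)),
                    n_scheme_reps = as.integer(num("n_scheme_reps", 2)),
                    genome = parse_kv("genome"), scheme = parse_kv("scheme"),
                    seed = as.integer(num("seed", 1)))
}

#' Write and read genomic relationship matrices
#'
#' Square matrix TSV with an id header row and an id first column.
#'
#' @param G symmetric relationship matrix.
#' @param path file path.
#' @param ids row/column identifiers; defaults to existing dimnames or 1..n.
#' @export
write_grm <- function(G, path, ids = NULL) {
  if (is.null(ids)) ids <- rownames(G)
  if (is.null(ids)) ids <- paste0("id", seq_len(nrow(G)))
  df <- data.frame(id = ids, G, check.names = FALSE)
  colnames(df) <- c("id", ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  G <- as.matrix(df[, -1L, drop = FALSE])
  rownames(G) <- colnames(G) <- df$id
  G
}

#' Plain-list report of a REML fit
#'
#' Collects estimates, standard errors, the convergence trajectory and the
#' log-likelihood into a plain list that serializes directly (e.g. with
#' \code{jsonlite::write_json}).
#'
#' @param fit a \code{reml_fit}.
#' @return named list.
#' @export
reml_report <- function(fit) {
  list(estimates = as.list(fit$estimates), se = as.list(fit$se),
       logLik = fit$logLik, converged = fit$converged,
       iterations = length(fit$trajectory) - 1L,
       trajectory = fit$trajectory, n = fit$n)
}
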