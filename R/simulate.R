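#' Causal locus description
#'
#' The single recessive mutation whose position the pipeline tries to
#' recover. The default mirrors a G-to-A EMS transition at position
#' 14,682,808 on the second chromosome, i.e. a classic stop-gain candidate
#' in a brittle-culm style mapping experiment.
#'
#' @param chrom Chromosome id.
#' @param pos 1-based physical position.
#' @param ref,alt Single-base reference and mutant alleles (must differ).
#' @return A list of class `causal_locus`.
#' @export
causal_locus <- function(chrom = "chr2", pos = 14682808, ref = "G", alt = "A") {
  bases <- c("A", "C", "G", "T")
  if (!ref %in% bases || !alt %in% bases) stop("alleles must be one of A, C, G, T")
  if (ref == alt) stop("ref and alt alleles must differ")
  structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         ref = ref, alt = alt, inheritance = "recessive"),
    class = "causal_locus"
  )
}

#' EMS mutation model
#'
#' Background (non-causal) SNP density and spectrum. EMS predominantly
#' alkylates guanine, producing G:C-to-A:T transitions; the genome-wide
#' share of transitions is tunable because reported spectra vary by dose
#' and species.
#'
#' @param snp_rate_per_Mb Expected background SNPs per megabase (>= 0).
#' @param transition_fraction Fraction of background SNPs that are G>A or
#'   C>T transitions, in `[0, 1]`.
#' @return A list of class `mutation_model`.
#' @export
mutation_model <- function(snp_rate_per_Mb = 10, transition_fraction = 0.9) {
  if (!is.finite(snp_rate_per_Mb) || snp_rate_per_Mb < 0) {
    stop("snp_rate_per_Mb must be finite and >= 0")
  }
  if (!is.finite(transition_fraction) || transition_fraction < 0 ||
      transition_fraction > 1) {
    stop("transition_fraction must be in [0, 1]")
  }
  structure(
    list(snp_rate_per_Mb = snp_rate_per_Mb,
         transition_fraction = transition_fraction),
    class = "mutation_model"
  )
}

#' Bulk design
#'
#' Sizes of the two phenotype-selected bulks; defaults to 20 mutant-phenotype
#' and 20 wild-phenotype F2 plants.
#'
#' @param n_mutant_bulk,n_wild_bulk Positive bulk sizes.
#' @return A list of class `bulk_design`.
#' @export
bulk_design <- function(n_mutant_bulk = 20, n_wild_bulk = 20) {
  if (n_mutant_bulk < 1 || n_wild_bulk < 1) stop("bulk sizes must be >= 1")
  structure(
    list(n_mutant_bulk = as.integer(n_mutant_bulk),
         n_wild_bulk = as.integer(n_wild_bulk)),
    class = "bulk_design"
  )
}

#' Sequencing depth model
#'
#' Per-site total depth is Poisson(`mean_depth`) per bulk; alt reads are
#' binomial with success probability `p (1 - e) + (1 - p) e` where `p` is
#' the bulk's true mutant-allele frequency and `e` the base error rate.
#'
#' @param mean_depth Mean per-site depth per bulk (> 0).
#' @param error_rate Per-base error rate in `[0, 0.5)`; default 0.005,
#'   a typical short-read post-filter value.
#' @return A list of class `depth_model`.
#' @export
depth_model <- function(mean_depth = 30, error_rate = 0.005) {
  if (!is.finite(mean_depth) || mean_depth <= 0) stop("mean_depth must be > 0")
  if (!is.finite(error_rate) || error_rate < 0 || error_rate >= 0.5) {
    stop("error_rate must be in [0, 0.5)")
  }
  structure(
    list(mean_depth = mean_depth, error_rate = error_rate),
    class = "depth_model"
  )
}

# ordered ref>alt substitution pairs that are NOT the EMS transitions G>A, C>T
.non_ems_pairs <- local({
  bases <- c("A", "C", "G", "T")
  p <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  p <- p[p$ref != p$alt, ]
  p[!(p$ref == "G" & p$alt == "A") & !(p$ref == "C" & p$alt == "T"), ]
})

#' Simulate parental variant sites
#'
#' Places the causal mutation plus a Poisson number of EMS-style background
#' SNPs per chromosome, with a configurable fraction of G>A / C>T
#' transitions. Positions are unique and sorted within each chromosome.
#'
#' @param genome A [genome_spec()].
#' @param causal A [causal_locus()] lying inside `genome`.
#' @param model A [mutation_model()].
#' @param seed Optional integer seed.
#' @return Data frame with columns `chrom`, `pos`, `ref`, `alt`, `causal`.
#' @export
simulate_parental_variants <- function(genome, causal, model = mutation_model(),
                                       seed = NULL) {
  stopifnot(inherits(genome, "genome_spec"), inherits(causal, "causal_locus"),
            inherits(model, "mutation_model"))
  if (!causal$chrom %in% genome$chrom_id) {
    stop("causal locus chromosome not in genome")
  }
  if (causal$pos < 1 || causal$pos > chrom_length(genome, causal$chrom)) {
    stop("causal locus position outside chromosome")
  }
  if (!is.null(seed)) set.seed(seed)

  per_chrom <- lapply(seq_len(nrow(genome)), function(i) {
    n_bg <- stats::rpois(1, genome$length_bp[i] / 1e6 * model$snp_rate_per_Mb)
    if (n_bg == 0) return(NULL)
    pos <- sample.int(genome$length_bp[i], n_bg)
    pos <- pos[!(genome$chrom_id[i] == causal$chrom & pos == causal$pos)]
    if (length(pos) == 0) return(NULL)
    n <- length(pos)
    is_ts <- stats::runif(n) < model$transition_fraction
    ref <- alt <- character(n)
    ref[is_ts] <- sample(c("G", "C"), sum(is_ts), replace = TRUE)
    alt[is_ts] <- ifelse(ref[is_ts] == "G", "A", "T")
    if (any(!is_ts)) {
      k <- sample.int(nrow(.non_ems_pairs), sum(!is_ts), replace = TRUE)
      ref[!is_ts] <- .non_ems_pairs$ref[k]
      alt[!is_ts] <- .non_ems_pairs$alt[k]
    }
    data.frame(chrom = genome$chrom_id[i], pos = pos, ref = ref, alt = alt,
               causal = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(per_chrom, list(
    data.frame(chrom = causal$chrom, pos = causal$pos, ref = causal$ref,
               alt = causal$alt, causal = TRUE, stringsAsFactors = FALSE)
  )))
  out <- out[order(match(out$chrom, genome$chrom_id), out$pos), ]
  rownames(out) <- NULL
  out
}

#' Simulate an F2 population
#'
#' Each individual is the union of two independent gametes from a uniformly
#' heterozygous F1. Gametes are generated under the Haldane model (Poisson
#' crossovers, no interference) using the equivalent Markov construction:
#' the allele at the first locus of a chromosome is Bernoulli(1/2) and
#' switches between adjacent loci with probability equal to their Haldane
#' recombination fraction. Single-locus genotype frequencies converge to
#' 1:2:1.
#'
#' @param variants Variant table from [simulate_parental_variants()] (every
#'   variant must lie on a chromosome of `genome`).
#' @param genome A [genome_spec()].
#' @param n Number of F2 individuals (>= 1).
#' @param seed Optional integer seed.
#' @param keep_gametes If `TRUE`, store the two gamete matrices (useful for
#'   inspecting recombinant fractions).
#' @return A list of class `f2_population` with elements `genotypes`
#'   (n x n_variants integer matrix of mutant-allele copies, columns named
#'   `chrom:pos`), `variants` and `genome`.
#' @export
simulate_f2_population <- function(variants, genome, n, seed = NULL,
                                   keep_gametes = FALSE) {
  stopifnot(inherits(genome, "genome_spec"))
  if (n < 1) stop("n must be >= 1")
  if (!all(variants$chrom %in% genome$chrom_id)) {
    stop("variant without a genetic position: chromosome not in genome")
  }
  if (!is.null(seed)) set.seed(seed)
  variants <- variants[order(match(variants$chrom, genome$chrom_id), variants$pos), ]
  cm <- genetic_position(genome, variants$chrom, variants$pos)

  n_gam <- 2L * n
  gam <- matrix(0L, nrow = n_gam, ncol = nrow(variants))
  for (chr in unique(variants$chrom)) {
    j <- which(variants$chrom == chr)
    a <- stats::rbinom(n_gam, 1L, 0.5)
    gam[, j[1]] <- a
    if (length(j) > 1) {
      r <- haldane(diff(cm[j]))
      for (k in seq_along(r)) {
        a <- (a + stats::rbinom(n_gam, 1L, r[k])) %% 2L
        gam[, j[k + 1]] <- a
      }
    }
  }
  g1 <- gam[seq_len(n), , drop = FALSE]
  g2 <- gam[n + seq_len(n), , drop = FALSE]
  geno <- g1 + g2
  colnames(geno) <- paste(variants$chrom, variants$pos, sep = ":")
  pop <- structure(
    list(genotypes = geno, variants = variants, genome = genome),
    class = "f2_population"
  )
  if (keep_gametes) pop$gametes <- list(g1, g2)
  pop
}

# column index of the causal locus in a population's genotype matrix
.causal_col <- function(pop, causal) {
  key <- paste(causal$chrom, causal$pos, sep = ":")
  j <- match(key, colnames(pop$genotypes))
  if (is.na(j)) stop("causal locus not among the population's variants")
  j
}

#' Assign phenotypes from a recessive causal locus
#'
#' The mutant phenotype appears iff the individual carries two copies of the
#' mutant allele at the causal locus. An optional misclassification rate
#' models bulking errors (default 0, error-free phenotyping).
#'
#' @param pop An [simulate_f2_population()] result.
#' @param causal A [causal_locus()] present among the population's variants.
#' @param misclassification_rate Probability that a phenotype is flipped.
#' @param seed Optional integer seed (used only when flipping).
#' @return `pop` with elements `phenotype` (character, `"mutant"`/`"wild"`)
#'   and `causal` added.
#' @export
assign_phenotypes <- function(pop, causal, misclassification_rate = 0,
                              seed = NULL) {
  stopifnot(inherits(pop, "f2_population"), inherits(causal, "causal_locus"))
  j <- .causal_col(pop, causal)
  phen <- ifelse(pop$genotypes[, j] == 2L, "mutant", "wild")
  if (misclassification_rate > 0) {
    if (!is.null(seed)) set.seed(seed)
    flip <- stats::runif(length(phen)) < misclassification_rate
    phen[flip] <- ifelse(phen[flip] == "mutant", "wild", "mutant")
  }
  pop$phenotype <- phen
  pop$causal <- causal
  pop
}

#' Form phenotype-selected bulks
#'
#' Draws the requested numbers of mutant- and wild-phenotype individuals,
#' without replacement within each phenotype class.
#'
#' @param pop A phenotyped population from [assign_phenotypes()].
#' @param design A [bulk_design()].
#' @param seed Optional integer seed.
#' @return A list of class `bulks` with integer index vectors `mutant` and
#'   `wild` (disjoint) and the `design`.
#' @export
form_bulks <- function(pop, design = bulk_design(), seed = NULL) {
  stopifnot(inherits(pop, "f2_population"), inherits(design, "bulk_design"))
  if (is.null(pop$phenotype)) stop("population has no phenotypes; run assign_phenotypes() first")
  if (!is.null(seed)) set.seed(seed)
  mut_idx <- which(pop$phenotype == "mutant")
  wt_idx <- which(pop$phenotype == "wild")
  if (length(mut_idx) < design$n_mutant_bulk) {
    stop(sprintf("only %d mutant-phenotype individuals available; %d requested",
                 length(mut_idx), design$n_mutant_bulk))
  }
  if (length(wt_idx) < design$n_wild_bulk) {
    stop(sprintf("only %d wild-phenotype individuals available; %d requested",
                 length(wt_idx), design$n_wild_bulk))
  }
  structure(
    list(mutant = sort(sample(mut_idx, design$n_mutant_bulk)),
         wild = sort(sample(wt_idx, design$n_wild_bulk)),
         design = design),
    class = "bulks"
  )
}

#' True mutant-allele frequency of a bulk at every variant
#'
#' @param pop A population.
#' @param idx Integer indices of the bulk members.
#' @return Numeric vector over variants (mean genotype / 2).
#' @export
bulk_allele_freq <- function(pop, idx) {
  colMeans(pop$genotypes[idx, , drop = FALSE]) / 2
}

#' Simulate bulked short-read allele counts
#'
#' For each variant site and bulk, total depth is drawn Poisson and alt
#' reads binomial with probability `p (1 - e) + (1 - p) e`, where `p` is the
#' bulk's true mutant-allele frequency at the site.
#'
#' @param pop A phenotyped population (with `causal`).
#' @param bulks A [form_bulks()] result.
#' @param depth A [depth_model()].
#' @param seed Optional integer seed.
#' @return A list of class `mutmap_dataset` with elements `counts` (a
#'   site-counts data frame: `chrom`, `pos`, `ref`, `alt`, `mut_ref`,
#'   `mut_alt`, `wt_ref`, `wt_alt`), `truth` (the causal locus) and
#'   `phenotype_counts`.
#' @export
simulate_read_counts <- function(pop, bulks, depth = depth_model(), seed = NULL) {
  stopifnot(inherits(pop, "f2_population"), inherits(bulks, "bulks"),
            inherits(depth, "depth_model"))
  if (!is.null(seed)) set.seed(seed)
  v <- pop$variants
  nv <- nrow(v)
  e <- depth$error_rate
  draw <- function(idx) {
    p <- bulk_allele_freq(pop, idx)
    d <- stats::rpois(nv, depth$mean_depth)
    alt <- stats::rbinom(nv, d, p * (1 - e) + (1 - p) * e)
    cbind(ref = d - alt, alt = alt)
  }
  m <- draw(bulks$mutant)
  w <- draw(bulks$wild)
  counts <- data.frame(
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    mut_ref = m[, "ref"], mut_alt = m[, "alt"],
    wt_ref = w[, "ref"], wt_alt = w[, "alt"],
    stringsAsFactors = FALSE
  )
  structure(
    list(counts = counts, truth = pop$causal,
         phenotype_counts = table(pop$phenotype),
         design = bulks$design, depth = depth),
    class = "mutmap_dataset"
  )
}

#' Simulate a complete mapping experiment
#'
#' Convenience wrapper running variants -> F2 population -> phenotypes ->
#' bulks -> read counts from a single seed.
#'
#' @param genome A [genome_spec()]; default [default_genome()].
#' @param causal A [causal_locus()].
#' @param model A [mutation_model()].
#' @param n_f2 F2 population size (default 200, comfortably enough
#'   mutant-phenotype plants for a 20-plant bulk).
#' @param design A [bulk_design()].
#' @param depth A [depth_model()].
#' @param misclassification_rate Phenotyping error rate (default 0).
#' @param seed Integer seed governing every random draw.
#' @return A `mutmap_dataset` (see [simulate_read_counts()]); the population
#'   is attached as attribute `"population"`.
#' @export
simulate_mapping_experiment <- function(genome = default_genome(),
                                        causal = causal_locus(),
                                        model = mutation_model(),
                                        n_f2 = 200,
                                        design = bulk_design(),
                                        depth = depth_model(),
                                        misclassification_rate = 0,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  variants <- simulate_parental_variants(genome, causal, model)
  pop <- simulate_f2_population(variants, genome, n_f2)
  pop <- assign_phenotypes(pop, causal, misclassification_rate)
  bulks <- form_bulks(pop, design)
  ds <- simulate_read_counts(pop, bulks, depth)
  attr(ds, "population") <- pop
  ds
}
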