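#' Genome specification
#'
#' Describes the chromosomes of a (typically scaled-down) genome used for
#' simulation and windowing: physical length in base pairs and genetic map
#' length in centimorgans. Physical and genetic coordinates are related
#' linearly within a chromosome (uniform cM/Mb), so a variant at physical
#' position `pos` sits at `pos / length_bp * map_length_cM` cM.
#'
#' @param chrom_id Character vector of unique chromosome identifiers.
#' @param length_bp Integer-valued vector of chromosome lengths in bp (>= 1).
#' @param map_length_cM Numeric vector of genetic map lengths in cM (> 0).
#'
#' @return A data frame of class `genome_spec` with columns `chrom_id`,
#'   `length_bp` and `map_length_cM`, one row per chromosome.
#' @examples
#' genome_spec(c("chr1", "chr2"), c(30e6, 30e6), c(100, 100))
#' @export
genome_spec <- function(chrom_id, length_bp, map_length_cM) {
  chrom_id <- as.character(chrom_id)
  if (length(chrom_id) < 1) stop("at least one chromosome is required")
  if (anyDuplicated(chrom_id)) stop("chromosome ids must be unique")
  if (length(length_bp) != length(chrom_id) ||
      length(map_length_cM) != length(chrom_id)) {
    stop("chrom_id, length_bp and map_length_cM must have equal length")
  }
  if (!all(is.finite(length_bp)) || any(length_bp < 1)) {
    stop("length_bp must be finite and >= 1")
  }
  if (!all(is.finite(map_length_cM)) || any(map_length_cM <= 0)) {
    stop("map_length_cM must be finite and > 0")
  }
  g <- data.frame(
    chrom_id = chrom_id,
    length_bp = as.numeric(length_bp),
    map_length_cM = as.numeric(map_length_cM),
    stringsAsFactors = FALSE
  )
  class(g) <- c("genome_spec", "data.frame")
  g
}

#' Default desk-scale genome
#'
#' Two chromosomes of 30 Mb and 100 cM each: small enough that a full
#' simulate-map-annotate run takes seconds, large enough that the
#' delta SNP-index peak visibly decays with genetic distance from the
#' causal locus.
#'
#' @return A [genome_spec()].
#' @export
default_genome <- function() {
  genome_spec(c("chr1", "chr2"), c(30e6, 30e6), c(100, 100))
}

# Length (bp) of a named chromosome; errors if absent.
chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom_id)
  if (anyNA(i)) {
    stop("unknown chromosome(s): ", paste(unique(chrom[is.na(i)]), collapse = ", "))
  }
  genome$length_bp[i]
}

#' Convert physical to genetic position
#'
#' Linear interpolation: `cM = pos / length_bp * map_length_cM` on the
#' variant's chromosome.
#'
#' @param genome A [genome_spec()].
#' @param chrom Chromosome id (recycled against `pos`).
#' @param pos 1-based physical positions (bp).
#' @return Numeric vector of genetic positions in cM.
#' @export
genetic_position <- function(genome, chrom, pos) {
  i <- match(chrom, genome$chrom_id)
  if (anyNA(i)) {
    stop("unknown chromosome(s): ", paste(unique(chrom[is.na(i)]), collapse = ", "))
  }
  if (any(pos < 1 | pos > genome$length_bp[i])) {
    stop("position outside chromosome bounds")
  }
  pos / genome$length_bp[i] * genome$map_length_cM[i]
}

#' Haldane map function
#'
#' Recombination fraction between two loci separated by `d` cM under the
#' Haldane model (Poisson crossovers, no interference):
#' `r = (1 - exp(-2 d / 100)) / 2`.
#'
#' @param d_cM Genetic distance in centimorgans (>= 0).
#' @return Recombination fraction in `[0, 0.5)`.
#' @examples
#' haldane(50)  # ~0.3161
#' @export
haldane <- function(d_cM) {
  if (any(d_cM < 0)) stop("genetic distance must be >= 0")
  (1 - exp(-2 * d_cM / 100)) / 2
}
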