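#' Synthetic gene fixture around the causal locus
#'
#' Builds a single-exon, plus-strand gene model and a synthetic chromosome
#' sequence for the causal chromosome so that annotation can be exercised on
#' simulated data: the CDS starts with ATG, ends with TAA, is filled with
#' GCT (Ala) codons, and carries one TGG (Trp) codon whose third base sits
#' exactly on the causal position — so the default G-to-A causal change is a
#' TGG-to-TGA stop gain. The default CDS length is 2433 nt (810 residues
#' plus the stop). Background-variant reference bases elsewhere on the
#' chromosome are written into the sequence so that every simulated variant
#' annotates cleanly; background variants landing inside the start, stop or
#' Trp codons (vanishingly rare) are reported in `skipped` and must not be
#' annotated against this sequence.
#'
#' @param variants Variant table (`chrom`, `pos`, `ref`, `alt`).
#' @param causal A [causal_locus()] (ref must be `G` for the stop-gain
#'   construction).
#' @param genome A [genome_spec()] containing the causal chromosome.
#' @param cds_codons CDS length in codons, including the stop (default 811).
#' @param trp_codon Codon index of the TGG codon (default 406, mid-CDS).
#' @return List with `genes` (length-1 list of [gene_model()]), `genome_seq`
#'   (a named [Biostrings::DNAStringSet] for the causal chromosome), `gene`,
#'   and `skipped` (positions excluded from annotation).
#' @export
causal_gene_fixture <- function(variants, causal, genome = default_genome(),
                                cds_codons = 811, trp_codon = 406) {
  stopifnot(inherits(causal, "causal_locus"), inherits(genome, "genome_spec"))
  if (causal$ref != "G") {
    stop("the stop-gain fixture requires a G reference allele at the causal locus")
  }
  if (trp_codon < 2 || trp_codon >= cds_codons) {
    stop("trp_codon must lie strictly inside the CDS")
  }
  len <- chrom_length(genome, causal$chrom)
  gene_start <- causal$pos - 3 * trp_codon + 1
  gene_end <- gene_start + 3 * cds_codons - 1
  if (gene_start < 1 || gene_end > len) {
    stop("gene fixture does not fit on the chromosome at this causal position")
  }

  codons <- rep("GCT", cds_codons)
  codons[1] <- "ATG"
  codons[trp_codon] <- "TGG"
  codons[cds_codons] <- "TAA"
  cds <- paste(codons, collapse = "")

  seq <- Biostrings::DNAString(strrep("A", len))
  Biostrings::subseq(seq, gene_start, gene_end) <- Biostrings::DNAString(cds)

  protected <- c(gene_start:(gene_start + 2),
                 (causal$pos - 2):causal$pos,
                 (gene_end - 2):gene_end)
  v <- variants[variants$chrom == causal$chrom & !(
    variants$pos == causal$pos), , drop = FALSE]
  skipped <- v$pos[v$pos %in% protected]
  v <- v[!v$pos %in% protected, , drop = FALSE]
  if (nrow(v) > 0) {
    seq <- Biostrings::replaceLetterAt(seq, at = v$pos, letter = v$ref)
  }

  genome_seq <- Biostrings::DNAStringSet(stats::setNames(list(seq), causal$chrom))
  gene <- gene_model("synthetic_causal_gene", causal$chrom, "+",
                     gene_start, gene_end)
  list(genes = list(gene), genome_seq = genome_seq, gene = gene,
       skipped = skipped)
}
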