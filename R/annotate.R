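#' Single-transcript gene model
#'
#' A gene is its ordered CDS exons on a strand; coordinates are 1-based
#' inclusive on the plus strand of the reference. Exons must be sorted,
#' non-overlapping, and total a multiple of 3 (a complete CDS); whether the
#' CDS actually begins with ATG and ends with a stop is a property of the
#' sequence and is checked by [translate_cds()].
#'
#' @param gene_id Locus identifier (e.g. a LOC-style id).
#' @param chrom Chromosome id.
#' @param strand `"+"` or `"-"`.
#' @param exon_start,exon_end Integer vectors of CDS exon bounds.
#' @return A list of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exon_start, exon_end) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (length(exon_start) != length(exon_end) || length(exon_start) < 1) {
    stop("exon_start and exon_end must be nonempty and of equal length")
  }
  o <- order(exon_start)
  exon_start <- as.numeric(exon_start[o]); exon_end <- as.numeric(exon_end[o])
  if (any(exon_end < exon_start)) stop("exon end before start")
  if (length(exon_start) > 1 &&
      any(exon_start[-1] <= exon_end[-length(exon_end)])) {
    stop("exons overlap")
  }
  cds_len <- sum(exon_end - exon_start + 1)
  if (cds_len %% 3 != 0) stop("total CDS length must be divisible by 3")
  structure(
    list(gene_id = as.character(gene_id), chrom = as.character(chrom),
         strand = strand,
         exons = data.frame(start = exon_start, end = exon_end),
         cds_length = cds_len),
    class = "gene_model"
  )
}

#' Read gene models from a minimal TSV
#'
#' Expects columns `gene_id chrom strand exon_start exon_end`, one row per
#' CDS exon; rows sharing a `gene_id` form one gene.
#'
#' @param path Path to the TSV.
#' @return List of [gene_model()]s.
#' @export
read_gene_models <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "exon_start", "exon_end")
  if (!all(need %in% names(tb))) {
    stop("gene model TSV must have columns ", paste(need, collapse = ", "))
  }
  lapply(split(tb, tb$gene_id), function(g) {
    gene_model(g$gene_id[1], g$chrom[1], g$strand[1], g$exon_start, g$exon_end)
  })
}

#' Read CDS gene models from a GFF3 file
#'
#' Imports the file with `rtracklayer` and assembles one [gene_model()] per
#' CDS group (grouped by `Parent`, falling back to `ID`).
#'
#' @param path Path to a GFF3 file.
#' @return List of [gene_model()]s.
#' @export
read_gff3_cds <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_gff3_cds() needs the rtracklayer package")
  }
  gr <- as.data.frame(rtracklayer::import(path))
  gr <- gr[gr$type == "CDS", , drop = FALSE]
  if (nrow(gr) == 0) stop("no CDS features in ", path)
  parent <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_,
           character(1))
  } else rep(NA_character_, nrow(gr))
  id <- ifelse(is.na(parent), as.character(gr$ID), parent)
  df <- data.frame(gene_id = id,
                   chrom = as.character(gr$seqnames),
                   strand = as.character(gr$strand),
                   exon_start = gr$start,
                   exon_end = gr$end,
                   stringsAsFactors = FALSE)
  lapply(split(df, df$gene_id), function(g) {
    gene_model(g$gene_id[1], g$chrom[1], g$strand[1], g$exon_start, g$exon_end)
  })
}

# complement of single bases
.comp <- c(A = "T", C = "G", G = "C", T = "A")

# [[ by name, returning NULL (not an error) when absent
.get_chrom_seq <- function(genome_seq, chrom) {
  tryCatch(genome_seq[[chrom]], error = function(e) NULL)
}

# coding-strand CDS sequence of a gene as a character string
.cds_sequence <- function(gene, genome_seq) {
  chrom_seq <- .get_chrom_seq(genome_seq, gene$chrom)
  if (is.null(chrom_seq)) stop("genome sequence has no chromosome ", gene$chrom)
  parts <- mapply(function(s, e) as.character(Biostrings::subseq(chrom_seq, s, e)),
                  gene$exons$start, gene$exons$end)
  cds <- paste(parts, collapse = "")
  if (gene$strand == "-") {
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  }
  cds
}

# CDS coordinate (1-based, coding strand) of a genomic position inside an
# exon, or NA if intronic/outside
.cds_position <- function(gene, pos) {
  ex <- gene$exons
  hit <- which(pos >= ex$start & pos <= ex$end)
  if (length(hit) == 0) return(NA_integer_)
  before <- if (hit > 1) sum(ex$end[seq_len(hit - 1)] - ex$start[seq_len(hit - 1)] + 1) else 0
  plus_pos <- before + (pos - ex$start[hit] + 1)
  if (gene$strand == "+") plus_pos else gene$cds_length - plus_pos + 1
}

#' Annotate a SNP by codon-level consequence
#'
#' Locates the variant relative to each overlapping gene, rebuilds the
#' affected codon on the coding strand, translates reference and alternate
#' codons with the standard genetic code, and assigns a category:
#' `stop_gain`, `stop_loss`, `nonsynonymous`, `synonymous`, `splice_site`
#' (the 2 intronic bases flanking an exon), `intronic`, or `intergenic`.
#' Overlapping genes each contribute one row.
#'
#' @param chrom,pos,ref,alt The SNP (single-base alleles).
#' @param genes List of [gene_model()]s.
#' @param genome_seq A [Biostrings::DNAStringSet] named by chromosome, or a
#'   named list of `DNAString`s, covering the variant (the reference base at
#'   `pos` must equal `ref`; mismatch is an error).
#' @return Data frame with one row per (variant, gene) pair: `chrom`, `pos`,
#'   `ref`, `alt`, `gene_id`, `category`, `codon_ref`, `codon_alt`,
#'   `aa_ref`, `aa_alt`, `protein_pos` (codon fields `NA` for non-exonic
#'   categories).
#' @examples
#' seq <- Biostrings::DNAStringSet(c(chr1 = "ATGTGGTAA"))
#' g <- gene_model("g1", "chr1", "+", 1, 9)
#' annotate_variant("chr1", 6, "G", "A", list(g), seq)  # TGG -> TGA stop gain
#' @export
annotate_variant <- function(chrom, pos, ref, alt, genes, genome_seq) {
  chrom_seq <- .get_chrom_seq(genome_seq, chrom)
  if (is.null(chrom_seq)) stop("genome sequence has no chromosome ", chrom)
  if (pos < 1 || pos > length(chrom_seq)) stop("position outside genome sequence")
  genome_base <- as.character(Biostrings::subseq(chrom_seq, pos, pos))
  if (genome_base != ref) {
    stop(sprintf("reference mismatch at %s:%d: genome has %s, variant says %s",
                 chrom, pos, genome_base, ref))
  }

  row0 <- function(gene_id, category, codon_ref = NA_character_,
                   codon_alt = NA_character_, aa_ref = NA_character_,
                   aa_alt = NA_character_, protein_pos = NA_integer_) {
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               gene_id = gene_id, category = category,
               codon_ref = codon_ref, codon_alt = codon_alt,
               aa_ref = aa_ref, aa_alt = aa_alt,
               protein_pos = protein_pos, stringsAsFactors = FALSE)
  }

  hits <- Filter(function(g) {
    g$chrom == chrom && pos >= min(g$exons$start) && pos <= max(g$exons$end)
  }, genes)
  if (length(hits) == 0) return(row0(NA_character_, "intergenic"))

  out <- lapply(hits, function(gene) {
    cds_pos <- .cds_position(gene, pos)
    if (is.na(cds_pos)) {
      # intronic: splice site if within 2 bp of an exon boundary
      d_left <- pos - gene$exons$end    # distance past an exon end
      d_right <- gene$exons$start - pos # distance before an exon start
      near <- any(d_left >= 1 & d_left <= 2) || any(d_right >= 1 & d_right <= 2)
      return(row0(gene$gene_id, if (near) "splice_site" else "intronic"))
    }
    cds <- .cds_sequence(gene, genome_seq)
    codon_idx <- (cds_pos + 2L) %/% 3L
    pos_in_codon <- cds_pos - (codon_idx - 1L) * 3L
    codon_ref <- substr(cds, (codon_idx - 1L) * 3L + 1L, codon_idx * 3L)
    alt_coding <- if (gene$strand == "+") alt else unname(.comp[alt])
    codon_alt <- codon_ref
    substr(codon_alt, pos_in_codon, pos_in_codon) <- alt_coding
    aa_ref <- unname(Biostrings::GENETIC_CODE[codon_ref])
    aa_alt <- unname(Biostrings::GENETIC_CODE[codon_alt])
    category <- if (aa_ref == aa_alt) "synonymous"
      else if (aa_alt == "*") "stop_gain"
      else if (aa_ref == "*") "stop_loss"
      else "nonsynonymous"
    row0(gene$gene_id, category, codon_ref, codon_alt, aa_ref, aa_alt,
         codon_idx)
  })
  do.call(rbind, out)
}

#' Annotate a table of SNPs
#'
#' Vectorized wrapper over [annotate_variant()].
#'
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param genes List of [gene_model()]s.
#' @param genome_seq Named sequence set (see [annotate_variant()]).
#' @return Row-bound annotation data frame.
#' @export
annotate_variants <- function(variants, genes, genome_seq) {
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    annotate_variant(variants$chrom[i], variants$pos[i], variants$ref[i],
                     variants$alt[i], genes, genome_seq)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Translate a coding sequence
#'
#' Standard-code translation of a complete CDS. The sequence must have
#' length divisible by 3 and start with ATG; the terminal stop codon is
#' dropped from the returned protein. An internal (premature) stop raises
#' an error reporting the codon index — the signature of a stop-gain
#' mutant CDS.
#'
#' @param cds A character string or `DNAString` of A/C/G/T.
#' @return The protein as a single character string (may be empty, e.g. for
#'   `"ATGTGA"`).
#' @examples
#' translate_cds("ATGTGGGGGTAA")  # "MWG"
#' @export
translate_cds <- function(cds) {
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  if (n %% 3 != 0) stop("CDS length must be divisible by 3")
  if (substr(cds, 1, 3) != "ATG") stop("CDS must start with ATG")
  codons <- substring(cds, seq(1, n - 2, by = 3), seq(3, n, by = 3))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) stop("CDS contains an invalid codon")
  stops <- which(aa == "*")
  if (any(stops < length(aa))) {
    stop(sprintf("premature termination: internal stop codon at codon %d",
                 stops[stops < length(aa)][1]))
  }
  if (length(stops) > 0) aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

#' Rank annotated variants by consequence severity
#'
#' Stable sort by category rank — stop loss/gain first, then nonsynonymous,
#' then splice site, then everything else — with ties broken by
#' `(chrom, pos)`. This is the usual triage order when shortlisting
#' candidate causal SNPs.
#'
#' @param effects Annotation data frame from [annotate_variants()].
#' @return `effects` reordered, with a `rank` column prepended.
#' @export
prioritize <- function(effects) {
  rank_map <- c(stop_loss = 1, stop_gain = 1, nonsynonymous = 2,
                splice_site = 3)
  r <- unname(rank_map[effects$category])
  r[is.na(r)] <- 4
  out <- effects[order(r, effects$chrom, effects$pos), , drop = FALSE]
  out <- cbind(rank = sort(r), out)
  rownames(out) <- NULL
  out
}
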