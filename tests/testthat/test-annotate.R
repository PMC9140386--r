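# CDS used across tests: ATG GCT TGG GGG TAA -> protein "MAWG"
base_cds <- "ATGGCTTGGGGGTAA"

test_that("G>A at the third base of TGG is a stop gain (Trp -> *)", {
  t <- toy_gene(base_cds)
  # TGG occupies CDS positions 7-9; genomic = cds_start + 6 .. + 8
  eff <- annotate_variant("chrX", t$cds_start + 8, "G", "A",
                          list(t$gene), t$seq)
  expect_equal(eff$category, "stop_gain")
  expect_equal(eff$codon_ref, "TGG")
  expect_equal(eff$codon_alt, "TGA")
  expect_equal(eff$aa_ref, "W")
  expect_equal(eff$aa_alt, "*")
  expect_equal(eff$protein_pos, 3)
})

test_that("third-position G>A in GGG is synonymous; first-position is not", {
  t <- toy_gene(base_cds)
  # GGG occupies CDS positions 10-12
  syn <- annotate_variant("chrX", t$cds_start + 11, "G", "A",
                          list(t$gene), t$seq)
  expect_equal(syn$category, "synonymous")
  nsyn <- annotate_variant("chrX", t$cds_start + 9, "G", "A",
                           list(t$gene), t$seq)
  expect_equal(nsyn$category, "nonsynonymous")
  expect_equal(nsyn$aa_alt, "R")  # GGG (Gly) -> AGG (Arg)
})

test_that("stop loss, splice site, intronic and intergenic are classified", {
  # two-exon gene: ATGGCT | intron (8 bp) | TGGGGGTAA
  full <- paste0("TTTTT", "ATGGCT", "ACGTACGT", "TGGGGGTAA", "GGGGG")
  seqs <- Biostrings::DNAStringSet(c(chrX = full))
  g <- gene_model("g2", "chrX", "+", c(6, 20), c(11, 28))
  # stop loss: TAA (last codon, genomic 26-28), A>C at third base -> TAC (Tyr)
  sl <- annotate_variant("chrX", 28, "A", "C", list(g), seqs)
  expect_equal(sl$category, "stop_loss")
  # 1 bp into the intron after exon 1 (position 12) -> splice site
  expect_equal(annotate_variant("chrX", 12, "A", "G", list(g), seqs)$category,
               "splice_site")
  expect_equal(annotate_variant("chrX", 13, "C", "G", list(g), seqs)$category,
               "splice_site")
  # middle of the intron -> intronic
  expect_equal(annotate_variant("chrX", 15, "T", "G", list(g), seqs)$category,
               "intronic")
  # outside the gene span -> intergenic
  expect_equal(annotate_variant("chrX", 2, "T", "G", list(g), seqs)$category,
               "intergenic")
})

test_that("reference mismatch with the genome is an error", {
  t <- toy_gene(base_cds)
  expect_error(annotate_variant("chrX", t$cds_start, "C", "A",
                                list(t$gene), t$seq),
               "reference mismatch")
})

test_that("annotation is strand-consistent", {
  # the same CDS on the minus strand of the reverse-complemented sequence
  tp <- toy_gene(base_cds, strand = "+")
  tm <- toy_gene(base_cds, strand = "-")
  # stop-gain position: third base of TGG, CDS coordinate 9
  pos_p <- tp$cds_start + 8
  pos_m <- tm$cds_end - 8  # CDS runs backwards on the genome
  ep <- annotate_variant("chrX", pos_p, "G", "A", list(tp$gene), tp$seq)
  em <- annotate_variant("chrX", pos_m, "C", "T", list(tm$gene), tm$seq)
  for (f in c("category", "codon_ref", "codon_alt", "aa_ref", "aa_alt",
              "protein_pos")) {
    expect_equal(ep[[f]], em[[f]])
  }
})

test_that("exonic annotations are self-consistent under re-translation", {
  set.seed(20)
  # random internal codons with no stops
  safe <- setdiff(names(Biostrings::GENETIC_CODE),
                  c("TAA", "TAG", "TGA"))
  for (i in 1:10) {
    cds <- paste0("ATG", paste(sample(safe, 20, replace = TRUE), collapse = ""),
                  "TAA")
    t <- toy_gene(cds)
    cds_pos <- sample(4:(nchar(cds) - 3), 1)
    gpos <- t$cds_start + cds_pos - 1
    ref <- substr(cds, cds_pos, cds_pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    eff <- annotate_variant("chrX", gpos, ref, alt, list(t$gene), t$seq)
    mutated <- cds
    substr(mutated, cds_pos, cds_pos) <- alt
    codon <- substr(mutated, (eff$protein_pos - 1) * 3 + 1, eff$protein_pos * 3)
    expect_equal(eff$codon_alt, codon)
    expect_equal(eff$aa_alt, unname(Biostrings::GENETIC_CODE[codon]))
  }
})

test_that("translate_cds handles the canonical cases", {
  # a start codon followed directly by a stop: single-residue peptide,
  # consistent with the length = len/3 - 1 rule
  expect_equal(translate_cds("ATGTGA"), "M")
  expect_equal(translate_cds(base_cds), "MAWG")
  # a 2433-nt CDS ending in a stop translates to 810 residues
  cds <- paste0("ATG", strrep("GCT", 809), "TAA")
  expect_equal(nchar(cds), 2433)
  expect_equal(nchar(translate_cds(cds)), 810)
  expect_error(translate_cds("ATGC"), "divisible by 3")
  expect_error(translate_cds("TTGTGA"), "start with ATG")
})

test_that("a TGG->TGA edit makes translation fail at the edited codon", {
  cds <- paste0("ATG", strrep("GCT", 100), "TGG", strrep("GCT", 100), "TAA")
  expect_equal(nchar(translate_cds(cds)), 202)
  mutant <- cds
  substr(mutant, 306, 306) <- "A"  # third base of codon 102: TGG -> TGA
  expect_error(translate_cds(mutant), "codon 102")
})

test_that("translating a twice-reverse-complemented CDS is the identity", {
  cds <- Biostrings::DNAString(base_cds)
  back <- Biostrings::reverseComplement(Biostrings::reverseComplement(cds))
  expect_equal(translate_cds(back), translate_cds(cds))
})

test_that("prioritize ranks stop changes first and is a stable sort", {
  eff <- data.frame(
    chrom = c("c1", "c1", "c1", "c2", "c1"),
    pos = c(500, 100, 300, 50, 200),
    category = c("synonymous", "stop_gain", "nonsynonymous", "stop_gain",
                 "intergenic"),
    stringsAsFactors = FALSE)
  p <- prioritize(eff)
  expect_equal(p$category[1:2], c("stop_gain", "stop_gain"))
  expect_equal(p$pos[1:2], c(100, 50))  # tie broken by (chrom, pos)
  expect_equal(p$category[3], "nonsynonymous")
  expect_equal(p$rank, c(1, 1, 2, 4, 4))

  # all same category: positional order preserved
  same <- data.frame(chrom = "c1", pos = c(30, 10, 20),
                     category = "synonymous", stringsAsFactors = FALSE)
  expect_equal(prioritize(same)$pos, c(10, 20, 30))
})

test_that("gene models validate exon geometry and read from TSV", {
  expect_error(gene_model("g", "c1", "+", c(1, 5), c(6, 9)), "overlap")
  expect_error(gene_model("g", "c1", "+", 1, 7), "divisible by 3")
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\tstrand\texon_start\texon_end",
               "gA\tc1\t+\t6\t11", "gA\tc1\t+\t20\t28",
               "gB\tc2\t-\t1\t9"), tsv)
  gm <- read_gene_models(tsv)
  expect_length(gm, 2)
  expect_equal(gm$gA$cds_length, 15)
  expect_equal(gm$gB$strand, "-")
})

test_that("GFF3 CDS subset reader assembles the same gene models", {
  skip_if_not_installed("rtracklayer")
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrX\ttest\tmRNA\t6\t28\t.\t+\t.\tID=tx1",
    "chrX\ttest\tCDS\t6\t11\t.\t+\t0\tID=cds1;Parent=tx1",
    "chrX\ttest\tCDS\t20\t28\t.\t+\t0\tID=cds2;Parent=tx1"), gff)
  gm <- read_gff3_cds(gff)
  expect_length(gm, 1)
  expect_equal(gm[[1]]$exons$start, c(6, 20))
  expect_equal(gm[[1]]$cds_length, 15)
})
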