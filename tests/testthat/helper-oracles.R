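# Independent brute-force oracles used to cross-check the vectorized paths.

# Naive per-window mean delta: double loop over windows and records.
naive_window_means <- function(records, genome, cfg) {
  out <- NULL
  for (i in seq_len(nrow(genome))) {
    chr <- genome$chrom_id[i]
    starts <- seq(1, genome$length_bp[i], by = cfg$step_bp)
    for (s in starts) {
      e <- min(s + cfg$window_bp - 1, genome$length_bp[i])
      d <- records$delta[records$chrom == chr & records$pos >= s &
                           records$pos <= e & !is.na(records$delta)]
      out <- rbind(out, data.frame(
        chrom = chr, start = s, end = e, n_snps = length(d),
        mean_delta = if (length(d) >= cfg$min_snps_per_window) mean(d) else NA_real_,
        stringsAsFactors = FALSE))
    }
  }
  out
}

# Hand-rolled type-7 (linear interpolation) quantile:
# h = (n-1)p + 1, q = (1-frac(h)) x_(floor(h)) + frac(h) x_(ceiling(h)).
manual_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  idx <- 1 + (n - 1) * p
  lo <- floor(idx)
  hi <- ceiling(idx)
  h <- idx - lo
  q <- s[lo]
  i <- which(idx > lo & s[hi] != q)
  q[i] <- (1 - h[i]) * q[i] + h[i] * s[hi][i]
  q
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of group labels.
enumerate_wilcoxon <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  sums <- apply(utils::combn(length(r), n1), 2, function(i) sum(r[i]))
  eps <- 1e-9
  min(1, 2 * min(mean(sums <= w_obs + eps), mean(sums >= w_obs - eps)))
}

# Tiny site-count table builder.
make_sites <- function(chrom, pos, mut_ref, mut_alt, wt_ref, wt_alt,
                       ref = "G", alt = "A") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             mut_ref = mut_ref, mut_alt = mut_alt,
             wt_ref = wt_ref, wt_alt = wt_alt, stringsAsFactors = FALSE)
}

# Gene + sequence toy: a plus-strand, single-exon CDS embedded in flanking
# sequence; returns the named DNAStringSet and the gene model.
toy_gene <- function(cds, flank5 = "TTTTT", flank3 = "GGGGG", chrom = "chrX",
                     strand = "+", gene_id = "toy") {
  full <- paste0(flank5, cds, flank3)
  if (strand == "-") {
    full <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(full)))
    start <- nchar(flank3) + 1
  } else {
    start <- nchar(flank5) + 1
  }
  end <- start + nchar(cds) - 1
  seqs <- Biostrings::DNAStringSet(stats::setNames(full, chrom))
  list(gene = mutmapr::gene_model(gene_id, chrom, strand, start, end),
       seq = seqs, cds_start = start, cds_end = end)
}
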