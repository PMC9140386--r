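#' Per-site SNP index and delta SNP index
#'
#' The SNP index of a bulk at a site is the fraction of reads carrying the
#' mutant (alt) allele, `alt / (ref + alt)`; it is missing (`NA`) when the
#' bulk has zero depth there. The delta SNP index is the mutant-bulk index
#' minus the wild-bulk index and is defined only when both indices are.
#' At a recessive causal locus the mutant bulk is fixed for the mutant
#' allele (index 1) while the phenotype-selected wild bulk has expected
#' index 1/3 (AA:Aa = 1:2 among non-mutant plants), so the expected delta
#' peaks at 2/3.
#'
#' @param sites Site-counts data frame with nonnegative columns `mut_ref`,
#'   `mut_alt`, `wt_ref`, `wt_alt` (as produced by [read_vcf()] or
#'   [simulate_read_counts()]).
#' @return `sites` with columns `index_mut`, `index_wt`, `delta` appended.
#' @examples
#' s <- data.frame(chrom = "chr1", pos = 100, ref = "G", alt = "A",
#'                 mut_ref = 0, mut_alt = 8, wt_ref = 5, wt_alt = 5)
#' compute_snp_index(s)
#' @export
compute_snp_index <- function(sites) {
  cols <- c("mut_ref", "mut_alt", "wt_ref", "wt_alt")
  if (!all(cols %in% names(sites))) {
    stop("sites must have columns ", paste(cols, collapse = ", "))
  }
  cnt <- sites[cols]
  if (any(unlist(cnt) < 0)) stop("read counts must be nonnegative")
  dm <- sites$mut_ref + sites$mut_alt
  dw <- sites$wt_ref + sites$wt_alt
  sites$index_mut <- ifelse(dm > 0, sites$mut_alt / dm, NA_real_)
  sites$index_wt <- ifelse(dw > 0, sites$wt_alt / dw, NA_real_)
  sites$delta <- delta_snp_index(sites$index_mut, sites$index_wt)
  sites
}

#' Delta SNP index
#'
#' `delta = index_mut - index_wt`, in `[-1, 1]`; `NA` whenever either input
#' is missing.
#'
#' @param index_mut,index_wt SNP indices in `[0, 1]` (or `NA`).
#' @return Numeric vector of the same length.
#' @export
delta_snp_index <- function(index_mut, index_wt) {
  ok_m <- is.na(index_mut) | (index_mut >= 0 & index_mut <= 1)
  ok_w <- is.na(index_wt) | (index_wt >= 0 & index_wt <= 1)
  if (!all(ok_m, ok_w)) stop("SNP indices must lie in [0, 1]")
  index_mut - index_wt
}

#' Site filter configuration
#'
#' Mirrors the read-quality filters used before windowing: a site is removed
#' if (a) one bulk has no coverage at all, or (b) its SNP index falls below
#' `min_index` in *both* bulks, or (c) fewer than `min_support` reads carry
#' the alt allele in *both* bulks. "Support" is read here as alt-supporting
#' read count, the usual MutMap reading.
#'
#' @param min_index SNP-index floor (default 0.3).
#' @param min_support Minimum alt-supporting reads (default 7).
#' @param drop_if_missing_one_bulk Drop sites with zero depth in either bulk
#'   (default `TRUE`).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_index = 0.3, min_support = 7,
                          drop_if_missing_one_bulk = TRUE) {
  if (min_index < 0 || min_index > 1) stop("min_index must be in [0, 1]")
  if (min_support < 0) stop("min_support must be >= 0")
  structure(
    list(min_index = min_index, min_support = as.integer(min_support),
         drop_if_missing_one_bulk = isTRUE(drop_if_missing_one_bulk)),
    class = "filter_config"
  )
}

#' Apply site filters
#'
#' Removal rules (OR of the three; (b) and (c) require failure in both
#' bulks):
#' (a) missing index in either bulk; (b) index below `min_index` in both
#' bulks; (c) alt-supporting reads below `min_support` in both bulks.
#'
#' @param records Output of [compute_snp_index()].
#' @param cfg A [filter_config()].
#' @return A list with `records` (retained rows) and `report` (data frame of
#'   per-rule removal counts plus totals in/out; a site can trigger several
#'   rules, so rule counts may exceed the number removed).
#' @export
apply_filters <- function(records, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  miss <- is.na(records$index_mut) | is.na(records$index_wt)
  rule_a <- if (cfg$drop_if_missing_one_bulk) miss else rep(FALSE, nrow(records))
  rule_b <- !miss & records$index_mut < cfg$min_index &
    records$index_wt < cfg$min_index
  rule_c <- !miss & records$mut_alt < cfg$min_support &
    records$wt_alt < cfg$min_support
  drop <- rule_a | rule_b | rule_c
  report <- data.frame(
    rule = c("missing_one_bulk", "low_index_both", "low_support_both",
             "total_in", "total_removed", "total_out"),
    n = c(sum(rule_a), sum(rule_b), sum(rule_c),
          nrow(records), sum(drop), sum(!drop))
  )
  kept <- records[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  list(records = kept, report = report)
}
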