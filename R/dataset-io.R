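#' Write a simulated dataset to disk
#'
#' Emits three plain-text files into `out_dir`:
#' * `dataset.vcf` — minimal VCF v4.2 dialect: `CHROM POS ID REF ALT QUAL
#'   FILTER INFO FORMAT bulk_mut bulk_wt` with `FORMAT=AD` and per-bulk
#'   allele depths `"ref,alt"`;
#' * `truth.tsv` — the causal locus (`chrom pos ref alt`);
#' * `manifest.yaml` — every simulation parameter and seed.
#'
#' @param dataset A `mutmap_dataset` from [simulate_read_counts()] or
#'   [simulate_mapping_experiment()].
#' @param out_dir Output directory (created if needed).
#' @param manifest Optional named list of parameters/seeds to record; written
#'   verbatim into `manifest.yaml`.
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_dataset <- function(dataset, out_dir, manifest = NULL) {
  stopifnot(inherits(dataset, "mutmap_dataset"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop("cannot create output directory: ", out_dir)

  vcf_path <- file.path(out_dir, "dataset.vcf")
  write_vcf(dataset$counts, vcf_path)

  truth_path <- file.path(out_dir, "truth.tsv")
  tr <- dataset$truth
  truth <- data.frame(chrom = tr$chrom, pos = tr$pos, ref = tr$ref, alt = tr$alt)
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  manifest_path <- file.path(out_dir, "manifest.yaml")
  if (is.null(manifest)) {
    manifest <- list(
      design = unclass(dataset$design),
      depth = unclass(dataset$depth),
      truth = unclass(tr),
      phenotype_counts = as.list(stats::setNames(
        as.integer(dataset$phenotype_counts), names(dataset$phenotype_counts)))
    )
  }
  yaml::write_yaml(manifest, manifest_path)

  invisible(c(vcf = vcf_path, truth = truth_path, manifest = manifest_path))
}

#' Write site counts as the minimal VCF dialect
#'
#' @param counts Site-counts data frame (`chrom`, `pos`, `ref`, `alt`,
#'   `mut_ref`, `mut_alt`, `wt_ref`, `wt_alt`).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(counts, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "bulk_mut", "bulk_wt", sep = "\t")
  )
  body <- character(0)
  if (nrow(counts) > 0) {
    body <- paste(counts$chrom, counts$pos, ".", counts$ref, counts$alt,
                  ".", ".", ".", "AD",
                  paste0(counts$mut_ref, ",", counts$mut_alt),
                  paste0(counts$wt_ref, ",", counts$wt_alt),
                  sep = "\t")
  }
  con <- file(path, "wb")  # binary mode: byte-identical output across platforms
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' Read the bulk-count VCF dialect
#'
#' Parses a biallelic-SNP VCF whose `FORMAT` contains `AD` and whose sample
#' columns include `bulk_mut` and `bulk_wt` (extra samples are ignored with
#' a warning). Positions are kept 1-based. Malformed lines raise an error
#' naming the offending line number.
#'
#' @param path Path to the VCF file.
#' @return Site-counts data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `mut_ref`, `mut_alt`, `wt_ref`, `wt_alt`; zero rows for a header-only
#'   file.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) != 1) stop("no #CHROM header line found in ", path)
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  samples <- cols[-(1:9)]
  need <- c("bulk_mut", "bulk_wt")
  if (!all(need %in% samples)) {
    stop("missing sample column(s): ", paste(setdiff(need, samples), collapse = ", "))
  }
  extra <- setdiff(samples, need)
  if (length(extra) > 0) {
    warning("ignoring extra sample column(s): ", paste(extra, collapse = ", "))
  }
  body_idx <- which(seq_along(lines) > hdr & !startsWith(lines, "#") &
                      nzchar(lines))
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      mut_ref = integer(0), mut_alt = integer(0),
                      wt_ref = integer(0), wt_alt = integer(0),
                      stringsAsFactors = FALSE)
  if (length(body_idx) == 0) return(empty)

  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(cols))) {
    bad <- body_idx[which(nf != length(cols))[1]]
    stop(sprintf("malformed VCF line %d: expected %d fields, found %d",
                 bad, length(cols), nf[which(nf != length(cols))[1]]))
  }
  m <- do.call(rbind, fields)
  colnames(m) <- cols

  fmt <- strsplit(m[, "FORMAT"], ":", fixed = TRUE)
  ad_i <- vapply(fmt, function(f) match("AD", f), integer(1))
  if (anyNA(ad_i)) {
    stop(sprintf("malformed VCF line %d: FORMAT has no AD field",
                 body_idx[which(is.na(ad_i))[1]]))
  }
  parse_ad <- function(sample_col) {
    parts <- strsplit(m[, sample_col], ":", fixed = TRUE)
    ad <- mapply(function(p, i) if (i <= length(p)) p[i] else NA_character_,
                 parts, ad_i)
    counts <- strsplit(ad, ",", fixed = TRUE)
    bad <- which(is.na(ad) | lengths(counts) != 2 |
                   vapply(counts, function(x) anyNA(suppressWarnings(as.integer(x))),
                          logical(1)))
    if (length(bad) > 0) {
      stop(sprintf("malformed VCF line %d: bad AD value in sample %s",
                   body_idx[bad[1]], sample_col))
    }
    matrix(as.integer(unlist(counts)), ncol = 2, byrow = TRUE)
  }
  ad_mut <- parse_ad("bulk_mut")
  ad_wt <- parse_ad("bulk_wt")

  pos <- suppressWarnings(as.integer(m[, "POS"]))
  if (anyNA(pos)) {
    stop(sprintf("malformed VCF line %d: non-integer POS",
                 body_idx[which(is.na(pos))[1]]))
  }
  data.frame(chrom = m[, "#CHROM"], pos = pos,
             ref = m[, "REF"], alt = m[, "ALT"],
             mut_ref = ad_mut[, 1], mut_alt = ad_mut[, 2],
             wt_ref = ad_wt[, 1], wt_alt = ad_wt[, 2],
             stringsAsFactors = FALSE)
}

#' Read a truth TSV (`chrom pos ref alt`)
#'
#' @param path Path to the TSV written by [write_dataset()].
#' @return A [causal_locus()].
#' @export
read_truth <- function(path) {
  tr <- utils::read.delim(path, stringsAsFactors = FALSE)
  causal_locus(tr$chrom[1], tr$pos[1], tr$ref[1], tr$alt[1])
}
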