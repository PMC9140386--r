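#' Sliding-window configuration
#'
#' Windows tile each chromosome from position 1 at `step_bp` increments;
#' the last window is truncated at the chromosome end. Windows with fewer
#' than `min_snps_per_window` contributing SNPs get a missing mean and are
#' never called as candidates.
#'
#' @param window_bp Window width in bp (default 2 Mb).
#' @param step_bp Step between window starts (default 50 kb; must be
#'   `<= window_bp`).
#' @param min_snps_per_window Minimum SNPs for a defined window mean
#'   (default 3).
#' @return A list of class `window_config`.
#' @export
window_config <- function(window_bp = 2e6, step_bp = 5e4,
                         min_snps_per_window = 3) {
  if (window_bp < 1 || step_bp < 1) stop("window_bp and step_bp must be >= 1")
  if (step_bp > window_bp) stop("step_bp must be <= window_bp")
  structure(
    list(window_bp = as.numeric(window_bp), step_bp = as.numeric(step_bp),
         min_snps_per_window = as.integer(min_snps_per_window)),
    class = "window_config"
  )
}

# Window tiling for one genome: data frame chrom/start/end plus, per window,
# the index range [lo+1, hi] into the chromosome-sorted record positions.
.window_frame <- function(pos_by_chrom, genome, cfg) {
  out <- lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length_bp[i]
    starts <- seq(1, len, by = cfg$step_bp)
    ends <- pmin(starts + cfg$window_bp - 1, len)
    pos <- pos_by_chrom[[genome$chrom_id[i]]]
    if (is.null(pos)) pos <- numeric(0)
    data.frame(chrom = genome$chrom_id[i], start = starts, end = ends,
               lo = findInterval(starts - 1, pos),
               hi = findInterval(ends, pos),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Sliding-window mean delta SNP index
#'
#' Computes, for every window of the tiling, the number of contributing SNPs
#' and the arithmetic mean of their delta SNP index. A SNP inside two
#' overlapping windows contributes to both. Records with missing delta are
#' ignored (they should already have been removed by [apply_filters()]).
#'
#' @param records Filtered records with columns `chrom`, `pos`, `delta`.
#' @param genome A [genome_spec()].
#' @param cfg A [window_config()].
#' @return Data frame of class `window_stats`: `chrom`, `start`, `end`,
#'   `n_snps`, `mean_delta` (`NA` when `n_snps < min_snps_per_window`).
#' @export
sliding_windows <- function(records, genome, cfg = window_config()) {
  stopifnot(inherits(genome, "genome_spec"), inherits(cfg, "window_config"))
  records <- records[!is.na(records$delta), , drop = FALSE]
  records <- records[order(match(records$chrom, genome$chrom_id), records$pos), ]
  pos_by_chrom <- split(records$pos, records$chrom)
  wf <- .window_frame(pos_by_chrom, genome, cfg)

  cs_by_chrom <- lapply(split(records$delta, records$chrom),
                        function(d) c(0, cumsum(d)))
  n <- wf$hi - wf$lo
  sums <- numeric(nrow(wf))
  for (chr in unique(wf$chrom)) {
    w <- wf$chrom == chr
    cs <- cs_by_chrom[[chr]]
    if (is.null(cs)) cs <- 0
    sums[w] <- cs[wf$hi[w] + 1] - cs[wf$lo[w] + 1]
  }
  mean_delta <- ifelse(n >= cfg$min_snps_per_window, sums / n, NA_real_)
  out <- data.frame(chrom = wf$chrom, start = wf$start, end = wf$end,
                    n_snps = n, mean_delta = mean_delta,
                    stringsAsFactors = FALSE)
  class(out) <- c("window_stats", "data.frame")
  out
}

#' Simulated null confidence thresholds per window
#'
#' Builds the null distribution of window-mean delta SNP index under "no
#' linkage to phenotype": in each replicate, every bulk member's genotype at
#' every site is drawn independently from \{0, 1, 2\} with probabilities
#' (1/4, 1/2, 1/4), the bulk allele frequency is formed, alt reads are drawn
#' binomial at the *observed* per-site depth, the delta is recomputed, and
#' windows are re-averaged. Thresholds are the two-sided
#' `(1 - confidence)/2` and `(1 + confidence)/2` quantiles of the replicate
#' window means.
#'
#' @param records Filtered records (need `chrom`, `pos`, and the four count
#'   columns for observed depths).
#' @param design A [bulk_design()] (bulk sizes drive the genotype-sampling
#'   variance).
#' @param genome A [genome_spec()].
#' @param cfg A [window_config()] (must match the one used for the observed
#'   windows).
#' @param n_rep Number of null replicates (default 1000).
#' @param confidence Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @param keep_replicates If `TRUE`, attach the windows x replicates matrix
#'   of null window means as attribute `"replicates"`.
#' @return Data frame of class `threshold_curve`: `chrom`, `start`, `end`,
#'   `n_snps`, `lower`, `upper`; attributes `n_rep`, `confidence`.
#' @export
simulate_null_thresholds <- function(records, design = bulk_design(),
                                     genome = default_genome(),
                                     cfg = window_config(),
                                     n_rep = 1000, confidence = 0.95,
                                     seed = NULL, keep_replicates = FALSE) {
  stopifnot(inherits(design, "bulk_design"), inherits(genome, "genome_spec"),
            inherits(cfg, "window_config"))
  if (n_rep < 1) stop("n_rep must be >= 1")
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)

  records <- records[order(match(records$chrom, genome$chrom_id), records$pos), ]
  d_mut <- records$mut_ref + records$mut_alt
  d_wt <- records$wt_ref + records$wt_alt
  if (any(d_mut == 0) || any(d_wt == 0)) {
    stop("records with zero depth in a bulk; filter them out first")
  }
  nv <- nrow(records)

  null_index <- function(depths, n_bulk) {
    # bulk mutant-allele freq: mean of n_bulk genotypes in {0,1,2} at 1:2:1,
    # i.e. Binomial(2 n_bulk, 1/2) / (2 n_bulk)
    freq <- stats::rbinom(nv * n_rep, 2L * n_bulk, 0.5) / (2 * n_bulk)
    alt <- stats::rbinom(nv * n_rep, rep.int(depths, n_rep), freq)
    matrix(alt / rep.int(depths, n_rep), nrow = nv)
  }
  delta <- null_index(d_mut, design$n_mutant_bulk) -
    null_index(d_wt, design$n_wild_bulk)

  pos_by_chrom <- split(records$pos, records$chrom)
  wf <- .window_frame(pos_by_chrom, genome, cfg)
  n <- wf$hi - wf$lo

  rep_means <- matrix(NA_real_, nrow = nrow(wf), ncol = n_rep)
  for (chr in unique(wf$chrom)) {
    w <- which(wf$chrom == chr)
    j <- which(records$chrom == chr)  # rows of this chromosome, position-sorted
    if (length(j) > 0) {
      cs <- apply(delta[j, , drop = FALSE], 2, cumsum)
      cs <- rbind(0, matrix(cs, ncol = n_rep))
      # wf$lo / wf$hi are chromosome-local indices into those rows
      rep_means[w, ] <- (cs[wf$hi[w] + 1L, , drop = FALSE] -
                           cs[wf$lo[w] + 1L, , drop = FALSE]) /
        (wf$hi[w] - wf$lo[w])
    }
  }
  defined <- n >= cfg$min_snps_per_window
  rep_means[!defined, ] <- NA_real_

  a <- (1 - confidence) / 2
  lower <- upper <- rep(NA_real_, nrow(wf))
  if (any(defined)) {
    q <- apply(rep_means[defined, , drop = FALSE], 1, stats::quantile,
               probs = c(a, 1 - a), names = FALSE)
    lower[defined] <- q[1, ]
    upper[defined] <- q[2, ]
  }
  out <- data.frame(chrom = wf$chrom, start = wf$start, end = wf$end,
                    n_snps = n, lower = lower, upper = upper,
                    stringsAsFactors = FALSE)
  class(out) <- c("threshold_curve", "data.frame")
  attr(out, "n_rep") <- as.integer(n_rep)
  attr(out, "confidence") <- confidence
  if (keep_replicates) attr(out, "replicates") <- rep_means
  out
}

#' Call candidate intervals
#'
#' Flags windows whose mean delta SNP index exceeds the upper null
#' threshold, merges maximal runs of consecutive exceeding windows per
#' chromosome into intervals, and reports each interval's peak window.
#' Windows with a missing mean are never candidates and break runs.
#' Only the upper bound is used: the mutant-phenotype bulk carries the
#' mutant allele, so the signal of interest is positive.
#'
#' @param windows A [sliding_windows()] result.
#' @param thresholds A [simulate_null_thresholds()] result on the same
#'   tiling (checked; mismatch is an error).
#' @return Data frame of class `candidate_intervals` with columns `chrom`,
#'   `start`, `end`, `peak_delta`, `peak_pos` (midpoint of the peak window),
#'   `n_windows`, ordered by decreasing `peak_delta`; zero rows when nothing
#'   exceeds.
#' @export
call_candidates <- function(windows, thresholds) {
  if (nrow(windows) != nrow(thresholds) ||
      !all(windows$chrom == thresholds$chrom) ||
      !all(windows$start == thresholds$start) ||
      !all(windows$end == thresholds$end)) {
    stop("windows and thresholds are misaligned (different tiling)")
  }
  exceeds <- !is.na(windows$mean_delta) & !is.na(thresholds$upper) &
    windows$mean_delta > thresholds$upper

  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), peak_delta = numeric(0),
                      peak_pos = numeric(0), n_windows = integer(0),
                      stringsAsFactors = FALSE)
  if (!any(exceeds)) {
    class(empty) <- c("candidate_intervals", "data.frame")
    return(empty)
  }
  out <- empty
  for (chr in unique(windows$chrom)) {
    w <- which(windows$chrom == chr)
    ex <- exceeds[w]
    if (!any(ex)) next
    runs <- rle(ex)
    stops <- cumsum(runs$lengths)
    starts <- stops - runs$lengths + 1
    for (k in which(runs$values)) {
      idx <- w[starts[k]:stops[k]]
      peak <- idx[which.max(windows$mean_delta[idx])]
      out <- rbind(out, data.frame(
        chrom = chr,
        start = min(windows$start[idx]),
        end = max(windows$end[idx]),
        peak_delta = windows$mean_delta[peak],
        peak_pos = floor((windows$start[peak] + windows$end[peak]) / 2),
        n_windows = length(idx),
        stringsAsFactors = FALSE
      ))
    }
  }
  out <- out[order(-out$peak_delta), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_intervals", "data.frame")
  out
}

#' Map a bulk-sequenced dataset end to end
#'
#' Orchestrates [read_vcf()] (or an in-memory site table) ->
#' [compute_snp_index()] -> [apply_filters()] -> [sliding_windows()] ->
#' [simulate_null_thresholds()] -> [call_candidates()].
#'
#' @param vcf Path to a bulk-count VCF, or a site-counts data frame.
#' @param genome A [genome_spec()].
#' @param design A [bulk_design()] used for the null.
#' @param filter_cfg A [filter_config()].
#' @param window_cfg A [window_config()].
#' @param n_rep Null replicates (default 1000).
#' @param confidence Confidence level (default 0.95).
#' @param seed Optional integer seed for the null simulation.
#' @return A list of class `mutmap_report`: `snps` (per-SNP table),
#'   `windows` (per-window table with `lower`, `upper`, `exceeds`),
#'   `thresholds`, `candidates`, and `log` (record counts at each stage).
#' @export
map_dataset <- function(vcf, genome = default_genome(),
                        design = bulk_design(),
                        filter_cfg = filter_config(),
                        window_cfg = window_config(),
                        n_rep = 1000, confidence = 0.95, seed = NULL) {
  sites <- if (is.character(vcf)) read_vcf(vcf) else vcf
  snps <- compute_snp_index(sites)
  flt <- apply_filters(snps, filter_cfg)
  log <- list(n_sites = nrow(snps), filter_report = flt$report,
              n_retained = nrow(flt$records))
  if (nrow(flt$records) == 0) {
    warning("no records survive filtering; empty report")
    empty <- data.frame()
    out <- list(snps = snps, windows = empty, thresholds = empty,
                candidates = empty, log = log)
    class(out) <- "mutmap_report"
    return(out)
  }
  windows <- sliding_windows(flt$records, genome, window_cfg)
  thresholds <- simulate_null_thresholds(flt$records, design, genome,
                                         window_cfg, n_rep = n_rep,
                                         confidence = confidence, seed = seed)
  candidates <- call_candidates(windows, thresholds)
  windows$lower <- thresholds$lower
  windows$upper <- thresholds$upper
  windows$exceeds <- !is.na(windows$mean_delta) & !is.na(windows$upper) &
    windows$mean_delta > windows$upper
  if (nrow(candidates) == 0) warning("no window exceeds the threshold; zero candidates")
  log$n_windows <- nrow(windows)
  log$n_windows_exceeding <- sum(windows$exceeds)
  log$n_candidates <- nrow(candidates)
  out <- list(snps = snps, windows = windows, thresholds = thresholds,
              candidates = candidates, log = log)
  class(out) <- "mutmap_report"
  out
}

#' Simulate a dataset from the null model
#'
#' Generates bulk counts with *no causal conditioning*: at every site,
#' independently, each bulk's allele frequency comes from bulk-size genotype
#' sampling at 1:2:1 and reads are binomial at Poisson depth. This is the
#' same generative process the threshold null assumes, so it is the natural
#' input for calibration checks of the confidence band.
#'
#' @param variants Variant table (`chrom`, `pos`, `ref`, `alt`).
#' @param design A [bulk_design()].
#' @param depth A [depth_model()].
#' @param seed Optional integer seed.
#' @return A site-counts data frame (same shape as
#'   `simulate_read_counts()$counts`).
#' @export
simulate_null_dataset <- function(variants, design = bulk_design(),
                                  depth = depth_model(), seed = NULL) {
  stopifnot(inherits(design, "bulk_design"), inherits(depth, "depth_model"))
  if (!is.null(seed)) set.seed(seed)
  nv <- nrow(variants)
  e <- depth$error_rate
  draw <- function(n_bulk) {
    p <- stats::rbinom(nv, 2L * n_bulk, 0.5) / (2 * n_bulk)
    d <- stats::rpois(nv, depth$mean_depth)
    alt <- stats::rbinom(nv, d, p * (1 - e) + (1 - p) * e)
    cbind(ref = d - alt, alt = alt)
  }
  m <- draw(design$n_mutant_bulk)
  w <- draw(design$n_wild_bulk)
  data.frame(chrom = variants$chrom, pos = variants$pos,
             ref = variants$ref, alt = variants$alt,
             mut_ref = m[, "ref"], mut_alt = m[, "alt"],
             wt_ref = w[, "ref"], wt_alt = w[, "alt"],
             stringsAsFactors = FALSE)
}
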