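#' Goodness-of-fit chi-square test for a segregation ratio
#'
#' Tests observed wild/mutant phenotype counts against an expected
#' Mendelian ratio (default 3:1, the F2 expectation for a monogenic
#' recessive trait): `chi2 = sum((obs - exp)^2 / exp)` on 1 df, compared
#' against a critical value (default 3.84, the upper 5% point).
#'
#' @param n_wild,n_mutant Observed phenotype counts (total > 0).
#' @param ratio Expected `c(wild, mutant)` ratio, default `c(3, 1)`.
#' @param critical Critical value, default `3.84`
#'   (= [chisq_critical()]`(0.05, 1)` to 2 dp).
#' @return A list of class `segregation_test`: `n_wild`, `n_mutant`,
#'   `expected`, `chi2`, `df` (1), `critical_value`, `consistent`
#'   (`chi2 < critical`).
#' @examples
#' segregation_chisq(160, 40)  # chi2 = 8/3, consistent with 3:1
#' @export
segregation_chisq <- function(n_wild, n_mutant, ratio = c(3, 1),
                              critical = 3.84) {
  if (n_wild < 0 || n_mutant < 0) stop("counts must be nonnegative")
  total <- n_wild + n_mutant
  if (total == 0) stop("total count must be > 0")
  expected <- total * ratio / sum(ratio)
  obs <- c(n_wild, n_mutant)
  chi2 <- sum((obs - expected)^2 / expected)
  structure(
    list(n_wild = n_wild, n_mutant = n_mutant, expected = expected,
         chi2 = chi2, df = 1L, critical_value = critical,
         consistent = chi2 < critical),
    class = "segregation_test"
  )
}

#' @export
print.segregation_test <- function(x, ...) {
  cat(sprintf("Segregation test: %d wild : %d mutant (expected %.1f : %.1f)\n",
              x$n_wild, x$n_mutant, x$expected[1], x$expected[2]))
  cat(sprintf("chi2 = %.4g (df = %d), critical = %.4g -> %s\n",
              x$chi2, x$df, x$critical_value,
              if (x$consistent) "consistent" else "inconsistent"))
  invisible(x)
}

#' Upper-alpha chi-square critical value
#'
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param df Degrees of freedom, default 1.
#' @return The upper-`alpha` quantile of the chi-square distribution.
#' @examples
#' chisq_critical(0.05, 1)  # 3.84
#' @export
chisq_critical <- function(alpha = 0.05, df = 1) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  stats::qchisq(1 - alpha, df = df)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact for combined group sizes with `max(n1, n2) <= exact_limit`
#' (default 10): tie-free data use the exact rank-sum distribution;
#' tied data fall back to full enumeration of the `choose(n1+n2, n1)`
#' group labelings of the midranks. Larger groups use the normal
#' approximation with tie-corrected variance and no continuity
#' correction. The two-sided p is `min(1, 2 * min(lower tail, upper
#' tail))`, each tail including the observed statistic.
#'
#' @param x,y Numeric samples (mutant and wild groups, say).
#' @param exact_limit Largest group size handled exactly (default 10).
#' @return The p-value.
#' @examples
#' wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3))  # 2/20 = 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 10) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups need at least one value")
  all_v <- c(x, y)
  r <- rank(all_v)
  w <- sum(r[seq_len(n1)])  # rank sum of x

  if (max(n1, n2) <= exact_limit) {
    if (!any(duplicated(all_v))) {
      # tie-free: exact Mann-Whitney tails via the rank-sum distribution
      u <- w - n1 * (n1 + 1) / 2
      p_lo <- stats::pwilcox(u, n1, n2)
      p_hi <- 1 - stats::pwilcox(u - 1, n1, n2)
      return(min(1, 2 * min(p_lo, p_hi)))
    }
    # ties: enumerate every assignment of n1 labels to the midranks
    sums <- utils::combn(n1 + n2, n1, function(i) sum(r[i]))
    eps <- 1e-9
    p_lo <- mean(sums <= w + eps)
    p_hi <- mean(sums >= w - eps)
    return(min(1, 2 * min(p_lo, p_hi)))
  }

  # normal approximation, tie-corrected variance, no continuity correction
  n <- n1 + n2
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Fold-change + rank-sum screen for differential accumulation
#'
#' For each analyte, computes the mutant/wild fold change from group means
#' and a two-sided Wilcoxon rank-sum p-value, then classifies: `up` when
#' fold change >= `up`, `down` when <= `down`, otherwise `ns`. By default
#' the classification gates on fold change alone (the p-value is reported
#' but not used); supply `p_gate` to additionally require `p < p_gate`.
#' A zero wild-group mean with a positive mutant mean yields a missing
#' fold change but status `up` (the direction is unambiguous).
#'
#' @param table Numeric matrix or data frame, analytes in rows (rownames =
#'   analyte ids), samples in columns.
#' @param groups List with elements `mutant` and `wild`: column names or
#'   indices of the two groups.
#' @param up,down Fold-change thresholds (defaults 2 and 0.5).
#' @param p_gate Optional p-value gate (default `NULL`, no gate).
#' @return Data frame with one row per analyte: `analyte_id`, `mean_mut`,
#'   `mean_wild`, `fold_change`, `p_value`, `status`.
#' @export
metabolite_screen <- function(table, groups, up = 2.0, down = 0.5,
                              p_gate = NULL) {
  m <- as.matrix(table)
  if (!all(c("mutant", "wild") %in% names(groups))) {
    stop("groups must be a list with elements 'mutant' and 'wild'")
  }
  gm <- m[, groups$mutant, drop = FALSE]
  gw <- m[, groups$wild, drop = FALSE]
  if (ncol(gm) < 1 || ncol(gw) < 1) stop("each group needs >= 1 sample")
  if (any(m < 0)) stop("abundances must be nonnegative")
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("analyte_", seq_len(nrow(m)))

  out <- lapply(seq_len(nrow(m)), function(i) {
    mm <- mean(gm[i, ]); mw <- mean(gw[i, ])
    fc <- if (mw > 0) mm / mw else NA_real_
    p <- wilcoxon_rank_sum(gm[i, ], gw[i, ])
    status <- if (is.na(fc)) {
      if (mm > 0) "up" else "ns"
    } else if (fc >= up) "up" else if (fc <= down) "down" else "ns"
    if (!is.null(p_gate) && status != "ns" && p >= p_gate) status <- "ns"
    data.frame(analyte_id = ids[i], mean_mut = mm, mean_wild = mw,
               fold_change = fc, p_value = p, status = status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Log2 expression ratios for a gene set
#'
#' `log2((fpkm_mut + pseudocount) / (fpkm_wt + pseudocount))` per gene, the
#' usual way to display expression differences for a family (e.g. laccase
#' precursors) between mutant and wild type. Results are sorted ascending
#' (strongest down-regulation first), ties broken by `gene_id`.
#'
#' @param fpkm_table Data frame with columns `gene_id`, `fpkm_mut`,
#'   `fpkm_wt` (all FPKM >= 0).
#' @param pseudocount Positive stabilizer added to both FPKM values
#'   (default 0.01) so that zero expression yields a finite ratio. Use 0
#'   only when no FPKM is zero.
#' @return `fpkm_table` with a `log2_ratio` column, sorted ascending.
#' @export
expression_log2_ratio <- function(fpkm_table, pseudocount = 0.01) {
  need <- c("gene_id", "fpkm_mut", "fpkm_wt")
  if (!all(need %in% names(fpkm_table))) {
    stop("fpkm_table must have columns ", paste(need, collapse = ", "))
  }
  if (any(fpkm_table$fpkm_mut < 0) || any(fpkm_table$fpkm_wt < 0)) {
    stop("FPKM values must be nonnegative")
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  out <- fpkm_table
  out$log2_ratio <- log2((out$fpkm_mut + pseudocount) /
                           (out$fpkm_wt + pseudocount))
  out <- out[order(out$log2_ratio, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
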