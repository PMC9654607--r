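#' Donor-blocked likelihood-ratio test for paired expression data
#'
#' For each gene, compares nested ordinary-least-squares models on the
#' `log2(TPM + 1)` scale: the full model has an intercept, a treatment term
#' and donor indicators; the reduced model drops the treatment term. The
#' statistic is `N * ln(RSS_reduced / RSS_full)` with `N` the sample count,
#' and the p-value comes from the exact F equivalent of the nested
#' comparison (df1 = 1, df2 = N - n_donors - 1), which is exactly
#' calibrated under Gaussian noise. Donor blocking means the statistic is
#' unchanged by adding any constant to all of one donor's samples.
#'
#' For the balanced paired design the nested fit has a closed form in the
#' per-donor treated-minus-control differences `d_g`:
#' `RSS_full = sum_d (d_gd - mean(d_g))^2 / 2` and
#' `RSS_reduced = sum_d d_gd^2 / 2`, identical to per-gene `lm()` fits.
#'
#' Degenerate genes are flagged rather than erroring: a gene constant
#' across all samples gets statistic 0 and p = 1 (`flag = "constant"`);
#' a gene fitted perfectly by the full model gets p = 0
#' (`flag = "saturated"`).
#'
#' @param m Expression tibble on the `log2p1` scale.
#' @param design Paired design tibble (`donor`, `control_sample`,
#'   `treated_sample`); every referenced sample must be a column of `m`.
#' @return A tibble with one row per gene: `gene_id`, `lrt_stat`,
#'   `p_value`, `flag` (`NA`, `"constant"` or `"saturated"`).
#' @export
paired_lrt <- function(m, design) {
  design <- validate_paired_design(design, m)
  if (nrow(design) < 2) abort("Paired LRT needs >= 2 donors.")
  if (!identical(expr_scale(m), "log2p1")) {
    abort("paired_lrt() expects log2(TPM+1)-scale data; see log2p1_transform().")
  }
  vals <- as_expr_matrix(m)
  ctrl <- vals[, design$control_sample, drop = FALSE]
  trt <- vals[, design$treated_sample, drop = FALSE]
  n_don <- nrow(design)
  n_obs <- 2L * n_don

  diffs <- trt - ctrl
  dbar <- rowMeans(diffs)
  rss_full <- rowSums((diffs - dbar)^2) / 2
  rss_red <- rowSums(diffs^2) / 2

  # no_effect: all paired differences (numerically) zero, including genes
  # constant across every sample; saturated: the full model fits perfectly
  # while treatment explains a real difference.
  no_effect <- rss_red <= 1e-12
  saturated <- !no_effect & rss_full <= 1e-10 * rss_red
  regular <- !no_effect & !saturated

  lrt_stat <- rep(0, nrow(vals))
  p <- rep(1, nrow(vals))
  lrt_stat[regular] <- n_obs * log(rss_red[regular] / rss_full[regular])
  f_stat <- (rss_red[regular] - rss_full[regular]) /
    (rss_full[regular] / (n_don - 1))
  p[regular] <- pf(f_stat, 1, n_don - 1, lower.tail = FALSE)
  lrt_stat[saturated] <- Inf
  p[saturated] <- 0

  row_constant <- no_effect &
    apply(vals, 1, function(r) diff(range(r)) == 0)
  flag <- rep(NA_character_, nrow(vals))
  flag[row_constant] <- "constant"
  flag[saturated] <- "saturated"
  tibble(
    gene_id = rownames(vals),
    lrt_stat = pmax(0, lrt_stat),
    p_value = p,
    flag = flag
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Converts p-values to q-values controlling the false discovery rate:
#' `q_(i) = min over j >= i of p_(j) * m / j` on the sorted p-values,
#' mapped back to input order. Delegates to [stats::p.adjust()] after
#' validation.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) abort("bh_adjust() needs a non-empty p-value vector.")
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Paired log2 fold-changes
#'
#' The per-gene log2 fold-change is the mean over donors of the
#' treated-minus-control difference of `log2(TPM + 1)` — the paired
#' estimate, which respects donor blocking (and coincides with the pooled
#' difference of means under this balanced design).
#'
#' @inheritParams paired_lrt
#' @return A tibble with `gene_id` and `log2fc`.
#' @export
fold_changes <- function(m, design) {
  design <- validate_paired_design(design, m)
  if (!identical(expr_scale(m), "log2p1")) {
    abort("fold_changes() expects log2(TPM+1)-scale data.")
  }
  vals <- as_expr_matrix(m)
  diffs <- vals[, design$treated_sample, drop = FALSE] -
    vals[, design$control_sample, drop = FALSE]
  tibble(gene_id = rownames(vals), log2fc = unname(rowMeans(diffs)))
}

#' Run the full paired differential-expression analysis
#'
#' Combines [paired_lrt()], [fold_changes()] and [bh_adjust()] into one
#' results table.
#'
#' @inheritParams paired_lrt
#' @return A tibble with `gene_id`, `log2fc`, `lrt_stat`, `p_value`,
#'   `q_value`, `flag`.
#' @export
diff_expression <- function(m, design) {
  lrt <- paired_lrt(m, design)
  fc <- fold_changes(m, design)
  lrt %>%
    left_join(fc, by = "gene_id") %>%
    mutate(q_value = bh_adjust(.data$p_value)) %>%
    select("gene_id", "log2fc", "lrt_stat", "p_value", "q_value", "flag")
}

#' Select significantly responsive genes
#'
#' Applies the screening rule for cytokine-responsive genes: strictly
#' `q < q_max` and strictly more than `2^min_abs_log2fc`-fold changed in
#' the requested direction (defaults: q < 0.05 and > 2-fold). Output is
#' sorted by descending absolute log2 fold-change.
#'
#' @param results A differential-expression tibble with at least `gene_id`,
#'   `log2fc` and `q_value` (see [diff_expression()]).
#' @param q_max Strict upper bound on the q-value. Default 0.05.
#' @param min_abs_log2fc Strict lower bound on `|log2fc|`. Default 1.
#' @param direction `"up"` or `"down"`.
#' @return Character vector of gene ids.
#' @export
select_responsive_genes <- function(results, q_max = 0.05,
                                    min_abs_log2fc = 1,
                                    direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!nrow(results)) abort("Empty differential-expression results.")
  keep <- results$q_value < q_max &
    if (direction == "up") results$log2fc > min_abs_log2fc
    else results$log2fc < -min_abs_log2fc
  sel <- results[keep, , drop = FALSE]
  sel$gene_id[order(-abs(sel$log2fc))]
}
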