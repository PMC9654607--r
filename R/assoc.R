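#' Mann-Whitney U test
#'
#' `U` counts, over all cross-group pairs, the times an `x` value exceeds a
#' `y` value (ties count one half), reported for group `x`. The two-sided
#' p-value is exact (full enumeration, via [stats::wilcox.test()]) when
#' both groups have at most 8 observations and there are no ties, and
#' otherwise uses the normal approximation with tie and continuity
#' corrections.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @return A one-row tibble: `U`, `p_value`, `method` (`"exact"` or
#'   `"normal_approx"`).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4)) # U = 0, p = 1/3
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) abort("Both groups must be non-empty.")
  r <- rank(c(x, y))
  u <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- length(x) <= 8 && length(y) <= 8 && !has_ties
  p <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value
  )
  tibble(
    U = u, p_value = p,
    method = if (use_exact) "exact" else "normal_approx"
  )
}

#' Simple linear regression with a slope test
#'
#' Ordinary least squares of `y` on `x`; the slope p-value is the
#' two-sided t-test of zero slope on `n - 2` degrees of freedom. A perfect
#' fit (zero residual variance) is flagged and reported with `slope_p = 0`.
#'
#' @param x Predictor (must not be constant).
#' @param y Response.
#' @return A one-row tibble: `slope`, `intercept`, `slope_p`, `r_squared`,
#'   `exact_fit`.
#' @export
linear_regression <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length.")
  if (length(x) < 3) abort("Linear regression needs n >= 3.")
  if (diff(range(x)) == 0) abort("Constant predictor: slope undefined.")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  exact_fit <- rss <= 1e-12 * max(tss, 1)
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    slope_p = if (exact_fit) 0 else unname(sm$coefficients["x", "Pr(>|t|)"]),
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    exact_fit = exact_fit
  )
}

#' Compare mutational-signature exposures between signature groups
#'
#' One Mann-Whitney U test per exposure column (the APOBEC signatures SBS2
#' and SBS13, the non-APOBEC controls SBS4 and SBS5) plus neoantigen load,
#' comparing signature-high vs signature-low patients. P-values are
#' reported per variable without multiplicity adjustment, mirroring
#' per-panel testing.
#'
#' @param mutation Mutation tibble (see [read_mutation_table()]).
#' @param groups Stratification tibble from [kmeans2()] (`patient_id`,
#'   `label`). Patient ids must match the mutation table exactly.
#' @return A tibble with one row per variable: `variable`, `method`,
#'   `statistic` (U for the high group), `p_value`, `n_high`, `n_low`.
#' @export
compare_exposures <- function(mutation, groups) {
  only_m <- setdiff(mutation$patient_id, groups$patient_id)
  only_g <- setdiff(groups$patient_id, mutation$patient_id)
  if (length(only_m) || length(only_g)) {
    abort(paste0(
      "Patient ids disagree. Only in mutation table: ",
      paste(head(only_m, 5), collapse = ", "),
      "; only in groups: ", paste(head(only_g, 5), collapse = ", ")
    ))
  }
  merged <- dplyr::inner_join(mutation, groups[c("patient_id", "label")],
                              by = "patient_id")
  if (!all(c("high", "low") %in% merged$label)) {
    abort("Both a high and a low group are required.")
  }
  vars <- c("SBS2", "SBS13", "SBS4", "SBS5", "neoantigen_load")
  purrr::map_dfr(vars, function(v) {
    hi <- merged[[v]][merged$label == "high"]
    lo <- merged[[v]][merged$label == "low"]
    res <- mann_whitney_u(hi, lo)
    tibble(
      variable = v, method = "mann_whitney_u",
      statistic = res$U, p_value = res$p_value,
      n_high = length(hi), n_low = length(lo)
    )
  })
}

#' Regress neoantigen load on the signature score
#'
#' Linear regression with neoantigen load as the response and the
#' continuous signature score as the predictor. Optionally `log1p`
#' transforms the load first (off by default).
#'
#' @param mutation Mutation tibble.
#' @param scores Score tibble from [compute_scores()].
#' @param log1p_load Apply `log1p` to the load before regressing?
#' @return A one-row tibble: `variable`, `method`, `statistic` (t-oriented
#'   slope), `p_value`, `slope`, `intercept`, `r_squared`.
#' @export
regress_neoantigens <- function(mutation, scores, log1p_load = FALSE) {
  merged <- dplyr::inner_join(
    mutation[c("patient_id", "neoantigen_load")],
    scores[c("patient_id", "score")],
    by = "patient_id"
  )
  if (nrow(merged) < 3) abort("Need >= 3 matched patients.")
  y <- if (log1p_load) log1p(merged$neoantigen_load) else merged$neoantigen_load
  res <- linear_regression(merged$score, y)
  tibble(
    variable = "neoantigen_load", method = "linear_regression",
    statistic = res$slope, p_value = res$slope_p,
    slope = res$slope, intercept = res$intercept, r_squared = res$r_squared
  )
}
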