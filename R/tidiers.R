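#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Cox proportional-hazards fit
#'
#' @param x A `uro_cox` object from [cox_ph()].
#' @param ... Unused.
#' @return A one-row tibble with `term`, `estimate` (log hazard ratio),
#'   `std.error`, `statistic` (Wald z), `p.value`, `hr`, `conf.low`,
#'   `conf.high` (on the hazard-ratio scale).
#' @export
tidy.uro_cox <- function(x, ...) {
  tibble(
    term = "score",
    estimate = x$beta,
    std.error = x$se,
    statistic = x$beta / x$se,
    p.value = x$wald_p,
    hr = x$hr,
    conf.low = x$ci_lo,
    conf.high = x$ci_hi
  )
}

#' @rdname tidy.uro_cox
#' @return `glance.uro_cox()`: a one-row tibble with `n`, `n_event`,
#'   `score_chisq`, `score_p`, `iterations`, `converged`, `ties`.
#' @export
glance.uro_cox <- function(x, ...) {
  tibble(
    n = x$n, n_event = x$n_event,
    score_chisq = x$score_chisq, score_p = x$score_p,
    iterations = x$iterations, converged = x$converged, ties = x$ties
  )
}

#' Tidy a consensus gene signature
#'
#' @param x A `uro_signature` from [refine_signature()].
#' @param ... Unused.
#' @return `tidy()`: the per-candidate table of per-cohort median Spearman
#'   rhos, `mean_rho` and `retained`. `glance()`: one row with
#'   `n_candidates`, `n_retained`, `rho_threshold`.
#' @export
tidy.uro_signature <- function(x, ...) x$table

#' @rdname tidy.uro_signature
#' @export
glance.uro_signature <- function(x, ...) {
  tibble(
    n_candidates = nrow(x$table),
    n_retained = length(x$genes),
    rho_threshold = x$rho_threshold
  )
}
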