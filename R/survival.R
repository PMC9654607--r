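#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] for a single group:
#' `S(t) = prod over event times t_j <= t of (1 - d_j / n_j)`. Individuals
#' censored at an event time are counted at risk at that time (the
#' standard convention). With no events at all the curve is identically 1.
#'
#' @param records Clinical tibble (`patient_id`, `time`, `event`).
#' @param group Optional group label attached to every row of the result
#'   (useful for plotting several curves together).
#' @return A tibble of class `uro_km`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival` (and `group` if given), one row per distinct
#'   observed time.
#' @export
km_estimate <- function(records, group = NULL) {
  if (!nrow(records)) abort("No records.")
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1,
    data = as.data.frame(records)
  )
  out <- tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv
  )
  if (!is.null(group)) out$group <- group
  class(out) <- c("uro_km", class(out))
  out
}

# Per-distinct-event-time 2x2 tables for two groups: at-risk counts, event
# counts, the expected events in group a under the null, and the
# hypergeometric variance. The shared backbone of the two-group tests and
# hazard-ratio estimators.
.logrank_tables <- function(a, b) {
  if (!nrow(a) || !nrow(b)) abort("Both groups must be non-empty.")
  time <- c(a$time, b$time)
  event <- c(a$event, b$event)
  in_a <- rep(c(TRUE, FALSE), c(nrow(a), nrow(b)))
  etimes <- sort(unique(time[event == 1]))
  if (!length(etimes)) abort("No events in either group.")
  purrr::map_dfr(etimes, function(t0) {
    at_risk <- time >= t0
    # doubles throughout: the variance product overflows integer range
    n <- as.numeric(sum(at_risk))
    n_a <- as.numeric(sum(at_risk & in_a))
    d <- as.numeric(sum(time == t0 & event == 1))
    d_a <- as.numeric(sum(time == t0 & event == 1 & in_a))
    v <- if (n > 1) n_a * (n - n_a) * d * (n - d) / (n^2 * (n - 1)) else 0
    tibble(
      time = t0, n = n, n_a = n_a, n_b = n - n_a,
      d = d, d_a = d_a, e_a = n_a * d / n, v = v
    )
  })
}

.two_group_test <- function(a, b, weights_fun, method) {
  tab <- .logrank_tables(a, b)
  w <- weights_fun(tab)
  denom <- sum(w^2 * tab$v)
  if (denom <= 0) {
    abort(sprintf(
      "Zero total variance in the %s test (every event time has d = n); groups cannot be compared.",
      method
    ))
  }
  num <- sum(w * (tab$d_a - tab$e_a))
  chi <- num^2 / denom
  tibble(
    method = method,
    chi_square = chi,
    p_value = pchisq(chi, df = 1, lower.tail = FALSE),
    observed_a = sum(tab$d_a),
    expected_a = sum(tab$e_a),
    observed_b = sum(tab$d - tab$d_a),
    expected_b = sum(tab$d - tab$e_a),
    variance_sum = sum(tab$v)
  )
}

#' Log-rank (Mantel-Cox) two-group survival test
#'
#' At each distinct event time, observed events in group `a` are compared
#' with their expectation under the null (`E_a = n_a d / n`) with the
#' hypergeometric variance; the chi-square statistic is
#' `(sum O_a - sum E_a)^2 / sum V` on 1 degree of freedom, two-sided.
#'
#' @param a,b Clinical tibbles for the two groups.
#' @return A one-row tibble: `method`, `chi_square`, `p_value`,
#'   observed/expected per group, `variance_sum`.
#' @export
logrank_test <- function(a, b) {
  .two_group_test(a, b, function(tab) rep(1, nrow(tab)), "mantel_cox")
}

#' Gehan-Breslow-Wilcoxon two-group survival test
#'
#' The log-rank family with weight `w_j = n_j` (total at risk) at each
#' event time, emphasising early differences between the curves:
#' `chi = (sum w_j (O_aj - E_aj))^2 / (sum w_j^2 V_j)`.
#'
#' @inheritParams logrank_test
#' @return A one-row tibble in the same layout as [logrank_test()].
#' @export
gehan_breslow_wilcoxon <- function(a, b) {
  .two_group_test(a, b, function(tab) tab$n, "gehan_breslow_wilcoxon")
}

#' Two-group hazard-ratio estimates
#'
#' Mantel-Haenszel form: `HR = exp((O_a - E_a) / V)` with
#' `CI = exp((O_a - E_a)/V +- 1.96 / sqrt(V))`. Log-rank (O/E ratio) form:
#' `HR = (O_a / E_a) / (O_b / E_b)` with the same normal-approximation CI
#' around its log. Both report group `a` relative to group `b`; swapping
#' the groups inverts the ratio.
#'
#' @inheritParams logrank_test
#' @param method `"mantel_haenszel"` or `"logrank_oe"`.
#' @return A one-row tibble: `method`, `hr`, `ci_lo`, `ci_hi`.
#' @export
hazard_ratio <- function(a, b, method = c("mantel_haenszel", "logrank_oe")) {
  method <- match.arg(method)
  if (!any(a$event == 1) || !any(b$event == 1)) {
    abort("Both groups need at least one event for a hazard ratio.")
  }
  tab <- .logrank_tables(a, b)
  o_a <- sum(tab$d_a)
  e_a <- sum(tab$e_a)
  o_b <- sum(tab$d - tab$d_a)
  e_b <- sum(tab$d - tab$e_a)
  v <- sum(tab$v)
  if (v <= 0) abort("Zero total variance; hazard ratio undefined.")
  if (method == "mantel_haenszel") {
    log_hr <- (o_a - e_a) / v
  } else {
    if (o_b == 0 || e_b == 0 || e_a == 0) {
      abort("O/E hazard ratio undefined: a group has zero observed or expected events.")
    }
    log_hr <- log((o_a / e_a) / (o_b / e_b))
  }
  half <- 1.96 / sqrt(v)
  tibble(
    method = method,
    hr = exp(log_hr),
    ci_lo = exp(log_hr - half),
    ci_hi = exp(log_hr + half)
  )
}

#' Cox proportional-hazards regression on a single covariate
#'
#' Fits the partial likelihood for one covariate (here, the
#' pseudo-continuous signature score) via [survival::coxph()], Efron tie
#' handling by default (Breslow available; the two agree exactly when no
#' event times are tied). Reports the log hazard ratio, its standard error
#' from the observed information, the Wald p-value, the hazard ratio with
#' 95% CI, and the score test at beta = 0 (which equals the log-rank
#' chi-square for a binary covariate without ties).
#'
#' @param records Clinical tibble.
#' @param covariate Numeric vector aligned with `records` (or named by
#'   patient id).
#' @param ties `"efron"` or `"breslow"`.
#' @return An object of class `uro_cox` (see [tidy.uro_cox()],
#'   [glance.uro_cox()]).
#' @export
cox_ph <- function(records, covariate, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (!is.null(names(covariate))) covariate <- covariate[records$patient_id]
  if (length(covariate) != nrow(records)) {
    abort("Covariate length must match the clinical table.")
  }
  if (sum(records$event) < 2) abort("Cox regression needs >= 2 events.")
  if (diff(range(covariate)) == 0) {
    abort("Constant covariate: hazard ratio unidentifiable.")
  }
  dat <- data.frame(time = records$time, event = records$event, x = covariate)
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(
      survival::Surv(time, event) ~ x,
      data = dat, ties = ties,
      control = survival::coxph.control(eps = 1e-9, iter.max = 50)
    ),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w))) {
        monotone <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  s <- summary(fit)
  beta <- unname(coef(fit))
  se <- unname(sqrt(fit$var[1, 1]))
  structure(
    list(
      beta = beta, se = se, hr = exp(beta),
      wald_p = unname(s$coefficients[1, "Pr(>|z|)"]),
      ci_lo = exp(beta - qnorm(0.975) * se),
      ci_hi = exp(beta + qnorm(0.975) * se),
      score_chisq = unname(s$sctest[["test"]]),
      score_p = unname(s$sctest[["pvalue"]]),
      iterations = fit$iter,
      converged = !monotone,
      n = nrow(dat), n_event = sum(dat$event),
      ties = ties, fit = fit
    ),
    class = "uro_cox"
  )
}

#' @export
print.uro_cox <- function(x, ...) {
  cat(sprintf(
    "Cox PH fit (%s ties): HR = %.4g (95%% CI %.4g-%.4g), beta = %.4g (se %.4g), Wald p = %.3g%s\n",
    x$ties, x$hr, x$ci_lo, x$ci_hi, x$beta, x$se, x$wald_p,
    if (x$converged) "" else " [non-convergence: possible monotone likelihood]"
  ))
  invisible(x)
}
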