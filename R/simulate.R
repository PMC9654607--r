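#' Simulate a paired control/treated in vitro expression experiment
#'
#' Emulates the design used to find interferon-gamma (IFN-gamma) responsive
#' genes in differentiated normal human urothelium: each donor contributes
#' one control and one cytokine-treated culture, and a planted subset of
#' genes responds with a log2 fold-change drawn from
#' `[effect_lo, effect_hi]` (up genes) or its negation (down genes).
#'
#' Values are built additively on the `log2(TPM + 1)` scale as
#' `baseline_g + donor_d + effect_g * treated + noise` with Gaussian noise,
#' then back-transformed to TPM via `max(0, 2^x - 1)`. The fraction of cells
#' clipped at zero is recorded in the returned truth; it is zero whenever
#' baselines sit comfortably above the noise floor.
#'
#' @param n_donors Number of donors (>= 2; the paired test is undefined
#'   below that). Default 6, the in vitro design size.
#' @param n_genes Total genes in the simulated transcriptome.
#' @param n_up,n_down Number of genes planted as up-/down-regulated.
#' @param effect_lo,effect_hi Bounds (log2 units) for the planted absolute
#'   effect sizes; `effect_lo` > 1 so planted genes clear a 2-fold screen.
#' @param noise_sd Residual standard deviation on the log2 scale.
#' @param donor_effect_sd Standard deviation of donor baseline shifts.
#' @param seed Integer seed; calls are pure functions of their arguments.
#' @return A list with `expression` (TPM-scale expression tibble), `design`
#'   (donor/control/treated tibble) and `truth` (planted gene sets, effects
#'   and parameters, including `clip_fraction`).
#' @examples
#' sim <- generate_invitro(n_genes = 50, n_up = 5, n_down = 3, seed = 1)
#' sim$design
#' @export
generate_invitro <- function(n_donors = 6, n_genes = 2000,
                             n_up = 107, n_down = 48,
                             effect_lo = 1.2, effect_hi = 3,
                             noise_sd = 0.4, donor_effect_sd = 0.5,
                             seed) {
  if (n_donors < 2) abort("Need >= 2 donors for a paired design.")
  if (n_up + n_down > n_genes) abort("n_up + n_down exceeds n_genes.")
  if (n_up > 0 && effect_lo <= 1) {
    abort("effect_lo must exceed 1 (log2 units) so up genes clear 2-fold.")
  }
  if (noise_sd <= 0) abort("noise_sd must be positive.")
  .with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    up_genes <- if (n_up) genes[seq_len(n_up)] else character()
    down_genes <- if (n_down) genes[n_up + seq_len(n_down)] else character()
    null_genes <- setdiff(genes, c(up_genes, down_genes))
    effect <- setNames(numeric(n_genes), genes)
    effect[up_genes] <- runif(n_up, effect_lo, effect_hi)
    effect[down_genes] <- -runif(n_down, effect_lo, effect_hi)

    donors <- sprintf("D%02d", seq_len(n_donors))
    donor_shift <- rnorm(n_donors, 0, donor_effect_sd)
    baseline <- runif(n_genes, 4, 10)

    log_ctrl <- outer(baseline, donor_shift, `+`) +
      matrix(rnorm(n_genes * n_donors, 0, noise_sd), n_genes, n_donors)
    log_trt <- outer(baseline + effect, donor_shift, `+`) +
      matrix(rnorm(n_genes * n_donors, 0, noise_sd), n_genes, n_donors)

    log_all <- cbind(log_ctrl, log_trt)
    clip_fraction <- mean(log_all < 0)
    tpm <- pmax(2^log_all - 1, 0)
    colnames(tpm) <- c(paste0(donors, "_ctrl"), paste0(donors, "_ifng"))

    expression <- expression_tbl(
      as_tibble(cbind(tibble(gene_id = genes), as.data.frame(tpm))),
      scale = "tpm"
    )
    design <- tibble(
      donor = donors,
      control_sample = paste0(donors, "_ctrl"),
      treated_sample = paste0(donors, "_ifng")
    )
    truth <- list(
      up_genes = up_genes, down_genes = down_genes, null_genes = null_genes,
      effect = effect, noise_sd = noise_sd, donor_effect_sd = donor_effect_sd,
      clip_fraction = clip_fraction, seed = seed
    )
    list(expression = expression, design = design, truth = truth)
  })
}

#' Simulate a tumour cohort driven by a latent IFN-gamma activity factor
#'
#' Each patient carries a latent activity `A_p` drawn from a two-component
#' Gaussian mixture (the high/low bimodality seen in tumour heatmaps, and
#' what k-means stratification is meant to recover). Expression on the
#' `log2(TPM + 1)` scale is `baseline_g + lambda_g * A_p + noise`, with a
#' strong loading `lambda_g = loading` for the planted module genes and a
#' weak loading `background_loading` for the remaining candidate genes,
#' then back-transformed to TPM.
#'
#' The weak background tier mirrors the biological situation the
#' correlation-consensus filter exploits: all candidates respond to the
#' cytokine in vitro, but only a core module co-expresses tightly in
#' tumours. With the defaults, planted module genes reach pairwise median
#' Spearman rho well above 0.5 while background candidates stay well below
#' it, so consensus refinement recovers exactly the module. Set
#' `background_loading = 0` for fully independent background genes.
#'
#' @param n_patients Cohort size.
#' @param module_genes Character vector of planted module gene ids.
#' @param n_background Number of weakly loading background candidate genes
#'   (named `BG0001`, `BG0002`, ...).
#' @param background_genes Optional explicit ids for the background genes
#'   (overrides `n_background`); useful when the background tier should
#'   carry the names of real candidate genes.
#' @param loading Module-gene loading on the latent activity.
#' @param background_loading Background-gene loading (default 0.35).
#' @param noise_sd Residual standard deviation on the log2 scale.
#' @param activity_mix Named vector `c(p_high, mu_low, mu_high, sd)`: mixing
#'   weight of the high-activity component, component means, and the shared
#'   within-component standard deviation.
#' @param planted_hr Planted low-vs-high hazard ratio carried in the truth
#'   for downstream survival simulation (> 0; hazard decreases with score).
#' @param censor_time Administrative censoring time (months) carried in the
#'   truth.
#' @param seed Integer seed.
#' @return A list with `expression` (TPM tibble over
#'   `module_genes` + background genes) and `truth` (latent activity,
#'   loadings, baselines, mixture component labels, `clip_fraction`,
#'   `planted_hr`, `censor_time`).
#' @export
generate_cohort <- function(n_patients = 200, module_genes,
                            n_background = 117, background_genes = NULL,
                            loading = 1.5, background_loading = 0.35,
                            noise_sd = 0.5,
                            activity_mix = c(p_high = 0.5, mu_low = 0,
                                             mu_high = 2, sd = 0.5),
                            planted_hr = 3, censor_time = 60,
                            seed) {
  if (!length(module_genes)) abort("module_genes must be non-empty.")
  if (loading < 0 || background_loading < 0) abort("Loadings must be >= 0.")
  if (noise_sd <= 0) abort("noise_sd must be positive.")
  if (planted_hr <= 0) abort("planted_hr must be positive.")
  p_high <- activity_mix[["p_high"]]
  if (p_high < 0 || p_high > 1) abort("p_high must lie in [0, 1].")
  .with_seed(seed, {
    module_genes <- unique(as.character(module_genes))
    bg_genes <- if (!is.null(background_genes)) {
      setdiff(unique(as.character(background_genes)), module_genes)
    } else if (n_background) {
      sprintf("BG%04d", seq_len(n_background))
    } else {
      character()
    }
    genes <- c(module_genes, bg_genes)
    patients <- sprintf("P%04d", seq_len(n_patients))

    comp_high <- rbinom(n_patients, 1, p_high) == 1
    activity <- ifelse(comp_high, activity_mix[["mu_high"]],
                       activity_mix[["mu_low"]]) +
      rnorm(n_patients, 0, activity_mix[["sd"]])

    lambda <- setNames(
      c(rep(loading, length(module_genes)),
        rep(background_loading, length(bg_genes))),
      genes
    )
    baseline <- setNames(runif(length(genes), 4, 10), genes)

    log_vals <- outer(lambda, activity) + baseline +
      matrix(rnorm(length(genes) * n_patients, 0, noise_sd),
             length(genes), n_patients)
    clip_fraction <- mean(log_vals < 0)
    tpm <- pmax(2^log_vals - 1, 0)
    colnames(tpm) <- patients

    expression <- expression_tbl(
      as_tibble(cbind(tibble(gene_id = genes), as.data.frame(tpm))),
      scale = "tpm"
    )
    truth <- list(
      patient_ids = patients, latent_activity = setNames(activity, patients),
      component_high = setNames(comp_high, patients),
      loadings = lambda, baseline = baseline, noise_sd = noise_sd,
      module_genes = module_genes, background_genes = bg_genes,
      planted_hr = planted_hr, censor_time = censor_time,
      clip_fraction = clip_fraction, seed = seed
    )
    list(expression = expression, truth = truth)
  })
}

#' Simulate survival outcomes under a proportional-hazards model in the score
#'
#' Event times are exponential with per-patient hazard
#' `baseline_hazard * planted_hr^(-score)`, so a LOW signature score means a
#' HIGHER hazard: `planted_hr` is the low-vs-high hazard ratio, matching the
#' direction in which signature-low tumours do worse. Administrative
#' censoring is applied at `truth$censor_time`.
#'
#' @param truth Cohort truth from [generate_cohort()] (supplies `planted_hr`
#'   and `censor_time`).
#' @param scores A score table (see [compute_scores()]) with `patient_id`
#'   and `score` in `[0, 1]`.
#' @param baseline_hazard Hazard (events per month) at score 0. Default
#'   0.05.
#' @param endpoint Endpoint label stored on the result.
#' @param seed Integer seed.
#' @return A clinical tibble (`patient_id`, `time`, `event`).
#' @export
generate_survival <- function(truth, scores, baseline_hazard = 0.05,
                              endpoint = c("RFS", "OS"), seed) {
  endpoint <- match.arg(endpoint)
  if (baseline_hazard <= 0) abort("baseline_hazard must be positive.")
  if (!all(c("patient_id", "score") %in% names(scores))) {
    abort("`scores` needs patient_id and score columns.")
  }
  s <- scores$score
  if (any(s < -1e-9 | s > 1 + 1e-9)) {
    abort("Scores must be rescaled to [0, 1] before survival simulation.")
  }
  .with_seed(seed, {
    rate <- baseline_hazard * truth$planted_hr^(-s)
    t_event <- rexp(length(s), rate = rate)
    time <- pmin(t_event, truth$censor_time)
    event <- as.numeric(t_event <= truth$censor_time)
    validate_clinical(
      tibble(patient_id = scores$patient_id, time = time, event = event),
      endpoint
    )
  })
}

#' Simulate mutational-signature exposures and neoantigen load
#'
#' APOBEC-attributed exposures (SBS2, SBS13) are log-normal with log-mean
#' shifted by `enrich * A_p` where `A_p` is the latent activity, so high
#' IFN-gamma activity is enriched for APOBEC damage; the control signatures
#' SBS4 and SBS5 are log-normal and independent of activity. Neoantigen
#' load is Poisson with log-mean tied to the patient's total APOBEC
#' exposure (`log1p(SBS2 + SBS13)`), coupling load to activity through the
#' APOBEC channel. `enrich = 0` decouples everything from activity.
#'
#' @param truth Cohort truth from [generate_cohort()].
#' @param enrich Enrichment of the APOBEC log-mean per unit latent activity
#'   (>= 0). Default 1.
#' @param seed Integer seed.
#' @return A mutation tibble (`patient_id`, `SBS2`, `SBS13`, `SBS4`, `SBS5`,
#'   `neoantigen_load`).
#' @export
generate_mutation_table <- function(truth, enrich = 1, seed) {
  if (enrich < 0) abort("enrich must be >= 0.")
  .with_seed(seed, {
    a <- truth$latent_activity
    n <- length(a)
    sbs2 <- rlnorm(n, meanlog = 3.5 + enrich * a, sdlog = 0.8)
    sbs13 <- rlnorm(n, meanlog = 3.2 + enrich * a, sdlog = 0.8)
    sbs4 <- rlnorm(n, meanlog = 3.5, sdlog = 0.8)
    sbs5 <- rlnorm(n, meanlog = 4.0, sdlog = 0.8)
    neo <- rpois(n, lambda = exp(0.5 + 0.55 * log1p(sbs2 + sbs13)))
    validate_mutation_table(tibble(
      patient_id = names(a),
      SBS2 = sbs2, SBS13 = sbs13, SBS4 = sbs4, SBS5 = sbs5,
      neoantigen_load = neo
    ))
  })
}
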