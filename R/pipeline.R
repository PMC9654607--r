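#' Read and write signature files
#'
#' The signature travels as a TSV with columns `gene_id`, per-cohort
#' `rho_*` columns, `mean_rho` and `retained`, plus a `# rho_threshold=`
#' header comment.
#'
#' @param sig A `uro_signature`.
#' @param path Destination/source path.
#' @return `write_signature()`: `path` invisibly; `read_signature()`: a
#'   `uro_signature`.
#' @export
write_signature <- function(sig, path) {
  writeLines(c(
    sprintf("# rho_threshold=%.17g", sig$rho_threshold),
    sub("\n$", "", readr::format_tsv(sig$table))
  ), path)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  first <- readLines(path, n = 1)
  thr <- if (startsWith(first, "# rho_threshold=")) {
    as.numeric(sub("# rho_threshold=", "", first))
  } else {
    0.5
  }
  tab <- readr::read_tsv(path, comment = "#", progress = FALSE,
                         show_col_types = FALSE)
  tab <- as_tibble(tab)
  structure(
    list(
      genes = tab$gene_id[tab$retained][order(-tab$mean_rho[tab$retained])],
      table = tab, rho_threshold = thr
    ),
    class = "uro_signature"
  )
}

#' Default pipeline configuration
#'
#' Thresholds default to the derivation rules: strict q < 0.05,
#' > 2-fold change (|log2FC| > 1), consensus mean Spearman rho > 0.5,
#' k-means with 50 restarts.
#'
#' @param ... Named overrides.
#' @return A named list of configuration values.
#' @export
default_config <- function(...) {
  modifyList(list(
    q_max = 0.05,
    min_abs_log2fc = 1,
    rho_threshold = 0.5,
    kmeans_n_init = 50,
    seed = 1L,
    log1p_load = FALSE
  ), list(...))
}

#' @rdname default_config
#' @param path Path to a YAML configuration file; keys override the
#'   defaults.
#' @export
read_pipeline_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

.write_provenance <- function(out_dir, stage, info) {
  if (is.null(out_dir)) return(invisible(NULL))
  jsonlite::write_json(
    c(list(stage = stage, timestamp = format(Sys.time(), tz = "UTC")), info),
    file.path(out_dir, paste0(stage, "_provenance.json")),
    auto_unbox = TRUE, digits = NA
  )
  invisible(NULL)
}

#' Derive the consensus signature end-to-end
#'
#' Runs the derivation arm of the pipeline: donor-blocked differential
#' expression on the paired in vitro experiment, selection of the
#' up-regulated candidates (strict q < `q_max`, log2FC > `min_abs_log2fc`),
#' then correlation-consensus refinement across the tumour cohorts.
#'
#' @param invitro Expression tibble of the paired experiment (`tpm` or
#'   `log2p1` scale; TPM is log-transformed internally).
#' @param design Paired design tibble.
#' @param cohorts Named list of >= 2 cohort expression tibbles (TPM is
#'   log-transformed internally).
#' @param config Configuration list from [default_config()].
#' @param out_dir Optional directory for artifacts (DE table, candidate
#'   lists, signature file, provenance record).
#' @return A list: `de` (full DE tibble), `up_genes`, `down_genes`,
#'   `signature` (`uro_signature`), `counts` (rows surviving each filter).
#' @export
run_derivation <- function(invitro, design, cohorts,
                           config = default_config(), out_dir = NULL) {
  if (identical(expr_scale(invitro), "tpm")) invitro <- log2p1_transform(invitro)
  cohorts <- purrr::map(cohorts, function(co) {
    if (identical(expr_scale(co), "tpm")) log2p1_transform(co) else co
  })
  de <- diff_expression(invitro, design)
  up <- select_responsive_genes(de, config$q_max, config$min_abs_log2fc, "up")
  down <- select_responsive_genes(de, config$q_max, config$min_abs_log2fc, "down")
  if (!length(up)) {
    warn("No up-regulated candidates passed the thresholds; signature will be empty.")
    sig <- structure(
      list(genes = character(),
           table = tibble(gene_id = character(), mean_rho = numeric(),
                          retained = logical()),
           rho_threshold = config$rho_threshold),
      class = "uro_signature"
    )
  } else {
    sig <- refine_signature(up, cohorts, config$rho_threshold)
  }
  counts <- list(
    n_genes_tested = nrow(de),
    n_up_candidates = length(up),
    n_down = length(down),
    n_signature = length(sig$genes)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(de, file.path(out_dir, "de_results.tsv"), progress = FALSE)
    write_gene_list(up, file.path(out_dir, "up_genes.txt"))
    write_gene_list(down, file.path(out_dir, "down_genes.txt"))
    write_signature(sig, file.path(out_dir, "signature.tsv"))
    .write_provenance(out_dir, "derivation", c(
      counts, config[c("q_max", "min_abs_log2fc", "rho_threshold")]
    ))
  }
  list(de = de, up_genes = up, down_genes = down, signature = sig,
       counts = counts)
}

#' Score, stratify and analyse tumour cohorts
#'
#' Runs the analysis arm for one or more cohorts under a pooling plan:
#'
#' * `"pool_expression"` — cohorts are merged into one expression matrix
#'   before scoring and clustering (the plan used for T1 non-muscle-
#'   invasive tumours from separate clinical series on the same platform).
#' * `"pool_groups"` — each cohort is scored and clustered separately and
#'   only the high/low labels are pooled for survival analysis (the plan
#'   used for muscle-invasive cohorts on different platforms).
#'
#' The pooled groups are compared by Kaplan-Meier curves, the Mantel-Cox
#' and Gehan-Breslow-Wilcoxon tests, hazard ratios in both the
#' Mantel-Haenszel and O/E-ratio forms (low vs high, so a ratio above 1
#' means signature-low patients fare worse), and Cox regression on the
#' continuous score. If a mutation table is supplied, group-wise exposure
#' comparisons and the neoantigen-load regression are added.
#'
#' @param cohorts Named list of cohort expression tibbles (TPM is
#'   log-transformed internally; array cohorts pass through).
#' @param signature `uro_signature` or character vector of signature genes.
#' @param clinical Clinical tibble covering the scored patients (rows for
#'   patients missing from the cohorts are ignored, and patients without
#'   clinical rows are dropped from survival with a message).
#' @param pooling `"pool_expression"` or `"pool_groups"`.
#' @param config Configuration list from [default_config()]; supplies the
#'   k-means seed and restart count.
#' @param mutation Optional mutation tibble.
#' @param out_dir Optional artifact directory.
#' @return A list: `scores`, `groups`, `km` (curve tibble with `group`),
#'   `tests` (both two-group tests), `hazard_ratios` (both forms, low vs
#'   high), `cox` (`uro_cox`), and optionally `associations`.
#' @export
run_cohort_analysis <- function(cohorts, signature, clinical,
                                pooling = c("pool_expression", "pool_groups"),
                                config = default_config(),
                                mutation = NULL, out_dir = NULL) {
  pooling <- match.arg(pooling)
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts)))) {
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  }
  cohorts <- purrr::map(cohorts, function(co) {
    if (identical(expr_scale(co), "tpm")) log2p1_transform(co) else co
  })

  if (pooling == "pool_expression") {
    pooled <- purrr::reduce(cohorts, function(a, b) {
      shared <- intersect(a$gene_id, b$gene_id)
      merged <- dplyr::inner_join(
        a[a$gene_id %in% shared, ], b[b$gene_id %in% shared, ],
        by = "gene_id"
      )
      attr(merged, "expr_scale") <- expr_scale(a)
      merged
    })
    label <- paste(names(cohorts), collapse = "+")
    scores <- compute_scores(pooled, signature, cohort = label)
    groups <- kmeans2(pooled, scores, genes = signature,
                      seed = config$seed, n_init = config$kmeans_n_init)
    groups$cohort <- label
  } else {
    per <- purrr::imap(cohorts, function(co, nm) {
      sc <- compute_scores(co, signature, cohort = nm)
      gr <- kmeans2(co, sc, genes = signature,
                    seed = config$seed, n_init = config$kmeans_n_init)
      gr$cohort <- nm
      list(scores = sc, groups = gr)
    })
    scores <- purrr::map_dfr(per, "scores")
    groups <- purrr::map_dfr(per, "groups")
  }

  with_clin <- dplyr::inner_join(
    groups, clinical, by = "patient_id"
  )
  n_missing <- nrow(groups) - nrow(with_clin)
  if (n_missing > 0) {
    inform(sprintf("%d patient(s) without survival data excluded.", n_missing))
  }
  hi <- with_clin[with_clin$label == "high", ]
  lo <- with_clin[with_clin$label == "low", ]
  km <- dplyr::bind_rows(
    km_estimate(hi, group = "high"),
    km_estimate(lo, group = "low")
  )
  class(km) <- c("uro_km", class(tibble()))
  tests <- dplyr::bind_rows(logrank_test(lo, hi), gehan_breslow_wilcoxon(lo, hi))
  hrs <- dplyr::bind_rows(
    hazard_ratio(lo, hi, "mantel_haenszel"),
    hazard_ratio(lo, hi, "logrank_oe")
  )
  cox <- cox_ph(with_clin,
                setNames(with_clin$score, with_clin$patient_id))

  out <- list(scores = scores, groups = groups, km = km, tests = tests,
              hazard_ratios = hrs, cox = cox)
  if (!is.null(mutation)) {
    out$associations <- dplyr::bind_rows(
      compare_exposures(mutation, groups),
      regress_neoantigens(mutation, scores,
                          log1p_load = isTRUE(config$log1p_load))
    )
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(scores, file.path(out_dir, "scores.tsv"), progress = FALSE)
    readr::write_tsv(groups, file.path(out_dir, "groups.tsv"), progress = FALSE)
    readr::write_tsv(km, file.path(out_dir, "km_curves.tsv"), progress = FALSE)
    readr::write_tsv(tests, file.path(out_dir, "tests.tsv"), progress = FALSE)
    readr::write_tsv(hrs, file.path(out_dir, "hazard_ratios.tsv"), progress = FALSE)
    readr::write_tsv(tidy(cox), file.path(out_dir, "cox.tsv"), progress = FALSE)
    if (!is.null(out$associations)) {
      readr::write_tsv(out$associations,
                       file.path(out_dir, "associations.tsv"), progress = FALSE)
    }
    .write_provenance(out_dir, "cohort_analysis", list(
      pooling = pooling, seed = config$seed,
      n_patients = nrow(groups),
      n_with_survival = nrow(with_clin),
      n_high = sum(groups$label == "high"),
      n_low = sum(groups$label == "low")
    ))
  }
  out
}

#' Simulate a complete synthetic study and write its tables
#'
#' Generates the paired in vitro experiment, two tumour cohorts driven by
#' the same planted module, survival outcomes for the first cohort and a
#' mutation table, and writes everything as TSV plus a ground-truth JSON.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_module Planted module size. Default 33.
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param ... Passed on to [generate_cohort()].
#' @return Invisibly, a list of the generated objects.
#' @export
simulate_all <- function(out_dir, n_module = 33, seed, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  invitro <- generate_invitro(seed = seed)
  module <- invitro$truth$up_genes[seq_len(n_module)]
  coh1 <- generate_cohort(module_genes = module, seed = seed + 1, ...)
  coh2 <- generate_cohort(module_genes = module, seed = seed + 2, ...)
  scores <- compute_scores(log2p1_transform(coh1$expression), module,
                           cohort = "cohort1")
  clinical <- generate_survival(coh1$truth, scores, seed = seed + 3)
  mutation <- generate_mutation_table(coh1$truth, seed = seed + 4)

  write_expression_matrix(invitro$expression,
                          file.path(out_dir, "invitro_tpm.tsv"))
  readr::write_tsv(invitro$design, file.path(out_dir, "invitro_design.tsv"),
                   progress = FALSE)
  write_expression_matrix(coh1$expression, file.path(out_dir, "cohort1_tpm.tsv"))
  write_expression_matrix(coh2$expression, file.path(out_dir, "cohort2_tpm.tsv"))
  readr::write_tsv(clinical, file.path(out_dir, "clinical.tsv"), progress = FALSE)
  readr::write_tsv(mutation, file.path(out_dir, "mutation.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(
      seed = seed,
      module_genes = module,
      up_genes = invitro$truth$up_genes,
      down_genes = invitro$truth$down_genes,
      planted_hr = coh1$truth$planted_hr,
      censor_time = coh1$truth$censor_time,
      clip_fraction_invitro = invitro$truth$clip_fraction,
      clip_fraction_cohort1 = coh1$truth$clip_fraction
    ),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(list(invitro = invitro, cohort1 = coh1, cohort2 = coh2,
                 scores = scores, clinical = clinical, mutation = mutation))
}
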