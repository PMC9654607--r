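#' Expression tables
#'
#' Gene-level expression travels through the pipeline as a wide tibble: a
#' `gene_id` character column followed by one numeric column per sample.
#' The measurement scale rides along as the `"expr_scale"` attribute, one of
#' `"tpm"` (non-negative transcripts per million), `"log2p1"`
#' (`log2(TPM + 1)`), or `"array_intensity"` (log-scale array values, treated
#' as opaque). `expression_tbl()` validates and stamps a tibble;
#' `expr_scale()` reads the stamp back.
#'
#' Invariants enforced: unique gene ids, unique sample ids, all-numeric
#' sample columns, and non-negative values when `scale = "tpm"`.
#'
#' @param x A data frame whose first column is `gene_id` and whose remaining
#'   columns are numeric sample values.
#' @param scale Measurement scale: `"tpm"`, `"log2p1"` or `"array_intensity"`.
#' @return A tibble with the `"expr_scale"` attribute set.
#' @examples
#' m <- expression_tbl(
#'   data.frame(gene_id = c("CXCL9", "GBP4"), s1 = c(1, 3), s2 = c(0, 7)),
#'   scale = "tpm"
#' )
#' expr_scale(m)
#' @export
expression_tbl <- function(x, scale = c("tpm", "log2p1", "array_intensity")) {
  scale <- match.arg(scale)
  x <- as_tibble(x)
  if (ncol(x) < 2 || names(x)[1] != "gene_id") {
    abort("Expression table must have a `gene_id` first column plus sample columns.")
  }
  x$gene_id <- as.character(x$gene_id)
  dup_g <- unique(x$gene_id[duplicated(x$gene_id)])
  if (length(dup_g)) {
    abort(paste0("Duplicate gene ids: ", paste(dup_g, collapse = ", ")))
  }
  smp <- names(x)[-1]
  dup_s <- unique(smp[duplicated(smp)])
  if (length(dup_s)) {
    abort(paste0("Duplicate sample ids: ", paste(dup_s, collapse = ", ")))
  }
  bad <- smp[!vapply(x[smp], is.numeric, logical(1))]
  if (length(bad)) {
    abort(paste0("Non-numeric sample columns: ", paste(bad, collapse = ", ")))
  }
  if (scale == "tpm") {
    vals <- as.matrix(x[smp])
    neg <- which(vals < 0, arr.ind = TRUE)
    if (nrow(neg)) {
      abort(sprintf(
        "Negative TPM at gene '%s', sample '%s'.",
        x$gene_id[neg[1, 1]], smp[neg[1, 2]]
      ))
    }
  }
  attr(x, "expr_scale") <- scale
  x
}

#' @rdname expression_tbl
#' @export
expr_scale <- function(x) {
  sc <- attr(x, "expr_scale", exact = TRUE)
  if (is.null(sc)) NA_character_ else sc
}

#' Convert a wide expression tibble to a genes-by-samples numeric matrix
#'
#' @param x An expression tibble (see [expression_tbl()]).
#' @return Numeric matrix, genes as rows (rownames = gene ids), samples as
#'   columns.
#' @export
as_expr_matrix <- function(x) {
  m <- as.matrix(x[-1])
  rownames(m) <- x$gene_id
  m
}

#' Read and write gene-by-sample expression tables
#'
#' TSV layout: header row `gene_id` then sample ids; one row per gene.
#' Values are serialised with 6 significant digits and read back as doubles,
#' so write-then-read round-trips exactly for values already at that
#' precision.
#'
#' @param path Path to a tab-separated file.
#' @param scale Measurement scale of the stored values (see
#'   [expression_tbl()]).
#' @return `read_expression_matrix()`: a validated expression tibble.
#'   `write_expression_matrix()`: `path`, invisibly.
#' @export
read_expression_matrix <- function(path,
                                   scale = c("tpm", "log2p1", "array_intensity")) {
  scale <- match.arg(scale)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (!nrow(raw) || names(raw)[1] != "gene_id") {
    abort(sprintf("'%s': expected a TSV with a 'gene_id' first column.", path))
  }
  for (s in names(raw)[-1]) {
    v <- suppressWarnings(as.numeric(raw[[s]]))
    bad <- which(is.na(v) & !is.na(raw[[s]]))
    if (length(bad)) {
      abort(sprintf(
        "'%s': non-numeric value '%s' at gene '%s', sample '%s'.",
        path, raw[[s]][bad[1]], raw$gene_id[bad[1]], s
      ))
    }
    raw[[s]] <- v
  }
  expression_tbl(raw, scale)
}

#' @rdname read_expression_matrix
#' @param x An expression tibble.
#' @export
write_expression_matrix <- function(x, path) {
  out <- x
  for (s in names(out)[-1]) {
    out[[s]] <- formatC(signif(out[[s]], 6), format = "g", digits = 6)
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a paired control/treated design table
#'
#' TSV columns: `donor`, `control_sample`, `treated_sample`; one row per
#' donor. When `expr` is supplied, every referenced sample must appear in it
#' exactly once.
#'
#' @param path Path to the design TSV.
#' @param expr Optional companion expression tibble to validate against.
#' @return A tibble with columns `donor`, `control_sample`, `treated_sample`.
#' @export
read_paired_design <- function(path, expr = NULL) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  validate_paired_design(d, expr)
}

#' @rdname read_paired_design
#' @param design A data frame with columns `donor`, `control_sample`,
#'   `treated_sample`.
#' @export
validate_paired_design <- function(design, expr = NULL) {
  design <- as_tibble(design)
  need <- c("donor", "control_sample", "treated_sample")
  if (!all(need %in% names(design))) {
    abort("Design needs columns donor, control_sample, treated_sample.")
  }
  design <- design[need]
  if (anyDuplicated(design$donor)) {
    abort("Each donor must appear exactly once in the design.")
  }
  ids <- c(design$control_sample, design$treated_sample)
  if (anyDuplicated(ids)) {
    abort("A sample id is referenced by more than one design slot.")
  }
  if (!is.null(expr)) {
    missing <- setdiff(ids, names(expr)[-1])
    if (length(missing)) {
      abort(paste0(
        "Design samples absent from expression table: ",
        paste(missing, collapse = ", ")
      ))
    }
  }
  design
}

#' Read a clinical follow-up table
#'
#' TSV columns: `patient_id`, `time` (months, non-negative), `event`
#' (1 = recurrence or death, 0 = censored). Rows with a missing time or
#' event are dropped; the number dropped is reported via a message and the
#' `"n_dropped"` attribute. An out-of-range event or a negative time is an
#' error.
#'
#' @param path Path to the clinical TSV.
#' @param endpoint Which endpoint the table encodes: `"RFS"`
#'   (recurrence-free survival) or `"OS"` (overall survival); stored as the
#'   `"endpoint"` attribute.
#' @return A tibble with columns `patient_id`, `time`, `event`.
#' @export
read_clinical <- function(path, endpoint = c("RFS", "OS")) {
  endpoint <- match.arg(endpoint)
  d <- readr::read_tsv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    time = readr::col_double(),
    event = readr::col_double()
  ), progress = FALSE)
  if (!all(c("patient_id", "time", "event") %in% names(d))) {
    abort("Clinical table needs columns patient_id, time, event.")
  }
  validate_clinical(d[c("patient_id", "time", "event")], endpoint)
}

#' @rdname read_clinical
#' @param clinical A data frame with columns `patient_id`, `time`, `event`.
#' @export
validate_clinical <- function(clinical, endpoint = c("RFS", "OS")) {
  endpoint <- match.arg(endpoint)
  d <- as_tibble(clinical)
  keep <- !is.na(d$time) & !is.na(d$event)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf("Dropped %d clinical row(s) with missing time or event.", n_dropped))
  }
  d <- d[keep, , drop = FALSE]
  if (anyDuplicated(d$patient_id)) {
    abort("Duplicate patient ids in clinical table.")
  }
  if (any(d$time < 0)) abort("Negative follow-up time in clinical table.")
  if (!all(d$event %in% c(0, 1))) {
    abort("Clinical `event` must be 0 (censored) or 1 (event).")
  }
  attr(d, "endpoint") <- endpoint
  attr(d, "n_dropped") <- n_dropped
  d
}

#' Read a per-patient mutational-signature exposure table
#'
#' TSV columns: `patient_id`, the single-base-substitution exposures `SBS2`,
#' `SBS13` (APOBEC), `SBS4`, `SBS5` (non-APOBEC controls), all non-negative,
#' and a non-negative integer `neoantigen_load`.
#'
#' @param path Path to the mutation TSV.
#' @return A validated tibble.
#' @export
read_mutation_table <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  validate_mutation_table(d)
}

#' @rdname read_mutation_table
#' @param mutation A data frame in the same layout.
#' @export
validate_mutation_table <- function(mutation) {
  d <- as_tibble(mutation)
  need <- c("patient_id", "SBS2", "SBS13", "SBS4", "SBS5", "neoantigen_load")
  if (!all(need %in% names(d))) {
    abort(paste0(
      "Mutation table needs columns: ", paste(need, collapse = ", ")
    ))
  }
  if (anyDuplicated(d$patient_id)) abort("Duplicate patient ids in mutation table.")
  num <- setdiff(need, "patient_id")
  if (any(as.matrix(d[num]) < 0, na.rm = TRUE)) {
    abort("Exposures and neoantigen load must be non-negative.")
  }
  d[need]
}

#' Read a plain-text gene list
#'
#' One symbol per line; lines starting with `#` and blank lines are ignored.
#' The result is de-duplicated preserving first occurrence. Gene symbols are
#' matched case-sensitively and exactly throughout the package.
#'
#' @param path Path to the list file.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) abort(sprintf("'%s': no gene symbols found.", path))
  unique(lines)
}

#' @rdname read_gene_list
#' @param genes Character vector of gene ids to write.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Log-transform a TPM expression table
#'
#' Replaces every TPM value `x` by `log2(x + 1)`, the pseudocount transform
#' that damps the influence of low-abundance transcripts before correlation
#' and clustering. Applying it to an already log-transformed table is an
#' error (double-transform guard).
#'
#' @param x An expression tibble on the `"tpm"` scale.
#' @return The same table on the `"log2p1"` scale.
#' @examples
#' m <- expression_tbl(
#'   data.frame(gene_id = c("A", "B"), s1 = c(0, 3), s2 = c(1, 7)),
#'   scale = "tpm"
#' )
#' log2p1_transform(m)
#' @export
log2p1_transform <- function(x) {
  sc <- expr_scale(x)
  if (!identical(sc, "tpm")) {
    abort(sprintf(
      "log2p1_transform() expects a 'tpm'-scale table, got '%s'.", sc
    ))
  }
  out <- x
  for (s in names(out)[-1]) out[[s]] <- log2(out[[s]] + 1)
  attr(out, "expr_scale") <- "log2p1"
  out
}
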