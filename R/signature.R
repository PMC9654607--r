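#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive mean ranks).
#' A constant input vector has no rank ordering; the correlation is
#' undefined and `NA` is returned (callers exclude such pairs from
#' medians).
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @return Correlation in `[-1, 1]`, or `NA` for a constant input.
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 0.8
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length.")
  if (length(x) < 3) abort("Spearman correlation needs n >= 3.")
  if (anyNA(x) || anyNA(y)) abort("Missing values are not supported.")
  if (diff(range(x)) == 0 || diff(range(y)) == 0) return(NA_real_)
  cor(rank(x), rank(y))
}

# All permutations of 1..n as an (n! x n) integer matrix; n <= 9.
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (pos in seq_len(n)) {
    rows <- (pos - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, pos] <- n
    out[rows, -pos] <- sub
  }
  out
}

# Two-sided p-value for a Spearman correlation: t approximation on n - 2 df
# for n >= 10, full permutation enumeration below that.
.spearman_p <- function(x, y, rho) {
  n <- length(x)
  if (is.na(rho)) return(NA_real_)
  if (n >= 10) {
    if (abs(rho) >= 1) return(0)
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    return(2 * pt(abs(t_stat), n - 2, lower.tail = FALSE))
  }
  rx <- scale(rank(x))[, 1]
  ry <- rank(y)
  perms <- .permutations(n)
  rho_perm <- (matrix(scale(ry)[, 1][perms], nrow(perms), n) %*% rx) / (n - 1)
  mean(abs(rho_perm) >= abs(rho) - 1e-12)
}

#' Per-gene pairwise median Spearman correlation
#'
#' For each candidate gene, computes the Spearman correlation of its
#' expression profile (across samples) with every other candidate, and
#' summarises by the median (even counts take the midpoint of the two
#' central values). Undefined correlations from constant genes are
#' excluded before the median. This is the per-cohort consensus statistic
#' used to refine the signature.
#'
#' @param m Expression tibble on the `log2p1` (or `array_intensity`) scale.
#' @param candidates Character vector of candidate gene ids; candidates
#'   absent from `m` are reported and skipped, but at least 3 must be
#'   present.
#' @return A tibble with `gene_id` and `median_rho`.
#' @export
pairwise_median_rho <- function(m, candidates) {
  candidates <- unique(as.character(candidates))
  present <- candidates[candidates %in% m$gene_id]
  absent <- setdiff(candidates, present)
  if (length(absent)) {
    inform(sprintf(
      "%d candidate(s) absent from the matrix: %s",
      length(absent), paste(head(absent, 10), collapse = ", ")
    ))
  }
  if (length(present) < 3) abort("Need >= 3 candidate genes present in the matrix.")
  vals <- as_expr_matrix(m)[present, , drop = FALSE]
  if (ncol(vals) < 3) abort("Need >= 3 samples.")
  ranks <- t(apply(vals, 1, rank))
  constant <- apply(vals, 1, function(r) diff(range(r)) == 0)
  rho <- suppressWarnings(cor(t(ranks)))
  rho[constant, ] <- NA
  rho[, constant] <- NA
  diag(rho) <- NA
  tibble(
    gene_id = present,
    median_rho = unname(apply(rho, 1, function(r) {
      r <- r[!is.na(r)]
      if (!length(r)) NA_real_ else median(r)
    }))
  )
}

#' Refine a candidate gene set into a consensus signature
#'
#' Computes [pairwise_median_rho()] for the candidates within each cohort,
#' averages the per-gene medians across cohorts, and retains genes whose
#' mean exceeds `rho_threshold` (strictly). The result is ordered by
#' descending mean correlation and is independent of candidate input order.
#'
#' @param candidates Character vector of candidate gene ids (for the
#'   IFN-gamma signature, the in vitro up-regulated genes).
#' @param cohorts Named list of at least two expression tibbles
#'   (`log2p1` or `array_intensity` scale). Candidates absent from any
#'   cohort are reported and dropped before correlation.
#' @param rho_threshold Strict retention threshold on the mean of
#'   per-cohort median rhos. Default 0.5.
#' @return An object of class `uro_signature`: a list with `genes` (ordered
#'   retained gene ids), `table` (per-candidate tibble of per-cohort median
#'   rhos, `mean_rho` and `retained`), and `rho_threshold`. An empty
#'   signature (with a warning) if no gene passes.
#' @export
refine_signature <- function(candidates, cohorts, rho_threshold = 0.5) {
  if (length(cohorts) < 2) abort("Consensus refinement needs >= 2 cohorts.")
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts)))) {
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  }
  candidates <- sort(unique(as.character(candidates)))
  shared <- candidates
  for (co in cohorts) shared <- shared[shared %in% co$gene_id]
  dropped <- setdiff(candidates, shared)
  if (length(dropped)) {
    inform(sprintf(
      "Dropped %d candidate(s) absent from at least one cohort.",
      length(dropped)
    ))
  }
  if (length(shared) < 3) abort("Fewer than 3 candidates shared by all cohorts.")

  per_cohort <- purrr::imap(cohorts, function(co, nm) {
    pm <- pairwise_median_rho(co, shared)
    unname(setNames(pm$median_rho, pm$gene_id)[shared])
  })
  tab <- tibble(gene_id = shared)
  for (nm in names(per_cohort)) tab[[paste0("rho_", nm)]] <- per_cohort[[nm]]
  tab$mean_rho <- rowMeans(as.matrix(tab[paste0("rho_", names(per_cohort))]))
  tab$retained <- !is.na(tab$mean_rho) & tab$mean_rho > rho_threshold
  tab <- tab[order(-tab$mean_rho, tab$gene_id), , drop = FALSE]
  genes <- tab$gene_id[tab$retained]
  if (!length(genes)) {
    warn("No candidate gene passed the consensus correlation threshold; empty signature.")
  }
  structure(
    list(genes = genes, table = tab, rho_threshold = rho_threshold),
    class = "uro_signature"
  )
}

#' @export
print.uro_signature <- function(x, ...) {
  cat(sprintf(
    "Consensus gene signature: %d of %d candidates retained (mean rho > %g)\n",
    length(x$genes), nrow(x$table), x$rho_threshold
  ))
  print(head(x$table, 10))
  invisible(x)
}

#' Unit-length scale a vector
#'
#' Divides a vector by its Euclidean norm so the result has norm 1. An
#' all-zero vector (a gene with no expression in a cohort) is returned
#' unchanged with a message: it contributes nothing to downstream sums
#' rather than erroring.
#'
#' @param v Numeric vector with at least one element.
#' @return `v / sqrt(sum(v^2))`, or `v` itself if all zero.
#' @examples
#' unit_length_scale(c(3, 4)) # 0.6 0.8
#' @export
unit_length_scale <- function(v) {
  if (!length(v)) abort("Cannot unit-length scale an empty vector.")
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) {
    inform("All-zero vector: left as zeros (contributes nothing to scores).")
    return(v)
  }
  v / nrm
}

#' Compute per-patient signature scores
#'
#' The single-value signature score: each signature gene's expression
#' vector (across the cohort's patients) is unit-length scaled, the scaled
#' values are summed per patient, and the sums are min-max rescaled to
#' `[0, 1]`. Scores are invariant to any positive per-gene rescaling of
#' the expression rows, which is what lets TPM-based and array-based
#' cohorts be scored on a common footing (each cohort is scored
#' separately).
#'
#' @param m Expression tibble (`log2p1` or `array_intensity` scale).
#' @param signature A `uro_signature` or a character vector of gene ids.
#'   Genes missing from `m` are reported and dropped; at least one must be
#'   present.
#' @param cohort Cohort label stored in the result. Default `"cohort"`.
#' @return A tibble with `patient_id`, `raw_sum` (pre-rescale sum), `score`
#'   in `[0, 1]` and `cohort`.
#' @examples
#' m <- expression_tbl(
#'   data.frame(gene_id = c("g1", "g2"), p1 = c(1, 0), p2 = c(2, 3), p3 = c(2, 4)),
#'   scale = "log2p1"
#' )
#' compute_scores(m, c("g1", "g2"))
#' @export
compute_scores <- function(m, signature, cohort = "cohort") {
  genes <- if (inherits(signature, "uro_signature")) signature$genes else
    as.character(signature)
  if (!length(genes)) abort("Empty signature.")
  present <- genes[genes %in% m$gene_id]
  if (!length(present)) abort("No signature gene present in the matrix.")
  if (length(present) < length(genes)) {
    inform(sprintf(
      "%d signature gene(s) missing from the matrix; scoring on %d.",
      length(genes) - length(present), length(present)
    ))
  }
  vals <- as_expr_matrix(m)[present, , drop = FALSE]
  if (ncol(vals) < 2) abort("Scoring needs >= 2 patients.")
  nrm <- sqrt(rowSums(vals^2))
  zero <- nrm == 0
  if (any(zero)) {
    inform(sprintf("%d all-zero signature gene row(s) contribute nothing.", sum(zero)))
    nrm[zero] <- 1
  }
  raw <- colSums(vals / nrm)
  rng <- range(raw)
  if (diff(rng) == 0) abort("Degenerate cohort: all raw signature sums equal.")
  tibble(
    patient_id = colnames(vals),
    raw_sum = unname(raw),
    score = unname((raw - rng[1]) / diff(rng)),
    cohort = cohort
  )
}

#' Spearman correlation of the signature score with a gene's expression
#'
#' Rank-correlates per-patient scores against a single gene's expression
#' (e.g. the *IFNG* transcript itself), with a two-sided p-value from the
#' t approximation on `n - 2` degrees of freedom for `n >= 10` and full
#' permutation enumeration below that.
#'
#' @param scores Score tibble from [compute_scores()].
#' @param gene_values Numeric vector of per-patient expression, either
#'   named by patient id or aligned with `scores$patient_id`.
#' @return A one-row tibble: `rho`, `p_value`, `n`.
#' @export
rank_correlate_score <- function(scores, gene_values) {
  if (!is.null(names(gene_values))) {
    missing <- setdiff(scores$patient_id, names(gene_values))
    if (length(missing)) {
      abort(paste0("gene_values missing patients: ", paste(head(missing, 5), collapse = ", ")))
    }
    gene_values <- gene_values[scores$patient_id]
  }
  if (length(gene_values) != nrow(scores)) {
    abort("gene_values length must match the score table.")
  }
  if (nrow(scores) < 3) abort("Need n >= 3 patients.")
  rho <- spearman_rho(scores$score, gene_values)
  tibble(
    rho = rho,
    p_value = .spearman_p(scores$score, gene_values, rho),
    n = nrow(scores)
  )
}
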