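# k-means++ seeding: first centre uniform, then points weighted by squared
# distance to the nearest chosen centre.
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- sample.int(n, 1)
  for (j in seq_len(k - 1)) {
    d2 <- matrix(Inf, n, 1)
    for (i in idx) {
      d2 <- pmin(d2, rowSums((x - matrix(x[i, ], n, ncol(x), byrow = TRUE))^2))
    }
    idx <- c(idx, if (sum(d2) == 0) sample.int(n, 1) else
      sample.int(n, 1, prob = d2))
  }
  x[idx, , drop = FALSE]
}

#' Stratify patients into signature-high and signature-low groups
#'
#' Runs two-group k-means on the patients-as-points cloud in signature-gene
#' expression space (raw `log2(TPM+1)` or array values, no
#' standardisation), with k-means++ initialisation and `n_init` restarts,
#' keeping the solution with the lowest within-cluster sum of squares
#' (inertia). The cluster whose members have the higher mean signature
#' score is labelled `"high"`; on an exact tie the cluster containing the
#' first patient of the input is `"low"`.
#'
#' Results are invariant to patient input order: patients are processed in
#' sorted-id order and the restart RNG is seeded from `seed` combined with
#' a hash of the sorted patient ids.
#'
#' @param m Expression tibble (`log2p1` or `array_intensity`).
#' @param scores Score tibble from [compute_scores()] covering the same
#'   patients.
#' @param genes Optional character vector (or `uro_signature`) restricting
#'   the feature space to the signature genes; default uses all genes
#'   in `m`.
#' @param seed Integer seed for the restarts.
#' @param n_init Number of k-means++ restarts. Default 50.
#' @return A tibble (`patient_id`, `label`, `score`) with attributes
#'   `cluster_means` (mean score per label), `kmeans_inertia`, `seed`,
#'   `n_init`.
#' @export
kmeans2 <- function(m, scores, genes = NULL, seed, n_init = 50) {
  if (!is.null(genes)) {
    g <- if (inherits(genes, "uro_signature")) genes$genes else as.character(genes)
    present <- g[g %in% m$gene_id]
    if (length(present) < 1) abort("No requested gene present in the matrix.")
    m <- m[match(present, m$gene_id), , drop = FALSE]
  }
  x <- t(as_expr_matrix(m)) # patients x genes
  patients_in <- rownames(x)
  missing <- setdiff(patients_in, scores$patient_id)
  if (length(missing)) {
    abort(paste0("Patients without scores: ", paste(head(missing, 5), collapse = ", ")))
  }
  ord <- order(patients_in)
  x <- x[ord, , drop = FALSE]
  if (nrow(x) < 2) abort("k-means needs >= 2 patients.")
  if (nrow(unique(as.data.frame(x))) < 2) {
    abort("All patient feature vectors identical; two clusters undefined.")
  }

  best <- NULL
  failures <- 0
  .with_seed(seed + .id_hash(patients_in), {
    for (r in seq_len(n_init)) {
      centers <- .kmeanspp_centers(x, 2)
      fit <- tryCatch(
        suppressWarnings(
          kmeans(x, centers = centers, iter.max = 100, algorithm = "Lloyd")
        ),
        error = function(e) NULL
      )
      if (is.null(fit) || any(fit$size == 0)) {
        failures <- failures + 1
        next
      }
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best)) {
    abort(sprintf("k-means failed to find a two-cluster solution in %d restarts.", n_init))
  }
  if (failures > 0) {
    inform(sprintf("%d restart(s) produced an empty cluster and were retried.", failures))
  }

  assign_tbl <- tibble(patient_id = rownames(x), cluster = best$cluster) %>%
    left_join(scores[c("patient_id", "score")], by = "patient_id")
  means <- tapply(assign_tbl$score, assign_tbl$cluster, mean)
  if (means[["1"]] == means[["2"]]) {
    # tie: the cluster containing the first input patient is "low"
    low_cluster <- assign_tbl$cluster[match(patients_in[1], assign_tbl$patient_id)]
    high_cluster <- setdiff(c(1L, 2L), low_cluster)
  } else {
    high_cluster <- as.integer(names(which.max(means)))
  }
  out <- assign_tbl %>%
    mutate(label = unname(ifelse(.data$cluster == high_cluster, "high", "low"))) %>%
    select("patient_id", "label", "score")
  out <- out[match(patients_in, out$patient_id), , drop = FALSE]
  attr(out, "cluster_means") <- c(
    high = unname(means[as.character(high_cluster)]),
    low = unname(means[as.character(setdiff(c(1L, 2L), high_cluster))])
  )
  attr(out, "kmeans_inertia") <- best$tot.withinss
  attr(out, "seed") <- seed
  attr(out, "n_init") <- n_init
  out
}

#' Dendrogram leaf order for heatmap display
#'
#' Agglomerative hierarchical clustering with Euclidean distance and
#' complete linkage on the chosen axis, returning the leaf order with a
#' deterministic orientation: at every merge, the subtree containing the
#' smaller original index is placed on the left.
#'
#' @param m Expression tibble.
#' @param axis `"genes"` (rows) or `"samples"` (columns).
#' @return Character vector of gene or sample ids in display order.
#' @export
hierarchical_order <- function(m, axis = c("genes", "samples")) {
  axis <- match.arg(axis)
  vals <- as_expr_matrix(m)
  if (axis == "samples") vals <- t(vals)
  if (nrow(vals) < 2) abort("Need >= 2 items to order.")
  hc <- hclust(dist(vals), method = "complete")
  leaves <- function(node) {
    if (node < 0) return(-node)
    a <- leaves(hc$merge[node, 1])
    b <- leaves(hc$merge[node, 2])
    if (min(a) <= min(b)) c(a, b) else c(b, a)
  }
  rownames(vals)[leaves(nrow(vals) - 1L)]
}
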