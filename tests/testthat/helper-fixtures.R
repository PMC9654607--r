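# Shared fixture builders. Everything is generated in code; no stored data.

# Wide expression tibble from a genes-by-samples matrix.
expr_from_matrix <- function(mat, scale = "log2p1",
                             genes = rownames(mat), samples = colnames(mat)) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(mat)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(mat)))
  d <- tibble::as_tibble(as.data.frame(mat), .name_repair = "minimal")
  names(d) <- samples
  expression_tbl(dplyr::bind_cols(tibble::tibble(gene_id = genes), d),
                 scale = scale)
}

# Clinical tibble from parallel vectors.
clin <- function(time, event, ids = sprintf("p%03d", seq_along(time))) {
  tibble::tibble(patient_id = ids, time = time, event = event)
}

# Independent brute-force Benjamini-Hochberg step-up.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(p[ord][i:m] * m / (i:m))
  }
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Brute-force complete-linkage merge heights for a small point set.
complete_linkage_heights <- function(x) {
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# Exhaustive best 2-partition within-cluster sum of squares (n <= 15).
best_two_partition_inertia <- function(x) {
  n <- nrow(x)
  wss <- function(rows) {
    if (length(rows) == 0) return(0)
    ctr <- colMeans(x[rows, , drop = FALSE])
    sum(sweep(x[rows, , drop = FALSE], 2, ctr)^2)
  }
  best <- Inf
  for (code in seq_len(2^(n - 1) - 1)) {
    grp <- as.logical(bitwAnd(code, 2^(seq_len(n) - 1)))
    best <- min(best, wss(which(grp)) + wss(which(!grp)))
  }
  best
}

# Hand computation of the weighted two-group statistic from per-time tables.
weighted_logrank_by_hand <- function(a, b, gehan = FALSE) {
  time <- c(a$time, b$time)
  event <- c(a$event, b$event)
  in_a <- rep(c(TRUE, FALSE), c(nrow(a), nrow(b)))
  ts <- sort(unique(time[event == 1]))
  num <- 0
  den <- 0
  for (t0 in ts) {
    n <- sum(time >= t0)
    na <- sum(time >= t0 & in_a)
    d <- sum(time == t0 & event == 1)
    da <- sum(time == t0 & event == 1 & in_a)
    v <- if (n > 1) na * (n - na) * d * (n - d) / (n^2 * (n - 1)) else 0
    w <- if (gehan) n else 1
    num <- num + w * (da - na * d / n)
    den <- den + w^2 * v
  }
  num^2 / den
}

# Brute-force two-sided exact Mann-Whitney p by enumerating group assignments.
mwu_exact_brute <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  u_of <- function(xi) {
    sum(outer(pooled[xi], pooled[-xi], ">")) +
      0.5 * sum(outer(pooled[xi], pooled[-xi], "=="))
  }
  u_obs <- u_of(seq_len(nx))
  combs <- utils::combn(length(pooled), nx)
  us <- apply(combs, 2, u_of)
  mu <- nx * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
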