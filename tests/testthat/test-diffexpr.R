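make_paired <- function(mat_ctrl, mat_trt, genes = NULL) {
  n_d <- ncol(mat_ctrl)
  samples <- c(paste0("d", seq_len(n_d), "_c"), paste0("d", seq_len(n_d), "_t"))
  m <- expr_from_matrix(cbind(mat_ctrl, mat_trt), scale = "log2p1",
                        genes = genes, samples = samples)
  design <- tibble::tibble(
    donor = paste0("d", seq_len(n_d)),
    control_sample = paste0("d", seq_len(n_d), "_c"),
    treated_sample = paste0("d", seq_len(n_d), "_t")
  )
  list(m = m, design = design)
}

test_that("paired LRT handles no-effect, constant and saturated genes", {
  ctrl <- rbind(c(5, 6, 7), c(5, 6, 7), c(4, 4, 4))
  trt <- rbind(c(5, 6, 7), c(7, 8, 9), c(4, 4, 4))
  px <- make_paired(ctrl, trt, genes = c("same", "shifted", "const"))
  res <- paired_lrt(px$m, px$design)

  expect_equal(res$lrt_stat[res$gene_id == "same"], 0)
  expect_equal(res$p_value[res$gene_id == "same"], 1)
  # constant shift with zero noise saturates the full model
  expect_identical(res$flag[res$gene_id == "shifted"], "saturated")
  expect_equal(res$p_value[res$gene_id == "shifted"], 0)
  expect_identical(res$flag[res$gene_id == "const"], "constant")
  expect_equal(res$p_value[res$gene_id == "const"], 1)
})

test_that("closed-form paired LRT agrees with explicit nested lm() fits", {
  set.seed(5)
  n_d <- 6
  ctrl <- matrix(rnorm(20 * n_d, 6, 1), 20)
  trt <- ctrl + matrix(rnorm(20 * n_d, 0.5, 0.7), 20)
  px <- make_paired(ctrl, trt)
  res <- paired_lrt(px$m, px$design)

  donor <- factor(rep(seq_len(n_d), 2))
  treat <- rep(c(0, 1), each = n_d)
  for (i in c(1, 7, 20)) {
    y <- c(ctrl[i, ], trt[i, ])
    full <- lm(y ~ treat + donor)
    red <- lm(y ~ donor)
    rss_f <- sum(residuals(full)^2)
    rss_r <- sum(residuals(red)^2)
    expect_equal(res$lrt_stat[i], 2 * n_d * log(rss_r / rss_f), tolerance = 1e-9)
    f_stat <- (rss_r - rss_f) / (rss_f / (2 * n_d - n_d - 1))
    expect_equal(res$p_value[i], pf(f_stat, 1, n_d - 1, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("paired LRT is invariant to donor-specific shifts (blocking)", {
  set.seed(8)
  ctrl <- matrix(rnorm(30, 6, 1), 10)
  trt <- ctrl + matrix(rnorm(30, 1, 0.5), 10)
  px <- make_paired(ctrl, trt)
  base <- paired_lrt(px$m, px$design)

  shift <- c(10, -3, 0.5)
  ctrl2 <- sweep(ctrl, 2, shift, "+")
  trt2 <- sweep(trt, 2, shift, "+")
  px2 <- make_paired(ctrl2, trt2)
  shifted <- paired_lrt(px2$m, px2$design)
  expect_equal(base$lrt_stat, shifted$lrt_stat, tolerance = 1e-9)
  expect_equal(base$p_value, shifted$p_value, tolerance = 1e-9)
})

test_that("null p-values are uniform (KS calibration)", {
  sim <- generate_invitro(n_donors = 6, n_genes = 2000, n_up = 0, n_down = 0,
                          noise_sd = 0.4, seed = 77)
  res <- paired_lrt(log2p1_transform(sim$expression), sim$design)
  ks <- suppressWarnings(stats::ks.test(res$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("BH adjustment matches the hand step-up example and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.05), 0.05)
  set.seed(10)
  p <- runif(100)
  q <- bh_adjust(p)
  expect_true(all(q >= p - 1e-15))
  expect_true(all(q >= 0 & q <= 1))
  expect_error(bh_adjust(numeric(0)), "non-empty")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("fold changes are per-donor paired means on the log scale", {
  ctrl_tpm <- matrix(1, 1, 3)
  trt_tpm <- matrix(3, 1, 3)
  samples <- c(paste0("d", 1:3, "_c"), paste0("d", 1:3, "_t"))
  m <- expr_from_matrix(cbind(ctrl_tpm, trt_tpm), scale = "tpm",
                        genes = "g1", samples = samples)
  design <- tibble::tibble(
    donor = paste0("d", 1:3),
    control_sample = paste0("d", 1:3, "_c"),
    treated_sample = paste0("d", 1:3, "_t")
  )
  fc <- fold_changes(log2p1_transform(m), design)
  expect_equal(fc$log2fc, 1) # log2(4) - log2(2)

  ctrl <- matrix(5, 1, 3)
  trt <- ctrl + matrix(c(1, 2, 3), 1)
  px <- make_paired(ctrl, trt)
  expect_equal(fold_changes(px$m, px$design)$log2fc, 2)
  pz <- make_paired(ctrl, ctrl)
  expect_equal(fold_changes(pz$m, pz$design)$log2fc, 0)
})

test_that("responsive-gene selection applies strict thresholds, sorted by effect", {
  res <- tibble::tibble(
    gene_id = c("a", "b", "c", "d", "e"),
    log2fc = c(1.5, 0.9, 3, -2, -0.5),
    q_value = c(0.04, 0.04, 0.05, 0.01, 0.01)
  )
  expect_identical(select_responsive_genes(res, direction = "up"), "a")
  expect_identical(select_responsive_genes(res, direction = "down"), "d")
  res2 <- tibble::tibble(
    gene_id = c("x", "y"), log2fc = c(2, 4), q_value = c(0.01, 0.02)
  )
  expect_identical(select_responsive_genes(res2, direction = "up"), c("y", "x"))
})

test_that("planted up-genes are recovered with FDR control on generator data", {
  recovered <- numeric(5)
  false_frac <- numeric(5)
  for (r in 1:5) {
    sim <- generate_invitro(n_donors = 6, n_genes = 400, n_up = 40, n_down = 0,
                            effect_lo = 1.2, noise_sd = 0.4, seed = 300 + r)
    de <- diff_expression(log2p1_transform(sim$expression), sim$design)
    up <- select_responsive_genes(de)
    recovered[r] <- length(intersect(up, sim$truth$up_genes)) / 40
    false_frac[r] <- length(setdiff(up, sim$truth$up_genes)) / max(1, length(up))
  }
  expect_gte(mean(recovered), 0.95)
  expect_lte(mean(false_frac), 0.05)
})
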