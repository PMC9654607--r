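test_that("Spearman correlation matches hand-ranked examples", {
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(spearman_rho(c(1, 2, 3), c(10, 20, 30)), 1)
  # d^2 = (0,1,1,0): 1 - 6*2/(4*15)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(spearman_rho(c(1, 1, 1), c(1, 2, 3))))
})

test_that("pairwise median rho reproduces the three-gene hand computation", {
  m <- expr_from_matrix(rbind(
    A = c(1, 2, 3, 4), B = c(2, 3, 4, 5), C = c(4, 3, 2, 1)
  ), samples = paste0("s", 1:4))
  med <- pairwise_median_rho(m, c("A", "B", "C"))
  expect_equal(med$median_rho[med$gene_id == "A"], 0) # median {1, -1}
  expect_equal(med$median_rho[med$gene_id == "B"], 0)
  expect_equal(med$median_rho[med$gene_id == "C"], -1)

  ident <- expr_from_matrix(rbind(
    A = c(1, 2, 3), B = c(1, 2, 3), C = c(1, 2, 3)
  ), samples = paste0("s", 1:3))
  expect_true(all(pairwise_median_rho(ident, c("A", "B", "C"))$median_rho == 1))

  # permutation of sample order leaves all medians unchanged
  perm <- m[, c(1, 4, 2, 5, 3)]
  attr(perm, "expr_scale") <- "log2p1"
  expect_equal(pairwise_median_rho(perm, c("A", "B", "C")), med)
})

test_that("consensus refinement recovers a planted module and orders by mean rho", {
  mod <- sprintf("MOD%02d", 1:15)
  cands <- c(mod, sprintf("BG%04d", 1:40))
  co1 <- generate_cohort(200, mod, n_background = 40, seed = 401)
  co2 <- generate_cohort(200, mod, n_background = 40, seed = 402)
  cohorts <- list(a = log2p1_transform(co1$expression),
                  b = log2p1_transform(co2$expression))
  sig <- refine_signature(cands, cohorts)
  expect_setequal(sig$genes, mod)
  expect_equal(sig$genes, sig$table$gene_id[sig$table$retained])
  expect_true(all(diff(sig$table$mean_rho) <= 0))

  # candidate order must not matter (set semantics)
  sig2 <- refine_signature(rev(cands), cohorts)
  expect_identical(sig$genes, sig2$genes)
  expect_identical(sig$table, sig2$table)

  # identical cohorts: mean equals the single-cohort median
  sig3 <- refine_signature(cands, list(x = cohorts$a, y = cohorts$a))
  expect_equal(sig3$table$mean_rho, sig3$table$rho_x)

  # unattainable threshold leaves an empty signature with a warning
  expect_warning(empty <- refine_signature(cands, cohorts, rho_threshold = 1),
                 "empty signature")
  expect_length(empty$genes, 0)
})

test_that("unit-length scaling normalises, is scale invariant, passes zeros through", {
  expect_equal(unit_length_scale(c(3, 4)), c(0.6, 0.8))
  expect_equal(unit_length_scale(5), 1)
  v <- c(2, 1, 7)
  expect_equal(unit_length_scale(13 * v), unit_length_scale(v))
  expect_message(z <- unit_length_scale(c(0, 0)), "All-zero")
  expect_equal(z, c(0, 0))
})

test_that("score computation reproduces the hand-worked oracle", {
  m1 <- expr_from_matrix(matrix(c(3, 4), 1), genes = "g1",
                         samples = c("p1", "p2"))
  s1 <- compute_scores(m1, "g1")
  expect_equal(s1$raw_sum, c(0.6, 0.8))
  expect_equal(s1$score, c(0, 1))

  m2 <- expr_from_matrix(rbind(g1 = c(1, 2, 2), g2 = c(0, 3, 4)),
                         samples = c("p1", "p2", "p3"))
  s2 <- compute_scores(m2, c("g1", "g2"))
  expect_equal(s2$raw_sum, c(1 / 3, 2 / 3 + 0.6, 2 / 3 + 0.8), tolerance = 1e-12)
  expect_equal(round(s2$score, 4), c(0, 0.8235, 1))
})

test_that("scores are exactly invariant to per-gene positive rescaling", {
  set.seed(6)
  vals <- matrix(runif(5 * 8, 1, 10), 5)
  m <- expr_from_matrix(vals, genes = paste0("g", 1:5),
                        samples = paste0("p", 1:8))
  base <- compute_scores(m, paste0("g", 1:5))
  m10 <- m
  m10[3, -1] <- m10[3, -1] * 10
  attr(m10, "expr_scale") <- "log2p1"
  rescaled <- compute_scores(m10, paste0("g", 1:5))
  expect_equal(base$score, rescaled$score, tolerance = 1e-12)
  expect_equal(base$raw_sum, rescaled$raw_sum, tolerance = 1e-12)

  # exactly one 0 and one 1 with distinct raw sums
  expect_equal(sum(base$score == 0), 1L)
  expect_equal(sum(base$score == 1), 1L)
})

test_that("degenerate and missing-gene scoring behave as specified", {
  m <- expr_from_matrix(rbind(g1 = c(2, 2, 2)), samples = paste0("p", 1:3))
  expect_error(compute_scores(m, "g1"), "Degenerate cohort")
  m2 <- expr_from_matrix(rbind(g1 = c(1, 2, 3)), samples = paste0("p", 1:3))
  expect_message(s <- compute_scores(m2, c("g1", "notthere")), "missing")
  expect_equal(nrow(s), 3L)
  expect_error(compute_scores(m2, "absent"), "No signature gene")
})

test_that("score-gene rank correlation recovers monotone links with calibrated p", {
  sc <- tibble::tibble(patient_id = paste0("p", 1:12),
                       raw_sum = 1:12, score = (0:11) / 11, cohort = "c")
  expect_equal(rank_correlate_score(sc, sc$score)$rho, 1)
  expect_equal(rank_correlate_score(sc, -sc$score)$rho, -1)

  # small-n p comes from full permutation enumeration
  set.seed(12)
  x <- rnorm(6)
  y <- rnorm(6)
  sc6 <- tibble::tibble(patient_id = paste0("p", 1:6), raw_sum = x,
                        score = (rank(x) - 1) / 5, cohort = "c")
  res <- rank_correlate_score(sc6, y)
  perms <- t(apply(expand.grid(rep(list(1:6), 6)), 1, identity))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6), ]
  rhos <- apply(perms, 1, function(pm) cor(rank(sc6$score), rank(y[pm])))
  expect_equal(res$p_value, mean(abs(rhos) >= abs(res$rho) - 1e-12),
               tolerance = 1e-12)

  # null calibration of the t approximation at n = 20
  set.seed(13)
  rej <- 0
  n_rep <- 400
  for (r in seq_len(n_rep)) {
    sc20 <- tibble::tibble(patient_id = paste0("p", 1:20),
                           raw_sum = runif(20), score = runif(20), cohort = "c")
    rej <- rej + (rank_correlate_score(sc20, runif(20))$p_value < 0.05)
  }
  expect_gte(rej, qbinom(0.0025, n_rep, 0.05))
  expect_lte(rej, qbinom(0.9975, n_rep, 0.05))
})
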