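test_that("between-set covariance matches direct covariances over subtype samples", {
  set.seed(15)
  m <- matrix(rnorm(30 * 12), 30, 12)
  m[5, ] <- m[20, ]  # candidate g20 duplicates signature gene g05
  expr <- make_expr(m)
  sub_samples <- sample_ids(expr)[1:8]
  sig_genes <- gene_ids(expr)[1:10]
  cand_genes <- gene_ids(expr)[11:25]
  C <- between_set_covariance(expr, sub_samples, sig_genes, cand_genes)
  expect_identical(dim(C), c(10L, 15L))
  # oracle: per-pair cov() over the subtype samples only
  for (i in c(1, 5, 10)) {
    for (j in c(1, 10, 15)) {
      expect_equal(C[i, j],
                   cov(m[i, 1:8], m[10 + j, 1:8]), tolerance = 1e-12)
    }
  }
  # cov(x, x) = var(x) when a candidate equals a signature gene
  expect_equal(C["g05", "g20"], var(m[5, 1:8]), tolerance = 1e-12)

  expect_error(between_set_covariance(expr, sub_samples, sig_genes,
                                      c("g05", cand_genes)), "overlap")
  expect_error(between_set_covariance(expr, sub_samples[1:2], sig_genes,
                                      cand_genes), "at least 3")
})

test_that("independent noise gives near-zero covariance entries", {
  set.seed(16)
  means <- vapply(1:10, function(s) {
    set.seed(s)
    m <- matrix(rnorm(130 * 30), 130, 30)
    expr <- make_expr(m)
    C <- between_set_covariance(expr, sample_ids(expr),
                                gene_ids(expr)[1:50], gene_ids(expr)[51:130])
    mean(C)
  }, numeric(1))
  expect_true(all(abs(means) < 3 / sqrt(50 * 80 * 30)))
})

test_that("SVD projection satisfies the paper identities and sign convention", {
  # exact rank-1 case: C = s * a b^T gives w_hat_b = s * b
  a <- c(0.6, 0.8)
  b <- c(1, 2, 2) / 3
  C <- 5 * a %o% b
  proj <- driver_potentials(C)
  expect_equal(unname(proj$w_hat_b), 5 * b, tolerance = 1e-10)
  expect_equal(proj$sigma1, 5, tolerance = 1e-10)
  expect_gt(proj$u1[which.max(abs(proj$u1))], 0)

  # zero matrix degenerates cleanly
  expect_warning(z <- driver_potentials(matrix(0, 3, 4)), "zero")
  expect_equal(unname(z$w_hat_b), rep(0, 4))
  expect_equal(z$sigma1, 0)

  # random matrix versus an eigendecomposition oracle
  set.seed(17)
  C6 <- matrix(rnorm(24), 6, 4)
  p6 <- driver_potentials(C6)
  ev <- eigen(crossprod(C6))  # C^T C: eigenvalues sigma^2, vectors v
  v1 <- ev$vectors[, 1]
  if (sum(v1 * p6$w_hat_b) < 0) v1 <- -v1
  expect_equal(unname(p6$w_hat_b), sqrt(ev$values[1]) * v1, tolerance = 1e-8)
  expect_equal(unname(p6$w_hat_b), p6$sigma1 * p6$v1, tolerance = 1e-8)
  expect_equal(drop(t(p6$u1) %*% C6 %*% t(C6) %*% p6$u1), p6$sigma1^2,
               tolerance = 1e-8)
  expect_equal(sum(p6$u1^2), 1, tolerance = 1e-12)
  expect_equal(sum(p6$v1^2), 1, tolerance = 1e-12)
})

test_that("permutation p-values flag a planted dependency and bound cleanly", {
  set.seed(18)
  m <- matrix(rnorm(300 * 60), 300, 60)
  # candidate g291 tracks the mean signature activity (unit variance,
  # small independent noise)
  f <- colMeans(m[1:20, ])
  m[291, ] <- f / sd(f) + rnorm(60, sd = 0.1)
  expr <- make_expr(m)
  rk <- permutation_pvalues(expr, sample_ids(expr),
                            signature = gene_ids(expr)[1:20],
                            candidates = gene_ids(expr)[291:300],
                            n_permutations = 1000, seed = 23)
  expect_lt(rk$p_value[rk$gene == "g291"][1], 0.01)
  expect_identical(rk$rank[order(rk$p_value, -abs(rk$driver_potential))],
                   seq_len(nrow(rk)))
  expect_true(all(rk$p_value > 0 & rk$p_value <= 1))

  # candidates with no variance have zero potential -> p = 1
  m2 <- matrix(rnorm(200 * 20), 200, 20)
  m2[191:195, ] <- 5
  expr2 <- make_expr(m2)
  expect_warning(
    rk2 <- permutation_pvalues(expr2, sample_ids(expr2),
                               signature = gene_ids(expr2)[1:20],
                               candidates = gene_ids(expr2)[191:195],
                               n_permutations = 100, seed = 5),
    "constant")
  expect_true(all(rk2$p_value == 1))

  expect_error(
    permutation_pvalues(expr2, sample_ids(expr2),
                        signature = gene_ids(expr2)[1:20],
                        candidates = gene_ids(expr2)[191:195],
                        n_permutations = 50, seed = 1),
    ">= 100")
})

test_that("scaling candidates scales potentials but not ranks", {
  set.seed(19)
  sim <- generate_driver_testbed(n_genes = 300, n_cases = 40,
                                 n_signature = 20, n_candidates = 30,
                                 regime = "pos", seed = 19)
  expr <- sim$expr
  cand <- sim$truth$candidate_genes
  rk1 <- permutation_pvalues(expr, sample_ids(expr),
                             sim$truth$signature_genes, cand,
                             n_permutations = 200, seed = 3)
  scaled <- expr
  scaled$values[cand, ] <- 4 * scaled$values[cand, ]
  rk2 <- permutation_pvalues(scaled, sample_ids(scaled),
                             sim$truth$signature_genes, cand,
                             n_permutations = 200, seed = 3)
  expect_equal(rk2$driver_potential, 4 * rk1$driver_potential,
               tolerance = 1e-8)
  expect_identical(rk2$rank, rk1$rank)
})

test_that("full driver analysis respects thresholds and subtype independence", {
  sim <- generate_subtype_testbed(n_subtypes = 2, tumors_per_subtype = 12,
                                  n_normals = 5, n_genes = 400,
                                  sig_block_size = 25, seed = 29)
  sig <- detect_signature(sim$expr, sim$truth$labels)
  cands <- list("1" = gene_ids(sim$expr)[301:330],
                "2" = gene_ids(sim$expr)[301:330])
  res <- run_driver_analysis(sim$expr, sim$truth$labels, sig, cands,
                             n_permutations = 100, seed = 2,
                             p_threshold = 0)
  expect_false(any(res$significant))
  expect_identical(sort(unique(res$subtype)), c(1L, 2L))
  # shared candidate list, independent rankings per subtype
  r1 <- res[res$subtype == 1, ]
  r2 <- res[res$subtype == 2, ]
  expect_setequal(r1$gene, r2$gene)
  expect_identical(sort(r1$rank), sort(r2$rank))

  # a subtype with an empty signature is skipped with a warning
  sig_empty <- sig
  sig_empty$sets[["2"]] <- character(0)
  expect_warning(res2 <- run_driver_analysis(sim$expr, sim$truth$labels,
                                             sig_empty, cands,
                                             n_permutations = 100, seed = 2),
                 "skipped")
  expect_identical(unique(res2$subtype), 1L)
})
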