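test_that("pair normalization hits the target moments exactly", {
  # worked example: m1 = 2, s1 = 1, n1 = 4; m2 = 4, s2 = 1, n2 = 4
  x1 <- (c(1, 2, 3, 4) - 2.5) / sd(c(1, 2, 3, 4)) + 2  # mean 2, sd 1
  x2 <- x1 + 2                                         # mean 4, sd 1
  e1 <- expression_matrix(rbind(g1 = x1) |>
                            `colnames<-`(paste0("a", 1:4)))
  e2 <- expression_matrix(rbind(g1 = x2) |>
                            `colnames<-`(paste0("b", 1:4)))
  nz <- normalize_pair(e1, e2)
  expect_equal(nz$normalization$target_mean, 3)
  expect_equal(nz$normalization$target_sd, sqrt(0.5), tolerance = 1e-12)
  expect_equal(mean(nz$expr1$values), 3, tolerance = 1e-10)
  expect_equal(sd(nz$expr1$values), sqrt(0.5), tolerance = 1e-10)
  expect_equal(mean(nz$expr2$values), 3, tolerance = 1e-10)
  expect_equal(sd(nz$expr2$values), sqrt(0.5), tolerance = 1e-10)
})

test_that("normalization restricts to common genes and hits moments on random data", {
  set.seed(41)
  m1 <- matrix(rnorm(20 * 8, mean = 5), 20, 8)
  m2 <- matrix(rnorm(15 * 12, mean = 7, sd = 2), 15, 12)
  rownames(m1) <- sprintf("g%02d", 1:20)
  rownames(m2) <- sprintf("g%02d", 6:20)
  colnames(m1) <- sprintf("a%02d", 1:8)
  colnames(m2) <- sprintf("b%02d", 1:12)
  nz <- normalize_pair(expression_matrix(m1), expression_matrix(m2))
  expect_setequal(gene_ids(nz$expr1), sprintf("g%02d", 6:20))
  expect_identical(gene_ids(nz$expr1), gene_ids(nz$expr2))
  for (d in 1:2) {
    v <- nz[[paste0("expr", d)]]$values
    expect_equal(unname(rowMeans(v)), nz$normalization$target_mean,
                 tolerance = 1e-10)
    expect_equal(unname(apply(v, 1, sd)), nz$normalization$target_sd,
                 tolerance = 1e-10)
  }
  # identical datasets: target mean m1 and sd s1 * sqrt(2/n)
  e <- expression_matrix(m1)
  nz2 <- normalize_pair(e, e)
  expect_equal(nz2$normalization$target_mean, unname(rowMeans(m1)))
  expect_equal(nz2$normalization$target_sd,
               unname(apply(m1, 1, sd)) * sqrt(2 / 8), tolerance = 1e-12)

  e3 <- expression_matrix(m1[1:3, ] * 0 + 1)  # constant genes
  expect_warning(normalize_pair(e3, e3), "constant")
  rownames(m2) <- sprintf("x%02d", 1:15)
  expect_error(normalize_pair(expression_matrix(m1), expression_matrix(m2)),
               "no genes in common")
})

test_that("k-NN transfer: zero distance wins, k = 1 equals brute force, affine invariant", {
  set.seed(43)
  n_per <- 8
  m <- matrix(rnorm(30 * 3 * n_per), 30, 3 * n_per)
  for (k in 0:2) m[(k * 10 + 1):(k * 10 + 10), (k * n_per + 1):((k + 1) * n_per)] <-
      m[(k * 10 + 1):(k * 10 + 10), (k * n_per + 1):((k + 1) * n_per)] + 4
  train <- make_expr(m)
  labels <- tibble::tibble(sample = sample_ids(train),
                           subtype = rep(1:3, each = n_per))
  # test set contains exact copies of training samples
  tv <- train$values
  test_m <- tv[, c(1, 9, 17)]
  colnames(test_m) <- paste0("t", 1:3)
  test <- expression_matrix(test_m)
  pred <- knn_transfer(train, labels, test, gene_ids(train), k = 3)
  expect_identical(pred$subtype, c(1L, 2L, 3L))

  # k = 1 equals the brute-force nearest neighbor
  set.seed(44)
  test2_m <- tv + rnorm(length(tv), sd = 0.5)
  colnames(test2_m) <- paste0("u", seq_len(ncol(m)))
  test2 <- expression_matrix(test2_m)
  pred1 <- knn_transfer(train, labels, test2, gene_ids(train), k = 1)
  brute <- apply(test2_m, 2, function(x) {
    labels$subtype[which.min(colSums((tv - x)^2))]
  })
  expect_identical(pred1$subtype, unname(brute))

  # common affine transform of both matrices leaves predictions unchanged
  aff <- function(e) expression_matrix(2.5 * e$values - 7, e$sample_class)
  pred_aff <- knn_transfer(aff(train), labels, aff(test2),
                           gene_ids(train), k = 3)
  expect_identical(pred_aff$subtype,
                   knn_transfer(train, labels, test2,
                                gene_ids(train), k = 3)$subtype)

  expect_error(knn_transfer(train, labels, test, character(0), 3), "empty")
  expect_error(knn_transfer(train, labels, test, gene_ids(train), k = 99),
               "exceeds")
})

test_that("confusion matrix counts, accuracy and row sums are correct", {
  a <- tibble::tibble(sample = paste0("s", 1:6), subtype = c(1, 1, 2, 2, 3, 3))
  cm <- confusion_and_accuracy(a, a)
  expect_equal(cm$accuracy, 1)
  expect_true(all(cm$table[upper.tri(cm$table)] == 0))

  b <- dplyr::mutate(a, subtype = c(2, 2, 3, 3, 1, 1))
  expect_equal(confusion_and_accuracy(a, b)$accuracy, 0)

  # 7 + 27 + 55 correct of 90 with one off-diagonal: accuracy 89/90
  self <- tibble::tibble(sample = sprintf("s%03d", 1:90),
                         subtype = rep(1:3, c(7, 28, 55)))
  pred <- self
  pred$subtype[8] <- 3L  # one subtype-2 case predicted as 3
  cm90 <- confusion_and_accuracy(self, pred)
  expect_equal(cm90$accuracy, 89 / 90)
  expect_equal(round(100 * cm90$accuracy, 1), 98.9)
  expect_equal(unname(rowSums(cm90$table)), c(7, 28, 55))
  expect_equal(sum(glance(cm90)$n), 90)

  expect_error(confusion_and_accuracy(a, a[1:3, ]), "same samples")
})

test_that("subtype identities match across datasets by signature overlap", {
  ref <- structure(list(sets = list("1" = paste0("a", 1:30),
                                    "2" = paste0("b", 1:30),
                                    "3" = paste0("c", 1:30))),
                   class = "signature_result")
  # own subtypes are a permuted version of ref's, with partial overlap
  own <- structure(list(sets = list("1" = paste0("c", 1:25),
                                    "2" = paste0("a", 5:30),
                                    "3" = paste0("b", 1:20))),
                   class = "signature_result")
  labels <- tibble::tibble(sample = paste0("s", 1:6),
                           subtype = c(1L, 1L, 2L, 2L, 3L, 3L))
  matched <- match_subtype_labels(ref, own, labels)
  expect_identical(matched$subtype, c(3L, 3L, 1L, 1L, 2L, 2L))
})

test_that("planted train/test pairs transfer labels almost perfectly", {
  accs <- vapply(1:5, function(s) {
    tr <- generate_subtype_testbed(seed = s, n_genes = 800,
                                   tumors_per_subtype = 12, n_normals = 6,
                                   sig_block_size = 40)
    te <- generate_subtype_testbed(seed = s + 500, n_genes = 800,
                                   tumors_per_subtype = 12, n_normals = 6,
                                   sig_block_size = 40)
    ftr <- iterate_subtyping(tr$expr, k_init = 10)
    fte <- iterate_subtyping(te$expr, k_init = 10)
    nz <- normalize_pair(tr$expr, te$expr)
    matched <- match_subtype_labels(ftr$signature, fte$signature, fte$labels)
    pred <- knn_transfer(nz$expr1, ftr$labels, nz$expr2,
                         intersect(ftr$signature$phi, gene_ids(nz$expr1)),
                         k = 3)
    confusion_and_accuracy(matched, pred)$accuracy
  }, numeric(1))
  expect_true(all(accs >= 0.95))
})
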