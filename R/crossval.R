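# Cross-dataset validation: two-moment gene-wise normalization to a common
# scale, k-NN label transfer on signature genes, and confusion/accuracy
# reporting with greedy subtype matching.

#' Normalize two expression datasets to a common per-gene scale
#'
#' Restricts both matrices to their common genes and affinely transforms
#' each gene in each dataset so that its per-dataset mean equals
#' `(m1 + m2) / 2` and its per-dataset standard deviation equals
#' `sqrt(s1^2/n1 + s2^2/n2)`, where `m_d`, `s_d`, `n_d` are the gene's mean,
#' SD and case count in dataset `d`.  A gene with zero SD in a dataset is
#' shifted to the target mean there and its scale left at zero (logged as a
#' warning).
#'
#' @param expr1,expr2 Two [expression_matrix()] objects sharing at least one
#'   gene id.
#' @return A list with `expr1`, `expr2` (normalized, common genes only) and
#'   `normalization`: a tibble with per-gene `gene`, `m1`, `s1`, `n1`, `m2`,
#'   `s2`, `n2`, `target_mean`, `target_sd`.
#' @export
normalize_pair <- function(expr1, expr2) {
  common <- intersect(gene_ids(expr1), gene_ids(expr2))
  if (length(common) == 0) stop("no genes in common", call. = FALSE)
  x1 <- expr1$values[common, , drop = FALSE]
  x2 <- expr2$values[common, , drop = FALSE]
  n1 <- ncol(x1)
  n2 <- ncol(x2)
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  s1 <- sqrt(row_vars(x1))
  s2 <- sqrt(row_vars(x2))
  target_mean <- (m1 + m2) / 2
  target_sd <- sqrt(s1^2 / n1 + s2^2 / n2)
  flat1 <- s1 == 0
  flat2 <- s2 == 0
  if (any(flat1 | flat2)) {
    warning(sum(flat1 | flat2), " gene(s) constant in one dataset; ",
            "shifted to the target mean with zero scale", call. = FALSE)
  }
  rescale <- function(x, m, s, flat) {
    scale_fac <- ifelse(flat, 0, target_sd / ifelse(flat, 1, s))
    (x - m) * scale_fac + target_mean
  }
  y1 <- rescale(x1, m1, s1, flat1)
  y2 <- rescale(x2, m2, s2, flat2)
  list(expr1 = expression_matrix(y1, expr1$sample_class),
       expr2 = expression_matrix(y2, expr2$sample_class),
       normalization = tibble::tibble(gene = common, m1 = unname(m1),
                                      s1 = unname(s1), n1 = n1,
                                      m2 = unname(m2), s2 = unname(s2),
                                      n2 = n2,
                                      target_mean = unname(target_mean),
                                      target_sd = unname(target_sd)))
}

#' Transfer subtype labels between datasets with k-NN
#'
#' Predicts a subtype label for every tumor sample of `test` by majority
#' vote among its `k` nearest training tumor samples (Euclidean distance
#' over `feature_genes`); vote ties are broken by the label of the single
#' nearest neighbor.
#'
#' @param train,test [expression_matrix()] objects on a common normalized
#'   scale (see [normalize_pair()]).
#' @param train_labels Tibble (`sample`, `subtype`) for the training tumors.
#' @param feature_genes Character vector of feature gene ids, typically the
#'   training run's signature union Phi.
#' @param k Number of neighbors (default 3).
#' @return Tibble with `sample`, `subtype` (predictions for test tumors).
#' @export
knn_transfer <- function(train, train_labels, test, feature_genes, k = 3) {
  if (length(feature_genes) == 0) stop("empty feature set", call. = FALSE)
  feature_genes <- unique(feature_genes)
  validate_labels(train, train_labels)
  missing <- setdiff(feature_genes,
                     intersect(gene_ids(train), gene_ids(test)))
  if (length(missing) > 0) {
    stop("feature genes absent from a dataset: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  if (k > nrow(train_labels)) stop("`k` exceeds training sample count",
                                   call. = FALSE)
  xtr <- t(train$values[feature_genes, train_labels$sample, drop = FALSE])
  test_samples <- tumor_samples(test)
  xte <- t(test$values[feature_genes, test_samples, drop = FALSE])
  lab <- train_labels$subtype
  pred <- vapply(seq_len(nrow(xte)), function(i) {
    d <- sqrt(colSums((t(xtr) - xte[i, ])^2))
    nn <- order(d)[seq_len(k)]
    votes <- table(lab[nn])
    top <- as.integer(names(votes)[votes == max(votes)])
    if (length(top) == 1) top else lab[nn[1]]
  }, integer(1))
  tibble::tibble(sample = test_samples, subtype = pred)
}

#' Confusion matrix and accuracy of transferred labels
#'
#' Cross-tabulates the test set's self-trained labels against the
#' k-NN-predicted labels (same samples, label alphabets already matched by
#' the caller, e.g. via [match_subtype_labels()]) and reports accuracy as
#' the diagonal fraction.
#'
#' @param self_labels,predicted Tibbles (`sample`, `subtype`) over the same
#'   samples.
#' @return An object of class `confusion_matrix`: list with `table`
#'   (square count matrix, rows = self-trained, columns = predicted) and
#'   `accuracy`.
#' @export
confusion_and_accuracy <- function(self_labels, predicted) {
  if (!setequal(self_labels$sample, predicted$sample)) {
    stop("`self_labels` and `predicted` must cover the same samples",
         call. = FALSE)
  }
  predicted <- predicted[match(self_labels$sample, predicted$sample), ]
  levs <- seq_len(max(self_labels$subtype, predicted$subtype))
  tab <- table(self = factor(self_labels$subtype, levels = levs),
               predicted = factor(predicted$subtype, levels = levs))
  structure(list(table = unclass(tab),
                 accuracy = sum(diag(tab)) / sum(tab)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> accuracy = ",
      sprintf("%.1f%%", 100 * x$accuracy), "\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Tidy a confusion matrix into long counts
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return Tibble with `self`, `predicted`, `n`.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  df <- as.data.frame(as.table(x$table))
  tibble::tibble(self = as.integer(as.character(df$self)),
                 predicted = as.integer(as.character(df$predicted)),
                 n = as.integer(df$Freq))
}

#' @rdname tidy.confusion_matrix
#' @export
glance.confusion_matrix <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n = sum(x$table))
}

#' Match subtype identities between two datasets by signature overlap
#'
#' Subtype integer labels are arbitrary per dataset; this greedily pairs
#' subtypes by descending Jaccard overlap of their signature gene sets and
#' returns `labels` relabeled into the reference's alphabet.  Unmatched
#' subtypes keep fresh labels after the reference's range.
#'
#' @param ref_sig,sig [detect_signature()] results for the reference and the
#'   relabeled dataset.
#' @param labels Tibble (`sample`, `subtype`) in `sig`'s alphabet.
#' @return `labels` with subtypes mapped into `ref_sig`'s alphabet.
#' @export
match_subtype_labels <- function(ref_sig, sig, labels) {
  ref_sets <- ref_sig$sets
  sets <- sig$sets
  overlap <- outer(seq_along(sets), seq_along(ref_sets),
                   Vectorize(function(i, j) {
                     a <- sets[[i]]
                     b <- ref_sets[[j]]
                     if (length(a) == 0 && length(b) == 0) return(0)
                     length(intersect(a, b)) / length(union(a, b))
                   }))
  mapping <- integer(length(sets))
  free_ref <- seq_along(ref_sets)
  free_own <- seq_along(sets)
  while (length(free_own) > 0 && length(free_ref) > 0) {
    sub <- overlap[free_own, free_ref, drop = FALSE]
    best <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    mapping[free_own[best[1]]] <- free_ref[best[2]]
    free_own <- free_own[-best[1]]
    free_ref <- free_ref[-best[2]]
  }
  nxt <- length(ref_sets)
  for (i in free_own) {
    nxt <- nxt + 1
    mapping[i] <- nxt
  }
  dplyr::mutate(labels, subtype = mapping[.data$subtype])
}

#' Autoplot a confusion matrix as a heatmap
#'
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy.confusion_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$self,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_reverse(breaks = unique(df$self)) +
    ggplot2::scale_x_continuous(breaks = unique(df$predicted)) +
    ggplot2::labs(x = "predicted subtype", y = "self-trained subtype",
                  fill = "count") +
    ggplot2::theme_minimal()
}
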