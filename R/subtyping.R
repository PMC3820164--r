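# Iterative, signature-regularized subtyping: alternate spectral clustering
# of tumor samples on the current gene set with signature detection on the
# full matrix, absorb singleton clusters, dissolve clusters whose signatures
# are too small, and re-cluster on the signature union until the partition
# stabilizes.

#' Spectral clustering dendrogram of tumor samples
#'
#' Builds a sample-sample similarity from the shifted Pearson correlation
#' `(1 + r) / 2` over the given gene subset, embeds the tumor samples with
#' the normalized graph Laplacian (top `embed_dims` non-trivial eigenvectors
#' of `D^(-1/2) S D^(-1/2)`, each scaled by its eigenvalue, rows normalized
#' to unit length), and agglomerates the embedded points into a dendrogram.
#' The default agglomeration is nearest-neighbor linkage on the
#' mutual-reachability distance
#' `d_mr(a, b) = max(core(a), core(b), d(a, b))` with `core(x)` the distance
#' from `x` to its `min_pts`-th nearest neighbor (the density-robust
#' single-linkage hierarchy): cutting such a tree beyond the number of
#' separable clusters peels off individual outlier samples rather than
#' bisecting a cluster, which is exactly the situation the core-cluster
#' absorption step of [cut_to_core_clusters()] repairs.  Plain
#' [stats::hclust()] linkages are available via `linkage`.  Eigenvector
#' signs are fixed by making each vector's largest-magnitude entry positive,
#' so the result is deterministic.  `method = "cor_hclust"` skips the
#' spectral step and clusters directly on correlation distance `1 - r` (the
#' embedding then comes from classical MDS, used only for centroid
#' computations).
#'
#' @param expr An [expression_matrix()] object; only tumor samples are
#'   clustered.
#' @param gene_subset Character vector of gene ids to compute similarity on.
#' @param embed_dims Number of embedding dimensions (capped at
#'   `n_tumors - 1`).
#' @param method `"spectral"` (default) or `"cor_hclust"`.
#' @param linkage `"mreach_single"` (default, see above) or any
#'   [stats::hclust()] agglomeration method.
#' @param min_pts Neighbor order of the core distance used by
#'   `"mreach_single"` (default 3).
#' @return An object of class `spectral_dendrogram`: list with `hclust`
#'   (the tree), `embedding` (samples x dims matrix), `samples`, `method`.
#' @export
build_dendrogram <- function(expr, gene_subset, embed_dims,
                             method = c("spectral", "cor_hclust"),
                             linkage = "mreach_single", min_pts = 3) {
  method <- match.arg(method)
  tumors <- tumor_samples(expr)
  if (length(tumors) < 3) stop("need at least 3 tumor samples", call. = FALSE)
  gene_subset <- intersect(gene_subset, gene_ids(expr))
  if (length(gene_subset) < 2) {
    stop("`gene_subset` must contain at least 2 genes present in the matrix",
         call. = FALSE)
  }
  x <- expr$values[gene_subset, tumors, drop = FALSE]
  r <- suppressWarnings(stats::cor(x))
  r[!is.finite(r)] <- 0  # constant sample profile => undefined correlation
  diag(r) <- 1
  n <- length(tumors)
  dims <- max(1L, min(as.integer(embed_dims), n - 1L))
  if (method == "spectral") {
    s <- (1 + r) / 2
    d <- rowSums(s)
    a <- s / sqrt(d %o% d)
    eig <- eigen(a, symmetric = TRUE)
    idx <- 1L + seq_len(dims)  # skip the trivial leading eigenvector
    emb <- eig$vectors[, idx, drop = FALSE]
    emb <- sweep(emb, 2, abs(eig$values[idx]), `*`)
    emb <- apply(emb, 2, fix_sign)
    if (is.null(dim(emb))) emb <- matrix(emb, nrow = n)
    rn <- sqrt(rowSums(emb^2))
    rn[rn == 0] <- 1
    emb <- emb / rn
    rownames(emb) <- tumors
    tree <- agglomerate(stats::dist(emb), linkage, min_pts)
    tree$labels <- tumors
  } else {
    dd <- stats::as.dist(1 - r)
    tree <- agglomerate(dd, linkage, min_pts)
    tree$labels <- tumors
    emb <- stats::cmdscale(dd, k = dims)
    if (is.null(dim(emb))) emb <- matrix(emb, nrow = n)
    rownames(emb) <- tumors
  }
  structure(list(hclust = tree, embedding = emb, samples = tumors,
                 method = method, n_genes = length(gene_subset)),
            class = "spectral_dendrogram")
}

# dendrogram construction: density-robust single linkage (single linkage on
# the mutual-reachability distance) or a plain hclust linkage
agglomerate <- function(dd, linkage, min_pts) {
  if (linkage == "mreach_single") {
    d <- as.matrix(dd)
    k <- min(min_pts, nrow(d) - 1)
    core <- apply(d, 1, function(r) sort(r)[k + 1])  # k-th NN, excluding self
    dm <- pmax(d, outer(core, core, pmax))
    diag(dm) <- 0
    stats::hclust(stats::as.dist(dm), method = "single")
  } else {
    stats::hclust(dd, method = linkage)
  }
}

# deterministic eigenvector sign: largest-magnitude entry positive
fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

#' @export
print.spectral_dendrogram <- function(x, ...) {
  cat("<spectral_dendrogram> ", length(x$samples), " tumor samples, ",
      ncol(x$embedding), "-dim ", x$method, " embedding over ",
      x$n_genes, " genes\n", sep = "")
  invisible(x)
}

#' Cut a dendrogram into core clusters
#'
#' Cuts the tree into `K` groups, then absorbs singleton clusters: each
#' singleton sample is re-assigned to the cluster whose centroid (mean
#' embedding coordinate) is nearest in Euclidean distance, preferring
#' clusters that already have two or more members.  The result has
#' `K' <= K` clusters, all of size at least 2, relabeled contiguously by
#' first appearance in sample order.
#'
#' @param dendro A [build_dendrogram()] result.
#' @param K Number of clusters to cut into (`1 <= K <=` number of samples).
#' @return A tibble with columns `sample`, `subtype`.
#' @export
cut_to_core_clusters <- function(dendro, K) {
  n <- length(dendro$samples)
  if (K < 1 || K > n) stop("`K` must be in 1..", n, call. = FALSE)
  labs <- stats::cutree(dendro$hclust, k = K)[dendro$samples]
  emb <- dendro$embedding
  repeat {
    sizes <- table(labs)
    if (length(sizes) == 1 || all(sizes >= 2)) break
    singleton_clusters <- names(sizes)[sizes == 1]
    sample_i <- dendro$samples[labs %in% as.integer(singleton_clusters)][1]
    from <- labs[sample_i]
    targets <- setdiff(names(sizes)[sizes >= 2], as.character(from))
    if (length(targets) == 0) {
      targets <- setdiff(names(sizes), as.character(from))
    }
    cent <- cluster_centroids(emb, labs, as.integer(targets))
    d <- sqrt(colSums((t(cent) - emb[sample_i, ])^2))
    labs[sample_i] <- as.integer(targets)[which.min(d)]
  }
  tibble::tibble(sample = dendro$samples,
                 subtype = relabel_contiguous(labs))
}

cluster_centroids <- function(emb, labs, clusters) {
  t(vapply(clusters, function(cl) {
    colMeans(emb[labs == cl, , drop = FALSE])
  }, numeric(ncol(emb))))
}

# integer labels -> contiguous 1..K by order of first appearance
relabel_contiguous <- function(labs) {
  as.integer(factor(labs, levels = unique(labs)))
}

#' Dissolve clusters with too few signature genes
#'
#' A cluster is *bad* when its signature holds fewer than
#' `factor * |Phi| / K'` genes (default `factor = 1/4`, i.e. fewer than
#' `|Phi| / (4 K')` where `K'` is the current number of core clusters and
#' `Phi` the union of all signatures).  Every sample of a bad cluster is
#' re-assigned, individually, to the good cluster with the nearest centroid
#' in the embedding.  The result is relabeled contiguously (`K'' <= K'`
#' clusters).
#'
#' @param labels Tibble with columns `sample`, `subtype` (the K' core
#'   clusters).
#' @param sig The [detect_signature()] result computed under `labels`.
#' @param embedding Samples x dims coordinate matrix (rownames = sample
#'   ids), e.g. `dendro$embedding`.
#' @param factor Fraction of `|Phi| / K'` below which a cluster is bad.
#' @return A tibble with columns `sample`, `subtype`.
#' @export
merge_bad_clusters <- function(labels, sig, embedding, factor = 0.25) {
  k_prime <- max(labels$subtype)
  phi_size <- length(sig$phi)
  sig_sizes <- lengths(sig$sets)[as.character(seq_len(k_prime))]
  threshold <- factor * phi_size / k_prime
  bad <- which(sig_sizes < threshold)
  if (length(bad) == k_prime) {
    stop("all ", k_prime, " clusters fall below the signature-size ",
         "threshold (", format(threshold, digits = 4),
         "); the partition carries no subtype-specific signal", call. = FALSE)
  }
  if (length(bad) == 0) return(labels)
  good <- setdiff(seq_len(k_prime), bad)
  labs <- stats::setNames(labels$subtype, labels$sample)
  emb <- embedding[labels$sample, , drop = FALSE]
  cent <- cluster_centroids(emb, labs, good)
  for (s in labels$sample[labels$subtype %in% bad]) {
    d <- sqrt(colSums((t(cent) - emb[s, ])^2))
    labs[s] <- good[which.min(d)]
  }
  tibble::tibble(sample = labels$sample,
                 subtype = relabel_contiguous(unname(labs)))
}

#' Iterative signature-regularized subtype discovery
#'
#' Runs the full loop: (1) build a spectral dendrogram of tumor samples on
#' the current gene set (initially the top `gene_fraction` of genes by
#' tumor-sample variance); (2) cut into `K` clusters and absorb singletons
#' (K' core clusters); (3) detect per-cluster signatures on the *original,
#' full* matrix; (4) form the union Phi; (5) dissolve clusters whose
#' signatures hold fewer than `|Phi| / (4 K')` genes (K'' good clusters);
#' (6) replace the clustering gene set by Phi; (7) set `K = K'' + delta_k`;
#' repeat until the partition and K'' are identical in two consecutive
#' iterations, or `max_iter` is reached.
#'
#' @inheritParams detect_signature
#' @param k_init Initial number of clusters requested (default 20).
#' @param delta_k Increment added to K'' for the next iteration (default 1).
#' @param max_iter Maximum number of iterations (default 10).
#' @param gene_fraction Fraction of genes (by tumor variance) in the initial
#'   clustering set (default 0.10).
#' @param bad_cluster_factor Signature-size factor for bad clusters
#'   (default 1/4).
#' @param embed_dims Spectral embedding dimension; default = the K requested
#'   at each iteration.
#' @param method Clustering method passed to [build_dendrogram()].
#' @param linkage,min_pts Dendrogram agglomeration options, passed to
#'   [build_dendrogram()].
#' @return An object of class `subtyping_result`: list with `labels` (final
#'   sample/subtype tibble), `signature` (final [detect_signature()] result
#'   under those labels), `trace` (one tibble row per iteration), `converged`,
#'   `iterations_run`, `params`.
#' @examples
#' \donttest{
#' sim <- generate_subtype_testbed(n_subtypes = 3, tumors_per_subtype = 15,
#'                                 n_normals = 8, n_genes = 600,
#'                                 sig_block_size = 40, seed = 1)
#' fit <- iterate_subtyping(sim$expr, k_init = 8)
#' glance(fit)
#' }
#' @export
iterate_subtyping <- function(expr, k_init = 20, fct = 1, delta_k = 1,
                              alpha = 0.05, max_iter = 10,
                              gene_fraction = 0.10, bad_cluster_factor = 0.25,
                              embed_dims = NULL,
                              method = c("spectral", "cor_hclust"),
                              linkage = "mreach_single", min_pts = 3) {
  method <- match.arg(method)
  stopifnot(k_init >= 2, delta_k >= 1, max_iter >= 1)
  tumors <- tumor_samples(expr)
  genes <- top_variance_genes(expr, gene_fraction)
  K <- min(k_init, length(tumors))
  prev <- NULL
  trace <- list()
  converged <- FALSE
  final_labels <- NULL
  for (iter in seq_len(max_iter)) {
    K <- min(K, length(tumors))
    dims <- if (is.null(embed_dims)) K else embed_dims
    dendro <- build_dendrogram(expr, genes, embed_dims = dims, method = method,
                               linkage = linkage, min_pts = min_pts)
    core <- cut_to_core_clusters(dendro, K)
    sig <- detect_signature(expr, core, fct = fct, alpha = alpha)
    if (length(sig$phi) == 0) {
      stop("signature union Phi is empty at iteration ", iter,
           "; lower `fct` (currently ", fct, ")", call. = FALSE)
    }
    merged <- merge_bad_clusters(core, sig, dendro$embedding,
                                 factor = bad_cluster_factor)
    k_prime <- max(core$subtype)
    k_dprime <- max(merged$subtype)
    trace[[iter]] <- tibble::tibble(
      iteration = iter, k_requested = K, k_prime = k_prime,
      k_double_prime = k_dprime, n_phi = length(sig$phi),
      n_genes_clustered = length(intersect(genes, gene_ids(expr))),
      cluster_sizes = list(as.integer(table(merged$subtype))),
      signature_sizes = list(unname(lengths(sig$sets))),
      labels = list(merged))
    final_labels <- merged
    if (!is.null(prev) && max(prev$subtype) == k_dprime &&
        same_partition(prev, merged)) {
      converged <- TRUE
      break
    }
    prev <- merged
    genes <- sig$phi
    K <- k_dprime + delta_k
  }
  final_sig <- detect_signature(expr, final_labels, fct = fct, alpha = alpha)
  structure(
    list(labels = final_labels, signature = final_sig,
         trace = dplyr::bind_rows(trace), converged = converged,
         iterations_run = length(trace),
         params = list(k_init = k_init, fct = fct, delta_k = delta_k,
                       alpha = alpha, max_iter = max_iter,
                       gene_fraction = gene_fraction,
                       bad_cluster_factor = bad_cluster_factor,
                       method = method, linkage = linkage,
                       min_pts = min_pts)),
    class = "subtyping_result")
}

# do two sample->label tables induce the same partition?
same_partition <- function(a, b) {
  a <- a[order(a$sample), ]
  b <- b[order(b$sample), ]
  if (!identical(a$sample, b$sample)) return(FALSE)
  identical(relabel_contiguous(a$subtype), relabel_contiguous(b$subtype))
}

#' @export
print.subtyping_result <- function(x, ...) {
  cat("<subtyping_result> ", max(x$labels$subtype), " subtypes after ",
      x$iterations_run, " iteration(s); converged: ", x$converged, "\n",
      sep = "")
  cat("  cluster sizes:",
      paste(as.integer(table(x$labels$subtype)), collapse = ", "), "\n")
  cat("  |Phi| =", length(x$signature$phi), "\n")
  invisible(x)
}

#' Tidy a subtyping result into the final sample-label table
#'
#' @param x A `subtyping_result`.
#' @param ... Unused.
#' @return Tibble with columns `sample`, `subtype`.
#' @export
tidy.subtyping_result <- function(x, ...) x$labels

#' One-row summary of a subtyping run
#'
#' @param x A `subtyping_result`.
#' @param ... Unused.
#' @return Tibble with `n_subtypes`, `converged`, `iterations_run`, `n_phi`.
#' @export
glance.subtyping_result <- function(x, ...) {
  tibble::tibble(n_subtypes = max(x$labels$subtype),
                 converged = x$converged,
                 iterations_run = x$iterations_run,
                 n_phi = length(x$signature$phi))
}

#' Plot the iteration trace of a subtyping run
#'
#' Shows the requested K, core-cluster count K' and good-cluster count K''
#' across iterations.
#'
#' @param object A `subtyping_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subtyping_result <- function(object, ...) {
  df <- object$trace |>
    dplyr::select("iteration", "k_requested", "k_prime", "k_double_prime") |>
    tidyr::pivot_longer(-"iteration", names_to = "quantity",
                        values_to = "clusters")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$clusters,
                                   colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(df$iteration)) +
    ggplot2::labs(x = "iteration", y = "number of clusters", colour = NULL) +
    ggplot2::theme_minimal()
}
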