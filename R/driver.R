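# Subtype-specific driver prioritization: between-set covariance of
# signature and candidate genes over the subtype's samples, projection onto
# the first left singular vector, and permutation p-values from random
# signature gene sets.

#' Between-set covariance of signature and candidate genes
#'
#' Sample covariance between each signature gene (rows, J) and each
#' candidate gene (columns, L), computed over the given subtype's samples
#' only.  The covariance centers every gene across those samples, which is
#' the row-wise zero-mean precondition of the PCA projection applied by
#' [driver_potentials()].
#'
#' @param expr An [expression_matrix()] object.
#' @param subtype_samples Character vector of sample ids (>= 3) belonging to
#'   the subtype.
#' @param signature Character vector of signature gene ids.
#' @param candidates Character vector of candidate gene ids (disjoint from
#'   `signature`).
#' @return A J x L numeric matrix with signature genes as rownames and
#'   candidate genes as colnames.
#' @export
between_set_covariance <- function(expr, subtype_samples, signature,
                                   candidates) {
  if (length(signature) == 0 || length(candidates) == 0) {
    stop("`signature` and `candidates` must be non-empty", call. = FALSE)
  }
  overlap <- intersect(signature, candidates)
  if (length(overlap) > 0) {
    stop("signature and candidate sets overlap: ",
         paste(utils::head(overlap, 5), collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(c(signature, candidates), gene_ids(expr))
  if (length(missing) > 0) {
    stop("genes absent from the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  if (length(subtype_samples) < 3) {
    stop("need at least 3 subtype samples", call. = FALSE)
  }
  xa <- t(expr$values[signature, subtype_samples, drop = FALSE])
  xb <- t(expr$values[candidates, subtype_samples, drop = FALSE])
  n_const <- sum(row_vars(t(xa)) == 0) + sum(row_vars(t(xb)) == 0)
  if (n_const > 0) {
    warning(n_const, " constant gene(s) over the subtype samples; their ",
            "covariances are zero", call. = FALSE)
  }
  stats::cov(xa, xb)
}

#' Driver potentials by SVD projection
#'
#' Thin SVD of the between-set covariance `C_ab = U S V^T`; the candidate
#' driver potentials are the projection onto the first left singular vector,
#' `w_hat_b = C_ab^T u_1 = sigma_1 v_1`.  The sign of `u_1` (and `v_1` with
#' it) is fixed by making the largest-magnitude entry of `u_1` positive, so
#' results are deterministic across linear-algebra backends.  A positive
#' entry of `w_hat_b` means the candidate is overall positively correlated
#' with the signature set, and vice versa.
#'
#' @param C_ab Numeric matrix (signature genes x candidate genes).
#' @return An object of class `svd_projection`: list with `u1`, `sigma1`,
#'   `v1`, `w_hat_b` (named by candidate when `C_ab` has colnames), and
#'   `C_ab`.
#' @export
driver_potentials <- function(C_ab) {
  C_ab <- as.matrix(C_ab)
  if (!all(is.finite(C_ab))) stop("`C_ab` must be finite", call. = FALSE)
  if (all(C_ab == 0)) {
    warning("C_ab is identically zero; all driver potentials are 0",
            call. = FALSE)
    u1 <- c(1, rep(0, nrow(C_ab) - 1))
    v1 <- c(1, rep(0, ncol(C_ab) - 1))
    w <- stats::setNames(rep(0, ncol(C_ab)), colnames(C_ab))
    return(structure(list(u1 = u1, sigma1 = 0, v1 = v1, w_hat_b = w,
                          C_ab = C_ab), class = "svd_projection"))
  }
  dec <- svd(C_ab, nu = 1, nv = 1)
  u1 <- dec$u[, 1]
  v1 <- dec$v[, 1]
  if (u1[which.max(abs(u1))] < 0) {
    u1 <- -u1
    v1 <- -v1
  }
  w <- drop(crossprod(C_ab, u1))
  names(w) <- colnames(C_ab)
  structure(list(u1 = u1, sigma1 = dec$d[1], v1 = v1, w_hat_b = w,
                 C_ab = C_ab), class = "svd_projection")
}

#' @export
print.svd_projection <- function(x, ...) {
  cat("<svd_projection> ", nrow(x$C_ab), " signature x ", ncol(x$C_ab),
      " candidate genes; sigma1 = ", format(x$sigma1, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Tidy an SVD projection into a per-candidate tibble
#'
#' @param x An `svd_projection`.
#' @param ... Unused.
#' @return Tibble with `gene`, `driver_potential`.
#' @export
tidy.svd_projection <- function(x, ...) {
  tibble::tibble(gene = names(x$w_hat_b) %||% as.character(seq_along(x$w_hat_b)),
                 driver_potential = unname(x$w_hat_b))
}

#' Permutation p-values for candidate driver potentials
#'
#' Repeats the covariance + SVD projection with random signature sets: each
#' permutation draws `|signature|` genes uniformly without replacement from
#' the pool of all genes excluding the candidates, and all resulting null
#' driver potentials are pooled into one empirical null distribution.  The
#' two-sided p-value of candidate `l` is
#' `(1 + #(|null| >= |w_hat_b[l]|)) / (1 + n_null)`.  Candidates are ranked
#' by ascending p-value, ties broken by larger `|w_hat_b|` then gene id.
#'
#' @inheritParams between_set_covariance
#' @param n_permutations Number of random signature sets (>= 100).
#' @param seed Integer RNG seed.
#' @return An object of class `driver_ranking`: a tibble with columns
#'   `gene`, `driver_potential`, `p_value`, `rank`, carrying the projection
#'   (`svd_projection`), the pooled null values and the run parameters as
#'   attributes.
#' @export
permutation_pvalues <- function(expr, subtype_samples, signature, candidates,
                                n_permutations = 1000, seed = 1) {
  if (n_permutations < 100) stop("`n_permutations` must be >= 100",
                                 call. = FALSE)
  pool <- setdiff(gene_ids(expr), candidates)
  if (length(pool) < length(signature)) {
    stop("gene pool (", length(pool), ") smaller than the signature (",
         length(signature), ")", call. = FALSE)
  }
  proj <- driver_potentials(
    between_set_covariance(expr, subtype_samples, signature, candidates))
  # centered candidate block reused across permutations
  xb <- t(expr$values[candidates, subtype_samples, drop = FALSE])
  xb <- scale(xb, center = TRUE, scale = FALSE)
  n <- length(subtype_samples)
  set.seed(seed)
  null_vals <- vector("list", n_permutations)
  for (b in seq_len(n_permutations)) {
    rand_sig <- sample(pool, length(signature))
    xa <- t(expr$values[rand_sig, subtype_samples, drop = FALSE])
    xa <- scale(xa, center = TRUE, scale = FALSE)
    C <- crossprod(xa, xb) / (n - 1)
    # degenerate null replicates (all-zero C) are routine, not reportable
    null_vals[[b]] <- unname(suppressWarnings(driver_potentials(C))$w_hat_b)
  }
  null_pool <- abs(unlist(null_vals))
  n_null <- length(null_pool)
  obs <- proj$w_hat_b
  # (1 + #{|null| >= |obs|}) / (1 + n_null), vectorized via sorted null
  sorted_null <- sort(null_pool)
  exceed <- n_null - findInterval(abs(obs), sorted_null, left.open = TRUE)
  p <- (1 + exceed) / (1 + n_null)
  ord <- order(p, -abs(obs), rank_lexicographic(names(obs)))
  rk <- integer(length(obs))
  rk[ord] <- seq_along(obs)
  out <- tibble::tibble(gene = names(obs), driver_potential = unname(obs),
                        p_value = p, rank = rk)
  structure(out,
            class = c("driver_ranking", class(out)),
            projection = proj, null_values = unlist(null_vals),
            params = list(n_permutations = n_permutations, seed = seed,
                          n_signature = length(signature),
                          n_candidates = length(candidates)))
}

#' Subtype-specific driver analysis across all subtypes
#'
#' Runs [permutation_pvalues()] once per subtype with that subtype's
#' signature genes and candidate list; the candidate lists come from
#' external pre-selection (e.g. GISTIC recurrent-CNA genes) and are supplied
#' per subtype.  Subtypes with an empty signature are skipped with a
#' warning.  Candidates overlapping a subtype's signature are dropped from
#' that subtype's list (with a warning), since the two sets must be
#' disjoint.
#'
#' @inheritParams permutation_pvalues
#' @param labels Subtype assignment tibble (`sample`, `subtype`).
#' @param sig A [detect_signature()] result for `labels`.
#' @param candidates_per_subtype Named list: subtype index (as character) ->
#'   character vector of candidate gene ids.
#' @param p_threshold Significance cutoff on permutation p-values
#'   (default 0.01).
#' @return A tibble with one row per (subtype, candidate): `subtype`,
#'   `gene`, `driver_potential`, `p_value`, `rank`, `significant`.
#' @export
run_driver_analysis <- function(expr, labels, sig, candidates_per_subtype,
                                n_permutations = 1000, seed = 1,
                                p_threshold = 0.01) {
  validate_labels(expr, labels)
  purrr::map_dfr(names(candidates_per_subtype), function(k_chr) {
    k <- as.integer(k_chr)
    s_k <- sig$sets[[k_chr]]
    if (is.null(s_k) || length(s_k) == 0) {
      warning("subtype ", k_chr, " has an empty signature; skipped",
              call. = FALSE)
      return(NULL)
    }
    cand <- candidates_per_subtype[[k_chr]]
    drop <- intersect(cand, s_k)
    if (length(drop) > 0) {
      warning("subtype ", k_chr, ": dropping ", length(drop),
              " candidate(s) overlapping the signature", call. = FALSE)
      cand <- setdiff(cand, drop)
    }
    rk <- permutation_pvalues(expr,
                              subtype_samples = labels$sample[labels$subtype == k],
                              signature = s_k, candidates = cand,
                              n_permutations = n_permutations,
                              seed = seed + k)
    tibble::tibble(subtype = k, gene = rk$gene,
                   driver_potential = rk$driver_potential,
                   p_value = rk$p_value, rank = rk$rank,
                   significant = rk$p_value < p_threshold)
  })
}

#' Candidate-versus-null density plot for a driver ranking
#'
#' Overlays the distribution of observed candidate driver potentials on the
#' pooled permutation null.
#'
#' @param object A `driver_ranking` from [permutation_pvalues()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.driver_ranking <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(value = object$driver_potential, set = "candidates"),
    tibble::tibble(value = attr(object, "null_values"), set = "null"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, colour = .data$set)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "driver potential", y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}
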