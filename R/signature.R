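# Subtype signature detection: a gene belongs to signature S_k when it is
# (i) differentially expressed in subtype k versus all other samples
# (moderated t, BH-adjusted) and (ii) subtype-specific by the fold-change
# rule FC_k = Delta_k - Delta'_k > FCT with a strict direction requirement.

#' Moderated differential-expression test for one subtype versus the rest
#'
#' Two-group comparison of subtype `k` against every other sample (all other
#' tumor subtypes pooled together with the normals).  Per-gene variances are
#' shrunk toward a common prior by empirical Bayes ([limma::squeezeVar()]),
#' giving the limma-style moderated t-statistic; `prior = "none"` disables
#' the shrinkage and yields the ordinary pooled-variance two-sample t.
#'
#' @param expr An [expression_matrix()] object.
#' @param labels Subtype assignment: a data frame with columns `sample` and
#'   `subtype` covering tumor samples only.
#' @param k Subtype index to test.
#' @param prior `"eb"` (default, empirical-Bayes moderation) or `"none"`
#'   (ordinary pooled t).
#' @return A tibble with one row per gene: `gene`, `mean_in`, `mean_out`,
#'   `t_stat`, `p_raw` (two-sided).
#' @export
moderated_de_test <- function(expr, labels, k, prior = c("eb", "none")) {
  prior <- match.arg(prior)
  validate_labels(expr, labels)
  in_samples <- labels$sample[labels$subtype == k]
  out_samples <- setdiff(sample_ids(expr), in_samples)
  n1 <- length(in_samples)
  n2 <- length(out_samples)
  if (n1 < 2 || n2 < 2) {
    stop("both groups need >= 2 samples (subtype ", k, ": ", n1,
         " vs rest: ", n2, ")", call. = FALSE)
  }
  m <- expr$values
  x1 <- m[, in_samples, drop = FALSE]
  x2 <- m[, out_samples, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  ss1 <- rowSums(x1 * x1) - n1 * m1 * m1
  ss2 <- rowSums(x2 * x2) - n2 * m2 * m2
  df <- n1 + n2 - 2
  s2 <- pmax(ss1 + ss2, 0) / df
  if (all(s2 == 0)) {
    stop("pooled variance is zero for every gene; nothing to test",
         call. = FALSE)
  }
  if (prior == "eb") {
    sq <- limma::squeezeVar(s2, df = df)
    s2_use <- sq$var.post
    df_total <- min(df + sq$df.prior, length(s2) * df)
  } else {
    s2_use <- s2
    df_total <- df
  }
  se <- sqrt(s2_use * (1 / n1 + 1 / n2))
  diff <- m1 - m2
  t_stat <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  p_raw <- 2 * stats::pt(-abs(t_stat), df = df_total)
  tibble::tibble(gene = gene_ids(expr), mean_in = unname(m1),
                 mean_out = unname(m2), t_stat = unname(t_stat),
                 p_raw = unname(p_raw))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, preserving the input order.
#'
#' @param p_raw Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_raw) {
  if (any(!is.finite(p_raw)) || any(p_raw < 0 | p_raw > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_raw, method = "BH")
}

#' Subtype-specific fold change of a gene
#'
#' Given per-group mean expressions (the K tumor subtypes, plus the normal
#' group as one extra group when normals are present), computes for group
#' `k` the subtype-specific deviation
#' `Delta_k = min(|mu_k - min_{l != k} mu_l|, |mu_k - max_{l != k} mu_l|)`,
#' the non-specific spread `Delta'_k = max_{l != k} mu_l - min_{l != k} mu_l`,
#' and the subtype-specific fold change `FC_k = Delta_k - Delta'_k`.
#' Direction is `"up"` iff `mu_k` strictly exceeds every other group mean,
#' `"down"` iff strictly below, else `"none"` (ties give `"none"`).
#'
#' @param mu Numeric vector of group means (length >= 2), or a matrix with
#'   one row per gene and one column per group for the vectorized form.
#' @param k Index of the group of interest.
#' @return A tibble with columns `delta_k`, `delta_prime_k`, `fc_k`,
#'   `direction` (one row per gene).
#' @examples
#' subtype_specific_fc(c(5, 1, 2, 3), k = 1)  # Delta 2, Delta' 2, FC 0, up
#' @export
subtype_specific_fc <- function(mu, k) {
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1)
  if (ncol(mu) < 2) stop("need at least 2 groups", call. = FALSE)
  if (!all(is.finite(mu))) stop("group means must be finite", call. = FALSE)
  if (k < 1 || k > ncol(mu)) stop("`k` out of range", call. = FALSE)
  mu_k <- mu[, k]
  others <- mu[, -k, drop = FALSE]
  lo <- do.call(pmin, as.data.frame(others))
  hi <- do.call(pmax, as.data.frame(others))
  delta_k <- pmin(abs(mu_k - lo), abs(mu_k - hi))
  delta_prime_k <- hi - lo
  direction <- ifelse(mu_k > hi, "up", ifelse(mu_k < lo, "down", "none"))
  tibble::tibble(delta_k = delta_k, delta_prime_k = delta_prime_k,
                 fc_k = delta_k - delta_prime_k, direction = direction)
}

#' Detect subtype-specific gene signatures
#'
#' For each subtype `k`, the signature `S_k` is the set of genes that are
#' both statistically differentially expressed in `k` versus all other
#' samples (BH-adjusted moderated-t p below `alpha`) and subtype-specific:
#' direction strictly up or down against every other group mean, with
#' subtype-specific fold change `FC_k` strictly above the threshold `fct`.
#' Group means are taken over the K tumor subtypes plus (when present) the
#' normal samples as one additional group, so a gene shifted in all tumors
#' alike is never called subtype-specific.
#'
#' @inheritParams moderated_de_test
#' @param fct Fold-change threshold (log2 units), `>= 0`.  Default 1.
#' @param alpha Cutoff on BH-adjusted p-values.  Default 0.05.
#' @return An object of class `signature_result`: list with
#'   * `stats`: tibble of per-(gene, subtype) statistics (`gene`, `subtype`,
#'     `mu_k`, `delta_k`, `delta_prime_k`, `fc_k`, `t_stat`, `p_raw`,
#'     `p_adj`, `direction`, `in_signature`);
#'   * `sets`: named list of per-subtype signature gene id vectors `S_k`;
#'   * `phi`: the union of all signatures;
#'   * `params`: the `fct`/`alpha` used.
#' @export
detect_signature <- function(expr, labels, fct = 1, alpha = 0.05,
                             prior = c("eb", "none")) {
  prior <- match.arg(prior)
  stopifnot(fct >= 0, alpha > 0, alpha < 1)
  validate_labels(expr, labels)
  K <- max(labels$subtype)
  groups <- split(labels$sample, labels$subtype)
  nrm <- normal_samples(expr)
  if (length(nrm) > 0) groups <- c(groups, list(normal = nrm))
  mu <- vapply(groups, function(s) {
    rowMeans(expr$values[, s, drop = FALSE])
  }, numeric(nrow(expr$values)))
  stats_tbl <- purrr::map_dfr(seq_len(K), function(k) {
    de <- moderated_de_test(expr, labels, k, prior = prior)
    fc <- subtype_specific_fc(mu, k)
    p_adj <- bh_adjust(de$p_raw)
    tibble::tibble(
      gene = de$gene, subtype = k, mu_k = mu[, k],
      delta_k = fc$delta_k, delta_prime_k = fc$delta_prime_k,
      fc_k = fc$fc_k, t_stat = de$t_stat, p_raw = de$p_raw,
      p_adj = p_adj, direction = fc$direction,
      in_signature = p_adj < alpha & fc$direction != "none" & fc$fc_k > fct
    )
  })
  sets <- purrr::map(seq_len(K), function(k) {
    stats_tbl$gene[stats_tbl$subtype == k & stats_tbl$in_signature]
  })
  names(sets) <- as.character(seq_len(K))
  res <- structure(
    list(stats = stats_tbl, sets = sets,
         phi = sort(unique(unlist(sets, use.names = FALSE))),
         params = list(fct = fct, alpha = alpha, n_subtypes = K)),
    class = "signature_result")
  check_signature_consistency(res)
  res
}

# A gene may carry direction "up" in at most one subtype and "down" in at
# most one (guaranteed by strict inequalities on the shared group means);
# warn loudly if numerical ties ever break this.
check_signature_consistency <- function(res) {
  sig <- res$stats[res$stats$in_signature, c("gene", "direction")]
  dup <- duplicated(sig)
  if (any(dup)) {
    warning("gene(s) assigned the same direction in multiple signatures: ",
            paste(unique(sig$gene[dup]), collapse = ", "), call. = FALSE)
  }
  invisible(res)
}

#' @export
print.signature_result <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat("<signature_result> ", x$params$n_subtypes, " subtypes, |Phi| = ",
      length(x$phi), " (fct = ", x$params$fct, ", alpha = ",
      x$params$alpha, ")\n", sep = "")
  cat("  |S_k|:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a signature result into its per-gene statistics table
#'
#' @param x A `signature_result`.
#' @param ... Unused.
#' @return The per-(gene, subtype) statistics tibble.
#' @export
tidy.signature_result <- function(x, ...) x$stats

#' One-row-per-subtype summary of a signature result
#'
#' @param x A `signature_result`.
#' @param ... Unused.
#' @return Tibble with `subtype`, `n_signature`, `n_up`, `n_down`.
#' @export
glance.signature_result <- function(x, ...) {
  sig <- x$stats[x$stats$in_signature, ]
  out <- tibble::tibble(subtype = seq_len(x$params$n_subtypes))
  counts <- sig |>
    dplyr::group_by(.data$subtype) |>
    dplyr::summarise(n_signature = dplyr::n(),
                     n_up = sum(.data$direction == "up"),
                     n_down = sum(.data$direction == "down"))
  out <- dplyr::left_join(out, counts, by = "subtype")
  dplyr::mutate(out, dplyr::across(dplyr::where(is.numeric),
                                   ~ tidyr::replace_na(.x, 0)))
}

#' Volcano-style plot of signature statistics
#'
#' One panel per subtype: subtype-specific fold change against adjusted
#' significance, with signature genes highlighted.
#'
#' @param object A `signature_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.signature_result <- function(object, ...) {
  df <- object$stats
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fc_k,
                                   y = -log10(pmax(.data$p_adj, 1e-300)),
                                   colour = .data$in_signature)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = object$params$fct, linetype = 2) +
    ggplot2::facet_wrap(~subtype, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "subtype-specific fold change FC_k",
                  y = "-log10 adjusted p", colour = "in signature") +
    ggplot2::theme_minimal()
}
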