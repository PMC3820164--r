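# Core container: a log2 expression matrix (genes x samples) with a
# tumor/normal flag per sample.  Kept as a plain numeric matrix internally;
# all analysis results downstream are tibbles.

#' Construct an expression matrix object
#'
#' Bundles a log2-scale genes x samples numeric matrix with a per-sample
#' tumor/normal annotation.  This is the input container for every analysis
#' in the package.  Gene and sample identifiers are taken from the matrix
#' dimnames and must be unique; all values must be finite; at least two
#' samples must be flagged `"tumor"`.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   complete `rownames` (gene ids) and `colnames` (sample ids).
#' @param sample_class Character vector of `"tumor"`/`"normal"` flags, one per
#'   column (optionally named by sample id).  Defaults to all tumor.
#'
#' @return An object of class `expr_mat`: a list with elements `values`
#'   (the matrix) and `sample_class` (named character vector).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' expression_matrix(m, c("tumor", "tumor", "tumor", "normal"))
#' @export
expression_matrix <- function(values, sample_class = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("`values` must have rownames (gene ids) and colnames (sample ids)",
         call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite expression value at gene '", gene_ids[bad[1]],
         "', sample '", sample_ids[bad[2]], "'", call. = FALSE)
  }
  if (is.null(sample_class)) {
    sample_class <- rep("tumor", ncol(values))
  }
  if (!is.null(names(sample_class))) {
    if (!setequal(names(sample_class), sample_ids)) {
      stop("names of `sample_class` do not match sample ids", call. = FALSE)
    }
    sample_class <- sample_class[sample_ids]
  }
  if (length(sample_class) != ncol(values) ||
      !all(sample_class %in% c("tumor", "normal"))) {
    stop("`sample_class` must be one 'tumor'/'normal' flag per sample",
         call. = FALSE)
  }
  names(sample_class) <- sample_ids
  if (sum(sample_class == "tumor") < 2) {
    stop("need at least 2 tumor samples", call. = FALSE)
  }
  structure(list(values = values, sample_class = sample_class),
            class = "expr_mat")
}

#' @export
print.expr_mat <- function(x, ...) {
  cat("<expr_mat> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", sum(x$sample_class == "tumor"), " tumor, ",
      sum(x$sample_class == "normal"), " normal)\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' Gene and sample accessors
#'
#' @param x An [expression_matrix()] object.
#' @return Character vector of identifiers.
#' @name expr-accessors
NULL

#' @rdname expr-accessors
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname expr-accessors
#' @export
sample_ids <- function(x) colnames(x$values)

#' @rdname expr-accessors
#' @export
tumor_samples <- function(x) names(x$sample_class)[x$sample_class == "tumor"]

#' @rdname expr-accessors
#' @export
normal_samples <- function(x) names(x$sample_class)[x$sample_class == "normal"]

#' Subset an expression matrix by gene and/or sample identifiers
#'
#' @param x An [expression_matrix()] object.
#' @param genes,samples Character vectors of identifiers to keep (default:
#'   all, in the stored order).
#' @return A new `expr_mat` restricted to the requested rows/columns.
#' @export
subset_expr <- function(x, genes = NULL, samples = NULL) {
  genes <- genes %||% gene_ids(x)
  samples <- samples %||% sample_ids(x)
  missing_g <- setdiff(genes, gene_ids(x))
  if (length(missing_g) > 0) {
    stop("genes not present: ", paste(utils::head(missing_g, 5), collapse = ", "),
         call. = FALSE)
  }
  missing_s <- setdiff(samples, sample_ids(x))
  if (length(missing_s) > 0) {
    stop("samples not present: ", paste(utils::head(missing_s, 5), collapse = ", "),
         call. = FALSE)
  }
  expression_matrix(x$values[genes, samples, drop = FALSE],
                    x$sample_class[samples])
}

#' Read an expression matrix from a tab-delimited file
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; remaining cells are log2 expression values.  An optional
#' companion table assigns each sample to class `"tumor"` or `"normal"`
#' (default: all tumor).  Rows sharing a gene identifier are collapsed by
#' their per-sample mean, with a warning.
#'
#' @param path Path to the tab-delimited expression file.
#' @param class_file Optional path to a tab-delimited table with columns
#'   `sample` and `class` (values `tumor`/`normal`).
#' @return An [expression_matrix()] object.
#' @export
read_expression_matrix <- function(path, class_file = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 2) stop("expression file needs gene id + >=1 sample column",
                          call. = FALSE)
  genes <- tab[[1]]
  samples <- colnames(tab)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals) | is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-numeric cell at gene '", genes[bad[1, 1]], "', sample '",
         samples[bad[1, 2]], "' in ", path, call. = FALSE)
  }
  dimnames(num) <- list(NULL, samples)
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("collapsing ", length(dup), " duplicated gene id(s) by mean: ",
            paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
    num <- rowsum(num, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
  }
  rownames(num) <- genes
  cls <- NULL
  if (!is.null(class_file)) {
    ct <- utils::read.delim(class_file, header = TRUE, sep = "\t",
                            colClasses = "character", check.names = FALSE)
    if (!all(c("sample", "class") %in% colnames(ct))) {
      stop("class file needs columns 'sample' and 'class'", call. = FALSE)
    }
    cls <- stats::setNames(ct$class, ct$sample)
    missing <- setdiff(samples, names(cls))
    if (length(missing) > 0) {
      stop("class file missing samples: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    cls <- cls[samples]
  }
  expression_matrix(num, cls)
}

#' Write an expression matrix to a tab-delimited file
#'
#' Writes the transpose-free genes x samples layout read back by
#' [read_expression_matrix()]; values round-trip to full double precision.
#'
#' @param x An [expression_matrix()] object.
#' @param path Output path.
#' @param class_file Optional path for the companion sample-class table.
#' @return `x`, invisibly.
#' @export
write_expression_matrix <- function(x, path, class_file = NULL) {
  df <- tibble::as_tibble(x$values, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(gene = gene_ids(x)), df)
  readr::write_tsv(df, path)
  if (!is.null(class_file)) {
    readr::write_tsv(tibble::tibble(sample = sample_ids(x),
                                    class = unname(x$sample_class)),
                     class_file)
  }
  invisible(x)
}

#' Write any result table as TSV
#'
#' Thin wrapper around [readr::write_tsv()] used by all result types; an
#' empty table yields a header-only file.
#'
#' @param records A data frame.
#' @param path Output path.
#' @return `records`, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  readr::write_tsv(records, path)
  invisible(records)
}

#' Read a plain-text gene list
#'
#' One gene identifier per line; blank lines and lines starting with `#`
#' are ignored.
#'
#' @param path Path to the gene list file.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}

#' Read / write subtype label tables
#'
#' Label tables are TSV with columns `sample` and `subtype` (integer labels
#' `1..K`).
#'
#' @param path Path to the label file.
#' @return A tibble with columns `sample` and `subtype`.
#' @export
read_labels <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (!all(c("sample", "subtype") %in% colnames(tab))) {
    stop("label file needs columns 'sample' and 'subtype'", call. = FALSE)
  }
  tibble::tibble(sample = tab$sample, subtype = as.integer(tab$subtype))
}

#' @rdname read_labels
#' @param labels A tibble with columns `sample` and `subtype`.
#' @export
write_labels <- function(labels, path) {
  readr::write_tsv(labels[, c("sample", "subtype")], path)
  invisible(labels)
}

# Validate a subtype assignment against an expression matrix: every labeled
# sample is a tumor sample, labels are a contiguous 1..K, no normals.
validate_labels <- function(expr, labels) {
  if (!is.data.frame(labels) || !all(c("sample", "subtype") %in% names(labels))) {
    stop("`labels` must be a data frame with columns 'sample' and 'subtype'",
         call. = FALSE)
  }
  if (anyDuplicated(labels$sample)) {
    stop("a sample appears more than once in `labels`", call. = FALSE)
  }
  if (any(labels$sample %in% normal_samples(expr))) {
    stop("normal samples must not carry subtype labels", call. = FALSE)
  }
  missing <- setdiff(labels$sample, tumor_samples(expr))
  if (length(missing) > 0) {
    stop("labeled samples absent from the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  k <- sort(unique(labels$subtype))
  if (!identical(k, seq_len(max(k)))) {
    stop("subtype labels must form a contiguous range 1..K", call. = FALSE)
  }
  invisible(labels)
}

#' Select the top-variance genes
#'
#' Returns the `ceiling(fraction * n_genes)` genes with largest expression
#' variance across tumor samples (normals are never clustered, so they do
#' not enter the filter).  Ties at the cutoff are broken by lexicographic
#' gene id, so the result is invariant to row and column order.
#'
#' @param expr An [expression_matrix()] object.
#' @param fraction Fraction of genes to keep, in (0, 1].
#' @return Character vector of gene ids (a gene set).
#' @export
top_variance_genes <- function(expr, fraction) {
  stopifnot(is.numeric(fraction), length(fraction) == 1)
  if (fraction <= 0 || fraction > 1) {
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  }
  v <- row_vars(expr$values[, tumor_samples(expr), drop = FALSE])
  if (all(v == 0)) {
    warning("all genes constant across tumor samples; selection is by gene id only",
            call. = FALSE)
  }
  n <- ceiling(fraction * length(v))
  ord <- order(-v, rank_lexicographic(gene_ids(expr)))
  sort(gene_ids(expr)[ord[seq_len(n)]])
}

# locale-independent lexicographic ranks (C collation)
rank_lexicographic <- function(ids) {
  match(ids, sort(ids, method = "radix"))
}

# fast per-row variance
row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2) return(stats::setNames(rep(0, nrow(m)), rownames(m)))
  mu <- rowMeans(m)
  (rowSums(m * m) - n * mu * mu) / (n - 1)
}
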