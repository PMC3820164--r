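# Synthetic testbeds: (i) the driver-identification testbed with planted
# candidate -> signature dependencies on an i.i.d. standard-Gaussian
# background; (ii) planted multi-subtype expression structure with
# subtype-specific up/down gene blocks plus normal controls.

#' Generate the synthetic driver-identification testbed
#'
#' Builds a genes x cases matrix initialized with i.i.d. standard Gaussian
#' noise.  The first `n_signature` genes act as signature genes and the next
#' `n_candidates` as candidate copy-number genes; the rest are NSNC
#' (non-signature, non-candidate) genes that serve as the empirical null.
#' Each candidate `i` receives a weight `w_i` drawn according to `regime`,
#' and each signature gene `j` is updated as
#' `x_j <- sum_i w_i c_ij x_i + x_j` with regulating potentials
#' `c_ij ~ U(0, 1)`, using the candidates' *initialized* values.  The four
#' weight regimes are `"pos"` (`w ~ U[0,1]`), `"neg"` (`w ~ U[-1,0]`),
#' `"zero"` (`w = 0`) and `"mixed"` (`w ~ U[-1,1]`).
#'
#' Defaults are the full testbed (10,000 genes, 100 cases, 100 signature,
#' 200 candidate genes); `scaled = TRUE` switches to a smaller testbed
#' (1,000 genes, 100 cases, 50 + 100) convenient for fast runs.
#'
#' @param n_genes,n_cases Matrix dimensions.
#' @param n_signature,n_candidates Sizes of the planted blocks.
#' @param regime One of `"pos"`, `"neg"`, `"zero"`, `"mixed"`.
#' @param seed Integer RNG seed; the same seed reproduces the matrix
#'   bit-for-bit.
#' @param scaled If `TRUE`, use the scaled-down default sizes.
#' @return A list with `expr` (an [expression_matrix()], all samples tumor)
#'   and `truth`: list with `signature_genes`, `candidate_genes`,
#'   `nsnc_genes`, `w` (per-candidate weights), `c` (candidates x signature
#'   regulating potentials), `regime`, `seed`.
#' @export
generate_driver_testbed <- function(n_genes = if (scaled) 1000 else 10000,
                                    n_cases = 100,
                                    n_signature = if (scaled) 50 else 100,
                                    n_candidates = if (scaled) 100 else 200,
                                    regime = c("pos", "neg", "zero", "mixed"),
                                    seed = 1, scaled = FALSE) {
  regime <- match.arg(regime)
  stopifnot(n_signature + n_candidates <= n_genes, n_cases >= 3)
  set.seed(seed)
  x <- matrix(stats::rnorm(n_genes * n_cases), n_genes, n_cases)
  # every regime consumes the same RNG stream, so for a fixed seed the
  # initialization and the c matrix are identical across regimes
  u <- stats::runif(n_candidates)
  w <- switch(regime,
              pos = u,
              neg = u - 1,
              zero = 0 * u,
              mixed = 2 * u - 1)
  cmat <- matrix(stats::runif(n_candidates * n_signature), n_candidates,
                 n_signature)
  sig_idx <- seq_len(n_signature)
  cand_idx <- n_signature + seq_len(n_candidates)
  nsnc_idx <- setdiff(seq_len(n_genes), c(sig_idx, cand_idx))
  # x~_j = sum_i w_i c_ij x_i + x_j over the initialized candidate values
  x[sig_idx, ] <- x[sig_idx, ] + t(cmat * w) %*% x[cand_idx, ]
  gid <- c(sprintf("SIG%04d", seq_len(n_signature)),
           sprintf("CAND%04d", seq_len(n_candidates)),
           sprintf("NSNC%05d", seq_along(nsnc_idx)))
  dimnames(x) <- list(gid, sprintf("case%03d", seq_len(n_cases)))
  list(expr = expression_matrix(x),
       truth = list(signature_genes = gid[sig_idx],
                    candidate_genes = gid[cand_idx],
                    nsnc_genes = gid[nsnc_idx],
                    w = w, c = cmat, regime = regime, seed = seed))
}

#' Generate a planted multi-subtype expression testbed
#'
#' Background expression is `N(0, noise_sd^2)` for every gene and sample.
#' Each subtype owns a disjoint block of `sig_block_size` genes; within the
#' block, half the genes are shifted by `+shift` and half by `-shift`, in
#' that subtype's tumor samples only.  Normal samples are pure background.
#'
#' @param n_subtypes Number of planted subtypes.
#' @param tumors_per_subtype Tumor samples per subtype.
#' @param n_normals Number of normal control samples.
#' @param n_genes Total number of genes.
#' @param sig_block_size Genes in each subtype's planted signature block.
#' @param shift Mean shift magnitude (log2 units), non-zero.
#' @param noise_sd Background standard deviation.
#' @param seed Integer RNG seed.
#' @return A list with `expr` (an [expression_matrix()]) and `truth`: list
#'   with `labels` (tibble `sample`/`subtype` for tumor samples),
#'   `blocks` (per-subtype list of tibbles `gene`/`direction`),
#'   `shift`, `noise_sd`, `seed`.
#' @export
generate_subtype_testbed <- function(n_subtypes = 3, tumors_per_subtype = 20,
                                     n_normals = 10, n_genes = 2000,
                                     sig_block_size = 50, shift = 3,
                                     noise_sd = 1, seed = 1) {
  stopifnot(n_subtypes >= 1, tumors_per_subtype >= 2, n_normals >= 0,
            n_subtypes * sig_block_size <= n_genes, shift != 0,
            noise_sd > 0)
  set.seed(seed)
  n_tumors <- n_subtypes * tumors_per_subtype
  n_samples <- n_tumors + n_normals
  x <- matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
              n_genes, n_samples)
  gid <- sprintf("gene%05d", seq_len(n_genes))
  sid <- c(sprintf("tumor%03d", seq_len(n_tumors)),
           if (n_normals > 0) sprintf("normal%03d", seq_len(n_normals)))
  dimnames(x) <- list(gid, sid)
  subtype_of <- rep(seq_len(n_subtypes), each = tumors_per_subtype)
  blocks <- vector("list", n_subtypes)
  for (k in seq_len(n_subtypes)) {
    rows <- (k - 1) * sig_block_size + seq_len(sig_block_size)
    cols <- which(subtype_of == k)
    n_up <- ceiling(sig_block_size / 2)
    dir_shift <- c(rep(shift, n_up), rep(-shift, sig_block_size - n_up))
    x[rows, cols] <- x[rows, cols] + dir_shift
    blocks[[k]] <- tibble::tibble(
      gene = gid[rows],
      direction = ifelse(dir_shift > 0, "up", "down"))
  }
  names(blocks) <- as.character(seq_len(n_subtypes))
  cls <- c(rep("tumor", n_tumors), rep("normal", n_normals))
  list(expr = expression_matrix(x, cls),
       truth = list(labels = tibble::tibble(sample = sid[seq_len(n_tumors)],
                                            subtype = subtype_of),
                    blocks = blocks, shift = shift, noise_sd = noise_sd,
                    seed = seed))
}
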