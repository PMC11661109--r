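#' FPKM from counts and gene lengths
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' `fpkm_gj = count_gj * 1e9 / (total_j * length_g)`, with `total_j` the raw
#' column total of sample j. Depth normalization therefore uses the raw
#' library totals, not size factors, matching the standard definition the
#' screen's absolute gates are set on.
#'
#' @param counts A [count_matrix()].
#' @param lengths Gene length table (`gene_id`, `length_bp`), covering every
#'   gene in `counts`.
#' @return An `fpkm_matrix`: list with `fpkm` (genes x samples) and
#'   `samples` (the metadata of `counts`).
#' @export
compute_fpkm <- function(counts, lengths) {
  mat <- counts$counts
  idx <- match(rownames(mat), lengths$gene_id)
  if (anyNA(idx))
    stop("no length for gene '", rownames(mat)[which(is.na(idx))[1]], "'",
         call. = FALSE)
  len <- lengths$length_bp[idx]
  totals <- colSums(mat)
  fpkm <- sweep(mat * 1e9 / len, 2, totals, "/")
  structure(list(fpkm = fpkm, samples = counts$samples),
            class = "fpkm_matrix")
}

#' Shifted-log transform of depth-normalized counts
#'
#' `log2(count_gj / s_j + pseudocount)`. Used for clustering/PCA quality
#' control only; the screen itself works on counts and FPKM.
#'
#' @param counts A [count_matrix()].
#' @param sf Size factors.
#' @param pseudocount Positive shift (default 1).
#' @return Numeric matrix, genes x samples.
#' @export
log_transform <- function(counts, sf, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  log2(sweep(counts$counts, 2, sf, "/") + pseudocount)
}

#' Laminar PCA on the most variable genes
#'
#' Centered principal component analysis of samples on the `top_n` most
#' variable genes of a log-scale expression matrix. The sign of each
#' component is fixed by forcing its largest-magnitude gene loading
#' positive, so scores are deterministic.
#'
#' @param mat Log-scale matrix, genes x samples (e.g. from
#'   [log_transform()]).
#' @param top_n_variable_genes Number of genes, ranked by variance, to keep
#'   (default 500, truncated to the number available).
#' @param k Number of components (default 2).
#' @return A `laminar_embedding`: list with `scores` (samples x k),
#'   `explained` (variance fractions) and `genes_used`.
#' @export
laminar_pca <- function(mat, top_n_variable_genes = 500, k = 2) {
  if (k > min(dim(mat)))
    stop("k = ", k, " exceeds min(genes, samples)", call. = FALSE)
  vars <- apply(mat, 1, stats::var)
  top_n <- min(top_n_variable_genes, nrow(mat))
  keep <- order(vars, decreasing = TRUE)[seq_len(top_n)]
  sub <- mat[keep, , drop = FALSE]
  pc <- stats::prcomp(t(sub), center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) {
      scores[, j] <- -scores[, j]
      load[, j] <- -load[, j]
    }
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, explained = expl[seq_len(k)],
                 genes_used = rownames(sub)),
            class = "laminar_embedding")
}

#' Replicate-mean FPKM per (species, layer)
#'
#' Arithmetic mean of FPKM across the replicates of each cortical layer,
#' the summarization the screen's absolute gates are applied to.
#'
#' @param fpkm An `fpkm_matrix` from [compute_fpkm()].
#' @return Matrix genes x layers of replicate means.
#' @export
layer_mean_fpkm <- function(fpkm) {
  layers <- unique(fpkm$samples$layer)
  out <- vapply(layers, function(l) {
    rowMeans(fpkm$fpkm[, fpkm$samples$layer == l, drop = FALSE])
  }, numeric(nrow(fpkm$fpkm)))
  colnames(out) <- layers
  out
}
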