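#' Closed vocabulary of cortical layers
#'
#' Laminar samples must come from one of the five recognised compartments of
#' the developing neocortical wall: the cortical plate (CP), the outer and
#' inner subventricular zones (OSVZ, ISVZ), the undivided subventricular zone
#' (SVZ, as in lissencephalic species), and the ventricular zone (VZ).
#'
#' @format Character vector of layer codes.
#' @export
CORTICAL_LAYERS <- c("CP", "OSVZ", "ISVZ", "VZ", "SVZ")

#' Layers counted as SVZ-type (germinal, basal-progenitor enriched)
#' @format Character vector, subset of [CORTICAL_LAYERS].
#' @export
SVZ_TYPE_LAYERS <- c("OSVZ", "ISVZ", "SVZ")

tsv_read <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

tsv_write <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(df)
}

#' Construct a laminar count matrix
#'
#' Bundles an integer gene-by-sample count matrix with its sample metadata
#' (species, cortical layer, replicate). This is the raw input of the screen:
#' one object per species, samples in metadata order.
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns.
#' @param samples Data frame with columns `sample_id`, `species`, `layer`,
#'   `replicate`; one row per column of `counts`, in column order.
#' @return An object of class `count_matrix` with elements `counts` and
#'   `samples`.
#' @examples
#' cm <- count_matrix(
#'   matrix(0:5, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2"))),
#'   data.frame(sample_id = c("s1", "s2"), species = "human",
#'              layer = c("CP", "VZ"), replicate = 1L))
#' dim(cm$counts)
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  require_columns(samples, c("sample_id", "species", "layer", "replicate"),
                  "sample metadata")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in metadata: ",
         samples$sample_id[duplicated(samples$sample_id)][1], call. = FALSE)
  bad_layer <- setdiff(unique(samples$layer), CORTICAL_LAYERS)
  if (length(bad_layer) > 0)
    stop("unknown layer '", bad_layer[1], "'; layers must be one of ",
         paste(CORTICAL_LAYERS, collapse = ", "), call. = FALSE)
  if (ncol(counts) != nrow(samples))
    stop("count matrix has ", ncol(counts), " columns but metadata has ",
         nrow(samples), " samples", call. = FALSE)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must carry unique gene ids as rownames", call. = FALSE)
  if (!is.null(colnames(counts))) {
    if (!setequal(colnames(counts), samples$sample_id))
      stop("count matrix columns do not match metadata sample_ids; first ",
           "mismatch: ",
           setdiff(union(colnames(counts), samples$sample_id),
                   intersect(colnames(counts), samples$sample_id))[1],
           call. = FALSE)
    counts <- counts[, samples$sample_id, drop = FALSE]
  } else {
    colnames(counts) <- samples$sample_id
  }
  validate_counts(counts)
  storage.mode(counts) <- "integer"
  if (!is.numeric(samples$replicate) || any(samples$replicate < 1))
    stop("replicate must be a positive integer", call. = FALSE)
  samples$replicate <- as.integer(samples$replicate)
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

validate_counts <- function(counts) {
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("invalid count at gene '", rownames(counts)[bad[1, 1]],
         "', sample '", colnames(counts)[bad[1, 2]],
         "': counts must be non-negative integers", call. = FALSE)
  invisible(counts)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("species:", paste(unique(x$samples$species), collapse = ", "), "\n")
  cat("layers: ", paste(unique(x$samples$layer), collapse = ", "), "\n")
  invisible(x)
}

#' Read a count matrix and its sample metadata from TSV files
#'
#' @param path Counts TSV: first column `gene_id`, then one integer column per
#'   sample.
#' @param metadata_path Metadata TSV with columns `sample_id`, `species`,
#'   `layer`, `replicate`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, metadata_path) {
  counts_df <- tsv_read(path)
  meta <- tsv_read(metadata_path)
  require_columns(meta, c("sample_id", "species", "layer", "replicate"),
                  basename(metadata_path))
  if (names(counts_df)[1] != "gene_id")
    stop("counts file must have 'gene_id' as its first column", call. = FALSE)
  missing <- setdiff(names(counts_df)[-1], meta$sample_id)
  if (length(missing) > 0)
    stop("sample '", missing[1], "' in counts has no metadata row",
         call. = FALSE)
  mat <- as.matrix(counts_df[, -1, drop = FALSE])
  rownames(mat) <- counts_df$gene_id
  count_matrix(mat, meta)
}

#' Write a count matrix (counts + metadata) to TSV files
#' @param cm A [count_matrix()].
#' @param path,metadata_path Output TSV paths.
#' @export
write_count_matrix <- function(cm, path, metadata_path) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  tsv_write(df, path)
  tsv_write(cm$samples, metadata_path)
  invisible(NULL)
}

#' Read a gene length table (gene_id, length_bp)
#' @param path TSV path.
#' @return Data frame with columns `gene_id`, `length_bp`.
#' @export
read_gene_lengths <- function(path) {
  df <- tsv_read(path)
  require_columns(df, c("gene_id", "length_bp"), basename(path))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in gene length table", call. = FALSE)
  if (any(df$length_bp < 1 | df$length_bp != round(df$length_bp)))
    stop("length_bp must be a positive integer", call. = FALSE)
  df$length_bp <- as.integer(df$length_bp)
  df
}

#' Read a cross-species ortholog table
#'
#' Rows of (reference_gene_id, species, target_gene_id, one_to_one) linking
#' reference-species gene ids to each comparison species.
#' @param path TSV path.
#' @return Data frame with those four columns; `one_to_one` logical.
#' @export
read_ortholog_table <- function(path) {
  df <- tsv_read(path)
  require_columns(df, c("reference_gene_id", "species", "target_gene_id",
                        "one_to_one"), basename(path))
  df$one_to_one <- as.logical(df$one_to_one)
  key <- paste(df$reference_gene_id, df$species)[df$one_to_one]
  if (anyDuplicated(key))
    stop("ortholog table has duplicated one-to-one pair: ",
         key[duplicated(key)][1], call. = FALSE)
  df
}

#' Read a species trait table (divergence time, brain weight, GI)
#' @param path TSV path with columns `species`, `divergence_mya`,
#'   `brain_weight_g`, `gyrification_index`.
#' @return Data frame.
#' @export
read_species_traits <- function(path) {
  df <- tsv_read(path)
  require_columns(df, c("species", "divergence_mya", "brain_weight_g",
                        "gyrification_index"), basename(path))
  if (any(df$divergence_mya < 0)) stop("divergence_mya must be >= 0",
                                       call. = FALSE)
  if (any(df$gyrification_index < 1))
    stop("gyrification_index must be >= 1", call. = FALSE)
  df
}

#' Read an allele-resolved expression table
#' @param path TSV with columns `gene_id`, `parental_human`, `parental_chimp`,
#'   `hybrid_human_allele`, `hybrid_chimp_allele`.
#' @return Data frame.
#' @export
read_allelic_table <- function(path) {
  df <- tsv_read(path)
  require_columns(df, c("gene_id", "parental_human", "parental_chimp",
                        "hybrid_human_allele", "hybrid_chimp_allele"),
                  basename(path))
  num <- df[, -1]
  if (any(num < 0, na.rm = TRUE))
    stop("allelic expression values must be >= 0", call. = FALSE)
  df
}

#' Read an ordered 2D contour from CSV
#'
#' The file holds one `x,y` pair per row (header `x,y`), tracing the cortical
#' section outline in order.
#' @param path CSV path.
#' @param closed Is the outline a closed curve? Default TRUE.
#' @return A [contour_points()].
#' @export
read_contour <- function(path, closed = TRUE) {
  df <- utils::read.csv(path, header = TRUE)
  require_columns(df, c("x", "y"), basename(path))
  contour_points(as.matrix(df[, c("x", "y")]), closed = closed)
}

#' Write a contour to CSV
#' @param contour A [contour_points()].
#' @param path Output CSV path.
#' @export
write_contour <- function(contour, path) {
  utils::write.csv(data.frame(x = contour$points[, 1],
                              y = contour$points[, 2]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
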