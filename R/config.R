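#' Default SVZ-type layer repertoire by species
#'
#' Gyrencephalic species (human, macaque) and the tree shrew carry a split
#' germinal zone (ISVZ + OSVZ); the mouse has a single undivided SVZ.
#' @return Named list mapping species to its SVZ-type layers.
#' @export
default_svz_layers <- function() {
  list(human      = c("ISVZ", "OSVZ"),
       macaque    = c("ISVZ", "OSVZ"),
       tree_shrew = c("ISVZ", "OSVZ"),
       mouse      = "SVZ")
}

#' Screen configuration
#'
#' Thresholds and options of the five-step cross-species screen. The
#' differential-expression cutoffs (`padj_threshold`, `lfc_threshold`) are
#' conventions, not values fixed by the underlying study; the FPKM gates
#' default to the published ones (human FPKM > 50, other species FPKM < 1.5,
#' both strict).
#'
#' @param padj_threshold BH-adjusted p cutoff for calling a layer-vs-CP
#'   contrast significant (fraction, default 0.05).
#' @param lfc_threshold Minimum log2 fold change, SVZ-type layer over CP
#'   (default 1).
#' @param svz_layers_by_species Named list mapping each species to its
#'   SVZ-type layers; see [default_svz_layers()].
#' @param human_fpkm_min Lower FPKM gate applied to the reference (human)
#'   SVZ; a candidate's replicate-mean FPKM must exceed it strictly
#'   (default 50).
#' @param other_fpkm_max Upper FPKM gate applied to every layer of every
#'   other species, strict (default 1.5).
#' @param gate_scope `"svz_only"` (default): the human gate uses the
#'   replicate-mean FPKM over human SVZ-type layers; `"all_layers_max"`:
#'   it uses the maximum per-layer mean instead.
#' @param reference_species Species whose gene ids index the report
#'   (default `"human"`).
#' @param random_seed Integer seed recorded in reports for provenance.
#' @return A `screen_config` list.
#' @export
screen_config <- function(padj_threshold = 0.05,
                          lfc_threshold = 1,
                          svz_layers_by_species = default_svz_layers(),
                          human_fpkm_min = 50,
                          other_fpkm_max = 1.5,
                          gate_scope = c("svz_only", "all_layers_max"),
                          reference_species = "human",
                          random_seed = 1L) {
  gate_scope <- match.arg(gate_scope)
  stopifnot(padj_threshold > 0, lfc_threshold > 0,
            human_fpkm_min > 0, other_fpkm_max > 0)
  if (!reference_species %in% names(svz_layers_by_species))
    stop("reference_species '", reference_species,
         "' absent from svz_layers_by_species", call. = FALSE)
  structure(list(padj_threshold = padj_threshold,
                 lfc_threshold = lfc_threshold,
                 svz_layers_by_species = svz_layers_by_species,
                 human_fpkm_min = human_fpkm_min,
                 other_fpkm_max = other_fpkm_max,
                 gate_scope = gate_scope,
                 reference_species = reference_species,
                 random_seed = as.integer(random_seed)),
            class = "screen_config")
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override the [screen_config()] defaults;
#' unknown fields are rejected so typos cannot silently fall back to a
#' default.
#' @param path YAML file path.
#' @return A `screen_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  allowed <- names(formals(screen_config))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0)
    stop("unknown config field: ", unknown[1], call. = FALSE)
  do.call(screen_config, cfg)
}

#' Write a run configuration to YAML
#' @param cfg A `screen_config`.
#' @param path Output path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(NULL)
}

#' @export
print.screen_config <- function(x, ...) {
  cat("screen_config:\n")
  cat("  DE gates: padj <", x$padj_threshold, ", log2FC >=",
      x$lfc_threshold, "\n")
  cat("  FPKM gates: reference >", x$human_fpkm_min, "(",
      x$gate_scope, "), others <", x$other_fpkm_max, "\n")
  cat("  reference species:", x$reference_species, "\n")
  invisible(x)
}
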