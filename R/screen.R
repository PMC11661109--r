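#' Genes SVZ-enriched within one species
#'
#' A gene is called SVZ-enriched when, for every SVZ-type layer of the
#' species (ISVZ and OSVZ where the germinal zone is split, the single SVZ
#' otherwise), the layer-vs-CP negative-binomial contrast is significant
#' (BH-adjusted p below `cfg$padj_threshold`) with log2 fold change of at
#' least `cfg$lfc_threshold`. The conjunction over layers implements
#' "consistently upregulated across the germinal zone".
#'
#' @param species_counts Single-species [count_matrix()] containing CP and
#'   the species' SVZ-type layers.
#' @param cfg A [screen_config()].
#' @return Character vector of gene ids (species' own id space), with the
#'   per-contrast DE tables attached as attribute `de_tables`.
#' @export
svz_enriched_genes <- function(species_counts, cfg) {
  sp <- unique(species_counts$samples$species)
  if (length(sp) != 1)
    stop("species_counts must hold a single species", call. = FALSE)
  svz_layers <- cfg$svz_layers_by_species[[sp]]
  if (is.null(svz_layers))
    stop("no SVZ-type layers configured for species '", sp, "'",
         call. = FALSE)
  layers_present <- unique(species_counts$samples$layer)
  if (!"CP" %in% layers_present)
    stop("species '", sp, "' has no CP samples", call. = FALSE)
  svz_layers <- intersect(svz_layers, layers_present)
  if (length(svz_layers) == 0)
    stop("species '", sp, "' has no SVZ-type layer samples", call. = FALSE)
  de_tables <- lapply(svz_layers, function(l)
    laminar_de(species_counts, "CP", l))
  names(de_tables) <- svz_layers
  hits <- lapply(de_tables, function(de)
    de$gene_id[de$tested & !is.na(de$padj) &
               de$padj < cfg$padj_threshold &
               de$log2_fc >= cfg$lfc_threshold])
  out <- sort(Reduce(intersect, hits))
  attr(out, "de_tables") <- de_tables
  out
}

# Map a set of species gene ids to reference ids (or back). Genes without a
# mapping row are dropped.
map_to_reference <- function(genes, orthologs, species, reference_species) {
  if (species == reference_species) return(genes)
  rows <- orthologs[orthologs$species == species, ]
  rows$reference_gene_id[match(genes, rows$target_gene_id, nomatch = 0)]
}

map_from_reference <- function(genes, orthologs, species,
                               reference_species) {
  if (species == reference_species) return(genes)
  rows <- orthologs[orthologs$species == species, ]
  rows$target_gene_id[match(genes, rows$reference_gene_id, nomatch = 0)]
}

#' Consensus SVZ program across species
#'
#' Intersection of the per-species SVZ-enriched sets after mapping every
#' set into reference-species gene ids through the ortholog table.
#'
#' @param per_species_sets Named list (by species) of gene-id vectors.
#' @param orthologs Ortholog table.
#' @param reference_species Reference species name (default `"human"`).
#' @return Character vector of reference gene ids.
#' @export
consensus_svz <- function(per_species_sets, orthologs,
                          reference_species = "human") {
  if (length(per_species_sets) < 2)
    stop("need sets from >= 2 species", call. = FALSE)
  for (sp in setdiff(names(per_species_sets), reference_species))
    if (!sp %in% orthologs$species)
      stop("species '", sp, "' absent from ortholog table", call. = FALSE)
  mapped <- lapply(names(per_species_sets), function(sp)
    map_to_reference(per_species_sets[[sp]], orthologs, sp,
                     reference_species))
  sort(Reduce(intersect, mapped))
}

#' Human-specific SVZ-enriched genes (screen step 2)
#'
#' Reference-species SVZ-enriched genes whose ortholog, where one exists,
#' is not SVZ-enriched in any other species. Genes without any ortholog are
#' retained here; the orthology filter (step 3) removes them.
#'
#' @param human_set SVZ-enriched genes of the reference species.
#' @param other_species_sets Named list of SVZ-enriched sets for the other
#'   species, in their own id spaces.
#' @param orthologs Ortholog table.
#' @param reference_species Reference species name (default `"human"`).
#' @return Character vector of reference gene ids.
#' @export
human_specific_genes <- function(human_set, other_species_sets, orthologs,
                                 reference_species = "human") {
  enriched_elsewhere <- unique(unlist(lapply(
    names(other_species_sets), function(sp)
      map_to_reference(other_species_sets[[sp]], orthologs, sp,
                       reference_species))))
  sort(setdiff(human_set, enriched_elsewhere))
}

#' One-to-one orthology filter (screen step 3)
#'
#' Keeps genes that carry a one-to-one ortholog in every listed species.
#'
#' @param genes Reference gene ids.
#' @param orthologs Ortholog table.
#' @param species_list Species that must each have a one-to-one ortholog
#'   (the reference species itself is ignored).
#' @param reference_species Reference species name (default `"human"`).
#' @return Character vector of reference gene ids.
#' @export
orthology_filter <- function(genes, orthologs, species_list,
                             reference_species = "human") {
  keep <- genes
  for (sp in setdiff(species_list, reference_species)) {
    rows <- orthologs[orthologs$species == sp & orthologs$one_to_one, ]
    keep <- keep[keep %in% rows$reference_gene_id]
  }
  sort(keep)
}

#' Absolute-expression FPKM gates (screen steps 4-5)
#'
#' Keeps genes whose replicate-mean FPKM in the reference species' SVZ-type
#' layers strictly exceeds `cfg$human_fpkm_min` (with
#' `gate_scope = "all_layers_max"`, the maximum per-layer mean is used
#' instead) and whose replicate-mean FPKM in every layer of every other
#' species stays strictly below `cfg$other_fpkm_max`.
#'
#' @param genes Reference gene ids (must have one-to-one orthologs in all
#'   species, i.e. step 3 output).
#' @param fpkm_by_species Named list of `fpkm_matrix` objects, one per
#'   species.
#' @param orthologs Ortholog table.
#' @param cfg A [screen_config()].
#' @return Character vector of reference gene ids.
#' @export
fpkm_gate <- function(genes, fpkm_by_species, orthologs, cfg) {
  if (length(genes) == 0) return(character(0))
  ref <- cfg$reference_species
  keep <- rep(TRUE, length(genes))
  for (sp in names(fpkm_by_species)) {
    lm <- layer_mean_fpkm(fpkm_by_species[[sp]])
    ids <- map_from_reference(genes, orthologs, sp, ref)
    if (length(ids) != length(genes) || !all(ids %in% rownames(lm)))
      stop("gene missing from '", sp,
           "' FPKM table after orthology mapping", call. = FALSE)
    if (sp == ref) {
      svz_layers <- intersect(cfg$svz_layers_by_species[[ref]],
                              colnames(lm))
      svz_mean <- rowMeans(lm[ids, svz_layers, drop = FALSE])
      human_val <- if (cfg$gate_scope == "all_layers_max") {
        apply(lm[ids, , drop = FALSE], 1, max)
      } else svz_mean
      keep <- keep & human_val > cfg$human_fpkm_min
    } else {
      keep <- keep & apply(lm[ids, , drop = FALSE], 1, max) <
        cfg$other_fpkm_max
    }
  }
  sort(genes[keep])
}

#' Run the five-step cross-species screen
#'
#' Executes, in order: (1) per-species SVZ-vs-CP differential expression
#' and the cross-species consensus; (2) restriction to genes SVZ-enriched
#' in the reference species only; (3) the one-to-one orthology filter;
#' (4-5) the absolute FPKM gates. Every intermediate set and its
#' cardinality is recorded.
#'
#' @param species_counts Named list of per-species [count_matrix()]
#'   objects.
#' @param gene_lengths Gene length table covering all species' gene ids.
#' @param orthologs Ortholog table (reference ids = reference species ids).
#' @param cfg A [screen_config()].
#' @return A `screen_report` list: per-step sets, cardinalities, resolved
#'   config and input provenance.
#' @export
run_screen <- function(species_counts, gene_lengths, orthologs, cfg) {
  ref <- cfg$reference_species
  if (!ref %in% names(species_counts))
    stop("reference species '", ref, "' missing from species_counts",
         call. = FALSE)
  stage <- "step1_svz_enrichment"
  report <- tryCatch({
    per_species <- lapply(species_counts, svz_enriched_genes, cfg = cfg)
    per_species <- lapply(per_species, as.character)
    stage <- "step1_consensus"
    consensus <- consensus_svz(per_species, orthologs, ref)
    stage <- "step2_human_specific"
    step2 <- human_specific_genes(per_species[[ref]],
                                  per_species[names(per_species) != ref],
                                  orthologs, ref)
    stage <- "step3_orthology"
    step3 <- orthology_filter(step2, orthologs, names(species_counts), ref)
    stage <- "step45_fpkm_gate"
    fpkm <- lapply(species_counts, compute_fpkm, lengths = gene_lengths)
    step45 <- fpkm_gate(step3, fpkm, orthologs, cfg)
    list(step1_per_species_sets = per_species,
         step1_consensus_set = consensus,
         step2_human_specific_set = step2,
         step3_ortholog_set = step3,
         step45_candidate_set = step45)
  }, error = function(e)
    stop("screen failed at stage ", stage, ": ", conditionMessage(e),
         call. = FALSE))
  report$cardinalities <- c(
    vapply(report$step1_per_species_sets, length, integer(1)),
    step1_consensus = length(report$step1_consensus_set),
    step2_human_specific = length(report$step2_human_specific_set),
    step3_orthologs = length(report$step3_ortholog_set),
    step45_candidates = length(report$step45_candidate_set))
  report$config <- cfg
  report$provenance <- list(
    n_genes = vapply(species_counts, function(cm) nrow(cm$counts),
                     integer(1)),
    n_samples = vapply(species_counts, function(cm) ncol(cm$counts),
                       integer(1)),
    total_counts = vapply(species_counts,
                          function(cm) sum(as.numeric(cm$counts)),
                          numeric(1)),
    seed = cfg$random_seed)
  class(report) <- "screen_report"
  report
}

#' @export
print.screen_report <- function(x, ...) {
  cat("screen_report\n")
  for (nm in names(x$cardinalities))
    cat(sprintf("  %-22s %d\n", nm, x$cardinalities[[nm]]))
  if (length(x$step45_candidate_set) > 0)
    cat("  candidates:", paste(x$step45_candidate_set, collapse = ", "),
        "\n")
  invisible(x)
}

#' Write a screen report to a directory of TSV files
#'
#' One gene-list TSV per step plus `summary.tsv` with the cardinalities and
#' the resolved configuration as `config.yaml`. Reading the directory back
#' with [read_screen_report()] reproduces the sets exactly.
#'
#' @param report A `screen_report`.
#' @param path Output directory (created if needed).
#' @export
write_screen_report <- function(report, path) {
  if (!dir.exists(path))
    if (!dir.create(path, recursive = TRUE))
      stop("cannot create report directory: ", path, call. = FALSE)
  write_set <- function(genes, file)
    tsv_write(data.frame(gene_id = as.character(genes),
                         stringsAsFactors = FALSE),
              file.path(path, file))
  for (sp in names(report$step1_per_species_sets))
    write_set(report$step1_per_species_sets[[sp]],
              paste0("step1_", sp, ".tsv"))
  write_set(report$step1_consensus_set, "step1_consensus.tsv")
  write_set(report$step2_human_specific_set, "step2_human_specific.tsv")
  write_set(report$step3_ortholog_set, "step3_orthologs.tsv")
  write_set(report$step45_candidate_set, "step45_candidates.tsv")
  tsv_write(data.frame(step = names(report$cardinalities),
                       n_genes = as.integer(report$cardinalities),
                       stringsAsFactors = FALSE),
            file.path(path, "summary.tsv"))
  write_run_config(report$config, file.path(path, "config.yaml"))
  invisible(NULL)
}

#' Read back a screen report directory
#' @param path Directory written by [write_screen_report()].
#' @return List with the per-step gene sets and the summary table.
#' @export
read_screen_report <- function(path) {
  read_set <- function(file) {
    df <- tsv_read(file.path(path, file))
    as.character(df$gene_id)
  }
  files <- list.files(path, pattern = "^step1_.*\\.tsv$")
  files <- setdiff(files, "step1_consensus.tsv")
  species <- sub("^step1_(.*)\\.tsv$", "\\1", files)
  per_species <- lapply(files, read_set)
  names(per_species) <- species
  list(step1_per_species_sets = per_species,
       step1_consensus_set = read_set("step1_consensus.tsv"),
       step2_human_specific_set = read_set("step2_human_specific.tsv"),
       step3_ortholog_set = read_set("step3_orthologs.tsv"),
       step45_candidate_set = read_set("step45_candidates.tsv"),
       summary = tsv_read(file.path(path, "summary.tsv")))
}
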