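#' Simulation specification for multi-species laminar count data
#'
#' Defines the statistical structure of a synthetic cross-species laminar
#' dataset: negative-binomial counts with configurable dispersion, a
#' conserved SVZ-enriched gene program planted in every species, and one or
#' more human-specific genes planted on the FPKM scale so that they pass
#' the screen's absolute gates by construction.
#'
#' Defaults mirror the screen's study design: four species (human, macaque,
#' tree shrew, mouse), a split germinal zone (ISVZ/OSVZ) in the three
#' gyrencephalic-side species and a single SVZ in mouse, three biological
#' replicates per layer, and NB dispersion 0.1 (a conventional bulk RNA-seq
#' value; the underlying study does not publish its empirical dispersions).
#'
#' @param species_layers Named list mapping species to its layer repertoire.
#' @param n_replicates Replicates per layer per species (>= 3).
#' @param n_genes Number of genes.
#' @param baseline_log_mean_range Range (log2) of baseline expected
#'   normalized counts, drawn uniformly per gene.
#' @param dispersion NB dispersion alpha (variance = mu + alpha * mu^2);
#'   0 gives Poisson counts.
#' @param library_size_range Range of per-sample library totals (reads).
#' @param n_conserved_svz_genes Genes upregulated in SVZ-type layers vs CP
#'   in every species.
#' @param conserved_svz_lfc Their planted log2 fold change (SVZ-type vs CP).
#' @param n_human_specific_genes Genes SVZ-upregulated in human only, with
#'   FPKM planted to pass the screen gates.
#' @param human_specific_target_fpkm Expected FPKM of those genes in human
#'   SVZ-type layers (default 100, comfortably above the >50 gate).
#' @param other_species_max_fpkm Their expected FPKM in every layer of every
#'   other species (default 0.5, below the <1.5 gate).
#' @param ortholog_dropout_fraction Fraction of non-planted genes lacking a
#'   one-to-one ortholog in at least one species.
#' @param seed Integer master seed; a per-purpose seed sequence is derived
#'   from it so the generator is fully reproducible.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(species_layers = list(
                              human      = c("CP", "OSVZ", "ISVZ", "VZ"),
                              macaque    = c("CP", "OSVZ", "ISVZ", "VZ"),
                              tree_shrew = c("CP", "OSVZ", "ISVZ", "VZ"),
                              mouse      = c("CP", "SVZ", "VZ")),
                            n_replicates = 3L,
                            n_genes = 2000L,
                            baseline_log_mean_range = c(1, 9),
                            dispersion = 0.1,
                            library_size_range = c(1e6, 2e6),
                            n_conserved_svz_genes = 30L,
                            conserved_svz_lfc = 2,
                            n_human_specific_genes = 1L,
                            human_specific_target_fpkm = 100,
                            other_species_max_fpkm = 0.5,
                            ortholog_dropout_fraction = 0.2,
                            seed = 1L) {
  if (n_replicates < 3)
    stop("n_replicates must be >= 3 (biological replication floor)",
         call. = FALSE)
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (ortholog_dropout_fraction < 0 || ortholog_dropout_fraction > 1)
    stop("ortholog_dropout_fraction must lie in [0, 1]", call. = FALSE)
  if (n_human_specific_genes + n_conserved_svz_genes > n_genes)
    stop("planted genes exceed n_genes", call. = FALSE)
  bad <- setdiff(unlist(species_layers), CORTICAL_LAYERS)
  if (length(bad) > 0) stop("unknown layer in species_layers: ", bad[1],
                            call. = FALSE)
  structure(as.list(environment()), class = "simulation_spec")
}

# Per-purpose seed stream derived from one master seed; keeps every derived
# seed a valid 32-bit integer.
derive_seed <- function(seed, purpose) {
  (as.integer(seed) %% 1048576L) * 2011L + as.integer(purpose)
}

#' Simulate multi-species laminar count data with planted truth
#'
#' Draws, for every species and layer, `n_replicates` NB count columns with
#' mean `s_j * q_gl` (depth factor times expected normalized count) and
#' dispersion `spec$dispersion`. Conserved SVZ genes carry a
#' `conserved_svz_lfc` log2 fold change in SVZ-type layers vs CP in every
#' species; human-specific genes are planted on the FPKM scale (solving
#' exactly for the expected count against each layer's total intensity) so
#' their expected FPKM equals `human_specific_target_fpkm` in human
#' SVZ-type layers and `other_species_max_fpkm` everywhere else, with CP/VZ
#' expression in human set 8-fold below the SVZ level so the gene is also
#' SVZ-enriched by differential expression.
#'
#' @param spec A [simulation_spec()].
#' @return List with `counts` (named list of per-species
#'   [count_matrix()]), `gene_lengths`, `orthologs` (reference ids are the
#'   human ids), and `truth` (planted gene ids, their fold changes, and the
#'   expected FPKM of human-specific genes).
#' @export
simulate_laminar_counts <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  species <- names(spec$species_layers)
  reference <- "human"
  if (!reference %in% species)
    stop("species_layers must include 'human'", call. = FALSE)
  n <- spec$n_genes
  gene_ids <- sprintf("g%05d", seq_len(n))

  set.seed(derive_seed(spec$seed, 1L))
  lengths_bp <- sample(500:5000, n, replace = TRUE)
  base_q <- 2^stats::runif(n, spec$baseline_log_mean_range[1],
                           spec$baseline_log_mean_range[2])
  planted <- sample(gene_ids, spec$n_conserved_svz_genes +
                              spec$n_human_specific_genes)
  conserved_ids <- planted[seq_len(spec$n_conserved_svz_genes)]
  human_ids <- setdiff(planted, conserved_ids)
  is_cons <- gene_ids %in% conserved_ids
  is_hum <- gene_ids %in% human_ids

  # expected normalized intensity q[gene, layer] per species
  q_for <- function(sp) {
    layers <- spec$species_layers[[sp]]
    svz <- intersect(layers, SVZ_TYPE_LAYERS)
    q <- matrix(base_q, n, length(layers),
                dimnames = list(gene_ids, layers))
    q[is_cons, svz] <- q[is_cons, svz, drop = FALSE] *
      2^spec$conserved_svz_lfc
    # human-specific genes: plant on the FPKM scale, exactly
    for (l in layers) {
      if (sp == reference) {
        f_target <- if (l %in% svz) spec$human_specific_target_fpkm else
          spec$human_specific_target_fpkm / 8
      } else {
        f_target <- spec$other_species_max_fpkm
      }
      t_other <- sum(q[!is_hum, l])
      u <- f_target * lengths_bp[is_hum] / 1e9
      if (any(u >= 1))
        stop("human_specific_target_fpkm infeasible for gene length",
             call. = FALSE)
      q_tot <- t_other * sum(u) / (1 - sum(u))
      q[is_hum, l] <- u * (t_other + q_tot)
    }
    q
  }

  counts <- list()
  truth_lfc <- list()
  expected_fpkm <- list()
  for (k in seq_along(species)) {
    sp <- species[k]
    layers <- spec$species_layers[[sp]]
    svz <- intersect(layers, SVZ_TYPE_LAYERS)
    q <- q_for(sp)
    set.seed(derive_seed(spec$seed, 10L + k))
    nsamp <- length(layers) * spec$n_replicates
    lib <- stats::runif(nsamp, spec$library_size_range[1],
                        spec$library_size_range[2])
    meta <- data.frame(
      sample_id = paste0(sp, "_", rep(layers, each = spec$n_replicates),
                         "_r", rep(seq_len(spec$n_replicates),
                                   length(layers))),
      species = sp,
      layer = rep(layers, each = spec$n_replicates),
      replicate = rep(seq_len(spec$n_replicates), length(layers)),
      stringsAsFactors = FALSE)
    sp_gene_ids <- if (sp == reference) gene_ids else
      paste0(sp, "_", gene_ids)
    mat <- matrix(0L, n, nsamp, dimnames = list(sp_gene_ids,
                                                meta$sample_id))
    for (j in seq_len(nsamp)) {
      l <- meta$layer[j]
      mu <- lib[j] * q[, l] / sum(q[, l])
      mat[, j] <- if (spec$dispersion == 0) {
        stats::rpois(n, mu)
      } else {
        stats::rnbinom(n, mu = mu, size = 1 / spec$dispersion)
      }
    }
    counts[[sp]] <- count_matrix(mat, meta)
    # record planted log2 fold changes (SVZ-type layer vs CP) and FPKM
    if (length(planted) > 0) {
      for (l in svz) {
        lfc <- log2(q[planted, l] / q[planted, "CP"])
        truth_lfc[[paste(sp, l)]] <- data.frame(
          species = sp, layer = l, gene_id = planted,
          true_log2_fc = lfc, stringsAsFactors = FALSE,
          row.names = NULL)
      }
    }
    if (length(human_ids) > 0)
      expected_fpkm[[sp]] <- data.frame(
        species = sp,
        gene_id = rep(human_ids, length(layers)),
        layer = rep(layers, each = length(human_ids)),
        expected_fpkm = as.vector(vapply(layers, function(l)
          q[is_hum, l] * 1e9 / (sum(q[, l]) * lengths_bp[is_hum]),
          numeric(sum(is_hum)))),
        stringsAsFactors = FALSE, row.names = NULL)
  }

  # ortholog table: reference ids are human ids; other species carry a
  # prefixed target id. A dropout fraction of non-planted genes loses its
  # one-to-one status (or the row entirely) in one random species.
  set.seed(derive_seed(spec$seed, 2L))
  others <- setdiff(species, reference)
  orth <- do.call(rbind, c(list(data.frame(
    reference_gene_id = character(0), species = character(0),
    target_gene_id = character(0), one_to_one = logical(0),
    stringsAsFactors = FALSE)),
    lapply(others, function(sp)
      data.frame(reference_gene_id = gene_ids, species = sp,
                 target_gene_id = paste0(sp, "_", gene_ids),
                 one_to_one = TRUE, stringsAsFactors = FALSE))))
  nontruth <- setdiff(gene_ids, planted)
  n_drop <- if (length(others) > 0)
    round(spec$ortholog_dropout_fraction * length(nontruth)) else 0L
  drop_genes <- character(0)
  if (n_drop > 0) {
    drop_genes <- sample(nontruth, n_drop)
    drop_sp <- sample(others, n_drop, replace = TRUE)
    remove_row <- stats::runif(n_drop) < 0.5
    key <- paste(orth$reference_gene_id, orth$species)
    flag_off <- key %in% paste(drop_genes[!remove_row],
                               drop_sp[!remove_row])
    orth$one_to_one[flag_off] <- FALSE
    orth <- orth[!(key %in% paste(drop_genes[remove_row],
                                  drop_sp[remove_row])), ]
    rownames(orth) <- NULL
  }

  gene_lengths <- do.call(rbind, c(
    list(data.frame(gene_id = gene_ids, length_bp = lengths_bp,
                    stringsAsFactors = FALSE)),
    lapply(others, function(sp)
      data.frame(gene_id = paste0(sp, "_", gene_ids),
                 length_bp = lengths_bp, stringsAsFactors = FALSE))))
  rownames(gene_lengths) <- NULL

  truth <- list(conserved_svz_gene_ids = sort(conserved_ids),
                human_specific_gene_ids = sort(human_ids),
                true_log2_fc = do.call(rbind, truth_lfc),
                expected_fpkm = do.call(rbind, expected_fpkm),
                dropout_gene_ids = sort(drop_genes))
  rownames(truth$true_log2_fc) <- NULL
  list(counts = counts, gene_lengths = gene_lengths, orthologs = orth,
       truth = truth)
}

#' Simulate hybrid allele-resolved expression
#'
#' Generates parental (human, chimpanzee) and within-hybrid allelic
#' expression for `n_genes`, with planted regulatory architecture: the
#' hybrid allelic log2 ratio carries the cis effect only, while the
#' parental log2 ratio carries cis + trans; independent Gaussian noise (log2
#' scale, sd `noise_sd`) is added to each of the two log-ratio measurements.
#'
#' @param n_genes Number of genes.
#' @param cis_effect,trans_effect Planted effects, log2 units.
#' @param noise_sd Measurement noise sd, log2 units (>= 0).
#' @param seed Integer seed.
#' @return List with `allelic` (a data frame readable by
#'   [read_allelic_table()] semantics) and `truth` (planted cis/trans per
#'   gene).
#' @export
simulate_allelic_expression <- function(n_genes, cis_effect, trans_effect,
                                        noise_sd, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  set.seed(derive_seed(seed, 3L))
  base_par <- 2^stats::runif(n_genes, 4, 10)
  base_hyb <- 2^stats::runif(n_genes, 4, 10)
  e_par <- stats::rnorm(n_genes, 0, noise_sd)
  e_hyb <- stats::rnorm(n_genes, 0, noise_sd)
  allelic <- data.frame(
    gene_id = sprintf("a%05d", seq_len(n_genes)),
    parental_human = base_par * 2^(cis_effect + trans_effect + e_par),
    parental_chimp = base_par,
    hybrid_human_allele = base_hyb * 2^(cis_effect + e_hyb),
    hybrid_chimp_allele = base_hyb,
    stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = allelic$gene_id,
                      true_cis = cis_effect, true_trans = trans_effect,
                      stringsAsFactors = FALSE)
  list(allelic = allelic, truth = truth)
}

#' Default species trait table
#'
#' Divergence time from human (millions of years), adult brain weight
#' (grams) and gyrification index for the seven species of the comparative
#' design. Values are literature-typical illustrations for simulation and
#' examples, not measurements shipped with any particular study.
#'
#' @return Data frame with columns `species`, `divergence_mya`,
#'   `brain_weight_g`, `gyrification_index`.
#' @export
default_species_traits <- function() {
  data.frame(
    species = c("human", "chimpanzee", "gibbon", "macaque", "marmoset",
                "tree_shrew", "mouse"),
    divergence_mya = c(0, 6, 20, 29, 43, 74, 90),
    brain_weight_g = c(1350, 400, 90, 95, 8, 3, 0.4),
    gyrification_index = c(2.57, 2.19, 1.9, 1.73, 1.18, 1.06, 1.03),
    stringsAsFactors = FALSE)
}

#' Simulate a species-trait expression trend
#'
#' Draws `n_replicates` expression values per species, linear in the chosen
#' trait plus Gaussian noise, with the slope calibrated so the population
#' correlation between expression and trait (over replicate-level points)
#' equals `target_R`.
#'
#' @param species_traits Trait table (see [default_species_traits()]).
#' @param target_R Desired population Pearson correlation, |R| <= 1.
#' @param noise_sd Residual sd in expression units; must be 0 when
#'   |target_R| = 1.
#' @param seed Integer seed.
#' @param trait_name Trait column driving the trend (default
#'   `"divergence_mya"`).
#' @param n_replicates Replicates per species (default 3).
#' @return List with `expression` (data frame `species`, `replicate`,
#'   `expression`) and `truth` (slope, intercept, target correlation).
#' @export
simulate_trait_trend <- function(species_traits, target_R, noise_sd,
                                 seed = 1L, trait_name = "divergence_mya",
                                 n_replicates = 3L) {
  if (abs(target_R) > 1) stop("|target_R| must be <= 1", call. = FALSE)
  if (nrow(species_traits) < 3)
    stop("need >= 3 species for a trend", call. = FALSE)
  if (!trait_name %in% names(species_traits))
    stop("unknown trait: ", trait_name, call. = FALSE)
  if (abs(target_R) == 1 && noise_sd > 0)
    stop("target_R of +/-1 requires noise_sd = 0", call. = FALSE)
  t_rep <- rep(species_traits[[trait_name]], each = n_replicates)
  sd_t <- stats::sd(t_rep) * sqrt((length(t_rep) - 1) / length(t_rep))
  slope <- if (target_R == 0) 0 else if (noise_sd == 0) {
    sign(target_R)  # any positive-magnitude slope gives |r| = 1
  } else {
    sign(target_R) * sqrt(target_R^2 / (1 - target_R^2)) * noise_sd / sd_t
  }
  set.seed(derive_seed(seed, 4L))
  expr <- 10 + slope * t_rep + stats::rnorm(length(t_rep), 0, noise_sd)
  out <- data.frame(
    species = rep(species_traits$species, each = n_replicates),
    replicate = rep(seq_len(n_replicates), nrow(species_traits)),
    expression = expr, stringsAsFactors = FALSE)
  list(expression = out,
       truth = list(slope = slope, intercept = 10, target_R = target_R,
                    trait_name = trait_name))
}
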