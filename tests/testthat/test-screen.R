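# Small ortholog table helper: ids map 1:1 with a species prefix.
make_orth <- function(genes, species, flag = TRUE) {
  do.call(rbind, lapply(species, function(sp)
    data.frame(reference_gene_id = genes, species = sp,
               target_gene_id = paste0(sp, "_", genes),
               one_to_one = rep_len(flag, length(genes)),
               stringsAsFactors = FALSE)))
}

test_that("SVZ enrichment requires the conjunction over germinal layers", {
  # gene 1 up in both ISVZ and OSVZ, gene 2 only in ISVZ, gene 3 flat,
  # plus a flat background so total-count size factors are stable
  set.seed(11)
  n_rep <- 3
  n_bg <- 200
  mu <- c(200, 200, 200, rep(150, n_bg))
  draw_layer <- function(f) {
    m <- mu; m[1:3] <- m[1:3] * f
    vapply(seq_len(n_rep), function(i)
      rnbinom(length(m), mu = m, size = 100), numeric(length(m)))
  }
  mat <- cbind(draw_layer(c(1, 1, 1)),        # CP
               draw_layer(c(8, 8, 1)),        # ISVZ
               draw_layer(c(8, 1, 1)))        # OSVZ
  rownames(mat) <- c("up_both", "up_isvz", "flat",
                     sprintf("bg%03d", seq_len(n_bg)))
  colnames(mat) <- sprintf("s%02d", 1:9)
  meta <- make_metadata(colnames(mat),
                        layer = rep(c("CP", "ISVZ", "OSVZ"), each = 3))
  cm <- count_matrix(mat, meta)
  hits <- svz_enriched_genes(cm, screen_config())
  expect_identical(as.character(hits), "up_both")
  # per-contrast DE tables confirm the conjunction rule
  de <- attr(hits, "de_tables")
  expect_true(de$ISVZ$padj[de$ISVZ$gene_id == "up_isvz"] < 0.05)
  expect_false("up_isvz" %in% hits)
  expect_error(svz_enriched_genes(
    count_matrix(mat, make_metadata(colnames(mat), layer = "ISVZ")),
    screen_config()), "CP")
})

test_that("consensus, specificity and orthology set algebra match
           brute-force scans", {
  orth <- make_orth(c("A", "B", "C", "D"), c("macaque", "mouse"))
  sets <- list(human = c("A", "B", "C"),
               macaque = paste0("macaque_", c("B", "C")),
               mouse = paste0("mouse_", "C"))
  expect_identical(consensus_svz(sets, orth), "C")
  empty <- sets; empty$mouse <- character(0)
  expect_identical(consensus_svz(empty, orth), character(0))
  expect_error(consensus_svz(list(human = "A", yeti = "A"), orth),
               "yeti")

  # brute-force membership scan oracle
  ref_sets <- list(human = sets$human, macaque = c("B", "C"),
                   mouse = "C")
  brute <- Filter(function(g) all(vapply(ref_sets, function(s) g %in% s,
                                         logical(1))),
                  unique(unlist(ref_sets)))
  expect_identical(consensus_svz(sets, orth), sort(unlist(brute)))

  # step 2: human minus any-other-species, no-ortholog genes retained
  hs <- human_specific_genes(c("A", "B", "C", "Z"),
                             sets[c("macaque", "mouse")], orth)
  expect_identical(hs, c("A", "Z"))  # Z has no ortholog row -> retained
  expect_false("C" %in% hs)          # consensus gene removed

  # step 3: one-to-one in every species, brute-force row scan oracle
  orth2 <- orth
  orth2$one_to_one[orth2$reference_gene_id == "A" &
                   orth2$species == "mouse"] <- FALSE
  kept <- orthology_filter(c("A", "B", "Z"), orth2,
                           c("human", "macaque", "mouse"))
  brute_keep <- Filter(function(g) {
    all(vapply(c("macaque", "mouse"), function(sp)
      any(orth2$reference_gene_id == g & orth2$species == sp &
          orth2$one_to_one), logical(1)))
  }, c("A", "B", "Z"))
  expect_identical(kept, sort(unlist(c(brute_keep, character(0)))))
  expect_identical(kept, "B")
})

test_that("FPKM gates are strict at both thresholds", {
  lengths <- data.frame(gene_id = c("A", "B", "C",
                                    paste0("mouse_", c("A", "B", "C"))),
                        length_bp = 1000L)
  orth <- make_orth(c("A", "B", "C"), "mouse")
  cfg <- screen_config()
  # build count matrices whose FPKM hit chosen values exactly:
  # FPKM = count * 1e9 / (total * 1000); with total = 1e6 -> FPKM = count
  mk <- function(vals, species, layers) {
    n_rep <- 2
    cols <- length(layers) * n_rep
    mat <- matrix(rep(vals, cols), length(vals), cols)
    filler <- 1e6 - colSums(mat)
    mat <- rbind(mat, filler)
    rownames(mat) <- c(names(vals), "filler")
    storage.mode(mat) <- "integer"
    colnames(mat) <- sprintf("%s_s%02d", species, seq_len(cols))
    meta <- make_metadata(colnames(mat), species = species,
                          layer = rep(layers, each = n_rep))
    count_matrix(mat, meta)
  }
  lengths <- rbind(lengths,
                   data.frame(gene_id = c("filler", "mouse_filler"),
                              length_bp = 1000L))
  # human: A=60 (passes), B=50 (boundary, fails), C=200
  hum_vals <- c(A = 60L, B = 50L, C = 200L)
  hum <- mk(hum_vals, "human", c("CP", "OSVZ", "ISVZ", "VZ"))
  # mouse orthologs: A=1, B=1, C=1.5 -> C fails the strict < 1.5 gate
  # (FPKM 1.5 needs count 1.5; use length 2000 with count 3)
  mouse_mat <- matrix(rep(c(1L, 1L, 3L), 6), 3, 6)
  mouse_mat <- rbind(mouse_mat, 1e6 - colSums(mouse_mat))
  rownames(mouse_mat) <- c("mouse_A", "mouse_B", "mouse_C",
                           "mouse_filler")
  storage.mode(mouse_mat) <- "integer"
  colnames(mouse_mat) <- sprintf("mouse_s%02d", 1:6)
  mouse <- count_matrix(mouse_mat,
                        make_metadata(colnames(mouse_mat), "mouse",
                                      rep(c("CP", "SVZ", "VZ"),
                                          each = 2)))
  lengths$length_bp[lengths$gene_id == "mouse_C"] <- 2000L
  fpkm <- list(human = compute_fpkm(hum, lengths),
               mouse = compute_fpkm(mouse, lengths))
  out <- fpkm_gate(c("A", "B", "C"), fpkm, orth, cfg)
  expect_identical(out, "A")
  # check the boundary values really were exact
  lm_h <- layer_mean_fpkm(fpkm$human)
  expect_equal(unname(rowMeans(lm_h[c("A", "B"), c("OSVZ", "ISVZ")])),
               c(60, 50), tolerance = 1e-9)
  lm_m <- layer_mean_fpkm(fpkm$mouse)
  expect_equal(unname(lm_m["mouse_C", "SVZ"]), 1.5, tolerance = 1e-9)
})

test_that("the full screen recovers the planted gene and nests its sets", {
  sim <- simulate_laminar_counts(simulation_spec(n_genes = 500, seed = 14))
  rep <- run_screen(sim$counts, sim$gene_lengths, sim$orthologs,
                    screen_config())
  expect_identical(rep$step45_candidate_set,
                   sim$truth$human_specific_gene_ids)
  expect_true(all(rep$step45_candidate_set %in% rep$step3_ortholog_set))
  expect_true(all(rep$step3_ortholog_set %in%
                  rep$step2_human_specific_set))
  expect_identical(unname(rep$cardinalities["step45_candidates"]), 1L)

  # rerun -> identical report
  rep2 <- run_screen(sim$counts, sim$gene_lengths, sim$orthologs,
                     screen_config())
  expect_identical(rep$cardinalities, rep2$cardinalities)
  expect_identical(rep$step1_per_species_sets, rep2$step1_per_species_sets)

  # no planted human-specific gene -> empty candidate set
  sim0 <- simulate_laminar_counts(
    simulation_spec(n_genes = 300, n_human_specific_genes = 0L,
                    seed = 15))
  rep0 <- run_screen(sim0$counts, sim0$gene_lengths, sim0$orthologs,
                     screen_config())
  expect_length(rep0$step45_candidate_set, 0)
})

test_that("relaxing FPKM gates never shrinks the candidate set", {
  sim <- simulate_laminar_counts(simulation_spec(n_genes = 300, seed = 16))
  base <- run_screen(sim$counts, sim$gene_lengths, sim$orthologs,
                     screen_config())
  relaxed <- run_screen(sim$counts, sim$gene_lengths, sim$orthologs,
                        screen_config(human_fpkm_min = 10,
                                      other_fpkm_max = 10))
  expect_true(all(base$step45_candidate_set %in%
                  relaxed$step45_candidate_set))
})
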