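# Small in-code fixtures shared across the suite.

make_metadata <- function(sample_ids, species = "human", layer = "CP") {
  data.frame(sample_id = sample_ids,
             species = rep_len(species, length(sample_ids)),
             layer = rep_len(layer, length(sample_ids)),
             replicate = seq_along(sample_ids),
             stringsAsFactors = FALSE)
}

make_count_matrix <- function(mat, species = "human", layer = "CP") {
  if (is.null(rownames(mat)))
    rownames(mat) <- sprintf("g%03d", seq_len(nrow(mat)))
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  count_matrix(mat, make_metadata(colnames(mat), species, layer))
}

# Two-layer (CP + one SVZ-type) single-species matrix with NB noise and a
# chosen set of upregulated genes.
make_two_layer_cm <- function(n_genes = 100, n_rep = 3, mu = 200,
                              up_genes = integer(0), lfc = 2,
                              alpha = 0.05, species = "human",
                              svz_layer = "OSVZ", seed = 1) {
  set.seed(seed)
  mu_cp <- rep(mu, n_genes)
  mu_svz <- mu_cp
  mu_svz[up_genes] <- mu_cp[up_genes] * 2^lfc
  draw <- function(m) {
    if (alpha == 0) rpois(n_genes, m) else
      rnbinom(n_genes, mu = m, size = 1 / alpha)
  }
  mat <- cbind(vapply(seq_len(n_rep), function(i) draw(mu_cp),
                      numeric(n_genes)),
               vapply(seq_len(n_rep), function(i) draw(mu_svz),
                      numeric(n_genes)))
  rownames(mat) <- sprintf("g%03d", seq_len(n_genes))
  colnames(mat) <- c(paste0("cp", seq_len(n_rep)),
                     paste0("svz", seq_len(n_rep)))
  meta <- data.frame(sample_id = colnames(mat), species = species,
                     layer = rep(c("CP", svz_layer), each = n_rep),
                     replicate = rep(seq_len(n_rep), 2),
                     stringsAsFactors = FALSE)
  count_matrix(mat, meta)
}

make_circle <- function(n = 360, r = 1, cx = 0, cy = 0) {
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  contour_points(cbind(cx + r * cos(theta), cy + r * sin(theta)))
}

# Radially folded circle r(theta) = 1 + a * sin(k * theta).
make_folded_circle <- function(n = 2000, a = 0.1, k = 8) {
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- 1 + a * sin(k * theta)
  contour_points(cbind(r * cos(theta), r * sin(theta)))
}

# Independent brute-force oracles -------------------------------------------

bh_oracle <- function(p) {
  m <- length(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- sum(p <= p[i]) # ties share the largest rank
    cands <- vapply(seq_len(m), function(j) {
      r_j <- sum(p <= p[j])
      if (p[j] >= p[i]) p[j] * m / r_j else Inf
    }, numeric(1))
    q[i] <- min(1, min(cands))
  }
  q
}

hull_oracle <- function(pts) {
  # a point is a hull vertex iff some line through it keeps all other
  # points strictly on one side (checked over all point pairs)
  n <- nrow(pts)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      v <- pts[j, ] - pts[i, ]
      cross <- (pts[, 1] - pts[i, 1]) * v[2] -
               (pts[, 2] - pts[i, 2]) * v[1]
      if (all(cross <= 1e-12) || all(cross >= -1e-12)) {
        on_hull[i] <- TRUE
        break
      }
    }
  }
  which(on_hull)
}

fpkm_oracle <- function(counts, totals, lengths) {
  out <- matrix(0, nrow(counts), ncol(counts))
  for (g in seq_len(nrow(counts)))
    for (j in seq_len(ncol(counts)))
      out[g, j] <- counts[g, j] * 1e9 / (totals[j] * lengths[g])
  dimnames(out) <- dimnames(counts)
  out
}
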