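#' Size factors from library totals
#'
#' Per-sample sequencing-depth factors computed from the total number of
#' reads: `s_j = total_j / geometric_mean(totals)`, so that the geometric
#' mean of the factors is exactly 1.
#'
#' @param counts A [count_matrix()].
#' @return Named numeric vector of positive factors, one per sample.
#' @examples
#' cm <- count_matrix(matrix(c(5L, 5L, 10L, 10L), 2,
#'                    dimnames = list(c("a", "b"), NULL)),
#'   data.frame(sample_id = c("s1", "s2"), species = "human",
#'              layer = "CP", replicate = 1:2))
#' compute_size_factors(cm)
#' @export
compute_size_factors <- function(counts) {
  totals <- colSums(counts$counts)
  zero <- totals == 0
  if (any(zero))
    stop("sample '", names(totals)[zero][1],
         "' has zero total counts; size factor undefined", call. = FALSE)
  sf <- totals / exp(mean(log(totals)))
  sf
}

#' Per-gene negative-binomial dispersion by method of moments
#'
#' On depth-normalized counts `y_j = c_j / s_j`, each gene's dispersion is
#' estimated as `(pooled within-group variance - pooled mean) / pooled
#' mean^2`, with within-group variance pooled across the two groups after
#' removing group means. Raw per-gene moment estimates are extremely noisy
#' at typical replicate numbers (2-4 per group), which inflates downstream
#' Wald type-I error; by default each gene's estimate is therefore floored
#' at the cohort median of the positive per-gene estimates
#' (`dispersion_guard = "median"`), a flat-trend analogue of the classic
#' "take the maximum of gene-wise and shared dispersion" rule. Set
#' `dispersion_guard = "none"` for the raw estimator.
#'
#' @param counts A [count_matrix()].
#' @param sf Size factors from [compute_size_factors()].
#' @param groups Two-level factor (or vector) over samples.
#' @param alpha_floor Absolute lower bound on the dispersion (default 1e-8).
#' @param dispersion_guard `"moderated"` (default): shrink each gene's
#'   estimate toward the cohort median with `prior_df` pseudo-degrees of
#'   freedom, then floor at that median — tames both tails of the
#'   estimation noise (underestimates inflate type-I error, overestimates
#'   destroy power); `"median"`: floor at the cohort median only;
#'   `"none"`: raw per-gene estimates.
#' @param prior_df Weight of the cohort median in the moderated estimate,
#'   in pseudo-degrees of freedom (default 4, i.e. comparable to the
#'   residual information of a 3-vs-3 contrast).
#' @return Named numeric vector of dispersions, with attribute `all_zero`
#'   flagging genes whose counts are zero in every sample (their dispersion
#'   is the floor and they are untestable downstream).
#' @export
estimate_dispersion <- function(counts, sf, groups, alpha_floor = 1e-8,
                                dispersion_guard = c("moderated",
                                                     "median", "none"),
                                prior_df = 4) {
  dispersion_guard <- match.arg(dispersion_guard)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2)
    stop("groups must have exactly two levels", call. = FALSE)
  if (any(table(groups) < 2))
    stop("each group needs at least two samples", call. = FALSE)
  y <- sweep(counts$counts, 2, sf, "/")
  g1 <- groups == levels(groups)[1]
  m1 <- rowMeans(y[, g1, drop = FALSE])
  m2 <- rowMeans(y[, !g1, drop = FALSE])
  gm <- (m1 + m2) / 2
  ss <- rowSums((y[, g1, drop = FALSE] - m1)^2) +
        rowSums((y[, !g1, drop = FALSE] - m2)^2)
  v <- ss / (ncol(y) - 2)
  alpha <- ifelse(gm > 0, (v - gm) / gm^2, 0)
  if (dispersion_guard != "none" && any(gm > 0)) {
    guard <- stats::median(pmax(alpha[gm > 0], 0))
    if (dispersion_guard == "moderated") {
      df_res <- ncol(y) - 2
      alpha <- (prior_df * guard + df_res * pmax(alpha, 0)) /
        (prior_df + df_res)
    }
    alpha <- pmax(alpha, guard)
  }
  alpha <- pmax(alpha, alpha_floor)
  names(alpha) <- rownames(counts$counts)
  attr(alpha, "all_zero") <- rowSums(counts$counts) == 0
  alpha
}

# Vectorized IRLS for the two-group NB GLM with log link and log-size-factor
# offsets, dispersion fixed per gene. Coefficients are clamped so the group
# log2 fold change stays in [-lfc_cap, lfc_cap]; genes separated by zeros
# converge onto that boundary instead of diverging.
nb_irls <- function(counts, sf, alpha, x, lfc_cap = 30, maxit = 100,
                    tol = 1e-8) {
  G <- nrow(counts); n <- ncol(counts)
  off <- matrix(log(sf), G, n, byrow = TRUE)
  X1 <- matrix(x, G, n, byrow = TRUE)
  b1_cap <- lfc_cap * log(2)
  eta <- pmin(pmax(log(counts + 0.5), -50), 50)
  beta0 <- rep(0, G); beta1 <- rep(0, G)
  converged <- rep(FALSE, G)
  iters <- rep(NA_integer_, G)
  for (it in seq_len(maxit)) {
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (counts - mu) / mu
    a11 <- rowSums(w)
    a12 <- rowSums(w * X1)
    a22 <- rowSums(w * X1 * X1)
    r1 <- rowSums(w * z)
    r2 <- rowSums(w * X1 * z)
    det <- a11 * a22 - a12^2
    nb0 <- (a22 * r1 - a12 * r2) / det
    nb1 <- (a11 * r2 - a12 * r1) / det
    nb1 <- pmin(pmax(nb1, -b1_cap), b1_cap)
    nb0 <- pmin(pmax(nb0, -b1_cap), b1_cap)
    delta <- pmax(abs(nb0 - beta0), abs(nb1 - beta1))
    beta0 <- nb0; beta1 <- nb1
    eta <- pmin(pmax(off + beta0 + beta1 * X1, -50), 50)
    newly <- !converged & delta < tol
    iters[newly] <- it
    converged <- converged | newly
    if (all(converged)) break
  }
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  a11 <- rowSums(w)
  a12 <- rowSums(w * X1)
  a22 <- rowSums(w * X1 * X1)
  det <- a11 * a22 - a12^2
  se1 <- sqrt(a11 / det)
  list(beta0 = beta0, beta1 = beta1, se1 = se1, converged = converged)
}

#' Two-group negative-binomial Wald test
#'
#' Fits, per gene, the model `count_j ~ NB(mean = s_j * exp(b0 + b1 * x_j),
#' dispersion alpha_g)` by iteratively reweighted least squares at the fixed
#' dispersion, where `x_j` indicates membership of group B. The reported
#' log2 fold change is `b1 / ln 2` (B over A), the Wald statistic is
#' `b1 / SE(b1)` with the standard error taken from the information matrix
#' at convergence, and two-sided p-values come from the standard normal.
#' Adjusted p-values are Benjamini-Hochberg, computed over tested genes
#' only; genes with zero counts in every sample are untestable
#' (`tested = FALSE`, `p_value = NA`). Fold changes are capped at +/-30
#' log2 units so that group-restricted zeros yield finite estimates.
#'
#' @param counts A [count_matrix()].
#' @param sf Size factors.
#' @param disp Dispersions from [estimate_dispersion()].
#' @param groups Two-level factor over samples; the first level is the
#'   reference (group A).
#' @param lfc_cap Cap on |log2 fold change| (default 30).
#' @param maxit,tol IRLS iteration cap and convergence tolerance on the
#'   maximum coefficient change.
#' @return Data frame of class `de_result`: `gene_id`,
#'   `mean_normalized_count`, `log2_fc`, `lfc_se`, `wald_stat`, `p_value`,
#'   `padj`, `tested`.
#' @export
nb_wald_test <- function(counts, sf, disp, groups, lfc_cap = 30,
                         maxit = 100, tol = 1e-8) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2)
    stop("groups must have exactly two levels", call. = FALSE)
  if (any(table(groups) < 2))
    stop("each group needs at least two samples", call. = FALSE)
  mat <- counts$counts
  if (length(disp) != nrow(mat))
    stop("disp must hold one dispersion per gene", call. = FALSE)
  if (!is.null(names(disp)) && !identical(names(disp), rownames(mat)))
    disp <- disp[rownames(mat)]
  if (anyNA(disp))
    stop("dispersions do not cover all genes", call. = FALSE)
  x <- as.numeric(groups == levels(groups)[2])
  all_zero <- rowSums(mat) == 0
  base_mean <- rowMeans(sweep(mat, 2, sf, "/"))
  res <- data.frame(gene_id = rownames(mat),
                    mean_normalized_count = base_mean,
                    log2_fc = NA_real_, lfc_se = NA_real_,
                    wald_stat = NA_real_, p_value = NA_real_,
                    padj = NA_real_, tested = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (any(!all_zero)) {
    fit <- nb_irls(mat[!all_zero, , drop = FALSE], sf,
                   as.numeric(disp[!all_zero]), x,
                   lfc_cap = lfc_cap, maxit = maxit, tol = tol)
    if (any(!fit$converged))
      message(sum(!fit$converged),
              " gene(s) did not converge within ", maxit,
              " IRLS iterations; flagged untestable")
    ln2 <- log(2)
    idx <- which(!all_zero)
    res$log2_fc[idx] <- fit$beta1 / ln2
    res$lfc_se[idx] <- fit$se1 / ln2
    res$wald_stat[idx] <- fit$beta1 / fit$se1
    p <- 2 * stats::pnorm(-abs(fit$beta1 / fit$se1))
    p[!fit$converged] <- NA_real_
    res$p_value[idx] <- p
    res$tested[idx] <- fit$converged
  }
  tested <- res$tested
  res$padj[tested] <- bh_adjust(res$p_value[tested])
  class(res) <- c("de_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment: sort ascending, take
#' `p_(i) * m / i`, enforce monotonicity from the largest rank down, cap at
#' 1, and return in the original order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)))
    stop("p-values must not be NA", call. = FALSE)
  if (any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Layer-vs-layer differential expression within one species
#'
#' Convenience wrapper chaining [compute_size_factors()],
#' [estimate_dispersion()] and [nb_wald_test()] on the samples of two
#' cortical layers of a single-species count matrix. Size factors and
#' dispersions are computed on the samples entering the contrast, and the
#' BH adjustment is applied within the contrast, matching a
#' per-comparison analysis.
#'
#' @param cm A single-species [count_matrix()].
#' @param layer_a Reference layer (e.g. `"CP"`).
#' @param layer_b Test layer; the reported log2 fold change is B over A.
#' @param ... Passed on to [estimate_dispersion()] and [nb_wald_test()].
#' @return A `de_result` data frame.
#' @export
laminar_de <- function(cm, layer_a, layer_b, ...) {
  keep <- cm$samples$layer %in% c(layer_a, layer_b)
  if (sum(cm$samples$layer == layer_a) < 2 ||
      sum(cm$samples$layer == layer_b) < 2)
    stop("need >= 2 replicates in each of '", layer_a, "' and '", layer_b,
         "'", call. = FALSE)
  sub <- count_matrix(cm$counts[, keep, drop = FALSE],
                      cm$samples[keep, , drop = FALSE])
  groups <- factor(sub$samples$layer, levels = c(layer_a, layer_b))
  sf <- compute_size_factors(sub)
  dots <- list(...)
  disp_args <- dots[names(dots) %in% c("alpha_floor", "dispersion_guard")]
  test_args <- dots[names(dots) %in% c("lfc_cap", "maxit", "tol")]
  disp <- do.call(estimate_dispersion,
                  c(list(sub, sf, groups), disp_args))
  do.call(nb_wald_test, c(list(sub, sf, disp, groups), test_args))
}
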