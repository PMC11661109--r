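#' Cis/trans decomposition of expression divergence
#'
#' From allele-resolved expression in an interspecies hybrid and its
#' parental lines: the cis effect is the hybrid allelic log2 ratio
#' (human allele over chimpanzee allele, measured in the shared
#' trans-acting environment of the hybrid cell), and the trans effect is
#' the parental log2 ratio minus that cis effect. By construction
#' `cis + trans` equals the parental log2 ratio exactly.
#'
#' @param allelic Data frame with columns `gene_id`, `parental_human`,
#'   `parental_chimp`, `hybrid_human_allele`, `hybrid_chimp_allele`
#'   (expression units, >= 0).
#' @return Data frame `gene_id`, `cis_effect`, `trans_effect`,
#'   `parental_log2_ratio`, `defined` (FALSE where a denominator or
#'   numerator is zero, effects NA).
#' @examples
#' cis_trans_decompose(data.frame(
#'   gene_id = "g", parental_human = 4, parental_chimp = 1,
#'   hybrid_human_allele = 4, hybrid_chimp_allele = 1))
#' @export
cis_trans_decompose <- function(allelic) {
  required <- c("gene_id", "parental_human", "parental_chimp",
                "hybrid_human_allele", "hybrid_chimp_allele")
  require_columns(allelic, required, "allelic table")
  vals <- allelic[, required[-1]]
  if (any(vals < 0, na.rm = TRUE))
    stop("expression values must be >= 0", call. = FALSE)
  defined <- rowSums(vals <= 0 | is.na(vals)) == 0
  cis <- trans <- par_ratio <- rep(NA_real_, nrow(allelic))
  cis[defined] <- log2(allelic$hybrid_human_allele[defined] /
                       allelic$hybrid_chimp_allele[defined])
  par_ratio[defined] <- log2(allelic$parental_human[defined] /
                             allelic$parental_chimp[defined])
  trans[defined] <- par_ratio[defined] - cis[defined]
  if (any(!defined))
    message(sum(!defined), " gene(s) with zero expression: cis/trans ",
            "undefined")
  data.frame(gene_id = allelic$gene_id, cis_effect = cis,
             trans_effect = trans, parental_log2_ratio = par_ratio,
             defined = defined, stringsAsFactors = FALSE)
}

#' Pearson correlation with t-based p-value
#'
#' Standard Pearson product-moment correlation; the two-sided p-value comes
#' from the t transform `r * sqrt((n - 2) / (1 - r^2))` with n - 2 degrees
#' of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return List of class `correlation_result`: `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need >= 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x)), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (n = %d, p = %.3g)\n", x$r, x$n,
              x$p_value))
  invisible(x)
}

#' Correlate expression with a species trait
#'
#' Pairs every replicate-level expression value with its species' trait
#' value and computes the Pearson correlation over the individual points
#' (replicates are not averaged, matching per-point trend clouds; a
#' species-mean option is provided). Brain weight is log10-transformed
#' before correlating, the conventional scale for brain-size allometry.
#'
#' @param expression Data frame with columns `species` and `expression`
#'   (one row per replicate measurement).
#' @param traits Trait table (see [default_species_traits()]).
#' @param trait_name One of `"divergence_mya"`, `"brain_weight_g"`,
#'   `"gyrification_index"`.
#' @param replicate_level Pair replicate points (default TRUE) or species
#'   means (FALSE).
#' @return A `correlation_result`.
#' @export
expression_trait_trend <- function(expression, traits,
                                   trait_name = c("divergence_mya",
                                                  "brain_weight_g",
                                                  "gyrification_index"),
                                   replicate_level = TRUE) {
  trait_name <- match.arg(trait_name)
  require_columns(expression, c("species", "expression"),
                  "expression table")
  unknown <- setdiff(unique(expression$species), traits$species)
  if (length(unknown) > 0)
    stop("species '", unknown[1], "' absent from trait table",
         call. = FALSE)
  if (!replicate_level) {
    expression <- stats::aggregate(expression ~ species, expression, mean)
  }
  t_val <- traits[[trait_name]][match(expression$species, traits$species)]
  if (trait_name == "brain_weight_g") t_val <- log10(t_val)
  pearson_correlation(t_val, expression$expression)
}
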