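#' Per-sample upper-quartile scaling factors
#'
#' Computes, for every sample, the 75th percentile of its counts across the
#' genes in `x` (linear interpolation between order statistics). The matrix
#' is expected to have been pre-filtered with [filter_all_zero_genes()]; by
#' default genes that are zero in a given sample still enter that sample's
#' quantile, following standard upper-quartile practice.
#'
#' @param x A count tibble.
#' @param positive_only If `TRUE`, each sample's upper quartile is computed
#'   over that sample's positive counts only.
#' @return Named numeric vector of per-sample upper quartiles.
#' @export
upper_quartile_factors <- function(x, positive_only = FALSE) {
  m <- counts_to_matrix(x)
  uq <- apply(m, 2, function(v) {
    if (positive_only) v <- v[v > 0]
    if (length(v) == 0) 0 else quantile(v, 0.75, type = 7, names = FALSE)
  })
  zero <- names(uq)[uq <= 0]
  if (length(zero) > 0) {
    abort(paste0("upper quartile is zero for sample(s) ",
                 paste(zero, collapse = ", "),
                 "; data too sparse for upper-quartile scaling"))
  }
  uq
}

#' UQ-pgQ2 two-stage normalization
#'
#' Stage 1 divides each sample by its upper quartile (75th percentile over
#' genes). Stage 2 divides each gene by its across-sample median of the
#' stage-1 values and multiplies by `scale_constant`, so every gene with a
#' positive stage-1 median ends up with an across-sample median equal to
#' `scale_constant`. Genes whose stage-1 median is zero fall back to their
#' smallest positive stage-1 value as the divisor and are flagged.
#'
#' @param x A count tibble with no all-zero genes (run
#'   [filter_all_zero_genes()] first).
#' @param scale_constant Positive constant the per-gene median is scaled to
#'   (default 100, keeping values count-like). Any positive value yields the
#'   same downstream Wald statistics because it is absorbed into the gene
#'   mean.
#' @param positive_only Passed to [upper_quartile_factors()].
#' @return An object of class `uqpgq2_norm`: a list with `values` (tibble of
#'   normalized values), `sample_factors` (tibble `sample_id`, `uq`),
#'   `gene_factors` (tibble `gene_id`, `q2`, `fallback`), `scale_constant`
#'   and `method`. Stored values satisfy
#'   `value = scale_constant * (count / uq) / q2` exactly.
#' @export
uq_pgq2_normalize <- function(x, scale_constant = 100, positive_only = FALSE) {
  stopifnot(is.numeric(scale_constant), length(scale_constant) == 1L,
            scale_constant > 0)
  m <- counts_to_matrix(x)
  if (any(rowSums(m) == 0)) {
    abort("matrix contains all-zero genes; run filter_all_zero_genes() first")
  }
  uq <- upper_quartile_factors(x, positive_only = positive_only)
  n1 <- sweep(m, 2, uq, "/")
  q2 <- apply(n1, 1, median)
  fallback <- q2 <= 0
  if (any(fallback)) {
    q2[fallback] <- apply(n1[fallback, , drop = FALSE], 1,
                          function(v) min(v[v > 0]))
  }
  vals <- scale_constant * n1 / q2
  structure(
    list(
      values = matrix_to_counts(vals),
      sample_factors = tibble::tibble(sample_id = colnames(m), uq = unname(uq)),
      gene_factors = tibble::tibble(gene_id = rownames(m), q2 = unname(q2),
                                    fallback = unname(fallback)),
      scale_constant = scale_constant,
      method = "uq_pgq2"
    ),
    class = "uqpgq2_norm"
  )
}

#' @export
print.uqpgq2_norm <- function(x, ...) {
  cat("<", x$method, " normalization: ", nrow(x$gene_factors), " genes x ",
      nrow(x$sample_factors), " samples, scale constant ", x$scale_constant,
      ">\n", sep = "")
  if (any(x$gene_factors$fallback)) {
    cat(sum(x$gene_factors$fallback),
        "gene(s) with zero stage-1 median used the smallest-positive fallback\n")
  }
  invisible(x)
}

#' Round normalized values half-to-even to integer pseudo-counts
#'
#' UQ-pgQ2 output destined for the negative-binomial Wald test is rounded to
#' integers and tested with all size factors set to 1.
#'
#' @param norm A `uqpgq2_norm` object.
#' @return A count tibble of rounded values.
#' @export
rounded_counts <- function(norm) {
  stopifnot(inherits(norm, "uqpgq2_norm"))
  out <- norm$values
  for (j in seq(2L, ncol(out))) out[[j]] <- as.integer(round(out[[j]]))
  out
}

#' Median-of-ratios size factors
#'
#' For every gene with a positive count in all samples, a reference value is
#' computed as the geometric mean of its counts across samples; each sample's
#' size factor is the median over those genes of the ratio of its count to
#' the reference, rescaled so the size factors have geometric mean 1.
#'
#' @param x A count tibble.
#' @return Named numeric vector of per-sample size factors (geometric mean 1,
#'   tolerance 1e-9).
#' @export
median_of_ratios_factors <- function(x) {
  m <- counts_to_matrix(x)
  allpos <- rowSums(m > 0) == ncol(m)
  if (!any(allpos)) {
    abort("no gene has positive counts in every sample; cannot compute median-of-ratios factors")
  }
  lm_ <- log(m[allpos, , drop = FALSE])
  logref <- rowMeans(lm_)
  s <- exp(apply(lm_ - logref, 2, median))
  s <- s / geometric_mean(s)
  s
}

#' Normalize a count matrix by a named route
#'
#' Dispatches to [uq_pgq2_normalize()] (`"uq-pgq2"`) or to median-of-ratios
#' scaling (`"deseq-mor"`, per-sample division by the size factor, per-gene
#' factors all 1).
#'
#' @param x A count tibble.
#' @param method `"uq-pgq2"` or `"deseq-mor"`.
#' @param scale_constant Passed to [uq_pgq2_normalize()].
#' @param positive_only Passed to [uq_pgq2_normalize()].
#' @return A `uqpgq2_norm` object (for `deseq_mor` the `sample_factors`
#'   tibble holds column `size_factor` and `gene_factors$q2` is all 1).
#' @export
normalize_counts <- function(x, method = c("uq-pgq2", "deseq-mor"),
                             scale_constant = 100, positive_only = FALSE) {
  method <- match.arg(method)
  if (method == "uq-pgq2") {
    return(uq_pgq2_normalize(x, scale_constant = scale_constant,
                             positive_only = positive_only))
  }
  m <- counts_to_matrix(x)
  s <- median_of_ratios_factors(x)
  vals <- sweep(m, 2, s, "/")
  structure(
    list(
      values = matrix_to_counts(vals),
      sample_factors = tibble::tibble(sample_id = colnames(m),
                                      size_factor = unname(s)),
      gene_factors = tibble::tibble(gene_id = rownames(m), q2 = 1,
                                    fallback = FALSE),
      scale_constant = 1,
      method = "deseq_mor"
    ),
    class = "uqpgq2_norm"
  )
}
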