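#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the input, excludes missing values from the number of tests,
#' and applies the Benjamini-Hochberg step-up procedure. Missing p-values
#' propagate as missing.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values in the original order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) abort("p-values must be numeric")
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- p.adjust(pvalues[ok], method = "BH")
  out
}

#' Two-group negative-binomial Wald test
#'
#' For every gene the two group means are estimated in closed form as the
#' ratio of summed counts to summed size factors; the log2 fold change is
#' the log2 ratio test / reference. Its standard error comes from the NB GLM
#' Fisher information with per-sample weights `w = mu / (1 + alpha * mu)`:
#' `lfc_se = sqrt(1/sum(w_ref) + 1/sum(w_test)) / ln 2`. The Wald statistic
#' `log2fc / lfc_se` is referred to the standard normal, and p-values are
#' Benjamini-Hochberg adjusted. Groups whose mean is exactly zero are
#' floored at `0.5 / median(size_factors)` and the gene is flagged.
#'
#' @param counts Count tibble or integer matrix (genes x samples).
#' @param groups Two-level grouping vector over samples.
#' @param test,ref Labels of the test and reference group (`log2fc > 0`
#'   means higher in `test`).
#' @param size_factors Optional positive per-sample size factors (default 1).
#' @param dispersions A `dispersion_model` or a per-gene numeric vector of
#'   final dispersions.
#' @return A `deg_result` tibble: `gene_id`, `base_mean`, `log2fc`,
#'   `lfc_se`, `wald_stat`, `pvalue`, `padj`, `flagged`, with the route and
#'   group labels in attributes.
#' @export
nb_wald_two_group <- function(counts, groups, test, ref, size_factors = NULL,
                              dispersions) {
  m <- if (is.data.frame(counts)) counts_to_matrix(counts) else {
    stopifnot(is.matrix(counts)); counts
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(m)) abort("groups length must equal sample count")
  if (!all(c(test, ref) %in% groups)) abort("test and ref must both appear in groups")
  idx_t <- which(groups == test); idx_r <- which(groups == ref)
  if (length(idx_t) == 0 || length(idx_r) == 0) abort("a group has zero samples")
  if (is.null(size_factors)) size_factors <- rep(1, ncol(m))
  stopifnot(all(size_factors > 0))
  alpha <- if (inherits(dispersions, "dispersion_model")) {
    dispersions$genes$disp_map
  } else {
    as.numeric(dispersions)
  }
  if (length(alpha) == 1L) alpha <- rep(alpha, nrow(m))
  stopifnot(length(alpha) == nrow(m), all(alpha > 0))

  norm <- sweep(m, 2, size_factors, "/")
  base_mean <- rowMeans(norm)
  floor_mu <- 0.5 / median(size_factors)

  mu_t <- rowSums(m[, idx_t, drop = FALSE]) / sum(size_factors[idx_t])
  mu_r <- rowSums(m[, idx_r, drop = FALSE]) / sum(size_factors[idx_r])
  flagged <- mu_t == 0 | mu_r == 0
  mu_t <- pmax(mu_t, floor_mu)
  mu_r <- pmax(mu_r, floor_mu)
  log2fc <- log2(mu_t / mu_r)

  sw <- function(mu_hat, idx) {
    w <- outer(mu_hat, size_factors[idx])     # mu_gj = s_j * mu_hat_g
    rowSums(w / (1 + alpha * w))
  }
  lfc_se <- sqrt(1 / sw(mu_r, idx_r) + 1 / sw(mu_t, idx_t)) / log(2)
  wald_stat <- log2fc / lfc_se
  pvalue <- 2 * pnorm(-abs(wald_stat))

  out <- tibble::tibble(
    gene_id = rownames(m) %||% paste0("gene", seq_len(nrow(m))),
    base_mean = unname(base_mean),
    log2fc = unname(log2fc),
    lfc_se = unname(lfc_se),
    wald_stat = unname(wald_stat),
    pvalue = unname(pvalue),
    padj = unname(bh_adjust(pvalue)),
    flagged = unname(flagged)
  )
  new_deg_result(out, method = "nb_wald", test = test, ref = ref,
                 size_factors = size_factors)
}

new_deg_result <- function(tbl, method, test, ref, size_factors,
                           route = NULL) {
  structure(tbl,
            class = c("deg_result", class(tbl)),
            method = method, test = test, ref = ref,
            size_factors = size_factors, route = route)
}

#' Run one normalization route plus the NB Wald test
#'
#' The `"uq-pgq2"` route normalizes the counts of the involved samples with
#' [uq_pgq2_normalize()], rounds the values half-to-even to integers and
#' tests them with unit size factors. The `"deseq-mor"` route tests the raw
#' counts with median-of-ratios size factors. Dispersions are estimated with
#' [estimate_dispersions()] in both cases.
#'
#' @param x Count tibble (raw integer counts; pre-filter all-zero genes).
#' @param samples Sample sheet tibble (`sample_id`, `group`).
#' @param test_group,ref_group Condition labels to compare (log2 fold change
#'   is test over reference).
#' @param route `"uq-pgq2"` or `"deseq-mor"`.
#' @param scale_constant Passed to [uq_pgq2_normalize()].
#' @return A `deg_result` tibble (see [nb_wald_two_group()]); the dispersion
#'   model is attached as attribute `dispersions`.
#' @export
deg_test <- function(x, samples, test_group, ref_group,
                     route = c("uq-pgq2", "deseq-mor"), scale_constant = 100) {
  route <- match.arg(route)
  x <- validate_count_tbl(x)
  samples <- validate_sample_sheet(samples)
  keep <- samples$group %in% c(test_group, ref_group)
  samples <- samples[keep, , drop = FALSE]
  missing <- setdiff(samples$sample_id, sample_ids_of(x))
  if (length(missing) > 0) {
    abort(paste0("samples absent from count matrix: ",
                 paste(missing, collapse = ", ")))
  }
  x <- x[, c("gene_id", samples$sample_id)]

  if (route == "uq-pgq2") {
    norm <- uq_pgq2_normalize(x, scale_constant = scale_constant)
    counts_for_test <- rounded_counts(norm)
    sf <- rep(1, nrow(samples))
  } else {
    counts_for_test <- x
    sf <- median_of_ratios_factors(x)
  }
  disp <- estimate_dispersions(counts_for_test, samples$group, sf)
  res <- nb_wald_two_group(counts_for_test, samples$group,
                           test = test_group, ref = ref_group,
                           size_factors = sf, dispersions = disp)
  attr(res, "route") <- route
  attr(res, "dispersions") <- disp
  res
}

#' Call differentially expressed genes from a test result
#'
#' A gene is called when its BH-adjusted p-value is at most `fdr` and its
#' absolute log2 fold change is at least `lfc_cutoff` (inclusive on both
#' sides).
#'
#' @param res A `deg_result` tibble.
#' @param fdr Adjusted-p threshold (default 0.05).
#' @param lfc_cutoff Non-negative |log2FC| threshold.
#' @return A `deg_call` tibble of the called genes (`gene_id`, `base_mean`,
#'   `log2fc`, `padj`, `direction`), with the thresholds, per-direction
#'   counts and the full result attached as attributes.
#' @export
call_degs <- function(res, fdr = 0.05, lfc_cutoff) {
  stopifnot(inherits(res, "deg_result"))
  if (lfc_cutoff < 0) abort("lfc_cutoff must be >= 0")
  hit <- !is.na(res$padj) & res$padj <= fdr & abs(res$log2fc) >= lfc_cutoff
  out <- tibble::as_tibble(res)[hit, c("gene_id", "base_mean", "log2fc", "padj")]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  structure(out,
            class = c("deg_call", class(out)),
            fdr = fdr, lfc_cutoff = lfc_cutoff,
            n_up = sum(out$direction == "up"),
            n_down = sum(out$direction == "down"),
            route = attr(res, "route"),
            result = res)
}

#' @export
print.deg_call <- function(x, ...) {
  cat("<deg_call: ", nrow(x), " genes (", attr(x, "n_up"), " up, ",
      attr(x, "n_down"), " down) at FDR <= ", attr(x, "fdr"),
      ", |log2FC| >= ", attr(x, "lfc_cutoff"), ">\n", sep = "")
  NextMethod()
}

#' @rdname call_degs
#' @param x A `deg_call`.
#' @param ... Unused.
#' @export
glance.deg_call <- function(x, ...) {
  tibble::tibble(
    n_called = nrow(x),
    n_up = attr(x, "n_up"),
    n_down = attr(x, "n_down"),
    fdr = attr(x, "fdr"),
    lfc_cutoff = attr(x, "lfc_cutoff")
  )
}

#' @rdname nb_wald_two_group
#' @param x A `deg_result`.
#' @param ... Unused.
#' @export
tidy.deg_result <- function(x, ...) tibble::as_tibble(x)

#' @rdname nb_wald_two_group
#' @export
glance.deg_result <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_flagged = sum(x$flagged),
    test = attr(x, "test"),
    ref = attr(x, "ref"),
    route = attr(x, "route") %||% NA_character_
  )
}
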