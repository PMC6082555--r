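#' Randomly split samples of one condition into two equal halves
#'
#' Uniform random partition into halves of sizes `ceiling(n/2)` and
#' `floor(n/2)`, deterministic given the seed.
#'
#' @param sample_ids Character vector of >= 4 sample IDs.
#' @param seed Integer seed.
#' @return A list of class `split_plan` with elements `group1`, `group2`,
#'   and `seed`.
#' @export
random_equal_split <- function(sample_ids, seed) {
  n <- length(sample_ids)
  if (n < 4L) abort("need at least 4 samples to form a within-group split")
  perm <- withr::with_seed(as.integer(seed), sample(sample_ids))
  k <- ceiling(n / 2)
  structure(list(group1 = perm[seq_len(k)], group2 = perm[seq(k + 1L, n)],
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Within-group mock-comparison false-positive rates
#'
#' Repeatedly splits the samples of a single condition into two random
#' halves, runs the full differential-expression route (normalize, NB Wald
#' test, BH adjustment) on each split, and counts genes called at
#' `padj <= fdr` and `|log2FC| >= c` for every cutoff `c` in the grid. All
#' such calls are false positives by construction, so the mean call count
#' divided by the number of genes tested is an empirical type-I error rate,
#' reported in percent.
#'
#' @param x Count tibble (raw integer counts). All-zero genes among the
#'   selected samples are removed before testing.
#' @param sample_ids Samples of the condition to split (>= 4).
#' @param route `"uq-pgq2"` or `"deseq-mor"`.
#' @param grid Ascending |log2FC| cutoff grid (default `c(1, 1.5, 2, 2.5, 3)`).
#' @param n_repeats Number of random splits (default 10).
#' @param fdr Adjusted-p threshold (default 0.05).
#' @param seed Master seed; per-repetition seeds are derived from it by a
#'   fixed counter scheme and recorded in the report.
#' @param scale_constant Passed to [uq_pgq2_normalize()].
#' @return A tibble of class `fpr_report` with columns `cutoff`, `mean_fp`,
#'   `sd_fp`, `fpr_percent`, and attributes `fp_counts` (repetition x cutoff
#'   matrix), `rep_seeds`, `splits`, `n_genes`, `n_repeats`, `route`,
#'   `fdr`, `seed`.
#' @export
within_group_fpr <- function(x, sample_ids, route = c("uq-pgq2", "deseq-mor"),
                             grid = c(1, 1.5, 2, 2.5, 3), n_repeats = 10,
                             fdr = 0.05, seed = 1L, scale_constant = 100) {
  route <- match.arg(route)
  if (length(grid) == 0 || is.unsorted(grid)) {
    abort("grid must be a non-empty ascending cutoff vector")
  }
  x <- validate_count_tbl(x)
  missing <- setdiff(sample_ids, sample_ids_of(x))
  if (length(missing) > 0) {
    abort(paste0("samples absent from count matrix: ",
                 paste(missing, collapse = ", ")))
  }
  x <- x[, c("gene_id", sample_ids)]
  x <- suppressMessages(filter_all_zero_genes(x))
  n_genes <- nrow(x)

  # normalization does not depend on the split, only the test labels do
  if (route == "uq-pgq2") {
    counts_for_test <- rounded_counts(
      uq_pgq2_normalize(x, scale_constant = scale_constant))
    sf <- rep(1, length(sample_ids))
  } else {
    counts_for_test <- x
    sf <- median_of_ratios_factors(x)
  }
  names(sf) <- sample_ids

  rep_seeds <- derive_seeds(seed, n_repeats)
  splits <- vector("list", n_repeats)
  fp <- matrix(NA_real_, n_repeats, length(grid),
               dimnames = list(NULL, paste0("cutoff_", grid)))
  for (r in seq_len(n_repeats)) {
    sp <- random_equal_split(sample_ids, rep_seeds[r])
    splits[[r]] <- sp
    groups <- ifelse(sample_ids %in% sp$group1, "half1", "half2")
    res <- tryCatch({
      disp <- estimate_dispersions(counts_for_test, groups, sf)
      nb_wald_two_group(counts_for_test, groups, test = "half2",
                        ref = "half1", size_factors = sf, dispersions = disp)
    }, error = function(e) {
      abort(paste0("within-group repetition ", r, " (seed ", rep_seeds[r],
                   ") failed: ", conditionMessage(e)))
    })
    sig <- !is.na(res$padj) & res$padj <= fdr
    fp[r, ] <- vapply(grid, function(cc) sum(sig & abs(res$log2fc) >= cc),
                      numeric(1))
  }
  out <- tibble::tibble(
    cutoff = grid,
    mean_fp = unname(colMeans(fp)),
    sd_fp = unname(apply(fp, 2, sd)),
    fpr_percent = unname(100 * colMeans(fp) / n_genes)
  )
  structure(out,
            class = c("fpr_report", class(out)),
            fp_counts = fp, rep_seeds = rep_seeds, splits = splits,
            n_genes = n_genes, n_repeats = n_repeats, route = route,
            fdr = fdr, seed = as.integer(seed))
}

#' @export
print.fpr_report <- function(x, ...) {
  cat("<fpr_report: route ", attr(x, "route"), ", ", attr(x, "n_genes"),
      " genes, ", attr(x, "n_repeats"), " repetitions, FDR <= ",
      attr(x, "fdr"), ", seed ", attr(x, "seed"), ">\n", sep = "")
  NextMethod()
}

#' @rdname within_group_fpr
#' @param x An `fpr_report`.
#' @param ... Unused.
#' @export
tidy.fpr_report <- function(x, ...) tibble::as_tibble(x)

#' @rdname within_group_fpr
#' @export
glance.fpr_report <- function(x, ...) {
  tibble::tibble(
    n_genes = attr(x, "n_genes"),
    n_repeats = attr(x, "n_repeats"),
    route = attr(x, "route"),
    fdr = attr(x, "fdr"),
    seed = attr(x, "seed")
  )
}

new_cutoff_selection <- function(cutoff, threshold, type) {
  structure(list(cutoff = cutoff, threshold = threshold, type = type,
                 satisfied = !is.na(cutoff)),
            class = "cutoff_selection")
}

#' @export
print.cutoff_selection <- function(x, ...) {
  cat("<cutoff_selection (", x$type, "): ",
      if (x$satisfied) paste0("|log2FC| >= ", x$cutoff) else "none qualifies",
      " at FPR <= ", x$threshold, "%>\n", sep = "")
  invisible(x)
}

#' Select the base |log2FC| cutoff from an FPR report
#'
#' The base cutoff is the smallest grid value whose observed FPR is at most
#' `fpr_threshold_percent` (the 0.05% working criterion).
#'
#' @param r An `fpr_report`.
#' @param fpr_threshold_percent FPR threshold in percent (default 0.05).
#' @return A `cutoff_selection`; `cutoff` is `NA` (with `satisfied = FALSE`)
#'   when no grid value qualifies.
#' @export
select_base_cutoff <- function(r, fpr_threshold_percent = 0.05) {
  stopifnot(inherits(r, "fpr_report"))
  ok <- which(r$fpr_percent <= fpr_threshold_percent)
  cutoff <- if (length(ok) > 0) r$cutoff[min(ok)] else NA_real_
  new_cutoff_selection(cutoff, fpr_threshold_percent, "base")
}

#' Select the maximum |log2FC| cutoff (FPR approximately zero)
#'
#' The maximum cutoff is the smallest grid value whose observed FPR is at
#' most `epsilon_percent`, operationalizing "FPR near zero". Genes unique to
#' one method qualify for the combined set only above this cutoff.
#'
#' @param r An `fpr_report`.
#' @param epsilon_percent Near-zero FPR threshold in percent (default
#'   0.005, about 1.7 expected false positives in 35,203 genes).
#' @return A `cutoff_selection`.
#' @export
select_max_cutoff <- function(r, epsilon_percent = 0.005) {
  stopifnot(inherits(r, "fpr_report"))
  ok <- which(r$fpr_percent <= epsilon_percent)
  cutoff <- if (length(ok) > 0) r$cutoff[min(ok)] else NA_real_
  new_cutoff_selection(cutoff, epsilon_percent, "max")
}
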