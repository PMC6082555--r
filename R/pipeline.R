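#' Run the within-group cutoff-selection stage for one condition
#'
#' Filters all-zero genes, runs the repeated mock-comparison procedure for
#' one condition's samples, and selects the base (FPR at most the working
#' threshold) and maximum (FPR near zero) |log2FC| cutoffs.
#'
#' @param x Count tibble (raw integer counts).
#' @param samples Sample sheet tibble.
#' @param group Condition label whose samples are split.
#' @param route `"uq-pgq2"` or `"deseq-mor"`.
#' @param grid,n_repeats,fdr,seed,scale_constant Passed to
#'   [within_group_fpr()].
#' @param fpr_threshold_percent Base-cutoff FPR threshold in percent.
#' @param epsilon_percent Max-cutoff near-zero FPR threshold in percent.
#' @return A list of class `within_group_run` with elements `report`
#'   (`fpr_report`), `base` and `max` (`cutoff_selection`s), and the call
#'   parameters.
#' @export
run_within_group <- function(x, samples, group,
                             route = c("uq-pgq2", "deseq-mor"),
                             grid = c(1, 1.5, 2, 2.5, 3), n_repeats = 10,
                             fdr = 0.05, seed = 1L, scale_constant = 100,
                             fpr_threshold_percent = 0.05,
                             epsilon_percent = 0.005) {
  route <- match.arg(route)
  samples <- validate_sample_sheet(samples)
  ids <- samples$sample_id[samples$group == group]
  if (length(ids) < 4L) {
    abort(paste0("condition '", group, "' has ", length(ids),
                 " samples; need >= 4 for a within-group split"))
  }
  report <- within_group_fpr(x, ids, route = route, grid = grid,
                             n_repeats = n_repeats, fdr = fdr, seed = seed,
                             scale_constant = scale_constant)
  structure(
    list(report = report,
         base = select_base_cutoff(report, fpr_threshold_percent),
         max = select_max_cutoff(report, epsilon_percent),
         group = group, route = route, seed = as.integer(seed)),
    class = "within_group_run"
  )
}

#' @export
print.within_group_run <- function(x, ...) {
  cat("<within_group_run: condition '", x$group, "', route ", x$route,
      ">\n", sep = "")
  print(x$base); print(x$max)
  invisible(x)
}

#' Run the between-group comparison with both routes and combine the calls
#'
#' Runs the UQ-pgQ2 and median-of-ratios routes on the same comparison,
#' calls DEGs at the per-route base cutoffs and the shared FDR, and applies
#' the combining rule with the per-route maximum cutoffs.
#'
#' @param x Count tibble (raw integer counts; all-zero genes are filtered).
#' @param samples Sample sheet tibble.
#' @param test_group,ref_group Condition labels (log2 fold change is test
#'   over reference).
#' @param base_cutoff_uq,base_cutoff_deseq Per-route calling cutoffs
#'   (typically from [run_within_group()]).
#' @param max_cutoff_uq,max_cutoff_deseq Per-route maximum cutoffs for
#'   method-unique genes.
#' @param fdr Shared FDR threshold (default 0.05).
#' @param scale_constant Passed to [uq_pgq2_normalize()].
#' @return A list of class `between_group_run` with `result_uq`,
#'   `result_deseq` (`deg_result`s), `call_uq`, `call_deseq` (`deg_call`s),
#'   and `combined` (`combined_deg_set`).
#' @export
run_between_group <- function(x, samples, test_group, ref_group,
                              base_cutoff_uq, base_cutoff_deseq,
                              max_cutoff_uq = base_cutoff_uq,
                              max_cutoff_deseq = base_cutoff_deseq,
                              fdr = 0.05, scale_constant = 100) {
  x <- suppressMessages(filter_all_zero_genes(validate_count_tbl(x)))
  res_uq <- deg_test(x, samples, test_group, ref_group, route = "uq-pgq2",
                     scale_constant = scale_constant)
  res_deseq <- deg_test(x, samples, test_group, ref_group,
                        route = "deseq-mor")
  call_uq <- call_degs(res_uq, fdr = fdr, lfc_cutoff = base_cutoff_uq)
  call_deseq <- call_degs(res_deseq, fdr = fdr, lfc_cutoff = base_cutoff_deseq)
  combined <- combine_true_degs(call_uq, call_deseq,
                                max_cutoff_uq = max_cutoff_uq,
                                max_cutoff_deseq = max_cutoff_deseq)
  structure(
    list(result_uq = res_uq, result_deseq = res_deseq,
         call_uq = call_uq, call_deseq = call_deseq, combined = combined,
         test_group = test_group, ref_group = ref_group, fdr = fdr),
    class = "between_group_run"
  )
}

#' @export
print.between_group_run <- function(x, ...) {
  cat("<between_group_run: ", x$test_group, " vs ", x$ref_group, " at FDR <= ",
      x$fdr, ">\n", sep = "")
  print(glance(x$combined))
  invisible(x)
}
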