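#' Combine the calls of two normalization routes into a true-DEG set
#'
#' Genes called by both routes ("common") are accepted outright. A gene
#' called by only one route is accepted only when that route's |log2 fold
#' change| is at least the route's maximum cutoff (the cutoff at which the
#' mock within-group FPR is approximately zero), inclusive. The result
#' carries per-gene provenance (`common`, `uq_only`, `deseq_only`) and the
#' statistics from each contributing route.
#'
#' @param call_uq,call_deseq `deg_call` objects from the UQ-pgQ2 and
#'   median-of-ratios routes, made at the same FDR over the same gene
#'   universe.
#' @param max_cutoff_uq,max_cutoff_deseq Maximum |log2FC| cutoffs for
#'   method-unique genes, one per route.
#' @return A tibble of class `combined_deg_set` with columns `gene_id`,
#'   `provenance`, `log2fc_uq`, `padj_uq`, `log2fc_deseq`, `padj_deseq`;
#'   component sizes and the cutoffs used are attached as attributes.
#' @export
combine_true_degs <- function(call_uq, call_deseq, max_cutoff_uq,
                              max_cutoff_deseq) {
  stopifnot(inherits(call_uq, "deg_call"), inherits(call_deseq, "deg_call"))
  if (!isTRUE(all.equal(attr(call_uq, "fdr"), attr(call_deseq, "fdr")))) {
    abort("both calls must be made at the same FDR")
  }
  res_uq <- attr(call_uq, "result")
  res_deseq <- attr(call_deseq, "result")
  if (!setequal(res_uq$gene_id, res_deseq$gene_id)) {
    abort(paste0("gene universes differ between routes: ",
                 length(setdiff(res_uq$gene_id, res_deseq$gene_id)),
                 " only in UQ-pgQ2, ",
                 length(setdiff(res_deseq$gene_id, res_uq$gene_id)),
                 " only in DESeq-MoR"))
  }
  set_uq <- call_uq$gene_id
  set_deseq <- call_deseq$gene_id
  common <- intersect(set_uq, set_deseq)
  uq_only <- setdiff(set_uq, set_deseq)
  uq_only <- uq_only[abs(call_uq$log2fc[match(uq_only, set_uq)]) >= max_cutoff_uq]
  deseq_only <- setdiff(set_deseq, set_uq)
  deseq_only <- deseq_only[
    abs(call_deseq$log2fc[match(deseq_only, set_deseq)]) >= max_cutoff_deseq]

  genes <- c(common, uq_only, deseq_only)
  provenance <- c(rep("common", length(common)),
                  rep("uq_only", length(uq_only)),
                  rep("deseq_only", length(deseq_only)))
  out <- tibble::tibble(
    gene_id = genes,
    provenance = provenance,
    log2fc_uq = res_uq$log2fc[match(genes, res_uq$gene_id)],
    padj_uq = res_uq$padj[match(genes, res_uq$gene_id)],
    log2fc_deseq = res_deseq$log2fc[match(genes, res_deseq$gene_id)],
    padj_deseq = res_deseq$padj[match(genes, res_deseq$gene_id)]
  )
  # provenance classes partition the set
  stopifnot(!anyDuplicated(out$gene_id),
            nrow(out) == length(common) + length(uq_only) + length(deseq_only))
  structure(out,
            class = c("combined_deg_set", class(out)),
            n_common = length(common), n_uq_only = length(uq_only),
            n_deseq_only = length(deseq_only),
            fdr = attr(call_uq, "fdr"),
            base_cutoff_uq = attr(call_uq, "lfc_cutoff"),
            base_cutoff_deseq = attr(call_deseq, "lfc_cutoff"),
            max_cutoff_uq = max_cutoff_uq,
            max_cutoff_deseq = max_cutoff_deseq)
}

#' @export
print.combined_deg_set <- function(x, ...) {
  cat("<combined_deg_set: ", nrow(x), " genes (", attr(x, "n_common"),
      " common + ", attr(x, "n_uq_only"), " UQ-pgQ2-only + ",
      attr(x, "n_deseq_only"), " DESeq-only)>\n", sep = "")
  NextMethod()
}

#' @rdname combine_true_degs
#' @param x A `combined_deg_set`.
#' @param ... Unused.
#' @export
glance.combined_deg_set <- function(x, ...) {
  tibble::tibble(
    n_total = nrow(x),
    n_common = attr(x, "n_common"),
    n_uq_only = attr(x, "n_uq_only"),
    n_deseq_only = attr(x, "n_deseq_only"),
    fdr = attr(x, "fdr"),
    max_cutoff_uq = attr(x, "max_cutoff_uq"),
    max_cutoff_deseq = attr(x, "max_cutoff_deseq")
  )
}

combined_lfc <- function(x) {
  ifelse(is.na(x$log2fc_uq), x$log2fc_deseq, x$log2fc_uq)
}

as_gene_ids <- function(x) {
  if (is.character(x)) x
  else if (is.data.frame(x) && "gene_id" %in% names(x)) x$gene_id
  else abort("expected a character vector or a tibble with a gene_id column")
}

#' Compare two subtype DEG sets
#'
#' Decomposes two gene sets (for example the combined true-DEG sets of two
#' disease subtypes) into the genes common to both and the genes unique to
#' each, with up/down counts per class when fold changes are available.
#'
#' @param a,b `combined_deg_set` objects, tibbles with a `gene_id` column,
#'   or plain character vectors of gene IDs.
#' @param labels Length-2 character vector naming the two sets.
#' @return A list of class `subtype_comparison` with `common`, `unique_a`,
#'   `unique_b` (character vectors), a `summary` tibble with per-class sizes
#'   and up/down counts (NA when no fold changes were supplied), and the
#'   labels.
#' @export
compare_subtype_sets <- function(a, b, labels = c("A", "B")) {
  ga <- as_gene_ids(a); gb <- as_gene_ids(b)
  common <- intersect(ga, gb)
  unique_a <- setdiff(ga, gb)
  unique_b <- setdiff(gb, ga)
  stopifnot(length(union(ga, gb)) ==
              length(common) + length(unique_a) + length(unique_b))
  updown <- function(set, src) {
    if (!inherits(src, "combined_deg_set")) return(c(NA_integer_, NA_integer_))
    lfc <- combined_lfc(src)[match(set, src$gene_id)]
    c(sum(lfc > 0), sum(lfc < 0))
  }
  ud_c_a <- updown(common, a)
  ud_a <- updown(unique_a, a)
  ud_b <- updown(unique_b, b)
  summary <- tibble::tibble(
    set = c("common", paste0("unique_", labels[1]), paste0("unique_", labels[2])),
    n = c(length(common), length(unique_a), length(unique_b)),
    n_up = c(ud_c_a[1], ud_a[1], ud_b[1]),
    n_down = c(ud_c_a[2], ud_a[2], ud_b[2])
  )
  structure(list(common = common, unique_a = unique_a, unique_b = unique_b,
                 summary = summary, labels = labels),
            class = "subtype_comparison")
}

#' @export
print.subtype_comparison <- function(x, ...) {
  cat("<subtype_comparison: ", x$labels[1], " vs ", x$labels[2], ">\n",
      sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname compare_subtype_sets
#' @param x A `subtype_comparison`.
#' @param ... Unused.
#' @export
tidy.subtype_comparison <- function(x, ...) {
  tibble::tibble(
    gene_id = c(x$common, x$unique_a, x$unique_b),
    set = c(rep("common", length(x$common)),
            rep(paste0("unique_", x$labels[1]), length(x$unique_a)),
            rep(paste0("unique_", x$labels[2]), length(x$unique_b)))
  )
}

#' Count up- and down-regulated genes in a called set
#'
#' @param s A tibble with columns `gene_id` and `log2fc` (for example a
#'   `deg_call`), or a `combined_deg_set`.
#' @return A tibble with `n_up`, `n_down`, and `n_total`. Errors if any gene
#'   has a log2 fold change of exactly zero, which cannot occur in a valid
#'   call made at a positive cutoff.
#' @export
summarize_direction <- function(s) {
  lfc <- if (inherits(s, "combined_deg_set")) combined_lfc(s)
         else if (is.data.frame(s) && "log2fc" %in% names(s)) s$log2fc
         else abort("expected a tibble with a log2fc column")
  if (any(lfc == 0)) abort("gene with log2fc == 0 present; not a valid call set")
  tibble::tibble(n_up = sum(lfc > 0), n_down = sum(lfc < 0),
                 n_total = length(lfc))
}

#' Look up candidate biomarker genes across both routes
#'
#' @param result_uq,result_deseq `deg_result` tibbles from the two routes.
#' @param genes Character vector of gene IDs (for example gene symbols used
#'   as matrix row IDs).
#' @param call_uq,call_deseq Optional `deg_call` objects; when supplied a
#'   `called` flag per route is included.
#' @return A tibble with one row per requested gene and route: `gene_id`,
#'   `route`, `log2fc`, `padj`, `called`, `absent`. Genes absent from the
#'   tested universe are flagged, not dropped.
#' @export
biomarker_report <- function(result_uq, result_deseq, genes,
                             call_uq = NULL, call_deseq = NULL) {
  if (length(genes) == 0) {
    return(tibble::tibble(gene_id = character(), route = character(),
                          log2fc = numeric(), padj = numeric(),
                          called = logical(), absent = logical()))
  }
  one_route <- function(res, call, route) {
    i <- match(genes, res$gene_id)
    tibble::tibble(
      gene_id = genes,
      route = route,
      log2fc = res$log2fc[i],
      padj = res$padj[i],
      called = if (is.null(call)) NA else genes %in% call$gene_id & !is.na(i),
      absent = is.na(i)
    )
  }
  dplyr::bind_rows(one_route(result_uq, call_uq, "uq-pgq2"),
                   one_route(result_deseq, call_deseq, "deseq-mor")) %>%
    dplyr::arrange(.data$gene_id, .data$route)
}
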