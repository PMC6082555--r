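#' Read a gene-by-sample count matrix from TSV
#'
#' Reads a tab-separated count table whose header row carries sample IDs and
#' whose first column carries gene IDs, validating that every cell is a
#' non-negative integer and that gene and sample IDs are unique.
#'
#' @param path Path to a TSV file. The first column holds gene IDs; remaining
#'   columns hold raw integer read counts, one column per sample.
#' @param strip_gene_version If `TRUE`, a trailing Ensembl-style version
#'   suffix (`".N"`) is removed from gene IDs. Off by default so that distinct
#'   versioned IDs can never silently collide.
#' @return A tibble with a character `gene_id` column followed by one integer
#'   column per sample, in file order.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t0\t5"), tf)
#' read_count_matrix(tf)
read_count_matrix <- function(path, strip_gene_version = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2L) abort("count matrix must have a gene-ID column plus >= 1 sample")
  names(raw)[1] <- "gene_id"
  for (j in seq(2L, ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !is.na(raw[[j]]))
    if (length(bad) > 0) {
      abort(paste0("cannot parse count for gene '", raw$gene_id[bad[1]],
                   "', sample '", names(raw)[j], "': '", raw[[j]][bad[1]], "'"))
    }
    raw[[j]] <- v
  }
  if (strip_gene_version) raw$gene_id <- sub("\\.\\d+$", "", raw$gene_id)
  x <- validate_count_tbl(raw)
  for (j in seq(2L, ncol(x))) x[[j]] <- as.integer(x[[j]])
  x
}

#' Write a count matrix to TSV
#'
#' @param x A count tibble (`gene_id` column plus sample columns).
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  x <- validate_count_tbl(x, integral = FALSE)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

#' Assemble a count matrix from htseq-count output files
#'
#' Each input file is the two-column (gene ID, count) output of
#' `htseq-count`. Summary rows whose gene ID starts with `"__"` (such as
#' `__no_feature` or `__ambiguous`) are dropped. All files must share the
#' same gene universe.
#'
#' @param paths Character vector of file paths, one per sample.
#' @param sample_ids Sample IDs in the same order as `paths`; defaults to the
#'   file basenames without extension.
#' @return A count tibble with genes in the order of the first file.
#' @export
read_htseq_counts <- function(paths, sample_ids = NULL) {
  if (length(paths) < 1L) abort("need at least one htseq-count file")
  if (is.null(sample_ids)) {
    sample_ids <- sub("\\.[^.]*$", "", basename(paths))
  }
  if (length(sample_ids) != length(paths)) {
    abort("sample_ids must match paths in length")
  }
  tabs <- lapply(paths, function(p) {
    tb <- readr::read_tsv(p, col_names = c("gene_id", "count"),
                          col_types = "cd", progress = FALSE)
    tb[!startsWith(tb$gene_id, "__"), ]
  })
  ref <- tabs[[1]]$gene_id
  for (i in seq_along(tabs)) {
    g <- tabs[[i]]$gene_id
    diff_n <- length(setdiff(ref, g)) + length(setdiff(g, ref))
    if (diff_n > 0) {
      abort(paste0("gene universes differ between '", paths[1], "' and '",
                   paths[i], "': symmetric difference of ", diff_n, " IDs"))
    }
  }
  out <- tibble::tibble(gene_id = ref)
  for (i in seq_along(tabs)) {
    out[[sample_ids[i]]] <- tabs[[i]]$count[match(ref, tabs[[i]]$gene_id)]
  }
  x <- validate_count_tbl(out)
  for (j in seq(2L, ncol(x))) x[[j]] <- as.integer(x[[j]])
  x
}

#' Read a sample sheet (sample-to-condition assignment)
#'
#' @param path CSV file with header `sample_id,group`.
#' @return A tibble with character columns `sample_id` and `group`.
#' @export
read_sample_sheet <- function(path) {
  s <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  validate_sample_sheet(s)
}

#' Read a gene-ID list from a plain-text file
#'
#' One ID per line; blank lines and `#` comments are ignored.
#'
#' @param path Text file path.
#' @return Character vector of gene IDs.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' Remove genes with zero counts in every sample
#'
#' Mirrors the standard pre-filter applied jointly across all loaded samples:
#' a gene is removed only when its count is zero in every column.
#'
#' @param x A count tibble.
#' @return The filtered tibble. The number of removed genes is attached as
#'   attribute `n_removed` and reported with a message.
#' @export
filter_all_zero_genes <- function(x) {
  x <- validate_count_tbl(x, integral = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  keep <- rowSums(m) > 0
  out <- x[keep, , drop = FALSE]
  n_removed <- sum(!keep)
  if (nrow(out) == 0L) warn("all genes have zero counts across all samples")
  inform(paste0("filter_all_zero_genes: removed ", n_removed, " of ",
                nrow(x), " genes"))
  attr(out, "n_removed") <- n_removed
  out
}

#' Restrict a count matrix to a gene-ID subset
#'
#' Typical use: restricting to protein-coding genes via a pre-made ID list.
#' Genes are kept in their original matrix order.
#'
#' @param x A count tibble.
#' @param keep Character vector of gene IDs to retain.
#' @return The subset tibble; the number of `keep` IDs absent from `x` is
#'   attached as attribute `n_absent` and reported with a message.
#' @export
subset_genes <- function(x, keep) {
  x <- validate_count_tbl(x, integral = FALSE)
  keep <- unique(as.character(keep))
  sel <- x$gene_id %in% keep
  if (!any(sel)) abort("no genes in common between the matrix and the keep list")
  n_absent <- sum(!(keep %in% x$gene_id))
  out <- x[sel, , drop = FALSE]
  inform(paste0("subset_genes: kept ", nrow(out), " genes; ", n_absent,
                " requested IDs absent from the matrix"))
  attr(out, "n_absent") <- n_absent
  out
}
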