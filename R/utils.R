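# Internal helpers shared across modules.

# Derive per-repetition RNG seeds from a master seed with a fixed counter
# scheme; kept below 2^31 - 1 so they remain valid R integers.
derive_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  s <- (as.double(seed) + 1009 * seq_len(n)) %% 2147483647
  as.integer(s)
}

geometric_mean <- function(x) exp(mean(log(x)))

# Extract the numeric count matrix (genes x samples, gene IDs as rownames)
# from a count tibble whose first column holds gene IDs.
counts_to_matrix <- function(x) {
  x <- validate_count_tbl(x)
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x[[1]]
  m
}

matrix_to_counts <- function(m) {
  tibble::as_tibble(as.data.frame(m), rownames = "gene_id")
}

sample_ids_of <- function(x) names(x)[-1]

# Validate the count-tibble contract: first column character gene IDs with no
# duplicates, remaining columns non-negative integral numerics with unique
# names. Returns the tibble with the first column named gene_id.
validate_count_tbl <- function(x, integral = TRUE) {
  if (!is.data.frame(x) || ncol(x) < 2L) {
    abort("expected a data frame with a gene-ID column followed by >= 1 sample column")
  }
  x <- tibble::as_tibble(x)
  names(x)[1] <- "gene_id"
  ids <- as.character(x$gene_id)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate gene IDs: ", paste(utils::head(dup, 5), collapse = ", ")))
  }
  sdup <- unique(names(x)[-1][duplicated(names(x)[-1])])
  if (length(sdup) > 0) {
    abort(paste0("duplicate sample IDs: ", paste(sdup, collapse = ", ")))
  }
  for (j in seq(2L, ncol(x))) {
    v <- x[[j]]
    if (!is.numeric(v)) {
      abort(paste0("non-numeric counts in sample '", names(x)[j], "'"))
    }
    bad <- which(!is.finite(v) | v < 0 | (integral & v != floor(v)))
    if (length(bad) > 0) {
      abort(paste0(
        "invalid count for gene '", ids[bad[1]], "', sample '", names(x)[j],
        "': ", v[bad[1]], " (counts must be non-negative integers)"
      ))
    }
  }
  x$gene_id <- ids
  x
}

validate_sample_sheet <- function(samples) {
  if (!is.data.frame(samples) || !all(c("sample_id", "group") %in% names(samples))) {
    abort("sample sheet must have columns 'sample_id' and 'group'")
  }
  samples <- tibble::as_tibble(samples)
  dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate sample IDs in sample sheet: ", paste(dup, collapse = ", ")))
  }
  samples
}
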