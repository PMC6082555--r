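#' Simulate negative-binomial RNA-seq counts
#'
#' Generates a gene-by-sample integer count matrix from the model
#' `x_gj ~ NB(mean = s_j * mu_g * 2^(beta_g * I[j in group 2]),
#' dispersion alpha_g)`, together with a per-gene truth table. Baseline
#' means are log-normal; dispersions follow either a constant or an
#' `a0 + a1/mu` trend; library-size factors are drawn uniformly from a
#' range (or supplied); a configurable fraction of genes is differentially
#' expressed with log2 effects drawn from a discrete magnitude set; and a
#' minority of "contaminant" genes mimics residual high-abundance species
#' (for example rRNA escaping depletion) via inflated means and dispersions.
#'
#' @param n_genes Number of genes.
#' @param n1,n2 Samples in group 1 / group 2. `n2 = 0` yields a
#'   single-condition matrix (useful for within-group null studies).
#' @param meanlog,sdlog Parameters of the log-normal baseline mean
#'   distribution (defaults 4 and 2, spanning low-count to very high-count
#'   genes).
#' @param dispersion Either a single constant dispersion, or a length-2
#'   numeric `c(a0, a1)` describing the trend `alpha(mu) = a0 + a1/mu`.
#' @param size_factor_range Length-2 range for uniform library-size factors.
#' @param size_factors Optional explicit per-sample size factors (overrides
#'   the range).
#' @param de_fraction Fraction of genes differentially expressed, in
#'   `[0, 1)`; the realized count is exactly `round(de_fraction * n_genes)`.
#' @param lfc_magnitudes Discrete set of |log2FC| magnitudes for DE genes.
#' @param de_up_fraction Fraction of DE genes that are up-regulated.
#' @param skew_fraction Fraction of contaminant genes (default 1%).
#' @param skew_mean_multiplier,skew_disp_multiplier Mean and dispersion
#'   inflation for contaminant genes (defaults 50 and 4).
#' @param seed Integer seed; the output is a deterministic function of it.
#' @return A list of class `sim_counts`: `counts` (count tibble), `truth`
#'   (tibble `gene_id`, `true_log2fc`, `is_contaminant`), `samples` (sample
#'   sheet with groups `"g1"`/`"g2"`), `size_factors`, `dispersions`, and
#'   the call parameters in `config`.
#' @export
simulate_counts <- function(n_genes = 20000, n1 = 21, n2 = 21,
                            meanlog = 4, sdlog = 2,
                            dispersion = c(0.05, 5),
                            size_factor_range = c(0.5, 2),
                            size_factors = NULL,
                            de_fraction = 0,
                            lfc_magnitudes = c(1.5, 2, 3),
                            de_up_fraction = 0.5,
                            skew_fraction = 0.01,
                            skew_mean_multiplier = 50,
                            skew_disp_multiplier = 4,
                            seed = 1L) {
  stopifnot(n_genes >= 1, n1 >= 1, n2 >= 0,
            de_fraction >= 0, de_fraction < 1,
            skew_fraction >= 0, skew_fraction < 1,
            length(dispersion) %in% c(1L, 2L), all(dispersion >= 0),
            skew_mean_multiplier > 0, skew_disp_multiplier > 0)
  if (de_fraction > 0 && n2 == 0) {
    abort("differential expression requires two groups (n2 > 0)")
  }
  n <- n1 + n2
  withr::with_seed(as.integer(seed), {
    mu <- exp(stats::rnorm(n_genes, meanlog, sdlog))
    contaminant <- rep(FALSE, n_genes)
    n_skew <- round(skew_fraction * n_genes)
    if (n_skew > 0) contaminant[sample.int(n_genes, n_skew)] <- TRUE
    mu[contaminant] <- mu[contaminant] * skew_mean_multiplier

    alpha <- if (length(dispersion) == 1L) rep(dispersion, n_genes)
             else dispersion[1] + dispersion[2] / mu
    alpha[contaminant] <- alpha[contaminant] * skew_disp_multiplier

    beta <- rep(0, n_genes)
    n_de <- round(de_fraction * n_genes)
    if (n_de > 0) {
      de_idx <- sample.int(n_genes, n_de)
      mag <- lfc_magnitudes[sample.int(length(lfc_magnitudes), n_de,
                                       replace = TRUE)]
      n_up <- round(de_up_fraction * n_de)
      sign_vec <- sample(c(rep(1, n_up), rep(-1, n_de - n_up)))
      beta[de_idx] <- mag * sign_vec
    }

    if (is.null(size_factors)) {
      size_factors <- runif(n, size_factor_range[1], size_factor_range[2])
    }
    stopifnot(length(size_factors) == n, all(size_factors > 0))

    group2 <- c(rep(FALSE, n1), rep(TRUE, n2))
    counts <- matrix(0L, n_genes, n)
    for (j in seq_len(n)) {
      mu_j <- size_factors[j] * mu * (if (group2[j]) 2^beta else 1)
      pois <- alpha == 0
      cj <- integer(n_genes)
      if (any(pois)) cj[pois] <- rpois(sum(pois), mu_j[pois])
      if (any(!pois)) {
        cj[!pois] <- rnbinom(sum(!pois), mu = mu_j[!pois],
                             size = 1 / alpha[!pois])
      }
      counts[, j] <- cj
    }
  })
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  sample_ids <- sprintf("sample%03d", seq_len(n))
  rownames(counts) <- gene_ids
  colnames(counts) <- sample_ids
  ctbl <- matrix_to_counts(counts)
  for (j in seq(2L, ncol(ctbl))) ctbl[[j]] <- as.integer(ctbl[[j]])
  structure(
    list(
      counts = ctbl,
      truth = tibble::tibble(gene_id = gene_ids, true_log2fc = beta,
                             is_contaminant = contaminant),
      samples = tibble::tibble(
        sample_id = sample_ids,
        group = c(rep("g1", n1), rep("g2", n2))
      ),
      size_factors = stats::setNames(size_factors, sample_ids),
      dispersions = alpha,
      config = list(n_genes = n_genes, n1 = n1, n2 = n2, meanlog = meanlog,
                    sdlog = sdlog, dispersion = dispersion,
                    size_factor_range = size_factor_range,
                    de_fraction = de_fraction,
                    lfc_magnitudes = lfc_magnitudes,
                    de_up_fraction = de_up_fraction,
                    skew_fraction = skew_fraction,
                    skew_mean_multiplier = skew_mean_multiplier,
                    skew_disp_multiplier = skew_disp_multiplier,
                    seed = as.integer(seed))
    ),
    class = "sim_counts"
  )
}

#' @export
print.sim_counts <- function(x, ...) {
  cfg <- x$config
  cat("<sim_counts: ", cfg$n_genes, " genes x ", cfg$n1 + cfg$n2,
      " samples (", cfg$n1, " + ", cfg$n2, "); ",
      sum(x$truth$true_log2fc != 0), " DE genes, ",
      sum(x$truth$is_contaminant), " contaminant genes; seed ", cfg$seed,
      ">\n", sep = "")
  invisible(x)
}
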