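# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force Benjamini-Hochberg step-up straight from its definition:
# padj_(i) = min over k >= i of m * p_(k) / k, capped at 1.
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Per-gene NB likelihood optimizer for the two-group model with unit size
# factors and a fixed dispersion: maximizes the joint log-likelihood over
# (log mu_ref, log mu_test) numerically and derives the log2FC standard
# error from the numerical Hessian.
nb_mle_oracle <- function(x_ref, x_test, alpha) {
  negll <- function(eta) {
    mu1 <- exp(eta[1]); mu2 <- exp(eta[2])
    -(sum(dnbinom(x_ref, mu = mu1, size = 1 / alpha, log = TRUE)) +
        sum(dnbinom(x_test, mu = mu2, size = 1 / alpha, log = TRUE)))
  }
  start <- log(c(max(mean(x_ref), 0.5), max(mean(x_test), 0.5)))
  fit <- optim(start, negll, method = "BFGS", hessian = TRUE,
               control = list(reltol = 1e-14, maxit = 500))
  a <- c(-1, 1) / log(2)                       # log2fc = (eta2 - eta1)/ln 2
  vcv <- solve(fit$hessian)
  list(log2fc = (fit$par[2] - fit$par[1]) / log(2),
       lfc_se = sqrt(drop(t(a) %*% vcv %*% a)))
}

# Tiny count tibble used by several parse/filter tests.
tiny_counts <- function() {
  tibble::tibble(gene_id = c("gA", "gB", "gC"),
                 s1 = c(1L, 0L, 7L), s2 = c(2L, 5L, 7L))
}

# Construct a minimal deg_result-shaped object from bare statistics, for
# tests of the calling and combining rules that do not need a real fit.
new_test_result <- function(log2fc, padj,
                            gene_id = paste0("g", seq_along(log2fc))) {
  tbl <- tibble::tibble(
    gene_id = gene_id,
    base_mean = rep(100, length(log2fc)),
    log2fc = log2fc,
    lfc_se = rep(0.1, length(log2fc)),
    wald_stat = log2fc / 0.1,
    pvalue = padj,
    padj = padj,
    flagged = FALSE
  )
  structure(tbl, class = c("deg_result", class(tbl)),
            method = "synthetic", test = "t", ref = "r")
}
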