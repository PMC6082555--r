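# Negative-binomial dispersion estimation for the two-group design:
# gene-wise Cox-Reid-adjusted MLE, an a0 + a1/mu mean-dispersion trend, and
# log-normal shrinkage of the gene-wise estimates toward the trend.

DISP_FLOOR <- 1e-8
PRIOR_SD_FLOOR <- 0.25

# Vectorized golden-section maximization over a scalar parameter per gene.
# f takes a vector theta (one value per gene) and returns the per-gene
# objective. lower/upper are vectors or scalars.
golden_max <- function(f, lower, upper, n, tol = 1e-6, maxit = 80) {
  invphi <- (sqrt(5) - 1) / 2
  a <- rep_len(lower, n); b <- rep_len(upper, n)
  c_ <- b - invphi * (b - a)
  d_ <- a + invphi * (b - a)
  fc <- f(c_); fd <- f(d_)
  for (it in seq_len(maxit)) {
    if (max(b - a) < tol) break
    m <- fc < fd            # maximum lies in [c_, b]
    a[m] <- c_[m]; c_[m] <- d_[m]; fc[m] <- fd[m]
    b[!m] <- d_[!m]; d_[!m] <- c_[!m]; fd[!m] <- fc[!m]
    d_new <- a + invphi * (b - a)
    c_new <- b - invphi * (b - a)
    probe <- ifelse(m, d_new, c_new)
    fp <- f(probe)
    d_[m] <- d_new[m]; fd[m] <- fp[m]
    c_[!m] <- c_new[!m]; fc[!m] <- fp[!m]
  }
  (a + b) / 2
}

# Cox-Reid-adjusted NB profile log-likelihood in alpha for fixed fitted
# means mu (genes x samples). Terms constant in alpha are dropped.
make_cr_loglik <- function(counts, mu, group_idx) {
  n <- ncol(counts)
  function(log_alpha) {
    alpha <- exp(log_alpha)
    r <- 1 / alpha
    rmu <- r + mu                       # recycles r over rows
    ll <- rowSums(lgamma(counts + r) - (counts + r) * log(rmu)) -
      n * lgamma(r) + n * r * log(r)
    w <- mu / (1 + alpha * mu)
    cr <- 0
    for (idx in group_idx) cr <- cr + log(rowSums(w[, idx, drop = FALSE]))
    ll - 0.5 * cr
  }
}

# Closed-form fitted means for the two-group NB model: group mean =
# sum(counts) / sum(size factors), floored for all-zero groups.
fitted_means <- function(counts, groups, size_factors) {
  lv <- levels(groups)
  floor_mu <- 0.5 / median(size_factors)
  mu_hat <- sapply(lv, function(g) {
    idx <- which(groups == g)
    rowSums(counts[, idx, drop = FALSE]) / sum(size_factors[idx])
  })
  flagged <- rowSums(mu_hat == 0) > 0
  mu_hat[mu_hat == 0] <- floor_mu
  mu <- matrix(0, nrow(counts), ncol(counts))
  for (g in lv) {
    idx <- which(groups == g)
    mu[, idx] <- outer(mu_hat[, g], size_factors[idx])
  }
  list(mu = mu, mu_hat = mu_hat, flagged = flagged, floor_mu = floor_mu)
}

# Weighted least squares for alpha ~ a0 + a1/mu with gamma-style weights
# 1/fitted^2, coefficients clamped to be non-negative.
fit_trend_irls <- function(alpha, basemean, n_iter = 10) {
  x2 <- 1 / basemean
  fit_wls <- function(w) {
    X <- cbind(1, x2)
    XtW <- t(X * w)
    beta <- tryCatch(solve(XtW %*% X, XtW %*% alpha),
                     error = function(e) NULL)
    if (is.null(beta)) return(c(stats::weighted.mean(alpha, w), 0))
    beta <- pmax(as.numeric(beta), 0)
    if (sum(beta) == 0) beta[1] <- stats::weighted.mean(alpha, w)
    beta
  }
  beta <- fit_wls(rep(1, length(alpha)))
  for (i in seq_len(n_iter)) {
    fitted <- pmax(beta[1] + beta[2] * x2, 1e-10)
    beta <- fit_wls(1 / fitted^2)
  }
  beta
}

#' Estimate negative-binomial dispersions for a two-group comparison
#'
#' Three-step scheme: (1) a gene-wise dispersion by Cox-Reid-adjusted maximum
#' likelihood with closed-form two-group fitted means (method-of-moments
#' estimates seed the search bracket); (2) a mean-dispersion trend
#' `alpha(mu) = a0 + a1/mu` fitted by iteratively reweighted least squares
#' over genes with gene-wise dispersion above the floor, with one
#' outlier-trim pass (log residuals beyond 2 MAD excluded, then refit);
#' (3) a maximum a posteriori dispersion per gene combining the CR-adjusted
#' likelihood with a log-normal prior centered on the trend, its standard
#' deviation estimated from the MAD of the log residuals (floored at 0.25).
#'
#' @param counts Count tibble or numeric matrix (genes x samples) of
#'   integers.
#' @param groups Two-level factor (or character vector) of length equal to
#'   the number of samples; each level needs >= 2 samples.
#' @param size_factors Optional positive per-sample size factors (default
#'   all 1, appropriate for pre-normalized rounded counts).
#' @return An object of class `dispersion_model`: list with `genes` (tibble
#'   `gene_id`, `base_mean`, `disp_raw`, `disp_trend`, `disp_map`,
#'   `trend_used`), `trend` (`a0`, `a1`), `sigma_prior`, and
#'   `trend_fallback` (`TRUE` when too few genes supported a trend fit and a
#'   constant median trend was used).
#' @export
estimate_dispersions <- function(counts, groups, size_factors = NULL) {
  m <- if (is.data.frame(counts)) counts_to_matrix(counts) else {
    stopifnot(is.matrix(counts)); counts
  }
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) abort("groups must have exactly two levels")
  if (any(table(groups) < 2L)) abort("each group needs at least 2 samples")
  if (length(groups) != ncol(m)) abort("groups length must equal sample count")
  if (is.null(size_factors)) size_factors <- rep(1, ncol(m))
  stopifnot(all(size_factors > 0), length(size_factors) == ncol(m))

  norm <- sweep(m, 2, size_factors, "/")
  base_mean <- rowMeans(norm)
  g1 <- which(groups == levels(groups)[1])
  g2 <- which(groups == levels(groups)[2])

  # method-of-moments start on normalized counts, within-group moments
  mu1 <- rowMeans(norm[, g1, drop = FALSE]); mu2 <- rowMeans(norm[, g2, drop = FALSE])
  v1 <- apply(norm[, g1, drop = FALSE], 1, var)
  v2 <- apply(norm[, g2, drop = FALSE], 1, var)
  n1 <- length(g1); n2 <- length(g2)
  v_pool <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mu_pool <- pmax(base_mean, 1e-8)
  mom <- pmax(0, (v_pool - mu_pool) / mu_pool^2)

  fm <- fitted_means(m, groups, size_factors)
  loglik <- make_cr_loglik(m, fm$mu, list(g1, g2))

  ng <- nrow(m)
  lower <- rep(log(DISP_FLOOR), ng)
  upper <- log(pmax(50, 10 * mom))
  disp_raw <- exp(golden_max(loglik, lower, upper, ng))
  disp_raw <- pmax(disp_raw, DISP_FLOOR)

  usable <- disp_raw > DISP_FLOOR * 1.0001 & base_mean > 0
  trend_fallback <- sum(usable) < 10
  if (trend_fallback) {
    med <- if (any(usable)) median(disp_raw[usable]) else DISP_FLOOR
    warn("fewer than 10 genes usable for the dispersion trend; using a constant median trend")
    a0 <- med; a1 <- 0
    used <- usable
  } else {
    beta <- fit_trend_irls(disp_raw[usable], base_mean[usable])
    fitted <- pmax(beta[1] + beta[2] / base_mean[usable], 1e-10)
    logres <- log(disp_raw[usable] / fitted)
    keep <- abs(logres) <= 2 * mad(logres)
    if (sum(keep) >= 10) {
      beta <- fit_trend_irls(disp_raw[usable][keep], base_mean[usable][keep])
    }
    a0 <- beta[1]; a1 <- beta[2]
    used <- usable
  }
  disp_trend <- pmax(a0 + a1 / pmax(base_mean, 1e-8), DISP_FLOOR)

  logres_all <- log(disp_raw[used] / disp_trend[used])
  sigma_prior <- max(PRIOR_SD_FLOOR,
                     if (length(logres_all) > 1) mad(logres_all) else 0)

  log_trend <- log(disp_trend)
  post <- function(log_alpha) {
    loglik(log_alpha) - (log_alpha - log_trend)^2 / (2 * sigma_prior^2)
  }
  disp_map <- exp(golden_max(post, rep(log(DISP_FLOOR), ng),
                             pmax(log(100), log_trend + 4 * sigma_prior), ng))
  disp_map <- pmax(disp_map, DISP_FLOOR)

  structure(
    list(
      genes = tibble::tibble(
        gene_id = rownames(m) %||% paste0("gene", seq_len(ng)),
        base_mean = base_mean,
        disp_raw = disp_raw,
        disp_trend = disp_trend,
        disp_map = disp_map,
        trend_used = used
      ),
      trend = c(a0 = a0, a1 = a1),
      sigma_prior = sigma_prior,
      trend_fallback = trend_fallback
    ),
    class = "dispersion_model"
  )
}

#' @export
print.dispersion_model <- function(x, ...) {
  cat("<dispersion_model: ", nrow(x$genes), " genes; trend a0 = ",
      signif(x$trend["a0"], 4), ", a1 = ", signif(x$trend["a1"], 4),
      "; prior log-sd = ", signif(x$sigma_prior, 4), ">\n", sep = "")
  invisible(x)
}

#' @rdname estimate_dispersions
#' @param x A `dispersion_model`.
#' @param ... Unused.
#' @export
tidy.dispersion_model <- function(x, ...) x$genes

#' @rdname estimate_dispersions
#' @export
glance.dispersion_model <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$genes),
    a0 = unname(x$trend["a0"]),
    a1 = unname(x$trend["a1"]),
    sigma_prior = x$sigma_prior,
    trend_fallback = x$trend_fallback,
    median_disp_map = median(x$genes$disp_map)
  )
}
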