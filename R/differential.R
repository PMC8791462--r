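#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median ratio of each
#' sample's counts to the per-feature geometric mean across samples, the
#' standard approach for negative-binomial count models. Features containing
#' a zero in any sample are excluded from the reference.
#'
#' @param counts Raw count matrix, features x samples.
#' @return Named numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- check_count_matrix(counts)
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use)) {
    stop("no feature has nonzero counts in every sample; cannot compute size factors")
  }
  apply(counts, 2, function(col) {
    exp(stats::median(log(col[use]) - log_geo[use]))
  })
}

#' Negative-binomial Wald test for differential HERV expression
#'
#' Two-group differential expression for tumor versus peritumoral (or any
#' two-class) comparisons. Counts are modeled as NB with a log link and a
#' per-feature dispersion `alpha` (Var = mu + alpha * mu^2). Size factors are
#' median-of-ratios, dispersion is a pooled within-group method-of-moments
#' estimate floored at `dispersion_floor`, coefficients are fit by iteratively
#' reweighted least squares, and the group coefficient is tested with a Wald
#' z statistic. Fold changes are optionally shrunk toward zero with a normal
#' prior whose scale is estimated from the spread of the MLE coefficients
#' (an empirical-Bayes posterior-mode shrinkage); p-values always refer to
#' the unshrunken estimate.
#'
#' @param counts Raw count matrix, features x samples.
#' @param group Factor (or coercible) of length `ncol(counts)` with exactly
#'   two levels; the **first** level is the reference (e.g. peritumoral), so
#'   positive log2 fold changes mean higher expression in the second level
#'   (tumor).
#' @param shrink Shrink reported `log2fc` toward zero (default `TRUE`);
#'   the unshrunken estimate is kept in `log2fc_mle`.
#' @param dispersion_floor Lower bound for the dispersion estimate.
#' @param comparison Optional label (e.g. cancer type) stored on every row.
#' @return A `data.frame` with one row per feature: `herv_id`, `baseMean`
#'   (mean of size-factor-normalized counts), `log2fc`, `fc` (= 2^log2fc),
#'   `log2fc_mle`, `se`, `pvalue`, `padj` (Benjamini-Hochberg across features
#'   with `baseMean > 0`), `comparison`. All-zero features get NA statistics.
#' @export
nb_differential <- function(counts, group, shrink = TRUE,
                            dispersion_floor = 1e-8, comparison = NA_character_) {
  counts <- check_count_matrix(counts)
  group <- as.factor(group)
  if (length(group) != ncol(counts)) {
    stop("group must have one label per sample")
  }
  if (nlevels(droplevels(group)) != 2L) stop("exactly two groups are required")
  group <- droplevels(group)
  if (any(table(group) < 2L)) stop("each group needs at least 2 samples")

  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(norm)
  x <- as.numeric(group == levels(group)[2L])

  ok <- base_mean > 0
  alpha <- rep(NA_real_, nrow(counts))
  alpha[ok] <- mom_dispersion(norm[ok, , drop = FALSE], group, sf,
                              floor = dispersion_floor)

  fit <- nb_irls_two_group(counts[ok, , drop = FALSE], x, log(sf), alpha[ok])

  beta <- se <- rep(NA_real_, nrow(counts))
  beta[ok] <- fit$beta1
  se[ok] <- fit$se1
  z <- beta / se
  pvalue <- 2 * stats::pnorm(-abs(z))
  padj <- rep(NA_real_, nrow(counts))
  padj[ok] <- bh_adjust(pvalue[ok])

  log2fc_mle <- beta / log(2)
  log2fc <- if (shrink) shrink_normal_prior(beta, se) / log(2) else log2fc_mle

  data.frame(
    herv_id = rownames(counts),
    baseMean = base_mean,
    log2fc = log2fc,
    fc = 2^log2fc,
    log2fc_mle = log2fc_mle,
    se = se / log(2),
    pvalue = pvalue,
    padj = padj,
    comparison = comparison,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

# Pooled within-group method-of-moments dispersion on normalized counts.
# E[s2_g] ~ mu_g * mean(1/sf) + alpha * mu_g^2, solved for alpha and pooled
# across groups by (n_g - 1) weights, then floored.
mom_dispersion <- function(norm, group, sf, floor = 1e-8) {
  num <- 0
  den <- 0
  for (g in levels(group)) {
    idx <- group == g
    n_g <- sum(idx)
    if (n_g < 2L) next
    m <- rowMeans(norm[, idx, drop = FALSE])
    v <- apply(norm[, idx, drop = FALSE], 1, stats::var)
    inv_sf <- mean(1 / sf[idx])
    num <- num + (n_g - 1) * (v - m * inv_sf)
    den <- den + (n_g - 1) * m^2
  }
  pmax(num / pmax(den, .Machine$double.eps), floor)
}

# Vectorized IRLS for the two-group NB GLM with log link and offset log(sf).
# Y: features x samples, x: 0/1 group indicator, alpha: per-feature dispersion.
nb_irls_two_group <- function(Y, x, log_sf, alpha,
                              max_iter = 50L, tol = 1e-8) {
  nfeat <- nrow(Y)
  if (nfeat == 0L) return(list(beta1 = numeric(0), se1 = numeric(0)))
  n <- ncol(Y)
  sf <- exp(log_sf)
  norm <- sweep(Y, 2, sf, "/")
  m0 <- rowMeans(norm[, x == 0, drop = FALSE])
  m1 <- rowMeans(norm[, x == 1, drop = FALSE])
  b0 <- log(pmax(m0, 0.1))
  b1 <- log(pmax(m1, 0.1)) - b0

  off <- matrix(log_sf, nfeat, n, byrow = TRUE)
  for (iter in seq_len(max_iter)) {
    eta <- b0 + outer(b1, x) + off
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    W <- mu / (1 + alpha * mu)
    Z <- (eta - off) + (Y - mu) / mu
    sw <- rowSums(W)
    swx <- W %*% x
    swz <- rowSums(W * Z)
    swxz <- (W * Z) %*% x
    det <- sw * swx - swx^2  # x is 0/1 so sum(W x^2) = sum(W x)
    det <- pmax(det, .Machine$double.eps)
    b0_new <- as.numeric((swx * swz - swx * swxz) / det)
    b1_new <- as.numeric((sw * swxz - swx * swz) / det)
    delta <- max(abs(c(b0_new - b0, b1_new - b1)))
    b0 <- b0_new
    b1 <- b1_new
    if (delta < tol) break
  }
  eta <- pmin(pmax(b0 + outer(b1, x) + off, -30), 30)
  mu <- exp(eta)
  W <- mu / (1 + alpha * mu)
  sw <- rowSums(W)
  swx <- as.numeric(W %*% x)
  det <- pmax(sw * swx - swx^2, .Machine$double.eps)
  list(beta1 = b1, se1 = sqrt(sw / det))
}

# Empirical-Bayes normal-prior shrinkage: posterior mode of beta under a
# N(0, tau2) prior and a normal likelihood approximation N(beta_hat, se^2).
# tau2 is estimated from the spread of the MLEs (method of moments).
shrink_normal_prior <- function(beta, se, min_prior_var = 1e-6) {
  use <- is.finite(beta) & is.finite(se)
  if (!any(use)) return(beta)
  tau2 <- max(mean(beta[use]^2) - mean(se[use]^2), min_prior_var)
  shrunk <- beta * tau2 / (tau2 + se^2)
  ifelse(is.finite(shrunk), shrunk, beta)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement and
#' `NA` passthrough; thin validating wrapper around [stats::p.adjust()].
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) stop("pvalues must be numeric")
  bad <- !is.na(pvalues) & (pvalues < 0 | pvalues > 1)
  if (any(bad)) stop("p-values outside [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Annotate cancer-associated HERVs (CAHs)
#'
#' Applies the two-step rule over a list of per-cancer tumor-versus-normal
#' differential results: first **exclude** every HERV overexpressed in normal
#' tissue in any cancer (log2fc at or below `-log2(fc_threshold)`), then
#' **include** HERVs overexpressed in tumor in at least one cancer (log2fc at
#' or above `log2(fc_threshold)`). When `padj_threshold` is non-`NULL`, both
#' directions additionally require `padj < padj_threshold`; `NULL` gives the
#' pure fold-change mode.
#'
#' @param de_by_cancer List of `data.frame`s as returned by
#'   [nb_differential()] (one per cancer type; positive `log2fc` = higher in
#'   tumor).
#' @param fc_threshold Fold-change threshold on the natural scale (default 2).
#' @param padj_threshold Significance cutoff, or `NULL` to ignore significance.
#' @return A list with `per_cancer_overexpressed` (named list of id vectors),
#'   `excluded` (ids overexpressed in any normal tissue) and `cah_ids`
#'   (the final set, sorted).
#' @export
annotate_cah <- function(de_by_cancer, fc_threshold = 2, padj_threshold = 0.05) {
  if (!length(de_by_cancer)) stop("empty comparison list")
  if (is.data.frame(de_by_cancer)) de_by_cancer <- list(de_by_cancer)
  lfc_thr <- log2(fc_threshold)
  sig <- function(de) {
    if (is.null(padj_threshold)) rep(TRUE, nrow(de)) else
      !is.na(de$padj) & de$padj < padj_threshold
  }
  up <- lapply(de_by_cancer, function(de) {
    de$herv_id[!is.na(de$log2fc) & de$log2fc >= lfc_thr & sig(de)]
  })
  down <- lapply(de_by_cancer, function(de) {
    de$herv_id[!is.na(de$log2fc) & de$log2fc <= -lfc_thr & sig(de)]
  })
  excluded <- sort(unique(unlist(down)))
  included <- sort(unique(unlist(up)))
  list(
    per_cancer_overexpressed = up,
    excluded = excluded,
    cah_ids = setdiff(included, excluded)
  )
}
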