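#' Cytolytic activity (CYT) score
#'
#' Geometric mean of two cytolytic effector gene expressions per sample.
#' The gene pair is configurable; both granzyme pairs in common use
#' (GZMB + PRF1 and GZMA + PRF1) are supported by passing the corresponding
#' rows.
#'
#' @param expr Numeric matrix with the two genes in rows (sample columns), or
#'   a length-2 list/vector pair via `g1`, `g2`.
#' @param genes Character vector of length 2 naming the rows of `expr` to use.
#' @return Named numeric vector of per-sample scores, `sqrt(g1 * g2)`.
#' @export
cyt_score <- function(expr, genes = c("GZMB", "PRF1")) {
  if (length(genes) != 2L) stop("exactly two genes define the CYT score")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) stop("gene(s) not found: ", paste(missing, collapse = ", "))
  g1 <- expr[genes[1L], ]
  g2 <- expr[genes[2L], ]
  if (any(g1 < 0 | g2 < 0)) stop("expression must be nonnegative")
  sqrt(g1 * g2)
}

#' Single-sample gene set enrichment score
#'
#' Rank-based single-sample enrichment in the ssGSEA convention: genes are
#' ordered by decreasing expression (ties broken stably by input order), the
#' in-set cumulative distribution is weighted by rank^`weight_exponent`, the
#' out-of-set distribution is uniform, and the score is the sum of their
#' running difference.
#'
#' @param expr Named numeric vector: one sample's expression (log2 CPM).
#' @param gene_set Character vector of gene ids.
#' @param weight_exponent Rank weighting exponent (default 0.25).
#' @return A single numeric enrichment score. By convention a set containing
#'   every measured gene scores 0.
#' @export
ssgsea_score <- function(expr, gene_set, weight_exponent = 0.25) {
  if (is.null(names(expr))) stop("expr must be a named vector")
  in_set <- names(expr) %in% gene_set
  if (!any(in_set)) stop("gene set does not intersect the measured genes")
  n <- length(expr)
  n_in <- sum(in_set)
  if (n_in == n) return(0)
  ord <- order(-expr)  # stable: ties keep input order
  in_ord <- in_set[ord]
  w <- (n - seq_len(n) + 1)^weight_exponent  # rank weight, top gene gets n^a
  w_in <- w * in_ord
  p_in <- cumsum(w_in) / sum(w_in)
  p_out <- cumsum(!in_ord) / (n - n_in)
  sum(p_in - p_out)
}

#' L1-penalized (lasso) association of HERVs with an immune signature
#'
#' Fits `y ~ X` under an L1 penalty, `(1/2n) deviance + lambda * ||beta||_1`,
#' over a log-spaced lambda path, choosing lambda by k-fold cross-validation
#' minimizing mean squared error (gaussian) or mean deviance (poisson).
#' Predictors are log2(CPM + 1) HERV expressions and are **not** standardized.
#' HERVs with a strictly positive coefficient at the selected lambda are
#' flagged as associated. Fitting is delegated to \pkg{glmnet}
#' (single-column designs are padded internally with an excluded dummy).
#'
#' @param x Numeric matrix, samples x HERVs (colnames = HERV ids).
#' @param y Response: signature values. Gaussian for continuous scores
#'   (CYT, IFN-gamma); poisson (log link) for nonnegative cell-type scores,
#'   applied to continuous values without rounding.
#' @param family `"gaussian"` or `"poisson"`.
#' @param n_folds Cross-validation folds (default 10).
#' @param seed Integer seed controlling fold assignment.
#' @param lambda Optional fixed lambda; skips cross-validation.
#' @param signature_name,cancer_type Labels copied into the output.
#' @return A `data.frame` with one row per HERV: `herv_id`, `signature_name`,
#'   `cancer_type`, `coefficient`, `selected` (coefficient > 0),
#'   `lambda_used`, `family`, `seed`.
#' @export
lasso_fit <- function(x, y, family = c("gaussian", "poisson"),
                      n_folds = 10L, seed = 1L, lambda = NULL,
                      signature_name = NA_character_,
                      cancer_type = NA_character_) {
  family <- match.arg(family)
  x <- as.matrix(x)
  if (!ncol(x)) stop("no predictors supplied")
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite predictors")
  if (stats::sd(y) == 0) stop("constant response")
  if (family == "poisson" && any(y < 0)) stop("poisson response must be nonnegative")
  n <- nrow(x)
  if (!is.null(lambda)) n_folds <- max(n_folds, 2L)
  if (is.null(lambda) && (n < n_folds || n_folds < 2L)) {
    stop("need n_samples >= n_folds >= 2")
  }
  ids <- colnames(x)
  if (is.null(ids)) ids <- paste0("herv_", seq_len(ncol(x)))

  # glmnet requires >= 2 columns; pad with a dummy excluded via Inf penalty
  pad <- ncol(x) == 1L
  xx <- if (pad) cbind(x, `.dummy` = 0) else x
  pf <- if (pad) c(1, Inf) else rep(1, ncol(xx))

  if (is.null(lambda)) {
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(n_folds), n))
    cv <- glmnet::cv.glmnet(
      xx, y, family = family, foldid = foldid, standardize = FALSE,
      penalty.factor = pf,
      type.measure = if (family == "gaussian") "mse" else "deviance",
      grouped = n >= 3L * n_folds,  # per-fold grouping needs >= 3 obs/fold
      thresh = 1e-8, maxit = 2e5
    )
    lambda_used <- cv$lambda.min
    beta <- stats::coef(cv, s = "lambda.min")
  } else {
    # include the requested lambda on a descending path for a stable solution
    lam_path <- sort(unique(c(exp(seq(log(max(lambda, 1e-3) * 50),
                                      log(max(lambda, 1e-4)), length.out = 20)),
                              lambda)), decreasing = TRUE)
    fit <- glmnet::glmnet(xx, y, family = family, lambda = lam_path,
                          standardize = FALSE, penalty.factor = pf,
                          thresh = 1e-12)
    lambda_used <- lambda
    idx <- which.min(abs(fit$lambda - lambda))  # lambda lies on the path
    beta <- c(fit$a0[idx], as.numeric(fit$beta[, idx]))
  }
  beta <- as.numeric(beta)[-1L]  # drop intercept
  if (pad) beta <- beta[1L]
  data.frame(
    herv_id = ids,
    signature_name = signature_name,
    cancer_type = cancer_type,
    coefficient = beta,
    selected = beta > 0,
    lambda_used = lambda_used,
    family = family,
    seed = seed,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Overexpression in purified T / NK cells (exclusion criterion C)
#'
#' Compares mean log2 CPM of each HERV in sorted T cells (and, independently,
#' NK cells) against the mean over the remaining sorted PBMC samples. A HERV
#' is flagged when either difference reaches `log2(fc_threshold)` (boundary
#' inclusive).
#'
#' @param log2cpm Matrix of log2(CPM + 1), HERVs x sorted-cell samples.
#' @param cell_class Character/factor per sample; must contain `"sorted_T"`,
#'   `"sorted_NK"` and at least one other class.
#' @param fc_threshold Fold-change threshold (default 2).
#' @return Named logical vector of C flags, one per HERV.
#' @export
pbmc_overexpression <- function(log2cpm, cell_class, fc_threshold = 2) {
  cell_class <- as.character(cell_class)
  if (length(cell_class) != ncol(log2cpm)) {
    stop("cell_class must have one label per sample")
  }
  for (cls in c("sorted_T", "sorted_NK")) {
    if (!any(cell_class == cls)) stop("missing cell class: ", cls)
  }
  if (all(cell_class %in% c("sorted_T", "sorted_NK"))) {
    stop("need at least one sorted PBMC class other than T and NK")
  }
  thr <- log2(fc_threshold)
  flag <- rep(FALSE, nrow(log2cpm))
  for (cls in c("sorted_T", "sorted_NK")) {
    in_cls <- cell_class == cls
    m_in <- rowMeans(log2cpm[, in_cls, drop = FALSE])
    m_out <- rowMeans(log2cpm[, !in_cls, drop = FALSE])
    flag <- flag | (m_in - m_out >= thr)
  }
  names(flag) <- rownames(log2cpm)
  flag
}

#' Annotate cytotoxicity-associated HERVs (cyt-HERVs)
#'
#' Combines per-cancer lasso associations and the sorted-cell exclusion into
#' the final rule: criterion A = selected for at least one *phenotype*
#' signature in at least one cancer, criterion B = likewise for a *function*
#' signature, criterion C = overexpressed in purified T or NK cells, and
#' `cyt = A & B & !C`. Only CAHs are eligible.
#'
#' @param cah_ids Character vector of cancer-associated HERV ids.
#' @param associations `data.frame` of stacked [lasso_fit()] results with an
#'   extra `kind` column (`"phenotype"` or `"function"`) per signature.
#' @param c_flags Named logical vector from [pbmc_overexpression()]; ids
#'   absent from it are treated as `FALSE`.
#' @return `data.frame` with columns `herv_id`, `A`, `B`, `C`, `cyt`, one row
#'   per CAH, ordered by `herv_id`.
#' @export
annotate_cyt <- function(cah_ids, associations, c_flags = logical(0)) {
  cah_ids <- sort(unique(cah_ids))
  stopifnot(all(c("herv_id", "selected", "kind") %in% names(associations)))
  sel <- associations[associations$selected, , drop = FALSE]
  a_ids <- unique(sel$herv_id[sel$kind == "phenotype"])
  b_ids <- unique(sel$herv_id[sel$kind == "function"])
  A <- cah_ids %in% a_ids
  B <- cah_ids %in% b_ids
  C <- rep(FALSE, length(cah_ids))
  if (length(c_flags)) {
    hit <- match(cah_ids, names(c_flags))
    C[!is.na(hit)] <- c_flags[hit[!is.na(hit)]]
  }
  data.frame(
    herv_id = cah_ids, A = A, B = B, C = C,
    cyt = A & B & !C,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Read a GMT gene-set file
#'
#' @param path Path to a tab-separated GMT file (set name, description,
#'   then gene ids).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a GMT gene-set file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
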