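#' Combined significance-magnitude (pi) value
#'
#' `pi = log2fc * log10(1/p)`, combining effect size and statistical
#' significance for one HERV and one tumor-vs-normal comparison. P-values are
#' floored at `p_floor` to avoid infinities.
#'
#' @param log2fc Log2 fold change(s).
#' @param p P-value(s) in `(0, 1]` (adjusted or raw; the caller chooses which
#'   convention to feed in).
#' @param p_floor Lower flooring bound for p (default 1e-300); set to `NULL`
#'   to disable flooring, in which case `p <= 0` is an error.
#' @return Numeric vector of pi values.
#' @export
pi_value <- function(log2fc, p, p_floor = 1e-300) {
  if (any(p > 1, na.rm = TRUE)) stop("p-values must be <= 1")
  if (is.null(p_floor)) {
    if (any(p <= 0, na.rm = TRUE)) stop("p <= 0 without flooring enabled")
  } else {
    p <- pmax(p, p_floor)
  }
  log2fc * log10(1 / p)
}

#' Cumulative epitope expression score
#'
#' Sums the pi values of all HERVs containing an epitope's sequence. Accepts
#' either a presence matrix from [relocate_epitopes()] (rows = peptides) and
#' a named pi vector, or an explicit list of containing-HERV pi values.
#'
#' @param presence Logical matrix, peptides x HERVs.
#' @param pi Named numeric vector of per-HERV pi values; HERVs missing from
#'   it contribute 0.
#' @return `data.frame` with `peptide` and `score`. Peptides contained in no
#'   HERV score 0 with a warning.
#' @export
cumulative_epitope_score <- function(presence, pi) {
  hit <- match(colnames(presence), names(pi))
  w <- ifelse(is.na(hit), 0, pi[hit])
  score <- as.numeric(presence %*% w)
  if (any(rowSums(presence) == 0)) {
    warning("some peptides are contained in no HERV; their score is 0")
  }
  data.frame(peptide = rownames(presence), score = score,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample HERV-set expression score with tercile groups
#'
#' The score is the arithmetic mean of the log2(CPM + 1) rows of the given
#' HERV set; samples are then split into `low` / `intermediate` / `high`
#' terciles of the empirical score distribution (lower-inclusive boundaries).
#' Group sizes differ by at most one; ties at a boundary are resolved by
#' stable sample order. If every score is identical all samples fall into a
#' single group and a warning is emitted.
#'
#' @param log2cpm Matrix of log2(CPM + 1), HERVs x samples.
#' @param herv_ids Character vector of HERV ids (rows) defining the set.
#' @return `data.frame` with `sample_id`, `set_score`, `tercile` (factor
#'   low < intermediate < high).
#' @export
herv_set_score <- function(log2cpm, herv_ids) {
  if (!length(herv_ids)) stop("empty HERV id set")
  missing <- setdiff(herv_ids, rownames(log2cpm))
  if (length(missing)) stop("HERV id(s) not found: ",
                            paste(missing, collapse = ", "))
  score <- colMeans(log2cpm[herv_ids, , drop = FALSE])
  data.frame(sample_id = colnames(log2cpm),
             set_score = unname(score),
             tercile = assign_terciles(score),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tercile assignment
#'
#' @param score Numeric vector.
#' @return Ordered factor with levels `low < intermediate < high`.
#' @export
assign_terciles <- function(score) {
  n <- length(score)
  lev <- c("low", "intermediate", "high")
  if (length(unique(score)) == 1L) {
    warning("constant scores: all samples assigned to one tercile group")
    return(factor(rep("low", n), levels = lev, ordered = TRUE))
  }
  base <- n %/% 3L
  rem <- n %% 3L
  sizes <- c(low = base, intermediate = base, high = base)
  if (rem == 1L) sizes["low"] <- sizes["low"] + 1L
  if (rem == 2L) sizes[c("low", "high")] <- sizes[c("low", "high")] + 1L
  ord <- order(score)  # stable: boundary ties resolved by sample order
  grp <- rep(lev, times = sizes)
  out <- character(n)
  out[ord] <- grp
  factor(out, levels = lev, ordered = TRUE)
}

#' Log-rank (Mantel-Cox) test across groups
#'
#' K-group log-rank test of survival differences; a thin wrapper around
#' [survival::survdiff()] returning the chi-square statistic, degrees of
#' freedom and p-value, plus the fitted Kaplan-Meier curves for plotting.
#'
#' @param time Follow-up times.
#' @param event Event indicator (1/TRUE = event, 0/FALSE = censored).
#' @param group Group labels (e.g. score terciles).
#' @return List with `chisq`, `df`, `p`, and `km` (a [survival::survfit]
#'   object).
#' @export
logrank_test <- function(time, event, group) {
  event <- as.integer(as.logical(event))
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) stop("need at least two groups")
  if (sum(event) == 0L) stop("no events observed")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       km = survival::survfit(survival::Surv(time, event) ~ group))
}

#' Correlation of HERV expression with local methylation
#'
#' For each HERV locus, takes the `n_probes` nearest methylation probes on
#' the same chromosome (distance from the locus midpoint, ties by position),
#' averages their beta values per sample, and correlates that mean beta with
#' the HERV's log2 CPM across samples. Correlations are BH-adjusted across
#' HERVs; a HERV is labeled `demethylation` when rho < 0 and padj < 0.05,
#' `methylation` when rho > 0 and padj < 0.05, otherwise `none`.
#'
#' @param loci `data.frame` with columns `herv_id`, `chrom`, `start`, `end`
#'   (midpoint = (start + end) / 2).
#' @param probes `data.frame` with columns `chrom`, `pos`, then one numeric
#'   beta column per sample.
#' @param log2cpm HERV expression matrix (rows must cover `loci$herv_id`,
#'   columns must cover the probe beta sample columns).
#' @param n_probes Number of nearest probes (default 10).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return `data.frame` per HERV: `herv_id`, `mean_beta` (grand mean over
#'   samples), `rho`, `pvalue`, `padj`, `label`.
#' @export
methylation_correlation <- function(loci, probes, log2cpm, n_probes = 10L,
                                    method = c("spearman", "pearson")) {
  method <- match.arg(method)
  sample_cols <- setdiff(names(probes), c("chrom", "pos"))
  samples <- intersect(sample_cols, colnames(log2cpm))
  if (!length(samples)) stop("no shared samples between probes and expression")
  res <- lapply(seq_len(nrow(loci)), function(i) {
    on_chr <- probes[probes$chrom == loci$chrom[i], , drop = FALSE]
    if (nrow(on_chr) < n_probes) {
      stop("fewer than ", n_probes, " probes on chromosome ", loci$chrom[i],
           " for ", loci$herv_id[i])
    }
    mid <- (loci$start[i] + loci$end[i]) / 2
    ord <- order(abs(on_chr$pos - mid), on_chr$pos)
    nn <- on_chr[ord[seq_len(n_probes)], samples, drop = FALSE]
    mean_beta <- colMeans(as.matrix(nn))
    expr <- log2cpm[loci$herv_id[i], samples]
    ct <- suppressWarnings(stats::cor.test(mean_beta, expr, method = method))
    data.frame(herv_id = loci$herv_id[i],
               mean_beta = mean(mean_beta),
               rho = unname(ct$estimate),
               pvalue = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- bh_adjust(out$pvalue)
  out$label <- ifelse(
    !is.na(out$padj) & out$padj < 0.05,
    ifelse(out$rho < 0, "demethylation", "methylation"),
    "none"
  )
  rownames(out) <- NULL
  out
}
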