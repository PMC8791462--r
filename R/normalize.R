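#' Counts-per-million normalization
#'
#' Scales each sample (column) of a raw count matrix to counts per million
#' total reads, optionally followed by the `log2(x + 1)` transform used
#' throughout the pipeline.
#'
#' @param counts Numeric matrix of nonnegative raw counts, features in rows
#'   (rownames = HERV ids), samples in columns (colnames = sample ids).
#' @param log2 If `TRUE` (default) return `log2(CPM + 1)`; otherwise plain CPM.
#' @return A matrix with the same dimnames as `counts`, on the CPM or
#'   log2(CPM + 1) scale.
#' @examples
#' m <- matrix(c(10, 999990, 5, 999995), 2,
#'             dimnames = list(c("h1", "h2"), c("s1", "s2")))
#' cpm_normalize(m, log2 = FALSE)["h1", "s1"]  # 10
#' @export
cpm_normalize <- function(counts, log2 = TRUE) {
  counts <- check_count_matrix(counts)
  totals <- colSums(counts)
  zero <- totals <= 0
  if (any(zero)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  cpm <- sweep(counts, 2, totals, "/") * 1e6
  if (log2) log2(cpm + 1) else cpm
}

# coerce an XStringSet or character vector to character, preserving names
as_named_chr <- function(x) {
  if (is.character(x)) return(x)
  nm <- names(x)
  out <- as.character(x)
  names(out) <- nm
  out
}

# validate a raw count matrix: numeric, nonnegative, finite, with dimnames
check_count_matrix <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (anyNA(counts) || any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("herv_", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  }
  counts
}
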