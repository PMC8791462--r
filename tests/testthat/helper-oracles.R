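# Independent oracles used across the suite. These deliberately reimplement
# the operations in the most naive way possible and never call the package
# functions they check.

# --- brute-force six-frame ORF finder -------------------------------------
GENETIC_CODE_TABLE <- {
  code <- Biostrings::GENETIC_CODE
  stats::setNames(unname(code), names(code))
}

oracle_translate <- function(dna) {
  n_codon <- nchar(dna) %/% 3
  if (n_codon == 0) return("")
  codons <- substring(dna, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
  aa <- GENETIC_CODE_TABLE[codons]
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}

oracle_revcomp <- function(dna) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", dna), "")[[1]]), collapse = "")
}

# returns a sorted character vector "frame:aa_seq:nt_start:nt_end"
oracle_six_frame <- function(dna, min_len) {
  len <- nchar(dna)
  out <- character(0)
  for (strand in c(1, -1)) {
    s <- if (strand == 1) dna else oracle_revcomp(dna)
    for (f in 1:3) {
      aa <- oracle_translate(substr(s, f, nchar(s)))
      if (!nzchar(aa)) next
      pieces <- strsplit(aa, "*", fixed = TRUE)[[1]]
      pos <- 1
      for (p in pieces) {
        if (nchar(p) >= min_len) {
          start_local <- (f - 1) + (pos - 1) * 3
          end_local <- (f - 1) + (pos + nchar(p) - 1) * 3
          ntp <- if (strand == 1) c(start_local, end_local)
                 else c(len - end_local, len - start_local)
          out <- c(out, paste(strand * f, p, ntp[1], ntp[2], sep = ":"))
        }
        pos <- pos + nchar(p) + 1
      }
    }
  }
  sort(out)
}

# --- plain affine-gap Smith-Waterman DP -----------------------------------
oracle_blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

oracle_sw_score <- function(a, b, gap_open = 11, gap_ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (vertical)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (horizontal)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- oracle_blosum62[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                            Iy[i - 1, j - 1]) + sub)
      Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, Ix[i - 1, j] - gap_ext)
      Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Iy[i, j - 1] - gap_ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

# --- hand Benjamini-Hochberg ----------------------------------------------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# --- naive ssGSEA running sum ---------------------------------------------
oracle_ssgsea <- function(expr, gene_set, alpha) {
  ord <- order(-expr)
  genes <- names(expr)[ord]
  n <- length(expr)
  inside <- genes %in% gene_set
  w <- (n - seq_len(n) + 1)^alpha
  p_in <- 0
  p_out <- 0
  total_in <- sum(w[inside])
  total_out <- sum(!inside)
  score <- 0
  for (i in seq_len(n)) {
    if (inside[i]) p_in <- p_in + w[i] / total_in
    else p_out <- p_out + 1 / total_out
    score <- score + (p_in - p_out)
  }
  score
}

# --- naive proteome scan ---------------------------------------------------
oracle_proteome_flags <- function(peptides, proteome) {
  vapply(peptides, function(p) {
    any(vapply(proteome, function(rec) {
      grepl(p, rec, fixed = TRUE)
    }, logical(1)))
  }, logical(1))
}

# --- random sequences ------------------------------------------------------
random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# --- small shared simulation configuration for fast tests ------------------
fast_config <- function(seed = 1L, ...) {
  ids <- sprintf("sherv_%04d", 1:60)
  simulation_config(
    n_hervs = 60L, n_tumor = 20L, n_normal = 20L, n_cancer_types = 1L,
    planted_cah_effects = c(stats::setNames(rep(2, 8), ids[1:8]),
                            stats::setNames(rep(-2, 2), ids[9:10])),
    planted_cyt_ids = ids[1:3],
    planted_tnk_effects = stats::setNames(rep(2, 2), ids[11:12]),
    n_sorted = c(sorted_T = 4L, sorted_NK = 4L, sorted_other = 8L),
    rng_seed = seed, ...
  )
}
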