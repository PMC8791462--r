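#' Six-frame ORF detection
#'
#' Translates a DNA sequence in all six frames with the standard genetic code
#' and returns every stop-to-stop segment (no start codon required) of at
#' least `min_len_aa` amino acids. Codons containing `N` translate to `X` and
#' do not terminate an ORF. Coordinates are 0-based half-open on the forward
#' strand; frames -1..-3 are defined on the reverse complement read 5'->3'.
#'
#' @param dna A single DNA sequence (character or [Biostrings::DNAString])
#'   over `{A, C, G, T, N}`.
#' @param min_len_aa Minimum ORF length in amino acids (inclusive,
#'   default 10).
#' @param herv_id Optional id recorded on every returned row.
#' @return `data.frame` with columns `herv_id`, `frame` (+1..+3, -1..-3),
#'   `aa_seq` (no stop symbol), `nt_start`, `nt_end`, `length_aa`.
#' @export
six_frame_orfs <- function(dna, min_len_aa = 10L, herv_id = NA_character_) {
  dna <- toupper(as.character(dna))
  if (!nzchar(dna)) stop("empty sequence")
  if (grepl("[^ACGTN]", dna)) stop("sequence must be over {A,C,G,T,N}")
  len <- nchar(dna)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))

  res <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) dna else rc
    for (f in 1:3) {
      n_codon <- (nchar(s) - f + 1L) %/% 3L
      if (n_codon < 1L) next
      aa <- translate_frame(s, f, n_codon)
      # split on stops, tracking codon positions
      runs <- orf_runs(aa)
      if (!nrow(runs)) next
      runs <- runs[runs$len >= min_len_aa, , drop = FALSE]
      if (!nrow(runs)) next
      start_local <- (f - 1L) + (runs$start - 1L) * 3L  # 0-based on strand
      end_local <- (f - 1L) + runs$end * 3L
      res[[length(res) + 1L]] <- data.frame(
        herv_id = herv_id,
        frame = strand * f,
        aa_seq = substring(aa, runs$start, runs$end),
        nt_start = if (strand == 1L) start_local else len - end_local,
        nt_end = if (strand == 1L) end_local else len - start_local,
        length_aa = runs$len,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(res)) {
    return(data.frame(herv_id = character(0), frame = integer(0),
                      aa_seq = character(0), nt_start = integer(0),
                      nt_end = integer(0), length_aa = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# translate one frame of a strand sequence; N-containing codons become X
translate_frame <- function(s, f, n_codon) {
  sub <- substr(s, f, f + n_codon * 3L - 1L)
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

# stop-free runs in a translated frame: start/end are 1-based aa positions
orf_runs <- function(aa) {
  chars <- strsplit(aa, "")[[1]]
  is_stop <- chars == "*"
  if (!length(chars)) return(data.frame(start = integer(0), end = integer(0),
                                        len = integer(0)))
  r <- rle(is_stop)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !r$values
  data.frame(start = starts[keep], end = ends[keep],
             len = r$lengths[keep])
}

#' Smith-Waterman local alignment against a reference protein
#'
#' Optimal local alignment with BLOSUM62 scoring and affine gaps (open 11,
#' extend 1; a length-L gap costs 11 + L), computed exactly (no heuristic
#' seeding). Percent identity is taken over all aligned columns, counting gap
#' columns as mismatches, and the e-value follows the Karlin-Altschul formula
#' `E = K * m * n * exp(-lambda * S)` with the gapped BLOSUM62 constants
#' `lambda = 0.267`, `K = 0.041`.
#'
#' @param query_aa Query amino-acid sequence (an ORF).
#' @param ref_aa Reference protein sequence.
#' @param ref_id Reference id stored in the result.
#' @param search_n Effective subject length for the e-value (defaults to
#'   `nchar(ref_aa)`; pass the summed length of all references when screening
#'   against a database).
#' @param gap_opening,gap_extension Affine gap parameters.
#' @return One-row `data.frame`: `ref_protein_id`, `score`, `bitscore`,
#'   `percent_identity`, `evalue`, `aligned_query`, `aligned_ref`.
#' @export
local_align <- function(query_aa, ref_aa, ref_id = NA_character_,
                        search_n = nchar(ref_aa),
                        gap_opening = 11, gap_extension = 1) {
  if (!nzchar(query_aa) || !nzchar(ref_aa)) stop("empty sequence")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query_aa), Biostrings::AAString(ref_aa),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  s <- Biostrings::score(al)
  lambda <- 0.267
  K <- 0.041
  evalue <- K * nchar(query_aa) * search_n * exp(-lambda * s)
  data.frame(
    ref_protein_id = ref_id,
    score = s,
    bitscore = (lambda * s - log(K)) / log(2),
    percent_identity = Biostrings::pid(al, type = "PID1"),
    evalue = evalue,
    aligned_query = as.character(Biostrings::alignedPattern(al)),
    aligned_ref = as.character(Biostrings::alignedSubject(al)),
    stringsAsFactors = FALSE
  )
}

#' Homology filter against reference retroviral proteins
#'
#' Retains ORFs whose best local-alignment hit to a kept reference protein
#' (by default the Gag and Pol records) reaches both the identity and the
#' e-value threshold. The e-value search space uses the summed length of all
#' kept references.
#'
#' @param orfs `data.frame` from [six_frame_orfs()] (columns `aa_seq`, ...).
#' @param reference_proteins Named [Biostrings::AAStringSet] (or named
#'   character vector) of reference proteins.
#' @param identity_min Minimum percent identity (inclusive, default 90).
#' @param evalue_max Maximum e-value (inclusive, default 0.05).
#' @param keep_refs Regular expression selecting reference names to screen
#'   against (default `"Gag|Pol"`).
#' @return The retained rows of `orfs` with extra columns `ref_protein_id`,
#'   `percent_identity`, `evalue`, `bitscore` of the best hit.
#' @export
homology_filter <- function(orfs, reference_proteins, identity_min = 90,
                            evalue_max = 0.05, keep_refs = "Gag|Pol") {
  refs <- as_named_chr(reference_proteins)
  if (is.null(names(refs)) || !length(refs)) stop("empty reference set")
  refs <- refs[grepl(keep_refs, names(refs))]
  if (!length(refs)) stop("no reference matches keep_refs = ", keep_refs)
  total_n <- sum(nchar(refs))
  if (!nrow(orfs)) return(orfs)
  lambda <- 0.267
  K <- 0.041
  queries <- Biostrings::AAStringSet(orfs$aa_seq)
  # one vectorized alignment call per reference, best hit per ORF by score
  best <- NULL
  for (nm in names(refs)) {
    al <- Biostrings::pairwiseAlignment(
      queries, Biostrings::AAString(refs[[nm]]), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1
    )
    s <- Biostrings::score(al)
    cur <- data.frame(
      ref_protein_id = nm,
      score = s,
      bitscore = (lambda * s - log(K)) / log(2),
      percent_identity = Biostrings::pid(al, type = "PID1"),
      evalue = K * nchar(orfs$aa_seq) * total_n * exp(-lambda * s),
      stringsAsFactors = FALSE
    )
    if (is.null(best)) best <- cur else {
      swap <- cur$score > best$score
      best[swap, ] <- cur[swap, ]
    }
  }
  keep <- best$percent_identity >= identity_min & best$evalue <= evalue_max
  out <- cbind(orfs[keep, , drop = FALSE],
               best[keep, c("ref_protein_id", "percent_identity",
                            "evalue", "bitscore"), drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Enumerate candidate k-mer peptides from ORFs
#'
#' @param orfs `data.frame` with an `aa_seq` column.
#' @param k Peptide length (default 9).
#' @return Sorted unique character vector of k-mers (peptides containing `X`
#'   are dropped).
#' @export
orf_peptides <- function(orfs, k = 9L) {
  peps <- unlist(lapply(orfs$aa_seq, function(aa) {
    n <- nchar(aa)
    if (n < k) return(character(0))
    substring(aa, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  }))
  sort(unique(peps[!grepl("X", peps)]))
}

#' HLA-binding percentile ranks for candidate peptides
#'
#' Two pluggable predictors are provided: `"table"` looks ranks up in an
#' externally computed table (e.g. from a neural binding predictor run outside
#' this package); `"anchor"` is a built-in test stub for HLA-A*02:01 that
#' flags a peptide as strong iff position 2 is L/M and the C-terminal position
#' is V/L/I. The anchor rule is a deliberately crude screening surrogate and
#' is documented as non-physiological.
#'
#' @param peptides Character vector of k-mers (all the same length).
#' @param allele HLA allele name (default `"HLA-A*02:01"`).
#' @param method `"table"` or `"anchor"`.
#' @param rank_table For `method = "table"`: `data.frame` with columns
#'   `peptide`, `allele`, `percentile_rank`. Peptides absent from the table
#'   get `NA` rank and are not strong binders.
#' @param cutoff Strong-binder percentile cutoff, inclusive (default 0.5).
#' @return `data.frame` with `peptide`, `allele`, `percentile_rank`,
#'   `strong_binder`.
#' @export
predict_binding <- function(peptides, allele = "HLA-A*02:01",
                            method = c("table", "anchor"),
                            rank_table = NULL, cutoff = 0.5) {
  method <- match.arg(method)
  if (!length(peptides)) {
    return(data.frame(peptide = character(0), allele = character(0),
                      percentile_rank = numeric(0), strong_binder = logical(0),
                      stringsAsFactors = FALSE))
  }
  k <- unique(nchar(peptides))
  if (length(k) != 1L) stop("all peptides must have the same length")
  if (method == "table") {
    if (is.null(rank_table)) stop("rank_table required for method = 'table'")
    key <- paste(rank_table$peptide, rank_table$allele)
    rank <- rank_table$percentile_rank[match(paste(peptides, allele), key)]
  } else {
    if (!grepl("^HLA-A\\*?02", allele)) {
      stop("anchor heuristic is only defined for HLA-A*02")
    }
    p2 <- substr(peptides, 2L, 2L)
    pC <- substr(peptides, k, k)
    rank <- ifelse(p2 %in% c("L", "M") & pC %in% c("V", "L", "I"), 0.25, 50)
  }
  data.frame(
    peptide = peptides,
    allele = allele,
    percentile_rank = rank,
    strong_binder = !is.na(rank) & rank <= cutoff,
    stringsAsFactors = FALSE
  )
}

#' Relocate epitopes across a HERV set and count sharing
#'
#' Exact k-mer substring search of each peptide over the six-frame ORF
#' translations (minimum ORF length relaxed to the peptide length) of every
#' HERV in scope. The sharing count is the number of **distinct** HERV ids
#' containing the peptide.
#'
#' @param peptides Character vector of peptides (equal length k).
#' @param sequences Named [Biostrings::DNAStringSet] (or named character) of
#'   the HERV nucleotide sequences in scope (e.g. cyt-HERVs, CAHs, or all).
#' @param orf_sets Optional precomputed list of ORF `data.frame`s named by
#'   HERV id, bypassing the six-frame scan.
#' @return List with `presence` (logical matrix peptide x HERV), and
#'   `sharing` (`data.frame` of `peptide`, `sharing_count`,
#'   `source_herv_ids`, ranked by decreasing count, ties broken
#'   lexicographically by peptide).
#' @export
relocate_epitopes <- function(peptides, sequences = NULL, orf_sets = NULL) {
  if (!length(peptides)) stop("no peptides supplied")
  k <- unique(nchar(peptides))
  if (length(k) != 1L) stop("all peptides must have the same length")
  if (is.null(orf_sets)) {
    if (is.null(sequences) || !length(sequences)) stop("empty scope")
    seqs <- as_named_chr(sequences)
    if (is.null(names(seqs))) stop("sequences must be named by HERV id")
    orf_sets <- lapply(seqs, six_frame_orfs, min_len_aa = k)
  }
  if (!length(orf_sets)) stop("empty scope")
  herv_ids <- names(orf_sets)
  # concatenate each HERV's ORFs with a separator that can't contain a k-mer
  blobs <- vapply(orf_sets, function(o) paste(o$aa_seq, collapse = "|"),
                  character(1))
  presence <- vapply(blobs, function(b) {
    vapply(peptides, function(p) grepl(p, b, fixed = TRUE), logical(1))
  }, logical(length(peptides)))
  presence <- matrix(presence, nrow = length(peptides),
                     dimnames = list(peptides, herv_ids))
  counts <- rowSums(presence)
  ord <- order(-counts, rownames(presence))
  sharing <- data.frame(
    peptide = rownames(presence)[ord],
    sharing_count = as.integer(counts[ord]),
    source_herv_ids = vapply(ord, function(i) {
      paste(herv_ids[presence[i, ]], collapse = ";")
    }, character(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  list(presence = presence, sharing = sharing)
}

#' Exclude epitopes matching the host proteome
#'
#' Flags every peptide whose exact sequence occurs as a substring of any
#' record of a proteome FASTA, and removes flagged peptides from the
#' candidate list (self-match exclusion before synthesis).
#'
#' @param peptides Character vector of candidate peptides.
#' @param proteome [Biostrings::AAStringSet], named character vector, or path
#'   to an amino-acid FASTA file.
#' @return `data.frame` with `peptide`, `self_match` (logical), plus an
#'   attribute-free convenience column `kept = !self_match`.
#' @export
proteome_exclusion <- function(peptides, proteome) {
  if (is.character(proteome) && length(proteome) == 1L &&
      file.exists(proteome)) {
    proteome <- Biostrings::readAAStringSet(proteome)
  }
  prot <- as_named_chr(proteome)
  if (!length(prot)) stop("empty or unreadable proteome")
  blob <- paste(prot, collapse = "|")
  flagged <- vapply(peptides, function(p) grepl(p, blob, fixed = TRUE),
                    logical(1))
  data.frame(peptide = peptides, self_match = unname(flagged),
             kept = unname(!flagged), stringsAsFactors = FALSE)
}

#' Reverse complement of a DNA string
#' @param dna Character DNA sequence.
#' @return Character reverse complement.
#' @export
revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}
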