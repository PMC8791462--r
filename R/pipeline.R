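#' Pipeline configuration
#'
#' Bundles every input path and threshold of the discovery pipeline. Inputs
#' are the standard formats written by [write_bundle()]: a counts TSV
#' (first column `herv_id`), a metadata TSV (`sample_id`, `cancer_type`,
#' `tissue_class`), a signature score TSV (`sample_id`, `signature_name`,
#' `value`, `kind`), FASTA files for HERV sequences, reference proteins and
#' the host proteome, and optional survival / methylation / rank-table TSVs.
#'
#' @param counts,metadata,signatures,sequences,reference_proteins,proteome
#'   Input file paths (all required).
#' @param survival,methylation,loci,rank_table Optional input paths.
#' @param out_dir Output directory.
#' @param fc_threshold,padj_threshold CAH annotation thresholds.
#' @param identity_min,evalue_max Homology filter thresholds.
#' @param rank_cutoff Strong-binder percentile cutoff (inclusive).
#' @param min_orf_len Minimum ORF length in amino acids.
#' @param k Peptide length.
#' @param binding_method `"anchor"` or `"table"` (see [predict_binding()]).
#' @param allele HLA allele.
#' @param scope Relocation scope: `"cyt_hervs"`, `"cahs"` or `"all_hervs"`.
#' @param pi_p Which p-value feeds the pi score: `"padj"` (default) or
#'   `"pvalue"`.
#' @param n_folds,seed Lasso cross-validation folds and run seed.
#' @return Validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(counts, metadata, signatures, sequences,
                            reference_proteins, proteome,
                            survival = NULL, methylation = NULL, loci = NULL,
                            rank_table = NULL, out_dir = tempfile("hervrun"),
                            fc_threshold = 2, padj_threshold = 0.05,
                            identity_min = 90, evalue_max = 0.05,
                            rank_cutoff = 0.5, min_orf_len = 10L, k = 9L,
                            binding_method = c("anchor", "table"),
                            allele = "HLA-A*02:01",
                            scope = c("cahs", "cyt_hervs", "all_hervs"),
                            pi_p = c("padj", "pvalue"),
                            n_folds = 10L, seed = 1L) {
  cfg <- list(
    counts = counts, metadata = metadata, signatures = signatures,
    sequences = sequences, reference_proteins = reference_proteins,
    proteome = proteome, survival = survival, methylation = methylation,
    loci = loci, rank_table = rank_table, out_dir = out_dir,
    fc_threshold = fc_threshold, padj_threshold = padj_threshold,
    identity_min = identity_min, evalue_max = evalue_max,
    rank_cutoff = rank_cutoff, min_orf_len = as.integer(min_orf_len),
    k = as.integer(k), binding_method = match.arg(binding_method),
    allele = allele, scope = match.arg(scope), pi_p = match.arg(pi_p),
    n_folds = as.integer(n_folds), seed = as.integer(seed)
  )
  required <- c("counts", "metadata", "signatures", "sequences",
                "reference_proteins", "proteome")
  for (f in required) {
    if (!file.exists(cfg[[f]])) stop("input file not found: ", cfg[[f]])
  }
  stopifnot(cfg$fc_threshold >= 1, cfg$identity_min >= 0,
            cfg$identity_min <= 100, cfg$evalue_max >= 0,
            cfg$rank_cutoff >= 0, cfg$min_orf_len >= 1L, cfg$k >= 1L)
  structure(cfg, class = "pipeline_config")
}

#' Run the full epitope discovery pipeline
#'
#' Executes normalize -> differential expression -> CAH annotation ->
#' cyt-HERV annotation -> ORF/homology/binding epitope screening ->
#' relocation -> proteome exclusion -> cumulative scoring (plus survival and
#' methylation stages when their inputs are configured), writing one TSV per
#' stage plus a YAML run manifest with a per-stage record-count funnel. Every
#' output carries a provenance header (package version, stage, seed, config
#' hash). A stage failure aborts with the stage named; earlier outputs are
#' retained.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  chash <- config_hash(config)
  funnel <- list()
  prov <- function(stage) {
    c(sprintf("# hervscreen %s", as.character(utils::packageVersion("hervscreen"))),
      sprintf("# stage: %s", stage),
      sprintf("# seed: %d", config$seed),
      sprintf("# config_hash: %s", chash))
  }
  emit <- function(df, stage, file) {
    path <- file.path(config$out_dir, file)
    writeLines(prov(stage), path)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
    path
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- normalize ---
  norm <- run_stage("normalize", {
    counts <- read_counts_tsv(config$counts)
    metadata <- utils::read.delim(config$metadata, comment.char = "#")
    if (!all(metadata$sample_id %in% colnames(counts))) {
      stop("metadata samples missing from counts")
    }
    counts <- counts[, metadata$sample_id, drop = FALSE]
    log2cpm <- cpm_normalize(counts)
    emit(data.frame(herv_id = rownames(log2cpm), log2cpm,
                    check.names = FALSE), "normalize", "log2cpm.tsv")
    list(counts = counts, metadata = metadata, log2cpm = log2cpm)
  })
  funnel$n_hervs <- nrow(norm$counts)
  funnel$n_samples <- ncol(norm$counts)

  # --- differential expression per cancer ---
  de_by_cancer <- run_stage("de", {
    md <- norm$metadata
    cancers <- sort(unique(md$cancer_type[md$tissue_class == "tumor"]))
    res <- lapply(cancers, function(ca) {
      sel <- md$cancer_type == ca & md$tissue_class %in% c("tumor", "peritumoral")
      de <- nb_differential(
        norm$counts[, md$sample_id[sel], drop = FALSE],
        factor(md$tissue_class[sel], levels = c("peritumoral", "tumor")),
        comparison = ca
      )
      emit(de, "de", sprintf("de_%s.tsv", ca))
      de
    })
    names(res) <- cancers
    res
  })

  # --- CAH annotation ---
  cah <- run_stage("annotate-cah", {
    out <- annotate_cah(de_by_cancer, config$fc_threshold,
                        config$padj_threshold)
    emit(data.frame(herv_id = out$cah_ids), "annotate-cah", "cah.tsv")
    out
  })
  funnel$n_cah <- length(cah$cah_ids)

  # --- cyt-HERV annotation ---
  cyt <- run_stage("annotate-cyt", {
    sig <- utils::read.delim(config$signatures, comment.char = "#")
    md <- norm$metadata
    cancers <- if (length(cah$cah_ids)) names(de_by_cancer) else character(0)
    assoc <- list(data.frame(
      herv_id = character(0), signature_name = character(0),
      cancer_type = character(0), coefficient = numeric(0),
      selected = logical(0), lambda_used = numeric(0),
      family = character(0), seed = integer(0), kind = character(0),
      stringsAsFactors = FALSE))
    for (ca in cancers) {
      tum <- md$sample_id[md$cancer_type == ca & md$tissue_class == "tumor"]
      x <- t(norm$log2cpm[cah$cah_ids, tum, drop = FALSE])
      for (nm in unique(sig$signature_name)) {
        rows <- sig[sig$signature_name == nm, ]
        y <- rows$value[match(tum, rows$sample_id)]
        if (anyNA(y)) next
        fam <- if (unique(rows$kind) == "phenotype") "poisson" else "gaussian"
        fit <- lasso_fit(x, y, family = fam, n_folds = config$n_folds,
                         seed = config$seed, signature_name = nm,
                         cancer_type = ca)
        fit$kind <- unique(rows$kind)
        assoc[[length(assoc) + 1L]] <- fit
      }
    }
    assoc <- do.call(rbind, assoc)
    sorted <- md$tissue_class %in% c("sorted_T", "sorted_NK", "sorted_other")
    c_flags <- if (any(sorted)) {
      pbmc_overexpression(norm$log2cpm[, md$sample_id[sorted], drop = FALSE],
                          md$tissue_class[sorted], config$fc_threshold)
    } else logical(0)
    ann <- annotate_cyt(cah$cah_ids, assoc, c_flags)
    emit(assoc, "annotate-cyt", "associations.tsv")
    emit(ann, "annotate-cyt", "cyt.tsv")
    ann
  })
  cyt_ids <- cyt$herv_id[cyt$cyt]
  funnel$n_cyt <- length(cyt_ids)

  # --- epitope screening on cyt-HERVs ---
  screen <- run_stage("screen-epitopes", {
    seqs <- as.character(Biostrings::readDNAStringSet(config$sequences))
    names(seqs) <- sub("\\s.*", "", names(seqs))
    refs <- Biostrings::readAAStringSet(config$reference_proteins)
    names(refs) <- sub("\\s.*", "", names(refs))
    orfs <- do.call(rbind, lapply(cyt_ids, function(id) {
      six_frame_orfs(seqs[[id]], config$min_orf_len, herv_id = id)
    }))
    if (is.null(orfs) || !nrow(orfs)) stop("no ORFs detected in cyt-HERVs")
    funnel$n_orfs <- nrow(orfs)
    kept <- homology_filter(orfs, refs, config$identity_min,
                            config$evalue_max)
    funnel$n_orfs_homologous <- nrow(kept)
    peptides <- orf_peptides(kept, config$k)
    funnel$n_peptides <- length(peptides)
    rank_table <- if (!is.null(config$rank_table)) {
      utils::read.delim(config$rank_table, comment.char = "#")
    }
    binding <- predict_binding(peptides, config$allele,
                               method = config$binding_method,
                               rank_table = rank_table,
                               cutoff = config$rank_cutoff)
    emit(kept, "screen-epitopes", "orfs_homologous.tsv")
    emit(binding, "screen-epitopes", "binding.tsv")
    list(seqs = seqs, orfs = kept, binding = binding,
         n_peptides = length(peptides))
  })
  funnel$n_peptides <- screen$n_peptides
  strong <- screen$binding$peptide[screen$binding$strong_binder]
  funnel$n_strong_binders <- length(strong)

  # --- relocation + proteome exclusion + scoring ---
  result <- run_stage("relocate-score", if (!length(strong)) {
    cand <- data.frame(peptide = character(0), allele = character(0),
                       percentile_rank = numeric(0),
                       sharing_count = integer(0),
                       source_herv_ids = character(0),
                       cumulative_pi = numeric(0))
    funnel$n_after_proteome <- 0L
    emit(cand, "relocate-score", "candidates.tsv")
    list(candidates = cand)
  } else {
    scope_ids <- switch(config$scope,
                        cyt_hervs = cyt_ids,
                        cahs = cah$cah_ids,
                        all_hervs = names(screen$seqs))
    reloc <- relocate_epitopes(strong, screen$seqs[scope_ids])
    excl <- proteome_exclusion(strong, config$proteome)
    keep <- excl$peptide[excl$kept]
    funnel$n_after_proteome <- length(keep)

    de1 <- de_by_cancer[[1L]]
    pi <- pi_value(de1$log2fc, de1[[config$pi_p]])
    names(pi) <- de1$herv_id
    pi <- pi[!is.na(pi)]
    pres <- reloc$presence[keep, , drop = FALSE]
    cum <- if (length(keep)) {
      suppressWarnings(cumulative_epitope_score(pres, pi))
    } else data.frame(peptide = character(0), score = numeric(0))

    cand <- reloc$sharing[reloc$sharing$peptide %in% keep &
                            reloc$sharing$sharing_count > 0, , drop = FALSE]
    cand$allele <- config$allele
    cand$percentile_rank <- screen$binding$percentile_rank[
      match(cand$peptide, screen$binding$peptide)]
    cand$cumulative_pi <- cum$score[match(cand$peptide, cum$peptide)]
    cand <- cand[, c("peptide", "allele", "percentile_rank",
                     "sharing_count", "source_herv_ids", "cumulative_pi")]
    emit(reloc$sharing, "relocate-score", "sharing.tsv")
    emit(excl, "relocate-score", "proteome_exclusion.tsv")
    emit(cand, "relocate-score", "candidates.tsv")
    list(candidates = cand, relocation = reloc)
  })
  funnel$n_candidates <- nrow(result$candidates)

  # --- optional survival stage ---
  surv_res <- NULL
  if (!is.null(config$survival) && nrow(result$candidates)) {
    surv_res <- run_stage("survival", {
      surv <- utils::read.delim(config$survival, comment.char = "#")
      set_ids <- unique(unlist(strsplit(
        result$candidates$source_herv_ids, ";")))
      set_ids <- intersect(set_ids, rownames(norm$log2cpm))
      common <- intersect(surv$sample_id, colnames(norm$log2cpm))
      sc <- herv_set_score(norm$log2cpm[, common, drop = FALSE], set_ids)
      sc <- merge(sc, surv, by = "sample_id", sort = TRUE)
      lr <- logrank_test(sc$time, sc$event, sc$tercile)
      sc$logrank_p <- lr$p
      emit(sc, "survival", "survival_terciles.tsv")
      list(scores = sc, logrank = lr, herv_set = set_ids)
    })
    funnel$n_survival_set <- length(surv_res$herv_set)
  }

  # --- optional methylation stage ---
  meth_res <- NULL
  if (!is.null(config$methylation) && !is.null(config$loci)) {
    meth_res <- run_stage("methylation", {
      probes <- utils::read.delim(config$methylation, check.names = FALSE,
                                  comment.char = "#")
      loci <- read_loci_bed(config$loci)
      loci <- loci[loci$herv_id %in% cyt_ids, , drop = FALSE]
      mc <- methylation_correlation(loci, probes, norm$log2cpm)
      emit(mc, "methylation", "methylation_correlation.tsv")
      mc
    })
    funnel$n_demethylation_linked <-
      sum(meth_res$label == "demethylation")
  }

  manifest <- list(
    package = "hervscreen",
    version = as.character(utils::packageVersion("hervscreen")),
    seed = config$seed,
    config_hash = chash,
    thresholds = config[c("fc_threshold", "padj_threshold", "identity_min",
                          "evalue_max", "rank_cutoff", "min_orf_len", "k",
                          "scope", "pi_p")],
    funnel = funnel
  )
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))

  invisible(list(de = de_by_cancer, cah = cah, cyt = cyt,
                 candidates = result$candidates, survival = surv_res,
                 methylation = meth_res, funnel = funnel,
                 manifest = manifest, out_dir = config$out_dir))
}

# md5 of the serialized configuration (file paths excluded so a relocated
# run with identical settings hashes identically)
config_hash <- function(config) {
  keep <- config[setdiff(names(config),
                         c("counts", "metadata", "signatures", "sequences",
                           "reference_proteins", "proteome", "survival",
                           "methylation", "loci", "rank_table", "out_dir"))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(keep, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' Read HERV loci from a BED file
#' @param path BED file with the HERV id in the name column.
#' @return `data.frame` with `herv_id`, `chrom`, `start`, `end`.
#' @export
read_loci_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(herv_id = gr$name,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}
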