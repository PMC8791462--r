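#' Configuration for the synthetic-data generator
#'
#' Collects the generative assumptions of the pipeline into one validated
#' object: negative-binomial counts (Var = mu + alpha * mu^2, one shared
#' dispersion), tumor overexpression planted as log2 effects on a subset of
#' HERVs, matched peritumoral samples sharing baselines with their tumors,
#' sorted-cell samples for the T/NK exclusion criterion, immune signatures
#' built as noisy linear combinations of the planted cytotoxicity-associated
#' HERVs, and exponential survival with hazard tied to a HERV-set score.
#'
#' @param n_hervs Total number of HERVs.
#' @param n_tumor,n_normal Samples per cancer type.
#' @param n_cancer_types Number of cancer types.
#' @param planted_cah_effects Named numeric vector of log2 effect sizes for
#'   planted HERVs (positive = tumor overexpression in every cancer type,
#'   negative = peritumoral overexpression; the latter exercises the CAH
#'   exclusion rule).
#' @param planted_cyt_ids Ids of planted cytotoxicity-associated HERVs; must
#'   be a subset of the positive-effect planted CAH ids.
#' @param planted_tnk_effects Named numeric vector of log2 effects applied in
#'   sorted T and NK samples (exclusion criterion C decoys).
#' @param n_sorted Named integer vector of sorted-PBMC sample counts.
#' @param dispersion Shared NB dispersion alpha (> 0).
#' @param library_size_mean Expected HERV-mapped reads per sample.
#' @param signature_noise_sd Gaussian noise SD for simulated signatures;
#'   `NA` (default) uses half the SD of the underlying signal.
#' @param survival_hazard_ratio_per_unit Hazard ratio per standard deviation
#'   of the HERV-set score (values < 1 make high scores protective).
#' @param rng_seed Integer seed; every generator is bit-reproducible given it.
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_hervs = 200L,
                              n_tumor = 50L,
                              n_normal = 50L,
                              n_cancer_types = 2L,
                              planted_cah_effects = NULL,
                              planted_cyt_ids = NULL,
                              planted_tnk_effects = NULL,
                              n_sorted = c(sorted_T = 8L, sorted_NK = 8L,
                                           sorted_other = 16L),
                              dispersion = 0.1,
                              library_size_mean = 1e5,
                              signature_noise_sd = NA_real_,
                              survival_hazard_ratio_per_unit = 0.5,
                              rng_seed = 1L) {
  # tolerate YAML-style named lists from configuration files
  if (is.list(planted_cah_effects)) planted_cah_effects <- unlist(planted_cah_effects)
  if (is.list(planted_tnk_effects)) planted_tnk_effects <- unlist(planted_tnk_effects)
  if (is.list(planted_cyt_ids)) planted_cyt_ids <- unlist(planted_cyt_ids)
  if (is.list(n_sorted)) n_sorted <- unlist(n_sorted)
  ids <- herv_ids(n_hervs)
  if (is.null(planted_cah_effects)) {
    planted_cah_effects <- c(
      stats::setNames(rep(2, 20L), ids[1:20]),       # tumor-overexpressed
      stats::setNames(rep(-2, 3L), ids[21:23])       # peritumoral decoys
    )
  }
  if (is.null(planted_cyt_ids)) {
    pos <- names(planted_cah_effects)[planted_cah_effects > 0]
    planted_cyt_ids <- pos[seq_len(min(5L, length(pos)))]
  }
  if (is.null(planted_tnk_effects)) {
    planted_tnk_effects <- stats::setNames(rep(2, 2L), ids[24:25])
  }
  cfg <- list(
    n_hervs = as.integer(n_hervs),
    n_tumor = as.integer(n_tumor),
    n_normal = as.integer(n_normal),
    n_cancer_types = as.integer(n_cancer_types),
    planted_cah_effects = planted_cah_effects,
    planted_cyt_ids = planted_cyt_ids,
    planted_tnk_effects = planted_tnk_effects,
    n_sorted = n_sorted,
    dispersion = dispersion,
    library_size_mean = library_size_mean,
    signature_noise_sd = signature_noise_sd,
    survival_hazard_ratio_per_unit = survival_hazard_ratio_per_unit,
    rng_seed = as.integer(rng_seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  counts <- c(cfg$n_hervs, cfg$n_tumor, cfg$n_normal, cfg$n_cancer_types,
              cfg$n_sorted)
  if (any(counts < 1L)) stop("all counts must be >= 1")
  if (!is.finite(cfg$dispersion) || cfg$dispersion <= 0) {
    stop("dispersion must be a finite positive number")
  }
  if (any(!is.finite(cfg$planted_cah_effects)) ||
      any(!is.finite(cfg$planted_tnk_effects))) {
    stop("effect sizes must be finite")
  }
  if (!is.finite(cfg$library_size_mean) || cfg$library_size_mean <= 0) {
    stop("library_size_mean must be finite and positive")
  }
  ids <- herv_ids(cfg$n_hervs)
  unknown <- setdiff(c(names(cfg$planted_cah_effects),
                       names(cfg$planted_tnk_effects), cfg$planted_cyt_ids),
                     ids)
  if (length(unknown)) stop("planted ids outside the HERV catalogue: ",
                            paste(unknown, collapse = ", "))
  pos_cah <- names(cfg$planted_cah_effects)[cfg$planted_cah_effects > 0]
  if (!all(cfg$planted_cyt_ids %in% pos_cah)) {
    stop("planted_cyt_ids must be a subset of the positive-effect planted CAHs")
  }
  invisible(cfg)
}

herv_ids <- function(n) sprintf("sherv_%04d", seq_len(n))

#' Simulate HERV raw counts and sample metadata
#'
#' Draws NB counts with mean `baseline * library_factor * 2^(effect * is_tumor)`
#' and the configured shared dispersion. Peritumoral samples share per-HERV
#' baselines with their matched tumors; sorted-cell samples (no tumor effect,
#' with the planted T/NK effects) are appended for the exclusion criterion.
#'
#' @param config A [simulation_config()].
#' @return List with `counts` (integer matrix, HERVs x samples) and
#'   `metadata` (`data.frame` of `sample_id`, `cancer_type`, `tissue_class`).
#' @export
simulate_counts <- function(config) {
  validate_simulation_config(config)
  set.seed(config$rng_seed)
  ids <- herv_ids(config$n_hervs)
  baseline <- stats::rlnorm(config$n_hervs, meanlog = log(30), sdlog = 1.2)
  names(baseline) <- ids
  rel <- baseline / sum(baseline)

  effect <- stats::setNames(rep(0, config$n_hervs), ids)
  effect[names(config$planted_cah_effects)] <- config$planted_cah_effects
  tnk_effect <- stats::setNames(rep(0, config$n_hervs), ids)
  tnk_effect[names(config$planted_tnk_effects)] <- config$planted_tnk_effects

  meta <- list()
  mu_cols <- list()
  for (c_idx in seq_len(config$n_cancer_types)) {
    cancer <- sprintf("cancer_%02d", c_idx)
    for (cls in c("tumor", "peritumoral")) {
      n_cls <- if (cls == "tumor") config$n_tumor else config$n_normal
      for (j in seq_len(n_cls)) {
        sid <- sprintf("%s_%s_%03d", cancer, substr(cls, 1, 1), j)
        lib <- config$library_size_mean * stats::rlnorm(1, 0, 0.15)
        fc <- if (cls == "tumor") 2^effect else rep(1, config$n_hervs)
        mu <- rel * fc
        mu_cols[[sid]] <- mu / sum(mu) * lib
        meta[[sid]] <- data.frame(sample_id = sid, cancer_type = cancer,
                                  tissue_class = cls,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  for (cls in names(config$n_sorted)) {
    for (j in seq_len(config$n_sorted[[cls]])) {
      sid <- sprintf("%s_%03d", cls, j)
      lib <- config$library_size_mean * stats::rlnorm(1, 0, 0.15)
      fc <- if (cls %in% c("sorted_T", "sorted_NK")) 2^tnk_effect
            else rep(1, config$n_hervs)
      mu <- rel * fc
      mu_cols[[sid]] <- mu / sum(mu) * lib
      meta[[sid]] <- data.frame(sample_id = sid, cancer_type = "sorted_pbmc",
                                tissue_class = cls, stringsAsFactors = FALSE)
    }
  }
  mu_mat <- do.call(cbind, mu_cols)
  counts <- matrix(
    stats::rnbinom(length(mu_mat), mu = mu_mat, size = 1 / config$dispersion),
    nrow = config$n_hervs,
    dimnames = list(ids, names(mu_cols))
  )
  list(counts = counts, metadata = do.call(rbind, c(meta, make.row.names = FALSE)))
}

#' Simulate immune signature scores from planted HERVs
#'
#' Each signature is the mean log2(CPM + 1) of the planted
#' cytotoxicity-associated HERVs plus Gaussian noise. Function signatures
#' (CYT, IFN-gamma) are left on the linear scale; cell-type (Xcell-like)
#' phenotype signatures are exponentiated (`exp(value / 2)`), i.e. they are
#' log-linear in the planted HERVs and nonnegative, matching the log-link
#' Poisson family used to analyze them.
#'
#' @param log2cpm Matrix of log2(CPM + 1), HERVs x samples.
#' @param planted_cyt_ids Ids driving every signature.
#' @param noise_sd Noise SD; `NA` = half the signal SD, computed over
#'   `noise_reference` samples.
#' @param seed Integer seed.
#' @param signatures Named character vector mapping signature name to kind
#'   (`"phenotype"` or `"function"`).
#' @param noise_reference Optional sample ids over which the signal SD for
#'   the automatic noise level is computed (default: all samples). Passing
#'   the tumor samples keeps the noise proportional to the biological
#'   variation the association analysis actually sees, rather than to the
#'   tumor-versus-normal separation.
#' @return `data.frame` with `sample_id`, `signature_name`, `value`, `kind`.
#' @export
simulate_signatures <- function(log2cpm, planted_cyt_ids, noise_sd = NA_real_,
                                seed = 1L,
                                signatures = c(CD8_T = "phenotype",
                                               CD4_T = "phenotype",
                                               CYT = "function",
                                               IFNG = "function"),
                                noise_reference = NULL) {
  missing <- setdiff(planted_cyt_ids, rownames(log2cpm))
  if (length(missing)) stop("planted ids not in expression matrix: ",
                            paste(missing, collapse = ", "))
  if (!is.na(noise_sd) && noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  signal <- colMeans(log2cpm[planted_cyt_ids, , drop = FALSE])
  sd_use <- if (is.na(noise_sd)) {
    ref <- if (is.null(noise_reference)) signal else signal[noise_reference]
    0.5 * stats::sd(ref)
  } else noise_sd
  res <- lapply(names(signatures), function(nm) {
    value <- signal + stats::rnorm(length(signal), 0, sd_use)
    if (signatures[[nm]] == "phenotype") value <- exp(value / 2)
    data.frame(sample_id = colnames(log2cpm), signature_name = nm,
               value = unname(value), kind = unname(signatures[[nm]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# uniform synonymous reverse translation of an amino-acid sequence
reverse_translate <- function(aa) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  codons <- vapply(strsplit(aa, "")[[1]], function(a) {
    opts <- by_aa[[a]]
    if (is.null(opts)) stop("cannot reverse-translate symbol: ", a)
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste(codons, collapse = "")
}

#' Simulate HERV nucleotide sequences with embedded protein fragments
#'
#' For each designated HERV, a window of a reference protein containing a
#' planted epitope is reverse-translated (uniform synonymous codon choice)
#' and embedded at a random frame and strand inside random background DNA.
#' Embedding records are returned as ground truth for recall tests.
#'
#' @param reference_proteins Named character vector /
#'   [Biostrings::AAStringSet] of reference proteins.
#' @param planted_epitopes `data.frame` with columns `peptide`, `protein`
#'   (the reference record containing the peptide) and optionally `embed_in`
#'   (list-column or ;-separated string of HERV ids).
#' @param herv_ids Ids of all HERVs to generate sequences for.
#' @param seed Integer seed.
#' @param seq_length Background sequence length in nt (default 2000).
#' @param window_aa Protein window embedded around each epitope (default 60).
#' @return List with `sequences` (named character vector of DNA) and `truth`
#'   (`data.frame`: `herv_id`, `peptide`, `protein`, `strand`, `frame`,
#'   `offset` 0-based on the forward strand).
#' @export
simulate_sequences <- function(reference_proteins, planted_epitopes, herv_ids,
                               seed = 1L, seq_length = 2000L, window_aa = 60L) {
  prot <- as_named_chr(reference_proteins)
  set.seed(seed)
  for (i in seq_len(nrow(planted_epitopes))) {
    p <- planted_epitopes$peptide[i]
    hostname <- planted_epitopes$protein[i]
    if (!hostname %in% names(prot) || !grepl(p, prot[[hostname]], fixed = TRUE)) {
      stop("epitope ", p, " is not contained in reference protein ", hostname)
    }
  }
  seqs <- vapply(herv_ids, function(id) {
    paste(sample(c("A", "C", "G", "T"), seq_length, replace = TRUE),
          collapse = "")
  }, character(1))

  truth <- list()
  # track used regions per herv to avoid overlapping embeddings
  used <- stats::setNames(vector("list", length(herv_ids)), herv_ids)
  for (i in seq_len(nrow(planted_epitopes))) {
    p <- planted_epitopes$peptide[i]
    hostname <- planted_epitopes$protein[i]
    targets <- planted_epitopes$embed_in[[i]]
    if (is.character(targets) && length(targets) == 1L && grepl(";", targets)) {
      targets <- strsplit(targets, ";")[[1]]
    }
    aa <- prot[[hostname]]
    pos <- regexpr(p, aa, fixed = TRUE)[1]
    w_start <- max(1L, pos - (window_aa - nchar(p)) %/% 2L)
    w_end <- min(nchar(aa), w_start + window_aa - 1L)
    fragment <- substr(aa, w_start, w_end)
    for (id in targets) {
      # stop codons flank the fragment so each embedding forms its own ORF
      # and cannot merge with a neighbouring same-frame embedding
      nt <- paste0("TAA", reverse_translate(fragment), "TAA")
      strand <- sample(c(1L, -1L), 1L)
      insert <- if (strand == 1L) nt else revcomp(nt)
      # non-overlapping random offset
      repeat {
        offset <- sample.int(seq_length - nchar(insert), 1L) - 1L
        span <- c(offset, offset + nchar(insert))
        clash <- any(vapply(used[[id]], function(u) {
          span[1] < u[2] && u[1] < span[2]
        }, logical(1)))
        if (!clash) break
      }
      used[[id]] <- c(used[[id]], list(span))
      s <- seqs[[id]]
      seqs[[id]] <- paste0(substr(s, 1, offset), insert,
                           substr(s, offset + nchar(insert) + 1L, seq_length))
      # frame of the fragment itself (3 nt in from the flanking stop)
      frag_off <- offset + 3L
      frame_local <- if (strand == 1L) (frag_off %% 3L) + 1L
                     else ((seq_length - (offset + nchar(insert) - 3L)) %% 3L) + 1L
      truth[[length(truth) + 1L]] <- data.frame(
        herv_id = id, peptide = p, protein = hostname,
        strand = strand, frame = strand * frame_local, offset = frag_off,
        fragment = fragment, stringsAsFactors = FALSE
      )
    }
  }
  list(sequences = seqs,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(herv_id = character(0), peptide = character(0)))
}

# deterministic random amino-acid string (no ambiguity codes)
random_protein <- function(n_aa, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(aa20, n_aa, replace = TRUE), collapse = "")
}

# anchor-positive 9-mer (position 2 L/M, position 9 V/L/I) for the test stub
random_epitope <- function(strong = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa20 <- strsplit("ACDEFGHIKNPQRSTWY", "")[[1]]  # avoid anchor residues
  core <- sample(aa20, 9, replace = TRUE)
  if (strong) {
    core[2] <- sample(c("L", "M"), 1)
    core[9] <- sample(c("V", "L", "I"), 1)
  } else {
    core[2] <- "G"
    core[9] <- "G"
  }
  paste(core, collapse = "")
}

#' Simulate methylation probes around HERV loci
#'
#' Places probes around each locus midpoint and draws per-sample beta values;
#' for `linked_ids` the beta decreases with the HERV's expression
#' (local demethylation), otherwise betas are independent noise.
#'
#' @param loci `data.frame` with `herv_id`, `chrom`, `start`, `end`.
#' @param log2cpm Expression matrix whose columns define the samples.
#' @param linked_ids HERVs whose local methylation tracks expression.
#' @param seed Integer seed.
#' @param n_probes Probes per locus (default 15).
#' @return `data.frame`: `chrom`, `pos`, one beta column per sample.
#' @export
simulate_methylation <- function(loci, log2cpm, linked_ids = character(0),
                                 seed = 1L, n_probes = 15L) {
  set.seed(seed)
  samples <- colnames(log2cpm)
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    mid <- (loci$start[i] + loci$end[i]) / 2
    offs <- sort(sample(c(-5000:-100, 100:5000), n_probes))
    expr <- log2cpm[loci$herv_id[i], ]
    z <- as.numeric(scale(expr))
    if (anyNA(z)) z <- rep(0, length(expr))
    linked <- loci$herv_id[i] %in% linked_ids
    betas <- t(vapply(seq_len(n_probes), function(j) {
      base <- stats::runif(1, 0.4, 0.8)
      if (linked) {
        b <- stats::plogis(stats::qlogis(base) - 1.5 * z +
                             stats::rnorm(length(z), 0, 0.1))
      } else {
        b <- stats::plogis(stats::qlogis(base) +
                             stats::rnorm(length(z), 0, 0.5))
      }
      pmin(pmax(b, 0), 1)
    }, numeric(length(samples))))
    out <- data.frame(chrom = loci$chrom[i], pos = mid + offs,
                      stringsAsFactors = FALSE)
    out[samples] <- as.data.frame(betas)
    out
  })
  do.call(rbind, rows)
}

#' Simulate survival times driven by a HERV-set score
#'
#' Exponential event times with hazard `h0 * HR^z`, where `z` is the
#' standardized (zero-mean, unit-SD) set score, and uniform administrative
#' censoring. Standardizing makes the hazard ratio scale-free with respect to
#' the HERV set size and expression units.
#'
#' @param set_score Named numeric vector of per-sample scores.
#' @param hazard_ratio_per_unit Hazard ratio per standard deviation of score.
#' @param seed Integer seed.
#' @param median_days Baseline median survival (default 1000 days).
#' @param admin_max Administrative censoring horizon (default 3000 days).
#' @return `data.frame`: `sample_id`, `time`, `event`.
#' @export
simulate_survival <- function(set_score, hazard_ratio_per_unit = 0.5,
                              seed = 1L, median_days = 1000,
                              admin_max = 3000) {
  set.seed(seed)
  h0 <- log(2) / median_days
  s <- stats::sd(set_score)
  z <- if (is.na(s) || s == 0) rep(0, length(set_score)) else
    (set_score - mean(set_score)) / s
  rate <- h0 * hazard_ratio_per_unit^z
  t_event <- stats::rexp(length(set_score), rate = rate)
  t_cens <- stats::runif(length(set_score), 0, admin_max)
  data.frame(sample_id = names(set_score),
             time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic input bundle
#'
#' Produces every input the pipeline consumes, with recoverable ground truth:
#' counts + metadata, log2 CPM, signature scores, synthetic reference
#' retroviral proteins (labelled `_synthetic`), HERV sequences with embedded
#' epitopes, a synthetic host proteome (containing one planted self-matching
#' epitope), genomic loci, methylation probes, and survival times tied to the
#' planted cyt-HERV set score.
#'
#' Planted epitopes fall into four classes: `shared` (anchor-strong binders
#' embedded in Gag/Pol windows; these must survive the whole funnel),
#' `weak_binder` (embedded in Gag but anchor-negative, eliminated at the
#' binding stage), `self` (anchor-strong, embedded in Gag and present in the
#' host proteome, eliminated at the proteome stage), and `nonhomologous`
#' (anchor-strong but embedded in a random non-retroviral protein window,
#' eliminated at the homology stage).
#'
#' @param config A [simulation_config()].
#' @return A list of class `"synthetic_bundle"`; see fields in the source /
#'   vignette. `truth` carries every planted label.
#' @export
simulate_bundle <- function(config = simulation_config()) {
  validate_simulation_config(config)
  seed <- config$rng_seed
  sim <- simulate_counts(config)
  log2cpm <- cpm_normalize(sim$counts)
  signatures <- simulate_signatures(
    log2cpm[, sim$metadata$tissue_class %in%
                c("tumor", "peritumoral"), drop = FALSE],
    config$planted_cyt_ids,
    noise_sd = config$signature_noise_sd, seed = seed + 1L,
    noise_reference =
      sim$metadata$sample_id[sim$metadata$tissue_class == "tumor"]
  )

  # reference proteins with planted epitopes at well-separated positions
  gag <- random_protein(400, seed = seed + 2L)
  pol <- random_protein(500)
  env <- random_protein(300)
  decoy_prot <- random_protein(300)
  ep_shared1 <- random_epitope(TRUE)
  ep_shared2 <- random_epitope(TRUE)
  ep_weak <- random_epitope(FALSE)
  ep_self <- random_epitope(TRUE)
  ep_nonhom <- random_epitope(TRUE)
  substr(gag, 50, 58) <- ep_shared1
  substr(gag, 150, 158) <- ep_weak
  substr(gag, 250, 258) <- ep_self
  substr(pol, 100, 108) <- ep_shared2
  substr(decoy_prot, 100, 108) <- ep_nonhom
  reference_proteins <- c(
    HML2_Gag_synthetic = gag,
    HML2_Pol_synthetic = pol,
    HML2_Env_synthetic = env,
    decoy_nonretroviral_synthetic = decoy_prot
  )

  ids <- herv_ids(config$n_hervs)
  cyt <- config$planted_cyt_ids
  pos_cah <- names(config$planted_cah_effects)[config$planted_cah_effects > 0]
  other_cah <- setdiff(pos_cah, cyt)
  planted_epitopes <- data.frame(
    peptide = c(ep_shared1, ep_shared2, ep_weak, ep_self, ep_nonhom),
    protein = c("HML2_Gag_synthetic", "HML2_Pol_synthetic",
                "HML2_Gag_synthetic", "HML2_Gag_synthetic",
                "decoy_nonretroviral_synthetic"),
    class = c("shared", "shared", "weak_binder", "self", "nonhomologous"),
    stringsAsFactors = FALSE
  )
  planted_epitopes$embed_in <- list(
    c(cyt, other_cah[seq_len(min(2L, length(other_cah)))]),  # shared1: cyt + 2
    cyt[seq_len(min(3L, length(cyt)))],                      # shared2: 3 cyt
    cyt[seq_len(min(2L, length(cyt)))],                      # weak binder
    cyt[seq_len(min(2L, length(cyt)))],                      # self-matching
    cyt[seq_len(min(2L, length(cyt)))]                       # non-homologous
  )
  seqres <- simulate_sequences(reference_proteins, planted_epitopes, ids,
                               seed = seed + 3L)

  # synthetic host proteome; one record carries the Gag window around ep_self
  set.seed(seed + 4L)
  proteome <- stats::setNames(
    vapply(1:20, function(i) random_protein(300), character(1)),
    sprintf("self_protein_%02d_synthetic", 1:20)
  )
  self_window <- substr(gag, 230, 280)
  proteome[["self_protein_01_synthetic"]] <-
    paste0(substr(proteome[["self_protein_01_synthetic"]], 1, 100),
           self_window,
           substr(proteome[["self_protein_01_synthetic"]], 101, 300))

  set.seed(seed + 5L)
  loci <- data.frame(
    herv_id = ids,
    chrom = sample(paste0("chr", 1:22), config$n_hervs, replace = TRUE),
    start = sample.int(1e8, config$n_hervs),
    stringsAsFactors = FALSE
  )
  loci$end <- loci$start + nchar(seqres$sequences)
  methylation <- simulate_methylation(loci, log2cpm,
                                      linked_ids = cyt, seed = seed + 6L)

  tumor_ids <- sim$metadata$sample_id[sim$metadata$tissue_class == "tumor"]
  set_score <- colMeans(log2cpm[cyt, tumor_ids, drop = FALSE])
  survival <- simulate_survival(
    set_score, config$survival_hazard_ratio_per_unit, seed = seed + 7L
  )

  structure(list(
    config = config,
    counts = sim$counts,
    metadata = sim$metadata,
    log2cpm = log2cpm,
    signatures = signatures,
    reference_proteins = reference_proteins,
    sequences = seqres$sequences,
    proteome = proteome,
    loci = loci,
    methylation = methylation,
    survival = survival,
    truth = list(
      planted_cah_effects = config$planted_cah_effects,
      planted_cah_ids = pos_cah,
      planted_normal_ids =
        names(config$planted_cah_effects)[config$planted_cah_effects < 0],
      planted_cyt_ids = cyt,
      planted_tnk_ids = names(config$planted_tnk_effects),
      epitopes = planted_epitopes,
      embeddings = seqres$truth,
      methylation_linked_ids = cyt
    )
  ), class = "synthetic_bundle")
}

#' Write a synthetic bundle to a directory of standard-format files
#'
#' Emits counts/metadata/signatures/methylation/survival TSVs, FASTA files
#' for HERV sequences, reference proteins and the host proteome, a BED file
#' of HERV loci, and a small GMT of the signature gene sets.
#'
#' @param bundle A [simulate_bundle()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts_tsv(bundle$counts, file.path(dir, "counts.tsv"))
  utils::write.table(bundle$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$signatures, file.path(dir, "signatures.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$methylation, file.path(dir, "methylation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$survival, file.path(dir, "survival.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(bundle$sequences),
    file.path(dir, "herv_sequences.fasta"))
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(bundle$reference_proteins),
    file.path(dir, "reference_proteins.fasta"))
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(bundle$proteome),
    file.path(dir, "proteome_synthetic.fasta"))
  gr <- GenomicRanges::GRanges(
    seqnames = bundle$loci$chrom,
    ranges = IRanges::IRanges(start = bundle$loci$start,
                              end = bundle$loci$end),
    name = bundle$loci$herv_id
  )
  rtracklayer::export(gr, file.path(dir, "herv_loci.bed"), format = "BED")
  invisible(dir)
}

#' Write / read a counts TSV (first column herv_id, header = sample ids)
#' @param counts Count matrix.
#' @param path Output path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(herv_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
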