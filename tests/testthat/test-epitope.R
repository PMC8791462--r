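test_that("homopolymer ORFs respect the inclusive length threshold", {
  dna <- strrep("A", 30)
  orfs <- six_frame_orfs(dna, min_len_aa = 10)
  plus1 <- orfs[orfs$frame == 1, ]
  expect_equal(plus1$aa_seq, "KKKKKKKKKK")
  expect_equal(plus1$nt_start, 0)
  expect_equal(plus1$nt_end, 30)
  expect_equal(nrow(six_frame_orfs(dna, min_len_aa = 11)), 0)
  expect_error(six_frame_orfs(""), "empty")
  expect_error(six_frame_orfs("ACGU"), "A,C,G,T,N")
})

test_that("N-containing codons translate to X without terminating an ORF", {
  dna <- paste0(strrep("GCT", 5), "ANT", strrep("GCT", 5))  # A x5, X, A x5
  orfs <- six_frame_orfs(dna, min_len_aa = 11)
  expect_true("AAAAAXAAAAA" %in% orfs$aa_seq)
})

test_that("six-frame detection matches the exhaustive oracle", {
  set.seed(41)
  for (rep in 1:10) {
    dna <- random_dna(300, alphabet = c("A", "C", "G", "T", "N"))
    got <- six_frame_orfs(dna, min_len_aa = 5)
    got_keys <- sort(paste(got$frame, got$aa_seq, got$nt_start, got$nt_end,
                           sep = ":"))
    expect_equal(got_keys, oracle_six_frame(dna, 5))
  }
})

test_that("reverse complement mirrors the ORF set across strands", {
  set.seed(42)
  dna <- random_dna(400)
  fwd <- six_frame_orfs(dna, min_len_aa = 5)
  rev <- six_frame_orfs(revcomp(dna), min_len_aa = 5)
  expect_setequal(fwd$aa_seq, rev$aa_seq)
  # coordinates mirror: forward [s, e) maps to [L - e, L - s)
  key_f <- sort(paste(fwd$aa_seq, fwd$nt_start, fwd$nt_end))
  key_r <- sort(paste(rev$aa_seq, 400 - rev$nt_end, 400 - rev$nt_start))
  expect_equal(key_f, key_r)
})

test_that("local alignment identity counts aligned columns", {
  a20 <- random_aa(20)
  hit <- local_align(a20, a20)
  expect_equal(hit$percent_identity, 100)
  b20 <- a20
  substr(b20, 10, 10) <- if (substr(a20, 10, 10) == "A") "W" else "A"
  hit2 <- local_align(a20, b20)
  # one substitution in 20 columns when the full-length alignment is optimal
  expect_true(hit2$percent_identity %in% c(95, 100) ||
                hit2$percent_identity > 90)
  expect_error(local_align("", a20), "empty")
})

test_that("Smith-Waterman scores equal the quadratic DP oracle", {
  set.seed(43)
  for (rep in 1:8) {
    a <- random_aa(40)
    b <- random_aa(40)
    expect_equal(local_align(a, b)$score, oracle_sw_score(a, b))
  }
  # and on related pairs, where gaps actually occur
  for (rep in 1:4) {
    a <- random_aa(50)
    b <- paste0(substr(a, 1, 20), substr(a, 26, 50))  # 5-aa deletion
    expect_equal(local_align(a, b)$score, oracle_sw_score(a, b))
  }
})

test_that("homology filter keeps Gag/Pol matches and rejects decoys", {
  set.seed(44)
  gag <- random_aa(300)
  env <- random_aa(300)
  refs <- c(HML2_Gag = gag, HML2_Env = env)
  frag <- substr(gag, 100, 160)
  shuffled <- paste(sample(strsplit(frag, "")[[1]]), collapse = "")
  env_frag <- substr(env, 50, 110)
  orfs <- data.frame(herv_id = c("h1", "h2", "h3"),
                     frame = 1L,
                     aa_seq = c(frag, shuffled, env_frag),
                     nt_start = 0L, nt_end = 3L * 61L,
                     length_aa = 61L, stringsAsFactors = FALSE)
  kept <- homology_filter(orfs, refs)
  expect_equal(kept$herv_id, "h1")  # exact Gag fragment survives
  expect_equal(kept$ref_protein_id, "HML2_Gag")
  expect_equal(kept$percent_identity, 100)
  # the Env-only hit survives if Env is added to the kept references
  kept2 <- homology_filter(orfs, refs, keep_refs = "Gag|Pol|Env")
  expect_setequal(kept2$herv_id, c("h1", "h3"))
  expect_error(homology_filter(orfs, refs, keep_refs = "Pol"), "keep_refs")
})

test_that("shuffled ORFs essentially never pass the e-value cutoff", {
  set.seed(45)
  gag <- random_aa(300)
  frag <- substr(gag, 100, 160)
  rejected <- sapply(1:50, function(i) {
    shuf <- paste(sample(strsplit(frag, "")[[1]]), collapse = "")
    hit <- local_align(shuf, gag, search_n = 300)
    hit$evalue > 0.05 || hit$percent_identity < 90
  })
  expect_gte(mean(rejected), 0.98)
})

test_that("binding prediction honors table lookups and the inclusive cutoff", {
  tab <- read.delim(system.file("extdata", "rank_table_synthetic.tsv",
                                package = "hervscreen"))
  res <- predict_binding(c("FLQFKTWWI", "YIDNSGKLI", "AAAAAAAAA", "QQQQQQQQQ"),
                         method = "table", rank_table = tab)
  got <- setNames(res$strong_binder, res$peptide)
  expect_true(got[["FLQFKTWWI"]])            # rank 0.2
  expect_true(got[["YIDNSGKLI"]])            # rank exactly 0.5: inclusive
  expect_false(got[["AAAAAAAAA"]])           # rank 35
  expect_false(got[["QQQQQQQQQ"]])           # absent from the table
  expect_true(is.na(res$percentile_rank[res$peptide == "QQQQQQQQQ"]))
  # allele-specific lookup
  resb <- predict_binding("FLQFKTWWI", allele = "HLA-B*07:02",
                          method = "table", rank_table = tab)
  expect_false(resb$strong_binder)
})

test_that("the anchor heuristic applies the documented stub rule", {
  res <- predict_binding(c("ALAAAAAAV", "AAAAAAAAA", "AMAAAAAAI"),
                         method = "anchor")
  expect_equal(res$strong_binder, c(TRUE, FALSE, TRUE))
  expect_error(predict_binding(c("SHORT"), method = "anchor"), NA)
  expect_error(predict_binding(c("AAAA", "AAAAAAAAA"), method = "anchor"),
               "same length")
  expect_error(predict_binding("AAAAAAAAA", allele = "HLA-B*07:02",
                               method = "anchor"), "HLA-A")
})

test_that("relocation counts distinct HERV ids, not occurrences", {
  pep <- "MKLVDDQSA"
  insert <- hervscreen:::reverse_translate(paste0(pep, "LLLLL"))
  set.seed(46)
  base <- random_dna(300)
  with_pep <- paste0(substr(base, 1, 90), insert,
                     substr(base, 91 + nchar(insert), 300), substr(base, 1, 42))
  seqs <- c(h1 = with_pep, h2 = with_pep, h3 = base)
  reloc <- relocate_epitopes(c(pep, "WWWWWWWWW"), seqs)
  sh <- reloc$sharing
  expect_equal(sh$sharing_count[sh$peptide == pep], 2)   # ids, twice-identical
  expect_equal(sh$sharing_count[sh$peptide == "WWWWWWWWW"], 0)
  expect_equal(sh$source_herv_ids[sh$peptide == pep], "h1;h2")
  # ties broken lexicographically by peptide at equal counts
  expect_equal(sh$peptide, sh$peptide[order(-sh$sharing_count, sh$peptide)])
  expect_error(relocate_epitopes(character(0), seqs), "no peptides")
  expect_error(relocate_epitopes(pep, character(0)), "empty scope")
})

test_that("relocation counts are monotone as the scope widens", {
  b <- simulate_bundle(fast_config(seed = 12))
  eps <- b$truth$epitopes$peptide[b$truth$epitopes$class == "shared"]
  cyt <- b$truth$planted_cyt_ids
  cah <- b$truth$planted_cah_ids
  r_cyt <- relocate_epitopes(eps, b$sequences[cyt])$sharing
  r_cah <- relocate_epitopes(eps, b$sequences[cah])$sharing
  r_all <- relocate_epitopes(eps, b$sequences)$sharing
  for (p in eps) {
    c1 <- r_cyt$sharing_count[r_cyt$peptide == p]
    c2 <- r_cah$sharing_count[r_cah$peptide == p]
    c3 <- r_all$sharing_count[r_all$peptide == p]
    expect_true(c1 <= c2 && c2 <= c3)
  }
})

test_that("proteome exclusion is an exact-substring rule", {
  prot <- c(p1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ", p2 = "GGGGGGGG")
  res <- proteome_exclusion(c("YIAKQRQIS", "YIAKQRQIA", "WWWWWWWWW"), prot)
  expect_equal(res$self_match, c(TRUE, FALSE, FALSE))
  expect_equal(res$kept, c(FALSE, TRUE, TRUE))
  # oracle equivalence on random inputs
  set.seed(47)
  proteome <- setNames(replicate(10, random_aa(120)), paste0("sp", 1:10))
  peps <- c(replicate(20, random_aa(9)),
            substr(proteome[[3]], 11, 19), substr(proteome[[7]], 50, 58))
  res2 <- proteome_exclusion(peps, proteome)
  expect_equal(res2$self_match, unname(oracle_proteome_flags(peps, proteome)))
  expect_error(proteome_exclusion("AAAAAAAAA", character(0)), "empty")
})
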