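test_that("pi values combine fold change and significance", {
  expect_equal(pi_value(2, 1e-5), 10)
  expect_equal(pi_value(3.7, 1), 0)
  expect_equal(pi_value(-2, 1e-5), -10)
  # linear in log2fc at fixed p; decreasing in p for positive log2fc
  expect_equal(pi_value(4, 1e-3), 2 * pi_value(2, 1e-3))
  expect_gt(pi_value(2, 1e-6), pi_value(2, 1e-4))
  # flooring keeps extreme p-values finite
  expect_true(is.finite(pi_value(2, 1e-310)))
  expect_error(pi_value(2, 0, p_floor = NULL), "flooring")
  expect_error(pi_value(2, 1.5), "<= 1")
})

test_that("pi reproduces the printed basal-breast worked example", {
  tab <- read.delim(system.file("extdata", "basal_brca_peptide_hervs.tsv",
                                package = "hervscreen"))
  row <- tab[tab$herv_id == "herv_4833", ]
  expect_equal(round(pi_value(row$log2FC, row$padj), 2), 306.11)
})

test_that("cumulative epitope scores are additive over containing HERVs", {
  presence <- rbind(pep1 = c(TRUE, TRUE, FALSE),
                    pep2 = c(TRUE, FALSE, FALSE),
                    pep3 = c(FALSE, FALSE, FALSE))
  colnames(presence) <- c("h1", "h2", "h3")
  pi <- c(h1 = 4, h2 = 6, h3 = 100)
  expect_warning(sc <- cumulative_epitope_score(presence, pi), "no HERV")
  got <- setNames(sc$score, sc$peptide)
  expect_equal(got[["pep1"]], 10)
  expect_equal(got[["pep2"]], 4)    # single HERV: score equals its pi
  expect_equal(got[["pep3"]], 0)
  # removing a containing HERV lowers the score by exactly its pi
  sc2 <- suppressWarnings(
    cumulative_epitope_score(presence[, c("h1", "h3"), drop = FALSE], pi))
  expect_equal(sc2$score[sc2$peptide == "pep1"], got[["pep1"]] - pi[["h2"]])
})

test_that("set scores average the requested rows and tercile cleanly", {
  lcpm <- rbind(h1 = 1:6, h2 = rep(0, 6))
  colnames(lcpm) <- paste0("s", 1:6)
  sc <- herv_set_score(lcpm, c("h1", "h2"))
  expect_equal(sc$set_score, (1:6) / 2)
  expect_equal(as.character(sc$tercile),
               rep(c("low", "intermediate", "high"), each = 2))
  # single-HERV set equals that HERV's expression
  expect_equal(herv_set_score(lcpm, "h1")$set_score, as.numeric(1:6))
  expect_error(herv_set_score(lcpm, character(0)), "empty")
  expect_error(herv_set_score(lcpm, "absent"), "not found")
})

test_that("terciles are invariant to monotone transforms and warn when flat", {
  set.seed(51)
  x <- rnorm(20)
  expect_equal(assign_terciles(x), assign_terciles(exp(x)))
  expect_equal(assign_terciles(x), assign_terciles(rank(x)))
  sizes <- table(assign_terciles(rnorm(65)))
  expect_lte(max(sizes) - min(sizes), 1)
  expect_warning(t3 <- assign_terciles(rep(1, 5)), "constant")
  expect_equal(length(unique(t3)), 1L)
})

test_that("the log-rank test matches a hand-computed Mantel-Cox table", {
  # textbook-style fixture, 8 subjects, no ties across groups at event times
  time <- c(1, 3, 5, 7, 2, 4, 6, 8)
  event <- c(1, 1, 1, 0, 1, 1, 0, 1)
  group <- rep(c("a", "b"), each = 4)
  # direct summation of observed - expected per event time (group a):
  # event times: 1,2,3,4,5,8
  at_risk_a <- c(4, 3, 3, 2, 2, 0)
  at_risk_b <- c(4, 4, 3, 3, 2, 1)
  obs_a <- c(1, 0, 1, 0, 1, 0)
  n <- at_risk_a + at_risk_b
  e_a <- at_risk_a / n
  v <- at_risk_a * at_risk_b / n^2  # single event at each time
  chisq_hand <- sum(obs_a - e_a)^2 / sum(v)
  lr <- logrank_test(time, event, group)
  expect_equal(lr$chisq, chisq_hand, tolerance = 1e-10)
  expect_equal(lr$df, 1L)
  expect_equal(lr$p, pchisq(chisq_hand, 1, lower.tail = FALSE))
})

test_that("identical groups give a null log-rank statistic", {
  time <- rep(c(2, 4, 6, 8), 2)
  event <- rep(c(1, 1, 0, 1), 2)
  group <- rep(c("a", "b"), each = 4)
  lr <- logrank_test(time, event, group)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  expect_error(logrank_test(1:4, rep(0, 4), rep(c("a", "b"), 2)), "events")
  expect_error(logrank_test(1:4, rep(1, 4), rep("a", 4)), "two groups")
})

test_that("log-rank power is adequate for a threefold hazard ratio", {
  set.seed(52)
  hits <- replicate(60, {
    t1 <- rexp(40, 1)
    t2 <- rexp(40, 3)
    cens <- runif(80, 0, quantile(c(t1, t2), 0.8) * 2)
    tt <- pmin(c(t1, t2), cens)
    ev <- as.integer(c(t1, t2) <= cens)
    logrank_test(tt, ev, rep(c("a", "b"), each = 40))$p < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("methylation correlation picks the nearest probes and labels signs", {
  samples <- paste0("s", 1:30)
  set.seed(53)
  expr <- matrix(rnorm(2 * 30, 5), 2, dimnames = list(c("h1", "h2"), samples))
  loci <- data.frame(herv_id = c("h1", "h2"), chrom = "chr1",
                     start = 1000, end = 3000)
  # probes at distances 1..20 from the midpoint (2000); betas for probes
  # 1..10 decrease monotonically with h1 expression
  probes <- data.frame(chrom = "chr1", pos = 2000 + 1:20)
  r <- rank(expr["h1", ])
  for (i in seq_along(samples)) {
    probes[[samples[i]]] <- c(rep(1 - r[i] / 31, 10), runif(10))
  }
  mc <- methylation_correlation(loci, probes, expr)
  expect_equal(mc$rho[mc$herv_id == "h1"], -1)
  expect_equal(mc$label[mc$herv_id == "h1"], "demethylation")
  expect_equal(mc$label[mc$herv_id == "h2"], "none")
  expect_true(all(mc$mean_beta >= 0 & mc$mean_beta <= 1))
  probes_few <- probes[1:5, ]
  expect_error(methylation_correlation(loci, probes_few, expr), "fewer than")
})

test_that("null methylation correlations are calibrated before adjustment", {
  set.seed(54)
  samples <- paste0("s", 1:40)
  nh <- 60
  expr <- matrix(rnorm(nh * 40, 5), nh,
                 dimnames = list(paste0("h", 1:nh), samples))
  loci <- data.frame(herv_id = paste0("h", 1:nh), chrom = "chr1",
                     start = seq(1e4, by = 1e5, length.out = nh), end = NA)
  loci$end <- loci$start + 2000
  probes <- do.call(rbind, lapply(seq_len(nh), function(i) {
    df <- data.frame(chrom = "chr1",
                     pos = loci$start[i] + 1000 + seq(-900, 900, length.out = 12))
    df[samples] <- matrix(runif(12 * 40), 12)
    df
  }))
  mc <- methylation_correlation(loci, probes, expr)
  expect_lt(mean(mc$pvalue < 0.05), 0.15)   # ~5% expected, generous MC bound
  expect_true(all(mc$label == "none"))
})
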