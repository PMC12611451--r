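test_that("hypergeometric tail matches enumeration and closed forms", {
  # P(X >= 0) = 1 for any valid configuration
  expect_equal(hypergeom_tail(0, 5, 3, 20), 1)
  # both marked balls drawn in 2 of 4: 1/C(4,2) = 1/6 by enumerating draws
  expect_equal(hypergeom_tail(2, 2, 2, 4), 1 / 6)
  # larger case against the explicit pmf summation
  expect_equal(hypergeom_tail(5, 10, 20, 1000),
               hyper_tail_oracle(5, 10, 20, 1000))
  # full-overlap limit: drawing the whole pathway, p = 1/C(N, K)
  expect_equal(hypergeom_tail(20, 20, 20, 1000), 1 / choose(1000, 20))
})

test_that("hypergeometric tail validates its bounds", {
  expect_error(hypergeom_tail(3, 2, 5, 10), "min")
  expect_error(hypergeom_tail(1, 11, 5, 10), "exceed N")
  expect_error(hypergeom_tail(-1, 2, 5, 10), "non-negative")
  expect_error(hypergeom_tail(0.5, 2, 5, 10), "integers")
})

test_that("BH adjustment reproduces the hand-applied step-up procedure", {
  # m = 3: raw steps are 0.01*3/1, 0.02*3/2, 0.03*3/3 = 0.03 each, so the
  # step-up minima give 0.03 everywhere
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # independent step-up oracle on random vectors of <= 10 p-values
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q_sorted <- pmin(1, p[o] * m / seq_len(m))
    for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
    q <- numeric(m); q[o] <- q_sorted; q
  }
  withr::local_seed(21)
  for (i in 1:50) {
    p <- round(stats::runif(sample(2:10, 1)), 3)
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
})

test_that("BH q-values dominate p-values and are monotone on the sorted scale", {
  withr::local_seed(8)
  for (i in 1:20) {
    p <- stats::runif(50)
    q <- bh_adjust(p)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    # tied p-values share a q-value
    p2 <- c(p, p[1])
    q2 <- bh_adjust(p2)
    expect_equal(q2[1], q2[length(p2)])
  }
})

test_that("ORA flags an exactly-overlapping pathway with the closed-form p", {
  genes <- sprintf("G%04d", 1:1000)
  pc <- pathway_collection("pw1", "whole-query pathway",
                           list(genes[1:20]), background = genes)
  res <- run_ora(genes[1:20], pc, ora_config())
  expect_equal(res$p_raw, 1 / choose(1000, 20))
  expect_equal(res$k, 20L)
  expect_true(res$significant)
  expect_error(run_ora("NOT_IN_BACKGROUND", pc), "disjoint")
})

test_that("ORA significance responds monotonically to its thresholds", {
  bundle <- generate_interactome(sim_config(seed = 9L))
  query <- bundle$truth$query_genes
  loose <- run_ora(query, bundle$pathways,
                   ora_config(fdr_threshold = 0.2, min_overlap_genes = 1))
  strict_fdr <- run_ora(query, bundle$pathways,
                        ora_config(fdr_threshold = 0.01, min_overlap_genes = 1))
  strict_k <- run_ora(query, bundle$pathways,
                      ora_config(fdr_threshold = 0.2, min_overlap_genes = 30))
  sig <- function(r) r$pathway_id[r$significant]
  expect_true(all(sig(strict_fdr) %in% sig(loose)))
  expect_true(all(sig(strict_k) %in% sig(loose)))
})

test_that("the planted enriched pathway attains the smallest q-value", {
  for (s in c(2L, 4L, 6L)) {
    bundle <- generate_interactome(sim_config(seed = s))
    res <- run_ora(bundle$truth$query_genes, bundle$pathways, ora_config())
    expect_equal(res$pathway_id[1], bundle$truth$planted_pathway)
    expect_true(res$significant[1])
  }
})

test_that("raw ORA p-values for a fixed pathway are conservative under the null", {
  # discreteness makes the hypergeometric tail stochastically >= uniform
  withr::local_seed(33)
  genes <- sprintf("G%03d", 1:400)
  pc <- pathway_collection("pw", "fixed", list(genes[1:40]), background = genes)
  p <- replicate(400, {
    q <- sample(genes, 30)
    k <- length(intersect(q, genes[1:40]))
    hypergeom_tail(k, 40, 30, 400)
  })
  for (t in c(0.05, 0.1, 0.25, 0.5)) {
    mc_err <- 3 * sqrt(t * (1 - t) / length(p))
    expect_lte(mean(p <= t), t + mc_err)
  }
})

test_that("pathway categorization matches keywords in priority order", {
  res <- data.frame(
    pathway_name = c("Interleukin‐1 signalling",
                     "PIP3 activates AKT signalling",
                     "SUMOylation of DNA replication proteins",
                     "RNA Polymerase II Transcription Termination",
                     "zzz unmatched zzz"),
    stringsAsFactors = FALSE
  )
  out <- categorize_pathways(res, ora_config())
  expect_equal(out$category,
               c("immune", "asd_related", "replication", "transcription",
                 "other"))
})

test_that("relevant genes clear per-category pathway-count cutoffs", {
  genes <- sprintf("G%03d", 1:200)
  # gene G001 sits in 3 transcription pathways; G002 in only 2; G003 in 2
  # replication pathways where the cutoff is 2. The query contains every
  # pathway gene, against a larger background, so all five pathways come
  # out significant.
  sets <- list(
    c("G001", "G002", genes[10:25]), c("G001", "G002", genes[26:41]),
    c("G001", genes[42:57]), c("G003", genes[10:25]), c("G003", genes[26:41])
  )
  pc <- pathway_collection(sprintf("p%d", 1:5),
                           c("mRNA splicing alpha", "mRNA splicing beta",
                             "mRNA splicing gamma", "DNA replication one",
                             "DNA replication two"),
                           sets, background = genes)
  cfg <- ora_config(fdr_threshold = 0.05, min_overlap_genes = 1)
  res <- categorize_pathways(run_ora(genes[1:60], pc, cfg), cfg)
  rel <- select_relevant_genes(res, pc, cfg)
  expect_true("G001" %in% rel$transcription)
  expect_false("G002" %in% rel$transcription)
  expect_true("G003" %in% rel$replication)
})

test_that("chord export lists one row per gene-pathway incidence", {
  genes <- sprintf("G%02d", 1:40)
  pc <- pathway_collection("p1", "interleukin signalling",
                           list(genes[1:10]), background = genes)
  cfg <- ora_config(fdr_threshold = 1, min_overlap_genes = 1)
  res <- categorize_pathways(run_ora(genes[1:5], pc, cfg), cfg)
  out <- chord_export(res, pc)
  expect_equal(nrow(out), 5L)
  expect_equal(unique(out$category), "immune")
})
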