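shared5 <- c("CREBBP", "NOTCH1", "PSMD11", "SRSF11", "TBL1X")

test_that("risk cross-referencing intersects with the catalog", {
  cat <- risk_fixture()
  expect_equal(cross_reference_risk(c("NOTCH1", "FAKE1"), cat), "NOTCH1")
  expect_equal(cross_reference_risk(character(0), cat), character(0))
  # the published overlap-figure gene lists all sit in the catalog
  lists <- jsonlite::read_json(fixture("figure8_gene_lists.json"),
                               simplifyVector = TRUE)
  expect_setequal(cross_reference_risk(lists$asd_only, cat),
                  sort(lists$asd_only))
})

test_that("the two published gene columns share exactly five risk genes", {
  cat <- risk_fixture()
  a <- cross_reference_risk(fixture_gene_column("table1_asd_network.tsv"), cat)
  b <- cross_reference_risk(fixture_gene_column("table2_placenta_network.tsv"),
                            cat)
  vr <- venn_partition(a, b, labels = c("ASD", "placenta"))
  expect_length(vr$shared, 5L)
  expect_setequal(vr$shared, shared5)
})

test_that("venn partitions are disjoint and reconstruct the inputs", {
  expect_equal(venn_partition(c("A", "B"), c("A", "B"))$a_only, character(0))
  expect_length(venn_partition(c("A", "B"), c("C"))$shared, 0L)
  withr::local_seed(14)
  for (i in 1:25) {
    a <- sample(LETTERS, sample(0:15, 1))
    b <- sample(LETTERS, sample(0:15, 1))
    vr <- venn_partition(a, b)
    expect_length(intersect(vr$a_only, vr$shared), 0L)
    expect_length(intersect(vr$b_only, vr$shared), 0L)
    expect_setequal(c(vr$a_only, vr$shared), unique(a))
    expect_setequal(c(vr$b_only, vr$shared), unique(b))
  }
})

test_that("network assembly keeps the documented sponge-to-gene chain", {
  net <- build_network(placenta_map(), tables_targets(), shared5)
  cm <- net$circ_mirna_edges
  mg <- net$mirna_gene_edges
  expect_true(any(cm$circRNA == "hsa-MAN1A2_0008" & cm$miRNA == "hsa-miR-623"))
  expect_true(any(mg$miRNA == "hsa-miR-623" & mg$gene == "NOTCH1"))
})

test_that("genes without regulators give an empty network with a warning", {
  expect_warning(
    net <- build_network(placenta_map(), tables_targets(), "UNREGULATED1"),
    "empty")
  expect_length(net$nodes$circRNA, 0L)
})

test_that("assembled networks are tripartite with no dangling miRNAs", {
  withr::local_seed(19)
  for (i in 1:25) {
    tri <- random_triple()
    net <- suppressWarnings(build_network(tri$sponge, tri$targets,
                                          sample(tri$genes, 3)))
    expect_setequal(net$circ_mirna_edges$miRNA, net$mirna_gene_edges$miRNA)
  }
  expect_error(
    cerna_network(data.frame(circRNA = "c1", miRNA = "hsa-miR-1"),
                  data.frame(miRNA = "hsa-miR-2", gene = "G1")),
    "dangling")
})

test_that("coverage ranking flags the full-cover candidate on the placental map", {
  net <- build_network(placenta_map(), tables_targets(), shared5)
  cov <- coverage_rank(net, shared5)
  top <- cov[cov$full_cover, ]
  expect_equal(top$circRNA, "hsa-MAN1A2_0008")
  expect_equal(top$coverage_count, 5L)
  expect_setequal(top$covered_genes[[1]], shared5)
})

test_that("no circRNA of the condition map covers all five shared genes", {
  net <- build_network(asd_map(), tables_targets(), shared5)
  cov <- coverage_rank(net, shared5)
  expect_false(any(cov$full_cover))
  # best coverage, by enumerating length-2 paths on the 19 printed rows:
  # the top condition-group sponge reaches 4 of the 5 genes
  expect_equal(max(cov$coverage_count), 4L)
})

test_that("single-edge network covers its single target", {
  net <- cerna_network(data.frame(circRNA = "c1", miRNA = "hsa-miR-1"),
                       data.frame(miRNA = "hsa-miR-1", gene = "G1"))
  cov <- coverage_rank(net, "G1")
  expect_true(cov$full_cover)
})

test_that("adding sponge edges never decreases coverage", {
  withr::local_seed(23)
  for (i in 1:10) {
    tri <- random_triple(nc = 6, nm = 8, ng = 5, e1 = 14, e2 = 15)
    net1 <- suppressWarnings(build_network(tri$sponge, tri$targets, tri$genes))
    # add two extra sponge edges and rebuild
    extra <- suppressMessages(sponge_map(
      c(tri$sponge$edges$circRNA, "hsa-C001_0001", "hsa-C002_0001"),
      c(tri$sponge$edges$miRNA, "hsa-miR-001", "hsa-miR-002")))
    net2 <- suppressWarnings(build_network(extra, tri$targets, tri$genes))
    cov1 <- coverage_rank(net1, tri$genes)
    cov2 <- coverage_rank(net2, tri$genes)
    common <- intersect(cov1$circRNA, cov2$circRNA)
    c1 <- stats::setNames(cov1$coverage_count, cov1$circRNA)[common]
    c2 <- stats::setNames(cov2$coverage_count, cov2$circRNA)[common]
    expect_true(all(c2 >= c1))
  }
})

test_that("the placental network admits a minimum cover of size one", {
  net <- build_network(placenta_map(), tables_targets(), shared5)
  mc <- min_cover(net, shared5)
  expect_equal(as.character(mc), "hsa-MAN1A2_0008")
  expect_equal(attr(mc, "cover_mode"), "exact")
  expect_length(min_cover(net, character(0)), 0L)
})

test_that("min_cover reports uncoverable genes by name", {
  net <- build_network(placenta_map(), tables_targets(), shared5)
  expect_error(min_cover(net, c(shared5, "ZZZ9")), "ZZZ9")
})

test_that("exact min_cover matches the exhaustive subset scan; greedy never beats it", {
  withr::local_seed(29)
  for (i in 1:40) {
    tri <- random_triple(nc = sample(4:9, 1), nm = 8, ng = 5, e1 = 20, e2 = 14)
    net <- suppressWarnings(build_network(tri$sponge, tri$targets, tri$genes))
    cov <- coverage_rank(net, tri$genes)
    coverable <- sort(unique(unlist(cov$covered_genes)))
    if (!length(coverable)) next
    exact <- min_cover(net, coverable)
    oracle <- min_cover_oracle(
      stats::setNames(cov$covered_genes, cov$circRNA), coverable)
    expect_equal(length(exact), length(oracle))
    greedy <- min_cover(net, coverable, exact_limit = 0L)
    expect_gte(length(greedy), length(exact))
  }
})

test_that("planted two-circRNA covers are found exactly", {
  # two circRNAs each exclusively cover half the targets; no single cover
  net <- cerna_network(
    data.frame(circRNA = c("cA", "cA", "cB", "cB", "cC"),
               miRNA = paste0("hsa-miR-", c(1, 2, 3, 4, 1))),
    data.frame(miRNA = paste0("hsa-miR-", 1:4),
               gene = c("G1", "G2", "G3", "G4"))
  )
  mc <- min_cover(net, c("G1", "G2", "G3", "G4"))
  expect_setequal(as.character(mc), c("cA", "cB"))
})

test_that("shared miRNAs between the groups match the published annotation", {
  sm <- shared_mirnas("hsa-MAN1A2_0008", placenta_map(), asd_map())
  expect_setequal(names(sm),
                  c("hsa-miR-4722-5p", "hsa-miR-6875-3p", "hsa-miR-942-5p"))
  expect_setequal(sm[["hsa-miR-6875-3p"]],
                  c("hsa-PAPPA2_0005", "hsa-PAPPA_0016", "hsa-SCLT1_0001",
                    "hsa-ERC1_0001"))
  expect_error(shared_mirnas("hsa-NOPE_0001", placenta_map(), asd_map()),
               "not found")
})

test_that("disjoint sponge maps share no miRNAs", {
  a <- suppressMessages(sponge_map("c1", "hsa-miR-1"))
  b <- suppressMessages(sponge_map("c2", "hsa-miR-2"))
  expect_length(shared_mirnas("c1", a, b), 0L)
})
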