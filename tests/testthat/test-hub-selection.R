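test_that("in-degree counts distinct circRNA partners per miRNA", {
  prof <- compute_in_degree(asd_map())
  expect_equal(prof[["hsa-miR-766-5p"]], 6L)  # six distinct sponges in group A
  expect_equal(sum(as.integer(prof)), 19L)

  single <- suppressMessages(sponge_map("c1", "hsa-miR-1"))
  expect_equal(as.integer(compute_in_degree(single)), 1L)

  star <- suppressMessages(sponge_map(sprintf("c%d", 1:7), "hsa-miR-9"))
  expect_equal(as.integer(compute_in_degree(star)), 7L)

  empty <- suppressMessages(sponge_map(character(0), character(0)))
  expect_error(compute_in_degree(empty), "no edges")
})

test_that("elbow cutoff sits at the maximum chord distance, ties toward stricter", {
  # frozen from the brute-force chord-distance oracle on this 5-point curve:
  # distances (0, 0.962, 1.374, 0.687, 0) peak at the third point
  expect_equal(elbow_cutoff(c(15L, 8L, 3L, 2L, 1L)), 3L)
  expect_equal(elbow_oracle(c(15L, 8L, 3L, 2L, 1L)), 3L)

  # strictly linear curve: all distances zero, tie rule forces the max
  expect_equal(elbow_cutoff(5:1), 5L)

  # flat profile: degenerate chord, returns max with a warning
  expect_warning(cut <- elbow_cutoff(rep(4L, 10)), "degenerate")
  expect_equal(cut, 4L)
})

test_that("elbow cutoff agrees with the brute-force scan on random profiles", {
  withr::local_seed(11)
  for (i in 1:300) {
    degs <- sample(1:50, sample(3:25, 1))
    expect_equal(elbow_cutoff(degs), elbow_oracle(degs))
  }
})

test_that("frequent-miRNA selection applies an inclusive threshold", {
  prof <- structure(c(a = 9L, b = 8L, c = 7L), class = "degree_profile")
  expect_equal(select_frequent_mirnas(prof, 8), c("a", "b"))
  expect_setequal(select_frequent_mirnas(prof, 1), c("a", "b", "c"))
  expect_message(sel <- select_frequent_mirnas(prof, 99), "no miRNA")
  expect_length(sel, 0L)
  expect_error(select_frequent_mirnas(prof, 0), ">= 1")
})

test_that("raising the cutoff never enlarges the selected set", {
  withr::local_seed(5)
  for (i in 1:20) {
    map <- random_sponge(15, 20, 60)
    prof <- compute_in_degree(map)
    prev <- select_frequent_mirnas(prof, 1)
    for (cutoff in 2:6) {
      cur <- select_frequent_mirnas(prof, cutoff)
      expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("reverse search ranks circRNAs by selected-miRNA hit count", {
  map <- suppressMessages(sponge_map(
    c("c1", "c1", "c2"), c("hsa-miR-1", "hsa-miR-2", "hsa-miR-1")))
  out <- reverse_search(map, c("hsa-miR-1", "hsa-miR-2"),
                        hub_selection_config(top_k = 2))
  expect_equal(out$circRNA, c("c1", "c2"))
  expect_equal(out$hit_count, c(2L, 1L))
  expect_error(reverse_search(map, character(0)), "empty")
})

test_that("the placental map's top reverse-search hit sponges five hub miRNAs", {
  t2 <- placenta_map()
  out <- reverse_search(t2, unique(t2$edges$miRNA))
  expect_equal(out$circRNA[1], "hsa-MAN1A2_0008")
  expect_equal(out$hit_count[1], 5L)
  # hit counts are non-increasing down the ranking
  expect_true(all(diff(out$hit_count) <= 0))
})

test_that("tie policy controls truncation at the top-k boundary", {
  # 6 circRNAs all tied at 1 hit
  map <- suppressMessages(sponge_map(sprintf("c%d", 1:6), "hsa-miR-1"))
  keep <- reverse_search(map, "hsa-miR-1", hub_selection_config(top_k = 3))
  expect_equal(nrow(keep), 6L)
  strict <- reverse_search(map, "hsa-miR-1",
                           hub_selection_config(top_k = 3,
                                                tie_policy = "lexicographic"))
  expect_equal(strict$circRNA, c("c1", "c2", "c3"))
})

test_that("elbow-based selection recovers the planted hub miRNAs", {
  bundle <- generate_interactome(sim_config(seed = 3L))
  prof <- compute_in_degree(bundle$sponge)
  sel <- select_frequent_mirnas(prof, elbow_cutoff(prof))
  expect_setequal(sel, bundle$truth$planted_hubs)
})

test_that("a circRNA wired to every selected miRNA ranks first in reverse search", {
  bundle <- generate_interactome(sim_config(seed = 3L))
  hubs <- bundle$truth$planted_hubs
  boosted <- suppressMessages(sponge_map(
    c(bundle$sponge$edges$circRNA, rep("hsa-AAACOVER_0001", length(hubs))),
    c(bundle$sponge$edges$miRNA, hubs)))
  out <- reverse_search(boosted, hubs)
  expect_equal(out$circRNA[1], "hsa-AAACOVER_0001")
  expect_equal(out$hit_count[1], length(hubs))
})
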