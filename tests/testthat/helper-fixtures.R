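# Shared helpers: fixture paths and small random-instance builders used by
# the property-style tests.

fixture <- function(name) cerna_extdata(name)

asd_map <- function() {
  suppressMessages(read_sponge_table(fixture("table1_asd_network.tsv"), "ASD"))
}

placenta_map <- function() {
  suppressMessages(read_sponge_table(fixture("table2_placenta_network.tsv"),
                                     "placenta"))
}

tables_targets <- function() {
  suppressMessages(read_target_map(fixture("tables_target_map.tsv"), "strong"))
}

risk_fixture <- function() {
  suppressMessages(read_risk_catalog(fixture("synthetic_risk_catalog.tsv")))
}

fixture_gene_column <- function(name) {
  unique(utils::read.delim(fixture(name), stringsAsFactors = FALSE)$gene)
}

# uniform random bipartite sponge map over nc circRNAs and nm miRNAs
random_sponge <- function(nc, nm, n_edges) {
  suppressMessages(sponge_map(
    sprintf("hsa-C%03d_0001", sample(nc, n_edges, replace = TRUE)),
    sprintf("hsa-miR-%03d", sample(nm, n_edges, replace = TRUE)),
    group_label = "rand"
  ))
}

# random tripartite instance: sponge + strong target map + gene universe
random_triple <- function(nc = 8, nm = 10, ng = 6, e1 = 25, e2 = 20) {
  sponge <- random_sponge(nc, nm, e1)
  targets <- suppressMessages(target_map(
    sprintf("hsa-miR-%03d", sample(nm, e2, replace = TRUE)),
    sprintf("G%02d", sample(ng, e2, replace = TRUE)),
    "strong"
  ))
  list(sponge = sponge, targets = targets,
       genes = sprintf("G%02d", seq_len(ng)))
}

# independent brute-force oracle for the elbow rule: point-to-line distance
# via explicit projection onto the chord, scanned in a loop
elbow_oracle <- function(degrees) {
  y <- sort(unique(as.integer(degrees)), decreasing = TRUE)
  d <- length(y)
  if (d < 3L) return(max(y))
  a <- c(1, y[1]); b <- c(d, y[d])
  u <- (b - a) / sqrt(sum((b - a)^2))
  best_i <- 1L; best_dist <- -1
  for (i in seq_len(d)) {
    p <- c(i, y[i]) - a
    perp <- p - sum(p * u) * u
    dist <- sqrt(sum(perp^2))
    if (dist > best_dist + 1e-12) {
      best_dist <- dist
      best_i <- i
    }
  }
  y[best_i]
}

# exhaustive set-cover oracle: scan all 2^n subsets, smallest covering size
min_cover_oracle <- function(covered, targets) {
  ids <- names(covered)
  n <- length(ids)
  best <- NULL
  for (mask in seq_len(2^n) - 1L) {
    subset <- ids[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
    if (all(targets %in% unlist(covered[subset], use.names = FALSE))) {
      if (is.null(best) || length(subset) < length(best)) best <- subset
    }
  }
  best
}

# exhaustive hypergeometric tail by summing the pmf built from choose()
hyper_tail_oracle <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}
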