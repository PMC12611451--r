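# Risk-catalog cross-referencing, two-group Venn partitions, tripartite
# ceRNA network assembly, per-circRNA gene-coverage ranking, minimum set
# cover and shared-miRNA analysis between groups.

#' Construct a tripartite ceRNA network
#'
#' Low-level constructor; most users will call [build_network()]. Validates
#' the tripartite structure: edges exist only circRNA -> miRNA and
#' miRNA -> gene, and every miRNA node has at least one edge in each layer
#' (no dangling intermediates).
#'
#' @param circ_mirna_edges data.frame with columns `circRNA`, `miRNA`.
#' @param mirna_gene_edges data.frame with columns `miRNA`, `gene`.
#' @return An object of class `cerna_network` with elements
#'   `circ_mirna_edges`, `mirna_gene_edges` and `nodes` (node ids per layer).
#' @export
cerna_network <- function(circ_mirna_edges, mirna_gene_edges) {
  cm <- unique(data.frame(circRNA = normalize_circ_id(as.character(circ_mirna_edges$circRNA)),
                          miRNA = normalize_mirna_id(as.character(circ_mirna_edges$miRNA)),
                          stringsAsFactors = FALSE))
  mg <- unique(data.frame(miRNA = normalize_mirna_id(as.character(mirna_gene_edges$miRNA)),
                          gene = normalize_gene_symbol(as.character(mirna_gene_edges$gene)),
                          stringsAsFactors = FALSE))
  if (nrow(cm) + nrow(mg) > 0L) {
    dangling <- union(setdiff(cm$miRNA, mg$miRNA), setdiff(mg$miRNA, cm$miRNA))
    if (length(dangling)) {
      stop(sprintf("dangling miRNA node(s) lacking an edge in one layer: %s",
                   paste(utils::head(sort(dangling), 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  cm <- cm[order(cm$circRNA, cm$miRNA), , drop = FALSE]
  mg <- mg[order(mg$miRNA, mg$gene), , drop = FALSE]
  rownames(cm) <- rownames(mg) <- NULL
  structure(list(
    circ_mirna_edges = cm,
    mirna_gene_edges = mg,
    nodes = list(circRNA = sort(unique(cm$circRNA)),
                 miRNA = sort(unique(cm$miRNA)),
                 gene = sort(unique(mg$gene)))
  ), class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf("<cerna_network>: %d circRNAs -> %d miRNAs -> %d genes (%d + %d edges)\n",
              length(x$nodes$circRNA), length(x$nodes$miRNA), length(x$nodes$gene),
              nrow(x$circ_mirna_edges), nrow(x$mirna_gene_edges)))
  invisible(x)
}

#' Cross-reference genes with a risk catalog
#'
#' Returns the genes previously described in the risk catalog (set
#' intersection after symbol normalization).
#'
#' @param genes Character vector of gene symbols.
#' @param catalog A [risk_gene_catalog].
#' @return Sorted character vector of catalogued genes.
#' @export
cross_reference_risk <- function(genes, catalog) {
  stopifnot(inherits(catalog, "risk_gene_catalog"))
  if (!length(genes)) return(character(0))
  sort(intersect(normalize_gene_symbol(as.character(genes)), catalog$entries$gene))
}

#' Two-set Venn partition
#'
#' Partitions two gene sets into A-only, shared and B-only components.
#'
#' @param set_a,set_b Character vectors (normalized internally).
#' @param labels Length-2 character vector naming the two sets.
#' @return An object of class `venn_result` with sorted elements `a_only`,
#'   `shared`, `b_only` and `labels`.
#' @export
venn_partition <- function(set_a, set_b, labels = c("A", "B")) {
  a <- if (length(set_a)) unique(normalize_gene_symbol(as.character(set_a))) else character(0)
  b <- if (length(set_b)) unique(normalize_gene_symbol(as.character(set_b))) else character(0)
  structure(list(a_only = sort(setdiff(a, b)),
                 shared = sort(intersect(a, b)),
                 b_only = sort(setdiff(b, a)),
                 labels = as.character(labels)),
            class = "venn_result")
}

#' @export
print.venn_result <- function(x, ...) {
  cat(sprintf("<venn_result>: %s-only %d | shared %d | %s-only %d\n",
              x$labels[1], length(x$a_only), length(x$shared),
              x$labels[2], length(x$b_only)))
  invisible(x)
}

#' Assemble the tripartite ceRNA network over a target gene set
#'
#' Keeps the strong-evidence miRNA -> gene edges whose gene belongs to
#' `genes`, then the circRNA -> miRNA edges whose miRNA retains at least one
#' gene edge; everything else is dropped, so no miRNA dangles.
#'
#' @param sponge A [sponge_map].
#' @param targets A [target_map] (only `"strong"` edges are used).
#' @param genes Non-empty character vector of target gene symbols.
#' @return A [cerna_network] (possibly empty, with a warning).
#' @export
build_network <- function(sponge, targets, genes) {
  stopifnot(inherits(sponge, "sponge_map"), inherits(targets, "target_map"))
  if (!length(genes)) stop("`genes` must be non-empty", call. = FALSE)
  genes <- unique(normalize_gene_symbol(as.character(genes)))
  mg <- targets$edges[targets$edges$evidence == "strong" &
                        targets$edges$gene %in% genes,
                      c("miRNA", "gene"), drop = FALSE]
  cm <- sponge$edges[sponge$edges$miRNA %in% mg$miRNA, , drop = FALSE]
  mg <- mg[mg$miRNA %in% cm$miRNA, , drop = FALSE]
  if (nrow(cm) == 0L || nrow(mg) == 0L) {
    warning("resulting ceRNA network is empty", call. = FALSE)
    cm <- data.frame(circRNA = character(0), miRNA = character(0))
    mg <- data.frame(miRNA = character(0), gene = character(0))
  }
  cerna_network(cm, mg)
}

covered_genes_by_circ <- function(net, target_genes) {
  # genes reachable from each circRNA via length-2 paths, restricted to targets
  mirna_genes <- split(net$mirna_gene_edges$gene, net$mirna_gene_edges$miRNA)
  circ_mirnas <- split(net$circ_mirna_edges$miRNA, net$circ_mirna_edges$circRNA)
  lapply(circ_mirnas, function(ms) {
    sort(intersect(unique(unlist(mirna_genes[ms], use.names = FALSE)),
                   target_genes))
  })
}

#' Rank circRNAs by target-gene coverage
#'
#' For each circRNA in the network, collects the target genes reachable
#' through its sponged miRNAs (length-2 paths) and ranks circRNAs by
#' coverage count, decreasing, ties broken lexicographically. A circRNA
#' covering every target gene is flagged `full_cover` — a set cover of size
#' one, the strongest single-molecule candidate.
#'
#' @param net A [cerna_network].
#' @param target_genes Non-empty character vector of target gene symbols.
#' @return A data.frame of class `coverage_report` with columns `circRNA`,
#'   `coverage_count`, `full_cover` and list-column `covered_genes`;
#'   attribute `target_genes` stores the (normalized) target set.
#' @export
coverage_rank <- function(net, target_genes) {
  stopifnot(inherits(net, "cerna_network"))
  if (!length(target_genes)) stop("`target_genes` must be non-empty", call. = FALSE)
  target_genes <- sort(unique(normalize_gene_symbol(as.character(target_genes))))
  covered <- covered_genes_by_circ(net, target_genes)
  out <- data.frame(circRNA = names(covered),
                    coverage_count = lengths(covered),
                    stringsAsFactors = FALSE)
  out$full_cover <- out$coverage_count == length(target_genes)
  out$covered_genes <- unname(covered)
  out <- out[order(-out$coverage_count, out$circRNA), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "target_genes") <- target_genes
  class(out) <- c("coverage_report", "data.frame")
  out
}

greedy_cover <- function(covered, targets) {
  chosen <- character(0)
  left <- targets
  while (length(left)) {
    gain <- vapply(covered, function(g) length(intersect(g, left)), integer(1))
    best <- names(covered)[order(-gain, names(covered))][1]
    chosen <- c(chosen, best)
    left <- setdiff(left, covered[[best]])
    covered[[best]] <- NULL
  }
  sort(chosen)
}

#' Minimum set of circRNAs covering the target genes
#'
#' Finds the smallest set of circRNAs whose sponged miRNAs jointly regulate
#' every target gene. Exact search (enumeration by increasing subset size)
#' is used for up to `exact_limit` candidate circRNAs; above that a greedy
#' approximation is returned and flagged in the `cover_mode` attribute.
#'
#' @param net A [cerna_network].
#' @param target_genes Character vector of target genes; an empty set yields
#'   an empty cover.
#' @param exact_limit Maximum number of candidate circRNAs for exact search
#'   (default 20, keeping the exhaustive scan sub-second).
#' @return Sorted character vector of circRNA ids with attribute
#'   `cover_mode` (`"exact"` or `"greedy"`).
#' @export
min_cover <- function(net, target_genes, exact_limit = 20L) {
  stopifnot(inherits(net, "cerna_network"))
  if (!length(target_genes)) {
    return(structure(character(0), cover_mode = "exact"))
  }
  targets <- sort(unique(normalize_gene_symbol(as.character(target_genes))))
  covered <- covered_genes_by_circ(net, targets)
  covered <- covered[lengths(covered) > 0L]
  uncoverable <- setdiff(targets, unique(unlist(covered, use.names = FALSE)))
  if (length(uncoverable)) {
    stop(sprintf("uncoverable target gene(s): %s",
                 paste(uncoverable, collapse = ", ")), call. = FALSE)
  }
  ids <- sort(names(covered))
  if (length(ids) <= exact_limit) {
    for (size in seq_along(ids)) {
      combos <- utils::combn(ids, size, simplify = FALSE)
      for (combo in combos) {
        if (all(targets %in% unlist(covered[combo], use.names = FALSE))) {
          return(structure(sort(combo), cover_mode = "exact"))
        }
      }
    }
  }
  log_info("min_cover: %d candidate circRNAs exceed exact_limit = %d; greedy approximation",
           length(ids), exact_limit)
  structure(greedy_cover(covered, targets), cover_mode = "greedy")
}

#' miRNAs of a circRNA shared with another group's sponge map
#'
#' For a circRNA of interest, finds which of its sponged miRNAs are also
#' targeted by circRNAs of the other group, annotating each shared miRNA
#' with the other-group circRNAs that target it.
#'
#' @param circ_id circRNA identifier; must occur in `own_group`.
#' @param own_group [sponge_map] containing `circ_id`.
#' @param other_group [sponge_map] of the other group.
#' @return Named list: one element per shared miRNA (sorted), each a sorted
#'   character vector of other-group circRNA ids targeting it. Empty list if
#'   no miRNA is shared.
#' @export
shared_mirnas <- function(circ_id, own_group, other_group) {
  stopifnot(inherits(own_group, "sponge_map"), inherits(other_group, "sponge_map"))
  circ_id <- normalize_circ_id(circ_id)
  own_edges <- own_group$edges[own_group$edges$circRNA == circ_id, , drop = FALSE]
  if (nrow(own_edges) == 0L) {
    stop(sprintf("circRNA '%s' not found in own-group sponge map", circ_id),
         call. = FALSE)
  }
  shared <- sort(intersect(own_edges$miRNA, other_group$edges$miRNA))
  stats::setNames(lapply(shared, function(m) {
    sort(other_group$edges$circRNA[other_group$edges$miRNA == m])
  }), shared)
}
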