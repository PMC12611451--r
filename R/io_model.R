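# Domain containers and file readers/writers for the sponge-network pipeline.
# All containers are plain S3 lists over data.frames so they serialize cleanly
# and stay inspectable with str().

log_info <- function(...) message(sprintf(...))

#' Construct a sponge map (circRNA -> miRNA bipartite edge set)
#'
#' A sponge map records which circRNAs carry binding sites for which miRNAs.
#' Identifiers are normalized and duplicate edges are collapsed, so the edge
#' count always equals the number of distinct (circRNA, miRNA) pairs — and
#' therefore also the sum of per-circRNA out-degrees and per-miRNA in-degrees.
#'
#' @param circRNA,miRNA Parallel character vectors, one edge per element.
#' @param group_label Label for the biological group the map describes
#'   (e.g. `"ASD"`, `"placenta"`).
#' @return An object of class `sponge_map` with elements `edges`
#'   (data.frame with columns `circRNA`, `miRNA`) and `group_label`.
#' @export
sponge_map <- function(circRNA, miRNA, group_label = "") {
  n <- max(length(circRNA), length(miRNA))
  if (length(circRNA) == 1L) circRNA <- rep_len(circRNA, n)
  if (length(miRNA) == 1L) miRNA <- rep_len(miRNA, n)
  if (length(circRNA) != length(miRNA)) {
    stop("`circRNA` and `miRNA` must have equal length", call. = FALSE)
  }
  edges <- data.frame(
    circRNA = normalize_circ_id(as.character(circRNA)),
    miRNA = normalize_mirna_id(as.character(miRNA)),
    stringsAsFactors = FALSE
  )
  dup <- duplicated(edges)
  if (any(dup)) {
    log_info("sponge_map: collapsed %d duplicate edge(s)", sum(dup))
    edges <- edges[!dup, , drop = FALSE]
  }
  edges <- edges[order(edges$circRNA, edges$miRNA), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, group_label = as.character(group_label)),
            class = "sponge_map")
}

#' @export
print.sponge_map <- function(x, ...) {
  cat(sprintf("<sponge_map '%s'>: %d edges, %d circRNAs, %d miRNAs\n",
              x$group_label, nrow(x$edges),
              length(unique(x$edges$circRNA)), length(unique(x$edges$miRNA))))
  invisible(x)
}

#' Construct a target map (miRNA -> gene edge set with evidence level)
#'
#' Mirrors validated-target exports: each edge carries an evidence level,
#' `"strong"` (experimentally validated by strong methods) or `"weak"`.
#' Duplicate (miRNA, gene) pairs are collapsed per evidence level.
#'
#' @param miRNA,gene Parallel character vectors.
#' @param evidence Evidence level per edge; recycled if scalar. Must be
#'   `"strong"` or `"weak"`.
#' @return An object of class `target_map` with element `edges`
#'   (columns `miRNA`, `gene`, `evidence`).
#' @export
target_map <- function(miRNA, gene, evidence = "strong") {
  if (length(miRNA) != length(gene)) {
    stop("`miRNA` and `gene` must have equal length", call. = FALSE)
  }
  evidence <- rep_len(as.character(evidence), length(miRNA))
  bad <- setdiff(unique(evidence), c("strong", "weak"))
  if (length(bad)) {
    stop(sprintf("unknown evidence level(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  edges <- data.frame(
    miRNA = normalize_mirna_id(as.character(miRNA)),
    gene = normalize_gene_symbol(as.character(gene)),
    evidence = evidence,
    stringsAsFactors = FALSE
  )
  dup <- duplicated(edges)
  if (any(dup)) {
    log_info("target_map: collapsed %d duplicate edge(s)", sum(dup))
    edges <- edges[!dup, , drop = FALSE]
  }
  edges <- edges[order(edges$miRNA, edges$gene, edges$evidence), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges), class = "target_map")
}

#' @export
print.target_map <- function(x, ...) {
  cat(sprintf("<target_map>: %d edges (%d strong, %d weak), %d miRNAs, %d genes\n",
              nrow(x$edges), sum(x$edges$evidence == "strong"),
              sum(x$edges$evidence == "weak"),
              length(unique(x$edges$miRNA)), length(unique(x$edges$gene))))
  invisible(x)
}

#' Construct a pathway collection (named gene sets plus background universe)
#'
#' @param ids Character vector of unique pathway identifiers.
#' @param names Character vector of human-readable pathway names.
#' @param genes List of character vectors, one non-empty gene set per pathway.
#' @param background Optional character vector giving the gene universe for
#'   overrepresentation tests. Defaults to the union of all pathway genes;
#'   when supplied explicitly, every pathway gene set must be a subset of it.
#' @return An object of class `pathway_collection`.
#' @export
pathway_collection <- function(ids, names = ids, genes, background = NULL) {
  ids <- as.character(ids)
  names <- as.character(names)
  if (length(ids) != length(genes) || length(ids) != length(names)) {
    stop("`ids`, `names` and `genes` must have equal length", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("pathway ids must be unique", call. = FALSE)
  genes <- lapply(genes, function(g) sort(unique(normalize_gene_symbol(as.character(g)))))
  if (any(lengths(genes) == 0L)) {
    stop("every pathway gene set must be non-empty", call. = FALSE)
  }
  union_genes <- sort(unique(unlist(genes, use.names = FALSE)))
  if (is.null(background)) {
    background <- union_genes
  } else {
    background <- sort(unique(normalize_gene_symbol(as.character(background))))
    outside <- setdiff(union_genes, background)
    if (length(outside)) {
      stop(sprintf("pathway genes outside the explicit background: %s",
                   paste(utils::head(outside, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  structure(list(ids = ids, names = names, genes = stats::setNames(genes, ids),
                 background = background),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("<pathway_collection>: %d pathways (sizes %d-%d), background %d genes\n",
              length(x$ids), min(lengths(x$genes)), max(lengths(x$genes)),
              length(x$background)))
  invisible(x)
}

#' Construct a risk-gene catalog
#'
#' A catalog of genes previously implicated in the condition of interest
#' (an SFARI-style gene/score table). Gene symbols are normalized and must be
#' unique after normalization (duplicates keep the first score seen).
#'
#' @param gene Character vector of gene symbols.
#' @param score_category Character vector of catalog score labels (recycled).
#' @return An object of class `risk_gene_catalog` with element `entries`
#'   (columns `gene`, `score_category`).
#' @export
risk_gene_catalog <- function(gene, score_category = "") {
  gene <- normalize_gene_symbol(as.character(gene))
  score_category <- rep_len(as.character(score_category), length(gene))
  dup <- duplicated(gene)
  if (any(dup)) {
    log_info("risk_gene_catalog: dropped %d duplicate gene(s)", sum(dup))
  }
  entries <- data.frame(gene = gene[!dup], score_category = score_category[!dup],
                        stringsAsFactors = FALSE)
  entries <- entries[order(entries$gene), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries), class = "risk_gene_catalog")
}

#' @export
print.risk_gene_catalog <- function(x, ...) {
  cat(sprintf("<risk_gene_catalog>: %d genes\n", nrow(x$entries)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Readers

read_tsv_checked <- function(path, required, caller, allow_empty = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("%s: file not found: %s", caller, path), call. = FALSE)
  }
  if (file.size(path) == 0L) {
    stop(sprintf("%s: empty file: %s", caller, path), call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  if (nrow(df) == 0L && !allow_empty) {
    stop(sprintf("%s: no data rows in %s", caller, path), call. = FALSE)
  }
  # header matching is case-insensitive to tolerate hand-edited snapshots
  idx <- match(tolower(required), tolower(names(df)))
  if (anyNA(idx)) {
    stop(sprintf("%s: missing required column '%s' in %s",
                 caller, required[which(is.na(idx))[1]], path), call. = FALSE)
  }
  names(df)[idx] <- required
  df
}

#' Read a circRNA -> miRNA sponge table
#'
#' Reads a TSV snapshot of a circRNA target-map export. The file must have a
#' header with columns `circRNA` and `miRNA` (case-insensitive; extra columns
#' such as gene or pathway annotations are ignored). Identifiers are
#' normalized and duplicate rows collapse silently with a logged count.
#'
#' @param path Path to a tab-separated file.
#' @param group_label Group label stored on the resulting map.
#' @return A [sponge_map].
#' @export
read_sponge_table <- function(path, group_label = "") {
  df <- read_tsv_checked(path, c("circRNA", "miRNA"), "read_sponge_table")
  sponge_map(df$circRNA, df$miRNA, group_label = group_label)
}

#' Read a miRNA -> gene validated-target table
#'
#' Reads a TSV with header columns `miRNA`, `gene`, `evidence` and retains only
#' rows at the requested evidence level.
#'
#' @param path Path to a tab-separated file.
#' @param evidence_filter Evidence level to retain, `"strong"` (default,
#'   matching the convention of keeping only strongly validated targets) or
#'   `"weak"`.
#' @return A [target_map] containing only edges at the requested level.
#' @export
read_target_map <- function(path, evidence_filter = c("strong", "weak")) {
  evidence_filter <- match.arg(evidence_filter)
  df <- read_tsv_checked(path, c("miRNA", "gene", "evidence"), "read_target_map")
  ev <- trimws(tolower(df$evidence))
  bad <- setdiff(unique(ev), c("strong", "weak"))
  if (length(bad)) {
    stop(sprintf("read_target_map: unknown evidence token(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  keep <- ev == evidence_filter
  if (!any(keep)) {
    log_info("read_target_map: no rows at evidence level '%s'", evidence_filter)
    return(target_map(character(0), character(0), character(0)))
  }
  target_map(df$miRNA[keep], df$gene[keep], ev[keep])
}

#' Read a GMT pathway file
#'
#' Standard GMT: one pathway per line, tab-separated fields
#' `id<TAB>name<TAB>gene1<TAB>gene2...` (at least three fields). The
#' background defaults to the union of all pathway genes; pass `universe` (a
#' character vector or a path to a one-gene-per-line file) to override it with
#' an explicit genome-wide universe.
#'
#' @param path Path to a GMT file.
#' @param universe Optional explicit background universe.
#' @return A [pathway_collection].
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("read_gmt: file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("read_gmt: empty file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop(sprintf("read_gmt: line %d has fewer than 3 tab-separated fields",
                 short[1]), call. = FALSE)
  }
  if (is.character(universe) && length(universe) == 1L && file.exists(universe)) {
    universe <- readLines(universe, encoding = "UTF-8", warn = FALSE)
    universe <- universe[nzchar(trimws(universe))]
  }
  pathway_collection(
    ids = vapply(fields, `[[`, character(1), 1L),
    names = vapply(fields, `[[`, character(1), 2L),
    genes = lapply(fields, function(f) f[-(1:2)]),
    background = universe
  )
}

#' Write a pathway collection to GMT
#'
#' Inverse of [read_gmt()]; the explicit background (if any) is not
#' representable in GMT and must be carried separately.
#'
#' @param collection A [pathway_collection].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "pathway_collection"))
  lines <- vapply(seq_along(collection$ids), function(i) {
    paste(c(collection$ids[i], collection$names[i], collection$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a risk-gene catalog
#'
#' TSV with header columns `gene` and `score_category` (case-insensitive).
#'
#' @param path Path to a tab-separated file.
#' @return A [risk_gene_catalog].
#' @export
read_risk_catalog <- function(path) {
  df <- read_tsv_checked(path, c("gene", "score_category"), "read_risk_catalog")
  risk_gene_catalog(df$gene, df$score_category)
}

# ---------------------------------------------------------------------------
# Network writers

#' Write a tripartite ceRNA network to disk
#'
#' @param net A [cerna_network] (see [build_network()]).
#' @param path Output path.
#' @param format One of `"edge_tsv"` (columns `from`, `to`, `layer`),
#'   `"graphml"` (via igraph, with a `layer` node attribute) or `"json"`
#'   (schema-versioned node/edge lists).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edge_tsv", "graphml", "json")) {
  stopifnot(inherits(net, "cerna_network"))
  format <- match.arg(format)
  ce <- net$circ_mirna_edges
  mg <- net$mirna_gene_edges
  edges <- rbind(
    data.frame(from = ce$circRNA, to = ce$miRNA,
               layer = rep_len("circRNA-miRNA", nrow(ce)),
               stringsAsFactors = FALSE),
    data.frame(from = mg$miRNA, to = mg$gene,
               layer = rep_len("miRNA-gene", nrow(mg)),
               stringsAsFactors = FALSE)
  )
  if (format == "edge_tsv") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else if (format == "graphml") {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    nodes <- data.frame(
      id = c(net$nodes$circRNA, net$nodes$miRNA, net$nodes$gene),
      layer = rep(c("circRNA", "miRNA", "gene"),
                  c(length(net$nodes$circRNA), length(net$nodes$miRNA),
                    length(net$nodes$gene))),
      stringsAsFactors = FALSE
    )
    jsonlite::write_json(
      list(schema_version = "1.0", nodes = nodes, edges = edges),
      path, auto_unbox = TRUE, pretty = TRUE
    )
  }
  invisible(path)
}

#' Read a ceRNA network written as edge TSV
#'
#' Inverse of [write_network()] with `format = "edge_tsv"`.
#'
#' @param path Path written by [write_network()].
#' @return A [cerna_network].
#' @export
read_network <- function(path) {
  df <- read_tsv_checked(path, c("from", "to", "layer"), "read_network",
                         allow_empty = TRUE)
  cm <- df[df$layer == "circRNA-miRNA", , drop = FALSE]
  mg <- df[df$layer == "miRNA-gene", , drop = FALSE]
  cerna_network(
    data.frame(circRNA = cm$from, miRNA = cm$to, stringsAsFactors = FALSE),
    data.frame(miRNA = mg$from, gene = mg$to, stringsAsFactors = FALSE)
  )
}

#' Convert a ceRNA network to an igraph object
#'
#' Nodes carry a `layer` attribute (`circRNA`, `miRNA` or `gene`).
#'
#' @param net A [cerna_network].
#' @return A directed igraph graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cerna_network"))
  edges <- rbind(
    stats::setNames(net$circ_mirna_edges, c("from", "to")),
    stats::setNames(net$mirna_gene_edges, c("from", "to"))
  )
  vertices <- data.frame(
    name = c(net$nodes$circRNA, net$nodes$miRNA, net$nodes$gene),
    layer = rep(c("circRNA", "miRNA", "gene"),
                c(length(net$nodes$circRNA), length(net$nodes$miRNA),
                  length(net$nodes$gene))),
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vertices)
}

#' Write a schema-versioned JSON report
#'
#' Serializes any report-like list (coverage reports, pipeline reports, hub
#' summaries) to JSON with a `schema_version` field.
#'
#' @param obj A list (or object coercible to one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(obj, path) {
  payload <- c(list(schema_version = "1.0"), unclass(obj))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Path to a packaged example/fixture file
#'
#' @param file File name under the package's `extdata/` directory; with no
#'   argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
cerna_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "cernasponge")))
  }
  path <- system.file("extdata", file, package = "cernasponge")
  if (!nzchar(path)) stop("no packaged file named ", file, call. = FALSE)
  path
}
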