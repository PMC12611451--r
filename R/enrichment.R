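# Overrepresentation analysis (ORA) of miRNA target genes against a pathway
# collection: hypergeometric upper-tail test, Benjamini-Hochberg FDR,
# keyword-based pathway categorization and per-category relevant-gene
# selection.

#' Default keyword lists for pathway categorization
#'
#' Case-insensitive substrings matched against pathway names to assign each
#' enriched pathway to one of four biological categories: pathways previously
#' linked to the condition of interest (`asd_related`: Notch/AKT/PTEN/MECP2
#' signalling and related developmental regulators), DNA `replication`/repair,
#' `immune` signalling, and `transcription`/RNA processing. Matching priority
#' is fixed to `asd_related`, `replication`, `immune`, `transcription` so that
#' names matching several lists categorize deterministically.
#'
#' @return Named list of character vectors, in priority order.
#' @export
default_category_keywords <- function() {
  list(
    asd_related = c("NOTCH", "AKT", "PTEN", "MECP2", "mTORC1", "RUNX2",
                    "HOX", "PI3K", "PI5P"),
    replication = c("replication", "prereplicative", "HDR", "homologous",
                    "double-strand break", "double strand break",
                    "ATM-mediated"),
    immune = c("interleukin", "NF-kB", "NF-kappaB", "interferon", "TNFR",
               "FCERI", "immunoregulatory", "dectin", "immune"),
    transcription = c("transcription", "transcribes", "mRNA", "snRNA", "rRNA",
                      "tRNA", "splicing", "RNA polymerase", "translation",
                      "SUMOylation of RNA binding")
  )
}

#' Configuration for overrepresentation analysis
#'
#' @param fdr_threshold Significance threshold on the BH-adjusted q-value
#'   (default 0.05).
#' @param min_overlap_genes Minimum overlap count `k` ("pathways enriched by
#'   at least this many query genes") for a pathway to be called significant
#'   (default 15). Interpreted as overlap, not pathway size.
#' @param category_keywords Named list of keyword vectors in priority order;
#'   see [default_category_keywords()].
#' @param relevance_cutoffs Named integer vector: minimum number of
#'   significant pathways of a category a gene must enrich to be considered
#'   relevant for that category. Defaults: 3 for transcription, immune and
#'   condition-related pathways; 2 for replication (fewer genes populate that
#'   category).
#' @param bh_scope Multiple-testing universe: `"tested"` (default; pathways
#'   with overlap `k >= 1`, the usual ORA-tool convention) or `"all"`
#'   (every pathway in the collection).
#' @return A list of class `ora_config`.
#' @export
ora_config <- function(fdr_threshold = 0.05,
                       min_overlap_genes = 15L,
                       category_keywords = default_category_keywords(),
                       relevance_cutoffs = c(transcription = 3L, immune = 3L,
                                             asd_related = 3L, replication = 2L),
                       bh_scope = c("tested", "all")) {
  bh_scope <- match.arg(bh_scope)
  if (!is.numeric(fdr_threshold) || fdr_threshold <= 0 || fdr_threshold > 1) {
    stop("fdr_threshold must be in (0, 1]", call. = FALSE)
  }
  min_overlap_genes <- as.integer(min_overlap_genes)
  if (is.na(min_overlap_genes) || min_overlap_genes < 1L) {
    stop("min_overlap_genes must be >= 1", call. = FALSE)
  }
  if (!length(category_keywords) || any(lengths(category_keywords) == 0L)) {
    stop("every category needs at least one keyword", call. = FALSE)
  }
  relevance_cutoffs <- vapply(relevance_cutoffs, as.integer, integer(1))
  structure(list(fdr_threshold = fdr_threshold,
                 min_overlap_genes = min_overlap_genes,
                 category_keywords = category_keywords,
                 relevance_cutoffs = relevance_cutoffs,
                 bh_scope = bh_scope),
            class = "ora_config")
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` pathway genes when `n` query genes are sampled without
#' replacement from a background of `N` genes of which `K` lie in the pathway.
#' The upper tail includes the observed `k`. Computation delegates to
#' `stats::phyper()` with `lower.tail = FALSE`, which is numerically stable in
#' the extreme tails. Vectorized over all four arguments.
#'
#' @param k Observed overlap count(s), `0 <= k <= min(K, n)`.
#' @param K Pathway size(s) within the background.
#' @param n Query size(s) within the background.
#' @param N Background (universe) size(s).
#' @return Probability vector.
#' @examples
#' hypergeom_tail(2, 2, 2, 4)  # 1/6: both marked balls in a 2-of-4 draw
#' @export
hypergeom_tail <- function(k, K, n, N) {
  args <- cbind(k = k, K = K, n = n, N = N)
  if (anyNA(args) || any(args < 0) || any(args != floor(args))) {
    stop("k, K, n, N must be non-negative integers", call. = FALSE)
  }
  if (any(args[, "K"] > args[, "N"]) || any(args[, "n"] > args[, "N"])) {
    stop("K and n must not exceed N", call. = FALSE)
  }
  if (any(args[, "k"] > pmin(args[, "K"], args[, "n"]))) {
    stop("k must not exceed min(K, n)", call. = FALSE)
  }
  unname(stats::phyper(args[, "k"] - 1, args[, "K"], args[, "N"] - args[, "K"],
                       args[, "n"], lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: on the sorted scale
#' `q_(i) = min_{j >= i} min(1, p_(j) * m / j)`, mapped back to input order
#' (ties share a q-value). Delegates to `stats::p.adjust(method = "BH")`
#' after validating the input.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values in the same order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop("p-values must be numeric", call. = FALSE)
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Run overrepresentation analysis of a gene set against a pathway collection
#'
#' For each pathway with at least one query gene, tests whether the pathway
#' contains more query genes than expected by chance under the hypergeometric
#' model, then adjusts across tested pathways with Benjamini-Hochberg.
#' A pathway is flagged significant when `q < fdr_threshold` and the overlap
#' reaches `min_overlap_genes`.
#'
#' @param query_genes Character vector of query gene symbols (normalized
#'   internally). Genes outside the background are dropped; the effective
#'   query size `n` is the post-intersection count.
#' @param pathways A [pathway_collection].
#' @param cfg An [ora_config()].
#' @return A data.frame of class `ora_result` with columns `pathway_id`,
#'   `pathway_name`, `k`, `K`, `n`, `N`, `p_raw`, `q_bh`, `significant`,
#'   `category` (initialized to `NA`, see [categorize_pathways()]), ordered by
#'   increasing `q_bh` then `p_raw`. The effective query is attached as
#'   attribute `query_genes`.
#' @export
run_ora <- function(query_genes, pathways, cfg = ora_config()) {
  stopifnot(inherits(pathways, "pathway_collection"), inherits(cfg, "ora_config"))
  query <- unique(normalize_gene_symbol(as.character(query_genes)))
  query <- intersect(query, pathways$background)
  if (!length(query)) {
    stop("query disjoint from background", call. = FALSE)
  }
  N <- length(pathways$background)
  n <- length(query)
  K <- lengths(pathways$genes)
  k <- vapply(pathways$genes, function(g) length(intersect(g, query)), integer(1))
  tested <- if (cfg$bh_scope == "tested") k >= 1L else rep(TRUE, length(k))
  res <- data.frame(
    pathway_id = pathways$ids[tested],
    pathway_name = pathways$names[tested],
    k = k[tested], K = K[tested], n = n, N = N,
    stringsAsFactors = FALSE
  )
  res$p_raw <- hypergeom_tail(res$k, res$K, res$n, res$N)
  res$q_bh <- bh_adjust(res$p_raw)
  res$significant <- res$q_bh < cfg$fdr_threshold & res$k >= cfg$min_overlap_genes
  res$category <- NA_character_
  res <- res[order(res$q_bh, res$p_raw, res$pathway_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "query_genes") <- query
  class(res) <- c("ora_result", "data.frame")
  res
}

#' Assign pathway categories by keyword matching
#'
#' Matches each pathway name case-insensitively against the configured keyword
#' substrings (hyphen variants normalized first). Categories are tried in the
#' fixed priority order of `cfg$category_keywords`; the first category with a
#' matching keyword wins, and unmatched pathways fall into `"other"`.
#'
#' @param results An `ora_result` from [run_ora()].
#' @param cfg An [ora_config()].
#' @return `results` with the `category` column filled in.
#' @export
categorize_pathways <- function(results, cfg = ora_config()) {
  stopifnot(is.data.frame(results), "pathway_name" %in% names(results))
  nm <- tolower(normalize_hyphens(results$pathway_name))
  category <- rep("other", nrow(results))
  unset <- rep(TRUE, nrow(results))
  for (cat_name in names(cfg$category_keywords)) {
    kws <- tolower(normalize_hyphens(cfg$category_keywords[[cat_name]]))
    hit <- Reduce(`|`, lapply(kws, function(kw) grepl(kw, nm, fixed = TRUE)))
    category[unset & hit] <- cat_name
    unset <- unset & !hit
  }
  results$category <- category
  results
}

#' Select relevant genes per pathway category
#'
#' Within each category, counts for every query gene the number of significant
#' pathways of that category containing it, and retains genes meeting the
#' category's relevance cutoff (a gene must enrich at least that many
#' pathways to be considered relevant).
#'
#' @param results A categorized `ora_result` (see [categorize_pathways()]).
#' @param pathways The [pathway_collection] the results came from.
#' @param cfg An [ora_config()]; `cfg$relevance_cutoffs` supplies the
#'   per-category thresholds.
#' @return Named list mapping each category in `cfg$relevance_cutoffs` to a
#'   sorted character vector of relevant genes (possibly empty).
#' @export
select_relevant_genes <- function(results, pathways, cfg = ora_config()) {
  stopifnot(inherits(pathways, "pathway_collection"))
  query <- attr(results, "query_genes")
  if (is.null(query)) stop("`results` must come from run_ora()", call. = FALSE)
  if (all(is.na(results$category))) {
    stop("`results` must be categorized first; see categorize_pathways()",
         call. = FALSE)
  }
  out <- stats::setNames(vector("list", length(cfg$relevance_cutoffs)),
                         names(cfg$relevance_cutoffs))
  for (cat_name in names(cfg$relevance_cutoffs)) {
    ids <- results$pathway_id[results$significant &
                                !is.na(results$category) &
                                results$category == cat_name]
    if (!length(ids)) {
      out[[cat_name]] <- character(0)
      next
    }
    genes_in_cat <- unlist(lapply(pathways$genes[ids], intersect, y = query),
                           use.names = FALSE)
    counts <- table(genes_in_cat)
    out[[cat_name]] <- sort(names(counts)[counts >= cfg$relevance_cutoffs[[cat_name]]])
  }
  out
}

#' Export gene-to-pathway-category links for chord plotting
#'
#' Emits one `gene,pathway,category` row per (query gene, significant pathway)
#' incidence, the input format expected by chord-diagram tools. Rendering is
#' out of scope; this is data export only.
#'
#' @param results A categorized `ora_result`.
#' @param pathways The [pathway_collection] the results came from.
#' @param path Optional CSV output path; when `NULL` the data.frame is
#'   returned without writing.
#' @return A data.frame with columns `gene`, `pathway`, `category`
#'   (invisibly when `path` is given).
#' @export
chord_export <- function(results, pathways, path = NULL) {
  stopifnot(inherits(pathways, "pathway_collection"))
  query <- attr(results, "query_genes")
  if (is.null(query)) stop("`results` must come from run_ora()", call. = FALSE)
  sig <- results[results$significant, , drop = FALSE]
  rows <- lapply(seq_len(nrow(sig)), function(i) {
    g <- intersect(pathways$genes[[sig$pathway_id[i]]], query)
    if (!length(g)) return(NULL)
    data.frame(gene = g, pathway = sig$pathway_name[i],
               category = sig$category[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(gene = character(0), pathway = character(0),
                      category = character(0))
  }
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
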