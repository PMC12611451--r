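# Hub-miRNA selection: in-degree profiles, frequency cutoffs (fixed or
# elbow-derived) and the reverse search for the circRNAs most recurrently
# targeting the selected miRNAs.

#' Configuration for hub selection
#'
#' @param cutoff_mode `"fixed"` uses `fixed_cutoff` as the inclusive in-degree
#'   threshold; `"elbow"` derives the threshold from the degree distribution
#'   with [elbow_cutoff()].
#' @param fixed_cutoff Inclusive in-degree threshold (default 8, the stricter
#'   of the two group-specific thresholds used for condition-associated maps;
#'   5 is typical for the broader tissue-expression maps).
#' @param top_k Number of circRNAs retained by [reverse_search()] (default 10).
#' @param tie_policy How to treat circRNAs tied with the rank-`top_k` hit
#'   count: `"keep_ties"` (default) retains all of them, `"lexicographic"`
#'   truncates strictly at `top_k` after breaking ties by identifier.
#' @return A list of class `hub_selection_config`.
#' @export
hub_selection_config <- function(cutoff_mode = c("fixed", "elbow"),
                                 fixed_cutoff = 8L,
                                 top_k = 10L,
                                 tie_policy = c("keep_ties", "lexicographic")) {
  cutoff_mode <- match.arg(cutoff_mode)
  tie_policy <- match.arg(tie_policy)
  fixed_cutoff <- as.integer(fixed_cutoff)
  top_k <- as.integer(top_k)
  if (is.na(fixed_cutoff) || fixed_cutoff < 1L) stop("fixed_cutoff must be >= 1", call. = FALSE)
  if (is.na(top_k) || top_k < 1L) stop("top_k must be >= 1", call. = FALSE)
  structure(list(cutoff_mode = cutoff_mode, fixed_cutoff = fixed_cutoff,
                 top_k = top_k, tie_policy = tie_policy),
            class = "hub_selection_config")
}

#' Compute the miRNA in-degree profile of a sponge map
#'
#' The in-degree of a miRNA is the number of distinct circRNAs carrying a
#' binding site for it. Because sponge maps are deduplicated edge sets, the
#' in-degrees always sum to the map's edge count.
#'
#' @param map A [sponge_map].
#' @return An object of class `degree_profile`: a named integer vector of
#'   in-degrees sorted decreasingly (names are miRNA ids), with a
#'   `group_label` attribute.
#' @export
compute_in_degree <- function(map) {
  stopifnot(inherits(map, "sponge_map"))
  if (nrow(map$edges) == 0L) stop("no edges in sponge map", call. = FALSE)
  counts <- table(map$edges$miRNA)
  counts <- sort(stats::setNames(as.integer(counts), names(counts)),
                 decreasing = TRUE)
  structure(counts, group_label = map$group_label, class = "degree_profile")
}

#' @export
print.degree_profile <- function(x, ...) {
  cat(sprintf("<degree_profile '%s'>: %d miRNAs, in-degree range %d-%d\n",
              attr(x, "group_label"), length(x), min(x), max(x)))
  invisible(x)
}

#' Elbow cutoff on an in-degree distribution
#'
#' Places the frequency threshold at the knee of the sorted degree curve:
#' the distinct in-degrees are sorted decreasingly into a curve `y(i)`,
#' `i = 1..d`, and the cutoff is the in-degree at the point of maximum
#' perpendicular distance from the chord joining the curve's endpoints
#' (a kneedle-style rule, deterministic and parameter-free; no smoothing).
#' Ties are broken toward the larger in-degree, i.e. the stricter cutoff.
#' The returned value is an inclusive threshold (`in-degree >= cutoff`).
#'
#' With fewer than three distinct in-degree values the chord is degenerate;
#' the maximum in-degree is returned with a warning.
#'
#' @param profile A `degree_profile` from [compute_in_degree()], or a bare
#'   integer vector of in-degrees.
#' @return Integer cutoff.
#' @export
elbow_cutoff <- function(profile) {
  degs <- sort(unique(as.integer(profile)), decreasing = TRUE)
  if (length(degs) < 3L) {
    warning("fewer than 3 distinct in-degree values; degenerate elbow, using max",
            call. = FALSE)
    return(max(degs))
  }
  d <- length(degs)
  x <- seq_len(d)
  # perpendicular distance of (x, y) to the chord (1, y1)-(d, yd), via the
  # cross product of the chord vector with the point offset
  dx <- d - 1
  dy <- degs[d] - degs[1]
  dist <- abs(dy * (x - 1) - dx * (degs - degs[1])) / sqrt(dx^2 + dy^2)
  # which.max takes the first (= larger-degree) index on ties
  degs[which.max(dist)]
}

#' Select frequent (hub) miRNAs at an inclusive cutoff
#'
#' @param profile A `degree_profile`.
#' @param cutoff Inclusive in-degree threshold (e.g. "targeted by eight or
#'   more circRNAs" corresponds to `cutoff = 8`).
#' @return Sorted character vector of miRNA ids with `in-degree >= cutoff`.
#' @export
select_frequent_mirnas <- function(profile, cutoff) {
  cutoff <- as.integer(cutoff)
  if (is.na(cutoff) || cutoff < 1L) stop("cutoff must be >= 1", call. = FALSE)
  sel <- names(profile)[as.integer(profile) >= cutoff]
  if (!length(sel)) log_info("select_frequent_mirnas: no miRNA reaches cutoff %d", cutoff)
  sort(sel)
}

#' Reverse search: rank circRNAs by how many selected miRNAs they target
#'
#' Given the hub miRNAs, ranks every circRNA by its hit count — the number of
#' selected miRNAs it carries binding sites for — in decreasing order, ties
#' broken lexicographically by circRNA id. Only circRNAs with at least one hit
#' appear. The list is truncated at `cfg$top_k`; with
#' `tie_policy = "keep_ties"` all circRNAs tied with the rank-`top_k` hit
#' count are retained.
#'
#' @param map A [sponge_map].
#' @param selected Non-empty character vector of selected miRNA ids.
#' @param cfg A [hub_selection_config()].
#' @return A data.frame with columns `circRNA` and `hit_count`, ranked.
#' @export
reverse_search <- function(map, selected, cfg = hub_selection_config()) {
  stopifnot(inherits(map, "sponge_map"))
  if (!length(selected)) stop("`selected` miRNA set is empty", call. = FALSE)
  selected <- normalize_mirna_id(selected)
  hit_edges <- map$edges[map$edges$miRNA %in% selected, , drop = FALSE]
  if (nrow(hit_edges) == 0L) {
    return(data.frame(circRNA = character(0), hit_count = integer(0)))
  }
  counts <- table(hit_edges$circRNA)
  out <- data.frame(circRNA = names(counts), hit_count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$hit_count, out$circRNA), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) > cfg$top_k) {
    if (cfg$tie_policy == "keep_ties") {
      boundary <- out$hit_count[cfg$top_k]
      out <- out[out$hit_count >= boundary, , drop = FALSE]
      if (nrow(out) > cfg$top_k) {
        log_info("reverse_search: kept %d circRNAs tied at hit_count %d beyond top_k = %d",
                 nrow(out) - cfg$top_k, boundary, cfg$top_k)
      }
    } else {
      out <- out[seq_len(cfg$top_k), , drop = FALSE]
    }
    rownames(out) <- NULL
  }
  out
}
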