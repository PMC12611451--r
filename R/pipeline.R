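# End-to-end two-group workflow: per-group hub selection -> (optional) ORA
# and categorization -> risk-catalog overlap; then the cross-group Venn,
# tripartite network on the shared genes, coverage/min-cover analysis and
# shared-miRNA annotation for every full-cover circRNA.

#' Configuration for the two-group pipeline
#'
#' @param group_a,group_b Lists describing each group:
#'   `list(sponge_path =, label =, cutoff_mode = "fixed"|"elbow",
#'   fixed_cutoff =, top_k =, tie_policy =)`. Missing hub-selection fields
#'   take the [hub_selection_config()] defaults. The conventional defaults
#'   are an inclusive in-degree cutoff of 8 for the condition-associated
#'   group and 5 for the tissue-expression group.
#' @param target_map_path Path to the miRNA -> gene validated-target TSV.
#' @param evidence_filter Evidence level retained from the target map
#'   (default `"strong"`).
#' @param gmt_path Optional path to a GMT pathway file. When `NULL`, the
#'   ORA/categorization stages are skipped and the relevant gene set of a
#'   group falls back to all retained targets of its selected miRNAs (the
#'   appropriate mode for small published snapshots whose gene columns are
#'   already pathway-filtered).
#' @param universe_path Optional path to a one-gene-per-line background
#'   universe overriding the GMT union.
#' @param ora An [ora_config()].
#' @param risk_catalog_path Path to the risk-gene catalog TSV.
#' @param output_dir Directory for stage artifacts and the report.
#' @param log_level `"info"` or `"quiet"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(group_a, group_b, target_map_path,
                            evidence_filter = "strong",
                            gmt_path = NULL, universe_path = NULL,
                            ora = ora_config(), risk_catalog_path,
                            output_dir = tempfile("cerna_run_"),
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  fill_group <- function(g, default_cutoff) {
    stopifnot(is.list(g), !is.null(g$sponge_path), !is.null(g$label))
    g$cutoff_mode <- if (is.null(g$cutoff_mode)) "fixed" else g$cutoff_mode
    g$fixed_cutoff <- if (is.null(g$fixed_cutoff)) default_cutoff else g$fixed_cutoff
    g$top_k <- if (is.null(g$top_k)) 10L else g$top_k
    g$tie_policy <- if (is.null(g$tie_policy)) "keep_ties" else g$tie_policy
    g$hub_cfg <- hub_selection_config(g$cutoff_mode, g$fixed_cutoff, g$top_k,
                                      g$tie_policy)
    g
  }
  group_a <- fill_group(group_a, 8L)
  group_b <- fill_group(group_b, 5L)
  if (identical(group_a$label, group_b$label)) {
    stop("group labels must be distinct", call. = FALSE)
  }
  for (p in c(group_a$sponge_path, group_b$sponge_path, target_map_path,
              risk_catalog_path, gmt_path, universe_path)) {
    if (!is.null(p) && !file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  structure(list(group_a = group_a, group_b = group_b,
                 target_map_path = target_map_path,
                 evidence_filter = evidence_filter,
                 gmt_path = gmt_path, universe_path = universe_path,
                 ora = ora, risk_catalog_path = risk_catalog_path,
                 output_dir = output_dir, log_level = log_level),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the [pipeline_config()] arguments; `ora` sub-fields map
#' onto [ora_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  ora <- if (is.null(y$ora)) ora_config() else do.call(ora_config, y$ora)
  pipeline_config(
    group_a = y$group_a, group_b = y$group_b,
    target_map_path = y$target_map_path,
    evidence_filter = if (is.null(y$evidence_filter)) "strong" else y$evidence_filter,
    gmt_path = y$gmt_path, universe_path = y$universe_path,
    ora = ora, risk_catalog_path = y$risk_catalog_path,
    output_dir = if (is.null(y$output_dir)) tempfile("cerna_run_") else y$output_dir,
    log_level = if (is.null(y$log_level)) "info" else y$log_level
  )
}

run_group_stage <- function(g, targets, pathways, ora_cfg, catalog, quiet) {
  note <- function(...) if (!quiet) log_info(...)
  sponge <- suppressMessages(read_sponge_table(g$sponge_path, g$label))
  profile <- compute_in_degree(sponge)
  cutoff <- if (g$hub_cfg$cutoff_mode == "elbow") {
    elbow_cutoff(profile)
  } else {
    g$hub_cfg$fixed_cutoff
  }
  note("[%s] in-degree cutoff %d (%s mode)", g$label, cutoff, g$hub_cfg$cutoff_mode)
  selected <- suppressMessages(select_frequent_mirnas(profile, cutoff))
  note("[%s] %d hub miRNA(s) selected", g$label, length(selected))
  if (!length(selected)) {
    warning(sprintf("[%s] no miRNA reaches cutoff %d; group contributes nothing",
                    g$label, cutoff), call. = FALSE)
    ranked <- data.frame(circRNA = character(0), hit_count = integer(0))
  } else {
    ranked <- reverse_search(sponge, selected, g$hub_cfg)
  }
  target_genes <- sort(unique(
    targets$edges$gene[targets$edges$miRNA %in% selected]))
  ora_res <- NULL
  if (!is.null(pathways) && length(target_genes)) {
    ora_res <- categorize_pathways(run_ora(target_genes, pathways, ora_cfg),
                                   ora_cfg)
    relevant <- sort(unique(unlist(
      select_relevant_genes(ora_res, pathways, ora_cfg), use.names = FALSE)))
    note("[%s] ORA: %d/%d pathways significant; %d relevant gene(s)", g$label,
         sum(ora_res$significant), nrow(ora_res), length(relevant))
  } else {
    relevant <- target_genes
    note("[%s] ORA skipped (%s): using %d target gene(s) as relevant set",
         g$label,
         if (is.null(pathways)) "no pathway collection" else "empty gene set",
         length(relevant))
  }
  risk_genes <- cross_reference_risk(relevant, catalog)
  note("[%s] %d gene(s) found in risk catalog", g$label, length(risk_genes))
  list(label = g$label, sponge = sponge, profile = profile, cutoff = cutoff,
       selected_mirnas = selected, ranked_circrnas = ranked,
       target_genes = target_genes, ora = ora_res, relevant_genes = relevant,
       risk_genes = risk_genes)
}

#' Run the full two-group ceRNA prioritization pipeline
#'
#' Executes, per group: in-degree profiling, frequency cutoff (fixed or
#' elbow), hub-miRNA selection, reverse search, target-gene expansion,
#' optional overrepresentation analysis with categorization and
#' relevant-gene selection, and risk-catalog cross-referencing. Across
#' groups it then computes the Venn partition of risk genes, assembles the
#' per-group tripartite networks restricted to the shared genes, ranks
#' circRNAs by coverage, finds minimum covers, and annotates every
#' full-cover circRNA with the miRNAs it shares with the other group.
#' All stage artifacts and a schema-versioned `report.json` are written to
#' `cfg$output_dir`.
#'
#' @param cfg A [pipeline_config()].
#' @return The pipeline report (list of class `pipeline_report`), invisibly
#'   containing every threshold actually used.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  quiet <- cfg$log_level == "quiet"
  note <- function(...) if (!quiet) log_info(...)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  targets <- suppressMessages(
    read_target_map(cfg$target_map_path, cfg$evidence_filter))
  catalog <- suppressMessages(read_risk_catalog(cfg$risk_catalog_path))
  pathways <- if (!is.null(cfg$gmt_path)) {
    read_gmt(cfg$gmt_path, universe = cfg$universe_path)
  }
  tick("load_inputs")

  groups <- list(
    a = run_group_stage(cfg$group_a, targets, pathways, cfg$ora, catalog, quiet),
    b = run_group_stage(cfg$group_b, targets, pathways, cfg$ora, catalog, quiet)
  )
  tick("group_stages")

  files <- character(0)
  for (g in groups) {
    hub_path <- file.path(cfg$output_dir, sprintf("hubs_%s.json", g$label))
    write_report(list(group = g$label, cutoff_used = g$cutoff,
                      selected_mirnas = g$selected_mirnas,
                      ranked_circrnas = g$ranked_circrnas,
                      risk_genes = g$risk_genes), hub_path)
    files <- c(files, hub_path)
    if (!is.null(g$ora)) {
      ora_path <- file.path(cfg$output_dir, sprintf("ora_%s.tsv", g$label))
      utils::write.table(g$ora, ora_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, ora_path)
    }
  }

  vr <- venn_partition(groups$a$risk_genes, groups$b$risk_genes,
                       labels = c(groups$a$label, groups$b$label))
  note("venn: %d %s-only | %d shared | %d %s-only", length(vr$a_only),
       vr$labels[1], length(vr$shared), length(vr$b_only), vr$labels[2])
  venn_path <- file.path(cfg$output_dir, "venn.json")
  write_report(unclass(vr), venn_path)
  files <- c(files, venn_path)
  tick("venn")

  coverage <- list(); covers <- list(); shared_mirna_report <- list()
  full_cover_circ <- character(0)
  if (!length(vr$shared)) {
    warning("no shared risk genes between groups; skipping network stages",
            call. = FALSE)
  } else {
    for (key in c("a", "b")) {
      g <- groups[[key]]
      other <- groups[[setdiff(c("a", "b"), key)]]
      net <- withCallingHandlers(
        build_network(g$sponge, targets, vr$shared),
        warning = function(w) {
          note("[%s] %s", g$label, conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      )
      cov <- coverage_rank(net, vr$shared)
      coverage[[g$label]] <- cov
      mc_call <- function() tryCatch(
        min_cover(net, vr$shared),
        error = function(e) structure(character(0),
                                      cover_mode = conditionMessage(e))
      )
      covers[[g$label]] <- if (quiet) suppressMessages(mc_call()) else mc_call()
      net_path <- file.path(cfg$output_dir,
                            sprintf("network_%s.graphml", g$label))
      edge_path <- file.path(cfg$output_dir,
                             sprintf("network_%s_edges.tsv", g$label))
      if (length(net$nodes$circRNA)) {
        write_network(net, net_path, "graphml")
        write_network(net, edge_path, "edge_tsv")
        files <- c(files, net_path, edge_path)
      }
      fc <- cov$circRNA[cov$full_cover]
      full_cover_circ <- c(full_cover_circ, fc)
      for (circ in fc) {
        shared_mirna_report[[circ]] <- shared_mirnas(circ, g$sponge,
                                                     other$sponge)
      }
      cov_path <- file.path(cfg$output_dir,
                            sprintf("coverage_%s.tsv", g$label))
      flat <- cov
      flat$covered_genes <- vapply(flat$covered_genes, paste,
                                   character(1), collapse = ",")
      utils::write.table(flat, cov_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, cov_path)
    }
    sm_path <- file.path(cfg$output_dir, "shared_mirnas.json")
    write_report(shared_mirna_report, sm_path)
    files <- c(files, sm_path)
  }
  tick("network_stages")

  report <- structure(list(
    config = list(
      groups = lapply(groups, function(g) list(
        label = g$label, cutoff_used = g$cutoff)),
      evidence_filter = cfg$evidence_filter,
      fdr_threshold = cfg$ora$fdr_threshold,
      min_overlap_genes = cfg$ora$min_overlap_genes,
      relevance_cutoffs = as.list(cfg$ora$relevance_cutoffs),
      used_pathways = !is.null(pathways)
    ),
    groups = lapply(groups, function(g) list(
      label = g$label, cutoff_used = g$cutoff,
      n_edges = nrow(g$sponge$edges),
      n_circrnas = length(unique(g$sponge$edges$circRNA)),
      selected_mirnas = g$selected_mirnas,
      ranked_circrnas = g$ranked_circrnas,
      relevant_genes = g$relevant_genes,
      risk_genes = g$risk_genes
    )),
    venn = list(a_only = vr$a_only, shared = vr$shared, b_only = vr$b_only,
                labels = vr$labels),
    coverage = lapply(coverage, function(cov) {
      flat <- cov
      flat$covered_genes <- vapply(flat$covered_genes, paste,
                                   character(1), collapse = ",")
      flat
    }),
    full_cover_circrnas = sort(unique(full_cover_circ)),
    min_cover = lapply(covers, function(x) list(
      circRNAs = as.character(x), mode = attr(x, "cover_mode"))),
    shared_mirnas = shared_mirna_report,
    timings = timings,
    files = files,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "pipeline_report")
  report_path <- file.path(cfg$output_dir, "report.json")
  emit_report(report, report_path)
  note("report written to %s", report_path)
  invisible(report)
}

#' Write a pipeline report to schema-versioned JSON
#'
#' The volatile timestamp lives in its own field, so two runs with identical
#' configuration differ only there.
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
emit_report <- function(report, path) {
  write_report(report, path)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %s vs %s\n", x$venn$labels[1], x$venn$labels[2]))
  cat(sprintf("  shared risk genes: %s\n",
              paste(x$venn$shared, collapse = ", ")))
  cat(sprintf("  full-cover circRNAs: %s\n",
              if (length(x$full_cover_circrnas))
                paste(x$full_cover_circrnas, collapse = ", ") else "(none)"))
  invisible(x)
}
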