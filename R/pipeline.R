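#' Assemble and validate a pipeline configuration
#'
#' Collects the input paths and the analysis parameters for a full run.
#' Defaults encode the reference analysis conventions: P < 0.01 cutoffs at
#' every stage, k = 3 clique percolation, 10000 permutation draws, induced
#' degree scope, strict hub threshold 0.9, inter-module eligibility minimum
#' of 2 modules, and top-5 connector selection.
#'
#' @param gene_expression,gene_groups paths to the gene expression TSV and
#'   its group annotation.
#' @param mirna_expression,mirna_groups paths for the miRNA matrix.
#' @param ppi path to the PPI edge-list TSV.
#' @param targets path to a miRNA-target pair TSV (columns `mirna`, `gene`);
#'   use [build_target_map()] first when starting from per-tool predictions.
#' @param out_dir output directory for all result tables.
#' @param case_group label of the case arm in both group files.
#' @param de_alpha,module_alpha,enrichment_alpha stage-level cutoffs,
#'   each in (0,1).
#' @param cpm_k clique-percolation k (>= 3).
#' @param n_perm permutation draws per module (>= 1).
#' @param seed integer seed governing the permutation null.
#' @param degree_scope `"induced"` or `"full"` (see [maoc_degrees()]).
#' @param hub_threshold strict scaled-connectivity hub cutoff.
#' @param min_modules inter-module connector eligibility minimum.
#' @param top_n connector genes reported per class.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(gene_expression, gene_groups,
                            mirna_expression, mirna_groups,
                            ppi, targets, out_dir,
                            case_group = NULL,
                            de_alpha = 0.01, module_alpha = 0.01,
                            enrichment_alpha = 0.01,
                            cpm_k = 3L, n_perm = 10000L, seed = 1L,
                            degree_scope = "induced", hub_threshold = 0.9,
                            min_modules = 2L, top_n = 5L) {
  cfg <- list(gene_expression = gene_expression, gene_groups = gene_groups,
              mirna_expression = mirna_expression,
              mirna_groups = mirna_groups, ppi = ppi, targets = targets,
              out_dir = out_dir, case_group = case_group,
              de_alpha = de_alpha, module_alpha = module_alpha,
              enrichment_alpha = enrichment_alpha,
              cpm_k = as.integer(cpm_k), n_perm = as.integer(n_perm),
              seed = as.integer(seed), degree_scope = degree_scope,
              hub_threshold = hub_threshold,
              min_modules = as.integer(min_modules),
              top_n = as.integer(top_n))
  for (f in c("de_alpha", "module_alpha", "enrichment_alpha")) {
    if (!(cfg[[f]] > 0 && cfg[[f]] < 1)) {
      stop("`", f, "` must be in (0,1)", call. = FALSE)
    }
  }
  if (cfg$n_perm < 1L) stop("`n_perm` must be >= 1", call. = FALSE)
  if (cfg$cpm_k < 3L) stop("`cpm_k` must be >= 3", call. = FALSE)
  if (!cfg$degree_scope %in% c("induced", "full")) {
    stop("`degree_scope` must be 'induced' or 'full'", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full module-discovery pipeline
#'
#' Executes the stages end to end: differential expression for genes and
#' miRNAs, k-clique percolation module detection on the PPI network,
#' permutation-calibrated module scoring and MAOC selection, topological
#' key-gene extraction (hubs and connectors), and miRNA-regulator screening
#' with direction anti-correlation. Every intermediate table, the resolved
#' configuration, and a machine-readable summary are written to
#' `config$out_dir`. The run is deterministic given the configuration seed.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_lines <- character()
  note <- function(...) {
    line <- paste0(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, paste0("FAILED at stage ", name, ": ",
                                     conditionMessage(e))), log_path)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  note("run_pipeline started; seed=", config$seed,
       " cpm_k=", config$cpm_k, " n_perm=", config$n_perm)

  de_gene <- stage("expression_de[gene]", {
    es <- read_expression_tsv(config$gene_expression, config$gene_groups,
                              case_group = config$case_group)
    if (anyNA(es$values)) es <- impute_missing(es, "mean")
    differential_test(es, alpha = config$de_alpha)
  })
  write_tsv(de_gene, file.path(config$out_dir, "de_genes.tsv"))
  de_mirna <- stage("expression_de[mirna]", {
    es <- read_expression_tsv(config$mirna_expression, config$mirna_groups,
                              case_group = config$case_group)
    if (anyNA(es$values)) es <- impute_missing(es, "mean")
    differential_test(es, alpha = config$de_alpha)
  })
  write_tsv(de_mirna, file.path(config$out_dir, "de_mirnas.tsv"))
  note("DEGs: ", sum(de_gene$is_significant), "/", nrow(de_gene),
       "; DEmiRs: ", sum(de_mirna$is_significant), "/", nrow(de_mirna))

  t_scores <- setNames(de_gene$t_score, de_gene$feature_id)
  net <- stage("network_modules[read]", read_ppi(config$ppi))
  modules <- stage("network_modules[detect]",
                   detect_modules(net, k = config$cpm_k))
  note("modules detected at k=", config$cpm_k, ": ", length(modules))
  scored <- stage("network_modules[score]",
                  score_modules(modules, t_scores, n_perm = config$n_perm,
                                seed = config$seed))
  maoc_df <- select_maocs(scored, alpha = config$module_alpha)
  maocs <- modules[maoc_df$module_id]
  write_modules_gmt(scored, modules,
                    file.path(config$out_dir, "modules.gmt.tsv"))
  write_tsv(scored, file.path(config$out_dir, "modules_summary.tsv"))
  write_tsv(maoc_df, file.path(config$out_dir, "maocs.tsv"))
  note("MAOCs at alpha=", config$module_alpha, ": ", nrow(maoc_df))

  topo <- stage("topology", {
    if (length(maocs)) {
      degs <- maoc_degrees(net, maocs, scope = config$degree_scope)
      hubs <- call_hubs(degs$degrees, degs$k_max,
                        threshold = config$hub_threshold)
      cs <- connecting_scores(net, maocs,
                              min_modules = config$min_modules)
      list(degrees = degs, hubs = hubs,
           intra = suppressMessages(
             suppressWarnings(top_connectors(cs$intra, config$top_n))),
           inter = suppressMessages(
             suppressWarnings(top_connectors(cs$inter, config$top_n))),
           cs = cs)
    } else {
      NULL
    }
  })
  if (!is.null(topo)) {
    member_of <- function(g) paste(
      names(maocs)[vapply(maocs, function(m) g %in% m, logical(1))],
      collapse = ";")
    report <- data.frame(
      gene = names(topo$degrees$degrees),
      degree = unname(topo$degrees$degrees),
      K = unname(topo$degrees$degrees) / topo$degrees$k_max,
      is_hub = names(topo$degrees$degrees) %in% topo$hubs$gene,
      member_of = vapply(names(topo$degrees$degrees), member_of, ""),
      stringsAsFactors = FALSE)
    write_tsv(report, file.path(config$out_dir, "topology.tsv"))
    write_tsv(topo$cs$intra,
              file.path(config$out_dir, "intra_connectors.tsv"))
    write_tsv(topo$cs$inter,
              file.path(config$out_dir, "inter_connectors.tsv"))
    note("hubs: ", nrow(topo$hubs), " (k_max=", topo$degrees$k_max, ")")
  } else {
    note("no MAOCs; topology and regulator stages degenerate")
  }

  target_map <- stage("mirna_regulation[read]",
                      read_tsv_strict(config$targets))
  screen <- stage("mirna_regulation[screen]", {
    regulator_screen(de_mirna, maocs, target_map,
                     network_genes = igraph::V(net)$name,
                     gene_de = de_gene, alpha = config$enrichment_alpha)
  })
  write_tsv(screen$calls, file.path(config$out_dir, "regulator_calls.tsv"))
  write_tsv(screen$edges,
            file.path(config$out_dir, "mirna_module_edges.tsv"))
  note("regulator calls: ", nrow(screen$calls),
       "; anti-correlated: ",
       sum(isTRUE_vec(screen$calls$anti_correlated)))

  summary <- list(
    n_features_gene = nrow(de_gene),
    n_features_mirna = nrow(de_mirna),
    n_deg = sum(de_gene$is_significant),
    n_demir = sum(de_mirna$is_significant),
    n_network_genes = igraph::vcount(net),
    n_network_edges = igraph::ecount(net),
    n_modules = length(modules),
    n_maocs = nrow(maoc_df),
    maoc_ids = maoc_df$module_id,
    n_hubs = if (is.null(topo)) 0L else nrow(topo$hubs),
    hub_genes = if (is.null(topo)) character() else topo$hubs$gene,
    n_intra_connectors = if (is.null(topo)) 0L else nrow(topo$cs$intra),
    n_inter_connectors = if (is.null(topo)) 0L else nrow(topo$cs$inter),
    n_regulator_calls = nrow(screen$calls),
    n_anti_correlated = sum(isTRUE_vec(screen$calls$anti_correlated)),
    regulator_mirnas = unique(screen$calls$mirna))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(config),
                       file.path(config$out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, log_path)
  invisible(summary)
}
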