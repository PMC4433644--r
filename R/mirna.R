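#' Build a consensus miRNA-target map
#'
#' Predicted miRNA-target pairs are retained only when supported by at least
#' `min_tools` distinct prediction tools; experimentally determined pairs are
#' added unconditionally. The result is a deduplicated pair table.
#'
#' @param predictions data frame with columns `mirna`, `gene`, `tool` (one
#'   row per tool-level prediction).
#' @param experimental optional data frame with columns `mirna`, `gene` of
#'   experimentally supported pairs.
#' @param tools declared tool vocabulary; an undeclared tool name is a
#'   validation error.
#' @param min_tools consensus threshold on distinct predicting tools.
#' @return data frame `mirna`, `gene`, `n_tools`, `experimental` (logical),
#'   one row per retained pair.
#' @export
build_target_map <- function(predictions, experimental = NULL,
                             tools = c("PicTar", "miRanda", "MicroT",
                                       "TargetScan"),
                             min_tools = 2L) {
  predictions <- as.data.frame(predictions)
  stopifnot(all(c("mirna", "gene", "tool") %in% names(predictions)))
  unknown <- setdiff(unique(predictions$tool), tools)
  if (length(unknown)) {
    stop("unknown prediction tool(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(predictions$mirna, predictions$gene, sep = "\r")
  n_tools <- tapply(predictions$tool, key,
                    function(tl) length(unique(tl)))
  pred_pairs <- do.call(rbind, strsplit(names(n_tools), "\r", fixed = TRUE))
  pred <- data.frame(mirna = pred_pairs[, 1L], gene = pred_pairs[, 2L],
                     n_tools = as.integer(n_tools),
                     stringsAsFactors = FALSE)
  exp_key <- character()
  if (!is.null(experimental) && nrow(as.data.frame(experimental))) {
    experimental <- as.data.frame(experimental)
    stopifnot(all(c("mirna", "gene") %in% names(experimental)))
    exp_key <- unique(paste(experimental$mirna, experimental$gene,
                            sep = "\r"))
  }
  pred$experimental <- paste(pred$mirna, pred$gene, sep = "\r") %in% exp_key
  keep <- pred[pred$n_tools >= min_tools | pred$experimental, , drop = FALSE]
  extra <- setdiff(exp_key, paste(keep$mirna, keep$gene, sep = "\r"))
  if (length(extra)) {
    ep <- do.call(rbind, strsplit(extra, "\r", fixed = TRUE))
    keep <- rbind(keep, data.frame(mirna = ep[, 1L], gene = ep[, 2L],
                                   n_tools = 0L, experimental = TRUE,
                                   stringsAsFactors = FALSE))
  }
  keep <- keep[order(keep$mirna, keep$gene), , drop = FALSE]
  rownames(keep) <- NULL
  message("build_target_map: ", nrow(keep), " interactions, ",
          length(unique(keep$mirna)), " miRNAs, ",
          length(unique(keep$gene)), " genes")
  keep
}

#' Fisher enrichment of a miRNA's targets in one module
#'
#' Tests whether the miRNA's target genes are over-represented among the
#' module's members, using a one-sided (greater) Fisher exact test on the
#' 2x2 in-module-by-is-target table over the chosen gene universe.
#'
#' @param target_map data frame with columns `mirna`, `gene` (extra columns
#'   ignored), e.g. from [build_target_map()].
#' @param mirna_id the miRNA to test.
#' @param members module member genes.
#' @param module_id label carried into the result.
#' @param universe background gene universe; module members must lie in it.
#' @param alpha significance cutoff (strict).
#' @return one-row data frame: `mirna`, `module_id`, `module_size`,
#'   `n_targets`, `overlap`, `enrichment_p`, `is_significant`.
#' @export
module_enrichment <- function(target_map, mirna_id, members,
                              module_id = NA_character_,
                              universe, alpha = 0.01) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  members <- intersect(unique(members), universe)
  targets <- intersect(
    unique(target_map$gene[target_map$mirna == mirna_id]), universe)
  overlap <- length(intersect(members, targets))
  n <- length(universe)
  m <- length(members)
  t <- length(targets)
  p <- if (m == 0L || t == 0L) {
    1
  } else {
    tab <- matrix(c(overlap, t - overlap,
                    m - overlap, n - m - t + overlap), nrow = 2L)
    fisher.test(tab, alternative = "greater")$p.value
  }
  data.frame(mirna = mirna_id, module_id = module_id, module_size = m,
             n_targets = t, overlap = overlap, enrichment_p = p,
             is_significant = p < alpha, stringsAsFactors = FALSE)
}

#' Direction anti-correlation between a miRNA and its in-module targets
#'
#' A miRNA is flagged anti-correlated exactly when every considered target
#' with a known change direction moves opposite to the miRNA (up vs down) —
#' the direction-based surrogate for repression used when the gene and miRNA
#' cohorts share no samples.
#'
#' @param mirna_direction `"up"` or `"down"` (case-insensitive).
#' @param target_directions character vector of target directions.
#' @return `TRUE`, `FALSE`, or `NA` when no target has a direction
#'   (not evaluable).
#' @export
direction_correlation <- function(mirna_direction, target_directions) {
  md <- tolower(mirna_direction)
  td <- tolower(target_directions)
  td <- td[!is.na(td) & td %in% c("up", "down")]
  if (is.na(md) || !md %in% c("up", "down") || !length(td)) {
    return(NA)
  }
  all(td != md)
}

#' Screen all differentially expressed miRNAs against all MAOCs
#'
#' Runs [module_enrichment()] for every (DEmiR, MAOC) pair, keeps the
#' significant calls, and annotates each with the direction
#' anti-correlation flag computed over the miRNA's in-module targets.
#'
#' @param demirs data frame of miRNA differential results (as from
#'   [differential_test()]) already filtered, or not, to significant rows;
#'   only rows with `is_significant` are screened.
#' @param maocs named list of MAOC member vectors.
#' @param target_map data frame with `mirna`, `gene` columns.
#' @param universe background gene universe for the enrichment test. The
#'   recommended default — used when `NULL` — is the intersection of network
#'   genes and target-map genes, supplied via `network_genes`.
#' @param network_genes gene symbols present in the PPI network (used only
#'   to form the default universe).
#' @param gene_de optional gene differential results supplying target
#'   directions for the anti-correlation flag.
#' @param alpha enrichment significance cutoff (strict).
#' @return list with `calls` (one row per significant pair, with
#'   `anti_correlated` and directions) and `edges` (two-column miRNA-module
#'   bipartite edge list).
#' @export
regulator_screen <- function(demirs, maocs, target_map, universe = NULL,
                             network_genes = NULL, gene_de = NULL,
                             alpha = 0.01) {
  if (is.null(universe)) {
    if (is.null(network_genes)) {
      stop("supply `universe` or `network_genes`", call. = FALSE)
    }
    universe <- intersect(network_genes, unique(target_map$gene))
  }
  keep <- demirs[isTRUE_vec(demirs$is_significant), , drop = FALSE]
  keep <- keep[keep$feature_id %in% target_map$mirna, , drop = FALSE]
  calls <- list()
  for (i in seq_len(nrow(keep))) {
    mirna <- keep$feature_id[i]
    for (mid in names(maocs)) {
      row <- module_enrichment(target_map, mirna, maocs[[mid]],
                               module_id = mid, universe = universe,
                               alpha = alpha)
      if (!isTRUE(row$is_significant)) next
      in_module <- intersect(
        unique(target_map$gene[target_map$mirna == mirna]), maocs[[mid]])
      tdir <- if (!is.null(gene_de)) {
        gene_de$direction[match(in_module, gene_de$feature_id)]
      } else {
        rep(NA_character_, length(in_module))
      }
      row$mirna_direction <- keep$direction[i]
      row$anti_correlated <- direction_correlation(keep$direction[i], tdir)
      row$targets_in_module <- paste(in_module, collapse = ";")
      row$target_directions <- paste(ifelse(is.na(tdir), "NA", tdir),
                                     collapse = ";")
      calls[[length(calls) + 1L]] <- row
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(mirna = character(), module_id = character(),
               module_size = integer(), n_targets = integer(),
               overlap = integer(), enrichment_p = numeric(),
               is_significant = logical(), mirna_direction = character(),
               anti_correlated = logical(), targets_in_module = character(),
               target_directions = character(), stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  list(calls = calls,
       edges = calls[, c("mirna", "module_id"), drop = FALSE])
}

isTRUE_vec <- function(x) !is.na(x) & x
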