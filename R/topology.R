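#' Degrees and maximum degree over MAOC member genes
#'
#' With `scope = "induced"` (default) degrees are counted inside the subgraph
#' induced by the union of all MAOC members — the module network itself, the
#' graph the scaled-connectivity definition speaks about. With
#' `scope = "full"` degrees are counted in the whole PPI network. `k_max` is
#' the maximum degree over MAOC member genes.
#'
#' @param net the PPI [igraph::graph].
#' @param maocs named list of module member vectors.
#' @param scope `"induced"` or `"full"`.
#' @return list with `degrees` (named integer over member genes) and `k_max`.
#' @export
maoc_degrees <- function(net, maocs, scope = c("induced", "full")) {
  scope <- match.arg(scope)
  members <- sort(unique(unlist(maocs, use.names = FALSE)))
  if (!length(members)) stop("empty MAOC union", call. = FALSE)
  members <- intersect(members, igraph::V(net)$name)
  if (!length(members)) stop("no MAOC member present in the network",
                             call. = FALSE)
  g <- if (scope == "induced") {
    igraph::induced_subgraph(net, members)
  } else {
    net
  }
  deg <- igraph::degree(g)[members]
  list(degrees = deg, k_max = max(deg))
}

#' Call hub genes by scaled connectivity
#'
#' Scaled connectivity is K_i = k_i / k_max; genes strictly above the
#' threshold (0.9 by convention) are hubs.
#'
#' @param degrees named integer vector of gene degrees.
#' @param k_max maximum degree (defaults to `max(degrees)`).
#' @param threshold strict lower bound on K for hub status.
#' @return data frame `gene`, `degree`, `K`, sorted by degree descending then
#'   symbol; only hub rows are kept.
#' @export
call_hubs <- function(degrees, k_max = max(degrees), threshold = 0.9) {
  if (k_max <= 0) stop("`k_max` must be positive", call. = FALSE)
  K <- degrees / k_max
  out <- data.frame(gene = names(degrees), degree = unname(degrees),
                    K = unname(K), stringsAsFactors = FALSE)
  out <- out[out$K > threshold, , drop = FALSE]
  out <- out[order(-out$degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Connecting scores of intra- and inter-MAOC genes
#'
#' Genes that bridge modules are scored by the number of distinct MAOCs they
#' link to. An intra-MAOC connector is a module member with at least one
#' interaction partner in a MAOC it does not belong to; its connecting score
#' counts the distinct other MAOCs containing at least one neighbour
#' (membership itself is not linkage, so the gene's own modules are
#' excluded). An inter-MAOC connector is a non-member whose neighbours fall
#' in at least `min_modules` distinct MAOCs; its score counts all MAOCs
#' containing a neighbour.
#'
#' @param net the PPI [igraph::graph] (the full network, so that non-member
#'   genes are visible).
#' @param maocs named list of module member vectors.
#' @param min_modules eligibility minimum for inter-MAOC connectors.
#' @return list of two data frames, `intra` and `inter`, each with columns
#'   `gene`, `connecting_score`, `degree` and (intra only) `member_of`
#'   (semicolon-joined module ids); sorted by (score desc, degree desc,
#'   symbol).
#' @export
connecting_scores <- function(net, maocs, min_modules = 2L) {
  stopifnot(igraph::is_igraph(net), length(maocs) > 0L)
  vnames <- igraph::V(net)$name
  member_union <- unique(unlist(maocs, use.names = FALSE))
  deg <- igraph::degree(net)
  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  neighbour_modules <- function(gene) {
    nb <- vnames[as.integer(adj[[match(gene, vnames)]])]
    names(maocs)[vapply(maocs, function(m) any(nb %in% m), logical(1))]
  }
  intra_rows <- list()
  inter_rows <- list()
  for (gene in vnames) {
    own <- names(maocs)[vapply(maocs, function(m) gene %in% m, logical(1))]
    linked <- neighbour_modules(gene)
    if (length(own)) {
      cs <- length(setdiff(linked, own))
      if (cs >= 1L) {
        intra_rows[[gene]] <- data.frame(
          gene = gene, connecting_score = cs, degree = unname(deg[gene]),
          member_of = paste(own, collapse = ";"), stringsAsFactors = FALSE)
      }
    } else if (gene %in% vnames && !(gene %in% member_union)) {
      cs <- length(linked)
      if (cs >= min_modules) {
        inter_rows[[gene]] <- data.frame(
          gene = gene, connecting_score = cs, degree = unname(deg[gene]),
          stringsAsFactors = FALSE)
      }
    }
  }
  sort_cs <- function(df) {
    if (!nrow(df)) return(df)
    df <- df[order(-df$connecting_score, -df$degree, df$gene), ,
             drop = FALSE]
    rownames(df) <- NULL
    df
  }
  empty_intra <- data.frame(gene = character(), connecting_score = integer(),
                            degree = numeric(), member_of = character(),
                            stringsAsFactors = FALSE)
  empty_inter <- empty_intra[, names(empty_intra) != "member_of"]
  list(
    intra = sort_cs(if (length(intra_rows))
      do.call(rbind, intra_rows) else empty_intra),
    inter = sort_cs(if (length(inter_rows))
      do.call(rbind, inter_rows) else empty_inter)
  )
}

#' Top-n connector genes
#'
#' Takes the first `n` rows under the connecting-score sort order
#' (score desc, degree desc, symbol); boundary ties are resolved by the
#' secondary keys and noted in a message.
#'
#' @param connectors a data frame from [connecting_scores()].
#' @param n selection size.
#' @return the first `n` rows (all rows, with a warning, if fewer exist).
#' @export
top_connectors <- function(connectors, n = 5L) {
  stopifnot(is.data.frame(connectors))
  df <- connectors[order(-connectors$connecting_score, -connectors$degree,
                         connectors$gene), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) < n) {
    warning("only ", nrow(df), " connector genes available (requested ",
            n, ")")
    return(df)
  }
  if (nrow(df) > n && df$connecting_score[n] == df$connecting_score[n + 1L]) {
    message("top_connectors: tie at the selection boundary (score ",
            df$connecting_score[n], ") resolved by degree then symbol")
  }
  head(df, n)
}
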