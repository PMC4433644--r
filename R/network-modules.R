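#' Read a protein-protein interaction network from a two-column edge list
#'
#' Edges are undirected gene-symbol pairs, one per tab-delimited line with a
#' header. Self-interactions are dropped and duplicate pairs (in either
#' order) are collapsed, so the result is a simple undirected graph; the
#' number of lines removed by each rule is reported.
#'
#' @param path edge-list TSV with two columns.
#' @return an undirected simple [igraph::graph] object.
#' @export
read_ppi <- function(path) {
  lines <- readLines(path)
  if (length(lines) <= 1L) {
    warning("empty PPI edge list: ", path)
    return(igraph::make_empty_graph(directed = FALSE))
  }
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad)) {
    stop("malformed PPI line ", bad[1L] + 1L, ": '", body[bad[1L]], "'",
         call. = FALSE)
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  self <- a == b
  if (any(self)) {
    message("read_ppi: dropped ", sum(self), " self-interactions")
  }
  a2 <- pmin(a[!self], b[!self])
  b2 <- pmax(a[!self], b[!self])
  dup <- duplicated(paste(a2, b2, sep = "\r"))
  if (any(dup)) {
    message("read_ppi: collapsed ", sum(dup), " duplicate edges")
  }
  g <- igraph::graph_from_edgelist(cbind(a2[!dup], b2[!dup]),
                                   directed = FALSE)
  message("read_ppi: ", igraph::vcount(g), " proteins, ",
          igraph::ecount(g), " interactions")
  g
}

#' Detect overlapping network modules by k-clique percolation
#'
#' A module (community) is a maximal union of k-cliques connected through
#' adjacency, where two k-cliques are adjacent when they share k-1 nodes.
#' Communities may overlap: a gene can belong to several modules, which is
#' the behaviour the module analysis relies on. The construction enumerates
#' all k-cliques, links cliques through shared (k-1)-node subsets, and takes
#' connected components of that clique graph.
#'
#' @param net an undirected [igraph::graph].
#' @param k clique size (>= 3); k = 3 is the canonical default.
#' @return named list (`M1`, `M2`, ...) of sorted member-gene vectors,
#'   ordered by decreasing size then lexicographically by first member.
#' @export
detect_modules <- function(net, k = 3L) {
  if (k < 3L) stop("`k` must be >= 3", call. = FALSE)
  stopifnot(igraph::is_igraph(net))
  if (igraph::vcount(net) == 0L) return(stats::setNames(list(), character()))
  cls <- igraph::cliques(net, min = k, max = k)
  if (!length(cls)) return(stats::setNames(list(), character()))
  vnames <- igraph::V(net)$name
  cliques <- lapply(cls, function(cl) sort(vnames[as.integer(cl)]))
  comp <- clique_components(cliques, k)
  members <- lapply(split(seq_along(cliques), comp), function(idx) {
    sort(unique(unlist(cliques[idx], use.names = FALSE)))
  })
  ord <- order(-lengths(members),
               vapply(members, `[[`, "", 1L))
  members <- members[ord]
  names(members) <- paste0("M", seq_along(members))
  members
}

# Union-find over cliques: two k-cliques are in the same community when
# they share a (k-1)-subset, chained transitively.
clique_components <- function(cliques, k) {
  n <- length(cliques)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  keys <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    cl <- cliques[[i]]
    for (drop in seq_len(k)) {
      key <- paste(cl[-drop], collapse = "\r")
      j <- keys[[key]]
      if (is.null(j)) {
        keys[[key]] <- i
      } else {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Score a module's relevance by the mean member t-score
#'
#' The module score S is the arithmetic mean of the t-scores of its member
#' genes, summing over the m members with an available t-score. Members with
#' no expression measurement contribute to neither numerator nor
#' denominator, so observed and permuted scores stay on the same scale.
#'
#' @param members character vector of member genes.
#' @param t_scores named numeric vector of per-gene t-scores.
#' @return list with `score` (S) and `n_scored` (m). If no member has a
#'   t-score, `score` is NA with a warning.
#' @export
score_module <- function(members, t_scores) {
  ts <- t_scores[intersect(members, names(t_scores))]
  ts <- ts[is.finite(ts)]
  if (!length(ts)) {
    warning("module has no member with a t-score; skipped")
    return(list(score = NA_real_, n_scored = 0L))
  }
  list(score = sum(ts) / length(ts), n_scored = length(ts))
}

#' Empirical permutation P-value for a module score
#'
#' Draws `n_perm` random gene sets of the same size as the module's scored
#' member count from the universe of genes with t-scores, scores each the
#' same way, and reports the frequency of permuted scores strictly larger
#' than the observed S. The test is one-sided toward high (positive-t)
#' scores, exactly as the score is defined. `add_one` switches to the
#' bias-corrected (r+1)/(n+1) estimator.
#'
#' @inheritParams score_module
#' @param n_perm number of random draws (10000 reproduces the reference
#'   calibration).
#' @param seed optional RNG seed; the caller's RNG state is restored.
#' @param add_one use the add-one corrected estimator (off by default).
#' @param universe optional character vector restricting the resampling pool;
#'   defaults to every feature with a finite t-score.
#' @return list with `p_value`, `score`, `n_scored`.
#' @export
permutation_pvalue <- function(members, t_scores, n_perm = 10000L,
                               seed = NULL, add_one = FALSE,
                               universe = NULL) {
  if (n_perm < 1L) stop("`n_perm` must be >= 1", call. = FALSE)
  finite <- t_scores[is.finite(t_scores)]
  obs <- score_module(members, finite)
  pool <- if (is.null(universe)) finite else
    finite[intersect(universe, names(finite))]
  if (obs$n_scored == 0L) {
    return(list(p_value = NA_real_, score = NA_real_, n_scored = 0L))
  }
  if (length(pool) < obs$n_scored) {
    stop("resampling universe (", length(pool),
         ") smaller than module (", obs$n_scored, ")", call. = FALSE)
  }
  draw <- function() {
    null_scores <- vapply(seq_len(n_perm), function(i) {
      mean(pool[sample.int(length(pool), obs$n_scored)])
    }, numeric(1))
    sum(null_scores > obs$score)
  }
  r <- if (is.null(seed)) draw() else with_seed(seed, draw())
  p <- if (add_one) (r + 1) / (n_perm + 1) else r / n_perm
  list(p_value = p, score = obs$score, n_scored = obs$n_scored)
}

#' Score and permutation-test every detected module
#'
#' @param modules named list of member vectors, as from [detect_modules()].
#' @inheritParams permutation_pvalue
#' @return data frame with one row per module: `module_id`, `size`,
#'   `n_scored`, `score`, `p_value`. Modules with no scored member are
#'   dropped with a warning.
#' @export
score_modules <- function(modules, t_scores, n_perm = 10000L, seed = NULL,
                          add_one = FALSE, universe = NULL) {
  if (!length(modules)) {
    return(data.frame(module_id = character(), size = integer(),
                      n_scored = integer(), score = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  }
  seeds <- if (is.null(seed)) rep(list(NULL), length(modules)) else
    as.list(seed + seq_along(modules) - 1L)
  rows <- lapply(seq_along(modules), function(i) {
    res <- suppressWarnings(
      permutation_pvalue(modules[[i]], t_scores, n_perm = n_perm,
                         seed = seeds[[i]], add_one = add_one,
                         universe = universe))
    data.frame(module_id = names(modules)[i],
               size = length(modules[[i]]),
               n_scored = res$n_scored, score = res$score,
               p_value = res$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  skipped <- is.na(out$score)
  if (any(skipped)) {
    warning(sum(skipped), " modules without scored members were skipped")
    out <- out[!skipped, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Select modules associated with the outcome (MAOCs)
#'
#' Keeps modules whose empirical permutation P-value is below `alpha`
#' (strict), ordered by (P ascending, score descending, module id).
#'
#' @param scored data frame from [score_modules()].
#' @param alpha module-level significance cutoff.
#' @return the filtered, sorted data frame.
#' @export
select_maocs <- function(scored, alpha = 0.01) {
  stopifnot(is.data.frame(scored),
            all(c("module_id", "score", "p_value") %in% names(scored)))
  keep <- scored[!is.na(scored$p_value) & scored$p_value < alpha, ,
                 drop = FALSE]
  keep <- keep[order(keep$p_value, -keep$score, keep$module_id), ,
               drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' Write modules in a GMT-like TSV
#'
#' One line per module: id, score, P-value, then the member symbols.
#'
#' @param scored data frame from [score_modules()] (or a subset).
#' @param modules named list of member vectors covering `scored$module_id`.
#' @param path output file.
#' @export
write_modules_gmt <- function(scored, modules, path) {
  lines <- vapply(seq_len(nrow(scored)), function(i) {
    id <- scored$module_id[i]
    paste(c(id, format(scored$score[i], digits = 10),
            format(scored$p_value[i], digits = 10), modules[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read modules written by [write_modules_gmt()]
#'
#' @param path GMT-like TSV path.
#' @return list with `scored` (data frame) and `modules` (named list).
#' @export
read_modules_gmt <- function(path) {
  fields <- strsplit(readLines(path), "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, "", 1L)
  scored <- data.frame(
    module_id = ids,
    size = lengths(fields) - 3L,
    n_scored = NA_integer_,
    score = as.numeric(vapply(fields, `[[`, "", 2L)),
    p_value = as.numeric(vapply(fields, `[[`, "", 3L)),
    stringsAsFactors = FALSE)
  modules <- lapply(fields, function(f) f[-(1:3)])
  names(modules) <- ids
  list(scored = scored, modules = modules)
}
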