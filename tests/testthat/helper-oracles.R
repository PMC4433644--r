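# Independent brute-force oracles used across the suite. These deliberately
# avoid the implementation paths they check.

# Exhaustive k-clique percolation: enumerate all k-subsets, keep cliques,
# join cliques sharing exactly k-1 nodes, take components by breadth-first
# search over the clique-adjacency relation.
cpm_oracle <- function(net, k) {
  vs <- sort(igraph::V(net)$name)
  adj <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  adj <- adj[vs, vs, drop = FALSE]
  if (length(vs) < k) return(list())
  subsets <- utils::combn(vs, k, simplify = FALSE)
  is_clique <- vapply(subsets, function(s) {
    all(adj[s, s][upper.tri(diag(length(s)))] > 0)
  }, logical(1))
  cliques <- subsets[is_clique]
  n <- length(cliques)
  if (!n) return(list())
  linked <- function(i, j) {
    length(intersect(cliques[[i]], cliques[[j]])) == k - 1L
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      i <- queue[[1L]]; queue <- queue[-1L]
      for (j in seq_len(n)) {
        if (is.na(comp[j]) && linked(i, j)) {
          comp[j] <- cid
          queue <- c(queue, j)
        }
      }
    }
  }
  out <- lapply(split(seq_len(n), comp), function(idx) {
    sort(unique(unlist(cliques[idx])))
  })
  unname(out[order(-lengths(out), vapply(out, `[[`, "", 1L))])
}

# Hypergeometric upper-tail sum: P(overlap >= a) for a universe of size N
# with t targets and a module of size m.
hyper_tail_oracle <- function(N, t, m, a) {
  xs <- a:min(t, m)
  sum(choose(t, xs) * choose(N - t, m - xs)) / choose(N, m)
}

# Small expression_set builder: `rows` is a named list of numeric vectors
# laid out case samples first.
make_es <- function(rows, n_case, n_ctrl) {
  vals <- do.call(rbind, rows)
  colnames(vals) <- c(sprintf("c%02d", seq_len(n_case)),
                      sprintf("k%02d", seq_len(n_ctrl)))
  expression_set(vals, rep(c("case", "control"), c(n_case, n_ctrl)),
                 case_group = "case")
}

random_named_gnp <- function(n, p, seed) {
  withr_seed <- function(expr) expr
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# Shared small synthetic config so expensive generation happens once per
# file, not per test.
tiny_config <- function(...) {
  defaults <- list(n_genes = 200L, n_mirnas = 40L,
                   n_samples_per_group = 10L, n_planted_modules = 2L,
                   planted_module_size = 6L, ppi_mean_degree = 4,
                   targets_per_mirna = 6L,
                   planted_regulator_fraction = 0.1)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}
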