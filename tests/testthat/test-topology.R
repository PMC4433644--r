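graph_from_pairs <- function(a, b) {
  igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
}

test_that("MAOC degrees and k_max follow the induced subgraph", {
  # isolated 4-clique: every member has degree 3
  g <- graph_from_pairs(c("a", "a", "a", "b", "b", "c"),
                        c("b", "c", "d", "c", "d", "d"))
  d <- maoc_degrees(g, list(M1 = c("a", "b", "c", "d")))
  expect_true(all(d$degrees == 3))
  expect_equal(d$k_max, 3)
  # two disjoint triangles as two MAOCs: all degrees 2
  g2 <- graph_from_pairs(c("a", "b", "c", "x", "y", "z"),
                         c("b", "c", "a", "y", "z", "x"))
  d2 <- maoc_degrees(g2, list(M1 = c("a", "b", "c"),
                              M2 = c("x", "y", "z")))
  expect_true(all(d2$degrees == 2))
  # induced scope ignores edges to non-members; full scope counts them
  g3 <- igraph::add_edges(g2, c("a", "x", "a", "y", "a", "z"))
  d3i <- maoc_degrees(g3, list(M1 = c("a", "b", "c")))
  expect_equal(unname(d3i$degrees["a"]), 2)
  d3f <- maoc_degrees(g3, list(M1 = c("a", "b", "c")), scope = "full")
  expect_equal(unname(d3f$degrees["a"]), 5)
  expect_error(maoc_degrees(g, list()), "empty")
})

test_that("induced degrees equal a brute-force adjacency scan", {
  g <- random_named_gnp(15, 0.4, seed = 21)
  maocs <- list(A = sprintf("n%02d", 1:6), B = sprintf("n%02d", 5:11))
  d <- maoc_degrees(g, maocs)
  members <- sort(unique(unlist(maocs)))
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)[members, members]
  expect_equal(d$degrees[members], rowSums(adj)[members])
  expect_equal(d$k_max, max(rowSums(adj)))
})

test_that("hub calling is strict and reproduces the reference pattern", {
  degrees <- c(STAT5B = 17, EGFR = 16, PDGFRB = 16, STAT5A = 16, RAF1 = 10)
  hubs <- call_hubs(degrees, threshold = 0.9)
  expect_equal(hubs$gene, c("STAT5B", "EGFR", "PDGFRB", "STAT5A"))
  expect_false("RAF1" %in% hubs$gene)   # 10/17 = 0.588
  # all degrees equal: K = 1 everywhere, all are hubs
  eq <- setNames(rep(4, 3), c("a", "b", "c"))
  expect_equal(nrow(call_hubs(eq, threshold = 0.9)), 3)
  # threshold 1.0 under strict inequality calls nothing
  expect_equal(nrow(call_hubs(degrees, threshold = 1.0)), 0)
})

test_that("connecting scores count distinct linked modules", {
  # gene 'a' in module A with all neighbours inside A: not a connector
  g <- graph_from_pairs(c("a", "a", "b"), c("b", "c", "c"))
  cs <- connecting_scores(g, list(A = c("a", "b", "c"),
                                  B = c("z1", "z2")), min_modules = 1)
  expect_false("a" %in% cs$intra$gene)
  # outside gene adjacent to one member of each of 3 MAOCs: inter CS = 3
  g2 <- graph_from_pairs(c("out", "out", "out", "a", "x", "p"),
                         c("a", "x", "p", "b", "y", "q"))
  maocs <- list(A = c("a", "b"), B = c("x", "y"), C = c("p", "q"))
  cs2 <- connecting_scores(g2, maocs)
  expect_equal(cs2$inter$gene, "out")
  expect_equal(cs2$inter$connecting_score, 3)
  # membership is not linkage: own modules are excluded from intra CS
  g3 <- graph_from_pairs(c("m", "m"), c("n", "x"))
  cs3 <- connecting_scores(g3, list(A = c("m", "n"), B = c("x", "w")))
  expect_equal(cs3$intra$connecting_score[cs3$intra$gene == "m"], 1)
  # a gene belonging to every MAOC can have no "other" module to link
  cs4 <- connecting_scores(g3, list(A = c("m", "n"), B = c("m", "x")))
  expect_false("m" %in% cs4$intra$gene)
})

test_that("connecting scores match an exhaustive (gene, module) scan", {
  g <- random_named_gnp(20, 0.25, seed = 31)
  vs <- igraph::V(g)$name
  maocs <- list(A = vs[1:5], B = vs[4:9], C = vs[10:13], D = vs[13:16])
  cs <- connecting_scores(g, maocs, min_modules = 2)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  for (gene in vs) {
    nb <- vs[adj[gene, ] > 0]
    linked <- names(maocs)[vapply(maocs, function(m) any(nb %in% m),
                                  logical(1))]
    own <- names(maocs)[vapply(maocs, function(m) gene %in% m, logical(1))]
    if (length(own)) {
      expected <- length(setdiff(linked, own))
      got <- cs$intra$connecting_score[cs$intra$gene == gene]
      if (expected >= 1) expect_equal(got, expected, info = gene)
      else expect_length(got, 0)
    } else {
      expected <- length(linked)
      got <- cs$inter$connecting_score[cs$inter$gene == gene]
      if (expected >= 2) expect_equal(got, expected, info = gene)
      else expect_length(got, 0)
    }
  }
})

test_that("removing an edge never increases a degree or connecting score", {
  g <- random_named_gnp(14, 0.35, seed = 77)
  vs <- igraph::V(g)$name
  maocs <- list(A = vs[1:4], B = vs[5:9], C = vs[10:12])
  before <- connecting_scores(g, maocs, min_modules = 1)
  deg_before <- maoc_degrees(g, maocs)
  el <- igraph::as_edgelist(g)
  for (i in sample(nrow(el), 5)) {
    g2 <- igraph::delete_edges(g, paste(el[i, 1], el[i, 2], sep = "|"))
    after <- connecting_scores(g2, maocs, min_modules = 1)
    for (lst in c("intra", "inter")) {
      shared <- intersect(before[[lst]]$gene, after[[lst]]$gene)
      expect_true(all(
        after[[lst]]$connecting_score[match(shared, after[[lst]]$gene)] <=
          before[[lst]]$connecting_score[match(shared,
                                               before[[lst]]$gene)]))
      # genes can leave the connector lists but never newly appear
      expect_true(all(after[[lst]]$gene %in% before[[lst]]$gene))
    }
    deg_after <- maoc_degrees(g2, maocs)
    expect_true(all(deg_after$degrees <= deg_before$degrees))
  }
})

test_that("top connector selection respects the documented sort order", {
  df <- data.frame(gene = c("g1", "g2", "g3", "g4", "g5", "g6"),
                   connecting_score = c(8, 7, 6, 6, 4, 3),
                   degree = c(5, 5, 9, 2, 2, 2))
  top <- suppressMessages(top_connectors(df, 5))
  expect_equal(top$gene, c("g1", "g2", "g3", "g4", "g5"))
  expect_warning(top_connectors(df[1:3, ], 5), "only 3")
  # randomized lists match an independent sort oracle
  set.seed(9)
  rnd <- data.frame(gene = sprintf("r%02d", 1:12),
                    connecting_score = sample(1:5, 12, replace = TRUE),
                    degree = sample(1:20, 12))
  got <- suppressMessages(top_connectors(rnd, 4))
  oracle <- rnd[order(-rnd$connecting_score, -rnd$degree, rnd$gene), ][1:4, ]
  rownames(oracle) <- NULL
  expect_equal(got, oracle)
})
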