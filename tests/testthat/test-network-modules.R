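write_edges <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c("gene_a\tgene_b", lines), path)
  path
}

test_that("the PPI reader builds a simple graph and reports cleanup", {
  p <- write_edges(c("A\tB", "B\tA", "C\tC"))
  g <- suppressMessages(read_ppi(p))
  expect_setequal(igraph::V(g)$name, c("A", "B"))
  expect_equal(igraph::ecount(g), 1)
  # 10-line toy: 2 duplicates (one reversed) and 1 self-loop leave 7 edges
  toy <- c("A\tB", "B\tC", "C\tD", "D\tE", "E\tF", "F\tA", "A\tC",
           "B\tA", "C\tB", "E\tE")
  g2 <- suppressMessages(read_ppi(write_edges(toy)))
  expect_equal(igraph::ecount(g2), 7)
  expect_warning(read_ppi(write_edges(character())), "empty")
  expect_error(suppressMessages(read_ppi(write_edges(c("A\tB", "oops")))),
               "line 3")
})

test_that("clique percolation handles the minimal textbook cases", {
  tri <- igraph::graph_from_edgelist(
    cbind(c("a", "b", "c"), c("b", "c", "a")), directed = FALSE)
  mods <- detect_modules(tri, k = 3)
  expect_length(mods, 1)
  expect_equal(mods$M1, c("a", "b", "c"))
  # two triangles sharing an edge percolate into one 4-node community
  g2 <- igraph::graph_from_edgelist(
    cbind(c("a", "b", "c", "b", "c"), c("b", "c", "a", "d", "d")),
    directed = FALSE)
  mods2 <- detect_modules(g2, k = 3)
  expect_length(mods2, 1)
  expect_equal(mods2$M1, c("a", "b", "c", "d"))
  # two triangles sharing only a vertex stay separate at k = 3
  g3 <- igraph::graph_from_edgelist(
    cbind(c("a", "b", "c", "x", "y"), c("b", "c", "a", "y", "c")),
    directed = FALSE)
  g3 <- igraph::add_edges(g3, c("x", "c"))
  expect_length(detect_modules(g3, k = 3), 2)
  expect_error(detect_modules(tri, k = 2), ">= 3")
})

test_that("clique percolation equals the exhaustive oracle on small graphs", {
  for (seed in 1:12) {
    n <- sample(6:12, 1)
    p <- runif(1, 0.25, 0.65)
    g <- random_named_gnp(n, p, seed)
    for (k in c(3L, 4L)) {
      got <- unname(detect_modules(g, k = k))
      expect_identical(got, cpm_oracle(g, k),
                       info = sprintf("seed=%d n=%d p=%.2f k=%d",
                                      seed, n, p, k))
    }
  }
})

test_that("module scores are mean member t-scores, order-invariant", {
  ts <- c(a = 2, b = 4, c = 1.1, d = -0.3, e = 2.2, f = 0, g = 0.5)
  expect_equal(score_module(c("a", "b"), ts)$score, 3)
  expect_equal(score_module(c("f", "f2"), c(f = 0, f2 = 0))$score, 0)
  s5 <- score_module(c("c", "d", "e", "f", "g"), ts)
  expect_equal(s5$score, 0.7)
  expect_equal(s5$n_scored, 5L)
  expect_equal(score_module(rev(c("c", "d", "e", "f", "g")), ts)$score,
               s5$score)
  # members without a t-score drop out of numerator and denominator
  expect_equal(score_module(c("a", "b", "nope"), ts),
               list(score = 3, n_scored = 2L))
  expect_warning(res <- score_module(c("zz"), ts), "skipped")
  expect_true(is.na(res$score))
})

test_that("permutation P matches exact enumeration and is seed-stable", {
  # singleton module in a 3-gene universe: exact P = 1/3
  ts <- c(g1 = 1, g2 = 2, g3 = 3)
  res <- permutation_pvalue("g2", ts, n_perm = 10000, seed = 99)
  se <- sqrt((1 / 3) * (2 / 3) / 10000)
  expect_lt(abs(res$p_value - 1 / 3), 3 * se)
  expect_equal(res$p_value,
               permutation_pvalue("g2", ts, n_perm = 10000,
                                  seed = 99)$p_value)
  # a module that attains the maximum possible mean gets P = 0
  expect_equal(permutation_pvalue("g3", ts, n_perm = 5000,
                                  seed = 1)$p_value, 0)
  # size-2 module against full enumeration of all C(6,2) draws
  set.seed(8)
  ts6 <- setNames(rnorm(6), paste0("x", 1:6))
  members <- c("x2", "x5")
  all_means <- combn(ts6, 2, mean)
  exact <- mean(all_means > mean(ts6[members]))
  est <- permutation_pvalue(members, ts6, n_perm = 10000, seed = 4)$p_value
  expect_lt(abs(est - exact),
            3 * sqrt(exact * (1 - exact) / 10000) + 1e-4)
  # negating every t-score flips the one-sided test: P -> 1 - P up to the
  # exact probability of score ties, known here from full enumeration
  est_neg <- permutation_pvalue(members, -ts6, n_perm = 10000,
                                seed = 4)$p_value
  exact_neg <- mean(all_means < mean(ts6[members]))
  expect_lt(abs(est_neg - exact_neg),
            3 * sqrt(exact_neg * (1 - exact_neg) / 10000) + 1e-4)
  tie_p <- mean(all_means == mean(ts6[members]))
  expect_equal(exact + exact_neg + tie_p, 1)
  # add-one correction applies (r+1)/(n+1)
  p_raw <- permutation_pvalue("g3", ts, n_perm = 100, seed = 2)$p_value
  p_corr <- permutation_pvalue("g3", ts, n_perm = 100, seed = 2,
                               add_one = TRUE)$p_value
  expect_equal(p_corr, (p_raw * 100 + 1) / 101)
  expect_error(permutation_pvalue(c("g1", "g2"), ts[1:2], universe = "g1"),
               "smaller")
})

test_that("MAOC selection filters by strict alpha and sorts stably", {
  scored <- data.frame(
    module_id = c("M1", "M2", "M3", "M4"),
    size = c(3L, 4L, 3L, 5L), n_scored = c(3L, 4L, 3L, 5L),
    score = c(1.2, 2.0, 0.4, 1.2),
    p_value = c(0.02, 0.001, 0.5, 0.001))
  sel <- select_maocs(scored, alpha = 0.01)
  expect_equal(sel$module_id, c("M2", "M4"))
  expect_equal(nrow(select_maocs(scored, alpha = 0.0005)), 0)
  all_half <- transform(scored, p_value = 0.5)
  expect_equal(nrow(select_maocs(all_half, alpha = 0.01)), 0)
})

test_that("GMT round trip preserves scores and members", {
  mods <- list(M1 = c("a", "b", "c"), M2 = c("b", "d", "e", "f"))
  scored <- data.frame(module_id = c("M1", "M2"), size = c(3L, 4L),
                       n_scored = c(3L, 4L), score = c(0.5, -1.25),
                       p_value = c(0.01, 0.2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_modules_gmt(scored, mods, path)
  back <- read_modules_gmt(path)
  expect_equal(back$modules, mods)
  expect_equal(back$scored$score, scored$score)
  expect_equal(back$scored$p_value, scored$p_value)
})
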