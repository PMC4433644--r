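test_that("probe collapsing averages probe rows and drops unmapped probes", {
  vals <- rbind(p1 = c(1, 3), p2 = c(3, 5), p3 = c(10, 10),
                p4 = c(0, 2), p5 = c(7, 7))
  # need >= 2 samples per group: duplicate columns into a 4-sample layout
  vals <- cbind(vals, vals)
  colnames(vals) <- c("a", "b", "c", "d")
  es <- expression_set(vals, c("case", "case", "control", "control"),
                       case_group = "case")
  pm <- data.frame(probe = c("p1", "p2", "p4", "p5"),
                   feature = c("G", "G", "H", "H"))
  out <- suppressMessages(collapse_probes(es, pm))
  expect_setequal(rownames(out$values), c("G", "H"))
  expect_equal(out$values["G", ], colMeans(vals[c("p1", "p2"), ]))
  expect_equal(unname(out$values["G", 1:2]), c(2, 4))
  # brute-force mean oracle over a random probe layout
  set.seed(5)
  rv <- matrix(rnorm(40), nrow = 10,
               dimnames = list(sprintf("pr%02d", 1:10), c("a", "b", "c", "d")))
  res <- expression_set(rv, c("case", "case", "control", "control"))
  map <- data.frame(probe = rownames(rv),
                    feature = sample(c("F1", "F2"), 10, replace = TRUE))
  got <- collapse_probes(res, map)
  for (f in unique(map$feature)) {
    expect_equal(got$values[f, ],
                 colMeans(rv[map$probe[map$feature == f], , drop = FALSE]))
  }
  # one probe per feature: identity on the rows
  id_map <- data.frame(probe = rownames(rv), feature = rownames(rv))
  expect_equal(collapse_probes(res, id_map)$values[rownames(rv), ],
               rv)
  expect_error(collapse_probes(res, data.frame(probe = "zzz",
                                               feature = "F")),
               "no probe")
})

test_that("imputation fills missing cells by row mean or nearest rows", {
  vals <- rbind(f1 = c(1, NA, 3, 4), f2 = c(2, 2, 2, 2),
                f3 = c(0, 4, NA, 8))
  colnames(vals) <- letters[1:4]
  es <- expression_set(vals, c("case", "case", "control", "control"))
  got <- impute_missing(es, "mean")
  expect_equal(unname(got$values["f1", 2]), mean(c(1, 3, 4)))
  expect_equal(unname(got$values["f3", 3]), mean(c(0, 4, 8)))
  expect_false(anyNA(got$values))
  # already complete: returned unchanged
  full <- impute_missing(got, "knn", k = 1)
  expect_identical(full$values, got$values)
  # knn with k = 1 equals the single nearest row's cell, by exhaustive
  # distance computation on co-observed columns
  kv <- rbind(r1 = c(1, 2, NA, 4), r2 = c(1, 2, 9, 4), r3 = c(50, 60, 1, 80))
  colnames(kv) <- letters[1:4]
  kes <- expression_set(kv, c("case", "case", "control", "control"))
  kout <- impute_missing(kes, "knn", k = 1)
  d12 <- sqrt(sum((kv["r1", c(1, 2, 4)] - kv["r2", c(1, 2, 4)])^2))
  d13 <- sqrt(sum((kv["r1", c(1, 2, 4)] - kv["r3", c(1, 2, 4)])^2))
  nearest <- if (d12 < d13) "r2" else "r3"
  expect_equal(unname(kout$values["r1", 3]), unname(kv[nearest, 3]))
  # a fully missing row is an error naming the feature
  bad <- rbind(ok = c(1, 2, 3, 4), gone = c(NA, NA, NA, NA))
  colnames(bad) <- letters[1:4]
  bes <- expression_set(bad, c("case", "case", "control", "control"))
  expect_error(impute_missing(bes, "mean"), "gone")
})

test_that("pooled t matches the closed form, t.test, and the worked example", {
  es <- make_es(list(f1 = c(1, 2, 3, 4, 5, 6)), 3, 3)
  de <- differential_test(es, alpha = 0.05)
  expect_equal(de$t_score, -3.674235, tolerance = 1e-6)
  expect_equal(de$p_value, 0.0213, tolerance = 1e-2)
  expect_equal(de$direction, "down")
  # identical group means with nonzero variance: t = 0, p = 1
  es0 <- make_es(list(f = c(1, 3, 2, 1, 3, 2)), 3, 3)
  de0 <- differential_test(es0)
  expect_equal(de0$t_score, 0)
  expect_equal(de0$p_value, 1)
  # random matrices: agreement with the textbook pooled formula (1e-10
  # relative) and with stats::t.test as an independent oracle
  set.seed(42)
  n1 <- 7; n2 <- 5
  vals <- matrix(rnorm(30 * (n1 + n2)), nrow = 30,
                 dimnames = list(sprintf("g%02d", 1:30),
                                 sprintf("s%02d", 1:(n1 + n2))))
  ees <- expression_set(vals, rep(c("case", "control"), c(n1, n2)))
  for (variant in c("pooled", "welch")) {
    de <- differential_test(ees, variant = variant)
    for (i in seq_len(nrow(vals))) {
      tt <- t.test(vals[i, 1:n1], vals[i, n1 + 1:n2],
                   var.equal = variant == "pooled")
      expect_equal(de$t_score[i], unname(tt$statistic), tolerance = 1e-10)
      expect_equal(de$p_value[i], tt$p.value, tolerance = 1e-10)
    }
  }
  de <- differential_test(ees)
  x1 <- vals[, 1:n1]; x2 <- vals[, n1 + 1:n2]
  sp2 <- ((n1 - 1) * apply(x1, 1, var) + (n2 - 1) * apply(x2, 1, var)) /
    (n1 + n2 - 2)
  t_manual <- (rowMeans(x1) - rowMeans(x2)) /
    sqrt(sp2 * (1 / n1 + 1 / n2))
  expect_equal(de$t_score, unname(t_manual), tolerance = 1e-10)
})

test_that("swapping group labels negates t and preserves p", {
  set.seed(7)
  vals <- matrix(rnorm(200), nrow = 20,
                 dimnames = list(sprintf("g%02d", 1:20),
                                 sprintf("s%02d", 1:10)))
  groups <- rep(c("case", "control"), each = 5)
  a <- differential_test(expression_set(vals, groups,
                                        case_group = "case"))
  b <- differential_test(expression_set(vals, groups,
                                        case_group = "control"))
  expect_equal(a$t_score, -b$t_score)
  expect_equal(a$p_value, b$p_value)
})

test_that("zero-variance features follow the documented convention", {
  vals <- rbind(shift = c(2, 2, 2, 1, 1, 1), flat = c(3, 3, 3, 3, 3, 3))
  colnames(vals) <- sprintf("s%d", 1:6)
  es <- expression_set(vals, rep(c("case", "control"), each = 3))
  de <- differential_test(es)
  expect_equal(de$t_score[de$feature_id == "shift"], Inf)
  expect_equal(de$p_value[de$feature_id == "shift"], 0)
  expect_equal(de$t_score[de$feature_id == "flat"], 0)
  expect_equal(de$p_value[de$feature_id == "flat"], 1)
})

test_that("the null DE rate at alpha = 0.01 sits inside binomial bounds", {
  set.seed(314)
  n_feat <- 1000
  vals <- matrix(rnorm(n_feat * 20), nrow = n_feat,
                 dimnames = list(sprintf("g%04d", seq_len(n_feat)),
                                 sprintf("s%02d", 1:20)))
  es <- expression_set(vals, rep(c("case", "control"), each = 10))
  de <- differential_test(es, alpha = 0.01)
  hits <- sum(de$is_significant)
  expect_gte(hits, qbinom(0.005, n_feat, 0.01))
  expect_lte(hits, qbinom(0.995, n_feat, 0.01))
})
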