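#' Construct a two-group expression data set
#'
#' Bundles a normalized feature-by-sample expression matrix with a two-group
#' sample annotation. The case group (group 1) fixes the sign convention used
#' everywhere downstream: a positive t-score means higher expression in the
#' case group ("up"), matching the progressing-versus-non-progressing
#' comparison of oral leukoplakia cohorts.
#'
#' @param values numeric matrix, features in rows (rownames are feature
#'   identifiers: gene symbols or miRNA names), samples in columns (colnames
#'   are sample identifiers).
#' @param groups character or factor giving each sample's group; either named
#'   by sample id or in column order of `values`. Exactly two groups.
#' @param case_group the group label treated as group 1 (the "case" arm).
#'   Defaults to the first label encountered in `groups`.
#' @return An object of class `expression_set`: a list with elements
#'   `values` (matrix) and `groups` (factor, levels `c(case, control)`).
#' @export
expression_set <- function(values, groups, case_group = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have feature rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample identifiers", call. = FALSE)
  }
  groups <- as.character(groups)
  if (!is.null(names(groups))) {
    missing_samples <- setdiff(colnames(values), names(groups))
    if (length(missing_samples)) {
      stop("samples without group annotation: ",
           paste(missing_samples, collapse = ", "), call. = FALSE)
    }
    groups <- groups[colnames(values)]
  } else if (length(groups) != ncol(values)) {
    stop("`groups` must annotate every sample", call. = FALSE)
  }
  lev <- unique(groups)
  if (length(lev) != 2L) {
    stop("exactly two groups required, got: ",
         paste(lev, collapse = ", "), call. = FALSE)
  }
  case_group <- case_group %||% lev[1L]
  if (!case_group %in% lev) {
    stop("`case_group` '", case_group, "' not among group labels",
         call. = FALSE)
  }
  lev <- c(case_group, setdiff(lev, case_group))
  groups <- factor(groups, levels = lev)
  if (any(table(groups) < 2L)) {
    stop("both groups need >= 2 samples for variance estimation",
         call. = FALSE)
  }
  structure(list(values = values, groups = groups),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  tab <- table(x$groups)
  cat("expression_set: ", nrow(x$values), " features x ",
      ncol(x$values), " samples (",
      levels(x$groups)[1], " n=", tab[1], " vs ",
      levels(x$groups)[2], " n=", tab[2], "); ",
      sum(is.na(x$values)), " missing values\n", sep = "")
  invisible(x)
}

#' Read an expression matrix and its group annotation from TSV files
#'
#' The expression file has feature identifiers in the first column and one
#' column per sample; the group file has two columns (sample id, group label).
#'
#' @param expr_path path to the expression TSV.
#' @param groups_path path to the two-column group TSV.
#' @inheritParams expression_set
#' @return An [expression_set].
#' @export
read_expression_tsv <- function(expr_path, groups_path, case_group = NULL) {
  df <- read_tsv_strict(expr_path)
  if (ncol(df) < 3L) {
    stop("expression file needs a feature column plus >= 2 samples",
         call. = FALSE)
  }
  values <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- as.character(df[[1L]])
  gdf <- read_tsv_strict(groups_path)
  groups <- setNames(as.character(gdf[[2L]]), as.character(gdf[[1L]]))
  expression_set(values, groups, case_group = case_group)
}

#' Collapse probe-level rows to feature-level rows
#'
#' Each feature's expression is the arithmetic mean of the rows of all probes
#' mapping to it; probes absent from the map are dropped (and counted in a
#' message), mirroring standard array summarisation.
#'
#' @param es an [expression_set] whose rows are probe identifiers.
#' @param probe_map data frame with columns `probe` and `feature` (each
#'   retained probe maps to exactly one feature).
#' @return An [expression_set] whose rows are features.
#' @export
collapse_probes <- function(es, probe_map) {
  stopifnot(inherits(es, "expression_set"))
  probe_map <- as.data.frame(probe_map)
  if (!all(c("probe", "feature") %in% names(probe_map))) {
    stop("`probe_map` needs columns 'probe' and 'feature'", call. = FALSE)
  }
  if (anyDuplicated(probe_map$probe)) {
    stop("probes mapping to multiple features: ",
         paste(unique(probe_map$probe[duplicated(probe_map$probe)]),
               collapse = ", "), call. = FALSE)
  }
  keep <- rownames(es$values) %in% probe_map$probe
  if (!any(keep)) {
    stop("no probe in the matrix is present in the probe map", call. = FALSE)
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message("collapse_probes: dropped ", n_dropped, " unmapped probes")
  }
  vals <- es$values[keep, , drop = FALSE]
  feat <- probe_map$feature[match(rownames(vals), probe_map$probe)]
  # rowsum sums per feature; divide by probe multiplicity for the mean
  summed <- rowsum(vals, group = feat, reorder = TRUE)
  counts <- as.vector(table(feat)[rownames(summed)])
  collapsed <- summed / counts
  expression_set(collapsed, as.character(es$groups),
                 case_group = levels(es$groups)[1L])
}

#' Impute missing expression values
#'
#' `method = "mean"` replaces each missing cell with its row mean over
#' observed cells. `method = "knn"` replaces it with the mean of the same
#' column across the `k` nearest rows, where nearness is Euclidean distance
#' computed on columns observed in both rows (rows missing the target column
#' are skipped). This is a small self-contained utility, not a full KNN
#' imputation framework.
#'
#' @param es an [expression_set].
#' @param method `"mean"` or `"knn"`.
#' @param k neighbour count for `"knn"`.
#' @return An [expression_set] with no missing values.
#' @export
impute_missing <- function(es, method = c("mean", "knn"), k = 10L) {
  stopifnot(inherits(es, "expression_set"))
  method <- match.arg(method)
  vals <- es$values
  if (!anyNA(vals)) {
    return(es)
  }
  all_missing <- rownames(vals)[rowSums(!is.na(vals)) == 0L]
  if (length(all_missing)) {
    stop("features with no observed value cannot be imputed: ",
         paste(all_missing, collapse = ", "), call. = FALSE)
  }
  if (method == "mean") {
    rm_ <- rowMeans(vals, na.rm = TRUE)
    idx <- which(is.na(vals), arr.ind = TRUE)
    vals[idx] <- rm_[idx[, 1L]]
  } else {
    if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
    miss_rows <- unique(which(is.na(vals), arr.ind = TRUE)[, 1L])
    for (i in miss_rows) {
      target <- vals[i, ]
      obs_i <- !is.na(target)
      d <- vapply(seq_len(nrow(vals)), function(j) {
        if (j == i) return(Inf)
        shared <- obs_i & !is.na(vals[j, ])
        if (!any(shared)) return(Inf)
        sqrt(sum((target[shared] - vals[j, shared])^2))
      }, numeric(1))
      for (jcol in which(is.na(target))) {
        donors <- which(is.finite(d) & !is.na(vals[, jcol]))
        if (!length(donors)) {
          stop("no donor row observed at column '", colnames(vals)[jcol],
               "' for feature '", rownames(vals)[i], "'", call. = FALSE)
        }
        nn <- donors[order(d[donors])][seq_len(min(k, length(donors)))]
        vals[i, jcol] <- mean(vals[nn, jcol])
      }
    }
  }
  expression_set(vals, as.character(es$groups),
                 case_group = levels(es$groups)[1L])
}

#' Two-group differential expression by the two-sample t-test
#'
#' Computes, for every feature, the signed two-sample t-statistic comparing
#' the case group (group 1) against the control group, with a two-sided
#' P-value. The default is the classical pooled-variance Student test; Welch's
#' unequal-variance form is available via `variant`. The full t-score vector
#' is retained for all features because module scoring consumes it regardless
#' of per-feature significance.
#'
#' Degenerate features with zero variance in both groups get the documented
#' convention: t is signed infinity and P = 0 when the group means differ,
#' t = 0 and P = 1 when they are equal.
#'
#' @param es an [expression_set] with no missing values.
#' @param alpha significance cutoff; `is_significant` uses the strict
#'   inequality `p_value < alpha`.
#' @param variant `"pooled"` (Student) or `"welch"`.
#' @param adjust `"none"` (raw P-values, the default) or `"BH"`
#'   (Benjamini-Hochberg) applied before the cutoff.
#' @return data frame with columns `feature_id`, `t_score`, `p_value`,
#'   `direction` (`"up"` = higher mean in the case group), `is_significant`.
#' @export
differential_test <- function(es, alpha = 0.01,
                              variant = c("pooled", "welch"),
                              adjust = c("none", "BH")) {
  stopifnot(inherits(es, "expression_set"))
  variant <- match.arg(variant)
  adjust <- match.arg(adjust)
  if (anyNA(es$values)) {
    stop("missing values present; run impute_missing() first", call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0,1)", call. = FALSE)
  g1 <- es$groups == levels(es$groups)[1L]
  x1 <- es$values[, g1, drop = FALSE]
  x2 <- es$values[, !g1, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1L, var); v2 <- apply(x2, 1L, var)
  diff <- m1 - m2
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(diff))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- diff / se
  p <- 2 * pt(abs(t), df = df, lower.tail = FALSE)
  degenerate <- se == 0
  if (any(degenerate)) {
    t[degenerate] <- sign(diff[degenerate]) * Inf
    t[degenerate & diff == 0] <- 0
    p[degenerate] <- ifelse(diff[degenerate] == 0, 1, 0)
  }
  if (adjust == "BH") {
    p_cut <- p.adjust(p, method = "BH")
  } else {
    p_cut <- p
  }
  data.frame(
    feature_id = rownames(es$values),
    t_score = unname(t),
    p_value = unname(p),
    direction = ifelse(t >= 0, "up", "down"),
    is_significant = unname(p_cut < alpha),
    stringsAsFactors = FALSE
  )
}
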