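#' Configuration for the synthetic two-group benchmark
#'
#' Defines the generating conditions for a synthetic benchmark with the
#' statistical structure the pipeline assumes: a scale-free-like PPI
#' background with planted dense (clique-rich) communities, two-group
#' expression in which planted-community genes carry a standardized mean
#' shift, and a sparse miRNA-target map in which a designated fraction of
#' miRNAs concentrate their targets in a planted community with the opposite
#' change direction.
#'
#' Defaults describe a desk-scale two-cohort study: 1000 genes and 100
#' miRNAs measured in 25 samples per group, four planted 8-gene modules with
#' a standardized shift of d = 3, homoscedastic unit-variance noise, a
#' preferential-attachment background of mean degree 4 with planted
#' within-module edge probability 0.9, and 10% of miRNAs planted as
#' regulators with 8 targets each.
#'
#' @param n_genes,n_mirnas feature counts.
#' @param n_samples_per_group samples in each of the two groups.
#' @param n_planted_modules,planted_module_size planted community layout.
#' @param planted_effect_size standardized group-mean shift (Cohen's d) of
#'   truly shifted features.
#' @param background_noise_sd Gaussian noise standard deviation
#'   (expression units).
#' @param ppi_mean_degree target mean degree of the background graph.
#' @param intra_module_edge_prob within-module edge probability of planted
#'   communities; must exceed the background edge density.
#' @param targets_per_mirna targets drawn per miRNA.
#' @param planted_regulator_fraction fraction of miRNAs planted as module
#'   regulators.
#' @param cpm_k the clique-percolation k the benchmark is meant for
#'   (planted modules must be at least this large).
#' @param seed integer RNG seed; each generator derives its own stream from
#'   it by a fixed offset, so graph, expression and targets can be
#'   regenerated independently.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 1000L, n_mirnas = 100L,
                             n_samples_per_group = 25L,
                             n_planted_modules = 4L,
                             planted_module_size = 8L,
                             planted_effect_size = 3,
                             background_noise_sd = 1,
                             ppi_mean_degree = 4,
                             intra_module_edge_prob = 0.9,
                             targets_per_mirna = 8L,
                             planted_regulator_fraction = 0.1,
                             cpm_k = 3L, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_mirnas = as.integer(n_mirnas),
              n_samples_per_group = as.integer(n_samples_per_group),
              n_planted_modules = as.integer(n_planted_modules),
              planted_module_size = as.integer(planted_module_size),
              planted_effect_size = planted_effect_size,
              background_noise_sd = background_noise_sd,
              ppi_mean_degree = ppi_mean_degree,
              intra_module_edge_prob = intra_module_edge_prob,
              targets_per_mirna = as.integer(targets_per_mirna),
              planted_regulator_fraction = planted_regulator_fraction,
              cpm_k = as.integer(cpm_k),
              seed = as.integer(seed))
  counts <- c("n_genes", "n_mirnas", "n_samples_per_group",
              "n_planted_modules", "planted_module_size",
              "targets_per_mirna", "cpm_k")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      stop("invalid synthetic_config field `", f, "`: must be a positive ",
           "count", call. = FALSE)
    }
  }
  for (f in c("intra_module_edge_prob", "planted_regulator_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("invalid synthetic_config field `", f, "`: must be in [0,1]",
           call. = FALSE)
    }
  }
  if (cfg$background_noise_sd <= 0) {
    stop("invalid synthetic_config field `background_noise_sd`: must be ",
         "positive", call. = FALSE)
  }
  if (cfg$planted_effect_size < 0) {
    stop("invalid synthetic_config field `planted_effect_size`: must be ",
         "non-negative", call. = FALSE)
  }
  if (cfg$planted_module_size < cfg$cpm_k) {
    stop("invalid synthetic_config field `planted_module_size`: must be ",
         ">= cpm_k so planted communities are detectable", call. = FALSE)
  }
  if (cfg$n_planted_modules * cfg$planted_module_size > cfg$n_genes) {
    stop("invalid synthetic_config field `n_planted_modules`: planted ",
         "modules exceed the gene universe", call. = FALSE)
  }
  if (cfg$targets_per_mirna > cfg$n_genes) {
    stop("invalid synthetic_config field `targets_per_mirna`: exceeds the ",
         "gene universe", call. = FALSE)
  }
  background_density <- min(1, cfg$ppi_mean_degree / (cfg$n_genes - 1))
  if (cfg$intra_module_edge_prob <= background_density) {
    stop("invalid synthetic_config field `intra_module_edge_prob`: planted ",
         "communities must be denser than the background (density ",
         signif(background_density, 3), ")", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

synthetic_gene_names <- function(n) sprintf("G%04d", seq_len(n))
synthetic_mirna_names <- function(n) sprintf("mir-%03d", seq_len(n))

#' Generate the synthetic PPI network and its ground truth
#'
#' The background is a preferential-attachment (scale-free-like) graph, so
#' the degree distribution is heavy-tailed like a real interactome and hub
#' calling is meaningful. Planted modules are near-cliques: disjoint gene
#' sets whose within-module pairs are connected independently with
#' probability `intra_module_edge_prob`. Gene labels are randomly permuted
#' over the background graph so planted genes are not systematically the
#' oldest (highest-degree) attachment targets. All planted module genes are
#' truly shifted upward in the case group; planted regulator miRNAs carry
#' the opposite (downward) direction.
#'
#' @param config a [synthetic_config()].
#' @return list with `graph` (simple undirected [igraph::graph] on all
#'   `n_genes` genes) and `truth`, a list recording
#'   `planted_module_members` (named list), `truly_shifted_genes` (named
#'   sign vector, +1 = up in the case group), and `planted_regulators`
#'   (data frame `mirna`, `module`, `sign`).
#' @export
generate_ppi <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  genes <- synthetic_gene_names(config$n_genes)
  with_seed(config$seed + 1L, {
    m_attach <- max(1L, round(config$ppi_mean_degree / 2))
    bg <- igraph::sample_pa(config$n_genes, m = m_attach,
                            directed = FALSE)
    igraph::V(bg)$name <- sample(genes)
    planted_pool <- sample(genes,
                           config$n_planted_modules *
                             config$planted_module_size)
    planted <- split(planted_pool,
                     rep(seq_len(config$n_planted_modules),
                         each = config$planted_module_size))
    names(planted) <- paste0("P", seq_len(config$n_planted_modules))
    planted <- lapply(planted, sort)
    planted_edges <- do.call(rbind, lapply(planted, function(mem) {
      pairs <- t(utils::combn(mem, 2L))
      pairs[stats::runif(nrow(pairs)) <= config$intra_module_edge_prob, ,
            drop = FALSE]
    }))
    g <- igraph::simplify(igraph::add_edges(
      bg, t(planted_edges)), remove.multiple = TRUE, remove.loops = TRUE)
  })
  shifted <- setNames(rep(1, length(planted_pool)), sort(planted_pool))
  regs <- synthetic_regulators(config)
  list(graph = g,
       truth = list(planted_module_members = planted,
                    truly_shifted_genes = shifted,
                    planted_regulators = regs))
}

# Planted regulators: the designated fraction of miRNAs, assigned to planted
# modules round-robin, each repressing (sign -1, i.e. down while the module
# is up).
synthetic_regulators <- function(config) {
  n_reg <- round(config$planted_regulator_fraction * config$n_mirnas)
  mirnas <- synthetic_mirna_names(config$n_mirnas)
  if (n_reg == 0L) {
    return(data.frame(mirna = character(), module = character(),
                      sign = numeric(), stringsAsFactors = FALSE))
  }
  data.frame(
    mirna = mirnas[seq_len(n_reg)],
    module = paste0("P", rep_len(seq_len(config$n_planted_modules), n_reg)),
    sign = -1,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic two-group expression matrix
#'
#' Per-feature baselines are constants drawn once; noise is homoscedastic
#' Gaussian with sd `background_noise_sd`, matching the pooled-variance
#' t-test assumption. Truly shifted features (planted-module genes for
#' `feature_kind = "gene"`, planted-regulator miRNAs for
#' `feature_kind = "mirna"`) have a case-minus-control mean difference of
#' `planted_effect_size * background_noise_sd` in their recorded direction.
#'
#' @param config a [synthetic_config()].
#' @param truth the truth component returned by [generate_ppi()].
#' @param feature_kind `"gene"` or `"mirna"`.
#' @return an [expression_set] with groups `case` (group 1) and `control`.
#' @export
generate_expression <- function(config, truth,
                                feature_kind = c("gene", "mirna")) {
  stopifnot(inherits(config, "synthetic_config"))
  feature_kind <- match.arg(feature_kind)
  if (feature_kind == "gene") {
    features <- synthetic_gene_names(config$n_genes)
    shift_sign <- setNames(rep(0, length(features)), features)
    sh <- truth$truly_shifted_genes
    shift_sign[names(sh)] <- sh
    offset <- 2L
  } else {
    features <- synthetic_mirna_names(config$n_mirnas)
    shift_sign <- setNames(rep(0, length(features)), features)
    regs <- truth$planted_regulators
    shift_sign[regs$mirna] <- regs$sign
    offset <- 3L
  }
  n <- config$n_samples_per_group
  samples <- c(sprintf("case_%02d", seq_len(n)),
               sprintf("ctrl_%02d", seq_len(n)))
  groups <- setNames(rep(c("case", "control"), each = n), samples)
  delta <- config$planted_effect_size * config$background_noise_sd
  vals <- with_seed(config$seed + offset, {
    baseline <- rnorm(length(features), mean = 8, sd = 1)
    noise <- matrix(rnorm(length(features) * 2L * n, sd =
                            config$background_noise_sd),
                    nrow = length(features))
    m <- baseline + noise
    m[, seq_len(n)] <- m[, seq_len(n)] + shift_sign * delta
    m
  })
  dimnames(vals) <- list(features, samples)
  expression_set(vals, groups, case_group = "case")
}

#' Generate a synthetic miRNA-target map
#'
#' Planted regulator miRNAs draw at least half of their targets from their
#' intended planted module (all of it, when half the quota exceeds the
#' module size) and the remainder uniformly from the other genes;
#' non-planted miRNAs draw all targets uniformly from the gene universe.
#'
#' @inheritParams generate_expression
#' @return data frame with columns `mirna`, `gene`, one row per interaction.
#' @export
generate_mirna_targets <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  genes <- synthetic_gene_names(config$n_genes)
  mirnas <- synthetic_mirna_names(config$n_mirnas)
  regs <- truth$planted_regulators
  with_seed(config$seed + 4L, {
    rows <- lapply(mirnas, function(mi) {
      ridx <- match(mi, regs$mirna)
      if (!is.na(ridx)) {
        module <- truth$planted_module_members[[regs$module[ridx]]]
        n_in <- min(length(module), ceiling(config$targets_per_mirna / 2))
        inside <- sample(module, n_in)
        outside <- sample(setdiff(genes, inside),
                          config$targets_per_mirna - n_in)
        data.frame(mirna = mi, gene = c(inside, outside),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(mirna = mi,
                   gene = sample(genes, config$targets_per_mirna),
                   stringsAsFactors = FALSE)
      }
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write a complete synthetic bundle to disk
#'
#' Writes the three artifacts in the same TSV formats the pipeline reads
#' (expression + groups for genes and miRNAs, PPI edge list, miRNA-target
#' pairs) plus the ground truth as a JSON sidecar.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `paths` (named written-file paths) and the
#'   in-memory objects (`graph`, `truth`, `genes`, `mirnas`, `targets`).
#' @export
write_synthetic_bundle <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ppi <- generate_ppi(config)
  genes <- generate_expression(config, ppi$truth, "gene")
  mirnas <- generate_expression(config, ppi$truth, "mirna")
  targets <- generate_mirna_targets(config, ppi$truth)
  paths <- list(
    gene_expression = file.path(dir, "gene_expression.tsv"),
    gene_groups = file.path(dir, "gene_groups.tsv"),
    mirna_expression = file.path(dir, "mirna_expression.tsv"),
    mirna_groups = file.path(dir, "mirna_groups.tsv"),
    ppi = file.path(dir, "ppi_edges.tsv"),
    targets = file.path(dir, "mirna_targets.tsv"),
    truth = file.path(dir, "truth.json"))
  write_expression_tsv <- function(es, expr_path, group_path) {
    df <- data.frame(feature_id = rownames(es$values), es$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(df, expr_path)
    write_tsv(data.frame(sample_id = colnames(es$values),
                         group = as.character(es$groups)), group_path)
  }
  write_expression_tsv(genes, paths$gene_expression, paths$gene_groups)
  write_expression_tsv(mirnas, paths$mirna_expression, paths$mirna_groups)
  el <- igraph::as_edgelist(ppi$graph)
  write_tsv(data.frame(gene_a = el[, 1L], gene_b = el[, 2L]), paths$ppi)
  write_tsv(targets, paths$targets)
  jsonlite::write_json(
    list(planted_module_members = ppi$truth$planted_module_members,
         truly_shifted_genes = as.list(ppi$truth$truly_shifted_genes),
         planted_regulators = ppi$truth$planted_regulators),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(paths = paths, graph = ppi$graph, truth = ppi$truth,
                 genes = genes, mirnas = mirnas, targets = targets))
}

#' Fraction of planted modules recovered by a set of selected modules
#'
#' A planted module counts as recovered when some selected module contains
#' at least `min_frac` of its members.
#'
#' @param maocs named list of selected module member vectors.
#' @param truth the truth component of [generate_ppi()].
#' @param min_frac minimum fraction of planted members that must be covered
#'   by a single selected module.
#' @return recovered fraction in [0,1].
#' @export
module_recovery <- function(maocs, truth, min_frac = 0.5) {
  planted <- truth$planted_module_members
  if (!length(planted)) return(NA_real_)
  hit <- vapply(planted, function(p) {
    any(vapply(maocs, function(m)
      length(intersect(m, p)) / length(p) >= min_frac, logical(1)))
  }, logical(1))
  mean(hit)
}

#' Fraction of planted regulators recovered by the regulator screen
#'
#' A planted regulator counts as recovered when it has a significant call on
#' a selected module that covers at least `min_frac` of its intended planted
#' module's members.
#'
#' @param calls the `calls` data frame from [regulator_screen()].
#' @param maocs named list of selected module member vectors (covering the
#'   `module_id` values in `calls`).
#' @inheritParams module_recovery
#' @return recovered fraction in [0,1] (NA with no planted regulators).
#' @export
regulator_recovery <- function(calls, maocs, truth, min_frac = 0.5) {
  regs <- truth$planted_regulators
  if (!nrow(regs)) return(NA_real_)
  hit <- vapply(seq_len(nrow(regs)), function(i) {
    planted <- truth$planted_module_members[[regs$module[i]]]
    called <- calls$module_id[calls$mirna == regs$mirna[i]]
    any(vapply(called, function(mid)
      length(intersect(maocs[[mid]], planted)) / length(planted) >=
        min_frac, logical(1)))
  }, logical(1))
  mean(hit)
}
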