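#' Locate the packaged reference fixtures
#'
#' The package ships transcriptions of the reference result tables of the
#' oral-leukoplakia module study it models (module memberships with DEG
#' flags, the annotated oral-cancer gene list with relevance scores, the
#' topological key genes, and the miRNA regulators with change directions),
#' plus the published summary figures and MD5 checksums of every fixture.
#'
#' @param file fixture file name; with no argument, the fixture directory.
#' @return a path inside the installed package.
#' @export
reference_fixture_path <- function(file = "") {
  system.file("extdata", "reference", file, package = "oncomodule",
              mustWork = TRUE)
}

#' Read the reference fixtures, verifying their checksums
#'
#' @param check verify MD5 checksums against the shipped manifest and abort
#'   on any mismatch.
#' @return list of data frames: `modules`, `oral_cancer_genes`, `topology`,
#'   `regulators`, `summary`.
#' @export
read_reference_tables <- function(check = TRUE) {
  files <- c(modules = "reference_modules.tsv",
             oral_cancer_genes = "reference_oral_cancer_genes.tsv",
             topology = "reference_topology.tsv",
             regulators = "reference_regulators.tsv",
             summary = "reference_summary.tsv")
  if (check) {
    manifest <- read_tsv_strict(
      reference_fixture_path("reference_checksums.tsv"))
    actual <- tools::md5sum(vapply(manifest$file, reference_fixture_path,
                                   ""))
    bad <- manifest$file[unname(actual) != manifest$md5]
    if (length(bad)) {
      stop("reference fixture integrity failure: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  out <- lapply(files, function(f) {
    read_tsv_strict(reference_fixture_path(f),
                    colClasses = if (f == "reference_summary.tsv")
                      "character" else NA)
  })
  names(out) <- names(files)
  out
}

#' Recompute the published summary figures from the reference fixtures
#'
#' From the shipped fixtures alone, recomputes: (a) the number of unique
#' genes across the 13 reference modules; (b) the percentage of those genes
#' flagged as differentially expressed; (c) the count and percentage of
#' module genes present in the annotated oral-cancer gene list; (d) the
#' number of miRNA regulators whose change direction opposes all of their
#' targets' directions (via [direction_correlation()]); and (e) the hub
#' genes implied by the published degrees at the strict scaled-connectivity
#' threshold (via [call_hubs()]). Each recomputed value is compared with the
#' published figure.
#'
#' @param fixtures as returned by [read_reference_tables()]; read (with
#'   checksum verification) when omitted.
#' @param hub_threshold strict scaled-connectivity cutoff.
#' @param quiet suppress the printed report.
#' @return data frame with columns `quantity`, `recomputed`, `reference`,
#'   `pass`.
#' @export
reproduce_reference_tables <- function(fixtures = NULL,
                                       hub_threshold = 0.9,
                                       quiet = FALSE) {
  fixtures <- fixtures %||% read_reference_tables(check = TRUE)
  genes <- unique(fixtures$modules$gene)
  n_genes <- length(genes)
  deg_genes <- unique(fixtures$modules$gene[fixtures$modules$is_deg == 1L])
  deg_pct <- round(100 * length(deg_genes) / n_genes, 2)
  overlap <- sum(fixtures$oral_cancer_genes$gene %in% genes)
  overlap_pct <- round(100 * overlap / n_genes, 2)

  reg <- fixtures$regulators
  anti <- vapply(split(reg, reg$mirna), function(df) {
    isTRUE(direction_correlation(df$mirna_direction[1L],
                                 df$target_direction))
  }, logical(1))
  n_anti <- sum(anti)

  topo <- fixtures$topology
  degs <- topo[!is.na(topo$degree), c("gene", "degree")]
  degs <- degs[!duplicated(degs$gene), ]
  hub_df <- call_hubs(setNames(degs$degree, degs$gene),
                      threshold = hub_threshold)

  expected <- setNames(fixtures$summary$value, fixtures$summary$quantity)
  rows <- data.frame(
    quantity = c("unique_module_genes", "deg_fraction_pct",
                 "oral_cancer_overlap_n", "oral_cancer_overlap_pct",
                 "anti_correlated_mirnas", "hub_gene_n", "hub_genes"),
    recomputed = c(n_genes, deg_pct, overlap, overlap_pct, n_anti,
                   nrow(hub_df), paste(hub_df$gene, collapse = ";")),
    stringsAsFactors = FALSE)
  rows$reference <- unname(expected[rows$quantity])
  same_set <- function(a, b) {
    setequal(strsplit(a, ";")[[1L]], strsplit(b, ";")[[1L]])
  }
  rows$pass <- mapply(function(q, rec, ref) {
    if (q == "hub_genes") same_set(rec, ref) else
      isTRUE(all.equal(as.numeric(rec), as.numeric(ref)))
  }, rows$quantity, rows$recomputed, rows$reference)
  if (!quiet) {
    for (i in seq_len(nrow(rows))) {
      cat(sprintf("%-24s recomputed %-22s reference %-22s %s\n",
                  rows$quantity[i], rows$recomputed[i], rows$reference[i],
                  if (rows$pass[i]) "PASS" else "FAIL"))
    }
  }
  rows
}
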