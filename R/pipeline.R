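#' Run configuration
#'
#' Assembles the parameters of a full pipeline run: the simulation block
#' (forwarded to [sim_config()]), per-stage analysis parameters, and the
#' global seed from which every stochastic stage derives its own sub-seed.
#'
#' @param simulation Named list of [sim_config()] arguments.
#' @param alpha FDR threshold of the per-tissue screen.
#' @param k,window,n_perm Permutation-null parameters; see
#'   [coloc_permutation_fdr()].
#' @param max_gap Maximum coding/non-coding pairing distance in bp.
#' @param flank Flanking-window width for peak-coverage statistics, bp.
#' @param qpcr Named list of [generate_qpcr()] arguments (or `NULL` to use
#'   its defaults).
#' @param seed Global integer seed.
#' @param outdir Output directory for stage files, or `NULL` to skip
#'   writing.
#' @return A list of class `run_config`.
#' @export
run_config <- function(simulation = list(), alpha = 0.05, k = 4,
                       window = 50000, n_perm = 10000, max_gap = 50000,
                       flank = 100000, qpcr = list(), seed = 1L,
                       outdir = NULL) {
  structure(list(simulation = simulation, alpha = alpha, k = k,
                 window = window, n_perm = n_perm, max_gap = max_gap,
                 flank = flank, qpcr = qpcr, seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys are [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[names(y) %in% names(formals(run_config))])
}

#' Run the whole analysis pipeline on simulated data
#'
#' Executes, in order: annotation and expression simulation, per-array
#' standardization, Xist-based sex QC and balancing per tissue, the
#' per-tissue Mann-Whitney/Benjamini-Hochberg screen, per-chromosome
#' enrichment, cross-tissue overlap and gene categorization, coding/lncRNA
#' domain pairing, the co-localization permutation null, histone-mark peak
#' simulation and domain coverage, and the qPCR validation analysis. Each
#' stochastic stage consumes a sub-seed derived from the global seed and
#' the stage name, so a stage re-run in isolation sees identical
#' randomness. If `config$outdir` is set, every stage writes its table to a
#' TSV/BED file plus a JSON run summary.
#'
#' @param config A [run_config()] (or the path of a YAML file for
#'   [read_run_config()]).
#' @return A list of class `escapex_run` with elements `annotation`, `sim`,
#'   `qc` (per-tissue tidied QC tables), `hits` (per-tissue
#'   `sexbias_result`s), `enrichment`, `overlap`, `categories`, `domains`,
#'   `coloc`, `coverage`, `qpcr`, `config`, `seed`.
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config(simulation = list(tissues = "eye",
#'                                     samples_per_sex_per_tissue = 10,
#'                                     n_probes = 200),
#'                   n_perm = 1000, seed = 7)
#' run <- run_pipeline(cfg)
#' glance(run)
#' }
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  scfg <- do.call(sim_config, config$simulation)
  ann <- generate_annotation(genome_spec(), scfg$n_probes,
                             seed = derive_seed(seed, "annotation"))
  sim <- generate_expression(scfg, ann,
                             seed = derive_seed(seed, "expression"))
  std <- standardize_arrays(sim$expression)
  xist_probes <- ann$probe_id[ann$role == "xist"]

  qc_tabs <- list()
  hits <- list()
  enrich <- list()
  for (tis in scfg$tissues) {
    sub <- filter_samples(std, std$samples$sample_id[
      std$samples$tissue == tis])
    qc <- xist_sex_check(sub, xist_probes)
    bal <- balance_by_sex(sub, qc, seed = derive_seed(seed,
                                                      paste0("balance_", tis)))
    qc$excluded <- attr(bal, "excluded")
    qc_tabs[[tis]] <- tidy(qc)
    hits[[tis]] <- screen_tissue(bal, alpha = config$alpha,
                                 annotation = ann)
    enrich[[tis]] <- chrom_enrichment(hits[[tis]], ann, tissue = tis)
  }
  enrichment <- dplyr::bind_rows(enrich)

  overlap <- if (length(hits) >= 2) {
    intersect_hits(lapply(hits, function(h) unique(h$gene)),
                   platform = "sim")
  } else NULL
  union_genes <- sort(unique(unlist(lapply(hits, function(h) h$gene))))
  categories <- if (length(union_genes)) {
    classify_genes(union_genes, ann)
  } else tibble::tibble(gene = character(), chr = character(),
                        category = character())

  female_x <- sort(unique(unlist(lapply(hits, function(h)
    h$gene[h$direction == "female_up"]))))
  domains <- pair_coding_noncoding(female_x, ann, max_gap = config$max_gap)

  coloc <- coloc_permutation_fdr(ann, k = config$k, window = config$window,
                                 n_perm = config$n_perm,
                                 seed = derive_seed(seed, "coloc"))

  peaks <- generate_peaks(ann, seed = derive_seed(seed, "peaks"))
  cov_targets <- dplyr::bind_rows(
    domains[, c("chr", "start", "end")] |>
      dplyr::mutate(region = paste(domains$coding, domains$noncoding,
                                   sep = "/")),
    gene_intervals(ann) |>
      dplyr::filter(.data$gene == "Rps4x") |>
      dplyr::transmute(chr = .data$chr, start = .data$start,
                       end = .data$end, region = "Rps4x"))
  coverage <- domain_peak_coverage(cov_targets, peaks, flank = config$flank)

  qargs <- config$qpcr %||% list()
  qargs$seed <- qargs$seed %||% derive_seed(seed, "qpcr")
  qpcr_data <- do.call(generate_qpcr, qargs)
  qpcr <- qpcr_analysis(qpcr_data)

  run <- structure(list(
    annotation = ann, sim = sim, qc = qc_tabs, hits = hits,
    enrichment = enrichment, overlap = overlap, categories = categories,
    domains = domains, coloc = coloc, coverage = coverage, qpcr = qpcr,
    peaks = peaks, config = config, seed = seed,
    version = as.character(utils::packageVersion("escapex"))
  ), class = "escapex_run")

  if (!is.null(config$outdir)) write_run(run, config$outdir)
  run
}

#' @export
print.escapex_run <- function(x, ...) {
  counts <- vapply(x$hits, nrow, integer(1))
  cat("<escapex_run>\n")
  cat("  hits per tissue:",
      paste(names(counts), counts, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  %d escapee domain(s); coloc FDR %.4f; seed %d\n",
              nrow(x$domains), x$coloc$fdr, x$seed))
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x An `escapex_run`.
#' @param ... Unused.
#' @return A tibble with total/female/male hit counts, domain count,
#'   permutation FDR and seed.
#' @export
glance.escapex_run <- function(x, ...) {
  all_hits <- dplyr::bind_rows(x$hits)
  tibble::tibble(
    n_tissues = length(x$hits),
    n_hits = nrow(all_hits),
    n_female_up = sum(all_hits$direction == "female_up"),
    n_male_up = sum(all_hits$direction == "male_up"),
    n_domains = nrow(x$domains),
    coloc_fdr = x$coloc$fdr,
    seed = x$seed)
}

# Write every stage table plus a machine-readable JSON summary.
write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(outdir, ...)
  write_annotation_bed(run$annotation, fp("annotation.bed"))
  write_expression_tsv(run$sim$expression, fp("expression.tsv"),
                       fp("samples.tsv"))
  write_peaks_bed(run$peaks, fp("peaks.bed"))
  for (tis in names(run$hits)) {
    readr::write_tsv(run$hits[[tis]], fp(paste0("hits_", tis, ".tsv")))
    readr::write_tsv(run$qc[[tis]], fp(paste0("qc_", tis, ".tsv")))
  }
  readr::write_tsv(run$enrichment, fp("enrichment.tsv"))
  readr::write_tsv(run$categories, fp("gene_categories.tsv"))
  readr::write_tsv(tibble::as_tibble(run$domains), fp("domains.tsv"))
  readr::write_tsv(run$coverage, fp("peak_coverage.tsv"))
  readr::write_tsv(run$qpcr, fp("qpcr.tsv"))
  summary <- list(
    version = run$version,
    seed = run$seed,
    hit_counts = lapply(run$hits, function(h) list(
      total = nrow(h),
      female_up = sum(h$direction == "female_up"),
      male_up = sum(h$direction == "male_up"))),
    enrichment = run$enrichment,
    domains = tibble::as_tibble(run$domains),
    coloc = glance(run$coloc),
    coverage = run$coverage,
    qpcr = run$qpcr)
  jsonlite::write_json(summary, fp("summary.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(outdir)
}
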