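#' Count distinct significant genes per chromosome
#'
#' @param hits A `sexbias_result` (or tibble with `gene` columns).
#' @param annotation A `probe_annotation` mapping genes to chromosomes.
#' @return A tibble `chr`, `n_genes` covering every chromosome present in
#'   the annotation (zero counts included). Distinct gene symbols are
#'   counted, so multiple significant probes of one gene count once.
#' @export
count_by_chromosome <- function(hits, annotation) {
  gene_chr <- dplyr::distinct(annotation[, c("gene", "chr")])
  hit_genes <- unique(hits$gene)
  missing <- setdiff(hit_genes, gene_chr$gene)
  if (length(missing)) {
    stop("unannotated hit gene(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  counts <- gene_chr |>
    dplyr::mutate(hit = .data$gene %in% hit_genes) |>
    dplyr::group_by(.data$chr) |>
    dplyr::summarise(n_genes = sum(.data$hit), .groups = "drop")
  counts
}

#' Expected significant-gene count for a chromosome
#'
#' Under the null that significant genes fall on chromosomes in proportion
#' to annotated gene content: `Exp = n_sig * m_chr / m_total` with gene
#' counts taken over distinct symbols.
#'
#' @param n_sig Number of distinct significant genes.
#' @param chromosome Chromosome name.
#' @param annotation A `probe_annotation`.
#' @return The real-valued expected count.
#' @export
expected_count <- function(n_sig, chromosome, annotation) {
  gene_chr <- dplyr::distinct(annotation[, c("gene", "chr")])
  if (nrow(gene_chr) == 0) stop("empty annotation", call. = FALSE)
  n_sig * sum(gene_chr$chr == chromosome) / nrow(gene_chr)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing at least `obs` significant genes on a
#' chromosome carrying `m_chr` of the `m_total` annotated genes when
#' `n_sig` genes are drawn without replacement.
#'
#' @param obs Observed count on the chromosome.
#' @param n_sig Total significant genes drawn.
#' @param m_chr Annotated genes on the chromosome.
#' @param m_total Annotated genes overall.
#' @return `P(X >= obs)`, in (0, 1].
#' @export
#' @examples
#' enrichment_test(5, 10, 10, 100)
enrichment_test <- function(obs, n_sig, m_chr, m_total) {
  if (obs > min(n_sig, m_chr) || m_chr > m_total || n_sig > m_total ||
      any(c(obs, n_sig, m_chr, m_total) < 0)) {
    stop("inconsistent counts for the hypergeometric test", call. = FALSE)
  }
  stats::phyper(obs - 1, m_chr, m_total - m_chr, n_sig, lower.tail = FALSE)
}

#' Observed vs expected sex-biased genes per chromosome
#'
#' Builds the per-chromosome enrichment table for one tissue's hit list:
#' observed distinct significant genes, the expected count under
#' proportional allocation, and a hypergeometric upper-tail p-value.
#'
#' @param hits A `sexbias_result`.
#' @param annotation A `probe_annotation`.
#' @param tissue Optional tissue label carried into the output.
#' @return A tibble with `tissue`, `chr`, `obs`, `exp`, `p`, one row per
#'   chromosome in the annotation. `sum(exp)` equals the number of distinct
#'   significant genes exactly.
#' @export
chrom_enrichment <- function(hits, annotation,
                             tissue = attr(hits, "tissue") %||% NA_character_) {
  gene_chr <- dplyr::distinct(annotation[, c("gene", "chr")])
  m_total <- nrow(gene_chr)
  counts <- count_by_chromosome(hits, annotation)
  n_sig <- sum(counts$n_genes)
  counts |>
    dplyr::left_join(dplyr::count(gene_chr, .data$chr, name = "m_chr"),
                     by = "chr") |>
    dplyr::mutate(
      tissue = tissue,
      obs = .data$n_genes,
      exp = n_sig * .data$m_chr / m_total,
      p = purrr::map2_dbl(.data$obs, .data$m_chr,
                          ~ enrichment_test(.x, n_sig, .y, m_total))
    ) |>
    dplyr::select("tissue", "chr", "obs", "exp", "p")
}
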