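#' Default qPCR target panel
#'
#' The four coding/lncRNA escapee pairs plus the X-inactivated negative
#' control (planted female/male ratio 1) and an Xist-like female-specific
#' positive control (~10^4-fold). Ratios for the escapee genes sit in the
#' 1.1-2-fold range typical of X-inactivation escape.
#'
#' @return A tibble with columns `gene` and `ratio` (true female/male ratio).
#' @export
qpcr_default_targets <- function() {
  tibble::tribble(
    ~gene,             ~ratio,
    "Ddx3x",           1.2,
    "2010308F09Rik",   1.4,
    "Eif2s3x",         1.5,
    "D330035K16Rik",   1.4,
    "Kdm5c",           1.6,
    "D930009K15Rik",   1.5,
    "2610029G23Rik",   1.3,
    "5530601H04Rik",   1.6,
    "Rps4x",           1.0,
    "Xist",            1e4
  )
}

#' Simulate a qPCR experiment (dilution series + per-sample Ct table)
#'
#' Each gene gets a cDNA dilution-series standard curve whose quantification
#' cycle follows `Ct = intercept + slope * log10(dilution)` with the ideal
#' slope of a perfectly efficient PCR (-1/log10(2) ~ -3.32), plus Gaussian
#' Ct noise. Per-sample target Ct values encode the planted female/male
#' expression ratios on top of a per-sample loading factor that affects all
#' genes alike; the two reference genes carry no sex effect, so
#' geometric-mean normalization removes the loading factor and recovers the
#' planted ratios.
#'
#' @param targets Tibble with `gene` and true female/male `ratio`; see
#'   [qpcr_default_targets()].
#' @param reference_genes Two endogenous control genes with no sex effect.
#' @param n_f,n_m Females and males per group.
#' @param tissue Tissue label.
#' @param dilutions Relative inputs of the standard-curve series (must be
#'   positive; at least 3 levels).
#' @param slope True Ct-per-log10(input) slope of the simulated instrument.
#' @param ct_noise_sd Gaussian Ct noise standard deviation (0 for a
#'   noiseless series).
#' @param loading_sd Log10 SD of the per-sample loading factor.
#' @param seed Integer seed.
#' @return A list of class `qpcr_dataset`: `ct` (tibble sample_id, sex,
#'   tissue, gene, ct), `dilution_series` (tibble gene, dilution, ct),
#'   `truth` (the `targets` table).
#' @export
#' @examples
#' qd <- generate_qpcr(n_f = 4, n_m = 4, seed = 1)
#' head(qd$ct)
generate_qpcr <- function(targets = qpcr_default_targets(),
                          reference_genes = c("Actb", "Gapdh"),
                          n_f = 16, n_m = 16,
                          tissue = "brain",
                          dilutions = 10^-(0:4),
                          slope = -1 / log10(2),
                          ct_noise_sd = 0.15,
                          loading_sd = 0.1,
                          seed = 1L) {
  if (any(dilutions <= 0)) stop("dilution factors must be positive",
                                call. = FALSE)
  if (length(unique(dilutions)) < 3) {
    stop("need at least 3 distinct dilution levels", call. = FALSE)
  }
  targets <- tibble::as_tibble(targets)
  stopifnot(all(c("gene", "ratio") %in% names(targets)), all(targets$ratio > 0))
  genes <- c(targets$gene, reference_genes)
  ratio <- c(targets$ratio, rep(1, length(reference_genes)))

  withr::with_seed(seed, {
    intercept <- stats::setNames(stats::runif(length(genes), 24, 30), genes)
    dil <- tidyr::expand_grid(gene = genes, dilution = dilutions)
    dil$ct <- intercept[dil$gene] + slope * log10(dil$dilution) +
      stats::rnorm(nrow(dil), 0, ct_noise_sd)

    samp <- tibble::tibble(
      sample_id = sprintf("%s_%s%02d", tissue, rep(c("F", "M"), c(n_f, n_m)),
                          c(seq_len(n_f), seq_len(n_m))),
      sex = rep(c("F", "M"), c(n_f, n_m)),
      tissue = tissue,
      loading = 10^stats::rnorm(n_f + n_m, 0, loading_sd))

    ct <- tidyr::expand_grid(samp[c("sample_id", "sex", "tissue")],
                             gene = genes)
    ct <- dplyr::left_join(ct, samp[c("sample_id", "loading")],
                           by = "sample_id")
    base_input <- 0.01  # relative input of the male mean
    rel <- base_input * ct$loading *
      ifelse(ct$sex == "F", ratio[match(ct$gene, genes)], 1)
    ct$ct <- intercept[ct$gene] + slope * log10(rel) +
      stats::rnorm(nrow(ct), 0, ct_noise_sd)
    ct$loading <- NULL
  })

  structure(list(ct = ct, dilution_series = dil,
                 truth = tibble::tibble(gene = genes, ratio = ratio),
                 reference_genes = reference_genes),
            class = "qpcr_dataset")
}

#' @export
print.qpcr_dataset <- function(x, ...) {
  cat(sprintf("<qpcr_dataset> %d genes, %d samples, %d dilution points\n",
              dplyr::n_distinct(x$ct$gene),
              dplyr::n_distinct(x$ct$sample_id),
              nrow(x$dilution_series)))
  invisible(x)
}
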