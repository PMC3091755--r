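#' Simulate repressive histone-mark peaks over the X chromosome
#'
#' Tiles the X chromosome with short enrichment peaks at high density —
#' emulating the blanket of a repressive chromatin mark (H3K27me3) over the
#' inactive X — while leaving the planted escapee domains essentially bare.
#' Intervals such as the Rps4x-like X-inactivated control remain covered,
#' so downstream coverage statistics can contrast depleted domains with an
#' inactivated locus.
#'
#' @param annotation A `probe_annotation` carrying a `domains` attribute (or
#'   any tibble; pass `domains` explicitly to override).
#' @param seed Integer seed.
#' @param domains Domain tibble with `chr`, `start`, `end`; defaults to the
#'   annotation's planted domains. An empty tibble tiles the whole X.
#' @param spacing Distance in bp between successive peak starts.
#' @param peak_width Mean peak width in bp (jittered per peak).
#' @param domain_margin Extra bp of clearance kept peak-free on each side of
#'   a domain.
#' @param mark,sex Labels stored on every emitted peak.
#' @return A tibble (class `peak_set`) with columns `chr`, `start`, `end`
#'   (0-based half-open), `mark`, `sex`.
#' @export
#' @examples
#' ann <- generate_annotation(genome_spec(), n_probes = 60, seed = 1)
#' pk <- generate_peaks(ann, seed = 1)
#' nrow(pk)
generate_peaks <- function(annotation, seed,
                           domains = planted_domains(annotation),
                           spacing = 1000, peak_width = 800,
                           domain_margin = 500,
                           mark = "H3K27me3", sex = "F") {
  genome <- attr(annotation, "genome")
  x_len <- if (!is.null(genome)) genome$chrom_lengths[["chrX"]] else
    max(annotation$end[annotation$chr == "chrX"], 0)
  if (x_len <= 0) stop("annotation has no X chromosome", call. = FALSE)

  withr::with_seed(seed, {
    starts <- seq(0, x_len - spacing, by = spacing)
    width <- pmax(50, round(stats::rnorm(length(starts), peak_width,
                                         peak_width / 10)))
    width <- pmin(width, spacing)  # keep peaks within their tile
    jitter <- floor(stats::runif(length(starts), 0, spacing - width + 1))
    peak_start <- starts + jitter
    peak_end <- peak_start + width
  })

  keep <- rep(TRUE, length(peak_start))
  dom <- domains
  if (!is.null(dom) && nrow(dom) > 0) {
    dom_ir <- as_iranges0(pmax(dom$start - domain_margin, 0),
                          dom$end + domain_margin)
    keep <- !IRanges::overlapsAny(as_iranges0(peak_start, peak_end), dom_ir)
  }
  out <- tibble::tibble(chr = "chrX",
                        start = peak_start[keep], end = peak_end[keep],
                        mark = mark, sex = sex)
  class(out) <- c("peak_set", class(out))
  out
}
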