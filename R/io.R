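#' Read and write pipeline file formats
#'
#' Plain-text interchange used by the pipeline: probe annotation as BED6
#' plus two extra columns (gene symbol, biotype), peaks as BED3, expression
#' as a probes-by-samples TSV with a sidecar sample-metadata TSV. All BED
#' coordinates are 0-based half-open.
#'
#' @param annotation,peaks,es Objects to write.
#' @param path,expr_path,meta_path File paths.
#' @name escapex-io
NULL

#' @rdname escapex-io
#' @export
write_annotation_bed <- function(annotation, path) {
  bed <- tibble::tibble(chrom = annotation$chr,
                        start = as.integer(annotation$start),
                        end = as.integer(annotation$end),
                        name = annotation$probe_id,
                        score = 0L,
                        strand = annotation$strand,
                        gene = annotation$gene,
                        biotype = annotation$biotype)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname escapex-io
#' @export
read_annotation_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chr", "start", "end",
                                             "probe_id", "score", "strand",
                                             "gene", "biotype"),
                         col_types = "ciiciccc", progress = FALSE)
  ann <- tibble::tibble(probe_id = bed$probe_id, gene = bed$gene,
                        chr = bed$chr, start = bed$start, end = bed$end,
                        strand = bed$strand, biotype = bed$biotype,
                        role = NA_character_)
  class(ann) <- c("probe_annotation", class(ann))
  ann
}

#' @rdname escapex-io
#' @export
write_peaks_bed <- function(peaks, path) {
  readr::write_tsv(tibble::tibble(chrom = peaks$chr,
                                  start = as.integer(peaks$start),
                                  end = as.integer(peaks$end)),
                   path, col_names = FALSE)
  invisible(path)
}

#' @rdname escapex-io
#' @export
read_peaks_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chr", "start", "end"),
                         col_types = "cii", progress = FALSE)
  class(bed) <- c("peak_set", class(bed))
  bed
}

#' @rdname escapex-io
#' @export
write_expression_tsv <- function(es, expr_path, meta_path) {
  stopifnot(inherits(es, "expr_set"))
  readr::write_tsv(tibble::as_tibble(es$values, rownames = "probe_id"),
                   expr_path)
  readr::write_tsv(es$samples, meta_path)
  invisible(expr_path)
}

#' @rdname escapex-io
#' @export
read_expression_tsv <- function(expr_path, meta_path) {
  tab <- readr::read_tsv(expr_path, col_types = readr::cols(
    probe_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  values <- as.matrix(tab[, -1])
  rownames(values) <- tab$probe_id
  meta <- readr::read_tsv(meta_path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  expr_set(values, meta)
}
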