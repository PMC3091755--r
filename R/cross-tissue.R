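#' Exact-region and intersection overlaps of per-tissue hit lists
#'
#' For every non-empty subset of tissues on one platform, reports both the
#' exclusive Venn region (genes significant in exactly that subset of
#' tissues) and the plain intersection (genes significant in at least those
#' tissues). The exclusive regions partition the union of all hit genes, so
#' their counts sum to the union size, as in a Venn diagram of overlapping
#' sex-biased genes.
#'
#' @param hit_lists Named list, one character vector of gene symbols per
#'   tissue.
#' @param platform Platform label carried into the output.
#' @return A tibble with `platform`, `tissues` (subset collapsed with
#'   `"&"`), `n_tissues`, `exclusive_genes` and `intersection_genes`
#'   (list-columns), `n_exclusive`, `n_intersection`.
#' @export
#' @examples
#' intersect_hits(list(striatum = c("A", "B"), neocortex = c("B", "C")))
intersect_hits <- function(hit_lists, platform = NA_character_) {
  tissues <- names(hit_lists)
  if (is.null(tissues) || any(tissues == "")) {
    stop("hit_lists must be a named list (tissue names)", call. = FALSE)
  }
  if (anyDuplicated(tissues)) stop("duplicate tissue names", call. = FALSE)
  hit_lists <- lapply(hit_lists, unique)
  all_genes <- unique(unlist(hit_lists))
  membership <- vapply(hit_lists, function(g) all_genes %in% g,
                       logical(length(all_genes)))
  if (length(all_genes) == 1) membership <- matrix(membership, nrow = 1,
                                                   dimnames = list(NULL, tissues))
  subsets <- unlist(lapply(seq_along(tissues), function(k)
    utils::combn(tissues, k, simplify = FALSE)), recursive = FALSE)
  purrr::map_dfr(subsets, function(ss) {
    inside <- rowSums(membership[, ss, drop = FALSE]) == length(ss)
    outside <- if (length(ss) == length(tissues)) rep(FALSE, length(all_genes))
      else rowSums(membership[, setdiff(tissues, ss), drop = FALSE]) > 0
    excl <- all_genes[inside & !outside]
    inter <- all_genes[inside]
    tibble::tibble(platform = platform,
                   tissues = paste(ss, collapse = "&"),
                   n_tissues = length(ss),
                   exclusive_genes = list(sort(excl)),
                   intersection_genes = list(sort(inter)),
                   n_exclusive = length(excl),
                   n_intersection = length(inter))
  })
}

#' Categorize genes as known sex-linked, novel sex-linked, or autosomal
#'
#' Genes on the X or Y chromosome are split by membership in a curated list
#' of previously described sex-biased sex-chromosome genes (Xist, Jpx, the
#' coding X-inactivation escapees and their Y paralogues); everything else
#' is autosomal.
#'
#' @param genes Character vector of gene symbols.
#' @param annotation A `probe_annotation` giving each gene's chromosome.
#' @param known_list Curated known sex-linked symbols; defaults to the
#'   fixture shipped with the package.
#' @return A tibble `gene`, `chr`, `category` with `category` one of
#'   `known_sex_linked`, `novel_sex_linked`, `autosomal`.
#' @export
classify_genes <- function(genes, annotation,
                           known_list = known_sex_linked_genes()) {
  gene_chr <- dplyr::distinct(annotation[, c("gene", "chr")])
  idx <- match(genes, gene_chr$gene)
  if (anyNA(idx)) {
    stop("unannotated gene(s): ", paste(genes[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  chr <- gene_chr$chr[idx]
  on_sex <- chr %in% c("chrX", "chrY", "X", "Y")
  tibble::tibble(
    gene = genes, chr = chr,
    category = dplyr::case_when(
      on_sex & genes %in% known_list ~ "known_sex_linked",
      on_sex ~ "novel_sex_linked",
      TRUE ~ "autosomal"))
}

#' Curated known sex-linked gene symbols
#'
#' Reads the editable fixture shipped in `inst/extdata/`: Xist, Jpx (alias
#' 2010000I03Rik), the coding X-inactivation escapees and their Y-linked
#' paralogues.
#'
#' @param path Override the fixture path.
#' @return Character vector of gene symbols.
#' @export
known_sex_linked_genes <- function(path = system.file(
  "extdata", "known_sex_linked_genes.txt", package = "escapex")) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}
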