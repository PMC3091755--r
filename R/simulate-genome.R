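#' Default escapee-domain gene templates
#'
#' Builds the template gene table used by [genome_spec()]: an Xist-like and a
#' Jpx-like locus, four coding/non-coding escapee gene pairs laid out with
#' the characteristic arrangements seen on the mouse X (a head-to-head pair
#' separated by 33 kb, a lncRNA nested in an intron of its coding partner, a
#' tandem pair 2.6 kb downstream, and a head-to-head pair separated by
#' 9.7 kb), a Kdm6a-like coding escapee without a lncRNA partner, an
#' Rps4x-like X-inactivated control, four Y-linked male-biased paralogues and
#' one autosomal female-biased gene. All loci are synthetic stand-ins named
#' after the real genes whose roles they play; coordinates are invented.
#'
#' @return A tibble with columns `gene`, `chr`, `start`, `end` (0-based
#'   half-open), `strand`, `biotype`, `role`, `partner` (coding partner of a
#'   lncRNA, else `NA`).
#' @export
escapee_domain_templates <- function() {
  tibble::tribble(
    ~gene,            ~chr,    ~start,     ~end,       ~strand, ~biotype,    ~role,            ~partner,
    "Xist",           "chrX",  100000000,  100010000,  "-",     "noncoding", "xist",           NA,
    "Jpx",            "chrX",  100050000,  100058000,  "+",     "noncoding", "jpx",            NA,
    # head-to-head, lncRNA 33 kb upstream of the coding gene
    "2010308F09Rik",  "chrX",  9965000,    9967000,    "-",     "noncoding", "lnc_escapee",    "Ddx3x",
    "Ddx3x",          "chrX",  10000000,   10010000,   "+",     "coding",    "coding_escapee", NA,
    # lncRNA nested within an intron of the coding gene
    "Eif2s3x",        "chrX",  20000000,   20010000,   "+",     "coding",    "coding_escapee", NA,
    "D330035K16Rik",  "chrX",  20003000,   20004500,   "+",     "noncoding", "lnc_escapee",    "Eif2s3x",
    # tandem, lncRNA 2.6 kb downstream of the coding gene
    "Kdm5c",          "chrX",  30000000,   30010000,   "+",     "coding",    "coding_escapee", NA,
    "D930009K15Rik",  "chrX",  30012600,   30014400,   "+",     "noncoding", "lnc_escapee",    "Kdm5c",
    # head-to-head separated by 9.7 kb
    "5530601H04Rik",  "chrX",  39988300,   39990300,   "-",     "noncoding", "lnc_escapee",    "2610029G23Rik",
    "2610029G23Rik",  "chrX",  40000000,   40006000,   "+",     "coding",    "coding_escapee", NA,
    # coding escapee with no lncRNA partner
    "Kdm6a",          "chrX",  50000000,   50010000,   "+",     "coding",    "coding_escapee", NA,
    # X-inactivated control
    "Rps4x",          "chrX",  60000000,   60005000,   "+",     "coding",    "xci_control",    NA,
    # Y-linked male-biased paralogues
    "Ddx3y",          "chrY",  1000000,    1010000,    "+",     "coding",    "y_male",         NA,
    "Kdm5d",          "chrY",  2000000,    2010000,    "+",     "coding",    "y_male",         NA,
    "Eif2s3y",        "chrY",  3000000,    3010000,    "+",     "coding",    "y_male",         NA,
    "Uty",            "chrY",  4000000,    4010000,    "+",     "coding",    "y_male",         NA,
    # autosomal female-biased gene
    "Prl",            "chr13", 50000000,   50010000,   "+",     "coding",    "autosomal_biased", NA
  )
}

#' Genome specification for the simulator
#'
#' A genome carries chromosome lengths (one X of ~166 Mb, one Y, at least two
#' autosomes) and a table of template genes, including the coding/non-coding
#' escapee pairs whose gap distances and orientations the downstream domain
#' finder must recover.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#'   Must contain `chrX` and `chrY`, plus at least two autosomes.
#' @param genes Template gene table as produced by
#'   [escapee_domain_templates()].
#' @return An object of class `genome_spec`: a list with `chrom_lengths`,
#'   `genes` and the derived `domains` table (one row per coding/lncRNA pair
#'   with `gap` and `relation`).
#' @export
#' @examples
#' gs <- genome_spec()
#' gs$domains
genome_spec <- function(chrom_lengths = c(chrX = 166e6, chrY = 16e6,
                                          chr1 = 195e6, chr2 = 182e6,
                                          chr13 = 120e6),
                        genes = escapee_domain_templates()) {
  if (!all(c("chrX", "chrY") %in% names(chrom_lengths))) {
    stop("genome must contain chrX and chrY", call. = FALSE)
  }
  autosomes <- setdiff(names(chrom_lengths), c("chrX", "chrY"))
  if (length(autosomes) < 2) {
    stop("genome must contain at least two autosomes", call. = FALSE)
  }
  genes <- tibble::as_tibble(genes)
  bad_chr <- setdiff(genes$chr, names(chrom_lengths))
  if (length(bad_chr)) {
    stop("template genes on unknown chromosomes: ",
         paste(bad_chr, collapse = ", "), call. = FALSE)
  }
  if (any(genes$start < 0 | genes$start >= genes$end)) {
    stop("invalid gene intervals (need 0 <= start < end)", call. = FALSE)
  }
  over <- genes$end > chrom_lengths[genes$chr]
  if (any(over)) {
    stop("chromosome overflow: ", paste(genes$gene[over], collapse = ", "),
         " exceed their chromosome length", call. = FALSE)
  }
  domains <- derive_domains(genes)
  structure(list(chrom_lengths = chrom_lengths, genes = genes,
                 domains = domains),
            class = "genome_spec")
}

# One row per lncRNA with a coding partner: the realized domain span,
# edge-to-edge gap and orientation class.
derive_domains <- function(genes) {
  lnc <- genes[!is.na(genes$partner), ]
  if (nrow(lnc) == 0) {
    return(tibble::tibble(noncoding = character(), coding = character(),
                          chr = character(), start = numeric(),
                          end = numeric(), gap = numeric(),
                          relation = character()))
  }
  purrr::map_dfr(seq_len(nrow(lnc)), function(i) {
    nc <- lnc[i, ]
    cd <- genes[genes$gene == nc$partner, ]
    if (nrow(cd) != 1) {
      stop("partner gene not found: ", nc$partner, call. = FALSE)
    }
    stopifnot(nc$chr == cd$chr)
    tibble::tibble(
      noncoding = nc$gene, coding = cd$gene, chr = nc$chr,
      start = min(nc$start, cd$start), end = max(nc$end, cd$end),
      gap = interval_gap(nc$start, nc$end, cd$start, cd$end),
      relation = classify_relation(nc$start, nc$end, nc$strand,
                                   cd$start, cd$end, cd$strand)
    )
  })
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("<genome_spec> %d chromosomes, %d template genes, %d domains\n",
              length(x$chrom_lengths), nrow(x$genes), nrow(x$domains)))
  invisible(x)
}

#' Generate a probe annotation from a genome specification
#'
#' Realizes every template gene as one probe (the Xist-like locus gets two,
#' mirroring the two-probe sex QC scatter) and fills the remaining probe
#' budget with filler probes placed uniformly at random across chromosomes,
#' each mapping to its own anonymous gene.
#'
#' @param genome A [genome_spec()].
#' @param n_probes Total number of probes to emit. Must be at least the
#'   number of template probes (template genes + 1 extra Xist probe).
#' @param seed Integer seed; the same seed yields a byte-identical table.
#' @param filler_noncoding_frac Fraction of filler probes annotated as
#'   non-coding.
#' @param probe_length Length in bp of filler probe gene intervals.
#' @return A tibble (class `probe_annotation`) with columns `probe_id`,
#'   `gene`, `chr`, `start`, `end`, `strand`, `biotype`, `role`, and
#'   attributes `genome` and `domains`.
#' @export
#' @examples
#' ann <- generate_annotation(genome_spec(), n_probes = 100, seed = 1)
#' attr(ann, "domains")
generate_annotation <- function(genome, n_probes, seed,
                                filler_noncoding_frac = 0.1,
                                probe_length = 1000) {
  stopifnot(inherits(genome, "genome_spec"))
  genes <- genome$genes
  template <- dplyr::mutate(genes,
                            probe_id = paste0(.data$gene, "_p1"),
                            .before = 1)
  xist <- genes[genes$role == "xist", ]
  if (nrow(xist) == 1) {
    template <- dplyr::bind_rows(
      template,
      dplyr::mutate(xist, probe_id = paste0(.data$gene, "_p2"), .before = 1))
  }
  n_template <- nrow(template)
  if (n_probes < n_template) {
    stop("n_probes (", n_probes, ") is below the ", n_template,
         " template probes implied by the genome spec", call. = FALSE)
  }
  n_fill <- n_probes - n_template
  filler <- NULL
  if (n_fill > 0) {
    filler <- withr::with_seed(seed, {
      lens <- genome$chrom_lengths
      chr <- sample(names(lens), n_fill, replace = TRUE, prob = lens)
      start <- floor(stats::runif(n_fill, 0, lens[chr] - probe_length))
      tibble::tibble(
        probe_id = sprintf("probe_%05d", seq_len(n_fill)),
        gene = sprintf("Gene%05d", seq_len(n_fill)),
        chr = chr,
        start = start,
        end = start + probe_length,
        strand = sample(c("+", "-"), n_fill, replace = TRUE),
        biotype = ifelse(stats::runif(n_fill) < filler_noncoding_frac,
                         "noncoding", "coding"),
        role = "filler",
        partner = NA_character_
      )
    })
  }
  ann <- dplyr::bind_rows(template, filler)
  ann$partner <- NULL
  attr(ann, "genome") <- genome
  attr(ann, "domains") <- genome$domains
  class(ann) <- c("probe_annotation", class(ann))
  ann
}

#' Planted escapee domains of an annotation
#'
#' @param annotation A `probe_annotation` from [generate_annotation()] (or a
#'   tibble carrying a `domains` attribute).
#' @return The domain tibble, or an empty tibble when none were planted.
#' @export
planted_domains <- function(annotation) {
  attr(annotation, "domains") %||% derive_domains(
    dplyr::mutate(annotation, partner = NA_character_))
}
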