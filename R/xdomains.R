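is_x_chr <- function(chr) chr %in% c("chrX", "X")

# Edge-to-edge distance of two 0-based half-open intervals; 0 on overlap
# or containment.
interval_gap <- function(start1, end1, start2, end2) {
  pmax(0, pmax(start1, start2) - pmin(end1, end2))
}

# Orientation class of a noncoding/coding gene pair.
classify_relation <- function(nc_start, nc_end, nc_strand,
                              cd_start, cd_end, cd_strand) {
  nested <- (nc_start >= cd_start && nc_end <= cd_end) ||
    (cd_start >= nc_start && cd_end <= nc_end)
  if (nested) return("nested_intronic")
  if (nc_strand != cd_strand && nc_strand %in% c("+", "-") &&
      cd_strand %in% c("+", "-")) {
    # head-to-head: 5' ends face each other across the gap
    left_strand <- if (nc_start <= cd_start) nc_strand else cd_strand
    right_strand <- if (nc_start <= cd_start) cd_strand else nc_strand
    if (left_strand == "-" && right_strand == "+") return("head_to_head")
  }
  "tandem"
}

#' Gap between two genomic intervals
#'
#' Distance in bp between the nearest edges of two 0-based half-open
#' intervals on the same chromosome; 0 when they overlap or one nests in
#' the other.
#'
#' @param a,b Interval-like objects: lists or one-row data frames with
#'   `chr`, `start`, `end`.
#' @return Gap in bp.
#' @export
#' @examples
#' gene_gap(list(chr = "chrX", start = 0, end = 1000),
#'          list(chr = "chrX", start = 34000, end = 40000))  # 33000
gene_gap <- function(a, b) {
  if (a$chr != b$chr) stop("intervals on different chromosomes",
                           call. = FALSE)
  interval_gap(a$start, a$end, b$start, b$end)
}

# Gene-level intervals (one row per gene, span of its probes).
gene_intervals <- function(annotation) {
  annotation |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(chr = dplyr::first(.data$chr),
                     start = min(.data$start), end = max(.data$end),
                     strand = dplyr::first(.data$strand),
                     biotype = dplyr::first(.data$biotype),
                     .groups = "drop")
}

#' Pair female-biased non-coding X genes with nearby coding genes
#'
#' For each female-biased non-coding gene on the X chromosome, finds the
#' nearest female-biased coding X gene within `max_gap` bp (or containing
#' it) and forms a candidate escapee domain, classifying the pair as
#' head-to-head, tandem, or nested-intronic. Each non-coding gene joins at
#' most one domain; candidates with no coding partner in range are returned
#' separately.
#'
#' @param female_biased Character vector of female-biased gene symbols.
#' @param annotation A `probe_annotation` supplying intervals, strands and
#'   biotypes.
#' @param max_gap Maximum pairing distance in bp (default 50,000).
#' @return A tibble (class `escapee_domains`) with columns `noncoding`,
#'   `coding`, `chr`, `start`, `end` (domain span), `gap`, `relation`.
#'   Attribute `unpaired` lists non-coding candidates left without a
#'   partner.
#' @export
pair_coding_noncoding <- function(female_biased, annotation,
                                  max_gap = 50000) {
  gi <- gene_intervals(annotation)
  cand <- gi[gi$gene %in% female_biased & is_x_chr(gi$chr), ]
  nc <- cand[cand$biotype == "noncoding", ]
  cd <- cand[cand$biotype == "coding", ]
  out <- list()
  unpaired <- character()
  for (i in seq_len(nrow(nc))) {
    if (nrow(cd) == 0) {
      unpaired <- c(unpaired, nc$gene[i])
      next
    }
    gaps <- interval_gap(nc$start[i], nc$end[i], cd$start, cd$end)
    j <- which.min(gaps)
    if (gaps[j] > max_gap) {
      unpaired <- c(unpaired, nc$gene[i])
      next
    }
    out[[length(out) + 1]] <- tibble::tibble(
      noncoding = nc$gene[i], coding = cd$gene[j], chr = nc$chr[i],
      start = min(nc$start[i], cd$start[j]),
      end = max(nc$end[i], cd$end[j]),
      gap = gaps[j],
      relation = classify_relation(nc$start[i], nc$end[i], nc$strand[i],
                                   cd$start[j], cd$end[j], cd$strand[j]))
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(noncoding = character(), coding = character(),
                   chr = character(), start = numeric(), end = numeric(),
                   gap = numeric(), relation = character())
  attr(res, "unpaired") <- unpaired
  class(res) <- c("escapee_domains", class(res))
  res
}

#' Default anchor genes for the co-localization null
#'
#' The Xist-like and Jpx-like loci plus the coding X-inactivation escapees
#' treated as fixed in the permutation test.
#'
#' @return Character vector of gene symbols.
#' @export
default_anchor_genes <- function() {
  c("Xist", "Jpx", "Ddx3x", "Eif2s3x", "Kdm5c", "Kdm6a", "2610029G23Rik")
}

#' Permutation false discovery rate for X-chromosome co-localization
#'
#' Implements the permutation null for the observation that the four
#' female-biased lncRNAs all sit close to fixed X-linked genes: the anchor
#' genes (Xist-like, Jpx-like and the coding escapees) are held fixed, and
#' each permutation draws `k` distinct non-anchor X-linked probes uniformly
#' without replacement. A permutation is a success when *all* `k` drawn
#' probes lie within `window` bp up- or downstream of some anchor gene body
#' (anchor interval extended by `window` on both sides). The FDR is the
#' success fraction over `n_perm` permutations.
#'
#' @param annotation A `probe_annotation` with X-linked probes.
#' @param anchors Anchor gene symbols (default [default_anchor_genes()]).
#' @param k Number of probes drawn per permutation (default 4, one per
#'   lncRNA candidate).
#' @param window Window in bp around each anchor (default 50,000).
#' @param n_perm Number of permutations (default 10,000).
#' @param seed Integer seed.
#' @return A list of class `coloc_result`: `fdr`, `successes`, `n_perm`,
#'   `n_in` (eligible probes inside some window), `n_total` (eligible
#'   probes), `analytic` (the exact probability
#'   [analytic_coloc_probability()] for comparison).
#' @export
coloc_permutation_fdr <- function(annotation,
                                  anchors = default_anchor_genes(),
                                  k = 4, window = 50000,
                                  n_perm = 10000, seed = 1L) {
  stopifnot(k >= 1, window >= 0, n_perm >= 1)
  gi <- gene_intervals(annotation)
  anc <- gi[gi$gene %in% anchors, ]
  missing <- setdiff(anchors, anc$gene)
  if (length(missing)) {
    stop("anchor gene(s) not in annotation: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  anc <- anc[is_x_chr(anc$chr), ]
  if (nrow(anc) == 0) stop("no X-linked anchor genes", call. = FALSE)
  probes <- annotation[is_x_chr(annotation$chr) &
                         !(annotation$gene %in% anchors), ]
  if (nrow(probes) < k) {
    stop("k exceeds the ", nrow(probes), " eligible X-linked probes",
         call. = FALSE)
  }
  win <- as_iranges0(pmax(anc$start - window, 0), anc$end + window)
  in_win <- IRanges::overlapsAny(as_iranges0(probes$start, probes$end), win)
  n_total <- nrow(probes)
  successes <- withr::with_seed(seed, {
    s <- 0L
    for (i in seq_len(n_perm)) {
      if (all(in_win[sample.int(n_total, k)])) s <- s + 1L
    }
    s
  })
  structure(list(
    fdr = successes / n_perm,
    successes = successes,
    n_perm = n_perm,
    n_in = sum(in_win),
    n_total = n_total,
    k = k,
    window = window,
    analytic = analytic_coloc_probability(sum(in_win), n_total, k)
  ), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "<coloc_result> FDR = %.4f (%d/%d permutations; %d of %d eligible probes in-window; exact p = %.3g)\n",
    x$fdr, x$successes, x$n_perm, x$n_in, x$n_total, x$analytic))
  invisible(x)
}

#' @export
glance.coloc_result <- function(x, ...) {
  tibble::tibble(fdr = x$fdr, successes = x$successes, n_perm = x$n_perm,
                 n_in = x$n_in, n_total = x$n_total, k = x$k,
                 window = x$window, analytic = x$analytic)
}

#' Exact probability that all drawn probes are in-window
#'
#' Closed-form counterpart of [coloc_permutation_fdr()]: the probability
#' that `k` probes drawn uniformly without replacement from `n_total`
#' eligible probes, of which `n_in` are in-window, are all in-window —
#' `choose(n_in, k) / choose(n_total, k)`, 0 when `n_in < k`.
#'
#' @param n_in In-window eligible probes.
#' @param n_total All eligible probes.
#' @param k Probes drawn.
#' @return A probability.
#' @export
#' @examples
#' analytic_coloc_probability(4, 10, 4)  # 1/210
analytic_coloc_probability <- function(n_in, n_total, k) {
  if (n_in > n_total || k > n_total || any(c(n_in, n_total, k) < 0)) {
    stop("inconsistent counts", call. = FALSE)
  }
  if (n_in < k) return(0)
  exp(lchoose(n_in, k) - lchoose(n_total, k))
}

coverage_fraction <- function(peaks_ir, start, end) {
  if (end <= start) return(NA_real_)
  q <- as_iranges0(start, end)
  hit <- IRanges::restrict(peaks_ir, start = BiocGenerics::start(q),
                           end = BiocGenerics::end(q))
  sum(BiocGenerics::width(hit)) / (end - start)
}

#' Peak coverage inside a domain versus its flanks
#'
#' Computes the fraction of a domain covered by the union of peak
#' intervals, the mean coverage of its two flanking windows, and the ratio
#' of the two — a depletion score for repressive-mark coverage over
#' candidate escapee domains (ratios well below 1 indicate depletion;
#' `Inf` marks a covered domain with bare flanks).
#'
#' @param domains A tibble of domains (`chr`, `start`, `end`); one row per
#'   domain. Extra columns are carried through.
#' @param peaks A `peak_set` tibble (`chr`, `start`, `end`).
#' @param flank Width in bp of each flanking window (default 100,000).
#' @return The input tibble with columns `inside`, `flank_mean`,
#'   `depletion_ratio` appended.
#' @export
domain_peak_coverage <- function(domains, peaks, flank = 100000) {
  stopifnot(flank >= 0)
  domains <- tibble::as_tibble(domains)
  res <- purrr::map_dfr(seq_len(nrow(domains)), function(i) {
    d <- domains[i, ]
    pk <- peaks[peaks$chr == d$chr, ]
    pk_ir <- IRanges::reduce(as_iranges0(pk$start, pk$end))
    inside <- coverage_fraction(pk_ir, d$start, d$end)
    fl <- if (flank == 0) NA_real_ else {
      left <- coverage_fraction(pk_ir, max(d$start - flank, 0), d$start)
      right <- coverage_fraction(pk_ir, d$end, d$end + flank)
      mean(c(left, right), na.rm = TRUE)
    }
    ratio <- if (is.na(fl)) NA_real_ else if (fl == 0) {
      if (inside == 0) 0 else Inf
    } else inside / fl
    tibble::tibble(inside = inside, flank_mean = fl, depletion_ratio = ratio)
  })
  dplyr::bind_cols(domains, res)
}
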