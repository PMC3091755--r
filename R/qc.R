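#' Standardize every array to a fixed mean and standard deviation
#'
#' Applies the affine map that gives each sample column a mean of
#' `target_mean` and a population (1/n) standard deviation of `target_sd`;
#' microarray sets preprocessed this way are conventionally put on a
#' mean-8 / sd-2 log2 scale before screening. The map is idempotent: a
#' second application leaves the values unchanged.
#'
#' @param es An [expr_set].
#' @param target_mean,target_sd Targets of the affine map.
#' @return The standardized [expr_set].
#' @export
#' @examples
#' m <- matrix(c(0, 2, 1, 5), 2, 2,
#'             dimnames = list(c("p1", "p2"), c("s1", "s2")))
#' meta <- tibble::tibble(sample_id = c("s1", "s2"), sex = c("F", "M"),
#'                        tissue = "t", platform = "sim")
#' standardize_arrays(expr_set(m, meta))$values
standardize_arrays <- function(es, target_mean = 8, target_sd = 2) {
  stopifnot(inherits(es, "expr_set"))
  v <- es$values
  mu <- colMeans(v)
  sd_pop <- sqrt(colMeans(sweep(v, 2, mu)^2))
  if (any(sd_pop == 0)) {
    stop("constant array column(s): ",
         paste(colnames(v)[sd_pop == 0], collapse = ", "), call. = FALSE)
  }
  out <- sweep(sweep(v, 2, mu), 2, sd_pop, "/") * target_sd + target_mean
  expr_set(out, es$samples)
}

#' Flag arrays whose Xist signal contradicts their recorded sex
#'
#' Xist is expressed from the inactive X and is therefore a near-binary
#' female marker. For every Xist probe a decision threshold is set at the
#' midpoint between the medians of the recorded-female and recorded-male
#' values; an array is flagged as sex-discordant only when *all* of its
#' Xist probes fall strictly on the opposite side of their thresholds
#' relative to the recorded sex — with two probes this is the
#' opposite-quadrant geometry of an Xist scatter plot.
#'
#' @param es An [expr_set].
#' @param xist_probe_ids Probe ids of the Xist probes present in `es`.
#' @return A list of class `qc_report`: `flagged` (tibble sample_id,
#'   reason), `xist_values` (per-sample tibble of Xist signals and the
#'   discordance call per probe), `thresholds` (per-probe tibble).
#' @export
xist_sex_check <- function(es, xist_probe_ids) {
  stopifnot(inherits(es, "expr_set"))
  xist_probe_ids <- intersect(xist_probe_ids, rownames(es$values))
  if (length(xist_probe_ids) < 1) {
    stop("no Xist probe ids found in the expression matrix", call. = FALSE)
  }
  sex <- es$samples$sex
  if (!all(c("F", "M") %in% sex)) {
    stop("both recorded sexes must be present to set Xist thresholds",
         call. = FALSE)
  }
  xv <- es$values[xist_probe_ids, , drop = FALSE]
  if (all(xv == xv[1])) {
    stop("all Xist values identical; thresholds undefined", call. = FALSE)
  }
  thr <- vapply(seq_along(xist_probe_ids), function(i) {
    (stats::median(xv[i, sex == "F"]) + stats::median(xv[i, sex == "M"])) / 2
  }, numeric(1))
  # discordant: female recorded but strictly below threshold, or male
  # recorded but strictly above
  disc <- (xv < thr & rep(sex == "F", each = nrow(xv))) |
    (xv > thr & rep(sex == "M", each = nrow(xv)))
  flagged_ids <- colnames(xv)[colSums(disc) == nrow(xv)]

  xist_values <- tibble::as_tibble(t(xv), rownames = "sample_id")
  xist_values$sex <- sex
  xist_values$n_discordant_probes <- unname(colSums(disc))
  structure(list(
    flagged = tibble::tibble(sample_id = flagged_ids,
                             reason = rep("xist_discordant",
                                          length(flagged_ids))),
    xist_values = xist_values,
    thresholds = tibble::tibble(probe_id = xist_probe_ids, threshold = thr),
    excluded = character()
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d array(s) flagged as sex-discordant, %d excluded by balancing\n",
              nrow(x$flagged), length(x$excluded)))
  invisible(x)
}

#' Tidy a QC report
#'
#' @param x A `qc_report` from [xist_sex_check()].
#' @param ... Unused.
#' @return Per-sample tibble of Xist signals, discordant-probe counts, and
#'   flag status.
#' @export
tidy.qc_report <- function(x, ...) {
  dplyr::mutate(x$xist_values,
                flagged = .data$sample_id %in% x$flagged$sample_id,
                excluded = .data$sample_id %in% x$excluded)
}

#' Remove flagged arrays and balance the sexes
#'
#' Drops the arrays flagged by [xist_sex_check()], then down-samples the
#' larger recorded-sex group uniformly at random (seeded) within each tissue
#' to the size of the smaller, so each tissue contributes an equal number of
#' female and male arrays.
#'
#' @param es An [expr_set].
#' @param qc A `qc_report` (or `NULL` for no flags).
#' @param seed Integer seed for the down-sampling draw.
#' @return The balanced [expr_set]; dropped ids are recorded in the
#'   `excluded` attribute.
#' @export
balance_by_sex <- function(es, qc = NULL, seed = 1L) {
  stopifnot(inherits(es, "expr_set"))
  drop_ids <- if (!is.null(qc)) qc$flagged$sample_id else character()
  keep <- !(es$samples$sample_id %in% drop_ids)
  meta <- es$samples[keep, ]
  excluded <- character()
  kept_ids <- character()
  withr::with_seed(seed, {
    for (tis in unique(meta$tissue)) {
      sub <- meta[meta$tissue == tis, ]
      f_ids <- sub$sample_id[sub$sex == "F"]
      m_ids <- sub$sample_id[sub$sex == "M"]
      if (length(f_ids) == 0 || length(m_ids) == 0) {
        stop("tissue ", tis, ": a sex group is empty after QC", call. = FALSE)
      }
      n <- min(length(f_ids), length(m_ids))
      keep_f <- if (length(f_ids) > n) sort(sample(f_ids, n)) else f_ids
      keep_m <- if (length(m_ids) > n) sort(sample(m_ids, n)) else m_ids
      kept_ids <- c(kept_ids, keep_f, keep_m)
      excluded <- c(excluded, setdiff(c(f_ids, m_ids), c(keep_f, keep_m)))
    }
  })
  out <- filter_samples(es, es$samples$sample_id[
    es$samples$sample_id %in% kept_ids])
  attr(out, "excluded") <- c(drop_ids[drop_ids %in% es$samples$sample_id],
                             excluded)
  out
}
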