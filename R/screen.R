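#' Mann-Whitney U test for a two-sex comparison
#'
#' Computes the U statistic of the first (female) group from joint midranks
#' and a two-sided p-value. The p-value is exact (from the null U
#' distribution) when the combined sample size is at most 12 and there are
#' no ties; otherwise the normal approximation with tie correction and
#' continuity correction is used. The convention is fixed so results are
#' bit-reproducible across group sizes.
#'
#' @param values_f,values_m Numeric vectors of log2 intensities for the
#'   female and male groups.
#' @return A list with `U` (female-group U) and `p` (two-sided, in (0, 1]).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$p  # 1/3 by exact enumeration
mann_whitney_u <- function(values_f, values_m) {
  n_f <- length(values_f)
  n_m <- length(values_m)
  if (n_f == 0 || n_m == 0) stop("both groups must be non-empty",
                                 call. = FALSE)
  r <- rank(c(values_f, values_m))
  u <- sum(r[seq_len(n_f)]) - n_f * (n_f + 1) / 2
  ties <- anyDuplicated(c(values_f, values_m)) > 0
  nm <- n_f * n_m
  if (n_f + n_m <= 12 && !ties) {
    p <- if (u > nm / 2) {
      stats::pwilcox(u - 1, n_f, n_m, lower.tail = FALSE)
    } else {
      stats::pwilcox(u, n_f, n_m)
    }
    p <- min(2 * p, 1)
  } else {
    n_tot <- n_f + n_m
    tab <- table(r)
    tie_term <- sum(tab^3 - tab) / (n_tot * (n_tot - 1))
    sigma2 <- nm / 12 * (n_tot + 1 - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u - nm / 2
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)
      p <- min(2 * stats::pnorm(-abs(z)), 1)
    }
  }
  list(U = u, p = max(p, .Machine$double.xmin))
}

# Vectorised normal-approximation path over the rows of a matrix; falls back
# to the scalar rule (including the exact small-sample branch) row-wise only
# when that branch can apply.
mw_batch <- function(values, is_f) {
  n_f <- sum(is_f)
  n_m <- sum(!is_f)
  n_tot <- n_f + n_m
  nm <- n_f * n_m
  if (n_tot <= 12) {
    res <- apply(values, 1, function(v)
      unlist(mann_whitney_u(v[is_f], v[!is_f])))
    return(list(U = res["U", ], p = res["p", ]))
  }
  ranks <- t(apply(values, 1, rank))
  u <- rowSums(ranks[, is_f, drop = FALSE]) - n_f * (n_f + 1) / 2
  tie_term <- apply(ranks, 1, function(r) {
    tab <- tabulate(match(r, unique(r)))
    sum(tab^3 - tab)
  }) / (n_tot * (n_tot - 1))
  sigma2 <- nm / 12 * (n_tot + 1 - tie_term)
  z <- u - nm / 2
  z <- ifelse(sigma2 > 0, (z - sign(z) * 0.5) / sqrt(sigma2), 0)
  p <- pmin(2 * stats::pnorm(-abs(z)), 1)
  p[sigma2 <= 0] <- 1
  list(U = u, p = pmax(p, .Machine$double.xmin))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of raw p-values, returned in input order. A thin
#' validating wrapper around [stats::p.adjust()].
#'
#' @param p_values Numeric vector of raw p-values, each in (0, 1].
#' @return Adjusted p-values (same length and order).
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric())
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Signed linear fold change from log2 group means
#'
#' Returns the female/male linear ratio `r = 2^(mean_f - mean_m)` as `+r`
#' when female expression is at least as high, and as `-1/r` (the negative
#' male/female ratio) otherwise, so `|FC| >= 1` always and the sign encodes
#' the direction of the bias.
#'
#' @param mean_log2_f,mean_log2_m Group means on the log2 scale (vectorised).
#' @return Signed fold change(s).
#' @export
#' @examples
#' fold_change_signed(9, 8)   # +2
#' fold_change_signed(8, 9)   # -2
fold_change_signed <- function(mean_log2_f, mean_log2_m) {
  r <- 2^(mean_log2_f - mean_log2_m)
  ifelse(r >= 1, r, -1 / r)
}

#' Screen one tissue for sex-biased probes
#'
#' Runs a Mann-Whitney test per probe (recorded females vs males), adjusts
#' the p-values by Benjamini-Hochberg across all probes of the tissue, and
#' reports the probes whose adjusted p-value is at most `alpha` together
#' with their signed fold change and direction. The input must be
#' sex-balanced (equal female and male arrays), as produced by
#' [balance_by_sex()].
#'
#' @param es A sex-balanced, single-tissue [expr_set].
#' @param alpha FDR threshold (default 0.05).
#' @param annotation Optional `probe_annotation`; adds `gene` and `chr`
#'   columns to the result.
#' @param return_all Return every probe (with a `significant` flag) instead
#'   of hits only.
#' @return A tibble (class `sexbias_result`) with columns `probe_id`,
#'   `gene`, `chr`, `U`, `p_raw`, `p_adj`, `fold_change`, `direction`,
#'   sorted by adjusted then raw p. Attribute `n_tested` records the BH
#'   family size.
#' @export
screen_tissue <- function(es, alpha = 0.05, annotation = NULL,
                          return_all = FALSE) {
  stopifnot(inherits(es, "expr_set"))
  if (dplyr::n_distinct(es$samples$tissue) != 1) {
    stop("screen_tissue() expects a single tissue; split the set first",
         call. = FALSE)
  }
  is_f <- es$samples$sex == "F"
  if (sum(is_f) != sum(!is_f)) {
    stop("input is not sex-balanced (", sum(is_f), " F vs ", sum(!is_f),
         " M); run balance_by_sex() first", call. = FALSE)
  }
  mw <- mw_batch(es$values, is_f)
  mean_f <- rowMeans(es$values[, is_f, drop = FALSE])
  mean_m <- rowMeans(es$values[, !is_f, drop = FALSE])
  fc <- fold_change_signed(mean_f, mean_m)
  res <- tibble::tibble(
    probe_id = rownames(es$values),
    U = unname(mw$U),
    p_raw = unname(mw$p),
    p_adj = bh_adjust(unname(mw$p)),
    fold_change = unname(fc),
    direction = unname(ifelse(fc >= 0, "female_up", "male_up"))
  )
  if (!is.null(annotation)) {
    res <- dplyr::left_join(
      res, annotation[, c("probe_id", "gene", "chr")], by = "probe_id")
    res <- dplyr::relocate(res, "gene", "chr", .after = "probe_id")
  } else {
    res$gene <- res$probe_id
    res$chr <- NA_character_
    res <- dplyr::relocate(res, "gene", "chr", .after = "probe_id")
  }
  res$significant <- res$p_adj <= alpha
  res <- dplyr::arrange(res, .data$p_adj, .data$p_raw)
  if (!return_all) {
    res <- dplyr::filter(res, .data$significant)
    res$significant <- NULL
  }
  attr(res, "n_tested") <- nrow(es$values)
  attr(res, "alpha") <- alpha
  attr(res, "tissue") <- es$samples$tissue[1]
  class(res) <- c("sexbias_result", class(res))
  res
}

#' Mean-centered expression grid for heatmap display
#'
#' Centers each significant probe's row by subtracting its overall
#' (both-sex) mean within the balanced tissue, so colour encodes deviation
#' from the probe's mean expression.
#'
#' @param es The balanced [expr_set] the screen ran on.
#' @param hits A `sexbias_result` (or any tibble with `probe_id`).
#' @return A probes-by-samples matrix with all row means zero.
#' @export
heatmap_matrix <- function(es, hits) {
  stopifnot(inherits(es, "expr_set"))
  ids <- unique(hits$probe_id)
  missing <- setdiff(ids, rownames(es$values))
  if (length(missing)) {
    stop("hit probes absent from the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  v <- es$values[ids, , drop = FALSE]
  sweep(v, 1, rowMeans(v))
}
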