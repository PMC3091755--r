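#' Fit a qPCR standard curve
#'
#' Least-squares regression of quantification cycle on log10 relative input
#' over a cDNA dilution series. The amplification efficiency is
#' `E = 10^(-1/slope) - 1`; a perfectly efficient reaction doubles per
#' cycle, giving slope `-1/log10(2) ~ -3.32` and `E = 1`.
#'
#' @param dilutions Positive relative input factors (>= 3 distinct levels).
#' @param ct Observed Ct values, same length.
#' @return A list of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `n`.
#' @export
#' @examples
#' sc <- fit_standard_curve(10^-(0:4), 25 + (1 / log10(2)) * (0:4))
#' sc$efficiency
fit_standard_curve <- function(dilutions, ct) {
  if (any(dilutions <= 0)) stop("dilution factors must be positive",
                                call. = FALSE)
  lx <- log10(dilutions)
  if (length(unique(lx)) < 3) {
    stop("need at least 3 distinct dilution levels", call. = FALSE)
  }
  fit <- stats::lm(ct ~ lx)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    warning("non-negative slope: not a valid amplification curve")
  }
  tss <- sum((ct - mean(ct))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    efficiency = 10^(-1 / slope) - 1,
    n = length(ct)
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> slope %.3f, intercept %.2f, R^2 %.4f, efficiency %.1f%%\n",
    x$slope, x$intercept, x$r_squared, 100 * x$efficiency))
  invisible(x)
}

#' @export
tidy.standard_curve <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, efficiency = x$efficiency,
                 n = x$n)
}

#' Convert a Ct value to relative copy number via a standard curve
#'
#' Inverts the fitted curve: `copies = 10^((ct - intercept) / slope)`.
#' Non-finite Ct values (undetermined wells) propagate as `NA` rather than
#' erroring.
#'
#' @param ct Ct value(s).
#' @param curve A [fit_standard_curve()] result.
#' @return Relative copy number(s).
#' @export
quantify <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  out <- 10^((ct - curve$intercept) / curve$slope)
  out[!is.finite(ct)] <- NA_real_
  out
}

#' Normalize a target quantity to the geometric mean of two reference genes
#'
#' `target / sqrt(ref1 * ref2)` — normalization to the geometric mean of
#' two endogenous controls (e.g. Actb and Gapdh), which cancels per-sample
#' loading differences.
#'
#' @param target Target copy number(s).
#' @param ref1,ref2 Reference copy numbers (positive).
#' @return Normalized expression.
#' @export
#' @examples
#' normalize_geomean(100, 4, 9)  # 100/6
normalize_geomean <- function(target, ref1, ref2) {
  if (any(ref1 <= 0 | ref2 <= 0, na.rm = TRUE)) {
    stop("reference quantities must be positive", call. = FALSE)
  }
  target / sqrt(ref1 * ref2)
}

#' Female/male comparison of normalized expression
#'
#' Ratio of group means with per-group standard errors, and a two-sided
#' unequal-variance (Welch) t-test on the normalized values, annotated with
#' the conventional significance stars (* <= 0.05, ** <= 0.01,
#' *** <= 0.001, else "ns").
#'
#' @param values_f,values_m Normalized expression per female / male sample
#'   (each of length >= 2).
#' @return One-row tibble: `ratio` (mean F / mean M), `mean_f`, `mean_m`,
#'   `sem_f`, `sem_m`, `p`, `stars`, `n_f`, `n_m`.
#' @export
compare_sexes <- function(values_f, values_m) {
  if (length(values_f) < 2 || length(values_m) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  mf <- mean(values_f)
  mm <- mean(values_m)
  p <- if (stats::sd(values_f) == 0 && stats::sd(values_m) == 0) {
    # degenerate noiseless groups: identical means are a perfect null,
    # different means an (effectively) infinite t
    if (mf == mm) 1 else .Machine$double.xmin
  } else {
    stats::t.test(values_f, values_m, alternative = "two.sided",
                  var.equal = FALSE)$p.value
  }
  tibble::tibble(
    ratio = mf / mm,
    mean_f = mf, mean_m = mm,
    sem_f = stats::sd(values_f) / sqrt(length(values_f)),
    sem_m = stats::sd(values_m) / sqrt(length(values_m)),
    p = p,
    stars = p_stars(p),
    n_f = length(values_f), n_m = length(values_m))
}

#' Run the full qPCR quantification and sex comparison
#'
#' Fits a standard curve per gene from the dilution series, converts sample
#' Ct values to relative copy numbers, normalizes each sample to the
#' geometric mean of the two reference genes, and compares female vs male
#' normalized expression per target gene and tissue.
#'
#' @param qpcr A `qpcr_dataset` from [generate_qpcr()], or a list with
#'   `ct` and `dilution_series` tibbles of the same shape.
#' @param reference_genes The two endogenous control genes.
#' @return A tibble (class `qpcr_result`), one row per target gene and
#'   tissue, with the [compare_sexes()] columns plus curve diagnostics
#'   (`slope`, `efficiency`, `r_squared`).
#' @export
qpcr_analysis <- function(qpcr, reference_genes = qpcr$reference_genes %||%
                            c("Actb", "Gapdh")) {
  ct <- tibble::as_tibble(qpcr$ct)
  dil <- tibble::as_tibble(qpcr$dilution_series)
  stopifnot(length(reference_genes) == 2)
  miss <- setdiff(reference_genes, unique(ct$gene))
  if (length(miss)) stop("reference gene(s) missing from Ct table: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  curves <- dil |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_map(~ tibble::tibble(
      gene = .y$gene, curve = list(fit_standard_curve(.x$dilution, .x$ct)))) |>
    dplyr::bind_rows()
  ct$copies <- purrr::map2_dbl(ct$gene, ct$ct, function(g, c1) {
    cv <- curves$curve[[match(g, curves$gene)]]
    quantify(c1, cv)
  })
  refs <- ct |>
    dplyr::filter(.data$gene %in% reference_genes) |>
    dplyr::select("sample_id", "gene", "copies") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "copies")
  norm <- ct |>
    dplyr::filter(!(.data$gene %in% reference_genes)) |>
    dplyr::left_join(refs, by = "sample_id")
  norm$normalized <- normalize_geomean(norm$copies,
                                       norm[[reference_genes[1]]],
                                       norm[[reference_genes[2]]])
  res <- norm |>
    dplyr::group_by(.data$tissue, .data$gene) |>
    dplyr::group_map(~ dplyr::bind_cols(
      tibble::tibble(tissue = .y$tissue, gene = .y$gene),
      compare_sexes(.x$normalized[.x$sex == "F"],
                    .x$normalized[.x$sex == "M"]))) |>
    dplyr::bind_rows()
  diag <- tibble::tibble(
    gene = curves$gene,
    slope = purrr::map_dbl(curves$curve, "slope"),
    efficiency = purrr::map_dbl(curves$curve, "efficiency"),
    r_squared = purrr::map_dbl(curves$curve, "r_squared"))
  res <- dplyr::left_join(res, diag, by = "gene")
  class(res) <- c("qpcr_result", class(res))
  res
}
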