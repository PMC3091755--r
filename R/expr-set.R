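#' Expression set container
#'
#' Bundles a probes-by-samples matrix of log2 intensities with a per-sample
#' metadata table. This is the unit the QC and screening stages operate on:
#' rows are array probes, columns are arrays, and `samples` records each
#' array's recorded sex, tissue and platform.
#'
#' @param values Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param samples A data frame with one row per column of `values`, columns
#'   `sample_id`, `sex` (`"F"` or `"M"`), `tissue`, `platform`. Order must
#'   match the columns of `values`.
#'
#' @return An object of class `expr_set`.
#' @export
#' @examples
#' m <- matrix(rnorm(20, 8, 2), 4, 5,
#'             dimnames = list(paste0("p", 1:4), paste0("s", 1:5)))
#' meta <- tibble::tibble(sample_id = paste0("s", 1:5),
#'                        sex = c("F", "F", "F", "M", "M"),
#'                        tissue = "liver", platform = "sim")
#' es <- expr_set(m, meta)
#' es
expr_set <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have probe rownames and sample colnames", call. = FALSE)
  }
  samples <- tibble::as_tibble(samples)
  req <- c("sample_id", "sex", "tissue", "platform")
  miss <- setdiff(req, names(samples))
  if (length(miss)) {
    stop("`samples` is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate probe ids in `values`", call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (!identical(colnames(values), as.character(samples$sample_id))) {
    stop("`samples$sample_id` must match colnames(values) in order",
         call. = FALSE)
  }
  if (!all(samples$sex %in% c("F", "M"))) {
    stop("every sample must have a recorded sex of \"F\" or \"M\"",
         call. = FALSE)
  }
  structure(list(values = values, samples = samples), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  ns <- table(x$samples$sex)
  cat(sprintf(
    "<expr_set> %d probes x %d samples (%d F / %d M), %d tissue(s)\n",
    nrow(x$values), ncol(x$values),
    sum(x$samples$sex == "F"), sum(x$samples$sex == "M"),
    dplyr::n_distinct(x$samples$tissue)))
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

#' Subset an expression set by sample ids
#'
#' @param es An [expr_set].
#' @param sample_ids Character vector of sample ids to keep (order kept).
#' @return An [expr_set] restricted to those samples.
#' @export
filter_samples <- function(es, sample_ids) {
  stopifnot(inherits(es, "expr_set"))
  keep <- match(sample_ids, es$samples$sample_id)
  if (anyNA(keep)) {
    stop("unknown sample ids: ",
         paste(sample_ids[is.na(keep)], collapse = ", "), call. = FALSE)
  }
  expr_set(es$values[, keep, drop = FALSE], es$samples[keep, ])
}

#' Tidy an expression set into a long tibble
#'
#' @param x An [expr_set].
#' @param ... Unused.
#' @return A tibble with columns `probe_id`, `sample_id`, `value`, plus the
#'   sample metadata columns.
#' @export
tidy.expr_set <- function(x, ...) {
  long <- tibble::tibble(
    probe_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
  dplyr::left_join(long, x$samples, by = "sample_id")
}

#' One-row summary of an expression set
#'
#' @param x An [expr_set].
#' @param ... Unused.
#' @return A one-row tibble with probe/sample counts and sex balance.
#' @export
glance.expr_set <- function(x, ...) {
  tibble::tibble(
    n_probes = nrow(x$values),
    n_samples = ncol(x$values),
    n_female = sum(x$samples$sex == "F"),
    n_male = sum(x$samples$sex == "M"),
    n_tissues = dplyr::n_distinct(x$samples$tissue)
  )
}
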