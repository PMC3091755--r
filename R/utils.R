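#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance

# Deterministic sub-seed for a named pipeline stage so stages can be re-run
# in isolation with the randomness they saw inside a full run.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 1009 + h * 31 + 17) %% 2147483647)
}

# 0-based half-open [start, end) intervals -> IRanges (1-based closed).
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = as.integer(start + 1), end = as.integer(end))
}

# Significance stars used in the qPCR bar plots.
p_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
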