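# Small fixtures built in code.

toy_expr_set <- function(values, sex, tissue = "t") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("p%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  expr_set(values, tibble::tibble(
    sample_id = colnames(values), sex = sex,
    tissue = rep_len(tissue, ncol(values)), platform = "sim"))
}

# A hand-built annotation tibble with the probe_annotation class.
toy_annotation <- function(df) {
  need <- c("probe_id", "gene", "chr", "start", "end", "strand", "biotype")
  for (nm in setdiff(need, names(df))) {
    df[[nm]] <- switch(nm, strand = "+", biotype = "coding",
                       stop("missing column ", nm))
  }
  if (!"role" %in% names(df)) df$role <- "filler"
  df <- tibble::as_tibble(df)
  class(df) <- c("probe_annotation", class(df))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Annotation with one X anchor gene and a controlled number of eligible
# probes inside / outside its window, for permutation-vs-analytic checks.
coloc_fixture <- function(n_in, n_total, window = 5000) {
  anchor <- tibble::tibble(probe_id = "anchor_p1", gene = "Anchor",
                           chr = "chrX", start = 0, end = 1000)
  n_out <- n_total - n_in
  inside <- if (n_in > 0) tibble::tibble(
    probe_id = sprintf("in_%03d", seq_len(n_in)),
    gene = sprintf("InGene%03d", seq_len(n_in)),
    chr = "chrX",
    start = 1200 + 100 * seq_len(n_in),
    end = 1200 + 100 * seq_len(n_in) + 50)
  outside <- if (n_out > 0) tibble::tibble(
    probe_id = sprintf("out_%03d", seq_len(n_out)),
    gene = sprintf("OutGene%03d", seq_len(n_out)),
    chr = "chrX",
    start = 10 * window + 1000 * seq_len(n_out),
    end = 10 * window + 1000 * seq_len(n_out) + 50)
  toy_annotation(dplyr::bind_rows(anchor, inside, outside))
}
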