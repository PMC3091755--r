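test_that("interval gaps follow the half-open convention", {
  expect_equal(gene_gap(list(chr = "chrX", start = 100, end = 200),
                        list(chr = "chrX", start = 150, end = 300)), 0)
  expect_equal(gene_gap(list(chr = "chrX", start = 0, end = 1000),
                        list(chr = "chrX", start = 34000, end = 40000)),
               33000)
  expect_error(gene_gap(list(chr = "chrX", start = 0, end = 10),
                        list(chr = "chr1", start = 0, end = 10)),
               "different chromosomes")
  set.seed(3)
  for (i in 1:20) {
    a <- sort(sample.int(1e5, 2)); b <- sort(sample.int(1e5, 2))
    ia <- list(chr = "c", start = a[1], end = a[2])
    ib <- list(chr = "c", start = b[1], end = b[2])
    expect_equal(gene_gap(ia, ib), gene_gap(ib, ia))
  }
})

test_that("planted coding/noncoding pairs are recovered with correct relations", {
  ann <- generate_annotation(genome_spec(), 60, seed = 1)
  female <- ann$gene[ann$role %in% c("lnc_escapee", "coding_escapee")]
  dom <- pair_coding_noncoding(unique(female), ann)
  expect_equal(nrow(dom), 4)
  expect_equal(dom$coding[dom$noncoding == "2010308F09Rik"], "Ddx3x")
  expect_equal(dom$gap[dom$noncoding == "2010308F09Rik"], 33000)
  expect_equal(dom$relation[dom$noncoding == "2010308F09Rik"],
               "head_to_head")
  expect_equal(dom$coding[dom$noncoding == "D330035K16Rik"], "Eif2s3x")
  expect_equal(dom$gap[dom$noncoding == "D330035K16Rik"], 0)
  expect_equal(dom$relation[dom$noncoding == "D330035K16Rik"],
               "nested_intronic")
  expect_equal(dom$coding[dom$noncoding == "D930009K15Rik"], "Kdm5c")
  expect_equal(dom$gap[dom$noncoding == "D930009K15Rik"], 2600)
  expect_equal(dom$relation[dom$noncoding == "D930009K15Rik"], "tandem")
  expect_equal(dom$coding[dom$noncoding == "5530601H04Rik"],
               "2610029G23Rik")
  expect_equal(dom$gap[dom$noncoding == "5530601H04Rik"], 9700)
  expect_equal(dom$relation[dom$noncoding == "5530601H04Rik"],
               "head_to_head")
})

test_that("noncoding genes beyond max_gap stay unpaired", {
  ann <- toy_annotation(tibble::tibble(
    probe_id = c("nc", "cd"), gene = c("LncFar", "CodNear"),
    chr = "chrX", start = c(0, 200000), end = c(1000, 210000),
    strand = c("+", "+"), biotype = c("noncoding", "coding")))
  dom <- pair_coding_noncoding(c("LncFar", "CodNear"), ann,
                               max_gap = 50000)
  expect_equal(nrow(dom), 0)
  expect_equal(attr(dom, "unpaired"), "LncFar")
  dom2 <- pair_coding_noncoding(c("LncFar", "CodNear"), ann,
                                max_gap = 300000)
  expect_equal(nrow(dom2), 1)
  expect_equal(dom2$relation, "tandem")
})

test_that("analytic co-localization probability is exact combinatorics", {
  expect_equal(analytic_coloc_probability(10, 10, 4), 1)
  expect_equal(analytic_coloc_probability(4, 10, 4), 1 / 210)
  expect_equal(analytic_coloc_probability(3, 10, 4), 0)
  expect_error(analytic_coloc_probability(11, 10, 4), "inconsistent")
})

test_that("permutation FDR is seeded, exact at the edges, and near its analytic value", {
  # all eligible probes in-window -> certain success
  ann_all <- coloc_fixture(n_in = 6, n_total = 6)
  r_all <- coloc_permutation_fdr(ann_all, anchors = "Anchor", k = 4,
                                 window = 5000, n_perm = 200, seed = 1)
  expect_equal(r_all$fdr, 1)
  # impossible event
  ann_none <- coloc_fixture(n_in = 2, n_total = 10)
  r_none <- coloc_permutation_fdr(ann_none, anchors = "Anchor", k = 4,
                                  window = 5000, n_perm = 200, seed = 1)
  expect_equal(r_none$fdr, 0)
  # determinism
  ann <- coloc_fixture(n_in = 4, n_total = 10)
  r1 <- coloc_permutation_fdr(ann, anchors = "Anchor", k = 4,
                              window = 5000, n_perm = 3000, seed = 9)
  r2 <- coloc_permutation_fdr(ann, anchors = "Anchor", k = 4,
                              window = 5000, n_perm = 3000, seed = 9)
  expect_identical(r1$successes, r2$successes)
  # estimator consistency at the spec's canonical point (p = 1/210)
  expect_equal(r1$analytic, 1 / 210)
  se <- sqrt(r1$analytic * (1 - r1$analytic) / r1$n_perm)
  expect_lte(abs(r1$fdr - r1$analytic), 3 * se + 1e-12)
  # guard rails
  expect_error(coloc_permutation_fdr(ann, anchors = "Ghost"), "Ghost")
  expect_error(coloc_permutation_fdr(ann, anchors = "Anchor", k = 50),
               "eligible")
})

test_that("coverage matches the sweep-line union oracle on random peak sets", {
  set.seed(17)
  for (i in 1:200) {
    n_pk <- sample(1:25, 1)
    s <- sample.int(10000, n_pk, replace = TRUE)
    w <- sample.int(800, n_pk, replace = TRUE)
    pk <- tibble::tibble(chr = "chrX", start = s, end = s + w)
    d <- sort(sample.int(9000, 2))
    dom <- tibble::tibble(chr = "chrX", start = d[1], end = d[2] + 100)
    got <- domain_peak_coverage(dom, pk, flank = 500)
    want <- sweep_union_length(pk$start, pk$end, dom$start, dom$end) /
      (dom$end - dom$start)
    expect_equal(got$inside, want, tolerance = 1e-12)
  }
})

test_that("coverage edge cases: no peaks, half coverage, bare flanks", {
  dom <- tibble::tibble(chr = "chrX", start = 1000, end = 2000)
  none <- tibble::tibble(chr = "chrX", start = numeric(), end = numeric())
  expect_equal(domain_peak_coverage(dom, none)$inside, 0)
  half <- tibble::tibble(chr = "chrX", start = 1000, end = 1500)
  cv <- domain_peak_coverage(dom, half, flank = 1000)
  expect_equal(cv$inside, 0.5)
  expect_equal(cv$flank_mean, 0)
  expect_true(is.infinite(cv$depletion_ratio))
  # covered flanks, empty domain -> ratio 0
  flanky <- tibble::tibble(chr = "chrX", start = c(0, 2000),
                           end = c(1000, 3000))
  cv2 <- domain_peak_coverage(dom, flanky, flank = 1000)
  expect_equal(cv2$inside, 0)
  expect_equal(cv2$flank_mean, 1)
  expect_equal(cv2$depletion_ratio, 0)
})

test_that("escapee domains are depleted while the inactivated control is covered", {
  ann <- generate_annotation(genome_spec(), 80, seed = 3)
  pk <- generate_peaks(ann, seed = 5)
  dom <- planted_domains(ann)
  cov <- domain_peak_coverage(dom[, c("chr", "start", "end")], pk,
                              flank = 100000)
  expect_true(all(cov$depletion_ratio < 0.2))
  rps <- ann[ann$gene == "Rps4x", ][1, ]
  expect_gt(domain_peak_coverage(rps[, c("chr", "start", "end")],
                                 pk)$inside, 0.5)
})
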