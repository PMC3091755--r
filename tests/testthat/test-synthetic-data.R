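test_that("annotation realizes the template gene layout with exact gaps", {
  gs <- genome_spec()
  ann <- generate_annotation(gs, n_probes = 100, seed = 3)
  dom <- planted_domains(ann)
  expect_setequal(dom$gap, c(33000, 0, 2600, 9700))
  # 33 kb head-to-head pair realized edge to edge
  hh <- dom[dom$gap == 33000, ]
  g1 <- ann[ann$gene == hh$noncoding, ][1, ]
  g2 <- ann[ann$gene == hh$coding, ][1, ]
  expect_equal(gene_gap(g1, g2), 33000)
  # every probe maps to exactly one gene interval
  expect_false(anyDuplicated(ann$probe_id) > 0)
  expect_true(all(ann$start < ann$end))
  lens <- gs$chrom_lengths[ann$chr]
  expect_true(all(ann$end <= lens))
})

test_that("annotation with no probe budget beyond templates has no filler", {
  gs <- genome_spec()
  n_template <- nrow(gs$genes) + 1  # Xist carries two probes
  ann <- generate_annotation(gs, n_probes = n_template, seed = 1)
  expect_equal(nrow(ann), n_template)
  expect_false(any(ann$role == "filler"))
  expect_error(generate_annotation(gs, n_probes = n_template - 1, seed = 1),
               "template probes")
})

test_that("annotation generation is deterministic under a fixed seed", {
  gs <- genome_spec()
  a1 <- generate_annotation(gs, 200, seed = 42)
  a2 <- generate_annotation(gs, 200, seed = 42)
  expect_identical(a1, a2)
  a3 <- generate_annotation(gs, 200, seed = 43)
  expect_false(identical(a1$start, a3$start))
})

test_that("genome spec rejects intervals exceeding their chromosome", {
  genes <- escapee_domain_templates()
  genes$end[1] <- 1e12
  expect_error(genome_spec(genes = genes), "overflow")
  expect_error(genome_spec(chrom_lengths = c(chrX = 1e6, chrY = 1e5,
                                             chr1 = 1e6)),
               "two autosomes")
})

test_that("null dataset has all-zero effects and biased counts track the config", {
  ann <- generate_annotation(genome_spec(), 300, seed = 1)
  null_cfg <- sim_config(tissues = "t", samples_per_sex_per_tissue = 5,
                         n_probes = 300, frac_sex_biased = 0,
                         mislabel_frac = 0, plant_templates = FALSE)
  sim <- generate_expression(null_cfg, ann, seed = 2)
  expect_true(all(sim$truth$effects$true_effect == 0))

  cfg <- sim_config(tissues = "t", samples_per_sex_per_tissue = 5,
                    n_probes = 300, frac_sex_biased = 0.1)
  sim2 <- generate_expression(cfg, ann, seed = 2)
  n_filler <- sum(ann$role[1:300] == "filler")
  n_template_planted <- sum(ann$role[1:300] %in%
    c("xist", "y_male", "lnc_escapee", "coding_escapee", "jpx",
      "autosomal_biased"))
  expect_equal(sum(sim2$truth$effects$true_effect != 0),
               round(0.1 * n_filler) + n_template_planted)
})

test_that("planted effects are recovered by group mean differences", {
  ann <- toy_annotation(tibble::tibble(
    probe_id = "pp", gene = "G", chr = "chr1", start = 0, end = 100))
  cfg <- sim_config(tissues = "t", samples_per_sex_per_tissue = 60,
                    n_probes = 1, frac_sex_biased = 1,
                    effect_range_log2 = c(1, 1), noise_sd = 0.5,
                    plant_templates = FALSE)
  se <- 0.5 * sqrt(2 / 60)
  for (s in 1:5) {
    sim <- generate_expression(cfg, ann, seed = s)
    is_f <- sim$truth$samples$true_sex == "F"
    diff <- mean(sim$expression$values[1, is_f]) -
      mean(sim$expression$values[1, !is_f])
    expect_lt(abs(abs(diff) - 1), 3 * se)
  }
})

test_that("Xist-like probes separate the sexes by about four orders of magnitude", {
  ann <- generate_annotation(genome_spec(), 50, seed = 1)
  cfg <- sim_config(tissues = "t", samples_per_sex_per_tissue = 30,
                    n_probes = 50, noise_sd = 0.5)
  sim <- generate_expression(cfg, ann, seed = 9)
  is_f <- sim$truth$samples$true_sex == "F"
  for (p in c("Xist_p1", "Xist_p2")) {
    ratio <- 2^(mean(sim$expression$values[p, is_f]) -
                  mean(sim$expression$values[p, !is_f]))
    expect_gt(ratio, 1e4 / 2)
    expect_lt(ratio, 1e4 * 2)
  }
  # Y-linked probes in females sit near the floor, not missing
  yv <- sim$expression$values["Ddx3y_p1", is_f]
  expect_true(all(is.finite(yv)))
  expect_lt(mean(yv), cfg$floor_log2 + 2)
})

test_that("expression generation is deterministic and rejects unbalanced mislabeling", {
  ann <- generate_annotation(genome_spec(), 60, seed = 1)
  cfg <- sim_config(tissues = "t", samples_per_sex_per_tissue = 4,
                    n_probes = 60, mislabel_frac = 0.2)
  s1 <- generate_expression(cfg, ann, seed = 5)
  s2 <- generate_expression(cfg, ann, seed = 5)
  expect_identical(s1$expression$values, s2$expression$values)
  expect_identical(s1$truth, s2$truth)
  bad <- sim_config(tissues = "t", samples_per_sex_per_tissue = 2,
                    n_probes = 60, mislabel_frac = 1)
  expect_error(generate_expression(bad, ann, seed = 1), "mislabel_frac")
})

test_that("mislabeling flips only the recorded label", {
  ann <- generate_annotation(genome_spec(), 60, seed = 1)
  cfg <- sim_config(tissues = "t", samples_per_sex_per_tissue = 10,
                    n_probes = 60, mislabel_frac = 0.2)
  sim <- generate_expression(cfg, ann, seed = 3)
  tr <- sim$truth$samples
  expect_gt(sum(tr$mislabeled), 0)
  expect_true(all(tr$recorded_sex[tr$mislabeled] !=
                    tr$true_sex[tr$mislabeled]))
  expect_true(all(tr$recorded_sex[!tr$mislabeled] ==
                    tr$true_sex[!tr$mislabeled]))
  expect_identical(sim$expression$samples$sex, tr$recorded_sex)
})

test_that("simulated peaks blanket the X but spare the escapee domains", {
  ann <- generate_annotation(genome_spec(), 80, seed = 2)
  pk <- generate_peaks(ann, seed = 4)
  dom <- planted_domains(ann)
  cov <- domain_peak_coverage(dom[, c("chr", "start", "end")], pk,
                              flank = 100000)
  expect_true(all(cov$inside < 0.05))
  rps <- ann[ann$gene == "Rps4x", ][1, ]
  cov_r <- domain_peak_coverage(rps[, c("chr", "start", "end")], pk)
  expect_gt(cov_r$inside, 0.5)
  # empty domain list: the whole X is covered above background
  pk_all <- generate_peaks(ann, seed = 4, domains = dom[0, ])
  cov_d <- domain_peak_coverage(dom[, c("chr", "start", "end")], pk_all)
  expect_true(all(cov_d$inside > 0.5))
  expect_identical(generate_peaks(ann, seed = 4), pk)
})

test_that("qPCR generator encodes planted ratios and a valid dilution law", {
  qd <- generate_qpcr(n_f = 16, n_m = 16, ct_noise_sd = 0, loading_sd = 0,
                      seed = 1)
  # noiseless: slopes are exactly the ideal -1/log10(2)
  for (g in unique(qd$dilution_series$gene)) {
    d <- qd$dilution_series[qd$dilution_series$gene == g, ]
    fit <- stats::lm(ct ~ log10(dilution), data = d)
    expect_equal(unname(coef(fit)[2]), -1 / log10(2), tolerance = 1e-10)
  }
  # noiseless planted ratio recovered exactly from Ct differences
  res <- qpcr_analysis(qd)
  expect_equal(res$ratio[match("Rps4x", res$gene)], 1, tolerance = 1e-9)
  expect_equal(res$ratio[match("Kdm5c", res$gene)],
               qd$truth$ratio[qd$truth$gene == "Kdm5c"], tolerance = 1e-9)
  expect_error(generate_qpcr(dilutions = c(1, -0.1, 0.01)), "positive")
})

test_that("noisy qPCR recovers a planted 1.5-fold ratio within simulation error", {
  ratios <- vapply(1:20, function(s) {
    qd <- generate_qpcr(targets = tibble::tibble(gene = "T", ratio = 1.5),
                        n_f = 16, n_m = 16, seed = s)
    res <- qpcr_analysis(qd)
    res$ratio[res$gene == "T"]
  }, numeric(1))
  mc_se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 1.5), 4 * mc_se + 0.02)
})

test_that("reference genes stay null in most replicates", {
  p_ref <- vapply(1:30, function(s) {
    qd <- generate_qpcr(targets = tibble::tibble(gene = "T", ratio = 1.5),
                        n_f = 8, n_m = 8, seed = 100 + s)
    # Welch test directly on the (null) reference-gene copies
    ct <- qd$ct[qd$ct$gene == "Actb", ]
    stats::t.test(ct$ct[ct$sex == "F"], ct$ct[ct$sex == "M"])$p.value
  }, numeric(1))
  expect_gte(mean(p_ref > 0.05), 0.9)
})
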