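test_that("Mann-Whitney handles the textbook cases", {
  # identical groups: perfect symmetry
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # {1,2} vs {3,4}: exact two-sided p = 2/6
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3)
  # swapping the groups maps U to n_f*n_m - U and keeps p
  a <- rnorm(5); b <- rnorm(4)
  r1 <- mann_whitney_u(a, b)
  r2 <- mann_whitney_u(b, a)
  expect_equal(r1$p, r2$p)
  expect_equal(r2$U, length(a) * length(b) - r1$U)
  expect_error(mann_whitney_u(numeric(), 1:3), "non-empty")
})

test_that("exact p equals brute-force enumeration for all sizes up to 10", {
  set.seed(31)
  for (n_f in 1:5) {
    for (n_m in n_f:(10 - n_f)) {
      if (n_m < 1) next
      vals <- sample(seq_len(40), n_f + n_m)  # distinct, no ties
      f <- vals[seq_len(n_f)]
      m <- vals[-seq_len(n_f)]
      expect_equal(mann_whitney_u(f, m)$p, mw_enum_p(f, m),
                   tolerance = 1e-12,
                   info = sprintf("n_f=%d n_m=%d", n_f, n_m))
    }
  }
})

test_that("approximate p matches wilcox.test with ties and larger groups", {
  set.seed(7)
  for (i in 1:20) {
    n_f <- sample(10:40, 1)
    n_m <- sample(10:40, 1)
    f <- round(rnorm(n_f, 8, 2), 1)  # rounding induces ties
    m <- round(rnorm(n_m, 8, 2), 1)
    ours <- mann_whitney_u(f, m)
    ref <- suppressWarnings(stats::wilcox.test(f, m, exact = FALSE,
                                               correct = TRUE))
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("the batch screen path agrees with the scalar test", {
  set.seed(11)
  v <- matrix(rnorm(50 * 30, 8, 2), 50, 30)
  v[1:5, ] <- round(v[1:5, ], 0)  # ties in some rows
  is_f <- rep(c(TRUE, FALSE), each = 15)
  batch <- escapex:::mw_batch(v, is_f)
  for (i in seq_len(nrow(v))) {
    sc <- mann_whitney_u(v[i, is_f], v[i, !is_f])
    expect_equal(batch$U[i], sc$U)
    expect_equal(batch$p[i], sc$p, tolerance = 1e-12)
  }
  # small combined n routes through the exact branch
  v2 <- matrix(rnorm(10 * 6, 8, 2), 10, 6)
  is_f2 <- rep(c(TRUE, FALSE), each = 3)
  batch2 <- escapex:::mw_batch(v2, is_f2)
  for (i in seq_len(nrow(v2))) {
    sc <- mann_whitney_u(v2[i, is_f2], v2[i, !is_f2])
    expect_equal(unname(batch2$U[i]), sc$U)
    expect_equal(unname(batch2$p[i]), sc$p, tolerance = 1e-12)
  }
})

test_that("BH adjustment applies the step-up rule and preserves order", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(2)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("signed fold change follows the female-positive convention", {
  expect_equal(fold_change_signed(8, 8), 1)
  expect_equal(fold_change_signed(9, 8), 2)
  expect_equal(fold_change_signed(8, 9), -2)
  fc <- fold_change_signed(rnorm(50, 8), rnorm(50, 8))
  expect_true(all(abs(fc) >= 1))
})

test_that("screen demands a balanced single tissue and reports coherent hits", {
  ann <- generate_annotation(genome_spec(), 120, seed = 1)
  cfg <- sim_config(tissues = "t", samples_per_sex_per_tissue = 20,
                    n_probes = 120)
  sim <- generate_expression(cfg, ann, seed = 4)
  hits <- screen_tissue(sim$expression, annotation = ann)
  # Xist is always a female-up hit
  expect_true(all(c("Xist_p1", "Xist_p2") %in% hits$probe_id))
  expect_true(all(hits$direction[hits$gene == "Xist"] == "female_up"))
  # invariants: p_adj >= p_raw, |FC| >= 1, sign matches direction
  expect_true(all(hits$p_adj >= hits$p_raw))
  expect_true(all(hits$p_adj > 0 & hits$p_adj <= 1))
  expect_true(all(abs(hits$fold_change) >= 1))
  expect_identical(hits$direction,
                   ifelse(hits$fold_change >= 0, "female_up", "male_up"))
  # direction matches the sign of the observed mean difference
  is_f <- sim$expression$samples$sex == "F"
  md <- rowMeans(sim$expression$values[hits$probe_id, is_f, drop = FALSE]) -
    rowMeans(sim$expression$values[hits$probe_id, !is_f, drop = FALSE])
  expect_identical(unname(md >= 0), hits$direction == "female_up")

  unbal <- filter_samples(sim$expression,
                          sim$expression$samples$sample_id[-1])
  expect_error(screen_tissue(unbal), "balanced")
  two_tis <- generate_expression(
    sim_config(tissues = c("a", "b"), samples_per_sex_per_tissue = 3,
               n_probes = 120), ann, seed = 1)
  expect_error(screen_tissue(two_tis$expression), "single tissue")
})

test_that("screen recovers planted 2-fold effects at 60 vs 60", {
  ann <- generate_annotation(genome_spec(), 500, seed = 2)
  cfg <- sim_config(tissues = "t", samples_per_sex_per_tissue = 60,
                    n_probes = 500, frac_sex_biased = 0.05,
                    effect_range_log2 = c(1, 1), noise_sd = 0.5,
                    plant_templates = FALSE)
  sim <- generate_expression(cfg, ann, seed = 8)
  planted <- sim$truth$effects$probe_id[sim$truth$effects$true_effect != 0]
  hits <- screen_tissue(sim$expression, annotation = ann)
  expect_gte(mean(planted %in% hits$probe_id), 0.9)
})

test_that("heatmap rows are centered on the overall mean", {
  m <- rbind(p1 = c(7, 9), p2 = c(5, 5), p3 = c(1, 3))
  colnames(m) <- c("a", "b")
  es <- expr_set(m, tibble::tibble(sample_id = c("a", "b"),
                                   sex = c("F", "M"), tissue = "t",
                                   platform = "sim"))
  hm <- heatmap_matrix(es, tibble::tibble(probe_id = c("p1", "p2")))
  expect_equal(hm["p1", ], c(a = -1, b = 1))
  expect_equal(hm["p2", ], c(a = 0, b = 0))
  expect_equal(unname(rowMeans(hm)), rep(0, 2))
  expect_error(heatmap_matrix(es, tibble::tibble(probe_id = "absent")),
               "absent")
})
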