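#' Simulation configuration
#'
#' Collects the parameters of the expression simulator. Defaults mirror the
#' design of a multi-tissue mouse microarray study: tens of arrays per sex
#' per tissue, most planted sex-bias effects between 1.1- and 2-fold, a
#' near-binary Xist signal separating the sexes by roughly four orders of
#' magnitude, and an optional fraction of arrays whose recorded sex label is
#' flipped relative to the true sex.
#'
#' @param tissues Character vector of tissue names.
#' @param samples_per_sex_per_tissue Arrays per sex in each tissue; a single
#'   value or one per tissue.
#' @param n_probes Total probes on the simulated array.
#' @param frac_sex_biased Fraction of filler probes given a planted sex
#'   effect (in addition to the always-planted escapee, Y-linked, Xist-like
#'   and autosomal-template probes).
#' @param effect_range_log2 Length-2 vector, bounds of planted |log2 fold
#'   change| for ordinary biased probes (default `log2(c(1.1, 2))`).
#' @param xist_log2_effect Female-vs-male log2 fold of the Xist-like probes
#'   (default 13.3, i.e. ~10^4-fold on the linear scale).
#' @param noise_sd Gaussian noise standard deviation on the log2 scale.
#' @param mislabel_frac Fraction of arrays (per tissue) whose recorded sex is
#'   flipped.
#' @param baseline_mean,baseline_sd Per-probe baseline log2 intensities are
#'   drawn from a Gaussian with these parameters.
#' @param floor_log2 Detection-floor log2 intensity used for Xist-like
#'   probes in males and Y-linked probes in females (signal present but near
#'   the floor, never missing).
#' @param plant_templates Plant the template effects (Xist-like, Y-linked,
#'   escapee and autosomal-biased genes)? Set `FALSE` for a global-null
#'   data set in which, with `frac_sex_biased = 0`, every true effect is
#'   zero.
#' @param seed Default seed used when the generator is called without one.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(tissues = c("striatum", "neocortex"),
                       samples_per_sex_per_tissue = 43,
                       n_probes = 1000,
                       frac_sex_biased = 0.05,
                       effect_range_log2 = log2(c(1.1, 2)),
                       xist_log2_effect = 13.3,
                       noise_sd = 0.5,
                       mislabel_frac = 0,
                       baseline_mean = 8,
                       baseline_sd = 2,
                       floor_log2 = 2,
                       plant_templates = TRUE,
                       seed = 1L) {
  stopifnot(length(tissues) >= 1, !anyDuplicated(tissues))
  n_per <- rep_len(as.integer(samples_per_sex_per_tissue), length(tissues))
  if (any(n_per < 1)) stop("need at least one array per sex per tissue",
                           call. = FALSE)
  for (p in c(frac_sex_biased, mislabel_frac)) {
    if (p < 0 || p > 1) stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  if (length(effect_range_log2) != 2 ||
      effect_range_log2[1] > effect_range_log2[2]) {
    stop("effect_range_log2 must be an ordered pair of log2 bounds",
         call. = FALSE)
  }
  stopifnot(noise_sd >= 0, baseline_sd >= 0)
  structure(list(
    tissues = tissues,
    samples_per_sex_per_tissue = n_per,
    n_probes = as.integer(n_probes),
    frac_sex_biased = frac_sex_biased,
    effect_range_log2 = effect_range_log2,
    xist_log2_effect = xist_log2_effect,
    noise_sd = noise_sd,
    mislabel_frac = mislabel_frac,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    floor_log2 = floor_log2,
    plant_templates = isTRUE(plant_templates),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d tissue(s), %s arrays/sex, %d probes, %.0f%% biased, noise_sd %.2f\n",
    length(x$tissues),
    paste(x$samples_per_sex_per_tissue, collapse = "/"),
    x$n_probes, 100 * x$frac_sex_biased, x$noise_sd))
  invisible(x)
}

#' Simulate a multi-tissue expression data set with known ground truth
#'
#' Draws per-probe baseline log2 intensities, adds planted female-positive
#' effects to the escapee-template probes (and male-positive effects to the
#' Y-linked probes), gives the Xist-like probes a near-binary sex signal
#' (males at the detection floor), plants effects of random sign on a
#' configurable fraction of filler probes, adds Gaussian noise, and
#' optionally flips the recorded sex label of a fraction of arrays. The
#' recorded label is all the downstream QC sees; Xist-like and Y-linked
#' signals always follow the true sex, which is what makes mislabels
#' detectable.
#'
#' @param config A [sim_config()].
#' @param annotation A `probe_annotation` from [generate_annotation()] with
#'   at least `config$n_probes` probes.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A list of class `sim_dataset` with elements `expression` (an
#'   [expr_set] whose metadata carries the *recorded* sex), and `truth`
#'   (list: `effects` tibble of per-probe true signed log2 effects,
#'   `samples` tibble with true/recorded sex and a `mislabeled` flag,
#'   `domains` planted domain tibble).
#' @export
#' @examples
#' ann <- generate_annotation(genome_spec(), n_probes = 60, seed = 1)
#' sim <- generate_expression(sim_config(tissues = "eye",
#'                                       samples_per_sex_per_tissue = 5,
#'                                       n_probes = 60), ann, seed = 1)
#' sim$expression
generate_expression <- function(config, annotation, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(annotation) < config$n_probes) {
    stop("annotation has fewer probes than config$n_probes", call. = FALSE)
  }
  ann <- annotation[seq_len(config$n_probes), ]
  probes <- ann$probe_id

  withr::with_seed(seed, {
    # per-probe sex-neutral baseline; floor for the binary-signal probes
    base <- stats::rnorm(length(probes), config$baseline_mean,
                         config$baseline_sd)
    female_mean <- male_mean <- base
    eff_lo <- config$effect_range_log2[1]
    eff_hi <- config$effect_range_log2[2]
    draw_eff <- function(n) stats::runif(n, eff_lo, eff_hi)

    plant <- config$plant_templates
    is_xist <- plant & ann$role == "xist"
    is_y <- plant & ann$role == "y_male"
    is_fem_template <- plant & ann$role %in% c("lnc_escapee",
                                               "coding_escapee", "jpx",
                                               "autosomal_biased")
    is_filler <- if (plant) ann$role == "filler" else rep(TRUE, nrow(ann))

    male_mean[is_xist] <- config$floor_log2
    female_mean[is_xist] <- config$floor_log2 + config$xist_log2_effect
    female_mean[is_y] <- config$floor_log2
    male_mean[is_y] <- pmax(base[is_y], config$floor_log2 + eff_hi)
    female_mean[is_fem_template] <-
      male_mean[is_fem_template] + draw_eff(sum(is_fem_template))

    n_extra <- round(config$frac_sex_biased * sum(is_filler))
    if (n_extra > 0) {
      idx <- sample(which(is_filler), n_extra)
      sgn <- sample(c(-1, 1), n_extra, replace = TRUE)
      shift <- sgn * draw_eff(n_extra)
      female_mean[idx] <- female_mean[idx] + pmax(shift, 0)
      male_mean[idx] <- male_mean[idx] + pmax(-shift, 0)
    }
    effects <- female_mean - male_mean

    # samples: balanced true sexes per tissue, then label flips
    samp <- purrr::map2_dfr(config$tissues, config$samples_per_sex_per_tissue,
      function(tis, n) {
        tibble::tibble(
          sample_id = sprintf("%s_%s%02d", tis, rep(c("F", "M"), each = n),
                              c(seq_len(n), seq_len(n))),
          true_sex = rep(c("F", "M"), each = n),
          tissue = tis)
      })
    samp$recorded_sex <- samp$true_sex
    samp$mislabeled <- FALSE
    for (tis in config$tissues) {
      rows <- which(samp$tissue == tis)
      n_mis <- round(config$mislabel_frac * length(rows))
      if (n_mis > 0) {
        flip <- sample(rows, n_mis)
        for (sx in c("F", "M")) {
          n_left <- sum(samp$true_sex[rows] == sx) -
            sum(samp$true_sex[flip] == sx)
          if (n_left < 1) {
            stop("mislabel_frac too high: no correctly labeled ", sx,
                 " arrays would remain in ", tis, call. = FALSE)
          }
        }
        samp$recorded_sex[flip] <- ifelse(samp$true_sex[flip] == "F",
                                          "M", "F")
        samp$mislabeled[flip] <- TRUE
      }
    }

    mu <- outer(effects, as.numeric(samp$true_sex == "F")) + male_mean
    values <- mu + stats::rnorm(length(mu), 0, config$noise_sd)
    dimnames(values) <- list(probes, samp$sample_id)
  })

  meta <- tibble::tibble(sample_id = samp$sample_id,
                         sex = samp$recorded_sex,
                         tissue = samp$tissue,
                         platform = "sim")
  structure(list(
    expression = expr_set(values, meta),
    truth = list(
      effects = tibble::tibble(probe_id = probes, gene = ann$gene,
                               chr = ann$chr, role = ann$role,
                               true_effect = effects),
      samples = samp,
      domains = planted_domains(annotation)
    ),
    annotation = ann
  ), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset>\n  ")
  print(x$expression)
  cat(sprintf("  %d probes with nonzero true effect, %d mislabeled arrays\n",
              sum(x$truth$effects$true_effect != 0),
              sum(x$truth$samples$mislabeled)))
  invisible(x)
}
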