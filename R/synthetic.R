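#' Default quantitative trait panel for the synthetic cohort
#'
#' Per-cluster means and standard deviations for thirteen routine clinical
#' traits (anthropometry, lipids, glycaemia, renal function, blood pressure,
#' haematology), in original clinical units, laid out as four phenotype
#' strata: a moderate-risk stratum, a low-risk ("healthy") stratum, a second
#' moderate stratum, and a high-risk stratum. These defaults define the study
#' conditions every downstream stage is exercised against.
#'
#' @return A list with elements `traits` (character vector), `means` and
#'   `sds` (4 x traits matrices) and `cor` (traits x traits correlation
#'   matrix shared across clusters).
#' @export
default_trait_panel <- function() {
  traits <- c("BMI", "T_CHO", "HDL_C", "LDL_C", "TG", "FASTING_GLUCOSE",
              "HBA1C", "URIC_ACID", "EGFR", "PLATELET", "SYSTOLIC",
              "DIASTOLIC", "T_BILIRUBIN")
  means <- rbind(
    c(24.4, 185, 48.7, 118, 113.0, 92.2, 5.61, 5.44, 106.0, 255, 117, 72.3, 0.56),
    c(21.6, 183, 62.3, 107,  64.6, 90.1, 5.46, 4.94, 106.0, 222, 111, 68.9, 0.75),
    c(23.3, 199, 55.4, 127,  99.3, 91.6, 5.50, 5.77,  99.2, 226, 115, 72.1, 0.74),
    c(27.1, 203, 46.8, 133, 152.0, 97.5, 5.84, 6.37, 102.0, 253, 124, 77.7, 0.62))
  sds <- rbind(
    c(2.92, 31.8,  9.92, 28.2, 56.1,  8.04, 0.365, 1.31, 13.2, 56.9, 15.6,  9.96, 0.21),
    c(2.54, 30.7, 12.40, 26.7, 24.3,  7.56, 0.334, 1.19, 12.5, 48.4, 15.3,  9.68, 0.25),
    c(2.60, 32.7, 12.10, 29.3, 45.7,  7.23, 0.328, 1.38, 14.3, 47.9, 16.2, 10.40, 0.24),
    c(3.16, 33.8,  9.54, 30.2, 68.4, 10.70, 0.450, 1.44, 14.0, 56.5, 16.5, 10.60, 0.23))
  colnames(means) <- colnames(sds) <- traits

  R <- diag(length(traits))
  dimnames(R) <- list(traits, traits)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_r("T_CHO", "LDL_C", 0.85)
  set_r("T_CHO", "TG", 0.30)
  set_r("T_CHO", "HDL_C", 0.15)
  set_r("LDL_C", "TG", 0.25)
  set_r("HDL_C", "TG", -0.40)
  set_r("HDL_C", "LDL_C", -0.05)
  set_r("FASTING_GLUCOSE", "HBA1C", 0.55)
  set_r("SYSTOLIC", "DIASTOLIC", 0.75)
  set_r("BMI", "TG", 0.30)
  set_r("BMI", "HDL_C", -0.30)
  set_r("BMI", "SYSTOLIC", 0.25)
  set_r("BMI", "URIC_ACID", 0.25)
  list(traits = traits, means = means, sds = sds, cor = R)
}

default_disease_models <- function() {
  # Coefficients act on full-sample-standardized traits, whose spread is
  # dominated by the between-cluster separation under the default config;
  # values are sized so the healthy stratum lands at ~1-3% prevalence and
  # the high-risk stratum at ~4-17%, the gradient the pipeline is meant to
  # detect.
  list(
    dyslipidemia = list(intercept = -3.0,
                        coef = c(TG = 0.33, LDL_C = 0.17, HDL_C = -0.17)),
    hypertension = list(intercept = -2.45,
                        coef = c(SYSTOLIC = 0.30, DIASTOLIC = 0.17, BMI = 0.13)),
    diabetes = list(intercept = -3.9,
                    coef = c(FASTING_GLUCOSE = 0.30, HBA1C = 0.25, BMI = 0.10)))
}

#' Default SNP panel: one causal variant with cluster-differential MAF
#'
#' The planted variant mimics an APOA5 promoter SNP whose minor (C) allele is
#' depleted in the low-disease-prevalence stratum: per-cluster minor-allele
#' frequencies 0.2843, 0.2419, 0.2715, 0.2877 for clusters 1-4.
#'
#' @return A data.frame with one row per causal SNP and a list-column `maf`
#'   of per-cluster minor-allele frequencies.
#' @export
default_snp_panel <- function() {
  data.frame(snp_id = "rs651821", chrom = "11", pos = 116662579L,
             gene = "APOA5",
             maf = I(list(c(0.2843, 0.2419, 0.2715, 0.2877))),
             stringsAsFactors = FALSE)
}

#' Default NMR peak model
#'
#' Gaussian peak positions/widths covering the far-methyl region (lipoprotein
#' CH3/CH2, leucine, valine), lactate, alanine, the GlycA N-acetyl resonance
#' at ~2.04 ppm, acetone, and glucose. Amplitudes for the lipoprotein,
#' branched-chain amino-acid and GlycA signals are lower in cluster 2 (the
#' low-prevalence stratum) and higher in cluster 4, mirroring the plasma
#' profile the pipeline is designed to detect.
#'
#' @return data.frame with columns `name`, `center`, `width` and `amp1`..`amp4`.
#' @export
default_spectrum_peaks <- function() {
  peaks <- rbind(
    data.frame(name = "lipoprotein_CH3", center = 0.86, width = 0.030,
               amp1 = 10.0, amp2 = 7.0, amp3 = 9.0, amp4 = 12.0),
    data.frame(name = "leucine", center = 0.95, width = 0.015,
               amp1 = 5.0, amp2 = 3.8, amp3 = 4.6, amp4 = 5.5),
    data.frame(name = "valine", center = 1.03, width = 0.015,
               amp1 = 4.0, amp2 = 3.2, amp3 = 3.8, amp4 = 4.4),
    data.frame(name = "lipoprotein_CH2", center = 1.26, width = 0.040,
               amp1 = 12.0, amp2 = 8.0, amp3 = 11.0, amp4 = 15.0),
    data.frame(name = "lactate", center = 1.33, width = 0.012,
               amp1 = 6.0, amp2 = 6.0, amp3 = 6.0, amp4 = 6.0),
    data.frame(name = "alanine", center = 1.48, width = 0.012,
               amp1 = 3.0, amp2 = 3.0, amp3 = 3.0, amp4 = 3.0),
    data.frame(name = "GlycA", center = 2.04, width = 0.020,
               amp1 = 10.0, amp2 = 8.0, amp3 = 9.5, amp4 = 11.0),
    data.frame(name = "acetone", center = 2.22, width = 0.010,
               amp1 = 2.0, amp2 = 2.0, amp3 = 2.0, amp4 = 2.0),
    data.frame(name = "glucose_a", center = 3.40, width = 0.050,
               amp1 = 8.0, amp2 = 7.8, amp3 = 8.0, amp4 = 8.6),
    data.frame(name = "glucose_b", center = 3.70, width = 0.040,
               amp1 = 7.0, amp2 = 6.8, amp3 = 7.0, amp4 = 7.6),
    data.frame(name = "glucose_anomeric", center = 5.23, width = 0.010,
               amp1 = 2.0, amp2 = 2.0, amp3 = 2.0, amp4 = 2.2))
  peaks
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the generator: cluster structure, per-cluster trait
#' distributions (multivariate normal), logistic disease-risk models, the SNP
#' panel with per-cluster minor-allele frequencies, the NMR peak model, and
#' nuisance parameters (baseline, noise, missingness). The defaults emulate a
#' biobank cohort with four phenotype strata whose trait separations match a
#' published east-Asian cohort at original clinical units, one causal variant
#' depleted in the healthy stratum, and spectra whose lipoprotein-methyl,
#' leucine and GlycA regions shift with cluster membership.
#'
#' @param n_subjects number of subjects to simulate.
#' @param n_clusters number of planted phenotype clusters.
#' @param cluster_weights probability vector of cluster membership (sums to 1).
#' @param trait_means `n_clusters` x traits matrix of per-cluster means
#'   (original units).
#' @param trait_sds matching matrix of per-cluster standard deviations.
#' @param trait_sd_scale factor applied to the default per-cluster SDs (only
#'   when `trait_sds` is not supplied). The tabulated per-cluster SDs of a
#'   k-means-partitioned cohort describe contiguous cells of one continuous
#'   trait cloud; Gaussian components with those full SDs overlap so heavily
#'   that no planted partition is identifiable. The default 0.15 keeps the
#'   tabulated cluster means exactly while shrinking component spread so the
#'   closest pair of planted centroids sits roughly ten component SDs apart,
#'   the separable regime the clustering stage assumes (see the methods
#'   vignette).
#' @param trait_cor traits x traits correlation matrix shared across clusters
#'   (per-cluster covariance is `diag(sd) %*% cor %*% diag(sd)`).
#' @param disease_models named list (one per disease) of
#'   `list(intercept=, coef=)` logistic models over standardized traits.
#' @param snp_panel data.frame of causal SNPs (see [default_snp_panel()]).
#' @param null_maf_range range the per-SNP MAF of cluster-independent null
#'   SNPs is drawn from.
#' @param spectrum_peaks peak model data.frame (see [default_spectrum_peaks()]).
#' @param ppm_range,ppm_step chemical-shift axis of generated spectra (ppm).
#' @param peak_shape "gaussian" (default) or "lorentzian" line shape.
#' @param amplitude_cv per-subject coefficient of variation of peak amplitudes.
#' @param baseline_amplitude amplitude (intensity units) of the smooth
#'   non-negative synthetic baseline added to each spectrum.
#' @param noise_sd standard deviation of additive white spectral noise.
#' @param missing_rate fraction of phenotype trait cells set missing.
#' @param geno_missing_rate fraction of genotype cells set missing.
#' @param age_mean,age_sd age distribution (years, normal, truncated 20-90).
#' @param seed integer seed; together with the config it fully determines all
#'   generated data.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 2000L,
                             n_clusters = 4L,
                             cluster_weights = c(4405, 4496, 4401, 3490) / 16792,
                             trait_means = NULL,
                             trait_sds = NULL,
                             trait_sd_scale = 0.15,
                             trait_cor = NULL,
                             disease_models = default_disease_models(),
                             snp_panel = default_snp_panel(),
                             null_maf_range = c(0.05, 0.5),
                             spectrum_peaks = default_spectrum_peaks(),
                             ppm_range = c(0.5, 5.5),
                             ppm_step = 0.002,
                             peak_shape = c("gaussian", "lorentzian"),
                             amplitude_cv = 0.10,
                             baseline_amplitude = 2,
                             noise_sd = 0.05,
                             missing_rate = 0.02,
                             geno_missing_rate = 0.01,
                             age_mean = 48.3,
                             age_sd = 11.0,
                             seed = 20200305L) {
  panel <- default_trait_panel()
  trait_means <- trait_means %||% panel$means
  trait_sds <- trait_sds %||% (panel$sds * trait_sd_scale)
  trait_cor <- trait_cor %||% panel$cor
  peak_shape <- match.arg(peak_shape)
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects), n_clusters = as.integer(n_clusters),
    cluster_weights = cluster_weights, trait_means = trait_means,
    trait_sds = trait_sds, trait_cor = trait_cor,
    disease_models = disease_models, snp_panel = snp_panel,
    null_maf_range = null_maf_range, spectrum_peaks = spectrum_peaks,
    ppm_range = ppm_range, ppm_step = ppm_step, peak_shape = peak_shape,
    amplitude_cv = amplitude_cv, baseline_amplitude = baseline_amplitude,
    noise_sd = noise_sd, missing_rate = missing_rate,
    geno_missing_rate = geno_missing_rate,
    age_mean = age_mean, age_sd = age_sd, seed = as.integer(seed)),
    class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config> n=%d, %d clusters, %d traits, %d causal SNP(s), seed %d\n",
              x$n_subjects, x$n_clusters, ncol(x$trait_means),
              nrow(x$snp_panel), x$seed))
  invisible(x)
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_subjects < 1L) stop("n_subjects must be positive", call. = FALSE)
  if (cfg$n_clusters < 1L) stop("n_clusters must be positive", call. = FALSE)
  if (length(cfg$cluster_weights) != cfg$n_clusters)
    stop("cluster_weights length must equal n_clusters", call. = FALSE)
  if (abs(sum(cfg$cluster_weights) - 1) > 1e-12)
    stop("cluster_weights must sum to 1 (within 1e-12)", call. = FALSE)
  if (any(cfg$cluster_weights < 0))
    stop("cluster_weights must be non-negative", call. = FALSE)
  if (nrow(cfg$trait_means) != cfg$n_clusters ||
      !identical(dim(cfg$trait_means), dim(cfg$trait_sds)))
    stop("trait_means/trait_sds must be n_clusters x traits matrices",
         call. = FALSE)
  if (any(cfg$trait_sds < 0)) stop("trait SDs must be >= 0", call. = FALSE)
  R <- cfg$trait_cor
  if (!isSymmetric(unname(R)))
    stop("trait correlation matrix must be symmetric", call. = FALSE)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf(
      "trait block '%s': correlation matrix is not positive semi-definite",
      paste(colnames(cfg$trait_means), collapse = ",")), call. = FALSE)
  for (i in seq_len(nrow(cfg$snp_panel))) {
    maf <- cfg$snp_panel$maf[[i]]
    if (any(maf <= 0) || any(maf > 0.5))
      stop(sprintf("SNP %s: MAFs must lie in (0, 0.5]",
                   cfg$snp_panel$snp_id[i]), call. = FALSE)
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  if (any(cfg$spectrum_peaks$center < min(cfg$ppm_range)) ||
      any(cfg$spectrum_peaks$center > max(cfg$ppm_range)))
    stop("spectrum peak center outside the ppm axis", call. = FALSE)
  invisible(cfg)
}

new_cohort_table <- function(df, traits, diseases = character(), stage = "raw") {
  structure(df, traits = traits, diseases = diseases, qc_stage = stage,
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d subjects, %d traits, stage '%s'\n",
              nrow(x), length(attr(x, "traits")), attr(x, "qc_stage")))
  if (length(attr(x, "diseases")))
    cat("  diseases:", paste(attr(x, "diseases"), collapse = ", "), "\n")
  invisible(x)
}

cohort_traits <- function(cohort) attr(cohort, "traits")
cohort_diseases <- function(cohort) attr(cohort, "diseases")
cohort_stage <- function(cohort) attr(cohort, "qc_stage") %||% "raw"

#' Extract the trait matrix of a cohort table
#'
#' @param cohort a `cohort_table`.
#' @return numeric matrix (subjects x traits) with subject IDs as rownames.
#' @export
trait_matrix <- function(cohort) {
  m <- as.matrix(as.data.frame(cohort)[, cohort_traits(cohort), drop = FALSE])
  rownames(m) <- cohort$subject_id
  m
}

#' Generate phenotypes for a synthetic cohort
#'
#' Draws cluster membership from the configured weights, then each subject's
#' quantitative traits from that cluster's multivariate normal
#' (`diag(sd) %*% cor %*% diag(sd)` covariance), ages from a truncated normal
#' and sex from {1, 2} with equal probability. Trait cells are then set
#' missing uniformly at random at `missing_rate`. Fully deterministic given
#' the config (including its seed).
#'
#' @param config a [synthetic_config()].
#' @return A `cohort_table` (stage "raw") with columns `subject_id`, `age`,
#'   `sex`, one column per trait, and `cluster_truth`.
#' @export
generate_phenotypes <- function(config) {
  validate_synthetic_config(config)
  n <- config$n_subjects
  traits <- colnames(config$trait_means)
  with_seed_(config$seed, {
    cl <- sample.int(config$n_clusters, n, replace = TRUE,
                     prob = config$cluster_weights)
    age <- pmin(pmax(rnorm(n, config$age_mean, config$age_sd), 20), 90)
    sex <- sample(c(1L, 2L), n, replace = TRUE)
    X <- matrix(NA_real_, n, length(traits), dimnames = list(NULL, traits))
    for (k in seq_len(config$n_clusters)) {
      idx <- which(cl == k)
      if (!length(idx)) next
      Sigma <- diag(config$trait_sds[k, ]) %*% config$trait_cor %*%
        diag(config$trait_sds[k, ])
      X[idx, ] <- MASS::mvrnorm(length(idx), mu = config$trait_means[k, ],
                                Sigma = Sigma)
    }
    if (config$missing_rate > 0) {
      miss <- which(runif(length(X)) < config$missing_rate)
      X[miss] <- NA_real_
    }
    df <- data.frame(subject_id = sprintf("S%06d", seq_len(n)),
                     age = age, sex = sex, X, cluster_truth = cl,
                     stringsAsFactors = FALSE, check.names = FALSE)
    new_cohort_table(df, traits)
  })
}

#' Assign disease status from logistic risk models
#'
#' For each disease, computes a linear predictor
#' `intercept + sum(coef * standardized trait)` (traits standardized by their
#' full-sample mean/SD, missing trait values contributing 0) and draws a
#' Bernoulli flag from its logistic transform. Deterministic given `seed`.
#'
#' @param cohort a `cohort_table` with trait columns.
#' @param disease_models named list of `list(intercept=, coef=)` models.
#' @param seed integer seed.
#' @return The cohort with one logical column per disease appended.
#' @export
generate_disease_status <- function(cohort,
                                    disease_models = default_disease_models(),
                                    seed = 20200306L) {
  traits <- cohort_traits(cohort)
  Z <- trait_matrix(cohort)
  Z <- scale(Z)
  Z[is.na(Z)] <- 0
  df <- as.data.frame(cohort)
  with_seed_(seed, {
    for (dz in names(disease_models)) {
      mod <- disease_models[[dz]]
      unknown <- setdiff(names(mod$coef), traits)
      if (length(unknown))
        stop(sprintf("disease model '%s' names unknown trait(s): %s",
                     dz, paste(unknown, collapse = ", ")), call. = FALSE)
      eta <- mod$intercept + as.vector(Z[, names(mod$coef), drop = FALSE] %*%
                                         mod$coef)
      df[[dz]] <- runif(nrow(df)) < stats::plogis(eta)
    }
  })
  new_cohort_table(df, traits, diseases = names(disease_models),
                   stage = cohort_stage(cohort))
}

new_genotype_matrix <- function(dosage, annotations) {
  structure(list(subjects = rownames(dosage), snp_ids = colnames(dosage),
                 dosage = dosage, annotations = annotations),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d subjects x %d SNPs (%.2f%% missing)\n",
              length(x$subjects), length(x$snp_ids),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

validate_genotype_matrix <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  vals <- g$dosage[!is.na(g$dosage)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("dosage values must be 0, 1, 2 or missing", call. = FALSE)
  if (nrow(g$dosage) != length(g$subjects) ||
      ncol(g$dosage) != length(g$snp_ids))
    stop("dosage dimensions inconsistent with ID lists", call. = FALSE)
  invisible(g)
}

#' Generate allele dosages for a synthetic cohort
#'
#' Causal SNPs are drawn Binomial(2, MAF of the subject's true cluster); null
#' SNPs are drawn at a per-SNP common MAF sampled from `null_maf_range`,
#' independent of cluster. Monomorphic realizations of null SNPs are redrawn
#' (deterministically, given the seed) so no all-zero column is emitted.
#' Missing genotypes are injected at `missing_rate`.
#'
#' @param cohort a `cohort_table` carrying `cluster_truth`.
#' @param snp_panel causal-SNP data.frame (see [default_snp_panel()]).
#' @param n_null_snps number of cluster-independent null SNPs to add.
#' @param null_maf_range MAF range for null SNPs.
#' @param missing_rate fraction of dosage cells set missing.
#' @param seed integer seed.
#' @return A `genotype_matrix`.
#' @export
generate_genotypes <- function(cohort, snp_panel = default_snp_panel(),
                               n_null_snps = 0L,
                               null_maf_range = c(0.05, 0.5),
                               missing_rate = 0, seed = 20200307L) {
  if (is.null(cohort$cluster_truth))
    stop("cohort must carry cluster_truth to generate genotypes", call. = FALSE)
  n <- nrow(cohort)
  cl <- cohort$cluster_truth
  n_causal <- nrow(snp_panel)
  with_seed_(seed, {
    cols <- vector("list", n_causal + n_null_snps)
    ann <- data.frame(snp_id = character(0), chrom = character(0),
                      pos = integer(0), gene = character(0),
                      stringsAsFactors = FALSE)
    for (i in seq_len(n_causal)) {
      maf <- snp_panel$maf[[i]]
      if (length(maf) == 1L) maf <- rep(maf, max(cl))
      if (length(maf) < max(cl))
        stop(sprintf("SNP %s: need one MAF per cluster", snp_panel$snp_id[i]),
             call. = FALSE)
      if (any(maf <= 0))
        stop(sprintf("SNP %s: MAF 0 would produce a monomorphic column",
                     snp_panel$snp_id[i]), call. = FALSE)
      cols[[i]] <- rbinom(n, 2L, maf[cl])
      ann <- rbind(ann, data.frame(snp_id = snp_panel$snp_id[i],
                                   chrom = as.character(snp_panel$chrom[i]),
                                   pos = snp_panel$pos[i],
                                   gene = snp_panel$gene[i],
                                   stringsAsFactors = FALSE))
    }
    for (j in seq_len(n_null_snps)) {
      maf <- runif(1, null_maf_range[1], null_maf_range[2])
      x <- rbinom(n, 2L, maf)
      tries <- 0L
      while (length(unique(x)) < 2L && tries < 100L) {  # monomorphic guard
        x <- rbinom(n, 2L, maf)
        tries <- tries + 1L
      }
      cols[[n_causal + j]] <- x
      ann <- rbind(ann, data.frame(snp_id = sprintf("null%05d", j),
                                   chrom = as.character(1L + (j %% 22L)),
                                   pos = 1000L * j, gene = "",
                                   stringsAsFactors = FALSE))
    }
    dosage <- do.call(cbind, cols)
    dimnames(dosage) <- list(cohort$subject_id, ann$snp_id)
    if (missing_rate > 0) {
      miss <- which(runif(length(dosage)) < missing_rate)
      dosage[miss] <- NA_integer_
    }
    new_genotype_matrix(dosage, ann)
  })
}

new_spectrum_set <- function(ppm, intensity, meta) {
  stopifnot(length(ppm) == ncol(intensity), nrow(meta) == nrow(intensity))
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0)))
    stop("ppm axis must be strictly monotone", call. = FALSE)
  if (any(!is.finite(intensity)))
    stop("spectral intensities must be finite", call. = FALSE)
  structure(list(ppm = ppm, intensity = intensity, meta = meta),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d points, %.3f-%.3f ppm\n",
              nrow(x$intensity), length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

peak_shape_profile <- function(ppm, center, width, shape = "gaussian") {
  if (shape == "gaussian") exp(-(ppm - center)^2 / (2 * width^2))
  else width^2 / ((ppm - center)^2 + width^2)
}

#' Generate 1D NMR-like spectra for a synthetic cohort
#'
#' Each spectrum is a sum of Gaussian (or Lorentzian) peaks whose amplitudes
#' are the subject's cluster mean perturbed by subject-level noise
#' (`amplitude_cv`), plus a smooth non-negative baseline and additive white
#' noise. The lipoprotein-methyl (~0.86 ppm), leucine (~0.95 ppm) and GlycA
#' (~2.04 ppm) amplitudes are lower in the low-prevalence cluster under the
#' default peak model. Deterministic given the config seed.
#'
#' @param cohort a `cohort_table` carrying `cluster_truth` (and optionally
#'   disease flags / allele counts to be carried into `meta`).
#' @param config a [synthetic_config()] supplying the peak model, axis,
#'   baseline and noise; or `NULL` for defaults.
#' @param allele_counts optional per-subject integer vector (0/1/2) stored in
#'   `meta$rs651821_C_count` for allele-dosage association runs.
#' @param seed integer seed (defaults to the config seed).
#' @return A `spectrum_set` with attributes `baseline` (the common true
#'   baseline vector) and `true_amplitudes` (subjects x peaks matrix).
#' @export
generate_spectra <- function(cohort, config = synthetic_config(),
                             allele_counts = NULL, seed = NULL) {
  if (is.null(cohort$cluster_truth))
    stop("cohort must carry cluster_truth to generate spectra", call. = FALSE)
  seed <- seed %||% child_seed(config$seed, 3L)
  ppm <- seq(config$ppm_range[1], config$ppm_range[2], by = config$ppm_step)
  if (min(ppm) > 0.5 || max(ppm) < 4.5)
    stop("ppm axis must cover at least 0.5-4.5 ppm", call. = FALSE)
  peaks <- config$spectrum_peaks
  if (any(peaks$center < min(ppm)) || any(peaks$center > max(ppm)))
    stop("spectrum peak center outside the ppm axis", call. = FALSE)
  n <- nrow(cohort)
  cl <- cohort$cluster_truth
  amp_cols <- paste0("amp", seq_len(max(cl)))
  P <- t(vapply(seq_len(nrow(peaks)), function(i)
    peak_shape_profile(ppm, peaks$center[i], peaks$width[i], config$peak_shape),
    numeric(length(ppm))))
  # smooth raised-cosine baseline, non-negative by construction
  baseline <- config$baseline_amplitude *
    (0.5 + 0.5 * cos(pi * (ppm - min(ppm)) / diff(range(ppm))))
  ampmat <- as.matrix(peaks[, amp_cols, drop = FALSE])  # peaks x clusters
  with_seed_(seed, {
    A <- do.call(rbind, lapply(seq_len(n), function(s) {
      mu <- ampmat[, cl[s]]
      pmax(mu + rnorm(nrow(peaks), 0, config$amplitude_cv * mu), 0)
    }))
    intensity <- A %*% P +
      matrix(baseline, n, length(ppm), byrow = TRUE) +
      matrix(rnorm(n * length(ppm), 0, config$noise_sd), n)
    rownames(intensity) <- cohort$subject_id
    meta <- data.frame(subject_id = cohort$subject_id, age = cohort$age,
                       sex = cohort$sex, cluster_label = cl,
                       stringsAsFactors = FALSE)
    if (!is.null(allele_counts)) meta$rs651821_C_count <- allele_counts
    s <- new_spectrum_set(ppm, intensity, meta)
    attr(s, "baseline") <- baseline
    attr(s, "true_amplitudes") <- A
    s
  })
}
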